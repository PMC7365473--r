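#' Screened Coulomb energy of two point charges
#'
#' Debye-Hueckel pair energy `q1*q2*(lB/r)*exp(-r/lDH)` in units of kBT,
#' with charges in units of e and the Bjerrum length `lB` derived from the
#' parameters. Vectorized over `r`.
#'
#' @param q1,q2 Charges in units of e.
#' @param r_nm Separation(s) in nm, strictly positive.
#' @param params An [electro_params()] object.
#' @return Energy in kBT.
#' @examples
#' p <- electro_params(screening_length_nm = Inf)
#' screened_pair_energy(2, 2, bjerrum_length(), p) # 4 kBT
#' @export
screened_pair_energy <- function(q1, q2, r_nm, params = electro_params()) {
  if (any(r_nm <= 0)) abort("r_nm must be > 0 (point-charge singularity)")
  kappa <- if (is.finite(params$screening_length_nm))
    1 / params$screening_length_nm else 0
  q1 * q2 * params$bjerrum_nm / r_nm * exp(-kappa * r_nm)
}

as_point_set <- function(x) {
  if (!all(c("x_nm", "z_nm", "charge") %in% names(x)))
    abort("point set needs columns x_nm, z_nm, charge")
  x
}

#' Total interaction energy between two charge point sets
#'
#' Double sum of [screened_pair_energy()] over all cross-chain pairs, with
#' pairs beyond `params$cutoff_nm` contributing zero. With the default
#' cutoff of 12 screening lengths the result differs from the literal sum
#' by far less than 1e-3 kBT on rod-sized chains; `cutoff_nm = Inf`
#' reproduces the exact double sum.
#'
#' @param a,b Point sets: tibbles with columns `x_nm`, `z_nm`, `charge`
#'   (e.g. from [place_straight_pair()] or [bent_rod_coordinates()]).
#' @param params An [electro_params()] object.
#' @return Energy in kBT.
#' @export
chain_interaction_energy <- function(a, b, params = electro_params()) {
  a <- as_point_set(a); b <- as_point_set(b)
  cpp_pair_energy(a$x_nm, a$z_nm, a$charge, b$x_nm, b$z_nm, b$charge,
                  params$bjerrum_nm, params$screening_length_nm,
                  params$cutoff_nm)
}

#' Place two straight rods at a given stagger
#'
#' Rod `a` lies on the z axis (site i at `z = i * spacing`, `x = 0`); rod
#' `b` lies on a parallel line at the lateral separation. For parallel
#' orientation b's site j sits at `z = stagger + j * spacing` (both
#' C-termini pointing up); for antiparallel orientation b is reversed so
#' its C-terminal tip sits at `z = stagger` and the maximum overlap of
#' equal-length rods is `rod_length - stagger`. Negative staggers are
#' rejected for antiparallel rods (the positive tips would not be in
#' contact, an extremely unfavorable regime).
#'
#' @param chain_a,chain_b Charge chains (a is the fixed rod, b the shifted
#'   one).
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param stagger_nm Axial stagger s in nm, `>= 0`.
#' @param params An [electro_params()] object (supplies the lateral
#'   separation).
#' @return A list of class `rod_pair` with point-set tibbles `a` and `b`
#'   (columns `x_nm`, `z_nm`, `charge`), plus `orientation`, `stagger_nm`
#'   and `overlap_max_nm`.
#' @export
place_straight_pair <- function(chain_a, chain_b,
                                orientation = c("parallel", "antiparallel"),
                                stagger_nm, params = electro_params()) {
  orientation <- match.arg(orientation)
  chain_a <- validate_charge_chain(chain_a)
  chain_b <- validate_charge_chain(chain_b)
  if (stagger_nm < 0)
    abort("negative staggers are not considered (tips out of contact)")
  la <- rod_length(chain_a); lb <- rod_length(chain_b)
  d <- params$lateral_sep_nm
  a <- tibble(x_nm = 0, z_nm = chain_a$position_nm, charge = chain_a$charge)
  zb <- if (orientation == "parallel") stagger_nm + chain_b$position_nm
        else stagger_nm + lb - chain_b$position_nm
  b <- tibble(x_nm = d, z_nm = zb, charge = chain_b$charge)
  structure(list(a = a, b = b, orientation = orientation,
                 stagger_nm = stagger_nm,
                 overlap_max_nm = min(la - stagger_nm, lb)),
            class = "rod_pair")
}

#' Electrostatic energy of straight rod pairs over a range of staggers
#'
#' Scans the stagger of two straight rods and records the total screened
#' Coulomb energy at each value. The default step is one lattice site
#' (0.1456 nm), the natural resolution of the charge chain.
#'
#' @inheritParams place_straight_pair
#' @param s_min,s_max Stagger range in nm.
#' @param s_step Stagger step in nm (default one lattice site).
#' @return A `stagger_scan` tibble with columns `stagger_nm`, `energy_kbt`
#'   and attributes `orientation` and `labels`.
#' @export
stagger_scan <- function(chain_a, chain_b,
                         orientation = c("parallel", "antiparallel"),
                         s_min = 0, s_max = NULL, s_step = rod_spacing_nm,
                         params = electro_params()) {
  orientation <- match.arg(orientation)
  chain_a <- validate_charge_chain(chain_a)
  chain_b <- validate_charge_chain(chain_b)
  if (s_step <= 0) abort("s_step must be positive")
  s_max <- s_max %||% rod_length(chain_a)
  if (s_max < s_min) abort("empty stagger range")
  staggers <- seq(s_min, s_max, by = s_step)
  energies <- vapply(staggers, function(s) {
    pair <- place_straight_pair(chain_a, chain_b, orientation, s, params)
    chain_interaction_energy(pair$a, pair$b, params)
  }, numeric(1))
  structure(tibble(stagger_nm = staggers, energy_kbt = energies),
            orientation = orientation,
            labels = c(attr(chain_a, "label") %||% "a",
                       attr(chain_b, "label") %||% "b"),
            class = c("stagger_scan", class(tibble())))
}

moving_average <- function(x, window) {
  if (window <= 1) return(x)
  k <- rep(1 / window, window)
  as.numeric(stats::filter(x, k, sides = 2))
}

#' Local minima of a stagger scan
#'
#' Finds staggers whose (optionally smoothed) energy is strictly lower than
#' both neighbours. Smoothing is a centered moving average; the default is
#' none.
#'
#' @param scan A `stagger_scan` (or any tibble with `stagger_nm` and
#'   `energy_kbt`).
#' @param smooth_window Moving-average window in grid points (default 1 =
#'   no smoothing).
#' @return A tibble of the minima, ordered by stagger.
#' @export
scan_minima <- function(scan, smooth_window = 1) {
  e <- moving_average(scan$energy_kbt, smooth_window)
  n <- length(e)
  if (n < 3) return(scan[0, ])
  ok <- !is.na(e)
  idx <- which(c(FALSE, e[2:(n - 1)] < e[1:(n - 2)] &
                   e[2:(n - 1)] < e[3:n], FALSE) & ok)
  scan[idx, ]
}

#' Local maxima of a profile (peaks)
#' @inheritParams scan_minima
#' @param value Column to use (default the last numeric column).
#' @return A tibble of strict local maxima.
#' @export
profile_peaks <- function(scan, value = NULL, smooth_window = 1) {
  value <- value %||% rev(names(scan)[vapply(scan, is.numeric, logical(1))])[1]
  e <- moving_average(scan[[value]], smooth_window)
  n <- length(e)
  if (n < 3) return(scan[0, ])
  ok <- !is.na(e)
  idx <- which(c(FALSE, e[2:(n - 1)] > e[1:(n - 2)] &
                   e[2:(n - 1)] > e[3:n], FALSE) & ok)
  scan[idx, ]
}

#' Electrostatic potential field around a rod
#'
#' Superposition of the Debye-Hueckel point potential of every site charge,
#' evaluated at radial distance(s) `r_nm` from the rod axis over axial
#' samples `z_nm`. Potentials are reported in kBT per unit charge e.
#'
#' @param chain A charge chain (on the z axis).
#' @param r_nm Radial distance(s), strictly positive.
#' @param z_nm Axial sample positions in nm.
#' @param params An [electro_params()] object.
#' @return A `potential_field` tibble with columns `r_nm`, `z_nm`,
#'   `phi_kbt_e`.
#' @export
potential_field <- function(chain, r_nm, z_nm, params = electro_params()) {
  chain <- validate_charge_chain(chain)
  if (any(r_nm <= 0)) abort("r_nm must be > 0")
  grid <- tidyr::expand_grid(r_nm = r_nm, z_nm = z_nm)
  kappa <- if (is.finite(params$screening_length_nm))
    1 / params$screening_length_nm else 0
  phi <- purrr::map2_dbl(grid$r_nm, grid$z_nm, function(r, z) {
    d <- sqrt(r^2 + (z - chain$position_nm)^2)
    sum(chain$charge * params$bjerrum_nm * exp(-kappa * d) / d)
  })
  structure(dplyr::mutate(grid, phi_kbt_e = phi),
            label = attr(chain, "label"),
            class = c("potential_field", class(tibble())))
}
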