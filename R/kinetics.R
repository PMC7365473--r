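#' Mean first-passage time to detachment in an overlap potential
#'
#' Treats the rolling/zipping of two attached rods as overdamped diffusion
#' of the overlap coordinate `x = L_o` in the potential `V(x)` (in kBT),
#' with a reflecting boundary at full overlap `x = L_max` and an absorbing
#' boundary at detachment `x = 0`. The mean first-passage time from `x0` is
#' the nested integral
#' `T1(x0) = (1/D) * int_0^x0 exp(V(z)) [ int_z^Lmax exp(-V(y)) dy ] dz`,
#' evaluated by the trapezoidal rule on a fine grid with the potential
#' interpolated linearly between its tabulated points. For a flat potential
#' this reproduces the closed form `(2 L x0 - x0^2) / (2 D)` essentially
#' exactly.
#'
#' @param potential An overlap potential: a data frame with columns `lo_nm`
#'   and `energy_kbt` (e.g. from [overlap_potential()] or
#'   [test_potential()]).
#' @param x0_nm Starting overlap in nm (default 3.6, an initial contact of
#'   25 residues).
#' @param d_nm2 Diffusion constant `D` of the overlap coordinate. Only the
#'   product `D * T1` is meaningful; with the default `D = 1` the return
#'   value is `D * T1` in nm^2.
#' @param grid_step_nm Quadrature step in nm (default 0.05).
#' @return `T1` (so `D * T1` equals `mean_first_passage_time(...) * d_nm2`).
#' @examples
#' flat <- test_potential("flat", l_max_nm = 100)
#' mean_first_passage_time(flat) # (2*100*3.6 - 3.6^2)/2 = 353.52
#' @export
mean_first_passage_time <- function(potential, x0_nm = 3.6, d_nm2 = 1,
                                    grid_step_nm = 0.05) {
  if (!all(c("lo_nm", "energy_kbt") %in% names(potential)))
    abort("potential needs columns lo_nm and energy_kbt")
  if (any(!is.finite(potential$energy_kbt)))
    abort("potential must be finite everywhere")
  if (d_nm2 <= 0) abort("d_nm2 must be positive")
  a <- max(potential$lo_nm)
  if (x0_nm < 0 || x0_nm > a + 1e-9)
    abort(sprintf("x0_nm must lie in [0, %.4f]", a))
  if (x0_nm == 0) return(0)
  if (max(abs(potential$energy_kbt)) > 500)
    abort("potential exceeds 500 kBT; exp() would overflow")
  g <- sort(unique(pmin(c(seq(0, a, by = grid_step_nm), a, x0_nm), a)))
  v <- approx(potential$lo_nm, potential$energy_kbt, xout = g,
              rule = 2)$y
  w <- exp(-v)
  n <- length(g)
  dg <- diff(g)
  seg <- dg * (w[-n] + w[-1]) / 2
  inner <- rev(c(0, cumsum(rev(seg))))   # inner[i] = int_{g_i}^{a} exp(-V)
  outer_i <- g <= x0_nm + 1e-12
  go <- g[outer_i]
  f <- exp(v[outer_i]) * inner[outer_i]
  sum(diff(go) * (f[-length(f)] + f[-1]) / 2) / d_nm2
}

#' Contact-time profile of an ordered rod pair over staggers
#'
#' For each stagger the overlap potential is taken from the bent-rod energy
#' landscape and fed to [mean_first_passage_time()]; the profile of
#' `D * T1` versus stagger shows which staggers keep two rods engaged the
#' longest. The first chain is the straight rod, the second the shifted and
#' bendable one. Staggers whose maximum overlap is below the initial
#' contact `x0` admit no contact under the model and are dropped (with a
#' message), not reported as zero.
#'
#' @inheritParams energy_landscape
#' @param x0_nm Initial contact in nm (default 3.6).
#' @param d_nm2 Diffusion constant (default 1; the profile reports `D*T1`).
#' @param grid_step_nm Quadrature step for the passage-time integral.
#' @param landscape Optionally, a precomputed [energy_landscape()] for this
#'   pair and orientation (skips recomputation).
#' @return A `contact_time_profile` tibble with columns `stagger_nm`,
#'   `overlap_max_nm`, `dt1_nm2` and attributes `orientation`,
#'   `straight_label`, `bent_label`, `x0_nm`.
#' @export
contact_time_profile <- function(chain_a, chain_b,
                                 orientation = c("parallel", "antiparallel"),
                                 staggers_nm, lo_step_sites = 7,
                                 params = electro_params(),
                                 wlc = wlc_params(),
                                 x0_nm = 3.6, d_nm2 = 1,
                                 grid_step_nm = 0.05, landscape = NULL) {
  orientation <- match.arg(orientation)
  landscape <- landscape %||%
    energy_landscape(chain_a, chain_b, orientation, staggers_nm,
                     lo_step_sites, params, wlc)
  ss <- unique(landscape$stagger_nm)
  rows <- purrr::map_dfr(ss, function(s) {
    v <- overlap_potential(landscape, s)
    l_max <- attr(v, "overlap_max_nm")
    if (l_max < x0_nm) return(NULL)
    t1 <- mean_first_passage_time(v, x0_nm, d_nm2 = 1, grid_step_nm)
    tibble(stagger_nm = s, overlap_max_nm = l_max, dt1_nm2 = t1)
  })
  if (nrow(rows) == 0)
    abort("no admissible stagger: all maximum overlaps are below x0")
  if (length(ss) > nrow(rows))
    inform(sprintf(
      "%d stagger(s) dropped: maximum overlap below the initial contact x0",
      length(ss) - nrow(rows)))
  structure(rows, orientation = orientation,
            straight_label = attr(landscape, "labels")[1],
            bent_label = attr(landscape, "labels")[2],
            x0_nm = x0_nm, d_nm2 = d_nm2, landscape = landscape,
            class = c("contact_time_profile", class(tibble())))
}

#' Contact-time profiles for every ordered pair of rods
#'
#' Computes [contact_time_profile()] for each ordered pair drawn from a
#' named list of charge chains (the first element of a pair is the straight
#' rod, the second the shifted and bent one; the diagonal holds the
#' homo-dimers) and summarizes the global peak of each profile.
#'
#' @param chains Named list of charge chains (length >= 1).
#' @inheritParams contact_time_profile
#' @return A `contact_time_matrix` tibble with one row per ordered pair:
#'   `straight`, `bent`, `orientation`, `peak_stagger_nm`, `peak_dt1_nm2`,
#'   `mean_dt1_nm2` and a list-column `profile`.
#' @export
contact_time_matrix <- function(chains,
                                orientation = c("parallel", "antiparallel"),
                                staggers_nm, lo_step_sites = 7,
                                params = electro_params(),
                                wlc = wlc_params(),
                                x0_nm = 3.6, d_nm2 = 1,
                                grid_step_nm = 0.05) {
  orientation <- match.arg(orientation)
  if (!length(chains)) abort("need at least one chain")
  if (is.null(names(chains)) || any(!nzchar(names(chains))))
    names(chains) <- vapply(seq_along(chains), function(i)
      attr(chains[[i]], "label") %||% paste0("rod", i), character(1))
  pairs <- tidyr::expand_grid(straight = names(chains),
                              bent = names(chains))
  out <- purrr::pmap_dfr(pairs, function(straight, bent) {
    prof <- contact_time_profile(chains[[straight]], chains[[bent]],
                                 orientation, staggers_nm, lo_step_sites,
                                 params, wlc, x0_nm, d_nm2, grid_step_nm)
    i <- which.max(prof$dt1_nm2)
    tibble(straight = straight, bent = bent, orientation = orientation,
           peak_stagger_nm = prof$stagger_nm[i],
           peak_dt1_nm2 = prof$dt1_nm2[i],
           mean_dt1_nm2 = mean(prof$dt1_nm2),
           profile = list(prof))
  })
  structure(out, class = c("contact_time_matrix", class(tibble())))
}
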