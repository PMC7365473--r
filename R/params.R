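# Physical constants (SI)
.const <- list(
  e  = 1.602176634e-19,   # elementary charge, C
  kB = 1.380649e-23,      # Boltzmann constant, J/K
  eps0 = 8.8541878128e-12, # vacuum permittivity, F/m
  avogadro = 6.02214076e23
)

#' Bjerrum length
#'
#' Distance at which two elementary charges in a dielectric interact with
#' thermal energy `kB*T`: `lB = e^2 / (4 pi eps eps0 kB T)`. About 0.7 nm in
#' water at room temperature.
#'
#' @param dielectric Relative dielectric constant (default 80, water).
#' @param temperature Temperature in K (default 298, so that
#'   `kB*T = 0.593` kcal/mol).
#' @return Bjerrum length in nm.
#' @examples
#' bjerrum_length() # ~0.70 nm
#' @export
bjerrum_length <- function(dielectric = 80, temperature = 298) {
  with(.const, e^2 / (4 * pi * dielectric * eps0 * kB * temperature)) * 1e9
}

#' Debye screening length from ionic strength
#'
#' Screening length of a symmetric monovalent electrolyte,
#' `lDH^2 = eps eps0 kB T / (2 e^2 n0)` with `n0` the number density of
#' ions. Exposed for exploration; the package default is the commonly
#' quoted physiological value of 1.3 nm rather than the value this formula
#' returns at 100 mM (about 0.96 nm).
#'
#' @param concentration_molar Salt concentration in mol/L.
#' @inheritParams bjerrum_length
#' @return Screening length in nm.
#' @export
debye_length <- function(concentration_molar, dielectric = 80,
                         temperature = 298) {
  n0 <- concentration_molar * 1e3 * .const$avogadro # ions per m^3
  with(.const,
       sqrt(dielectric * eps0 * kB * temperature / (2 * e^2 * n0))) * 1e9
}

#' Electrostatic model parameters
#'
#' Bundles the Debye-Hueckel parameters used throughout: dielectric constant,
#' screening length, temperature, the lateral axis-to-axis separation of two
#' touching rods, and an optional pairwise distance cutoff.
#'
#' @param dielectric Relative dielectric constant of the solvent (default 80).
#' @param screening_length_nm Debye-Hueckel screening length in nm (default
#'   1.3, physiological salt). Use `Inf` for unscreened Coulomb.
#' @param temperature_k Temperature in K (default 298).
#' @param lateral_sep_nm Axis-to-axis distance of two touching rods in nm
#'   (default 2, i.e. twice the 1 nm rod radius).
#' @param cutoff_nm Pairwise interaction cutoff in nm; pairs farther apart
#'   contribute zero. Defaults to `12 * screening_length_nm`, which agrees
#'   with the uncut sum to well below 1e-3 kBT on rod-sized chains; set to
#'   `Inf` (or `NULL`) for the literal double sum.
#' @return An object of class `electro_params` (a named list with the above
#'   plus the derived Bjerrum length `bjerrum_nm`).
#' @examples
#' electro_params()
#' electro_params(cutoff_nm = Inf)
#' @export
electro_params <- function(dielectric = 80, screening_length_nm = 1.3,
                           temperature_k = 298, lateral_sep_nm = 2,
                           cutoff_nm = NULL) {
  if (dielectric <= 0 || temperature_k <= 0)
    abort("dielectric and temperature must be positive")
  if (screening_length_nm <= 0)
    abort("screening_length_nm must be positive (use Inf for no screening)")
  if (lateral_sep_nm <= 0) abort("lateral_sep_nm must be positive")
  cutoff_nm <- cutoff_nm %||%
    (if (is.finite(screening_length_nm)) 12 * screening_length_nm else Inf)
  if (cutoff_nm <= 0) abort("cutoff_nm must be positive (use Inf for none)")
  structure(list(
    dielectric = dielectric,
    screening_length_nm = screening_length_nm,
    temperature_k = temperature_k,
    lateral_sep_nm = lateral_sep_nm,
    cutoff_nm = cutoff_nm,
    bjerrum_nm = bjerrum_length(dielectric, temperature_k)
  ), class = "electro_params")
}

#' Worm-like-chain bending parameters
#'
#' Parameters of the circular-arc bending model for the mobile rod: the
#' persistence length and the grid of candidate arc radii and arc lengths
#' searched when minimizing total energy at fixed stagger and overlap.
#'
#' @param persistence_nm Persistence length of the rod in nm (default 130).
#' @param radius_range_nm Range of candidate arc radii in nm (default
#'   `c(75, 300)`).
#' @param arc_range_nm Range of candidate arc lengths in nm (default
#'   `c(15, 40)`).
#' @param radius_steps,arc_steps Number of grid points along each range
#'   (defaults 16 and 11, i.e. 15 nm and 2.5 nm steps).
#' @param include_straight Also consider the unbent rod where it is
#'   geometrically admissible, i.e. at full overlap (default `TRUE`).
#' @return An object of class `wlc_params`.
#' @export
wlc_params <- function(persistence_nm = 130,
                       radius_range_nm = c(75, 300),
                       arc_range_nm = c(15, 40),
                       radius_steps = 16, arc_steps = 11,
                       include_straight = TRUE) {
  stopifnot(length(radius_range_nm) == 2, length(arc_range_nm) == 2)
  if (any(radius_range_nm <= 0) || diff(radius_range_nm) < 0)
    abort("radius_range_nm must be positive and ordered")
  if (any(arc_range_nm < 0) || diff(arc_range_nm) < 0)
    abort("arc_range_nm must be non-negative and ordered")
  if (radius_steps < 2 || arc_steps < 2) abort("need at least 2 grid steps")
  if (persistence_nm <= 0) abort("persistence_nm must be positive")
  structure(list(
    persistence_nm = persistence_nm,
    radius_range_nm = radius_range_nm,
    arc_range_nm = arc_range_nm,
    radius_steps = radius_steps,
    arc_steps = arc_steps,
    include_straight = isTRUE(include_straight),
    radius_grid = seq(radius_range_nm[1], radius_range_nm[2],
                      length.out = radius_steps),
    arc_grid = seq(arc_range_nm[1], arc_range_nm[2], length.out = arc_steps)
  ), class = "wlc_params")
}

#' @export
print.electro_params <- function(x, ...) {
  cat("<electro_params>\n")
  cat(sprintf("  dielectric: %g   screening length: %g nm   T: %g K\n",
              x$dielectric, x$screening_length_nm, x$temperature_k))
  cat(sprintf("  lateral separation: %g nm   cutoff: %g nm   Bjerrum: %.4f nm\n",
              x$lateral_sep_nm, x$cutoff_nm, x$bjerrum_nm))
  invisible(x)
}

#' @export
print.wlc_params <- function(x, ...) {
  cat("<wlc_params>\n")
  cat(sprintf("  persistence: %g nm\n", x$persistence_nm))
  cat(sprintf("  radius grid: [%g, %g] nm, %d steps\n",
              x$radius_range_nm[1], x$radius_range_nm[2], x$radius_steps))
  cat(sprintf("  arc grid: [%g, %g] nm, %d steps; straight candidate: %s\n",
              x$arc_range_nm[1], x$arc_range_nm[2], x$arc_steps,
              x$include_straight))
  invisible(x)
}

#' Rod surface charge density
#'
#' Net charge per residue of a charge chain spread over the surface of a
#' cylinder of given radius: `|sum(q)| / n_sites / (spacing * 2 pi r)`.
#' For an NM2-like rod (net ~0.085 e per residue) this is about 0.09 e/nm^2,
#' which places the electrostatics in the weak-coupling (linearizable)
#' regime.
#'
#' @param chain A [charge chain][build_charge_chain].
#' @param radius_nm Rod cylinder radius in nm (default 1).
#' @return A list with `net_charge_e`, `charge_per_residue_e` and
#'   `sigma_e_nm2`.
#' @export
surface_charge_density <- function(chain, radius_nm = 1) {
  chain <- validate_charge_chain(chain)
  spacing <- attr(chain, "spacing")
  net <- sum(chain$charge)
  per_res <- abs(net) / nrow(chain)
  list(net_charge_e = net,
       charge_per_residue_e = per_res,
       sigma_e_nm2 = per_res / (spacing * 2 * pi * radius_nm))
}
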