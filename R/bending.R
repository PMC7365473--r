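#' Worm-like-chain bending energy of a circular arc
#'
#' `E = lp * La / (2 R^2)` in kBT for an arc of radius `R` and length `La`
#' on a chain with persistence length `lp`. The straight rod (infinite
#' radius or zero arc) costs nothing.
#'
#' @param radius_nm Arc radius in nm (`Inf` for straight), `> 0`.
#' @param arc_nm Arc length in nm, `>= 0`.
#' @param persistence_nm Persistence length in nm (default 130).
#' @return Energy in kBT.
#' @examples
#' bending_energy(130, 20) # ~0.0769 kBT
#' @export
bending_energy <- function(radius_nm, arc_nm, persistence_nm = 130) {
  if (any(radius_nm <= 0)) abort("radius_nm must be > 0")
  if (any(arc_nm < 0)) abort("arc_nm must be >= 0")
  ifelse(is.finite(radius_nm), persistence_nm * arc_nm / (2 * radius_nm^2), 0)
}

# Orientation-dependent frame of the mobile (shifted, bendable) rod b:
# position of its C-terminal tip on the z axis, the direction dz in which
# contour distance from the tip advances, and the straight overhang of b
# beyond the partner's extent (parallel rods only).
mobile_rod_frame <- function(chain_b, orientation, stagger_nm,
                             partner_length_nm) {
  lb <- rod_length(chain_b)
  if (orientation == "parallel") {
    tip_z <- stagger_nm + lb
    anchor_z <- min(partner_length_nm, tip_z)
    list(tip_z = tip_z, dz = -1, overhang = tip_z - anchor_z, length = lb)
  } else {
    list(tip_z = stagger_nm, dz = +1, overhang = 0, length = lb)
  }
}

# Planar path of the mobile rod: straight from the C-tip over contour c0,
# then a tangent-continuous arc of radius R and length La curving away from
# the partner (x increasing), then a straight tangent continuation.
# `contour` are distances from the C-tip; returns x (lateral) and zeta
# (signed axial advance from the tip, to be mapped as z = tip_z + dz*zeta).
bent_path_local <- function(contour, c0, radius_nm, arc_nm) {
  x <- numeric(length(contour))
  zeta <- contour
  if (arc_nm > 0 && is.finite(radius_nm)) {
    tau <- contour - c0
    on_arc <- tau > 0 & tau <= arc_nm
    beyond <- tau > arc_nm
    phi <- tau[on_arc] / radius_nm
    x[on_arc] <- radius_nm * (1 - cos(phi))
    zeta[on_arc] <- c0 + radius_nm * sin(phi)
    phi_m <- arc_nm / radius_nm
    tail_len <- tau[beyond] - arc_nm
    x[beyond] <- radius_nm * (1 - cos(phi_m)) + tail_len * sin(phi_m)
    zeta[beyond] <- c0 + radius_nm * sin(phi_m) + tail_len * cos(phi_m)
  }
  list(x = x, zeta = zeta)
}

#' Coordinates of the bent mobile rod
#'
#' The shifted rod stays straight (alongside its partner) for an overlap
#' length `overlap_nm` measured from the anchored C-terminal side, then
#' bends along a tangent-continuous circular arc of radius `radius_nm` and
#' length `arc_nm` curving away from the partner, and continues straight
#' along the final tangent. Contour length is preserved exactly; an arc
#' longer than the remaining contour is clamped with a warning.
#'
#' @param chain_b The mobile charge chain.
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param stagger_nm Stagger s in nm.
#' @param overlap_nm Overlap `L_o` in nm, at most the maximum overlap.
#' @param radius_nm Arc radius (`Inf` for a straight rod).
#' @param arc_nm Arc length in nm.
#' @param params An [electro_params()] object (lateral separation).
#' @param partner_length_nm Length of the straight partner rod in nm.
#' @return A point-set tibble (`x_nm`, `z_nm`, `charge`) in the same site
#'   order as `chain_b`.
#' @export
bent_rod_coordinates <- function(chain_b, orientation, stagger_nm, overlap_nm,
                                 radius_nm, arc_nm,
                                 params = electro_params(),
                                 partner_length_nm) {
  orientation <- match.arg(orientation, c("parallel", "antiparallel"))
  chain_b <- validate_charge_chain(chain_b)
  fr <- mobile_rod_frame(chain_b, orientation, stagger_nm, partner_length_nm)
  l_max <- min(partner_length_nm - stagger_nm, fr$length)
  if (overlap_nm < 0 || overlap_nm > l_max + 1e-9)
    abort(sprintf("overlap_nm must be in [0, %.4f] at this stagger", l_max))
  c0 <- fr$overhang + overlap_nm
  arc_eff <- arc_nm
  if (is.finite(radius_nm) && c0 + arc_nm > fr$length + 1e-9) {
    arc_eff <- max(fr$length - c0, 0)
    warn(sprintf("arc length clamped from %.3f to %.3f nm (remaining contour)",
                 arc_nm, arc_eff))
  }
  contour <- fr$length - chain_b$position_nm # distance from the C-tip
  if (!is.finite(radius_nm)) arc_eff <- 0
  p <- bent_path_local(contour, c0, radius_nm, arc_eff)
  tibble(x_nm = params$lateral_sep_nm + p$x,
         z_nm = fr$tip_z + fr$dz * p$zeta,
         charge = chain_b$charge)
}

bend_candidates <- function(wlc) {
  tidyr::expand_grid(radius_nm = wlc$radius_grid, arc_nm = wlc$arc_grid)
}

# least-bending tie-break: among candidates within tol of the minimum total
# energy prefer larger radius, then shorter (effective) arc
pick_min_bend <- function(cand, tol = 1e-9) {
  best <- min(cand$e_total_kbt)
  near <- cand[cand$e_total_kbt <= best + tol, ]
  near <- near[order(-near$radius_nm, near$arc_eff_nm), ]
  near[1, ]
}

#' Minimize total energy over the bend grid at fixed stagger and overlap
#'
#' Evaluates the total energy (full-chain screened Coulomb sum over both
#' rods, bent-away charges included, plus the worm-like-chain arc energy)
#' for every candidate `(R, La)` on the grid and returns the minimal
#' configuration. Arcs are clamped to the remaining contour where
#' necessary. The unbent rod is admissible only at full overlap (a straight
#' rod realizes `L_o = L_max` by construction) and is included there when
#' `wlc$include_straight` is set. Ties are broken toward the least bending
#' (larger radius, then shorter arc).
#'
#' @param chain_a The fixed straight chain.
#' @param chain_b The mobile chain.
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param stagger_nm,overlap_nm The cell, in nm (`overlap_nm <= L_max`).
#' @param params An [electro_params()] object.
#' @param wlc A [wlc_params()] object.
#' @return A one-row tibble: `stagger_nm`, `lo_nm`, `radius_nm`, `arc_nm`
#'   (effective, after clamping), `e_bend_kbt`, `e_elec_kbt`,
#'   `e_total_kbt`, `straight`.
#' @export
optimize_bend <- function(chain_a, chain_b,
                          orientation = c("parallel", "antiparallel"),
                          stagger_nm, overlap_nm,
                          params = electro_params(), wlc = wlc_params()) {
  orientation <- match.arg(orientation)
  chain_a <- validate_charge_chain(chain_a)
  chain_b <- validate_charge_chain(chain_b)
  la_nm <- rod_length(chain_a)
  fr <- mobile_rod_frame(chain_b, orientation, stagger_nm, la_nm)
  l_max <- min(la_nm - stagger_nm, fr$length)
  a_pts <- tibble(x_nm = 0, z_nm = chain_a$position_nm,
                  charge = chain_a$charge)
  cand <- bend_candidates(wlc)
  if (nrow(cand) == 0) abort("empty bend grid")
  c0 <- fr$overhang + overlap_nm
  cand$arc_eff_nm <- pmin(cand$arc_nm, pmax(fr$length - c0, 0))
  at_top <- overlap_nm >= l_max - 1e-9
  if (wlc$include_straight && at_top)
    cand <- dplyr::bind_rows(cand, tibble(radius_nm = Inf, arc_nm = 0,
                                          arc_eff_nm = 0))
  cand$e_elec_kbt <- purrr::pmap_dbl(
    cand[c("radius_nm", "arc_eff_nm")],
    function(radius_nm, arc_eff_nm) {
      b_pts <- suppressWarnings(bent_rod_coordinates(
        chain_b, orientation, stagger_nm, overlap_nm,
        radius_nm, arc_eff_nm, params, la_nm))
      chain_interaction_energy(a_pts, b_pts, params)
    })
  cand$e_bend_kbt <- bending_energy(cand$radius_nm, cand$arc_eff_nm,
                                    wlc$persistence_nm)
  cand$e_total_kbt <- cand$e_elec_kbt + cand$e_bend_kbt
  best <- pick_min_bend(cand)
  tibble(stagger_nm = stagger_nm, lo_nm = overlap_nm,
         radius_nm = best$radius_nm, arc_nm = best$arc_eff_nm,
         e_bend_kbt = best$e_bend_kbt, e_elec_kbt = best$e_elec_kbt,
         e_total_kbt = best$e_total_kbt,
         straight = best$arc_eff_nm == 0)
}

snap_to_lattice <- function(x, spacing = rod_spacing_nm) {
  round(x / spacing) * spacing
}

#' Stagger/overlap energy landscape of a rod pair
#'
#' For every stagger and every accessible overlap the total energy is
#' minimized over the bend grid (see [optimize_bend()]); cells with
#' `L_o > L_max(s)` are kept as masked (inaccessible) rows. Staggers and
#' the overlap step are snapped to the 0.1456 nm charge lattice, which lets
#' the straight-rod part of every cell be reused across the bend grid; the
#' per-stagger column always contains the exact `L_o = L_max` cell.
#'
#' @inheritParams optimize_bend
#' @param staggers_nm Staggers to evaluate, in nm.
#' @param lo_step_sites Overlap step in lattice sites (default 7, about
#'   1.02 nm).
#' @return An `energy_landscape` tibble with columns `stagger_nm`, `lo_nm`,
#'   `accessible`, `radius_nm`, `arc_nm`, `e_bend_kbt`, `e_elec_kbt`,
#'   `e_total_kbt`, `straight`.
#' @export
energy_landscape <- function(chain_a, chain_b,
                             orientation = c("parallel", "antiparallel"),
                             staggers_nm, lo_step_sites = 7,
                             params = electro_params(), wlc = wlc_params()) {
  orientation <- match.arg(orientation)
  chain_a <- validate_charge_chain(chain_a)
  chain_b <- validate_charge_chain(chain_b)
  if (length(staggers_nm) == 0) abort("empty stagger grid")
  spacing <- attr(chain_b, "spacing") %||% rod_spacing_nm
  staggers_nm <- sort(unique(snap_to_lattice(staggers_nm, spacing)))
  if (any(staggers_nm < 0))
    abort("negative staggers are not considered")
  la_nm <- rod_length(chain_a)
  lb_nm <- rod_length(chain_b)
  lo_step <- lo_step_sites * spacing
  l_max_all <- pmin(la_nm - staggers_nm, lb_nm)
  if (all(l_max_all < 0)) abort("no stagger leaves the rods in contact")
  lo_global <- seq(0, max(l_max_all), by = lo_step)

  a_pts <- tibble(x_nm = 0, z_nm = chain_a$position_nm,
                  charge = chain_a$charge)
  tmpl <- bend_templates(chain_b, wlc, spacing)
  cells <- purrr::map(seq_along(staggers_nm), function(si) {
    s <- staggers_nm[si]
    l_max <- l_max_all[si]
    if (l_max < 0) return(NULL)
    lo_vals <- unique(c(lo_global[lo_global <= l_max + 1e-9],
                        snap_to_lattice(l_max, spacing)))
    done <- landscape_column(chain_a, chain_b, a_pts, orientation, s,
                             lo_vals, tmpl, params, wlc, spacing)
    masked <- lo_global[lo_global > l_max + 1e-9]
    if (length(masked))
      done <- dplyr::bind_rows(done, tibble(
        stagger_nm = s, lo_nm = masked, accessible = FALSE,
        radius_nm = NA_real_, arc_nm = NA_real_, e_bend_kbt = NA_real_,
        e_elec_kbt = NA_real_, e_total_kbt = NA_real_, straight = NA))
    done
  })
  out <- dplyr::bind_rows(cells)
  structure(out, orientation = orientation,
            labels = c(attr(chain_a, "label") %||% "a",
                       attr(chain_b, "label") %||% "b"),
            lo_step_nm = lo_step, params = params, wlc = wlc,
            class = c("energy_landscape", class(tibble())))
}

# Per-(R, La) templates of the bent path beyond the bend start, sampled at
# lattice-spaced contour offsets tau = spacing, 2*spacing, ...; shared by
# every (stagger, overlap) cell because the local path shape is
# c0-independent.
bend_templates <- function(chain_b, wlc, spacing) {
  n <- nrow(chain_b)
  tau <- spacing * seq_len(n)
  cand <- bend_candidates(wlc)
  shapes <- purrr::pmap(cand, function(radius_nm, arc_nm) {
    p <- bent_path_local(tau, 0, radius_nm, arc_nm)
    list(x = p$x, zeta = p$zeta)
  })
  list(cand = cand, tau = tau, shapes = shapes)
}

landscape_column <- function(chain_a, chain_b, a_pts, orientation, s,
                             lo_vals, tmpl, params, wlc, spacing) {
  la_nm <- rod_length(chain_a)
  fr <- mobile_rod_frame(chain_b, orientation, s, la_nm)
  l_max <- min(la_nm - s, fr$length)
  pair <- place_straight_pair(chain_a, chain_b, orientation, s, params)
  site_e <- cpp_site_energies(a_pts$x_nm, a_pts$z_nm, a_pts$charge,
                              pair$b$x_nm, pair$b$z_nm, pair$b$charge,
                              params$bjerrum_nm, params$screening_length_nm,
                              params$cutoff_nm)
  contour <- fr$length - chain_b$position_nm
  ord <- order(contour)                    # tip first
  e_sorted <- site_e[ord]
  q_sorted <- chain_b$charge[ord]
  cum_e <- c(0, cumsum(e_sorted))
  e_straight_full <- cum_e[length(cum_e)]
  n <- nrow(chain_b)
  d <- params$lateral_sep_nm
  lp <- wlc$persistence_nm
  cand <- tmpl$cand

  nc <- nrow(cand)
  purrr::map_dfr(lo_vals, function(lo) {
    c0 <- fr$overhang + lo
    m0 <- min(n, floor(c0 / spacing + 1e-6) + 1) # sites with contour <= c0
    e_straight_part <- cum_e[m0 + 1]
    n_tail <- n - m0
    tail_q <- if (n_tail > 0) q_sorted[(m0 + 1):n] else numeric(0)
    i <- seq_len(n_tail)
    rad <- c(cand$radius_nm, if (wlc$include_straight && lo >= l_max - 1e-9) Inf)
    arc_eff <- e_elec <- numeric(length(rad))
    for (k in seq_along(rad)) {
      arc_k <- if (k > nc) 0 else min(cand$arc_nm[k], max(fr$length - c0, 0))
      if (n_tail == 0 || arc_k <= 0) {
        arc_eff[k] <- 0
        e_elec[k] <- e_straight_full
        next
      }
      arc_eff[k] <- arc_k
      if (arc_k < cand$arc_nm[k]) {
        # clamped arc near full overlap: compute this tail directly
        p <- bent_path_local(tmpl$tau[i], 0, rad[k], arc_k)
        tx <- p$x; tz <- p$zeta
      } else {
        sh <- tmpl$shapes[[k]]
        tx <- sh$x[i]; tz <- sh$zeta[i]
      }
      e_elec[k] <- e_straight_part + cpp_pair_energy(
        a_pts$x_nm, a_pts$z_nm, a_pts$charge,
        d + tx, fr$tip_z + fr$dz * (c0 + tz), tail_q,
        params$bjerrum_nm, params$screening_length_nm, params$cutoff_nm)
    }
    e_bend <- bending_energy(rad, arc_eff, lp)
    best <- pick_min_bend(tibble(radius_nm = rad, arc_eff_nm = arc_eff,
                                 e_elec_kbt = e_elec, e_bend_kbt = e_bend,
                                 e_total_kbt = e_elec + e_bend))
    tibble(stagger_nm = s, lo_nm = lo, accessible = TRUE,
           radius_nm = best$radius_nm, arc_nm = best$arc_eff_nm,
           e_bend_kbt = best$e_bend_kbt, e_elec_kbt = best$e_elec_kbt,
           e_total_kbt = best$e_total_kbt,
           straight = best$arc_eff_nm == 0)
  })
}

#' Extract the overlap potential at a fixed stagger
#'
#' Returns the accessible landscape column at the requested stagger as the
#' one-dimensional potential `V(L_o)` (total energy in kBT) that feeds the
#' mean-first-passage-time calculation. If the stagger is not exactly on
#' the landscape grid the nearest column is used (with a message); staggers
#' outside the grid range are an error.
#'
#' @param landscape An [energy_landscape()] result.
#' @param stagger_nm Stagger in nm.
#' @return An `overlap_potential` tibble (`lo_nm`, `energy_kbt`) with
#'   attributes `stagger_nm` and `overlap_max_nm`.
#' @export
overlap_potential <- function(landscape, stagger_nm) {
  ss <- unique(landscape$stagger_nm)
  tol <- rod_spacing_nm / 2
  if (stagger_nm < min(ss) - tol || stagger_nm > max(ss) + tol)
    abort(sprintf("stagger %.3f nm is outside the landscape grid [%.3f, %.3f]",
                  stagger_nm, min(ss), max(ss)))
  s <- ss[which.min(abs(ss - stagger_nm))]
  if (abs(s - stagger_nm) > 1e-6)
    inform(sprintf("using nearest landscape stagger %.4f nm for %.4f nm",
                   s, stagger_nm))
  col <- landscape[landscape$stagger_nm == s & landscape$accessible, ]
  col <- col[order(col$lo_nm), ]
  structure(tibble(lo_nm = col$lo_nm, energy_kbt = col$e_total_kbt),
            stagger_nm = s, overlap_max_nm = max(col$lo_nm),
            orientation = attr(landscape, "orientation"),
            class = c("overlap_potential", class(tibble())))
}
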