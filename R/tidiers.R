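#' Tidy a stagger scan: its local energy minima
#'
#' @param x A `stagger_scan`.
#' @param smooth_window Moving-average window for the minima search.
#' @param ... Unused.
#' @return A tibble of local minima (`stagger_nm`, `energy_kbt`).
#' @export
tidy.stagger_scan <- function(x, smooth_window = 1, ...) {
  as_tibble(scan_minima(x, smooth_window))
}

#' @rdname tidy.stagger_scan
#' @export
glance.stagger_scan <- function(x, ...) {
  m <- scan_minima(x)
  tibble(orientation = attr(x, "orientation"),
         n_staggers = nrow(x),
         min_energy_kbt = min(x$energy_kbt),
         max_energy_kbt = max(x$energy_kbt),
         n_minima = nrow(m))
}

#' Tidy an energy landscape: the per-stagger optimum
#'
#' One row per stagger with the overlap, bend and energy of the most
#' favorable accessible cell.
#'
#' @param x An `energy_landscape`.
#' @param ... Unused.
#' @export
tidy.energy_landscape <- function(x, ...) {
  acc <- x[x$accessible, ]
  acc |>
    dplyr::group_by(.data$stagger_nm) |>
    dplyr::slice_min(.data$e_total_kbt, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    as_tibble()
}

#' @rdname tidy.energy_landscape
#' @export
glance.energy_landscape <- function(x, ...) {
  acc <- x[x$accessible, ]
  i <- which.min(acc$e_total_kbt)
  tibble(orientation = attr(x, "orientation"),
         n_staggers = length(unique(x$stagger_nm)),
         n_cells = nrow(acc),
         min_energy_kbt = acc$e_total_kbt[i],
         min_at_stagger_nm = acc$stagger_nm[i],
         min_at_lo_nm = acc$lo_nm[i])
}

#' Tidy a contact-time profile: its peaks
#'
#' @param x A `contact_time_profile`.
#' @param smooth_window Moving-average window for the peak search.
#' @param ... Unused.
#' @export
tidy.contact_time_profile <- function(x, smooth_window = 1, ...) {
  as_tibble(profile_peaks(x, value = "dt1_nm2",
                          smooth_window = smooth_window))
}

#' @rdname tidy.contact_time_profile
#' @export
glance.contact_time_profile <- function(x, ...) {
  i <- which.max(x$dt1_nm2)
  tibble(orientation = attr(x, "orientation"),
         straight = attr(x, "straight_label"),
         bent = attr(x, "bent_label"),
         n_staggers = nrow(x),
         peak_stagger_nm = x$stagger_nm[i],
         peak_dt1_nm2 = x$dt1_nm2[i],
         mean_dt1_nm2 = mean(x$dt1_nm2))
}
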