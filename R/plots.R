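#' Plot the windowed charge profile of a rod
#'
#' @param object A `charge_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.charge_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$center_nm, .data$net_charge_e)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position along rod (nm)",
                  y = sprintf("net charge in %d-residue window (e)",
                              attr(object, "window") %||% NA),
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Plot a straight-rod stagger scan with its local minima
#'
#' @param object A `stagger_scan`.
#' @param smooth_window Window for the minima overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stagger_scan <- function(object, smooth_window = 1, ...) {
  m <- scan_minima(object, smooth_window)
  ggplot2::ggplot(object, ggplot2::aes(.data$stagger_nm, .data$energy_kbt)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = m, colour = "red", size = 1.5) +
    ggplot2::labs(x = "stagger s (nm)", y = "energy (kBT)",
                  title = paste(attr(object, "labels"), collapse = " / "),
                  subtitle = attr(object, "orientation")) +
    ggplot2::theme_minimal()
}

#' Heat map of a stagger/overlap energy landscape
#'
#' Inaccessible cells (overlap above the per-stagger maximum) are masked.
#'
#' @param object An `energy_landscape`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_landscape <- function(object, ...) {
  acc <- object[object$accessible, ]
  ggplot2::ggplot(acc, ggplot2::aes(.data$stagger_nm, .data$lo_nm,
                                    fill = .data$e_total_kbt)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", midpoint = 0,
                                  name = "E (kBT)") +
    ggplot2::labs(x = "stagger s (nm)", y = "overlap Lo (nm)",
                  title = paste(attr(object, "labels"), collapse = " / "),
                  subtitle = attr(object, "orientation")) +
    ggplot2::theme_minimal()
}

#' Plot an overlap potential V(Lo)
#'
#' @param object An `overlap_potential`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.overlap_potential <- function(object, ...) {
  s <- attr(object, "stagger_nm")
  ggplot2::ggplot(object, ggplot2::aes(.data$lo_nm, .data$energy_kbt)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "overlap Lo (nm)", y = "V (kBT)",
                  title = if (is.finite(s %||% NA_real_))
                    sprintf("stagger s = %.1f nm", s) else NULL) +
    ggplot2::theme_minimal()
}

#' Plot a contact-time profile (log scale)
#'
#' @param object A `contact_time_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.contact_time_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$stagger_nm, .data$dt1_nm2)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "stagger s (nm)",
                  y = expression(D %.% T[1] ~ (nm^2)),
                  title = sprintf("%s (straight) / %s (bent)",
                                  attr(object, "straight_label"),
                                  attr(object, "bent_label")),
                  subtitle = attr(object, "orientation")) +
    ggplot2::theme_minimal()
}
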