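## Base-graphics views of the main result types.

#' Plot a vibrational spectrum
#'
#' Histogram of non-rigid wavenumbers with the cumulative fraction of modes
#' `G(omega)` overlaid on a secondary axis.
#'
#' @param modeset A `mode_set`.
#' @param n_bins Histogram bins.
#' @param ... Passed to [graphics::hist()].
#' @return Invisibly, the [spectrum_and_powerfit()] result.
#' @export
plot_spectrum <- function(modeset, n_bins = 30, ...) {
  sp <- spectrum_and_powerfit(modeset, n_bins)
  graphics::hist(sp$cumulative$omega, breaks = n_bins,
                 xlab = expression(omega ~ (cm^-1)),
                 main = "vibrational spectrum", ...)
  graphics::par(new = TRUE)
  graphics::plot(sp$cumulative$omega, sp$cumulative$G, type = "l",
                 col = "red3", axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "red3")
  graphics::mtext(expression(G(omega)), side = 4, line = 2, col = "red3")
  invisible(sp)
}

#' Plot predicted against experimental B-factors
#'
#' @param profile A `fluct_profile`.
#' @param experimental_b Experimental B-factors (A^2).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the Pearson correlation.
#' @export
plot_bfactors <- function(profile, experimental_b, ...) {
  stopifnot(inherits(profile, "fluct_profile"))
  i <- seq_along(profile$bfactor)
  graphics::plot(i, experimental_b, type = "l", xlab = "node",
                 ylab = expression(B ~ (ring(A)^2)), ...)
  sc <- sum(profile$bfactor * experimental_b) / sum(profile$bfactor^2)
  graphics::lines(i, profile$bfactor * sc, col = "red3")
  graphics::legend("topright", c("experimental", "predicted (scaled)"),
                   col = c("black", "red3"), lty = 1, bty = "n")
  invisible(stats::cor(profile$bfactor, experimental_b))
}

#' Plot per-mode overlaps of a conformational change
#'
#' @param report An `overlap_report`.
#' @param n_modes Number of lowest modes to show (default 50).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `report`.
#' @export
plot_overlap <- function(report, n_modes = 50, ...) {
  stopifnot(inherits(report, "overlap_report"))
  per <- utils::head(report$per_mode, n_modes)
  graphics::plot(per$mode, abs(per$overlap), type = "h", ylim = c(0, 1),
                 xlab = "mode (non-rigid index)", ylab = "|overlap|", ...)
  graphics::lines(per$mode, sqrt(per$cumulative), col = "red3")
  graphics::abline(h = sqrt(0.90), lty = 2, col = "grey50")
  invisible(report)
}
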