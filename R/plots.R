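#' Plot a vibrogram waveform
#'
#' Glottal width against time; invalid stretches are left blank and, when
#' an [onset_report()] is supplied, the adduction criterion, oscillation
#' onset and steady-state landmarks are marked with arrows.
#'
#' @param x a [vibrogram()].
#' @param report optional [onset_report()] whose landmarks to annotate.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vibrogram <- function(x, report = NULL, ...) {
  w <- x$width_px
  w[!x$valid] <- NA
  graphics::plot(x$time_s * 1000, w, type = "l",
                 xlab = "time (ms)", ylab = "glottal width (px)", ...)
  if (!is.null(report)) {
    fps <- attr(x, "fps")
    mark <- function(frame, col, lab) {
      if (is.na(frame)) return(invisible())
      t_ms <- frame / fps * 1000
      graphics::arrows(t_ms, max(w, na.rm = TRUE) * 0.95, t_ms,
                       max(w, na.rm = TRUE) * 0.75, length = 0.08, col = col)
      graphics::text(t_ms, max(w, na.rm = TRUE), lab, col = col, cex = 0.7)
    }
    mark(report$adduction_criterion_frame, "blue", "1/3 width")
    mark(report$oscillation_onset_frame, "darkgreen", "onset")
    mark(report$steady_state_frame, "red", "steady")
  }
  invisible(x)
}

#' Plot a vibrogram power spectrum
#'
#' Power in dB re the maximum bin against frequency.
#'
#' @param x a [compute_spectrum()] result.
#' @param fmax upper frequency limit (Hz) for the plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vibrogram_spectrum <- function(x, fmax = 1500, ...) {
  keep <- x$freq_hz <= fmax
  db <- 10 * log10(x$power[keep] / max(x$power[keep]))
  graphics::plot(x$freq_hz[keep], db, type = "l",
                 xlab = "frequency (Hz)", ylab = "power (dB re max)", ...)
  invisible(x)
}

#' Display a kymogram as an image
#'
#' Time runs down the vertical axis (one row per frame), medial-lateral
#' position across the horizontal axis.
#'
#' @param x a [kymogram()].
#' @param max_rows draw at most this many rows (downsampled evenly).
#' @param ... passed to [graphics::image()].
#' @export
plot.kymogram <- function(x, max_rows = 2000, ...) {
  m <- x$rows
  if (nrow(m) > max_rows)
    m <- m[round(seq(1, nrow(m), length.out = max_rows)), ]
  graphics::image(t(m)[, nrow(m):1], col = grDevices::grey.colors(256, 0, 1),
                  axes = FALSE, ...)
  invisible(x)
}
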