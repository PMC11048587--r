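#' FFT power spectrum of a vibrogram segment
#'
#' The width series over the chosen segment is mean-detrended, windowed
#' (Hann by default) and zero-padded to the next power of two; the
#' one-sided power spectrum is returned in px^2 units, scaled so that with
#' no zero padding the bin powers sum to the windowed-signal energy
#' (Parseval-consistent).
#'
#' @param vib a [vibrogram()].
#' @param segment 0-based inclusive frame range `c(from, to)`; default the
#'   longest run of valid frames.
#' @param window `"hann"` (default) or `"rect"`.
#' @param nominal_f0_hz optional expected fundamental; when given, the
#'   segment must cover at least 4 of its cycles.
#' @param pad logical; zero-pad to the next power of two (default TRUE).
#' @return an object of class `vibrogram_spectrum`: `freq_hz`, `power`
#'   (px^2), `window`, `segment`, `nfft`, `fps`.
#' @export
compute_spectrum <- function(vib, segment = NULL, window = c("hann", "rect"),
                             nominal_f0_hz = NULL, pad = TRUE) {
  stopifnot(inherits(vib, "vibrogram"))
  window <- match.arg(window)
  fps <- attr(vib, "fps")
  if (is.null(segment)) {
    runs <- true_runs(vib$valid)
    j <- which.max(runs$end - runs$start)
    segment <- c(vib$frame[runs$start[j]], vib$frame[runs$end[j]])
  }
  idx <- which(vib$frame >= segment[1] & vib$frame <= segment[2])
  if (length(idx) == 0L) stop("empty segment", call. = FALSE)
  if (any(!vib$valid[idx]))
    stop("segment contains invalid frames; apply fill_gaps() first or ",
         "choose a valid segment", call. = FALSE)
  x <- vib$width_px[idx]
  n <- length(x)
  if (!is.null(nominal_f0_hz) && n < 4 * fps / nominal_f0_hz)
    stop("segment shorter than 4 cycles of the nominal fundamental",
         call. = FALSE)
  if (n < 8L) stop("segment too short for spectral analysis", call. = FALSE)

  x <- x - mean(x)
  w <- if (window == "hann")
    0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1))) else rep(1, n)
  xw <- x * w
  nfft <- if (pad) 2^ceiling(log2(n)) else n
  xp <- c(xw, rep(0, nfft - n))
  X <- stats::fft(xp)
  p_all <- Mod(X)^2 / nfft
  half <- floor(nfft / 2)
  power <- p_all[1:(half + 1)]
  if (half >= 2) power[2:half] <- 2 * power[2:half]
  if (nfft %% 2 == 1) power[half + 1] <- 2 * power[half + 1]
  structure(list(freq_hz = (0:half) * fps / nfft, power = power,
                 window = window, segment = segment, n_signal = n,
                 nfft = nfft, fps = fps),
            class = "vibrogram_spectrum")
}

#' @export
print.vibrogram_spectrum <- function(x, ...) {
  cat(sprintf(
    "<vibrogram_spectrum> %d bins to %g Hz (df = %.3g Hz), %s window, frames %d-%d\n",
    length(x$freq_hz), max(x$freq_hz), x$fps / x$nfft, x$window,
    x$segment[1], x$segment[2]))
  invisible(x)
}

#' Estimate the oscillation fundamental frequency
#'
#' Primary estimate: `fps / mean(period_frames)` over the detected cycles.
#' The mean is used rather than the median because cycle boundaries are
#' quantised to whole frames: at, say, a true period of 8.4 frames the
#' individual periods alternate between 8 and 9 and the median snaps to
#' one of them (an error of up to half a frame, several Hz), while the
#' mean converges at `1/n_cycles` frame resolution. The estimate is
#' cross-checked against the dominant spectral peak of the same vibrogram;
#' a discrepancy above 10% is flagged via the `"spectral_discrepancy"`
#' attribute and a warning.
#'
#' @param vib a [vibrogram()].
#' @param cycles optional cycle table (computed when `NULL`).
#' @param f0_range physiologic search range in Hz for the spectral
#'   cross-check.
#' @return estimated F0 in Hz, with attributes `f0_spectral_hz` and
#'   `spectral_discrepancy`.
#' @export
estimate_f0 <- function(vib, cycles = NULL, f0_range = c(50, 600)) {
  stopifnot(inherits(vib, "vibrogram"))
  cycles <- cycles %||% detect_cycles(vib)
  if (nrow(cycles) < 3L)
    stop("need at least 3 detected cycles to estimate F0", call. = FALSE)
  fps <- attr(vib, "fps")
  # early growth cycles have displaced valleys; use established cycles
  amp <- cycles$peak_to_peak_amplitude_px
  est_set <- cycles[amp >= 0.5 * max(amp), , drop = FALSE]
  if (nrow(est_set) < 3L) est_set <- cycles
  f0 <- fps / mean(est_set$period_frames)

  spec <- compute_spectrum(vib)
  in_range <- spec$freq_hz >= f0_range[1] & spec$freq_hz <= f0_range[2]
  f0_spec <- spec$freq_hz[in_range][which.max(spec$power[in_range])]
  disc <- abs(f0_spec - f0) / f0 > 0.10
  if (isTRUE(disc))
    warning(sprintf(
      "cycle-based F0 (%.1f Hz) and spectral peak (%.1f Hz) disagree by >10%%",
      f0, f0_spec), call. = FALSE)
  attr(f0, "f0_spectral_hz") <- f0_spec
  attr(f0, "spectral_discrepancy") <- isTRUE(disc)
  f0
}

#' Extract harmonic peak powers from a vibrogram spectrum
#'
#' Peak power at the fundamental and its first three harmonics: for
#' `k = 1..4` the maximum bin power within `search_bins` bins of
#' `k * f0` (the search window tolerates F0 drift across the segment).
#' Harmonics above Nyquist are reported absent (`NA`). Powers are given
#' linearly (px^2) and in dB re the fundamental; each peak carries its
#' half-power bandwidth.
#'
#' Indexing note: `p0` is the fundamental and `p1..p3` are the first three
#' harmonics above it (2, 3 and 4 times `f0`). The returned
#' `harmonic_hz` vector records the convention explicitly.
#'
#' @param spec a [compute_spectrum()] result.
#' @param f0 fundamental frequency in Hz (e.g. from [estimate_f0()]).
#' @param search_bins half-width of the peak search window, in bins.
#' @param f0_range admissible physiologic F0 range.
#' @return an object of class `harmonic_peaks`: `f0_hz`, `p0..p3`,
#'   `ratios` (`r1 = p1/p0`, `r2 = p2/p0`), `db_re_p0`,
#'   `half_power_bw_hz`, `harmonic_hz`.
#' @export
extract_harmonic_peaks <- function(spec, f0, search_bins = 2,
                                   f0_range = c(50, 600)) {
  stopifnot(inherits(spec, "vibrogram_spectrum"))
  if (f0 < f0_range[1] || f0 > f0_range[2])
    stop(sprintf("f0 = %.1f Hz outside the physiologic range [%g, %g]",
                 f0, f0_range[1], f0_range[2]), call. = FALSE)
  df <- spec$fps / spec$nfft
  if (f0 < 2 * df)
    stop("f0 must be at least 2 frequency bins above 0", call. = FALSE)
  nyq <- spec$fps / 2
  nb <- length(spec$power)

  peak_at <- function(f_target) {
    if (f_target > nyq) return(c(NA_real_, NA_real_, NA_real_))
    b <- round(f_target / df) + 1L
    lo <- max(2L, b - search_bins); hi <- min(nb, b + search_bins)
    j <- lo:hi
    pk <- j[which.max(spec$power[j])]
    c(spec$power[pk], spec$freq_hz[pk], half_power_bw(spec$power, pk, df))
  }
  res <- vapply(1:4, function(k) peak_at(k * f0), numeric(3))
  p <- res[1, ]
  structure(list(
    f0_hz = f0,
    p0 = p[1], p1 = p[2], p2 = p[3], p3 = p[4],
    peak_freq_hz = res[2, ],
    ratios = c(r1 = unname(p[2] / p[1]), r2 = unname(p[3] / p[1])),
    db_re_p0 = 10 * log10(p / p[1]),
    half_power_bw_hz = res[3, ],
    harmonic_hz = c(fundamental = f0, harmonic1 = 2 * f0,
                    harmonic2 = 3 * f0, harmonic3 = 4 * f0)
  ), class = "harmonic_peaks")
}

# half-power (-3 dB) bandwidth around peak bin `pk`, linear interpolation
half_power_bw <- function(power, pk, df) {
  half <- power[pk] / 2
  n <- length(power)
  i <- pk
  while (i > 1L && power[i] > half) i <- i - 1L
  lo <- if (power[i] > half) 1 else
    i + (half - power[i]) / (power[i + 1L] - power[i])
  i <- pk
  while (i < n && power[i] > half) i <- i + 1L
  hi <- if (power[i] > half) n else
    i - (half - power[i]) / (power[i - 1L] - power[i])
  (hi - lo) * df
}

#' @export
print.harmonic_peaks <- function(x, ...) {
  cat(sprintf("<harmonic_peaks> f0 = %.1f Hz\n", x$f0_hz))
  lab <- c("f0", "2f0", "3f0", "4f0")
  p <- c(x$p0, x$p1, x$p2, x$p3)
  for (i in 1:4)
    cat(sprintf("  %-4s %10.4g px^2  (%+.1f dB re f0)\n",
                lab[i], p[i], x$db_re_p0[i]))
  invisible(x)
}
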