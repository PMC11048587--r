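#' Detect glottal cycles in a vibrogram
#'
#' Cycles are delimited valley-to-valley on the 3-frame-median-smoothed
#' width series, each containing one width maximum. Alternating extrema
#' whose swing falls below `min_amplitude_px` are pruned (smallest swing
#' first), which suppresses noise ripples without shifting genuine
#' extrema. Cycles never span invalid frames: each maximal valid segment
#' is processed on its own.
#'
#' @param vib a [vibrogram()].
#' @param min_amplitude_px minimum peak-to-peak width excursion (px) for a
#'   cycle to count.
#' @return a data frame of class `cycle_table`: per cycle `start_frame`,
#'   `end_frame`, `peak_frame` (0-based), `period_frames`,
#'   `peak_to_peak_amplitude_px` (peak width minus the cycle's starting
#'   valley width) and `max_width_px`. Empty when no cycles are found (not
#'   an error).
#' @export
detect_cycles <- function(vib, min_amplitude_px = 0.5) {
  stopifnot(inherits(vib, "vibrogram"))
  segs <- true_runs(vib$valid)
  out <- list()
  for (k in seq_len(nrow(segs))) {
    idx <- segs$start[k]:segs$end[k]
    if (length(idx) < 5L) next
    w <- smooth_width(vib$width_px[idx])
    ext <- alternating_extrema(w, min_amplitude_px)
    if (is.null(ext) || length(ext$pos) < 3L) next
    types <- ext$type
    pos <- ext$pos
    # cycles: valley, peak, valley triplets
    vall <- which(types == "min")
    for (v in vall) {
      if (v + 2L > length(pos)) break
      if (types[v + 1L] != "max" || types[v + 2L] != "min") next
      i0 <- pos[v]; ip <- pos[v + 1L]; i1 <- pos[v + 2L]
      if (i1 >= length(w)) next   # end valley truncated by the segment edge
      amp <- w[ip] - w[i0]     # peak minus the cycle's starting valley
      if (amp < min_amplitude_px) next
      out[[length(out) + 1L]] <- data.frame(
        start_frame = vib$frame[idx[i0]],
        end_frame = vib$frame[idx[i1]],
        peak_frame = vib$frame[idx[ip]],
        period_frames = idx[i1] - idx[i0],
        peak_to_peak_amplitude_px = amp,
        max_width_px = max(vib$width_px[idx[i0:i1]]))
    }
  }
  tab <- if (length(out)) do.call(rbind, out) else
    data.frame(start_frame = integer(), end_frame = integer(),
               peak_frame = integer(), period_frames = integer(),
               peak_to_peak_amplitude_px = numeric(),
               max_width_px = numeric())
  class(tab) <- c("cycle_table", "data.frame")
  tab
}

smooth_width <- function(w, k = 3L) {
  if (length(w) < k) return(w)
  as.numeric(stats::runmed(w, k, endrule = "median"))
}

# alternating local extrema of w with all swings >= min_swing;
# smallest-swing pairs are pruned iteratively
alternating_extrema <- function(w, min_swing) {
  n <- length(w)
  if (n < 3L) return(NULL)
  d <- diff(w)
  # collapse plateaus: sign of change, carrying last non-zero sign
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(NULL)
  pos <- integer(0); type <- character(0)
  last_sign <- s[nz[1]]
  # leading endpoint as extremum
  pos <- nz[1]; type <- if (last_sign > 0) "min" else "max"
  for (i in nz[-1]) {
    if (s[i] != last_sign) {
      pos <- c(pos, i)
      type <- c(type, if (s[i] > 0) "min" else "max")
      last_sign <- s[i]
    }
  }
  pos <- c(pos, n)
  type <- c(type, if (last_sign > 0) "max" else "min")

  # prune smallest swings below threshold
  repeat {
    if (length(pos) < 2L) return(NULL)
    swings <- abs(diff(w[pos]))
    small <- which(swings < min_swing)
    if (length(small) == 0L) break
    j <- small[which.min(swings[small])]
    # removing the pair (j, j+1) merges neighbours of equal type
    keep <- setdiff(seq_along(pos), c(j, j + 1L))
    if (length(keep) == 0L) return(NULL)
    pos <- pos[keep]; type <- type[keep]
    # merge consecutive same-type extrema, keeping the more extreme one
    i <- 1L
    while (i < length(pos)) {
      if (type[i] == type[i + 1L]) {
        drop <- if (type[i] == "max") {
          if (w[pos[i]] >= w[pos[i + 1L]]) i + 1L else i
        } else {
          if (w[pos[i]] <= w[pos[i + 1L]]) i + 1L else i
        }
        pos <- pos[-drop]; type <- type[-drop]
      } else i <- i + 1L
    }
  }
  list(pos = pos, type = type)
}

# pre-gesture quiet segment: frames before the smoothed width first drops
# persistently below 90% of its initial median; 1-based index range
quiet_segment <- function(vib) {
  first_valid <- which(vib$valid)[1]
  w <- smooth_width(vib$width_px)
  n0 <- max(5L, round(0.01 * attr(vib, "fps")))      # first 10 ms
  m0 <- stats::median(w[first_valid:min(length(w), first_valid + n0 - 1L)])
  dropped <- which(w < 0.9 * m0 & vib$valid)
  q_end <- if (length(dropped)) max(first_valid, dropped[1] - 1L)
           else length(w)
  c(first_valid, q_end)
}

#' Detect the adduction criterion frame
#'
#' First frame at which the smoothed glottal width falls to one third of
#' its pre-gesture reference and stays there for at least `persist_ms`.
#' The reference defaults to the median width over the initial quiet
#' segment (the pre-gesture glottal gap); the one-third criterion is
#' interpreted on that gap width and the reference used is attached to the
#' result.
#'
#' @param vib a [vibrogram()].
#' @param reference_width_px reference width (px); default as above.
#' @param persist_ms minimum time the width must remain at or below the
#'   criterion.
#' @return 0-based frame index with attributes `reference_width_px` and
#'   `criterion_width_px`; `NA` when the criterion is never met.
#' @export
detect_adduction_criterion <- function(vib, reference_width_px = NULL,
                                       persist_ms = 5) {
  stopifnot(inherits(vib, "vibrogram"))
  fps <- attr(vib, "fps")
  w <- smooth_width(vib$width_px)
  if (is.null(reference_width_px)) {
    q <- quiet_segment(vib)
    reference_width_px <- stats::median(w[q[1]:q[2]])
  }
  if (!is.numeric(reference_width_px) || reference_width_px <= 0)
    stop("`reference_width_px` must be positive", call. = FALSE)
  crit <- reference_width_px / 3
  hold <- max(1L, ceiling(persist_ms / 1000 * fps))
  below <- w <= crit & vib$valid
  runs <- true_runs(below)
  runs <- runs[runs$end - runs$start + 1L >= hold |
               runs$end == length(w), , drop = FALSE]
  idx <- if (nrow(runs)) runs$start[1] else NA_integer_
  out <- if (is.na(idx)) NA_integer_ else vib$frame[idx]
  attr(out, "reference_width_px") <- reference_width_px
  attr(out, "criterion_width_px") <- crit
  out
}

#' Detect the just-noticeable oscillation onset
#'
#' The onset is anchored at the first detected cycle whose peak-to-peak
#' amplitude exceeds `k` times the noise floor (estimated as the SD of the
#' detrended width over the pre-adduction quiet segment), then refined
#' backwards from that cycle's peak: the slow adduction trend is removed
#' with a one-period running median, and the onset is placed at the last
#' pair of consecutive frames whose residual stays within the noise floor.
#' Raising `k` can only move the onset later (monotone in `k`).
#'
#' @param vib a [vibrogram()].
#' @param cycles a cycle table from [detect_cycles()]; computed when `NULL`.
#' @param noise_floor_sd noise floor (px); estimated from the quiet segment
#'   when `NULL`.
#' @param k amplitude threshold in noise-floor SDs (default 3).
#' @return 0-based frame index, or `NA` when no cycle qualifies.
#' @export
detect_oscillation_onset <- function(vib, cycles = NULL,
                                     noise_floor_sd = NULL, k = 3) {
  stopifnot(inherits(vib, "vibrogram"))
  cycles <- cycles %||% detect_cycles(vib)
  if (nrow(cycles) == 0L) return(NA_integer_)
  w <- smooth_width(vib$width_px)
  q <- quiet_segment(vib)
  if (is.null(noise_floor_sd)) {
    wq <- w[q[1]:q[2]]
    noise_floor_sd <- if (length(wq) >= 3L) stats::sd(wq) else 0
  }
  thr_amp <- k * noise_floor_sd
  qual <- which(cycles$peak_to_peak_amplitude_px > thr_amp)
  if (length(qual) == 0L) return(NA_integer_)
  c1 <- qual[1]

  # detrend with a one-period running median and walk back from the peak
  per <- stats::median(cycles$period_frames[qual])
  win <- odd_window(per)
  trend <- as.numeric(stats::runmed(w, win, endrule = "median"))
  resid <- w - trend
  sd_r <- stats::sd(resid[q[1]:q[2]])
  if (!is.finite(sd_r)) sd_r <- 0
  thr_r <- max(k * sd_r, 0.02 * cycles$peak_to_peak_amplitude_px[c1], 1e-9)

  pk <- which(vib$frame == cycles$peak_frame[c1])
  lo <- which(vib$frame == cycles$start_frame[c1])
  onset_idx <- lo                                    # fallback: cycle start
  i <- pk
  while (i > max(2L, q[1])) {
    if (abs(resid[i]) <= thr_r && abs(resid[i - 1L]) <= thr_r) {
      onset_idx <- i
      break
    }
    i <- i - 1L
  }
  vib$frame[onset_idx]
}

#' Detect steady-state oscillation
#'
#' Steady state begins at the first cycle of the earliest run of `m`
#' consecutive, contiguous cycles that is stable in both period and
#' amplitude: every period within `tol_fraction` of the run median (with a
#' one-frame floor, since cycle boundaries are quantised to frames), and
#' the total amplitude spread of the run within `tol_fraction` of the run
#' median amplitude. Measuring the amplitude spread (rather than each
#' cycle's deviation from the median) makes the rule sensitive to slow
#' monotone growth: a run drifting 2 x `tol_fraction` upward has every
#' member within `tol_fraction` of its median yet is clearly not steady.
#'
#' @param cycles a cycle table from [detect_cycles()].
#' @param tol_fraction relative tolerance on period and amplitude
#'   (default 0.10).
#' @param m run length defining stability (default 3 cycles).
#' @param from_frame only cycles starting at or after this 0-based frame
#'   are considered (typically the oscillation onset).
#' @return list with `steady_state_frame` (0-based, `NA` if never
#'   stabilises), `cycles_to_steady` (cycles from the first considered
#'   cycle up to, excluding, the steady one) and `reached_steady`.
#' @export
detect_steady_state <- function(cycles, tol_fraction = 0.10, m = 3,
                                from_frame = 0L) {
  stopifnot(inherits(cycles, "cycle_table"))
  cyc <- cycles[cycles$start_frame >= from_frame, , drop = FALSE]
  n <- nrow(cyc)
  if (n < m)
    return(list(steady_state_frame = NA_integer_,
                cycles_to_steady = NA_integer_, reached_steady = FALSE))
  for (i in seq_len(n - m + 1L)) {
    run <- cyc[i:(i + m - 1L), ]
    if (any(run$start_frame[-1] != run$end_frame[-m])) next  # not contiguous
    mp <- stats::median(run$period_frames)
    ma <- stats::median(run$peak_to_peak_amplitude_px)
    amp_spread <- max(run$peak_to_peak_amplitude_px) -
                  min(run$peak_to_peak_amplitude_px)
    if (all(abs(run$period_frames - mp) <= max(tol_fraction * mp, 1)) &&
        amp_spread <= tol_fraction * ma) {
      return(list(steady_state_frame = run$start_frame[1],
                  cycles_to_steady = i - 1L, reached_steady = TRUE))
    }
  }
  list(steady_state_frame = NA_integer_,
       cycles_to_steady = NA_integer_, reached_steady = FALSE)
}

#' Voice-onset report
#'
#' Composes the three landmark detectors on a vibrogram and derives the
#' timing measures: pre-phonation time (adduction criterion to oscillation
#' onset) and frames/cycles from oscillation onset to steady state. A
#' landmark is reported absent (`NA`) when untrackable (e.g. whiteout)
#' frames intervene between the previous landmark and it, since the
#' waveform cannot be followed across the obliterated view.
#'
#' @param vib a [vibrogram()].
#' @param min_amplitude_px passed to [detect_cycles()].
#' @param k oscillation-onset threshold in noise SDs.
#' @param steady_m,steady_tol steady-state run length and tolerance.
#' @param reference_width_px optional adduction reference width.
#' @return an object of class `onset_report`: 0-based landmark frames
#'   `adduction_criterion_frame`, `oscillation_onset_frame`,
#'   `steady_state_frame`; `prephonation_time_ms`, `frames_to_steady`,
#'   `cycles_to_steady`, `reached_steady`, plus the detector settings.
#' @export
onset_report <- function(vib, min_amplitude_px = 0.5, k = 3,
                         steady_m = 3, steady_tol = 0.10,
                         reference_width_px = NULL) {
  stopifnot(inherits(vib, "vibrogram"))
  if (!any(vib$valid)) stop("vibrogram has no valid frames", call. = FALSE)
  fps <- attr(vib, "fps")
  cycles <- detect_cycles(vib, min_amplitude_px)
  crit <- detect_adduction_criterion(vib, reference_width_px)
  ref_width <- attr(crit, "reference_width_px")
  crit <- as.integer(crit)
  onset <- detect_oscillation_onset(vib, cycles, k = k)
  steady <- if (is.na(onset))
    list(steady_state_frame = NA_integer_, cycles_to_steady = NA_integer_,
         reached_steady = FALSE)
  else detect_steady_state(cycles, steady_tol, steady_m, from_frame = onset)

  # landmarks are untrustworthy across untracked (non-imputed) frames
  blocked <- function(from, to) {
    if (is.na(from) || is.na(to)) return(FALSE)
    idx <- vib$frame >= from & vib$frame <= to
    any(!vib$valid[idx])
  }
  q <- quiet_segment(vib)
  q_frame <- vib$frame[q[2]]
  if (!is.na(crit) && blocked(q_frame, crit)) crit <- NA_integer_
  if (is.na(crit) || blocked(crit, onset)) onset <- NA_integer_
  if (is.na(onset) || blocked(onset, steady$steady_state_frame)) {
    steady <- list(steady_state_frame = NA_integer_,
                   cycles_to_steady = NA_integer_, reached_steady = FALSE)
  }

  structure(list(
    adduction_criterion_frame = as.integer(crit),
    oscillation_onset_frame = as.integer(onset),
    steady_state_frame = as.integer(steady$steady_state_frame),
    prephonation_time_ms = if (is.na(crit) || is.na(onset)) NA_real_
      else (onset - crit) / fps * 1000,
    frames_to_steady = if (is.na(onset) || is.na(steady$steady_state_frame))
      NA_integer_ else as.integer(steady$steady_state_frame - onset),
    cycles_to_steady = steady$cycles_to_steady,
    reached_steady = steady$reached_steady,
    reference_width_px = ref_width,
    settings = list(min_amplitude_px = min_amplitude_px, k = k,
                    steady_m = steady_m, steady_tol = steady_tol,
                    width_reference = "pre-gesture glottal gap width"),
    fps = fps,
    n_cycles = nrow(cycles)
  ), class = "onset_report")
}

#' @export
print.onset_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "absent" else format(v)
  cat("<onset_report>\n")
  cat("  adduction criterion frame: ", fmt(x$adduction_criterion_frame), "\n")
  cat("  oscillation onset frame:   ", fmt(x$oscillation_onset_frame), "\n")
  cat("  steady state frame:        ", fmt(x$steady_state_frame), "\n")
  cat("  pre-phonation time (ms):   ", fmt(round(x$prephonation_time_ms, 2)), "\n")
  cat("  frames to steady:          ", fmt(x$frames_to_steady), "\n")
  cat("  cycles to steady:          ", fmt(x$cycles_to_steady), "\n")
  cat("  reached steady:            ", x$reached_steady, "\n")
  invisible(x)
}
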