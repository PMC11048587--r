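#' Parameters for the synthetic glottis simulator
#'
#' Bundles and validates the parameters of the synthetic high-speed
#' laryngoscopy simulator. The simulated gesture is: a quiet pre-gesture
#' segment with the glottal half-gap at `resting_half_gap_px`; a linear
#' adduction ramp of `adduction_time_ms` down to the post-adduction
#' (phonatory-posture) half-gap; then, `prephonation_delay_ms` after the
#' half-gap first reaches one third of its resting value, oscillation whose
#' half-amplitude grows as `1 - exp(-t/tau)` towards `steady_amplitude_px`
#' with `tau = growth_tau_cycles / f0_hz` seconds.
#'
#' The per-frame half-gap is `g(t) = max(0, G(t) - A(t) * cos(2 pi f0 (t -
#' t_osc)))`, a cosine clipped at closure, so the closed fraction of the
#' steady cycle is `acos(G_final / A) / pi`. For `closed_quotient` to be an
#' exact dial the post-adduction half-gap is therefore tied to the amplitude:
#' `G_final = steady_amplitude_px * cos(pi * closed_quotient)`. With
#' `closed_quotient = 0` the steady half-gap is a pure sinusoid about
#' `G_final = steady_amplitude_px`, grazing closure once per cycle: onset
#' does not require a complete approximation of the folds.
#'
#' @param fps frames per second (default 2000, typical of high-speed
#'   laryngoscopy).
#' @param duration_s recording length in seconds.
#' @param frame_height,frame_width frame size in pixels. The default
#'   120 x 160 is a scaled-down field of view that keeps simulated stacks
#'   small; the geometry is resolution-independent.
#' @param fold_length_px anterior-posterior extent of the fold band in
#'   pixel rows (default 60% of `frame_height`).
#' @param resting_half_gap_px pre-gesture half-width of the glottal gap.
#'   Default `3 * steady_amplitude_px`, which guarantees the one-third
#'   adduction criterion is crossed at or before the end of the ramp.
#' @param adduction_start_ms time at which the adduction ramp begins.
#' @param adduction_time_ms duration of the linear adduction ramp.
#' @param prephonation_delay_ms delay from the one-third-width adduction
#'   criterion to oscillation onset. This is a free ground-truth parameter;
#'   typical values used here span 20-300 ms.
#' @param f0_hz oscillation fundamental in Hz.
#' @param steady_amplitude_px steady-state half-amplitude of each edge, px.
#' @param growth_tau_cycles time constant of amplitude growth after
#'   oscillation onset, in glottal cycles.
#' @param closed_quotient fraction of the steady cycle with zero width,
#'   in `[0, 0.8]`.
#' @param asymmetry left/right edge amplitude ratio (1 = symmetric).
#' @param noise_sd additive Gaussian pixel-intensity noise (8-bit units).
#' @param whiteout_interval_ms optional `c(start, end)` in ms during which
#'   frames are rendered fully saturated (loss of glottal view, as when the
#'   epiglottis retroflexes over the larynx).
#' @param seed integer seed; identical seeds give bit-identical output.
#'
#' @return an object of class `glottis_sim_params`.
#' @seealso [generate_glottis_frames()], [generate_kymogram_direct()]
#' @export
glottis_sim_params <- function(fps = 2000,
                               duration_s = 0.5,
                               frame_height = 120,
                               frame_width = 160,
                               fold_length_px = NULL,
                               resting_half_gap_px = NULL,
                               adduction_start_ms = 50,
                               adduction_time_ms = 100,
                               prephonation_delay_ms = 100,
                               f0_hz = 200,
                               steady_amplitude_px = 15,
                               growth_tau_cycles = 1.5,
                               closed_quotient = 0.2,
                               asymmetry = 1,
                               noise_sd = 2,
                               whiteout_interval_ms = NULL,
                               seed = 1L) {
  stopifnot_scalar_pos(fps, "fps")
  stopifnot_scalar_pos(duration_s, "duration_s")
  stopifnot_scalar_pos(f0_hz, "f0_hz")
  stopifnot_scalar_pos(steady_amplitude_px, "steady_amplitude_px")
  stopifnot_scalar_pos(growth_tau_cycles, "growth_tau_cycles")
  stopifnot_scalar_pos(asymmetry, "asymmetry")
  if (frame_height < 8 || frame_width < 16)
    stop("frame dimensions must be at least 8 x 16 pixels", call. = FALSE)
  if (closed_quotient < 0 || closed_quotient > 0.8)
    stop("`closed_quotient` must lie in [0, 0.8]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  fold_length_px <- fold_length_px %||% round(0.6 * frame_height)
  resting_half_gap_px <- resting_half_gap_px %||% (3 * steady_amplitude_px)
  g_final <- steady_amplitude_px * cos(pi * closed_quotient)
  if (resting_half_gap_px <= g_final)
    stop("`resting_half_gap_px` must exceed the post-adduction half-gap ",
         sprintf("(%.2f px); adduction must narrow the glottis", g_final),
         call. = FALSE)
  mid <- (frame_width - 1) / 2
  widest <- max(resting_half_gap_px, g_final + steady_amplitude_px)
  if (mid - widest < 1.5 || mid + widest > frame_width - 2.5)
    stop("frame too narrow: the widest simulated gap (half-width ",
         sprintf("%.1f px) does not fit with a fold margin", widest),
         call. = FALSE)
  if (!is.null(whiteout_interval_ms)) {
    if (length(whiteout_interval_ms) != 2L ||
        whiteout_interval_ms[1] >= whiteout_interval_ms[2])
      stop("`whiteout_interval_ms` must be c(start, end) with start < end",
           call. = FALSE)
    if (whiteout_interval_ms[1] < 0 ||
        whiteout_interval_ms[2] > duration_s * 1000)
      stop("whiteout interval lies outside the recording", call. = FALSE)
  }
  structure(list(
    fps = fps, duration_s = duration_s,
    frame_height = as.integer(frame_height),
    frame_width = as.integer(frame_width),
    fold_length_px = as.integer(fold_length_px),
    resting_half_gap_px = resting_half_gap_px,
    adduction_start_ms = adduction_start_ms,
    adduction_time_ms = adduction_time_ms,
    prephonation_delay_ms = prephonation_delay_ms,
    f0_hz = f0_hz, steady_amplitude_px = steady_amplitude_px,
    growth_tau_cycles = growth_tau_cycles,
    closed_quotient = closed_quotient, asymmetry = asymmetry,
    noise_sd = noise_sd, whiteout_interval_ms = whiteout_interval_ms,
    seed = as.integer(seed)
  ), class = "glottis_sim_params")
}

# Analytic ground truth of the simulated gesture. Returns per-frame truth
# series and 0-based landmark frames.
glottis_truth <- function(p) {
  n <- round(p$duration_s * p$fps)
  t <- (0:(n - 1)) / p$fps
  g0 <- p$resting_half_gap_px
  gf <- p$steady_amplitude_px * cos(pi * p$closed_quotient)
  t_a <- p$adduction_start_ms / 1000
  t_e <- t_a + p$adduction_time_ms / 1000

  ramp <- function(tt) {
    gg <- rep(g0, length(tt))
    on_ramp <- tt >= t_a & tt < t_e
    gg[on_ramp] <- g0 + (gf - g0) * (tt[on_ramp] - t_a) / (t_e - t_a)
    gg[tt >= t_e] <- gf
    gg
  }
  G <- ramp(t)

  # landmarks falling beyond the recording are absent, not errors: short
  # clips of the quiet or ramp phase are legitimate recordings
  g_crit <- g0 / 3
  crit_idx <- which(G <= g_crit + 1e-9)[1]           # 1-based or NA
  t_osc <- if (is.na(crit_idx)) NA_real_
           else t[crit_idx] + p$prephonation_delay_ms / 1000
  osc_idx <- if (is.na(t_osc)) NA_integer_
             else which(t >= t_osc - 1e-12)[1]

  # per-side amplitudes: asymmetry = left/right ratio, mean preserved
  a_mean <- p$steady_amplitude_px
  a_left <- a_mean * 2 * p$asymmetry / (1 + p$asymmetry)
  a_right <- a_mean * 2 / (1 + p$asymmetry)

  if (is.na(osc_idx)) {
    env <- osc <- rep(0, n)
  } else {
    env <- ifelse(t >= t_osc,
                  1 - exp(-(t - t_osc) * p$f0_hz / p$growth_tau_cycles), 0)
    osc <- ifelse(t >= t_osc, cos(2 * pi * p$f0_hz * (t - t_osc)), 0)
  }
  g_left <- pmax(0, G - a_left * env * osc)
  g_right <- pmax(0, G - a_right * env * osc)

  # steady state: first run of 3 consecutive cycles whose analytic
  # peak-to-peak amplitude spread is within 10% of the run median
  # (periods are exactly constant, so amplitude decides); this is the
  # same operational rule detect_steady_state() applies to tracked data
  n_cyc <- floor((t[n] - t_osc) * p$f0_hz)
  steady_idx <- NA_integer_
  cycles_to_steady <- NA_integer_
  if (!is.na(n_cyc) && n_cyc >= 3) {
    k <- 0:(n_cyc - 1)
    t_pk <- t_osc + (k + 0.5) / p$f0_hz
    e_pk <- 1 - exp(-(t_pk - t_osc) * p$f0_hz / p$growth_tau_cycles)
    w_pk <- pmax(0, ramp(t_pk) + a_left * e_pk) +
            pmax(0, ramp(t_pk) + a_right * e_pk)
    t_tr <- t_osc + k / p$f0_hz
    e_tr <- 1 - exp(-(t_tr - t_osc) * p$f0_hz / p$growth_tau_cycles)
    w_tr <- pmax(0, ramp(t_tr) - a_left * e_tr) +
            pmax(0, ramp(t_tr) - a_right * e_tr)
    amp <- w_pk - w_tr      # peak width minus the cycle's starting valley
    for (i in seq_len(n_cyc - 2)) {
      run <- amp[i:(i + 2)]
      m <- stats::median(run)
      if (max(run) - min(run) <= 0.10 * m) {
        steady_t <- t_osc + (i - 1) / p$f0_hz
        steady_idx <- which(t >= steady_t - 1e-12)[1]
        cycles_to_steady <- i - 1L
        break
      }
    }
  }

  whiteout <- rep(FALSE, n)
  if (!is.null(p$whiteout_interval_ms)) {
    w <- p$whiteout_interval_ms / 1000
    whiteout <- t >= w[1] & t < w[2]
  }

  list(
    n_frames = n,
    time_s = t,
    adduction_start_frame = which(t >= t_a - 1e-12)[1] - 1L,
    adduction_criterion_frame = crit_idx - 1L,
    oscillation_start_frame = osc_idx - 1L,
    steady_state_frame = if (is.na(steady_idx)) NA_integer_ else steady_idx - 1L,
    cycles_to_steady = cycles_to_steady,
    true_f0_hz = p$f0_hz,
    true_width_series = g_left + g_right,
    true_left_edge = (p$frame_width - 1) / 2 - g_left,
    true_right_edge = (p$frame_width - 1) / 2 + g_right,
    posture_half_gap_px = gf,
    whiteout = whiteout
  )
}

# Anti-aliased scanline profile: bright folds, dark medial gap.
# g_left/g_right: per-frame half-gaps; returns T x W intensity matrix.
render_scanline <- function(g_left, g_right, width, bright = 200, dark = 20) {
  n <- length(g_left)
  mid <- (width - 1) / 2
  x <- matrix(0:(width - 1), n, width, byrow = TRUE)
  lg <- matrix(mid - g_left, n, width)
  rg <- matrix(mid + g_right, n, width)
  ov <- pmin(x + 0.5, rg) - pmax(x - 0.5, lg)   # pixel overlap with the gap
  ov <- pmin(pmax(ov, 0), 1)
  bright - (bright - dark) * ov
}

finish_intensities <- function(m, noise_sd, whiteout_mask = NULL) {
  if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
  m <- round(clip01(m, 0, 255))
  if (!is.null(whiteout_mask) && any(whiteout_mask)) {
    if (is.matrix(m)) m[whiteout_mask, ] <- 255 else m[whiteout_mask, , ] <- 255
  }
  m
}

#' Generate a synthetic high-speed laryngoscopy frame stack
#'
#' Renders the simulated glottis as monochrome frames: two bright fold
#' bands converging on a dark medial gap, with subpixel (area-coverage)
#' edge rendering so the true edge positions are recoverable to a fraction
#' of a pixel. The anterior-posterior fold band is centred vertically;
#' rows outside it are dim background tissue.
#'
#' @param params a [glottis_sim_params()] object.
#' @return a list with components `stack` (a [frame_stack()]) and `truth`,
#'   the ground truth: 0-based landmark frames `adduction_start_frame`,
#'   `adduction_criterion_frame`, `oscillation_start_frame`,
#'   `steady_state_frame` (ordered non-decreasingly), `cycles_to_steady`,
#'   `true_f0_hz`, per-frame `true_width_series` / `true_left_edge` /
#'   `true_right_edge` (px), and the `whiteout` frame mask.
#' @export
generate_glottis_frames <- function(params) {
  stopifnot(inherits(params, "glottis_sim_params"))
  p <- params
  tr <- glottis_truth(p)
  with_seed(p$seed, {
    prof <- render_scanline(
      (p$frame_width - 1) / 2 - tr$true_left_edge,
      tr$true_right_edge - (p$frame_width - 1) / 2,
      p$frame_width)
    h <- p$frame_height
    band <- max(1L, round(h / 2 - p$fold_length_px / 2)):
            min(h, round(h / 2 + p$fold_length_px / 2))
    arr <- array(60, dim = c(tr$n_frames, h, p$frame_width))
    for (r in band) arr[, r, ] <- prof
    arr <- finish_intensities(arr, p$noise_sd, tr$whiteout)
    list(stack = frame_stack(arr, fps = p$fps, source_id = "kymovox simulator"),
         truth = tr)
  })
}

#' Generate a synthetic digital kymogram directly
#'
#' Fast path that renders only the mid-membranous scanline, bypassing frame
#' rendering; equals [extract_kymogram()] applied to
#' [generate_glottis_frames()] at that scanline up to rendering noise
#' (bit-identical when `noise_sd = 0`).
#'
#' @inheritParams generate_glottis_frames
#' @return a list with components `kymogram` (a [kymogram()]) and `truth`
#'   (see [generate_glottis_frames()]).
#' @export
generate_kymogram_direct <- function(params) {
  stopifnot(inherits(params, "glottis_sim_params"))
  p <- params
  tr <- glottis_truth(p)
  with_seed(p$seed, {
    prof <- render_scanline(
      (p$frame_width - 1) / 2 - tr$true_left_edge,
      tr$true_right_edge - (p$frame_width - 1) / 2,
      p$frame_width)
    rows <- finish_intensities(prof, p$noise_sd, tr$whiteout)
    list(kymogram = kymogram(rows, scanline_index = round(p$frame_height / 2) - 1L,
                             fps = p$fps),
         truth = tr)
  })
}
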