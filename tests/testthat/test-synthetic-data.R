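test_that("identical seeds give bit-identical output from every generator", {
  p <- sim_params(seed = 42, noise_sd = 3, duration_s = 0.15)
  f1 <- generate_glottis_frames(p)
  f2 <- generate_glottis_frames(p)
  expect_identical(f1$stack$frames, f2$stack$frames)

  k1 <- generate_kymogram_direct(p)
  k2 <- generate_kymogram_direct(p)
  expect_identical(k1$kymogram$rows, k2$kymogram$rows)

  pp <- pas_sim_params(seed = 9)
  expect_identical(as.data.frame(generate_pas_trace(pp)),
                   as.data.frame(generate_pas_trace(pp)))

  # and the generator leaves the caller's RNG stream untouched
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(generate_kymogram_direct(p)); b <- runif(1)
  expect_identical(a, b)
})

test_that("oscillation period in the true width series matches f0 (zero-crossing oracle)", {
  p <- sim_params(f0_hz = 200, fps = 2000, growth_tau_cycles = 1,
                  closed_quotient = 0, noise_sd = 0)
  tr <- generate_kymogram_direct(p)$truth
  x <- tr$true_width_series[(tr$steady_state_frame + 1):tr$n_frames]
  x <- x - mean(x)
  up <- which(diff(sign(x)) > 0)          # upward zero crossings
  expect_gt(length(up), 10)
  expect_equal(median(diff(up)), 10)      # 2000 fps / 200 Hz
})

test_that("closed_quotient = 0 gives a pure sinusoid after steady state", {
  p <- sim_params(closed_quotient = 0, noise_sd = 0, growth_tau_cycles = 1)
  tr <- generate_kymogram_direct(p)$truth
  # use the last two cycles, where the growth envelope has fully converged
  per <- p$fps / p$f0_hz
  idx <- (tr$n_frames - 2 * per + 1):tr$n_frames
  x <- tr$true_width_series[idx]
  t <- (idx - 1) / p$fps
  fit <- lm(x ~ cos(2 * pi * p$f0_hz * t) + sin(2 * pi * p$f0_hz * t))
  amp <- 2 * p$steady_amplitude_px
  expect_lt(max(abs(residuals(fit))), 1e-3 * amp)
  # oscillates about the post-adduction gap width
  expect_equal(mean(x), 2 * tr$posture_half_gap_px, tolerance = 1e-3)
})

test_that("ground-truth landmarks are ordered for every parameterisation", {
  grid <- expand.grid(f0 = c(100, 180, 250), amp = c(6, 20),
                      cq = c(0, 0.4), delay = c(20, 250))
  for (i in seq_len(nrow(grid))) {
    p <- glottis_sim_params(duration_s = 0.6, frame_width = 200,
                            f0_hz = grid$f0[i],
                            steady_amplitude_px = grid$amp[i],
                            closed_quotient = grid$cq[i],
                            prephonation_delay_ms = grid$delay[i],
                            seed = i)
    tr <- generate_kymogram_direct(p)$truth
    expect_true(tr$adduction_start_frame <= tr$adduction_criterion_frame)
    expect_true(tr$adduction_criterion_frame <= tr$oscillation_start_frame)
    expect_false(is.na(tr$steady_state_frame))
    expect_true(tr$oscillation_start_frame <= tr$steady_state_frame)
  }
})

test_that("noiseless kymogram rows carry the true width exactly (integrated darkness)", {
  p <- sim_params(noise_sd = 0, closed_quotient = 0.2)
  g <- generate_kymogram_direct(p)
  dark_width <- rowSums((200 - pmin(g$kymogram$rows, 200)) / 180)
  # exact up to 8-bit intensity rounding (0.5/180 px per partial pixel)
  expect_lt(max(abs(dark_width - g$truth$true_width_series)), 0.02)
})

test_that("whiteout frames are saturated; symmetric folds mirror about the midline", {
  p <- sim_params(noise_sd = 2, whiteout_interval_ms = c(100, 140), seed = 5)
  g <- generate_kymogram_direct(p)
  wo <- g$truth$whiteout
  expect_true(any(wo))
  expect_true(all(g$kymogram$rows[wo, ] >= 0.9 * 255))

  p2 <- sim_params(asymmetry = 1, noise_sd = 0)
  g2 <- generate_kymogram_direct(p2)
  mid <- (p2$frame_width - 1) / 2
  expect_lt(max(abs((mid - g2$truth$true_left_edge) -
                    (g2$truth$true_right_edge - mid))), 0.5)
  # and in the tracked kymogram too
  vib <- track_edges(g2$kymogram)
  open <- vib$width_px > 2
  expect_lt(max(abs((mid - vib$left_px[open]) -
                    (vib$right_px[open] - mid))), 0.5)
})

test_that("asymmetric folds have unequal edge excursions with the dialled ratio", {
  p <- sim_params(asymmetry = 2, noise_sd = 0, closed_quotient = 0)
  tr <- generate_kymogram_direct(p)$truth
  mid <- (p$frame_width - 1) / 2
  gl <- mid - tr$true_left_edge
  gr <- tr$true_right_edge - mid
  # on open frames (no closure clamp) the two half-gaps co-vary with the
  # dialled left/right amplitude ratio
  i <- which(seq_along(gl) > tr$steady_state_frame & gl > 0.5 & gr > 0.5)
  slope <- unname(coef(lm(gl[i] ~ gr[i]))[2])
  expect_equal(slope, 2, tolerance = 1e-6)
})

test_that("invalid simulator parameters are rejected", {
  expect_error(glottis_sim_params(frame_height = 2), "at least")
  expect_error(glottis_sim_params(closed_quotient = 0.9), "closed_quotient")
  expect_error(glottis_sim_params(whiteout_interval_ms = c(100, 9000)),
               "outside the recording")
  expect_error(glottis_sim_params(steady_amplitude_px = 60,
                                  frame_width = 100), "too narrow")
})

test_that("noiseless PAS occlusion plateau equals the subglottic target exactly", {
  tok <- data.frame(label = "modal", spl_db = 80, f0_hz = 150,
                    flow_ccps = 120, psub_cmH2O = 9)
  pp <- pas_sim_params(tokens = tok,
                       noise_sd = list(spl_db = 0, f0_hz = 0, flow_ccps = 0,
                                       pressure_cmH2O = 0))
  rec <- generate_pas_trace(pp)
  expect_identical(max(rec$pressure_cmH2O), 9)
  seg <- segment_tokens(rec, labels = "modal")
  expect_equal(nrow(seg), 1L)
  est <- estimate_subglottic_pressure(rec, seg[1, ])
  expect_equal(as.numeric(est), 9, tolerance = 0.01)
})

test_that("three-token PAS trace is segmented into three labelled intervals", {
  tok <- data.frame(label = c("soft", "modal", "loud"),
                    spl_db = c(74, 84, 87), f0_hz = c(110, 112, 114),
                    flow_ccps = c(210, 180, 140), psub_cmH2O = c(3, 5, 7))
  rec <- generate_pas_trace(pas_sim_params(tokens = tok, seed = 4))
  seg <- segment_tokens(rec)
  expect_equal(nrow(seg), 3L)
  expect_equal(seg$label, c("soft", "modal", "loud"))
  truth <- attr(rec, "truth")
  expect_lt(max(abs(seg$start_s - truth$start_s)), 0.010)
  expect_lt(max(abs(seg$end_s - truth$end_s)), 0.010)
})

test_that("the bundled reference token table prints the expected rows", {
  t1 <- table1_fixture()
  expect_equal(nrow(t1), 18L)
  expect_equal(sum(t1$sex == "male"), 9L)
  expect_equal(sum(t1$sex == "female"), 9L)
  r1 <- t1[t1$subject == 1 & t1$token == "soft", ]
  expect_equal(unlist(r1[c("spl_db", "f0_hz", "flow_ccps", "pressure_cmH2O")],
                      use.names = FALSE), c(74, 110, 210, 3))
  r5 <- t1[t1$subject == 5 & t1$token == "loud", ]
  expect_equal(unlist(r5[c("spl_db", "f0_hz", "flow_ccps", "pressure_cmH2O")],
                      use.names = FALSE), c(90, 217, 60, 15))
})
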