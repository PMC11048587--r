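test_that("resistance follows (pressure/flow) x 1000", {
  expect_equal(resistance(3, 210), 14.28571, tolerance = 5e-7)
  expect_equal(resistance(15, 60), 250)
  expect_equal(resistance(0, 100), 0)
  expect_error(resistance(5, 0), "positive")
  expect_error(resistance(5, -10), "positive")
})

test_that("every derived column of the reference table is reproduced", {
  d <- derive_token_table(table1_fixture())
  expect_lt(max(abs(d$resistance - printed_resistance)), 5e-5)
  trans <- !is.na(d$db_change)
  expect_equal(d$db_change[trans], printed_db_change)
  expect_lt(max(abs(d$resistance_change[trans] - printed_resistance_change)),
            5e-5)
  expect_lt(max(abs(d$resistance_change_per_db[trans] - printed_per_db)),
            5e-5)
})

test_that("resistance changes chain exactly from soft to loud", {
  t1 <- table1_fixture()
  for (s in unique(t1$subject)) {
    sub <- t1[t1$subject == s, ]
    del <- token_deltas(normalise <- data.frame(
      label = as.character(sub$token), spl_db = sub$spl_db,
      flow_ccps = sub$flow_ccps, psub_cmH2O = sub$pressure_cmH2O))
    r <- resistance(sub$pressure_cmH2O, sub$flow_ccps)
    expect_equal(sum(del$resistance_change),
                 r[sub$token == "loud"] - r[sub$token == "soft"])
  }
})

test_that("identical tokens give zero deltas with per-dB undefined", {
  tok <- data.frame(label = c("soft", "modal"), spl_db = c(80, 80),
                    flow_ccps = c(100, 100), psub_cmH2O = c(5, 5))
  del <- token_deltas(tok)
  expect_equal(del$db_change, 0)
  expect_equal(del$resistance_change, 0)
  expect_true(is.na(del$resistance_change_per_db))
  expect_false(del$per_db_defined)
})

test_that("closed-form paired t agrees with the reference implementation", {
  x <- c(11.4082, 8.668142, 3.060012)
  y <- c(1.375095, -0.98109, -1.06061)
  ours <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)

  same <- paired_t(c(2, 3), c(2, 3))
  expect_equal(same$t, 0)
})

test_that("silent recordings yield no tokens; six tokens follow the protocol order", {
  sr <- 500
  quiet <- pas_recording(time_s = (0:999) / sr, f0_hz = rep(0, 1000),
                         spl_db = rep(50, 1000), flow_ccps = rep(0, 1000),
                         pressure_cmH2O = rep(0, 1000), sample_rate_hz = sr)
  expect_equal(nrow(segment_tokens(quiet)), 0L)

  tok6 <- data.frame(label = rep(c("soft", "modal", "loud"), each = 2),
                     spl_db = rep(c(74, 84, 89), each = 2),
                     f0_hz = rep(c(180, 185, 190), each = 2),
                     flow_ccps = rep(c(100, 140, 120), each = 2),
                     psub_cmH2O = rep(c(4, 6, 10), each = 2))
  rec <- generate_pas_trace(pas_sim_params(tokens = tok6, seed = 8))
  seg <- segment_tokens(rec)
  expect_equal(seg$label,
               c("soft", "soft", "modal", "modal", "loud", "loud"))
})

test_that("subglottic pressure interpolates between drifting plateaus", {
  # three occlusion plateaus at 5, 6, 7 cm H2O: the two interior vowels
  # interpolate to 5.5 and 6.5, so the token estimate is 6.0
  sr <- 1000
  n <- 3000
  pres <- rep(0, n)
  pres[201:500] <- 5; pres[1201:1500] <- 6; pres[2201:2500] <- 7
  rec <- pas_recording(time_s = (0:(n - 1)) / sr, f0_hz = rep(150, n),
                       spl_db = rep(80, n), flow_ccps = rep(100, n),
                       pressure_cmH2O = pres, sample_rate_hz = sr)
  est <- estimate_subglottic_pressure(rec, c(1L, n))
  expect_equal(as.numeric(est), 6.0, tolerance = 1e-9)
  expect_equal(attr(est, "per_vowel"), c(5.5, 6.5), tolerance = 1e-9)

  single <- rec
  single$pressure_cmH2O[1201:1500] <- 0
  single$pressure_cmH2O[2201:2500] <- 0
  expect_error(estimate_subglottic_pressure(single, c(1L, n)),
               "at least 2 occlusion peaks")
})

test_that("token means recover the generating targets within 1%", {
  tok <- data.frame(label = "soft", spl_db = 74, f0_hz = 110,
                    flow_ccps = 210, psub_cmH2O = 3)
  rec <- generate_pas_trace(pas_sim_params(tokens = tok, seed = 12))
  seg <- segment_tokens(rec, labels = "soft")
  tm <- token_means(rec, seg[1, ])
  expect_equal(tm$spl_db, 74, tolerance = 0.01)
  expect_equal(tm$f0_hz, 110, tolerance = 0.01)
  expect_equal(tm$flow_ccps, 210, tolerance = 0.01)
  expect_equal(tm$psub_cmH2O, 3, tolerance = 0.01)
})

test_that("repetitions average to the midpoint", {
  reps <- data.frame(label = c("soft", "soft"), spl_db = c(73, 75),
                     f0_hz = c(110, 112), flow_ccps = c(200, 220),
                     psub_cmH2O = c(3, 3))
  avg <- average_repetitions(reps)
  expect_equal(nrow(avg), 1L)
  expect_equal(avg$spl_db, 74)
  expect_equal(avg$flow_ccps, 210)

  twin <- average_repetitions(reps[c(1, 1), ])
  expect_equal(twin$spl_db, reps$spl_db[1])
})

test_that("group summary reproduces the reference-table statistics", {
  gs <- group_summary(table1_fixture())
  expect_equal(unname(gs$psub_by_level),
               c(3.933333, 5.716667, 9.7), tolerance = 1e-6)
  expect_equal(gs$mean_spl_rise_db, 15.33333, tolerance = 1e-5)
  male <- gs$sex_stats[gs$sex_stats$sex == "male", ]
  female <- gs$sex_stats[gs$sex_stats$sex == "female", ]
  expect_equal(round(male$f0_mean), 119)
  expect_equal(round(female$f0_mean), 189)
  expect_equal(round(male$flow_mean), 142)
  ml <- gs$per_db[gs$per_db$transition == "modal_to_loud", ]
  expect_equal(round(ml$sd, 1), 8.5)
  expect_gt(gs$contrast$t, 0)
  expect_equal(gs$contrast$df, 5L)
  expect_lt(gs$contrast$p_two_sided, 0.05)
})

test_that("incomplete token triples are excluded with a warning", {
  t1 <- table1_fixture()
  broken <- t1[!(t1$subject == 6 & t1$token == "loud"), ]
  expect_warning(gs <- group_summary(broken), "incomplete")
  expect_equal(gs$n_subjects, 5L)
})

test_that("PAS CSV round trip preserves the channels", {
  rec <- generate_pas_trace(pas_sim_params(seed = 3))
  path <- file.path(tempdir(), "pas.csv")
  write_pas_csv(rec, path)
  back <- read_pas_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(rec), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(attr(back, "sample_rate_hz"), attr(rec, "sample_rate_hz"),
               tolerance = 1e-6)
  file.remove(path)
})

test_that("the full synthetic chain reproduces printed derived values within 1%", {
  t1 <- table1_fixture()
  for (s in unique(t1$subject)) {
    sub <- t1[t1$subject == s, ]
    tok <- data.frame(label = as.character(sub$token), spl_db = sub$spl_db,
                      f0_hz = sub$f0_hz, flow_ccps = sub$flow_ccps,
                      psub_cmH2O = sub$pressure_cmH2O)
    rec <- generate_pas_trace(pas_sim_params(
      tokens = tok, seed = s,
      noise_sd = list(spl_db = 0, f0_hz = 0, flow_ccps = 0,
                      pressure_cmH2O = 0)))
    seg <- segment_tokens(rec)
    measured <- do.call(rbind, lapply(seq_len(nrow(seg)), function(i)
      token_means(rec, seg[i, ])))
    del <- token_deltas(average_repetitions(measured))
    ref <- token_deltas(tok)
    expect_lt(max(abs(del$resistance_change_per_db /
                      ref$resistance_change_per_db - 1)), 0.01)
    expect_lt(max(abs(del$resistance_change /
                      ref$resistance_change - 1)), 0.01)
  }
  # spot value: subject 5 modal->loud per-dB is 27.5 in the printed table
  sub5 <- t1[t1$subject == 5, ]
  ref5 <- token_deltas(data.frame(label = as.character(sub5$token),
                                  spl_db = sub5$spl_db,
                                  flow_ccps = sub5$flow_ccps,
                                  psub_cmH2O = sub5$pressure_cmH2O))
  expect_equal(ref5$resistance_change_per_db[ref5$transition == "modal_to_loud"],
               27.5, tolerance = 1e-7)
})
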