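#' Parameters for the synthetic PAS trace generator
#'
#' Builds the multichannel phonatory-aerodynamic recording of [pa:pa:]
#' tokens: each token alternates bilabial occlusions (intraoral pressure
#' plateau at the subglottic target, zero flow) with voiced vowel segments
#' (flow, SPL and F0 at their targets, pressure near zero), at soft, modal
#' and loud loudness levels.
#'
#' @param tokens data frame with one row per token, columns `label`
#'   (`"soft"`, `"modal"`, `"loud"`), `spl_db`, `f0_hz`, `flow_ccps`,
#'   `psub_cmH2O`, and optionally `n_syllables` (default 3),
#'   `syllable_rate_hz` (default 2.5) and `occlusion_fraction`
#'   (default 0.35, must lie in (0, 0.6)). The default tokens are a
#'   typical normophonic series rising about 15 dB from soft to loud with
#'   a steadily increasing subglottic pressure.
#' @param sample_rate_hz channel sampling rate.
#' @param gap_s silent gap between consecutive tokens (> 0; tokens may not
#'   overlap).
#' @param lead_s lead-in silence before the first token.
#' @param noise_sd named list of per-channel Gaussian noise SDs:
#'   `spl_db`, `f0_hz`, `flow_ccps`, `pressure_cmH2O`.
#' @param ambient_spl_db SPL of the silent floor (recording-room ambience).
#' @param seed integer seed.
#' @return an object of class `pas_sim_params`.
#' @export
pas_sim_params <- function(tokens = default_pas_tokens(),
                           sample_rate_hz = 500,
                           gap_s = 0.5, lead_s = 0.5,
                           noise_sd = list(spl_db = 0.5, f0_hz = 1,
                                           flow_ccps = 5,
                                           pressure_cmH2O = 0.05),
                           ambient_spl_db = 50,
                           seed = 1L) {
  stopifnot_scalar_pos(sample_rate_hz, "sample_rate_hz")
  if (gap_s <= 0) stop("`gap_s` must be positive: tokens may not overlap",
                       call. = FALSE)
  tokens <- as.data.frame(tokens)
  need <- c("label", "spl_db", "f0_hz", "flow_ccps", "psub_cmH2O")
  if (!all(need %in% names(tokens)))
    stop("`tokens` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tokens$label %in% c("soft", "modal", "loud")))
    stop("token labels must be soft/modal/loud", call. = FALSE)
  if (is.null(tokens$n_syllables)) tokens$n_syllables <- 3L
  if (is.null(tokens$syllable_rate_hz)) tokens$syllable_rate_hz <- 2.5
  if (is.null(tokens$occlusion_fraction)) tokens$occlusion_fraction <- 0.35
  num <- c("spl_db", "f0_hz", "flow_ccps", "psub_cmH2O",
           "n_syllables", "syllable_rate_hz")
  for (cn in num) if (any(tokens[[cn]] <= 0))
    stop("per-token targets must be positive (", cn, ")", call. = FALSE)
  if (any(tokens$occlusion_fraction <= 0 | tokens$occlusion_fraction >= 0.6))
    stop("`occlusion_fraction` must lie in (0, 0.6)", call. = FALSE)
  structure(list(tokens = tokens, sample_rate_hz = sample_rate_hz,
                 gap_s = gap_s, lead_s = lead_s, noise_sd = noise_sd,
                 ambient_spl_db = ambient_spl_db, seed = as.integer(seed)),
            class = "pas_sim_params")
}

#' @rdname pas_sim_params
#' @export
default_pas_tokens <- function() {
  data.frame(
    label = c("soft", "modal", "loud"),
    spl_db = c(75, 85, 90),
    f0_hz = c(180, 185, 190),
    flow_ccps = c(110, 140, 115),
    psub_cmH2O = c(3.9, 5.7, 9.7)
  )
}

#' Generate a synthetic PAS recording
#'
#' @param params a [pas_sim_params()] object.
#' @return a [pas_recording()]; the generating token intervals and targets
#'   are attached as attribute `"truth"` (data frame with `label`,
#'   `start_s`, `end_s` and the per-token targets).
#' @export
generate_pas_trace <- function(params) {
  stopifnot(inherits(params, "pas_sim_params"))
  p <- params
  sr <- p$sample_rate_hz
  tok <- p$tokens
  tok$duration_s <- tok$n_syllables / tok$syllable_rate_hz
  tok$start_s <- p$lead_s +
    cumsum(c(0, utils::head(tok$duration_s + p$gap_s, -1)))
  tok$end_s <- tok$start_s + tok$duration_s
  total_s <- tok$end_s[nrow(tok)] + p$gap_s
  n <- round(total_s * sr)
  t <- (0:(n - 1)) / sr

  f0 <- numeric(n)
  spl <- rep(p$ambient_spl_db, n)
  flow <- numeric(n)
  pres <- numeric(n)
  for (i in seq_len(nrow(tok))) {
    in_tok <- t >= tok$start_s[i] & t < tok$end_s[i]
    syl_phase <- (t - tok$start_s[i]) * tok$syllable_rate_hz[i]
    occluded <- in_tok & (syl_phase %% 1) < tok$occlusion_fraction[i]
    voiced <- in_tok & !occluded
    spl[in_tok] <- tok$spl_db[i]
    pres[occluded] <- tok$psub_cmH2O[i]
    flow[voiced] <- tok$flow_ccps[i]
    f0[voiced] <- tok$f0_hz[i]
  }
  with_seed(p$seed, {
    ns <- p$noise_sd
    add <- function(x, sd, floor0 = FALSE) {
      if (!is.null(sd) && sd > 0) x <- x + stats::rnorm(length(x), 0, sd)
      if (floor0) x <- pmax(x, 0)
      x
    }
    rec <- pas_recording(time_s = t,
                         f0_hz = add(f0, ns$f0_hz, TRUE),
                         spl_db = add(spl, ns$spl_db),
                         flow_ccps = add(flow, ns$flow_ccps, TRUE),
                         pressure_cmH2O = add(pres, ns$pressure_cmH2O, TRUE),
                         sample_rate_hz = sr)
    attr(rec, "truth") <- tok
    rec
  })
}

#' PAS recording container
#'
#' Equal-length channels of a phonatory-aerodynamic recording: voice
#' fundamental frequency (Hz), sound pressure level (dB), mean airflow
#' (cc/s) and intraoral pressure (cm H2O), sampled at `sample_rate_hz`.
#'
#' @param time_s,f0_hz,spl_db,flow_ccps,pressure_cmH2O channel vectors.
#' @param sample_rate_hz sampling rate.
#' @param subject optional metadata list (`id`, `sex`, `age`).
#' @return a data frame of class `pas_recording`.
#' @export
pas_recording <- function(time_s, f0_hz, spl_db, flow_ccps, pressure_cmH2O,
                          sample_rate_hz, subject = list()) {
  lens <- lengths(list(time_s, f0_hz, spl_db, flow_ccps, pressure_cmH2O))
  if (length(unique(lens)) != 1L)
    stop("all channels must have equal length", call. = FALSE)
  stopifnot_scalar_pos(sample_rate_hz, "sample_rate_hz")
  out <- data.frame(time_s = time_s, f0_hz = f0_hz, spl_db = spl_db,
                    flow_ccps = flow_ccps, pressure_cmH2O = pressure_cmH2O)
  attr(out, "sample_rate_hz") <- sample_rate_hz
  attr(out, "subject") <- subject
  class(out) <- c("pas_recording", "data.frame")
  out
}

#' @export
print.pas_recording <- function(x, ...) {
  cat(sprintf("<pas_recording> %d samples (%.2f s) at %g Hz\n",
              nrow(x), nrow(x) / attr(x, "sample_rate_hz"),
              attr(x, "sample_rate_hz")))
  invisible(x)
}

#' Read and write PAS recordings as CSV
#'
#' Columns: `time_s`, `f0_hz`, `spl_db`, `flow_ccps`, `pressure_cmH2O`.
#' The sampling rate is recovered from the time column on read.
#'
#' @param rec a [pas_recording()].
#' @param path CSV file path.
#' @return `read_pas_csv()` returns a [pas_recording()].
#' @export
write_pas_csv <- function(rec, path) {
  stopifnot(inherits(rec, "pas_recording"))
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pas_csv
#' @export
read_pas_csv <- function(path) {
  d <- utils::read.csv(path)
  sr <- 1 / stats::median(diff(d$time_s))
  pas_recording(d$time_s, d$f0_hz, d$spl_db, d$flow_ccps, d$pressure_cmH2O,
                sample_rate_hz = sr)
}

#' Bundled reference token measurements
#'
#' Per-token aerodynamic and acoustic measurements for six normophonic
#' adults (three male, three female), each producing soft, modal and loud
#' [pa:pa:] tokens: mean SPL (dB), fundamental frequency (Hz), airflow
#' (cc/s) and subglottic pressure (cm H2O), the two repetitions of each
#' token already averaged. Only the four measured columns are shipped;
#' every derived quantity (resistance, per-transition changes, group
#' statistics) is recomputed by the package, see [resistance()],
#' [token_deltas()] and [group_summary()].
#'
#' @return data frame with 18 rows and columns `subject`, `sex`, `age`,
#'   `token`, `spl_db`, `f0_hz`, `flow_ccps`, `pressure_cmH2O`.
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "reference_tokens.csv",
                      package = "kymovox", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$token <- factor(d$token, levels = c("soft", "modal", "loud"))
  d
}
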