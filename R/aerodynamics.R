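#' Segment phonation tokens in a PAS recording
#'
#' Tokens are maximal runs where SPL stays at or above `spl_floor_db` for
#' at least `min_duration_ms` (runs separated by brief dips under 50 ms
#' are merged). Labels follow the recording protocol sequence -- soft,
#' medium (modal), loud, each level produced `reps` times in order. When
#' the detected token count does not match the expected sequence, a
#' warning is raised and labels are assigned by rank of mean SPL instead.
#'
#' @param rec a [pas_recording()].
#' @param spl_floor_db SPL threshold separating phonation from silence.
#' @param min_duration_ms minimum token duration.
#' @param labels optional explicit label sequence overriding the protocol
#'   default.
#' @return data frame with one row per token: `label`, `start_s`, `end_s`,
#'   `start_idx`, `end_idx` (1-based sample indices).
#' @export
segment_tokens <- function(rec, spl_floor_db = 65, min_duration_ms = 500,
                           labels = NULL) {
  stopifnot(inherits(rec, "pas_recording"))
  sr <- attr(rec, "sample_rate_hz")
  runs <- true_runs(rec$spl_db >= spl_floor_db)
  # merge runs separated by dips shorter than 50 ms
  if (nrow(runs) > 1L) {
    keep <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if ((runs$start[i] - last$end) / sr < 0.05) {
        keep[[length(keep)]]$end <- runs$end[i]
      } else keep[[length(keep) + 1L]] <- runs[i, ]
    }
    runs <- do.call(rbind, keep)
  }
  runs <- runs[(runs$end - runs$start + 1L) / sr >= min_duration_ms / 1000, ,
               drop = FALSE]
  n <- nrow(runs)
  if (n == 0L)
    return(data.frame(label = character(), start_s = numeric(),
                      end_s = numeric(), start_idx = integer(),
                      end_idx = integer()))
  lab <- labels
  if (is.null(lab)) {
    levels3 <- c("soft", "modal", "loud")
    if (n %% 3 == 0) {
      lab <- rep(levels3, each = n / 3)
    } else {
      warning(sprintf(
        "detected %d tokens, not a multiple of 3; labelling by SPL rank", n),
        call. = FALSE)
      mean_spl <- vapply(seq_len(n), function(i)
        mean(rec$spl_db[runs$start[i]:runs$end[i]]), numeric(1))
      lab <- levels3[cut(rank(mean_spl, ties.method = "first"),
                         breaks = 3, labels = FALSE)]
    }
  }
  data.frame(label = lab,
             start_s = rec$time_s[runs$start],
             end_s = rec$time_s[runs$end],
             start_idx = runs$start, end_idx = runs$end)
}

#' Estimate subglottic pressure from bilabial occlusion peaks
#'
#' During the [p] occlusions of a [pa:pa:] token the intraoral pressure
#' equilibrates with the subglottic pressure; during the vowels it falls
#' to zero while the folds vibrate. The subglottic pressure driving each
#' vowel is therefore estimated by linear interpolation between the
#' flanking occlusion plateau values, and the token estimate is the mean
#' over the vowels with an occlusion on both sides.
#'
#' @param rec a [pas_recording()].
#' @param interval one row of [segment_tokens()] output, or
#'   `c(start_idx, end_idx)` 1-based sample indices.
#' @param peak_fraction occlusion plateaus are samples at or above this
#'   fraction of the interval pressure maximum.
#' @return estimated subglottic pressure (cm H2O), with per-vowel
#'   estimates attached as attribute `"per_vowel"`. Errors when fewer
#'   than two occlusion peaks exist (interpolation impossible).
#' @export
estimate_subglottic_pressure <- function(rec, interval, peak_fraction = 0.7) {
  stopifnot(inherits(rec, "pas_recording"))
  idx <- interval_indices(interval)
  x <- rec$pressure_cmH2O[idx[1]:idx[2]]
  tt <- rec$time_s[idx[1]:idx[2]]
  runs <- true_runs(x >= peak_fraction * max(x))
  # merge plateau fragments separated by less than a quarter of the median
  # inter-plateau period (guards against noise splitting one occlusion)
  if (nrow(runs) > 2L) {
    centres <- (runs$start + runs$end) / 2
    med_gap <- stats::median(diff(centres))
    merged <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs$start[i] - last$end < 0.25 * med_gap) {
        merged[[length(merged)]]$end <- runs$end[i]
      } else merged[[length(merged) + 1L]] <- runs[i, ]
    }
    runs <- do.call(rbind, merged)
  }
  if (nrow(runs) < 2L)
    stop("need at least 2 occlusion peaks to interpolate subglottic pressure",
         call. = FALSE)
  plateau <- vapply(seq_len(nrow(runs)), function(i)
    stats::median(x[runs$start[i]:runs$end[i]]), numeric(1))
  centre_t <- vapply(seq_len(nrow(runs)), function(i)
    mean(tt[c(runs$start[i], runs$end[i])]), numeric(1))
  per_vowel <- numeric(0)
  for (i in seq_len(nrow(runs) - 1L)) {
    tm <- (tt[runs$end[i]] + tt[runs$start[i + 1L]]) / 2   # vowel midpoint
    f <- (tm - centre_t[i]) / (centre_t[i + 1L] - centre_t[i])
    per_vowel <- c(per_vowel, plateau[i] + (plateau[i + 1L] - plateau[i]) * f)
  }
  est <- mean(per_vowel)
  attr(est, "per_vowel") <- per_vowel
  attr(est, "plateaus") <- plateau
  est
}

interval_indices <- function(interval) {
  if (is.data.frame(interval)) {
    c(interval$start_idx[1], interval$end_idx[1])
  } else as.integer(interval[1:2])
}

#' Per-token acoustic-aerodynamic means
#'
#' SPL, F0 and flow are averaged over the voiced (vowel) samples of the
#' token; the subglottic pressure comes from
#' [estimate_subglottic_pressure()]. Voiced samples are those with flow
#' above half the token's 90th flow percentile (the occlusions have zero
#' flow).
#'
#' @param rec a [pas_recording()].
#' @param interval as in [estimate_subglottic_pressure()]; its `label` is
#'   carried through when present.
#' @return one-row data frame: `label`, `spl_db`, `f0_hz`, `flow_ccps`,
#'   `psub_cmH2O`.
#' @export
token_means <- function(rec, interval) {
  stopifnot(inherits(rec, "pas_recording"))
  idx <- interval_indices(interval)
  sel <- idx[1]:idx[2]
  flow <- rec$flow_ccps[sel]
  voiced <- flow > 0.5 * stats::quantile(flow, 0.9)
  if (!any(voiced)) stop("no voiced samples in token interval", call. = FALSE)
  data.frame(
    label = if (is.data.frame(interval) && !is.null(interval$label))
      as.character(interval$label[1]) else NA_character_,
    spl_db = mean(rec$spl_db[sel][voiced]),
    f0_hz = mean(rec$f0_hz[sel][voiced]),
    flow_ccps = mean(flow[voiced]),
    psub_cmH2O = as.numeric(estimate_subglottic_pressure(rec, interval))
  )
}

#' Average token repetitions
#'
#' Collapses repeated tokens of the same loudness level into one row per
#' level (soft, modal, loud) by averaging each measure, the standard
#' treatment of the two protocol repetitions.
#'
#' @param measures data frame of [token_means()] rows.
#' @return data frame with one row per level, ordered soft, modal, loud.
#' @export
average_repetitions <- function(measures) {
  lv <- c("soft", "modal", "loud")
  measures$label <- factor(measures$label, levels = lv)
  out <- do.call(rbind, lapply(split(measures, measures$label), function(d) {
    if (nrow(d) == 0L) return(NULL)
    data.frame(label = d$label[1], spl_db = mean(d$spl_db),
               f0_hz = mean(d$f0_hz), flow_ccps = mean(d$flow_ccps),
               psub_cmH2O = mean(d$psub_cmH2O))
  }))
  rownames(out) <- NULL
  out
}

#' Glottal (laryngeal airway) resistance
#'
#' `resistance = (psub / flow) * 1000`, converting cm H2O per cc/s to
#' cm H2O per litre/s.
#'
#' @param psub_cmH2O subglottic pressure, cm H2O.
#' @param flow_ccps mean airflow, cc/s (must be positive).
#' @return resistance in cm H2O/(L/s); vectorised.
#' @export
resistance <- function(psub_cmH2O, flow_ccps) {
  if (any(flow_ccps <= 0))
    stop("flow must be positive to compute resistance", call. = FALSE)
  (psub_cmH2O / flow_ccps) * 1000
}

#' Per-transition derived measures
#'
#' For tokens ordered soft, modal, loud: the SPL change, resistance change
#' and resistance change per dB across each adjacent transition. A zero dB
#' change leaves the per-dB quantity undefined (`NA`, flagged).
#'
#' @param tokens data frame with one row per level (columns `label`,
#'   `spl_db`, `flow_ccps`, `psub_cmH2O`), e.g. from
#'   [average_repetitions()].
#' @return data frame with one row per transition: `transition`,
#'   `db_change`, `resistance_change`, `resistance_change_per_db`,
#'   `per_db_defined`.
#' @export
token_deltas <- function(tokens) {
  lv <- c("soft", "modal", "loud")
  tokens <- tokens[order(factor(tokens$label, levels = lv)), , drop = FALSE]
  if (nrow(tokens) < 2L)
    stop("need at least 2 ordered tokens", call. = FALSE)
  r <- resistance(tokens$psub_cmH2O, tokens$flow_ccps)
  i <- seq_len(nrow(tokens) - 1L)
  db <- tokens$spl_db[i + 1L] - tokens$spl_db[i]
  dr <- r[i + 1L] - r[i]
  per_db <- ifelse(db != 0, dr / db, NA_real_)
  data.frame(
    transition = paste(tokens$label[i], tokens$label[i + 1L], sep = "_to_"),
    db_change = db,
    resistance_change = dr,
    resistance_change_per_db = per_db,
    per_db_defined = db != 0
  )
}

#' Per-subject derived token table
#'
#' Rebuilds, for every subject in a long token table (such as
#' [table1_fixture()]), the derived columns: resistance, and per-transition
#' dB change, resistance change and resistance change per dB.
#'
#' @param tokens long data frame with columns `subject`, `token` (or
#'   `label`), `spl_db`, `f0_hz`, `flow_ccps` and `pressure_cmH2O` (or
#'   `psub_cmH2O`).
#' @return the input with `resistance` plus transition columns appended
#'   (transition rows aligned to the arriving token, as in standard
#'   per-token tabulations; the soft row's transition fields are `NA`).
#' @export
derive_token_table <- function(tokens) {
  d <- normalise_tokens(tokens)
  d$resistance <- resistance(d$psub_cmH2O, d$flow_ccps)
  d$db_change <- NA_real_
  d$resistance_change <- NA_real_
  d$resistance_change_per_db <- NA_real_
  for (s in unique(d$subject)) {
    rows <- which(d$subject == s)
    sub <- d[rows, ]
    o <- order(factor(sub$label, levels = c("soft", "modal", "loud")))
    del <- token_deltas(sub[o, ])
    arriving <- rows[o][-1]
    d$db_change[arriving] <- del$db_change
    d$resistance_change[arriving] <- del$resistance_change
    d$resistance_change_per_db[arriving] <- del$resistance_change_per_db
  }
  d
}

normalise_tokens <- function(tokens) {
  d <- as.data.frame(tokens)
  if (is.null(d$label) && !is.null(d$token)) d$label <- as.character(d$token)
  if (is.null(d$psub_cmH2O) && !is.null(d$pressure_cmH2O))
    d$psub_cmH2O <- d$pressure_cmH2O
  if (is.null(d$subject)) d$subject <- 1L
  d$label <- as.character(d$label)
  d
}

#' Group summary of token measures across subjects
#'
#' Computes, over all subjects with complete soft/modal/loud triples:
#' sex-stratified means and sample SDs (n-1 denominator) of F0, flow and
#' subglottic pressure over all tokens; mean subglottic pressure per
#' loudness level; the mean soft-to-loud SPL rise; and the paired contrast
#' of resistance change per dB between the soft-to-modal and
#' modal-to-loud transitions. The paired t statistic is computed from its
#' closed form, `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1`;
#' two-sided and one-sided p-values are both reported since either
#' convention may be audited. Because F0 central tendency is sometimes
#' quoted as a median, both mean and median are emitted.
#'
#' @param tokens long data frame as in [derive_token_table()], with a
#'   `sex` column.
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(tokens) {
  d <- normalise_tokens(tokens)
  if (is.null(d$sex)) stop("`tokens` needs a `sex` column", call. = FALSE)
  d$sex <- tolower(as.character(d$sex))
  complete <- vapply(split(d, d$subject), function(s)
    all(c("soft", "modal", "loud") %in% s$label), logical(1))
  if (any(!complete)) {
    warning("excluding subjects with incomplete token triples: ",
            paste(names(complete)[!complete], collapse = ", "),
            call. = FALSE)
    d <- d[d$subject %in% names(complete)[complete], ]
  }
  if (length(unique(d$subject)) < 2L)
    stop("need at least 2 subjects with complete triples", call. = FALSE)

  sex_stats <- do.call(rbind, lapply(split(d, d$sex), function(s)
    data.frame(sex = s$sex[1], n_tokens = nrow(s),
               f0_mean = mean(s$f0_hz), f0_sd = stats::sd(s$f0_hz),
               f0_median = stats::median(s$f0_hz),
               flow_mean = mean(s$flow_ccps), flow_sd = stats::sd(s$flow_ccps),
               psub_mean = mean(s$psub_cmH2O), psub_sd = stats::sd(s$psub_cmH2O))))
  rownames(sex_stats) <- NULL

  psub_by_level <- vapply(split(d$psub_cmH2O, factor(d$label,
    levels = c("soft", "modal", "loud"))), mean, numeric(1))

  per_subj <- split(d, d$subject)
  spl_rise <- vapply(per_subj, function(s)
    s$spl_db[s$label == "loud"][1] - s$spl_db[s$label == "soft"][1],
    numeric(1))
  deltas <- lapply(per_subj, function(s) token_deltas(s))
  sm <- vapply(deltas, function(x)
    x$resistance_change_per_db[x$transition == "soft_to_modal"], numeric(1))
  ml <- vapply(deltas, function(x)
    x$resistance_change_per_db[x$transition == "modal_to_loud"], numeric(1))

  ct <- paired_t(ml, sm)
  structure(list(
    n_subjects = length(per_subj),
    sex_stats = sex_stats,
    psub_by_level = psub_by_level,
    mean_spl_rise_db = mean(spl_rise),
    per_db = data.frame(
      transition = c("soft_to_modal", "modal_to_loud"),
      mean = c(mean(sm), mean(ml)),
      sd = c(stats::sd(sm), stats::sd(ml))),
    contrast = ct
  ), class = "group_summary")
}

#' Paired t test from its closed form
#'
#' `t = mean(x - y) / (sd(x - y) / sqrt(n))`, `df = n - 1`. Both the
#' two-sided and the one-sided (mean difference > 0) p-values are
#' returned.
#'
#' @param x,y paired observation vectors.
#' @return list with `t`, `df`, `mean_diff`, `sd_diff`, `p_two_sided`,
#'   `p_one_sided`, `n`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors differ in length",
                                   call. = FALSE)
  d <- x - y
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  sd_d <- stats::sd(d)
  tval <- if (sd_d == 0 && mean(d) == 0) 0 else mean(d) / (sd_d / sqrt(n))
  list(t = tval, df = n - 1L, mean_diff = mean(d), sd_diff = sd_d,
       p_two_sided = 2 * stats::pt(-abs(tval), n - 1L),
       p_one_sided = stats::pt(-tval, n - 1L),
       n = n)
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %d subjects\n", x$n_subjects))
  cat("  psub by level (cm H2O): ",
      paste(sprintf("%s %.1f", names(x$psub_by_level), x$psub_by_level),
            collapse = ", "), "\n")
  cat(sprintf("  mean soft->loud SPL rise: %.1f dB\n", x$mean_spl_rise_db))
  print(x$sex_stats, digits = 3)
  cat(sprintf(
    "  per-dB contrast (modal->loud vs soft->modal): t = %.3f, df = %d, p(two-sided) = %.4f\n",
    x$contrast$t, x$contrast$df, x$contrast$p_two_sided))
  invisible(x)
}
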