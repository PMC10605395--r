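#' @title Synthetic data generation
#' @description Two-level synthetic data: feature-level two-group cohorts
#'   whose biomarker marginals match the packaged published group
#'   statistics, and stream-level 60 Hz gaze sessions driven by an
#'   explicit fixation/saccade policy with generator-side bookkeeping for
#'   oracle tests.
#' @name synth
NULL

#' Packaged two-group biomarker specification
#'
#' Loads the packaged transcription of the published group statistics:
#' 27 digital biomarkers with group-wise mean (SD) at n = 29 per group,
#' together with each metric's domain bounds (FT bounded by stimulus
#' duration, AL in \[0, 1\], SPL/ASS/AT non-negative) and the printed
#' t, p, FDR and Cohen's d values for reference.
#'
#' @return A data frame (`group_spec`), one row per biomarker.
#' @export
default_group_spec <- function() {
  path <- system.file("extdata", "group_spec.csv", package = "gazedep")
  spec <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(spec$hd_sd >= 0), all(spec$ld_sd >= 0))
  spec
}

#' Simulate a feature-level two-group cohort
#'
#' Draws independent truncated-Gaussian biomarker values per subject from
#' a group specification: Gaussian draws with each group's mean and SD,
#' clipped to the metric's domain bounds. Attention-times biomarkers are
#' optionally rounded to integers (the published tables treat them as
#' continuous mean (SD), so rounding is off by default). Reproducible
#' given `seed`.
#'
#' @param spec A `group_spec` data frame (see [default_group_spec()]).
#' @param n_per_group Subjects per group (default 29, the study size).
#' @param seed Integer seed.
#' @param round_attention_times Round AT biomarkers to integers?
#' @param correlation Optional common inter-biomarker correlation matrix
#'   (biomarkers x biomarkers, applied within each subject's draw) for
#'   sensitivity studies; default independent.
#' @return A `biomarker_table` data frame: `subject`, `group`, one column
#'   per biomarker name.
#' @export
simulate_feature_table <- function(spec = default_group_spec(),
                                   n_per_group = 29, seed = 1,
                                   round_attention_times = FALSE,
                                   correlation = NULL) {
  set.seed(seed)
  p <- nrow(spec)
  chol_R <- if (!is.null(correlation)) {
    stopifnot(nrow(correlation) == p, ncol(correlation) == p)
    chol(correlation)
  }
  draw_group <- function(n, means, sds) {
    z <- matrix(stats::rnorm(n * p), n, p)
    if (!is.null(chol_R)) z <- z %*% chol_R
    vals <- sweep(sweep(z, 2, sds, `*`), 2, means, `+`)
    for (j in seq_len(p)) {
      vals[, j] <- pmin(pmax(vals[, j], spec$lower[j]), spec$upper[j])
      if (round_attention_times && isTRUE(spec$integer[j]))
        vals[, j] <- round(vals[, j])
    }
    vals
  }
  hd <- draw_group(n_per_group, spec$hd_mean, spec$hd_sd)
  ld <- draw_group(n_per_group, spec$ld_mean, spec$ld_sd)
  out <- data.frame(
    subject = c(sprintf("HD%03d", seq_len(n_per_group)),
                sprintf("LD%03d", seq_len(n_per_group))),
    group = rep(c("HD", "LD"), each = n_per_group),
    stringsAsFactors = FALSE, check.names = FALSE)
  vals <- rbind(hd, ld)
  for (j in seq_len(p)) out[[spec$name[j]]] <- vals[, j]
  out
}

#' Gaze-generation policy
#'
#' Parameters of the scripted fixation/saccade generator: how often each
#' emotion's photos are fixated on matrix stimuli, which feature AOIs are
#' fixated on single faces, dwell durations, within-fixation jitter, the
#' chance of a dwell landing off the stimulus, and saccade speed.
#'
#' @param emotion_weights Named non-negative weights over
#'   neutral/sad/happy/angry for matrix-cell choice; normalised to sum 1.
#' @param feature_weights Named non-negative weights over O/F/EM/EN/E for
#'   single-face AOI choice; normalised to sum 1.
#' @param dwell_mean,dwell_sd Dwell duration distribution (seconds).
#' @param jitter_sd Within-fixation positional jitter SD (pixels); drift
#'   and microsaccade scale, which sets scan-path length and speed.
#' @param saccade_speed Inter-fixation saccade speed (pixels/second).
#' @param offstim_rate Named per-emotion probability that a dwell lands
#'   on the background outside the stimulus (disengagement).
#' @return A `gaze_policy` object.
#' @export
gaze_policy <- function(emotion_weights = c(neutral = 0.25, sad = 0.25,
                                            happy = 0.25, angry = 0.25),
                        feature_weights = c(O = 0.1, F = 0.2, EM = 0.2,
                                            EN = 0.2, E = 0.3),
                        dwell_mean = 0.5, dwell_sd = 0.15,
                        jitter_sd = 4, saccade_speed = 15000,
                        offstim_rate = c(neutral = 0.05, sad = 0.05,
                                         happy = 0.05, angry = 0.05)) {
  stopifnot(all(emotion_weights >= 0), sum(emotion_weights) > 0,
            all(feature_weights >= 0), sum(feature_weights) > 0,
            dwell_mean > 0, jitter_sd >= 0, saccade_speed > 0,
            all(offstim_rate >= 0 & offstim_rate <= 1))
  structure(list(
    emotion_weights = emotion_weights / sum(emotion_weights),
    feature_weights = feature_weights / sum(feature_weights),
    dwell_mean = dwell_mean, dwell_sd = dwell_sd,
    jitter_sd = jitter_sd, saccade_speed = saccade_speed,
    offstim_rate = offstim_rate), class = "gaze_policy")
}

clip_to_rect <- function(x, y, rect) {
  list(x = pmin(pmax(x, rect$x_min), rect$x_max),
       y = pmin(pmax(y, rect$y_min), rect$y_max))
}

# enclosing chain for nested single-face AOIs (target counts toward all)
.NEST_CHAIN <- list(E = c("E", "EN", "EM", "F", "O"),
                    EN = c("EN", "EM", "F", "O"),
                    EM = c("EM", "F", "O"), F = c("F", "O"), O = "O")

#' Simulate a gaze session from a policy
#'
#' Builds, for every stimulus of the paradigm, a 60 Hz gaze stream from
#' scripted fixations: dwell targets are chosen from the policy's AOI /
#' emotion weights, dwell samples are the target point plus Gaussian
#' jitter clipped inside the target rectangle, and successive dwells are
#' connected by constant-speed linear saccades. The generator's own
#' bookkeeping (true per-AOI dwell sample counts, true within-dwell path
#' lengths, transition counts, and saccade/background sample counts) is
#' attached as attribute `"bookkeeping"` for oracle tests. Saccade
#' samples passing through an AOI are not in the dwell counts, so for
#' any AOI the extracted fixation-sample count is at least the bookkept
#' dwell count and, for disjoint regions (matrix cells, the overall
#' area), at most the dwell count plus `n_saccade`.
#'
#' @param policy A [gaze_policy()].
#' @param paradigm A `paradigm_spec`.
#' @param aois An `aoi_config`.
#' @param seed Integer seed.
#' @param subject,group Identity attached to the session.
#' @return A [session_log()] with a `bookkeeping` attribute (list per
#'   stimulus key: `dwell_samples`, `dwell_path`, `transitions`).
#' @export
simulate_gaze_session <- function(policy, paradigm = default_paradigm(),
                                  aois = default_aois(paradigm),
                                  seed = 1, subject = "S1", group = "unknown") {
  stopifnot(inherits(policy, "gaze_policy"))
  set.seed(seed)
  recording <- recording_spec()
  sr <- recording$sampling_rate
  step_len <- policy$saccade_speed / sr
  series <- list()
  book <- list()
  for (key in names(paradigm$stimuli)) {
    st <- paradigm$stimuli[[key]]
    n_total <- round(st$duration * sr)
    rects <- aois[[key]]
    single <- st$kind == "single"
    xs <- numeric(0); ys <- numeric(0)
    lab <- character(0)                     # per-sample dwell AOI (NA: saccade/background)
    did <- integer(0)                       # per-sample dwell id
    dwell_n <- 0L
    cur <- c(960, 540)                      # calibration cross at centre
    while (length(xs) < n_total) {
      # choose a dwell target: AOI for single faces, emotion->cell for matrices
      if (single) {
        tgt_name <- sample(names(policy$feature_weights), 1,
                           prob = policy$feature_weights)
        emo <- unname(st$layout[1])
      } else {
        emo <- sample(names(policy$emotion_weights), 1,
                      prob = policy$emotion_weights)
        cells_e <- names(st$layout)[st$layout == emo]
        tgt_name <- sample(cells_e, 1)
      }
      offstim <- stats::runif(1) < policy$offstim_rate[[emo]]
      if (offstim) {
        rect <- NULL                        # background dwell, outside O / cells
        tgt <- c(stats::runif(1, 10, 200), stats::runif(1, 10, 200))
      } else {
        rect <- rects[[tgt_name]]
        tgt <- c(stats::runif(1, rect$x_min, rect$x_max),
                 stats::runif(1, rect$y_min, rect$y_max))
      }
      # saccade: constant-speed linear interpolation, endpoints exclusive
      d <- sqrt(sum((tgt - cur)^2))
      n_sac <- if (d > 0) max(0L, ceiling(d / step_len) - 1L) else 0L
      if (n_sac > 0) {
        fr <- seq_len(n_sac) / (n_sac + 1L)
        xs <- c(xs, cur[1] + fr * (tgt[1] - cur[1]))
        ys <- c(ys, cur[2] + fr * (tgt[2] - cur[2]))
        lab <- c(lab, rep(NA_character_, n_sac))
        did <- c(did, rep(NA_integer_, n_sac))
      }
      # dwell: jittered samples clipped inside the target rectangle
      k <- max(3L, round(stats::rnorm(1, policy$dwell_mean, policy$dwell_sd) * sr))
      px <- tgt[1] + stats::rnorm(k, 0, policy$jitter_sd)
      py <- tgt[2] + stats::rnorm(k, 0, policy$jitter_sd)
      if (!is.null(rect)) {
        cl <- clip_to_rect(px, py, rect); px <- cl$x; py <- cl$y
      }
      dwell_n <- dwell_n + 1L
      xs <- c(xs, px); ys <- c(ys, py)
      lab <- c(lab, rep(if (is.null(rect)) NA_character_ else tgt_name, k))
      did <- c(did, rep(dwell_n, k))
      cur <- c(px[k], py[k])
    }
    keep <- seq_len(n_total)
    xs <- pmin(pmax(xs[keep], 0), recording$screen_width)
    ys <- pmin(pmax(ys[keep], 0), recording$screen_height)
    lab <- lab[keep]; did <- did[keep]
    series[[key]] <- gaze_series(
      stimulus_ref(st$task, st$stimulus),
      data.frame(i = keep, x = xs, y = ys, valid = TRUE),
      recording)
    # bookkeeping from the trimmed stream: exact dwell counts and paths
    bk_counts <- stats::setNames(numeric(length(rects)), names(rects))
    bk_path <- stats::setNames(numeric(length(rects)), names(rects))
    for (dwell in unique(did[!is.na(did) & !is.na(lab)])) {
      sel <- which(!is.na(did) & did == dwell & !is.na(lab))
      tgt_name <- lab[sel[1]]
      path <- if (length(sel) > 1)
        sum(sqrt(diff(xs[sel])^2 + diff(ys[sel])^2)) else 0
      tally <- if (single) .NEST_CHAIN[[tgt_name]] else tgt_name
      bk_counts[tally] <- bk_counts[tally] + length(sel)
      bk_path[tally] <- bk_path[tally] + path
    }
    book[[key]] <- list(dwell_samples = bk_counts, dwell_path = bk_path,
                        transitions = length(unique(did[!is.na(did)])),
                        n_saccade = sum(is.na(did)),
                        n_background = sum(!is.na(did) & is.na(lab)))
  }
  out <- session_log(subject, group, series, recording, paradigm)
  attr(out, "bookkeeping") <- book
  out
}

#' Calibrated high-risk / low-risk gaze policies
#'
#' A pair of policies whose extracted biomarker group differences
#' reproduce the direction of the published effects: the high-risk (HD)
#' policy dwells more on sad photos and less on happy and neutral photos
#' (attention bias), disengages from sad photos less often (longer sad
#' fixation time), and moves with smaller within-fixation jitter (shorter
#' scan paths, slower average scanning speed — psychomotor retardation);
#' the low-risk (LD) policy is the complementary baseline.
#'
#' @return Named list with elements `HD` and `LD`, each a [gaze_policy()].
#' @export
calibrated_group_policies <- function() {
  list(
    HD = gaze_policy(
      emotion_weights = c(neutral = 0.18, sad = 0.40, happy = 0.13, angry = 0.29),
      feature_weights = c(O = 0.15, F = 0.25, EM = 0.20, EN = 0.15, E = 0.25),
      dwell_mean = 0.60, dwell_sd = 0.15,
      jitter_sd = 3.0, saccade_speed = 15000,
      offstim_rate = c(neutral = 0.08, sad = 0.01, happy = 0.10, angry = 0.04)),
    LD = gaze_policy(
      emotion_weights = c(neutral = 0.27, sad = 0.22, happy = 0.26, angry = 0.25),
      feature_weights = c(O = 0.15, F = 0.25, EM = 0.20, EN = 0.15, E = 0.25),
      dwell_mean = 0.45, dwell_sd = 0.15,
      jitter_sd = 4.5, saccade_speed = 15000,
      offstim_rate = c(neutral = 0.05, sad = 0.07, happy = 0.03, angry = 0.05)))
}

#' Simulate a two-group cohort of gaze sessions
#'
#' Convenience wrapper: one simulated session per subject, HD subjects
#' from the HD policy and LD subjects from the LD policy, with per-subject
#' seeds derived from `seed`.
#'
#' @param n_per_group Subjects per group.
#' @param seed Integer base seed.
#' @param policies Named list `HD`/`LD` of [gaze_policy()].
#' @param paradigm,aois Paradigm and AOI configuration.
#' @return List of [session_log()].
#' @export
simulate_cohort_sessions <- function(n_per_group = 29, seed = 1,
                                     policies = calibrated_group_policies(),
                                     paradigm = default_paradigm(),
                                     aois = default_aois(paradigm)) {
  sessions <- list()
  idx <- 0L
  for (grp in c("HD", "LD")) {
    for (s in seq_len(n_per_group)) {
      idx <- idx + 1L
      sessions[[idx]] <- simulate_gaze_session(
        policies[[grp]], paradigm, aois,
        seed = (seed * 1000L + idx) %% .Machine$integer.max,
        subject = sprintf("%s%03d", grp, s), group = grp)
    }
  }
  sessions
}

#' Build a gaze series from an explicit dwell script
#'
#' Deterministic test helper: each script row contributes `n` identical
#' samples at (`x`, `y`), concatenated in order with no interpolation or
#' jitter. Useful for checking extracted metrics against hand-computed
#' values.
#'
#' @param script Data frame with columns `x`, `y`, `n` (and optionally
#'   `valid`).
#' @param ref A [stimulus_ref()].
#' @param recording A [recording_spec()].
#' @return A [gaze_series()].
#' @export
scripted_gaze_series <- function(script, ref = stimulus_ref(1, 1),
                                 recording = recording_spec()) {
  stopifnot(all(c("x", "y", "n") %in% names(script)))
  if (is.null(script$valid)) script$valid <- TRUE
  idx <- rep(seq_len(nrow(script)), script$n)
  gaze_series(ref, data.frame(x = script$x[idx], y = script$y[idx],
                              valid = script$valid[idx]), recording)
}

#' Moments of a clipped (censored) normal distribution
#'
#' Mean and SD of `min(max(Y, lower), upper)` for `Y ~ N(mean, sd)` — the
#' exact marginal distribution the feature-level simulator draws from.
#' Useful for computing the effect sizes the generator actually implies
#' once domain clipping (FT floors/ceilings, AL bounds) is applied.
#'
#' @param mean,sd Parameters of the underlying Gaussian.
#' @param lower,upper Clipping bounds (may be infinite).
#' @return List with `mean` and `sd` of the clipped variable.
#' @export
clipped_normal_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(list(mean = min(max(mean, lower), upper), sd = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Pa <- stats::pnorm(a); Pb <- stats::pnorm(b)
  fa <- stats::dnorm(a); fb <- stats::dnorm(b)
  lowpart <- if (is.finite(lower)) lower * Pa else 0
  highpart <- if (is.finite(upper)) upper * (1 - Pb) else 0
  m1 <- lowpart + highpart + mean * (Pb - Pa) + sd * (fa - fb)
  low2 <- if (is.finite(lower)) lower^2 * Pa else 0
  high2 <- if (is.finite(upper)) upper^2 * (1 - Pb) else 0
  mid2 <- mean^2 * (Pb - Pa) + 2 * mean * sd * (fa - fb) +
    sd^2 * ((Pb - Pa) + (if (is.finite(a)) a * fa else 0) -
              (if (is.finite(b)) b * fb else 0))
  v <- low2 + high2 + mid2 - m1^2
  list(mean = m1, sd = sqrt(max(v, 0)))
}

#' Effect sizes implied by a group specification
#'
#' Cohen's d per biomarker implied by a `group_spec`, either from the raw
#' Gaussian parameters (`clipped = FALSE`) or from the clipped
#' distributions the simulator actually samples (`clipped = TRUE`).
#'
#' @param spec A `group_spec` data frame.
#' @param clipped Account for domain clipping?
#' @return Named numeric vector of effect sizes.
#' @export
spec_implied_d <- function(spec = default_group_spec(), clipped = TRUE) {
  d <- numeric(nrow(spec))
  for (j in seq_len(nrow(spec))) {
    if (clipped) {
      hd <- clipped_normal_moments(spec$hd_mean[j], spec$hd_sd[j],
                                   spec$lower[j], spec$upper[j])
      ld <- clipped_normal_moments(spec$ld_mean[j], spec$ld_sd[j],
                                   spec$lower[j], spec$upper[j])
      d[j] <- abs(hd$mean - ld$mean) / sqrt((hd$sd^2 + ld$sd^2) / 2)
    } else {
      d[j] <- abs(spec$hd_mean[j] - spec$ld_mean[j]) /
        sqrt((spec$hd_sd[j]^2 + spec$ld_sd[j]^2) / 2)
    }
  }
  stats::setNames(d, spec$name)
}
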