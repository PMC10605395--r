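test_that("feature-level simulation is seed-deterministic and respects bounds", {
  a <- simulate_feature_table(n_per_group = 20, seed = 42)
  b <- simulate_feature_table(n_per_group = 20, seed = 42)
  expect_identical(a, b)
  c <- simulate_feature_table(n_per_group = 20, seed = 43)
  expect_false(identical(a, c))
  spec <- default_group_spec()
  for (j in seq_len(nrow(spec))) {
    v <- a[[spec$name[j]]]
    expect_true(all(v >= spec$lower[j] & v <= spec$upper[j]))
  }
  # AL columns in [0,1]
  expect_true(all(a[["Task 4_P(4) Neutral_AL"]] >= 0 &
                  a[["Task 4_P(4) Neutral_AL"]] <= 1))
  # integer rounding flag
  r <- simulate_feature_table(n_per_group = 20, seed = 42,
                              round_attention_times = TRUE)
  at <- r[["Task 2_P(4) Neutral_AT"]]
  expect_identical(at, round(at))
})

test_that("zero-SD specifications collapse to the group means", {
  spec <- default_group_spec()
  spec$hd_sd[] <- 0; spec$ld_sd[] <- 0
  tab <- simulate_feature_table(spec, n_per_group = 5, seed = 1)
  for (j in seq_len(nrow(spec))) {
    expect_equal(unique(tab[[spec$name[j]]][tab$group == "HD"]), spec$hd_mean[j])
    expect_equal(unique(tab[[spec$name[j]]][tab$group == "LD"]), spec$ld_mean[j])
  }
})

test_that("simulated marginals approach the specified group means at large n", {
  spec <- default_group_spec()
  row <- spec[spec$name == "Task 1_P(2) Sad(FT,O)", ]
  tab <- simulate_feature_table(spec, n_per_group = 10000, seed = 77)
  v <- tab[[row$name]]
  # truncation at the 5 s ceiling pulls the mean down slightly; 2 SE plus
  # the analytic clipping shift bound the error
  se <- row$hd_sd / sqrt(10000)
  expect_lt(abs(mean(v[tab$group == "HD"]) - row$hd_mean), 0.02 + 2 * se)
  expect_lt(abs(mean(v[tab$group == "LD"]) - row$ld_mean), 0.03 + 2 * se)
})

test_that("correlation hook induces the requested dependence", {
  spec <- default_group_spec()[1:3, ]
  R <- matrix(0.8, 3, 3); diag(R) <- 1
  tab <- simulate_feature_table(spec, n_per_group = 3000, seed = 5,
                                correlation = R)
  # SPL column is effectively unclipped; check its correlation with ASS
  r_obs <- cor(tab[[spec$name[2]]], tab[[spec$name[3]]])
  expect_gt(r_obs, 0.6)
})

test_that("stream-level generator is deterministic and complete", {
  s1 <- simulate_gaze_session(gaze_policy(), seed = 8, subject = "D", group = "HD")
  s2 <- simulate_gaze_session(gaze_policy(), seed = 8, subject = "D", group = "HD")
  expect_identical(s1$series, s2$series)
  expect_true(s1$complete)
  for (ser in s1$series)
    expect_identical(nrow(ser$samples),
                     as.integer(round(5 * 60 * ifelse(ser$ref$task %in% c(2, 4), 2, 1))))
})

test_that("extracted fixation times are sandwiched by generator bookkeeping", {
  set.seed(55)
  aois <- default_aois()
  for (rep in 1:6) {
    pol <- gaze_policy(
      emotion_weights = as.numeric(stats::runif(4, 0.1, 1)) |>
        (\(w) stats::setNames(w, c("neutral", "sad", "happy", "angry")))(),
      dwell_mean = stats::runif(1, 0.3, 0.7),
      jitter_sd = stats::runif(1, 1, 8),
      saccade_speed = stats::runif(1, 9000, 20000))
    ses <- simulate_gaze_session(pol, seed = 100 + rep)
    book <- attr(ses, "bookkeeping")
    for (key in c("1_1", "1_2", "2_1", "4_1")) {
      bk <- book[[key]]
      ser <- ses$series[[key]]
      sr <- ser$recording$sampling_rate
      for (aoi in names(bk$dwell_samples)) {
        ft_samples <- fixation_time(ser, aois[[key]][[aoi]]) * sr
        # every bookkept dwell sample lies inside its AOI
        expect_gte(ft_samples, bk$dwell_samples[[aoi]] - 1e-9)
        # disjoint regions (cells, overall area) gain at most the
        # saccade pass-through samples beyond their own dwells
        if (aoi == "O" || grepl("^[0-9]+$", aoi))
          expect_lte(ft_samples,
                     bk$dwell_samples[[aoi]] + bk$n_saccade + 1e-9)
      }
      # accounting closes: dwell + saccade + background = presentation window
      on_stim <- if ("O" %in% names(bk$dwell_samples))
        bk$dwell_samples[["O"]] else sum(bk$dwell_samples)
      expect_equal(on_stim + bk$n_saccade + bk$n_background,
                   nrow(ser$samples))
    }
  }
})

test_that("degenerate all-sad policy yields sad attention level near one", {
  pol <- gaze_policy(emotion_weights = c(neutral = 0, sad = 1, happy = 0, angry = 0),
                     offstim_rate = c(neutral = 0, sad = 0, happy = 0, angry = 0))
  ses <- simulate_gaze_session(pol, seed = 21)
  eb <- extract_emotion_biomarkers(ses)
  sad_al <- eb$value[eb$name == "Task 2_P(1) Sad_AL"]
  expect_gt(sad_al, 0.9)   # only saccade transit lies outside sad cells
  expect_equal(eb$value[eb$name == "Task 2_P(1) Happy_AT"], 0)
})

test_that("calibrated policies reproduce the directions of the published effects", {
  paradigm <- default_paradigm()
  aois <- default_aois(paradigm)
  sessions <- simulate_cohort_sessions(10, seed = 31, paradigm = paradigm,
                                       aois = aois)
  tidy <- do.call(rbind, lapply(sessions, function(s)
    rbind(extract_feature_biomarkers(s, aois, paradigm),
          extract_emotion_biomarkers(s, aois, paradigm))))
  gm <- function(nm) {
    sub <- tidy[tidy$name == nm, ]
    c(hd = mean(sub$value[sub$group == "HD"], na.rm = TRUE),
      ld = mean(sub$value[sub$group == "LD"], na.rm = TRUE))
  }
  # HD dwells longer on sad photos
  m <- gm("Task 1_P(2) Sad(FT,O)"); expect_gt(m["hd"], m["ld"])
  # HD scan paths shorter, scanning slower
  m <- gm("Task 1_P(1) Neutral(SPL,O)"); expect_lt(m["hd"], m["ld"])
  m <- gm("Task 3_P(5) Neutral(ASS,EM)"); expect_lt(m["hd"], m["ld"])
  # HD attends more to sad, less to happy/neutral on matrices
  m <- gm("Task 4_P(4) Sad_AL"); expect_gt(m["hd"], m["ld"])
  m <- gm("Task 4_P(4) Happy_AL"); expect_lt(m["hd"], m["ld"])
  m <- gm("Task 4_P(4) Neutral_AL"); expect_lt(m["hd"], m["ld"])
  # identical policies produce no systematic sad-AL gap at matched seeds
  pols <- calibrated_group_policies()
  null_sessions <- simulate_cohort_sessions(10, seed = 31,
    policies = list(HD = pols$LD, LD = pols$LD))
  tidy0 <- do.call(rbind, lapply(null_sessions, extract_emotion_biomarkers))
  sub <- tidy0[tidy0$name == "Task 4_P(4) Sad_AL", ]
  d0 <- abs(mean(sub$value[sub$group == "HD"]) - mean(sub$value[sub$group == "LD"])) /
    stats::sd(sub$value)
  expect_lt(d0, 0.8)
})

test_that("raising the HD sad weight monotonically widens the sad-AL gap", {
  base <- calibrated_group_policies()$LD
  gaps <- vapply(c(0.25, 0.45, 0.7), function(w) {
    pol <- gaze_policy(
      emotion_weights = c(neutral = (1 - w) / 3, sad = w,
                          happy = (1 - w) / 3, angry = (1 - w) / 3),
      dwell_mean = base$dwell_mean, jitter_sd = base$jitter_sd)
    vals <- vapply(1:6, function(i) {
      ses <- simulate_gaze_session(pol, seed = 600 + i)
      eb <- extract_emotion_biomarkers(ses)
      mean(eb$value[eb$metric == "AL" & eb$aoi == "matrix" & eb$emotion == "sad"])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})
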