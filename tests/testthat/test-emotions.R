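matrix_fixture <- function() {
  paradigm <- default_paradigm()
  aois <- default_aois(paradigm)
  list(cells = aois[["2_1"]], layout = paradigm$stimuli[["2_1"]]$layout)
}

cell_center <- function(rect) c((rect$x_min + rect$x_max) / 2,
                                (rect$y_min + rect$y_max) / 2)

test_that("view times tally per-cell, per-emotion and matrix viewing time", {
  fx <- matrix_fixture()
  c1 <- cell_center(fx$cells[["1"]])
  s <- gaze_series(stimulus_ref(2, 1),
                   data.frame(x = rep(c1[1], 600), y = rep(c1[2], 600)))
  vt <- view_times(s, fx$cells, fx$layout)
  expect_equal(unname(vt$T_cell[["1"]]), 10)
  expect_equal(sum(vt$T_cell), 10)
  expect_equal(vt$T_matrix, 10)
  expect_equal(unname(vt$T_emotion[["neutral"]]), 10)  # cell 1 is neutral
  # uniform quarter split
  pts <- do.call(rbind, lapply(fx$cells, cell_center))
  idx <- rep(1:4, each = 150)
  s2 <- gaze_series(stimulus_ref(2, 1),
                    data.frame(x = pts[idx, 1], y = pts[idx, 2]))
  vt2 <- view_times(s2, fx$cells, fx$layout)
  expect_equal(unname(vt2$T_cell), rep(vt2$T_matrix / 4, 4))
  # invalid samples shrink numerator and denominator coherently
  s3 <- gaze_series(stimulus_ref(2, 1),
                    data.frame(x = rep(c1[1], 600), y = rep(c1[2], 600),
                               valid = rep(c(TRUE, FALSE), 300)))
  vt3 <- view_times(s3, fx$cells, fx$layout)
  expect_equal(vt3$T_matrix, 5)
  expect_equal(attention_level(vt3, cell = 1), 1)
  # nominal-duration mode keeps the scheduled denominator
  vt4 <- view_times(s3, fx$cells, fx$layout, nominal_duration = 10)
  expect_equal(attention_level(vt4, cell = 1), 0.5)
})

test_that("attention level and shift follow their defining ratios", {
  fx <- matrix_fixture()
  c3 <- cell_center(fx$cells[["3"]])  # sad cell
  mix <- data.frame(
    x = c(rep(c3[1], 150), rep(cell_center(fx$cells[["1"]])[1], 60), rep(10, 390)),
    y = c(rep(c3[2], 150), rep(cell_center(fx$cells[["1"]])[2], 60), rep(10, 390)))
  s <- gaze_series(stimulus_ref(2, 1), mix)
  vt <- view_times(s, fx$cells, fx$layout)
  expect_equal(attention_level(vt, cell = 3), 150 / 600)
  expect_equal(attention_level(vt, emotion = "sad"), 0.25)
  expect_equal(attention_level(vt, emotion = "neutral"), 0.1)
  expect_equal(attention_shift(vt, "sad"), 0.25 - 0.1)
  expect_equal(attention_shift(vt, "happy"), 0 - 0.1)
  # per-emotion ALs over disjoint cells sum to at most 1
  expect_lte(sum(vapply(c("neutral", "sad", "happy", "angry"),
                        function(e) attention_level(vt, emotion = e),
                        numeric(1))), 1)
  # zero matrix time -> missing
  s0 <- gaze_series(stimulus_ref(2, 1),
                    data.frame(x = 900, y = 500, valid = FALSE))
  vt0 <- view_times(s0, fx$cells, fx$layout)
  expect_true(is.na(attention_level(vt0, cell = 1)))
  expect_true(is.na(attention_shift(vt0, "sad")))
})

test_that("view times and AL/AS equal the literal transcription on random series", {
  set.seed(303)
  fx <- matrix_fixture()
  for (rep in 1:100) {
    df <- data.frame(x = runif(40, 300, 1600), y = runif(40, 0, 1080),
                     valid = runif(40) > 0.1)
    s <- gaze_series(stimulus_ref(2, 1), df)
    vt <- view_times(s, fx$cells, fx$layout)
    o <- oracle_view_times(s$samples, fx$cells, fx$layout, 60)
    expect_equal(vt$T_matrix, o$T_matrix)
    expect_equal(unname(vt$T_cell), unname(o$T_cell))
    expect_equal(unname(vt$T_emotion[c("neutral", "sad", "happy", "angry")]),
                 unname(o$T_emotion))
    if (o$T_matrix > 0) {
      for (e in c("sad", "happy"))
        expect_equal(attention_shift(vt, e),
                     (o$T_emotion[[e]] - o$T_emotion[["neutral"]]) / o$T_matrix)
    }
  }
})

test_that("attention times implement switch-and-return counting", {
  fx <- matrix_fixture()
  seq_series <- function(cells_visited, n_each = 5) {
    pts <- do.call(rbind, lapply(cells_visited, function(cy)
      if (is.na(cy)) c(10, 10) else cell_center(fx$cells[[as.character(cy)]])))
    idx <- rep(seq_len(nrow(pts)), each = n_each)
    gaze_series(stimulus_ref(2, 1),
                data.frame(x = pts[idx, 1], y = pts[idx, 2]))
  }
  # happy (cell 4), neutral (1), happy: one completed switch-and-return
  expect_identical(attention_times(seq_series(c(4, 1, 4)), fx$cells, fx$layout,
                                   "happy"), 1L)
  # never leaves happy
  expect_identical(attention_times(seq_series(c(4, 4)), fx$cells, fx$layout,
                                   "happy"), 0L)
  # background-only excursion does not count by default, counts with the flag
  bg <- seq_series(c(4, NA, 4))
  expect_identical(attention_times(bg, fx$cells, fx$layout, "happy"), 0L)
  expect_identical(attention_times(bg, fx$cells, fx$layout, "happy",
                                   require_different_emotion = FALSE), 1L)
  # AT depends only on the visit sequence, not dwell lengths
  a <- attention_times(seq_series(c(4, 3, 4, 1, 4), n_each = 2),
                       fx$cells, fx$layout, "happy")
  b <- attention_times(seq_series(c(4, 3, 4, 1, 4), n_each = 25),
                       fx$cells, fx$layout, "happy")
  expect_identical(a, b)
  expect_identical(a, 2L)
})

test_that("attention times equal the finite-state oracle on random visit sequences", {
  set.seed(404)
  fx <- matrix_fixture()
  for (rep in 1:100) {
    visits <- sample(c(1:4, NA), sample(3:12, 1), replace = TRUE)
    pts <- do.call(rbind, lapply(visits, function(cy)
      if (is.na(cy)) c(10, 10) else cell_center(fx$cells[[as.character(cy)]])))
    idx <- rep(seq_len(nrow(pts)), each = 3)
    s <- gaze_series(stimulus_ref(2, 1),
                     data.frame(x = pts[idx, 1], y = pts[idx, 2]))
    emo_seq <- ifelse(is.na(visits), NA, unname(fx$layout[as.character(visits)]))
    emo_seq <- rep(emo_seq, each = 3)
    for (target in c("neutral", "sad", "happy", "angry")) {
      expect_identical(attention_times(s, fx$cells, fx$layout, target),
                       oracle_at(emo_seq, target))
      expect_identical(
        attention_times(s, fx$cells, fx$layout, target,
                        require_different_emotion = FALSE),
        oracle_at(emo_seq, target, require_different = FALSE))
    }
  }
})

test_that("emotion extraction emits per-cell and per-matrix biomarkers for all matrices", {
  ses <- simulate_gaze_session(gaze_policy(), seed = 9, subject = "E1", group = "LD")
  eb <- extract_emotion_biomarkers(ses)
  # per matrix: 2 per cell (FT, AL) + 4 AL + 4 AT + 2 AS
  expect_identical(nrow(eb), 4L * (2L * 4L + 10L) + 4L * (2L * 16L + 10L))
  expect_true("Task 2_P(4) Neutral_AL" %in% eb$name)
  expect_true("Task 2_P(4) Neutral_AT" %in% eb$name)
  expect_true("Task 4_P(4)3 Sad_FT" %in% eb$name)
  expect_true("Task 4_P(4)12 Happy_AL" %in% eb$name)
  # AS identity holds exactly on extracted values
  for (m in 1:4) {
    al <- function(nm) eb$value[eb$name == nm]
    base <- sprintf("Task 2_P(%d)", m)
    expect_equal(al(paste(base, "Sad_AS")),
                 al(paste(base, "Sad_AL")) - al(paste(base, "Neutral_AL")))
    expect_equal(al(paste(base, "Happy_AS")),
                 al(paste(base, "Happy_AL")) - al(paste(base, "Neutral_AL")))
  }
  # AL bounds
  alv <- eb$value[eb$metric == "AL" & !eb$missing]
  expect_true(all(alv >= 0 & alv <= 1))
})

test_that("a series confined to one sad cell drives that cell's AL and AS", {
  fx <- matrix_fixture()
  c3 <- cell_center(fx$cells[["3"]])
  ses <- session_log("C", "HD", list(
    gaze_series(stimulus_ref(2, 1),
                data.frame(x = rep(c3[1], 600), y = rep(c3[2], 600)))))
  eb <- extract_emotion_biomarkers(ses)
  val <- function(nm) eb$value[eb$name == nm]
  expect_equal(val("Task 2_P(1)3 Sad_AL"), 1)
  expect_equal(val("Task 2_P(1) Happy_AL"), 0)
  expect_equal(val("Task 2_P(1) Sad_AS"), 1)
})
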