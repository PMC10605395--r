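# Literal, loop-based transcriptions of the defining formulas, used as
# independent oracles. Deliberately naive; no shared code with R/.

oracle_in_rect <- function(x, y, rect) {
  x >= rect$x_min && x <= rect$x_max && y >= rect$y_min && y <= rect$y_max
}

oracle_membership <- function(s, rect) {
  out <- integer(nrow(s))
  for (i in seq_len(nrow(s)))
    out[i] <- if (isTRUE(s$valid[i]) && oracle_in_rect(s$x[i], s$y[i], rect)) 1L else 0L
  out
}

oracle_ft <- function(s, rect, sr) sum(oracle_membership(s, rect)) / sr

# maximal runs of consecutive member samples
oracle_runs <- function(member) {
  runs <- list()
  start <- NA
  for (i in seq_along(member)) {
    if (member[i] == 1L && is.na(start)) start <- i
    if ((member[i] == 0L || i == length(member)) && !is.na(start)) {
      end <- if (member[i] == 0L) i - 1L else i
      runs[[length(runs) + 1L]] <- c(start, end)
      start <- NA
    }
  }
  runs
}

oracle_track_stats <- function(s, rect, sr) {
  runs <- oracle_runs(oracle_membership(s, rect))
  dist <- vel <- numeric(length(runs))
  for (j in seq_along(runs)) {
    idx <- runs[[j]][1]:runs[[j]][2]
    d <- 0
    if (length(idx) > 1)
      for (i in seq_len(length(idx) - 1))
        d <- d + sqrt((s$x[idx[i + 1]] - s$x[idx[i]])^2 +
                      (s$y[idx[i + 1]] - s$y[idx[i]])^2)
    dist[j] <- d
    vel[j] <- sr * d / length(idx)
  }
  list(a = length(runs), distance = dist, velocity = vel,
       spl = sum(dist), ass = if (length(runs)) mean(vel) else NA_real_)
}

oracle_view_times <- function(s, cells, layout, sr) {
  T_cell <- sapply(names(cells), function(cy) oracle_ft(s, cells[[cy]], sr))
  T_matrix <- sum(s$valid) / sr
  T_emotion <- sapply(c("neutral", "sad", "happy", "angry"), function(e)
    sum(T_cell[layout[names(T_cell)] == e]))
  list(T_matrix = T_matrix, T_cell = T_cell, T_emotion = T_emotion)
}

# finite-state oracle for attention times over a per-sample emotion
# sequence (NA = background / outside all cells)
oracle_at <- function(emo_seq, target, require_different = TRUE) {
  count <- 0L
  visited <- FALSE       # target visited before
  eligible <- FALSE      # excursion qualifies for a "return"
  for (e in emo_seq) {
    if (is.na(e)) next_state <- "background"
    else if (e == target) next_state <- "target"
    else next_state <- "other"
    if (next_state == "target") {
      if (visited && eligible) count <- count + 1L
      visited <- TRUE
      eligible <- FALSE
    } else if (next_state == "other") {
      eligible <- TRUE
    } else if (!require_different && visited) {
      eligible <- TRUE   # background-only excursions count in this mode
    }
  }
  count
}

# brute-force BH step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (k in (m - 1):1) if (m > 1) q[k] <- min(q[k], q[k + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# pair-counting AUC with half credit for ties
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# random small gaze series around / across a rect, with invalid samples
random_series <- function(n = 30, p_invalid = 0.1,
                          ref = gazedep::stimulus_ref(1, 1)) {
  df <- data.frame(x = runif(n, 600, 1300), y = runif(n, 100, 1000),
                   valid = runif(n) > p_invalid)
  gazedep::gaze_series(ref, df)
}

test_rect <- function() gazedep::aoi_rect(700, 300, 1200, 800)
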