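#' @title Paradigm structure and gaze-log data model
#' @description Core data model for the four-task free-viewing paradigm:
#'   recording metadata, stimulus references, AOI rectangles, gaze series,
#'   and session logs with JSON read/write support.
#' @name paradigm
NULL

# stimulus counts per task; matrix tasks carry a fixed cell count
.TASK_STIMULI <- c(`1` = 8L, `2` = 4L, `3` = 12L, `4` = 4L)
.TASK_CELLS   <- c(`2` = 4L,  `4` = 16L)
.TASK_DURATION <- c(`1` = 5, `2` = 10, `3` = 5, `4` = 10)
.EMOTIONS <- c("neutral", "sad", "happy", "angry")

#' Recording specification
#'
#' Sampling rate and screen geometry of the eye tracker used to acquire a
#' session. Defaults match the acquisition setup: 60 Hz sampling on a
#' 1920 x 1080 pixel display.
#'
#' @param sampling_rate Samples per second (Hz). Must be positive.
#' @param screen_width,screen_height Screen size in pixels.
#' @param notes Free-text viewing metadata (distance, device, ...).
#' @return A `recording_spec` object.
#' @export
recording_spec <- function(sampling_rate = 60, screen_width = 1920,
                           screen_height = 1080, notes = "") {
  stopifnot(is.numeric(sampling_rate), length(sampling_rate) == 1,
            sampling_rate > 0, screen_width > 0, screen_height > 0)
  structure(list(sampling_rate = sampling_rate,
                 screen_width = as.integer(screen_width),
                 screen_height = as.integer(screen_height),
                 notes = as.character(notes)),
            class = "recording_spec")
}

#' Stimulus reference
#'
#' Identifies one presented stimulus: task `n` in 1..4, photo (or photo
#' matrix) `m`, and, for matrix tasks, optionally a cell `y`. Ranges are
#' validated against the paradigm definition: task 1 has 8 single photos,
#' task 2 has 4 two-by-two matrices, task 3 has 12 single photos, task 4
#' has 4 four-by-four matrices.
#'
#' @param task Task number, 1..4.
#' @param stimulus Photo / matrix number within the task.
#' @param cell Optional cell index within a matrix stimulus.
#' @return A `stimulus_ref` object.
#' @export
stimulus_ref <- function(task, stimulus, cell = NA_integer_) {
  task <- as.integer(task); stimulus <- as.integer(stimulus)
  cell <- as.integer(cell)
  if (!task %in% 1:4) stop("task must be in 1..4, got ", task)
  mmax <- .TASK_STIMULI[[as.character(task)]]
  if (is.na(stimulus) || stimulus < 1L || stimulus > mmax)
    stop(sprintf("task %d expects stimulus in [1,%d], got %s", task, mmax, stimulus))
  if (!is.na(cell)) {
    if (!task %in% c(2L, 4L))
      stop("cell index only valid for matrix tasks (2, 4)")
    ymax <- .TASK_CELLS[[as.character(task)]]
    if (cell < 1L || cell > ymax)
      stop(sprintf("task %d expects cell in [1,%d], got %d", task, ymax, cell))
  }
  structure(list(task = task, stimulus = stimulus, cell = cell),
            class = "stimulus_ref")
}

#' Abbreviated stimulus label
#'
#' Formats a stimulus reference as `"Task n_P(m)"` or `"Task n_P(m)y"`.
#'
#' @param task,stimulus,cell Components of the reference.
#' @return A character scalar.
#' @export
stimulus_label <- function(task, stimulus, cell = NA) {
  base <- sprintf("Task %d_P(%d)", as.integer(task), as.integer(stimulus))
  if (length(cell) && !is.na(cell)) paste0(base, as.integer(cell)) else base
}

#' Axis-aligned AOI rectangle
#'
#' An area of interest given by the pixel coordinates of its corners.
#' Bounds are inclusive: a gaze sample on the boundary belongs to the AOI.
#'
#' @param x_min,y_min,x_max,y_max Corner coordinates, pixels, origin at the
#'   top-left of the screen, y increasing downwards.
#' @return An `aoi_rect` object.
#' @export
aoi_rect <- function(x_min, y_min, x_max, y_max) {
  stopifnot(x_min <= x_max, y_min <= y_max)
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max),
            class = "aoi_rect")
}

#' AOI membership indicator
#'
#' Indicator of whether gaze coordinates fall inside an AOI rectangle,
#' with inclusive bounds. Invalid samples (tracking loss) never belong to
#' any AOI.
#'
#' @param x,y Gaze coordinates (vectors, pixels).
#' @param rect An [aoi_rect()].
#' @param valid Logical vector of tracking validity; defaults to all valid.
#' @return Integer vector of 0/1 indicators.
#' @export
aoi_membership <- function(x, y, rect, valid = TRUE) {
  stopifnot(inherits(rect, "aoi_rect"))
  valid <- rep_len(valid, length(x))
  inside <- x >= rect$x_min & x <= rect$x_max &
            y >= rect$y_min & y <= rect$y_max
  as.integer(inside & valid & !is.na(x) & !is.na(y))
}

#' Gaze series for one stimulus presentation
#'
#' Time-ordered screen-pixel gaze samples recorded while one stimulus was
#' on screen. Sample timing is reconstructed from the 1-based index and the
#' sampling rate (t_i = i / SR).
#'
#' @param ref A [stimulus_ref()].
#' @param samples Data frame with columns `i` (1-based index, strictly
#'   increasing), `x`, `y` (pixels) and `valid` (logical). A missing
#'   `valid` column defaults to `TRUE`; missing `i` defaults to row order.
#' @param recording A [recording_spec()].
#' @return A `gaze_series` object.
#' @export
gaze_series <- function(ref, samples, recording = recording_spec()) {
  stopifnot(inherits(ref, "stimulus_ref"), is.data.frame(samples))
  if (is.null(samples$i)) samples$i <- seq_len(nrow(samples))
  if (is.null(samples$valid)) samples$valid <- rep(TRUE, nrow(samples))
  samples <- samples[, c("i", "x", "y", "valid")]
  samples$i <- as.integer(samples$i)
  samples$valid <- as.logical(samples$valid)
  if (nrow(samples) && any(diff(samples$i) <= 0))
    stop("sample indices must be strictly increasing")
  # off-screen coordinates are kept but flagged invalid
  off <- !is.na(samples$x) & !is.na(samples$y) &
    (samples$x < 0 | samples$x > recording$screen_width |
     samples$y < 0 | samples$y > recording$screen_height)
  if (any(off)) {
    warning(sprintf("%d sample(s) outside screen bounds flagged invalid", sum(off)))
    samples$valid[off] <- FALSE
  }
  samples$valid[is.na(samples$x) | is.na(samples$y)] <- FALSE
  structure(list(ref = ref, samples = samples, recording = recording),
            class = "gaze_series")
}

#' @export
print.gaze_series <- function(x, ...) {
  cat(sprintf("<gaze_series %s: %d samples @ %g Hz>\n",
              stimulus_label(x$ref$task, x$ref$stimulus), nrow(x$samples),
              x$recording$sampling_rate))
  invisible(x)
}

series_key <- function(task, stimulus) sprintf("%d_%d", task, stimulus)

#' Default paradigm specification
#'
#' The canonical four-task free-viewing paradigm: task 1, eight single
#' European face photos shown for 5 s each in neutral/sad/happy/angry
#' order (two actors); task 2, four 2x2 European face-photo matrices shown
#' for 10 s (neutral upper-left, angry upper-right, sad lower-left, happy
#' lower-right); task 3, twelve single Asian face photos for 5 s each
#' (three actors, neutral/sad/happy/angry order); task 4, four 4x4 Asian
#' matrices for 10 s. The 4x4 cell-to-emotion layout is not prescribed by
#' the paradigm and is configuration; the packaged default is an arbitrary
#' balanced layout (four cells per emotion) documented in the vignette.
#'
#' @return A `paradigm_spec`: list of per-stimulus entries with fields
#'   `task`, `stimulus`, `kind` ("single" or "matrix"), `duration`
#'   (seconds) and `layout` (cell/emotion mapping).
#' @export
default_paradigm <- function() {
  stimuli <- list()
  t1 <- rep(.EMOTIONS, 2)
  for (m in 1:8)
    stimuli[[series_key(1L, m)]] <- list(task = 1L, stimulus = m, kind = "single",
                                         duration = 5, layout = t1[m])
  lay2 <- c(`1` = "neutral", `2` = "angry", `3` = "sad", `4` = "happy")
  for (m in 1:4)
    stimuli[[series_key(2L, m)]] <- list(task = 2L, stimulus = m, kind = "matrix",
                                         duration = 10, layout = lay2)
  t3 <- rep(.EMOTIONS, 3)
  for (m in 1:12)
    stimuli[[series_key(3L, m)]] <- list(task = 3L, stimulus = m, kind = "single",
                                         duration = 5, layout = t3[m])
  # balanced default 4x4 layout (row-major); four cells per emotion
  lay4 <- c("neutral", "angry", "sad", "happy",
            "happy", "neutral", "angry", "sad",
            "angry", "neutral", "sad", "happy",
            "neutral", "angry", "sad", "happy")
  names(lay4) <- as.character(1:16)
  for (m in 1:4)
    stimuli[[series_key(4L, m)]] <- list(task = 4L, stimulus = m, kind = "matrix",
                                         duration = 10, layout = lay4)
  structure(list(stimuli = stimuli), class = "paradigm_spec")
}

#' Default AOI configuration
#'
#' AOI rectangles for every stimulus of the default paradigm on a
#' 1920 x 1080 screen. Single-face photos carry five nested rectangles —
#' overall (O), face (F), eye-to-mouth (EM), eye-to-nose (EN) and eye (E)
#' — centred on the display; matrix stimuli carry one rectangle per cell.
#' Pixel bounds are configuration (the paradigm defines the AOI taxonomy,
#' not its geometry); these defaults place a 1000 x 1000 px photo region
#' centred on screen with anatomically ordered nested feature boxes.
#'
#' @param paradigm A `paradigm_spec`.
#' @return An `aoi_config`: list keyed like the paradigm's stimuli; each
#'   entry is a named list of [aoi_rect()] (names O/F/EM/EN/E for single
#'   faces, cell indices for matrices).
#' @export
default_aois <- function(paradigm = default_paradigm()) {
  single <- list(
    O  = aoi_rect(460, 40, 1460, 1040),
    F  = aoi_rect(660, 190, 1260, 890),
    EM = aoi_rect(710, 340, 1210, 740),
    EN = aoi_rect(735, 340, 1185, 640),
    E  = aoi_rect(760, 340, 1160, 490))
  grid_cells <- function(nrow, ncol, cell_w, cell_h, gap) {
    total_w <- ncol * cell_w + (ncol - 1) * gap
    total_h <- nrow * cell_h + (nrow - 1) * gap
    x0 <- (1920 - total_w) / 2; y0 <- (1080 - total_h) / 2
    cells <- list()
    for (r in seq_len(nrow)) for (c in seq_len(ncol)) {
      idx <- (r - 1) * ncol + c
      xm <- x0 + (c - 1) * (cell_w + gap)
      ym <- y0 + (r - 1) * (cell_h + gap)
      cells[[as.character(idx)]] <- aoi_rect(xm, ym, xm + cell_w, ym + cell_h)
    }
    cells
  }
  m2 <- grid_cells(2, 2, 450, 450, 30)
  m4 <- grid_cells(4, 4, 220, 220, 20)
  cfg <- list()
  for (key in names(paradigm$stimuli)) {
    st <- paradigm$stimuli[[key]]
    cfg[[key]] <- if (st$kind == "single") single
                  else if (st$task == 2L) m2 else m4
  }
  structure(cfg, class = "aoi_config")
}

#' Validate a paradigm specification
#'
#' Report-only check of a paradigm spec against the canonical task
#' structure: stimulus counts (8/4/12/4), durations (5 s single, 10 s
#' matrix), matrix cell counts (4 or 16) and complete emotion layouts.
#'
#' @param spec A `paradigm_spec`.
#' @return Character vector of violation messages; empty when canonical.
#' @export
validate_paradigm <- function(spec) {
  out <- character()
  for (n in 1:4) {
    keys <- names(spec$stimuli)[vapply(spec$stimuli, function(s) s$task == n, logical(1))]
    expect_m <- .TASK_STIMULI[[as.character(n)]]
    got <- sort(vapply(spec$stimuli[keys], function(s) s$stimulus, integer(1)))
    if (!identical(as.integer(got), seq_len(expect_m)))
      out <- c(out, sprintf("task %d expects m in [1,%d], found %d stimuli",
                            n, expect_m, length(got)))
    for (k in keys) {
      st <- spec$stimuli[[k]]
      dur <- .TASK_DURATION[[as.character(n)]]
      if (!isTRUE(all.equal(st$duration, dur)))
        out <- c(out, sprintf("%s: duration %g, expected %g",
                              stimulus_label(n, st$stimulus), st$duration, dur))
      if (n %in% c(2L, 4L)) {
        ncell <- .TASK_CELLS[[as.character(n)]]
        if (length(st$layout) != ncell)
          out <- c(out, sprintf("%s: %d cells, expected %d",
                                stimulus_label(n, st$stimulus), length(st$layout), ncell))
        if (!all(st$layout %in% .EMOTIONS))
          out <- c(out, sprintf("%s: unknown emotion label",
                                stimulus_label(n, st$stimulus)))
      } else if (!(length(st$layout) == 1 && st$layout %in% .EMOTIONS)) {
        out <- c(out, sprintf("%s: single-face stimulus needs one emotion label",
                              stimulus_label(n, st$stimulus)))
      }
    }
  }
  out
}

expected_series_keys <- function(paradigm = default_paradigm())
  names(paradigm$stimuli)

#' Session log
#'
#' All gaze series recorded for one subject across the paradigm. A session
#' is complete when every stimulus of the paradigm (8 + 4 + 12 + 4 = 28)
#' has a series.
#'
#' @param subject Subject identifier.
#' @param group Group label: `"HD"`, `"LD"` or `"unknown"`.
#' @param series List of [gaze_series()].
#' @param recording A [recording_spec()].
#' @param paradigm A `paradigm_spec` used to assess completeness.
#' @return A `session_log` with a `complete` flag.
#' @export
session_log <- function(subject, group = "unknown", series = list(),
                        recording = recording_spec(),
                        paradigm = default_paradigm()) {
  stopifnot(group %in% c("HD", "LD", "unknown"))
  keys <- vapply(series, function(s) series_key(s$ref$task, s$ref$stimulus), character(1))
  if (anyDuplicated(keys)) stop("duplicate series for one stimulus")
  names(series) <- keys
  complete <- setequal(keys, expected_series_keys(paradigm)) &&
    length(keys) == length(expected_series_keys(paradigm))
  structure(list(subject = as.character(subject), group = group,
                 series = series, recording = recording, complete = complete),
            class = "session_log")
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf("<session_log %s [%s]: %d series, %s>\n", x$subject, x$group,
              length(x$series), if (x$complete) "complete" else "INCOMPLETE"))
  invisible(x)
}

#' Write a session log to JSON
#'
#' Serialises a session to the documented schema (version 1): top level
#' `subject`, `group`, `recording` (sr/width/height), and `series`, each
#' with `task`, `stimulus` and per-sample `i`, `x`, `y`, `valid`.
#'
#' @param session A [session_log()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  ser <- unname(lapply(session$series, function(s) list(
    task = s$ref$task, stimulus = s$ref$stimulus,
    samples = list(i = s$samples$i, x = s$samples$x, y = s$samples$y,
                   valid = s$samples$valid))))
  obj <- list(schema = "gazedep-session/1",
              subject = session$subject, group = session$group,
              recording = list(sr = session$recording$sampling_rate,
                               width = session$recording$screen_width,
                               height = session$recording$screen_height),
              series = ser)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a session log from JSON
#'
#' Parses a session written by [write_session_log()] (or by the
#' acquisition system using the same schema), validates fields, and
#' flags the session incomplete when any paradigm stimulus is missing.
#'
#' @param path JSON file path.
#' @param paradigm A `paradigm_spec` for completeness checking.
#' @return A [session_log()].
#' @export
load_session_log <- function(path, paradigm = default_paradigm()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (f in c("subject", "recording", "series"))
    if (is.null(obj[[f]])) stop("session log missing field '", f, "'")
  rec <- obj$recording
  for (f in c("sr", "width", "height"))
    if (is.null(rec[[f]])) stop("recording block missing field '", f, "'")
  recording <- recording_spec(rec$sr, rec$width, rec$height)
  series <- lapply(obj$series, function(s) {
    for (f in c("task", "stimulus", "samples"))
      if (is.null(s[[f]])) stop("series entry missing field '", f, "'")
    smp <- s$samples
    if (is.null(smp$x) || is.null(smp$y)) stop("samples block missing field 'x'/'y'")
    df <- data.frame(i = if (is.null(smp$i)) seq_along(smp$x) else smp$i,
                     x = as.numeric(smp$x), y = as.numeric(smp$y),
                     valid = if (is.null(smp$valid)) TRUE else as.logical(smp$valid))
    gaze_series(stimulus_ref(s$task, s$stimulus), df, recording)
  })
  session_log(obj$subject, if (is.null(obj$group)) "unknown" else obj$group,
              series, recording, paradigm)
}

#' Write a paradigm + AOI configuration file
#'
#' Serialises a paradigm spec and its AOI rectangles to YAML or JSON
#' (chosen by file extension), the format consumed by
#' [read_paradigm_config()]. Rectangles are stored as
#' `[x_min, y_min, x_max, y_max]`.
#'
#' @param paradigm A `paradigm_spec`.
#' @param aois An `aoi_config`.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_paradigm_config <- function(paradigm, aois, path) {
  obj <- list(schema = "gazedep-paradigm/1", stimuli = list())
  for (key in names(paradigm$stimuli)) {
    st <- paradigm$stimuli[[key]]
    obj$stimuli[[key]] <- list(
      task = st$task, stimulus = st$stimulus, kind = st$kind,
      duration = st$duration, layout = as.list(st$layout),
      aois = lapply(aois[[key]], function(r)
        c(r$x_min, r$y_min, r$x_max, r$y_max)))
  }
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(obj, path)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a paradigm + AOI configuration file
#'
#' Parses a YAML or JSON configuration written by
#' [write_paradigm_config()] (or authored by hand to the same schema)
#' and validates the rectangles.
#'
#' @param path Configuration file path.
#' @return List with elements `paradigm` (a `paradigm_spec`) and `aois`
#'   (an `aoi_config`).
#' @export
read_paradigm_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  if (is.null(obj$stimuli)) stop("paradigm config missing field 'stimuli'")
  stimuli <- list(); aois <- list()
  for (key in names(obj$stimuli)) {
    e <- obj$stimuli[[key]]
    for (f in c("task", "stimulus", "kind", "duration", "layout", "aois"))
      if (is.null(e[[f]])) stop("stimulus '", key, "' missing field '", f, "'")
    layout <- unlist(e$layout)
    if (e$kind == "single" && is.null(names(layout))) names(layout) <- NULL
    stimuli[[key]] <- list(task = as.integer(e$task),
                           stimulus = as.integer(e$stimulus),
                           kind = e$kind, duration = as.numeric(e$duration),
                           layout = layout)
    aois[[key]] <- lapply(e$aois, function(v) {
      v <- as.numeric(unlist(v))
      if (length(v) != 4) stop("AOI rectangle in '", key, "' needs 4 numbers")
      aoi_rect(v[1], v[2], v[3], v[4])
    })
  }
  list(paradigm = structure(list(stimuli = stimuli), class = "paradigm_spec"),
       aois = structure(aois, class = "aoi_config"))
}
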