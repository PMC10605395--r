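#' @title Facial emotional perception biomarkers
#' @description Fixation time (FT), attention level (AL), attention shift
#'   (AS) and attention times (AT) for the face-photo-matrix viewing tasks
#'   (tasks 2 and 4).
#' @name emotions
NULL

#' Viewing-time table for a matrix stimulus
#'
#' Tallies, from raw samples, the total matrix viewing time, the time on
#' each cell, and the time on each emotion category. The matrix viewing
#' time is the count of valid samples during the presentation divided by
#' the sampling rate, so tracking loss shrinks numerator and denominator
#' coherently; set `nominal_duration` to use the scheduled presentation
#' duration instead.
#'
#' @param series A [gaze_series()] of a matrix stimulus.
#' @param cells Named list of [aoi_rect()], one per cell.
#' @param layout Named character vector mapping cell index to emotion.
#' @param sr Sampling rate (Hz).
#' @param nominal_duration Optional scheduled duration (seconds) to use
#'   as the denominator time instead of the valid-sample time.
#' @return A `view_times` list: `T_matrix` (s), `T_cell` (named, s),
#'   `T_emotion` (named, s).
#' @export
view_times <- function(series, cells, layout,
                       sr = series$recording$sampling_rate,
                       nominal_duration = NULL) {
  stopifnot(sr > 0, all(names(cells) %in% names(layout)))
  s <- series$samples
  T_cell <- vapply(names(cells), function(cy)
    sum(aoi_membership(s$x, s$y, cells[[cy]], s$valid)) / sr, numeric(1))
  T_matrix <- if (is.null(nominal_duration)) sum(s$valid) / sr
              else nominal_duration
  T_emotion <- vapply(.EMOTIONS, function(e)
    sum(T_cell[names(T_cell)[layout[names(T_cell)] == e]]), numeric(1))
  structure(list(T_matrix = T_matrix, T_cell = T_cell, T_emotion = T_emotion,
                 layout = layout[names(cells)]),
            class = "view_times")
}

#' Attention level
#'
#' Fraction of matrix viewing time spent on a target: either one cell
#' (`cell`) or all cells of one emotion (`emotion`). Missing (`NA`) when
#' the matrix viewing time is zero.
#'
#' @param times A [view_times()] table.
#' @param cell Cell index (character or integer), or `NULL`.
#' @param emotion Emotion label, or `NULL`. Exactly one of `cell`/`emotion`
#'   must be given.
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
attention_level <- function(times, cell = NULL, emotion = NULL) {
  stopifnot(inherits(times, "view_times"), xor(is.null(cell), is.null(emotion)))
  if (times$T_matrix <= 0) return(NA_real_)
  num <- if (!is.null(cell)) times$T_cell[[as.character(cell)]]
         else times$T_emotion[[emotion]]
  num / times$T_matrix
}

#' Attention shift
#'
#' An emotion's attention level minus the neutral attention level on the
#' same matrix: `AS_e = AL_e - AL_neutral`, for e in {sad, happy}.
#' Propagates missingness.
#'
#' @param times A [view_times()] table.
#' @param emotion `"sad"` or `"happy"`.
#' @return Proportion difference in `[-1, 1]`, or `NA`.
#' @export
attention_shift <- function(times, emotion = c("sad", "happy")) {
  emotion <- match.arg(emotion)
  attention_level(times, emotion = emotion) -
    attention_level(times, emotion = "neutral")
}

# per-sample cell index (NA = background/invalid), used by attention_times
cell_sequence <- function(series, cells) {
  s <- series$samples
  idx <- rep(NA_integer_, nrow(s))
  for (cy in names(cells)) {
    hit <- aoi_membership(s$x, s$y, cells[[cy]], s$valid) == 1L
    idx[hit] <- as.integer(cy)
  }
  idx
}

#' Attention times
#'
#' Number of switch-and-return gaze cycles into the cells of a target
#' emotion: the count of re-entries into the target-emotion cell set
#' after at least one intervening sample inside a cell of a *different*
#' emotion. The initial entry is not counted, and excursions that touch
#' only the background (no cell) do not count. Set
#' `require_different_emotion = FALSE` to count every re-entry, including
#' after background-only excursions.
#'
#' @param series A [gaze_series()] of a matrix stimulus.
#' @param cells Named list of cell [aoi_rect()].
#' @param layout Named character vector mapping cell index to emotion.
#' @param emotion Target emotion label.
#' @param require_different_emotion Convention flag (default `TRUE`).
#' @return Non-negative integer count.
#' @export
attention_times <- function(series, cells, layout, emotion,
                            require_different_emotion = TRUE) {
  idx <- cell_sequence(series, cells)
  emo <- ifelse(is.na(idx), NA_character_, unname(layout[as.character(idx)]))
  if (require_different_emotion) {
    seq_emo <- emo[!is.na(emo)]               # background does not break cycles
    if (!length(seq_emo)) return(0L)
    seq_emo <- rle(seq_emo)$values            # compress dwells
    max(0L, sum(seq_emo == emotion) - 1L)
  } else {
    on_target <- !is.na(emo) & emo == emotion # any re-entry counts
    r <- rle(on_target)
    max(0L, sum(r$values) - 1L)
  }
}

#' Extract facial-emotional-perception biomarkers from a session
#'
#' For every matrix stimulus (tasks 2 and 4): per-cell fixation time and
#' attention level, per-emotion (matrix-level) attention level, sad and
#' happy attention shifts, and per-emotion attention times. Naming
#' follows the published abbreviations (`"Task 4_P(4)3 Sad_FT"` for cell
#' metrics, `"Task 2_P(4) Neutral_AL"` for matrix-level metrics).
#'
#' @param session A [session_log()].
#' @param aois An `aoi_config`.
#' @param paradigm A `paradigm_spec`.
#' @param require_different_emotion Passed to [attention_times()].
#' @return A tibble with the same columns as
#'   [extract_feature_biomarkers()]; `aoi` carries the cell index or
#'   `"matrix"`.
#' @export
extract_emotion_biomarkers <- function(session, aois = default_aois(),
                                       paradigm = default_paradigm(),
                                       require_different_emotion = TRUE) {
  cap <- function(e) paste0(toupper(substring(e, 1, 1)), substring(e, 2))
  rows <- list()
  add <- function(st, cell, emotion, metric, aoi, value, missing, name) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      subject = session$subject, group = session$group,
      task = st$task, stimulus = st$stimulus, cell = cell,
      emotion = emotion, metric = metric, aoi = aoi,
      value = value, missing = missing, name = name)
  }
  for (key in names(paradigm$stimuli)) {
    st <- paradigm$stimuli[[key]]
    if (st$kind != "matrix") next
    cells <- aois[[key]]
    layout <- st$layout
    ser <- session$series[[key]]
    vt <- if (!is.null(ser)) view_times(ser, cells, layout)
    mlab <- stimulus_label(st$task, st$stimulus)
    for (cy in names(cells)) {
      e <- unname(layout[cy]); clab <- stimulus_label(st$task, st$stimulus, cy)
      ft <- if (is.null(ser)) NA_real_ else unname(vt$T_cell[cy])
      al <- if (is.null(ser)) NA_real_ else attention_level(vt, cell = cy)
      add(st, as.integer(cy), e, "FT", cy, ft, is.na(ft),
          sprintf("%s %s_FT", clab, cap(e)))
      add(st, as.integer(cy), e, "AL", cy, al, is.na(al),
          sprintf("%s %s_AL", clab, cap(e)))
    }
    for (e in .EMOTIONS) {
      al <- if (is.null(ser)) NA_real_ else attention_level(vt, emotion = e)
      add(st, NA_integer_, e, "AL", "matrix", al, is.na(al),
          sprintf("%s %s_AL", mlab, cap(e)))
      at <- if (is.null(ser)) NA_real_
            else as.numeric(attention_times(ser, cells, layout, e,
                                            require_different_emotion))
      add(st, NA_integer_, e, "AT", "matrix", at, is.na(at),
          sprintf("%s %s_AT", mlab, cap(e)))
    }
    for (e in c("sad", "happy")) {
      as_ <- if (is.null(ser)) NA_real_ else attention_shift(vt, e)
      add(st, NA_integer_, e, "AS", "matrix", as_, is.na(as_),
          sprintf("%s %s_AS", mlab, cap(e)))
    }
  }
  do.call(rbind, rows)
}

#' Pivot tidy biomarkers to a subjects-by-biomarkers table
#'
#' Turns long-format biomarker rows (one row per subject x biomarker,
#' from the extraction functions, possibly row-bound over subjects) into
#' the wide table the statistics and screening stages consume: one row
#' per subject, one column per biomarker `name`, plus `subject` and
#' `group`.
#'
#' @param biomarkers Tidy tibble from the extraction functions.
#' @return A data frame (`biomarker_table`) with `subject`, `group`, and
#'   one numeric column per biomarker.
#' @export
pivot_biomarkers <- function(biomarkers) {
  subj <- unique(biomarkers[, c("subject", "group")])
  if (anyDuplicated(subj$subject)) stop("subjects with conflicting group labels")
  nm <- unique(biomarkers$name)
  out <- as.data.frame(subj, stringsAsFactors = FALSE)
  for (b in nm) {
    sub <- biomarkers[biomarkers$name == b, ]
    out[[b]] <- sub$value[match(out$subject, sub$subject)]
  }
  rownames(out) <- NULL
  out
}
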