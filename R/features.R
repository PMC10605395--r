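#' @title Facial feature perception biomarkers
#' @description Fixation time (FT), scan-path length (SPL) and average
#'   scanning speed (ASS) per AOI for the single-face viewing tasks
#'   (tasks 1 and 3). All metrics are computed directly on raw 60 Hz
#'   samples; no fixation/saccade event detection is applied.
#' @name features
NULL

.FEATURE_AOIS <- c("O", "F", "EM", "EN", "E")

#' Fixation time in an AOI
#'
#' Total time gaze dwelt inside an AOI rectangle: the count of valid
#' in-AOI samples divided by the sampling rate.
#'
#' @param series A [gaze_series()].
#' @param rect An [aoi_rect()].
#' @param sr Sampling rate (Hz); defaults to the series' recording.
#' @return Seconds (0 for an empty series).
#' @export
fixation_time <- function(series, rect, sr = series$recording$sampling_rate) {
  stopifnot(sr > 0)
  s <- series$samples
  if (!nrow(s)) return(0)
  sum(aoi_membership(s$x, s$y, rect, s$valid)) / sr
}

#' Segment continuous in-AOI gaze tracks
#'
#' Splits a gaze series into maximal runs of consecutive valid samples
#' inside an AOI. Continuity is broken by any out-of-AOI sample and by
#' any invalid sample. Each track carries its length in samples (`k`),
#' its summed consecutive Euclidean step length (`distance`, pixels) and
#' its speed `velocity = sr * distance / k` (pixels/second); a
#' single-sample track has distance and velocity 0.
#'
#' @param series A [gaze_series()].
#' @param rect An [aoi_rect()].
#' @param sr Sampling rate (Hz).
#' @return A `track_set`: list with `tracks` (data frame: `start`, `end`,
#'   `k`, `distance`, `velocity`, row per track in time order) and `a`
#'   (the track count).
#' @export
segment_tracks <- function(series, rect, sr = series$recording$sampling_rate) {
  s <- series$samples
  member <- aoi_membership(s$x, s$y, rect, s$valid) == 1L
  if (!length(member) || !any(member)) {
    tracks <- data.frame(start = integer(), end = integer(), k = integer(),
                         distance = numeric(), velocity = numeric())
    return(structure(list(tracks = tracks, a = 0L, sr = sr), class = "track_set"))
  }
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  dist <- numeric(length(starts)); vel <- numeric(length(starts))
  for (j in seq_along(starts)) {
    idx <- starts[j]:ends[j]
    k <- length(idx)
    d <- if (k > 1)
      sum(sqrt(diff(s$x[idx])^2 + diff(s$y[idx])^2)) else 0
    dist[j] <- d
    vel[j] <- sr * d / k
  }
  tracks <- data.frame(start = starts, end = ends,
                       k = ends - starts + 1L, distance = dist, velocity = vel)
  structure(list(tracks = tracks, a = nrow(tracks), sr = sr), class = "track_set")
}

#' Scan-path length
#'
#' Total in-AOI scan-path length: the sum over continuous tracks of the
#' within-track consecutive Euclidean distances. Distances across track
#' breaks are not counted.
#'
#' @param tracks A `track_set` from [segment_tracks()].
#' @return Pixels (0 when there are no tracks).
#' @export
scan_path_length <- function(tracks) {
  stopifnot(inherits(tracks, "track_set"))
  if (tracks$a == 0L) 0 else sum(tracks$tracks$distance)
}

#' Average scanning speed
#'
#' Unweighted mean of per-track speeds, each track's speed being
#' `sr * distance / k`. Undefined (missing, `NA`) when the AOI holds no
#' tracks; single-sample tracks contribute speed 0.
#'
#' @param tracks A `track_set` from [segment_tracks()].
#' @param sr Sampling rate (Hz); defaults to the rate the tracks were
#'   segmented with.
#' @return Pixels/second, or `NA` when no tracks exist.
#' @export
average_scanning_speed <- function(tracks, sr = tracks$sr) {
  stopifnot(inherits(tracks, "track_set"), sr > 0)
  if (tracks$a == 0L) return(NA_real_)
  mean(sr * tracks$tracks$distance / tracks$tracks$k)
}

#' Extract facial-feature-perception biomarkers from a session
#'
#' Computes FT, SPL and ASS for each of the five nested AOIs (O, F, EM,
#' EN, E) of every single-face stimulus (tasks 1 and 3): 15 biomarkers
#' per photo, 300 for a complete session. Emotion labels are attached
#' from the paradigm's stimulus layout. Missing series yield rows with
#' `missing = TRUE`.
#'
#' @param session A [session_log()].
#' @param aois An `aoi_config` (see [default_aois()]).
#' @param paradigm A `paradigm_spec`.
#' @return A tibble with columns `subject`, `group`, `task`, `stimulus`,
#'   `cell` (`NA` here), `emotion`, `metric` (`FT`/`SPL`/`ASS`), `aoi`,
#'   `value`, `missing` and `name` (the standard abbreviated biomarker label such as
#'   `"Task 1_P(2) Sad(FT,O)"`).
#' @export
extract_feature_biomarkers <- function(session, aois = default_aois(),
                                       paradigm = default_paradigm()) {
  rows <- list()
  for (key in names(paradigm$stimuli)) {
    st <- paradigm$stimuli[[key]]
    if (st$kind != "single") next
    emo <- unname(st$layout[1])
    ser <- session$series[[key]]
    for (aoi in .FEATURE_AOIS) {
      if (is.null(ser)) {
        vals <- c(FT = NA_real_, SPL = NA_real_, ASS = NA_real_)
        miss <- c(TRUE, TRUE, TRUE)
      } else {
        rect <- aois[[key]][[aoi]]
        ts <- segment_tracks(ser, rect)
        ass <- average_scanning_speed(ts)
        vals <- c(FT = fixation_time(ser, rect),
                  SPL = scan_path_length(ts), ASS = ass)
        miss <- c(FALSE, FALSE, is.na(ass))
      }
      lab <- stimulus_label(st$task, st$stimulus)
      emo_cap <- paste0(toupper(substring(emo, 1, 1)), substring(emo, 2))
      for (mi in seq_along(vals)) {
        metric <- names(vals)[mi]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = session$subject, group = session$group,
          task = st$task, stimulus = st$stimulus, cell = NA_integer_,
          emotion = emo, metric = metric, aoi = aoi,
          value = unname(vals[mi]), missing = miss[mi],
          name = sprintf("%s %s(%s,%s)", lab, emo_cap, metric, aoi))
      }
    }
  }
  do.call(rbind, rows)
}
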