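#' @title End-to-end pipeline
#' @description Orchestration of the full analysis: simulate or ingest
#'   sessions, extract biomarkers, compare groups, select biomarkers,
#'   evaluate screening performance, render heat maps, and write a
#'   machine-readable run report.
#' @name pipeline
NULL

#' Pipeline run configuration
#'
#' @param mode Input mode: `"simulate"` (stream-level synthetic
#'   sessions), `"sessions"` (JSON session-log files) or
#'   `"feature_table"` (a ready biomarker table / CSV).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed used for every stochastic stage.
#' @param n_per_group Subjects per group in simulate mode.
#' @param session_paths Character vector of JSON paths (sessions mode).
#' @param feature_table A `biomarker_table` data frame or CSV path
#'   (feature_table mode).
#' @param fdr_family,levene_alpha Options of [compare_groups()].
#' @param entry_alpha,removal_alpha Options of [forward_stepwise()].
#' @param exclusion_threshold Maximum tolerated fraction of missing /
#'   invalid samples in any task before a session is excluded.
#' @param heatmap_stimuli List of `c(task, stimulus)` pairs to render.
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "sessions", "feature_table"),
                       out_dir = tempfile("gazedep-run-"), seed = 1,
                       n_per_group = 29, session_paths = NULL,
                       feature_table = NULL,
                       fdr_family = "per_task", levene_alpha = 0.05,
                       entry_alpha = 0.05, removal_alpha = 0.10,
                       exclusion_threshold = 0.2,
                       heatmap_stimuli = list(c(1, 1), c(1, 2))) {
  mode <- match.arg(mode)
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 n_per_group = n_per_group, session_paths = session_paths,
                 feature_table = feature_table, fdr_family = fdr_family,
                 levene_alpha = levene_alpha, entry_alpha = entry_alpha,
                 removal_alpha = removal_alpha,
                 exclusion_threshold = exclusion_threshold,
                 heatmap_stimuli = heatmap_stimuli),
            class = "run_config")
}

session_missing_fraction <- function(session, paradigm = default_paradigm()) {
  worst <- 0
  for (n in 1:4) {
    keys <- names(paradigm$stimuli)[vapply(paradigm$stimuli,
                                           function(s) s$task == n, logical(1))]
    expected <- sum(vapply(paradigm$stimuli[keys], function(s)
      round(s$duration * session$recording$sampling_rate), numeric(1)))
    got <- 0
    for (k in keys) {
      ser <- session$series[[k]]
      if (!is.null(ser)) got <- got + sum(ser$samples$valid)
    }
    worst <- max(worst, 1 - got / expected)
  }
  worst
}

#' Run the full screening pipeline
#'
#' Executes the stages in order — input (simulate / load sessions / load
#' feature table), biomarker extraction, group comparison, forward
#' stepwise selection, ROC evaluation, heat maps — and writes artifacts
#' to `config$out_dir`: `biomarkers.csv` (tidy), `biomarker_table.csv`
#' (wide), `comparison.csv`, `model.json`, `roc.png`, `heatmap_*.png`
#' and `report.json` (seed, config hash, stage checksums). Sessions
#' missing more than `exclusion_threshold` of their expected valid
#' samples in any task are excluded and listed in the report.
#'
#' @param config A [run_config()].
#' @return The run report (list), invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paradigm <- default_paradigm()
  aois <- default_aois(paradigm)
  report <- list(seed = config$seed, mode = config$mode,
                 package_version = as.character(utils::packageVersion("gazedep")),
                 excluded_subjects = character(0))
  stage <- "input"
  res <- tryCatch({
    table <- NULL
    sessions <- NULL
    if (config$mode == "simulate") {
      sessions <- simulate_cohort_sessions(config$n_per_group, config$seed,
                                           paradigm = paradigm, aois = aois)
    } else if (config$mode == "sessions") {
      stopifnot(length(config$session_paths) > 0)
      sessions <- lapply(config$session_paths, load_session_log, paradigm = paradigm)
    } else {
      table <- config$feature_table
      if (is.character(table))
        table <- utils::read.csv(table, check.names = FALSE, stringsAsFactors = FALSE)
    }
    if (!is.null(sessions)) {
      stage <- "extract"
      frac <- vapply(sessions, session_missing_fraction, numeric(1),
                     paradigm = paradigm)
      excl <- frac > config$exclusion_threshold
      report$excluded_subjects <- vapply(sessions[excl], `[[`, character(1), "subject")
      sessions <- sessions[!excl]
      tidy <- do.call(rbind, lapply(sessions, function(s)
        rbind(extract_feature_biomarkers(s, aois, paradigm),
              extract_emotion_biomarkers(s, aois, paradigm))))
      utils::write.csv(tidy, file.path(config$out_dir, "biomarkers.csv"),
                       row.names = FALSE)
      table <- pivot_biomarkers(tidy)
    }
    utils::write.csv(table, file.path(config$out_dir, "biomarker_table.csv"),
                     row.names = FALSE)
    stage <- "compare"
    comparison <- compare_groups(table, fdr_family = config$fdr_family,
                                 levene_alpha = config$levene_alpha)
    utils::write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE)
    stage <- "select"
    candidates <- comparison$biomarker[comparison$p < 0.05]
    model <- NULL; screening <- NULL
    if (length(candidates)) {
      cc <- stats::complete.cases(table[, candidates, drop = FALSE])
      model <- forward_stepwise(table[cc, candidates, drop = FALSE],
                                table$group[cc],
                                config$entry_alpha, config$removal_alpha)
      stage <- "evaluate"
      if (length(model$selected)) {
        screening <- evaluate_screening(table, model$selected)
        grDevices::png(file.path(config$out_dir, "roc.png"), 640, 640)
        plot(screening$combined$curve$fpr, screening$combined$curve$sensitivity,
             type = "s", xlab = "1 - specificity", ylab = "sensitivity",
             main = sprintf("Combined ROC (AUC = %.3f)", screening$combined$auc))
        graphics::abline(0, 1, lty = 2)
        grDevices::dev.off()
      }
      jsonlite::write_json(list(
        selected = model$selected,
        intercept = model$intercept,
        coefficients = as.list(model$coefficients),
        entry_alpha = config$entry_alpha, removal_alpha = config$removal_alpha,
        separation = model$separation, seed = config$seed),
        file.path(config$out_dir, "model.json"), auto_unbox = TRUE, digits = NA)
    }
    stage <- "heatmaps"
    if (!is.null(sessions)) {
      for (hs in config$heatmap_stimuli) {
        for (grp in c("HD", "LD")) {
          sel <- Filter(function(s) s$group == grp, sessions)
          if (!length(sel)) next
          hm <- group_gaze_density(sel, hs[1], hs[2], cell = 8)
          key <- series_key(as.integer(hs[1]), as.integer(hs[2]))
          st <- paradigm$stimuli[[key]]
          bg <- placeholder_face(if (st$kind == "single") "single" else "matrix",
                                 cells = if (st$kind == "matrix") aois[[key]],
                                 cell = 8)
          render_overlay(hm, bg,
                         file.path(config$out_dir,
                                   sprintf("heatmap_task%s_p%s_%s.png",
                                           hs[1], hs[2], grp)))
        }
      }
    }
    list(comparison = comparison, model = model, screening = screening,
         table = table)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  artifacts <- list.files(config$out_dir, full.names = TRUE)
  artifacts <- artifacts[basename(artifacts) != "report.json"]
  report$n_subjects <- nrow(res$table)
  report$n_biomarkers <- ncol(res$table) - 2L
  report$n_significant <- sum(res$comparison$p < 0.05)
  report$selected <- if (is.null(res$model)) character(0) else res$model$selected
  report$combined_auc <- if (is.null(res$screening)) NA else res$screening$combined$auc
  report$checksums <- as.list(tools::md5sum(sort(artifacts)))
  names(report$checksums) <- basename(sort(artifacts))
  report$config_hash <- unname(tools::md5sum(
    write_temp_json(config[setdiff(names(config), "feature_table")])))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(res, list(report = report)))
}

write_temp_json <- function(x) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
  f
}
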