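#' @title Biomarker screening: stepwise logistic selection and ROC/AUC
#' @description Forward stepwise binary logistic selection over candidate
#'   biomarkers (likelihood-ratio entry/removal), maximum-likelihood
#'   logistic fits with separation detection, and ROC curves with
#'   trapezoidal / rank-equivalent AUC, for single and combined markers.
#' @name screening
NULL

as_binary_labels <- function(labels, positive = "HD") {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == positive)
}

#' Fit a binary logistic regression with separation detection
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares
#' via `stats::glm`, log-likelihood convergence tolerance 1e-8).
#' Constant features are dropped with a warning; quasi-complete or
#' complete separation (diverging coefficients / boundary fitted
#' probabilities) is flagged, and the fit at the iteration cap is
#' returned rather than silently regularised.
#'
#' @param features Data frame or matrix of predictors (subjects x
#'   features).
#' @param labels Binary outcome: logical, 0/1, or group labels with
#'   `positive` as the positive class.
#' @param positive Positive class label (default `"HD"`).
#' @param standardize Centre and scale predictors first?
#' @return A `screening_model`: selected feature names, `intercept`,
#'   `coefficients`, `log_likelihood`, `iterations`, `converged`,
#'   `separation`, `fitted` probabilities and the underlying `glm` fit.
#' @export
logistic_fit <- function(features, labels, positive = "HD",
                         standardize = FALSE) {
  y <- as_binary_labels(labels, positive)
  stopifnot(sum(y == 1) >= 2, sum(y == 0) >= 2)
  X <- as.data.frame(features, check.names = FALSE)
  keep <- vapply(X, function(v) stats::var(v, na.rm = TRUE) > 0, logical(1))
  if (!all(keep)) {
    warning("dropping constant feature(s): ",
            paste(names(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  if (standardize) X[] <- lapply(X, function(v) as.numeric(scale(v)))
  dat <- cbind(.y = y, X)
  names(dat) <- c(".y", sprintf("x%d", seq_along(X)))
  form <- stats::as.formula(paste(".y ~", if (ncol(X)) paste(names(dat)[-1], collapse = " + ") else "1"))
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = dat,
                                     control = stats::glm.control(epsilon = 1e-8,
                                                                  maxit = 100)))
  co <- stats::coef(fit)
  eps <- 1e-8
  separation <- any(abs(co[-1]) > 15 / apply(as.matrix(X), 2, stats::sd)) ||
    any(fit$fitted.values > 1 - eps | fit$fitted.values < eps)
  structure(list(
    selected = names(X),
    intercept = unname(co[1]),
    coefficients = stats::setNames(unname(co[-1]), names(X)),
    log_likelihood = as.numeric(stats::logLik(fit)),
    iterations = fit$iter,
    converged = fit$converged,
    separation = isTRUE(separation),
    fitted = unname(fit$fitted.values),
    glm = fit), class = "screening_model")
}

#' @export
print.screening_model <- function(x, ...) {
  cat(sprintf("<screening_model: %d feature(s), logLik %.3f%s>\n",
              length(x$selected), x$log_likelihood,
              if (x$separation) ", SEPARATION flagged" else ""))
  if (length(x$selected)) {
    print(round(c(`(Intercept)` = x$intercept, x$coefficients), 4))
  }
  invisible(x)
}

# likelihood-ratio p for adding/removing one term between two nested fits
lr_pvalue <- function(ll_small, ll_big, df = 1) {
  stat <- max(0, 2 * (ll_big - ll_small))
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Forward stepwise logistic selection
#'
#' Starting from the intercept-only model, iteratively adds the candidate
#' with the smallest likelihood-ratio p value below `entry_alpha`, then
#' removes any included term whose likelihood-ratio p value (against the
#' current model without it) exceeds `removal_alpha`; stops when neither
#' step changes the model. Ties are broken deterministically by candidate
#' name order. An empty selection is a valid outcome.
#'
#' @param features Data frame of candidate predictors.
#' @param labels Binary outcome (see [logistic_fit()]).
#' @param entry_alpha Likelihood-ratio entry threshold (default 0.05).
#' @param removal_alpha Removal threshold (default 0.10).
#' @param positive Positive class label.
#' @return A `screening_model` for the selected set (intercept-only when
#'   nothing enters), with `selected` in entry order and the thresholds
#'   recorded in `entry_alpha`/`removal_alpha`.
#' @export
forward_stepwise <- function(features, labels, entry_alpha = 0.05,
                             removal_alpha = 0.10, positive = "HD") {
  X <- as.data.frame(features, check.names = FALSE)
  stopifnot(ncol(X) >= 1)
  y <- as_binary_labels(labels, positive)
  candidates <- names(X)[order(names(X))]
  selected <- character(0)
  ll_of <- function(vars) {
    if (!length(vars)) {
      p1 <- mean(y)
      if (p1 %in% c(0, 1)) return(0)
      return(sum(y) * log(p1) + sum(1 - y) * log(1 - p1))
    }
    logistic_fit(X[, vars, drop = FALSE], y)$log_likelihood
  }
  ll_cur <- ll_of(selected)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 100L) break  # guard against entry/removal cycling
    changed <- FALSE
    # entry step: best (smallest p) candidate below entry_alpha
    pool <- setdiff(candidates, selected)
    if (length(pool)) {
      pvals <- vapply(pool, function(v)
        lr_pvalue(ll_cur, ll_of(c(selected, v))), numeric(1))
      best <- which.min(pvals)   # ties: first in name order
      if (pvals[best] < entry_alpha) {
        selected <- c(selected, pool[best])
        ll_cur <- ll_of(selected)
        changed <- TRUE
      }
    }
    # removal step: drop worst term above removal_alpha
    if (length(selected)) {
      pvals <- vapply(selected, function(v)
        lr_pvalue(ll_of(setdiff(selected, v)), ll_cur), numeric(1))
      worst <- which.max(pvals)
      if (pvals[worst] > removal_alpha) {
        selected <- setdiff(selected, selected[worst])
        ll_cur <- ll_of(selected)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  model <- if (length(selected))
    logistic_fit(X[, selected, drop = FALSE], y) else
    structure(list(selected = character(0), intercept = stats::qlogis(mean(y)),
                   coefficients = numeric(0), log_likelihood = ll_of(character(0)),
                   iterations = 0L, converged = TRUE, separation = FALSE,
                   fitted = rep(mean(y), length(y)), glm = NULL),
              class = "screening_model")
  model$entry_alpha <- entry_alpha
  model$removal_alpha <- removal_alpha
  model$selected <- selected  # entry order
  model
}

#' ROC curve and AUC
#'
#' Receiver operating characteristic built at the unique score values.
#' The AUC is the trapezoidal area, which equals the tie-corrected
#' rank statistic (concordant pairs plus half the tied pairs over all
#' case-control pairs). With `orient = TRUE` the score direction is
#' flipped when needed so that AUC >= 0.5; the flip is recorded.
#'
#' @param scores Numeric scores, higher = more case-like (before
#'   orientation).
#' @param labels Binary outcome (see [logistic_fit()]).
#' @param positive Positive class label.
#' @param orient Flip direction to force AUC >= 0.5?
#' @return An `roc_result`: `curve` (data frame `threshold`,
#'   `sensitivity`, `fpr` = 1 - specificity), `auc`, `flipped`,
#'   `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels, positive = "HD", orient = FALSE) {
  y <- as_binary_labels(labels, positive)
  stopifnot(length(scores) == length(y))
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  auc_of <- function(s) {
    r <- rank(s, ties.method = "average")
    (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  flipped <- FALSE
  if (orient && auc_of(scores) < 0.5) {
    scores <- -scores
    flipped <- TRUE
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n_neg, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr),
                      sensitivity = c(0, sens), fpr = c(0, fpr))
  auc_trap <- sum(diff(curve$fpr) * (utils::head(curve$sensitivity, -1) +
                                     utils::tail(curve$sensitivity, -1)) / 2) +
    (1 - curve$fpr[nrow(curve)]) * 1  # close the curve to (1,1); sens already 1 there
  structure(list(curve = curve, auc = auc_of(scores), auc_trapezoid = auc_trap,
                 flipped = flipped, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.4f (%d cases / %d controls)%s>\n",
              x$auc, x$n_pos, x$n_neg, if (x$flipped) ", score flipped" else ""))
  invisible(x)
}

#' Evaluate screening performance of selected biomarkers
#'
#' In-sample evaluation, as in the source analysis: one ROC per selected
#' biomarker (direction oriented so AUC >= 0.5) and one combined ROC
#' using predicted probabilities from a multivariate logistic fit on the
#' same data. Subjects with missing values in any selected biomarker are
#' dropped listwise for the combined model.
#'
#' @param table A `biomarker_table`.
#' @param selected Character vector of biomarker column names.
#' @param positive Positive class label (default `"HD"`).
#' @return List with `per_feature` (named list of `roc_result`),
#'   `combined` (`roc_result`), `model` (`screening_model`) and
#'   `n_dropped` (listwise-dropped subjects).
#' @export
evaluate_screening <- function(table, selected, positive = "HD") {
  stopifnot(all(selected %in% names(table)))
  per_feature <- lapply(stats::setNames(selected, selected), function(b)
    roc_curve(table[[b]], table$group, positive, orient = TRUE))
  cc <- stats::complete.cases(table[, selected, drop = FALSE])
  n_dropped <- sum(!cc)
  if (n_dropped) message(n_dropped, " subject(s) dropped listwise for the combined model")
  sub <- table[cc, , drop = FALSE]
  model <- logistic_fit(sub[, selected, drop = FALSE], sub$group, positive)
  combined <- roc_curve(model$fitted, sub$group, positive)
  list(per_feature = per_feature, combined = combined, model = model,
       n_dropped = n_dropped)
}
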