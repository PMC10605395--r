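#' @title Group comparison statistics
#' @description Levene variance check, two-sample t-tests (pooled and
#'   Welch, from raw data or printed summary statistics), Cohen's d,
#'   Pearson chi-square for 2x2 tables, Benjamini-Hochberg FDR, and the
#'   biomarker-table comparison driver.
#' @name stats-module
NULL

#' Levene's test for homogeneity of variance
#'
#' Classic mean-centred Levene test: a one-way ANOVA F test on the
#' absolute deviations from each group's mean.
#'
#' @param x,y Numeric samples (each of size >= 2; `NA` dropped).
#' @return List with `statistic` (F), `df` (c(1, n-2)) and `p.value`.
#'   Two samples with zero spread give statistic 0 and p = 1 by
#'   convention.
#' @export
levene_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  zx <- abs(x - mean(x)); zy <- abs(y - mean(y))
  z <- c(zx, zy)
  g <- factor(rep(c("x", "y"), c(length(zx), length(zy))))
  # essentially constant deviations (both groups near-degenerate): the
  # F test is meaningless there, report no evidence of heterogeneity
  if (stats::var(z) <= 1e-12 * (mean(z)^2 + .Machine$double.eps))
    return(list(statistic = 0, df = c(1L, length(z) - 2L), p.value = 1))
  # one group exactly at a domain ceiling gives an "essentially perfect
  # fit" anova warning; the tiny p (-> Welch) is the wanted outcome
  fit <- withCallingHandlers(
    stats::anova(stats::aov(z ~ g)),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(statistic = fit$`F value`[1], df = c(fit$Df[1], fit$Df[2]),
       p.value = fit$`Pr(>F)`[1])
}

#' Two-sample t-test
#'
#' Independent-sample t-test on raw data, pooled-variance (`"pooled"`)
#' or Welch (`"unequal"`) variant. The statistic is oriented as
#' `mean(x) - mean(y)`.
#'
#' @param x,y Numeric samples (`NA` dropped).
#' @param variant `"pooled"` or `"unequal"`.
#' @return List with `t`, `df`, `p.value`, `variant`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "unequal")) {
  variant <- match.arg(variant)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (variant == "pooled" && stats::var(x) == 0 && stats::var(y) == 0)
    stop("degenerate samples: zero pooled variance")
  ht <- stats::t.test(x, y, var.equal = (variant == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, variant = variant)
}

#' Two-sample t statistic from summary statistics
#'
#' Pooled or Welch t from group means, SDs and sizes — the form needed to
#' recompute a published comparison table from its printed mean (SD)
#' entries. Oriented as `m1 - m2`.
#'
#' @param m1,s1,n1 First group's mean, SD, size.
#' @param m2,s2,n2 Second group's mean, SD, size.
#' @param variant `"pooled"` or `"unequal"`.
#' @return List with `t`, `df`, `p.value`, `variant`.
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                           variant = c("pooled", "unequal")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0) stop("degenerate samples: zero pooled variance")
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se2 <- s1^2 / n1 + s2^2 / n2
    if (se2 == 0) stop("degenerate samples: zero variance")
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  list(t = t, df = df, p.value = 2 * stats::pt(-abs(t), df), variant = variant)
}

#' Cohen's d (pooled-SD effect size)
#'
#' `d = |m1 - m2| / s_p` with the pooled standard deviation
#' `s_p = sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`; with equal group
#' sizes this reduces to `sqrt((s1^2 + s2^2)/2)`. Reported as a
#' magnitude.
#'
#' @param x,y Numeric samples (`NA` dropped).
#' @return Non-negative effect size.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  cohens_d_from_summary(mean(x), stats::sd(x), length(x),
                        mean(y), stats::sd(y), length(y))
}

#' Cohen's d from summary statistics
#'
#' @param m1,s1,n1,m2,s2,n2 Group means, SDs and sizes.
#' @return Non-negative effect size.
#' @rdname cohens_d
#' @export
cohens_d_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("degenerate samples: zero pooled SD")
  abs(m1 - m2) / sp
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson chi-square without continuity correction (df = 1), the variant
#' that reproduces the published sex comparison.
#'
#' @param table 2x2 matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p.value`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in 2x2 table")
  ht <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR-adjusted p values (monotonicity enforced, capped at 1).
#'
#' @param pvalues Numeric vector of p values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Compare biomarker distributions between two groups
#'
#' Per biomarker: Levene's test chooses the t-test variant (Welch when
#' Levene p < `levene_alpha`, pooled otherwise, unless overridden),
#' then the two-sample t, Cohen's d and group summaries are computed,
#' and BH adjustment is applied over the configured family (per task
#' table, or globally). Missing values are dropped pairwise per
#' biomarker; biomarkers that are entirely missing in a group or
#' degenerate (zero pooled variance) are skipped with a message.
#'
#' The reported `t` is oriented so that a negative value means the HD
#' mean exceeds the LD mean, matching the published tables.
#'
#' @param table A `biomarker_table` (columns `subject`, `group`, then
#'   biomarkers), with groups `"HD"` and `"LD"`.
#' @param fdr_family `"per_task"` (default) or `"global"`.
#' @param levene_alpha Variance-homogeneity decision level.
#' @param variant_override `NULL`, `"pooled"` or `"unequal"` to force a
#'   variant.
#' @param tasks Optional named assignment of biomarker name to task for
#'   per-task FDR; by default parsed from the `"Task n_"` name prefix.
#' @return A tibble: `biomarker`, `task`, group summaries, `levene_p`,
#'   `variant`, `t`, `df`, `p`, `fdr`, `d`.
#' @export
compare_groups <- function(table, fdr_family = c("per_task", "global"),
                           levene_alpha = 0.05, variant_override = NULL,
                           tasks = NULL) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(all(c("subject", "group") %in% names(table)))
  groups <- unique(table$group)
  if (!setequal(groups, c("HD", "LD")))
    stop("comparison requires exactly the groups HD and LD")
  markers <- setdiff(names(table), c("subject", "group"))
  rows <- list()
  for (b in markers) {
    hd <- table[[b]][table$group == "HD"]
    ld <- table[[b]][table$group == "LD"]
    hd <- hd[!is.na(hd)]; ld <- ld[!is.na(ld)]
    if (length(hd) < 2 || length(ld) < 2) {
      message("skipping '", b, "': insufficient non-missing values")
      next
    }
    if (stats::var(hd) == 0 && stats::var(ld) == 0) {
      message("skipping '", b, "': zero variance in both groups")
      next
    }
    lev <- levene_test(hd, ld)
    variant <- if (!is.null(variant_override)) variant_override
               else if (lev$p.value < levene_alpha) "unequal" else "pooled"
    tt <- two_sample_t(ld, hd, variant)  # LD - HD: negative <=> HD larger
    task <- if (!is.null(tasks)) tasks[[b]]
            else suppressWarnings(as.integer(sub("^Task ([0-9]+)_.*$", "\\1", b)))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      biomarker = b, task = task,
      n_hd = length(hd), n_ld = length(ld),
      mean_hd = mean(hd), sd_hd = stats::sd(hd),
      mean_ld = mean(ld), sd_ld = stats::sd(ld),
      levene_p = lev$p.value, variant = variant,
      t = tt$t, df = tt$df, p = tt$p.value, d = cohens_d(hd, ld))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$fdr <- NA_real_
  if (fdr_family == "global" || all(is.na(out$task))) {
    out$fdr <- bh_fdr(out$p)
  } else {
    for (tk in unique(out$task)) {
      sel <- if (is.na(tk)) is.na(out$task) else !is.na(out$task) & out$task == tk
      out$fdr[sel] <- bh_fdr(out$p[sel])
    }
  }
  out
}
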