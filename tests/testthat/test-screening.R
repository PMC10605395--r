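make_cohort <- function(n, d, seed, noise = 0) {
  set.seed(seed)
  p <- length(d)
  X <- rbind(matrix(rnorm(n * p, rep(d, each = n)), n, p),
             matrix(rnorm(n * p), n, p))
  if (noise > 0) X <- cbind(X, matrix(rnorm(2 * n * noise), 2 * n, noise))
  colnames(X) <- c(sprintf("sig%02d", seq_len(p)),
                   if (noise > 0) sprintf("noise%02d", seq_len(noise)))
  list(X = as.data.frame(X), y = rep(c(1L, 0L), each = n))
}

test_that("logistic fit finds the forced coefficient sign and a null fit stays near zero", {
  co <- make_cohort(100, d = 2, seed = 1)
  fit <- logistic_fit(co$X, co$y)
  expect_gt(fit$coefficients[["sig01"]], 0)
  expect_true(fit$converged)
  null <- make_cohort(400, d = 0, seed = 2)
  fit0 <- logistic_fit(null$X, null$y)
  expect_lt(abs(fit0$coefficients[["sig01"]]), 0.3)
  # constant feature dropped with a warning
  co$X$flat <- 1
  expect_warning(logistic_fit(co$X, co$y), "constant feature")
})

test_that("logistic fit matches direct likelihood maximisation on a small dataset", {
  co <- make_cohort(15, d = c(1, 0.5), seed = 3)
  fit <- logistic_fit(co$X, co$y)
  nll <- function(b) {
    eta <- b[1] + as.matrix(co$X) %*% b[-1]
    -sum(co$y * eta - log(1 + exp(eta)))
  }
  opt <- stats::optim(c(0, 0, 0), nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(fit$log_likelihood, -opt$value, tolerance = 1e-4)
  expect_equal(unname(c(fit$intercept, fit$coefficients)), opt$par,
               tolerance = 1e-2)
})

test_that("complete separation is flagged, not silently accepted", {
  X <- data.frame(x = c(1:5, 11:15))
  y <- rep(c(0L, 1L), each = 5)
  fit <- logistic_fit(X, y)
  expect_true(fit$separation)
})

test_that("stepwise selects a strongly informative candidate and respects thresholds", {
  co <- make_cohort(100, d = 1.5, seed = 4)
  m <- forward_stepwise(co$X, co$y)
  expect_identical(m$selected, "sig01")
  expect_equal(m$entry_alpha, 0.05)
  # mostly-noise candidates: informative ones dominate the selection
  co2 <- make_cohort(200, d = c(1, 0.8, 0.6), seed = 5, noise = 8)
  m2 <- forward_stepwise(co2$X, co2$y)
  expect_true(all(c("sig01", "sig02", "sig03") %in% m2$selected))
  expect_lt(sum(grepl("noise", m2$selected)), 3)
  # an empty selection is a valid outcome on pure noise
  null <- make_cohort(50, d = 0, seed = 6)
  m0 <- forward_stepwise(null$X["sig01"], null$y)
  expect_length(m0$selected, 0)
  expect_equal(m0$fitted, rep(0.5, 100))
})

test_that("stepwise log-likelihood is non-decreasing along the entry order", {
  co <- make_cohort(150, d = c(1, 0.7, 0.5, 0.3), seed = 7, noise = 4)
  m <- forward_stepwise(co$X, co$y)
  lls <- vapply(seq_along(m$selected), function(k)
    logistic_fit(co$X[, m$selected[1:k], drop = FALSE], co$y)$log_likelihood,
    numeric(1))
  expect_true(all(diff(lls) > 0))
})

test_that("ROC handles perfect separation, ties, and matches the pair-count oracle", {
  y <- rep(c(1L, 0L), each = 5)
  expect_equal(roc_curve(c(6:10, 1:5), y)$auc, 1.0)
  expect_equal(roc_curve(rep(1, 10), y)$auc, 0.5)
  expect_error(roc_curve(1:5, rep(1L, 5)), "both classes")
  set.seed(8)
  for (rep in 1:50) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    sc <- sample(1:8, n1 + n0, replace = TRUE)  # heavy ties
    yy <- c(rep(1L, n1), rep(0L, n0))
    r <- roc_curve(sc, yy)
    expect_equal(r$auc, oracle_auc(sc, yy))
    expect_equal(r$auc_trapezoid, r$auc)
    # symmetry: AUC(s) + AUC(-s) = 1
    expect_equal(r$auc + roc_curve(-sc, yy)$auc, 1)
    # invariance under strictly monotone transforms
    expect_equal(roc_curve(exp(sc / 3), yy)$auc, r$auc)
  }
})

test_that("ROC curve coordinates are monotone and agree with pROC", {
  set.seed(9)
  sc <- rnorm(60); y <- rep(c(1L, 0L), 30)
  r <- roc_curve(sc, y)
  expect_true(all(diff(r$curve$sensitivity) >= 0))
  expect_true(all(diff(r$curve$fpr) >= 0))
  skip_if_not_installed("pROC")
  pr <- pROC::roc(y, sc, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)))
})

test_that("orientation flips weak-direction scores to AUC >= 0.5 and records it", {
  set.seed(10)
  sc <- c(rnorm(30, 0), rnorm(30, 1))      # cases score LOWER
  y <- rep(c(1L, 0L), each = 30)
  r <- roc_curve(sc, y, orient = TRUE)
  expect_gte(r$auc, 0.5)
  expect_true(r$flipped)
})

test_that("single-marker AUC approaches the binormal closed form", {
  set.seed(12)
  d <- 0.9; n <- 4000
  sc <- c(rnorm(n, d), rnorm(n))
  y <- rep(c(1L, 0L), each = n)
  expect_lt(abs(roc_curve(sc, y)$auc - pnorm(d / sqrt(2))), 0.015)
})

test_that("combined screening beats single markers and collapses under shuffling", {
  spec <- default_group_spec()
  tab <- simulate_feature_table(spec, n_per_group = 29, seed = 13)
  sel <- c("Task 1_P(2) Sad(FT,O)", "Task 3_P(5) Neutral(ASS,EM)",
           "Task 4_P(4)3 Sad_AL")
  ev <- evaluate_screening(tab, sel)
  best_single <- max(vapply(ev$per_feature, `[[`, numeric(1), "auc"))
  expect_gte(ev$combined$auc, best_single)
  expect_true(all(vapply(ev$per_feature, `[[`, numeric(1), "auc") >= 0.5))
  # shuffled labels: combined AUC near chance
  set.seed(13)
  tab$group <- sample(tab$group)
  ev0 <- evaluate_screening(tab, sel)
  expect_lt(ev0$combined$auc, 0.75)
  # listwise dropping of missing subjects
  tab2 <- simulate_feature_table(spec, n_per_group = 20, seed = 14)
  tab2[[sel[1]]][1:3] <- NA
  expect_message(ev2 <- evaluate_screening(tab2, sel), "dropped listwise")
  expect_equal(ev2$n_dropped, 3L)
})
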