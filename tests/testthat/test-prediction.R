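test_that("HSIC statistic matches trace and closed-form oracles", {
  set.seed(2)
  m <- 5
  x <- as.numeric(scale(rnorm(m))); y <- as.numeric(scale(rnorm(m)))
  # constant response: centring annihilates the gram
  expect_identical(hsic_statistic(gaussian_gram(x), matrix(1, m, m)), 0)
  # linear kernels on standardized vectors: HSIC = cov(x, y)^2
  K <- outer(x, x); L <- outer(y, y)
  H <- diag(m) - 1 / m
  expect_equal(hsic_statistic(K, L),
               sum(diag(K %*% H %*% L %*% H)) / (m - 1)^2, tolerance = 1e-12)
  expect_equal(hsic_statistic(K, L), cov(x, y)^2, tolerance = 1e-12)
  # shift invariance of the gaussian-kernel statistic
  K1 <- gaussian_gram(x, bandwidth = 1)
  K2 <- gaussian_gram(x + 100, bandwidth = 1)
  Ly <- gaussian_gram(y, bandwidth = 1)
  expect_equal(hsic_statistic(K1, Ly), hsic_statistic(K2, Ly),
               tolerance = 1e-10)
  expect_error(hsic_statistic(matrix(1, 1, 1), matrix(1, 1, 1)), "m >= 2")
})

test_that("HSIC of independent variables sits inside its permutation null", {
  set.seed(33)
  m <- 200
  x <- rnorm(m); y <- rnorm(m)
  K <- gaussian_gram(x); L <- gaussian_gram(y)
  obs <- hsic_statistic(K, L)
  null <- replicate(100, {
    p <- sample(m)
    hsic_statistic(K, L[p, p])
  })
  expect_lt(obs, quantile(null, 0.95))
})

test_that("sparse HSIC selection finds a planted signal gene at target size 1", {
  hits <- sapply(1:20, function(s) {
    set.seed(1000 + s)
    m <- 30
    expr <- matrix(rnorm(50 * m), 50, m,
                   dimnames = list(paste0("G", 1:50), paste0("S", 1:m)))
    ttd <- expr["G7", ] + 10
    sel <- shs_select(expr, ttd, target_size = 1, screen_size = 50,
                      seed = s)
    identical(sel$selected, "G7")
  })
  expect_equal(mean(hits), 1)
})

test_that("duplicated signal genes share the selection weight", {
  set.seed(77)
  m <- 30
  expr <- matrix(rnorm(40 * m), 40, m,
                 dimnames = list(paste0("G", 1:40), paste0("S", 1:m)))
  expr["G2", ] <- expr["G1", ]                 # duplicate under a second id
  ttd <- expr["G1", ] + 8
  sel <- shs_select(expr, ttd, target_size = 2, screen_size = 40, seed = 1)
  expect_true(all(sel$selected %in% c("G1", "G2")))
  dup_weight <- sum(sel$weights[c("G1", "G2")])
  expect_gt(dup_weight, max(sel$weights[setdiff(names(sel$weights),
                                                c("G1", "G2"))]))
  # full shrinkage: an extreme penalty empties the selection
  G <- diag(3); cvec <- c(1, 0.5, 0.2)
  expect_equal(amniotime:::nn_lasso(G, cvec, lambda = 1e6), rep(0, 3))
})

test_that("random-forest fitting is deterministic, learns signal, and falls back", {
  set.seed(9)
  m <- 200
  expr <- matrix(rnorm(5 * m), 5, m,
                 dimnames = list(paste0("G", 1:5), paste0("S", 1:m)))
  ttd <- ifelse(expr["G1", ] > 0, 8, 2)        # step function of one gene
  fit <- suppressWarnings(fit_rf(expr, ttd, "G1", n_trees = 500, seed = 4))
  oob <- fit$model$predicted
  expect_gt(1 - mean((oob - ttd)^2) / var(ttd), 0.8)
  # same seed twice: identical predictions
  fit2 <- suppressWarnings(fit_rf(expr, ttd, "G1", n_trees = 500, seed = 4))
  expect_identical(predict(fit, expr), predict(fit2, expr))
  # constant response
  cfit <- suppressWarnings(fit_rf(expr, rep(5, m), "G1", n_trees = 100,
                                  seed = 1))
  expect_equal(predict(cfit, expr), rep(5, m), tolerance = 1e-10)
  # empty selection: training-mean fallback with warning
  expect_warning(fb <- fit_rf(expr, ttd, character(0)), "training-mean")
  expect_equal(predict(fb, expr[, 1:3]), rep(mean(ttd), 3))
})

test_that("LOOCV never leaks the held-out sample into selection", {
  co <- generate_cohort(small_config(seed = 15, n_genes = 120,
                                     n_response_genes = 20))
  expr <- co$expression[, 1:12]
  ttd <- co$samples$time_to_delivery[1:12]
  cv <- suppressWarnings(loocv_ttd(expr, ttd, target_size = 5, n_trees = 50,
                                   screen_size = 60, seed = 2))
  # corrupting the held-out response must not change that fold at all
  ttd_bad <- ttd; ttd_bad[1] <- 1e3
  cv_bad <- suppressWarnings(loocv_ttd(expr, ttd_bad, target_size = 5,
                                       n_trees = 50, screen_size = 60,
                                       seed = 2))
  expect_identical(cv$fold_sets[[1]], cv_bad$fold_sets[[1]])
  expect_identical(cv$predictions[[1]], cv_bad$predictions[[1]])
  # constant response toy: all predictions equal, RMSE 0
  cv_const <- suppressWarnings(loocv_ttd(expr[, 1:5], rep(4, 5),
                                         target_size = 2, n_trees = 50,
                                         screen_size = 20, seed = 1))
  expect_equal(unname(cv_const$predictions), rep(4, 5), tolerance = 1e-10)
  expect_equal(evaluate_predictions(cv_const)$rmse, 0, tolerance = 1e-10)
})

test_that("performance metrics match their oracles", {
  ttd <- c(0.05, 0.1, 0.5, 2, 3, 5, 7, 9)
  perfect <- list(predictions = ttd, ttd = ttd)
  m <- evaluate_predictions(perfect)
  expect_equal(m$rho, 1); expect_equal(m$rmse, 0)
  expect_true(all(m$auroc == 1, na.rm = TRUE))
  # constant predictions: all-tie AUROC is 0.5 by the midrank convention
  const <- list(predictions = rep(3, 8), ttd = ttd)
  expect_true(all(evaluate_predictions(const)$auroc == 0.5, na.rm = TRUE))
  # risk score is the negated prediction
  cvx <- list(predictions = c(1, 2, 3, 4), ttd = c(0.1, 0.12, 5, 6))
  expect_equal(unname(evaluate_predictions(cvx, horizons = 1)$auroc), 1)
  # one-class horizon is undefined
  expect_true(is.na(evaluate_predictions(cvx, horizons = 10)$auroc))
  # rank formula equals exhaustive pair counting, with ties, n <= 12
  set.seed(55)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    scores <- sample(1:5, n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    expect_equal(auroc(scores, labels), oracle_auroc(scores, labels))
  }
})

test_that("stability measures match hand values and the kappa formula", {
  expect_equal(selection_stability(list(c("a", "b"), c("a", "b")),
                                   letters[1:5])$mean_jaccard, 1)
  expect_equal(selection_stability(list(c("a", "b"), c("a", "b")),
                                   letters[1:5])$mean_kappa, 1)
  expect_equal(selection_stability(list(c("a"), c("b")),
                                   letters[1:5])$mean_jaccard, 0)
  uni10 <- letters[1:10]
  st <- selection_stability(list(c("a", "b", "c"), c("b", "c", "d")), uni10)
  expect_equal(st$mean_jaccard, 0.5, tolerance = 1e-12)
  expect_equal(st$mean_kappa, (0.8 - 0.58) / 0.42, tolerance = 1e-10)
  # pairwise kappas agree with the agreement-table oracle on random sets
  set.seed(66)
  for (i in 1:20) {
    a <- sample(uni10, sample(0:6, 1)); b <- sample(uni10, sample(1:6, 1))
    expect_equal(cohen_kappa(a, b, uni10), oracle_kappa(a, b, uni10),
                 tolerance = 1e-12)
  }
  expect_equal(cohen_kappa(uni10, uni10, uni10), 1)
})

test_that("consensus selection keeps always-selected genes and rejects noise", {
  uni <- paste0("G", 1:200)
  # extreme evidence: selected in all 38 folds at p0 ~ 0.05
  folds <- replicate(38, c("G1", sample(uni[-1], 9)), simplify = FALSE)
  res <- consistent_selection(folds, uni)
  expect_true("G1" %in% res$consensus)
  expect_true("G1" %in% res$always_selected)
  # a single selection is never retained
  folds1 <- c(list(c("G5", "G2")), replicate(37, c("G2", "G3"),
                                             simplify = FALSE))
  expect_false("G5" %in% consistent_selection(folds1, uni)$consensus)
  # planted always-selected genes recovered over 20 seeds
  planted <- paste0("G", 1:5)
  exact <- sapply(1:20, function(s) {
    set.seed(700 + s)
    folds <- replicate(38, c(planted, sample(setdiff(uni, planted), 5)),
                       simplify = FALSE)
    setequal(consistent_selection(folds, uni)$consensus, planted)
  })
  expect_gte(mean(exact), 0.95)
})
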