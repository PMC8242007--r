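#' Gaussian gram matrix with median-heuristic bandwidth
#'
#' `K_ij = exp(-(x_i - x_j)^2 / (2 s^2))` with `s` the median of the positive
#' pairwise absolute differences (the median heuristic); a constant input
#' yields an all-ones gram.
#'
#' @param x numeric vector.
#' @param bandwidth optional fixed bandwidth (> 0).
#' @return symmetric `length(x)` x `length(x)` matrix.
#' @export
gaussian_gram <- function(x, bandwidth = NULL) {
  d <- abs(outer(x, x, "-"))
  if (is.null(bandwidth)) {
    pos <- d[d > 0]
    bandwidth <- if (length(pos)) stats::median(pos) else 1
  }
  stopifnot(bandwidth > 0)
  exp(-d^2 / (2 * bandwidth^2))
}

#' Double-centre a gram matrix
#'
#' Computes `H K H` with `H = I - 11'/m`.
#'
#' @param K symmetric matrix.
#' @return centred matrix.
#' @export
center_gram <- function(K) {
  rm <- rowMeans(K)
  K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), colMeans(K)) + mean(K)
}

#' Hilbert-Schmidt independence criterion (biased estimator)
#'
#' `HSIC = tr(K H L H) / (m - 1)^2`. Zero when either variable is constant
#' (centring annihilates constant grams); nonnegative for positive
#' semidefinite kernels.
#'
#' @param K,L symmetric m x m gram matrices of the two variables.
#' @return scalar statistic.
#' @export
hsic_statistic <- function(K, L) {
  m <- nrow(K)
  stopifnot(is.matrix(K), is.matrix(L), m >= 2L, ncol(K) == m,
            nrow(L) == m, ncol(L) == m)
  sum(center_gram(K) * center_gram(L)) / (m - 1)^2
}

# Vectorised per-gene centred, Frobenius-normalised Gaussian grams.
# Returns a genes x m^2 matrix whose g-th row is vec(Kbar_g); rows of
# degenerate (constant) genes are zero.
gene_gram_rows <- function(expr) {
  m <- ncol(expr)
  sds <- apply(expr, 1L, stats::sd)
  xs <- (expr - rowMeans(expr)) / ifelse(sds > 0, sds, 1)
  xs[sds == 0, ] <- 0
  pi_ <- rep(seq_len(m), times = m)
  pj_ <- rep(seq_len(m), each = m)
  D <- xs[, pi_, drop = FALSE] - xs[, pj_, drop = FALSE]   # genes x m^2
  absD <- abs(D)
  bw <- apply(absD, 1L, function(r) {
    pos <- r[r > 0]
    if (length(pos)) stats::median(pos) else 1
  })
  K <- exp(-(D / bw)^2 / 2)
  # centring: HKH = K - rowmean_i - rowmean_j + grand (grams are symmetric)
  agg <- matrix(0, m * m, m)
  agg[cbind(seq_len(m * m), pi_)] <- 1 / m
  M <- K %*% agg                                           # genes x m
  Kc <- K - M[, pi_, drop = FALSE] - M[, pj_, drop = FALSE] + rowMeans(K)
  nrm <- sqrt(rowSums(Kc^2))
  Kc / ifelse(nrm > 0, nrm, Inf)
}

# Nonnegative lasso  min 0.5||l - sum_g a_g k_g||^2 + lambda * sum a  solved
# by projected proximal gradient on the gram form (G = <k_g, k_h>,
# c = <k_g, l>); warm-startable and exactly sparse.
nn_lasso <- function(G, c_vec, lambda, alpha0 = NULL, step = NULL,
                     maxit = 2000L, tol = 1e-8) {
  p <- length(c_vec)
  a <- if (is.null(alpha0)) numeric(p) else alpha0
  if (is.null(step)) {
    v <- rep(1 / sqrt(p), p)                     # power iteration for ||G||_2
    for (i in 1:30) { v <- G %*% v; v <- v / sqrt(sum(v^2)) }
    step <- 1 / max(sum(v * (G %*% v)), .Machine$double.eps)
  }
  for (it in seq_len(maxit)) {
    grad <- G %*% a - c_vec
    a_new <- pmax(0, a - step * (grad + lambda))
    if (max(abs(a_new - a)) < tol * max(1, max(a_new))) { a <- a_new; break }
    a <- a_new
  }
  as.numeric(a)
}

#' Sparse HSIC feature selection (HSIC lasso)
#'
#' Selects genes whose kernel similarity structure best reconstructs the
#' response's kernel structure: nonnegative lasso of the centred response
#' gram on the per-gene centred, Frobenius-normalised Gaussian grams,
#' `min 0.5 ||Lbar - sum_g a_g Kbar_g||_F^2 + lambda ||a||_1, a >= 0`.
#' Redundant (correlated) genes share weight, so the selected set is
#' parsimonious. The penalty `lambda` is tuned by bisection to the largest
#' support not exceeding `target_size`. A marginal screen keeps the
#' `screen_size` genes with the largest `<Kbar_g, Lbar>` before the lasso,
#' which leaves the solution path of relevant genes intact at a fraction of
#' the cost.
#'
#' @param expr_train log2 expression, genes x training samples (>= 4).
#' @param ttd_train response (time-to-delivery, weeks) per training sample.
#' @param target_size maximum number of selected genes.
#' @param screen_size genes retained by the marginal relevance screen.
#' @param seed integer; selection is deterministic given inputs and seed.
#' @return object of class `selection_result`: `selected` (gene ids),
#'   `weights` (named, all screened genes), `lambda`, `target_size`.
#' @export
shs_select <- function(expr_train, ttd_train, target_size = 50L,
                       screen_size = 400L, seed = 1L) {
  m <- ncol(expr_train)
  stopifnot(m >= 4L, length(ttd_train) == m, target_size >= 1L)
  if (any(!is.finite(expr_train)) || any(!is.finite(ttd_train)))
    stop("non-finite inputs")
  if (target_size > nrow(expr_train))
    stop("target_size exceeds the number of genes")
  set.seed(seed)
  y <- (ttd_train - mean(ttd_train)) /
    max(stats::sd(ttd_train), .Machine$double.eps)
  Lc <- center_gram(gaussian_gram(y))
  Kv <- gene_gram_rows(expr_train)                  # genes x m^2
  c_all <- as.numeric(Kv %*% as.vector(Lc))
  keep <- order(c_all, decreasing = TRUE)[seq_len(min(screen_size, nrow(Kv)))]
  Kv <- Kv[keep, , drop = FALSE]
  c_vec <- c_all[keep]
  G <- tcrossprod(Kv)
  genes <- rownames(expr_train)[keep]

  v <- rep(1 / sqrt(nrow(G)), nrow(G))
  for (i in 1:30) { v <- G %*% v; v <- v / sqrt(sum(v^2)) }
  step <- 1 / max(sum(v * (G %*% v)), .Machine$double.eps)

  support_at <- function(a) sum(a > 0)
  lo <- 0; hi <- max(c_vec, 0) + 1e-12
  a_lo <- nn_lasso(G, c_vec, lo, step = step)
  best <- NULL; best_lambda <- NA_real_
  if (support_at(a_lo) <= target_size) {
    best <- a_lo; best_lambda <- lo
  } else {
    a_warm <- a_lo
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      a_mid <- nn_lasso(G, c_vec, mid, alpha0 = a_warm, step = step)
      s <- support_at(a_mid)
      if (s > target_size) {
        lo <- mid
      } else {
        hi <- mid
        if (is.null(best) || s > support_at(best) ||
            (s == support_at(best) && mid < best_lambda)) {
          best <- a_mid; best_lambda <- mid
        }
      }
      a_warm <- a_mid
      if (hi - lo < 1e-10 * (1 + hi)) break
    }
    if (is.null(best)) { best <- nn_lasso(G, c_vec, hi, step = step)
                         best_lambda <- hi }
  }
  w <- stats::setNames(best, genes)
  structure(list(selected = genes[best > 0], weights = w,
                 lambda = best_lambda, target_size = target_size),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Sparse HSIC selection: %d gene(s) at lambda = %.4g (target %d)\n",
              length(x$selected), x$lambda, x$target_size))
  invisible(x)
}

#' Fit a random forest time-to-delivery model on selected genes
#'
#' 1000-tree regression forest (package defaults otherwise) on the selected
#' features. With an empty selection the model falls back to the training
#' mean predictor, with a warning.
#'
#' @param expr_train log2 expression, genes x training samples.
#' @param ttd_train response per training sample (weeks).
#' @param selected character vector of selected gene ids.
#' @param n_trees number of trees.
#' @param seed RNG seed; predictions are deterministic given it.
#' @return object of class `ttd_model`.
#' @export
fit_rf <- function(expr_train, ttd_train, selected, n_trees = 1000L,
                   seed = 1L) {
  if (!length(selected)) {
    warning("no genes selected; falling back to the training-mean predictor")
    return(structure(list(model = NULL, mean = mean(ttd_train),
                          selected = character(0)),
                     class = "ttd_model"))
  }
  stopifnot(all(selected %in% rownames(expr_train)))
  set.seed(seed)
  x <- t(expr_train[selected, , drop = FALSE])
  # a floored response legitimately has few unique values in small folds
  rf <- withCallingHandlers(
    randomForest::randomForest(x = x, y = ttd_train, ntree = n_trees),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(model = rf, mean = mean(ttd_train), selected = selected),
            class = "ttd_model")
}

#' @export
predict.ttd_model <- function(object, expr_new, ...) {
  if (is.null(object$model))
    return(rep(object$mean, ncol(expr_new)))
  as.numeric(stats::predict(object$model,
                            t(expr_new[object$selected, , drop = FALSE])))
}

#' Leave-one-out cross-validated time-to-delivery prediction
#'
#' For each held-out sample, sparse HSIC selection and random-forest fitting
#' are both re-run on the remaining samples only (selection never sees the
#' held-out sample), and the held-out sample's time-to-delivery is predicted.
#'
#' @param expr log2 expression matrix, genes x samples (n >= 5).
#' @param ttd time-to-delivery per sample, weeks.
#' @param target_size selection target size per fold.
#' @param n_trees trees per forest.
#' @param screen_size marginal screen size passed to [shs_select()].
#' @param seed global seed; fold f uses `seed + f`.
#' @return object of class `ttd_cv`: `predictions` (one per sample,
#'   out-of-fold), `fold_sets` (selected genes per fold), `ttd`, `seed`.
#' @export
loocv_ttd <- function(expr, ttd, target_size = 50L, n_trees = 1000L,
                      screen_size = 400L, seed = 1L) {
  n <- ncol(expr)
  stopifnot(n >= 5L, length(ttd) == n)
  preds <- stats::setNames(numeric(n), colnames(expr))
  fold_sets <- vector("list", n)
  names(fold_sets) <- colnames(expr)
  for (i in seq_len(n)) {
    sel <- shs_select(expr[, -i, drop = FALSE], ttd[-i],
                      target_size = target_size, screen_size = screen_size,
                      seed = seed + i)
    fit <- fit_rf(expr[, -i, drop = FALSE], ttd[-i], sel$selected,
                  n_trees = n_trees, seed = seed + i)
    preds[i] <- predict(fit, expr[, i, drop = FALSE])
    fold_sets[[i]] <- sel$selected
  }
  structure(list(predictions = preds, fold_sets = fold_sets, ttd = ttd,
                 seed = seed),
            class = "ttd_cv")
}

#' @export
print.ttd_cv <- function(x, ...) {
  cat(sprintf("Leave-one-out CV over %d samples; median fold selection %d genes\n",
              length(x$predictions),
              as.integer(stats::median(lengths(x$fold_sets)))))
  invisible(x)
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' Midranks handle ties, so a constant score yields 0.5. Returns `NA` when
#' only one class is present.
#'
#' @param scores numeric risk scores (higher = more likely positive).
#' @param labels logical (or 0/1) outcome labels.
#' @return AUROC in \[0, 1\], or `NA`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)                       # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Prediction performance metrics
#'
#' Spearman correlation (with two-sided p), RMSE in weeks, and AUROC for
#' imminent delivery at each horizon. The binary label at horizon `h` is
#' `ttd <= h` and the risk score is the negated predicted time-to-delivery
#' (shorter predicted interval = higher risk).
#'
#' @param cv a [loocv_ttd()] result (or any list with `predictions`, `ttd`).
#' @param horizons risk horizons in weeks; default 24 h, 1 week, 2 weeks.
#' @return object of class `ttd_metrics`: `rho`, `rho_p`, `rmse`, `auroc`
#'   (named by horizon).
#' @export
evaluate_predictions <- function(cv, horizons = c(24 / 168, 1, 2)) {
  pred <- cv$predictions; ttd <- cv$ttd
  stopifnot(length(pred) == length(ttd), all(is.finite(pred)))
  ct <- suppressWarnings(
    stats::cor.test(pred, ttd, method = "spearman", exact = FALSE))
  aucs <- vapply(horizons, function(h) auroc(-pred, ttd <= h), numeric(1))
  names(aucs) <- sprintf("%gwk", horizons)
  structure(list(rho = unname(ct$estimate), rho_p = ct$p.value,
                 rmse = sqrt(mean((pred - ttd)^2)), auroc = aucs,
                 horizons = horizons),
            class = "ttd_metrics")
}

#' @export
print.ttd_metrics <- function(x, ...) {
  cat(sprintf("Spearman rho = %.2f (p = %.3g), RMSE = %.2f weeks\n",
              x$rho, x$rho_p, x$rmse))
  cat("  AUROC:", paste(sprintf("%s %.2f", names(x$auroc), x$auroc),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Chance-corrected agreement of the two binary inclusion vectors.
#'
#' @param a,b character vectors (subsets of `universe`).
#' @param universe character vector of all candidate genes.
#' @return kappa in \[-1, 1\] (1 when the sets agree everywhere).
#' @export
cohen_kappa <- function(a, b, universe) {
  m <- length(universe)
  ina <- universe %in% a; inb <- universe %in% b
  po <- mean(ina == inb)
  pa <- mean(ina); pb <- mean(inb)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (po == 1) return(1)
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Stability of per-fold gene selections
#'
#' Mean pairwise Jaccard similarity (defined as 1 when both sets are empty)
#' and mean pairwise Cohen's kappa over the gene universe, plus per-gene
#' selection frequencies.
#'
#' @param fold_sets list of >= 2 character vectors (per-fold selections).
#' @param universe character vector containing every selected gene.
#' @return object of class `stability_report`: `mean_jaccard`, `mean_kappa`,
#'   `frequency` (named, per gene with nonzero frequency).
#' @export
selection_stability <- function(fold_sets, universe) {
  stopifnot(length(fold_sets) >= 2L, length(universe) >= 1L)
  if (!all(unlist(fold_sets) %in% universe))
    stop("universe must contain every selected gene")
  nf <- length(fold_sets)
  jac <- kap <- numeric(0)
  for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf) {
    A <- fold_sets[[i]]; B <- fold_sets[[j]]
    u <- length(union(A, B))
    jac <- c(jac, if (u == 0L) 1 else length(intersect(A, B)) / u)
    kap <- c(kap, cohen_kappa(A, B, universe))
  }
  freq <- table(factor(unlist(fold_sets), levels = universe)) / nf
  freq <- freq[freq > 0]
  structure(list(mean_jaccard = mean(jac), mean_kappa = mean(kap),
                 frequency = stats::setNames(as.numeric(freq), names(freq)),
                 n_folds = nf),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Selection stability over %d folds: mean Jaccard %.2f, mean kappa %.2f\n",
              x$n_folds, x$mean_jaccard, x$mean_kappa))
  invisible(x)
}

#' Consensus genes by frequency of selection across folds
#'
#' Each gene's selection count over folds is tested against the chance rate
#' `p0 = (mean fold set size) / |universe|` with a one-sided binomial test;
#' genes with Bonferroni-adjusted p below `alpha` form the consensus list.
#' The genes selected in every fold are reported separately.
#'
#' @param fold_sets list of >= 5 per-fold gene selections.
#' @param universe character vector of all candidate genes.
#' @param alpha significance level after Bonferroni correction over the
#'   universe.
#' @return list with `consensus`, `always_selected`, `frequency`, `p0`.
#' @export
consistent_selection <- function(fold_sets, universe, alpha = 0.05) {
  stopifnot(length(fold_sets) >= 5L)
  nf <- length(fold_sets)
  p0 <- mean(lengths(fold_sets)) / length(universe)
  if (p0 <= 0 || p0 >= 1) stop("degenerate null selection probability")
  counts <- table(factor(unlist(fold_sets), levels = universe))
  pvals <- stats::pbinom(as.numeric(counts) - 1L, size = nf, prob = p0,
                         lower.tail = FALSE)
  padj <- pmin(1, pvals * length(universe))
  consensus <- universe[padj < alpha]
  always <- universe[as.numeric(counts) == nf]
  list(consensus = consensus, always_selected = always,
       frequency = stats::setNames(as.numeric(counts) / nf, universe),
       p0 = p0)
}
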