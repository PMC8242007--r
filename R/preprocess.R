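#' Remove additive batch effects by gene-wise linear modelling
#'
#' For each gene, expression is regressed on an intercept, the protected
#' covariates and sum-to-zero-coded batch indicators; only the fitted batch
#' component is subtracted. Sum-to-zero coding makes the removed component
#' average to zero over batches, so the grand mean and any protected
#' (biological) effects are preserved.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param batch batch label per sample (length `ncol(expr)`).
#' @param protect optional numeric matrix or data.frame of covariates to
#'   protect (e.g. the study-group indicator), one row per sample. An
#'   intercept is always included.
#' @return corrected matrix of the same shape.
#' @export
remove_batch_effects <- function(expr, batch, protect = NULL) {
  stopifnot(is.matrix(expr), length(batch) == ncol(expr))
  batch <- as.factor(batch)
  if (nlevels(batch) < 2L) return(expr)
  if (any(table(batch) == 1L))
    warning("batch level(s) with a single sample: ",
            paste(names(which(table(batch) == 1L)), collapse = ", "))
  B <- stats::model.matrix(~ batch,
                           contrasts.arg = list(batch = "contr.sum"))[, -1L,
                                                                      drop = FALSE]
  P <- matrix(1, ncol(expr), 1L)
  if (!is.null(protect)) {
    protect <- as.matrix(as.data.frame(protect))
    storage.mode(protect) <- "double"
    P <- cbind(P, protect)
  }
  X <- cbind(P, B)
  if (qr(X)$rank < ncol(X))
    stop("design is rank deficient: batch is confounded with protected covariates")
  fit <- stats::lm.fit(X, t(expr))
  beta_batch <- fit$coefficients[(ncol(P) + 1L):ncol(X), , drop = FALSE]
  expr - t(B %*% beta_batch)
}

#' Principal component analysis of an expression matrix
#'
#' Samples are projected onto the principal axes of the gene-centred (not
#' standardised) matrix via singular value decomposition. The variance
#' fraction of component k is its squared singular value over the total.
#'
#' @param expr log2 expression matrix, genes x samples (all genes are used).
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (genes x components), `var_fraction`.
#' @export
pca_expression <- function(expr) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2L)
  X <- t(expr - rowMeans(expr))            # samples x genes, gene-centred
  sv <- svd(X)
  tot <- sum(sv$d^2)
  if (tot < .Machine$double.eps * length(X)) {
    warning("constant expression matrix: no variance to decompose")
    frac <- rep(0, length(sv$d))
  } else {
    frac <- sv$d^2 / tot
  }
  k <- seq_len(min(ncol(expr) - 1L, length(sv$d)))
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  structure(list(
    scores = structure(scores[, k, drop = FALSE],
                       dimnames = list(colnames(expr), paste0("PC", k))),
    loadings = structure(sv$v[, k, drop = FALSE],
                         dimnames = list(rownames(expr), paste0("PC", k))),
    var_fraction = stats::setNames(frac[k], paste0("PC", k))),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of expression matrix:", nrow(x$scores), "samples,",
      nrow(x$loadings), "genes\n")
  k <- seq_len(min(5L, length(x$var_fraction)))
  cat("  variance explained:",
      paste(sprintf("%s %.1f%%", names(x$var_fraction)[k],
                    100 * x$var_fraction[k]), collapse = ", "), "\n")
  invisible(x)
}

#' Correlate a principal component with a covariate
#'
#' Pearson correlation between the scores of component `k` and a sample-level
#' covariate, with the two-sided t-based p-value.
#'
#' @param pca a [pca_expression()] result.
#' @param k component index.
#' @param covariate numeric vector, one value per sample.
#' @return list with `r` and `p`.
#' @export
correlate_pc <- function(pca, k, covariate) {
  s <- pca$scores[, k]
  stopifnot(length(covariate) == length(s))
  if (stats::sd(covariate) == 0) stop("covariate has zero variance")
  ct <- stats::cor.test(s, covariate, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
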