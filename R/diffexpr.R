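#' Fit gene-wise linear models
#'
#' Ordinary least squares of each gene's log2 expression on a shared design
#' matrix. The effect of interest is one named design column (by default the
#' group indicator); its coefficient is the log2 group difference. The
#' residual degrees of freedom `n - rank(design)` are shared across genes.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param design numeric design matrix, samples x p, full rank, including an
#'   intercept.
#' @param coef name or index of the design column whose coefficient is the
#'   effect of interest.
#' @return object of class `gene_fit`: `beta` (per-gene effect), `s2`
#'   (per-gene residual variance), `df_residual`, `stdev_unscaled` (the
#'   unit standard error sqrt((X'X)^-1[coef,coef])).
#' @export
fit_gene_models <- function(expr, design, coef = 2L) {
  stopifnot(is.matrix(expr), nrow(design) == ncol(expr))
  design <- as.matrix(design)
  if (ncol(expr) <= ncol(design))
    stop("fewer samples than design columns plus one")
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) stop("design matrix is rank deficient")
  fit <- stats::lm.fit(design, t(expr))
  beta_all <- fit$coefficients
  if (is.character(coef)) coef <- match(coef, colnames(design))
  if (is.na(coef) || coef < 1L || coef > ncol(design))
    stop("coef does not name a design column")
  df_res <- ncol(expr) - qr_x$rank
  res <- t(expr) - design %*% beta_all
  s2 <- colSums(res^2) / df_res
  xtx_inv <- chol2inv(chol(crossprod(design)))
  structure(list(beta = stats::setNames(beta_all[coef, ], rownames(expr)),
                 s2 = stats::setNames(s2, rownames(expr)),
                 df_residual = df_res,
                 stdev_unscaled = sqrt(xtx_inv[coef, coef])),
            class = "gene_fit")
}

#' Build a two-group design matrix
#'
#' Intercept plus an indicator of the imminent-delivery group (so a positive
#' coefficient means higher expression in women delivering within 24 h of
#' amniocentesis), plus optional covariate columns.
#'
#' @param group character or factor of group labels; the level
#'   `"imminent_le_24h"` is the indicator's 1.
#' @param covariates optional data.frame/matrix of numeric covariates.
#' @return design matrix with columns `(Intercept)`, `group`, covariates.
#' @export
de_design <- function(group, covariates = NULL) {
  g <- as.integer(group == "imminent_le_24h")
  X <- cbind(`(Intercept)` = 1, group = g)
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    storage.mode(covariates) <- "double"
    X <- cbind(X, covariates)
  }
  X
}

# Invert the trigamma function by Newton iteration on 1/x steps
# (monotone, converges in a handful of iterations for y > 0).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of gene-wise variances
#'
#' Assumes the hierarchical model in which the true gene variances follow a
#' scaled inverse-chi-square prior with degrees of freedom `d0` and scale
#' `s0^2`. Under that model the sample log-variances are shifted, scaled
#' F-distributed, and the hyperparameters are estimated by moment matching:
#' `e_g = log(s_g^2) - digamma(d/2) + log(d/2)` has mean
#' `log(s0^2) + digamma(d0/2) - log(d0/2)` and excess variance
#' `trigamma(d0/2)`, which is inverted numerically. Posterior variances are
#' the weighted mean `(d0*s0^2 + d*s_g^2)/(d0 + d)`; the moderated t uses
#' them with `d0 + d` degrees of freedom.
#'
#' @param fits a [fit_gene_models()] result with at least 10 genes of
#'   positive residual df.
#' @param prior_df optional forced prior df `d0` (`0` recovers the ordinary
#'   t; `Inf` pools all genes to `s0^2`); by default estimated from the data.
#' @return object of class `moderated_fit`: `prior_df`, `prior_var`,
#'   `s2_post`, `t`, `p`, `df_total`, plus the inputs' `beta`.
#' @export
moderate <- function(fits, prior_df = NULL) {
  stopifnot(inherits(fits, "gene_fit"))
  d <- fits$df_residual
  if (d <= 0) stop("no residual degrees of freedom")
  s2 <- fits$s2
  if (all(s2 <= 0)) stop("all residual variances are zero; moderation is degenerate")
  ok <- s2 > 0
  if (sum(ok) < 10L) stop("need >= 10 genes with positive residual variance")
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (!is.null(prior_df)) {
    d0 <- prior_df
    s0_sq <- if (is.finite(d0) && d0 > 0) {
      exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      exp(emean)                     # d0 = 0 or Inf: bias term vanishes/limits
    }
  } else if (evar <= 0) {
    d0 <- Inf
    s0_sq <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  names(s2_post) <- names(s2)
  tval <- fits$beta / (fits$stdev_unscaled * sqrt(s2_post))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tval), df = df_total)
  structure(list(prior_df = d0, prior_var = s0_sq, s2_post = s2_post,
                 t = tval, p = p, df_total = df_total, beta = fits$beta),
            class = "moderated_fit")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values): `q_(i) = min_{j>=i} p_(j) * m / j`,
#' capped at 1 and mapped back to the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Joint threshold on the linear-scale fold change (strictly greater than
#' `fc_threshold`) and the BH-adjusted p-value (strictly less than
#' `q_threshold`), the published calling rule (fold change > 1.25,
#' q < 0.1). Fold changes are `2^|beta|` with the sign of the log2 effect;
#' positive means up-regulated with imminent delivery.
#'
#' @param mod a [moderate()] result.
#' @param fc_threshold linear-scale fold-change threshold (> 1).
#' @param q_threshold FDR threshold.
#' @return object of class `de_result`: a data.frame with columns `gene`,
#'   `log2fc`, `fold_change`, `t`, `p`, `q`, `direction`, `is_de`, plus
#'   attributes `n_de`, `n_up`, `n_down`.
#' @export
call_de <- function(mod, fc_threshold = 1.25, q_threshold = 0.1) {
  stopifnot(inherits(mod, "moderated_fit"), fc_threshold > 1)
  q <- bh_adjust(mod$p)
  fc <- 2^abs(mod$beta)
  dir <- ifelse(mod$beta >= 0, "up", "down")
  is_de <- (fc > fc_threshold) & (q < q_threshold)
  res <- data.frame(gene = names(mod$beta), log2fc = unname(mod$beta),
                    fold_change = unname(sign(mod$beta) * fc),
                    t = unname(mod$t), p = unname(mod$p), q = unname(q),
                    direction = unname(dir), is_de = unname(is_de),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("de_result", "data.frame"),
            n_de = sum(is_de), n_up = sum(is_de & dir == "up"),
            n_down = sum(is_de & dir == "down"),
            fc_threshold = fc_threshold, q_threshold = q_threshold,
            prior_df = mod$prior_df, prior_var = mod$prior_var)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf(
    "Differential expression: %d genes tested, %d called (%d up, %d down)\n",
    nrow(x), attr(x, "n_de"), attr(x, "n_up"), attr(x, "n_down")))
  cat(sprintf("  thresholds: fold change > %.3g, q < %.3g; prior df %.2f, prior var %.4g\n",
              attr(x, "fc_threshold"), attr(x, "q_threshold"),
              attr(x, "prior_df"), attr(x, "prior_var")))
  invisible(x)
}

#' One-call differential expression
#'
#' Convenience wrapper: builds the two-group design, fits gene-wise models,
#' moderates variances and applies the joint fold-change/q calling rule.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param group group label per sample (`"imminent_le_24h"` vs other).
#' @param covariates optional numeric covariates (samples x k).
#' @param config a [pipeline_config()].
#' @return a `de_result`.
#' @export
differential_expression <- function(expr, group, covariates = NULL,
                                    config = pipeline_config()) {
  fits <- fit_gene_models(expr, de_design(group, covariates), coef = "group")
  call_de(moderate(fits), fc_threshold = config$fc_threshold,
          q_threshold = config$de_q_threshold)
}
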