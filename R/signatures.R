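#' Define tissue-specific signatures from a reference atlas
#'
#' A gene is specific to a tissue when its median expression there is at
#' least `ratio` times (default 30, boundary inclusive) its median over all
#' other tissues. By default the comparison pools the other tissues' values
#' (`compare = "pooled"`); `compare = "max"` instead uses the maximum of the
#' other tissues' medians. A zero denominator is replaced by a pseudocount
#' of 1e-8, which avoids division by zero while leaving attained ratios
#' exact (so the inclusive 30x boundary is honoured). Each signature keeps up to
#' `top_n` genes ranked by descending preferential-expression ratio.
#'
#' @param atlas a `tissue_atlas` (linear-scale, nonnegative, tissues x genes).
#' @param ratio specificity ratio threshold (inclusive).
#' @param top_n maximum genes retained per signature.
#' @param compare `"pooled"` or `"max"` (see above).
#' @return object of class `signature_set`: named list, one element per
#'   tissue with any qualifying gene, each a list of `genes` (ordered by
#'   ratio, descending) and `ratios`.
#' @export
define_signatures <- function(atlas, ratio = 30, top_n = 20,
                              compare = c("pooled", "max")) {
  stopifnot(inherits(atlas, "tissue_atlas"), length(atlas$tissues) >= 2L)
  compare <- match.arg(compare)
  eps <- 1e-8
  v <- atlas$values
  sigs <- list()
  for (t in seq_along(atlas$tissues)) {
    own <- v[t, ]
    others <- v[-t, , drop = FALSE]
    denom <- if (compare == "pooled") {
      apply(others, 2L, stats::median)
    } else {
      apply(others, 2L, max)       # one row per tissue: median = the value
    }
    r <- own / pmax(denom, eps)
    keep <- which(r >= ratio)
    if (!length(keep)) next
    ord <- keep[order(r[keep], decreasing = TRUE)]
    ord <- utils::head(ord, top_n)
    sigs[[atlas$tissues[t]]] <- list(genes = atlas$genes[ord],
                                     ratios = unname(r[ord]))
  }
  structure(sigs, class = "signature_set",
            ratio = ratio, top_n = top_n, compare = compare)
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("%d tissue/cell-type signatures (ratio >= %g, top %d genes)\n",
              length(x), attr(x, "ratio"), attr(x, "top_n")))
  invisible(x)
}

#' Per-sample signature Z-scores
#'
#' Each gene's log2 expression is standardised against the reference study
#' group (Z = (x - mean_ref) / sd_ref); a sample's signature score is the
#' mean Z over the signature's top `top_n` available member genes. Member
#' genes absent from the matrix, or with zero reference standard deviation,
#' are dropped with a warning; a signature left with no genes is dropped.
#'
#' @param expr log2 expression matrix, genes x samples.
#' @param signatures a [define_signatures()] result (or named list of
#'   character vectors of member genes, ordered by preference).
#' @param reference_samples character vector of reference (term-delivery)
#'   sample ids, a non-empty subset of `colnames(expr)`.
#' @param top_n genes averaged per signature.
#' @return matrix of scores, samples x signatures, class `signature_scores`.
#' @export
signature_scores <- function(expr, signatures, reference_samples, top_n = 20) {
  stopifnot(is.matrix(expr), length(reference_samples) >= 2L)
  if (!all(reference_samples %in% colnames(expr)))
    stop("reference_samples must be columns of the expression matrix")
  members <- lapply(signatures, function(s) if (is.list(s)) s$genes else s)
  ref <- expr[, reference_samples, drop = FALSE]
  mu <- rowMeans(ref)
  sd_ref <- apply(ref, 1L, stats::sd)
  usable <- rownames(expr)[sd_ref > 0]
  if (length(usable) < nrow(expr))
    warning(nrow(expr) - length(usable),
            " gene(s) with zero reference sd dropped from scoring")
  z <- (expr[usable, , drop = FALSE] - mu[usable]) / sd_ref[usable]
  out <- matrix(NA_real_, ncol(expr), 0L,
                dimnames = list(colnames(expr), NULL))
  kept <- character(0)
  for (nm in names(members)) {
    g <- members[[nm]]
    missing <- setdiff(g, usable)
    if (length(missing))
      warning("signature ", nm, ": ", length(missing),
              " member gene(s) unavailable")
    g <- utils::head(intersect(g, usable), top_n)
    if (!length(g)) next
    out <- cbind(out, colMeans(z[g, , drop = FALSE]))
    kept <- c(kept, nm)
  }
  colnames(out) <- kept
  structure(out, class = c("signature_scores", "matrix"),
            reference_samples = reference_samples, top_n = top_n)
}

#' Compare signature scores between study groups
#'
#' Per signature, ordinary least squares of the score on the imminent-group
#' indicator (equivalently a pooled-variance two-sample comparison); the
#' difference is imminent minus later. P-values are BH-adjusted across
#' signatures and significance is declared at `q < q_threshold`.
#'
#' @param scores a [signature_scores()] matrix.
#' @param group group label per sample (`"imminent_le_24h"` vs other).
#' @param q_threshold FDR threshold (default 0.05).
#' @return data.frame with `signature`, `difference`, `t`, `p`, `q`,
#'   `significant`.
#' @export
compare_signatures <- function(scores, group, q_threshold = 0.05) {
  g <- group == "imminent_le_24h"
  stopifnot(length(g) == nrow(scores), sum(g) >= 2L, sum(!g) >= 2L)
  n1 <- sum(g); n0 <- sum(!g); n <- n1 + n0
  res <- lapply(colnames(scores), function(nm) {
    y <- scores[, nm]
    diff <- mean(y[g]) - mean(y[!g])
    rss <- sum((y[g] - mean(y[g]))^2) + sum((y[!g] - mean(y[!g]))^2)
    s2 <- rss / (n - 2)
    if (s2 <= 0) {                       # constant within groups
      tval <- 0
      p <- 1
      if (abs(diff) > 0) { tval <- Inf * sign(diff); p <- 0 }
    } else {
      tval <- diff / sqrt(s2 * (1 / n1 + 1 / n0))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
    data.frame(signature = nm, difference = diff, t = tval, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- bh_adjust(res$p)
  res$significant <- res$q < q_threshold
  res
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a gene list (e.g.
#' up-regulated DE genes) and each gene set, within a fixed universe
#' (typically all genes on the expression matrix). `p = P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`; q-values are BH-adjusted across the tested
#' sets and enrichment is declared at `q < q_threshold`.
#'
#' @param de_list character vector of hit genes (intersected with universe).
#' @param universe character vector of all testable genes.
#' @param genesets `gene_sets` object or named list of character vectors.
#' @param q_threshold FDR threshold (default 0.05).
#' @return data.frame of class `enrichment_result` with `set`, `N`, `K`,
#'   `n`, `k`, `p`, `q`, `enriched`.
#' @export
hypergeometric_enrichment <- function(de_list, universe, genesets,
                                      q_threshold = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  de_list <- unique(intersect(de_list, universe))
  if (!length(de_list)) stop("empty gene list after intersecting with universe")
  N <- length(universe); n <- length(de_list)
  rows <- lapply(names(genesets), function(nm) {
    set <- intersect(genesets[[nm]], universe)
    K <- length(set)
    if (K == 0L) return(NULL)
    k <- length(intersect(set, de_list))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, N = N, K = K, n = n, k = k, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no gene set overlaps the universe")
  res$q <- bh_adjust(res$p)
  res$enriched <- res$q < q_threshold
  class(res) <- c("enrichment_result", "data.frame")
  res
}
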