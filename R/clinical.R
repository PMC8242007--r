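#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value by point-probability summation: over all tables with the
#' observed margins, the hypergeometric point probabilities no greater than
#' the observed table's (within a relative tolerance of 1e-7 for floating
#' ties) are summed. This is the convention that reproduces standard
#' clinical-table p-values. An empty row or column margin yields p = 1 with
#' a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts (rows = study group,
#'   columns = condition present/absent).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0), all(tab == round(tab)))
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (r1 == 0L || r1 == n || c1 == 0L || c1 == n) {
    warning("empty margin: p = 1")
    return(1)
  }
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  dens <- stats::dhyper(support, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Welch's unequal-variance t-test
#'
#' `t = (mean(x) - mean(y)) / sqrt(sx^2/nx + sy^2/ny)` with the
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value. With zero
#' variance in both samples and equal means, t = 0 and p = 1.
#'
#' @param x,y numeric vectors (each >= 2 finite values).
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  vx <- stats::var(x) / length(x); vy <- stats::var(y) / length(y)
  if (vx + vy == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = Inf * sign(mean(x) - mean(y)), df = NA_real_, p = 0))
  }
  tval <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Clinical characteristics table
#'
#' Group summaries in the style of a demographics table: continuous
#' variables as median (Q1-Q3) with quartiles by linear interpolation
#' (type-7) and a Welch's t p-value; categorical (binary) variables as
#' count/denominator (%) over non-missing values with a two-sided Fisher's
#' exact p-value. Significance is flagged at a nominal p < 0.05.
#'
#' @param samples data.frame of per-sample metadata.
#' @param variables named character vector mapping variable names (columns of
#'   `samples`) to type, `"continuous"` or `"categorical"`.
#' @param group_by column holding the two group labels.
#' @param reference_level group level reported in the second column; the
#'   other level is reported first.
#' @return data.frame of class `clinical_table` with one row per variable:
#'   `variable`, `type`, `summary_group1`, `summary_group2`, `p`,
#'   `significant`.
#' @export
summarize_cohort <- function(samples, variables,
                             group_by = "group",
                             reference_level = NULL) {
  stopifnot(group_by %in% colnames(samples))
  g <- samples[[group_by]]
  lev <- unique(g)
  if (length(lev) != 2L) stop("group_by must have exactly two levels")
  if (!is.null(reference_level)) lev <- c(setdiff(lev, reference_level),
                                          reference_level)
  unknown <- setdiff(names(variables), colnames(samples))
  if (length(unknown)) stop("unknown variable(s): ",
                            paste(unknown, collapse = ", "))
  quart <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), type = 7,
                                       names = FALSE)
  rows <- lapply(names(variables), function(nm) {
    type <- match.arg(variables[[nm]], c("continuous", "categorical"))
    v <- samples[[nm]]
    out <- data.frame(variable = nm, type = type,
                      summary_group1 = NA_character_,
                      summary_group2 = NA_character_,
                      p = NA_real_, stringsAsFactors = FALSE)
    if (all(is.na(v))) return(out)
    if (type == "continuous") {
      x <- v[g == lev[1L]]; y <- v[g == lev[2L]]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      qx <- quart(x); qy <- quart(y)
      out$summary_group1 <- sprintf("%.1f (%.1f-%.1f)", qx[2], qx[1], qx[3])
      out$summary_group2 <- sprintf("%.1f (%.1f-%.1f)", qy[2], qy[1], qy[3])
      out$p <- welch_t(x, y)$p
    } else {
      v <- as.logical(v)
      a <- sum(v[g == lev[1L]], na.rm = TRUE)
      na_ <- sum(!is.na(v[g == lev[1L]]))
      b <- sum(v[g == lev[2L]], na.rm = TRUE)
      nb <- sum(!is.na(v[g == lev[2L]]))
      out$summary_group1 <- sprintf("%d/%d (%.1f%%)", a, na_, 100 * a / na_)
      out$summary_group2 <- sprintf("%d/%d (%.1f%%)", b, nb, 100 * b / nb)
      out$p <- fisher_exact_2x2(matrix(c(a, na_ - a, b, nb - b), 2L,
                                       byrow = TRUE))
    }
    out
  })
  res <- do.call(rbind, rows)
  res$significant <- !is.na(res$p) & res$p < 0.05
  class(res) <- c("clinical_table", "data.frame")
  attr(res, "groups") <- lev
  res
}

#' @export
print.clinical_table <- function(x, ...) {
  cat("Clinical characteristics (group 1 =", attr(x, "groups")[1L],
      "; group 2 =", attr(x, "groups")[2L], ")\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
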