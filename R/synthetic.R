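#' Simulation configuration for a synthetic preterm-labor cohort
#'
#' Builds the parameter set used by [generate_cohort()], [generate_atlas()]
#' and [generate_genesets()]. Defaults emulate the design of the motivating
#' study: 38 amniotic fluid samples from women sampled after an episode of
#' preterm labor, 10 of whom delivered within 24 h of amniocentesis and 28
#' later, profiled in batches, with a latent intra-amniotic inflammation axis
#' that both up-regulates a block of response genes and shortens the interval
#' from amniocentesis to delivery.
#'
#' @param n_genes number of genes on the array.
#' @param n_samples number of samples; must equal `sum(group_sizes)`.
#' @param group_sizes integer pair: samples delivering within 24 h of
#'   amniocentesis and samples delivering later.
#' @param n_batches number of processing batches (samples assigned round-robin).
#' @param n_response_genes number of genes coupled to the inflammation axis.
#' @param effect_size_log2 expected log2 group difference (imminent minus
#'   later) of a response gene; the per-sample shift is
#'   `effect_size_log2 * z_i / z_shift` so the group contrast equals the
#'   stated value in the noise-free limit.
#' @param up_fraction fraction of response genes shifted upward with imminent
#'   delivery (the remainder are shifted down).
#' @param var_prior_df,var_prior_var prior degrees of freedom d0 and prior
#'   variance s0^2 of the scaled inverse-chi-square distribution the per-gene
#'   residual variances are drawn from, so empirical-Bayes moderation is
#'   well-posed and its hyperparameters are recoverable.
#' @param batch_sd standard deviation of the additive per-gene batch shifts.
#' @param z_shift mean of the latent inflammation score in the imminent group
#'   (the later group is centred at 0, both have unit sd).
#' @param ttd_intercept,ttd_slope,ttd_noise_sd time-to-delivery (weeks) is
#'   `max(ttd_floor, ttd_intercept - ttd_slope * z + noise)`.
#' @param ttd_floor positive floor on time-to-delivery, weeks.
#' @param n_tissues,sig_block_size,sig_fold reference-atlas parameters: number
#'   of tissues, genes per tissue-specific block, and the fold by which a
#'   block gene's level exceeds the background in its tissue.
#' @param n_terms,term_size,planted_terms,planted_fraction gene-set annotation
#'   parameters: number of sets, genes per set, number of sets enriched for
#'   response genes, and the fraction of a planted set drawn from them.
#' @param seed integer RNG seed; all generators are deterministic given the
#'   configuration.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L,
                       n_samples = 38L,
                       group_sizes = c(10L, 28L),
                       n_batches = 2L,
                       n_response_genes = 200L,
                       effect_size_log2 = 1,
                       up_fraction = 0.6,
                       var_prior_df = 4,
                       var_prior_var = 0.05,
                       batch_sd = 0.3,
                       z_shift = 3,
                       ttd_intercept = 3,
                       ttd_slope = 2,
                       ttd_noise_sd = 1.5,
                       ttd_floor = 0.02,
                       n_tissues = 8L,
                       sig_block_size = 20L,
                       sig_fold = 100,
                       n_terms = 50L,
                       term_size = 40L,
                       planted_terms = 5L,
                       planted_fraction = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    group_sizes = as.integer(group_sizes), n_batches = as.integer(n_batches),
    n_response_genes = as.integer(n_response_genes),
    effect_size_log2 = effect_size_log2, up_fraction = up_fraction,
    var_prior_df = var_prior_df, var_prior_var = var_prior_var,
    batch_sd = batch_sd, z_shift = z_shift,
    ttd_intercept = ttd_intercept, ttd_slope = ttd_slope,
    ttd_noise_sd = ttd_noise_sd, ttd_floor = ttd_floor,
    n_tissues = as.integer(n_tissues),
    sig_block_size = as.integer(sig_block_size), sig_fold = sig_fold,
    n_terms = as.integer(n_terms), term_size = as.integer(term_size),
    planted_terms = as.integer(planted_terms),
    planted_fraction = planted_fraction,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L, cfg$n_samples >= 1L, cfg$n_batches >= 1L)
  if (length(cfg$group_sizes) != 2L || any(cfg$group_sizes < 0L))
    stop("group_sizes must be a pair of nonnegative counts")
  if (sum(cfg$group_sizes) != cfg$n_samples)
    stop("group_sizes must sum to n_samples (",
         sum(cfg$group_sizes), " != ", cfg$n_samples, ")")
  if (cfg$n_response_genes > cfg$n_genes)
    stop("n_response_genes exceeds n_genes")
  if (cfg$term_size > cfg$n_genes)
    stop("term_size exceeds the gene universe")
  pos <- c("var_prior_df", "var_prior_var", "batch_sd", "ttd_noise_sd",
           "ttd_floor", "sig_fold")
  for (p in pos) if (cfg[[p]] <= 0) stop(p, " must be strictly positive")
  if (cfg$planted_fraction < 0 || cfg$planted_fraction > 1)
    stop("planted_fraction must lie in [0, 1]")
  invisible(cfg)
}

gene_ids <- function(n) sprintf("G%06d", seq_len(n))
sample_ids <- function(n) sprintf("S%02d", seq_len(n))

#' Generate a synthetic amniotic fluid cell-free RNA cohort
#'
#' Draws a gene-level log2 expression matrix and sample metadata with the
#' statistical structure the downstream analysis assumes. Each sample carries
#' a latent inflammation score `z` (unit-sd, shifted upward by
#' `z_shift` in the imminent-delivery group). Time-to-delivery decreases
#' linearly in `z` with Gaussian noise, floored at `ttd_floor` weeks, so that
#' the imminent group averages about 24 h. Response genes gain a mean shift
#' proportional to `z`; per-gene residual variances are drawn from a scaled
#' inverse-chi-square distribution with hyperparameters
#' (`var_prior_df`, `var_prior_var`); additive per-gene batch shifts with sd
#' `batch_sd` are applied by batch assignment.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `af_cohort`: a list with `expression` (genes x
#'   samples log2 matrix), `samples` (data.frame: sample_id, group, batch,
#'   gestational_age_at_amnio, time_to_delivery, reference_group, il6_high),
#'   and `truth` (response gene ids and signs, per-sample latent inflammation
#'   score, the per-gene residual variances used).
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_samples
  gid <- gene_ids(ng); sid <- sample_ids(ns)

  group <- rep(c("imminent_le_24h", "later_gt_24h"), times = config$group_sizes)
  z <- stats::rnorm(ns) + ifelse(group == "imminent_le_24h", config$z_shift, 0)
  ttd <- pmax(config$ttd_floor,
              config$ttd_intercept - config$ttd_slope * z +
                stats::rnorm(ns, sd = config$ttd_noise_sd))
  batch <- paste0("B", rep_len(seq_len(config$n_batches), ns))
  ga <- round(stats::runif(ns, 22, 34), 1)

  # per-gene residual variances: scaled inverse chi-square(d0, s0^2)
  s2 <- config$var_prior_df * config$var_prior_var /
    stats::rchisq(ng, df = config$var_prior_df)
  mu <- stats::runif(ng, 4, 12)

  resp_idx <- seq_len(config$n_response_genes)
  sign_vec <- integer(0)
  if (config$n_response_genes > 0L) {
    n_up <- round(config$up_fraction * config$n_response_genes)
    sign_vec <- sample(c(rep(1L, n_up),
                         rep(-1L, config$n_response_genes - n_up)))
  }

  expr <- matrix(stats::rnorm(ng * ns, sd = rep(sqrt(s2), ns)),
                 nrow = ng, ncol = ns, dimnames = list(gid, sid))
  expr <- expr + mu
  if (config$n_response_genes > 0L && config$z_shift != 0) {
    beta <- config$effect_size_log2 / config$z_shift
    expr[resp_idx, ] <- expr[resp_idx, ] +
      outer(sign_vec * beta, z)
  }
  if (config$n_batches > 1L) {
    shifts <- matrix(stats::rnorm(ng * config$n_batches, sd = config$batch_sd),
                     nrow = ng)
    expr <- expr + shifts[, match(batch, paste0("B", seq_len(config$n_batches)))]
  }

  samples <- data.frame(
    sample_id = sid, group = group, batch = batch,
    gestational_age_at_amnio = ga,
    time_to_delivery = ttd,
    reference_group = group == "later_gt_24h" & ttd > 3,
    il6_high = z > stats::quantile(z, 0.6),
    stringsAsFactors = FALSE)

  truth <- list(response_genes = gid[resp_idx],
                response_sign = sign_vec,
                inflammation = stats::setNames(z, sid),
                residual_var = stats::setNames(s2, gid))
  structure(list(expression = expr, samples = samples, truth = truth,
                 config = config),
            class = "af_cohort")
}

#' @export
print.af_cohort <- function(x, ...) {
  cat("Synthetic amniotic fluid cohort\n")
  cat(sprintf("  %d genes x %d samples (%d imminent <=24h, %d later)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$samples$group == "imminent_le_24h"),
              sum(x$samples$group == "later_gt_24h")))
  cat(sprintf("  %d response genes coupled to the inflammation axis; %d batches\n",
              length(x$truth$response_genes), length(unique(x$samples$batch))))
  invisible(x)
}

#' Generate a synthetic tissue reference atlas
#'
#' Builds a nonnegative linear-scale expression matrix (tissues x genes) in
#' which each tissue owns a disjoint block of `sig_block_size` genes raised
#' `sig_fold`-fold above the shared background, while background genes are
#' uniform across tissues. Blocks start after the response-gene block so
#' signature genes and inflammation-response genes do not collide.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `tissue_atlas`: list with `values` (tissues x
#'   genes matrix), `tissues`, `genes`.
#' @export
generate_atlas <- function(config = sim_config()) {
  validate_sim_config(config)
  if (config$n_tissues < 2L) stop("need at least 2 tissues")
  need <- config$n_response_genes + config$n_tissues * config$sig_block_size
  if (need > config$n_genes)
    stop("tissue blocks exceed the gene universe (need ", need,
         " genes, have ", config$n_genes, ")")
  set.seed(config$seed + 101L)
  gid <- gene_ids(config$n_genes)
  tis <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  background <- stats::runif(config$n_genes, 50, 150)
  vals <- matrix(rep(background, each = config$n_tissues),
                 nrow = config$n_tissues, ncol = config$n_genes,
                 dimnames = list(tis, gid))
  for (t in seq_len(config$n_tissues)) {
    block <- config$n_response_genes + (t - 1L) * config$sig_block_size +
      seq_len(config$sig_block_size)
    vals[t, block] <- vals[t, block] * config$sig_fold
  }
  structure(list(values = vals, tissues = tis, genes = gid),
            class = "tissue_atlas")
}

#' Generate gene-set annotations with planted enrichment
#'
#' The first `planted_terms` sets draw `planted_fraction` of their members
#' from the cohort's planted response genes and the rest uniformly from the
#' remaining universe; all other sets draw uniformly from the whole universe
#' and act as nulls.
#'
#' @param config a [sim_config()] object.
#' @param truth the `truth` component of an [generate_cohort()] result.
#' @return an object of class `gene_sets`: named list of character vectors,
#'   with attribute `planted` naming the enriched sets.
#' @export
generate_genesets <- function(config = sim_config(), truth) {
  validate_sim_config(config)
  set.seed(config$seed + 202L)
  gid <- gene_ids(config$n_genes)
  resp <- intersect(truth$response_genes, gid)
  other <- setdiff(gid, resp)
  sets <- vector("list", config$n_terms)
  names(sets) <- sprintf("TERM%03d", seq_len(config$n_terms))
  n_resp_draw <- round(config$planted_fraction * config$term_size)
  for (i in seq_len(config$n_terms)) {
    if (i <= config$planted_terms && length(resp) > 0L) {
      k <- min(n_resp_draw, length(resp))
      sets[[i]] <- c(sample(resp, k),
                     sample(other, config$term_size - k))
    } else {
      sets[[i]] <- sample(gid, config$term_size)
    }
  }
  structure(sets, class = "gene_sets",
            planted = names(sets)[seq_len(config$planted_terms)])
}
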