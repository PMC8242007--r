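# Independent brute-force oracles used to validate the analytic routines.
# These stay deliberately naive (loops, enumeration, closed forms) and share
# no code with the implementation.

# Two-sided Fisher p by explicit enumeration of the hypergeometric support,
# point probabilities from choose().
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- sapply(support, function(a)
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1))
  obs <- pr[match(tab[1, 1], support)]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# BH step-up computed literally from its definition.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) p[ord[j]] * m / j)
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# Upper-tail hypergeometric p by enumerating every size-n subset of the
# universe as an equally likely gene list.
oracle_hyper <- function(N, K, n, k) {
  universe <- seq_len(N)
  inset <- universe <= K
  subsets <- utils::combn(N, n)
  mean(apply(subsets, 2, function(s) sum(inset[s]) >= k))
}

# AUROC by exhaustive positive/negative pair counting with half-credit ties.
oracle_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Cohen's kappa from the 2x2 agreement table.
oracle_kappa <- function(a, b, universe) {
  ina <- universe %in% a; inb <- universe %in% b
  n11 <- sum(ina & inb); n00 <- sum(!ina & !inb)
  po <- (n11 + n00) / length(universe)
  pe <- mean(ina) * mean(inb) + mean(!ina) * mean(!inb)
  (po - pe) / (1 - pe)
}

# A small cohort most tests share (fast to generate, full structure).
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 300, n_response_genes = 40,
         n_tissues = 4, sig_block_size = 10,
         n_terms = 20, term_size = 15, planted_terms = 3,
         seed = seed),
    list(...))
  do.call(sim_config, args)
}
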