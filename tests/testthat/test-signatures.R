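test_that("specificity screening selects exclusive genes and drops uniform ones", {
  v <- rbind(tisA = c(100, 5, 5, 0.1),
             tisB = c(0,  5, 5, 200),
             tisC = c(0,  5, 5, 0.1))
  colnames(v) <- paste0("G", 1:4)
  atlas <- structure(list(values = v, tissues = rownames(v),
                          genes = colnames(v)), class = "tissue_atlas")
  sigs <- define_signatures(atlas, ratio = 30, top_n = 20)
  # G1 expressed only in tisA: ratio = 100 / 1e-8, ranked first
  expect_identical(sigs$tisA$genes, "G1")
  expect_equal(sigs$tisA$ratios, 100 / 1e-8)
  # uniform genes G2, G3 excluded everywhere
  expect_false(any(c("G2", "G3") %in% unlist(lapply(sigs, `[[`, "genes"))))
  expect_identical(sigs$tisB$genes, "G4")
  # pooled vs max-of-other-medians switch
  v2 <- rbind(tisA = c(90), tisB = c(3), tisC = c(1))
  colnames(v2) <- "G1"
  atlas2 <- structure(list(values = v2, tissues = rownames(v2),
                           genes = "G1"), class = "tissue_atlas")
  expect_identical(define_signatures(atlas2, ratio = 30,
                                     compare = "pooled")$tisA$genes, "G1")
  expect_null(define_signatures(atlas2, ratio = 31, compare = "max")$tisA)
})

test_that("signature Z-scores are reference-anchored, linear, and order-invariant", {
  co <- generate_cohort(small_config(seed = 12))
  expr <- co$expression
  sigs <- list(sigX = rownames(expr)[1:10], sigY = rownames(expr)[11:20])
  # all samples as reference: scores average to zero across samples
  sc_all <- signature_scores(expr, sigs, colnames(expr))
  expect_true(all(abs(colMeans(sc_all)) < 1e-10))
  # reference anchoring within construction tolerance
  ref <- co$samples$sample_id[co$samples$reference_group]
  sc <- signature_scores(expr, sigs, ref)
  expect_true(all(abs(colMeans(sc[ref, ])) < 0.15))
  # adding delta to every member gene of sigX in non-reference samples
  # shifts those samples' score by ~ delta / ref sd
  delta <- 0.8
  expr2 <- expr
  nonref <- setdiff(colnames(expr), ref)
  expr2[sigs$sigX, nonref] <- expr2[sigs$sigX, nonref] + delta
  sc2 <- signature_scores(expr2, sigs, ref)
  sd_ref <- apply(expr[sigs$sigX, ref], 1, sd)
  expected_shift <- mean(delta / sd_ref)
  expect_equal(mean(sc2[nonref, "sigX"] - sc[nonref, "sigX"]),
               expected_shift, tolerance = 1e-10)
  expect_equal(sc2[, "sigY"], sc[, "sigY"], tolerance = 1e-12)
  # invariance to gene and sample ordering
  perm_g <- sample(nrow(expr)); perm_s <- sample(ncol(expr))
  sc_perm <- signature_scores(expr[perm_g, perm_s], sigs, ref)
  expect_equal(sc_perm[rownames(sc), ], sc, tolerance = 1e-12,
               ignore_attr = TRUE)
  # absent genes warn; fully absent signature is dropped
  expect_warning(sc3 <- signature_scores(expr, c(sigs, list(gone = "NOPE")),
                                         ref), "unavailable")
  expect_false("gone" %in% colnames(sc3))
})

test_that("group comparison of scores is the OLS group-mean difference", {
  set.seed(5)
  group <- rep(c("imminent_le_24h", "later_gt_24h"), c(10, 28))
  scores <- matrix(rnorm(38 * 3), 38, 3,
                   dimnames = list(paste0("S", 1:38), paste0("sig", 1:3)))
  cmp <- compare_signatures(scores, group)
  imm <- group == "imminent_le_24h"
  for (j in 1:3) {
    expect_equal(cmp$difference[j],
                 mean(scores[imm, j]) - mean(scores[!imm, j]),
                 tolerance = 1e-12)
    lm_p <- summary(lm(scores[, j] ~ imm))$coefficients[2, 4]
    expect_equal(cmp$p[j], lm_p, tolerance = 1e-10)
  }
  # permuting labels within one group leaves differences ~ 0 in expectation
  sym <- matrix(rnorm(38), 38, 1, dimnames = list(paste0("S", 1:38), "s"))
  cmp_null <- compare_signatures(sym, sample(group))
  expect_lt(abs(cmp_null$difference), 1)       # no systematic separation
  # constant scores: p = 1
  const <- matrix(2, 38, 1, dimnames = list(paste0("S", 1:38), "c"))
  expect_equal(compare_signatures(const, group)$p, 1)
})

test_that("a planted score shift at study group sizes is reliably detected", {
  hits <- sapply(1:20, function(s) {
    set.seed(400 + s)
    group <- rep(c("imminent_le_24h", "later_gt_24h"), c(10, 28))
    scores <- matrix(rnorm(38 * 5, sd = 0.5), 38, 5,
                     dimnames = list(paste0("S", 1:38), paste0("sig", 1:5)))
    scores[group == "imminent_le_24h", 1] <-
      scores[group == "imminent_le_24h", 1] + 1.0
    cmp <- compare_signatures(scores, group, q_threshold = 0.05)
    cmp$significant[cmp$signature == "sig1"]
  })
  expect_gte(mean(hits), 0.95)
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  # N = 20, K = 5, n = 5, k = 5 -> p = 1 / choose(20, 5)
  uni <- paste0("G", 1:20)
  sets <- list(S = uni[1:5])
  res <- hypergeometric_enrichment(uni[1:5], uni, sets)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  # k = 0 -> upper tail from 0 is 1
  res0 <- hypergeometric_enrichment(uni[6:10], uni, sets)
  expect_equal(res0$p, 1)
  # exhaustive subset enumeration on a universe of 8
  uni8 <- paste0("G", 1:8)
  for (K in c(2, 3, 5)) for (n in c(2, 4, 6)) {
    set_genes <- uni8[seq_len(K)]
    off_genes <- setdiff(uni8, set_genes)
    for (k in max(0, n - length(off_genes)):min(K, n)) {
      p_exp <- oracle_hyper(8, K, n, k)
      de_list <- c(head(set_genes, k), head(off_genes, n - k))
      got <- hypergeometric_enrichment(de_list, uni8,
                                       list(S = set_genes))$p
      expect_equal(got, p_exp, tolerance = 1e-12)
    }
  }
  expect_error(hypergeometric_enrichment(character(0), uni, sets), "empty")
})

test_that("enrichment p-values are super-uniform under random lists and monotone in k", {
  set.seed(31)
  uni <- paste0("G", 1:100)
  sets <- list(A = uni[1:20], B = uni[41:60])
  pvals <- replicate(200, {
    hypergeometric_enrichment(sample(uni, 15), uni, sets)$p
  })
  for (j in 1:2)
    expect_gte(mean(pvals[j, ] > 0.5), 0.40)   # empirical super-uniformity
  # monotone decreasing in k at fixed margins
  ps <- sapply(0:10, function(k) {
    de <- c(uni[seq_len(k)], uni[91:100])[1:10]
    hypergeometric_enrichment(de, uni, list(A = uni[1:20]))$p
  })
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("planted terms outrank null terms on synthetic cohorts", {
  wins <- sapply(1:10, function(s) {
    cfg <- small_config(seed = 500 + s)
    co <- generate_cohort(cfg)
    gs <- generate_genesets(cfg, co$truth)
    de <- differential_expression(co$expression, co$samples$group)
    hits <- de$gene[de$is_de]
    res <- hypergeometric_enrichment(hits, de$gene, gs)
    planted <- res$set %in% attr(gs, "planted")
    max(res$p[planted]) < min(res$p[!planted])
  })
  expect_gte(mean(wins), 0.9)
})
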