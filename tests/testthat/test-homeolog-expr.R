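# The cross-mapping filter, normalization chain, homeolog statistics and
# the Wilcoxon DE machinery.

make_em <- function(counts, subgenome, species, lengths = NULL) {
  n <- nrow(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  if (is.null(lengths)) lengths <- rep(1000, n)
  genes <- data.frame(gene_id = rownames(counts), length = lengths,
                      subgenome = subgenome)
  samples <- data.frame(sample = colnames(counts), species = species,
                        accession = colnames(counts), replicate = 1L)
  expression_matrix(counts, genes, samples)
}

test_that("cross-mapping filter removes genes driven by the wrong species", {
  counts <- rbind(g_keep = c(100, 100, 0, 0),
                  g_drop = c(10, 10, 100, 100),
                  g_tie  = c(50, 50, 50, 50),
                  a_keep = c(0, 0, 80, 80))
  em <- make_em(counts, c("TH", "TH", "TH", "AR"),
                c("thaliana", "thaliana", "arenosa", "arenosa"))
  kept <- filter_cross_mappers(em)
  expect_true(all(c("g_keep", "g_tie", "a_keep") %in% kept))
  expect_false("g_drop" %in% kept)
})

test_that("TPM sums to one million and is scale- and closed-form-correct", {
  counts <- cbind(s1 = c(10, 10), s2 = c(3, 7))
  tpm <- compute_tpm(counts, lengths = c(1000, 2000))
  expect_equal(colSums(tpm), c(s1 = 1e6, s2 = 1e6))
  # equal counts at lengths L and 2L split 2:1
  expect_equal(tpm[, "s1"], c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  expect_equal(compute_tpm(counts * 2, c(1000, 2000)), tpm)
  # a single expressed gene takes the whole million
  one <- compute_tpm(cbind(s = c(5, 0)), c(1000, 2000))
  expect_equal(unname(one[1, 1]), 1e6)
})

test_that("TMM factors are 1 for duplicated or globally rescaled samples", {
  set.seed(1)
  a <- rnbinom(200, mu = 100, size = 5) + 1
  counts <- cbind(a = a, dup = a, double = 2 * a)
  f <- tmm_factors(counts)
  expect_equal(unname(f), c(1, 1, 1), tolerance = 1e-9)
  expect_equal(exp(mean(log(tmm_factors(cbind(a, a + rpois(200, 20)))))), 1,
               tolerance = 1e-12)
})

test_that("TMM matches the reference edgeR implementation on a 100-gene fixture", {
  set.seed(7)
  counts <- matrix(rnbinom(100 * 4, mu = 80, size = 2), ncol = 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  counts[counts == 0] <- 1
  mine <- tmm_factors(counts)
  oracle <- edgeR::calcNormFactors(counts, method = "TMM")
  expect_equal(unname(mine), unname(oracle), tolerance = 1e-6)
})

test_that("effective library sizes balance the two subgenomes in allopolyploids", {
  tpm <- rbind(th_gene = c(1e6, 4e6, 1e6), ar_gene = c(3e6, 2e6, 5e6))
  colnames(tpm) <- c("sue", "ath", "aar")
  samples <- data.frame(sample = colnames(tpm),
                        species = c("suecica_natural", "thaliana", "arenosa"),
                        accession = colnames(tpm), replicate = 1L)
  sz <- effective_library_sizes(tpm, c("TH", "AR"), samples)
  expect_equal(unname(sz["sue"]), 2e6)   # mean of the subgenome totals
  # ancestors use only their own subgenome's total
  expect_equal(unname(sz["ath"]), 4e6)
  expect_equal(unname(sz["aar"]), 5e6)
  # equal subgenome totals give that total
  tpm2 <- rbind(th = 5e5, ar = 5e5)
  colnames(tpm2) <- "sue"
  sz2 <- effective_library_sizes(tpm2, c("TH", "AR"), samples[1, ])
  expect_equal(unname(sz2), 5e5)
})

test_that("log CPM hits its closed-form anchors and is monotone in counts", {
  expect_equal(log_cpm(matrix(0), 1e6, prior = 1)[1], 0)
  expect_equal(log_cpm(matrix(1023), 1e6, prior = 1)[1], 10)
  x <- log_cpm(matrix(0:50, ncol = 1), 1e6)
  expect_true(all(diff(x[, 1]) > 0))
})

test_that("the normalization pipeline is invariant to rescaling one sample", {
  p <- tiny_params()
  ref <- tiny_reference(p)
  sim <- simulate_expression(ref$annotation, ref$map, tiny_design(), p)
  em2 <- sim$matrix
  em2$counts[, 3] <- em2$counts[, 3] * 5L
  n1 <- normalize_expression(sim$matrix)
  n2 <- normalize_expression(em2)
  expect_equal(n2$logcpm, n1$logcpm, tolerance = 1e-12)
})

test_that("expression filtering enforces the per-panel accession thresholds", {
  accs <- c(paste0("th", 1:4), paste0("ar", 1:2), paste0("sn", 1:4), "ss1")
  species <- c(rep("thaliana", 4), rep("arenosa", 2),
               rep("suecica_natural", 4), "suecica_synthetic")
  hi <- 5; lo <- -5   # log2 CPM clearly above / below the CPM > 1 cutoff
  x <- matrix(hi, nrow = 4, ncol = length(accs),
              dimnames = list(c("t1", "a1", "t2", "a2"), accs))
  # pair 2 (t2/a2): t2 expressed in only 2 thaliana accessions
  x["t2", c("th3", "th4")] <- lo
  norm <- fake_norm(x, species, c("TH", "AR", "TH", "AR"))
  map <- data.frame(pair_id = c("p1", "p2"), th_gene = c("t1", "t2"),
                    ar_gene = c("a1", "a2"))
  kept <- expression_filter(norm, map)
  expect_equal(kept$pair_id, "p1")
  # synthetic-only expression is dropped too
  x2 <- matrix(lo, nrow = 2, ncol = length(accs),
               dimnames = list(c("t1", "a1"), accs))
  x2[, "ss1"] <- hi
  norm2 <- fake_norm(x2, species, c("TH", "AR"))
  expect_equal(nrow(expression_filter(norm2, map[1, ])), 0)
  # a missing panel drops its threshold with a warning
  keep3 <- species != "suecica_synthetic"
  expect_warning(
    kept3 <- expression_filter(fake_norm(x[, keep3], species[keep3],
                                         c("TH", "AR", "TH", "AR")), map),
    "absent")
  expect_equal(kept3$pair_id, "p1")
})

test_that("homeolog logFC is zero at parity, +2 at 4x AR, and antisymmetric", {
  accs <- paste0("sn", 1:3)
  x <- rbind(t1 = c(3, 3, 3), a1 = c(3, 3, 3),
             t2 = c(1, 2, 3), a2 = c(3, 4, 5))
  colnames(x) <- accs
  norm <- fake_norm(x, rep("suecica_natural", 3), c("TH", "AR", "TH", "AR"))
  map <- data.frame(pair_id = c("p1", "p2"), th_gene = c("t1", "t2"),
                    ar_gene = c("a1", "a2"))
  hp <- homeolog_logfc(norm, map)
  expect_equal(unname(hp$pair_mean["p1"]), 0)
  expect_equal(unname(hp$pair_mean["p2"]), 2)   # AR = 4x TH in CPM
  swapped <- fake_norm(x, rep("suecica_natural", 3),
                       c("AR", "TH", "AR", "TH"))
  map_sw <- data.frame(pair_id = c("p1", "p2"), th_gene = c("a1", "a2"),
                       ar_gene = c("t1", "t2"))
  hp_sw <- homeolog_logfc(swapped, map_sw)
  expect_equal(hp_sw$logfc, -hp$logfc, ignore_attr = TRUE)
})

test_that("tissue specificity flags members at |logFC| >= 2, inclusive", {
  accs <- paste0("sn", 1:2)
  mk <- function(delta) {
    x <- cbind(r1 = c(5, 5), r2 = c(5, 5), f1 = c(5 - delta, 5),
               f2 = c(5 - delta, 5))
    rownames(x) <- c("t1", "a1")
    samples <- data.frame(sample = colnames(x), species = "suecica_natural",
                          accession = c("sn1", "sn2", "sn1", "sn2"),
                          replicate = 1L,
                          tissue = c("rosette", "rosette", "flower", "flower"))
    genes <- data.frame(gene_id = rownames(x), length = 1000,
                        subgenome = c("TH", "AR"))
    structure(list(logcpm = x, prior = 1, genes = genes, samples = samples),
              class = "normalized_expression")
  }
  map <- data.frame(pair_id = "p1", th_gene = "t1", ar_gene = "a1")
  t3 <- tissue_specific_pairs(mk(3), map, c("rosette", "flower"))
  expect_true(t3$th_flagged); expect_true(t3$pair_flagged)
  t15 <- tissue_specific_pairs(mk(1.5), map, c("rosette", "flower"))
  expect_false(t15$th_flagged); expect_false(t15$pair_flagged)
  t2 <- tissue_specific_pairs(mk(2), map, c("rosette", "flower"))
  expect_true(t2$th_flagged)
  expect_error(tissue_specific_pairs(mk(2), map, c("rosette", "root")),
               "tissue")
})

test_that("Wilcoxon DE matches exact enumeration and wilcox.test", {
  # identical groups: p = 1
  x <- matrix(rep(c(1, 2, 3, 4, 1, 2, 3, 4), 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("a", 1:8)))
  norm <- fake_norm(x, rep("thaliana", 8), c("TH", "TH"))
  de <- differential_expression(norm, paste0("a", 1:4), paste0("a", 5:8))
  expect_equal(de$p, c(1, 1))

  # fully separated ranks at n = 4 vs 4: brute-force enumeration oracle
  x2 <- matrix(c(1, 2, 3, 4, 10, 11, 12, 13), nrow = 1,
               dimnames = list("g", paste0("a", 1:8)))
  vals <- x2[1, ]
  combos <- combn(8, 4)
  w_obs <- sum(rank(vals)[1:4]) - 10
  w_all <- apply(combos, 2, function(ix) sum(rank(vals)[ix]) - 10)
  p_brute <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  norm2 <- fake_norm(x2, rep("thaliana", 8), "TH")
  de2 <- differential_expression(norm2, paste0("a", 1:4), paste0("a", 5:8))
  expect_equal(de2$p, p_brute)
  expect_equal(p_brute, 2 / 70)

  # random data, exact path and tie path, against stats::wilcox.test
  set.seed(3)
  x3 <- matrix(c(rnorm(40), sample(1:3, 24, TRUE)), nrow = 8, byrow = TRUE)
  rownames(x3) <- paste0("g", 1:8); colnames(x3) <- paste0("a", 1:8)
  norm3 <- fake_norm(x3, rep("thaliana", 8), rep("TH", 8))
  de3 <- differential_expression(norm3, paste0("a", 1:4), paste0("a", 5:8))
  oracle <- vapply(1:8, function(i) {
    suppressWarnings(wilcox.test(x3[i, 1:4], x3[i, 5:8],
                                 correct = TRUE)$p.value)
  }, numeric(1))
  expect_equal(de3$p, oracle, tolerance = 1e-10)

  # large groups take the normal path; still agrees with wilcox.test
  set.seed(4)
  x4 <- matrix(rnorm(30), nrow = 1,
               dimnames = list("g", paste0("a", 1:30)))
  norm4 <- fake_norm(x4, rep("thaliana", 30), "TH")
  de4 <- differential_expression(norm4, paste0("a", 1:15), paste0("a", 16:30))
  or4 <- suppressWarnings(wilcox.test(x4[1, 1:15], x4[1, 16:30], exact = FALSE,
                                      correct = TRUE)$p.value)
  expect_equal(de4$p, or4, tolerance = 1e-10)
})

test_that("PCA per subgenome orders variance and fixes signs deterministically", {
  p <- tiny_params()
  ref <- tiny_reference(p)
  sim <- simulate_expression(ref$annotation, ref$map, tiny_design(), p)
  norm <- normalize_expression(sim$matrix)
  pc <- pca_by_subgenome(norm, n_components = 3)
  for (sg in c("TH", "AR")) {
    ev <- pc[[sg]]$explained_variance
    expect_true(all(diff(ev) <= 1e-9))
    cv <- cov(pc[[sg]]$scores)
    expect_equal(cv[upper.tri(cv)], rep(0, sum(upper.tri(cv))),
                 tolerance = 1e-8)
    # largest loading of each component is positive (sign convention)
    for (j in seq_len(ncol(pc[[sg]]$loadings))) {
      l <- pc[[sg]]$loadings[, j]
      expect_gt(l[which.max(abs(l))], 0)
    }
  }
})

test_that("DEG clustering separates planted patterns and is order-invariant", {
  set.seed(9)
  up <- matrix(rep(c(5, 5, 0, 0), each = 10), nrow = 10) +
    matrix(rnorm(40, sd = 0.1), nrow = 10)
  down <- matrix(rep(c(0, 0, 5, 5), each = 10), nrow = 10) +
    matrix(rnorm(40, sd = 0.1), nrow = 10)
  x <- rbind(up, down)
  rownames(x) <- paste0("g", 1:20)
  lab <- cluster_degs(x, k = 2)
  expect_equal(length(unique(lab[1:10])), 1)
  expect_equal(length(unique(lab[11:20])), 1)
  expect_true(lab[1] != lab[11])
  perm <- sample(20)
  expect_equal(cluster_degs(x[perm, ], k = 2)[rownames(x)], lab)
  expect_equal(unname(unique(cluster_degs(x, k = 1))), 1L)
  # zero-variance gene is assigned to the nearest centroid
  x2 <- rbind(x, flat = rep(4, 4))
  lab2 <- cluster_degs(x2, k = 2)
  expect_true(lab2["flat"] %in% 1:2)
})
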