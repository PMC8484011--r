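test_that("insertion merging is single-linkage within 400 bp per family and idempotent", {
  calls <- data.frame(chrom = "TH1", pos = c(100, 450, 2000, 2401, 3000),
                      family = c("fA", "fA", "fA", "fB", "fB"))
  m <- merge_insertions(calls)
  # 100/450 merge (gap 350 <= 400); 2000 stays; fB: 2401 and 3000 stay apart
  expect_equal(nrow(m), 4)
  expect_equal(m$pos[m$family == "fA"], c(275, 2000))
  # boundary: a gap of exactly 400 merges, 401 does not
  expect_equal(nrow(merge_insertions(
    data.frame(chrom = "c", pos = c(100, 500), family = "f"))), 1)
  expect_equal(nrow(merge_insertions(
    data.frame(chrom = "c", pos = c(100, 501), family = "f"))), 2)
  # same positions, different families: never merged
  expect_equal(nrow(merge_insertions(
    data.frame(chrom = "c", pos = c(100, 200), family = c("f1", "f2")))), 2)
  # idempotence
  expect_equal(merge_insertions(m[, 1:3])$pos, m$pos)
})

test_that("sharing classification matches sites across panels and partitions them", {
  poly <- te_matrix(data.frame(chrom = "TH1", pos = c(100, 5000, 9000),
                               family = "fA", subgenome = "TH"),
                    cbind(a1 = c(1L, 1L, 0L), a2 = c(0L, 1L, 1L)),
                    species = "suecica")
  anc <- te_matrix(data.frame(chrom = "TH1", pos = c(350, 7000),
                              family = "fA", subgenome = "TH"),
                   cbind(t1 = c(1L, 1L), t2 = c(1L, 0L)),
                   species = "thaliana")
  cls <- classify_sharing(poly, anc)
  expect_equal(sort(cls$class), c("shared", "unique_ancestor",
                                  "unique_polyploid", "unique_polyploid"))
  expect_equal(cls$class[cls$pos == 100], "shared")     # matched at 350
  expect_equal(nrow(cls), 4)                            # partition of the union
  # mismatched subgenome coordinates are an error
  anc_ar <- te_matrix(data.frame(chrom = "AR1", pos = 1, family = "fA",
                                 subgenome = "AR"), cbind(t1 = 1L))
  expect_error(classify_sharing(poly, anc_ar), "different subgenome")
})

test_that("genome load is the median present count with missing cells excluded", {
  sites <- data.frame(chrom = "TH1", pos = c(1, 500, 1000) * 10,
                      family = c("fA", "fB", "fC"))
  calls <- cbind(a1 = c(1L, NA, 0L), a2 = c(1L, 1L, 0L), a3 = c(1L, 1L, 1L))
  mat <- te_matrix(sites, calls)
  gl <- genome_load(mat)
  expect_equal(gl$median_load, 2)   # per-accession loads 1, 2, 3
  per <- attr(gl, "per_accession")
  expect_equal(unname(per["all", ]), c(1, 2, 3))
  # identical accessions: the common count
  same <- te_matrix(sites, cbind(a = c(1L, 0L, 1L), b = c(1L, 0L, 1L),
                                 c = c(1L, 0L, 1L)))
  expect_equal(genome_load(same)$median_load, 2)
  # counts {1, 2, 9}: median 2
  wide <- te_matrix(data.frame(chrom = "c", pos = 10 * (1:9), family = "f"),
                    matrix(c(rep(0L, 8), 1L, rep(0L, 7), 1L, 1L, rep(1L, 9)),
                           nrow = 9))
  expect_equal(genome_load(wide)$median_load, 2)
})

test_that("4n pooling takes the accession union and is bounded by it", {
  sites <- data.frame(chrom = "AR1", pos = 100 * (1:18), family = "f")
  calls <- matrix(0L, 18, 5,
                  dimnames = list(NULL, paste0("s", 1:5)))
  calls[1:3, 1] <- 1L; calls[4:7, 2] <- 1L; calls[8:12, 3] <- 1L
  calls[13:18, 4] <- 1L; calls[, 5] <- 0L
  mat <- te_matrix(sites, calls)
  # force the four disjoint accessions by pooling a 4-column panel
  mat4 <- te_matrix(sites, calls[, 1:4])
  pool <- pool_4n(mat4, k = 4, seed = 1)
  expect_equal(pool$load, 18)   # union of disjoint sets of 3+4+5+6
  # pooled count is at least the largest single accession
  pool5 <- pool_4n(mat, k = 4, seed = 2)
  expect_gte(pool5$load, max(colSums(calls[, pool5$accessions] == 1)))
  # identical accessions pool to themselves
  same <- te_matrix(sites, matrix(rep(c(1L, 0L), c(10, 8)), 18, 4))
  expect_equal(pool_4n(same, seed = 3)$load, 10)
  expect_error(pool_4n(te_matrix(sites, calls[, 1:3]), k = 4), "smaller")
})

test_that("the SFS bins by count class and conserves included sites", {
  calls <- rbind(c(1L, 1L, 0L, 0L, 0L),
                 c(1L, 0L, 0L, 0L, 0L),
                 c(1L, 1L, 1L, 1L, 1L),
                 c(0L, 0L, 0L, 0L, 0L))
  sfs <- compute_sfs(calls)
  expect_equal(sfs$n, 5)
  expect_equal(unname(sfs$counts[c("1", "2", "5")]), c(1, 1, 1))
  expect_equal(sum(sfs$counts), sfs$n_sites)  # conservation, fixed included
  # rare-skewed Beta frequencies give a larger singleton share
  set.seed(5)
  draw <- function(a, b) {
    f <- rbeta(400, a, b)
    matrix(rbinom(400 * 10, 1, rep(f, 10)), nrow = 400)
  }
  s_rare <- compute_sfs(draw(0.2, 2))
  s_common <- compute_sfs(draw(2, 0.2))
  expect_gt(s_rare$counts["1"] / s_rare$n_sites,
            s_common$counts["1"] / s_common$n_sites)
})

test_that("the joint SFS has consistent marginals and concentrates fixed sites", {
  fa <- c(1, 1, 1); fp <- c(1, 1, 1)
  j <- joint_sfs(fa, fp)
  expect_equal(unname(j$counts[10, 10]), 3)  # single corner bin
  set.seed(6)
  fa2 <- runif(200); fp2 <- runif(200); fp2[sample(200, 50)] <- NA
  j2 <- joint_sfs(fa2, fp2)
  expect_equal(sum(j2$counts), 200)
  expect_equal(unname(rowSums(j2$counts)), unname(j2$marginal_anc))
  expect_equal(unname(colSums(j2$counts)), unname(j2$marginal_poly))
  j3 <- joint_sfs(fa2, fp2, matched_only = TRUE)
  expect_equal(sum(j3$counts), 150)
})

test_that("family collapse keeps the longest member of each >85%/85% component", {
  lengths <- c(teA = 5000, teB = 4000, teC = 3000)
  hits <- data.frame(query = c("teA", "teB", "teB"),
                     subject = c("teB", "teA", "teC"),
                     identity = c(90, 90, 90),
                     frac_aligned = c(0.95, 0.95, 0.50))
  expect_equal(collapse_families(hits, lengths), c("teA", "teC"))
  # identity at or below the threshold keeps both
  hits2 <- data.frame(query = "teA", subject = "teB", identity = 80,
                      frac_aligned = 0.95)
  expect_equal(collapse_families(hits2, lengths), c("teA", "teB", "teC"))
})

test_that("ancestry assignment applies the 80/80 rule with explicit ambiguity", {
  th_hit <- data.frame(query = "te1", subject = "x", identity = 85,
                       frac_aligned = 0.9, subject_genome = "TH")
  ar_hit <- data.frame(query = "te1", subject = "y", identity = 88,
                       frac_aligned = 0.85, subject_genome = "AR")
  expect_equal(assign_ancestry(th_hit), "TH")
  expect_equal(assign_ancestry(rbind(th_hit, ar_hit)), "ambiguous")
  weak <- transform(th_hit, identity = 79)
  expect_equal(assign_ancestry(weak), "unassigned")
  # boundary: exactly 80% identity does not pass (strict >)
  expect_equal(assign_ancestry(transform(th_hit, identity = 80)), "unassigned")
})

test_that("the jump null model reproduces the printed expectations", {
  expect_equal(round(expected_jump_ratio(33420, 66722, 119, 143), 1), 1.7)
  expect_equal(expected_jump_ratio(10, 10, 50, 50), 1)
  expect_equal(expected_jump_ratio(10, 20, 100, 100), 2)
  obs <- observed_jump_ratio(1515, 496,
                             expected = expected_jump_ratio(33420, 66722,
                                                            119, 143))
  expect_equal(round(obs$observed), 3)
  expect_equal(round(obs$excess, 2), 1.84)
  expect_equal(observed_jump_ratio(7, 7)$observed, 1)
  expect_warning(und <- observed_jump_ratio(5, 0), "undefined")
  expect_true(is.na(und$observed))
})
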