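# Copy-state calling, segmentation and reciprocal-event detection.

state_track <- function(ratios, depth = 20, chrom = "TH1") {
  # build a track whose median is `depth` by padding with baseline windows
  n <- length(ratios)
  pad <- rep(1, 4 * n)
  all_r <- c(ratios, pad)
  coverage_track(data.frame(chrom = chrom,
                            start = (seq_along(all_r) - 1) * 1000,
                            end = seq_along(all_r) * 1000,
                            depth = all_r * depth))
}

test_that("window copy states follow the ratio thresholds", {
  tr <- state_track(c(1.0, 0.05, 2.0))
  st <- window_copy_states(tr)
  expect_equal(st$state[1:3], c(2L, 0L, 4L))
  # ambiguous ratio inherits the majority of its nearest neighbours
  tr2 <- state_track(c(2, 1.55, 2, 2, 2))
  st2 <- window_copy_states(tr2)
  expect_equal(st2$state[2], 4L)
})

test_that("segmentation finds maximal runs and absorbs short blips", {
  uni <- data.frame(chrom = "c1", start = 0:99 * 1000, end = 1:100 * 1000,
                    ratio = 1, state = 2L)
  seg <- segment_states(uni)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$n_windows, 100)
  # planted 0-run: breakpoints at the run edges
  st <- uni; st$state[41:60] <- 0L
  seg2 <- segment_states(st)
  z <- seg2[seg2$state == 0, ]
  expect_equal(c(z$start, z$end), c(40000, 60000))
  # a 2-window state-4 blip inside state 2 is absorbed at min_run 5
  st3 <- uni; st3$state[10:11] <- 4L
  seg3 <- segment_states(st3, min_run = 5)
  expect_equal(nrow(seg3), 1)
  expect_equal(seg3$state, 2L)
})

test_that("reciprocal 0/4 segments pair into HE candidates with the right direction", {
  p <- tiny_params()
  ref <- tiny_reference(p)
  he <- he_copy_map(ref$annotation, ref$map$ar_gene[1:4])
  cov <- simulate_coverage(ref$annotation, he$copy_map, depth_mean = 30,
                           seed = 11)
  st <- window_copy_states(cov$track)
  segs <- segment_states(st)
  cand <- pair_reciprocal_events(segs, ref$annotation, ref$map)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$replacing_subgenome, "TH")
  expect_equal(cand$lost_subgenome, "AR")
  expect_gte(cand$jaccard, 0.5)
  # a deletion (0-state with homeologous region at 2 copies) is no candidate
  del_map <- he$copy_map[1, , drop = FALSE]   # only the loss, no gain
  cov_d <- simulate_coverage(ref$annotation, del_map, depth_mean = 30,
                             seed = 12)
  cand_d <- pair_reciprocal_events(segment_states(window_copy_states(cov_d$track)),
                                   ref$annotation, ref$map)
  expect_equal(nrow(cand_d), 0)
  # no aberrant segments at all: empty candidate list
  cov_n <- simulate_coverage(ref$annotation, NULL, depth_mean = 30, seed = 13)
  cand_n <- pair_reciprocal_events(segment_states(window_copy_states(cov_n$track)),
                                   ref$annotation, ref$map)
  expect_equal(nrow(cand_n), 0)
})

test_that("contact enrichment is 1 on uniform trans backgrounds and ~spike at planted breakpoints", {
  bins <- data.frame(bin = 1:20, chrom = rep(c("TH1", "AR1"), each = 10),
                     start = rep(0:9 * 25000, 2), end = rep(1:10 * 25000, 2))
  m <- matrix(5, 20, 20)
  cm <- contact_matrix(bins, m)
  expect_equal(contact_enrichment(cm, "TH1", 125000, "AR1", 125000), 1)
  # plant a 10x spike at the breakpoint flank
  m2 <- m
  m2[4:8, 14:18] <- 50; m2[14:18, 4:8] <- 50
  cm2 <- contact_matrix(bins, m2)
  # background is the whole chromosome pair (spiked cells included), so the
  # statistic is the spike diluted by the spiked fraction: 50 / 16.25
  enr <- contact_enrichment(cm2, "TH1", 137500, "AR1", 137500)
  expect_equal(enr, 50 / 16.25)
  # empty chromosome pair: missing evidence
  expect_true(is.na(contact_enrichment(contact_matrix(bins, matrix(0, 20, 20)),
                                       "TH1", 0, "AR1", 0)))
})

test_that("discordant pair support counts only pairs within the window", {
  bp <- list(chrom1 = "AR1", pos1 = 50000, chrom2 = "TH1", pos2 = 80000)
  none <- data.frame(chromA = "AR1", posA = 1, chromB = "AR2", posB = 1)
  expect_equal(discordant_support(none, bp$chrom1, bp$pos1, bp$chrom2, bp$pos2), 0)
  hits <- data.frame(chromA = rep("AR1", 12), posA = 50000 + seq(-600, 500, 100),
                     chromB = "TH1", posB = 80000 + seq(-500, 600, 100))
  expect_equal(discordant_support(hits, bp$chrom1, bp$pos1, bp$chrom2, bp$pos2),
               12)
  far <- data.frame(chromA = "AR1", posA = 55000, chromB = "TH1", posB = 80000)
  expect_equal(discordant_support(far, bp$chrom1, bp$pos1, bp$chrom2, bp$pos2,
                                  window = 2000), 0)
})

test_that("HE calls require orthogonal evidence when it is supplied", {
  p <- tiny_params()
  ref <- tiny_reference(p)
  he <- he_copy_map(ref$annotation, ref$map$ar_gene[1:4])
  cov <- simulate_coverage(ref$annotation, he$copy_map, depth_mean = 30,
                           seed = 21)
  cand <- pair_reciprocal_events(segment_states(window_copy_states(cov$track)),
                                 ref$annotation, ref$map)
  bp <- data.frame(chrom1 = he$truth$lost_chrom, pos1 = he$truth$lost_start,
                   chrom2 = he$truth$dup_chrom, pos2 = he$truth$dup_start)
  cm <- simulate_contacts(ref$annotation, bp, background = 10, spike = 10,
                          binsize = 10000, seed = 22)
  disc <- data.frame(chromA = he$truth$lost_chrom,
                     posA = he$truth$lost_start + c(-300, 100, 700),
                     chromB = he$truth$dup_chrom,
                     posB = he$truth$dup_start + c(200, -400, 900))
  called <- call_he(cand, contacts = cm, discordant = disc)
  expect_equal(nrow(called), 1)
  expect_gte(called$contact_enrichment, 2)
  expect_gte(called$discordant_pairs, 3)
  expect_equal(called$replacing_subgenome, he$truth$replacing_subgenome)
  # with evidence tables that do not support it, the candidate is dropped
  flat <- simulate_contacts(ref$annotation, NULL, background = 10, spike = 1,
                            binsize = 10000, seed = 23)
  not_called <- call_he(cand, contacts = flat,
                        discordant = data.frame(chromA = character(),
                                                posA = numeric(),
                                                chromB = character(),
                                                posB = numeric()))
  expect_equal(nrow(not_called), 0)
})

test_that("genes lost are those without a partner copy in the replacing segment", {
  p <- tiny_params(n_genes_per_subgenome = 80)
  ref <- generate_reference(p)
  # lost segment holds 10 genes; shrink the duplicated interval so only 7
  # partners sit inside it: 3 genes are genuinely lost
  lost_genes <- ref$map$ar_gene[1:10]
  he <- he_copy_map(ref$annotation, lost_genes)
  g <- ref$annotation$genes
  partners <- g[match(ref$map$th_gene[1:10], g$gene_id), ]
  partners <- partners[order(partners$start), ]
  call <- data.frame(lost_chrom = he$truth$lost_chrom,
                     lost_start = he$truth$lost_start,
                     lost_end = he$truth$lost_end,
                     dup_chrom = he$truth$dup_chrom,
                     dup_start = partners$start[1],
                     dup_end = partners$end[7])
  lost <- genes_lost(call, ref$annotation)
  expect_equal(length(lost), 3)
  expect_true(all(lost %in% lost_genes))
})
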