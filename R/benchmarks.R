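# Seeded simulation studies validating each estimator against planted truth.
#
# These are the package's recovery benchmarks: each one builds synthetic
# data under the study conditions the pipeline targets, runs the estimator
# under test, and reports recovery statistics. They back the package's
# validation suite and are reproducible entry points for users who want to
# re-check an estimator under their own conditions.

#' Homeologous-exchange recovery benchmark
#'
#' Simulates genomes with one planted reciprocal 4:0 exchange (>= 20
#' windows) per replicate plus the same number of exchange-free genomes,
#' runs the coverage-based HE caller, and reports recall, direction
#' correctness, breakpoint error (in windows, measured on the lost-segment
#' breakpoints, the side with unambiguous depth signal) and false calls.
#'
#' @param n_case,n_null replicates with and without a planted exchange.
#' @param depth_mean sequencing depth per window at 2 copies.
#' @param seed integer seed.
#' @return list: \code{recall}, \code{direction_ok} (fraction),
#'   \code{max_breakpoint_error_windows}, \code{false_calls},
#'   \code{n_case}, \code{n_null}.
#' @export
benchmark_he_recovery <- function(n_case = 50, n_null = 50, depth_mean = 20,
                                  seed = 1L) {
  p <- synth_params(n_genes_per_subgenome = 120, chrom_len_th = 2e5,
                    chrom_len_ar = 2e5, seed = 1L)
  ref <- generate_reference(p)
  hits <- 0; dir_ok <- 0; bp_err <- numeric(0)
  for (i in seq_len(n_case)) {
    set.seed(seed + i)
    s <- sample(2:9, 1)
    genes <- if (i %% 2) ref$map$ar_gene[s:(s + 5)]
             else ref$map$th_gene[s:(s + 5)]
    he <- he_copy_map(ref$annotation, genes)
    cov <- simulate_coverage(ref$annotation, he$copy_map,
                             depth_mean = depth_mean, seed = seed + i)
    calls <- detect_he(cov$track, ref$annotation, ref$map)
    if (nrow(calls) == 1 && calls$lost_chrom == he$truth$lost_chrom) {
      hits <- hits + 1
      dir_ok <- dir_ok +
        (calls$replacing_subgenome == he$truth$replacing_subgenome)
      bp_err <- c(bp_err, max(abs(calls$lost_start - he$truth$lost_start),
                              abs(calls$lost_end - he$truth$lost_end)) /
                    attr(cov$track, "window"))
    }
  }
  false_calls <- sum(vapply(seq_len(n_null), function(i) {
    cov <- simulate_coverage(ref$annotation, NULL, depth_mean = depth_mean,
                             seed = seed + 100000L + i)
    nrow(detect_he(cov$track, ref$annotation, ref$map))
  }, numeric(1)))
  list(recall = hits / n_case, direction_ok = dir_ok / max(hits, 1),
       max_breakpoint_error_windows = if (length(bp_err)) max(bp_err) else NA,
       false_calls = false_calls, n_case = n_case, n_null = n_null)
}

#' Copy-number recovery benchmark
#'
#' Poisson coverage simulations with a planted multi-copy locus (the
#' collapsed-consensus situation of an rDNA array): for each planted copy
#' number, the mean coverage-ratio estimate over \code{reps} replicates and
#' its relative error.
#'
#' @param copies planted copy numbers.
#' @param reps replicates per copy number.
#' @param depth_mean depth at the single-copy baseline.
#' @param seed integer seed.
#' @return data.frame: \code{copies}, \code{mean_estimate},
#'   \code{rel_error}, \code{reps}.
#' @export
benchmark_copy_number <- function(copies = c(1, 8, 50, 159, 174),
                                  reps = 500, depth_mean = 10, seed = 1L) {
  p <- synth_params(n_genes_per_subgenome = 10, n_chrom_th = 1,
                    n_chrom_ar = 1, chrom_len_th = 5e5, chrom_len_ar = 5e5,
                    seed = 1L)
  ref <- generate_reference(p)
  locus <- list(chrom = "TH1", start = 100000, end = 150000)
  out <- lapply(seq_along(copies), function(ci) {
    cm <- data.frame(chrom = locus$chrom, start = locus$start,
                     end = locus$end, copies = 2 * copies[ci])
    ests <- vapply(seq_len(reps), function(i) {
      cov <- simulate_coverage(ref$annotation, cm, depth_mean = depth_mean,
                               seed = seed + ci * 10000L + i)
      estimate_copy_number(cov$track, locus$chrom, locus$start,
                           locus$end)$copies
    }, numeric(1))
    data.frame(copies = copies[ci], mean_estimate = mean(ests),
               rel_error = mean(ests) / copies[ci] - 1, reps = reps)
  })
  do.call(rbind, out)
}

#' Null homeolog balance and cross-mapping recovery benchmark
#'
#' Runs the full normalization pipeline on an allopolyploid simulation with
#' no planted subgenome effect and reports the population mean homeolog
#' logFC with its standard error (across pairs), plus the cross-mapping
#' leak estimates recovered from replicated pure-ancestor panels against
#' the planted rates.
#'
#' @param leak_reps replicate simulations for the leak estimate.
#' @param seed integer seed.
#' @return list: \code{logfc_mean}, \code{logfc_se}, \code{logfc_z},
#'   \code{n_pairs}, \code{leak} (data.frame: species, planted, estimate,
#'   se, reps).
#' @export
benchmark_normalization_null <- function(leak_reps = 20, seed = 1L) {
  p <- synth_params(seed = seed)
  ref <- generate_reference(p)
  design <- expression_design(c(thaliana = 15, arenosa = 4,
                                suecica_natural = 15,
                                suecica_synthetic = 2), replicates = 3)
  sim <- simulate_expression(ref$annotation, ref$map, design, p)
  norm <- normalize_expression(sim$matrix)
  keep <- expression_filter(norm, ref$map)
  hp <- homeolog_logfc(norm, keep, species = "suecica_natural")
  se <- sd(hp$pair_mean) / sqrt(length(hp$pair_mean))

  ests <- t(vapply(seq_len(leak_reps), function(i) {
    pi <- synth_params(n_genes_per_subgenome = 100, seed = seed + 1000L + i)
    refi <- generate_reference(pi)
    d <- expression_design(c(thaliana = 5, arenosa = 5), replicates = 2)
    cross_mapping_rate(simulate_expression(refi$annotation, refi$map,
                                           d, pi)$matrix)
  }, numeric(2)))
  leak <- data.frame(
    species = c("thaliana", "arenosa"),
    planted = c(p$leak_ar, p$leak_th),
    estimate = colMeans(ests),
    se = apply(ests, 2, sd) / sqrt(leak_reps),
    reps = leak_reps)
  list(logfc_mean = hp$grand_mean, logfc_se = se,
       logfc_z = hp$grand_mean / se, n_pairs = length(hp$pair_mean),
       leak = leak)
}

# One DE calibration replicate: simulate, normalize, Wilcoxon TH genes
# thaliana vs natural allopolyploid. Returns the DE table plus the planted
# truth.
.de_replicate <- function(params, design) {
  ref <- generate_reference(params)
  sim <- simulate_expression(ref$annotation, ref$map, design, params)
  norm <- normalize_expression(sim$matrix)
  acc <- unique(design[, c("accession", "species")])
  de <- differential_expression(
    norm,
    acc$accession[acc$species == "thaliana"],
    acc$accession[acc$species == "suecica_natural"],
    genes = ref$map$th_gene)
  list(de = de, truth = sim$truth)
}

#' Wilcoxon differential-expression calibration benchmark
#'
#' Null calibration: replicated simulations with no planted effect, 15 vs
#' 15 accessions and 2,000 tested genes; the false-discovery proportion at
#' q < 0.05 is recorded per replicate. Sensitivity: simulations with
#' planted |logFC| = 2 shifts; the fraction of planted genes recovered at
#' q < 0.05.
#'
#' @param null_reps,sens_reps replicates for the two arms.
#' @param n_genes genes tested per replicate.
#' @param seed integer seed.
#' @return list: \code{mean_fdp}, \code{fdp_se}, \code{sensitivity},
#'   \code{null_reps}, \code{sens_reps}, \code{n_genes}.
#' @export
benchmark_de_calibration <- function(null_reps = 100, sens_reps = 5,
                                     n_genes = 2000, seed = 1L) {
  design <- expression_design(c(thaliana = 15, arenosa = 2,
                                suecica_natural = 15,
                                suecica_synthetic = 1), replicates = 2)
  fdp <- vapply(seq_len(null_reps), function(i) {
    p <- synth_params(n_genes_per_subgenome = n_genes, gene_spacing = 2000,
                      seed = seed + i)
    r <- .de_replicate(p, design)
    sum(r$de$deg) / max(1, sum(r$de$deg))   # all discoveries are false
  }, numeric(1))
  sens <- vapply(seq_len(sens_reps), function(i) {
    p <- synth_params(n_genes_per_subgenome = n_genes, gene_spacing = 2000,
                      deg_frac = 0.1, deg_logfc = 2,
                      seed = seed + 200000L + i)
    r <- .de_replicate(p, design)
    planted <- r$truth$deg$gene_id[r$truth$deg$subgenome == "TH"]
    planted <- intersect(planted, r$de$gene_id)
    mean(r$de$deg[match(planted, r$de$gene_id)])
  }, numeric(1))
  list(mean_fdp = mean(fdp), fdp_se = sd(fdp) / sqrt(null_reps),
       sensitivity = mean(sens), null_reps = null_reps,
       sens_reps = sens_reps, n_genes = n_genes)
}

#' Exhaustive exactness sweep of the hypergeometric tail
#'
#' Compares \code{\link{hyper_upper_tail}} with the distribution-function
#' oracle \code{stats::phyper} over every table with universe size
#' \code{N <= n_max}, and \code{\link{fisher_one_sided}} with the
#' equivalent tails.
#'
#' @param n_max largest universe size swept.
#' @return list: \code{max_abs_error}, \code{n_tables}.
#' @export
benchmark_enrichment_exactness <- function(n_max = 25) {
  worst <- 0; n_tables <- 0
  for (N in 1:n_max) for (K in 0:N) for (n in 0:N) {
    for (k in max(0, K + n - N):min(K, n)) {
      mine <- hyper_upper_tail(k, K, n, N)
      oracle <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      worst <- max(worst, abs(mine - oracle))
      a <- k; b <- K - k; cc <- n - k; d <- N - K - n + k
      worst <- max(worst, abs(fisher_one_sided(a, b, cc, d) - mine))
      n_tables <- n_tables + 1
    }
  }
  list(max_abs_error = worst, n_tables = n_tables)
}

#' Founder-bottleneck site-frequency shift benchmark
#'
#' Paired TE population simulations: a founder bottleneck
#' (\code{founder_k} genome copies) versus a no-bottleneck control
#' (founder sample as large as the panel). Per replicate, the mass of the
#' shared-site joint SFS in the polyploid's top (fixed) frequency class is
#' compared between the two; a positive shift means the bottleneck pushed
#' shared insertions toward fixation in the allopolyploid.
#'
#' @param reps replicate pairs.
#' @param founder_k bottleneck size.
#' @param seed integer seed.
#' @return list: \code{mean_shift}, \code{shift_se},
#'   \code{frac_positive}, \code{p_one_sided} (t-test of shift > 0),
#'   \code{reps}.
#' @export
benchmark_bottleneck_sfs <- function(reps = 200, founder_k = 2, seed = 1L) {
  fixed_mass <- function(p) {
    te <- simulate_te_populations(generate_reference(p)$annotation, p)
    shared <- te$truth$site_class$class == "shared" &
      te$truth$site_class$subgenome == "TH"
    key <- paste(te$truth$site_class$chrom, te$truth$site_class$pos,
                 te$truth$site_class$family)[shared]
    poly_key <- paste(te$polyploid$sites$chrom, te$polyploid$sites$pos,
                      te$polyploid$sites$family)
    anc_key <- paste(te$ancestor_th$sites$chrom, te$ancestor_th$sites$pos,
                     te$ancestor_th$sites$family)
    freq <- function(m, rows) {
      pres <- rowSums(m$calls[rows, , drop = FALSE] == 1, na.rm = TRUE)
      nm <- rowSums(!is.na(m$calls[rows, , drop = FALSE]))
      ifelse(nm > 0, pres / nm, NA)
    }
    fp <- freq(te$polyploid, match(key, poly_key))
    fa <- freq(te$ancestor_th, match(key, anc_key))
    j <- joint_sfs(fa, fp)
    sum(j$counts[, ncol(j$counts)]) / max(1, sum(j$counts))
  }
  shifts <- vapply(seq_len(reps), function(i) {
    pb <- synth_params(n_genes_per_subgenome = 10, founder_k = founder_k,
                       n_sites_shared = 150, n_sites_private_poly = 30,
                       n_sites_private_anc = 30, seed = seed + i)
    # control: founder sample as large as the whole panel of genome copies
    pc <- synth_params(n_genes_per_subgenome = 10,
                       founder_k = 2 * pb$n_accessions, n_sites_shared = 150,
                       n_sites_private_poly = 30, n_sites_private_anc = 30,
                       seed = seed + i)
    fixed_mass(pb) - fixed_mass(pc)
  }, numeric(1))
  tt <- stats::t.test(shifts, alternative = "greater")
  list(mean_shift = mean(shifts), shift_se = sd(shifts) / sqrt(reps),
       frac_positive = mean(shifts > 0), p_one_sided = tt$p.value,
       reps = reps)
}
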