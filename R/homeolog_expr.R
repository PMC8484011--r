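# Subgenome-aware expression pipeline.
#
# The unusual step is the effective library size: in an allopolyploid both
# subgenomes contribute to a library, so scaling each sample by its total
# count would halve every homeolog's apparent expression relative to the
# pure ancestors. Instead, TPM totals are computed per subgenome, TMM
# scaling factors are computed separately per subgenome, and an
# allopolyploid sample's effective size is the mean of its two (TMM-scaled)
# subgenome totals, while an ancestor sample's size uses only its own
# subgenome. CPM with a prior count of 1 and log2 transformation follow.

#' Filter genes whose signal is driven by the wrong species
#'
#' A residual-cross-mapping control computed on the pure ancestor panels:
#' for each TH-subgenome gene the log2 ratio of its mean count in the
#' thaliana panel over its mean count in the arenosa panel (with a
#' pseudo-count) is computed; a ratio below 0 means the gene's reads come
#' predominantly from the wrong species, and the gene is removed. The
#' mirrored rule applies to AR-subgenome genes. Ratios of exactly 0 are
#' kept (strict inequality).
#'
#' @param em an \code{\link{expression_matrix}} containing pure
#'   \code{thaliana} and \code{arenosa} samples.
#' @param pseudo pseudo-count added to both means.
#' @return Character vector of gene ids kept.
#' @export
filter_cross_mappers <- function(em, pseudo = 0.5) {
  sp <- em$samples$species
  .assert(any(sp == "thaliana") && any(sp == "arenosa"),
          "cannot filter: need pure thaliana and arenosa samples")
  th_mean <- rowMeans(em$counts[, sp == "thaliana", drop = FALSE])
  ar_mean <- rowMeans(em$counts[, sp == "arenosa", drop = FALSE])
  ratio <- log2((th_mean + pseudo) / (ar_mean + pseudo))
  keep <- ifelse(em$genes$subgenome == "TH", ratio >= 0, -ratio >= 0)
  em$genes$gene_id[keep]
}

#' Transcripts per million
#'
#' @param counts gene-by-sample count matrix.
#' @param lengths gene lengths in bp (> 0), one per row.
#' @return Matrix of TPM values; each column sums to 1e6. All-zero samples
#'   are flagged with a warning and return NaN.
#' @export
compute_tpm <- function(counts, lengths) {
  .assert(all(lengths > 0), "gene lengths must be positive")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) warning("all-zero sample: TPM undefined")
  sweep(rate, 2, tot / 1e6, "/")
}

#' Trimmed mean of M-values scaling factors
#'
#' Standard TMM: against a reference sample (the one whose upper-quartile
#' count fraction is closest to the panel mean), genes zero in either sample
#' are dropped, the top and bottom \code{logratio_trim} of M-values
#' (log-ratios) and \code{sum_trim} of A-values (log-abundances) are
#' trimmed, and the factor is 2 to the inverse-asymptotic-variance weighted
#' mean of the remaining M-values. Factors are normalized to geometric
#' mean 1. Intended to be run separately per subgenome in allopolyploid
#' designs.
#'
#' @param counts gene-by-sample count matrix.
#' @param lib_size library sizes (defaults to column sums).
#' @param reference reference column (index or name); chosen automatically
#'   when NULL.
#' @param logratio_trim,sum_trim trim fractions for M and A values.
#' @return Named numeric vector of scaling factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_size = colSums(counts), reference = NULL,
                        logratio_trim = 0.30, sum_trim = 0.05) {
  .assert(ncol(counts) >= 2, "TMM needs at least two samples")
  uq <- apply(counts, 2, quantile, probs = 0.75) / lib_size
  if (is.null(reference)) reference <- which.min(abs(uq - mean(uq)))
  if (is.character(reference)) reference <- match(reference, colnames(counts))
  ref <- counts[, reference]
  nr <- lib_size[reference]

  one_factor <- function(obs, no) {
    keep <- obs > 0 & ref > 0
    if (!any(keep)) {
      warning("no genes survive trimming; factor set to 1")
      return(1)
    }
    o <- obs[keep]; r <- ref[keep]
    m <- log2((o / no) / (r / nr))
    a <- 0.5 * log2((o / no) * (r / nr))
    v <- (no - o) / (no * o) + (nr - r) / (nr * r)
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * sum_trim) + 1;      hi_a <- n + 1 - lo_a
    rm_ <- rank(m); ra <- rank(a)
    sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(sel)) {
      warning("no genes survive trimming; factor set to 1")
      return(1)
    }
    f <- sum(m[sel] / v[sel]) / sum(1 / v[sel])
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(counts)),
              function(j) one_factor(counts[, j], lib_size[j]), numeric(1))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Subgenome-balanced effective library sizes
#'
#' For a pure ancestor sample the effective size is its TPM total over its
#' own subgenome's genes, multiplied by that subgenome's TMM factor; rows
#' of the other subgenome (residual cross-mapping) are ignored. For an
#' allopolyploid sample, both subgenomes are genuinely expressed, and the
#' effective size is the mean of the two TMM-scaled subgenome totals.
#'
#' @param tpm TPM matrix (genes x samples), e.g. from
#'   \code{\link{compute_tpm}}.
#' @param gene_subgenome subgenome per row ("TH"/"AR").
#' @param samples sample metadata (needs \code{sample}, \code{species}).
#' @param tmm_th,tmm_ar per-sample TMM factors computed on the TH and AR
#'   subgenome counts (default 1).
#' @return Named numeric vector of effective library sizes.
#' @export
effective_library_sizes <- function(tpm, gene_subgenome, samples,
                                    tmm_th = NULL, tmm_ar = NULL) {
  ns <- ncol(tpm)
  if (is.null(tmm_th)) tmm_th <- rep(1, ns)
  if (is.null(tmm_ar)) tmm_ar <- rep(1, ns)
  tot_th <- colSums(tpm[gene_subgenome == "TH", , drop = FALSE]) * tmm_th
  tot_ar <- colSums(tpm[gene_subgenome == "AR", , drop = FALSE]) * tmm_ar
  if (any(tot_th == 0) || any(tot_ar == 0))
    warning("a subgenome has zero TPM total in some sample")
  sizes <- ifelse(samples$species == "thaliana", tot_th,
           ifelse(samples$species == "arenosa", tot_ar,
                  (tot_th + tot_ar) / 2))
  setNames(sizes, samples$sample)
}

#' Log2 counts per million with a prior count
#'
#' @param counts gene-by-sample matrix.
#' @param sizes effective library size per sample (> 0).
#' @param prior prior count added before the log (default 1).
#' @return Matrix of \code{log2((count + prior) / size * 1e6)}.
#' @export
log_cpm <- function(counts, sizes, prior = 1) {
  .assert(all(sizes > 0), "effective library sizes must be positive")
  log2(sweep(counts + prior, 2, sizes, "/") * 1e6)
}

#' Run the full normalization pipeline on an expression matrix
#'
#' Convenience wrapper: TPM (removing depth and gene-length effects),
#' per-subgenome TMM on the TPM table, subgenome-balanced effective library
#' sizes, then log2 CPM of the TPM values against those sizes. Because
#' every step after TPM operates on depth-free quantities, the result is
#' invariant to a global rescaling of any sample's counts.
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param prior prior count for \code{\link{log_cpm}}.
#' @return list of class \code{normalized_expression}: \code{logcpm}
#'   matrix, \code{tpm}, \code{sizes}, \code{tmm} (per subgenome),
#'   \code{prior}, \code{genes}, \code{samples}.
#' @export
normalize_expression <- function(em, prior = 1) {
  tpm <- compute_tpm(em$counts, em$genes$length)
  sg <- em$genes$subgenome
  tpm_th <- tpm[sg == "TH", , drop = FALSE]
  tpm_ar <- tpm[sg == "AR", , drop = FALSE]
  tmm_th <- tmm_factors(tpm_th, lib_size = colSums(tpm_th))
  tmm_ar <- tmm_factors(tpm_ar, lib_size = colSums(tpm_ar))
  sizes <- effective_library_sizes(tpm, sg, em$samples, tmm_th, tmm_ar)
  structure(list(logcpm = log_cpm(tpm, sizes, prior), tpm = tpm,
                 sizes = sizes,
                 tmm = list(TH = tmm_th, AR = tmm_ar), prior = prior,
                 genes = em$genes, samples = em$samples),
            class = "normalized_expression")
}

# Accession-level means of log CPM (replicates averaged), restricted to one
# tissue when the design has several.
.accession_means <- function(norm, tissue = NULL) {
  s <- norm$samples
  keep <- if (is.null(tissue)) rep(TRUE, nrow(s)) else s$tissue == tissue
  acc <- unique(s$accession[keep])
  out <- vapply(acc, function(a) {
    rowMeans(norm$logcpm[, keep & s$accession == a, drop = FALSE])
  }, numeric(nrow(norm$logcpm)))
  if (is.null(dim(out)))   # single-gene matrices collapse to a vector
    out <- matrix(out, nrow = 1,
                  dimnames = list(rownames(norm$logcpm), acc))
  meta <- unique(s[keep, c("accession", "species")])
  list(means = out, meta = meta[match(colnames(out), meta$accession), ])
}

#' Retain homeolog pairs expressed across the species panels
#'
#' A gene is "expressed" in an accession when its accession-mean CPM
#' exceeds \code{min_cpm} (i.e. accession-mean log2 CPM > log2(min_cpm)).
#' A pair is retained when each member is expressed in at least
#' \code{min_natural} natural allopolyploid accessions, at least
#' \code{min_synthetic} synthetic allopolyploid accessions, and in at least
#' \code{min_th} (TH member) / \code{min_ar} (AR member) accessions of its
#' own ancestral panel. A species panel absent from the design drops its
#' thresholds with a warning.
#'
#' @param norm a \code{normalized_expression}.
#' @param map homeolog pair table.
#' @param min_cpm expression cutoff in CPM units.
#' @param min_th,min_ar,min_natural,min_synthetic minimum expressing
#'   accessions per panel.
#' @return The retained subset of \code{map}.
#' @export
expression_filter <- function(norm, map, min_cpm = 1, min_th = 3,
                              min_ar = 1, min_natural = 3,
                              min_synthetic = 1) {
  am <- .accession_means(norm)
  expressed <- am$means > log2(min_cpm)
  species <- am$meta$species
  n_expr <- function(gene, sp) {
    cols <- species == sp
    sum(expressed[gene, cols])
  }
  need <- c(thaliana = min_th, arenosa = min_ar,
            suecica_natural = min_natural, suecica_synthetic = min_synthetic)
  for (sp in names(need)) {
    if (!any(species == sp)) {
      warning("panel absent from design, threshold skipped: ", sp)
      need[sp] <- 0
    }
  }
  pass_member <- function(gene, own_panel, own_need) {
    n_expr(gene, own_panel) >= own_need &
      n_expr(gene, "suecica_natural") >= need["suecica_natural"] &
      n_expr(gene, "suecica_synthetic") >= need["suecica_synthetic"]
  }
  ok <- vapply(seq_len(nrow(map)), function(i) {
    pass_member(map$th_gene[i], "thaliana", need["thaliana"]) &&
      pass_member(map$ar_gene[i], "arenosa", need["arenosa"])
  }, logical(1))
  map[ok, , drop = FALSE]
}

#' Homeolog log fold changes per accession
#'
#' For each retained pair and each allopolyploid accession, the
#' replicate-mean log2 CPM difference AR homeolog minus TH homeolog
#' (equivalently log2 of the CPM ratio). Swapping the subgenome labels
#' negates every value.
#'
#' @param norm a \code{normalized_expression}.
#' @param map homeolog pairs (typically after
#'   \code{\link{expression_filter}}).
#' @param species species whose accessions are summarized.
#' @return list of class \code{homeolog_pair_stats}: \code{logfc} (pair x
#'   accession matrix), \code{pair_mean} (mean per pair across accessions),
#'   \code{accession_mean} (mean per accession across pairs),
#'   \code{grand_mean}.
#' @export
homeolog_logfc <- function(norm, map,
                           species = c("suecica_natural",
                                       "suecica_synthetic")) {
  am <- .accession_means(norm)
  cols <- am$meta$species %in% species
  .assert(any(cols), "no accessions of the requested species")
  m <- am$means[, cols, drop = FALSE]
  present <- map$th_gene %in% rownames(m) & map$ar_gene %in% rownames(m)
  if (!all(present)) map <- map[present, , drop = FALSE]
  lfc <- m[map$ar_gene, , drop = FALSE] - m[map$th_gene, , drop = FALSE]
  rownames(lfc) <- map$pair_id
  structure(list(logfc = lfc,
                 pair_mean = rowMeans(lfc),
                 accession_mean = colMeans(lfc),
                 grand_mean = mean(lfc)),
            class = "homeolog_pair_stats")
}

#' Flag tissue-specific homeolog pair members
#'
#' A member is flagged when the absolute difference of its accession-mean
#' log2 CPM between the two tissues is \code{>= min_lfc} (inclusive). A
#' pair is analysed (returned flagged) when at least one member is flagged.
#'
#' @param norm a \code{normalized_expression} whose design has both tissues
#'   for the same accessions.
#' @param map homeolog pairs.
#' @param tissues length-2 character vector of tissue names.
#' @param min_lfc flag threshold (log2, default 2).
#' @param species species panels considered.
#' @return data.frame per pair: member log fold changes and flags, plus
#'   \code{pair_flagged}.
#' @export
tissue_specific_pairs <- function(norm, map, tissues, min_lfc = 2,
                                  species = "suecica_natural") {
  .assert(length(tissues) == 2, "exactly two tissues required")
  .assert(all(tissues %in% norm$samples$tissue),
          "unmatched tissue design: tissue absent from samples")
  a1 <- .accession_means(norm, tissues[1])
  a2 <- .accession_means(norm, tissues[2])
  shared <- intersect(colnames(a1$means), colnames(a2$means))
  shared <- shared[a1$meta$species[match(shared, colnames(a1$means))]
                   %in% species]
  .assert(length(shared) > 0, "unmatched tissue design: no shared accessions")
  d <- rowMeans(a1$means[, shared, drop = FALSE]) -
    rowMeans(a2$means[, shared, drop = FALSE])
  th_lfc <- d[map$th_gene]; ar_lfc <- d[map$ar_gene]
  data.frame(pair_id = map$pair_id,
             th_lfc = th_lfc, ar_lfc = ar_lfc,
             th_flagged = abs(th_lfc) >= min_lfc,
             ar_flagged = abs(ar_lfc) >= min_lfc,
             pair_flagged = abs(th_lfc) >= min_lfc | abs(ar_lfc) >= min_lfc,
             row.names = NULL)
}

# Vectorized two-sided Wilcoxon rank-sum test across the rows of a matrix.
# Exact null enumeration when both groups are small and the row has no
# ties; otherwise normal approximation with tie correction and continuity
# correction. Rows constant across both groups get p = 1.
.wilcox_rows <- function(x, ga, gb, exact_max = 8) {
  na <- length(ga); nb <- length(gb)
  xa <- x[, ga, drop = FALSE]; xb <- x[, gb, drop = FALSE]
  xx <- cbind(xa, xb)
  n <- na + nb
  rk <- t(apply(xx, 1, rank))
  w <- rowSums(rk[, seq_len(na), drop = FALSE]) - na * (na + 1) / 2
  has_ties <- apply(xx, 1, function(v) anyDuplicated(v) > 0)
  p <- numeric(nrow(x))
  use_exact <- (na <= exact_max && nb <= exact_max) & !has_ties
  if (any(use_exact)) {
    we <- w[use_exact]
    p_lo <- pwilcox(we, na, nb)
    p_hi <- pwilcox(we - 1, na, nb, lower.tail = FALSE)
    p[use_exact] <- pmin(1, 2 * pmin(p_lo, p_hi))
  }
  if (any(!use_exact)) {
    idx <- which(!use_exact)
    mu <- na * nb / 2
    tie_term <- vapply(idx, function(i) {
      tt <- table(xx[i, ])
      sum(tt^3 - tt)
    }, numeric(1))
    sigma2 <- (na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1)))
    z <- w[idx] - mu
    cc <- sign(z) * 0.5
    pv <- ifelse(sigma2 > 0, 2 * pnorm(-abs((z - cc) / sqrt(sigma2))), 1)
    p[idx] <- pmin(1, pv)
  }
  list(statistic = w, p = p)
}

#' Wilcoxon differential expression between two accession groups
#'
#' The analysis unit is the accession (replicate-mean log2 CPM); a
#' two-sided Wilcoxon rank-sum test is run per gene, with exact null
#' enumeration when both groups have at most \code{exact_max} accessions
#' and the gene has no tied values, otherwise a normal approximation with
#' tie and continuity corrections. P-values are Benjamini-Hochberg adjusted
#' across all tested genes; a gene is a DEG when \code{q < fdr}.
#'
#' @param norm a \code{normalized_expression}.
#' @param group_a,group_b character vectors of accession ids.
#' @param genes genes to test (default all rows).
#' @param fdr FDR threshold for the \code{deg} flag.
#' @param exact_max largest group size for which the exact null is used.
#' @return data.frame with \code{gene_id}, \code{subgenome},
#'   \code{statistic} (rank-sum statistic), \code{p}, \code{q},
#'   \code{direction} (sign of group A minus group B median), \code{deg}.
#' @export
differential_expression <- function(norm, group_a, group_b,
                                    genes = NULL, fdr = 0.05,
                                    exact_max = 8) {
  am <- .accession_means(norm)
  .assert(all(c(group_a, group_b) %in% colnames(am$means)),
          "unknown accession in group")
  .assert(length(group_a) >= 2 && length(group_b) >= 2,
          "each group needs at least two accessions")
  x <- am$means
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  wt <- .wilcox_rows(x, match(group_a, colnames(x)),
                     match(group_b, colnames(x)), exact_max)
  q <- p.adjust(wt$p, method = "BH")
  med_a <- apply(x[, group_a, drop = FALSE], 1, median)
  med_b <- apply(x[, group_b, drop = FALSE], 1, median)
  sg <- norm$genes$subgenome[match(rownames(x), norm$genes$gene_id)]
  data.frame(gene_id = rownames(x), subgenome = sg,
             statistic = wt$statistic, p = wt$p, q = q,
             direction = sign(med_a - med_b), deg = q < fdr,
             row.names = NULL)
}

#' PCA of samples, computed separately per subgenome
#'
#' Genes are centered but not scaled; components are ordered by explained
#' variance and the sign of each component is fixed so that its largest
#' absolute loading is positive.
#'
#' @param norm a \code{normalized_expression}.
#' @param n_components components to return (truncated to what the sample
#'   count supports).
#' @param accession_level use accession means (default) rather than
#'   individual replicates.
#' @return Named list (TH, AR), each with \code{scores},
#'   \code{explained_variance} and \code{loadings}.
#' @export
pca_by_subgenome <- function(norm, n_components = 5,
                             accession_level = TRUE) {
  x_all <- if (accession_level) .accession_means(norm)$means else norm$logcpm
  .assert(ncol(x_all) >= 3, "PCA needs at least three samples")
  lapply(setNames(.SUBGENOMES, .SUBGENOMES), function(sg) {
    rows <- norm$genes$gene_id[norm$genes$subgenome == sg]
    x <- t(x_all[intersect(rownames(x_all), rows), , drop = FALSE])
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(pc$x))
    flip <- vapply(seq_len(k), function(j) {
      l <- pc$rotation[, j]
      sign(l[which.max(abs(l))])
    }, numeric(1))
    scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
    loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, "*")
    list(scores = scores,
         explained_variance = pc$sdev[seq_len(k)]^2,
         loadings = loadings)
  })
}

#' Cluster differentially expressed genes by expression pattern
#'
#' Hierarchical clustering (average linkage) of genes on a 1 - Pearson
#' correlation distance, with the tree cut at \code{k} clusters. Genes with
#' zero variance (correlation undefined) are held out and assigned to the
#' nearest cluster centroid (Euclidean) afterwards. The partition is
#' invariant to the order of input rows.
#'
#' @param x genes-by-samples matrix of (normalized) expression.
#' @param k number of clusters.
#' @return Named integer vector of cluster labels (1..k), in input row
#'   order; cluster ids are renumbered by order of first appearance so the
#'   labelling is permutation-stable.
#' @export
cluster_degs <- function(x, k = 3) {
  .assert(nrow(x) >= k, "need at least k genes")
  v <- apply(x, 1, stats::var)
  ok <- v > 0
  .assert(sum(ok) >= k, "need at least k genes with non-zero variance")
  xo <- x[ok, , drop = FALSE]
  ord <- order(rownames(xo))              # permutation-stable input order
  xo <- xo[ord, , drop = FALSE]
  d <- as.dist(1 - cor(t(xo)))
  lab <- cutree(hclust(d, method = "average"), k = k)
  lab <- as.integer(factor(lab, levels = unique(lab[order(names(lab))])))
  names(lab) <- rownames(xo)
  out <- setNames(integer(nrow(x)), rownames(x))
  out[names(lab)] <- lab
  if (any(!ok)) {
    cent <- vapply(seq_len(k), function(cl) {
      colMeans(xo[lab == cl, , drop = FALSE])
    }, numeric(ncol(x)))
    for (g in rownames(x)[!ok]) {
      dists <- colSums((cent - x[g, ])^2)
      out[g] <- which.min(dists)
    }
  }
  out
}

#' Estimate the cross-mapping leak rate from pure-ancestor samples
#'
#' Given samples whose true subgenome of origin is known (pure ancestors),
#' the leak estimate for a species is the fraction of its total signal
#' attributed to the wrong subgenome's gene rows.
#'
#' @param em an \code{\link{expression_matrix}}.
#' @return Named numeric vector: \code{thaliana} (fraction of thaliana
#'   signal on AR rows, the planted \code{leak_ar}) and \code{arenosa}
#'   (fraction of arenosa signal on TH rows, the planted \code{leak_th}).
#' @export
cross_mapping_rate <- function(em) {
  sp <- em$samples$species
  .assert(any(sp %in% c("thaliana", "arenosa")),
          "inapplicable: no pure-ancestor samples")
  sg <- em$genes$subgenome
  rate <- function(species, wrong_sg) {
    cols <- sp == species
    if (!any(cols)) return(NA_real_)
    cnt <- em$counts[, cols, drop = FALSE]
    sum(cnt[sg == wrong_sg, ]) / sum(cnt)
  }
  c(thaliana = rate("thaliana", "AR"), arenosa = rate("arenosa", "TH"))
}
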