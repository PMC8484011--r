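# Population transposable-element dynamics.
#
# Accessions are selfing and effectively homozygous, so presence calls are
# haploid-like profiles and a site's population frequency is simply its
# accession frequency (missing calls excluded from the denominator).

#' Merge nearby same-family insertion calls
#'
#' Single-linkage merge: calls on the same chromosome and TE family whose
#' positions lie within \code{dist} bp of the next call in the chain are
#' collapsed to one site at the midpoint of the merged cluster. Calls of
#' different families never merge. Merging is idempotent.
#'
#' @param calls data.frame with \code{chrom}, \code{pos}, \code{family} and
#'   any further columns (first value of the cluster is kept for them).
#' @param dist merge distance in bp (default 400; gaps of exactly
#'   \code{dist} merge, \code{dist + 1} do not).
#' @return Merged data.frame with an added \code{n_merged} column.
#' @export
merge_insertions <- function(calls, dist = 400) {
  if (nrow(calls) == 0) return(cbind(calls, n_merged = integer(0)))
  o <- order(calls$chrom, calls$family, calls$pos)
  d <- calls[o, , drop = FALSE]
  new_cluster <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                     d$family[-1] != d$family[-nrow(d)] |
                     diff(d$pos) > dist)
  cl <- cumsum(new_cluster)
  pos <- round((tapply(d$pos, cl, min) + tapply(d$pos, cl, max)) / 2)
  first <- !duplicated(cl)
  out <- d[first, , drop = FALSE]
  out$pos <- as.integer(pos)
  out$n_merged <- as.integer(table(cl))
  rownames(out) <- NULL
  out
}

# Match sites of x against sites of y by family and position within dist.
# Returns index into y (NA when unmatched); nearest match wins.
.match_sites <- function(x, y, dist = 400) {
  idx <- rep(NA_integer_, nrow(x))
  ykey <- paste(y$chrom, y$family)
  xkey <- paste(x$chrom, x$family)
  for (k in unique(xkey)) {
    xi <- which(xkey == k)
    yi <- which(ykey == k)
    if (!length(yi)) next
    for (i in xi) {
      dd <- abs(y$pos[yi] - x$pos[i])
      j <- which.min(dd)
      if (dd[j] <= dist) idx[i] <- yi[j]
    }
  }
  idx
}

#' Classify insertion sites as shared or panel-private
#'
#' Sites of the allopolyploid and ancestor panels are matched by family and
#' position (within \code{dist} bp); a site with at least one present call
#' in both panels is \code{shared}, otherwise it is private to whichever
#' panel shows it (\code{unique_polyploid} / \code{unique_ancestor}).
#'
#' @param poly,anc \code{\link{te_matrix}} panels on the same subgenome
#'   coordinate system.
#' @param dist matching tolerance in bp (the merge distance is reused).
#' @return data.frame of the union of sites: \code{chrom}, \code{pos},
#'   \code{family}, \code{subgenome}, \code{class}, plus row indices
#'   \code{poly_row}, \code{anc_row} into the two matrices (NA when
#'   absent).
#' @export
classify_sharing <- function(poly, anc, dist = 400) {
  sgp <- unique(poly$sites$subgenome)
  sga <- unique(anc$sites$subgenome)
  if (!all(is.na(sgp)) && !all(is.na(sga)) && !any(sga %in% sgp))
    stop("panels are on different subgenome coordinates", call. = FALSE)
  has_present <- function(m) rowSums(m$calls == 1, na.rm = TRUE) > 0
  pp <- has_present(poly); pa <- has_present(anc)
  m <- .match_sites(poly$sites, anc$sites, dist)
  poly_part <- data.frame(poly$sites[, c("chrom", "pos", "family",
                                         "subgenome")],
                          poly_row = seq_len(nrow(poly$sites)),
                          anc_row = m, stringsAsFactors = FALSE)
  unmatched_anc <- setdiff(seq_len(nrow(anc$sites)), m[!is.na(m)])
  anc_part <- data.frame(anc$sites[unmatched_anc,
                                   c("chrom", "pos", "family", "subgenome")],
                         poly_row = NA_integer_, anc_row = unmatched_anc,
                         stringsAsFactors = FALSE)
  out <- rbind(poly_part, anc_part)
  in_poly <- !is.na(out$poly_row) & pp[pmax(out$poly_row, 1)]
  in_anc <- !is.na(out$anc_row) & pa[pmax(out$anc_row, 1)]
  out$class <- ifelse(in_poly & in_anc, "shared",
               ifelse(in_poly, "unique_polyploid",
               ifelse(in_anc, "unique_ancestor", "absent_everywhere")))
  out <- out[out$class != "absent_everywhere", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median TE load per genome, split by sharing class
#'
#' @param mat a \code{\link{te_matrix}}.
#' @param classes optional per-site class vector (same order as
#'   \code{mat$sites}); when NULL a single class \code{all} is used.
#' @return data.frame: \code{class}, \code{median_load}, plus an attribute
#'   \code{"per_accession"} with the full per-accession count table.
#'   Missing cells never count as present.
#' @export
genome_load <- function(mat, classes = NULL) {
  if (is.null(classes)) classes <- rep("all", nrow(mat$sites))
  .assert(length(classes) == nrow(mat$sites),
          "one class per site required")
  per_acc <- rowsum(1 * (mat$calls == 1), classes, na.rm = TRUE)
  out <- data.frame(class = rownames(per_acc),
                    median_load = apply(per_acc, 1, median),
                    row.names = NULL)
  attr(out, "per_accession") <- per_acc
  out
}

#' Pool k haploid-like accessions into a pseudo-tetraploid profile
#'
#' Four randomly chosen subgenome profiles combined into one "4n" pseudo
#' accession make ancestor panels comparable with an allotetraploid's
#' per-genome TE load. The pooled call is present when any pooled
#' accession is present, absent when all non-missing calls are absent, and
#' missing only when every pooled call is missing.
#'
#' @param mat a \code{\link{te_matrix}} (e.g. restricted to one subgenome).
#' @param k accessions to pool (default 4).
#' @param seed integer seed for the accession draw.
#' @return list: \code{calls} (pooled site vector), \code{accessions}
#'   (those pooled), \code{load} (pooled present count).
#' @export
pool_4n <- function(mat, k = 4, seed = 1L) {
  .assert(ncol(mat$calls) >= k,
          paste("panel smaller than k =", k))
  set.seed(as.integer(seed))
  pick <- sample(ncol(mat$calls), k)
  sub <- mat$calls[, pick, drop = FALSE]
  pooled <- ifelse(rowSums(sub == 1, na.rm = TRUE) > 0, 1L,
            ifelse(rowSums(!is.na(sub)) > 0, 0L, NA_integer_))
  list(calls = pooled, accessions = colnames(mat$calls)[pick],
       load = sum(pooled == 1, na.rm = TRUE))
}

#' Site-frequency spectrum of insertion (or variant) presence
#'
#' Per site, the derived/present count over the non-missing denominator;
#' sites with more than \code{max_missing} missing calls are excluded, and
#' counts at denominators other than the panel's modal denominator are
#' rescaled to it (rounded). Classes run 1..n with the fixed class
#' included; sites observed in zero accessions are not segregating and are
#' excluded.
#'
#' @param calls matrix of 1/0/NA, sites x accessions (for polarized SNPs,
#'   recode so 1 is the derived allele before calling).
#' @param max_missing maximum tolerated missing fraction per site
#'   (default 0.2).
#' @return list of class \code{sfs}: \code{n} (modal denominator),
#'   \code{counts} (named vector over classes 1..n), \code{n_sites},
#'   \code{freqs} (per included site).
#' @export
compute_sfs <- function(calls, max_missing = 0.2) {
  .assert(ncol(calls) >= 2, "SFS needs at least two accessions")
  nonmiss <- rowSums(!is.na(calls))
  pres <- rowSums(calls == 1, na.rm = TRUE)
  ok <- nonmiss > 0 & (1 - nonmiss / ncol(calls)) <= max_missing & pres > 0
  if (!any(ok)) {
    warning("no polarizable segregating sites; empty SFS")
    return(structure(list(n = ncol(calls),
                          counts = setNames(rep(0, ncol(calls)),
                                            seq_len(ncol(calls))),
                          n_sites = 0, freqs = numeric(0)), class = "sfs"))
  }
  n_modal <- as.integer(names(which.max(table(nonmiss[ok]))))
  cls <- pmin(n_modal, pmax(1, round(pres[ok] / nonmiss[ok] * n_modal)))
  counts <- tabulate(cls, nbins = n_modal)
  structure(list(n = n_modal,
                 counts = setNames(counts, seq_len(n_modal)),
                 n_sites = sum(ok),
                 freqs = pres[ok] / nonmiss[ok]),
            class = "sfs")
}

#' Joint (2D) site-frequency spectrum across two panels
#'
#' Sites are matched across the two panels (see
#' \code{\link{classify_sharing}}); in \code{matched_only = FALSE} mode a
#' site absent from one panel enters with frequency 0 there, in
#' \code{matched_only = TRUE} mode only sites present in both are binned.
#' Marginals of the returned histogram equal the 1D spectra computed on
#' the same site set.
#'
#' @param freq_anc,freq_poly per-site frequency vectors over the SAME site
#'   set (use NA for a site unobserved in a panel).
#' @param breaks bin edges over [0, 1] (default deciles).
#' @param matched_only drop sites with NA in either panel instead of
#'   padding with 0.
#' @return list: \code{counts} (matrix, ancestor bins x polyploid bins),
#'   \code{breaks}, \code{marginal_anc}, \code{marginal_poly}.
#' @export
joint_sfs <- function(freq_anc, freq_poly, breaks = seq(0, 1, by = 0.1),
                      matched_only = FALSE) {
  .assert(length(freq_anc) == length(freq_poly),
          "frequency vectors must align site-wise")
  if (matched_only) {
    keep <- !is.na(freq_anc) & !is.na(freq_poly)
    freq_anc <- freq_anc[keep]; freq_poly <- freq_poly[keep]
  } else {
    freq_anc[is.na(freq_anc)] <- 0
    freq_poly[is.na(freq_poly)] <- 0
  }
  bin <- function(f) cut(f, breaks = breaks, include.lowest = TRUE,
                         right = TRUE)
  ba <- bin(freq_anc); bp <- bin(freq_poly)
  counts <- table(ancestor = ba, polyploid = bp)
  list(counts = unclass(counts), breaks = breaks,
       marginal_anc = rowSums(counts), marginal_poly = colSums(counts))
}

#' Collapse highly similar TE consensus families
#'
#' Families are nodes of a graph with an edge when a pairwise hit exceeds
#' \code{id_min}\% identity over more than \code{frac_min} of the sequence
#' length; each connected component is represented by its longest
#' sequence (the 85\%/85\% redundancy rule).
#'
#' @param hits pairwise hit table (see \code{\link{read_hits}}).
#' @param lengths named vector of consensus lengths (all families, also
#'   those without hits).
#' @param id_min,frac_min thresholds (strict \code{>}), defaults 85 and
#'   0.85.
#' @return Character vector of representative family ids.
#' @export
collapse_families <- function(hits, lengths, id_min = 85, frac_min = 0.85) {
  keep <- hits$identity > id_min & hits$frac_aligned > frac_min &
    hits$query != hits$subject
  edges <- hits[keep, c("query", "subject")]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = names(lengths)))
  comp <- igraph::components(g)$membership
  reps <- tapply(names(comp), comp, function(members) {
    members[which.max(lengths[members])]
  })
  sort(unname(reps))
}

#' Assign ancestral-genome origin to a TE family
#'
#' A family passes for an ancestral genome when any hit against that genome
#' exceeds \code{id_min}\% identity over more than \code{frac_min} of the
#' consensus length (the 80\%/80\% rule). Exactly one passing genome gives
#' that ancestry; both give \code{ambiguous}; neither gives
#' \code{unassigned}.
#'
#' @param hits hit table for ONE family, with \code{subject_genome} in
#'   \code{"TH"}/\code{"AR"}.
#' @param id_min,frac_min thresholds (strict \code{>}), defaults 80, 0.80.
#' @return One of \code{"TH"}, \code{"AR"}, \code{"ambiguous"},
#'   \code{"unassigned"}.
#' @export
assign_ancestry <- function(hits, id_min = 80, frac_min = 0.80) {
  pass <- function(sg) {
    h <- hits[hits$subject_genome == sg, , drop = FALSE]
    any(h$identity > id_min & h$frac_aligned > frac_min)
  }
  th <- pass("TH"); ar <- pass("AR")
  if (th && ar) "ambiguous" else if (th) "TH" else if (ar) "AR"
  else "unassigned"
}

#' Inter-subgenome jump null model
#'
#' Under equal transposition activity, jumps in each direction are
#' proportional to the number of potential source elements times the size
#' of the target subgenome, so the expected fold difference of AR-to-TH
#' over TH-to-AR jumps is \code{(n_ar * l_th) / (n_th * l_ar)}.
#'
#' @param n_th,n_ar source element counts on the TH and AR subgenomes.
#' @param l_th,l_ar subgenome sizes (any common unit, e.g. Mb).
#' @return Expected fold (AR-to-TH over TH-to-AR).
#' @export
expected_jump_ratio <- function(n_th, n_ar, l_th, l_ar) {
  .assert(all(c(n_th, n_ar, l_th, l_ar) > 0),
          "source counts and lengths must be positive")
  (n_ar * l_th) / (n_th * l_ar)
}

#' Observed jump fold and excess over the null expectation
#'
#' @param obs_ar_to_th,obs_th_to_ar observed jump polymorphism counts per
#'   direction.
#' @param expected optional expected fold from
#'   \code{\link{expected_jump_ratio}}.
#' @return list: \code{observed} fold (AR-to-TH over TH-to-AR; NA with a
#'   zero denominator), \code{expected}, \code{excess}
#'   (observed / expected).
#' @export
observed_jump_ratio <- function(obs_ar_to_th, obs_th_to_ar,
                                expected = NULL) {
  obs <- if (obs_th_to_ar > 0) obs_ar_to_th / obs_th_to_ar else NA_real_
  if (is.na(obs)) warning("zero count in one direction; ratio undefined")
  list(observed = obs,
       expected = expected,
       excess = if (!is.null(expected) && !is.na(obs)) obs / expected
                else NA_real_)
}
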