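# Coverage-ratio copy number, nucleolar dominance, flow-cytometry 2C.
#
# Repetitive loci such as 45S rDNA arrays collapse to a single consensus in
# an assembly; their true copy number in a sequenced individual is then the
# relative increase of read depth over the locus compared with the
# genome-wide mean depth. The estimate is invariant to uniform depth
# rescaling and unbiased under Poisson sampling.

#' Estimate locus copy number from relative depth
#'
#' \code{copies = (mean depth over locus / genome-wide mean depth) * baseline},
#' where \code{baseline} is the copy number the locus has in the reference
#' (1 for a collapsed consensus). The genome-wide normalizer is the mean
#' depth; the median is returned alongside as a robustness diagnostic.
#'
#' @param track a \code{\link{coverage_track}}.
#' @param chrom,start,end locus interval (0-based half-open).
#' @param baseline reference copy number of the locus.
#' @param exclude_locus exclude the locus windows from the genome-wide
#'   normalizer (default TRUE: a collapsed repeat consensus is not part of
#'   the single-copy reference background, and a high-copy locus would
#'   otherwise inflate its own normalizer).
#' @return list: \code{copies}, \code{locus_mean}, \code{genome_mean},
#'   \code{genome_median}, \code{n_windows}.
#' @export
estimate_copy_number <- function(track, chrom, start, end, baseline = 1,
                                 exclude_locus = TRUE) {
  hit <- IRanges::overlapsAny(
    IRanges::IRanges(track$start + 1L, track$end),
    IRanges::IRanges(start + 1L, end)) & track$chrom == chrom
  .assert(any(hit), "locus not covered by any window")
  bg <- if (exclude_locus) track$depth[!hit] else track$depth
  genome_mean <- mean(bg)
  .assert(is.finite(genome_mean) && genome_mean > 0,
          "undefined: genome-wide mean depth is zero")
  locus_mean <- mean(track$depth[hit])
  list(copies = locus_mean / genome_mean * baseline,
       locus_mean = locus_mean, genome_mean = genome_mean,
       genome_median = median(bg), n_windows = sum(hit))
}

#' Truncate two consensus sequences to their aligned span
#'
#' When comparing copy numbers of two homeologous consensus loci (e.g. the
#' TH and AR 45S rDNA units), only the mutually alignable span should be
#' counted, so that the compared sequence sizes are equal. Given the best
#' hit between the two consensus sequences (with \code{qstart},
#' \code{qend}, \code{sstart}, \code{send}), both loci are truncated to the
#' aligned span. With no hit, full-length loci are returned with a warning.
#'
#' @param hit one row of a hit table (see \code{\link{read_hits}}), or NULL
#'   for the no-alignment path.
#' @param query_length,subject_length full consensus lengths (bp).
#' @return list: \code{query_span}, \code{subject_span} (1-based inclusive
#'   c(start, end)), \code{span_length} (on the query coordinate system),
#'   \code{aln_length} (gapped alignment length if the hit provides one,
#'   else NA) and \code{aligned} (logical).
#' @export
equalize_consensus_regions <- function(hit, query_length, subject_length) {
  if (is.null(hit) || nrow(as.data.frame(hit)) == 0) {
    warning("no alignment between consensus sequences; ",
            "full-length estimates are not size-matched")
    return(list(query_span = c(1L, query_length),
                subject_span = c(1L, subject_length),
                span_length = query_length, aln_length = NA_real_,
                aligned = FALSE))
  }
  hit <- as.data.frame(hit)[1, ]
  .assert(all(c("qstart", "qend", "sstart", "send") %in% names(hit)),
          "hit needs qstart, qend, sstart, send")
  qs <- sort(c(hit$qstart, hit$qend))
  ss <- sort(c(hit$sstart, hit$send))
  list(query_span = qs, subject_span = ss,
       span_length = qs[2] - qs[1] + 1L,
       aln_length = if (!is.null(hit$aln_length)) hit$aln_length else NA_real_,
       aligned = TRUE)
}

#' Call nucleolar dominance from 45S rRNA expression
#'
#' In a hybrid, one parent's 45S rRNA arrays are often silenced ("nucleolar
#' dominance"). Each subgenome's 45S allele is called expressed when its
#' log2 CPM strictly exceeds \code{threshold} (the cutoff separating true
#' expression from the cross-mapping floor); the call combines the two
#' flags.
#'
#' @param th_log_cpm,ar_log_cpm log2 CPM of the TH and AR 45S rRNA.
#' @param threshold expression cutoff (default 15).
#' @return list: \code{call} (\code{both}, \code{th_only}, \code{ar_only}
#'   or \code{neither}), \code{th_expressed}, \code{ar_expressed},
#'   \code{threshold}.
#' @export
call_nucleolar_dominance <- function(th_log_cpm, ar_log_cpm,
                                     threshold = 15) {
  .assert(is.finite(th_log_cpm) && is.finite(ar_log_cpm),
          "both expression values must be finite")
  th <- th_log_cpm > threshold
  ar <- ar_log_cpm > threshold
  call <- if (th && ar) "both" else if (th) "th_only"
          else if (ar) "ar_only" else "neither"
  list(call = call, th_expressed = th, ar_expressed = ar,
       threshold = threshold)
}

#' Flow-cytometry 2C DNA content
#'
#' \code{sample 2C = (sample G1 peak mean / standard G1 peak mean) *
#' standard 2C}, with an internal standard of known genome size co-run with
#' each sample.
#'
#' @param sample_g1_mean G1 peak mean fluorescence of the sample.
#' @param standard_g1_mean G1 peak mean of the standard (> 0).
#' @param standard_2c 2C DNA content of the standard in pg (default 1.96,
#'   the tomato standard).
#' @return Sample 2C DNA content in pg.
#' @export
flow_2c_content <- function(sample_g1_mean, standard_g1_mean,
                            standard_2c = 1.96) {
  .assert(standard_g1_mean > 0, "standard G1 peak mean must be positive")
  .assert(sample_g1_mean > 0 && standard_2c > 0,
          "peak means and standard 2C must be positive")
  sample_g1_mean / standard_g1_mean * standard_2c
}
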