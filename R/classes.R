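# Core containers. Light S3 wrappers around data.frames/matrices, in the
# style of edgeR's DGEList: validated on construction, printed compactly.
# All genomic intervals are 0-based half-open internally; conversion to the
# 1-based conventions of GFF3 happens only at the I/O boundary (see
# read_annotation/write_annotation).

#' Genome annotation for a two-subgenome reference
#'
#' @param chromosomes data.frame with columns \code{chrom}, \code{length}
#'   (bp) and \code{subgenome} (one of \code{"TH"}, \code{"AR"}).
#' @param genes data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end} (0-based half-open), \code{strand}
#'   (\code{"+"}/\code{"-"}) and optionally \code{partner} (the 1:1 homeolog
#'   on the other subgenome, \code{NA} if unpaired).
#'
#' @return An object of class \code{genome_annotation}: a list with elements
#'   \code{chromosomes} and \code{genes}; \code{genes} gains a
#'   \code{subgenome} column derived from its chromosome.
#' @export
genome_annotation <- function(chromosomes, genes) {
  .assert(all(c("chrom", "length", "subgenome") %in% names(chromosomes)),
          "chromosomes needs columns chrom, length, subgenome")
  .assert(!anyDuplicated(chromosomes$chrom), "duplicate chromosome names")
  .assert(all(chromosomes$subgenome %in% .SUBGENOMES),
          "unknown subgenome label (expected TH or AR)")
  .assert(all(chromosomes$length > 0), "chromosome lengths must be positive")
  .assert(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)),
          "genes needs columns gene_id, chrom, start, end, strand")
  .assert(!anyDuplicated(genes$gene_id), "duplicate gene ids")
  .assert(all(genes$chrom %in% chromosomes$chrom),
          "gene on unknown chromosome")
  clen <- setNames(chromosomes$length, chromosomes$chrom)
  .assert(all(genes$start >= 0 & genes$end <= clen[genes$chrom] &
                genes$start < genes$end),
          "gene interval outside chromosome bounds")
  if (is.null(genes$partner)) genes$partner <- NA_character_
  genes$subgenome <- setNames(chromosomes$subgenome,
                              chromosomes$chrom)[genes$chrom]
  # Partner links must be bijective where present.
  linked <- genes[!is.na(genes$partner), ]
  if (nrow(linked)) {
    .assert(all(linked$partner %in% genes$gene_id),
            "dangling homeolog partner id")
    back <- setNames(genes$partner, genes$gene_id)[linked$partner]
    .assert(all(!is.na(back) & back == linked$gene_id),
            "homeolog partner listed on one side only")
  }
  rownames(chromosomes) <- NULL
  rownames(genes) <- NULL
  structure(list(chromosomes = chromosomes, genes = genes),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$chromosomes), "chromosomes (",
      sum(x$chromosomes$subgenome == "TH"), "TH +",
      sum(x$chromosomes$subgenome == "AR"), "AR ),",
      nrow(x$genes), "genes,",
      sum(!is.na(x$genes$partner)) / 2, "homeolog pairs\n")
  invisible(x)
}

#' Extract the 1:1 homeolog pair table from an annotation
#'
#' @param annotation a \code{\link{genome_annotation}}.
#' @return data.frame with columns \code{pair_id}, \code{th_gene},
#'   \code{ar_gene}, one row per homeolog pair.
#' @export
homeolog_map <- function(annotation) {
  g <- annotation$genes
  th <- g[g$subgenome == "TH" & !is.na(g$partner), ]
  out <- data.frame(pair_id = paste0("pair_", seq_len(nrow(th))),
                    th_gene = th$gene_id, ar_gene = th$partner,
                    stringsAsFactors = FALSE)
  out[order(out$th_gene), , drop = FALSE]
}

#' Gene-by-sample count container
#'
#' @param counts non-negative integer matrix, genes in rows (rownames are
#'   gene ids), samples in columns.
#' @param genes data.frame with \code{gene_id}, \code{length} (bp, > 0) and
#'   \code{subgenome}; one row per counts row.
#' @param samples data.frame with \code{sample}, \code{species} (one of
#'   \code{thaliana}, \code{arenosa}, \code{suecica_natural},
#'   \code{suecica_synthetic}), \code{accession}, \code{replicate} and
#'   optionally \code{tissue}; one row per counts column.
#' @return An object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(counts, genes, samples) {
  counts <- as.matrix(counts)
  .assert(all(counts >= 0) && !anyNA(counts), "counts must be non-negative")
  .assert(nrow(counts) == nrow(genes), "genes table does not match counts rows")
  .assert(ncol(counts) == nrow(samples),
          "samples table does not match counts columns")
  .assert(all(genes$length > 0), "every gene needs a positive length")
  .assert(all(c("sample", "species", "accession", "replicate") %in%
                names(samples)), "samples needs sample, species, accession, replicate")
  .assert(all(samples$species %in% c("thaliana", "arenosa", "suecica_natural",
                                     "suecica_synthetic")),
          "unknown species label in sample metadata")
  if (is.null(samples$tissue)) samples$tissue <- "rosette"
  rownames(counts) <- genes$gene_id
  colnames(counts) <- samples$sample
  structure(list(counts = counts, genes = genes, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples;", length(unique(x$samples$accession)), "accessions\n")
  invisible(x)
}

#' Population TE insertion presence/absence matrix
#'
#' @param sites data.frame with \code{chrom}, \code{pos} (bp, >= 1),
#'   \code{family} and optionally \code{subgenome}.
#' @param calls matrix of \code{1} (present), \code{0} (absent) or \code{NA}
#'   (no coverage to support either call), sites in rows, accessions in
#'   columns.
#' @param species label for the panel (free text, e.g. \code{"suecica"}).
#' @return An object of class \code{te_matrix}.
#' @export
te_matrix <- function(sites, calls, species = NA_character_) {
  calls <- as.matrix(calls)
  .assert(all(c("chrom", "pos", "family") %in% names(sites)),
          "sites needs chrom, pos, family")
  .assert(all(sites$pos >= 1), "positions are 1-based (pos >= 1)")
  .assert(nrow(sites) == nrow(calls), "sites table does not match calls rows")
  .assert(all(calls %in% c(0, 1) | is.na(calls)),
          "calls must be 1, 0 or NA")
  key <- paste(sites$chrom, sites$pos, sites$family)
  .assert(!anyDuplicated(key), "duplicate (chrom, pos, family) site")
  if (is.null(sites$subgenome)) sites$subgenome <- NA_character_
  rownames(sites) <- NULL
  structure(list(sites = sites, calls = calls, species = species),
            class = "te_matrix")
}

#' @export
print.te_matrix <- function(x, ...) {
  cat("te_matrix (", x$species, "):", nrow(x$sites), "sites x",
      ncol(x$calls), "accessions\n")
  invisible(x)
}

#' Fixed-width windowed depth track
#'
#' @param windows data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and \code{depth} (mean depth, >= 0). Window width
#'   must be constant across the track.
#' @return An object of class \code{coverage_track} with the window width in
#'   attribute \code{"window"}.
#' @export
coverage_track <- function(windows) {
  .assert(all(c("chrom", "start", "end", "depth") %in% names(windows)),
          "windows needs chrom, start, end, depth")
  .assert(all(windows$depth >= 0), "depths must be non-negative")
  w <- unique(windows$end - windows$start)
  .assert(length(w) == 1 && w > 0, "window width must be constant")
  windows <- windows[order(windows$chrom, windows$start), , drop = FALSE]
  rownames(windows) <- NULL
  structure(windows, class = c("coverage_track", "data.frame"), window = w)
}

#' Genome-wide depth normalizers of a coverage track
#'
#' The mean is the normalizer used for copy-number estimation; the median is
#' reported alongside as a robustness diagnostic (and is the baseline for
#' copy-state calling, where aneuploid segments would distort the mean).
#'
#' @param track a \code{\link{coverage_track}}.
#' @return list with elements \code{mean} and \code{median}.
#' @export
coverage_summary <- function(track) {
  list(mean = mean(track$depth), median = median(track$depth))
}

#' Binned Hi-C style contact matrix
#'
#' @param bins data.frame with \code{bin} (integer id), \code{chrom},
#'   \code{start}, \code{end} (0-based half-open; fixed bin width).
#' @param counts square symmetric non-negative matrix, one row/column per
#'   bin, in bin order.
#' @return An object of class \code{contact_matrix}.
#' @export
contact_matrix <- function(bins, counts) {
  counts <- as.matrix(counts)
  .assert(nrow(counts) == ncol(counts), "contact matrix must be square")
  .assert(nrow(counts) == nrow(bins), "bin table does not match matrix")
  .assert(all(counts >= 0), "contact counts must be non-negative")
  .assert(isTRUE(all.equal(counts, t(counts))),
          "contact matrix must be symmetric")
  structure(list(bins = bins, counts = counts), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", nrow(x$bins), "bins of",
      x$bins$end[1] - x$bins$start[1], "bp\n")
  invisible(x)
}
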