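# Readers and writers for the external formats the pipeline touches.
#
# Conventions: GFF3 is 1-based inclusive on disk, converted to the internal
# 0-based half-open convention on read (and back on write). bedGraph is
# 0-based half-open on disk, matching the internal convention. Floats are
# written with 6 significant digits so that write-then-read is byte-stable.
# Contact triplets are stored upper-triangle and mirrored on read.

.fmt_num <- function(x) {
  out <- formatC(signif(x, 6), format = "fg", flag = "#")
  sub("\\.$", "", trimws(out))
}

#' Read a two-subgenome genome annotation
#'
#' Gene features come from a GFF3 file (attributes \code{ID} and, where a
#' 1:1 homeolog exists, \code{partner}); chromosome lengths and subgenome
#' labels come from a sidecar TSV with columns \code{chrom}, \code{length},
#' \code{subgenome}. Coordinates are converted from GFF3's 1-based inclusive
#' convention to the internal 0-based half-open one, and partner links are
#' cross-checked for bijectivity.
#'
#' @param gff path to the GFF3 gene file.
#' @param chromosomes path to the chromosome sidecar TSV.
#' @return A \code{\link{genome_annotation}}.
#' @export
read_annotation <- function(gff, chromosomes) {
  chrom <- read.delim(chromosomes, stringsAsFactors = FALSE)
  .assert(all(c("chrom", "length", "subgenome") %in% names(chrom)),
          "chromosome table needs chrom, length, subgenome")
  .assert(all(chrom$subgenome %in% .SUBGENOMES),
          paste("format error: unknown subgenome label:",
                paste(setdiff(chrom$subgenome, .SUBGENOMES), collapse = ", ")))
  gr <- rtracklayer::import(gff, format = "gff3")
  gr <- gr[gr$type == "gene"]
  partner <- if (!is.null(gr$partner)) as.character(gr$partner)
             else rep(NA_character_, length(gr))
  genes <- data.frame(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # GFF 1..100 -> internal (0,100)
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    partner = partner,
    stringsAsFactors = FALSE)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genome_annotation(chrom[, c("chrom", "length", "subgenome")], genes)
}

#' Write a genome annotation to GFF3 plus chromosome sidecar
#'
#' @param annotation a \code{\link{genome_annotation}}.
#' @param gff,chromosomes output paths (see \code{\link{read_annotation}}).
#' @return Invisibly, the GFF3 path.
#' @export
write_annotation <- function(annotation, gff, chromosomes) {
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand)
  gr$type <- "gene"
  gr$ID <- g$gene_id
  gr$partner <- g$partner
  GenomeInfoDb::seqlengths(gr) <- setNames(
    annotation$chromosomes$length,
    annotation$chromosomes$chrom)[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, gff, format = "gff3")
  write.table(annotation$chromosomes, chromosomes, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(gff)
}

#' Read a population TE call matrix
#'
#' Expects a rectangular TSV with site columns \code{chrom}, \code{pos},
#' \code{family} followed by one column per accession holding \code{1}
#' (insertion present), \code{0} (absent) or \code{NA} (no coverage to
#' support either call; such cells are excluded from frequency
#' denominators downstream). This dialect is the presence/absence
#' abstraction emitted at the end of a PoPoolationTE2-style pipeline; a
#' converter from other callers only needs to produce these columns.
#'
#' @param path TSV path.
#' @param chrom_subgenome optional named vector mapping chromosome to
#'   subgenome, used to tag sites.
#' @param species panel label.
#' @return A \code{\link{te_matrix}}.
#' @export
read_te_calls <- function(path, chrom_subgenome = NULL,
                          species = NA_character_) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  .assert(all(c("chrom", "pos", "family") %in% names(d)),
          "TE call table needs chrom, pos, family")
  acc_cols <- setdiff(names(d), c("chrom", "pos", "family", "subgenome"))
  .assert(length(acc_cols) >= 1, "no accession columns in TE call table")
  calls <- as.matrix(d[, acc_cols, drop = FALSE])
  bad <- !(calls %in% c(0, 1) | is.na(calls))
  if (any(bad))
    stop("format error: TE calls must be 1, 0 or NA", call. = FALSE)
  storage.mode(calls) <- "integer"
  sites <- d[, c("chrom", "pos", "family")]
  if (!is.null(d$subgenome)) sites$subgenome <- d$subgenome
  else if (!is.null(chrom_subgenome))
    sites$subgenome <- unname(chrom_subgenome[sites$chrom])
  te_matrix(sites, calls, species = species)
}

#' Write a TE call matrix as rectangular TSV
#'
#' @param x a \code{\link{te_matrix}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_te_calls <- function(x, path) {
  d <- cbind(x$sites[, c("chrom", "pos", "family", "subgenome")], x$calls)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a bedGraph depth track
#'
#' bedGraph intervals are 0-based half-open, the internal convention; the
#' interval width must be constant (one depth value per fixed window).
#'
#' @param path bedGraph path.
#' @return A \code{\link{coverage_track}}.
#' @export
read_coverage <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  coverage_track(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    depth = gr$score, stringsAsFactors = FALSE))
}

#' Write a coverage track as bedGraph
#'
#' @param track a \code{\link{coverage_track}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_coverage <- function(track, path) {
  d <- data.frame(track$chrom, track$start, track$end, .fmt_num(track$depth))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a binned contact matrix from triplet TSV
#'
#' The triplet file has columns \code{bin1}, \code{bin2}, \code{count} and
#' stores the upper triangle (\code{bin1 <= bin2}); the matrix is
#' symmetrized by mirroring on read. A conflicting lower-triangle entry
#' (both (i,j) and (j,i) present with different counts) is a format error.
#' The bin sidecar TSV has columns \code{bin}, \code{chrom}, \code{start},
#' \code{end}.
#'
#' @param path triplet TSV path.
#' @param bins bin sidecar TSV path.
#' @return A \code{\link{contact_matrix}}.
#' @export
read_contacts <- function(path, bins) {
  b <- read.delim(bins, stringsAsFactors = FALSE)
  .assert(all(c("bin", "chrom", "start", "end") %in% names(b)),
          "bin table needs bin, chrom, start, end")
  trip <- read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("bin1", "bin2", "count") %in% names(trip)),
          "triplet table needs bin1, bin2, count")
  .assert(is.numeric(trip$count) && !anyNA(trip$count),
          "format error: non-numeric contact count")
  .assert(all(trip$bin1 %in% b$bin) && all(trip$bin2 %in% b$bin),
          "format error: triplet bin not resolvable to a window")
  i <- match(trip$bin1, b$bin); j <- match(trip$bin2, b$bin)
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  key <- paste(i, j)
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    .assert(all(trip$count[dup] == trip$count[first]),
            "format error: asymmetric contact triplets")
  }
  n <- nrow(b)
  m <- matrix(0, n, n)
  m[cbind(i, j)] <- trip$count
  m[cbind(j, i)] <- trip$count
  contact_matrix(b, m)
}

#' Write a contact matrix as upper-triangle triplets plus bin table
#'
#' @param cm a \code{\link{contact_matrix}}.
#' @param path triplet TSV output path.
#' @param bins bin sidecar TSV output path.
#' @return Invisibly, \code{path}.
#' @export
write_contacts <- function(cm, path, bins) {
  n <- nrow(cm$counts)
  ut <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
              arr.ind = TRUE)
  trip <- data.frame(bin1 = cm$bins$bin[ut[, 1]],
                     bin2 = cm$bins$bin[ut[, 2]],
                     count = .fmt_num(cm$counts[ut]))
  write.table(trip, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cm$bins, bins, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix with sample metadata
#'
#' The counts TSV has columns \code{gene_id}, \code{length},
#' \code{subgenome}, then one integer column per sample. The metadata TSV
#' has columns \code{sample}, \code{species}, \code{accession},
#' \code{replicate} and optionally \code{tissue}.
#'
#' @param path counts TSV path.
#' @param metadata sample metadata TSV path.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_counts <- function(path, metadata) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  .assert(all(c("gene_id", "length", "subgenome") %in% names(d)),
          "counts table needs gene_id, length, subgenome")
  meta <- read.delim(metadata, stringsAsFactors = FALSE)
  .assert(all(meta$sample %in% names(d)),
          "metadata sample missing from counts table")
  counts <- as.matrix(d[, meta$sample, drop = FALSE])
  .assert(is.numeric(counts) && !anyNA(counts) && all(counts >= 0) &&
            all(counts == round(counts)),
          "format error: counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  expression_matrix(counts, d[, c("gene_id", "length", "subgenome")], meta)
}

#' Write an expression matrix as counts TSV plus metadata TSV
#'
#' @param em an \code{\link{expression_matrix}}.
#' @param path counts TSV output path.
#' @param metadata metadata TSV output path.
#' @return Invisibly, \code{path}.
#' @export
write_counts <- function(em, path, metadata) {
  d <- cbind(em$genes[, c("gene_id", "length", "subgenome")], em$counts)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(em$samples, metadata, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a tabular alignment hit table
#'
#' A BLAST-like TSV with columns \code{query}, \code{subject},
#' \code{identity} (percent, 0-100), \code{frac_aligned} (fraction of query
#' length aligned, 0-1), optional \code{subject_genome} and optional
#' \code{qstart}, \code{qend}, \code{sstart}, \code{send},
#' \code{aln_length}.
#'
#' @param path TSV path.
#' @return data.frame of validated hits.
#' @export
read_hits <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("query", "subject", "identity", "frac_aligned") %in% names(d)),
          "hit table needs query, subject, identity, frac_aligned")
  .assert(all(d$identity >= 0 & d$identity <= 100),
          "format error: identity outside [0, 100]")
  .assert(all(d$frac_aligned >= 0 & d$frac_aligned <= 1),
          "format error: frac_aligned outside [0, 1]")
  d
}

#' Read a VCF-lite SNP table
#'
#' A TSV with columns \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#' \code{effect} and optionally \code{ancestral} (the outgroup-polarized
#' ancestral allele) followed by per-accession genotype columns (\code{0}
#' reference, \code{1} alternate, \code{NA} missing). Effect classes other
#' than \code{synonymous}/\code{nonsynonymous} are mapped to \code{other}.
#'
#' @param path TSV path.
#' @return list with \code{sites} (site table, normalized \code{effect}) and
#'   \code{genotypes} (matrix).
#' @export
read_snps <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  .assert(all(c("chrom", "pos", "ref", "alt", "effect") %in% names(d)),
          "SNP table needs chrom, pos, ref, alt, effect")
  site_cols <- intersect(c("chrom", "pos", "ref", "alt", "effect",
                           "ancestral"), names(d))
  geno_cols <- setdiff(names(d), site_cols)
  geno <- as.matrix(d[, geno_cols, drop = FALSE])
  .assert(all(geno %in% c(0, 1) | is.na(geno)),
          "format error: genotypes must be 0, 1 or NA")
  storage.mode(geno) <- "integer"
  sites <- d[, site_cols]
  sites$effect[!sites$effect %in% c("synonymous", "nonsynonymous")] <- "other"
  list(sites = sites, genotypes = geno)
}
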