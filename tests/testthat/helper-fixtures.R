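# Shared fixture builders. Everything is generated in code; no files.

tiny_params <- function(...) {
  args <- list(n_genes_per_subgenome = 40, chrom_len_th = 2e5,
               chrom_len_ar = 2e5, n_sites_shared = 80,
               n_sites_private_poly = 40, n_sites_private_anc = 40,
               seed = 42L)
  args <- utils::modifyList(args, list(...))
  do.call(synth_params, args)
}

tiny_reference <- function(params = tiny_params()) generate_reference(params)

tiny_design <- function(replicates = 2) {
  expression_design(c(thaliana = 4, arenosa = 3, suecica_natural = 4,
                      suecica_synthetic = 2), replicates = replicates)
}

# A hand-built normalized_expression with accession-level control:
# `logcpm_by_acc` is genes x accessions; each accession gets one sample.
fake_norm <- function(logcpm_by_acc, species, gene_subgenome,
                      tissue = "rosette") {
  acc <- colnames(logcpm_by_acc)
  samples <- data.frame(sample = acc, species = species, accession = acc,
                        replicate = 1L,
                        tissue = rep_len(tissue, length(acc)),
                        stringsAsFactors = FALSE)
  genes <- data.frame(gene_id = rownames(logcpm_by_acc), length = 1000,
                      subgenome = gene_subgenome, stringsAsFactors = FALSE)
  structure(list(logcpm = logcpm_by_acc, sizes = NULL, tmm = NULL,
                 prior = 1, genes = genes, samples = samples),
            class = "normalized_expression")
}

# Uniform coverage track: `n` windows of width `w`, depth `depth`.
flat_track <- function(n = 100, depth = 10, w = 1000, chrom = "TH1") {
  coverage_track(data.frame(chrom = chrom, start = (seq_len(n) - 1) * w,
                            end = seq_len(n) * w, depth = depth))
}
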