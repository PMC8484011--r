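# Synthetic allopolyploid generator.
#
# Emulates the observable structure of a young allotetraploid formed from
# two diverged parents: a 5 + 8 chromosome reference with 1:1 homeologs,
# negative-binomial expression with asymmetric cross-mapping leakage,
# founder-bottlenecked TE insertion frequencies with selection-skewed
# private insertions and inter-subgenome jumps, Poisson read depth with
# planted 4:0 homeologous-exchange segments and rDNA-like multi-copy loci,
# and a Hi-C trans-contact background with breakpoint spikes.
#
# Every generator is a pure function of (params, seed): RNG sub-streams are
# derived from params$seed by fixed offsets so that adding one output never
# perturbs another.

.SEED_OFFSETS <- c(reference = 11L, expression = 23L, te = 37L,
                   coverage = 53L, contacts = 71L)

#' Parameters of the synthetic allopolyploid system
#'
#' Defaults mirror the system the package targets: 5 TH + 8 AR chromosomes,
#' around 11.6\% parental divergence, and asymmetric cross-mapping leakage of
#' about 1\% (thaliana signal onto the AR copy) and 6\% (arenosa signal onto
#' the TH copy).
#'
#' @param n_genes_per_subgenome number of genes per subgenome.
#' @param n_chrom_th,n_chrom_ar chromosomes per subgenome.
#' @param chrom_len_th,chrom_len_ar chromosome length in bp.
#' @param gene_spacing distance between gene starts (bp); genes that do not
#'   fit at this spacing raise a sizing error in
#'   \code{\link{generate_reference}}.
#' @param divergence nucleotide divergence between the subgenomes (fraction;
#'   carried as metadata, sequences are not simulated).
#' @param leak_th fraction of true arenosa-subgenome signal attributed to the
#'   thaliana homeolog in pure arenosa samples.
#' @param leak_ar fraction of true thaliana-subgenome signal attributed to
#'   the arenosa homeolog in pure thaliana samples.
#' @param nb_dispersion negative-binomial dispersion of counts
#'   (variance \eqn{\mu + \phi \mu^2}).
#' @param accession_sdlog standard deviation (log2 scale) of per-accession
#'   expression effects.
#' @param deg_frac fraction of homeolog pairs given a planted expression
#'   shift in natural allopolyploid samples.
#' @param deg_logfc absolute log2 fold change of planted shifts.
#' @param n_accessions accessions per species panel (TE simulator).
#' @param founder_k number of founder genome copies in the polyploid
#'   bottleneck; allopolyploid TE frequencies at shared sites are binomial
#'   resamples of \code{founder_k} draws from the ancestral frequency.
#' @param te_beta_shared,te_beta_private Beta shape pairs for ancestral
#'   (shared) and private (selection-skewed, rare-biased) insertion
#'   frequencies.
#' @param n_sites_shared,n_sites_private_poly,n_sites_private_anc numbers of
#'   ancestral and private TE insertion sites per subgenome.
#' @param n_fam_th,n_fam_ar TE families (potential jump sources) per
#'   subgenome; the roughly 2:1 AR:TH default follows the annotated
#'   transposon imbalance of the target system.
#' @param jump_rate expected inter-subgenome jumps per source family per Mb
#'   of target subgenome.
#' @param te_missing_rate probability that a call is missing (no coverage).
#' @param depth_mean expected reads per window at two copies.
#' @param he_events data.frame of planted homeologous exchanges (columns
#'   \code{chrom}, \code{start}, \code{end}, \code{direction}; direction
#'   \code{"gain"} plants 4 copies, \code{"loss"} plants 0).
#' @param seed integer seed; identical seed and params give identical output.
#'
#' @return A validated list of class \code{synth_params}.
#' @export
synth_params <- function(n_genes_per_subgenome = 200,
                         n_chrom_th = 5, n_chrom_ar = 8,
                         chrom_len_th = 1e6, chrom_len_ar = 1e6,
                         gene_spacing = 4000,
                         divergence = 0.116,
                         leak_th = 0.06, leak_ar = 0.01,
                         nb_dispersion = 0.05,
                         accession_sdlog = 0.25,
                         deg_frac = 0, deg_logfc = 2,
                         n_accessions = 15,
                         founder_k = 2,
                         te_beta_shared = c(0.5, 0.5),
                         te_beta_private = c(0.2, 2),
                         n_sites_shared = 300,
                         n_sites_private_poly = 150,
                         n_sites_private_anc = 150,
                         n_fam_th = 20, n_fam_ar = 40,
                         jump_rate = 0.05,
                         te_missing_rate = 0.05,
                         depth_mean = 20,
                         he_events = NULL,
                         seed = 1L) {
  p <- as.list(environment())
  fracs <- c(p$divergence, p$leak_th, p$leak_ar, p$deg_frac, p$te_missing_rate)
  .assert(all(fracs >= 0 & fracs <= 1), "fractions must lie in [0, 1]")
  counts <- c(p$n_genes_per_subgenome, p$n_chrom_th, p$n_chrom_ar,
              p$n_accessions, p$founder_k, p$n_fam_th, p$n_fam_ar)
  .assert(all(counts >= 1), "counts must be positive")
  .assert(p$nb_dispersion > 0, "nb_dispersion must be positive")
  .assert(p$depth_mean >= 0, "depth_mean must be non-negative")
  .assert(p$founder_k <= 2 * p$n_accessions,
          "founder_k cannot exceed the ancestral panel of genome copies")
  .assert(all(p$te_beta_shared > 0) && all(p$te_beta_private > 0),
          "Beta shapes must be positive")
  p$seed <- as.integer(p$seed)
  structure(p, class = "synth_params")
}

.sub_seed <- function(params, stream) {
  params$seed + .SEED_OFFSETS[[stream]]
}

#' Generate the two-subgenome reference and homeolog pairing
#'
#' Lays out \code{n_genes_per_subgenome} non-overlapping genes per subgenome
#' on 5 + 8 chromosomes (by default), pairing gene i of TH with gene i of AR
#' as 1:1 homeologs. Genes are placed on a fixed grid of
#' \code{gene_spacing} bp with lengths drawn uniformly within the grid cell.
#'
#' @param params a \code{\link{synth_params}} object.
#' @return list with elements \code{annotation}
#'   (\code{\link{genome_annotation}}) and \code{map} (homeolog pair table,
#'   see \code{\link{homeolog_map}}).
#' @export
generate_reference <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(.sub_seed(params, "reference"))
  chroms <- data.frame(
    chrom = c(paste0("TH", seq_len(params$n_chrom_th)),
              paste0("AR", seq_len(params$n_chrom_ar))),
    length = c(rep(params$chrom_len_th, params$n_chrom_th),
               rep(params$chrom_len_ar, params$n_chrom_ar)),
    subgenome = c(rep("TH", params$n_chrom_th), rep("AR", params$n_chrom_ar)),
    stringsAsFactors = FALSE)

  # Homeolog partners keep the ancestral gene's length: one draw per pair.
  pair_len <- round(runif(params$n_genes_per_subgenome, 500,
                          min(3000, params$gene_spacing - 100)))
  place_genes <- function(sg) {
    cc <- chroms[chroms$subgenome == sg, ]
    capacity <- floor(cc$length / params$gene_spacing)
    n <- params$n_genes_per_subgenome
    # Consecutive blocks per chromosome, so gene rank order is syntenic
    # between the subgenomes (a contiguous run of genes projects to a
    # contiguous run of homeolog partners, as in largely collinear
    # parental genomes).
    block <- diff(floor(seq(0, n, length.out = nrow(cc) + 1)))
    if (any(block > capacity))
      stop("sizing error: ", n, " genes do not fit on the ", sg,
           " subgenome at a spacing of ", params$gene_spacing, " bp",
           call. = FALSE)
    chrom_idx <- rep(seq_len(nrow(cc)), block)
    slot <- stats::ave(seq_len(n), chrom_idx, FUN = seq_along)
    start <- (slot - 1L) * params$gene_spacing
    len <- pair_len
    data.frame(
      gene_id = sprintf("%s_g%04d", sg, seq_len(n)),
      chrom = cc$chrom[chrom_idx],
      start = start, end = start + len,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  th <- place_genes("TH")
  ar <- place_genes("AR")
  th$partner <- ar$gene_id
  ar$partner <- th$gene_id
  ann <- genome_annotation(chroms, rbind(th, ar))
  list(annotation = ann, map = homeolog_map(ann))
}

#' Build a sample design table
#'
#' @param n_per_species named integer vector, accessions per species (names
#'   among \code{thaliana}, \code{arenosa}, \code{suecica_natural},
#'   \code{suecica_synthetic}).
#' @param replicates biological replicates per accession.
#' @param tissues character vector of tissues; each accession x replicate is
#'   sampled in every tissue.
#' @return data.frame usable as the \code{design} of
#'   \code{\link{simulate_expression}}.
#' @export
expression_design <- function(n_per_species = c(thaliana = 5, arenosa = 4,
                                                suecica_natural = 5,
                                                suecica_synthetic = 2),
                              replicates = 3, tissues = "rosette") {
  .assert(all(names(n_per_species) %in%
                c("thaliana", "arenosa", "suecica_natural", "suecica_synthetic")),
          "design error: unknown species label")
  .assert(replicates >= 1, "at least one replicate per accession")
  rows <- do.call(rbind, lapply(names(n_per_species), function(sp) {
    expand.grid(species = sp,
                accession = sprintf("%s_acc%02d", sp,
                                    seq_len(n_per_species[[sp]])),
                replicate = seq_len(replicates),
                tissue = tissues,
                stringsAsFactors = FALSE)
  }))
  rows$sample <- sprintf("%s_r%d_%s", rows$accession, rows$replicate,
                         rows$tissue)
  rows[, c("sample", "species", "accession", "replicate", "tissue")]
}

#' Simulate homeolog-resolved RNA-seq counts
#'
#' Counts are negative-binomial draws around per-gene means. Pure ancestor
#' samples express only their own subgenome's rows, but a leak fraction of
#' each gene's signal is reattributed to the homeolog's row
#' (\code{leak_ar} of thaliana signal onto the AR copy, \code{leak_th} of
#' arenosa signal onto the TH copy), emulating the observable effect of
#' read cross-mapping between diverged subgenomes. Allopolyploid samples
#' express both rows with no leak. Optional planted expression shifts
#' (\code{deg_frac}, \code{deg_logfc}) apply to natural allopolyploid
#' accessions and are recorded in the returned truth.
#'
#' @param annotation,map from \code{\link{generate_reference}}.
#' @param design sample table from \code{\link{expression_design}}.
#' @param params a \code{\link{synth_params}} object.
#' @return list with \code{matrix} (an \code{\link{expression_matrix}}) and
#'   \code{truth} (list: \code{base_mean} per gene, \code{deg} table with
#'   planted per-subgenome log2 fold changes, \code{leak_th}, \code{leak_ar},
#'   \code{tissue_effects}).
#' @export
simulate_expression <- function(annotation, map, design, params) {
  stopifnot(inherits(params, "synth_params"))
  .assert(all(design$species %in% c("thaliana", "arenosa", "suecica_natural",
                                    "suecica_synthetic")),
          "design error: unknown species label")
  set.seed(.sub_seed(params, "expression"))
  genes <- annotation$genes
  genes$length <- genes$end - genes$start
  n_pairs <- nrow(map)
  ord <- match(c(map$th_gene, map$ar_gene), genes$gene_id)
  genes <- genes[ord, ]                     # paired genes only, TH block first
  n_genes <- nrow(genes)

  # Per-pair baseline expression level (reads/kb); both members share it so
  # that the null homeolog logFC is zero.
  pair_level <- exp(rnorm(n_pairs, log(80), 1))
  base_rate <- rep(pair_level, 2)           # per gene, reads per kb
  base_mean <- base_rate * genes$length / 1000

  # Planted differential expression between natural allopolyploid and the
  # corresponding ancestor panel, per subgenome.
  deg <- data.frame(gene_id = character(), subgenome = character(),
                    logfc = numeric(), stringsAsFactors = FALSE)
  if (params$deg_frac > 0) {
    idx <- which(runif(n_genes) < params$deg_frac)
    if (length(idx)) {
      deg <- data.frame(
        gene_id = genes$gene_id[idx],
        subgenome = genes$subgenome[idx],
        logfc = sample(c(-1, 1), length(idx), replace = TRUE) * params$deg_logfc,
        stringsAsFactors = FALSE)
    }
  }
  deg_mult <- setNames(rep(1, n_genes), genes$gene_id)
  deg_mult[deg$gene_id] <- 2^deg$logfc

  # Tissue effects: if the design has more than one tissue, plant a strong
  # shift for a subset of pairs in all non-reference tissues.
  tissues <- unique(design$tissue)
  tissue_eff <- setNames(rep(1, n_genes), genes$gene_id)
  tissue_genes <- character()
  if (length(tissues) > 1) {
    t_idx <- which(runif(n_genes) < 0.1)
    tissue_eff[t_idx] <- 2^sample(c(-3, 3), length(t_idx), replace = TRUE)
    tissue_genes <- genes$gene_id[t_idx]
  }

  # Accession effects, shared by replicates of the same accession.
  accs <- unique(design$accession)
  acc_eff <- matrix(2^rnorm(n_genes * length(accs), 0, params$accession_sdlog),
                    nrow = n_genes, dimnames = list(genes$gene_id, accs))

  partner_row <- match(genes$partner, genes$gene_id)
  counts <- matrix(0L, n_genes, nrow(design),
                   dimnames = list(genes$gene_id, design$sample))
  for (j in seq_len(nrow(design))) {
    sp <- design$species[j]
    mu <- base_mean * acc_eff[, design$accession[j]]
    if (design$tissue[j] != tissues[1]) mu <- mu * tissue_eff
    if (sp == "suecica_natural") mu <- mu * deg_mult
    expressed <- switch(sp,
      thaliana = genes$subgenome == "TH",
      arenosa = genes$subgenome == "AR",
      rep(TRUE, n_genes))
    mu[!expressed] <- 0
    if (sp == "thaliana") {
      leaked <- mu * params$leak_ar
      mu <- mu - leaked
      mu[partner_row] <- mu[partner_row] + leaked
    } else if (sp == "arenosa") {
      leaked <- mu * params$leak_th
      mu <- mu - leaked
      mu[partner_row] <- mu[partner_row] + leaked
    }
    counts[, j] <- rnbinom(n_genes, mu = mu, size = 1 / params$nb_dispersion)
  }

  em <- expression_matrix(counts, genes[, c("gene_id", "length", "subgenome")],
                          design)
  truth <- list(base_mean = setNames(base_mean, genes$gene_id),
                deg = deg, leak_th = params$leak_th, leak_ar = params$leak_ar,
                tissue_effect_genes = tissue_genes)
  list(matrix = em, truth = truth)
}

#' Simulate ancestral and allopolyploid TE insertion panels
#'
#' Ancestral (shared-origin) sites get population frequencies from
#' \code{te_beta_shared}; their allopolyploid frequencies are binomial
#' resamples of \code{founder_k} founder draws, emulating the fixation-shift
#' of a founder bottleneck. Private insertions (post-origin) get
#' \code{te_beta_private} frequencies, skewed to rare as expected under
#' purifying selection. Inter-subgenome jump insertions are planted at a
#' Poisson rate proportional to source-family count times target subgenome
#' length, the null model of \code{\link{expected_jump_ratio}}.
#'
#' @param annotation from \code{\link{generate_reference}}.
#' @param params a \code{\link{synth_params}} object.
#' @return list with \code{ancestor_th}, \code{ancestor_ar} and
#'   \code{polyploid} (\code{\link{te_matrix}} objects; the polyploid panel
#'   spans both subgenomes) and \code{truth} (per-site class, per-family
#'   ancestry, planted jump counts per direction).
#' @export
simulate_te_populations <- function(annotation, params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(.sub_seed(params, "te"))
  chroms <- annotation$chromosomes
  .assert(all(chroms$length > 0), "configuration error: zero target length")
  n_acc <- params$n_accessions

  fams <- list(TH = sprintf("famTH_%02d", seq_len(params$n_fam_th)),
               AR = sprintf("famAR_%02d", seq_len(params$n_fam_ar)))

  rand_sites <- function(n, sg, fam_pool) {
    cc <- chroms[chroms$subgenome == sg, ]
    if (n == 0)
      return(data.frame(chrom = character(), pos = numeric(),
                        family = character(), subgenome = character(),
                        stringsAsFactors = FALSE))
    ci <- sample(nrow(cc), n, replace = TRUE, prob = cc$length)
    data.frame(chrom = cc$chrom[ci],
               pos = floor(runif(n, 1, cc$length[ci])),
               family = sample(fam_pool, n, replace = TRUE),
               subgenome = sg, stringsAsFactors = FALSE)
  }
  draw_calls <- function(freq, n_acc) {
    calls <- matrix(rbinom(length(freq) * n_acc, 1, rep(freq, n_acc)),
                    nrow = length(freq))
    miss <- matrix(runif(length(calls)) < params$te_missing_rate,
                   nrow = nrow(calls))
    calls[miss] <- NA
    calls
  }

  per_sg <- lapply(.SUBGENOMES, function(sg) {
    own <- fams[[sg]]
    sh <- rand_sites(params$n_sites_shared, sg, own)
    pp <- rand_sites(params$n_sites_private_poly, sg, own)
    pa <- rand_sites(params$n_sites_private_anc, sg, own)
    f_sh <- rbeta(nrow(sh), params$te_beta_shared[1], params$te_beta_shared[2])
    # Founder bottleneck: allopolyploid frequency is the founder-sample
    # frequency of founder_k genome copies.
    f_sh_poly <- rbinom(nrow(sh), params$founder_k, f_sh) / params$founder_k
    f_priv <- function(n) rbeta(n, params$te_beta_private[1],
                                params$te_beta_private[2])
    # Jumps INTO this subgenome from the other subgenome's families.
    src_sg <- .other_subgenome(sg)
    lambda <- params$jump_rate * length(fams[[src_sg]]) *
      sum(chroms$length[chroms$subgenome == sg]) / 1e6
    n_jump <- rpois(1, lambda)
    jp <- rand_sites(n_jump, sg, fams[[src_sg]])

    anc_sites <- rbind(sh, pa)
    anc_calls <- draw_calls(c(f_sh, f_priv(nrow(pa))), n_acc)
    poly_sites <- rbind(sh, pp, jp)
    poly_calls <- draw_calls(c(f_sh_poly, f_priv(nrow(pp)), f_priv(nrow(jp))),
                             n_acc)
    classes <- data.frame(
      chrom = poly_sites$chrom, pos = poly_sites$pos,
      family = poly_sites$family, subgenome = sg,
      class = rep(c("shared", "private", "jump"),
                  c(nrow(sh), nrow(pp), nrow(jp))),
      stringsAsFactors = FALSE)
    list(anc_sites = anc_sites, anc_calls = anc_calls,
         poly_sites = poly_sites, poly_calls = poly_calls,
         classes = classes, n_jump = n_jump)
  })
  names(per_sg) <- .SUBGENOMES

  dedupe <- function(sites, calls) {
    keep <- !duplicated(paste(sites$chrom, sites$pos, sites$family))
    list(sites = sites[keep, , drop = FALSE], calls = calls[keep, , drop = FALSE])
  }
  mk <- function(sites, calls, acc_prefix, species) {
    d <- dedupe(sites, calls)
    colnames(d$calls) <- sprintf("%s%02d", acc_prefix, seq_len(ncol(d$calls)))
    te_matrix(d$sites, d$calls, species = species)
  }
  anc_th <- mk(per_sg$TH$anc_sites, per_sg$TH$anc_calls, "th", "thaliana")
  anc_ar <- mk(per_sg$AR$anc_sites, per_sg$AR$anc_calls, "ar", "arenosa")
  poly <- mk(rbind(per_sg$TH$poly_sites, per_sg$AR$poly_sites),
             rbind(per_sg$TH$poly_calls, per_sg$AR$poly_calls),
             "as", "suecica")

  ancestry <- data.frame(family = unlist(fams, use.names = FALSE),
                         ancestry = rep(.SUBGENOMES, lengths(fams)),
                         stringsAsFactors = FALSE)
  truth <- list(
    site_class = rbind(per_sg$TH$classes, per_sg$AR$classes),
    family_ancestry = ancestry,
    jump_counts = c(ar_to_th = per_sg$TH$n_jump, th_to_ar = per_sg$AR$n_jump),
    founder_k = params$founder_k)
  list(ancestor_th = anc_th, ancestor_ar = anc_ar, polyploid = poly,
       truth = truth)
}

#' Simulate windowed sequencing depth with planted copy states
#'
#' Window depth is Poisson with mean \code{depth_mean * copies / 2}: the
#' baseline diploid-per-subgenome state is 2 copies. Homeologous exchanges
#' plant reciprocal 0- and 4-copy segments; an rDNA-like locus with
#' multiplier m is planted as \code{copies = 2 m} (so that a collapsed
#' single-copy reference consensus shows an m-fold depth gain).
#'
#' @param annotation a \code{\link{genome_annotation}}.
#' @param copy_map optional data.frame (\code{chrom}, \code{start},
#'   \code{end}, \code{copies}) overriding the baseline of 2 on those
#'   intervals; \code{copies} must be non-negative (0/2/4 for HE states).
#' @param depth_mean expected depth per window at copy state 2.
#' @param window window width in bp.
#' @param seed integer seed.
#' @return list with \code{track} (a \code{\link{coverage_track}}) and
#'   \code{truth} (per-window planted copy number).
#' @export
simulate_coverage <- function(annotation, copy_map = NULL, depth_mean = 20,
                              window = 1000, seed = 1L) {
  .assert(depth_mean >= 0, "parameter error: depth_mean must be non-negative")
  set.seed(as.integer(seed) + .SEED_OFFSETS[["coverage"]])
  chroms <- annotation$chromosomes
  win <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    starts <- seq(0, chroms$length[i] - window, by = window)
    data.frame(chrom = chroms$chrom[i], start = starts, end = starts + window,
               stringsAsFactors = FALSE)
  }))
  copies <- rep(2, nrow(win))
  if (!is.null(copy_map)) {
    .assert(all(copy_map$copies >= 0), "copies must be non-negative")
    for (i in seq_len(nrow(copy_map))) {
      hit <- win$chrom == copy_map$chrom[i] &
        win$start < copy_map$end[i] & win$end > copy_map$start[i]
      copies[hit] <- copy_map$copies[i]
    }
  }
  win$depth <- rpois(nrow(win), depth_mean * copies / 2)
  list(track = coverage_track(win),
       truth = data.frame(win[, c("chrom", "start", "end")], copies = copies))
}

#' Copy map and truth for a planted homeologous exchange
#'
#' Builds the \code{copy_map} rows that plant a reciprocal 4:0 exchange:
#' the windows covering a contiguous run of genes drop to 0 copies, the
#' windows covering their homeolog partners rise to 4. Intervals are
#' snapped outward to the window grid.
#'
#' @param annotation a \code{\link{genome_annotation}}.
#' @param lost_genes contiguous gene ids (one chromosome) to delete; their
#'   partners define the duplicated segment.
#' @param window window width the coverage track will use.
#' @return list: \code{copy_map} (for \code{\link{simulate_coverage}}) and
#'   \code{truth} (lost/duplicated intervals, replacing subgenome, lost
#'   gene ids).
#' @export
he_copy_map <- function(annotation, lost_genes, window = 1000) {
  g <- annotation$genes
  rows <- g[match(lost_genes, g$gene_id), ]
  .assert(!anyNA(rows$gene_id), "unknown gene id")
  .assert(length(unique(rows$chrom)) == 1, "lost genes must share a chromosome")
  .assert(all(!is.na(rows$partner)), "lost genes must all have partners")
  prows <- g[match(rows$partner, g$gene_id), ]
  .assert(length(unique(prows$chrom)) == 1,
          "partner genes span several chromosomes; pick a syntenic run")
  clen <- setNames(annotation$chromosomes$length, annotation$chromosomes$chrom)
  snap <- function(d) {
    c(floor(min(d$start) / window) * window,
      min(ceiling(max(d$end) / window) * window, clen[[d$chrom[1]]]))
  }
  lost <- snap(rows); dup <- snap(prows)
  copy_map <- data.frame(
    chrom = c(rows$chrom[1], prows$chrom[1]),
    start = c(lost[1], dup[1]), end = c(lost[2], dup[2]),
    copies = c(0, 4), stringsAsFactors = FALSE)
  truth <- list(lost_chrom = rows$chrom[1], lost_start = lost[1],
                lost_end = lost[2], dup_chrom = prows$chrom[1],
                dup_start = dup[1], dup_end = dup[2],
                replacing_subgenome = prows$subgenome[1],
                lost_subgenome = rows$subgenome[1],
                lost_genes = rows$gene_id)
  list(copy_map = copy_map, truth = truth)
}

#' Simulate a binned Hi-C contact map with breakpoint spikes
#'
#' Cis contacts follow a distance decay; trans contacts are uniform Poisson
#' at \code{background}, except bin pairs within \code{flank} bins of each
#' planted breakpoint pair, whose mean is multiplied by \code{spike} — the
#' footprint a homeologous exchange leaves in chromatin-contact data.
#'
#' @param annotation a \code{\link{genome_annotation}}.
#' @param breakpoints optional data.frame (\code{chrom1}, \code{pos1},
#'   \code{chrom2}, \code{pos2}) of inter-subgenome breakpoints to spike.
#' @param background mean trans contact count per bin pair.
#' @param spike fold elevation at breakpoints (>= 1).
#' @param flank bins on each side of a breakpoint that receive the spike.
#' @param binsize bin width in bp (default 25 kb).
#' @param cis_scale contact count scale at distance zero.
#' @param seed integer seed.
#' @return A \code{\link{contact_matrix}}.
#' @export
simulate_contacts <- function(annotation, breakpoints = NULL, background = 5,
                              spike = 10, flank = 2, binsize = 25000,
                              cis_scale = 200, seed = 1L) {
  .assert(spike >= 1, "spike must be >= 1")
  set.seed(as.integer(seed) + .SEED_OFFSETS[["contacts"]])
  chroms <- annotation$chromosomes
  bins <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    starts <- seq(0, chroms$length[i] - 1, by = binsize)
    data.frame(chrom = chroms$chrom[i], start = starts,
               end = pmin(starts + binsize, chroms$length[i]),
               stringsAsFactors = FALSE)
  }))
  bins <- data.frame(bin = seq_len(nrow(bins)), bins)
  n <- nrow(bins)
  same <- outer(bins$chrom, bins$chrom, "==")
  d <- abs(outer(bins$start, bins$start, "-")) / binsize
  mu <- matrix(background, n, n)
  mu[same] <- cis_scale / (1 + d[same])
  if (!is.null(breakpoints)) {
    for (i in seq_len(nrow(breakpoints))) {
      b1 <- which(bins$chrom == breakpoints$chrom1[i] &
                    abs(bins$start + binsize / 2 - breakpoints$pos1[i]) <=
                      (flank + 0.5) * binsize)
      b2 <- which(bins$chrom == breakpoints$chrom2[i] &
                    abs(bins$start + binsize / 2 - breakpoints$pos2[i]) <=
                      (flank + 0.5) * binsize)
      mu[b1, b2] <- mu[b1, b2] * spike
      mu[b2, b1] <- mu[b2, b1] * spike
    }
  }
  counts <- matrix(0, n, n)
  ut <- upper.tri(counts, diag = TRUE)
  counts[ut] <- rpois(sum(ut), mu[ut])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(bins, counts)
}
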