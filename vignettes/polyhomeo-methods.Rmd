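---
title: "Subgenome-aware allopolyploid analysis: models and design"
author: "polyhomeo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subgenome-aware allopolyploid analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyhomeo)
```

# The setting

An allopolyploid carries the complete chromosome sets of two parental
species side by side. polyhomeo targets a young allotetraploid of the
*Arabidopsis thaliana* x *A. arenosa* type: 5 + 8 chromosomes (subgenomes
labelled TH and AR), roughly 11.6% sequence divergence between the
subgenomes, a selfing habit (so accessions are effectively homozygous and
each subgenome sits at 2 copies), and a single recent origin (a founder
bottleneck). Four questions drive the package's design:

1. Is either subgenome's half of the transcriptome globally up- or
   down-regulated relative to the other (homeolog expression balance)?
2. Which repetitive loci (45S rDNA arrays above all) have changed copy
   number, and which parent's rRNA genes are actually transcribed
   (nucleolar dominance)?
3. Have segments of one subgenome replaced their homeologous counterparts
   (homeologous exchange, HE), and which genes were thereby lost?
4. Are transposable elements behaving abnormally in the merged genome —
   in particular, how many insertions have jumped between subgenomes, and
   is that more than a neutral null model predicts?

Every analysis is validated against a synthetic data generator with known
ground truth; the acceptance script re-runs those validations end to end.

# Normalization with subgenome-balanced library sizes

The subtle point in allopolyploid expression analysis is the library
size. An allopolyploid library samples reads from ~2x as many expressed
genes as a pure parent's library, so naive per-library CPM halves every
homeolog's apparent expression relative to the parents. The pipeline
therefore works as follows:

* **Cross-mapping filter.** With ~11.6% divergence most reads map to the
  correct subgenome, but a residue does not. Using the pure parental
  panels as controls, each TH-subgenome gene's log2 ratio of mean counts
  (thaliana panel over arenosa panel, pseudo-count 0.5) is computed;
  genes with a ratio below 0 — their signal comes from the wrong species —
  are removed, and mirrored for AR-subgenome genes. The boundary (ratio
  exactly 0) keeps the gene. `filter_cross_mappers()`.
* **TPM** per sample removes gene-length and depth effects
  (`compute_tpm()`).
* **TMM scaling factors**, computed separately per subgenome on the TPM
  table (`tmm_factors()`): the standard trimmed-mean-of-M-values recipe —
  reference sample chosen by upper-quartile proximity to the panel mean,
  genes zero in either sample dropped, 30% M-trim, 5% A-trim,
  inverse-asymptotic-variance weights, factors normalized to geometric
  mean 1. The implementation is in-package so that tests can check it
  against an independent reference implementation.
* **Effective library sizes** (`effective_library_sizes()`): a pure
  ancestor's size is its TPM total over its own subgenome (times its TMM
  factor); an allopolyploid's size is the mean of its two TMM-scaled
  subgenome totals. This is the step that restores comparability between
  a parent's library and the corresponding half of an allopolyploid
  library.
* **log2 CPM with prior count 1** of the TPM values against those sizes
  (`log_cpm()`). Because everything after TPM is depth-free, the whole
  chain is invariant to rescaling any sample's counts (a property the
  test suite asserts exactly).

Downstream analysis units are accession means over replicates. A homeolog
pair enters analysis only if expressed (accession-mean CPM > 1; the prior
makes this a log2 CPM > 0 cutoff) in at least 3 natural allopolyploid
accessions, at least 1 synthetic allopolyploid accession, and in its own
ancestral panel (>= 3 thaliana accessions for the TH member, >= 1 arenosa
accession for the AR member). The published panel sizes differ strongly
between species (15 thaliana vs 4 arenosa accessions), which is why the
two ancestor thresholds differ; a member cannot be required to be
expressed in the *other* species' panel, where its subgenome is absent.
"Expressed" is defined on CPM rather than raw counts so that the cutoff
is depth-independent.

The homeolog log fold change is log2(AR homeolog CPM / TH homeolog CPM)
per accession (replicate-averaged); it is antisymmetric under subgenome
relabelling, and under a null simulation with no subgenome effect its
population mean is statistically indistinguishable from 0 (asserted
within 3 standard errors in the acceptance suite).

## Differential expression

Per gene, a two-sided Wilcoxon rank-sum test compares accession-level
log2 CPM between two panels (e.g. thaliana vs the TH subgenome of the
allopolyploid). The exact null distribution is enumerated when both
groups have at most 8 accessions and the gene has no ties; otherwise the
normal approximation with tie and continuity corrections is used.
P-values are Benjamini–Hochberg adjusted; a gene is a DEG at q < 0.05.
Calibration: on null simulations (15 vs 15 accessions, 2,000 genes, 100
replicates) the mean false-discovery proportion stays consistent with
<= 0.05, and planted 4-fold (|log2 FC| = 2) shifts are recovered with
sensitivity above 0.9 — in practice essentially 1, because a 4-fold shift
dwarfs the ~0.25 log2 accession-to-accession variability the generator
plants.

DEG expression patterns are clustered by average-linkage hierarchical
clustering on a 1 − Pearson distance with the tree cut at k = 3 (the
cluster count used in the target system's published heat maps);
zero-variance genes, for which correlation is undefined, are assigned to
the nearest centroid afterwards. Cluster labels are renumbered by sorted
gene id so the partition is invariant to input row order. Sample
structure is summarized by PCA per subgenome (genes centred, not scaled,
component signs fixed by the largest-loading-positive convention).

# Copy number from relative coverage

Tandem repeat arrays collapse to a single consensus in an assembly, so an
individual's copy number is estimated as

    copies = (mean depth over locus / genome-wide mean depth) x baseline

with baseline 1 for a collapsed consensus (`estimate_copy_number()`). The
genome-wide normalizer is the mean depth, with the median reported
alongside as a robustness diagnostic. The locus itself is excluded from
the normalizer by default: the collapsed consensus is not part of the
single-copy background, and on a small simulated genome a 150-fold locus
would otherwise inflate its own denominator (on a 140-Mb genome the
effect is negligible either way). The estimator is invariant to uniform
depth rescaling, and unbiased on Poisson simulations: mean recovery over
500 replicates at depth 10 is within 1% for planted copy numbers from 1
to 174 (acceptance suite; the locus spans 50 one-kilobase windows on a
500-window background so Monte-Carlo error is well below the tolerance).

When two homeologous consensus loci are compared (TH vs AR 45S rDNA),
only their mutually alignable span should be counted;
`equalize_consensus_regions()` truncates both loci to the best hit's
aligned span and reports both the coordinate span and the gapped
alignment length, which differ when the alignment contains indels.

Nucleolar dominance is called from 45S rRNA expression with a strict
log2 CPM cutoff (default 15, the ceiling of cross-mapping artifacts seen
in pure parents): each subgenome's allele is "expressed" strictly above
the cutoff, giving the four calls both / th_only / ar_only / neither. The
boundary value itself is *not* expressed — the cutoff marks the top of
the noise floor, so a value at the floor is noise.

Flow-cytometry genome sizes use the standard peak-ratio equation
(`flow_2c_content()`, default standard 2C = 1.96 pg, the tomato
standard).

# Homeologous exchange detection

In a selfing allotetraploid an HE leaves a reciprocal footprint: 0 copies
on one subgenome, 4 on the other, over homeologous intervals. The caller
(the detection scheme is this package's own formalization — published
analyses of this kind present the evidence, not an algorithm):

1. **Window states** (`window_copy_states()`): depth ratio r to the
   genome-wide *median* (robust to the aberrant segments themselves):
   r < 0.25 gives state 0, 0.5 <= r <= 1.5 state 2, r > 1.6 state 4;
   ratios between the bands are ambiguous and inherit the majority state
   of their nearest resolved neighbours (ties resolve to the baseline
   state 2).
2. **Segmentation** (`segment_states()`): maximal same-state runs; runs
   shorter than 5 windows are absorbed into a flank if they are aberrant
   (0/4) or are normal gaps splitting two runs of one aberrant state.
   Short *normal* runs elsewhere — chromosome ends in particular — are
   kept: absorbing real 2-copy sequence into an adjacent aberrant segment
   would misplace its breakpoint, a failure mode observed during
   development when an event sat near a chromosome end.
3. **Reciprocity** (`pair_reciprocal_events()`): a 0-segment is projected
   onto the other subgenome through the homeolog partners of the gene
   pairs it contains (gene-anchored projection, not sequence alignment —
   the parental genomes are largely collinear and the homeolog map is the
   natural coordinate system); it pairs with a 4-segment when the
   projected and observed gene sets overlap with Jaccard >= 0.5. A
   0-segment whose homeologous region sits at 2 copies is a plain
   deletion, not an HE.
4. **Orthogonal evidence** (`call_he()`): Hi-C trans-contact enrichment
   around the breakpoints (mean contact over breakpoint-flank bin pairs
   over the chromosome-pair mean; >= 2 passes) or discordant read pairs
   linking the breakpoints (>= 3 pass). When neither evidence source is
   supplied the call rests on coverage reciprocity alone.

Call breakpoints are taken from the lost (0-copy) segment. At realistic
depth the 0-copy side is unambiguous (Poisson mean 0), while the 4-copy
side's edge windows have intrinsically fuzzy ratios (a mean-40 window
reads at or below 1.5x the median about 7% of the time at depth 20), so
the deletion edge is the precise side — it is also the side that defines
which genes are lost. `genes_lost()` returns the genes inside the lost
segment with no homeolog partner inside the replacing segment.

On simulations at depth 20 with one planted event of >= 20 windows,
recall and direction correctness are 1.0 with zero false calls on
event-free genomes and lost-side breakpoint error within one window
(acceptance suite, 50 + 50 replicates). All thresholds (0.25 / 0.5–1.5 /
1.6, min_run 5, Jaccard 0.5, contact 2.0, pairs 3) are exposed as
arguments; none is inferred from published data.

# Transposable-element dynamics

TE insertion calls (presence / absence / missing per accession, the
abstraction a PoPoolationTE2-style pipeline ends in) are merged by
single-linkage within 400 bp for calls of the same family (a gap of
exactly 400 bp merges; different families never merge), with the merged
site at the cluster midpoint; merging is idempotent. Sites are matched
across panels with the same 400-bp tolerance (the matching tolerance is
this package's choice; reusing the merge distance keeps one spatial scale)
and classified shared / unique-to-polyploid / unique-to-ancestor by
whether each panel has at least one present call. Genome loads are median
present-counts per accession; missing calls never count and are excluded
from frequency denominators throughout. Because the ancestors are
diploid-per-genome while the allotetraploid carries two subgenomes,
`pool_4n()` builds a pseudo-tetraploid by pooling four randomly chosen
subgenome profiles (present if any present; missing only if all missing)
for fair load comparisons.

Site-frequency spectra bin each site's present-fraction (over non-missing
calls) into count classes at the panel's modal denominator, excluding
sites with more than 20% missing calls (an explicit package rule — some
missing-data policy is required and this one keeps denominators
comparable). The joint 2-D spectrum across ancestor and polyploid panels
supports both conventions for sites absent from one panel (frequency 0,
the default, or matched-only), since either could be meant in published
joint spectra; marginals equal the 1-D spectra on the same site set by
construction.

Family redundancy and ancestry use alignment-identity rules: families
more than 85% identical over more than 85% of their length collapse to
the longest representative of each connected component; a family's
ancestry is the ancestral genome it hits at more than 80% identity over
more than 80% of its length, with both-pass explicitly *ambiguous* (not
resolved by best hit — the data cannot distinguish the parents there) and
neither-pass unassigned.

## The jump null model

Under equal transposition activity, inter-subgenome jumps in each
direction are proportional to (number of potential source elements) x
(target subgenome size):

    expected fold (AR->TH : TH->AR) = (N_AR x L_TH) / (N_TH x L_AR)

With the annotated counts (66,722 AR vs 33,420 TH transposons) and
subgenome sizes (119 vs 143 Mb) this gives 1.66, i.e. 1.7 at one decimal
— against an observed 1,515 : 496 = 3.05, a three-fold asymmetry and a
1.8-fold excess over the null. `expected_jump_ratio()`,
`observed_jump_ratio()`.

# Gene-set enrichment

Hypergeometric upper tails are summed directly in log space from the
observed overlap upward (log-sum-exp over exact log-binomial terms)
rather than via 1 − CDF, so deep tails keep full relative precision.
`fisher_one_sided()` is the same tail on the equivalent 2x2 table. A full
sweep over every table with universe size N <= 25 agrees with the
distribution-function oracle to < 1e−12 (acceptance suite). The natural
universe for expression-derived gene sets is the set of homeolog pairs
surviving the expression filter.

# The synthetic generator

`synth_params()` fixes the study conditions; all generators are pure
functions of (params, seed), with RNG sub-streams at fixed offsets so
adding one output never perturbs another. What it emulates, and how the
defaults were chosen:

* **Reference** (`generate_reference()`): 5 + 8 chromosomes; genes on a
  fixed spacing grid in consecutive per-chromosome blocks, so homeolog
  rank order is syntenic (a contiguous segment projects to a contiguous
  homeologous segment, as in the largely collinear parents); partners
  share the ancestral gene length.
* **Expression** (`simulate_expression()`): negative-binomial counts
  (dispersion 0.05, a typical biological RNA-seq value), per-pair
  baselines shared by both members (null logFC 0), log-normal accession
  effects (sd 0.25 on log2, modest natural variation), three replicates
  per accession as in the published design. Cross-mapping is modelled at
  the count level as signal *reassignment*: a pure thaliana sample puts
  fraction leak (default 1%) of each gene's signal on the AR partner row
  and keeps 1 − leak (6% in the arenosa direction, reflecting that
  species' higher polymorphism). Reassignment conserves total signal, so
  the `cross_mapping_rate()` estimator recovers the planted fraction
  exactly in expectation. Read-level simulation is deliberately out of
  scope; only the observable effect of cross-mapping is modelled.
* **TE populations** (`simulate_te_populations()`): shared (ancestral)
  sites draw frequencies from Beta(0.5, 0.5); the allopolyploid's
  frequency at a shared site is the frequency among founder_k founder
  genome copies (binomial resampling), default founder_k = 2 — a selfing
  allopolyploid of single origin is founded by very few genome copies,
  and two is the natural minimal choice. Private insertions draw from
  Beta(0.2, 2), skewed to rare as purifying selection predicts. These
  Beta shapes are explicit stand-ins chosen to reproduce the qualitative
  spectra, not inferences about any real population. Jump insertions
  into each subgenome arrive at Poisson rate jump_rate x (source
  families) x (target Mb), the same law the jump null model assumes — so
  the simulation-vs-analytic check in the test suite is a genuine
  recovery test, with the 2:1 family imbalance of the defaults mirroring
  the real annotation imbalance. The generator returns one ancestor
  panel per subgenome (the two parental species are distinct
  populations) plus one polyploid panel spanning both.
* **Coverage** (`simulate_coverage()`): Poisson window depths at
  depth_mean x copies/2, baseline 2 copies; HEs plant reciprocal 0/4
  segments (`he_copy_map()` snaps a gene run and its partners to the
  window grid); an rDNA-like locus of multiplier m is planted as
  copies = 2m so its depth gain over a single-copy consensus is m-fold.
* **Contacts** (`simulate_contacts()`): cis decay ~ 1/(1 + distance),
  uniform Poisson trans background, breakpoint-flank bin pairs multiplied
  by the spike factor; 25-kb bins by default.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real data: read-level artifacts (mapping
bias, duplicates, GC), sequence-level divergence (no sequences are
simulated), linkage and recombination, heterozygosity (copy states 1 and
3 are out of scope by the selfing assumption), tissue-specific expression
beyond planted shifts, and mosaic/somatic HEs. Problem sizes in the
validation runs (e.g. 200-kb chromosomes, 1-kb windows, 2,000 genes for
DE calibration, 500 copy-number replicates) are chosen so each recovery
statistic's Monte-Carlo error sits well inside the tolerance it is tested
against.

# Numerical and degenerate-input conventions

Intervals are 0-based half-open internally; conversions happen only at
the I/O boundary (GFF3 is 1-based inclusive on disk, bedGraph half-open).
Floats are written with 6 significant digits so write-then-read is
stable. Contact triplets are stored upper-triangle and mirrored on read;
conflicting mirror entries are format errors. Boundary semantics follow
each rule's source: the cross-mapping filter removes strictly negative
ratios; tissue-specificity flags |logFC| >= 2 inclusively; the dominance
cutoff and the 80/80 and 85/85 identity rules are strict. Degenerate
inputs fail loudly (all-zero samples, zero standard peaks, empty
universes) or take documented fallback paths (TMM factor 1 when no genes
survive trimming; p = 1 for constant Wilcoxon rows; full-length loci with
a warning when consensus sequences do not align; enrichment evidence
reported as missing when a Hi-C background is empty).

# Limitations

The HE caller assumes homozygous 0/2/4 states and breakpoints resolvable
at window resolution; real heterozygous or mosaic exchanges need a
different model. The cross-mapping filter and leak estimator assume the
pure parental panels are truly pure. TMM assumes most genes are not
differentially expressed between samples; extreme global shifts (e.g. a
full nucleolar-dominance switch affecting rRNA-adjacent signal) violate
that. The jump null model treats all families in a subgenome as equally
active sources and target size as the only insertion-opportunity factor;
it is a neutral yardstick, not a transposition model.
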