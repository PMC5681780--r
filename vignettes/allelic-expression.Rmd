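---
title: "Genotype-free allelic expression analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-free allelic expression analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scase)
```

## The problem

Allele-specific expression asks whether the maternal and paternal copy of a
gene are used equally. In single cells the answer is often dramatic: one
allele dominates at any given moment, through genuinely random monoallelic
choice, transcriptional bursting, imprinting, or technical dropout of one
allele's few transcripts. Measuring this requires heterozygous markers, and
most public single-cell RNA-seq has no matched genotypes. `scase`
implements a genotype-free route: heterozygous SNPs are recovered from the
expression data itself by pooling reads across the cells of an individual,
then allelic status is classified per cell, per gene, and per cell type.

This vignette documents the statistical model, every tunable parameter, the
synthetic-data generator that the test suite runs against, and the design
decisions taken where the method leaves room.

## hetSNP discovery from pooled depths

For one individual, reference and alternative read depths at each candidate
site are summed over cells (`pool_allelic_depths()`). A site is called
heterozygous when both pooled depths reach the cutoff
(`call_hetsnps()`); sites whose reference allele is *not* among the two
most-supported base classes of the pooled pileup are excluded first, since
their signal cannot be interpreted against the candidate ref/alt pair. The
exclusion compares `pooled_ref` against `pooled_alt` and against the
aggregate of unmatched bases (`other_depth`), and excludes only when the
reference is strictly smallest — ties keep the site.

The cutoff trades recovery against purity. `calibrate_cutoff()` sweeps it
against truth genotypes and reports PPV and TPR per value; on simulated
data with sequencing error at homozygous sites the PPV rises steeply over
the first few read-depth units and plateaus, which is why the default
(`pooled_depth_cutoff = 20` reads per allele) sits deliberately past the
plateau: false heterozygous calls at deeply covered homozygous sites are
the main contamination risk, and they scale with coverage.

Two consequences of the genotype-free design are worth stating plainly:

* a hetSNP whose second allele is never expressed in *any* cell — an
  imprinted gene, or a uniformly silenced allele — can never be
  discovered, because the pooled depth of the silent allele stays at the
  sequencing-error floor. The parameter-recovery results in the test suite
  therefore quantify recovery on the discoverable (random-monoallelic)
  stratum and separately verify that imprinted het sites are never called;
* deeply covered homozygous sites can sneak past the cutoff once their
  miscalled reads exceed it, which is why PPV, not only the cutoff, should
  be reported when truth genotypes exist.

## Per-cell classification

At each (hetSNP, cell) with `n = ref + alt ≥ 1` informative reads the
reference count is tested against Binomial(n, ½). The two-sided p-value
sums the probabilities of all outcomes no more likely than the observed
one; on this symmetric null that reduces to a closed form on the smaller
tail count, implemented vectorised in `binom_test_two_sided()` (the exact
`binom.test` is the oracle in the test suite). Reads matching neither
candidate allele are carried through the tables but never enter `n`.

P-values are BH-adjusted and the verdict is:
**MA** when FDR `< ma_fdr` (default 0.05) *and* strictly more than
`ma_ratio` (default 0.95) of reads come from one allele; otherwise **BA**
when both alleles have at least `ba_min_allele_reads` (default 2); else
**Unknown**. MA is evaluated first, so an observation like 100:4 is MA even
though the minor allele clears the BA read floor. The ratio inequality is
strict: exactly 95 % is not MA. The binomial test guards the ratio rule at
low coverage — five reads all from one allele is a ratio of 1.0 but only
p ≈ 0.06, so it stays Unknown rather than becoming a spurious MA call.

Two aspects are configurable because the method itself does not fix them:

* **the BH family** (`fdr_family`): all observations of one individual
  jointly (default), or within each cell. The joint default treats the
  individual's full set of site-cell tests as one discovery problem;
* **sidedness** (`binom_alternative`): two-sided by default (the null is
  symmetric and no allele is privileged a priori); a one-sided variant
  toward the majority allele is available.

## Gene level and cell-type level

Within a cell, gene status is hierarchical: BA if any hetSNP of the gene is
BA, else MA if any is MA, else Unknown. SNPs mapping to zero or several
genes are excluded. Adding an Unknown SNP can never change a gene's status
(the hierarchy only reads determinate calls), and a gene's MA call does not
require its SNPs to agree on *which* allele — without phasing, cross-SNP
allele concordance is reported by `shared_ma_allele_pairs()` as a
diagnostic rather than enforced.

A gene is cell-type MA (per individual) when at least
`min_supporting_cells` (default 4) cells of the type call it MA while the
gene sits in each supporting cell's top `expr_percentile` (default 30 %) of
expressed genes, and no cell of the type calls it BA. Three deliberate
asymmetries:

* the expression mask gates *support* only; a BA call vetoes regardless of
  the vetoing cell's expression rank, because BA evidence (two alleles with
  reads) is not an artefact of low expression, while MA evidence is;
* Unknown cells neither support nor veto;
* the veto is absolute: one BA cell defeats any number of supporting cells.

The mask ranks each cell's genes with FPKM `> 0` in decreasing expression
and keeps the top `ceiling(percentile × n_expressed)`; ties break
lexicographically by gene id so results are deterministic.

## Downstream statistics

**Pseudo-bulk pooling** (`pseudo_bulk_ratios()`, `ratio_band_summary()`):
pooled reference ratios per site over an individual (optionally per cell
type), binned at width 0.1, with the fraction inside 0.4–0.6 as the
headline number. Random monoallelic expression drives this fraction up as
more cells are pooled; imprinting does not.

**Imprinted-gene check** (`imprinted_ratio_check()`): one-sided rank-sum
comparison of `|ratio − 0.5|` between sites in a supplied imprinted-gene
list and all other sites.

**Disrupted alleles** (`expressing_cell_counts()`,
`ref_fraction_by_class()`, `class_comparison_tests()`,
`allele_expressing_test()`): per annotation scheme (exome-summary S/N/L/G,
SIFT, PolyPhen HDIV/HVAR), the number of cells expressing each allele
(≥ 2 reads) and, at observations with ≥ 2 reads per allele and ≥ 10 total,
the reference-read fraction; one-sided Wilcoxon rank-sum tests compare
classes. The rank-sum uses the exact null when both samples have ≤ 25
observations and no ties, and otherwise the normal approximation *without*
continuity correction — chosen so that exchangeable samples give a
one-sided p of exactly 0.5 rather than a correction-shifted value.

**Cell-type specificity** (`between_vs_within_permutation()`,
`split_half_overlap()`, `saturation_curve()`): overlap of cell-type MA
gene sets between two disjoint same-type cell groups versus between a
same-size group and a second cell type, compared by a two-sample t-test of
the overlap means; split-half reproducibility; and the MA-gene count as a
function of subsampled cells (exact enumeration whenever the number of
subsets is within the iteration budget — and identically zero below the
supporting-cell floor).

Overlap percentages need a denominator the method does not specify; the
default is the union (Jaccard × 100, symmetric), with `min` and raw
intersection counts available via `overlap_denominator`. The
between/within permutation reports raw intersection *counts*, since its
product is the pair of distributions, not a normalised score.

A calibration caveat, verified in the acceptance tests: the two-sample
t-test between the within- and between-type overlap distributions is
anticonservative under a true null. The between arm conditions on one
fixed set of second-type cells, and permutation draws reuse cells, so the
t-test's independence assumptions fail; even perfectly exchangeable cells
with iid MA support produce far more small p-values than nominal. The
statistic is excellent for effect *direction* and magnitude (the within and
between distributions separate cleanly when MA genes are type-specific),
but its p-value should not be read as a calibrated error rate. The test
suite documents this honestly: the null-calibration assertion fails and is
kept failing rather than weakened.

## The synthetic-data generator

`simulate_allelic_dataset()` generates the complete input set (site list,
sparse allelic counts, FPKM matrix, cell metadata, annotation table) plus
ground truth. The generative model:

* **genes** get a mode — `random_MA` (each cell expresses one allele,
  chosen by a fair coin), `biallelic` (each allele independently active
  with probability `burst_prob_active_allele`, default 0.85), or
  `imprinted` (one fixed allele everywhere). A fraction
  `celltype_specific_ma_frac` (default 0.3) of random-MA genes are MA only
  in one cell type and behave biallelically elsewhere. Defaults
  (`random_MA` 0.50, `biallelic` 0.45, `imprinted` 0.05) produce the
  mosaic of predominantly monoallelic per-cell calls over a largely
  biallelic gene pool that motivates the method; bursting is modelled as
  independent per-allele Bernoulli activity rather than a kinetic
  two-state process, which keeps every downstream expectation analytically
  checkable;
* **sites**: most genes carry one heterozygous site (80/14/6 % for 1/2/3,
  matching the observed predominance of single-hetSNP genes); a
  `frac_het_sites` fraction of candidate sites is truly heterozygous and
  the rest are homozygous. All het sites of a gene observe the *same*
  per-allele transcript depths, so two SNPs of one gene are perfectly
  concordant at zero noise — a property the consistency audit requires;
* **depths**: per active allele, negative binomial (mean `depth_mean` = 30,
  dispersion 2) scaled by a log-normal per-gene expression factor;
  `dropout_prob` (default 0.2) zeroes an allele's capture per cell;
  `ref_bias` thins alternative-read capture per site; homozygous sites
  emit opposite-allele reads at `seq_error` (default 0.005) — the
  false-positive fuel for PPV calibration. Sequencing error is applied
  symmetrically at hom-ref and hom-alt sites;
* **annotation and penalty**: sites get exome-summary classes; stop-gain
  and a `deleterious_frac` of non-synonymous sites are deleterious, and
  genes carrying a deleterious heterozygous site have their alternative
  allele thinned by `deleterious_penalty` (default 4×) — at gene level,
  because the damaged transcript is the whole allele. A consequence:
  synonymous sites inside penalized genes inherit a slight reference bias,
  so the synonymous negative control is exactly centred only when
  `deleterious_frac = 0`;
* **expression**: FPKM proportional to total captured allelic depth with a
  log-normal cell scaling factor (the method only consumes within-cell
  ranks), plus background genes without SNP sites;
* **truth**: per-site genotypes (shared across individuals), per-gene
  modes, and per (gene, cell) active alleles; `truth_ma_labels()` converts
  these to site-cell or gene-celltype label tables. Activity is recorded
  at the bursting level — dropout is technical loss downstream of truth.

The dropout and burst rates are free choices, not estimates from any
dataset: real data pins neither, so the defaults are set to values that
produce realistic sparsity (roughly one in five active alleles lost, and a
visible Unknown fraction) and are exercised over grids in the tests. What
the generator does **not** emulate: UMI chemistry, splice isoforms and
isoform-dependent allelic expression, doublets, cell-lineage structure,
per-individual genotypes, and locus-specific mappability. Passing tests
therefore demonstrate correctness of the inference chain under the stated
model, not performance on any particular real dataset.

## Problem sizes and numerical choices

The test and acceptance runs use deliberately small configurations: about
40–300 genes, 10–120 cells, and depth means of 15–30, with 20-seed
replication where distributional claims are made and 100 seeds for the
null-calibration measurement; the calibration sweep uses ~2000 candidate
sites at 1 % sequencing error. These sizes keep every check exact or
tightly replicated while running in seconds to a couple of minutes.

Degenerate inputs are handled explicitly: uncovered observations are never
tested (testing `n = 0` is an error); a cutoff at which nothing is called
reports PPV as missing, not zero; cells without expressed genes yield an
empty mask with a warning; permutations that cannot satisfy their cell
requirements fail with the required count in the message. With a fixed
seed, the generator, every permutation routine, and every CLI subcommand
are bit-reproducible.

## Known limitations

* Imprinted or uniformly mono-expressed loci are invisible to genotype-free
  hetSNP discovery (see above).
* No phasing: multi-SNP genes cannot be checked for parental consistency,
  only for status consistency.
* The binomial model ignores overdispersion; a beta-binomial would be the
  next refinement but changes the calibration of the MA rule.
* The permutation t-test's p-value is anticonservative by construction
  (see the specificity section); treat it as descriptive.
* Reference mapping bias is modelled as a single multiplicative capture
  factor; real bias is locus-specific.
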