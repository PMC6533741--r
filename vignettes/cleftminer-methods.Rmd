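---
title: "Methods: candidate-gene enrichment and trio TDT for orofacial clefts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-gene enrichment and trio TDT for orofacial clefts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleftminer)
```

## The scientific problem

Cleft lip with or without cleft palate (CL/P) is one of the most common
congenital malformations. Its etiology mixes many genes of small effect
with environmental exposures, and a recurring question is how the known
candidate genes are jointly regulated. `cleftminer` implements the two
statistical workhorses of that question:

1. **miRNA target-set enrichment.** MicroRNAs repress sets of genes
   post-transcriptionally. If the validated target set of a miRNA contains
   far more CL/P candidate genes than chance predicts, that miRNA is a
   plausible coordinate regulator of the trait. We test this per miRNA
   with a one-sided Fisher's exact test and control the false discovery
   rate across all tested miRNAs, then aggregate significant miRNAs into
   seed families and ask which genes are hit by several distinct families.
2. **Trio-based association.** For parent-offspring trios, the
   transmission disequilibrium test (TDT) compares how often heterozygous
   parents transmit each allele to the affected child. It is immune to
   population stratification, which matters for a trait whose prevalence
   varies several-fold between ancestries.

A curated candidate-gene catalog supplies the foreground set for the
enrichment analyses; the package ships one as a plain-text fixture
(172 genes with loci and syndromic annotations) together with the
published per-miRNA target lists it reproduces in its tests.

## The enrichment model

For a universe of $N$ genes containing $K$ foreground (candidate) genes,
a miRNA with $n$ targets in the universe and $k$ of them in the
foreground is scored by the hypergeometric upper tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeometric}(N, K, n),$$

the one-sided Fisher's exact test of the implied 2×2 table. We test
enrichment only: depletion of candidate genes among a miRNA's targets is
not biologically interpretable here. The tail is evaluated with
`stats::phyper()`, which works in log space and is accurate over the full
range; the test suite checks it against a direct pmf-enumeration oracle
for every valid table up to $N = 60$ and against exact big-integer
rational arithmetic on a random sample.

P-values are adjusted with the Benjamini–Hochberg step-up procedure.
The adjustment family is *all miRNAs tested in the run* — the analysis-level
FDR a practitioner reports — not a genome-wide family. Rows with
$q <$ `fdr_threshold` (default 0.1) are flagged significant. Output is
sorted by $(q, p, \text{miRNA id})$ so ties break deterministically and
table diffs are meaningful.

### Building the target map

Interaction evidence arrives as per-source TSV exports (columns `source`,
`mirna`, `gene`, `validated`). Three design choices deserve explanation
because the upstream databases do not force them:

* **Consensus across prediction sources.** A pair must be predicted by at
  least `min_sources` distinct *prediction* databases (default 2 of 3 —
  a middle ground between the noisy union and the very conservative
  intersection; configurable 1–3, and the choice is recorded in run
  metadata). A source whose records are all `validated = TRUE` (a
  miRTarbase-style export) is treated as a validation resource: it never
  adds prediction support.
* **Validation filter.** After the consensus, only pairs with
  experimental support (`validated = TRUE` in any source) are kept. Both
  filters are monotone: raising `min_sources` and adding the validation
  filter can only shrink the pair set, which the property tests assert.
* **Background universe.** The databases do not define one. The default
  universe is the union of all target genes surviving the filters — the
  set about which the data can actually speak. An explicit universe
  (e.g. all protein-coding genes) can be supplied; it must contain every
  target gene, and widening it mechanically deflates every $p$, so the
  universe size is always recorded in metadata.

### Family rollup

miRNAs sharing a seed family tend to share targets, so counting families
rather than miRNAs avoids double-counting near-identical regulators. For
each gene appearing in any significant miRNA's foreground overlap we
count the *distinct known* families among those miRNAs. miRNAs with no
family assignment are tested for enrichment like any other but contribute
no family to the rollup — a gene reached only by unknown-family miRNAs
has a family count of zero. The published table this reproduces lists
genes targeted by at least two families (`min_families = 2`).

`run_mirna_pipeline()` normally rolls up only the significant rows. When
the pipeline is replayed on the packaged target-list fixture there is no
wider universe — every within-fixture test is saturated ($k = n$,
$p = 1$) — so the pipeline accepts `family_scope = "all"` to roll up all
tested miRNAs. That is also the honest description of what the fixture
is: a published list of already-significant miRNAs.

### Generic gene-set enrichment

`geneset_enrichment()` applies the identical statistic to GMT annotation
collections (GO, KEGG, HPO, ...) supplied by the user. Terms whose
foreground overlap falls below `min_overlap` are removed *before* testing
and before the BH family is formed, mirroring the "at least four genes
per pathway" (KEGG-style, `min_overlap = 4`) and "minimum five genes per
category" (HPO-style, `min_overlap = 5`) filters common in DAVID and
WebGestalt runs. GO-hierarchy pruning is out of scope: users pre-filter
their GMT.

`cohen_kappa()` is included for the screening stage of catalog curation
(two raters' include/exclude calls); it returns
$(p_o - p_e)/(1 - p_e)$, defined as 1 when both raters are constant and
identical.

## The trio TDT

Genotypes are read from PLINK-style PED/MAP text. Internally a panel
stores, per SNP and trio, the count of `allele_a` (the lexicographically
smaller allele — the statistic is label-invariant, which the tests verify
by swapping labels). Counting rules, stated explicitly because naive
implementations diverge:

* Only heterozygous parents are informative; each contributes exactly one
  transmission. With $b$ transmissions of `allele_a` and $c$ of
  `allele_b`, the statistic is $\chi^2 = (b-c)^2/(b+c)$ on 1 df.
* A het × het → het trio is phase-ambiguous; the standard resolution
  counts one transmission of each allele, and that is what the
  closed-form counting used here produces.
* Mendelian-inconsistent trios are excluded *at that SNP only* (per-SNP
  exclusion is the standard TDT convention and preserves the rest of the
  trio's data); trios with a missing genotype at a SNP are likewise
  skipped at that SNP.
* Only biallelic SNPs are tested; multiallelic markers are dropped at
  load with a warning. SNPs with $b + c = 0$ are uninformative and
  excluded from scan output.

### Coordinates and gene assignment

Gene intervals come from BED (0-based, half-open); SNP positions from MAP
(1-based). The conversion is done once, explicitly, at import: a SNP at
1-based position $p$ lies in BED interval $[s, e)$ iff
$s \le p - 1 < e$. A configurable symmetric flank (default 0, since the
window rule for "variants in a gene" is a study-level choice) widens
intervals monotonically. Overlap is computed with `GenomicRanges`.

### Tiers and the per-gene summary

Each gene's association signal is its top (minimum-$p$) marker, with no
intra-gene multiplicity correction — SNPs within a gene are usually in
strong linkage disequilibrium, so a per-gene Bonferroni would be badly
conservative. Across genes, the candidate-wise threshold is
$\alpha / G$ with $G$ the number of genes actually tested (e.g.
$0.05/179 = 2.79\times10^{-4}$), below fixed gene-wide
($2.5\times10^{-6}$) and genome-wide ($5\times10^{-8}$) tiers. Each
result is labeled with the strongest tier it reaches.

## What the synthetic generators emulate

The generators exist so that every stage is testable with no downloads;
their defaults *are* the regimes the package's statistical checks run
under, chosen once as realistic for this kind of study:

* **Target universe** (`simulate_target_universe()`): 3000 genes, a
  150-gene foreground (the scale of a curated candidate catalog within a
  validated-interaction universe), 50 miRNAs with target sets of 30–80
  genes (the scale of the published per-miRNA lists), 3 planted miRNAs
  sampling foreground genes at 10:1 odds. Null miRNAs sample uniformly
  without replacement. At odds 1 planted miRNAs are statistically
  indistinguishable from the null (tested); as odds grow their targets
  concentrate in the foreground.
* **Trios** (`simulate_trios()`): 300 trios × 100 SNPs (2000 SNPs for
  calibration runs), minor-allele frequency 0.3, Hardy–Weinberg parents,
  heterozygous parents transmitting `allele_a` with probability $\tau$
  (0.5 = null; per-SNP overrides plant association signals). At these
  sizes a SNP yields ≈ 252 informative transmissions, enough for the
  asymptotic χ² to hold to within half a percentage point of its nominal
  level — the calibration test asserts an empirical type-I rate in
  [0.04, 0.06] at $\alpha = 0.05$ over 2000 SNPs.

What the generators deliberately do **not** model: linkage disequilibrium
between SNPs (loci are independent), ascertainment or population
structure, realistic allele-frequency spectra, genotyping error, and any
correlation structure among miRNA target sets beyond the planted
enrichment. Passing tests therefore demonstrate correctness of the
statistics and plumbing under clean sampling assumptions, not robustness
to the artifacts of real cohort data.

Each generator call consumes a single seeded RNG stream, so identical
specs give byte-identical PED/MAP output (asserted in the tests), and
pipeline metadata records seed, thresholds and universe size — enough to
replay any run exactly.

## Numerical and degenerate-input choices

* Hypergeometric tails via `phyper` (log-space); BH via `p.adjust`. Both
  are wrapped with domain checks that turn silent misuse (counts out of
  range, p-values outside [0, 1]) into classed errors.
* Sorting of every output table is fully specified: enrichment by
  $(q, p, \text{id})$, rollup by (families desc, gene), per-gene TDT by
  $(p, \text{gene})$, top-marker ties by $(p, \chi^2$ desc$,$ snp id$)$.
* Degenerate inputs fail early with classed conditions: empty catalogs,
  interaction tables, pair sets and annotation collections raise
  empty-input errors naming the stage; a foreground disjoint from the
  universe is an error rather than a silent all-null result; an
  uninformative SNP raises its own condition class that scan code
  catches.
* Symbol harmonization is intentionally minimal (trim, uppercase, strip
  internal whitespace; alias collisions resolve to the primary symbol
  with a warning). No live HGNC lookups — catalogs are reproducible
  artifacts.

## Problem sizes used by the checks

The calibration and recovery checks run at: all hypergeometric tables up
to $N = 60$ against the enumeration oracle; 1000 random vectors against
the brute-force BH definition; one 2000-SNP × 300-trio null panel for
type-I calibration; 100 seeded planted-enrichment runs (recovery
threshold ≥ 90% at $q < 0.1$); and 100 seeded distorted-SNP panels
($\tau = 0.75$, 20 SNPs, recovery threshold ≥ 95% for the top-marker
rank). These sizes give each binomial check a standard error well inside
its acceptance margin while keeping the whole suite under a minute.

## Known limitations

* Published FDR columns cannot be reproduced exactly from target lists
  alone: the raw p-values, the exact adjustment family and the authors'
  background universe are not recoverable from a printed table. The
  package reproduces the *structure* — target counts, family rollup,
  thresholds — and validates its statistics against oracles instead.
* The TDT here is the classic biallelic trio test; sibship-based
  variants, X-specific tests and haplotype TDTs are out of scope.
* Foreground choice is explicit configuration. Curated catalogs drift
  (the shipped catalog, its abstract-level summary and the enrichment
  table's title each count slightly differently: 172 vs 177 vs 161
  genes), so no single "right" foreground is hard-coded anywhere.
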