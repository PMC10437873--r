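---
title: "Methods: secreted enzyme potential profiling in geothermal springs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: secreted enzyme potential profiling in geothermal springs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geothermenz)
```

## The question and the quantities

Hot springs fed by deep volatiles host chemolithoautotrophic primary
producers; the heterotrophs living alongside them must hydrolyze polymeric
organic matter outside the cell before they can import it. The mix of
secreted hydrolases a community encodes is therefore a readout of its
carbon sources: lysozymes, lytic transglycosylases, chitinases and
peptidoglycan-directed peptidases indicate consumption of microbial
necromass produced in situ, while xylanases and cellulases indicate
photosynthate (algal or plant) input. This package quantifies that
contrast from metagenome annotations and from fluorometric activity
assays.

The central statistic is the per-sample **necromass fraction**

$$\phi = \frac{A_{\mathrm{cell}}}{A_{\mathrm{cell}} + A_{\mathrm{photo}}},$$

where $A_{\mathrm{cell}}$ sums the normalized abundances of the distinct
families in the chitin and peptidoglycan substrate groups and
$A_{\mathrm{photo}}$ those of the xylan and cellulose groups. $\phi$ is
scale-free: it is invariant to the normalization constant and to any
uniform rescaling of one sample's read depths (tested as a property).

## Annotation model and filters

An annotation is a (gene, scheme, label) triple with tool support and a
secretion flag. Three schemes are handled: CAZy families (GH, GT, PL, CE,
AA, CBM prefixes; dbcan subfamily suffixes such as `GH13_20` are truncated
to the family, since all grouping and visualization operate at family
level), MEROPS peptidase families (catalytic type letter + number;
subfamily letters truncated likewise), and EC numbers.

Filters, all on by default in `filter_annotations()`:

* **Secretion** — only genes with a signal-peptide prediction. Which
  predictor column counts as "secreted" is a user-facing option of
  `read_secretion_flags()`; any value starting `SP`/`Y`/`yes`/`TRUE`/`1`
  is positive.
* **Two-tool support** — CAZy calls must be supported by *both* HMMER and
  DIAMOND. Other callers (eCAMI and the like) are recorded in
  `tool_support` but neither satisfy nor veto the rule. The rule applies
  to the CAZY scheme only: MEROPS and EC labels come from a single
  annotator in this workflow.
* **EC class 3** — only hydrolases (`3.*`) are tabulated for the EC
  scheme.

## Abundance normalization

Read coverage is taken per contig (mean depth); every passing annotated
gene inherits its host contig's depth, and several genes on one contig
each count. Gene→contig resolution uses GFF3 `ID` attributes, with the
prokka naming convention (`<contig>_<n>`) as fallback when a gene is
absent from the map. The matrix entry is

$$a(f, s) = \sum_{g \in f,\,s} d(\mathrm{contig}(g)) \cdot \frac{10^9}{L_s},$$

with $L_s$ the total assembly length of sample $s$. The $10^9$ puts
values on a depth-per-gigabase scale; the choice is arbitrary and is
recorded in the matrix's `normalization` attribute and TSV sidecar. All
reported conclusions use scale-free quantities. A gene carrying several
family labels contributes to each family in full (no fractional
splitting). Whether the original coverage summarization used mean depth
or total mapped bases is not recoverable from the inputs; the per-base
reader path (`read_coverage(format = "per_base")`) aggregates to the mean
and is cross-checked against precomputed means in the tests.

For display, matrices are prevalence-filtered (families present — i.e.
strictly positive — in at least `ceiling(0.75 · n)` samples) and
transformed entrywise as $\log_{10}(x + 0.5)$. Rank statistics never use
the transform: Spearman correlation is computed on untransformed
abundances, and the tests verify the clustering is bit-identical either
way.

## Substrate groups and the dedup convention

The packaged family→group map assigns CAZy and MEROPS families to six
substrate groups (chitin, peptidoglycan, starch/glycogen, trehalose,
xylan, cellulose). Supergroups are fixed: cell = chitin ∪ peptidoglycan,
photosynthate = xylan ∪ cellulose. Some families (GH5, GH7, GH8) appear
under both supergroups; the map states no exclusion rule, so the package
makes a choice and exposes it:

* `dedup = "within_supergroup"` (default): a family counts once per
  supergroup, even if listed in two of its member groups, and counts
  toward *both* supergroups when it is listed under both.
* `dedup = "exclusive"`: shared families are dropped from both
  supergroups.

By default only CAZy families enter the cell/photosynthate score
(peptidoglycan-directed MEROPS families are reported separately);
`schemes = c("CAZY", "MEROPS")` pools them in. Samples whose grouped
abundance is entirely zero get an explicit `NA` fraction rather than
being dropped. Reported fractions are rounded to two decimals with R's
round-half-even, matching the reference tables' formatting.

## Ordination and statistics

* **Spearman + hclust**: pairwise Spearman $\rho$ (average ranks for
  ties) between sample columns or family rows; agglomerative clustering
  on $d = 1 - \rho$ (not $1 - |\rho|$ — anti-correlated profiles should
  separate). The linkage is `complete` by default (configurable:
  average, single). Labels are sorted lexicographically before
  clustering so tied merges resolve independently of input order.
  Constant profiles have undefined correlations and are a hard error
  with a pointer to the prevalence filter, never a silent zero.
* **PCA**: samples as observations, `log10(x + 0.5)`-transformed by
  default, centered, unscaled (the transform and scaling are flags, as
  no single convention is canonical for these profiles). Signs follow a
  deterministic convention (dominant loading positive). Verified against
  a covariance eigendecomposition to 1e−10 and by full reconstruction of
  the centered data.
* **Kruskal-Wallis**: base R's tie-corrected test behind a thin wrapper
  that adds the degenerate-case convention (all observations equal →
  H = 0, p = 1), errors on a single group, and is verified against the
  general rank-statistic form on small tied fixtures. No multiple-testing
  correction is applied across substrates, matching how such assay
  panels are conventionally reported (raw p per enzyme).

## Enzyme assay model

The slurry bookkeeping follows the standard fluorometric protocol:
2.75 g wet sediment in 91 mL buffer, 0.8 mL slurry + 0.2 mL of 200 µM
substrate per well, timepoints 0 / 1.5 / 3 h. Per replicate well the
fluorescence slope (FU/h) is estimated by ordinary least squares over all
timepoints — using the middle timepoint makes the estimate robust to a
single noisy reading, unlike an endpoint difference — then converted:

$$r = \frac{\beta_{\mathrm{FU/h}}}{c_{\mathrm{FU/\mu M}}}
      \cdot \frac{V_{\mathrm{well}}}{m_{\mathrm{well}}}
      \;\;[\mu mol\, g_{wet}^{-1}\, h^{-1}],$$

with $V_{\mathrm{well}} = 1.0$ mL (aliquot + substrate; the 200 µL
withdrawn per timepoint is assumed not to change concentration) and
$m_{\mathrm{well}} = 2.75 \times 0.8 / 91 = 0.0242$ g (sediment volume
neglected — no slurry density is assumed). Additive fluorescence offsets
cancel in the slope; optional substrate-only and slurry-only blanks are
subtracted when provided; negative rates are reported as-is, since rates
indistinguishable from zero are themselves informative. Assays are
defined for sediment samples only and the province comparison refuses
fluids.

## The synthetic generator

`generate_study()` emulates the *shape* of a multi-province spring survey
at annotation level — no reads or sequences are simulated. Per sample:
province drawn from seven defaults whose temperature/pH ranges are the
extremes of the curated site table; fluid/sediment type; contigs with
log-normal lengths (median ≈ 5 kb, ≥ 1.5 kb) and gamma mean depths
(shape 4, rate 0.4, mean 10×; `depth_dist = NULL` gives noise-free
constant depth); Poisson gene counts per contig, genes named
`<contig>_<n>` so both the GFF3 path and the prokka fallback are
exercised.

Planted structure, all validated by tests:

* **Composition** — a grouped CAZy gene is cell-directed with probability
  `cell_vs_photo_ratio` (default 0.7). Grouped genes are drawn from
  supergroup-*exclusive* families: families listed under both
  supergroups would add identically to both sums and pull every fraction
  toward 0.5, making the planted ratio unrecoverable, so they are left
  out of the planting pools. Background (ungrouped) families keep the
  no-group code paths honest.
* **Province signal** — cellulose-exclusive families get a
  multiplicative draw weight (default 3) at volcanic provinces, so
  photosynthate-family ordination separates volcanic from non-volcanic
  sites while cell-family ordination does not.
* **Depauperation** — annotation rows of samples hotter than 80 °C are
  retained with probability `hightemp_depauperation` (default 0.1),
  mirroring the observed scarcity of secreted-enzyme annotations at
  near-boiling sites. The retention uniforms are drawn unconditionally so
  the RNG stream — and hence everything else — is identical across
  depauperation settings, which is what makes the monotonicity property
  testable by coupling.
* **Noise channels** — Bernoulli signal peptides (0.6) and
  HMMER+DIAMOND support (0.85) thin genes independently of group, so the
  post-filter fraction is unbiased for the planted ratio.

Because no quantitative model links province to enzyme composition in
real systems, the planted effect sizes are free parameters chosen once to
be plausibly sized, not estimates. What passing recovery tests show is
that the *pipeline arithmetic* is faithful — unbiased accumulation,
correct normalization, correct dedup — not that real springs behave like
the generator. Real data differ in ways the generator deliberately omits:
compositional correlations among families, depth–length biases, chimeric
contigs, annotation errors correlated between tools, and uneven secretion
prediction quality.

Determinism: a fixed config (including seed) reproduces byte-identical
files; tests assert this on file hashes.

## Problem sizes and numerical conventions

The validation suite runs small studies (3–10 samples, 25–250 contigs,
~150–5,000 genes per sample). Recovery of a planted 0.70 composition is
asserted pooled across six 5,000-gene samples within ±0.02, and exactly
(to 1e−10) on a noise-free study where every gene is a grouped, secreted,
two-tool CAZyme on constant-depth contigs — in that regime the pipeline
sees precisely the planted gene set, so any discrepancy would be an
arithmetic bug. Kruskal-Wallis type-I error is checked at 0.05 ± 0.02
over 1,000 null simulations. Tolerances of 1e−10 to 1e−12 are used where
the check is algebraic identity; stochastic checks use fixed seeds.

Degenerate inputs follow explicit conventions: empty annotation tables
produce empty (not absent) structures; samples with no passing
annotations keep all-zero matrix columns; zero-coverage contigs and
zero-abundance samples are retained; undefined fractions are `NA` with
the sample kept; constant profiles make correlation an error, not 0.

## Known limitations

* The absolute abundance scale (depth per gigabase) is a convention; only
  scale-free quantities are comparable across studies.
* The within-supergroup dedup question (GH5/GH7/GH8) has no
  authoritative answer in the source map; both conventions are
  implemented and the default is stated above.
* The EC scheme is tabulated at the full four-field label; no hierarchy
  folding (e.g. to 3.4) is provided.
* `hydrolysis_rate()` models linear product accumulation; substrate
  depletion, quenching and Michaelis–Menten kinetics are out of scope.
* The generator plants province structure only through family draw
  weights; it cannot emulate taxonomic composition or genuine ecological
  covariance.
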