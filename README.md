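# geothermenz

Post-annotation analysis of **secreted organic-matter-degrading enzyme
potential** in geothermal-spring metagenome assemblies.

Microbial communities in terrestrial hot springs are typically fed by
chemolithoautotrophic primary production rather than by surface
photosynthesis. One way to see what the heterotrophs in such a system
actually eat is to profile their *extracellular* hydrolytic enzymes:
carbohydrate-active enzymes (CAZymes, families GH/GT/PL/CE/AA/CBM),
peptidases (MEROPS families) and EC class-3 hydrolases, restricted to
genes predicted to carry a signal peptide. Enzymes that attack
peptidoglycan and chitin point to dead microbial cell material
(**necromass**) as the substrate; xylanases and cellulases point to
algal/plant **photosynthate**.

`geothermenz` implements that workflow as a tested R package:

1. **IO** — readers for dbcan-style CAZyme overview tables, DRAM-style
   peptidase/EC tables, signal-peptide summaries, GFF3 gene maps, contig
   coverage (summary or `samtools depth` per-base dialect), assembly
   statistics and site metadata.
2. **Filtering** — keep annotations that are secreted and (for CAZymes)
   supported by both HMMER and DIAMOND; restrict EC numbers to class 3.
3. **Abundance** — family × sample matrices where each passing gene
   contributes its host contig's mean read depth, normalized by total
   assembly length:
   `a(f, s) = Σ_{g ∈ f, s} depth(contig(g)) × 10⁹ / L(s)`
   (depth per gigabase), plus a 75% prevalence filter and the
   `log10(x + 0.5)` display transform.
4. **Substrate scoring** — map families to substrate groups (chitin,
   peptidoglycan, starch/glycogen, trehalose, xylan, cellulose), sum the
   *cell* supergroup (chitin ∪ peptidoglycan) against *photosynthate*
   (xylan ∪ cellulose), and report the necromass fraction
   `cell / (cell + photosynthate)` per sample.
5. **Ordination & statistics** — Spearman correlation matrices,
   hierarchical clustering on `d = 1 − ρ`, PCA of grouped profiles,
   Kruskal-Wallis comparisons across geological provinces.
6. **Enzyme assays** — convert fluorometric plate time series
   (MUB-/AMC-linked substrates, timepoints 0 / 1.5 / 3 h) into potential
   hydrolysis rates in µmol g_wet⁻¹ h⁻¹ via a standard curve and the
   slurry bookkeeping (2.75 g sediment in 91 mL buffer, 0.8 mL + 0.2 mL
   per well).
7. **Synthetic studies** — `generate_study()` writes a complete fake
   study (all the file dialects above) with *planted* structure: a known
   cell:photosynthate gene composition, cellulose enrichment at volcanic
   provinces, and annotation depauperation above 80 °C, so every stage
   can be validated against ground truth.

The package also ships curated reference tables for the 63 surveyed
springs (site metadata; per-assembly cell/photosynthate sums; per-class
family counts) under `inst/extdata/`.

## Worked example

```r
library(geothermenz)

cfg <- simulation_config(n_sites = 4, seed = 7)   # planted cell:photo = 0.7
res <- run_pipeline(cfg, "demo_out")
res$scores
#> substrate_scores: 4 samples
#>   sample_id cell_abundance photo_abundance                       province
#> 1    SYN04S         490182          340080 Costa Rica active volcanic arc
#> 2    SYN02S         772758          509656           Cordillera Talamanca
#> 3    SYN03F         903971          529290 Costa Rica active volcanic arc
#> 4    SYN01F         687236          260020       Costa Rica outer forearc
#>   sample_type temperature   pH necromass_fraction
#> 1    sediment        35.3 1.27             0.5904
#> 2    sediment        41.6 6.80             0.6026
#> 3       fluid        31.2 3.29             0.6307
#> 4       fluid        30.1 9.26             0.7255
```

The `necromass_fraction` column is the share of grouped secreted-enzyme
abundance directed at microbial cell walls; at this small scale (~150
genes per sample) the per-sample fractions scatter around the planted
0.7 composition, and `res$truth$samples$true_necromass_fraction` holds
the exact planted values (0.718, 0.615, 0.701, 0.666) for comparison.
`demo_out/` contains the abundance matrices (TSV + JSON sidecars), the
score table, a Newick sample dendrogram, PCA scores, `report.md` and a
`manifest.json` with input checksums.

Assay rates invert the plate model:

```r
cal <- calibration(slope = 100, intercept = 400)  # FU per uM
plates <- generate_assay_plate(c(NAG = 0.02, BG = 0.005), cal,
                               noise_sd = 2, seed = 7)
hydrolysis_rate(plates$NAG, cal)
#> SYN01S / NAG: 0.01959 umol g_wet^-1 h^-1 (replicates: 0.0191, 0.02007)
```

And the curated survey tables reproduce their published summaries:

```r
summary(reference_substrate_scores())
#> 100 samples; totals cell 521794.33 / photosynthate 227434.94
#> 20 samples with necromass fraction < 0.50
#> 43 samples with photosynthate share > 0.30 (33 sediments)
```

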