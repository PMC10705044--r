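# granulefate

Analysis tools for pharmaceutical-exposure experiments in aerobic granular
sludge (AGS) sequencing batch reactors (SBRs). The package is aimed at
environmental engineers and microbial ecologists who dose a reactor with
trace organic contaminants (here diclofenac, erythromycin and gemfibrozil),
track their fate chemically, and ask which members of the granule
microbiome are *active* while it happens.

Three analysis layers are implemented, plus a seeded synthetic-data
generator with known ground truth that drives end-to-end testing:

1. **Pharmaceutical quantification and mass balance.** Peak areas are
   converted to concentrations via an ordinary least-squares calibration
   curve, corrected for solid-phase-extraction losses using spike-recovery
   triplets,

       Recovery = (C_prespike − C_unspiked) / (C_postspike − C_unspiked),

   and per-timepoint percent removal follows the concentration mass
   balance `100 (C_in − C_eff)/C_in` (negative during desorption: effluent
   at twice influent gives −100 %).

2. **Suspect screening of degradation products.** Mass-spectral peaks are
   screened against a compound database (parents plus literature
   transformation products with chemical formulas): a peak is reported
   when its mass error against the theoretical [M+H]⁺ m/z is **< 5 ppm**
   and its signal-to-noise ratio is **≥ 10**. Relative levels are tracked
   via corrected peak areas,

       aqueous: area × CF / area_100        solid: area / (area_100 × dry weight)

   where `area_100` is the same-run 100 µg/L parent standard and `CF` the
   SPE concentration factor (100 mL → 1 mL ⇒ 100).

3. **Active-community analysis.** Paired rRNA gene (DNA) and transcript
   (cDNA) ZOTU count matrices are rarefied over repeated trials (default
   100); per trial each taxon's transcript:gene ratio is the ratio of
   rarefied relative abundances, with *phantom* taxa (reads in cDNA, none
   in DNA) set to 100. Taxa with an across-trial mean ratio ≥ 1 form the
   active community; their unrarefied DNA reads give active relative
   abundances, aggregated to family level. Shifts between timepoints use
   the bounded response ratio `(b − a)/(b + a)` in [−1, 1] (|r| ≤ 0.5
   neutral), over active ZOTUs with > 0.1 % abundance at either timepoint,
   and environmental vectors (effluent drug concentrations) are fitted
   onto ordination coordinates with a permutation test.

## Worked example

```r
library(granulefate)

average_mass("C37H67NO13")        # 733.937  (erythromycin, g/mol)
compute_recovery(140, 45, 145)$recovery   # 0.95
removal_percent(150, 300)         # -100  (desorption: effluent = 2x influent)

cfg <- pipeline_config(
  simulation = list(n_zotus = 60, n_samples_per_reactor = 4,
                    depth_dna = 4000, depth_cdna = 4000),
  seed = 42, n_trials = 25, n_perm = 199, outdir = file.path(tempdir(), "demo"))
res <- run_pipeline(cfg)

subset(res$report$removal, analyte == "DCF" & reactor == "test")[1:6, ]
#>  day influent_conc effluent_conc removal_percent
#>    0           167          71.0           57.39
#>    5           142          64.6           54.44
#>    9           131          77.4           41.15
#>   13           151         359.0         -137.64
#>   18           155         308.4          -99.25
#>   23           160         291.8          -82.06

res$report$response_summary
#>   category n_zotus
#> 1 negative       3
#> 2  neutral       7
#> 3 positive       2

res$vector_fits
#>   variable r_squared p_value axis1  axis2
#> 1      DCF     0.836    0.01 0.912 -0.409
#> 2      ERY     0.802    0.04 0.883 -0.469
#> 3      GEM     0.868    0.03 0.909 -0.416
```

The removal column shows the simulated scenario being recovered from the
synthetic raw data: partial removal (~40–60 % for diclofenac) during the
first 12 days, strongly negative removal while retained drug desorbs
(days 12–23), then near-zero removal. The response summary partitions the
filtered active ZOTUs between two timepoints, and the vector fits report
how strongly effluent drug concentrations align with the community
ordination (r², permutation p).

Every table is also written as CSV under `outdir`, together with
`manifest.json` recording parameters, seed and an MD5 hash of each file;
rerunning with the same configuration reproduces identical hashes.

## Acceptance script

`scripts/acceptance.R` recomputes the package's reference quantities from
scratch — the phantom-taxon ratio assigned in a paired rarefaction trial,
and the two response-ratio extremes (appearance and disappearance,
verified against a 10,000-pair brute-force sweep) — and writes them as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
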