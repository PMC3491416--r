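# deltadnase

Quantitative analysis of chromatin accessibility change upon nuclear
receptor activation, from per-base DNase I cleavage profiles.

When a hormone-activated transcription factor such as the androgen
receptor (AR) engages the genome, DNase-seq sees it at two scales:
regions of open chromatin (DNase I hypersensitive sites, DHS) gain or
lose cleavage, and the bound protein leaves a base-pair-scale footprint
of protected DNA inside its recognition motif. `deltadnase` implements
the complete analysis chain for a replicated two-condition
(untreated vs. hormone-induced) experiment, for computational biologists
who want each stage as a tested, reusable R function:

* **DHS peak calling** — Gaussian-kernel cut density; threshold at the
  P < 0.05 upper tail of a maximum-likelihood gamma fit to the positive
  signal (`kde_signal()`, `gamma_threshold()`, `call_peaks()`).
* **Differential accessibility (ΔDNase)** — union DHS regions tiled
  with overlapping 300-bp windows (10 % edge rule, exact-coverage
  adjustment), replicate tag counting with a < 5-read filter, an exact
  negative-binomial test per window (trimmed-M library normalization;
  common dispersion by conditional maximum likelihood; two-sided
  conditional p = sum of split probabilities no more likely than the
  observed split), and merging into strict (FDR < 0.05) and loose
  (raw p < 0.05) increase/decrease region sets
  (`tile_regions()`, `count_and_filter()`, `nb_exact_test()`,
  `classify_and_merge()`, `normalized_differential_score()`).
* **Expression coupling** — the same exact test at gene level
  (`de_genes()`, `rpkm()`), then two permutation tests: nearest genes
  of differential regions vs. DE genes (100,000 permutations) and DE
  genes with a differential region within 20 kb (1,000 permutations)
  (`nearest_gene()`, `permutation_enrichment()`,
  `reverse_association()`).
* **Motif analysis** — first-order log-likelihood PWM scanning with a
  90th-percentile score threshold and strand resolution
  (`scan_sequence()`), and relative motif enrichment between region
  sets (`relative_enrichment()`).
* **Footprint clustering** — 31-bp per-site cut vectors, k-means
  repeated 100 times, cross-run stability as the distribution of
  optimally matched center correlations, Mann–Whitney comparison
  between conditions, and stability-guided choice of k
  (`footprint_matrix()`, `kmeans_stability()`, `compare_stability()`,
  `select_k()`).

A first-class synthetic-data module (`build_scenario()`,
`simulate_cuts()`, `simulate_sequence()`, `simulate_expression()`)
generates replicate profiles with background and DHS-elevated
negative-binomial rates, region-level biological replicate variability,
planted condition-specific accessibility increases, planted motif
instances carrying three footprint-protection shapes (left half-site,
right half-site, full site with a central spike), and expression counts
whose DE genes sit near the planted increases — so the entire pipeline
is exercised and calibrated without any external data. See the methods
vignette (`vignettes/differential-accessibility.Rmd`) for the model,
assumptions and design decisions.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
packaged 2-Mb scenario (500 DHS, 50 planted fold-3 increases, 600 motif
sites, 200 genes with 40 DE) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_call_peaks.R
Rscript analysis/03_delta_dnase.R
Rscript analysis/04_expression.R
Rscript analysis/05_association.R
Rscript analysis/06_motif_scan.R
Rscript analysis/07_footprints.R
```

Output from a run with the default seed:

```
untreated: threshold 0.532, 501 peaks; truth recall 100.0%, precision 100.0%
induced: threshold 0.646, 499 peaks; truth recall 99.0%, precision 100.0%

500 union regions -> 1064 windows
common dispersion: 0.1042
<delta_region_sets> strict increase 48, loose increase 61, strict decrease 3, loose decrease 18
loose recall of planted increases: 100.0%

41 DE genes at FDR < 0.05 (39 up, 2 down)
recall of planted DE genes: 97.5%

forward test: observed 32 DE genes among nearest genes (null mean 11.7) -> p_enrich = 1e-05
reverse test: 39 of 39 upregulated genes have an increase within 20 kb (null mean 34.0) -> p_enrich = 0.003

planted-site recovery: 99.2%

  untreated stability: median 0.471, mean 0.475
  induced stability: median 1.000, mean 0.982
stability comparison: induced side higher, Mann-Whitney p = 0
recommended k = 3
```

Reading the numbers: peak calling recovers essentially all planted DHS
in both conditions; the window test estimates the planted replicate
dispersion (0.1) and calls increases almost exclusively — the handful
of decrease regions is within the false-positive budget of the
thresholds, reproducing the strong one-sidedness expected when receptor
activation only opens chromatin. DE genes are recovered and are
significantly associated with the differential regions in both test
directions. At base-pair resolution, clustering the induced-condition
footprint vectors is highly reproducible (matched-center correlations
near 1), collapses onto k = 3 — the two half-site protections and the
full-site dimer — and is significantly less stable in untreated cells,
where the motif carries no footprint.

The same analysis can be driven in one call:

```r
library(deltadnase)
res <- run_pipeline(default_config(seed = 1, out_dir = "results/pipeline"))
res$summary$n_delta
```

Reruns with the same seed are byte-identical.

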