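---
title: "Quantifying chromatin accessibility change and receptor footprints from DNase-seq"
author: "deltadnase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin accessibility change and receptor footprints from DNase-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltadnase)
```

## The scientific problem

A ligand-activated nuclear receptor such as the androgen receptor (AR)
reshapes chromatin when hormone arrives: regions of open chromatin —
DNase I hypersensitive sites (DHS) — gain or lose accessibility, and the
bound receptor leaves a base-pair-scale "footprint" of protected DNA
inside its recognition motif. DNase-seq measures all of this in one
assay: the 5' ends of sequenced DNase I cleavage fragments give a
per-base cut-count profile whose local density reflects accessibility
and whose fine structure reveals protein-DNA contact.

`deltadnase` implements the full quantitative analysis chain for a
two-condition (untreated vs. hormone-induced) DNase-seq experiment with
replicates:

1. **Peak calling** — smooth cuts into a continuous signal, call DHS
   peaks above a gamma-tail threshold;
2. **Differential accessibility** — tile the union DHS space with
   overlapping 300-bp windows, test replicate tag counts with an exact
   negative-binomial (NB) test, merge significant windows into
   increase/decrease regions at a strict (FDR < 0.05) and a loose
   (raw p < 0.05) threshold;
3. **Expression coupling** — call differentially expressed (DE) genes
   from mRNA tag counts with the same exact test and relate them to
   differential regions by two permutation tests;
4. **Motif analysis** — scan sequence with a first-order log-likelihood
   PWM scanner at a 90th-percentile score threshold and compute relative
   motif enrichment between region sets;
5. **Footprint clustering** — extract 31-bp per-site cut vectors,
   cluster them with k-means repeated 100 times, and quantify cluster
   reproducibility by the distribution of optimally matched center
   correlations across run pairs.

A synthetic-data module generates replicate cut profiles, sequence, gene
models and expression counts with all of this structure planted, so every
stage is testable end to end without any external data.

## The statistical core

### Window testing

Windows are 300 bp at a default 150-bp stride. Regions shorter than the
window are expanded to 300 bp (centered); longer regions get
`n = floor((len-300)/150)+1` stride-150 windows when that discards fewer
than 10% of the bases on each edge, otherwise one extra window with the
stride recomputed (floored, last window pinned to the region end) so the
windows cover the region exactly. Windows with fewer than five tags
total across all replicates are dropped.

The differential test conditions on the total count of each window: with
per-group library-size-adjusted totals \(t_1, t_2\) from \(n_1, n_2\)
replicates and common dispersion \(\phi\), the null conditional
distribution of the split \(t_1 \mid t_1+t_2\) is free of the window
mean, and the two-sided p-value sums the probabilities of all splits no
more likely than the observed one. The common dispersion is the
maximizer of the conditional log-likelihood given within-group totals,
computed on counts linearly scaled to the geometric-mean effective
library size (a simpler equalization than iterative quantile
adjustment; with the near-equal effective sizes produced by
normalization the difference is negligible, and the estimate recovers a
planted dispersion of 0.1 to three decimals in the test suite).

Effective library sizes come from trimmed-M-value normalization. We use
the **median** of the intensity-trimmed M-values rather than the
classical precision-weighted trimmed mean: at the scale of a small
simulated genome, ~12% of windows carry a strong one-directional true
change, and symmetric trimming then removes unequal tail masses of the
*unchanged* windows' M distribution, biasing the trimmed mean by a few
percent — enough, at count depths of ~100 per window, to call systematic
spurious decreases. The median stays anchored on the unchanged majority.
The classical estimator remains available (`tmm_factors(method =
"mean")`).

P-values are Benjamini–Hochberg adjusted; because BH never lowers a
p-value, the strict (FDR) region sets are provably nested inside the
loose (raw p) sets. Significant windows sharing a direction are merged
when overlapping or book-ended; a merged region inherits its smallest
window p-value.

One property of the exact test worth knowing: its p-values are discrete
(the conditional support at a window total of ~120 has ~120 atoms, with
a sizable atom at exactly 1 from modal splits), so the null p
distribution is sub-uniform — type-I error at p < 0.05 is ~0.044, and
the Kolmogorov–Smirnov distance from uniform is ~0.06. The reference
count-based exact test in wide use behaves identically on the same
data; this is intrinsic to discrete exact tests, not an artifact.

### Peak calling

The signal is a Gaussian kernel density (default bandwidth 60 bp,
kernel mass 1 so signal integrates to the cut count) evaluated at every
base. The peak threshold fits a gamma distribution to the positive
signal values by maximum likelihood (digamma Newton iteration on the
shape) and takes the upper-tail quantile at P < 0.05; peaks are maximal
runs above threshold, merged across gaps below 50 bp. The gamma
approximation is good when the background is dense enough that each
base's signal averages several cuts (per-base exceedance 0.041–0.045 at
background rates ≥ 0.05 cuts/bp in calibration simulations); in very
sparse backgrounds the smoothed marginal is a mixture of isolated kernel
bumps and near-zero mass with a lighter-than-gamma tail, and the
threshold becomes conservative. For peak detection this errs in the safe
direction (DHS signal sits far above either threshold).

### Permutation association

Differential regions are mapped to their nearest gene (region midpoint
to TSS; ties to the lexicographically smaller gene id) and the overlap
of those genes with the DE set is compared against 100,000 draws of
equally many genes from the universe. The reverse test asks how many DE
genes have a differential region within 20 kb of the (isoform-merged)
gene span, against 1,000 such draws. Both one-sided p-values use the
(+1)/(N+1) correction and are never exactly zero. In small universes the
overlap statistic is coarse and the permutation p is visibly discrete —
the test suite verifies the empirical null against the hypergeometric
law exactly in that regime.

### Motif scanning

The scanner scores every window of PWM width on both strands:
log-likelihood of the PWM minus the log-likelihood of the window under a
first-order (dinucleotide) background, the first base scored against the
stationary distribution. The background is estimated from the scanned
sequence itself with pseudocount 1, using circular dinucleotide counts
symmetrized over strands, with the stationary distribution taken as the
joint's row marginal — this construction makes the background
probability of a window *exactly* equal that of its reverse complement,
so scanning is exactly strand-symmetric. The match threshold is the
90th percentile of all window scores in the scanned space (restricted
to a mask when one is given — here the union DHS regions); where both
strands pass, the stronger strand is kept (ties to `+`). Windows
containing N are skipped; with a constant score (degenerate PWM) every
window ties and all are kept.

### Footprint stability

Per-site vectors are cut counts over the motif center ± 15 bp (length
31), minus-strand sites reversed. K-means (from random row
initializations; run *r* seeded by `(seed + 1000003 r) mod (2^31-1)`) is
repeated 100 times; for every unordered pair of runs the two center
sets are matched one-to-one by the permutation maximizing total Pearson
correlation (exhaustive over k!, exact for k ≤ 8), and all k matched
correlations are recorded. A tight distribution near 1 means the
cluster structure is reproducibly found; the two conditions'
distributions are compared with a two-sided Mann–Whitney test.

Two methodological choices matter here:

* **Row normalization.** Stability is measured with Pearson correlation,
  which is scale-invariant — so clusters that differ only in overall
  magnitude (replicate depth, region accessibility) are invisible to
  the metric yet perfectly "stable" under it. Clustering raw counts
  therefore lets k-means spend clusters on magnitude splits and makes
  over-clustering look stable. The pipeline clusters row-normalized
  vectors (each site scaled to unit total), aligning the clustering
  space with the similarity metric; `kmeans_stability()` still defaults
  to raw counts, with `row_normalize = TRUE` as the analysis choice.
* **Choosing k and reporting centers.** `select_k()` recommends the k
  with the highest *mean* matched correlation: when k exceeds the number
  of real patterns, most run pairs still reproduce the real centers
  (median stays ≈ 1) but the surplus centers split clusters
  inconsistently, creating a low-correlation tail that only the mean
  registers. Reported centers come from the *consensus run* — the
  restart whose centers correlate best with all other restarts — rather
  than an arbitrary first run, which can be an outlier local optimum.
  Zero-variance centers are assigned correlation 0 by convention.

## What the generator emulates — and what it does not

`build_scenario()` lays out a 2-Mb chromosome with 500 non-overlapping
DHS (widths 300–700 bp) on a background of 0.01 cuts/bp/replicate, with
a DHS rate multiplier of 32 (≈ 0.32 cuts/bp, i.e. ~100 tags per 300-bp
window per replicate and ~30 pooled cuts per 31-bp footprint vector over
three replicates). Fifty DHS carry a fold-3 accessibility increase in
the induced condition; 600 motif sites (200 per footprint template, up
to two per bound DHS) sit inside a minority of DHS; 200 genes include 40
DE genes (fold 4) placed with their TSS within 2 kb of distinct planted
increases, which makes the region–gene association true by
construction. Defaults are three replicates per condition; unbalanced
designs (e.g. 3+2 after dropping a discordant replicate) are supported
through `n_rep`.

Noise has three layers. Per-base counts are negative binomial
(dispersion 0.1; 0 gives Poisson). Each DHS additionally receives an
independent mean-1 gamma factor per replicate (`phi_region = 0.1`)
modelling biological variability of region accessibility — this is what
makes *window* tag counts overdispersed across replicates (independent
per-base noise alone averages out over 300 bp to near-Poisson window
sums, which no real replicated DNase-seq data shows). The estimated
common dispersion on the default scenario is ≈ 0.10, matching the
region-level dispersion by design.

Footprint protection is **mass-conserving**: the length-31 template
(protection multiplier 0.15 over the protected stretches; left half,
mirrored right half, or full site with an exposed 3-bp central spike) is
rescaled to mean 1 before being applied, so cleavage displaced from
protected bases accumulates on the exposed bases of the same site and
binding does not change the site's total cut rate. This mirrors the
observed biology (cuts pile up beside a bound factor) and keeps the
window-level test neutral at bound sites; because the rescaling is
affine, correlations with the templates are unchanged. Protection is
applied only in the induced condition, so the untreated condition
provides the flat-profile contrast for the stability comparison.

The generator does not emulate: read-level artifacts (mappability,
repeats, PCR duplicates), fragment-length structure, sequence-bias of
DNase I cleavage, multiple chromosomes, isoform complexity, or trans
effects linking expression to accessibility other than the planted
DE placement. Passing tests therefore demonstrate that the analysis
machinery is correct and calibrated under the stated stochastic model —
not that it is robust to every artifact of real libraries.

## Problem sizes and numerical choices

The packaged scenario (2 Mb, 500 DHS, ~1,060 windows, 600 sites, 200
genes) runs the full pipeline in well under a minute and was chosen so
repeated end-to-end runs, calibration simulations (20,000 null windows;
1-Mb background tracks) and 100-restart clustering all remain
interactive. Other numerical conventions: all coordinates are 0-based
half-open everywhere (BED convention); unstranded features are treated
as plus-strand for sequence extraction; the gamma fit refuses degenerate
all-equal signal; `scan_sequence` floors zero PWM probabilities at
1e-12 inside the log; exact-test splits whose every outcome is no more
likely than the observed one return p exactly 1; and all stochastic
stages derive child seeds from one user seed, making every result table
byte-reproducible (`run_pipeline()` reruns are diff-identical).

Gene-relative annotation uses a five-way partition by region midpoint
with fixed precedence: promoter (2 kb upstream of a TSS, strand-aware),
then first exon/intron, then other intragenic, then 3'-proximal (2 kb
downstream of the gene end), then intergenic.

## Known limitations

* The exact test's discreteness makes its null p-values sub-uniform
  (see above); downstream FDR control is conservative, not broken.
* The gamma threshold is conservative on sparse backgrounds.
* The relative motif-enrichment score contrasts match frequencies in
  differential vs. unchanged regions; in the synthetic scenario the
  motif is planted only in bound DHS, so the score is informative only
  when those coincide with differential regions — the headline
  magnitudes reported for real data (e.g. AR ≈ 4.8 on tens of thousands
  of regions) are not reproducible at this scale and are not targets of
  the test suite.
* Tagwise/trended dispersion and covariate designs are out of scope; a
  single common dispersion is estimated.
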