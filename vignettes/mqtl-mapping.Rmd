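---
title: "Methods: metabolite QTL mapping in a haploid yeast cross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolite QTL mapping in a haploid yeast cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlmap)
```

# The problem and the model

`mqtlmap` maps metabolite abundance variation in a haploid two-parent
yeast cross (the laboratory strain BY and the vineyard strain RM). Each
haploid segregant carries one parental allele at every locus, so a
single-marker scan reduces to a two-group comparison at each of the
~2,820 mapped SNP markers. The trait for compound $c$ and segregant $s$
is the day-normalized log abundance ratio

$$ y_{cs} = \log_2 \frac{\bar{x}_{cs}}{\bar{r}_{c,d(s)}}, $$

where $\bar{x}_{cs}$ is the OD-normalized mean over biological replicates
and $\bar{r}_{c,d}$ is the mean over the same-day RM reference runs. The
normal-model LOD at a marker is

$$ \mathrm{LOD} = \frac{n}{2}\,\log_{10}\frac{RSS_0}{RSS_1}, $$

with $RSS_0$ the residual sum of squares about the grand mean and $RSS_1$
about the two genotype-class means; the nonparametric alternative is the
ties-corrected Kruskal–Wallis statistic scaled by $1/(2\ln 10)$.
Significance is per-trait: the genome-wide maximum LOD is recorded for
each of 100 permutations of the trait values, and the threshold is the
90th order statistic of those maxima ("top 10%" rule). QTL location
uncertainty is summarized by a Bayesian credible interval: posterior mass
$\propto 10^{\mathrm{LOD}_i}$ over the peak chromosome's markers,
accumulated in decreasing order until 95%, expanded by one flanking
marker per side.

Downstream, peak positions are gridded into 10-kb bins; a bin is a hot
spot when its linkage count exceeds the smallest $k$ with
$P(X \ge k) < 0.05/n_\text{bins}$ for $X \sim$
Poisson($n_\text{linkages}/n_\text{bins}$), and adjacent significant bins
merge. Credible intervals are tested for metabolic-gene enrichment by
relocating the intervals uniformly 10,000 times. Broad-sense
heritability per compound comes from replicate pairs:
$H^2 = (\sigma^2_\text{total} - \sigma^2_\text{within}) /
\sigma^2_\text{total}$, with $\sigma^2_\text{within}$ the mean
per-segregant replicate variance and $\sigma^2_\text{total}$ the variance
of all replicate-level values. Per-QTL variance fractions are sequential
sums of squares (decreasing-LOD order) over the replicate-level values,
and the association between QTL count and $H^2$ is a log-link Poisson
regression.

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `floor` | 32 counts | detection floor; not-detected and sub-floor ion counts are raised to it |
| `min_detect_frac` | 0.25 | compounds detected in fewer than this fraction of biological samples are dropped (inclusive boundary: exactly 25% is kept) |
| `n_perm`, `quantile` | 100, 0.90 | permutation count and the order-statistic quantile for per-trait thresholds |
| `prob` | 0.95 | credible-interval posterior mass |
| `bin_size` | 10,000 bp | hot-spot grid; the default yeast layout yields 1,216 bins |
| `fw_alpha` | 0.05 | family-wise level Bonferroni-split across bins |
| `n_perm` (enrichment) | 10,000 | interval relocations for the gene-content null |

The packaged genome layout uses the 16 S. cerevisiae nuclear chromosome
lengths (sacCer3, 12.07 Mb), which reproduce the 1,216-bin grid exactly;
genetic lengths total 4,300 cM so 2,820 uniformly placed markers average
~1.5 cM (~4.3 kb) spacing. Layouts are explicit and replaceable because
the bin count — and therefore the Bonferroni correction — depends on the
assembly.

# What the synthetic generator emulates — and what it does not

`sim_scenario()`/`simulate_cross()` generate: a marker map allocated
proportionally to genetic length; haploid genotypes under a Haldane
(no-interference) meiosis model; phenotypes with planted additive QTLs
(±1 allele coding), per-day batch shifts shared by all samples run that
day, replicate noise calibrated so that the replicate-based $H^2$
estimator recovers `target_h2`, log-normal ion-count scaling around a
base intensity of 10,000 counts, OD scaling, floor censoring at 32
counts, and per-compound detection dropout; same-day RM reference and
parental replicate samples (13 BY / 18 RM by default); and optional
mock-extraction samples with planted media-derived compounds.

Deliberate simplifications, hence what a green test does *not*
establish:

* **Trait distributions are Gaussian on the log scale.** Real metabolite
  log-ratios are heavier-tailed. Permutation thresholds are
  trait-distribution dependent, so the synthetic mean per-trait threshold
  (~3.1 LOD at the full design) sits at the low end of the 3.14–3.58
  per-trait range printed for the real data (mean 3.35). Part of the
  remaining gap is also attributable to the original analysis having run
  scans on an interpolated position grid rather than at markers only.
  We report the honest simulated value rather than inflating noise to
  match.
* **No crossover interference** (Haldane). At ~1.5 cM marker spacing and
  marker-based scans, interference is immaterial for localization.
* **Replicates of a segregant share a day** (two filters from one
  culture), which is what lets the same-day reference ratio cancel the
  batch effect for both replicates. Designs with replicates split across
  days would leave residual day variance inside $H^2$.
* **Detection dropout is random given the compound**, except that counts
  below the floor are always not-detected. Real dropout is
  intensity-driven throughout.

# Numerical and design choices

* **Reference means use quantifiable runs only.** A not-detected
  reference run floored to 32 would shift every log-ratio of its day by
  several log2 units; the day reference mean therefore averages only
  detected reference runs, falling back to floored values when a day has
  none. Likewise $H^2$ uses only segregants with two *quantifiable*
  replicates — floored not-detected values would masquerade as replicate
  disagreement. Scan traits, by contrast, keep floored values: flooring
  is the stated treatment of not-detected measurements.
* **Variance partition on the replicate level.** Per-QTL fractions
  divide by the same replicate-level total variance that defines $H^2$,
  so fractions stack under the $H^2$ bar (and a single QTL explaining
  all genetic variance at $H^2 = 0.5$ recovers a fraction of ~0.5).
  Sequential (decreasing-LOD) attribution keeps the partition
  deterministic and handles collinear peaks; a simultaneous (drop-one)
  variant is available.
* **Threshold = order statistic**, not an interpolated quantile: the
  90th smallest of 100 permuted maxima, reproducible and faithful to
  "top 10% of this set".
* **Poisson tail convention.** The inclusive tail $P(X \ge k)$
  reproduces the metabolite cutoff of 3 linkages per bin exactly. For
  the transcript parameters ($\lambda = 4.151$) the inclusive tail gives
  15 where the original analysis printed 14; an exclusive-tail option
  (`tail = "gt"`) reproduces 14. The default stays inclusive and the
  discrepancy is documented rather than silently matched.
* **Missing genotypes** are imputed from the nearest non-missing flanking
  marker (ties leftmost); at ~1.5 cM spacing this is near-lossless. The
  original analysis does not state its handling; this choice is recorded
  in the run manifest.
* **FDR**: Storey q-values with $\hat\pi_0 = \overline{(p > 0.5)}/0.5$
  at fixed $\lambda = 0.5$, falling back to Benjamini–Hochberg when the
  estimate leaves $(0, 1]$. Stable at the ~100-test scale of a
  metabolome panel.
* **Mode-of-inheritance rules are explicit stand-ins.** The cited
  formulae are not restated in the source; we flag transgression when
  the count of segregants beyond either parental mean by >2 pooled
  parental SDs exceeds the binomial expectation under Gaussian noise
  (FDR 5% across compounds), and directionality when the segregant mean
  lies between the parental means and the fraction inside the closed
  parental interval is significantly above 0.5. Both are isolated behind
  one operation so they can be swapped.
* **Interval relocation null**: intervals relocate independently,
  chromosome drawn proportionally to length among those the interval
  fits, start uniform; a same-chromosome variant is available for
  sensitivity analysis. Empirical p-values use the add-one rule, so
  $p > 0$ always.
* **Hot-spot overlap null** relocates each hot spot whole
  (width-preserving) among genome bins, retaining spatial extent.
* **Noise calibration**: replicate noise is
  $\sigma_e^2 = \mathrm{var}(g)(1 - h^2)/h^2$; same-day references get a
  small technical noise (0.1 log2) so the day anchor does not inflate
  $H^2$ — reference error is shared within a day and invisible to the
  within-replicate variance. With 2 reference runs per day this keeps
  the $H^2$ bias within the ±0.05 recovery tolerance.
* **Config is JSON** (single file mirroring the Methods parameters).
  The preinstalled stack has no YAML parser; JSON keeps the
  round-trip lossless with `jsonlite`.

# Known limitations

* Real-data headline results (52 mQTLs for 34 of 74 compounds, 62% mean
  heritability, 471/904 metabolic genes in intervals) depend on the
  original measurements and annotation coordinates and are not
  reproducible from synthetic data; the package reproduces the *methods*
  and their calibration properties.
* The credible-interval construction is known to under-cover slightly;
  the test suite asserts a ≥85% floor at moderate effect sizes, not
  nominal 95% coverage.
* One peak per chromosome per trait: closely linked QTLs on one
  chromosome merge into a single (wider) interval.
* The scan is marker-based; no pseudomarkers, multi-QTL models, or
  epistasis scans.
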