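---
title: "Dating admixture from ancestry covariance decay"
author: "admixtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating admixture from ancestry covariance decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

When a population forms by the mixing of two diverged sources *A* and *B*,
every genome in it is a mosaic of ancestry tracts. Recombination shortens
these tracts each generation, so the extent of allelic association created
by the mixture ("admixture LD") carries a clock. `admixtime` reads that
clock from unphased genotypes of as little as a single diploid — or
pseudo-haploid — genome.

For individual genotype $g_i$ at SNP $i$, with reference allele frequencies
$p_{Ai}$ and $p_{Bi}$, the genotype likelihood under each source is
binomial, $a_i = P(g_i \mid A)$ and $b_i = P(g_i \mid B)$ (a single-draw
Bernoulli for pseudo-haploid calls). The ancestry fraction $\alpha$ is
first estimated by least squares on the dosage scale,
$\min_\alpha \sum_i (g_i/2 - [\alpha p_{Ai} + (1-\alpha) p_{Bi}])^2$.
Each site then gets the ancestry-informative weight

$$K_i = \frac{a_i - b_i}{\alpha a_i + (1-\alpha) b_i},$$

whose sign says which source better explains the call. For marker pairs a
genetic distance $d$ Morgans apart the binned covariance

$$A(d) = \frac{\sum_{S(d)} (K_1 - \bar K)(K_2 - \bar K)}{|S(d)|}$$

decays as $e^{-(t+1)d}$ after a single pulse of admixture $t$ generations
ago. The $+1$ arises because first-generation offspring carry one intact
chromosome from each parent population; tracts only begin to fragment from
the second generation on. We therefore fit $y = A e^{-\lambda d} + c$ by
least squares and report $t = \lambda - 1$.

### Assumptions

* a single instantaneous pulse of two-way admixture (continuous or
  multi-pulse gene flow yields whatever the single-exponential fit gives,
  typically an intermediate date);
* reference allele frequencies correlated with the true ancestral ones —
  the references need not be the actual sources;
* genetic distances (Morgans in `.snp`) accurate at the sub-cM scale;
* no within-source LD at the distances fitted, which is why the fit starts
  at 0.45 cM by default.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `binsize` | 0.001 | Morgans (0.1 cM) | distance resolution of the covariance curve |
| `maxdis` | 1.0 | Morgans | largest pair distance accumulated |
| `lo` | 0.0045 | Morgans | fit start; masks residual background LD below ~0.45 cM |
| `hi` | 1.0 | Morgans | fit end |
| `generation_time` | 28 | years | generations-to-years conversion |
| `method` | `"fft"` | — | autocorrelation path; `"naive"` enumerates pairs |
| `pooling` | `"pooled"` | — | sum numerators and pair counts across individuals before dividing |

The command-line surface (`inst/cli/admixtime`) takes distances in cM;
everything internal is Morgans, converted once at that boundary, which
avoids the classic 100-fold unit mistake.

An estimate is flagged significant when Z > 2 **and** $\lambda$ < 200
generations **and** NRMSD < 0.7, all strict, where NRMSD is the RMS
deviation between empirical and fitted bins normalised by the range of the
fitted values. NRMSD has no absolute interpretation; 0.7 is a conservative
empirical cutoff and fits should still be inspected visually (`plot()` on
the fitted object).

## Numerical choices

* **Decay-rate search.** $\lambda$ is profiled on a deterministic
  multiplicative grid (0.5–500, step 1.02) with the amplitude and affine
  term solved in closed form at each grid point, then refined by
  golden-section search on $\log\lambda$ to a relative tolerance well below
  $10^{-3}$; ties break toward the smaller rate and an optimum at the grid
  edge is flagged `boundary`. No random initialisation anywhere — the
  dating path is fully deterministic.
* **FFT path.** Centered weights are aggregated onto a uniform grid of
  cell width `binsize` per chromosome; distance-lag sums of products and
  pair counts come from autocorrelation of the sum track and the count
  track, with self-pairs removed at lag zero. Lag $\ell$ maps to the bin
  the naive path uses for distance $\ell \cdot \mathrm{binsize}$; two
  markers sharing a grid cell land in the first bin, a discretisation
  difference from pair enumeration bounded by one bin width. On markers
  occupying distinct cells the two paths agree exactly on counts and to
  floating-point accuracy on sums, which the test suite asserts.
* **Frequency clamp.** Reference frequencies are clamped to
  $[10^{-4}, 1-10^{-4}]$ instead of special-casing division by zero;
  markers monomorphic and identical in both references are dropped
  ($K = 0$ there carries no information).
* **Centering.** $\bar K$ is the per-individual genome-wide mean over
  valid markers. Global centering matches the covariance interpretation
  and is stable when large fractions of the genome are missing; per-bin or
  per-chromosome centering would add noise at the sparse end.
* **Jackknife.** Standard errors use the weighted delete-one-chromosome
  jackknife (Busing-style), block weights proportional to the marker pairs
  each chromosome contributes inside the fit range. With equal pair counts
  it reduces to the unweighted delete-one formulas exactly.
* **Multiple individuals.** The default pools numerators and pair counts
  per bin before dividing; averaging per-individual curves is available as
  `pooling = "mean"`. Pooling weights individuals by the data they
  contribute, which is the behaviour wanted when coverage varies wildly,
  and is the sense in which per-individual likelihoods are summed.
* **Degenerate inputs.** Empty curves, too few populated bins, flat fitted
  curves, and delete-one failures produce structured errors (or dropped
  blocks with a warning) rather than NaNs.

## The simulator

`make_source_panels()` draws ancestral frequencies uniform on
$[0.05, 0.95]$ and source frequencies from the Balding–Nichols
distribution; the default divergence `fst = 0.15` reproduces the
European–West-African contrast commonly used to validate admixture dating
(the pairwise Hudson $F_{ST}$ between emitted panels matches the parameter,
which the suite checks). `simulate_admixed()` then builds each haploid
chromosome by the copying walk: recombination between neighbouring markers
with probability $1 - e^{-(t+1)g}$ for gap $g$, re-drawing ancestry
Bernoulli($\alpha$) at each event (switches to the same ancestry allowed),
and copying a fresh haplotype drawn without replacement from the chosen
source's pool, replenished per chromosome. Haploids are paired at random
into diploids, and ground-truth tract tables are emitted for every haploid
chromosome. `pseudo_haploidize()` and `mask_missing()` reproduce the two
dominant ancient-DNA degradations.

What the generator deliberately does **not** emulate: within-panel LD
(panel haplotypes are independent draws given the population frequency),
genotyping error beyond missingness, non-uniform genetic maps, sex
chromosomes, and drift after admixture. Passing tests therefore show the
estimator is correct for the pulse-admixture model it targets, not that
real background LD below ~0.45 cM is handled — that is what the `lo`
cutoff is for on real data.

### Validation conditions

The recovery experiments in the test suite use 50,000 markers on 22
uniform chromosomes totalling 35 Morgans, 10 admixed diploids at
$\alpha = 0.2$, and 40 fresh diploid reference individuals per side drawn
from the same Balding–Nichols populations (never the haplotypes the
targets copied from, to avoid overfitting). These sizes keep a full
20-replicate grid cell under a few minutes on one core while leaving the
curve dense enough to date $t$ up to 200 generations; the original
characterisation of this class of methods used ~380,000 markers, so
intervals here are proportionally wider. Copying pools scale with the
admixture time (about $80 + 1.9t$ haplotypes for the majority source)
because every recombination consumes a fresh haplotype.

Two honest edges are worth knowing. At true $t = 200$ the decay rate
concentrates near $\lambda = t + 1 = 201$, so the strict $\lambda < 200$
significance gate cannot fire reliably there even though the date itself
is recovered; the gate is kept exactly as defined. And with a single
target individual at this marker count the jackknife interval is mildly
anticonservative (roughly 90% realised coverage for nominal 95%), which
the test suite reports honestly rather than masking with wider tolerances.

## Known limitations

* Amplitude and $\alpha$ are **not** reliable ancestry-proportion
  estimators (the regression overestimates small minority fractions);
  use dedicated ancestry-modelling tools for proportions.
* Multi-pulse histories are reported as a single intermediate date.
* Sources with $F_{ST}$ below ~0.005 are effectively indistinguishable.
* Dates beyond ~200 generations fail the significance gate by design.
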