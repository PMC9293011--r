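# admixtime

Dates population admixture from genotype data — down to a single diploid
(or pseudo-haploid, ancient-DNA style) genome.

## The problem and the statistic

When two diverged populations mix, each descendant genome is a mosaic of
ancestry tracts that recombination fragments every generation, so the
association between ancestry-informative alleles decays with genetic
distance at a rate set by the time since mixing. `admixtime` measures this
with an *ancestry covariance* curve. Given genotype likelihoods under the
two reference panels, $a_i = P(g_i \mid A)$ and $b_i = P(g_i \mid B)$, and
the least-squares ancestry fraction $\alpha$, each site is scored

$$K_i = \frac{a_i - b_i}{\alpha a_i + (1 - \alpha) b_i},$$

and for all within-chromosome marker pairs a distance $d$ Morgans apart

$$A(d) = \frac{\sum_{S(d)} (K_1 - \bar K)(K_2 - \bar K)}{|S(d)|}
       \;\sim\; e^{-(t+1)\,d}.$$

Fitting $y = Ae^{-\lambda d} + c$ by least squares over 0.45–100 cM
(0.1 cM bins) gives the admixture time $t = \lambda - 1$ generations.
Standard errors come from a weighted leave-one-chromosome-out jackknife,
fit quality from the normalised RMS deviation (NRMSD), and dates convert to
years at 28 years/generation (plus mean sampling age for ancient samples;
BCE via the 1950 convention). Because the statistic works on unphased
genotypes and tolerates heavy missingness and pseudo-haploid calls, it
suits ancient-DNA datasets where haplotype-based clocks fail.

The package also contains the matching haplotype-copying simulator
(synthetic Balding–Nichols source panels, recombination probability
$1 - e^{-(t+1)g}$ per marker gap, pseudo-haploidisation and masking
transforms, ground-truth tract tables), so every accuracy claim can be
verified end to end without downloading any data.

## Worked example

```r
library(admixtime)

panels <- make_source_panels(n_snps = 4000, n_haps = c(30, 60), fst = 0.15,
                             chrom_lengths = rep(1, 6), seed = 1)
sim  <- simulate_admixed(panels[[1]], panels[[2]],
                         admixture_spec(alpha = 0.2, t = 20,
                                        n_individuals = 4, seed = 2))
refA <- allele_frequencies(sample_panel_genotypes(panels[[1]], 25, seed = 3))
refB <- allele_frequencies(sample_panel_genotypes(panels[[2]], 25, seed = 4))

fit <- date_admixture(sim$genotypes, refA, refB)
fit
#> Admixture date from ancestry covariance decay
#>   4 target individual(s), 3920 markers; alpha = 0.237
#>   t = 19.1 +/- 9.3 generations (jackknife), Z = 2.06, NRMSD = 0.635
#>   date: 534 years BP = 1416 CE (generation time 28 y, mean sampling age 0 BP)
#>   significant: yes
```

The truth here is t = 20 generations of 20% `source1` ancestry: the
jackknife interval 19.1 ± 9.3 covers it, the per-run ancestry fraction
(0.237) is close to the simulated 0.2, and the wide interval honestly
reflects the deliberately tiny instance (4,000 markers on 6 chromosomes).
`summary(fit)` adds the fitted coefficients (here $A$ = 0.026,
$\lambda$ = 21.8, $c$ = 0.0005) and the per-chromosome jackknife blocks;
`plot(fit)` draws the binned curve with the fitted decay; `coef`,
`predict`, `residuals` and `simulate` behave as on any fitted model.

Real datasets enter through `read_eigenstrat()` (text EIGENSTRAT
`.geno/.snp/.ind`, genetic positions in Morgans, `9` = missing), with
sampling ages in a two-column side table. A command-line front end is
installed too:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "admixtime", package = "admixtime"))')
$CLI simulate --alpha 0.2 --t 50 --n 10 --seed 7 --out sim
$CLI run --geno data.geno --snp data.snp --ind data.ind \
         --target Admixed --refA French --refB Yoruba --out result
```

`run` writes a summary TSV (t, SE, Z, NRMSD, calendar dates, significance
verdict), the binned curve with fitted values, and per-jackknife-block
estimates, each with full parameter/checksum headers.

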