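---
title: "Genomic prediction from high-frequency marker haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction from high-frequency marker haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploblup)
```

## The problem

Genomic selection in dairy cattle predicts a young bull's genetic merit
from its marker genotypes before any daughter records exist. The usual
approach fits one random effect per SNP. `haploblup` implements the
haplotype alternative: SNPs in strong mutual linkage disequilibrium (LD)
are grouped into blocks, each block is treated as a single multi-allelic
locus, and the *direct genomic value* of animal $i$ is the sum of its
haplotype effects,

$$\mathrm{DGV}_i = \sum_j Z_{ij}\, \hat h_j ,$$

where the $\hat h_j$ come from the random-haplotype-effect linear model

$$y = \mu + Z h + \varepsilon, \qquad
  h_j \sim N(0, \sigma^2_{h_j}), \quad
  \varepsilon \sim N(0, \sigma^2_e),$$

with $y$ the vector of deregressed proofs of the training animals.
Because most haplotype alleles in a population are rare, only
high-frequency haplotypes (carried by more than 25% of animals) are kept
as model terms; this bounds the number of effects at roughly three per
block and keeps the mixed model equations desk-scale.

## Pipeline stages and their parameters

**SNP quality control.** Markers are dropped when more than
`max_missing` (default 0.10) of their calls are missing, then when their
minor allele frequency is not strictly above `min_maf` (default 0.01;
0.05 is the stricter panel). MAF is computed over non-missing calls
only. The two filters commute on the kept set; the report counts the
missingness stage first. The boundary is strict (`maf > min_maf`)
because the subsets are defined by ">" — with the threshold
configurable, the choice only matters for SNPs exactly at the cut.

**LD blocks.** Within each chromosome, $r^2$ is computed for every SNP
pair at most `window_snps` (default 50) apart in map order, using the
two-locus EM haplotype-frequency estimator for unphased genotypes
(double heterozygotes are split between cis and trans phase in
proportion to the current frequency estimates — the estimator PLINK
reports). Pairs with $r^2 \ge$ `r2_threshold` (default 0.8; 0.9 is the
stricter setting) are linked, and blocks are the connected components
with at least two SNPs. Single-linkage components were chosen because
they are simple, deterministic, and monotone: lowering the threshold can
only merge blocks, never split them. Blocks may therefore be
non-contiguous in map order; a `contiguous = TRUE` mode (adjacent pairs
only) is available for sensitivity analysis. The window exists purely
for tractability and can be set to the chromosome length to reproduce an
all-pairs computation.

**Phasing.** Each block is phased by multi-locus EM: the E-step weights
every haplotype pair compatible with an animal's genotype by the product
of the current frequencies; the M-step re-estimates frequencies from
expected counts. The log-likelihood is asserted non-decreasing at every
sweep, convergence is `|Δ log L| < 1e-8` (tunable), initialisation is
uniform over observed-compatible haplotypes, and the default run is
fully deterministic. Missing calls are marginalised by enumerating all
compatible alleles; an animal with every call missing in a block gets
the Hardy–Weinberg population prior as its posterior. Blocks whose
candidate space exceeds `enum_cap` ($2^{20}$ haplotypes) are skipped and
reported. A deterministic EM was preferred over Bayesian
coalescent-informed phasing because it is reproducible and adequate at
the short block lengths LD thresholding produces; this is a known
fidelity gap relative to samplers that borrow strength across blocks.

**Haplotype frequency filter.** "Frequency" is read as *carrier
frequency* — the fraction of individuals whose posterior probability of
carrying at least one copy exceeds one half — with chromosome-count
population frequency available as an alternative basis
(`freq_basis = "population"`). Both quantities are always reported.
Under Hardy–Weinberg a carrier threshold of 0.25 corresponds to a
population frequency of about 0.134 ($2p - p^2 > 0.25$). The inequality
is strict.

**Deregression.** Proofs enter the model as
$\mathrm{DRP}_i = m + (\mathrm{EBV}_i - m)/\mathrm{REL}_i$ with $m$ the
group mean — a transparent reliability-scaled deviation that restores
the dispersion shrunk by the genetic evaluation and reduces to the
identity at full reliability. Full mixed-model deregression (iterating
on the evaluation's own equations) is out of scope but the rule is
isolated behind `deregress()` so it can be substituted. Weights
$w_i = \mathrm{REL}_i/(1-\mathrm{REL}_i)$ are attached; the model is
unweighted by default (`use_weights = FALSE`) since a homogeneous
residual is the simpler assumption and the weighted option is one switch
away.

**The four model variants.** Two design-matrix kinds crossed with two
variance partitions:

| variant | $Z_{ij}$ | $\sigma^2_{h_j}$ |
|---|---|---|
| 1 | transmission probability (expected copies / 2) | $\sigma^2_g / H$ |
| 2 | carrier indicator of the modal diplotype | $\sigma^2_g / H$ |
| 3 | as 1 | $\sigma^2_g L_j / \sum_k L_k$ |
| 4 | as 2 | $\sigma^2_g L_j / \sum_k L_k$ |

$H$ is the number of selected haplotypes and $L_j$ the SNP count of
haplotype $j$'s block, so both partitions sum to $\sigma^2_g$ — the
size-weighted normalisation uses the total SNP count across selected
haplotypes, which is the reading that preserves that conservation
(a per-block-allele-count mode would not); the sum is made exact in
floating point by absorbing the compensated-summation residual into the
smallest element. "Transmission probability" bounds probability-kind
entries to $[0,1]$; an expected-dosage scale on $[0,2]$ is available as
`scale = "dosage"` for sensitivity. The residual variance defaults to
$\sigma^2_e = \sigma^2_g (1-h^2)/h^2$ from the trait's heritability and
can be overridden.

**Solver.** $\mu$ is a fixed effect inside the mixed model equations
(standard BLUP practice), and the symmetric coefficient matrix is
factorised by Cholesky. After the 25% filter the system has at most a
few thousand equations, so no iterative solver is needed. A singular
system — possible only in degenerate limits — falls back to the
minimum-norm solution with a warning naming any all-zero design
columns. DGV excludes $\hat\mu$, which leaves correlations unchanged
and affects only regression intercepts; intercepts are reported but are
not a headline statistic.

**Validation.** The split is generational: the oldest
$\lfloor n \cdot 0.875 \rfloor$ animals (birth year, ties by id) train
the model, the youngest validate it — 1064/152 at $n = 1216$. Accuracy
is the Pearson correlation between DGV and EBV; bias is the slope of
EBV regressed on DGV, where a slope above 1 means the DGV dispersion is
underestimated. Train-set statistics are in-sample refits and are
labelled as such. EBV is the default comparison target; in simulation
the true breeding value can be targeted instead
(`validation_report(..., target = "tbv")`), which is the cleaner
accuracy measure when truth is available.

## The synthetic population generator

No public dataset carries the structure this analysis needs (proofs
with reliabilities, block-structured genotypes, birth years), so
`simulate_population()` generates it:

* per block, a handful of haplotype alleles (default 4) with
  frequencies drawn from a symmetric Dirichlet (concentration 1);
* diplotypes drawn independently per animal under Hardy–Weinberg;
* haplotype effects drawn from the equal-partition prior
  $N(0, \sigma^2_g/H)$, centred within block on the frequency-weighted
  mean, then rescaled once so that the analytic variance of the sum of
  the two transmitted effects — given the drawn frequencies — equals
  $\sigma^2_g$ exactly. Without this calibration the realised additive
  variance would fall well short of $\sigma^2_g$ (by roughly the factor
  $2(1-\sum_a f_a^2)/A$), and heritability would lose its meaning as a
  simulation input. Effects are generated under the equal partition, so
  variants 3 and 4 are evaluated under prior misspecification, matching
  how the variants compete on one dataset;
* $\mathrm{EBV} = \mathrm{TBV} + e$ with
  $e \sim N(0, \sigma^2_g (1-\mathrm{REL})/\mathrm{REL})$ — the
  prediction-error-variance relation — and REL uniform on
  `reliability_range` (default 0.70–0.99, typical of progeny-tested
  bulls); birth years uniform on 1987–2003;
* independent 2% missingness injected into the calls.

Blocks are mutually independent (no between-block LD) and laid out
across the 29 bovine autosomes with megabase gaps, so LD-based block
discovery cannot bridge them; within-block LD is implicit in the finite
allele set. Diplotypes are stored ordered internally but all comparisons
are unordered, since parental origin is unobservable. Defaults describe
a milk-yield-like trait ($h^2 = 0.33$, $\sigma^2_g = 213{,}490$); the
ten-trait parameter table (production, conformation, fertility, somatic
cell score) ships in `inst/extdata/trait_parameters.tsv`, and
`scs_transform()` provides the somatic cell count to score mapping
$\log_2(\mathrm{SCC}/100{,}000) + 3$.

What the generator does *not* emulate: realistic allele-frequency
spectra and LD decay (the Dirichlet-over-alleles design is a stand-in,
not a claim about any real population), pedigree structure, selection,
recombination history, or genetic trend across birth years. Passing
tests therefore demonstrate the correctness and qualitative behaviour
of the machinery, not calibrated accuracy on real cattle data.

For heritability-contrast experiments the generator is paired with
`progeny_test_reliability()`: with a fixed effective daughter count
(default 100), $\mathrm{REL} = n t/(1 + (n-1)t)$, $t = h^2/4$, so a
$h^2 = 0.30$ trait carries reliabilities near 0.89 while a
$h^2 = 0.02$ fertility-like trait drops to about 0.33 — the realistic
coupling that makes low-heritability proofs noisier.

## A worked replicate

```{r replicate}
cfg <- simulation_config(n_animals = 300, n_blocks = 20, seed = 1)
replicate_validation(cfg, variant = 1)
```

Deliberate over-shrinkage (haplotype variances scaled down 1000-fold)
reproduces the characteristic bias signature, a validation slope far
above 1:

```{r overshrink}
replicate_validation(cfg, variant = 1, shrink = 1e-3)$slope
```

## Numerical choices and degenerate inputs

* Simulation sizes used throughout the tests and the acceptance script
  — 200–500 animals, 10–40 blocks, 10 replicates per qualitative
  contrast — were chosen as the smallest populations at which the
  binomial and sampling tolerances stated with each check are
  comfortably met.
* EM convergence is absolute log-likelihood change (`tol = 1e-8`,
  phasing; `1e-12`, two-locus $r^2$); the phasing likelihood is checked
  monotone at every sweep and the run aborts if it ever decreases.
* Monomorphic locus pairs return $r^2 = 0$; pairs with fewer than two
  jointly observed animals return `NA` and form no edge.
* Posterior probabilities are renormalised after pruning alleles below
  $10^{-12}$; per-animal posterior mass is asserted to be 1 within
  $10^{-10}$.
* Indicator designs break modal-diplotype ties by descending
  probability, then allele indices; haplotype selection orders by
  block, descending frequency, then allele string — all artifacts are
  byte-reproducible from the configuration seed, and every module draws
  its randomness from a named substream of that seed.
* Reliability 1 yields an infinite deregression weight; such records
  are accepted by the default unweighted fit and rejected by the
  weighted one.

## Known limitations

EM phasing ignores coalescent structure and phase information across
blocks; the deregression rule is a stand-in for full mixed-model
deregression; X-chromosome genotypes are treated as autosomal codes
(heterogametic dosage is not modelled); and the generational split is
the only cross-validation layout implemented — K-fold layouts and
relationship-aware reliability analysis are out of scope.
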