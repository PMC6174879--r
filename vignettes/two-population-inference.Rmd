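---
title: "Two-population divergence inference from multi-SNP loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-population divergence inference from multi-SNP loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucepopgen)
```

## The problem

`ucepopgen` analyses phased diploid genotypes at many short sequence loci
(the motivating case: ultraconserved-element loci captured from two
recently diverged bird populations, four diploids per population) and asks
the classic two-population questions: how diverged are the populations
(FST, dxy, dA), are individuals diagnosable to population, how much
recombination is visible within loci, and which demographic history — no
divergence, a clean split, a split with gene flow, growth after isolation —
best explains the folded joint site frequency spectrum (SFS). Fitted
parameters are finally converted into individuals, years and migrants per
generation.

Because raw sequence data of the motivating study are not redistributable,
the package carries a first-class structured-coalescent simulator that
reproduces the *shape* of such a dataset (locus counts and lengths, SNP
density, Z-linked fraction, optional intra-locus recombination) under known
truth parameters. All statistical machinery is exercised end-to-end on that
synthetic data.

## Units and models

Everything uses the diffusion convention so that fitted numbers are
directly comparable across tools: time in units of $2N_{ref}$ generations,
population sizes as ratios $\nu_i = N_i/N_{ref}$, and migration scaled as
$m = 2N_{ref}\times$ (per-generation migration fraction), so a lineage in
population 1 traces its ancestry to population 2 backward in time at rate
$m_{12}/2$. Six models are supported (`DIVERGENCE_MODELS`): `neutral`
(panmixia), `split_mig` (split at $T$ with one symmetric $m$),
`split_no_mig`, `im` (ancestral fractions $s$, $1-s$ growing exponentially
to $\nu_1$, $\nu_2$, asymmetric migration), `im_no_mig`, and `split_bimig`
(independent $m_{12}$, $m_{21}$). The no-migration variants are the
migration models with the rates fixed at zero.

## The simulator

`simulate_genealogy()` draws genealogies under the structured coalescent:
within-population pairwise coalescence at rate $1/\nu_i$, migration per
lineage at $m_{ij}/2$, all lineages merged into the ancestral population
(size 1) at $T$. Exponentially growing demes are handled by thinning
against the interval maximum of the coalescence rate, which is exact.
`sprinkle_mutations()` drops $\mathrm{Poisson}(\theta_{locus}/2 \times
L_{tree})$ infinite-sites mutations on branches chosen proportionally to
length. Recurrent mutation is ignored: at the SNP densities this package
targets (~3 SNPs/kb) multiple hits are negligible.

`generate_dataset()` assembles a full dataset. Defaults emulate the
motivating study's shape: 2 populations × 4 diploids, 2,600 variable loci,
800 invariant loci, locus lengths normal with mean 1,153.6 bp and SD 148 bp
truncated at 200 bp, 4.9% of loci flagged Z-linked, and
`theta_per_site = 3.0e-4`, calibrated once so the default
split-with-migration truth ($\nu_1 = 3.52$, $\nu_2 = 5.95$, $T = 1.44$,
$m = 1.65$ — the fitted values the package's conversion layer works from)
yields ≈3.6 SNPs per variable locus. Loci drawn with zero mutations are
discarded, invariant loci are emitted as annotation-only rows, and a
configurable fraction of loci is spliced from two independent genealogies
at a uniform breakpoint, creating four-gamete violations. Z-flagged loci
are simulated identically to autosomes; the flag only drives downstream
exclusion.

What the generator does **not** emulate: sequencing error, capture bias,
missing genotypes, genotype-quality structure (GQ values are drawn high,
matching a GQ≥10-filtered complete matrix), selection, and realistic
per-locus recombination landscapes. Passing tests on synthetic data
therefore validate the statistical machinery, not robustness to those
artefacts.

## Summary statistics

* π is the unbiased per-site heterozygosity $(1-\sum_a p_a^2)\,n/(n-1)$
  summed over SNPs and divided by the **total surveyed length including
  invariant loci** — matching diversity computed from full concatenated
  alignments. `dxy` is the mean per-site between-population difference;
  `dA = dxy − (π_1+π_2)/2`. These are plain average-pairwise distances; at
  the divergences this package targets (~5×10⁻⁴) composite-likelihood
  corrections are numerically irrelevant.
* FST is Weir & Cockerham's (1984) variance-components estimator, with
  locus and overall levels formed as ratios of summed components — the
  convention of the standard VCF tooling. Multi-allelic sites are excluded.
* The differentiation test pools per-SNP allele-count G statistics and
  permutes individuals across populations;
  $p = (1+\#\{G^* \ge G\})/(n_{perm}+1)$.
* Hardy–Weinberg testing is the exact conditional test (enumeration over
  heterozygote counts given allele counts); monomorphic sites return
  $p = 1$. Populations are pooled by default; the out-of-HWE locus count
  uses an uncorrected 0.05 threshold, since the motivating workflow reports
  a raw count.
* The paired Ho-vs-He comparison reports both one- and two-tailed p-values:
  the convention in published summaries is ambiguous (a negative t paired
  with p = 1 implies a one-tailed test), so both are given.
* `assign_individuals()` is the DAPC idea reduced to its core: center the
  dosage matrix, keep the top principal components (default 4), fit a
  linear discriminant, report posteriors and diagnosability. With eight
  individuals and four PCs, training-data posteriors overfit: under
  panmixia training diagnosability averages ~0.85, and naive leave-one-out
  is *anti*-predictive (~0.06) because removing an individual shifts its
  own group centroid away from it. `cv = "none"` reproduces the
  conventional training-data report; `cv = "loo"` is the honest
  generalization check. Neither sits at 50% under the null at this sample
  size; tests therefore check "no signal" rather than an exact 50%.

## Four-gamete filtering

Two biallelic sites showing all four gametes imply recombination (or
recurrent mutation, excluded here by the infinite-sites model). For each
locus with incompatible pairs the filter chooses, deterministically, the
action retaining the most haplotype-sites (rows × retained contiguous site
window): trim the locus, remove up to `k = 2` individuals (both
haplotypes), or both. Individuals are removed only when strictly better
than trimming alone; ties break toward the smaller window start and
sample order. The search over (removal subset × window) is exhaustive —
at these locus sizes that costs nothing and makes the exhaustive-oracle
test an identity. The retained block always passes a full re-scan.

Under the one-breakpoint splicing mechanism the fraction of loci with any
filter action tops out near 11% even when every locus recombines, because
two independent genealogies produce all-four-gamete site pairs only for a
minority of frequency configurations. Real data, with many potential
breakpoints per kilobase-scale locus, show higher affected fractions; the
simulated fraction is therefore a qualitative knob, not a calibrated match.

## Folded joint SFS

`prepare_snp_matrix()` applies, in order: Z-exclusion (the annotation flag
stands in for sequence-similarity identification of sex-linked loci),
dropping loci containing a >2-allele site, and thinning to one SNP per
locus (`random` by default, seeded; `first` for strict determinism — the
order Z → biallelic → thinning is a documented choice, as published
workflows rarely state theirs). Folding sends counts $(i,j)$ with
$i+j > (n_1+n_2)/2$ to $(n_1-i, n_2-j)$ and splits mass half-and-half on
the ambiguous diagonal — the convention that keeps likelihoods comparable
with diffusion-based tools. Corners and the redundant half-plane are
masked; unmasked mass equals the SNP count exactly, and folding is
idempotent. A three-line text dialect (`write_sfs()`/`read_sfs()`)
round-trips spectra bit-exactly. `jackknife_datasets()` partitions loci
into `n_reps = 10` random equal blocks and builds leave-one-block-out
spectra (delete-m jackknife).

## Demographic fitting

Instead of a diffusion PDE solver, the expected spectrum is computed by
Monte-Carlo coalescent expectation: simulate genealogies, add each
branch's length to the cell indexed by its descendant counts, divide by
the number of genealogies (`expected_sfs()`). At 8+8 haplotypes this is
exact up to Monte-Carlo error, has no grid-resolution tuning, and is
directly testable against closed forms ($E[\xi_i] = \theta/i$ for the
neutral single-population spectrum). The ancestral phase uses the
conditional expectation of each holding time given the coalescence order
(a Rao–Blackwellized estimator): in that phase rates are constant and pair
choices are independent of the waiting times, so the substitution is
unbiased and reduces variance noticeably.

The fit maximizes the Poisson composite likelihood; the spectrum scale
$\hat\theta = \sum d / \sum m$ is profiled out analytically. Within one
fit every likelihood evaluation re-simulates genealogies from one fixed
seed (common random numbers), making the Monte-Carlo surface deterministic
and optimizable. The surface has a long curved ridge in $(T, m, \nu)$ and
distant local basins, so `fit_model()` explores before it polishes: ~120
log-uniform probes scored on a cheap (fifth-size) genealogy set, short
Nelder–Mead races from the best probes, full Nelder–Mead runs with a
restart from the survivors, and a final polish on a larger
(`final_n_genealogies = 100,000`) surface. Default evaluation sizes
(20,000 during optimization) put the Monte-Carlo likelihood SD well under
one unit at a 9×9 spectrum with a few thousand SNPs. A fit is declared
converged when the three best starts agree within 0.5 likelihood units —
the repeatability rule (trust an optimum once it is found three times)
with an explicit tolerance, which published workflows leave unstated.
Model cells that are zero where data are positive are floored at 1e-12
and counted.

`compare_models()` ranks models by maximum log composite likelihood; for
fits that failed the agreement rule it reports the mean of the top five
per-start likelihoods (an unstable model's single best value is not
trustworthy) alongside the maximum. `jackknife_ci()` refits each
leave-one-block-out spectrum from the full-data optimum — all replicates
sharing one genealogy seed, so replicate scatter reflects the data alone —
and forms delete-m standard errors
$SE^2 = \frac{g-1}{g}\sum_r(\hat\theta_r - \bar\theta)^2$ with normal
95% intervals; the exact interval construction of the motivating analysis
is unstated, and this is the standard choice. Non-convergent replicates
are excluded and counted.

## Unit conversion

With a per-generation rate $\mu_{gen} = \text{rate} \times G$ (rate from
outgroup divergence: substitutions/site divided by $2\,TMRCA$ years,
averaged over available outgroups; generation time $G = \alpha +
s/(1-s)$):

$$N_{ref} = \frac{\theta}{4\mu_{gen}L},\quad N_i = \nu_i N_{ref},\quad
T_{years} = T \cdot 2N_{ref} \cdot G,\quad
\text{migrants}_i = \frac{m\,\nu_i}{2}.$$

$L$ is the adjusted surveyed length in bp and is taken as an input: the
published adjustment formula (total bp × proportion of SNPs retained)
does not exactly reproduce the published value from the published counts,
so when a printed $L$ exists it is authoritative; in pipeline runs without
one, $L$ is computed from the data by that formula. Confidence intervals
map through the same monotone conversions with the other inputs held at
their point estimates; migrant intervals formed this way are wider than
jointly-jackknifed ones, since $m$ and $\nu$ co-vary. "Substitutions" in
a tabular alignment hit table are the mismatch counts of the
best-bit-score hit per locus (gaps excluded).

## Problem sizes and numerical choices

The shipped tests run the full machinery at sizes chosen to keep the whole
suite in the tens of minutes on one core: parameter recovery fits a
2,500-SNP folded 9×9 spectrum (20,000 genealogies per evaluation, 100,000
for the final polish); model ranking uses twenty replicate datasets with
1,500-genealogy evaluations, ample for likelihood gaps of hundreds of
units; closed-form and oracle checks use 3-SE Monte-Carlo tolerances.
Recovery tolerances (±30% on parameters, ±15% on $\hat\theta$) reflect the
sampling variance of a single 2,500-SNP dataset on the $(T, m)$ ridge —
the published analysis's own jackknife intervals on comparable data are
±25% — plus residual Monte-Carlo displacement.

Degenerate inputs are errors, not guesses: zero surveyed length, empty
populations, monomorphic-only FST input, allele counts outside $[0, n]$,
jackknife blocks exceeding loci. Fixed seeds make every pipeline stage,
the simulator's VCF output, and every fit bit-reproducible.

## Known limitations

* Composite likelihood ignores linkage between the (thinned) SNPs;
  jackknife intervals, not curvature, provide uncertainty.
* Thinning multi-SNP loci to one SNP weights genealogies by normalized
  rather than absolute branch lengths; the induced spectrum distortion is
  small (≤5% per cell at study scale) but the likelihood ridge can amplify
  systematic distortions of this size into visible parameter shifts — one
  reason real-data fits warrant jackknifing.
* The Monte-Carlo expected spectrum makes likelihood *values* noisy at the
  0.1–1 unit scale; comparisons of nested models separated by a few units
  should increase `n_genealogies`.
* The four-gamete filter's objective is a transparent reconstruction of
  the behaviour of sequence-trimming tools, not a byte-for-byte port of
  any of them.
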