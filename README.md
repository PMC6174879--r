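# ucepopgen

Population-genomic analysis of two recently diverged populations genotyped
at many short multi-SNP sequence loci — the data shape produced by
ultraconserved-element (UCE) capture with a handful of diploids per
population. The package takes phased genotypes (VCF + popmap + locus
annotation), computes the standard divergence layer (nucleotide diversity
π, between-population distances d<sub>xy</sub> and d<sub>A</sub>,
Weir–Cockerham F<sub>ST</sub> with a permutation G-test, exact
Hardy–Weinberg tests, heterozygosity summaries, PCA+LDA population
assignment), screens loci for intra-locus recombination with the
four-gamete test, builds the folded joint site frequency spectrum (SFS),
fits six two-population divergence models to it by maximum Poisson
composite likelihood, and converts the fitted diffusion-scale parameters
into effective population sizes, years, and migrants per generation.

## The model at the core

Everything is expressed in diffusion units: sizes ν<sub>i</sub> =
N<sub>i</sub>/N<sub>ref</sub>, split time *T* in units of
2N<sub>ref</sub> generations, migration *m* = 2N<sub>ref</sub> ×
(per-generation fraction). Six histories are supported: `neutral`,
`split_mig`, `split_no_mig`, `im` (exponential growth from ancestral
fractions *s*, 1−*s* with asymmetric migration), `im_no_mig`, and
`split_bimig`. The expected folded joint SFS under each model is computed
by Monte-Carlo coalescent expectation — genealogies are simulated under
the structured coalescent and each branch's length accumulates in the
cell indexed by its descendant leaf counts — so the model spectrum is
exact up to Monte-Carlo error at these sample sizes, with no grid tuning.
The data spectrum is fitted by maximizing

&nbsp;&nbsp;ℓ(θ, p) = Σ<sub>cells</sub> [ d·ln(θ·m(p)) − θ·m(p) − ln d! ],
&nbsp;&nbsp;θ̂ = Σd / Σm,

with multi-start Nelder–Mead in log-parameter space on a
common-random-numbers likelihood surface. Uncertainty comes from a
delete-m jackknife over loci. Fitted (θ, ν₁, ν₂, T, m) convert to
biological units via N<sub>ref</sub> = θ/(4 μ<sub>gen</sub> L),
N<sub>i</sub> = ν<sub>i</sub> N<sub>ref</sub>, T<sub>years</sub> =
T · 2N<sub>ref</sub> · G, migrants<sub>i</sub> = m ν<sub>i</sub>/2, with
the substitution rate calibrated from outgroup divergence and the
generation time from G = α + s/(1−s).

A built-in structured-coalescent simulator generates complete synthetic
datasets of the study shape (2 × 4 diploids, ~2,600 variable loci of mean
length ~1,154 bp at ~3.6 SNPs/locus, ~800 invariant loci, ~5% Z-flagged
loci, optional intra-locus recombination) with known truth parameters, so
the whole pipeline is testable end-to-end.

## Worked example

A complete simulated run — generate data under the split-with-migration
truth (ν₁ = 3.52, ν₂ = 5.95, T = 1.44, m = 1.65), compute statistics,
filter, build the SFS, compare models, convert units:

```r
library(ucepopgen)

cfg <- run_config(
  simulation = list(n_variable_loci_target = 400, n_invariant_loci = 120,
                    seed = 42),
  stages  = c("stats", "fourgametes", "sfs", "demography", "convert"),
  models  = c("neutral", "split_mig"),
  seed = 7, n_perm = 1000, n_starts = 2, n_genealogies = 5000,
  final_n_genealogies = 20000, jackknife_reps = 5,
  calibration = list(
    comparisons = data.frame(
      sites = c(1e6, 1e6),
      substitutions = c(1e6 * 6.83e-10 * 2 * 60.5e6,
                        1e6 * 6.67e-10 * 2 * 53e6),
      tmrca_years = c(60.5e6, 53e6)),
    gen_time = 2.7),
  out_dir = "demo_run")
rep <- run_pipeline(cfg)
```

which logs:

```
[ucepopgen] simulated 400 variable loci (1457 SNPs)
[ucepopgen] stats: FST = 0.0499, pi = 0.000521
[ucepopgen] four-gamete filter: 6/400 loci affected
[ucepopgen] SFS built from 368 one-SNP loci
[ucepopgen] best model: split_mig (log composite likelihood -65.14)
[ucepopgen] Nref = 28769, split time = 338994 years
```

Reading it: per-site diversity (~5.2×10⁻⁴) and differentiation
(F<sub>ST</sub> ≈ 0.05, significant by the permutation G-test, p ≈ 0.025)
are at realistic UCE levels; individuals are 100% diagnosable to
population (`rep$stats$diagnosability`); a handful of loci show
four-gamete evidence of recombination; the split-with-migration model
beats panmixia decisively; and at the calibrated substitution rate
(6.75×10⁻¹⁰ /site/yr, G = 2.7 yr) the fitted spectrum implies an
ancestral size of ~29,000 and a split ~340,000 years ago — a 400-locus
run, so parameter scatter around the truth is expected; `jackknife_ci.tsv`
in the output directory quantifies it. Every artifact (VCF, per-locus
tables, SFS text file, model table, Table-1-style conversion table,
`report.json` with full provenance) lands in `demo_run/`.

The same stages are scriptable from a shell via the thin dispatcher
`inst/cli/ucepopgen.R` (`simulate`, `stats`, `fourgametes`, `sfs`, `fit`,
`convert`, `run` subcommands).

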