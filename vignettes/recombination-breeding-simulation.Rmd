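---
title: "Simulating doubled-haploid breeding programs under modified recombination rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating doubled-haploid breeding programs under modified recombination rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the simulator answers

Genome-editing targets such as *RECQ4* or *FIGL1* can raise the meiotic
crossover rate of crop plants several-fold. Whether that is worth doing in a
breeding program is a population-scale question: more recombination breaks
repulsion linkage between favourable and unfavourable alleles and releases
genetic variance for selection, but it also erodes the marker–QTL linkage
that genomic prediction depends on. `recombsim` implements a stochastic
forward-in-time simulator of a sorghum-style doubled-haploid (DH)
recurrent-selection program designed to quantify these effects for
phenotypic selection (PS) and RRBLUP genomic selection (GS) under 2-, 4-,
and 8-fold expansions of the genetic map.

## The breeding scheme

One cycle, implemented by `run_cycle()`:

1. select the 30 individuals with the best criterion (phenotype or GEBV)
   out of 3,000 DH lines;
2. make 60 random crosses among them (distinct parents within a cross,
   repeats allowed across crosses);
3. self each F1 once to obtain one F2 plant per cross;
4. derive 50 doubled haploids from each F2, restoring a population of
   3,000 fully homozygous lines.

A program is a burn-in of 10 such cycles under phenotypic selection on the
unmodified map (the founder generation is selected in the first cycle),
followed by 15 cycles under the treatment condition. The map factor is
applied only after burn-in: all centimorgan positions are multiplied by 2,
4, or 8 (`scale_map()`), which scales the expected crossover count per
chromosome by the same factor.

## Meiosis model

Crossovers follow a stationary gamma renewal process on the four-strand
bundle with chiasma rate 2 per Morgan; inter-chiasma distances are
Gamma(shape $\nu$, mean 50 cM), and each chiasma is transmitted to a gamete
with probability 1/2 (thinning, i.e. no chromatid interference). The first
event distance is drawn from the equilibrium residual distribution, so no
edge artefacts arise at chromosome ends. $\nu = 2.6$ by default — the
conventional interference strength of gamma-model breeding simulators —
and $\nu = 1$ recovers the interference-free Poisson (Haldane) limit, which
the test suite exploits as an exact oracle. There is no obligate crossover
by default; a flag exists for sensitivity analyses. A crossover at position
$x$ switches strands for loci with position $> x$ (half-open convention,
ties resolved after the locus).

## Synthetic genome and founders

No genotype data are downloaded at run time. The genome is synthetic but
calibrated to the documented landscape:

* **Map.** Ten chromosomes with the consensus genetic lengths of the
  sorghum map (summing to 1545.1 cM; shipped as a plain-text fixture).
  Locus placement mimics SNP positions translated from physical to genetic
  coordinates: because crossovers concentrate in distal euchromatin (about
  80% of COs in roughly a quarter of the genome), most of the physical
  genome — and with it most SNPs of a resequencing panel — collapses into
  a narrow pericentromeric stretch of the *genetic* map. By default 70% of
  loci are placed inside a central window covering 5% of each chromosome's
  genetic length and the rest uniformly
  (`pericentromeric_fraction`/`pericentromeric_window` in
  `founder_spec()`; set the fraction to 0 for uniform placement). This
  compression is load-bearing: it creates the tightly linked repulsion
  blocks whose release is the point of increasing recombination.
* **Founders.** 3,000 fully homozygous lines descend from
  `n_ancestral_haplotypes = 100` ancestral haplotypes — an elite-pool
  scale — mixed by `mixing_generations = 30` rounds of random mating
  before one final doubled-haploid step. Ancestral allele frequencies are
  drawn from a U-shaped Beta(0.2, 0.2) spectrum truncated at
  `maf_floor = 0.1`, and every locus is conditioned to segregate among the
  ancestors (loci are SNPs by construction); drift during mixing may still
  fix some. The mixing builds linkage disequilibrium that decays with
  centimorgan distance, with strength comparable to an effective
  population size of order 100.

What the generator does *not* emulate: the exact sorghum site-frequency
spectrum and LD landscape, mutation, and any real accession panel. A
passing test suite therefore demonstrates internal correctness of the
machinery and realistic qualitative behaviour, not agreement with any
particular empirical sorghum population; founder structure is declared a
stand-in and every parameter of it is exposed.

## Trait and variance bookkeeping

A single additive trait: QTL (10, 100, or 1,000 per chromosome) are sampled
uniformly per chromosome, raw effects are N(0, 1), and one common scaling
constant calibrates the founder genetic variance to exactly 1, so genetic
values are expressed in founder additive standard deviations. The
environmental variance is fixed once from the target heritability,
$\sigma_e^2 = (1 - h^2)/h^2$, and never rescaled; realised heritability
therefore declines as selection depletes variance, which is the intended
behaviour of a trait whose measurement error is a property of the assay,
not of the population.

Per cycle the simulator records, per replicate:

* the population mean genetic value, both raw (founder-SD units, burn-in
  end subtracted) and divided by the burn-in-end genetic SD — headline
  gains are reported on the founder scale, which reproduces the magnitude
  and replicate dispersion the method is known for, while the variance
  trajectory is reported relative to the burn-in-end variance;
* genetic variance (realised, denominator $n$) and genic variance
  $\sum_i 2 p_i (1 - p_i) a_i^2$;
* the Bulmer ratio `genetic / (genic / 2)`, whose halved denominator
  accounts for the doubled additive variance of fully inbred DH lines
  (`NA` once the genic variance hits 0 at fixation);
* prediction accuracy (Pearson correlation of GEBV with true genetic
  values) where a genomic model is in force.

## RRBLUP genomic selection

`train_rrblup()` fits $y = 1\mu + Zu + e$ with $u \sim N(0, \sigma_u^2 I)$
on the column-centred chip dosages (chips of 100–1,000 markers per
chromosome, sampled disjointly from the QTL, no MAF filter).
$\lambda = \sigma_e^2/\sigma_u^2$ is estimated by REML through the spectral
decomposition of $ZZ^\top$ (the efficient mixed-model parameterisation):
with $ZZ^\top = UDU^\top$ and $\eta = U^\top(y - \bar y)$, the restricted
likelihood is a one-dimensional function of $\delta = \lambda$ over the
$n - 1$ dimensions orthogonal to the intercept (the centred $Z$ makes the
intercept an exact null eigenvector), minimised by golden-section search on
$\log\delta$. Effects follow from the mixed-model equations at the optimum.
Numerical choices: eigenvalues are clamped at 0; a boundary solution at the
low end (noiseless data) is accepted with a small floor on $\lambda$, while
a boundary at the high end (no signal) falls back to $\lambda = m$ with a
warning; all-constant phenotypes yield a zero-effect model by definition.
Training is deterministic, so identical training sets give bit-identical
models.

Because $\lambda$ is a ratio of variance components — free of the sample
size — the scheme runs estimate it on an evenly spaced subset of at most
`reml_n = 1000` individuals (a principal submatrix of $ZZ^\top$,
double-centred) and then solve the full-size equations by Cholesky
factorisation. This cuts the $O(n^3)$ eigendecomposition cost at
$n = 3{,}000$ by an order of magnitude; the package's tests verify the
subsystem path tracks full REML closely.

Selection under GS uses the GEBVs of the current DH generation only, also
when the model was trained on merged generations. Retraining every cycle,
every second, or every fourth cycle is configurable
(`training_interval`), as is a rolling multi-generation training window
(`training_window`, used by the merged-training experiment with window 3).
When training is skipped the previous model is reused verbatim. Merged
training pools raw phenotypes across generations without per-generation
standardisation (a flagged assumption).

## Experiments, seeds, and replication

`run_arms()` replays every experimental arm from the identical
post-burn-in RNG state, so arms share founders, burn-in trajectory, and
standardisation constants within a replicate: contrasts between map
factors or training cadences are seed-paired by construction, which is how
the gain ratio (`gain_ratio()`, ratio of replicate-mean final gains; the
replicate-mean-of-ratios alternative is one line of user code on
`final_gains()`) is computed. Per-replicate seeds derive from one base
seed; everything is reproducible bit-for-bit.

Problem sizes: the phenotypic-selection experiments and the first-cycle
accuracy experiment run at the full population size of 3,000 DH with
QTL-only genomes (PS) or QTL + chip loci (GS) — simulating only the loci
that can ever be sampled is statistically equivalent to sampling them from
a dense SNP set at the same positions. The genomic-selection experiments
run at five-sixths scale (2,500 DH: 25 selected, 50 crosses, 50 DH per
F2 — the same 1% selected fraction and two crosses per selected parent),
which keeps the RRBLUP trainings of the scenario grid tractable on a
single CPU; the smaller training sets and slightly stronger drift give
long-term GS gains a modest downward bias relative to full scale. Once a
population fixes completely (zero genetic and genic variance), the
remaining cycles of that replicate are statistically frozen rather than
simulated, which changes no recorded quantity. Replicate counts are 30
(100 where the across-replicate variance itself is the quantity of
interest).

## Known limitations

* Founder structure is a parameterised stand-in, not a coalescent sample
  of any real panel; absolute long-term responses to recombination change
  are sensitive to it. In our calibration the baseline (normal-map)
  dynamics and the replicate dispersion match the published scale well,
  while 4- and 8-fold gain *ratios* plateau lower than the published
  ones — the package reports what the model produces.
* Single trait, purely additive; no dominance, epistasis, genotype-by-
  environment interaction, or fertility cost of modified recombination.
* No mutation and no migration: variance only depletes after burn-in.
* The recombination landscape within chromosomes is uniform per map
  interval; hotspot-shifting interventions are out of scope.
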