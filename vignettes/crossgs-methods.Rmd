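---
title: "Genomic selection for crossbred performance with dominance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic selection for crossbred performance with dominance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

crossgs simulates a two-way crossbreeding program in which purebred sire and
dam lines are selected genomically — either for their own performance or for
the performance of their crossbred offspring — using additive *and* dominance
SNP effects estimated from purebred data only. This vignette documents the
models, the parameter choices, and the places where the design was genuinely
open, so that results can be interpreted and the simulator reused with
confidence.

## The pipeline at a glance

One replicate runs:

1. **Ancestral simulation** (`simulate_historical()`): a single 1-Morgan
   chromosome with ~2500 candidate biallelic loci; 1000 generations at census
   2000, then 1000 generations of gradual decline to 100, building LD.
2. **Breed formation** (`split_and_diverge()`): two disjoint founder sets
   (25 males + 25 females each) drawn from the last ancestral generation;
   100 generations of random mating per breed at census 250.
3. **Expansion** (`expand_breed()`): 8 generations with 100 sires, 100 dams
   and litters of 10; the final generation of 1000 animals per breed is the
   reference (training) population.
4. **Trait architecture** (`sample_qtl_effects()`, `scale_effects()`): 100
   QTL with gamma additive effects and normally distributed dominance
   degrees, scaled to additive variance 0.3 and dominance variance 0.1.
5. **Marker-effect estimation** (`fit_blasso()`): a Bayesian LASSO with an
   extra dominance term, fit once per training mode (per breed, or on the
   two breeds combined), 10 000 Gibbs iterations with 1500 burn-in.
6. **Selection program** (`found_base()`, `run_scenario()`): five
   generations of truncation selection (top 100 of 500 males, top 200 of
   500 females per breed) on GEBVs for purebred (GEBVP) or crossbred (GEBVC)
   performance, with a terminal crossbred cohort produced each round.
7. **Summaries**: LD decay and between-breed persistence of LD phase
   (`ld_decay()`, `phase_persistence()`), response, heterosis and accuracy
   trajectories (`run_study()`).

```{r}
library(crossgs)
study <- run_study(n_replicates = 2, master_seed = 1,
                   cfg = sim_config("low", "smoke"),
                   mcmc = mcmc_config(1000, 200),
                   scenarios = c("ref", "2"))
study$summary
```

## The genome simulator

Meiosis follows Haldane's model: the number of crossovers per gamete is
Poisson with mean equal to the map length (1 Morgan) and crossover positions
are uniform, i.e. no interference. Recurrent mutation flips each transmitted
allele with probability 2.5e-4 per locus per gamete; on biallelic loci
"recurrent" means reversible, so mutation–drift balance keeps loci
segregating through the long ancestral phase. Starting allele frequencies
are uniform on (0, 1), and the last ancestral generation indeed shows a
roughly uniform frequency distribution with fluctuation at the boundaries.

Three structural points were open and are settled as follows:

* **Decline schedule.** The "gradual decrease" from 2000 to 100 is linear in
  census size, rounded to the nearest even count so the sexes stay equal.
  Exponential and step declines were considered during calibration;
  exponential schedules fix too many candidate loci to fill the SNP panel.
* **Breed-formation mating.** Each generation samples 50 sires and 50 dams,
  each dam receives one sire drawn uniformly with replacement and a litter
  of 5, giving a census of 250 and an effective size near 100. Among the
  readings of "random mating with litters of 5" explored during calibration
  (parents restricted to 50/50 versus random union of gametes over all 250
  animals, i.e. effective sizes ~100 versus ~250), this is the one whose
  training-population LD and phase persistence land in the study's working
  range; the larger effective size produces markedly too little within-breed
  LD and too much phase persistence.
* **Sex assignment.** Offspring sexes are balanced exactly (random
  assignment of which offspring are male), which the selected proportions of
  the program stage (100/500 males, 200/500 females) presuppose.

Panels are drawn in the last ancestral generation: 1000 SNPs and 100 QTL
sampled without replacement, disjoint, from candidate loci with minor allele
frequency at least 0.05. With 2500 candidates under the low regime this
succeeds with a wide margin; the high regime ships with 3300 candidates
because its deeper bottleneck fixes more loci.

Coordinates are Morgans on one chromosome; exports use 1 cM ≈ 1 Mb
(`round(position_Morgan * 1e8)` bp).

## Trait architecture and the variance-scaling anchor

Unsigned additive effects |a| are Gamma(shape 0.4, scale 1.66) — an L-shaped
distribution with a few large QTL — with a random sign. Dominance degrees
are h ~ N(0.5, 0.1), independent of a, and dominance effects are d = h·|a|,
so dominance is directional (mean d > 0), which produces both heterosis and
inbreeding depression.

Scaling targets V_A = 0.3 and V_D = 0.1 under the single-locus
Hardy–Weinberg decomposition with average substitution effect
α = a + d(q − p), V_A = Σ 2pq α², V_D = Σ (2pq d)². The two-stage scheme is
exact: V_D is quadratic in the dominance vector, so d is scaled first in
closed form; V_A is then a quadratic in the additive scale factor (with the
already-scaled d inside α), and the positive root is taken analytically.
Scaling is idempotent and the realized variances match the targets to
1e-8 at the anchoring frequencies.

**The anchor is p = q = 0.5 at every QTL, not the realized (drifted)
frequencies.** This choice deserves its derivation. The per-locus dominance
variance (2pq d)² is *second order* in heterozygosity while the additive
variance 2pq α² is first order; demanding V_D = V_A/3 from only 100 QTL at
realistic drifted frequencies (mean 2pq ≈ 0.37, mean (2pq)² ≈ 0.15) forces
typical |d| up to the size of |α| — Monte-Carlo over architectures puts the
share of overdominant QTL (|d| > |a|) at 39–45%. Anchored at p = 0.5 the
same targets give 10–15% overdominance, stable across draws, which is the
regime of moderate directional dominance this study design describes. The
consequences are documented rather than hidden: at the realized training
frequencies the realized variances average V_A ≈ 0.26 and V_D ≈ 0.06, and
the training phenotypic variance is ≈ 0.96 rather than exactly 1. The
purebred–crossbred correlation of true breeding values among unselected
candidates is correspondingly ≈ 0.8 at generation 0, declining into the
0.5–0.7 range as selection drives the breeds' QTL frequencies apart. (Note
the trade-off: anchoring at realized frequencies would lower that
correlation to ≈ 0.73 at generation 0 but triple the overdominant share; the
two diagnostics cannot both be matched by the scaling anchor alone.)

Phenotypes add N(0, 0.6) residuals to the genotypic value
G = Σ (−a, d, +a) by QTL dosage (0, 1, 2).

## The Bayesian LASSO with dominance

The model is `y_i = μ + Σ_j X_ij a_j + Σ_j Z_ij d_j + e_i`, with X the
0/1/2 reference-allele dosage, Z the heterozygosity indicator, and an
intercept as the only fixed effect (in common-training mode there is *no*
breed effect; the intercept absorbs the average). Codings are used as is —
no centring or standardisation.

Priors and full conditionals (single-site Gibbs, residual updated
incrementally after every effect):

* a_j ~ N(0, σ²_e τ²_j), τ²_j ~ Exp(rate λ²/2), so each marker has its own
  shrinkage; 1/τ²_j has an inverse-Gaussian full conditional with mean
  √(λ²σ²_e)/|a_j| and shape λ².
* λ² ~ Gamma(shape 0.52, rate 1e-4), a weakly-informative default in the
  Park–Casella family; its gamma full conditional has shape m + 0.52 and
  rate Στ²_j/2 + 1e-4. Results are insensitive to this prior within a
  factor of ten in either parameter.
* d_j ~ N(0, σ²_d) with a common dominance variance,
  σ²_d ~ scaled-inv-χ²(df 3, scale 5e-4).
* σ²_e ~ scaled-inv-χ²(df 3.5, scale 3). The scaled-inverse-χ² density is
  parameterised as (σ²)^(−df/2−1) exp(−df·S/(2σ²)) — S is a scale, not a sum
  of squares, which is the only reading under which S_e = 3 and S_d = 5e-4
  are sensible together.

Estimates are plain posterior means of the 8500 post-burn-in draws (no
thinning). Zero-variance columns are sampled from their priors, so
monomorphic markers cannot destabilise the chain. The sampler is validated
against the conjugate ridge closed form with all variances frozen, against
parameter recovery on data with known effects, and for bit-identical
determinism under a fixed seed.

## Breeding values and accuracies

A parent's breeding value for a given mate line is its expected offspring
genotypic value: at a locus with mate-line reference-allele frequency p,
an AA parent contributes p·a + q·d, a heterozygote
0.5p·a + 0.5q·d + 0.5p·d − 0.5q·a, and an aa parent −q·a + p·d. Purebred
values (TBVP/GEBVP) use own-line frequencies, crossbred values (TBVC/GEBVC)
the other line's. True values use the 100 QTL and true effects; genomic
values use the 1000 SNPs and posterior means. Frequencies always come from
the *current selection candidates* of the relevant breed and are updated
every generation — marker effects are estimated once, before selection
starts, and reused, so any adaptation over generations comes through the
frequencies alone.

Each value partitions exactly into an additive component (set d = 0 in the
weights) and a dominance component (set a = 0); accuracy is the Pearson
correlation between the matching true and genomic quantities, and the
"criterion accuracy" of a scenario correlates the criterion GEBV with its
matching TBV. The three-genotype weights are affine in dosage with slope
α/2, which is tested as an algebraic identity.

Generation indexing follows the selection rounds: accuracies (and the
purebred–crossbred correlation) at generation g are evaluated on the
candidate cohort that the g-th selection acts on, while the phenotypic means
(breed average, crossbred mean) at g describe the cohorts that selection
produces. Under this convention generation-1 accuracies are measured one
generation from training (the highest values, ~0.83–0.90 across scenarios)
and generation-1 breed averages already differ between scenarios, both as
expected; accuracy then declines over rounds while the accuracy of the
dominance component tends to *rise*, because selection moves allele
frequencies and the dominance term of the breeding value grows in relative
importance.

## The selection program

Breed A is the sire line, breed B the dam line. The five scenarios cross two
choices: the criterion per breed (GEBVP vs GEBVC; the reference scenario
selects both breeds on GEBVP, scenario 2 both on GEBVC) and the reference
population (separate per breed vs the two breeds combined, n = 2000). All
scenarios of a replicate share the same steps 1–4 (identical base
populations and architecture), so scenario contrasts are paired.

Selection is truncation within sex with ties broken by individual id.
Selected dams each receive one selected sire drawn uniformly with
replacement (100 sires cannot serve 200 dams without reuse) and a litter of
5 — giving 1000 purebred replacements; simultaneously the 100 selected breed-A
males are mated to the 200 selected breed-B females to produce 1000
terminal crossbreds, phenotyped with the same residual variance. Expected
heterosis for a crossbred cohort is H = Σ_l d_l (p_Al − p_Bl)² computed from
its actual parents' allele frequencies (their gamete pools), which is the
exact expectation for that cohort; in the reference scenario H stays
roughly constant while selection on GEBVC makes it grow by pushing the two
breeds' QTL frequencies apart.

## LD and persistence of LD phase

Signed r is computed from phased haplotypes (exactly, as the correlation of
allele indicators across the 2n haplotypes); r² summaries use SNPs with
MAF > 0.1, and phase persistence uses SNPs segregating (MAF > 0) in both
breeds with a consistent reference allele. Pairs are grouped into half-open
1-cM bins `[k, k+1)` labelled by the left edge; the "statistic at 1 cM" is
the first interval (pairs up to 1 cM apart), matching the convention of
distance-interval analyses in the pig-breed LD literature this design
follows — under the alternative reading (the `[1,2)` bin) the simulated
values (r² ≈ 0.14, phase correlation ≈ 0.06) are far from the study's
working range. The between-breed phase correlation R_AB is the Pearson
correlation, across pairs within a bin, of signed r in breed A with signed
r in breed B, with bin means subtracted. One caveat is worth knowing: with
bin-mean centring, relabelling a SNP's alleles consistently in both breeds
is only *asymptotically* neutral (the uncentred cross-product is exactly
invariant); the package's tests pin down both facts.

## The two LD-phase regimes, and an honest ceiling

The low regime is the plain decline to 100; its training populations show
adjacent-SNP r² ≈ 0.49, first-interval r² ≈ 0.35, R_AB ≈ 0.2–0.3 at 1 cM
and ≈ 0.4–0.5 below 50 kb. The high regime compresses the decline so the
population spends its last 200 generations at size 100, with 3300 candidate
loci so the panels remain selectable; it yields R_AB ≈ 0.38 at 1 cM and
≈ 0.6–0.7 below 50 kb — a clear, reproducible contrast with the low regime.

Much higher 1-cM phase persistence is *not attainable* by ancestral
bottlenecks under this divergence structure, and the package documents this
rather than chasing it. After the split the breeds drift apart for
T = 108 generations at effective size Ne ≈ 100, and the correlation of
signed LD between them decays like exp(−T(2c + 1/(2Ne))): at c = 0.01 per
Morgan-fraction (1 cM) this is ≈ 0.2 — precisely the low-regime value —
and the term generated *after* the split does not depend on how much LD the
ancestral population had. Calibration sweeps (see
`inst/scripts/calibrate_regimes.R`) over plateaus of 200–950 generations and
bottlenecks down to size 24 confirm the saturation at ≈ 0.35–0.40 at 1 cM,
with longer plateaus additionally fixing so many loci that the MAF ≥ 0.05
panels cannot be filled. A 1-cM phase correlation of ~0.7 would require an
effective divergence of only ~15–20 generations, i.e. a different recent
population structure, not a smaller ancestral size.

## What the generator does and does not emulate

It emulates: mutation–drift LD build-up through a bottleneck; two related
pure breeds with realistic within-breed LD; a finite-locus dominance trait
with directional dominance, heterosis and inbreeding depression; genomic
prediction transfer between breeds limited by LD-phase persistence.

It does not emulate: multiple chromosomes (one Morgan total, so long-range
map structure is compressed); sequence-scale variant density or U-shaped
frequency spectra; selection, migration or admixture during the historical
phases; epistasis or genotype-by-environment interaction (dominance is the
*only* source of purebred–crossbred divergence, by design); unbalanced sex
ratios or overlapping generations. Passing tests therefore demonstrate
internal correctness and behaviour under these idealisations — not that any
particular livestock population will show the same accuracy or response.

## Numerical and reproducibility choices

* Every stage draws its seed from a master seed and a named substream
  (`substream_seed()`), so reruns are bit-identical, replicates are
  independent, and scenarios within a replicate are paired. All randomness,
  including in compiled code, flows through R's RNG.
* Selection ties break by ascending id; selection requires finite criteria.
* Variance scaling is exact to 1e-8 (asserted), the breeding-value
  partition to 1e-12.
* Degenerate inputs are defined: monomorphic loci are excluded from LD pair
  sets, produce prior draws in the sampler, and pass through the
  breeding-value formulas untouched (p ∈ {0,1} is valid there); empty
  distance bins are NA; accuracy with zero variance or n < 3 is NA.
* A fixed QTL in the scaling reference or an unfillable panel is an error
  with an actionable message, not a silent adjustment.

## Problem sizes used by the shipped checks

The test suite exercises the full Table-1-scale simulation for the LD and
phase statistics (three seeds per regime), ten pipeline replicates for the
purebred–crossbred correlation, sixty architecture draws for the
overdominance share, and three full replicates (two in the high regime) —
each with three 10 000-iteration Gibbs fits and all five scenarios — for
accuracy and response; the acceptance script uses five full replicates for
the accuracy block. These sizes are the package's choice of a reproducible
desk-scale experiment; the study-scale experiment (30 replicates per regime)
is one `run_study()` call away.

## Known limitations

* Replicate-level phenotypic means carry a random architecture offset
  (additive offset of the base mean, s.d. ≈ 0.6, plus a dominance base mean
  that drift erodes), so absolute response levels need ~30 replicates to
  stabilise; accuracy, heterosis and LD statistics are much less affected.
* The common-training mode fits no breed effect (faithful to the model
  statement); with strongly diverged breed means some of the between-breed
  signal is absorbed by marker effects.
* The Gibbs sampler is single-site; at much larger marker counts a
  blocked or GPU sampler would be preferable.
* One chromosome means panel-level statistics mix linked and effectively
  unlinked pairs differently than a 30-chromosome genome would.
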