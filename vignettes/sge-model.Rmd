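---
title: "Social genetic effects: model, estimation, and windowed single-step GWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Social genetic effects: model, estimation, and windowed single-step GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

When animals are raised in groups, each record is shaped by the genotype of
the animal that produced it *and* by the genotypes of its group mates.  The
extended animal model implemented here decomposes a record into

$$y = Xb + Z_D a_D + Z_S a_S + Wc + Vg + T\,pe + Ul + Qk + e,$$

with fixed effects $b$ (birth year-month, sex, group-size class, and an
age-at-target-weight covariate), direct genetic effects $a_D$, social
genetic effects $a_S$, pen $c$, group $g$, maternal permanent environment
$pe$, birth litter $l$, early-life environment $k$ (the effect of the group
mates' birth litters), and residual $e$.  The two genetic vectors are
jointly Gaussian, $[a_D; a_S] \sim \mathrm{MVN}(0, C \otimes H)$, with $C$
the $2\times2$ direct/social covariance matrix; $l$ and $k$ form a second
correlated pair with an identity kernel.

**Dilution.**  Groups vary in size, so a covariate
$d = (\bar n - 1)/(n - 1)$ multiplies every social and early-life incidence
entry.  Each row of $Z_S$ then sums to exactly $\bar n - 1$: an animal in a
small group receives more influence from each of its few mates, and the
total social load is the same for everyone.  We weight *entries* (each
nonzero of $Z_S$ and $Q$ equals the record's $d$) rather than row-scaling
afterwards, which is the only reading that keeps per-mate symmetry; the
same matrices are used by the simulator, the sampler and the solver.

**Single-step kernel.**  The genetic kernel is the combined
pedigree/genomic matrix $H$.  Only its inverse is needed:
$H^{-1} = A^{-1} + \begin{bmatrix}0&0\\0&G^{-1}-A_{22}^{-1}\end{bmatrix}$,
where $A$ is the numerator relationship matrix (tabular method; inverse by
Henderson's rules with inbreeding), $A_{22}$ its genotyped submatrix, and
$G = ZDZ'q$ the weighted VanRaden matrix with $q$ chosen so that the mean
diagonal of $G$ equals that of $A_{22}$.  The defining prior is sometimes
written with $A$; since the evaluation is single-step throughout, $H$ is
used as the kernel wherever genotypes are present, and reduces to $A$
otherwise.

Allele frequencies for centring $Z$ are the observed frequencies of the
genotyped sample.  A consequence worth knowing: with observed frequencies
$Z$ is exactly column-centred, so the raw $ZDZ'$ is singular.  `build_G()`
therefore supports blending, $G \leftarrow (1-\varepsilon)G + \varepsilon
A_{22}$, with default $\varepsilon = 0.05$ applied before inversion;
$\varepsilon = 0$ reproduces the unblended formula exactly and is used by
the unit tests against the printed expressions.

# Estimation

`gibbs_fit()` runs a single-site Gibbs sampler (compiled core): every
location effect is drawn from its scalar Gaussian full conditional, the two
$2\times2$ covariance blocks from inverse-Wishart full conditionals, and
the scalar variances and the residual from scaled-inverse-chi-square full
conditionals.  The default chain is 55,000 rounds with 5,000 burn-in and
thinning 5 — a ten-fold reduction of the full-scale settings (550,000 /
50,000 / 50, which retain exactly 10,000 samples and are available through
`gibbs_config()`).  One integer seed reproduces the whole chain bitwise.

**Priors, and one numerical choice that matters.**  Fixed effects are flat;
scalar variances use a flat scaled-inverse-chi-square ($\nu = -2$); the
$2\times2$ blocks use an inverse-Wishart with minimal degrees of freedom
($\nu_0 = 3$).  The Wishart *scale* deserves care.  With a numerically zero
scale the singular boundary of a covariance block ($|r| = 1$) becomes an
absorbing state of the sampler: once the sampled effect pair is nearly
collinear, the conditional draws of the second vector become deterministic,
the scatter matrix stays singular, and the chain freezes there regardless
of the likelihood (we verified this against an independent, exactly
blocked sampler: both implementations freeze, so it is a property of the
limit, not of the code).  The default scale is therefore
$\mathrm{diag}(0.01\,\mathrm{var}(y))$ — still vague (it shifts posterior
means by roughly $0.01\,\mathrm{var}(y)/q$, well under one $(g/day)^2$ at
realistic sizes) but enough to bound the sampled correlation away from
$\pm1$ and keep the chain ergodic.  All hyperparameters are exposed in
`gibbs_config()`.

Flat scalar priors have their own small-data failure mode: with very few
levels (say, three pens) the variance posterior is so heavy-tailed that the
chain visits numerically infinite values, where nested terms (pens contain
groups) become exactly collinear.  A full-scale structure (hundreds of
pens) is safe; tiny test fixtures should pass a weakly proper
`nu_scalar`/`s_scalar`.

**Reported estimates.**  `summarize_chain()` computes the derived
parameters ($\sigma^2_{TBV}$, $\sigma^2_P$, $h^2$, $T^2$, the two
correlations) per retained draw and then averages, so reported ratios are
posterior means of ratios with their own posterior SDs — matching the
"estimate (posterior SD)" presentation convention.  Whether a published
$r_{lk}$ of this kind is a mean of ratios or a ratio of means is not
resolvable from a table alone; we standardise on the former.

**Point solutions.**  `solve_mme()` solves Henderson's mixed-model
equations at fixed components (sparse Cholesky; effect order fixed as
$b, a_D, a_S, c, g, pe, l, k$ for reproducible output).  A rank-deficient
fixed block is repaired by dropping pivoted-out columns, with a message.
The maternal permanent environment is a dam-indexed random effect whose
levels are the dams of recorded animals; dams that also have records do not
share parameters with their own animal effect.

# Windowed single-step GWAS

`run_ssgwas()` implements the back-solve/re-weight iteration: starting from
$D = I$, breeding values are solved from the MME with the current kernel,
the genotyped animals' solutions are converted to marker effects
$\hat u = DZ'[ZDZ']^{-1}\hat a_g$, weights are recomputed as
$d_i = \hat u_i^2\,2p_i(1-p_i)$ and rescaled so that
$\sum_i d_i 2p_i(1-p_i)$ is conserved, $G$ and $H^{-1}$ are rebuilt, and
the cycle repeats — two iterations by default.  Variance components stay
fixed at their posterior means; re-running the whole chain inside the loop
is not implied by the five-step procedure and would change nothing but the
cost.  The DGE and SGE runs share the $G$ construction but keep their own
weights; which of the two weight sets the original analysis reused is not
documented, so we default to effect-kind-specific weights.

`window_variance()` tiles each chromosome with non-overlapping windows of
1 Mb anchored at position 0 (half-open $[start, start + 1\,\mathrm{Mb})$,
1-based labels in the "61–62 Mb" style) and reports each window's
$\mathrm{Var}(\sum_{j \in \mathrm{window}} Z_j\hat u_j)/\sigma^2_a \times
100$.  Fixed-count windows (runs of, say, 10 adjacent SNPs) are a common
alternative; only the fixed-width 1-Mb scheme -- the one QTL intervals and
Manhattan plots are reported in -- is implemented.  The denominator $\sigma^2_a$ defaults to the model's
estimated additive variance for the chosen effect kind; a self-normalised
mode (denominator = empirical variance of the total genomic value) is
provided and makes the percentages scale-invariant.  `call_qtl()` flags
windows at or above 0.5% (inclusive, per the calling rule) and sorts them.

# The synthetic world

`sim_scenario()` fixes the generative world; its defaults are the stated
conditions of the motivating pig data set, and everything else is a
documented choice:

* **Groups**: same-sex groups of 4–13 with target mean 6.8, drawn from a
  shifted binomial (mean exactly 6.8, SD 1.4 versus the reported 1.9 — the
  simplest one-parameter family on the stated support); groups are filled
  from a flow of contemporaneous litters, so littermates are co-housed.
  This matters: with fully random group composition the social (co)variance
  is unidentifiable at desk scale (we verified by direct marginal-likelihood
  evaluation that the likelihood is then maximised at a singular $C$), while
  the litters-per-group ratio implied by the real design (≈1.7 litter-sex
  cohorts per group) identifies it.
* **Pedigree**: discrete generations; litter sizes Poisson with mean 4.12;
  dams reused across litters (3.2 litters per dam, the ratio implied by the
  reported litter and dam counts) and sires serving ~8 litters, giving the
  half-sib family structure of a nucleus herd.
* **Fixed effects**: levels drawn once from centred normals (SDs 30 / 20 /
  10 g/day for year-month, sex, group-size class — magnitudes are not
  reported, these are plausible husbandry effects); age uniform on 135–165
  days with slope −2 (g/day)/day; intercept 804 g/day.
* **Genotypes**: founder frequencies uniform on [0.05, 0.5], Hardy–Weinberg
  founders, Mendelian gene dropping, *unlinked* markers placed uniformly on
  equal chromosomes.  Windowing tests need positional clustering, not
  realistic LD; nothing in the method does either.
* **Components**: the published posterior means for daily gain (direct
  2235, social 16, covariance 43, pen 43, group 227, maternal 48, litter
  218, early-life 17, litter covariance 36, residual 3299 (g/day)²).
* **Planted QTLs**: a marker (by id, or `"auto"` = the marker with realized
  frequency closest to 0.5) receives a stated fraction of the direct
  genetic variance; the polygenic remainder keeps the covariance structure.

A green simulation test therefore establishes that the estimation machinery
recovers the parameters of *this* world — multivariate-normal effects,
unlinked markers, random mating, no selection, no genotyping error — not
that it would do so under real LD, selection history, or pedigree errors.

# Known limitations

* At the mandated desk scale (1,500 records) several components are only
  weakly identified: the likelihood in the social variance and in the
  litter/early-life covariance is nearly flat, so their posteriors lean on
  the (vague) priors; the litter/early-life covariance in particular tends
  to centre near zero and its interval can clip a true value of ≈36 by a
  few units.  The full-scale data (≈21,500 records) do not have this
  problem.
* Single-site Gibbs mixes slowly across strongly confounded blocks
  (pen/group, litter/maternal); the default chain is sized for the reduced
  scale, and full-scale runs should use the 550k settings.
* The QC engine implements call-rate, monomorphic, MAF, Hardy–Weinberg
  (exact test) and sex-chromosome filters in a fixed order (the order is
  part of the contract; the filters do not commute).  Published threshold
  listings for this panel class are often ambiguous, so every threshold is
  an explicit argument; defaults are MAF ≥ 0.05, call rates ≥ 0.90,
  HWE p ≥ 1e-6.  No segregation-distortion filter is implemented (there is no
  standard definition to implement against).
* No metafounders, genetic groups, APY approximation, dominance, maternal
  genetic effects, multi-trait models, or REML.
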