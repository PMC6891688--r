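---
title: "Methods: analysing venom-profile evolution in replicated parasitoid lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing venom-profile evolution in replicated parasitoid lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomevol)
```

## The experimental system

venomevol analyses experimental-evolution studies in which hybrid parasitoid
wasps (F1 of a cross between two isofemale lines, here called ISm and ISy)
are propagated as replicated small populations on two strains of their
*Drosophila* host — one resistant (R), one susceptible (S) — and the venom
composition of individual females is read off 1D SDS-PAGE densitometry
profiles at several generations. The default design mirrors a typical study
of this kind: 8 replicates x 2 hosts x 3 assayed generations (F2, F6, F10)
x 10 females, with one F2 cell on the S host reduced to 4 females, i.e. 474
individuals. Each (replicate, host) pair is an experimental *population*;
every generation is propagated by 10 breeding females and 5 males. F2 is
treated as the first generation under selection, so trait trends are
parameterized in `generation - 2`.

Venom composition is quantified as the intensities ("heights") of a fixed
set of reference protein bands at known relative migration distances; the
two parental control lanes loaded on every gel anchor the reference set and
the *origin index* of each band,
`origin = I_ISm / (I_ISm + I_ISy)` (1 = purely ISm, 0 = purely ISy).

The package has five analysis layers, each usable alone:

1. **gel profiles** — from lane traces to a normalized band matrix;
2. **multivariate** — permutational MANOVA and replicate-centered LDA;
3. **band selection** — which bands changed, directly or indirectly;
4. **marker tests** — a simulation-based neutrality test for single venom
   marker loci under haplodiploid drift, and a mixed-model stage for a
   continuous marker;
5. **workflow** — a serialized, seeded pipeline over synthetic or
   user-supplied data.

A synthetic-data module generates every input with known ground truth, so
all stages are testable end to end without any laboratory data.

## Lane processing

`remove_background()` estimates the baseline of a lane by morphological
opening (rolling minimum then rolling maximum) with a window of 0.05
relative-distance units — wide compared with band peaks (default Gaussian
peak sd 0.006) and narrow compared with baseline drift. The resulting white
top-hat transform is idempotent and non-negative. `detect_peaks()` keeps
local maxima with topographic prominence at least 0.5 intensity units; the
default sits roughly ten noise standard deviations above the top-hat noise
floor while real bands have prominences of 1–5. Peak "height" is the
background-removed apex value.

`build_reference_set()` unions the control-lane peaks, merging peaks closer
than the matching tolerance `delta` (default 0.01); `match_reference_bands()`
assigns each detected peak to at most one reference band, greedily by
distance, and falls back to the profile value at the reference position so
the band matrix is always complete. `quantile_normalize()` equalizes the
intensity distribution across all lanes of the experiment jointly, replacing
each order statistic by its across-lane mean (ties receive the mean of the
order-statistic means they occupy; all-zero lanes are left as zeros with a
warning).

Two caveats that the synthetic studies make explicit. First, quantile
normalization fixes each lane's intensity multiset, so a genuine coordinated
rise of several bands is partly redistributed as an apparent fall of the
others — a compositional constraint inherent to the normalization, not an
artifact of this implementation. Second, at high band density adjacent
Gaussian tails overlap at the inter-band valleys, which perturbs the opening
baseline by a neighbor-dependent amount; extraction is therefore
rank-perfect on noise-free, fully resolved gels, and at the default 34-band
density achieves a median per-band Spearman correlation of about 0.99
against the simulated truth.

## Multivariate detection of venom evolution

`permutational_manova()` partitions the total sum of squares of the
Euclidean distance matrix among individuals. The squared distance matrix is
Gower-centered, `G = -1/2 J D^2 J`, and each term's sequential (Type-I) sum
of squares is `trace((H_k - H_{k-1}) G)` for the nested hat matrices of the
cumulative model in the order given — by default generation (continuous,
coded 2/6/10), host, their interaction, then population. Sequential SS are
used deliberately: host is constant within population, so a marginal test of
host adjusted for population is undefined (the package raises an aliasing
error if a term adds no rank). Significance is assessed by permuting
individuals within replicates only — individuals never cross replicates —
with the add-one convention `p = (1 + #{F* >= F}) / (n_perm + 1)`. An
explicit permutation matrix can be supplied instead, in which case the
p-value is the plain enumeration proportion; the test suite uses this to
match an exhaustive 720-permutation oracle exactly.

`discriminant_analysis()` solves the between- versus pooled within-group
SSCP eigenproblem for the six host x generation groups after
`replicate_center()` has removed replicate means (centering by population
would also absorb the host effect, so the 8 replicates are the centering
labels). The within-group matrix is ridge-regularized by
`1e-8 * trace / n_bands` by default; six groups give exactly five axes.
Eigenvector signs being arbitrary, `orient_axes()` flips axes so that axis-1
scores of S-host individuals and axis-2 scores of R-host individuals
increase with generation — the axes then read as "venom evolution on S" and
"venom evolution on R". `lda_permutation_test()` tests the between/total
inertia ratio with the same within-replicate permutation scheme.

A structural point the null simulations surfaced: population random effects
(drift) are genuine structure at the individual level. Two populations of
the same replicate differ by their drift histories, so with nonzero
between-population variance the within-replicate permutation null is
violated *by design* and host-group differences are detected even without
selection. Distinguishing drift from selection rests on the replication
logic — consistent direction across 8 independent replicates — not on the
permutation machinery. Calibration properties are therefore stated and
tested at the exchangeable null (iid responses independent of the design),
which is also the only null under which any permutation test is exact.

## Direct versus indirect selection on bands

`axis_correlations()` computes Spearman rank correlations (midranks,
t-approximation) between every band and the two oriented axes, Bonferroni-
corrected over the full 2B-test family. Because the axes are linear
combinations of the bands themselves, these correlations are only meaningful
when the groups are actually discriminated; `classify_band_evolution()`
therefore gates all selection calls on the overall discrimination p-value.
With the gate, the probability of calling any band selected on null data is
at the nominal level (measured 0.035 over 200 null experiments).

Bands are then clustered by UPGMA on `1 - |Pearson correlation|` and the
tree is cut at height 0.6, i.e. clusters of bands correlated at |r| >= 0.4 —
a deliberately conservative threshold. Within every cluster containing at
least two bands initially significant on the same axis,
`partial_axis_correlations()` regresses each band on the other bands of its
cluster and correlates the residual with the axes (Bonferroni over the
partial tests actually run); bands in unanalyzed clusters carry their
initial result forward. A band that tracks the axes only through its
correlation with a directly selected neighbour (gel overlap, linkage
disequilibrium) loses its signal at this stage, while the directly selected
band keeps the share of its trend not explained by the passenger.

The synthetic recovery scenario (`recovery_effect_spec()`) encodes exactly
this situation: five direct bands with a total intensity change of 1.5
residual standard deviations between F2 and F10, and three passenger bands
that are linear readouts of a direct band plus independent noise, at total
correlation 0.8. The total-change parameterization matters: the space of
linear generation trends over the design is two-dimensional (one direction
per host), so direct bands with very steep trends become mutually collinear,
cluster together, and no partial-correlation analysis can separate them —
the method's honest limitation, visible in real data whenever a cluster
holds several truly selected bands. With the default scenario the partial
stage retains 5.0/5 direct bands and discards 2.5/3 passengers on average
over 100 seeds.

## The haplodiploid drift test for marker loci

Under haplodiploidy, daughters are diploid (one maternal, one paternal
allele) and sons haploid (maternal allele only). For allele frequencies
`q_f` (females) and `q_m` (males) the infinite-population neutral recursion
is

```
q_f' = (q_f + q_m) / 2,      q_m' = q_f,
```

which conserves the copy-weighted frequency `(2 q_f + q_m) / 3` exactly.
From the F1 state of the ISm female x ISy male cross (`q_f = 0.5`,
`q_m = 0`), the expected allele-y frequency among females is 0.328125 at F6
and 0.3330078125 at F10 (`expected_frequency_trajectory()`); for a dominant
marker, the expected carrier frequency among daughters at generation *t* is
`1 - q_f(t-1) q_m(t-1)` (`expected_dominant_phenotype()`).

`simulate_wf_replicate()` is the finite-population counterpart: 10 breeding
females and 5 males per generation; each female takes one mate drawn
uniformly with replacement (monandry — the configurable alternative
`mating = "polyandry"` draws a sire per offspring); daughters and sons draw
uniform random mothers with Mendelian transmission; viability selection
acts by rejection sampling on offspring genotypes; and the genotyped females
are an additional, independent offspring sample (assayed females are never
breeders), so binomial observation noise is part of the model. The
simulator's variance matches the canonical haplodiploid variance-effective
size `Ne = 9 Nf Nm / (2 Nf + 4 Nm) = 11.25` for the default sizes, and its
mean tracks an independently coded deterministic selection recursion.

`drift_test()` compares the observed summary statistic — the signed mean of
(observed − expected frequency) over all replicate x assayed-generation
cells — with its null distribution from 20,000 simulated pseudo-experiments
of 8 neutral populations (`build_null_distribution()`). The expectations
used inside the statistic are the null-simulation means: for dominant
markers the infinite-population product formula ignores the positive
covariance drift induces between `q_f` and `q_m`, so the simulator mean sits
measurably below it (both are reported). The tail is chosen by the sign of
the observed statistic and the p-value doubles the add-one tail proportion,
`p = min(1, 2 (k + 1) / (n_sim + 1))` — a unilateral test, doubled. An
absolute-deviation statistic and per-generation restriction are available as
variants; the signed combined statistic is the default.

Calibration and power, measured by the test suite at the study design:
type-I error 0.05 ± 0.01 at nominal 0.05 over 1,000 neutral experiments; and
for female viabilities (1, 1, 0.5) against allele y, power ≈ 0.29 at
alpha = 0.05. That power is a property of the design, not of the test: the
deterministic selection response places the mean statistic at −0.113 while
the neutral spread of the statistic across 8 such small populations is
0.084, so the standardized effect is only ~1.4 at an effective one-sided
level of 0.025. Real detections at this design will typically be borderline.

## The continuous marker

A continuous venom marker measured by Western blot is normalized by
`corrected_lbgap2()` — the blot signal divided by the median raw
reference-band intensity of the same individual's silver-stained lane, a
proxy for the amount of venom loaded that cancels common exposure scaling.
`lbgap2_mixed_model()` Box-Cox-transforms the corrected intensity
(lambda = 0.23 by default, a profile-likelihood estimator is available),
fits a REML linear mixed model with the six host x generation cell means as
fixed effects and random intercepts for populations nested within
replicates (`nlme`), and performs single-step Tukey all-pairs comparisons of
the six cells (`multcomp`) with a compact letter display. The joint
comparison uses a multivariate *t* with the population-stratum degrees of
freedom (populations − hosts, 14 at the default design) rather than the
normal limit: host contrasts are population-level comparisons, and the
normal approximation understates the uncertainty of the estimated variance
components (measured family-wise error 0.09 with the normal limit versus
0.04 with the stratum t at nominal 0.05). When a variance component sits on
the zero boundary the default optimizer can stall; the fit is retried once
with `optim` and a convergence failure is reported, never silently replaced.

## Numerical and design choices

* Intensities are truncated at zero everywhere (silver-stain and
  densitometry signal cannot be negative); noise is therefore
  truncated-Normal in the generators.
* All p-values from permutation or simulation use the add-one convention,
  which keeps them positive and the tests valid.
* The within-cluster residual correlation of the band generator is
  factorized through the correlation matrix, so zero-variance bands are
  valid degenerate cases.
* Collinear bands leave numerically zero partial-regression residuals; their
  partial correlation is treated as undefined and non-significant.
* One ISm and one ISy control lane are emitted per simulated gel of 12
  individual lanes; the reduced default design cell is replicate 1, host S,
  generation 2 (fixed, arbitrary).
* `run_pipeline()` expands the master seed into fixed per-stage substreams,
  so any stage subset reproduces byte-identical files; stages communicate
  only through their serialized outputs.
* Monte-Carlo studies that need many replicated experiments are simulated in
  one batched stream (`drift_test_batch`), not by reseeding per experiment.

## Problem sizes used by the checks

The packaged studies are sized to run on a laptop in a few minutes: 1,000
neutral experiments against 2,000-simulation nulls and 500 null datasets for
the permutation-test calibrations; 20,000 replicates for the martingale
check; 100 seeds for the recovery study; 200 experiments against a
20,000-simulation null for the power study; 200 null fits for the Tukey
family-wise error. The corresponding statements above are the values these
runs compute; nothing is asserted that the suite does not measure.

## What the synthetic data do and do not show

The generators emulate the study design, block-correlated band intensities,
replicate random effects, host-specific trends, Mendelian haplodiploid
inheritance and the observation process. They do not emulate saturation,
spatial gel distortions, band identity changes across gels, linkage between
venom bands and the marker loci (bands and markers are independent modules),
mutation, or migration between replicates. Passing the packaged checks shows
the machinery is correct and calibrated under the stated model — not that
any particular biological dataset satisfies that model.
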