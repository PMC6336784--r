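---
title: "Measuring pre- and post-copulatory sexual selection with polysel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pre- and post-copulatory sexual selection with polysel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysel)
```

## The biological setting

`polysel` targets replicated group-mating experiments: each vial houses
one marked focal male, a set of rival males and a set of females (the
canonical design is 1 focal + 3 rivals with 4 females), observed over
several daily windows so that the complete mating history is known.
Offspring are counted per female and paternity is scored from a genetic
marker.  Because typical eye-colour marker schemes only make *daughters*
assignable, all fitness quantities in the package are daughter-based:
the package treats daughter production as the proxy for reproductive
success and makes no attempt to impute sons.

The scientific contrast of interest is between groups whose females
remate freely (high polyandry, e.g. females lacking the sex-peptide
receptor, which shortens the post-mating refractory period) and control
groups with ordinary remating rates.  Theory predicts that elevating
polyandry within an already polyandrous system compresses the variance
in male mating success — weakening pre-copulatory sexual selection —
while shifting the determination of reproductive success towards
post-copulatory paternity share.

## Fitness components and the exact product identity

For each focal male the package computes mating success `M` (unique
mates), mate productivity `N` (arithmetic mean daughters produced by his
mates), paternity share `P`, and reproductive success `T` (daughters
sired).  `P` is defined as the *pooled* share — daughters he sired
divided by all daughters his mates produced — rather than the average of
per-female proportions.  This choice is deliberate: with the pooled `P`
and the arithmetic-mean `N`, the identity

$$T = M \cdot N \cdot P$$

holds *exactly* for every male with at least one mate, which in turn
makes the variance decomposition below well-behaved.  The per-female
average proportion is still reported (`mean_share_per_mate`) for
descriptive use.  A male's `repetitive_rate` is his total copulations
divided by `M`, so 1 means he never remated the same female; the
"re-mating count" convention (`rate - 1`) is a trivial transformation of
the same column, and the ratio form is what the gradient models use.

One data-contract subtlety: a paternity record for a female the focal
male never mated is accepted when (and only when) it attributes zero
daughters to him.  Such records are legitimate — they carry the rival-
sired daughters that enter vial fecundity and per-female conservation
checks — whereas focal-sired daughters from a never-mated female indicate
corrupted data and raise an error.

## Opportunity for selection

The opportunity indices are standardised variances across the focal
males of a treatment: `I = var(T)/mean(T)^2`, `I_S` on `M`, `I_P` on
`P`.  Sample variance (n − 1 denominator) is used throughout, matching
the convention of standard statistical tooling.  Uncertainty is
percentile bootstrap (default 10,000 resamples of males with
replacement; the resampling unit can be set to whole groups, though with
one focal per group the two coincide).  Treatment differences are
declared only when the two intervals are disjoint — a conservative
convention that the comparison helper `compare_indices()` encodes.
Resamples on which an index is undefined (an all-zero draw) are dropped
and counted rather than silently imputed.

## Bateman gradients and their standardisations

The Bateman gradient is the least-squares slope of relative reproductive
success (T divided by its treatment mean) on mating success.  Two
standardisations are reported: mean-standardised (slope × mean(M)),
interpreted as the proportional change in relative success per
proportional change in mating success, and variance-standardised (slope
× sd(M)), the change per standard deviation — the maximum standardised
selection differential s'max, also called Jones' index.  The two scales
are linked through the coefficient of variation,

$$\beta^{\sigma} = \beta^{\mu}\,\mathrm{CV}_M
  = \beta^{\mu}\sqrt{I_S},$$

an identity the test suite verifies to 1e-10 through two independent
code paths.  Multivariate gradients regress relative T jointly on
mean-standardised `M`, `P` and `N`, so each coefficient is a partial
gradient controlling for the other components and their covariances;
the multivariate s'max variants use z-scored predictors in the same
model.  Vial fecundity (total daughters in the group) enters as a
continuous covariate and replicate block as a categorical one; the
repetitive-mating gradient uses replicate only.  Covariates that are
constant in a subset are dropped automatically, constant fitness
components are reported as `NA` rows (a constant carries no selection),
and genuine collinearity among varying predictors raises an error naming
the offending columns.

For significance testing of T-gradients the package refits the model
with square-root (Box–Cox) transformed raw T, which stabilises the
variance of the count response; reported gradients always come from the
standardised least-squares fits, and the transformed-refit p-value is
exposed alongside (`p_boxcox`).  General Box–Cox lambda estimation is
deliberately out of scope.  Cross-treatment gradient differences are
tested by the t-statistic of the treatment-by-predictor interaction in a
pooled model after within-treatment standardisation, so the interaction
coefficient is literally the difference of within-treatment slopes.

## Variance decomposition

Dividing T, M, P, N by their treatment means, the variance in relative
reproductive success is apportioned, delta-method style, into the three
component variances, the three pairwise covariances (each entered once)
and a residual `D` defined so the ledger

$$\mathrm{var}(T) = \mathrm{var}(M) + \mathrm{var}(P) + \mathrm{var}(N)
 + \mathrm{cov}(M,P) + \mathrm{cov}(M,N) + \mathrm{cov}(N,P) + D$$

closes exactly on every input.  Whether published tables of this form
absorb the conventional factor 2 into their covariance entries is often
unstated; defining `D` as the closing residual makes the output
well-defined under either convention, and the residual itself absorbs
the higher-order terms of the expansion of a product of three non-
independent factors.  Percent contributions are descriptive, with the
denominator configurable (`var_T`, the default, or the component sum),
because no single denominator reproduces every published percentage
column we are aware of.

## Mating networks, SCI and the randomization null

Each vial's mating matrix is the binary male × female incidence of
unique mating pairs.  A male's sperm competition intensity is the
harmonic mean of his mates' polyandry,
`SCI_i = M_i / sum_j (1/k_j)`, and the SCI correlation (SCIC) is the
least-squares slope of mean-standardised SCI on mean-standardised M over
*all* males, focal and rival.  Negative SCIC means the most polygynous
males monopolise the least polyandrous females.

Non-zero SCIC arises easily by chance, so observed values are referred
to a null in which, within every vial, the binary matrix is replaced by
a uniform draw from all binary matrices with the same row and column
sums — every male's and female's number of partners is preserved while
the pairing is randomised.  Copulation multiplicities are deliberately
not shuffled: the null randomises the *identity* of copulating pairs at
fixed mating-success variation.  The sampler enumerates the fixed-margin
family exhaustively whenever it has at most 10,000 members (which covers
every 4 × 4 vial) and samples it uniformly; larger matrices use a
checkerboard-swap Markov chain written in C++ (burn-in and thinning both
default to 100 × the number of 1-entries; the proposal is symmetric and
stays in place on invalid swaps, so the stationary distribution is
uniform).  Uniformity is verified in the tests against exhaustive
enumeration and against an independent curveball sampler.  Vials whose
margins admit a single matrix are passed through and flagged, and all
three tail probabilities are reported (`p_lower`, the share of null
values at or below the observed SCIC, is the headline under the
directional hypothesis of negative SCIC; the tail convention is a
reporting choice, not a property of the null).

A structural feature worth knowing: because margins are preserved, a
male's SCI changes under the null only when a swap exchanges females of
*different* polyandry.  In heavily saturated vials most females share
the same polyandry, so the null SCIC distribution collapses towards the
observed value — saturation restricts the range of attainable SCIC and
pushes it negative, which is precisely the mechanism the statistic is
designed to expose.

## The simulator

The generator reproduces the experimental design generatively so that
every downstream stage has a test bed with known truth.  Within each of
`window_slots` opportunities per daily window, one currently receptive
female (uniform among receptive ones) mates a male drawn proportionally
to mating propensity; her receptivity then lapses for a geometric number
of slots.  The geometric refractory clock is the simplest one-parameter,
memoryless receptivity model that reproduces the phenotype of interest:
a short mean (default 4 slots) yields high polyandry, a long mean
(default 24 slots) control-like remating.  After the last day each
female that mated draws daughters from
`Poisson(fecundity_mean × multiplier × n_days)` and sires are drawn
multinomially with tickets equal to copulation counts, the final mate's
tickets multiplied by `last_male_weight` (default 1 — a fair raffle;
values above 1 emulate last-male sperm precedence).

Default parameters encode the design the package targets: 29 groups per
arm of 1 focal + 3 rivals and 4 females over 4 days; focal propensity
1.5 so the focal male takes about one third of matings against three
rivals; 12 slots per 4-hour window (a free abstraction — per-slot mating
kinetics are not calibrated to data); 12 daughters per female per day,
with a multiplier of 0.85 in the high-polyandry arm reflecting the
slightly reduced productivity of receptor-lacking females.  These
defaults are the simulation's definition of the study conditions and are
not adjusted per analysis.

What the simulator does *not* model: courtship and male–male
interference, sperm-storage kinetics, egg-to-adult survival variation,
and any male quality differences beyond the single focal-propensity
knob.  Consequently, passing the simulation-based checks demonstrates
that the *pipeline* recovers the qualitative consequences of elevated
polyandry from data of this structure; it does not validate the
biological realism of any particular mechanism, and absolute magnitudes
of the indices in simulation are smaller than in real data, where male
variation is larger and paternity is far from a fair raffle.

## Numerical and testing choices

Randomness is always funnelled through explicit seeds; library calls
restore the caller's RNG state.  The pipeline derives per-stage seeds
from one top-level seed so stages are independently reproducible.
Degenerate inputs follow a uniform policy: quantities undefined for a
male (SCI with no mates, P with no daughters) are `NA` and excluded with
counts, while structurally impossible requests (opportunity index of a
zero-mean vector, gradients with fewer than 3–5 males or zero predictor
variance) raise errors.  Stochastic directional properties of the
paired-treatment simulation — lower `I_S` in the high-polyandry arm,
overlapping `I_P` intervals, the shift of variance shares from `M` to
`P`, the steeper repetitive-mating gradient under last-male weighting —
are evaluated over a fixed ensemble of seeds with a majority criterion,
because single realisations of interval-overlap checks sit close to the
decision boundary at realistic effect sizes; deterministic identities
(the ledger, the CV identity, closed forms) are tested to 1e-8–1e-12.
Test problem sizes (100 groups per arm for directional checks, 50,000
draws for sampler uniformity, 10,000 bootstrap resamples) were chosen to
keep Monte-Carlo error comfortably below the effects being asserted.

## Using the package on real data

Three delimited tables (comma or tab, chosen by extension) drive the
analysis: events (`group_id, replicate_id, treatment, day, order,
male_id, female_id`), paternity (`group_id, female_id, daughters_focal,
daughters_other`) and roster (`group_id, treatment, id, sex, role`).
`run_pipeline()` chains reading/validation, summarisation, indices,
gradients, decomposition and the SCIC null into one seeded run whose
configuration, logs and tables land in a single output directory.  For
trio-style datasets (each female mated exactly twice, both shares
known), `resample_focal_ip()` applies the focal-male resampling
estimator of `I_P`: per iteration one male per trio is labelled focal,
so that each trio contributes exactly one share, and iterations are
independent across repetitions — our reading of sampling "without
replacement" within an iteration.

## Known limitations

Only daughters are modelled; paternity share of full broods is
unobservable under the marker scheme.  The bootstrap is percentile (not
BCa).  The randomization preserves binary margins, not copulation
multiplicities.  Degrees of freedom in pooled cross-treatment tests
follow the pooled-model convention and may differ from other reasonable
choices.  The simulator's slot-level kinetics are an abstraction, so
quantities that depend on absolute mating rates (e.g. raw mating
frequencies) should not be compared numerically against real data.
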