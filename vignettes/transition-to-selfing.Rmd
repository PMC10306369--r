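---
title: "Dating transitions to self-fertilization: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating transitions to self-fertilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfkit)
```

## The model

selfkit studies a single population of `N` diploid individuals in which each
offspring arises by self-fertilization with probability `sigma` and by
outcrossing otherwise. At equilibrium, partial selfing inflates homozygosity
to the inbreeding coefficient `F = sigma / (2 - sigma)`, which rescales the
two population-scaled rates in opposite directions relative to a naive
size change:

* effective population size: `N_sigma = N / (1 + F)`;
* effective recombination rate: `r_sigma = r (1 - F)`;
* hence `rho_sigma = 4 N r (1 - F) / (1 + F)` and
  `theta_sigma = 4 N mu / (1 + F)`.

Because recombination is suppressed by `(1 - F)` while drift is accelerated
only by `1 / (1 + F)`, a *dated* switch from outcrossing to predominant
selfing at time `t_sigma` changes the ratio `rho/theta` through time, and
this is distinguishable in principle from any history of population-size
changes alone. `selfing_rescalings()` exposes the algebra;
`transition_scenario()` and `epoch_model()` describe piecewise-constant
histories of `(N, sigma, r)` in generations before present (half-open
epochs, right-continuous lookups).

For a sample of size two with coalescence time `s`, the probability that an
effective recombination event falls on the genealogy is

```
p(rec | s) = 1 - exp( - Int_0^s 2 (1 - sigma_k) (2 - sigma_k)^-2 r_k dk ),
```

implemented in closed form by `recomb_prob_given_tmrca()`, summing the
piecewise-constant integrand across epochs. We keep this printed form
exactly as stated, including its time-unit convention: at `sigma = 0` the
exponent is `r s / 2` per pair, whereas the simulators use the physically
explicit pair hazard `2 r (1 - F)` (two branches, each with effective rate
`r (1 - F)`). The two conventions differ by a constant factor by design; the
analytic operation is a faithful transcription while the simulators are
calibrated against a forward Wright-Fisher oracle (see below), and no silent
reconciliation between the two is attempted.

## Simulators

Three generators with one output contract: T_MRCA-segments are maximal runs
of contiguous sites sharing a pairwise MRCA, delimited by *consequential*
recombination events; silent events of the SMC' kind never create
boundaries.

**Pairwise sequential simulator** (`simulate_pair()`). Works directly in
natural time. The first coalescence time is drawn from the inhomogeneous
pairwise coalescent with rate `(1 + F(t)) / (2 N(t))`. Along the genome the
distance to the next breakpoint is exponential with per-bp hazard
`H(s) = Int_0^s 2 r (1 - F)`. At a breakpoint, the detachment height `u` has
density proportional to the hazard on `[0, s]`; below `s` the floating
lineage meets two branches (total rate twice the pairwise rate), and half of
those events rejoin its own ancestral branch, which is silent; an event on
the partner branch sets the new MRCA to the event height, and failing both,
the lineage coalesces with the root branch above `s`. This transition has
the stationary pairwise law as its invariant: under a constant model the
marginal T_MRCA at any position is exponential with rate `(1+F)/(2N)`, which
the tests verify, along with the stationary negative covariance between
segment age and length.

**Multi-sample simulator** (`simulate_sample()`). The coalescent-with-
selfing prescribes, at time `t`, pairwise coalescence at `(1+F)/(2N)` and
per-lineage effective recombination `r (1 - F)`. We realise this law through
the time change `dtau = (1 - F(t)) dt`: in rescaled time, recombination runs
at the plain rate `r` while the effective size becomes
`N (1 - F) / (1 + F)`, so standard machinery applies. Genealogies are
generated sequentially along the genome with the SMC' transition (detach at
a hazard-weighted point of the local tree; re-coalesce into the original
tree, own-branch events silent), node times are mapped back through the
piecewise-linear inverse time change, and mutations fall on branches at rate
`mu` per bp per *generation* (i.e. natural-time branch lengths), which
automatically supplies the `mu / (1 - F)` intensity on rescaled intervals.
The sequential formulation keeps the cost linear in the number of
recombination events, making reference tables of thousands of simulations
practical on one core; its marginal genealogies are exact, while
correlations along the genome carry the Markov approximation — the same
approximation the segment analytics themselves assume. Selfing rates are
capped at 0.999 here (at `sigma = 1` the time rescaling degenerates);
`simulate_pair()` handles full selfing, where the answer is a single
segment. Breakpoints are continuous and floored to integer bp on output;
zero-length pieces are dropped; mutation position collisions on the same
integer site are dropped (infinite sites on integers).

**Forward Wright-Fisher oracle** (`simulate_wf_oracle()`). An explicit
diploid forward simulation — offspring self with probability `sigma`, else
outcross between two distinct parents; meioses place crossovers at `r` per
bp — whose stored pedigree is traced backwards to extract exact
T_MRCA-segments for sampled chromosome pairs, and which tracks mutations
forward when `mu > 0`. It is deliberately restricted to `N <= 2000` and
`L <= 100` kb: it exists to check the coalescent approximations, not to
generate data. Under full selfing, lineages in different individuals never
coalesce, so the `pair_mode = "within"` option samples both chromosomes of
an individual — the configuration in which complete selfing predicts exactly
one segment. Intervals that fail to coalesce within the simulated
generations are reported with `NA` ages; with the burn-in of at least `10 N`
generations enforced by the function this censoring affects well under one
percent of pairs.

## Segment analytics

`time_grid()` discretizes time with bin boundaries `-8 N_ref ln(1 - i/m)`
(natural log), the familiar coalescent-HMM spacing: uniform coverage under a
constant-size pairwise coalescent. The reference size and `m = 20` default
are descriptive choices; nothing downstream depends on them analytically.
`tl_summaries()` reports the joint (log10 age, log10 length) distribution
and its covariance — negative and constant under constant selfing, with a
characteristic break at `t_sigma` after a transition. `tm_true()` counts
transitions between the age bins of adjacent segments; rows without
observations are emitted as zero rows and flagged rather than smoothed,
because the matrix is used descriptively, not as a likelihood. Ages exactly
zero cannot arise from the simulators and map to the first bin if supplied
from external data.

## Summary statistics for inference

Three summaries, separately or concatenated (`summary_vector()` with specs
`sfs_ld`, `tmwin`, `all`):

* **Unfolded SFS** — raw counts of derived-allele frequencies `1..n-1`.
  Counts are not normalised by sequence length because observed and
  simulated data share it by construction.
* **LD decay** — mean haplotype `r^2` in physical-distance bins with
  breakpoints 6105, 11379, 21209, 39531, 73680, 137328, 255958, 477066,
  889175 bp; at most 10,000 sites enter, and at most 200,000 site pairs are
  evaluated (uniformly sampled beyond that). Pairs closer than the first
  breakpoint are excluded. Empty bins are encoded as 0 with a companion 0/1
  missingness flag so the vector keeps a fixed length.
* **TM_win** — the package's key statistic: pairwise diversity is summed in
  non-overlapping windows of `omega = 10` kb for a sample of size two, each
  window count is assigned to a diversity class, and the matrix of
  class-to-class transitions between adjacent windows is flattened
  row-major. Windows discretize the clustered low/high-diversity mosaics
  that dated transitions leave along chromosomes. Matrices are averaged over
  up to 15 haplotype pairs chosen deterministically under the seed.

The diversity-class edges are a calibration, not a constant: they are set at
the 12.5, 25, ..., 87.5 percentiles (eight classes) of window counts pooled
over a pilot batch of 1,000 prior-predictive simulations
(`calibrate_class_edges()`, run with the pairwise simulator since only
two-haplotype counts are needed), deduplicated over tied integer quantiles,
then frozen and stored with the reference table. Observed and simulated data
must be discretized with identical edges for the ABC distances to mean
anything, which is why every TM_win entry point demands explicit edges.

Multi-locus datasets are summarised per locus and averaged element-wise.

## The ABC machinery

Two competing demographies: model 1 holds `N` constant and lets `sigma`
jump from `sigma_anc` to `sigma_pres` at `t_sigma`; model 2 holds `sigma`
constant and lets `N` jump at `t_N`. Default priors (declared in
`model1_prior()` / `model2_prior()`, easily overridden): log-uniform
`[1e3, 1e6]` for sizes, log-uniform `[1e2, 1e6]` generations for change
times, uniform `[0, 0.2]` for `sigma_anc`, uniform `[0.8, 0.999]` for
`sigma_pres`, and uniform `[0, 0.999]` for model 2's constant rate.

`build_reference_table()` simulates the prior predictive, fits a per-column
centre/scale normaliser (zero-variance columns dropped and recorded), and
`fit_pls()` adds a supervised linear map: partial least squares regression
of the parameters (log10 scale for log-uniform ones) on the normalised
statistics, 20 components by default. `abc_reject()` takes Euclidean
distances on the PLS scores (or the normalised statistics if no PLS is
fitted) and accepts the closest `tolerance` fraction — 1% by default, with
ties at the cutoff broken by row order. A local-linear regression
adjustment of the accepted draws (`adjust = "loclinear"`) is provided but
disabled by default: with sharply bounded priors, and a posterior that is
often truncated at the detection horizon, the linear shift tends to
overcorrect, shrinking credible intervals below their nominal coverage in
our calibration runs, so plain rejection is the reported posterior. Default table size in the tests is
5,000 rows per model; applications use much larger tables (the shipped
`athaliana_preset()` documents 20 PLS components and a 130,000-row
table as the reference A. thaliana settings).

**Model choice.** The pooled two-model table is normalised jointly and
projected by PLS-DA against the model label (20 components), the
classification analogue of the parameter-side PLS. On that projection two
estimators of `P(m1 | obs)` are available. Plain rejection counts model
labels among the accepted rows — simple, but an inefficient density-ratio
estimator when the two prior predictives overlap: its detection curve
flattens and can even invert across transition ages, because the nearest-
neighbour label fractions saturate around the prior odds. The default is
therefore the classical local-regression estimator: a logistic regression
of the model label on the projected statistics, fitted over the 10% of rows
nearest the observation with Epanechnikov weights in distance and evaluated
at the observation. The window size and component count were chosen by
cross-validation on held-out reference-table rows (classification of table
rows whose true model is known), never on the evaluation datasets. Bayes
factors are `P(m1|obs) / P(m2|obs)` under equal model priors, capped and
flagged when an estimate is degenerate, with "transition detected" declared
at `BF >= sqrt(10)`. Both estimators remain available
(`method = "rejection"` / `"logistic"`); rejection keeps the exact
acceptance-fraction contract that the unit tests pin down.

**Posterior summaries.** `posterior_summary()` follows the
averaged-posterior convention: per replicate, a Gaussian kernel density
(bandwidth by the standard reference rule) of the accepted values on a fixed
512-point grid spanning the prior support (log10 scale for log-uniform
parameters); densities are averaged across replicates and the mode is the
grid argmax; credibility intervals are quantiles of the pooled accepted
draws. A degenerate acceptance set (all values equal) yields that value as
mode with a zero-width interval.

## What the synthetic data emulate — and what they do not

The generators reproduce the study conditions: neutral polymorphism under
piecewise-constant `(N, sigma, r)`, the validation scenario with `N =
40,000`, `sigma` jumping 0.1 to 0.99, `mu = r = 1e-8`, and the
signature scenarios at `N_sigma` 26,250/50,000 with `r = 3.6e-9`. They do
not emulate selection (background selection magnified by selfing is a known
robustness concern addressed in the literature, out of scope here), gene
flow or structure, seed banks, variable recombination or mutation rates
along the genome, genotyping or phasing error, or missing data beyond
explicit masks. Passing tests therefore demonstrate correctness of the
method under its own model, and nothing about those violations.

## Problem sizes in the test suite

The validation experiments in the tests run at reduced dimensions chosen as
the package's own trade-off between statistical resolution and a test suite
that completes comfortably on a single core: reference tables of 5,000 rows
per model over datasets of 8 haplotypes on two 500-kb loci; 30 recovery
datasets with true transition ages drawn log-uniformly over `[1e3, 2e5]`
generations (the validated range; data-generating values otherwise fixed at
the `N = 40,000`, 0.1 to 0.99 scenario); 25 model-choice datasets per
transition age at 5,000 and 20,000 generations; forward-oracle concordance
at `N = 500` over 50-kb chromosomes with 500 pairs per selfing rate; and
signature comparisons on 10-Mb pairwise chromosomes with eight replicates
per scenario. The full-scale validation design (20
haplotypes, five 1-Mb loci, 100 datasets per age) is cluster-scale work;
`validate_performance()` runs it unchanged given the larger tables.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open bp internally, converted only at file
boundaries (VCF 1-based inclusive; BED 0-based half-open). Epochs are
half-open in time. Single-segment series have undefined TL covariance
(`NaN`, flagged by count). `tm_true()` requires two segments; `tm_win()` two
windows; a single diversity class returns the trivial matrix `[1]`.
Monomorphic alignments give all-missing LD bins. Ties in rejection
distances resolve by row order; integer ties in pilot window-count quantiles
are deduplicated, so fewer than eight classes can result. All randomness
flows through R's RNG — a seed argument (or an enclosing `set.seed()`)
reproduces every simulator byte-for-byte.

## Known limitations

* The multi-sample simulator is sequentially Markovian; long-range
  identity-by-descent beyond the SMC' horizon is approximated. The forward
  oracle bounds the practical error at test scale.
* `sigma = 1` is exact only in the pairwise path.
* The rejection-count Bayes factor is reliable only far from prior-
  predictive overlap; use the default logistic estimator for model choice.
* Ancestral-allele polarisation of real data defaults to REF-as-ancestral;
  supply an `AA` INFO tag when available, or the unfolded SFS is
  misspecified.
* The class-edge calibration conditions on the model-1 prior; transferring
  tables between incompatible priors requires re-calibration.
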