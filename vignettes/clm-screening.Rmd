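---
title: "Pooled screening of whole-cell redox biocatalysts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled screening of whole-cell redox biocatalysts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clmscreen)
```

## The screening problem

Finding a microorganism that performs a wanted biotransformation — here,
reducing a prochiral ketone to an enantiopure secondary alcohol — normally
means culturing every strain of a library, incubating each with the
substrate, and following every incubation by chromatography. For a library
of $n$ strains and $m$ substrates that is $n \times m$ assays, most of which
return "inactive".

Pooled (group-testing) screening cuts this cost. Strains are distributed
over a small number of incubation *batches* so that each strain occupies a
characteristic subset of batches, its **signature**. One GC measurement per
batch then constrains which strains can be active: under the *union model*,
a batch shows activity if and only if it contains at least one active
strain, so the set of active batches (the **hit set**) must be the union of
the active strains' signatures. Decoding the hit set back to strains needs
no further chemistry, only combinatorics; ambiguities are resolved by a
handful of confirmatory single-strain incubations.

`clmscreen` implements this workflow end to end for whole-cell
ketone-reduction / alcohol-oxidation screening: design construction and
validation, a kinetic simulator producing realistic batch readouts,
hit-calling and union-model deconvolution with anomaly flagging, the
stereochemical algebra used to reason about enantioselective redox activity,
and a least-squares fitter for rate constants.

## Pooling designs

A design is a binary strain-by-batch incidence matrix with constant column
sums (the pool size). `build_design()` fills the $b \times k$ slots by a
seeded random shuffle under replication quotas: with $n$ strains, each
strain is replicated $\lfloor bk/n \rfloor$ or $\lceil bk/n \rceil$ times,
its copies always landing in distinct batches. For the canonical
12-strain, 4-batch, pool-size-5 library this puts 8 strains in two batches
and 4 in one. Construction retries the shuffle (boundedly) until the
within-batch-uniqueness — and, if requested, distinct-signature —
constraints hold, and fails with an explicit *capacity error* when the
request is infeasible (more strains than slots, or more distinct
signatures demanded than exist: over $b$ batches only
$\sum_r \binom{b}{r}$ signatures of the allowed replications $r$ are
available). Nothing is silently relaxed. Note that the canonical 12/4/5
library *cannot* have all-distinct signatures — its 8 doubly-replicated
strains would need 8 of the $\binom{4}{2} = 6$ available pairs — which is
exactly why two-candidate decodes and confirmatory assays arise in
practice.

`validate_design()` quantifies decodability: a design is
$d$-**separable** when unions of up to $d$ signatures are pairwise
distinct, so any hit set produced by at most $d$ active strains has a
unique explanation. Separability is checked by exhaustive subset
enumeration; the designs this package targets are small (tens of strains,
a handful of batches), so no algebraic $d$-disjunct construction is
attempted. `assay_count()` does the economics: one pooled round costs
(batches × substrate mixtures) incubations against (strains × substrates)
for the conventional approach, plus one confirmatory incubation per
unresolved candidate.

## Kinetic model

Within one incubation the ketone $K$ and the two alcohol enantiomers $R$,
$S$ (fractions of initial material; $K+R+S$ conserved) follow parallel
first-order reduction and oxidation:

$$
\begin{aligned}
dK/dt &= -(k_{red,R}+k_{red,S})\,g(t)\,K + \varphi\,(k_{ox,S} S + k_{ox,R} R)\\
dR/dt &= k_{red,R}\,g(t)\,K - \varphi\,k_{ox,R} R\\
dS/dt &= k_{red,S}\,g(t)\,K - \varphi\,k_{ox,S} S
\end{aligned}
$$

The two reduction constants cover, without distinguishing, the two
mechanistic hypotheses for a poorly selective reduction — one unselective
alcohol dehydrogenase, or two dehydrogenases of opposite
enantiotoposelectivity. The model deliberately stays first-order: at the
1–2 g/L substrate loads typical of resting-cell incubations the enzymes
are far from saturation, so no Michaelis–Menten terms, cofactor balances
or dissolved-oxygen transport are included. A documented consequence is
that concentration-dependent selectivity (anaerobic ee varying with
ketone concentration) is outside the model class.

**Oxygen.** $\varphi \in [0,1]$ multiplies the oxidation rates only:
$\varphi = 0$ reproduces anaerobic incubation exactly (an oxidase cannot
run without O$_2$), $\varphi = 1$ is a fully aerated suspension. Dense
resting-cell suspensions consume oxygen for maintenance at the expense of
the oxidase, so `oxygen_factor_from_biomass()` maps wet-biomass density to
$\varphi = h/(h + \text{biomass})$ — 1 at zero biomass, halved at the
half-saturation density $h$ (default 100 g/L, the middle of the 50–150 g/L
range over which the biomass effect is typically observed), strictly
decreasing. Only the direction of this dependence is empirically
constrained; the hyperbolic form is the package's choice, and only
order/monotonicity conclusions should be drawn from it.

**Reductase deactivation, $g(t)$.** By default $g(t) = 1$ and the system
is time-invariant. That time-invariant system has a sharp structural
property: started from pure ketone with $k_{ox,R}=0$, the ketone fraction
is strictly decreasing (at any critical point of $K$,
$K'' = -\varphi^2 k_{ox,S} k_{red,R} K < 0$, so no interior minimum
exists), hence total alcohol $1-K$ can only rise. A *falling* product
curve between two sampling times — the tell-tale of tandem
reduction-then-oxidation observed in pooled batches — therefore requires a
mechanism outside the time-invariant model. The package models the
biologically standard one: resting cells progressively lose reduction
activity (NAD(P)H regeneration fades) while the oxygen-driven oxidase
persists, as an optional exponential decay
$g(t) = e^{-\lambda t}$ (`red_decay`, default 0, applied to the reduction
rates only). With it, alcohol accumulates fast while reduction lives, then
the persistent (S)-oxidase pulls the product back down: a non-monotone
total-alcohol curve. Mass conservation and the anaerobic closed form below
are unaffected (a common decay factor cancels from the ee ratio).

**Closed forms.** Under anaerobic conditions from pure ketone both
alcohols accumulate proportionally to their formation rates, so the
alcohol ee is time-independent:
$ee = (k_{red,R}-k_{red,S})/(k_{red,R}+k_{red,S})$
(`anaerobic_alcohol_ee()`). With oxidation only (no reduction) the
(R)-pool can never grow, giving the yield bound of the next section. With
$k_{ox,S}>0$, $k_{ox,R}=0$ and any re-reduction $k_{red,R}>0$, $R$ is the
only absorbing species and the system deracemizes completely
($R \to 1$).

Integration uses `deSolve::lsoda` (adaptive, stiff-capable) at absolute
tolerance $10^{-9}$ and relative tolerance $10^{-8}$; fixture rate ratios
reach $\sim 10^3$ and trajectories conserve mass to well under the
$10^{-6}$ the property tests assert. Degenerate inputs (all rates zero,
empty pools) return flat trajectories rather than errors; ee is reported
as `NA` while no alcohol exists.

## Stereochemical algebra and the re-reduction inference

All ee values are signed fractions with (R) positive, and all yields are
molar fractions of initial material — percentages appear only at
reporting edges. `ee_from_amounts()` / `split_from_ee()` are exact
inverses:
$R = \text{total}\cdot(1+ee)/2$, $S = \text{total}\cdot(1-ee)/2$.

The inferential core is `max_R_yield_oxidation_only()`: if oxidation is
the *only* available reaction, the (R)-alcohol yield from a starting
alcohol of excess $ee_0$ is bounded by its initial share $(1+ee_0)/2$ —
50% from a racemate. An observed (R)-fraction strictly above the bound
proves concurrent ketone re-reduction, i.e. a tandem
stereoinversion rather than a simple kinetic resolution
(`infer_reduction_present()`; equality is deliberately *not* taken as
evidence — conservative inference at the boundary). For example, an
incubation of racemic alcohol ending at 15% ketone with 83% ee residual
alcohol implies an (R)-fraction of $0.85 \times 1.83/2 = 0.77775$,
exceeding the bound by 0.27775.

`kinetic_resolution_E()` supplies the standard selectivity measure
$E = \ln[(1-c)(1-ee_s)] / \ln[(1-c)(1+ee_s)]$ for irreversible
resolutions. When the residual-substrate ee saturates at 1 to machine
precision the selectivity is indistinguishable from infinity and a capped
sentinel (1000) is returned; when a back-reaction is known to be active
the estimate carries a caveat attribute instead of pretending validity.

## The synthetic-data generator

`generate_strain_profiles()` draws per-strain, per-substrate rate sets
from documented priors chosen to emulate a small yeast library under
resting-cell conditions: 60% of strains fully inactive (most of a random
library does nothing to any one substrate), active strains drawing total
reduction rates uniformly from 0.02–0.35 h$^{-1}$ (single-strain 24 h
conversions from ~40% to ~100%, 4 h conversions 8–75%) with uniform
enantioselectivity, and 15% of active strains carrying an additional
oxygen-dependent (S)-oxidation of 0.1–0.5 h$^{-1}$. Pooling combines
members as *parallel catalysts* — rates add, because each strain
contributes its own cells at full density (suspensions are prepared per
strain and merged volumetrically), not by competing for a shared slot.
Measurement noise is multiplicative Gaussian on conversion (sd 0.03,
clipped to [0,1]); no error model is empirically available, and 3% is a
routine day-to-day GC reproducibility figure. Sampling at 4 h and 24 h
mirrors standard practice.

`make_study_fixture()` pins down, deterministically, the full two-library
study scenario: batches A–D and E–H (12 strains, pool size 5 each), three
two-ketone mixtures (2-octanone + acetonaphthone and 3-octanone +
propiophenone for the first library; 3-octanone + acetophenone for the
second), and ground-truth profiles engineered to produce every decoding
situation of interest — a unique batch-D aliphatic reducer, an {A,D}
signature collision between two aromatic reducers, a batch-B-exclusive
suspected oxidizer (with the alternative excreted-inhibitor hypothesis
switchable via `batch_b_mode`, since resting-cell metabolism makes
inhibitor production unlikely but the data alone cannot decide), a
batch-E fast 3-octanone reducer, a propiophenone-inhibited batch-B
3-octanone reducer (control/assay divergence), and the {E,F} tandem pair:
fast, deactivating acetophenone reducers pooled with a persistent
oxygen-dependent (S)-oxidizer whose signature-mate is inactive. The batch
memberships are a *synthetic reconstruction* satisfying the reported
membership constraints, not a transcription of an original table (none is
available in-text); they ship as
`inst/extdata/design_clm[12]_synthetic.csv`.

What the generator does **not** emulate — growth-phase physiology,
substrate toxicity, cofactor pools, metabolite-level inhibition mechanisms,
GC integration artefacts — bounds what green tests mean: they validate the
decoding and inference machinery against the model class, not the wet lab.

## Decoding, anomalies, confirmation

`call_hits()` applies an absolute conversion threshold (default 0.5 at
24 h) per substrate; the underlying comparisons in practice are
qualitative ("best" vs "low" reduction), so the threshold is a package
choice, kept explicit and reported with the scores. Missing batches are a
hard error: a hit set computed from partial data would decode to wrong
candidates. Raising the threshold can only shrink the hit set (tested as a
property).

`candidates()` enumerates every strain set of size ≤ `max_actives`
(default 1, the usual operating assumption per channel; exhaustive up to
~3) whose signature union equals the hit set, using bitmask arithmetic
with a containment pre-filter; the test suite proves it equivalent to
naive brute-force enumeration over all small designs. Reports order
candidate sets smallest-first, then lexically. A hit set explainable by no
such union returns an *explained empty* report (noise or tandem effects
suspected), not an error.

Tandem activity breaks the union model by construction — an oxidizer
*removes* the very product the hit-calling measures. It is therefore
handled as a separate channel: `flag_anomalies()` flags
`non_monotone_product` when the pooled product falls between timepoints by
more than 0.10 (absolute), and `control_assay_divergence` when single-
substrate control and mixture assay differ by more than 0.20; the batches
flagged non-monotone are then decoded directly as their own hit set. The
margins are set well above the noise scale: with 3% multiplicative noise a
0.10 drop is a $\gtrsim 2.4\sigma$ event even for near-saturated
conversions, though the implied false-positive probability is *not* zero —
on plateaued curves near conversion 1 it is roughly
$\Phi(-0.10/(0.042)) \approx 0.8\%$ per batch — so the zero-false-flag
property is asserted on noiseless oxidation-free simulations (200 profile
seeds), and noisy-readout behaviour is tested at the fixture's actual,
non-saturated conversions. Divergence-implicated batches contribute a
*suspicion* field (their exclusive strains) kept deliberately separate
from candidate sets: interference evidence disqualifies a channel, it does
not identify an active reducer.

`plan_confirmation()` converts ambiguity into wet-lab work: one
individual assay per unresolved candidate strain (zero for unique
decodes; a warning-carrying fall-back to all strains of the implicated
batches for inconsistent patterns). `run_study()` chains everything on
the fixture and accounts: 12 pooled incubations (4 batches × 2 mixtures
+ 4 × 1) plus 4 confirmations — the two aromatic-reducer candidates and
the two tandem candidates, each confirmed once as a strain — against
24 strains × 5 substrates = 120 conventional assays. Tandem candidates
are confirmed on the racemic *product alcohol* (does the strain transform
it?), reductive candidates on the ketone.

## Parameter fitting

`fit_redox()` recovers the four rates from observed $(K,R,S)$ time
courses by bounded Levenberg–Marquardt (`minpack.lm::nls.lm`, rates
$\ge 0$), stacking residuals across series with per-series fixed oxygen
factors and initial states. Identifiability is diagnosed, not assumed: the
oxidation rates are structurally invisible in anaerobic-only data
($\varphi = 0$ multiplies them away), which is reported via an
`unidentifiable` flag backed by a finite-difference Jacobian column-norm
check; standard errors come from the usual
$\hat\sigma^2 (J^\top J)^{-1}$ approximation restricted to identifiable
parameters. The returned object follows the classic fitted-model idiom
(`print`, `summary`, `coef`, `vcov`, `predict`, `fitted`, `residuals`,
`plot`, `simulate`).

A small simulation study (run by the acceptance script and test suite)
fits 50 replicate paired aerobic + anaerobic courses of 8 points each
with 5% multiplicative noise on every species, truth
$(0.15, 0.30, 0.25, 0.10)$ h$^{-1}$: the median relative error of each
rate stays well under 15%.

## Numerical choices and problem sizes

* Integrator `lsoda`, atol $10^{-9}$ / rtol $10^{-8}$; conservation
  asserted to $10^{-6}$.
* Decoder tie-breaks: smaller candidate sets first, then lexical strain
  order; batch labels default to consecutive letters.
* `kinetic_resolution_E` cap 1000; conversion 0 or 1 is an error
  (undefined), substrate-ee exactly 0 gives $E = 1$.
* Boundary of the re-reduction inference returns `FALSE` (strict
  excess required).
* Empty pools and all-zero rate sets are valid inputs returning zero
  conversion; zero alcohol reports ee as undefined rather than 0.
* Test problem sizes, chosen so the whole suite runs in well under two
  minutes while still exercising every property: decoder/oracle
  equivalence sweeps all $2^b$ hit sets of seeded designs up to 16
  strains × 6 batches at `max_actives` ≤ 2; single-active recovery runs
  200 seeded distinct-signature designs; conservation/closed-form
  properties use 10–30 random parameter draws each; the recovery study
  uses 50 replicates.

## Limitations

The union model assumes activities combine non-destructively; the package
detects its breakdown (tandem oxidation) rather than modelling attribution
of a batch's conversion among members — quantitative attribution and
Bayesian decoding with activity priors are out of scope, as are adaptive
multi-round pooling strategies, optimal information-theoretic designs,
diastereomers/multiple stereocenters, and mechanistic cofactor or oxygen-
transport modelling. Whether a small residual $k_{ox,R}$ exists (ee
plateaus slightly below 1) cannot be decided from endpoint data alone;
the fitter treats it as a free, possibly zero, rate.
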