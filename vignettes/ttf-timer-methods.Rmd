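---
title: "Modeling the neuroblast TTF timer: decay versus relay"
author: "nbtimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the neuroblast TTF timer: decay versus relay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Embryonic *Drosophila* neuroblasts (NBs) express four temporal transcription
factors (TTFs) — Hunchback (Hb), Krüppel (Kr), Pdm, Castor (Cas) — in a
stereotyped order, stamping birth-order identities on their progeny. The
cross-regulatory circuit between these factors admits two timer readings:
an **activator relay**, where each factor accumulates past the threshold
needed to induce the next, and a **repressor decay**, where the next factor
turns on once its upstream repressor has decayed below threshold. Which
mechanism dominates depends on kinetic parameters that are unknown and hard
to measure. `nbtimer` implements the computational programme for deciding
between them: an ODE circuit model, a random-parameter consistency screen, a
combinatorial robustness score, a decay–relay significance mapping,
in-silico perturbations, closed-form one-step timer theory, and the
statistics that position an in-vivo circuit in the same coordinate space
from staged staining data.

## The circuit model

Each TTF `X` follows

    dX/dt = [ beta_X * g_X(t) * prod A(Y; T) + beta0_X ] * prod R(Y; T)
            - alpha_X * X

with Hill activation `A(Y;T) = (Y/T)^n / (1 + (Y/T)^n)`, repression
`R = 1 - A`, and Hill coefficient `n = 4` as a fixed structural constant
(a step-like regulation limit is available through the config). Hb has no
upstream activator in the circuit: its production is gated by an external
input `g(t) = 1[t < t_off]` with `t_off = 45` min, reflecting that hb is
transcribed for roughly one cell cycle. Pdm and Cas carry basal production
`beta0` that is subject to repression but not to activation — this is what
produces the early, transient Pdm/Cas expression before their repressors
have accumulated, as observed at stage 9 in embryos.

The default topology has seven interactions: activations Hb→Kr, Kr→Pdm,
Pdm→Cas; repressions Hb⊣Pdm, Kr⊣Cas, Hb⊣Cas; and one backward repression
Cas⊣Pdm. Each bears a free threshold, which with 4 production, 2 basal and
4 degradation rates gives **17 free parameters**. Only ratios of levels to
thresholds matter: rescaling all production rates and thresholds jointly
leaves the dynamics of phase boundaries unchanged (a tested invariant), so
concentration units are arbitrary.

Integration uses a compiled fixed-step RK4 on `[0, 400]` min with a 1-min
output grid and 0.25-min internal steps; the external-input gate is held
piecewise-constant per internal step, so a `t_off` aligned with the grid is
handled exactly. The screen performs on the order of 10^5 solves, which is
why the integrator is compiled; `deSolve::lsoda` drives the identical
right-hand side as an alternative engine and as the independent cross-check
in the test suite (agreement within 5e-4 of the level scale; a single
species against its closed form agrees within 1e-6 relative).

## Phases, identities, consistency

A TTF is "on" where its level is at least `on_fraction` (default 0.1) of
its maximal level `(beta + beta0)/alpha`. Thresholds are always taken from
the *unperturbed* parameter set, also when discretizing perturbed
trajectories, so that a deletion does not degenerate the scale. Phase
boundaries are refined by linear interpolation of the crossing TTF's level,
so durations are continuous rather than quantized to the output grid —
without this, sub-10-min phases fail any relative-duration comparison for
spurious reasons. Phases shorter than 2 min are treated as grid artifacts
and merged into their predecessor.

Progeny identities attach to on-sets through a configurable map; Hb-only
and Hb+Kr co-expression share the early U1/U2 identity, so those phases
merge when durations are compared (the published bookkeeping). A circuit is
**consistent** when, for wild type and every genotype of the phenotype
table, the ordered list of non-empty on-sets equals the expected list —
exact equality, durations ignored. Empty on-sets are dropped before
comparison since every trajectory starts at zero.

The shipped phenotype table encodes: WT = {Hb}, {Hb,Kr}, {Kr}, {Kr,Pdm},
{Pdm}, {Pdm,Cas}, {Cas}; Kr-null = {Hb}, {Pdm}, {Pdm,Cas}, {Cas}; pdm-null
= {Hb}, {Hb,Kr}, {Kr}, {Cas}; constitutive Hb locked in {Hb}, {Hb,Kr}; and
hb-null = {Pdm}, {Pdm,Cas}, {Cas}. The hb-null entry deserves a note: Kr's
induction by a cascade-external factor is real but outside the model's
scope (Hb→Kr is Kr's only activating input here), so an hb-null simulation
cannot express Kr for any parameter choice; the entry encodes the two
facts the model can represent — Pdm induction is strongly advanced, and the
Pdm→Pdm+Cas→Cas tail is preserved. The table is a plain config file
precisely so that a user with richer genotype data can transcribe it.

## The screen and its ranges

Parameters are drawn independently log-uniformly. Degradation rates span
0.005–0.5 1/min, geometrically centred on 0.05 1/min — the rate implied by
the ~15-min Hb half-life. Production and basal rates span 0.01–10 in
arbitrary concentration units. Regulation thresholds are drawn as ratios of
1–10% of the source factor's maximal level, the range implied by Pdm
turning on when Hb has decayed to 1–10% of maximum. These ranges are
reconstructed defaults (the original range table is unpublished) and live
in `inst/extdata/parameter_ranges.yaml`.

Draw `i` of a screen uses an RNG substream derived from `(seed, i)`, so
the consistent subset is invariant to chunking and restart, and records can
be streamed to disk with bounded memory. With these ranges roughly 12% of
draws reproduce the WT sequence and ~0.1% survive all genotypes; a
2×10^4-draw screen — the package's standard desk-scale ensemble, also used
by the acceptance script — yields a few dozen consistent circuits. The
published ensemble (10^6 draws, ~10% consistent) used a tuned, unpublished
range table; desk-scale statistics here are therefore qualitative twins,
not reproductions, of the published densities.

## Robustness

Each consistent circuit is re-solved for all 2^6 = 64 combinations of ±20%
on the six production parameters; a combination is "close" when the
identity-merged expression-phase durations all stay within 10% of the
unperturbed durations (same identity order; the final open-ended phase is
measured to the horizon). The robustness score is the percentage of close
combinations. Degradation rates stay fixed — they set the time scale.
Intervals in which no TTF is expressed are not expression phases and are
excluded from the duration comparison; including them would score grid
noise, not biology.

## Decay–relay coordinates

For Pdm the decay-removal perturbation deletes the Hb⊣Pdm term and the
relay removal deletes Kr→Pdm; for Cas they are Kr⊣Cas (leaving Hb⊣Cas
intact, since Hb has already decayed when Cas turns on) and Pdm→Cas.
Induction times are first sustained upcrossings of the on-threshold
(sustain 10 min, discounting early transients); shifts are
`100 (t_pert - t_wt)/t_wt`, with never-induced cases capped at the horizon
and flagged. Per-TTF absolute shifts are normalized by the ensemble maximum
(to 100), the two decay contributions averaged, likewise relay, giving
coordinates in `[0, 100]^2`. The plane splits into decay-dominant, mixed,
and relay-dominant thirds by the dominance difference `±100/3`
(`dominance_class()`).

Deletion sensitivities (full knockouts of Hb or Kr, measuring the Pdm
shift) give the experimentally accessible coordinates, and the
deletion-versus-link-removal correlations justify translating measured
deletion shifts into link-removal shifts through the screened ensemble.
Capped shifts (the perturbed TTF never reaches a sustained induction
before the horizon) are bounds rather than measurements; they carry a
flag and are excluded from correlations by default, where they would act
as leverage points.

Two structural facts about this ensemble are worth stating plainly.
First, the WT sequence itself forces Kr to be visibly on before Pdm, so
the relay gate can only shape Pdm timing when the activation threshold
sits high on Kr's rise — which is why the activation-threshold range
extends to 100% of the activator's maximum (with all thresholds capped at
10%, every relay-removal shift is exactly zero and the relay axis
degenerates). Second, even so, circuits whose timing is relay-limited are
rare among consistent ones: in a 3×10^5-draw screen no consistent circuit
had relay significance exceeding decay significance. The decay-dominant
bias of the consistent set is a finding, not an artifact, but it means a
desk-scale screen can leave the relay-dominant third of the plane empty,
and a relay-dominant fixture circuit cannot be shipped.

## One-step timer theory

Closed forms: accumulation delay `-(1/k) ln(1 - Tr k/beta)` (finite only
for `Tr < beta/k`), decay delay `(1/k) ln(P0/Tr)`. Under a production fold
change `f` the decay shift is `-ln(f)/k` exactly — independent of the
threshold. At matched nominal delay `T` and equal `k`, the accumulation
shift exceeds the decay shift precisely when the threshold fraction
`u = Tr k/beta` satisfies `u ≥ f/(1+f)`; for `u → 0` (delays much shorter
than a half-life) the accumulation timer is actually the less sensitive
design. The package therefore asserts the "accumulation is more fragile"
claim on `u ≥ 2/3` — delays of at least `ln(3)/k ≈ 22` min at `k = 0.05`,
comfortably the regime of a timer spanning 45-min cell cycles — together
with the divergence of the accumulation shift as `Tr` approaches the
perturbed steady state.

## In-vivo positioning

Measurements are per-NB `log(TTF/En)` intensities with embryonic stage
labels. Nuclear-volume outliers beyond 2 SD of the wild-type mean are
excluded. Induction stages are called as the first stage (scanning in stage
order, never the first stage, which can carry the early transient) whose
`mean - 1.96 SEM` exceeds the background (mean of the WT stage means at
S10E and S10). Note the calling rule's arithmetic: scanning five stages at
one-sided ~5.5% each (n = 10 per stage) yields a ~25% family-wise
false-call rate on null data; with a genuine 3-SD effect it recovers the
planted stage in over 95% of seeded replicates. The rule is kept exactly as
published rather than tightened.

Measured induction times are stage midpoints with half-stage error margins,
propagated by worst-case interval arithmetic. The stage→minutes table
(S9 0–40, S10E 40–70, S10 70–100, S11E 100–160, S11 160–220, S12 220–340)
is a reconstructed default — the published mapping is implicit in figure
axes — and every stage-dependent output carries the table's hash. Deletion
shift intervals are translated to link-removal intervals by taking, among
robust (score > 80) ensemble members whose deletion shift falls in the
measured interval, the min–max of the corresponding link-removal shift.
The stage clock saturates at both ends: a mutant calling at the first
scannable stage bounds its advance only from above (a circuit inducing at
t = 0 would read the same), so the advanced end of the measured interval
extends to −100%; a call at the last stage bounds its delay only from
below, so the delayed end extends without bound. Normalizers follow the
same measurement logic: Pdm decay shifts by 100% (induction at t = 0 is
the largest observable advance); relay shifts by the largest observable
delay (induction at the middle of the last stage); Cas decay shifts by the
largest simulated value, since Hb repression forbids Cas induction at
t = 0.

## The synthetic staining generator

The generator emulates exactly the data structure the statistics consume:
per-cell log-ratios equal to baseline + step effect from the true induction
stage onward (+ optional first-stage transient) + Gaussian noise on the log
scale (a log-normal intensity model), and volumes with a planted outlier
fraction. Defaults are the study conditions used throughout: n = 10 cells
per stage, noise SD 0.5 log units, effect 1.5 (three per-cell SDs),
transient 1.0 for WT Pdm, 5% volume outliers at 3 SD. A linear ramp option
stresses the step assumption. What the generator does *not* emulate:
staining batch effects, stage-assignment error, segmentation error, or any
correlation between intensity and volume — passing recovery tests
demonstrates the statistics, not the microscopy.

Fixture circuits (a consistent reference, a robust one, a decay-dominant
robust one) are frozen with the seeds and draw indices that produced them
in `inst/extdata/fixture_circuits.csv`; `scripts/make_fixtures.R` holds
the minting procedure. Globally robust circuits are rare (none above the
80 cutoff among 476 random consistent circuits), but the local
neighborhood of a good circuit is dense in them, so the robust fixtures
come from a short local screen around the best stage-compatible global
hit. Stage compatibility — WT Pdm inducing within S11E and WT Cas later,
as in the real lineage — matters because the induction-stage caller
defines its background from S10E/S10: a circuit inducing Pdm inside the
background window is undetectable by construction. `find_fixture_circuits()`
remains the random-search API for minting fixtures from scratch.

The end-to-end recovery study (synthetic staining from the decay-dominant
fixture, positioned back into the plane) uses a local scored ensemble
around the robust fixture for the deletion-to-link translation, since the
published translation rule consults robust sets only and a desk-scale
global screen contains none. Its recovery rate runs at roughly 80%, not
higher, for a reason worth knowing: each replicate needs six induction
stages called correctly, and the 1.96-SEM calling rule false-positives on
pre-induction stages at its fixed per-stage rate, occasionally producing a
measured window that no robust ensemble member occupies. The failures are
loud (the translation refuses, naming the nearest robust record), never
silently wrong.

## Numerical and design choices

- Zero initial conditions; horizon 400 min covers the full cascade.
- Fixed-step RK4 (0.25-min steps) rather than an adaptive solver in the
  screen loop; adaptive lsoda is the cross-check, not the workhorse.
- Negative excursions are clipped at 0 (tolerance 1e-9).
- Ties at thresholds count as "on".
- On-thresholds and identity thresholds are per-TTF fractions (0.1) of
  maximal level; a single absolute threshold would be arbitrary under
  per-TTF rescaling freedom.
- The backward edge set defaults to Cas⊣Pdm alone, honoring the
  17-parameter count; additional backward edges can be configured but
  change the free-parameter count.
- Problem sizes: screens of 2×10^4 draws, 200-replicate recovery runs, and
  50-replicate end-to-end runs are the package's standard desk-scale
  conditions.

## Known limitations

- No stochastic dynamics, no mRNA/protein separation, no division-coupled
  dilution, no Seven-up arm.
- Kr's external induction is not modeled; hb-null expectations are
  restricted accordingly (see above).
- The reconstructed parameter ranges produce a consistent-circuit yield two
  orders below the published one; ensemble statistics at desk scale carry
  correspondingly wide sampling error, and the relay-dominant third of the
  plane can be empty in a 2×10^4-draw screen.
- The stage→minutes mapping is a stated convention, not a measurement.
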