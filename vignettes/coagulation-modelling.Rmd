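---
title: "Modelling donor-specific thrombin generation with clotsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling donor-specific thrombin generation with clotsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

clotsim simulates the tissue-factor (extrinsic) pathway of blood
coagulation for an individual donor. The network follows the Hockin–Mann
stoichiometric scheme: 34 molecular species — the zymogens FII
(prothrombin), FV, FVII, FVIII, FIX and FX, their activated forms, the
initiator tissue factor (TF), the inhibitors TFPI and antithrombin (AT),
and the enzymatic complexes they assemble (TF:VIIa, the tenase IXa:VIIIa,
the prothrombinase Xa:Va, and their intermediates) — coupled by 42
uni- and bimolecular reactions. Under mass action each reaction $j$ with
rate constant $k_j$ contributes velocity $v_j = k_j \prod_i x_i$ over its
reactants, and the state evolves as

$$\frac{d\mathbf{x}}{dt} = S\,\mathbf{v}(\mathbf{x}),$$

with $S$ the stoichiometry matrix. Prothrombin, for example, obeys the
three-term balance

$$\frac{d[\mathrm{II}]}{dt} =
  -k_{16}[\mathrm{Xa}][\mathrm{II}]
  -k_{30}[\mathrm{Va{:}Xa}][\mathrm{II}]
  +k_{29}[\mathrm{Va{:}Xa{:}II}],$$

free FXa activating prothrombin slowly ($k_{16}$), prothrombinase binding
it ($k_{30}$) and releasing it unconverted ($k_{29}$), with conversion to
meizothrombin and thrombin handled by the downstream complex reactions.

Key structural assumptions, shared with the source scheme:

* **Closed, well-mixed system.** No flow, no replenishment from
  circulation, no platelet surface dynamics; phospholipid is assumed
  saturating.
* **No intrinsic-pathway entry points.** FXI, FXII, fibrinogen and the
  protein C pathway are outside the network.
* **Initiation requires TF.** A configurable trace of circulating FVIIa
  (default 1% of total FVII) is present, but free FVIIa catalyses nothing
  on its own: with TF = 0 the system is exactly silent, a property the
  test-suite checks symbolically and numerically.

Every number — species list, reactions, rate constants, reference
concentrations, drug defaults and the summary-series configuration — lives
in a versioned YAML parameter file
(`system.file("extdata", "coagulation_scheme.yaml", package = "clotsim")`),
not in code. `load_scheme()` accepts any edited copy, validates it
(species uniqueness, rate-constant resolution and positivity, units
matching molecularity) and audits that every reaction conserves every
zymogen/inhibitor lineage before it will run. If a published supplement or
a newer parameter set differs from these defaults, replacing the file is
the supported path.

## From assay units to initial conditions

Clinical panels report clotting-factor activities as percent of a
reference plasma, TF activity in pM and TFPI activity in U/mL.
`panel_to_profile()` converts linearly: percent factors scale the
reference molar concentrations (FII 1.4 µM, FV 20 nM, FVII 10 nM, FVIII
0.7 nM, FIX 90 nM, FX 160 nM, AT 3.4 µM at 100%), TF passes through
pM → M unchanged, and 1 U/mL TFPI equals the 2.5 nM reference
concentration — linearity of the TFPI activity-to-molarity map is an
assumption, and the reference entry is configurable. The conversion is
exactly invertible on the measured subspace (`profile_to_panel()`), which
the tests exercise as a round-trip property.

## Numerical choices

* **Integrator.** `deSolve::ode(method = "lsoda")`, which switches to a
  BDF method on stiff segments. The system is genuinely stiff: species
  span pM to µM and on-rates reach $4\times10^8\,\mathrm{M^{-1}s^{-1}}$.
  Defaults: relative tolerance $10^{-8}$, absolute tolerance
  $10^{-14}$ M, horizon 1200 s (the slowest factors deplete over
  ~15–20 min), output grid 1 s. The derivative is evaluated in C for
  cohort-scale throughput; a pure-R implementation of the same scheme is
  retained and the two are cross-checked in the tests.
* **Negativity clipping.** lsoda's local error allows excursions a few
  multiples of the absolute tolerance below zero. Excursions smaller than
  `clip_tol` (default $100 \times$ atol $= 10^{-12}$ M, i.e. 1 pM —
  far below any meaningful concentration) are clipped to zero after
  integration; anything larger aborts with an error rather than being
  silently repaired.
* **Conservation as a correctness oracle.** Mass action conserves each
  lineage total (e.g. all prothrombin-derived species) exactly; the
  numerical solution is required to conserve all nine to $10^{-6}$
  relative, and the suite verifies this on seeded random profiles.
* **Peaks and times.** Summary peaks are refined by a quadratic fit
  through the grid maximum and its neighbours (exact for a parabola, and
  sub-grid accurate for the smooth maxima this system produces);
  depletion times interpolate the first crossing of
  $\theta \times$ initial linearly, with $\theta = 0.10$ by default — the
  observation that factors are "rapidly depleted" does not fix a
  threshold, so it is a configuration value. Peaks still rising at the
  horizon are reported at the horizon; drug-effect percentages therefore
  measure suppression *within the observation window*, which is the
  clinically relevant window but understates differences between
  slow-peaking donors.
* **Thrombin headline.** Whether plotted "thrombin" includes
  meizothrombin is ambiguous in much of the literature; clotsim emits
  both free FIIa (the default headline used for stratification) and total
  activity FIIa + 1.2·mIIa.
* **Tertiles.** Rank-based: sort by key then donor id (a deterministic
  tie-break), cut into contiguous thirds, remainder assigned to the lower
  tertiles; all-equal keys are flagged degenerate rather than split
  arbitrarily.
* **Statistics.** Unpaired pooled-variance t-test by default (Welch
  optional), matching the era's convention for cohort tables; a
  summary-statistics mode reproduces the test from printed
  mean ± SD rows. Pearson chi-squared without continuity correction by
  default. Zero-variance degenerate inputs follow explicit conventions
  (identical constant groups give p = 1).

## Anticoagulant models

Three classes, at standard therapeutic exposure by default:

* **Vitamin K antagonist (warfarin).** Equilibrium model: the
  vitamin-K-dependent factors FII, FVII (including its FVIIa split), FIX
  and FX are scaled to 33% of the donor's level before simulation. No
  pharmacokinetics.
* **Direct FXa inhibitor (rivaroxaban-like), 6 nM.** A drug species is
  added to the network with reversible binding to free FXa:
  on-rate $10^8\,\mathrm{M^{-1}s^{-1}}$, off-rate from the published
  equilibrium affinity ($K_i \approx 0.4$ nM → 0.04 s⁻¹).
* **Direct thrombin inhibitor (dabigatran-like), 0.3 µM.** Same
  construction against free FIIa ($K_i \approx 4.5$ nM → 0.45 s⁻¹).

Whether the direct inhibitors also bind their complex-bound targets
(prothrombinase-bound FXa; meizothrombin) is a configuration toggle,
default off. The drug forms its own conserved lineage, so the
conservation audit extends to drugged simulations. Reported effects are
the percent reduction in peak free thrombin and the percent change in
time to peak. Note that at these exposures, with free-target binding and
equilibrium-level affinities, both direct inhibitors suppress free
thrombin almost completely within the default horizon; donors then
differ mainly in the time-to-peak response. The binding parameters are
deliberately data, not code: substituting a supplement's inhibitor scheme
is a parameter-file edit.

## Key-driver analysis

The substitution design: build "typical" case and control donors as
arithmetic per-factor means of the cohort (on assay units, as measured —
not molar), then (i) replace one factor at a time in the typical case
with its control mean and record the change in peak and time-to-peak
(`oat_contributions()`), and (ii) replace factors cumulatively in a
stated order (`sequential_adjustment()`), which with all nine factors
substituted must reproduce the typical-control simulation — an identity
the acceptance suite requires to hold to < 0.5% in peak thrombin.
Automatic ordering ranks by descending |Δpeak|, ties broken by
|Δtime-to-peak| then name. Both sex-pooled and sex-stratified reference
means are supported, since published analyses have used each. No
variance-based global sensitivity indices are computed — the method is
substitution-based by design.

## The synthetic cohort generator

No public accession exists for the clinical measurements this pipeline
was built around, so `generate_cohort()` produces cohorts with the same
*structure*: 162 cases and 186 controls by default, 86%/87% male
(deterministic counts), case means shifted up for TF (+25%), FVIII
(+20%), FIX (+15%) and FX (+10%) and down for TFPI (−10%), females with
elevated FVIII (+15%) and — among cases — FII (+10%) and FIX (+15%), a
prothrombin-20210A minor-allele frequency of 2% whose carriers have +25%
FII, and per-factor dispersions (CV 10–40%) that make mean ± 2 SD normal
ranges meaningful. TF and FVIII are drawn lognormal (right-skewed, as in
real plasma); other factors are normal truncated at zero by redraw.
Factors are drawn independently — real panels correlate, and no copula is
fitted because inter-factor correlations are unreported.

The multipliers are deliberately modest effect *directions*, not
estimates of any cohort's effect sizes. Consequently, passing tests show
that the pipeline recovers planted structure (cases enriched in the
high-thrombin tertile, configured mean ratios recovered at large n,
direction-consistent driver orders) — they do not validate the model
against clinical outcomes, and absolute percentages from synthetic runs
should never be quoted as study results.

## Problem sizes in the test and acceptance runs

The packaged checks use: 50 random profiles for the conservation audit,
20 for solver-convergence (tolerances tightened 10×, agreement < 0.1%
required), a 50-donor cohort for drug directionality, four-point dose
grids per drug, full 348-donor cohorts over 20 seeds for the
stratification-recovery property, and 10⁴ donors per group for
generator-mean recovery (within 2%). These sizes give stable medians and
tight Monte-Carlo error while keeping a full run in minutes on a single
CPU.

## Known limitations

* Closed-system kinetics: factors such as FV deplete irreversibly,
  whereas in vivo they are replenished by flow and platelet release;
  late-time behaviour (beyond ~20 min) is not meaningful.
* No FXI feedback, so low-TF initiation regimes that depend on intrinsic
  amplification are outside the model's validity.
* TFPI and AT are the only inhibitors; protein C / thrombomodulin surface
  regulation is absent.
* Drug models are equilibrium-affinity approximations at a fixed plasma
  concentration; no absorption, clearance or dosing schedules.
* The default rate constants are a literature parameterisation, not a fit
  to any donor data; donor-specificity enters only through initial
  conditions.
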