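---
title: "The sacchsim model: substrate, kinetics, engine and fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The sacchsim model: substrate, kinetics, engine and fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacchsim)
```

This vignette documents the model implemented by `sacchsim`, the
assumptions behind it, the tunable parameters and their defaults, the
numerical choices made where the design was genuinely open, and the
limitations a user should keep in mind.  No empirical claim is made here
beyond what the package's test suite and `scripts/acceptance.R` compute.

## The substrate

A lignocellulose microfibril is modelled as a square lattice extruded
axially.  Every occupied lattice site `(row, col)` carries one polymer
chain of `n_bonds_per_chain + 1` monomers (default 200 bonds; the bundled
`demo` configuration uses 60 so that multi-replicate runs finish in
seconds).  The cellulose core occupies an inner rectangle fixed by the
cross-section preset — the preset stands in for the plant species, which
in reality determines both the cross-section shape and the chain count.
Hemicellulose fills the concentric rectangular rings around the core and
lignin the rings outside those, with a partially needed ring realised by a
randomly chosen (seeded) subset of its sites.  Because every site carries
a full-length chain, site fractions equal monomer fractions, and the
realised composition converges to the requested
cellulose/hemicellulose/lignin fractions as the cross-section grows; the
realised values are recorded on the object.  Hemicellulose is represented
as axial chains mirroring cellulose — a modelling choice, not a structural
fact about xylan; lignin monomers (monolignols) carry no cleavable bonds
and are never solubilised.

Crystallinity is assigned per monomer.  Amorphous material is placed
first at the fibril boundaries — chain-end monomers
(`end_amorphous_length` per end), then monomers of boundary chains — and
then as interior defect patches: per chain a Poisson(`defect_density`)
number of patches of `defect_patch_length` monomers at uniform axial
starts, topped up with further random patches until the realised
amorphous fraction reaches `1 − crystalline_frac`.  The final patch is
truncated so the realised fraction stays within one patch length of the
target; requesting 95 % crystallinity on the full-size bundle lands
within two percentage points of the 5 % amorphous target (this is
asserted by the test suite).  A bond counts as crystalline when either of
its monomers is crystalline.

**Exposure.**  A monomer is exposed when at least one of its six lattice
neighbours (four lateral at the same axial index, two axial along its own
chain) is unoccupied; a bond is actable only when both its monomers are
exposed.  This single surface rule yields all the occlusion behaviour the
model needs: cellulose buried under hemicellulose/lignin sheaths is
blocked until the sheath is digested, interior core chains are shielded
by outer chains, and removing material can only enlarge the exposed set.

## Kinetics

Every reaction channel has the propensity (events per hour)

$$a \;=\; k_\mathrm{cat}\,
\frac{E_\mathrm{free}}{K_m\,\big(1 + \tfrac{G}{K_{i,G}} +
\tfrac{C}{K_{i,C}}\big) + S}\; f_\mathrm{cryst}\; \sigma$$

* `E_free` — the enzyme's free concentration after non-productive lignin
  adsorption, a quasi-equilibrium partition
  `E / (1 + K_lignin · L_exp / N_exp)` with `L_exp` the exposed lignin
  monomers and `N_exp` all exposed monomers.  There is no explicit
  bound-enzyme species.  The partition applies to all four enzymes,
  including XYL; setting `K_lignin = 0` disables it.
* The bracket — competitive end-product inhibition of the cellulases
  (EG, CBH, BGL) by glucose and cellobiose; XYL is not inhibited.
* `S` — a concentration proxy for the accessible substrate: the count of
  actable targets of that enzyme divided by the `reaction_volume`
  constant, which maps discrete counts onto the concentration scale of
  `Km`.  For BGL, `S` is the cellobiose concentration itself.
* `f_cryst` — the crystallinity factor: a rate multiplier for EG and XYL
  on crystalline targets, and for CBH both the initiation multiplier at a
  crystalline chain end and the per-step success probability of
  continuing through a crystalline pair.  Making crystallinity a
  continuous rate modifier (rather than a hard block) is what lets the
  crystalline fraction be fitted as a smooth parameter.
* `σ` — steric availability: the footprint-length window centred on the
  bond must overlap no explicitly occupied interval on the same or an
  adjacent chain.  Events are instantaneous in this implementation, so no
  occupancy accumulates during a normal run; the footprint machinery acts
  when occupancy is supplied explicitly (e.g. for what-if analyses) and
  is otherwise neutral.

Mechanisms per enzyme: EG cleaves one exposed cellulose bond per event;
CBH executes a processive run from an exposed fragment end (fragments of
at least two monomers), releasing one cellobiose per step with geometric
continuation probability `1 − 1/processivity`; BGL converts one soluble
cellobiose into two glucose; XYL cleaves one exposed hemicellulose bond,
with all hemicellulose bonds sharing one rate law.  After any cleavage,
fragments of at most `solubilization_cutoff` monomers (default 6) leave
the fibril; soluble cello-oligomers are booked immediately as
`⌊ℓ/2⌋` cellobiose plus `ℓ mod 2` glucose equivalents, and xylan
fragments as `ℓ` xylose monomers.  Only the glucose, cellobiose and
xylose pools are tracked — whether soluble oligomers deserve explicit
dynamics is a known divergence risk of this design.

**Units.**  Concentrations (`Km`, `Ki`, enzyme loading, pools divided by
the reaction volume) share one arbitrary concentration scale; `kcat` is
in events per hour per enzyme.  The defaults are calibrated as a set (see
below) rather than traceable to specific assays; the shipped preset
catalogue (`enzyme_presets()`) offers per-organism kcat/Km alternatives
on the same scale and is explicitly illustrative.

## The Gillespie engine

The engine is an exact stochastic simulation: the waiting time to the
next event is exponential in the summed propensity and the event is
chosen proportionally to its propensity.  Internally, targets sharing a
rate (e.g. all exposed amorphous cellulose bonds) are grouped into
classes; the engine samples a class, then a uniform member.  After every
event the full channel census is recomputed with vectorised matrix
operations rather than updated incrementally per neighbourhood: at the
lattice sizes this package targets (hundreds to a few thousand sites)
the full recompute is cheaper in R than incremental bookkeeping and
eliminates staleness bugs by construction.  `enumerate_channels()`
exposes the per-target channel list for inspection and testing.

Conversions and per-enzyme event counts are recorded on a fixed grid
(default every 0.5 h over 72 h), mirroring the sampling style of
experimental time courses.  *Relative activity* is defined as events per
recording window normalised by that enzyme's own trajectory maximum.
One seedable RNG stream drives everything in a run — substrate
construction, crystallinity assignment and event sampling — so identical
parameters and seed give bitwise-identical trajectories.  Glucan
conversion is `100 ×` solubilised glucose equivalents (cellobiose
counting twice) over initial cellulose monomers; pre-loaded pool contents
do not count as conversion; lignin has no conversion.

## The fitting algorithm

`run_fit()` minimises the summed per-series mean squared deviation
between the replicate-averaged simulated curve — linearly interpolated at
the experimental time points — and the data, over up to five samples.
"Variance" is taken as MSE; the flat, unweighted sum over series is the
simplest aggregation consistent with recording one objective per
sub-generation.  Generations work as follows: from the current seed
vector, `N_subsets` proposals are drawn, each fitted parameter uniform in
`[p(1−Δ), p(1+Δ)]`, clipped to its schema range; when the best proposal
improves on the previous generation's best, it becomes the next seed and
the next generation's proposals lie along the winning displacement vector
at integer scales `1..N_subsets` (the "directed" mode); otherwise the
seed reverts and the search re-randomises.  The reported optimum is the
minimum over every evaluation ever made, and the accepted-generation best
is non-increasing by construction.  Kinetic parameters are shared across
samples in every proposal; initial-configuration parameters are fitted
per sample and returned as distinct records.  Proposals touching a
distribution-constrained group (composition or cocktail fractions)
rescale the fitted members so the group, including its fixed members,
sums to one.

Two numerical choices deserve emphasis:

* **Common random numbers.**  The objective is stochastic.  The
  replicate seeds are frozen across all candidate evaluations within a
  fit, so that comparing sub-generations compares parameter values, not
  noise realisations.  Without this, the minimum over hundreds of noisy
  evaluations systematically "fits the noise" and the reported best
  variance is biased far below any re-evaluation.
* **Reporting.**  Fitted curves and per-series R² are recomputed at the
  optimum on fresh seeds with at least five trajectories, so the report
  is an out-of-sample assessment rather than an echo of the frozen
  objective.

Defaults `N_gens = 30`, `N_subsets = 8`, `replicates = 3`, `Δ = 0.25`
are sized for desk-scale runs on the reduced substrate.  Because
proposals are relative (±Δ of the current value), walking a parameter
from 0.95 down to 0.05 needs on the order of ten accepted generations;
budget generations accordingly when the start is far from the optimum.
A failed simulation inside an evaluation scores `+Inf`, is logged, and
the search continues.

## The synthetic-data generator

`generate_fixture()` stands in for uploaded experimental data: it
simulates a known "truth" document (replicate-averaged), samples the
curve at evenly spaced times, adds Gaussian noise (default 1 percentage
point), clips to [0, 100] and writes files in the exact input dialect,
plus a `truth.json` for recovery experiments.  It emulates the sampling
grid, scale and noise magnitude of typical saccharification assays.  It
does **not** emulate systematic experimental error (enzyme deactivation
over days, evaporation, calibration drift), correlated errors between
time points, or model misspecification — the generating process is the
model itself.  Recovery tests built on it therefore demonstrate that the
optimiser can invert the model, not that the model is true of any real
material.

## Default parameter values

The kinetic and concentration defaults form a calibrated set chosen once
for realism on the bundled demonstration substrate (3×3 chains × 60
bonds, composition 0.60/0.25/0.15, cocktail 25 % EG / 45 % CBH / 15 %
BGL / 15 % XYL): at the default ~2 % crystallinity — a typical best-fit
value for severely pre-treated herbaceous biomass — glucan conversion
reaches a high plateau within the 72 h horizon rather than saturating in
the first hours, and raising both crystalline fractions to 95 % collapses
conversion severalfold.  The individual values (`kcat_EG = 40 h⁻¹`,
`Km_EG = 25`, `kcat_CBH = 12 h⁻¹`, `processivity = 30`,
`crystalline_factor_EG = 0.15`, `K_lignin = 0.5`, total enzyme
concentration 0.03, reaction volume 100, …) are therefore meaningful as
a set on the package's concentration scale, not as literature constants;
`parameter_schema()` lists all 50 parameters with ranges and
descriptions.  `n_threads` is accepted for schema completeness but runs
are serial in this implementation.

## Problem sizes used by the tests

The test suite and the acceptance script run on the reduced substrate:
72 h trajectories for the crystallinity-contrast experiments (20 seeds
per condition), 24 h horizons for fitting, and the recovery experiment at
20 generations × 6 sub-generations × 4 replicates.  These sizes were
chosen so a complete run stays in the minutes range on one core while
every qualitative behaviour of the full-size substrate (200-bond chains,
larger cross-sections) is preserved; the full size remains the default
for `default_params()`.

## Known limitations

* The lattice is square with concentric integer shells; real microfibril
  cross-sections and hemicellulose coating geometries are more varied.
* Enzyme binding is implicit (instantaneous events, quasi-equilibrium
  lignin partition); there are no explicit adsorption/desorption channels
  and steric occupancy does not accumulate during a run.
* Soluble oligomer dynamics are collapsed to cellobiose/glucose/xylose
  equivalents at the moment of solubilisation.
* Xylanase shares the Michaelis–Menten-form rate law with a crystallinity
  multiplier but has no mechanistic substructure; hemicellulose branching
  chemistry is not represented.
* No temperature/pH dependence, enzyme deactivation, or diffusion; the
  fitted constants absorb these effects.
* The optimiser is a local hybrid search: with few generations and a far
  start it can park a weakly identified parameter at a range boundary;
  inspect the generation trace (`summary(fit)`) and the out-of-sample R²
  before interpreting fitted values.
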