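# sacchsim

Stochastic simulation and fitting of enzymatic lignocellulose
saccharification.

## The problem

Enzymatic hydrolysis of lignocellulosic biomass into fermentable sugars is
the central step of bio-refinery pipelines, and its yield is limited by the
substrate's *recalcitrance*: crystallinity of cellulose and hemicellulose,
structural occlusion of cellulases by the hemicellulose/lignin sheath,
non-productive adsorption of enzymes onto lignin, end-product inhibition by
glucose and cellobiose, steric crowding of bound enzymes, and pre-treatment
"defects" in crystalline regions.  Which of these factors dominates for a
given material is hard to measure directly.

`sacchsim` simulates the digestion of a single lignocellulose microfibril —
resolved in three dimensions at the level of individual glucose, xylose and
monolignol monomers — by a cocktail of endoglucanase (EG),
cellobiohydrolase (CBH), β-glucosidase (BGL) and xylanase (XYL), and fits
the model's parameters to experimental glucan/xylan conversion time
courses.  Fitted parameters quantify exactly the properties that are
difficult to assay: crystallinity, inhibition constants, lignin-adsorption
strength, kinetic rates.  The package is aimed at researchers who have
saccharification time-course data and want a mechanistic reading of it, or
who want to test enzyme cocktails *in silico*.

## The model

The substrate is a square-lattice bundle: a core of cellulose chains (the
cross-section preset fixes the chain count, the chain length is
`n_bonds_per_chain` glycosidic bonds, 200 by default), sheathed by
concentric hemicellulose and lignin layers whose thickness realises the
requested composition fractions.  Each cellulose/hemicellulose monomer is
crystalline or amorphous; amorphous material sits at the fibril boundaries
and in randomly seeded interior defect patches.

Digestion is an exact Gillespie (kinetic Monte Carlo) simulation.  Each
actable target contributes a channel with propensity

    a = kcat · E_free / (Km · (1 + G/Ki_G + C/Ki_C) + S) · f_cryst · steric

where `E_free = E · 1/(1 + K_lignin · L_exp/N_exp)` is the enzyme
concentration left free after quasi-equilibrium adsorption onto exposed
lignin, `S` is the accessible-substrate concentration (actable targets per
reaction volume), the bracket is competitive product inhibition (cellulases
only), and `f_cryst ∈ [0,1]` applies on crystalline targets.  Mechanisms:
EG cleaves exposed internal cellulose bonds (preferring amorphous);
CBH initiates at exposed chain ends and runs processively, releasing one
cellobiose per step with a geometric run length; BGL hydrolyses soluble
cellobiose into two glucose; XYL cleaves exposed hemicellulose bonds.
Fragments at or below a solubilisation cutoff leave the fibril.  Glucan
conversion is reported as solubilised glucose equivalents (cellobiose
counts twice) as a percentage of the initial cellulose monomers; xylan
conversion likewise.

Fitting uses a hybrid random/directed generational search: each generation
proposes `N_subsets` candidate parameter sets within a relative range ±Δ
(random mode), scores each by the mean squared deviation between the
replicate-averaged simulated curve and the experimental points (summed
over all series of up to five samples), and, when a generation improves,
follows the winning displacement vector (directed mode); otherwise it
reverts and re-randomises.  Kinetic parameters are shared across samples;
initial-configuration parameters are fitted per sample.

## Worked example

```r
library(sacchsim)

params <- demo_params()          # reduced 3x3-chain, 60-bond substrate
tc <- run_simulation(params, seed = 42)
tc
#> <sacch_timecourse> 145 records over 72 h
#>   final conversion: glucose 95.45%, xylose 97.13%

composition_report(attr(tc, "state")$fibril)
#>         polymer    monomer initial in_fibril solubilized crystalline amorphous
#> 1     cellulose    glucose     549        25         524           8        17
#> 2 hemicellulose     xylose     244         7         237           1         6
#> 3        lignin monolignol     122       122           0          NA        NA
```

At the default configuration (2 % crystallinity — a typical best-fit value
for severely pre-treated corn stover) 95 % of the glucan and 97 % of the
xylan are converted within 72 h; the lignin is never digested and remains
in the fibril.  Raising both crystalline fractions to 95 %
(`params$samples[[1]]$crystalline_frac_cellulose <- 0.95`, likewise for
hemicellulose) collapses 72-h conversion to roughly a quarter of the
glucan — the model's signature prediction that crystallinity, more than
composition, controls saccharification yield.

To fit parameters to data (tab-separated files, column 1 time in hours,
column 2 percent conversion):

```r
glc <- read_timecourse_tsv("sample1_glc.tsv")
spec <- fit_spec(demo_params(), list(sample_1 = list(glucose = glc)),
                 fit_config = "crystalline_frac_cellulose", seed = 1)
fit <- run_fit(spec)
coef(fit); summary(fit); plot(fit)
predict(fit, list(list(frac_cellulose = 0.5, frac_hemicellulose = 0.3,
                       frac_lignin = 0.2, crystalline_frac_cellulose = 0.4,
                       crystalline_frac_hemicellulose = 0.4)))
```

A command-line interface with `simulate`, `fit`, `predict` and
`make-fixture` subcommands is installed under `exec/` (see
`?sacch_cli`); every run writes a `manifest.json` making it reproducible
from its inputs and seed.

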