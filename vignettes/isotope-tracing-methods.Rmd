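---
title: "Positional 13C isotopomer simulation and pathway estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Positional 13C isotopomer simulation and pathway estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopath)
```

## The problem

Cultured cells fed a positionally 13C-labeled substrate — [1,2-13C]glucose,
[1,6-13C]glucose, [1,2-13C]acetate or [1-13C]lactate — distribute that label
through central carbon metabolism in a way that encodes which pathways are
active.  Two instruments read the result: GC-MS measures, per metabolite
fragment, the mass isotopologue distribution (MID: the fractions of M+0,
M+1, ... species), and 13C-NMR resolves *where* the label sits, because a
13C with a 13C neighbour splits into a doublet while an isolated 13C gives
a singlet.  `isopath` implements the forward model from tracer to both
observables, and the estimators that invert specific labeling contrasts
into pathway activities: the pentose phosphate pathway (PPP) share of
glucose catabolism, anaplerotic pyruvate carboxylation (PC), pyruvate
recycling, and the partitioning of glycolytic carbon between lactate
release and mitochondrial oxidation.

## The forward model

### Atom-mapped network

`build_default_network()` defines each reaction as a per-carbon map from
substrate positions to product positions, with explicit CO2 losses and a
symmetry flag.  The positional state of a metabolite with $n$ carbons is a
probability vector over all $2^n$ labeling patterns
(`pid` objects); reactions push the joint pattern distribution of their
substrate pools (assumed independent, i.e. well-mixed pools) through the
map.  The key mappings, chosen so the classic named isotopomers come out
verbatim:

* glycolysis: hexose C1,C2,C3 → one triose's pyruvate carbons 3,2,1 and
  C4,C5,C6 → the other's 1,2,3, so [1,2-13C]glucose yields 50 %
  [2,3-13C]pyruvate and 50 % unlabeled pyruvate, and [1,6-13C]glucose
  yields 100 % [3-13C]pyruvate (the "half maximal enrichment" relation
  between the two tracers is exact);
* oxidative PPP: hexose loses C1 as CO2 → [1-13C]pentose-P from
  [1,2-13C]glucose; the non-oxidative branch runs one full
  transketolase/transaldolase pass (3 pentose-P → 2 hexose-P + 1
  triose-P) with the complete carbon maps;
* PDH removes pyruvate C1 (so [1-13C]lactate-derived label dies there);
  PC preserves pyruvate C1–C3 and fixes an unlabeled CO2 as OAA C4;
* citrate is treated stereospecifically: acetyl C1,C2 → citrate C1,C2 →
  glutamate C5,C4; OAA C1 → citrate C6, which is the carbon lost at the
  α-ketoglutarate step (hence [1-13C]OAA → [6-13C]citrate → unlabeled
  α-KG); OAA C4,C3,C2 → glutamate C1,C2,C3;
* succinate/fumarate form one symmetric 4-carbon species; a 50/50 mix of
  the two rotational orientations is applied on formation, the only place
  scrambling enters.

Glucose, G6P and F6P are collapsed into one hexose-P pool, and 3PG, PEP
and the glycolytic trioses into one pyruvate-numbered triose pool, because
no measurement in this design distinguishes their labeling states.

### Steady state and the mixing parameters

`simulate_labeling()` iterates TCA turns to a fixed point of the OAA
distribution (L1 change below `convergence_tol`, default 1e-10, typically
30–40 turns; `max_turns` 500).  The tunable parameters are dimensionless
pool shares per turn, which is what labeling data can constrain (absolute
fluxes are out of scope):

| parameter | meaning | default (study conditions) |
|---|---|---|
| `f_ppp` | hexose-P entering the oxidative PPP | 0.10 |
| `f_pc` | PC-derived share of the OAA pool | 0.10 |
| `f_recycle` | malate-derived share of the pyruvate pool (malic enzyme) | 0.05 |
| `f_pyr_unlabeled` | unlabeled dilution of pyruvate | 0.10 |
| `f_acetyl_from_acetate` | acetyl CoA drawn from the acetate pool | 0 (0.5 in the acetate condition) |
| `f_acetyl_unlabeled` | unlabeled dilution of acetyl CoA | 0.05 |
| `f_gln_dilution` | unlabeled share of glutamine | 0.5 |

The defaults are the synthetic study conditions: `f_ppp` 0.10 matches the
~10 % PPP activity the estimators are designed around; `f_pc` and
`f_recycle` are set at clearly-detectable-but-modest levels appropriate to
pathways demonstrated qualitatively; dilution values reflect that amino
acid pools in 0.5 % serum medium are mostly tracer-derived while glutamine
labels much more slowly than glutamate.  They are package choices for a
synthetic study, not measured values.

Two conventions deserve note.  First, the sources define `f_pc` as the PC
fraction of pyruvate disposal and `f_recycle` as the fraction of malate
decarboxylated; converting those flux fractions into pool compositions
would require absolute fluxes that labeling alone cannot supply, so both
are implemented directly as the PC-derived share of the OAA pool and the
malate-derived share of the pyruvate pool.  All qualitative diagnostics
(zero signal at zero parameter, monotone increase) are unaffected.
Second, glutamate and aspartate inherit the α-KG and OAA distributions
(fast-exchange assumption), and exogenous labeled lactate competes with
glucose-derived pyruvate through its `pool_fraction_labeled`, which is how
the under-estimation of PC by lactate tracers in glucose-containing medium
is represented.

A `two_compartment` option routes acetate-derived acetyl CoA through a
separate TCA pool whose pyruvate inflow is unlabeled, mixing the measured
metabolites across compartments.  This reproduces the signature that
motivates compartmentation — acetate labels citrate and glutamate while
second-turn M+1 isotopologues stay near zero — without claiming a fitted
compartment model.

### Multi-turn subtleties

Two textbook diagram claims hold only on a two-turn horizon, and the
turn-resolved API (`simulate_turns()`) exists to expose this:

* "only PC produces [2,3-13C]glutamate from [1,2-13C]glucose" is exact for
  turns 1–2; from turn 3 the symmetric succinate step relays
  acetyl-derived label into OAA C2–C3 and a small PC-independent
  [2,3-13C]glutamate appears at steady state.  The C2 doublet *contrast*
  remains monotone in `f_pc`, which is what the estimator uses.
* the two PPP readouts are not numerically identical under the full
  non-oxidative mapping: three PPP hexoses yield one [3-13C] (M+1) and one
  [1,3-13C] (M+2) triose, and both feed [2-13C]acetyl CoA, so the
  glutamate-C4 singlet/doublet ratio runs about twice the triose M+1/M+2
  ratio.  The often-quoted "1/3 re-enter as M+1" rule is a simplification;
  `ppp_reentry_passes` exposes repeated oxidative re-entry, and neither
  behaviour is asserted as ground truth.  Both estimators are reported
  with method tags, and both rise monotonically with `f_ppp`.

### The Monte-Carlo oracle

`monte_carlo_oracle()` re-derives the same steady state by brute force: it
tracks 10^4–10^5 individual molecules as integer bit masks, choosing every
branch (PPP vs glycolysis, PDH vs PC vs recycling, symmetric orientation)
at random with the mixing-parameter probabilities, and never touches the
distribution algebra.  Agreement within three standard errors across
random parameter grids is the package's deepest correctness check; the
oracle shares only the carbon maps with the deterministic code.

## Measurement models

`positional_to_mid()` collapses patterns by label count.  GC-MS spectra
are contaminated by natural heavy isotopes of every atom in the
derivatized fragment; `natural_abundance_convolve()` and
`natural_abundance_correct()` implement the classic correction-matrix
convention in which column $k$ is the fragment's natural-isotope spectrum
shifted by $k$ mass units (13C 1.07 % by default, 2H/15N/17O/18O/29Si/30Si
at standard values).  Under this convention the forward convolution and
the lower-triangular solve are exact inverses (round-trip identity to
1e-8), and an empirical correction built from a measured unenriched
standard coincides with the theoretical one when the standard matches the
theoretical spectrum.  The refinement of excluding enriched backbone
positions from the natural-abundance draw is second order
(≈ 0.01 × enrichment) and would break that equivalence, so it is not
used.  Corrected components may come out slightly negative on noisy data;
components above `-neg_tol` are clipped and renormalized, anything lower
is reported as a data-quality error.  The default `neg_tol` of 1e-6 suits
noise-free spectra; the pipeline scales it to three times the stated
replicate noise.

Fragment formulas for the TBDMS-style derivatives are user configuration;
the package ships *synthetic* default compositions (backbone plus a fixed
derivatization moiety) so that every test is self-contained — they are
stand-ins, not literature fragment ions.

NMR multiplets are predicted from adjacent-carbon (one-bond) couplings
only: conditional on the observed carbon being 13C, singlet = no labeled
neighbour, one doublet per labeled neighbour, doublet-of-doublets = both.
Quantification follows the internal-standard rule (area ratio times the
standard's 13C amount, times a user-supplied NOE/relaxation factor — those
physics are accepted as factors, not computed), and the glutamate-C4
singlet is corrected by subtracting 1.07 % of the 1H-quantified pool, the
same subtraction the synthetic generator applies in reverse.

## Estimators

* `ppp_fraction_from_mid()`: 100 × M+1/M+2 of PEP/3PG (method `M1/M2`),
  with `M1/(M1+M2)` co-reported.  The primary reading is the one
  compatible with interpreting the ratio as "percent of glucose via the
  PPP"; it is a known underestimate.
* `ppp_fraction_from_glutamate_c4()`: corrected C4 singlet divided by the
  C4–C5 doublet (`s/d`, literal quotient; `s/(s+d)` co-reported).
* `pc_evidence_from_lactate_tracer()`: percent M+1 citrate under
  [1-13C]lactate — exactly zero without PC, because PDH discards the only
  labeled carbon.
* `pc_evidence_from_glutamate_c2()`: the C2–C3 vs C1–C2 doublet
  decomposition; the PC share is d23/(d23+d12).
* `recycling_index()`: the alanine isotopologues unreachable without TCA
  carbon returning to pyruvate (M+1 under [1,2-13C]glucose; any label
  under [1,2-13C]acetate).
* `medium_rate()` and `lactate_oxidation_partition()`: net medium changes
  normalized to µmol/10^6 cells/24 h, and lactate release over twice the
  glucose consumption, with a display ratio rounded to the nearest ten
  (60:40-style); raw percentages are always retained.
* Evidence flags use a threshold of three times a user-stated noise sigma;
  the data give no natural threshold, so it is configuration, not a fitted
  quantity.

`fit_params()` closes the loop: bounded derivative-free least squares
(multi-start Nelder–Mead on a logit scale, Brent for one parameter, Latin
hypercube starts, seed required, ties broken by the smaller parameter
norm) between forward-model observables and measured corrected MIDs plus
multiplet fractions.  On noiseless synthetic data it returns the
generating parameters to ~1e-3; at the default noise (below) the
acceptance suite requires 90 % of fitted `f_ppp`, `f_pc`, `f_recycle`
values within ±0.05 of truth over 20 Latin-hypercube truth sets drawn from
f_ppp, f_pc ∈ [0.02, 0.40] and f_recycle ∈ [0.02, 0.30], fitted from the
[1,2-13C]glucose and [1-13C]lactate designs with four starts each.

## Synthetic data

`generate_condition()` and `generate_fixture_suite()` emulate the four
incubation designs (2 mM [1,6-13C]glucose; 2 mM [1,2-13C]glucose; 2 mM
[1,2-13C]acetate; 5 mM [1-13C]lactate + 2 mM unlabeled glucose, lactate
taking a 0.55 share of the pyruvate sources) in the reference geometry of
2 mL medium over 4 × 10^5 cells for 24 h, plus an astrocyte-style
medium-only dataset generated from the printed astrocyte rates (glucose
consumption 3.2, lactate release 5.3 µmol/10^6 cells/24 h).  Oligodendrocyte-style
medium rates are set to glucose −3.0 and lactate +3.6, consistent with the
reported 60:40 lactate:oxidation partition.  Noise defaults — additive
σ = 0.005 on MID fractions (clipped, renormalized), 5 % lognormal CV on
NMR areas, 0.05 mM on concentrations — are chosen to resemble
replicate-level scatter of well-plate tracer experiments; they are
generator choices, not measured values.  A manifest (parameters, tracers,
noise, seed, geometry) fully determines regeneration, bit for bit.

What the generator does *not* emulate: correlated within-batch errors,
chromatographic interferences, incomplete derivatization, NMR baseline and
phasing artefacts, lipogenic carbon sinks, or cell proliferation.  Passing
tests therefore demonstrate internal consistency of model, measurement
simulation and inversion — not instrument-level realism.

## Numerical choices and degenerate inputs

Distributions are renormalized after every reaction application; sums are
enforced to 1e-9.  The fixed point is independent of the OAA
initialization (checked against a uniform start at 10 × tolerance).
Multiplet prediction on a carbon that is never labeled returns a flagged
empty result rather than 0/0.  Ratio estimators raise errors on zero
denominators (M+2 = 0, zero doublet, both C2 doublets zero) instead of
returning infinities.  Percentages outside [0, 100] — possible when net
lactate release exceeds glycolytic pyruvate — are reported with explicit
warnings, never silently clamped.  All stochastic components (oracle,
noise, start designs) consume a single integer seed and no global state.

## Problem sizes

The shipped tests run the oracle at 10^5 molecules over 20 random
parameter sets, the recovery study at 20 truth sets with 4 starts, and the
analysis scripts use 6 replicates per condition; these sizes give
per-channel Monte-Carlo error near 0.001 and stable recovery statistics
while keeping a laptop run comfortable.

## Known limitations

Pool shares, not fluxes; one lumped hexose and triose pool each; no
glycogen, lipid or nucleotide sinks; CO2 refixed by PC is always
unlabeled (no bicarbonate labeling); glutamine dilution is a single
fraction rather than a kinetic model; the two-compartment option is a
reporting mixture, not a fitted compartment model; and the PPP re-entry
depth is a configuration choice that the data in this design cannot
identify.
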