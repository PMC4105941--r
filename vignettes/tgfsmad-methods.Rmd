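---
title: "Models and methods: negative regulation of TGF-β/Smad signalling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: negative regulation of TGF-β/Smad signalling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgfsmad)
```

## The model family

All variants share one skeleton and differ only in which
negative-regulation blocks are active (`modelEffectsTable()`):

* **Skeleton.** Extracellular TGF-β binds the type-II receptor
  reversibly, the complex recruits the type-I receptor to form the
  ligand–receptor complex (LRC), which internalizes in parallel to the
  early endosome (the signalling pool, recycled with ligand
  degradation) and to caveolae (recycled intact). Receptors are
  produced at constant rates and all receptor-containing species share
  one constitutive turnover rate. Smad2 is phosphorylated by the
  endosomal LRC acting catalytically; phospho-Smad2 forms homomeric and
  heteromeric complexes with itself and Smad4 at the same association
  rate (the simplest treatment of an unresolved stoichiometry; the
  homomeric complex carries stoichiometric weight 2 in all Smad2
  totals). Monomeric Smads shuttle in and out of the nucleus; Smad
  complexes import faster and do not export; monomeric phospho-Smad2
  imports but must be dephosphorylated before it can leave.
* **Effect blocks.** Dephosphorylation of nuclear phospho-Smad2 (one
  reaction, or explicit two-step PPM1A catalysis in the variants that
  model PPM1A); Smad7-driven LRC degradation in caveolae (Smad7 is a
  high, constant, buffered species in HaCaT — the inhibitory-Smad
  feedback variant S1 makes it dynamic instead, with basal plus
  Smad-complex-driven synthesis so its pre-stimulus level is nonzero);
  proteasomal degradation of nuclear phospho-Smad2; endogenous Smad2
  synthesis and first-order turnover of monomeric Smad2 (complexes are
  protected); PPM1A upregulation either by Smad-complex-driven
  expression (S2) or by PTEN-mediated stabilization (Models 8 and S3):
  cytoplasmic phospho-Smad2 scaffolds the association of PTEN with
  PPM1A, the ternary complex releases a degradation-resistant
  PTEN–PPM1A dimer whose nuclear import is slow, so total PPM1A rises
  quickly while its nuclear phosphatase activity rises with a delay.
* **Variant conventions.** Model 8 is Model 7 plus stabilization. For
  the supplementary variants this package uses: S1 = Model 5 plus
  dynamic Smad7 feedback; S2 = Model 7 effects with PPM1A upregulation
  by expression; S3 = dephosphorylation (two-step) plus stabilization
  only. S3's composition is a package convention: it isolates the
  stabilization mechanism from the degradation/turnover effects so the
  two PPM1A hypotheses can be compared like-for-like.

## Units and the relative-concentration convention

Concentrations are nM, time is minutes. Nuclear species are stored as
cytoplasm-volume-relative concentrations: the cytoplasm-to-nucleus
volume ratio (slot `volumeRatio`, default 3) is applied once when
literature per-volume shuttling rates are converted, never inside the
right-hand side. This makes stoichiometry-weighted sums across
compartments directly additive, so total Smad2 (571.43 nM) and total
Smad4 (1333.33 nM) in HaCaT are plain weighted sums and are conserved
exactly in variants without Smad turnover. Extracellular ligand uses
the same bookkeeping with a medium-to-cell volume factor of 1000: a
2 ng/ml dose (80 pM at the 25-kDa mass of the mature dimer) enters as
80 nM relative, receptor binding depletes it with integer
stoichiometry, and the low-dose regime (0.025–0.5 ng/ml) is genuinely
ligand-limited, which reproduces depletion-dominated kinetics at low
dose without any special-casing.

## Default rate constants

Receptor-module rates (association, internalization, recycling,
turnover, production) are fixed at values in the range established by
the receptor-trafficking models this skeleton follows; shuttling and
complex rates follow the nucleocytoplasmic-shuttling lineage (complex
import faster than monomer import; slow complex dissociation). The
effect-block rates are the free parameters of the fitter. Their
defaults were calibrated once, before the estimation machinery was
built, against the qualitative behaviour the family must show:
phospho-Smad2 peaking near one hour at a minority share (~30%) of the
Smad2 pool; washout elimination within four hours; a substantial
(roughly two-fold) decline by 24 hr under continuous stimulation in the
feedback model; total PPM1A rising ~2.4-fold by one hour; total T1R
and total Smad2 flat. Two calibration choices deserve comment:

* `kdeg_P = 0.05/min` gives basal PPM1A a ~14-min half-life. The rise
  of *total* PPM1A under stabilization is bounded by
  `fold(t) ≤ exp(-kdeg_P t) + kdeg_P t` (old unprotected pool decaying,
  new synthesis fully protected), so a ~2.4-fold rise within an hour
  *requires* fast basal turnover; slower turnover caps the fold change
  below the observed one regardless of binding rates.
* The Smad complex dissociation rate (0.18/min) and the nuclear
  rebinding rate (kon × Smad4n ≈ 2.2/min) put the nuclear monomer in
  quasi-equilibrium with a large complex reservoir. Post-washout decay
  of total phospho-Smad2 is then dissociation-gated and mostly
  insensitive to the proteasomal degradation rate, while under
  continuous stimulation the same degradation rate drains the
  recirculating Smad pool cumulatively — which is what makes proteasome
  inhibition nearly invisible after a 30-min exposure yet strongly
  visible after an 8-hr exposure with identical parameters.

## Protocols and perturbations

`StimulusProtocol` covers continuous ("long") and washout ("short")
exposure. Washout at `tWash` (default 30 min) is a hard integration
restart: extracellular ligand is set to zero *and* the receptor kinase
is disabled (`kphos = 0`), because the washout compound is a type-I
receptor kinase inhibitor — removing only the ligand would let
pre-formed LRC keep signalling. Chemical perturbations are parameter
overrides on a copy: proteasome inhibition zeroes `kdeg_pSmad2` and
nothing else (basal receptor, Smad and PPM1A turnover untouched);
cycloheximide halves every zeroth-order synthesis rate. Events are
implemented as integrator restarts, not smoothed switches, so results
are integrator-independent.

## Simulation and estimation

The right-hand side is assembled once per network from index vectors
(reactant, second reactant, modifier) and the stoichiometry matrix, and
evaluated in C; a pure-R implementation of the same contract is kept and
the test-suite asserts equality to machine precision, alongside an
independent hand-coded-derivative oracle on toy networks. Integration
uses a stiff-capable solver (`deSolve::lsoda`) with relative tolerance
1e-8 for reported simulations; the fitter uses 1e-6 for speed, which
changes SSE values well below the replicate noise floor.

Estimation minimizes the sum of squared errors between simulated
observables and data records, with the simulation normalized exactly as
the data channel is (relative-to-max for western-style channels,
relative-to-t0 for receptor blots, absolute nM for ELISA). The local
optimizer is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) in
log10-parameter space with box bounds [1e-8, 1e3] — effect rates span
several decades, and log space equalizes step sizes. Multistart uses
the model's default parameter vector as the first start and log-uniform
draws within ±2 decades of it for the rest; restarts are deterministic
given the seed. Integration failures inside the objective return a
large finite penalty (1e12) so optimizers survive pathological
parameter regions. Model 7's constrained fit ties the Smad2 synthesis
rate to the pre-stimulus degradation flux *and* adds penalty records
that hold total Smad2 at its initial value across 24 hr, so turnover
cannot be exploited as a disguised decline mechanism — without the
penalty the optimizer does exactly that.

## The rejection workflow

Each variant is fitted to the phospho-Smad2 short- and long-exposure
channels simultaneously (the primary data); receptor, total-Smad2 and
PPM1A channels are out-of-sample predictions. A channel rejects a model
when its SSE exceeds 3× the family-best SSE on that channel *and* the
replicate-mean residuals contain a same-sign run of length ≥ 4 (a
systematic misfit, not noise). The verdict follows the sequential logic
of model-driven experiments: if the phospho-Smad2 fit itself rejects,
the verdict is the phospho-Smad2 data. Otherwise the mechanism tested
by the strongest rejecting prediction channel is capped (its rate
clamped to zero — receptor degradation for the T1R channel, proteasomal
degradation for the total-Smad2 channel) and the model is refitted;
the verdict is the channel whose cap finally leaves the model unable to
fit the primary data. This reproduces the intuitive attributions: a
model whose only slow mechanism is receptor degradation is killed
directly by the flat receptor data, while a model that can reroute its
decline through degradation survives the receptor channel only to be
killed by flat total Smad2.

## The synthetic-data generator

`generateBundle()` emulates the statistical structure of the
western/ELISA time courses: phospho-Smad2 under both exposures
(experimental grids to 4 hr and 24 hr), total T1R at nine points from
15 min to 24 hr, total Smad2 by ELISA at seven points, and total PPM1A
to 8 hr — with multiplicative lognormal replicate noise (mean-unbiased;
cv 0.2 for densitometry channels, 0.1 for ELISA, three replicates) and
per-channel normalization applied before noise. Bundles are
bit-identical given truth and seed. The generator emulates replicate
scatter with constant coefficient of variation; it does not emulate
blot saturation, background subtraction, loading-control error,
between-blot batch effects, or detection censoring. Passing recovery
and rejection tests on these bundles therefore demonstrates that the
estimation and rejection machinery works under honest replicate noise —
not that the real quantifications are this well behaved.

## Adopted definitions and numerical choices

* **Relative change under proteasome inhibition** is
  (treated − control)/control at 1, 2, 4 and 6 hr. Control levels
  below 5% of the control peak — a western-style detection floor — are
  masked as unquantifiable; when the masked points enter a time
  average they count as "no measurable change" (zero), which is what
  the underlying experiment reports at those points. The sign
  convention is positive when inhibition raises phospho-Smad2.
* **Adaptation index** of a response series is (peak − final)/peak:
  0 for a non-adapting plateau, 1 for complete adaptation.
* **Effect removal** in the contribution decomposition zeroes the
  effect's rate constants without re-equilibration, so all curves start
  from the same state.
* **Sensitivity summary** is the relative change of each species'
  24-hr trajectory integral under rate rescaling (folds 1e-4–1e2);
  failed integrations at extreme folds are masked cells.
* Ties and degenerate inputs: zero-dose protocols skip the washout
  branch; observables normalize only against positive maxima;
  an all-zero series has no adaptation index (error by design).

## Problem sizes

The shipped tests and the acceptance script run the full model family
(18–28 state variables per variant) on 24-hr horizons; rejection
comparisons use two restarts per model, sweeps a five-point decade grid
with two restarts per point, and recovery ten Monte-Carlo trials of the
one-parameter variant — sizes chosen so a complete run of the suite
finishes in about a minute on a laptop-class core while every workflow
is exercised end to end at full model fidelity.

## Known limitations

* The skeleton is a reconstruction in the lineage of the established
  receptor-trafficking and shuttling models, with rate constants
  calibrated to qualitative HaCaT behaviour; absolute concentrations
  and rates are plausible rather than measured, and conclusions should
  be read at the level of mechanism discrimination, not kinetic
  constants.
* Linker- and tail-phosphorylation of Smad2 are not distinguished;
  proteasomal degradation acts directly on nuclear phospho-Smad2 under
  the proportionality assumption.
* Gene-regulatory events downstream of nuclear Smad complexes, SnoN
  sequestration, and stochastic effects are out of scope; rate laws are
  strictly mass action (the two-step phosphatase catalysis included).
* The SBML layer covers mass-action kinetic laws only and rejects
  anything else explicitly; compartment sizes are exported as 1 with
  the relative-concentration convention recorded in the model notes, so
  round trips do not rescale.
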