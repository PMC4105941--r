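# tgfsmad

Mass-action ODE models of negative regulation in TGF-β/Smad signalling.

## The problem

TGF-β signalling is strongly self-limiting: after the ligand binds its
type-II/type-I receptor complex and the activated type-I receptor kinase
phosphorylates Smad2, nuclear phospho-Smad2 peaks at about one hour and
then declines — quickly when the stimulus is removed after 30 minutes,
gradually over 24 hours under continuous stimulation. Several molecular
mechanisms can produce this decline: PPM1A-mediated dephosphorylation of
nuclear phospho-Smad2 (fast), Smad7-recruited degradation of the
ligand–receptor complex (slow), Smurf2-driven proteasomal degradation of
nuclear phospho-Smad2 (slow), and endogenous Smad synthesis/turnover.
Which combination actually operates in HaCaT keratinocytes is not
resolvable from phospho-Smad2 kinetics alone, because different
mechanisms produce nearly interchangeable fits while making sharply
different predictions for other observables (total type-I receptor,
total Smad2, total PPM1A).

`tgfsmad` implements a family of compartmental mass-action ODE models
(Models 1–8 plus supplementary variants S1–S3) that share one skeleton —
ligand binding, receptor trafficking through early endosomes and
caveolae, Smad2 phosphorylation, homo-/heteromeric complex formation and
nucleocytoplasmic shuttling — and differ only in which
negative-regulation blocks are switched on. Model 8 adds the package's
headline mechanism: a negative feedback loop in which phospho-Smad2
scaffolds the association of PTEN with PPM1A, protecting PPM1A from
degradation so that total PPM1A rises ~2.4-fold within an hour of
stimulation and, after delayed nuclear import, shuts the pathway down.

## The model

Every reaction is strict mass action. For reaction j with rate constant
k_j, reactant multiset R_j and optional catalytic modifier m_j,

    v_j = k_j · Π_{i ∈ R_j} c_i · c_{m_j},      dc/dt = S v(c),

with S the stoichiometry matrix. Nuclear species are stored as
cytoplasm-volume-relative concentrations, so stoichiometry-weighted sums
over compartments (the lysate observables: total phospho-Smad2, total
Smad2, total T1R, total PPM1A) are directly additive, and total Smad2
and Smad4 in HaCaT are 571.43 nM and 1333.33 nM. Initial conditions are
pre-stimulus steady states obtained by simulating 10⁴ minutes without
ligand. Parameters are estimated by multistart bounded
Levenberg–Marquardt least squares in log10 space, fitting the
short-exposure (30-min washout plus receptor-kinase inhibition) and
long-exposure (continuous 2 ng/ml ≙ 80 pM) phospho-Smad2 time courses
simultaneously; receptor, total-Smad2 and PPM1A channels are evaluated
as out-of-sample predictions in a model-rejection workflow.

## Worked example

```r
library(tgfsmad)

model8 <- assembleModel(8)                      # equilibrated variant
protocol <- StimulusProtocol(dose = 2)          # continuous 2 ng/ml, 24 hr
trajectory <- simulateModel(model8, protocol,
                            times = c(0, 15, 30, 45, 60, 120, 240, 480, 1440))
pSmad2 <- observe(trajectory, "PSmad2_total")
ppm1a  <- observe(trajectory, "PPM1A_total")
data.frame(time_min = pSmad2$time_min,
           PSmad2_nM = round(pSmad2$value, 1),
           PPM1A_fold = round(ppm1a$value / ppm1a$value[1], 2))
```

```
 time_min PSmad2_nM PPM1A_fold
        0       0.0       1.00
       15      64.2       1.17
       30     120.4       1.63
       45     155.8       2.19
       60     168.8       2.74
      120     111.9       3.48
      240      91.4       3.45
      480      89.3       3.44
     1440      89.8       3.44
```

Phospho-Smad2 peaks near one hour (168.8 nM, ~30% of the Smad2 pool) and
declines to 53% of its peak by 24 hr, driven by the PPM1A rise (2.7-fold
at 1 hr); total T1R and total Smad2 stay flat (T1R exactly, Smad2 within
2%) — the signature that rejects the receptor-degradation and
unbalanced-degradation alternatives. The rejection workflow itself:

```r
bundle <- generateBundle("8", seed = 42)   # synthetic western/ELISA bundle
cmp <- compareModels(bundle, nStarts = 2, seed = 1)
cmp$verdicts
#>    1     2     3     4     5     6     7     8
#> "pS" "T1R"  "pS"  "pS"  "tS"  "tS"  "pS" "None"
```

Each verdict names the dataset that rejects the variant (`pS`
phospho-Smad2 kinetics, `T1R` receptor level, `tS` total Smad2); only
the PPM1A-feedback model survives every channel.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/scripts/tgfsmad-cli.R simulate --model 8 --dose 2 --out traj.csv
Rscript inst/scripts/tgfsmad-cli.R generate-data --truth 8 --seed 42 --out bundle/
```

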