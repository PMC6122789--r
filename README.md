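# trajstate

Temporal classification of model-quality states along molecular-dynamics
refinement trajectories of protein models.

## What it does, and for whom

Refinement simulations of template-based protein models occasionally
sample conformations closer to the native structure than the starting
model — but only a few percent of snapshots, buried among a large
majority that drift away. When a reference crystal structure exists,
each snapshot can be labeled by its GDT_TS change against the starting
model:

```
I (improved)   ΔGDTTS ≥  0.01
N (no change) -0.01 ≤ ΔGDTTS < 0.01
D (decreased)  ΔGDTTS < -0.01
```

`trajstate` is for structural bioinformaticians who want to recognize
those improved states *without* the reference, from the 19 per-snapshot
descriptors that are always computable (17 energy/statistical-potential
terms plus RMSD and GDT_TS to the starting model). Its core is a stacked
gated-recurrent-unit (GRU) classifier

```
z = σ(W_z x + U_z h),  r = σ(W_r x + U_r h)
h̃ = tanh(W x + U (r ⊙ h)),  h' = z ⊙ h + (1 − z) ⊙ h̃
y = softmax(W_out h')
```

trained with a class-weighted cross-entropy
`L = −Σ_j ω_j y'_j log y_j` (default ω = [0.05, 1, 10] for I/N/D) under
stateful truncated backpropagation through time: all trajectories are
concatenated, split into 50 parallel streams, and consumed in contiguous
30-snapshot windows with hidden state carried across windows. The point
of the temporal model is that quality states persist (self-transition
probabilities ≈ 0.806 / 0.626 / 0.947 for I/N/D), so weak per-snapshot
evidence accumulates along the trajectory.

Around the classifier the package provides: feature-table CSV ingestion
and per-target standardization; Kabsch superposition, CA-RMSD, GDT_TS
and per-residue RMSF from PDB files; random-forest, k-NN and logistic
baselines configured identically; class-balanced grouped 7-fold
cross-validation; Markov-chain and segment-length trajectory
statistics, outcome-restricted cumulative distributions and
assigned-probability densities; position/distance restraint generation
and exclusive/minimum-distance contact maps with the CV1/CV2
switching-function collective variables; and a synthetic trajectory
generator that reproduces the dataset's statistical structure at desk
scale. A thin command-line interface lives at
`inst/cli/trajstate-cli.R` (subcommands `label`, `simulate`, `train`,
`predict`, `evaluate`, `baselines`, `folds`, `markov`, `restraints`).

## A worked example

```r
library(trajstate)

ts  <- standardize(makeFixture("unit"))       # 800 synthetic snapshots
fit <- trainModel(ts, trainConfig(hidden_size = 16, num_layers = 1,
                                  sequence_length = 10, batch_size = 4,
                                  epochs = 2, learning_rate = 1e-3,
                                  seed = 1))
pred <- predictModel(fit$model, ts)
classMetrics(confusionMatrix3(stateLabels(ts), pred$predicted))
#>   class  tp  fp  fn  precision    recall        f1
#> 1     I  12 160  32 0.06976744 0.2727273 0.1111111
#> 2     N  69 179  52 0.27822581 0.5702479 0.3739837
#> 3     D 363  17 272 0.95526316 0.5716535 0.7152709
```

Precision/recall/F1 are per class (0/0 cases report 0); improved-class
precision is the headline quantity — the fraction of snapshots flagged
as improved that truly are. The low improved-class numbers of this
two-epoch toy run are the expected starting point: single snapshots
barely identify improvements, which is why the temporal model, longer
training and the checkpoint selection exist
(see `temporalAdvantageStudy()` for the real comparison). On trajectory
statistics:

```r
P <- estimateMarkov(ts)
round(P[1:3, 1:3], 3)
#>       I     N     D
#> I 0.705 0.295 0.000
#> N 0.099 0.603 0.298
#> D 0.002 0.049 0.949
```

the estimated self-transitions recover the generator's configured chain
(0.806 / 0.626 / 0.947) up to the sampling error of this small fixture
(only 44 improved-state transitions).

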