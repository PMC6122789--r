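---
title: "Classifying model-quality states along refinement trajectories"
author: "trajstate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying model-quality states along refinement trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajstate)
```

## The problem

Molecular-dynamics refinement of template-based protein models samples
thousands of conformations, only a small fraction of which are actually
closer to the native structure than the starting model. When a reference
crystal structure is available, every saved snapshot (one per 2 ps here)
can be scored by GDT_TS and labeled by the change relative to the
starting model:

* **I** (improved): dGDT_TS >= 0.01,
* **N** (no change): -0.01 <= dGDT_TS < 0.01,
* **D** (decreased): dGDT_TS < -0.01.

In production refinement no reference exists, so the practical question
is whether the 19 per-snapshot descriptors that *are* computable --- 17
potential-energy and statistical-potential terms plus the RMSD and GDT_TS
to the *starting* model --- carry enough signal to recognize improved
states. Snapshot-by-snapshot they barely do: the states are heavily
imbalanced (roughly 8 / 15 / 77 percent for I / N / D) and improved and
no-change snapshots overlap strongly in feature space. What rescues the
problem is time: states persist (self-transition probabilities of about
0.806, 0.626 and 0.947 for I, N, D), so evidence about the current state
accumulates along the trajectory. `trajstate` implements a stacked-GRU
recurrent classifier that exploits exactly this temporal structure,
together with the full surrounding machinery: feature-table ingestion and
per-target standardization, structure metrics from PDB coordinates,
non-temporal baselines, class-balanced grouped cross-validation,
trajectory statistics, and restraint/contact-map generation for
restrained and metadynamics sampling.

A note on the lower labeling boundary: the band definition places
dGDT_TS = -0.01 in **N**. An alternative convention assigns it to **D**;
`assignLabel(strict = TRUE)` provides it. The default follows the formal
piecewise definition.

## The model

Each snapshot contributes a standardized 19-vector $x_t$. A stack of GRU
layers (default 3, hidden width 1024) transforms the sequence; layer $l$
at time $t$ consumes the state of layer $l-1$ and its own previous
state:

$$z = \sigma(W_z x + U_z h_{t-1}), \quad r = \sigma(W_r x + U_r h_{t-1}),$$
$$\tilde h_t = \tanh(W x + U(r \odot h_{t-1})), \quad
  h_t = z \odot h_{t-1} + (1 - z) \odot \tilde h_t.$$

A softmax layer maps the last hidden state to class probabilities, and
the class with the highest probability is the prediction (exact ties
resolve D, then N, then I, so an uninformative model yields the majority
class). As defined, the network carries no bias terms; a configuration
flag can add conventional biases.

Training minimizes the class-weighted cross-entropy
$L = -\sum_j \omega_j\, y'_j \log y_j$ with default
$\omega = (0.05, 1, 10)$ for (I, N, D), which trades recall on I for
precision on I and recall on D --- the operationally useful regime, since
acting on a falsely-improved snapshot is costly. Probabilities are
clipped at $10^{-12}$ inside the loss.

### Stateful truncated BPTT

All training trajectories are concatenated into one sequence, split into
`batch_size` (default 50) contiguous streams, and consumed in
non-overlapping windows of `sequence_length` (default 30 snapshots =
60 ps). Hidden state carries across consecutive windows within an epoch
and is reset at epoch boundaries; gradients are truncated at window
boundaries. This is the standard stateful truncated-BPTT layout; the
stream construction (contiguous equal splits) is the one consistent with
windows that "continue without overlap". Note that state deliberately
leaks across trajectory boundaries during training (the concatenation
makes this unavoidable without padding); at prediction time the state is
always reset per trajectory, which the per-trajectory analyses require.
Both behaviours are flag-controlled.

Optimization uses Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-8}$) at learning rate $10^{-4}$ (default), with inverted
dropout (keep 0.9) on the non-recurrent connections only: the inputs of
each layer and the pre-softmax state, with masks resampled every
timestep (so the effective regularization is identical across BPTT
window lengths).
Weights initialize i.i.d. uniform on $[-0.08, 0.08]$, seeded. No
gradient clipping is applied. When a validation set is supplied,
per-class precision/recall/F1 are recorded every `eval_interval_steps`
and the returned checkpoint maximizes the trailing moving average
(window 30 evaluation points, truncated while fewer exist) of
improved-class precision.

The implementation is plain R matrix arithmetic. Two independent checks
guard it: the vectorized forward pass agrees with a scalar-loop
per-element reference to $10^{-10}$, and the analytic BPTT gradient
agrees with central finite differences to $10^{-5}$ relative error.

## Structure metrics

`rmsdStructures` computes CA RMSD after an optimal rigid-body
superposition (Kabsch, via SVD, proper rotation enforced).
`gdtts` reports the mean over the 1, 2, 4, 8 Angstrom cutoffs of the
fraction of residues under the cutoff, as a fraction in [0, 1]. The
superposition policy for the cutoff counts is not uniquely defined by
the score's definition; search-based implementations (LGA) explore many
local fits. The default here is a single global Kabsch fit on all paired
CA atoms, with an optional iterative mode (re-fit on residues under the
cutoff, at most 5 iterations) that approximates the search. Deposited
labels, where present in an ingested table, are taken as-is rather than
recomputed. Residues pair by residue index --- refinement snapshots share
numbering with their starting model --- and unpaired residues drop out of
both numerator and denominator. `rmsfEnsemble` superposes members onto
the first structure and measures per-residue CA fluctuation about the
ensemble mean.

## Baselines

The three non-temporal references consume the identical standardized
tables and folds: a 500-tree random forest (gini, bootstrap, no depth
limit, minimum node size 31 to split, all 19 features available to every
tree --- i.e. no feature subsampling, an unusual but deliberate setting),
5-nearest-neighbours with uniform weights and Euclidean distance, and
one-vs-rest L2 logistic regression with strength 1.0 (ridge at
$\lambda = 1/n$ on the mean-loss scale), predictions by argmax over the
per-class scores without renormalization. No class weights are applied
to the baselines. The forest is backed by `ranger`, whose
`min.node.size` gates splitting and is the closest available analogue of
a minimum internal-node sample size of 31.

## Cross-validation and trajectory statistics

`buildFolds` assigns whole targets to 7 folds at random and re-draws
until every fold's per-class snapshot percentages differ from its
training complement by at most 6 percentage points; the mechanism
(rejection sampling) is the simplest one consistent with a random but
balance-enforced assignment. All trajectories of a target share its
fold, so standardization per target cannot leak across the split.

`estimateMarkov` counts consecutive label pairs within trajectories
(never across boundaries --- the only physically meaningful choice, and
the default; counting over the raw concatenation is available for
comparison) and row-normalizes. `segmentLengths` run-length encodes the
labels. `cumulativeBy` restricts predictions to TP/FN/FP of one class
and returns a right-continuous empirical CDF along dGDT_TS or GDT_TS;
`probabilityDensity` histograms the winning-class probability with bin
width 0.05 (the figures this mirrors do not state bins).

## Restraints and contact-map collective variables

From an ensemble of predictor models (filtered at 10 Angstrom CA-RMSD to
the starting model), the package derives: position restraints for
residues with ensemble CA-RMSF under 3 Angstrom; distance restraints for
CA pairs at sequence separation of at least 5 whose ensemble-mean
distance is under 9 Angstrom with standard deviation under 1 Angstrom
(the reference distance is the ensemble mean --- the natural reading of a
single distance criterion applied to a fluctuating ensemble); and two
contact maps over residue pairs with CA or CB distance under 8 Angstrom
(CB when present, CA for glycine; the shorter qualifying distance fixes
the atom choice; direct neighbours $|i-j| = 1$ excluded --- the 5-residue
separation rule applies only to distance restraints, as specified).
CM_exl keeps contacts observed in exactly one model; CM_min keeps every
observed contact at its minimum distance across the ensemble (ties to
the first model id). The switching function
$D_\gamma(r) = (1 - (r/r_0)^6)/(1 - (r/r_0)^{10})$ is continuous through
its removable singularity at $r = r_0$ (value $6/10$), and the two
collective variables are mean squared differences of $D_\gamma$ between
a structure and each contact's own reference model, normalized by the
respective map's contact count (the normalizations are per-map; the
shared symbol in the two definitions is read per-map). Metadynamics
parameters (Gaussian deposition every 2 ps, sigma 0.5, bias factor 10,
height 5 kJ/mol) are recorded as metadata only; the package generates
inputs for and consumes outputs of MD engines, it does not run physics.

## The synthetic generator

Real refinement trajectories require GPUs, force fields and weeks of
sampling; the generator provides desk-scale data with the statistical
structure the classifier relies on:

1. a hidden three-state Markov chain per trajectory (starting in N),
   whose default matrix fixes the self-transitions at 0.806/0.626/0.947
   and resolves the remaining off-diagonal freedom so that the
   stationary distribution equals the observed prevalences
   8.2/14.5/77.3 percent (with a small direct D-to-I rate of 0.002,
   since recoveries essentially always pass through the no-change
   band);
2. a GDT_TS-change walk that mean-reverts toward a state-specific level
   (+0.05 in I, 0 in N, -0.08 in D; rate 0.5 per step, innovation sd
   0.01 --- magnitudes matching the observed dGDT_TS range of roughly
   -0.3 to +0.12) and is constrained to the state's labeling band, so
   labels re-derived from the walk always coincide with the hidden
   state while boundary-adjacent values still occur;
3. feature emissions built from the walk: the two distance metrics to
   the starting model respond to the walk's *magnitude* (RMSD rises,
   GDT_TS-to-start falls as the structure moves away from its start,
   loading 1.5 per 0.05 dGDT_TS against unit noise) --- they cannot tell
   improvement from decay, only displacement, which is why their
   ablation in the real data mainly hurt the no-change class; four
   energy terms carry a weak *directional* signal (loading -0.3 per
   0.05: genuine improvement lowers energy scores); the other 13
   descriptors are pure noise. All 19 channels add AR(1) noise with
   coefficient 0.5.

This construction places single-snapshot classification of improved
states in the weak regime the real data exhibits (where static
classifiers reach near-zero to modest improved-class precision), while
temporal integration of the noisy level evidence is genuinely
informative --- the regime the recurrent model is built for. What the
generator does *not* emulate: real energy-term distributions and their
correlations, target-to-target heterogeneity beyond the starting
GDT_TS, measurement artifacts, or any physics. Passing the desk-scale
comparisons therefore demonstrates that the machinery works and that
the temporal signal is exploited when present; it does not re-establish
the full-data performance numbers.

## The desk-scale temporal-advantage study

`temporalAdvantageStudy()` is the package's scaled analogue of the
headline comparison. It simulates the integration fixture (42 targets
x 4 trajectories x 301 snapshots, about 3 percent of the real
snapshot count), standardizes per target, holds out the six targets of
fold 0 of the balanced 7-fold split, and compares improved-class
validation precision across arms: the recurrent model with window 30,
the same model with window 1, the same model trained on
temporally-shuffled trajectories, and logistic regression (optionally
KNN and the forest).

Scaled-study choices, fixed here once: hidden width 64, 3 layers, batch
50, Adam at $10^{-3}$ (the default $10^{-4}$ is tied to 300-epoch
training on the full data), 20 epochs, evaluation three times per epoch
so that the window-30 moving average used for checkpoint selection
spans several epochs, and uniform loss weights across all arms --- the full-scale weighting $(0.05, 1, 10)$ is
designed to shape the precision/recall trade-off over millions of
training steps, and at this scale it drives every arm into the trivial
all-D solution before temporal structure can be learned, which would
make the arms indistinguishable rather than comparable.

## Numerical conventions

* Standardization: population (1/n) standard deviation, per target over
  all of that target's snapshots; degenerate columns (sd below 1e-12)
  map to zeros and are recorded with sd 1 so the transform inverts.
* Undefined precision/recall/F1 (0/0) report 0, matching how an
  all-negative classifier is conventionally scored.
* Probability ties at prediction resolve D, then N, then I.
* A state never visited yields a uniform transition-matrix row, flagged.
* The fold sampler errors after 1000 rejections, reporting the best
  imbalance achieved.
* CSV tables are comma-separated UTF-8 with a mandatory header; unknown
  extra columns are ignored on input. Snapshot tables may start at time
  0 (the starting model itself) or at 2 ps; the time-0 snapshot, when
  present, must carry dGDT_TS = 0.

What the study does and does not show, given the generator's design: the
synthetic temporal structure is first-order (a Markov state chain with
AR(1) emissions around a walk), so a recurrent model trained with even a
one-step BPTT window can learn the optimal filter — at prediction time
the network runs fully recurrently regardless of how gradients were
truncated, and the one-step arm receives thirty times more parameter
updates per epoch. Temporally shuffling the training trajectories, which
destroys the structure itself, degrades the result; shortening the
gradient window, which only changes credit assignment, need not. A
sequence-length effect like the one observed on the real data would
require longer-range dependence than the generator (or a first-order
Markov world generally) contains, and plausibly also the interaction of
the strongly imbalanced class weights with small per-update sample
counts — both full-scale phenomena that this desk-scale analogue does
not reproduce. The study therefore reads on: does the network exploit
temporal structure when it is present (shuffled vs. unshuffled), and
does it buy operating points static classifiers cannot reach
(recall/F1 against the logistic baseline at comparable precision).

## Known limitations

* The GDT_TS implementation approximates search-based scoring; scores
  on adversarial multi-domain cases can exceed those of a full search
  under the default single-fit policy.
* Training runs on a single CPU in plain R; the full 1.7M-snapshot,
  300-epoch regime is out of scope, and conclusions at desk scale are
  qualitative (orderings), not the full-data magnitudes.
* The logistic-regression backend solves the ridge problem by
  coordinate descent to machine-practical tolerance; coefficients match
  a summed-loss formulation with C = 1 up to that tolerance.
* Residue pairing is index-based; structures with inconsistent
  numbering need renumbering upstream.

## A worked example

```{r example, eval = FALSE}
ts <- standardize(makeFixture("unit"))
fit <- trainModel(ts, trainConfig(hidden_size = 16, num_layers = 1,
                                  sequence_length = 10, batch_size = 4,
                                  epochs = 2, learning_rate = 1e-3,
                                  seed = 1))
pred <- predictModel(fit$model, ts)
classMetrics(confusionMatrix3(stateLabels(ts), pred$predicted))
estimateMarkov(ts)
```
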