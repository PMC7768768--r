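---
title: "A bilateral recurrent network model of word repetition, aphasia and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bilateral recurrent network model of word repetition, aphasia and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Speech production is left-lateralized in most people, yet the right
hemisphere is not idle: functional imaging shows bilateral, left-asymmetric
activation in healthy speakers, chronic aphasia follows left- but rarely
right-hemisphere stroke, and recovery from aphasia is accompanied by
dynamic shifts of activation between the hemispheres. `bisrn` implements a
computational account of this whole pattern with a single mechanism:
*one* functional language network distributed over two hemispheric
pathways that differ only in computational capacity (number of hidden
units). Lateralization, vulnerability to left lesions, recovery dynamics
and interhemispheric compensation all emerge from the division of labor
that learning induces over this asymmetric substrate.

## The model

The network is a simple recurrent (Elman) network with two parallel
pathways between a shared phonological input layer and a shared
phonological output layer (25 units each, one per phonetic feature):

```
input (25) --> LH1 --> LH2 --\
         \                    +--> output (25)
          \--> RH1 --> RH2 --/
```

`LH1`/`LH2` have `n_left` units each and `RH1`/`RH2` have `n_right`; the
total per layer pair is fixed at 90, and the standard left-dominant model
is 60/30. Each first hidden layer has an Elman context: a copy of its own
previous-tick activation fed back as additional input, the model's
short-term memory. Optionally, sparse homotopic cross-connections link
LH1 with RH1 and LH2 with RH2 in both directions.

A repetition trial spans six ticks. The word's three phonemes are
presented at the input layer on ticks 1-3 (25-dimensional feature vectors);
on ticks 4-6 the input is zero and the network must reproduce the three
phonemes in order at the output layer, driven by its context. Hidden
activation is `logistic(gain * net)`; the per-layer gain (default 1) is the
lever used to model inefficient learning after damage. The error is the
cross-entropy between the production-tick outputs and the word's feature
vectors, and weights are updated by plain gradient descent after every
presentation.

### Backpropagation through the trial

Within a trial, gradients are propagated through all six ticks, including
the context copy (truncating the gradient at the tick boundary is
available as `backprop = "truncated"`). The choice matters more than it
may appear: with targets confined to ticks 4-6 and input confined to
ticks 1-3, a fully truncated learner gives the input-to-hidden weights
exactly zero gradient — no error signal ever reaches the ticks on which
the input arrives — and the network never rises above floor on this task.
Full within-trial backpropagation restores the path from production-tick
errors to input-tick weights. Trials remain independent: contexts reset
to zero between words and no gradient crosses trial boundaries.

### Cross-connection timing

Mutual connections between two layers at the same depth cannot be resolved
within a single tick without circularity, so cross input arrives with a
one-tick delay: LH1 at tick *t* receives RH1's activation from tick
*t - 1* (and vice versa, and likewise for LH2/RH2). Under
`cross_constraint = "negative_only"` the cross weights are clipped at zero
from above after every update, implementing the classical hypothesis of
purely inhibitory transcallosal connectivity.

## The training environment

The lexicon emulates a monosyllabic consonant-vowel-consonant (CVC)
repetition corpus: 100 high-frequency and 100 low-frequency words drawn
without replacement from an inventory of 18 consonants and 6 vowels
(1944 possible triples), plus 25 nonword probes built by substituting a
single phoneme (same slot, same class) in a word. Nonwords are never
trained; they measure generalization.

Each phoneme is a 25-dimensional binary feature vector: feature 1 is a
consonant/vowel indicator and the remaining 24 are drawn independently
with probability 0.3, resampled until all phonemes are pairwise distinct.
The sparsity is deliberate: real phonetic feature systems activate a
minority of their features per phoneme, and a sparse code is also what
gives the mean-output-activation measure (below) a meaningful baseline —
under a dense (p = 0.5) code the mean output is pinned near 0.5 for any
pathway and the activation laterality index degenerates to zero.

Token frequencies are drawn uniformly from disjoint bands (high-frequency
200-2000, low-frequency 1-20) and a word's presentation probability is
proportional to `log(1 + frequency)`, the usual logarithmic compression of
word-frequency effects. High-frequency words therefore dominate training
without starving the low-frequency band.

What the generator does *not* emulate: real phonotactics, stress,
articulatory similarity structure, or a natural frequency distribution
within bands. Passing tests show that the simulated phenomena follow from
capacity asymmetry plus distributed learning over *a* compositional
phonological code, not from the phonetics of any language.

## Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `learning_rate` | 0.02 | gradient step per presentation |
| `init_range` | 0.5 | weights start uniform in [-0.5, 0.5] |
| `n_io` | 25 | phonological feature dimensionality |
| `cross_density` | 0 | fraction of homotopic cross links |
| gain | 1 | per-layer multiplier inside the logistic |

The learning rate and initial weight range are calibrated to a single
stated criterion — the intact 60/30 model must repeat words at > 98% and
nonwords at > 96% after 300,000 presentations — and are otherwise
untouched. Both matter: at 0.05 the loss diverges, at 0.005 convergence
takes far longer than 300K presentations, and with a narrow initial range
(0.1) whole-word learning succeeds while nonword generalization plateaus
below criterion; the wider range breaks symmetry early and yields
systematic, compositional solutions. Laterality should be measured on
converged models: mid-training, transient symmetry breaking can
lateralize the network either way regardless of capacity.

## Lesions and recovery

`apply_lesion()` damages one first hidden layer: a uniformly chosen
fraction of its units dies permanently (activation clamped to zero, no
further updates; the units stay addressable so lesioned and perilesional
populations can be measured separately), and every weight into and out of
the layer receives one draw of additive Gaussian noise. The graded
severity scheme pairs damage proportions 0.1-1.0 with noise levels
0.1-1.0. The noise level is interpreted as a variance by default (so the weight
perturbation has standard deviation `sqrt(v)`); because graded noise
levels of this kind are sometimes stated as standard deviations or
ranges instead, a `noise_as = "sd"` switch makes the alternative reading
testable (the qualitative results do not depend on it). Noise is applied once, at
lesion time.

`retrain()` then re-exposes the model to the unchanged training
environment (default 100,000 presentations). Inefficient early
relearning is modelled by a gain ramp on the lesioned layer's surviving
units: gain 0 for the first 1,000 presentations, then steps of 0.1 every
1,000 up to 1 from 10,000 on. At gain 0 a unit's activation is flat at
0.5 and its incoming weights receive no gradient, so the layer neither
varies its response nor learns; capacity returns gradually. The ramp can
be disabled (`ramp = FALSE`) — recovered performance is similar without
it.

## Model "neuroimaging"

All read-outs are pure measurements (they never change weights):

* **Pathway silencing.** The unique contribution of one pathway is probed
  by zeroing the *other* side's input-to-H1 drive for a trial
  (`silence` in `forward_trial()`). Silencing removes the stimulus signal
  only; bias- and context-driven activity on the silenced side remains,
  matching the reading that the probe removes the input signal rather
  than the pathway. Cross-connections, when present, stay active during
  the probe.
* **Functional contribution** (`functional_contribution()`): Pearson
  correlation between the side-only and full-model output patterns over
  all words and production ticks, after centering each output unit x tick
  across words — so the measure captures the stimulus-driven pattern a
  pathway transmits, not shared baseline activity, and a fully lesioned
  pathway's contribution collapses to zero. A proxy for effective
  connectivity.
* **Output activation** (`mean_output_activation()`): mean side-only
  output activation over words and production ticks — a proxy for BOLD
  amplitude.
* **Laterality index**: `(L - R) / (L + R)` of either measure; positive
  is left-dominant. The capacity asymmetry index is the same formula over
  unit counts (60/30 gives +1/3).
* **RSA** (`compute_rdm()`, `rsa_score()`, `target_rdm()`): per word, a
  hidden layer's live-unit activations over the three production ticks
  are concatenated; representational dissimilarity matrices are
  1 - Pearson over words; the RSA score is the lower-triangle correlation
  between a layer's RDM and the target RDM. The target RDM is computed
  from the ground-truth phonological feature vectors rather than from
  produced outputs: the reference must stay fixed and non-degenerate
  while the model is severely impaired (a produced-output variant is
  available via `target_rdm(..., patterns = state)`).
* **Weight statistics** (`weight_statistics()`): mean |w| and mean |Δw|
  versus a pre-lesion snapshot, over live entries only.

Output-activation summaries use the production ticks; hidden-activation
summaries average all six ticks. Mean hidden activation, perilesional and
lesioned populations, and per-layer RSA scores are recorded at every
checkpoint of a recovery trajectory.

## Experiments

The four study runners mirror the structure of the simulated experiments:

* `run_capacity_sweep()`: capacities 15/75, 30/60, 45/45, 60/30, 75/15;
  correlates both laterality indices with the capacity asymmetry index
  pooled over models.
* `run_lesion_sweep()`: graded left and right lesions, full retraining,
  final recovered accuracy per level; left levels group into mild
  (0.1-0.3), moderate (0.4-0.6), severe (0.7-1.0). Recovered performance
  is summarized as overall item accuracy (words and nonwords pooled),
  since generalization to nonwords is the component most sensitive to
  residual damage.
* `run_recovery_timecourse()`: the left mild / left moderate / left
  severe / right severe conditions; trajectories plus phase contrasts of
  pathway output activation between the acute (first 1K presentations),
  subacute (1K-5K) and chronic (5K-40K) windows, paired t-tests across
  seeds with Bonferroni correction (the most conservative default, since
  the correction method is a free choice).
* `run_interconnectivity()`: repeats the above at cross-connection
  densities 0/0.3/0.7, free or negative-only, and collects the learned
  cross-weight distribution.

Every run is fully determined by its seeds: generators take explicit
seeds and restore the caller's RNG state, network initialization is a
function of `config$seed`, the presentation sequence follows R's global
RNG (`set.seed()` before training), and lesion draws use the lesion
spec's own seed, independent of the training stream. Statistical tests
across seeds mirror a multi-participant design, with each seed playing
the role of one simulated participant.

## Numerical choices and degenerate inputs

* Output probabilities are clamped to `[1e-12, 1 - 1e-12]` inside the
  cross-entropy only; activations themselves are never clamped.
* Decoding is nearest-neighbour in feature space (Euclidean), ties broken
  by inventory order; an item is correct only if all three phonemes are.
* Zero-variance patterns: `compute_rdm()` refuses them (naming the word),
  `functional_contribution()` returns 0 with a warning, and
  `correlate_measures()` flags constant series as `NA` rather than
  silently reporting zero.
* `laterality_index(0, 0)` is an error, not a zero.
* Lesioning a fully dead layer is an error; killing 100% of a layer is
  allowed and downstream measures either work (activation means) or fail
  loudly (RSA on an empty pattern).

## Problem sizes used by the test suite and acceptance script

Unit and property tests run on small networks (3-12 units per layer) and
a 30-word lexicon; the gradient oracle compares analytic gradients with
central finite differences of an independent R implementation of the
forward pass (for the truncated mode, of the frozen-context loss whose
exact gradient the truncated scheme computes). The acceptance-level runs
use the full 200-word lexicon with the full 300,000-presentation
developmental protocol where a criterion depends on convergence
(intact accuracy, capacity sweep, developmental RSA correlations), and
scale seed counts and recovery lengths down (2-5 seeds, 40-100K recovery
presentations) elsewhere; each test states its sizes inline.

## Known limitations

* The phonological code is synthetic; effects that depend on genuine
  phonetic similarity structure (e.g. realistic error confusions) are out
  of scope.
* One output attempt per tick; no reaction times, no cascaded dynamics,
  no semantic/ventral route.
* Lesions are single events; progressive damage and re-lesioning are not
  modelled.
* With 25 nonwords, generalization accuracy moves in 4% steps, so
  nonword accuracy is intrinsically coarse.
* The gain ramp applies to the lesioned layer only; distributed
  diaschisis-like effects on remote layers are not modelled.
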