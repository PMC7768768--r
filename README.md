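# bisrn — a bilateral recurrent network model of word repetition, aphasia, and recovery

`bisrn` implements a connectionist model of spoken word repetition built
around one idea: the two hemispheres host a *single* functional language
network whose pathways differ only in computational capacity. The package
lets you train that network, damage it, let it recover, and read out the
model analogues of neuroimaging measures — so that hemispheric
lateralization, chronic aphasia after left (but not right) stroke, the
acute→subacute→chronic activation shifts of recovery, and the effects of
interhemispheric connectivity can all be simulated from synthetic inputs
alone.

## The model in brief

A simple recurrent (Elman) network runs each trial for six ticks: three
phonemes of a consonant–vowel–consonant word are presented at a shared
25-feature phonological input layer (ticks 1–3), and the network must
reproduce them in order at a shared output layer (ticks 4–6), driven by
its context memory. Two parallel hidden pathways connect input to output
(`input → LH1 → LH2 → output` and `input → RH1 → RH2 → output`), with
n<sub>L</sub> and n<sub>R</sub> units per hidden layer and
n<sub>L</sub> + n<sub>R</sub> = 90; the left-dominant reference model is
60/30. Training is online cross-entropy backpropagation over 300,000
word presentations sampled by log-compressed word frequency.

Key read-outs, for any trained or lesioned state:

* **Laterality** — silence one pathway's input and measure the other's
  unique contribution, either as the correlation of its output patterns
  with the full model's (*functional contribution*) or as mean output
  activation; laterality index = (L − R)/(L + R).
* **Lesion & recovery** — kill a fraction of a hidden layer's units, add
  Gaussian noise to its weights, retrain under a gain ramp that models
  initially inefficient relearning, and track accuracy, pathway
  activations, perilesional activity, and weight change.
* **RSA** — correlate each hidden layer's representational dissimilarity
  matrix (1 − Pearson over words) with the target phonological RDM; the
  score tracks what a layer actually encodes, in a way raw activation
  does not.

## Worked example

```r
library(bisrn)

inv <- build_inventory(seed = 42)          # 18 C + 6 V, 25 binary features
lex <- generate_lexicon(inv, seed = 42)    # 100 HF + 100 LF words, 25 nonwords

cfg <- network_config(n_left = 60, n_right = 30, seed = 1)
net <- init_network(cfg)
set.seed(1)                                # presentation sequence
fit <- train(net, lex, inv, n_presentations = 300000, eval_every = 50000)
tail(fit$log[, 1:5], 1)
#>   presentations accuracy_hf accuracy_lf accuracy_nw accuracy_words
#> 7         3e+05         100         100         100            100

feats <- bisrn:::encode_items(lex$words, inv)
fc_l <- functional_contribution(fit$state, feats, "left")  # 0.997
fc_r <- functional_contribution(fit$state, feats, "right") # 0.123
laterality_index(fc_l, fc_r)
#> [1] 0.7795894
```

The trained model repeats every word and generalizes to the untrained
nonwords. The left pathway alone almost fully reproduces the model's
output patterns (functional contribution 0.997) while the right alone
carries much less (0.123), a strongly left-lateralized division of labor
(laterality +0.78) for a 60/30 capacity split (asymmetry index +0.33).

Damage it and let it recover:

```r
les <- apply_lesion(fit$state,
                    lesion_spec("LH1", proportion = 0.5, noise = 0.5,
                                seed = 2))
set.seed(3)
rec <- retrain(les, lex, inv, n_presentations = 100000, eval_every = 5000,
               reference_state = fit$state)
rec$trajectory[c(1, 2, 21), c("presentations", "accuracy_words",
                              "out_act_left", "out_act_right")]
#>    presentations accuracy_words out_act_left out_act_right
#> 1          0e+00              0   0.08413502     0.1100437
#> 2          5e+03             61   0.24718033     0.2617541
#> 21         1e+05            100   0.24709022     0.2224393
```

Immediately after a moderate left lesion, performance is at floor; with
retraining, word accuracy recovers while output activation becomes more
bilateral, the right pathway transiently overshooting the left before
settling back. More severe left lesions leave persistent deficits —
chiefly in nonword generalization — and a complete left lesion is never
overcome, whereas right lesions of any severity recover quickly.

The four study-level experiments are packaged as runners:
`run_capacity_sweep()`, `run_lesion_sweep()`, `run_recovery_timecourse()`,
and `run_interconnectivity()`. A thin command-line front end over the same
functions lives in `inst/cli/bisrn.R` (subcommands `make-lexicon`,
`train`, `lesion`, `retrain`, `measure`, `experiment`).

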