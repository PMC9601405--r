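---
title: "Methods: screen design, featurization and outcome modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen design, featurization and outcome modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amidescreen)
library(dplyr)
```

This vignette records the methodological choices behind `amidescreen`: how
the condition ramp is constructed, how outcomes are labelled and aggregated,
how reactions are turned into feature vectors, how the outcome classifier is
trained and selected, and what statistical structure the synthetic generator
guarantees. It is the reference for anyone auditing the numbers the package
produces.

## 1. The condition ramp

A screening campaign explores reaction conditions along a one-dimensional
*harshness* axis anchored at three points — soft (120 s, 50 °C), mid
(360 s, 120 °C) and harsh (600 s, 200 °C). `build_condition_grid(n)` places
`n` points on this axis:

* reaction time is linear from soft to harsh (for the 9-point preset:
  120 s to 600 s in 60 s steps);
* temperature is piecewise linear, soft→mid over the first half of the
  ranks and mid→harsh over the second, with the mid anchor landing exactly
  on the middle rank. The two segments have different slopes
  (17.5 °C/rank, then 20 °C/rank for the preset), which is why temperature
  is not a single line.

```{r grid}
build_condition_grid(9)
```

Anchors must be ordered (soft ≤ mid ≤ harsh in both coordinates); even
`n` snaps the mid anchor to the nearest rank with a classed warning. The
grids are monotone non-decreasing in both coordinates by construction, a
property the test suite checks over random anchor triples.

### Stopped-flow accounting

In a stopped-flow run the reagent slugs transit the reactor and are then
held stationary, so the reaction time is the sum of two parts:

```{r flow}
setup <- flow_setup()   # 1 mL reactor, 3 x 500 uL/min pumps, 0.5 mL slugs
reaction_time_components(setup, stationary_time_s = 600)
```

Reagent economy is the point of the technique: a 0.5 mL slug with a 2x
safety margin consumes 1 mL of stock per experiment, against the ~10 mL a
continuous-flow experiment needs to reach steady state before sampling —
the 90 % reduction that `reagent_usage_comparison()` reports.

## 2. Labelling and success rates

An experiment is *successful* when its product UV peak area at 254 nm,
relative to all product-related peaks, reaches 10 %. `label_outcomes()`
applies the rule inclusively (`>= 10`) by default; `inclusive = FALSE`
gives the strict variant. Records with `status = "instrument_failure"` are
labelled `missing` and excluded from every downstream computation rather
than imputed.

Success-rate tables count *products* (acid–amine pairs), not experiments,
at three scopes:

* `single_condition`: a product succeeds under one (agent, condition) cell;
* `per_agent_sequence`: a product succeeds anywhere in an agent's ramp;
* `full_screen`: a product succeeds anywhere in the campaign.

The denominator is always the number of designed products, so the three
scopes are nested and their rates ordered. The test suite verifies every
table against a brute-force loop over products.

## 3. Featurization

### Molecular graphs

SMILES are parsed through OpenBabel (`ChemmineOB`) into V2000 molfiles,
from which `amidescreen` reads the heavy-atom graph (elements, formal
charges, bonds) and computes implicit hydrogen counts from standard
valences. `amide_product_smiles()` forms the condensation product at the
graph level — drop the carboxyl hydroxyl oxygen, bond the carbonyl carbon
to the amine nitrogen — and returns OpenBabel's canonical SMILES. Reactants
with zero or multiple reactive sites raise classed errors instead of
guessing.

### Circular count fingerprints

Fingerprints are implemented in the package (they are part of the method,
not an off-the-shelf step). Each atom receives an initial invariant hashed
from (element, heavy degree, implicit H count, formal charge); the
invariant is then iteratively re-hashed with the sorted invariants of its
neighbours up to radius 3. Each iteration emits an environment identifier,
but only while the atom's reach set is still growing — so a methane carbon
contributes one environment, not four. Identifiers are folded modulo
`n_bits` (default 2048) into a **count** vector, not a bit vector:

```{r fp}
fp <- circular_count_fp("CC(=O)O", n_bits = 256)
sum(fp)            # total environments emitted
sum(fp > 0)        # distinct buckets hit
```

The `"circular_path"` variant appends a same-width block counting simple
bond paths of length 1–5, each canonicalized over its two traversal
directions.

A **reaction fingerprint** is the product count vector minus the sum of the
reactant vectors. The reconstruction identity
`product = reaction + sum(reactants)` holds exactly for every assembled
feature row, and environments farther than the radius from the reacting
centre cancel, which the tests confirm by lengthening an alkyl chain.

### Condition and property blocks

Conditions are one-hot encoded per block (agents, temperatures, times) over
a vocabulary fixed from the full campaign, so a 4-agent, 5-temperature,
5-time screen encodes in exactly 14 bits and every row sums to 3. Reagent
property tables (including pKa columns) are median-imputed with missingness
indicators and standardized with statistics fitted on the training side of
a split only — `assemble_features()` takes the fitted standardizer when it
assembles held-out data. The registry crosses
{reaction fp, product fp, both} × {± conditions} × {± properties} into 12
named feature sets.

## 4. The outcome classifier

The classifier is a small feed-forward network written in base R: 1–3
ReLU hidden layers, a sigmoid output, binary cross-entropy loss, Adam
updates, inverted dropout and He initialization. Training is deterministic
given the config seed (all randomness flows through `withr::with_seed`).
The package deliberately does not wrap an external deep-learning framework;
`nnet` appears only in the test suite as an independent cross-check on a
separable problem.

Hyperparameters are chosen by random search (`tune_hyperparameters()`):
`budget` configurations sampled from a space of layer counts, widths,
dropout rates, log-uniform learning rates, epochs and batch sizes, each
scored by mean inner stratified 3-fold accuracy at cutoff 0.5, with ties
broken toward fewer parameters.

Metrics (`evaluate_metrics()`) report the confusion counts at a cutoff plus
precision, recall, accuracy and ROC AUC. The AUC is computed cutoff-free by
the Mann–Whitney rank statistic with mid-ranks for ties; the tests pin it
against `pROC` on tied and untied score sets. Undefined values (no positive
predictions, single-class labels) surface as `NA` with a classed warning,
never as silent zeros.

## 5. Validation protocol and selection

`run_cv_protocol()` evaluates each feature set on eight outer splits of the
first campaign — three random stratified 60/40 splits and one
leave-one-amine-out split per amine — and trains each split twice: once on
the true labels and once on a shuffled-label twin that passes through the
identical tuning pipeline. With five amines that is 16 models per feature
set. The shuffled twins estimate the protocol's chance level; any feature
set that cannot beat its own twin on hold-on precision is rejected
(`select_best_model()` raises a no-signal error if none survives).

Selection ranks feature sets by mean hold-on precision of the true-label
models — precision because the downstream use is choosing which experiments
to run, and a selected failure costs real material — with ties broken by
mean ROC AUC and then smaller feature width.

Leakage is guarded structurally: the protocol refuses datasets spanning
more than one campaign, trained models record their training campaigns, and
`evaluate_temporal()` refuses any temporal dataset that overlaps them. The
temporal campaign therefore never touches training, tuning,
standardization or selection.

`prioritization_analysis()` replays the "what would the model have told us
to run" question: experiment and unique-product tallies above each score
threshold, plus a highest-score-per-product selector (score ties broken
toward the harsher condition, then the lexicographically first agent, so
the selection is deterministic).

## 6. The synthetic generator

`generate_library()` draws campaigns from a logistic latent surface:

$$p = \mathrm{logit}^{-1}\big(\beta_0 + \beta_{\text{agent}}
 + \beta_T\, z(T) + \beta_t\, z(t) + u_{\text{acid}} + v_{\text{amine}}
 + w_{\text{pair}}\big)$$

with temperature and time standardized over the grid. The defaults encode
the study conditions the analysis assumes: agent effects ordered
PyCIU > TCFH > HATU > T3P; a strong temperature slope (1.5 log-odds/SD) and
a *zero* time slope; reagent and pair random effects of SD 0.8; Gaussian
response noise (SD 4 area-%) clipped to [0, 100]; and a 64/900 dropout
rate. The intercept `qlogis(0.1)` centres the latent response on the 10 %
threshold so the outcome classes are roughly balanced.

Two guarantees matter for testing. First, reagent effects are keyed to
`(seed, reagent id)`, so a later campaign generated from the same config
reuses the effects of every reagent it shares with the first — exactly what
a temporal hold-out needs. Second, the returned ground truth carries every
per-record probability and realized effect, so recovery tests (agent-order
Kendall tau, temperature monotonicity, chi-square structure on a crossed
time × temperature grid) compare observed behaviour against the generating
parameters rather than against the implementation itself.

```{r truth}
syn <- generate_library(synthetic_config(seed = 1))
d <- label_outcomes(syn$dataset)
d |> filter(label != "missing") |>
  group_by(agent_id) |>
  summarise(success = mean(label == "successful"))
```

## 7. Determinism and oracles

Every stochastic element — splits, tuning draws, weight initialization,
label shuffling, synthetic campaigns — derives from integer seeds through
one mixing function, so whole-pipeline runs are bit-reproducible. The test
suite never checks the implementation against itself: success rates are
pinned to brute-force loops, AUC to `pROC`, the network to `nnet`,
fingerprints to hand-enumerated environment censuses, and amide products to
independently drawn canonical structures.
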