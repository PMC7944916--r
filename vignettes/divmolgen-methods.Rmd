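---
title: "Generating diverse, property-targeted molecules with divmolgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating diverse, property-targeted molecules with divmolgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

De novo molecular design asks a generative model to propose novel,
synthesizable molecules whose properties — typically predicted binding
affinity (pIC50, the negative decadic logarithm of IC50 in molar) or a
physicochemical property like the octanol/water partition coefficient
(logP) — are shifted toward a target. The well-known failure mode of
reward-driven fine-tuning is mode collapse: the policy finds a handful of
high-reward molecules and emits them over and over. divmolgen implements a
generation framework built specifically against that failure: the reward is
shaped to *preserve diversity* while the property is optimized.

## The model

**Generator.** A character-level SMILES language model: tokens (atoms,
bonds, branches, ring closures; two-letter elements such as `Cl`/`Br`,
bracket atoms and `%NN` closures are single tokens) are wrapped in a start
marker `G` and end marker `E`, padded with spaces to a fixed length, one-hot
encoded, and fed through stacked LSTM layers with a softmax head. Training
uses teacher forcing with the token-wise binary cross-entropy

$$J(\theta) = -\frac{1}{T}\sum_{t=1}^{T}\left[y_t\log\hat y_t +
(1-y_t)\log(1-\hat y_t)\right],$$

where the inner product runs over vocabulary components, probabilities are
floored at $10^{-8}$ inside the logarithms, and pad positions are excluded
from both the sum and $T$ (otherwise pad tokens dominate the gradient).
Molecules are sampled token by token from the temperature-scaled softmax;
the pad and start tokens are removed from the sampling support so a
sequence can only end by emitting `E` or reaching the length limit.

**Predictor.** A QSAR regressor mapping SMILES to pIC50. The headline
variant embeds tokens (learned embedding), runs two GRU layers, and reads
the hidden state at the last real token through a dense layer into a linear
output. Baselines operate on radius-3 Morgan fingerprints folded to 4096
bits: a fully connected network, polynomial-kernel SVR, random forest, and
k-nearest neighbours. The protocol holds out 15% as a test set, splits the
rest into five folds, trains one model per fold (with an inner 85/15
train/validation split and early stopping for the neural variants), and
standardizes labels with statistics of the inner training portion only —
fitting the scaler on anything wider would leak test information. The
reported metrics are MSE and $Q^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$, with
the observed mean of the evaluation set itself in the denominator (the
choice is not forced by the definition; we flag it as a convention).
Predictions for new molecules average the five fold models after
de-standardization.

**Reinforcement learning.** Fine-tuning treats the generator as the policy:
tokens are actions, the partially built SMILES the state. Each iteration
samples a batch of molecules, scores the valid ones through the property
oracle, converts the property to a reward — $R = \exp(p\mathrm{IC}_{50}/4 -
1)$ for maximization, a flat-plateau rule ($3$ inside the logP window
$[1,4]$, $3e^{-d}$ outside, $d$ the distance to the nearest bound) for the
partition-coefficient objective — and updates the policy by REINFORCE:

$$J(\theta) = -\frac{1}{n}\sum_i\sum_j R_i\,\gamma^{j}\,
\ln p(s_j \mid s_0\ldots s_{j-1}, \theta).$$

Gradients are clipped elementwise to $[-3, 3]$ and applied with Adam.

## The diversity machinery

Two mechanisms distinguish this framework from plain REINFORCE
fine-tuning:

* **Dual-generator exploration.** Two copies of the pre-trained generator
  participate: $G_u$ stays frozen, $G_b$ is updated. At every token
  position a uniform draw $\epsilon$ below a threshold $\lambda$ delegates
  the next token to $G_u$; both models always condition on the same shared
  prefix, and the log-probabilities entering the loss are always $G_b$'s
  (the policy being optimized). $\lambda$ is chosen per batch from the
  recent reward trend: with the triple $\tau = [\lambda_{\uparrow},
  \lambda_{\downarrow}, \lambda_{0}]$, two consecutive increases of the
  batch-mean reward select the small $\lambda_{\uparrow}$ (exploit while it
  works), two decreases the large $\lambda_{\downarrow}$ (fall back to the
  unbiased model), anything else the intermediate $\lambda_{0}$. The
  default triple is $[0.05, 0.2, 0.1]$ with $[0,0,0]$ as the no-exploration
  baseline.

* **Rolling-memory penalty.** The fingerprints of the last 30 generated
  valid molecules form a FIFO memory. For each new molecule the mean
  Tanimoto *distance* to the memory is computed; below the threshold
  $\kappa$ (default 0.75) the reward is cut by 15%. Invalid molecules never
  enter the memory and never trigger the penalty.

Every `eval_every` iterations a snapshot of sampled molecules is scored,
and the checkpoint maximizing desirable-fraction × internal Tanimoto
diversity is kept — the best policy is typically *not* the final one, since
late-stage exploitation trades diversity for reward.

## Evaluation metrics

For a generated set the package reports percent valid (own sanitizer, see
below), percent unique (unique canonical forms among valid molecules — the
denominator choice makes uniqueness independent of validity), percent
desirable (predicted pIC50 ≥ 6.5, or logP inside the window), mean
synthetic-accessibility score, and internal/external diversity
$\mathrm{Div}(A,B) = \frac{1}{|A||B|}\sum_{a}\sum_{b} d(a,b)$ under three
distances: $1 - $ Tanimoto over 4096-bit radius-3 Morgan fingerprints,
raw-character Levenshtein edit distance (reported unnormalized), and $1 -$
MCS similarity, where MCS similarity is
$\mathrm{mcs}/(\mathrm{atoms}_a + \mathrm{atoms}_b - \mathrm{mcs})$ over
the maximum common induced substructure. Internal diversity keeps the
strict $1/n^2$ normalization, i.e. self-pairs are included (they
contribute 0 for the normalized distances). One fingerprint definition is
used everywhere — predictor features, memory penalty, diversity — so the
numbers are mutually consistent.

The MCS is found by a maximum-clique search on the modular product of the
two molecular graphs (element and bond-order matching). The search is exact
with a configurable timeout; on timeout a greedy lower bound is returned
and flagged approximate. Because the search is exponential in the worst
case, set-level MCS diversity is computed on a capped subset (default 30
molecules).

## Chemistry backend and the validity oracle

Canonical SMILES, logP, molecular weight and ECFP fingerprints are
delegated to OpenBabel (one batch call per operation; ~30 ms for 500
molecules). OpenBabel alone, however, is too permissive as a validity
oracle — it accepts pentavalent carbon and silently repairs unbalanced
syntax — so the package implements its own sanitizer: a linear graph parse
of the token stream (balanced branches, matched ring bonds, no dangling
bond symbols) followed by a valence check (bond-order sums against
per-element maxima, aromatic bonds counted as 1.5, positive charges
widening the allowance, aromatic atoms required to sit on at least two
aromatic bonds), and finally an OpenBabel parse. A molecule is valid only
if all three agree. This is deliberately conservative for exotic bracket
chemistry; for the organic subset the package generates, it matches
chemical intuition.

**Synthetic accessibility.** The score follows the fragment-contribution
scheme: mean rarity of the molecule's circular fragments plus size, ring
and branching penalties, affinely mapped and clamped to $[1, 10]$ (above 6
conventionally reads "hard to synthesize"). The published
fragment-frequency table is not shipped; fragment rarity is instead
calibrated on a reference corpus — by default the package's own
deterministic fixture corpus — via `sas_calibration()`. Absolute values are
therefore corpus-relative; orderings (ethane below a fused polycycle) and
the bounded scale are preserved, which is what the desk-scale checks rely
on.

## The fixture corpus: what it emulates and what it does not

`generate_fixture_corpus()` builds small molecules (3–13 heavy atoms) by a
valence-tracked random tree construction over C/N/O/S with single/double
bonds, optional 5/6-membered rings and halogen decoration, written out by
the package's own SMILES writer — every string is valid by construction,
and the whole corpus is deterministic in the seed. It emulates the
*syntactic* structure of a SMILES corpus (branching, rings, heteroatoms)
at a scale where the full pipeline trains in minutes on one CPU. It does
not emulate drug-like property distributions, stereochemistry, aromatic
ring systems, or the 45-token vocabulary of a screening library; passing
the desk-scale tests therefore demonstrates that the machinery (training,
scheduling, penalty, metrics) behaves as specified, not that a
fixture-trained generator is a useful drug designer. Full-scale behaviour
requires pre-training on a curated library (the curation defaults — logP in
$[-2, 6]$, molecular weight in $[200, 600]$ g/mol, canonical
deduplication, padded length 65 — are the settings for that regime).

## Numerical and design choices

* **Network sizes.** Full-scale defaults follow the protocol (2×LSTM-256
  generator, embedding-128 + 2×GRU-128 predictor, padded length 65). The
  desk-scale runs in tests and `scripts/acceptance.R` use 2×LSTM-64 with
  padded length 32 for the generator and embedding-16 + 2×GRU-32 for the
  predictor: the fixture molecules are short and the smaller nets keep the
  end-to-end suite within minutes while leaving every mechanism intact.
* **Engine.** The recurrent networks, backpropagation through time and
  Adam are implemented in batch-vectorized R inside the package and are
  verified against finite-difference gradients in the test suite.
* **Discounting.** A per-molecule-constant discount (indexing $\gamma$ by
  the molecule's position in the batch) only rescales molecules by their
  arbitrary batch order, so the default discounts by token position $j$
  (from 1), consistent with the definition of the discounted return. The
  per-molecule-index variant stays available via
  `discount_by = "molecule"`. $\gamma$ defaults to 0.97.
* **"25 training iterations"** for generator pre-training is read as
  epochs, consistent with the batch-size phrasing.
* **Invalid molecules** receive reward 0: they contribute no gradient,
  which neither rewards unparseable strings nor destabilizes the loss.
  Configurable via `invalid_reward`.
* **Minimization reward** (for selecting *against* a target) is
  $\exp((k_0 - p)/4)$ with $k_0 = 2$, mirroring the maximization rule's
  scale; the constant is configurable.
* **Trend detection** reads "reward increasing" as two consecutive
  positive deltas of the batch-mean reward; $\epsilon$ is drawn per token,
  $\lambda$ frozen per batch.
* **Output-layer width** always equals the actual vocabulary size: the
  vocabulary is rebuilt from the training corpus, persisted with the
  model, and every layer is sized from it, so generator and checkpoints
  can never disagree about the token set.
* **Baseline hyperparameters** (SVR poly kernel with C 0.125 and gamma 8,
  RF 500 trees with sqrt feature sampling, kNN k = 11) render ambiguously
  in the source table; they are exposed in `qsar_config()` so they can be
  re-tuned. Early-stopping patience (10) and FCNN dropout (0.25) are
  common defaults, also exposed.
* **Q² denominator** uses the evaluation set's own mean; ties are broken
  toward the earliest iteration in checkpoint selection; RL fine-tuning
  runs without dropout.

## Problem sizes used by the shipped runs

The acceptance script pre-trains on 2,000 fixture molecules for 5 epochs,
runs the full RL budget (85 iterations × 10 molecules) for both the
exploration configuration ($\tau_2$, $\kappa = 0.75$) and the baseline
($\tau_1$, penalty off), evaluates 500-molecule samples, runs 200 bandit
updates, and fits the recurrent QSAR on 500 planted-rule records. These
sizes are the package's desk-scale study conditions; they complete in a
couple of minutes on one CPU.

## Known limitations

* OpenBabel's canonical SMILES and logP differ numerically from other
  toolkits; curation windows are applied in OpenBabel's scale.
* The sanitizer is stricter than full aromaticity perception: unusual
  aromatic systems written in lowercase may be rejected.
* SAS values are calibrated to a reference corpus, not to the published
  fragment table; compare SAS values only within one calibration.
* The exact MCS search is exponential; pairs of large molecules fall back
  to the flagged greedy bound after the timeout.
* Single-objective rewards only; multi-objective scalarization is out of
  scope.
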