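# divmolgen

Diversity-aware de novo molecule generation by reinforcement learning, in R.

`divmolgen` is for computational chemists and method developers who want to
fine-tune a SMILES language model toward a property target — predicted
binding affinity (pIC50) from a built-in QSAR module, or computed logP —
*without* the usual mode collapse into a handful of repeated molecules. The
package implements the whole loop: corpus curation, generator pre-training,
QSAR prediction, REINFORCE fine-tuning with two diversity mechanisms, and a
full evaluation suite.

## The method in brief

A recurrent SMILES generator (stacked LSTMs over a tokenized, padded,
one-hot corpus) is pre-trained by teacher forcing with the token-wise
cross-entropy

    J(θ) = −(1/T) Σ_t [ y_t log ŷ_t + (1 − y_t) log(1 − ŷ_t) ]

and then fine-tuned as a policy with REINFORCE:

    J(θ) = −(1/n) Σ_i Σ_j R_i · γ^j · ln p(s_j | s_0…s_{j−1}, θ)

where the reward converts the predicted property, e.g.
`R = exp(pIC50/4 − 1)` for affinity maximization. Two mechanisms preserve
novelty during fine-tuning:

* **Dual-generator exploration** — a frozen copy `G_u` and the updated copy
  `G_b` alternate *per token*: with probability λ the next token comes from
  `G_u`. λ is picked each batch from the reward trend out of a triple
  τ = [λ_increasing, λ_decreasing, λ_no-trend] (default `[0.05, 0.2, 0.1]`).
* **Rolling-memory penalty** — the reward is cut by 15% whenever the new
  molecule's mean Tanimoto distance to the last 30 generated molecules
  falls below κ (default 0.75).

Generated sets are scored for % valid, % unique, % desirable (pIC50 ≥ 6.5
or logP in [1, 4]), synthetic accessibility (1–10), and internal/external
diversity Div(A,B) = (1/|A||B|) Σ Σ distance(a,b) under 1 − Tanimoto
(4096-bit radius-3 Morgan fingerprints), Levenshtein edit distance, and
1 − MCS (maximum common substructure atom ratio).

Chemistry (canonical SMILES, logP, molecular weight, fingerprints) runs
through the OpenBabel CLI (`obabel` must be on the PATH); validity uses the
package's own stricter syntax + valence sanitizer. The recurrent networks
and backpropagation are implemented inside the package and verified against
finite-difference gradients in the test suite.

## Worked example

Desk-scale run on the package's built-in fixture corpus (2,000 small
valid-by-construction molecules), optimizing logP into the window [1, 4]:

```r
library(divmolgen)

corpus <- generate_fixture_corpus(2000, seed = 1)
gen <- train_generator(corpus,
  generator_config(recurrent_units = 64, max_len = 32, epochs = 5, dropout = 0.2),
  seed = 1)
gen
#> <dmg_policy> 2 x LSTM-64 over 13 tokens (max_len 32)
#>   final training loss 1.9853 after 5 epoch(s)

rule <- desirability_rule(reward_spec("logp_range"))
evaluate_generated_set(sample_batch(gen, 500, temperature = 1, seed = 2),
                       reference = corpus, desirability = rule)
#> <dmg_evaluation_report> n = 500
#>   % valid        45
#>   % unique     86.2
#>   % desirable  57.8
#>   mean SAS     2.59
#>   internal diversity (tanimoto)  0.927
#>   internal diversity (levenshtein)  8.23
#>   external diversity (tanimoto)  0.942
#>   external diversity (levenshtein)  9.85

run <- rl_training_run(gen,
  rl_config(reward_spec("logp_range"), tau = c(0.05, 0.2, 0.1), kappa = 0.75,
            eval_every = 10, eval_n = 300), seed = 3)
run
#> <dmg_rl_run> 85 iterations; mean reward 1.064 -> 2.529; best snapshot at iteration 60

evaluate_generated_set(sample_batch(run$model, 500, temperature = 1, seed = 4),
                       desirability = rule)
#> <dmg_evaluation_report> n = 500
#>   % valid      83.2
#>   % unique     29.1
#>   % desirable  82.5
#>   mean SAS     1.98
#>   internal diversity (tanimoto)  0.827
#>   internal diversity (levenshtein)  3.61
```

Reading the numbers: five epochs of pre-training give a generator whose
samples are 45% chemically valid and highly diverse (internal Tanimoto
diversity 0.93); 85 REINFORCE iterations raise the batch-mean reward from
1.06 to 2.53 (the plateau maximum is 3) and push desirability from 58% to
82% — while the exploration schedule and memory penalty keep 29% of the
500 samples unique, against single-digit uniqueness for the pure
exploitation baseline (`tau = c(0,0,0)`, `penalty_fraction = 0`). The best
desirability-×-diversity snapshot occurred at iteration 60, before the end
of training. Full-scale use is identical in shape: curate a real library
with `curate_corpus()` (logP −2–6, MW 200–600 g/mol, padded length 65),
train with the default `generator_config()` (2×LSTM-256, 25 epochs), fit
the QSAR on a `smiles,pIC50` table with `train_qsar()`, and pass
`reward_spec("maximize_pic50", predictor_oracle(fit))` to `rl_config()`.

A thin CLI over the same functions is installed at
`inst/cli/divmolgen` (stages: `curate`, `train-generator`,
`train-predictor`, `rl-train`, `sample`, `evaluate`), with per-stage
manifests, seeds and logs handled by `run_experiment()`.

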