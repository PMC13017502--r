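---
title: "Methods: data distributions, minimal learners and strategy metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data distributions, minimal learners and strategy metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A learner faced with a sequence-classification task can succeed in two
qualitatively different ways. It can generalise a rule from the examples in
its current input (*in-context* learning: answer the query by finding its
copy in the context and reading off the bound label) or it can retrieve an
association stored during training (*in-weights* learning: ignore the
context and answer from memory). `zipflearn` provides the machinery to study
how the rank-frequency structure of the training data — its diversity and
redundancy — pushes a minimal transformer, matched baselines, and simulated
behavioural cohorts between these two strategies.

# The task

Each trial presents `N = 7` context pairs (item token, label token) followed
by a query item; the learner classifies the query into one of `L = 10`
labels. Items are `D = 8`-dimensional Gaussian vectors drawn from a
vocabulary of `K = 2^14`; each item carries one fixed, arbitrary label.
Tokens are embedded in `D + P` dimensions, with a one-hot positional code of
width `P = 2N + 1 = 15` (one slot per sequence position; the minimal
faithful choice given that positions must be distinguishable). During
training a copy of the query is always present in the context, so both
strategies are viable on every training trial.

Probes dissociate them:

* **in-context test** — every item (query and distractors) is a freshly
  drawn Gaussian vector that never occurred in training, and context labels
  are uniform; only the context can give the answer. Drawing probe items
  fresh, rather than holding out vocabulary items, is what guarantees
  novelty when the training stream eventually touches the whole vocabulary.
* **in-weights test** — the query is a trained item but the context is
  novel with uniform labels; only memory can give the answer.
* **arbitrage** — the query is trained *and* present in context, but bound
  to a different label than in training; the response reveals the dominant
  strategy. The two response shares need not sum to one.

Two token layouts are provided: `pair_adjacent` places each label directly
after its item (the alternating-sequence reading), and `ring_offset3`
unrolls the "+3 steps around a ring" display rule, placing the label of
slot *s* at the label position of slot `((s + 2) mod 7) + 1`. The default is
`pair_adjacent`; under a causal mask the ring layout makes some bindings
anticausal (the label precedes its item for three of the seven slots), which
measurably handicaps in-context learning, and the idealized attention
templates are parameterised by layout so both remain testable.

# Training distributions

Query items are sampled by rank from:

* `zipf_spec(alpha, n_ranks)` — probability of rank `k` proportional to
  `k^-alpha`; `alpha = 0` is uniform (maximal diversity), large `alpha`
  maximally redundant.
* `composite_spec(p_uniform, alpha_s, n_ranks)` — a mixture placing
  fraction `P_c` on the uniform component and the rest on `Zipf(alpha_s)`.
* `curriculum_spec(...)` — phase schedules over a training run: C1 trains
  on the uniform component for the first half and the skewed component for
  the second, C2 reverses that, C3/C4 alternate in quarters.

For network training the support equals the vocabulary (`n_ranks = K`), and
ranks bind to items through a seeded permutation per run so "the frequent
item" differs across replicates. For human-style 150-trial blocks,
`allocate_block_frequencies()` gives the deterministic per-rank counts: with
`c = round(n / H(n, alpha))` rank `k` receives `ceiling(c / k^alpha)`
trials, accumulated until the block is full, with the remainder as novel
singletons. This rule reproduces the published alpha = 2 and alpha = 4
allocations exactly ([92, 23, 11, 6, 4, 3, 2, 2, 2, 1, ...] and
[139, 9, 2]); the corresponding printed alpha = 1 array instead follows
`ceiling(25/k)`, whose leading constant is not generated by the same rule —
it ships as a data fixture, not as output of the allocator.

# The learners

The reference learner is a **two-layer attention-only transformer**: one
causal softmax attention head per layer (scores scaled by `1/sqrt(D_M)`),
residual connections, and a classifier of two ReLU layers with `D_M = 16`
units followed by a linear map to the `L` logits, read from the final
(query) position. Training uses cross-entropy at the query position, Adam
(learning rate 0.01, beta1 0.9, beta2 0.999, eps 1e-8), batches of 128
fresh trials per step, 5,000 steps. Forward and backward passes are
hand-written in C++ (float32, flush-to-zero), with Adam state in float64.

The attention layer itself admits several minimal parameterisations, and
the phrase "intrinsic dimensionality `D_M`" two readings; the package
implements the whole family and had to pick defaults:

* **stream width** (`embed`): with a learned embedding (`embed = TRUE`)
  each `D + P = 23`-dimensional token is mapped into a 16-dimensional
  residual stream; without one (`embed = FALSE`, the default for
  attention-only models) the stream stays at the raw token width 23 and
  only the query/key projections are `16 x 23`, so `D_M` is the width of
  the attention's score space. The second reading preserves the one-hot
  positional code in the stream.
* **value pathway** (`values`): `"single"` (default) learns one combined
  `23 x 23` value/output matrix per layer, the combined-OV form standard
  in minimal induction-circuit analyses; `"learned"` splits it into
  separate value and output projections; `"identity"` learns only
  queries/keys and adds the raw attention-weighted stream back.

The defaults (no embedding, combined OV) are what make the
binding-plus-search circuit converge to near-perfect in-context accuracy
within the 5,000-step budget at `alpha = 0` while preserving full
in-weights learning at `alpha = 4`; a learned embedding leaves the
induction circuit a few points short at the same budget, and the
identity-value variant roughly halves its convergence speed (which has
interesting consequences for strategy competition; see the limitations
section). `attn_mlp` (attention layers interleaved with a feed-forward
block, residual connection and layer normalisation) always embeds, since
its blocks are defined at `D_M` width. Score scaling and residual
connections are also exposed (`score_scale`, `residual`); removing either
prevents the task from being learned at all at these sizes, which is
itself a useful negative control.

Weights are initialised from centred Gaussians at `1/sqrt(fan_in)`, except
the query/key projections, which start at `0.3/sqrt(fan_in)`: attention
begins near-uniform and the score pathway sharpens only where the data
demand it. This matters at extreme redundancy — with a standard-scale
query/key start, a minority of `alpha = 4` runs answered rare items
through a half-formed context pathway instead of memory and finished short
of ceiling on in-weights probes; the softer start removes that failure
mode without affecting any other condition.

**Baselines** are parameter-matched to the default transformer within 10%:
a two-hidden-layer ReLU MLP consuming the flattened sequence, and a
two-layer LSTM (standard gate order, forget bias 1) reading the sequence
token by token with a linear readout at the last step — plus a query-first
LSTM variant that sees the query before the context. Width is chosen
automatically to hit the parameter target.

# Metrics

* `evaluate_block()` — argmax accuracy against the block's criterion label.
* `arbitrage_decompose()` — shares of context-consistent and
  memory-consistent responses; the remainder matched neither.
* `double_learning_index(m_ic, m_iw, chance)` —
  `scale(m_ic) * scale(m_iw)` with `scale(m) = (m - chance)/(1 - chance)`;
  1 means dual mastery, 0 means chance on at least one probe, negative
  values indicate below-chance performance on one probe.
* `classify_learner()` — quadrant classification at a threshold of 0.5
  (well above chance 0.1 and between the empirical clusters; configurable,
  and set to midway between chance and 1 for the binary transitive task).

**Attention diagnostics.** `idealized_templates()` builds, per layer, the
attention pattern an ideal in-context (induction) circuit would show —
layer 1: each label row attends one-hot to its bound item (binding); layer
2: the query row attends one-hot to the target label (match-and-retrieve) —
and an in-weights pattern, declared here as uniform attention over the
causally valid positions (the maximum-entropy pattern of a model that
ignores context; the source text does not print its template, so this is a
package convention). `template_similarity()` scores a trained model by the
cosine between its attention (restricted to the causal region) and each
template, averaged over at least 100 in-context probe trials. Rows of every
attention matrix sum to 1 and are exactly zero above the diagonal, which
the test suite asserts on every forward pass it examines.

# Training evaluation cadence

During training, fixed probe sets (1,000 trials per block type by default)
are evaluated every 100 steps without gradient flow, so trajectories are
comparable across checkpoints. In-weights and arbitrage probes need a
record of trained items; the trajectory probes use the ranks whose expected
exposure over the whole run is at least 2, while the final evaluation uses
the realised record (ranks actually sampled at least twice). One master
seed per run splits into independent streams (vocabulary, rank permutation,
initialisation, trial stream, probes), making every run bitwise
reproducible end to end.

# Transitive inference variant

Each environment holds six Gaussian images with implicit ranks 1..6. A
trial's context presents ten one-step comparisons drawn with replacement
from the five adjacent pairs — resampled until all five appear, so two-step
queries are always solvable in context — each rendered canonically as
`higher > lower` ('>' and '<' are two extra Gaussian content vectors), in
shuffled order. The query is a pair at rank distance exactly two and the
model classifies the relation (chance 0.5). Environments are sampled by a
Zipf law over a pool (1,000 by default); in-context probes use entirely
novel environments, in-weights probes show a trained query pair inside a
novel environment's context, and arbitrage probes reuse a trained
environment with every comparison reversed. A brute-force transitive
closure over the asserted relations serves as the logic oracle: it attains
ceiling on consistent contexts and recovers the reversed answer on
arbitrage contexts. Canonical symbol orientation (rather than balancing
'A > B' with 'B < A') is a declared convention.

# The synthetic behavioural cohort

Human-scale data enters only through a generative stand-in: each
participant is a mixture with probability `p_ic` of applying the context
rule when available, `p_iw` of retrieving a trained association, and
`lapse` of responding uniformly. On arbitrage trials both strategies may
fire; the context response then wins with probability
`p_ic / (p_ic + p_iw)` (declared convention). The default block structure
mirrors the behavioural design: 150 training trials and three 30-trial
test blocks. Because the branch model is linear in its parameters given
the lapse rate, method-of-moments inversion (`recover_profiles()`)
recovers group-level `(p_ic, p_iw)` to within 0.05 at 30 trials x 30
participants, which the tests verify against the generating values.

The statistics stage mirrors the analysis pipeline: per-block logistic
regressions of correctness on the group covariate, a linear model for
participant-level indices such as the double-learning index, BIC for both
the fitted and the intercept-only model, the BIC-approximated Bayes factor
`BF = exp((BIC0 - BIC1)/2)` with the conventional 3/10/100 evidence bands,
and Bonferroni correction. The default logistic fit aggregates trials to
per-participant binomials and uses cluster-robust (participant-level)
standard errors with Wald p values — a deliberate, documented divergence
from a random-intercept mixed model with Satterthwaite degrees of freedom;
`method = "glmer"` provides the random-intercept refinement when lme4 is
wanted. Perfect separation is detected and handled by a half-success /
half-failure augmentation, flagged in the result. Under the null the
contrast's type-I error stays at or below 7% at nominal 5% (checked over
500 simulated cohorts).

# Problem sizes and what the tests show

The package's own quality gates run at two scales. Unit tests use small
vocabularies (hundreds of items) and short runs (tens to hundreds of
steps) to pin down algebra, geometry, gradients (finite-difference checks
on every learner kind) and reproducibility. The acceptance suite trains
full-scale models — 5,000 steps, batch 128, `K = 2^14` — with 10 replicates
per Zipf exponent for population claims, 10 for the composite condition,
and 5 per curriculum (seed-paired with the static composite control), with
1,000-trial probe sets. These replicate counts are the package's chosen
population sizes for its verification suite; the original behavioural-scale
study used 30-50.

Passing tests show that the implementation reproduces the computational
study's structure and its model-level claims under the stated conditions.
They do not show anything about human data: the cohort simulator emulates
the strategy-mixture structure the analysis assumes (including lapses),
not perceptual, motivational or sequential effects in real participants —
in particular, it has no trial-order effects within a block, no learning
during test blocks, and no mouse-tracking observables (only the
attention-template analysis plays that conceptual role for models).

# Numerical notes and limitations

* float32 forward/backward with flush-to-zero; softmax rows are computed
  with the max-subtraction trick; cross-entropy clamps probabilities at
  1e-12. Ties in the argmax response resolve to the lowest label index.
* A non-finite training loss aborts with a structured condition carrying
  the offending step and the parameter state.
* Layer normalisation uses eps = 1e-5; the `attn_mlp` block with zeroed
  weights reduces exactly to layer norm of its input (the residual path).
* The learner-class threshold (0.5) is a convention; results near the
  threshold should be read via the continuous accuracies, not the classes.

**Strategy competition is architecture-sensitive.** The clearest limitation
found while validating the package concerns population-level claims at
intermediate and mixed distributions. In the default learner the induction
circuit forms very early (within a few hundred steps), and whichever
strategy forms first largely preempts the other:

* at `alpha = 1`, every replicate becomes a pure in-context learner
  (the strategy hand-off happens between `alpha = 1` and `alpha = 2`
  rather than producing a mixed population at `alpha = 1`);
* under the composite distribution (`P_c = 0.5`, `alpha_s = 2`), models
  stay in-context-dominant (in-weights accuracy 0.09-0.22) instead of
  mastering both strategies at once;
* under curriculum C1 (uniform first), the in-context strategy is only
  partially forgotten during the skewed half (≈0.98 to ≈0.80 by the end),
  whereas C2 (skewed first) shows complete catastrophic forgetting of the
  in-weights strategy (≈0.98 to ≈0.02) and occasional replicates that
  never recover any strategy — an asymmetry mirroring the idea that
  in-weights-first training traps the learner.

Variants that slow induction (identity values, optionally with rescaled
query/key initialisation) flip the composite condition entirely to
in-weights learning rather than producing dual mastery: across every
parameterisation explored, the two strategies behave as competitors on a
knife edge, not as co-learnable solutions. Reproducing reference results
in which a balanced composite yields a majority of double learners appears
to require an architecture whose memorisation forms before its induction
circuit while induction still completes within the training budget at
`alpha = 0`; none of the minimal readings implemented here has that
property. The corresponding population-share checks in the acceptance
suite are therefore expected to fail under the default architecture, and
they are left failing rather than being tuned, as an accurate record of
what this implementation does.
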