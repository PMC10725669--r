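---
title: "Pharmacological-representation LSTMs for DDI extraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pharmacological-representation LSTMs for DDI extraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharddi)
```

## The problem

A drug–drug interaction (DDI) is a change in one drug's effect caused by the
presence of another. Extracting DDIs from biomedical text is cast as pair
classification: a sentence mentioning $n$ drugs yields $\binom{n}{2}$
candidate pairs, and each pair is labeled either interacting/non-interacting
(the coarse-grained, binary task) or with one of the five fine-grained types
ADVICE, EFFECT, MECHANISM, INT, NEGATIVE. `pharddi` implements a complete
pipeline for this problem: corpus I/O in the DDIExtraction XML dialect, a
target-drug-aware input encoding, a family of eleven recurrent cells, a
multi-task trainer, an evaluation suite, and a synthetic-corpus generator
that makes the whole pipeline testable without the licensed corpora.

## The pharmacological representation

Sentences are tokenized by whitespace and then punctuation (so
`aspirin-warfarin` becomes two tokens and the token count is at least the
word count). Every token type is assigned a random-encoded vector of
dimension $d$ (default 400) with components uniform on
$[-1/\sqrt d, 1/\sqrt d]$; no pretrained vectors are used, and target drug
mentions are kept verbatim rather than blinded to `drug1`/`drug2`, so the
lexical identity of the drugs stays available to the model. The vocabulary
is built from the training split; unseen tokens map to a reserved `<UNK>`
row.

Each token additionally receives a 4-dimensional filter vector relating it
to the candidate pair's two target mentions:

* **target** — 1 inside either target's token run;
* **neighbor** — 1 within `neighbor_radius` positions of a run (default 1,
  i.e. directly adjacent; the radius is a configuration knob because
  "neighbor" admits wider readings);
* **path** — 1 strictly between the two runs;
* **importance** — $I = 1/(r+1)^2$, with $r$ the token distance to the
  nearest token of the nearer target run (a target token has $r = 0$,
  $I = 1$; an adjacent token $r = 1$, $I = 1/4$).

Distances are counted in token positions rather than characters: the two
anchor cases ($r = 0$ on the target, $r = 1$ beside it) are only consistent
with token counting once multi-token mentions are treated as a run of
distance-0 tokens. Punctuation tokens are dropped by default (a
`keep_punctuation` mode retains them), so filler punctuation never dilutes
the distance scale.

## The cell family

The PHAR cell passes the filter vector through its own sigmoid
("pharmacological") gate, $g(W^P x^{(\mathrm{Phar})}_t + b^P)$, whose
output (dimension `p_dim`, default 4 — preserving the filter signal's
native scale) is concatenated with the recurrent input
$z_t = (H_{t-1}, x^{(\mathrm{token})}_t)$ to form $P_t$. The cell update,
following the published equations literally, is

$$C_t = g(W^I P_t + b^I) \circ C_{t-1} + g(W^F P_t + b^F) \circ
\tanh(W^C P_t + b^C), \qquad
H_t = g(W^O P_t + b^O) \circ \tanh(C_t).$$

Note that in this arrangement the gate named "input" multiplies $C_{t-1}$
and the gate named "forget" multiplies the candidate — the reverse of the
conventional naming. For the symmetric base cells this is a pure
relabeling, but it changes which structure the NIG and NFG ablations
remove, so the published form is implemented literally and a
`conventional_gate_roles` switch provides the standard arrangement for
comparison. The lone lowercase $p_t$ in the published candidate term is read
as $P_t$ (a typesetting slip).

The ten variants: **NPG** drops the pharmacological gate (recovering the
vanilla LSTM); **NIG**/**NFG**/**NOG** drop one gate entirely;
**NIAF**/**NFAF**/**NOAF** keep the gate but remove its sigmoid, leaving
an unbounded linear gate; **CIFG** couples the two cell-state gates as $a$
and $1-a$; **PEEPHOLE** appends $C_{t-1}$ to the inputs of the two
cell-state gates and $C_t$ to the output gate's input (because the published
equations concatenate full vectors, the peephole connections are full
matrices, not the diagonal form some implementations use); **FGR** feeds
$(I_{t-1}, F_{t-1}, O_{t-1}, C_{t-1})$ into every gate. The classifier
consumes the final hidden state $H_n$ only — the published classifier
equation uses $H_n$ and nothing suggests pooling.

The hidden size is not specified by the published method; the default is 128.
Weights initialize uniformly on $\pm 1/\sqrt{\text{fan-in}}$ per matrix,
biases at zero, all under a caller-supplied seed.

All forward and backward passes are authored in the package as batched
matrix algebra (there is no tensor/autograd engine among the package's
dependencies, and the cell family is the point of the package). Analytic
gradients for every variant are verified against central finite
differences in the test suite at small shapes (relative error below
$10^{-4}$; observed around $10^{-7}$).

## Classification and training

Each task has a SoftMax head $softmax(W H_n + b)$; ties in the argmax
break toward the lowest class index. The objective is mean cross-entropy
plus a ridge penalty $\frac{\lambda}{2}\lVert W\rVert_F^2$ on the head
matrices ($\lambda$ is not specified in the published setup; default $10^{-4}$),
computed through log-sum-exp so probability underflow cannot produce
`NaN`.

Training uses RMSprop (learning rate 0.001, smoothing 0.9, epsilon
$10^{-8}$ — recorded in the run manifest), batch size 32, 200 epochs by
default, and dropout 0.2 applied to the embedding output and to the final
hidden feature, during training only. The multi-task scheme pretrains the
shared embedding and cell parameters through temporary throwaway heads for
`pretrain_epochs` (default 20 of the 200), then attaches fresh heads and
fine-tunes everything jointly: the published description fixes only that
pretraining excludes the multi-task output layer, and this is the simplest
procedure honoring that constraint. Tasks are trained simultaneously by
interleaving their mini-batches in shuffled order, which makes each task's
share proportional to its corpus size; the published description does not dictate
simultaneous versus sequential task training, and simultaneous alternation
is the standard reading of joint multi-task learning. With a fixed
configuration seed the entire run — initialization, shuffling, dropout —
is reproducible to the bit.

If a batch produces a non-finite loss the trainer either raises an error
naming the epoch (default) or, with `on_divergence = "stop"`, ends
training and keeps the trace accumulated so far; the unbounded-gate
variants (especially NOAF) can need the latter.

## Evaluation

`contingency_metrics` implements $P$, $R$, $F$, accuracy from TP/FP/FN/TN;
0/0 ratios return 0 with a warning (configurable to `NaN`) so empty
classes do not poison macro averages. `multiclass_report` builds
one-vs-rest tables per class; CLA is the micro-averaged F from the summed
table and MAVG the unweighted mean of per-class F. Because published
fine-grained tables report a NEGATIVE row, the default averages include
all five classes; an exclusion set reproduces the official challenge
convention of scoring interaction types only — both modes exist because
the inclusive/exclusive choice cannot be determined from the published
aggregates alone.

The cross-corpus scalability score is one minus the **population**
standard deviation of the two per-corpus F-scores,
$1-\sqrt{\tfrac12(F_a-\mu)^2 + \tfrac12(F_b-\mu)^2} = 1 - |F_a - F_b|/2$;
the $\tfrac12$ weights force the divide-by-$n$ convention, which the
multi-run reproducibility summary (per-epoch variance and standard
deviation across runs, summed over epochs) therefore also uses. Welch's
$t$-test (unequal-variance statistic, Welch–Satterthwaite degrees of
freedom, two-sided $p$, $\alpha = 0.05$) is authored directly and
cross-checked against `stats::t.test` in the tests; two zero-variance
samples return $t=0, p=1$ when their means agree and a significant $p=0$
otherwise.

## The synthetic generator

`generate_corpus` emits the same XML dialect the parser reads: sentences
with 2–3 drug mentions (a preamble of 2–5 filler tokens, gaps of 3–7
tokens between mentions, a tail of 3–7 tokens), every pair annotated, and
the gold class of a pair determined by the first trigger token lying
strictly between its two mentions — no trigger means NEGATIVE. Trigger
lexicons per class are disjoint; label noise replaces a gold label with a
uniform draw over all $k$ classes with probability $\varepsilon$, so the
best achievable accuracy is $1-\varepsilon(k-1)/k$ and training curves
can be checked against that ceiling. Generation is byte-deterministic
under the seed.

The generator emulates the *structure* of the real corpora — pair
enumeration, offset conventions, path-dependent labels — and deliberately
not their lexical statistics, parse complexity, nested or discontinuous
mentions, or class imbalance. Passing tests on synthetic data therefore
demonstrate that the machinery is correct and that the representation
carries target-relative signal; they say nothing about corpus-scale
F-scores, which require the licensed DDIExtraction data and multi-hour
training runs and are out of scope here.

## Problem sizes used by the test suite

Gradient checks run all eleven variants at hidden size 3, $d=2$, sequence
length 3, batch 2 — small enough that the finite-difference probe is
exact to machine-level resolution. The end-to-end learning experiment uses
a noiseless binary corpus of 1,000 sentences (about 2,000 candidate
instances) and a 75/25 sentence-level split. The full PHAR cell trains for
a 50-epoch window at the default configuration; the NOG and NOAF
ablations are compared against it on mean held-out F over an equal
25-epoch budget (the first 25 PHAR epochs are the deterministic prefix of
the same run), mirroring over-epochs boxplot comparisons.
Reproducibility and multi-task checks use reduced dimensions (embedding
16–48, hidden 12–32) because they test contracts, not capacity.

## What the synthetic experiments do and do not show

On the synthetic task the learnable cells first settle on a
trigger-presence heuristic (held-out F near 0.90), then break through to
near-perfect F once they learn to conjoin trigger identity with the
on-path filter — PHAR does so within the 50-epoch window. NOAF, whose
unbounded output gate destabilizes early training, underperforms clearly
throughout. NOG, however, does **not** underperform: with a single binary
trigger rule the output gate is not load-bearing, and the simpler cell
converges at least as fast as the full one. The published claim that
removing the output gate significantly hurts performance manifests on the
real five-class corpora, not on this simpler synthetic task; the package
reports that comparison honestly rather than tuning the generator until
the expected ordering appears. Error analysis of the pre-breakthrough
plateau shows the residual errors are adjacent pairs in three-drug
sentences whose *other* gap contains a trigger — the models lean on
trigger presence and initially under-use the path filter, a conjunction
that is representable but slow to learn at this learning rate.

## Known limitations

* Discontinuous entity mentions use only their first span for positioning.
* The encoder is a single forward recurrent layer; no bidirectional or
  stacked variants, no pretrained embeddings, no hyperparameter search,
  no early stopping — matching the published training protocol.
* Corpus-scale results on DDIExtraction 2011/2013 are not reproduced; the
  corpora are licensed and the published training time is on the order of
  hours per run on a GPU.
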