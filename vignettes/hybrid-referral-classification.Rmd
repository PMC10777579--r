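---
title: "Methods: hybrid attention-CNN classification of referral letters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid attention-CNN classification of referral letters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

General practitioners refer patients to specialists with a free-text
referral letter describing the complaint, history and examination findings.
`refdx` treats primary diagnosis from such a letter as a 4-way text
classification problem over common neurological ICD codes: G40
(epilepsy-recurrent seizures), R51 (headache), M54 (dorsalgia) and I63
(cerebral infarction). Two properties distinguish this from generic text
classification: the decisive evidence is a small set of multi-word symptom
phrases buried in long narrative text, and symptoms are often mentioned
*negated* ("did not lose consciousness"), in which case they are evidence
of absence, not presence.

## Preprocessing pipeline

Four deterministic steps turn a raw letter into model inputs.

1. **Cleaning** (`clean_text`). Junk character tokens (`$$`, `**`, `Å`,
   `??`, `XXX`) and configurable greeting boilerplate are deleted by string
   matching, then whitespace is normalised. Removal iterates to a fixed
   point, which makes cleaning idempotent even when deleting one junk token
   spells out another. One deliberate deviation from pure character
   matching: a comma or colon dangling immediately after a removed greeting
   is removed with it, so salutations disappear wholly.

2. **Symptom extraction** (`extract_symptoms`). A deterministic
   longest-match lexicon extractor stands behind a pluggable interface
   where a clinical annotation service could equally sit. Matches are
   case-insensitive, anchored at word boundaries, and resolved left to
   right preferring the longest phrase (so "chronic back pain" wins over
   "back pain"). Negation is a NegEx-style forward rule: a mention is
   negated when one of `no, not, did not, denies, without, never` ends
   within 5 whitespace tokens before it with no intervening sentence
   punctuation (`. ; ? !`). The window length and trigger set are
   arguments.

3. **Symptom dot separating** (`dot_separate`). Positive (non-negated)
   symptoms are joined with a semantically empty dot separator
   (`"falling down. dizziness. pass out."`) so that adjacent phrases form
   no spurious word-to-word dependencies in a sequence model. Canonical
   lower-case headwords are emitted rather than surface forms: this is what
   makes the representation exactly invertible (`split_symptoms` recovers
   the phrase list), a property the test-suite leans on. Letters with no
   positive symptom get the placeholder `[NOSYM]` so the Symptoms dataset
   stays well defined. Negated mentions are dropped here, never earlier:
   the mention list retains them for explainability.

4. **Complaint-symptoms integration** (`integrate_complaint`). The cleaned
   complaint and the dot-separated symptoms are concatenated with a single
   `[SEP]`, the connector sentence-pair encoders already understand. The
   complaint comes first, the symptom summary second; the result reads as
   "context, then highlighted key information".

`build_variants` materialises the three dataset views used everywhere:
**Symptoms** (step-3 output only), **Complaints** (step-1 output only) and
**Integration** (step-4 output).

## The hybrid architecture

Both branches read the same text through their own tokenizers.

* **Attention branch.** A transformer encoder over WordPiece-style subword
  ids (`[CLS] x1 ... xm [SEP]`). The first-position final hidden state $H$
  summarises the input; a linear head maps it to 4 logits and a softmax to
  class probabilities $p_{\mathrm{attn}}$, trained with cross-entropy.
  The reference description of this head mentions a sigmoid inside the
  softmax layer; since the task is single-label 4-class and the loss is
  cross-entropy, the head is implemented as plain
  $\mathrm{Softmax}(\mathrm{Linear}(H))$ — the right-hand side of the
  defining equation — and no sigmoid is applied. $H$ is the raw first-token
  state; no pooler transform is interposed.

* **CNN branch.** Word-level tokens are looked up in a *frozen* (static)
  embedding table — the package loads word2vec-format text files such as
  fastText `crawl-300d-2M.vec` for full-fidelity runs, and uses a seeded
  random table at desk scale. Three 1-D convolutions over time with kernel
  widths 2, 3 and 4 and two filters each (a map of length $m-k+1$ per
  filter) are max-pooled over time and concatenated into a 6-dimensional
  vector, then dropout and a single linear layer produce 4 logits and
  $p_{\mathrm{cnn}}$. ReLU precedes the pooling, the standard text-CNN
  arrangement. Windows that touch padding are masked out of the max
  (equivalent to setting them to $-\infty$), so appended padding never
  changes the pooled features.

**Adaptive loss fusion.** The joint training objective is

$$\mathcal{L} \;=\; \alpha\,\mathcal{L}_{\mathrm{CNN}}
  \;+\; (1-\alpha)\,\mathcal{L}_{\mathrm{attn}},$$

with the scalar weight updated by the rule-based recurrence

$$\alpha_{m+1} \;=\; \alpha_m \;-\;
  (\mathcal{L}_{\mathrm{CNN}} - \mathcal{L}_{\mathrm{attn}})
  \cdot lr \cdot \alpha_m,$$

$\alpha_0 = 0.3$, $lr = 10^{-5}$. Under a constant loss gap $d$ this is the
geometric trajectory $\alpha_m = \alpha_0 (1 - d \cdot lr)^m$, which the
tests verify to $10^{-10}$ over 1000 steps. Design choices around the rule:

* $\alpha$ receives no gradient; the branches share no parameters and
  couple only through this scalar. Gradient isolation is asserted
  numerically in the acceptance tests.
* The update fires once per optimisation step using that batch's mean
  branch losses (a per-epoch mode is available); the update counter is a
  step index, distinct from the sequence-length symbol.
* $\alpha$ is clamped to $[0.01, 0.99]$. The recurrence is unbounded under
  a large persistent loss gap, and clamping keeps both the fused loss and
  the inference rule convex combinations. Bounds are configurable.

**Inference rule.** The reference protocol reports one accuracy for the
hybrid but does not state how the two branches combine at test time. The
package mirrors the loss weights:
$p = \alpha\, p_{\mathrm{cnn}} + (1-\alpha)\, p_{\mathrm{attn}}$ with the
final $\alpha$. Single-branch rules (`attn`, `cnn`) are selectable for
ablation.

**Baselines.** The single-branch models are the two branches trained alone.
The *sequential* model chains them instead of running them in parallel: the
encoder's full per-token hidden-state matrix replaces the static embedding
layer (conv input channels = encoder hidden size) and one cross-entropy
trains the whole stack; there is no $\alpha$ anywhere in it.

All networks, backpropagation and the Adam optimiser are implemented in
base R matrix code within the package; gradients of every trainable path
are validated against central finite differences in the test suite.

## Experimental protocol

Records are split 7:2:1 into train/validation/test, stratified by class
(with four classes and a few dozen letters per class, an unstratified 10%
test set can miss a class entirely). Within each class the ratio is
apportioned by largest remainder, ties broken toward the part with the
smaller floor allocation so no part is starved — 5 records per class yield
3/1/1, and quotas are respected to within one record per class per part.
Training is mini-batch Adam (standard moments, $\epsilon = 10^{-8}$);
accuracy is the fraction of argmax-correct predictions, argmax ties
resolving to the lowest class index. The final-epoch model is evaluated;
no early stopping.

Two named profiles ship with the package:

| parameter | `paper_profile()` | `desk_profile()` |
|---|---|---|
| encoder | pluggable pretrained (hidden 768) | tiny: hidden 32, 2 layers, 2 heads, FF 64 |
| static embedding dim | 300 (`crawl-300d-2M.vec`) | 50, seeded random table |
| truncation length | 256 | 96 |
| learning rate | 1e-6 | 1e-3 |
| epochs | 200 | 50 |
| batch size / dropout | 8 / 0.5 | 8 / 0.5 |
| $\alpha_0$, $\alpha$-lr | 0.3, 1e-5 | 0.3, 1e-5 |

The desk profile exists because the package's verification strategy is
parameter-recovery on synthetic data, not reproduction of results on the
(unavailable) clinical corpus: a tiny randomly initialised encoder trained
at lr 1e-3 can memorise a separable synthetic corpus within 50 epochs,
which is what the learnability acceptance check asserts. Truncation at 96
tokens was sized to the synthetic letters (cleaned complaints run ~30-60
tokens, integrated texts ~50-80), so the symptom summary after `[SEP]` is
never cut off.

## The synthetic corpus

The generator (`generate_corpus`) emulates the statistical structure the
method assumes, not clinical language. Each letter is a greeting sentence,
a demographics sentence, one short sentence per sampled class-lexicon
symptom phrase, optional negated mentions of *other* classes' symptoms
(each phrase placed directly after a negation trigger drawn from the
extractor's own trigger set, so injected negations are detectable by
construction), an optional shared "distractor" symptom carrying no class
signal, a closing sentence, and junk tokens injected as standalone
whitespace-delimited tokens. The shipped lexicon phrases are the kind of
multi-word symptoms that appear in the bundled example letters
(`inst/extdata/example_letters.tsv`).

Defaults: 65 letters per class (≈260 letters, the scale of a single-site
neurology referral corpus), 3 signal phrases and 1 negated off-class phrase
per letter, junk-token rate 0.05, distractor probability 0.3. Classes are
balanced although real referral corpora are mildly imbalanced; whether
imbalance affects the method is untested here. A single seeded stream
drives all draws, so equal configurations give byte-identical corpora.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: lexical variety beyond the lexicon (no synonyms,
misspellings or paraphrases), discourse structure, symptom co-occurrence
statistics, extractor misses (every positive symptom is extractable by
construction), and class imbalance. Results on the synthetic corpus
establish that the implementation learns what it is supposed to learn, not
that the architecture reaches any particular accuracy on clinical text.

## Numerical choices and degenerate inputs

* Cross-entropy is computed from logits via log-sum-exp; a vanishing
  probability never produces `-log 0`.
* Weight init: $\mathcal{N}(0, 0.02^2)$ for encoder tables and projections
  (layernorm gains 1, biases 0), He-scaled normal for conv and output
  layers. All initialisation, shuffling and dropout derive from the run
  seed through scoped RNG; nothing touches global RNG state.
* Dropout (p = 0.5) is applied to the pooled CNN vector and to $H$ only —
  placement inside the encoder is left out deliberately at desk scale.
  Inverted dropout keeps eval-time forward passes scale-free.
* Max-pool argmax ties take the first (earliest) position; accuracy argmax
  ties take the lowest class index and are logged.
* Inputs shorter than the largest kernel are zero-padded up to it with a
  warning. Empty text encodes to a specials-only sequence, which is valid.
* Out-of-vocabulary words in the CNN branch map to a seeded random vector
  cached per type (so distinct unknown clinical terms do not collapse onto
  one point); a zero-vector policy is available. The subword tokenizer
  instead decomposes unseen words into character pieces.
* Non-finite batch losses abort training with the offending batch ids; a
  non-finite loss pair leaves the fusion state unchanged with a warning.

## Problem sizes used in verification

The test-suite and `scripts/acceptance.R` run entirely at desk scale: the
learnability check trains the hybrid on a 400-letter separable corpus
(100 per class, 280 train / 80 validation / 40 test) for 50 epochs; the
variant comparison trains the hybrid on the default 260-letter noisy corpus
for each of Symptoms/Complaints/Integration across 3 seeds; the
dot-separation ablation repeats the Symptoms runs without the dot join.
These sizes were chosen as the smallest at which the corpus is comfortably
larger than the model's effective capacity and per-class test counts are
non-trivial.

A structural consequence worth spelling out: because every class-indicative
phrase a synthetic letter contains is by construction in the extractor's
lexicon, extraction is *lossless* on synthetic data, and the Symptoms view
is a noise-free sufficient statistic for the label. On such data the
Integration view can at best tie it — the added complaint context
contributes negated off-class mentions and boilerplate, never information
the symptom summary lacks. On real referral letters the extractor is lossy
and the complaint retains evidence the symptom list misses, which is
exactly the regime where integrating the two views is designed to help.
Synthetic-corpus comparisons between Integration and Symptoms therefore
probe robustness to contextual noise, not the integration method's
real-data advantage; the Integration-versus-Complaints comparison, by
contrast, transfers cleanly.

## Known limitations

* The extractor is lexicon-bound: symptoms outside the lexicon are
  invisible, and negation handling is a 5-token forward window, not a
  scope parser.
* The shipped encoder is desk-scale; plugging in a pretrained checkpoint
  is an interface contract (`register_tokenizer` + encoder weights), not a
  bundled feature.
* The fused-inference rule is one defensible reading of an unstated
  protocol detail; the ablation switches exist precisely because it is a
  choice.
* Accuracies reported by the acceptance script quantify behaviour on
  synthetic letters only.
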