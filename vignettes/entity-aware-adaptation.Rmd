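---
title: "Entity-aware domain adaptation for clinical NER: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entity-aware domain adaptation for clinical NER: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibdner)
```

## The problem

Clinical registries hold most of their information as free-text consultation
notes. For inflammatory bowel disease (IBD), the clinically relevant facts —
the diagnosis (Crohn's disease or ulcerative colitis), its date, the Montreal
classification of disease location (L1–L3), behaviour (B1–B3) and extent
(E1–E3), history of peri-anal disease, previous surgery, and the patient's
height and weight — appear as short entity mentions scattered through
sectioned notes. Annotated data is scarce and heavily imbalanced (peri-anal
disease is by far the rarest class), and surface forms are ambiguous: "CD"
is a diagnosis in a conclusion section but a laboratory measurement under a
lab heading, and a diagnosis string in a *family history* section describes a
relative, not the patient, and must not be extracted.

`ibdner` implements an adaptation recipe for this regime as a sequence
labelling pipeline over BIO tags, built on a small trainable transformer
encoder so that every component is testable end to end on a bundled
synthetic corpus generator.

## The model and its training objectives

**Encoder.** A pre-norm transformer (token + positional embeddings,
multi-head self-attention, ReLU feed-forward blocks, final layer norm) with
hand-written backpropagation and Adam. The package default is deliberately
small — 2 layers, 64 dimensions, 2 heads — because the scientific content
here is the *objectives*, not scale; any checkpoint implementing the same
interface can be substituted.

**Domain MLM.** Continued pre-training with random masking at rate
$p = 0.15$ and the standard 80/10/10 corruption split, as a domain-adaptive
baseline.

**Entity MLM (EMLM).** Instead of random tokens, only *entity* tokens are
masked, each independently with ratio $\eta = 0.7$, and a label token
encoding the entity's BIO tag (e.g. `<B-diagnosis>`) is inserted immediately
before and after each entity token. Label tokens behave as ordinary context,
so reconstructing a masked entity is conditioned on both its context and its
label. The reconstruction loss is the negative log-likelihood over masked
positions only:
$L_{\text{E-MLM}} = -\sum_i m_i \log P(x_i \mid X^m)$, with $m_i$ the mask
indicator. Label-token embeddings are initialised as the mean of the
embeddings of the words making up the label name, when those words are in
the vocabulary. Masks are re-drawn every step (dynamic masking).

**Masked-entity contrastive learning.** A frozen teacher and a trainable
student start from the identical initialisation. The teacher encodes the
unmasked sequence, the student the masked one; for every masked entity
position $i$ the student representation $h^m_i$ is pulled toward the
teacher's $h_i$ and pushed away from the teacher representations of the
other positions of the same sentence, through a temperature-scaled cosine
softmax:

$$L_{CL} = -\sum_i \mathbf{1}[i \text{ masked}]\,
\log \frac{\exp(\mathrm{sim}(h^m_i, h_i)/\tau)}
{\sum_{j=1}^{n} \exp(\mathrm{sim}(h^m_i, h_j)/\tau)},
\qquad L_{\text{pretrain}} = L_{CL} + L_{\text{E-MLM}}.$$

Gradients flow to the student only; the teacher is bit-identical before and
after training (a test asserts this on a parameter hash). The softmax
denominator runs over the positions of one sentence, not across the batch,
and inserted label tokens participate in it as ordinary positions.

**Fine-tuning.** Token classification over the 19 BIO labels with
label-smoothed cross-entropy ($\epsilon = 0.1$; $\epsilon = 0$ recovers the
plain objective), optionally combined with:

* **R-drop consistency** — the same sentence is passed through the encoder
  twice under independent dropout draws and the two token distributions are
  tied together by the symmetric KL penalty
  $\frac{1}{n}\sum_i \frac12[KL(P_1\Vert P_2) + KL(P_2\Vert P_1)]$, weighted
  by $\alpha$ (default 1, a design choice: the combination rule
  $L = L_{CE} + \alpha L_{rdrop}$ specifies no weight).
* **Section fusion** — the section title is injected at one of three
  points: concatenated to the token embedding as a learned attribute and
  projected back to model width (`embed`, the default for the fused
  variants), prepended as text behind a separator token (`text`), or added
  as a per-section bias on the label logits (`bias`). Unknown titles fall
  back to a learned UNK attribute.
* **Simulated CRF** — a transition-score matrix over BIO labels (plus
  start/stop) used in Viterbi decoding, with structurally invalid bigrams
  (`I-x` after anything but `B-x`/`I-x`) held at a large negative score. By
  default training remains per-token cross-entropy and the transitions act
  as decoding constraints; with `crf_nll = TRUE` they are trained with the
  exact linear-chain sequence NLL (forward–backward gradients).
* **Multi-task head** — a sentence-level binary head (peri-anal disease
  mention, the weakest class) reading only the first-position state, trained
  with BCE at weight 1 alongside the token loss; at inference it does not
  touch token predictions.
* **Pseudo-labelling** — a fitted model decodes the unlabelled pool
  (Viterbi + BIO repair) and the predictions are kept as silver data,
  flagged distinct from gold through serialisation; no confidence filter by
  default, an optional mean-max-probability threshold is provided.
* **Class up-sampling** — sentences of under-represented entity classes are
  duplicated until each class reaches (max class count)/r.

Early stopping selects the best epoch by development-set strict micro-F1
with a patience of 10 rounds.

## Evaluation

Two span-level criteria are computed per class and micro-averaged.
*Strict*: exact (start, end, type) agreement. *Entity type*: type agreement
with a character overlap of at least 1 (the boundary may be missed). The
overlap threshold is 1 character because no stricter threshold is inherent
to the definition; span-level matching is used because the defining worked
example (gold "warfarin" vs predicted "of warfarin": strict 0, type 1) is
only reproducible span-wise — a token-level tagging accuracy is exposed
separately as a diagnostic. The type matcher is a maximum-cardinality
one-to-one matching (augmenting paths), seeded with the exact matches and
deterministically ordered by overlap; maximality makes the dominance
invariant (strict F1 ≤ type F1) structural, and tests verify agreement with
an exhaustive assignment oracle.

Prediction errors are sorted into five deterministic categories: missing
information (prediction strictly inside a same-type gold), extra
information (prediction strictly containing one), conjunction merge (one
prediction covering two or more same-type golds with a conjunction token in
the gap), missing gold annotation (prediction with no overlapping gold),
and different entity type (overlap with a type disagreement).

## The synthetic corpus generator

The generator emulates the *structure* of sectioned IBD consultation notes,
not their language: template sentences with slot-filled surface forms,
section headers ("Anamnese", "Endoscopie", "Familiaal", "Labo", ...), and
exact 0-based half-open character offsets in BRAT standoff output. It
reproduces the features the method is designed around:

* nine entity types with a configurable weight vector; the default realises
  heavy imbalance with peri-anal disease rarest. The real corpus's class
  distribution is only reported graphically, so the defaults are
  order-of-magnitude choices, not reproductions;
* per-section admissibility: a type never occurs as gold in a section that
  forbids it; the family-history and lab sections admit none;
* section-dependent validity: at `ambiguity_rate`, notes carry a
  family-history sentence containing a diagnosis surface with *no* gold
  span. Half of these reuse the diagnosis sentence templates verbatim, so
  the sentence is genuinely indistinguishable from a true mention without
  its section title — the mechanism by which section fusion can raise
  precision;
* abbreviation ambiguity: lab sentences reuse "CD"/"UC" as measurements;
* conjunction joins: at `conjunction_rate`, an entity sentence carries two
  same-type spans joined by "en";
* an `unlabeled_fraction` of notes emitted without annotations for
  continued pre-training and pseudo-labelling (their hidden gold is kept in
  memory for audits only and never written).

A fixed seed yields a byte-identical corpus. What the generator does *not*
emulate: realistic Dutch grammar, misspellings, discontinuous or nested
entities, annotator disagreement, and note-length heterogeneity beyond
sampling. Passing tests therefore demonstrate that the objectives,
machinery and metrics behave as specified and that the directional effects
(pre-training benefit, section-fusion precision gain) operate through their
intended mechanisms — not that the pipeline attains any particular score on
real clinical text.

## Numerical and design choices

* $\eta$ is a per-token Bernoulli rate, not an exact per-sentence fraction;
  the alternative would couple masks across tokens and complicate the
  closed-form rate checks.
* MLM uses 80/10/10 corruption; EMLM uses pure mask replacement, since only
  masking is specified for the entity variant.
* One student forward pass serves both $L_{\text{E-MLM}}$ and $L_{CL}$.
* Convergence of continued pre-training is operationalised as a fixed step
  budget exposed in configuration.
* Entities are assumed flat and never to cross sentence boundaries (the
  generator enforces this); overlapping gold spans are rejected.
* BIO violations in model output are repaired (stray `I-` promoted to
  `B-`) rather than rejected, because pseudo-labelled output must be
  consumable; repairs are counted.
* In `embed` fusion the concatenation is followed by a projection
  initialised as the identity on the token block. The attribute rows are
  initialised with small random values: a fully zero attribute pathway is a
  saddle point whose gradient is identically zero and which can never start
  learning. The degenerate zero configuration remains available and
  reproduces the unfused model exactly.
* Probabilities are clamped at $10^{-12}$ inside logs; cosine similarity
  raises an error on zero-norm vectors rather than guessing.
* Viterbi ties break toward the lowest label index.
* The default fine-tuning learning rate is $10^{-3}$ with 10% linear
  warmup. This is calibrated for the package's from-scratch tiny encoder;
  an adapted pre-trained encoder of realistic scale would use rates around
  $5\times10^{-5}$. The remaining defaults are the settings standard for
  this kind of adaptation study: batch 16, 10–30 epochs, dropout 0.1,
  $\tau = 0.01$, $\eta = 0.7$, $\epsilon = 0.1$, patience 10.

## Problem sizes used in tests

The bundled experiments run on a 120-note corpus (about 500 sentences,
vocabulary of a few hundred types), a 2-layer/64-dimensional encoder, 200
pre-training steps, up to 30 fine-tuning epochs, and medians over 3 seeds
for the directional comparisons — sizes chosen so the whole suite runs on a
single CPU desk machine while leaving the directional effects measurable.
The variant matrix (`run_matrix()`) shares one document-level 70/15/15
split across all variants; test documents never enter the pre-training,
fine-tuning, up-sampling or pseudo-labelling pools.

## Limitations

The encoder is orders of magnitude smaller than production clinical
language models, and the synthetic language is templated; absolute scores
on this benchmark say nothing about absolute performance on real notes.
Pseudo-labelling is a single generation pass (re-invoke for iteration).
Discontinuous entities, relation annotations and BRAT attribute/event lines
are out of scope.
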