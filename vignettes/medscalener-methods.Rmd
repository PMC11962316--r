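---
title: "Recognizing medical-scale entities with retrieval-augmented LLM prompting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing medical-scale entities with retrieval-augmented LLM prompting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medscalener)
```

## The task and the model

Standardized assessment scales are central to measurement-based care, and
most of what is known about them in Chinese medicine sits in unstructured
journal text. `medscalener` treats the extraction problem as named entity
recognition over three types — `scale` (the recognized title of a scale),
`concept` (the construct it measures), and `item` (an individual question
within it) — and solves it with a chat LLM steered entirely through
prompts, without any fine-tuning. That design targets the low-resource
regime: with only a few hundred annotated sentences available as a
demonstration pool, in-context learning is competitive where trained
taggers starve.

The per-sentence procedure is a three-step chain of thought:

1. **Entity-type recognition (zero-shot).** A prompt with task
   description, per-type definitions, output format and the input
   sentence asks which types are present. The model answers with a
   brace-delimited list (`{scale, concept}`) or `{null}`. An empty answer
   ends the sentence immediately — no further model calls are made.
2. **Entity labeling (few-shot).** The `k` most relevant annotated
   sentences are retrieved from the training pool and shown as
   input→labeled-output pairs; the model then reproduces the input
   sentence with each entity wrapped in markers. Retrieval is
   type-conditioned: if step 1 predicted `{scale, concept}`, candidates
   are restricted to demonstrations containing both types.
3. **Self-verification (few-shot).** Each extracted entity is shown in
   its sentence context and the model answers Yes/No on whether it is a
   correct entity of its type. "No" removes the entity; this is the
   guard against over-prediction and hallucination.

The ablation arms `baseline` (one labeling call, unconditioned
retrieval), `baseline_sv` (+ verification), `baseline_cot` (two-step
chain), and `full` (all three) isolate the contribution of each
component.

## Demonstration retrieval

Sentences are embedded by a pluggable encoder (`encoder()` wraps any
text→unit-vector function). Embeddings are L2-normalized at index build
time, so cosine similarity is an inner product and exact top-k retrieval
is a single matrix–vector product; at the pool sizes this package
targets (tens of thousands of sentences) exact search is well inside
interactive latency, and exactness is part of the retrieval contract —
an approximate index would only be admissible if it returned the exact
top-k.

Numerical tie-breaking: similarities are snapped to 9 decimals before
ranking, and ties break toward the smaller demonstration index. Genuine
duplicates (identical texts) therefore rank deterministically instead of
at the mercy of floating-point summation order; distinct sentences are
never closer than $10^{-9}$ in cosine under the bundled encoder.

When fewer than `k` demonstrations contain all required types, the
restriction relaxes in tiers — candidates sharing at least one required
type, then the whole pool — appending without duplicates. The
alternative (returning fewer examples) wastes prompt budget precisely in
the scarce-type cases where examples matter most.

Demonstrations appear in the prompt in *ascending* similarity, the most
similar example adjacent to the input sentence. This exploits the
recency bias of decoder-only models; the order is configurable.

## The marker grammar and parsing untrusted output

Labeled text uses `[[type]]surface[[/type]]`. Double square brackets
essentially never occur in Chinese prose, so the grammar survives model
copy-through. Parsing treats the response as untrusted: unbalanced or
unknown-type markers degrade to warnings, never errors.

Offset recovery is two-stage. If the response preserves the original
sentence outside the markers (the instructed behavior), offsets are
reconstructed positionally by counting non-marker characters, which makes
`parse_marked(render_marked(s, M), s) == M` an exact identity even when
the same surface string occurs several times. If the model rewrote the
surroundings, each surface falls back to a leftmost exact search starting
after the previous anchor; surfaces not found at all are kept
*unanchored*. Anchoring failures never invent offsets — evaluation
operates on (surface, type) pairs, so unanchored predictions still count.

All offsets are Unicode code points, 0-based half-open: the only
unambiguous convention for Chinese text, where byte offsets depend on
encoding.

## The gold-playback backend and what it can show

The oracle backend answers the three prompt kinds from the gold
annotation of the corpus it wraps, after passing each sentence through an
error-injection model: mentions are dropped with `p_drop`, mistyped with
`p_type_flip`, boundary-shifted by 1–2 characters with `p_boundary`, and
spurious mentions are cut from unoccupied stretches of the sentence at a
Poisson rate of `p_spurious` per gold mention (enumerating free spans, so
crowded sentences do not silently bias the realized rate downward).
Verification answers are checked against the *true* gold annotation —
spurious and corrupted mentions draw "No" — with `p_verify_no` flipping
correct answers, modeling an imperfect verifier. Perturbation seeds
derive from (config seed, sentence id), so responses are independent of
call order; that property is what makes the response cache and rerun
determinism sound.

Two calibration identities anchor the test suite: with all rates zero,
every ablation arm reproduces the gold annotation exactly (end-to-end
identity); with `p_drop = 0.2` and `p_spurious = 0.25` and verification
off, recall converges to $0.8$ and micro precision to
$0.8/(0.8+0.25) \approx 0.762$ over $\ge 1000$ mentions (binomial and
Poisson standard errors of roughly $0.01$ at that size explain the
tolerance band of $\pm 0.03$).

The sentence identity the oracle needs travels in prompt *metadata*, a
side channel the renderers populate; the rendered prompt text is
byte-identical to what a remote backend would receive, so swapping in a
real adapter (`fn_backend()`) changes nothing upstream.

## Synthetic corpora

The generator emulates the structure of an annotated scale-development
corpus: documents of a few Methods/Results/Discussion-style paragraphs,
sentences closed by Chinese terminal punctuation, 0–3 anchored typed
mentions per sentence drawn from small per-type lexicons embedded between
filler clauses. Default type weights are 0.45/0.43/0.12 — the scale ≈
concept ≫ item mix of such corpora — and the default mention-count
distribution averages about 1.25 mentions per sentence, matching the
density of roughly 25k mentions over 20k sentences. Sentence-length and
mention-density distributions of real corpora are not published, so these
are structural choices, made once.

What passing tests on synthetic data do show: the plumbing is exact
(round trips, offsets, retrieval ranking, metric arithmetic, the
end-to-end composition). What they cannot show: real extraction quality,
which depends on the LLM and encoder behind the adapters; linguistic
phenomena like nested or discontinuous mentions, annotator disagreement,
and genuinely ambiguous boundaries are absent from the generator by
design.

## Corpus preparation, agreement, and evaluation conventions

* **Paragraph filtering** retains paragraphs containing at least one clue
  word (dimension/domain/variable/concept/factor/item/entry and their
  Chinese equivalents, configurable) — the cheap high-recall filter used
  to concentrate annotation effort on entity-dense text.
* **Splitting** is at the document level (no document contributes to both
  sides) with sizes `floor(ratio * N + 0.5)`; round-half-up is what
  reproduces 648/72 from 720 documents and 205/1023/2045/10227 from a
  20,454-sentence pool at 1/5/10/50%. The same rounding governs pool
  subsampling for the low-resource protocol.
* **Sentence splitting** is rule-based on 。？！；and newline, delimiters
  kept with the preceding sentence so concatenation is the identity;
  the splitter is pluggable.
* **Cohen's κ** is computed on character-level BIO labels; per-type
  agreement binarizes to in-type vs out. The agreement unit is not
  standardized in the field, so both modes are exposed.
* **Scoring** matches (surface, type) multisets per sentence — exact
  string matching robust to unanchored LLM output; offset-strict matching
  is available by flag. Macro F1 averages over types present in gold or
  predictions, which on the full three-type inventory is the plain
  three-type macro while avoiding 0/0 artifacts on small fixtures.
  Conventions: P = 0 with no predictions, R = 0 with no gold, F1 = 0 when
  P + R = 0.
* **Error taxonomy** precedence for an unmatched prediction: exact
  surface with wrong type → `type`; surface containment or span overlap
  with a gold mention → `boundary`; otherwise `identification`. Gold
  mentions with neither a match nor an overlapping prediction are
  `missing`. Boundary detection is surface/offset overlap because the
  category is defined by example, not by rule.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 20 | demonstrations per labeling prompt; 20 is the best-performing shot count, with quality degrading beyond ~25 |
| `temperature` | 0.02 | near-greedy sampling for reproducible extraction |
| `max_tokens` | 2048 | completion cap; must exceed the marked sentence length |
| `training_fraction` | 1 | pool fraction indexed (low-resource protocol uses 0.01–1) |
| `n_verify_examples` | 4 | few-shot cases per verification prompt, synthesized from the retrieved demonstrations (gold entities as "Yes", one type-corrupted "No") |
| `type_match` | superset | demonstration type-conditioning; `exact` is stricter |

The verification few-shot source and count are genuinely open design
points (the procedure is specified only as "few-shot"); synthesizing the
cases from the already-retrieved demonstrations keeps the prompt
self-contained and adds no retrieval pass, and an unparseable verdict
defaults to *keep* — entities are removed only on an explicit "No".

## A small end-to-end run

```{r demo}
co <- generate_corpus(synthetic_config(n_documents = 20, seed = 42))
sp <- split_documents(co, 0.9, seed = 7)
res <- run_corpus(corpus_sentences(sp$test), corpus_sentences(sp$train),
                  oracle_backend(co), pipeline_config(mode = "full", k = 5))
evaluate(res$predictions, sentences_as_corpus(corpus_sentences(sp$test)))
```

With the zero-error backend this prints a perfect report — the
end-to-end identity that every test of the pipeline composition rests
on. The test suite exercises the same identity on a 200-sentence corpus
in all four ablation arms, the calibration band on ~1300 mentions, and
retrieval equivalence against a brute-force ranking on a 100-sentence
pool; those sizes keep the full suite under a minute on one CPU while
leaving the statistical checks adequately powered.

## Known limitations

* Exact search only; no ANN backend is bundled (nor needed at target
  pool sizes).
* Overlapping gold mentions are representable and scored, but cannot be
  marker-rendered in one sentence (the grammar is linear), and CoNLL/BIO
  export rejects them.
* The bundled toy encoder is a structural stand-in: adequate for ranking
  determinism and surface overlap, blind to synonymy; real deployments
  should wrap a sentence-embedding model.
* Remote backends are an adapter contract (`fn_backend()`); no vendor
  SDKs, credentials, or rate-limit handling beyond simple retries.
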