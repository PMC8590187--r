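---
title: "Compound-term NER for radiology reports: models, measures and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound-term NER for radiology reports: models, measures and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radterm)
```

## The model

radterm implements a dictionary-lookup NER pipeline specialised for
*compound terms*: multi-word noun phrases whose head — the **stem term** —
is the rightmost content word and whose remaining words are modifiers. The
pipeline assumes head-final English noun phrases, which holds for the large
majority of radiology phrases (*right upper lobe*, *small pleural
effusion*). Multi-token heads ("vena cava") are not modelled; the rightmost
token is always taken as the stem, so *lung base* has stem *base*.

The processing chain is:

1. **Normalization.** Text is lowercased only. Stop words are *flagged* on
   tokens, never deleted, so every character offset into the raw report
   remains valid for span-level evaluation; dictionary matching simply skips
   flagged tokens. Offsets are 0-based and half-open throughout. The corpus
   contract is ASCII-range text, where lowercasing is length-preserving and
   the offset map is the identity.
2. **Tokenization.** Whitespace/punctuation splitting; hyphenated words
   ("right-sided") stay single tokens and count as one word everywhere.
   Sentences split at `.`, `!`, `?` tokens, with a configurable abbreviation
   list.
3. **Tagging.** A deterministic rule/lexicon tagger: closed lists for
   prepositions, conjunctions and determiners; a short adjective lexicon
   plus suffix heuristics (-al, -ous, -ic, -ive, -ary, -ar, -ed, -ing on
   words longer than four characters); a small verb-like list; everything
   else defaults to NOUN. This is a documented stand-in for a full POS
   pipeline, not a reproduction of any particular chunker: the NP grammar
   below only needs the modifier/head/glue distinction, and misclassifying
   a noun modifier as adjective (or vice versa) does not change the chunks.
   The tagger sits behind the `pos_tag()` contract and can be replaced.
4. **Noun-phrase chunking.** Maximal runs matching `(ADJ|NOUN)* NOUN` over
   non-stop tokens within a sentence. With `join_prepositions = TRUE` two
   runs separated by exactly one preposition merge into one phrase; runs
   never join across a conjunction, which is what splits *right pleural
   effusion and left lung pneumothorax* into two phrases.
5. **Decomposition.** Phrases split at conjunctions and prepositions; each
   segment of *n* words generates the suffix patterns of length 2..*n*.
   "All conceivable patterns" is interpreted as *all suffixes*: the three
   canonical worked examples (*right upper lobe*, *right-sided ij central
   venous catheter*, *right upper lobe of lung base*) are all suffix
   patterns, and non-contiguous modifier subsets (e.g. "right lobe") are
   excluded. The bare stem is not a pattern, because the compound-term
   experiments remove single terms from every dictionary.
6. **Matching.** Inside each noun phrase, every contiguous window of
   content tokens is joined with single spaces and looked up by exact
   string equality against the normalized dictionary surfaces (amortized
   O(1) via a hash index). No stemming, lemmatization or fuzzy matching.
   Homonyms are all returned; no dictionary source takes precedence over
   another. `policy = "all"` (default) emits nested matches — the gold
   standard contains every pattern, so nested emission is what maximises
   agreement with it; `policy = "longest"` keeps only non-nested matches
   for comparison with longest-match lookup engines.

## Evaluation

Matching against gold is exact on (document, start, end) and — by default —
semantic class; `check_class = FALSE` relaxes this, since whether a typed or
untyped criterion is wanted depends on the downstream use. Counts satisfy
`TP + FN = |gold|` and `TP + FP = |unique predictions|` by construction.
*Partial positives* (same class, overlapping, unequal span) are enumerated
on request but always counted as FN/FP in the scores. Scores are on the
percent scale:

$$P = \frac{TP}{TP+FP}\times 100,\quad R = \frac{TP}{TP+FN}\times 100,\quad
F = \frac{2PR}{P+R}$$

Degenerate cells (zero denominators) score 0 and are flagged rather than
propagating NaN. Per-modality tables add an "All" row that **pools counts**
across modalities; it is not a macro-average of the per-modality scores.

## Dictionary enhancement (CtED)

`build_cted()` adds one entry per distinct multi-word FN gold surface and
removes every entry whose surface produced an FP — globally, from all
source dictionaries, since no per-context removal rule is defensible for a
pure lookup engine. A surface appearing in both sets is removed, keeping
the delta's added and removed sets disjoint. Minted concept ids
(`CTED:NNNN`) are numbered by sorted surface, making rebuilds reproducible;
when the added surface or its stem is an ontology term, the concept id and
the traced top class are reused, otherwise the class is `"unclassified"`.
On its own development corpus the enhanced dictionary attains recall 100 and
a second enhancement round produces an empty delta (a fixed point); both
properties are asserted in the test suite on generated corpora.

## Stem analytics

The occurrence ratio of stem $s$ in a (modality, TP/FN) cell and the
matching ratio of an ontology over the FN stems are

$$OR_s = \frac{n_s}{N_{cell}}\times 100, \qquad
MR = \frac{n_{matched}}{N_{FN}}\times 100 .$$

Both denominators count stem *occurrences* — one per annotation — not
unique stem types; that is the semantics under which the published
denominators of such analyses (thousands of FN stems over a few hundred
reports) arise, and it is the package default, with `count = "types"`
available. MR matching is exact lowercased string equality against the
ontology's preferred terms; tracing follows all parent paths, and a stem
reachable from two or more top classes is bucketed as *Over two
categories* for every ontology (the bucket is symmetric even where only one
ontology's published profile prints it). The COMBINED block counts
occurrences matched by at least one ontology, so
$MR_{combined} \ge \max_i MR_i$ and $MR_{combined} \le \sum_i MR_i$.

## The synthetic study design

`sim_config()` fixes the study conditions; its defaults are the conditions
the pipeline is designed around, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| reports per modality | 100 | 400-report development corpus over CT/MRI/PET/x-ray |
| sentences per report | mean 29 | matches the target corpus profile (~29 sentences, ~179 tokens per report) |
| sections | findings, interpretations, impressions | the diagnostic core of a radiology report |
| word-count mass on 2/3/4 words | 0.74 / 0.18 / 0.05 | observed concentration of compound terms on 2–4 words (≈98%) |
| dictionary coverage `c` | 0.8 | high-but-incomplete coverage typical of a curated domain dictionary |
| top classes | 15 (RadLex-like), 19 (SNOMED-like) | the top-level class inventories used for ancestor tracing |
| stem boosts | uptake→PET, effusion/tube→x-ray, change→CT/MRI, artery→MRI | modality-specific stem frequency profile |

Sentences are fixed token frames with slots for planted terms — no language
model — so every gold offset is exact and generation is byte-reproducible
from the seed. Distractor phrases (e.g. *comparison film*) drawn from a
vocabulary disjoint from the stem/modifier lists are planted in non-gold
contexts and included in the dictionary as false-positive bait. The
dictionary holds `round(c · |distinct gold surfaces|)` surfaces sampled
uniformly, so expected recall equals `100c` — the coverage-recovery
experiment in the tests checks recall within ±5 points of `100c` for
c ∈ {0.2, 0.5, 0.8} at ≥500 gold spans.

What the generator does *not* emulate — and what passing tests therefore do
not show about real reports: abbreviation and negation phenomena, free word
order and long-range syntax, misspellings, section-header noise,
non-suffix annotation patterns, and the heavy-tailed vocabulary of real
clinical text. Results on the generator validate the machinery
(offset bookkeeping, matching semantics, metric algebra, the enhancement
loop), not clinical-grade extraction quality.

## Numerical and degenerate-input choices

* Ratios are computed in double precision and rounded only at the reported
  digit (2 d.p. for OR/MR, 1 d.p. for P/R/F by default); unrounded values
  are used in all internal algebra.
* Empty dictionaries, empty corpora and empty annotation sets flow through
  every stage as empty tibbles rather than errors; `compute_metrics(0,0,0)`
  returns zeros with a `degenerate` flag.
* BSV canonical form sorts by (surface, concept_id) with radix order, so
  round-trips are byte-identical across locales.
* Ontology validation rejects cycles, self-loops, multiple roots and
  concepts unreachable from the root, naming the offenders; tracing visits
  each concept at most once, so multi-parent diamonds cost linear time.
* Test and example problem sizes (2–30 reports per modality, 5–29 sentences
  per report) are chosen to keep the full suite under a minute while the
  acceptance study runs the full 400-report design; all sizes are stated at
  the call sites.

## Open design points, resolved

* *Dictionary precedence*: a lookup-first directory hints at preferential
  extraction among sources, but no precedence semantics is specified; all
  sources are treated equally at lookup, and all homonym hits are returned.
* *Typed matching*: span-scoring agreement on semantic class is required by
  default and switchable (`check_class`).
* *FP removal scope*: false-positive surfaces are removed from the merged
  dictionary globally rather than per source — a lookup engine cannot
  distinguish which source's copy fired.
* *OR/MR counting unit*: occurrences, not types (see above).
* *Word-length profiling* is category-agnostic: either the FP or FN set can
  be profiled with the same function.

## Limitations

The chunker's grammar is a stand-in; real NP identification in clinical
text is harder, and the pipeline is tuned to short compound terms — long
coordinated phrases are deliberately split at stop words, so capturing a
long compound term requires recombining its short segments. Exact-match
lookup cannot bridge inflection or spelling variants. The enhancement loop
learns surfaces, not rules: a CtED transfers to held-out reports only to
the extent that their phrases recur.
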