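---
title: "Mining disease-drug-gene-polymorphism relationships from abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining disease-drug-gene-polymorphism relationships from abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxminer)
```

## The problem

Pharmacogenomics (PGx) asks how genetic variation changes drug response —
efficacy, dosing, toxicity. The clinically useful unit of knowledge is a
quaternary relationship *disease–drug–gene–polymorphism*: in patients with
some disease, carriers of a variant in some gene respond differently to some
drug. Curated knowledge bases (PharmGKB, OMIM, CTD) hold many such
assertions, but most of the evidence sits in unstructured MEDLINE abstracts.

`pgxminer` implements a semiautomated co-occurrence pipeline for harvesting
candidate relationships from an abstract corpus:

1. **Corpus screening** — a publication-level filter cascade (original
   articles only, human studies only, abstract available) with auditable
   per-stage counts, followed downstream by an entity-presence filter.
2. **Entity recognition** — dictionary/longest-match recognition of disease,
   drug, gene and population mentions against pluggable lexica, plus
   pattern-based recognition of genetic variants (dbSNP rsIDs, simple
   substitution HGVS).
3. **Normalization** — resolution of each mention to a canonical identifier
   (HGNC-style symbol, ICD-10-style parent chapter, DrugBank-style drug id,
   rsID) with explicit failure codes; failures feed a curation queue rather
   than raising errors.
4. **Relation extraction** — the cross-product of normalized diseases ×
   drugs × genes per abstract, each tuple duplicated per co-mentioned
   variant owned by that gene; corpus-wide aggregation by distinct
   supporting PMIDs.
5. **Ranking and validation** — cross-database support scoring against
   PharmGKB-, OMIM- and CTD-style reference sets, a strict frequency
   threshold for unsupported relationships, novelty flagging, and
   confusion-matrix evaluation against a gold standard.

The method is deliberately *probabilistic co-occurrence*: if an abstract
mentions n drugs and m genes, all n×m pairs are extracted. No syntactic
analysis is attempted; the ranking layer and the curation queue are the
corrective, which is why the pipeline is "semiautomated".

## Matching model

All dictionary matching happens on a shared *normal form*
(`normalize_surface()`): case-folded, Unicode dashes and apostrophes mapped
to ASCII, whitespace collapsed, leading/trailing punctuation stripped. The
function is idempotent, and both lexicon index keys and text windows pass
through it.

On top of the normal form, `expand_variants()` generates the orthographic
variants authors actually use, as the closure of four switchable rule
families:

* **hyphen/space/fused** alternation — for names with up to three
  separators every separator assignment is enumerated, so mixed forms
  ("tgf-beta 1" vs "tgf beta-1") are reachable from either side; fused
  forms ("tgfbeta1") are generated but never re-split, because splitting
  without a dictionary of word boundaries is ill-posed;
* **Greek letters** and their spelled forms ("α" ↔ "alpha"), token-bounded
  in the spelled direction so "betamethasone" is untouched;
* **Roman/Arabic numerals** as whole tokens ("type II" ↔ "type 2"),
  restricted to I–X;
* **head-word dropping** ("gene", "protein", "receptor"), gene class only;
  the head words are dropped wherever they occur, because real synonym
  pairs ("IL-1 receptor type II" vs "type II IL-1 receptor") elide them in
  non-final positions too.

The closure is capped at three rounds. The rules commute in practice —
extensive property tests never found a form that a fourth round would add —
so the cap is a termination guarantee, not an accuracy trade-off. Each rule
family can be disabled individually so that error analysis can attribute
failures to rules.

Recognition scans token windows (tokens are alphanumeric runs with internal
hyphens/dots retained) and accepts a window when any of its expanded forms
hits the lexicon's surface index. Same-class overlaps are resolved
longest-then-leftmost, which makes the output independent of lexicon entry
order. Cross-class overlaps are allowed. An abstract's annotated text is the
title and abstract joined by one space (the PubTator convention), and all
offsets are 0-based half-open into that string. A window containing
characters that no expansion can remove (commas, parentheses) is skipped
without expansion whenever the lexicon's own surfaces avoid such characters;
this is a pure optimization and cannot change results.

## Normalization conventions

Statuses form a partition: `exact` (hit on the canonical name/symbol),
`variant_match` (synonym, brand, or orthographic-variant hit),
`partial_match` (disease only, see below), `ambiguous` (several candidate
ids; kept for curation, never used in tuples), `failed` (with a reason code:
`abbreviated`, `unconventional`, `unspecified`, `family_level`,
`metabolite`, `other`).

Choices that were genuinely open, and how this package resolves them:

* **Synonym hits are `variant_match`, not `exact`.** "P-glycoprotein"
  resolving to *ABCB1* is a recovered synonym, and the distinction matters
  when auditing how much of the yield depended on variant matching.
* **Diseases are reported at their parent chapter.** Leaf terms
  ("cerebral infarction") resolve to their ICD-style chapter ("diseases of
  the circulatory system"). Terms filed under several chapters (the classic
  examples are "stroke", "aneurysm", "embolism") come back `ambiguous`
  unless a `chapter_priority` order is configured.
* **Partial disease matching** accepts a mention when *every token of a
  chapter's head term* occurs among the mention's tokens, order-free. This
  is the weakest criterion that cannot fire on a bare qualifier.
* **Symptom exclusion** is a configurable term list (defaults: pain,
  nausea, fever, toxicity, ...), applied as a token-subset test so
  "severe nausea" is caught by "nausea". Symptom phrasings of outcomes are
  a known precision risk and are excluded rather than normalized.
* **Metabolites** are excluded via an explicit `metabolite` flag on lexicon
  entries (with `parent_id` linking to the parent drug), not via chemistry
  logic: the exclusion is a curation policy, so it lives in data.
* **Family-level gene terms** ("major histocompatibility complex") fail
  with `family_level` from a configurable list; resolving them to one
  symbol would manufacture precision.
* **HGVS variants are resolved gene-scoped**: "c.521T>C" is looked up only
  among variants owned by genes normalized in the same abstract. Unscoped
  HGVS lookup would collide across genes. Star alleles (`CYP2D6*2`) are
  recognized only behind the `star_alleles` flag and never mapped to
  rsIDs; copy-number and haplotype notations are out of scope.

## Relation extraction and ranking

Co-occurrence is scoped to the **whole abstract**, not the sentence.
Abstracts qualify for extraction when they contain at least one drug
mention and at least one gene or variant mention (the entity-presence
filter, appended to the same filter report as the corpus cascade). A
disease-less abstract emits tuples under the reserved disease id
`UNSPECIFIED` so drug–gene evidence is not lost. A variant joins only
tuples whose gene owns it in the variant index; a variant whose owner gene
is not co-mentioned joins no tuple — the package prefers losing a variant
annotation to fabricating a cross-gene tuple. Projections onto the five
binary relations (disease–drug, disease–gene, drug–gene, drug–variant,
gene–variant) union the supporting PMID sets; they never sum frequencies,
so a pair supported by overlapping tuples is counted once per article.

Ranking uses the simplest total order consistent with "databases first":
rows supported by s ≥ 1 reference datasets sort by (s desc, f desc,
lexicographic key); unsupported rows with f > 10 are appended (f desc,
key); unsupported rows with f ≤ 10 are dropped and counted — ten or fewer
co-occurrences are treated as potentially random, and the inequality is
strict (f = 10 drops, f = 11 stays). Support is granularity-aware: each
dataset must assert every sub-pair of the relationship *that it is able to
assert* (PharmGKB: drug–gene and, when present, drug–variant; OMIM:
disease–gene; CTD: drug–gene, disease–drug, disease–gene). A dataset that
can assert no sub-pair of a relationship contributes nothing — without this
rule a disease-less tuple would collect OMIM support vacuously. A
relationship is flagged **novel** when PharmGKB asserts none of its
sub-pairs; novel rows are the candidate additions to the knowledge base.

The tie-break key sort uses C-locale (radix) ordering everywhere, so ranked
output is byte-stable across platforms and input shuffling.

## Evaluation

Confusion counting in an open-world extraction task needs an explicit
candidate universe for true negatives to be countable. The default universe
is the union of test keys, gold keys and (when supplied) reference keys at
the comparison granularity; the report records the universe definition and
size. Granularity is configurable — quaternary, triplet (disease–drug–gene),
or pair (drug–gene, the granularity of a PharmGKB-style gold standard) —
and is always stated in the report. Metrics use the standard definitions;
zero denominators yield `NA`, never an error.

Error-percentage bookkeeping divides the absolute error by the true count
(×100). Displayed values are **truncated** (not rounded) to two decimals —
the convention under which the package's bundled worked examples (in
`inst/extdata/error_analysis_counts.tsv`) reproduce their reference
percentages exactly; stored values keep full precision.

## The synthetic study corpus

Everything is testable offline through `fixture_spec()` /
`pgx_simulate()`, which generate the five lexica, a MEDLINE-dialect corpus,
the three reference datasets and a gold standard, all deterministic
functions of the spec (including its seed) and byte-identical across runs.

The default spec defines the package's standard study conditions, chosen
once as a realistic miniature of a screening corpus: **200 abstracts**, 30
genes / 15 diseases (under 5 chapters) / 20 drugs / 40 variants, ten
planted relationships with frequencies 1–12 spanning the ranking threshold
(one unsupported relationship at f = 11, one at the f = 10 boundary),
support patterns cycling 3–2–1–0 across the reference datasets, trap
records for every cascade stage (3 reviews, 2 non-human, 2 abstract-less, 3
gene-without-drug), two synonyms per lexicon entry (a hyphen variant and a
Greek-letter variant), two gold-only tuples to exercise false negatives,
and a decoy noise rate of 0. At this size a full
generate–mine–rank–evaluate cycle runs in a few seconds on one CPU, so the
test suite can afford exhaustive oracle comparisons.

What the generator emulates: the file dialects, synonym/orthographic
variation, ambiguity, metabolite flags, filter traps, planted frequencies
and support patterns. What it does **not** emulate: statistical properties
of biomedical prose (abstracts are template sentences — dictionary NER is
offset-based and does not need linguistic realism), annotation-tool errors
(beyond an optional mention-dropout via decoys), and corpus-scale entity
distributions. Passing the end-to-end recovery test therefore demonstrates
correctness of the machinery — exact recovery of planted truth — not
real-world NER accuracy, which is bounded by lexicon coverage.

## Known limitations

* Co-occurrence cannot distinguish a studied association from an incidental
  co-mention; precision on real corpora depends on the ranking layer and
  manual curation of the exported queue.
* Only abstracts are mined; evidence in full text, tables or supplements is
  invisible.
* Fused-form splitting ("TGFbeta1" → "TGF beta 1") is not attempted from
  the text side; recovery of fused mentions relies on the lexicon carrying
  the fused synonym or the expansion generating it from the lexicon side.
* Gene mentions are not species-disambiguated beyond the corpus-level
  human filter.
* Reported performance metrics on real data require a trustworthy gold
  standard; published confusion tables in this domain are not always
  internally consistent with the standard metric formulas, so this package
  always recomputes metrics from counts rather than accepting printed
  values.
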