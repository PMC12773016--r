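---
title: "Evidence-grounded genomics answering: models, parameters and guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-grounded genomics answering: models, parameters and guarantees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoground)
```

`genoground` implements the deterministic core of an evidence-grounded
genomics question-answering system: everything that extracts, resolves,
serializes, verifies and stress-tests *without* a language model. This
vignette explains the models and procedures behind each module, the
parameters that matter (with units and defaults), the numerical choices,
what the synthetic fixtures do and do not demonstrate, and the known
limitations.

## Entity extraction

Pattern-based extraction covers the identifier families whose syntax is
fixed by public convention:

| family | pattern | example |
|---|---|---|
| rsID | `rs` + 1–12 digits | `rs334` |
| coordinate variant | optional `chr`, chromosome 1–22/X/Y/MT, `:`, 1-based position, `REF>ALT` over `ACGT` | `chr7:117559590 G>A` |
| Ensembl | `ENS{G,T,P}` + 11 digits | `ENSG00000141510` |
| miRNA | optional 3-letter species prefix, `miR`/`let`/`lin` stem (case-insensitive), hyphenated number, optional `-3p`/`-5p` arm | `hsa-miR-21-5p` |

Overlapping matches are resolved longest-first, then by earlier start, so
the output spans never overlap. Coordinate positions are kept 1-based as
printed in dbSNP-style text. A name counts as a miRNA when it contains
`mir`, `let` or `lin` case-insensitively — both `MiR-21` and `mir-21`
occur in real text, so the case rule is deliberately permissive.
Consolidation groups miRNA aliases by their stem (species prefix and arm
stripped) and keeps the most specific alias — species prefix and arm
present — as canonical, because `hsa-miR-21-5p` identifies one molecule
where `miR-21` is ambiguous.

Drug scanning is recall-biased: library names and synonyms are matched
fuzzily under normalized indel similarity
\(1 - d_{indel}/(|a| + |b|)\) (substitutions cost 2, i.e. modeled as one
deletion plus one insertion), with default threshold 0.9. At threshold
1.0 fuzzy matching provably reduces to exact substring search, which the
tests exploit as an oracle. Explicit IDs (`CHEMBL\d+`, DrugCentral IDs
and CAS numbers from the library) match exactly regardless of the name
threshold. Ties between equally-scoring library entries go to the longer
name, then lexicographic, for determinism.

## Sequence-to-gene resolution

Full alignment is deliberately avoided. Stage 1 finds, per database
record, the best *gapless* same-length window for the query: similarity
is `100 ×` the best per-position identity fraction over all windows
(stride 1), `X` matches nothing (including another `X`), coverage is 1
whenever a valid window exists, and records shorter than the query yield
no hit. Stage 2 decomposes the query into overlapping k-mers (k = 5, set
semantics: repeated k-mers count once) and scores each candidate
accession as `100 × |shared k-mers| / |query k-mers|`; that ratio also
serves as a heuristic coverage estimate, and the alignment length is the
ratio scaled by the query length, rounded. Candidates are ranked by
shared k-mers and trimmed to a configurable cap (default 50) before
merging; within equal shared-k-mer counts the merge-stage sort order is
reused as the tie-break.

Merging applies the 80% similarity threshold **after** both stages are
pooled (the threshold is inclusive: 79.999 fails, 80 passes — compared
as floating `>=` on a scale where all stage scores are exact multiples
of `100/m`), keeps only the highest-scoring hit per (gene symbol,
accession) pair, sorts by gene-symbol presence, then similarity
descending, canonical accession, full accession, and retains at most 5
hits per query. Queries are uppercased and stripped of non-letters first,
so FASTA wrapping and residue numbering are tolerated. Unique gene
symbols with a retained hit become gene entities; an existing entity
with the same symbol is reused rather than duplicated, and hits without
a symbol stay in the hit list but create no entity.

On synthetic databases the planted-homolog experiment recovers the
source record at rank 1 for identities ≥ 0.85 over a 60-residue query
against 15 records of 100–180 residues: a 0.85-identity window scores 85
≥ 80 while the best random window of an unrelated record stays far below
the threshold. This demonstrates threshold and ranking behavior, not
sensitivity on real proteomes, where low-complexity regions and homology
families make the k-mer stage much noisier.

## Grounded answers and context budgeting

Each resolved entity is serialized to exactly one document (IDs listed
explicitly, all tool annotations appended verbatim), with a manifest
mapping titles to dense 0-based indices bidirectionally. When the total
context exceeds its budget, the longest document is shortened to a target
length keeping the leading 70% and trailing 30% verbatim with a fixed
elision sentinel (`<<ELIDED>>`) between — the sentinel makes truncation
detectable downstream so elided text is never mistaken for evidence. A
second attempt targets the two longest documents with a 1.5× enlarged
reduction margin (the enlargement factor is a package choice; the
procedure it scales is fixed). More than two attempts is a hard error,
never a silent further truncation.

Citations use a neutral inline syntax, `[[doc=<i> start=<s> end=<e>]]`
with an optional `text="…"` attribute, one statement per line. Spans are
0-based half-open character intervals into document text; invalid spans
fall back to the marker's own cited text and are flagged, and a marker
naming a document outside the manifest is flagged invalid for the
verifier to consume. For well-formed markers reconstruction is loss-free:
the statements joined in order reproduce the generator's plain text.

## Verification

Two ensemble members judge each statement and the worse label wins
(order: supported < speculation-ok < partial < speculation-overreach ≈
unsupported; a tie between the two worst labels resolves to unsupported
so combination stays commutative):

1. **Deterministic check** — flags missing proofs and bad document
   indices, then searches every identifier referenced in the statement
   (rsID, Ensembl, pathway — Reactome `R-HSA-` by default, with an
   extensible registry — and HGNC/MGI/RGD) in the concatenated proof
   texts. All present with valid citations → supported; mixed → partial;
   none present, no proofs or no valid citations → unsupported. The
   partial/unsupported split is the most conservative assignment
   consistent with the three-label scheme.
2. **Qualitative reviewer** — pluggable behind a strict schema
   (per-statement labels from the five-label set, an ordinal
   support quality high/medium/low, overall pass/fail, concerns). The
   bundled default is rule-based: lexical overlap of statement content
   words with proof text, plus a requirement that every number in the
   statement appear in its proofs. Numeric grounding therefore lives in
   the reviewer, identifier grounding in the deterministic layer — an
   LLM reviewer can be substituted without touching either.

An answer passes only if the overall judgment passes **and** fewer than
30% of statements are unsupported; the comparison is exact integer
arithmetic (`10·k ≥ 3·n`), so 3 of 10 fails. Speculation labels do not
count toward the fraction — hedged statements are a quality concern, not
a grounding failure. An empty answer fails with concern "no content".

The central guarantee is constructional: corrupting an identifier so that
the corrupted form is absent from the statement's proofs is detected with
probability 1, because the deterministic check searches for exactly that
form. No analogous guarantee holds for contradictions, overstatements or
numeric edits — those depend on the reviewer, and the bundled rule-based
one catches most numeric edits (a mutated number can evade it only by
colliding as a substring of another evidence number) and makes no claim
on contradiction or overstatement.

## Protein tracks

All tracks use 1-based UniProt residue numbering over one fragment.

* **Polarity index** `δ = (Ap − Aa)/(Ap + Aa)` from polar/apolar SASA in
  Å²; bounded in [−1, 1], antisymmetric under swapping the components,
  and forced to 0 where the denominator is 0 or a component is missing so
  the track stays continuous for visualization.
* **Pocket track** — each residue gets the mean druggability of the
  pockets containing it, neutral 0 elsewhere; a min–max normalized view
  lies in [0, 1] with raw extrema preserved. A constant raw track
  normalizes to all zeros — the degenerate case is defined this way to
  avoid 0/0 while preserving gaps-are-zero semantics.
* **pLDDT** — bands >90 (very reliable), 70–90 (backbone usually
  correct), <70 (often flexible/disordered); the low-mean flag fires only
  strictly below 70, so a mean of exactly 70 does not flag.
* **Disorder consensus** — per residue, the mean of the available
  contributors: IUPred-style short and long scores, and the curated
  region vote where the merged-region mask is positive (the vote value is
  the mask value, 1.0 or 0.5 in ambiguous regions — an ambiguous region
  contributes a weaker vote rather than being excluded). Clipped to
  [0, 1]; no contributors → 0. Overlapping curated regions merge with
  ambiguity propagated; adjacent-but-not-overlapping regions do **not**
  merge ("overlap" read literally).
* **MoRF propensity** — per-residue max of the short/long
  binding-propensity tracks, 0 where both are missing.
* **Segment metrics** — min/max/mean, fraction of residues ≥ 0.5, count
  of maximal runs ≥ 0.5 of length ≥ 5, and the longest *qualifying* run
  (0 when none reaches the minimum length — the defined convention here,
  checked against an exhaustive run-scan oracle).
* **Cysteine flags** — per-category counts (detected, hyperreactive,
  ligandable, active/binding site and near-site), stable
  `<accession>_C<position>` labels, neighbor lists surfaced for near-site
  cysteines, and binary per-category tracks for overlay.

## Annotation summarization and drug evidence

GO terms are embedded as the mean of their token vectors. The bundled
embedder is a deterministic hashed projection: each token seeds a Lehmer
stream (modulus 2³¹ − 1, exact in doubles) that emits a fixed vector in
[−1, 1]⁶⁴, so embeddings need no training corpus and no RNG state; a
trained skip-gram model plugs in through the same token→vector
interface. Farthest-point sampling then greedily maximizes the minimum
cosine distance: the start point is the term farthest from the group
centroid (ties lexicographic by term ID), and with separate sampling
(default) terms group by the label prefix before the colon with FPS run
independently per group, k = 6 per group, groups of ≤ k returned whole.
Cosine distances are computed with per-pair scalar sums rather than
matrix products so ties resolve identically across code paths.

Enrichment is a one-sided (upper-tail) Fisher exact test per term with at
least one gene in the set, run separately per namespace with BH
correction within the namespace, significant at q ≤ 0.05. Potencies are
restricted to positive IC50/Ki/EC50 values in nM; the strongest (lowest)
value per type is reported with pChEMBL = −log₁₀(value · 10⁻⁹), shown at
two decimals (38 nM → 7.42, 39 nM → 7.41) with full precision retained.
Drug-target evidence keeps human rows only, aggregates per gene–protein
pair, scores as activity count + mechanism-of-action count, and retains
the top 5 per drug on the final score ranking (ties by gene symbol).

## Benchmark harness and adversary

Question generation is a pure function of (fixture tables, configuration,
seed): per category, a sampled row provides the key answer, three
distractors are drawn from the remaining distinct values of the same
table, and the key letter is seeded-uniform over A–D. The default
configuration is 8 categories × 90 questions = 720; templates are JSON
data, so categories change without code. Answer parsing takes the first
`<answer>` tag containing a letter, else the first `<solution>` tag, else
the last standalone uppercase A–D token (word-boundary, case-sensitive —
lowercase "a" in prose must not match), else no answer; unparsed counts
as incorrect. Accuracy intervals come from a seeded nonparametric
bootstrap (1,000 resamples, 2.5th/97.5th percentiles).

The adversary filters candidate statements (≥ 1 proof, no hedging
markers — may/might/could/possibly/suggests/potentially/hypothes‑, a
configurable list — and ≥ 40 characters, a default chosen to exclude
fragment statements), plus mode-specific requirements: a digit outside
identifier-like tokens for numeric mode, a mixed alphanumeric token for
alphanumeric mode. Up to 3 candidate indices are sampled with the seed
and generation iterates, bounded at 10 attempts for termination. The
default generator is rule-based (digit substitution inside or outside
identifiers, verb negation, quantifier escalation); an LLM generator can
be plugged in behind the same stay-on-topic/no-new-entities contract.
Every perturbation log carries the original statement, proofs, modified
statement and mode — enough to reverse it exactly.

The document-access ablation replaces the verifier with a no-context
judge that sees only statement text and can react to lexical cues
(negations, universal quantifiers) but not to evidence mismatches; on
numeric perturbations its detection rate is therefore strictly below the
context-aware verifier's on the same fixtures, which is the point the
ablation makes.

## Synthetic fixtures: what they show and what they do not

All generators are pure functions of their parameters and seed
(byte-identical reruns, caller RNG state restored) and ship ground truth
alongside. Sequence fixtures draw residues uniformly over the 20-letter
alphabet; uniform composition makes random 5-mer collisions rarer than in
real proteomes (20⁻⁵ per aligned pair vs. the higher rate under natural
frequencies), so k-mer specificity here is optimistic. Grounded corpora
build statements that quote their proof spans verbatim with identifiers
drawn from the recognized regex families — ideal grounding by
construction, which is exactly what a clean control requires but says
nothing about paraphrased real answers. Protein fixtures are
statistically plausible tracks, not physical structures. Passing tests
therefore demonstrate algorithmic correctness, determinism and the
constructional guarantees — not performance on live databases, real
UniProt content or LLM-written answers.

## Problem sizes and runtime choices

The default test and acceptance runs use: 100-fixture oracle-equivalence
suites per operation (window scan, k-mer ratio, FPS, Fisher tail, segment
metrics — the last at 1,000 tracks), 500 recovery trials at 15 records ×
100–180 residues, 50 grounded corpora (400 statements) for the verifier
guarantees, and 100 boundary answers for the 30% rule. These sizes keep
the whole suite in the low minutes on a single CPU while leaving each
statistical check comfortably powered; all are parameters, not limits.

## Known limitations

* Verification is strictly against supplied evidence; truth against
  external databases is out of scope by design.
* The deterministic layer grounds identifiers only; numeric and
  qualitative grounding ride on the reviewer, with the rule-based default
  a lower bound on what a stronger reviewer would catch.
* The resolver does no gapped alignment, so insertions/deletions between
  query and reference degrade both stages quickly; it targets exact and
  point-substituted matches.
* GO terms are flat labels here — no ontology graph, no ancestor
  propagation in enrichment.
* The pipeline's tool selection is static routing on entity kinds; the
  dynamic selection a full assistant performs is replaced by config data.
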