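---
title: "Curating GWAS associations with weak supervision: models and design choices"
author: "gwasminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating GWAS associations with weak supervision}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasminer)
```

## The problem

A genome-wide association study (GWAS) reports which genetic variants
(identified by rsid) are statistically associated with which traits, at
which p-values. Human-curated databases transcribe these triples from the
literature at substantial cost, and most of the information sits in
publication tables rather than prose. `gwasminer` automates this
transcription for publications distributed as JATS/PMC-style XML: its
output is one record per (rsid, phenotype) pair per paper, with the
minimum p-value over the supporting table rows, full row-level provenance,
a strict significance flag (some p < 1e-5), and the paper-level
phenotype(s) attached.

The central methodological difficulty is that no labeled training data
exists for "is this table cell really a phenotype?" The package therefore
uses *data programming*: a handful of cheap, noisy heuristics (labeling
functions, LFs) vote on each candidate, and a generative model learns how
much to trust each heuristic *from the unlabeled votes alone*.

## Document model

`parse_document()` turns the XML tree into a hierarchical model: title,
abstract and body paragraphs are split into sentences (sentence-final
punctuation followed by whitespace and a capital; a protected list keeps
"e.g.", "vs.", "et al." intact), and every table becomes a dense grid.
Cells carry 0-based row/column coordinates; `rowspan`/`colspan` are
expanded with the standard HTML placement algorithm so that every grid
position is covered by exactly one cell, and a multi-row header column is
summarized as the header texts above a cell joined top-to-bottom. This
dense-grid convention is our normalization of multi-level headers; truly
transposed layouts are handled separately by the acronym component, which
accepts both column- and row-oriented definition tables. Unknown elements
are skipped rather than fatal, because real PMC XML is heterogeneous.

Full syntactic parsing is deliberately not performed. The only syntactic
signal consumed downstream is a per-token noun flag (one labeling function
asks whether a mention contains a noun), so tokens are tagged with a
closed-class lexicon: a token is a noun unless it is a known function word
or contains no letter. On title and trait text, which is noun-heavy, this
cheap tagger errs in the right direction; it would be a poor general-purpose
tagger, and the contract is only the boolean flag.

## Candidate generation

Candidates are generated for recall, not precision:

* **rsids** — `\brs[1-9][0-9]{2,}\b`, case-insensitive. Real rsids have at
  least three digits and no leading zero; word boundaries prevent matches
  inside words like "versus".
* **p-values** — three typographic dialects: E-notation (`1.00E−06`),
  typeset powers of ten (`3.2 × 10−7`), and plain decimals in (0, 1].
  Unicode minus (U+2212), dashes, `×`/`·`, and a leading `p =` / `p <`
  comparator are tolerated; dialects are scanned in that order with
  masking so the mantissa of a typeset value is never re-matched as a
  plain decimal. `normalize_pvalue()` is closed against the corpus
  generator's renderer by construction.
* **phenotypes** — exact-surface, case-folded longest match against a flat
  term list (EFO/SNOMED/MeSH style), with optional plural `-s`; no
  stemming. A nested shorter term ("blood pressure" inside "systolic blood
  pressure") is suppressed. This mirrors the known failure mode that
  non-surface variants ("bipolar patients") generate no candidate.
* **relations** — horizontally aligned pairs in the expanded grid. A table
  row with two or more rsid mentions is ambiguous and contributes no
  rsid/p-value relation (at most one rsid per row). Phenotype cells are
  those whose column header contains "phenotype", "trait" or "outcome"
  (case-insensitive substring).
* **acronyms** — text pattern `<words> (<ACRO>)` with ACRO 2-10 characters
  containing an uppercase letter (digit-only parentheticals like "(2019)"
  rejected), taking as many preceding words as the acronym has characters;
  plus aligned cells of definition tables labeled
  phenotype/trait/description vs. abbreviation/acronym/phenotype.

## The generative label model

Let y_i ∈ {−1, +1} be the latent correctness of candidate i with prior
π = P(y = +1), and let LF j vote Λ_ij ∈ {−1, 0, +1}:

* abstain with probability 1 − β_j,
* vote the truth with probability β_j α_j,
* vote against it with probability β_j (1 − α_j),

independently across LFs given y (Naive Bayes). Correlated-LF extensions
exist in the data-programming literature but are out of scope here; the
LF sets are small (3-5 per kind) and kept within the 4-12 band the
approach is designed for.

Fitting is by EM rather than stochastic gradient descent: the M-steps are
closed-form counts, the fit is deterministic given the initialization
(α = 0.7, β = empirical coverage, π = 0.5; tolerance 1e-6, at most 500
iterations), and determinism makes the pipeline reproducible bit-for-bit.
Add-one smoothing — equivalently Beta(2, 2) priors on every parameter —
keeps estimates off the boundary. Two numerical points deserve care:

* **What is monotone.** With smoothing, EM ascends the *penalized*
  log-likelihood (log posterior), stored as `objective`; the bare marginal
  `log_lik` is reported alongside and can dip by the prior's O(1)
  contribution on small inputs. Tests assert monotonicity of the
  objective, which is the quantity EM provably does not decrease.
* **Label-swap symmetry.** (α, π) and (1 − α, 1 − π) give identical
  likelihood. Since LFs are assumed better than random, the fit is
  canonicalized to mean(α) ≥ 0.5 after convergence.
* **Identifiability.** A single LF's accuracy is confounded with the
  prior (at π = 0.5 the vote marginal is β/2 per side for *every* α);
  three conditionally independent LFs are the smallest setting where the
  two-component product mixture is identifiable. Consequently, when a
  candidate pool is very small (fewer than 20 candidates) or effectively
  only one LF votes, the pipeline does not fit at all and scores with the
  fixed initialization (α = 0.7, π = 0.5) — posteriors depend only on α
  and π, so this is a well-defined, conservative scorer. On pooled
  corpora of realistic size the EM fit takes over.

Posteriors follow from Bayes' rule; abstains contribute (1 − β_j) to both
classes and cancel, so an all-abstain row scores exactly π. Acceptance is
a strict `posterior > threshold` with default 0.5; a candidate sitting
exactly at the threshold is rejected.

```{r em-demo}
sim <- simulate_label_matrix(2000, alphas = c(0.9, 0.7, 0.8),
                             betas = c(0.8, 0.6, 0.7), pi = 0.5, seed = 1)
fit_label_model(sim$L)
```

## LF polarities and thresholds

The questions the LFs ask do not by themselves fix the sign of the vote;
polarities are set by intent and are configurable, and the label model
degrades gracefully if one is mis-set, because it learns each LF's
accuracy. The built-in registry:

| kind | LF | vote |
|---|---|---|
| simple phenotype | mention in title | +1 else abstain |
| | mention shorter than 5 characters | −1 else abstain |
| | mention contains a noun | +1 else −1 |
| | mention in first half of sentence | +1 else abstain |
| precise phenotype | cell mostly a number (or bare punctuation) | −1 else +1 |
| | column header longer than 30 characters | −1 else abstain |
| | cell contains rsid-like words | −1 else abstain |
| acronym | short form all capitals | +1 else abstain |
| | either side matches the ontology dictionary | +1 else abstain |
| | short form spells the expansion's initials | +1 else −1 |
| | one side a prefix of the other | +1 else abstain |

The "mostly a number" LF is the positive-evidence member of the precise
trio (a trait name is words), which is what lets a clean trait cell clear
the 0.5 threshold while a numeric or dash cell falls below it. The
30-character header threshold is a configurable default
(`builtin_lfs(..., long_header = )`); the 5-character mention threshold is
the conventional one for this task.

## Extraction components

* **Simple phenotypes** — dictionary candidates in title+abstract, scored;
  the up-to-three distinct highest-scoring candidates above threshold, or
  the single best if none clears it. Papers with several valid high-level
  phenotypes thus keep up to three, attached to every record of the paper.
* **Precise phenotypes** — accepted phenotype cells joined to the unique
  rsid of their row; rows with zero or several rsids contribute nothing.
* **Acronyms** — accepted pairs form a per-document map; conflicts resolve
  to the higher-posterior pair (lexicographic tie-break). Replacement is
  whole-token and case-sensitive on the acronym side, so "SUBMIT" is never
  rewritten by a "BMI" entry; an acronym with no definition anywhere in
  the paper is kept verbatim.
* **p-value relations** — reported in full without classification; this
  rule-based stage is precise in practice because tables rarely align an
  rsid with a non-p-value by accident, and the failure modes that do occur
  (haplotype rows, multi-rsid rows) are excluded structurally.
* **Assembly** — one record per distinct (rsid, resolved-or-precise
  phenotype); p-value is the minimum over the rsid's rows with all rows
  kept as provenance; significance is strict (exactly 1e-5 is not
  significant); de-duplication by minimum is our merge policy. All
  associations are retained with the flag rather than filtered, so users
  can apply their own stringency downstream.

## Evaluation harness

Recovery of a reference (pmid, rsid, phenotype, p-value) tuple keys on
pmid + rsid + phenotype equivalence; equivalence is string identity after
case folding and whitespace normalization, or an entry in an external
curated mapping table graded exact/approximate (the harness externalizes
human judgment rather than claiming to reproduce it). P-values are not
required to match — reported p-values legitimately differ between a
paper's cohorts and a catalog's chosen analysis — but an optional
relative-tolerance check (`check_pvalue = 0.01`) is available. The error
breakdown partitions the reference into recovered-exact /
recovered-approximate / wrong-phenotype / missed-variant, which always sum
to the reference size.

## LD novelty filter

LD is computed as the squared Pearson correlation of allele-dosage vectors
(0/1/2), which needs no phasing and is invariant under allele flip;
haplotype-based D′ estimation is out of scope. Filtering is within-paper:
pass 1 drops extracted variants with r² > threshold (default 0.5, strict)
against any curated variant of the same paper; pass 2 greedily thins the
survivors, ordered by ascending p-value then rsid (the ordering is our
tie-break; a most-significant-first order is the natural curator
convention). Variants absent from the panel cannot be tested and are
retained with a `not_in_panel` flag — retention is the conservative choice
for a candidate-generation tool. Zero-variance dosage vectors are an
explicit error, not a silent NA.

## Synthetic corpus: what it does and does not show

`generate_corpus()` emulates the structural features the pipeline keys on:
a title/abstract mentioning a dictionary phenotype; an association table
with rsid, trait and p-value columns (headers sampled from the accepted
keyword sets); the three p-value dialects with configurable unicode
typography; dash cells for missing precise phenotypes (rate 0.15);
acronym-valued traits (rate 0.3) defined in a definition table (transposed
with rate 0.2) or in running text, with a 0.1 rate of deliberately
undefined acronyms; and distractor rows modeled on documented real-world
failure modes — multi-rsid rows, p-values attached to haplotypes,
malformed numerics, and real associations whose trait cell is numeric
junk. Sample sizes default to 50 papers with 4-10 true rows per table;
generation is byte-deterministic given the seed and the ground-truth
sidecar is written in the same schema as the extractor output.

What passing on this corpus shows: the grid expansion, dialect parsing,
alignment logic, LF/label-model classification and assembly are correct
end to end, including under the listed distractors. What it does not
show: robustness to free-form scientific prose, to journal-specific XML
quirks, to variants reported only in text, or to phenotype vocabulary
outside the dictionary — on real corpora those are exactly the documented
error sources, and recall there is bounded by dictionary coverage.

## Problem sizes and reproducibility

The test suite and the acceptance script use 50-paper corpora, label
matrices of n = 5000 with 5 LFs over 10 seeds, and 100-fixture property
sweeps; these sizes give stable estimates (binomial noise on a 350-triple
corpus is ~1-2 percentage points) while keeping a full run in tens of
seconds. All randomness flows through explicit seeds via
`withr::with_seed`, so no global RNG state leaks between stages, and
identical seeds reproduce identical corpora, fits and reports.
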