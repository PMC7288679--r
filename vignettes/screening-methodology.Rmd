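---
title: "Screening food compounds for protein-target bioactivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening food compounds for protein-target bioactivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(phytoscreen)
```

## The problem

Food contains thousands of small molecules whose biological activity is
largely uncharacterized, while drug databases hold extensive, curated
structure–activity data for the same protein targets. phytoscreen
transfers that pharmacological knowledge to food chemistry: given a
protein target (an HGNC gene symbol) and an effect type (agonist or
antagonist), it learns what potent ligands of that target look like
structurally, then scores a food-compound library for the probability of
similar bioactivity. The output — scored compounds with source foods,
amounts, and a novelty flag — is a prioritization list for experimental
or epidemiological follow-up, not a set of validated interactions.

## Pipeline overview

`run_pipeline()` executes, in order:

1. **Positive retrieval** — distinct compounds in the bioactivity store
   with at least one sufficiently potent record for the target.
2. **Negative sampling** — random non-target compounds, ten per
   positive, excluding anything structurally similar to a positive.
3. **Fingerprinting** — every molecule becomes a 1024-bit binary
   path-fingerprint.
4. **Split / train / evaluate** — a 30% held-out split, a 100-tree
   random forest, precision/recall/F1 on the held-out set.
5. **Full-data refit** — the model used for scoring is retrained on all
   labeled data (evaluation always precedes the refit and refers only to
   the held-out split).
6. **Scoring and reporting** — every food compound is scored; records
   above the score threshold are annotated with novelty and source
   foods.

All randomness is seeded. Stage seeds are derived from the master seed
by fixed offsets so sampling, splitting and training streams are
independently reproducible; two runs with the same stores and seed
produce byte-identical output files.

## Molecular representation

### The SMILES subset

The package parses SMILES itself into an explicit heavy-atom graph
(`parse_smiles()`). The supported subset — organic-subset atoms,
aromatic lowercase notation, bracket atoms with charge and H-count,
bonds `- = # :`, branches, one- and two-digit ring closures, and the
`.` separator — covers what path-based fingerprinting consumes.
Three choices are deliberate:

* **Aromaticity is syntactic.** Lowercase atoms are aromatic; no
  perception or kekulization is performed. This keeps parsing
  deterministic and matches what the fragment encoder needs. An
  unspecified bond between two aromatic atoms is recorded as aromatic,
  otherwise single.
* **Stereochemistry and isotopes are ignored.** Path fragments are
  insensitive to both, so `/ \ @` and isotope labels are accepted and
  discarded.
* **Implicit hydrogens are never graph atoms.** Fragments are paths
  over heavy atoms; a bracket H-count is recorded but not instantiated.

Whitespace is stripped before parsing, so strings copied from typeset
sources (which often break SMILES around `=`) parse as written. No
valence checking is done: the parser's job is faithful graph
construction, not chemical validation.

### Path fingerprints

`compute_fingerprint()` indexes every simple path of 1–7 heavy atoms
(`enumerate_linear_fragments()`). Each path is encoded as alternating
atom codes (element, aromatic case, formal charge) and bond codes
(`1 2 3 a`); the canonical form is the byte-wise minimum of the forward
and reversed encodings, so a path read from either end is one fragment.
Single-atom fragments of uncharged aliphatic C, N and O are excluded by
default — they carry no discriminative signal and would otherwise set
the same bits in essentially every organic molecule — with a switch
(`exclude_single_cno = FALSE`) for the inclusive behaviour.

Fragments are hashed to bit positions with 32-bit FNV-1a modulo 1024.
FNV-1a is fixed, well-known, and platform-independent, which makes
fingerprints — and therefore models and scores — reproducible across
machines. Hash collisions fold distinct fragments onto shared bits;
with typical drug-sized molecules setting 100–200 of 1024 bits this
loses little discrimination, and all similarity filtering and learning
operate on the same folded representation.

```{r}
fp <- compute_fingerprint(parse_smiles("CC(C)Cc1ccc(cc1)C(C)C(=O)O"))
sum(fp)
```

Tanimoto similarity (`tanimoto()`, `tanimoto_matrix()`) is the standard
bit-set Jaccard coefficient; two all-zero fingerprints are defined to
have similarity 0.

## Training data

### Positive set

`fetch_positives()` selects distinct compounds with any record for the
target gene whose potency is **strictly** below the 20,000 nM cutoff.
Effect type is mapped to assay type — IC50 for antagonists, EC50 for
agonists — because bioactivity databases rarely annotate effect type
directly and the assay serves as the standard heuristic. A compound
with several qualifying records counts once (any-qualifying
aggregation; no median or other summary across records is taken).
Other activity types (Ki, Kd) are not consulted. The 20,000 nM default
is generous by medicinal-chemistry standards; it trades precision of
the "active" label for training-set size, and is configurable per run.

### Negative set

`sample_negatives()` draws candidates without replacement in seeded
random order and keeps the first `ratio × n_positives` whose maximum
Tanimoto similarity to any positive is at most 0.6 (a candidate at
exactly 0.6 is kept; the exclusion is strictly above). This rejection
sampling settles an order-of-operations ambiguity — filter first or
draw first — in favour of the interpretation that preserves the target
count whenever the pool allows, while fingerprinting only the
candidates actually examined. When the eligible pool runs out, all
eligible compounds are returned with a prominent warning rather than an
error: a short negative set degrades the model but does not invalidate
it. Unparseable candidate SMILES are skipped and counted; real
compound dumps contain entries outside any parser subset.

The 10:1 ratio reflects the asymmetry of the real problem — almost all
molecules are inactive against any given target — and means a trivial
always-negative classifier scores F1 = 0 while doing nothing useful.

## The classifier

`train_forest()` fits a random forest: bootstrap resamples, random
feature subsetting (√1024 = 32 bits per split), Gini impurity,
unlimited depth, 100 trees. These are the standard defaults of the
underlying implementation, pinned here so behaviour cannot drift across
versions. The score of a compound is the fraction of trees voting
positive.

The evaluation split (`split_dataset()`) assigns `round(0.3 × n)` rows
to the test set, unstratified — at 10:1 imbalance both classes appear
in both subsets with overwhelming probability at realistic sizes, and a
guard rejects a single-class input. R's banker's rounding decides
half-way sizes. Performance is reported from this one held-out split,
not cross-validation; with small positive sets the resulting F1
estimate carries sampling variance that cross-validation would average
away, a trade made for speed and for exactness of the "30% held-out"
contract. `evaluate_model()` counts a prediction as positive when its
score strictly exceeds the 0.5 decision threshold, and computes
precision = TP/(TP+FP), recall = TP/(TP+FN), and F1 as their harmonic
mean, with degenerate denominators yielding 0 by convention.

After evaluation, `retrain_full()` refits on the entire labeled set;
that final model, not the evaluated one, scores the food library.

## Scoring and reporting

`score_food_library()` fingerprints and scores every parseable food
compound, sorting by descending score with ties broken by compound id
so output is deterministic. `filter_and_annotate()` keeps records
scoring strictly above the threshold and supports two conventions:

* **default** — threshold 0.5, foods optional (the complete
  prioritization list);
* **table mode** — threshold 0.6 and at least one recorded source food
  (`require_foods = TRUE`), the convention for a compact headline
  table.

The novelty flag is the negation of `has_target_evidence()`: a
compound is novel when no bioactivity-store compound with an identical
whitespace-normalized SMILES has any record for the target. This is
string-level identity; the same molecule written with a different atom
ordering, or as a different salt, will not match. Structure-level
canonicalization is out of scope, so novelty is conservative in one
direction only: `novel = FALSE` is always correct, `novel = TRUE` may
occasionally mark a known ligand written differently. Food compounds
that also appear in the positive training set are scored and reported
(with `novel = FALSE`) rather than suppressed. Amounts are reported as
`min–max mg/100 g` ranges, collapsing to a single value when the bounds
agree or only one is recorded.

## The synthetic fixture

`generate_fixture()` builds both stores from a small combinatorial
grammar: active compounds are one of three "active" scaffold motifs
plus 0–2 random decoration substituents; decoys come from six unrelated
scaffold families; food actives reuse the motifs. Concatenating
validated fragments guarantees parseability by construction. The
planted structure makes three properties true and verifiable before any
model is fit:

* activity is perfectly separable from structure (a single rule on
  motif fragments classifies the labels with F1 = 1);
* every motif carrier has Tanimoto similarity > 0.6 to at least one
  other carrier, so the negative filter is exercised from both sides;
* every decoy is resampled during generation until its similarity to
  all carriers is at most 0.6.

Active potencies are drawn log-uniformly over 100–10⁶ nM — a range
chosen to straddle the 20,000 nM cutoff so the potency filter operates
on known ground truth (roughly 55% of actives pass). Two planted food
actives share an exact SMILES with known ligands, exercising the
novelty flag in both directions. Default sizes — 60 actives, 2,000
decoys, 300 food compounds with 10 planted actives — keep a full
end-to-end run in the tens of seconds on one CPU while leaving the
10:1 negative quota comfortably satisfiable.

What the fixture does **not** emulate: realistic medicinal-chemistry
property distributions, activity cliffs (near-identical structures with
opposite activity), assay noise, inter-target correlation, or the scale
of real compound databases. A pipeline that recovers the planted signal
has demonstrated its machinery — retrieval, filtering, fingerprinting,
learning, scoring — is sound; it has not demonstrated predictive
accuracy on real food chemistry, which depends on the density and
quality of real training data.

## Numerical conventions

* Potency filter: strict `< 20000` nM. Score filters: strict `>` at
  both 0.5 and 0.6. Similarity filter: candidates kept at `<= 0.6`.
* Tanimoto of two empty bit sets is 0; precision/recall/F1 with a zero
  denominator are 0.
* Fragment canonicalization compares byte-wise (C locale), independent
  of the session locale.
* All derived seeds stay in 32-bit integer range.

## Limitations

Only IC50/EC50 evidence is used, and effect type is inferred from assay
type; mechanism, binding site, and direction of effect within an assay
class are not distinguished. Novelty is string-exact. The SMILES
subset excludes extended stereo/reaction syntax. Fingerprints are
hashed, so bit collisions are possible in principle. Reported
performance comes from one held-out split. These are the points to
revisit before using scores for anything beyond prioritization.
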