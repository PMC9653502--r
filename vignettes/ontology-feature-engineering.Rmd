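---
title: "Ontology-based feature engineering for heterogeneous neuropathology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-based feature engineering for heterogeneous neuropathology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontofeat)
```

## The problem

Surgical epilepsy neuropathology reports describe microscopy,
immunohistochemistry, imaging and anatomical findings in free text, and
assign one or more diagnoses (hippocampal sclerosis, malformations of
cortical development, tumors, encephalitis, gliosis, and a long tail of
rarer entities, sometimes two at once — "dual pathology"). The same
concept appears under many surface forms: *depletion of neuron in CA2*,
*neuronal cell loss in CA2* and *reduced neuronal density in CA2* all
denote neuronal loss in the CA2 subfield. A cohort of a few hundred
patients can easily carry over a thousand distinct terms, so a
bag-of-terms encoding hands a learner more columns than patients, with
the signal for each concept shredded across its synonyms.

`ontofeat` implements the remedy studied in that setting: normalize
every term against an ontology before model fitting, so that features
and labels live at the level of ontology classes rather than surface
strings, then quantify what that buys in multilabel classification
accuracy and runtime.

## The mapping cascade

Terms are mapped by three matchers applied in a fixed order; the first
success wins and the step is recorded as provenance
(`syntactic`, `compositional`, `semantic`, or `unmapped`):

1. **Syntactic matching** succeeds iff the whole normalized term equals
   the normalized preferred label or synonym of exactly one class.
   Normalization lowercases, maps punctuation to spaces, collapses
   whitespace and removes a small stopword list
   (*of, in, at, the, with, and*).
2. **Compositional matching** repeatedly consumes the longest
   contiguous token span that equals a label or synonym (leftmost wins
   among ties) and succeeds when at least two classes are found, or one
   class with at most half of the tokens left unconsumed
   (`max_residual = 0.5`). This is what maps
   *depletion of neuron in CA2* to {NeuronalLoss, CA2}.
3. **Semantic transformation** strips adjectival suffixes
   (*-ial, -ous, -al, -ic*) and matches at stem level (a residue of up
   to two trailing characters is tolerated, stems shorter than four
   characters must match exactly), then expands each anchor class by its
   one-hop neighborhood — isA parents and relation targets — to at most
   `max_expansion = 3` classes in total, anchors always kept. This is
   what maps *astroglial phenotype* to {Astrocyte, GlialCell,
   BrainGlialTumor}.

Two readings of the expansion cap were possible (cap the neighbors, or
cap the result); we cap the **total** result size because the worked
examples all produce exactly three classes and an unbounded anchor set
plus three neighbors could produce diffuse mappings that a reviewer
would reject anyway.

Ambiguous surface forms — one string indexing more than one class — are
resolved only when exactly one of the candidates holds the string as its
*preferred* label; otherwise the term is left unmapped and flagged
`needs_review`. The study's workflow had every mapping verified by a
neuropathologist, so the package mirrors that: `export_review_table()`
writes a TSV audit table, and rows re-imported with `approved = yes`
override the automatic result and are never overwritten by remapping.
Fuzzy string distance is deliberately absent: lexical variants are
handled by synonym entries in the terminology, which keeps every mapping
deterministic and auditable.

## From mappings to matrices

`build_features()` encodes each patient as binary indicators. In
`mapped` mode every class in a term's mapped set becomes one column (a
"bag of classes"): a compositional mapping contributes one column per
member class, not a conjunction column — this is what actually shrinks
the space. Terms that fail all three matchers fall back to raw-term
columns rather than being dropped, so a mapped category can contain both
column kinds; the kind is tracked per column. `build_labels()` treats
the diagnosis strings the same way, and the ground truth is the
patient's *set* of positive label columns with no primary/secondary
ordering.

`reduction_stats()` reports the per-category vocabulary consolidation as
`100 * (raw - mapped) / raw`, at full precision (the print method rounds
to two decimals). Raw vocabularies are counted as distinct *normalized*
strings; whether the study counted before or after normalization is not
stated, and normalized counting is the conservative choice (it never
inflates the raw count).

## Models and evaluation

Multilabel classification uses binary relevance: one independent binary
classifier per label, a patient's prediction being the set of labels
whose model crosses a 0.5 posterior. Three learners are provided:

* **Logistic regression** — ridge-penalized (`C = 1`, i.e.
  `lambda = 1/(n C)`), fitted by glmnet down a short warm-start path;
  labels with fewer than two observations of either class get the prior
  as a constant predictor.
* **Random forest** — 100 bagged depth-limited CART trees with
  `mtry = floor(sqrt(p))`. Because all features are binary indicators,
  each split is `x == 0` vs `x == 1` and the variance-reduction
  criterion coincides with Gini gain; the trees are implemented in
  compiled code in this package (no tree-ensemble package is assumed).
* **Gradient tree boosting** — 100 depth-3 trees, learning rate 0.1,
  logistic loss with Newton leaf steps clamped to ±4, stopping early
  when the mean absolute gradient falls below 0.01 (converged fits on
  rare labels would otherwise burn the full tree budget on noise).

Evaluation is repeated stratified 5-fold cross-validation (default 5
repetitions; the study says "a fixed number of repetitions" without
quantifying it). Patients are stratified on their **rarest positive
label**, which keeps diagnoses with one to five cases represented across
folds; purely random folds frequently strand a rare label with zero
training positives. Held-out predictions are pooled per repetition,
metrics computed on the pool, and repetitions averaged.

Metrics follow the conventional multilabel definitions, since the
document that defined them for the study is not available: hamming loss
(fraction of disagreeing label cells), macro balanced accuracy (mean of
TPR and TNR per label, skipping labels with no positives or no
negatives), and macro recall (labels with at least one positive). A
patient's result is *correct* when predicted and true label sets are
equal, *partially correct* when they overlap without equality, and
*incorrect* when disjoint. "Partially correct" is described in the
source both as a subset of the truth and as possibly containing wrong
labels; the overlap reading adopted here covers both phrasings and keeps
the three categories a partition.

Feature importance is computed on baseline (unmapped) features: impurity
gain for the tree models, absolute standardized coefficients for
logistic regression, averaged over the per-label binary models, summed
by category and normalized to 1. Runtime comparisons measure fit plus
predict over the CV loop only — mapping and matrix construction are
excluded, because the published comparison concerns model training and
testing time. The standalone `runtime_benchmark()` averages seven
executions, the study's protocol; ablation grid cells default to a
single execution to stay inside practical time budgets (the count is
configurable and echoed into outputs).

## The synthetic cohort

The clinical corpus is restricted, so every end-to-end claim is
exercised on `generate_cohort()`, which emulates the cohort's published
structure: 312 patients; 12 diagnosis classes at the published
prevalences (MCD 136, tumor 81, HS 36, gliosis 20, encephalitis 11,
gliosis-without-HS 10, NOS 7, cyst 3, encephalopathy 2, cavernoma 2,
Alzheimer's disease 1, arteriovenous malformation 1) plus a
dual-pathology rate of 5/312; diagnosis-conditioned findings drawn from
a packaged YAML concept model in which every diagnosis has at least one
high-probability signature concept; and heterogeneous surface renderings
that collapse to far fewer classes under mapping.

Choices a reader should know about, with their reasons:

* **Surface pools** seed each concept with up to four curated synonyms
  and extend them with descriptive modifier variants (*marked …*,
  *focal …*); location-bearing microscopy findings render as
  "finding in location" composites half the time, exercising the
  compositional matcher.
* **Zipfian frequencies.** Surfaces are drawn with probability
  proportional to `rank^-0.7`, not uniformly. Term frequencies in
  report language are heavily skewed; a uniform draw shatters the raw
  label space so completely that baseline models degenerate to
  predicting nothing, which no real corpus produces.
* **Lexical noise** perturbs 20% of renderings: filler-word insertion
  (60%), a plural/singular toggle of the head noun (20%), and an
  adjacent-token swap (20%). Fillers are the most common benign
  variation and are invisible after normalization; plural toggles stay
  inside the lexicon because the fixture carries regular number variants
  as synonyms; swaps are the one perturbation the cascade cannot always
  recover and are kept rare accordingly.
* **Vocabulary calibration.** Per-category surface richness defaults to
  the published raw:mapped ratios (microscopy 6.4:1 down to
  immunohistochemistry 1.7:1) and a calibration loop (at most six
  deterministic passes) scales richness per category toward the
  published vocabulary of 1328 distinct terms, distributed in the
  published per-category proportions; an unreachable target produces a
  warning with the achieved count, never a silent shortfall.
  `table2_profile()` freezes richness at exactly the published ratios
  (scale 1, no noise) for checking the consolidation pattern itself.
* **Restatement.** Input-category concepts are rendered a second time
  with probability 0.5, reflecting findings restated in narrative and
  summary sections; this also gives the vocabulary enough draws to
  approach its target.

The generator's ground truth contains the mapping oracle (every surface
form with its canonical class set) and each patient's diagnosis and
concept sets, so mapping recovery and learnability are testable without
any restricted data. All randomness flows from one seed through named
substreams (`derive_seed()`), and a cohort is bit-identical across runs
for a fixed configuration.

**What a green test does and does not establish.** The synthetic world
shares the cohort's label prevalences, vocabulary size and
synonym-collapse structure, but its diagnosis–finding associations are
authored, clinically plausible stand-ins (the true frequencies are
unpublished), its surfaces are generated from the same lexicon the
mapper consults (real reports contain out-of-lexicon language), and at
the stated heterogeneity the unmapped baseline is nearly degenerate —
correct counts near zero against the published baseline's small but
nonzero counts. Green effect-direction tests therefore establish that
the pipeline recovers the *direction and mechanism* of the published
effects (mapping consolidates the space, accuracy and runtime improve),
not their magnitudes.

The feature-importance check deserves its own caveat. Impurity and
coefficient importances reward column *frequency* as well as signal: at
full default heterogeneity the microscopy signal is spread over many
rare Zipf-tail columns and only the random forest still ranks
microscopy first. The importance test therefore runs on a cohort built
for it — non-microscopy concept tables flattened to
diagnosis-independent noise and richness held at the published
consolidation ratios — where microscopy demonstrably carries the
dominant signal and tops the ranking for all three models. A green
importance test validates the attribution machinery under dominance,
not that dominance itself is inevitable.

## Numerical and degenerate-input conventions

* Greedy span ties break leftmost-longest; equal-length overlaps take
  the earlier start — mapping is order-deterministic.
* An empty string normalizes to an empty token sequence and is rejected
  as a term; corpora without any report rows yield empty mapping tables.
* isA cycles are a hard load error (ancestor closure must terminate);
  dangling references name the offending id.
* Labels that are all-positive or all-negative in a training fold get
  constant predictors with a logged message, and labels with no
  positives (or no negatives) in the truth are skipped by the metrics
  that would be undefined on them; balanced accuracy errors only when
  every label is skipped.
* OWL import is a best-effort projection of RDF/XML: named classes,
  labels, annotation properties whose name contains "synonym"
  (BioPortal ontologies disagree on synonym properties, so the match is
  by name), named subclass axioms, and quantified restrictions;
  anything else is skipped with a message. Turtle is not parsed.

## Limitations

Mapping here is automatic with a review loop, whereas the study's
mappings were curated by hand; the cascade's thresholds (residual 0.5,
stem residue 2, expansion cap 3) are this package's smallest rule set
that reproduces all published worked examples, not values from the
study. Published accuracy and runtime magnitudes depend on the
restricted corpus and are not reproduction targets; only their printed
derived arithmetic and effect directions are. The importance measure
inherits the known biases of impurity-based scores and ignores feature
interactions.
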