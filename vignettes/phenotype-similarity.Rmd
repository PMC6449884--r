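---
title: "Phenotype semantic similarity and disease ranking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype semantic similarity and disease ranking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorank)
```

# The problem

Phenotype-driven diagnosis asks: given the set of phenotypic abnormalities a
patient presents, which disease (or causative gene) in a candidate list best
explains them?  The standard machinery is a semantic similarity measure over
the Human Phenotype Ontology (HPO): each disease is an annotated set of HPO
terms, a patient is another term set, and candidates are ranked by
set-to-set similarity.  `phenorank` implements a measure that combines four
ingredients that most classic measures (Resnik/Lin-style IC measures and
their best-match-average extensions) use only partially:

1. **dual-source information content** — term specificity estimated from
   gene annotations *and* disease annotations, blended with a weight `w`;
2. **definition-weighted edges** — each `is_a` edge carries the TF-IDF
   cosine similarity of its endpoints' textual definitions, so a step
   between lexically close terms costs less than a step between loosely
   related ones;
3. **path-constrained term similarity** — two terms are similar only when a
   directed path links them (ancestor/descendant); siblings that merely
   share an ancestor score 0, reflecting that sibling leaves in a phenotype
   hierarchy need share neither genes nor symptoms;
4. **PMI-weighted set similarity** — the best-match average between two term
   sets weights each matched pair by the pointwise mutual information of
   their co-annotation across diseases (or genes).

# The model

## Information content (IC)

For an annotation source with `N` units (genes or diseases), each unit's
term set is closed upward under the true-path rule (an annotation to a term
implies annotation to all its ancestors).  With `n_t` the number of units
whose closed set contains `t`:

$$IC_{src}(t) = \ln\frac{N}{n_t}, \qquad
  IC(t) = w\,IC_{gene}(t) + (1-w)\,IC_{disease}(t).$$

The root has `n_root = N`, hence IC 0.  Propagation is essential: without
it, `n_t = 0` for most internal terms and the logarithm is undefined.  Terms
with zero propagated count in a source (no unit annotates them or any
descendant) are treated as maximally specific and receive that source's
maximum observed IC, keeping every downstream product finite.

`w` defaults to 0.5, i.e. equal trust in both sources; `w = 1` and `w = 0`
reduce exactly to single-source IC, and `sweep_w()` exists to study the
blend empirically.

## The weighted DAG

Each term's definition (falling back to name + synonyms when the definition
is empty) is tokenized — lowercased, punctuation stripped, a small fixed
English stop-word list removed — and embedded as a TF-IDF vector over the
whole ontology: component for word `p` in document `t` is
$(n_p/|t|)\cdot\ln(|T|/df(p))$.  Every `is_a` edge `(c, p)` gets weight
`cos(v_c, v_p)`, clamped to `[0, 1]`.  An endpoint with an empty or
all-zero vector yields the *neutral* weight 1.0: term similarity multiplies
weights along a path, and a 0 would annihilate every path through that term,
which a missing definition cannot justify.  Only edge entries of the
pairwise definition-similarity matrix are materialised; nothing downstream
consumes non-edge entries.

## Term similarity

For terms `t_i, t_j`:

$$sim(t_i,t_j)=
 \begin{cases}
 \min(IC(t_i),IC(t_j)) \cdot W(t_i,t_j) \cdot
 \left(1-\dfrac{dist(t_i,t_j)}{mostDepth}\right) & \text{reachable}\\[4pt]
 0 & \text{otherwise}
 \end{cases}$$

where *reachable* means one term is an ancestor of the other (or they are
equal), `dist` is the minimum number of edges on a directed path between
them, `W` is the edge-weight product along such a path, and `mostDepth` is
the longest leaf-to-root path of the ontology.  Consequences:
`sim(t, t) = IC(t)` (distance 0, empty product 1), and
`0 ≤ sim ≤ min(IC)` always.

Two readings of the formula are genuinely open and were fixed as follows:

* **Which path?**  Ontologies are DAGs, so several directed paths can link
  an ancestor/descendant pair.  `dist` is the shortest path (the only
  reading consistent with the `1 - dist/mostDepth` factor, which must stay
  non-negative), and among shortest paths `W` takes the maximum weight
  product — the least destructive tie-break.  Both are computed by a
  level-order dynamic programme up the ancestor cone of each term, exact by
  construction and verified against exhaustive path enumeration in the
  tests.
* **min IC, literally.**  After propagation the ancestor of a reachable pair
  always has the smaller count-based IC, so `min(IC_i, IC_j)` usually equals
  the ancestor's IC; the minimum is kept literal because the zero-count
  fallback can break that ordering between sources.

Degenerate case: a single-node ontology has `mostDepth = 0`; the distance
factor is then defined as 1.

## PMI and set similarity

With propagated unit term sets, `p(t)` is the fraction of units containing
`t` and `p(a, b)` the fraction containing both, and
$PMI(a,b) = \ln\frac{p(a,b)}{p(a)p(b)}$.  Conventions the formula itself
does not determine:

* never-co-annotated pairs (including terms absent from the corpus) get PMI
  0 rather than $-\infty$: no evidence of association;
* `PMI(t, t) = -\ln p(t) \ge 0`;
* the default mode clamps negative PMI to 0 ("positive PMI").  A negative
  weight would flip the sign of `sim × PMI` inside a max and make the
  best-match prefer *weaker* matches; raw mode is retained for sensitivity
  analysis.

Set similarity is the PMI-weighted symmetric best-match average:

$$Sim_{set}(T_p \to T_c)=\frac{1}{|T_p|}\sum_{t_i\in T_p}
  \max_{t_j\in T_c}\big(sim(t_i,t_j)\cdot PMI(t_i,t_j)\big), \qquad
  Sim_{sym} = \tfrac12\big(Sim_{set}(T_p\to T_c)+Sim_{set}(T_c\to T_p)\big).$$

The PMI source defaults to the corpus of the candidate type being ranked
(disease annotations when ranking diseases); `gene` and `union` are
available.

## Ablation toggles

The four components are first-class switches of `sim_config()`: `ic_source`
(dual vs single-source IC), `use_depth` (distance factor), `use_weight`
(definition weights vs unit weights), `pmi_mode` (`positive`/`raw`/`off`).
With everything off the measure degrades to a plain path-constrained IC
best-match average, which the test suite uses as an independent reference.

# Patient simulation

Three profile types, generated per disease from its frequency-annotated term
set:

* **optimal** — each annotated phenotype is included independently with
  probability equal to its frequency (penetrance); empty draws are redrawn
  (budget 100, then an error);
* **noisy** — the optimal set plus `⌈n/2⌉` terms drawn uniformly from the
  ontology terms *outside* the propagated annotation set of the true
  disease;
* **noisy & imprecise** — `⌊n/2⌋` of the optimal terms are first replaced by
  a uniformly drawn proper ancestor (root excluded — it carries no
  information; a term whose only ancestor is the root is resampled from the
  remaining optimal terms), then noise is added, half the size of the
  post-replacement set.  "Half of the imprecision dataset" is ambiguous
  between the post-replacement set size and the replaced count; the set-size
  reading is implemented and the noise count is a parameter.

All generators are pure functions of their seed.  Provenance tags
(`optimal` / `noise` / `imprecise`) partition every patient's term set.

# The synthetic fixture generator

`make_fixture()` emulates the full input stack so the measure is testable
without any download: a layered random DAG (single root, every term wired to
the previous layer, ~30% of terms receiving a second, diamond-forming
parent), Zipf-vocabulary definitions in which a child keeps each token of
its primary parent's definition with probability `def_overlap` (so edge
weights are informative), leaf-biased annotation sets, gene–disease coupling
(a gene copies most of a random disease's annotations with probability
`coupling`), and per-(disease, term) penetrance drawn from the HPO
frequency-modifier midpoints.

Defaults are fixed once as the package's study conditions:

* 200 terms, depth 6, 30 diseases, 40 genes — a desk-scale corpus;
* penetrance weights 0.05 / 0.30 / 0.40 / 0.25 over 1.0 / 0.895 / 0.545 /
  0.17, mirroring the real disease-annotation corpus, where near-obligate
  phenotypes are a small minority;
* a 20-term **common-phenotype pool** from which each disease draws ~35% of
  its annotations, giving diseases the overlapping, co-annotated structure
  real annotation corpora have (think seizures or short stature recurring
  across syndromes).  `common_frac = 0` and `coupling = 0` switch the
  structure off, which the tests use to verify that PMI is then centred on
  zero.

What the generator does **not** emulate: real lexical structure of medical
definitions (tokens are synthetic words), obsolete-term churn, non-`is_a`
relationships, multi-ontology cross-references, and the scale of the real
corpus (10⁴ terms, 10⁵ annotations).  Passing tests on fixtures therefore
validate the algebra and the implementation, not clinical performance.

# Numerical and procedural choices

* Natural logarithms throughout (IC, idf, PMI).
* Cosine weights are clamped to `[0, 1]` against floating-point overshoot.
* Ranking ties: the true target takes the *maximal* rank within its tie
  block by default (pessimistic); mean rank is available.  All-zero score
  vectors therefore give rank = number of candidates.
* Seeds are kept below 2³¹ and all randomness flows through
  `withr::with_seed`, so generators never disturb the caller's RNG state.
* Frequency cells accept `n/m`, percentages, bare probabilities and the six
  HPO frequency-modifier ids (midpoint mapping: Obligate 1.0, Very frequent
  0.895, Frequent 0.545, Occasional 0.17, Very rare 0.025, Excluded 0.0);
  a missing cell means 1.0, which keeps unannotated phenotypes available to
  the simulator.
* Root handling: the root is auto-detected as the unique parentless term;
  when an ontology has several apexes (or when restricting real HPO to the
  Phenotypic-abnormality subtree, the usual clinical choice) the root is
  passed explicitly and the graph is restricted to that subtree.
* Alternative ids are resolved to primary ids while parsing annotations;
  rows with unknown term ids are dropped and counted.

# Problem sizes

The bundled experiments run at the fixture's pinned size: the ranking
experiment uses 100 optimal and 100 noisy patients over the 30 diseases,
repeated with three simulation seeds; the oracle-equivalence suite checks
200 random DAGs of at most 12 nodes against exhaustive enumeration; the
blend sweep uses 11 values of `w` on a 40-patient cohort.  These sizes were
chosen so the whole pipeline (index construction included) re-runs in a few
minutes on one CPU.

# Known limitations

* **PMI on small dense corpora.**  On the pinned fixture the acceptance
  experiment consistently finds the PMI-off ablation slightly *ahead* of the
  full configuration on noisy patients (mean true rank ≈ 1.03 vs ≈ 1.15,
  both near ceiling).  The mechanism is visible in individual patients: with
  30 diseases annotating 200 terms, a uniformly drawn noise term is often
  itself an annotated phenotype of some wrong disease, and its identity
  match there is weighted `IC(t)·(−ln p(t))` — rarity squared — which can
  outweigh the true disease's matches on common phenotypes.  This is a real
  property of the measure at desk scale, not an implementation artefact
  (distances, weights, IC and PMI are all oracle-verified); at the scale of
  the real corpus the trade-off between noise amplification and
  co-annotation recall can land differently.  The `pmi_mode` toggle exists
  precisely so users can measure this on their own corpus.
* Term similarity is *not* normalised into `[0, 1]`; scores are comparable
  within one (ontology, corpus, config) triple only.
* Reachability is strict ancestry.  Two specific terms under a common
  ancestor score 0 even when clinically related; the imprecise-patient
  simulator shows what this costs when clinicians code ancestors.
* No stemming, lemmatisation or synonym expansion beyond the empty
  definition fallback; definition weighting inherits the vocabulary quality
  of the ontology.
* Gene candidates are ranked directly by their annotated phenotype sets;
  mapping causative genes to diseases is out of scope.
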