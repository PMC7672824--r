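---
title: "Methods: nearest-neighbor voting for protein GO prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nearest-neighbor voting for protein GO prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goknn)
```

## The problem

Assigning Gene Ontology (GO) terms to a protein from its sequence is a
hierarchical multi-label classification problem: tens of thousands of
candidate terms, organized as a directed acyclic graph (DAG) in three
namespaces (biological process, cellular component, molecular function),
with far fewer experimentally annotated proteins than terms. `goknn`
implements an instance-based approach: proteins are embedded in a feature
space built from their evolutionary profiles, neighbors are found by
Euclidean distance after PCA, and the neighbors' annotations are transferred
by weighted voting with scores propagated up the ontology.

Each namespace is processed independently end to end: a DAG never mixes
namespaces (cross-namespace edges are a parse error), and training,
prediction and evaluation are meant to be run per ontology.

## Feature representation (TFPSSM)

A protein of length $n$ with position-specific scoring matrix (PSSM)
$M \in \mathbb{R}^{n \times 20}$ (log-odds from an iterative profile search)
is represented by the frequencies of *gapped dipeptides* $XdY$ — residue
types $X$ and $Y$ separated by exactly $d$ positions, $0 \le d \le l$. The
per-position residue weights are the logistic transform of the log-odds,

$$ w_{i,X} = \frac{1}{1 + e^{-M_{i,X}}}, $$

and the raw value of pattern $XdY$ is the product-sum over all eligible
position pairs,

$$ v_{XdY} = \sum_{i\,:\,i+d+1 \le n} w_{i,X}\, w_{i+d+1,Y}, $$

normalized to unit sum per protein (a term frequency). The vector has
$20 \times (l+1) \times 20$ entries; the default maximum gap $l = 13$ gives
5600 dimensions.

**This exact formula is a reconstruction.** The TFPSSM literature this
design follows does not pin down the transform or the normalization; the
logistic/unit-sum combination is this package's documented choice. It has
the property (tested) that a saturating one-hot profile reduces the feature
vector to plain normalized gapped-dipeptide counts of the sequence, which is
also the fallback used for proteins that have only a FASTA sequence and no
PSSM (`one_hot_pssm()`). Nonstandard residues (B, Z, X, U, O) keep their
positions — so gap distances are preserved — but contribute no weight.

The package never runs the profile search itself; PSSMs are consumed as
PSI-BLAST ASCII files (`parse_ascii_pssm()`), and the recommended parameter
string for generating them externally is shipped as `PSIBLAST_PARAMS`.

## Dimensionality reduction

PCA is fitted on training vectors only (`fit_pca()`, SVD on mean-centered
data via `stats::prcomp`). The number of retained components is the smallest
count whose cumulative explained-variance ratio reaches `target_ratio`
(default 0.96, a regime where whitening preprocessing is most effective);
whitening (default on) scales each retained component to unit training
variance. Whitening is applied to the retained components only — whether to
whiten before or after truncation was an open choice; truncation-first keeps
the discarded subspace out of the scaling entirely. Distance between
proteins is the Euclidean distance of the projected coordinates.

Two numerical conventions make fits reproducible: components are
sign-normalized (largest-magnitude loading positive), and whitening divides
by `max(sdev, 1e-12)` so a degenerate component cannot produce infinities.

Sequence-redundancy reduction (e.g. clustering at 50% identity) is honored
through a precomputed cluster table (`select_cluster_representatives()`);
the clustering itself is out of scope.

## Neighbor selection

Four strategies (`knn_config(mode = ...)`):

* **1NN** — the single nearest training protein; its closed GO set is
  assigned with confidence 1.00.
* **Fixed-KNN** — the $k$ nearest, $k$ chosen by cross-validation
  (`run_experiment_grid()` sweeps $k = 1..10$).
* **Dynamic-KNN** — all training proteins strictly closer than a trained
  distance threshold: each training protein's distance to its nearest other
  training protein is collected, and the threshold is the first, second or
  third quartile (Q1/Q2/Q3) of that distribution. Queries with no neighbor
  inside the threshold are left unpredicted (partial-mode evaluation covers
  this case).
* **Hybrid-KNN** — dynamic, falling back to fixed-$k$ for unpredictable
  queries, so coverage is always 100%.

Conventions chosen where the method description is silent: distance ties
are broken by ascending protein id (platform-independent determinism);
"closer than the threshold" is strict (<); the threshold distribution uses
each training protein's *single* nearest neighbor; quartiles use the
standard linear-interpolation quantile (type 7). A zero trained threshold
(possible when training vectors coincide exactly) admits no neighbors rather
than erroring.

## Vote weighting

Each selected neighbor at distance $d$ votes with weight

* `equal`: 1,
* `inverse`: $1/d$,
* `sqrt_inverse`: $\sqrt{1/d}$ (constrains extreme weights),

with $d$ clamped below at $10^{-9}$ so exact duplicates get a large finite
weight. The fourth scheme, `funoverlap` (dynamic mode only), weights a
neighbor by the overlap of its CATH FunFam assignments with the query's,
both E-value-filtered at $10^{-5}$ at read time. "Overlap proportion" is
implemented as Jaccard, $|A \cap B| / |A \cup B|$; the asymmetric
$|A \cap B| / |A_\mathrm{query}|$ variant is available via
`knn_config(overlap = "query_fraction")`. A neighbor with no retained
FunFams or zero overlap is *not applicable* and is excluded from voting
entirely (not merely down-weighted).

## Propagation and normalization

A term's raw score is the sum of the weights of neighbors annotated with it
(after true-path closure of the training annotations). Scores then flow up
the DAG over the sub-graph spanned by the scored terms and their ancestors,
children before parents; each term merges its own votes with its direct
children's propagated scores — `max` takes the maximum, `sum` the sum. For
the canonical two-child example (children carrying 2.3 and 1.2), Sum gives
the parent 3.5 and Max gives 2.3.

Two conventions matter here:

* **Roots never accumulate score.** Predicting a namespace root is vacuous,
  so roots are excluded from closed annotation sets, from propagation, and
  from predictions. This also makes max-normalization meaningful: in sum
  mode the root would otherwise always dominate, and no non-root score could
  reach 1.
* **Diamond DAGs.** When a descendant reaches an ancestor along several
  paths, the recursive child-wise definition counts its contribution once
  per path. That is the default. `unique_descendants = TRUE` switches to
  counting each descendant's direct votes once; the worked two-child example
  and every tree are unaffected, only multi-parent DAGs differ.

Finally scores are divided by their maximum (`normalize_scores()`), giving
confidences in $(0, 1]$ with the best-supported term at exactly 1;
propagation guarantees hierarchy consistency (every parent scores at least
as much as any positively scored child, in both modes).

## Baselines

* **Naive**: every query receives every term scored by its training
  frequency (fraction of training proteins annotated with it after closure).
* **BLAST**: consumes a 12-column tabular hit file; a hit's weight is
  $-\log_{10}(\max(E, 10^{-180}))$ and a term's score is the maximum weight
  over hits whose subject carries the term, max-normalized per query. The
  E-value-to-confidence conversion is a monotone reconstruction — only the
  existence of a conversion is prescribed by the method this follows.

## Evaluation

Protein-centric precision/recall over a threshold grid
$\tau \in \{0, 0.01, \ldots, 1\}$, with $P_i(\tau)$ the terms scoring
$\ge \tau$ (inclusive reading of "above threshold"):

$$ pr_i(\tau) = \frac{|P_i(\tau) \cap T_i|}{|P_i(\tau)|}, \qquad
   rc_i(\tau) = \frac{|P_i(\tau) \cap T_i|}{|T_i|}, $$

$$ pr(\tau) = \frac{1}{m(\tau)} \sum_{i \in m(\tau)} pr_i(\tau), \qquad
   rc(\tau) = \frac{1}{n_e} \sum_{i=1}^{n_e} rc_i(\tau), \qquad
   F_{\max} = \max_\tau \frac{2\, pr(\tau)\, rc(\tau)}{pr(\tau) + rc(\tau)}, $$

where $m(\tau)$ is the set of proteins with a non-empty prediction at
$\tau$ and the recall denominator $n_e$ is all benchmark proteins (**full
mode**) or $m(0)$, the proteins the method attempted (**partial mode**).
Both predicted and true sets are ancestor-closed (roots excluded) before
counting; the implementation closes a confidence vector by giving each term
the maximum confidence over itself and its descendants, which thresholds to
exactly the set-wise closure at every $\tau$. Proteins whose closed truth is
empty are excluded from $n_e$ with a warning. Precision is undefined where
$m(\tau) = 0$; such grid points are dropped from the curve. Coverage is
$|m(0)|$ over all benchmark proteins.

Cross-validation uses seeded five-fold splits (shuffle + round-robin, fold
sizes within one of each other); with a redundancy cluster table, whole
clusters are kept in a single fold to avoid leakage between train and
validation.

## The synthetic benchmark

`generate_synthetic_benchmark()` emulates the study conditions at desk
scale so the full pipeline is testable without downloads: a random rooted
DAG (default depth 3, branching 2, with occasional second parents creating
diamonds), `n_clusters = 4` protein clusters of `n_proteins = 60` total,
each cluster sharing an integer PSSM profile (log-odds in $-8..8$, the
typical range of profile log-odds) and `terms_per_cluster = 2` deep GO
terms; members perturb the profile with integer-rounded Gaussian noise
(`intra_cluster_noise`, default sd 1 score unit — small relative to the
inter-cluster profile differences, emulating families that a profile search
separates cleanly). Sequences are the per-position argmax residue of the
profile. Optional `n_outliers` adds singleton-profile test queries far from
all training data. All artifacts are deterministic functions of the seed,
and every file written is read back by the package's own parsers.

What this generator does *not* emulate: realistic amino-acid composition and
alignment-depth effects in PSSMs, shared terms between clusters, annotation
incompleteness, and the heavy-tailed term frequencies of real corpora.
Passing tests therefore demonstrate the correctness of the machinery
(features, reduction, voting, propagation, metrics) — not real-data Fmax.

## Problem sizes used in the test-suite and verification runs

Tests run the generator at 8–60 proteins, 2–4 clusters, sequence lengths
20–60, gap $l \le 5$, and random DAGs of up to 50 terms; oracle-equivalence
suites use 50 random instances per operation and 500 propagation cases with
brute-force reference implementations (flat loops, recursion, igraph
reachability). These sizes exercise every code path — the algorithms are
dimension- and scale-agnostic, and `l = 13`-sized vectors (5600 dimensions)
are covered by the feature-dimension checks.

## Known limitations

* The exact TFPSSM transform is a documented reconstruction (above); real
  deployments should treat `target_ratio`, `l` and the weighting scheme as
  tunable and select them by cross-validation, as `run_experiment_grid()`
  does.
* FunFam assignment itself (HMM scanning) and sequence clustering are
  consumed as files, never computed.
* Term-centric evaluation (per-term AUC) and semantic-distance metrics are
  out of scope; Fmax and PR curves are the implemented surface.
* `one_nn` mode with several exactly equidistant nearest neighbors picks
  the lexicographically first rather than merging their term sets.
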