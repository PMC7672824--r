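# goknn — protein GO prediction by nearest-neighbor voting on PSSM features

`goknn` predicts Gene Ontology (GO) annotations for proteins from their
evolutionary sequence profiles. It is aimed at people building or
benchmarking sequence-based function predictors: it covers the whole
pipeline from PSI-BLAST ASCII PSSM files to CAFA-style evaluated
predictions, with no external services and a seeded synthetic-benchmark
generator for testing.

## The method in brief

1. **TFPSSM features.** A protein with PSSM $M \in \mathbb{R}^{n\times 20}$
   is represented by gapped-dipeptide term frequencies: for each pattern
   $XdY$ (residues $X$, $Y$ separated by $d \le l$ positions),
   $v_{XdY} = \sum_i \sigma(M_{i,X})\,\sigma(M_{i+d+1,Y})$ with
   $\sigma$ the logistic function, normalized to unit sum. With the default
   $l = 13$ the vector has $20 \times 14 \times 20 = 5600$ dimensions.
2. **PCA.** Axes are fitted on training data only; the retained dimension is
   the smallest reaching a cumulative explained-variance ratio (default
   0.96) and components are whitened. Protein distance is Euclidean in the
   projected space.
3. **Neighbor voting.** Four selection modes — single nearest neighbor
   (1NN), fixed $k$, dynamic (all neighbors inside a distance threshold
   trained as a quartile Q1/Q2/Q3 of the training nearest-neighbor distance
   distribution), and hybrid (dynamic with fixed-$k$ fallback) — with vote
   weights 1, $1/d$, $\sqrt{1/d}$, or the Jaccard overlap of CATH FunFam
   assignments.
4. **Propagation.** Votes flow up the GO DAG (children before parents),
   merged by Sum or Max; scores are max-normalized to confidences in
   $(0,1]$. Namespace roots never carry score.
5. **Evaluation.** Protein-centric precision/recall over a threshold grid,
   $F_{\max} = \max_\tau 2\,pr\,rc/(pr+rc)$, in full mode (recall averaged
   over all benchmark proteins) or partial mode (over the proteins the
   method attempted), plus coverage tables and clustered five-fold CV
   splitting. Naive (term frequency) and BLAST (hit-table homology
   transfer) baselines are included.

See `vignettes/goknn-methods.Rmd` for the full model description, the
conventions adopted where the method description is ambiguous, and what the
synthetic benchmark does and does not emulate.

## Worked example

```r
library(goknn)

# simulate a benchmark of 4 protein families on a random ontology
bench <- generate_synthetic_benchmark(
  synthetic_spec(seed = 42, n_proteins = 40, n_clusters = 4,
                 intra_cluster_noise = 1)
)
feats <- tfpssm_matrix(bench$pssms, l = 13)
dim(feats)
#> [1]   40 5600

pca <- fit_pca(feats[bench$splits$train, ], target_ratio = 0.96)
pca
#> PCA model: 11 components, cumulative ratio 0.9619 (whitened)
train <- pca_transform(pca, feats[bench$splits$train, ])
test  <- pca_transform(pca, feats[bench$splits$test, ])

model <- go_knn(train, bench$annotations, bench$dag,
                knn_config(mode = "fixed", k = 3, weight_scheme = "inverse",
                           propagation = "sum"))
preds <- predict(model, test)
preds
#> Prediction set: 8 of 8 queries predicted
preds[[1]]
#> GO:0000002 GO:0000004 GO:0000005 GO:0000008 GO:0000011 GO:0000003 GO:0000006
#> 1.00000000 0.50000000 0.33333333 0.16666667 0.16666667 0.33056905 0.24792679
#> GO:0000012 GO:0000013
#> 0.08264226 0.08264226

evaluate_predictions(preds, bench$annotations[bench$splits$test],
                     bench$dag, mode = "full")
#> Fmax 0.930 at tau 0.11 (full mode, n_e = 8, coverage 100.0%)
```

The first query's confidences read as: every term the three neighbors agree
on (the query's own family terms and their ancestors, e.g. `GO:0000002`,
scores 1.00 after Sum propagation and max-normalization), while terms voted
by only the more distant neighbor get proportionally lower confidence. The
evaluation line says that at the best threshold (tau = 0.11) the harmonic
mean of averaged precision and recall is 0.93, with every test protein
receiving at least one prediction.

The same pipeline is scriptable from a shell via the thin CLI
(`inst/cli/goknn`): `simulate`, `featurize`, `fit-pca`, `predict`,
`evaluate`, `baseline`, `grid`.

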