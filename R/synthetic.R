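# Synthetic benchmark generator: random GO DAGs, clustered annotation
# structure and cluster-profiled PSSMs, so the whole pipeline is testable
# without any external database.

#' Specification of a synthetic benchmark
#'
#' Describes the generative model: `n_clusters` groups of proteins, each
#' sharing a cluster-specific PSSM score profile and a coherent GO term set;
#' member PSSMs are the profile plus integer-rounded Gaussian noise.
#' Outlier proteins with their own singleton profiles are placed in the test
#' split to model queries far from all training data.
#'
#' @param seed Integer seed; every downstream artifact is a deterministic
#'   function of it.
#' @param n_proteins Total clustered proteins (split round-robin over
#'   clusters).
#' @param seq_length Range `c(min, max)` of profile lengths; one length is
#'   drawn per cluster.
#' @param n_clusters Number of protein clusters.
#' @param intra_cluster_noise Standard deviation (in log-odds score units)
#'   of the perturbation added to the cluster profile for each member;
#'   rounded to integers to stay in the PSSM dialect. 0 means members are
#'   exact copies of the profile.
#' @param dag_depth,dag_branching Levels below the root and children per
#'   node of the random ontology; extra cross edges (probability 0.25 per
#'   eligible node) create multi-parent terms.
#' @param terms_per_cluster GO terms annotated to every member of a cluster
#'   (sampled from the deepest DAG level).
#' @param n_outliers Isolated test proteins with singleton profiles
#'   (default 0; set to 1 to model a query far from all training data).
#' @param test_fraction Fraction of each cluster held out as test queries.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_proteins = 60L,
                           seq_length = c(40L, 60L), n_clusters = 4L,
                           intra_cluster_noise = 1,
                           dag_depth = 3L, dag_branching = 2L,
                           terms_per_cluster = 2L, n_outliers = 0L,
                           test_fraction = 0.2) {
  stopifnot(n_proteins >= 1, n_clusters >= 1, intra_cluster_noise >= 0,
            dag_depth >= 1, dag_branching >= 1, terms_per_cluster >= 1,
            n_outliers >= 0, test_fraction > 0, test_fraction < 1,
            length(seq_length) == 2L, all(seq_length >= 2))
  if (terms_per_cluster > dag_branching^dag_depth) {
    stop("terms_per_cluster exceeds the number of terms at the deepest level")
  }
  structure(
    list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
         seq_length = as.integer(seq_length),
         n_clusters = as.integer(n_clusters),
         intra_cluster_noise = intra_cluster_noise,
         dag_depth = as.integer(dag_depth),
         dag_branching = as.integer(dag_branching),
         terms_per_cluster = as.integer(terms_per_cluster),
         n_outliers = as.integer(n_outliers),
         test_fraction = test_fraction),
    class = "synthetic_spec"
  )
}

# Random rooted DAG: a (branching)-ary tree of the given depth plus random
# cross edges to a second parent in the level above (diamonds).
.random_dag <- function(depth, branching, cross_prob = 0.25) {
  levels <- list("1")
  next_id <- 2L
  for (lv in seq_len(depth)) {
    prev <- levels[[lv]]
    cur <- character()
    for (p in prev) {
      cur <- c(cur, as.character(seq(next_id, next_id + branching - 1L)))
      next_id <- next_id + branching
    }
    levels[[lv + 1L]] <- cur
  }
  fmt <- function(i) sprintf("GO:%07d", as.integer(i))
  ids <- fmt(unlist(levels))
  parents <- stats::setNames(rep(list(character()), length(ids)), ids)
  for (lv in seq_len(depth)) {
    prev <- levels[[lv]]
    cur <- levels[[lv + 1L]]
    primary <- rep(prev, each = branching)
    for (j in seq_along(cur)) {
      par <- fmt(primary[j])
      if (length(prev) > 1L && stats::runif(1) < cross_prob) {
        extra <- sample(setdiff(prev, primary[j]), 1L)
        par <- c(par, fmt(extra))
      }
      parents[[fmt(cur[j])]] <- par
    }
  }
  dag <- go_dag(ids, parents = parents[ids])
  attr(dag, "levels") <- lapply(levels, fmt)
  dag
}

#' Generate a synthetic GO prediction benchmark
#'
#' Deterministic given `spec$seed`. Builds a random ontology, assigns each
#' cluster a term set from the deepest level, samples one integer PSSM
#' profile per cluster (log-odds in -8..8) and perturbs it per member with
#' integer-rounded Gaussian noise of the specified standard deviation.
#' Sequences are read off each profile as the highest-scoring residue per
#' position. Outlier proteins get independent profiles and term sets and go
#' to the test split.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory; when given, all standard-format files are
#'   written there (`ontology.obo`, `annotations.tsv`, `pssm/<id>.pssm`,
#'   `train.txt`, `test.txt`, `clusters.tsv`).
#' @return List with `pssms` (list of `pssm`), `dag`, `annotations` (raw,
#'   un-closed), `splits` (`$train`, `$test`), `clusters` (named vector),
#'   and `spec`.
#' @export
generate_synthetic_benchmark <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    dag <- .random_dag(spec$dag_depth, spec$dag_branching)
    deepest <- attr(dag, "levels")[[spec$dag_depth + 1L]]

    cluster_terms <- lapply(seq_len(spec$n_clusters), function(i) {
      sample(deepest, spec$terms_per_cluster)
    })
    lens <- sample(seq(spec$seq_length[1], spec$seq_length[2]),
                   spec$n_clusters, replace = TRUE)
    profiles <- lapply(lens, function(L) {
      matrix(sample(-8:8, L * 20L, replace = TRUE), nrow = L)
    })

    cluster_of <- rep_len(seq_len(spec$n_clusters), spec$n_proteins)
    ids <- sprintf("P%04d", seq_len(spec$n_proteins + spec$n_outliers))
    pssms <- vector("list", length(ids))
    annotations <- vector("list", length(ids))
    clusters <- character(length(ids))
    for (i in seq_len(spec$n_proteins)) {
      c_ <- cluster_of[i]
      sc <- profiles[[c_]]
      if (spec$intra_cluster_noise > 0) {
        sc <- sc + matrix(round(stats::rnorm(length(sc), 0,
                                             spec$intra_cluster_noise)),
                          nrow = nrow(sc))
      }
      seq_ <- paste(AA_PSIBLAST[max.col(sc, ties.method = "first")],
                    collapse = "")
      pssms[[i]] <- pssm(ids[i], seq_, sc)
      annotations[[i]] <- cluster_terms[[c_]]
      clusters[i] <- paste0("C", c_)
    }
    for (j in seq_len(spec$n_outliers)) {
      i <- spec$n_proteins + j
      L <- sample(seq(spec$seq_length[1], spec$seq_length[2]), 1L)
      sc <- matrix(sample(-8:8, L * 20L, replace = TRUE), nrow = L)
      seq_ <- paste(AA_PSIBLAST[max.col(sc, ties.method = "first")],
                    collapse = "")
      pssms[[i]] <- pssm(ids[i], seq_, sc)
      annotations[[i]] <- sample(deepest, 1L)
      clusters[i] <- paste0("O", j)
    }
    names(annotations) <- ids
    names(clusters) <- ids

    test <- character()
    for (c_ in seq_len(spec$n_clusters)) {
      members <- ids[seq_len(spec$n_proteins)][cluster_of == c_]
      n_test <- max(1L, floor(length(members) * spec$test_fraction))
      test <- c(test, members[seq_len(n_test)])
    }
    if (spec$n_outliers > 0) {
      test <- c(test, ids[spec$n_proteins + seq_len(spec$n_outliers)])
    }
    train <- setdiff(ids, test)

    out <- list(pssms = pssms, dag = dag, annotations = annotations,
                splits = list(train = train, test = test),
                clusters = clusters, spec = spec)
    if (!is.null(dir)) {
      dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
      write_obo(dag, file.path(dir, "ontology.obo"))
      write_annotations(annotations, file.path(dir, "annotations.tsv"))
      for (p in pssms) {
        write_ascii_pssm(p, file.path(dir, "pssm", paste0(p$protein_id, ".pssm")))
      }
      writeLines(train, file.path(dir, "train.txt"))
      writeLines(test, file.path(dir, "test.txt"))
      writeLines(c("# protein_id\tcluster_id",
                   paste(ids, clusters, sep = "\t")),
                 file.path(dir, "clusters.tsv"))
    }
    out
  })
}

#' Cross-validated grid search over predictor configurations
#'
#' For each fold of a seeded split of the supplied proteins and each grid
#' row, fits PCA on the training folds, trains the configured predictor,
#' predicts the validation fold and evaluates it. Results are averaged over
#' folds. Deterministic given `seed` and invariant to the row order of
#' `features` (ids are sorted before splitting).
#'
#' @param features TFPSSM feature matrix (rownames = protein ids).
#' @param annotations Annotation list covering the proteins.
#' @param dag A `go_dag`.
#' @param grid data.frame with columns `mode`, `k`, `quartile`,
#'   `weight_scheme`, `propagation` (missing columns take
#'   [knn_config()] defaults).
#' @param target_ratio,whiten PCA settings.
#' @param mode Evaluation mode, `"full"` or `"partial"`.
#' @param n_folds,seed Cross-validation settings.
#' @return `grid` with appended columns `fmax` and `coverage` (fold means).
#' @export
run_experiment_grid <- function(features, annotations, dag, grid,
                                target_ratio = 0.96, whiten = TRUE,
                                mode = "full", n_folds = 5L, seed = 1L) {
  ids <- sort(rownames(features))
  folds <- five_fold_split(ids, seed = seed, n_folds = n_folds)
  defaults <- knn_config()
  fmax <- matrix(NA_real_, nrow(grid), n_folds)
  cov <- matrix(NA_real_, nrow(grid), n_folds)
  for (f in seq_len(n_folds)) {
    val_ids <- ids[folds == f]
    tr_ids <- setdiff(ids, val_ids)
    pca <- fit_pca(features[tr_ids, , drop = FALSE], target_ratio, whiten)
    tr <- pca_transform(pca, features[tr_ids, , drop = FALSE])
    va <- pca_transform(pca, features[val_ids, , drop = FALSE])
    for (g in seq_len(nrow(grid))) {
      cfg <- knn_config(
        mode = as.character(grid$mode[g]),
        k = if ("k" %in% names(grid)) grid$k[g] else defaults$k,
        quartile = if ("quartile" %in% names(grid)) {
          as.character(grid$quartile[g])
        } else defaults$quartile,
        weight_scheme = if ("weight_scheme" %in% names(grid)) {
          as.character(grid$weight_scheme[g])
        } else defaults$weight_scheme,
        propagation = if ("propagation" %in% names(grid)) {
          as.character(grid$propagation[g])
        } else defaults$propagation
      )
      model <- go_knn(tr, annotations, dag, cfg)
      preds <- predict(model, va)
      res <- evaluate_predictions(preds, annotations[val_ids], dag,
                                  mode = mode)
      fmax[g, f] <- res$fmax
      cov[g, f] <- res$coverage
    }
  }
  grid$fmax <- rowMeans(fmax)
  grid$coverage <- rowMeans(cov)
  grid
}
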