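# Nearest-neighbor voting predictors: neighbor selection (1NN / Fixed /
# Dynamic / Hybrid), vote weighting, hierarchical score propagation,
# normalization, and the Naive / BLAST baselines.

#' Configuration for a KNN voting predictor
#'
#' @param mode Neighbor selection strategy: `"one_nn"` (single nearest
#'   neighbor, scores fixed at 1.00), `"fixed"` (k nearest), `"dynamic"`
#'   (all neighbors strictly closer than a distance threshold trained from
#'   the data), or `"hybrid"` (dynamic with fixed-k fallback for queries no
#'   training protein is close enough to).
#' @param k Neighbor count for `fixed` / `hybrid`.
#' @param quartile Which quartile of the training nearest-neighbor distance
#'   distribution to use as the dynamic threshold: `"Q1"`, `"Q2"` or `"Q3"`.
#' @param weight_scheme Vote weight per neighbor: `"equal"` (1),
#'   `"inverse"` (1/d), `"sqrt_inverse"` (sqrt(1/d)), or `"funoverlap"`
#'   (overlap of CATH FunFam assignments with the query; dynamic mode only).
#' @param propagation How scores merge up the GO DAG: `"sum"` or `"max"`.
#' @param overlap FunOverlap definition: `"jaccard"` (intersection over
#'   union, default) or `"query_fraction"` (intersection over query set).
#' @param unique_descendants For Sum propagation on DAGs with multiple
#'   paths: count each descendant's direct votes once per descendant instead
#'   of once per path (default FALSE, the recursive reading).
#' @return A `knn_config` list.
#' @export
knn_config <- function(mode = c("fixed", "one_nn", "dynamic", "hybrid"),
                       k = 3L,
                       quartile = c("Q2", "Q1", "Q3"),
                       weight_scheme = c("inverse", "equal", "sqrt_inverse",
                                         "funoverlap"),
                       propagation = c("sum", "max"),
                       overlap = c("jaccard", "query_fraction"),
                       unique_descendants = FALSE) {
  mode <- match.arg(mode)
  quartile <- match.arg(quartile)
  weight_scheme <- match.arg(weight_scheme)
  propagation <- match.arg(propagation)
  overlap <- match.arg(overlap)
  if (mode %in% c("fixed", "hybrid")) {
    if (!is.numeric(k) || k < 1) stop("k must be a positive integer")
    k <- as.integer(k)
  }
  if (weight_scheme == "funoverlap" && mode != "dynamic") {
    stop("the funoverlap weight scheme is only used with dynamic mode")
  }
  structure(list(mode = mode, k = k, quartile = quartile,
                 weight_scheme = weight_scheme, propagation = propagation,
                 overlap = overlap, unique_descendants = unique_descendants),
            class = "knn_config")
}

.neighbor_frame <- function(ids, distances) {
  o <- order(distances, ids)
  data.frame(protein_id = ids[o], distance = distances[o],
             stringsAsFactors = FALSE, row.names = NULL)
}

.dists_to <- function(query, train) {
  sqrt(colSums((t(train) - as.numeric(query))^2))
}

#' k nearest training proteins of a query
#'
#' Distance ties are broken by ascending protein id for determinism.
#'
#' @param query Reduced coordinate vector.
#' @param train Matrix of reduced training coordinates, rownames = ids.
#' @param k Number of neighbors, `1 <= k <= nrow(train)`.
#' @return data.frame with columns `protein_id`, `distance`, sorted by
#'   (distance, protein_id).
#' @export
nearest_neighbors_fixed <- function(query, train, k) {
  if (k > nrow(train)) {
    stop("k = ", k, " exceeds training set size ", nrow(train))
  }
  if (k < 1) stop("k must be >= 1")
  d <- .dists_to(query, train)
  .neighbor_frame(rownames(train), d)[seq_len(k), , drop = FALSE]
}

#' Train the dynamic distance threshold
#'
#' For every training protein, the distance to its single nearest other
#' training protein is computed; the requested quartile (Q1/Q2/Q3, linear
#' interpolation between order statistics) of that distribution is the
#' threshold. This is a trained parameter: it depends only on the training
#' set, never on queries.
#'
#' @param train Matrix of reduced training coordinates (>= 2 rows).
#' @param quartile `"Q1"`, `"Q2"` or `"Q3"`.
#' @return The threshold distance (scalar).
#' @export
dynamic_distance_threshold <- function(train, quartile = c("Q2", "Q1", "Q3")) {
  quartile <- match.arg(quartile)
  if (nrow(train) < 2L) stop("need at least 2 training proteins")
  dm <- as.matrix(stats::dist(train))
  diag(dm) <- Inf
  nn <- apply(dm, 1L, min)
  p <- c(Q1 = 0.25, Q2 = 0.5, Q3 = 0.75)[[quartile]]
  unname(stats::quantile(nn, probs = p, type = 7))
}

#' Training proteins strictly closer than a distance threshold
#'
#' May return zero rows: such a query cannot be predicted in dynamic mode
#' and is left out of the prediction set (partial-mode bookkeeping).
#'
#' @inheritParams nearest_neighbors_fixed
#' @param threshold Positive distance threshold.
#' @return data.frame as in [nearest_neighbors_fixed()] (possibly empty).
#' @export
nearest_neighbors_dynamic <- function(query, train, threshold) {
  stopifnot(threshold > 0)
  d <- .dists_to(query, train)
  keep <- d < threshold
  .neighbor_frame(rownames(train)[keep], d[keep])
}

#' Dynamic neighbors with fixed-k fallback
#'
#' Uses the dynamic result when non-empty; otherwise falls back to the k
#' nearest neighbors ignoring the threshold, so every query is predicted.
#'
#' @inheritParams nearest_neighbors_fixed
#' @param threshold Dynamic distance threshold.
#' @return data.frame as in [nearest_neighbors_fixed()].
#' @export
hybrid_neighbors <- function(query, train, k, threshold) {
  nb <- nearest_neighbors_dynamic(query, train, threshold)
  if (nrow(nb) > 0L) nb else nearest_neighbors_fixed(query, train, k)
}

#' Vote weight from neighbor distance
#'
#' `equal` gives every neighbor weight 1; `inverse` gives 1/d; and
#' `sqrt_inverse` gives sqrt(1/d), constraining the range to avoid extreme
#' weights. Distances are clamped below at 1e-9 so exact duplicates get a
#' large finite weight.
#'
#' @param distance Non-negative distance(s).
#' @param scheme `"equal"`, `"inverse"` or `"sqrt_inverse"`.
#' @return Positive weight(s).
#' @export
voting_weight <- function(distance,
                          scheme = c("equal", "inverse", "sqrt_inverse")) {
  scheme <- match.arg(scheme)
  if (any(distance < 0)) stop("distance must be >= 0")
  d <- pmax(distance, 1e-9)
  switch(scheme,
         equal = rep(1, length(distance)),
         inverse = 1 / d,
         sqrt_inverse = sqrt(1 / d))
}

#' FunFam overlap weight between query and neighbor
#'
#' The overlap proportion of the CATH functional-family (FunFam) assignments
#' of neighbor and query, by default Jaccard (|intersection| / |union|); the
#' asymmetric |intersection| / |query| variant is available as
#' `"query_fraction"`. A neighbor with no retained FunFams, or with zero
#' overlap, is not applicable and must be excluded from voting (weight 0 is
#' the sentinel).
#'
#' @param query_ff,neighbor_ff Character vectors of FunFam ids (already
#'   E-value-filtered, see [read_funfams()]).
#' @param method `"jaccard"` or `"query_fraction"`.
#' @return Weight in `[0, 1]`; 0 means "exclude this neighbor".
#' @export
funoverlap_weight <- function(query_ff, neighbor_ff,
                              method = c("jaccard", "query_fraction")) {
  method <- match.arg(method)
  query_ff <- unique(query_ff)
  neighbor_ff <- unique(neighbor_ff)
  if (!length(query_ff) || !length(neighbor_ff)) return(0)
  inter <- length(intersect(query_ff, neighbor_ff))
  denom <- if (method == "jaccard") {
    length(union(query_ff, neighbor_ff))
  } else {
    length(query_ff)
  }
  inter / denom
}

#' Read a FunFam assignment table
#'
#' Three tab-separated columns: `protein_id`, `funfam_id`, `e_value`.
#' Assignments with E-value above the threshold are discarded at read time,
#' so downstream code only ever sees retained FunFams.
#'
#' @param file Path to the TSV (`#` comments skipped).
#' @param evalue_threshold Maximum E-value to retain (default 1e-5).
#' @return Named list: protein id -> character vector of FunFam ids.
#' @export
read_funfams <- function(file, evalue_threshold = 1e-5) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed FunFam line ", bad[1])
  prot <- vapply(parts, `[`, "", 1L)
  ff <- vapply(parts, `[`, "", 2L)
  ev <- as.numeric(vapply(parts, `[`, "", 3L))
  keep <- !is.na(ev) & ev <= evalue_threshold
  split(ff[keep], factor(prot[keep], levels = unique(prot[keep])))
}

#' Weighted vote over neighbor annotations
#'
#' Each GO term's raw score is the sum of the weights of the neighbors
#' annotated (after true-path closure) with that term.
#'
#' @param neighbors data.frame with columns `protein_id` and `weight`.
#' @param annotations Closed annotation list (protein id -> GO ids).
#' @return Named numeric vector of raw term scores.
#' @export
vote <- function(neighbors, annotations) {
  scores <- numeric()
  for (i in seq_len(nrow(neighbors))) {
    id <- neighbors$protein_id[i]
    terms <- annotations[[id]]
    if (is.null(terms)) stop("neighbor ", id, " has no annotation record")
    for (t in terms) {
      scores[t] <- (if (is.na(scores[t])) 0 else scores[t]) +
        neighbors$weight[i]
    }
  }
  scores
}

#' Propagate term scores up the GO DAG
#'
#' Scores flow from children to parents over the sub-DAG spanned by the
#' scored terms and their ancestors (namespace roots excluded — predicting a
#' root is vacuous, so roots never accumulate score). Terms are processed
#' children-before-parents; each term's propagated score merges its own
#' direct votes with its direct children's propagated scores:
#' `max` mode takes the maximum, `sum` mode the sum.
#'
#' In `sum` mode on a DAG where a descendant reaches an ancestor along
#' several paths, the recursive definition counts it once per path. Setting
#' `unique_descendants = TRUE` instead scores each term as its own votes
#' plus the direct votes of each distinct descendant, counted once.
#'
#' @param scores Named numeric vector of raw term scores.
#' @param dag A `go_dag`; all scored terms must exist in it.
#' @param mode `"sum"` or `"max"`.
#' @param unique_descendants See above (sum mode only).
#' @return Named numeric vector over scored terms and their non-root
#'   ancestors.
#' @export
propagate_scores <- function(scores, dag, mode = c("sum", "max"),
                             unique_descendants = FALSE) {
  mode <- match.arg(mode)
  terms <- names(scores)
  unknown <- setdiff(terms, dag$terms$id)
  if (length(unknown)) stop("scored term not in DAG: ", unknown[1])
  nodes <- unique(c(terms, unlist(lapply(terms, ancestors, dag = dag),
                                  use.names = FALSE)))
  nodes <- setdiff(nodes, dag$roots)
  if (!length(nodes)) return(stats::setNames(numeric(0), character(0)))

  own <- stats::setNames(numeric(length(nodes)), nodes)
  live <- intersect(terms, nodes)  # scored roots carry no score
  own[live] <- scores[live]

  if (mode == "sum" && unique_descendants) {
    out <- own
    for (t in nodes) {
      desc <- intersect(descendants(dag, t), nodes)
      out[t] <- own[t] + sum(own[desc])
    }
    return(out)
  }

  # children-before-parents order within the induced sub-DAG (Kahn on
  # child -> parent edges)
  sub_parents <- lapply(dag$parents[nodes], intersect, nodes)
  indeg <- stats::setNames(integer(length(nodes)), nodes)  # children count
  for (t in nodes) {
    for (p in sub_parents[[t]]) indeg[p] <- indeg[p] + 1L
  }
  queue <- nodes[indeg == 0L]
  prop <- own
  while (length(queue)) {
    t <- queue[1]
    queue <- queue[-1]
    for (p in sub_parents[[t]]) {
      prop[p] <- if (mode == "sum") prop[p] + prop[t] else max(prop[p], prop[t])
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  prop
}

#' Normalize term scores to confidences in (0, 1]
#'
#' Divides every score by the maximum, so the best-supported term gets
#' confidence exactly 1. Idempotent. All-zero input yields an empty
#' prediction with a warning.
#'
#' @param scores Named numeric vector of non-negative scores.
#' @return Named numeric vector with maximum 1, or empty vector.
#' @export
normalize_scores <- function(scores) {
  if (!length(scores) || max(scores) <= 0) {
    if (length(scores)) warning("all scores are zero; empty prediction")
    return(stats::setNames(numeric(0), character(0)))
  }
  scores / max(scores)
}

#' Train a KNN voting predictor
#'
#' Bundles the reduced training coordinates, the (closed) training
#' annotations, the ontology and the configuration; for dynamic and hybrid
#' modes the distance threshold is trained here from the training set's
#' nearest-neighbor distance distribution.
#'
#' @param train Matrix of reduced training coordinates (rownames = ids).
#' @param annotations Annotation list for (at least) the training proteins;
#'   closed internally under the true-path rule.
#' @param dag A `go_dag`.
#' @param config A [knn_config()].
#' @param funfams Optional FunFam assignment list ([read_funfams()]);
#'   required for the funoverlap weight scheme.
#' @return An object of class `go_knn`.
#' @export
go_knn <- function(train, annotations, dag, config = knn_config(),
                   funfams = NULL) {
  stopifnot(inherits(dag, "go_dag"), inherits(config, "knn_config"))
  train <- as.matrix(train)
  if (is.null(rownames(train))) stop("training matrix needs protein ids as rownames")
  missing_ann <- setdiff(rownames(train), names(annotations))
  if (length(missing_ann)) {
    stop("training protein without annotations: ", missing_ann[1])
  }
  if (config$weight_scheme == "funoverlap" && is.null(funfams)) {
    stop("funoverlap weighting requires FunFam assignments")
  }
  threshold <- NULL
  if (config$mode %in% c("dynamic", "hybrid")) {
    threshold <- dynamic_distance_threshold(train, config$quartile)
  }
  structure(
    list(train = train,
         annotations = close_annotations(dag, annotations[rownames(train)]),
         dag = dag, config = config, threshold = threshold,
         funfams = funfams),
    class = "go_knn"
  )
}

#' @export
print.go_knn <- function(x, ...) {
  cat("KNN GO predictor:", x$config$mode, "mode,",
      nrow(x$train), "training proteins")
  if (!is.null(x$threshold)) {
    cat(",", x$config$quartile, "threshold", sprintf("%.4g", x$threshold))
  }
  cat("\n")
  invisible(x)
}

#' Predict GO terms for query proteins
#'
#' Runs the full pipeline per query: select neighbors per the configured
#' mode, weight their votes, sum votes per term, propagate up the DAG,
#' normalize to confidences. In `one_nn` mode the single nearest neighbor's
#' closed GO set is assigned with confidence 1.00. Queries with no
#' applicable neighbors (dynamic mode, or all FunOverlap weights zero) are
#' absent from the result.
#'
#' @param object A `go_knn` model.
#' @param newdata Matrix of reduced query coordinates (rownames = ids).
#' @param funfams Optional FunFam assignments for the queries (defaults to
#'   the table stored in the model).
#' @param ... Unused.
#' @return A `prediction_set`: named list (protein id -> named confidence
#'   vector) with attribute `queries` recording every query id attempted.
#' @export
predict.go_knn <- function(object, newdata, funfams = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(rownames(newdata))) stop("query matrix needs protein ids as rownames")
  if (is.null(funfams)) funfams <- object$funfams
  cfg <- object$config
  preds <- list()
  for (q in rownames(newdata)) {
    qv <- newdata[q, ]
    # a degenerate (zero) trained threshold admits no neighbors at all
    thr_ok <- is.null(object$threshold) || object$threshold > 0
    nb <- switch(cfg$mode,
      one_nn = nearest_neighbors_fixed(qv, object$train, 1L),
      fixed = nearest_neighbors_fixed(qv, object$train, cfg$k),
      dynamic = if (thr_ok) {
        nearest_neighbors_dynamic(qv, object$train, object$threshold)
      } else .neighbor_frame(character(), numeric()),
      hybrid = if (thr_ok) {
        hybrid_neighbors(qv, object$train, cfg$k, object$threshold)
      } else nearest_neighbors_fixed(qv, object$train, cfg$k)
    )
    if (nrow(nb) == 0L) next
    if (cfg$mode == "one_nn") {
      terms <- object$annotations[[nb$protein_id[1]]]
      if (!length(terms)) next
      preds[[q]] <- stats::setNames(rep(1, length(terms)), terms)
      next
    }
    if (cfg$weight_scheme == "funoverlap") {
      qff <- funfams[[q]]
      w <- vapply(nb$protein_id, function(id) {
        funoverlap_weight(qff, funfams[[id]], cfg$overlap)
      }, 0)
      nb$weight <- w
      nb <- nb[nb$weight > 0, , drop = FALSE]
      if (nrow(nb) == 0L) next
    } else {
      nb$weight <- voting_weight(nb$distance, cfg$weight_scheme)
    }
    raw <- vote(nb, object$annotations)
    if (!length(raw)) next
    prop <- propagate_scores(raw, object$dag, cfg$propagation,
                             cfg$unique_descendants)
    conf <- normalize_scores(prop)
    if (length(conf)) preds[[q]] <- conf
  }
  structure(preds, queries = rownames(newdata), class = "prediction_set")
}

#' @export
print.prediction_set <- function(x, ...) {
  nq <- length(attr(x, "queries"))
  cat("Prediction set:", length(x), "of", nq, "queries predicted\n")
  invisible(x)
}

#' Naive baseline: training-frequency scores
#'
#' Scores every GO term by its normalized frequency among the training
#' proteins (fraction of training proteins annotated with it, after
#' closure). Every query receives this same score vector.
#'
#' @param annotations Closed annotation list for the training proteins.
#' @return Named numeric vector of term frequencies in (0, 1].
#' @export
naive_baseline <- function(annotations) {
  if (!length(annotations)) stop("empty training annotation set")
  counts <- table(unlist(annotations, use.names = FALSE))
  stats::setNames(as.numeric(counts) / length(annotations), names(counts))
}

#' @rdname naive_baseline
#' @param query_ids Character vector of query protein ids.
#' @return `naive_predict`: a `prediction_set` assigning the same scores to
#'   every query.
#' @export
naive_predict <- function(query_ids, annotations) {
  scores <- naive_baseline(annotations)
  preds <- stats::setNames(rep(list(scores), length(query_ids)), query_ids)
  structure(preds, queries = query_ids, class = "prediction_set")
}

#' Read BLAST tabular hits (outfmt 6)
#'
#' Twelve tab-separated columns: query, subject, %identity, alignment
#' length, mismatches, gap opens, qstart, qend, sstart, send, evalue,
#' bitscore.
#'
#' @param file Path to the hit table (`#` comments skipped).
#' @return data.frame with columns `query`, `subject`, `evalue` (plus
#'   `pident`, `bitscore`).
#' @export
read_blast_hits <- function(file) {
  lines <- readLines(file, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12L)
  if (length(bad)) stop("malformed BLAST tabular row at line ", idx[bad[1]])
  ev <- as.numeric(vapply(parts, `[`, "", 11L))
  if (anyNA(ev)) {
    stop("non-numeric E-value at line ", idx[which(is.na(ev))[1]])
  }
  data.frame(
    query = vapply(parts, `[`, "", 1L),
    subject = vapply(parts, `[`, "", 2L),
    pident = as.numeric(vapply(parts, `[`, "", 3L)),
    evalue = ev,
    bitscore = as.numeric(vapply(parts, `[`, "", 12L)),
    stringsAsFactors = FALSE
  )
}

#' BLAST baseline: homology-transfer predictions from a hit table
#'
#' Each hit's weight is `-log10(E)` with E clamped below at 1e-180; a GO
#' term's score for a query is the maximum weight over hits whose subject is
#' annotated (after closure) with the term, max-normalized per query to
#' (0, 1]. Queries without hits are absent from the prediction set.
#'
#' @param hits data.frame from [read_blast_hits()] (or with columns `query`,
#'   `subject`, `evalue`).
#' @param annotations Closed annotation list covering the subjects.
#' @return A `prediction_set`.
#' @export
blast_baseline <- function(hits, annotations) {
  missing_subj <- setdiff(unique(hits$subject), names(annotations))
  if (length(missing_subj)) {
    stop("BLAST subject without annotations: ", missing_subj[1])
  }
  hits$w <- -log10(pmax(hits$evalue, 1e-180))
  preds <- list()
  for (q in unique(hits$query)) {
    h <- hits[hits$query == q, , drop = FALSE]
    scores <- numeric()
    for (i in seq_len(nrow(h))) {
      for (t in annotations[[h$subject[i]]]) {
        scores[t] <- max(if (is.na(scores[t])) 0 else scores[t], h$w[i])
      }
    }
    conf <- normalize_scores(scores)
    if (length(conf)) preds[[q]] <- conf
  }
  structure(preds, queries = unique(hits$query), class = "prediction_set")
}

#' Write / read predictions in CAFA submission style
#'
#' One line per (protein, term, score) with the score printed to two
#' decimals in `[0.01, 1.00]`, preceded by AUTHOR / MODEL / KEYWORDS header
#' lines and terminated by END.
#'
#' @param predictions A `prediction_set`.
#' @param path Output path.
#' @param author,model,keywords Header fields.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, author = "goknn",
                              model = 1, keywords = "sequence properties.") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("AUTHOR", author), paste("MODEL", model),
               paste("KEYWORDS", keywords)), con)
  for (q in names(predictions)) {
    s <- predictions[[q]]
    s <- pmin(pmax(round(s, 2), 0.01), 1)
    writeLines(sprintf("%s\t%s\t%.2f", q, names(s), s), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' @rdname write_predictions
#' @param file Path to a CAFA-style prediction file.
#' @return `read_predictions`: a `prediction_set`.
#' @export
read_predictions <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^(AUTHOR|MODEL|KEYWORDS|END)\\b", lines)]
  if (!length(lines)) {
    return(structure(list(), queries = character(), class = "prediction_set"))
  }
  parts <- strsplit(lines, "\\s+")
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed prediction line ", bad[1])
  prot <- vapply(parts, `[`, "", 1L)
  term <- vapply(parts, `[`, "", 2L)
  score <- as.numeric(vapply(parts, `[`, "", 3L))
  preds <- lapply(split(seq_along(prot), factor(prot, levels = unique(prot))),
                  function(i) stats::setNames(score[i], term[i]))
  structure(preds, queries = unique(prot), class = "prediction_set")
}
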