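# Fixtures and independent brute-force oracles. Oracles deliberately share
# no code path with the package implementation: graph reachability goes
# through igraph, everything else through flat loops.

# Seven-term toy ontology: one root, two intermediate terms, four leaves
# (2.3/1.2-style vote weights land on the leaves under GO:0000002).
fig9_dag <- function() {
  go_dag(
    sprintf("GO:%07d", 1:7),
    parents = list(
      character(),              # GO:1 root
      "GO:0000001", "GO:0000001",        # GO:2, GO:3
      "GO:0000002", "GO:0000002",        # GO:4, GO:5
      "GO:0000003", "GO:0000003"         # GO:6, GO:7
    )
  )
}

go_id <- function(i) sprintf("GO:%07d", i)

# Random DAG over n terms: ids are in topological order, each non-first
# term gets 1-2 parents among earlier terms.
random_dag <- function(n, max_parents = 2L) {
  ids <- go_id(seq_len(n))
  parents <- vector("list", n)
  parents[[1]] <- character()
  for (i in seq_len(n)[-1]) {
    np <- sample(seq_len(max_parents), 1L)
    parents[[i]] <- ids[sample(i - 1L, min(np, i - 1L))]
  }
  go_dag(ids, parents = parents)
}

dag_igraph <- function(dag) {
  edges <- data.frame(
    from = rep(names(dag$parents), lengths(dag$parents)),
    to = unlist(dag$parents, use.names = FALSE)
  )
  igraph::graph_from_data_frame(edges, directed = TRUE,
                                vertices = dag$terms$id)
}

# child -> parent reachability via igraph
oracle_ancestors <- function(dag, term, g = dag_igraph(dag)) {
  setdiff(names(igraph::subcomponent(g, term, mode = "out")), term)
}

oracle_close <- function(dag, terms, g = dag_igraph(dag)) {
  closed <- terms
  for (t in terms) closed <- c(closed, oracle_ancestors(dag, t, g))
  sort(setdiff(unique(closed), dag$roots))
}

# full-sort KNN; returns ids in (distance, id) order
oracle_knn <- function(query, train, k) {
  d <- apply(train, 1L, function(r) sqrt(sum((r - query)^2)))
  o <- order(d, rownames(train))
  rownames(train)[o][seq_len(k)]
}

oracle_dynamic <- function(query, train, threshold) {
  d <- apply(train, 1L, function(r) sqrt(sum((r - query)^2)))
  ids <- rownames(train)[d < threshold]
  ids[order(d[d < threshold], ids)]
}

# nested loop over (neighbor, term)
oracle_vote <- function(neighbors, annotations) {
  scores <- list()
  for (i in seq_len(nrow(neighbors))) {
    for (t in annotations[[neighbors$protein_id[i]]]) {
      scores[[t]] <- (if (is.null(scores[[t]])) 0 else scores[[t]]) +
        neighbors$weight[i]
    }
  }
  unlist(scores)
}

# memoized recursion over children (vs the package's iterative Kahn order)
oracle_propagate <- function(scores, dag, mode, g = dag_igraph(dag)) {
  nodes <- unique(c(names(scores),
                    unlist(lapply(names(scores), oracle_ancestors,
                                  dag = dag, g = g))))
  nodes <- setdiff(nodes, dag$roots)
  own <- function(t) if (t %in% names(scores)) scores[[t]] else 0
  memo <- new.env(parent = emptyenv())
  rec <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    kids <- intersect(dag$children[[t]], nodes)
    vals <- if (length(kids)) vapply(kids, rec, 0) else numeric()
    r <- if (mode == "sum") own(t) + sum(vals) else max(c(own(t), vals))
    assign(t, r, envir = memo)
    r
  }
  stats::setNames(vapply(nodes, rec, 0), nodes)
}

# flat-loop protein-centric evaluation over the tau grid
oracle_evaluate <- function(predictions, truth, dag, mode,
                            tau_grid = seq(0, 1, by = 0.01)) {
  g <- dag_igraph(dag)
  closed_truth <- lapply(truth, oracle_close, dag = dag, g = g)
  closed_truth <- closed_truth[lengths(closed_truth) > 0]
  bench <- names(closed_truth)
  predicted <- bench[vapply(bench, function(q) {
    !is.null(predictions[[q]]) && length(predictions[[q]]) > 0
  }, TRUE)]
  n_e <- if (mode == "full") length(bench) else length(predicted)
  best <- 0
  pts <- list()
  for (tau in sort(tau_grid)) {
    prs <- c(); rcs <- c(); m <- 0L; rc_sum <- 0
    for (q in bench) {
      s <- predictions[[q]]
      p <- if (is.null(s)) character() else names(s)[s >= tau]
      p <- if (length(p)) oracle_close(dag, p, g) else character()
      tset <- closed_truth[[q]]
      if (length(p)) {
        m <- m + 1L
        prs <- c(prs, length(intersect(p, tset)) / length(p))
        rc_sum <- rc_sum + length(intersect(p, tset)) / length(tset)
      }
    }
    if (m == 0L) next
    pr <- mean(prs)
    rc <- rc_sum / n_e
    f <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
    pts[[length(pts) + 1L]] <- c(tau = tau, pr = pr, rc = rc, m = m)
    best <- max(best, f)
  }
  list(fmax = best, curve = do.call(rbind, pts),
       coverage = length(predicted) / length(bench))
}

# random prediction/truth toys for evaluation tests
random_benchmark <- function(n_prot, dag, p_predict = 0.8) {
  terms <- setdiff(dag$terms$id, dag$roots)
  ids <- sprintf("T%03d", seq_len(n_prot))
  truth <- lapply(ids, function(i) sample(terms, sample(1:3, 1)))
  names(truth) <- ids
  preds <- list()
  for (i in ids) {
    if (stats::runif(1) < p_predict || i == ids[1]) {  # never all-unpredicted
      ts <- sample(terms, sample(1:4, 1))
      preds[[i]] <- stats::setNames(stats::runif(length(ts)), ts)
    }
  }
  list(truth = truth, predictions = structure(preds, queries = ids,
                                              class = "prediction_set"))
}
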