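# Protein-centric CAFA-style evaluation: per-protein precision/recall,
# threshold curves, Fmax in full or partial mode, coverage, and
# cross-validation fold assignment.

#' Per-protein precision and recall at a threshold
#'
#' The predicted set P(tau) holds the terms with confidence >= tau (the
#' inclusive reading of "above threshold"). Precision is |P & T| / |P| —
#' undefined when P is empty, in which case the protein does not count
#' toward m(tau); recall is |P & T| / |T|. Both sets are assumed already
#' closed under the true-path rule with roots removed.
#'
#' @param scores Named numeric confidence vector (may be NULL/empty).
#' @param truth Non-empty character vector of true terms.
#' @param tau Threshold in `[0, 1]`.
#' @return List with `pr` (NA when P is empty), `rc`, and `predicted`.
#' @export
protein_pr <- function(scores, truth, tau) {
  if (!length(truth)) stop("empty truth set; protein should have been skipped")
  p <- if (length(scores)) names(scores)[scores >= tau] else character()
  if (!length(p)) {
    return(list(pr = NA_real_, rc = 0, predicted = FALSE))
  }
  hit <- length(intersect(p, truth))
  list(pr = hit / length(p), rc = hit / length(truth), predicted = TRUE)
}

#' Aggregate per-protein precision/recall into one curve point
#'
#' Precision averages over the m(tau) proteins with a non-empty prediction
#' at tau; recall averages over `n_e` — all benchmark proteins in full mode,
#' or the m(0) proteins the method attempted in partial mode.
#'
#' @param pr_i Numeric vector, NA where the protein had no prediction.
#' @param rc_i Numeric vector of per-protein recalls (same order).
#' @param n_e Evaluation denominator for recall.
#' @param tau Threshold the point belongs to.
#' @return List `(tau, pr, rc, m_tau)`; `pr` is NA when m(tau) = 0.
#' @export
aggregate_pr <- function(pr_i, rc_i, n_e, tau) {
  stopifnot(n_e >= 1)
  m_tau <- sum(!is.na(pr_i))
  pr <- if (m_tau > 0) sum(pr_i, na.rm = TRUE) / m_tau else NA_real_
  rc <- sum(rc_i) / n_e
  list(tau = tau, pr = pr, rc = rc, m_tau = m_tau)
}

# Hierarchical closure of a confidence vector: each term (and each ancestor
# of a scored term) gets the maximum confidence over itself and its
# descendants, so that {score >= tau} is ancestor-closed at every tau.
# Identical to Max propagation over the scored sub-DAG.
.close_scores <- function(scores, dag) {
  if (!length(scores)) return(scores)
  propagate_scores(scores, dag, mode = "max")
}

#' Evaluate predictions against a gold standard
#'
#' Both predictions and truth are closed under the true-path rule (roots
#' excluded) before counting. For every threshold on `tau_grid`, per-protein
#' precision/recall (Eqs. of the protein-centric CAFA protocol) are
#' aggregated by [aggregate_pr()]; Fmax is the maximum harmonic mean of the
#' aggregated precision and recall over the grid. Coverage is the fraction
#' of benchmark proteins with at least one prediction, regardless of mode.
#'
#' @param predictions A `prediction_set` (or plain named list of named
#'   confidence vectors).
#' @param truth Annotation list (protein id -> GO ids); closed internally.
#'   Proteins whose closed truth is empty are dropped with a warning.
#' @param dag A `go_dag`.
#' @param mode `"full"` (recall denominator = all benchmark proteins) or
#'   `"partial"` (denominator = proteins with any prediction, m(0)).
#' @param tau_grid Thresholds; default `seq(0, 1, by = 0.01)`.
#' @return Object of class `go_eval`: `curve` (data.frame tau/pr/rc/m_tau),
#'   `fmax`, `tau_at_fmax`, `coverage`, `mode`, `n_e`.
#' @export
evaluate_predictions <- function(predictions, truth, dag,
                                 mode = c("full", "partial"),
                                 tau_grid = seq(0, 1, by = 0.01)) {
  mode <- match.arg(mode)
  stopifnot(all(tau_grid >= 0 & tau_grid <= 1))
  closed_truth <- close_annotations(dag, truth)
  empty <- lengths(closed_truth) == 0L
  if (any(empty)) {
    warning(sum(empty), " protein(s) with empty truth after closure skipped")
    closed_truth <- closed_truth[!empty]
  }
  bench <- names(closed_truth)
  if (!length(bench)) stop("no benchmark proteins with non-empty truth")
  if (!length(intersect(names(predictions), bench))) {
    if (length(predictions)) {
      stop("prediction and truth protein sets are disjoint")
    }
  }
  closed_pred <- lapply(bench, function(q) {
    s <- predictions[[q]]
    if (is.null(s) || !length(s)) NULL else .close_scores(s, dag)
  })
  names(closed_pred) <- bench

  m0 <- sum(!vapply(closed_pred, is.null, TRUE))
  n_full <- length(bench)
  n_e <- if (mode == "full") n_full else m0
  if (n_e == 0L) stop("no predictions overlap the benchmark")

  pts <- lapply(sort(tau_grid), function(tau) {
    per <- lapply(bench, function(q) {
      protein_pr(closed_pred[[q]], closed_truth[[q]], tau)
    })
    aggregate_pr(vapply(per, `[[`, 0, "pr"),
                 vapply(per, `[[`, 0, "rc"), n_e, tau)
  })
  curve <- data.frame(
    tau = vapply(pts, `[[`, 0, "tau"),
    pr = vapply(pts, `[[`, 0, "pr"),
    rc = vapply(pts, `[[`, 0, "rc"),
    m_tau = vapply(pts, `[[`, 0L, "m_tau")
  )
  curve <- curve[curve$m_tau > 0L, , drop = FALSE]  # pr undefined otherwise
  f <- with(curve, ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0))
  fmax <- if (nrow(curve)) max(f) else 0
  structure(
    list(curve = curve, fmax = fmax,
         tau_at_fmax = if (nrow(curve)) curve$tau[which.max(f)] else NA_real_,
         coverage = m0 / n_full, mode = mode, n_e = n_e),
    class = "go_eval"
  )
}

#' @export
print.go_eval <- function(x, ...) {
  cat(sprintf("Fmax %.3f at tau %.2f (%s mode, n_e = %d, coverage %.1f%%)\n",
              x$fmax, x$tau_at_fmax, x$mode, x$n_e, 100 * x$coverage))
  invisible(x)
}

#' Save an evaluation result (JSON + PR-curve TSV)
#'
#' Writes `<path>` as JSON (fmax, tau, coverage, mode) and `<path>.curve.tsv`
#' with columns tau, pr, rc, m_tau.
#'
#' @param result A `go_eval`.
#' @param path Output path for the JSON summary.
#' @return `path`, invisibly.
#' @export
write_eval <- function(result, path) {
  jsonlite::write_json(
    list(fmax = result$fmax, tau_at_fmax = result$tau_at_fmax,
         coverage = result$coverage, mode = result$mode, n_e = result$n_e),
    path, auto_unbox = TRUE, digits = NA
  )
  utils::write.table(result$curve, paste0(path, ".curve.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Coverage per configuration
#'
#' Counts, per named prediction set, the proteins with at least one
#' prediction and the percentage of the dataset covered.
#'
#' @param prediction_sets Named list of `prediction_set` objects.
#' @param dataset_ids Character vector of all benchmark protein ids.
#' @return data.frame with columns `config`, `n_pred`, `pct`.
#' @export
coverage_table <- function(prediction_sets, dataset_ids) {
  n <- length(dataset_ids)
  rows <- lapply(names(prediction_sets), function(cfg) {
    np <- length(intersect(names(prediction_sets[[cfg]]), dataset_ids))
    data.frame(config = cfg, n_pred = np,
               pct = if (n > 0) 100 * np / n else 0)
  })
  do.call(rbind, rows)
}

#' Assign proteins to cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment, so fold sizes differ
#' by at most one. When a redundancy cluster table is supplied, whole
#' clusters go to a single fold (assigned greedily, largest cluster first,
#' to the currently smallest fold) so near-identical sequences never span
#' the train/validation boundary.
#'
#' @param protein_ids Character vector (>= n_folds proteins).
#' @param seed Integer seed; the same seed always yields the same split.
#' @param clusters Optional named character vector protein -> cluster id.
#' @param n_folds Number of folds (default 5).
#' @return Named integer vector protein id -> fold in `1..n_folds`.
#' @export
five_fold_split <- function(protein_ids, seed, clusters = NULL, n_folds = 5L) {
  if (length(protein_ids) < n_folds) {
    stop("need at least ", n_folds, " proteins for ", n_folds, "-fold CV")
  }
  ids <- sort(unique(protein_ids))
  .with_seed(seed, {
    if (is.null(clusters)) {
      shuffled <- sample(ids)
      folds <- stats::setNames(rep_len(seq_len(n_folds), length(ids)),
                               shuffled)
    } else {
      cl <- clusters[ids]
      cl[is.na(cl)] <- paste0(".singleton.", ids[is.na(cl)])
      groups <- split(ids, cl)
      groups <- groups[sample(length(groups))]
      groups <- groups[order(-lengths(groups))]
      sizes <- integer(n_folds)
      folds <- stats::setNames(integer(length(ids)), character(length(ids)))
      pos <- 1L
      for (g in groups) {
        f <- which.min(sizes)
        sizes[f] <- sizes[f] + length(g)
        folds[pos:(pos + length(g) - 1L)] <- f
        names(folds)[pos:(pos + length(g) - 1L)] <- g
        pos <- pos + length(g)
      }
    }
    folds[ids]
  })
}

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
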