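# GO directed acyclic graph: parsing, validation, ancestor queries and
# true-path closure of annotation sets.

#' Construct a validated GO DAG
#'
#' Builds a `go_dag` object from per-term fields. Validation enforces the
#' structural invariants every downstream step relies on: all parent ids
#' resolve, no term is its own parent, edges never cross namespaces, and the
#' graph is acyclic. Obsolete terms are retained (so stale annotations can be
#' recognized and warned about) but carry no edges and are never roots.
#'
#' @param id Character vector of GO accessions (`GO:` + 7 digits).
#' @param name Character vector of term names.
#' @param namespace Character vector; one of `BPO`, `CCO`, `MFO` or the OBO
#'   long forms (`biological_process`, ...).
#' @param parents List of character vectors of parent accessions (both
#'   `is_a` and `relationship: part_of` edges).
#' @param obsolete Logical vector.
#' @return An object of class `go_dag` with elements `terms` (data.frame of
#'   id, name, namespace, obsolete), `parents` and `children` (named lists of
#'   character vectors), and `roots` (character vector of non-obsolete terms
#'   with no parents).
#' @export
go_dag <- function(id, name = id, namespace = "BPO", parents = NULL,
                   obsolete = FALSE) {
  n <- length(id)
  if (n == 0L) stop("a GO DAG needs at least one term")
  if (anyDuplicated(id)) stop("duplicate term id: ", id[duplicated(id)][1])
  bad <- !grepl("^GO:[0-9]{7}$", id)
  if (any(bad)) stop("malformed GO accession: ", id[bad][1])
  name <- rep_len(name, n)
  namespace <- rep_len(namespace, n)
  obsolete <- rep_len(obsolete, n)
  ns <- unname(GO_NAMESPACE_MAP[namespace])
  if (anyNA(ns)) stop("unknown namespace: ", namespace[is.na(ns)][1])
  if (is.null(parents)) parents <- rep(list(character()), n)
  parents <- lapply(parents, function(p) unique(as.character(p)))
  names(parents) <- id

  for (i in seq_len(n)) {
    p <- parents[[i]]
    if (id[i] %in% p) stop("term ", id[i], " lists itself as a parent")
    missing <- setdiff(p, id)
    if (length(missing)) {
      stop("dangling parent id ", missing[1], " referenced by ", id[i])
    }
    pns <- ns[match(p, id)]
    if (any(pns != ns[i])) {
      stop("cross-namespace edge: ", id[i], " (", ns[i], ") -> ",
           p[pns != ns[i]][1])
    }
  }
  # obsolete terms keep no edges
  parents[obsolete] <- rep(list(character()), sum(obsolete))
  live <- id[!obsolete]
  parents[live] <- lapply(parents[live], function(p) setdiff(p, id[obsolete]))

  .check_acyclic(id, parents)

  children <- rep(list(character()), n)
  names(children) <- id
  for (t in id) {
    for (p in parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  roots <- id[!obsolete & vapply(parents, length, 1L)[id] == 0L]

  structure(
    list(
      terms = data.frame(id = id, name = name, namespace = ns,
                         obsolete = obsolete, stringsAsFactors = FALSE),
      parents = parents,
      children = children,
      roots = roots
    ),
    class = "go_dag"
  )
}

# Kahn's algorithm; stops naming one edge on a cycle.
.check_acyclic <- function(id, parents) {
  indeg <- vapply(parents, length, 1L)[id]
  names(indeg) <- id
  queue <- id[indeg == 0L]
  seen <- 0L
  children <- split(
    rep(names(parents), lengths(parents)),
    unlist(parents, use.names = FALSE)
  )
  while (length(queue)) {
    t <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(id)) {
    rem <- names(indeg)[indeg > 0L]
    t <- rem[1]
    p <- intersect(parents[[t]], rem)[1]
    stop("cycle detected in ontology involving edge ", t, " -> ", p)
  }
  invisible(TRUE)
}

#' @export
print.go_dag <- function(x, ...) {
  cat("GO DAG:", nrow(x$terms), "terms (",
      sum(x$terms$obsolete), "obsolete ),",
      length(x$roots), "root(s):", paste(x$roots, collapse = " "), "\n")
  invisible(x)
}

#' Parse an OBO 1.2 ontology file (subset)
#'
#' Reads `[Term]` stanzas honoring the tags `id`, `name`, `namespace`,
#' `is_a`, `relationship: part_of` and `is_obsolete`; everything else is
#' ignored. Both `is_a` and `part_of` become parent edges, following the GO
#' consortium's propagation convention. The result is validated by
#' [go_dag()] (acyclicity, no dangling parents, no cross-namespace edges).
#'
#' @param file Path to an OBO file, or a character vector of OBO lines, or a
#'   single string containing newlines.
#' @return A `go_dag`.
#' @export
parse_obo <- function(file) {
  lines <- .as_lines(file)
  lines <- sub("\\s*!.*$", "", lines)  # strip trailing comments
  lines <- trimws(lines)

  stanza_starts <- which(lines == "[Term]")
  if (!length(stanza_starts)) stop("no [Term] stanzas found")
  other_starts <- grep("^\\[", lines)
  bounds <- c(other_starts, length(lines) + 1L)

  id <- character(); nm <- character(); ns <- character()
  par <- list(); obs <- logical()
  for (s in stanza_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[s:e][-1]
    block <- block[nzchar(block)]
    tag_val <- regmatches(block, regexec("^([a-z_]+):\\s*(.*)$", block))
    tid <- tname <- tns <- NA_character_
    tpar <- character(); tobs <- FALSE
    for (tv in tag_val) {
      if (length(tv) < 3) next
      tag <- tv[2]; val <- tv[3]
      if (tag == "id") tid <- val
      else if (tag == "name") tname <- val
      else if (tag == "namespace") tns <- val
      else if (tag == "is_a") tpar <- c(tpar, sub("\\s.*$", "", val))
      else if (tag == "relationship" && grepl("^part_of\\s", val)) {
        tpar <- c(tpar, sub("^part_of\\s+", "", val))
      }
      else if (tag == "is_obsolete") tobs <- identical(val, "true")
    }
    if (is.na(tid)) stop("[Term] stanza without id near line ", s)
    id <- c(id, tid)
    nm <- c(nm, if (is.na(tname)) tid else tname)
    ns <- c(ns, if (is.na(tns)) "BPO" else tns)
    par <- c(par, list(unique(tpar)))
    obs <- c(obs, tobs)
  }
  go_dag(id, nm, ns, par, obs)
}

.as_lines <- function(file) {
  if (length(file) == 1L && !grepl("\n", file, fixed = TRUE) &&
      file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
}

#' Write a GO DAG in the OBO subset understood by [parse_obo()]
#'
#' @param dag A `go_dag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  long_ns <- c(BPO = "biological_process", CCO = "cellular_component",
               MFO = "molecular_function")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    t <- dag$terms[i, ]
    writeLines("[Term]", con)
    writeLines(paste0("id: ", t$id), con)
    writeLines(paste0("name: ", t$name), con)
    writeLines(paste0("namespace: ", long_ns[[t$namespace]]), con)
    for (p in dag$parents[[t$id]]) {
      writeLines(paste0("is_a: ", p), con)
    }
    if (t$obsolete) writeLines("is_obsolete: true", con)
    writeLines("", con)
  }
  invisible(path)
}

#' Transitive ancestors of a term
#'
#' All terms reachable from `term` by repeatedly following parent edges,
#' excluding `term` itself. Roots have no ancestors.
#'
#' @param dag A `go_dag`.
#' @param term A GO accession present in `dag`.
#' @return Character vector of ancestor accessions (unsorted, no duplicates).
#' @export
ancestors <- function(dag, term) {
  .reach(dag, term, "parents")
}

#' Transitive descendants of a term
#'
#' @inheritParams ancestors
#' @return Character vector of descendant accessions.
#' @export
descendants <- function(dag, term) {
  .reach(dag, term, "children")
}

.reach <- function(dag, term, dir) {
  if (!term %in% dag$terms$id) stop("unknown GO term: ", term)
  seen <- character()
  frontier <- dag[[dir]][[term]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(dag[[dir]][new], use.names = FALSE))
  }
  seen
}

#' Close annotation sets under the true-path rule
#'
#' Replaces each protein's term set by its union with all ancestors, then
#' removes namespace roots (predicting or scoring a root is vacuous, so
#' roots never appear in closed sets, predictions, or evaluation).
#' Annotations to obsolete terms are dropped with a warning. The operation
#' is idempotent.
#'
#' @param dag A `go_dag`.
#' @param annotations Named list: protein id -> character vector of GO ids.
#' @return Named list of the same shape with closed term sets.
#' @export
close_annotations <- function(dag, annotations) {
  stopifnot(inherits(dag, "go_dag"), is.list(annotations))
  obs <- dag$terms$id[dag$terms$obsolete]
  anc_cache <- new.env(parent = emptyenv())
  out <- lapply(annotations, function(terms) {
    terms <- unique(as.character(terms))
    unknown <- setdiff(terms, dag$terms$id)
    if (length(unknown)) stop("annotation to unknown GO term: ", unknown[1])
    dead <- intersect(terms, obs)
    if (length(dead)) {
      warning("dropping annotation(s) to obsolete term(s): ",
              paste(dead, collapse = ", "))
      terms <- setdiff(terms, dead)
    }
    closed <- terms
    for (t in terms) {
      a <- anc_cache[[t]]
      if (is.null(a)) {
        a <- ancestors(dag, t)
        assign(t, a, envir = anc_cache)
      }
      closed <- c(closed, a)
    }
    sort(setdiff(unique(closed), dag$roots))
  })
  names(out) <- names(annotations)
  out
}

#' Read a protein-to-GO annotation table
#'
#' Two tab-separated columns (`protein_id`, `go_id`); lines starting with
#' `#` are skipped.
#'
#' @param file Path to the TSV file.
#' @return Named list: protein id -> character vector of GO ids.
#' @export
read_annotations <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) stop("malformed annotation line ", bad[1])
  prot <- vapply(parts, `[`, "", 1L)
  term <- vapply(parts, `[`, "", 2L)
  split(term, factor(prot, levels = unique(prot)))
}

#' Write an annotation table readable by [read_annotations()]
#'
#' @param annotations Named list: protein id -> GO ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  prot <- rep(names(annotations), lengths(annotations))
  term <- unlist(annotations, use.names = FALSE)
  writeLines(c("# protein_id\tgo_id", paste(prot, term, sep = "\t")), path)
  invisible(path)
}
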