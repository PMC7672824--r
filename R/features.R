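# TFPSSM features: gapped-dipeptide term frequencies computed from a
# protein's position-specific scoring matrix.

#' Construct a PSSM object
#'
#' @param protein_id Protein identifier.
#' @param sequence Amino-acid sequence (one-letter codes, length n).
#' @param scores n x 20 numeric matrix of log-odds scores; columns must be
#'   in PSI-BLAST print order (`AA_PSIBLAST`). Column names are set
#'   accordingly.
#' @return An object of class `pssm`.
#' @export
pssm <- function(protein_id, sequence, scores) {
  sequence <- toupper(sequence)
  scores <- as.matrix(scores)
  if (nrow(scores) != nchar(sequence)) {
    stop("PSSM row count (", nrow(scores), ") != sequence length (",
         nchar(sequence), ") for ", protein_id)
  }
  if (ncol(scores) != 20L) stop("PSSM must have 20 score columns")
  colnames(scores) <- AA_PSIBLAST
  rownames(scores) <- NULL
  structure(list(protein_id = protein_id, sequence = sequence,
                 scores = scores),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM", x$protein_id, "-", nchar(x$sequence), "residues\n")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the `-out_ascii_pssm` dialect: header lines, then one row per
#' residue starting with the position number and the residue letter followed
#' by at least 20 numeric columns. The first 20 numeric columns (the
#' log-odds block) are kept; weighted-percentage columns and trailing
#' statistics lines are ignored.
#'
#' @param file Path to the ASCII PSSM file (or character vector of lines).
#' @param protein_id Identifier to attach; defaults to the file base name.
#' @return A `pssm`.
#' @export
parse_ascii_pssm <- function(file, protein_id = NULL) {
  lines <- .as_lines(file)
  if (is.null(protein_id)) {
    protein_id <- if (length(file) == 1L && file.exists(file)) {
      sub("\\.[^.]*$", "", basename(file))
    } else "pssm"
  }
  row_re <- "^\\s*([0-9]+)\\s+([A-Za-z])\\s+(-?[0-9])"
  is_row <- grepl(row_re, lines)
  if (!any(is_row)) stop("no PSSM data rows found")
  rows <- which(is_row)
  pos <- integer(length(rows))
  letters_ <- character(length(rows))
  scores <- matrix(0, nrow = length(rows), ncol = 20L)
  for (j in seq_along(rows)) {
    i <- rows[j]
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    pos[j] <- as.integer(toks[1])
    letters_[j] <- toks[2]
    vals <- suppressWarnings(as.numeric(toks[-(1:2)]))
    if (length(vals) < 20L || anyNA(vals[1:20])) {
      stop("non-numeric or missing score cell on line ", i)
    }
    scores[j, ] <- vals[1:20]
  }
  if (!identical(pos, seq_along(pos))) {
    stop("PSSM positions are not consecutive from 1; row/sequence mismatch")
  }
  pssm(protein_id, paste(letters_, collapse = ""), scores)
}

#' Write a PSSM in PSI-BLAST-style ASCII
#'
#' Emits the minimal dialect [parse_ascii_pssm()] reads back: two header
#' lines, a column-label line, one row per residue. Integer scores
#' round-trip exactly.
#'
#' @param p A `pssm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(p, path) {
  stopifnot(inherits(p, "pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "",
    "Last position-specific scoring matrix computed",
    paste0("          ", paste(sprintf("%5s", AA_PSIBLAST), collapse = ""))
  ), con)
  seq_chars <- strsplit(p$sequence, "")[[1]]
  for (i in seq_len(nrow(p$scores))) {
    writeLines(paste0(
      sprintf("%5d %s ", i, seq_chars[i]),
      paste(sprintf("%6s", as.character(p$scores[i, ])), collapse = "")
    ), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Used for proteins that lack a PSSM; such proteins get a sequence-only
#' (one-hot) profile via [one_hot_pssm()].
#'
#' @param file Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(file) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readAAStringSet(file)
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
    return(seqs)
  }
  lines <- readLines(file, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", file)
  ids <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- mapply(function(s, e) {
    paste(lines[seq(s, e)], collapse = "")
  }, hdr + 1L, ends)
  names(seqs) <- ids
  toupper(seqs)
}

#' One-hot PSSM from a bare sequence
#'
#' Builds a surrogate profile for proteins without evolutionary information:
#' a large positive log-odds score at the observed residue and a large
#' negative score elsewhere, so that after the logistic transform the
#' per-position weights are effectively an indicator of the sequence and the
#' TFPSSM reduces to plain gapped-dipeptide counts. Nonstandard residues
#' (B, Z, X, U, O, ...) get all-negative rows: they keep their position
#' (preserving gap distances) but contribute no weight.
#'
#' @param protein_id Identifier.
#' @param sequence Amino-acid sequence.
#' @param hi,lo Scores for the observed / other residues.
#' @return A `pssm`.
#' @export
one_hot_pssm <- function(protein_id, sequence, hi = 15, lo = -15) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  scores <- matrix(lo, nrow = length(chars), ncol = 20L)
  hit <- match(chars, AA_PSIBLAST)
  for (i in seq_along(chars)) {
    if (!is.na(hit[i])) scores[i, hit[i]] <- hi
  }
  pssm(protein_id, sequence, scores)
}

#' Enumerate gapped-dipeptide occurrences in a sequence
#'
#' A gapped dipeptide XdY is a pair of residues of types X and Y separated
#' by exactly d positions. Every occurrence (S[i], d, S[i+d+1]) with
#' 0 <= d <= l and i+d+1 <= n is emitted, labelled like `"M0P"`. Pairs
#' involving nonstandard residues are skipped.
#'
#' @param sequence Amino-acid sequence.
#' @param l Maximum gap length (>= 0).
#' @return Character vector with one element per occurrence (a multiset).
#' @export
enumerate_patterns <- function(sequence, l) {
  stopifnot(l >= 0)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  out <- character()
  for (d in 0:l) {
    if (n < d + 2L) break
    x <- chars[seq_len(n - d - 1L)]
    y <- chars[seq(d + 2L, n)]
    ok <- x %in% AA_CANONICAL & y %in% AA_CANONICAL
    out <- c(out, paste0(x[ok], d, y[ok]))
  }
  out
}

#' Position of a gapped dipeptide in the TFPSSM vector layout
#'
#' The feature vector is indexed by (X, d, Y) as
#' `index = aa(X) * (l+1) * 20 + d * 20 + aa(Y)` with amino acids ordered
#' `ACDEFGHIKLMNPQRSTVWY`. The index is zero-based: `(A, 0, A)` maps to 0
#' and `(Y, l, Y)` to `20*(l+1)*20 - 1`.
#'
#' @param x,y Amino-acid letters.
#' @param d Gap length, `0 <= d <= l`.
#' @param l Maximum gap of the layout.
#' @return Zero-based integer index.
#' @export
pattern_index <- function(x, d, y, l) {
  ix <- match(x, AA_CANONICAL)
  iy <- match(y, AA_CANONICAL)
  if (anyNA(ix) || anyNA(iy)) {
    stop("nonstandard amino-acid letter: ", paste(c(x, y)[is.na(c(ix, iy))],
                                                  collapse = " "))
  }
  if (any(d < 0) || any(d > l)) stop("gap d must satisfy 0 <= d <= ", l)
  (ix - 1L) * (l + 1L) * 20L + d * 20L + (iy - 1L)
}

#' Logistic transform of PSSM log-odds to per-position weights
#'
#' Maps each score s to `1 / (1 + exp(-s))`, giving a residue weight in
#' (0, 1) per position; saturates without overflow for extreme scores.
#'
#' @param p A `pssm`.
#' @return n x 20 matrix with the same column order as `p$scores`.
#' @export
pssm_to_prob <- function(p) {
  stopifnot(inherits(p, "pssm"))
  stats::plogis(p$scores)
}

#' Compute the TFPSSM gapped-dipeptide feature vector
#'
#' The raw value of pattern (X, d, Y) is the sum over sequence positions i
#' (with i + d + 1 <= n) of `w(i, X) * w(i + d + 1, Y)`, where `w` is the
#' logistic transform of the PSSM log-odds ([pssm_to_prob()]). The vector is
#' then normalized to unit sum (a term-frequency), giving a
#' `20 * (l + 1) * 20`-dimensional representation (5600 for the default
#' l = 13).
#'
#' @param p A `pssm`.
#' @param l Maximum gap (default 13).
#' @param normalize Divide by the vector sum (default TRUE).
#' @return Numeric vector of length `20 * (l + 1) * 20`, named by pattern
#'   label (e.g. `"A0A"`), with attribute `protein_id`.
#' @export
compute_tfpssm <- function(p, l = 13, normalize = TRUE) {
  stopifnot(inherits(p, "pssm"), l >= 0)
  n <- nrow(p$scores)
  dim_out <- 20L * (l + 1L) * 20L
  v <- numeric(dim_out)
  if (n < 2L) {
    warning("sequence of length ", n, " has no residue pairs; zero vector")
  } else {
    w <- stats::plogis(p$scores)[, AA_CANONICAL, drop = FALSE]
    for (d in 0:min(l, n - 2L)) {
      m <- crossprod(w[seq_len(n - d - 1L), , drop = FALSE],
                     w[seq(d + 2L, n), , drop = FALSE])  # m[X, Y]
      idx <- rep((0:19) * (l + 1L) * 20L, each = 20L) + d * 20L + 0:19
      v[idx + 1L] <- as.vector(t(m))
    }
    if (normalize) {
      s <- sum(v)
      if (s > 0) v <- v / s
    }
  }
  names(v) <- paste0(
    rep(AA_CANONICAL, each = (l + 1L) * 20L),
    rep(rep(0:l, each = 20L), times = 20L),
    rep(AA_CANONICAL, times = 20L * (l + 1L))
  )
  attr(v, "protein_id") <- p$protein_id
  v
}

#' TFPSSM feature matrix for a set of proteins
#'
#' @param pssms List of `pssm` objects.
#' @param l Maximum gap.
#' @param normalize Passed to [compute_tfpssm()].
#' @return Numeric matrix, one row per protein (rownames = protein ids).
#' @export
tfpssm_matrix <- function(pssms, l = 13, normalize = TRUE) {
  rows <- lapply(pssms, compute_tfpssm, l = l, normalize = normalize)
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(pssms, function(p) p$protein_id, "")
  m
}

#' Persist / load a feature matrix
#'
#' Written as a TSV (`protein_id` + dense vector) plus a JSON sidecar
#' (`<path>.json`) recording the maximum gap `l` and whether rows were
#' unit-sum normalized.
#'
#' @param x Feature matrix with protein ids as rownames.
#' @param path Output TSV path.
#' @param l,normalized Metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_features <- function(x, path, l, normalized = TRUE) {
  df <- data.frame(protein_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(l = l, normalized = normalized, n_features = ncol(x)),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_features
#' @return `read_features`: a list with `matrix`, `l`, `normalized`.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(matrix = m, l = meta$l, normalized = meta$normalized)
}
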