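# PCA reduction of TFPSSM vectors and the distance metric used for
# neighbor search.

#' Fit PCA on training feature vectors
#'
#' Principal axes are computed by singular value decomposition of the
#' mean-centered training matrix (via [stats::prcomp()]). The number of
#' retained components is the smallest count whose cumulative
#' explained-variance ratio reaches `target_ratio`. With `whiten = TRUE`
#' (the default) projected coordinates are scaled so each retained component
#' has unit variance on the training data. For reproducible serialization,
#' each component's entry of largest magnitude is made positive (the SVD
#' sign is otherwise arbitrary).
#'
#' Test data must never influence the fit: fit on training rows only and
#' apply [pca_transform()] to everything else.
#'
#' @param x Numeric training matrix (rows = proteins, >= 2 rows).
#' @param target_ratio Cumulative explained-variance ratio to reach, in
#'   (0, 1]. Default 0.96.
#' @param whiten Scale projected components to unit training variance.
#' @return An object of class `tfpssm_pca`: `center`, `rotation` (columns =
#'   retained axes), `sdev`, `explained_ratio` (per retained component),
#'   `n_components`, `target_ratio`, `whiten`.
#' @export
fit_pca <- function(x, target_ratio = 0.96, whiten = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("PCA needs at least 2 training rows")
  if (!is.numeric(target_ratio) || target_ratio <= 0 || target_ratio > 1) {
    stop("target_ratio must be in (0, 1]")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_ <- pr$sdev^2
  tot <- sum(var_)
  if (tot <= 0) stop("training data has zero variance")
  ratio <- var_ / tot
  ncomp <- which(cumsum(ratio) >= target_ratio - 1e-12)[1]
  rot <- pr$rotation[, seq_len(ncomp), drop = FALSE]
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  structure(
    list(center = pr$center, rotation = rot,
         sdev = pr$sdev[seq_len(ncomp)],
         explained_ratio = ratio[seq_len(ncomp)],
         n_components = ncomp, target_ratio = target_ratio,
         whiten = whiten),
    class = "tfpssm_pca"
  )
}

#' @export
print.tfpssm_pca <- function(x, ...) {
  cat("PCA model:", x$n_components, "components, cumulative ratio",
      sprintf("%.4f", sum(x$explained_ratio)),
      if (x$whiten) "(whitened)" else "", "\n")
  invisible(x)
}

#' Project feature vectors into the fitted PCA space
#'
#' Coordinates are `(v - center) %*% rotation`, divided per component by the
#' training standard deviation when the model whitens.
#'
#' @param model A `tfpssm_pca`.
#' @param x Numeric vector or matrix (rows = proteins) of the model's input
#'   dimension.
#' @return Matrix of projected coordinates (rows = proteins).
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "tfpssm_pca"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(attr(x, "protein_id")))
  if (ncol(x) != length(model$center)) {
    stop("input dimension ", ncol(x), " does not match model dimension ",
         length(model$center))
  }
  z <- sweep(as.matrix(x), 2L, model$center) %*% model$rotation
  if (model$whiten) {
    z <- sweep(z, 2L, pmax(model$sdev, 1e-12), "/")
  }
  z
}

#' @export
predict.tfpssm_pca <- function(object, newdata, ...) {
  pca_transform(object, newdata)
}

#' Euclidean distance between reduced vectors
#'
#' The distance between two proteins is the L2 norm of the difference of
#' their PCA-projected coordinates.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("length mismatch: ", length(a), " vs ", length(b))
  }
  sqrt(sum((a - b)^2))
}

#' Keep one representative per redundancy cluster
#'
#' Sequence-redundancy reduction (e.g. clustering at 50% identity) is done
#' upstream; this honors a precomputed cluster table by keeping the
#' lexicographically first protein of each cluster. Proteins absent from the
#' table are kept.
#'
#' @param ids Character vector of protein ids.
#' @param clusters Named character vector or two-column data.frame
#'   (`protein_id`, `cluster_id`) mapping protein to cluster.
#' @return Character subset of `ids`.
#' @export
select_cluster_representatives <- function(ids, clusters) {
  if (is.data.frame(clusters)) {
    clusters <- stats::setNames(as.character(clusters[[2]]),
                                as.character(clusters[[1]]))
  }
  cl <- clusters[ids]
  keep <- is.na(cl)
  for (c_ in unique(cl[!is.na(cl)])) {
    members <- sort(ids[!is.na(cl) & cl == c_])
    keep[ids == members[1]] <- TRUE
  }
  ids[keep]
}

#' Read a cluster membership table (`protein_id TAB cluster_id`)
#'
#' @param file Path to TSV; `#` comment lines skipped.
#' @return Named character vector protein -> cluster.
#' @export
read_clusters <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
}

#' Persist / load a PCA model as JSON
#'
#' @param model A `tfpssm_pca`.
#' @param path Output path.
#' @return `path` / the reloaded `tfpssm_pca`.
#' @export
save_pca <- function(model, path) {
  jsonlite::write_json(
    list(center = model$center, rotation = model$rotation,
         sdev = model$sdev, explained_ratio = model$explained_ratio,
         n_components = model$n_components,
         target_ratio = model$target_ratio, whiten = model$whiten),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_pca
#' @export
load_pca <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(center = as.numeric(j$center),
         rotation = matrix(as.numeric(as.matrix(j$rotation)),
                           ncol = j$n_components,
                           dimnames = list(NULL,
                                           paste0("PC", seq_len(j$n_components)))),
         sdev = as.numeric(j$sdev),
         explained_ratio = as.numeric(j$explained_ratio),
         n_components = as.integer(j$n_components),
         target_ratio = j$target_ratio, whiten = j$whiten),
    class = "tfpssm_pca"
  )
}
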