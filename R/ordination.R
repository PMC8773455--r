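#' Build a population x macro-haplogroup frequency matrix
#'
#' Rows are populations with at least `min_n` classified samples (smaller
#' groups are dropped with a warning, mirroring the <30 exclusion rule);
#' columns are the macro labels of `macro_table` (all of them, so absent
#' macros appear as structural zeros); cells are relative frequencies and
#' every row sums to 1.
#'
#' @param classifications data frame from [classify_all()] (needs columns
#'   `population`, `macro`).
#' @param macro_table a [load_macro_table()] table (fixes column order).
#' @param min_n minimum population size (default 30).
#' @return numeric matrix of relative frequencies.
#' @export
build_frequency_matrix <- function(classifications, macro_table = load_macro_table(),
                                   min_n = 30L) {
  stopifnot(all(c("population", "macro") %in% names(classifications)))
  macros <- unique(macro_table$macro)
  sizes <- table(classifications$population)
  keep <- names(sizes)[sizes >= min_n]
  dropped <- setdiff(names(sizes), keep)
  if (length(dropped)) {
    warning("dropping population(s) below n=", min_n, ": ",
            paste(sprintf("%s (n=%d)", dropped, sizes[dropped]), collapse = ", "))
  }
  if (length(keep) == 0L) stop("no population reaches n >= ", min_n)
  keep <- sort(keep)
  freq <- base::matrix(0, length(keep), length(macros),
                       dimnames = list(keep, macros))
  sub <- classifications[classifications$population %in% keep, ]
  tab <- table(sub$population, factor(sub$macro, levels = macros))
  freq[rownames(tab), ] <- tab / rowSums(tab)
  freq
}

# deterministic axis signs: make the largest-magnitude loading (PCA) or
# coordinate (MDS) positive on every axis
fix_axis_signs <- function(scores, loadings = NULL) {
  anchor <- if (is.null(loadings)) scores else loadings
  flip <- vapply(seq_len(ncol(anchor)), function(j) {
    v <- anchor[, j]
    sign(v[which.max(abs(v))]) < 0
  }, logical(1))
  scores[, flip] <- -scores[, flip, drop = FALSE]
  if (!is.null(loadings)) loadings[, flip] <- -loadings[, flip, drop = FALSE]
  list(scores = scores, loadings = loadings)
}

#' PCA of a frequency matrix
#'
#' Principal component analysis of the rows of a (population x
#' macro-haplogroup) frequency matrix: columns are mean-centered and, by
#' default, *not* variance-scaled, since frequencies share a unit. Scores
#' are the centered rows projected onto the eigenvectors of the column
#' covariance matrix; the per-axis explained-variance fractions are
#' reported. Axis signs, arbitrary in any eigendecomposition, are fixed by
#' making the largest-magnitude loading on each axis positive.
#'
#' @param freq numeric matrix, populations in rows.
#' @param n_axes number of axes to keep (at most `min(nrow - 1, ncol)`).
#' @param scale. logical; variance-scale columns before decomposition
#'   (default FALSE).
#' @return list of class `ordination` with `coordinates` (rows x axes),
#'   `explained` (variance fractions, non-increasing), `loadings`, and
#'   `method = "pca"`.
#' @export
pca_frequencies <- function(freq, n_axes = 2L, scale. = FALSE) {
  if (nrow(freq) < 2L) stop("PCA needs at least 2 rows")
  max_axes <- min(nrow(freq) - 1L, ncol(freq))
  if (n_axes > max_axes) {
    stop("n_axes must be <= min(rows - 1, cols) = ", max_axes)
  }
  fit <- stats::prcomp(freq, center = TRUE, scale. = scale.)
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  k <- seq_len(n_axes)
  fx <- fix_axis_signs(fit$x[, k, drop = FALSE],
                       fit$rotation[, k, drop = FALSE])
  structure(list(coordinates = fx$scores, explained = explained[k],
                 loadings = fx$loadings, method = "pca"),
            class = "ordination")
}

#' Classical (metric, Torgerson) multidimensional scaling
#'
#' Embeds a symmetric distance matrix via double-centering of squared
#' distances (B = -1/2 J D^2 J) and eigendecomposition, keeping the top
#' axes with positive eigenvalues. When fewer positive eigenvalues exist
#' than axes requested, the embedding is truncated with a warning; a
#' distance matrix with no positive eigenvalue (e.g. all zeros) is an
#' error. Per-axis `explained` values are eigenvalue shares among the
#' positive eigenvalues. Axis signs follow the same largest-magnitude
#' convention as [pca_frequencies()].
#'
#' @param dist symmetric non-negative matrix with zero diagonal (e.g. from
#'   [build_distance_matrix()]).
#' @param n_axes number of axes requested (default 2).
#' @return list of class `ordination` with `coordinates`, `explained`,
#'   `eigenvalues`, and `method = "mds"`.
#' @export
classical_mds <- function(dist, n_axes = 2L) {
  dist <- as.matrix(dist)
  if (!isSymmetric(unname(dist), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(dist < 0)) stop("distance matrix must be non-negative")
  if (any(abs(diag(dist)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  # cmdscale's own eigenvalue warning is superseded by the explicit
  # truncation warning / error below
  fit <- suppressWarnings(
    stats::cmdscale(dist, k = min(n_axes, nrow(dist) - 1L), eig = TRUE))
  pos <- fit$eig > max(fit$eig) * 1e-12
  if (max(fit$eig) <= 0 || sum(pos) == 0L) {
    stop("no positive eigenvalue: the distances admit no metric embedding")
  }
  n_keep <- min(n_axes, sum(pos))
  if (n_keep < n_axes) {
    warning("only ", n_keep, " positive eigenvalue(s); embedding truncated")
  }
  coords <- fit$points[, seq_len(n_keep), drop = FALSE]
  colnames(coords) <- paste0("axis", seq_len(n_keep))
  coords <- fix_axis_signs(coords)$scores
  eig_pos <- fit$eig[fit$eig > 0]
  structure(list(coordinates = coords,
                 explained = fit$eig[seq_len(n_keep)] / sum(eig_pos),
                 eigenvalues = fit$eig, method = "mds"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination:%s> %d points x %d axes; explained: %s\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}
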