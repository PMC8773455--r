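#' Materialize an aligned matrix from haplotype profiles
#'
#' Builds the rectangular samples x positions character matrix the
#' diversity and distance statistics operate on. Columns are the window's
#' rCRS positions (in window order) plus one extra column per insertion
#' observed in any sample (named `"<pos>.<k>"`, placed after its anchor
#' position); samples lacking an insertion carry a gap `"-"` there, and
#' deleted positions are gaps too, so indel columns are excluded by the
#' complete-deletion site filter. Heteroplasmy-masked calls appear as `N`.
#'
#' @param profiles list of [haplotype_profile()]s sharing one window (or
#'   with windows nested in `window`).
#' @param reference an [mt_reference()].
#' @param window optional [coord_window()]; defaults to the first profile's
#'   window. Profiles are restricted to it.
#' @return character matrix with rownames = sample ids, an attribute
#'   `populations` (named character vector) and attribute `positions`
#'   (column coordinate labels).
#' @export
build_aligned_matrix <- function(profiles, reference, window = NULL) {
  stopifnot(length(profiles) > 0L)
  if (is.null(window)) window <- profiles[[1L]]$window
  profiles <- lapply(profiles, restrict_window, window = window)
  pos <- window_positions(window)
  pos_lab <- as.character(pos)
  # collect insertion columns across samples
  ins_keys <- unique(unlist(lapply(profiles, function(p) {
    v <- p$variants
    i <- v$kind == "ins"
    if (any(i)) paste0(v$position[i], ".", v$ins_index[i]) else character()
  })))
  cols <- pos_lab
  if (length(ins_keys)) {
    anchor <- as.integer(sub("\\..*$", "", ins_keys))
    idx <- as.integer(sub("^.*\\.", "", ins_keys))
    ord <- order(match(anchor, pos), idx)
    ins_keys <- ins_keys[ord]
    # splice each insertion column right after its anchor
    for (k in ins_keys) {
      a <- sub("\\..*$", "", k)
      at <- max(which(cols == a | startsWith(cols, paste0(a, "."))))
      cols <- append(cols, k, after = at)
    }
  }
  mat <- matrix("-", nrow = length(profiles), ncol = length(cols),
                dimnames = list(vapply(profiles, function(p) p$sample_id, ""),
                                cols))
  base_row <- reference$chars[pos]
  mat[, pos_lab] <- matrix(base_row, nrow = length(profiles),
                           ncol = length(pos), byrow = TRUE)
  for (i in seq_along(profiles)) {
    v <- profiles[[i]]$variants
    if (nrow(v) == 0L) next
    s <- v$kind == "sub"
    mat[i, as.character(v$position[s])] <- v$base[s]
    d <- v$kind == "del"
    mat[i, as.character(v$position[d])] <- "-"
    ii <- v$kind == "ins"
    if (any(ii)) mat[i, paste0(v$position[ii], ".", v$ins_index[ii])] <- v$base[ii]
  }
  attr(mat, "populations") <- stats::setNames(
    vapply(profiles, function(p) p$population, ""), rownames(mat))
  attr(mat, "positions") <- cols
  mat
}

#' Usable columns under the complete-deletion rule
#'
#' Drops every column in which any row carries a gap or an ambiguous base
#' (anything outside A, C, G, T) — the "excluding gaps and ambiguous sites"
#' filter applied before counting polymorphic sites and computing
#' diversity.
#'
#' @param matrix an aligned character matrix ([build_aligned_matrix()]).
#' @return integer vector of retained column indices (possibly empty).
#' @export
usable_columns <- function(matrix) {
  ok <- matrix %in% c("A", "C", "G", "T")
  dim(ok) <- dim(matrix)
  which(colSums(ok) == nrow(matrix))
}

#' Number of segregating (polymorphic) sites
#' @inheritParams usable_columns
#' @param columns columns to scan; defaults to [usable_columns()].
#' @return count of columns with two or more distinct bases.
#' @export
segregating_sites <- function(matrix, columns = usable_columns(matrix)) {
  if (length(columns) == 0L) return(0L)
  sum(vapply(columns, function(j) length(unique(matrix[, j])) > 1L,
             logical(1)))
}

# distinct row strings over the given columns
row_haplotypes <- function(matrix, columns) {
  if (length(columns) == 0L) return(rep("", nrow(matrix)))
  apply(matrix[, columns, drop = FALSE], 1L, paste, collapse = "")
}

#' Haplotype diversity (Hd)
#'
#' Hd = n (1 - sum p_i^2) / (n - 1), where p_i are the relative frequencies
#' of the distinct haplotypes (exact string identity over the usable
#' columns). 0 for all-identical samples, exactly 1 when all n samples are
#' distinct.
#'
#' @inheritParams segregating_sites
#' @return Hd in \[0, 1\].
#' @export
haplotype_diversity <- function(matrix, columns = usable_columns(matrix)) {
  n <- nrow(matrix)
  if (n < 2L) stop("haplotype diversity needs at least 2 samples")
  p <- table(row_haplotypes(matrix, columns)) / n
  n * (1 - sum(p^2)) / (n - 1)
}

#' Number of distinct haplotypes
#' @inheritParams segregating_sites
#' @return count of distinct row strings over the usable columns.
#' @export
count_haplotypes <- function(matrix, columns = usable_columns(matrix)) {
  length(unique(row_haplotypes(matrix, columns)))
}

#' Nucleotide diversity (pi)
#'
#' Mean per-site proportion of differences over all sample pairs:
#' \deqn{\pi = \sum_{i<j} d_{ij} / ( C(n,2) L )}
#' with `d_ij` the number of differing usable columns of rows i and j and
#' `L` the number of usable columns (complete-deletion mode, the default).
#' In pairwise-deletion mode each pair is compared over the columns where
#' both rows are base-called and pi is the mean per-pair p-distance.
#'
#' @inheritParams usable_columns
#' @param deletion `"complete"` (default) or `"pairwise"` site filtering.
#' @return pi per site (non-negative).
#' @export
nucleotide_diversity <- function(matrix, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  n <- nrow(matrix)
  if (n < 2L) stop("nucleotide diversity needs at least 2 samples")
  if (deletion == "complete") {
    cols <- usable_columns(matrix)
    if (length(cols) == 0L) stop("no usable columns after complete deletion")
    sub <- matrix[, cols, drop = FALSE]
    npairs <- choose(n, 2)
    # per-column count of differing pairs = C(n,2) - sum_b C(n_b,2)
    total_diffs <- sum(vapply(seq_len(ncol(sub)), function(j) {
      npairs - sum(choose(table(sub[, j]), 2))
    }, numeric(1)))
    total_diffs / (npairs * length(cols))
  } else {
    pd <- pairwise_p_matrix(matrix, matrix)
    mean(pd$p[upper.tri(pd$p)])
  }
}

# p-distance machinery: for two row-blocks A and B, counts of comparable
# columns and differences for every cross pair, via per-base indicator
# matrix products (exact, just vectorized).
pairwise_p_matrix <- function(a, b) {
  bases <- c("A", "C", "G", "T")
  called_a <- matrix(a %in% bases, nrow(a)); called_b <- matrix(b %in% bases, nrow(b))
  comp <- called_a %*% t(called_b)
  same <- matrix(0, nrow(a), nrow(b))
  for (bs in bases) {
    ma <- matrix(a == bs, nrow(a)); mb <- matrix(b == bs, nrow(b))
    same <- same + ma %*% t(mb)
  }
  diff <- comp - same
  if (any(comp == 0)) {
    i <- which(comp == 0, arr.ind = TRUE)[1L, ]
    stop("no comparable columns between samples ",
         rownames(a)[i[1L]], " and ", rownames(b)[i[2L]])
  }
  list(p = diff / comp, comp = comp, diff = diff)
}

#' Mean p-distance between (or within) population groups
#'
#' p-distance: the proportion of compared nucleotide positions at which two
#' sequences differ. By default each pair is compared over the columns
#' where both sequences are base-called (pairwise deletion, as in MEGA);
#' complete-deletion mode restricts all pairs to the globally usable
#' columns. The value returned is the mean over all cross-group pairs, or
#' over distinct unordered pairs when `group_a == group_b`.
#'
#' @inheritParams usable_columns
#' @param group_a,group_b population labels (see the `populations`
#'   attribute of [build_aligned_matrix()]).
#' @param deletion `"pairwise"` (default) or `"complete"`.
#' @return mean p-distance (non-negative scalar).
#' @export
mean_p_distance <- function(matrix, group_a, group_b,
                            deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  pops <- attr(matrix, "populations")
  if (is.null(pops)) stop("matrix has no populations attribute")
  ia <- which(pops == group_a); ib <- which(pops == group_b)
  if (length(ia) == 0L) stop("empty population: ", group_a)
  if (length(ib) == 0L) stop("empty population: ", group_b)
  m <- matrix
  if (deletion == "complete") {
    cols <- usable_columns(matrix)
    if (length(cols) == 0L) stop("no usable columns after complete deletion")
    m <- matrix[, cols, drop = FALSE]
  }
  pd <- pairwise_p_matrix(m[ia, , drop = FALSE], m[ib, , drop = FALSE])
  if (identical(group_a, group_b)) {
    mean(pd$p[upper.tri(pd$p)])
  } else {
    mean(pd$p)
  }
}

#' Between-population distance matrix
#'
#' Mean p-distances for every pair of populations, for use as MDS input.
#' Populations with fewer than `min_n` samples are dropped with a warning
#' (mirroring the exclusion of comparison groups below 30 individuals).
#' The diagonal is zero by convention.
#'
#' @inheritParams mean_p_distance
#' @param min_n minimum samples per population (default 30).
#' @return symmetric numeric matrix with zero diagonal, population labels
#'   as dimnames.
#' @export
build_distance_matrix <- function(matrix, min_n = 30L,
                                  deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  pops <- attr(matrix, "populations")
  if (is.null(pops)) stop("matrix has no populations attribute")
  sizes <- table(pops)
  keep <- names(sizes)[sizes >= min_n]
  dropped <- setdiff(names(sizes), keep)
  if (length(dropped)) {
    warning("dropping population(s) below n=", min_n, ": ",
            paste(sprintf("%s (n=%d)", dropped, sizes[dropped]), collapse = ", "))
  }
  if (length(keep) < 2L) stop("fewer than 2 populations with n >= ", min_n)
  keep <- sort(keep)
  d <- base::matrix(0, length(keep), length(keep), dimnames = list(keep, keep))
  for (i in seq_along(keep)) {
    for (j in seq_len(i - 1L)) {
      d[i, j] <- d[j, i] <- mean_p_distance(matrix, keep[i], keep[j],
                                            deletion = deletion)
    }
  }
  d
}

#' Per-population diversity summary
#'
#' @inheritParams usable_columns
#' @param by_population when TRUE (default) one row per population plus an
#'   `overall` row; otherwise just the overall row. Within-population
#'   statistics use the usable columns of that population's own rows.
#' @return data frame with columns `population`, `n`, `k_hap`, `S`, `Hd`,
#'   `Pi` (Hd and Pi are `NA` for single-sample populations).
#' @export
diversity_summary <- function(matrix, by_population = TRUE) {
  pops <- attr(matrix, "populations")
  groups <- if (by_population && !is.null(pops)) {
    c(as.list(split(seq_len(nrow(matrix)), pops)),
      list(overall = seq_len(nrow(matrix))))
  } else list(overall = seq_len(nrow(matrix)))
  rows <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    sub <- matrix[idx, , drop = FALSE]
    attr(sub, "populations") <- pops[idx]
    cols <- usable_columns(sub)
    data.frame(population = g, n = length(idx),
               k_hap = count_haplotypes(sub, cols),
               S = segregating_sites(sub, cols),
               Hd = if (length(idx) >= 2L) haplotype_diversity(sub, cols) else NA_real_,
               Pi = if (length(idx) >= 2L && length(cols) > 0L)
                 nucleotide_diversity(sub) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
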