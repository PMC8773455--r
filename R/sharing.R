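#' Canonical haplotype key of a profile
#'
#' Two samples share a haplotype iff their keys are byte-identical: the key
#' is the profile's masked variant set restricted to the comparison window,
#' in canonical token order. `N` is a literal character — heteroplasmies
#' are masked *before* sharing is computed, and wildcard matching would
#' break the transitivity of key identity.
#'
#' @param profile a masked [haplotype_profile()].
#' @param window comparison [coord_window()] (default the 546-bp
#'   cross-dataset window, nps 16024-16569).
#' @return single string key.
#' @export
haplotype_key <- function(profile, window = standard_window("eurasian546")) {
  p <- restrict_window(profile, window)
  paste(format_variants(p$variants), collapse = " ")
}

#' Distinct haplotype sets per population
#'
#' @param profiles list of masked [haplotype_profile()]s.
#' @param window comparison window.
#' @param origin_filter `"all"`, `"EAs"` or `"WEu"`; with a non-`"all"`
#'   filter only samples whose macro-haplogroup origin matches are kept,
#'   and `classifications` must be supplied.
#' @param classifications [classify_all()] output with `origin` filled in.
#' @return named list: population -> character vector of distinct keys.
#' @export
haplotype_sets <- function(profiles, window = standard_window("eurasian546"),
                           origin_filter = c("all", "EAs", "WEu"),
                           classifications = NULL) {
  origin_filter <- match.arg(origin_filter)
  ids <- vapply(profiles, function(p) p$sample_id, "")
  pops <- vapply(profiles, function(p) p$population, "")
  keep <- rep(TRUE, length(profiles))
  if (origin_filter != "all") {
    if (is.null(classifications)) {
      stop("origin_filter = \"", origin_filter,
           "\" needs a classifications table")
    }
    origin <- classifications$origin[match(ids, classifications$sample_id)]
    if (anyNA(origin)) {
      stop("missing classification for sample(s): ",
           paste(utils::head(ids[is.na(origin)], 5L), collapse = ", "))
    }
    keep <- origin == origin_filter
  }
  keys <- vapply(profiles[keep], haplotype_key, "", window = window)
  lapply(split(keys, pops[keep]), unique)
}

#' Pairwise haplotype-sharing ratio
#'
#' The number of haplotypes shared between two populations divided by the
#' total distinct haplotypes in each group: for key sets A and B,
#' `shared = |A intersect B|`, `ratio_ab = shared/|A|`,
#' `ratio_ba = shared/|B|`, and the symmetric mean
#' `ratio_sym = (ratio_ab + ratio_ba)/2` is the headline value. All four
#' are returned so either directional reading can be reconstructed.
#'
#' @param sets output of [haplotype_sets()].
#' @param a,b population names present in `sets`.
#' @return list with `shared`, `n_hap_a`, `n_hap_b`, `ratio_ab`,
#'   `ratio_ba`, `ratio_sym`.
#' @export
sharing_ratio <- function(sets, a, b) {
  for (p in c(a, b)) {
    if (is.null(sets[[p]])) stop("population not in sets: ", p)
    if (length(sets[[p]]) == 0L) stop("empty haplotype set for population: ", p)
  }
  shared <- length(intersect(sets[[a]], sets[[b]]))
  ab <- shared / length(sets[[a]])
  ba <- shared / length(sets[[b]])
  list(shared = shared, n_hap_a = length(sets[[a]]), n_hap_b = length(sets[[b]]),
       ratio_ab = ab, ratio_ba = ba, ratio_sym = (ab + ba) / 2)
}

#' Haplotype-sharing matrix over all population pairs
#'
#' @param sets output of [haplotype_sets()] (at least 2 populations).
#' @param origin_filter label recorded on the result (the filtering itself
#'   happens in [haplotype_sets()]).
#' @return list of class `sharing_matrix` with `shared` (integer matrix;
#'   diagonal = distinct-haplotype counts), `ratio` (symmetric `ratio_sym`
#'   matrix, unit diagonal), `long` (long-format data frame of all pairs)
#'   and `origin_filter`.
#' @export
sharing_matrix <- function(sets, origin_filter = "all") {
  pops <- sort(names(sets))
  if (length(pops) < 2L) stop("sharing matrix needs at least 2 populations")
  shared <- base::matrix(0L, length(pops), length(pops),
                         dimnames = list(pops, pops))
  ratio <- base::matrix(1, length(pops), length(pops),
                        dimnames = list(pops, pops))
  diag(shared) <- vapply(pops, function(p) length(sets[[p]]), 0L)
  long <- list()
  for (i in seq_along(pops)) {
    for (j in seq_len(i - 1L)) {
      sr <- sharing_ratio(sets, pops[i], pops[j])
      shared[i, j] <- shared[j, i] <- sr$shared
      ratio[i, j] <- ratio[j, i] <- sr$ratio_sym
      long[[length(long) + 1L]] <- data.frame(
        pop_a = pops[j], pop_b = pops[i], origin_filter = origin_filter,
        shared = sr$shared, n_hap_a = sr$n_hap_b, n_hap_b = sr$n_hap_a,
        ratio_ab = sr$ratio_ba, ratio_ba = sr$ratio_ab,
        ratio_sym = sr$ratio_sym, stringsAsFactors = FALSE)
    }
  }
  long <- if (length(long)) do.call(rbind, long) else data.frame()
  structure(list(shared = shared, ratio = ratio, long = long,
                 origin_filter = origin_filter),
            class = "sharing_matrix")
}

#' @export
print.sharing_matrix <- function(x, ...) {
  cat(sprintf("<sharing_matrix> %d populations (origin filter: %s)\n",
              nrow(x$ratio), x$origin_filter))
  print(round(x$ratio, 3))
  invisible(x)
}
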