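#' Haplotype profile: one sample's rCRS-relative variant set
#'
#' The atom every analysis stage consumes: a sample id, its population
#' label, the coordinate window the sample was sequenced over, and the set
#' of variant calls (all inside the window).
#'
#' @param sample_id text id.
#' @param population population label (use `"unspecified"` when unknown).
#' @param window a [coord_window()].
#' @param variants a [variant_table()]; all positions must fall inside
#'   `window` under circular arithmetic.
#' @return object of class `haplotype_profile`.
#' @export
haplotype_profile <- function(sample_id, population, window,
                              variants = variant_table()) {
  if (!inherits(variants, "variant_table")) {
    variants <- variant_table(variants$position, variants$kind,
                              variants$base, variants$ins_index)
  }
  if (nrow(variants) > 0L) {
    outside <- !window_contains(window, variants$position)
    if (any(outside)) {
      stop("variant(s) outside profile window: ",
           paste(format_variants(variants)[outside], collapse = " "))
    }
  }
  structure(list(sample_id = as.character(sample_id),
                 population = as.character(population),
                 window = window, variants = variants),
            class = "haplotype_profile")
}

#' @export
print.haplotype_profile <- function(x, ...) {
  cat(sprintf("<haplotype_profile> %s [%s] %d..%d: %s\n", x$sample_id,
              x$population, x$window$start, x$window$end,
              if (nrow(x$variants)) paste(format_variants(x$variants), collapse = " ")
              else "(reference)"))
  invisible(x)
}

#' Mask heteroplasmic calls to N
#'
#' Point heteroplasmies are encoded as two-base IUPAC ambiguity codes
#' (R, Y, S, W, K, M, and the three/four-base codes B, D, H, V). Before
#' haplotype-level comparisons these are converted to `N`, so that an
#' ambiguous base never distinguishes two haplotypes by its code. The
#' operation is idempotent and touches nothing else.
#'
#' @param profile a [haplotype_profile()].
#' @return the profile with every ambiguity-base call replaced by an
#'   identical call with base `N`.
#' @export
mask_heteroplasmies <- function(profile) {
  v <- profile$variants
  v$base[v$base %in% IUPAC_AMBIG] <- "N"
  profile$variants <- variant_table(v$position, v$kind, v$base, v$ins_index)
  profile
}

#' Restrict a profile to a sub-window
#'
#' @param profile a [haplotype_profile()].
#' @param window a [coord_window()] nested inside `profile$window`.
#' @return the profile restricted to `window`: variants outside are dropped
#'   and the profile's window updated.
#' @export
restrict_window <- function(profile, window) {
  if (!window_is_nested(window, profile$window)) {
    stop("window ", window$start, "..", window$end,
         " is not nested in profile window ",
         profile$window$start, "..", profile$window$end)
  }
  keep <- window_contains(window, profile$variants$position)
  v <- profile$variants[keep, , drop = FALSE]
  haplotype_profile(profile$sample_id, profile$population, window,
                    variant_table(v$position, v$kind, v$base, v$ins_index))
}

#' Reconstruct a sequence from a reference and a profile
#'
#' Applies the profile's variants to the reference over the profile window:
#' substitutions replace the base, deletions remove it, insertions add the
#' inserted bases after their anchor position in `.1,.2,...` order.
#'
#' @param profile a [haplotype_profile()].
#' @param reference an [mt_reference()].
#' @return single sequence string.
#' @export
profile_to_sequence <- function(profile, reference) {
  pos <- window_positions(profile$window)
  chars <- reference$chars[pos]
  v <- profile$variants
  at <- match(v$position, pos)
  subs <- which(v$kind == "sub")
  chars[at[subs]] <- v$base[subs]
  chars[at[v$kind == "del"]] <- ""
  ins <- which(v$kind == "ins")
  if (length(ins)) {
    ins <- ins[order(v$position[ins], v$ins_index[ins])]
    add <- vapply(split(v$base[ins], at[ins]), paste, "", collapse = "")
    slot <- as.integer(names(add))
    chars[slot] <- paste0(chars[slot], add)
  }
  paste(chars, collapse = "")
}

#' Read / write rCRS-relative variant tables
#'
#' The on-disk haplotype table is a TSV with columns `sample_id`,
#' `population`, `window_start`, `window_end`, `variants` (space-separated
#' canonical tokens; empty string for a reference-identical sample).
#' `write_variant_table()` followed by `read_variant_table()` is the
#' identity on canonical profiles.
#'
#' @param path file path.
#' @return `read_variant_table()`: a list of [haplotype_profile()]s.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(variants = "character"))
  need <- c("sample_id", "population", "window_start", "window_end", "variants")
  if (!all(need %in% names(df))) {
    stop("variant table needs columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    toks <- strsplit(trimws(df$variants[i]), "[ ,]+")[[1L]]
    vars <- tryCatch(parse_variants(toks), error = function(e) {
      stop("row ", i, " (", df$sample_id[i], "): ", conditionMessage(e),
           call. = FALSE)
    })
    haplotype_profile(df$sample_id[i], df$population[i],
                      coord_window(df$window_start[i], df$window_end[i]),
                      vars)
  })
}

#' @rdname read_variant_table
#' @param profiles list of [haplotype_profile()]s.
#' @export
write_variant_table <- function(profiles, path) {
  df <- data.frame(
    sample_id = vapply(profiles, function(p) p$sample_id, ""),
    population = vapply(profiles, function(p) p$population, ""),
    window_start = vapply(profiles, function(p) p$window$start, 0L),
    window_end = vapply(profiles, function(p) p$window$end, 0L),
    variants = vapply(profiles, function(p)
      paste(format_variants(p$variants), collapse = " "), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
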