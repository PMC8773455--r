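# Minimal-edit alignment of a sample sequence to the reference window,
# reported as rCRS-relative variant calls with forensic indel placement.

unit_cost_matrix <- function() {
  alphabet <- VARIANT_BASES
  n <- length(alphabet)
  m <- matrix(-1, n, n, dimnames = list(alphabet, alphabet))
  diag(m) <- 0
  m
}

# Shift every gap to its 3'-most (rightmost) score-equivalent placement,
# the EMPOP/forensic convention for indels in homopolymer runs. `a` and `b`
# are equal-length character vectors of one global alignment; gaps in `a`
# are insertions (relative to the reference in `a`), gaps in `b` deletions.
shift_gaps_right <- function(a, b) {
  n <- length(a)
  for (c in rev(which(a == "-"))) {
    j <- c
    while (j < n && a[j + 1L] != "-" && b[j] == b[j + 1L]) {
      a[c(j, j + 1L)] <- a[c(j + 1L, j)]
      j <- j + 1L
    }
  }
  for (c in rev(which(b == "-"))) {
    j <- c
    while (j < n && b[j + 1L] != "-" && a[j] == a[j + 1L]) {
      b[c(j, j + 1L)] <- b[c(j + 1L, j)]
      j <- j + 1L
    }
  }
  list(ref = a, seq = b)
}

# Turn one gapped alignment (reference chars `a`, sample chars `b`) into a
# variant_table, mapping window offsets to rCRS coordinates via `positions`.
alignment_to_variants <- function(a, b, positions, genome_length = 16569L) {
  pos <- integer(); kind <- character(); base <- character(); idx <- integer()
  ref_i <- 0L
  last_anchor <- ((positions[1L] - 2L) %% genome_length) + 1L  # before window
  ins_count <- 0L
  for (c in seq_along(a)) {
    if (a[c] == "-") {            # insertion relative to the reference
      ins_count <- ins_count + 1L
      pos <- c(pos, last_anchor); kind <- c(kind, "ins")
      base <- c(base, b[c]); idx <- c(idx, ins_count)
    } else {
      ref_i <- ref_i + 1L
      last_anchor <- positions[ref_i]
      ins_count <- 0L
      if (b[c] == "-") {
        pos <- c(pos, last_anchor); kind <- c(kind, "del")
        base <- c(base, ""); idx <- c(idx, NA_integer_)
      } else if (b[c] != a[c]) {
        pos <- c(pos, last_anchor); kind <- c(kind, "sub")
        base <- c(base, b[c]); idx <- c(idx, NA_integer_)
      }
    }
  }
  variant_table(pos, kind, base, idx)
}

#' Call rCRS-relative variants from a sequence
#'
#' Aligns a sample sequence to the reference over a coordinate window by
#' minimal-edit (unit-cost) global alignment and reports the differences as
#' variant calls at rCRS coordinates. Among the optimal alignments, indels
#' are placed at the 3'-most position of a homopolymer run (the
#' forensic/EMPOP convention), so calls are reproducible across tools.
#' IUPAC ambiguity bases in the input are carried through as the derived
#' base of a substitution call (mask them afterwards with
#' [mask_heteroplasmies()]).
#'
#' @param sequence sample sequence string covering the window (length within
#'   `length_slack` of the window length).
#' @param reference an [mt_reference()].
#' @param window a [coord_window()]; the returned profile's window.
#' @param sample_id,population labels for the returned profile.
#' @param max_edits ceiling on the edit distance; a sequence too divergent
#'   to be a credible control-region read is rejected rather than profiled.
#' @param length_slack tolerated deviation of sequence length from window
#'   length (default 20 bp).
#' @return a [haplotype_profile()].
#' @examples
#' ref <- build_synthetic_rcrs()
#' w <- standard_window("hvs1")
#' call_variants(ref_window_sequence(ref, w), ref, w)  # empty profile
#' @export
call_variants <- function(sequence, reference, window,
                          sample_id = "sample", population = "unspecified",
                          max_edits = 60L, length_slack = 20L) {
  profiles <- call_variants_many(stats::setNames(sequence, sample_id),
                                 reference, window,
                                 populations = stats::setNames(population, sample_id),
                                 max_edits = max_edits,
                                 length_slack = length_slack)
  profiles[[1L]]
}

#' Call variants for many sequences at once
#'
#' Vectorized form of [call_variants()]: all sequences are aligned to the
#' same reference window in one pass.
#'
#' @param sequences named character vector (names = sample ids).
#' @param populations named character vector of population labels, or a
#'   single label recycled for all samples.
#' @inheritParams call_variants
#' @return list of [haplotype_profile()]s in input order.
#' @export
call_variants_many <- function(sequences, reference, window,
                               populations = "unspecified",
                               max_edits = 60L, length_slack = 20L) {
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("sample", seq_along(sequences))
  }
  ids <- names(sequences)
  if (length(populations) == 1L && is.null(names(populations))) {
    populations <- stats::setNames(rep(populations, length(ids)), ids)
  }
  sequences <- toupper(chartr("Uu", "Tt", sequences))
  wlen <- window_length(window)
  lens <- nchar(sequences)
  bad <- abs(lens - wlen) > length_slack
  if (any(bad)) {
    stop("sequence length too far from window length (", wlen, " bp): ",
         paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  refw <- ref_window_sequence(reference, window)
  positions <- window_positions(window)

  out <- vector("list", length(sequences))
  names(out) <- ids
  exact <- sequences == refw
  out[exact] <- lapply(ids[exact], function(id) {
    haplotype_profile(id, populations[[id]], window)
  })
  todo <- which(!exact)
  if (length(todo)) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(unname(sequences[todo])),
      subject = Biostrings::DNAString(refw),
      type = "global",
      substitutionMatrix = unit_cost_matrix(),
      gapOpening = 0, gapExtension = 1)
    dist <- -Biostrings::score(pa)
    too_far <- dist > max_edits
    if (any(too_far)) {
      stop("sequence(s) too divergent to align (> ", max_edits, " edits): ",
           paste(utils::head(ids[todo][too_far], 5L), collapse = ", "))
    }
    ref_aln <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")
    seq_aln <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")
    for (k in seq_along(todo)) {
      i <- todo[k]
      sh <- shift_gaps_right(ref_aln[[k]], seq_aln[[k]])
      vars <- alignment_to_variants(sh$ref, sh$seq, positions,
                                    length(reference$chars))
      out[[i]] <- haplotype_profile(ids[i], populations[[ids[i]]], window, vars)
    }
  }
  out
}
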