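#' Reference mitochondrial sequence
#'
#' A reference is the 16,569-bp circular sequence all variant calls are
#' reported against (in real work, the revised Cambridge Reference Sequence,
#' rCRS, NC_012920.1). Position arithmetic is 1-based and modular.
#'
#' @param name text identifier.
#' @param bases a single string of length 16,569 over `A,C,G,T,N`.
#' @return object of class `mt_reference` with fields `name`, `bases` and a
#'   precomputed per-position character vector `chars`.
#' @export
mt_reference <- function(name, bases) {
  bases <- toupper(bases)
  chars <- strsplit(bases, "", fixed = TRUE)[[1L]]
  if (length(chars) != 16569L) {
    stop("reference must be 16,569 bp, got ", length(chars))
  }
  if (!all(chars %in% c("A", "C", "G", "T", "N"))) {
    stop("reference alphabet must be A,C,G,T,N")
  }
  structure(list(name = name, bases = bases, chars = chars),
            class = "mt_reference")
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf("<mt_reference> %s (%d bp)\n", x$name, length(x$chars)))
  invisible(x)
}

#' Read a reference sequence from FASTA
#' @param path FASTA file containing exactly one 16,569-bp record.
#' @return an [mt_reference()].
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) stop("reference FASTA must contain exactly one record")
  mt_reference(names(seqs)[1L], as.character(seqs[[1L]]))
}

#' Reference base at given positions
#' @param reference an [mt_reference()].
#' @param positions integer vector of 1-based positions (taken modulo the
#'   genome length, so position 16570 wraps to 1).
#' @return character vector of bases.
#' @export
ref_base <- function(reference, positions) {
  n <- length(reference$chars)
  reference$chars[((as.integer(positions) - 1L) %% n) + 1L]
}

#' Extract the reference sequence over a window
#' @param reference an [mt_reference()].
#' @param window a [coord_window()].
#' @return single string of the window's bases in window order.
#' @export
ref_window_sequence <- function(reference, window) {
  paste(reference$chars[window_positions(window)], collapse = "")
}

#' Build the packaged synthetic reference
#'
#' The package cannot redistribute the rCRS itself, so it ships a synthetic
#' 16,569-bp stand-in with human-mtDNA-like base composition, generated
#' deterministically (own RNG stream; independent of the caller's seed).
#' The packaged FASTA fixture `rcrs_synthetic.fasta` is byte-identical to
#' this function's output; real analyses should pass the true rCRS to
#' [read_reference_fasta()] instead.
#'
#' @return an [mt_reference()] named `"rCRS_synthetic"`.
#' @export
build_synthetic_rcrs <- function() {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(16569L)
  # heavy-strand composition of human mtDNA, approximately
  chars <- sample(c("A", "C", "G", "T"), 16569L, replace = TRUE,
                  prob = c(0.309, 0.313, 0.131, 0.247))
  mt_reference("rCRS_synthetic", paste(chars, collapse = ""))
}

#' Load the packaged synthetic reference fixture
#' @return an [mt_reference()].
#' @export
packaged_reference <- function() {
  read_reference_fasta(system.file("extdata", "rcrs_synthetic.fasta",
                                   package = "mtlineage", mustWork = TRUE))
}
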