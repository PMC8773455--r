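#' Read a sample-to-population map
#' @param path two-column TSV (`sample_id`, `population`), with header.
#' @return named character vector, population keyed by sample id.
#' @export
read_population_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "population") %in% names(df))) {
    stop("population map needs columns sample_id, population")
  }
  stats::setNames(as.character(df$population), as.character(df$sample_id))
}

#' Parse a FASTA file of control-region sequences
#'
#' Sequences are upper-cased and `U` is normalized to `T`. Record order is
#' preserved. Every record id must resolve to a population through
#' `population_map`, or `default_population` must be given (the reserved
#' label `"unspecified"` is the conventional choice).
#'
#' @param path FASTA file.
#' @param population_map named character vector (population keyed by sample
#'   id), a data frame with columns `sample_id`/`population`, or a path to a
#'   two-column TSV.
#' @param default_population population assigned to unmapped ids; `NULL`
#'   (default) makes an unmapped id an error.
#' @return data frame with columns `sample_id`, `sequence`, `population`,
#'   in file order.
#' @export
parse_fasta <- function(path, population_map = NULL, default_population = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in FASTA: ", ids[duplicated(ids)][1L])
  }
  map <- population_map
  if (is.character(map) && length(map) == 1L && file.exists(map)) {
    map <- read_population_map(map)
  } else if (is.data.frame(map)) {
    map <- stats::setNames(as.character(map$population),
                           as.character(map$sample_id))
  }
  pop <- if (is.null(map)) rep(NA_character_, length(ids)) else unname(map[ids])
  if (!is.null(default_population)) pop[is.na(pop)] <- default_population
  if (anyNA(pop)) {
    stop("no population for sample id(s): ",
         paste(utils::head(ids[is.na(pop)], 5L), collapse = ", "))
  }
  sequence <- chartr("Uu", "Tt", as.character(seqs))
  data.frame(sample_id = ids, sequence = toupper(unname(sequence)),
             population = pop, stringsAsFactors = FALSE)
}
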