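#' Load a macro-haplogroup table
#'
#' The table maps haplogroup-name prefixes to one of 18 coarse
#' macro-haplogroup labels (A, B, D, G, JT, L3*, M*, M7, M8, M9, N1, N2,
#' N9, R*, R0, R9, U, X) and each macro label to a geographic-origin class,
#' eastern Asian (`EAs`) or western Eurasian (`WEu`). Prefix rules are
#' applied longest-match-first, so e.g. `"M7b"` resolves through `M7`
#' rather than `M`, and `"H1j"` through `H` to `R0`. The packaged default
#' assigns WEu = \{JT, N1, N2, R0, U, X\} and EAs = \{A, B, D, G, M*, M7,
#' M8, M9, N9, R*, R9, L3*\}; the L3*, M* and R* assignments are inferences
#' (the origin classes of these rare paragroups are not settled) and the
#' table is deliberately user-overridable.
#'
#' @param path TSV with columns `prefix`, `macro`, `origin`; `NULL` loads
#'   the packaged default.
#' @return data frame of class `macro_table`.
#' @export
load_macro_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "macro_groups.tsv", package = "mtlineage",
                        mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("prefix", "macro", "origin") %in% names(df))) {
    stop("macro table needs columns prefix, macro, origin")
  }
  if (anyDuplicated(df$prefix)) {
    stop("duplicate prefix in macro table: ",
         df$prefix[duplicated(df$prefix)][1L])
  }
  per_macro <- tapply(df$origin, df$macro, function(o) length(unique(o)))
  if (any(per_macro != 1L)) {
    stop("macro label with conflicting origins: ",
         names(per_macro)[per_macro != 1L][1L])
  }
  if (!all(df$origin %in% c("EAs", "WEu"))) {
    stop("origin must be EAs or WEu")
  }
  class(df) <- c("macro_table", "data.frame")
  df
}

#' Macro-haplogroup of a haplogroup name
#'
#' Longest-prefix lookup in a [load_macro_table()] table.
#'
#' @param haplogroup haplogroup name (e.g. `"D4"`, `"H1j"`, `"J1b2"`).
#' @param table a macro table.
#' @return macro label (scalar character).
#' @examples
#' tab <- load_macro_table()
#' macro_group("H1j", tab)   # "R0"
#' macro_group("C4a", tab)   # "M8"
#' @export
macro_group <- function(haplogroup, table) {
  stopifnot(length(haplogroup) == 1L)
  hits <- table$prefix[startsWith(haplogroup, table$prefix)]
  if (length(hits) == 0L) {
    stop("haplogroup '", haplogroup, "' matches no macro-group prefix")
  }
  longest <- hits[nchar(hits) == max(nchar(hits))]
  if (length(longest) != 1L) {
    stop("ambiguous macro-group prefixes for '", haplogroup, "'")
  }
  table$macro[table$prefix == longest]
}

#' Geographic origin class of a macro-haplogroup
#' @param macro macro label (one of the table's `macro` values).
#' @param table a [load_macro_table()] table.
#' @return `"EAs"` or `"WEu"`.
#' @export
origin_of <- function(macro, table) {
  stopifnot(length(macro) == 1L)
  i <- which(table$macro == macro)
  if (length(i) == 0L) stop("unknown macro-haplogroup: ", macro)
  table$origin[i[1L]]
}
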