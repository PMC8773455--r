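#' Read an ancient-mitogenome metadata table
#'
#' TSV with columns `record_id`, `haplogroup`, `longitude`, `latitude`,
#' `site`, and either `date_ce` (signed calendar years, negative = BCE) or
#' `date_bp` (years before present, 1950 datum, converted at load time).
#'
#' @param path TSV file.
#' @return data frame with a `date_ce` column, one row per record.
#' @export
read_ancient_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("record_id", "haplogroup", "longitude", "latitude", "site")
  if (!all(need %in% names(df))) {
    stop("ancient table needs columns: ", paste(need, collapse = ", "),
         " plus date_ce or date_bp")
  }
  if (!"date_ce" %in% names(df)) {
    if (!"date_bp" %in% names(df)) stop("need a date_ce or date_bp column")
    df$date_ce <- 1950 - df$date_bp
  }
  if (any(df$date_ce <= -50000 | df$date_ce >= 2100)) {
    stop("implausible date_ce (must be in -50000..2100)")
  }
  if (any(abs(df$longitude) > 180)) stop("longitude out of range")
  df
}

#' Does a record's haplogroup belong to a lineage?
#'
#' TRUE when the record's haplogroup equals the lineage or is nested inside
#' it. With a motif tree, nesting is phylogenetic descent. Without one,
#' plain prefix mode is used with a token-boundary guard reflecting
#' PhyloTree's alternating letter/digit nomenclature: the first character
#' after the prefix must switch character class, so `"H5a1a"` matches
#' lineage `"H5a1"` but `"H51"` does not match `"H5"`.
#'
#' @param record_haplogroup haplogroup of the ancient record.
#' @param lineage lineage name being traced.
#' @param tree optional [load_motif_tree()] tree; both names must resolve
#'   in it when given.
#' @return logical scalar.
#' @export
lineage_match <- function(record_haplogroup, lineage, tree = NULL) {
  if (!is.null(tree)) {
    if (!record_haplogroup %in% names(tree$nodes)) {
      stop("unresolvable haplogroup in tree: ", record_haplogroup)
    }
    return(is_descendant(tree, record_haplogroup, lineage))
  }
  if (record_haplogroup == lineage) return(TRUE)
  if (!startsWith(record_haplogroup, lineage)) return(FALSE)
  nxt <- substr(record_haplogroup, nchar(lineage) + 1L, nchar(lineage) + 1L)
  last <- substr(lineage, nchar(lineage), nchar(lineage))
  is_digit <- function(ch) grepl("^[0-9]$", ch)
  is_digit(last) != is_digit(nxt)
}

#' Trace the arrival history of one lineage
#'
#' Classifies a maternal lineage's presence in a longitude band (by default
#' Mongolia and nearby regions, 85-125 degrees E) from dated, georeferenced
#' ancient mitogenomes:
#' * `pre_cutoff_presence` - the earliest matching record inside the band
#'   is dated at or before the cutoff (default -1000, i.e. 1000 BCE);
#' * `post_cutoff_arrival` - the earliest in-band record postdates the
#'   cutoff;
#' * `absent_in_band` - no matching record falls inside the band.
#'
#' For post-cutoff arrivals the earliest-dated matching record lying west
#' of the band's earliest record (ties broken westernmost) is taken as the
#' western precursor; the arrival is flagged `route_consistent` when that
#' precursor strictly predates the in-band arrival and sits 20-40 degrees
#' of longitude to the west (the trans-Eurasian trade-route signature).
#'
#' @param lineage lineage name.
#' @param records data frame from [read_ancient_table()].
#' @param band numeric `c(lon_min, lon_max)` of the target region.
#' @param cutoff_ce arrival cutoff in signed calendar years.
#' @param offset_range admissible westward offset `c(min, max)` in degrees.
#' @param tree optional motif tree for phylogenetic lineage matching.
#' @return list of class `trace_result`: `lineage`, `status`,
#'   `earliest_in_band`, `earliest_western_precursor` (one-row data frames
#'   or NULL), `lon_offset`, `route_consistent`.
#' @export
trace_lineage <- function(lineage, records, band = c(85, 125),
                          cutoff_ce = -1000, offset_range = c(20, 40),
                          tree = NULL) {
  if (nrow(records) == 0L) stop("empty ancient record set")
  if (band[1L] >= band[2L]) stop("band must satisfy lon_min < lon_max")
  hit <- vapply(records$haplogroup, lineage_match, logical(1),
                lineage = lineage, tree = tree)
  matching <- records[hit, , drop = FALSE]
  in_band <- matching[matching$longitude >= band[1L] &
                        matching$longitude <= band[2L], , drop = FALSE]
  res <- list(lineage = lineage, status = "absent_in_band",
              earliest_in_band = NULL, earliest_western_precursor = NULL,
              lon_offset = NA_real_, route_consistent = FALSE)
  if (nrow(in_band) == 0L) return(structure(res, class = "trace_result"))
  eb <- in_band[order(in_band$date_ce, in_band$longitude), , drop = FALSE][1L, ]
  res$earliest_in_band <- eb
  res$status <- if (eb$date_ce <= cutoff_ce) "pre_cutoff_presence"
                else "post_cutoff_arrival"
  west <- matching[matching$longitude < eb$longitude, , drop = FALSE]
  if (nrow(west) > 0L) {
    pre <- west[order(west$date_ce, west$longitude), , drop = FALSE][1L, ]
    res$earliest_western_precursor <- pre
    res$lon_offset <- eb$longitude - pre$longitude
    res$route_consistent <- res$status == "post_cutoff_arrival" &&
      res$lon_offset >= offset_range[1L] && res$lon_offset <= offset_range[2L] &&
      pre$date_ce < eb$date_ce
  }
  structure(res, class = "trace_result")
}

#' @export
print.trace_result <- function(x, ...) {
  cat(sprintf("<trace> %s: %s%s\n", x$lineage, x$status,
              if (x$route_consistent) " [route-consistent]" else ""))
  invisible(x)
}

#' Trace a list of lineages and summarize
#'
#' @param lineages character vector of lineage names.
#' @inheritParams trace_lineage
#' @return list of class `trace_report`: `results` (data frame, one row
#'   per lineage with status, earliest dates/longitudes, offset and
#'   route-consistency) and `summary` (counts per status plus
#'   `route_consistent`).
#' @export
trace_report <- function(lineages, records, band = c(85, 125),
                         cutoff_ce = -1000, offset_range = c(20, 40),
                         tree = NULL) {
  rows <- lapply(lineages, function(lg) {
    tr <- trace_lineage(lg, records, band, cutoff_ce, offset_range, tree)
    data.frame(
      lineage = lg, status = tr$status,
      band_record = if (is.null(tr$earliest_in_band)) NA_character_
                    else tr$earliest_in_band$record_id,
      band_date_ce = if (is.null(tr$earliest_in_band)) NA_real_
                     else tr$earliest_in_band$date_ce,
      band_lon = if (is.null(tr$earliest_in_band)) NA_real_
                 else tr$earliest_in_band$longitude,
      precursor_record = if (is.null(tr$earliest_western_precursor)) NA_character_
                         else tr$earliest_western_precursor$record_id,
      precursor_date_ce = if (is.null(tr$earliest_western_precursor)) NA_real_
                          else tr$earliest_western_precursor$date_ce,
      precursor_lon = if (is.null(tr$earliest_western_precursor)) NA_real_
                      else tr$earliest_western_precursor$longitude,
      lon_offset = tr$lon_offset,
      route_consistent = tr$route_consistent,
      stringsAsFactors = FALSE)
  })
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lineage = character(), status = character(),
               route_consistent = logical())
  summary <- list(
    pre_cutoff_presence = sum(results$status == "pre_cutoff_presence"),
    post_cutoff_arrival = sum(results$status == "post_cutoff_arrival"),
    absent_in_band = sum(results$status == "absent_in_band"),
    route_consistent = sum(results$route_consistent))
  structure(list(results = results, summary = summary), class = "trace_report")
}

#' @export
print.trace_report <- function(x, ...) {
  cat(sprintf("<trace_report> %d lineages: %d pre-cutoff, %d post-cutoff (%d route-consistent), %d absent\n",
              nrow(x$results), x$summary$pre_cutoff_presence,
              x$summary$post_cutoff_arrival, x$summary$route_consistent,
              x$summary$absent_in_band))
  invisible(x)
}
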