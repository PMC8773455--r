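#' Coordinate window on the circular mitochondrial genome
#'
#' Windows are closed intervals of 1-based rCRS positions. Because the
#' mitochondrial genome is circular, a window may span the origin: the
#' control region runs from np 16024 through np 16569 and on to np 576,
#' written `coord_window(16024, 576)`. Origin-spanning windows are detected
#' automatically (`start > end`).
#'
#' @param start first 1-based position of the window.
#' @param end last 1-based position of the window (inclusive). `end < start`
#'   denotes an origin-spanning window.
#' @param genome_length length of the circular genome (16,569 for the rCRS).
#' @return An object of class `coord_window` with fields `start`, `end`,
#'   `circular` (TRUE when the window wraps past the origin) and
#'   `genome_length`.
#' @examples
#' cr <- coord_window(16024, 576)    # full control region, spans the origin
#' window_length(cr)                 # 1122
#' window_contains(cr, c(310, 16050, 600))
#' @export
coord_window <- function(start, end, genome_length = 16569L) {
  start <- as.integer(start); end <- as.integer(end)
  stopifnot(length(start) == 1L, length(end) == 1L)
  if (is.na(start) || is.na(end) || start < 1L || end < 1L ||
      start > genome_length || end > genome_length) {
    stop("window positions must lie in 1..", genome_length)
  }
  structure(
    list(start = start, end = end, circular = start > end,
         genome_length = as.integer(genome_length)),
    class = "coord_window"
  )
}

#' @export
print.coord_window <- function(x, ...) {
  cat(sprintf("<coord_window> %d..%d%s (%d bp)\n", x$start, x$end,
              if (x$circular) " (origin-spanning)" else "",
              window_length(x)))
  invisible(x)
}

#' Number of positions covered by a window
#' @param window a [coord_window()].
#' @return integer length of the window.
#' @export
window_length <- function(window) {
  if (window$circular) {
    window$genome_length - window$start + 1L + window$end
  } else {
    window$end - window$start + 1L
  }
}

#' Positions covered by a window, in window order
#'
#' For an origin-spanning window the positions run `start..genome_length`
#' followed by `1..end`, i.e. in the order the bases occur on the molecule.
#'
#' @inheritParams window_length
#' @return integer vector of 1-based positions.
#' @export
window_positions <- function(window) {
  if (window$circular) {
    c(window$start:window$genome_length, 1L:window$end)
  } else {
    window$start:window$end
  }
}

#' Window membership test under circular arithmetic
#' @inheritParams window_length
#' @param positions integer vector of 1-based positions.
#' @return logical vector, TRUE where the position falls inside the window.
#' @export
window_contains <- function(window, positions) {
  positions <- as.integer(positions)
  if (window$circular) {
    positions >= window$start | positions <= window$end
  } else {
    positions >= window$start & positions <= window$end
  }
}

#' Is `inner` entirely contained in `outer`?
#' @param inner,outer [coord_window()] objects on the same genome.
#' @return logical scalar.
#' @export
window_is_nested <- function(inner, outer) {
  stopifnot(inner$genome_length == outer$genome_length)
  all(window_contains(outer, c(inner$start, inner$end))) &&
    all(window_contains(outer, window_positions(inner)))
}

#' Predefined analysis windows
#'
#' Convenience constructors for the three windows used throughout:
#' `"hvs1"` (nps 16024-16365), `"cr"` (the full control region,
#' nps 16024-576, origin-spanning), and `"eurasian546"` (nps 16024-16569,
#' the 546-bp window used for cross-dataset comparison).
#'
#' @param name one of `"hvs1"`, `"cr"`, `"eurasian546"`.
#' @return a [coord_window()].
#' @export
standard_window <- function(name = c("hvs1", "cr", "eurasian546")) {
  switch(match.arg(name),
         hvs1 = coord_window(16024L, 16365L),
         cr = coord_window(16024L, 576L),
         eurasian546 = coord_window(16024L, 16569L))
}
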