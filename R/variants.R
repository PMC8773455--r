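IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
VARIANT_BASES <- c("A", "C", "G", "T", "N", IUPAC_AMBIG)

# Two-base IUPAC codes, used by the simulator to encode point heteroplasmies.
IUPAC2 <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")

#' Construct a variant table
#'
#' Variants are rCRS-relative calls in the forensic notation used by EMPOP
#' and PhyloTree: substitutions `"16189C"`, insertions `"16193.1C"` (the
#' `.k` suffix numbers successive inserted bases after the anchor position),
#' deletions `"249del"`. A variant *set* is represented as a data frame with
#' columns `position` (1-based rCRS coordinate), `kind`
#' (`"sub"`/`"ins"`/`"del"`), `base` (derived base; `""` for deletions) and
#' `ins_index` (`NA` except for insertions).
#'
#' @param position integer vector of 1-based positions.
#' @param kind character vector, `"sub"`, `"ins"` or `"del"`.
#' @param base derived base per call (IUPAC letter or `N`; `""` for `del`).
#' @param ins_index insertion index (`.1`, `.2`, ...), `NA` otherwise.
#' @return a `data.frame` of class `variant_table`, canonically ordered.
#' @seealso [parse_variants()], [format_variants()]
#' @export
variant_table <- function(position = integer(), kind = character(),
                          base = character(), ins_index = NA_integer_) {
  df <- data.frame(position = as.integer(position),
                   kind = as.character(kind),
                   base = as.character(base),
                   ins_index = as.integer(rep_len(ins_index, length(position))),
                   stringsAsFactors = FALSE)
  bad <- !df$kind %in% c("sub", "ins", "del")
  if (any(bad)) stop("unknown variant kind: ", paste(unique(df$kind[bad]), collapse = ", "))
  if (any(df$position < 1L | df$position > 16569L, na.rm = TRUE)) {
    stop("variant positions must lie in 1..16569")
  }
  if (any(df$kind == "sub" & !df$base %in% VARIANT_BASES)) {
    stop("invalid substitution base")
  }
  if (any(df$kind == "ins" & (is.na(df$ins_index) | df$ins_index < 1L))) {
    stop("insertions need a positive ins_index")
  }
  df <- df[order(df$position, match(df$kind, c("sub", "del", "ins")),
                 df$ins_index, method = "radix"), , drop = FALSE]
  key <- paste(df$position, df$kind, ifelse(is.na(df$ins_index), 0L, df$ins_index))
  if (anyDuplicated(key)) {
    stop("duplicate variant at (position, kind, ins_index): ",
         key[duplicated(key)][1L])
  }
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Parse variant tokens
#'
#' @param tokens character vector of tokens such as `"16189C"`, `"16193.1C"`,
#'   `"249del"`. Whitespace-only and empty tokens are dropped.
#' @return a [variant_table()].
#' @examples
#' parse_variants(c("16189C", "16193.1C", "249del"))
#' @export
parse_variants <- function(tokens) {
  tokens <- tokens[nzchar(trimws(tokens))]
  if (length(tokens) == 0L) return(variant_table())
  tokens <- trimws(tokens)
  m_sub <- regmatches(tokens, regexec("^([0-9]+)([A-Za-z])$", tokens))
  m_ins <- regmatches(tokens, regexec("^([0-9]+)\\.([0-9]+)([A-Za-z])$", tokens))
  m_del <- regmatches(tokens, regexec("^([0-9]+)del$", tokens))
  pos <- integer(length(tokens)); kind <- character(length(tokens))
  base <- character(length(tokens)); idx <- rep(NA_integer_, length(tokens))
  for (i in seq_along(tokens)) {
    if (length(m_del[[i]])) {
      pos[i] <- as.integer(m_del[[i]][2]); kind[i] <- "del"; base[i] <- ""
    } else if (length(m_ins[[i]])) {
      b <- toupper(m_ins[[i]][4])
      if (!b %in% VARIANT_BASES) stop("unparseable variant token: ", tokens[i])
      pos[i] <- as.integer(m_ins[[i]][2]); kind[i] <- "ins"
      idx[i] <- as.integer(m_ins[[i]][3]); base[i] <- b
    } else if (length(m_sub[[i]])) {
      b <- toupper(m_sub[[i]][3])
      if (!b %in% VARIANT_BASES) stop("unparseable variant token: ", tokens[i])
      pos[i] <- as.integer(m_sub[[i]][2]); kind[i] <- "sub"; base[i] <- b
    } else {
      stop("unparseable variant token: ", tokens[i])
    }
  }
  variant_table(pos, kind, base, idx)
}

#' Canonical text form of a variant table
#' @param variants a [variant_table()].
#' @return character vector of canonical tokens, in canonical order.
#' @export
format_variants <- function(variants) {
  if (nrow(variants) == 0L) return(character())
  ifelse(variants$kind == "del", paste0(variants$position, "del"),
    ifelse(variants$kind == "ins",
           paste0(variants$position, ".", variants$ins_index, variants$base),
           paste0(variants$position, variants$base)))
}
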