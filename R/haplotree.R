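#' Load a PhyloTree-style motif tree
#'
#' The motif-tree dialect is a TSV with header columns `node_name`,
#' `parent_name`, `motif`. One row per haplogroup node; the single root row
#' has an empty `parent_name` and an empty motif. `motif` holds the
#' space-separated mutations expected on the branch *into* the node, in the
#' variant notation of [parse_variants()], plus reversion tokens
#' `"<position>!"` which cancel an expectation inherited from an ancestor
#' at that position (a second reversion at the same position re-adds it,
#' following PhyloTree's back-mutation convention).
#'
#' @param path tree file.
#' @return object of class `motif_tree`: named list of nodes (each with
#'   `name`, `parent`, `motif` tokens, `depth`) plus the root name.
#' @export
load_motif_tree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = "character")
  if (!all(c("node_name", "parent_name", "motif") %in% names(df))) {
    stop("motif tree needs columns node_name, parent_name, motif")
  }
  df$node_name <- trimws(df$node_name)
  df$parent_name <- trimws(df$parent_name)
  if (any(df$node_name == "")) {
    stop("empty node name at line ", which(df$node_name == "")[1L] + 1L)
  }
  if (anyDuplicated(df$node_name)) {
    stop("duplicate node name: ", df$node_name[duplicated(df$node_name)][1L])
  }
  roots <- which(df$parent_name == "")
  if (length(roots) != 1L) {
    stop("tree must have exactly one root (empty parent_name), found ",
         length(roots))
  }
  orphan <- !df$parent_name %in% c("", df$node_name)
  if (any(orphan)) {
    stop("line ", which(orphan)[1L] + 1L, ": unknown parent '",
         df$parent_name[orphan][1L], "'")
  }
  nodes <- vector("list", nrow(df))
  names(nodes) <- df$node_name
  for (i in seq_len(nrow(df))) {
    toks <- strsplit(trimws(df$motif[i]), "[ ,]+")[[1L]]
    toks <- toks[nzchar(toks)]
    plain <- toks[!grepl("^[0-9]+!$", toks)]
    tryCatch(parse_variants(plain), error = function(e) {
      stop("line ", i + 1L, " (", df$node_name[i], "): ",
           conditionMessage(e), call. = FALSE)
    })
    if (df$parent_name[i] == "" && length(toks)) {
      stop("root node '", df$node_name[i], "' must carry an empty motif")
    }
    nodes[[i]] <- list(name = df$node_name[i],
                       parent = if (df$parent_name[i] == "") NA_character_
                                else df$parent_name[i],
                       motif = toks, depth = NA_integer_)
  }
  root <- df$node_name[roots]
  # depths; also detects cycles (cannot occur with single root + known
  # parents unless a node is its own ancestor)
  depth_of <- function(name, seen = character()) {
    if (name %in% seen) stop("cycle in tree at node ", name)
    node <- nodes[[name]]
    if (is.na(node$parent)) 0L
    else 1L + depth_of(node$parent, c(seen, name))
  }
  for (nm in names(nodes)) nodes[[nm]]$depth <- depth_of(nm)
  structure(list(nodes = nodes, root = root), class = "motif_tree")
}

#' @export
print.motif_tree <- function(x, ...) {
  cat(sprintf("<motif_tree> %d nodes, root '%s'\n", length(x$nodes), x$root))
  invisible(x)
}

# Root path of a node, root first.
tree_root_path <- function(tree, node) {
  if (!node %in% names(tree$nodes)) stop("unknown node: ", node)
  path <- character()
  cur <- node
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- tree$nodes[[cur]]$parent
  }
  path
}

#' Is `node` a (proper or improper) descendant of `ancestor`?
#' @param tree a [load_motif_tree()] tree.
#' @param node,ancestor node names.
#' @return logical scalar; TRUE also when `node == ancestor`.
#' @export
is_descendant <- function(tree, node, ancestor) {
  if (!ancestor %in% names(tree$nodes)) stop("unknown node: ", ancestor)
  ancestor %in% tree_root_path(tree, node)
}

#' Cumulative mutational motif of a haplogroup node
#'
#' Applies the branch motifs along the root path sequentially: a later
#' expectation at a position overrides an earlier one, a reversion token
#' `"<pos>!"` cancels the currently expected mutation at that position (and
#' a second reversion re-adds it). Insertion and deletion expectations are
#' keyed by their full token.
#'
#' @param tree a [load_motif_tree()] tree.
#' @param node node name.
#' @param window optional [coord_window()]; when given, the cumulative
#'   motif is restricted to expectations inside the window.
#' @return a [variant_table()] of expected calls.
#' @export
cumulative_motif <- function(tree, node, window = NULL) {
  path <- tree_root_path(tree, node)
  current <- list()  # position key -> token
  shadow <- list()   # last cancelled expectation per position
  for (nm in path) {
    for (tok in tree$nodes[[nm]]$motif) {
      if (grepl("^[0-9]+!$", tok)) {
        key <- sub("!$", "", tok)
        if (!is.null(current[[key]])) {
          shadow[[key]] <- current[[key]]
          current[[key]] <- NULL
        } else if (!is.null(shadow[[key]])) {
          current[[key]] <- shadow[[key]]
          shadow[[key]] <- NULL
        }
      } else {
        v <- parse_variants(tok)
        key <- if (v$kind == "ins") paste0(v$position, ".", v$ins_index)
               else as.character(v$position)
        current[[key]] <- tok
        shadow[[key]] <- NULL
      }
    }
  }
  vars <- parse_variants(unlist(current, use.names = FALSE))
  if (!is.null(window) && nrow(vars)) {
    vars <- vars[window_contains(window, vars$position), , drop = FALSE]
    vars <- variant_table(vars$position, vars$kind, vars$base, vars$ins_index)
  }
  vars
}

# Precompute per-node expected tokens for one window; used by classify.
expected_token_sets <- function(tree, window) {
  lapply(tree$nodes, function(node) {
    exp <- cumulative_motif(tree, node$name, window)
    list(tokens = format_variants(exp), kind = exp$kind,
         position = exp$position, depth = node$depth)
  })
}

#' Classify a haplotype profile into a haplogroup
#'
#' Scores every node of the motif tree against the profile and returns the
#' best match. For a node with cumulative motif E (restricted to the
#' profile's window) and observed variant set O:
#' \deqn{score = (matched - w \cdot missing) / (matched + private)}
#' where `matched` counts expected calls present in O (an observed `N`
#' substitution matches any expected substitution at that position),
#' `missing` the expected-but-absent calls, `private` the observed calls no
#' expectation explains, and `w` (default 0.5) down-weights missing
#' expectations so that window-truncated data are not over-penalized. Ties
#' are broken by greater node depth, then lexicographic name. Because
#' `matched + private = |O|` for every node, the ranking is driven by
#' `matched - w * missing`; a private mutation never reshuffles it.
#'
#' @param profile a masked [haplotype_profile()] (no ambiguity codes other
#'   than N; see [mask_heteroplasmies()]).
#' @param tree a [load_motif_tree()] tree.
#' @param missing_weight penalty weight `w` for expected-in-window but
#'   absent calls.
#' @param expected optional precomputed [expected_token_sets] (internal
#'   use, for bulk classification).
#' @return list of class `classification_result`: `sample_id`,
#'   `haplogroup`, `score`, `matched`, `unmatched_expected`, `private`
#'   (token vectors).
#' @export
classify <- function(profile, tree, missing_weight = 0.5, expected = NULL) {
  if (length(tree$nodes) == 0L) stop("empty motif tree")
  if (any(profile$variants$base %in% IUPAC_AMBIG)) {
    stop("profile contains unmasked ambiguity codes; run mask_heteroplasmies()")
  }
  if (is.null(expected)) expected <- expected_token_sets(tree, profile$window)
  obs <- profile$variants
  obs_tokens <- format_variants(obs)
  obs_n_pos <- obs$position[obs$kind == "sub" & obs$base == "N"]
  n_obs <- length(obs_tokens)

  # expected call matched if observed verbatim, or (substitutions only)
  # observed as an N at the same position
  matched_mask <- function(e) {
    e$tokens %in% obs_tokens |
      (e$kind == "sub" & e$position %in% obs_n_pos)
  }
  best <- NULL
  for (nm in names(expected)) {
    e <- expected[[nm]]
    n_match <- sum(matched_mask(e))
    n_miss <- length(e$tokens) - n_match
    n_priv <- n_obs - n_match
    score <- (n_match - missing_weight * n_miss) / (n_match + n_priv + 1e-9)
    cand <- list(name = nm, score = score, depth = e$depth)
    if (is.null(best) ||
        score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
         (cand$depth > best$depth ||
          (cand$depth == best$depth && nm < best$name)))) {
      best <- cand
    }
  }
  e <- expected[[best$name]]
  m <- matched_mask(e)
  matched_exp <- e$tokens[m]
  matched_sub_pos <- e$position[m & e$kind == "sub"]
  obs_matched <- obs_tokens %in% matched_exp |
    (obs$kind == "sub" & obs$base == "N" & obs$position %in% matched_sub_pos)
  structure(list(sample_id = profile$sample_id,
                 haplogroup = best$name,
                 score = best$score,
                 matched = matched_exp,
                 unmatched_expected = setdiff(e$tokens, matched_exp),
                 private = obs_tokens[!obs_matched]),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s -> %s (score %.3f; %d matched, %d missing, %d private)\n",
              x$sample_id, x$haplogroup, x$score, length(x$matched),
              length(x$unmatched_expected), length(x$private)))
  invisible(x)
}

#' Classify many profiles
#'
#' @param profiles list of masked [haplotype_profile()]s sharing one window.
#' @param tree a [load_motif_tree()] tree.
#' @param macro_table a macro-group table ([load_macro_table()]); when
#'   given, macro-haplogroup and origin columns are filled in.
#' @param missing_weight see [classify()].
#' @return data frame with columns `sample_id`, `population`, `haplogroup`,
#'   `macro`, `origin`, `score`, `private_variants`.
#' @export
classify_all <- function(profiles, tree, macro_table = NULL,
                         missing_weight = 0.5) {
  if (length(profiles) == 0L) {
    return(data.frame(sample_id = character(), population = character(),
                      haplogroup = character(), macro = character(),
                      origin = character(), score = numeric(),
                      private_variants = character()))
  }
  expected <- expected_token_sets(tree, profiles[[1L]]$window)
  rows <- lapply(profiles, function(p) {
    res <- classify(p, tree, missing_weight, expected = expected)
    macro <- origin <- NA_character_
    if (!is.null(macro_table)) {
      macro <- macro_group(res$haplogroup, macro_table)
      origin <- origin_of(macro, macro_table)
    }
    data.frame(sample_id = p$sample_id, population = p$population,
               haplogroup = res$haplogroup, macro = macro, origin = origin,
               score = res$score,
               private_variants = paste(res$private, collapse = " "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
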