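# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from outside the package.

# Packaged resources, loaded once per test run.
pkg_ref <- packaged_reference()
pkg_tree <- load_packaged_tree()
pkg_macro <- load_macro_table()

# A reference whose bases around `at` are overwritten with `pattern`,
# so alignment tests can work against known local sequence.
patched_reference <- function(pattern, at = 101L) {
  chars <- pkg_ref$chars
  pat <- strsplit(pattern, "")[[1]]
  chars[at:(at + length(pat) - 1L)] <- pat
  mt_reference("patched", paste(chars, collapse = ""))
}

# Write a motif-tree TSV from a data.frame(node_name, parent_name, motif)
# and load it.
toy_tree <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(rows, f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_motif_tree(f)
}

tree_rows <- function(...) {
  # rows as c(name, parent, motif) triplets
  args <- list(...)
  do.call(rbind, lapply(args, function(x) {
    data.frame(node_name = x[1], parent_name = x[2], motif = x[3],
               stringsAsFactors = FALSE)
  }))
}

# Random aligned character matrix with optional N/gap contamination.
random_matrix <- function(n, L, n_prob = 0, gap_prob = 0,
                          populations = NULL) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  if (n_prob > 0) m[runif(n * L) < n_prob] <- "N"
  if (gap_prob > 0) m[runif(n * L) < gap_prob] <- "-"
  rownames(m) <- sprintf("s%02d", seq_len(n))
  if (is.null(populations)) {
    populations <- sample(c("popA", "popB"), n, replace = TRUE)
  }
  attr(m, "populations") <- stats::setNames(populations, rownames(m))
  m
}

# Random small rooted motif tree (substitutions only, unique positions),
# returned as its raw rows (for the oracle) plus the loaded tree.
random_toy_tree <- function(n_nodes = 8, seed_positions = 200:400) {
  pool <- sample(seed_positions)
  k <- 0L
  next_tok <- function() {
    k <<- k + 1L
    pos <- pool[k]
    paste0(pos, sample(setdiff(c("A", "C", "G", "T"), ref_base(pkg_ref, pos)), 1))
  }
  rows <- data.frame(node_name = "root", parent_name = "", motif = "",
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_nodes - 1L)) {
    parent <- sample(rows$node_name, 1)
    motif <- paste(replicate(sample(1:2, 1), next_tok()), collapse = " ")
    rows <- rbind(rows, data.frame(node_name = paste0("n", i),
                                   parent_name = parent, motif = motif,
                                   stringsAsFactors = FALSE))
  }
  list(rows = rows, tree = toy_tree(rows))
}

# Random profile over a window: a handful of substitutions (some N).
random_profile <- function(window, n_sub = 3, n_prob = 0.2,
                           id = "r1", pop = "test") {
  pos <- sample(window_positions(window), n_sub)
  base <- vapply(pos, function(p) {
    if (runif(1) < n_prob) "N"
    else sample(setdiff(c("A", "C", "G", "T"), ref_base(pkg_ref, p)), 1)
  }, "")
  haplotype_profile(id, pop, window,
                    variant_table(pos, rep("sub", n_sub), base))
}

# Profiles with prescribed variant token strings (window defaults to the
# 546-bp comparison window).
profile_from_tokens <- function(tokens, id = "p1", pop = "test",
                                window = standard_window("eurasian546")) {
  haplotype_profile(id, pop, window, parse_variants(tokens))
}
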