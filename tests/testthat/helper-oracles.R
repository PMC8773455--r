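# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops, textbook formulas, recursive enumeration.

# --- alignment: enumerate ALL optimal unit-cost global alignments -----
# Returns list(dist = <edit distance>, alignments = list of list(ref, seq)
# as character vectors with "-" gaps). Exponential; use tiny strings only.
oracle_alignments <- function(ref, seq) {
  r <- strsplit(ref, "")[[1]]; s <- strsplit(seq, "")[[1]]
  n <- length(r); m <- length(s)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in 1:n) for (j in 1:m) {
    D[i + 1, j + 1] <- min(D[i, j] + (r[i] != s[j]),
                           D[i, j + 1] + 1L, D[i + 1, j] + 1L)
  }
  walk <- function(i, j) {
    if (i == 0 && j == 0) return(list(list(ref = character(), seq = character())))
    out <- list()
    if (i > 0 && j > 0 && D[i + 1, j + 1] == D[i, j] + (r[i] != s[j])) {
      for (al in walk(i - 1, j - 1)) {
        out <- c(out, list(list(ref = c(al$ref, r[i]), seq = c(al$seq, s[j]))))
      }
    }
    if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + 1L) {
      for (al in walk(i - 1, j)) {
        out <- c(out, list(list(ref = c(al$ref, r[i]), seq = c(al$seq, "-"))))
      }
    }
    if (j > 0 && D[i + 1, j + 1] == D[i + 1, j] + 1L) {
      for (al in walk(i, j - 1)) {
        out <- c(out, list(list(ref = c(al$ref, "-"), seq = c(al$seq, s[j]))))
      }
    }
    out
  }
  list(dist = D[n + 1, m + 1], alignments = walk(n, m))
}

# 3'-most placement applied to one alignment, by repeated single-gap swaps
# (independent re-implementation: bubble every gap right while legal).
oracle_shift_right <- function(al) {
  a <- al$ref; b <- al$seq
  repeat {
    moved <- FALSE
    for (c in seq_along(a)) {
      if (c < length(a) && a[c] == "-" && a[c + 1] != "-" && b[c] == b[c + 1]) {
        a[c] <- a[c + 1]; a[c + 1] <- "-"; moved <- TRUE
      }
      if (c < length(b) && b[c] == "-" && b[c + 1] != "-" && a[c] == a[c + 1]) {
        b[c] <- b[c + 1]; b[c + 1] <- "-"; moved <- TRUE
      }
    }
    if (!moved) break
  }
  list(ref = a, seq = b)
}

# variant tokens of one gapped alignment, positions taken from `positions`
oracle_tokens <- function(al, positions) {
  toks <- character(); ref_i <- 0L; ins_k <- 0L
  for (c in seq_along(al$ref)) {
    if (al$ref[c] == "-") {
      ins_k <- ins_k + 1L
      anchor <- if (ref_i == 0) positions[1] - 1 else positions[ref_i]
      toks <- c(toks, paste0(anchor, ".", ins_k, al$seq[c]))
    } else {
      ref_i <- ref_i + 1L; ins_k <- 0L
      if (al$seq[c] == "-") toks <- c(toks, paste0(positions[ref_i], "del"))
      else if (al$seq[c] != al$ref[c]) {
        toks <- c(toks, paste0(positions[ref_i], al$seq[c]))
      }
    }
  }
  toks
}

# set of canonical token vectors over all optimal alignments
oracle_canonical_calls <- function(ref, seq, positions) {
  res <- oracle_alignments(ref, seq)
  sets <- lapply(res$alignments, function(al) {
    sort(oracle_tokens(oracle_shift_right(al), positions))
  })
  unique(sets)
}

# --- diversity statistics (naive loops) --------------------------------
oracle_usable <- function(mat) {
  keep <- integer()
  for (j in seq_len(ncol(mat))) {
    ok <- TRUE
    for (i in seq_len(nrow(mat))) {
      if (!mat[i, j] %in% c("A", "C", "G", "T")) ok <- FALSE
    }
    if (ok) keep <- c(keep, j)
  }
  keep
}

oracle_segsites <- function(mat, cols = oracle_usable(mat)) {
  s <- 0L
  for (j in cols) if (length(unique(mat[, j])) >= 2) s <- s + 1L
  s
}

oracle_hd <- function(mat, cols = oracle_usable(mat)) {
  n <- nrow(mat)
  haps <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
  p <- as.numeric(table(haps)) / n
  n * (1 - sum(p^2)) / (n - 1)
}

oracle_pi <- function(mat, cols = oracle_usable(mat)) {
  n <- nrow(mat); total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + sum(mat[i, cols] != mat[j, cols])
  }
  total / (choose(n, 2) * length(cols))
}

oracle_p_distance <- function(mat, ia, ib) {
  vals <- c()
  for (i in ia) for (j in ib) {
    ok <- mat[i, ] %in% c("A", "C", "G", "T") & mat[j, ] %in% c("A", "C", "G", "T")
    vals <- c(vals, sum(mat[i, ok] != mat[j, ok]) / sum(ok))
  }
  mean(vals)
}

# --- ordination --------------------------------------------------------
oracle_pca_scores <- function(freq, k) {
  x <- scale(freq, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(x), symmetric = TRUE)
  x %*% eg$vectors[, seq_len(k), drop = FALSE]
}

oracle_mds_coords <- function(d, k) {
  d <- as.matrix(d); n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- seq_len(k)
  sweep(eg$vectors[, keep, drop = FALSE], 2, sqrt(pmax(eg$values[keep], 0)), `*`)
}

# --- sharing -----------------------------------------------------------
oracle_sharing <- function(keys_a, keys_b) {
  A <- unique(keys_a); B <- unique(keys_b)
  shared <- 0L
  for (x in A) if (x %in% B) shared <- shared + 1L
  list(shared = shared, ab = shared / length(A), ba = shared / length(B),
       sym = (shared / length(A) + shared / length(B)) / 2)
}

# --- classification score (recomputed from scratch) --------------------
# sequential application of branch motifs along the root path
oracle_cumulative <- function(tree_rows, node) {
  # tree_rows: data.frame(node_name, parent_name, motif)
  path <- character(); cur <- node
  while (cur != "") {
    path <- c(cur, path)
    cur <- tree_rows$parent_name[tree_rows$node_name == cur]
  }
  state <- list(); hidden <- list()
  for (nm in path) {
    toks <- strsplit(tree_rows$motif[tree_rows$node_name == nm], " +")[[1]]
    for (tok in toks[nzchar(toks)]) {
      if (grepl("!$", tok)) {
        key <- sub("!$", "", tok)
        if (!is.null(state[[key]])) {
          hidden[[key]] <- state[[key]]; state[[key]] <- NULL
        } else if (!is.null(hidden[[key]])) {
          state[[key]] <- hidden[[key]]; hidden[[key]] <- NULL
        }
      } else {
        key <- sub("^([0-9]+).*", "\\1", tok)
        if (grepl("\\.", tok)) key <- sub("^([0-9]+\\.[0-9]+).*", "\\1", tok)
        state[[key]] <- tok; hidden[[key]] <- NULL
      }
    }
  }
  out <- unlist(state, use.names = FALSE)
  if (is.null(out)) character(0) else sort(out)
}

oracle_best_node <- function(tree_rows, obs_tokens, in_window, w = 0.5) {
  # in_window: function(position) -> logical; obs_tokens canonical
  obs_pos_n <- as.integer(sub("^([0-9]+).*", "\\1",
                              obs_tokens[grepl("^[0-9]+N$", obs_tokens)]))
  depth_of <- function(nm) {
    d <- 0L
    while (nm != "") {
      nm <- tree_rows$parent_name[tree_rows$node_name == nm]; d <- d + 1L
    }
    d - 1L
  }
  best <- NULL
  for (nm in tree_rows$node_name) {
    exp_toks <- oracle_cumulative(tree_rows, nm)
    exp_toks <- exp_toks[in_window(as.integer(sub("^([0-9]+).*", "\\1", exp_toks)))]
    matched <- 0L
    for (tok in exp_toks) {
      pos <- as.integer(sub("^([0-9]+).*", "\\1", tok))
      is_sub <- grepl("^[0-9]+[A-Z]$", tok)
      if (tok %in% obs_tokens || (is_sub && pos %in% obs_pos_n)) {
        matched <- matched + 1L
      }
    }
    miss <- length(exp_toks) - matched
    priv <- length(obs_tokens) - matched
    score <- (matched - w * miss) / (matched + priv + 1e-9)
    d <- depth_of(nm)
    if (is.null(best) || score > best$score + 1e-12 ||
        (abs(score - best$score) <= 1e-12 &&
         (d > best$depth || (d == best$depth && nm < best$name)))) {
      best <- list(name = nm, score = score, depth = d)
    }
  }
  best
}

# --- ancient tracing rule table ---------------------------------------
oracle_trace_status <- function(band_dates, cutoff) {
  if (length(band_dates) == 0) return("absent_in_band")
  if (min(band_dates) <= cutoff) "pre_cutoff_presence" else "post_cutoff_arrival"
}
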