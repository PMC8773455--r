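test_that("motif tree loading validates structure", {
  rows <- tree_rows(c("root", "", ""),
                    c("H", "root", "7028T 263G"),
                    c("H1", "H", "3010A"))
  tr <- toy_tree(rows)
  expect_equal(length(tr$nodes), 3L)
  expect_equal(tr$root, "root")
  expect_equal(tr$nodes$H1$depth, 2L)
  # orphan parent
  expect_error(toy_tree(tree_rows(c("root", "", ""), c("A", "zzz", "73G"))),
               "unknown parent")
  # duplicate names
  expect_error(toy_tree(tree_rows(c("root", "", ""), c("A", "root", "73G"),
                                  c("A", "root", "146C"))),
               "duplicate")
  # two roots
  expect_error(toy_tree(tree_rows(c("r1", "", ""), c("r2", "", ""))),
               "exactly one root")
  # bad motif token carries a line number
  expect_error(toy_tree(tree_rows(c("root", "", ""), c("A", "root", "73Q"))),
               "line 3")
  # packaged fixture sanity: loads, has EAs and WEu leaves
  origins <- vapply(names(pkg_tree$nodes), function(n)
    origin_of(macro_group(n, pkg_macro), pkg_macro), "")
  expect_true(sum(origins == "EAs") > 0 && sum(origins == "WEu") > 0)
})

test_that("cumulative motifs accumulate, override and revert sequentially", {
  rows <- tree_rows(c("root", "", ""),
                    c("H", "root", "7028T 263G"),
                    c("H1", "H", "3010A"),
                    c("H1x", "H1", "16189C"),
                    c("H1xr", "H1x", "16189!"),
                    c("H1xrr", "H1xr", "16189!"))
  tr <- toy_tree(rows)
  expect_equal(nrow(cumulative_motif(tr, "root")), 0L)
  expect_setequal(format_variants(cumulative_motif(tr, "H1")),
                  c("263G", "3010A", "7028T"))
  # window restriction
  expect_equal(format_variants(cumulative_motif(tr, "H1x",
                                                standard_window("hvs1"))),
               "16189C")
  # reversion removes, double reversion re-adds
  expect_false("16189C" %in% format_variants(cumulative_motif(tr, "H1xr")))
  expect_true("16189C" %in% format_variants(cumulative_motif(tr, "H1xrr")))
  expect_error(cumulative_motif(tr, "nope"), "unknown node")
  # sequential-application oracle on random toy trees
  set.seed(11)
  for (rep in 1:10) {
    tt <- random_toy_tree(n_nodes = 7)
    for (nm in tt$rows$node_name) {
      expect_equal(sort(format_variants(cumulative_motif(tt$tree, nm))),
                   oracle_cumulative(tt$rows, nm))
    }
  }
})

test_that("classification matches the exhaustive-scoring oracle", {
  set.seed(23)
  w <- coord_window(150L, 450L)
  for (rep in 1:30) {
    tt <- random_toy_tree(n_nodes = sample(4:12, 1), seed_positions = 150:450)
    prof <- random_profile(w, n_sub = sample(0:5, 1), n_prob = 0.3,
                           id = sprintf("r%02d", rep))
    got <- classify(prof, tt$tree)
    want <- oracle_best_node(tt$rows, format_variants(prof$variants),
                             function(p) window_contains(w, p))
    expect_equal(got$haplogroup, want$name)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("classification is order-invariant and robust to private variants", {
  w <- standard_window("cr")
  m <- cumulative_motif(pkg_tree, "U5a1", w)
  base_prof <- haplotype_profile("x", "t", w, m)
  expect_equal(classify(base_prof, pkg_tree)$haplogroup, "U5a1")
  # evidence partition: matched + private = observed
  res <- classify(base_prof, pkg_tree)
  expect_setequal(c(res$matched, res$private), format_variants(m))
  # add a private variant at a position no motif uses: winner unchanged
  motif_pos <- unique(unlist(lapply(pkg_tree$nodes, function(n)
    as.integer(sub("^([0-9]+).*", "\\1", n$motif)))))
  free <- setdiff(window_positions(w), motif_pos)[1]
  vb <- setdiff(c("A", "C", "G", "T"), ref_base(pkg_ref, free))[1]
  aug <- variant_table(c(m$position, free), c(m$kind, "sub"),
                       c(m$base, vb), c(m$ins_index, NA))
  res2 <- classify(haplotype_profile("x", "t", w, aug), pkg_tree)
  expect_equal(res2$haplogroup, "U5a1")
  expect_equal(res2$private, format_variants(parse_variants(paste0(free, vb))))
  # N at an expected position still matches
  nvar <- m
  nvar$base[1] <- "N"
  resN <- classify(haplotype_profile("x", "t", w,
                                     variant_table(nvar$position, nvar$kind,
                                                   nvar$base, nvar$ins_index)),
                   pkg_tree)
  expect_equal(resN$haplogroup, "U5a1")
  # unmasked ambiguity codes are rejected
  amb <- variant_table(16189, "sub", "Y")
  expect_error(classify(haplotype_profile("x", "t", w, amb), pkg_tree),
               "mask_heteroplasmies")
})

test_that("empty profiles classify to the reference haplogroup", {
  for (nm in c("cr", "hvs1")) {
    w <- standard_window(nm)
    res <- classify(haplotype_profile("e", "t", w), pkg_tree)
    expect_equal(res$haplogroup, pkg_tree$root)
  }
})

test_that("macro-grouping follows longest-prefix rules over the 18 labels", {
  expect_equal(macro_group("H", pkg_macro), "R0")
  expect_equal(macro_group("H1j", pkg_macro), "R0")
  expect_equal(macro_group("D4", pkg_macro), "D")
  expect_equal(macro_group("J1b1b1", pkg_macro), "JT")
  expect_equal(macro_group("J1b2", pkg_macro), "JT")
  expect_equal(macro_group("C4a", pkg_macro), "M8")
  expect_equal(macro_group("M7b", pkg_macro), "M7")   # beats prefix M
  expect_equal(macro_group("M10", pkg_macro), "M*")
  expect_error(macro_group("Q1", pkg_macro), "no macro-group prefix")
  # longest-match uniqueness oracle: apply every rule by hand
  for (nm in c("C4a", "M7b", "HV13b1", "N9a", "R11", "U5b1c2")) {
    hits <- pkg_macro$prefix[startsWith(nm, pkg_macro$prefix)]
    expect_equal(sum(nchar(hits) == max(nchar(hits))), 1L, info = nm)
    expect_equal(macro_group(nm, pkg_macro),
                 pkg_macro$macro[pkg_macro$prefix ==
                                   hits[which.max(nchar(hits))]])
  }
  # totality over every node of the packaged tree
  for (nm in names(pkg_tree$nodes)) expect_silent(macro_group(nm, pkg_macro))
})

test_that("origin classes partition the 18 macro-haplogroups", {
  expect_equal(origin_of("R0", pkg_macro), "WEu")
  expect_equal(origin_of(macro_group("C", pkg_macro), pkg_macro), "EAs")
  expect_error(origin_of("Z9", pkg_macro), "unknown")
  macros <- unique(pkg_macro$macro)
  expect_equal(length(macros), 18L)
  origins <- vapply(macros, origin_of, "", table = pkg_macro)
  expect_setequal(unique(origins), c("EAs", "WEu"))
  expect_setequal(names(origins)[origins == "WEu"],
                  c("JT", "N1", "N2", "R0", "U", "X"))
})
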