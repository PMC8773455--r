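test_that("haplotype keys canonicalize variant order and window", {
  w <- standard_window("eurasian546")
  a <- profile_from_tokens(c("16189C", "16224C"), id = "a", pop = "p")
  b <- haplotype_profile("b", "p", w, parse_variants(c("16224C", "16189C")))
  expect_identical(haplotype_key(a, w), haplotype_key(b, w))
  # restriction: CR-window profile keyed on the 546-bp window drops np 310
  cr <- profile_from_tokens(c("310C", "16189C"), id = "c", pop = "p",
                            window = standard_window("cr"))
  expect_identical(haplotype_key(cr, w), "16189C")
  # N is a literal character: N-masked and explicit calls differ
  n1 <- profile_from_tokens("16189N", id = "d", pop = "p")
  expect_false(identical(haplotype_key(n1, w), haplotype_key(a, w)))
})

test_that("sharing ratios follow the paired-group definition", {
  sets <- list(A = c("h1", "h2", "h3"), B = c("h2", "h3", "h4", "h5"))
  sr <- sharing_ratio(sets, "A", "B")
  expect_equal(sr$shared, 2L)
  expect_equal(sr$ratio_ab, 2 / 3, tolerance = 1e-9)
  expect_equal(sr$ratio_ba, 0.5)
  expect_equal(sr$ratio_sym, (2 / 3 + 1 / 2) / 2)
  o <- oracle_sharing(sets$A, sets$B)
  expect_equal(sr$ratio_sym, o$sym)
  # identical and disjoint populations
  same <- list(X = c("k1", "k2"), Y = c("k1", "k2"))
  expect_equal(sharing_ratio(same, "X", "Y")$ratio_sym, 1.0)
  disj <- list(X = c("k1"), Y = c("k2"))
  expect_equal(sharing_ratio(disj, "X", "Y")$ratio_sym, 0.0)
  expect_error(sharing_ratio(sets, "A", "Z"), "not in sets")
  expect_error(sharing_ratio(list(A = character(), B = "h"), "A", "B"),
               "empty")
})

test_that("adding haplotypes moves ratios the right way", {
  set.seed(19)
  for (rep in 1:10) {
    A <- paste0("h", sample(50, 8))
    B <- c(sample(A, 3), paste0("x", 1:4))
    sets <- list(A = unique(A), B = unique(B))
    base <- sharing_ratio(sets, "A", "B")
    # adding an A-and-B haplotype to B: shared unchanged
    sets2 <- list(A = sets$A, B = unique(c(sets$B, sets$B[1])))
    expect_equal(sharing_ratio(sets2, "A", "B")$shared, base$shared)
    # adding a novel haplotype to B strictly decreases ratio_ba
    sets3 <- list(A = sets$A, B = c(sets$B, "zz_novel"))
    expect_lt(sharing_ratio(sets3, "A", "B")$ratio_ba, base$ratio_ba)
    # symmetry
    expect_equal(sharing_ratio(sets, "A", "B")$ratio_sym,
                 sharing_ratio(sets, "B", "A")$ratio_sym)
  }
})

test_that("haplotype sets dedup samples and honor the origin filter", {
  w <- standard_window("eurasian546")
  profs <- list(
    profile_from_tokens("16189C", id = "s1", pop = "p1"),
    haplotype_profile("s2", "p1", w, parse_variants("16189C")),  # same key
    profile_from_tokens("16224C", id = "s3", pop = "p1"),
    profile_from_tokens("16189C", id = "s4", pop = "p2"),
    profile_from_tokens(character(), id = "s5", pop = "p2"))
  sets <- haplotype_sets(profs, w)
  expect_equal(sort(lengths(sets)), sort(c(p1 = 2L, p2 = 2L)))
  # brute-force dedup count
  expect_equal(length(sets$p1), length(unique(c("16189C", "16189C", "16224C"))))
  # origin filter needs classifications
  expect_error(haplotype_sets(profs, w, origin_filter = "WEu"), "classifications")
  cl <- data.frame(sample_id = paste0("s", 1:5),
                   origin = c("WEu", "WEu", "EAs", "EAs", "WEu"),
                   stringsAsFactors = FALSE)
  weu <- haplotype_sets(profs, w, origin_filter = "WEu", classifications = cl)
  expect_equal(weu$p1, "16189C")        # the EAs sample s3 is dropped
  eas <- haplotype_sets(profs, w, origin_filter = "EAs", classifications = cl)
  expect_equal(eas$p1, "16224C")
})

test_that("sharing matrices are symmetric and match looped ratios", {
  sets <- list(a = c("h1", "h2"), b = c("h2", "h3", "h4"), c = c("h5"))
  sm <- sharing_matrix(sets)
  expect_equal(dim(sm$ratio), c(3L, 3L))
  expect_equal(sm$ratio, t(sm$ratio))
  expect_equal(diag(sm$shared), c(a = 2L, b = 3L, c = 1L))
  for (i in 1:2) for (j in (i + 1):3) {
    pops <- sort(names(sets))
    expect_equal(sm$ratio[pops[i], pops[j]],
                 sharing_ratio(sets, pops[i], pops[j])$ratio_sym)
  }
  expect_error(sharing_matrix(sets["a"]), "at least 2")
})

test_that("origin-partitioned shared counts add up to the overall count", {
  # every haplotype has a unique origin class by construction
  set.seed(20)
  w <- standard_window("eurasian546")
  pos <- window_positions(w)
  mk <- function(id, pop, p) {
    b <- setdiff(c("A", "C", "G", "T"), ref_base(pkg_ref, p))[1]
    profile_from_tokens(paste0(p, b), id = id, pop = pop)
  }
  # pool of 12 haplotypes: first 6 WEu, last 6 EAs; populations overlap
  hpos <- sample(pos, 12)
  profs <- list(); cl <- list(); k <- 0
  for (pop in c("p1", "p2")) {
    for (i in sample(12, 9)) {
      k <- k + 1
      id <- sprintf("s%02d", k)
      profs[[k]] <- mk(id, pop, hpos[i])
      cl[[k]] <- data.frame(sample_id = id,
                            origin = if (i <= 6) "WEu" else "EAs",
                            stringsAsFactors = FALSE)
    }
  }
  cl <- do.call(rbind, cl)
  s_all <- sharing_matrix(haplotype_sets(profs, w))
  s_weu <- sharing_matrix(haplotype_sets(profs, w, "WEu", cl), "WEu")
  s_eas <- sharing_matrix(haplotype_sets(profs, w, "EAs", cl), "EAs")
  expect_equal(s_all$shared["p1", "p2"],
               s_weu$shared["p1", "p2"] + s_eas$shared["p1", "p2"])
})
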