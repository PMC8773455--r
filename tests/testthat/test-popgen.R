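test_that("complete-deletion column filter matches a brute-force scan", {
  set.seed(5)
  m <- random_matrix(8, 30, n_prob = 0.02, gap_prob = 0.02)
  expect_equal(usable_columns(m), oracle_usable(m))
  # a single N knocks out exactly its column
  clean <- random_matrix(6, 20)
  expect_equal(usable_columns(clean), 1:20)
  clean[3, 7] <- "N"
  expect_equal(usable_columns(clean), setdiff(1:20, 7))
})

test_that("segregating sites counted per polymorphic usable column", {
  m <- matrix("A", 4, 10)
  expect_equal(segregating_sites(m), 0L)
  m[1, c(2, 5, 9)] <- "G"
  expect_equal(segregating_sites(m), 3L)
  set.seed(6)
  for (rep in 1:20) {
    r <- random_matrix(8, 30, n_prob = 0.02)
    expect_equal(segregating_sites(r), oracle_segsites(r))
  }
})

test_that("haplotype diversity follows the unbiased formula", {
  all_same <- matrix("A", 5, 12)
  expect_equal(haplotype_diversity(all_same), 0)
  set.seed(8)
  distinct <- random_matrix(7, 40)           # distinct almost surely
  expect_equal(haplotype_diversity(distinct), 1.0)
  # counts {2,1,1}, n = 4: Hd = (4/3)(1 - 6/16) = 0.8333...
  m <- rbind(c("A", "A"), c("A", "A"), c("A", "C"), c("C", "C"))
  expect_equal(haplotype_diversity(m), (4 / 3) * (1 - 6 / 16))
  expect_equal(haplotype_diversity(m), 0.833333, tolerance = 1e-6)
  expect_error(haplotype_diversity(m[1, , drop = FALSE]), "at least 2")
  for (rep in 1:10) {
    r <- random_matrix(8, 25, n_prob = 0.05)
    expect_equal(haplotype_diversity(r), oracle_hd(r), tolerance = 1e-12)
  }
})

test_that("nucleotide diversity equals the all-pairs average", {
  expect_equal(nucleotide_diversity(matrix("G", 4, 9)), 0)
  # 2 rows, 2 diffs over 100 usable columns -> 0.02
  m <- matrix("A", 2, 100)
  m[2, c(10, 60)] <- "T"
  expect_equal(nucleotide_diversity(m), 0.02)
  set.seed(9)
  for (rep in 1:15) {
    r <- random_matrix(6, 50, n_prob = 0.03)
    expect_equal(nucleotide_diversity(r), oracle_pi(r), tolerance = 1e-12)
  }
  allN <- matrix("N", 3, 5)
  expect_error(nucleotide_diversity(allN), "usable")
})

test_that("Hd and Pi are invariant under row and column permutation", {
  set.seed(10)
  m <- random_matrix(9, 30, n_prob = 0.03)
  pr <- sample(nrow(m)); pc <- sample(ncol(m))
  m2 <- m[pr, pc]
  attr(m2, "populations") <- attr(m, "populations")[pr]
  expect_equal(haplotype_diversity(m2), haplotype_diversity(m))
  expect_equal(nucleotide_diversity(m2), nucleotide_diversity(m))
  expect_equal(segregating_sites(m2), segregating_sites(m))
  # Pi <= S/L on random matrices; duplicating every row keeps the
  # haplotype spectrum, so Hd moves from n/(n-1) toward the 2n/(2n-1)
  # correction of the same 1 - sum p^2
  for (rep in 1:10) {
    r <- random_matrix(7, 20)
    L <- length(usable_columns(r))
    expect_lte(nucleotide_diversity(r), segregating_sites(r) / L)
    doubled <- r[rep(seq_len(nrow(r)), 2), ]
    haps <- apply(r, 1, paste, collapse = "")
    p <- as.numeric(table(haps)) / nrow(r)
    n2 <- 2 * nrow(r)
    expect_equal(haplotype_diversity(doubled),
                 n2 * (1 - sum(p^2)) / (n2 - 1), tolerance = 1e-12)
    expect_lte(haplotype_diversity(doubled), haplotype_diversity(r))
    expect_equal(haplotype_diversity(doubled), oracle_hd(doubled))
  }
})

test_that("mean p-distance uses pairwise deletion and is symmetric", {
  m <- rbind(a = c("A", "A", "A", "A"),
             b = c("A", "A", "A", "T"),
             c = c("T", "T", "T", "T"))
  attr(m, "populations") <- c(a = "g1", b = "g2", c = "g2")
  # hand oracle: d(a,b) = 1/4; d(a,c) = 4/4; mean = 0.625
  expect_equal(mean_p_distance(m, "g1", "g2"), mean(c(1 / 4, 1)))
  expect_equal(mean_p_distance(m, "g2", "g1"), mean_p_distance(m, "g1", "g2"))
  # identical single-sequence groups
  id <- rbind(x = c("A", "C"), y = c("A", "C"))
  attr(id, "populations") <- c(x = "p", y = "q")
  expect_equal(mean_p_distance(id, "p", "q"), 0)
  # per-pair comparable columns (pairwise deletion)
  pn <- rbind(x = c("A", "N", "G"), y = c("T", "C", "N"))
  attr(pn, "populations") <- c(x = "p", y = "q")
  expect_equal(mean_p_distance(pn, "p", "q"), 1)  # only column 1 comparable
  # zero comparable columns is an error naming the pair
  z <- rbind(x = c("A", "N"), y = c("N", "C"))
  attr(z, "populations") <- c(x = "p", y = "q")
  expect_error(mean_p_distance(z, "p", "q"), "x.*y")
  # random matrices against the naive oracle
  set.seed(12)
  for (rep in 1:15) {
    r <- random_matrix(8, 30, n_prob = 0.05)
    pops <- attr(r, "populations")
    if (length(unique(pops)) < 2) next
    ia <- which(pops == "popA"); ib <- which(pops == "popB")
    expect_equal(mean_p_distance(r, "popA", "popB"),
                 oracle_p_distance(r, ia, ib), tolerance = 1e-12)
  }
})

test_that("distance matrices drop small populations and match looped calls", {
  set.seed(13)
  pops <- rep(c("big1", "big2", "small"), c(8, 8, 3))
  m <- random_matrix(19, 25, populations = pops)
  expect_warning(d <- build_distance_matrix(m, min_n = 5), "small")
  expect_equal(dim(d), c(2L, 2L))
  expect_equal(diag(d), c(big1 = 0, big2 = 0))
  expect_equal(d["big1", "big2"], mean_p_distance(m, "big1", "big2"))
  expect_equal(d, t(d))
  expect_error(suppressWarnings(build_distance_matrix(m, min_n = 10)),
               "fewer than 2")
})

test_that("aligned matrices materialize variants over the window", {
  w <- standard_window("hvs1")
  profs <- list(
    profile_from_tokens(c("16189N", "16224C"), id = "a", pop = "p1", window = w),
    profile_from_tokens("16189C", id = "b", pop = "p1", window = w),
    profile_from_tokens(c("16126del", "16193.1C"), id = "c", pop = "p2",
                        window = w))
  m <- build_aligned_matrix(profs, pkg_ref, w)
  expect_equal(nrow(m), 3L)
  expect_equal(ncol(m), window_length(w) + 1L)   # one insertion column
  expect_equal(m["a", "16189"], "N")
  expect_equal(m["b", "16189"], "C")
  expect_equal(m["c", "16126"], "-")
  expect_equal(m["c", "16193.1"], "C")
  expect_equal(m["a", "16193.1"], "-")
  # untouched cells carry the reference base
  expect_equal(m["a", "16050"], ref_base(pkg_ref, 16050))
  # the N/gap columns are excluded from usable columns
  cols <- colnames(m)[usable_columns(m)]
  expect_false(any(c("16189", "16126", "16193.1") %in% cols))
  # per-population summary shape
  ds <- diversity_summary(m)
  expect_setequal(ds$population, c("p1", "p2", "overall"))
  expect_equal(ds$n[ds$population == "overall"], 3L)
})
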