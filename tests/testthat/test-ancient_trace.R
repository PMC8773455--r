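rec <- function(id, hg, date, lon, lat = 46, site = "site") {
  data.frame(record_id = id, haplogroup = hg, date_ce = date,
             longitude = lon, latitude = lat, site = site,
             stringsAsFactors = FALSE)
}

test_that("lineage matching honors clade-name token boundaries", {
  expect_true(lineage_match("U4b1a4", "U4b1a4"))
  expect_true(lineage_match("H5a1a", "H5a1"))
  expect_false(lineage_match("H51", "H5"))
  expect_false(lineage_match("HV13", "HV1"))
  expect_true(lineage_match("T2g1a", "T2g"))
  expect_false(lineage_match("T2g1a", "T1"))
  # oracle over a toy name list: descendant names extend by switching
  # character class at the boundary
  names_ok <- list(c("J1b2a", "J1b2"), c("U2e1a1", "U2e1"), c("K1a", "K1"))
  names_no <- list(c("J1b21", "J1b2"), c("U2e11", "U2e1"), c("K11", "K1"))
  for (p in names_ok) expect_true(lineage_match(p[1], p[2]), info = p[1])
  for (p in names_no) expect_false(lineage_match(p[1], p[2]), info = p[1])
  # tree mode resolves nested clades through topology
  expect_true(lineage_match("J1b1b1", "JT", tree = pkg_tree))
  expect_true(lineage_match("HV13b1", "HV", tree = pkg_tree))
  expect_false(lineage_match("J1b1b1", "U", tree = pkg_tree))
  expect_error(lineage_match("ZZZ9", "JT", tree = pkg_tree), "unresolvable")
})

test_that("trace_lineage applies the band/cutoff/offset rule table", {
  band <- c(85, 125)
  # pre-cutoff presence
  r1 <- rbind(rec("a", "H5a1", -1500, 100), rec("b", "H5a1", -800, 45))
  t1 <- trace_lineage("H5a1", r1, band)
  expect_equal(t1$status, "pre_cutoff_presence")
  expect_equal(t1$earliest_in_band$record_id, "a")
  # post-cutoff with precursor 55 degrees west: NOT route-consistent
  r2 <- rbind(rec("w", "H5a1", -800, 45), rec("m", "H5a1", -500, 100))
  t2 <- trace_lineage("H5a1", r2, band)
  expect_equal(t2$status, "post_cutoff_arrival")
  expect_equal(t2$lon_offset, 55)
  expect_false(t2$route_consistent)
  # same but precursor at 70 E: offset 30, consistent
  r3 <- rbind(rec("w", "H5a1", -800, 70), rec("m", "H5a1", -500, 100))
  t3 <- trace_lineage("H5a1", r3, band)
  expect_true(t3$route_consistent)
  expect_equal(t3$lon_offset, 30)
  # precursor must strictly predate the band arrival
  r4 <- rbind(rec("w", "H5a1", -400, 70), rec("m", "H5a1", -500, 100))
  expect_false(trace_lineage("H5a1", r4, band)$route_consistent)
  # absent in band
  t5 <- trace_lineage("H5a1", rec("w", "H5a1", -800, 45), band)
  expect_equal(t5$status, "absent_in_band")
  expect_false(t5$route_consistent)
  expect_error(trace_lineage("H5a1", r2[0, ], band), "empty")
})

test_that("tracing is record-order invariant and cutoff-monotone", {
  set.seed(21)
  recs <- rbind(rec("a", "U4d2", -1200, 95), rec("b", "U4d2", -400, 110),
                rec("c", "U4d2", -2000, 60), rec("d", "U4d2", 300, 120),
                rec("e", "U4d2a", -900, 100))
  base <- trace_lineage("U4d2", recs)
  for (rep in 1:5) {
    sh <- recs[sample(nrow(recs)), ]
    got <- trace_lineage("U4d2", sh)
    expect_equal(got$status, base$status)
    expect_equal(got$earliest_in_band$record_id, base$earliest_in_band$record_id)
    expect_equal(got$lon_offset, base$lon_offset)
  }
  # moving the cutoff earlier never flips post -> pre
  for (cut in c(-500, -1000, -2000, -3000)) {
    st <- trace_lineage("U4d2", recs, cutoff_ce = cut)$status
    if (st == "post_cutoff_arrival") {
      expect_equal(trace_lineage("U4d2", recs, cutoff_ce = cut - 500)$status,
                   "post_cutoff_arrival")
    }
  }
  # earliest-dated precursor wins; date ties break westernmost
  tie <- rbind(rec("m", "I1c", -500, 100), rec("w1", "I1c", -900, 75),
               rec("w2", "I1c", -900, 70), rec("w3", "I1c", -600, 72))
  tt <- trace_lineage("I1c", tie)
  expect_equal(tt$earliest_western_precursor$record_id, "w2")
})

test_that("trace reports aggregate statuses and route flags", {
  recs <- rbind(
    rec("p1", "H1b", -1500, 95), rec("p2", "K1", -2200, 100),
    rec("q1", "J1b2", -450, 100), rec("q1w", "J1b2", -800, 68),
    rec("q2", "U4b1a4", -400, 110), rec("q2w", "U4b1a4", -600, 78),
    rec("q3", "U5b1c2", -250, 106))
  tr <- trace_report(c("H1b", "K1", "J1b2", "U4b1a4", "U5b1c2", "X2b"), recs)
  expect_equal(tr$summary$pre_cutoff_presence, 2L)
  expect_equal(tr$summary$post_cutoff_arrival, 3L)
  expect_equal(tr$summary$absent_in_band, 1L)
  expect_equal(tr$summary$route_consistent, 2L)
  expect_setequal(tr$results$lineage[tr$results$route_consistent],
                  c("J1b2", "U4b1a4"))
  # statuses match the hand rule per lineage
  for (lg in c("H1b", "K1", "J1b2", "U4b1a4", "U5b1c2")) {
    hit <- vapply(recs$haplogroup, lineage_match, logical(1), lineage = lg)
    in_band <- recs$date_ce[hit & recs$longitude >= 85 & recs$longitude <= 125]
    expect_equal(tr$results$status[tr$results$lineage == lg],
                 oracle_trace_status(in_band, -1000))
  }
  # empty lineage list
  empty <- trace_report(character(), recs)
  expect_equal(nrow(empty$results), 0L)
})

test_that("ancient tables load with BP conversion and validation", {
  f <- tempfile(fileext = ".tsv")
  df <- rec("r1", "U5a1", NA, 101)
  df$date_ce <- NULL
  df$date_bp <- 4950
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_ancient_table(f)
  expect_equal(got$date_ce, -3000)   # 1950 datum
  bad <- rec("r2", "H", -60000, 50)
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ancient_table(f), "date_ce")
  bad2 <- rec("r3", "H", -500, 200)
  utils::write.table(bad2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ancient_table(f), "longitude")
})
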