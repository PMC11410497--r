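test_that("well-formed visit logs read, sort and round-trip losslessly", {
  v <- mk_visits(c("c1", "c2", "c3"), c("B2", "B1", "B1"),
                 c(300, 0, 200), c(360, 100, 260), intake = c(1.5, 2, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_visit_log(validate_visits(v), path)
  got <- read_visit_log(path)
  expect_equal(nrow(got), 3L)
  expect_equal(nrow(attr(got, "rejections")), 0L)
  # canonical (bin_id, start) order
  expect_equal(got$bin_id, c("B1", "B1", "B2"))
  expect_true(!is.unsorted(got$start[got$bin_id == "B1"]))
  # round trip field for field
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_visit_log(got, path2)
  again <- read_visit_log(path2)
  attr(got, "rejections") <- attr(again, "rejections") <- NULL
  expect_equal(again, got)
})

test_that("invariant-violating rows are rejected with reasons", {
  v <- rbind(
    mk_visits("c1", "B1", 0, 100),          # fine
    mk_visits("c2", "B1", 150, 150),        # end == start
    mk_visits("c3", "B1", 200, 300),        # fine
    mk_visits("c4", "B1", 250, 400),        # overlaps previous at B1
    mk_visits("c5", "B2", 0, 50, intake = -1))  # negative intake
  out <- validate_visits(v)
  rej <- attr(out, "rejections")
  expect_equal(nrow(out), 2L)
  expect_setequal(rej$reason, c("end <= start", "overlaps previous visit at bin",
                                "missing or negative intake"))
})

test_that("overlap rejection matches a brute-force pairwise scan", {
  set.seed(42)
  for (trial in 1:5) {
    n <- 40
    v <- mk_visits(sprintf("c%d", sample(5, n, TRUE)),
                   sprintf("B%d", sample(2, n, TRUE)),
                   start_s <- sample(0:2000, n), start_s + sample(20:400, n, TRUE))
    out <- validate_visits(v)
    # oracle: every kept pair at one bin must be disjoint
    for (b in unique(out$bin_id)) {
      vb <- out[out$bin_id == b, ]
      if (nrow(vb) < 2) next
      for (i in seq_len(nrow(vb) - 1)) for (j in (i + 1):nrow(vb)) {
        disjoint <- vb$end[i] <= vb$start[j] || vb$end[j] <= vb$start[i]
        expect_true(disjoint)
      }
    }
    # greedy keep-earlier rule: a row is rejected only if it overlaps a kept one
    expect_true(all(table(paste(out$bin_id, out$start)) == 1))
  }
})

test_that("missing columns and malformed timestamps are flagged", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("animal_id,bin_id,start,end,intake_kg\nc1,B1,x,y,1", path)
  expect_error(read_visit_log(path), "missing required column")
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,bin_id,bin_type,start,end,intake_kg",
               "c1,B1,drinker,not-a-time,2020-07-01 00:01:00,1"), path2)
  got <- read_visit_log(path2)
  expect_equal(nrow(got), 0L)
  expect_equal(attr(got, "rejections")$reason, "unparseable timestamp")
  expect_equal(attr(got, "rejections")$line, 2L)
})

test_that("climate logs are sorted, bounded and non-empty", {
  path <- withr::local_tempfile(fileext = ".csv")
  ts <- format(base_ts + c(600, 0, 300, 900, 1200), "%Y-%m-%d %H:%M:%S")
  writeLines(c("timestamp,temp_c,rh_pct",
               paste(ts, c(20, 21, 22, 23, 24), c(50, 101, 60, 70, 80),
                     sep = ",")), path)
  got <- read_climate_log(path)
  expect_equal(nrow(got), 4L)  # rh=101 rejected
  expect_true(!is.unsorted(got$timestamp))
  expect_match(attr(got, "rejections")$reason, "rh outside")

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("timestamp,temp_c,rh_pct", empty)
  expect_error(read_climate_log(empty), "empty")
})

test_that("exclusions: day and bin rules, idempotence, order independence", {
  v <- validate_visits(mk_visits(
    sprintf("c%d", 1:10), rep(c("B1", "B2"), 5),
    (0:9) * 86400, (0:9) * 86400 + 60))  # one visit per day, alternating bins
  expect_equal(nrow(apply_exclusions(v, list())), 10L)
  all_rule <- exclusion_rule("2020-07-01", "2020-07-10")
  expect_equal(nrow(apply_exclusions(v, all_rule)), 0L)

  # rule matching 3 records: B1 on days 1,3,5 (2020-07-01/03/05)
  r1 <- exclusion_rule("2020-07-01", "2020-07-05", "B1")
  out <- apply_exclusions(v, r1)
  expect_equal(nrow(out), 7L)
  expect_equal(attr(out, "n_removed"), 3L)
  # brute-force membership check
  d <- as.Date(format(v$start, "%Y-%m-%d", tz = "UTC"))
  keep_oracle <- !(d >= as.Date("2020-07-01") & d <= as.Date("2020-07-05") &
                     v$bin_id == "B1")
  expect_equal(out$animal_id, v$animal_id[keep_oracle])

  r2 <- exclusion_rule("2020-07-08", "2020-07-09")
  a <- apply_exclusions(apply_exclusions(v, r1), r2)
  b <- apply_exclusions(v, list(r2, r1))
  c2 <- apply_exclusions(b, list(r1, r2))  # idempotent
  expect_equal(a$start, b$start)
  expect_equal(b$start, c2$start)
  expect_error(exclusion_rule("2020-07-05", "2020-07-01"), "start_date")
})
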