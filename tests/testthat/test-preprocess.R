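make_record <- function(patient = "A", nights = 1L, drop_slots = list()) {
  ts0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  rows <- list()
  for (d in seq_len(nights)) {
    drop <- if (d <= length(drop_slots)) drop_slots[[d]] else integer(0)
    slots <- setdiff(seq_len(72L), drop)
    t <- ts0 + (d - 1L) * 86400 + (slots - 1L) * 300
    rows[[d]] <- data.frame(patient_id = patient, time = t,
                            glucose = 6 + 0.01 * slots)
  }
  do.call(rbind, rows)
}

test_that("extraction aligns readings to 5-min slots per night", {
  segs <- extract_nocturnal_segments(make_record(nights = 2L))
  expect_length(segs, 2L)
  expect_false(any(segs[[1]]$missing_mask))
  expect_false(any(segs[[2]]$missing_mask))
  expect_identical(vapply(segs, `[[`, integer(1), "night_index"), c(1L, 2L))

  # missing 00:15 and 00:20 readings -> slots 4 and 5 (0-based 3 and 4)
  segs <- extract_nocturnal_segments(
    make_record(drop_slots = list(c(4L, 5L))))
  expect_identical(which(segs[[1]]$missing_mask), c(4L, 5L))

  # daytime-only record yields nothing
  day <- make_record()
  day$time <- day$time + 12 * 3600
  expect_length(extract_nocturnal_segments(day), 0L)

  # unsorted timestamps are a data error
  bad <- make_record()[c(2, 1, 3:72), ]
  expect_error(extract_nocturnal_segments(bad), class = "data_error")
})

test_that("short gaps are filled with the left/right-neighbor mean", {
  s <- nocturnal_segment(c(5, 0, 6, 7), c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(impute_short_gaps(s)$values, c(5, 5.5, 6, 7))

  s2 <- nocturnal_segment(c(5, 0, 0, 7), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(impute_short_gaps(s2)$values, c(5, 6, 6, 7))

  complete <- nocturnal_segment(c(5, 6, 7, 8))
  expect_identical(impute_short_gaps(complete), complete)

  # idempotent, and never touches observed readings
  once <- impute_short_gaps(gap_segment(c(10L, 20L, 21L)))
  expect_identical(impute_short_gaps(once), once)
  raw <- gap_segment(c(10L, 20L, 21L))
  expect_equal(once$values[-c(10L, 20L, 21L)], raw$values[-c(10L, 20L, 21L)])
  expect_false(any(once$missing_mask))

  expect_error(impute_short_gaps(
    nocturnal_segment(c(0, 5, 6, 7), c(TRUE, FALSE, FALSE, FALSE))),
    class = "boundary_gap_error")
  expect_error(impute_short_gaps(gap_segment(c(30L, 31L, 32L))),
               class = "precondition_error")
})

test_that("filtering rejects long gaps, sparse segments and boundary gaps", {
  expect_identical(filter_segment(gap_segment(c(10L, 11L, 12L)))$reason,
                   "LONG_GAP")
  scattered8 <- gap_segment(c(5L, 9L, 13L, 21L, 33L, 45L, 57L, 69L))
  expect_identical(filter_segment(scattered8)$reason, "TOO_SPARSE")
  scattered7 <- gap_segment(c(5L, 9L, 13L, 21L, 33L, 45L, 57L))
  expect_true(filter_segment(scattered7)$keep)  # 7/72 < 10%
  expect_identical(filter_segment(gap_segment(1L))$reason, "BOUNDARY_GAP")
  expect_identical(filter_segment(gap_segment(c(71L, 72L)))$reason,
                   "BOUNDARY_GAP")
  expect_true(filter_segment(gap_segment())$keep)
})

test_that("filtering and imputation commute on kept segments", {
  set.seed(42)
  for (rep in 1:50) {
    miss <- sort(sample(72L, sample(0:9, 1)))
    seg <- gap_segment(miss)
    dec <- filter_segment(seg)
    if (dec$keep) {
      imputed <- impute_short_gaps(seg)
      expect_true(filter_segment(imputed)$keep)
      expect_false(any(imputed$missing_mask))
    } else if (dec$reason == "BOUNDARY_GAP") {
      expect_error(impute_short_gaps(seg), class = "boundary_gap_error")
    }
  }
})

test_that("programmed-gap fixture reproduces hand-enumerated keep counts", {
  segs <- programmed_gap_cohort()   # 5 blocks x 8 patterns
  reasons <- vapply(segs, function(s) filter_segment(s)$reason, character(1))
  tally <- table(factor(reasons, c("OK", "LONG_GAP", "TOO_SPARSE",
                                   "BOUNDARY_GAP")))
  # per block: complete, 1-gap, 2-gap, 1-gap kept; 3-gap, scattered-8,
  # boundary each rejected with their own reason
  expect_identical(as.integer(tally), c(25L, 5L, 5L, 5L))
})

test_that("NH labeling requires a sustained sub-threshold run", {
  expect_false(label_nocturnal_hypoglycemia(rep(5.5, 72)))
  run3 <- c(rep(5, 30), 3.8, 3.7, 3.8, rep(5, 39))
  expect_true(label_nocturnal_hypoglycemia(run3))
  run2 <- c(rep(5, 30), 3.5, 3.6, rep(5, 40))
  expect_false(label_nocturnal_hypoglycemia(run2))
  expect_true(label_nocturnal_hypoglycemia(run2, min_run = 2))

  incomplete <- nocturnal_segment(rep(5, 72), c(TRUE, rep(FALSE, 71)))
  expect_error(label_nocturnal_hypoglycemia(incomplete),
               class = "precondition_error")
})

test_that("NH labeling is monotone in the threshold", {
  set.seed(19)
  for (rep in 1:100) {
    vals <- 4 + cumsum(rnorm(72, 0, 0.3))
    vals <- pmin(pmax(vals, 2.2), 22.2)
    th <- sort(runif(2, 3, 6))
    if (label_nocturnal_hypoglycemia(vals, threshold = th[1])) {
      expect_true(label_nocturnal_hypoglycemia(vals, threshold = th[2]))
    }
  }
})

test_that("the split is stratified, seeded, and sized by largest remainder", {
  mk <- function(n, nh) lapply(seq_len(n), function(i) {
    s <- nocturnal_segment(rep(6, 72), patient_id = sprintf("%s%03d", nh, i))
    s$nh_label <- nh == "H"
    s
  })
  segs <- c(mk(100, "N"), mk(10, "H"))
  set <- split_dataset(segs, c(0.7, 0.1, 0.2), seed = 4L)
  expect_identical(as.integer(table(set$role[!set$nh_label])[
    c("train", "validation", "test")]), c(70L, 10L, 20L))
  expect_identical(as.integer(table(set$role[set$nh_label])[
    c("train", "validation", "test")]), c(7L, 1L, 2L))
  # partition: every segment gets exactly one role
  expect_false(any(is.na(set$role)))

  # reproducible under the seed, sizes invariant to it
  set2 <- split_dataset(segs, c(0.7, 0.1, 0.2), seed = 4L)
  expect_identical(set$role, set2$role)
  set3 <- split_dataset(segs, c(0.7, 0.1, 0.2), seed = 99L)
  expect_false(identical(set$role, set3$role))
  expect_identical(table(set$role), table(set3$role))

  expect_error(split_dataset(segs[1:2], c(0.7, 0.1, 0.2)),
               class = "size_error")
  expect_error(split_dataset(segs, c(0.7, 0.1, 0.1)), class = "config_error")
})

test_that("preprocess_cohort splits kept segments into NH groups", {
  coh <- generate_cohort(cohort_config(120, seed = 21L))
  prep <- preprocess_cohort(coh)
  expect_identical(sum(prep$counts), 120L)
  expect_setequal(names(prep$sets), c("no_NH", "NH"))
  expect_true(all(prep$sets$NH$nh_label))
  expect_false(any(prep$sets$no_NH$nh_label))
  n_kept <- nrow(prep$sets$NH$values) + nrow(prep$sets$no_NH$values)
  expect_identical(n_kept, as.integer(prep$counts[["OK"]]))
})
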