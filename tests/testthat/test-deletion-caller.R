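kb_windows <- function(n) data.frame(start = (0:(n - 1)) * 1000L,
                                     end = (1:n) * 1000L)

test_that("a clean null-copy run yields one three-window call", {
  calls <- call_segments(c(2, 2, 0, 0, 0, 2, 2), kb_windows(7))
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$state, 0L)
  expect_identical(calls$end - calls$start, 3000L)
  expect_identical(calls$n_windows, 3L)
})

test_that("a nested-deletion profile yields a one-copy then a null segment", {
  calls <- call_segments(c(2, 1, 1, 0, 0), kb_windows(5), min_windows = 2)
  expect_identical(calls$state, c(1L, 0L))
  expect_identical(calls$start, c(1000L, 3000L))
  expect_identical(calls$end, c(3000L, 5000L))
})

test_that("unsorted or overlapping windows are rejected", {
  w <- kb_windows(3)[c(2, 1, 3), ]
  expect_error(call_segments(c(0, 0, 0), w), "sorted")
  w2 <- data.frame(start = c(0L, 500L), end = c(1000L, 1500L))
  expect_error(call_segments(c(0, 0), w2), "non-overlapping")
})

test_that("ambiguous windows bridge short gaps but states never mix", {
  # gap of 2 ambiguous windows is bridged...
  calls <- call_segments(c(0, 0, 1.5, 1.5, 0, 0), kb_windows(6),
                         min_windows = 4)
  expect_identical(nrow(calls), 1L)
  expect_identical(calls$n_windows, 4L)
  expect_identical(calls$end - calls$start, 6000L)
  # ...a gap of 3 is not
  expect_identical(
    nrow(call_segments(c(0, 0, 1.5, 1.5, 1.5, 0, 0), kb_windows(7),
                       min_windows = 4)), 0L)
  # a one-copy window splits a null segment regardless of gap allowance
  expect_identical(
    nrow(call_segments(c(0, 0, 1, 0, 0), kb_windows(5), min_windows = 4)),
    0L)
})

test_that("segment calls equal the literal merge-rule oracle on random vectors", {
  set.seed(6)
  vals <- c(0, 0.05, 0.2, 0.5, 1, 1.2, 1.5, 2, 2.1, 2.6, NA)
  for (rep in 1:300) {
    n <- sample(1:20, 1)
    cn <- sample(vals, n, replace = TRUE)
    gap <- sample(0:3, 1)
    mw <- sample(1:4, 1)
    w <- kb_windows(n)
    got <- call_segments(cn, w, max_gap_windows = gap, min_windows = mw)
    want <- oracle_segments(cn, w, max_gap = gap, min_win = mw)
    expect_equal(got[, names(want)], want, ignore_attr = TRUE)
  }
})

test_that("clips at the background rate produce no peaks", {
  set.seed(7)
  depth <- rpois(50000, 10)
  clip <- rbinom(50000, depth, 0.01)
  enr <- softclip_enrichment(clip, depth, background_clip_rate = 0.01)
  expect_identical(nrow(enr$peaks), 0L)
})

test_that("an injected ten-fold clip excess is located to within the window", {
  truth <- 23000L
  hits <- 0L
  for (s in 1:20) {
    set.seed(300 + s)
    depth <- rpois(50000, 7)
    rate <- rep(0.01, 50000)
    rate[(truth - 500):(truth + 500)] <- 0.1
    clip <- rbinom(50000, depth, rate)
    enr <- softclip_enrichment(clip, depth, background_clip_rate = 0.01)
    if (nrow(enr$peaks) >= 1 &&
        all(abs(enr$peaks$position - truth) <= 1000))
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("zero depth everywhere yields no peaks and no error", {
  enr <- softclip_enrichment(integer(5000), integer(5000))
  expect_identical(nrow(enr$peaks), 0L)
  expect_error(softclip_enrichment(c(2, 0), c(1, 0)), "exceeds depth")
  expect_error(softclip_enrichment(0L, 1L, background_clip_rate = 0), "0, 1")
})

test_that("carrier tracks show clip peaks at their anchored junctions only", {
  rm <- default_model()
  trk <- simulate_depth(rm, sample_spec("k", c("Del1", "WT")), seed = 61)
  peaks <- softclip_enrichment(trk$softclip, trk$depth)$peaks
  expect_gte(nrow(peaks), 2L)
  bp <- rm$breakpoints[c("BP1", "BP3")]
  expect_true(all(vapply(peaks$position, function(p)
    min(abs(p - bp)) <= 1000, logical(1))))
  nearest <- vapply(bp, function(b) min(abs(peaks$position - b)), numeric(1))
  expect_true(all(nearest <= 1000))

  hom <- simulate_depth(rm, sample_spec("h", c("Del1", "Del1")), seed = 62)
  expect_identical(nrow(softclip_enrichment(hom$softclip, hom$depth)$peaks),
                   0L)
})

test_that("motif runs are found exactly, matching the quadratic scanner", {
  got <- find_motif_runs("TGGATGGATGGA", "TGGA", min_run_length_bp = 8)
  expect_identical(got, data.frame(start = 0L, end = 12L, copies = 3L))
  expect_identical(nrow(find_motif_runs("ACACACAC", "TGGA", 4)), 0L)
  expect_error(find_motif_runs("ACGT", ""), "non-empty")

  set.seed(8)
  for (rep in 1:50) {
    seq <- paste(sample(c("A", "C", "G", "T", "TGGA", "TGGATGGA"),
                        60, replace = TRUE), collapse = "")
    for (min_len in c(4, 8, 16)) {
      got <- find_motif_runs(seq, "TGGA", min_len)
      want <- oracle_motif_runs(seq, "TGGA", min_len)
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("deletion boundaries are recovered within one window across replicates", {
  rm <- default_model()
  ok <- 0L
  for (s in 1:50) {
    trks <- list(
      hom = simulate_depth(rm, sample_spec("hom", c("Del1", "Del1")),
                           seed = 1000 + s),
      pool = simulate_depth(rm, wt_pool_spec(), seed = 2000 + s))
    wt <- build_window_table(trks, "pool")
    calls <- call_deletions(wt)
    calls <- calls[calls$state == 0L, , drop = FALSE]
    if (nrow(calls) == 1 &&
        abs(calls$start - rm$del1[1]) <= 1000 &&
        abs(calls$end - rm$del1[2]) <= 1000)
      ok <- ok + 1L
  }
  expect_gte(ok, 48L)   # >= 95% of 50 replicates
})

test_that("the estimated large-deletion span falls in the expected size bracket", {
  rm <- default_model()
  trks <- list(
    hom = simulate_depth(rm, sample_spec("hom", c("Del1", "Del1")), seed = 71),
    pool = simulate_depth(rm, wt_pool_spec(), seed = 72))
  calls <- call_deletions(build_window_table(trks, "pool"))
  calls <- calls[calls$state == 0L, ]
  span <- calls$end - calls$start
  expect_gte(span, 160000L)
  expect_lte(span, 180000L)
})

test_that("breakpoint annotation pairs clip peaks with flanking repeat runs", {
  rm <- default_model()
  trk <- simulate_depth(rm, sample_spec("k", c("Del1", "WT")), seed = 81)
  seqs <- simulate_region_sequence(rm, seed = 82)
  ann <- annotate_breakpoints(trk, seqs)
  expect_gte(nrow(ann), 1L)
  near_bp1 <- which(abs(ann$position - rm$breakpoints[["BP1"]]) <= 1000)
  expect_gte(length(near_bp1), 1L)
  expect_false(any(is.na(ann$repeat_start[near_bp1])))
  expect_true(all(ann$repeat_copies[near_bp1] * 4 >= 1000))
  # BED6 export of the matching deletion calls
  wt <- build_window_table(list(k = trk,
                                pool = simulate_depth(rm, wt_pool_spec(),
                                                      seed = 83)), "pool")
  calls <- call_deletions(wt)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_deletion_bed(calls, bed)
  bed_df <- read.delim(bed, header = FALSE)
  expect_identical(nrow(bed_df), nrow(calls))
  expect_true(all(grepl("^k:", bed_df$V4)))
})
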