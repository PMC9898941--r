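# per-read call parsing, segment extraction, statistics, writers

write_calls_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# a toy chromosome: CpG sites at 1-based positions 101, 110, 120, 131, 140, 152
toy_sites <- c(101L, 110L, 120L, 131L, 140L, 152L)

toy_calls <- function(n_reads, sites = toy_sites, states_fun = NULL,
                      chrom = "chr1", prefix = "r") {
  vapply(seq_len(n_reads), function(i) {
    st <- if (is.null(states_fun)) rep(0L, length(sites)) else states_fun(i)
    paste(paste0(prefix, i), chrom, paste(sites, collapse = ","),
          paste(st, collapse = ""), sep = "\t")
  }, "")
}

test_that("well-formed calls parse; malformed lines raise with line number", {
  f <- write_calls_file(c("# comment",
                          "r1\tchr1\t101,110\t01",
                          "r2\tchr1\t101,110,120\t111",
                          "",
                          "r3\tchr2\t5,9\t10"))
  rec <- read_methylation_calls(f)
  expect_s3_class(rec, "meth_reads")
  expect_equal(nrow(rec), 3)
  expect_equal(rec$sites[[1]], c(100L, 109L))  # converted to 0-based
  expect_equal(rec$states[[2]], c(1L, 1L, 1L))

  f <- write_calls_file("r1\tchr1\t101,110\t0N")
  expect_error(read_methylation_calls(f), "line 1.*non-binary")
  f <- write_calls_file(c("r1\tchr1\t101,110\t01", "r2\tchr1\t110,101\t01"))
  expect_error(read_methylation_calls(f), "line 2.*ascending")
  f <- write_calls_file("r1\tchr1\t101,110\t011")
  expect_error(read_methylation_calls(f), "does not match")

  f <- write_calls_file(character())
  expect_equal(nrow(read_methylation_calls(f)), 0)
})

test_that("round trip through write_methylation_calls preserves records", {
  f <- write_calls_file(c("r1\tchr1\t101,110\t01",
                          "r2\tchr2\t5,9,22\t110"))
  rec <- read_methylation_calls(f)
  f2 <- tempfile()
  write_methylation_calls(rec, f2)
  expect_identical(read_methylation_calls(f2), rec)
})

test_that("sliding windows over fully covering reads give C - n + 1 segments", {
  f <- write_calls_file(toy_calls(25))
  rec <- read_methylation_calls(f)
  segs <- extract_segments(rec, n = 4, min_depth = 20)
  expect_length(segs, 3)  # windows 1-4, 2-5, 3-6
  expect_equal(vapply(segs, `[[`, 0L, "m"), rep(25L, 3))
  expect_equal(segs[[1]]$sites, toy_sites[1:4] - 1L)
  expect_equal(segs[[2]]$sites, toy_sites[2:5] - 1L)

  # below depth threshold: nothing
  f <- write_calls_file(toy_calls(19))
  expect_length(extract_segments(read_methylation_calls(f), 4, 20), 0)

  # disjoint mode steps by n
  f <- write_calls_file(toy_calls(25))
  segs <- extract_segments(read_methylation_calls(f), n = 3, min_depth = 20,
                           mode = "disjoint")
  expect_length(segs, 2)
  expect_equal(segs[[2]]$sites, toy_sites[4:6] - 1L)
})

test_that("reads partially covering a window are excluded from it", {
  lines <- c(toy_calls(25, sites = toy_sites[1:4], prefix = "a"),
             toy_calls(25, sites = toy_sites[3:6], prefix = "b"))
  f <- write_calls_file(lines)
  segs <- extract_segments(read_methylation_calls(f), n = 4, min_depth = 20)
  starts <- vapply(segs, function(s) s$sites[1], 0L)
  expect_equal(starts, (toy_sites[c(1, 3)] - 1L))  # windows 1-4 and 3-6 only
  expect_equal(vapply(segs, `[[`, 0L, "m"), c(25L, 25L))
})

test_that("extraction is invariant to the order of input reads", {
  set.seed(61)
  lines <- toy_calls(30, states_fun = function(i) rbinom(6, 1, 0.5))
  f1 <- write_calls_file(lines)
  f2 <- write_calls_file(sample(lines))
  s1 <- extract_segments(read_methylation_calls(f1), 4, 20)
  s2 <- extract_segments(read_methylation_calls(f2), 4, 20)
  expect_equal(segment_stats_table(s1), segment_stats_table(s2))
})

test_that("segment statistics compose levels, entropy, test and flag", {
  seg <- structure(list(chrom = "chr1", sites = c(100L, 109L, 119L, 130L),
                        x = rbind(matrix(0L, 20, 4), matrix(1L, 20, 4)),
                        m = 40L), class = "meth_segment")
  st <- segment_statistics(seg, r_threshold = 0.6)
  expect_equal(st$mml, 0.5)
  expect_equal(st$ome, 1)
  expect_true(st$bipolar)  # threshold curve at (0.5, r = 0.6) is ~2.95 bits
  expect_equal(st$chisq_stat, 280)
  expect_equal(st$start, 100L)
  expect_equal(st$end, 132L)

  seg$x <- matrix(0L, 40, 4)
  st <- segment_statistics(seg)
  expect_equal(st$mml, 0)
  expect_false(st$testable)
  expect_false(st$bipolar)

  seg$x <- sample_reads(bernoulli_params(0.5, n = 4), 100, seed = 9)
  st <- segment_statistics(seg)
  expect_gt(st$ome, 3)
  expect_false(st$bipolar)
})

test_that("stats tables round-trip byte-identically and BED uses 0-based half-open", {
  ds <- simulate_two_sample_calls(n_segments = 6, n_planted = 3, m = 25,
                                  seed = 71)
  segs <- extract_segments(ds$sample_a, 4, 20)
  stats <- segment_stats_table(segs)
  f1 <- tempfile(); write_segment_stats(stats, f1)
  back <- read_segment_stats(f1)
  f2 <- tempfile(); write_segment_stats(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  # segment spanning CpGs at 1-based 101 and 110: BED start 100, end 111
  seg <- structure(list(chrom = "chr1", sites = c(100L, 109L),
                        x = rbind(matrix(0L, 10, 2), matrix(1L, 10, 2)),
                        m = 20L), class = "meth_segment")
  st <- segment_statistics(seg, r_threshold = 0.6,
                           mml_window = c(0.2, 0.8))
  st$n_sites <- 2L
  fb <- tempfile(); write_bipolar_bed(st, fb)
  bed <- read.table(fb, sep = "\t")
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 111)
  expect_equal(bed$V4, "bipolar")
  expect_equal(bed$V5, round(1000 * (1 - st$ome / 2)))

  # empty stats: header-only TSV, empty BED
  empty <- segment_stats_table(list())
  fe <- tempfile(); write_segment_stats(empty, fe)
  expect_length(readLines(fe), 1)
  fbe <- tempfile(); write_bipolar_bed(empty, fbe)
  expect_length(readLines(fbe), 0)
})
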