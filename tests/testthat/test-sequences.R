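test_that("sub-threshold gaps join tokens into one sequence", {
  seqs <- segment_sequences(tokens_with_gaps(c(0.5, 0.5)))
  expect_identical(nrow(seqs$sequences), 1L)
  expect_identical(seqs$sequences$size_n, 3L)
})

test_that("the 1 s boundary is exclusive: a gap of exactly 1.00 s splits", {
  seqs <- segment_sequences(tokens_with_gaps(c(0.99, 1.00)))
  expect_identical(seqs$sequences$size_n, c(2L, 1L))
})

test_that("overlapping tokens (negative gaps) stay in one sequence", {
  toks <- make_tokens(start = c(0, 0.2, 0.6), end = c(0.4, 0.56, 1.0))
  seqs <- segment_sequences(toks)
  expect_identical(nrow(seqs$sequences), 1L)
})

test_that("a missing end time closes the sequence and marks it incomplete", {
  toks <- make_tokens(start = c(0, 1.0, 1.6), end = c(NA, 1.4, 2.0))
  seqs <- segment_sequences(toks)
  # token 1 cannot attach forward: gap undefined
  expect_identical(seqs$sequences$size_n, c(1L, 2L))
  expect_identical(seqs$sequences$complete, c(FALSE, TRUE))
})

test_that("sequences never span signallers or videos", {
  toks <- rbind(make_tokens(c(0, 0.8), c(0.4, 1.2), signaller = "s1"),
                make_tokens(c(0.9, 1.7), c(1.3, 2.1), signaller = "s2"))
  seqs <- segment_sequences(toks)
  expect_identical(nrow(seqs$sequences), 2L)
  expect_identical(sort(seqs$sequences$signaller), c("s1", "s2"))
})

test_that("segmentation agrees with a brute-force partitioner on random streams", {
  for (seed in 1:8) {
    toks <- random_stream(n = sample(5:50, 1), seed = seed)
    for (mode in c("end_start", "start_start")) {
      seqs <- segment_sequences(toks, gap_threshold_s = 1.0, gap_mode = mode)
      oracle <- brute_force_partition(toks, 1.0, mode)
      got <- as.integer(factor(seqs$tokens$sequence_id,
                               levels = unique(seqs$tokens$sequence_id)))
      expect_identical(got, oracle)
    }
  }
})

test_that("segmentation conserves tokens and is monotone in the threshold", {
  toks <- random_stream(40, seed = 99)
  prev <- Inf
  for (thr in c(0.2, 0.5, 1, 2, 5)) {
    seqs <- segment_sequences(toks, gap_threshold_s = thr)
    expect_identical(nrow(seqs$tokens), nrow(toks))
    expect_identical(sum(seqs$sequences$size_n), nrow(toks))
    expect_lte(nrow(seqs$sequences), prev)
    prev <- nrow(seqs$sequences)
  }
})

test_that("filter_complete drops whole sequences with any unknown duration", {
  toks <- rbind(tokens_with_gaps(c(0.5), video = "v1"),
                make_tokens(c(100, 100.9), c(NA, 101.3), video = "v1"))
  seqs <- segment_sequences(toks)
  out <- filter_complete(seqs)
  expect_identical(out$n_excluded, 1L)  # only the NA-duration singleton goes
  expect_true(all(out$kept$sequences$complete))

  all_ok <- filter_complete(segment_sequences(tokens_with_gaps(c(0.5, 0.5))))
  expect_identical(all_ok$n_excluded, 0L)
  expect_identical(nrow(all_ok$kept$sequences), 1L)

  empty <- filter_complete(segment_sequences(make_tokens(numeric(0),
                                                         numeric(0))))
  expect_identical(empty$n_excluded, 0L)
  expect_identical(nrow(empty$kept$sequences), 0L)
})

test_that("token CSVs are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  toks <- make_tokens(c(0, 2, 4), c(0.4, 2.4, 4.4))
  write_tokens(toks, path)
  expect_identical(nrow(read_tokens(path)), 3L)

  # blank end_s: token retained with missing duration
  raw <- readLines(path)
  raw[2] <- sub("0.4$", "", raw[2])
  writeLines(raw, path)
  back <- read_tokens(path)
  expect_identical(nrow(back), 3L)
  expect_true(is.na(back$duration_s[1]))

  # end before start: rejected naming the row
  toks_bad <- make_tokens(c(0, 2), c(0.4, 1.5))
  write_tokens(toks_bad, path)
  expect_error(read_tokens(path), "row\\(s\\) 2")

  # missing required column
  writeLines(c("signaller,start_s", "a,1"), path)
  expect_error(read_tokens(path), "missing required column")

  expect_error(read_tokens(file.path(tempdir(), "no-such.csv")), "not found")

  # non-numeric time names the column
  toks_ok <- make_tokens(c(0, 2), c(0.4, 2.4))
  write_tokens(toks_ok, path)
  raw <- readLines(path)
  raw[3] <- sub("^([^,]*,[^,]*,[^,]*,[^,]*,[^,]*,[^,]*,[^,]*,)2(,.*)$",
                "\\1two\\2", raw[3])
  writeLines(raw, path)
  expect_error(read_tokens(path), "non-numeric start_s")
})
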