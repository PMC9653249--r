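test_that("an empty configuration yields an empty stream", {
  toks <- simulate_tokens(simulation_config(n_sequences = 0))
  expect_s3_class(toks, "gesture_tokens")
  expect_identical(nrow(toks), 0L)
  expect_true(all(c("signaller", "gesture_type", "start_s", "end_s") %in%
                    names(toks)))
})

test_that("the degenerate noiseless configuration is fully determined", {
  cfg <- simulation_config(
    n_signallers = 2, n_types = 1, n_manual = 1,
    type_frequency_weights = 1,
    beta_freq = 0, beta_size = 0, beta_category = 0,
    sd_signaller = 0, sd_sequence = 0, sd_type = 0, sd_date = 0,
    sd_resid = 0, mu0 = 0,
    sequence_size_distribution = 1, n_sequences = 12, seed = 4
  )
  toks <- simulate_tokens(cfg)
  expect_identical(nrow(toks), 12L)
  expect_true(all(toks$duration_s == 1.00))
})

test_that("identical seeds give identical streams; different seeds differ", {
  cfg <- default_study_config(seed = 21L)
  a <- simulate_tokens(cfg)
  b <- simulate_tokens(cfg)
  expect_identical(a, b)
  cfg2 <- default_study_config(seed = 22L)
  expect_false(identical(simulate_tokens(cfg2)$start_s, a$start_s))
})

test_that("study-scale streams match the configured scale and weights", {
  for (seed in c(101L, 202L)) {
    toks <- simulate_tokens(default_study_config(seed = seed))
    expect_gt(nrow(toks), 0.9 * 560)
    expect_lt(nrow(toks), 1.1 * 560)
    counts <- table(factor(toks$gesture_type,
                           levels = sprintf("type%02d", 1:26)))
    expect_gt(cor(as.numeric(counts), 1 / (1:26), method = "spearman"), 0.8)
    # durations live on the frame grid with a one-frame floor
    expect_true(all(toks$duration_s >= 0.04 - 1e-9))
    expect_true(all(abs(toks$duration_s / 0.04 -
                          round(toks$duration_s / 0.04)) < 1e-6))
  }
})

test_that("segmentation recovers the simulated sequence partition exactly", {
  toks <- simulate_tokens(default_study_config(seed = 31L))
  seqs <- segment_sequences(toks, gap_threshold_s = 1.0)
  expect_identical(nrow(seqs$sequences),
                   length(unique(toks$sim_sequence_id)))
  # each recovered sequence is exactly one simulated sequence
  cross <- table(seqs$tokens$sequence_id, seqs$tokens$sim_sequence_id)
  expect_true(all(rowSums(cross > 0) == 1))
  expect_true(all(colSums(cross > 0) == 1))
})

test_that("larger sequences have shorter mean log-durations when beta_size < 0", {
  cfg <- default_study_config(beta_size = -0.3, n_sequences = 2000,
                              seed = 55L)
  toks <- simulate_tokens(cfg)
  seqs <- segment_sequences(toks)
  m <- match(seqs$tokens$sequence_id, seqs$sequences$sequence_id)
  size <- seqs$sequences$size_n[m]
  means <- tapply(log(seqs$tokens$duration_s), size, mean)
  expect_true(all(diff(means[as.character(1:4)]) < 0))
})

test_that("the canonical CSV and truth sidecar round-trip", {
  cfg <- simulation_config(n_sequences = 25, seed = 8L)
  toks <- simulate_tokens(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tokens(toks, path, config = cfg)
  back <- read_tokens(path)
  expect_identical(nrow(back), nrow(toks))
  expect_equal(back$duration_s, toks$duration_s, tolerance = 1e-9)
  truth <- jsonlite::read_json(paste0(path, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$beta_size, cfg$beta_size)
  expect_equal(truth$seed, cfg$seed)
})
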