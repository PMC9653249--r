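rep_frame <- function(freq, d) {
  data.frame(gesture_type = letters[seq_along(freq)], n_tokens = freq,
             proportion_p = freq / sum(freq),
             mean_duration_s = d, median_duration_s = d,
             stringsAsFactors = FALSE)
}

test_that("perfect anti-concordance gives a Kendall coefficient of -1", {
  b <- brevity_correlation(rep_frame(c(10, 5, 1), c(1, 2, 3)),
                           n_perm = 999, seed = 1)
  expect_equal(b$coefficient, -1)
  expect_true(b$exact)  # 3! pairings enumerated
})

test_that("constant durations carry no brevity signal", {
  b <- brevity_correlation(rep_frame(c(10, 5, 1), c(2, 2, 2)),
                           n_perm = 999, seed = 1)
  expect_identical(b$coefficient, 0)
})

test_that("tau-b matches the pairwise enumeration on a tied-free example", {
  b <- brevity_correlation(rep_frame(c(4, 3, 2, 1), c(1, 2, 4, 3)),
                           n_perm = 999, seed = 1)
  expect_equal(b$coefficient, -2 / 3)  # 1 concordant, 5 discordant pairs
})

test_that("degenerate repertoires are refused", {
  expect_error(brevity_correlation(rep_frame(c(2, 1), c(1, 2))),
               "at least 3")
  expect_error(brevity_correlation(rep_frame(c(3, 2, 1), c(1, 2, 3)),
                                   n_perm = 10), "n_perm")
  expect_error(compression_test(rep_frame(5, 1)), "at least 2")
})

test_that("symmetric frequencies make all code-length pairings equal", {
  cc <- compression_test(rep_frame(c(5, 5), c(1, 3)), n_perm = 99, seed = 1)
  expect_equal(cc$L_obs, 2)
  expect_equal(cc$L_min, 2)
  expect_equal(cc$L_max, 2)
})

test_that("two-type code lengths follow the sorted pairings", {
  cc <- compression_test(rep_frame(c(3, 1), c(1, 2)), n_perm = 99, seed = 1)
  expect_equal(cc$L_obs, 1.25)
  expect_equal(cc$L_min, 1.25)
  expect_equal(cc$L_max, 1.75)
})

test_that("three-type compression matches the brute-force pairing oracle", {
  # p = (0.5, 0.3, 0.2), d = (2, 1, 3); all 6 pairings enumerated by hand:
  # L in {1.7, 1.8, 1.9, 2.1, 2.2, 2.3}; observed pairing gives 1.9
  p <- c(0.5, 0.3, 0.2)
  d <- c(2, 1, 3)
  cc <- compression_test(rep_frame(p * 10, d), n_perm = 999, seed = 1)
  expect_equal(cc$L_obs, 1.9)
  expect_equal(cc$L_min, 1.7)
  expect_equal(cc$L_max, 2.3)
  expect_equal(cc$p_value, 3 / 6)  # exact: Pr(L* <= 1.9) over all pairings
  expect_equal(cc$L_rand_mean, mean(c(1.7, 1.8, 1.9, 2.1, 2.2, 2.3)))
})

test_that("exact permutation p-values agree with an independent enumerator", {
  for (seed in c(5L, 6L)) {
    set.seed(seed)
    k <- sample(4:5, 1)
    freq <- sort(sample(1:40, k), decreasing = TRUE)
    d <- round(runif(k, 0.2, 3), 2)
    rep <- rep_frame(freq, d)
    p <- freq / sum(freq)

    cc <- compression_test(rep, n_perm = 999, seed = 1)
    Ls <- vapply(enumerate_perms(k), function(ix) sum(p * d[ix]), numeric(1))
    expect_equal(cc$p_value, mean(Ls <= cc$L_obs + 1e-12))
    expect_equal(cc$L_rand_mean, mean(Ls))
    expect_equal(cc$L_min, min(Ls))
    expect_equal(cc$L_max, max(Ls))

    b <- brevity_correlation(rep, n_perm = 999, seed = 1)
    taus <- vapply(enumerate_perms(k),
                   function(ix) cor(freq, d[ix], method = "kendall"),
                   numeric(1))
    expect_equal(b$p_value, mean(abs(taus) >= abs(b$coefficient) - 1e-12))
  }
})

test_that("L_obs equals the overall mean token duration for mean summaries", {
  toks <- simulate_tokens(default_study_config(seed = 61L))
  rep <- repertoire_summary(toks)
  cc <- compression_test(rep, n_perm = 99, seed = 1)
  expect_equal(cc$L_obs, mean(toks$duration_s))
})

test_that("rescaling durations rescales L and leaves tests invariant", {
  rep1 <- null_repertoire(7)
  rep2 <- rep1
  rep2$mean_duration_s <- rep2$mean_duration_s * 3.5
  rep2$median_duration_s <- rep2$median_duration_s * 3.5
  c1 <- compression_test(rep1, n_perm = 499, seed = 2)
  c2 <- compression_test(rep2, n_perm = 499, seed = 2)
  expect_equal(c2$L_obs, 3.5 * c1$L_obs)
  expect_equal(c2$L_min, 3.5 * c1$L_min)
  expect_equal(c2$L_rand_mean, 3.5 * c1$L_rand_mean)
  expect_identical(c2$p_value, c1$p_value)
  b1 <- brevity_correlation(rep1, n_perm = 499, seed = 3)
  b2 <- brevity_correlation(rep2, n_perm = 499, seed = 3)
  expect_identical(b1$coefficient, b2$coefficient)
  expect_identical(b1$p_value, b2$p_value)
})

test_that("an exact power law is recovered to machine precision", {
  sizes <- rep(1:5, each = 4)
  d <- 2.4 * sizes^(-0.5)
  start <- seq(0, by = 100, length.out = length(sizes))
  toks <- make_tokens(start, start + d)
  toks$duration_s <- d
  seqs <- segment_sequences(toks)
  seqs$sequences$size_n <- sizes          # one point per sequence
  seqs$sequences$mean_duration_s <- d
  mz <- menzerath_stats(seqs, n_perm = 99, seed = 1)
  expect_equal(mz$mal_b, -0.5, tolerance = 1e-10)
  expect_equal(mz$mal_a, 2.4, tolerance = 1e-10)
  expect_equal(mz$coefficient, -1)
})

test_that("size-independent durations give zero slope and coefficient", {
  sizes <- rep(1:4, each = 3)
  start <- seq(0, by = 50, length.out = 12)
  toks <- make_tokens(start, start + 1)  # binary-exact constant duration
  seqs <- segment_sequences(toks)
  seqs$sequences$size_n <- sizes
  mz <- menzerath_stats(seqs, n_perm = 99, seed = 1)
  expect_identical(mz$coefficient, 0)
  expect_equal(mz$mal_b, 0)
})

test_that("single-size collections are flagged as degenerate", {
  toks <- make_tokens(c(0, 50, 100), c(0.4, 50.4, 100.4))
  mz <- menzerath_stats(segment_sequences(toks), n_perm = 99, seed = 1)
  expect_true(mz$degenerate)
  expect_true(is.na(mz$mal_b))
})

test_that("a configured negative size effect is recovered in sign", {
  hits <- 0L
  for (i in 1:20) {
    cfg <- default_study_config(beta_size = -0.2, seed = 700L + i)
    seqs <- filter_complete(segment_sequences(simulate_tokens(cfg)))$kept
    mz <- menzerath_stats(seqs, n_perm = 99, seed = i)
    hits <- hits + (mz$mal_b < 0)
  }
  expect_gte(hits, 19L)
})

test_that("ICC(3,1) is one for identical and for shifted codings", {
  x <- c(0.4, 1.2, 2.0, 3.6, 5.2)
  expect_equal(icc3_single(cbind(x, x))$icc, 1)
  expect_equal(icc3_single(cbind(x, x + 0.5))$icc, 1)
})

test_that("ICC(3,1) matches an independent ANOVA computation", {
  check_against_aov <- function(m) {
    long <- data.frame(y = c(m[, 1], m[, 2]),
                       item = factor(rep(seq_len(nrow(m)), 2)),
                       occ = factor(rep(1:2, each = nrow(m))))
    tab <- anova(lm(y ~ item + occ, data = long))
    msr <- tab["item", "Mean Sq"]
    mse <- tab["Residuals", "Mean Sq"]
    (msr - mse) / (msr + mse)
  }
  m1 <- cbind(c(1, 2, 3, 4, 5), c(2, 1, 3, 4, 5))
  expect_equal(icc3_single(m1)$icc, check_against_aov(m1))
  set.seed(12)
  m2 <- cbind(rnorm(20, 2), rnorm(20, 2))
  m2[, 2] <- 0.8 * m2[, 1] + 0.2 * m2[, 2]
  expect_equal(icc3_single(m2)$icc, check_against_aov(m2))
})

test_that("reliability input contracts are enforced", {
  expect_error(icc3_single(cbind(1:2, 1:2)), "at least 3")
  expect_error(icc3_single(cbind(c(1, 2, NA), 1:3)), "non-finite")
  expect_error(icc3_single(cbind(1:3, 1:3, 1:3)), "two columns")
})
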