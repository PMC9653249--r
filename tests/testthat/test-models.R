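test_that("the noiseless limit recovers the generative slope almost exactly", {
  cfg <- simulation_config(
    n_signallers = 4, n_types = 3, n_manual = 3,
    type_frequency_weights = c(3, 2, 1),
    beta_freq = 0, beta_size = -0.3, beta_category = 0,
    sd_signaller = 0, sd_sequence = 0, sd_type = 0, sd_date = 0,
    sd_resid = 0, mu0 = 0.6,
    sequence_size_distribution = c(0.4, 0.3, 0.2, 0.1),
    n_sequences = 120, frame = 1e-6, seed = 2
  )
  seqs <- filter_complete(segment_sequences(simulate_tokens(cfg)))$kept
  fit <- fit_law_model(seqs, "menzerath")
  expect_equal(unname(coef(fit)["size_n"]), -0.3, tolerance = 1e-4)
})

test_that("the Menzerath model recovers a configured size effect", {
  ests <- vapply(1:3, function(i) {
    cfg <- default_study_config(beta_size = -0.3, seed = 810L + i)
    seqs <- filter_complete(segment_sequences(simulate_tokens(cfg)))$kept
    fit <- fit_law_model(seqs, "menzerath")
    co <- fit$coefficients
    expect_true(co$lower[co$term == "size_n"] <= co$estimate[co$term == "size_n"])
    unname(coef(fit)["size_n"])
  }, numeric(1))
  expect_equal(mean(ests), -0.3, tolerance = 0.1)
})

test_that("a null proportion effect is covered by the Zipf interval", {
  covered <- vapply(1:3, function(i) {
    cfg <- default_study_config(beta_freq = 0, seed = 910L + i)
    seqs <- filter_complete(segment_sequences(simulate_tokens(cfg)))$kept
    co <- fit_law_model(seqs, "zipf")$coefficients
    j <- co$term == "proportion_p"
    co$lower[j] <= 0 && 0 <= co$upper[j]
  }, logical(1))
  expect_gte(sum(covered), 2L)
})

test_that("underdetermined random structure raises a structural error", {
  cfg <- duane_study_config(n_sequences = 40, seed = 5L)
  seqs <- filter_complete(segment_sequences(simulate_tokens(cfg)))$kept
  expect_error(fit_law_model(seqs, "menzerath", subset = "all"),
               "random term 'signaller'")
  # the prolific-only spec swaps date in for signaller and fits fine
  fit <- fit_law_model(seqs, "menzerath", subset = "prolific_only")
  expect_true(any(grepl("date", deparse(fit$formula))))
  expect_false(any(grepl("signaller", deparse(fit$formula))))
})

test_that("models use exactly the tokens of complete sequences", {
  toks <- rbind(tokens_with_gaps(rep(0.5, 2), video = "v1"),
                make_tokens(c(50, 50.8), c(NA, 51.2), video = "v1",
                            signaller = "sigB"),
                tokens_with_gaps(rep(0.4, 3), video = "v2",
                                 signaller = "sigB"))
  seqs <- segment_sequences(toks)
  # 3 + 1 + 4 complete tokens; the NA-duration singleton is excluded
  frame <- gesturelaws:::build_analysis_frame(seqs)
  expect_identical(nrow(frame), 8L)
  expect_false(any(is.na(frame$log_dur)))
})

test_that("an identical null model yields a delta of exactly zero", {
  cfg <- simulation_config(n_sequences = 60, n_signallers = 4, seed = 3L)
  seqs <- filter_complete(segment_sequences(simulate_tokens(cfg)))$kept
  cmp <- compare_full_null(seqs, "menzerath", drop_term = character(0),
                           k_folds = 4, seed = 1)
  expect_identical(cmp$delta, 0)
  expect_identical(cmp$se, 0)
})

test_that("a strong configured size effect favours the full model", {
  cfg <- default_study_config(beta_size = -0.4, sd_resid = 0.3,
                              sd_sequence = 0.1, seed = 77L)
  seqs <- filter_complete(segment_sequences(simulate_tokens(cfg)))$kept
  cmp <- compare_full_null(seqs, "menzerath", seed = 3)
  expect_lt(cmp$delta, -cmp$se)  # negative favours full, beyond one SE
})

test_that("subset analyses partition the data and adjust the random terms", {
  cfg <- default_study_config(prolific_fraction = 0.5, seed = 23L)
  seqs <- filter_complete(segment_sequences(simulate_tokens(cfg)))$kept
  res <- run_subset_analyses(seqs, k_folds = 5, seed = 2)
  n_all <- res$all$menzerath$n_tokens
  n_pro <- res$prolific_only$menzerath$n_tokens
  n_exc <- res$exclude_prolific$menzerath$n_tokens
  expect_identical(n_pro + n_exc, n_all)
  expect_gt(n_pro, 0.35 * n_all)
  expect_lt(n_pro, 0.65 * n_all)
  f_pro <- deparse(res$prolific_only$menzerath$formula)
  expect_true(grepl("date", f_pro))
  expect_false(grepl("signaller", f_pro))
  # smaller subsets estimate the same effect less precisely
  se_all <- with(res$all$menzerath$coefficients, se[term == "size_n"])
  se_exc <- with(res$exclude_prolific$menzerath$coefficients,
                 se[term == "size_n"])
  expect_gt(se_exc, se_all)
})

test_that("single-seed recovery is deterministic", {
  cfg <- default_study_config(seed = 333L)
  r1 <- recovery_experiment(cfg, "beta_size", n_seeds = 1)
  r2 <- recovery_experiment(cfg, "beta_size", n_seeds = 1)
  expect_identical(nrow(r1$estimates), 1L)
  expect_equal(r1$estimates, r2$estimates)
  expect_identical(r1$estimates$seed, 333L)
})
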