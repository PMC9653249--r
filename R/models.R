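# Token-level analysis frame: one row per token of a complete sequence,
# with the natural-log response and all model predictors. Type proportions
# are computed on the analysis dataset (after exclusions/subsetting).
build_analysis_frame <- function(seqs) {
  stopifnot(inherits(seqs, "gesture_sequences"))
  keep <- seqs$sequences$complete
  s <- seqs$sequences[keep, , drop = FALSE]
  tok <- seqs$tokens[seqs$tokens$sequence_id %in% s$sequence_id, , drop = FALSE]
  if (!nrow(tok)) stop("no tokens in complete sequences", call. = FALSE)
  if (any(tok$duration_s <= 0))
    stop("non-positive durations cannot be log-transformed", call. = FALSE)
  m <- match(tok$sequence_id, s$sequence_id)
  data.frame(
    log_dur = log(tok$duration_s),
    proportion_p = as.numeric(table(tok$gesture_type)[tok$gesture_type]) /
      nrow(tok),
    category = factor(tok$category, levels = c("manual", "whole_body")),
    size_n = s$size_n[m],
    pwb = s$pwb[m],
    signaller = factor(tok$signaller),
    sequence_id = factor(tok$sequence_id),
    gesture_type = factor(tok$gesture_type),
    date = factor(tok$date),
    stringsAsFactors = FALSE
  )
}

subset_frame <- function(frame, subset) {
  counts <- table(frame$signaller)
  prolific <- names(counts)[which.max(counts)]
  rows <- switch(subset,
                 all = rep(TRUE, nrow(frame)),
                 prolific_only = frame$signaller == prolific,
                 exclude_prolific = frame$signaller != prolific)
  out <- droplevels(frame[rows, , drop = FALSE])
  # proportions are recomputed on the analysed subset
  out$proportion_p <- as.numeric(table(out$gesture_type)[out$gesture_type]) /
    nrow(out)
  out
}

model_terms <- function(model, subset, add_type_random = FALSE) {
  fixed <- switch(model,
                  zipf = c("proportion_p", "category"),
                  menzerath = c("size_n", "pwb"))
  random <- switch(model,
                   zipf = c("signaller", "sequence_id", "gesture_type"),
                   menzerath = c("signaller", "sequence_id"))
  if (add_type_random) random <- union(random, "gesture_type")
  if (subset == "prolific_only") {
    # a single individual: the signaller term is no longer identifiable and
    # date enters instead, guarding against prolific recording days
    random <- setdiff(random, "signaller")
    random <- union(random, "date")
  }
  list(fixed = fixed,
       interest = if (model == "zipf") "proportion_p" else "size_n",
       random = random)
}

check_random_terms <- function(frame, random) {
  for (r in random) {
    if (nlevels(droplevels(frame[[r]])) < 2L)
      stop(sprintf("random term '%s' has fewer than 2 levels", r),
           call. = FALSE)
  }
}

build_formula <- function(fixed, random) {
  rhs <- c(if (length(fixed)) fixed else "1",
           sprintf("(1 | %s)", random))
  stats::as.formula(paste("log_dur ~", paste(rhs, collapse = " + ")))
}

fit_lmm <- function(formula, frame) {
  suppressWarnings(suppressMessages(
    lme4::lmer(formula, data = frame, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE))))
}

#' Fit a hierarchical linguistic-law regression
#'
#' Fits one of the two mixed-effects regressions of natural-log gesture
#' duration:
#' * `model = "zipf"`: `log_dur ~ proportion_p + category +
#'   (1|signaller) + (1|sequence_id) + (1|gesture_type)` — the brevity
#'   question, with gesture category as control;
#' * `model = "menzerath"`: `log_dur ~ size_n + pwb + (1|signaller) +
#'   (1|sequence_id)` — sequence size as predictor with the proportion of
#'   whole-body gestures (PWB) as control.
#'
#' Only tokens belonging to complete sequences enter. For
#' `subset = "prolific_only"` the signaller intercept is removed (a single
#' individual) and a recording-date intercept is added. Type proportions
#' are recomputed on the analysed subset. The backend is a Gaussian linear
#' mixed model estimated by maximum likelihood ([lme4::lmer()]); intervals
#' are Wald 95%.
#'
#' @param seqs A `gesture_sequences` object (see [segment_sequences()]).
#' @param model `"zipf"` or `"menzerath"`.
#' @param subset `"all"`, `"prolific_only"` (the signaller with the most
#'   tokens), or `"exclude_prolific"`.
#' @param add_type_random Also give the Menzerath model a gesture-type
#'   random intercept.
#' @return A `law_fit` object with a `coefficients` table (estimate, se,
#'   Wald 95% bounds per fixed term), the underlying `lmerMod` in `$fit`,
#'   convergence diagnostics, and the analysed row count.
#' @examples
#' toks <- simulate_tokens(default_study_config(seed = 11))
#' seqs <- filter_complete(segment_sequences(toks))$kept
#' fit <- fit_law_model(seqs, "menzerath")
#' coef(fit)["size_n"]
#' @export
fit_law_model <- function(seqs, model = c("zipf", "menzerath"),
                          subset = c("all", "prolific_only",
                                     "exclude_prolific"),
                          add_type_random = FALSE) {
  model <- match.arg(model)
  subset <- match.arg(subset)
  frame <- subset_frame(build_analysis_frame(seqs), subset)
  tm <- model_terms(model, subset, add_type_random)
  fixed <- tm$fixed
  # a control with no variation in the data carries no information
  if ("category" %in% fixed && nlevels(droplevels(frame$category)) < 2L)
    fixed <- setdiff(fixed, "category")
  if ("pwb" %in% fixed && length(unique(frame$pwb)) < 2L)
    fixed <- setdiff(fixed, "pwb")
  check_random_terms(frame, tm$random)
  formula <- build_formula(fixed, tm$random)
  fit <- fit_lmm(formula, frame)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se),
                      lower = unname(est - z * se),
                      upper = unname(est + z * se),
                      row.names = NULL)
  structure(list(model = model, subset = subset, formula = formula,
                 coefficients = coefs, term_of_interest = tm$interest,
                 n_tokens = nrow(frame),
                 n_sequences = nlevels(frame$sequence_id),
                 fit = fit, data = frame,
                 diagnostics = list(
                   singular = lme4::isSingular(fit),
                   converged = length(fit@optinfo$conv$lme4) == 0L,
                   logLik = as.numeric(stats::logLik(fit)))),
            class = "law_fit")
}

#' @export
print.law_fit <- function(x, digits = 3, ...) {
  cat(sprintf("%s-model (%s subset): %d tokens in %d sequences\n",
              tools::toTitleCase(x$model), x$subset, x$n_tokens,
              x$n_sequences))
  cat("  ", deparse(x$formula), "\n", sep = "")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  if (x$diagnostics$singular)
    cat("  note: singular fit (a variance component estimated at zero)\n")
  invisible(x)
}

#' @export
summary.law_fit <- function(object, ...) {
  print(object)
  cat("\nRandom-effect standard deviations (log scale):\n")
  vc <- as.data.frame(lme4::VarCorr(object$fit))
  print(format(vc[, c("grp", "sdcor")], digits = 3), row.names = FALSE)
  invisible(object)
}

#' @export
coef.law_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
confint.law_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients$estimate - z * object$coefficients$se,
              object$coefficients$estimate + z * object$coefficients$se)
  rownames(ci) <- object$coefficients$term
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.law_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...)
  else stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.law_fit <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
fitted.law_fit <- function(object, ...) stats::fitted(object$fit, ...)

# Pointwise out-of-sample log predictive density by K-fold CV at the
# sequence level: held-out tokens are scored under the marginal Gaussian
# N(X beta, sigma^2 + sum of random-intercept variances) of a new cluster.
kfold_elpd <- function(frame, formula, folds) {
  elpd <- numeric(nrow(frame))
  for (k in sort(unique(folds))) {
    test <- folds == k
    fit <- fit_lmm(formula, frame[!test, , drop = FALSE])
    vc <- as.data.frame(lme4::VarCorr(fit))
    total_var <- sum(vc$vcov)
    mu <- stats::predict(fit, newdata = frame[test, , drop = FALSE],
                         re.form = NA, allow.new.levels = TRUE)
    elpd[test] <- stats::dnorm(frame$log_dur[test], mu, sqrt(total_var),
                               log = TRUE)
  }
  elpd
}

#' Full-versus-null predictive comparison
#'
#' Fits the full law model and a null in which the fixed term of interest
#' is removed (controls and random intercepts retained), and compares their
#' out-of-sample expected log predictive density (ELPD) by K-fold
#' cross-validation with whole sequences held out together. The reported
#' `delta` is ELPD(null) − ELPD(full): negative values favour the full
#' model, matching the sign convention of leave-one-out information
#' criterion differences. Its standard error treats the K fold-level
#' difference sums as independent replicates
#' (\eqn{\sqrt{K}\,\mathrm{sd}(\Delta_k)}), the usual K-fold CV
#' uncertainty.
#'
#' @inheritParams fit_law_model
#' @param k_folds Number of cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param drop_term Fixed term(s) removed in the null; defaults to the
#'   model's term of interest (`proportion_p` for Zipf, `size_n` for
#'   Menzerath). An empty character vector makes the null identical to the
#'   full model (delta exactly 0).
#' @return A `law_comparison` object: `delta`, `se`, the two ELPDs, fold
#'   count and row count.
#' @export
compare_full_null <- function(seqs, model = c("zipf", "menzerath"),
                              subset = c("all", "prolific_only",
                                         "exclude_prolific"),
                              k_folds = 10, seed = 1L, drop_term = NULL,
                              add_type_random = FALSE) {
  model <- match.arg(model)
  subset <- match.arg(subset)
  frame <- subset_frame(build_analysis_frame(seqs), subset)
  tm <- model_terms(model, subset, add_type_random)
  fixed <- tm$fixed
  if ("category" %in% fixed && nlevels(droplevels(frame$category)) < 2L)
    fixed <- setdiff(fixed, "category")
  if ("pwb" %in% fixed && length(unique(frame$pwb)) < 2L)
    fixed <- setdiff(fixed, "pwb")
  check_random_terms(frame, tm$random)
  drop_term <- drop_term %||% tm$interest
  f_full <- build_formula(fixed, tm$random)
  f_null <- build_formula(setdiff(fixed, drop_term), tm$random)

  seq_ids <- levels(frame$sequence_id)
  k_folds <- min(k_folds, length(seq_ids))
  fold_of_seq <- with_seed(seed,
    sample(rep_len(seq_len(k_folds), length(seq_ids))))
  folds <- fold_of_seq[match(frame$sequence_id, seq_ids)]

  elpd_full <- kfold_elpd(frame, f_full, folds)
  elpd_null <- if (identical(f_full, f_null)) elpd_full
               else kfold_elpd(frame, f_null, folds)
  diff_i <- elpd_null - elpd_full
  # K-fold CV standard error: fold sums are the independent replicates
  fold_sums <- as.numeric(tapply(diff_i, folds, sum))
  structure(list(delta = sum(diff_i),
                 se = stats::sd(fold_sums) * sqrt(length(fold_sums)),
                 elpd_full = sum(elpd_full), elpd_null = sum(elpd_null),
                 model = model, subset = subset, dropped = drop_term,
                 k_folds = k_folds, n_tokens = nrow(frame),
                 seed = as.integer(seed)),
            class = "law_comparison")
}

#' @export
print.law_comparison <- function(x, ...) {
  cat(sprintf("%s-model full vs null (%s subset, %d-fold CV, %d tokens)\n",
              tools::toTitleCase(x$model), x$subset, x$k_folds, x$n_tokens))
  cat(sprintf("  dropped in null: %s\n",
              if (length(x$dropped)) paste(x$dropped, collapse = ", ")
              else "(nothing)"))
  cat(sprintf("  ELPD difference (null - full): %.2f +/- %.2f  (negative favours full)\n",
              x$delta, x$se))
  invisible(x)
}

#' Replicate both law models across data subsets
#'
#' Runs the Zipf and Menzerath models, each with its full/null comparison,
#' on the full dataset, on the prolific individual only (date random
#' intercept replacing signaller), and on all data excluding the prolific
#' individual. A subset whose fit fails (e.g. too few tokens) is skipped
#' with a warning.
#'
#' @inheritParams compare_full_null
#' @param subsets Which subsets to run.
#' @return A named list (class `subset_analyses`); per subset: `zipf`,
#'   `menzerath` (`law_fit`s), `zipf_delta`, `menzerath_delta`
#'   (`law_comparison`s), or an `error` message.
#' @export
run_subset_analyses <- function(seqs,
                                subsets = c("all", "prolific_only",
                                            "exclude_prolific"),
                                k_folds = 10, seed = 1L) {
  out <- lapply(subsets, function(ss) {
    tryCatch({
      list(zipf = fit_law_model(seqs, "zipf", ss),
           menzerath = fit_law_model(seqs, "menzerath", ss),
           zipf_delta = compare_full_null(seqs, "zipf", ss,
                                          k_folds = k_folds, seed = seed),
           menzerath_delta = compare_full_null(seqs, "menzerath", ss,
                                               k_folds = k_folds,
                                               seed = seed))
    }, error = function(e) {
      warning(sprintf("subset '%s' skipped: %s", ss, conditionMessage(e)),
              call. = FALSE)
      list(error = conditionMessage(e))
    })
  })
  names(out) <- subsets
  class(out) <- "subset_analyses"
  out
}

#' @export
print.subset_analyses <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    if (!is.null(x[[nm]]$error)) {
      cat("  skipped:", x[[nm]]$error, "\n")
    } else {
      print(x[[nm]]$zipf)
      print(x[[nm]]$menzerath)
      print(x[[nm]]$zipf_delta)
      print(x[[nm]]$menzerath_delta)
    }
  }
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Simulates token streams from a configuration with a known slope,
#' re-analyses each stream with the matching law model (Zipf for
#' `beta_freq`, Menzerath for `beta_size`), and summarizes how well the
#' configured truth is recovered: per-seed point estimates, the mean
#' estimate, and the coverage of the Wald 95% intervals. Single-signaller
#' configurations are fitted with the date-for-signaller random-term swap.
#' A seed whose fit fails is recorded, not fatal.
#'
#' @param config A [simulation_config()]; `config$seed` seeds the first
#'   replicate and successive replicates increment it.
#' @param parameter `"beta_size"` or `"beta_freq"`.
#' @param n_seeds Number of simulate-and-refit replicates.
#' @param gap_threshold_s Segmentation threshold used in re-analysis.
#' @return A `recovery_summary`: `true_value`, per-seed `estimates` data
#'   frame (estimate, se, interval, coverage flag), `mean_estimate`,
#'   `coverage`, and the count of successful fits.
#' @examples
#' \donttest{
#' cfg <- default_study_config(beta_size = -0.18, seed = 100)
#' recovery_experiment(cfg, "beta_size", n_seeds = 3)
#' }
#' @export
recovery_experiment <- function(config, parameter = c("beta_size",
                                                      "beta_freq"),
                                n_seeds = 10, gap_threshold_s = 1.0) {
  parameter <- match.arg(parameter)
  validate_sim_config(config)
  model <- if (parameter == "beta_size") "menzerath" else "zipf"
  term <- if (parameter == "beta_size") "size_n" else "proportion_p"
  subset <- if (config$n_signallers == 1L) "prolific_only" else "all"
  true_value <- config[[parameter]]
  rows <- lapply(seq_len(n_seeds), function(i) {
    cfg_i <- config
    cfg_i$seed <- as.integer(config$seed + i - 1L)
    tryCatch({
      toks <- simulate_tokens(cfg_i)
      seqs <- filter_complete(segment_sequences(toks, gap_threshold_s))$kept
      fit <- fit_law_model(seqs, model, subset)
      co <- fit$coefficients
      j <- match(term, co$term)
      data.frame(seed = cfg_i$seed, estimate = co$estimate[j], se = co$se[j],
                 lower = co$lower[j], upper = co$upper[j],
                 covered = co$lower[j] <= true_value &
                   true_value <= co$upper[j],
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(seed = cfg_i$seed, estimate = NA_real_, se = NA_real_,
                 lower = NA_real_, upper = NA_real_, covered = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
  })
  est <- do.call(rbind, rows)
  ok <- !is.na(est$estimate)
  structure(list(parameter = parameter, true_value = true_value,
                 model = model, subset = subset, estimates = est,
                 mean_estimate = mean(est$estimate[ok]),
                 coverage = mean(est$covered[ok]),
                 n_ok = sum(ok), n_seeds = n_seeds),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat(sprintf("Parameter recovery for %s (true value %.3f, %s-model, %s)\n",
              x$parameter, x$true_value, x$model, x$subset))
  cat(sprintf("  %d/%d fits succeeded; mean estimate %.3f; 95%% interval coverage %.2f\n",
              x$n_ok, x$n_seeds, x$mean_estimate, x$coverage))
  invisible(x)
}
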