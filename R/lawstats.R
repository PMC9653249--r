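# Rank correlation with explicit tie degeneracy: a constant vector carries
# no ordering signal, so the coefficient is defined as 0 rather than NaN.
rank_cor <- function(x, y, method = "kendall") {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(0)
  stats::cor(x, y, method = method)
}

# All permutations of 1..n (n small); used for exact permutation nulls.
perm_all <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Decide between exhaustive enumeration of the n! pairings and Monte Carlo
# sampling: enumerate whenever it is no more work than the requested draws.
perm_scheme <- function(n_items, n_perm, exact) {
  exact <- match.arg(exact, c("auto", "never", "always"))
  use_exact <- switch(exact,
                      always = TRUE,
                      never = FALSE,
                      auto = factorial(n_items) <= n_perm)
  if (use_exact && n_items > 9)
    stop("exact enumeration infeasible for ", n_items, " items", call. = FALSE)
  use_exact
}

#' Zipf's law of brevity: frequency-duration rank correlation
#'
#' Correlates per-type token counts with per-type duration summaries and
#' obtains a permutation p-value by shuffling the duration vector across
#' types while holding frequencies fixed. Kendall's tau-b (tie-corrected) is
#' the default coefficient, appropriate for durations tied at frame
#' resolution; the per-type median duration is the default summary. When the
#' number of types is small enough that all pairings can be enumerated (or
#' `exact = "always"`), the p-value is the exact permutation probability;
#' otherwise it is the add-one Monte Carlo estimate
#' \eqn{(r + 1)/(n_{perm} + 1)}.
#'
#' @param repertoire A `repertoire` data frame from [repertoire_summary()].
#' @param method `"kendall"` (tau-b) or `"spearman"`.
#' @param duration_summary Per-type duration summary: `"median"` (default)
#'   or `"mean"`.
#' @param n_perm Number of Monte Carlo permutations (at least 99).
#' @param seed Integer seed for the permutation draws.
#' @param alternative `"two.sided"` (default) or `"less"`, the one-sided
#'   test in the brevity direction (negative correlation).
#' @param exact `"auto"` (enumerate all pairings when feasible within
#'   `n_perm`), `"never"`, or `"always"`.
#' @return A `brevity_test` object: coefficient, p-value, number of types,
#'   and the settings used.
#' @examples
#' rep <- data.frame(gesture_type = c("a", "b", "c", "d"),
#'                   n_tokens = c(40, 30, 20, 10),
#'                   median_duration_s = c(0.5, 1, 2, 4),
#'                   mean_duration_s = c(0.5, 1, 2, 4))
#' brevity_correlation(rep, n_perm = 999, seed = 1)
#' @export
brevity_correlation <- function(repertoire,
                                method = c("kendall", "spearman"),
                                duration_summary = c("median", "mean"),
                                n_perm = 999, seed = 1L,
                                alternative = c("two.sided", "less"),
                                exact = "auto") {
  method <- match.arg(method)
  duration_summary <- match.arg(duration_summary)
  alternative <- match.arg(alternative)
  if (nrow(repertoire) < 3L)
    stop("brevity correlation needs at least 3 gesture types", call. = FALSE)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  freq <- repertoire$n_tokens
  d <- repertoire[[paste0(duration_summary, "_duration_s")]]
  obs <- rank_cor(freq, d, method)
  stat <- function(dd) rank_cor(freq, dd, method)
  as_extreme <- function(r) {
    if (alternative == "two.sided") abs(r) >= abs(obs) - 1e-12
    else r <= obs + 1e-12
  }
  if (perm_scheme(length(d), n_perm, exact)) {
    perms <- perm_all(length(d))
    rs <- apply(perms, 1L, function(ix) stat(d[ix]))
    p <- mean(as_extreme(rs))
    n_used <- nrow(perms)
  } else {
    rs <- with_seed(seed, replicate(n_perm, stat(sample(d))))
    p <- (1 + sum(as_extreme(rs))) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(coefficient = obs, p_value = p, n_types = length(d),
                 duration_summary = duration_summary, method = method,
                 alternative = alternative, n_perm = n_used,
                 exact = n_used != n_perm || factorial(length(d)) == n_used,
                 seed = as.integer(seed)),
            class = "brevity_test")
}

#' @export
print.brevity_test <- function(x, ...) {
  cat("Zipf's law of brevity: frequency-duration rank correlation\n")
  cat(sprintf("  %s correlation (%s durations, %d types): %.4f\n",
              x$method, x$duration_summary, x$n_types, x$coefficient))
  cat(sprintf("  permutation p (%s, %s%d permutations): %.4g\n",
              x$alternative, if (x$exact) "exact, " else "", x$n_perm,
              x$p_value))
  invisible(x)
}

#' Compression test of the mean code length
#'
#' Computes the frequency-weighted mean signal duration
#' \eqn{L = \sum_i p_i d_i} over gesture types and asks whether it is
#' significantly smaller than expected were durations assigned to
#' frequencies at random: the null distribution permutes the per-type
#' duration vector across types with frequencies fixed, and the p-value is
#' the (add-one) fraction of permutations with \eqn{L^* \le L_{obs}}. Also
#' reported are the minimal code length \eqn{L_{min}} (largest \eqn{p_i}
#' paired with smallest \eqn{d_i}), the pessimal \eqn{L_{max}}, and the
#' degree of optimization
#' \eqn{\eta = (\bar L_{rand} - L_{obs}) / (\bar L_{rand} - L_{min})}.
#'
#' @inheritParams brevity_correlation
#' @param duration_summary Per-type duration used for \eqn{d_i}: `"mean"`
#'   (default; L is then an expectation and, with token proportions for
#'   \eqn{p_i}, equals the overall mean token duration) or `"median"`.
#' @return A `compression_test` object with fields `L_obs`, `L_min`,
#'   `L_max`, `L_rand_mean`, `L_rand_sd`, `p_value`, `optimization_eta`,
#'   `n_perm`.
#' @examples
#' rep <- data.frame(gesture_type = c("a", "b"), n_tokens = c(3, 1),
#'                   proportion_p = c(0.75, 0.25),
#'                   mean_duration_s = c(1, 2), median_duration_s = c(1, 2))
#' compression_test(rep, n_perm = 999, seed = 1)$L_obs
#' @export
compression_test <- function(repertoire, n_perm = 999, seed = 1L,
                             duration_summary = c("mean", "median"),
                             exact = "auto") {
  duration_summary <- match.arg(duration_summary)
  if (nrow(repertoire) < 2L)
    stop("compression test needs at least 2 gesture types", call. = FALSE)
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  p <- repertoire$proportion_p %||%
    (repertoire$n_tokens / sum(repertoire$n_tokens))
  d <- repertoire[[paste0(duration_summary, "_duration_s")]]
  L_obs <- sum(p * d)
  L_min <- sum(sort(p, decreasing = TRUE) * sort(d))
  L_max <- sum(sort(p, decreasing = TRUE) * sort(d, decreasing = TRUE))
  if (perm_scheme(length(d), n_perm, exact)) {
    perms <- perm_all(length(d))
    Ls <- apply(perms, 1L, function(ix) sum(p * d[ix]))
    p_val <- mean(Ls <= L_obs + 1e-12)
    n_used <- nrow(perms)
    is_exact <- TRUE
  } else {
    Ls <- with_seed(seed, replicate(n_perm, sum(p * sample(d))))
    p_val <- (1 + sum(Ls <= L_obs + 1e-12)) / (n_perm + 1)
    n_used <- n_perm
    is_exact <- FALSE
  }
  L_rand_mean <- mean(Ls)
  denom <- L_rand_mean - L_min
  eta <- if (denom > 1e-12) (L_rand_mean - L_obs) / denom else NA_real_
  structure(list(L_obs = L_obs, L_min = L_min, L_max = L_max,
                 L_rand_mean = L_rand_mean, L_rand_sd = stats::sd(Ls),
                 p_value = p_val, n_perm = n_used, exact = is_exact,
                 optimization_eta = eta, n_types = length(d),
                 duration_summary = duration_summary,
                 seed = as.integer(seed)),
            class = "compression_test")
}

#' @export
print.compression_test <- function(x, ...) {
  cat("Compression test: mean code length vs permutation null\n")
  cat(sprintf("  L_obs = %.4f s  (L_min = %.4f, L_max = %.4f)\n",
              x$L_obs, x$L_min, x$L_max))
  cat(sprintf("  permutation null: mean %.4f, sd %.4f (%s%d permutations)\n",
              x$L_rand_mean, x$L_rand_sd, if (x$exact) "exact, " else "",
              x$n_perm))
  cat(sprintf("  Pr(L* <= L_obs) = %.4g;  optimization eta = %.3f\n",
              x$p_value, x$optimization_eta))
  invisible(x)
}

#' Menzerath's law: sequence size versus mean constituent duration
#'
#' Builds one point per complete sequence (its size and the mean duration of
#' its member gestures), rank-correlates duration on size with a permutation
#' p-value (shuffling mean durations across sequences), and fits the
#' two-parameter Menzerath-Altmann power law \eqn{d = a n^b} by least
#' squares on the log-log scale.
#'
#' @param seqs A `gesture_sequences` object; only complete sequences enter.
#' @inheritParams brevity_correlation
#' @param alternative `"two.sided"` (default) or `"less"` (the Menzerath
#'   direction: duration decreasing in size).
#' @return A `menzerath_test` object: `points` (data frame `size_n`,
#'   `mean_duration_s`), `coefficient`, `p_value`, `mal_a`, `mal_b`, counts
#'   and settings. With all sequences of one size the correlation and the
#'   power-law fit are undefined and returned as `NA` with a flag.
#' @examples
#' toks <- simulate_tokens(default_study_config(seed = 2))
#' seqs <- filter_complete(segment_sequences(toks))$kept
#' menzerath_stats(seqs, n_perm = 199, seed = 1)
#' @export
menzerath_stats <- function(seqs, method = c("kendall", "spearman"),
                            n_perm = 999, seed = 1L,
                            alternative = c("two.sided", "less")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  stopifnot(inherits(seqs, "gesture_sequences"))
  if (n_perm < 99) stop("n_perm must be at least 99", call. = FALSE)
  s <- seqs$sequences[seqs$sequences$complete, , drop = FALSE]
  if (!nrow(s)) stop("no complete sequences", call. = FALSE)
  pts <- data.frame(size_n = s$size_n, mean_duration_s = s$mean_duration_s)
  degenerate <- length(unique(pts$size_n)) < 2L
  if (degenerate) {
    res <- list(points = pts, coefficient = NA_real_, p_value = NA_real_,
                mal_a = NA_real_, mal_b = NA_real_, degenerate = TRUE)
  } else {
    obs <- rank_cor(pts$size_n, pts$mean_duration_s, method)
    as_extreme <- function(r) {
      if (alternative == "two.sided") abs(r) >= abs(obs) - 1e-12
      else r <= obs + 1e-12
    }
    rs <- with_seed(seed, replicate(n_perm,
      rank_cor(pts$size_n, sample(pts$mean_duration_s), method)))
    p <- (1 + sum(as_extreme(rs))) / (n_perm + 1)
    fit <- stats::lm(log(mean_duration_s) ~ log(size_n), data = pts)
    res <- list(points = pts, coefficient = obs, p_value = p,
                mal_a = exp(unname(stats::coef(fit)[1])),
                mal_b = unname(stats::coef(fit)[2]), degenerate = FALSE)
  }
  res$n_sequences <- nrow(pts)
  res$method <- method
  res$alternative <- alternative
  res$n_perm <- n_perm
  res$seed <- as.integer(seed)
  structure(res, class = "menzerath_test")
}

#' @export
print.menzerath_test <- function(x, ...) {
  cat("Menzerath's law: sequence size vs mean gesture duration\n")
  if (x$degenerate) {
    cat(sprintf("  %d sequences, all of one size: correlation undefined\n",
                x$n_sequences))
    return(invisible(x))
  }
  cat(sprintf("  %s correlation over %d sequences: %.4f (permutation p = %.4g, %s)\n",
              x$method, x$n_sequences, x$coefficient, x$p_value,
              x$alternative))
  cat(sprintf("  Menzerath-Altmann fit d = a*n^b:  a = %.3f s,  b = %.3f\n",
              x$mal_a, x$mal_b))
  invisible(x)
}

#' @export
plot.menzerath_test <- function(x, ...) {
  pts <- x$points
  plot(jitter(pts$size_n, 0.15), pts$mean_duration_s, log = "y",
       xlab = "sequence size (tokens)",
       ylab = "mean gesture duration (s)", pch = 16,
       col = grDevices::adjustcolor("steelblue", 0.5), ...)
  if (!x$degenerate) {
    nn <- seq(min(pts$size_n), max(pts$size_n), length.out = 50)
    graphics::lines(nn, x$mal_a * nn^x$mal_b, lwd = 2)
  }
  invisible(x)
}

#' Intra-observer reliability: ICC(3,1), two-way mixed, consistency
#'
#' Single-measure intraclass correlation for two coding occasions of the
#' same items by the same rater, from the two-way ANOVA decomposition:
#' \eqn{(MS_{rows} - MS_{err}) / (MS_{rows} + (k-1) MS_{err})} with
#' \eqn{k = 2}. The consistency form is insensitive to an additive shift
#' between occasions. An F test of the row effect supplies the p-value.
#'
#' @param pairs A two-column matrix or data frame: first and second coding
#'   of each item (seconds).
#' @return An `icc_result` with fields `icc`, `p_value`, `n_items`, `model`.
#' @examples
#' icc3_single(cbind(c(1, 2, 3, 4, 5), c(1.1, 2.0, 3.2, 3.9, 5.1)))
#' @export
icc3_single <- function(pairs) {
  m <- as.matrix(pairs)
  if (ncol(m) != 2L) stop("pairs must have exactly two columns", call. = FALSE)
  if (nrow(m) < 3L)
    stop("at least 3 items are required for the ICC", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite coding values", call. = FALSE)
  n <- nrow(m); k <- 2L
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc <- if (ms_rows + (k - 1) * ms_err <= 0) NA_real_ else
    (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  f <- if (ms_err > 0) ms_rows / ms_err else Inf
  p <- stats::pf(f, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = icc, p_value = p, n_items = n,
                 model = "ICC(3,1), two-way mixed, consistency, k=2"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s\n  ICC = %.4f over %d items (F-test p = %.3g)\n",
              x$model, x$icc, x$n_items, x$p_value))
  invisible(x)
}
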