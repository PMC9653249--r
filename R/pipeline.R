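#' Run the full linguistic-laws analysis on a token stream
#'
#' Ties all stages together: segmentation at the gap rule, the completeness
#' exclusion, repertoire and contingency summaries, the brevity and
#' compression permutation tests, Menzerath statistics, and the
#' hierarchical models with full/null comparison per subset. All
#' randomness fans out deterministically from the single `seed`.
#'
#' @param tokens A `gesture_tokens` data frame (see [read_tokens()]).
#' @param gap_threshold_s Sequence gap threshold in seconds.
#' @param n_perm Permutations for the law tests (at least 99).
#' @param seed Master seed.
#' @param subsets Model subsets to run (see [run_subset_analyses()]).
#' @param k_folds Cross-validation folds for the full/null comparison.
#' @param fit_models Set `FALSE` to skip the (slower) model stage.
#' @return A `gesture_report` list with components `counts`, `sequences`
#'   (the filtered `gesture_sequences`), `n_excluded`, `repertoire`,
#'   `contingency`, `composition`, `brevity`, `compression`, `menzerath`,
#'   `models`, `timings` (seconds per stage) and `settings`.
#' @examples
#' toks <- simulate_tokens(simulation_config(n_sequences = 40, seed = 5))
#' rep <- analyze_gestures(toks, n_perm = 99, fit_models = FALSE)
#' rep$counts
#' @export
analyze_gestures <- function(tokens, gap_threshold_s = 1.0, n_perm = 9999,
                             seed = 1L,
                             subsets = c("all", "prolific_only",
                                         "exclude_prolific"),
                             k_folds = 10, fit_models = TRUE) {
  if (!nrow(as.data.frame(tokens)))
    stop("empty token stream: nothing to analyse", call. = FALSE)
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  seed <- as.integer(seed)

  segmented <- clock("segmentation",
                     segment_sequences(tokens, gap_threshold_s))
  filt <- filter_complete(segmented)
  seqs <- filt$kept
  repertoire <- clock("repertoire", repertoire_summary(seqs$tokens))
  contingency <- length_composition_table(seqs)
  composition <- composition_by_size(seqs)
  brevity <- clock("brevity",
                   brevity_correlation(repertoire, n_perm = n_perm,
                                       seed = seed + 1L))
  compression <- clock("compression",
                       compression_test(repertoire, n_perm = n_perm,
                                        seed = seed + 2L))
  menzerath <- clock("menzerath",
                     menzerath_stats(seqs, n_perm = n_perm,
                                     seed = seed + 3L))
  models <- if (fit_models)
    clock("models", run_subset_analyses(seqs, subsets = subsets,
                                        k_folds = k_folds,
                                        seed = seed + 4L))
  else NULL

  structure(list(
    counts = list(n_tokens = nrow(as.data.frame(tokens)),
                  n_tokens_analysed = nrow(seqs$tokens),
                  n_types = length(unique(seqs$tokens$gesture_type)),
                  n_signallers = length(unique(seqs$tokens$signaller)),
                  n_sequences_detected = nrow(segmented$sequences),
                  n_sequences_analysed = nrow(seqs$sequences),
                  n_excluded = filt$n_excluded),
    sequences = seqs, n_excluded = filt$n_excluded,
    repertoire = repertoire, contingency = contingency,
    composition = composition, brevity = brevity,
    compression = compression, menzerath = menzerath, models = models,
    timings = timings,
    settings = list(gap_threshold_s = gap_threshold_s, n_perm = n_perm,
                    seed = seed, k_folds = k_folds,
                    version = as.character(utils::packageVersion("gesturelaws")))),
    class = "gesture_report")
}

#' @export
print.gesture_report <- function(x, ...) {
  c0 <- x$counts
  cat("Linguistic-laws analysis report\n")
  cat(sprintf("  %d tokens (%d types, %d signallers); %d sequences detected, %d excluded as incomplete, %d analysed\n",
              c0$n_tokens, c0$n_types, c0$n_signallers,
              c0$n_sequences_detected, c0$n_excluded,
              c0$n_sequences_analysed))
  print(x$brevity)
  print(x$compression)
  print(x$menzerath)
  if (!is.null(x$models)) print(x$models)
  invisible(x)
}

report_models_list <- function(models) {
  lapply(models, function(sub) {
    if (!is.null(sub$error)) return(list(error = sub$error))
    lapply(sub[c("zipf", "menzerath")], function(f) {
      list(formula = deparse(f$formula), coefficients = f$coefficients,
           n_tokens = f$n_tokens, n_sequences = f$n_sequences,
           singular = f$diagnostics$singular)
    }) |>
      c(list(zipf_delta = sub$zipf_delta[c("delta", "se", "k_folds")],
             menzerath_delta = sub$menzerath_delta[c("delta", "se",
                                                     "k_folds")]))
  })
}

#' Write a report bundle to disk
#'
#' Emits `repertoire.csv`, `contingency.csv`, `sequences.csv`,
#' `composition.csv`, `lawstats.json`, `models.json` (when models were
#' fitted), a human-readable `summary.txt`, and a `manifest.json` listing
#' the files written, the settings and stage timings.
#'
#' @param report A `gesture_report` from [analyze_gestures()].
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gesture_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit_csv <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    files <<- c(files, name)
  }
  emit_csv(report$repertoire, "repertoire.csv")
  emit_csv(report$contingency, "contingency.csv")
  emit_csv(report$sequences$sequences, "sequences.csv")
  emit_csv(report$composition, "composition.csv")

  law <- list(
    brevity = unclass(report$brevity),
    compression = unclass(report$compression),
    menzerath = unclass(report$menzerath)[
      setdiff(names(report$menzerath), "points")],
    version = report$settings$version
  )
  jsonlite::write_json(law, file.path(dir, "lawstats.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, "lawstats.json")
  if (!is.null(report$models)) {
    jsonlite::write_json(c(report_models_list(report$models),
                           list(version = report$settings$version)),
                         file.path(dir, "models.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    files <- c(files, "models.json")
  }

  summary_path <- file.path(dir, "summary.txt")
  writeLines(utils::capture.output({
    print(report)
    cat("\nSequence composition by length:\n")
    print(report$contingency)
    cat("\nStage timings (s):\n")
    print(unlist(report$timings))
    cat("\nSettings:\n")
    utils::str(report$settings, give.attr = FALSE)
  }), summary_path)
  files <- c(files, "summary.txt")

  jsonlite::write_json(list(files = files, settings = report$settings,
                            timings = as.list(report$timings)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Command-style entry points
#'
#' Thin wrappers used by the command-line script: `cmd_simulate()` reads a
#' plain-text `key: value` configuration, simulates a token stream and
#' writes the canonical CSV plus a ground-truth JSON sidecar;
#' `cmd_analyze()` reads a token CSV, runs [analyze_gestures()] and writes
#' the report bundle. On a stage failure `cmd_analyze()` still writes a
#' manifest of the outputs completed so far before signalling the error.
#'
#' @param config_path Path to a simulation config file
#'   (see [write_sim_config()]).
#' @param out_csv Output CSV path for the simulated stream.
#' @param input_csv Token CSV to analyse.
#' @param out_dir Report output directory.
#' @inheritParams analyze_gestures
#' @return `cmd_simulate()`: the CSV path; `cmd_analyze()`: the
#'   `gesture_report`, invisibly.
#' @export
cmd_simulate <- function(config_path, out_csv) {
  cfg <- read_sim_config(config_path)
  toks <- simulate_tokens(cfg)
  write_tokens(toks, out_csv, config = cfg)
  message(sprintf("wrote %d tokens to %s", nrow(toks), out_csv))
  invisible(out_csv)
}

#' @rdname cmd_simulate
#' @export
cmd_analyze <- function(input_csv, out_dir, gap_threshold_s = 1.0,
                        n_perm = 9999, seed = 1L,
                        subsets = c("all", "prolific_only",
                                    "exclude_prolific"),
                        fit_models = TRUE) {
  toks <- read_tokens(input_csv)
  report <- tryCatch(
    analyze_gestures(toks, gap_threshold_s = gap_threshold_s,
                     n_perm = n_perm, seed = seed, subsets = subsets,
                     fit_models = fit_models),
    error = function(e) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(list(error = conditionMessage(e), files = list()),
                           file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE)
      stop(e)
    })
  write_report(report, out_dir)
  invisible(report)
}
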