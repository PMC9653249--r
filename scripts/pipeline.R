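#!/usr/bin/env Rscript
# Command-line wrapper over the package pipeline.
#
#   Rscript scripts/pipeline.R simulate --config <cfg> --out <tokens.csv>
#   Rscript scripts/pipeline.R analyze --in <tokens.csv> --out <dir>
#          [--gap 1.0] [--n-perm 9999] [--seed 1]
#          [--subset all,prolific,exclude-prolific] [--no-models]

suppressPackageStartupMessages(library(gesturelaws))

args <- commandArgs(trailingOnly = TRUE)
if (!length(args)) {
  message("usage: pipeline.R {simulate|analyze} [flags]; see script header")
  quit(status = 2)
}
verb <- args[1]
flags <- args[-1]
get_flag <- function(name, default = NULL) {
  i <- match(name, flags)
  if (is.na(i) || i == length(flags)) return(default)
  flags[i + 1L]
}

status <- tryCatch({
  if (verb == "simulate") {
    cmd_simulate(get_flag("--config"), get_flag("--out", "tokens.csv"))
  } else if (verb == "analyze") {
    subset_map <- c(all = "all", prolific = "prolific_only",
                    `exclude-prolific` = "exclude_prolific")
    subsets <- unname(subset_map[strsplit(
      get_flag("--subset", "all,prolific,exclude-prolific"), ",")[[1]]])
    if (anyNA(subsets)) stop("unknown --subset value")
    cmd_analyze(get_flag("--in"), get_flag("--out", "report"),
                gap_threshold_s = as.numeric(get_flag("--gap", "1.0")),
                n_perm = as.integer(get_flag("--n-perm", "9999")),
                seed = as.integer(get_flag("--seed", "1")),
                subsets = subsets,
                fit_models = !"--no-models" %in% flags)
  } else {
    stop("unknown verb: ", verb)
  }
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
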