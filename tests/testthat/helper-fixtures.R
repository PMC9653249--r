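# Construct a token table from explicit start/end times (one signaller and
# video unless stated), for engineering exact gap patterns.
make_tokens <- function(start, end, type = NULL, signaller = "sigA",
                        video = "vid1", category = "manual",
                        form = "loose", date = "2010-01-01") {
  n <- length(start)
  type <- type %||% sprintf("type%02d", seq_len(n))
  data.frame(
    signaller = rep_len(signaller, n), recipient = rep_len("femA", n),
    date = rep_len(date, n), video_id = rep_len(video, n),
    gesture_type = rep_len(type, n),
    category = rep_len(category, n), duration_form = rep_len(form, n),
    start_s = start, end_s = end, duration_s = end - start,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tokens spaced by explicit gaps (end-to-start), all of a given duration.
tokens_with_gaps <- function(gaps, dur = 0.4, ...) {
  start <- numeric(length(gaps) + 1L)
  for (i in seq_along(gaps)) start[i + 1L] <- start[i] + dur + gaps[i]
  make_tokens(start, start + dur, ...)
}

# Independent scan partitioner: walks each signaller-video group token by
# token, opening a new sequence whenever the gap rule says so. Used as the
# brute-force oracle for segment_sequences().
brute_force_partition <- function(tokens, threshold = 1.0,
                                  mode = c("end_start", "start_start")) {
  mode <- match.arg(mode)
  tokens <- tokens[order(tokens$signaller, tokens$video_id,
                         tokens$start_s), , drop = FALSE]
  ids <- integer(nrow(tokens))
  cur <- 0L
  for (i in seq_len(nrow(tokens))) {
    open_new <- TRUE
    if (i > 1L &&
        tokens$signaller[i] == tokens$signaller[i - 1L] &&
        tokens$video_id[i] == tokens$video_id[i - 1L]) {
      ref <- if (mode == "end_start") tokens$end_s[i - 1L]
             else tokens$start_s[i - 1L]
      gap <- tokens$start_s[i] - ref
      if (!is.na(gap) && gap < threshold) open_new <- FALSE
    }
    if (open_new) cur <- cur + 1L
    ids[i] <- cur
  }
  ids
}

# Random token stream (possibly with overlaps and missing ends) for
# property tests of the segmentation.
random_stream <- function(n, seed) {
  set.seed(seed)
  sig <- sample(c("s1", "s2"), n, replace = TRUE)
  vid <- sample(c("v1", "v2"), n, replace = TRUE)
  start <- round(runif(n, 0, 30), 2)
  dur <- sample(1:20, n, replace = TRUE) * 0.04
  end <- start + dur
  end[runif(n) < 0.1] <- NA
  make_tokens(start, end, type = sample(letters[1:4], n, replace = TRUE),
              signaller = sig, video = vid)
}

# Independent recursive permutation enumerator (oracle for exact
# permutation p-values; deliberately separate from the package internals).
enumerate_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in enumerate_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Type-level null repertoire: frequencies from a study-scale multinomial,
# per-type duration summaries drawn iid (duration independent of type).
null_repertoire <- function(seed, n_types = 26, n_tokens = 560) {
  set.seed(seed)
  w <- (1 / seq_len(n_types)) / sum(1 / seq_len(n_types))
  counts <- pmax(as.integer(stats::rmultinom(1, n_tokens, w)), 1L)
  d <- stats::rlnorm(n_types, meanlog = 0.44, sdlog = 0.6)
  data.frame(gesture_type = sprintf("t%02d", seq_len(n_types)),
             n_tokens = counts, proportion_p = counts / sum(counts),
             mean_duration_s = d * 1.2, median_duration_s = d,
             stringsAsFactors = FALSE)
}
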