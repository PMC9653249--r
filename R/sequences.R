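#' Segment a token stream into rapid sequences by the 1-second gap rule
#'
#' Within each signaller-by-video group, consecutive tokens whose
#' inter-token gap is strictly less than `gap_threshold_s` join the same
#' sequence; a gap of the threshold or more closes it ("less than 1 s" —
#' the boundary is exclusive). Single gestures form sequences of length one.
#' The gap is measured end-to-start by default (the interval between the end
#' of one token and the start of the next); negative gaps (overlapping
#' tokens) always join. A token with a missing end time closes its sequence,
#' since its gap to the next token is undefined, and marks the sequence
#' incomplete. Sequences never span videos or signallers.
#'
#' @param tokens A `gesture_tokens` data frame (see [read_tokens()]).
#' @param gap_threshold_s Gap threshold in seconds (default 1.0).
#' @param gap_mode `"end_start"` (default) measures the silent interval
#'   between tokens; `"start_start"` measures onset-to-onset.
#' @return An object of class `gesture_sequences`: a list with
#'   * `sequences`: one row per sequence (`sequence_id`, `signaller`,
#'     `video_id`, `date`, `size_n`, `complete`, `pwb` — proportion of
#'     whole-body tokens, `same_type` — `NA` for singletons,
#'     `mean_duration_s` — `NA` unless complete),
#'   * `tokens`: the input tokens with a `sequence_id` column, in
#'     segmentation order,
#'   * the threshold and gap mode used.
#' @examples
#' toks <- simulate_tokens(simulation_config(n_sequences = 10, seed = 3))
#' seqs <- segment_sequences(toks)
#' seqs$sequences$size_n
#' @export
segment_sequences <- function(tokens, gap_threshold_s = 1.0,
                              gap_mode = c("end_start", "start_start")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(is_scalar_num(gap_threshold_s), gap_threshold_s > 0)
  tokens <- as.data.frame(tokens)
  if (!nrow(tokens)) {
    empty <- structure(list(
      sequences = data.frame(sequence_id = character(0),
                             signaller = character(0),
                             video_id = character(0), date = character(0),
                             size_n = integer(0), complete = logical(0),
                             pwb = numeric(0), same_type = logical(0),
                             mean_duration_s = numeric(0)),
      tokens = cbind(tokens, sequence_id = character(0)),
      gap_threshold_s = gap_threshold_s, gap_mode = gap_mode),
      class = "gesture_sequences")
    return(empty)
  }
  ord <- order(tokens$signaller, tokens$video_id, tokens$start_s)
  tokens <- tokens[ord, , drop = FALSE]
  grp <- paste(tokens$signaller, tokens$video_id, sep = "\r")
  n <- nrow(tokens)
  prev_ref <- if (gap_mode == "end_start") tokens$end_s else tokens$start_s
  gap_to_prev <- c(NA_real_, tokens$start_s[-1] - prev_ref[-n])
  new_seq <- c(TRUE, grp[-1] != grp[-n]) |
    is.na(gap_to_prev) | gap_to_prev >= gap_threshold_s
  seq_index <- cumsum(new_seq)
  tokens$sequence_id <- sprintf("seq%05d", seq_index)

  idx <- split(seq_len(n), seq_index)
  seq_df <- data.frame(
    sequence_id = sprintf("seq%05d", as.integer(names(idx))),
    signaller = vapply(idx, function(i) tokens$signaller[i[1]], character(1)),
    video_id = vapply(idx, function(i) tokens$video_id[i[1]], character(1)),
    date = vapply(idx, function(i) tokens$date[i[1]], character(1)),
    size_n = lengths(idx),
    complete = vapply(idx, function(i) !anyNA(tokens$duration_s[i]),
                      logical(1)),
    pwb = vapply(idx, function(i) mean(tokens$category[i] == "whole_body"),
                 numeric(1)),
    same_type = vapply(idx, function(i)
      if (length(i) < 2L) NA else length(unique(tokens$gesture_type[i])) == 1L,
      logical(1)),
    mean_duration_s = vapply(idx, function(i) {
      d <- tokens$duration_s[i]
      if (anyNA(d)) NA_real_ else mean(d)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(sequences = seq_df, tokens = tokens,
                 gap_threshold_s = gap_threshold_s, gap_mode = gap_mode),
            class = "gesture_sequences")
}

#' @export
print.gesture_sequences <- function(x, ...) {
  s <- x$sequences
  cat(sprintf("Gesture sequences: %d sequences from %d tokens (gap %s < %.3g s)\n",
              nrow(s), nrow(x$tokens), x$gap_mode, x$gap_threshold_s))
  if (nrow(s)) {
    tab <- table(s$size_n)
    cat("  sizes: ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "),
        "\n", sep = "")
    if (any(!s$complete))
      cat(sprintf("  %d sequence(s) incomplete (missing token durations)\n",
                  sum(!s$complete)))
  }
  invisible(x)
}

#' Drop sequences with any missing token duration
#'
#' A sequence is retained only if the duration of every one of its tokens is
#' known; the whole sequence is excluded otherwise, mirroring the exclusion
#' applied before Menzerath analyses.
#'
#' @param seqs A `gesture_sequences` object.
#' @return A list with `kept` (a filtered `gesture_sequences`) and
#'   `n_excluded` (number of dropped sequences).
#' @export
filter_complete <- function(seqs) {
  stopifnot(inherits(seqs, "gesture_sequences"))
  keep <- seqs$sequences$complete
  kept <- seqs
  kept$sequences <- seqs$sequences[keep, , drop = FALSE]
  kept$tokens <- seqs$tokens[
    seqs$tokens$sequence_id %in% kept$sequences$sequence_id, , drop = FALSE]
  rownames(kept$sequences) <- NULL
  rownames(kept$tokens) <- NULL
  list(kept = kept, n_excluded = sum(!keep))
}

#' Tabulate sequence composition by length
#'
#' For each sequence length, counts sequences composed of a single repeated
#' gesture type versus more than one type. The same/different split is
#' undefined (`NA`) for singletons.
#'
#' @param seqs A `gesture_sequences` object (typically after
#'   [filter_complete()]).
#' @return A `length_composition` data frame with columns `length`,
#'   `n_same_type`, `n_different_type`, `n_total`, one row per occurring
#'   length from 1 to the maximum.
#' @export
length_composition_table <- function(seqs) {
  stopifnot(inherits(seqs, "gesture_sequences"))
  s <- seqs$sequences
  max_len <- if (nrow(s)) max(s$size_n) else 0L
  lens <- seq_len(max_len)
  out <- data.frame(
    length = lens,
    n_same_type = vapply(lens, function(L)
      if (L == 1L) NA_integer_ else
        sum(s$size_n == L & s$same_type, na.rm = TRUE), integer(1)),
    n_different_type = vapply(lens, function(L)
      if (L == 1L) NA_integer_ else
        sum(s$size_n == L & !s$same_type, na.rm = TRUE), integer(1)),
    n_total = vapply(lens, function(L) sum(s$size_n == L), integer(1))
  )
  class(out) <- c("length_composition", "data.frame")
  out
}

#' @export
print.length_composition <- function(x, ...) {
  cat("Sequence composition by length (same vs different gesture types)\n")
  print.data.frame(x, row.names = FALSE)
  multi <- x[x$length >= 2, , drop = FALSE]
  if (nrow(multi))
    cat(sprintf("  totals: %d sequences; length>=2: %d same-type, %d mixed\n",
                sum(x$n_total), sum(multi$n_same_type),
                sum(multi$n_different_type)))
  invisible(x)
}

#' Per-type repertoire summary
#'
#' Counts, dataset proportions and duration summaries per gesture type,
#' sorted by descending token count with alphabetical tie-break. These
#' per-type proportions \eqn{p_i} and durations \eqn{d_i} are the inputs of
#' the brevity and compression tests.
#'
#' @param tokens A `gesture_tokens` data frame in which every token has a
#'   known duration (drop incomplete sequences first).
#' @return A `repertoire` data frame with columns `gesture_type`,
#'   `category`, `duration_form`, `n_tokens`, `proportion_p`,
#'   `mean_duration_s`, `median_duration_s`.
#' @export
repertoire_summary <- function(tokens) {
  tokens <- as.data.frame(tokens)
  if (!nrow(tokens)) {
    out <- data.frame(gesture_type = character(0), category = character(0),
                      duration_form = character(0), n_tokens = integer(0),
                      proportion_p = numeric(0), mean_duration_s = numeric(0),
                      median_duration_s = numeric(0))
    class(out) <- c("repertoire", "data.frame")
    return(out)
  }
  if (anyNA(tokens$duration_s))
    stop("tokens with missing durations; apply filter_complete() first",
         call. = FALSE)
  by_type <- split(tokens, tokens$gesture_type)
  out <- data.frame(
    gesture_type = names(by_type),
    category = vapply(by_type, function(d) d$category[1], character(1)),
    duration_form = vapply(by_type, function(d) d$duration_form[1],
                           character(1)),
    n_tokens = vapply(by_type, nrow, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$proportion_p <- out$n_tokens / sum(out$n_tokens)
  out$mean_duration_s <- vapply(by_type, function(d) mean(d$duration_s),
                                numeric(1))
  out$median_duration_s <- vapply(by_type,
                                  function(d) stats::median(d$duration_s),
                                  numeric(1))
  out <- out[order(-out$n_tokens, out$gesture_type), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("repertoire", "data.frame")
  out
}

#' @export
print.repertoire <- function(x, ...) {
  cat(sprintf("Gesture repertoire: %d types, %d tokens\n",
              nrow(x), sum(x$n_tokens)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... %d more types\n", nrow(x) - 10L))
  invisible(x)
}

#' Duration-form composition of sequences by size
#'
#' For each sequence size, the fraction of sequences made only of loose
#' duration forms, only of fixed forms, or of a mix — the descriptive check
#' that a Menzerath pattern is not an artefact of switching from fixed to
#' loose gesture types in longer sequences.
#'
#' @param seqs A `gesture_sequences` object with `duration_form` populated
#'   on its tokens.
#' @return A data frame with columns `size_n`, `n_sequences`, `all_loose`,
#'   `all_fixed`, `mixed`; the three fractions sum to 1 within each size.
#' @export
composition_by_size <- function(seqs) {
  stopifnot(inherits(seqs, "gesture_sequences"))
  toks <- seqs$tokens
  forms <- split(toks$duration_form, toks$sequence_id)
  cls <- vapply(forms, function(f) {
    if (all(f == "loose")) "all_loose"
    else if (all(f == "fixed")) "all_fixed"
    else "mixed"
  }, character(1))
  size <- seqs$sequences$size_n[match(names(forms),
                                      seqs$sequences$sequence_id)]
  sizes <- sort(unique(size))
  out <- data.frame(
    size_n = sizes,
    n_sequences = vapply(sizes, function(s) sum(size == s), integer(1)),
    all_loose = vapply(sizes, function(s) mean(cls[size == s] == "all_loose"),
                       numeric(1)),
    all_fixed = vapply(sizes, function(s) mean(cls[size == s] == "all_fixed"),
                       numeric(1)),
    mixed = vapply(sizes, function(s) mean(cls[size == s] == "mixed"),
                   numeric(1))
  )
  out
}
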