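#' Synthetic token stream reproducing the published contingency table
#'
#' Builds, deterministically and without random numbers, a token stream
#' whose segmentation at the 1 s rule reproduces the published
#' sequence-length composition: per-length totals 244, 82, 21, 3, 7, 2
#' (359 complete sequences, 530 tokens), with the same/different gesture
#' type split by length of 24/58, 1/20, 0/3, 1/6 and 0/2 (26 same-type and
#' 89 mixed sequences among the 115 of length two or more). A further 18
#' sequences (8 singletons, 8 pairs, 2 triples; 30 tokens) carry one token
#' with a missing end time each, so that the completeness exclusion drops
#' exactly 18 of 377 sequences. The sizes of the excluded sequences are not
#' published; this reconstruction of them is synthetic.
#'
#' @return A `gesture_tokens` data frame of 560 rows.
#' @examples
#' toks <- table1_example_stream()
#' length(unique(segment_sequences(toks)$sequences$sequence_id))
#' @export
table1_example_stream <- function() {
  # complete sequences: length, same-type count, different-type count
  plan <- rbind(
    c(1L, 244L, 0L),  # singletons: same/different undefined
    c(2L, 24L, 58L),
    c(3L, 1L, 20L),
    c(4L, 0L, 3L),
    c(5L, 1L, 6L),
    c(6L, 0L, 2L)
  )
  types <- sprintf("type%02d", 1:26)
  category <- ifelse(1:26 <= 21, "manual", "whole_body")
  form <- ifelse(1:26 %in% c(5, 6, 8, 10, 13, 15), "fixed", "loose")
  durations <- c(0.4, 0.8, 1.2, 1.6, 2.0)  # frame multiples, cycled

  seqs <- list()
  for (r in seq_len(nrow(plan))) {
    len <- plan[r, 1]
    for (kind in c("same", "different")) {
      n_of_kind <- if (kind == "same") plan[r, 2] else plan[r, 3]
      if (len == 1L && kind == "different") n_of_kind <- 0L
      for (i in seq_len(n_of_kind))
        seqs[[length(seqs) + 1L]] <- list(len = len, kind = kind,
                                          complete = TRUE)
    }
  }
  for (len in c(rep(1L, 8), rep(2L, 8), rep(3L, 2)))
    seqs[[length(seqs) + 1L]] <- list(len = len, kind = "different",
                                      complete = FALSE)

  rows <- vector("list", length(seqs))
  counter <- 0L
  for (s in seq_along(seqs)) {
    info <- seqs[[s]]
    sig <- sprintf("sig%02d", ((s - 1L) %% 16L) + 1L)
    vid <- sprintf("vid_%s", sig)
    date <- sprintf("2010-%02d-%02d", ((s - 1L) %% 12L) + 1L,
                    ((s - 1L) %% 28L) + 1L)
    base_type <- ((s - 1L) %% 26L) + 1L
    type_idx <- if (info$kind == "same") rep(base_type, info$len)
                else ((base_type + seq_len(info$len) - 2L) %% 26L) + 1L
    dur <- durations[((counter + seq_len(info$len) - 1L) %% 5L) + 1L]
    # 100 s lanes per sequence within a video keep between-gaps >= 1 s
    start <- 100 * ceiling(s / 16) + cumsum(c(0, (dur + 0.5)[-info$len]))
    end <- start + dur
    if (!info$complete) end[info$len] <- NA_real_
    counter <- counter + info$len
    rows[[s]] <- data.frame(
      signaller = sig,
      recipient = sprintf("fem%02d", ((s - 1L) %% 26L) + 1L),
      date = date, video_id = vid,
      gesture_type = types[type_idx],
      category = category[type_idx],
      duration_form = form[type_idx],
      start_s = start, end_s = end,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$duration_s <- out$end_s - out$start_s
  class(out) <- c("gesture_tokens", "data.frame")
  out
}
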