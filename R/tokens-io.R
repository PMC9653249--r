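#' Read a canonical gesture-token CSV
#'
#' Reads and validates a flat token table: one row per produced gesture,
#' with columns `signaller`, `recipient`, `date`, `video_id`,
#' `gesture_type`, `category`, `duration_form`, `start_s`, `end_s`. A blank
#' `end_s` is legal and yields a missing duration (the token is retained for
#' segmentation but marks its sequence incomplete). Malformed rows raise
#' errors naming the row and column.
#'
#' @param path Path to the CSV file.
#' @param frame Frame grid (s) against which present durations are checked;
#'   durations must be at least one frame and a whole number of frames.
#' @param check_frame Set to `FALSE` to skip the frame-grid check, e.g. for
#'   data digitized at unknown resolution.
#' @return A `gesture_tokens` data frame with an added `duration_s` column
#'   (`end_s - start_s`, `NA` when the end time is missing).
#' @export
read_tokens <- function(path, frame = 0.04, check_frame = TRUE) {
  if (!file.exists(path)) stop("token file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("signaller", "recipient", "date", "video_id", "gesture_type",
                "category", "duration_form", "start_s", "end_s")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  validate_tokens(as_tokens_frame(raw), frame = frame,
                  check_frame = check_frame)
}

as_tokens_frame <- function(raw) {
  num_field <- function(col) {
    v <- trimws(raw[[col]])
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & nzchar(v) & is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric %s at row(s) %s", col,
                   paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
    out[!nzchar(v)] <- NA_real_
    out
  }
  raw$start_s <- num_field("start_s")
  raw$end_s <- num_field("end_s")
  raw$duration_s <- raw$end_s - raw$start_s
  class(raw) <- c("gesture_tokens", "data.frame")
  raw
}

#' Validate a gesture-token table
#'
#' Checks the token invariants: start times present and numeric,
#' `end_s >= start_s` where both exist, categories and duration forms from
#' their legal sets, and (optionally) durations on the frame grid with a
#' one-frame floor.
#'
#' @inheritParams read_tokens
#' @param tokens A `gesture_tokens` data frame.
#' @return `tokens`, invisibly validated (durations recomputed from times).
#' @export
validate_tokens <- function(tokens, frame = 0.04, check_frame = TRUE) {
  if (!nrow(tokens)) return(tokens)
  if (anyNA(tokens$start_s))
    stop("missing start_s at row(s) ",
         paste(utils::head(which(is.na(tokens$start_s)), 5), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(tokens$end_s) & tokens$end_s < tokens$start_s)
  if (length(bad))
    stop("end_s earlier than start_s at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  bad_cat <- which(!tokens$category %in% c("manual", "whole_body"))
  if (length(bad_cat))
    stop("category must be 'manual' or 'whole_body'; bad row(s) ",
         paste(utils::head(bad_cat, 5), collapse = ", "), call. = FALSE)
  bad_form <- which(!tokens$duration_form %in% c("fixed", "loose"))
  if (length(bad_form))
    stop("duration_form must be 'fixed' or 'loose'; bad row(s) ",
         paste(utils::head(bad_form, 5), collapse = ", "), call. = FALSE)
  tokens$duration_s <- tokens$end_s - tokens$start_s
  if (check_frame) {
    d <- tokens$duration_s
    ok <- is.na(d) | (d >= frame - 1e-6 &
                        abs(d / frame - round(d / frame)) < 1e-6)
    if (any(!ok))
      stop(sprintf("duration off the %.3g s frame grid at row(s) %s",
                   frame, paste(utils::head(which(!ok), 5), collapse = ", ")),
           call. = FALSE)
  }
  invisible(tokens)
}
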