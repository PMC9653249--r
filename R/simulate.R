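#' Simulate a gesture-token stream with known ground truth
#'
#' Generates timed, typed gesture tokens under the hierarchical lognormal
#' model described in [simulation_config()]: sequence sizes are drawn from
#' the configured size distribution, each sequence is assigned a signaller
#' (one prolific signaller receives about `prolific_fraction` of tokens, the
#' rest are uniform), token types are drawn from the type frequency weights,
#' and log-durations combine the fixed slopes (type proportion, sequence
#' size, gesture category) with signaller, sequence, type and recording-date
#' random intercepts plus residual noise. Durations are quantized up to the
#' frame grid, never below one frame. Consecutive tokens within a sequence
#' are separated by gaps uniform on `(0, within_gap_max)`; consecutive
#' sequences within a video by at least `between_gap_min`, so segmentation
#' at any threshold between the two bounds recovers the simulated partition
#' exactly.
#'
#' @param config A validated [simulation_config()].
#' @return A `gesture_tokens` data frame with the canonical columns
#'   (`signaller`, `recipient`, `date`, `video_id`, `gesture_type`,
#'   `category`, `duration_form`, `start_s`, `end_s`, `duration_s`) plus the
#'   ground-truth column `sim_sequence_id`. Identical config and seed give a
#'   byte-identical stream.
#' @examples
#' toks <- simulate_tokens(default_study_config(seed = 7))
#' nrow(toks)
#' @export
simulate_tokens <- function(config) {
  validate_sim_config(config)
  cfg <- config
  cols <- c("signaller", "recipient", "date", "video_id", "gesture_type",
            "category", "duration_form", "start_s", "end_s", "duration_s",
            "sim_sequence_id")
  if (cfg$n_sequences == 0L) {
    out <- as.data.frame(sapply(cols, function(x) character(0),
                                simplify = FALSE))
    for (f in c("start_s", "end_s", "duration_s")) out[[f]] <- numeric(0)
    class(out) <- c("gesture_tokens", "data.frame")
    return(out)
  }

  with_seed(cfg$seed, {
    sig_ids <- sprintf("sig%02d", seq_len(cfg$n_signallers))
    type_ids <- sprintf("type%02d", seq_len(cfg$n_types))
    rec_ids <- sprintf("fem%02d", seq_len(cfg$n_recipients))
    p_type <- cfg$type_frequency_weights / sum(cfg$type_frequency_weights)
    category <- ifelse(seq_len(cfg$n_types) <= cfg$n_manual,
                       "manual", "whole_body")
    form <- ifelse(seq_len(cfg$n_types) %in% cfg$fixed_type_ids,
                   "fixed", "loose")

    # recording calendar: distinct days per signaller within a field window
    all_days <- as.Date("2008-01-01") + 0:2190
    dates_by_sig <- lapply(seq_len(cfg$n_signallers), function(i)
      sort(sample(all_days, cfg$n_dates_per_signaller)))

    sizes <- sample.int(length(cfg$sequence_size_distribution),
                        cfg$n_sequences, replace = TRUE,
                        prob = cfg$sequence_size_distribution)
    sig_of_seq <- if (cfg$n_signallers == 1L) {
      rep(1L, cfg$n_sequences)
    } else {
      ifelse(stats::runif(cfg$n_sequences) < cfg$prolific_fraction, 1L,
             sample(2:cfg$n_signallers, cfg$n_sequences, replace = TRUE))
    }
    date_idx <- sample.int(cfg$n_dates_per_signaller, cfg$n_sequences,
                           replace = TRUE)
    date_of_seq <- as.Date(vapply(seq_len(cfg$n_sequences), function(s)
      as.character(dates_by_sig[[sig_of_seq[s]]][date_idx[s]]), character(1)))

    u_sig <- stats::rnorm(cfg$n_signallers, 0, cfg$sd_signaller)
    u_type <- stats::rnorm(cfg$n_types, 0, cfg$sd_type)
    u_seq <- stats::rnorm(cfg$n_sequences, 0, cfg$sd_sequence)
    date_key <- paste(sig_ids[sig_of_seq], date_of_seq)
    u_date_all <- stats::rnorm(length(unique(date_key)), 0, cfg$sd_date)
    names(u_date_all) <- unique(date_key)

    n_tok <- sum(sizes)
    seq_of_tok <- rep.int(seq_len(cfg$n_sequences), sizes)
    type_of_tok <- sample.int(cfg$n_types, n_tok, replace = TRUE,
                              prob = p_type)
    log_d <- cfg$mu0 +
      cfg$beta_freq * p_type[type_of_tok] +
      cfg$beta_size * sizes[seq_of_tok] +
      cfg$beta_category * (category[type_of_tok] == "whole_body") +
      u_sig[sig_of_seq[seq_of_tok]] +
      u_seq[seq_of_tok] +
      u_type[type_of_tok] +
      u_date_all[date_key[seq_of_tok]] +
      stats::rnorm(n_tok, 0, cfg$sd_resid)
    dur <- quantize_up(exp(log_d), cfg$frame)

    recipient <- rec_ids[sample.int(cfg$n_recipients, cfg$n_sequences,
                                    replace = TRUE)]

    # lay sequences on per-video timelines (one video per signaller-date)
    video_of_seq <- paste0("vid_", gsub(" ", "_", date_key))
    within_gaps <- stats::runif(n_tok, 0, cfg$within_gap_max)
    between_gaps <- cfg$between_gap_min +
      stats::runif(cfg$n_sequences, 0, cfg$between_gap_min)
    start_s <- numeric(n_tok)
    tok_of_seq <- split(seq_len(n_tok), seq_of_tok)
    for (vid in unique(video_of_seq)) {
      t_cur <- 0
      for (s in which(video_of_seq == vid)) {
        for (k in tok_of_seq[[s]]) {
          start_s[k] <- t_cur
          t_cur <- t_cur + dur[k] + within_gaps[k]
        }
        last <- tok_of_seq[[s]][sizes[s]]
        t_cur <- start_s[last] + dur[last] + between_gaps[s]
      }
    }

    out <- data.frame(
      signaller = sig_ids[sig_of_seq[seq_of_tok]],
      recipient = recipient[seq_of_tok],
      date = format(date_of_seq[seq_of_tok], "%Y-%m-%d"),
      video_id = video_of_seq[seq_of_tok],
      gesture_type = type_ids[type_of_tok],
      category = category[type_of_tok],
      duration_form = form[type_of_tok],
      start_s = start_s,
      end_s = start_s + dur,
      duration_s = dur,
      sim_sequence_id = sprintf("sim_seq%04d", seq_of_tok),
      stringsAsFactors = FALSE
    )
    class(out) <- c("gesture_tokens", "data.frame")
    out
  })
}

#' @export
print.gesture_tokens <- function(x, ...) {
  cat(sprintf("Gesture token stream: %d tokens, %d types, %d signallers\n",
              nrow(x), length(unique(x$gesture_type)),
              length(unique(x$signaller))))
  if (nrow(x)) {
    d <- x$duration_s[!is.na(x$duration_s)]
    if (length(d))
      cat(sprintf("  durations: %.2f-%.2f s (median %.2f), %d missing\n",
                  min(d), max(d), stats::median(d), sum(is.na(x$duration_s))))
    print.data.frame(utils::head(as.data.frame(x), 5))
    if (nrow(x) > 5) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  }
  invisible(x)
}

#' Write a simulated stream to the canonical token CSV plus truth sidecar
#'
#' Emits the canonical nine-column token CSV (ground-truth simulation columns
#' dropped) and, when a config is supplied, a JSON sidecar
#' `<csv_path>.truth.json` recording every configured parameter.
#'
#' @param tokens A `gesture_tokens` data frame.
#' @param path Output CSV path.
#' @param config Optional `sim_config` used to generate `tokens`.
#' @return `path`, invisibly.
#' @export
write_tokens <- function(tokens, path, config = NULL) {
  keep <- c("signaller", "recipient", "date", "video_id", "gesture_type",
            "category", "duration_form", "start_s", "end_s")
  utils::write.csv(as.data.frame(tokens)[, keep, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(config)) {
    validate_sim_config(config)
    jsonlite::write_json(unclass(config), paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
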