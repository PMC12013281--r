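#' Participant screening on block-pair performance
#'
#' A demanding deadline task produces participants who trade accuracy away
#' entirely or stop making the deadline; these are screened out. A
#' participant is excluded iff, in at least one of block pairs 2-7 (the
#' first pair is warm-up and never triggers exclusion), the error rate
#' strictly exceeds `error_threshold` or the proportion of too-slow
#' (deadline-exceeded) trials strictly exceeds `slow_threshold`. Rates use
#' all trials of the block pair as denominator.
#'
#' @param trials Trial-record data.frame (unfiltered).
#' @param error_threshold Error-rate cutoff (exclusive).
#' @param slow_threshold Too-slow-rate cutoff (exclusive).
#' @return An object of class `screening_report`: list with `by_pair`
#'   (per participant x block pair rates), and `participants` (per
#'   participant: `included` flag and `exclusion_reason`).
#' @export
screen_participants <- function(trials, error_threshold = 0.50,
                                slow_threshold = 0.30) {
  if (nrow(trials) == 0L) stop("empty dataset")
  key <- interaction(trials$participant, trials$block_pair, drop = TRUE)
  agg <- data.frame(
    participant = tapply(trials$participant, key, `[`, 1L),
    block_pair = as.integer(tapply(trials$block_pair, key, `[`, 1L)),
    n_trials = as.integer(tapply(trials$correct, key, length)),
    error_rate = as.numeric(tapply(!trials$correct, key, mean)),
    slow_rate = as.numeric(tapply(trials$deadline_exceeded, key, mean)),
    row.names = NULL)
  agg <- agg[order(agg$participant, agg$block_pair), ]

  n_pairs <- max(agg$block_pair)
  per_part <- split(agg, agg$participant)
  res <- lapply(per_part, function(d) {
    if (length(setdiff(seq_len(n_pairs), d$block_pair)))
      stop("participant ", d$participant[1], " has missing block pairs")
    d2 <- d[d$block_pair >= 2L, ]
    err_bad <- d2$error_rate > error_threshold
    slow_bad <- d2$slow_rate > slow_threshold
    reason <- if (any(err_bad))
      sprintf("error rate %.2f in block pair %d",
              d2$error_rate[which(err_bad)[1]],
              d2$block_pair[which(err_bad)[1]])
    else if (any(slow_bad))
      sprintf("too-slow rate %.2f in block pair %d",
              d2$slow_rate[which(slow_bad)[1]],
              d2$block_pair[which(slow_bad)[1]])
    else NA_character_
    data.frame(participant = d$participant[1],
               included = is.na(reason),
               exclusion_reason = reason)
  })
  participants <- do.call(rbind, res)
  rownames(participants) <- NULL
  structure(list(by_pair = agg, participants = participants,
                 error_threshold = error_threshold,
                 slow_threshold = slow_threshold),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  n <- nrow(x$participants)
  excl <- x$participants[!x$participants$included, ]
  cat(sprintf("screening: %d of %d participants retained\n",
              n - nrow(excl), n))
  for (i in seq_len(nrow(excl)))
    cat("  excluded", excl$participant[i], "-", excl$exclusion_reason[i], "\n")
  invisible(x)
}

#' Apply the trial-level filters
#'
#' Flags and removes, as independent rules whose union is dropped:
#' post-feedback trials (the trial after an error or deadline violation),
#' the first four trials of each block, responses faster than `rt_min` ms
#' and slower than `rt_max` ms. Error responses themselves are retained
#' (only trials *after* feedback are dropped); deadline-exceeded trials are
#' retained here and optionally dropped at model-building time.
#'
#' @param trials Trial-record data.frame.
#' @param rt_min,rt_max Response-time window in ms.
#' @return The filtered data.frame, with attribute `filter_counts`: named
#'   counts of trials flagged by each rule (overlaps possible) and the total
#'   removed.
#' @export
filter_trials <- function(trials, rt_min = 20, rt_max = 2000) {
  post_fb <- trials$post_feedback
  warmup <- trials$trial_in_block <= 4L
  too_fast <- trials$rt_ms < rt_min
  too_slow <- trials$rt_ms > rt_max
  drop <- post_fb | warmup | too_fast | too_slow
  out <- trials[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(
    post_feedback = sum(post_fb), first_four = sum(warmup),
    rt_below_min = sum(too_fast), rt_above_max = sum(too_slow),
    removed = sum(drop), retained = sum(!drop))
  out
}

#' Assign block pairs
#'
#' Collapses consecutive blocks into analysis units: `block_pair =
#' ceiling(block / 2)`.
#'
#' @param trials Trial-record data.frame with a `block` column in
#'   `1:n_blocks`.
#' @param n_blocks Upper bound for validation.
#' @return The data.frame with `block_pair` (re)computed.
#' @export
assign_block_pairs <- function(trials, n_blocks = max(trials$block)) {
  if (any(trials$block < 1L | trials$block > n_blocks))
    stop("block index out of range")
  trials$block_pair <- as.integer(ceiling(trials$block / 2))
  trials
}

#' Screen and filter in one step
#'
#' Convenience wrapper: applies [screen_participants()], drops excluded
#' participants, then applies [filter_trials()].
#'
#' @inheritParams screen_participants
#' @inheritParams filter_trials
#' @return Filtered trials of included participants; attributes
#'   `screening` (the report) and `filter_counts`.
#' @export
prepare_dataset <- function(trials, error_threshold = 0.50,
                            slow_threshold = 0.30, rt_min = 20,
                            rt_max = 2000) {
  scr <- screen_participants(trials, error_threshold, slow_threshold)
  keep <- scr$participants$participant[scr$participants$included]
  kept <- trials[trials$participant %in% keep, , drop = FALSE]
  out <- filter_trials(kept, rt_min, rt_max)
  attr(out, "screening") <- scr
  out
}
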