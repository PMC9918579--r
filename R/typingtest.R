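#' Typing speed and accuracy from copy-typing transcripts
#'
#' Scores a copy-typing test using the five-character-word convention: the
#' produced character stream of each trial is segmented into consecutive,
#' non-overlapping five-character chunks aligned positionally to the
#' target text.  A chunk is correct iff its five characters match the
#' corresponding characters of the target and no backspace event fell
#' within its production span.  Accuracy is the percentage of correct
#' chunks; speed is the number of correct chunks divided by the total time
#' needed to produce all chunks, in minutes.  Chunk production time is
#' measured from the completion of the previous chunk (trial onset for the
#' first), so the per-trial denominator is the time from onset to the last
#' chunk's final keystroke.
#'
#' @param keylog a `keylog` data frame with the copy-typing keystrokes,
#'   one `trial` per text.
#' @param targets data frame with columns `pid`, `trial`, `text` giving
#'   each trial's target text (matching is case-insensitive after the
#'   upper-casing performed on ingestion; supply upper-case targets).
#' @return data frame of class `"typing_test_result"` with one row per
#'   participant: `pid`, `wpm_5char`, `accuracy_pct`, `n_chunks`.
#'   Participants with no complete chunk get `n_chunks = 0` and `NA`
#'   metrics.
#' @export
typing_metrics <- function(keylog, targets) {
  pids <- unique(as.character(targets$pid))
  rows <- lapply(pids, function(p) {
    tr <- targets[targets$pid == p, , drop = FALSE]
    n_chunks <- n_correct <- 0L
    total_ms <- 0
    for (i in seq_len(nrow(tr))) {
      ev <- keylog[keylog$pid == p & keylog$trial == tr$trial[i], ,
                   drop = FALSE]
      sc <- score_copy_trial(ev, toupper(tr$text[i]))
      n_chunks <- n_chunks + sc$n_chunks
      n_correct <- n_correct + sc$n_correct
      total_ms <- total_ms + sc$time_ms
    }
    data.frame(pid = p,
               wpm_5char = if (total_ms > 0) n_correct / (total_ms / 60000)
               else NA_real_,
               accuracy_pct = if (n_chunks > 0) 100 * n_correct / n_chunks
               else NA_real_,
               n_chunks = n_chunks, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("typing_test_result", "data.frame")
  out
}

# Score one copy-typing trial against its target text.
score_copy_trial <- function(events, target, chunk_size = 5L) {
  n_target_chunks <- nchar(target) %/% chunk_size
  # an empty stream contributes no chunks (metrics stay absent, never NaN)
  if (n_target_chunks == 0L || nrow(events) == 0L)
    return(list(n_chunks = 0L, n_correct = 0L, time_ms = 0))
  printable <- is_printable_key(events$key)
  chars <- events$key[printable]
  times <- events$t_ms[printable]
  bs_times <- events$t_ms[events$key == "BACKSPACE"]
  n_prod_chunks <- length(chars) %/% chunk_size
  n_correct <- 0L
  last_end <- 0
  time_ms <- 0
  for (k in seq_len(min(n_target_chunks, n_prod_chunks))) {
    ix <- ((k - 1L) * chunk_size + 1L):(k * chunk_size)
    span <- c(times[ix[1L]], times[ix[chunk_size]])
    produced <- paste(chars[ix], collapse = "")
    expected <- substr(target, ix[1L], ix[chunk_size])
    bs_inside <- any(bs_times >= span[1L] & bs_times <= span[2L])
    if (produced == expected && !bs_inside) n_correct <- n_correct + 1L
    time_ms <- time_ms + (span[2L] - last_end)
    last_end <- span[2L]
  }
  # chunks of the target never produced count as (incorrect) chunks
  list(n_chunks = n_target_chunks, n_correct = n_correct, time_ms = time_ms)
}
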