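#' Read a keystroke log in the JSON-lines dialect
#'
#' One JSON object per line, one object per key event:
#' `{"pid": "...", "trial": 1, "item": "...", "key": "a", "t": 812}` with
#' `key` following the W3C `KeyboardEvent.key` vocabulary (`"a"`..`"z"`,
#' umlauts, `"Backspace"`, `"Shift"`, `" "`, `"Enter"`, `"CapsLock"`) and
#' `t` in milliseconds since picture onset.  On ingestion printable keys
#' are upper-cased (participants are instructed to type in capitals, and
#' typed characters are displayed capitalized regardless), named special
#' keys are normalized to `BACKSPACE`, `SPACE`, `ENTER`, `SHIFT`,
#' `CAPSLOCK`, and any other key name (e.g. `"F13"`) maps to `OTHER`.
#' Events are sorted by time within trial (with a warning if they arrived
#' out of order).
#'
#' @param path file path of the JSON-lines log.
#' @param strict if `TRUE`, malformed lines raise an error; otherwise they
#'   are skipped and collected in the `"rejects"` attribute.
#' @return a `keylog` data frame with columns `pid`, `trial`, `item_id`,
#'   `key`, `t_ms`, ordered by participant, trial and time.
#' @export
read_keylog <- function(path, strict = FALSE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  bad <- integer()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    ok <- is.list(rec) && all(c("pid", "trial", "item", "key", "t") %in%
                                names(rec)) &&
      is.numeric(rec$t) && rec$t >= 0
    if (!ok) {
      if (strict) stop("malformed keylog record at line ", i, ": ", lines[i])
      bad <- c(bad, i)
    } else {
      recs[[i]] <- rec
    }
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) {
    out <- empty_keylog()
  } else {
    out <- data.frame(
      pid = vapply(recs, function(r) as.character(r$pid), character(1)),
      trial = vapply(recs, function(r) as.integer(r$trial), integer(1)),
      item_id = vapply(recs, function(r) as.character(r$item), character(1)),
      key = normalize_key(vapply(recs, function(r) as.character(r$key),
                                 character(1))),
      t_ms = vapply(recs, function(r) as.numeric(r$t), numeric(1)),
      stringsAsFactors = FALSE
    )
    unsorted <- any(stats::ave(out$t_ms, out$pid, out$trial,
                               FUN = function(x) any(diff(x) < 0)) > 0)
    if (unsorted) warning("out-of-order timestamps re-sorted within trial")
    out <- out[order(out$pid, out$trial, out$t_ms), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("keylog", "data.frame")
  attr(out, "rejects") <- data.frame(line = bad,
                                     text = lines[bad],
                                     stringsAsFactors = FALSE)
  out
}

#' Write a keystroke log in the JSON-lines dialect
#'
#' Inverse of [read_keylog()]; symbolic key names are serialized back to
#' the `KeyboardEvent.key` vocabulary.
#'
#' @param keylog a `keylog` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_keylog <- function(keylog, path) {
  key_out <- denormalize_key(keylog$key)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(keylog))) {
    writeLines(jsonlite::toJSON(
      list(pid = keylog$pid[i], trial = keylog$trial[i],
           item = keylog$item_id[i], key = key_out[i], t = keylog$t_ms[i]),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

empty_keylog <- function() {
  data.frame(pid = character(), trial = integer(), item_id = character(),
             key = character(), t_ms = numeric(), stringsAsFactors = FALSE)
}

normalize_key <- function(key) {
  out <- character(length(key))
  special <- c("Backspace" = "BACKSPACE", " " = "SPACE", "Enter" = "ENTER",
               "Shift" = "SHIFT", "CapsLock" = "CAPSLOCK",
               "BACKSPACE" = "BACKSPACE", "SPACE" = "SPACE",
               "ENTER" = "ENTER", "SHIFT" = "SHIFT", "CAPSLOCK" = "CAPSLOCK")
  is_special <- key %in% names(special)
  out[is_special] <- special[key[is_special]]
  printable <- !is_special & nchar(key) == 1L
  out[printable] <- toupper(key[printable])
  out[!is_special & !printable] <- "OTHER"
  out
}

denormalize_key <- function(key) {
  back <- c("BACKSPACE" = "Backspace", "SPACE" = " ", "ENTER" = "Enter",
            "SHIFT" = "Shift", "CAPSLOCK" = "CapsLock", "OTHER" = "Unidentified")
  is_special <- key %in% names(back)
  out <- key
  out[is_special] <- back[key[is_special]]
  out
}

#' Strip terminal space/enter keys from a trial's events
#'
#' Participants finish a typed response with the space bar or enter key;
#' those closing keys are not part of the word.  This removes the maximal
#' trailing run of `SPACE`/`ENTER` events; interior ones are retained.
#' Idempotent.
#'
#' @param events data frame of one trial's events with columns `key`,
#'   `t_ms` (and any others, preserved).
#' @return the events data frame without its trailing space/enter run.
#' @export
strip_terminal_keys <- function(events) {
  n <- nrow(events)
  if (n == 0L) return(events)
  keep <- n
  while (keep >= 1L && events$key[keep] %in% c("SPACE", "ENTER")) {
    keep <- keep - 1L
  }
  events[seq_len(keep), , drop = FALSE]
}

#' Reconstruct the typed word entry from a trial's keystrokes
#'
#' Replays a trial's events through a simple text editor: printable keys
#' append their character, `BACKSPACE` deletes the last character (a no-op
#' on an empty buffer), and `SHIFT`/`CAPSLOCK`/`SPACE`/`ENTER`/`OTHER`
#' contribute nothing.  The raw string is the concatenation of printable
#' characters in typed order (e.g. events C,H,E,BACKSPACE,A,I,R give raw
#' "CHEAIR" and corrected "CHAIR").  The first-keystroke latency is the
#' trial's reaction time; it is defined for any first event, including
#' special keys, because the classifier needs to see special-key starts.
#'
#' @param events data frame of one trial's events (columns `key`, `t_ms`),
#'   normally after [strip_terminal_keys()].
#' @return list with `raw_string`, `corrected_string`, `first_key`
#'   (NA if no events), `rt_ms` (NA if no events), and `n_backspace`.
#' @export
reconstruct_entry <- function(events) {
  n <- nrow(events)
  if (n == 0L) {
    return(list(raw_string = "", corrected_string = "",
                first_key = NA_character_, rt_ms = NA_real_,
                n_backspace = 0L))
  }
  keys <- events$key
  printable <- is_printable_key(keys)
  raw <- paste(keys[printable], collapse = "")
  buf <- character(0)
  for (k in keys) {
    if (k == "BACKSPACE") {
      if (length(buf)) buf <- buf[-length(buf)]
    } else if (is_printable_key(k)) {
      buf <- c(buf, k)
    }
  }
  list(raw_string = raw,
       corrected_string = paste(buf, collapse = ""),
       first_key = keys[1L],
       rt_ms = events$t_ms[1L],
       n_backspace = sum(keys == "BACKSPACE"))
}

#' Reconstruct entries for every trial of a keystroke log
#'
#' Applies [strip_terminal_keys()] then [reconstruct_entry()] per trial.
#'
#' @param keylog a `keylog` data frame (see [read_keylog()]).
#' @param trials optional data frame of expected trials (`pid`, `trial`,
#'   `item_id`); trials absent from the log (no keystroke detected) are
#'   returned as empty entries so they can be classified as no-answer.
#' @return data frame with one row per trial: `pid`, `trial`, `item_id`,
#'   `raw_string`, `corrected_string`, `first_key`, `rt_ms`, `n_backspace`,
#'   `n_events`.
#' @export
reconstruct_entries <- function(keylog, trials = NULL) {
  split_idx <- split(seq_len(nrow(keylog)),
                     paste(keylog$pid, keylog$trial, sep = "\r"),
                     drop = TRUE)
  m <- length(split_idx)
  pid <- item <- raw <- corr <- first_key <- character(m)
  trial <- n_back <- n_ev <- integer(m)
  rt <- numeric(m)
  all_keys <- keylog$key
  all_t <- keylog$t_ms
  for (g in seq_len(m)) {
    ix <- split_idx[[g]]
    keys <- all_keys[ix]
    # strip the trailing SPACE/ENTER run, then replay (see
    # strip_terminal_keys / reconstruct_entry for the documented rules)
    keep <- length(keys)
    while (keep >= 1L && keys[keep] %in% c("SPACE", "ENTER"))
      keep <- keep - 1L
    pid[g] <- keylog$pid[ix[1L]]
    trial[g] <- keylog$trial[ix[1L]]
    item[g] <- keylog$item_id[ix[1L]]
    n_ev[g] <- length(ix)
    if (keep == 0L) {
      raw[g] <- corr[g] <- ""
      first_key[g] <- NA_character_
      rt[g] <- NA_real_
      n_back[g] <- 0L
      next
    }
    keys <- keys[seq_len(keep)]
    printable <- is_printable_key(keys)
    raw[g] <- paste(keys[printable], collapse = "")
    buf <- character(0)
    for (k in keys) {
      if (k == "BACKSPACE") {
        if (length(buf)) buf <- buf[-length(buf)]
      } else if (is_printable_key(k)) {
        buf <- c(buf, k)
      }
    }
    corr[g] <- paste(buf, collapse = "")
    first_key[g] <- keys[1L]
    rt[g] <- all_t[ix[1L]]
    n_back[g] <- sum(keys == "BACKSPACE")
  }
  out <- data.frame(pid = pid, trial = trial, item_id = item,
                    raw_string = raw, corrected_string = corr,
                    first_key = first_key, rt_ms = rt,
                    n_backspace = n_back, n_events = n_ev,
                    stringsAsFactors = FALSE)
  if (!is.null(trials)) {
    key_have <- paste(out$pid, out$trial)
    key_want <- paste(trials$pid, trials$trial)
    missing <- !(key_want %in% key_have)
    if (any(missing)) {
      blank <- data.frame(pid = as.character(trials$pid[missing]),
                          trial = as.integer(trials$trial[missing]),
                          item_id = as.character(trials$item_id[missing]),
                          raw_string = "", corrected_string = "",
                          first_key = NA_character_, rt_ms = NA_real_,
                          n_backspace = 0L, n_events = 0L,
                          stringsAsFactors = FALSE)
      out <- rbind(out, blank)
    }
  }
  out <- out[order(out$pid, out$trial), , drop = FALSE]
  rownames(out) <- NULL
  out
}
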