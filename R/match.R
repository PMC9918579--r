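#' String distances for typed-response classification
#'
#' `jaro_distance()` computes the Jaro distance, the primary metric used to
#' score typed picture-naming responses: it counts characters of `a` and `b`
#' that match within a sliding window of `floor(max(|a|, |b|)/2) - 1`
#' positions and penalizes transpositions among them.  With `m` matching
#' characters and `t` transpositions (half-transposition pairs / 2) the
#' similarity is `(m/|a| + m/|b| + (m - t)/m) / 3` (0 when `m = 0`) and the
#' distance is one minus the similarity.  This equals the Jaro-Winkler
#' distance with prefix weight `p = 0`.  It is bounded in `[0, 1]`: 0 for
#' identical strings, 1 for complete dissimilarity.
#'
#' `levenshtein_norm()` and `osa_norm()` are edit distances with unit costs
#' (optimal string alignment additionally allows transposition of adjacent
#' characters, each substring being edited at most once), normalized by the
#' length of the longer string.  They are provided for comparison with the
#' Jaro metric; all three are conventionally used with the same cut-off.
#'
#' Comparisons operate on Unicode code points, so German umlauts and the
#' sharp s count as single characters.  Inputs are not case-folded here;
#' the keystroke layer upper-cases everything on ingestion.
#'
#' @param a,b character vectors of equal length (or length 1, recycled).
#' @return numeric vector of distances in `[0, 1]`.
#' @examples
#' jaro_distance("KESSEL", "KELLE")              # ~0.261
#' jaro_distance("GESCHIRR", "GESCHIRRSPUELER")
#' levenshtein_norm("AB", "BA")                  # 1.0 (two substitutions)
#' osa_norm("AB", "BA")                          # 0.5 (one transposition)
#' @export
jaro_distance <- function(a, b) {
  string_distance(a, b, "jaro")
}

#' @rdname jaro_distance
#' @export
levenshtein_norm <- function(a, b) {
  string_distance(a, b, "levenshtein")
}

#' @rdname jaro_distance
#' @export
osa_norm <- function(a, b) {
  string_distance(a, b, "osa")
}

string_distance <- function(a, b, method) {
  a <- enc2utf8(as.character(a))
  b <- enc2utf8(as.character(b))
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else stop("`a` and `b` must have the same length (or length 1)")
  }
  .string_distance_cpp(a, b, method)
}

#' Configuration for automated response classification
#'
#' @param distance which string distance to use: `"jaro"` (default),
#'   `"levenshtein"` (normalized), or `"osa"` (normalized optimal string
#'   alignment).
#' @param threshold correctness cut-off in (0, 1); a response can only be
#'   correct when its distance to the matched target is strictly below it.
#'   The conventional value for all three distances is 0.3.
#' @return an object of class `"match_config"`.
#' @export
match_config <- function(distance = c("jaro", "levenshtein", "osa"),
                         threshold = 0.3) {
  distance <- match.arg(distance)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  structure(list(distance = distance, threshold = threshold),
            class = "match_config")
}

#' Choose the best-matching target for a typed entry
#'
#' Accepted naming alternatives (synonyms) are allowed to stand in for the
#' canonical picture name: an alternative is eligible when its first
#' character equals the first character of the corrected entry AND its
#' distance to the entry is strictly lower than the distance between entry
#' and picture name.  Among eligible alternatives the one with minimal
#' distance wins; ties resolve to the picture name first, then to list
#' order.
#'
#' @param corrected backspace-corrected word entry (single string).
#' @param picture_name canonical picture name (non-empty string).
#' @param alternatives character vector of accepted alternatives (may be
#'   empty).
#' @param config a [match_config()].
#' @return list with `target` (the matched string), `d` (its distance), and
#'   `kind` (`"picture_name"` or `"alternative"`).
#' @export
best_match <- function(corrected, picture_name, alternatives = character(),
                       config = match_config()) {
  stopifnot(nzchar(picture_name))
  alternatives <- alternatives[!is.na(alternatives) & nzchar(alternatives)]
  d_name <- string_distance(corrected, picture_name, config$distance)
  res <- list(target = picture_name, d = d_name, kind = "picture_name")
  if (length(alternatives)) {
    d_alt <- string_distance(rep(corrected, length(alternatives)),
                             alternatives, config$distance)
    first_entry <- substr(corrected, 1L, 1L)
    eligible <- substr(alternatives, 1L, 1L) == first_entry & d_alt < d_name
    if (any(eligible)) {
      i <- which(eligible)[which.min(d_alt[eligible])]
      res <- list(target = alternatives[i], d = d_alt[i],
                  kind = "alternative")
    }
  }
  res
}

#' Classify a reconstructed typed entry as correct or incorrect
#'
#' Implements the automated correctness decision for typed picture naming.
#' In order: (1) a trial with no keystrokes is incorrect with subtype
#' `"na"`; (2) a trial whose first key is space, backspace, caps lock or
#' enter is incorrect with subtype `"special_key_start"`, and a first shift
#' key gives `"shift_start"`; (3) otherwise the backspace-corrected entry
#' is matched against the picture name and accepted alternatives via
#' [best_match()], and the trial is correct iff the first typed character
#' (before and after backspace correction) equals the first character of
#' the matched target and the distance is strictly below the threshold.
#' Correct trials are subtyped `"identical"` (entry equals the target, no
#' backspace used), `"corrected"` (entry equals the target after at least
#' one backspace) or `"below_threshold"`; incorrect trials are subtyped
#' `"first_letter_error"`, `"distance_exceeded"`, or `"combined"` when both
#' conditions fail.
#'
#' @param entry a single reconstructed entry: a list or one-row data frame
#'   with fields `raw_string`, `corrected_string`, `first_key`,
#'   `n_backspace` (as produced by [reconstruct_entry()]).
#' @param stimulus a list or one-row data frame with fields `name` and
#'   `alternatives` (character vector, or a single `";"`-separated string).
#' @param config a [match_config()].
#' @return list with `status` (`"correct"`/`"incorrect"`), `subtype`,
#'   `matched_target`, `d` (NA for subtype `"na"`), and `target_kind`
#'   (`"picture_name"`, `"alternative"`, or NA).
#' @export
classify_entry <- function(entry, stimulus, config = match_config()) {
  first_key <- as.character(entry$first_key)
  if (is.na(first_key) || !nzchar(first_key)) {
    return(list(status = "incorrect", subtype = "na",
                matched_target = NA_character_, d = NA_real_,
                target_kind = NA_character_))
  }
  if (first_key %in% SPECIAL_START_KEYS) {
    return(list(status = "incorrect", subtype = "special_key_start",
                matched_target = NA_character_, d = NA_real_,
                target_kind = NA_character_))
  }
  if (first_key == "SHIFT") {
    return(list(status = "incorrect", subtype = "shift_start",
                matched_target = NA_character_, d = NA_real_,
                target_kind = NA_character_))
  }
  alternatives <- stimulus$alternatives
  if (is.list(alternatives)) alternatives <- alternatives[[1L]]
  alternatives <- split_alternatives(alternatives)
  bm <- best_match(entry$corrected_string, stimulus$name, alternatives,
                   config)
  first_target <- substr(bm$target, 1L, 1L)
  first_ok <- nzchar(entry$raw_string) && nzchar(entry$corrected_string) &&
    substr(entry$raw_string, 1L, 1L) == first_target &&
    substr(entry$corrected_string, 1L, 1L) == first_target
  dist_ok <- bm$d < config$threshold
  if (first_ok && dist_ok) {
    exact <- identical(entry$corrected_string, bm$target)
    subtype <- if (exact && entry$n_backspace == 0L) "identical"
    else if (exact) "corrected"
    else "below_threshold"
    status <- "correct"
  } else {
    status <- "incorrect"
    subtype <- if (!first_ok && !dist_ok) "combined"
    else if (!first_ok) "first_letter_error"
    else "distance_exceeded"
  }
  list(status = status, subtype = subtype, matched_target = bm$target,
       d = bm$d, target_kind = bm$kind)
}

#' Classify a full table of reconstructed entries
#'
#' Vectorized application of [classify_entry()] across a table of
#' reconstructed entries, joined to the stimulus set by `item_id`.
#'
#' @param entries data frame from [reconstruct_entries()]; one row per
#'   trial with columns `item_id`, `raw_string`, `corrected_string`,
#'   `first_key`, `n_backspace`.
#' @param stimuli stimulus table (see [read_stimuli()]) with columns
#'   `item_id`, `name`, `alternatives`.
#' @param config a [match_config()].
#' @return `entries` with added columns `status`, `subtype`,
#'   `matched_target`, `d`, `target_kind`.
#' @export
classify_entries <- function(entries, stimuli, config = match_config()) {
  idx <- match(entries$item_id, stimuli$item_id)
  if (anyNA(idx)) {
    bad <- unique(entries$item_id[is.na(idx)])
    stop("unknown item_id(s) in entries: ", paste(bad, collapse = ", "))
  }
  n <- nrow(entries)
  status <- subtype <- target <- kind <- character(n)
  d <- numeric(n)
  for (i in seq_len(n)) {
    cl <- classify_entry(
      list(raw_string = entries$raw_string[i],
           corrected_string = entries$corrected_string[i],
           first_key = entries$first_key[i],
           n_backspace = entries$n_backspace[i]),
      list(name = stimuli$name[idx[i]],
           alternatives = stimuli$alternatives[idx[i]]),
      config)
    status[i] <- cl$status
    subtype[i] <- cl$subtype
    target[i] <- cl$matched_target
    d[i] <- cl$d
    kind[i] <- cl$target_kind
  }
  entries$status <- status
  entries$subtype <- subtype
  entries$matched_target <- target
  entries$d <- d
  entries$target_kind <- kind
  entries
}

#' Summarize a classified experiment in the error-taxonomy layout
#'
#' Counts and within-status percentages of classification subtypes, the
#' layout conventionally reported for typed-naming studies: correct trials
#' broken down by identical/corrected/below-threshold crossed with picture
#' name vs accepted alternative, incorrect trials by the error taxonomy.
#'
#' @param classified output of [classify_entries()].
#' @return list with `n_total`, `n_correct`, `n_incorrect`,
#'   `pct_correct`, `pct_incorrect`, and data frames `correct` and
#'   `incorrect` (columns `subtype`, `n`, `pct_within_status`).
#' @export
classification_summary <- function(classified) {
  n <- nrow(classified)
  is_corr <- classified$status == "correct"
  n_corr <- sum(is_corr)
  n_inc <- n - n_corr
  corr_levels <- c("identical.picture_name", "corrected.picture_name",
                   "below_threshold.picture_name", "identical.alternative",
                   "corrected.alternative", "below_threshold.alternative")
  corr_key <- paste(classified$subtype[is_corr],
                    classified$target_kind[is_corr], sep = ".")
  corr_n <- as.integer(table(factor(corr_key, levels = corr_levels)))
  inc_levels <- c("na", "special_key_start", "shift_start",
                  "distance_exceeded", "first_letter_error", "combined")
  inc_n <- as.integer(table(factor(classified$subtype[!is_corr],
                                   levels = inc_levels)))
  pct <- function(x, tot) if (tot > 0) 100 * x / tot else rep(NA_real_, length(x))
  list(
    n_total = n,
    n_correct = n_corr,
    n_incorrect = n_inc,
    pct_correct = pct(n_corr, n),
    pct_incorrect = pct(n_inc, n),
    correct = data.frame(subtype = corr_levels, n = corr_n,
                         pct_within_status = pct(corr_n, n_corr)),
    incorrect = data.frame(subtype = inc_levels, n = inc_n,
                           pct_within_status = pct(inc_n, n_inc))
  )
}

# "A;B;C" -> c("A", "B", "C"); empty/NA -> character()
split_alternatives <- function(x) {
  if (is.null(x) || length(x) == 0L) return(character())
  if (length(x) > 1L) return(x[nzchar(x) & !is.na(x)])
  if (is.na(x) || !nzchar(x)) return(character())
  strsplit(x, ";", fixed = TRUE)[[1L]]
}
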