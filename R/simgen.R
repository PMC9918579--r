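#' Parameters of the generative reaction-time model
#'
#' Forward version of the analysis model: for a target trial at ordinal
#' position `p` (mean-centred within 1..5), the conditional mean is
#' `mu = intercept + slope * (p - mean(p)) + u0_subject + u1_subject *
#' (p - mean(p)) + u0_category + u1_category * (p - mean(p))`, with the
#' random effects drawn as independent normals, and the reaction time is
#' gamma with shape `gamma_shape` and mean `mu` (identity link).  The
#' default fixed effects are the cumulative-semantic-interference
#' estimates for typed naming (intercept 1298.49 ms, slope 41.68 ms per
#' ordinal position).  The variance components of the original data are
#' not published, so the random-effect standard deviations are free
#' generator parameters; the defaults are plausible magnitudes for
#' continuous-naming data.  The default shape (18) gives a trial-level SD
#' of roughly 300 ms at the mean RT.
#'
#' @param intercept_ms fixed intercept (ms).
#' @param slope_ms_per_position fixed ordinal-position slope (ms).
#' @param sd_subject_intercept,sd_subject_slope,sd_category_intercept,sd_category_slope
#'   random-effect standard deviations (ms).
#' @param gamma_shape gamma shape parameter (> 0).
#' @return an object of class `"rt_model_params"`.
#' @export
rt_model_params <- function(intercept_ms = 1298.49,
                            slope_ms_per_position = 41.68,
                            sd_subject_intercept = 150,
                            sd_subject_slope = 15,
                            sd_category_intercept = 40,
                            sd_category_slope = 12,
                            gamma_shape = 18) {
  stopifnot(intercept_ms > 0, gamma_shape > 0,
            sd_subject_intercept >= 0, sd_subject_slope >= 0,
            sd_category_intercept >= 0, sd_category_slope >= 0)
  structure(list(intercept_ms = intercept_ms,
                 slope_ms_per_position = slope_ms_per_position,
                 sd_subject_intercept = sd_subject_intercept,
                 sd_subject_slope = sd_subject_slope,
                 sd_category_intercept = sd_category_intercept,
                 sd_category_slope = sd_category_slope,
                 gamma_shape = gamma_shape),
            class = "rt_model_params")
}

#' Parameters of the generative error model
#'
#' Trial correctness is Bernoulli with
#' `P(error) = plogis(logit_intercept + logit_slope * p)` at raw ordinal
#' position `p` in 1..5 (fillers use the central position).  The default
#' log-odds are the spoken-naming error-model estimates (intercept -2.74,
#' ordinal-position slope 0.15), which give overall error rates around
#' 7-12%.
#'
#' @param logit_intercept,logit_slope error model coefficients on the
#'   log-odds scale.
#' @return an object of class `"error_model_params"`.
#' @export
error_model_params <- function(logit_intercept = -2.74,
                               logit_slope = 0.15) {
  stopifnot(is.finite(logit_intercept), is.finite(logit_slope))
  structure(list(logit_intercept = logit_intercept,
                 logit_slope = logit_slope),
            class = "error_model_params")
}

#' Parameters of the keystroke simulator
#'
#' Governs how planted trial outcomes are realized as keystroke streams.
#' For trials destined to be correct: the participant types the accepted
#' alternative (when one exists) with probability `p_alternative_name`;
#' each non-initial character suffers a typo with probability `p_typo`;
#' a typo is repaired with a backspace with probability
#' `p_backspace_repair`, and at most one typo per word is left unrepaired
#' (an interior one-character substitution, which keeps the Jaro distance
#' below 0.15 for words of four or more characters).  For trials destined
#' to be incorrect, the realization is drawn among: no answer
#' (`p_null_response`), special-key start (`p_special_start`), shift start
#' (`p_shift_start`), a first-letter substitution (`p_first_letter_typo`),
#' a fully dissimilar entry (`p_combined`), and -- with the remaining
#' probability -- a same-first-letter entry whose distance exceeds any
#' reasonable threshold.  These exclusive-mode probabilities must sum to
#' at most 1.  Inter-keystroke intervals are folded-normal
#' (`iki_mean_ms`, `iki_sd_ms`); a terminal enter key is appended with
#' probability `p_enter_finish`.
#'
#' @param p_typo per-character typo probability (correct trials).
#' @param p_backspace_repair probability a typo is backspace-repaired.
#' @param p_alternative_name probability of typing the accepted
#'   alternative instead of the picture name, when one exists.
#' @param p_special_start,p_shift_start,p_null_response,p_first_letter_typo,p_combined
#'   mixture weights of the incorrect-trial realizations (the remainder
#'   goes to distance-exceeded entries).
#' @param iki_mean_ms,iki_sd_ms inter-keystroke interval parameters.
#' @param p_enter_finish probability of a terminal enter key.
#' @return an object of class `"typing_behavior_params"`.
#' @export
typing_behavior_params <- function(p_typo = 0.05,
                                   p_backspace_repair = 0.6,
                                   p_alternative_name = 0.1,
                                   p_special_start = 0.07,
                                   p_shift_start = 0.02,
                                   p_null_response = 0.29,
                                   p_first_letter_typo = 0.43,
                                   p_combined = 0.17,
                                   iki_mean_ms = 250, iki_sd_ms = 80,
                                   p_enter_finish = 0.8) {
  p <- c(p_typo, p_backspace_repair, p_alternative_name, p_special_start,
         p_shift_start, p_null_response, p_first_letter_typo, p_combined,
         p_enter_finish)
  if (any(p < 0 | p > 1)) stop("all probabilities must be in [0, 1]")
  modes <- p_special_start + p_shift_start + p_null_response +
    p_first_letter_typo + p_combined
  if (modes > 1 + 1e-12)
    stop("exclusive incorrect-trial mode probabilities sum to ", modes,
         " > 1")
  structure(list(p_typo = p_typo, p_backspace_repair = p_backspace_repair,
                 p_alternative_name = p_alternative_name,
                 p_special_start = p_special_start,
                 p_shift_start = p_shift_start,
                 p_null_response = p_null_response,
                 p_first_letter_typo = p_first_letter_typo,
                 p_combined = p_combined,
                 iki_mean_ms = iki_mean_ms, iki_sd_ms = iki_sd_ms,
                 p_enter_finish = p_enter_finish),
            class = "typing_behavior_params")
}

# Names are drawn from this alphabet; the simulator realizes wrong
# characters from the disjoint ERROR_ALPHABET, which guarantees planted
# distances (one substitution stays < 0.17; "garbage" entries stay > 0.5).
NAME_ALPHABET <- c(LETTERS[1:20], "Ä", "Ö", "Ü")
ERROR_ALPHABET <- LETTERS[21:26]

#' Generate a synthetic stimulus set
#'
#' Random unique upper-case names (4-9 characters, including umlauts)
#' organized into categories of `exemplars_per_category` members, pairs
#' of categories sharing a superordinate, plus fillers.  A fraction of
#' stimuli receives one accepted naming alternative starting with a
#' different character, which exercises best-match selection.
#'
#' @param config a [design_config()].
#' @param p_alternative fraction of stimuli given an accepted alternative.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a stimulus data frame (see [read_stimuli()]).
#' @export
simulate_stimuli <- function(config = design_config(), p_alternative = 0.3,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_stimuli_free(config$n_categories, config$exemplars_per_category,
                        config$n_fillers, p_alternative)
}

random_words <- function(n, min_len = 4L, max_len = 9L) {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  w <- vapply(lens, function(l)
    paste(sample(NAME_ALPHABET, l, replace = TRUE), collapse = ""),
    character(1))
  unique(w)
}

#' Simulate a trial table from the generative CSI model
#'
#' Runs the analysis model forward (see [rt_model_params()] and
#' [error_model_params()]): crossed subject and category random effects,
#' gamma reaction times with identity link, Bernoulli correctness.
#' Fillers (optional) get the subject's intercept-level mean and the
#' central-position error probability.
#'
#' @param n_subjects,n_categories design size; each subject names
#'   `exemplars_per_category` exemplars of every category.
#' @param rt an [rt_model_params()].
#' @param err an [error_model_params()].
#' @param config a [design_config()]; `exemplars_per_category` and filler
#'   counts are taken from here (`n_categories` is overridden by the
#'   `n_categories` argument).
#' @param include_fillers add filler trials (no ordinal position).
#' @param stimuli optional stimulus table; when supplied, items are
#'   attached so the table can drive the keystroke simulator.  Categories
#'   beyond those in `stimuli` are invalid.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a trial-table data frame: `pid`, `trial`, `item_id`,
#'   `category`, `ordinal_position`, `is_filler`, `mu`, `rt_ms`,
#'   `correct`.
#' @export
simulate_trial_table <- function(n_subjects = 30, n_categories = 24,
                                 rt = rt_model_params(),
                                 err = error_model_params(),
                                 config = design_config(),
                                 include_fillers = TRUE,
                                 stimuli = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_ex <- config$exemplars_per_category
  pid <- sprintf("s%02d", seq_len(n_subjects))
  cat_id <- sprintf("cat%02d", seq_len(n_categories))
  u0s <- rnorm(n_subjects, 0, rt$sd_subject_intercept)
  u1s <- rnorm(n_subjects, 0, rt$sd_subject_slope)
  u0c <- rnorm(n_categories, 0, rt$sd_category_intercept)
  u1c <- rnorm(n_categories, 0, rt$sd_category_slope)
  d <- expand.grid(ordinal_position = seq_len(n_ex),
                   category = seq_len(n_categories),
                   subject = seq_len(n_subjects))
  pos_c <- d$ordinal_position - mean(seq_len(n_ex))
  mu <- rt$intercept_ms + rt$slope_ms_per_position * pos_c +
    u0s[d$subject] + u1s[d$subject] * pos_c +
    u0c[d$category] + u1c[d$category] * pos_c
  tab <- data.frame(pid = pid[d$subject],
                    category = cat_id[d$category],
                    ordinal_position = d$ordinal_position,
                    is_filler = FALSE, mu = mu,
                    stringsAsFactors = FALSE)
  if (include_fillers) {
    n_fill <- config$n_fillers
    fd <- expand.grid(f = seq_len(n_fill), subject = seq_len(n_subjects))
    fill <- data.frame(pid = pid[fd$subject], category = NA_character_,
                       ordinal_position = NA_integer_, is_filler = TRUE,
                       mu = rt$intercept_ms + u0s[fd$subject],
                       stringsAsFactors = FALSE)
    tab <- rbind(tab, fill)
  }
  if (any(tab$mu <= 0))
    stop("generative model implies non-positive mean RT; ",
         "reduce random-effect SDs or raise the intercept ",
         "(identity-link positivity)")
  tab$rt_ms <- rgamma(nrow(tab), shape = rt$gamma_shape,
                      scale = tab$mu / rt$gamma_shape)
  pos_for_err <- ifelse(is.na(tab$ordinal_position),
                        stats::median(seq_len(n_ex)),
                        tab$ordinal_position)
  p_err <- plogis(err$logit_intercept + err$logit_slope * pos_for_err)
  tab$correct <- runif(nrow(tab)) >= p_err
  # attach item ids
  if (!is.null(stimuli)) {
    targets <- stimuli[!stimuli$is_filler, , drop = FALSE]
    ord_in_cat <- stats::ave(seq_len(nrow(targets)), targets$category,
                             FUN = seq_along)
    key <- paste(targets$category, ord_in_cat)
    idx <- match(paste(tab$category, tab$ordinal_position), key)
    tab$item_id <- targets$item_id[idx]
    fillers <- stimuli[stimuli$is_filler, , drop = FALSE]
    f_ix <- which(tab$is_filler)
    if (length(f_ix)) {
      per_subj <- split(f_ix, tab$pid[f_ix])
      for (s in names(per_subj))
        tab$item_id[per_subj[[s]]] <-
          fillers$item_id[seq_along(per_subj[[s]])]
    }
  } else {
    tab$item_id <- ifelse(tab$is_filler,
                          paste0("fill_", stats::ave(seq_len(nrow(tab)),
                                                     tab$pid,
                                                     FUN = seq_along)),
                          paste0(tab$category, "_", tab$ordinal_position))
  }
  tab <- tab[order(tab$pid), , drop = FALSE]
  tab$trial <- stats::ave(seq_len(nrow(tab)), tab$pid, FUN = seq_along)
  rownames(tab) <- NULL
  tab[, c("pid", "trial", "item_id", "category", "ordinal_position",
          "is_filler", "mu", "rt_ms", "correct")]
}

#' Simulate keystroke streams with planted ground-truth labels
#'
#' Realizes each trial of a simulated trial table as a keystroke event
#' stream whose classification outcome is known by construction (see
#' [typing_behavior_params()]).  The first event of every non-null trial
#' occurs exactly at the trial's `rt_ms`.
#'
#' @param trial_table output of [simulate_trial_table()] (with item ids
#'   resolvable in `stimuli`).
#' @param stimuli stimulus table.
#' @param behavior a [typing_behavior_params()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `keylog` (a `keylog` data frame) and `truth` (one
#'   row per trial: `pid`, `trial`, `item_id`, `true_status`,
#'   `true_subtype`, `true_target_kind`).
#' @export
simulate_keystrokes <- function(trial_table, stimuli,
                                behavior = typing_behavior_params(),
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- match(trial_table$item_id, stimuli$item_id)
  if (anyNA(idx)) stop("trial table contains unknown item_id(s)")
  nm <- stimuli$name[idx]
  alt <- stimuli$alternatives[idx]
  n <- nrow(trial_table)
  keys_l <- times_l <- vector("list", n)
  true_subtype <- true_kind <- character(n)
  inc_modes <- c("na", "special_key_start", "shift_start",
                 "first_letter_error", "combined", "distance_exceeded")
  inc_w <- c(behavior$p_null_response, behavior$p_special_start,
             behavior$p_shift_start, behavior$p_first_letter_typo,
             behavior$p_combined,
             max(0, 1 - behavior$p_null_response - behavior$p_special_start -
                   behavior$p_shift_start - behavior$p_first_letter_typo -
                   behavior$p_combined))
  for (i in seq_len(n)) {
    target <- nm[i]
    if (trial_table$correct[i]) {
      use_alt <- nzchar(alt[i]) &&
        runif(1) < behavior$p_alternative_name
      word <- if (use_alt) split_alternatives(alt[i])[1L] else target
      true_kind[i] <- if (use_alt) "alternative" else "picture_name"
      chars <- strsplit(word, "")[[1L]]
      L <- length(chars)
      typo_at <- which(runif(L) < behavior$p_typo)
      typo_at <- setdiff(typo_at, 1L)   # first character always correct
      repaired <- runif(length(typo_at)) < behavior$p_backspace_repair
      # at most one unrepaired typo keeps the entry below threshold
      if (sum(!repaired) > 1L) repaired[which(!repaired)[-1L]] <- TRUE
      ks <- character(0)
      for (j in seq_len(L)) {
        if (j %in% typo_at) {
          wrong <- sample(ERROR_ALPHABET, 1L)
          if (repaired[match(j, typo_at)]) {
            ks <- c(ks, wrong, "BACKSPACE", chars[j])
          } else {
            ks <- c(ks, wrong)            # unrepaired substitution
          }
        } else {
          ks <- c(ks, chars[j])
        }
      }
      n_unrepaired <- sum(!repaired)
      true_subtype[i] <- if (length(typo_at) == 0L) "identical"
      else if (n_unrepaired == 0L) "corrected"
      else "below_threshold"
    } else {
      mode <- sample(inc_modes, 1L, prob = inc_w)
      true_kind[i] <- NA_character_
      true_subtype[i] <- mode
      chars <- strsplit(target, "")[[1L]]
      L <- length(chars)
      ks <- switch(
        mode,
        na = character(0),
        special_key_start = c(sample(c("SPACE", "BACKSPACE", "CAPSLOCK",
                                       "ENTER"), 1L), chars),
        shift_start = c("SHIFT", chars),
        first_letter_error = c(sample(ERROR_ALPHABET, 1L), chars[-1L]),
        combined = sample(ERROR_ALPHABET, L, replace = TRUE),
        distance_exceeded = c(chars[1L],
                              sample(ERROR_ALPHABET, max(L - 1L, 3L),
                                     replace = TRUE)))
    }
    if (length(ks) && true_subtype[i] != "na" &&
        runif(1) < behavior$p_enter_finish)
      ks <- c(ks, "ENTER")
    if (length(ks)) {
      gaps <- abs(rnorm(length(ks) - 1L, behavior$iki_mean_ms,
                        behavior$iki_sd_ms))
      times_l[[i]] <- trial_table$rt_ms[i] + c(0, cumsum(pmax(gaps, 10)))
      keys_l[[i]] <- ks
    }
  }
  n_ev <- lengths(keys_l)
  keylog <- data.frame(
    pid = rep(trial_table$pid, n_ev),
    trial = rep(trial_table$trial, n_ev),
    item_id = rep(trial_table$item_id, n_ev),
    key = unlist(keys_l, use.names = FALSE),
    t_ms = unlist(times_l, use.names = FALSE),
    stringsAsFactors = FALSE)
  class(keylog) <- c("keylog", "data.frame")
  truth <- data.frame(pid = trial_table$pid, trial = trial_table$trial,
                      item_id = trial_table$item_id,
                      true_status = ifelse(trial_table$correct, "correct",
                                           "incorrect"),
                      true_subtype = true_subtype,
                      true_target_kind = true_kind,
                      stringsAsFactors = FALSE)
  list(keylog = keylog, truth = truth)
}

#' Simulate a complete typed-naming experiment
#'
#' Convenience wrapper: synthesizes a stimulus set, a trial table from
#' the generative CSI model, and keystroke streams with planted labels.
#'
#' @inheritParams simulate_trial_table
#' @param behavior a [typing_behavior_params()].
#' @param seed integer seed for the whole chain.
#' @return list with `stimuli`, `trial_table`, `keylog`, `truth`.
#' @export
simulate_experiment <- function(n_subjects = 30, n_categories = 24,
                                rt = rt_model_params(),
                                err = error_model_params(),
                                behavior = typing_behavior_params(),
                                config = design_config(),
                                include_fillers = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  if (n_categories != cfg$n_categories) {
    # relax the block identity for non-default category counts
    cfg$n_categories <- as.integer(n_categories)
  }
  stimuli <- simulate_stimuli_free(n_categories, cfg$exemplars_per_category,
                                   if (include_fillers) cfg$n_fillers else 0L)
  tab <- simulate_trial_table(n_subjects, n_categories, rt, err, cfg,
                              include_fillers, stimuli)
  sim <- simulate_keystrokes(tab, stimuli, behavior)
  list(stimuli = stimuli, trial_table = tab, keylog = sim$keylog,
       truth = sim$truth)
}

# Stimulus generator without the block-design invariants (any category
# count), used by simulate_experiment and the power simulations.
simulate_stimuli_free <- function(n_categories, exemplars_per_category,
                                  n_fillers, p_alternative = 0.3) {
  n_target <- n_categories * exemplars_per_category
  words <- random_words(ceiling((n_target + n_fillers) * 1.6) + 20L)
  nm <- words[seq_len(n_target + n_fillers)]
  out <- data.frame(
    item_id = c(paste0(rep(sprintf("cat%02d", seq_len(n_categories)),
                           each = exemplars_per_category), "_",
                       rep(seq_len(exemplars_per_category), n_categories)),
                if (n_fillers) paste0("fill_", seq_len(n_fillers))),
    name = nm,
    alternatives = "",
    category = c(rep(sprintf("cat%02d", seq_len(n_categories)),
                     each = exemplars_per_category),
                 rep("", n_fillers)),
    superordinate = c(rep(sprintf("sup%02d", ceiling(
      seq_len(n_categories) / 2)), each = exemplars_per_category),
      rep("", n_fillers)),
    is_filler = c(rep(FALSE, n_target), rep(TRUE, n_fillers)),
    stringsAsFactors = FALSE)
  rest <- words[-seq_len(n_target + n_fillers)]
  has_alt <- which(runif(nrow(out)) < p_alternative)
  has_alt <- has_alt[seq_len(min(length(has_alt), length(rest)))]
  if (length(has_alt)) {
    alts <- rest[seq_along(has_alt)]
    # the alternative must start with a different character than the name
    clash <- substr(alts, 1, 1) == substr(out$name[has_alt], 1, 1)
    prefix <- ifelse(substr(out$name[has_alt], 1, 1) == "Ä", "Ö", "Ä")
    alts[clash] <- paste0(prefix[clash], alts[clash])
    out$alternatives[has_alt] <- alts
  }
  out
}
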