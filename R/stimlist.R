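#' Design configuration for a continuous-naming experiment
#'
#' Defaults describe the standard cumulative semantic interference layout:
#' 24 semantic categories of five closely related exemplars distributed
#' over eight blocks of three categories each, with five fillers added per
#' block (eight blocks of 20 items, 160 trials), and members of the same
#' category separated by at least two and at most eight intervening items
#' (including fillers).
#'
#' @param n_categories number of target categories.
#' @param exemplars_per_category exemplars per category.
#' @param n_fillers total number of filler items.
#' @param n_blocks number of blocks.
#' @param categories_per_block target categories per block.
#' @param fillers_per_block fillers per block.
#' @param lag_min,lag_max minimum/maximum number of intervening items
#'   between consecutive members of the same category.
#' @return an object of class `"design_config"`.
#' @export
design_config <- function(n_categories = 24, exemplars_per_category = 5,
                          n_fillers = 40, n_blocks = 8,
                          categories_per_block = 3, fillers_per_block = 5,
                          lag_min = 2, lag_max = 8) {
  cfg <- list(n_categories = as.integer(n_categories),
              exemplars_per_category = as.integer(exemplars_per_category),
              n_fillers = as.integer(n_fillers),
              n_blocks = as.integer(n_blocks),
              categories_per_block = as.integer(categories_per_block),
              fillers_per_block = as.integer(fillers_per_block),
              lag_min = as.integer(lag_min), lag_max = as.integer(lag_max))
  if (cfg$n_categories != cfg$n_blocks * cfg$categories_per_block)
    stop("n_categories must equal n_blocks * categories_per_block")
  if (cfg$n_fillers != cfg$n_blocks * cfg$fillers_per_block)
    stop("n_fillers must equal n_blocks * fillers_per_block")
  if (cfg$lag_min < 1L) stop("lag_min must be >= 1")
  if (cfg$lag_max < cfg$lag_min) stop("lag_max must be >= lag_min")
  structure(cfg, class = "design_config")
}

#' Read / write a stimulus table
#'
#' CSV columns: `item_id`, `name`, `alternatives` (`";"`-separated,
#' possibly empty), `category`, `superordinate`, `is_filler`.  Fillers
#' have empty `category`/`superordinate`.
#'
#' @param path CSV file path.
#' @return a stimulus data frame.
#' @export
read_stimuli <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  need <- c("item_id", "name", "alternatives", "category", "superordinate",
            "is_filler")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("stimulus table missing columns: ",
                         paste(miss, collapse = ", "))
  df$is_filler <- as.logical(df$is_filler) |
    df$is_filler %in% c("1", "true", "TRUE")
  df$alternatives[is.na(df$alternatives)] <- ""
  if (any(!nzchar(df$name))) stop("stimulus names must be non-empty")
  df
}

#' @rdname read_stimuli
#' @param stimuli stimulus data frame.
#' @export
write_stimuli <- function(stimuli, path) {
  utils::write.csv(stimuli, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Assign categories to blocks, separating shared superordinates
#'
#' Categories that share a superordinate semantic category (e.g. fish and
#' insects are both animals) should appear in blocks as far apart as
#' possible.  This searches for an assignment of categories to ordered
#' blocks (capacity `categories_per_block` each) maximizing the summed
#' pairwise block distance between same-superordinate categories.  The
#' search is exhaustive when the number of distinct assignments is small
#' (at most `exhaustive_limit`); otherwise seeded random-restart
#' hill-climbing over pairwise swaps is used.
#'
#' @param stimuli stimulus table; only non-filler rows are used.
#' @param config a [design_config()].
#' @param n_restarts hill-climbing restarts (ignored when exhaustive).
#' @param exhaustive_limit assignment-count cut-off for exhaustive search.
#' @return data frame with columns `category`, `superordinate`, `block`;
#'   attribute `"score"` holds the achieved separation score.
#' @export
assign_categories_to_blocks <- function(stimuli, config = design_config(),
                                        n_restarts = 25,
                                        exhaustive_limit = 20000) {
  targets <- stimuli[!stimuli$is_filler, , drop = FALSE]
  cats <- unique(targets[, c("category", "superordinate")])
  if (nrow(cats) != config$n_categories)
    stop("expected ", config$n_categories, " categories, found ",
         nrow(cats))
  k <- config$categories_per_block
  nb <- config$n_blocks
  sup <- cats$superordinate
  # pairs of categories sharing a superordinate
  pair_i <- pair_j <- integer(0)
  for (s in unique(sup)) {
    ix <- which(sup == s)
    if (length(ix) > 1L) {
      cmb <- utils::combn(ix, 2L)
      pair_i <- c(pair_i, cmb[1L, ])
      pair_j <- c(pair_j, cmb[2L, ])
    }
  }
  score <- function(block_of) {
    if (!length(pair_i)) return(0)
    sum(abs(block_of[pair_i] - block_of[pair_j]))
  }
  n_assign <- factorial(config$n_categories) /
    prod(rep(factorial(k), nb)) / factorial(0L)
  if (is.finite(n_assign) && n_assign <= exhaustive_limit) {
    best <- NULL
    best_score <- -Inf
    recurse <- function(block_of, cap, i) {
      if (i > length(block_of)) {
        s <- score(block_of)
        if (s > best_score) {
          best_score <<- s
          best <<- block_of
        }
        return(invisible())
      }
      for (b in seq_len(nb)) {
        if (cap[b] > 0L) {
          block_of[i] <- b
          cap[b] <- cap[b] - 1L
          recurse(block_of, cap, i + 1L)
          cap[b] <- cap[b] + 1L
        }
      }
    }
    recurse(integer(nrow(cats)), rep(k, nb), 1L)
    block_of <- best
  } else {
    best <- NULL
    best_score <- -Inf
    for (r in seq_len(n_restarts)) {
      block_of <- sample(rep(seq_len(nb), each = k))
      s <- score(block_of)
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (a in seq_len(length(block_of) - 1L)) {
          for (b in seq((a + 1L), length(block_of))) {
            if (block_of[a] == block_of[b]) next
            cand <- block_of
            cand[c(a, b)] <- cand[c(b, a)]
            s2 <- score(cand)
            if (s2 > s) {
              block_of <- cand
              s <- s2
              improved <- TRUE
            }
          }
        }
      }
      if (s > best_score) {
        best_score <- s
        best <- block_of
      }
    }
    block_of <- best
  }
  out <- data.frame(category = cats$category,
                    superordinate = cats$superordinate,
                    block = block_of, stringsAsFactors = FALSE)
  attr(out, "score") <- best_score
  out
}

#' Randomize one block's trial order under lag constraints
#'
#' Produces a permutation of a block's items (targets of
#' `categories_per_block` categories plus fillers) such that consecutive
#' members of the same category are separated by `lag_min` to `lag_max`
#' intervening items.  Sequences are proposed by seeded constrained
#' sequential placement: trial slots are filled left to right, drawing
#' among items whose category respects the minimum lag, forcing a category
#' whose maximum-lag deadline or remaining-slot budget would otherwise be
#' violated, and restarting on dead ends.  Uses the current RNG state.
#'
#' @param block_stimuli stimulus rows for one block.
#' @param config a [design_config()].
#' @param max_restarts proposal budget before giving up.
#' @return `block_stimuli` reordered; error if no admissible sequence is
#'   found within the budget.
#' @export
randomize_block <- function(block_stimuli, config = design_config(),
                            max_restarts = 10000) {
  n_target <- config$categories_per_block * config$exemplars_per_category
  if (sum(!block_stimuli$is_filler) != n_target ||
      sum(block_stimuli$is_filler) != config$fillers_per_block)
    stop("block composition does not match the design configuration")
  cats <- unique(block_stimuli$category[!block_stimuli$is_filler])
  seq_cats <- NULL
  for (r in seq_len(max_restarts)) {
    seq_cats <- propose_block_sequence(cats, config)
    if (!is.null(seq_cats)) break
  }
  if (is.null(seq_cats))
    stop("no block sequence satisfying lag constraints [",
         config$lag_min, ", ", config$lag_max, "] found within ",
         max_restarts, " proposals")
  # map category slots to shuffled exemplars, filler slots to shuffled fillers
  out_idx <- integer(length(seq_cats))
  fill_idx <- sample(which(block_stimuli$is_filler))
  f <- 1L
  for (cc in cats) {
    slots <- which(seq_cats == cc)
    out_idx[slots] <- sample(which(block_stimuli$category == cc &
                                     !block_stimuli$is_filler))
  }
  out_idx[seq_cats == ".filler"] <- fill_idx
  block_stimuli[out_idx, , drop = FALSE]
}

# One constrained sequential placement proposal; NULL on dead end.
propose_block_sequence <- function(cats, config) {
  n_ex <- config$exemplars_per_category
  n <- length(cats) * n_ex + config$fillers_per_block
  lag_min <- config$lag_min
  lag_max <- config$lag_max
  rem <- stats::setNames(rep(n_ex, length(cats)), cats)
  rem_fill <- config$fillers_per_block
  last <- stats::setNames(rep(NA_integer_, length(cats)), cats)
  out <- character(n)
  for (t in seq_len(n)) {
    interv <- t - last - 1L          # intervening items if placed at t
    open <- rem > 0L
    elig <- open & (is.na(last) | interv >= lag_min)
    overdue <- open & !is.na(last) & interv >= lag_max
    # remaining members of c must fit into slots t..n at minimal spacing
    pressed <- open & ((n - t + 1L) <= (rem - 1L) * (lag_min + 1L) + 1L)
    forced <- (overdue | pressed) & elig
    if (any(overdue & !elig) || sum(forced) > 1L) return(NULL)
    if (any(forced)) {
      pick <- names(which(forced))[1L]
    } else {
      pool <- names(which(elig))
      w <- rem[pool]
      if (rem_fill > 0L) {
        pool <- c(pool, ".filler")
        w <- c(w, rem_fill)
      }
      if (!length(pool)) return(NULL)
      pick <- if (length(pool) == 1L) pool else sample(pool, 1L, prob = w)
    }
    out[t] <- pick
    if (pick == ".filler") {
      rem_fill <- rem_fill - 1L
    } else {
      rem[pick] <- rem[pick] - 1L
      last[pick] <- t
    }
  }
  out
}

#' Generate a full pseudorandomized trial list
#'
#' Assigns categories to blocks via [assign_categories_to_blocks()],
#' distributes fillers evenly, randomizes each block under the lag
#' constraints via [randomize_block()], and numbers trials and
#' within-category ordinal positions.  The same seed with the same inputs
#' reproduces the identical list.
#'
#' @param stimuli stimulus table (see [read_stimuli()]).
#' @param config a [design_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param ... passed on to [randomize_block()].
#' @return a `trial_list` data frame: `trial` (1-based position), `block`,
#'   `item_id`, `name`, `category`, `superordinate`, `is_filler`,
#'   `ordinal_position` (1..exemplars for targets, NA for fillers).
#' @export
generate_trial_list <- function(stimuli, config = design_config(),
                                seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  assignment <- assign_categories_to_blocks(stimuli, config)
  fillers <- stimuli[stimuli$is_filler, , drop = FALSE]
  if (nrow(fillers) != config$n_fillers)
    stop("expected ", config$n_fillers, " fillers, found ", nrow(fillers))
  filler_block <- sample(rep(seq_len(config$n_blocks),
                             each = config$fillers_per_block))
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    cats_b <- assignment$category[assignment$block == b]
    rows <- rbind(
      stimuli[!stimuli$is_filler & stimuli$category %in% cats_b, ,
              drop = FALSE],
      fillers[filler_block == b, , drop = FALSE])
    ordered <- randomize_block(rows, config, ...)
    ordered$block <- b
    blocks[[b]] <- ordered
  }
  out <- do.call(rbind, blocks)
  out$trial <- seq_len(nrow(out))
  out$ordinal_position <- NA_integer_
  for (cc in unique(out$category[!out$is_filler])) {
    ix <- which(!out$is_filler & out$category == cc)
    out$ordinal_position[ix] <- seq_along(ix)
  }
  rownames(out) <- NULL
  out <- out[, c("trial", "block", "item_id", "name", "category",
                 "superordinate", "is_filler", "ordinal_position")]
  class(out) <- c("trial_list", "data.frame")
  out
}

#' Validate a trial list against the design constraints
#'
#' Checks block composition (targets and fillers per block), that every
#' category's exemplars fall within a single block, that within-category
#' lags (intervening items between consecutive members) lie in
#' `[lag_min, lag_max]`, and that ordinal positions equal the
#' within-category occurrence rank.  Reports violations instead of
#' raising.
#'
#' @param trial_list a `trial_list` data frame (see
#'   [generate_trial_list()]).
#' @param config a [design_config()].
#' @return list of class `"list_validation"` with `pass` (logical) and
#'   `violations` (data frame: `type`, `block`, `category`, `detail`).
#' @export
validate_list <- function(trial_list, config = design_config()) {
  v <- list()
  add <- function(type, block, category, detail) {
    v[[length(v) + 1L]] <<- data.frame(type = type,
                                       block = as.integer(block),
                                       category = as.character(category),
                                       detail = detail,
                                       stringsAsFactors = FALSE)
  }
  n_expected <- config$n_categories * config$exemplars_per_category +
    config$n_fillers
  if (nrow(trial_list) != n_expected)
    add("list_length", NA, NA, paste0("expected ", n_expected, " trials, got ",
                                      nrow(trial_list)))
  for (b in unique(trial_list$block)) {
    bl <- trial_list[trial_list$block == b, , drop = FALSE]
    n_t <- sum(!bl$is_filler)
    n_f <- sum(bl$is_filler)
    if (n_t != config$categories_per_block * config$exemplars_per_category ||
        n_f != config$fillers_per_block)
      add("block_composition", b, NA,
          paste0(n_t, " targets + ", n_f, " fillers"))
  }
  targets <- trial_list[!trial_list$is_filler, , drop = FALSE]
  for (cc in unique(targets$category)) {
    rows <- targets[targets$category == cc, , drop = FALSE]
    if (length(unique(rows$block)) > 1L)
      add("category_split_across_blocks", NA, cc,
          paste("blocks", paste(sort(unique(rows$block)), collapse = ",")))
    if (nrow(rows) != config$exemplars_per_category)
      add("category_size", NA, cc, paste0(nrow(rows), " exemplars"))
    pos <- sort(rows$trial)
    lags <- diff(pos) - 1L
    if (any(lags < config$lag_min))
      add("lag_min", rows$block[1L], cc,
          paste("lag", min(lags), "<", config$lag_min))
    if (any(lags > config$lag_max))
      add("lag_max", rows$block[1L], cc,
          paste("lag", max(lags), ">", config$lag_max))
    ord <- rows$ordinal_position[order(rows$trial)]
    if (!identical(as.integer(ord), seq_len(nrow(rows))))
      add("ordinal_position", rows$block[1L], cc,
          paste("found", paste(ord, collapse = ",")))
  }
  if (any(!is.na(trial_list$ordinal_position[trial_list$is_filler])))
    add("filler_ordinal_position", NA, NA,
        "fillers must not carry an ordinal position")
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(type = character(), block = integer(),
               category = character(), detail = character(),
               stringsAsFactors = FALSE)
  structure(list(pass = nrow(violations) == 0L, violations = violations),
            class = "list_validation")
}

#' @param x a `list_validation` object.
#' @param ... ignored.
#' @rdname validate_list
#' @method print list_validation
#' @export
print.list_validation <- function(x, ...) {
  cat("Trial-list validation:", if (x$pass) "PASS" else "FAIL", "\n")
  if (!x$pass) print(x$violations)
  invisible(x)
}

#' Within-category lags of a trial list
#'
#' Number of intervening items between consecutive members of each
#' category (the "lag" whose admissible range the design constrains).
#'
#' @param trial_list a `trial_list` data frame.
#' @return data frame with columns `category`, `from_ordinal`, `lag`.
#' @export
list_lags <- function(trial_list) {
  targets <- trial_list[!trial_list$is_filler, , drop = FALSE]
  out <- lapply(unique(targets$category), function(cc) {
    pos <- sort(targets$trial[targets$category == cc])
    if (length(pos) < 2L) return(NULL)
    data.frame(category = cc, from_ordinal = seq_len(length(pos) - 1L),
               lag = diff(pos) - 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read / write a trial list
#'
#' CSV export/import with 1-based trial numbering.
#'
#' @param trial_list a `trial_list` data frame.
#' @param path CSV file path.
#' @export
write_trial_list <- function(trial_list, path) {
  utils::write.csv(trial_list, path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_list
#' @export
read_trial_list <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  df$is_filler <- as.logical(df$is_filler)
  df$ordinal_position <- as.integer(df$ordinal_position)
  class(df) <- c("trial_list", "data.frame")
  df
}
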