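#' Trial exclusion with full accounting
#'
#' Builds the two analysis tables used in continuous-naming studies: the
#' reaction-time table (non-filler AND correct trials) and the error table
#' (all non-filler trials with their correctness flag), together with an
#' accounting report satisfying the identity
#' `n_retained = n_total - n_filler - n_erroneous + n_erroneous_fillers`.
#'
#' @param trial_table data frame with columns `pid`, `trial`,
#'   `ordinal_position`, `is_filler`, `rt_ms`, and (unless
#'   `classifications` is given) `correct`.
#' @param classifications optional classified entries (from
#'   [classify_entries()]) carrying `pid`, `trial` and `status`; when
#'   supplied, correctness is taken from `status == "correct"` and every
#'   trial must be classified.
#' @return list with `rt_table`, `error_table` (adds an `error` column),
#'   and `accounting` (named list of the five counts).
#' @export
exclude_trials <- function(trial_table, classifications = NULL) {
  tab <- as.data.frame(trial_table)
  if (!is.null(classifications)) {
    key_t <- paste(tab$pid, tab$trial)
    key_c <- paste(classifications$pid, classifications$trial)
    idx <- match(key_t, key_c)
    if (anyNA(idx)) {
      stop("trials without classification: ",
           paste(utils::head(key_t[is.na(idx)], 5L), collapse = "; "))
    }
    tab$correct <- classifications$status[idx] == "correct"
  }
  if (is.null(tab$correct)) stop("no correctness information available")
  n_total <- nrow(tab)
  n_filler <- sum(tab$is_filler)
  n_err <- sum(!tab$correct)
  n_err_fill <- sum(!tab$correct & tab$is_filler)
  rt_table <- tab[!tab$is_filler & tab$correct, , drop = FALSE]
  error_table <- tab[!tab$is_filler, , drop = FALSE]
  error_table$error <- as.integer(!error_table$correct)
  accounting <- list(n_total = n_total, n_filler = n_filler,
                     n_erroneous = n_err,
                     n_erroneous_fillers = n_err_fill,
                     n_retained = n_total - n_filler - n_err + n_err_fill)
  stopifnot(accounting$n_retained == nrow(rt_table))
  list(rt_table = rt_table, error_table = error_table,
       accounting = accounting)
}

#' Fit the gamma-identity GLMM for reaction times
#'
#' The canonical analysis of the cumulative semantic interference effect:
#' a generalized linear mixed model with gamma distribution and identity
#' link, `rt ~ ordinal_position + (ordinal_position | subject) +
#' (ordinal_position | category)`, with ordinal position entered as a
#' continuous, mean-centred predictor (centred on the retained analysis
#' rows).  Inference on the fixed effects is by Wald Z: `CI = estimate
#' +/- 1.96 SE`, p-values from the standard normal.  On non-convergence
#' the random-structure reduction ladder is applied (see
#' [reduction_ladder()]).
#'
#' @param table reaction-time analysis table (see [exclude_trials()]):
#'   columns `pid`, `category`, `ordinal_position`, `rt_ms`.
#' @param ladder logical: apply the reduction ladder on non-convergence.
#' @param backend `"glmmTMB"` (default; automatic-differentiation Laplace
#'   likelihood, started at the sample mean so the identity link stays
#'   positive) or `"lme4"`.  The two backends agree closely on the fixed
#'   effects and serve as mutual cross-checks.
#' @return a `csi_fit` object.
#' @export
fit_rt_model <- function(table, ladder = TRUE,
                         backend = c("glmmTMB", "lme4")) {
  backend <- match.arg(backend)
  stopifnot(nrow(table) > 0, all(table$rt_ms > 0))
  dat <- model_frame(table, response = "rt_ms")
  fit_with_ladder(response = "rt_ms", dat = dat,
                  family = stats::Gamma(link = "identity"),
                  apply_ladder = ladder, backend = backend)
}

#' Fit the binomial GLMM for error rates
#'
#' Logistic mixed model `error ~ ordinal_position +
#' (ordinal_position | subject) + (ordinal_position | category)` on all
#' non-filler trials.  On non-convergence the reduction ladder is applied:
#' (1) raise the optimizer iteration cap to 2e5, (2) set random-effect
#' correlations to zero, (3) drop random slopes (subject slope first, then
#' category slope).  Every attempted structure is recorded in the
#' reduction trace.
#'
#' @param table error analysis table (see [exclude_trials()]): columns
#'   `pid`, `category`, `ordinal_position`, `error` (0/1).
#' @param ladder logical: apply the reduction ladder on non-convergence.
#' @return a `csi_fit` object.
#' @export
fit_error_model <- function(table, ladder = TRUE) {
  stopifnot(nrow(table) > 0)
  if (is.null(table$error)) table$error <- as.integer(!table$correct)
  dat <- model_frame(table, response = "error")
  fit_with_ladder(response = "error", dat = dat,
                  family = stats::binomial(), apply_ladder = ladder)
}

#' Fit the log-transformed linear mixed model for reaction times
#'
#' Fallback analysis used where the gamma GLMM is impractical (notably in
#' refit-based power simulation): a linear mixed model on log RT with the
#' same fixed and random structure.  P-values use the Satterthwaite
#' approximation for the denominator degrees of freedom.
#'
#' @param table reaction-time analysis table.
#' @param ladder logical: apply the reduction ladder on non-convergence.
#' @return a `csi_fit` object.
#' @export
fit_log_lmm <- function(table, ladder = TRUE) {
  stopifnot(nrow(table) > 0, all(table$rt_ms > 0))
  dat <- model_frame(table, response = "rt_ms")
  dat$log_rt <- log(dat$rt_ms)
  fit_with_ladder(response = "log_rt", dat = dat, family = NULL,
                  apply_ladder = ladder)
}

model_frame <- function(table, response) {
  need <- c("pid", "category", "ordinal_position", response)
  need <- setdiff(need, "log_rt")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("analysis table missing columns: ",
                         paste(miss, collapse = ", "))
  dat <- data.frame(subject = factor(table$pid),
                    category = factor(table$category),
                    pos_c = table$ordinal_position -
                      mean(table$ordinal_position))
  dat[[response]] <- table[[response]]
  dat
}

# Random-structure ladder, most complex first.  Ladder steps on
# non-convergence: more iterations, then zero correlations, then drop the
# subject slope, then the category slope.
ladder_structures <- function() {
  list(
    list(label = "(pos | subject) + (pos | category)",
         rhs = "pos_c + (pos_c | subject) + (pos_c | category)",
         maxfun = 1e4),
    list(label = "(pos | subject) + (pos | category), 2e5 iterations",
         rhs = "pos_c + (pos_c | subject) + (pos_c | category)",
         maxfun = 2e5),
    list(label = "(pos || subject) + (pos || category)",
         rhs = "pos_c + (pos_c || subject) + (pos_c || category)",
         maxfun = 2e5),
    list(label = "(1 | subject) + (pos || category)",
         rhs = "pos_c + (1 | subject) + (pos_c || category)",
         maxfun = 2e5),
    list(label = "(1 | subject) + (1 | category)",
         rhs = "pos_c + (1 | subject) + (1 | category)",
         maxfun = 2e5)
  )
}

#' @rdname fit_error_model
#' @export
reduction_ladder <- function() {
  vapply(ladder_structures(), `[[`, character(1), "label")
}

fit_with_ladder <- function(response, dat, family, apply_ladder = TRUE,
                            backend = "lme4") {
  steps <- ladder_structures()
  if (!apply_ladder) steps <- steps[1L]
  trace <- character(0)
  last_fit <- NULL
  for (st in steps) {
    fml <- stats::as.formula(paste(response, "~", st$rhs))
    fit <- try_mixed_fit(fml, dat, family, st$maxfun, backend)
    trace <- c(trace, paste0(st$label, ": ",
                             if (fit$converged) "converged" else
                               paste("failed -", fit$note)))
    last_fit <- fit
    if (fit$converged) break
  }
  as_csi_fit(last_fit, family, trace)
}

try_mixed_fit <- function(formula, dat, family, maxfun,
                          backend = "lme4") {
  is_glmm <- !is.null(family)
  warn <- character(0)
  res <- withCallingHandlers(
    tryCatch({
      if (is_glmm && backend == "glmmTMB") {
        # start fixed effects at the marginal mean so the identity-link
        # linear predictor is positive at the first likelihood evaluation
        y <- dat[[all.vars(formula)[1L]]]
        start <- if (family$link == "identity")
          list(beta = c(mean(y), 0)) else NULL
        # the autodiff optimizer needs orders of magnitude fewer
        # iterations than derivative-free bobyqa; a tight cap makes
        # degenerate fits fail fast and fall down the ladder
        cap <- min(maxfun, 2000)
        glmmTMB::glmmTMB(formula, data = dat, family = family,
                         start = start,
                         control = glmmTMB::glmmTMBControl(
                           optCtrl = list(iter.max = cap,
                                          eval.max = cap)))
      } else if (is_glmm) {
        lme4::glmer(formula, data = dat, family = family,
                    control = lme4::glmerControl(
                      optimizer = "bobyqa",
                      optCtrl = list(maxfun = maxfun)))
      } else {
        lmerTest::lmer(formula, data = dat,
                       control = lme4::lmerControl(
                         optimizer = "bobyqa",
                         optCtrl = list(maxfun = maxfun)))
      }
    }, error = function(e) e),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) invokeRestart("muffleMessage"))
  if (inherits(res, "error")) {
    return(list(model = NULL, converged = FALSE,
                note = conditionMessage(res)))
  }
  if (inherits(res, "glmmTMB")) {
    opt_ok <- isTRUE(res$fit$convergence == 0)
    hess_ok <- isTRUE(res$sdr$pdHess)
    note <- if (!opt_ok) paste("glmmTMB optimizer:", res$fit$message)
    else if (!hess_ok) "glmmTMB: Hessian not positive definite (singular fit)"
    else ""
    return(list(model = res, converged = opt_ok && hess_ok, note = note))
  }
  conv_warn <- grepl("converge|Hessian|eigenvalue", warn,
                     ignore.case = TRUE)
  list(model = res, converged = !any(conv_warn),
       note = paste(warn[conv_warn], collapse = "; "))
}

as_csi_fit <- function(fit, family, trace) {
  if (is.null(fit$model)) {
    return(structure(list(fixed = NULL, family = family_label(family),
                          converged = FALSE, trace = trace, model = NULL,
                          random = NA_character_),
                     class = "csi_fit"))
  }
  # degenerate fits can warn while assembling the coefficient table
  co <- suppressWarnings(stats::coef(summary(fit$model)))
  if (inherits(fit$model, "glmmTMB")) co <- co$cond
  est <- co[, "Estimate"]
  se <- co[, "Std. Error"]
  is_lmm <- inherits(fit$model, "lmerModLmerTest")
  if (is_lmm) {
    stat <- co[, "t value"]
    p <- co[, "Pr(>|t|)"]        # Satterthwaite df
    stat_label <- "t (Satterthwaite p)"
  } else {
    stat <- est / se
    p <- 2 * stats::pnorm(-abs(stat))
    stat_label <- "Wald z"
  }
  fixed <- data.frame(term = rownames(co), estimate = est, se = se,
                      ci_ll = est - 1.96 * se, ci_ul = est + 1.96 * se,
                      statistic = stat, p = p,
                      row.names = NULL, stringsAsFactors = FALSE)
  bars <- lme4::findbars(stats::formula(fit$model))
  structure(list(fixed = fixed, family = family_label(family),
                 statistic = stat_label,
                 converged = fit$converged, trace = trace,
                 random = paste(vapply(bars, function(b)
                   paste0("(", deparse(b), ")"), character(1)),
                   collapse = " + "),
                 model = fit$model),
            class = "csi_fit")
}

family_label <- function(family) {
  if (is.null(family)) "gaussian (log RT, LMM)"
  else paste(family$family, family$link, sep = "-")
}

#' Print a fitted mixed-model result
#'
#' A `csi_fit` bundles the fixed-effect table (estimate, SE, 95% Wald CI,
#' test statistic, p-value), the family/link, the convergence flag, the
#' random-structure reduction trace, and the underlying `merMod` object.
#'
#' @param x a `csi_fit` object.
#' @param ... ignored.
#' @method print csi_fit
#' @export
print.csi_fit <- function(x, ...) {
  cat("Mixed model (", x$family, "), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  cat("Random structure:", x$random, "\n")
  if (!is.null(x$fixed)) {
    print(format(x$fixed, digits = 4), row.names = FALSE)
  }
  if (length(x$trace) > 1L) {
    cat("Reduction trace:\n")
    for (s in x$trace) cat("  -", s, "\n")
  }
  invisible(x)
}

#' Morey-adjusted within-subject summary by ordinal position
#'
#' Means and within-subject standard errors per ordinal position for
#' within-participant designs: each observation is normalized by
#' subtracting its subject's mean and adding the grand mean, the SE of
#' the normalized values is computed per position, and the variance is
#' corrected by the factor `K/(K-1)` where `K` is the number of positions
#' (so the SE is multiplied by `sqrt(K/(K-1))`).
#'
#' @param table data frame with columns `pid`, `ordinal_position`, and
#'   the measurement column `value_col`.
#' @param value_col name of the measurement column (default `"rt_ms"`).
#' @return data frame with columns `ordinal_position`, `n`, `mean`,
#'   `se_within`.
#' @export
within_subject_summary <- function(table, value_col = "rt_ms") {
  y <- table[[value_col]]
  subj <- as.character(table$pid)
  pos <- table$ordinal_position
  ok <- !is.na(y) & !is.na(pos)
  y <- y[ok]; subj <- subj[ok]; pos <- pos[ok]
  if (length(unique(subj)) < 2L)
    stop("within-subject SE undefined for a single subject")
  K <- length(unique(pos))
  if (K < 2L) stop("need at least two ordinal positions")
  subj_mean <- tapply(y, subj, mean)
  y_norm <- y - subj_mean[subj] + mean(y)
  morey <- sqrt(K / (K - 1))
  agg <- lapply(sort(unique(pos)), function(p) {
    v <- y_norm[pos == p]
    data.frame(ordinal_position = p, n = length(v),
               mean = mean(y[pos == p]),
               se_within = morey * stats::sd(v) / sqrt(length(v)))
  })
  do.call(rbind, agg)
}
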