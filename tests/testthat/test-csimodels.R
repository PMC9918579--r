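make_analysis_table <- function(n_total = 100, n_filler = 20, n_err = 10,
                                n_err_filler = 2, seed = 1) {
  set.seed(seed)
  is_filler <- c(rep(TRUE, n_filler), rep(FALSE, n_total - n_filler))
  correct <- rep(TRUE, n_total)
  correct[seq_len(n_err_filler)] <- FALSE                   # filler errors
  n_err_target <- n_err - n_err_filler
  if (n_err_target > 0) correct[n_filler + seq_len(n_err_target)] <- FALSE
  data.frame(pid = rep(c("a", "b"), length.out = n_total),
             trial = seq_len(n_total),
             category = rep(sprintf("c%d", 1:5), length.out = n_total),
             ordinal_position = ifelse(is_filler, NA,
                                       rep(1:5, length.out = n_total)),
             is_filler = is_filler,
             rt_ms = rgamma(n_total, 20, scale = 60),
             correct = correct, stringsAsFactors = FALSE)
}

test_that("trial exclusion satisfies the accounting identity", {
  tab <- make_analysis_table()
  res <- exclude_trials(tab)
  acc <- res$accounting
  expect_identical(acc$n_total, 100L)
  expect_identical(acc$n_filler, 20L)
  expect_identical(acc$n_erroneous, 10L)
  expect_identical(acc$n_erroneous_fillers, 2L)
  expect_identical(acc$n_retained, 72L)                 # 100 - 20 - 10 + 2
  expect_identical(nrow(res$rt_table), 72L)
  expect_identical(nrow(res$error_table), 80L)          # all non-fillers
  expect_identical(sum(res$error_table$error), 8L)

  # no fillers, no errors: everything is retained
  tab2 <- make_analysis_table(n_filler = 0, n_err = 0, n_err_filler = 0)
  expect_identical(exclude_trials(tab2)$accounting$n_retained, 100L)

  # the identity holds across random configurations
  set.seed(5)
  for (i in 1:20) {
    nf <- sample(0:30, 1)
    nef <- sample(0:min(nf, 5), 1)
    ne <- nef + sample(0:10, 1)
    t3 <- make_analysis_table(n_filler = nf, n_err = ne,
                              n_err_filler = nef, seed = i)
    a <- exclude_trials(t3)$accounting
    expect_identical(a$n_retained,
                     a$n_total - a$n_filler - a$n_erroneous +
                       a$n_erroneous_fillers)
  }
})

test_that("exclusion takes correctness from classifications and demands completeness", {
  ex <- simulate_experiment(n_subjects = 2, n_categories = 4, seed = 3)
  cl <- classify_entries(reconstruct_entries(ex$keylog, ex$trial_table),
                         ex$stimuli)
  res <- exclude_trials(ex$trial_table, cl)
  expect_identical(res$accounting$n_retained, nrow(res$rt_table))
  expect_error(exclude_trials(ex$trial_table, cl[-1, ]),
               "without classification")
})

test_that("a zero-slope model is recovered as a null effect", {
  rt0 <- rt_model_params(slope_ms_per_position = 0)
  tab <- simulate_trial_table(12, 8, rt = rt0, include_fillers = FALSE,
                              seed = 42)
  fit <- fit_rt_model(exclude_trials(tab)$rt_table)
  i <- which(fit$fixed$term == "pos_c")
  expect_lt(abs(fit$fixed$estimate[i]), 2.5 * fit$fixed$se[i])
  expect_identical(fit$family, "Gamma-identity")
  # Wald construction: CI = estimate +/- 1.96 SE, p from the normal
  expect_equal(fit$fixed$ci_ul - fit$fixed$estimate,
               1.96 * fit$fixed$se, tolerance = 1e-9)
  expect_equal(fit$fixed$p[i],
               2 * pnorm(-abs(fit$fixed$estimate[i] / fit$fixed$se[i])),
               tolerance = 1e-9)
})

test_that("gamma backends agree on the slope within cross-implementation tolerance", {
  tab <- simulate_trial_table(15, 12, include_fillers = FALSE, seed = 7)
  rt_tab <- exclude_trials(tab)$rt_table
  f_tmb <- fit_rt_model(rt_tab, backend = "glmmTMB")
  f_lme4 <- fit_rt_model(rt_tab, backend = "lme4")
  s_tmb <- f_tmb$fixed$estimate[f_tmb$fixed$term == "pos_c"]
  s_lme4 <- f_lme4$fixed$estimate[f_lme4$fixed$term == "pos_c"]
  expect_lt(abs(s_tmb - s_lme4) / abs(s_lme4), 0.01)
})

test_that("mean-centering leaves the slope invariant under position shifts", {
  tab <- simulate_trial_table(10, 8, include_fillers = FALSE, seed = 14)
  rt_tab <- exclude_trials(tab)$rt_table
  shifted <- rt_tab
  shifted$ordinal_position <- shifted$ordinal_position + 10
  f1 <- fit_rt_model(rt_tab)
  f2 <- fit_rt_model(shifted)
  expect_equal(f1$fixed$estimate[f1$fixed$term == "pos_c"],
               f2$fixed$estimate[f2$fixed$term == "pos_c"],
               tolerance = 1e-6)
})

test_that("the binomial error model recovers the generating log-odds slope", {
  tab <- simulate_trial_table(30, 24, include_fillers = FALSE, seed = 8)
  err_tab <- exclude_trials(tab)$error_table
  fit <- fit_error_model(err_tab)
  expect_true(length(fit$trace) >= 1)
  i <- which(fit$fixed$term == "pos_c")
  expect_lt(abs(fit$fixed$estimate[i] - 0.15), 2 * fit$fixed$se[i])
  expect_identical(fit$family, "binomial-logit")
})

test_that("the reduction ladder is recorded and ends in a usable structure", {
  expect_identical(length(reduction_ladder()), 5L)
  # near-degenerate data (tiny, quasi-separable) exercises the ladder
  set.seed(3)
  tab <- data.frame(pid = rep(c("a", "b", "c"), each = 10),
                    category = rep(sprintf("c%d", 1:5), 6),
                    ordinal_position = rep(1:5, 6),
                    error = as.integer(rep(1:5, 6) == 5))
  fit <- fit_error_model(tab)
  expect_s3_class(fit, "csi_fit")
  expect_true(length(fit$trace) >= 1)
})

test_that("the log-linear mixed model recovers an exact log-normal process", {
  set.seed(99)
  ns <- 12; nc <- 8
  u0s <- rnorm(ns, 0, 0.1); u0c <- rnorm(nc, 0, 0.05)
  d <- expand.grid(s = 1:ns, c = 1:nc, pos = 1:5)
  pos_c <- d$pos - 3
  log_mu <- 7 + 0.03 * pos_c + u0s[d$s] + u0c[d$c]
  tab <- data.frame(pid = sprintf("s%02d", d$s),
                    category = sprintf("c%02d", d$c),
                    ordinal_position = d$pos,
                    rt_ms = exp(log_mu + rnorm(nrow(d), 0, 0.15)))
  fit <- fit_log_lmm(tab)
  i <- which(fit$fixed$term == "pos_c")
  expect_lt(abs(fit$fixed$estimate[i] - 0.03), 2 * fit$fixed$se[i])
  expect_identical(fit$statistic, "t (Satterthwaite p)")
  # the typed-naming effect is ~0.03 on the log scale: same magnitude
  expect_lt(abs(fit$fixed$estimate[i]), 0.1)
})

test_that("constant reaction times are flagged rather than reported as a fit", {
  tab <- data.frame(pid = rep(c("a", "b"), each = 10),
                    category = rep(sprintf("c%d", 1:5), 4),
                    ordinal_position = rep(1:5, 4),
                    rt_ms = 1000)
  fit <- fit_log_lmm(tab)
  expect_s3_class(fit, "csi_fit")
  expect_true(!fit$converged || all(abs(fit$fixed$estimate[-1]) < 1e-8))
})

test_that("Morey-adjusted within-subject summaries match the direct formula", {
  # two subjects with identical profiles shifted by a constant
  tab <- data.frame(pid = rep(c("a", "b"), each = 5),
                    ordinal_position = rep(1:5, 2),
                    rt_ms = c(10, 20, 30, 40, 50,
                              110, 120, 130, 140, 150))
  s <- within_subject_summary(tab)
  expect_equal(s$se_within, rep(0, 5))
  expect_equal(s$mean, c(60, 70, 80, 90, 100))

  # hand-computed 2x2 example, evaluated independently inline
  tab2 <- data.frame(pid = c("a", "a", "b", "b"),
                     ordinal_position = c(1, 2, 1, 2),
                     rt_ms = c(10, 20, 30, 36))
  s2 <- within_subject_summary(tab2)
  grand <- mean(tab2$rt_ms)
  norm <- tab2$rt_ms - rep(tapply(tab2$rt_ms, tab2$pid, mean),
                           each = 2) + grand
  for (p in 1:2) {
    v <- norm[tab2$ordinal_position == p]
    expect_equal(s2$se_within[s2$ordinal_position == p],
                 sqrt(2 / 1) * sd(v) / sqrt(2), tolerance = 1e-12)
    expect_equal(s2$mean[s2$ordinal_position == p],
                 mean(tab2$rt_ms[tab2$ordinal_position == p]))
  }

  # balanced data: normalized means equal raw condition means
  tab3 <- simulate_trial_table(6, 4, include_fillers = FALSE, seed = 2)
  s3 <- within_subject_summary(tab3)
  raw <- tapply(tab3$rt_ms, tab3$ordinal_position, mean)
  expect_equal(s3$mean, as.vector(raw), tolerance = 1e-9)

  expect_error(within_subject_summary(tab[tab$pid == "a", ]),
               "single subject")
})
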