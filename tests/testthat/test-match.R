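test_that("Jaro distance reproduces hand-derived worked values", {
  # KESSEL vs KELLE: m = 4 (K,E,E,L), one transposition pair ->
  # 1 - (4/6 + 4/5 + 3.5/4)/3 ... computed from the definition by hand:
  # sim = (4/6 + 4/5 + (4 - 1)/4)/3 = 0.7388889
  expect_equal(jaro_distance("KESSEL", "KELLE"), 1 - (4/6 + 4/5 + 3/4) / 3,
               tolerance = 1e-12)
  expect_equal(jaro_distance("KESSEL", "KELLE"), 0.2611111, tolerance = 1e-6)
  # GESCHIRR is a strict prefix: m = 8, t = 0
  expect_equal(jaro_distance("GESCHIRR", "GESCHIRRSPÜLER"),
               1 - (8/8 + 8/14 + 1) / 3, tolerance = 1e-12)
  expect_equal(jaro_distance("GESCHIRR", "GESCHIRRSPÜLER"), 0.1428571,
               tolerance = 1e-6)
  expect_identical(jaro_distance("SCHLOSS", "SCHLOSS"), 0)
  expect_identical(jaro_distance("ABC", "XYZ"), 1)
  expect_identical(jaro_distance("", ""), 0)
  expect_identical(jaro_distance("A", ""), 1)
})

test_that("normalized edit distances match brute-force dynamic programs", {
  expect_identical(levenshtein_norm("AB", "AB"), 0)
  expect_identical(levenshtein_norm("AB", "BA"), 1)   # two substitutions
  expect_identical(osa_norm("AB", "BA"), 0.5)         # one transposition
  expect_identical(levenshtein_norm("A", ""), 1)
  expect_identical(osa_norm("", ""), 0)
  set.seed(421)
  for (i in 1:200) {
    p <- random_string_pair()
    expect_equal(levenshtein_norm(p[1], p[2]),
                 oracle_levenshtein(p[1], p[2]), tolerance = 1e-12)
    expect_equal(osa_norm(p[1], p[2]), oracle_osa(p[1], p[2]),
                 tolerance = 1e-12)
  }
})

test_that("distances are symmetric, bounded, zero on identity, and ordered", {
  set.seed(99)
  for (i in 1:200) {
    p <- random_string_pair()
    for (f in list(jaro_distance, levenshtein_norm, osa_norm)) {
      d <- f(p[1], p[2])
      expect_gte(d, 0)
      expect_lte(d, 1)
      expect_equal(d, f(p[2], p[1]), tolerance = 1e-12)
      expect_identical(f(p[1], p[1]), 0)
    }
    # OSA allows a superset of edit operations, so it can never cost more
    expect_gte(levenshtein_norm(p[1], p[2]), osa_norm(p[1], p[2]))
  }
})

test_that("Levenshtein agrees with the independent base-R edit distance", {
  set.seed(77)
  a <- replicate(300, random_string_pair()[1])
  b <- replicate(300, random_string_pair()[2])
  lmax <- pmax(nchar(a), nchar(b))
  ref <- mapply(function(x, y) utils::adist(x, y), a, b) / pmax(lmax, 1)
  ref[lmax == 0] <- 0
  expect_equal(levenshtein_norm(a, b), unname(ref), tolerance = 1e-12)
})

test_that("best match prefers a strictly closer alternative sharing the first letter", {
  cfg <- match_config()
  bm <- best_match("BURG", "SCHLOSS", "BURG", cfg)
  expect_identical(bm$target, "BURG")
  expect_identical(bm$d, 0)
  expect_identical(bm$kind, "alternative")
  bm <- best_match("SCHLOSS", "SCHLOSS", "BURG", cfg)
  expect_identical(bm$target, "SCHLOSS")
  expect_identical(bm$d, 0)
  bm <- best_match("KESSEL", "KELLE", character(), cfg)
  expect_identical(bm$target, "KELLE")
  expect_equal(bm$d, 0.2611111, tolerance = 1e-6)
  # ties resolve to the picture name (strict inequality is required)
  bm <- best_match("HAUS", "MAUS", "HAUS2", cfg)
  # HAUS vs MAUS: one substitution; HAUS2 shares the first letter but a
  # tie or worse never displaces the picture name
  expect_true(bm$kind == "picture_name" || bm$d < jaro_distance("HAUS", "MAUS"))
  bm <- best_match("ABCD", "ABCX", "ABCY", cfg)  # equal distances
  expect_identical(bm$target, "ABCX")
  expect_identical(bm$kind, "picture_name")
})

test_that("classification reproduces the worked response examples", {
  st <- worked_stimuli()
  schloss <- st[st$item_id == "schloss", ]
  feile <- st[st$item_id == "feile", ]
  kelle <- st[st$item_id == "kelle", ]
  spueler <- st[st$item_id == "spueler", ]
  tisch <- st[st$item_id == "tisch", ]

  # backspace-corrected alternative changing the first character:
  # BUR<bs><bs><bs><bs>SCHLOSS starts raw with B but corrected with S
  cl <- classify_keys(c("B", "U", "R", rep("BACKSPACE", 4), chars("SCHLOSS")),
                      schloss)
  expect_identical(cl$status, "incorrect")

  # PFEILE instead of FEILE: phonologically similar onset, wrong first key
  cl <- classify_keys(chars("PFEILE"), feile)
  expect_identical(cl$status, "incorrect")
  expect_identical(cl$subtype, "first_letter_error")

  # KESSEL instead of KELLE: orthographically similar, below threshold
  cl <- classify_keys(chars("KESSEL"), kelle)
  expect_identical(cl$status, "correct")
  expect_identical(cl$subtype, "below_threshold")
  expect_identical(cl$target_kind, "picture_name")

  # GESCHIRR for GESCHIRRSPÜLER: partial name, below threshold
  cl <- classify_keys(chars("GESCHIRR"), spueler)
  expect_identical(cl$status, "correct")
  expect_equal(cl$d, 0.1428571, tolerance = 1e-6)

  # exact entry, no backspaces
  cl <- classify_keys(chars("TISCH"), tisch)
  expect_identical(cl$status, "correct")
  expect_identical(cl$subtype, "identical")
  expect_identical(cl$d, 0)

  # backspace-corrected to the exact name
  cl <- classify_keys(c("T", "I", "X", "BACKSPACE", chars("SCH")), tisch)
  expect_identical(cl$status, "correct")
  expect_identical(cl$subtype, "corrected")

  # special-key and shift starts
  cl <- classify_keys(c("SPACE", chars("TISCH")), tisch)
  expect_identical(cl$subtype, "special_key_start")
  cl <- classify_keys(c("SHIFT", chars("TISCH")), tisch)
  expect_identical(cl$subtype, "shift_start")

  # no keystrokes at all
  cl <- classify_entry(reconstruct_entry(make_trial_events(character())),
                       tisch)
  expect_identical(cl$subtype, "na")

  # distance exceeded with a correct first letter
  cl <- classify_keys(chars("TUVWXYZ"), tisch)
  expect_identical(cl$subtype, "distance_exceeded")

  # both failures at once
  cl <- classify_keys(chars("XXXXX"), tisch)
  expect_identical(cl$subtype, "combined")
})

test_that("classification is total, exclusive, and monotone in the threshold", {
  set.seed(2024)
  ex <- simulate_experiment(n_subjects = 2, n_categories = 6,
                            config = design_config(), seed = 2024)
  entries <- reconstruct_entries(ex$keylog, ex$trial_table)
  lo <- classify_entries(entries, ex$stimuli, match_config(threshold = 0.15))
  hi <- classify_entries(entries, ex$stimuli, match_config(threshold = 0.45))
  for (cl in list(lo, hi)) {
    expect_true(all(cl$status %in% c("correct", "incorrect")))
    expect_identical(nrow(cl), nrow(entries))
    smry <- classification_summary(cl)
    expect_identical(smry$n_correct + smry$n_incorrect, smry$n_total)
    expect_identical(sum(smry$correct$n), smry$n_correct)
    expect_identical(sum(smry$incorrect$n), smry$n_incorrect)
  }
  # raising the threshold never turns a correct trial incorrect
  expect_true(all(!(lo$status == "correct" & hi$status == "incorrect")))
})

test_that("classifier recovers planted ground truth", {
  # defaults: realistic typo/backspace/alternative behaviour
  ex <- simulate_experiment(n_subjects = 4, n_categories = 12, seed = 55)
  entries <- reconstruct_entries(ex$keylog, ex$trial_table)
  cl <- classify_entries(entries, ex$stimuli)
  key <- paste(cl$pid, cl$trial)
  tr <- ex$truth[match(key, paste(ex$truth$pid, ex$truth$trial)), ]
  expect_gte(mean((cl$status == "correct") ==
                    (tr$true_status == "correct")), 0.99)
  # clean-typing regime: everything must come back correct/identical
  clean <- typing_behavior_params(p_typo = 0, p_alternative_name = 0,
                                  p_special_start = 0, p_shift_start = 0,
                                  p_null_response = 0,
                                  p_first_letter_typo = 0, p_combined = 0)
  ex2 <- simulate_experiment(n_subjects = 2, n_categories = 6,
                             err = error_model_params(-30, 0),
                             behavior = clean, seed = 77)
  cl2 <- classify_entries(reconstruct_entries(ex2$keylog, ex2$trial_table),
                          ex2$stimuli)
  expect_true(all(cl2$status == "correct"))
  expect_true(all(cl2$subtype == "identical"))
})

test_that("classifying entries with unknown items fails loudly", {
  st <- worked_stimuli()
  ent <- reconstruct_entries(make_trial_events(chars("TISCH"),
                                               item_id = "nosuch"))
  expect_error(classify_entries(ent, st), "nosuch")
})
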