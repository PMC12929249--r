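test_that("bin_age maps the printed boundaries and rejects minors", {
  expect_equal(as.character(bin_age(c(25, 26, 35, 36, 45, 46, 55, 56))),
               c("<=25", "26-35", "26-35", "36-45", "36-45", "46-55", "46-55", ">55"))
  expect_equal(as.character(bin_age(18)), "<=25")
  expect_equal(as.character(bin_age(90)), ">55")
  expect_error(bin_age(17), "18")
  expect_error(bin_age(NA_integer_), "missing")
})

test_that("diagnosis_flags unions encounter and problem-list codes", {
  map <- c(I10 = "hypertension", E11 = "diabetes", F32 = "mood")
  f <- diagnosis_flags("I10", character(0), map)
  expect_equal(f, c(diabetes = 0L, hypertension = 1L, mood = 0L))
  expect_equal(sum(diagnosis_flags(character(0), character(0), map)), 0L)
  # code only on the problem list still counts
  f2 <- diagnosis_flags(character(0), "E11", map)
  expect_equal(f2[["diabetes"]], 1L)
  expect_warning(diagnosis_flags("Z99", character(0), map), "unmapped")
})

test_that("lab_flags flags positives for tracked tests only", {
  rec <- data.frame(test = c("syphilis", "chlamydia", "hba1c"),
                    result = c("Positive", "negative", "positive"))
  f <- suppressWarnings(lab_flags(rec))
  expect_equal(f[["lab_syphilis"]], 1L)
  expect_equal(f[["lab_chlamydia"]], 0L)
  expect_equal(sum(f), 1L)
  expect_warning(lab_flags(rec), "unknown lab tests")
  expect_equal(sum(lab_flags(data.frame(test = "syphilis", result = "negative"))), 0L)
})

test_that("retention_history follows first-visit precedence then the 365-day gap", {
  o <- as.Date("2017-01-01")
  expect_equal(as.character(retention_history(o + c(0, 100, 200), o + 200)),
               "retained_prev_year")
  expect_equal(as.character(retention_history(o + c(0, 400), o + 400)),
               "prev_visit_was_first")
  expect_equal(as.character(retention_history(o + c(0, 100, 500), o + 500)),
               "ltfu_prev_year")
  expect_equal(as.character(retention_history(o, o)), "prev_visit_was_first")
  # gap of exactly 365 days is retained (LTFU needs > 365)
  expect_equal(as.character(retention_history(o + c(0, 10, 375), o + 375)),
               "retained_prev_year")
  # unsorted input is sorted; duplicate same-day visits collapse
  expect_equal(as.character(retention_history(o + c(200, 0, 100, 100), o + 200)),
               "retained_prev_year")
  expect_error(retention_history(o + c(0, 10), o + 5), "not among")
})

test_that("build_feature_matrix assembles the declared columns with no missing cells", {
  cfg <- small_config(n_patients = 30L, seed = 8L)
  coh <- generate_cohort(cfg)
  flags <- annotate_corpus(coh$notes, cfg$lexicon)
  fm <- build_feature_matrix(coh$visits, flags)
  expect_s3_class(fm, "feature_matrix")
  expect_equal(nrow(fm), nrow(coh$visits))
  expect_true(all(c("visit_id", "age_bin", "retention_history",
                    "dx_a", "dx_b", "lab_x", "pregnancy", "mental_illness") %in% names(fm)))
  expect_false(anyNA(as.data.frame(fm)))
  lv <- attr(fm, "levels")
  expect_equal(lv$age_bin, age_bin_levels())
  expect_equal(lv$retention_history, retention_levels())
  # retention-history shares over the cohort sum to 1
  expect_equal(sum(prop.table(table(fm$retention_history))), 1)
})

test_that("feature construction is invariant to input row order", {
  cfg <- small_config(n_patients = 20L, seed = 4L)
  coh <- generate_cohort(cfg)
  flags <- annotate_corpus(coh$notes, cfg$lexicon)
  fm1 <- build_feature_matrix(coh$visits, flags)
  set.seed(1)
  perm <- sample(nrow(coh$visits))
  fm2 <- build_feature_matrix(coh$visits[perm, ], flags[sample(nrow(flags)), ])
  df1 <- as.data.frame(fm1); df2 <- as.data.frame(fm2)
  df2 <- df2[match(df1$visit_id, df2$visit_id), ]
  rownames(df1) <- rownames(df2) <- NULL
  expect_identical(df1, df2)
})

test_that("build_feature_matrix errors on id mismatches and missing demographics", {
  cfg <- small_config(n_patients = 10L, seed = 2L)
  coh <- generate_cohort(cfg)
  flags <- annotate_corpus(coh$notes, cfg$lexicon)
  expect_error(build_feature_matrix(coh$visits, flags[-1, ]),
               "visit/topic mismatch")
  v2 <- coh$visits; v2$age_years[1] <- NA
  expect_error(build_feature_matrix(v2, flags), "age_years")
})

test_that("per-class indicator means match item_probs within sampling tolerance", {
  cfg <- small_config(n_patients = 600L, seed = 10L)
  coh <- generate_cohort(cfg)
  flags <- annotate_corpus(coh$notes, cfg$lexicon)
  fm <- build_feature_matrix(coh$visits, flags)
  cls <- coh$truth$true_class[match(fm$visit_id, coh$truth$visit_id)]
  for (item in c("dx_a", "dx_b")) {
    for (cl in 1:2) {
      p <- cfg$item_probs[item, cl]
      n_c <- sum(cls == cl)
      expect_lt(abs(mean(fm[[item]][cls == cl]) - p),
                3 * sqrt(p * (1 - p) / n_c) + 1e-9)
    }
  }
  # topic columns: observed prevalence targets p * (1 - negation_rate)
  for (item in cfg$topics) {
    for (cl in 1:2) {
      p <- cfg$item_probs[item, cl] * (1 - cfg$negation_rate)
      n_c <- sum(cls == cl)
      expect_lt(abs(mean(fm[[item]][cls == cl]) - p),
                4 * sqrt(max(p * (1 - p), 0.01) / n_c))
    }
  }
})

test_that("feature matrix CSV round-trip is lossless", {
  cfg <- small_config(n_patients = 15L, seed = 6L)
  coh <- generate_cohort(cfg)
  fm <- build_feature_matrix(coh$visits, annotate_corpus(coh$notes, cfg$lexicon))
  path <- file.path(tempdir(), "fm.csv")
  write_feature_matrix(fm, path)
  fm2 <- read_feature_matrix(path)
  df1 <- as.data.frame(fm); df2 <- as.data.frame(fm2)
  rownames(df1) <- rownames(df2) <- NULL
  expect_equal(df1, df2)
  expect_equal(attr(fm2, "levels")[names(attr(fm, "levels"))], attr(fm, "levels"))
  # integer coding for the LCA engine
  m <- lca_data(fm2)
  expect_equal(unname(attr(m, "item_levels")[1:2]), c(5L, 3L))
  expect_true(all(m >= 1L))
})
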