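test_that("odds_ratio reproduces printed estimates and enforces preconditions", {
  # class 4 LTFU vs class 1 from the packaged count fixture
  r <- odds_ratio(86, 425, 111, 763)
  expect_equal(round(r$or_point, 2), 1.39)
  expect_equal(r$ci_low, 1.02, tolerance = 0.01)
  expect_equal(r$ci_high, 1.89, tolerance = 0.01)
  # class 2 LTFU: counts give 1.5637 (the source prints 1.57; documented mismatch)
  expect_equal(odds_ratio(149, 655, 111, 763)$or_point, 1.5637, tolerance = 1e-4)
  expect_equal(odds_ratio(10, 20, 10, 20)$or_point, 1)
  expect_error(odds_ratio(0, 5, 3, 4), "zero cell")
  expect_message(r0 <- odds_ratio(0, 5, 3, 4, haldane = TRUE), "Haldane")
  expect_gt(r0$or_point, 0)
  expect_error(odds_ratio(-1, 2, 3, 4), "non-negative")
  expect_error(odds_ratio(1.5, 2, 3, 4), "integers")
})

test_that("odds_ratio satisfies reciprocity and matches the logistic MLE", {
  set.seed(14)
  for (rep in 1:25) {
    tab <- sample(5:80, 4)
    r1 <- odds_ratio(tab[1], tab[2], tab[3], tab[4])
    r2 <- odds_ratio(tab[3], tab[4], tab[1], tab[2])
    expect_equal(r1$or_point * r2$or_point, 1, tolerance = 1e-12)
    # independent iterative fit: glm on the expanded 2x2 data
    y <- c(rep(1, tab[1]), rep(0, tab[2]), rep(1, tab[3]), rep(0, tab[4]))
    g <- rep(c(1, 0), c(tab[1] + tab[2], tab[3] + tab[4]))
    fit <- stats::glm(y ~ g, family = stats::binomial())
    expect_equal(r1$or_point, unname(exp(stats::coef(fit)["g"])), tolerance = 1e-6)
  }
})

test_that("chi_squared matches direct formula, oracle and stats::chisq.test", {
  r <- chi_squared(rbind(c(10, 20), c(20, 10)))
  expect_equal(r$statistic, 6.6667, tolerance = 1e-4)
  expect_equal(r$df, 1L)
  # table equal to its expected counts
  expect_equal(chi_squared(rbind(c(10, 10), c(20, 20)))$statistic, 0)
  # df formula for a 6x2 table
  expect_equal(chi_squared(matrix(5, 6, 2))$df, 5L)
  set.seed(6)
  for (rep in 1:25) {
    tab <- matrix(sample(1:40, 12, TRUE), sample(2:4, 1))
    mine <- chi_squared(tab)
    # brute-force expected counts
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(mine$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
  expect_error(chi_squared(rbind(c(0, 0), c(1, 2))), "zero margin")
  expect_error(chi_squared(matrix(1, 1, 2)), "2x2")
})

test_that("kruskal_wallis matches a hand-ranked oracle and stats::kruskal.test", {
  # groups {1,2,3} vs {4,5,6}: ranks 1..6, H = 12/(6*7)*(3*(2-3.5)^2+3*(5-3.5)^2)
  r <- kruskal_wallis(list(1:3, 4:6))
  expect_equal(r$H, 12 / 42 * (3 * 2.25 + 3 * 2.25), tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$H, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$p_value, 1)
  set.seed(9)
  for (rep in 1:20) {
    gs <- lapply(seq_len(sample(2:4, 1)), function(i)
      sample(1:8, sample(3:10, 1), replace = TRUE))  # heavy ties
    mine <- kruskal_wallis(gs)
    ref <- stats::kruskal.test(gs)
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    # permutation symmetry
    expect_equal(kruskal_wallis(rev(gs))$H, mine$H, tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("outcome_table builds Table-4-style reports", {
  asg <- data.frame(visit_id = sprintf("V%03d", 1:100),
                    class = rep(1:2, each = 50))
  oc <- data.frame(visit_id = sprintf("V%03d", 1:100),
                   ltfu_primary = c(rep(c(1, 0), c(10, 40)), rep(c(1, 0), c(20, 30))),
                   ltfu_primary_evaluable = 1L)
  tab <- outcome_table(asg, oc, "ltfu_primary", reference = 1)
  expect_equal(tab$n, c(50L, 50L))
  expect_equal(tab$percent, c(20, 40))
  expect_true(is.na(tab$or[1]))
  expect_equal(tab$or[2], odds_ratio(20, 30, 10, 40)$or_point)
  # identical rates across classes give OR 1
  oc$ltfu_primary <- rep(rep(c(1, 0), c(10, 40)), 2)
  expect_equal(outcome_table(asg, oc, "ltfu_primary")$or[2], 1)
  expect_error(outcome_table(asg, oc, "ltfu_primary", reference = 9),
               "reference class")
  expect_error(outcome_table(asg, oc, "nope"), "unknown outcome")
  # non-evaluable visits drop from denominators by default
  oc$ltfu_primary_evaluable <- rep(c(0L, 1L), 50)
  expect_equal(sum(outcome_table(asg, oc, "ltfu_primary")$n), 50L)
  expect_equal(sum(outcome_table(asg, oc, "ltfu_primary", evaluable_only = FALSE)$n), 100L)
})

test_that("profile_table flags distinct class profiles at P < 0.001", {
  cfg <- small_config(n_patients = 500L, seed = 33L)
  coh <- generate_cohort(cfg)
  fm <- build_feature_matrix(coh$visits, annotate_corpus(coh$notes, cfg$lexicon))
  asg <- data.frame(visit_id = coh$truth$visit_id, class = coh$truth$true_class)
  pt <- profile_table(fm, asg)
  row_for <- function(v) pt[pt$variable == v, ][1, ]
  expect_true(row_for("dx_a")$significant)       # 0.8 vs 0.1 across classes
  expect_false(row_for("lab_x")$significant)     # identical prevalence
  # single-class assignment: per-class column equals overall
  asg1 <- transform(asg, class = 1L)
  pt1 <- profile_table(fm, asg1)
  expect_identical(pt1$overall, pt1$class_1)
  # binary rows report the "1" level; categorical rows cover all levels
  expect_equal(sum(pt$variable == "age_bin"), 5L)
  expect_equal(sum(pt$variable == "dx_a"), 1L)
  md <- render_markdown(pt)
  expect_true(startsWith(md[1], "|"))
})
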