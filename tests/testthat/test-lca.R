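# 2-item binary model used by the hand-computed oracle cases
two_item_model <- function(p1 = 0.9, p2 = 0.1) {
  th <- function(p) rbind(1 - p, p)
  lca_model(c(0.5, 0.5), list(cbind(th(p1), th(p2)), cbind(th(p1), th(p2))), c(2L, 2L))
}

test_that("e_step matches hand-computed responsibilities and degenerate cases", {
  m <- two_item_model()
  d <- matrix(c(2L, 2L), 1, 2)  # observation (1,1) coded as level 2
  es <- e_step(m, d)
  expect_equal(es$resp[1, ], c(0.81, 0.01) / 0.82, tolerance = 1e-12)
  expect_equal(es$logLik, log(0.5 * 0.81 + 0.5 * 0.01), tolerance = 1e-12)
  # C = 1: responsibilities exactly 1
  m1 <- lca_model(1, list(rbind(0.3, 0.7)), 2L)
  expect_equal(e_step(m1, matrix(1L, 5, 1))$resp, matrix(1, 5, 1))
  # identical theta, pi = (0.5, 0.5): all responsibilities are 0.5
  sym <- lca_model(c(0.5, 0.5), list(cbind(rbind(0.4, 0.6), rbind(0.4, 0.6))), 2L)
  expect_true(all(abs(e_step(sym, matrix(c(1L, 2L), 4, 1))$resp - 0.5) < 1e-12))
  expect_error(e_step(m, matrix(3L, 1, 2)), "outside declared set")
})

test_that("responsibility rows always sum to 1", {
  set.seed(31)
  d <- matrix(sample(1:2, 200, TRUE), 50, 4)
  m <- m_step(matrix(stats::rgamma(150, 1), 50, 3) |> (\(r) r / rowSums(r))(),
              d, rep(2L, 4))
  es <- e_step(m, d)
  expect_true(all(abs(rowSums(es$resp) - 1) < 1e-9))
})

test_that("m_step recovers subgroup frequencies from hard and uniform responsibilities", {
  d <- matrix(c(1L, 1L, 2L, 2L, 1L, 2L, 1L, 2L), 4, 2)
  hard <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  m <- m_step(hard, d, c(2L, 2L))
  expect_equal(m$pi, c(0.5, 0.5))
  expect_equal(m$theta[[1]][2, ], c(0, 1), tolerance = 1e-5)  # clipped near 0/1
  expect_equal(m$theta[[2]][2, 1], 0.5, tolerance = 1e-9)
  # uniform responsibilities: every class equals the pooled frequencies
  unif <- matrix(0.5, 4, 2)
  mu <- m_step(unif, d, c(2L, 2L))
  expect_equal(mu$theta[[1]][2, 1], mu$theta[[1]][2, 2])
  expect_equal(mu$theta[[1]][2, 1], 0.5, tolerance = 1e-9)
  expect_error(m_step(rbind(c(1, 0), c(1, 0)), d[1:2, ], c(2L, 2L)),
               "degenerate class")
  # single observation, C = 1: clipped mass on the observed level
  m1 <- m_step(matrix(1, 1, 1), matrix(2L, 1, 1), 2L)
  expect_gt(m1$theta[[1]][2, 1], 1 - 2e-6)
})

test_that("C = 1 log-likelihood equals the independent-marginals closed form", {
  set.seed(41)
  d <- cbind(sample(1:2, 300, TRUE, prob = c(0.3, 0.7)),
             sample(1:3, 300, TRUE, prob = c(0.2, 0.3, 0.5)))
  attr(d, "item_levels") <- c(2L, 3L)
  fit <- fit_lca(d, 1L)
  closed <- sum(vapply(1:2, function(j) {
    tab <- table(factor(d[, j], levels = seq_len(c(2, 3)[j])))
    sum(tab * log(tab / nrow(d)))
  }, 0))
  expect_equal(fit$stats$logLik, closed, tolerance = 1e-6)
})

test_that("EM log-likelihood trace is monotone non-decreasing", {
  for (seed in c(3L, 19L)) {
    b <- gen_binary_lca(400, cbind(rep(0.8, 6), rep(0.2, 6)), c(0.5, 0.5), seed)
    fit <- fit_lca(b$data, 2L, n_restarts = 5, seed = seed)
    expect_true(all(diff(fit$trace) >= -1e-8))
    expect_true(fit$converged)
  }
})

test_that("fit_lca is reproducible, orders classes by prevalence, validates n >= C", {
  b <- gen_binary_lca(200, cbind(rep(0.9, 5), rep(0.1, 5)), c(0.7, 0.3), 55L)
  f1 <- fit_lca(b$data, 2L, n_restarts = 5, seed = 9L)
  f2 <- fit_lca(b$data, 2L, n_restarts = 5, seed = 9L)
  expect_identical(f1$model, f2$model)
  expect_true(all(diff(f1$model$pi) <= 0))
  expect_error(fit_lca(b$data[1:3, ], 4L), "observations")
})

test_that("fit_statistics implements the four criteria and the parameter count", {
  fs <- fit_statistics(-1000, C = 2L, item_levels = rep(2L, 9), n = 100)
  expect_equal(fs$k, 1 + 2 * 9)
  # printed-formula case: k = 10 via one 5-level + 6 binary items at C = 1
  fs10 <- fit_statistics(-1000, C = 1L, item_levels = c(5L, rep(2L, 6)), n = 100)
  expect_equal(fs10$k, 10)
  expect_equal(fs10$AIC, 2020)
  expect_equal(fs10$BIC, 2046.0517, tolerance = 1e-3)
  expect_equal(fs10$SABIC, 2014.4692, tolerance = 1e-3)
  expect_equal(fs10$CAIC, 2056.0517, tolerance = 1e-3)
  expect_equal(fit_statistics(0, 1L, rep(2L, 40), 10)$k, 40)
  expect_equal(fit_statistics(0, 6L, c(rep(2L, 40), 5L), 10)$k, 269)
})

test_that("assign_classes takes the max posterior with low-index ties", {
  m <- two_item_model()
  d <- rbind(c(2L, 2L), c(1L, 1L))
  a <- assign_classes(m, d)
  expect_equal(a$class, c(1L, 2L))
  expect_equal(dim(a$posterior), c(2L, 2L))
  # exact tie: symmetric model, ambiguous observation -> class 1
  sym <- lca_model(c(0.5, 0.5),
                   list(cbind(rbind(0.9, 0.1), rbind(0.1, 0.9)),
                        cbind(rbind(0.1, 0.9), rbind(0.9, 0.1))), c(2L, 2L))
  expect_equal(assign_classes(sym, matrix(c(1L, 1L), 1))$class, 1L)
})

test_that("align_classes finds the exact optimal permutation", {
  b <- gen_binary_lca(300, cbind(rep(0.9, 4), rep(0.5, 4), rep(0.1, 4)), rep(1, 3) / 3, 61L)
  fit <- fit_lca(b$data, 3L, n_restarts = 5, seed = 3L)
  m <- fit$model
  expect_equal(align_classes(m, m), 1:3)
  swap <- lca_model(m$pi[c(2, 1, 3)],
                    lapply(m$theta, function(th) th[, c(2, 1, 3)]), m$item_levels)
  expect_equal(align_classes(m, swap), c(2L, 1L, 3L))
  # brute-force check over all 24 permutations of random 4-class pairs
  perms4 <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms4 <- perms4[apply(perms4, 1, function(p) length(unique(p)) == 4L), ]
  set.seed(8)
  for (rep in 1:10) {
    mk <- function() {
      th <- lapply(1:3, function(j) {
        x <- matrix(stats::runif(8), 2, 4); sweep(x, 2, colSums(x), "/")
      })
      lca_model(rep(0.25, 4), th, rep(2L, 3))
    }
    a <- mk(); b2 <- mk()
    costs <- apply(perms4, 1, function(p)
      sum(vapply(1:3, function(j) sum(abs(a$theta[[j]] - b2$theta[[j]][, p])), 0)))
    expect_equal(sum(vapply(1:3, function(j)
      sum(abs(a$theta[[j]] - b2$theta[[j]][, align_classes(a, b2)])), 0)),
      min(costs), tolerance = 1e-12)
  }
  expect_error(align_classes(m, two_item_model()), "share C")
})

test_that("select_lca reports all criteria, breaks ties toward smaller C", {
  b <- gen_binary_lca(300, cbind(rep(0.9, 6), rep(0.1, 6)), c(0.5, 0.5), 71L)
  sel <- select_lca(b$data, C_range = 1:3, n_restarts = 5, seed = 5L)
  expect_equal(sel$table$C, 1:3)
  expect_true(all(c("AIC", "BIC", "SABIC", "CAIC") %in% names(sel$table)))
  expect_equal(sel$selected[["BIC"]], 2L)
  # -2 logLik non-increasing in C (generous restarts on a tiny problem)
  expect_true(all(diff(-2 * sel$table$logLik) <= 1e-6))
})

test_that("permuting data rows permutes assignments and nothing else", {
  b <- gen_binary_lca(150, cbind(rep(0.85, 5), rep(0.15, 5)), c(0.5, 0.5), 81L)
  fit <- fit_lca(b$data, 2L, n_restarts = 4, seed = 2L)
  set.seed(3); perm <- sample(nrow(b$data))
  a1 <- assign_classes(fit, b$data)
  a2 <- assign_classes(fit, b$data[perm, , drop = FALSE])
  expect_identical(a2$class, a1$class[perm])
})

test_that("model JSON serialization round-trips", {
  b <- gen_binary_lca(120, cbind(rep(0.8, 4), rep(0.2, 4)), c(0.6, 0.4), 91L)
  fit <- fit_lca(b$data, 2L, n_restarts = 4, seed = 12L)
  path <- tempfile(fileext = ".json")
  write_lca_model(fit, path)
  m2 <- read_lca_model(path)
  expect_equal(m2$pi, fit$model$pi, tolerance = 1e-12)
  for (j in seq_along(m2$theta))
    expect_equal(unname(m2$theta[[j]]), unname(fit$model$theta[[j]]), tolerance = 1e-12)
})
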