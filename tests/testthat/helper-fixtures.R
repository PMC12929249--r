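# Shared builders for small in-code fixtures.

# tiny two-topic lexicon used by matcher unit tests
tiny_lexicon <- function(window = 3L) {
  topic_lexicon(list(
    depression = list(include = "depression", exclude = c("no", "neg"), window = window),
    sud = list(include = list("substance use", "cocaine"), exclude = c("no", "neg"),
               window = window)))
}

# binary latent-class sample: theta is J x C matrix of P(level 2), returns
# integer data (1/2) plus true class labels
gen_binary_lca <- function(n, theta, weights, seed) {
  set.seed(seed)
  C <- ncol(theta)
  cl <- sample.int(C, n, replace = TRUE, prob = weights)
  x <- matrix(0L, n, nrow(theta))
  for (j in seq_len(nrow(theta))) x[, j] <- as.integer(stats::runif(n) < theta[j, cl])
  d <- x + 1L
  attr(d, "item_levels") <- rep(2L, nrow(theta))
  list(data = d, cl = cl)
}

# small visit table builder: days is a list of per-patient day offsets
make_visits <- function(days, origin = as.Date("2017-01-01"), age = 40L) {
  rows <- lapply(seq_along(days), function(p) {
    data.frame(patient_id = sprintf("P%02d", p),
               visit_id = sprintf("P%02d_V%02d", p, seq_along(days[[p]])),
               visit_date = format(origin + days[[p]]),
               age_years = age, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# small generator config: 2 classes, a few indicators + 2 topics
small_config <- function(n_patients = 50L, seed = 1L, negation_rate = 0.25,
                         weights = c(0.5, 0.5)) {
  ip <- rbind(dx_a = c(0.8, 0.1),
              dx_b = c(0.2, 0.7),
              lab_x = c(0.5, 0.5),
              pregnancy = c(0.6, 0.1),
              mental_illness = c(0.2, 0.8))
  generator_config(
    n_patients = n_patients, class_weights = weights, item_probs = ip,
    age_dist = matrix(0.2, 5, 2),
    p_long_gap = c(0.1, 0.3), vl_detect_prob = c(0.2, 0.5),
    negation_rate = negation_rate, seed = seed)
}

# brute-force windowed matcher: enumerates every include occurrence and
# checks every exclude occurrence's distance; independent of match_topic()
brute_match <- function(tokens, entry, window = NULL) {
  win <- if (is.null(window)) entry$window else window
  n <- length(tokens)
  for (ph in entry$include_tokens) {
    k <- length(ph)
    if (k > n) next
    for (s in seq_len(n - k + 1L)) {
      if (!all(tokens[s:(s + k - 1L)] == ph)) next
      clean <- TRUE
      for (e in seq_len(n)) {
        if (!(tokens[e] %in% entry$exclude)) next
        if (e >= s && e <= s + k - 1L) next  # inside the span: not in a window
        dist <- if (e < s) s - e else e - (s + k - 1L)
        if (dist <= win) { clean <- FALSE; break }
      }
      if (clean) return(1L)
    }
  }
  0L
}
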