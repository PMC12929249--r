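# z multiplier for 95% Wald intervals, fixed (qnorm(0.975) to 6 decimals)
.Z95 <- 1.959964

#' Odds ratio from a 2x2 contingency table
#'
#' For a single binary predictor the logistic-regression MLE equals the
#' cross-product ratio `(a d) / (b c)`. The Wald 95% interval uses the
#' log-scale standard error `sqrt(1/a + 1/b + 1/c + 1/d)`; the p-value is the
#' two-sided Wald z test.
#'
#' @param a Outcome-positive count in the comparison class.
#' @param b Outcome-negative count in the comparison class.
#' @param c Outcome-positive count in the reference class.
#' @param d Outcome-negative count in the reference class.
#' @param haldane If `TRUE`, add 0.5 to every cell (with a message) so tables
#'   with a zero cell can be analysed; by default a zero cell is an error.
#' @return List of class `or_result`: `or_point`, `ci_low`, `ci_high`,
#'   `p_value`, `counts`.
#' @export
odds_ratio <- function(a, b, c, d, haldane = FALSE) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(counts == 0)) {
    if (!haldane)
      stop("zero cell in 2x2 table; rerun with haldane = TRUE to apply the +0.5 correction",
           call. = FALSE)
    message("odds_ratio: zero cell, applying Haldane +0.5 correction to all cells")
    counts <- counts + 0.5
  }
  or <- (counts["a"] * counts["d"]) / (counts["b"] * counts["c"])
  se <- sqrt(sum(1 / counts))
  z <- log(or) / se
  structure(list(or_point = unname(or),
                 ci_low = unname(exp(log(or) - .Z95 * se)),
                 ci_high = unname(exp(log(or) + .Z95 * se)),
                 p_value = unname(2 * stats::pnorm(-abs(z))),
                 se_log = unname(se),
                 counts = c(a = a, b = b, c = c, d = d)),
            class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), P = %.3g\n",
              x$or_point, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Pearson chi-squared test for an r x c count table
#'
#' Statistic `sum (O - E)^2 / E` with expected counts from the margins;
#' `df = (r - 1)(c - 1)`. No continuity correction is applied (visit-level
#' counts in this setting are large).
#'
#' @param tab Matrix of non-negative counts, at least 2 x 2.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_squared <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("zero margin in contingency table", call. = FALSE)
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Kruskal-Wallis rank test with tie correction
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @return List with `H` (tie-corrected statistic), `df`, `p_value`. When all
#'   values across all groups are identical, returns `H = 0`, `p_value = 1`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) stop("every group must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("missing values not allowed", call. = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  df <- length(groups) - 1L
  if (length(unique(x)) == 1L) return(list(H = 0, df = df, p_value = 1))
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  H <- 12 / (N * (N + 1)) * sum(lengths(groups) * (Rbar - (N + 1) / 2)^2)
  tie <- table(x)
  H <- H / (1 - sum(tie^3 - tie) / (N^3 - N))
  list(H = unname(H), df = df,
       p_value = stats::pchisq(H, df, lower.tail = FALSE))
}

#' Per-class outcome table with odds ratios versus a reference class
#'
#' Builds the class-by-outcome summary: per class the number of evaluable
#' visits, the outcome count and percent (one decimal), and the Wald odds
#' ratio against the reference class. The reference row carries `NA` estimates
#' and is rendered as "Ref.".
#'
#' @param assignments Data.frame with `visit_id` and `class`, or the list
#'   returned by [assign_classes()] plus `visit_id`s in `outcomes` order.
#' @param outcomes Data.frame of outcome labels (see [label_outcomes()]).
#' @param outcome Name of the 0/1 outcome column (e.g. `"ltfu_primary"`).
#' @param reference Reference class (default 1).
#' @param evaluable_only Drop visits whose matching `<outcome>_evaluable`
#'   column is 0 (default `TRUE`; set `FALSE` to reproduce full-denominator
#'   class sizes).
#' @return Data.frame of class `outcome_table` with columns `class`, `n`,
#'   `events`, `percent`, `or`, `ci_low`, `ci_high`, `p_value`.
#' @export
outcome_table <- function(assignments, outcomes, outcome, reference = 1L,
                          evaluable_only = TRUE) {
  stopifnot(is.data.frame(assignments), all(c("visit_id", "class") %in% names(assignments)))
  if (!outcome %in% names(outcomes)) stop("unknown outcome column: ", outcome, call. = FALSE)
  df <- merge(assignments[, c("visit_id", "class")], outcomes, by = "visit_id")
  ev_col <- paste0(outcome, "_evaluable")
  if (evaluable_only && ev_col %in% names(df)) df <- df[df[[ev_col]] == 1L, ]
  if (!reference %in% df$class)
    stop("reference class ", reference, " absent from assignments", call. = FALSE)
  classes <- sort(unique(df$class))
  n <- tapply(df[[outcome]], df$class, length)[as.character(classes)]
  ev <- tapply(df[[outcome]], df$class, sum)[as.character(classes)]
  out <- data.frame(class = classes, n = as.integer(n), events = as.integer(ev),
                    percent = round(100 * ev / n, 1),
                    or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p_value = NA_real_)
  ref_i <- which(classes == reference)
  for (i in seq_along(classes)) {
    if (i == ref_i) next
    orr <- odds_ratio(out$events[i], out$n[i] - out$events[i],
                      out$events[ref_i], out$n[ref_i] - out$events[ref_i])
    out$or[i] <- orr$or_point
    out$ci_low[i] <- orr$ci_low
    out$ci_high[i] <- orr$ci_high
    out$p_value[i] <- orr$p_value
  }
  structure(out, class = c("outcome_table", "data.frame"),
            outcome = outcome, reference = reference)
}

#' @export
print.outcome_table <- function(x, ...) {
  cat("Outcome:", attr(x, "outcome"), " (reference class ", attr(x, "reference"), ")\n", sep = "")
  disp <- data.frame(class = x$class,
                     `n (%)` = sprintf("%d (%.1f)", x$events, x$percent),
                     OR = ifelse(is.na(x$or), "Ref.",
                                 sprintf("%.2f (%.2f-%.2f)", x$or, x$ci_low, x$ci_high)),
                     P = ifelse(is.na(x$p_value), "", format.pval(x$p_value, digits = 2)),
                     check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

#' Per-variable class profile table
#'
#' For every feature column, tabulates overall and per-class counts and
#' percents and a chi-squared p-value across classes, starring variables
#' significant at the study threshold `P < 0.001`.
#'
#' @param features A `feature_matrix` or plain data.frame with `visit_id`.
#' @param assignments Data.frame with `visit_id` and `class`.
#' @param alpha Significance threshold (default 0.001).
#' @return Data.frame of class `profile_table`: one row per (variable, level)
#'   with per-class `n (percent)` strings, plus a per-variable p-value and
#'   significance flag.
#' @export
profile_table <- function(features, assignments, alpha = 0.001) {
  feats <- as.data.frame(features)
  stopifnot("visit_id" %in% names(feats))
  df <- merge(feats, assignments[, c("visit_id", "class")], by = "visit_id")
  if (nrow(df) != nrow(feats))
    stop("assignments must cover every feature row", call. = FALSE)
  classes <- sort(unique(df$class))
  vars <- setdiff(names(feats), "visit_id")
  rows <- list()
  for (v in vars) {
    x <- df[[v]]
    if (is.numeric(x) && all(x %in% c(0, 1))) x <- factor(x, levels = c(0, 1))
    x <- as.factor(x)
    tab <- table(x, df$class)
    p <- tryCatch(chi_squared(tab)$p_value, error = function(e) NA_real_)
    lvls <- if (nlevels(x) == 2L && all(levels(x) %in% c("0", "1"))) "1" else levels(x)
    for (l in lvls) {
      cnt_all <- sum(x == l)
      row <- data.frame(variable = v, level = l,
                        overall = sprintf("%d (%.1f)", cnt_all, 100 * cnt_all / length(x)),
                        stringsAsFactors = FALSE)
      for (cl in classes) {
        idx <- df$class == cl
        cnt <- sum(x[idx] == l)
        row[[paste0("class_", cl)]] <- sprintf("%d (%.1f)", cnt, 100 * cnt / sum(idx))
      }
      row$p_value <- p
      row$significant <- !is.na(p) && p < alpha
      rows[[length(rows) + 1L]] <- row
    }
  }
  structure(do.call(rbind, rows), class = c("profile_table", "data.frame"),
            alpha = alpha)
}

#' Render a profile or outcome table as Markdown
#'
#' @param x A `profile_table` or `outcome_table`.
#' @return Character vector of Markdown lines.
#' @export
render_markdown <- function(x) {
  df <- as.data.frame(x)
  if (inherits(x, "outcome_table")) {
    df <- data.frame(Class = df$class,
                     `Events n (%)` = sprintf("%d (%.1f)", df$events, df$percent),
                     `OR (95% CI)` = ifelse(is.na(df$or), "Ref.",
                                            sprintf("%.2f (%.2f-%.2f)", df$or, df$ci_low, df$ci_high)),
                     check.names = FALSE)
  } else if (inherits(x, "profile_table")) {
    df$p_value <- ifelse(is.na(df$p_value), "",
                         paste0(format.pval(df$p_value, digits = 2),
                                ifelse(df$significant, " *", "")))
    df$significant <- NULL
  }
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, unname(body))
}
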