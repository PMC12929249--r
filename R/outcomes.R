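#' Label the primary loss-to-follow-up outcome
#'
#' A visit is LTFU when more than 365 days elapse before the patient's next
#' attended visit, or when there is no next visit and more than 365 days
#' remain between the visit and the end of the study (the gap can no longer
#' be closed). A last visit within 365 days of study end has insufficient
#' follow-up and is marked non-evaluable; `boundary_rule` controls whether
#' such visits are excluded from downstream denominators (default) or counted
#' as not LTFU.
#'
#' @param visits Data.frame with `patient_id`, `visit_id`, `visit_date`.
#' @param study_end `Date` (or ISO string): last day of the study window.
#' @param boundary_rule `"exclude"` (default) or `"count_as_not_ltfu"`.
#' @return Data.frame `visit_id`, `ltfu_primary`, `ltfu_primary_evaluable`
#'   in the input row order.
#' @export
label_ltfu_primary <- function(visits, study_end,
                               boundary_rule = c("exclude", "count_as_not_ltfu")) {
  boundary_rule <- match.arg(boundary_rule)
  study_end <- as.Date(study_end)
  d <- as.Date(visits$visit_date)
  if (any(d > study_end)) stop("visit dated after study_end", call. = FALSE)
  ltfu <- integer(nrow(visits))
  ev <- rep(1L, nrow(visits))
  for (idx in split(seq_len(nrow(visits)), visits$patient_id)) {
    idx <- idx[order(d[idx])]
    dd <- d[idx]
    nxt <- c(as.numeric(diff(dd)), NA)
    for (i in seq_along(idx)) {
      if (!is.na(nxt[i])) {
        ltfu[idx[i]] <- as.integer(nxt[i] > 365)
      } else {
        tail_days <- as.numeric(study_end - dd[i])
        if (tail_days > 365) {
          ltfu[idx[i]] <- 1L
        } else {
          ev[idx[i]] <- 0L
          ltfu[idx[i]] <- 0L
        }
      }
    }
  }
  if (boundary_rule == "count_as_not_ltfu") ev[] <- 1L
  data.frame(visit_id = visits$visit_id, ltfu_primary = ltfu,
             ltfu_primary_evaluable = ev, stringsAsFactors = FALSE)
}

#' Label the NHAS retention outcome
#'
#' Under the National HIV/AIDS Strategy definition a patient is retained at an
#' index visit when, within the 365-day period starting at that visit (days 0
#' through 364), they attended at least two visits more than 90 days apart.
#' The index visit itself counts. `nhas_ltfu = 1` when the condition fails.
#'
#' @param visits Data.frame with `patient_id`, `visit_id`, `visit_date`.
#' @return Data.frame `visit_id`, `nhas_ltfu` in input row order.
#' @export
label_nhas <- function(visits) {
  d <- as.Date(visits$visit_date)
  out <- integer(nrow(visits))
  for (idx in split(seq_len(nrow(visits)), visits$patient_id)) {
    dd <- d[idx]
    for (i in seq_along(idx)) {
      win <- dd[dd >= dd[i] & dd <= dd[i] + 364]
      retained <- length(win) >= 2L &&
        (as.numeric(max(win) - min(win)) > 90)
      out[idx[i]] <- as.integer(!retained)
    }
  }
  data.frame(visit_id = visits$visit_id, nhas_ltfu = out, stringsAsFactors = FALSE)
}

#' Label the high-viral-load outcome
#'
#' A visit is flagged when any viral-load sample drawn in the 365 days after
#' the visit is at or above `threshold` copies/ml. The window is half-open,
#' `(visit_date, visit_date + 365]`: same-day draws are excluded unless
#' `include_day0 = TRUE`. Visits with no sample in the window are
#' non-evaluable.
#'
#' @param visits Data.frame with `patient_id`, `visit_id`, `visit_date`.
#' @param labs Data.frame with `patient_id`, `draw_date`,
#'   `viral_load_copies_ml`.
#' @param threshold Copies/ml cutoff (default 200; the boundary value itself
#'   counts as high).
#' @param include_day0 Include samples drawn on the visit day (default FALSE).
#' @return Data.frame `visit_id`, `high_vl`, `high_vl_evaluable` in input
#'   row order.
#' @export
label_high_vl <- function(visits, labs, threshold = 200, include_day0 = FALSE) {
  if (any(labs$viral_load_copies_ml < 0)) stop("negative viral-load value", call. = FALSE)
  d <- as.Date(visits$visit_date)
  ld <- as.Date(labs$draw_date)
  hv <- integer(nrow(visits))
  ev <- integer(nrow(visits))
  labs_by_pat <- split(seq_len(nrow(labs)), labs$patient_id)
  for (i in seq_len(nrow(visits))) {
    li <- labs_by_pat[[as.character(visits$patient_id[i])]]
    if (is.null(li)) next
    off <- as.numeric(ld[li] - d[i])
    in_win <- if (include_day0) off >= 0 & off <= 365 else off > 0 & off <= 365
    if (!any(in_win)) next
    ev[i] <- 1L
    hv[i] <- as.integer(any(labs$viral_load_copies_ml[li][in_win] >= threshold))
  }
  data.frame(visit_id = visits$visit_id, high_vl = hv, high_vl_evaluable = ev,
             stringsAsFactors = FALSE)
}

#' Label all outcomes for a visit table
#'
#' Convenience wrapper producing the full visit-level outcome table: primary
#' LTFU (with evaluability), NHAS LTFU, and high viral load (with
#' evaluability).
#'
#' @inheritParams label_ltfu_primary
#' @inheritParams label_high_vl
#' @return Data.frame `visit_id`, `ltfu_primary`, `ltfu_primary_evaluable`,
#'   `nhas_ltfu`, `high_vl`, `high_vl_evaluable`.
#' @export
label_outcomes <- function(visits, labs, study_end,
                           boundary_rule = c("exclude", "count_as_not_ltfu"),
                           threshold = 200, include_day0 = FALSE) {
  a <- label_ltfu_primary(visits, study_end, boundary_rule)
  b <- label_nhas(visits)
  c3 <- label_high_vl(visits, labs, threshold, include_day0)
  stopifnot(identical(a$visit_id, b$visit_id), identical(a$visit_id, c3$visit_id))
  cbind(a, b["nhas_ltfu"], c3[c("high_vl", "high_vl_evaluable")])
}
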