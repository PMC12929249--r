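#' Age bins used for phenotyping
#'
#' Five categories: `<=25`, `26-35`, `36-45`, `46-55`, `>55` years; boundary
#' values fall in the bin whose printed range includes them (25 is `<=25`,
#' 26 is `26-35`, ...). The cohort is adult, so ages below 18 are rejected.
#'
#' @param age Integer vector of ages in years.
#' @return Factor with levels `c("<=25","26-35","36-45","46-55",">55")`.
#' @export
bin_age <- function(age) {
  if (anyNA(age) || any(!is.finite(age))) stop("age must be non-missing", call. = FALSE)
  if (any(age < 18)) stop("age below 18: cohort is adults only", call. = FALSE)
  cut(age, breaks = c(-Inf, 25, 35, 45, 55, Inf),
      labels = age_bin_levels(), right = TRUE)
}

#' @rdname bin_age
#' @export
age_bin_levels <- function() c("<=25", "26-35", "36-45", "46-55", ">55")

#' @rdname retention_history
#' @export
retention_levels <- function() c("retained_prev_year", "ltfu_prev_year", "prev_visit_was_first")

#' Map diagnosis codes to binary indicator variables
#'
#' An indicator is 1 iff any code in the union of the encounter-level list and
#' the problem list maps to it. Unmapped codes are ignored with a warning.
#'
#' @param visit_codes Character vector of encounter-level diagnosis codes.
#' @param problem_list_codes Character vector of problem-list codes.
#' @param code_map Named character vector or list mapping code -> variable
#'   name (many codes may map to one variable).
#' @return Named integer 0/1 vector over the map's variables (sorted unique).
#' @export
diagnosis_flags <- function(visit_codes, problem_list_codes = character(0), code_map) {
  map <- unlist(code_map)
  vars <- sort(unique(unname(map)))
  codes <- unique(c(visit_codes, problem_list_codes))
  codes <- codes[!is.na(codes) & nzchar(codes)]
  unknown <- setdiff(codes, names(map))
  if (length(unknown))
    warning("ignoring unmapped diagnosis codes: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  hit <- unique(unname(map[intersect(codes, names(map))]))
  stats::setNames(as.integer(vars %in% hit), vars)
}

#' Positive-laboratory flags for the four tracked STIs
#'
#' @param lab_records Data.frame with columns `test`, `result` (qualitative),
#'   and optionally `date`. Recognized tests: gonorrhea, chlamydia, syphilis,
#'   trichomoniasis (case-insensitive); others are ignored with a warning.
#'   A result counts as positive when it matches (case-insensitively) one of
#'   "positive", "pos", "detected", "reactive".
#' @return Named integer 0/1 vector `lab_gonorrhea`, `lab_chlamydia`,
#'   `lab_syphilis`, `lab_trichomoniasis`.
#' @export
lab_flags <- function(lab_records) {
  tracked <- c("gonorrhea", "chlamydia", "syphilis", "trichomoniasis")
  out <- stats::setNames(integer(4L), paste0("lab_", tracked))
  if (is.null(lab_records) || nrow(lab_records) == 0L) return(out)
  stopifnot(all(c("test", "result") %in% names(lab_records)))
  test <- tolower(lab_records$test)
  unknown <- setdiff(unique(test), tracked)
  if (length(unknown))
    warning("ignoring unknown lab tests: ", paste(unknown, collapse = ", "), call. = FALSE)
  pos <- tolower(lab_records$result) %in% c("positive", "pos", "detected", "reactive")
  for (t in tracked)
    out[paste0("lab_", t)] <- as.integer(any(pos & test == t))
  out
}

#' Retention history of each visit
#'
#' Three mutually exclusive levels per visit: `prev_visit_was_first` when the
#' visit is the patient's first recorded visit or immediately follows it,
#' `ltfu_prev_year` when the gap from the preceding visit exceeds 365 days,
#' otherwise `retained_prev_year`. The first-visit rule takes precedence over
#' the gap test. Input dates are sorted internally and duplicate same-day
#' visits collapsed.
#'
#' @param visit_dates `Date` vector of one patient's attended visits.
#' @param index_dates Optional `Date` vector of visits to label (default: all
#'   of `visit_dates`); each must be one of the patient's visit dates.
#' @return Factor over [retention_levels()], one entry per index date.
#' @export
retention_history <- function(visit_dates, index_dates = NULL) {
  d <- sort(unique(as.Date(visit_dates)))
  if (is.null(index_dates)) index_dates <- visit_dates
  index_dates <- as.Date(index_dates)
  if (!all(index_dates %in% d))
    stop("index visit not among the patient's visit dates", call. = FALSE)
  pos <- match(index_dates, d)
  lab <- character(length(pos))
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (p <= 2L) {
      lab[i] <- "prev_visit_was_first"
    } else if (as.numeric(d[p] - d[p - 1L]) > 365) {
      lab[i] <- "ltfu_prev_year"
    } else {
      lab[i] <- "retained_prev_year"
    }
  }
  factor(lab, levels = retention_levels())
}

#' Build the visit-level feature matrix for LCA
#'
#' Combines the visit table's indicator columns with note-topic flags and
#' derives `age_bin` and `retention_history`. Every cell is categorical; the
#' result carries a declared level set per column.
#'
#' @param visits Data.frame with `visit_id`, `patient_id`, `visit_date`
#'   (Date or ISO-8601 string), `age_years`, plus 0/1 indicator columns.
#' @param topic_flags Data.frame from [annotate_corpus()]; must cover exactly
#'   the visit ids in `visits`.
#' @return Object of class `feature_matrix` (a data.frame: `visit_id`,
#'   `age_bin`, `retention_history`, indicator columns) with attribute
#'   `levels`, a named list of level sets.
#' @export
build_feature_matrix <- function(visits, topic_flags) {
  req <- c("visit_id", "patient_id", "visit_date", "age_years")
  miss <- setdiff(req, names(visits))
  if (length(miss)) stop("visit table missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyNA(visits$age_years)) stop("missing age_years; no imputation is performed",
                                    call. = FALSE)
  only_v <- setdiff(visits$visit_id, topic_flags$visit_id)
  only_t <- setdiff(topic_flags$visit_id, visits$visit_id)
  if (length(only_v) || length(only_t))
    stop("visit/topic mismatch; visits without flags: [",
         paste(utils::head(only_v, 5L), collapse = ", "), "], flags without visits: [",
         paste(utils::head(only_t, 5L), collapse = ", "), "]", call. = FALSE)
  visits <- visits[order(visits$patient_id, as.Date(visits$visit_date), visits$visit_id), ]
  dates <- as.Date(visits$visit_date)
  reth <- unlist(lapply(split(seq_len(nrow(visits)), visits$patient_id), function(idx) {
    as.character(retention_history(dates[idx], dates[idx]))
  })[as.character(unique(visits$patient_id))], use.names = FALSE)
  # split() groups by patient in first-appearance order after the sort above
  out <- data.frame(visit_id = visits$visit_id,
                    age_bin = bin_age(visits$age_years),
                    retention_history = factor(reth, levels = retention_levels()),
                    stringsAsFactors = FALSE)
  demo_cols <- c(req, "sex", "race", "ethnicity")
  ind_cols <- setdiff(names(visits), demo_cols)
  for (col in ind_cols) {
    v <- visits[[col]]
    if (!all(v %in% c(0L, 1L)))
      stop("indicator column ", col, " must be 0/1", call. = FALSE)
    out[[col]] <- as.integer(v)
  }
  tf <- topic_flags[match(out$visit_id, topic_flags$visit_id), , drop = FALSE]
  for (col in setdiff(names(tf), "visit_id")) {
    if (!all(tf[[col]] %in% c(0L, 1L)))
      stop("topic flag column ", col, " must be 0/1", call. = FALSE)
    out[[col]] <- as.integer(tf[[col]])
  }
  if (anyNA(out)) stop("feature matrix has missing cells", call. = FALSE)
  lv <- c(list(age_bin = age_bin_levels(), retention_history = retention_levels()),
          stats::setNames(rep(list(c("0", "1")),
                              ncol(out) - 3L),
                          setdiff(names(out), c("visit_id", "age_bin", "retention_history"))))
  structure(out, levels = lv, class = c("feature_matrix", "data.frame"))
}

#' Convert a feature matrix to the integer coding used by the LCA engine
#'
#' Each column is recoded to integer levels `1..L_j` following its declared
#' level set; the result carries `item_levels` and `item_names` attributes.
#'
#' @param fm A `feature_matrix`.
#' @return Integer matrix with attributes `item_levels`, `item_names`,
#'   `visit_id`.
#' @export
lca_data <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  lv <- attr(fm, "levels")
  cols <- setdiff(names(fm), "visit_id")
  m <- matrix(NA_integer_, nrow(fm), length(cols), dimnames = list(NULL, cols))
  for (i in seq_along(cols)) {
    col <- cols[i]
    m[, i] <- match(as.character(fm[[col]]), lv[[col]])
    if (anyNA(m[, i])) stop("value outside declared levels in column ", col, call. = FALSE)
  }
  attr(m, "item_levels") <- vapply(lv[cols], length, integer(1))
  attr(m, "item_names") <- cols
  attr(m, "visit_id") <- fm$visit_id
  m
}

#' Write / read a feature matrix (CSV plus JSON level-set sidecar)
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".levels.json")`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm)
  df$age_bin <- as.character(df$age_bin)
  df$retention_history <- as.character(df$retention_history)
  data.table::fwrite(df, path)
  jsonlite::write_json(attr(fm, "levels"), paste0(path, ".levels.json"), pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(character = "visit_id")))
  lv <- jsonlite::read_json(paste0(path, ".levels.json"), simplifyVector = TRUE)
  df$age_bin <- factor(df$age_bin, levels = lv$age_bin)
  df$retention_history <- factor(df$retention_history, levels = lv$retention_history)
  structure(df, levels = lv, class = c("feature_matrix", "data.frame"))
}
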