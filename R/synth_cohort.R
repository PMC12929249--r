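# filler vocabulary for synthetic note prose; kept disjoint from every
# lexicon token so that annotator round-trips are exact by construction
.FILLER <- c("patient", "seen", "clinic", "today", "for", "routine", "review",
             "stable", "plan", "continue", "current", "regimen", "discussed",
             "goals", "ordered", "return", "weeks", "doing", "well", "feeling",
             "overall", "visit", "went", "smoothly", "and", "the", "was",
             "agreed", "with", "recommendations")

#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort drawn from a known latent-class model: each patient
#' belongs to one of `true_C` classes; every attended visit carries
#' class-conditional Bernoulli indicator draws and a clinical note with
#' planted topic tokens; inter-visit gaps follow a two-component renewal
#' mixture (short gaps uniform on `gap_short` days, long gaps uniform on
#' `gap_long` days) with class-specific long-gap probability, so the
#' loss-to-follow-up rate is controllable per class; post-visit viral loads
#' are at-or-above threshold with class-specific probability.
#'
#' @param n_patients Number of patients (>= 1).
#' @param class_weights Probability vector over classes; sums to 1.
#' @param item_probs Numeric matrix, items x classes, entries in `[0, 1]`,
#'   with rownames. Rows whose names are topics of `lexicon` are realized as
#'   note-text plantings; all other rows become 0/1 indicator columns.
#' @param age_dist 5 x C matrix of per-class age-bin distributions (columns
#'   sum to 1).
#' @param p_long_gap Per-class probability that an inter-visit gap comes from
#'   the long component.
#' @param vl_detect_prob Per-class probability a viral-load draw is at or
#'   above the detection threshold.
#' @param sex_male_prob Per-class probability of male sex (cosmetic
#'   demographic; default 0.66 everywhere).
#' @param negation_rate Probability a planted topic token is negated.
#' @param study_start,study_end Calendar dates bounding the study window.
#' @param seed Integer seed; identical config + seed reproduces byte-identical
#'   outputs.
#' @param lexicon A `topic_lexicon` (default [default_lexicon()]).
#' @param gap_short,gap_long Integer length-2 ranges (days) of the two gap
#'   components (defaults 30-180 and 400-700).
#' @param vl_sample_prob Probability a visit is followed by a viral-load draw
#'   (default 0.9); the draw lag is uniform on 7-180 days.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_patients, class_weights, item_probs, age_dist,
                             p_long_gap, vl_detect_prob,
                             sex_male_prob = NULL, negation_rate = 0.2,
                             study_start = "2017-01-01", study_end = "2020-12-31",
                             seed = 1L, lexicon = NULL,
                             gap_short = c(30L, 180L), gap_long = c(400L, 700L),
                             vl_sample_prob = 0.9) {
  if (is.null(lexicon)) lexicon <- default_lexicon()
  true_C <- length(class_weights)
  if (true_C < 1L) stop("need at least one latent class", call. = FALSE)
  if (abs(sum(class_weights) - 1) > 1e-9)
    stop("class_weights must sum to 1", call. = FALSE)
  if (any(class_weights < 0)) stop("class_weights must be non-negative", call. = FALSE)
  item_probs <- as.matrix(item_probs)
  if (is.null(rownames(item_probs))) stop("item_probs needs rownames", call. = FALSE)
  if (ncol(item_probs) != true_C)
    stop("item_probs must have one column per class", call. = FALSE)
  probs_ok <- function(p) all(is.finite(p)) && all(p >= 0) && all(p <= 1)
  if (!probs_ok(item_probs)) stop("item_probs entries must lie in [0,1]", call. = FALSE)
  age_dist <- as.matrix(age_dist)
  if (nrow(age_dist) != 5L || ncol(age_dist) != true_C)
    stop("age_dist must be 5 x C", call. = FALSE)
  if (!probs_ok(age_dist) || any(abs(colSums(age_dist) - 1) > 1e-6))
    stop("age_dist columns must be distributions", call. = FALSE)
  if (is.null(sex_male_prob)) sex_male_prob <- rep(0.66, true_C)
  for (nm in c("p_long_gap", "vl_detect_prob", "sex_male_prob")) {
    v <- get(nm)
    if (length(v) != true_C || !probs_ok(v))
      stop(nm, " must be a per-class probability vector", call. = FALSE)
  }
  if (!probs_ok(negation_rate) || !probs_ok(vl_sample_prob))
    stop("negation_rate and vl_sample_prob must lie in [0,1]", call. = FALSE)
  study_start <- as.Date(study_start); study_end <- as.Date(study_end)
  if (!(study_start < study_end))
    stop("study window must span at least one day", call. = FALSE)
  topics <- intersect(rownames(item_probs), names(lexicon))
  fill_clash <- intersect(.FILLER, c(unlist(lapply(lexicon, function(e)
    c(unlist(e$include_tokens), e$exclude)))))
  if (length(fill_clash))
    stop("lexicon tokens collide with the filler vocabulary: ",
         paste(fill_clash, collapse = ", "), call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), true_C = true_C,
                 class_weights = class_weights, item_probs = item_probs,
                 topics = topics,
                 indicators = setdiff(rownames(item_probs), topics),
                 age_dist = age_dist, p_long_gap = p_long_gap,
                 vl_detect_prob = vl_detect_prob, sex_male_prob = sex_male_prob,
                 negation_rate = negation_rate, study_start = study_start,
                 study_end = study_end, seed = as.integer(seed),
                 lexicon = lexicon, gap_short = as.integer(gap_short),
                 gap_long = as.integer(gap_long), vl_sample_prob = vl_sample_prob),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> ", x$n_patients, " patients, ", x$true_C, " classes, ",
      length(x$indicators), " indicators + ", length(x$topics), " note topics; window ",
      format(x$study_start), " .. ", format(x$study_end), ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# sample k filler words (with replacement) as a character vector
.filler_words <- function(k) .FILLER[sample.int(length(.FILLER), k, replace = TRUE)]

#' Compose a synthetic clinical note
#'
#' Produces filler prose with one include token planted per requested topic.
#' Non-negated plantings are surrounded by filler only, so the exclusion
#' window is clean; negated plantings put the word "no" directly before the
#' include token (within the default 3-word window). Topic segments are
#' separated by at least five filler words so plantings never interfere.
#' Consumes the current RNG stream.
#'
#' @param topics_present Character vector of topics to plant (may be empty).
#' @param lexicon A `topic_lexicon` covering every requested topic.
#' @param negate Logical vector parallel to `topics_present`.
#' @return A single note string.
#' @export
plant_note_text <- function(topics_present, lexicon, negate = logical(length(topics_present))) {
  missing_t <- setdiff(topics_present, names(lexicon))
  if (length(missing_t))
    stop("topics not in lexicon: ", paste(missing_t, collapse = ", "), call. = FALSE)
  stopifnot(length(negate) == length(topics_present))
  parts <- .filler_words(5L)
  for (i in seq_along(topics_present)) {
    entry <- lexicon[[topics_present[i]]]
    phrase <- entry$include[[sample.int(length(entry$include), 1L)]]
    seg <- if (negate[i]) paste("no", tolower(phrase)) else tolower(phrase)
    parts <- c(parts, seg, .filler_words(5L))
  }
  paste(parts, collapse = " ")
}

#' Generate a synthetic EHR cohort
#'
#' Draws a full cohort from the latent-class world described by `config`:
#' a visit table with demographic columns and 0/1 indicator columns, a
#' clinical-note corpus with planted (and possibly negated) topic tokens, a
#' long-format viral-load table, and the ground truth needed for recovery
#' testing (true class, planted pre-negation topic flags, negation flags,
#' intended loss-to-follow-up status).
#'
#' @param config A `generator_config`.
#' @return List of class `synth_cohort` with elements `visits`, `notes`,
#'   `labs`, `truth` (data.frames) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_days <- as.numeric(config$study_end - config$study_start)
  C <- config$true_C
  ind <- config$indicators
  topics <- config$topics
  visits <- list(); notes_id <- character(0); notes_tx <- character(0)
  labs <- list(); truth <- list()
  age_lo <- c(18L, 26L, 36L, 46L, 56L); age_hi <- c(25L, 35L, 45L, 55L, 85L)
  races <- c("Black", "White", "Other")
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%05d", p)
    cl <- sample.int(C, 1L, prob = config$class_weights)
    bin <- sample.int(5L, 1L, prob = config$age_dist[, cl])
    age <- age_lo[bin] + sample.int(age_hi[bin] - age_lo[bin] + 1L, 1L) - 1L
    sex <- if (stats::runif(1) < config$sex_male_prob[cl]) "Male" else "Female"
    race <- races[sample.int(3L, 1L, prob = c(0.85, 0.11, 0.04))]
    eth <- if (stats::runif(1) < 0.04) "Hispanic" else "Non-Hispanic"
    # renewal process: entry uniform in the window (leaving >= 30 days),
    # then class-dependent short/long gap mixture until past study end
    day <- sample.int(max(1L, as.integer(n_days) - 30L), 1L) - 1L
    v <- 0L
    repeat {
      v <- v + 1L
      vid <- sprintf("%s_V%03d", pid, v)
      vdate <- config$study_start + day
      long_next <- stats::runif(1) < config$p_long_gap[cl]
      rng <- if (long_next) config$gap_long else config$gap_short
      gap <- rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L
      flags <- stats::setNames(as.integer(stats::runif(length(ind)) < config$item_probs[ind, cl]), ind)
      planted <- stats::runif(length(topics)) < config$item_probs[topics, cl]
      negated <- planted & (stats::runif(length(topics)) < config$negation_rate)
      row <- data.frame(patient_id = pid, visit_id = vid,
                        visit_date = format(vdate), age_years = age,
                        sex = sex, race = race, ethnicity = eth,
                        stringsAsFactors = FALSE)
      for (nm in ind) row[[nm]] <- flags[[nm]]
      visits[[length(visits) + 1L]] <- row
      notes_id <- c(notes_id, vid)
      notes_tx <- c(notes_tx, plant_note_text(topics[planted], config$lexicon,
                                              negated[planted]))
      if (stats::runif(1) < config$vl_sample_prob) {
        lag <- 7L + sample.int(174L, 1L) - 1L
        detect <- stats::runif(1) < config$vl_detect_prob[cl]
        vl <- if (detect) 200L + sample.int(49800L, 1L) - 1L else sample.int(200L, 1L) - 1L
        labs[[length(labs) + 1L]] <- data.frame(
          patient_id = pid, visit_id = vid,
          draw_date = format(vdate + lag), viral_load_copies_ml = vl,
          stringsAsFactors = FALSE)
      }
      tr <- data.frame(visit_id = vid, true_class = cl,
                       intended_ltfu = as.integer(long_next),
                       stringsAsFactors = FALSE)
      for (i in seq_along(topics)) {
        tr[[paste0("planted_", topics[i])]] <- as.integer(planted[i])
        tr[[paste0("negated_", topics[i])]] <- as.integer(negated[i])
      }
      truth[[length(truth) + 1L]] <- tr
      if (day + gap > n_days) break
      day <- day + gap
    }
  }
  structure(list(visits = do.call(rbind, visits),
                 notes = data.frame(visit_id = notes_id, text = notes_tx,
                                    stringsAsFactors = FALSE),
                 labs = do.call(rbind, labs),
                 truth = do.call(rbind, truth),
                 config = config),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat("<synth_cohort> ", length(unique(x$visits$patient_id)), " patients, ",
      nrow(x$visits), " visits, ", nrow(x$labs), " viral-load draws\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits `visits.csv`, `notes.jsonl`, `labs.csv` and `truth.csv` into `dir`.
#' Output bytes are a pure function of the cohort, so identical config + seed
#' reproduces identical files.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(visits = file.path(dir, "visits.csv"),
             notes = file.path(dir, "notes.jsonl"),
             labs = file.path(dir, "labs.csv"),
             truth = file.path(dir, "truth.csv"))
  data.table::fwrite(cohort$visits, paths[["visits"]])
  write_notes_jsonl(cohort$notes, paths[["notes"]])
  data.table::fwrite(cohort$labs, paths[["labs"]])
  data.table::fwrite(cohort$truth, paths[["truth"]])
  paths
}
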