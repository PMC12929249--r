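#' Load and validate a pipeline configuration
#'
#' Accepts a YAML path or a list. A configuration either names a `simulate`
#' block (synthetic cohort) or paths to existing `visits`, `notes` and `labs`
#' files. Validation is fail-fast: referenced files must exist before any
#' stage runs. All stage randomness derives from the single top-level `seed`
#' (the LCA stage uses `seed + 1000`, and each class count adds its own
#' offset), so a config + seed pair fully determines every output.
#'
#' @param config YAML file path or list.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(seed = 1L, reference_class = 1L,
                   lca = list(c_min = 2L, c_max = 3L, n_restarts = 3L,
                              max_iter = 200L, tol = 1e-6, criterion = "BIC"),
                   outcomes = list(vl_threshold = 200, boundary_rule = "exclude",
                                   include_day0 = FALSE),
                   study_start = "2017-01-01", study_end = "2020-12-31")
  config <- utils::modifyList(defaults, config)
  if (is.null(config$simulate)) {
    for (f in c("visits", "notes", "labs")) {
      if (is.null(config[[f]]))
        stop("config needs either a `simulate` block or a `", f, "` path", call. = FALSE)
      if (!file.exists(config[[f]]))
        stop("configured ", f, " file does not exist: ", config[[f]], call. = FALSE)
    }
  }
  if (!is.null(config$lexicon) && !file.exists(config$lexicon))
    stop("configured lexicon file does not exist: ", config$lexicon, call. = FALSE)
  if (as.Date(config$study_start) >= as.Date(config$study_end))
    stop("study_start must precede study_end", call. = FALSE)
  if (!config$outcomes$boundary_rule %in% c("exclude", "count_as_not_ltfu"))
    stop("unknown boundary_rule: ", config$outcomes$boundary_rule, call. = FALSE)
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full phenotyping pipeline
#'
#' Executes, in order: simulate (or load) the cohort, annotate notes, build
#' the feature matrix, label outcomes, fit/select the latent class model and
#' assign classes, and compare classes (outcome tables and class profile).
#' Every stage writes its output under `out_dir` and the run ends with a
#' provenance manifest recording the seed and an MD5 content hash per file;
#' rerunning an identical config reproduces identical hashes.
#'
#' @param config A `pipeline_config` (or YAML path / list, coerced).
#' @param out_dir Output directory.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lexicon <- if (is.null(config$lexicon)) default_lexicon() else read_lexicon(config$lexicon)
  stage_files <- list()
  step <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage `", stage, "` failed: ", conditionMessage(e), call. = FALSE))
  }

  # 1. simulate / load
  if (!is.null(config$simulate)) {
    cohort <- step("simulate", {
      cfg <- default_generator_config(
        n_patients = config$simulate$n_patients %||% 200L,
        seed = config$seed,
        negation_rate = config$simulate$negation_rate %||% 0.2)
      generate_cohort(cfg)
    })
    paths <- write_cohort(cohort, out_dir)
    visits <- cohort$visits; notes <- cohort$notes; labs <- cohort$labs
    stage_files$simulate <- unname(paths)
  } else {
    visits <- step("load", as.data.frame(data.table::fread(config$visits,
                                                           colClasses = list(character = c("patient_id", "visit_id", "visit_date")))))
    notes <- step("load", read_notes_jsonl(config$notes))
    labs <- step("load", as.data.frame(data.table::fread(config$labs,
                                                         colClasses = list(character = c("patient_id", "visit_id", "draw_date")))))
    stage_files$load <- c(config$visits, config$notes, config$labs)
  }

  # 2. annotate notes
  flags <- step("annotate", annotate_corpus(notes, lexicon))
  f_flags <- file.path(out_dir, "topic_flags.csv")
  data.table::fwrite(flags, f_flags)
  stage_files$annotate <- f_flags

  # 3. feature matrix
  fm <- step("features", build_feature_matrix(visits, flags))
  f_fm <- file.path(out_dir, "features.csv")
  write_feature_matrix(fm, f_fm)
  stage_files$features <- c(f_fm, paste0(f_fm, ".levels.json"))

  # 4. outcomes
  oc <- step("outcomes", label_outcomes(visits, labs, config$study_end,
                                        boundary_rule = config$outcomes$boundary_rule,
                                        threshold = config$outcomes$vl_threshold,
                                        include_day0 = isTRUE(config$outcomes$include_day0)))
  f_oc <- file.path(out_dir, "outcomes.csv")
  data.table::fwrite(oc, f_oc)
  stage_files$outcomes <- f_oc

  # 5. LCA: selection over the configured range, then assignment
  sel <- step("lca", select_lca(fm, C_range = config$lca$c_min:config$lca$c_max,
                                criterion = config$lca$criterion,
                                n_restarts = config$lca$n_restarts,
                                tol = config$lca$tol, max_iter = config$lca$max_iter,
                                seed = config$seed + 1000L))
  best <- sel$fits[[which(sel$table$C == sel$selected_C)]]
  f_sel <- file.path(out_dir, "selection.csv")
  data.table::fwrite(sel$table, f_sel)
  f_model <- file.path(out_dir, "model.json")
  write_lca_model(best, f_model)
  asg <- assign_classes(best, fm)
  assignments <- data.frame(visit_id = fm$visit_id, class = asg$class,
                            stringsAsFactors = FALSE)
  f_asg <- file.path(out_dir, "assignments.csv")
  data.table::fwrite(assignments, f_asg)
  stage_files$lca <- c(f_sel, f_model, f_asg)

  # 6. compare classes
  cmp <- step("compare", {
    ref <- config$reference_class
    if (!ref %in% assignments$class) ref <- sort(unique(assignments$class))[1L]
    list(ltfu = outcome_table(assignments, oc, "ltfu_primary", reference = ref),
         vl = outcome_table(assignments, oc, "high_vl", reference = ref),
         profile = profile_table(fm, assignments))
  })
  f_cmp <- c(file.path(out_dir, "outcome_ltfu.tsv"),
             file.path(out_dir, "outcome_high_vl.tsv"),
             file.path(out_dir, "profile.tsv"))
  data.table::fwrite(as.data.frame(cmp$ltfu), f_cmp[1], sep = "\t")
  data.table::fwrite(as.data.frame(cmp$vl), f_cmp[2], sep = "\t")
  data.table::fwrite(as.data.frame(cmp$profile), f_cmp[3], sep = "\t")
  stage_files$compare <- f_cmp

  all_files <- unlist(stage_files, use.names = FALSE)
  hashes <- unname(tools::md5sum(all_files))
  manifest <- list(seed = config$seed,
                   stages = lapply(stage_files, function(fs)
                     lapply(seq_along(fs), function(i)
                       list(file = basename(fs[i]),
                            md5 = unname(tools::md5sum(fs[i]))))),
                   files = stats::setNames(as.list(hashes), basename(all_files)),
                   selected_C = sel$selected_C)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a packaged fixture
#'
#' Available fixtures: `"table4_counts"` — the published per-class visit
#' counts, loss-to-follow-up counts and high-viral-load counts of the
#' six-phenotype cohort; `"toy_notes"` — eight hand-written notes with their
#' known topic truth table.
#'
#' @param name Fixture name.
#' @return `table4_counts`: a data.frame `class`, `n`, `ltfu_count`,
#'   `high_vl_count`. `toy_notes`: a list with `notes` and `truth`
#'   data.frames.
#' @export
load_fixture <- function(name) {
  known <- c("table4_counts", "toy_notes")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available fixtures: ",
         paste(known, collapse = ", "), call. = FALSE)
  ext <- function(f) system.file("extdata", f, package = "phenolca")
  switch(name,
         table4_counts = utils::read.csv(ext("table4_counts.csv")),
         toy_notes = list(notes = read_notes_jsonl(ext("toy_notes.jsonl")),
                          truth = utils::read.csv(ext("toy_notes_truth.csv"),
                                                  check.names = FALSE)))
}

#' Reproduce the published outcome odds-ratio table from packaged counts
#'
#' Runs the odds-ratio engine on the `table4_counts` fixture: for each class
#' and each outcome, the 2x2 table against the reference class is formed from
#' the printed class sizes and outcome counts.
#'
#' @param reference Reference class (default 1).
#' @return Data.frame with one row per (class, outcome): `class`, `outcome`,
#'   `events`, `n`, `percent`, `or`, `ci_low`, `ci_high`, `p_value`
#'   (reference rows carry `NA` estimates).
#' @export
reproduce_table4 <- function(reference = 1L) {
  counts <- load_fixture("table4_counts")
  ref <- counts[counts$class == reference, ]
  rows <- list()
  for (outc in c("ltfu", "high_vl")) {
    cc <- paste0(outc, "_count")
    for (i in seq_len(nrow(counts))) {
      ev <- counts[[cc]][i]; n <- counts$n[i]
      row <- data.frame(class = counts$class[i], outcome = outc, events = ev, n = n,
                        percent = round(100 * ev / n, 1),
                        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_)
      if (counts$class[i] != reference) {
        orr <- odds_ratio(ev, n - ev, ref[[cc]], ref$n - ref[[cc]])
        row$or <- orr$or_point; row$ci_low <- orr$ci_low
        row$ci_high <- orr$ci_high; row$p_value <- orr$p_value
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
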