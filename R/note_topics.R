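#' Tokenize clinical-note text
#'
#' Lowercases and splits on any run of non-alphanumeric characters, so
#' `"HIV-1 viral load"` becomes `c("hiv", "1", "viral", "load")`. This is the
#' word definition used throughout the windowed negation matcher: window
#' distances are counted in these tokens.
#'
#' @param text A character string (length 1; may be empty or `NA`).
#' @return A character vector of lowercase tokens; `character(0)` for empty
#'   input.
#' @examples
#' tokenize("No, denies Depression.")
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("tokenize() expects a single string", call. = FALSE)
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Construct a topic lexicon
#'
#' A lexicon maps each clinical topic to the token sequences whose exact
#' occurrence marks the topic present, plus single-word exclusion terms that
#' suppress a mention when found within `window` words of it.
#'
#' @param entries Named list: one element per topic, each a list with
#'   `include` (character vector; elements may be multi-word phrases),
#'   `exclude` (character vector of single words; default `c("no", "neg")`)
#'   and `window` (integer word count, default 3).
#' @return An object of class `topic_lexicon`.
#' @export
topic_lexicon <- function(entries) {
  if (!is.list(entries) || length(entries) == 0L)
    stop("lexicon must be a non-empty named list of topic entries", call. = FALSE)
  nm <- names(entries)
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm)))
    stop("every lexicon entry must be named by its topic", call. = FALSE)
  if (anyDuplicated(nm)) stop("duplicate topic names in lexicon", call. = FALSE)
  entries <- lapply(entries, function(e) {
    inc <- as.character(unlist(e$include, use.names = FALSE))
    if (length(inc) == 0L || any(!nzchar(inc)))
      stop("each topic needs at least one non-empty include token", call. = FALSE)
    exc <- e$exclude
    if (is.null(exc)) exc <- c("no", "neg")
    exc <- tolower(as.character(unlist(exc, use.names = FALSE)))
    win <- e$window
    if (is.null(win)) win <- 3L
    win <- as.integer(win)
    if (is.na(win) || win < 1L) stop("window must be >= 1", call. = FALSE)
    # pre-tokenize include phrases once; an include phrase must survive
    # tokenization (e.g. "hiv-1" -> c("hiv","1"))
    inc_tok <- lapply(inc, tokenize)
    if (any(lengths(inc_tok) == 0L))
      stop("include token tokenizes to nothing: ", paste(inc[lengths(inc_tok) == 0L], collapse = ", "),
           call. = FALSE)
    list(include = inc, include_tokens = inc_tok, exclude = exc, window = win)
  })
  structure(entries, class = "topic_lexicon")
}

#' @export
print.topic_lexicon <- function(x, ...) {
  cat("<topic_lexicon> ", length(x), " topics: ",
      paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write a lexicon as JSON
#'
#' The on-disk format is `{"topic": {"include": [...], "exclude": [...],
#' "window": 3}, ...}`.
#'
#' @param path Path to a JSON lexicon file.
#' @return `read_lexicon()` returns a `topic_lexicon`.
#' @export
read_lexicon <- function(path) {
  topic_lexicon(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_lexicon
#' @param lexicon A `topic_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  out <- lapply(unclass(lexicon), function(e)
    list(include = e$include, exclude = e$exclude, window = e$window))
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Default 12-topic lexicon
#'
#' Ships illustrative include tokens for the twelve clinical topics reported
#' in HIV-care phenotyping (opportunistic infection, comorbidities, adherence,
#' sexual and gender minorities, heterosexual, life stressors, mental illness,
#' pregnancy, preventive health, STI, substance use disorder). The real
#' token lists used in the source study are not public; these defaults are
#' user-replaceable via [read_lexicon()].
#'
#' @return A `topic_lexicon` with 12 topics.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "default_lexicon.json", package = "phenolca"))
}

# find all contiguous occurrences of phrase `ph` (character vector of tokens)
# in `tokens`; returns integer start positions (1-based), possibly empty
.find_phrase <- function(tokens, ph) {
  k <- length(ph)
  n <- length(tokens)
  if (n < k) return(integer(0))
  hits <- which(tokens == ph[1L])
  if (k > 1L) {
    hits <- hits[hits + k - 1L <= n]
    for (j in seq_len(k - 1L)) hits <- hits[tokens[hits + j] == ph[j + 1L]]
  }
  hits
}

#' Match one topic in a tokenized note
#'
#' Returns 1 iff at least one occurrence of an include phrase has no exclusion
#' term within `window` whole words on either side of the matched span (the
#' window is measured from the span's outermost token on each side; exclusion
#' terms match whole tokens only, so "nose" never negates). Only exact token
#' matching is performed: no stemming, no fuzzy match.
#'
#' @param tokens Character vector from [tokenize()].
#' @param entry One element of a `topic_lexicon`.
#' @param window Optional window override (integer >= 1); defaults to the
#'   entry's own window.
#' @return Integer 0 or 1.
#' @export
match_topic <- function(tokens, entry, window = NULL) {
  win <- if (is.null(window)) entry$window else as.integer(window)
  if (is.na(win) || win < 1L) stop("window must be >= 1", call. = FALSE)
  n <- length(tokens)
  for (ph in entry$include_tokens) {
    k <- length(ph)
    for (s in .find_phrase(tokens, ph)) {
      lo <- max(1L, s - win)
      hi <- min(n, s + k - 1L + win)
      ctx <- tokens[c(seq2(lo, s - 1L), seq2(s + k, hi))]
      if (!any(ctx %in% entry$exclude)) return(1L)
    }
  }
  0L
}

# base::seq_len-safe ascending sequence (empty when from > to)
seq2 <- function(from, to) if (from > to) integer(0) else from:to

#' Annotate a note corpus with topic flags
#'
#' Applies [match_topic()] to every note for every lexicon topic. A topic is
#' marked absent when none of its include tokens occur or every occurrence is
#' suppressed by a nearby exclusion term.
#'
#' @param corpus A data.frame with columns `visit_id` and `text`, or a path to
#'   a JSONL file of `{"visit_id": ..., "text": ...}` records.
#' @param lexicon A `topic_lexicon`.
#' @param window Optional window override applied to every topic.
#' @return A data.frame: `visit_id` plus one 0/1 column per topic, one row per
#'   corpus record, in corpus order.
#' @export
annotate_corpus <- function(corpus, lexicon, window = NULL) {
  if (is.character(corpus) && length(corpus) == 1L) corpus <- read_notes_jsonl(corpus)
  stopifnot(is.data.frame(corpus), all(c("visit_id", "text") %in% names(corpus)))
  if (anyDuplicated(corpus$visit_id))
    stop("duplicate visit_id in note corpus: ",
         paste(unique(corpus$visit_id[duplicated(corpus$visit_id)]), collapse = ", "),
         call. = FALSE)
  if (!inherits(lexicon, "topic_lexicon")) lexicon <- topic_lexicon(lexicon)
  topics <- names(lexicon)
  flags <- matrix(0L, nrow = nrow(corpus), ncol = length(topics),
                  dimnames = list(NULL, topics))
  for (i in seq_len(nrow(corpus))) {
    toks <- tokenize(corpus$text[i])
    for (t in topics) flags[i, t] <- match_topic(toks, lexicon[[t]], window)
  }
  cbind(data.frame(visit_id = corpus$visit_id, stringsAsFactors = FALSE),
        as.data.frame(flags))
}

#' Read / write note corpora as JSONL
#'
#' One JSON object per line: `{"visit_id": ..., "text": ...}`.
#'
#' @param path File path.
#' @return `read_notes_jsonl()` returns a data.frame with `visit_id`, `text`.
#' @export
read_notes_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(visit_id = vapply(recs, function(r) as.character(r$visit_id), ""),
             text = vapply(recs, function(r) as.character(r$text), ""),
             stringsAsFactors = FALSE)
}

#' @rdname read_notes_jsonl
#' @param notes A data.frame with `visit_id` and `text` columns.
#' @export
write_notes_jsonl <- function(notes, path) {
  con <- file(path, open = "wb")  # binary mode: byte-identical across platforms
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    writeLines(jsonlite::toJSON(list(visit_id = notes$visit_id[i], text = notes$text[i]),
                                auto_unbox = TRUE),
               con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}
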