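# Literature sentence mining: clean article text, segment sentences, extract
# key phrases (RAKE-style degree/frequency scoring), and select the relevant
# sentences -- those containing at least one main term (exact token match)
# and one connection word (token-prefix match against truncated lemmas such
# as "decreas", "relat").

# Compact English stopword list (standard function words) used by the
# RAKE-style phrase extractor.
.stopwords <- c(
  "a", "about", "above", "after", "again", "against", "all", "also", "am",
  "an", "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "cannot", "could",
  "did", "do", "does", "doing", "down", "during", "each", "few", "for",
  "from", "further", "had", "has", "have", "having", "he", "her", "here",
  "hers", "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
  "itself", "just", "more", "most", "my", "no", "nor", "not", "now", "of",
  "off", "on", "once", "only", "or", "other", "our", "ours", "out", "over",
  "own", "same", "she", "should", "so", "some", "such", "than", "that",
  "the", "their", "theirs", "them", "then", "there", "these", "they",
  "this", "those", "through", "to", "too", "under", "until", "up", "very",
  "was", "we", "were", "what", "when", "where", "which", "while", "who",
  "whom", "why", "will", "with", "would", "you", "your", "yours"
)

#' Mining configuration
#'
#' Main terms are matched as whole tokens (case-insensitive); connection
#' words are matched by token prefix, reproducing truncated lemmas
#' ("decreas" matches "decreases", "decreasing", ...). Defaults are the
#' published term lists for acute aquatic toxicity.
#'
#' @param main_terms lowercase terms, at least one of which must appear in a
#'   relevant sentence.
#' @param connection_stems lowercase stems, at least one of which must
#'   prefix-match a token in a relevant sentence.
#' @param match_mode `"prefix"` (stems match token prefixes, default) or
#'   `"exact"`.
#' @return list of class `mining_config`.
#' @export
mining_config <- function(
    main_terms = c("toxicity", "acute", "lc50", "ec50"),
    connection_stems = c("increase", "decreas", "relat", "correlate",
                         "structure", "fragment", "class", "significant",
                         "high", "affect", "low", "link", "reason",
                         "determin", "predict", "influence", "severe",
                         "depend"),
    match_mode = c("prefix", "exact")) {
  match_mode <- match.arg(match_mode)
  check <- function(x, what) {
    assert_that(is.character(x) && length(x) > 0, paste(what, "must be non-empty"),
                class = "toxhybrid_config_error")
    assert_that(all(x == tolower(x)), paste(what, "must be lowercase"),
                class = "toxhybrid_config_error")
    assert_that(!anyDuplicated(x), paste(what, "must not contain duplicates"),
                class = "toxhybrid_config_error")
  }
  check(main_terms, "main_terms")
  check(connection_stems, "connection_stems")
  structure(list(main_terms = main_terms, connection_stems = connection_stems,
                 match_mode = match_mode),
            class = "mining_config")
}

#' Clean article text
#'
#' Removes front matter (everything up to and including a configurable
#' abstract-end marker), the reference block (everything from a
#' references-start marker on), and collapses runs of whitespace to single
#' spaces.
#'
#' @param text the raw article text (single string).
#' @param abstract_end regex marking the end of the front matter; `NULL`
#'   keeps the head. Default matches an "Introduction" heading.
#' @param references_start regex marking the start of the reference block;
#'   `NULL` keeps the tail. Default matches a "References"/"Bibliography"
#'   heading.
#' @return the cleaned body text.
#' @export
clean_text <- function(text,
                       abstract_end = "\\bIntroduction\\b",
                       references_start = "\\b(References|Bibliography)\\b") {
  assert_that(is.character(text) && length(text) == 1L,
              "text must be a single string")
  if (!nzchar(trimws(text))) {
    th_stop("empty document", "toxhybrid_empty_error")
  }
  body <- text
  if (!is.null(abstract_end)) {
    m <- regexpr(abstract_end, body)
    if (m > 0) body <- substr(body, m + attr(m, "match.length"), nchar(body))
  }
  if (!is.null(references_start)) {
    m <- regexpr(references_start, body)
    if (m > 0) body <- substr(body, 1, m - 1)
  }
  body <- gsub("\\s+", " ", body)
  trimws(body)
}

#' Split text into sentences
#'
#' Rule-based segmentation on terminal `.`, `!`, `?` followed by whitespace
#' and an uppercase/digit start, with a protected-abbreviation list
#' ("Fig.", "et al.", ...) that never splits. The concatenation of the
#' result reconstructs the body modulo whitespace.
#'
#' @param body_text cleaned text (see [clean_text()]).
#' @param protected abbreviations that must not end a sentence.
#' @return character vector of sentences (empty for empty input).
#' @export
split_sentences <- function(body_text,
                            protected = c("Fig.", "Figs.", "Tab.", "et al.",
                                          "e.g.", "i.e.", "vs.", "cf.",
                                          "approx.", "No.")) {
  assert_that(is.character(body_text) && length(body_text) == 1L,
              "body_text must be a single string")
  if (!nzchar(trimws(body_text))) return(character(0))
  txt <- body_text
  # shield protected abbreviations (replace their dot with a placeholder)
  shield <- vapply(protected, function(p) gsub(".", "\x01", p, fixed = TRUE),
                   character(1))
  for (i in seq_along(protected)) {
    txt <- gsub(protected[i], shield[i], txt, fixed = TRUE)
  }
  # also shield dots inside decimal numbers
  txt <- gsub("(?<=[0-9])\\.(?=[0-9])", "\x01", txt, perl = TRUE)
  parts <- strsplit(txt, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- gsub("\x01", ".", parts, fixed = TRUE)
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Extract key phrases
#'
#' RAKE-style extraction: candidate phrases are maximal stopword-free token
#' runs; each word scores degree/frequency over the co-occurrence graph and
#' a phrase scores the sum of its word scores. Deterministic; ties broken
#' lexicographically.
#'
#' @param body_text cleaned text.
#' @param top_n number of phrases to return.
#' @return data.frame with `phrase` and `score`, scores non-increasing.
#' @export
extract_keyphrases <- function(body_text, top_n = 10) {
  assert_that(is_count(top_n), "top_n must be a positive integer",
              class = "toxhybrid_parameter_error")
  sentences <- split_sentences(body_text)
  if (length(sentences) == 0) {
    return(data.frame(phrase = character(0), score = numeric(0)))
  }
  phrases <- unlist(lapply(sentences, function(s) {
    toks <- tokenize(s)
    if (length(toks) == 0) return(character(0))
    stop_mask <- toks %in% .stopwords
    runs <- split(toks[!stop_mask], cumsum(stop_mask)[!stop_mask])
    vapply(runs, paste, "", collapse = " ")
  }))
  phrases <- phrases[nzchar(phrases)]
  if (length(phrases) == 0) {
    return(data.frame(phrase = character(0), score = numeric(0)))
  }
  words_by_phrase <- strsplit(phrases, " ", fixed = TRUE)
  freq <- table(unlist(words_by_phrase))
  degree <- tapply(
    rep(vapply(words_by_phrase, length, 0L), vapply(words_by_phrase, length, 0L)),
    unlist(words_by_phrase), sum)
  wscore <- degree[names(freq)] / as.numeric(freq)
  pscore <- vapply(words_by_phrase, function(w) sum(wscore[w]), numeric(1))
  agg <- tapply(pscore, phrases, max)
  ord <- order(-as.numeric(agg), names(agg))
  res <- data.frame(phrase = names(agg)[ord], score = as.numeric(agg)[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  utils::head(res, top_n)
}

# Matching predicate for one sentence: returns the matched main terms and
# connection stems (empty vectors when not relevant).
match_sentence <- function(text, cfg) {
  toks <- unique(tokenize(text))
  mains <- cfg$main_terms[cfg$main_terms %in% toks]
  stems <- if (cfg$match_mode == "prefix") {
    cfg$connection_stems[vapply(cfg$connection_stems,
                                function(s) any(startsWith(toks, s)), logical(1))]
  } else {
    cfg$connection_stems[cfg$connection_stems %in% toks]
  }
  list(main = mains, stems = stems,
       relevant = length(mains) > 0 && length(stems) > 0)
}

#' Extract relevant sentences
#'
#' A sentence is relevant iff it contains at least one main term (exact
#' token match after lowercasing) and at least one token prefix-matching a
#' connection stem. Order is preserved; matches are recorded.
#'
#' @param sentences character vector (see [split_sentences()]).
#' @param cfg a [mining_config()].
#' @param doc_id document identifier recorded in the result.
#' @return data.frame with `doc_id`, `sentence_index` (position in input),
#'   `text`, `matched_main_terms`, `matched_connection_stems` (both
#'   `;`-joined).
#' @export
extract_relevant <- function(sentences, cfg = mining_config(), doc_id = "doc") {
  stopifnot(inherits(cfg, "mining_config"))
  if (length(sentences) == 0) {
    return(data.frame(doc_id = character(0), sentence_index = integer(0),
                      text = character(0), matched_main_terms = character(0),
                      matched_connection_stems = character(0)))
  }
  hits <- lapply(sentences, match_sentence, cfg = cfg)
  rel <- vapply(hits, `[[`, logical(1), "relevant")
  if (!any(rel)) {
    return(data.frame(doc_id = character(0), sentence_index = integer(0),
                      text = character(0), matched_main_terms = character(0),
                      matched_connection_stems = character(0)))
  }
  data.frame(
    doc_id = doc_id,
    sentence_index = which(rel),
    text = sentences[rel],
    matched_main_terms = vapply(hits[rel], function(h) paste(h$main, collapse = ";"), ""),
    matched_connection_stems = vapply(hits[rel], function(h) paste(h$stems, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
}

#' Mine a corpus of article files
#'
#' Applies clean / segment / select to each UTF-8 text file and reports the
#' per-document sentence reduction achieved by the relevance filter.
#'
#' @param paths character vector of `.txt` files, or a directory (all
#'   `.txt` files within).
#' @param cfg a [mining_config()].
#' @param ... passed to [clean_text()].
#' @return list with `sentences` (stacked [extract_relevant()] output) and
#'   `report` (per-document total/relevant counts and `reduction_pct`, the
#'   percentage of sentences removed).
#' @export
mine_corpus <- function(paths, cfg = mining_config(), ...) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.txt$", full.names = TRUE)
  }
  assert_that(length(paths) > 0 && all(file.exists(paths)),
              "no input files found", class = "toxhybrid_io_error")
  res <- lapply(paths, function(p) {
    doc_id <- sub("\\.txt$", "", basename(p))
    body <- clean_text(paste(readLines(p, warn = FALSE, encoding = "UTF-8"),
                             collapse = "\n"), ...)
    sents <- split_sentences(body)
    rel <- extract_relevant(sents, cfg, doc_id = doc_id)
    list(rel = rel,
         report = data.frame(doc_id = doc_id, n_sentences = length(sents),
                             n_relevant = nrow(rel),
                             reduction_pct = if (length(sents) > 0)
                               100 * (1 - nrow(rel) / length(sents)) else NA_real_))
  })
  list(sentences = do.call(rbind, lapply(res, `[[`, "rel")),
       report = do.call(rbind, lapply(res, `[[`, "report")))
}
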