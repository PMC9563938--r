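#' Default English stopword list
#'
#' A fixed list shipped with the package (articles, conjunctions, prepositions,
#' pronouns, auxiliaries and a handful of publication boilerplate words).
#' Preprocessing removes these before vectorization; pass your own character
#' vector to [preprocess_abstract()] to override.
#'
#' @return Character vector of lowercase stopwords.
#' @export
english_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "semhub")
  readLines(path, warn = FALSE)
}

# Irregular plural table for the pinned rule lemmatizer.
.LEMMA_IRREGULAR <- c(
  men = "man", women = "woman", children = "child", teeth = "tooth",
  feet = "foot", mice = "mouse", people = "person",
  analyses = "analysis", diagnoses = "diagnosis", prognoses = "prognosis",
  crises = "crisis", hypotheses = "hypothesis", metastases = "metastasis",
  stenoses = "stenosis", fibroses = "fibrosis", thromboses = "thrombosis",
  criteria = "criterion", phenomena = "phenomenon", bacteria = "bacterium",
  sera = "serum", genera = "genus"
)

#' Lemmatize tokens with the pinned rule set
#'
#' The package pins a small deterministic English noun-plural lemmatizer
#' (`"semhub-rules"`, version 1): an irregular-plural table followed by
#' suffix rules (`-ies` to `-y`; `-sses`/`-xes`/`-ches`/`-shes`/`-zes` drop
#' `-es`; a trailing `-s` not preceded by `s`/`u`/`i` is dropped). Verb forms
#' are left untouched, so `"reported"` stays `"reported"`. The identity and
#' version of the lemmatizer are recorded in the attribute
#' `lemmatizer` of the result so processed corpora are self-describing.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of lemmas, same length; attribute `lemmatizer`
#'   gives the rule-set identity.
#' @export
lemmatize <- function(tokens) {
  out <- tokens
  hit <- out %in% names(.LEMMA_IRREGULAR)
  out[hit] <- .LEMMA_IRREGULAR[out[hit]]
  reg <- !hit & nchar(out) > 3L
  ies <- reg & grepl("ies$", out)
  out[ies] <- sub("ies$", "y", out[ies])
  es <- reg & !ies & grepl("(sses|xes|ches|shes|zes)$", out)
  out[es] <- sub("es$", "", out[es])
  s <- reg & !ies & !es & grepl("[^sui]s$", out)
  out[s] <- sub("s$", "", out[s])
  attr(out, "lemmatizer") <- "semhub-rules v1"
  out
}

#' Tokenize free text
#'
#' Lowercases, splits on any non-alphanumeric character, and drops tokens
#' with no alphabetic character (pure numbers and punctuation fragments).
#'
#' @param text Character scalar.
#' @return Character vector of lowercase tokens in order of appearance.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1]]
  toks[grepl("[a-z]", toks)]
}

#' Preprocess one abstract record
#'
#' Tokenizes, removes stopwords, and lemmatizes. Records with empty text are
#' rejected with a warning and return `NULL` (not an error), so corpus-level
#' processing can skip them.
#'
#' @param record List with fields `id` and `text` (see [read_abstracts_jsonl()]).
#' @param stopwords Character vector of stopwords; defaults to the shipped
#'   English list.
#' @return A `tokenized_doc`: list with `id` and `tokens`, or `NULL` for an
#'   empty record.
#' @examples
#' preprocess_abstract(list(id = "a1", text = "Patients reported rashes"))
#' @export
preprocess_abstract <- function(record, stopwords = english_stopwords()) {
  txt <- trimws(record$text %||% "")
  if (!nzchar(txt)) {
    warning("record '", record$id, "' has empty text; skipped", call. = FALSE)
    return(NULL)
  }
  toks <- tokenize(txt)
  toks <- toks[!(toks %in% stopwords)]
  toks <- as.character(lemmatize(toks))
  structure(list(id = record$id, tokens = toks), class = "tokenized_doc")
}

#' Preprocess a list of abstract records
#'
#' @param records List of abstract records (each with `id`, `text`).
#' @param stopwords Character vector of stopwords.
#' @return List of `tokenized_doc` objects; empty-text records are dropped
#'   with one warning each. Ids must be unique.
#' @export
preprocess_corpus <- function(records, stopwords = english_stopwords()) {
  ids <- vapply(records, function(r) as.character(r$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate abstract ids in corpus")
  docs <- lapply(records, preprocess_abstract, stopwords = stopwords)
  docs[!vapply(docs, is.null, logical(1))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
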