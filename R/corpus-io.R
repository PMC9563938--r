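#' Read a JSON-lines abstract corpus
#'
#' One JSON object per line with fields `id`, `title`, `abstract`. Title and
#' abstract are concatenated into the record's `text`.
#'
#' @param path Path to a `.jsonl` file.
#' @return List of abstract records (`id`, `text`).
#' @export
read_abstracts_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("malformed JSON on line ", i, ": ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(obj$id)) stop("missing 'id' on line ", i, call. = FALSE)
    list(id = as.character(obj$id),
         text = trimws(paste(obj$title %||% "", obj$abstract %||% "")))
  })
  ids <- vapply(recs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate abstract ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  recs
}

#' Write abstracts as JSON-lines
#'
#' @param records List of abstract records (`id`, `text`; an optional `title`
#'   field is emitted separately, otherwise the whole text goes to `abstract`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abstracts_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(id = r$id, title = r$title %||% "",
                          abstract = if (is.null(r$title)) r$text else r$abstract),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a MEDLINE-style flat-text corpus
#'
#' Minimal reader for records separated by blank lines, with `PMID-`, `TI  -`
#' and `AB  -` tagged fields (continuation lines indented). Title and abstract
#' are concatenated into `text`.
#'
#' @param path Path to the flat file.
#' @return List of abstract records (`id`, `text`).
#' @export
read_abstracts_medline <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL; field <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id)) return(NULL)
    list(id = cur$id, text = trimws(paste(cur$TI %||% "", cur$AB %||% "")))
  }
  for (ln in c(lines, "")) {
    if (!nzchar(trimws(ln))) {
      r <- flush(cur)
      if (!is.null(r)) recs[[length(recs) + 1L]] <- r
      cur <- NULL; field <- NULL
      next
    }
    if (grepl("^[A-Z]+\\s*-", ln)) {
      tag <- trimws(sub("-.*$", "", ln))
      val <- trimws(sub("^[A-Z]+\\s*-\\s*", "", ln))
      if (is.null(cur)) cur <- list()
      if (tag == "PMID") { cur$id <- val; field <- NULL }
      else if (tag %in% c("TI", "AB")) { cur[[tag]] <- paste(c(cur[[tag]], val), collapse = " "); field <- tag }
      else field <- NULL
    } else if (!is.null(field) && grepl("^\\s", ln)) {
      cur[[field]] <- paste(cur[[field]], trimws(ln))
    }
  }
  ids <- vapply(recs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate PMIDs in MEDLINE file")
  recs
}

#' Export a TF-IDF result as MatrixMarket plus sidecar files
#'
#' Writes `<stem>.mtx` (sparse docs x terms weights), `<stem>.terms.txt`
#' (vocabulary, one per line) and `<stem>.docs.txt` (document ids).
#'
#' @param tfidf A [build_tfidf()] result.
#' @param stem Output path stem (no extension).
#' @return Character vector of the three paths written, invisibly.
#' @export
write_tfidf <- function(tfidf, stem) {
  stopifnot(inherits(tfidf, "tfidf_result"))
  paths <- paste0(stem, c(".mtx", ".terms.txt", ".docs.txt"))
  Matrix::writeMM(tfidf$matrix, paths[1])
  writeLines(tfidf$vocabulary, paths[2])
  writeLines(tfidf$doc_ids, paths[3])
  invisible(paths)
}
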