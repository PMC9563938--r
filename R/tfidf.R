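#' Build a bounded-vocabulary TF-IDF matrix
#'
#' Terms are retained when their document frequency (fraction of documents
#' containing the term at least once) lies inside the inclusive interval
#' `[min_df, max_df]`; the defaults keep terms occurring in between 1% and
#' 85% of the documents. Weights use the smoothed convention
#' `tf * (ln((1 + N) / (1 + df_count)) + 1)` with `tf` the raw in-document
#' count, followed by L2 row normalization, so every document with at least
#' one retained term has unit Euclidean norm. Vocabulary columns are in
#' lexicographic (C-locale) order.
#'
#' @param docs List of `tokenized_doc` objects (see [preprocess_corpus()]).
#' @param min_df,max_df Inclusive document-frequency bounds as fractions.
#' @param normalize L2-normalize rows (default `TRUE`).
#' @return A `tfidf_result`: list with `doc_ids`, `vocabulary`, `matrix`
#'   (sparse `dgCMatrix`, docs x terms), and `df` (per-term document
#'   frequency as a fraction).
#' @export
build_tfidf <- function(docs, min_df = 0.01, max_df = 0.85, normalize = TRUE) {
  n <- length(docs)
  if (n < 2L) stop("need at least 2 documents")
  stopifnot(min_df >= 0, min_df < max_df, max_df <= 1)
  ids <- vapply(docs, `[[`, character(1), "id")

  # document-frequency counts over presence
  df_tab <- table(unlist(lapply(docs, function(d) unique(d$tokens))))
  df_count <- as.integer(df_tab)
  names(df_count) <- names(df_tab)
  df_frac <- df_count / n
  keep <- df_frac >= min_df & df_frac <= max_df
  vocab <- sort(names(df_count)[keep], method = "radix")
  if (length(vocab) == 0L)
    stop("vocabulary empty after document-frequency filtering with bounds [",
         min_df, ", ", max_df, "]")

  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (d in seq_len(n)) {
    tab <- table(docs[[d]]$tokens)
    idx <- match(names(tab), vocab)
    ok <- !is.na(idx)
    i <- c(i, rep.int(d, sum(ok))); j <- c(j, idx[ok]); x <- c(x, as.numeric(tab)[ok])
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, length(vocab)),
                            dimnames = list(ids, vocab))
  idf <- log((1 + n) / (1 + df_count[vocab])) + 1
  m <- m %*% Matrix::Diagonal(x = unname(idf))
  if (normalize) {
    nrm <- sqrt(Matrix::rowSums(m^2))
    nrm[nrm == 0] <- 1
    m <- Matrix::Diagonal(x = 1 / nrm) %*% m
  }
  m <- as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(m) <- list(ids, vocab)
  structure(list(doc_ids = ids, vocabulary = vocab, matrix = m,
                 df = unname(df_frac[vocab])),
            class = "tfidf_result")
}

#' Reduce a TF-IDF matrix by truncated SVD
#'
#' Exact singular-value decomposition truncated to `n_components` (default
#' 50), the latent representation used for clustering. Deterministic: the
#' sign of each component is fixed so its largest-magnitude loading is
#' positive, making results independent of the `seed` argument (kept for
#' interface stability).
#'
#' @param tfidf A `tfidf_result`.
#' @param n_components Number of components to retain; requesting more than
#'   `min(docs, terms)` is an error, never a silent clamp.
#' @param seed Unused by the exact decomposition; accepted for call-site
#'   uniformity with stochastic reducers.
#' @return A `reduced_matrix`: `doc_ids`, `components` (docs x n_components),
#'   `n_components`, and `variance` (per-component explained variance,
#'   non-increasing).
#' @export
reduce_dimensions <- function(tfidf, n_components = 50L, seed = NULL) {
  stopifnot(inherits(tfidf, "tfidf_result"), n_components >= 1L)
  m <- as.matrix(tfidf$matrix)
  if (n_components > min(dim(m)))
    stop("n_components (", n_components, ") exceeds min(docs, terms) = ",
         min(dim(m)))
  sv <- svd(m, nu = n_components, nv = n_components)
  d <- sv$d[seq_len(n_components)]
  comp <- sv$u %*% diag(d, nrow = n_components)
  # sign convention: largest |loading| of each right-singular vector positive
  for (k in seq_len(n_components)) {
    piv <- which.max(abs(sv$v[, k]))
    if (sv$v[piv, k] < 0) comp[, k] <- -comp[, k]
  }
  rownames(comp) <- tfidf$doc_ids
  structure(list(doc_ids = tfidf$doc_ids, components = comp,
                 n_components = as.integer(n_components),
                 variance = d^2 / nrow(m)),
            class = "reduced_matrix")
}

#' Project documents to two dimensions for visualization
#'
#' Deterministic linear projection onto the two leading principal axes of the
#' centered reduced matrix. Intended only for plotting cluster structure;
#' distances are faithful to the leading variance directions, not to local
#' neighborhoods.
#'
#' @param reduced A `reduced_matrix`.
#' @param seed Unused by the deterministic projection; accepted for call-site
#'   uniformity.
#' @return Numeric matrix, docs x 2, rownames = doc ids.
#' @export
embed_2d <- function(reduced, seed = NULL) {
  stopifnot(inherits(reduced, "reduced_matrix"))
  x <- reduced$components
  if (nrow(x) < 3L) stop("need at least 3 documents")
  xc <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = 2L, nv = 2L)
  out <- sv$u[, 1:2, drop = FALSE] %*% diag(sv$d[1:2], nrow = 2L)
  for (k in 1:2) {
    piv <- which.max(abs(sv$v[, k]))
    if (sv$v[piv, k] < 0) out[, k] <- -out[, k]
  }
  dimnames(out) <- list(reduced$doc_ids, c("dim1", "dim2"))
  out
}
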