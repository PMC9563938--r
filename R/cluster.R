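#' K-means clustering of documents
#'
#' Standard k-means (Lloyd/Hartigan-Wong via [stats::kmeans()]) on the
#' reduced document representation, with `nstart` restarts under an explicit
#' seed so runs are reproducible. The default `k = 30` reflects the typical
#' working granularity for a corpus of a few thousand abstracts; `k` is a
#' free parameter.
#'
#' @param reduced A `reduced_matrix` from [reduce_dimensions()].
#' @param k Number of clusters (1 <= k <= number of documents).
#' @param seed Integer seed controlling initialization.
#' @param nstart Number of random restarts (default 10).
#' @return A `cluster_assignment`: `doc_ids`, `labels` (integer cluster ids
#'   in `[0, k)`), `k`, and `inertia` (total within-cluster sum of squares).
#' @export
cluster_docs <- function(reduced, k = 30L, seed = 1L, nstart = 10L) {
  stopifnot(inherits(reduced, "reduced_matrix"), k >= 1L)
  n <- nrow(reduced$components)
  if (k > n) stop("k (", k, ") exceeds number of documents (", n, ")")
  set.seed(seed)
  if (k == 1L) {
    ctr <- colMeans(reduced$components)
    labels <- rep.int(0L, n)
    inertia <- sum(sweep(reduced$components, 2, ctr)^2)
  } else {
    km <- stats::kmeans(reduced$components, centers = k, nstart = nstart,
                        iter.max = 100L)
    labels <- as.integer(km$cluster) - 1L
    inertia <- km$tot.withinss
  }
  structure(list(doc_ids = reduced$doc_ids, labels = labels,
                 k = as.integer(k), inertia = inertia),
            class = "cluster_assignment")
}

#' Top TF-IDF terms of a cluster
#'
#' Terms ordered by mean in-cluster TF-IDF weight, descending, ties broken
#' lexicographically. Inspecting the top terms (default 200) of each cluster
#' is how clusters are screened for drug relevance.
#'
#' @param assignment A `cluster_assignment`.
#' @param tfidf The matching `tfidf_result`.
#' @param cluster Cluster id in `[0, k)`.
#' @param n Number of terms to return; larger than the vocabulary returns it
#'   all.
#' @return Character vector of terms (possibly empty, with a warning, for an
#'   empty cluster).
#' @export
top_cluster_terms <- function(assignment, tfidf, cluster, n = 200L) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(tfidf, "tfidf_result"))
  idx <- which(assignment$labels == cluster)
  if (length(idx) == 0L) {
    warning("cluster ", cluster, " is empty")
    return(character(0))
  }
  mw <- Matrix::colSums(tfidf$matrix[idx, , drop = FALSE]) / length(idx)
  ord <- order(-mw, tfidf$vocabulary, method = "radix")
  head(tfidf$vocabulary[ord], n)
}

# document-level presence frequency of each term per cluster (and corpus)
.presence_counts <- function(assignment, docs, terms) {
  ids <- vapply(docs, `[[`, character(1), "id")
  docs <- docs[match(assignment$doc_ids, ids)]
  has <- vapply(docs, function(d) terms %in% d$tokens,
                logical(length(terms)))
  if (length(terms) == 1L) has <- matrix(has, nrow = 1L)
  rownames(has) <- terms
  has  # terms x docs logical
}

#' Map clusters to drugs by in-cluster drug-term frequency
#'
#' For each drug in the lexicon, finds the cluster where the drug term's
#' document frequency is maximal. A cluster is reported only when that
#' frequency exceeds `min_freq`. When two or more drugs tie on frequency
#' within the same cluster, all are reported and the cluster is flagged
#' ambiguous rather than resolved silently.
#'
#' @param assignment A `cluster_assignment`.
#' @param docs The tokenized documents the assignment was built from.
#' @param drug_lexicon Non-empty character vector of drug terms (lowercase
#'   lemmas).
#' @param min_freq Minimum in-cluster frequency for a mapping (default 0).
#' @return Data frame with columns `cluster`, `drug`, `freq`, `ambiguous`.
#'   Drugs absent from the corpus are unmapped, with a warning.
#' @export
map_clusters_to_drugs <- function(assignment, docs, drug_lexicon,
                                  min_freq = 0) {
  stopifnot(length(drug_lexicon) > 0L)
  has <- .presence_counts(assignment, docs, drug_lexicon)
  out <- list()
  for (drug in drug_lexicon) {
    if (!any(has[drug, ])) {
      warning("drug '", drug, "' absent from corpus; unmapped")
      next
    }
    freqs <- vapply(seq_len(assignment$k) - 1L, function(cl) {
      idx <- assignment$labels == cl
      if (!any(idx)) return(0)
      mean(has[drug, idx])
    }, numeric(1))
    best <- which.max(freqs) - 1L  # lowest cluster id on ties
    if (freqs[best + 1L] > min_freq)
      out[[length(out) + 1L]] <- data.frame(cluster = best, drug = drug,
                                            freq = freqs[best + 1L])
  }
  if (length(out) == 0L)
    return(data.frame(cluster = integer(0), drug = character(0),
                      freq = numeric(0), ambiguous = logical(0)))
  res <- do.call(rbind, out)
  res$ambiguous <- FALSE
  for (cl in unique(res$cluster)) {
    rows <- which(res$cluster == cl)
    if (length(rows) > 1L && length(unique(res$freq[rows])) < length(rows))
      res$ambiguous[rows[duplicated(res$freq[rows]) |
                           duplicated(res$freq[rows], fromLast = TRUE)]] <- TRUE
  }
  rownames(res) <- NULL
  res
}

#' Per-cluster AE term frequencies and fold changes
#'
#' Frequencies are document-level presence fractions (a term counts once per
#' document). `fold_change` is the in-cluster frequency divided by the
#' whole-corpus frequency; the per-term maximum across clusters is flagged in
#' `is_max` (the boldface analogue of a frequency table). Terms absent from
#' the corpus are excluded with a warning, keeping fold changes finite.
#'
#' @param assignment A `cluster_assignment`.
#' @param docs Tokenized documents.
#' @param terms AE term list (lowercase lemmas).
#' @return Data frame: `term`, `cluster`, `cluster_freq`, `corpus_freq`,
#'   `fold_change`, `is_max`.
#' @export
term_cluster_stats <- function(assignment, docs, terms) {
  has <- .presence_counts(assignment, docs, terms)
  present <- rowSums(has) > 0
  if (any(!present))
    warning("terms absent from corpus excluded: ",
            paste(terms[!present], collapse = ", "))
  terms <- terms[present]
  if (length(terms) == 0L)
    return(data.frame(term = character(0), cluster = integer(0),
                      cluster_freq = numeric(0), corpus_freq = numeric(0),
                      fold_change = numeric(0), is_max = logical(0)))
  has <- has[terms, , drop = FALSE]
  n <- length(assignment$labels)
  corpus_freq <- rowSums(has) / n
  res <- do.call(rbind, lapply(seq_len(assignment$k) - 1L, function(cl) {
    idx <- assignment$labels == cl
    cf <- if (any(idx)) rowSums(has[, idx, drop = FALSE]) / sum(idx) else
      rep(0, length(terms))
    data.frame(term = terms, cluster = cl, cluster_freq = unname(cf),
               corpus_freq = unname(corpus_freq),
               fold_change = unname(cf / corpus_freq))
  }))
  res$is_max <- FALSE
  for (tm in terms) {
    rows <- which(res$term == tm)
    res$is_max[rows] <- res$cluster_freq[rows] == max(res$cluster_freq[rows])
  }
  rownames(res) <- NULL
  res
}

#' Pairwise chi-square tests between cluster AE profiles
#'
#' For every unordered pair of the selected clusters, builds the AE-term by
#' cluster contingency table of document-presence counts and applies the
#' Pearson chi-square test of independence (no continuity correction). Term
#' rows whose expected count is zero (the term appears in neither cluster)
#' are dropped with a warning. Significance uses a Bonferroni-corrected
#' alpha: `family_alpha / choose(m, 2)` for `m` selected clusters.
#'
#' @param assignment A `cluster_assignment`.
#' @param docs Tokenized documents.
#' @param terms AE term list defining the profile.
#' @param clusters Integer vector of >= 2 cluster ids to compare.
#' @param family_alpha Family-wise alpha (default 0.05).
#' @return Data frame: `cluster_a`, `cluster_b`, `statistic`, `dof`,
#'   `p_value`, `corrected_alpha`, `significant`.
#' @export
pairwise_cluster_chisq <- function(assignment, docs, terms, clusters,
                                   family_alpha = 0.05) {
  stopifnot(length(clusters) >= 2L)
  has <- .presence_counts(assignment, docs, terms)
  m <- length(clusters)
  corrected_alpha <- family_alpha / choose(m, 2)
  counts <- vapply(clusters, function(cl) {
    idx <- assignment$labels == cl
    rowSums(has[, idx, drop = FALSE])
  }, numeric(length(terms)))
  colnames(counts) <- as.character(clusters)
  pairs <- utils::combn(seq_len(m), 2)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    tab <- counts[, c(a, b), drop = FALSE]
    keep <- rowSums(tab) > 0
    if (any(!keep))
      warning("pair (", clusters[a], ",", clusters[b],
              "): dropped zero-count term rows: ",
              paste(terms[!keep], collapse = ", "))
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) < 2L || any(colSums(tab) == 0))
      return(data.frame(cluster_a = clusters[a], cluster_b = clusters[b],
                        statistic = NA_real_, dof = NA_integer_,
                        p_value = NA_real_, corrected_alpha = corrected_alpha,
                        significant = NA))
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(cluster_a = clusters[a], cluster_b = clusters[b],
               statistic = unname(ct$statistic), dof = unname(ct$parameter),
               p_value = unname(ct$p.value), corrected_alpha = corrected_alpha,
               significant = unname(ct$p.value) < corrected_alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
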