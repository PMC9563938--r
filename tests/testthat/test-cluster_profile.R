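make_reduced <- function(comp, ids = sprintf("d%02d", seq_len(nrow(comp)))) {
  structure(list(doc_ids = ids, components = comp,
                 n_components = ncol(comp), variance = rep(1, ncol(comp))),
            class = "reduced_matrix")
}

test_that("k-means contract: k = 1, determinism, k > n error, planted recovery", {
  set.seed(3)
  comp <- rbind(matrix(rnorm(20 * 4), 20), matrix(rnorm(20 * 4, mean = 50), 20))
  rd <- make_reduced(comp)
  one <- cluster_docs(rd, k = 1, seed = 9)
  expect_true(all(one$labels == 0L))
  expect_error(cluster_docs(rd, k = 41, seed = 1), "exceeds")
  a <- cluster_docs(rd, k = 2, seed = 5)
  b <- cluster_docs(rd, k = 2, seed = 5)
  expect_identical(a$labels, b$labels)
  expect_true(all(a$labels %in% 0:1))
  # two planted well-separated groups recovered exactly (ARI = 1)
  truth <- rep(0:1, each = 20)
  expect_equal(mclust::adjustedRandIndex(a$labels, truth), 1)
})

test_that("top cluster terms order by mean in-cluster weight, ties lexicographic", {
  docs <- list(tokdoc("d1", c("anemia", "anemia", "rash")),
               tokdoc("d2", c("anemia", "nausea")),
               tokdoc("d3", c("edema")))
  tf <- build_tfidf(docs, min_df = 0, max_df = 1)
  asg <- structure(list(doc_ids = c("d1", "d2", "d3"),
                        labels = c(0L, 0L, 1L), k = 2L, inertia = 0),
                   class = "cluster_assignment")
  got <- top_cluster_terms(asg, tf, 0, n = 10)
  mw <- Matrix::colSums(tf$matrix[1:2, ]) / 2
  expect_identical(got, tf$vocabulary[order(-mw, tf$vocabulary)])
  expect_identical(got[1], "anemia")
  expect_length(top_cluster_terms(asg, tf, 1, n = 99), length(tf$vocabulary))
  asg$labels <- c(0L, 0L, 0L)
  expect_warning(out <- top_cluster_terms(asg, tf, 1), "empty")
  expect_identical(out, character(0))
})

test_that("cluster-drug mapping handles clear winners, absences and ties", {
  docs <- c(lapply(1:10, function(i)
              tokdoc(paste0("a", i), c(if (i <= 3) "imatinib", "x"))),
            lapply(1:10, function(i) tokdoc(paste0("b", i), "y")))
  asg <- structure(list(doc_ids = vapply(docs, `[[`, "", "id"),
                        labels = rep(0:1, each = 10), k = 2L, inertia = 0),
                   class = "cluster_assignment")
  expect_warning(map <- map_clusters_to_drugs(asg, docs,
                                              c("imatinib", "bosutinib")),
                 "bosutinib")
  expect_identical(map$drug, "imatinib")
  expect_identical(map$cluster, 0L)
  expect_equal(map$freq, 0.3)
  expect_false(map$ambiguous)

  # two drugs tied in the same cluster are both reported and flagged
  docs2 <- lapply(1:10, function(i)
    tokdoc(paste0("c", i), c(if (i <= 4) c("dasatinib", "nilotinib"), "z")))
  asg2 <- structure(list(doc_ids = vapply(docs2, `[[`, "", "id"),
                         labels = rep(0L, 10), k = 1L, inertia = 0),
                    class = "cluster_assignment")
  map2 <- map_clusters_to_drugs(asg2, docs2, c("dasatinib", "nilotinib"))
  expect_identical(sort(map2$drug), c("dasatinib", "nilotinib"))
  expect_true(all(map2$ambiguous))
})

test_that("term stats compute presence fractions, fold changes and max flags", {
  # 200 docs, term in 9/100 of cluster 0 and 0/100 of cluster 1,
  # corpus frequency 9/200 = 0.045 -> fold change 2.0 in cluster 0
  docs <- lapply(1:200, function(i)
    tokdoc(paste0("d", i), c("base", if (i <= 9) "nausea")))
  asg <- structure(list(doc_ids = vapply(docs, `[[`, "", "id"),
                        labels = rep(0:1, each = 100), k = 2L, inertia = 0),
                   class = "cluster_assignment")
  st <- term_cluster_stats(asg, docs, c("nausea", "base"))
  n0 <- st[st$term == "nausea" & st$cluster == 0, ]
  expect_equal(n0$cluster_freq, 0.09)
  expect_equal(n0$corpus_freq, 0.045)
  expect_equal(n0$fold_change, 2)
  expect_true(n0$is_max)
  expect_false(st$is_max[st$term == "nausea" & st$cluster == 1])
  # uniformly distributed term has fold change 1 everywhere
  expect_true(all(abs(st$fold_change[st$term == "base"] - 1) < 1e-12))
  # exact counting identity: sum over clusters of size * freq = N * corpus_freq
  sizes <- table(asg$labels)
  for (tm in unique(st$term)) {
    rows <- st[st$term == tm, ]
    expect_equal(sum(sizes[as.character(rows$cluster)] * rows$cluster_freq),
                 200 * rows$corpus_freq[1])
  }
  expect_warning(term_cluster_stats(asg, docs, c("base", "ghost")), "ghost")
})

test_that("pairwise chi-square: count, Bonferroni alpha, degenerate pairs", {
  set.seed(21)
  terms <- c("t1", "t2", "t3")
  docs <- lapply(1:150, function(i)
    tokdoc(paste0("d", i), sample(terms, 2)))
  asg <- structure(list(doc_ids = vapply(docs, `[[`, "", "id"),
                        labels = rep(0:4, each = 30), k = 5L, inertia = 0),
                   class = "cluster_assignment")
  res <- pairwise_cluster_chisq(asg, docs, terms, 0:4, family_alpha = 0.05)
  expect_identical(nrow(res), 10L)                 # C(5,2)
  expect_true(all(res$corrected_alpha == 0.005))   # 0.05 / 10
  expect_true(all(res$significant == (res$p_value < 0.005), na.rm = TRUE))
})

test_that("identical cluster profiles give statistic 0 and p = 1", {
  docs <- lapply(1:40, function(i)
    tokdoc(paste0("d", i), if (i %% 2 == 0) "t1" else "t2"))
  asg <- structure(list(doc_ids = vapply(docs, `[[`, "", "id"),
                        labels = rep(0:1, each = 20), k = 2L, inertia = 0),
                   class = "cluster_assignment")
  res <- pairwise_cluster_chisq(asg, docs, c("t1", "t2"), 0:1)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("worked 2x2 table yields the closed-form statistic 13.333, dof 1", {
  # cluster A: term1 in 25 docs, term2 in 75; cluster B: 50 / 50
  mk <- function(pre, n1, n2) c(
    lapply(seq_len(n1), function(i) tokdoc(paste0(pre, "x", i), "term1")),
    lapply(seq_len(n2), function(i) tokdoc(paste0(pre, "y", i), "term2")))
  docs <- c(mk("a", 25, 75), mk("b", 50, 50))
  asg <- structure(list(doc_ids = vapply(docs, `[[`, "", "id"),
                        labels = rep(0:1, each = 100), k = 2L, inertia = 0),
                   class = "cluster_assignment")
  res <- pairwise_cluster_chisq(asg, docs, c("term1", "term2"), 0:1)
  expect_equal(res$statistic, 40 / 3, tolerance = 1e-9)
  expect_identical(as.integer(res$dof), 1L)
  o <- oracle_chisq(matrix(c(25, 75, 50, 50), 2, byrow = TRUE))
  expect_equal(res$statistic, o$stat, tolerance = 1e-12)
})

test_that("Bonferroni-significant pairs are a subset of uncorrected ones", {
  set.seed(8)
  for (rep in 1:5) {
    docs <- lapply(1:120, function(i)
      tokdoc(paste0("d", i), sample(c("t1", "t2", "t3", "t4"), 2)))
    asg <- structure(list(doc_ids = vapply(docs, `[[`, "", "id"),
                          labels = sample(0:3, 120, replace = TRUE), k = 4L,
                          inertia = 0), class = "cluster_assignment")
    res <- pairwise_cluster_chisq(asg, docs, c("t1", "t2", "t3", "t4"), 0:3,
                                  family_alpha = 0.05)
    corrected <- which(res$significant)
    uncorrected <- which(res$p_value < 0.05)
    expect_true(all(corrected %in% uncorrected))
  }
})

test_that("chi-square agrees with the closed form on random tables", {
  set.seed(99)
  for (rep in 1:25) {
    tab <- matrix(sample(1:60, 10, replace = TRUE), 5, 2)
    got <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    o <- oracle_chisq(tab)
    expect_lt(abs(unname(got$statistic) - o$stat), 1e-9)
    expect_identical(as.integer(got$parameter), o$dof)
  }
})
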