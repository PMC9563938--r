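# Shared fixtures and independent oracles. Oracles are deliberately written
# as plain loops over concrete edges so they share no code path with the
# package internals they check.

tokdoc <- function(id, tokens) {
  structure(list(id = id, tokens = tokens), class = "tokenized_doc")
}

# toy 3-document corpus used for hand-checked TF-IDF values
toy_docs <- function() {
  list(tokdoc("d1", c("a", "b")), tokdoc("d2", c("a", "c")),
       tokdoc("d3", c("a", "b", "c")))
}

tiny_kg <- function() {
  nodes <- data.frame(
    id = c("drug1", "gene1", "gene2", "dis1", "dis2", "proc1"),
    name = c("drug one", "gene one", "gene two", "disease one",
             "disease two", "procedure one"),
    ntype = c("PHSU", "GNGM", "GNGM", "DSYN", "DSYN", "TOPP"))
  edges <- data.frame(
    head = c("drug1", "drug1", "dis1", "dis2", "proc1", "dis1"),
    predicate = c("STIMULATES", "STIMULATES", "AFFECTS", "AFFECTS",
                  "AFFECTS", "CAUSES"),
    tail = c("gene1", "gene2", "gene1", "gene1", "gene2", "dis2"),
    weight = c(2, 2, 1, 3, 4, 5))
  knowledge_graph(nodes, edges)
}

# random typed graph for property tests and the exhaustive oracle
random_typed_graph <- function(seed, max_nodes = 15L, max_edges = 40L) {
  set.seed(seed)
  n <- sample(4:max_nodes, 1)
  ntypes <- sample(c("DSYN", "GNGM", "PHSU", "AAPP", "TOPP"), n, replace = TRUE)
  nodes <- data.frame(id = sprintf("n%02d", seq_len(n)),
                      name = sprintf("node %d", seq_len(n)), ntype = ntypes)
  ne <- sample(3:max_edges, 1)
  preds <- c("CAUSES", "AFFECTS", "TREATS")
  edges <- data.frame(head = sample(nodes$id, ne, replace = TRUE),
                      predicate = sample(preds, ne, replace = TRUE),
                      tail = sample(nodes$id, ne, replace = TRUE),
                      weight = sample(1:5, ne, replace = TRUE))
  edges <- edges[edges$head != edges$tail, , drop = FALSE]
  if (nrow(edges) == 0L)
    edges <- data.frame(head = nodes$id[1], predicate = "CAUSES",
                        tail = nodes$id[2], weight = 1)
  knowledge_graph(nodes, edges)
}

# ---- exhaustive HeteSim oracle ------------------------------------------

# one-step transition-probability vector of `v` over middle nodes `mids`
# along (pred, dir), built by scanning every edge
oracle_profile <- function(g, v, pred, dir, mids) {
  out <- stats::setNames(numeric(length(mids)), mids)
  for (k in seq_len(nrow(g$edges))) {
    e <- g$edges[k, ]
    if (e$predicate != pred) next
    if (dir == "out" && e$head == v && e$tail %in% mids)
      out[e$tail] <- out[e$tail] + e$weight
    if (dir == "in" && e$tail == v && e$head %in% mids)
      out[e$head] <- out[e$head] + e$weight
  }
  s <- sum(out)
  if (s > 0) out <- out / s
  out
}

# mean HeteSim over supported length-2 metapaths, plus concreteness
oracle_pair <- function(g, s, t) {
  total <- 0; count <- 0L; concrete <- FALSE
  preds <- unique(g$edges$predicate)
  for (mtype in unique(g$nodes$ntype)) {
    mids <- sort(g$nodes$id[g$nodes$ntype == mtype])
    if (length(mids) == 0L) next
    for (p1 in preds) for (d1 in c("out", "in")) {
      v1 <- oracle_profile(g, s, p1, d1, mids)
      if (sum(v1) == 0) next
      for (p2 in preds) for (d2 in c("out", "in")) {
        v2 <- oracle_profile(g, t, p2, d2, mids)
        if (sum(v2) == 0) next
        count <- count + 1L
        total <- total + sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        if (any(v1 > 0 & v2 > 0)) concrete <- TRUE
      }
    }
  }
  list(sim = if (count > 0L) total / count else NA_real_,
       npaths = count, concrete = concrete)
}

# full ranking oracle mirroring the documented aggregation rules
oracle_rank_sources <- function(g, targets, source_ntypes = c("DSYN", "TOPP")) {
  cand <- sort(g$nodes$id[g$nodes$ntype %in% source_ntypes])
  rows <- list()
  for (s in cand) {
    sims <- c(); any_concrete <- FALSE
    for (t in targets) {
      if (s == t) next
      pr <- oracle_pair(g, s, t)
      if (!is.na(pr$sim)) sims <- c(sims, pr$sim)
      if (pr$concrete) any_concrete <- TRUE
    }
    if (any_concrete)
      rows[[s]] <- data.frame(id = s, similarity = mean(sims))
  }
  if (length(rows) == 0L)
    return(data.frame(id = character(0), similarity = numeric(0)))
  out <- do.call(rbind, rows)
  out$score <- 1 - out$similarity
  out <- out[order(out$score, out$id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# closed-form chi-square of independence
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(stat = sum((tab - E)^2 / E),
       dof = (nrow(tab) - 1L) * (ncol(tab) - 1L))
}
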