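#' The six predicates used for entity prediction
#' @return Character vector.
#' @export
prediction_predicates <- function() {
  c("CAUSES", "PRECEDES", "AUGMENTS", "DISRUPTS", "STIMULATES", "AFFECTS")
}

#' The five semantic types admitted as predicted entities
#' @return Character vector.
#' @export
prediction_ntypes <- function() {
  c("AAPP", "BACS", "DSYN", "GNGM", "PHSU")
}

#' Train a TransE embedding on a knowledge graph
#'
#' Translational embedding: a true triple `(h, r, t)` should satisfy
#' `h + r ~ t` in the embedding space, scored by the Euclidean distance
#' `||h + r - t||`. Training minimizes the margin-ranking loss
#' `max(0, margin + d(pos) - d(neg))` by mini-batch stochastic gradient
#' descent, with one negative per positive obtained by uniformly corrupting
#' the head or the tail, and entity vectors renormalized to unit L2 norm at
#' the end of each epoch. Deterministic for a fixed seed. Defaults
#' (`dim = 32`, `margin = 1`, 100 epochs) are sized for desk-scale graphs
#' and exposed in the returned model's `hyper` field.
#'
#' @param g A `knowledge_graph` with at least one edge.
#' @param dim Embedding dimension.
#' @param margin Ranking margin.
#' @param lr Learning rate.
#' @param epochs Number of passes over the triples; `epochs = 0` returns the
#'   random initialization (the untrained baseline).
#' @param batch Mini-batch size.
#' @param seed Integer seed for initialization, shuffling and corruption.
#' @return A `transe_model`: `entities` (matrix, rownames = node ids),
#'   `relations` (matrix, rownames = predicates), `hyper`, and `loss`
#'   (per-epoch mean margin loss).
#' @export
train_transe <- function(g, dim = 32L, margin = 1, lr = 0.05, epochs = 100L,
                         batch = 128L, seed = 1L) {
  stopifnot(inherits(g, "knowledge_graph"))
  if (nrow(g$edges) == 0L) stop("cannot train on an empty graph")
  set.seed(seed)
  ents <- g$nodes$id
  rels <- sort(unique(g$edges$predicate), method = "radix")
  b <- 6 / sqrt(dim)
  E <- matrix(runif(length(ents) * dim, -b, b), ncol = dim,
              dimnames = list(ents, NULL))
  R <- matrix(runif(length(rels) * dim, -b, b), ncol = dim,
              dimnames = list(rels, NULL))
  R <- R / pmax(sqrt(rowSums(R^2)), 1e-12)
  E <- E / pmax(sqrt(rowSums(E^2)), 1e-12)
  hi <- match(g$edges$head, ents)
  ri <- match(g$edges$predicate, rels)
  ti <- match(g$edges$tail, ents)
  ne <- length(hi); nent <- length(ents)
  losses <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(ne)
    eploss <- 0
    for (start in seq(1L, ne, by = batch)) {
      idx <- perm[start:min(start + batch - 1L, ne)]
      h <- hi[idx]; r <- ri[idx]; t <- ti[idx]
      corrupt_head <- runif(length(idx)) < 0.5
      rnd <- sample.int(nent, length(idx), replace = TRUE)
      hn <- ifelse(corrupt_head, rnd, h)
      tn <- ifelse(corrupt_head, t, rnd)
      dpos_v <- E[h, , drop = FALSE] + R[r, , drop = FALSE] - E[t, , drop = FALSE]
      dneg_v <- E[hn, , drop = FALSE] + R[r, , drop = FALSE] - E[tn, , drop = FALSE]
      dpos <- rowSums(dpos_v^2); dneg <- rowSums(dneg_v^2)
      viol <- margin + dpos - dneg > 0
      eploss <- eploss + sum(pmax(0, margin + dpos - dneg))
      if (any(viol)) {
        gpos <- 2 * dpos_v[viol, , drop = FALSE]
        gneg <- 2 * dneg_v[viol, , drop = FALSE]
        upd <- function(M, rows, delta) {
          u <- rowsum(delta, rows)
          ur <- as.integer(rownames(u))
          M[ur, ] <- M[ur, , drop = FALSE] + u
          M
        }
        E <- upd(E, h[viol], -lr * gpos)
        E <- upd(E, t[viol], lr * gpos)
        E <- upd(E, hn[viol], lr * gneg)
        E <- upd(E, tn[viol], -lr * gneg)
        R <- upd(R, r[viol], -lr * (gpos - gneg))
      }
    }
    E <- E / pmax(sqrt(rowSums(E^2)), 1e-12)
    losses[ep] <- eploss / ne
  }
  structure(list(entities = E, relations = R,
                 hyper = list(dim = dim, margin = margin, norm_p = 2,
                              lr = lr, epochs = epochs, batch = batch,
                              negatives_per_positive = 1L, seed = seed),
                 loss = losses),
            class = "transe_model")
}

#' Triple distance under a TransE model
#'
#' @param model A `transe_model`.
#' @param h,r,t Head id, predicate, tail id (vectors recycle).
#' @return Euclidean distance(s) `||h + r - t||_2`.
#' @export
transe_distance <- function(model, h, r, t) {
  d <- model$entities[h, , drop = FALSE] + model$relations[r, , drop = FALSE] -
    model$entities[t, , drop = FALSE]
  unname(sqrt(rowSums(d^2)))
}

#' Predict tail entities for a head and predicate
#'
#' Candidates are all embedded entities of the allowed semantic types,
#' excluding the head itself and tails already observed for
#' `(head, predicate)` in the graph (filtered setting), ranked by ascending
#' distance (ties by id). Each candidate carries a degree-normalized
#' predicted strength `raw_weight = exp(-distance) / (1 + ln(1 + deg(tail)))`
#' (`deg` = weighted degree, so heavily published tails are discounted) and
#' its min-max rescaling `norm_weight` within the candidate list (a single
#' candidate gets 1).
#'
#' @param model A `transe_model`.
#' @param g The training `knowledge_graph`.
#' @param head Head node id.
#' @param predicate Predicate in the trained vocabulary.
#' @param ntypes Allowed tail semantic types (default the five prediction
#'   types).
#' @param top_k Number of predictions to return.
#' @return Data frame: `head`, `predicate`, `tail`, `distance`,
#'   `raw_weight`, `norm_weight`.
#' @export
predict_entities <- function(model, g, head, predicate,
                             ntypes = prediction_ntypes(), top_k = 25L) {
  stopifnot(inherits(model, "transe_model"), inherits(g, "knowledge_graph"))
  if (!(head %in% rownames(model$entities))) stop("unknown head: ", head)
  if (!(predicate %in% rownames(model$relations)))
    stop("unknown predicate: ", predicate)
  observed <- g$edges$tail[g$edges$head == head & g$edges$predicate == predicate]
  cand <- g$nodes$id[g$nodes$ntype %in% ntypes]
  cand <- sort(setdiff(intersect(cand, rownames(model$entities)),
                       c(head, observed)), method = "radix")
  if (length(cand) == 0L)
    return(data.frame(head = character(0), predicate = character(0),
                      tail = character(0), distance = numeric(0),
                      raw_weight = numeric(0), norm_weight = numeric(0)))
  q <- model$entities[head, ] + model$relations[predicate, ]
  d <- sqrt(rowSums(sweep(model$entities[cand, , drop = FALSE], 2, q)^2))
  raw <- exp(-d) / (1 + log(1 + .wdeg(g, cand)))
  rng <- range(raw)
  nw <- if (length(raw) == 1L || rng[1] == rng[2]) rep(1, length(raw)) else
    (raw - rng[1]) / (rng[2] - rng[1])
  ord <- order(d, cand, method = "radix")
  out <- data.frame(head = head, predicate = predicate, tail = cand[ord],
                    distance = unname(d[ord]), raw_weight = unname(raw[ord]),
                    norm_weight = unname(nw[ord]), stringsAsFactors = FALSE)
  head(out, top_k)
}

#' Filtered hits@k on held-out edges
#'
#' For each held-out triple `(h, r, t)`, ranks the true tail by distance
#' among all entities sharing the true tail's semantic type, excluding the
#' head and tails observed for `(h, r)` in the training graph (filtered
#' evaluation). Returns the fraction of triples whose true tail ranks in the
#' top `k`.
#'
#' @param model A `transe_model`.
#' @param g Training `knowledge_graph`.
#' @param heldout Data frame with columns `head`, `predicate`, `tail`,
#'   disjoint from the training edges.
#' @param k Rank cutoff (default 10).
#' @return Fraction in `[0, 1]`.
#' @export
evaluate_hits <- function(model, g, heldout, k = 10L) {
  stopifnot(inherits(model, "transe_model"), inherits(g, "knowledge_graph"))
  if (is.null(heldout) || nrow(heldout) == 0L) stop("heldout set is empty")
  trainkey <- paste(g$edges$head, g$edges$predicate, g$edges$tail, sep = "\r")
  hkey <- paste(heldout$head, heldout$predicate, heldout$tail, sep = "\r")
  if (any(hkey %in% trainkey))
    stop("heldout edges overlap the training graph")
  hits <- vapply(seq_len(nrow(heldout)), function(i) {
    h <- heldout$head[i]; r <- heldout$predicate[i]; t <- heldout$tail[i]
    tt <- g$nodes$ntype[match(t, g$nodes$id)]
    cand <- g$nodes$id[g$nodes$ntype == tt]
    observed <- g$edges$tail[g$edges$head == h & g$edges$predicate == r]
    cand <- setdiff(intersect(cand, rownames(model$entities)), c(h, observed))
    cand <- union(cand, t)
    d <- transe_distance(model, rep(h, length(cand)), rep(r, length(cand)), cand)
    rank_t <- sum(d < d[match(t, cand)]) + 1L
    rank_t <= k
  }, logical(1))
  mean(hits)
}
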