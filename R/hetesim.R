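.flip_dir <- function(d) ifelse(d == "out", "in", "out")

#' Define a length-2 schema metapath
#'
#' A metapath here is two typed steps through a middle layer: step 1 takes
#' the source to a middle node of semantic type `middle` along `pred1`
#' (direction `dir1` relative to the source), and step 2 takes the middle
#' node to the target along `pred2` (direction `dir2` relative to the middle
#' node).
#'
#' @param pred1,pred2 Predicate codes for the two steps.
#' @param middle Semantic type of the middle layer.
#' @param dir1 `"out"` if the source is the subject of step 1, else `"in"`.
#' @param dir2 `"out"` if the middle node is the subject of step 2, else
#'   `"in"`.
#' @return A `metapath` object.
#' @export
metapath <- function(pred1, middle, pred2, dir1 = "out", dir2 = "out") {
  stopifnot(dir1 %in% c("out", "in"), dir2 %in% c("out", "in"))
  structure(list(pred1 = pred1, dir1 = dir1, middle = middle,
                 pred2 = pred2, dir2 = dir2), class = "metapath")
}

#' Reverse a metapath
#'
#' @param mp A `metapath`.
#' @return The `metapath` read from target to source; satisfies the
#'   symmetry `hetesim_length2(g, s, t, mp) == hetesim_length2(g, t, s,
#'   reverse_metapath(mp))`.
#' @export
reverse_metapath <- function(mp) {
  metapath(pred1 = mp$pred2, dir1 = .flip_dir(mp$dir2), middle = mp$middle,
           pred2 = mp$pred1, dir2 = .flip_dir(mp$dir1))
}

# transition-probability profiles of `ids` into the middle layer `mids`
# along one step (pred, dir); rows sum to 1 (or are all-zero).
.profile_matrix <- function(g, ids, pred, dir, mids) {
  e <- g$edges[g$edges$predicate == pred, , drop = FALSE]
  if (dir == "out") {
    from <- e$head; to <- e$tail
  } else {
    from <- e$tail; to <- e$head
  }
  sel <- from %in% ids & to %in% mids
  i <- match(from[sel], ids); j <- match(to[sel], mids)
  p <- Matrix::sparseMatrix(i = i, j = j, x = e$weight[sel],
                            dims = c(length(ids), length(mids)),
                            dimnames = list(ids, mids))
  rs <- Matrix::rowSums(p)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% p
}

# step combos (pred, dir) that can reach middle type `mtype` in graph g
.step_combos <- function(g, mtype) {
  nt <- g$nodes$ntype[match(g$edges$tail, g$nodes$id)]
  ht <- g$nodes$ntype[match(g$edges$head, g$nodes$id)]
  rbind(
    if (any(nt == mtype))
      data.frame(pred = unique(g$edges$predicate[nt == mtype]), dir = "out"),
    if (any(ht == mtype))
      data.frame(pred = unique(g$edges$predicate[ht == mtype]), dir = "in"))
}

# Pairwise mean HeteSim over all supported length-2 schema metapaths.
# Returns sources x targets matrices: sim (NA where no metapath supported),
# npaths (count of supported metapaths), concrete (any shared middle).
.hetesim_engine <- function(g, sources, targets) {
  ns <- length(sources); nt <- length(targets)
  sumsim <- matrix(0, ns, nt, dimnames = list(sources, targets))
  cnt <- matrix(0L, ns, nt, dimnames = list(sources, targets))
  concrete <- matrix(FALSE, ns, nt, dimnames = list(sources, targets))
  for (mtype in sort(unique(g$nodes$ntype))) {
    mids <- sort(g$nodes$id[g$nodes$ntype == mtype], method = "radix")
    combos <- .step_combos(g, mtype)
    if (is.null(combos) || nrow(combos) == 0L) next
    profS <- list(); profT <- list()
    for (c1 in seq_len(nrow(combos))) {
      ps <- .profile_matrix(g, sources, combos$pred[c1], combos$dir[c1], mids)
      if (any(Matrix::rowSums(ps) > 0)) profS[[as.character(c1)]] <- ps
      pt <- .profile_matrix(g, targets, combos$pred[c1], combos$dir[c1], mids)
      if (any(Matrix::rowSums(pt) > 0)) profT[[as.character(c1)]] <- pt
    }
    if (length(profS) == 0L || length(profT) == 0L) next
    for (ps in profS) {
      nzS <- Matrix::rowSums(ps) > 0
      u1 <- .unit_rows(ps)
      for (pt in profT) {
        nzT <- Matrix::rowSums(pt) > 0
        mask <- outer(nzS, nzT, FUN = "&")
        if (!any(mask)) next
        cosm <- as.matrix(Matrix::tcrossprod(u1, .unit_rows(pt)))
        sumsim <- sumsim + cosm * mask
        cnt <- cnt + mask
        shared <- as.matrix(Matrix::tcrossprod(ps > 0, pt > 0)) > 0
        concrete <- concrete | (shared & mask)
      }
    }
  }
  sim <- sumsim / ifelse(cnt > 0L, cnt, NA_integer_)
  list(sim = sim, npaths = cnt, concrete = concrete)
}

.unit_rows <- function(p) {
  nrm <- sqrt(Matrix::rowSums(p^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% p
}

#' Length-2 HeteSim similarity along one metapath
#'
#' Cosine of the forward transition-probability vector of the source (step 1)
#' and the backward transition-probability vector of the target (step 2
#' reversed), both over the middle-layer nodes of the metapath's middle
#' type. Returns 0 when either vector is all-zero. Invariant to uniform
#' rescaling of edge weights.
#'
#' @param g A `knowledge_graph`.
#' @param s,t Source and target node ids (must exist).
#' @param mp A [metapath()] of length 2.
#' @return Similarity in `[0, 1]` (higher = stronger).
#' @export
hetesim_length2 <- function(g, s, t, mp) {
  stopifnot(inherits(g, "knowledge_graph"), inherits(mp, "metapath"))
  if (!(s %in% g$nodes$id)) stop("unknown node: ", s)
  if (!(t %in% g$nodes$id)) stop("unknown node: ", t)
  mids <- sort(g$nodes$id[g$nodes$ntype == mp$middle], method = "radix")
  if (length(mids) == 0L) stop("no nodes of middle type ", mp$middle)
  v1 <- as.numeric(.profile_matrix(g, s, mp$pred1, mp$dir1, mids))
  v2 <- as.numeric(.profile_matrix(g, t, mp$pred2, .flip_dir(mp$dir2), mids))
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(0)
  sum(v1 * v2) / (n1 * n2)
}

#' Mean HeteSim over all supported length-2 metapaths
#'
#' Arithmetic mean of [hetesim_length2()] over every length-2 schema
#' metapath (step predicates/directions and middle type) on which both
#' endpoints have a nonzero transition vector. With no supported metapath
#' the pair is unrankable and `NA` is returned with a warning (never 0,
#' which would mean "maximally dissimilar").
#'
#' @param g A `knowledge_graph`.
#' @param s,t Node ids.
#' @return Mean similarity in `[0, 1]`, or `NA` if unsupported.
#' @export
mean_hetesim <- function(g, s, t) {
  if (!(s %in% g$nodes$id)) stop("unknown node: ", s)
  if (!(t %in% g$nodes$id)) stop("unknown node: ", t)
  res <- .hetesim_engine(g, s, t)
  out <- res$sim[1, 1]
  if (is.na(out)) warning("no supported metapath between ", s, " and ", t)
  out
}

#' Novelty score of a source node
#'
#' Relevance discounted by how much the node is written about:
#' `similarity / (1 + ln(1 + w))` with `w` the node's total weighted degree
#' (summed predication occurrence counts). Strictly decreasing in `w` for
#' fixed similarity, so under-published but relevant nodes surface. The
#' functional form is this package's own choice of a monotone
#' literature-volume discount.
#'
#' @param g A `knowledge_graph`.
#' @param s Node id.
#' @param similarity Mean HeteSim similarity in `[0, 1]`.
#' @return Nonnegative novelty score.
#' @export
novelty_score <- function(g, s, similarity) {
  stopifnot(similarity >= 0, similarity <= 1)
  if (!(s %in% g$nodes$id)) stop("unknown node: ", s)
  similarity / (1 + log(1 + .wdeg(g, s)))
}

#' Rank source nodes against one or more targets
#'
#' Candidate sources are nodes of the allowed semantic types connected to at
#' least one target by a concrete length-2 path. Each candidate-target pair
#' is scored by the mean HeteSim over its supported metapaths; multi-target
#' relevance is the arithmetic mean across targets with at least one
#' supported metapath. A candidate that is itself a target is still ranked,
#' but its self-pair is excluded from the mean (a node is not evidence for
#' its own relevance). The reported `score` is `1 - similarity` so that a
#' *lower* score indicates a *stronger* relationship; `novelty` applies the
#' degree discount of [novelty_score()].
#'
#' @param g A `knowledge_graph`.
#' @param targets Character vector of target node ids.
#' @param source_ntypes Allowed candidate semantic types (default
#'   `c("DSYN", "TOPP")`, diseases/syndromes and therapeutic procedures).
#' @param order_by `"score"` (ascending; lower = stronger) or `"novelty"`
#'   (descending). Ties break by node id.
#' @return Data frame: `id`, `name`, `ntype`, `score`, `similarity`,
#'   `novelty`, `n_metapaths`. Empty (with a warning) when no candidate is
#'   reachable.
#' @export
rank_sources <- function(g, targets, source_ntypes = c("DSYN", "TOPP"),
                         order_by = c("score", "novelty")) {
  stopifnot(inherits(g, "knowledge_graph"))
  order_by <- match.arg(order_by)
  miss <- setdiff(targets, g$nodes$id)
  if (length(miss) > 0L) stop("unknown target(s): ", paste(miss, collapse = ", "))
  cand <- sort(g$nodes$id[g$nodes$ntype %in% source_ntypes], method = "radix")
  if (length(cand) == 0L) {
    warning("no nodes of the requested source types")
    return(.empty_ranking())
  }
  res <- .hetesim_engine(g, cand, targets)
  self <- outer(cand, targets, `==`)
  res$npaths[self] <- 0L
  res$concrete[self] <- FALSE
  res$sim[self] <- NA_real_
  ranked <- which(rowSums(res$concrete) > 0)
  if (length(ranked) == 0L) {
    warning("no candidate source reachable from the targets")
    return(.empty_ranking())
  }
  sim <- vapply(ranked, function(r) mean(res$sim[r, ], na.rm = TRUE), numeric(1))
  npaths <- rowSums(res$npaths)[ranked]
  ids <- cand[ranked]
  nov <- sim / (1 + log(1 + .wdeg(g, ids)))
  out <- data.frame(id = ids,
                    name = g$nodes$name[match(ids, g$nodes$id)],
                    ntype = g$nodes$ntype[match(ids, g$nodes$id)],
                    score = 1 - sim, similarity = sim, novelty = nov,
                    n_metapaths = as.integer(npaths),
                    stringsAsFactors = FALSE)
  ord <- if (order_by == "score") order(out$score, out$id, method = "radix")
         else order(-out$novelty, out$id, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_ranking <- function() {
  data.frame(id = character(0), name = character(0), ntype = character(0),
             score = numeric(0), similarity = numeric(0),
             novelty = numeric(0), n_metapaths = integer(0))
}
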