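#' Select hub nodes shared between two anchor concepts
#'
#' Hubs are candidates in the intersection of both anchors' neighborhoods
#' (any predicate, both directions), ranked by total weighted degree
#' descending (ties by id); the top `n` are returned. An empty intersection
#' yields an empty result with a warning so hubs can be supplied manually.
#'
#' @param g A `knowledge_graph`.
#' @param anchors Character vector of the two anchor node ids.
#' @param n Number of hubs (default 6).
#' @return Character vector of hub ids (possibly fewer than `n`).
#' @export
select_hubs <- function(g, anchors, n = 6L) {
  stopifnot(length(anchors) == 2L)
  n1 <- kg_neighbors(g, anchors[1])$id
  n2 <- kg_neighbors(g, anchors[2])$id
  shared <- setdiff(intersect(n1, n2), anchors)
  if (length(shared) == 0L) {
    warning("anchor neighborhoods share no nodes; supply hubs manually")
    return(character(0))
  }
  deg <- .wdeg(g, shared)
  head(shared[order(-deg, shared, method = "radix")], n)
}

#' Build a hub's predicted neighborhood
#'
#' Unions [predict_entities()] over the prediction predicates, deduplicates
#' (keeping each node's maximum normalized weight and the predicate that
#' produced it), sorts by weight descending (ties by id), and truncates to
#' `cap` members. The hub itself is never a member.
#'
#' @param model A `transe_model`.
#' @param g The training `knowledge_graph`.
#' @param hub Hub node id.
#' @param predicates Relation set to predict under (default the six
#'   prediction predicates).
#' @param ntypes Allowed member semantic types (default the five prediction
#'   types).
#' @param cap Maximum neighborhood size (default 25).
#' @return A `hub_neighborhood`: `hub` and `members` data frame (`id`,
#'   `norm_weight`, `predicate`).
#' @export
build_hub_neighborhood <- function(model, g, hub,
                                   predicates = prediction_predicates(),
                                   ntypes = prediction_ntypes(), cap = 25L) {
  preds <- predicates[predicates %in% rownames(model$relations)]
  all <- do.call(rbind, lapply(preds, function(p)
    predict_entities(model, g, hub, p, ntypes = ntypes, top_k = cap)))
  if (is.null(all) || nrow(all) == 0L) {
    members <- data.frame(id = character(0), norm_weight = numeric(0),
                          predicate = character(0))
  } else {
    ord <- order(-all$norm_weight, all$tail, all$predicate, method = "radix")
    all <- all[ord, , drop = FALSE]
    all <- all[!duplicated(all$tail), , drop = FALSE]
    members <- head(data.frame(id = all$tail, norm_weight = all$norm_weight,
                               predicate = all$predicate,
                               stringsAsFactors = FALSE), cap)
    rownames(members) <- NULL
  }
  structure(list(hub = hub, members = members), class = "hub_neighborhood")
}

#' Run one hub relevance simulation
#'
#' Ranks candidate sources (default semantic type DSYN) against the target
#' set formed by the focal concept plus the hub's predicted neighborhood
#' members, then min-max normalizes the scores to `[0, 1]` preserving the
#' lower-is-stronger orientation. With a single ranked candidate (or all
#' scores equal) the normalized score is 0, the strongest value, since
#' min-max is undefined.
#'
#' @param g A `knowledge_graph`, typically after [kg_remove_generic()].
#' @param neighborhood A `hub_neighborhood`.
#' @param focal Focal target node id (e.g. the kinase concept).
#' @param source_ntypes Candidate semantic types (default `"DSYN"`).
#' @return A `hub_sim_result`: `hub` and `candidates` data frame (`id`,
#'   `score`, `norm_score`, `similarity`, `novelty`). Empty with a warning
#'   when nothing is rankable.
#' @export
run_hub_simulation <- function(g, neighborhood, focal,
                               source_ntypes = "DSYN") {
  stopifnot(inherits(neighborhood, "hub_neighborhood"))
  if (nrow(neighborhood$members) == 0L) stop("neighborhood is empty")
  targets <- unique(c(focal, neighborhood$members$id))
  targets <- targets[targets %in% g$nodes$id]
  ranked <- rank_sources(g, targets, source_ntypes = source_ntypes,
                         order_by = "score")
  if (nrow(ranked) == 0L) {
    warning("hub ", neighborhood$hub, ": no ranked candidates")
    cands <- data.frame(id = character(0), score = numeric(0),
                        norm_score = numeric(0), similarity = numeric(0),
                        novelty = numeric(0))
    return(structure(list(hub = neighborhood$hub, candidates = cands),
                     class = "hub_sim_result"))
  }
  rng <- range(ranked$score)
  norm <- if (nrow(ranked) == 1L || rng[1] == rng[2])
    rep(0, nrow(ranked)) else (ranked$score - rng[1]) / (rng[2] - rng[1])
  cands <- data.frame(id = ranked$id, score = ranked$score, norm_score = norm,
                      similarity = ranked$similarity, novelty = ranked$novelty,
                      stringsAsFactors = FALSE)
  structure(list(hub = neighborhood$hub, candidates = cands),
            class = "hub_sim_result")
}

#' Aggregate candidate rankings across hub simulations
#'
#' For each candidate appearing in at least one simulation:
#' `occurrence_rate` is the fraction of simulations containing it,
#' `mean_score` the mean of its normalized scores over those simulations,
#' and `composite = occurrence_rate * (1 - mean_score)`, a bounded quantity
#' increasing in prevalence and in strength. The ranking is by composite
#' descending, ties by id, and is invariant to the order of the
#' simulations.
#'
#' @param sims List of `hub_sim_result` objects (>= 1 non-empty).
#' @return An `aggregate_ranking` data frame: `id`, `occurrence_rate`,
#'   `mean_score`, `composite`, `rank`.
#' @export
aggregate_hub_sims <- function(sims) {
  stopifnot(length(sims) >= 1L)
  nonempty <- vapply(sims, function(s) nrow(s$candidates) > 0L, logical(1))
  if (!any(nonempty)) stop("all simulations are empty")
  nsims <- length(sims)
  tab <- do.call(rbind, lapply(sims[nonempty], function(s)
    s$candidates[, c("id", "norm_score")]))
  occ <- table(tab$id) / nsims
  ms <- tapply(tab$norm_score, tab$id, mean)
  ids <- sort(names(occ), method = "radix")
  out <- data.frame(id = ids, occurrence_rate = as.numeric(occ[ids]),
                    mean_score = as.numeric(ms[ids]), stringsAsFactors = FALSE)
  out$composite <- out$occurrence_rate * (1 - out$mean_score)
  out <- out[order(-out$composite, out$id, method = "radix"), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("aggregate_ranking", "data.frame")
  out
}

#' Assign top-percentage tiers to an aggregate ranking
#'
#' Tier 1 covers ranks 1 through `ceiling(cutoffs[1] * N)`, tier 2 extends
#' through `ceiling(cutoffs[2] * N)`, tier 3 through
#' `ceiling(cutoffs[3] * N)`; the remainder is `"none"`. Ceilings guarantee
#' no tier is empty for `N >= 1` (for tiny `N` the nested tiers collapse
#' onto the same top ranks).
#'
#' @param ranking An `aggregate_ranking`.
#' @param cutoffs Strictly increasing fractions in `(0, 1]`; default
#'   `c(0.01, 0.05, 0.10)` (top 1%, 5%, 10%).
#' @return The ranking with a `tier` column (`"1"`, `"2"`, `"3"`, `"none"`).
#' @export
assign_tiers <- function(ranking, cutoffs = c(0.01, 0.05, 0.10)) {
  stopifnot(nrow(ranking) >= 1L, length(cutoffs) == 3L)
  if (any(diff(cutoffs) <= 0) || any(cutoffs <= 0) || any(cutoffs > 1))
    stop("cutoffs must be strictly increasing fractions in (0, 1]")
  n <- nrow(ranking)
  b <- ceiling(cutoffs * n)
  tier <- rep("none", n)
  tier[ranking$rank <= b[3]] <- "3"
  tier[ranking$rank <= b[2]] <- "2"
  tier[ranking$rank <= b[1]] <- "1"
  ranking$tier <- tier
  ranking
}

#' Read a foci map file
#'
#' Two-column tab-separated text: node id, focus label. Malformed lines
#' raise an error naming the line number.
#'
#' @param path Path to the map file.
#' @return Named character vector (names = node ids, values = foci).
#' @export
read_foci_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L || !nzchar(trimws(f[1])) || !nzchar(trimws(f[2])))
      stop("malformed foci map line ", i, ": expected 'id<TAB>focus'")
    out[trimws(f[1])] <- trimws(f[2])
  }
  out
}

#' Label a tiered ranking with physiological foci
#'
#' Foci assignment is file-driven (curated, typically ontology-based), never
#' automatic. Unmapped nodes are labeled `"other"`. The summary lists, per
#' focus, the three highest-ranked members.
#'
#' @param ranking A tiered `aggregate_ranking` (see [assign_tiers()]).
#' @param foci_map Named character vector from [read_foci_map()] (or built
#'   in code).
#' @return List with `ranking` (a `focus` column added) and `summary` (data
#'   frame `focus`, `n`, `top3` comma-separated).
#' @export
apply_foci <- function(ranking, foci_map) {
  focus <- unname(foci_map[ranking$id])
  focus[is.na(focus)] <- "other"
  ranking$focus <- focus
  tiered <- ranking[ranking$tier != "none", , drop = FALSE]
  summ <- do.call(rbind, lapply(split(tiered, tiered$focus), function(d) {
    d <- d[order(d$rank), , drop = FALSE]
    data.frame(focus = d$focus[1], n = nrow(d),
               top3 = paste(head(d$id, 3), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(summ)) rownames(summ) <- NULL
  list(ranking = ranking, summary = summ)
}

#' Export a curation template for human-in-the-loop review
#'
#' One row per tiered node, with an empty `verdict` column to be filled with
#' exactly one of `agrees`, `disagrees`, or `missing` by curators reviewing
#' full-text evidence for each predicted relationship.
#'
#' @param ranking A tiered `aggregate_ranking`.
#' @param path Optional TSV output path.
#' @return The template data frame (invisibly if written to `path`).
#' @export
export_curation_template <- function(ranking, path = NULL) {
  stopifnot(!is.null(ranking$tier))
  tmpl <- ranking[ranking$tier != "none",
                  c("rank", "id", "composite", "occurrence_rate",
                    "mean_score", "tier"), drop = FALSE]
  tmpl$verdict <- ""
  rownames(tmpl) <- NULL
  if (!is.null(path)) {
    utils::write.table(tmpl, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tmpl))
  }
  tmpl
}

#' Validate a completed curation template
#'
#' @param x A data frame (or TSV path) with a `verdict` column; every verdict
#'   must be one of `agrees`, `disagrees`, `missing`.
#' @return Table of verdict counts.
#' @export
read_curation_template <- function(x) {
  if (is.character(x)) x <- utils::read.delim(x, stringsAsFactors = FALSE)
  bad <- setdiff(unique(x$verdict), c("agrees", "disagrees", "missing"))
  if (length(bad) > 0L)
    stop("invalid verdict(s): ", paste(sprintf("'%s'", bad), collapse = ", "),
         "; allowed: agrees, disagrees, missing")
  table(factor(x$verdict, levels = c("agrees", "disagrees", "missing")))
}
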