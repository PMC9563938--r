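#' Default semantic-type registry
#'
#' UMLS-style semantic-type codes accepted without warning; files carrying
#' other codes are still loaded (the code is registered with a warning).
#'
#' @return Character vector of type codes.
#' @export
default_ntype_registry <- function() {
  c("AAPP", "BACS", "DSYN", "GNGM", "PHSU", "TOPP", "NEOP", "ORCH", "CELC",
    "CELL", "HORM", "ENZY", "SOSY", "PATF", "MOFT")
}

#' Default generic-node stoplist
#'
#' Over-general concepts ("protein", "complication", "infection", "disease")
#' whose hub-like connectivity is an artifact of concept granularity rather
#' than signal; removed before relevance ranking. User-extensible.
#'
#' @return Character vector of lowercase names.
#' @export
generic_stoplist <- function() {
  readLines(system.file("extdata", "generic_stoplist.txt", package = "semhub"),
            warn = FALSE)
}

#' Construct a typed predication knowledge graph
#'
#' Nodes carry an opaque concept `id` (the identity key), a display `name`,
#' and a semantic-type code `ntype`. Edges are directed subject-to-object
#' predications with a positive occurrence-count `weight`; duplicate
#' `(head, predicate, tail)` triples are merged by summing weights. Degree
#' caches (weighted/unweighted, in/out) are built once at construction.
#'
#' @param nodes Data frame with columns `id`, `name`, `ntype`.
#' @param edges Data frame with columns `head`, `predicate`, `tail`, and
#'   optional `weight` (default 1 per row).
#' @param registry Accepted semantic-type codes; unknown codes warn and are
#'   registered.
#' @return A `knowledge_graph` object.
#' @export
knowledge_graph <- function(nodes, edges, registry = default_ntype_registry()) {
  nodes <- data.frame(id = as.character(nodes$id), name = as.character(nodes$name),
                      ntype = as.character(nodes$ntype), stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  unknown <- setdiff(unique(nodes$ntype), registry)
  if (length(unknown) > 0L) {
    warning("unknown semantic types registered: ", paste(unknown, collapse = ", "))
    registry <- c(registry, unknown)
  }
  if (is.null(edges$weight)) edges$weight <- 1
  edges <- data.frame(head = as.character(edges$head),
                      predicate = as.character(edges$predicate),
                      tail = as.character(edges$tail),
                      weight = as.numeric(edges$weight), stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    miss <- setdiff(unique(c(edges$head, edges$tail)), nodes$id)
    if (length(miss) > 0L)
      stop("edge endpoints missing from node table: ",
           paste(head(miss, 5), collapse = ", "))
    if (any(edges$weight < 1)) stop("edge weights must be >= 1")
    key <- paste(edges$head, edges$predicate, edges$tail, sep = "\r")
    w <- tapply(edges$weight, key, sum)
    parts <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
    edges <- data.frame(head = parts[, 1], predicate = parts[, 2],
                        tail = parts[, 3], weight = as.numeric(w),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$head, edges$predicate, edges$tail,
                         method = "radix"), , drop = FALSE]
    rownames(edges) <- NULL
  }
  g <- structure(list(nodes = nodes, edges = edges, registry = registry),
                 class = "knowledge_graph")
  g$deg <- .degree_cache(g)
  g
}

.degree_cache <- function(g) {
  ids <- g$nodes$id
  zero <- stats::setNames(numeric(length(ids)), ids)
  out <- list(w_out = zero, w_in = zero, d_out = zero, d_in = zero)
  if (nrow(g$edges) > 0L) {
    wo <- tapply(g$edges$weight, g$edges$head, sum)
    wi <- tapply(g$edges$weight, g$edges$tail, sum)
    co <- table(g$edges$head); ci <- table(g$edges$tail)
    out$w_out[names(wo)] <- wo; out$w_in[names(wi)] <- wi
    out$d_out[names(co)] <- co; out$d_in[names(ci)] <- ci
  }
  out
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat("knowledge_graph:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges;",
      length(unique(x$nodes$ntype)), "semantic types,",
      length(unique(x$edges$predicate)), "predicates\n")
  invisible(x)
}

#' Load predications from a delimited file
#'
#' Headerless tab-separated rows in the 8-column dialect
#' `subject_id, subject_name, subject_type, predicate, object_id,
#' object_name, object_type, count` or the 7-column dialect without the
#' count (each row then contributes weight 1). Duplicate triples are merged
#' by summing counts. Malformed rows raise an error naming the line.
#'
#' @param path Path to the TSV file.
#' @param dialect `"auto"` (default, by column count), `"count"` (8 columns)
#'   or `"unit"` (7 columns).
#' @param registry Semantic-type registry (see [knowledge_graph()]).
#' @return A `knowledge_graph`.
#' @export
load_predications <- function(path, dialect = c("auto", "count", "unit"),
                              registry = default_ntype_registry()) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no predication rows in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_want <- switch(dialect, auto = NA_integer_, count = 8L, unit = 7L)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (is.na(ncol_want)) {
      if (!(length(f) %in% c(7L, 8L)))
        stop("malformed predication row at line ", i, ": expected 7 or 8 ",
             "fields, got ", length(f))
    } else if (length(f) != ncol_want) {
      stop("malformed predication row at line ", i, ": expected ", ncol_want,
           " fields, got ", length(f))
    }
    w <- if (length(f) == 8L) suppressWarnings(as.numeric(f[8])) else 1
    if (is.na(w) || w < 1)
      stop("malformed count at line ", i, ": '", f[8], "'")
    rows[[i]] <- c(f[1:7], w)
  }
  m <- do.call(rbind, rows)
  nodes <- unique(rbind(
    data.frame(id = m[, 1], name = m[, 2], ntype = m[, 3], stringsAsFactors = FALSE),
    data.frame(id = m[, 5], name = m[, 6], ntype = m[, 7], stringsAsFactors = FALSE)))
  dup <- duplicated(nodes$id)
  nodes <- nodes[!dup, , drop = FALSE]
  edges <- data.frame(head = m[, 1], predicate = m[, 4], tail = m[, 5],
                      weight = as.numeric(m[, 8]), stringsAsFactors = FALSE)
  knowledge_graph(nodes, edges, registry = registry)
}

#' Write predications to a delimited file
#'
#' Canonical 8-column TSV (sorted by head, predicate, tail; counts merged),
#' so a load/write round trip is content-stable.
#'
#' @param g A `knowledge_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predications <- function(g, path) {
  stopifnot(inherits(g, "knowledge_graph"))
  idx_h <- match(g$edges$head, g$nodes$id)
  idx_t <- match(g$edges$tail, g$nodes$id)
  out <- cbind(g$edges$head, g$nodes$name[idx_h], g$nodes$ntype[idx_h],
               g$edges$predicate, g$edges$tail, g$nodes$name[idx_t],
               g$nodes$ntype[idx_t], format(g$edges$weight, trim = TRUE,
                                            scientific = FALSE))
  writeLines(apply(out, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Neighbors of a node under predicate/type/direction filters
#'
#' Returns the unique neighbors with weights aggregated across matching
#' edges, ordered by weight descending then id (deterministic).
#'
#' @param g A `knowledge_graph`.
#' @param node Node id (must exist).
#' @param predicates Character vector of predicates, or `NULL` for any.
#' @param ntypes Character vector of neighbor semantic types, or `NULL` for
#'   any.
#' @param direction `"both"` (default), `"out"` (node as subject) or `"in"`.
#' @return Data frame with columns `id`, `ntype`, `weight`.
#' @export
kg_neighbors <- function(g, node, predicates = NULL, ntypes = NULL,
                         direction = c("both", "out", "in")) {
  stopifnot(inherits(g, "knowledge_graph"))
  direction <- match.arg(direction)
  if (!(node %in% g$nodes$id)) stop("unknown node: ", node)
  e <- g$edges
  if (!is.null(predicates)) e <- e[e$predicate %in% predicates, , drop = FALSE]
  nb <- character(0); w <- numeric(0)
  if (direction %in% c("out", "both")) {
    sel <- e$head == node
    nb <- c(nb, e$tail[sel]); w <- c(w, e$weight[sel])
  }
  if (direction %in% c("in", "both")) {
    sel <- e$tail == node
    nb <- c(nb, e$head[sel]); w <- c(w, e$weight[sel])
  }
  if (length(nb) > 0L) {
    agg <- tapply(w, nb, sum)
    nb <- names(agg); w <- as.numeric(agg)
    nt <- g$nodes$ntype[match(nb, g$nodes$id)]
    if (!is.null(ntypes)) {
      keep <- nt %in% ntypes
      nb <- nb[keep]; w <- w[keep]; nt <- nt[keep]
    }
    ord <- order(-w, nb, method = "radix")
    return(data.frame(id = nb[ord], ntype = nt[ord], weight = w[ord],
                      stringsAsFactors = FALSE, row.names = NULL))
  }
  data.frame(id = character(0), ntype = character(0), weight = numeric(0))
}

#' Remove generic nodes and their incident edges
#'
#' Matches the stoplist against normalized lowercase node names or ids. The
#' input graph is unmodified; a pruned copy is returned. Idempotent.
#'
#' @param g A `knowledge_graph`.
#' @param stoplist Character vector of names/ids; defaults to the shipped
#'   generic-node list.
#' @return A pruned `knowledge_graph`.
#' @export
kg_remove_generic <- function(g, stoplist = generic_stoplist()) {
  stopifnot(inherits(g, "knowledge_graph"))
  stop_lc <- tolower(trimws(stoplist))
  drop <- tolower(trimws(g$nodes$name)) %in% stop_lc |
    tolower(g$nodes$id) %in% stop_lc
  if (!any(drop)) return(g)
  keep_ids <- g$nodes$id[!drop]
  e <- g$edges[g$edges$head %in% keep_ids & g$edges$tail %in% keep_ids, ,
               drop = FALSE]
  knowledge_graph(g$nodes[!drop, , drop = FALSE], e, registry = g$registry)
}

#' Degree of a node
#'
#' Weighted (sum of occurrence counts) and unweighted (edge count) degree,
#' totalled over both directions or broken down per predicate or per
#' neighbor semantic type.
#'
#' @param g A `knowledge_graph`.
#' @param node Node id (must exist).
#' @param scope `"total"` (default), `"predicate"`, or `"ntype"`.
#' @return For `"total"`, a list with `weighted` and `unweighted`; otherwise
#'   a data frame with one row per predicate/type carrying both counts.
#' @export
kg_degree <- function(g, node, scope = c("total", "predicate", "ntype")) {
  stopifnot(inherits(g, "knowledge_graph"))
  scope <- match.arg(scope)
  if (!(node %in% g$nodes$id)) stop("unknown node: ", node)
  if (scope == "total") {
    return(list(weighted = unname(g$deg$w_out[node] + g$deg$w_in[node]),
                unweighted = unname(g$deg$d_out[node] + g$deg$d_in[node])))
  }
  e <- g$edges[g$edges$head == node | g$edges$tail == node, , drop = FALSE]
  key <- if (scope == "predicate") e$predicate else {
    other <- ifelse(e$head == node, e$tail, e$head)
    g$nodes$ntype[match(other, g$nodes$id)]
  }
  if (nrow(e) == 0L)
    return(data.frame(key = character(0), weighted = numeric(0),
                      unweighted = integer(0)))
  w <- tapply(e$weight, key, sum); cnt <- table(key)
  data.frame(key = names(w), weighted = as.numeric(w),
             unweighted = as.integer(cnt[names(w)]), row.names = NULL)
}

# total weighted degree, vectorized over ids
.wdeg <- function(g, ids) {
  unname(g$deg$w_out[ids] + g$deg$w_in[ids])
}
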