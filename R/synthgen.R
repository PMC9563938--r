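.DEFAULT_DRUGS <- c("imatinib", "dasatinib", "nilotinib", "bosutinib",
                    "ponatinib")

# Drug-specific AE lexicons used by the default corpus generator. Terms are
# fixed points of the pinned lemmatizer so planted ground truth survives
# preprocessing unchanged.
.DEFAULT_AE_SETS <- list(
  imatinib  = c("edema", "rash", "myelosuppression", "hematological",
                "lesion", "hepatitis", "liver", "dermatitis", "periorbital",
                "fluid"),
  dasatinib = c("pulmonary", "pleural", "effusion", "platelet",
                "hypertension", "dyspnea", "pneumonitis", "bleeding",
                "hemorrhage", "lung"),
  nilotinib = c("hyperglycemia", "glucose", "insulin", "metabolic",
                "pancreatitis", "lipase", "cholesterol", "glycemic",
                "mellitus", "thyroid"),
  bosutinib = c("diarrhea", "nausea", "vomiting", "gastrointestinal",
                "abdominal", "colitis", "dyspepsia", "dehydration",
                "anorexia", "cramp"),
  ponatinib = c("cardiovascular", "vascular", "arterial", "thrombosis",
                "occlusion", "ischemia", "stenosis", "infarction",
                "hypertensive", "stroke"))

#' Specify a synthetic drug-labelled abstract corpus
#'
#' The generator emulates the structure of a drug-specific AE corpus: each
#' abstract belongs to one drug (balanced within one document), always
#' mentions its drug name, and draws its remaining tokens from a mixture of
#' a shared Zipf-like background multinomial and AE terms whose probability
#' is multiplied by `enrichment` when the term belongs to the abstract's
#' drug. `enrichment = 1` is the null (AE terms independent of drug).
#'
#' @param n_drugs Number of drugs (<= 5 uses the named kinase-inhibitor
#'   lexicons shipped with the package; more get synthetic names/terms).
#' @param n_abstracts Total number of abstracts.
#' @param vocab_background Background vocabulary size.
#' @param ae_per_drug AE terms per drug (only for synthetic lexicons).
#' @param enrichment Multiplicative boost (>= 1) of a drug's own AE terms.
#' @param tokens_per_abstract Tokens sampled per abstract (plus the drug
#'   mentions).
#' @param drug_mentions Mean extra drug-name mentions per abstract; each
#'   abstract carries `1 + Poisson(drug_mentions)` copies of its drug name,
#'   reflecting repeated mentions across title and body.
#' @param ae_base_prob Per-token baseline probability of each AE term before
#'   boosting (default 8e-4, giving a document-presence baseline of a few
#'   percent at the default abstract length).
#' @param seed Integer seed.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_drugs = 5L, n_abstracts = 250L,
                        vocab_background = 500L, ae_per_drug = 10L,
                        enrichment = 5, tokens_per_abstract = 150L,
                        drug_mentions = 2, ae_base_prob = 8e-4, seed = 1L) {
  stopifnot(n_drugs >= 2L, n_abstracts >= n_drugs, enrichment >= 1,
            vocab_background >= 10L, tokens_per_abstract >= 5L,
            drug_mentions >= 0,
            ae_base_prob > 0, ae_base_prob * ae_per_drug * n_drugs < 0.5)
  structure(list(n_drugs = n_drugs, n_abstracts = n_abstracts,
                 vocab_background = vocab_background,
                 ae_per_drug = ae_per_drug, enrichment = enrichment,
                 tokens_per_abstract = tokens_per_abstract,
                 drug_mentions = drug_mentions,
                 ae_base_prob = ae_base_prob, seed = seed),
            class = "corpus_spec")
}

#' Generate a synthetic corpus with planted drug-AE enrichment
#'
#' @param spec A [corpus_spec()].
#' @return List: `records` (abstract records consumable by
#'   [preprocess_corpus()]), `labels` (data frame `id`, `drug`), `drugs`,
#'   `ae_terms` (named list of per-drug AE term sets), `spec`.
#'   Deterministic per seed.
#' @export
gen_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  set.seed(spec$seed)
  if (spec$n_drugs <= length(.DEFAULT_DRUGS)) {
    drugs <- .DEFAULT_DRUGS[seq_len(spec$n_drugs)]
    ae <- .DEFAULT_AE_SETS[drugs]
    ae <- lapply(ae, head, spec$ae_per_drug)
  } else {
    drugs <- sprintf("drug%02d", seq_len(spec$n_drugs))
    ae <- lapply(seq_len(spec$n_drugs), function(d)
      sprintf("ae%02dterm%02d", d, seq_len(spec$ae_per_drug)))
    names(ae) <- drugs
  }
  bg <- sprintf("w%04d", seq_len(spec$vocab_background))
  ae_all <- unlist(ae, use.names = FALSE)
  if (length(ae_all) + spec$vocab_background > 26^4)
    stop("vocabulary sizes infeasible")
  bg_w <- 1 / (seq_len(spec$vocab_background) + 10)
  vocab <- c(bg, ae_all)
  ae_w_base <- spec$ae_base_prob / (1 - spec$ae_base_prob * length(ae_all)) *
    sum(bg_w)
  labels <- sample(rep_len(seq_along(drugs), spec$n_abstracts))
  probs <- lapply(seq_along(drugs), function(d) {
    w <- c(bg_w, rep(ae_w_base, length(ae_all)))
    own <- spec$vocab_background + which(ae_all %in% ae[[d]])
    w[own] <- w[own] * spec$enrichment
    w / sum(w)
  })
  records <- lapply(seq_len(spec$n_abstracts), function(i) {
    d <- labels[i]
    toks <- sample(vocab, spec$tokens_per_abstract - 1L, replace = TRUE,
                   prob = probs[[d]])
    mentions <- 1L + stats::rpois(1, spec$drug_mentions)
    list(id = sprintf("abs%05d", i),
         text = paste(c(rep(drugs[d], mentions), toks), collapse = " "))
  })
  list(records = records,
       labels = data.frame(id = sprintf("abs%05d", seq_len(spec$n_abstracts)),
                           drug = drugs[labels], stringsAsFactors = FALSE),
       drugs = drugs, ae_terms = ae, spec = spec)
}

#' Specify a synthetic typed knowledge graph with hub communities
#'
#' The generated graph mirrors the structure the hub-network pipeline
#' assumes: two anchor concepts (a disease anchor and a kinase anchor), hub
#' disease nodes adjacent to both anchors with maximal connectivity, a
#' community of mixed-type entities around each hub (each community uses a
#' characteristic predicate, making held-out community edges learnable by a
#' translational embedding), a planted set of "relevant" disease nodes that
#' share middle-layer neighbors with hub-community members, decoy shared
#' neighbors with low degree, and background nodes with sparse random
#' edges. Edge weights are `1 + Geometric` (many single-occurrence
#' predications, few heavy ones).
#'
#' @param n_dsyn,n_aapp,n_bacs,n_gngm,n_phsu,n_topp Node counts per
#'   semantic type (hubs, decoys and the planted set are drawn from the
#'   DSYN pool).
#' @param n_hubs Number of hub nodes.
#' @param n_decoys Low-degree shared anchor neighbors.
#' @param n_relevant Size of the planted relevant DSYN set.
#' @param community_size Members per hub community (including the core).
#' @param core_size Heavily co-cited core members per community: every
#'   community member links to each core member, the kinase anchor links to
#'   all cores, and planted nodes link to the cores of their communities.
#' @param planted_communities Number of hub communities each planted node
#'   attaches to.
#' @param bg_links_dsyn Mean background links per non-planted DSYN node.
#' @param bg_links_other Mean extra random links per non-DSYN node.
#' @param weight_geom_prob Success probability of the geometric weight draw.
#' @param holdout_frac Fraction of member-to-hub community edges held out
#'   of the training graph (in `[0, 1)`).
#' @param seed Integer seed.
#' @return A `kg_spec` list.
#' @export
kg_spec <- function(n_dsyn = 200L, n_aapp = 40L, n_bacs = 30L, n_gngm = 40L,
                    n_phsu = 30L, n_topp = 10L, n_hubs = 6L, n_decoys = 2L,
                    n_relevant = 10L, community_size = 12L, core_size = 4L,
                    planted_communities = 6L,
                    bg_links_dsyn = 3, bg_links_other = 0.5,
                    weight_geom_prob = 0.5, holdout_frac = 0, seed = 1L) {
  stopifnot(n_hubs >= 1L, n_relevant >= 0L,
            n_dsyn >= n_hubs + n_decoys + n_relevant,
            community_size >= 2L, core_size >= 1L,
            core_size < community_size,
            planted_communities >= 1L, planted_communities <= n_hubs,
            holdout_frac >= 0, holdout_frac < 1,
            n_aapp + n_bacs + n_gngm + n_phsu >= community_size)
  structure(as.list(environment()), class = "kg_spec")
}

.rgeomw <- function(n, prob) 1 + stats::rgeom(n, prob)

#' Generate a synthetic knowledge graph with planted ground truth
#'
#' @param spec A [kg_spec()].
#' @return List: `graph` (training `knowledge_graph`, holdout removed),
#'   `truth` (list: `anchors`, `hubs`, `decoys`, `planted`, `communities`
#'   per hub, `focal`), and `holdout` (data frame `head`, `predicate`,
#'   `tail`, disjoint from the training edges). Deterministic per seed.
#' @export
gen_kg <- function(spec) {
  stopifnot(inherits(spec, "kg_spec"))
  set.seed(spec$seed)
  preds <- prediction_predicates()
  mk <- function(pre, nt, n) if (n > 0L)
    data.frame(id = sprintf("%s%03d", pre, seq_len(n)),
               name = sprintf("%s %d (synthetic)", tolower(nt), seq_len(n)),
               ntype = nt, stringsAsFactors = FALSE)
  nodes <- rbind(
    data.frame(id = "ANCH_DIS", name = "leukemia target (synthetic)",
               ntype = "NEOP", stringsAsFactors = FALSE),
    data.frame(id = "ANCH_KIN", name = "tyrosine kinase target (synthetic)",
               ntype = "AAPP", stringsAsFactors = FALSE),
    mk("DSYN", "DSYN", spec$n_dsyn), mk("AAPP", "AAPP", spec$n_aapp),
    mk("BACS", "BACS", spec$n_bacs), mk("GNGM", "GNGM", spec$n_gngm),
    mk("PHSU", "PHSU", spec$n_phsu), mk("TOPP", "TOPP", spec$n_topp))
  dsyn <- nodes$id[nodes$ntype == "DSYN" & nodes$id != "ANCH_DIS"]
  hubs <- dsyn[seq_len(spec$n_hubs)]
  decoys <- if (spec$n_decoys > 0L)
    dsyn[spec$n_hubs + seq_len(spec$n_decoys)] else character(0)
  planted <- if (spec$n_relevant > 0L)
    dsyn[spec$n_hubs + spec$n_decoys + seq_len(spec$n_relevant)] else
      character(0)
  background_dsyn <- setdiff(dsyn, c(hubs, decoys, planted))
  pool <- nodes$id[nodes$ntype %in% c("AAPP", "BACS", "GNGM", "PHSU") &
                     nodes$id != "ANCH_KIN"]

  E <- list()
  add <- function(h, p, t, w) {
    E[[length(E) + 1L]] <<- data.frame(head = h, predicate = p, tail = t,
                                       weight = w, stringsAsFactors = FALSE)
  }
  # anchors -> hubs, heavy; anchors -> decoys, light
  add("ANCH_DIS", "CAUSES", hubs, 8 + .rgeomw(length(hubs), spec$weight_geom_prob))
  add("ANCH_KIN", "AFFECTS", hubs, 8 + .rgeomw(length(hubs), spec$weight_geom_prob))
  if (length(decoys) > 0L) {
    add("ANCH_DIS", "CAUSES", decoys, .rgeomw(length(decoys), spec$weight_geom_prob))
    add("ANCH_KIN", "AFFECTS", decoys, .rgeomw(length(decoys), spec$weight_geom_prob))
  }
  # hub communities, each with a characteristic predicate and a dense core:
  # every member cites each core member, so cores are the shared
  # middle-layer through which planted nodes and community members meet
  communities <- list(); cores <- list()
  member_edges <- list()  # structured member -> hub edges, holdout pool
  for (i in seq_along(hubs)) {
    cp <- preds[(i - 1L) %% length(preds) + 1L]
    members <- sample(pool, spec$community_size)
    core <- members[seq_len(spec$core_size)]
    communities[[hubs[i]]] <- members
    cores[[hubs[i]]] <- core
    member_edges[[i]] <- data.frame(
      head = members, predicate = cp, tail = hubs[i],
      weight = .rgeomw(length(members), spec$weight_geom_prob),
      stringsAsFactors = FALSE)
    for (m in members) {
      tgt <- setdiff(core, m)
      if (length(tgt) > 0L)
        add(m, cp, tgt, .rgeomw(length(tgt), spec$weight_geom_prob))
    }
    add("ANCH_KIN", "AFFECTS", core, .rgeomw(length(core), spec$weight_geom_prob))
  }
  # planted relevant DSYN cite the cores of a few communities, sharing
  # middle-layer neighbors with those communities' members
  for (p in planted) {
    hub_pick <- sample(seq_along(hubs), spec$planted_communities)
    for (i in hub_pick) {
      cp <- preds[(i - 1L) %% length(preds) + 1L]
      core <- cores[[hubs[i]]]
      add(p, cp, core, .rgeomw(length(core), spec$weight_geom_prob))
    }
  }
  # background noise
  for (b in background_dsyn) {
    k <- stats::rpois(1, spec$bg_links_dsyn)
    if (k == 0L) k <- 1L  # keep every DSYN rankable in principle
    others <- sample(setdiff(nodes$id, b), k)
    pp <- sample(preds, k, replace = TRUE)
    flip <- stats::runif(k) < 0.5
    add(ifelse(flip, others, b), pp, ifelse(flip, b, others),
        .rgeomw(k, spec$weight_geom_prob))
  }
  other_nodes <- setdiff(nodes$id, c(dsyn, "ANCH_DIS", "ANCH_KIN"))
  nbg <- stats::rpois(length(other_nodes), spec$bg_links_other)
  for (j in which(nbg > 0L)) {
    b <- other_nodes[j]; k <- nbg[j]
    others <- sample(setdiff(nodes$id, b), k)
    add(b, sample(preds, k, replace = TRUE), others,
        .rgeomw(k, spec$weight_geom_prob))
  }

  member_edges <- do.call(rbind, member_edges)
  nho <- floor(spec$holdout_frac * nrow(member_edges))
  if (nho > 0L) {
    ho_idx <- sample(nrow(member_edges), nho)
    holdout <- member_edges[ho_idx, c("head", "predicate", "tail")]
    rownames(holdout) <- NULL
    member_edges <- member_edges[-ho_idx, , drop = FALSE]
  } else {
    holdout <- data.frame(head = character(0), predicate = character(0),
                          tail = character(0))
  }
  edges <- rbind(do.call(rbind, E), member_edges)
  # drop any background duplicate of a held-out triple to keep disjointness
  if (nrow(holdout) > 0L) {
    hk <- paste(holdout$head, holdout$predicate, holdout$tail, sep = "\r")
    ek <- paste(edges$head, edges$predicate, edges$tail, sep = "\r")
    edges <- edges[!(ek %in% hk), , drop = FALSE]
  }
  g <- knowledge_graph(nodes, edges)
  list(graph = g,
       truth = list(anchors = c("ANCH_DIS", "ANCH_KIN"), hubs = hubs,
                    decoys = decoys, planted = planted,
                    communities = communities, cores = cores,
                    focal = "ANCH_KIN"),
       holdout = holdout)
}
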