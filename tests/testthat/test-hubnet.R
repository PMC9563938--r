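sim_result <- function(hub, ids, scores) {
  structure(list(hub = hub,
                 candidates = data.frame(id = ids, score = scores,
                                         norm_score = scores,
                                         similarity = 1 - scores,
                                         novelty = 0)),
            class = "hub_sim_result")
}

test_that("hub selection intersects anchor neighborhoods and sorts by degree", {
  nodes <- data.frame(id = c("a1", "a2", "s1", "s2", "s3", "only1", "x"),
                      name = c("a1", "a2", "s1", "s2", "s3", "only1", "x"),
                      ntype = "DSYN")
  edges <- data.frame(
    head = c("a1", "a1", "a1", "a1", "a2", "a2", "a2", "s2"),
    predicate = "CAUSES",
    tail = c("s1", "s2", "s3", "only1", "s1", "s2", "s3", "x"),
    weight = c(1, 1, 1, 1, 5, 1, 2, 10))
  g <- knowledge_graph(nodes, edges)
  # shared: s1 (deg 6), s2 (deg 12), s3 (deg 3); brute-force order by degree
  expect_identical(select_hubs(g, c("a1", "a2"), n = 6), c("s2", "s1", "s3"))
  expect_identical(select_hubs(g, c("a1", "a2"), n = 2), c("s2", "s1"))
  # disjoint neighborhoods
  g2 <- knowledge_graph(nodes, edges[c(1, 7), ])
  expect_warning(h <- select_hubs(g2, c("a1", "a2")), "manually")
  expect_identical(h, character(0))
})

test_that("hub neighborhoods dedup to max weight and respect the cap", {
  kg <- gen_kg(kg_spec(n_dsyn = 40, n_aapp = 15, n_bacs = 10, n_gngm = 15,
                       n_phsu = 10, n_topp = 4, n_relevant = 4, seed = 9))
  g <- kg$graph
  model <- train_transe(g, epochs = 20, seed = 9)
  hub <- kg$truth$hubs[1]
  nb <- build_hub_neighborhood(model, g, hub, cap = 10)
  expect_lte(nrow(nb$members), 10)
  expect_false(hub %in% nb$members$id)
  expect_false(anyDuplicated(nb$members$id) > 0)
  expect_true(all(nb$members$norm_weight >= 0 & nb$members$norm_weight <= 1))
  # brute-force oracle: per-node max norm_weight across the six predicates
  preds <- do.call(rbind, lapply(prediction_predicates(), function(p)
    predict_entities(model, g, hub, p, top_k = 10)))
  best <- tapply(preds$norm_weight, preds$tail, max)
  expect_equal(nb$members$norm_weight,
               as.numeric(best[nb$members$id]), tolerance = 1e-12)
  expect_true(all(nb$members$norm_weight >=
                    max(best[setdiff(names(best), nb$members$id)],
                        -Inf)))
})

test_that("per-simulation normalization spans [0,1] and preserves order", {
  kg <- gen_kg(kg_spec(n_dsyn = 40, n_aapp = 15, n_bacs = 10, n_gngm = 15,
                       n_phsu = 10, n_topp = 4, n_relevant = 4, seed = 5))
  g <- kg_remove_generic(kg$graph)
  model <- train_transe(g, epochs = 20, seed = 5)
  nb <- build_hub_neighborhood(model, g, kg$truth$hubs[2], cap = 10)
  sim <- run_hub_simulation(g, nb, kg$truth$focal)
  cand <- sim$candidates
  expect_gte(nrow(cand), 2)
  expect_equal(min(cand$norm_score), 0)
  expect_equal(max(cand$norm_score), 1)
  expect_identical(order(cand$score), order(cand$norm_score))
  expect_error(run_hub_simulation(g, structure(list(
    hub = "h", members = data.frame(id = character(0))),
    class = "hub_neighborhood"), kg$truth$focal), "empty")
})

test_that("aggregation computes occurrence, mean score and composite", {
  sims <- c(lapply(1:6, function(i) sim_result(paste0("h", i), "best", 0)),
            lapply(1:3, function(i) sim_result(paste0("g", i), "half", 0.5)))
  # 'best' in 6/9 sims at score 0; 'half' in 3/9 at 0.5
  agg <- aggregate_hub_sims(sims)
  expect_equal(agg$composite[agg$id == "best"], 6 / 9)
  expect_equal(agg$composite[agg$id == "half"], (3 / 9) * 0.5)
  expect_false("absent" %in% agg$id)
  # candidate in all sims with perfect scores has composite exactly 1
  sims2 <- lapply(1:6, function(i) sim_result(paste0("h", i), "best", 0))
  agg2 <- aggregate_hub_sims(sims2)
  expect_equal(agg2$composite, 1)
  expect_identical(agg2$rank, 1L)
})

test_that("aggregate ranking is invariant to simulation order", {
  set.seed(14)
  sims <- lapply(1:6, function(i) {
    ids <- sample(sprintf("c%02d", 1:15), 8)
    sim_result(paste0("h", i), ids, round(runif(8), 3))
  })
  a <- aggregate_hub_sims(sims)
  b <- aggregate_hub_sims(sims[sample(6)])
  expect_identical(a, b)
  expect_true(all(a$composite >= 0 & a$composite <= 1))
  expect_true(all(diff(a$composite) <= 0))
})

test_that("tier boundaries follow ceiling arithmetic and nest", {
  mk_ranking <- function(n) {
    r <- data.frame(id = sprintf("n%04d", 1:n),
                    occurrence_rate = 1, mean_score = seq(0, 1, length.out = n))
    r$composite <- r$occurrence_rate * (1 - r$mean_score)
    r <- r[order(-r$composite, r$id), ]
    r$rank <- seq_len(n)
    class(r) <- c("aggregate_ranking", "data.frame")
    r
  }
  t1000 <- assign_tiers(mk_ranking(1000))
  expect_identical(sum(t1000$tier == "1"), 10L)
  expect_identical(sum(t1000$tier %in% c("1", "2")), 50L)
  expect_identical(sum(t1000$tier %in% c("1", "2", "3")), 100L)
  t10 <- assign_tiers(mk_ranking(10))
  expect_identical(which(t10$tier == "1"), 1L)   # ceil(0.1) = 1
  t3 <- assign_tiers(mk_ranking(3))
  expect_identical(t3$tier, c("1", "none", "none"))  # all cutoffs collapse
  for (n in c(1, 7, 99, 250)) {
    tt <- assign_tiers(mk_ranking(n))
    in1 <- tt$id[tt$tier == "1"]
    in12 <- tt$id[tt$tier %in% c("1", "2")]
    in123 <- tt$id[tt$tier %in% c("1", "2", "3")]
    expect_true(all(in1 %in% in12) && all(in12 %in% in123))
    expect_gte(length(in1), 1)
  }
  expect_error(assign_tiers(mk_ranking(10), cutoffs = c(0.05, 0.05, 0.1)),
               "strictly increasing")
})

test_that("foci labelling is file-driven with top-3 summaries", {
  r <- data.frame(id = sprintf("n%02d", 1:10), occurrence_rate = 1,
                  mean_score = seq(0, 0.9, by = 0.1))
  r$composite <- 1 - r$mean_score
  r$rank <- 1:10
  class(r) <- c("aggregate_ranking", "data.frame")
  r <- assign_tiers(r, cutoffs = c(0.1, 0.5, 1))
  empty <- apply_foci(r, setNames(character(0), character(0)))
  expect_true(all(empty$ranking$focus == "other"))
  map <- setNames(rep("hematology", 5), sprintf("n%02d", 1:5))
  out <- apply_foci(r, map)
  hem <- out$summary[out$summary$focus == "hematology", ]
  expect_identical(hem$n, 5L)
  expect_identical(hem$top3, "n01,n02,n03")  # only 3 listed of 5 members
  f <- tempfile()
  writeLines(c("n01\thematology", "brokenline"), f)
  expect_error(read_foci_map(f), "line 2")
  writeLines(c("n01\thematology", "n02\tglucose"), f)
  expect_identical(read_foci_map(f), c(n01 = "hematology", n02 = "glucose"))
})

test_that("curation templates export tiered rows and validate verdicts", {
  r <- data.frame(id = sprintf("n%02d", 1:20), occurrence_rate = 1,
                  mean_score = 0.5, composite = seq(1, 0.05, length.out = 20),
                  rank = 1:20)
  class(r) <- c("aggregate_ranking", "data.frame")
  r <- assign_tiers(r, cutoffs = c(0.1, 0.3, 0.5))
  tmpl <- export_curation_template(r)
  expect_identical(nrow(tmpl), 10L)   # tiers cover the top 50% here
  expect_true(all(tmpl$verdict == ""))
  tmpl$verdict <- "agrees"
  counts <- read_curation_template(tmpl)
  expect_identical(as.integer(counts["agrees"]), 10L)
  tmpl$verdict[1] <- "maybe"
  expect_error(read_curation_template(tmpl), "maybe")
  p <- tempfile()
  export_curation_template(r, p)
  expect_identical(nrow(utils::read.delim(p)), 10L)
})
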