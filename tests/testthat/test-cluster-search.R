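path_graph <- function(ids) {
  county_graph(ids, cbind(ids[-length(ids)], ids[-1]))
}

test_that("connected-subset enumeration matches the spec counts", {
  p3 <- path_graph(c("A", "B", "C"))
  expect_length(enumerate_connected_subsets(p3, 3), 6L) # {A,C} excluded

  tri <- county_graph(c("A", "B", "C"),
                      rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  expect_length(enumerate_connected_subsets(tri, 3), 7L)

  star <- county_graph(c("S", "a", "b", "c"),
                       rbind(c("S", "a"), c("S", "b"), c("S", "c")))
  expect_length(enumerate_connected_subsets(star, 2), 7L)
})

test_that("enumeration equals the powerset filter on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in c(3, 14, 27)) {
    inst <- random_instance(seed, n_max = 8L)
    got <- enumerate_connected_subsets(inst$graph, 4)
    want <- oracle_connected_subsets(inst$graph, 4)
    key <- function(l) sort(vapply(l, paste, character(1), collapse = "|"))
    expect_equal(key(got), key(want))
    expect_false(anyDuplicated(key(got)) > 0)
  }
})

test_that("exact search returns the brute-force argmax with tie-breaking", {
  ids <- sprintf("v%d", 1:5)
  g <- path_graph(ids)
  tab <- count_table(data.frame(county = ids, year = 2015,
                                tot_b = 100, opioid_b = c(1, 9, 9, 1, 1),
                                tot_p = 100, opioid_p = c(1, 9, 9, 1, 1)))
  cfg <- search_config("kulldorff_poisson", "claims", max_size = 2)
  best <- exact_best_cluster(g, tab, 2015, cfg)
  expect_equal(best$members, c("v2", "v3"))

  # uniform rates: no elevated cluster; tie-break singleton, score 0
  flat <- count_table(data.frame(county = ids, year = 2015,
                                 tot_b = 100, opioid_b = 10,
                                 tot_p = 100, opioid_p = 10))
  tie <- exact_best_cluster(g, flat, 2015, cfg)
  expect_equal(tie$score, 0)
  expect_equal(tie$members, "v1")

  one <- exact_best_cluster(g, tab, 2015,
                            search_config("kulldorff_poisson", "claims",
                                          max_size = 1))
  expect_equal(one$members, "v2") # v2 before v3 on equal score

  expect_error(exact_best_cluster(make_grid_graph(10, 10), tab, 2015, cfg,
                                  budget = 100),
               "search_best_cluster")
})

test_that("heuristic equals exact search on small random instances", {
  cfg <- search_config("kulldorff_poisson", "claims", max_size = 5)
  for (seed in 1:12) {
    inst <- random_instance(seed)
    ex <- exact_best_cluster(inst$graph, inst$table, 2015, cfg)
    he <- search_best_cluster(inst$graph, inst$table, 2015, cfg)
    expect_equal(he$score, ex$score, tolerance = 1e-9,
                 info = sprintf("seed %d", seed))
  }
})

test_that("returned clusters are connected and respect the size bound", {
  sim <- simulate_scenario(synthetic_scenario(seed = 5))
  cfg <- search_config("kulldorff_poisson", "claims", max_size = 4)
  cl <- search_best_cluster(sim$graph, sim$counts, 2015, cfg)
  expect_lte(length(cl$members), 4L)
  expect_true(netscan:::is_connected_set(sim$graph, cl$members))
})

test_that("ranked clusters are disjoint with nonincreasing scores", {
  # two disjoint elevated paths on a grid
  g <- make_grid_graph(4, 5)
  hot1 <- c("c001", "c002", "c003")
  hot2 <- c("c018", "c019", "c020")
  ev <- ifelse(g$nodes %in% hot1, 40, ifelse(g$nodes %in% hot2, 25, 10))
  tab <- count_table(data.frame(county = g$nodes, year = 2015,
                                tot_b = 100, opioid_b = ev,
                                tot_p = 100, opioid_p = ev))
  cfg <- search_config("kulldorff_poisson", "claims", max_size = 3,
                       n_secondary = 3)
  cls <- top_k_clusters(g, tab, 2015, cfg)
  expect_gte(length(cls), 2L)
  scores <- vapply(cls, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 1e-9))
  mem <- lapply(cls, `[[`, "members")
  expect_equal(anyDuplicated(unlist(mem)), 0L)
  expect_equal(cls[[1]]$members, hot1)
  expect_equal(cls[[2]]$members, hot2)
  # per-region exact scores confirm the ordering
  cfg1 <- search_config("kulldorff_poisson", "claims", max_size = 3)
  ex <- exact_best_cluster(g, tab, 2015, cfg1)
  expect_equal(cls[[1]]$score, ex$score)

  flat <- count_table(data.frame(county = g$nodes, year = 2015,
                                 tot_b = 100, opioid_b = 10,
                                 tot_p = 100, opioid_p = 10))
  u <- top_k_clusters(g, flat, 2015, cfg)
  expect_length(u, 1L)
  expect_equal(u[[1]]$score, 0)

  only1 <- top_k_clusters(g, tab, 2015,
                          search_config("kulldorff_poisson", "claims",
                                        max_size = 3, n_secondary = 0))
  expect_length(only1, 1L)
})

test_that("heuristic recovers an injected cluster on the grid", {
  hits <- 0
  for (seed in 0:9) {
    sim <- simulate_scenario(synthetic_scenario(seed = seed))
    cfg <- search_config("kulldorff_poisson", "claims", max_size = 10)
    cl <- search_best_cluster(sim$graph, sim$counts, 2015, cfg)
    if (jaccard(cl$members, sim$cluster) >= 0.7) hits <- hits + 1
  }
  expect_gte(hits, 9L)
})

test_that("circular scan needs centroids and finds a hot singleton", {
  g <- make_grid_graph(3, 3)
  ev <- ifelse(g$nodes == "c005", 40, 10)
  tab <- count_table(data.frame(county = g$nodes, year = 2015,
                                tot_b = 100, opioid_b = ev,
                                tot_p = 100, opioid_p = ev))
  cfg <- search_config("kulldorff_poisson", "claims", max_size = 9)

  # brute force over all center/k zones
  best <- -Inf; best_zone <- NULL
  D <- geosphere::distm(g$centroids)
  bl <- rep(100, 9); evv <- ev
  for (ci in 1:9) {
    ord <- order(D[ci, ], seq_len(9))
    for (k in 1:9) {
      zone <- ord[1:k]
      if (sum(bl[zone]) > 0.5 * sum(bl)) break
      s <- netscan:::kulldorff_llr(sum(evv[zone]), sum(bl[zone]),
                                   sum(evv), sum(bl))
      if (s > best) { best <- s; best_zone <- sort(zone) }
    }
  }
  zones <- circular_scan(g, tab, 2015, cfg)
  expect_equal(zones[[1]]$members, "c005")
  expect_equal(zones[[1]]$score, best, tolerance = 1e-12)
  expect_equal(sort(match(zones[[1]]$members, g$nodes)), best_zone)

  nog <- county_graph(g$nodes, g$edges) # no centroids
  expect_error(circular_scan(nog, tab, 2015, cfg), "centroid")
})

test_that("connected search dominates circular zones that are connected", {
  for (seed in 101:110) {
    set.seed(seed)
    g <- make_grid_graph(4, 4)
    bl <- sample(200:800, 16, replace = TRUE)
    ev <- pmin(rpois(16, 0.1 * bl * exp(rnorm(16, 0, 0.5))), bl)
    tab <- count_table(data.frame(county = g$nodes, year = 2015,
                                  tot_b = bl, opioid_b = ev,
                                  tot_p = bl, opioid_p = ev))
    cfg <- search_config("kulldorff_poisson", "claims", max_size = 8)
    zone <- circular_scan(g, tab, 2015, cfg)[[1]]
    if (!netscan:::is_connected_set(g, zone$members) ||
        length(zone$members) > 8) next
    conn <- search_best_cluster(g, tab, 2015, cfg)
    expect_gte(conn$score + 1e-9, zone$score)
  }
})
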