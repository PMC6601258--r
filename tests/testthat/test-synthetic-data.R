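test_that("grid graphs have lattice structure and centroids", {
  g1 <- make_grid_graph(1, 1)
  expect_length(g1$nodes, 1L)
  expect_equal(nrow(g1$edges), 0L)

  g2 <- make_grid_graph(2, 2)
  expect_length(g2$nodes, 4L)
  expect_equal(nrow(g2$edges), 4L)

  g4 <- make_grid_graph(4, 4)
  expect_equal(nrow(g4$edges), 2 * 4 * 4 - 4 - 4) # 2mn - m - n
  expect_false(is.null(g4$centroids))
  expect_equal(max(netscan:::graph_components(g4)), 1L)
})

test_that("generated tables satisfy all validators and the seed contract", {
  sc <- synthetic_scenario(rows = 5, cols = 5, baseline_mean = 800,
                           cluster_size = 4, n_providers_per_county = 3,
                           seed = 42)
  sim1 <- simulate_scenario(sc)
  sim2 <- simulate_scenario(sc)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$covariates, sim2$covariates)
  expect_identical(sim1$providers, sim2$providers)

  expect_silent(netscan:::validate_count_table(sim1$counts))
  expect_silent(netscan:::validate_covariates(sim1$covariates))
  expect_silent(netscan:::validate_providers(sim1$providers))
  expect_true(netscan:::is_connected_set(sim1$graph, sim1$cluster))
  expect_length(sim1$cluster, 4L)
})

test_that("injected cluster attains the target pooled rate", {
  rates <- numeric(20)
  for (seed in 0:19) {
    sim <- simulate_scenario(synthetic_scenario(seed = seed))
    yr <- sim$counts[sim$counts$year == 2015, ]
    inside <- yr$county %in% sim$cluster
    rates[seed + 1] <- sum(yr$opioid_p[inside]) / sum(yr$tot_p[inside])
  }
  # pooled claims across 20 seeds: ~ 6 counties x 5000 claims each
  se <- sqrt(0.2 / (20 * 6 * 5000))
  expect_lt(abs(mean(rates) - 0.2), 3 * se / sqrt(1))
})

test_that("null scenarios have no spatial rate structure", {
  sim <- simulate_scenario(synthetic_scenario(cluster_rate = 0.1, seed = 3))
  yr <- sim$counts[sim$counts$year == 2015, ]
  inside <- yr$county %in% sim$cluster
  r_in <- sum(yr$opioid_p[inside]) / sum(yr$tot_p[inside])
  r_out <- sum(yr$opioid_p[!inside]) / sum(yr$tot_p[!inside])
  se <- sqrt(0.1 / sum(yr$tot_p[inside]))
  expect_lt(abs(r_in - r_out), 4 * se)
})

test_that("covariate effects shift inside means and clipping holds", {
  eff <- default_covariate_effects()
  g <- make_grid_graph(10, 10)
  cl <- c("c001", "c002", "c003", "c011", "c012", "c013")
  set.seed(1)
  cov1 <- generate_covariates(g, cl, eff)
  inside <- cov1$county %in% cl
  gap <- mean(cov1$pct_medicaid[inside]) - mean(cov1$pct_medicaid[!inside])
  se <- 4 * sqrt(1 / 6 + 1 / 94)
  expect_lt(abs(gap - 5), 3 * se)

  # zero-effect covariate: means indistinguishable
  gap0 <- mean(cov1$pct_medicare[inside]) - mean(cov1$pct_medicare[!inside])
  expect_lt(abs(gap0), 3 * 4 * sqrt(1 / 6 + 1 / 94))

  # clipping at 100
  eff$pct_male <- list(inside = 99, outside = 99, sd = 5)
  set.seed(2)
  cov2 <- generate_covariates(g, cl, eff)
  expect_lte(max(cov2$pct_male), 100)
})

test_that("provider counts conserve county totals exactly", {
  sc <- synthetic_scenario(rows = 4, cols = 4, baseline_mean = 600,
                           cluster_size = 3, n_providers_per_county = 5,
                           seed = 11)
  sim <- simulate_scenario(sc)
  yr <- sim$counts[sim$counts$year == 2015, ]
  agg <- aggregate(sim$providers[c("tot_b", "opioid_b", "tot_p", "opioid_p")],
                   by = list(county = sim$providers$county), FUN = sum)
  agg <- agg[match(yr$county, agg$county), ]
  expect_equal(agg$tot_p, yr$tot_p)
  expect_equal(agg$opioid_p, yr$opioid_p)
  expect_equal(agg$tot_b, yr$tot_b)
  expect_equal(agg$opioid_b, yr$opioid_b)
  expect_true(all(sim$providers$opioid_p <= sim$providers$tot_p))
  expect_true(all(sim$providers$opioid_b <= sim$providers$tot_b))
})

test_that("one provider per county reproduces the county rows", {
  sc <- synthetic_scenario(rows = 3, cols = 3, baseline_mean = 400,
                           cluster_size = 2, n_providers_per_county = 1,
                           seed = 6)
  sim <- simulate_scenario(sc)
  yr <- sim$counts[sim$counts$year == 2015, ]
  p <- sim$providers[match(yr$county, sim$providers$county), ]
  expect_equal(p$tot_p, yr$tot_p)
  expect_equal(p$opioid_b, yr$opioid_b)
})

test_that("provider shares follow the symmetric Dirichlet expectation", {
  set.seed(9)
  sc <- synthetic_scenario(rows = 4, cols = 4, baseline_mean = 2000,
                           cluster_size = 3, n_providers_per_county = 5,
                           seed = 9)
  shares <- numeric(0)
  for (s in 1:10) {
    sc$seed <- s
    sim <- simulate_scenario(sc)
    yr <- sim$counts[sim$counts$year == 2015, ]
    first <- sim$providers[grepl("_pr01$", sim$providers$provider_id), ]
    shares <- c(shares, first$tot_p[match(yr$county, first$county)] / yr$tot_p)
  }
  # mean share of one of 5 symmetric providers is 1/5
  expect_lt(abs(mean(shares) - 0.2), 3 * stats::sd(shares) / sqrt(length(shares)))
})

test_that("temporal change multiplies the region's rate in one year only", {
  region <- c("c044", "c045", "c046")
  sc <- synthetic_scenario(cluster_rate = 0.1, # no persistent cluster
                           temporal_change = list(year = 2015, region = region,
                                                  multiplier = 2),
                           seed = 13)
  sim <- simulate_scenario(sc)
  for (yy in 2013:2015) {
    yr <- sim$counts[sim$counts$year == yy, ]
    inr <- yr$county %in% region
    rate <- sum(yr$opioid_p[inr]) / sum(yr$tot_p[inr])
    target <- if (yy == 2015) 0.2 else 0.1
    expect_lt(abs(rate - target), 4 * sqrt(target / sum(yr$tot_p[inr])))
  }
})
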