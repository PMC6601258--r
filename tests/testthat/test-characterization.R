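test_that("county labeling marks exactly the significant-cluster members", {
  roster <- sprintf("c%02d", 1:20)
  expect_equal(sum(label_counties(roster, list())), 0L)
  cl <- netscan:::new_cluster(roster[3:7], 5, "kulldorff_poisson", "claims", 2015)
  lab <- label_counties(roster, list(cl))
  expect_equal(sum(lab), 5L)
  expect_equal(names(lab)[lab == 1], roster[3:7])
  bad <- netscan:::new_cluster("zz", 1, "kulldorff_poisson", "claims", 2015)
  expect_error(label_counties(roster, list(bad)), "roster")
})

test_that("correlation pruning keeps the first of each correlated group", {
  set.seed(8)
  n <- 200
  df <- data.frame(county = sprintf("c%03d", 1:n))
  x <- rnorm(n)
  df$pct_african_american <- pmin(100, pmax(0, 15 + 5 * x))
  df$pct_american_indian <- pmin(100, pmax(0, 15 + 5 * x + rnorm(n, 0, 0.5))) # r ~ 1
  df$pct_male <- pmin(100, pmax(0, rnorm(n, 49, 2)))
  df$n_housing_units <- round(pmax(0, rnorm(n, 3e4, 1e4)))
  df$pct_medicaid <- pmin(100, pmax(0, rnorm(n, 15, 3)))
  df$pct_medicare <- pmin(100, pmax(0, rnorm(n, 17, 3)))
  df$pct_direct_purchase <- pmin(100, pmax(0, 12 + 0.5 * scale(df$pct_medicaid)[, 1] + rnorm(n, 0, 0.67)))
  df$pct_income_poverty_lt_0_5 <- pmin(100, pmax(0, rnorm(n, 6, 2)))

  pruned <- prune_correlated(df, 0.6)
  kept <- setdiff(names(pruned), "county")
  expect_true("pct_african_american" %in% kept)
  expect_false("pct_american_indian" %in% kept) # duplicate dropped
  # audit: all surviving pairs below the threshold
  cm <- cor(pruned[kept])
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.6)

  # identical column dropped; orthogonal columns kept
  two <- data.frame(county = df$county, pct_medicaid = df$pct_medicaid,
                    pct_medicare = df$pct_medicaid)
  p2 <- prune_correlated(two, 0.6)
  expect_equal(setdiff(names(p2), "county"), "pct_medicaid")

  const <- df
  const$pct_male <- 50
  expect_warning(pc <- prune_correlated(const, 0.6), "zero variance")
  expect_false("pct_male" %in% names(pc))
})

make_reg_data <- function(seed, n = 300, beta = 0, target = "pct_medicaid") {
  set.seed(seed)
  df <- data.frame(county = sprintf("c%03d", seq_len(n)))
  mus <- c(pct_african_american = 15, pct_american_indian = 1, pct_male = 49,
           n_housing_units = 30000, pct_medicaid = 18, pct_medicare = 17,
           pct_direct_purchase = 12, pct_income_poverty_lt_0_5 = 6)
  sds <- c(3, 0.4, 1.5, 8000, 1, 2, 2, 1.5)
  for (i in seq_along(mus)) {
    df[[names(mus)[i]]] <- rnorm(n, mus[i], sds[i])
  }
  eta <- beta * (df[[target]] - mus[[target]])
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  list(covariates = df, labels = setNames(y, df$county))
}

test_that("stepwise-AIC selects a strong true effect and reports its OR", {
  d <- make_reg_data(21, n = 500, beta = 0.7)
  fit <- stepwise_aic_logistic(d$labels, d$covariates)
  expect_true("pct_medicaid" %in% fit$selected_variables)
  row <- fit$table[fit$table$variable == "pct_medicaid", ]
  expect_equal(log(row$odds_ratio), 0.7, tolerance = 0.25)
  expect_true(row$significant)
  # stepwise AIC <= full-model AIC and <= null-model AIC
  cand <- setdiff(names(d$covariates), "county")
  dat <- d$covariates[cand]
  dat$.y <- unname(d$labels)
  full <- glm(.y ~ ., family = binomial(), data = dat)
  nul <- glm(.y ~ 1, family = binomial(), data = dat)
  expect_lte(fit$aic, AIC(full) + 1e-9)
  expect_lte(fit$aic, AIC(nul) + 1e-9)
})

test_that("stepwise agrees with exhaustive subset enumeration", {
  for (seed in c(5, 6)) {
    d <- make_reg_data(seed, n = 250, beta = 0.7)
    fit <- stepwise_aic_logistic(d$labels, d$covariates)
    X <- as.matrix(d$covariates[setdiff(names(d$covariates), "county")])
    ex <- oracle_exhaustive_aic(unname(d$labels), X)
    expect_equal(sort(fit$selected_variables), ex$vars)
    expect_equal(fit$aic, ex$aic, tolerance = 1e-8)
  }
})

test_that("pure-noise covariates mostly yield small models", {
  picks <- integer(20)
  for (seed in 1:20) {
    d <- make_reg_data(seed + 100, n = 200, beta = 0)
    fit <- suppressWarnings(stepwise_aic_logistic(d$labels, d$covariates))
    picks[seed] <- length(fit$selected_variables)
  }
  # each noise variable enters with prob ~ P(chisq_1 > 2) ~ 0.157
  expect_lt(mean(picks), 8 * 0.3)
})

test_that("degenerate regressions are rejected", {
  d <- make_reg_data(33, n = 100, beta = 0)
  all0 <- setNames(rep(0L, 100), d$covariates$county)
  expect_error(stepwise_aic_logistic(all0, d$covariates), "single class")
  sep <- d$labels
  sep[] <- as.integer(d$covariates$pct_medicaid > 18)
  expect_error(stepwise_aic_logistic(sep, d$covariates),
               "separation.*pct_medicaid")
})

prov_df <- function(ob, op, county = "A", specialty = "Family Practice") {
  n <- length(ob)
  data.frame(provider_id = sprintf("p%02d", seq_len(n)), county = county,
             specialty = specialty, tot_b = pmax(ob, 1) * 10,
             opioid_b = ob, tot_p = pmax(op, 1) * 10, opioid_p = op,
             stringsAsFactors = FALSE)
}

test_that("top-decile providers require both axes and honor ties", {
  p <- prov_df(1:10, 1:10)
  top <- top_decile_providers(p, "A")
  expect_equal(top$provider_id, "p10")

  # top decile in beneficiaries but not claims -> excluded
  p2 <- prov_df(c(1:9, 100), c(100, 1:9))
  expect_equal(nrow(top_decile_providers(p2, "A")), 0L)

  ties <- prov_df(rep(5, 8), rep(7, 8))
  expect_equal(nrow(top_decile_providers(ties, "A")), 8L)

  # idempotent
  again <- top_decile_providers(top, "A")
  expect_equal(again, top)

  expect_warning(none <- top_decile_providers(p, "ZZ"), "no providers")
  expect_equal(nrow(none), 0L)
})

test_that("provider profiles average percentages within specialty", {
  p <- rbind(prov_df(20, 10), prov_df(30, 10))
  p$provider_id <- c("a", "b")
  p$tot_b <- 100
  p$tot_p <- 100
  prof <- provider_profile(p)
  expect_equal(prof$n_providers, 2L)
  expect_equal(prof$mean_pct_opioid_beneficiaries, 25)
  expect_equal(prof$mean_pct_opioid_claims, 10)
  expect_equal(prof$mean_total_beneficiaries, 100)

  p$tot_b[2] <- 0
  expect_warning(prof2 <- provider_profile(p), "zero totals")
  expect_equal(prof2$mean_pct_opioid_beneficiaries, 20)

  expect_error(provider_profile(p[0, ]), "empty")
})

test_that("recovered coefficient signs match the generative model", {
  ok <- 0
  for (seed in 1:20) {
    d <- make_reg_data(seed + 500, n = 500, beta = 0.7)
    fit <- suppressWarnings(stepwise_aic_logistic(d$labels, d$covariates))
    row <- fit$table[fit$table$variable == "pct_medicaid", ]
    if (row$selected && log(row$odds_ratio) > 0) ok <- ok + 1
  }
  expect_gte(ok, 19L)
})
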