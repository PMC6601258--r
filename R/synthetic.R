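#' Grid county graph
#'
#' A rows x cols rook-adjacency lattice with zero-padded county ids and
#' centroids at the cell centers (degrees), convenient as a synthetic
#' study area.
#'
#' @param rows,cols lattice dimensions (>= 1).
#' @return a [county_graph()].
#' @examples
#' make_grid_graph(2, 2)
#' @export
make_grid_graph <- function(rows, cols) {
  if (rows < 1L || cols < 1L) stopf("rows and cols must be >= 1")
  n <- rows * cols
  w <- max(3L, nchar(as.character(n)))
  id <- function(r, c) sprintf(paste0("c%0", w, "d"), (r - 1L) * cols + c)
  ea <- character(0); eb <- character(0)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) { ea <- c(ea, id(r, c)); eb <- c(eb, id(r, c + 1L)) }
      if (r < rows) { ea <- c(ea, id(r, c)); eb <- c(eb, id(r + 1L, c)) }
    }
  }
  cen <- expand.grid(c = seq_len(cols), r = seq_len(rows))
  centroids <- data.frame(county = mapply(id, cen$r, cen$c),
                          lon = cen$c - 0.5, lat = cen$r - 0.5)
  if (length(ea)) county_graph(centroids$county, cbind(ea, eb), centroids)
  else county_graph(centroids$county, centroids = centroids)
}

#' Synthetic study scenario
#'
#' Generative parameters for a synthetic county study area: a grid
#' contiguity graph, log-normal county baselines, Poisson event counts at
#' background rate `background_rate` outside and `cluster_rate` inside a
#' connected injected cluster, an optional one-year temporal rate change,
#' covariates whose means may differ inside/outside the cluster, and a
#' provider layer splitting county counts.
#'
#' Defaults describe the reference simulation conditions used throughout
#' the package's validation: a 10 x 10 grid, background rate 0.1,
#' cluster rate 0.2 (a doubled rate) on a 6-county connected cluster,
#' mean county baseline 5000 claims, three years of data.
#'
#' @param rows,cols grid dimensions.
#' @param background_rate events per unit baseline outside the cluster
#'   (mu > 0).
#' @param cluster_rate rate inside the cluster (eta >= mu; eta = mu is a
#'   null scenario).
#' @param cluster_members `"auto"` (random connected subset of
#'   `cluster_size` counties, grown by random walk) or a character vector
#'   of county ids that must induce a connected subgraph.
#' @param cluster_size size of the auto-selected cluster.
#' @param baseline_mean mean county baseline count (claims layer).
#' @param baseline_dispersion log-scale standard deviation of the county
#'   size distribution (county sizes are right-skewed).
#' @param year_jitter log-scale sd of the small year-to-year multiplier on
#'   a county's baseline (county exposures are nearly constant in time).
#' @param beneficiary_fraction mean beneficiary baseline as a fraction of
#'   the claims baseline.
#' @param years vector of years to generate.
#' @param temporal_change optional `list(year =, region =, multiplier =)`:
#'   multiply the event rate of `region` (county ids, or `"cluster"`) in
#'   that one year only.
#' @param covariate_effects named list, one entry per covariate column,
#'   each `list(inside =, outside =, sd =)` giving the truncated-normal
#'   means inside/outside the cluster and the sd. Defaults give most
#'   covariates no inside/outside difference, with elevated Medicaid
#'   access and a lower African-American percentage inside the cluster —
#'   the qualitative contrast the characterization stage is meant to
#'   recover.
#' @param n_providers_per_county providers per county.
#' @param specialties character vector of provider specialties.
#' @param specialty_probs sampling probabilities for `specialties`.
#' @param seed root seed; [simulate_scenario()] is a pure function of the
#'   scenario including this seed.
#' @return a `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(rows = 10L, cols = 10L,
                               background_rate = 0.1, cluster_rate = 0.2,
                               cluster_members = "auto", cluster_size = 6L,
                               baseline_mean = 5000, baseline_dispersion = 0.5,
                               year_jitter = 0.05,
                               beneficiary_fraction = 0.5,
                               years = 2013:2015,
                               temporal_change = NULL,
                               covariate_effects = default_covariate_effects(),
                               n_providers_per_county = 5L,
                               specialties = default_specialties(),
                               specialty_probs = NULL,
                               seed = 1L) {
  if (background_rate <= 0) stopf("background_rate must be > 0")
  if (cluster_rate < background_rate) stopf("cluster_rate must be >= background_rate")
  if (is.null(specialty_probs)) specialty_probs <- rep(1, length(specialties))
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 background_rate = background_rate, cluster_rate = cluster_rate,
                 cluster_members = cluster_members,
                 cluster_size = as.integer(cluster_size),
                 baseline_mean = baseline_mean,
                 baseline_dispersion = baseline_dispersion,
                 year_jitter = year_jitter,
                 beneficiary_fraction = beneficiary_fraction,
                 years = as.integer(years), temporal_change = temporal_change,
                 covariate_effects = covariate_effects,
                 n_providers_per_county = as.integer(n_providers_per_county),
                 specialties = specialties,
                 specialty_probs = specialty_probs / sum(specialty_probs),
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' @rdname synthetic_scenario
#' @export
default_covariate_effects <- function() {
  list(
    pct_african_american      = list(inside = 12, outside = 18, sd = 7),
    pct_american_indian       = list(inside = 1,  outside = 1,  sd = 0.5),
    pct_male                  = list(inside = 49, outside = 49, sd = 1.5),
    n_housing_units           = list(inside = 30000, outside = 30000, sd = 10000),
    pct_medicaid              = list(inside = 20, outside = 15, sd = 4),
    pct_medicare              = list(inside = 17, outside = 17, sd = 4),
    pct_direct_purchase       = list(inside = 12, outside = 12, sd = 3),
    pct_income_poverty_lt_0_5 = list(inside = 6,  outside = 6,  sd = 2)
  )
}

#' @rdname synthetic_scenario
#' @export
default_specialties <- function() {
  c("Family Practice", "Internal Medicine", "Nurse Practitioner",
    "Physician Assistant", "Dentist", "Physical Medicine and Rehabilitation",
    "Pain Management", "Orthopedic Surgery")
}

# Random connected subset grown by random walk from a random seed node.
random_connected_subset <- function(graph, size) {
  n <- length(graph$nodes)
  if (size > n) stopf("cluster_size exceeds the number of counties")
  cur <- sample.int(n, 1L)
  mem <- cur
  while (length(mem) < size) {
    frontier <- setdiff(unique(unlist(graph$adj[mem])), mem)
    if (!length(frontier)) break
    mem <- c(mem, frontier[sample.int(length(frontier), 1L)])
  }
  graph$nodes[sort(mem)]
}

# Poisson draw bounded by cap; resamples a few times, then caps with a
# warning (only relevant when the rate approaches 1).
rpois_capped <- function(lambda, cap) {
  x <- rpois(length(lambda), lambda)
  for (k in 1:10) {
    bad <- x > cap
    if (!any(bad)) return(x)
    x[bad] <- rpois(sum(bad), lambda[bad])
  }
  bad <- x > cap
  if (any(bad)) {
    warnf("%d event count(s) capped at their baseline (rate near 1)", sum(bad))
    x[bad] <- cap[bad]
  }
  x
}

#' Generate a synthetic count table
#'
#' County baselines are log-normal (one size per county, with a small
#' log-normal year-to-year jitter), rounded with a floor of 1. Event
#' counts are Poisson with mean `rate * baseline`, where the rate is
#' `cluster_rate` inside the injected cluster and `background_rate`
#' outside; an optional `temporal_change` multiplies the rate of a region
#' in a single year. Beneficiary baselines and events are generated
#' analogously (scaled by `beneficiary_fraction`), independently of the
#' claims layer. Uses the current RNG state.
#'
#' @param graph a [county_graph()].
#' @param scenario a [synthetic_scenario()].
#' @param cluster_members resolved cluster member ids (connected set).
#' @return a [count_table()].
#' @export
generate_counts <- function(graph, scenario, cluster_members) {
  n <- length(graph$nodes)
  inside <- graph$nodes %in% cluster_members
  sdl <- scenario$baseline_dispersion
  meanlog_p <- log(scenario$baseline_mean) - sdl^2 / 2
  meanlog_b <- log(scenario$baseline_mean * scenario$beneficiary_fraction) - sdl^2 / 2
  size_p <- rlnorm(n, meanlog_p, sdl)
  size_b <- rlnorm(n, meanlog_b, sdl)

  out <- vector("list", length(scenario$years))
  for (k in seq_along(scenario$years)) {
    yr <- scenario$years[k]
    tot_p <- pmax(1, round(size_p * rlnorm(n, 0, scenario$year_jitter)))
    tot_b <- pmax(1, round(size_b * rlnorm(n, 0, scenario$year_jitter)))
    rate <- ifelse(inside, scenario$cluster_rate, scenario$background_rate)
    tc <- scenario$temporal_change
    if (!is.null(tc) && tc$year == yr) {
      region <- if (identical(tc$region, "cluster")) cluster_members else tc$region
      rate[graph$nodes %in% region] <- rate[graph$nodes %in% region] * tc$multiplier
    }
    opioid_p <- rpois_capped(rate * tot_p, tot_p)
    opioid_b <- rpois_capped(rate * tot_b, tot_b)
    out[[k]] <- data.frame(county = graph$nodes, year = yr,
                           tot_b = tot_b, opioid_b = opioid_b,
                           tot_p = tot_p, opioid_p = opioid_p)
  }
  count_table(do.call(rbind, out))
}

#' Generate synthetic county covariates
#'
#' Each covariate is drawn from a normal with the inside or outside mean
#' depending on cluster membership; percentage columns are clipped to
#' \[0, 100\] and `n_housing_units` is rounded and floored at 0. Uses the
#' current RNG state.
#'
#' @param graph a [county_graph()].
#' @param cluster_members county ids inside the anomalous cluster.
#' @param covariate_effects see [synthetic_scenario()].
#' @return a covariate data frame (see [read_covariates()]).
#' @export
generate_covariates <- function(graph, cluster_members,
                                covariate_effects = default_covariate_effects()) {
  n <- length(graph$nodes)
  inside <- graph$nodes %in% cluster_members
  df <- data.frame(county = graph$nodes, stringsAsFactors = FALSE)
  for (cn in COVARIATE_COLUMNS) {
    eff <- covariate_effects[[cn]]
    if (is.null(eff)) stopf("covariate_effects lacks entry for '%s'", cn)
    mu <- ifelse(inside, eff$inside, eff$outside)
    v <- rnorm(n, mu, eff$sd)
    if (cn == "n_housing_units") {
      v <- pmax(0, round(v))
    } else {
      v <- pmin(100, pmax(0, v))
    }
    df[[cn]] <- v
  }
  validate_covariates(df)
}

# Multivariate hypergeometric split of `k` successes among urns of sizes
# `sizes` (sequential rhyper); preserves sum(k) and per-urn bounds.
rmvhyper <- function(k, sizes) {
  n <- length(sizes)
  out <- numeric(n)
  rem_k <- k
  rem_n <- sum(sizes)
  for (i in seq_len(n)) {
    if (rem_k <= 0) break
    if (i == n) {
      out[i] <- rem_k
    } else {
      out[i] <- rhyper(1L, sizes[i], rem_n - sizes[i], rem_k)
      rem_k <- rem_k - out[i]
    }
    rem_n <- rem_n - sizes[i]
  }
  out
}

#' Generate a synthetic provider table
#'
#' Splits each county's totals for one year across providers with a
#' symmetric Dirichlet-multinomial, then allocates the county's opioid
#' counts among providers by multivariate hypergeometric sampling (so
#' provider sums reproduce county counts exactly and opioid <= total holds
#' per provider). Specialties are sampled with county-independent
#' probabilities. Uses the current RNG state.
#'
#' @param graph a [county_graph()].
#' @param table a [count_table()].
#' @param scenario a [synthetic_scenario()].
#' @param year which year's counts to split (default: last scenario year).
#' @return a provider data frame (see [read_providers()]).
#' @export
generate_providers <- function(graph, table, scenario,
                               year = max(scenario$years)) {
  yr <- table[table$year == year, , drop = FALSE]
  m <- scenario$n_providers_per_county
  rows <- vector("list", nrow(yr))
  for (i in seq_len(nrow(yr))) {
    w <- rgamma(m, shape = 1)      # symmetric Dirichlet(1)
    w <- w / sum(w)
    tot_b <- as.numeric(rmultinom(1L, yr$tot_b[i], w))
    tot_p <- as.numeric(rmultinom(1L, yr$tot_p[i], w))
    opioid_b <- rmvhyper(yr$opioid_b[i], tot_b)
    opioid_p <- rmvhyper(yr$opioid_p[i], tot_p)
    rows[[i]] <- data.frame(
      provider_id = sprintf("%s_pr%02d", yr$county[i], seq_len(m)),
      county = yr$county[i],
      specialty = sample(scenario$specialties, m, replace = TRUE,
                         prob = scenario$specialty_probs),
      tot_b = tot_b, opioid_b = opioid_b, tot_p = tot_p, opioid_p = opioid_p,
      stringsAsFactors = FALSE)
  }
  validate_providers(do.call(rbind, rows))
}

#' Simulate a full synthetic study
#'
#' Seeds the RNG from the scenario and generates the graph, the injected
#' cluster, the count table, covariates and providers. A pure function of
#' the scenario: the same scenario (including seed) gives bit-identical
#' output.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a list with `graph`, `cluster` (true injected member ids),
#'   `counts`, `covariates`, `providers`, `scenario`.
#' @examples
#' sim <- simulate_scenario(synthetic_scenario(rows = 4, cols = 4,
#'   baseline_mean = 500, n_providers_per_county = 2, seed = 7))
#' head(sim$counts)
#' @export
simulate_scenario <- function(scenario) {
  set.seed(scenario$seed)
  graph <- make_grid_graph(scenario$rows, scenario$cols)
  cluster <- if (identical(scenario$cluster_members, "auto")) {
    random_connected_subset(graph, scenario$cluster_size)
  } else {
    mem <- as.character(scenario$cluster_members)
    if (!is_connected_set(graph, mem)) {
      stopf("cluster_members do not induce a connected subgraph")
    }
    csort(mem)
  }
  counts <- generate_counts(graph, scenario, cluster)
  covariates <- generate_covariates(graph, cluster, scenario$covariate_effects)
  providers <- generate_providers(graph, counts, scenario)
  list(graph = graph, cluster = cluster, counts = counts,
       covariates = covariates, providers = providers, scenario = scenario)
}
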