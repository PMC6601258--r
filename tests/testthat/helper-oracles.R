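# Independent oracles used across the suite. These deliberately avoid the
# package's own closed forms and search machinery.

# Numeric maximization oracle for the Kulldorff Poisson log likelihood
# ratio: maximize the two-rate Poisson likelihood subject to eta >= mu,
# maximize the one-rate null likelihood, return the log ratio.
oracle_kulldorff <- function(c, b, Ctot, Btot) {
  stopifnot(b > 0, Btot > b)
  c_out <- Ctot - c
  b_out <- Btot - b
  ll_in <- function(eta) if (eta <= 0) ifelse(c == 0, 0, -Inf) else c * log(eta * b) - eta * b
  ll_out <- function(mu) if (mu <= 0) ifelse(c_out == 0, 0, -Inf) else c_out * log(mu * b_out) - mu * b_out
  ll_null <- function(mu) {
    if (mu <= 0) return(ifelse(Ctot == 0, 0, -Inf))
    c * log(mu * b) - mu * b + c_out * log(mu * b_out) - mu * b_out
  }
  opt1 <- function(f, hint) {
    lo <- max(hint / 50, 1e-12); hi <- hint * 50 + 1
    o <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
    # refine on a narrow bracket: golden-section accuracy is relative to
    # the interval, so a second pass gains several digits
    stats::optimize(f, c(o$maximum * 0.99, o$maximum * 1.01),
                    maximum = TRUE, tol = .Machine$double.eps^0.5 * o$maximum)
  }
  # unconstrained separable maximizers; a zero count puts the supremum at
  # the rate -> 0 boundary with log-likelihood 0, outside any finite bracket
  oin <- if (c == 0) list(maximum = 0, objective = 0) else opt1(ll_in, c / b)
  oout <- if (c_out == 0) list(maximum = 0, objective = 0) else opt1(ll_out, c_out / b_out)
  onull <- if (Ctot == 0) list(maximum = 0, objective = 0) else opt1(ll_null, Ctot / Btot)
  if (oin$maximum > oout$maximum) {
    h1 <- oin$objective + oout$objective
  } else {
    # constraint active: eta = mu, which collapses to the null model
    h1 <- onull$objective
  }
  max(h1 - onull$objective, 0)
}

# Numeric oracle for the expectation-based score: maximize the
# Poisson(mu * b) log likelihood over mu >= 1, subtract it at mu = 1.
oracle_expectation <- function(c, b) {
  stopifnot(b > 0)
  ll <- function(mu) c * log(mu * b) - mu * b
  o <- stats::optimize(ll, c(1, max(c / b, 1) * 50 + 1), maximum = TRUE,
                       tol = 1e-13)
  best <- max(o$objective, ll(1)) # boundary mu = 1
  max(best - ll(1), 0)
}

# Brute-force connected subsets by powerset filtering, with igraph as the
# independent connectivity check.
oracle_connected_subsets <- function(graph, max_size) {
  n <- length(graph$nodes)
  ig <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  ig <- ig + igraph::vertices(setdiff(graph$nodes, igraph::V(ig)$name))
  out <- list()
  for (k in seq_len(min(max_size, n))) {
    combos <- utils::combn(graph$nodes, k, simplify = FALSE)
    for (s in combos) {
      sub <- igraph::induced_subgraph(ig, s)
      if (igraph::is_connected(sub)) out[[length(out) + 1L]] <- sort(s)
    }
  }
  out
}

# Exhaustive all-subsets AIC search for the logistic model (independent of
# MASS::stepAIC): returns the variable set minimizing AIC.
oracle_exhaustive_aic <- function(y, X) {
  vars <- colnames(X)
  stopifnot(length(vars) <= 12)
  best_aic <- Inf
  best_set <- character(0)
  dat <- as.data.frame(X)
  dat$.y <- y
  for (mask in 0:(2^length(vars) - 1)) {
    inc <- vars[bitwAnd(mask, 2^(seq_along(vars) - 1)) > 0]
    f <- if (length(inc)) paste(".y ~", paste(inc, collapse = "+")) else ".y ~ 1"
    fit <- suppressWarnings(stats::glm(stats::as.formula(f),
                                       family = stats::binomial(), data = dat))
    a <- stats::AIC(fit)
    if (a < best_aic - 1e-9) {
      best_aic <- a
      best_set <- inc
    }
  }
  list(aic = best_aic, vars = sort(best_set))
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Random sparse graph + Poisson count table for small-instance checks.
random_instance <- function(seed, n_max = 12L) {
  set.seed(seed)
  n <- sample(4:n_max, 1L)
  ids <- sprintf("n%02d", seq_len(n))
  p <- 0.35
  ea <- character(0); eb <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (runif(1) < p) { ea <- c(ea, ids[i]); eb <- c(eb, ids[j]) }
    }
  }
  g <- if (length(ea)) county_graph(ids, cbind(ea, eb)) else county_graph(ids)
  bl <- sample(50:500, n, replace = TRUE)
  ev <- rpois(n, 0.1 * bl * exp(rnorm(n, 0, 0.4)))
  ev <- pmin(ev, bl)
  tab <- count_table(data.frame(county = ids, year = 2015,
                                tot_b = bl, opioid_b = ev,
                                tot_p = bl, opioid_p = ev))
  list(graph = g, table = tab)
}
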