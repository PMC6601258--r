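#' Simulate one null replicate of a count table
#'
#' For the Kulldorff statistic the null replicate keeps every baseline
#' fixed and redistributes the year's total event count across counties by
#' a single multinomial draw with probabilities proportional to the
#' baselines — i.i.d. Poisson counts conditioned on their observed total.
#' For the expectation-based statistic the null fixes each county's mean
#' at its history-based expectation, so events are drawn independently
#' Poisson per county without conditioning on the total.
#'
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param table a [count_table()].
#' @param year year whose event counts are replaced.
#' @param count_kind `"beneficiary"` or `"claims"`.
#' @param statistic which null model to draw from.
#' @param expected per-county expected counts, in `sort(county)` order,
#'   required for the expectation-based null.
#' @return a `count_table` (not re-validated: conditioning can in
#'   principle place more events than baseline in a county).
#' @export
simulate_null_replicate <- function(table, year,
                                    count_kind = c("beneficiary", "claims"),
                                    statistic = c("kulldorff_poisson",
                                                  "expectation_poisson"),
                                    expected = NULL) {
  count_kind <- match.arg(count_kind)
  statistic <- match.arg(statistic)
  cols <- kind_cols(count_kind)
  rows <- which(table$year == year)
  if (!length(rows)) stopf("no rows for year %s", year)
  # count_table() sorts by (county, year): rows are in sorted county order
  if (statistic == "kulldorff_poisson") {
    bl <- table[[cols$baseline]][rows]
    tot <- sum(table[[cols$event]][rows])
    if (sum(bl) <= 0) stopf("total baseline must be positive")
    draw <- as.numeric(rmultinom(1L, size = tot, prob = bl))
  } else {
    if (is.null(expected)) stopf("expectation-based null needs 'expected'")
    if (length(expected) != length(rows)) {
      stopf("'expected' must have one entry per county row of the year")
    }
    draw <- as.numeric(rpois(length(rows), expected))
  }
  table[[cols$event]][rows] <- draw
  table
}

#' Null distribution of the maximum scan score
#'
#' Runs the full cluster search on `R` null replicates and records each
#' replicate's maximum score. Replicate r uses a deterministic child seed
#' derived from the root seed, so the distribution is reproducible and
#' independent of evaluation order.
#'
#' @inheritParams exact_best_cluster
#' @return a `null_distribution` list with `replicate_max_scores`, `seed`,
#'   `statistic`, `count_kind`.
#' @export
simulate_null_distribution <- function(graph, table, year, config) {
  R <- config$replicates
  seeds <- child_seeds(config$seed, R)
  sig <- node_signal(graph, table, year, config)
  expected <- if (config$statistic == "expectation_poisson") sig$bl else NULL
  maxima <- numeric(R)
  for (r in seq_len(R)) {
    set.seed(seeds[r])
    rep_tab <- simulate_null_replicate(table, year, config$count_kind,
                                       config$statistic, expected)
    rep_sig <- node_signal(graph, rep_tab, year, config)
    cl <- search_masked(graph, rep_sig, config)
    maxima[r] <- cl$score
  }
  structure(list(replicate_max_scores = maxima, seed = config$seed,
                 statistic = config$statistic, count_kind = config$count_kind),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> R = %d max scores (%s/%s), quantiles:\n",
              length(x$replicate_max_scores), x$statistic, x$count_kind))
  print(quantile(x$replicate_max_scores, c(0.5, 0.9, 0.95, 0.99)))
  invisible(x)
}

mc_pvalue <- function(observed, maxima) {
  (1 + sum(maxima >= observed)) / (length(maxima) + 1)
}

#' Monte Carlo p-value of an observed scan score
#'
#' `p = (1 + #\{r : S_r >= observed\}) / (R + 1)` where `S_r` is the
#' maximum score on null replicate r. The add-one estimator never returns
#' zero; the smallest attainable p is `1/(R+1)`.
#'
#' @param observed_score observed maximum score (nats).
#' @inheritParams exact_best_cluster
#' @return a list with `p_value` and the `null_distribution`.
#' @export
monte_carlo_pvalue <- function(observed_score, graph, table, year, config) {
  null <- simulate_null_distribution(graph, table, year, config)
  list(p_value = mc_pvalue(observed_score, null$replicate_max_scores),
       null = null)
}

#' Attach Monte Carlo p-values to a ranked cluster list
#'
#' Every cluster, primary and secondary, is compared against the same null
#' distribution of replicate maxima (the conservative, standard scan
#' convention); those with `p <= alpha` are flagged significant. Only
#' flagged clusters should feed the downstream characterization.
#'
#' @param clusters list of `cluster` objects (from [top_k_clusters()]).
#' @param null a `null_distribution`.
#' @param alpha significance level (default 0.05).
#' @return the cluster list with `p_value` and `significant` filled in.
#' @export
mark_significant <- function(clusters, null, alpha = 0.05) {
  lapply(clusters, function(cl) {
    cl$p_value <- mc_pvalue(cl$score, null$replicate_max_scores)
    cl$significant <- cl$p_value <= alpha
    cl
  })
}
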