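#' Search configuration
#'
#' Bundles the knobs of a cluster search: which statistic, which count
#' kind, the cluster size bound, how many secondary clusters, the Monte
#' Carlo replicate count, the significance level and the root seed.
#'
#' @param statistic `"kulldorff_poisson"` (rate elevated relative to the
#'   rest of the study area in the same year) or `"expectation_poisson"`
#'   (counts elevated relative to the county's own history).
#' @param count_kind `"beneficiary"` or `"claims"`.
#' @param max_size maximum cluster size in counties (default 30, the
#'   largest cluster scale of interest for state-level county analyses).
#' @param n_secondary number of secondary clusters to report after the
#'   primary one (disjoint, found by node removal).
#' @param replicates Monte Carlo replicates R; p-values have resolution
#'   1/(R+1). Default 999.
#' @param alpha significance level for flagging clusters (default 0.05).
#' @param seed root RNG seed; replicate r uses a deterministic child seed.
#' @param history_years years averaged into the expectation-based
#'   baseline (required for the expectation statistic).
#' @param continuity floor for zero expected counts (default 0.5).
#' @return a `search_config` list.
#' @export
search_config <- function(statistic = c("kulldorff_poisson", "expectation_poisson"),
                          count_kind = c("claims", "beneficiary"),
                          max_size = 30L, n_secondary = 0L,
                          replicates = 999L, alpha = 0.05, seed = 1L,
                          history_years = NULL, continuity = 0.5) {
  if (length(statistic) == 1L && statistic %in% c("kulldorff", "expectation")) {
    statistic <- paste0(statistic, "_poisson") # accepted short aliases
  }
  statistic <- match.arg(statistic)
  count_kind <- match.arg(count_kind)
  if (max_size < 1L) stopf("max_size must be >= 1")
  if (n_secondary < 0L) stopf("n_secondary must be >= 0")
  if (replicates < 1L) stopf("replicates must be >= 1")
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (statistic == "expectation_poisson" && is.null(history_years)) {
    stopf("the expectation-based statistic needs history_years")
  }
  structure(list(statistic = statistic, count_kind = count_kind,
                 max_size = as.integer(max_size),
                 n_secondary = as.integer(n_secondary),
                 replicates = as.integer(replicates), alpha = alpha,
                 seed = as.integer(seed), history_years = history_years,
                 continuity = continuity),
            class = "search_config")
}

new_cluster <- function(members, score, statistic, count_kind, year,
                        rank = NA_integer_, p_value = NA_real_,
                        significant = NA) {
  structure(list(members = csort(members), score = score,
                 statistic = statistic, count_kind = count_kind,
                 year = year, rank = rank, p_value = p_value,
                 significant = significant),
            class = "cluster")
}

#' @export
print.cluster <- function(x, ...) {
  cat(sprintf("<cluster> rank %s | %s/%s %s | score %.4f | p %s | %d counties\n",
              ifelse(is.na(x$rank), "?", x$rank), x$statistic, x$count_kind,
              x$year, x$score,
              ifelse(is.na(x$p_value), "?", format(x$p_value, digits = 3)),
              length(x$members)))
  cat("  ", paste(x$members, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convert a cluster list to the output data frame
#'
#' Columns: `rank,statistic,count_kind,year,score,p_value,n_members,members`
#' with members a `;`-joined sorted list.
#'
#' @param clusters a list of `cluster` objects.
#' @return a data frame.
#' @export
clusters_to_df <- function(clusters) {
  data.frame(
    rank = vapply(clusters, function(x) as.integer(x$rank), integer(1)),
    statistic = vapply(clusters, function(x) x$statistic, character(1)),
    count_kind = vapply(clusters, function(x) x$count_kind, character(1)),
    year = vapply(clusters, function(x) as.integer(x$year), integer(1)),
    score = vapply(clusters, function(x) x$score, numeric(1)),
    p_value = vapply(clusters, function(x) x$p_value, numeric(1)),
    n_members = vapply(clusters, function(x) length(x$members), integer(1)),
    members = vapply(clusters, function(x) paste(x$members, collapse = ";"),
                     character(1)),
    stringsAsFactors = FALSE
  )
}

# Per-node event/baseline signal for a given year and config. For the
# Kulldorff statistic the baseline is the same-year exposure and the
# totals are the whole-roster sums; for the expectation statistic the
# baseline is the county's expected count from history (totals unused by
# the score).
node_signal <- function(graph, table, year, config) {
  cols <- kind_cols(config$count_kind)
  yr <- table[table$year == year, , drop = FALSE]
  idx <- match(graph$nodes, yr$county)
  if (anyNA(idx)) {
    stopf("missing (county, year) row(s): %s",
          paste(sprintf("%s (%s)", graph$nodes[is.na(idx)], year), collapse = ", "))
  }
  ev <- yr[[cols$event]][idx]
  if (config$statistic == "kulldorff_poisson") {
    bl <- yr[[cols$baseline]][idx]
    list(ev = ev, bl = bl, Ctot = sum(ev), Btot = sum(bl), stat_code = 0L)
  } else {
    bl <- vapply(graph$nodes, function(cty) {
      expected_from_history(table, cty, year, config$history_years,
                            config$count_kind, config$continuity)
    }, numeric(1L))
    list(ev = ev, bl = unname(bl), Ctot = sum(ev), Btot = sum(bl), stat_code = 1L)
  }
}

signal_score <- function(sig, c, b) {
  if (sig$stat_code == 0L) kulldorff_llr(c, b, sig$Ctot, sig$Btot)
  else expectation_llr(c, b)
}

#' Enumerate all connected county subsets up to a size bound
#'
#' Yields every node subset of size 1..`max_size` that induces a connected
#' subgraph, each exactly once, using reverse-search extension (each
#' subset is generated only from its minimum-index node). Intended as the
#' exact search space for [exact_best_cluster()]; feasible only on small
#' graphs.
#'
#' @param graph a [county_graph()].
#' @param max_size maximum subset size.
#' @return a list of character vectors (sorted county ids).
#' @export
enumerate_connected_subsets <- function(graph, max_size) {
  if (max_size < 1L) stopf("max_size must be >= 1")
  idx_subs <- enum_connected_idx(graph, max_size)
  lapply(idx_subs, function(s) graph$nodes[s])
}

# Index-space ESU enumeration; returns list of sorted integer vectors.
enum_connected_idx <- function(graph, max_size) {
  adj <- graph$adj
  n <- length(graph$nodes)
  acc <- new.env(parent = emptyenv())
  acc$k <- 0L
  acc$subs <- vector("list", 256L)
  emit <- function(sub) {
    k <- acc$k + 1L
    if (k > length(acc$subs)) acc$subs <- c(acc$subs, vector("list", length(acc$subs)))
    acc$subs[[k]] <- sort(sub)
    acc$k <- k
  }
  recurse <- function(sub, ext, v) {
    emit(sub)
    if (length(sub) >= max_size) return(invisible())
    while (length(ext)) {
      w <- ext[[1L]]
      ext <- ext[-1L]
      nb_sub <- unique(unlist(adj[sub], use.names = FALSE))
      nw <- adj[[w]]
      excl <- nw[nw > v & !(nw %in% sub) & !(nw %in% nb_sub)]
      recurse(c(sub, w), c(ext, setdiff(excl, ext)), v)
    }
    invisible()
  }
  for (v in seq_len(n)) {
    nv <- adj[[v]]
    recurse(v, nv[nv > v], v)
  }
  acc$subs[seq_len(acc$k)]
}

#' Exact maximum-score connected cluster (exhaustive)
#'
#' Scores every connected subset within the size bound and returns the
#' argmax, with deterministic tie-breaking toward the lexicographically
#' smallest sorted member list. Refuses graphs whose enumeration would
#' exceed the subset budget; use [search_best_cluster()] there.
#'
#' @param graph a [county_graph()].
#' @param table a [count_table()].
#' @param year analysis year.
#' @param config a [search_config()].
#' @param budget upper bound on `sum(choose(n, 1:max_size))` before the
#'   search refuses (default 5e5).
#' @return a `cluster`.
#' @export
exact_best_cluster <- function(graph, table, year, config, budget = 5e5) {
  n <- length(graph$nodes)
  est <- sum(choose(n, seq_len(min(config$max_size, n))))
  if (est > budget) {
    stopf(paste0("exhaustive search refused: up to %.3g subsets exceeds the ",
                 "budget of %.3g; use search_best_cluster()"), est, budget)
  }
  sig <- node_signal(graph, table, year, config)
  subs <- enum_connected_idx(graph, config$max_size)
  cs <- vapply(subs, function(s) sum(sig$ev[s]), numeric(1))
  bs <- vapply(subs, function(s) sum(sig$bl[s]), numeric(1))
  scores <- signal_score(sig, cs, bs)
  best <- max(scores)
  cand <- which(scores >= best - 1e-12)
  pick <- cand[1L]
  for (i in cand[-1L]) {
    if (lex_less_idx(subs[[i]], subs[[pick]])) pick <- i
  }
  new_cluster(graph$nodes[subs[[pick]]], scores[pick],
              config$statistic, config$count_kind, year)
}

# Masked heuristic search on precomputed signal; core shared by the
# public search and the Monte Carlo replicate loop.
search_masked <- function(graph, sig, config, active = NULL) {
  n <- length(graph$nodes)
  if (is.null(active)) active <- rep(TRUE, n)
  if (!any(active)) return(NULL)
  res <- greedy_search_cpp(graph$adj, as.numeric(sig$ev), as.numeric(sig$bl),
                           active, sig$stat_code, sig$Ctot, sig$Btot,
                           config$max_size)
  new_cluster(graph$nodes[res$members], res$score,
              config$statistic, config$count_kind, NA_integer_)
}

#' Heuristic maximum-score connected cluster
#'
#' Multi-seed greedy growth (every county as a seed; repeatedly add the
#' adjacent county that maximizes the statistic; keep the best prefix
#' within the size bound) followed by best-improvement 1-swap local search
#' (add/drop/swap while connectivity holds) on the strongest seed
#' candidates; the best result over all seeds is returned. On graphs small
#' enough for [exact_best_cluster()] the two agree empirically; the exact
#' search is the oracle that enforces this.
#'
#' @inheritParams exact_best_cluster
#' @return a `cluster`.
#' @export
search_best_cluster <- function(graph, table, year, config) {
  sig <- node_signal(graph, table, year, config)
  cl <- search_masked(graph, sig, config)
  cl$year <- as.integer(year)
  cl
}

#' Ranked disjoint clusters
#'
#' Finds the best cluster, removes its counties from the graph, and
#' repeats, up to `1 + n_secondary` clusters or until the best remaining
#' score is zero. Ranks are 1..k with nonincreasing scores and pairwise
#' disjoint member sets. Totals for the Kulldorff statistic stay fixed at
#' the whole-roster sums; removal only restricts the candidate space.
#'
#' @inheritParams exact_best_cluster
#' @return a list of `cluster` objects.
#' @export
top_k_clusters <- function(graph, table, year, config) {
  sig <- node_signal(graph, table, year, config)
  active <- rep(TRUE, length(graph$nodes))
  out <- list()
  for (r in seq_len(1L + config$n_secondary)) {
    cl <- search_masked(graph, sig, config, active)
    if (is.null(cl)) break
    if (cl$score <= 0 && length(out)) break
    cl$rank <- r
    cl$year <- as.integer(year)
    out[[r]] <- cl
    if (cl$score <= 0) break
    active[match(cl$members, graph$nodes)] <- FALSE
  }
  out
}

#' Circular-window scan baseline
#'
#' The classical scan over circular zones: for each county as a center,
#' candidate zones are that county plus its k nearest counties by
#' great-circle centroid distance, for growing k while the zone baseline
#' stays within `max_baseline_fraction` of the total baseline. Zones need
#' not be connected in the contiguity graph. Secondary zones are found by
#' the same disjoint-removal rule as [top_k_clusters()].
#'
#' @inheritParams exact_best_cluster
#' @param max_baseline_fraction largest fraction of the total baseline a
#'   zone may cover (default 0.5, the common circular-scan convention).
#' @return a list of `cluster` objects (statistic recorded with a
#'   `circular:` prefix in the `statistic` field).
#' @export
circular_scan <- function(graph, table, year, config,
                          max_baseline_fraction = 0.5) {
  if (is.null(graph$centroids)) stopf("circular_scan needs centroids")
  missing_c <- graph$nodes[!stats::complete.cases(graph$centroids)]
  if (length(missing_c)) {
    stopf("missing centroid for county: %s", paste(missing_c, collapse = ", "))
  }
  sig <- node_signal(graph, table, year, config)
  n <- length(graph$nodes)
  D <- geosphere::distm(graph$centroids, fun = geosphere::distHaversine)
  cap <- max_baseline_fraction * sig$Btot

  active <- rep(TRUE, n)
  out <- list()
  for (r in seq_len(1L + config$n_secondary)) {
    live <- which(active)
    if (!length(live)) break
    best_score <- -Inf
    best_mem <- NULL
    for (ci in live) {
      ord <- live[order(D[ci, live], live, method = "radix")]
      cb <- cumsum(sig$bl[ord])
      ce <- cumsum(sig$ev[ord])
      ok <- which(cb <= cap)
      if (!length(ok)) next
      sc <- signal_score(sig, ce[ok], cb[ok])
      j <- which.max(sc)
      mem <- sort(ord[seq_len(ok[j])])
      if (sc[j] > best_score + 1e-12 ||
          (abs(sc[j] - best_score) <= 1e-12 && !is.null(best_mem) &&
           lex_less_idx(mem, best_mem))) {
        best_score <- sc[j]
        best_mem <- mem
      }
    }
    if (is.null(best_mem)) break
    if (best_score <= 0 && length(out)) break
    cl <- new_cluster(graph$nodes[best_mem], best_score,
                      paste0("circular:", config$statistic),
                      config$count_kind, as.integer(year), rank = r)
    out[[r]] <- cl
    if (best_score <= 0) break
    active[best_mem] <- FALSE
  }
  out
}
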