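#' Pipeline run configuration
#'
#' Validated bundle of input paths and analysis settings for
#' [run_scan()] / [run_characterize()].
#'
#' @param counts path to the counts CSV.
#' @param adjacency path to the `county_a,county_b` edge-list CSV
#'   (exactly one of `adjacency` / `boundaries` is required).
#' @param boundaries path to a GeoJSON boundary file.
#' @param covariates optional path to the covariate CSV.
#' @param providers optional path to the provider CSV.
#' @param out_dir output directory (created if absent).
#' @param statistic,count_kind,year,history_years,max_size,n_secondary,replicates,alpha,seed
#'   analysis settings, see [search_config()].
#' @param contiguity rook/queen rule when boundaries are used.
#' @param allow_missing zero-fill counties present in the graph but absent
#'   from the count table for the analysis year (logged); by default such
#'   counties are an error. Mirrors public claims files that suppress
#'   small counts.
#' @return a `run_config` list.
#' @export
run_config <- function(counts, adjacency = NULL, boundaries = NULL,
                       covariates = NULL, providers = NULL,
                       out_dir = "netscan-run",
                       statistic = "kulldorff_poisson",
                       count_kind = "claims", year,
                       history_years = NULL, max_size = 30L,
                       n_secondary = 2L, replicates = 999L, alpha = 0.05,
                       seed = 1L, contiguity = "rook",
                       allow_missing = FALSE) {
  if (is.null(adjacency) == is.null(boundaries)) {
    stopf("supply exactly one of 'adjacency' or 'boundaries'")
  }
  if (!is.null(history_years) && year %in% history_years) {
    stopf("year must not be one of the history_years")
  }
  cfg <- search_config(statistic = statistic, count_kind = count_kind,
                       max_size = max_size, n_secondary = n_secondary,
                       replicates = replicates, alpha = alpha, seed = seed,
                       history_years = history_years)
  structure(c(list(counts = counts, adjacency = adjacency,
                   boundaries = boundaries, covariates = covariates,
                   providers = providers, out_dir = out_dir,
                   year = as.integer(year), contiguity = contiguity,
                   allow_missing = allow_missing),
              unclass(cfg)),
            class = "run_config")
}

load_run_inputs <- function(config) {
  table <- read_counts(config$counts)
  graph <- if (!is.null(config$adjacency)) {
    load_adjacency(config$adjacency)
  } else {
    graph_from_boundaries(config$boundaries, config$contiguity)
  }
  need_years <- c(config$year, config$history_years)
  for (yy in need_years) {
    present <- table$county[table$year == yy]
    missing <- setdiff(graph$nodes, present)
    if (length(missing)) {
      if (config$allow_missing) {
        warnf("zero-filling %d count row(s) for year %s: %s", length(missing),
              yy, paste(missing, collapse = ", "))
        fill <- data.frame(county = missing, year = yy, tot_b = 0,
                           opioid_b = 0, tot_p = 0, opioid_p = 0)
        table <- count_table(rbind(as.data.frame(table), fill))
      } else {
        stopf("counties missing from count table for year %s: %s",
              yy, paste(missing, collapse = ", "))
      }
    }
  }
  list(graph = graph, table = table)
}

#' Run the scan stage of the pipeline
#'
#' Loads and validates the inputs, finds the ranked clusters, simulates
#' the Monte Carlo null, attaches p-values, and writes `clusters.csv`,
#' `null_distribution.csv` and `run_metadata.json` into the output
#' directory. A pure function of (inputs, config): identical reruns give
#' byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `clusters`, `null`, `graph`, `table`.
#' @export
run_scan <- function(config) {
  inp <- load_run_inputs(config)
  clusters <- top_k_clusters(inp$graph, inp$table, config$year, config)
  null <- simulate_null_distribution(inp$graph, inp$table, config$year, config)
  clusters <- mark_significant(clusters, null, config$alpha)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cdf <- clusters_to_df(clusters)
  write.csv(cdf, file.path(config$out_dir, "clusters.csv"),
            row.names = FALSE, quote = FALSE)
  ndf <- data.frame(replicate = seq_along(null$replicate_max_scores),
                    score = null$replicate_max_scores)
  write.csv(ndf, file.path(config$out_dir, "null_distribution.csv"),
            row.names = FALSE, quote = FALSE)
  meta <- list(
    stage = "scan",
    statistic = config$statistic, count_kind = config$count_kind,
    year = config$year, history_years = config$history_years,
    baseline_convention = if (config$statistic == "expectation_poisson")
      "mean of supplied history years, floored at the continuity constant"
    else "same-year exposure totals over the full roster",
    continuity_constant = config$continuity,
    max_size = config$max_size, n_secondary = config$n_secondary,
    replicates = config$replicates, alpha = config$alpha, seed = config$seed,
    contiguity = if (is.null(config$boundaries)) NULL else config$contiguity,
    allow_missing = config$allow_missing,
    tie_break = "lexicographically smallest sorted member list",
    secondary_rule = "disjoint node removal; shared null of replicate maxima",
    package_version = as.character(utils::packageVersion("netscan"))
  )
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(list(clusters = clusters, null = null,
                 graph = inp$graph, table = inp$table))
}

#' Read a clusters CSV back into cluster objects
#'
#' @param path path to a `clusters.csv` written by [run_scan()].
#' @return a list of `cluster` objects.
#' @export
read_clusters <- function(path) {
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c(members = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    new_cluster(strsplit(df$members[i], ";", fixed = TRUE)[[1L]],
                df$score[i], df$statistic[i], df$count_kind[i],
                df$year[i], rank = df$rank[i], p_value = df$p_value[i],
                significant = df$p_value[i] <= attr(df, "alpha") %||% NA)
  })
}

#' Run the characterization stage
#'
#' Labels counties by membership in the significant clusters
#' (`p <= alpha`), prunes correlated covariates, runs the stepwise-AIC
#' logistic regression, and profiles the top-decile providers of the
#' rank-1 significant cluster. Writes `regression.csv`
#' (`year,count_kind,variable,odds_ratio,p_value,selected`) and, when
#' providers are supplied, `provider_profile.csv`.
#'
#' @param config a [run_config()] with a `covariates` path.
#' @param clusters list of `cluster` objects; defaults to reading
#'   `clusters.csv` from the output directory.
#' @return invisibly, a list with `regression` (or NULL), `profile`
#'   (or NULL), `labels`.
#' @export
run_characterize <- function(config, clusters = NULL) {
  if (is.null(config$covariates)) stopf("run_characterize needs a covariates path")
  if (is.null(clusters)) {
    clusters <- read_clusters(file.path(config$out_dir, "clusters.csv"))
  }
  covariates <- read_covariates(config$covariates)
  sig <- Filter(function(cl) !is.na(cl$p_value) && cl$p_value <= config$alpha,
                clusters)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  reg_path <- file.path(config$out_dir, "regression.csv")

  empty <- data.frame(year = integer(), count_kind = character(),
                      variable = character(), odds_ratio = numeric(),
                      p_value = numeric(), selected = logical())
  if (!length(sig)) {
    message("no significant clusters; regression skipped")
    write.csv(empty, reg_path, row.names = FALSE, quote = FALSE)
    return(invisible(list(regression = NULL, profile = NULL,
                          labels = setNames(integer(0), character(0)))))
  }

  labels <- label_counties(covariates$county, sig)
  pruned <- prune_correlated(covariates)
  reg <- stepwise_aic_logistic(labels, pruned)
  out <- cbind(year = config$year, count_kind = config$count_kind, reg$table)
  write.csv(out[c("year", "count_kind", "variable", "odds_ratio",
                  "p_value", "selected")],
            reg_path, row.names = FALSE, quote = FALSE)

  profile <- NULL
  if (!is.null(config$providers)) {
    providers <- read_providers(config$providers)
    top <- sig[[which.min(vapply(sig, `[[`, numeric(1), "rank"))]]
    sub <- top_decile_providers(providers, top)
    if (nrow(sub)) {
      profile <- provider_profile(sub)
      write.csv(profile, file.path(config$out_dir, "provider_profile.csv"),
                row.names = FALSE, quote = FALSE)
    } else {
      message("no providers in the top cluster; profile skipped")
    }
  }
  invisible(list(regression = reg, profile = profile, labels = labels))
}

#' Export clusters as GeoJSON
#'
#' Writes a FeatureCollection with one feature per clustered county,
#' carrying `rank`, `score` and `p_value` properties, using the geometries
#' of a supplied boundary file.
#'
#' @param clusters list of `cluster` objects.
#' @param boundaries path to the GeoJSON boundary file the scan used.
#' @param path output path.
#' @export
export_clusters_geojson <- function(clusters, boundaries, path) {
  gj <- jsonlite::fromJSON(boundaries, simplifyVector = FALSE)
  by_id <- setNames(gj$features,
                    vapply(gj$features, function(f) as.character(f$properties$county),
                           character(1)))
  feats <- list()
  for (cl in clusters) {
    for (m in cl$members) {
      f <- by_id[[m]]
      if (is.null(f)) stopf("no boundary feature for county '%s'", m)
      f$properties <- list(county = m, rank = cl$rank, score = cl$score,
                           p_value = cl$p_value)
      feats[[length(feats) + 1L]] <- f
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
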