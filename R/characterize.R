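# The eight candidate demographic covariates, in their declared order.
# The order matters: correlation pruning scans columns left to right.
COVARIATE_COLUMNS <- c("pct_african_american", "pct_american_indian",
                       "pct_male", "n_housing_units", "pct_medicaid",
                       "pct_medicare", "pct_direct_purchase",
                       "pct_income_poverty_lt_0_5")

#' Read a county covariate CSV
#'
#' Schema: `county` plus the eight candidate columns
#' (`pct_african_american, pct_american_indian, pct_male, n_housing_units,
#' pct_medicaid, pct_medicare, pct_direct_purchase,
#' pct_income_poverty_lt_0_5`). Percentages must lie in \[0, 100\] and
#' counts be nonnegative.
#'
#' @param path CSV path.
#' @return a validated data frame with one row per county.
#' @export
read_covariates <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  validate_covariates(df)
}

validate_covariates <- function(df) {
  df <- as.data.frame(df)
  miss <- setdiff(c("county", COVARIATE_COLUMNS), names(df))
  if (length(miss)) stopf("covariate table lacks column(s): %s", paste(miss, collapse = ", "))
  df$county <- as.character(df$county)
  if (anyDuplicated(df$county)) stopf("duplicate county in covariate table")
  pct <- setdiff(COVARIATE_COLUMNS, "n_housing_units")
  for (cn in pct) {
    v <- df[[cn]]
    if (anyNA(v) || any(v < 0 | v > 100)) stopf("column '%s' must lie in [0, 100]", cn)
  }
  if (anyNA(df$n_housing_units) || any(df$n_housing_units < 0)) {
    stopf("n_housing_units must be nonnegative")
  }
  df
}

#' Read a provider-level CSV
#'
#' Schema: `provider_id,county,specialty,total_beneficiaries,
#' opioid_beneficiaries,total_claims,opioid_claims`.
#'
#' @param path CSV path.
#' @return a validated data frame with internal count names
#'   (`tot_b, opioid_b, tot_p, opioid_p`).
#' @export
read_providers <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  validate_providers(df)
}

validate_providers <- function(df) {
  df <- as.data.frame(df)
  ext <- c(total_beneficiaries = "tot_b", opioid_beneficiaries = "opioid_b",
           total_claims = "tot_p", opioid_claims = "opioid_p")
  for (nm in names(ext)) {
    if (nm %in% names(df) && !(ext[[nm]] %in% names(df))) {
      names(df)[names(df) == nm] <- ext[[nm]]
    }
  }
  need <- c("provider_id", "county", "specialty", "tot_b", "opioid_b",
            "tot_p", "opioid_p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("provider table lacks column(s): %s", paste(miss, collapse = ", "))
  df <- df[need]
  df$provider_id <- as.character(df$provider_id)
  df$county <- as.character(df$county)
  df$specialty <- as.character(df$specialty)
  if (anyDuplicated(df$provider_id)) stopf("duplicate provider_id")
  for (cn in c("tot_b", "opioid_b", "tot_p", "opioid_p")) {
    if (anyNA(df[[cn]]) || any(df[[cn]] < 0)) stopf("provider counts must be nonnegative")
  }
  if (any(df$opioid_b > df$tot_b) || any(df$opioid_p > df$tot_p)) {
    stopf("provider opioid counts exceed totals")
  }
  df
}

#' Label counties by membership in significant clusters
#'
#' @param all_counties character vector: the full county roster.
#' @param significant_clusters list of `cluster` objects already filtered
#'   to the significant ones (same statistic/count kind/year).
#' @return named integer vector: 1 if the county belongs to any
#'   significant cluster, else 0.
#' @export
label_counties <- function(all_counties, significant_clusters) {
  all_counties <- as.character(all_counties)
  members <- unique(unlist(lapply(significant_clusters, `[[`, "members")))
  unknown <- setdiff(members, all_counties)
  if (length(unknown)) {
    stopf("cluster member(s) not in county roster: %s",
          paste(csort(unknown), collapse = ", "))
  }
  setNames(as.integer(all_counties %in% members), all_counties)
}

#' Drop highly correlated covariate columns
#'
#' Greedy scan in the declared column order: a column is dropped when its
#' absolute Pearson correlation with an already-kept column reaches the
#' threshold, so every surviving pair satisfies `|r| < threshold`.
#' Zero-variance columns are dropped with a warning (their correlation is
#' undefined).
#'
#' @param covariates covariate data frame (see [read_covariates()]); the
#'   `county` column is carried through untouched.
#' @param threshold correlation threshold in (0, 1\]; default 0.6.
#' @return the reduced covariate data frame.
#' @export
prune_correlated <- function(covariates, threshold = 0.6) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  cols <- intersect(COVARIATE_COLUMNS, names(covariates))
  if (!length(cols)) cols <- setdiff(names(covariates), "county")
  if (nrow(covariates) < 2L) stopf("need at least 2 counties to estimate correlations")
  kept <- character(0)
  for (cn in cols) {
    v <- covariates[[cn]]
    if (stats::sd(v) == 0) {
      warnf("covariate '%s' has zero variance; dropped", cn)
      next
    }
    ok <- TRUE
    for (kc in kept) {
      if (abs(cor(v, covariates[[kc]])) >= threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, cn)
  }
  covariates[c(intersect("county", names(covariates)), kept)]
}

#' Stepwise-AIC logistic regression of cluster membership
#'
#' Fits a binomial (logit link) GLM of the binary anomalous-cluster label
#' on the pruned covariates, then runs stepwise selection in both
#' directions from the full model with `MASS::stepAIC`, moving while the
#' AIC strictly decreases. Coefficients are reported as odds ratios
#' `exp(beta)` with Wald p-values; variables with `p < 0.1` are flagged
#' significant.
#'
#' @param labels named 0/1 integer vector (county -> label), as from
#'   [label_counties()].
#' @param covariates pruned covariate data frame with a `county` column.
#' @return a `scan_regression` list: `table` (variable, odds_ratio,
#'   p_value, selected, significant; includes the intercept),
#'   `selected_variables`, `aic`.
#' @export
stepwise_aic_logistic <- function(labels, covariates) {
  if (length(unique(labels)) < 2L) {
    stopf("labels contain a single class; regression is degenerate")
  }
  cand <- setdiff(names(covariates), "county")
  if (!length(cand)) stopf("no candidate covariates")
  m <- match(names(labels), covariates$county)
  if (anyNA(m)) stopf("covariates missing for county: %s",
                      paste(names(labels)[is.na(m)], collapse = ", "))
  dat <- covariates[m, cand, drop = FALSE]
  dat$.y <- as.integer(labels)

  # complete separation makes the MLE diverge; detect it per variable
  for (cn in cand) {
    x1 <- dat[[cn]][dat$.y == 1]
    x0 <- dat[[cn]][dat$.y == 0]
    if (min(x1) > max(x0) || max(x1) < min(x0)) {
      stopf("complete separation on variable '%s'", cn)
    }
  }

  full <- glm(as.formula(paste(".y ~", paste(cand, collapse = " + "))),
              family = binomial(), data = dat)
  sel <- MASS::stepAIC(full, direction = "both", trace = 0)
  sm <- summary(sel)$coefficients
  selected <- setdiff(rownames(sm), "(Intercept)")

  vars <- c("(Intercept)", cand)
  or <- p <- rep(NA_real_, length(vars))
  in_model <- vars %in% rownames(sm)
  or[in_model] <- exp(sm[vars[in_model], "Estimate"])
  p[in_model] <- sm[vars[in_model], "Pr(>|z|)"]
  tab <- data.frame(variable = vars, odds_ratio = or, p_value = p,
                    selected = in_model, stringsAsFactors = FALSE)
  tab$significant <- tab$selected & !is.na(tab$p_value) & tab$p_value < 0.1

  structure(list(table = tab, selected_variables = selected,
                 aic = AIC(sel), model = sel),
            class = "scan_regression")
}

#' @export
print.scan_regression <- function(x, ...) {
  cat(sprintf("<scan_regression> AIC %.2f, selected: %s\n", x$aic,
              if (length(x$selected_variables))
                paste(x$selected_variables, collapse = ", ")
              else "(intercept only)"))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Providers in the top decile of a cluster
#'
#' Restricts the provider table to the cluster's counties and keeps
#' providers at or above the empirical 90th-percentile cutoff (nearest
#' rank, ties inclusive) of *both* opioid beneficiary and opioid claim
#' counts within that restriction.
#'
#' @param providers provider data frame (see [read_providers()]).
#' @param cluster a `cluster` object or character vector of county ids.
#' @return the provider subset (possibly empty, with a warning).
#' @export
top_decile_providers <- function(providers, cluster) {
  members <- if (inherits(cluster, "cluster")) cluster$members else as.character(cluster)
  sub <- providers[providers$county %in% members, , drop = FALSE]
  if (!nrow(sub)) {
    warnf("no providers located in the cluster's counties")
    return(sub)
  }
  # nearest-rank, right-continuous: the cutoff is the smallest value whose
  # rank exceeds 0.9 n, so exactly the top 10% qualify, ties inclusive
  cutoff <- function(x) sort(x)[min(length(x), floor(0.9 * length(x)) + 1L)]
  qb <- cutoff(sub$opioid_b)
  qp <- cutoff(sub$opioid_p)
  out <- sub[sub$opioid_b >= qb & sub$opioid_p >= qp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-specialty profile of a provider subset
#'
#' Summarizes a provider subset (typically from [top_decile_providers()])
#' by medical specialty: number of providers, mean percentage of opioid
#' beneficiaries (`100 * opioid_b / tot_b`), mean percentage of opioid
#' claims, and mean total beneficiaries; sorted by provider count
#' descending. Providers with a zero total are excluded from the means
#' with a warning.
#'
#' @param subset nonempty provider data frame.
#' @return a data frame with columns `specialty, n_providers,
#'   mean_pct_opioid_beneficiaries, mean_pct_opioid_claims,
#'   mean_total_beneficiaries`.
#' @export
provider_profile <- function(subset) {
  if (!nrow(subset)) stopf("provider subset is empty")
  drop <- subset$tot_b == 0 | subset$tot_p == 0
  if (any(drop)) {
    warnf("%d provider(s) with zero totals excluded from the profile", sum(drop))
    subset <- subset[!drop, , drop = FALSE]
    if (!nrow(subset)) stopf("no providers with positive totals remain")
  }
  sp <- split(subset, subset$specialty)
  rows <- lapply(sp, function(d) {
    data.frame(specialty = d$specialty[1L],
               n_providers = nrow(d),
               mean_pct_opioid_beneficiaries = mean(100 * d$opioid_b / d$tot_b),
               mean_pct_opioid_claims = mean(100 * d$opioid_p / d$tot_p),
               mean_total_beneficiaries = mean(d$tot_b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n_providers, out$specialty, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
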