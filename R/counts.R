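#' County count table
#'
#' Per-county, per-year baseline and event counts for the two count kinds:
#' beneficiaries (`tot_b` total, `opioid_b` opioid) and prescription claims
#' (`tot_p` total, `opioid_p` opioid). Baselines are the denominators of
#' the scan rates; opioid counts are the events.
#'
#' @param df data frame with columns `county`, `year`, `tot_b`, `opioid_b`,
#'   `tot_p`, `opioid_p` (or the external CSV names, see [read_counts()]).
#' @param validate run the invariant checks (nonnegative integers,
#'   opioid <= total, unique `(county, year)` keys). Internal callers that
#'   construct null replicates skip this.
#' @return a data frame of class `count_table`.
#' @export
count_table <- function(df, validate = TRUE) {
  df <- as.data.frame(df)
  ext <- c(total_beneficiaries = "tot_b", opioid_beneficiaries = "opioid_b",
           total_claims = "tot_p", opioid_claims = "opioid_p")
  for (nm in names(ext)) {
    if (nm %in% names(df) && !(ext[[nm]] %in% names(df))) {
      names(df)[names(df) == nm] <- ext[[nm]]
    }
  }
  need <- c("county", "year", "tot_b", "opioid_b", "tot_p", "opioid_p")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("count table lacks column(s): %s", paste(miss, collapse = ", "))
  df <- df[need]
  df$county <- as.character(df$county)
  df$year <- as.integer(df$year)
  for (cn in need[-(1:2)]) df[[cn]] <- as.numeric(df[[cn]])
  if (validate) validate_count_table(df)
  o <- order(df$county, df$year, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("count_table", "data.frame")
  df
}

validate_count_table <- function(df) {
  cnt <- c("tot_b", "opioid_b", "tot_p", "opioid_p")
  for (cn in cnt) {
    v <- df[[cn]]
    if (anyNA(v)) stopf("count column '%s' has missing values", cn)
    if (any(v < 0)) stopf("count column '%s' has negative values", cn)
    if (any(v != round(v))) stopf("count column '%s' has non-integer values", cn)
  }
  if (any(df$opioid_b > df$tot_b)) {
    bad <- df[df$opioid_b > df$tot_b, ]
    stopf("opioid beneficiaries exceed total beneficiaries for %s (%d)",
          bad$county[1L], bad$year[1L])
  }
  if (any(df$opioid_p > df$tot_p)) {
    bad <- df[df$opioid_p > df$tot_p, ]
    stopf("opioid claims exceed total claims for %s (%d)",
          bad$county[1L], bad$year[1L])
  }
  key <- paste(df$county, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ]
    stopf("duplicate (county, year) key: %s (%d)", d$county[1L], d$year[1L])
  }
  invisible(df)
}

#' Read / write county count CSV files
#'
#' The external schema is
#' `county,year,total_beneficiaries,opioid_beneficiaries,total_claims,opioid_claims`.
#'
#' @param path CSV file path.
#' @return [read_counts()] returns a `count_table`; [write_counts()] is
#'   called for its side effect.
#' @export
read_counts <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  count_table(df)
}

#' @rdname read_counts
#' @param table a `count_table`.
#' @export
write_counts <- function(table, path) {
  out <- data.frame(county = table$county, year = table$year,
                    total_beneficiaries = table$tot_b,
                    opioid_beneficiaries = table$opioid_b,
                    total_claims = table$tot_p,
                    opioid_claims = table$opioid_p)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Map a count kind to its event/baseline columns.
kind_cols <- function(count_kind = c("beneficiary", "claims")) {
  count_kind <- match.arg(count_kind)
  if (count_kind == "beneficiary") {
    list(event = "opioid_b", baseline = "tot_b")
  } else {
    list(event = "opioid_p", baseline = "tot_p")
  }
}

#' Aggregate counts over a cluster of counties
#'
#' Sums event and baseline counts over a county set for one year, together
#' with the totals over every county in the table for that year. For the
#' claims kind the event is opioid claims and the baseline total claims;
#' for the beneficiary kind, opioid/total beneficiaries.
#'
#' @param table a [count_table()].
#' @param cluster character vector of county ids (may be empty).
#' @param year analysis year.
#' @param count_kind `"beneficiary"` or `"claims"`.
#' @return a `cluster_counts` list with `event`, `baseline`, `total_event`,
#'   `total_baseline`.
#' @export
aggregate_counts <- function(table, cluster, year,
                             count_kind = c("beneficiary", "claims")) {
  cols <- kind_cols(count_kind)
  yr <- table[table$year == year, , drop = FALSE]
  if (!nrow(yr)) stopf("no rows for year %s in count table", year)
  cluster <- unique(as.character(cluster))
  idx <- match(cluster, yr$county)
  if (anyNA(idx)) {
    miss <- cluster[is.na(idx)]
    stopf("missing (county, year) row(s): %s",
          paste(sprintf("%s (%s)", csort(miss), year), collapse = ", "))
  }
  cc <- list(
    event = sum(yr[[cols$event]][idx]),
    baseline = sum(yr[[cols$baseline]][idx]),
    total_event = sum(yr[[cols$event]]),
    total_baseline = sum(yr[[cols$baseline]])
  )
  class(cc) <- "cluster_counts"
  cc
}

#' @export
print.cluster_counts <- function(x, ...) {
  cat(sprintf("<cluster_counts> event %g / baseline %g (totals %g / %g)\n",
              x$event, x$baseline, x$total_event, x$total_baseline))
  invisible(x)
}
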