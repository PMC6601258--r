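#' Statewide (global) event rate
#'
#' The rate under the null hypothesis that every county's events are
#' Poisson with mean proportional to its baseline: total events divided by
#' total baseline over the whole study area.
#'
#' @param cc a `cluster_counts` object (see [aggregate_counts()]).
#' @return the global rate, events per unit baseline.
#' @export
global_rate <- function(cc) {
  if (cc$total_baseline <= 0) stopf("global rate undefined: total baseline is zero")
  cc$total_event / cc$total_baseline
}

score_value <- function(llr, high_rate) {
  structure(list(log_likelihood_ratio = llr, high_rate = high_rate),
            class = "score_value")
}

#' @export
print.score_value <- function(x, ...) {
  cat(sprintf("<score_value> log LR = %.6g (%s)\n", x$log_likelihood_ratio,
              if (x$high_rate) "elevated rate" else "not elevated"))
  invisible(x)
}

# Vectorized Kulldorff Poisson log likelihood ratio. c/b are cluster event
# and baseline sums; Ctot/Btot the study-area totals. One-sided: 0 unless
# the cluster rate exceeds its null expectation E = Ctot * b / Btot.
kulldorff_llr <- function(c, b, Ctot, Btot) {
  if (Btot <= 0) stopf("total baseline must be positive")
  E <- Ctot * b / Btot
  if (any(c > 0 & E == 0)) {
    stopf("invalid input: positive events with zero expected count")
  }
  out <- numeric(length(c))
  hi <- c > E & E > 0
  if (any(hi)) {
    ch <- c[hi]; Eh <- E[hi]
    t2 <- ifelse(Ctot - ch > 0, (Ctot - ch) * log((Ctot - ch) / (Ctot - Eh)), 0)
    out[hi] <- ch * log(ch / Eh) + t2
  }
  out
}

# Vectorized expectation-based Poisson log likelihood ratio (profile over
# the fold-change mu >= 1): c log(c/b) + b - c when c > b, else 0.
expectation_llr <- function(c, b) {
  out <- numeric(length(c))
  hi <- c > b & b > 0
  out[hi] <- c[hi] * log(c[hi] / b[hi]) + b[hi] - c[hi]
  out
}

#' Kulldorff Poisson scan score of a cluster
#'
#' The generalized log likelihood ratio comparing the hypothesis of an
#' elevated Poisson rate inside the cluster (rate eta inside, mu outside,
#' eta > mu) against the uniform-rate null. With cluster events `c`,
#' cluster baseline `b`, totals `C` and `B` and null expectation
#' `E = C b / B`, the log score is `c log(c/E) + (C - c) log((C - c)/(C - E))`
#' when `c > E` and 0 otherwise (one-sided, high-rate scan). This is the
#' profile log likelihood ratio with rate estimates `c/b` inside and
#' `(C - c)/(B - b)` outside; it is reported in nats.
#'
#' @param cc a `cluster_counts` object.
#' @return a `score_value` with the log likelihood ratio and a `high_rate`
#'   flag (TRUE iff the cluster rate exceeds its null expectation).
#' @export
kulldorff_poisson_score <- function(cc) {
  if (cc$baseline <= 0 && cc$event > 0) {
    stopf("invalid input: positive events with zero cluster baseline")
  }
  llr <- kulldorff_llr(cc$event, cc$baseline, cc$total_event, cc$total_baseline)
  E <- cc$total_event * cc$baseline / cc$total_baseline
  score_value(llr, cc$event > E)
}

#' Expectation-based Poisson scan score
#'
#' Scores a current count against a county- (or cluster-) specific
#' expectation built from past counts. Under the null the current count is
#' Poisson with mean equal to the expectation; under the alternative the
#' mean is inflated by a fold-change mu > 1. Profiling over mu gives the
#' log score `c log(c/b) + b - c` when `c > b`, else 0.
#'
#' @param current observed event count `c`.
#' @param expected positive expected count `b` (e.g. the mean of past
#'   years' counts, see [expected_from_history()]).
#' @param continuity floor applied to a nonpositive expectation so the
#'   score stays finite; a warning is logged when it engages.
#' @return a `score_value`.
#' @export
expectation_poisson_score <- function(current, expected, continuity = 0.5) {
  if (expected <= 0) {
    warnf("nonpositive expected count floored at continuity constant %g", continuity)
    expected <- continuity
  }
  llr <- expectation_llr(current, expected)
  score_value(llr, current > expected)
}

#' Expected count from a county's history
#'
#' The arithmetic mean of a county's event counts over the supplied
#' history years, floored by the continuity constant so that counties with
#' an all-zero history cannot produce unbounded scores.
#'
#' @param table a [count_table()].
#' @param county county id.
#' @param target_year the year being scanned (must not be in
#'   `history_years`).
#' @param history_years years whose counts are averaged.
#' @param count_kind `"beneficiary"` or `"claims"`.
#' @param continuity floor for a zero mean (default 0.5).
#' @return a positive expected count.
#' @export
expected_from_history <- function(table, county, target_year, history_years,
                                  count_kind = c("beneficiary", "claims"),
                                  continuity = 0.5) {
  if (!length(history_years)) stopf("history_years must be nonempty")
  if (target_year %in% history_years) {
    stopf("target year %s cannot be one of its own history years", target_year)
  }
  cols <- kind_cols(count_kind)
  vals <- vapply(history_years, function(y) {
    row <- table[table$county == county & table$year == y, , drop = FALSE]
    if (!nrow(row)) stopf("missing history row: %s (%s)", county, y)
    row[[cols$event]][1L]
  }, numeric(1L))
  m <- mean(vals)
  if (m < continuity) {
    warnf("county %s: zero/near-zero history floored at %g", county, continuity)
    m <- continuity
  }
  m
}
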