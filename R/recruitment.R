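#' Expected cumulative enrollment by a given day
#'
#' Requests are re-sent daily to non-consenters, so participant `i` first
#' consents on day `d` with probability `(1 - q_i)^(d-1) * q_i` — a
#' geometric law. Summing the series, the chance that `i` has consented by
#' day `j` is `1 - (1 - q_i)^j`, and the expected cumulative enrollment is
#' `sum_i [1 - (1 - q_i)^j]`.
#'
#' @param q numeric vector of per-participant daily consent probabilities.
#' @param j day, integer `>= 1` (vectorized).
#' @return Expected number of enrollees by day `j`, in `[0, length(q)]`.
#' @examples
#' expected_enrollment(c(0.5), 2)  # 0.75
#' @export
expected_enrollment <- function(q, j) {
  if (any(j < 1)) {
    stop(errorCondition("day index j must be >= 1",
                        class = c("domain_error", "error")))
  }
  stopifnot(all(q >= 0), all(q <= 1))
  vapply(j, function(jj) sum(1 - (1 - q)^jj), numeric(1))
}

#' Expected enrollment curve over a horizon
#'
#' @param q consent probabilities.
#' @param max_days horizon in days.
#' @param target target enrollment, carried as an attribute.
#' @return Numeric vector `expected_by_day` (days `1..max_days`), class
#'   `"recruitment_curve"`, nondecreasing and bounded by `length(q)`.
#' @export
recruitment_curve <- function(q, max_days, target = NA_integer_) {
  structure(expected_enrollment(q, seq_len(max_days)),
            target = target, class = "recruitment_curve")
}

#' Minimal expected recruitment time
#'
#' The smallest day `j` on which the expected cumulative enrollment
#' reaches the target (`>=` convention: with all-certain consent the
#' campaign completes on day 1). If even the horizon cannot reach the
#' target, an `unreachable_target` error is signalled carrying the
#' asymptotic ceiling `sum(q > 0)`.
#'
#' @param q consent probabilities.
#' @param target required number of enrollees, `>= 1`.
#' @param max_days search horizon, `>= 1`.
#' @return Integer day.
#' @examples
#' expected_recruitment_time(rep(0.5, 2), target = 1)  # 1
#' @export
expected_recruitment_time <- function(q, target, max_days = 365L) {
  stopifnot(target >= 1, max_days >= 1)
  if (expected_enrollment(q, max_days) < target) {
    stop(errorCondition(
      sprintf(
        "target %d unreachable within %d days (asymptotic ceiling: %d participants with q > 0)",
        as.integer(target), as.integer(max_days), sum(q > 0)
      ),
      class = c("unreachable_target", "error"),
      asymptote = sum(q > 0)
    ))
  }
  # binary search for the first day reaching the target
  lo <- 1L
  hi <- as.integer(max_days)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (expected_enrollment(q, mid) >= target) hi <- mid else lo <- mid + 1L
  }
  lo
}

#' Simulate one recruitment campaign
#'
#' Day-by-day Bernoulli process: every not-yet-consented participant
#' consents that day with their own probability; consent is permanent.
#' Returns the first day on which the cumulative count reaches the target.
#' Uses the true individual probabilities regardless of the recruiter's
#' planning view. Consumes the ambient RNG stream.
#'
#' @param q_true individual-mode consent probabilities.
#' @param target required enrollees.
#' @param max_days horizon; exceeding it signals a `horizon_exceeded`
#'   error carrying the count achieved.
#' @return Integer completion day.
#' @export
simulate_recruitment_once <- function(q_true, target, max_days = 365L) {
  stopifnot(target >= 1, max_days >= 1)
  pending <- seq_along(q_true)
  enrolled <- 0L
  for (day in seq_len(max_days)) {
    hits <- stats::runif(length(pending)) < q_true[pending]
    enrolled <- enrolled + sum(hits)
    if (enrolled >= target) return(day)
    pending <- pending[!hits]
  }
  stop(errorCondition(
    sprintf("target %d not reached by day %d (achieved %d)",
            as.integer(target), as.integer(max_days), enrolled),
    class = c("horizon_exceeded", "error"),
    achieved = enrolled
  ))
}

#' Simulate many recruitment campaigns
#'
#' Independent replicates of [simulate_recruitment_once()]. Replicates
#' that fail to reach the target by the horizon are kept as censored rows
#' (`day = max_days`, `censored = TRUE`), never dropped.
#'
#' @inheritParams simulate_recruitment_once
#' @param runs number of replicates, `>= 1`.
#' @param seed optional integer seed; when given, results are reproducible
#'   and the global RNG state is left untouched.
#' @return A `data.frame` (`run`, `day`, `censored`) of class
#'   `"recruitment_runs"`.
#' @export
simulate_recruitment_many <- function(q_true, target, runs, max_days = 365L,
                                      seed = NULL) {
  if (runs < 1) {
    stop(errorCondition("runs must be >= 1",
                        class = c("domain_error", "error")))
  }
  one <- function(i) {
    tryCatch(
      c(simulate_recruitment_once(q_true, target, max_days), 0L),
      horizon_exceeded = function(e) c(as.integer(max_days), 1L)
    )
  }
  res <- if (is.null(seed)) {
    vapply(seq_len(runs), one, integer(2))
  } else {
    withr::with_seed(seed, vapply(seq_len(runs), one, integer(2)))
  }
  structure(
    data.frame(run = seq_len(runs), day = res[1, ],
               censored = as.logical(res[2, ])),
    class = c("recruitment_runs", "data.frame")
  )
}
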