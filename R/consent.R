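#' Participant welfare in the life-log program
#'
#' Welfare of joining the program at a given token reward:
#' `W = sqrt(reward / sp) - annoyance * T^2`. The square root makes the
#' monetary part concave, so a token is worth less, at the margin, to a
#' participant of higher socioeconomic status; the quadratic term is the
#' fatigue of uploading logs for `T` days, weighted by the participant's
#' annoyance. A participant considers joining only when welfare is
#' positive.
#'
#' @param p participant(s): a `data.frame` with columns `sp` and
#'   `annoyance` (vectorized over rows).
#' @param reward token reward, `>= 0`.
#' @param T_days program duration in days, `>= 0`.
#' @return Numeric vector of welfare values.
#' @examples
#' welfare_basic(data.frame(sp = 9, annoyance = 0.1), reward = 36, T_days = 5)
#' @export
welfare_basic <- function(p, reward, T_days) {
  if (any(reward < 0)) {
    stop(errorCondition("reward must be nonnegative",
                        class = c("domain_error", "error")))
  }
  stopifnot(all(p$sp > 0), T_days >= 0)
  sqrt(reward / p$sp) - p$annoyance * T_days^2
}

#' Daily consent probability, basic scenario
#'
#' Zero when the participant's welfare is nonpositive (they would not
#' consider the program at all); otherwise proportional to the reward and
#' the perceived company reliability and inversely proportional to
#' socioeconomic status, scaled by the normalizer and clamped to `[0, 1]`:
#' `q = clamp(reward * R / (sp * normalizer), 0, 1)`.
#'
#' @param p participant(s): `data.frame` with `sp`, `annoyance`,
#'   `reliability`.
#' @param reward token reward, `>= 0`.
#' @param T_days program duration in days.
#' @param normalizer positive scale constant (default 200).
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @examples
#' consent_prob_basic(
#'   data.frame(sp = 5, annoyance = 0.05, reliability = 0.5),
#'   reward = 200, T_days = 5, normalizer = 200
#' )
#' @export
consent_prob_basic <- function(p, reward, T_days, normalizer = 200) {
  stopifnot(normalizer > 0)
  w <- welfare_basic(p, reward, T_days)
  q <- pmin(pmax(reward * p$reliability / (p$sp * normalizer), 0), 1)
  ifelse(w > 0, q, 0)
}

#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`: strictly increasing, maps the real line to (0, 1).
#'
#' @param x numeric vector.
#' @return Numeric vector in (0, 1).
#' @export
sigmoid <- function(x) {
  1 / (1 + exp(-x))
}

#' Daily consent probability, clinical-trial scenario
#'
#' Patients follow their oncologist's advice: the fewer treatment
#' protocols `k` remain available, the stronger the advice to enroll, and
#' larger rewards help. The probability is a sigmoid in the reward per
#' remaining option, shifted right by `middle` so that small rewards give
#' near-zero consent: `q = sigmoid(steepness * (reward / k - middle))`.
#' Equals 0.5 exactly at `reward = middle * k`.
#'
#' @param p participant(s): `data.frame` with integer column `k >= 1`.
#' @param reward token reward, `>= 0`.
#' @param middle sigmoid shift in tokens per option (default 150).
#' @param steepness sigmoid slope per token (default 0.05).
#' @return Numeric vector of probabilities in (0, 1).
#' @examples
#' consent_prob_validation(data.frame(k = 1), reward = 150)  # 0.5
#' @export
consent_prob_validation <- function(p, reward, middle = 150,
                                    steepness = 0.05) {
  if (any(p$k < 1)) {
    stop(errorCondition("k must be >= 1",
                        class = c("domain_error", "error")))
  }
  if (any(reward < 0)) {
    stop(errorCondition("reward must be nonnegative",
                        class = c("domain_error", "error")))
  }
  stopifnot(steepness > 0)
  sigmoid(steepness * (reward / p$k - middle))
}

#' Per-participant daily consent probabilities at a reward
#'
#' Dispatches on the scenario and on the planning view. In
#' `"expectation"` mode the recruiter cannot see individual attributes and
#' computes one probability from the [expected_participant()], replicated
#' across the pool; in `"individual"` mode each participant's true
#' attributes are used.
#'
#' @param pop population `data.frame` from [generate_population()].
#' @param reward token reward.
#' @param config a [scenario_config()].
#' @param mode planning view; defaults to `config$company_view`.
#' @return A numeric vector of probabilities (one per pool member) of class
#'   `"probability_vector"`, with attributes `reward` and `mode`.
#' @export
consent_probabilities <- function(pop, reward, config,
                                  mode = config$company_view) {
  stopifnot(inherits(config, "scenario_config"), nrow(pop) > 0)
  mode <- match.arg(mode, c("expectation", "individual"))
  src <- if (mode == "expectation") expected_participant(config) else pop
  q <- if (config$scenario == "basic") {
    consent_prob_basic(src, reward, config$duration, config$normalizer)
  } else {
    consent_prob_validation(src, reward, config$middle, config$steepness)
  }
  if (mode == "expectation") q <- rep(q, nrow(pop))
  structure(q, reward = reward, mode = mode,
            class = "probability_vector")
}
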