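#' Scenario configuration
#'
#' Bundle every knob of one recruitment experiment. Defaults reproduce the
#' two study scenarios: the `basic` life-log program (attribute ranges
#' SP 5-10, annoyance 0.05-0.1, reliability 0.5-0.7, normalizer 200, time
#' weight 1500, expectation-mode planning) and the `validation`
#' clinical-trial recruitment (SP 0-3, k 1-5, data provider index 1-2,
#' sigmoid midpoint 150, time weight 100, individual-mode planning).
#'
#' @param scenario `"basic"` or `"validation"`.
#' @param pool_size number of candidates receiving consent requests (M).
#' @param target number of enrollees the recruiter needs (N), `<= pool_size`.
#' @param duration program length in days (T); enters the basic-scenario
#'   welfare through the quadratic fatigue term.
#' @param alpha time weight: cost per day of recruitment duration. Default
#'   1500 (basic) or 100 (validation).
#' @param normalizer positive scale constant in the basic consent
#'   probability (default 200).
#' @param middle sigmoid shift in the validation consent probability
#'   (default 150 tokens per treatment option).
#' @param steepness sigmoid slope per token (validation; default 0.05).
#' @param reward_grid strictly increasing candidate rewards, in tokens.
#' @param max_days search/simulation horizon in days.
#' @param seed integer RNG seed governing population generation and
#'   simulation.
#' @param company_view `"expectation"` (plan with distribution midpoints;
#'   basic default) or `"individual"` (plan with each participant's true
#'   attributes; validation default).
#' @param sp_range,annoyance_range,reliability_range closed uniform ranges
#'   for the private attributes (annoyance and reliability are used by the
#'   basic scenario only).
#' @param k_range integer range for the number of available treatment
#'   protocols (validation only).
#' @param dp_values admissible data-provider indices for tested
#'   participants (validation only).
#' @param n_genotypes number of genotype labels for tested participants.
#' @param provider_fee optional per-consent token fee paid to data
#'   providers, added to the recruiter's cost (default 0).
#'
#' @return A list of class `"scenario_config"`.
#' @examples
#' cfg <- scenario_config("basic", pool_size = 200, target = 20)
#' cfg$alpha
#' @export
scenario_config <- function(scenario = c("basic", "validation"),
                            pool_size = 1000L,
                            target = 100L,
                            duration = 5,
                            alpha = NULL,
                            normalizer = 200,
                            middle = 150,
                            steepness = 0.05,
                            reward_grid = 1:500,
                            max_days = 365L,
                            seed = 1L,
                            company_view = NULL,
                            sp_range = NULL,
                            annoyance_range = c(0.05, 0.1),
                            reliability_range = c(0.5, 0.7),
                            k_range = c(1L, 5L),
                            dp_values = c(1L, 2L),
                            n_genotypes = 3L,
                            provider_fee = 0) {
  scenario <- match.arg(scenario)
  if (is.null(alpha)) alpha <- if (scenario == "basic") 1500 else 100
  if (is.null(company_view)) {
    company_view <- if (scenario == "basic") "expectation" else "individual"
  }
  company_view <- match.arg(company_view, c("expectation", "individual"))
  if (is.null(sp_range)) {
    sp_range <- if (scenario == "basic") c(5, 10) else c(0, 3)
  }

  cfg <- structure(
    list(
      scenario = scenario,
      pool_size = as.integer(pool_size),
      target = as.integer(target),
      duration = duration,
      alpha = alpha,
      normalizer = normalizer,
      middle = middle,
      steepness = steepness,
      reward_grid = reward_grid,
      max_days = as.integer(max_days),
      seed = as.integer(seed),
      company_view = company_view,
      sp_range = sp_range,
      annoyance_range = annoyance_range,
      reliability_range = reliability_range,
      k_range = as.integer(k_range),
      dp_values = as.integer(dp_values),
      n_genotypes = as.integer(n_genotypes),
      provider_fee = provider_fee
    ),
    class = "scenario_config"
  )
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  stop_cfg <- function(msg) {
    stop(errorCondition(msg, class = c("config_error", "error")))
  }
  if (cfg$pool_size < 1L) stop_cfg("pool_size must be a positive integer")
  if (cfg$target < 1L) stop_cfg("target must be a positive integer")
  if (cfg$target > cfg$pool_size) {
    stop_cfg("target exceeds pool_size: cannot enroll more than the pool")
  }
  if (cfg$max_days < 1L) stop_cfg("max_days must be >= 1")
  if (length(cfg$reward_grid) == 0L || any(diff(cfg$reward_grid) <= 0)) {
    stop_cfg("reward_grid must be nonempty and strictly increasing")
  }
  if (any(cfg$reward_grid < 0)) stop_cfg("reward_grid entries must be >= 0")
  if (cfg$normalizer <= 0) stop_cfg("normalizer must be positive")
  if (cfg$middle <= 0) stop_cfg("middle must be positive")
  if (cfg$steepness <= 0) stop_cfg("steepness must be positive")
  if (cfg$alpha < 0) stop_cfg("alpha (time weight) must be nonnegative")
  if (cfg$duration < 0) stop_cfg("duration must be nonnegative")
  if (cfg$provider_fee < 0) stop_cfg("provider_fee must be nonnegative")
  for (nm in c("sp_range", "annoyance_range", "reliability_range", "k_range")) {
    rg <- cfg[[nm]]
    if (length(rg) != 2L || rg[1] > rg[2]) {
      stop_cfg(sprintf("%s must be a valid (min <= max) range", nm))
    }
  }
  if (cfg$k_range[1] < 1L) stop_cfg("k_range minimum must be >= 1")
  if (any(cfg$dp_values < 1L)) stop_cfg("dp_values must be >= 1")
  if (cfg$n_genotypes < 1L) stop_cfg("n_genotypes must be >= 1")
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %s: M=%d, N=%d, alpha=%g, view=%s, grid=[%g..%g], seed=%d\n",
    x$scenario, x$pool_size, x$target, x$alpha, x$company_view,
    min(x$reward_grid), max(x$reward_grid), x$seed
  ))
  invisible(x)
}
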