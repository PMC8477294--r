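#' Recruiter's cost
#'
#' `cost = reward * N + t * alpha` (plus an optional per-enrollee data
#' provider fee, default 0): the token outlay to enrollees plus the
#' time-weighted recruitment duration. A larger time weight `alpha` means
#' the recruiter values speed over reward spending.
#'
#' @param reward token reward per enrollee.
#' @param t recruitment duration in days.
#' @param target number of enrollees N.
#' @param alpha time weight (cost per day).
#' @param provider_fee per-enrollee token fee to data providers.
#' @return Numeric cost.
#' @examples
#' cost(reward = 10, t = 13, target = 100, alpha = 1500)  # 20500
#' @export
cost <- function(reward, t, target, alpha, provider_fee = 0) {
  if (any(c(reward, t, target, alpha, provider_fee) < 0)) {
    stop(errorCondition("cost arguments must be nonnegative",
                        class = c("domain_error", "error")))
  }
  (reward + provider_fee) * target + t * alpha
}

#' Sweep the reward grid
#'
#' For every candidate reward: compute the planning-view consent
#' probabilities, the minimal expected recruitment time, and the cost.
#' Rewards whose expected enrollment can never reach the target within the
#' horizon are kept as infeasible rows (`feasible = FALSE`, `t_expected`
#' and `cost` are `NA`) and excluded from minimization.
#'
#' @param config a [scenario_config()].
#' @param pop population `data.frame`; defaults to a pool regenerated from
#'   `config$seed`.
#' @return A `data.frame` (`reward`, `t_expected`, `cost`, `feasible`) of
#'   class `"sweep_table"`.
#' @examples
#' cfg <- scenario_config("basic", pool_size = 100, target = 10,
#'                        reward_grid = seq(20, 200, by = 20))
#' sweep_rewards(cfg)
#' @export
sweep_rewards <- function(config, pop = generate_population(config)) {
  stopifnot(inherits(config, "scenario_config"))
  rows <- lapply(config$reward_grid, function(r) {
    q <- consent_probabilities(pop, r, config)
    t_exp <- tryCatch(
      expected_recruitment_time(q, config$target, config$max_days),
      unreachable_target = function(e) NA_integer_
    )
    c(t_expected = t_exp,
      cost = if (is.na(t_exp)) NA_real_ else {
        cost(r, t_exp, config$target, config$alpha, config$provider_fee)
      })
  })
  rows <- do.call(rbind, rows)
  out <- data.frame(reward = config$reward_grid,
                    t_expected = rows[, "t_expected"],
                    cost = rows[, "cost"],
                    feasible = !is.na(rows[, "t_expected"]))
  if (!any(out$feasible)) {
    stop(errorCondition(
      "no feasible reward: the target is unreachable everywhere on the grid",
      class = c("no_feasible_reward", "error")
    ))
  }
  structure(out, class = c("sweep_table", "data.frame"))
}

#' Cost-minimizing reward
#'
#' Selects the minimum-cost feasible row of a sweep; ties are broken by
#' the smaller reward, then the smaller expected time. Invariant under row
#' permutation.
#'
#' @param sweep a sweep `data.frame` from [sweep_rewards()].
#' @return A list (`reward_star`, `t_star`, `cost_star`) of class
#'   `"optimum"`.
#' @export
select_optimum <- function(sweep) {
  feas <- sweep[sweep$feasible & !is.na(sweep$cost), , drop = FALSE]
  if (nrow(feas) == 0L) {
    stop(errorCondition("no feasible row to optimize over",
                        class = c("no_feasible_reward", "error")))
  }
  ord <- order(feas$cost, feas$reward, feas$t_expected)
  best <- feas[ord[1L], ]
  structure(
    list(reward_star = best$reward, t_star = best$t_expected,
         cost_star = best$cost),
    class = "optimum"
  )
}

#' @export
print.optimum <- function(x, ...) {
  cat(sprintf("<optimum> reward* = %g tokens, t* = %g days, cost* = %g\n",
              x$reward_star, x$t_star, x$cost_star))
  invisible(x)
}

#' Sensitivity of the optimal recruitment time
#'
#' Re-optimizes after scaling one configuration parameter (the target
#' enrollment N or the time weight alpha) by `1 + delta_fraction`, and
#' reports the relative change in the optimal expected recruitment time
#' t*. Integer parameters are rounded half-up after scaling.
#'
#' @param config a [scenario_config()].
#' @param pop population; defaults to a pool regenerated from
#'   `config$seed` (shared between base and perturbed problems).
#' @param parameter `"target_N"` or `"alpha"`.
#' @param delta_fraction relative perturbation, nonzero (0.01 = +1%).
#' @return A list of class `"elasticity"`: `parameter`, `delta_fraction`,
#'   `response_fraction` (relative change in t*), plus the base and
#'   perturbed optima.
#' @export
sensitivity <- function(config, pop = generate_population(config),
                        parameter = c("target_N", "alpha"),
                        delta_fraction = 0.01) {
  parameter <- match.arg(parameter)
  if (delta_fraction == 0) {
    stop(errorCondition("delta_fraction must be nonzero",
                        class = c("domain_error", "error")))
  }
  base <- select_optimum(sweep_rewards(config, pop))
  pert_cfg <- config
  if (parameter == "target_N") {
    pert_cfg$target <- as.integer(floor(config$target *
                                          (1 + delta_fraction) + 0.5))
  } else {
    pert_cfg$alpha <- config$alpha * (1 + delta_fraction)
  }
  validate_scenario_config(pert_cfg)
  pert <- select_optimum(sweep_rewards(pert_cfg, pop))
  structure(
    list(parameter = parameter,
         delta_fraction = delta_fraction,
         response_fraction = (pert$t_star - base$t_star) / base$t_star,
         base = base, perturbed = pert),
    class = "elasticity"
  )
}

# deterministic per-initialization substream: a pure function of
# (seed, init), so adding initializations never reshuffles earlier ones
init_seed <- function(seed, init) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + init * 1009) %%
               2147483647)
}

#' Compare optimized recruitment time with simulation
#'
#' The core validation experiment: for each initialization, regenerate the
#' participant pool, find the cost-optimal reward and its expected
#' recruitment time t* under the recruiter's planning view, then simulate
#' the day-by-day campaign `runs` times with the participants' true
#' individual probabilities, and report the mean and SD of the signed
#' error (simulated completion day minus t*). Under expectation-mode
#' planning (basic scenario) t* is identical across initializations; under
#' individual-mode planning it varies with the pool.
#'
#' @param config a [scenario_config()].
#' @param n_inits number of pool initializations.
#' @param runs simulated campaigns per initialization.
#' @param seed master seed; per-initialization substreams are derived
#'   deterministically from it.
#' @return A `data.frame` of class `"comparison_report"` with one row per
#'   initialization: `init`, `reward_star`, `expected_days`, `error_mean`,
#'   `error_sd`, `censored`. Attribute `runs_per_init` records `runs`.
#' @export
compare_with_simulation <- function(config, n_inits = 10L, runs = 100L,
                                    seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"), n_inits >= 1, runs >= 1)
  rows <- lapply(seq_len(n_inits), function(i) {
    s <- init_seed(seed, i)
    pop <- generate_population(config, seed = s)
    opt <- select_optimum(sweep_rewards(config, pop))
    q_true <- consent_probabilities(pop, opt$reward_star, config,
                                    mode = "individual")
    sims <- simulate_recruitment_many(q_true, config$target, runs,
                                      config$max_days,
                                      seed = init_seed(s, 1L))
    err <- sims$day - opt$t_star
    data.frame(init = i, reward_star = opt$reward_star,
               expected_days = opt$t_star,
               error_mean = mean(err),
               error_sd = if (runs > 1) stats::sd(err) else 0,
               censored = sum(sims$censored))
  })
  structure(do.call(rbind, rows),
            runs_per_init = as.integer(runs),
            class = c("comparison_report", "data.frame"))
}
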