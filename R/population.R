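#' Generate a synthetic participant pool
#'
#' Draws `pool_size` participants with attributes sampled independently and
#' uniformly from the scenario's configured ranges. Socioeconomic status
#' `sp`, task annoyance and perceived reliability are continuous uniforms;
#' the number of treatment protocols `k` is a uniform integer (protocols
#' are counts); the data-provider index `dp` is uniform over the configured
#' provider set. A participant has a genotype label if and only if some
#' provider stores their data (`genotype == 0` exactly when `dp == 0`).
#' Attributes not used by a scenario are `NA`.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed; defaults to `config$seed`. The global RNG
#'   state is left untouched.
#' @return A `data.frame` with one row per participant and columns
#'   `id`, `sp`, `annoyance`, `reliability`, `k`, `dp`, `genotype`.
#' @examples
#' pop <- generate_population(scenario_config("basic", pool_size = 5))
#' range(pop$sp)
#' @export
generate_population <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  m <- config$pool_size
  withr::with_seed(seed, {
    sp <- stats::runif(m, config$sp_range[1], config$sp_range[2])
    if (config$scenario == "basic") {
      annoyance <- stats::runif(m, config$annoyance_range[1],
                                config$annoyance_range[2])
      reliability <- stats::runif(m, config$reliability_range[1],
                                  config$reliability_range[2])
      k <- rep(NA_integer_, m)
      dp <- rep(NA_integer_, m)
      genotype <- rep(NA_integer_, m)
    } else {
      annoyance <- rep(NA_real_, m)
      reliability <- rep(NA_real_, m)
      k <- sample(seq.int(config$k_range[1], config$k_range[2]), m,
                  replace = TRUE)
      dp <- sample(config$dp_values, m, replace = TRUE)
      genotype <- ifelse(dp > 0L,
                         sample.int(config$n_genotypes, m, replace = TRUE),
                         0L)
    }
    data.frame(id = seq_len(m), sp = sp, annoyance = annoyance,
               reliability = reliability, k = k, dp = dp,
               genotype = genotype)
  })
}

#' The expected participant
#'
#' The fictitious pool member whose every attribute sits at the midpoint
#' (expectation) of its uniform range. Used for expectation-mode planning,
#' when the recruiter only knows the attribute distributions and not the
#' individuals.
#'
#' @inheritParams generate_population
#' @return A one-row `data.frame` with the same columns as
#'   [generate_population()].
#' @examples
#' expected_participant(scenario_config("basic"))$sp  # 7.5
#' @export
expected_participant <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  mid <- function(rg) mean(rg)
  if (config$scenario == "basic") {
    data.frame(id = 0L, sp = mid(config$sp_range),
               annoyance = mid(config$annoyance_range),
               reliability = mid(config$reliability_range),
               k = NA_integer_, dp = NA_integer_, genotype = NA_integer_)
  } else {
    data.frame(id = 0L, sp = mid(config$sp_range),
               annoyance = NA_real_, reliability = NA_real_,
               k = mid(config$k_range), dp = mid(config$dp_values),
               genotype = NA_real_)
  }
}

#' Write a participant pool to CSV
#'
#' Flat one-row-per-participant CSV for reproducibility audits.
#'
#' @param pop a population `data.frame` from [generate_population()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(pop, path, row.names = FALSE)
  invisible(path)
}
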