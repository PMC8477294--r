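# small, fast configurations used across tests
tiny_basic <- function(...) {
  scenario_config("basic", pool_size = 100L, target = 10L,
                  reward_grid = seq(10, 300, by = 10), ...)
}

tiny_validation <- function(...) {
  scenario_config("validation", pool_size = 100L, target = 10L,
                  reward_grid = seq(10, 300, by = 10), ...)
}

# exhaustive scan used as the independent optimum oracle: no ordering
# tricks, just filter-and-min
brute_force_optimum <- function(sweep) {
  feas <- sweep[sweep$feasible, , drop = FALSE]
  feas <- feas[feas$cost == min(feas$cost), , drop = FALSE]
  feas <- feas[feas$reward == min(feas$reward), , drop = FALSE]
  feas <- feas[feas$t_expected == min(feas$t_expected), , drop = FALSE]
  list(reward_star = feas$reward[1], t_star = feas$t_expected[1],
       cost_star = feas$cost[1])
}
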