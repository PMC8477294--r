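test_that("the recruiter's cost is reward outlay plus weighted time", {
  expect_equal(cost(10, 13, 100, 1500), 20500)
  expect_equal(cost(7, 9, 50, 0), 350)
  expect_equal(cost(0, 5, 30, 100), 500)
  expect_equal(cost(10, 13, 100, 1500, provider_fee = 2), 20700)
  expect_error(cost(-1, 1, 1, 1), class = "domain_error")
})

test_that("reward sweeps carry monotone times and exact cost algebra", {
  cfg <- tiny_basic(seed = 4L)
  pop <- generate_population(cfg)
  sw <- sweep_rewards(cfg, pop)
  expect_equal(sw$reward, cfg$reward_grid)
  feas <- sw[sw$feasible, ]
  expect_true(all(diff(feas$t_expected) <= 0))
  expect_equal(feas$cost,
               feas$reward * cfg$target + feas$t_expected * cfg$alpha)
  # where t is flat between consecutive grid rewards, cost steps by N * dr
  flat <- which(diff(feas$t_expected) == 0)
  expect_true(length(flat) > 0)
  expect_equal(diff(feas$cost)[flat], cfg$target * diff(feas$reward)[flat])

  # single-reward grid gives a single row
  one <- sweep_rewards(scenario_config("basic", pool_size = 100L,
                                       target = 10L, reward_grid = 150),
                       pop)
  expect_equal(nrow(one), 1L)
  expect_true(one$feasible)

  # a grid of hopeless rewards has no feasible row
  expect_error(
    sweep_rewards(scenario_config("basic", pool_size = 100L, target = 90L,
                                  reward_grid = c(1, 2, 3), max_days = 30L),
                  pop),
    class = "no_feasible_reward"
  )
})

test_that("optimum selection matches brute force and breaks ties low", {
  sw <- structure(
    data.frame(reward = c(10, 20, 30), t_expected = c(9, 5, 5),
               cost = c(500, 400, 400), feasible = TRUE),
    class = c("sweep_table", "data.frame")
  )
  opt <- select_optimum(sw)
  expect_equal(opt$reward_star, 20)
  expect_equal(opt$t_star, 5)
  # equal cost and reward: smaller t wins
  sw2 <- data.frame(reward = c(5, 5), t_expected = c(8, 6),
                    cost = c(100, 100), feasible = TRUE)
  expect_equal(select_optimum(sw2)$t_star, 6)
  # permutation invariance
  perm <- sw[c(3, 1, 2), ]
  expect_equal(select_optimum(perm), opt)
  # infeasible-only input errors
  sw$feasible <- FALSE
  expect_error(select_optimum(sw), class = "no_feasible_reward")

  for (s in 1:5) {
    cfg <- if (s %% 2) tiny_basic(seed = s) else tiny_validation(seed = s)
    sweep <- sweep_rewards(cfg, generate_population(cfg))
    expect_equal(unclass(select_optimum(sweep)), brute_force_optimum(sweep))
  }
})

test_that("sensitivity reports relative t* changes with guarded input", {
  cfg <- tiny_basic(seed = 6L)
  pop <- generate_population(cfg)
  expect_error(sensitivity(cfg, pop, "alpha", delta_fraction = 0),
               class = "domain_error")
  e <- sensitivity(cfg, pop, "alpha", delta_fraction = 0.5)
  expect_lte(e$response_fraction, 0)
  en <- sensitivity(cfg, pop, "target_N", delta_fraction = 0.5)
  expect_gte(en$response_fraction, 0)
  # target scaling rounds half-up: 10 * 1.5 -> 15 enters the cost
  expect_equal(en$perturbed$cost_star,
               en$perturbed$reward_star * 15 + en$perturbed$t_star * cfg$alpha)

  # cost* itself is monotone in both knobs (envelope property): a higher
  # time weight or a larger target can never cheapen the optimum
  base <- select_optimum(sweep_rewards(cfg, pop))
  expect_gte(sensitivity(cfg, pop, "alpha", 0.25)$perturbed$cost_star,
             base$cost_star)
  expect_gte(sensitivity(cfg, pop, "target_N", 0.25)$perturbed$cost_star,
             base$cost_star)
})

test_that("comparison report contrasts planning views across initializations", {
  cfg <- tiny_basic(seed = 10L)
  rep_b <- compare_with_simulation(cfg, n_inits = 4L, runs = 20L)
  expect_equal(nrow(rep_b), 4L)
  # expectation-mode planning cannot see the pool: t* identical per init
  expect_equal(length(unique(rep_b$expected_days)), 1L)
  expect_true(all(rep_b$error_sd >= 0))
  expect_identical(rep_b, compare_with_simulation(cfg, n_inits = 4L,
                                                  runs = 20L))
  # earlier initializations are unchanged when more are added
  rep_b6 <- compare_with_simulation(cfg, n_inits = 6L, runs = 20L)
  expect_identical(rep_b6[1:4, ], rep_b[1:4, ])

  # a reward so large that everyone consents at once: zero error, zero SD
  sure <- scenario_config("validation", pool_size = 20L, target = 5L,
                          reward_grid = 5000)
  rep_s <- compare_with_simulation(sure, n_inits = 2L, runs = 1L)
  expect_equal(rep_s$error_mean, c(0, 0))
  expect_equal(rep_s$error_sd, c(0, 0))
})
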