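test_that("basic-scenario welfare follows the concave-minus-fatigue form", {
  # T = 0 removes the labor term; sqrt(9/9) = 1
  expect_equal(welfare_basic(data.frame(sp = 9, annoyance = 0.05),
                             reward = 9, T_days = 0), 1)
  # sqrt(36/9) - 0.1 * 25 = 2 - 2.5
  expect_equal(welfare_basic(data.frame(sp = 9, annoyance = 0.1),
                             reward = 36, T_days = 5), -0.5)
  # zero reward leaves only the (negative) fatigue term
  expect_equal(welfare_basic(data.frame(sp = 5, annoyance = 0.08),
                             reward = 0, T_days = 10), -8)
  expect_error(welfare_basic(data.frame(sp = 5, annoyance = 0.08),
                             reward = -1, T_days = 1),
               class = "domain_error")
})

test_that("basic consent probability gates on welfare and clamps to [0,1]", {
  p <- data.frame(sp = 5, annoyance = 0.05, reliability = 0.5)
  # zero reward: welfare <= 0, probability exactly 0
  expect_equal(consent_prob_basic(p, 0, T_days = 5), 0)
  # welfare positive at reward 200: q = 200 * 0.5 / (5 * 200)
  expect_equal(consent_prob_basic(p, 200, T_days = 5, normalizer = 200), 0.1)
  # huge reward: raw value exceeds 1, clamped
  expect_equal(consent_prob_basic(p, 1e6, T_days = 5, normalizer = 200), 1)
  # every participant has a welfare-gate threshold: below it q is 0
  pop <- generate_population(scenario_config("basic", pool_size = 30L,
                                             target = 3L, seed = 11L))
  low <- consent_prob_basic(pop, 1e-6, T_days = 5)
  expect_true(all(low == 0))
})

test_that("the sigmoid has its closed-form values and symmetry", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(log(3)), 0.75)
  xs <- c(-5, -0.3, 0.7, 12)
  expect_equal(sigmoid(xs) + sigmoid(-xs), rep(1, length(xs)))
})

test_that("validation consent probability is a shifted sigmoid in reward/k", {
  expect_equal(consent_prob_validation(data.frame(k = 1), 150), 0.5)
  expect_equal(consent_prob_validation(data.frame(k = 4), 600), 0.5)
  expect_equal(consent_prob_validation(data.frame(k = 1), 0,
                                       middle = 150, steepness = 0.05),
               1 / (1 + exp(7.5)))
  # fewer remaining protocols means higher consent at any fixed reward
  q_by_k <- consent_prob_validation(data.frame(k = 1:5), 200)
  expect_true(all(diff(q_by_k) < 0))
  expect_error(consent_prob_validation(data.frame(k = 0), 10),
               class = "domain_error")
})

test_that("consent_probabilities dispatches on scenario and planning view", {
  cfgb <- tiny_basic(seed = 3L)
  popb <- generate_population(cfgb)
  q_exp <- consent_probabilities(popb, 100, cfgb, mode = "expectation")
  expect_length(q_exp, nrow(popb))
  expect_equal(length(unique(as.numeric(q_exp))), 1L)
  expect_identical(attr(q_exp, "mode"), "expectation")
  expect_identical(attr(q_exp, "reward"), 100)

  cfgv <- tiny_validation(seed = 3L)
  popv <- generate_population(cfgv)
  q_ind <- consent_probabilities(popv, 200, cfgv, mode = "individual")
  # ordered inversely to k
  expect_true(all(diff(as.numeric(q_ind)[order(popv$k)]) <= 0))
})

test_that("probabilities are valid and monotone in reward across seeds", {
  for (s in 1:5) {
    for (make in list(tiny_basic, tiny_validation)) {
      cfg <- make(seed = s)
      pop <- generate_population(cfg)
      qs <- sapply(cfg$reward_grid, function(r) {
        as.numeric(consent_probabilities(pop, r, cfg, mode = "individual"))
      })
      expect_true(all(qs >= 0 & qs <= 1))
      # elementwise nondecreasing along the reward grid
      expect_true(all(t(apply(qs, 1, diff)) >= 0))
    }
  }
})
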