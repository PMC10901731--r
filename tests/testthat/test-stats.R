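test_that("final-window surplus summarises trajectories", {
  mk <- function(surplus) structure(list(
    surplus = surplus, var_share = rep(0, length(surplus)),
    snapshot = NULL, competition_log = NULL, seed = 1,
    config = list(final_fraction = 0.1)), class = "replicate_result")
  rs <- list(mk(rep(0, 100)), mk(c(rep(0, 90), rep(1, 10))))
  ms <- mean_surplus(rs, final_fraction = 0.1)
  expect_equal(ms$per_replicate, c(0, 1))
  expect_equal(ms$mean, 0.5)
  expect_error(mean_surplus(list()), "at least one")
  expect_error(mean_surplus(rs, final_fraction = 0), "final_fraction")
})

test_that("extreme populations give the extreme surplus values", {
  cfgD <- small_cfg("RI", play_mode = "repeated", m_j = 4,
                    init = "all-selfish", generations = 5L, mu = 0)
  rD <- run_simulation(cfgD, seed = 2)
  expect_equal(mean_surplus(list(rD))$mean, 0)
  cfgC <- small_cfg("RI", play_mode = "repeated", m_j = 4,
                    init = "all-perfect", generations = 5L, mu = 0)
  rC <- run_simulation(cfgC, seed = 2)
  expect_equal(mean_surplus(list(rC))$mean, 1)  # kappa - 1 with kappa = 2
})

test_that("percentile bootstrap behaves as a percentile bootstrap", {
  set.seed(51)
  expect_equal(unname(bootstrap_ci(rep(3.2, 10), B = 1000)), c(3.2, 3.2))
  x <- rnorm(50)
  ci <- bootstrap_ci(x, B = 2000)
  expect_lt(ci["lo"], mean(x))
  expect_gt(ci["hi"], mean(x))
  expect_gte(ci["lo"], min(x))
  expect_lte(ci["hi"], max(x))
  expect_error(bootstrap_ci(1), "two values")
  expect_error(bootstrap_ci(1:10, B = 10), "1000")
})

test_that("the decomposition identity holds exactly", {
  d <- superadditive_decomposition(0.9, 0.05, 0.1, 0.02)
  expect_equal(unname(d["super_effect"]), 0.77)
  expect_equal(unname(d["ri_effect"]), 0.03)
  expect_equal(unname(d["gc_effect"]), 0.08)
  # additive case: zero interaction
  d0 <- superadditive_decomposition(0.13, 0.1, 0.05, 0.02)
  expect_equal(unname(d0["super_effect"]), 0)
  set.seed(52)
  for (k in 1:25) {
    v <- runif(4)
    d <- superadditive_decomposition(v[1], v[2], v[3], v[4])
    expect_equal(unname(sum(d)), v[1] - v[4])
  }
})

test_that("between-group variance share matches its ANOVA definition", {
  pop <- make_fixture("tiny", init = "all-selfish")
  expect_equal(between_group_variance_share(pop), 0)  # monomorphic: 0
  # internally homogeneous, mutually distinct groups: share 1
  pop$ingroup[, 1] <- pop$group / 10
  pop$ingroup[, 2] <- pop$group / 20
  expect_equal(between_group_variance_share(pop), 1)
  # random assignment: share near the ANOVA expectation (G-1)/(N-1)
  set.seed(53)
  pop2 <- make_fixture("paperscale", init = "random")
  null_shares <- replicate(200, {
    pop2$group <- sample(pop2$group)
    between_group_variance_share(pop2)
  })
  expect_lt(abs(mean(null_shares) - 39 / 959), 0.005)
  # invariance under group relabeling and within-group permutation
  pop3 <- make_fixture("small", init = "random")
  s0 <- between_group_variance_share(pop3)
  relab <- sample(10)
  pop3$group <- relab[pop3$group]
  expect_equal(between_group_variance_share(pop3), s0)
  ord <- order(pop3$group, runif(120))
  pop3$ingroup <- pop3$ingroup[ord, ]
  pop3$group <- pop3$group[ord]
  expect_equal(between_group_variance_share(pop3), s0)
})

test_that("strategy-type frequencies sum to one and recover constructed mixes", {
  pop <- make_fixture("small", init = "all-perfect")
  fr <- strategy_type_frequencies(pop)
  expect_equal(sum(fr$types), 1)
  expect_equal(unname(fr$types["perfect"]), 1)
  expect_equal(sum(fr$initial_transfer_bins), 1)
  expect_equal(unname(fr$initial_transfer_bins[10]), 1)  # all i = 1
  # constructed half-escalator / half-de-escalator population
  pop$ingroup[1:60, 2:3] <- matrix(c(0.2, 1), 60, 2, byrow = TRUE)
  pop$ingroup[61:120, 2:3] <- matrix(c(0, 0.7), 60, 2, byrow = TRUE)
  fr2 <- strategy_type_frequencies(pop)
  expect_equal(unname(fr2$types["escalating"]), 0.5)
  expect_equal(unname(fr2$types["de-escalating"]), 0.5)
  expect_error(strategy_type_frequencies(pop, role = "outgroup"),
               "no outgroup")
})

test_that("the linear fixed-point oracle gives the documented limits", {
  fp <- fixed_point_linear(c(0.4, 0.6), c(0.4, 0.6))
  expect_true(fp$contractive)
  expect_equal(unname(fp$limits), c(0.5, 0.5))
  # two escalators converge on full cooperation
  fp <- fixed_point_linear(c(0.3, 1), c(0.1, 1))
  expect_equal(unname(fp$limits), c(1, 1))
  # two de-escalators converge on full defection
  fp <- fixed_point_linear(c(0, 0.8), c(0, 0.5))
  expect_equal(unname(fp$limits), c(0, 0))
  # slope product >= 1: initial-condition dependent
  fp <- fixed_point_linear(c(0, 1), c(0, 1))
  expect_false(fp$contractive)
  expect_error(fixed_point_linear(c(0.5, 2), c(0, 1)), "0, 1")
})

test_that("simulated long-run transfers match the oracle on contractive pairs", {
  set.seed(55)
  for (k in 1:25) {
    ab1 <- runif(2)
    ab2 <- runif(2)
    if (abs((ab1[2] - ab1[1]) * (ab2[2] - ab2[1])) >= 0.95) next
    fp <- fixed_point_linear(ab1, ab2)
    s1 <- strategy(runif(1), response_curve(3, ab1))
    s2 <- strategy(runif(1), response_curve(3, ab2))
    rec <- play_match(s1, s2, match_config(1000, 2))
    expect_lt(abs(rec$t_first[1000] - fp$limits["first"]), 1e-6)
    expect_lt(abs(rec$t_second[1000] - fp$limits["second"]), 1e-6)
  }
})
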