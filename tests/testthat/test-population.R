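test_that("migration conserves group sizes and deals migrants uniformly", {
  set.seed(7)
  pop <- make_fixture("paperscale", init = "random")
  expect_identical(migrate_individuals(pop, 0), pop)
  m1 <- migrate_individuals(pop, 8)
  expect_equal(as.integer(table(m1$group)), rep(24L, 40))
  expect_error(migrate_individuals(pop, 25), "group size")
  # uniform redistribution: expected natal fraction after one migration of
  # 16/24 is (8 + 16/40)/24 = 0.35
  fr <- replicate(2000, {
    m <- migrate_individuals(pop, 16)
    mean(m$group == m$natal)
  })
  expect_lt(abs(mean(fr) - 0.35), 0.01)
})

test_that("migrants carry their accumulated payoff with them", {
  set.seed(8)
  pop <- make_fixture("tiny", init = "random")
  pop$payoff <- seq_len(24)
  m <- migrate_individuals(pop, 3)
  expect_identical(m$payoff, pop$payoff)  # payoff stays with the slot
  expect_equal(sum(m$payoff), sum(pop$payoff))
})

test_that("ingroup pairing is a within-group perfect matching with fair roles", {
  set.seed(9)
  pop <- make_fixture("paperscale", init = "random")
  pr <- pair_ingroup(pop)
  expect_equal(nrow(pr), 480)
  expect_setequal(c(pr$first, pr$second), seq_len(960))
  # no pair spans two groups
  expect_true(all(pop$group[pr$first] == pop$group[pr$second]))
  # a focal individual is first mover about half the time
  focal_first <- replicate(2000, 1 %in% pair_ingroup(pop)$first[1:12])
  expect_lt(abs(mean(focal_first) - 0.5), 0.05)
})

test_that("parent sampling is exponential-payoff softmax", {
  set.seed(12)
  # equal payoffs: uniform regardless of beta
  idx <- select_parents(rep(2.5, 4), 4e4, beta = 1)
  expect_lt(max(abs(tabulate(idx, 4) / 4e4 - 0.25)), 0.02)
  # beta = 0: uniform even with unequal payoffs (pure drift)
  idx <- select_parents(c(10, 0, 5, 1), 4e4, beta = 0)
  expect_lt(max(abs(tabulate(idx, 4) / 4e4 - 0.25)), 0.02)
  # two-member toy group: P(parent 1) = e^2 / (e^2 + e^1)
  idx <- select_parents(c(2, 1), 1e5, beta = 1)
  expect_lt(abs(mean(idx == 1) - exp(2) / (exp(2) + exp(1))), 0.01)
  expect_error(select_parents(c(1, Inf), 2, 1), "finite")
})

test_that("reproduction copies parents within groups, resets payoffs, mutates", {
  set.seed(13)
  pop <- make_fixture("tiny", init = "random")
  pop$payoff <- runif(24)
  off <- reproduce_population(pop, beta = 1, mutation_params(mu = 0))
  expect_equal(off$payoff, rep(0, 24))
  expect_identical(off$natal, off$group)
  # with mu = 0 every offspring strategy equals some parent's strategy in
  # the same group
  for (g in 1:4) {
    kid <- off$ingroup[off$group == g, ]
    par <- pop$ingroup[pop$group == g, ]
    expect_true(all(apply(kid, 1, function(r)
      any(colSums(abs(t(par) - r)) < 1e-12))))
  }
})

test_that("a generation conserves population structure and logs its events", {
  set.seed(14)
  cfg <- small_cfg("JOINT", life_cycle = "decoupled", m_j = 4,
                   init = "random", generations = 5L)
  pop <- make_population(10, 12, 3, "random", outgroup = TRUE)
  stepped <- step_generation(pop, cfg)
  expect_equal(attr(stepped, "events"),
               c("play", "migrate", "compete", "select"))
  expect_equal(as.integer(table(stepped$group)), rep(12L, 10))
  expect_equal(stepped$generation, 1L)
  cfg2 <- small_cfg("JOINT", life_cycle = "coupled", m_j = 4,
                    init = "random", generations = 5L)
  stepped2 <- step_generation(pop, cfg2)
  expect_equal(attr(stepped2, "events"),
               c("migrate", "play", "compete", "select"))
  # RI omits the competition stage entirely
  cfgRI <- small_cfg("RI", play_mode = "repeated", m_j = 4, init = "random",
                     generations = 5L)
  popRI <- make_population(10, 12, 3, "random")
  sRI <- step_generation(popRI, cfgRI)
  expect_equal(attr(sRI, "events"), c("play", "migrate", "select"))
  expect_equal(nrow(attr(sRI, "competition_log")), 0)
  # scenario/population mismatch is a config error
  expect_error(step_generation(popRI, cfg), "outgroup")
  expect_error(step_generation(pop, cfgRI), "without outgroup")
})

test_that("shared-natal-group probability among partners decreases with migration", {
  set.seed(15)
  shared <- sapply(c(2, 6, 10), function(m) {
    mean(replicate(300, {
      pop <- make_fixture("small", init = "random")
      pop <- migrate_individuals(pop, m)
      pr <- pair_ingroup(pop)
      mean(pop$natal[pr$first] == pop$natal[pr$second])
    }))
  })
  expect_true(all(diff(shared) < 0))
})

test_that("with no migration the two life cycles are dynamically identical", {
  cfg_d <- small_cfg("RI", play_mode = "repeated", life_cycle = "decoupled",
                     m_j = 0, init = "random", generations = 40L)
  cfg_c <- small_cfg("RI", play_mode = "repeated", life_cycle = "coupled",
                     m_j = 0, init = "random", generations = 40L)
  r_d <- run_simulation(cfg_d, seed = 99)
  r_c <- run_simulation(cfg_c, seed = 99)
  expect_identical(r_d$surplus, r_c$surplus)
  expect_identical(r_d$snapshot$ingroup, r_c$snapshot$ingroup)
})

test_that("neutral evolution shows no systematic trend in strategy means", {
  # beta = 0, no competition: each parameter's population mean is an
  # unbiased random walk (reflected at the bounds); across replicates the
  # net drift from a centred start should vanish
  set.seed(16)
  cfg <- scenario_config("RI", dims = 3, play_mode = "one-shot", m_j = 4,
                         init = "random", beta = 0, generations = 1000L,
                         n_groups = 4L, group_size = 6L)
  drift <- t(replicate(8, {
    r <- run_simulation(cfg)
    colMeans(r$snapshot$ingroup) - 0.5
  }))
  # per-parameter bound ~2.5 sigma of the replicate spread of a bounded
  # random walk; the pooled mean is a tighter check of unbiasedness
  for (j in 1:3) {
    expect_lt(abs(mean(drift[, j])), 0.2)
  }
  expect_lt(abs(mean(drift)), 0.08)
})
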