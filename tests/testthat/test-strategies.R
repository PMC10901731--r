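test_that("response evaluation matches the three parameterizations", {
  # perfect reciprocity mimics the partner exactly
  expect_equal(evaluate_response(response_curve(2, 0), 0.37), 0.37)
  # linear curve: intercepts and midpoint
  lin <- response_curve(3, c(0.4, 0.6))
  expect_equal(evaluate_response(lin, 0), 0.4)
  expect_equal(evaluate_response(lin, 1), 0.6)
  expect_equal(evaluate_response(lin, 0.5), 0.5)
  # quadratic passes through its three nodes
  quad <- response_curve(4, c(0.1, 0.9, 0.2))
  expect_equal(evaluate_response(quad, 0), 0.1)
  expect_equal(evaluate_response(quad, 0.5), 0.9)
  expect_equal(evaluate_response(quad, 1), 0.2)
  # offset family: location (c >= 0) and slope (c < 0)
  expect_equal(evaluate_response(response_curve(2, 0.5), 0.4), 0.5 + 0.5 * 0.4)
  expect_equal(evaluate_response(response_curve(2, -0.5), 0.4), 0.5 * 0.4)
})

test_that("evaluation stays in [0, 1] over the whole admissible space", {
  set.seed(11)
  xs <- seq(0, 1, length.out = 41)
  for (dims in 2:4) {
    rng <- coopdyn:::response_param_range(dims)
    ok <- vapply(1:200, function(k) {
      cv <- response_curve(dims, runif(nrow(rng), rng[, 1], rng[, 2]))
      y <- evaluate_response(cv, xs)
      all(y >= 0 & y <= 1)
    }, TRUE)
    expect_true(all(ok))
  }
})

test_that("invalid inputs and parameters are rejected", {
  expect_error(response_curve(3, c(0.5, 1.5)), "admissible")
  expect_error(response_curve(5, c(0, 0, 0, 0)), "dims")
  expect_error(evaluate_response(response_curve(3, c(0, 1)), 1.2), "0, 1")
  expect_error(strategy(-0.1, response_curve(3, c(0, 1))), "0, 1")
  expect_error(classify_response(response_curve(3, c(0, 1)), tol = 0), "tol")
  expect_error(classify_response(response_curve(3, c(0, 1)),
                                 quasi_threshold = 0.4), "quasi_threshold")
})

test_that("classification recovers the named reciprocity types", {
  expect_equal(classify_response(response_curve(3, c(0, 1))), "perfect")
  expect_equal(classify_response(response_curve(2, 0)), "perfect")
  expect_equal(classify_response(response_curve(3, c(0.2, 1))), "escalating")
  expect_equal(classify_response(response_curve(3, c(0, 0.7))), "de-escalating")
  expect_equal(classify_response(response_curve(3, c(0.4, 0.6))), "ambiguous")
  # extreme ambiguous forms via the symmetric fixed point a / (1 - b + a)
  expect_equal(classify_response(response_curve(3, c(0.2, 0.99)),
                                 quasi_threshold = 0.9), "quasi-escalating")
  expect_equal(classify_response(response_curve(3, c(0.01, 0.8)),
                                 quasi_threshold = 0.9), "quasi-de-escalating")
  # negatively sloped linear curves fall outside the taxonomy
  expect_equal(classify_response(response_curve(3, c(0.9, 0.1))), "other")
  # nonlinear ambiguity analogue
  expect_equal(classify_response(response_curve(4, c(0.3, 0.55, 0.6))),
               "ambiguous")
  # non-monotone nonlinear curve falls outside the taxonomy
  expect_equal(classify_response(response_curve(4, c(0.9, 0.1, 0.9))), "other")
})

test_that("the two-dimensional family can never be ambiguous", {
  cc <- seq(-1, 1, by = 0.005)
  lab <- coopdyn:::classify_matrix(matrix(cc, ncol = 1), 2L)
  expect_false(any(lab %in% c("ambiguous", "quasi-escalating",
                              "quasi-de-escalating")))
  expect_setequal(unique(lab), c("perfect", "escalating", "de-escalating"))
})

test_that("every admissible curve receives exactly one label", {
  set.seed(23)
  for (dims in 2:4) {
    rng <- coopdyn:::response_param_range(dims)
    P <- sapply(seq_len(nrow(rng)), function(j) runif(200, rng[j, 1], rng[j, 2]))
    lab <- coopdyn:::classify_matrix(as.matrix(P), dims)
    expect_true(all(lab %in% strategy_type_labels()))
    expect_length(lab, 200)
  }
})

test_that("a three-dimensional perfect reciprocator equals the offset-family one", {
  xs <- seq(0, 1, length.out = 101)
  expect_equal(evaluate_response(response_curve(3, c(0, 1)), xs),
               evaluate_response(response_curve(2, 0), xs))
})

test_that("mutation respects bounds, identity limits, and creates ambiguity", {
  set.seed(31)
  s <- random_strategy(3)
  expect_identical(mutate_strategy(s, mutation_params(mu = 0)), s)
  expect_identical(mutate_strategy(s, mutation_params(sigma = 0)), s)
  # closure: heavy mutation keeps every parameter admissible
  for (dims in 2:4) {
    rng <- coopdyn:::response_param_range(dims)
    s <- random_strategy(dims)
    ok <- vapply(1:400, function(k) {
      s <<- mutate_strategy(s, mutation_params(mu = 1, sigma = 0.5))
      p <- s$response$params
      s$initial_transfer >= 0 && s$initial_transfer <= 1 &&
        all(p >= rng[, 1] & p <= rng[, 2])
    }, TRUE)
    expect_true(all(ok))
  }
  # an upward left-intercept perturbation of a de-escalator is ambiguous
  expect_equal(classify_response(response_curve(3, c(0.1, 0.7))), "ambiguous")
})

test_that("initial conditions seed the stated strategies", {
  p3 <- initial_strategy("all-perfect", 3)
  expect_equal(p3$initial_transfer, 1)
  expect_equal(p3$response$params, c(0, 1))
  s3 <- initial_strategy("all-selfish", 3)
  expect_equal(s3$initial_transfer, 0)
  expect_equal(evaluate_response(s3$response, seq(0, 1, 0.1)), rep(0, 11))
  for (dims in 2:4) {
    expect_equal(classify_response(initial_strategy("all-perfect", dims)$response),
                 "perfect")
    expect_equal(evaluate_response(initial_strategy("all-selfish", dims)$response,
                                   c(0, 0.5, 1)), c(0, 0, 0))
  }
  set.seed(5)
  M <- coopdyn:::init_strategy_matrix(2000, 2L, "random")
  expect_true(all(M[, 1] >= 0 & M[, 1] <= 1))
  expect_true(all(M[, 2] >= -1 & M[, 2] <= 1))
  # uniform over the stated ranges
  expect_gt(ks.test(M[, 2], "punif", -1, 1)$p.value, 1e-4)
  expect_error(initial_strategy("nice", 3), "unknown")
})
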