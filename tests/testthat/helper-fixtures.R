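# Shared fixtures and small generators used across the suite.

# A strategy from a flat parameter vector (i, response params).
mk_strategy <- function(dims, i, ...) {
  strategy(i, response_curve(dims, c(...)))
}

# Uniformly random admissible strategy.
random_strategy <- function(dims) {
  rng <- coopdyn:::response_param_range(dims)
  strategy(runif(1), response_curve(dims, runif(nrow(rng), rng[, 1], rng[, 2])))
}

# Scaled-down desk configurations used throughout the suite: 10 groups of
# 12, n = 25 ingroup interactions.
small_cfg <- function(scenario, ...) {
  args <- list(scenario = scenario, n_groups = 10L, group_size = 12L, ...)
  if (scenario != "RI") {
    if (is.null(args$xi)) args$xi <- 10L
    if (is.null(args$lambda)) args$lambda <- 100
  }
  if (is.null(args$n_interactions) &&
      !identical(args$play_mode, "one-shot") && scenario != "GC") {
    args$n_interactions <- 25L
  }
  do.call(scenario_config, args)
}
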