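# The three scenarios:
#   RI    — repeated interactions: ingroup play only (one-shot or repeated),
#           no group competition.
#   GC    — group competition: all games one-shot; each individual plays one
#           ingroup match and one outgroup match against the paired group;
#           paired groups then compete with positive probability.
#   JOINT — identical to GC except that ingroup interactions are repeated.

#' Scenario configuration
#'
#' One cell of the factorial design. Scenario-specific invariants are
#' enforced: RI takes no `xi`/`lambda` and no outgroup strategies; GC play
#' is always one-shot (`n_interactions` must be 1); JOINT ingroup play is
#' always repeated (`n_interactions >= 2`).
#'
#' @param scenario `"RI"`, `"GC"` or `"JOINT"`.
#' @param dims Strategy dimensionality (2, 3 or 4).
#' @param life_cycle `"decoupled"` (play, migrate, compete, select) or
#'   `"coupled"` (migrate, play, compete, select).
#' @param m_j Migrants per group per generation (canonically 8 or 16 of 24).
#' @param init Initial condition (`"all-perfect"`, `"all-selfish"`,
#'   `"random"`).
#' @param play_mode RI only: `"one-shot"` or `"repeated"`.
#' @param xi GC/JOINT: number of groups reshuffled across territories per
#'   generation (canonically 0, 20 or 40).
#' @param lambda GC/JOINT: contest sensitivity (canonically 0, 10, 25, 100).
#' @param n_interactions Interactions per ingroup match (1 for one-shot
#'   play; default 100 for repeated play).
#' @param kappa Transfer multiplier (2 or 4).
#' @param mistakes,mistake_sd Whether transfers are mistake-perturbed, and
#'   the truncated-normal mistake scale.
#' @param beta Selection intensity of within-group reproduction.
#' @param generations Number of generations per replicate.
#' @param n_groups,group_size Metapopulation shape (default 40 x 24).
#' @param p_max Maximum competition-occurrence probability.
#' @param mu,sigma_mut,jump_mu Mutation kernel: probability and scale of
#'   local Gaussian perturbations, and probability of uniform redraws (see
#'   [mutation_params()]).
#' @param final_fraction Fraction of final generations forming the summary
#'   window.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(scenario, dims = 3L, life_cycle = "decoupled",
                            m_j = 8L, init = "random",
                            play_mode = NULL, xi = NULL, lambda = NULL,
                            n_interactions = NULL, kappa = 2,
                            mistakes = FALSE, mistake_sd = 0.05,
                            beta = 1, generations = 5000L,
                            n_groups = 40L, group_size = 24L,
                            p_max = 0.2, mu = 0.01, sigma_mut = 0.05,
                            jump_mu = 0.005, final_fraction = 0.1) {
  scenario <- match.arg(scenario, c("RI", "GC", "JOINT"))
  life_cycle <- match.arg(life_cycle, c("decoupled", "coupled"))
  init <- match.arg(init, c("all-perfect", "all-selfish", "random"))
  dims <- as.integer(dims)
  if (!dims %in% 2:4) stop("`dims` must be 2, 3 or 4", call. = FALSE)
  n_groups <- as.integer(n_groups)
  group_size <- as.integer(group_size)
  m_j <- as.integer(m_j)
  if (m_j < 0L || m_j > group_size) {
    stop("`m_j` must lie between 0 and `group_size`", call. = FALSE)
  }
  generations <- as.integer(generations)
  if (generations < 1L) stop("`generations` must be >= 1", call. = FALSE)
  if (final_fraction <= 0 || final_fraction > 1) {
    stop("`final_fraction` must lie in (0, 1]", call. = FALSE)
  }

  if (scenario == "RI") {
    if (!is.null(xi) || !is.null(lambda)) {
      stop("the RI scenario takes no `xi` or `lambda`", call. = FALSE)
    }
    play_mode <- match.arg(play_mode, c("repeated", "one-shot"))
    if (play_mode == "one-shot") {
      if (is.null(n_interactions)) n_interactions <- 1L
      if (n_interactions != 1L) {
        stop("one-shot play means `n_interactions = 1`", call. = FALSE)
      }
    } else {
      if (is.null(n_interactions)) n_interactions <- 100L
      if (n_interactions < 2L) {
        stop("repeated play means `n_interactions >= 2`", call. = FALSE)
      }
    }
  } else {
    if (!is.null(play_mode)) {
      stop("`play_mode` applies only to the RI scenario", call. = FALSE)
    }
    if (is.null(xi)) xi <- 0L
    if (is.null(lambda)) lambda <- 0
    xi <- as.integer(xi)
    if (xi < 0L || xi > n_groups) {
      stop("`xi` must lie between 0 and `n_groups`", call. = FALSE)
    }
    if (!is.finite(lambda) || lambda < 0) {
      stop("`lambda` must be >= 0", call. = FALSE)
    }
    if (scenario == "GC") {
      if (is.null(n_interactions)) n_interactions <- 1L
      if (n_interactions != 1L) {
        stop("all games are one-shot in the GC scenario (`n_interactions = 1`)",
             call. = FALSE)
      }
    } else {
      if (is.null(n_interactions)) n_interactions <- 100L
      if (n_interactions < 2L) {
        stop("ingroup interactions are repeated in the joint scenario (`n_interactions >= 2`)",
             call. = FALSE)
      }
    }
  }
  n_interactions <- as.integer(n_interactions)
  if (!is.finite(kappa) || kappa <= 1) stop("`kappa` must be > 1", call. = FALSE)
  if (!is.finite(beta) || beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (p_max <= 0 || p_max > 1) stop("`p_max` must lie in (0, 1]", call. = FALSE)
  mutation_params(mu, sigma_mut, jump_mu)  # validates the kernel

  structure(list(
    scenario = scenario, dims = dims, life_cycle = life_cycle, m_j = m_j,
    init = init, play_mode = play_mode, xi = xi, lambda = lambda,
    n_interactions = n_interactions, kappa = kappa,
    mistakes = isTRUE(mistakes), mistake_sd = mistake_sd, beta = beta,
    generations = generations, n_groups = n_groups, group_size = group_size,
    p_max = p_max, mu = mu, sigma_mut = sigma_mut, jump_mu = jump_mu,
    final_fraction = final_fraction
  ), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  extra <- if (x$scenario == "RI") {
    sprintf("play_mode=%s", x$play_mode)
  } else {
    sprintf("xi=%d, lambda=%g", x$xi, x$lambda)
  }
  cat(sprintf(
    "<scenario_config %s: dims=%d, %s, m_j=%d, init=%s, %s, n=%d, kappa=%g, beta=%g, T=%d, %dx%d>\n",
    x$scenario, x$dims, x$life_cycle, x$m_j, x$init, extra,
    x$n_interactions, x$kappa, x$beta, x$generations, x$n_groups,
    x$group_size))
  invisible(x)
}

scenario_has_competition <- function(cfg) cfg$scenario %in% c("GC", "JOINT")

#' Enumerate the full factorial design
#'
#' RI crosses play mode (one-shot, repeated), dimensionality (2, 3, 4),
#' life cycle, migration rate (8, 16) and initial condition: 72 cells.
#' GC and JOINT each cross dimensionality, life cycle, Xi (0, 20, 40),
#' lambda (0, 10, 25, 100), migration rate and initial condition: 432 cells
#' each. The total is 936. Defaults: `n = 100` for repeated play,
#' `kappa = 2`, no mistakes, `beta = 1`.
#'
#' @return A data frame with one row per configuration, in a deterministic
#'   order, with columns `scenario`, `play_mode`, `dims`, `life_cycle`,
#'   `xi`, `lambda`, `m_j`, `init`, `n_interactions`, `kappa`, `mistakes`
#'   and `beta` (`play_mode`, `xi`, `lambda` are `NA` where inapplicable).
#' @export
enumerate_configurations <- function() {
  dims <- 2:4
  lc <- c("decoupled", "coupled")
  mj <- c(8L, 16L)
  ini <- c("all-perfect", "all-selfish", "random")
  ri <- expand.grid(scenario = "RI", play_mode = c("one-shot", "repeated"),
                    dims = dims, life_cycle = lc, xi = NA_integer_,
                    lambda = NA_real_, m_j = mj, init = ini,
                    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  comp <- expand.grid(scenario = c("GC", "JOINT"), play_mode = NA_character_,
                      dims = dims, life_cycle = lc, xi = c(0L, 20L, 40L),
                      lambda = c(0, 10, 25, 100), m_j = mj, init = ini,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid <- rbind(ri, comp)
  grid <- unique(grid)
  grid$n_interactions <- ifelse(grid$scenario == "GC", 1L,
                                ifelse(grid$scenario == "RI" &
                                         grid$play_mode == "one-shot", 1L, 100L))
  grid$kappa <- 2
  grid$mistakes <- FALSE
  grid$beta <- 1
  rownames(grid) <- NULL
  grid
}

#' Build a [scenario_config()] from one row of the factorial grid
#'
#' @param row A single-row data frame as returned by
#'   [enumerate_configurations()].
#' @param ... Overrides passed on to [scenario_config()] (e.g. scaled-down
#'   `n_groups`, `group_size`, `generations`).
#' @return A `scenario_config`.
#' @export
config_from_row <- function(row, ...) {
  stopifnot(is.data.frame(row), nrow(row) == 1L)
  args <- list(scenario = row$scenario, dims = row$dims,
               life_cycle = row$life_cycle, m_j = row$m_j, init = row$init,
               n_interactions = row$n_interactions, kappa = row$kappa,
               mistakes = row$mistakes, beta = row$beta)
  if (row$scenario == "RI") {
    args$play_mode <- row$play_mode
  } else {
    args$xi <- row$xi
    args$lambda <- row$lambda
  }
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(scenario_config, args)
}

# --- generation engine -----------------------------------------------------

# Ingroup (and, for GC/JOINT, outgroup) game play for one generation.
# Adds payoffs in place and returns the generation's ingroup surplus per
# individual per ingroup interaction.
play_phase <- function(pop, cfg) {
  n <- pop_size(pop)
  msd <- if (cfg$mistakes) cfg$mistake_sd else 0
  pairs <- pair_ingroup(pop)
  res <- play_cohort(pop$ingroup[pairs$first, , drop = FALSE],
                     pop$ingroup[pairs$second, , drop = FALSE],
                     pop$dims, cfg$n_interactions, cfg$kappa, msd)
  pop$payoff[pairs$first] <- pop$payoff[pairs$first] + res$pay_first
  pop$payoff[pairs$second] <- pop$payoff[pairs$second] + res$pay_second
  surplus <- (cfg$kappa - 1) * sum(res$transfer_sum) /
    (n * cfg$n_interactions)

  if (scenario_has_competition(cfg)) {
    # one one-shot outgroup match per individual: a uniform random
    # bijection between the members of paired groups, roles by fair coin
    gp <- pair_groups(pop$territory)
    ia <- unlist(lapply(gp$group_a,
                        function(g) sample(which(pop$group == g))),
                 use.names = FALSE)
    ib <- unlist(lapply(gp$group_b,
                        function(g) sample(which(pop$group == g))),
                 use.names = FALSE)
    swap <- stats::runif(length(ia)) < 0.5
    first <- ifelse(swap, ib, ia)
    second <- ifelse(swap, ia, ib)
    out <- play_cohort(pop$outgroup[first, , drop = FALSE],
                       pop$outgroup[second, , drop = FALSE],
                       pop$dims, 1L, cfg$kappa, msd)
    pop$payoff[first] <- pop$payoff[first] + out$pay_first
    pop$payoff[second] <- pop$payoff[second] + out$pay_second
  }
  list(pop = pop, surplus = surplus)
}

#' Advance a metapopulation by one generation
#'
#' Executes the configured life cycle. Decoupled: game play, migration,
#' group competition (when the scenario includes it), individual selection.
#' Coupled: migration, game play, competition, selection. Territory mixing
#' (`Xi`) happens at the beginning of the generation. Birth (payoff reset
#' and inheritance with mutation) is part of the selection step.
#'
#' @param pop A `metapop` matching the scenario (outgroup strategies
#'   present iff the scenario includes group competition).
#' @param cfg A [scenario_config()].
#' @return The advanced `metapop`, with attributes `"events"` (ordered
#'   event log), `"surplus"` (mean surplus per individual per ingroup
#'   interaction this generation), `"var_share"` (between-group variance
#'   share of the new generation's ingroup strategy parameters) and
#'   `"competition_log"` (data frame, empty for RI).
#' @export
step_generation <- function(pop, cfg) {
  stopifnot(inherits(pop, "metapop"), inherits(cfg, "scenario_config"))
  has_gc <- scenario_has_competition(cfg)
  if (has_gc && is.null(pop$outgroup)) {
    stop("the GC and joint scenarios need a population with outgroup strategies",
         call. = FALSE)
  }
  if (!has_gc && !is.null(pop$outgroup)) {
    stop("the RI scenario uses a population without outgroup strategies",
         call. = FALSE)
  }
  if (pop$n_groups != cfg$n_groups || pop$group_size != cfg$group_size) {
    stop("population shape does not match the configuration", call. = FALSE)
  }
  mut <- mutation_params(cfg$mu, cfg$sigma_mut, cfg$jump_mu)
  # beta is the selection intensity on the per-interaction payoff scale, so
  # its meaning does not change with the number of interactions played
  beta_eff <- cfg$beta / (cfg$n_interactions + has_gc)
  events <- character(0)
  comp_log <- empty_competition_log()

  if (has_gc) pop$territory <- mix_groups(pop$territory, cfg$xi)

  if (cfg$life_cycle == "coupled") {
    pop <- migrate_individuals(pop, cfg$m_j)
    events <- c(events, "migrate")
    ph <- play_phase(pop, cfg)
    pop <- ph$pop
    events <- c(events, "play")
  } else {
    ph <- play_phase(pop, cfg)
    pop <- ph$pop
    events <- c(events, "play")
    pop <- migrate_individuals(pop, cfg$m_j)
    events <- c(events, "migrate")
  }
  if (has_gc) {
    comp <- run_competitions(pop, cfg$lambda, cfg$p_max, mut)
    pop <- comp$pop
    comp_log <- comp$log
    events <- c(events, "compete")
  }
  pop <- reproduce_population(pop, beta_eff, mut)
  events <- c(events, "select")
  pop$generation <- pop$generation + 1L

  attr(pop, "events") <- events
  attr(pop, "surplus") <- ph$surplus
  attr(pop, "var_share") <- var_share_matrix(pop$ingroup, pop$group)
  attr(pop, "competition_log") <- comp_log
  pop
}

empty_competition_log <- function() {
  data.frame(generation = integer(0), territory_a = integer(0),
             territory_b = integer(0), group_a = integer(0),
             group_b = integer(0), R_a = numeric(0), R_b = numeric(0),
             occurred = logical(0), winner = integer(0))
}

#' @rdname step_generation
#' @export
run_generation_RI <- function(pop, cfg) {
  if (cfg$scenario != "RI") stop("`cfg` is not an RI configuration", call. = FALSE)
  step_generation(pop, cfg)
}

#' @rdname step_generation
#' @export
run_generation_GC <- function(pop, cfg) {
  if (cfg$scenario != "GC") stop("`cfg` is not a GC configuration", call. = FALSE)
  step_generation(pop, cfg)
}

#' @rdname step_generation
#' @export
run_generation_JOINT <- function(pop, cfg) {
  if (cfg$scenario != "JOINT") stop("`cfg` is not a joint configuration", call. = FALSE)
  step_generation(pop, cfg)
}

#' Run one replicate simulation
#'
#' Builds the initial metapopulation from the configuration and iterates
#' [step_generation()] for `cfg$generations` generations, recording the
#' per-generation ingroup surplus, the between-group variance share of
#' ingroup strategy parameters, and the competition log.
#'
#' @param cfg A [scenario_config()].
#' @param seed Optional integer seed (set before any randomness).
#' @return A `replicate_result`: list with `surplus` and `var_share`
#'   trajectories (length `generations`), the final `snapshot` (a
#'   `metapop`), the `competition_log`, the `seed` and the `config`.
#' @export
run_simulation <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  pop <- make_population(cfg$n_groups, cfg$group_size, cfg$dims, cfg$init,
                         outgroup = scenario_has_competition(cfg))
  T <- cfg$generations
  surplus <- numeric(T)
  vshare <- numeric(T)
  logs <- vector("list", T)
  for (t in seq_len(T)) {
    pop <- step_generation(pop, cfg)
    surplus[t] <- attr(pop, "surplus")
    vshare[t] <- attr(pop, "var_share")
    cl <- attr(pop, "competition_log")
    if (nrow(cl)) logs[[t]] <- cl[cl$occurred, , drop = FALSE]
  }
  attributes(pop)[c("events", "surplus", "var_share", "competition_log")] <- NULL
  class(pop) <- "metapop"
  kept <- logs[!vapply(logs, is.null, TRUE)]
  comp_log <- if (length(kept)) do.call(rbind, kept) else empty_competition_log()
  rownames(comp_log) <- NULL
  structure(list(
    surplus = surplus,
    var_share = vshare,
    snapshot = pop,
    competition_log = comp_log,
    seed = seed,
    config = cfg
  ), class = "replicate_result")
}

#' @export
print.replicate_result <- function(x, ...) {
  w <- final_window(length(x$surplus), x$config$final_fraction)
  cat(sprintf(
    "<replicate_result %s: T=%d, final-window mean surplus %.4f>\n",
    x$config$scenario, length(x$surplus), mean(x$surplus[w])))
  invisible(x)
}

#' Run seeded replicate simulations
#'
#' Per-replicate seeds are derived deterministically from `base_seed`, so
#' the same base seed reproduces every trajectory bit for bit while
#' replicates remain mutually independent.
#'
#' @param cfg A [scenario_config()].
#' @param n_reps Number of replicates (the reference design uses 50).
#' @param base_seed Integer base seed.
#' @return A `replicate_set`: list of `replicate_result`s with the derived
#'   seeds attached.
#' @export
run_replicates <- function(cfg, n_reps = 50L, base_seed = 1L) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("`n_reps` must be >= 1", call. = FALSE)
  seeds <- derive_seeds(base_seed, n_reps)
  out <- lapply(seq_len(n_reps), function(r) run_simulation(cfg, seeds[r]))
  structure(out, class = "replicate_set", base_seed = base_seed, seeds = seeds)
}

# Distinct 31-bit per-replicate seeds from one base seed.
derive_seeds <- function(base_seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(base_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set: %d replicates of %s, base_seed=%s>\n",
              length(x), x[[1L]]$config$scenario,
              format(attr(x, "base_seed"))))
  invisible(x)
}

# Indices of the final summary window: the last ceil(fraction * T)
# generations.
final_window <- function(T, fraction) {
  k <- max(1L, ceiling(fraction * T))
  seq.int(T - k + 1L, T)
}
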