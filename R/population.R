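# Island-model metapopulation. Individuals are rows of flat strategy
# matrices (columns: initial transfer, response params); group membership,
# natal group and accumulated payoff are parallel vectors. Groups are fixed
# entities occupying territories; the territory vector maps territory index
# to occupying group id.

#' Construct a metapopulation
#'
#' @param n_groups Number of groups (even, so territories can be paired).
#' @param group_size Individuals per group (even, so members can pair off).
#' @param dims Strategy dimensionality (2, 3 or 4).
#' @param init Initial condition: `"all-perfect"`, `"all-selfish"` or
#'   `"random"`.
#' @param outgroup Whether individuals also carry a separate outgroup
#'   strategy (required for the group-competition and joint scenarios).
#' @return An object of class `metapop`: strategy matrices `ingroup` and
#'   (optionally) `outgroup`, vectors `payoff`, `group`, `natal`, the
#'   territory layout, and a generation counter.
#' @export
make_population <- function(n_groups = 40L, group_size = 24L, dims = 3L,
                            init = "random", outgroup = FALSE) {
  n_groups <- as.integer(n_groups)
  group_size <- as.integer(group_size)
  if (n_groups < 2L || n_groups %% 2L != 0L) {
    stop("`n_groups` must be even and >= 2", call. = FALSE)
  }
  if (group_size < 2L || group_size %% 2L != 0L) {
    stop("`group_size` must be even and >= 2", call. = FALSE)
  }
  n <- n_groups * group_size
  grp <- rep(seq_len(n_groups), each = group_size)
  pop <- structure(list(
    ingroup = init_strategy_matrix(n, as.integer(dims), init),
    outgroup = if (outgroup) init_strategy_matrix(n, as.integer(dims), init),
    payoff = numeric(n),
    group = grp,
    natal = grp,
    territory = seq_len(n_groups),
    dims = as.integer(dims),
    n_groups = n_groups,
    group_size = group_size,
    generation = 0L
  ), class = "metapop")
  pop
}

#' @export
print.metapop <- function(x, ...) {
  cat(sprintf(
    "<metapop: %d groups x %d individuals, dims=%d%s, generation %d>\n",
    x$n_groups, x$group_size, x$dims,
    if (is.null(x$outgroup)) "" else ", with outgroup strategies",
    x$generation))
  invisible(x)
}

pop_size <- function(pop) pop$n_groups * pop$group_size

# Slot indices of each group's members, in group order.
group_members <- function(pop) split(seq_len(pop_size(pop)), pop$group)

#' Migrate individuals between groups
#'
#' Exactly `m_j` members per group, chosen uniformly, enter a global pool;
#' the pooled migrants are dealt back uniformly at random so that every
#' group again has `group_size` members and receives exactly `m_j`
#' immigrants (possibly including returns to the natal group). Migrants
#' carry their accumulated payoff with them.
#'
#' @param pop A [make_population()] object.
#' @param m_j Migrants per group per generation, `0 <= m_j <= group_size`.
#' @return The migrated `metapop`.
#' @export
migrate_individuals <- function(pop, m_j) {
  m <- as.integer(m_j)
  if (is.na(m) || m < 0L || m > pop$group_size) {
    stop("`m_j` must lie between 0 and the group size", call. = FALSE)
  }
  if (m == 0L) return(pop)
  n <- pop_size(pop)
  gs <- pop$group_size
  # random order within each group; the first m of each block migrate
  ord <- order(pop$group, stats::runif(n))
  pick <- rep((seq_len(pop$n_groups) - 1L) * gs, each = m) + seq_len(m)
  migrants <- ord[pick]
  dest <- rep(seq_len(pop$n_groups), each = m)
  pop$group[migrants[sample.int(length(migrants))]] <- dest
  pop
}

#' Pair group members for ingroup play
#'
#' Within every group, members pair off uniformly at random into a perfect
#' matching; first/second-mover roles are assigned by fair coin (implicit
#' in the random order).
#'
#' @param pop A `metapop` (every group must have even size).
#' @return A data frame with columns `first`, `second` (slot indices of the
#'   first and second mover) and `group`.
#' @export
pair_ingroup <- function(pop) {
  n <- pop_size(pop)
  if (pop$group_size %% 2L != 0L) {
    stop("groups must have even size to pair off", call. = FALSE)
  }
  ord <- order(pop$group, stats::runif(n))
  first <- ord[seq(1L, n, by = 2L)]
  second <- ord[seq(2L, n, by = 2L)]
  data.frame(first = first, second = second, group = pop$group[first])
}

#' Sample parents proportionally to exponential payoff fitness
#'
#' Fitness is `exp(beta * payoff)`; weights are normalized within the pool
#' (softmax), so `beta = 0` is uniform sampling (pure drift) and larger
#' `beta` concentrates reproduction on high-payoff individuals.
#'
#' @param payoff Numeric vector of accumulated payoffs.
#' @param n_offspring Number of parents to draw (with replacement).
#' @param beta Selection intensity, `>= 0`.
#' @return Integer vector of sampled indices into `payoff`.
#' @export
select_parents <- function(payoff, n_offspring, beta) {
  if (any(!is.finite(payoff))) stop("payoffs must be finite", call. = FALSE)
  if (beta == 0) {
    sample.int(length(payoff), n_offspring, replace = TRUE)
  } else {
    w <- exp(beta * (payoff - max(payoff)))
    sample.int(length(payoff), n_offspring, replace = TRUE, prob = w)
  }
}

#' Within-group reproduction (individual selection)
#'
#' Every group is replaced by `group_size` offspring whose parents are
#' sampled with replacement from the group with probability proportional to
#' `exp(beta * payoff)`. Offspring inherit the parent's strategies subject
#' to mutation, start with zero payoff, and are natal to the group.
#'
#' @param pop A `metapop` with accumulated payoffs.
#' @param beta Selection intensity.
#' @param mut A [mutation_params()] object.
#' @return The next-generation `metapop` (generation counter untouched;
#'   [step_generation()] advances it).
#' @export
reproduce_population <- function(pop, beta, mut = mutation_params()) {
  n <- pop_size(pop)
  parent <- integer(n)
  for (ix in group_members(pop)) {
    parent[ix] <- ix[select_parents(pop$payoff[ix], length(ix), beta)]
  }
  pop$ingroup <- mutate_matrix(pop$ingroup[parent, , drop = FALSE],
                               pop$dims, mut$mu, mut$sigma, mut$jump_mu)
  if (!is.null(pop$outgroup)) {
    pop$outgroup <- mutate_matrix(pop$outgroup[parent, , drop = FALSE],
                                  pop$dims, mut$mu, mut$sigma, mut$jump_mu)
  }
  pop$payoff <- numeric(n)
  pop$natal <- pop$group
  pop
}
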