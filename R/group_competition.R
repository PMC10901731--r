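# Group competition: paired territories, stochastic contest occurrence
# driven by resource asymmetry, a logistic contest success function with
# sensitivity lambda, and replacement of losing groups by descendants of
# the winner. Territory mixing (Xi groups reshuffled per generation)
# controls how often winners later face their own descendant groups
# (group-level cancellation).

#' Reshuffle groups across territories
#'
#' `Xi` territories are chosen uniformly; their occupant groups enter a
#' pool and are redistributed uniformly at random over the vacated
#' territories. `Xi = 0` leaves the layout untouched; `Xi = n_groups`
#' produces a uniformly random permutation (a well-mixed population of
#' groups).
#'
#' @param territory Integer vector mapping territory index to occupying
#'   group id (a bijection).
#' @param xi Number of groups to reshuffle, `0 <= Xi <= length(territory)`.
#' @return The new territory vector (still a bijection).
#' @export
mix_groups <- function(territory, xi) {
  xi <- as.integer(xi)
  if (is.na(xi) || xi < 0L || xi > length(territory)) {
    stop("`xi` must lie between 0 and the number of groups", call. = FALSE)
  }
  if (xi == 0L) return(territory)
  vacated <- sample.int(length(territory), xi)
  territory[vacated] <- territory[vacated][sample.int(xi)]
  territory
}

#' Pair groups on adjacent territories
#'
#' Territories are paired as (1, 2), (3, 4), ...; the occupants of each
#' territory pair meet (and possibly compete) this generation.
#'
#' @param territory Territory-to-group bijection (even length).
#' @return A data frame with columns `territory_a`, `territory_b`,
#'   `group_a`, `group_b`, one row per territory pair.
#' @export
pair_groups <- function(territory) {
  g <- length(territory)
  if (g %% 2L != 0L) stop("the number of territories must be even", call. = FALSE)
  odd <- seq(1L, g, by = 2L)
  data.frame(territory_a = odd, territory_b = odd + 1L,
             group_a = territory[odd], group_b = territory[odd + 1L])
}

#' Total resources held by a group
#'
#' Resources reside in the members: the group's resources are the sum of
#' its current members' accumulated payoffs, so migration moves resources
#' with the migrants.
#'
#' @param pop A `metapop`.
#' @param group_id Group id.
#' @return Non-negative total resources.
#' @export
group_resources <- function(pop, group_id) {
  sum(pop$payoff[pop$group == group_id])
}

#' Probability that a competition occurs
#'
#' Paired groups compete with a probability that is low overall and
#' decreases as the groups become more similar:
#' `p = p_max * |R_i - R_j| / (R_i + R_j)` (0 when both are resourceless).
#'
#' @param R_i,R_j Non-negative group resources.
#' @param p_max Maximum occurrence probability, in (0, 1\].
#' @return The occurrence probability.
#' @export
competition_probability <- function(R_i, R_j, p_max = 0.2) {
  tot <- R_i + R_j
  ifelse(tot > 0, p_max * abs(R_i - R_j) / tot, 0)
}

#' Draw whether a competition occurs
#'
#' @inheritParams competition_probability
#' @return Logical flag.
#' @export
competition_occurs <- function(R_i, R_j, p_max = 0.2) {
  stats::runif(length(R_i)) < competition_probability(R_i, R_j, p_max)
}

#' Contest win probability of the first group
#'
#' Logistic in the normalized resource difference:
#' `1 / (1 + exp(-lambda * (R_i - R_j) / (R_i + R_j)))`. With `lambda = 0`
#' the contest is a fair coin; large `lambda` makes the richer group win
#' near-deterministically. Two resourceless groups flip a fair coin.
#'
#' @param R_i,R_j Non-negative group resources.
#' @param lambda Sensitivity of the outcome to the resource difference.
#' @return Probability that the first group wins.
#' @export
contest_win_prob <- function(R_i, R_j, lambda) {
  tot <- R_i + R_j
  d <- ifelse(tot > 0, (R_i - R_j) / tot, 0)
  1 / (1 + exp(-lambda * d))
}

#' Draw the winner of a contest
#'
#' @inheritParams contest_win_prob
#' @return `1L` if the first group wins, `2L` otherwise.
#' @export
contest_winner <- function(R_i, R_j, lambda) {
  if (stats::runif(1L) < contest_win_prob(R_i, R_j, lambda)) 1L else 2L
}

#' Replace a losing group by descendants of the winner
#'
#' The loser's members are replaced by offspring sampled uniformly with
#' replacement from the winner's members; offspring inherit strategies
#' subject to mutation, start with zero payoff, and are natal to the
#' replaced group (which retains the loser's territory). The winner group
#' is unchanged.
#'
#' @param pop A `metapop`.
#' @param winner,loser Distinct group ids.
#' @param mut A [mutation_params()] object.
#' @return The updated `metapop`.
#' @export
replace_loser <- function(pop, winner, loser, mut = mutation_params()) {
  if (winner == loser) stop("`winner` and `loser` must differ", call. = FALSE)
  slots <- which(pop$group == loser)
  src <- which(pop$group == winner)
  parents <- src[sample.int(length(src), length(slots), replace = TRUE)]
  pop$ingroup[slots, ] <- mutate_matrix(
    pop$ingroup[parents, , drop = FALSE], pop$dims, mut$mu, mut$sigma, mut$jump_mu)
  if (!is.null(pop$outgroup)) {
    pop$outgroup[slots, ] <- mutate_matrix(
      pop$outgroup[parents, , drop = FALSE], pop$dims, mut$mu, mut$sigma, mut$jump_mu)
  }
  pop$payoff[slots] <- 0
  pop$natal[slots] <- as.integer(loser)
  pop
}

# Resolve all territory-pair competitions for the current generation.
# Returns the updated population and a per-pair log.
run_competitions <- function(pop, lambda, p_max, mut) {
  gp <- pair_groups(pop$territory)
  k <- nrow(gp)
  R_a <- vapply(gp$group_a, function(g) group_resources(pop, g), 0)
  R_b <- vapply(gp$group_b, function(g) group_resources(pop, g), 0)
  occurred <- competition_occurs(R_a, R_b, p_max)
  winner <- rep(NA_integer_, k)
  for (i in which(occurred)) {
    w <- contest_winner(R_a[i], R_b[i], lambda)
    if (w == 1L) {
      winner[i] <- gp$group_a[i]
      pop <- replace_loser(pop, gp$group_a[i], gp$group_b[i], mut)
    } else {
      winner[i] <- gp$group_b[i]
      pop <- replace_loser(pop, gp$group_b[i], gp$group_a[i], mut)
    }
  }
  log <- data.frame(generation = pop$generation,
                    territory_a = gp$territory_a, territory_b = gp$territory_b,
                    group_a = gp$group_a, group_b = gp$group_b,
                    R_a = R_a, R_b = R_b, occurred = occurred, winner = winner)
  list(pop = pop, log = log)
}
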