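# Sequential social dilemma: each interaction, the first mover transfers
# part of a unit endowment, the transfer is multiplied by kappa, then the
# second mover responds within the same interaction and her transfer is
# multiplied too. Repeated play alternates through the response functions:
# the second mover answers the first mover's transfer of the current
# interaction; from interaction two onward the first mover answers the
# second mover's transfer of the preceding interaction.

#' Match configuration
#'
#' @param n_interactions Number of interactions in the match (`>= 1`).
#' @param multiplier Transfer multiplier `kappa > 1` (2 doubles transfers,
#'   4 quadruples them).
#' @param mistakes Whether realized transfers deviate stochastically from
#'   the stipulated ones.
#' @param mistake_sd Standard deviation of the mistake distribution (a
#'   normal centred on the stipulated transfer, truncated to \[0, 1\]).
#' @return An object of class `match_config`.
#' @export
match_config <- function(n_interactions = 100L, multiplier = 2,
                         mistakes = FALSE, mistake_sd = 0.05) {
  n <- as.integer(n_interactions)
  if (is.na(n) || n < 1L) stop("`n_interactions` must be >= 1", call. = FALSE)
  if (!is.finite(multiplier) || multiplier <= 1) {
    stop("`multiplier` must be > 1", call. = FALSE)
  }
  if (!is.finite(mistake_sd) || mistake_sd < 0) {
    stop("`mistake_sd` must be >= 0", call. = FALSE)
  }
  structure(list(n_interactions = n, multiplier = multiplier,
                 mistakes = isTRUE(mistakes), mistake_sd = mistake_sd),
            class = "match_config")
}

#' Stage-game payoffs
#'
#' Each player keeps her unit endowment minus her own transfer and receives
#' the partner's transfer multiplied by `kappa`.
#'
#' @param t_first,t_second Transfers of the first and second mover, in
#'   \[0, 1\]; vectorized.
#' @param kappa Transfer multiplier.
#' @return A list with components `first` and `second`, the two payoffs.
#' @examples
#' stage_payoffs(1, 0, 2)  # first mover gets 0, second gets 3
#' @export
stage_payoffs <- function(t_first, t_second, kappa) {
  if (any(t_first < 0 | t_first > 1) || any(t_second < 0 | t_second > 1)) {
    stop("transfers must lie in [0, 1]", call. = FALSE)
  }
  list(first = 1 - t_first + kappa * t_second,
       second = 1 - t_second + kappa * t_first)
}

# Truncated-normal draw on [0, 1] via the inverse CDF (vectorized).
rnorm_trunc01 <- function(mean, sd) {
  if (sd == 0) return(mean)
  lo <- stats::pnorm(0, mean, sd)
  hi <- stats::pnorm(1, mean, sd)
  x <- stats::qnorm(stats::runif(length(mean), lo, hi), mean, sd)
  pmin(1, pmax(0, x))
}

#' Apply a transfer mistake
#'
#' Realized transfers are distributed around the stipulated transfer: a
#' normal draw with mean `stipulated` and standard deviation `sigma_e`,
#' truncated to \[0, 1\]. With `sigma_e = 0` the stipulated transfer is
#' returned unchanged.
#'
#' @param stipulated Stipulated transfer(s) in \[0, 1\]; vectorized.
#' @param sigma_e Mistake standard deviation, `>= 0`.
#' @return Realized transfer(s) in \[0, 1\].
#' @export
apply_mistake <- function(stipulated, sigma_e) {
  if (!is.finite(sigma_e) || sigma_e < 0) {
    stop("`sigma_e` must be >= 0", call. = FALSE)
  }
  if (any(stipulated < 0 | stipulated > 1)) {
    stop("`stipulated` must lie in [0, 1]", call. = FALSE)
  }
  rnorm_trunc01(stipulated, sigma_e)
}

# Vectorized match engine. `first` and `second` are strategy matrices
# (columns: initial transfer, response params) with one row per pair.
# Returns accumulated payoffs, the per-pair transfer sums, and the final
# interaction's transfers.
play_cohort <- function(first, second, dims, n, kappa, mistake_sd = 0) {
  P1 <- first[, -1L, drop = FALSE]
  P2 <- second[, -1L, drop = FALSE]
  npair <- nrow(first)
  t1 <- first[, 1L]
  if (mistake_sd > 0) t1 <- rnorm_trunc01(t1, mistake_sd)
  pay1 <- numeric(npair)
  pay2 <- numeric(npair)
  tsum <- numeric(npair)
  for (k in seq_len(n)) {
    if (k > 1L) {
      t1 <- resp_eval_matrix(dims, P1, t2)
      if (mistake_sd > 0) t1 <- rnorm_trunc01(t1, mistake_sd)
    }
    t2 <- resp_eval_matrix(dims, P2, t1)
    if (mistake_sd > 0) t2 <- rnorm_trunc01(t2, mistake_sd)
    pay1 <- pay1 + 1 - t1 + kappa * t2
    pay2 <- pay2 + 1 - t2 + kappa * t1
    tsum <- tsum + t1 + t2
  }
  list(pay_first = pay1, pay_second = pay2, transfer_sum = tsum,
       last_t_first = t1, last_t_second = t2)
}

#' Play a match between two strategies
#'
#' Interaction 1: the first mover plays her initial transfer
#' (mistake-perturbed when mistakes are enabled) and the second mover
#' responds to it. From interaction 2 onward the first mover responds to
#' the second mover's transfer of the preceding interaction, then the
#' second mover responds within the interaction. Roles are fixed for the
#' whole match.
#'
#' @param s_first,s_second [strategy()] objects for the first and second
#'   mover.
#' @param cfg A [match_config()].
#' @return A `match_record`: a data frame with one row per interaction and
#'   columns `interaction`, `t_first`, `t_second`, `payoff_first`,
#'   `payoff_second`, with the multiplier stored in attribute `"kappa"`.
#' @examples
#' perfect <- strategy(0.6, response_curve(3, c(0, 1)))
#' rec <- play_match(perfect, perfect, match_config(5))
#' all(rec$t_first == 0.6)
#' @export
play_match <- function(s_first, s_second, cfg = match_config()) {
  stopifnot(inherits(s_first, "strategy"), inherits(s_second, "strategy"),
            inherits(cfg, "match_config"))
  dims <- s_first$response$dims
  if (dims != s_second$response$dims) {
    stop("both strategies must have the same dimensionality", call. = FALSE)
  }
  n <- cfg$n_interactions
  kappa <- cfg$multiplier
  msd <- if (cfg$mistakes) cfg$mistake_sd else 0
  P1 <- matrix(s_first$response$params, nrow = 1L)
  P2 <- matrix(s_second$response$params, nrow = 1L)
  t1v <- t2v <- p1v <- p2v <- numeric(n)
  t1 <- s_first$initial_transfer
  if (msd > 0) t1 <- rnorm_trunc01(t1, msd)
  for (k in seq_len(n)) {
    if (k > 1L) {
      t1 <- resp_eval_matrix(dims, P1, t2v[k - 1L])
      if (msd > 0) t1 <- rnorm_trunc01(t1, msd)
    }
    t2 <- resp_eval_matrix(dims, P2, t1)
    if (msd > 0) t2 <- rnorm_trunc01(t2, msd)
    t1v[k] <- t1
    t2v[k] <- t2
    p1v[k] <- 1 - t1 + kappa * t2
    p2v[k] <- 1 - t2 + kappa * t1
  }
  rec <- data.frame(interaction = seq_len(n), t_first = t1v, t_second = t2v,
                    payoff_first = p1v, payoff_second = p2v)
  attr(rec, "kappa") <- kappa
  class(rec) <- c("match_record", "data.frame")
  rec
}

#' Surplus of a match, per individual per interaction
#'
#' Surplus is the payoff created above the endowments:
#' `(kappa - 1) * sum(transfers) / (2 * n)`, which lies in
#' \[0, kappa - 1\].
#'
#' @param record A `match_record` from [play_match()].
#' @param kappa Transfer multiplier; defaults to the one stored in the
#'   record.
#' @return Mean surplus per individual per interaction.
#' @export
match_surplus <- function(record, kappa = attr(record, "kappa")) {
  if (is.null(record) || nrow(record) == 0L) {
    stop("`record` must contain at least one interaction", call. = FALSE)
  }
  n <- nrow(record)
  (kappa - 1) * sum(record$t_first + record$t_second) / (2 * n)
}
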