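# Summary statistics: final-window surplus, bootstrap confidence
# intervals, the super-additive decomposition, the between-group variance
# partition, discrete strategy-type frequencies, and the analytic
# fixed-point oracle for pairs of linear response curves.

#' Mean surplus over the final generations
#'
#' @param results A `replicate_set` (or list of `replicate_result`s).
#' @param final_fraction Fraction of final generations to average over
#'   (default: the configs' own `final_fraction`, falling back to 0.1).
#' @return List with `per_replicate` (one mean per replicate) and `mean`
#'   (the grand mean across replicates).
#' @export
mean_surplus <- function(results, final_fraction = NULL) {
  if (inherits(results, "replicate_result")) results <- list(results)
  if (length(results) == 0L) {
    stop("`results` must contain at least one replicate", call. = FALSE)
  }
  if (is.null(final_fraction)) {
    final_fraction <- results[[1L]]$config$final_fraction
    if (is.null(final_fraction)) final_fraction <- 0.1
  }
  if (final_fraction <= 0 || final_fraction > 1) {
    stop("`final_fraction` must lie in (0, 1]", call. = FALSE)
  }
  per <- vapply(results, function(r) {
    mean(r$surplus[final_window(length(r$surplus), final_fraction)])
  }, 0)
  list(per_replicate = per, mean = mean(per))
}

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values Numeric vector (at least two values, e.g. per-replicate
#'   surplus means across independently simulated populations).
#' @param B Number of bootstrap resamples (`>= 1000`).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(values, B = 1000L, level = 0.95) {
  n <- length(values)
  if (n < 2L) stop("`values` must contain at least two values", call. = FALSE)
  if (B < 1000L) stop("`B` must be >= 1000", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)", call. = FALSE)
  means <- colMeans(matrix(sample(values, n * B, replace = TRUE), n, B))
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lo = q[1L], hi = q[2L])
}

#' Decompose joint-scenario surplus into component effects
#'
#' Relative to a common baseline (by convention the matched one-shot RI
#' scenario: no repetition, no competition), the repeated-interactions
#' effect is `S_RI - S_base`, the group-competition effect is
#' `S_GC - S_base`, and the super-additive effect is whatever of
#' `S_joint - S_base` the two main effects do not account for. The three
#' components sum to `S_joint - S_base` exactly.
#'
#' @param S_joint,S_RI,S_GC,S_base Mean surplus of the joint, repeated
#'   interactions, group competition and baseline scenarios at matched
#'   parameter cells, on a common scale.
#' @return Named vector `c(ri_effect, gc_effect, super_effect)`.
#' @export
superadditive_decomposition <- function(S_joint, S_RI, S_GC, S_base) {
  ri <- S_RI - S_base
  gc <- S_GC - S_base
  c(ri_effect = ri, gc_effect = gc,
    super_effect = S_joint - S_base - ri - gc)
}

# Between-group share of total variance of each column of M under the
# grouping `group`; shares averaged over columns. Columns without any
# variation are excluded; an all-degenerate matrix gives 0 by convention.
var_share_matrix <- function(M, group, eps = 1e-12) {
  cnt <- tabulate(group)
  means <- rowsum(M, group, reorder = TRUE) / cnt
  grand <- colMeans(M)
  ssb <- colSums(cnt * sweep(means, 2L, grand)^2)
  sst <- colSums(sweep(M, 2L, grand)^2)
  ok <- sst > eps
  if (!any(ok)) return(0)
  mean(ssb[ok] / sst[ok])
}

#' Between-group share of strategy variance
#'
#' For each ingroup strategy parameter (initial transfer and response
#' parameters), the between-group sum of squares is divided by the total
#' sum of squares; the shares are averaged across parameters. Parameters
#' with no variation in the population are left out of the average, and a
#' fully monomorphic population returns 0 by convention. This is the scope
#' for group selection: how much of the population's strategic variation
#' lies between rather than within groups.
#'
#' @param pop A `metapop` snapshot with at least two groups of at least two
#'   members.
#' @return A share in \[0, 1\].
#' @export
between_group_variance_share <- function(pop) {
  stopifnot(inherits(pop, "metapop"))
  if (pop$n_groups < 2L || pop$group_size < 2L) {
    stop("need at least two groups with at least two members", call. = FALSE)
  }
  var_share_matrix(pop$ingroup, pop$group)
}

#' Discrete strategy-type frequencies and initial-transfer bins
#'
#' Classifies every individual's response curve (see
#' [classify_response()]) and tabulates relative frequencies over the
#' seven types, plus relative frequencies of initial transfers on a fixed
#' 10-bin grid over \[0, 1\].
#'
#' @param pop A `metapop` snapshot.
#' @param role `"ingroup"` or `"outgroup"` strategies.
#' @param tol,quasi_threshold Classification parameters, see
#'   [classify_response()].
#' @return List with `types` (named frequencies summing to 1) and
#'   `initial_transfer_bins` (10 named frequencies summing to 1).
#' @export
strategy_type_frequencies <- function(pop, role = c("ingroup", "outgroup"),
                                      tol = 1e-3, quasi_threshold = 0.9) {
  stopifnot(inherits(pop, "metapop"))
  role <- match.arg(role)
  M <- pop[[role]]
  if (is.null(M)) {
    stop(sprintf("this population carries no %s strategies", role),
         call. = FALSE)
  }
  lab <- classify_matrix(M[, -1L, drop = FALSE], pop$dims, tol,
                         quasi_threshold)
  lv <- strategy_type_labels()
  types <- table(factor(lab, levels = lv)) / length(lab)
  breaks <- seq(0, 1, by = 0.1)
  bins <- table(cut(M[, 1L], breaks = breaks, include.lowest = TRUE)) /
    nrow(M)
  list(types = c(types), initial_transfer_bins = c(bins))
}

#' Long-run transfers of two linear response curves
#'
#' For a first mover with linear response `f(y) = a1 + (b1 - a1) y` and a
#' second mover with `g(x) = a2 + (b2 - a2) x`, repeated play iterates the
#' composition `f(g(.))` on the first mover's transfer. When the slope
#' product `s = (b1 - a1)(b2 - a2)` satisfies `|s| < 1` the composition is
#' a contraction with the unique fixed point
#' `x* = (a1 + (b1 - a1) a2) / (1 - s)`, and the second mover's limit
#' transfer is `g(x*)`. With `|s| >= 1` the long-run transfers depend on
#' the initial condition and the pair is flagged non-contractive.
#'
#' @param curve_f First mover's curve: a `dims = 3` [response_curve()] or a
#'   numeric `(a, b)` pair.
#' @param curve_g Second mover's curve, likewise.
#' @return List with `contractive` (flag), `slope_product`, and — when
#'   contractive — `limits`, the pair of long-run transfers
#'   `(first, second)`.
#' @examples
#' fixed_point_linear(c(0.4, 0.6), c(0.4, 0.6))$limits  # c(0.5, 0.5)
#' @export
fixed_point_linear <- function(curve_f, curve_g) {
  as_ab <- function(cv, nm) {
    if (inherits(cv, "response_curve")) {
      if (cv$dims != 3L) {
        stop(sprintf("`%s` must be a linear (dims = 3) curve", nm),
             call. = FALSE)
      }
      cv$params
    } else {
      cv <- as.numeric(cv)
      if (length(cv) != 2L || any(cv < 0) || any(cv > 1)) {
        stop(sprintf("`%s` must be an (a, b) pair in [0, 1]^2", nm),
             call. = FALSE)
      }
      cv
    }
  }
  f <- as_ab(curve_f, "curve_f")
  g <- as_ab(curve_g, "curve_g")
  s <- (f[2L] - f[1L]) * (g[2L] - g[1L])
  if (abs(s) >= 1) {
    return(list(contractive = FALSE, slope_product = s, limits = NULL))
  }
  x <- (f[1L] + (f[2L] - f[1L]) * g[1L]) / (1 - s)
  y <- g[1L] + (g[2L] - g[1L]) * x
  list(contractive = TRUE, slope_product = s,
       limits = c(first = x, second = y))
}

#' Plot surplus trajectories of a replicate set
#'
#' @param x A `replicate_set`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the matrix of trajectories (generations x replicates).
#' @export
plot.replicate_set <- function(x, ...) {
  traj <- vapply(x, function(r) r$surplus, numeric(length(x[[1L]]$surplus)))
  graphics::matplot(traj, type = "l", lty = 1,
                    col = grDevices::grey(seq(0.1, 0.6, length.out = ncol(traj))),
                    xlab = "generation",
                    ylab = "surplus per individual per ingroup interaction",
                    ...)
  invisible(traj)
}
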