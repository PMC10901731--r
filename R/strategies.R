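# Strategy space: initial transfer + response curve in 2/3/4 dimensions.
#
# A strategy's dimensionality counts the initial transfer plus the response
# parameters. The parameterizations are:
#   dims = 2: one offset c in [-1, 1];  f(x) = clip(c + (1 - c) x) for c >= 0,
#             f(x) = (1 + c) x for c < 0. c = 0 is perfect reciprocity, c > 0
#             escalates, c < 0 de-escalates; ambiguity is structurally
#             impossible in this family.
#   dims = 3: left/right intercepts (a, b) in [0, 1]^2; f(x) = a + (b - a) x.
#   dims = 4: quadratic Lagrange interpolation through (0, a), (1/2, v),
#             (1, b), clipped to [0, 1].

#' Admissible ranges of response-curve parameters
#'
#' @param dims Strategy dimensionality, one of 2, 3 or 4.
#' @return A two-column matrix (lower, upper), one row per response parameter.
#' @keywords internal
response_param_range <- function(dims) {
  dims <- as.integer(dims)
  if (dims == 2L) {
    matrix(c(-1, 1), nrow = 1L, dimnames = list("c", c("lower", "upper")))
  } else if (dims == 3L) {
    matrix(c(0, 0, 1, 1), nrow = 2L,
           dimnames = list(c("a", "b"), c("lower", "upper")))
  } else if (dims == 4L) {
    matrix(c(0, 0, 0, 1, 1, 1), nrow = 3L,
           dimnames = list(c("a", "v", "b"), c("lower", "upper")))
  } else {
    stop("`dims` must be 2, 3 or 4", call. = FALSE)
  }
}

#' Construct a response curve
#'
#' A response curve maps the partner's most recent transfer in \[0, 1\] to
#' the focal individual's next transfer in \[0, 1\].
#'
#' @param dims Strategy dimensionality (2, 3 or 4); the curve itself has
#'   `dims - 1` parameters.
#' @param params Numeric vector of response parameters. For `dims = 2` a
#'   single offset `c` in \[-1, 1\]; for `dims = 3` the left and right
#'   intercepts `(a, b)`, each in \[0, 1\]; for `dims = 4` the values
#'   `(a, v, b)` of the curve at 0, 1/2 and 1, each in \[0, 1\].
#' @return An object of class `response_curve`.
#' @examples
#' evaluate_response(response_curve(3, c(0.4, 0.6)), 0.5)
#' @export
response_curve <- function(dims, params) {
  dims <- as.integer(dims)
  rng <- response_param_range(dims)
  params <- as.numeric(params)
  if (length(params) != nrow(rng)) {
    stop(sprintf("a %d-dimensional strategy needs %d response parameter(s)",
                 dims, nrow(rng)), call. = FALSE)
  }
  if (any(!is.finite(params)) ||
      any(params < rng[, 1] - 1e-12) || any(params > rng[, 2] + 1e-12)) {
    stop("response parameters outside their admissible range", call. = FALSE)
  }
  structure(list(dims = dims, params = params), class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf("<response_curve dims=%d: %s>\n", x$dims,
              paste(sprintf("%s=%.4g", rownames(response_param_range(x$dims)),
                            x$params), collapse = ", ")))
  invisible(x)
}

# Vectorized response evaluation. `P` is a parameter matrix whose rows are
# curves (or a single row recycled against `x`); `x` is a vector of partner
# transfers. Returns transfers clipped to [0, 1].
resp_eval_matrix <- function(dims, P, x) {
  if (dims == 2L) {
    cc <- P[, 1L]
    pos <- cc >= 0
    y <- pos * (cc + (1 - cc) * x) + (!pos) * ((1 + cc) * x)
  } else if (dims == 3L) {
    y <- P[, 1L] + (P[, 2L] - P[, 1L]) * x
  } else {
    a <- P[, 1L]; v <- P[, 2L]; b <- P[, 3L]
    y <- 2 * a * (x - 0.5) * (x - 1) - 4 * v * x * (x - 1) + 2 * b * x * (x - 0.5)
  }
  pmin(1, pmax(0, y))
}

#' Evaluate a response curve
#'
#' @param curve A [response_curve()].
#' @param partner_transfer Partner's most recent transfer(s), in \[0, 1\];
#'   vectorized.
#' @return The focal individual's transfer(s), in \[0, 1\].
#' @export
evaluate_response <- function(curve, partner_transfer) {
  stopifnot(inherits(curve, "response_curve"))
  x <- as.numeric(partner_transfer)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`partner_transfer` must lie in [0, 1]", call. = FALSE)
  }
  resp_eval_matrix(curve$dims, matrix(curve$params, nrow = 1L), x)
}

#' Construct a strategy
#'
#' A strategy is the heritable unit: an initial transfer (used when first
#' mover in the first interaction) plus a response curve used for all later
#' transfers.
#'
#' @param initial_transfer Fraction of the endowment transferred in the
#'   first interaction when first mover, in \[0, 1\].
#' @param response A [response_curve()].
#' @return An object of class `strategy`.
#' @export
strategy <- function(initial_transfer, response) {
  stopifnot(inherits(response, "response_curve"))
  i <- as.numeric(initial_transfer)
  if (length(i) != 1L || !is.finite(i) || i < 0 || i > 1) {
    stop("`initial_transfer` must be a single value in [0, 1]", call. = FALSE)
  }
  structure(list(initial_transfer = i, response = response), class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("<strategy dims=%d: i=%.4g, params=(%s)>\n",
              x$response$dims, x$initial_transfer,
              paste(sprintf("%.4g", x$response$params), collapse = ", ")))
  invisible(x)
}

# A strategy as a numeric row (i, p1, ...), the layout used by the engine.
strategy_row <- function(s) c(s$initial_transfer, s$response$params)

row_to_strategy <- function(row, dims) {
  strategy(row[1L], response_curve(dims, row[-1L]))
}

#' Mutation parameters
#'
#' Each strategy parameter mutates independently. The kernel has a local
#' and a large-effect component, both clipped to the parameter's
#' admissible range: with probability `mu` the parameter receives a
#' Gaussian perturbation of standard deviation `sigma` (on the
#' parameter's own scale), and with probability `jump_mu` it is redrawn
#' uniformly over its range. Occasional mutations of large effect keep
#' distant strategy classes reachable (an escalator can arise in an
#' uncooperative population in one step, and ambiguous mutants of
#' cooperative escalators arise at an appreciable rate); purely local
#' steps of scale `sigma` would have to cross long, selectively flat or
#' deleterious paths for the same transitions. Setting `mu = 0` or
#' `sigma = 0` disables mutation entirely.
#'
#' @param mu Per-parameter probability of a local Gaussian perturbation,
#'   in \[0, 1\].
#' @param sigma Perturbation standard deviation, `>= 0`.
#' @param jump_mu Per-parameter probability of a uniform redraw, in
#'   \[0, 1\].
#' @return An object of class `mutation_params`.
#' @export
mutation_params <- function(mu = 0.01, sigma = 0.05, jump_mu = 0.005) {
  if (!is.finite(mu) || mu < 0 || mu > 1) {
    stop("`mu` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (!is.finite(jump_mu) || jump_mu < 0 || jump_mu > 1) {
    stop("`jump_mu` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(mu = mu, sigma = sigma, jump_mu = jump_mu),
            class = "mutation_params")
}

# Clip a strategy matrix (columns: i, response params) to admissible ranges.
clip_strategy_matrix <- function(M, dims) {
  M[M > 1] <- 1
  lo <- c(0, response_param_range(dims)[, 1L])
  for (j in seq_len(ncol(M))) {
    bad <- M[, j] < lo[j]
    if (any(bad)) M[bad, j] <- lo[j]
  }
  M
}

# Vectorized mutation of a strategy matrix: Gaussian perturbations at rate
# mu, uniform redraws at rate jump_mu. mu = 0 or sigma = 0 disables both.
mutate_matrix <- function(M, dims, mu, sigma, jump_mu = 0) {
  if (mu <= 0 || sigma <= 0) return(M)
  hit <- which(stats::runif(length(M)) < mu)
  if (length(hit)) {
    M[hit] <- M[hit] + stats::rnorm(length(hit), 0, sigma)
    M <- clip_strategy_matrix(M, dims)
  }
  if (jump_mu > 0) {
    hit <- which(stats::runif(length(M)) < jump_mu)
    if (length(hit)) {
      lo <- c(0, response_param_range(dims)[, 1L])
      col <- ((hit - 1L) %/% nrow(M)) + 1L
      M[hit] <- stats::runif(length(hit), lo[col], 1)
    }
  }
  M
}

#' Mutate a strategy
#'
#' @param s A [strategy()].
#' @param params A [mutation_params()] object.
#' @return A new, admissible [strategy()].
#' @export
mutate_strategy <- function(s, params = mutation_params()) {
  stopifnot(inherits(s, "strategy"), inherits(params, "mutation_params"))
  dims <- s$response$dims
  row <- mutate_matrix(matrix(strategy_row(s), nrow = 1L), dims,
                       params$mu, params$sigma, params$jump_mu)
  row_to_strategy(as.numeric(row), dims)
}

# Strategy matrix for n individuals under a named initial condition.
init_strategy_matrix <- function(n, dims, condition) {
  npar <- dims - 1L
  if (condition == "all-perfect") {
    p <- switch(as.character(dims), "2" = 0, "3" = c(0, 1), "4" = c(0, 0.5, 1))
    cbind(1, matrix(p, n, npar, byrow = TRUE))
  } else if (condition == "all-selfish") {
    p <- switch(as.character(dims), "2" = -1, "3" = c(0, 0), "4" = c(0, 0, 0))
    cbind(0, matrix(p, n, npar, byrow = TRUE))
  } else if (condition == "random") {
    rng <- response_param_range(dims)
    P <- vapply(seq_len(npar),
                function(j) stats::runif(n, rng[j, 1L], rng[j, 2L]),
                numeric(n))
    cbind(stats::runif(n), matrix(P, n, npar))
  } else {
    stop(sprintf("unknown initial condition '%s'", condition), call. = FALSE)
  }
}

#' Draw an initial strategy
#'
#' `"all-perfect"` gives a perfect reciprocator that initially transfers the
#' full endowment; `"all-selfish"` gives an unconditionally selfish
#' individual (zero initial transfer, response identically zero);
#' `"random"` draws every parameter uniformly over its range.
#'
#' @param condition One of `"all-perfect"`, `"all-selfish"`, `"random"`.
#' @param dims Strategy dimensionality (2, 3 or 4).
#' @return A [strategy()].
#' @export
initial_strategy <- function(condition, dims) {
  row <- init_strategy_matrix(1L, as.integer(dims), condition)
  row_to_strategy(as.numeric(row), as.integer(dims))
}

#' Discrete strategy-type labels
#'
#' @return Character vector of the seven recognized response-curve types.
#' @export
strategy_type_labels <- function() {
  c("perfect", "escalating", "de-escalating", "ambiguous",
    "quasi-escalating", "quasi-de-escalating", "other")
}

# Grid used for curve-shape classification.
.classify_grid <- seq(0, 1, length.out = 201)

# Long-run transfer of a symmetric pair both playing the same curve:
# iterate x <- f(x). For linear (dims = 3) ambiguous curves the closed form
# a / (1 - b + a) applies (slope b - a < 1 whenever the curve is ambiguous).
symmetric_fixed_point <- function(dims, params, n_iter = 2000L) {
  if (dims == 3L) {
    a <- params[1L]; b <- params[2L]
    s <- b - a
    if (abs(s) < 1) return(a / (1 - s))
  }
  P <- matrix(params, nrow = 1L)
  x <- 0.5
  for (k in seq_len(n_iter)) x <- resp_eval_matrix(dims, P, x)
  x
}

# Vectorized classification of a parameter matrix of curves.
# Returns a character vector of labels.
classify_matrix <- function(P, dims, tol = 1e-3, quasi_threshold = 0.9) {
  n <- nrow(P)
  if (n == 0L) return(character(0))
  grid <- .classify_grid
  # F: n x length(grid) matrix of responses
  F <- vapply(grid, function(x) resp_eval_matrix(dims, P, rep(x, n)), numeric(n))
  if (n == 1L) F <- matrix(F, nrow = 1L)
  D <- sweep(F, 2L, grid)
  above <- D > tol
  below <- D < -tol
  any_above <- rowSums(above) > 0L
  any_below <- rowSums(below) > 0L
  # non-negative slope within tolerance, on the grid
  slope_ok <- apply(F, 1L, function(f) min(diff(f)) >= -tol)
  # escalation at some x strictly left of a de-escalated x
  first_above <- apply(above, 1L, function(z) if (any(z)) which(z)[1L] else NA_integer_)
  last_below <- apply(below, 1L, function(z) if (any(z)) max(which(z)) else NA_integer_)

  lab <- rep("other", n)
  perfect <- !any_above & !any_below
  esc <- !perfect & any_above & !any_below
  de <- !perfect & any_below & !any_above
  amb <- !perfect & any_above & any_below & slope_ok &
    !is.na(first_above) & !is.na(last_below) & first_above < last_below
  lab[perfect] <- "perfect"
  lab[esc] <- "escalating"
  lab[de] <- "de-escalating"
  if (any(amb)) {
    idx <- which(amb)
    fp <- vapply(idx, function(i) symmetric_fixed_point(dims, P[i, ]), 0)
    lab[idx] <- ifelse(fp >= quasi_threshold, "quasi-escalating",
                       ifelse(fp <= 1 - quasi_threshold,
                              "quasi-de-escalating", "ambiguous"))
  }
  lab
}

#' Classify a response curve into a discrete reciprocity type
#'
#' Curves are compared against the identity (perfect reciprocity) on a fine
#' grid. `perfect` means the curve tracks the identity within `tol`;
#' `escalating` (`de-escalating`) means it never falls below (rises above)
#' the identity by more than `tol` and exceeds it somewhere; `ambiguous`
#' means a non-negatively sloped curve that escalates low transfers and
#' de-escalates high ones. Ambiguous curves whose symmetric long-run
#' transfer is at least `quasi_threshold` (at most `1 - quasi_threshold`)
#' are the extreme forms `quasi-escalating` (`quasi-de-escalating`).
#' Everything else, e.g. negatively sloped curves, is `other`.
#'
#' @param curve A [response_curve()].
#' @param tol Positive comparison tolerance (default `1e-3`).
#' @param quasi_threshold Threshold in (0.5, 1) for the extreme ambiguous
#'   forms (default 0.9).
#' @return A single label from [strategy_type_labels()].
#' @export
classify_response <- function(curve, tol = 1e-3, quasi_threshold = 0.9) {
  stopifnot(inherits(curve, "response_curve"))
  if (!is.finite(tol) || tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  if (quasi_threshold <= 0.5 || quasi_threshold >= 1) {
    stop("`quasi_threshold` must lie in (0.5, 1)", call. = FALSE)
  }
  classify_matrix(matrix(curve$params, nrow = 1L), curve$dims,
                  tol, quasi_threshold)
}
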