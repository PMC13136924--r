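#' Discretized distribution of the covariate event time
#'
#' Under the discretized proportional-hazards model for T1, the conditional
#' point mass at support point `t1_l` given covariates `z1` is
#' \deqn{P(T_1 = t_{1\ell} \mid z_1) =
#'   e^{-e^{\gamma^\top z_1}\sum_{l' \le \ell-1}\lambda_{1l'}}
#'   \left(1 - e^{-e^{\gamma^\top z_1}\lambda_{1\ell}}\right),}
#' and the residual tail mass beyond the last support point is
#' \eqn{e^{-e^{\gamma^\top z_1}\sum_l \lambda_{1l}}}. Masses and tail sum
#' to one by construction.
#'
#' @param gamma coefficient vector for z1 (length 0 allowed).
#' @param lambda1 nonnegative baseline hazard increments.
#' @param z1 covariate vector (same length as `gamma`).
#' @param grid a `dic_grid` (only `t1_points` is used) or a numeric vector
#'   of support points; must match `length(lambda1)`.
#' @return list with `pmf` (length m1) and `tail` (scalar).
#' @examples
#' t1_pmf(numeric(0), log(2), numeric(0), 1)  # P = 0.5, tail = 0.5
#' @export
t1_pmf <- function(gamma, lambda1, z1, grid) {
  t1 <- if (inherits(grid, "dic_grid")) grid$t1_points else as.numeric(grid)
  if (length(lambda1) != length(t1))
    stop("lambda1 length does not match the T1 grid")
  if (any(lambda1 < 0)) stop("lambda1 must be nonnegative")
  if (length(gamma) != length(z1)) stop("gamma and z1 lengths differ")
  mu <- exp(sum(gamma * z1))
  cum_prev <- c(0, cumsum(lambda1))[seq_along(lambda1)]
  pmf <- exp(-mu * cum_prev) * (-expm1(-mu * lambda1))
  list(pmf = pmf, tail = exp(-mu * sum(lambda1)))
}

#' Observed log-likelihood of a doubly interval-censored dataset
#'
#' Evaluates the discretized observed-data log-likelihood at a parameter
#' state: for each episode, the sum over T1 support points in its bracket of
#' the T1 point mass times the probability that T2 falls in its bracket
#' given that T1 value (a difference of two survival terms; a single
#' survival term for right-censored T2; 1 when the rebound bracket is
#' unobserved). For clustered data the same expression is the independence
#' composite log-likelihood: the per-cluster entries are the sums of their
#' episodes' contributions under working independence.
#'
#' An episode whose contribution underflows to zero yields `-Inf` (never an
#' error), with the offending episodes listed in the `bad_episodes`
#' attribute; this keeps the function usable inside line searches.
#'
#' @param theta a [dic_theta] (or bare numeric vector in internal layout).
#' @param data a [dic_data] object.
#' @param grid optionally a precomputed [build_support_grid()] result.
#' @return list of class `dic_loglik` with `total`, `per_episode`,
#'   `per_cluster`.
#' @export
dic_loglik <- function(theta, data, grid = NULL) {
  stopifnot(inherits(data, "dic_data"))
  if (is.null(grid)) grid <- build_support_grid(data)
  pk <- pack_dic(data, grid)
  v <- if (inherits(theta, "dic_theta")) theta_to_vec(theta) else as.numeric(theta)
  d_expect <- 1 + pk$p2 + pk$p1 + pk$m1 + pk$m2
  if (length(v) != d_expect)
    stop("theta has length ", length(v), "; expected ", d_expect)
  per <- cpp_loglik(v, pk)
  per_cluster <- tapply(per, data$episodes$cluster, sum)
  out <- list(total = sum(per), per_episode = per,
              per_cluster = as.numeric(per_cluster))
  if (any(!is.finite(per)))
    attr(out, "bad_episodes") <- which(!is.finite(per))
  class(out) <- "dic_loglik"
  out
}

#' @export
print.dic_loglik <- function(x, ...) {
  cat("<dic_loglik> total =", format(x$total, digits = 8),
      "over", length(x$per_episode), "episodes\n")
  bad <- attr(x, "bad_episodes")
  if (!is.null(bad))
    cat("  non-finite contributions from episode(s):",
        paste(utils::head(bad, 10), collapse = ", "), "\n")
  invisible(x)
}

#' E-step posterior quantities of the Poisson-augmented EM
#'
#' For each episode, the posterior probabilities `p` that T1 equals each
#' supported grid point (including the residual tail class for
#' right-censored T1), and the conditional expectations `W` of the latent
#' Poisson counts at the T2 grid points within the observed rebound bracket.
#' Exposed mainly for testing and diagnostics; [dic_fit()] runs the same
#' computation internally.
#'
#' @inheritParams dic_loglik
#' @return list with `p` (list of per-episode probability vectors), `W`
#'   (list of m2-by-classes matrices), `support` (list of support-point
#'   indices; `m1 + 1` denotes the tail class), `loglik` per episode.
#' @export
dic_estep <- function(theta, data, grid = NULL) {
  stopifnot(inherits(data, "dic_data"))
  if (is.null(grid)) grid <- build_support_grid(data)
  pk <- pack_dic(data, grid)
  v <- if (inherits(theta, "dic_theta")) theta_to_vec(theta) else as.numeric(theta)
  es <- cpp_estep(v, pk, want_w = TRUE)
  n <- pk$n
  p <- vector("list", n); sup <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- (pk$sup_ptr[i] + 1):pk$sup_ptr[i + 1]
    p[[i]] <- es$phat[idx]
    sup[[i]] <- pk$sup_idx[idx] + 1L
  }
  list(p = p, W = es$W, support = sup, loglik = es$loglik)
}
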