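#' Central finite-difference Hessian of an arbitrary function
#'
#' Differentiation harness used for cross-checks: central second differences
#' of `fn` around `x`. For the model log-likelihood itself,
#' [observed_information()] uses the much faster route of differencing the
#' analytic score.
#'
#' @param fn function of a numeric vector returning a scalar.
#' @param x evaluation point.
#' @param step per-coordinate step; default `1e-5 * max(1, |x|)`.
#' @return symmetric numeric matrix.
#' @export
fd_hessian <- function(fn, x, step = NULL) {
  d <- length(x)
  if (is.null(step)) step <- 1e-5 * pmax(1, abs(x))
  step <- rep_len(step, d)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  fp <- fm <- numeric(d)
  for (i in seq_len(d)) {
    e <- rep(0, d); e[i] <- step[i]
    fp[i] <- fn(x + e); fm[i] <- fn(x - e)
    H[i, i] <- (fp[i] - 2 * f0 + fm[i]) / step[i]^2
  }
  if (d > 1) {
    for (i in seq_len(d - 1)) for (j in (i + 1):d) {
      ei <- rep(0, d); ei[i] <- step[i]
      ej <- rep(0, d); ej[j] <- step[j]
      H[i, j] <- H[j, i] <-
        (fn(x + ei + ej) - fn(x + ei - ej) - fn(x - ei + ej) + fn(x - ei - ej)) /
        (4 * step[i] * step[j])
    }
  }
  (H + t(H)) / 2
}

# indices (1-based) of coordinates retained in the information matrix:
# all regression coefficients plus interior baseline increments. An
# increment is interior when it is strictly positive AND structurally
# bounded: some episode must remain at risk beyond it (for T1, a support
# class beyond the point; for T2, a bracket left endpoint at or beyond it),
# otherwise the NPMLE sends it to infinity (conditional mass one) and the
# likelihood is flat there.
interior_idx <- function(fit, boundary_tol = 1e-3) {
  v <- fit$theta_vec
  pk <- fit$pack
  nfix <- 1 + pk$p2 + (if (fit$fixed) 0 else pk$p1)
  m1 <- if (fit$fixed) 0L else pk$m1
  keep1 <- logical(0)
  if (m1 > 0) {
    lam1 <- v[nfix + seq_len(m1)]
    maxsup <- max(pk$sup_idx)                 # 0-based; m1 denotes tail class
    keep1 <- lam1 > boundary_tol & (seq_len(m1) - 1L) < maxsup
  }
  lam2 <- v[nfix + m1 + seq_len(pk$m2)]
  maxKL <- max(c(0L, pk$kL[pk$o2 == 1L]))
  keep2 <- lam2 > boundary_tol & seq_len(pk$m2) <= maxKL
  c(seq_len(nfix), nfix + which(c(keep1, keep2)))
}

#' Observed information matrix
#'
#' Negative Hessian of the observed (composite) log-likelihood at the
#' fitted parameters, over the retained coordinates: all regression
#' coefficients and the baseline increments away from the zero boundary
#' (zero increments are structural zeros of the NPMLE and are profiled
#' out, since the Hessian is undefined on the boundary). Computed by
#' central finite differences of the analytic score, symmetrized.
#'
#' @param fit a [dic_fit].
#' @param step_scale relative finite-difference step (default `1e-5`).
#' @param boundary_tol increments at or below this value are treated as on
#'   the boundary and excluded.
#' @return symmetric matrix with attributes `idx` (retained coordinates in
#'   the full parameter vector) and `n_xi` (number of leading regression
#'   coordinates).
#' @export
observed_information <- function(fit, step_scale = 1e-5, boundary_tol = 1e-3) {
  stopifnot(inherits(fit, "dic_fit"))
  idx <- interior_idx(fit, boundary_tol)
  v <- fit$theta_vec
  steps <- step_scale * pmax(1, abs(v[idx]))
  nfix <- fit$n_xi
  lam_pos <- idx > nfix
  steps[lam_pos] <- pmin(steps[lam_pos], 0.49 * v[idx[lam_pos]])
  H <- cpp_hessian_fd(v, fit$pack, idx - 1L, steps)
  if (any(!is.finite(H))) {
    bad <- which(!is.finite(H), arr.ind = TRUE)[1, ]
    stop("non-finite observed-information entry at coordinate pair (",
         idx[bad[1]], ", ", idx[bad[2]], ")")
  }
  info <- -H
  # increments with vanishing curvature (posterior mass beyond them has
  # numerically disappeared, so the likelihood is flat) behave as boundary
  # coordinates: screen them out before inversion
  dg <- diag(info)
  keep <- seq_along(idx) <= nfix | dg > 1e-8 * max(dg, 1)
  if (!all(keep)) {
    info <- info[keep, keep, drop = FALSE]
    idx <- idx[keep]
  }
  attr(info, "idx") <- idx
  attr(info, "n_xi") <- nfix
  info
}

new_dic_variance <- function(method, cov_xi, est, level_mult = 1.96,
                             bootstrap_reps = NULL) {
  cov_xi <- (cov_xi + t(cov_xi)) / 2
  se <- sqrt(pmax(diag(cov_xi), 0))
  ci <- cbind(lower = est - level_mult * se, upper = est + level_mult * se)
  rownames(ci) <- names(est)
  structure(list(method = method, cov_xi = cov_xi, se = stats::setNames(se, names(est)),
                 ci = ci, est = est, bootstrap_reps = bootstrap_reps),
            class = "dic_variance")
}

#' @export
print.dic_variance <- function(x, ...) {
  cat("<dic_variance> method:", x$method,
      if (!is.null(x$bootstrap_reps)) paste0("(B = ", x$bootstrap_reps, ")"), "\n")
  print(cbind(estimate = x$est, se = x$se, x$ci))
  invisible(x)
}

#' Model-based variance from the inverse observed information
#'
#' Inverts the full retained-coordinate observed information and extracts
#' the block for the regression parameters `xi = (beta1, beta2, gamma)`.
#' Appropriate for independent episodes; for clustered data use
#' [sandwich_variance()] or [cluster_bootstrap()].
#'
#' @param fit a [dic_fit].
#' @param info optionally a precomputed [observed_information()] matrix.
#' @return A `dic_variance` object (covariance, SEs, 95% normal CIs).
#' @export
model_based_variance <- function(fit, info = NULL) {
  stopifnot(inherits(fit, "dic_fit"))
  if (is.null(info)) info <- observed_information(fit)
  n_xi <- attr(info, "n_xi")
  Vfull <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
  if (is.null(Vfull))
    Vfull <- tryCatch(solve(info), error = function(e)
      stop("observed information is singular; consider bootstrap variance"))
  new_dic_variance("model_based", Vfull[seq_len(n_xi), seq_len(n_xi), drop = FALSE],
                   fit$coefficients)
}

#' Sandwich (robust) variance for clustered composite likelihood
#'
#' Computes `A^{-1} B A^{-1}` where `A` is the observed information of the
#' independence composite log-likelihood and `B` is the sum over clusters
#' of the outer products of per-cluster score vectors, all evaluated at the
#' maximum composite likelihood estimate; returns the block for the
#' regression parameters.
#'
#' @param fit a [dic_fit] on clustered data.
#' @param info optional precomputed [observed_information()].
#' @return A `dic_variance` object.
#' @export
sandwich_variance <- function(fit, info = NULL) {
  stopifnot(inherits(fit, "dic_fit"))
  if (is.null(info)) info <- observed_information(fit)
  idx <- attr(info, "idx"); n_xi <- attr(info, "n_xi")
  S <- cpp_gradient(fit$theta_vec, fit$pack, by = 1L)  # nclust x d
  S <- S[, idx, drop = FALSE]
  M <- tryCatch(solve(info, t(S)), error = function(e)
    stop("composite information is singular; consider bootstrap variance"))
  V <- tcrossprod(M)  # A^{-1} B A^{-1}
  new_dic_variance("sandwich", V[seq_len(n_xi), seq_len(n_xi), drop = FALSE],
                   fit$coefficients)
}

#' Cluster bootstrap variance
#'
#' Resamples clusters with replacement, refits the model on each resample
#' (support grids are rebuilt per replicate), and reports the empirical
#' covariance of the regression-coefficient replicates. Deterministic given
#' `seed`. Replicates whose fit fails are dropped and counted; more than
#' 10% failures is an error.
#'
#' @param data a [dic_data] object.
#' @param B number of bootstrap replicates (>= 50 recommended; default 200).
#' @param seed integer seed.
#' @param control a [dic_control()].
#' @param fit0 optional original fit (for the point estimates; refitted if
#'   absent).
#' @return A `dic_variance` object with `bootstrap_reps` set.
#' @export
cluster_bootstrap <- function(data, B = 200L, seed = NULL,
                              control = dic_control(), fit0 = NULL) {
  stopifnot(inherits(data, "dic_data"))
  if (is.null(fit0)) fit0 <- dic_fit(data, control = control)
  if (!is.null(seed)) set.seed(seed)
  ids <- unique(data$episodes$cluster)
  nc <- length(ids)
  reps <- matrix(NA_real_, B, fit0$n_xi)
  n_fail <- 0L
  for (b in seq_len(B)) {
    take <- sample.int(nc, nc, replace = TRUE)
    rows <- lapply(seq_along(take), function(j) which(data$episodes$cluster == ids[take[j]]))
    idx <- unlist(rows, use.names = FALSE)
    ep <- data$episodes[idx, , drop = FALSE]
    ep$cluster <- rep(seq_along(take), lengths(rows))  # resampled copies are distinct clusters
    bd <- dic_data(ep, data$z1[idx, , drop = FALSE], data$z2[idx, , drop = FALSE],
                   clustered = data$clustered)
    fb <- tryCatch(dic_fit(bd, control = control), error = function(e) NULL)
    if (is.null(fb)) n_fail <- n_fail + 1L else reps[b, ] <- fb$coefficients
  }
  if (n_fail > 0.1 * B)
    stop("cluster bootstrap: ", n_fail, " of ", B, " replicate fits failed")
  ok <- stats::complete.cases(reps)
  V <- stats::cov(reps[ok, , drop = FALSE])
  out <- new_dic_variance("bootstrap", V, fit0$coefficients,
                          bootstrap_reps = sum(ok))
  out$n_failed <- n_fail
  out
}

#' Score vector of the observed (composite) log-likelihood
#'
#' Analytic gradient at arbitrary parameters; `by` selects totals,
#' per-cluster rows, or per-episode rows. Used in tests (score condition at
#' the EM fixed point) and by the sandwich estimator.
#'
#' @param fit a [dic_fit].
#' @param theta optional parameter vector (defaults to the fitted one).
#' @param by `"total"`, `"cluster"`, or `"episode"`.
#' @return numeric vector or matrix.
#' @export
dic_score <- function(fit, theta = NULL, by = c("total", "cluster", "episode")) {
  by <- match.arg(by)
  v <- if (is.null(theta)) fit$theta_vec else
    if (inherits(theta, "dic_theta")) theta_to_vec(theta, fit$fixed) else as.numeric(theta)
  cpp_gradient(v, fit$pack, by = match(by, c("total", "cluster", "episode")) - 1L)
}
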