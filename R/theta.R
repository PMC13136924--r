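#' Full parameter state
#'
#' Bundles the regression coefficients and the nonnegative jump sizes of the
#' two step-function baseline cumulative hazards: `beta1` (log hazard ratio
#' of T2 per unit of the covariate event time T1), `beta2` (coefficients of
#' the T2 covariates), `gamma` (coefficients of the T1 covariates), and
#' `lambda1`, `lambda2` (baseline hazard increments at the support grid
#' points of T1 and T2).
#'
#' @param beta1 scalar.
#' @param beta2,gamma numeric vectors (possibly length 0).
#' @param lambda1,lambda2 nonnegative numeric vectors matching the grid.
#' @return An object of class `dic_theta`.
#' @export
dic_theta <- function(beta1 = 0, beta2 = numeric(0), gamma = numeric(0),
                      lambda1 = numeric(0), lambda2 = numeric(0)) {
  if (any(lambda1 < 0) || any(lambda2 < 0))
    stop("baseline hazard increments must be nonnegative")
  structure(list(beta1 = as.numeric(beta1), beta2 = as.numeric(beta2),
                 gamma = as.numeric(gamma),
                 lambda1 = as.numeric(lambda1), lambda2 = as.numeric(lambda2)),
            class = "dic_theta")
}

#' @export
print.dic_theta <- function(x, ...) {
  cat("<dic_theta> beta1 =", format(x$beta1, digits = 4))
  if (length(x$beta2)) cat(", beta2 =", paste(format(x$beta2, digits = 4), collapse = ", "))
  if (length(x$gamma)) cat(", gamma =", paste(format(x$gamma, digits = 4), collapse = ", "))
  cat("\n  lambda1:", length(x$lambda1), "increments; lambda2:",
      length(x$lambda2), "increments\n")
  invisible(x)
}

theta_to_vec <- function(theta, fixed = FALSE) {
  if (fixed) c(theta$beta1, theta$beta2, theta$lambda2)
  else c(theta$beta1, theta$beta2, theta$gamma, theta$lambda1, theta$lambda2)
}

vec_to_theta <- function(v, p1, p2, m1, m2, fixed = FALSE) {
  if (fixed) {
    dic_theta(beta1 = v[1], beta2 = v[seq_len(p2) + 1],
              lambda2 = v[1 + p2 + seq_len(m2)])
  } else {
    off <- 1 + p2
    dic_theta(beta1 = v[1], beta2 = v[seq_len(p2) + 1],
              gamma = v[off + seq_len(p1)],
              lambda1 = v[off + p1 + seq_len(m1)],
              lambda2 = v[off + p1 + m1 + seq_len(m2)])
  }
}

theta_names <- function(p1, p2, m1, m2, fixed = FALSE) {
  nm <- c("beta1", if (p2) paste0("beta2_", seq_len(p2)))
  if (!fixed) nm <- c(nm, if (p1) paste0("gamma_", seq_len(p1)),
                      if (m1) paste0("lambda1_", seq_len(m1)))
  c(nm, if (m2) paste0("lambda2_", seq_len(m2)))
}

#' Default starting values for the EM algorithm
#'
#' Regression coefficients start at zero and every baseline increment starts
#' at `1/m1` (T1) and `1/m2` (T2), so that both starting cumulative baseline
#' hazards reach 1 at the last support point.
#'
#' @param p1,p2 covariate dimensions.
#' @param m1,m2 numbers of support points.
#' @return A [dic_theta] object.
#' @export
dic_init <- function(p1, p2, m1, m2) {
  dic_theta(beta1 = 0, beta2 = rep(0, p2), gamma = rep(0, p1),
            lambda1 = rep(1 / max(m1, 1), m1), lambda2 = rep(1 / m2, m2))
}

#' EM control parameters
#'
#' @param tol_loglik absolute convergence tolerance on the observed
#'   log-likelihood between successive EM iterations.
#' @param tol_param convergence tolerance on `max |delta theta|`; both
#'   criteria must hold.
#' @param max_iter maximum EM iterations.
#' @param newton_max inner Newton iterations per M-step block (the M-step
#'   need not fully converge; each block only has to increase the expected
#'   augmented log-likelihood).
#' @param halve_max maximum step halvings in the safeguarded Newton updates.
#' @param trunc baseline increments below this are truncated to zero.
#' @param cap upper bound applied in the one-dimensional T1-increment
#'   solves when no posterior mass lies beyond a support point; an
#'   increment at the cap encodes an effectively infinite hazard jump
#'   (conditional probability one of the event at that point).
#' @param sat saturation threshold: increments above this value have
#'   survival factors that underflow (`exp(-sat)` is negligible), so the
#'   likelihood is flat in them and their drift is excluded from the
#'   parameter-change convergence criterion.
#' @param t1_cycles sweeps of (gamma Newton, exact lambda1 coordinate
#'   maximization) per M-step.
#' @return A list of class `dic_control`.
#' @export
dic_control <- function(tol_loglik = 1e-8, tol_param = 1e-6, max_iter = 5000L,
                        newton_max = 25L, halve_max = 30L, trunc = 1e-10,
                        cap = 1e3, sat = 20, t1_cycles = 2L) {
  structure(list(tol_loglik = tol_loglik, tol_param = tol_param,
                 max_iter = as.integer(max_iter),
                 newton_max = as.integer(newton_max),
                 halve_max = as.integer(halve_max),
                 trunc = trunc, cap = cap, sat = sat,
                 t1_cycles = as.integer(t1_cycles)),
            class = "dic_control")
}
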