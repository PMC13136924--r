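# fixtures shared across test files

# small, fully anchored instance on a {1, 2} x {1, 2} endpoint lattice,
# no covariates: every baseline increment has event mass and at least one
# episode at risk beyond it, and a T2-surviving episode with an early T1
# pins beta1, so the NPMLE is interior and unique (verified against direct
# maximization).
anchored_data <- function() {
  ep <- data.frame(cluster = 1:5, episode = 1,
                   L1 = c(0, 1, 0, 0, 2), R1 = c(1, 2, 1, 1, Inf),
                   o2 = c(1, 1, 1, 1, 0),
                   L2 = c(0, 1, 2, 0, NA), R2 = c(1, 2, Inf, 2, NA))
  dic_data(ep)
}

# wider mixed instance exercising all episode types (interval/right-censored
# T1 and T2, unobserved rebound, tail class)
mixed_data <- function() {
  ep <- data.frame(cluster = 1:8, episode = 1,
                   L1 = c(0, 1, 1, 0, 2, 0, 0, 1), R1 = c(1, 2, 2, 1, Inf, 2, 1, 2),
                   o2 = c(1, 1, 1, 1, 0, 1, 1, 1),
                   L2 = c(0, 1, 2, 0, NA, 0, 1, 2),
                   R2 = c(1, 2, Inf, 2, NA, 1, 2, Inf))
  z <- c(0, 1, 0, 1, 0, 1, 0, 1)
  dic_data(ep, z1 = z, z2 = z)
}

# random positive parameter state matching a dataset's grid
random_theta <- function(data, seed = 1) {
  set.seed(seed)
  g <- build_support_grid(data)
  dic_theta(beta1 = rnorm(1, 0, 0.4),
            beta2 = rnorm(ncol(data$z2), 0, 0.4),
            gamma = rnorm(ncol(data$z1), 0, 0.4),
            lambda1 = runif(length(g$t1_points), 0.1, 1),
            lambda2 = runif(length(g$t2_points), 0.1, 1))
}

# independent enumeration of the discretized likelihood for one dataset:
# T1 mass per support point times the discrete bracket probability of T2
enum_loglik <- function(theta, data) {
  g <- build_support_grid(data)
  t1 <- g$t1_points; t2 <- g$t2_points
  ep <- data$episodes
  Lam2 <- cumsum(theta$lambda2)
  Lam2_at <- function(x) if (!is.finite(x)) Inf else {
    k <- sum(t2 <= x + 1e-12); if (k == 0) 0 else Lam2[k]
  }
  out <- numeric(nrow(ep))
  for (i in seq_len(nrow(ep))) {
    pm <- t1_pmf(theta$gamma, theta$lambda1, data$z1[i, ], g)
    cls <- which(t1 > ep$L1[i] & t1 <= ep$R1[i])
    q <- pm$pmf[cls]; tval <- t1[cls]
    if (!is.finite(ep$R1[i])) { q <- c(q, pm$tail); tval <- c(tval, max(t1)) }
    tot <- 0
    for (j in seq_along(q)) {
      if (ep$o2[i] == 0) { u <- 1 }
      else {
        eta <- exp(theta$beta1 * tval[j] + sum(theta$beta2 * data$z2[i, ]))
        SL <- exp(-eta * Lam2_at(ep$L2[i]))
        SR <- if (is.finite(ep$R2[i])) exp(-eta * Lam2_at(ep$R2[i])) else 0
        u <- if (is.finite(ep$R2[i])) SL - SR else SL
      }
      tot <- tot + q[j] * u
    }
    out[i] <- log(tot)
  }
  out
}

ctl_fast <- function(...) dic_control(max_iter = 600, tol_loglik = 1e-7,
                                      tol_param = 1e-5, ...)
ctl_tight <- function(...) dic_control(max_iter = 200000, tol_loglik = 1e-12,
                                       tol_param = 1e-9, ...)
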