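test_that("E-step posterior probabilities handle the degenerate cases", {
  # bracket containing exactly one support point, rebound unobserved
  ep <- data.frame(cluster = 1:2, episode = 1,
                   L1 = c(0, 1), R1 = c(1, 2),
                   o2 = c(0, 1), L2 = c(NA, 0), R2 = c(NA, 2))
  d <- dic_data(ep, z1 = c(1, 0), z2 = c(1, 0))
  th <- random_theta(d, seed = 2)
  es <- dic_estep(th, d)
  expect_equal(es$p[[1]], 1)                       # single class, o2 = 0
  expect_equal(sum(es$p[[2]]), 1, tolerance = 1e-12)
  # no Poisson mass for the o2 = 0 episode
  expect_true(all(es$W[[1]] == 0))
})

test_that("expected Poisson counts vanish at or below the bracket left end", {
  d <- mixed_data()
  g <- build_support_grid(d)
  th <- random_theta(d, seed = 4)
  es <- dic_estep(th, d, g)
  ep <- d$episodes
  for (i in seq_len(nrow(ep))) {
    W <- es$W[[i]]
    if (ep$o2[i] == 0 || !is.finite(ep$R2[i])) {
      expect_true(all(W == 0))
    } else {
      below <- which(g$t2_points <= ep$L2[i])
      if (length(below)) expect_true(all(W[below, ] == 0))
      expect_true(all(W >= 0))
    }
  }
})

test_that("conditional Poisson expectation matches Monte-Carlo conditioning", {
  # single class, single T2 grid point in the bracket: the latent count
  # given that the event fell in the bracket is Poisson(c) conditioned on
  # being >= 1, with mean c / (1 - exp(-c))
  ep <- data.frame(cluster = 1, episode = 1, L1 = 0, R1 = 1,
                   o2 = 1, L2 = 0, R2 = 1)
  d <- dic_data(ep)
  lam2 <- 0.9
  th <- dic_theta(beta1 = 0.4, lambda1 = 0.7, lambda2 = lam2)
  es <- dic_estep(th, d)
  cc <- lam2 * exp(0.4 * 1)
  expect_equal(es$W[[1]][1, 1], cc / (1 - exp(-cc)), tolerance = 1e-10)
  set.seed(99)
  draws <- stats::rpois(1e6, cc)
  mc <- mean(draws[draws >= 1])
  expect_equal(es$W[[1]][1, 1], mc, tolerance = 1e-3)
})

test_that("EM fixed point satisfies the profiled closed-form identities", {
  # at convergence, every interior T2 increment equals the ratio of expected
  # Poisson counts to the at-risk weighted linear predictor total, and every
  # interior T1 increment solves its coordinate score equation
  d <- anchored_data()
  f <- dic_fit(d, control = ctl_tight())
  g <- f$grid
  th <- f$theta
  es <- dic_estep(th, d, g)
  ep <- d$episodes
  eta_ic <- function(i, tval) exp(th$beta1 * tval + sum(th$beta2 * d$z2[i, ]))
  m2 <- length(g$t2_points)
  Wk <- numeric(m2); Dk <- numeric(m2)
  for (i in seq_len(nrow(ep))) {
    if (ep$o2[i] != 1) next
    sup <- es$support[[i]]
    tval <- ifelse(sup > length(g$t1_points), max(g$t1_points),
                   g$t1_points[pmin(sup, length(g$t1_points))])
    Wk <- Wk + rowSums(es$W[[i]])
    r2s <- if (is.finite(ep$R2[i])) ep$R2[i] else ep$L2[i]
    kcap <- sum(g$t2_points <= r2s)
    if (kcap >= 1) {
      contrib <- sum(es$p[[i]] * sapply(tval, function(tv) eta_ic(i, tv)))
      Dk[seq_len(kcap)] <- Dk[seq_len(kcap)] + contrib
    }
  }
  interior <- which(th$lambda2 > 1e-6 & Wk > 0)
  expect_gt(length(interior), 0)
  expect_equal(th$lambda2[interior], (Wk / Dk)[interior], tolerance = 1e-6)

  # T1 coordinate score: -A_l + sum_i p_il mu_i / (exp(mu_i lam) - 1) = 0
  mu <- exp(drop(d$z1 %*% th$gamma))
  for (l in seq_along(g$t1_points)) {
    lam <- th$lambda1[l]
    if (lam < 1e-6) next
    A <- 0; S <- 0
    for (i in seq_len(nrow(ep))) {
      sup <- es$support[[i]]; p <- es$p[[i]]
      A <- A + mu[i] * sum(p[sup > l])
      j <- which(sup == l)
      if (length(j)) S <- S + p[j] * mu[i] / expm1(mu[i] * lam)
    }
    expect_lt(abs(S - A), 1e-6)
  }
})

test_that("observed log-likelihood ascends along the EM trace", {
  sets <- list(anchored_data(), mixed_data(),
               simulate_dic(dic_scenario("study1", "1.1", n = 60), seed = 8),
               simulate_dic(dic_scenario("study2", "2.1", n = 60), seed = 9),
               simulate_dic(dic_scenario("clustered", "1.1", n = 40, rho = 0.5),
                            seed = 10))
  for (d in sets) {
    f <- dic_fit(d, control = ctl_fast())
    expect_true(all(diff(f$trace) > -1e-10))
  }
})

test_that("EM solution matches direct numerical maximization on a small instance", {
  d <- anchored_data()
  f <- dic_fit(d, control = ctl_tight())
  expect_true(f$converged)
  pk <- f$pack
  dlt <- length(f$theta_vec)
  nll <- function(v) {
    s <- -sum(dicph:::cpp_loglik(v, pk))
    if (!is.finite(s)) 1e10 else s
  }
  best <- NULL
  for (r in 1:10) {
    set.seed(100 + r)
    v0 <- c(rnorm(1, 0, 0.5), runif(dlt - 1, 0.05, 2))
    o <- stats::optim(v0, nll, method = "L-BFGS-B",
                      lower = c(-20, rep(1e-10, dlt - 1)),
                      upper = c(20, rep(1000, dlt - 1)),
                      control = list(maxit = 20000, factr = 1))
    if (is.null(best) || o$value < best$value) best <- o
  }
  expect_equal(f$loglik, -best$value, tolerance = 1e-7)
  expect_lt(max(abs(f$theta_vec - best$par)), 1e-3)
})

test_that("the score vanishes at the EM fixed point", {
  d <- anchored_data()
  f <- dic_fit(d, control = ctl_tight())
  sc <- dic_score(f)
  ii <- dicph:::interior_idx(f, boundary_tol = 1e-6)
  expect_lt(max(abs(sc[ii])), 1e-4)
})

test_that("a null covariate-event effect is recovered from the truth start", {
  cfg <- dic_scenario("study1", "1.1", n = 300,
                      coefficients = list(beta1 = 0))
  d <- simulate_dic(cfg, seed = 123)
  g <- build_support_grid(d)
  init <- dic_theta(beta1 = 0, beta2 = 1, gamma = -0.5,
                    lambda1 = diff(c(0, (g$t1_points / 3)^2)),
                    lambda2 = diff(c(0, (g$t2_points / 10)^5)))
  f <- dic_fit(d, init = init, control = ctl_fast())
  vr <- model_based_variance(f)
  expect_lt(abs(coef(f)["beta1"]), 3 * vr$se["beta1"])
})

test_that("with exactly known T1 the fit reduces to the fixed-covariate engine", {
  set.seed(77)
  cfg <- dic_scenario("study1", "1.1", n = 80)
  d <- simulate_dic(cfg, seed = 77)
  tr <- attr(d, "truth")
  eps <- 1e-7
  ep <- d$episodes
  ep$L1 <- tr$T1 * (1 - eps); ep$R1 <- tr$T1 * (1 + eps)
  d2 <- dic_data(ep, d$z1, d$z2)
  full <- dic_fit(d2, control = ctl_fast())
  fixed <- dic_fit(d2, control = ctl_fast(), fixed_t1 = tr$T1)
  expect_lt(max(abs(coef(full)[c("beta1", "beta2_1")] -
                    coef(fixed)[c("beta1", "beta2_1")])), 2e-3)
})

test_that("degenerate posterior mass drives the matching increment to the boundary", {
  # all posterior mass on one support class: remaining T1 increments at 0,
  # the class's own increment grows to represent conditional mass one
  ep <- data.frame(cluster = 1:3, episode = 1,
                   L1 = c(1, 1, 1), R1 = c(2, 2, 2),
                   o2 = 1, L2 = c(0, 0, 1), R2 = c(1, 1, 2))
  d <- dic_data(ep)  # no covariates
  f <- dic_fit(d, control = ctl_fast())
  g <- f$grid
  # T1 support {1, 2}: all brackets are (1,2], so class at t = 2 takes all mass
  pm <- t1_pmf(numeric(0), f$theta$lambda1, numeric(0), g)
  expect_lt(pm$pmf[1], 1e-8)
  expect_gt(pm$pmf[2], 1 - 1e-6)
})

test_that("midpoint warm start reaches the same solution as the default start", {
  d <- simulate_dic(dic_scenario("study1", "1.1", n = 60), seed = 15)
  f0 <- dic_fit(d, control = ctl_fast())
  f1 <- dic_fit(d, init = "midpoint", control = ctl_fast())
  expect_lt(max(abs(coef(f0) - coef(f1))), 5e-3)
})
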