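test_that("monitoring schedules follow the gap construction", {
  set.seed(1)
  s <- sim_schedule(monitoring_level(1), n = 4000)
  expect_equal(dim(s), c(4000, 30))
  expect_true(all(diff(t(s)) > 0))
  gaps <- s[, -1] - s[, -30]
  expect_equal(mean(gaps), 1 / 15 + 0.5, tolerance = 1e-2)
  expect_true(all(gaps >= 1 / 15))
  # expected last visit: E[U(1)] + (K-1)(c + d/2)
  expect_equal(mean(s[, 30]), 0.5 + 29 * (1 / 15 + 0.5), tolerance = 0.05)

  # vanishing-jitter limit: visits approach (d, c+2d, ...) deterministically
  s0 <- sim_schedule(list(c = 1, d = 1e-9, K = 5), n = 1)
  expect_equal(drop(s0), cumsum(c(0, rep(1, 4))), tolerance = 1e-7)

  s2 <- sim_schedule(2, n = 10)
  expect_equal(ncol(s2), 60)
})

test_that("event-time generation inverts the cumulative hazard", {
  # unit cumulative hazard point: Lambda(3) = 1 for (t/3)^2
  expect_equal(ph_quantile(exp(-1), 2, 3, 0), 3)
  # closed-form survival at deciles
  set.seed(2)
  u <- runif(1e6)
  T <- ph_quantile(u, 2, 3, 0.4)
  qs <- quantile(T, probs = seq(0.1, 0.9, 0.1))
  S_true <- exp(-(qs / 3)^2 * exp(0.4))
  expect_lt(max(abs(S_true - seq(0.9, 0.1, -0.1))), 2e-3)
})

test_that("piecewise hazard generation decays at the baseline rate beyond the change point", {
  set.seed(3)
  tau <- 3 * sqrt(log(2))
  T <- dicph:::ph_quantile_piecewise(runif(2e5), 2, 3, z = 1,
                                     g1 = -0.5, g2 = 0, tau = tau)
  # conditional survival beyond tau is baseline: S(t)/S(tau) = exp(-((t/3)^2 - (tau/3)^2))
  Tc <- T[T > tau]
  t0 <- unname(quantile(Tc, 0.5))
  emp <- mean(Tc > t0)
  theo <- exp(-((t0 / 3)^2 - (tau / 3)^2))
  expect_equal(emp, theo, tolerance = 0.02)
  # before tau the covariate effect is active: P(T <= tau | z=1) is
  # exp(gamma)-tempered
  expect_equal(mean(T <= tau), 1 - exp(-(tau / 3)^2 * exp(-0.5)), tolerance = 5e-3)
})

test_that("bracketing returns the shortest covering inter-visit interval", {
  b <- bracket_event(c(2.5, 5, 0.5), matrix(c(1, 2, 3), 3, 3, byrow = TRUE))
  expect_equal(b$L, c(2, 3, 0))
  expect_equal(b$R, c(3, Inf, 1))
  expect_error(bracket_event(0, c(1, 2)), "positive")
  # right-closed membership: an event exactly at a visit is bracketed by it
  b2 <- bracket_event(2, c(1, 2, 3))
  expect_equal(c(b2$L, b2$R), c(1, 2))
})

test_that("generators are reproducible and pass validation", {
  for (st in c("study1", "study2", "study3a", "study3b")) {
    cfg <- dic_scenario(st, "2.1", n = 30)
    d1 <- simulate_dic(cfg, seed = 11)
    d2 <- simulate_dic(cfg, seed = 11)
    expect_identical(d1$episodes, d2$episodes)
    expect_s3_class(dic_validate(d1), "dic_report")
  }
  cfgc <- dic_scenario("clustered", "1.2", n = 30, rho = 0.3)
  expect_identical(simulate_dic(cfgc, seed = 12)$episodes,
                   simulate_dic(cfgc, seed = 12)$episodes)
})

test_that("the noise covariate does not perturb the event-time draws", {
  cfg1 <- dic_scenario("study1", "1.1", n = 40)
  cfg3 <- dic_scenario("study3a", "1.1", n = 40)
  d1 <- simulate_dic(cfg1, seed = 21)
  d3 <- simulate_dic(cfg3, seed = 21)
  expect_identical(attr(d1, "truth"), attr(d3, "truth"))
  expect_identical(d1$episodes$L1, d3$episodes$L1)
  expect_equal(colnames(d3$z2), c("Z", "X"))
})

test_that("the low-suppression-rate design right-censors T1 but rarely T2", {
  # Weibull (t/15)^2 baseline against ~17 units of follow-up
  fr1 <- fr2 <- c()
  for (sc in c("1.1", "2.2")) {
    d <- simulate_dic(dic_scenario("study2", sc, n = 4000), seed = 31)
    rep <- dic_validate(d)
    fr1 <- c(fr1, rep$t1_right_censored)
    fr2 <- c(fr2, rep$t2_right_censored)
  }
  expect_lt(max(abs(fr1 - 0.284)), 0.02)
  expect_lt(max(fr2), 0.003)
})

test_that("null coefficients make the two event times independent", {
  cfg <- dic_scenario("study1", "1.1", n = 4000,
                      coefficients = list(beta1 = 0, beta2 = 0, gamma = 0))
  d <- simulate_dic(cfg, seed = 41)
  tr <- attr(d, "truth")
  expect_lt(abs(cor(tr$T1, tr$T2)), 0.04)
})

test_that("the exchangeable copula reproduces the requested dependence", {
  cfg <- dic_scenario("clustered", "1.1", n = 3000, rho = 0.5)
  d <- simulate_dic(cfg, seed = 51)
  tr <- attr(d, "truth")
  ep <- d$episodes
  z <- drop(d$z1)
  # recover the copula normal scores from the marginal model
  u <- exp(-(tr$T1 / 3)^2 * exp(-0.5 * z))
  x <- qnorm(u)
  first <- !duplicated(ep$cluster)
  sizes <- table(ep$cluster)
  pairs <- do.call(rbind, lapply(unique(ep$cluster)[sizes[as.character(unique(ep$cluster))] >= 2],
    function(cl) {
      xi <- x[ep$cluster == cl]
      t(combn(xi, 2))
    }))
  expect_equal(cor(pairs[, 1], pairs[, 2]), 0.5, tolerance = 0.05)

  # rho = 0: sibling times uncorrelated
  d0 <- simulate_dic(dic_scenario("clustered", "1.1", n = 3000, rho = 0), seed = 52)
  tr0 <- attr(d0, "truth"); ep0 <- d0$episodes; z0 <- drop(d0$z1)
  u0 <- qnorm(exp(-(tr0$T1 / 3)^2 * exp(-0.5 * z0)))
  sizes0 <- table(ep0$cluster)
  pairs0 <- do.call(rbind, lapply(names(sizes0)[sizes0 >= 2], function(cl) {
    xi <- u0[ep0$cluster == cl]
    t(combn(xi, 2))
  }))
  expect_lt(abs(cor(pairs0[, 1], pairs0[, 2])), 0.05)
})

test_that("clustering preserves the marginal event-time laws", {
  dc <- simulate_dic(dic_scenario("clustered", "1.1", n = 2500, rho = 0.7), seed = 61)
  di <- simulate_dic(dic_scenario("study1", "1.1", n = 4000), seed = 62)
  trc <- attr(dc, "truth"); tri <- attr(di, "truth")
  ks1 <- suppressWarnings(ks.test(trc$T1, tri$T1))
  ks2 <- suppressWarnings(ks.test(trc$T2, tri$T2))
  expect_gt(ks1$p.value, 0.01)
  expect_gt(ks2$p.value, 0.01)
})

test_that("last-episode rebound brackets are missing at the configured rate", {
  d <- simulate_dic(dic_scenario("clustered", "1.1", n = 4000, rho = 0.5), seed = 71)
  ep <- d$episodes
  sizes <- ave(ep$episode, ep$cluster, FUN = max)
  last <- ep$episode == sizes
  expect_lt(abs(mean(ep$o2[last] == 0) - 0.7), 0.025)
  expect_true(all(ep$o2[!last] == 1))
})

test_that("invalid copula correlations are rejected", {
  expect_error(dic_scenario("clustered", n = 10, rho = -0.6), "rho")
})
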