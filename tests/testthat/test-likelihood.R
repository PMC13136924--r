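test_that("discretized T1 pmf matches closed forms", {
  # single support point, unit hazard multiplier
  p <- t1_pmf(numeric(0), log(2), numeric(0), 1)
  expect_equal(p$pmf, 0.5)
  expect_equal(p$tail, 0.5)
  # two points: P(T1 = t12) = exp(-a) (1 - exp(-b))
  a <- 0.4; b <- 0.9
  p2 <- t1_pmf(numeric(0), c(a, b), numeric(0), c(1, 2))
  expect_equal(p2$pmf[2], exp(-a) * (1 - exp(-b)))
  # covariate doubling the hazard
  cc <- 0.37
  p3 <- t1_pmf(log(2), cc, 1, 1)
  expect_equal(p3$pmf, 1 - exp(-2 * cc))
})

test_that("pmf masses plus tail sum to one and ignore zero increments", {
  set.seed(2)
  for (r in 1:25) {
    m <- sample(1:8, 1); pdim <- sample(0:2, 1)
    lam <- runif(m, 0, 2)
    gam <- rnorm(pdim); z <- rnorm(pdim)
    p <- t1_pmf(gam, lam, z, seq_len(m))
    expect_lt(abs(sum(p$pmf) + p$tail - 1), 1e-12)
    # appending a zero increment leaves existing masses unchanged
    p0 <- t1_pmf(gam, c(lam, 0), z, seq_len(m + 1))
    expect_equal(p0$pmf[seq_len(m)], p$pmf)
    expect_equal(p0$pmf[m + 1], 0)
    expect_equal(p0$tail, p$tail)
  }
})

test_that("single-support episodes reduce to the closed form", {
  ep <- data.frame(cluster = 1, episode = 1, L1 = 0, R1 = 1,
                   o2 = 1, L2 = 0, R2 = 1)
  z <- matrix(1, 1, 1)
  d <- dic_data(ep, z1 = z, z2 = z)
  th <- dic_theta(beta1 = 0.25, beta2 = 0.5, gamma = 0.3,
                  lambda1 = 0.8, lambda2 = 0.6)
  eta <- exp(0.25 * 1 + 0.5)
  expected <- log((1 - exp(-eta * 0.6)) * (1 - exp(-exp(0.3) * 0.8)))
  expect_equal(dic_loglik(th, d)$total, expected, tolerance = 1e-12)
})

test_that("unobserved-rebound episodes contribute the T1 bracket mass only", {
  ep <- data.frame(cluster = 1, episode = 1, L1 = 1, R1 = 3,
                   o2 = 1, L2 = 0, R2 = 1)
  ep2 <- data.frame(cluster = 2, episode = 1, L1 = 1, R1 = 3,
                    o2 = 0, L2 = NA, R2 = NA)
  d <- dic_data(rbind(ep, ep2), z1 = c(0.5, 0.5), z2 = c(0.5, 0.5))
  g <- build_support_grid(d)
  th <- random_theta(d, seed = 11)
  ll <- dic_loglik(th, d, g)
  pm <- t1_pmf(th$gamma, th$lambda1, 0.5, g)
  cls <- which(g$t1_points > 1 & g$t1_points <= 3)
  expect_equal(ll$per_episode[2], log(sum(pm$pmf[cls])), tolerance = 1e-12)
})

test_that("episode likelihood equals independent enumeration", {
  for (mk in list(anchored_data, mixed_data)) {
    d <- mk()
    for (s in 1:5) {
      th <- random_theta(d, seed = s)
      ll <- dic_loglik(th, d)
      expect_equal(ll$per_episode, enum_loglik(th, d), tolerance = 1e-10)
    }
  }
})

test_that("total likelihood has product structure and breakdowns agree", {
  d <- mixed_data()
  th <- random_theta(d, seed = 3)
  ll <- dic_loglik(th, d)
  expect_equal(ll$total, sum(ll$per_episode), tolerance = 1e-12)
  expect_equal(sum(ll$per_cluster), ll$total, tolerance = 1e-12)

  # duplicating every episode doubles the total
  ep2 <- rbind(d$episodes, d$episodes)
  ep2$cluster <- seq_len(nrow(ep2))
  d2 <- dic_data(ep2, rbind(d$z1, d$z1), rbind(d$z2, d$z2))
  expect_equal(dic_loglik(th, d2)$total, 2 * ll$total, tolerance = 1e-10)

  # reordering episodes leaves the total unchanged
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  ep3 <- d$episodes[perm, ]; ep3$cluster <- seq_len(8)
  d3 <- dic_data(ep3, d$z1[perm, , drop = FALSE], d$z2[perm, , drop = FALSE])
  expect_equal(dic_loglik(th, d3)$total, ll$total, tolerance = 1e-12)
})

test_that("raising pre-bracket T2 hazard lowers an episode's likelihood", {
  d <- mixed_data()
  g <- build_support_grid(d)
  th <- random_theta(d, seed = 6)
  # episode 3 has L2 = 2: grid point 1 (t = 1) lies at or below L2
  base <- dic_loglik(th, d, g)$per_episode[3]
  th2 <- th; th2$lambda2[1] <- th2$lambda2[1] + 0.05
  expect_lt(dic_loglik(th2, d, g)$per_episode[3], base)
})

test_that("impossible episodes yield -Inf with diagnostics, not an error", {
  ep <- data.frame(cluster = 1, episode = 1, L1 = 0, R1 = 1,
                   o2 = 1, L2 = 0, R2 = 1)
  d <- dic_data(ep)
  th <- dic_theta(beta1 = 0, lambda1 = 0.5, lambda2 = 0)  # no T2 mass in bracket
  ll <- dic_loglik(th, d)
  expect_identical(ll$per_episode[1], -Inf)
  expect_equal(attr(ll, "bad_episodes"), 1L)
})

test_that("discretized likelihood approaches the continuous one for narrow brackets", {
  # one episode with narrow brackets around known times; baselines fixed at
  # the Weibull truths Lambda1 = (t/3)^2, Lambda2 = (t/10)^2 discretized on
  # a fine grid. The continuous-likelihood oracle integrates over t1.
  h <- 0.05
  grid1 <- seq(h, 6, by = h); grid2 <- seq(h, 6, by = h)
  T1 <- 2.5; T2 <- 1.7
  L1 <- T1 - h / 2; R1 <- T1 + h / 2
  L2 <- T2 - h / 2; R2 <- T2 + h / 2
  # snap brackets onto the grid
  L1 <- grid1[which.min(abs(grid1 - L1))]; R1 <- L1 + h
  L2 <- grid2[which.min(abs(grid2 - L2))]; R2 <- L2 + h
  ep <- data.frame(cluster = 1, episode = 1, L1 = L1, R1 = R1,
                   o2 = 1, L2 = L2, R2 = R2)
  # pad with episodes defining the full grid so the support includes it
  pad <- data.frame(cluster = 2:(length(grid1) + 1), episode = 1,
                    L1 = c(0, grid1[-length(grid1)]), R1 = grid1,
                    o2 = 1, L2 = c(0, grid2[-length(grid2)]), R2 = grid2)
  d <- dic_data(rbind(ep, pad), z1 = rep(1, nrow(ep) + nrow(pad)),
                z2 = rep(1, nrow(ep) + nrow(pad)))
  beta1 <- 0.3; beta2 <- 0.6; gamma <- -0.4
  th <- dic_theta(beta1, beta2, gamma,
                  lambda1 = diff(c(0, (grid1 / 3)^2)),
                  lambda2 = diff(c(0, (grid2 / 10)^2)))
  disc <- dic_loglik(th, d)$per_episode[1]
  integrand <- function(t) {
    eta <- exp(beta1 * t + beta2)
    (exp(-eta * (L2 / 10)^2) - exp(-eta * (R2 / 10)^2)) *
      exp(-exp(gamma) * (t / 3)^2) * (2 * t / 9) * exp(gamma)
  }
  cont <- log(stats::integrate(integrand, L1, R1, rel.tol = 1e-10)$value)
  expect_equal(disc, cont, tolerance = 0.02)
})
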