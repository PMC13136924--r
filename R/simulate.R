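#' Monitoring schedule presets
#'
#' Visit schedules are generated as `U(1) ~ Unif(0, d)` and
#' `U(h) = U(h-1) + c + Unif(0, d)`: `c` is the minimum gap between visits,
#' `d` controls the average gap (`c + d/2`), and `K` is the number of
#' visits. Level 1 is low-frequency monitoring (`c = 1/15`, `d = 1`,
#' `K = 30`, mean gap about 0.57 time units); level 2 is high-frequency
#' (`c = 19/590`, `d = 0.5`, `K = 60`, mean gap about 0.28). Both levels
#' reach a comparable administrative end of follow-up (about 17 time
#' units), so right-censoring rates are similar across levels.
#'
#' @param level 1 or 2, or a list with fields `c`, `d`, `K`.
#' @return list with `c`, `d`, `K`.
#' @export
monitoring_level <- function(level) {
  if (is.list(level)) {
    stopifnot(all(c("c", "d", "K") %in% names(level)),
              level$c >= 0, level$d > 0, level$K >= 1)
    return(level[c("c", "d", "K")])
  }
  switch(as.character(level),
         "1" = list(c = 1 / 15, d = 1.0, K = 30L),
         "2" = list(c = 19 / 590, d = 0.5, K = 60L),
         stop("monitoring level must be 1 or 2"))
}

#' Simulate monitoring schedules
#'
#' @param cfg a [monitoring_level()] list.
#' @param n number of schedules.
#' @return `n` by `K` matrix of strictly increasing visit times.
#' @export
sim_schedule <- function(cfg, n = 1L) {
  cfg <- monitoring_level(cfg)
  K <- cfg$K
  gaps <- matrix(stats::runif(n * K, 0, cfg$d), n, K)
  if (K > 1) gaps[, -1] <- gaps[, -1] + cfg$c
  t(apply(gaps, 1, cumsum))
}

#' Quantile function of a proportional-hazards Weibull event time
#'
#' Inverse-transform sampling: with cumulative baseline hazard
#' `(t/scale)^shape` and linear predictor `lp`, the survival probability
#' `u` corresponds to `T = scale * (-log(u) * exp(-lp))^(1/shape)`.
#'
#' @param u survival probabilities in (0, 1).
#' @param shape,scale Weibull baseline parameters (both > 0).
#' @param linpred linear predictor(s).
#' @return event times.
#' @export
ph_quantile <- function(u, shape, scale, linpred = 0) {
  stopifnot(shape > 0, scale > 0)
  scale * (-log(u) * exp(-linpred))^(1 / shape)
}

# piecewise-PH inversion: hazard lam0(t) * exp(g1*z) for t <= tau and
# lam0(t) * exp(g2*z) beyond, with Weibull baseline.
ph_quantile_piecewise <- function(u, shape, scale, z, g1, g2, tau) {
  E <- -log(u)
  Ltau <- (tau / scale)^shape
  thr <- Ltau * exp(g1 * z)
  ifelse(E <= thr,
         scale * (E * exp(-g1 * z))^(1 / shape),
         scale * (Ltau + (E - thr) * exp(-g2 * z))^(1 / shape))
}

#' Bracket an event time by a visit schedule
#'
#' Returns the shortest inter-visit interval `(U(k-1), U(k)]` containing the
#' event time, with `U(0) = 0`; events after the last visit are
#' right-censored: `(U(K), Inf)`.
#'
#' @param T event time(s), > 0.
#' @param schedule increasing visit times: a vector (single schedule shared
#'   by all events) or a matrix with one row per event.
#' @return data.frame with columns `L`, `R`.
#' @export
bracket_event <- function(T, schedule) {
  if (any(T <= 0)) stop("event times must be positive")
  if (is.vector(schedule)) schedule <- matrix(schedule, nrow = length(T),
                                              ncol = length(schedule), byrow = TRUE)
  stopifnot(nrow(schedule) == length(T))
  K <- ncol(schedule)
  idx <- rowSums(schedule < T)
  L <- ifelse(idx == 0, 0, schedule[cbind(seq_along(T), pmax(idx, 1L))])
  R <- ifelse(idx == K, Inf, schedule[cbind(seq_along(T), pmin(idx + 1L, K))])
  data.frame(L = L, R = R)
}

#' Simulation scenario configuration
#'
#' Encodes the data-generating mechanisms of the simulation studies:
#' Weibull (or piecewise proportional-hazards) baselines, regression
#' coefficients, monitoring frequencies for each event, and (for clustered
#' data) the episode-count distribution, Gaussian-copula correlation, and
#' missingness of the last episode's rebound bracket.
#'
#' Presets: `"study1"` uses baselines `(t/3)^2` and `(t/10)^5` with
#' `(beta1, beta2, gamma) = (0.3, 1, -0.5)` and a Bernoulli(0.5) covariate;
#' `"study2"` uses `(t/15)^2` and `(t/10)^2` with `gamma = 0` (so about 28%
#' of T1 times are right-censored by the last visit while T2 censoring is
#' negligible); `"study3a"` adds an independent standard-normal noise
#' covariate to study 1; `"study3b"` replaces the T1 hazard by a piecewise
#' model whose covariate effect `gamma` vanishes after the marginal median
#' of T1 under `Z = 0` (so the fitted proportional-hazards working model is
#' misspecified); `"clustered"` draws 1, 2 or 3 episodes per participant
#' with probabilities (0.3, 0.5, 0.2), exchangeable Gaussian-copula
#' dependence between sibling event times, and a 70% chance that the last
#' episode's rebound bracket is unobserved.
#'
#' @param study one of `"study1"`, `"study2"`, `"study3a"`, `"study3b"`,
#'   `"clustered"`.
#' @param scenario `"a.b"`: T1 monitored at level `a`, T2 at level `b`.
#' @param n number of independent episodes, or clusters when clustered.
#' @param rho copula correlation (clustered only).
#' @param covariate `"bernoulli"` (Bern(0.5)) or `"normal"` (N(0,1)).
#' @param coefficients optional named list overriding any of `beta1`,
#'   `beta2`, `gamma` (useful for null-effect checks).
#' @return list of class `dic_scenario`.
#' @export
dic_scenario <- function(study = c("study1", "study2", "study3a", "study3b",
                                   "clustered"),
                         scenario = "1.1", n = 200L, rho = 0.5,
                         covariate = c("bernoulli", "normal"),
                         coefficients = NULL) {
  study <- match.arg(study)
  covariate <- match.arg(covariate)
  ab <- strsplit(scenario, ".", fixed = TRUE)[[1]]
  if (length(ab) != 2 || !all(ab %in% c("1", "2")))
    stop("scenario must be \"a.b\" with a, b in {1, 2}")
  cfg <- list(study = study, scenario = scenario, n = as.integer(n),
              mon1 = monitoring_level(ab[1]), mon2 = monitoring_level(ab[2]),
              base1 = list(shape = 2, scale = 3),
              base2 = list(shape = 5, scale = 10),
              beta1 = 0.3, beta2 = 1.0, gamma = -0.5,
              covariate = covariate, noise_x = FALSE,
              piecewise = NULL, clustered = FALSE,
              episode_pmf = NULL, rho = NA_real_, o2_miss = 0)
  if (study == "study2") {
    cfg$base1 <- list(shape = 2, scale = 15)
    cfg$base2 <- list(shape = 2, scale = 10)
    cfg$gamma <- 0
  } else if (study == "study3a") {
    cfg$noise_x <- TRUE
  } else if (study == "study3b") {
    # effect gamma before the change point, none after; change point at the
    # marginal median of T1 under Z = 0: scale * log(2)^(1/shape)
    cfg$piecewise <- list(g1 = cfg$gamma, g2 = 0,
                          tau = cfg$base1$scale * log(2)^(1 / cfg$base1$shape))
  } else if (study == "clustered") {
    cfg$clustered <- TRUE
    cfg$episode_pmf <- c(0.3, 0.5, 0.2)
    if (!(rho > -0.5 && rho < 1)) stop("rho must lie in (-1/(max n_i - 1), 1)")
    cfg$rho <- rho
    cfg$o2_miss <- 0.7
  }
  if (!is.null(coefficients)) {
    for (nm in names(coefficients)) {
      if (!nm %in% c("beta1", "beta2", "gamma"))
        stop("unknown coefficient override: ", nm)
      cfg[[nm]] <- coefficients[[nm]]
    }
    if (study == "study3b") cfg$piecewise$g1 <- cfg$gamma
  }
  class(cfg) <- "dic_scenario"
  cfg
}

#' Generate a synthetic dataset from a scenario
#'
#' Deterministic given `(cfg, seed)`. Draws are made in a fixed order
#' (cluster sizes, covariate Z, event-time latents for T1 then T2,
#' monitoring schedules for T1 then T2, then the optional noise covariate
#' X) so that switching the noise covariate on or off does not perturb the
#' event times. The true event times are attached as `attr(x, "truth")`.
#'
#' @param cfg a [dic_scenario()].
#' @param seed integer seed.
#' @return A [dic_data] object.
#' @export
simulate_dic <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "dic_scenario"))
  if (!is.null(seed)) set.seed(seed)
  if (cfg$clustered) sim_clustered_impl(cfg) else sim_independent_impl(cfg)
}

draw_cov <- function(n, kind) {
  if (kind == "bernoulli") stats::rbinom(n, 1, 0.5) else stats::rnorm(n)
}

sim_independent_impl <- function(cfg) {
  n <- cfg$n
  Z <- draw_cov(n, cfg$covariate)
  u1 <- stats::runif(n); u2 <- stats::runif(n)
  T1 <- if (is.null(cfg$piecewise))
    ph_quantile(u1, cfg$base1$shape, cfg$base1$scale, cfg$gamma * Z)
  else ph_quantile_piecewise(u1, cfg$base1$shape, cfg$base1$scale, Z,
                             cfg$piecewise$g1, cfg$piecewise$g2, cfg$piecewise$tau)
  T2 <- ph_quantile(u2, cfg$base2$shape, cfg$base2$scale,
                    cfg$beta1 * T1 + cfg$beta2 * Z)
  s1 <- sim_schedule(cfg$mon1, n)
  s2 <- sim_schedule(cfg$mon2, n)
  b1 <- bracket_event(T1, s1)
  b2 <- bracket_event(T2, s2)
  zmat <- cbind(Z = Z)
  if (cfg$noise_x) zmat <- cbind(zmat, X = stats::rnorm(n))
  ep <- data.frame(cluster = seq_len(n), episode = 1L,
                   L1 = b1$L, R1 = b1$R, o2 = 1L, L2 = b2$L, R2 = b2$R)
  out <- dic_data(ep, z1 = zmat, z2 = zmat, clustered = FALSE)
  attr(out, "truth") <- data.frame(T1 = T1, T2 = T2)
  out
}

# exchangeable Gaussian copula uniforms: one vector per cluster member
copula_uniforms <- function(sizes, rho) {
  M <- sum(sizes)
  if (rho >= 0) {
    z0 <- stats::rnorm(length(sizes))
    zi <- stats::rnorm(M)
    stats::pnorm(sqrt(rho) * rep(z0, sizes) + sqrt(1 - rho) * zi)
  } else {
    u <- numeric(M)
    pos <- 1L
    chols <- list()
    zi <- stats::rnorm(M)
    for (ci in seq_along(sizes)) {
      k <- sizes[ci]
      key <- as.character(k)
      if (is.null(chols[[key]])) {
        S <- matrix(rho, k, k); diag(S) <- 1
        chols[[key]] <- chol(S)
      }
      u[pos:(pos + k - 1)] <- stats::pnorm(drop(crossprod(chols[[key]], zi[pos:(pos + k - 1)])))
      pos <- pos + k
    }
    u
  }
}

sim_clustered_impl <- function(cfg) {
  N <- cfg$n
  sizes <- sample.int(length(cfg$episode_pmf), N, replace = TRUE,
                      prob = cfg$episode_pmf)
  M <- sum(sizes)
  cl <- rep(seq_len(N), sizes)
  epi <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  Z <- draw_cov(M, cfg$covariate)
  u1 <- copula_uniforms(sizes, cfg$rho)
  u2 <- copula_uniforms(sizes, cfg$rho)
  T1 <- ph_quantile(u1, cfg$base1$shape, cfg$base1$scale, cfg$gamma * Z)
  T2 <- ph_quantile(u2, cfg$base2$shape, cfg$base2$scale,
                    cfg$beta1 * T1 + cfg$beta2 * Z)
  # last episode's rebound bracket unobserved with probability o2_miss
  is_last <- epi == rep(sizes, sizes)
  o2 <- rep(1L, M)
  o2[is_last] <- as.integer(stats::runif(sum(is_last)) >= cfg$o2_miss)
  s1 <- sim_schedule(cfg$mon1, M)
  s2 <- sim_schedule(cfg$mon2, M)
  b1 <- bracket_event(T1, s1)
  b2 <- bracket_event(T2, s2)
  L2 <- ifelse(o2 == 1, b2$L, NA_real_)
  R2 <- ifelse(o2 == 1, b2$R, NA_real_)
  ep <- data.frame(cluster = cl, episode = epi,
                   L1 = b1$L, R1 = b1$R, o2 = o2, L2 = L2, R2 = R2)
  out <- dic_data(ep, z1 = cbind(Z = Z), z2 = cbind(Z = Z), clustered = TRUE)
  attr(out, "truth") <- data.frame(T1 = T1, T2 = T2)
  out
}
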