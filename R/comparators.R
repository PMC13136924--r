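#' Midpoint imputation of bracketed event times
#'
#' Imputes each event time by the midpoint of its bracket; a right-censored
#' time (no midpoint defined) is imputed by the left endpoint. For T2 the
#' event indicator is retained: a right-censored rebound stays censored at
#' `L2`.
#'
#' @param data a [dic_data] object.
#' @return list with `t1_star`, `t2_star`, `t2_event` (NA where `o2 = 0`).
#' @export
midpoint_impute <- function(data) {
  stopifnot(inherits(data, "dic_data"))
  ep <- data$episodes
  t1_star <- ifelse(is.finite(ep$R1), (ep$L1 + ep$R1) / 2, ep$L1)
  t2_star <- ifelse(ep$o2 == 1,
                    ifelse(is.finite(ep$R2), (ep$L2 + ep$R2) / 2, ep$L2),
                    NA_real_)
  t2_event <- ifelse(ep$o2 == 1, as.numeric(is.finite(ep$R2)), NA_real_)
  list(t1_star = t1_star, t2_star = t2_star, t2_event = t2_event)
}

#' Midpoint-imputation comparator (a): impute T1 only
#'
#' Imputes T1 by its bracket midpoint (left endpoint when right-censored),
#' treats it as a fixed covariate, and fits the Cox model for the
#' interval-censored outcome T2 by NPMLE (the same EM engine with a single
#' degenerate T1 class per episode). Standard errors come from a
#' nonparametric bootstrap over subjects.
#'
#' @param data a [dic_data] object (independent setting).
#' @param boot_reps bootstrap replicates (0 to skip SEs).
#' @param seed optional seed for the bootstrap.
#' @param control a [dic_control()].
#' @return list of class `dic_comparator` with `coefficients`, `se`, `ci`,
#'   `fit`, `method = "midpoint_a"`.
#' @export
midpoint_a_fit <- function(data, boot_reps = 200L, seed = NULL,
                           control = dic_control()) {
  stopifnot(inherits(data, "dic_data"))
  imp <- midpoint_impute(data)
  keep <- data$episodes$o2 == 1
  sub <- subset_dic(data, keep)
  fit <- dic_fit(sub, control = control, fixed_t1 = imp$t1_star[keep])
  est <- fit$coefficients
  se <- rep(NA_real_, length(est))
  n_fail <- 0L
  if (boot_reps > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(sub$episodes)
    reps <- matrix(NA_real_, boot_reps, length(est))
    for (b in seq_len(boot_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      bd <- resample_dic(sub, idx)
      fb <- tryCatch(
        dic_fit(bd, control = control, fixed_t1 = imp$t1_star[keep][idx]),
        error = function(e) NULL)
      if (is.null(fb)) n_fail <- n_fail + 1L else reps[b, ] <- fb$coefficients
    }
    if (n_fail > 0.1 * boot_reps)
      stop("midpoint-(a) bootstrap: ", n_fail, " of ", boot_reps, " fits failed")
    se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  }
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  structure(list(coefficients = est, se = stats::setNames(se, names(est)),
                 ci = ci, fit = fit, method = "midpoint_a",
                 boot_reps = boot_reps, n_failed = n_fail),
            class = "dic_comparator")
}

#' Midpoint-imputation comparator (b): impute both event times
#'
#' Imputes both T1 and T2 by bracket midpoints (left endpoints when
#' right-censored; a right-censored T2 keeps event indicator 0) and fits a
#' standard right-censored Cox proportional hazards model by
#' Newton-Raphson on the partial likelihood with the Efron correction for
#' the ties that midpoint imputation creates. Model-based SEs come from the
#' partial-likelihood information.
#'
#' @param data a [dic_data] object (independent setting).
#' @return list of class `dic_comparator` with `coefficients`, `se`, `ci`,
#'   `method = "midpoint_b"`.
#' @export
midpoint_b_fit <- function(data) {
  stopifnot(inherits(data, "dic_data"))
  imp <- midpoint_impute(data)
  keep <- data$episodes$o2 == 1
  X <- cbind(imp$t1_star, data$z2)[keep, , drop = FALSE]
  cf <- cox_efron(imp$t2_star[keep], imp$t2_event[keep], X)
  est <- cf$coef
  names(est) <- c("beta1", if (ncol(data$z2))
    paste0("beta2_", seq_len(ncol(data$z2))))
  se <- sqrt(diag(cf$var))
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  structure(list(coefficients = est, se = stats::setNames(se, names(est)),
                 ci = ci, method = "midpoint_b", loglik = cf$loglik,
                 iter = cf$iter),
            class = "dic_comparator")
}

#' @export
print.dic_comparator <- function(x, ...) {
  cat("<dic_comparator>", x$method, "\n")
  print(cbind(estimate = x$coefficients, se = x$se, x$ci))
  invisible(x)
}

# subset/resample helpers keeping covariate rows aligned
subset_dic <- function(data, keep) {
  ep <- data$episodes[keep, , drop = FALSE]
  ep$cluster <- seq_len(nrow(ep)); ep$episode <- 1L
  dic_data(ep, data$z1[keep, , drop = FALSE], data$z2[keep, , drop = FALSE],
           clustered = FALSE)
}

resample_dic <- function(data, idx) {
  ep <- data$episodes[idx, , drop = FALSE]
  ep$cluster <- seq_along(idx); ep$episode <- 1L
  dic_data(ep, data$z1[idx, , drop = FALSE], data$z2[idx, , drop = FALSE],
           clustered = FALSE)
}

#' Cox partial-likelihood fit for right-censored data (Efron ties)
#'
#' Newton-Raphson maximization of the Cox partial likelihood with the Efron
#' approximation for tied event times. Used by the midpoint-imputation
#' comparator (b), where imputation produces many ties.
#'
#' @param time follow-up times.
#' @param status 1 = event, 0 = censored.
#' @param X covariate matrix.
#' @param max_iter,tol Newton controls.
#' @return list with `coef`, `var` (inverse information), `loglik`,
#'   `score0` (score at beta = 0), `iter`.
#' @export
cox_efron <- function(time, status, X, max_iter = 30L, tol = 1e-9) {
  X <- as.matrix(X)
  n <- length(time); p <- ncol(X)
  status <- rep_len(status, n)
  stopifnot(nrow(X) == n, p >= 1)
  ord <- order(time)
  time <- time[ord]; status <- status[ord]; X <- X[ord, , drop = FALSE]
  ev_times <- unique(time[status == 1])

  eval_pl <- function(beta) {
    lp <- drop(X %*% beta)
    w <- exp(lp)
    # reverse cumulative sums over the time-ordered sample
    rs0 <- rev(cumsum(rev(w)))
    rs1 <- apply(X * w, 2, function(col) rev(cumsum(rev(col))))
    rs1 <- matrix(rs1, ncol = p)
    ll <- 0; g <- rep(0, p); H <- matrix(0, p, p)
    for (tj in ev_times) {
      f <- match(TRUE, time >= tj)          # first index in the risk set
      Dj <- which(time == tj & status == 1)
      d <- length(Dj)
      S0 <- rs0[f]
      S1 <- rs1[f, ]
      wD <- w[Dj]
      S0D <- sum(wD)
      XD <- X[Dj, , drop = FALSE]
      S1D <- colSums(XD * wD)
      # second moments over risk set (computed locally; risk set = f..n)
      Xr <- X[f:n, , drop = FALSE]; wr <- w[f:n]
      S2 <- crossprod(Xr, Xr * wr)
      S2D <- crossprod(XD, XD * wD)
      ll <- ll + sum(lp[Dj])
      for (r in seq_len(d) - 1) {
        a <- r / d
        den <- S0 - a * S0D
        m1 <- (S1 - a * S1D) / den
        m2 <- (S2 - a * S2D) / den
        ll <- ll - log(den)
        g <- g - m1
        H <- H - (m2 - tcrossprod(m1))
      }
      g <- g + colSums(XD)
    }
    list(ll = ll, g = g, H = H)
  }

  beta <- rep(0, p)
  e0 <- eval_pl(beta)
  score0 <- e0$g
  ll_old <- e0$ll; g <- e0$g; H <- e0$H
  iter <- 0L
  repeat {
    iter <- iter + 1L
    step <- tryCatch(solve(-H, g), error = function(e)
      stop("singular partial-likelihood information"))
    sf <- 1
    repeat {
      cand <- beta + sf * step
      ec <- eval_pl(cand)
      if (is.finite(ec$ll) && ec$ll >= ll_old - 1e-12) break
      sf <- sf / 2
      if (sf < 1e-10) stop("partial-likelihood step failed (possible separation)")
    }
    if (any(abs(cand) > 50))
      stop("monotone partial likelihood (separation): coefficients diverge")
    done <- max(abs(ec$g)) < tol || max(abs(cand - beta)) < 1e-10
    beta <- cand; ll_old <- ec$ll; g <- ec$g; H <- ec$H
    if (done || iter >= max_iter) break
  }
  list(coef = beta, var = solve(-H), loglik = ll_old, score0 = score0,
       iter = iter)
}
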