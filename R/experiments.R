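#' Run a replicated simulation study
#'
#' Generates `reps` datasets from a scenario with replicate-indexed seed
#' substreams, fits the requested methods, and aggregates the usual
#' operating characteristics per parameter: bias (mean estimate minus
#' truth), empirical standard error (SD of estimates), average of the
#' standard-error estimates (sandwich-based in clustered mode), and the
#' coverage probability of the 95% normal-approximation confidence
#' intervals. Replicates whose fit fails are dropped from all metrics and
#' counted.
#'
#' @param study,scenario,n,rho passed to [dic_scenario()].
#' @param reps number of replicates.
#' @param seed master seed; each replicate receives its own seed drawn
#'   deterministically from it, so results do not depend on execution
#'   order.
#' @param methods subset of `"proposed"`, `"midpoint_a"`, `"midpoint_b"`.
#' @param fit_z1,fit_z2 names of generated covariate columns entering each
#'   fitted model (defaults to `"Z"`); used for the covariate
#'   misspecification study, e.g. `character(0)` omits the true covariate
#'   and `c("Z", "X")` adds the noise covariate.
#' @param boot_reps bootstrap replicates for the midpoint-(a) SEs.
#' @param control a [dic_control()].
#' @param keep_estimates if `TRUE`, attach the per-replicate estimate and
#'   SE arrays as attributes.
#' @return data.frame of class `dic_metrics` with one row per
#'   (method, parameter): `truth`, `bias`, `ese`, `ase`, `cp`, `cp_mc_se`
#'   (binomial Monte-Carlo error band of the coverage estimate), `n_reps`,
#'   `n_failed`.
#' @export
run_study <- function(study, scenario = "1.1", n = 200L, reps = 100L,
                      seed = 1L, methods = "proposed", rho = 0.5,
                      fit_z1 = "Z", fit_z2 = "Z", boot_reps = 100L,
                      control = dic_control(), keep_estimates = FALSE) {
  methods <- match.arg(methods, c("proposed", "midpoint_a", "midpoint_b"),
                       several.ok = TRUE)
  cfg <- dic_scenario(study, scenario, n, rho)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)

  truth_for <- function(nms, cols1, cols2) {
    tr <- numeric(length(nms)); names(tr) <- nms
    tr["beta1"] <- cfg$beta1
    for (j in seq_along(cols2))
      tr[paste0("beta2_", j)] <- if (cols2[j] == "Z") cfg$beta2 else 0
    gn <- grep("^gamma_", nms, value = TRUE)
    for (j in seq_along(gn))
      tr[gn[j]] <- if (cols1[j] == "Z") cfg$gamma else 0
    tr
  }

  res <- list()  # res[[method]]: list of est rows, se rows
  for (m in methods) res[[m]] <- list(est = list(), se = list(), fail = 0L)

  for (r in seq_len(reps)) {
    dat <- simulate_dic(cfg, rep_seeds[r])
    d2 <- dic_data_select(dat, fit_z1, fit_z2)
    for (m in methods) {
      out <- tryCatch(switch(m,
        proposed = {
          f <- dic_fit(d2, control = control)
          vr <- if (d2$clustered) sandwich_variance(f) else model_based_variance(f)
          list(est = f$coefficients, se = vr$se)
        },
        midpoint_a = {
          a <- midpoint_a_fit(d2, boot_reps = boot_reps, control = control)
          list(est = a$coefficients, se = a$se)
        },
        midpoint_b = {
          b <- midpoint_b_fit(d2)
          list(est = b$coefficients, se = b$se)
        }), error = function(e) NULL)
      if (is.null(out)) res[[m]]$fail <- res[[m]]$fail + 1L
      else {
        res[[m]]$est[[length(res[[m]]$est) + 1L]] <- out$est
        res[[m]]$se[[length(res[[m]]$se) + 1L]] <- out$se
      }
    }
  }

  rows <- list()
  est_store <- list()
  for (m in methods) {
    E <- do.call(rbind, res[[m]]$est)
    S <- do.call(rbind, res[[m]]$se)
    if (is.null(E) || nrow(E) == 0) next
    nms <- colnames(E)
    tr <- truth_for(nms, fit_z1, fit_z2)
    nr <- nrow(E)
    if (nr == 1L)
      warning("single replicate: empirical SE and coverage are undefined")
    cover <- abs(E - matrix(tr, nr, length(tr), byrow = TRUE)) <= 1.96 * S
    cp <- colMeans(cover)
    rows[[m]] <- data.frame(
      method = m, parameter = nms, truth = unname(tr),
      bias = unname(colMeans(E) - tr),
      ese = if (nr > 1) apply(E, 2, stats::sd) else NA_real_,
      ase = colMeans(S),
      cp = if (nr > 1) unname(cp) else NA_real_,
      cp_mc_se = if (nr > 1) unname(sqrt(cp * (1 - cp) / nr)) else NA_real_,
      n_reps = nr, n_failed = res[[m]]$fail,
      row.names = NULL)
    est_store[[m]] <- list(est = E, se = S)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  fail_frac <- max(vapply(methods, function(m) res[[m]]$fail, 0L)) / reps
  if (fail_frac > 0.05)
    warning(sprintf("%.0f%% of replicates failed for at least one method",
                    100 * fail_frac))
  if (keep_estimates) attr(out, "estimates") <- est_store
  attr(out, "config") <- cfg
  class(out) <- c("dic_metrics", "data.frame")
  out
}

#' @export
print.dic_metrics <- function(x, digits = 3, ...) {
  cfg <- attr(x, "config")
  if (!is.null(cfg))
    cat("Study:", cfg$study, " scenario", cfg$scenario, " n =", cfg$n,
        if (cfg$clustered) paste0(" rho = ", cfg$rho), "\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' The 16-scenario covariate-misspecification grid
#'
#' Declarative encoding of the robustness study: 2 monitoring frequencies
#' x 2 misspecification mechanisms (omit the true covariate Z, or add the
#' noise covariate X) x 4 model-specification combinations (both models
#' correct; T1 misspecified; T2 misspecified; both misspecified).
#'
#' @return data.frame with one row per scenario and list-columns `fit_z1`,
#'   `fit_z2` to pass to [run_study()] with `study = "study3a"`.
#' @export
study3a_grid <- function() {
  combos <- expand.grid(scenario = c("1.1", "2.2"),
                        mechanism = c("omit", "add"),
                        spec = c("both_correct", "t1_misspec",
                                 "t2_misspec", "both_misspec"),
                        stringsAsFactors = FALSE)
  mis <- function(mech) if (mech == "omit") character(0) else c("Z", "X")
  combos$fit_z1 <- mapply(function(mech, sp)
    if (sp %in% c("t1_misspec", "both_misspec")) mis(mech) else "Z",
    combos$mechanism, combos$spec, SIMPLIFY = FALSE)
  combos$fit_z2 <- mapply(function(mech, sp)
    if (sp %in% c("t2_misspec", "both_misspec")) mis(mech) else "Z",
    combos$mechanism, combos$spec, SIMPLIFY = FALSE)
  combos
}

# restrict a generated dataset to the covariate columns used in the fit
dic_data_select <- function(data, cols1, cols2) {
  pick <- function(z, cols) {
    if (is.null(cols)) return(z)
    miss <- setdiff(cols, colnames(z))
    if (length(miss)) stop("unknown covariate column(s): ",
                           paste(miss, collapse = ", "))
    z[, cols, drop = FALSE]
  }
  out <- dic_data(data$episodes, pick(data$z1, cols1), pick(data$z2, cols2),
                  clustered = data$clustered)
  attr(out, "truth") <- attr(data, "truth")
  out
}
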