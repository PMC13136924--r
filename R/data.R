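#' Episode-level doubly interval-censored data
#'
#' Container for episode-level data in which the covariate event time T1
#' (e.g. time to viral suppression after starting therapy) and the outcome
#' event time T2 (e.g. time to viral rebound after interrupting therapy) are
#' each only known to lie in a half-open bracketing interval `(L, R]`
#' determined by intermittent monitoring. `R = Inf` encodes right censoring
#' at `L`. In clustered data a participant (cluster) contributes several
#' suppression-rebound episodes; the rebound bracket of an episode may be
#' missing (`o2 = 0`), typically for the last episode when therapy was
#' resumed and never interrupted again.
#'
#' @param episodes data.frame with columns `cluster`, `episode`, `L1`, `R1`,
#'   `o2`, `L2`, `R2`. `R1`/`R2` may be `Inf`; `L2`/`R2` must be `NA` when
#'   `o2 = 0`. Times are on the study time scale (months in the motivating
#'   application), with each episode's own time origin.
#' @param z1 numeric matrix (or vector, or `NULL`) of covariates entering the
#'   T1 proportional-hazards model, one row per episode.
#' @param z2 covariates entering the T2 model, same shape rules as `z1`.
#' @param clustered logical; if `NULL`, inferred from repeated cluster ids.
#'
#' @return An object of class `dic_data`: a list with elements `episodes`,
#'   `z1`, `z2`, `clustered`.
#' @examples
#' ep <- data.frame(cluster = 1:2, episode = 1, L1 = c(1, 2), R1 = c(2, 3),
#'                  o2 = 1, L2 = c(0.5, 1), R2 = c(1.5, 2))
#' d <- dic_data(ep, z1 = c(0, 1), z2 = c(0, 1))
#' d
#' @export
dic_data <- function(episodes, z1 = NULL, z2 = NULL, clustered = NULL) {
  stopifnot(is.data.frame(episodes))
  need <- c("cluster", "episode", "L1", "R1", "o2", "L2", "R2")
  miss <- setdiff(need, names(episodes))
  if (length(miss))
    stop("episodes is missing mandatory column(s): ", paste(miss, collapse = ", "))
  ep <- episodes[need]
  n <- nrow(ep)
  if (n == 0L) stop("dataset contains zero episodes")

  as_covmat <- function(z, what) {
    if (is.null(z)) return(matrix(numeric(0), nrow = n, ncol = 0))
    if (is.vector(z) && !is.list(z)) z <- matrix(z, ncol = 1)
    z <- as.matrix(z)
    if (!is.numeric(z)) stop(what, " covariates must be numeric")
    if (anyNA(z)) stop(what, " covariates contain missing values")
    if (nrow(z) != n) stop(what, " has ", nrow(z), " rows; expected ", n)
    z
  }
  z1 <- as_covmat(z1, "z1"); z2 <- as_covmat(z2, "z2")

  bad_row <- function(cond, msg) {
    if (any(cond)) stop(msg, " in row(s): ",
                        paste(utils::head(which(cond), 5), collapse = ", "))
  }
  bad_row(!is.finite(ep$L1) | ep$L1 < 0, "L1 must be finite and >= 0")
  bad_row(is.na(ep$R1) | ep$R1 <= ep$L1, "malformed T1 interval (R1 <= L1)")
  bad_row(!ep$o2 %in% c(0, 1), "o2 must be 0 or 1")
  i1 <- ep$o2 == 1
  bad_row(i1 & (!is.finite(ep$L2) | ep$L2 < 0), "L2 must be finite and >= 0 when o2 = 1")
  bad_row(i1 & (is.na(ep$R2) | ep$R2 <= ep$L2), "malformed T2 interval (R2 <= L2)")
  ep$L2[!i1] <- NA_real_; ep$R2[!i1] <- NA_real_

  # episode indices within each cluster must be 1..ni
  sp <- split(ep$episode, ep$cluster)
  ok <- vapply(sp, function(j) identical(sort(as.integer(j)), seq_along(j)), logical(1))
  if (!all(ok))
    stop("episode indices within cluster(s) ",
         paste(utils::head(names(sp)[!ok], 5), collapse = ", "),
         " are not 1..n_i without gaps")
  if (is.null(clustered)) clustered <- anyDuplicated(ep$cluster) > 0
  if (!clustered && anyDuplicated(ep$cluster) > 0)
    stop("clustered = FALSE but some cluster ids appear more than once")

  structure(list(episodes = ep, z1 = z1, z2 = z2, clustered = clustered),
            class = "dic_data")
}

#' @export
print.dic_data <- function(x, ...) {
  ep <- x$episodes
  cat("<dic_data> ", nrow(ep), " episodes, ",
      length(unique(ep$cluster)), " cluster(s)",
      if (x$clustered) " [clustered]", "\n", sep = "")
  cat("  T1: ", sum(is.finite(ep$R1)), " interval-censored, ",
      sum(!is.finite(ep$R1)), " right-censored\n", sep = "")
  cat("  T2: ", sum(ep$o2 == 1 & is.finite(ep$R2)), " interval-censored, ",
      sum(ep$o2 == 1 & !is.finite(ep$R2)), " right-censored, ",
      sum(ep$o2 == 0), " unobserved (o2 = 0)\n", sep = "")
  cat("  covariates: p1 = ", ncol(x$z1), ", p2 = ", ncol(x$z2), "\n", sep = "")
  invisible(x)
}

#' Read episode data from a delimited text file
#'
#' Reads a CSV file (header row required) into a [dic_data] object. Right
#' censoring in the `R1`/`R2` columns may be encoded as the literal token
#' `"inf"` (any capitalisation) or an empty field. Rows with `o2 = 0` have
#' their `L2`/`R2` fields ignored.
#'
#' @param path file path.
#' @param schema named list mapping the roles `cluster`, `episode`, `L1`,
#'   `R1`, `o2`, `L2`, `R2`, `z1`, `z2` to column names in the file; `z1` and
#'   `z2` may each name several columns (or be absent for no covariates).
#' @return A [dic_data] object.
#' @seealso [write_dic_data()]
#' @examples
#' # fully synthetic cohort-shaped demo data (82 participants, repeated
#' # suppression-rebound episodes; no real participant data)
#' path <- system.file("extdata", "zphi_synthetic.csv", package = "dicph")
#' d <- read_dic_data(path, schema = list(z1 = "female", z2 = "female"))
#' dic_validate(d)
#' @export
read_dic_data <- function(path, schema = list()) {
  def <- list(cluster = "cluster", episode = "episode", L1 = "L1", R1 = "R1",
              o2 = "o2", L2 = "L2", R2 = "R2", z1 = character(), z2 = character())
  schema <- utils::modifyList(def, schema)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  for (role in c("cluster", "episode", "L1", "R1", "o2"))
    if (!schema[[role]] %in% names(raw))
      stop("missing mandatory column '", schema[[role]], "' in ", path)

  num <- function(col, allow_inf = FALSE, allow_na = FALSE) {
    v <- trimws(raw[[col]])
    if (allow_inf) v[v == "" | tolower(v) == "inf"] <- "Inf"
    if (allow_na) v[v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out) & !is.na(v)
    if (!allow_na && any(bad))
      stop("non-numeric value in column '", col, "', row(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    out
  }
  o2 <- num(schema$o2)
  has_t2 <- schema$L2 %in% names(raw) && schema$R2 %in% names(raw)
  if (any(o2 == 1) && !has_t2)
    stop("columns '", schema$L2, "'/'", schema$R2, "' required when any o2 = 1")
  L2 <- if (has_t2) num(schema$L2, allow_na = TRUE) else rep(NA_real_, nrow(raw))
  R2 <- if (has_t2) num(schema$R2, allow_inf = TRUE) else rep(NA_real_, nrow(raw))
  L2[o2 == 0] <- NA_real_; R2[o2 == 0] <- NA_real_

  getz <- function(cols, what) {
    if (!length(cols)) return(NULL)
    miss <- setdiff(cols, names(raw))
    if (length(miss)) stop("missing ", what, " column(s): ", paste(miss, collapse = ", "))
    m <- sapply(cols, function(cl) num(cl), simplify = TRUE)
    m <- matrix(m, nrow = nrow(raw), dimnames = list(NULL, cols))
    m
  }
  ep <- data.frame(cluster = raw[[schema$cluster]],
                   episode = num(schema$episode),
                   L1 = num(schema$L1), R1 = num(schema$R1, allow_inf = TRUE),
                   o2 = o2, L2 = L2, R2 = R2)
  dic_data(ep, z1 = getz(schema$z1, "z1"), z2 = getz(schema$z2, "z2"))
}

#' Write episode data to CSV
#'
#' Inverse of [read_dic_data()]: infinite right endpoints are written as
#' `"inf"` and unobserved T2 fields as empty strings, so that a write/read
#' round trip reproduces the dataset exactly.
#'
#' @param data a [dic_data] object.
#' @param path output file path.
#' @export
write_dic_data <- function(data, path) {
  stopifnot(inherits(data, "dic_data"))
  ep <- data$episodes
  fmt <- function(v) {
    out <- vapply(v, function(x) {
      if (is.na(x)) "" else if (is.infinite(x)) "inf" else
        format(x, digits = 17, scientific = FALSE, trim = TRUE)
    }, character(1))
    out
  }
  out <- data.frame(cluster = ep$cluster, episode = ep$episode,
                    L1 = fmt(ep$L1), R1 = fmt(ep$R1), o2 = ep$o2,
                    L2 = fmt(ep$L2), R2 = fmt(ep$R2),
                    check.names = FALSE, stringsAsFactors = FALSE)
  addz <- function(z, prefix) {
    if (ncol(z) == 0) return(NULL)
    cn <- colnames(z)
    if (is.null(cn)) cn <- paste0(prefix, seq_len(ncol(z)))
    m <- as.data.frame(apply(z, 2, fmt, simplify = FALSE))
    names(m) <- cn
    m
  }
  z1df <- addz(data$z1, "z1_"); z2df <- addz(data$z2, "z2_")
  if (!is.null(z1df)) out <- cbind(out, z1df)
  if (!is.null(z2df)) out <- cbind(out, z2df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Support grid of candidate jump points for the baseline hazards
#'
#' The nonparametric maximum likelihood estimates of the two cumulative
#' baseline hazards are step functions jumping only at the pooled unique
#' finite bracket endpoints: `t1_points` collects endpoints of all T1
#' brackets, `t2_points` those of T2 brackets over episodes with `o2 = 1`.
#' Zero and infinity are excluded (time 0 carries no hazard increment by
#' convention). Endpoints equal within `tol` are merged to guard against
#' floating-point noise.
#'
#' @param data a [dic_data] object.
#' @param tol merge tolerance for numerically tied endpoints.
#' @return An object of class `dic_grid`: list with `t1_points`, `t2_points`.
#' @export
build_support_grid <- function(data, tol = 1e-12) {
  stopifnot(inherits(data, "dic_data"))
  ep <- data$episodes
  if (nrow(ep) == 0L) stop("dataset contains zero episodes")
  merge_pts <- function(x) {
    x <- sort(unique(x[is.finite(x) & x > 0]))
    if (length(x) > 1) x <- x[c(TRUE, diff(x) > tol)]
    x
  }
  t1 <- merge_pts(c(ep$L1, ep$R1))
  i1 <- ep$o2 == 1
  if (!any(i1)) stop("no T2 information: all episodes have o2 = 0")
  t2 <- merge_pts(c(ep$L2[i1], ep$R2[i1]))
  if (length(t1) < 1 || length(t2) < 1)
    stop("degenerate dataset: empty support grid")
  structure(list(t1_points = t1, t2_points = t2), class = "dic_grid")
}

#' @export
print.dic_grid <- function(x, ...) {
  cat("<dic_grid> m1 =", length(x$t1_points), "T1 jump points,",
      "m2 =", length(x$t2_points), "T2 jump points\n")
  invisible(x)
}

#' Export a fitted step-function baseline hazard as a data frame
#'
#' @param time,increment numeric vectors of jump points and jump sizes.
#' @return data.frame with columns `time`, `increment`, `cumulative`.
#' @keywords internal
baseline_table <- function(time, increment) {
  data.frame(time = time, increment = increment, cumulative = cumsum(increment))
}

#' Summarise censoring patterns and cluster structure
#'
#' Report-only validation: re-checks the container invariants and tabulates
#' interval- versus right-censored brackets for each event, the prevalence of
#' observed rebound brackets, and the episode-count distribution across
#' clusters.
#'
#' @param data a [dic_data] object.
#' @return An object of class `dic_report` (a list of summary quantities).
#' @export
dic_validate <- function(data) {
  stopifnot(inherits(data, "dic_data"))
  # re-run constructor checks
  dic_data(data$episodes, data$z1, data$z2, data$clustered)
  ep <- data$episodes
  n <- nrow(ep)
  epc <- table(table(ep$cluster))
  structure(list(
    n_episodes = n,
    n_clusters = length(unique(ep$cluster)),
    t1_right_censored = sum(!is.finite(ep$R1)) / n,
    t2_observed = mean(ep$o2 == 1),
    t2_right_censored = if (any(ep$o2 == 1))
      sum(ep$o2 == 1 & !is.finite(ep$R2)) / sum(ep$o2 == 1) else NA_real_,
    episodes_per_cluster = epc,
    p1 = ncol(data$z1), p2 = ncol(data$z2),
    clustered = data$clustered), class = "dic_report")
}

#' @export
print.dic_report <- function(x, ...) {
  cat("<dic_report>\n")
  cat("  episodes:", x$n_episodes, " clusters:", x$n_clusters, "\n")
  cat(sprintf("  T1 right-censoring fraction: %.4f\n", x$t1_right_censored))
  cat(sprintf("  T2 observed (o2 = 1) fraction: %.4f\n", x$t2_observed))
  if (!is.na(x$t2_right_censored))
    cat(sprintf("  T2 right-censoring fraction (among o2 = 1): %.4f\n",
                x$t2_right_censored))
  cat("  episodes per cluster:\n")
  print(x$episodes_per_cluster)
  invisible(x)
}

# ---- internal: flatten a dataset + grid for the C++ core -------------------

snap_to_grid <- function(x, grid, tol = 1e-9) {
  fin <- is.finite(x)
  if (!any(fin) || length(grid) == 0) return(x)
  i <- findInterval(x[fin], grid)
  xf <- x[fin]
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(grid))
  dlo <- abs(grid[lo] - xf); dhi <- abs(grid[hi] - xf)
  use_lo <- dlo <= dhi
  cand <- ifelse(use_lo, grid[lo], grid[hi])
  dist <- pmin(dlo, dhi)
  xf[dist < tol] <- cand[dist < tol]
  x[fin] <- xf
  x
}

pack_dic <- function(data, grid, fixed_t1 = NULL) {
  ep <- data$episodes
  n <- nrow(ep)
  fixed <- !is.null(fixed_t1)
  t1 <- grid$t1_points; t2 <- grid$t2_points
  m1 <- length(t1); m2 <- length(t2)

  L2 <- snap_to_grid(ep$L2, t2); R2 <- snap_to_grid(ep$R2, t2)
  o2 <- as.integer(ep$o2)
  kL <- integer(n); kR <- integer(n)
  i1 <- o2 == 1L
  kL[i1] <- findInterval(L2[i1], t2)
  kRt <- rep(-1L, sum(i1))
  fin2 <- is.finite(R2[i1])
  kRt[fin2] <- findInterval(R2[i1][fin2], t2)
  kR[i1] <- kRt
  kL[!i1] <- 0L; kR[!i1] <- -2L

  if (fixed) {
    sup_ptr <- integer(n + 1); sup_idx <- integer(0)
    if (length(fixed_t1) != n || any(!is.finite(fixed_t1)))
      stop("fixed_t1 must be a finite numeric vector with one value per episode")
    t1fix <- as.numeric(fixed_t1)
    m1 <- 0L; t1 <- numeric(0)
  } else {
    L1 <- snap_to_grid(ep$L1, t1); R1 <- snap_to_grid(ep$R1, t1)
    sup <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- which(t1 > L1[i] & t1 <= R1[i]) - 1L
      if (!is.finite(R1[i])) cls <- c(cls, m1)  # residual tail class
      if (!length(cls))
        stop("episode ", i, ": T1 bracket contains no support point")
      sup[[i]] <- cls
    }
    len <- lengths(sup)
    sup_ptr <- c(0L, cumsum(len))
    sup_idx <- as.integer(unlist(sup, use.names = FALSE))
    t1fix <- numeric(0)
  }
  clus <- as.integer(factor(ep$cluster, levels = unique(ep$cluster))) - 1L
  list(n = n, p1 = if (fixed) 0L else ncol(data$z1), p2 = ncol(data$z2),
       m1 = m1, m2 = m2, nclust = max(clus) + 1L,
       z1 = if (fixed) matrix(numeric(0), n, 0) else unname(data$z1),
       z2 = unname(data$z2),
       t1 = t1, t2 = t2,
       sup_ptr = sup_ptr, sup_idx = sup_idx,
       o2 = o2, kL = kL, kR = kR, cluster = clus,
       fixed = fixed, t1fix = t1fix)
}
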