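test_that("CSV parsing handles the interval encodings", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("cluster,episode,L1,R1,o2,L2,R2,z",
               "1,1,2.0,3.5,1,1.0,2.2,1",
               "2,1,2.0,inf,1,1.0,2.2,0",
               "3,1,1.0,2.0,0,,,1",
               "4,1,0.5,1.5,1,0.3,INF,0"), f)
  d <- read_dic_data(f, schema = list(z1 = "z", z2 = "z"))
  ep <- d$episodes
  expect_equal(nrow(ep), 4)
  expect_equal(ep$L1[1], 2.0); expect_equal(ep$R1[1], 3.5)
  expect_equal(ep$R1[2], Inf)                 # "inf" token
  expect_true(is.na(ep$L2[3]) && is.na(ep$R2[3]))  # o2 = 0, empty fields
  expect_equal(ep$R2[4], Inf)                 # case-insensitive
  expect_equal(ncol(d$z1), 1)
})

test_that("malformed rows are rejected with row-identifying messages", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("cluster,episode,L1,R1,o2,L2,R2",
               "1,1,3.0,2.0,0,,"), f)
  expect_error(read_dic_data(f), "row.*1")
  ep <- data.frame(cluster = 1, episode = 1, L1 = -1, R1 = 2, o2 = 0,
                   L2 = NA, R2 = NA)
  expect_error(dic_data(ep), "L1")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("cluster,episode,L1,o2", "1,1,1,0"), f2)
  expect_error(read_dic_data(f2), "mandatory")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("cluster,episode,L1,R1,o2,L2,R2,z",
               "1,1,1,2,0,,,abc"), f3)
  expect_error(read_dic_data(f3, schema = list(z1 = "z")), "non-numeric")
})

test_that("write/read round trip reproduces brackets and covariates exactly", {
  d <- mixed_data()
  f <- tempfile(fileext = ".csv")
  write_dic_data(d, f)
  d2 <- read_dic_data(f, schema = list(z1 = "z1_1", z2 = "z2_1"))
  expect_equal(d2$episodes$L1, d$episodes$L1)
  expect_equal(d2$episodes$R1, d$episodes$R1)
  expect_equal(d2$episodes$L2, d$episodes$L2)
  expect_equal(d2$episodes$R2, d$episodes$R2)
  expect_equal(unname(d2$z1), unname(d$z1))
  # also with irrational times
  set.seed(4)
  d3 <- simulate_dic(dic_scenario("study1", n = 25), seed = 9)
  f3 <- tempfile(fileext = ".csv")
  write_dic_data(d3, f3)
  d4 <- read_dic_data(f3, schema = list(z1 = "Z", z2 = "Z"))
  expect_identical(d4$episodes$L1, d3$episodes$L1)
  expect_identical(d4$episodes$R2, d3$episodes$R2)
})

test_that("support grid collects unique finite endpoints", {
  ep <- data.frame(cluster = 1:3, episode = 1,
                   L1 = c(0, 1, 0), R1 = c(1, 2, 2),
                   o2 = 1, L2 = c(0, 0, 1), R2 = c(1, 1, 2))
  d <- dic_data(ep)
  g <- build_support_grid(d)
  expect_equal(g$t1_points, c(1, 2))
  expect_equal(g$t2_points, c(1, 2))

  # right-censored episode contributes only its finite endpoint
  ep2 <- rbind(ep, data.frame(cluster = 4, episode = 1, L1 = 3, R1 = Inf,
                              o2 = 0, L2 = NA, R2 = NA))
  g2 <- build_support_grid(dic_data(ep2))
  expect_equal(g2$t1_points, c(1, 2, 3))

  # all-o2=0 dataset has no T2 information
  ep3 <- ep; ep3$o2 <- 0; ep3$L2 <- NA; ep3$R2 <- NA
  expect_error(build_support_grid(dic_data(ep3)), "o2")

  # endpoints equal within 1e-12 are merged
  ep4 <- ep
  ep4$R1[1] <- 1 + 1e-13
  g4 <- build_support_grid(dic_data(ep4))
  expect_equal(length(g4$t1_points), 2)
})

test_that("grid construction is idempotent and order-invariant", {
  d <- simulate_dic(dic_scenario("study2", "1.2", n = 60), seed = 3)
  g <- build_support_grid(d)
  perm <- sample(nrow(d$episodes))
  ep <- d$episodes[perm, ]
  ep$cluster <- seq_len(nrow(ep))
  d2 <- dic_data(ep, d$z1[perm, , drop = FALSE], d$z2[perm, , drop = FALSE])
  g2 <- build_support_grid(d2)
  expect_identical(g$t1_points, g2$t1_points)
  expect_identical(g$t2_points, g2$t2_points)
  expect_identical(build_support_grid(d)$t1_points, g$t1_points)
})

test_that("validation report summarises censoring and cluster structure", {
  d <- mixed_data()
  rep <- dic_validate(d)
  expect_equal(rep$n_episodes, 8)
  expect_equal(rep$t1_right_censored, 1 / 8)
  expect_equal(rep$t2_observed, 7 / 8)
  expect_equal(rep$t2_right_censored, 2 / 7)

  # all-finite brackets give zero right censoring
  ep <- data.frame(cluster = 1:3, episode = 1, L1 = 0:2, R1 = 1:3,
                   o2 = 1, L2 = 0:2, R2 = 1:3)
  expect_equal(dic_validate(dic_data(ep))$t1_right_censored, 0)

  # clustered generator: episode-count histogram matches the configured pmf
  dcl <- simulate_dic(dic_scenario("clustered", n = 4000, rho = 0), seed = 5)
  repc <- dic_validate(dcl)
  frac <- as.numeric(repc$episodes_per_cluster) / repc$n_clusters
  expect_lt(max(abs(frac - c(0.3, 0.5, 0.2))), 0.03)
})
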