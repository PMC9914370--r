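unit_bounds <- function(p, names = paste0("x", seq_len(p))) {
  data.frame(name = names, low = 0, high = 1, stringsAsFactors = FALSE)
}

test_that("LHS is exactly stratified: one draw per equal-probability stratum", {
  d <- lhs_sample(unit_bounds(1), n = 4, seed = 3)
  q <- sort(d$samples[, 1])
  expect_true(all(q > c(0, 0.25, 0.5, 0.75) & q < c(0.25, 0.5, 0.75, 1)))
  # holds per column for a larger design too
  d2 <- lhs_sample(unit_bounds(5), n = 50, seed = 3)
  for (j in 1:5) {
    strata <- findInterval(sort(d2$samples[, j]), seq(0, 1, by = 1 / 50),
                           rightmost.closed = TRUE)
    expect_identical(strata, 1:50)
  }
})

test_that("LHS respects bounds and is seed-reproducible", {
  b <- data.frame(name = c("a", "b"), low = c(10, -2), high = c(20, -1))
  d1 <- lhs_sample(b, n = 100, seed = 11)
  d2 <- lhs_sample(b, n = 100, seed = 11)
  d3 <- lhs_sample(b, n = 100, seed = 12)
  expect_identical(d1$samples, d2$samples)
  expect_false(identical(d1$samples, d3$samples))
  expect_true(all(d1$samples[, "a"] >= 10 & d1$samples[, "a"] <= 20))
  expect_true(all(d1$samples[, "b"] >= -2 & d1$samples[, "b"] <= -1))
  expect_error(lhs_sample(data.frame(name = "a", low = 1, high = 1), 10),
               "degenerate")
  expect_error(lhs_sample(unit_bounds(2), n = 1), "n must be")
})

test_that("LHS margins are uniform on their bounds (KS at n = 500, p = 45)", {
  b <- ovt_param_bounds()
  d <- lhs_sample(rbind(b, data.frame(name = "dummy", low = 0, high = 1)),
                  n = 500, seed = 2024)
  crit <- 1.358 / sqrt(500)  # 5% two-sided KS critical value, large-sample
  ks <- vapply(seq_len(ncol(d$samples)), function(j) {
    lo <- d$bounds$low[j]; hi <- d$bounds$high[j]
    u <- (d$samples[, j] - lo) / (hi - lo)
    max(abs(sort(u) - (seq_len(500) - 0.5) / 500)) + 0.5 / 500
  }, numeric(1))
  expect_gte(sum(ks < crit), 44)  # at least 44 of 46 columns pass
})

test_that("PRCC recovers perfect monotone association and the null case", {
  set.seed(5)
  d <- lhs_sample(unit_bounds(4, c("x1", "x2", "x3", "dummy")), n = 500,
                  seed = 5)
  y <- exp(3 * d$samples[, "x1"])  # monotone in x1 only
  r <- prcc(d, y)
  expect_gte(r$prcc[r$parameter == "x1"], 0.99)
  expect_true(all(abs(r$prcc) <= 1))
  # output independent of every column: all coefficients comparable to dummy
  y0 <- rnorm(500)
  r0 <- prcc(d, y0)
  expect_true(all(abs(r0$prcc) < 0.2))
})

test_that("PRCC matches the correlation-matrix-inversion oracle to 1e-10", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 120
    X <- cbind(x1 = runif(n), x2 = runif(n), x3 = 0, dummy = runif(n))
    X[, "x3"] <- 0.8 * X[, "x1"] + 0.2 * runif(n)  # correlated regressor
    y <- 2 * X[, "x1"] - X[, "x2"] + 0.1 * rnorm(n)
    d <- structure(list(parameter_names = colnames(X),
                        bounds = data.frame(name = colnames(X), low = 0,
                                            high = 1),
                        samples = X, seed = rep, n = n),
                   class = "ovt_lhs")
    got <- prcc(d, y)
    want <- oracle_prcc(X, y)
    expect_equal(got$prcc, as.numeric(want), tolerance = 1e-10)
    expect_gt(got$prcc[got$parameter == "x1"], 0)
    expect_lt(got$prcc[got$parameter == "x2"], 0)
    expect_lt(abs(got$prcc[got$parameter == "dummy"]),
              min(abs(got$prcc[got$parameter %in% c("x1", "x2")])))
  }
})

test_that("PRCC is invariant to parameter column order", {
  set.seed(13)
  d <- lhs_sample(unit_bounds(4, c("x1", "x2", "x3", "dummy")), n = 200,
                  seed = 13)
  y <- d$samples[, "x1"] - 2 * d$samples[, "x2"] + rnorm(200, sd = 0.1)
  r1 <- prcc(d, y)
  perm <- c(3, 1, 4, 2)
  d2 <- d
  d2$samples <- d$samples[, perm]
  d2$parameter_names <- d$parameter_names[perm]
  d2$bounds <- d$bounds[perm, ]
  r2 <- prcc(d2, y)
  m <- match(r1$parameter, r2$parameter)
  expect_equal(r1$prcc, r2$prcc[m], tolerance = 1e-12)
})

test_that("dummy PRCC stays a small-magnitude floor across seeded repeats", {
  # synthetic outputs with realistic signal; the dummy has no effect by
  # construction, so its |PRCC| must stay well below the active parameters
  for (seed in 1:20) {
    d <- lhs_sample(unit_bounds(6, c(paste0("x", 1:5), "dummy")), n = 500,
                    seed = seed)
    y <- exp(d$samples[, "x1"]) - 3 * d$samples[, "x2"] +
      d$samples[, "x3"]^2 + rnorm(500, sd = 0.3)
    r <- prcc(d, y)
    expect_lt(abs(attr(r, "dummy_value")), 0.15)
  }
})

test_that("PRCC input contracts: sizes, NA handling, degenerate columns", {
  d <- lhs_sample(unit_bounds(3, c("x1", "x2", "dummy")), n = 30, seed = 1)
  expect_error(prcc(d, rnorm(10)), "length")
  y <- rnorm(30); y[c(3, 7)] <- NA
  r <- prcc(d, y)
  expect_identical(attr(r, "n_dropped"), 2L)
  expect_identical(attr(r, "n_used"), 28L)
  dd <- d; dd$samples[, "x2"] <- 1
  expect_error(prcc(dd, rnorm(30)), "x2")
  expect_error(prcc(d, rnorm(30)[rep(1, 30)] * NA), "insufficient|NA")
  small <- lhs_sample(unit_bounds(3, c("x1", "x2", "dummy")), n = 4, seed = 1)
  expect_error(prcc(small, rnorm(4)), "insufficient")
})

test_that("cohort GSA is seed-reproducible and structurally sane at small n", {
  g1 <- gsa_run("ovt_only", n = 60, seed = 77)
  g2 <- gsa_run("ovt_only", n = 60, seed = 77)
  expect_identical(g1$prcc, g2$prcc)
  expect_true(all(abs(g1$prcc) <= 1))
  expect_identical(nrow(g1), 46L)  # 45 model parameters + dummy
  # the restricted design samples only virus-related parameters + dummy
  g3 <- gsa_run("ov_params_only", n = 60, seed = 77)
  expect_identical(nrow(g3), 11L)
  expect_true(all(c("d_v", "a_v", "b_t", "dummy") %in% g3$parameter))
})
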