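# The untreated-growth figure 1.8630e9 is the published day-18 validation
# value; the solver must land within 1% of it (it lands much closer).
test_that("untreated tumor growth reproduces the day-18 validation size", {
  tr <- ovt_simulate(schedule = ovt_schedule(0, 0), start_day = 8,
                     end_day = 18)
  tu <- state_at(tr, 18)[["Tu"]]
  expect_equal(tu, 1.8630e9, tolerance = 1e-2)
  expect_false(eradicated(tr, 18))
})

test_that("a source-free zero state stays identically zero", {
  p <- ovt_params(s_n = 0)
  zero <- stats::setNames(numeric(9),
                          c("Tu", "Ti", "V", "X", "Y", "C", "W", "Z", "N"))
  tr <- ovt_simulate(params = p, schedule = ovt_schedule(0, 0), init = zero,
                     start_day = 8, end_day = 18)
  expect_true(all(as.matrix(tr[, -1]) == 0))
})

test_that("trajectories carry no NaN/Inf, start at init, stay near-nonnegative", {
  for (arm in list(c(0, 0), c(2e6, 0), c(2e6, 0.76))) {
    tr <- ovt_simulate(schedule = ovt_schedule(arm[1], arm[2]),
                       end_day = 30)
    m <- as.matrix(tr[, -1])
    expect_true(all(is.finite(m)))
    expect_true(all(m >= -1e-8 * 1000))  # within solver undershoot
    expect_equal(as.numeric(tr[1, -1]), as.numeric(ovt_init()))
    expect_true(all(diff(tr$day) > 0))
    expect_true(all(8:30 %in% tr$day))  # every integer day on the grid
  }
})

test_that("solver self-convergence: tightening rtol moves day-18 Tu by < 1e-4", {
  sched <- ovt_schedule(2e6, 0.76)
  a <- state_at(ovt_simulate(schedule = sched, rtol = 1e-8, atol = 1e-8),
                18)[["Tu"]]
  b <- state_at(ovt_simulate(schedule = sched, rtol = 1e-10, atol = 1e-10),
                18)[["Tu"]]
  expect_lt(abs(a - b) / abs(b), 1e-4)
})

test_that("grid refinement leaves day-18 compartments essentially unchanged", {
  sched <- ovt_schedule(2e6, 0.76)
  a <- state_at(ovt_simulate(schedule = sched, grid_step = 0.25), 18)
  b <- state_at(ovt_simulate(schedule = sched, grid_step = 0.125), 18)
  rel <- abs(a - b) / pmax(abs(b), 1e-6)
  expect_true(all(rel < 1e-6))
})

test_that("BDF agrees with a high-order explicit method on a short horizon", {
  sched <- ovt_schedule(2e6, 0.76)
  stiff <- ovt_simulate(schedule = sched, end_day = 10, rtol = 1e-10,
                        atol = 1e-10)
  f <- function(t, y, p) list(ovtsim:::.ovt_deriv(y, p, 2e6, 0.76))
  exp45 <- deSolve::ode(ovt_init(), times = c(8, 10), func = f,
                        parms = ovt_params(), method = "ode45",
                        rtol = 1e-10, atol = 1e-10, maxsteps = 1e6)
  a <- state_at(stiff, 10)
  b <- exp45[2, -1]
  rel <- abs(a - b) / pmax(abs(b), 1)
  expect_true(all(rel < 1e-5))
})

test_that("time-translation invariance: shifting schedule and horizon together", {
  base <- ovt_simulate(schedule = ovt_schedule(2e6, 0.76, start_day = 8),
                       start_day = 8, end_day = 18)
  shifted <- ovt_simulate(schedule = ovt_schedule(2e6, 0.76, start_day = 11),
                          start_day = 11, end_day = 21)
  for (off in c(2, 5.5, 10)) {
    a <- state_at(base, 8 + off)
    b <- state_at(shifted, 11 + off)
    expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-6)
  }
})

test_that("state_at is exact on grid, bounded between neighbors off grid", {
  tr <- ovt_simulate(schedule = ovt_schedule(0, 0), end_day = 18)
  expect_identical(as.numeric(state_at(tr, 8)), as.numeric(ovt_init()))
  g <- which(tr$day == 12)
  expect_equal(as.numeric(state_at(tr, 12)), as.numeric(tr[g, -1]))
  # between two grid points each component lies between its neighbors
  mid <- (tr$day[g] + tr$day[g + 1]) / 2
  v <- state_at(tr, mid)
  lohi <- rbind(pmin(as.numeric(tr[g, -1]), as.numeric(tr[g + 1, -1])),
                pmax(as.numeric(tr[g, -1]), as.numeric(tr[g + 1, -1])))
  expect_true(all(v >= lohi[1, ] - 1e-12 & v <= lohi[2, ] + 1e-12))
  expect_error(state_at(tr, 31), "within")
})

test_that("eradication uses a strict one-cell threshold", {
  tr <- ovt_simulate(schedule = ovt_schedule(0, 0), end_day = 18)
  fake <- tr
  fake$Tu[fake$day == 18] <- 1.0
  expect_false(eradicated(fake, 18))
  fake$Tu[fake$day == 18] <- 1 - 1e-9
  expect_true(eradicated(fake, 18))
})

test_that("compiled and interpreted right-hand sides integrate identically", {
  sched <- ovt_schedule(2e6, 0.76)
  a <- ovt_simulate(schedule = sched, end_day = 18, compiled = TRUE)
  b <- ovt_simulate(schedule = sched, end_day = 18, compiled = FALSE)
  expect_equal(as.matrix(a[, -1]), as.matrix(b[, -1]), tolerance = 1e-12)
  # and under the alternative proliferation form
  a2 <- ovt_simulate(schedule = sched, end_day = 12, x_prolif = "x_scaled")
  b2 <- ovt_simulate(schedule = sched, end_day = 12, x_prolif = "x_scaled",
                     compiled = FALSE)
  expect_equal(as.matrix(a2[, -1]), as.matrix(b2[, -1]), tolerance = 1e-12)
})

test_that("degenerate horizons and invalid initial states are rejected", {
  expect_error(ovt_simulate(end_day = 8, start_day = 8), "end_day")
  bad <- ovt_init(); bad["Tu"] <- -5
  expect_error(ovt_simulate(init = bad), "Tu")
})
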