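test_that("GL binomial coefficients follow the recurrence and closed form", {
  expect_equal(gl_coefficients(1, 4), c(1, -1, 0, 0, 0))
  cj <- gl_coefficients(0.9, 3)
  expect_identical(cj[1], 1)                      # c_0 = 1 for any order
  expect_equal(cj[2:4], c(-0.9, -0.045, -0.0165), tolerance = 1e-15)
  # closed form (-1)^j C(q, j) for j <= 50
  for (q in c(0.3, 0.7, 0.9)) {
    cj <- gl_coefficients(q, 50)
    closed <- vapply(0:50, function(j) gl_coef_closed(q, j), 0.0)
    expect_equal(cj, closed, tolerance = 1e-12)
  }
  expect_error(gl_coefficients(1.2, 5), "q")
  expect_error(gl_coefficients(0, 5), "q")
})

test_that("GL partial sums decrease monotonically toward zero", {
  cj <- gl_coefficients(0.9, 2000)
  ps <- cumsum(cj)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0))
  expect_lt(ps[2001], 0.002)    # ~ K^{-q} / Gamma(1 - q)
})

test_that("Mittag-Leffler matches the exponential at alpha = 1 and the series oracle", {
  expect_equal(mittag_leffler(1, -1), exp(-1), tolerance = 1e-12)
  expect_equal(mittag_leffler(1, c(0.3, -2.5)), exp(c(0.3, -2.5)),
               tolerance = 1e-12)
  expect_identical(mittag_leffler(0.9, 0), 1)
  for (z in c(-1, -4, 0.5, 2)) {
    expect_equal(mittag_leffler(0.9, z), ml_ref(0.9, z), tolerance = 1e-10)
  }
  expect_equal(mittag_leffler(0.5, -3), ml_ref(0.5, -3, K = 400),
               tolerance = 1e-10)
  # large negative arguments: spectral integral vs asymptotic expansion
  expect_equal(mittag_leffler(0.9, -19), ml_asym(0.9, 19), tolerance = 1e-4)
  expect_equal(mittag_leffler(0.7, -15), ml_asym(0.7, 15), tolerance = 1e-4)
  # continuity across the series/integral switch at z = -2
  expect_equal(mittag_leffler(0.9, -2 + 1e-9), mittag_leffler(0.9, -2 - 1e-9),
               tolerance = 1e-7)
  expect_error(mittag_leffler(0.9, -25), "regime")
})

test_that("the reference integrator tracks the Mittag-Leffler solution", {
  sol <- gl_integrate(function(t, x) -x, 1, alpha = 0.9, h = 0.01, t_end = 2)
  truth <- c(1, mittag_leffler(0.9, -sol$times[-1]^0.9))
  expect_lt(max(abs(sol$states[, 1] - truth)), 5e-3)
  # without the Caputo starting correction the early transient is badly wrong
  raw <- gl_integrate(function(t, x) -x, 1, alpha = 0.9, h = 0.01, t_end = 2,
                      ic_correction = FALSE)
  expect_gt(max(abs(raw$states[, 1] - truth)), 0.1)
  # the bare recursion satisfies its own algebra exactly
  cj <- gl_coefficients(0.9, 3)
  x <- raw$states[1:4, 1]
  expect_equal(x[4],
               -x[3] * 0.01^0.9 - sum(cj[2:4] * x[3:1]),
               tolerance = 1e-15)
})

test_that("compiled solver agrees with the reference integrator on the two-cell model", {
  p <- table1_params()
  top <- two_cell_topology()
  f <- function(t, x) as.numeric(nd_rhs(matrix(x, 2, 3), p, top))
  ref <- gl_integrate(f, rep(0.5, 6), alpha = 0.9, h = 0.1, t_end = 20)
  traj <- gl_simulate(p, top, h = 0.1, t_end = 20)
  ts <- terminal_state(traj)
  expect_equal(c(ts$D, ts$N, ts$A), unname(ref$states[nrow(ref$states), ]),
               tolerance = 1e-12)
  # and with a short memory window
  refw <- gl_integrate(f, rep(0.5, 6), alpha = 0.9, h = 0.1, t_end = 20,
                       memory_window = 50)
  tsw <- terminal_state(gl_simulate(p, top, h = 0.1, t_end = 20,
                                    memory_window = 50))
  expect_equal(c(tsw$D, tsw$N, tsw$A), unname(refw$states[nrow(refw$states), ]),
               tolerance = 1e-12)
})

test_that("at alpha = 1 the GL scheme is exactly forward Euler", {
  p <- table1_params(alpha = 1)
  top <- two_cell_topology()
  a <- gl_simulate(p, top, h = 0.1, t_end = 100)
  b <- euler_simulate(p, top, h = 0.1, t_end = 100)
  expect_equal(as.matrix(a[, c("D", "N", "A")]),
               as.matrix(b[, c("D", "N", "A")]), tolerance = 1e-14)
})

test_that("Euler endpoint error shrinks roughly linearly under h-halving", {
  p <- table1_params(alpha = 1)
  top <- two_cell_topology()
  ends <- lapply(c(0.4, 0.2, 0.1, 0.05), function(h) {
    ts <- terminal_state(euler_simulate(p, top, h = h, t_end = 200))
    c(ts$D, ts$N, ts$A)
  })
  d1 <- max(abs(ends[[2]] - ends[[1]]))
  d2 <- max(abs(ends[[3]] - ends[[2]]))
  d3 <- max(abs(ends[[4]] - ends[[3]]))
  expect_gt(d1, d2)
  expect_gt(d2, d3)
  expect_lt(d3 / d2, 0.75)   # ~0.5 for a first-order method
})

test_that("an equilibrium initial condition stays fixed under Euler", {
  p <- table1_params(lambda = 0)
  top <- two_cell_topology()
  eq <- equilibrium_no_delta(p, top)
  st <- cbind(D = eq$D, N = eq$N, A = eq$A)
  traj <- euler_simulate(p, top, x0 = st, h = 0.5, t_end = 50)
  expect_equal(traj$N, rep(eq$N[1], nrow(traj)), tolerance = 1e-13)
  expect_true(all(traj$D == 0))
})

test_that("symmetric initial conditions stay symmetric to machine precision", {
  p <- table1_params()
  traj <- gl_simulate(p, two_cell_topology(), h = 0.1, t_end = 200)
  wide <- tidyr::pivot_wider(tibble::as_tibble(traj), id_cols = "time",
                             names_from = "cell",
                             values_from = c("D", "N", "A"))
  expect_equal(wide$D_1, wide$D_2, tolerance = 1e-12)
  expect_equal(wide$N_1, wide$N_2, tolerance = 1e-12)
  expect_equal(wide$A_1, wide$A_2, tolerance = 1e-12)
})

test_that("memory truncation converges to the full-memory solution", {
  p <- table1_params()
  top <- two_cell_topology()
  full <- terminal_state(gl_simulate(p, top, h = 0.1, t_end = 200))
  err <- vapply(c(100, 400, 1600), function(w) {
    ts <- terminal_state(gl_simulate(p, top, h = 0.1, t_end = 200,
                                     memory_window = w))
    max(abs(ts$N - full$N))
  }, 0.0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 5e-3)
})

test_that("trajectory bookkeeping: times, initial state, thinning, divergence", {
  p <- table1_params()
  top <- two_cell_topology()
  traj <- gl_simulate(p, top, x0 = 0.5, h = 0.1, t_end = 10, record_stride = 7)
  times <- unique(traj$time)
  expect_true(all(diff(times) > 0))
  expect_equal(times[1], 0)
  expect_equal(max(times), 10)          # final step always recorded
  first <- traj[traj$time == 0, ]
  expect_true(all(as.matrix(first[, c("D", "N", "A")]) == 0.5))
  # thinned output agrees with the unthinned run at shared times
  dense <- gl_simulate(p, top, x0 = 0.5, h = 0.1, t_end = 10)
  shared <- dplyr::inner_join(tibble::as_tibble(traj),
                              tibble::as_tibble(dense),
                              by = c("time", "cell"))
  expect_equal(shared$N.x, shared$N.y, tolerance = 1e-15)
  expect_error(gl_simulate(p, top, x0 = -1, h = 0.1, t_end = 1), "nonnegative")
  expect_error(
    gl_simulate(table1_params(d = 1e-9, lambda = 1e11), top, h = 10, t_end = 1e4),
    "diverged at t = .*cell .*component")
})
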