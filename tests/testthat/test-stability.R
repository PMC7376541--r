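# symmetric-reduction vector field: one cell whose neighbour mirrors its state
symmetric_reduction <- function(p) {
  r <- effective_rates(p)
  function(x) {
    D <- x[1]; N <- x[2]; A <- x[3]
    c(r$lambda / (1 + r$theta * A) - r$f * D * N - r$d * D,
      r$lambda_n + r$f * D * N - r$d * N,
      r$a * D * N / (r$b + D * N) - r$d * A)
  }
}

test_that("per-cell Jacobian matches finite differences of the reduction", {
  set.seed(3)
  for (i in 1:20) {
    p <- rand_params()
    x <- runif(3, 0.1, 8)
    J <- jacobian_cell(p, x)
    Jfd <- fd_jacobian(symmetric_reduction(p), x)
    expect_equal(unname(J), Jfd, tolerance = 1e-6)
  }
})

test_that("full-system Jacobian matches finite differences of the rhs", {
  set.seed(4)
  top <- grid_topology(2, 3)
  p <- rand_params()
  lam <- runif(6, 0, 1000)
  st <- matrix(runif(18, 0.1, 5), 6, 3)
  fn <- function(v) as.numeric(nd_rhs(matrix(v, 6, 3), p, top,
                                      lambda_per_cell = lam))
  expect_equal(system_jacobian(p, top, st, lam), fd_jacobian(fn, as.numeric(st)),
               tolerance = 1e-6)
})

test_that("E0 eigenvalues are the closed form and match the Jacobian", {
  p <- table1_params(alpha = 0.9)
  e <- e0_eigenvalues(p)
  expect_equal(e[1:2], rep(-0.01^0.9, 2), tolerance = 1e-14)
  expect_equal(e[3], -(0.07^0.9 * 0.01^0.9 / 0.01^0.9) - 0.01^0.9,
               tolerance = 1e-14)
  expect_equal(e[3], -0.1071736, tolerance = 1e-6)
  # numeric eigenvalues of the per-cell Jacobian at E0 (lambda = 0)
  p0 <- table1_params(lambda = 0)
  eq <- equilibrium_no_delta(p0)
  J <- jacobian_cell(p0, c(0, eq$N[1], 0))
  expect_equal(sort(Re(eigen(J, only.values = TRUE)$values)), sort(e),
               tolerance = 1e-10)
  # all negative real for any valid draw => E0 stable
  set.seed(6)
  for (i in 1:25) {
    pp <- rand_params()
    expect_true(all(e0_eigenvalues(pp) < 0))
    expect_identical(stability_report(pp, equilibrium_no_delta(pp))$verdict,
                     "stable")
  }
})

test_that("characteristic cubic has unit leading coefficient and the Jacobian's spectrum", {
  set.seed(8)
  for (i in 1:15) {
    p <- rand_params()
    eq <- suppressWarnings(equilibrium_with_delta(p))
    ch <- characteristic_coefficients(p, eq)
    expect_identical(unname(ch["a3"]), 1)
    roots <- charpoly_roots(ch)
    ev <- eigen(jacobian_cell(p, c(eq$D[1], eq$N[1], eq$A[1])),
                only.values = TRUE)$values
    expect_equal(sort(Re(roots)), sort(Re(ev)), tolerance = 1e-8)
    expect_equal(sort(abs(Im(roots))), sort(abs(Im(ev))), tolerance = 1e-8)
  }
})

test_that("Routh-Hurwitz verdict equals the root-sign oracle", {
  expect_true(routh_hurwitz(c(1, 2, 3, 1))$stable)   # 2*3 - 1 = 5 > 0
  expect_false(routh_hurwitz(c(1, 1, 1, 2))$stable)  # 1 - 2 < 0
  set.seed(9)
  for (i in 1:200) {
    a <- c(1, rnorm(3, sd = 2))
    verdict <- routh_hurwitz(a)$stable
    roots <- polyroot(rev(a))
    expect_identical(verdict, all(Re(roots) < 0))
  }
})

test_that("fractional argument condition: sector geometry and boundary", {
  expect_identical(fractional_arg_condition(-1, 0.9)$verdict, "stable")
  expect_identical(fractional_arg_condition(1, 0.5)$verdict, "unstable")
  expect_identical(fractional_arg_condition(0, 0.9)$verdict, "inconclusive")
  # complex pair with |arg| = 0.4*pi: verdict flips as alpha crosses 0.8
  z <- exp(1i * 0.4 * pi)
  zz <- c(z, Conj(z))
  expect_identical(fractional_arg_condition(zz, 0.79)$verdict, "stable")
  expect_identical(fractional_arg_condition(zz, 0.81)$verdict, "unstable")
  expect_identical(fractional_arg_condition(zz, 0.8)$verdict, "inconclusive")
  m <- fractional_arg_condition(zz, 0.79)$margins
  expect_equal(m, rep(0.4 * pi - 0.79 * pi / 2, 2), tolerance = 1e-12)
  # negative real roots are stable for every order (RH implies the arg condition)
  for (alpha in c(0.1, 0.5, 0.9, 1)) {
    expect_identical(fractional_arg_condition(c(-2, -0.3, -1e-3), alpha)$verdict,
                     "stable")
  }
})

test_that("sufficient ratio: value, monotonicity in f, and implication for E1", {
  p <- table1_params()
  r <- effective_rates(p)
  s <- sufficient_condition_ratio(p)
  expect_equal(s$ratio,
               (r$d^3 + r$f^2 * r$d) / (4 * r$f^2 * r$lambda_n + 2 * r$f * r$d^2),
               tolerance = 1e-14)
  # monotone decreasing in f over a sweep
  fs <- seq(0.005, 0.1, length.out = 12)
  ratios <- vapply(fs, function(f) {
    sufficient_condition_ratio(table1_params(f = f))$ratio
  }, 0.0)
  expect_true(all(diff(ratios) < 0))
  # whenever the ratio is < 1, the Routh-Hurwitz verdict at E1 is stable
  set.seed(10)
  checked <- 0
  for (i in 1:40) {
    pp <- rand_params()
    if (sufficient_condition_ratio(pp)$satisfied) {
      eq <- tryCatch(equilibrium_with_delta(pp), error = function(e) NULL,
                     warning = function(w) NULL)
      if (is.null(eq)) next
      expect_true(routh_hurwitz(characteristic_coefficients(pp, eq))$stable)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 5)
})

test_that("the stability report assembles a consistent verdict", {
  rep1 <- stability_report(table1_params(lambda = 1000))
  expect_identical(rep1$kind, "E1")
  expect_identical(rep1$verdict, "stable")
  g <- glance(rep1)
  expect_identical(g$routh_hurwitz, TRUE)
  expect_lt(g$sufficient_ratio, 1)
  td <- tidy(rep1)
  expect_identical(nrow(td), 3L)
  expect_true(all(td$arg_margin > 0))
  # the symmetric (per-cell) block is stable, but the full two-cell system has
  # a weakly unstable anti-symmetric (patterning) mode; the report exposes the
  # disagreement instead of hiding it
  expect_identical(g$full_system_verdict, "unstable")
  expect_false(rep1$reduction_agrees)
  expect_identical(sum(Re(rep1$full_eigenvalues) > 0), 1L)

  rep0 <- stability_report(table1_params(lambda = 0))
  expect_identical(rep0$kind, "E0")
  expect_identical(rep0$verdict, "stable")
})
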