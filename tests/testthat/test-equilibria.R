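test_that("the no-Delta equilibrium is the closed form with exact zeros", {
  p <- table1_params()
  eq <- equilibrium_no_delta(p)
  expect_identical(eq$D, c(0, 0))
  expect_identical(eq$A, c(0, 0))
  expect_equal(eq$N, rep(7^0.9, 2), tolerance = 1e-14)
  expect_lt(attr(eq, "residual"), 1e-12)

  eq1 <- equilibrium_no_delta(table1_params(alpha = 1))
  expect_equal(eq1$N, c(7, 7), tolerance = 1e-14)

  # lambda in params is ignored: E0 is the lambda = 0 fixed point
  eq2 <- equilibrium_no_delta(table1_params(lambda = 1000))
  expect_equal(eq2$N, eq$N)

  # on a larger graph every cell carries the same closed form
  eqL <- equilibrium_no_delta(p, grid_topology(3, 4))
  expect_equal(eqL$N, rep(7^0.9, 12))
  expect_lt(attr(eqL, "residual"), 1e-12)
})

test_that("cubic coefficients match an independent polynomial expansion", {
  # independent construction: expand
  #   (d N - lamN)(f N + d) * [(d^2 + a th d) N + (d b f - d lamN - a th lamN)]
  #     - lam f d N * [f d N^2 + f (b f - lamN) N]   (as polynomials in N)
  polymul <- function(u, v) {
    out <- numeric(length(u) + length(v) - 1)
    for (i in seq_along(u)) {
      out[i:(i + length(v) - 1)] <- out[i:(i + length(v) - 1)] + u[i] * v
    }
    out
  }
  set.seed(11)
  for (i in 1:10) {
    p <- rand_params()
    r <- effective_rates(p)
    q1 <- polymul(c(-r$lambda_n, r$d), c(r$d, r$f))        # (dN - lamN)(fN + d)
    q2 <- c(r$d * r$b * r$f - r$d * r$lambda_n - r$a * r$theta * r$lambda_n,
            r$d^2 + r$a * r$theta * r$d)
    lhs <- polymul(q1, q2)                                  # degree 3, asc order
    rhs <- c(0, r$lambda * r$d * r$f * (r$b * r$f - r$lambda_n),
             r$lambda * r$d^2 * r$f, 0)
    want <- rev(lhs - rhs)                                  # B1, B2, B3, B4
    cc <- cubic_coefficients(p)
    got <- c(cc$B1, cc$B2, cc$B3, cc$B4)
    expect_equal(got, want, tolerance = 1e-12)
    # B1 as printed, and positive
    expect_equal(cc$B1, r$d * r$f * (r$d^2 + r$a * r$theta * r$d))
    expect_gt(cc$B1, 0)
    # depressed-cubic parameters
    expect_equal(cc$p, (3 * cc$B1 * cc$B3 - cc$B2^2) / (3 * cc$B1^2))
    expect_equal(cc$q_card,
                 (27 * cc$B1^2 * cc$B4 - 9 * cc$B1 * cc$B2 * cc$B3 +
                    2 * cc$B2^3) / (27 * cc$B1^3))
  }
  # theta = 0 collapses B1 to d^{3a} f^a
  p0 <- table1_params(theta = 0)
  r0 <- effective_rates(p0)
  expect_equal(cubic_coefficients(p0)$B1, r0$d^3 * r0$f)
})

test_that("the published coefficient variant does not give a fixed point", {
  p <- table1_params(lambda = 1000)
  r <- effective_rates(p)
  roots_printed <- cardano_roots(cubic_coefficients(p, printed = TRUE))
  adm <- roots_printed[roots_printed > r$lambda_n / r$d]
  expect_length(adm, 1)
  D <- (r$d * adm - r$lambda_n) / (r$f * adm)
  A <- (r$a / r$d) * (D * adm) / (r$b + D * adm)
  res <- max(abs(nd_rhs(cbind(D = rep(D, 2), N = rep(adm, 2), A = rep(A, 2)),
                        p, two_cell_topology())))
  expect_gt(res, 1e-3)
})

test_that("Cardano roots agree with the companion-matrix oracle", {
  # factored cubic (N-1)(N-2)(N-3): three real roots, trig branch
  rts <- cardano_roots(c(1, -6, 11, -6))
  expect_equal(as.numeric(rts), c(1, 2, 3), tolerance = 1e-10)
  expect_identical(attr(rts, "method"), "trigonometric")
  # N^3 = 8: one real root, Cardano branch
  rts2 <- cardano_roots(c(1, 0, 0, -8))
  expect_equal(as.numeric(rts2), 2, tolerance = 1e-12)
  expect_identical(attr(rts2, "method"), "cardano")

  set.seed(2024)
  for (i in 1:100) {
    B <- c(runif(1, 0.5, 2) * sample(c(-1, 1), 1), rnorm(3, sd = 3))
    got <- as.numeric(cardano_roots(B))
    oracle <- companion_roots(B)
    oracle_real <- sort(Re(oracle[abs(Im(oracle)) < 1e-7 * pmax(1, Mod(oracle))]))
    expect_equal(got, oracle_real, tolerance = 1e-8)
  }
})

test_that("the Delta-expressing equilibrium is a true fixed point", {
  p <- table1_params(lambda = 1000)
  eq <- equilibrium_with_delta(p)
  expect_identical(attr(eq, "kind"), "E1")
  expect_lt(attr(eq, "residual"), 1e-9)
  # residual of the model rhs itself
  st <- cbind(D = eq$D, N = eq$N, A = eq$A)
  expect_lt(max(abs(nd_rhs(st, p, two_cell_topology()))), 1e-9)
  # both cells identical
  expect_equal(eq[1, c("D", "N", "A")], eq[2, c("D", "N", "A")],
               ignore_attr = TRUE)
  # independent scalar-reduction oracle
  want <- e1_oracle(p)
  expect_equal(c(eq$D[1], eq$N[1], eq$A[1]), unname(want), tolerance = 1e-8)
  # frozen magnitudes at the packaged parameter set
  expect_equal(eq$N[1], 9.4811, tolerance = 1e-4)
  expect_equal(eq$D[1], 0.3922, tolerance = 1e-3)
  expect_equal(eq$A[1], 0.03062, tolerance = 1e-3)
})

test_that("E1 degenerates toward E0 as lambda -> 0 and errors at lambda = 0", {
  p <- table1_params(lambda = 1e-8)
  eq <- equilibrium_with_delta(p)
  e0 <- equilibrium_no_delta(p)
  expect_equal(eq$N[1], e0$N[1], tolerance = 1e-4)
  expect_lt(eq$D[1], 1e-4)
  expect_error(equilibrium_with_delta(table1_params(lambda = 0)), "lambda")
})

test_that("equilibria are stable under tiny parameter perturbations", {
  set.seed(5)
  for (i in 1:10) {
    p <- rand_params()
    n0 <- length(attr(equilibrium_with_delta(p), "candidates")$N_root)
    q <- unclass(p)
    q$d <- q$d * (1 + 1e-6)
    n1 <- length(attr(equilibrium_with_delta(do.call(nd_params, q)),
                      "candidates")$N_root)
    expect_identical(n0, n1)
  }
})
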