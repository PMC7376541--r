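# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: hand-coded model equations, finite differences,
# companion matrices, direct series summation.

# Hand-coded right-hand side of the two-cell system, one equation per line.
ref_two_cell_rhs <- function(x, p) {
  a <- p$alpha
  lam <- p$lambda^a; f <- p$f^a; d <- p$d^a; lamN <- p$lambda_n^a
  aa <- p$a^a; b <- p$b^a; th <- p$theta^a
  D1 <- x[1]; N1 <- x[2]; A1 <- x[3]; D2 <- x[4]; N2 <- x[5]; A2 <- x[6]
  c(lam / (1 + th * A1) - f * D1 * N2 - d * D1,
    lamN + f * D2 * N1 - d * N1,
    aa * D2 * N1 / (b + D2 * N1) - d * A1,
    lam / (1 + th * A2) - f * D2 * N1 - d * D2,
    lamN + f * D1 * N2 - d * N2,
    aa * D1 * N2 / (b + D1 * N2) - d * A2)
}

# Roots of B1 x^3 + B2 x^2 + B3 x + B4 via the companion matrix.
companion_roots <- function(B) {
  b <- B / B[1]
  C <- rbind(c(0, 0, -b[4]),
             c(1, 0, -b[3]),
             c(0, 1, -b[2]))
  eigen(C, only.values = TRUE)$values
}

# Central finite-difference Jacobian.
fd_jacobian <- function(fn, x, eps = 1e-6) {
  n <- length(x)
  f0 <- fn(x)
  J <- matrix(0, length(f0), n)
  for (i in seq_len(n)) {
    hi <- eps * max(1, abs(x[i]))
    xp <- x; xp[i] <- xp[i] + hi
    xm <- x; xm[i] <- xm[i] - hi
    J[, i] <- (fn(xp) - fn(xm)) / (2 * hi)
  }
  J
}

# Generalised binomial coefficient (-1)^j * C(q, j) via the falling product.
gl_coef_closed <- function(q, j) {
  if (j == 0) return(1)
  (-1)^j * prod(q - seq_len(j) + 1) / factorial(j)
}

# Direct series for the one-parameter Mittag-Leffler function, summed in log
# space to dodge overflow of z^k and of the gamma function separately.
ml_ref <- function(alpha, z, K = 300) {
  if (z == 0) return(1)
  k <- 0:K
  sum(sign(z)^k * exp(k * log(abs(z)) - lgamma(alpha * k + 1)))
}

# Asymptotic expansion of E_alpha(-x) for large x > 0 (0 < alpha < 1):
# sum_k (-1)^{k+1} x^{-k} / Gamma(1 - alpha k).
ml_asym <- function(alpha, x, K = 6) {
  k <- seq_len(K)
  sum((-1)^(k + 1) * x^(-k) / gamma(1 - alpha * k))
}

# Delta-expressing two-cell equilibrium by bisection on the scalar reduction
# g(N) obtained by eliminating D and A from the fixed-point equations.
e1_oracle <- function(p) {
  a <- p$alpha
  lam <- p$lambda^a; f <- p$f^a; d <- p$d^a; lamN <- p$lambda_n^a
  aa <- p$a^a; b <- p$b^a; th <- p$theta^a
  Dof <- function(N) (d * N - lamN) / (f * N)
  Aof <- function(N) { DN <- Dof(N) * N; (aa / d) * DN / (b + DN) }
  g <- function(N) lam / (1 + th * Aof(N)) - f * Dof(N) * N - d * Dof(N)
  nmin <- lamN / d
  lo <- nmin * (1 + 1e-10)
  hi <- nmin + 1
  while (g(hi) > 0 && hi < 1e12) hi <- hi * 2
  N <- uniroot(g, c(lo, hi), tol = 1e-13)$root
  c(D = Dof(N), N = N, A = Aof(N))
}

# Random valid parameter draw around the packaged nominal values.
rand_params <- function(alpha = NULL) {
  jitter <- function(x) x * runif(1, 0.5, 1.5)
  nd_params(lambda = jitter(1000), f = jitter(0.01), d = jitter(0.01),
            lambda_n = jitter(0.07), a = jitter(0.01), b = jitter(200),
            theta = jitter(1e6),
            alpha = if (is.null(alpha)) runif(1, 0.55, 1) else alpha)
}
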