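#' No-Delta equilibrium (E0)
#'
#' When Delta production is absent (\eqn{\lambda = 0}) the model has the
#' closed-form fixed point \eqn{(D, N, A) = (0,\; \lambda_N^\alpha / d^\alpha,\; 0)}
#' in every cell: Delta and activated Notch vanish exactly and inactive Notch
#' balances production against degradation.
#'
#' @param params An [nd_params()] object. `lambda` is treated as 0 regardless
#'   of its value.
#' @param topology An [nd_topology()]; default two cells.
#' @return An `nd_equilibrium`: a tibble with one row per cell (`cell`, `D`,
#'   `N`, `A`) and attributes `kind = "E0"`, `residual` (max-norm of the model
#'   right-hand side at the point) and `refined = FALSE`.
#' @examples
#' equilibrium_no_delta(table1_params())
#' @export
equilibrium_no_delta <- function(params, topology = two_cell_topology()) {
  stopifnot(inherits(params, "nd_params"), inherits(topology, "nd_topology"))
  r <- effective_rates(params)
  n <- topology$n_cells
  vals <- cbind(D = rep(0, n), N = rep(r$lambda_n / r$d, n), A = rep(0, n))
  p0 <- params; p0$lambda <- 0
  res <- max(abs(nd_rhs(vals, p0, topology)))
  new_nd_equilibrium(vals, kind = "E0", residual = res, refined = FALSE)
}

#' Cubic reduction for the Delta-expressing equilibrium
#'
#' For the symmetric two-cell system with \eqn{\lambda > 0}, eliminating `D`
#' and `A` from the fixed-point equations reduces the equilibrium condition to
#' a cubic \eqn{B_1 N^3 + B_2 N^2 + B_3 N + B_4 = 0} in the inactive-Notch
#' level `N`. The coefficients returned by default are derived directly from
#' the fixed-point equations, so the admissible root is an exact equilibrium
#' (residual at machine precision). The corresponding published closed form
#' differs by the sign of the \eqn{\lambda_N^\alpha f^\alpha} term in two
#' coefficients and does not reproduce a fixed point; it can be obtained with
#' `printed = TRUE` for comparison. Also returns the depressed-cubic
#' parameters `p` and `q_card` used by Cardano's formula.
#'
#' @param params An [nd_params()] object with `lambda > 0`.
#' @param printed Return the published coefficient variant instead of the
#'   derived one (default `FALSE`).
#' @return An object of class `nd_cubic`: list with `B1`-`B4`, `p`, `q_card`.
#' @seealso [cardano_roots()], [equilibrium_with_delta()]
#' @export
cubic_coefficients <- function(params, printed = FALSE) {
  stopifnot(inherits(params, "nd_params"))
  r <- effective_rates(params)
  lam <- r$lambda; f <- r$f; d <- r$d; lamN <- r$lambda_n
  a <- r$a; b <- r$b; th <- r$theta
  sgn <- if (printed) +1 else -1   # sign of the lamN*f term in (d^2a +/- lamN f^a)
  lin <- d^2 + sgn * lamN * f
  B1 <- d * f * (d^2 + a * th * d)
  B2 <- (d^2 + a * th * d) * lin +
    d * f * (d * b * f - d * lamN - a * th * lamN) - lam * d^2 * f
  B3 <- lin * (d * b * f - d * lamN - a * th * lamN) -
    d * lamN * (d^2 + a * th * d) - lam * d * f * (b * f - lamN)
  B4 <- -d * lamN * (d * b * f - d * lamN - a * th * lamN)
  if (abs(B1) < .Machine$double.xmin) {
    stop("degenerate rates: leading cubic coefficient B1 = 0")
  }
  p_dep <- (3 * B1 * B3 - B2^2) / (3 * B1^2)
  q_dep <- (27 * B1^2 * B4 - 9 * B1 * B2 * B3 + 2 * B2^3) / (27 * B1^3)
  structure(list(B1 = B1, B2 = B2, B3 = B3, B4 = B4,
                 p = p_dep, q_card = q_dep, printed = printed),
            class = "nd_cubic")
}

#' Real roots of a cubic by Cardano's formula
#'
#' Solves \eqn{B_1 N^3 + B_2 N^2 + B_3 N + B_4 = 0} for its real roots. With a
#' nonnegative discriminant \eqn{(q/2)^2 + (p/3)^3} the single real root is the
#' classical Cardano expression with real cube roots; with three distinct real
#' roots (negative discriminant, "casus irreducibilis") the trigonometric
#' method is used. Each root receives a final Newton polish so that
#' \eqn{|P(N)| / \max(1, |B_4|) < 10^{-10}}.
#'
#' @param coeffs An `nd_cubic` from [cubic_coefficients()], or a numeric vector
#'   `c(B1, B2, B3, B4)`.
#' @return Sorted numeric vector of the real roots (length 1, 2 or 3), with
#'   attribute `method` (`"cardano"` or `"trigonometric"`).
#' @examples
#' cardano_roots(c(1, -6, 11, -6)) # 1, 2, 3
#' @export
cardano_roots <- function(coeffs) {
  B <- if (inherits(coeffs, "nd_cubic")) {
    c(coeffs$B1, coeffs$B2, coeffs$B3, coeffs$B4)
  } else {
    stopifnot(is.numeric(coeffs), length(coeffs) == 4)
    as.numeric(coeffs)
  }
  if (B[1] == 0) stop("leading coefficient B1 must be nonzero")
  b2 <- B[2] / B[1]; b1 <- B[3] / B[1]; b0 <- B[4] / B[1]
  shift <- -b2 / 3
  p <- b1 - b2^2 / 3
  q <- 2 * b2^3 / 27 - b2 * b1 / 3 + b0
  disc <- (q / 2)^2 + (p / 3)^3
  cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
  if (disc >= 0) {
    s <- sqrt(disc)
    t1 <- cbrt(-q / 2 + s) + cbrt(-q / 2 - s)
    roots <- t1 + shift
    if (disc == 0 && (p != 0 || q != 0)) {
      roots <- c(roots, -t1 / 2 + shift)
    }
    method <- "cardano"
  } else {
    # three distinct real roots
    rho <- 2 * sqrt(-p / 3)
    phi <- acos(pmin(1, pmax(-1, 3 * q / (p * rho))))
    roots <- rho * cos((phi - 2 * pi * (0:2)) / 3) + shift
    method <- "trigonometric"
  }
  poly  <- function(x) ((B[1] * x + B[2]) * x + B[3]) * x + B[4]
  dpoly <- function(x) (3 * B[1] * x + 2 * B[2]) * x + B[3]
  roots <- vapply(roots, function(x) {
    for (it in 1:8) {
      fx <- poly(x)
      if (abs(fx) / max(1, abs(B[4])) < 1e-14) break
      dp <- dpoly(x)
      if (dp == 0) break
      x <- x - fx / dp
    }
    x
  }, 0.0)
  bad <- abs(poly(roots)) / max(1, abs(B[4])) >= 1e-10
  if (any(bad)) {
    warning("cardano_roots(): residual tolerance not met for ",
            sum(bad), " root(s)")
  }
  structure(sort(unname(roots)), method = method)
}

#' Delta-expressing equilibrium (E1)
#'
#' Computes the symmetric two-cell fixed point with \eqn{\lambda > 0}. The
#' inactive-Notch level `N*` is an admissible real root of the cubic reduction
#' (see [cubic_coefficients()]); admissibility requires
#' \eqn{N^* > \lambda_N^\alpha / d^\alpha} so that
#' \eqn{D = (d^\alpha N^* - \lambda_N^\alpha) / (f^\alpha N^*) > 0}, and
#' \eqn{A = (a^\alpha / d^\alpha)\, D N^* / (b^\alpha + D N^*) \ge 0}. The full
#' six-dimensional point is then polished by damped Newton iteration on the
#' model right-hand side (analytic Jacobian, tolerance `1e-12`, at most 50
#' iterations) and the final max-norm residual is reported.
#'
#' @param params An [nd_params()] object with `lambda > 0`.
#' @param refine Apply Newton polishing (default `TRUE`).
#' @return An `nd_equilibrium` tibble (2 cells) with attributes `kind = "E1"`,
#'   `residual`, `refined`, `roots` (all real roots of the cubic) and
#'   `candidates` (one row per admissible root, flagged when several are
#'   admissible).
#' @examples
#' eq <- equilibrium_with_delta(table1_params(lambda = 1000))
#' glance(eq)
#' @export
equilibrium_with_delta <- function(params, refine = TRUE) {
  stopifnot(inherits(params, "nd_params"))
  if (params$lambda <= 0) {
    stop("`lambda` must be > 0 for the Delta-expressing equilibrium; ",
         "use equilibrium_no_delta() for lambda = 0")
  }
  r <- effective_rates(params)
  roots <- cardano_roots(cubic_coefficients(params))
  n_floor <- r$lambda_n / r$d
  adm <- roots[roots > n_floor]
  if (length(adm) == 0) {
    stop("no admissible equilibrium root (need N > lambda_n^alpha/d^alpha = ",
         signif(n_floor, 6), "); real roots found: ",
         paste(signif(roots, 6), collapse = ", "))
  }
  topology <- two_cell_topology()
  cand <- lapply(adm, function(N) {
    D <- (r$d * N - r$lambda_n) / (r$f * N)
    A <- (r$a / r$d) * (D * N) / (r$b + D * N)
    vals <- cbind(D = c(D, D), N = c(N, N), A = c(A, A))
    res <- max(abs(nd_rhs(vals, params, topology)))
    if (refine) {
      pol <- newton_refine(vals, params, topology)
      vals <- pol$state
      res <- pol$residual
    }
    list(vals = vals, residual = res)
  })
  best <- which.min(vapply(cand, `[[`, 0.0, "residual"))
  vals <- cand[[best]]$vals
  cand_tbl <- tibble::tibble(
    N_root = adm,
    residual = vapply(cand, `[[`, 0.0, "residual"),
    selected = seq_along(adm) == best
  )
  if (length(adm) > 1) {
    warning("multiple admissible equilibrium roots (",
            paste(signif(adm, 6), collapse = ", "),
            "); selected the smallest-residual one. See attr(, 'candidates').")
  }
  new_nd_equilibrium(vals, kind = "E1", residual = cand[[best]]$residual,
                     refined = refine, roots = as.numeric(roots),
                     candidates = cand_tbl)
}

# Damped Newton iteration on the full-system right-hand side.
newton_refine <- function(state, params, topology, lambda_per_cell = NULL,
                          tol = 1e-12, max_iter = 50) {
  x <- as.numeric(state)
  n <- topology$n_cells
  fx <- function(v) {
    as.numeric(nd_rhs(matrix(v, n, 3), params, topology, lambda_per_cell))
  }
  fv <- fx(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(fv)) < tol) break
    J <- system_jacobian(params, topology, matrix(x, n, 3), lambda_per_cell)
    step <- tryCatch(solve(J, fv), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      xn <- x - lam * step
      fn <- fx(xn)
      if (max(abs(fn)) < max(abs(fv)) || lam < 1e-6) break
      lam <- lam / 2
    }
    if (max(abs(fn)) >= max(abs(fv))) break
    x <- xn; fv <- fn
  }
  st <- matrix(x, n, 3); colnames(st) <- c("D", "N", "A")
  list(state = st, residual = max(abs(fv)))
}

new_nd_equilibrium <- function(vals, kind, residual, refined, ...) {
  tbl <- tibble::tibble(cell = seq_len(nrow(vals)),
                        D = vals[, 1], N = vals[, 2], A = vals[, 3])
  structure(tbl, class = c("nd_equilibrium", class(tbl)),
            kind = kind, residual = residual, refined = refined, ...)
}

#' @export
print.nd_equilibrium <- function(x, ...) {
  cat(sprintf("<nd_equilibrium> kind = %s, residual = %.3g, refined = %s\n",
              attr(x, "kind"), attr(x, "residual"), attr(x, "refined")))
  NextMethod()
}

#' @export
tidy.nd_equilibrium <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.nd_equilibrium <- function(x, ...) {
  tibble::tibble(kind = attr(x, "kind"),
                 n_cells = nrow(x),
                 residual = attr(x, "residual"),
                 refined = attr(x, "refined"),
                 D = x$D[1], N = x$N[1], A = x$A[1])
}

#' Serialise an equilibrium to JSON
#'
#' @param eq An `nd_equilibrium`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_equilibrium_json <- function(eq, path) {
  obj <- list(kind = attr(eq, "kind"),
              residual = attr(eq, "residual"),
              refined = attr(eq, "refined"),
              values = tibble::as_tibble(eq))
  if (!is.null(attr(eq, "roots"))) obj$roots_considered <- attr(eq, "roots")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
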