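#' Per-cell Jacobian of the symmetric two-cell reduction
#'
#' The 3x3 Jacobian block of the model at a symmetric point \eqn{(D, N, A)}:
#' \deqn{J = \begin{pmatrix}
#'  -f^\alpha N - d^\alpha & -f^\alpha D &
#'     -\theta^\alpha \lambda^\alpha / (1+\theta^\alpha A)^2 \\
#'  f^\alpha N & f^\alpha D - d^\alpha & 0 \\
#'  a^\alpha b^\alpha N/(b^\alpha + DN)^2 &
#'  a^\alpha b^\alpha D/(b^\alpha + DN)^2 & -d^\alpha
#' \end{pmatrix}}
#' This reduction treats the neighbouring cell's state as equal to the cell's
#' own (valid at the symmetric equilibria of the two-cell system). For the full
#' coupled matrix on an arbitrary graph use [system_jacobian()].
#'
#' @param params An [nd_params()] object.
#' @param point Numeric length-3 vector `(D, N, A)`.
#' @param lambda Delta production rate entering the inhibition entry; defaults
#'   to `params$lambda`.
#' @return A 3x3 numeric matrix.
#' @export
jacobian_cell <- function(params, point, lambda = params$lambda) {
  stopifnot(inherits(params, "nd_params"), length(point) == 3)
  r <- effective_rates(params)
  D <- point[1]; N <- point[2]; A <- point[3]
  lam_eff <- lambda^params$alpha
  hill <- r$a * r$b / (r$b + D * N)^2
  matrix(c(-r$f * N - r$d, -r$f * D, -r$theta * lam_eff / (1 + r$theta * A)^2,
           r$f * N,         r$f * D - r$d, 0,
           hill * N,        hill * D,     -r$d),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("dD", "dN", "dA"), c("D", "N", "A")))
}

#' Full-system Jacobian on an arbitrary cell graph
#'
#' Analytic Jacobian of [nd_rhs()] with respect to the stacked state
#' `(D_1..D_n, N_1..N_n, A_1..A_n)`. Used by the Newton refinement of
#' equilibria and for eigenvalue cross-checks of the per-cell reduction.
#'
#' @param params An [nd_params()] object.
#' @param topology An [nd_topology()].
#' @param state `n_cells x 3` matrix `(D, N, A)`.
#' @param lambda_per_cell Optional per-cell Delta production rates (base
#'   values).
#' @return A `3n x 3n` numeric matrix.
#' @export
system_jacobian <- function(params, topology, state, lambda_per_cell = NULL) {
  stopifnot(inherits(params, "nd_params"), inherits(topology, "nd_topology"),
            is.matrix(state), nrow(state) == topology$n_cells, ncol(state) == 3)
  n <- topology$n_cells
  r <- effective_rates(params)
  lam_eff <- resolve_lambda(params, topology, lambda_per_cell)^params$alpha
  D <- state[, 1]; N <- state[, 2]; A <- state[, 3]
  sumD <- neighbor_sums(D, topology)
  sumN <- neighbor_sums(N, topology)
  J <- matrix(0, 3 * n, 3 * n)
  iD <- seq_len(n); iN <- n + seq_len(n); iA <- 2 * n + seq_len(n)
  for (i in seq_len(n)) {
    nb <- topology$neighbors[[i]]
    # dD_i' / d.
    J[iD[i], iD[i]] <- -r$f * sumN[i] - r$d
    J[iD[i], iN[nb]] <- J[iD[i], iN[nb]] - r$f * D[i]
    J[iD[i], iA[i]] <- -r$theta * lam_eff[i] / (1 + r$theta * A[i])^2
    # dN_i' / d.
    J[iN[i], iN[i]] <- r$f * sumD[i] - r$d
    J[iN[i], iD[nb]] <- J[iN[i], iD[nb]] + r$f * N[i]
    # dA_i' / d.  A_i' = a S/(b+S) - d A_i, S = sumD_i * N_i
    S <- sumD[i] * N[i]
    g <- r$a * r$b / (r$b + S)^2
    J[iA[i], iN[i]] <- g * sumD[i]
    J[iA[i], iD[nb]] <- J[iA[i], iD[nb]] + g * N[i]
    J[iA[i], iA[i]] <- -r$d
  }
  J
}

#' Eigenvalues at the no-Delta equilibrium
#'
#' At E0 the per-cell characteristic determinant factors and the eigenvalues
#' (in the \eqn{\xi = s^\alpha} variable) are read off directly:
#' \eqn{\xi_{1,2} = -d^\alpha} and
#' \eqn{\xi_3 = -\lambda_N^\alpha f^\alpha / d^\alpha - d^\alpha}. All three
#' are negative real for any valid parameter set, so E0 is locally
#' asymptotically stable for every order \eqn{0 < \alpha \le 1}.
#'
#' @param params An [nd_params()] object (`lambda` is irrelevant here).
#' @return Numeric vector of the three eigenvalues.
#' @export
e0_eigenvalues <- function(params) {
  stopifnot(inherits(params, "nd_params"))
  r <- effective_rates(params)
  c(-r$d, -r$d, -r$lambda_n * r$f / r$d - r$d)
}

#' Characteristic polynomial at the Delta-expressing equilibrium
#'
#' Coefficients of the per-cell characteristic equation in \eqn{\xi = s^\alpha},
#' \eqn{\xi^3 + a_2 \xi^2 + a_1 \xi + a_0 = 0}, at a symmetric equilibrium
#' \eqn{(D, N, A)}:
#' \deqn{a_2 = f^\alpha N - f^\alpha D + 3 d^\alpha}
#' \deqn{a_1 = 2 d^\alpha f^\alpha (N - D) + 3 d^{2\alpha} + H}
#' \deqn{a_0 = d^{2\alpha} f^\alpha (N - D) + d^{3\alpha} + d^\alpha H}
#' with the inhibition-activation coupling
#' \eqn{H = a^\alpha b^\alpha \theta^\alpha \lambda^\alpha N /
#' [(1+\theta^\alpha A)^2 (b^\alpha + DN)^2]}. The leading coefficient is 1 by
#' construction.
#'
#' @param params An [nd_params()] object.
#' @param eq An `nd_equilibrium` (typically from [equilibrium_with_delta()]),
#'   or a numeric length-3 vector `(D, N, A)`.
#' @return Named numeric vector `c(a3 = 1, a2, a1, a0)` of class `nd_charpoly`.
#' @export
characteristic_coefficients <- function(params, eq) {
  stopifnot(inherits(params, "nd_params"))
  pt <- if (inherits(eq, "nd_equilibrium")) {
    c(eq$D[1], eq$N[1], eq$A[1])
  } else {
    stopifnot(is.numeric(eq), length(eq) == 3)
    as.numeric(eq)
  }
  r <- effective_rates(params)
  D <- pt[1]; N <- pt[2]; A <- pt[3]
  H <- r$a * r$b * r$theta * r$lambda * N /
    ((1 + r$theta * A)^2 * (r$b + D * N)^2)
  a2 <- r$f * N - r$f * D + 3 * r$d
  a1 <- 2 * r$d * r$f * N - 2 * r$d * r$f * D + 3 * r$d^2 + H
  a0 <- -r$d^2 * r$f * D + r$d^2 * r$f * N + r$d^3 + r$d * H
  structure(c(a3 = 1, a2 = a2, a1 = a1, a0 = a0), class = "nd_charpoly")
}

#' Roots of a cubic characteristic polynomial
#'
#' @param char An `nd_charpoly` (or numeric `c(a3, a2, a1, a0)`).
#' @return Complex vector of the three roots.
#' @export
charpoly_roots <- function(char) {
  a <- as.numeric(char)
  stopifnot(length(a) == 4)
  polyroot(rev(a))
}

#' Routh-Hurwitz criterion for a cubic
#'
#' For \eqn{a_3 \xi^3 + a_2 \xi^2 + a_1 \xi + a_0} with \eqn{a_3 > 0}, all
#' roots have negative real part iff \eqn{a_2 > 0}, \eqn{a_1 > 0},
#' \eqn{a_0 > 0} and \eqn{a_2 a_1 - a_3 a_0 > 0}.
#'
#' @param char An `nd_charpoly` or numeric `c(a3, a2, a1, a0)`.
#' @return List with `stable` (logical) and `conditions`, a tibble of the five
#'   tested quantities.
#' @examples
#' routh_hurwitz(c(1, 2, 3, 1))$stable # TRUE
#' @export
routh_hurwitz <- function(char) {
  a <- as.numeric(char)
  stopifnot(length(a) == 4)
  vals <- c(a3 = a[1], a2 = a[2], a1 = a[3], a0 = a[4],
            `a2*a1 - a3*a0` = a[2] * a[3] - a[1] * a[4])
  conditions <- tibble::tibble(quantity = names(vals),
                               value = unname(vals),
                               positive = unname(vals) > 0)
  list(stable = all(conditions$positive), conditions = conditions)
}

#' Fractional argument (Matignon) stability condition
#'
#' A linearised Caputo system of order \eqn{\alpha} is locally asymptotically
#' stable iff every eigenvalue \eqn{\xi} of the Jacobian satisfies
#' \eqn{|\arg(\xi)| > \alpha\pi/2}. Reports the per-eigenvalue margins
#' \eqn{|\arg(\xi_i)| - \alpha\pi/2}; margins within `tol` of zero (or an
#' eigenvalue at the origin) give the verdict `"inconclusive"`.
#'
#' @param eigenvalues Numeric or complex vector.
#' @param alpha Fractional order.
#' @param tol Margin below which the verdict is inconclusive (default `1e-10`).
#' @return List with `verdict` (`"stable"`, `"unstable"` or `"inconclusive"`)
#'   and `margins`.
#' @export
fractional_arg_condition <- function(eigenvalues, alpha, tol = 1e-10) {
  stopifnot(alpha > 0, alpha <= 1, all(is.finite(c(Re(eigenvalues),
                                                   Im(eigenvalues)))))
  z <- as.complex(eigenvalues)
  margins <- abs(Arg(z)) - alpha * pi / 2
  verdict <- if (any(Mod(z) < tol) || any(abs(margins) < tol)) {
    "inconclusive"
  } else if (all(margins > 0)) "stable" else "unstable"
  list(verdict = verdict, margins = margins)
}

#' Sufficient-condition ratio for stability of E1
#'
#' The ratio
#' \deqn{\frac{d^{3\alpha} + f^{2\alpha} d^\alpha}
#'            {4 f^{2\alpha} \lambda_N^\alpha + 2 f^\alpha d^{2\alpha}}}
#' being below 1 is a parameter-only sufficient condition for the
#' Routh-Hurwitz conditions to hold at the Delta-expressing equilibrium, and
#' hence for its local asymptotic stability at every order
#' \eqn{0 < \alpha \le 1}.
#'
#' @param params An [nd_params()] object.
#' @return List with `ratio` and `satisfied` (`ratio < 1`).
#' @export
sufficient_condition_ratio <- function(params) {
  stopifnot(inherits(params, "nd_params"))
  r <- effective_rates(params)
  ratio <- (r$d^3 + r$f^2 * r$d) / (4 * r$f^2 * r$lambda_n + 2 * r$f * r$d^2)
  list(ratio = ratio, satisfied = ratio < 1)
}

#' Local stability report at an equilibrium
#'
#' Assembles the full local stability analysis at an equilibrium of the
#' two-cell system: the characteristic cubic of the per-cell reduction, the
#' Routh-Hurwitz conditions, the parameter-only sufficient ratio, numeric
#' eigenvalues (roots of the cubic, plus the full coupled-system spectrum for
#' cross-checking), and the fractional argument condition with margins.
#' The printed per-cell reduction implicitly uses the symmetry of the
#' equilibrium; the full `3n x 3n` spectrum is computed alongside and any
#' disagreement of verdicts is reported, not hidden.
#'
#' @param params An [nd_params()] object.
#' @param eq An `nd_equilibrium`; by default E1 when `lambda > 0`, else E0.
#' @return An object of class `nd_stability` (list) with components `char`,
#'   `rh`, `sufficient`, `eigenvalues`, `arg`, `full_eigenvalues`, `full_arg`,
#'   `verdict`, `alpha`, `kind`.
#' @examples
#' rep <- stability_report(table1_params(lambda = 0))
#' glance(rep)
#' @export
stability_report <- function(params, eq = NULL) {
  stopifnot(inherits(params, "nd_params"))
  topology <- two_cell_topology()
  if (is.null(eq)) {
    eq <- if (params$lambda > 0) equilibrium_with_delta(params)
          else equilibrium_no_delta(params, topology)
  }
  kind <- attr(eq, "kind")
  if (kind == "E0") {
    eigs <- as.complex(e0_eigenvalues(params))
    p0 <- params; p0$lambda <- 0
    char <- characteristic_coefficients(p0, c(eq$D[1], eq$N[1], eq$A[1]))
    params_used <- p0
  } else {
    char <- characteristic_coefficients(params, eq)
    eigs <- charpoly_roots(char)
    params_used <- params
  }
  rh <- routh_hurwitz(char)
  arg <- fractional_arg_condition(eigs, params$alpha)
  state <- cbind(D = eq$D, N = eq$N, A = eq$A)
  Jfull <- system_jacobian(params_used, topology, state)
  full_eigs <- eigen(Jfull, only.values = TRUE)$values
  full_arg <- fractional_arg_condition(full_eigs, params$alpha)
  structure(list(kind = kind, alpha = params$alpha, char = char, rh = rh,
                 sufficient = sufficient_condition_ratio(params),
                 eigenvalues = eigs, arg = arg,
                 full_eigenvalues = full_eigs, full_arg = full_arg,
                 verdict = arg$verdict,
                 reduction_agrees = identical(arg$verdict, full_arg$verdict),
                 equilibrium = eq),
            class = "nd_stability")
}

#' @export
print.nd_stability <- function(x, ...) {
  cat(sprintf("<nd_stability> equilibrium %s, alpha = %g\n", x$kind, x$alpha))
  cat(sprintf("  characteristic cubic: xi^3 + %.6g xi^2 + %.6g xi + %.6g\n",
              x$char[["a2"]], x$char[["a1"]], x$char[["a0"]]))
  cat(sprintf("  Routh-Hurwitz: %s\n",
              if (x$rh$stable) "satisfied" else "violated"))
  cat(sprintf("  sufficient ratio: %.6g (%s)\n", x$sufficient$ratio,
              if (x$sufficient$satisfied) "< 1" else ">= 1"))
  cat(sprintf("  |arg| margins over alpha*pi/2: %s\n",
              paste(signif(x$arg$margins, 4), collapse = ", ")))
  cat(sprintf("  verdict: %s (full-system check %s)\n", x$verdict,
              if (x$reduction_agrees) "agrees" else
                paste0("DISAGREES: ", x$full_arg$verdict)))
  invisible(x)
}

#' @export
tidy.nd_stability <- function(x, ...) {
  tibble::tibble(eigenvalue = x$eigenvalues,
                 re = Re(x$eigenvalues),
                 im = Im(x$eigenvalues),
                 arg_margin = x$arg$margins)
}

#' @export
glance.nd_stability <- function(x, ...) {
  tibble::tibble(kind = x$kind, alpha = x$alpha,
                 a2 = x$char[["a2"]], a1 = x$char[["a1"]], a0 = x$char[["a0"]],
                 routh_hurwitz = x$rh$stable,
                 sufficient_ratio = x$sufficient$ratio,
                 verdict = x$verdict,
                 full_system_verdict = x$full_arg$verdict)
}

#' Serialise a stability report to JSON
#'
#' @param report An `nd_stability`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stability_json <- function(report, path) {
  obj <- list(kind = report$kind, alpha = report$alpha,
              char = as.list(setNames(as.numeric(report$char),
                                      names(report$char))),
              routh_hurwitz = report$rh$stable,
              sufficient_ratio = report$sufficient$ratio,
              eigenvalues = data.frame(re = Re(report$eigenvalues),
                                       im = Im(report$eigenvalues)),
              arg_margins = report$arg$margins,
              verdict = report$verdict,
              full_system_verdict = report$full_arg$verdict)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
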