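#' Right-hand side of the fractional Delta-Notch model
#'
#' Evaluates, for every cell `i` with neighbour set `NG(i)`, the instantaneous
#' rates of change of Delta (`D`), inactive Notch (`N`) and activated Notch
#' (`A`) under the improved lateral-inhibition model. All rate constants enter
#' raised to the fractional order \eqn{\alpha}:
#' \deqn{\dot D_i = \frac{\lambda_i^\alpha}{1 + \theta^\alpha A_i}
#'   - \sum_{j \in NG(i)} f^\alpha D_i N_j - d^\alpha D_i}
#' \deqn{\dot N_i = \lambda_N^\alpha + \sum_{j \in NG(i)} f^\alpha D_j N_i
#'   - d^\alpha N_i}
#' \deqn{\dot A_i = \frac{a^\alpha \sum_{j} D_j N_i}{b^\alpha + \sum_{j} D_j N_i}
#'   - d^\alpha A_i}
#' The activation term is a saturating (Hill-type) function of the *summed*
#' neighbour signal \eqn{\sum_{j \in NG(i)} D_j N_i}, in both numerator and
#' denominator.
#'
#' @param state An `n_cells x 3` matrix of concentrations, columns `(D, N, A)`.
#' @param params An [nd_params()] object.
#' @param topology An [nd_topology()].
#' @param lambda_per_cell Optional numeric vector of per-cell Delta production
#'   rates (base values, raised to `alpha` internally). Defaults to
#'   `params$lambda` for every cell. Row-wise production patterns on a lattice
#'   are expressed through this argument.
#' @return An `n_cells x 3` matrix of derivatives, columns `(dD, dN, dA)`.
#' @examples
#' p <- table1_params()
#' top <- two_cell_topology()
#' nd_rhs(initial_state(top), p, top)
#' @export
nd_rhs <- function(state, params, topology, lambda_per_cell = NULL) {
  stopifnot(inherits(params, "nd_params"), inherits(topology, "nd_topology"))
  n <- topology$n_cells
  if (!is.matrix(state) || nrow(state) != n || ncol(state) != 3) {
    stop("`state` must be an n_cells x 3 matrix (columns D, N, A); got ",
         paste(dim(state), collapse = " x "), " for ", n, " cells")
  }
  lam <- resolve_lambda(params, topology, lambda_per_cell)
  r <- effective_rates(params)
  lam_eff <- lam^params$alpha

  D <- state[, 1]; N <- state[, 2]; A <- state[, 3]
  sumN <- neighbor_sums(N, topology)
  sumD <- neighbor_sums(D, topology)
  S <- sumD * N
  out <- cbind(dD = lam_eff / (1 + r$theta * A) - r$f * D * sumN - r$d * D,
               dN = r$lambda_n + r$f * sumD * N - r$d * N,
               dA = r$a * S / (r$b + S) - r$d * A)
  out
}

neighbor_sums <- function(v, topology) {
  vapply(topology$neighbors, function(idx) sum(v[idx]), 0.0)
}

resolve_lambda <- function(params, topology, lambda_per_cell) {
  n <- topology$n_cells
  if (is.null(lambda_per_cell)) {
    rep(params$lambda, n)
  } else {
    if (length(lambda_per_cell) != n) {
      stop("`lambda_per_cell` must have one entry per cell (", n, ")")
    }
    if (any(lambda_per_cell < 0)) stop("`lambda_per_cell` entries must be >= 0")
    as.numeric(lambda_per_cell)
  }
}
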