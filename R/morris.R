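#' Morris elementary (base) effect of one parameter
#'
#' Forward-difference sensitivity of a scalar model output to the `i`-th input:
#' \eqn{d_i = [f(x + \Delta e_i) - f(x)] / \Delta}.
#'
#' @param output_fn Function mapping a named numeric parameter vector to a
#'   single number.
#' @param x Named numeric parameter vector (the base point).
#' @param i Index (or name) of the perturbed parameter.
#' @param delta Perturbation \eqn{\Delta} (> 0).
#' @return The base effect `d_i` (single number).
#' @examples
#' base_effect(function(x) 2 * x[["a"]] + 3 * x[["b"]], c(a = 1, b = 1), "a", 0.1)
#' @export
base_effect <- function(output_fn, x, i, delta) {
  stopifnot(is.numeric(x), delta > 0)
  xp <- x
  xp[i] <- xp[i] + delta
  f0 <- output_fn(x)
  f1 <- output_fn(xp)
  if (!is.finite(f0) || !is.finite(f1)) {
    stop("output function failed at base point or perturbed point; x = ",
         paste(sprintf("%s=%g", names(x), x), collapse = ", "),
         "; perturbed: ", names(x)[if (is.character(i)) match(i, names(x)) else i])
  }
  (f1 - f0) / delta
}

#' Morris elementary-effects sensitivity screening
#'
#' Repeated-sampling Morris screening: `R` base points are drawn uniformly
#' from per-parameter ranges (seeded, reproducible), the forward-difference
#' base effect of every parameter is computed at every base point, and the
#' sensitivity of parameter `i` is the mean absolute effect
#' \eqn{S_i = R^{-1} \sum_j |d_i(j)|}. Parameters are ranked by decreasing
#' \eqn{S_i}.
#'
#' The default design screens the eight model parameters (lambda, f, d,
#' lambda_n, a, b, alpha, theta) around their packaged nominal values: ranges
#' are +/-10% of nominal, the perturbation is 1% of nominal (for `alpha` an
#' absolute step of 0.01, with the range capped so that `alpha + delta <= 1`),
#' and `R = 10` with seed 20200723. The published account of this analysis
#' omits the design entirely, so only the resulting *ranking* is meaningful;
#' sensitivity magnitudes depend on the design and are not comparable across
#' studies.
#'
#' @param output_fn Function from a named parameter vector to a scalar output,
#'   e.g. [morris_default_output()].
#' @param nominal Named numeric vector of nominal values, or an [nd_params()]
#'   object.
#' @param R Number of repeated samples (default 10).
#' @param ranges Optional named list of `c(lo, hi)` ranges; default +/-10%
#'   around nominal (for `alpha`, additionally capped at `1 - delta`).
#' @param delta Optional named numeric vector of perturbations; default 1% of
#'   nominal, and 0.01 absolute for `alpha`.
#' @param seed RNG seed for the base-point sample (default 20200723).
#' @return A tibble of class `nd_morris` with columns `parameter`,
#'   `sensitivity`, `rank`, and attributes `effects` (the `R x n` base-effect
#'   matrix) and `design`.
#' @examples
#' f <- function(x) 2 * x[["u"]] - 3 * x[["v"]] + 0 * x[["w"]]
#' morris_sensitivity(f, c(u = 1, v = 1, w = 1), R = 3)
#' @export
morris_sensitivity <- function(output_fn, nominal, R = 10, ranges = NULL,
                               delta = NULL, seed = 20200723) {
  if (inherits(nominal, "nd_params")) nominal <- as_param_vector(nominal)
  stopifnot(is.numeric(nominal), !is.null(names(nominal)), R >= 1)
  nms <- names(nominal)
  n <- length(nominal)

  if (is.null(delta)) {
    delta <- abs(nominal) * 0.01
    if ("alpha" %in% nms) delta[["alpha"]] <- 0.01
    delta[delta == 0] <- 0.01
  } else {
    delta <- unlist(delta)[nms]
  }
  stopifnot(all(delta > 0))

  if (is.null(ranges)) {
    ranges <- lapply(nms, function(nm) sort(c(nominal[[nm]] * 0.9,
                                              nominal[[nm]] * 1.1)))
    names(ranges) <- nms
    if ("alpha" %in% nms) {
      hi <- min(nominal[["alpha"]] * 1.1, 1 - delta[["alpha"]])
      ranges[["alpha"]] <- c(nominal[["alpha"]] * 0.9, hi)
    }
  } else {
    ranges <- ranges[nms]
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  base_points <- matrix(0, R, n, dimnames = list(NULL, nms))
  for (j in seq_len(n)) {
    rg <- ranges[[j]]
    base_points[, j] <- runif(R, rg[1], rg[2])
  }

  effects <- matrix(0, R, n, dimnames = list(NULL, nms))
  for (jrep in seq_len(R)) {
    x <- base_points[jrep, ]
    f0 <- output_fn(x)
    if (!is.finite(f0)) {
      stop("output function failed at base point ", jrep)
    }
    for (i in seq_len(n)) {
      xp <- x
      xp[i] <- xp[i] + delta[[i]]
      f1 <- output_fn(xp)
      if (!is.finite(f1)) {
        stop("output function failed when perturbing `", nms[i],
             "` at base point ", jrep)
      }
      effects[jrep, i] <- (f1 - f0) / delta[[i]]
    }
  }

  S <- colMeans(abs(effects))
  out <- tibble::tibble(parameter = nms, sensitivity = unname(S))
  out$rank <- as.integer(rank(-out$sensitivity, ties.method = "min"))
  structure(out, class = c("nd_morris", class(out)),
            effects = effects,
            design = list(R = R, ranges = ranges, delta = delta, seed = seed,
                          nominal = nominal))
}

#' Default sensitivity output: terminal inactive Notch of cell 1
#'
#' Builds the scalar output functional used by the packaged Morris design: the
#' inactive-Notch concentration of cell 1 at the end of a two-cell simulation
#' (default horizon 4000, step 0.1), as a function of the eight model
#' parameters.
#'
#' @param h Step size (default 0.1).
#' @param t_end Horizon (default 4000).
#' @param ... Further arguments passed to [gl_simulate()].
#' @return A function mapping a named parameter vector (see
#'   [as_param_vector()]) to terminal `N` of cell 1.
#' @export
morris_default_output <- function(h = 0.1, t_end = 4000, ...) {
  force(h); force(t_end)
  dots <- list(...)
  function(x) {
    p <- params_from_vector(x)
    traj <- do.call(gl_simulate,
                    c(list(params = p, topology = two_cell_topology(),
                           h = h, t_end = t_end,
                           record_stride = max(1L, as.integer(t_end / h))),
                      dots))
    ts <- terminal_state(traj)
    ts$N[1]
  }
}

#' @export
print.nd_morris <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf("<nd_morris> R = %d, seed = %s\n", d$R, format(d$seed)))
  NextMethod()
}

#' @export
tidy.nd_morris <- function(x, ...) tibble::as_tibble(x)

#' Parameter perturbation sweep
#'
#' Simulates the two-cell model once per value of a swept parameter and stacks
#' the trajectories, for overlay plotting of how strongly the output responds.
#'
#' @param params Baseline [nd_params()].
#' @param parameter Name of the swept parameter (one of the eight fields).
#' @param values Numeric vector of values to sweep (may be empty).
#' @param topology An [nd_topology()]; default two cells.
#' @param h,t_end,record_stride Solver settings (defaults 0.1, 4000, 100).
#' @param ... Further arguments to [gl_simulate()].
#' @return A tibble with columns `parameter`, `value`, `time`, `cell`, `D`,
#'   `N`, `A`.
#' @examples
#' \donttest{
#' sw <- perturbation_sweep(table1_params(), "d", c(0.008, 0.012), t_end = 400)
#' }
#' @export
perturbation_sweep <- function(params, parameter, values,
                               topology = two_cell_topology(),
                               h = 0.1, t_end = 4000, record_stride = 100,
                               ...) {
  stopifnot(inherits(params, "nd_params"),
            parameter %in% names(unclass(params)))
  pieces <- lapply(values, function(v) {
    p <- unclass(params)
    p[[parameter]] <- v
    p <- do.call(nd_params, p)
    traj <- gl_simulate(p, topology, h = h, t_end = t_end,
                        record_stride = record_stride, ...)
    dplyr::bind_cols(tibble::tibble(parameter = rep(parameter, nrow(traj)),
                                    value = rep(v, nrow(traj))),
                     tibble::as_tibble(traj))
  })
  if (length(pieces) == 0) {
    return(tibble::tibble(parameter = character(), value = numeric(),
                          time = numeric(), cell = integer(),
                          D = numeric(), N = numeric(), A = numeric()))
  }
  dplyr::bind_rows(pieces)
}
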