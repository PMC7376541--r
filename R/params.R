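#' Model parameters for the fractional Delta-Notch model
#'
#' Constructs and validates the eight constants of the improved fractional-order
#' Delta-Notch lateral-inhibition model. All rates are stored as *base* values;
#' inside the model every rate enters raised to the fractional order
#' \eqn{\alpha} (see [effective_rates()]), so the same parameter set describes
#' the whole family of orders \eqn{0 < \alpha \le 1}.
#'
#' @param lambda Delta production rate \eqn{\lambda} (concentration/time,
#'   \eqn{\ge 0}). Set to 0 to model absence of Delta expression.
#' @param f Delta-Notch binding rate (> 0). A single rate is used for both the
#'   Delta-side and Notch-side binding terms.
#' @param d Common degradation rate of Delta, inactive and activated Notch
#'   (> 0).
#' @param lambda_n Production rate of inactive Notch \eqn{\lambda_N} (> 0).
#' @param a Notch activation rate (> 0).
#' @param b Activation saturation constant (> 0).
#' @param theta Inhibition coefficient of activated Notch on Delta production
#'   (\eqn{\ge 0}). The literature writes this constant both as \eqn{\Delta}
#'   and as \eqn{\theta}; one field represents both.
#' @param alpha Fractional derivative order, \eqn{0 < \alpha \le 1}.
#'
#' @return An object of class `nd_params`: a named list with the eight fields.
#' @seealso [table1_params()] for the packaged default scenario,
#'   [effective_rates()] for the \eqn{\alpha}-powered rates.
#' @examples
#' p <- nd_params(lambda = 1000)
#' effective_rates(p)
#' @export
nd_params <- function(lambda = 1000, f = 0.01, d = 0.01, lambda_n = 0.07,
                      a = 0.01, b = 200, theta = 1e6, alpha = 0.9) {
  p <- list(lambda = lambda, f = f, d = d, lambda_n = lambda_n,
            a = a, b = b, theta = theta, alpha = alpha)
  validate_nd_params(p)
  structure(p, class = "nd_params")
}

validate_nd_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) {
      stop("parameter `", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  strictly_pos <- c("f", "d", "lambda_n", "a", "b")
  for (nm in strictly_pos) {
    if (p[[nm]] <= 0) stop("parameter `", nm, "` must be > 0", call. = FALSE)
  }
  if (p$lambda < 0) stop("parameter `lambda` must be >= 0", call. = FALSE)
  if (p$theta < 0) stop("parameter `theta` must be >= 0", call. = FALSE)
  if (p$alpha <= 0 || p$alpha > 1) {
    stop("fractional order `alpha` must satisfy 0 < alpha <= 1", call. = FALSE)
  }
  invisible(p)
}

#' Default simulation parameter set
#'
#' The packaged default scenario: \eqn{f = d = 0.01}, \eqn{\lambda_N = 0.07},
#' \eqn{a = 0.01}, \eqn{b = 200}, \eqn{\theta = 10^6}, \eqn{\alpha = 0.9}, with
#' the Delta production rate \eqn{\lambda \in \{0, 1000\}} selectable.
#'
#' @param lambda Delta production rate, typically 0 (no Delta expression) or
#'   1000 (normal/over-expression).
#' @param ... Overrides for any other field of [nd_params()].
#' @return An `nd_params` object.
#' @examples
#' table1_params(lambda = 0)
#' @export
table1_params <- function(lambda = 1000, ...) {
  nd_params(lambda = lambda, ...)
}

#' Rates raised to the fractional order
#'
#' In the fractional model every rate constant enters the right-hand side
#' raised to the power \eqn{\alpha}: \eqn{\lambda^\alpha, f^\alpha, \dots}.
#' This function materialises those effective rates so they can be audited;
#' at \eqn{\alpha = 1} the result equals the base parameters componentwise.
#'
#' @param params An [nd_params()] object.
#' @return An object of class `nd_rates`: a named list with fields `lambda`,
#'   `f`, `d`, `lambda_n`, `a`, `b`, `theta` (each equal to
#'   `base^alpha`) and `alpha` (carried through unchanged).
#' @examples
#' effective_rates(table1_params())$lambda # 1000^0.9
#' @export
effective_rates <- function(params) {
  stopifnot(inherits(params, "nd_params"))
  a <- params$alpha
  r <- list(lambda   = params$lambda^a,
            f        = params$f^a,
            d        = params$d^a,
            lambda_n = params$lambda_n^a,
            a        = params$a^a,
            b        = params$b^a,
            theta    = params$theta^a,
            alpha    = a)
  structure(r, class = "nd_rates")
}

#' @export
print.nd_params <- function(x, ...) {
  cat("<nd_params> fractional Delta-Notch model parameters\n")
  vals <- unlist(x)
  cat(paste0("  ", format(names(vals), width = 9), " ",
             format(vals, digits = 6)), sep = "\n")
  invisible(x)
}

#' @export
print.nd_rates <- function(x, ...) {
  cat("<nd_rates> effective rates (base^alpha), alpha =", x$alpha, "\n")
  vals <- unlist(x[setdiff(names(x), "alpha")])
  cat(paste0("  ", format(names(vals), width = 9), " ",
             format(vals, digits = 6)), sep = "\n")
  invisible(x)
}

# Canonical parameter ordering used for sensitivity designs and vectorisation.
param_names <- function() {
  c("lambda", "f", "d", "lambda_n", "a", "b", "alpha", "theta")
}

#' Convert parameters to and from a named vector
#'
#' Utility pair used by the Morris sensitivity design, where a parameter set is
#' treated as a point in an 8-dimensional input space.
#'
#' @param params An `nd_params` object.
#' @return `as_param_vector()` returns a named numeric vector in the canonical
#'   order (lambda, f, d, lambda_n, a, b, alpha, theta);
#'   `params_from_vector()` is its inverse.
#' @examples
#' x <- as_param_vector(table1_params())
#' identical(params_from_vector(x), table1_params())
#' @export
as_param_vector <- function(params) {
  stopifnot(inherits(params, "nd_params"))
  vapply(param_names(), function(nm) params[[nm]], 0.0)
}

#' @rdname as_param_vector
#' @param x A named numeric vector with the eight parameter names.
#' @export
params_from_vector <- function(x) {
  stopifnot(is.numeric(x), !is.null(names(x)),
            setequal(names(x), param_names()))
  do.call(nd_params, as.list(x[param_names()]))
}

#' @export
tidy.nd_params <- function(x, ...) {
  tibble::tibble(parameter = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}

#' @export
tidy.nd_rates <- function(x, ...) {
  tibble::tibble(parameter = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}
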