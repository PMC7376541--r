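#' Simulation scenarios
#'
#' A scenario bundles everything one run needs: parameters, cell topology,
#' per-cell Delta production rates and solver settings. `lattice_scenario()`
#' builds the multi-cell intestine grid (default 5 rows x 12 columns, von
#' Neumann neighbourhood, non-periodic) with row-wise Delta production:
#' the canonical pattern is \eqn{\lambda = 1000} in the first three rows
#' (the Delta-expressing domain) and \eqn{\lambda = 0} in rows four and five.
#' `two_cell_scenario()` builds the minimal two-cell configuration analysed in
#' closed form.
#'
#' @param rows,cols Grid dimensions (default 5 x 12).
#' @param lambda_rows Per-row Delta production rates (length `rows`).
#' @param params An [nd_params()] object (its `lambda` field is superseded by
#'   `lambda_rows` on the lattice).
#' @param periodic_cols Wrap columns into a ring (default `FALSE`).
#' @param h,t_end,memory_window,record_stride Solver settings; lattice default
#'   `h = 0.5`, two-cell default `h = 0.1`, horizon 4000.
#' @param x0 Initial state specification (default 0.5 everywhere).
#' @return An object of class `nd_scenario`.
#' @export
lattice_scenario <- function(rows = 5, cols = 12,
                             lambda_rows = c(1000, 1000, 1000, 0, 0),
                             params = table1_params(),
                             periodic_cols = FALSE,
                             h = 0.5, t_end = 4000, memory_window = 0,
                             record_stride = 100, x0 = 0.5) {
  stopifnot(length(lambda_rows) == rows, all(lambda_rows >= 0))
  structure(list(kind = "lattice", rows = as.integer(rows),
                 cols = as.integer(cols),
                 lambda_rows = as.numeric(lambda_rows), params = params,
                 periodic_cols = periodic_cols,
                 h = h, t_end = t_end, memory_window = memory_window,
                 record_stride = record_stride, x0 = x0),
            class = "nd_scenario")
}

#' @rdname lattice_scenario
#' @export
two_cell_scenario <- function(params = table1_params(), h = 0.1, t_end = 4000,
                              memory_window = 0, record_stride = 100,
                              x0 = 0.5) {
  structure(list(kind = "two_cell", params = params,
                 h = h, t_end = t_end, memory_window = memory_window,
                 record_stride = record_stride, x0 = x0),
            class = "nd_scenario")
}

#' @export
print.nd_scenario <- function(x, ...) {
  if (x$kind == "lattice") {
    cat(sprintf("<nd_scenario> %dx%d lattice, lambda rows: %s\n",
                x$rows, x$cols, paste(x$lambda_rows, collapse = ", ")))
  } else {
    cat("<nd_scenario> two cells\n")
  }
  cat(sprintf("  params: d = %g, alpha = %g; solver: h = %g, t_end = %g\n",
              x$params$d, x$params$alpha, x$h, x$t_end))
  invisible(x)
}

#' Build the topology and per-cell production rates of a scenario
#'
#' @param scenario An `nd_scenario`.
#' @return List with `topology` ([nd_topology()]) and `lambda_per_cell`.
#' @examples
#' build_lattice(lattice_scenario())$topology
#' @export
build_lattice <- function(scenario) {
  stopifnot(inherits(scenario, "nd_scenario"))
  if (scenario$kind == "two_cell") {
    return(list(topology = two_cell_topology(),
                lambda_per_cell = rep(scenario$params$lambda, 2)))
  }
  top <- grid_topology(scenario$rows, scenario$cols, scenario$periodic_cols)
  list(topology = top,
       lambda_per_cell = rep(scenario$lambda_rows, each = scenario$cols))
}

#' Run a scenario and classify its phenotype
#'
#' Simulates the scenario with [gl_simulate()] and, for lattice scenarios,
#' classifies the terminal inactive-Notch matrix into a row phenotype with
#' [classify_phenotype()].
#'
#' @param scenario An `nd_scenario`.
#' @param component Component used for the phenotype read-out (default `"N"`,
#'   the Notch level the stainings report).
#' @param ... Further arguments to [gl_simulate()] (e.g. `ic_correction`).
#' @return List with `trajectory` (an `nd_trajectory`), and for lattices also
#'   `notch` (the terminal matrix) and `phenotype` (an `nd_phenotype`).
#' @export
run_scenario <- function(scenario, component = "N", ...) {
  stopifnot(inherits(scenario, "nd_scenario"))
  bl <- build_lattice(scenario)
  traj <- gl_simulate(scenario$params, bl$topology, x0 = scenario$x0,
                      h = scenario$h, t_end = scenario$t_end,
                      memory_window = scenario$memory_window,
                      record_stride = scenario$record_stride,
                      lambda_per_cell = bl$lambda_per_cell, ...)
  out <- list(trajectory = traj)
  if (scenario$kind == "lattice") {
    out$notch <- notch_matrix(traj, scenario$rows, scenario$cols, component)
    out$phenotype <- classify_phenotype(out$notch)
  }
  out
}

#' Classify a lattice Notch matrix into a row phenotype
#'
#' Operationalises the colour read-out of the intestine heatmaps: the per-row
#' mean Notch level is normalised by the maximum row mean, giving a row
#' intensity in `[0, 1]`, and each row is binned as `deep`
#' (intensity >= `thresholds["deep"]`), `light` (< `thresholds["light"]`) or
#' `medium` (in between). The row-class vector is matched against three named
#' templates (for a grid with `r` rows and middle row `m = ceiling(r/2)`):
#' * `wild-type` - deep exactly at the middle row, light elsewhere
#'   (the one-row boundary strand);
#' * `mutant` - rows `1..m` deep, the remaining rows light (Notch
#'   over-expressed throughout the Delta-expressing domain);
#' * `complete-mutant` - all rows deep;
#' anything else is `other`. The classification is scale-invariant by
#' construction.
#'
#' @param notch Nonnegative numeric matrix of terminal Notch levels.
#' @param thresholds Named numeric vector `c(light = 1/3, deep = 2/3)`.
#' @return A tibble of class `nd_phenotype` with columns `row`, `intensity`,
#'   `class`, and attributes `phenotype`, `thresholds` and `notch`.
#' @examples
#' classify_phenotype(matrix(c(0, 0, 1, 0, 0), 5, 12))
#' @export
classify_phenotype <- function(notch, thresholds = c(light = 1 / 3, deep = 2 / 3)) {
  stopifnot(is.matrix(notch), all(is.finite(notch)))
  if (any(notch < 0)) stop("`notch` must be nonnegative")
  stopifnot(all(c("light", "deep") %in% names(thresholds)),
            thresholds[["light"]] <= thresholds[["deep"]])
  r <- nrow(notch)
  rm <- rowMeans(notch)
  if (max(rm) == 0) {
    warning("all-zero Notch matrix; phenotype 'other'")
    intensity <- rep(0, r)
  } else {
    intensity <- rm / max(rm)
  }
  cls <- ifelse(intensity >= thresholds[["deep"]], "deep",
                ifelse(intensity < thresholds[["light"]], "light", "medium"))
  mid <- ceiling(r / 2)
  wild <- rep("light", r); wild[mid] <- "deep"
  mutant <- c(rep("deep", mid), rep("light", r - mid))
  phen <- if (max(rm) == 0) {
    "other"
  } else if (all(cls == "deep")) {
    "complete-mutant"
  } else if (identical(cls, wild)) {
    "wild-type"
  } else if (identical(cls, mutant)) {
    "mutant"
  } else {
    "other"
  }
  out <- tibble::tibble(row = seq_len(r), intensity = intensity, class = cls)
  structure(out, class = c("nd_phenotype", class(out)),
            phenotype = phen, thresholds = thresholds, notch = notch)
}

#' @export
print.nd_phenotype <- function(x, ...) {
  cat(sprintf("<nd_phenotype> %s (rows: %s)\n", attr(x, "phenotype"),
              paste(substr(x$class, 1, 1), collapse = ",")))
  NextMethod()
}

#' @export
glance.nd_phenotype <- function(x, ...) {
  tibble::tibble(phenotype = attr(x, "phenotype"),
                 n_deep = sum(x$class == "deep"),
                 n_medium = sum(x$class == "medium"),
                 n_light = sum(x$class == "light"))
}

#' Compare fractional orders on the same scenario
#'
#' Runs one scenario for each order in `alphas` (the scheme reduces exactly to
#' forward Euler at \eqn{\alpha = 1}, so the integer-order model is the
#' `alpha = 1` member of the family) and tabulates the terminal states, plus
#' the phenotype classification for lattice scenarios.
#'
#' @param scenario An `nd_scenario`.
#' @param alphas Numeric vector of orders in `(0, 1]`.
#' @param ... Further arguments to [run_scenario()].
#' @return List with `endpoints` (tibble: `alpha`, `cell`, `D`, `N`, `A`) and
#'   `phenotypes` (named list of `nd_phenotype`, lattice scenarios only).
#' @export
compare_orders <- function(scenario, alphas, ...) {
  stopifnot(inherits(scenario, "nd_scenario"),
            all(alphas > 0), all(alphas <= 1))
  runs <- lapply(alphas, function(a) {
    sc <- scenario
    p <- unclass(sc$params); p$alpha <- a
    sc$params <- do.call(nd_params, p)
    run_scenario(sc, ...)
  })
  endpoints <- dplyr::bind_rows(lapply(seq_along(alphas), function(i) {
    ts <- terminal_state(runs[[i]]$trajectory)
    dplyr::bind_cols(tibble::tibble(alpha = rep(alphas[i], nrow(ts))), ts)
  }))
  phenos <- if (scenario$kind == "lattice") {
    setNames(lapply(runs, `[[`, "phenotype"), paste0("alpha=", alphas))
  } else NULL
  list(endpoints = endpoints, phenotypes = phenos)
}
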