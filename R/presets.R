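#' Packaged scenario presets
#'
#' Named scenario bundles for the canonical experiments:
#' * `"table1-lambda0"` - two cells, default parameters, no Delta production.
#' * `"table1-lambda1000"` - two cells, Delta over-expression
#'   (\eqn{\lambda = 1000}).
#' * `"lattice-wildtype"` - 5x12 lattice, `d = 0.018`.
#' * `"lattice-mutant"` - 5x12 lattice, `d = 0.012`.
#' * `"lattice-complete"` - 5x12 lattice, `d = 0.001`.
#' * `"lattice-order-compare"` - 5x12 lattice, `d = 0.004`, for comparing
#'   fractional orders.
#'
#' All lattice presets use the row pattern \eqn{\lambda = (1000, 1000, 1000,
#' 0, 0)} and otherwise the default parameters (`f = 0.01`,
#' `lambda_n = 0.07`, `a = 0.01`, `b = 200`, `theta = 1e6`, `alpha = 0.9`).
#'
#' @param name Preset name (see above).
#' @return An `nd_scenario`.
#' @examples
#' scenario_preset("table1-lambda1000")
#' @export
scenario_preset <- function(name) {
  switch(name,
    "table1-lambda0" = two_cell_scenario(table1_params(lambda = 0)),
    "table1-lambda1000" = two_cell_scenario(table1_params(lambda = 1000)),
    "lattice-wildtype" = lattice_scenario(params = table1_params(d = 0.018)),
    "lattice-mutant" = lattice_scenario(params = table1_params(d = 0.012)),
    "lattice-complete" = lattice_scenario(params = table1_params(d = 0.001)),
    "lattice-order-compare" = lattice_scenario(params = table1_params(d = 0.004)),
    stop("unknown preset `", name, "`; available: table1-lambda0, ",
         "table1-lambda1000, lattice-wildtype, lattice-mutant, ",
         "lattice-complete, lattice-order-compare")
  )
}

config_keys <- function() {
  c("preset", "rows", "cols", "lambda_rows", "params", "periodic_cols",
    "h", "t_end", "memory_window", "record_stride", "x0", "seed", "alphas")
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a scenario description, applies defaults, validates parameter
#' domains, and rejects unknown keys. An empty file yields the default
#' two-cell scenario. Recognised keys: `preset`, `rows`, `cols`,
#' `lambda_rows`, `params` (sub-keys of [nd_params()]), `periodic_cols`, `h`,
#' `t_end`, `memory_window`, `record_stride`, `x0`, `seed`, `alphas`.
#' Explicit keys override the preset's values.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file.
#' @return List with `scenario` (an `nd_scenario`), `seed`, `alphas` and
#'   `config` (the fully resolved key-value list).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a mapping of keys to values")
  unknown <- setdiff(names(cfg), config_keys())
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(cfg$params)) {
    bad <- setdiff(names(cfg$params), names(unclass(nd_params())))
    if (length(bad) > 0) {
      stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
    }
  }

  scenario <- if (!is.null(cfg$preset)) scenario_preset(cfg$preset)
              else two_cell_scenario()
  params <- unclass(scenario$params)
  for (nm in names(cfg$params)) params[[nm]] <- cfg$params[[nm]]
  params <- do.call(nd_params, params)   # validates domains (e.g. alpha <= 1)

  if (scenario$kind == "lattice" || !is.null(cfg$rows) || !is.null(cfg$cols) ||
      !is.null(cfg$lambda_rows)) {
    if (scenario$kind != "lattice") scenario <- lattice_scenario(params = params)
    sc <- unclass(scenario)
    for (nm in intersect(names(cfg), c("rows", "cols", "lambda_rows",
                                       "periodic_cols", "h", "t_end",
                                       "memory_window", "record_stride", "x0"))) {
      sc[[nm]] <- cfg[[nm]]
    }
    scenario <- lattice_scenario(rows = sc$rows, cols = sc$cols,
                                 lambda_rows = unlist(sc$lambda_rows),
                                 params = params,
                                 periodic_cols = isTRUE(sc$periodic_cols),
                                 h = sc$h, t_end = sc$t_end,
                                 memory_window = sc$memory_window,
                                 record_stride = sc$record_stride, x0 = sc$x0)
  } else {
    sc <- unclass(scenario)
    for (nm in intersect(names(cfg), c("h", "t_end", "memory_window",
                                       "record_stride", "x0"))) {
      sc[[nm]] <- cfg[[nm]]
    }
    scenario <- two_cell_scenario(params = params, h = sc$h, t_end = sc$t_end,
                                  memory_window = sc$memory_window,
                                  record_stride = sc$record_stride, x0 = sc$x0)
  }

  resolved <- unclass(scenario)
  resolved$params <- unclass(params)
  list(scenario = scenario,
       seed = if (is.null(cfg$seed)) 20200723L else as.integer(cfg$seed),
       alphas = cfg$alphas,
       config = resolved)
}

#' Write the outputs of a scenario run to a directory
#'
#' Writes, with deterministic file names: the trajectory as tidy CSV
#' (`trajectory.csv`: time, cell, D, N, A), the phenotype report
#' (`phenotype.json`) and Notch matrix (`notch.csv`) when present, a PNG
#' heatmap (`heatmap.png`, blue intensity proportional to normalised Notch)
#' when present, and a reproducibility manifest (`manifest.json`) echoing the
#' resolved configuration, the seed, the package version and a configuration
#' hash.
#'
#' @param run A list as returned by [run_scenario()].
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the manifest.
#' @param config Resolved configuration list to echo into the manifest.
#' @param heatmap Write the PNG heatmap (default `TRUE`; requires a lattice
#'   run).
#' @return Character vector of the files written, invisibly.
#' @export
write_run_outputs <- function(run, dir, seed = NULL, config = list(),
                              heatmap = TRUE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)

  traj_path <- file.path(dir, "trajectory.csv")
  write.csv(tibble::as_tibble(run$trajectory)[, c("time", "cell", "D", "N", "A")],
            traj_path, row.names = FALSE)
  written <- c(written, traj_path)

  if (!is.null(run$notch)) {
    notch_path <- file.path(dir, "notch.csv")
    write.csv(as.data.frame(run$notch), notch_path, row.names = FALSE)
    written <- c(written, notch_path)
  }
  if (!is.null(run$phenotype)) {
    ph <- run$phenotype
    ph_path <- file.path(dir, "phenotype.json")
    jsonlite::write_json(list(phenotype = attr(ph, "phenotype"),
                              thresholds = as.list(attr(ph, "thresholds")),
                              rows = tibble::as_tibble(ph)),
                         ph_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, ph_path)
    if (heatmap) {
      hm_path <- file.path(dir, "heatmap.png")
      ggplot2::ggsave(hm_path, autoplot(ph), width = 6, height = 3.2, dpi = 150)
      written <- c(written, hm_path)
    }
  }

  cfg <- attr(run$trajectory, "config")
  manifest <- list(package = "fdnotch",
                   version = as.character(packageVersion("fdnotch")),
                   seed = seed,
                   solver = cfg,
                   config = config,
                   config_hash = rlang::hash(list(cfg, config, seed)),
                   files = basename(written))
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  written <- c(written, man_path)
  invisible(written)
}
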