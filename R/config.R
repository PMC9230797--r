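#' Load a model configuration file
#'
#' Reads a YAML configuration with `compound`, `metabolite`, `formulation`,
#' `pd` and `simulation` blocks, validates it against the known schema
#' (unknown keys are rejected with the offending name), fills defaults from
#' the shipped tegoprazan parameter set, and returns ready-to-use parameter
#' objects. The shipped configuration is at
#' `system.file("extdata", "tegoprazan.yaml", package = "tegopbpk")`.
#'
#' @param path Path to a YAML file.
#' @return An object of class `model_config`: list with `compound`,
#'   `metabolite`, `formulation`, `pd`, `baseline`, `simulation` (list with
#'   `seed`, `n_subjects`, `n_trials`, `scenario`, `feedback`), and `raw`.
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  known_blocks <- c("compound", "metabolite", "formulation", "pd",
                    "baseline", "simulation")
  extra <- setdiff(names(raw), known_blocks)
  if (length(extra))
    stop("unknown config block(s): ", paste(extra, collapse = ", "))

  take <- function(block, builder, unit_hints = character()) {
    vals <- raw[[block]]
    if (is.null(vals)) vals <- list()
    allowed <- names(formals(builder))
    bad <- setdiff(names(vals), allowed)
    if (length(bad))
      stop(sprintf("unknown key '%s.%s'%s", block, bad[1],
                   if (bad[1] %in% names(unit_hints))
                     paste0(" (", unit_hints[[bad[1]]], ")") else ""))
    num_named <- intersect(names(vals), c("clint_cyp"))
    for (k in num_named) vals[[k]] <- unlist(vals[[k]])
    do.call(builder, vals)
  }

  compound <- take("compound", compound_params)
  metabolite <- take("metabolite", metabolite_params)
  formulation <- take("formulation", formulation_params)
  if (!is.null(raw$formulation) && is.null(raw$formulation$dose_mg))
    stop("missing required key 'formulation.dose_mg' (mg)")
  pd <- take("pd", pd_params)
  bl_raw <- raw$baseline
  baseline <- if (is.null(bl_raw)) fourier_baseline() else
    fourier_baseline(
      a0 = if (is.null(bl_raw[["a0"]])) 1.49 else bl_raw[["a0"]],
      a = if (is.null(bl_raw[["a"]])) numeric(6) else unlist(bl_raw[["a"]]),
      b = if (is.null(bl_raw[["b"]])) numeric(6) else unlist(bl_raw[["b"]]))

  sim_defaults <- list(seed = 20220618L, n_subjects = 100L, n_trials = 10L,
                       scenario = "single_100", feedback = TRUE,
                       rtol = 1e-8, atol = 1e-10)
  sim <- raw$simulation
  bad <- setdiff(names(sim), names(sim_defaults))
  if (length(bad)) stop("unknown key 'simulation.", bad[1], "'")
  sim_defaults[names(sim)] <- sim

  structure(list(compound = compound, metabolite = metabolite,
                 formulation = formulation, pd = pd, baseline = baseline,
                 simulation = sim_defaults, raw = raw),
            class = "model_config")
}

#' Write a normalized configuration back to YAML
#'
#' @param config A `model_config` from [load_model_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  strip <- function(x) {
    x <- unclass(x)
    x <- x[!vapply(x, is.null, logical(1))]
    # yaml drops names of atomic vectors; write named vectors as maps
    lapply(x, function(v)
      if (is.atomic(v) && !is.null(names(v))) as.list(v) else v)
  }
  out <- list(compound = strip(config$compound),
              metabolite = strip(config$metabolite),
              formulation = strip(config$formulation),
              pd = strip(config$pd),
              baseline = list(a0 = config$baseline$a0,
                              a = config$baseline$a, b = config$baseline$b),
              simulation = config$simulation)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Command-line dispatcher
#'
#' A thin, testable dispatcher over the package's functions, mirroring the
#' analysis stages: `simulate`, `synth`, `nca`, `holding-rate`,
#' `fit-baseline`. Returns an integer exit code (0 success, 2 usage error)
#' rather than calling `quit()`, so it can be wrapped by an Rscript front-end
#' or called from tests.
#'
#' @param argv Character vector of arguments, e.g.
#'   `c("simulate", "--scenario", "single_100", "--seed", "1", "--out", dir)`.
#' @return Integer exit code, invisibly.
#' @export
tegopbpk_cli <- function(argv = character()) {
  usage <- function() {
    cat("usage: tegopbpk <simulate|synth|nca|holding-rate|fit-baseline> [options]\n",
        "  simulate --scenario <name> [--seed S] [--n N] [--trials K] --out DIR\n",
        "  synth --seed S --out FILE.csv [--n N]\n",
        "  nca --in FILE.csv --dose MG\n",
        "  holding-rate --in FILE.csv\n",
        "  fit-baseline --in FILE.csv\n", sep = "")
  }
  opt <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (length(i) && i < length(argv)) argv[i + 1] else default
  }
  if (!length(argv) || argv[1] %in% c("--help", "-h")) { usage(); return(invisible(0L)) }
  cmd <- argv[1]
  res <- try(switch(cmd,
    "simulate" = {
      out_dir <- opt("--out", "results")
      s <- run_scenario(opt("--scenario", "single_100"),
                        n_subjects = as.integer(opt("--n", "10")),
                        n_trials = as.integer(opt("--trials", "1")),
                        seed = as.integer(opt("--seed", "20220618")),
                        out_dir = out_dir)
      manifest <- list(scenario = attr(s, "scenario"),
                       seed = as.integer(opt("--seed", "20220618")),
                       n_subjects = as.integer(opt("--n", "10")),
                       n_trials = as.integer(opt("--trials", "1")),
                       version = as.character(utils::packageVersion("tegopbpk")),
                       n_failures = length(s$failures))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE)
      0L
    },
    "synth" = {
      out <- opt("--out", "observed.csv")
      d <- generate_observed_pk(n_subjects = as.integer(opt("--n", "12")),
                                seed = as.integer(opt("--seed", "1")))
      utils::write.csv(d$data, out, row.names = FALSE)
      0L
    },
    "nca" = {
      d <- utils::read.csv(opt("--in"))
      s <- nca(d$time_h, d$conc_ng_ml, dose_mg = as.numeric(opt("--dose", "100")))
      print(s)
      0L
    },
    "holding-rate" = {
      d <- utils::read.csv(opt("--in"))
      cat(sprintf("holding rate (pH>=4): %.1f%%\n",
                  holding_rate(d$time_h, d$ph)))
      0L
    },
    "fit-baseline" = {
      d <- utils::read.csv(opt("--in"))
      bl <- fit_fourier_baseline(d$time_h, d$ph)
      cat("a0:", bl$a0, "\na:", bl$a, "\nb:", bl$b, "\n")
      0L
    },
    { usage(); 2L }), silent = TRUE)
  if (inherits(res, "try-error")) {
    message("error: ", attr(res, "condition")$message)
    return(invisible(1L))
  }
  invisible(res)
}
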