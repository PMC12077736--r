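# Configuration loading/validation, tabular results writing with run
# manifests, and the command-line interface.

#' Load a simulation configuration file
#'
#' Reads a YAML (or JSON) file with optional top-level blocks `params`,
#' `simulation`, `scenarios` and `gsa`. Unspecified parameters take the
#' package defaults. Capacities (`egg_capacity`, `summer_capacity`,
#' `winter_capacity`) may be given directly or as a block
#' `{density_per_m2: , area_km2: }` (see [capacity_from_density()]).
#' Scenario entries are `{label: , overrides: {...}}`; the `gsa` block takes
#' `{preset: broad|restricted, n_samples: , seed: }`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `params` ([lamprey_params()]), `config`
#'   ([sim_config()]), `scenarios` (list of [scenario_spec()] or `NULL`) and
#'   `gsa` (list of [dist_spec()] or `NULL`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  raw <- raw %||% list()
  known <- c("params", "simulation", "scenarios", "gsa")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown top-level config key(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(known, collapse = ", "), call. = FALSE)

  pargs <- as.list(raw$params %||% list())
  bad <- setdiff(names(pargs), names(formals(lamprey_params)))
  if (length(bad))
    stop("unknown parameter(s) in `params`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (cap in c("egg_capacity", "summer_capacity", "winter_capacity")) {
    v <- pargs[[cap]]
    if (is.list(v)) {
      bad <- setdiff(names(v), c("density_per_m2", "area_km2"))
      if (length(bad))
        stop("`", cap, "` block accepts density_per_m2 and area_km2 only",
             call. = FALSE)
      pargs[[cap]] <- capacity_from_density(v$density_per_m2, v$area_km2)
    }
  }
  # YAML sequences arrive as lists when empty ([]) or of mixed int/double
  for (nm in names(pargs))
    if (is.list(pargs[[nm]]))
      pargs[[nm]] <- as.numeric(unlist(pargs[[nm]]) %||% numeric(0))
  params <- do.call(lamprey_params, pargs)

  cargs <- as.list(raw$simulation %||% list())
  bad <- setdiff(names(cargs), names(formals(sim_config)))
  if (length(bad))
    stop("unknown setting(s) in `simulation`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  config <- do.call(sim_config, cargs)

  scenarios <- NULL
  if (!is.null(raw$scenarios)) {
    scenarios <- lapply(raw$scenarios, function(s)
      scenario_spec(s$label, as.list(s$overrides %||% list())))
  }

  gsa <- NULL
  if (!is.null(raw$gsa)) {
    preset <- match.arg(raw$gsa$preset, c("broad", "restricted"))
    gsa <- list(specs = gsa_presets()[[preset]],
                n_samples = raw$gsa$n_samples %||% 100,
                seed = raw$gsa$seed %||% config$seed)
  }

  list(params = params, config = config, scenarios = scenarios, gsa = gsa)
}

#' Long-format counts from a simulation
#'
#' One row per (replicate, year, stage, age): larvae ages 0-10,
#' transformers, juvenile ocean ages 0-10, adult river ages 0-2, spawners
#' and eggs (28 rows per replicate-year). `age` is `NA` for unaged stages.
#'
#' @param x A `lamprey_sim`.
#' @param ... Unused.
#' @return A data frame with columns `replicate`, `year`, `stage`, `age`,
#'   `count`.
#' @export
as.data.frame.lamprey_sim <- function(x, ...) {
  d <- dim(x$counts)
  grid <- expand.grid(slot = seq_len(d[3]), year = seq_len(d[2]),
                      replicate = seq_len(d[1]))
  data.frame(replicate = grid$replicate,
             year = grid$year,
             stage = STATE_STAGES[grid$slot],
             age = STATE_AGES[grid$slot],
             count = as.vector(aperm(x$counts, c(3, 2, 1))))
}

write_manifest <- function(path, files, seed = NULL, extra = list()) {
  hashes <- tools::md5sum(files)
  manifest <- c(list(created = format(Sys.time(), tz = "UTC",
                                      usetz = TRUE),
                     package = "lampresim",
                     version = as.character(packageVersion("lampresim")),
                     seed = seed,
                     files = as.list(setNames(unname(hashes),
                                              basename(files)))),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Write results as CSV with a run manifest
#'
#' Writes a header-row CSV (long counts or wide summary for simulations;
#' the importance table or scenario summaries for the other classes) plus a
#' JSON manifest (`<path>.manifest.json`) holding the file MD5, seed,
#' package version and timestamp.
#'
#' @param x A `lamprey_sim`, `scenario_comparison`, `gsa_design` or
#'   `importance_table`.
#' @param path Output CSV path.
#' @param format For simulations: `"long"` (replicate, year, stage, age,
#'   count) or `"summary"` (year, statistic, value across replicates).
#' @param ... Unused.
#' @return Invisibly, the CSV path.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @rdname write_results
#' @export
write_results.lamprey_sim <- function(x, path, format = c("long", "summary"),
                                      ...) {
  format <- match.arg(format)
  df <- if (format == "long") as.data.frame(x) else {
    med <- summarize_replicates(x, "spawners", "median",
                                include_burn_in = TRUE)
    mn <- summarize_replicates(x, "spawners", "mean",
                               include_burn_in = TRUE)
    rbind(cbind(statistic = "median", med), cbind(statistic = "mean", mn))
  }
  write.csv(df, path, row.names = FALSE)
  write_manifest(paste0(path, ".manifest.json"), path,
                 seed = x$config$seed,
                 extra = list(mode = x$config$mode,
                              replicates = x$config$replicates,
                              years = x$config$years,
                              burn_in = x$config$burn_in))
  invisible(path)
}

#' @rdname write_results
#' @export
write_results.scenario_comparison <- function(x, path, ...) {
  write.csv(x$summaries, path, row.names = FALSE)
  write_manifest(paste0(path, ".manifest.json"), path,
                 seed = x$config$seed)
  invisible(path)
}

#' @rdname write_results
#' @export
write_results.gsa_design <- function(x, path, ...) {
  write.csv(as.data.frame(x$matrix), path, row.names = FALSE)
  write_manifest(paste0(path, ".manifest.json"), path, seed = x$seed)
  invisible(path)
}

#' @rdname write_results
#' @export
write_results.importance_table <- function(x, path, ...) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  write_manifest(paste0(path, ".manifest.json"), path)
  invisible(path)
}

cli_usage <- function() {
  cat("usage: lampresim <simulate|scenarios|gsa|importance> [options]\n",
      "  simulate    run a life cycle simulation and write long-format counts\n",
      "  scenarios   run management scenarios (--preset case-study)\n",
      "  gsa         build a sensitivity design and run the model over it\n",
      "  importance  random-forest importance from a design + response CSV\n",
      sep = "")
}

cli_common_options <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML/JSON configuration file"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--deterministic", action = "store_true",
                          default = FALSE),
    optparse::make_option("--replicates", type = "integer", default = NULL),
    optparse::make_option("--years", type = "integer", default = NULL),
    optparse::make_option("--burn-in", type = "integer", default = NULL,
                          dest = "burn_in"),
    optparse::make_option("--out", type = "character", default = "out.csv"),
    optparse::make_option("--verbose", action = "store_true",
                          default = FALSE))
}

cli_load <- function(opt) {
  loaded <- if (!is.null(opt$config)) load_config(opt$config)
            else list(params = lamprey_params(), config = sim_config())
  cfg <- loaded$config
  cfg$seed <- opt$seed
  if (opt$deterministic) cfg$mode <- "deterministic"
  if (!is.null(opt$replicates)) cfg$replicates <- opt$replicates
  if (!is.null(opt$years)) cfg$years <- opt$years
  if (!is.null(opt$burn_in)) cfg$burn_in <- opt$burn_in
  loaded$config <- do.call(sim_config, unclass(cfg))
  loaded
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `scenarios`, `gsa` and `importance`
#' subcommands (see the thin wrapper installed at `inst/cli/lampresim`).
#' Validation failures print a message and return a non-zero status instead
#' of raising.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit status (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 ||
      !args[1] %in% c("simulate", "scenarios", "gsa", "importance")) {
    cli_usage()
    return(1L)
  }
  sub <- args[1]
  rest <- args[-1]
  tryCatch({
    switch(sub,
      simulate = {
        opt <- optparse::parse_args(
          optparse::OptionParser(option_list = cli_common_options()),
          args = rest)
        loaded <- cli_load(opt)
        sim <- run_simulation(loaded$params, loaded$config)
        write_results(sim, opt$out)
        if (opt$verbose) print(sim)
      },
      scenarios = {
        opts <- c(cli_common_options(),
                  list(optparse::make_option("--preset", type = "character",
                                             default = "case-study")))
        opt <- optparse::parse_args(
          optparse::OptionParser(option_list = opts), args = rest)
        loaded <- cli_load(opt)
        scen <- if (!is.null(loaded$scenarios)) loaded$scenarios
                else if (opt$preset == "case-study") scenario_presets()
                else stop("unknown scenario preset: ", opt$preset)
        cmp <- run_scenarios(loaded$params, scen, loaded$config)
        write_results(cmp, opt$out)
        if (opt$verbose) print(cmp)
      },
      gsa = {
        opts <- c(cli_common_options(),
                  list(optparse::make_option("--preset", type = "character",
                                             default = "broad"),
                       optparse::make_option("--n", type = "integer",
                                             default = 100L)))
        opt <- optparse::parse_args(
          optparse::OptionParser(option_list = opts), args = rest)
        loaded <- cli_load(opt)
        specs <- if (!is.null(loaded$gsa)) loaded$gsa$specs
                 else gsa_presets()[[match.arg(opt$preset,
                                               c("broad", "restricted"))]]
        des <- latin_hypercube_design(specs, opt$n, seed = opt$seed)
        y <- run_gsa(des, loaded$params,
                     sim_config(years = loaded$config$years,
                                burn_in = loaded$config$burn_in))
        write_results(des, opt$out)
        resp_path <- sub("\\.csv$", "", opt$out)
        resp_path <- paste0(resp_path, "_responses.csv")
        write.csv(data.frame(row = seq_along(y), spawners = as.numeric(y)),
                  resp_path, row.names = FALSE)
        if (opt$verbose)
          cat("wrote", opt$out, "and", resp_path, "\n")
      },
      importance = {
        opts <- c(cli_common_options(),
                  list(optparse::make_option("--design", type = "character"),
                       optparse::make_option("--responses",
                                             type = "character"),
                       optparse::make_option("--forests", type = "integer",
                                             default = 100L),
                       optparse::make_option("--trees", type = "integer",
                                             default = 501L),
                       optparse::make_option("--mtry", type = "integer",
                                             default = 8L)))
        opt <- optparse::parse_args(
          optparse::OptionParser(option_list = opts), args = rest)
        x <- as.matrix(read.csv(opt$design, check.names = FALSE))
        y <- read.csv(opt$responses)$spawners
        imp <- random_forest_importance(x, y, n_forests = opt$forests,
                                        n_trees = opt$trees,
                                        m_try = opt$mtry, seed = opt$seed)
        write_results(imp, opt$out)
      })
    0L
  }, error = function(e) {
    message("lampresim ", sub, ": ", conditionMessage(e))
    1L
  })
}
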