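# Multi-year, multi-replicate simulation engine with burn-in, replicate
# summaries, and the management scenario comparison.

STATE_STAGES <- c(rep("larvae", 11), "transformers", rep("juvenile", 11),
                  rep("adult", 3), "spawners", "eggs")
STATE_AGES <- c(0:10, NA, 0:10, 0:2, NA, NA)
STATE_VARS <- ifelse(is.na(STATE_AGES), STATE_STAGES,
                     paste(STATE_STAGES, STATE_AGES, sep = "_"))

#' Simulation configuration
#'
#' @param years Analysis years after burn-in (>= 1).
#' @param burn_in Burn-in years run before the analysis window (>= 0);
#'   retained in the output but flagged.
#' @param replicates Number of stochastic replicates (>= 1).
#' @param seed Integer seed; replicate r, year t always uses the same RNG
#'   substream, independent of execution order.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @param initial_spawners First-year spawner injection; `NULL` uses the
#'   value in the parameter record.
#' @return A `sim_config` object.
#' @export
sim_config <- function(years = 50, burn_in = 50, replicates = 100, seed = 1,
                       mode = "stochastic", initial_spawners = NULL) {
  stopifnot(years >= 1, burn_in >= 0, replicates >= 1,
            is.numeric(seed), length(seed) == 1L)
  mode <- check_mode(mode)
  if (!is.null(initial_spawners)) check_count(initial_spawners,
                                              "initial_spawners")
  structure(list(years = as.integer(years), burn_in = as.integer(burn_in),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), mode = mode,
                 initial_spawners = initial_spawners),
            class = "sim_config")
}

# Run fn() with the global RNG isolated; restores kind and seed on exit.
with_preserved_rng <- function(fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  fn()
}

replicate_streams <- function(seed, n) {
  RNGkind("L'Ecuyer-CMRG")
  set.seed(seed)
  streams <- vector("list", n)
  s <- get(".Random.seed", envir = globalenv())
  for (r in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[r]] <- s
  }
  streams
}

#' Run a multi-replicate life cycle simulation
#'
#' Simulates `burn_in + years` annual steps for each replicate from an empty
#' state seeded with the configured initial spawners in year 1. Each
#' (replicate, year) pair is pinned to its own L'Ecuyer-CMRG RNG substream,
#' so trajectories are reproducible and independent of execution order and
#' of the total replicate count. Burn-in years are retained and flagged.
#'
#' @param params A [lamprey_params()] record.
#' @param config A [sim_config()].
#' @return A `lamprey_sim` object: `counts` is a
#'   replicate x year x variable array (28 variables: larvae ages 0-10,
#'   transformers, juvenile ocean ages 0-10, adult ages 0-2, spawners,
#'   eggs), `transform_by_age` a replicate x year x larval-age array of
#'   transformer recruitment, plus the params, config and a burn-in flag
#'   per year.
#' @examples
#' sim <- run_simulation(lamprey_params(),
#'                       sim_config(years = 5, burn_in = 0, replicates = 2,
#'                                  mode = "deterministic"))
#' dim(sim$counts)
#' @export
run_simulation <- function(params, config = sim_config()) {
  stopifnot(inherits(params, "lamprey_params"),
            inherits(config, "sim_config"))
  total <- config$burn_in + config$years
  init0 <- config$initial_spawners %||% params$initial_spawners
  det <- config$mode == "deterministic"

  counts <- array(0, dim = c(config$replicates, total, length(STATE_VARS)),
                  dimnames = list(NULL, NULL, STATE_VARS))
  tba <- array(0, dim = c(config$replicates, total, N_LARVAL_AGES),
               dimnames = list(NULL, NULL, paste0("age_", 0:10)))

  run_all <- function() {
    streams <- if (!det) replicate_streams(config$seed, config$replicates)
    for (r in seq_len(config$replicates)) {
      state <- lamprey_state()
      if (!det) sub <- streams[[r]]
      for (t in seq_len(total)) {
        if (!det) {
          assign(".Random.seed", sub, envir = globalenv())
          sub <- parallel::nextRNGSubStream(sub)
        }
        prev <- state
        state <- step_year(state, params, config$mode,
                           init_spawners = if (t == 1L) init0 else 0)
        row <- c(state$larvae_spring, state$transformers, prev$juveniles,
                 prev$adults, state$spawners, state$eggs)
        if (any(!is.finite(row)))
          stop("non-finite abundance at replicate ", r, ", year ", t,
               " (variable ", STATE_VARS[which(!is.finite(row))[1]], ")",
               call. = FALSE)
        counts[r, t, ] <<- row
        tba[r, t, ] <<- state$transform_by_age
      }
    }
  }
  if (det) run_all() else with_preserved_rng(run_all)

  structure(list(counts = counts, transform_by_age = tba, params = params,
                 config = config,
                 burn_in = seq_len(total) <= config$burn_in),
            class = "lamprey_sim")
}

#' @export
print.lamprey_sim <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("Lamprey life cycle simulation: %d replicate(s) x %d year(s) (%d burn-in), %s mode\n",
              d[1], d[2], x$config$burn_in, x$config$mode))
  sp <- stage_totals(x, "spawners")
  post <- sp[, !x$burn_in, drop = FALSE]
  cat(sprintf("  post-burn-in spawners: median %g (range %g-%g)\n",
              median(post), min(post), max(post)))
  invisible(x)
}

#' Per-replicate, per-year totals for one life stage
#'
#' @param result A `lamprey_sim` from [run_simulation()].
#' @param stage One of `"spawners"`, `"eggs"`, `"transformers"`,
#'   `"larvae"`, `"juveniles"`, `"adults"` (age-structured stages are
#'   summed over ages).
#' @return A replicates x years matrix.
#' @export
stage_totals <- function(result, stage) {
  stopifnot(inherits(result, "lamprey_sim"))
  stage <- match.arg(stage, c("spawners", "eggs", "transformers", "larvae",
                              "juveniles", "adults"))
  key <- c(spawners = "spawners", eggs = "eggs",
           transformers = "transformers", larvae = "larvae",
           juveniles = "juvenile", adults = "adult")[[stage]]
  idx <- which(STATE_STAGES == key)
  m <- result$counts[, , idx, drop = FALSE]
  apply(m, c(1, 2), sum)
}

#' Summarize a stage across replicates
#'
#' @inheritParams stage_totals
#' @param statistic `"median"`, `"mean"` or `"quantile"`.
#' @param prob Quantile probability (used when `statistic = "quantile"`).
#' @param include_burn_in Keep burn-in years in the output (default FALSE).
#' @return A data frame with `year` (1-based simulation year), `value` and
#'   `burn_in`.
#' @export
summarize_replicates <- function(result, stage,
                                 statistic = c("median", "mean", "quantile"),
                                 prob = 0.5, include_burn_in = FALSE) {
  statistic <- match.arg(statistic)
  m <- stage_totals(result, stage)
  value <- switch(statistic,
                  median = apply(m, 2, median),
                  mean = colMeans(m),
                  quantile = apply(m, 2, quantile, probs = prob,
                                   names = FALSE))
  out <- data.frame(year = seq_len(ncol(m)), value = value,
                    burn_in = result$burn_in)
  if (!include_burn_in) out <- out[!out$burn_in, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Management scenario specification
#'
#' A labelled set of parameter overrides applied on top of a base parameter
#' record (see [modify_params()] for the override syntax).
#'
#' @param label Scenario label.
#' @param overrides Named list of parameter overrides.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(label, overrides = list()) {
  stopifnot(is.character(label), length(label) == 1L, is.list(overrides))
  structure(list(label = label, overrides = overrides),
            class = "scenario_spec")
}

#' The five case-study management scenarios
#'
#' Baseline defaults; one upstream barrier with passability 0.6; the barrier
#' plus yearly translocation of up to 100 adults; the barrier plus yearly
#' hatchery release of 1000 transformers; and the barrier plus both
#' operations combined.
#'
#' @return A list of five [scenario_spec()] objects.
#' @export
scenario_presets <- function() {
  list(
    scenario_spec("Baseline"),
    scenario_spec("Barrier.US", list(upstream_barriers = 0.6)),
    scenario_spec("Barrier.US.Trans",
                  list(upstream_barriers = 0.6, adult_translocation_n = 100)),
    scenario_spec("Barrier.US.Hatch",
                  list(upstream_barriers = 0.6,
                       hatchery_transformers = 1000)),
    scenario_spec("Barrier.US.Trans.Hatch",
                  list(upstream_barriers = 0.6, adult_translocation_n = 100,
                       hatchery_transformers = 1000))
  )
}

#' Run and compare management scenarios
#'
#' Runs each scenario with the same base configuration (hence the same seed
#' and replicate RNG streams) and summarizes the per-year median spawner
#' abundance across replicates.
#'
#' @param base_params Base [lamprey_params()] record.
#' @param scenarios List of [scenario_spec()] objects (default: the five
#'   case-study presets).
#' @param config A [sim_config()].
#' @param keep_raw Keep the full `lamprey_sim` objects (default FALSE).
#' @return A `scenario_comparison`: `summaries` (data frame of scenario,
#'   year, median spawners, burn-in flag), `final_medians` (named vector of
#'   median final-year spawners), and optionally `results`.
#' @export
run_scenarios <- function(base_params, scenarios = scenario_presets(),
                          config = sim_config(), keep_raw = FALSE) {
  stopifnot(length(scenarios) >= 1)
  labels <- vapply(scenarios, function(s) s$label, "")
  if (anyDuplicated(labels)) stop("scenario labels must be unique",
                                  call. = FALSE)
  summaries <- list()
  finals <- numeric(0)
  results <- list()
  for (s in scenarios) {
    p <- do.call(modify_params, c(list(base_params), s$overrides))
    sim <- run_simulation(p, config)
    sm <- summarize_replicates(sim, "spawners", "median",
                               include_burn_in = TRUE)
    sm <- cbind(scenario = s$label, sm)
    summaries[[s$label]] <- sm
    sp <- stage_totals(sim, "spawners")
    finals[s$label] <- median(sp[, ncol(sp)])
    if (keep_raw) results[[s$label]] <- sim
  }
  structure(list(summaries = do.call(rbind, c(summaries,
                                              make.row.names = FALSE)),
                 final_medians = finals,
                 results = if (keep_raw) results,
                 config = config),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Management scenario comparison (median final-year spawners):\n")
  for (nm in names(x$final_medians))
    cat(sprintf("  %-24s %g\n", nm, x$final_medians[[nm]]))
  invisible(x)
}
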