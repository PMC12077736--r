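# Life cycle parameter record: every rate, probability and capacity of the
# annual model in one validated list, with the Pacific lamprey defaults.

N_LARVAL_AGES <- 11L   # larval ages 0-10
N_OCEAN_AGES  <- 11L   # ocean (juvenile) ages 0-10
N_ADULT_AGES  <- 3L    # in-river adult ages 0-2

expand_ages <- function(x, n, what) {
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n)
    stop("`", what, "` must have length 1 or ", n, " (got ", length(x), ")",
         call. = FALSE)
  x
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("`", what, "` must lie in [0, 1]", call. = FALSE)
  x
}

check_pos <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop("`", what, "` must be a single positive number", call. = FALSE)
  x
}

check_count <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    stop("`", what, "` must be a single non-negative number", call. = FALSE)
  x
}

#' Convert an areal density and habitat area to a carrying capacity
#'
#' Capacities can be given directly (in individuals or eggs) or derived from
#' a density per square metre and an available habitat area in square
#' kilometres; the m^2 -> km^2 conversion factor of 1e6 is applied exactly
#' once here. The default egg density of 575 eggs/m^2 over 1 km^2 of
#' spawning habitat gives the default egg capacity of 575 million; the
#' default larval density of 0.13/m^2 over 10 km^2 of rearing habitat gives
#' 1.3 million.
#'
#' @param density_per_m2 Density (individuals or eggs per m^2).
#' @param area_km2 Available habitat area (km^2).
#' @return Carrying capacity in individuals (or eggs).
#' @examples
#' capacity_from_density(575, 1)    # 575e6 eggs
#' capacity_from_density(0.13, 10)  # 1.3e6 larvae
#' @export
capacity_from_density <- function(density_per_m2, area_km2) {
  check_pos(density_per_m2, "density_per_m2")
  check_pos(area_km2, "area_km2")
  density_per_m2 * 1e6 * area_km2
}

#' Compose the default egg-to-larva survival from its component rates
#'
#' The baseline egg survival is built from four observable components: the
#' fraction of eggs that stay in the redd and hatch, the fraction washed out
#' of the redd, the survival of washed-out eggs, and the survival of hatched
#' prolarvae to the first-feeding larval stage. With the default components
#' (0.12, 0.815, 0.22, 0.06) this composes to about 0.018, rounded to the
#' working default of 0.02.
#'
#' @param hatch_in_redd Fraction of eggs retained in the redd that hatch.
#' @param washed_out Fraction of eggs washed out of the redd.
#' @param washout_survival Survival of washed-out eggs.
#' @param to_first_feeding Survival of hatched larvae to first feeding.
#' @return The composite egg-to-age-0-larva survival probability.
#' @examples
#' compose_egg_survival()  # ~0.018
#' @export
compose_egg_survival <- function(hatch_in_redd = 0.12, washed_out = 0.815,
                                 washout_survival = 0.22,
                                 to_first_feeding = 0.06) {
  check_prob(hatch_in_redd, "hatch_in_redd")
  check_prob(washed_out, "washed_out")
  check_prob(washout_survival, "washout_survival")
  check_prob(to_first_feeding, "to_first_feeding")
  (hatch_in_redd + washed_out * washout_survival) * to_first_feeding
}

#' Default upstream dam passability from per-dam passage extremes
#'
#' The default single-barrier upstream passability is the mean of the lower
#' and upper passage estimates at three mainstem Columbia River dams
#' (Bonneville 38-47%, The Dalles 50-82%, McNary 65-75%), which rounds to
#' the working default of 0.6.
#'
#' @param extremes Numeric vector of per-dam passage extremes.
#' @return Mean passability.
#' @export
upstream_passage_default <- function(extremes = c(bonneville_low = 0.38,
                                                  bonneville_high = 0.47,
                                                  dalles_low = 0.50,
                                                  dalles_high = 0.82,
                                                  mcnary_low = 0.65,
                                                  mcnary_high = 0.75)) {
  mean(check_prob(extremes, "extremes"))
}

#' Life cycle parameters
#'
#' Builds and validates the full parameter record of the annual life cycle
#' model. Defaults are a Pacific lamprey parameterization. Age-indexed
#' vectors (`larval_survival`, `transform_prob`, `upriver_prob`: ages 0-10;
#' `spawn_prob`: adult ages 0-2) accept a single value recycled to all ages.
#' Two structural constraints are always enforced: all age-10 larvae
#' transform (`transform_prob[11]` is set to 1 — there is no age-11 larval
#' class) and all age-2 adults spawn (`spawn_prob[3]` is set to 1).
#'
#' @param fecundity_mean,fecundity_sd Mean and SD of individual female
#'   fecundity (eggs); the negative-binomial shape is moment-matched.
#' @param female_ratio Female sex ratio in `[0, 1]`.
#' @param egg_survival Baseline egg-to-larva survival without density
#'   dependence.
#' @param egg_capacity Egg carrying capacity (eggs); see
#'   [capacity_from_density()] for the density x area form.
#' @param summer_mortality,winter_mortality Additional seasonal larval
#'   mortality (default 0).
#' @param summer_capacity,winter_capacity Seasonal larval carrying
#'   capacities (larvae).
#' @param larval_survival Density-independent larval survival by age 0-10.
#' @param transform_prob Transformation probability by larval age 0-10
#'   (only ages 2-10 can transform; the age-10 entry is forced to 1).
#' @param downstream_barriers Vector of per-barrier downstream passabilities
#'   (empty = no barriers).
#' @param ocean_entry_mean,ocean_entry_sd Moments of the yearly ocean-entry
#'   survival beta draw.
#' @param upriver_prob Probability that an ocean-age 0-10 juvenile heads
#'   upstream in a given year.
#' @param yearly_ocean_mean,yearly_ocean_sd Moments of the yearly at-sea
#'   survival beta draw.
#' @param river_entry_mean,river_entry_sd Moments of the yearly river-mouth
#'   entry survival beta draw.
#' @param upstream_barriers Vector of per-barrier upstream passabilities.
#' @param transformer_translocation_n Transformers translocated below all
#'   downstream barriers each year (capped at availability).
#' @param transformer_translocation_survival Survival of translocated
#'   transformers.
#' @param adult_translocation_n Adults translocated above all upstream
#'   barriers each year (capped at availability).
#' @param adult_translocation_survival Survival of translocated adults.
#' @param spawn_prob Probability an adult of river age 0-2 spawns this year
#'   (the age-2 entry is forced to 1).
#' @param hatchery_larvae Yearly hatchery release of larvae by age 0-10
#'   (the age-0 entry must be 0: only age-1 to age-10 larvae are released).
#' @param hatchery_transformers Yearly hatchery release of transformers.
#' @param initial_spawners Spawner abundance injected in the first simulated
#'   year; afterwards internal dynamics determine spawner numbers.
#' @return A validated object of class `lamprey_params`.
#' @examples
#' p <- lamprey_params()
#' p$egg_capacity
#' @export
lamprey_params <- function(fecundity_mean = 127000,
                           fecundity_sd = 33500,
                           female_ratio = 0.5,
                           egg_survival = 0.02,
                           egg_capacity = 575e6,
                           summer_mortality = 0,
                           winter_mortality = 0,
                           summer_capacity = 1.3e6,
                           winter_capacity = 1.3e6,
                           larval_survival = c(0.33, 0.45, 0.61, 0.69, 0.74,
                                               0.77, 0.79, 0.8, 0.8, 0.8, 0.8),
                           transform_prob = c(0, 0, 0.002, 0.042, 0.555,
                                              1, 1, 1, 1, 1, 1),
                           downstream_barriers = numeric(0),
                           ocean_entry_mean = 0.46,
                           ocean_entry_sd = 0.09,
                           upriver_prob = c(0, 0.02, 0.05, 0.1, 0.15, 0.45,
                                            1, 1, 1, 1, 1),
                           yearly_ocean_mean = 0.7,
                           yearly_ocean_sd = 0.1,
                           river_entry_mean = 0.67,
                           river_entry_sd = 0.09,
                           upstream_barriers = numeric(0),
                           transformer_translocation_n = 0,
                           transformer_translocation_survival = 0.99,
                           adult_translocation_n = 0,
                           adult_translocation_survival = 0.99,
                           spawn_prob = c(0.05, 0.7, 1),
                           hatchery_larvae = rep(0, 11),
                           hatchery_transformers = 0,
                           initial_spawners = 800) {
  check_pos(fecundity_mean, "fecundity_mean")
  check_pos(fecundity_sd, "fecundity_sd")
  check_prob(female_ratio, "female_ratio")
  check_prob(egg_survival, "egg_survival")
  check_pos(egg_capacity, "egg_capacity")
  check_prob(summer_mortality, "summer_mortality")
  check_prob(winter_mortality, "winter_mortality")
  check_pos(summer_capacity, "summer_capacity")
  check_pos(winter_capacity, "winter_capacity")

  larval_survival <- check_prob(
    expand_ages(larval_survival, N_LARVAL_AGES, "larval_survival"),
    "larval_survival")
  transform_prob <- check_prob(
    expand_ages(transform_prob, N_LARVAL_AGES, "transform_prob"),
    "transform_prob")
  transform_prob[N_LARVAL_AGES] <- 1  # all age-10 larvae transform
  upriver_prob <- check_prob(
    expand_ages(upriver_prob, N_OCEAN_AGES, "upriver_prob"), "upriver_prob")
  spawn_prob <- check_prob(
    expand_ages(spawn_prob, N_ADULT_AGES, "spawn_prob"), "spawn_prob")
  spawn_prob[N_ADULT_AGES] <- 1       # all age-2 adults spawn

  check_prob(downstream_barriers, "downstream_barriers")
  check_prob(upstream_barriers, "upstream_barriers")
  check_prob(ocean_entry_mean, "ocean_entry_mean")
  check_prob(yearly_ocean_mean, "yearly_ocean_mean")
  check_prob(river_entry_mean, "river_entry_mean")
  stopifnot(ocean_entry_sd >= 0, yearly_ocean_sd >= 0, river_entry_sd >= 0)

  check_count(transformer_translocation_n, "transformer_translocation_n")
  check_prob(transformer_translocation_survival,
             "transformer_translocation_survival")
  check_count(adult_translocation_n, "adult_translocation_n")
  check_prob(adult_translocation_survival, "adult_translocation_survival")

  hatchery_larvae <- expand_ages(hatchery_larvae, N_LARVAL_AGES,
                                 "hatchery_larvae")
  if (any(!is.finite(hatchery_larvae)) || any(hatchery_larvae < 0))
    stop("`hatchery_larvae` must be non-negative", call. = FALSE)
  if (hatchery_larvae[1] > 0)
    stop("hatchery releases of age-0 larvae are not supported ",
         "(ages 1-10 only)", call. = FALSE)
  check_count(hatchery_transformers, "hatchery_transformers")
  check_count(initial_spawners, "initial_spawners")

  structure(list(
    fecundity_mean = fecundity_mean, fecundity_sd = fecundity_sd,
    female_ratio = female_ratio,
    egg_survival = egg_survival, egg_capacity = egg_capacity,
    summer_mortality = summer_mortality, winter_mortality = winter_mortality,
    summer_capacity = summer_capacity, winter_capacity = winter_capacity,
    larval_survival = larval_survival, transform_prob = transform_prob,
    downstream_barriers = as.numeric(downstream_barriers),
    ocean_entry_mean = ocean_entry_mean, ocean_entry_sd = ocean_entry_sd,
    upriver_prob = upriver_prob,
    yearly_ocean_mean = yearly_ocean_mean, yearly_ocean_sd = yearly_ocean_sd,
    river_entry_mean = river_entry_mean, river_entry_sd = river_entry_sd,
    upstream_barriers = as.numeric(upstream_barriers),
    transformer_translocation_n = transformer_translocation_n,
    transformer_translocation_survival = transformer_translocation_survival,
    adult_translocation_n = adult_translocation_n,
    adult_translocation_survival = adult_translocation_survival,
    spawn_prob = spawn_prob,
    hatchery_larvae = hatchery_larvae,
    hatchery_transformers = hatchery_transformers,
    initial_spawners = initial_spawners
  ), class = "lamprey_params")
}

#' Modify a parameter record
#'
#' Returns a revalidated copy of `params` with the named fields replaced.
#' Indexed scalar overrides of age vectors are supported with names of the
#' form `larval_survival_4`, `transform_prob_10`, `upriver_prob_6`,
#' `spawn_prob_0` (the suffix is the age class).
#'
#' @param params A `lamprey_params` object.
#' @param ... Named replacements (full fields or indexed scalars).
#' @return A new `lamprey_params` object.
#' @examples
#' modify_params(lamprey_params(), upstream_barriers = 0.6,
#'               larval_survival_0 = 0.4)
#' @export
modify_params <- function(params, ...) {
  stopifnot(inherits(params, "lamprey_params"))
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == "")))
    stop("all overrides must be named", call. = FALSE)
  args <- unclass(params)
  aged <- c("larval_survival", "transform_prob", "upriver_prob", "spawn_prob")
  for (nm in names(dots)) {
    m <- regmatches(nm, regexec("^(.*)_(\\d+)$", nm))[[1]]
    if (length(m) == 3L && m[2] %in% aged) {
      idx <- as.integer(m[3]) + 1L
      if (idx < 1L || idx > length(args[[m[2]]]))
        stop("age index out of range in override `", nm, "`", call. = FALSE)
      args[[m[2]]][idx] <- dots[[nm]]
    } else if (nm %in% names(args)) {
      args[[nm]] <- dots[[nm]]
    } else {
      stop("unknown parameter `", nm, "`", call. = FALSE)
    }
  }
  do.call(lamprey_params, args)
}

#' @export
print.lamprey_params <- function(x, ...) {
  cat("Lamprey life cycle parameters\n")
  cat(sprintf("  fecundity: %g +/- %g eggs; female ratio %g\n",
              x$fecundity_mean, x$fecundity_sd, x$female_ratio))
  cat(sprintf("  egg survival %g (K = %g); larval K summer/winter %g/%g\n",
              x$egg_survival, x$egg_capacity, x$summer_capacity,
              x$winter_capacity))
  cat("  larval survival:", paste(x$larval_survival, collapse = " "), "\n")
  cat("  transform prob: ", paste(x$transform_prob, collapse = " "), "\n")
  cat("  upriver prob:   ", paste(x$upriver_prob, collapse = " "), "\n")
  cat(sprintf("  ocean entry %g+/-%g; yearly ocean %g+/-%g; river entry %g+/-%g\n",
              x$ocean_entry_mean, x$ocean_entry_sd, x$yearly_ocean_mean,
              x$yearly_ocean_sd, x$river_entry_mean, x$river_entry_sd))
  cat(sprintf("  barriers: %d downstream, %d upstream; translocation %g transformers / %g adults\n",
              length(x$downstream_barriers), length(x$upstream_barriers),
              x$transformer_translocation_n, x$adult_translocation_n))
  if (x$hatchery_transformers > 0 || any(x$hatchery_larvae > 0))
    cat(sprintf("  hatchery: %g transformers, %g larvae / year\n",
                x$hatchery_transformers, sum(x$hatchery_larvae)))
  invisible(x)
}
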