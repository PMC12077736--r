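# The eleven annual life cycle transitions and the composed one-year step.
# State convention: a `lamprey_state` holds start-of-year pools (larvae ages
# 0-10 with age 0 empty between years, ocean juveniles ages 0-10, in-river
# adults ages 0-2) plus the quantities realized during the year that produced
# it (spawners, eggs, transformers and transformers-by-age, spring larvae).

#' Create a population state
#'
#' @param larvae Larval abundance by age 0-10.
#' @param juveniles Ocean juvenile abundance by ocean age 0-10.
#' @param adults In-river adult abundance by river age 0-2.
#' @param spawners,eggs,transformers Within-year quantities (informational).
#' @return A `lamprey_state` object.
#' @export
lamprey_state <- function(larvae = rep(0, 11), juveniles = rep(0, 11),
                          adults = rep(0, 3), spawners = 0, eggs = 0,
                          transformers = 0) {
  larvae <- expand_ages(larvae, N_LARVAL_AGES, "larvae")
  juveniles <- expand_ages(juveniles, N_OCEAN_AGES, "juveniles")
  adults <- expand_ages(adults, N_ADULT_AGES, "adults")
  pools <- c(larvae, juveniles, adults, spawners, eggs, transformers)
  if (any(!is.finite(pools)) || any(pools < 0))
    stop("state counts must be non-negative and finite", call. = FALSE)
  structure(list(larvae = larvae, juveniles = juveniles, adults = adults,
                 spawners = spawners, eggs = eggs,
                 transformers = transformers,
                 transform_by_age = rep(0, N_LARVAL_AGES),
                 larvae_spring = rep(0, N_LARVAL_AGES)),
            class = "lamprey_state")
}

#' @export
print.lamprey_state <- function(x, ...) {
  cat("Lamprey population state\n")
  cat(sprintf("  larvae (ages 0-10): %s  [total %g]\n",
              paste(signif(x$larvae, 4), collapse = " "), sum(x$larvae)))
  cat(sprintf("  juveniles (ocean ages 0-10): %s  [total %g]\n",
              paste(signif(x$juveniles, 4), collapse = " "),
              sum(x$juveniles)))
  cat(sprintf("  adults (ages 0-2): %s\n",
              paste(signif(x$adults, 4), collapse = " ")))
  cat(sprintf("  this year: %g spawners, %g eggs, %g transformers\n",
              x$spawners, x$eggs, x$transformers))
  invisible(x)
}

#' Spawners to eggs
#'
#' The number of females is a binomial draw of the spawners with the female
#' sex ratio (its expectation in deterministic mode); total eggs are the sum
#' of moment-matched negative-binomial individual fecundities.
#'
#' @param n_spawners Spawner count (>= 0).
#' @param params A [lamprey_params()] record.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return Total eggs produced.
#' @export
spawners_to_eggs <- function(n_spawners, params, mode = "stochastic") {
  females <- draw_count(n_spawners, params$female_ratio, mode)
  draw_fecundity_total(females, params$fecundity_mean, params$fecundity_sd,
                       mode)
}

#' Eggs to age-0 larvae
#'
#' Egg survival is Beverton-Holt density dependent in the egg total with
#' baseline `egg_survival` and capacity `egg_capacity`; survivors are a
#' binomial draw.
#'
#' @inheritParams spawners_to_eggs
#' @param n_eggs Egg count (>= 0).
#' @return Age-0 larvae.
#' @export
eggs_to_age0_larvae <- function(n_eggs, params, mode = "stochastic") {
  if (n_eggs == 0) return(0)
  p <- beverton_holt_survival(params$egg_survival, n_eggs, params$egg_capacity)
  draw_count(n_eggs, p, mode)
}

#' Add hatchery releases to a state
#'
#' Released larvae (ages 1-10) join the matching larval age classes and
#' released transformers join the transformer pool of the same year, all
#' before density dependence and downstream passage; no survival penalty is
#' applied (hatchery fish are treated as equivalent to wild fish).
#'
#' @param state A [lamprey_state()].
#' @param releases List with elements `larvae` (length-11 vector by age, the
#'   age-0 entry must be 0) and `transformers` (count).
#' @return The updated state.
#' @export
apply_hatchery_additions <- function(state, releases) {
  larvae <- expand_ages(releases$larvae %||% rep(0, N_LARVAL_AGES),
                        N_LARVAL_AGES, "releases$larvae")
  if (any(larvae < 0) || (releases$transformers %||% 0) < 0)
    stop("hatchery release counts must be non-negative", call. = FALSE)
  if (larvae[1] > 0)
    stop("hatchery releases of age-0 larvae are not supported ",
         "(ages 1-10 only)", call. = FALSE)
  state$larvae <- state$larvae + larvae
  state$transformers <- state$transformers + (releases$transformers %||% 0)
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Seasonal density-dependent larval survival
#'
#' Pools all age-1+ larvae, applies sequential summer and winter
#' Beverton-Holt survivals (each with optional additional mortality and its
#' own capacity), and returns the realized density-dependent survival
#' fraction pi_dd = spring(t+1) / spring(t). With no age-1+ larvae the
#' convention pi_dd = 1 is used (it is applied over empty pools only).
#'
#' @inheritParams spawners_to_eggs
#' @param larvae Larval abundance by age 0-10 (age 0 is excluded from the
#'   density-dependent pool).
#' @return The density-dependent survival probability for the year.
#' @export
seasonal_density_dependence <- function(larvae, params, mode = "stochastic") {
  n_spring <- sum(larvae[-1])
  if (n_spring == 0) return(1)
  p_summer <- beverton_holt_survival(1 - params$summer_mortality, n_spring,
                                     params$summer_capacity)
  n_fall <- draw_count(n_spring, p_summer, mode)
  p_winter <- beverton_holt_survival(1 - params$winter_mortality, n_fall,
                                     params$winter_capacity)
  n_next <- draw_count(n_fall, p_winter, mode)
  n_next / n_spring
}

#' Age-specific larval survival
#'
#' Each age class survives with the product of the shared density-dependent
#' fraction `pdd` and its density-independent survival; age-0 larvae are
#' subject to their density-independent survival only (they are outside the
#' age-1+ density-dependent pool).
#'
#' @inheritParams seasonal_density_dependence
#' @param pdd Density-dependent survival fraction from
#'   [seasonal_density_dependence()].
#' @return Surviving larvae by age 0-10.
#' @export
survive_larvae_by_age <- function(larvae, pdd, params, mode = "stochastic") {
  check_prob(pdd, "pdd")
  p <- c(params$larval_survival[1],
         pdd * params$larval_survival[-1])
  draw_count(larvae, p, mode)
}

#' Larval transformation and aging
#'
#' Surviving larvae of ages 2-10 transform with age-specific probability;
#' non-transformers advance one age class by subtraction (transformed +
#' advanced = survived in every age class and every draw, so larvae are
#' neither created nor destroyed). Ages 0-1 never transform. All age-10
#' larvae transform (enforced at parameter construction), so no larva
#' exceeds age 10.
#'
#' @inheritParams spawners_to_eggs
#' @param survived Surviving larvae by age 0-10.
#' @return List with `transformers` (total), `transform_by_age` (length 11)
#'   and `larvae_next` (next year's larvae by age 0-10; age 0 empty).
#' @export
transform_larvae <- function(survived, params, mode = "stochastic") {
  n_transform <- rep(0, N_LARVAL_AGES)
  can <- 3:N_LARVAL_AGES  # ages 2-10
  n_transform[can] <- draw_count(survived[can], params$transform_prob[can],
                                 mode)
  larvae_next <- rep(0, N_LARVAL_AGES)
  larvae_next[2:N_LARVAL_AGES] <-
    survived[1:(N_LARVAL_AGES - 1)] - n_transform[1:(N_LARVAL_AGES - 1)]
  list(transformers = sum(n_transform), transform_by_age = n_transform,
       larvae_next = larvae_next)
}

#' Downstream migration past barriers
#'
#' Transformers pass all downstream barriers with the product of per-barrier
#' passabilities; a requested number of transformers (capped at
#' availability) is instead translocated below all barriers with the
#' translocation survival. With no barriers and no translocation, output
#' equals input.
#'
#' @inheritParams spawners_to_eggs
#' @param transformers Transformer count (wild + hatchery).
#' @return Juveniles arriving at the ocean mouth.
#' @export
downstream_migration <- function(transformers, params, mode = "stochastic") {
  theta <- prod(params$downstream_barriers)
  n_t <- min(params$transformer_translocation_n, transformers)
  passed <- draw_count(transformers - n_t, theta, mode)
  moved <- draw_count(n_t, params$transformer_translocation_survival, mode)
  passed + moved
}

#' Ocean entry survival
#'
#' One beta-distributed survival probability is drawn per year (shared by
#' every juvenile entering that year) and applied binomially.
#'
#' @inheritParams spawners_to_eggs
#' @param arrivals Juveniles arriving at the ocean mouth.
#' @return Ocean-age-0 juveniles.
#' @export
ocean_entry <- function(arrivals, params, mode = "stochastic") {
  p <- draw_probability(params$ocean_entry_mean, params$ocean_entry_sd, mode)
  draw_count(arrivals, p, mode)
}

#' One year at sea: returns and ocean survival
#'
#' One river-entry survival and one yearly ocean survival are drawn per year
#' (environmental stochasticity). Each ocean age class attempts an upstream
#' return with its age-specific upriver probability times the river-entry
#' survival; only successful returners leave the sea pool, so fish that
#' attempted return and died at the river mouth remain in the pool for the
#' ocean survival draw. Non-returners of ages 0-9 survive to the next ocean
#' age; age-10 fish are not advanced (those that do not return die).
#'
#' @inheritParams spawners_to_eggs
#' @param juveniles Ocean juvenile abundance by ocean age 0-10.
#' @return List with `returners` (in-river adult recruits this year) and
#'   `juveniles_next` (next year's ocean pool by age; age 0 empty, to be
#'   filled by this year's ocean entrants).
#' @export
juvenile_year <- function(juveniles, params, mode = "stochastic") {
  p_river <- draw_probability(params$river_entry_mean, params$river_entry_sd,
                              mode)
  p_ocean <- draw_probability(params$yearly_ocean_mean,
                              params$yearly_ocean_sd, mode)
  returns <- draw_count(juveniles, params$upriver_prob * p_river, mode)
  juveniles_next <- rep(0, N_OCEAN_AGES)
  stay <- juveniles - returns
  juveniles_next[2:N_OCEAN_AGES] <-
    draw_count(stay[1:(N_OCEAN_AGES - 1)], p_ocean, mode)
  list(returners = sum(returns), juveniles_next = juveniles_next)
}

#' Upstream migration past barriers
#'
#' Returning adults pass all upstream barriers with the product of
#' per-barrier passabilities; a requested number of adults (capped at the
#' adults available that year) is instead translocated above all barriers
#' with the translocation survival.
#'
#' @inheritParams spawners_to_eggs
#' @param n_returners Adults arriving at the river (>= 0).
#' @return River-age-0 adults above the barriers.
#' @export
upstream_migration <- function(n_returners, params, mode = "stochastic") {
  theta <- prod(params$upstream_barriers)
  n_t <- min(params$adult_translocation_n, n_returners)
  passed <- draw_count(n_returners - n_t, theta, mode)
  moved <- draw_count(n_t, params$adult_translocation_survival, mode)
  passed + moved
}

#' Adults to spawners
#'
#' Each adult age class spawns with its age-specific probability;
#' non-spawners of ages 0 and 1 hold in the river and advance one age class
#' with no holding mortality. All age-2 adults spawn (enforced at parameter
#' construction), so no adult exceeds river age 2. Spawners die after
#' reproduction (semelparity) and are not carried forward.
#'
#' @inheritParams spawners_to_eggs
#' @param adults In-river adults by age 0-2.
#' @return List with `spawners` (total this year) and `held` (length 2:
#'   next year's age-1 and age-2 adults).
#' @export
adults_to_spawners <- function(adults, params, mode = "stochastic") {
  spawn <- draw_count(adults, params$spawn_prob, mode)
  list(spawners = sum(spawn),
       held = (adults - spawn)[1:2])
}

#' Advance the population one year
#'
#' Composes the annual transitions in their within-year order: spawning,
#' egg production, egg survival, hatchery additions, seasonal density
#' dependence, age-specific larval survival, transformation (larval aging),
#' downstream migration with translocation, ocean entry, the juvenile ocean
#' year (juvenile aging), and upstream migration with translocation.
#' Spawners are removed after producing eggs.
#'
#' The spawner abundance carried in the returned state (and reported by
#' [run_simulation()]) is the egg-producing spawner pool: the female subset
#' of the adults that spawned this year, drawn with the female sex ratio.
#' Individual fecundities are summed over exactly this pool.
#'
#' Draws use R's global RNG in stochastic mode; seed it (or use
#' [run_simulation()], which pins one RNG substream per replicate-year) for
#' reproducibility.
#'
#' @inheritParams spawners_to_eggs
#' @param state A [lamprey_state()] holding start-of-year pools.
#' @param init_spawners Extra spawners injected this year (used to seed the
#'   first simulated year); default 0.
#' @return The next year's `lamprey_state`; its `spawners`, `eggs`,
#'   `transformers`, `transform_by_age` and `larvae_spring` fields describe
#'   the year just simulated.
#' @examples
#' s <- step_year(lamprey_state(), lamprey_params(), "deterministic",
#'                init_spawners = 800)
#' s$eggs  # 50.8 million
#' @export
step_year <- function(state, params, mode = "stochastic", init_spawners = 0) {
  mode <- check_mode(mode)
  stopifnot(inherits(state, "lamprey_state"),
            inherits(params, "lamprey_params"))

  sp <- adults_to_spawners(state$adults, params, mode)
  n_adults_spawning <- sp$spawners + init_spawners

  # The egg-producing spawner pool is the female subset of the spawning
  # adults; it is also the spawner abundance the model reports.
  n_spawners <- draw_count(n_adults_spawning, params$female_ratio, mode)
  eggs <- draw_fecundity_total(n_spawners, params$fecundity_mean,
                               params$fecundity_sd, mode)
  age0 <- eggs_to_age0_larvae(eggs, params, mode)

  work <- state
  work$larvae[1] <- age0
  work$transformers <- 0
  work <- apply_hatchery_additions(
    work, list(larvae = params$hatchery_larvae,
               transformers = params$hatchery_transformers))
  larvae_spring <- work$larvae

  pdd <- seasonal_density_dependence(work$larvae, params, mode)
  survived <- survive_larvae_by_age(work$larvae, pdd, params, mode)
  tr <- transform_larvae(survived, params, mode)
  transformers <- tr$transformers + work$transformers

  arrivals <- downstream_migration(transformers, params, mode)
  entrants <- ocean_entry(arrivals, params, mode)

  jy <- juvenile_year(state$juveniles, params, mode)
  juveniles_next <- jy$juveniles_next
  juveniles_next[1] <- entrants

  adults0 <- upstream_migration(jy$returners, params, mode)

  out <- lamprey_state(larvae = tr$larvae_next, juveniles = juveniles_next,
                       adults = c(adults0, sp$held),
                       spawners = n_spawners, eggs = eggs,
                       transformers = transformers)
  out$transform_by_age <- tr$transform_by_age
  out$larvae_spring <- larvae_spring
  out
}
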