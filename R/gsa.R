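# Global sensitivity analysis: Latin hypercube designs over 44 life cycle
# parameters, deterministic model runs, and repeated random-forest
# permutation importance (%IncMSE).

#' Parameter distribution specification for a sensitivity design
#'
#' @param name Parameter name; indexed names (`larval_survival_4`,
#'   `spawn_prob_0`, ...) address single ages of the vector parameters (see
#'   [modify_params()]).
#' @param family `"uniform"`, `"normal"`, `"beta"` (by moments) or
#'   `"fixed"`.
#' @param lo,hi Bounds (uniform).
#' @param mean,sd Moments (normal and beta; beta shapes are moment-matched
#'   via [beta_shape_from_moments()]).
#' @param value Constant (fixed).
#' @return A `dist_spec` object.
#' @export
dist_spec <- function(name, family = c("uniform", "normal", "beta", "fixed"),
                      lo = NULL, hi = NULL, mean = NULL, sd = NULL,
                      value = NULL) {
  family <- match.arg(family)
  ok <- switch(family,
    uniform = !is.null(lo) && !is.null(hi) && lo < hi,
    normal = !is.null(mean) && !is.null(sd) && sd > 0,
    beta = !is.null(mean) && !is.null(sd) &&
      mean > 0 && mean < 1 && sd^2 < mean * (1 - mean),
    fixed = !is.null(value))
  if (!ok)
    stop("invalid distribution spec for parameter `", name, "` (family ",
         family, ")", call. = FALSE)
  structure(list(name = name, family = family, lo = lo, hi = hi,
                 mean = mean, sd = sd, value = value),
            class = "dist_spec")
}

q_dist_spec <- function(spec, u) {
  switch(spec$family,
         uniform = qunif(u, spec$lo, spec$hi),
         normal = qnorm(u, spec$mean, spec$sd),
         beta = {
           sh <- beta_shape_from_moments(spec$mean, spec$sd)
           qbeta(u, sh[["alpha"]], sh[["beta"]])
         },
         fixed = rep(spec$value, length(u)))
}

#' Latin hypercube design over parameter distributions
#'
#' Generates one stratified uniform sample per column (exactly one draw in
#' each of the `n_samples` equal-probability strata, via [lhs::randomLHS()])
#' and maps it through each spec's quantile function.
#'
#' @param specs List of [dist_spec()] objects.
#' @param n_samples Number of design points (strata per parameter).
#' @param seed Integer seed.
#' @return A `gsa_design`: `matrix` (n_samples x n_parameters, columns named
#'   by parameter), `specs` and `seed`.
#' @export
latin_hypercube_design <- function(specs, n_samples = 100, seed = 1) {
  stopifnot(n_samples >= 1, length(specs) >= 1)
  for (s in specs) if (!inherits(s, "dist_spec"))
    stop("`specs` must be a list of dist_spec objects", call. = FALSE)
  nms <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nms)) stop("duplicated parameter names in `specs`",
                               call. = FALSE)
  u <- with_preserved_rng(function() {
    RNGkind("Mersenne-Twister")
    set.seed(seed)
    lhs::randomLHS(n_samples, length(specs))
  })
  x <- vapply(seq_along(specs),
              function(j) q_dist_spec(specs[[j]], u[, j]),
              numeric(n_samples))
  x <- matrix(x, nrow = n_samples, dimnames = list(NULL, nms))
  structure(list(matrix = x, specs = specs, seed = seed),
            class = "gsa_design")
}

#' @export
print.gsa_design <- function(x, ...) {
  cat(sprintf("Latin hypercube design: %d samples x %d parameters (seed %d)\n",
              nrow(x$matrix), ncol(x$matrix), x$seed))
  invisible(x)
}

#' Broad and restricted sensitivity designs over the 44 life cycle parameters
#'
#' Both designs vary fecundity (normal, mean 127000, sd 33500), the egg
#' capacity (uniform on 1e5-1e12), the two seasonal larval capacities
#' (uniform on 1e4-1e8), and 40 probabilities: sex ratio, egg survival, the
#' 11 larval survivals, the 11 transformation probabilities, ocean entry
#' survival, the 11 upriver probabilities, yearly ocean survival, river
#' entry survival, and the age-0/age-1 spawn probabilities. The broad design
#' samples every probability uniformly on (0, 1); the restricted design
#' samples them from moment-matched beta distributions centred on the
#' default values, with default means too close to 0 or 1 for beta sampling
#' replaced by 0.05 and 0.9 respectively (transformation ages 0-3 use 0.05,
#' age 4 uses 0.515, ages 5-10 use 0.9; upriver ages 0-2 use 0.05, ages
#' 6-10 use 0.9). The sd is 0.1 except the sex ratio (0.05) and egg
#' survival (0.04).
#'
#' @return List with elements `broad` and `restricted`, each a list of 44
#'   [dist_spec()] objects.
#' @export
gsa_presets <- function() {
  fec <- dist_spec("fecundity_mean", "normal", mean = 127000, sd = 33500)
  caps <- list(
    dist_spec("egg_capacity", "uniform", lo = 1e5, hi = 1e12),
    dist_spec("summer_capacity", "uniform", lo = 1e4, hi = 1e8),
    dist_spec("winter_capacity", "uniform", lo = 1e4, hi = 1e8))
  prob_names <- c("female_ratio", "egg_survival",
                  paste0("larval_survival_", 0:10),
                  paste0("transform_prob_", 0:10),
                  "ocean_entry_mean", paste0("upriver_prob_", 0:10),
                  "yearly_ocean_mean", "river_entry_mean",
                  "spawn_prob_0", "spawn_prob_1")
  broad_probs <- lapply(prob_names, dist_spec, family = "uniform",
                        lo = 0, hi = 1)
  restricted_means <- c(
    female_ratio = 0.5, egg_survival = 0.02,
    setNames(c(0.33, 0.45, 0.61, 0.69, 0.74, 0.77, 0.79, 0.8, 0.8, 0.8, 0.8),
             paste0("larval_survival_", 0:10)),
    setNames(c(rep(0.05, 4), 0.515, rep(0.9, 6)),
             paste0("transform_prob_", 0:10)),
    ocean_entry_mean = 0.46,
    setNames(c(rep(0.05, 3), 0.1, 0.15, 0.45, rep(0.9, 5)),
             paste0("upriver_prob_", 0:10)),
    yearly_ocean_mean = 0.7, river_entry_mean = 0.67,
    spawn_prob_0 = 0.05, spawn_prob_1 = 0.7)
  restricted_sds <- setNames(rep(0.1, length(prob_names)), prob_names)
  restricted_sds["female_ratio"] <- 0.05
  restricted_sds["egg_survival"] <- 0.04
  restricted_probs <- lapply(prob_names, function(nm)
    dist_spec(nm, "beta", mean = restricted_means[[nm]],
              sd = restricted_sds[[nm]]))
  list(broad = c(list(fec), caps, broad_probs),
       restricted = c(list(fec), caps, restricted_probs))
}

#' Run a sensitivity design through the deterministic life cycle model
#'
#' For each design row, the named parameters override the base record and
#' one deterministic simulation is run; the response is the spawner count in
#' the last simulated year. Rows producing a non-finite response are
#' excluded with a warning (their indices are kept in the `excluded`
#' attribute). The run is a pure function of (design, base parameters,
#' configuration).
#'
#' @param design A [latin_hypercube_design()].
#' @param base_params Base [lamprey_params()] record.
#' @param config A [sim_config()]; forced to deterministic mode with one
#'   replicate. Default: 50 analysis years after 50 burn-in years.
#' @return Numeric response vector aligned to design rows (NA where
#'   excluded), with attribute `excluded`.
#' @export
run_gsa <- function(design, base_params = lamprey_params(),
                    config = sim_config(years = 50, burn_in = 50)) {
  stopifnot(inherits(design, "gsa_design"))
  config$mode <- "deterministic"
  config$replicates <- 1L
  x <- design$matrix
  y <- rep(NA_real_, nrow(x))
  for (i in seq_len(nrow(x))) {
    ov <- as.list(x[i, ])
    p <- do.call(modify_params, c(list(base_params), ov))
    y[i] <- tryCatch({
      sim <- run_simulation(p, config)
      sp <- stage_totals(sim, "spawners")
      sp[1, ncol(sp)]
    }, error = function(e) NA_real_)
  }
  excluded <- which(!is.finite(y))
  if (length(excluded))
    warning(length(excluded), " design row(s) excluded for non-finite ",
            "responses: ", paste(excluded, collapse = ", "), call. = FALSE)
  attr(y, "excluded") <- excluded
  y
}

#' Repeated random-forest permutation importance
#'
#' Fits `n_forests` regression forests of `n_trees` trees with `m_try`
#' candidate variables per split and extracts the out-of-bag permutation
#' importance of each predictor (the per-tree increase in out-of-bag MSE
#' after permuting the variable, averaged over trees and normalized by the
#' standard deviation of the per-tree differences: the %IncMSE convention
#' of [randomForest::importance()]). Importances are aggregated across
#' forests into a mean and a 95% confidence interval (1.96 x SE).
#'
#' @param x Predictor matrix (design matrix; columns named).
#' @param y Numeric response vector; rows with non-finite `y` are dropped.
#' @param n_forests Number of repeated forests (>= 1).
#' @param n_trees Trees per forest.
#' @param m_try Candidate variables per split.
#' @param seed Integer seed (forest f uses `seed + f - 1`).
#' @return An `importance_table` data frame: `parameter`,
#'   `mean_pct_inc_mse`, `se`, `ci_low`, `ci_high`, `rank`, sorted by
#'   decreasing mean importance. With `n_forests = 1` the SE and CI are
#'   `NA`.
#' @export
random_forest_importance <- function(x, y, n_forests = 100, n_trees = 501,
                                     m_try = 8, seed = 1) {
  if (inherits(x, "gsa_design")) x <- x$matrix
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (n_forests < 1 || n_trees < 1)
    stop("`n_forests` and `n_trees` must be >= 1", call. = FALSE)
  keep <- is.finite(y)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  if (length(y) < 10)
    stop("need at least 10 finite responses", call. = FALSE)
  imps <- matrix(NA_real_, n_forests, ncol(x))
  with_preserved_rng(function() {
    RNGkind("Mersenne-Twister")
    for (f in seq_len(n_forests)) {
      set.seed(seed + f - 1L)
      rf <- randomForest::randomForest(x, y, ntree = n_trees, mtry = m_try,
                                       importance = TRUE)
      imps[f, ] <<- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
    }
  })
  mean_imp <- colMeans(imps)
  se <- if (n_forests > 1) apply(imps, 2, sd) / sqrt(n_forests)
        else rep(NA_real_, ncol(x))
  out <- data.frame(parameter = colnames(x),
                    mean_pct_inc_mse = mean_imp,
                    se = se,
                    ci_low = mean_imp - 1.96 * se,
                    ci_high = mean_imp + 1.96 * se,
                    rank = rank(-mean_imp, ties.method = "min"))
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}
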