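# Latin hypercube designs, the deterministic response sweep and repeated
# random-forest permutation importance.

test_that("distribution specs validate their hyperparameters", {
  expect_s3_class(dist_spec("a", "uniform", lo = 0, hi = 1), "dist_spec")
  expect_error(dist_spec("a", "uniform", lo = 1, hi = 0), "invalid")
  expect_error(dist_spec("a", "beta", mean = 0.5, sd = 0.6), "invalid")
  expect_error(dist_spec("a", "normal", mean = 1), "invalid")
})

test_that("every design column is stratified: one draw per equal-probability stratum", {
  specs <- list(dist_spec("u", "uniform", lo = 0, hi = 1),
                dist_spec("w", "uniform", lo = 10, hi = 30),
                dist_spec("n", "normal", mean = 127000, sd = 33500),
                dist_spec("b", "beta", mean = 0.46, sd = 0.09))
  n <- 100
  des <- latin_hypercube_design(specs, n, seed = 1)
  # map each column back to (0,1) with its own CDF, then bin
  backmap <- list(
    u = function(x) x,
    w = function(x) (x - 10) / 20,
    n = function(x) pnorm(x, 127000, 33500),
    b = function(x) {
      sh <- beta_shape_from_moments(0.46, 0.09)
      pbeta(x, sh[["alpha"]], sh[["beta"]])
    })
  for (nm in names(backmap)) {
    u <- backmap[[nm]](des$matrix[, nm])
    expect_equal(sort(floor(u * n)), 0:(n - 1))
  }
})

test_that("designs are reproducible by seed and support n = 1", {
  specs <- gsa_presets()$broad[1:5]
  a <- latin_hypercube_design(specs, 20, seed = 9)
  b <- latin_hypercube_design(specs, 20, seed = 9)
  expect_identical(a$matrix, b$matrix)
  one <- latin_hypercube_design(specs, 1, seed = 1)
  expect_equal(dim(one$matrix), c(1L, 5L))
})

test_that("a large normal column reproduces its moments", {
  des <- latin_hypercube_design(
    list(dist_spec("fec", "normal", mean = 127000, sd = 33500)),
    10000, seed = 1)
  expect_lt(abs(mean(des$matrix[, "fec"]) - 127000), 1000)
})

test_that("both sensitivity presets vary exactly 44 parameters with the published families", {
  pres <- gsa_presets()
  for (nm in c("broad", "restricted")) {
    expect_length(pres[[nm]], 44)
    pn <- vapply(pres[[nm]], function(s) s$name, "")
    expect_false(anyDuplicated(pn) > 0)
  }
  by_name <- function(specs, name)
    specs[[which(vapply(specs, function(s) s$name, "") == name)]]
  sex_b <- by_name(pres$broad, "female_ratio")
  expect_equal(sex_b$family, "uniform")
  expect_equal(c(sex_b$lo, sex_b$hi), c(0, 1))
  sex_r <- by_name(pres$restricted, "female_ratio")
  expect_equal(sex_r$family, "beta")
  expect_equal(c(sex_r$mean, sex_r$sd), c(0.5, 0.05))
  egg_r <- by_name(pres$restricted, "egg_survival")
  expect_equal(c(egg_r$mean, egg_r$sd), c(0.02, 0.04))
  keg <- by_name(pres$broad, "egg_capacity")
  expect_equal(c(keg$lo, keg$hi), c(1e5, 1e12))
  # means too close to the support edges are pulled to 0.05 / 0.9
  tp10 <- by_name(pres$restricted, "transform_prob_10")
  expect_equal(tp10$mean, 0.9)
  tp0 <- by_name(pres$restricted, "transform_prob_0")
  expect_equal(tp0$mean, 0.05)
})

test_that("the response sweep is pure and a broken life cycle yields zero spawners", {
  specs <- list(dist_spec("fecundity_mean", "fixed", value = 127000),
                dist_spec("ocean_entry_mean", "uniform", lo = 0.3, hi = 0.6))
  des <- latin_hypercube_design(specs, 4, seed = 3)
  cfg <- sim_config(years = 10, burn_in = 10)
  y1 <- run_gsa(des, lamprey_params(), cfg)
  y2 <- run_gsa(des, lamprey_params(), cfg)
  expect_identical(y1, y2)
  expect_true(all(is.finite(y1)))

  dead <- latin_hypercube_design(
    list(dist_spec("ocean_entry_mean", "fixed", value = 0)), 2, seed = 1)
  y0 <- run_gsa(dead, lamprey_params(), sim_config(years = 30, burn_in = 30))
  expect_equal(as.numeric(y0), c(0, 0))

  # identical rows (all fixed) give identical responses
  fixed <- latin_hypercube_design(
    list(dist_spec("egg_survival", "fixed", value = 0.02)), 3, seed = 1)
  yf <- run_gsa(fixed, lamprey_params(), cfg)
  expect_equal(length(unique(as.numeric(yf))), 1L)
})

test_that("a planted strong predictor ranks first with a CI excluding zero", {
  set.seed(1)
  x <- matrix(runif(100 * 11), 100, 11,
              dimnames = list(NULL, paste0("x", 1:11)))
  y <- 10 * x[, 1] + rnorm(100, sd = 0.1)
  imp <- random_forest_importance(x, y, n_forests = 10, n_trees = 201,
                                  m_try = 3, seed = 1)
  expect_equal(imp$parameter[1], "x1")
  expect_gt(imp$ci_low[1], 0)
})

test_that("pure-noise responses give importances centred on zero", {
  # across independent datasets (repeated forests on one dataset converge
  # to that dataset's idiosyncratic importances, not to zero)
  set.seed(2)
  reps <- t(replicate(12, {
    x <- matrix(runif(100 * 10), 100, 10,
                dimnames = list(NULL, paste0("x", 1:10)))
    imp <- random_forest_importance(x, rnorm(100), n_forests = 1,
                                    n_trees = 201, m_try = 3,
                                    seed = sample.int(1e6, 1))
    imp$mean_pct_inc_mse[order(imp$parameter)]
  }))
  mu <- colMeans(reps)
  se <- apply(reps, 2, sd) / sqrt(nrow(reps))
  covers <- abs(mu) <= 1.96 * se
  expect_gte(mean(covers), 0.9)
  # and the grand mean over columns and datasets sits at zero
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(length(reps)))
})

test_that("duplicated predictors share depressed importance", {
  set.seed(3)
  x_lone <- matrix(runif(150 * 5), 150, 5,
                   dimnames = list(NULL, paste0("x", 1:5)))
  y <- 10 * x_lone[, 1] + rnorm(150, sd = 0.5)
  x_dup <- cbind(x_lone, x1_copy = x_lone[, 1])
  imp_lone <- random_forest_importance(x_lone, y, n_forests = 5,
                                       n_trees = 201, m_try = 2, seed = 1)
  imp_dup <- random_forest_importance(x_dup, y, n_forests = 5,
                                      n_trees = 201, m_try = 2, seed = 1)
  lone <- imp_lone$mean_pct_inc_mse[imp_lone$parameter == "x1"]
  dup <- imp_dup$mean_pct_inc_mse[imp_dup$parameter %in% c("x1", "x1_copy")]
  expect_true(all(dup < lone))
})

test_that("importance aggregation handles a single forest", {
  set.seed(4)
  x <- matrix(runif(60 * 4), 60, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- x[, 1] + rnorm(60, sd = 0.2)
  imp <- random_forest_importance(x, y, n_forests = 1, n_trees = 101,
                                  m_try = 2, seed = 1)
  expect_true(all(is.na(imp$se)))
  expect_true(all(is.na(imp$ci_low)))
  expect_error(random_forest_importance(x, y, n_forests = 0), ">= 1")
})
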