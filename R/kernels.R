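# Stochastic kernels: moment matching, Beverton-Holt density dependence, and
# the draw abstraction that lets every life cycle transition run in stochastic
# or deterministic (expectation) mode. All draws use R's global RNG; the
# simulation engine pins an L'Ecuyer-CMRG substream per (replicate, year).

DRAW_MODES <- c("stochastic", "deterministic")

check_mode <- function(mode) match.arg(mode, DRAW_MODES)

#' Negative-binomial shape parameter from mean and standard deviation
#'
#' Moment matching for the negative binomial used for individual fecundity:
#' a distribution with mean \eqn{\mu} and shape \eqn{k} has variance
#' \eqn{\mu + \mu^2/k}, so \eqn{k = \mu^2 / (\sigma^2 - \mu)}. The target
#' variance must exceed the mean (over-dispersion); at \eqn{\sigma^2 \le \mu}
#' the negative binomial is undefined and a Poisson would be the limit.
#'
#' @param mean Target mean (eggs per female); must be positive.
#' @param sd Target standard deviation; `sd^2` must exceed `mean`.
#' @return The dimensionless shape parameter `k`.
#' @examples
#' nb_shape_from_moments(127000, 33500)
#' @export
nb_shape_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd),
            length(mean) == 1L, length(sd) == 1L)
  if (!is.finite(mean) || mean <= 0)
    stop("`mean` must be a positive finite number", call. = FALSE)
  if (!is.finite(sd) || sd^2 <= mean)
    stop("negative binomial undefined for sd^2 <= mean (got sd^2 = ", sd^2,
         ", mean = ", mean, "); the Poisson is the sd^2 = mean limit",
         call. = FALSE)
  mean^2 / (sd^2 - mean)
}

#' Beta shape parameters from mean and standard deviation
#'
#' Moment matching for the beta distributions used for yearly survival
#' probabilities (ocean entry, yearly ocean survival, river entry):
#' \eqn{\alpha = (\mu(1-\mu)/\sigma^2 - 1)\mu} and
#' \eqn{\beta = (\mu(1-\mu)/\sigma^2 - 1)(1-\mu)}. Requires
#' \eqn{\sigma^2 < \mu(1-\mu)} so that both shapes are positive.
#'
#' @param mean Target mean, strictly between 0 and 1.
#' @param sd Target standard deviation; `sd^2` must be below `mean * (1 - mean)`.
#' @return Named numeric vector `c(alpha = , beta = )`.
#' @examples
#' beta_shape_from_moments(0.46, 0.09)
#' @export
beta_shape_from_moments <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd),
            length(mean) == 1L, length(sd) == 1L)
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("`mean` must lie strictly between 0 and 1", call. = FALSE)
  if (!is.finite(sd) || sd <= 0 || sd^2 >= mean * (1 - mean))
    stop("beta distribution undefined for sd^2 >= mean * (1 - mean) ",
         "(got sd^2 = ", sd^2, ", bound = ", mean * (1 - mean), ")",
         call. = FALSE)
  nu <- mean * (1 - mean) / sd^2 - 1
  c(alpha = nu * mean, beta = nu * (1 - mean))
}

#' Beverton-Holt density-dependent survival
#'
#' Compensatory survival \eqn{\pi = 1 / (1/S + n/K)}: at `n = 0` the baseline
#' `base_survival` is recovered, and survival declines monotonically as
#' abundance `n` approaches and exceeds the capacity `K`.
#'
#' @param base_survival Density-independent baseline survival in (0, 1].
#'   A value of 0 is accepted and returns 0 (complete seasonal mortality).
#' @param n Abundance competing for the habitat (>= 0).
#' @param capacity Carrying capacity `K` (> 0), same units as `n`.
#' @return A survival probability in `[0, base_survival]`.
#' @examples
#' beverton_holt_survival(0.02, 50.8e6, 575e6)
#' @export
beverton_holt_survival <- function(base_survival, n, capacity) {
  stopifnot(length(base_survival) == 1L, length(n) == 1L,
            length(capacity) == 1L)
  if (!is.finite(capacity) || capacity <= 0)
    stop("`capacity` must be positive", call. = FALSE)
  if (!is.finite(n) || n < 0)
    stop("`n` must be non-negative", call. = FALSE)
  if (!is.finite(base_survival) || base_survival < 0 || base_survival > 1)
    stop("`base_survival` must lie in [0, 1]", call. = FALSE)
  if (base_survival == 0) return(0)
  1 / (1 / base_survival + n / capacity)
}

# rbinom's size is limited to integers < 2^31; fall back to a clipped normal
# approximation for astronomically large pools (only reachable with extreme
# user capacities).
rbinom_large <- function(n, p) {
  if (n <= .Machine$integer.max) return(rbinom(1L, round(n), p))
  mu <- n * p
  sigma <- sqrt(n * p * (1 - p))
  min(max(round(rnorm(1L, mu, sigma)), 0), n)
}

#' Binomial transition draw
#'
#' The workhorse of every stage transition: the number of `n` individuals
#' experiencing an event of probability `p`. In stochastic mode this is one
#' binomial draw; in deterministic mode the exact expectation `n * p` is
#' propagated as a real number (no rounding), so a deterministic trajectory
#' is a smooth map on abundances.
#'
#' @param n Pool size(s), non-negative. Vectors are drawn element-wise.
#' @param p Event probability (scalar or same length as `n`) in `[0, 1]`.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return Count(s): integers in `[0, n]` (stochastic) or `n * p`
#'   (deterministic).
#' @examples
#' draw_count(1000, 0.6, "deterministic")
#' @export
draw_count <- function(n, p, mode = "stochastic") {
  mode <- check_mode(mode)
  if (any(!is.finite(n)) || any(n < 0))
    stop("`n` must be non-negative and finite", call. = FALSE)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("`p` must lie in [0, 1]", call. = FALSE)
  if (mode == "deterministic") return(n * p)
  if (length(n) > 1L || length(p) > 1L) {
    k <- max(length(n), length(p))
    n <- rep_len(n, k)
    p <- rep_len(p, k)
    if (all(n <= .Machine$integer.max)) return(rbinom(k, round(n), p))
    return(vapply(seq_len(k), function(i) rbinom_large(n[i], p[i]), 0))
  }
  rbinom_large(n, p)
}

#' Yearly survival probability draw
#'
#' One beta variate with moment-matched shapes (environmental stochasticity:
#' the same realized probability applies to every fish that year), or the
#' mean exactly in deterministic mode.
#'
#' @param mean,sd Moments of the beta distribution (see
#'   [beta_shape_from_moments()]). `sd` is not needed (and not validated) in
#'   deterministic mode.
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return One probability in `[0, 1]`.
#' @export
draw_probability <- function(mean, sd, mode = "stochastic") {
  mode <- check_mode(mode)
  if (mode == "deterministic") {
    if (!is.finite(mean) || mean < 0 || mean > 1)
      stop("`mean` must lie in [0, 1]", call. = FALSE)
    return(mean)
  }
  sh <- beta_shape_from_moments(mean, sd)
  rbeta(1L, sh[["alpha"]], sh[["beta"]])
}

#' Total egg production of a group of females
#'
#' Individual fecundity is negative binomial with mean `mean` and shape
#' moment-matched from `sd`; the total over `n_females` independent females
#' is drawn as a single negative binomial with shape `n_females * k` and mean
#' `n_females * mean` (exactly the distribution of the per-female sum).
#' Deterministic mode returns `n_females * mean`.
#'
#' @param n_females Number of spawning females (>= 0).
#' @param mean,sd Per-female fecundity moments (eggs).
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return Total egg count.
#' @examples
#' draw_fecundity_total(400, 127000, 33500, "deterministic")
#' @export
draw_fecundity_total <- function(n_females, mean, sd, mode = "stochastic") {
  mode <- check_mode(mode)
  if (!is.finite(n_females) || n_females < 0)
    stop("`n_females` must be non-negative", call. = FALSE)
  if (n_females == 0) return(0)
  if (mode == "deterministic") return(n_females * mean)
  k <- nb_shape_from_moments(mean, sd)
  rnbinom(1L, size = n_females * k, mu = n_females * mean)
}
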