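# Shared fixtures: everything is generated in code at test time.

default_params <- function(...) modify_params(lamprey_params(), ...)

tiny_config <- function(...) {
  args <- modifyList(list(years = 3, burn_in = 2, replicates = 2, seed = 1),
                     list(...))
  do.call(sim_config, args)
}

# analytic beta moments, used as the independent side of round-trip checks
beta_moments <- function(alpha, beta) {
  m <- alpha / (alpha + beta)
  v <- alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1))
  c(mean = m, sd = sqrt(v))
}

write_yaml_config <- function(lines) {
  path <- tempfile(fileext = ".yaml")
  writeLines(lines, path)
  path
}
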