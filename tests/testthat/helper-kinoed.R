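# shared fixtures: corner support of the log-case design region and the
# printed discriminating-design weights used across tests
log_corners <- function() data.frame(xS = c(0.02, 30, 0.02, 30),
                                     xI = c(0, 0, 60, 60))

printed_A1_weights <- c(0.0095, 0.1402, 0.3600, 0.4903)
printed_A2_weights <- c(0.1688, 0.1818, 0.3002, 0.3492)

# random admissible parameter vector for a model (log-uniform around
# plausible kinetic magnitudes)
random_theta <- function(spec) {
  th <- exp(stats::runif(3, log(0.5), log(20)))
  if (spec$model == "michaelis_menten") return(th[1:2])
  if (spec$model == "encompassing") return(c(th, stats::runif(1)))
  th
}

# small all-positive test dataset on a coarse plate
tiny_dataset <- function(spec, theta, sigma = 0, seed = 1) {
  tpl <- default_template(substrate_levels = c(0.5, 1, 2, 5, 10, 20, 30),
                          inhibitor_levels = c(0, 5, 20, 60))
  generate_study(tpl, spec, theta, sigma,
                 error_structure = "multiplicative_lognormal", seed = seed)
}
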