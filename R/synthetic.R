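#' Default substrate-inhibitor study template
#'
#' A 15 x 8 factorial plate emulating the dextromethorphan-sertraline
#' initial experiment: 15 substrate concentrations on [0, 30], denser at the
#' low end to give reasonable substrate saturation, crossed with 8 inhibitor
#' concentrations spanning [0, 60]; both ladders include 0 (which exercises
#' the zero-replacement rule of the log-scale pipeline).  The exact
#' concentration ladders of the original plate were never published; these
#' are a realistic choice matching its qualitative layout and can be
#' overridden.
#'
#' @param substrate_levels,inhibitor_levels optional replacement ladders.
#' @return a list of class `kinoed_template` with `substrate_levels`
#'   (length 15 by default), `inhibitor_levels` (length 8) and the implied
#'   `N = 120` combinations.
#' @export
default_template <- function(substrate_levels = c(0, 0.5, 1, 1.5, 2, 3, 4, 5,
                                                  7, 9, 12, 15, 20, 25, 30),
                             inhibitor_levels = c(0, 2, 5, 10, 20, 30, 45, 60)) {
  substrate_levels <- sort(substrate_levels)
  inhibitor_levels <- sort(inhibitor_levels)
  structure(list(substrate_levels = substrate_levels,
                 inhibitor_levels = inhibitor_levels,
                 N = length(substrate_levels) * length(inhibitor_levels)),
            class = "kinoed_template")
}

#' Generate a synthetic inhibition dataset
#'
#' Simulates one observation per substrate-inhibitor combination of the
#' template from a kinetic model under either error structure: additive
#' normal (`y = eta + e`, which can produce non-positive rates when `sigma`
#' is large -- the motivation for the multiplicative specification) or
#' multiplicative log-normal (`y = eta * exp(e)` with
#' `e ~ N(0, sigma^2)`, always positive).
#'
#' @param template a [default_template()].
#' @param spec a [model_spec()]; only its mean function is used (the error
#'   structure is chosen separately).
#' @param theta generating parameter values.
#' @param sigma error standard deviation (additive: rate units; multiplicative:
#'   log-rate units).
#' @param error_structure `"multiplicative_lognormal"` or `"additive_normal"`.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @return a rate data frame (columns `substrate`, `inhibitor`, `rate`).
#' @export
generate_study <- function(template, spec, theta, sigma,
                           error_structure = c("multiplicative_lognormal",
                                               "additive_normal"),
                           seed = NULL) {
  error_structure <- match.arg(error_structure)
  stopifnot(inherits(template, "kinoed_template"), sigma >= 0)
  g <- expand.grid(substrate = template$substrate_levels,
                   inhibitor = template$inhibitor_levels)
  std_spec <- model_spec(spec$model, "standard")
  eta <- eval_rate(std_spec, theta, g$substrate, g$inhibitor)
  with_seed(seed, {
    e <- stats::rnorm(nrow(g), 0, sigma)
    y <- if (error_structure == "multiplicative_lognormal")
      eta * exp(e) else eta + e
  })
  data.frame(substrate = g$substrate, inhibitor = g$inhibitor, rate = y)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}
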