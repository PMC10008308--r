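#' Model specification for an enzyme kinetic rate law
#'
#' The package works with four Michaelis-Menten type mean rate functions:
#' the two-parameter Michaelis-Menten law, the competitive and
#' non-competitive inhibition extensions (three parameters each), and the
#' four-parameter encompassing model whose mixing parameter `lambda` nests
#' both inhibition mechanisms (`lambda = 1` competitive, `lambda = 0`
#' non-competitive).  Each model can be used on the `standard` scale, where
#' the response is the rate itself with additive normal errors, or on the
#' `log` scale, where the response is the natural log of the rate and errors
#' are multiplicative log-normal.
#'
#' @param model one of `"michaelis_menten"`, `"competitive"`,
#'   `"noncompetitive"`, `"encompassing"`.
#' @param scale response scale, `"standard"` (rate) or `"log"` (log rate).
#' @return an object of class `kinoed_model` with fields `model`, `scale`
#'   and `m`, the number of parameters (2, 3, 3 or 4).
#' @examples
#' model_spec("competitive", "log")
#' @export
model_spec <- function(model = c("michaelis_menten", "competitive",
                                 "noncompetitive", "encompassing"),
                       scale = c("standard", "log")) {
  model <- match.arg(model)
  scale <- match.arg(scale)
  m <- switch(model,
              michaelis_menten = 2L,
              competitive = 3L,
              noncompetitive = 3L,
              encompassing = 4L)
  structure(list(model = model, scale = scale, m = m), class = "kinoed_model")
}

#' @export
print.kinoed_model <- function(x, ...) {
  cat(sprintf("<kinoed model: %s, %s scale, %d parameters>\n",
              x$model, x$scale, x$m))
  invisible(x)
}

param_names <- function(spec) {
  switch(spec$model,
         michaelis_menten = c("thetaV", "thetaM"),
         competitive = c("thetaV", "thetaM", "thetaK"),
         noncompetitive = c("thetaV", "thetaM", "thetaK"),
         encompassing = c("thetaV", "thetaM", "thetaK", "lambda"))
}

check_theta <- function(spec, theta) {
  theta <- as.numeric(theta)
  if (length(theta) != spec$m)
    stop(sprintf("model '%s' needs %d parameters, got %d",
                 spec$model, spec$m, length(theta)), call. = FALSE)
  if (any(!is.finite(theta)))
    stop("parameters must be finite", call. = FALSE)
  if (any(theta[seq_len(min(spec$m, 3L))] <= 0))
    stop("thetaV, thetaM, thetaK must be strictly positive", call. = FALSE)
  if (spec$model == "encompassing" && (theta[4L] < 0 || theta[4L] > 1))
    stop("lambda must lie in [0, 1]", call. = FALSE)
  names(theta) <- param_names(spec)
  theta
}

check_points <- function(xS, xI) {
  if (length(xI) == 1L) xI <- rep(xI, length(xS))
  if (length(xS) != length(xI))
    stop("substrate and inhibitor vectors must have equal length", call. = FALSE)
  if (any(!is.finite(xS)) || any(!is.finite(xI)) || any(xS < 0) || any(xI < 0))
    stop("design points must be finite and non-negative", call. = FALSE)
  list(xS = xS, xI = xI)
}

# rate denominator for the inhibition models; the encompassing denominator
# theta_M (1 + xI/thetaK) + xS (1 + (1-lambda) xI/thetaK) reduces to the
# competitive one at lambda = 1 and factorises as (thetaM + xS)(1 + xI/thetaK)
# at lambda = 0.
rate_standard <- function(spec, theta, xS, xI) {
  tV <- theta[[1L]]; tM <- theta[[2L]]
  switch(spec$model,
         michaelis_menten = tV * xS / (tM + xS),
         competitive = {
           tK <- theta[[3L]]
           tV * xS / (tM * (1 + xI / tK) + xS)
         },
         noncompetitive = {
           tK <- theta[[3L]]
           tV * xS / ((tM + xS) * (1 + xI / tK))
         },
         encompassing = {
           tK <- theta[[3L]]; lam <- theta[[4L]]
           tV * xS / (tM * (1 + xI / tK) + xS * (1 + (1 - lam) * xI / tK))
         })
}

#' Expected response of a kinetic model
#'
#' Evaluates the mean reaction rate \eqn{\eta(\theta, x)} at substrate /
#' inhibitor concentrations, or its natural log when the spec is on the log
#' scale.
#'
#' @param spec a [model_spec()].
#' @param theta numeric parameter vector (`thetaV`, `thetaM`, `thetaK`,
#'   `lambda` as required by the model).
#' @param xS,xI substrate and inhibitor concentrations (vectors recycled to a
#'   common length).
#' @return numeric vector of expected responses.
#' @examples
#' eval_rate(model_spec("competitive"), c(7.2976, 4.3860, 2.5821), 30, 0)
#' @export
eval_rate <- function(spec, theta, xS, xI = 0) {
  theta <- check_theta(spec, theta)
  pts <- check_points(xS, xI)
  eta <- rate_standard(spec, theta, pts$xS, pts$xI)
  if (spec$scale == "log") {
    bad <- which(eta <= 0)
    if (length(bad))
      stop(sprintf("log response undefined: zero rate at (x_S = %g, x_I = %g)",
                   pts$xS[bad[1L]], pts$xI[bad[1L]]), call. = FALSE)
    eta <- log(eta)
  }
  eta
}

#' Parameter gradient of the expected response
#'
#' Analytic partial derivatives of the (possibly log-transformed) expected
#' rate with respect to the model parameters.  On the log scale the gradient
#' is the standard-scale gradient divided by the rate (chain rule), which is
#' exactly the linearisation entering the Fisher information of the
#' log-normal model.
#'
#' @inheritParams eval_rate
#' @return an `n x m` matrix, one row per design point, columns named after
#'   the parameters.
#' @export
gradient <- function(spec, theta, xS, xI = 0) {
  theta <- check_theta(spec, theta)
  pts <- check_points(xS, xI); xS <- pts$xS; xI <- pts$xI
  tV <- theta[[1L]]; tM <- theta[[2L]]
  g <- switch(spec$model,
    michaelis_menten = {
      cbind(xS / (tM + xS), -tV * xS / (tM + xS)^2)
    },
    competitive = {
      tK <- theta[[3L]]
      D <- tM * (1 + xI / tK) + xS
      cbind(xS / D,
            -tV * xS * (1 + xI / tK) / D^2,
            tV * xS * tM * xI / (tK^2 * D^2))
    },
    noncompetitive = {
      tK <- theta[[3L]]
      D <- (tM + xS) * (1 + xI / tK)
      eta <- tV * xS / D
      cbind(xS / D,
            -eta / (tM + xS),
            eta * (xI / tK^2) / (1 + xI / tK))
    },
    encompassing = {
      tK <- theta[[3L]]; lam <- theta[[4L]]
      D <- tM * (1 + xI / tK) + xS * (1 + (1 - lam) * xI / tK)
      cbind(xS / D,
            -tV * xS * (1 + xI / tK) / D^2,
            tV * xS * xI * (tM + xS * (1 - lam)) / (tK^2 * D^2),
            tV * xS * (xS * xI / tK) / D^2)
    })
  colnames(g) <- param_names(spec)
  if (spec$scale == "log") {
    eta <- rate_standard(spec, theta, xS, xI)
    bad <- which(eta <= 0)
    if (length(bad))
      stop(sprintf("log gradient undefined: zero rate at (x_S = %g, x_I = %g)",
                   xS[bad[1L]], xI[bad[1L]]), call. = FALSE)
    g <- g / eta
  }
  g
}

#' IC50 of the encompassing model
#'
#' The half-maximal inhibitory concentration: the inhibitor concentration at
#' which the expected rate drops to half of its uninhibited (`x_I = 0`)
#' value, with the substrate held at the Michaelis constant estimate
#' `x_S = thetaM`.  Computed by one-dimensional root finding on the rate
#' ratio to tolerance 1e-10.
#'
#' @param theta encompassing-model parameter vector
#'   `(thetaV, thetaM, thetaK, lambda)`.
#' @return the IC50, in inhibitor concentration units.
#' @examples
#' ic50_encompassing(c(6.9897, 3.9799, 3.7380, 0.8737)) # 6.638
#' @export
ic50_encompassing <- function(theta) {
  spec <- model_spec("encompassing")
  theta <- check_theta(spec, theta)
  xS <- theta[2L]
  half <- rate_standard(spec, theta, xS, 0) / 2
  f <- function(xI) rate_standard(spec, theta, xS, xI) - half
  hi <- theta[3L]
  while (f(hi) > 0) hi <- hi * 2
  out <- stats::uniroot(f, c(0, hi), tol = 1e-10)
  if (abs(out$f.root) > 1e-8 * half && out$estim.prec > 1e-6)
    stop("IC50 root finding did not converge", call. = FALSE)
  unname(out$root)
}

#' Inhibitor concentration for a target fractional activity
#'
#' For a well-behaved concentration-response relationship (Hill coefficient
#' 1), the inhibitor concentration achieving fractional activity
#' \eqn{E_i[y]/E_0[y]} is \eqn{x_I = IC_{50} (E_0[y]/E_i[y] - 1)}.  Used to
#' lay out percent-inhibition schemes on a well plate (e.g. 90% inhibition
#' requires nine times the IC50).
#'
#' @param ic50 half-maximal inhibitory concentration (> 0).
#' @param fractional_activity remaining activity, in (0, 1].
#' @return inhibitor concentration.
#' @examples
#' inhibitor_for_activity(6.638, 0.10) / 6.638 # 9
#' @export
inhibitor_for_activity <- function(ic50, fractional_activity) {
  if (!is.finite(ic50) || ic50 <= 0)
    stop("ic50 must be a positive number", call. = FALSE)
  if (any(fractional_activity <= 0) || any(fractional_activity > 1))
    stop("fractional_activity must lie in (0, 1]", call. = FALSE)
  ic50 * (1 / fractional_activity - 1)
}
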