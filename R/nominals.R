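#' Built-in nominal parameter estimates
#'
#' Locally optimal designs for nonlinear models require nominal parameter
#' values.  The package ships the nominal estimates (with standard errors
#' and residual standard errors) obtained from an initial
#' dextromethorphan-sertraline inhibition experiment for the competitive,
#' non-competitive and encompassing models, on both the standard and the log
#' scale.  All design computations in the package default to these values.
#'
#' @param model `"competitive"`, `"noncompetitive"` or `"encompassing"`.
#' @param scale `"standard"` or `"log"`.
#' @return a list with components `theta` (named estimates), `se` (standard
#'   errors) and `sigma` (residual standard error of the fit).
#' @examples
#' nominal_estimates("encompassing", "log")$theta
#' @export
nominal_estimates <- function(model = c("competitive", "noncompetitive",
                                        "encompassing"),
                              scale = c("standard", "log")) {
  model <- match.arg(model)
  scale <- match.arg(scale)
  tab <- list(
    competitive = list(
      standard = list(theta = c(thetaV = 7.2976, thetaM = 4.3860, thetaK = 2.5821),
                      se = c(0.1143, 0.2333, 0.1454), sigma = 0.1553),
      log = list(theta = c(thetaV = 6.0645, thetaM = 3.2799, thetaK = 3.3153),
                 se = c(0.9260, 0.7288, 0.6041), sigma = 0.5160)),
    noncompetitive = list(
      standard = list(theta = c(thetaV = 8.6957, thetaM = 8.0664, thetaK = 12.0566),
                      se = c(0.2227, 0.4880, 0.6709), sigma = 0.2272),
      log = list(theta = c(thetaV = 12.0125, thetaM = 8.5359, thetaK = 5.6638),
                 se = c(2.0553, 1.5721, 0.8879), sigma = 0.5306)),
    encompassing = list(
      standard = list(theta = c(thetaV = 7.4253, thetaM = 4.6808, thetaK = 3.0581,
                                lambda = 0.9636),
                      se = c(0.1298, 0.2724, 0.2815, 0.0191), sigma = 0.1526),
      log = list(theta = c(thetaV = 6.9897, thetaM = 3.9799, thetaK = 3.7380,
                           lambda = 0.8737),
                 se = c(1.3406, 1.0403, 0.7218, 0.1123), sigma = 0.5128)))
  out <- tab[[model]][[scale]]
  names(out$se) <- names(out$theta)
  out
}

# encompassing-model nominals with lambda pinned to 0 or 1 and the pure-model
# estimates for thetaV, thetaM, thetaK -- the parameterisation behind the
# 4-parameter designs "4D_N" (lambda = 0) and "4D_C" (lambda = 1).
encompassing_at <- function(pure_model, scale) {
  nom <- nominal_estimates(pure_model, scale)
  lam <- if (pure_model == "competitive") 1 else 0
  c(nom$theta, lambda = lam)
}
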