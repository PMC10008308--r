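#' Read and write rate datasets
#'
#' Datasets are delimited text files with header columns `substrate`,
#' `inhibitor`, `rate`, one observation per row.
#'
#' @param path file path.
#' @param sep field separator (default comma).
#' @return `read_rates` returns a data frame with columns `substrate`,
#'   `inhibitor`, `rate`.
#' @export
read_rates <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("substrate", "inhibitor", "rate")
  if (!all(need %in% names(d)))
    stop("dataset must have columns substrate, inhibitor, rate", call. = FALSE)
  d <- d[, need]
  if (any(!is.finite(as.matrix(d))))
    stop("dataset contains non-finite values", call. = FALSE)
  if (any(d$substrate < 0) || any(d$inhibitor < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  d
}

#' @rdname read_rates
#' @param data a rate data frame.
#' @export
write_rates <- function(data, path, sep = ",") {
  utils::write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Replace zero substrate concentrations and rates by a small floor
#'
#' Log transformation is undefined at zero, so zero substrate
#' concentrations and zero measured rates are replaced by a small positive
#' floor before fitting on the log scale.  The default floor 0.02 is the
#' value that minimises the back-transformed residual standard error in the
#' reference study; inhibitor concentrations are never modified (a zero
#' inhibitor level is meaningful and log-safe).
#'
#' @param data a rate data frame (see [read_rates()]).
#' @param floor positive replacement value.
#' @return the data frame with zeros in `substrate` and `rate` replaced.
#' @examples
#' replace_zeros(data.frame(substrate = 0, inhibitor = 10, rate = 0))
#' @export
replace_zeros <- function(data, floor = 0.02) {
  if (!is.numeric(floor) || floor <= 0) stop("floor must be > 0", call. = FALSE)
  i <- data$substrate == 0
  if (any(i)) data$substrate[i] <- floor
  j <- data$rate == 0
  if (any(j)) data$rate[j] <- floor
  data
}

# deterministic multiplicative jitter factors for multistart fitting; rows
# are starts, recycled over parameters.  The first start is the unperturbed
# initial value.
start_factors <- function(n_starts, m) {
  base <- c(1, 0.5, 2, 0.8, 1.25, 0.65, 1.6, 0.9, 1.15, 0.4)
  f <- matrix(1, n_starts, m)
  for (s in seq_len(n_starts)[-1])
    for (j in seq_len(m))
      f[s, j] <- base[((s - 1) * 3 + j - 1) %% length(base) + 1]
  f
}

theta_bounds <- function(spec) {
  lower <- rep(1e-8, spec$m)
  upper <- rep(Inf, spec$m)
  if (spec$model == "encompassing") {
    lower[4L] <- 0
    upper[4L] <- 1
  }
  list(lower = lower, upper = upper)
}

#' Fit an enzyme kinetic model by nonlinear least squares
#'
#' Minimises the residual sum of squares of the rate (standard scale) or of
#' the log rate (log scale, i.e. multiplicative log-normal errors) using
#' box-constrained Levenberg-Marquardt with several deterministically
#' jittered starting values.  Standard errors come from the usual
#' linearisation covariance \eqn{\hat\sigma^2 (F^T F)^{-1}} with the
#' analytic Jacobian.
#'
#' @param data rate data frame; on the log scale all rates and substrate
#'   concentrations must be positive (apply [replace_zeros()] first).
#' @param spec a [model_spec()].
#' @param init initial parameter values; defaults to the built-in
#'   [nominal_estimates()] for the model (Michaelis-Menten starts from the
#'   competitive nominals without `thetaK`).
#' @param starts number of jittered starts (default 5).
#' @param compute_se if `FALSE`, skip the covariance/identifiability step
#'   (used when only the residual sum of squares is needed, e.g. for
#'   classification on near-saturated designs where the linearisation can
#'   be numerically rank-deficient).
#' @return an object of class `kinoed_fit`: `theta_hat`, `se`, `sigma_hat`,
#'   `sse`, `dof`, `scale`, `model`, `fitted` (on the analysis scale),
#'   `boundary` (`TRUE` when `lambda` ended on 0 or 1, in which case its
#'   standard error is unreliable), and the data used.
#' @export
fit_model <- function(data, spec, init = NULL, starts = 5L,
                      compute_se = TRUE) {
  stopifnot(inherits(spec, "kinoed_model"))
  N <- nrow(data)
  if (N <= spec$m)
    stop("need more observations than parameters", call. = FALSE)
  if (is.null(init)) {
    init <- switch(spec$model,
                   michaelis_menten = nominal_estimates("competitive", spec$scale)$theta[1:2],
                   nominal_estimates(spec$model, spec$scale)$theta)
  }
  init <- check_theta(spec, init)
  y <- data$rate
  if (spec$scale == "log") {
    if (any(y <= 0))
      stop("log-scale fitting requires positive rates; use replace_zeros()",
           call. = FALSE)
    if (any(data$substrate <= 0))
      stop("log-scale fitting requires positive substrate; use replace_zeros()",
           call. = FALSE)
    yresp <- log(y)
  } else yresp <- y
  b <- theta_bounds(spec)
  resid_fn <- function(th) yresp - eval_rate(spec, th, data$substrate, data$inhibitor)
  jac_fn <- function(th) -gradient(spec, th, data$substrate, data$inhibitor)

  fac <- start_factors(starts, spec$m)
  best <- NULL
  for (s in seq_len(starts)) {
    st <- pmin(pmax(init * fac[s, ], b$lower + 1e-9), c(100, 100, 100, 1)[seq_len(spec$m)] * 10)
    if (spec$model == "encompassing") st[4L] <- min(max(init[4L] * fac[s, 4L], 0), 1)
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = st, lower = b$lower, upper = b$upper,
                           fn = resid_fn, jac = jac_fn,
                           control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("nonlinear least squares did not converge from any start", call. = FALSE)
  th <- check_theta(spec, best$fit$par)
  sse <- best$sse
  dof <- N - spec$m
  sigma_hat <- sqrt(sse / dof)
  boundary <- spec$model == "encompassing" && (th[4L] < 1e-6 || th[4L] > 1 - 1e-6)
  if (compute_se) {
    J <- gradient(spec, th, data$substrate, data$inhibitor)
    XtX <- crossprod(J)
    cv <- if (qr(J)$rank < spec$m) NULL
          else tryCatch(solve(XtX), error = function(e) NULL)
    if (is.null(cv) || !all(is.finite(cv)))
      stop(sprintf("information matrix singular at the optimum: model '%s' is not identifiable from these design points", spec$model),
           call. = FALSE)
    se <- sigma_hat * sqrt(pmax(diag(cv), 0))
    names(se) <- names(th)
  } else se <- rep(NA_real_, spec$m)
  structure(list(theta_hat = th, se = se, sigma_hat = sigma_hat, sse = sse,
                 dof = dof, scale = spec$scale, model = spec$model,
                 spec = spec, boundary = boundary,
                 fitted = yresp - best$fit$fvec, data = data),
            class = "kinoed_fit")
}

#' @export
print.kinoed_fit <- function(x, ...) {
  cat(sprintf("Nonlinear least-squares fit: %s model, %s scale\n",
              x$model, x$scale))
  tab <- cbind(Estimate = x$theta_hat, `Std. Error` = x$se)
  print(round(tab, 4))
  cat(sprintf("sigma_hat = %.4f on %d degrees of freedom (SSE = %.4f)\n",
              x$sigma_hat, x$dof, x$sse))
  if (isTRUE(x$boundary))
    cat("note: lambda at its boundary; its standard error is unreliable\n")
  invisible(x)
}

#' Residual summaries on the standard, log and back-transformed scales
#'
#' Three residual sums of squares used to compare the additive and the
#' multiplicative error specifications: the standard case compares rates
#' with standard-scale fitted values; the log case compares log rates with
#' log-scale fitted values; the back-transformed case compares rates with
#' exponentiated log-scale fitted values.  Each MSE divides by `N - m`.
#'
#' @param fit_standard a `kinoed_fit` on the standard scale, or `NULL`.
#' @param fit_log a `kinoed_fit` on the log scale, or `NULL`.
#' @return data frame with columns `case`, `sse`, `mse` (rows only for the
#'   fits supplied; the back-transformed row accompanies the log fit).
#' @export
residual_summaries <- function(fit_standard = NULL, fit_log = NULL) {
  rows <- list()
  if (!is.null(fit_standard)) {
    stopifnot(fit_standard$scale == "standard")
    sse <- sum((fit_standard$data$rate - fit_standard$fitted)^2)
    rows$standard <- c(sse, sse / fit_standard$dof)
  }
  if (!is.null(fit_log)) {
    stopifnot(fit_log$scale == "log")
    lsse <- sum((log(fit_log$data$rate) - fit_log$fitted)^2)
    bsse <- sum((fit_log$data$rate - exp(fit_log$fitted))^2)
    rows$log <- c(lsse, lsse / fit_log$dof)
    rows$back_transformed <- c(bsse, bsse / fit_log$dof)
  }
  if (!length(rows)) stop("supply at least one fit", call. = FALSE)
  data.frame(case = names(rows),
             sse = vapply(rows, `[`, 0, 1),
             mse = vapply(rows, `[`, 0, 2),
             row.names = NULL)
}

#' Serialise a fit as JSON
#'
#' @param fit a `kinoed_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$model, scale = fit$scale,
         theta = as.list(fit$theta_hat), se = as.list(fit$se),
         sigma_hat = fit$sigma_hat, sse = fit$sse, dof = fit$dof),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
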