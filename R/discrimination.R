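#' Lack-of-fit distance of a rival model (T-criterion value)
#'
#' For an assumed true model \eqn{\eta_0} at fixed nominal parameters and a
#' rival model \eqn{\eta_1} with free parameters, computes
#' \deqn{\Delta_0(\xi) = \inf_{\theta_1} \sum_i \omega_i
#'   (\eta_0(x_i) - \eta_1(\theta_1, x_i))^2,}
#' the weighted lack-of-fit sum of squares the rival cannot remove.  The
#' inner minimisation is box-constrained Levenberg-Marquardt from several
#' deterministically jittered starts.
#'
#' @param design a `kinoed_design` (or exact design).
#' @param true_spec,theta0 the assumed true model and its nominal values.
#' @param rival_spec the rival model (same scale).
#' @param rival_init starting values for the rival parameters; defaults to
#'   the rival's built-in nominal estimates.
#' @param starts number of jittered starts (default 10).
#' @param warm optional single warm-start parameter vector (used internally
#'   by the Fedorov-Wynn loop; overrides multistart).
#' @return object of class `kinoed_topt`: `design`, `delta0`, `theta1_hat`,
#'   and the criterion's defining models.
#' @export
lack_of_fit <- function(design, true_spec, theta0, rival_spec,
                        rival_init = NULL, starts = 10L, warm = NULL) {
  design <- as_approx(design)
  stopifnot(true_spec$scale == rival_spec$scale)
  eta0 <- eval_rate(true_spec, theta0, design$points$xS, design$points$xI)
  fit <- fit_rival(eta0, design$points, design$weights, rival_spec,
                   rival_init, starts, warm)
  structure(list(design = design, delta0 = fit$delta,
                 theta1_hat = fit$theta, true_spec = true_spec,
                 theta0 = check_theta(true_spec, theta0),
                 rival_spec = rival_spec),
            class = "kinoed_topt")
}

# weighted inner NLS: minimise sum w (eta0 - eta1(theta))^2
fit_rival <- function(eta0, points, weights, rival_spec, rival_init,
                      starts, warm = NULL) {
  if (is.null(rival_init)) {
    rival_init <- switch(rival_spec$model,
      michaelis_menten = nominal_estimates("competitive", rival_spec$scale)$theta[1:2],
      nominal_estimates(rival_spec$model, rival_spec$scale)$theta)
  }
  rival_init <- check_theta(rival_spec, rival_init)
  b <- theta_bounds(rival_spec)
  sw <- sqrt(weights)
  rf <- function(th) sw * (eta0 - eval_rate(rival_spec, th, points$xS, points$xI))
  jf <- function(th) -sw * gradient(rival_spec, th, points$xS, points$xI)
  run1 <- function(st) tryCatch({
    f <- suppressWarnings(
      minpack.lm::nls.lm(par = st, lower = b$lower, upper = b$upper,
                         fn = rf, jac = jf,
                         control = minpack.lm::nls.lm.control(maxiter = 300)))
    list(theta = check_theta(rival_spec, f$par), delta = sum(f$fvec^2))
  }, error = function(e) NULL)
  best <- NULL
  if (!is.null(warm)) best <- run1(check_theta(rival_spec, warm))
  if (is.null(warm) || is.null(best)) {
    fac <- start_factors(starts, rival_spec$m)
    for (s in seq_len(starts)) {
      st <- pmax(rival_init * fac[s, ], b$lower + 1e-9)
      if (rival_spec$model == "encompassing") st[4L] <- min(st[4L], 1)
      r <- run1(st)
      if (!is.null(r) && (is.null(best) || r$delta < best$delta - 1e-14)) best <- r
    }
  }
  if (is.null(best)) stop("inner rival fit did not converge", call. = FALSE)
  best
}

#' @export
print.kinoed_topt <- function(x, ...) {
  cat(sprintf("T-criterion result: true %s vs rival %s (%s scale)\n",
              x$true_spec$model, x$rival_spec$model, x$true_spec$scale))
  print(x$design)
  cat(sprintf("Delta = %.6g; rival minimiser: %s\n", x$delta0,
              paste(sprintf("%.4f", x$theta1_hat), collapse = ", ")))
  invisible(x)
}

#' T-criterion sensitivity function
#'
#' \eqn{\psi(x) = (\eta_0(x) - \eta_1(\hat\theta_1, x))^2} at the rival
#' minimiser of a T computation.  At a T-optimum its maximum over the design
#' region equals \eqn{\Delta_0} and is attained on the support; for any
#' design its weighted average over the design equals \eqn{\Delta_0}.
#'
#' @param result a `kinoed_topt`.
#' @param xS,xI evaluation points.
#' @export
sensitivity_t <- function(result, xS, xI = 0) {
  e0 <- eval_rate(result$true_spec, result$theta0, xS, xI)
  e1 <- eval_rate(result$rival_spec, result$theta1_hat, xS, xI)
  (e0 - e1)^2
}

#' T-efficiency of a design
#'
#' \eqn{Eff_T(\xi) = \Delta(\xi) / \Delta(\xi^*)} in percent, where both
#' lack-of-fit values are computed under the reference result's criterion
#' (its true model, nominal values and rival family).
#'
#' @param design design to evaluate.
#' @param reference a converged `kinoed_topt` defining the criterion and
#'   supplying the optimal value.
#' @export
t_efficiency <- function(design, reference) {
  stopifnot(inherits(reference, "kinoed_topt"))
  if (reference$delta0 <= 0) stop("reference Delta must be positive", call. = FALSE)
  val <- lack_of_fit(design, reference$true_spec, reference$theta0,
                     reference$rival_spec)$delta0
  100 * val / reference$delta0
}

# polish T/CT weights on a fixed support: BFGS on softmax logits with the
# envelope gradient w_i (psi_i - avg) gets close, then pairwise Frank-Wolfe
# steps (mass transfer from the worst to the best support point with exact
# line search) resolve the kinks of the piecewise-smooth criterion.
# `evalfun(points, w)` must return list(value, psi) with psi the gradient
# of the criterion in the weights.
polish_weights_generic <- function(points, w0, evalfun) {
  n <- length(w0)
  if (n == 1L) return(1)
  towt <- function(z) { w <- exp(z - max(z)); w / sum(w) }
  obj <- function(z) -evalfun(points, towt(z))$value
  grr <- function(z) {
    w <- towt(z)
    e <- evalfun(points, w)
    -(w * (e$psi - sum(w * e$psi)))
  }
  fit <- stats::optim(log(pmax(w0, 1e-12)), obj, grr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-13))
  w <- towt(fit$par)
  for (it in seq_len(400)) {
    e <- evalfun(points, w)
    g <- e$psi
    avg <- sum(w * g)
    pos <- which(w > 1e-11)
    mx <- which.max(g)
    mn <- pos[which.min(g[pos])]
    scale <- max(abs(avg), 1e-12)
    if ((g[mx] - avg) / scale < 1e-8 && (avg - g[mn]) / scale < 1e-8) break
    if (mx == mn) break
    f1 <- function(a) {
      w2 <- w; w2[mx] <- w2[mx] + a; w2[mn] <- w2[mn] - a
      evalfun(points, w2)$value
    }
    opt <- stats::optimize(f1, c(0, w[mn]), maximum = TRUE, tol = 1e-11)
    if (opt$objective <= e$value + 1e-15) {
      # kink at the boundary: try dropping the worst point entirely
      if (f1(w[mn]) > e$value + 1e-15) {
        w[mx] <- w[mx] + w[mn]; w[mn] <- 0
      } else break
    } else {
      w[mx] <- w[mx] + opt$maximum
      w[mn] <- w[mn] - opt$maximum
    }
  }
  w / sum(w)
}

# shared Fedorov-Wynn driver over a candidate grid.
# evalfun(points, w, warm): list(value    = criterion (to maximise),
#                                psi_grid = sensitivity over the full grid,
#                                psi      = sensitivity at support,
#                                warm     = state passed to the next call)
# At the optimum max(psi_grid) equals the weighted average of psi (gap 0).
fedorov_wynn <- function(grid, evalfun, max_iter, tol, refine,
                         init_points = NULL, prune = 1e-5) {
  pts <- grid$points
  if (is.null(init_points)) {
    cor <- expand.grid(xS = range(pts$xS), xI = range(pts$xI))
    mid <- data.frame(xS = stats::median(pts$xS), xI = stats::median(pts$xI))
    init_points <- unique(rbind(cor, mid))
  }
  sup <- init_points
  w <- rep(1 / nrow(sup), nrow(sup))
  warm <- NULL
  key <- function(p) paste(signif(p$xS, 12), signif(p$xI, 12))
  polish_and_gap <- function(sup, w, warm) {
    ev <- function(points, wts) evalfun(points, wts, warm)
    w <- polish_weights_generic(sup, w, function(p, wts) {
      e <- ev(p, wts); list(value = e$value, psi = e$psi)
    })
    e <- evalfun(sup, w, warm)
    avg <- sum(w * e$psi)
    gap <- (max(e$psi_grid) - avg) / max(abs(avg), 1e-12)
    list(w = w, gap = gap, e = e)
  }
  degenerate <- FALSE
  for (k in seq_len(max_iter)) {
    e <- evalfun(sup, w, warm)
    warm <- e$warm
    if (max(e$psi_grid) < 1e-12) { degenerate <- TRUE; break }
    avg <- sum(w * e$psi)
    i <- which.max(e$psi_grid)
    gap <- (e$psi_grid[i] - avg) / max(abs(avg), 1e-12)
    if (gap < tol) break
    if (k %% 50 == 0) {          # periodic exact weight polish + convergence test
      pg <- polish_and_gap(sup, w, warm)
      w <- pg$w; warm <- pg$e$warm
      if (pg$gap < tol) break
      keep <- w > prune
      sup <- sup[keep, , drop = FALSE]; w <- w[keep] / sum(w[keep])
      next
    }
    alpha <- 1 / (k + 1)
    w <- w * (1 - alpha)
    kx <- key(pts[i, ])
    hit <- match(kx, key(sup))
    if (is.na(hit)) {
      sup <- rbind(sup, pts[i, ])
      w <- c(w, alpha)
    } else w[hit] <- w[hit] + alpha
    keep <- w > prune
    sup <- sup[keep, , drop = FALSE]; w <- w[keep] / sum(w[keep])
  }
  if (degenerate)
    return(list(points = sup, weights = w, gap = 0,
                e = list(value = 0, warm = warm)))
  # consolidate support, polish weights exactly, optionally refine coordinates
  ms <- merge_support(sup, w, if (refine)
    sqrt(grid$sub_step^2 + grid$inh_step^2) else 0)
  sup <- ms$points; w <- ms$weights
  pg <- polish_and_gap(sup, w, warm)
  w <- pg$w; warm <- pg$e$warm
  if (refine) {
    n <- nrow(sup)
    p0 <- c(sup$xS, sup$xI, log(pmax(w, 1e-12)))
    lower <- c(rep(grid$substrate[1], n), rep(grid$inhibitor[1], n),
               rep(-30, n))
    upper <- c(rep(grid$substrate[2], n), rep(grid$inhibitor[2], n),
               rep(30, n))
    free <- upper - lower > 1e-12
    build <- function(pf) { p <- p0; p[free] <- pf; p }
    obj <- function(pf) {
      p <- build(pf)
      xs <- pmin(pmax(p[1:n], grid$substrate[1]), grid$substrate[2])
      xi <- pmin(pmax(p[(n + 1):(2 * n)], grid$inhibitor[1]), grid$inhibitor[2])
      z <- p[(2 * n + 1):(3 * n)]
      wts <- exp(z - max(z)); wts <- wts / sum(wts)
      -evalfun(data.frame(xS = xs, xI = xi), wts, warm)$value
    }
    fit <- stats::optim(p0[free], obj, method = "L-BFGS-B",
                        lower = lower[free], upper = upper[free],
                        control = list(maxit = 300))
    p <- build(fit$par)
    sup <- data.frame(xS = p[1:n], xI = p[(n + 1):(2 * n)])
    z <- p[(2 * n + 1):(3 * n)]
    w <- exp(z - max(z)); w <- w / sum(w)
    pg <- polish_and_gap(sup, w, warm)
    w <- pg$w
  }
  keep <- w > prune
  sup <- sup[keep, , drop = FALSE]; w <- w[keep] / sum(w[keep])
  pg <- polish_and_gap(sup, w, warm)
  list(points = sup, weights = pg$w, gap = pg$gap, e = pg$e)
}

#' T-optimal discriminating design (Fedorov-Wynn algorithm)
#'
#' Maximises the lack-of-fit criterion \eqn{\Delta_0(\xi)} over probability
#' measures on the grid by the Fedorov-Wynn vertex-direction algorithm: at
#' iteration `k` the rival model is refitted, mass \eqn{1/(k+1)} is moved to
#' the grid point with the largest squared model separation, and low-weight
#' points are pruned; the final support receives an exact weight
#' optimisation (and, on the standard scale, joint continuous refinement of
#' coordinates and weights).  Convergence is declared when the relative
#' sensitivity gap drops below `tol`.
#'
#' @inheritParams lack_of_fit
#' @param grid a [design_grid()] on the models' scale.
#' @param max_iter maximum Fedorov-Wynn iterations (default 5000).
#' @param tol relative sensitivity-gap tolerance (default 1e-4).
#' @param refine continuous support refinement (default on for standard
#'   scale).
#' @return a converged `kinoed_topt` with attribute `gap`.
#' @export
t_optimal <- function(grid, true_spec, theta0, rival_spec, max_iter = 5000,
                      tol = 1e-4, refine = (grid$scale == "standard")) {
  stopifnot(inherits(grid, "kinoed_grid"), true_spec$scale == rival_spec$scale)
  theta0 <- check_theta(true_spec, theta0)
  pts <- grid$points
  eta0_grid <- eval_rate(true_spec, theta0, pts$xS, pts$xI)
  evalfun <- function(points, w, warm = NULL) {
    eta0 <- eval_rate(true_spec, theta0, points$xS, points$xI)
    fit <- fit_rival(eta0, points, w, rival_spec, NULL,
                     starts = if (is.null(warm)) 10L else 1L, warm = warm)
    eta1_grid <- eval_rate(rival_spec, fit$theta, pts$xS, pts$xI)
    eta1 <- eval_rate(rival_spec, fit$theta, points$xS, points$xI)
    list(value = fit$delta, psi_grid = (eta0_grid - eta1_grid)^2,
         psi = (eta0 - eta1)^2, warm = fit$theta)
  }
  out <- fedorov_wynn(grid, evalfun, max_iter, tol, refine)
  if (out$e$value <= 1e-10)
    stop("models are not separable on this grid: lack-of-fit stays at zero",
         call. = FALSE)
  if (out$gap > tol)
    stop(sprintf("Fedorov-Wynn did not converge: sensitivity gap %.3g", out$gap),
         call. = FALSE)
  res <- lack_of_fit(approx_design(out$points, out$weights), true_spec,
                     theta0, rival_spec, warm = out$e$warm)
  attr(res, "gap") <- out$gap
  res
}

#' Compound-T (CT) optimal discriminating design
#'
#' Maximises the convex log-combination
#' \eqn{(1-\nu)\ln\Delta_0(\xi) + \nu\ln\Delta_1(\xi)} of the two directed
#' T-criteria (model 0 true vs model 1 true), equivalent to maximising the
#' weighted product of T-efficiencies.  `nu = 0` and `nu = 1` reproduce the
#' pure T-optimal designs.  Uses Fedorov-Wynn with the composite
#' sensitivity \eqn{(1-\nu)\psi_0/\Delta_0 + \nu\psi_1/\Delta_1}.
#'
#' @inheritParams t_optimal
#' @param spec0,theta0 model 0 and its nominal values.
#' @param spec1,theta1 model 1 and its nominal values.
#' @param nu weighting coefficient in `[0, 1]`.
#' @return a list of class `kinoed_ct`: `design`, `nu`, `delta0`, `delta1`
#'   and the two rival minimisers.
#' @export
ct_optimal <- function(grid, spec0, theta0, spec1, theta1, nu,
                       max_iter = 5000, tol = 1e-4,
                       refine = (grid$scale == "standard")) {
  stopifnot(nu >= 0, nu <= 1)
  if (nu == 0 || nu == 1) {
    res <- if (nu == 0) t_optimal(grid, spec0, theta0, spec1, max_iter, tol, refine)
           else t_optimal(grid, spec1, theta1, spec0, max_iter, tol, refine)
    other <- lack_of_fit(res$design,
                         if (nu == 0) spec1 else spec0,
                         if (nu == 0) theta1 else theta0,
                         if (nu == 0) spec0 else spec1)
    d0 <- if (nu == 0) res$delta0 else other$delta0
    d1 <- if (nu == 0) other$delta0 else res$delta0
    return(structure(list(design = res$design, nu = nu, delta0 = d0,
                          delta1 = d1,
                          theta1_hat = if (nu == 0) res$theta1_hat else other$theta1_hat,
                          theta0_hat = if (nu == 0) other$theta1_hat else res$theta1_hat,
                          spec0 = spec0, theta0 = check_theta(spec0, theta0),
                          spec1 = spec1, theta1 = check_theta(spec1, theta1)),
                     class = "kinoed_ct"))
  }
  theta0 <- check_theta(spec0, theta0); theta1 <- check_theta(spec1, theta1)
  pts <- grid$points
  e0g <- eval_rate(spec0, theta0, pts$xS, pts$xI)
  e1g <- eval_rate(spec1, theta1, pts$xS, pts$xI)
  evalfun <- function(points, w, warm = NULL) {
    e0 <- eval_rate(spec0, theta0, points$xS, points$xI)
    e1 <- eval_rate(spec1, theta1, points$xS, points$xI)
    st <- if (is.null(warm)) 10L else 1L
    f01 <- fit_rival(e0, points, w, spec1, NULL, st,
                     warm = if (is.null(warm)) NULL else warm$t01)
    f10 <- fit_rival(e1, points, w, spec0, NULL, st,
                     warm = if (is.null(warm)) NULL else warm$t10)
    d0 <- f01$delta; d1 <- f10$delta
    p0 <- (e0 - eval_rate(spec1, f01$theta, points$xS, points$xI))^2
    p1 <- (e1 - eval_rate(spec0, f10$theta, points$xS, points$xI))^2
    p0g <- (e0g - eval_rate(spec1, f01$theta, pts$xS, pts$xI))^2
    p1g <- (e1g - eval_rate(spec0, f10$theta, pts$xS, pts$xI))^2
    list(value = (1 - nu) * log(max(d0, 1e-300)) + nu * log(max(d1, 1e-300)),
         psi_grid = (1 - nu) * p0g / d0 + nu * p1g / d1,
         psi = (1 - nu) * p0 / d0 + nu * p1 / d1,
         warm = list(t01 = f01$theta, t10 = f10$theta),
         delta0 = d0, delta1 = d1,
         theta1_hat = f01$theta, theta0_hat = f10$theta)
  }
  out <- fedorov_wynn(grid, evalfun, max_iter, tol, refine)
  if (out$gap > tol)
    stop(sprintf("Fedorov-Wynn (CT) did not converge: sensitivity gap %.3g",
                 out$gap), call. = FALSE)
  structure(list(design = approx_design(out$points, out$weights), nu = nu,
                 delta0 = out$e$delta0, delta1 = out$e$delta1,
                 theta1_hat = out$e$theta1_hat, theta0_hat = out$e$theta0_hat,
                 spec0 = spec0, theta0 = theta0, spec1 = spec1,
                 theta1 = theta1),
            class = "kinoed_ct")
}

#' @export
print.kinoed_ct <- function(x, ...) {
  cat(sprintf("CT-optimal design (nu = %g): %s vs %s (%s scale)\n", x$nu,
              x$spec0$model, x$spec1$model, x$spec0$scale))
  print(x$design)
  cat(sprintf("Delta0 = %.6g, Delta1 = %.6g\n", x$delta0, x$delta1))
  invisible(x)
}
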