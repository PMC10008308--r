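#' Fisher information matrix of a design
#'
#' For an approximate design \eqn{\xi} with support \eqn{x_i} and weights
#' \eqn{\omega_i}, the (normalised) Fisher information of the nonlinear
#' regression at nominal parameters \eqn{\theta} is
#' \eqn{M(\xi,\theta) = \sum_i \omega_i f(x_i) f(x_i)^T}, where \eqn{f} is
#' the parameter gradient of the (possibly log) mean response.  On the log
#' scale \eqn{f} is the standard-scale gradient divided by the rate, which
#' is how the multiplicative error structure reshapes the information.
#'
#' @param design a `kinoed_design` (or `kinoed_exact`, using weights
#'   `n_i / N`).
#' @param spec a [model_spec()].
#' @param theta nominal parameter values.
#' @return an `m x m` symmetric positive semi-definite matrix.
#' @export
fim <- function(design, spec, theta) {
  design <- as_approx(design)
  f <- gradient(spec, theta, design$points$xS, design$points$xI)
  crossprod(f * sqrt(design$weights))
}

#' D- and Ds-criterion values
#'
#' `d_criterion` is the determinant of the information matrix.
#' `ds_criterion` is the criterion for estimating the parameter subset
#' `subset` with the remaining parameters as nuisance:
#' \eqn{\Phi_{Ds} = \det M / \det M_{22}} where \eqn{M_{22}} is the
#' nuisance-parameter block (equivalently the determinant of the Schur
#' complement of \eqn{M_{22}} in \eqn{M}).
#'
#' @param M information matrix.
#' @param subset integer indices of the parameters of interest.
#' @return criterion value; 0 when singular (with attribute
#'   `singular = TRUE`; for `ds_criterion` a singular nuisance block gives
#'   `NA` with the same attribute).
#' @export
d_criterion <- function(M) {
  d <- det(M)
  if (!is.finite(d) || d <= .Machine$double.eps^2 * max(1, max(abs(M)))^nrow(M))
    return(structure(max(d, 0), singular = d <= 0))
  d
}

#' @rdname d_criterion
#' @export
ds_criterion <- function(M, subset) {
  m <- nrow(M)
  subset <- as.integer(subset)
  stopifnot(all(subset %in% seq_len(m)))
  nuis <- setdiff(seq_len(m), subset)
  if (!length(nuis)) return(d_criterion(M))
  d22 <- det(M[nuis, nuis, drop = FALSE])
  if (!is.finite(d22) || d22 <= 0)
    return(structure(NA_real_, singular = TRUE))
  det(M) / d22
}

#' Design efficiencies
#'
#' `d_efficiency` compares a design to a reference optimum in a given model:
#' \eqn{(\det M(\xi) / \det M(\xi^*))^{1/m}}, reported in percent, so the
#' optimum scores 100 and a singular design 0.  `ds_efficiency` uses the
#' Ds-criterion with exponent `1/s`.
#'
#' @param design design under evaluation.
#' @param reference the optimal design for (`spec`, `theta`).
#' @param spec,theta the reference model and nominal values in which both
#'   designs are assessed.
#' @param subset parameter-of-interest indices (Ds only).
#' @return efficiency in percent; singular designs give 0 with attribute
#'   `singular = TRUE`.
#' @export
d_efficiency <- function(design, reference, spec, theta) {
  num <- d_criterion(fim(design, spec, theta))
  den <- d_criterion(fim(reference, spec, theta))
  if (den <= 0) stop("reference design is singular", call. = FALSE)
  if (isTRUE(attr(num, "singular")) || num <= 0)
    return(structure(0, singular = TRUE))
  100 * (as.numeric(num) / as.numeric(den))^(1 / spec$m)
}

#' @rdname d_efficiency
#' @export
ds_efficiency <- function(design, reference, spec, theta, subset) {
  num <- ds_criterion(fim(design, spec, theta), subset)
  den <- ds_criterion(fim(reference, spec, theta), subset)
  if (!is.finite(den) || den <= 0) stop("reference design is singular", call. = FALSE)
  if (is.na(num) || isTRUE(attr(num, "singular")) || num <= 0)
    return(structure(0, singular = TRUE))
  100 * (as.numeric(num) / as.numeric(den))^(1 / length(subset))
}

# sensitivity values psi(x) at arbitrary points for the D (subset = NULL)
# or Ds criterion; psi averages to m (resp. s) under the design measure.
psi_values <- function(Fx, M, subset = NULL) {
  p <- rowSums((Fx %*% solve(M)) * Fx)
  if (!is.null(subset)) {
    nuis <- setdiff(seq_len(ncol(Fx)), subset)
    if (length(nuis)) {
      F2 <- Fx[, nuis, drop = FALSE]
      p <- p - rowSums((F2 %*% solve(M[nuis, nuis, drop = FALSE])) * F2)
    }
  }
  p
}

#' Sensitivity function of the D-criterion
#'
#' \eqn{\psi(x) = f(x)^T M(\xi)^{-1} f(x)}.  The general equivalence
#' theorem states that \eqn{\xi} is D-optimal iff \eqn{\psi \le m}
#' everywhere on the design region, with equality on the support.
#'
#' @inheritParams fim
#' @param xS,xI evaluation points.
#' @param subset if non-`NULL`, the Ds sensitivity (bound `s = length(subset)`).
#' @return numeric vector of sensitivity values.
#' @export
sensitivity_d <- function(design, spec, theta, xS, xI = 0, subset = NULL) {
  M <- fim(design, spec, theta)
  Fx <- gradient(spec, theta, xS, xI)
  psi_values(Fx, M, subset)
}

#' Equivalence-theorem check for D/Ds-optimality
#'
#' Evaluates the sensitivity function over the candidate grid (plus the
#' design's own support) and compares its maximum with the theoretical
#' bound (`m` for D, `s` for Ds).
#'
#' @inheritParams sensitivity_d
#' @param grid a [design_grid()].
#' @param tol relative tolerance on the bound.
#' @return list with `pass`, `max_psi`, `bound`, `gap` (relative) and the
#'   arg-max point.
#' @export
equivalence_check <- function(design, grid, spec, theta, subset = NULL,
                              tol = 1e-4) {
  design <- as_approx(design)
  M <- fim(design, spec, theta)
  bound <- if (is.null(subset)) spec$m else length(subset)
  pts <- rbind(grid$points, design$points)
  psi <- psi_values(gradient(spec, theta, pts$xS, pts$xI), M, subset)
  i <- which.max(psi)
  gap <- (psi[i] - bound) / bound
  list(pass = gap <= tol, max_psi = psi[i], bound = bound, gap = gap,
       argmax = pts[i, ])
}

# ---- optimisation engine ---------------------------------------------------

# single-linkage clustering of support points with a distance threshold;
# returns cluster id per point (used to merge grid-adjacent support before
# continuous refinement)
cluster_support <- function(points, radius) {
  n <- nrow(points)
  if (n == 1L) return(1L)
  d <- stats::dist(points)
  stats::cutree(stats::hclust(d, method = "single"), h = radius * 1.01)
}

merge_support <- function(points, weights, radius) {
  cl <- cluster_support(points, radius)
  idx <- split(seq_len(nrow(points)), cl)
  agg <- lapply(idx, function(i) {
    if (length(i) == 1L)
      c(points$xS[i], points$xI[i], weights[i])
    else
      c(sum(weights[i] * points$xS[i]) / sum(weights[i]),
        sum(weights[i] * points$xI[i]) / sum(weights[i]),
        sum(weights[i]))
  })
  m <- do.call(rbind, agg)
  list(points = data.frame(xS = m[, 1], xI = m[, 2]), weights = m[, 3])
}

info_logcrit <- function(Fa, w, subset) {
  M <- crossprod(Fa * sqrt(w))
  ld <- determinant(M, logarithm = TRUE)
  if (ld$sign <= 0) return(-Inf)
  out <- as.numeric(ld$modulus)
  if (!is.null(subset)) {
    nuis <- setdiff(seq_len(ncol(Fa)), subset)
    if (length(nuis)) {
      ld2 <- determinant(M[nuis, nuis, drop = FALSE], logarithm = TRUE)
      if (ld2$sign <= 0) return(-Inf)
      out <- out - as.numeric(ld2$modulus)
    }
  }
  out
}

# optimal weights on a fixed support: maximise the log criterion over the
# probability simplex via a softmax parameterisation with the analytic
# gradient w_i (psi_i - bound)
polish_weights <- function(Fa, w0, subset) {
  n <- nrow(Fa)
  if (n == 1L) return(1)
  bound <- if (is.null(subset)) ncol(Fa) else length(subset)
  obj <- function(z) {
    w <- exp(z - max(z)); w <- w / sum(w)
    -info_logcrit(Fa, w, subset)
  }
  grr <- function(z) {
    w <- exp(z - max(z)); w <- w / sum(w)
    M <- crossprod(Fa * sqrt(w))
    psi <- tryCatch(psi_values(Fa, M, subset), error = function(e) rep(bound, n))
    -(w * (psi - bound))
  }
  z0 <- log(pmax(w0, 1e-12))
  fit <- stats::optim(z0, obj, grr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  w <- exp(fit$par - max(fit$par))
  w / sum(w)
}

# joint continuous refinement of support coordinates and weights inside the
# design rectangle (used on the standard scale, where optimal support is
# interior and a grid only localises it)
refine_support <- function(points, weights, spec, theta, grid, subset) {
  n <- nrow(points)
  p0 <- c(points$xS, points$xI, log(pmax(weights, 1e-12)))
  lower <- c(rep(grid$substrate[1], n), rep(grid$inhibitor[1], n), rep(-30, n))
  upper <- c(rep(grid$substrate[2], n), rep(grid$inhibitor[2], n), rep(30, n))
  free <- upper - lower > 1e-12      # pinned coordinates stay fixed
  build <- function(pf) { p <- p0; p[free] <- pf; p }
  obj <- function(pf) {
    p <- build(pf)
    xs <- pmin(pmax(p[1:n], grid$substrate[1]), grid$substrate[2])
    xi <- pmin(pmax(p[(n + 1):(2 * n)], grid$inhibitor[1]), grid$inhibitor[2])
    z <- p[(2 * n + 1):(3 * n)]
    w <- exp(z - max(z)); w <- w / sum(w)
    Fa <- gradient(spec, theta, xs, xi)
    v <- info_logcrit(Fa, w, subset)
    if (!is.finite(v)) 1e10 else -v
  }
  fit <- stats::optim(p0[free], obj, method = "L-BFGS-B",
                      lower = lower[free], upper = upper[free],
                      control = list(maxit = 400))
  p <- build(fit$par)
  xs <- p[1:n]; xi <- p[(n + 1):(2 * n)]
  z <- p[(2 * n + 1):(3 * n)]
  w <- exp(z - max(z)); w <- w / sum(w)
  list(points = data.frame(xS = xs, xI = xi), weights = w)
}

optimize_info <- function(grid, spec, theta, subset = NULL, max_iter = 5000,
                          tol = 1e-4, refine = (grid$scale == "standard"),
                          prune = 1e-6) {
  stopifnot(inherits(grid, "kinoed_grid"))
  theta <- check_theta(spec, theta)
  if (!is.null(subset)) {
    subset <- as.integer(subset)
    if (length(setdiff(seq_len(spec$m), subset)) == 0L) subset <- NULL
  }
  bound <- if (is.null(subset)) spec$m else length(subset)
  pts <- grid$points
  Fg <- gradient(spec, theta, pts$xS, pts$xI)
  nG <- nrow(Fg)
  active <- seq_len(nG)
  w <- rep(1 / nG, nG)
  gap <- Inf
  for (k in seq_len(max_iter)) {
    Fa <- Fg[active, , drop = FALSE]
    M <- crossprod(Fa * sqrt(w))
    psi <- psi_values(Fa, M, subset)
    w <- w * psi / bound
    w <- pmax(w, 0); w <- w / sum(w)
    if (k %% 100 == 0 || k == max_iter) {
      keep <- w > 1e-9
      active <- active[keep]; w <- w[keep] / sum(w[keep])
      Fa <- Fg[active, , drop = FALSE]
      M <- crossprod(Fa * sqrt(w))
      psi_all <- psi_values(Fg, M, subset)
      i <- which.max(psi_all)
      gap <- (psi_all[i] - bound) / bound
      if (gap < 1e-3) break
      if (!(i %in% active)) {            # vertex step: admit the violator
        active <- c(active, i)
        w <- c(w * (1 - 1e-3), 1e-3)
      }
    }
  }
  keep <- w > prune / 10
  radius <- if (refine) sqrt(grid$sub_step^2 + grid$inh_step^2) else 0
  sup <- merge_support(pts[active[keep], , drop = FALSE], w[keep], radius)
  for (round in 1:6) {
    Fa <- gradient(spec, theta, sup$points$xS, sup$points$xI)
    sup$weights <- polish_weights(Fa, sup$weights, subset)
    # weights this small cannot belong to the optimum here; softmax descent
    # stalls before driving them fully to zero, so cut them (the
    # equivalence check below re-admits any genuinely needed point)
    drop <- sup$weights < max(prune, 1e-4)
    if (any(drop)) {
      sup$points <- sup$points[!drop, , drop = FALSE]
      sup$weights <- sup$weights[!drop] / sum(sup$weights[!drop])
    }
    if (refine) {
      sup <- refine_support(sup$points, sup$weights, spec, theta, grid, subset)
      Fa <- gradient(spec, theta, sup$points$xS, sup$points$xI)
      sup$weights <- polish_weights(Fa, sup$weights, subset)
    }
    des <- approx_design(sup$points, sup$weights)
    chk <- equivalence_check(des, grid, spec, theta, subset, tol)
    if (chk$pass) {
      attr(des, "equivalence") <- chk
      attr(des, "criterion") <- if (is.null(subset))
        d_criterion(fim(des, spec, theta))
      else ds_criterion(fim(des, spec, theta), subset)
      return(des)
    }
    # admit the worst uncovered point and re-polish
    sup$points <- rbind(sup$points, chk$argmax[, c("xS", "xI")])
    sup$weights <- c(sup$weights * (1 - 0.05), 0.05)
    sup <- merge_support(sup$points, sup$weights, radius / 2)
  }
  stop(sprintf("design optimisation did not certify: sensitivity gap %.3g above bound %d",
               chk$gap, bound), call. = FALSE)
}

#' Locally D-optimal approximate design
#'
#' Maximises the determinant of the Fisher information over probability
#' measures on the candidate grid using the multiplicative weight algorithm
#' with periodic vertex (violator-admission) steps, merges grid-adjacent
#' support, optimises the weights exactly on the final support and -- on the
#' standard scale, where optimal support is interior -- jointly refines
#' support coordinates and weights by constrained continuous optimisation.
#' The result is certified by the equivalence theorem (sensitivity bounded
#' by `m` over the grid); failure to certify is an error.
#'
#' @inheritParams equivalence_check
#' @param max_iter maximum multiplicative iterations.
#' @param tol relative equivalence-theorem tolerance for certification.
#' @param refine logical: continuous refinement of support coordinates
#'   (default on for standard-scale grids).
#' @return a certified `kinoed_design` with attributes `criterion` and
#'   `equivalence`.
#' @export
optimize_d <- function(grid, spec, theta, max_iter = 5000, tol = 1e-4,
                       refine = (grid$scale == "standard")) {
  optimize_info(grid, spec, theta, subset = NULL, max_iter = max_iter,
                tol = tol, refine = refine)
}

#' Locally Ds-optimal approximate design
#'
#' As [optimize_d()] but for precise estimation of a parameter subset
#' (typically the mixing parameter `lambda` of the encompassing model,
#' `subset = 4`), maximising \eqn{\det M / \det M_{22}} with the remaining
#' parameters as nuisance, certified against the bound `s`.
#'
#' @inheritParams optimize_d
#' @param subset indices of the parameters of interest.
#' @export
optimize_ds <- function(grid, spec, theta, subset, max_iter = 5000,
                        tol = 1e-4, refine = (grid$scale == "standard")) {
  optimize_info(grid, spec, theta, subset = subset, max_iter = max_iter,
                tol = tol, refine = refine)
}
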