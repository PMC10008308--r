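#' Flexible nominal box for the delta-criterion
#'
#' The delta discrimination criterion restricts each model's parameters to a
#' box around its nominal estimate, \eqn{[\hat\theta_v \pm r \hat\sigma_v]}
#' per coordinate, where `r >= 0` tunes the box size.  Negative lower
#' bounds (which violate parameter positivity for large `r`) are handled by
#' two alternatives: `"a"` clips the lower bound at zero; `"b"` clips at
#' zero and adds the clipped amount to the upper bound (shifting it up).
#'
#' @param theta_hat nominal parameter estimates (box centre).
#' @param se their standard errors.
#' @param r non-negative tuning multiplier.
#' @param alternative `"a"` (clip at zero, default) or `"b"` (clip and
#'   shift the upper bound).
#' @return a list of class `kinoed_box`: `center`, `lower`, `upper`, `r`,
#'   `alternative`.
#' @examples
#' nominal_box(c(6.0645, 3.2799, 3.3153), c(0.9260, 0.7288, 0.6041), r = 2)
#' @export
nominal_box <- function(theta_hat, se, r, alternative = c("a", "b")) {
  alternative <- match.arg(alternative)
  stopifnot(r >= 0, all(se > 0), length(theta_hat) == length(se))
  lower <- theta_hat - r * se
  upper <- theta_hat + r * se
  deficit <- pmax(0, -lower)
  lower <- pmax(lower, 0)
  if (alternative == "b") upper <- upper + deficit
  structure(list(center = theta_hat, lower = lower, upper = upper,
                 r = r, alternative = alternative),
            class = "kinoed_box")
}

# box-constrained linear least squares: minimise ||b - A theta||^2 subject
# to lo <= theta <= up.  Convex quadratic with a unique box projection
# solution; solved by projected quasi-Newton (L-BFGS-B) with the analytic
# gradient.
bvls_solve <- function(A, b, lo, up) {
  if (all(up - lo < 1e-12)) {
    th <- (lo + up) / 2
    return(list(theta = th, value = sum((b - A %*% th)^2)))
  }
  start <- (lo + up) / 2
  fn <- function(th) sum((b - A %*% th)^2)
  gr <- function(th) as.numeric(-2 * crossprod(A, b - A %*% th))
  fit <- stats::optim(start, fn, gr, method = "L-BFGS-B", lower = lo,
                      upper = up,
                      control = list(maxit = 500, factr = 10))
  list(theta = fit$par, value = fit$value)
}

# linearisation of a model at its box centre over the (expanded) design
# points: response ~ F theta + a with a = eta(center) - F center
linearize_at <- function(spec, box, points) {
  Fm <- gradient(spec, box$center, points$xS, points$xI)
  eta <- eval_rate(spec, box$center, points$xS, points$xI)
  list(F = Fm, a = eta - as.numeric(Fm %*% box$center))
}

#' Linearised distance between two models on an exact design
#'
#' The delta-criterion value: both models are linearised at their nominal
#' centres, and the criterion is the minimal Euclidean distance between the
#' two linear expectation surfaces with each parameter vector restricted to
#' its flexible nominal box,
#' \deqn{\delta^2(D) = \min_{\theta_0, \theta_1}
#'   \| (a_0 - a_1) - [-F_0, F_1] (\theta_0^T, \theta_1^T)^T \|^2,}
#' a box-constrained linear least-squares problem.  A symmetric
#' discrimination criterion: no model is assumed true.
#'
#' @param design a `kinoed_exact` (replicated points enter the distance
#'   once per run) or `kinoed_design`.
#' @param spec0,spec1 the two rival models (same scale).
#' @param box0,box1 their [nominal_box()]es.
#' @return the distance `delta` (not squared), with attribute `theta` (the
#'   minimising compound parameter vector).
#' @export
delta_value <- function(design, spec0, spec1, box0, box1) {
  pts <- if (inherits(design, "kinoed_exact")) expand_exact(design)
         else design$points
  l0 <- linearize_at(spec0, box0, pts)
  l1 <- linearize_at(spec1, box1, pts)
  A <- cbind(-l0$F, l1$F)
  b <- l0$a - l1$a
  sol <- bvls_solve(A, b, c(box0$lower, box1$lower),
                    c(box0$upper, box1$upper))
  structure(sqrt(max(sol$value, 0)), theta = sol$theta)
}

#' Delta-optimal exact design by KL-exchange
#'
#' Searches for the `N`-run exact design maximising the linearised distance
#' criterion over a candidate grid by the standard exchange heuristic:
#' starting from a uniformly random sample of `N` grid points (with
#' replacement), each design slot in turn is given its best improving
#' exchange against all grid candidates, and passes repeat until no
#' exchange improves the criterion.  Deterministic given `seed`.
#'
#' @param N number of runs.
#' @param grid a [design_grid()].
#' @inheritParams delta_value
#' @param seed integer seed for the random start (required).
#' @return a `kinoed_exact` with attribute `delta`.
#' @export
delta_optimal <- function(N, grid, spec0, spec1, box0, box1, seed) {
  stopifnot(N >= 1, inherits(grid, "kinoed_grid"))
  pts <- grid$points
  nG <- nrow(pts)
  # cache per-candidate linearisation rows
  l0 <- linearize_at(spec0, box0, pts)
  l1 <- linearize_at(spec1, box1, pts)
  Arows <- cbind(-l0$F, l1$F)
  brow <- l0$a - l1$a
  lo <- c(box0$lower, box1$lower); up <- c(box0$upper, box1$upper)
  dval <- function(idx) bvls_solve(Arows[idx, , drop = FALSE], brow[idx],
                                   lo, up)$value
  idx <- with_seed(seed, sample.int(nG, N, replace = TRUE))
  cur <- dval(idx)
  repeat {
    improved <- FALSE
    for (slot in seq_len(N)) {
      old <- idx[slot]
      best_v <- cur; best_g <- old
      for (g in seq_len(nG)) {
        if (g == old) next
        idx[slot] <- g
        v <- dval(idx)
        if (v > best_v + 1e-12) { best_v <- v; best_g <- g }
      }
      idx[slot] <- best_g
      if (best_g != old) { cur <- best_v; improved <- TRUE }
    }
    if (!improved) break
  }
  tab <- table(idx)
  sel <- as.integer(names(tab))
  out <- exact_design(pts[sel, , drop = FALSE], as.integer(tab))
  attr(out, "delta") <- sqrt(max(cur, 0))
  out
}
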