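#' Design grids over the substrate-inhibitor rectangle
#'
#' Candidate grids for the design algorithms on the rectangle
#' `[0, 30] x [0, 60]`.  On the log scale the substrate axis starts at the
#' zero floor (default 0.02, matching the zero-replacement value) because
#' the log response is undefined at zero substrate; the default log grid is
#' the 31 x 61 lattice `{0.02, 1, 2, ..., 30} x {0, 1, ..., 60}`.  On the
#' standard scale the default is a fine step (0.1 for estimation designs)
#' from which support points are later refined continuously.
#'
#' @param scale `"standard"` or `"log"`.
#' @param substrate,inhibitor range of each axis.
#' @param sub_step,inh_step grid steps on the standard scale.
#' @param zero_floor substrate lower bound used on the log scale.
#' @return object of class `kinoed_grid`: data frame `points` (`xS`, `xI`),
#'   the axis ranges, steps and scale.
#' @export
design_grid <- function(scale = c("standard", "log"),
                        substrate = c(0, 30), inhibitor = c(0, 60),
                        sub_step = 0.1, inh_step = 0.1, zero_floor = 0.02) {
  scale <- match.arg(scale)
  stopifnot(substrate[1] < substrate[2], inhibitor[1] <= inhibitor[2])
  if (scale == "log") {
    lo <- max(substrate[1], zero_floor)
    xs <- unique(c(lo, seq(ceiling(lo), substrate[2], by = 1)))
    xi <- if (inhibitor[1] == inhibitor[2]) inhibitor[1] else
      seq(inhibitor[1], inhibitor[2], by = 1)
    sub_step <- 1; inh_step <- 1
  } else {
    xs <- seq(substrate[1], substrate[2], by = sub_step)
    xi <- if (inhibitor[1] == inhibitor[2]) inhibitor[1] else
      seq(inhibitor[1], inhibitor[2], by = inh_step)
    lo <- substrate[1]
  }
  pts <- expand.grid(xS = xs, xI = xi)
  structure(list(points = pts, substrate = c(lo, substrate[2]),
                 inhibitor = inhibitor, sub_step = sub_step,
                 inh_step = inh_step, scale = scale),
            class = "kinoed_grid")
}

#' Approximate and exact designs
#'
#' An approximate design is a probability measure on design points: a set of
#' distinct `(xS, xI)` support points with positive weights summing to one.
#' An exact design allocates an integer number of replicates to each support
#' point, summing to the run size `N`.
#'
#' @param points data frame with columns `xS`, `xI` (or a two-column matrix).
#' @param weights non-negative weights, summed to 1 after dropping
#'   zero-weight points.
#' @return `approx_design` returns a `kinoed_design`; `exact_design` a
#'   `kinoed_exact`.
#' @export
approx_design <- function(points, weights) {
  points <- as.data.frame(points)
  names(points)[1:2] <- c("xS", "xI")
  weights <- as.numeric(weights)
  stopifnot(nrow(points) == length(weights), all(weights >= -1e-12))
  keep <- weights > 0
  points <- points[keep, , drop = FALSE]
  weights <- weights[keep]
  if (abs(sum(weights) - 1) > 1e-9) weights <- weights / sum(weights)
  if (anyDuplicated(points)) stop("support points must be distinct", call. = FALSE)
  o <- order(points$xS, points$xI)
  structure(list(points = points[o, , drop = FALSE], weights = weights[o]),
            class = "kinoed_design")
}

#' @rdname approx_design
#' @param replicates positive integer replication counts.
#' @export
exact_design <- function(points, replicates) {
  points <- as.data.frame(points)
  names(points)[1:2] <- c("xS", "xI")
  replicates <- as.integer(replicates)
  stopifnot(nrow(points) == length(replicates), all(replicates >= 1))
  o <- order(points$xS, points$xI)
  structure(list(points = points[o, , drop = FALSE],
                 replicates = replicates[o], N = sum(replicates)),
            class = "kinoed_exact")
}

#' @export
print.kinoed_design <- function(x, ...) {
  cat("Approximate design (", nrow(x$points), " support points)\n", sep = "")
  print(cbind(round(x$points, 4), weight = round(x$weights, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @export
print.kinoed_exact <- function(x, ...) {
  cat("Exact design, N = ", x$N, "\n", sep = "")
  print(cbind(round(x$points, 4), replicates = x$replicates),
        row.names = FALSE)
  invisible(x)
}

#' Round an approximate design to an exact design of size N
#'
#' Largest-remainder apportionment: each support point first receives
#' `floor(N * w_i)` replicates and the remaining runs go to the points with
#' the largest fractional parts (ties broken lexicographically by
#' `(xS, xI)`).  Every allocation satisfies the quota bound
#' `|n_i - N w_i| <= 1`; points receiving zero replicates are dropped, so a
#' very low-weight point may vanish at small `N`.
#'
#' @param design a `kinoed_design`.
#' @param N total number of runs (>= 1).
#' @return a `kinoed_exact`.
#' @export
round_design <- function(design, N) {
  stopifnot(inherits(design, "kinoed_design"))
  N <- as.integer(N)
  if (is.na(N) || N < 1) stop("N must be a positive integer", call. = FALSE)
  quota <- N * design$weights
  n <- floor(quota)
  rem <- quota - n
  short <- N - sum(n)
  if (short > 0) {
    o <- order(-rem, design$points$xS, design$points$xI)
    n[o[seq_len(short)]] <- n[o[seq_len(short)]] + 1
  }
  keep <- n > 0
  exact_design(design$points[keep, , drop = FALSE], n[keep])
}

# expand an exact design into one row per run
expand_exact <- function(design) {
  idx <- rep(seq_len(nrow(design$points)), design$replicates)
  design$points[idx, , drop = FALSE]
}

# exact design as an approximate one (weights n_i / N)
as_approx <- function(design) {
  if (inherits(design, "kinoed_design")) return(design)
  approx_design(design$points, design$replicates / design$N)
}

#' Serialise designs
#'
#' Writes a design as CSV (columns `xS`, `xI` and `weight` or `replicates`).
#'
#' @param design a `kinoed_design` or `kinoed_exact`.
#' @param path output path.
#' @export
write_design_csv <- function(design, path) {
  df <- if (inherits(design, "kinoed_exact"))
    cbind(design$points, replicates = design$replicates)
  else cbind(design$points, weight = design$weights)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
write_design_json <- function(design, path) {
  obj <- if (inherits(design, "kinoed_exact"))
    list(type = "exact", points = design$points,
         replicates = design$replicates, N = design$N)
  else list(type = "approximate", points = design$points,
            weights = design$weights)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
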