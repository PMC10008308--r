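log_boxes <- function(r, alternative = "a") {
  nomC <- nominal_estimates("competitive", "log")
  nomN <- nominal_estimates("noncompetitive", "log")
  list(box0 = nominal_box(nomC$theta, nomC$se, r, alternative),
       box1 = nominal_box(nomN$theta, nomN$se, r, alternative))
}

test_that("nominal boxes implement both clipping alternatives", {
  # theta_M of the competitive log fit: 3.2799 (se 0.7288); r = 5 makes the
  # lower bound negative
  ba <- nominal_box(3.2799, 0.7288, r = 5, alternative = "a")
  expect_equal(ba$lower, 0)
  expect_equal(ba$upper, 6.9239)
  bb <- nominal_box(3.2799, 0.7288, r = 5, alternative = "b")
  expect_equal(bb$lower, 0)
  expect_equal(bb$upper, 6.9239 + (5 * 0.7288 - 3.2799))
  # r = 0 degenerates to the point estimate
  b0 <- nominal_box(c(2, 3), c(1, 1), r = 0)
  expect_equal(b0$lower, b0$upper)
  expect_equal(b0$lower, c(2, 3))
  # within-positivity boxes are unaffected by the alternative
  b1a <- nominal_box(c(2, 3), c(0.5, 0.5), 2, "a")
  b1b <- nominal_box(c(2, 3), c(0.5, 0.5), 2, "b")
  expect_equal(b1a$upper, b1b$upper)
})

test_that("identical models with identical boxes are at distance zero", {
  sC <- model_spec("competitive", "log")
  nomC <- nominal_estimates("competitive", "log")
  b <- nominal_box(nomC$theta, nomC$se, 1)
  des <- exact_design(data.frame(xS = c(1, 10, 30), xI = c(0, 20, 60)),
                      c(1, 1, 1))
  expect_lt(delta_value(des, sC, sC, b, b), 1e-8)
})

test_that("the distance is non-increasing in the box multiplier r", {
  sC <- model_spec("competitive", "log")
  sN <- model_spec("noncompetitive", "log")
  des <- exact_design(data.frame(xS = c(0.02, 30, 30), xI = c(0, 0, 60)),
                      c(2, 2, 2))
  vals <- vapply(c(0, 1, 2, 3, 4, 5), function(r) {
    b <- log_boxes(r)
    as.numeric(delta_value(des, sC, sN, b$box0, b$box1))
  }, 0)
  expect_true(all(diff(vals) <= 1e-9))
  # r = 0 reduces to the fixed-nominal linearised distance
  b0 <- log_boxes(0)
  l0 <- delta_value(des, sC, sN, b0$box0, b0$box1)
  e0 <- eval_rate(sC, nominal_estimates("competitive", "log")$theta,
                  c(0.02, 0.02, 30, 30, 30, 30), c(0, 0, 0, 0, 60, 60))
  e1 <- eval_rate(sN, nominal_estimates("noncompetitive", "log")$theta,
                  c(0.02, 0.02, 30, 30, 30, 30), c(0, 0, 0, 0, 60, 60))
  expect_equal(as.numeric(l0), sqrt(sum((e0 - e1)^2)), tolerance = 1e-10)
})

test_that("the box-constrained solver agrees with a brute-force oracle", {
  sC <- model_spec("competitive", "log")
  sN <- model_spec("noncompetitive", "log")
  b <- log_boxes(1)
  des <- exact_design(data.frame(xS = c(0.5, 8, 30), xI = c(0, 15, 60)),
                      c(1, 1, 1))
  d <- delta_value(des, sC, sN, b$box0, b$box1)
  # oracle: coarse 6-D grid over both boxes, then projected coordinate
  # descent (no quasi-Newton involved)
  pts <- data.frame(xS = c(0.5, 8, 30), xI = c(0, 15, 60))
  F0 <- gradient(sC, b$box0$center, pts$xS, pts$xI)
  F1 <- gradient(sN, b$box1$center, pts$xS, pts$xI)
  a0 <- eval_rate(sC, b$box0$center, pts$xS, pts$xI) - F0 %*% b$box0$center
  a1 <- eval_rate(sN, b$box1$center, pts$xS, pts$xI) - F1 %*% b$box1$center
  A <- cbind(-F0, F1); bb <- as.numeric(a0 - a1)
  lo <- c(b$box0$lower, b$box1$lower); up <- c(b$box0$upper, b$box1$upper)
  f <- function(th) sum((bb - A %*% th)^2)
  gr_axes <- lapply(1:6, function(j) seq(lo[j], up[j], length.out = 7))
  gridth <- as.matrix(expand.grid(gr_axes))
  vals <- rowSums((matrix(bb, nrow(gridth), 3, byrow = TRUE) -
                     gridth %*% t(A))^2)
  th <- gridth[which.min(vals), ]
  for (sweep in 1:400) {
    for (j in 1:6) {
      # exact univariate minimiser, clipped to the box
      r_j <- bb - A[, -j, drop = FALSE] %*% th[-j]
      tj <- sum(A[, j] * r_j) / sum(A[, j]^2)
      th[j] <- min(max(tj, lo[j]), up[j])
    }
  }
  expect_equal(as.numeric(d)^2, f(th), tolerance = 1e-4)
})

test_that("the exchange search matches exhaustive enumeration on a tiny instance", {
  sC <- model_spec("competitive", "log")
  sN <- model_spec("noncompetitive", "log")
  b <- log_boxes(2)
  cand <- data.frame(xS = c(0.02, 2, 12, 30), xI = c(0, 50, 5, 60))
  grid <- structure(list(points = cand, substrate = c(0.02, 30),
                         inhibitor = c(0, 60), sub_step = 1, inh_step = 1,
                         scale = "log"), class = "kinoed_grid")
  out <- delta_optimal(3, grid, sC, sN, b$box0, b$box1, seed = 11)
  # enumerate all 20 multisets of size 3 from 4 candidates
  best <- -Inf
  combos <- t(combn(6, 3)) - 1L     # stars-and-bars over 4 bins
  for (i in seq_len(nrow(combos))) {
    stars <- combos[i, ] - 0:2
    counts <- tabulate(c(stars + 1L), nbins = 4L)
    idx <- rep(1:4, counts)
    des <- exact_design(cand[unique(idx), , drop = FALSE],
                        as.integer(table(idx)))
    best <- max(best, as.numeric(delta_value(des, sC, sN, b$box0, b$box1)))
  }
  expect_equal(as.numeric(attr(out, "delta")), best, tolerance = 1e-8)
  # ascent property: the result beats its own random start
  start <- with(list(), {
    set.seed(11); sample.int(4, 3, replace = TRUE)
  })
  sdes <- exact_design(cand[unique(start), , drop = FALSE],
                       as.integer(table(start)))
  expect_gte(attr(out, "delta") + 1e-12,
             as.numeric(delta_value(sdes, sC, sN, b$box0, b$box1)))
  # determinism
  out2 <- delta_optimal(3, grid, sC, sN, b$box0, b$box1, seed = 11)
  expect_identical(out$points, out2$points)
  expect_identical(out$replicates, out2$replicates)
})
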