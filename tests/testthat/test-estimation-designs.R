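test_that("the information matrix is the weighted gradient outer-product sum", {
  spec <- model_spec("encompassing", "log")
  th <- nominal_estimates("encompassing", "log")$theta
  des <- approx_design(log_corners(), rep(0.25, 4))
  M <- fim(des, spec, th)
  # element-by-element brute-force sum
  Mb <- matrix(0, 4, 4)
  for (i in 1:4) {
    f <- as.numeric(gradient(spec, th, des$points$xS[i], des$points$xI[i]))
    Mb <- Mb + des$weights[i] * (f %o% f)
  }
  expect_equal(unname(M), Mb, tolerance = 1e-12)
  expect_equal(M, t(M))
  expect_true(all(eigen(M, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  # a one-point design is rank one
  M1 <- fim(approx_design(log_corners()[4, ], 1), spec, th)
  d1 <- d_criterion(M1)
  expect_equal(as.numeric(d1), 0)
  expect_true(attr(d1, "singular"))
  expect_equal(qr(M1)$rank, 1)
  # information is convex-linear in the design measure
  desB <- approx_design(log_corners(), c(0.1, 0.2, 0.3, 0.4))
  mix <- approx_design(log_corners(), 0.5 * rep(0.25, 4) + 0.5 * c(0.1, 0.2, 0.3, 0.4))
  expect_equal(fim(mix, spec, th), 0.5 * M + 0.5 * fim(desB, spec, th))
})

test_that("the log-scale information equals the standard one with gradient rows scaled by 1/rate", {
  th <- nominal_estimates("encompassing", "standard")$theta
  des <- approx_design(data.frame(xS = c(2, 9, 25, 30), xI = c(0, 8, 30, 60)),
                       c(0.3, 0.3, 0.2, 0.2))
  Fs <- gradient(model_spec("encompassing", "standard"), th,
                 des$points$xS, des$points$xI)
  eta <- eval_rate(model_spec("encompassing", "standard"), th,
                   des$points$xS, des$points$xI)
  Ml <- fim(des, model_spec("encompassing", "log"), th)
  expect_equal(Ml, crossprod((Fs / eta) * sqrt(des$weights)), tolerance = 1e-12)
})

test_that("the Ds criterion agrees with the Schur complement and reduces to D", {
  set.seed(5)
  Fr <- matrix(rnorm(40), 10, 4)
  w <- runif(10); w <- w / sum(w)
  M <- crossprod(Fr * sqrt(w))
  for (s in list(1L, 4L, c(2L, 3L))) {
    nuis <- setdiff(1:4, s)
    schur <- M[s, s, drop = FALSE] -
      M[s, nuis, drop = FALSE] %*% solve(M[nuis, nuis, drop = FALSE]) %*%
      M[nuis, s, drop = FALSE]
    expect_equal(as.numeric(ds_criterion(M, s)), det(schur), tolerance = 1e-10)
  }
  expect_equal(ds_criterion(M, 1:4), d_criterion(M))
  # diagonal information: the Ds value is the diagonal entry of interest
  D <- diag(c(4, 9, 16, 25))
  expect_equal(as.numeric(ds_criterion(D, 2L)), 9)
})

test_that("sensitivity obeys the trace identity and flags non-optimal designs", {
  spec <- model_spec("encompassing", "log")
  th <- nominal_estimates("encompassing", "log")$theta
  des <- approx_design(log_corners(), c(0.4, 0.3, 0.2, 0.1))
  psi <- sensitivity_d(des, spec, th, des$points$xS, des$points$xI)
  expect_equal(sum(des$weights * psi), spec$m, tolerance = 1e-10)
  # Ds sensitivity averages to s
  psis <- sensitivity_d(des, spec, th, des$points$xS, des$points$xI,
                        subset = 4L)
  expect_equal(sum(des$weights * psis), 1, tolerance = 1e-10)
  # a perturbed (non-optimal) design violates the equivalence bound
  grid <- design_grid("log")
  chk <- equivalence_check(des, grid, spec, th)
  expect_false(chk$pass)
  expect_gt(chk$max_psi, spec$m)
})

test_that("largest-remainder rounding matches the apportionment examples and quota bound", {
  eq <- approx_design(log_corners(), rep(0.25, 4))
  r8 <- round_design(eq, 8)
  expect_equal(r8$replicates, rep(2L, 4))
  # the low-weight support point of the printed T-optimal design drops out
  # at small N
  A1 <- approx_design(log_corners(), printed_A1_weights)
  for (N in 6:9) {
    ex <- round_design(A1, N)
    expect_equal(ex$N, N)
    expect_false(any(ex$points$xS == 0.02 & ex$points$xI == 0))
  }
  # quota bound |n_i - N w_i| <= 1 on random designs
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(3:7, 1)
    w <- runif(k); w <- w / sum(w)
    des <- approx_design(data.frame(xS = seq_len(k), xI = 0), w)
    N <- sample(3:40, 1)
    ex <- round_design(des, N)
    expect_equal(sum(ex$replicates), N)
    full <- merge(cbind(des$points, w = des$weights),
                  cbind(ex$points, n = ex$replicates), all.x = TRUE)
    full$n[is.na(full$n)] <- 0L
    expect_true(all(abs(full$n - N * full$w) <= 1 + 1e-9))
  }
  expect_error(round_design(eq, 0), "positive integer")
})

test_that("the D optimiser matches exhaustive simplex enumeration on a small candidate set", {
  # 4 candidate points, weight simplex discretised at step 0.01, full
  # enumeration as the independent oracle
  spec <- model_spec("michaelis_menten", "log")
  th <- c(6.99, 3.98)
  cand <- data.frame(xS = c(0.02, 1, 8, 30), xI = 0)
  Fc <- gradient(spec, th, cand$xS, cand$xI)
  step <- 100L
  best <- -Inf
  for (a in 0:step) for (b in 0:(step - a)) for (cc in 0:(step - a - b)) {
    w <- c(a, b, cc, step - a - b - cc) / step
    M <- crossprod(Fc * sqrt(w))
    v <- M[1, 1] * M[2, 2] - M[1, 2]^2
    if (v > best) best <- v
  }
  grid <- structure(list(points = cand, substrate = c(0.02, 30),
                         inhibitor = c(0, 0), sub_step = 1, inh_step = 1,
                         scale = "log"), class = "kinoed_grid")
  des <- optimize_d(grid, spec, th, refine = FALSE)
  opt <- d_criterion(fim(des, spec, th))
  expect_gt(opt / best, 1 - 0.005)
})

test_that("a two-parameter model yields the saturated equal-weight design", {
  grid <- design_grid("standard", inhibitor = c(0, 0), sub_step = 0.1)
  th <- nominal_estimates("competitive", "standard")$theta[1:2]
  des <- optimize_d(grid, model_spec("michaelis_menten"), th)
  expect_equal(nrow(des$points), 2)
  expect_equal(des$weights, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(max(des$points$xS), 30, tolerance = 1e-6)
})

test_that("log-case optimal designs sit on the corners and are certified", {
  grid <- design_grid("log")
  expect_equal(nrow(grid$points), 31 * 61)
  spec <- model_spec("encompassing", "log")
  th <- encompassing_at("noncompetitive", "log")
  des <- optimize_d(grid, spec, th)
  expect_equal(des$points, log_corners()[order(log_corners()$xS,
                                               log_corners()$xI), ],
               ignore_attr = TRUE)
  expect_equal(des$weights, rep(0.25, 4), tolerance = 1e-4)
  chk <- attr(des, "equivalence")
  expect_true(chk$pass)
  # sensitivity equals the parameter count on the support
  psi <- sensitivity_d(des, spec, th, des$points$xS, des$points$xI)
  expect_equal(psi, rep(4, 4), tolerance = 1e-3)
  # subset = all parameters reproduces the D design
  des_s <- optimize_ds(grid, spec, th, subset = 1:4)
  expect_equal(des_s$weights, des$weights, tolerance = 1e-4)
})

test_that("no design beats a certified optimum, and efficiencies are capped at 100", {
  grid <- design_grid("log")
  spec <- model_spec("encompassing", "log")
  th <- nominal_estimates("encompassing", "log")$theta
  opt <- optimize_d(grid, spec, th)
  set.seed(12)
  for (rep in 1:10) {
    k <- sample(4:7, 1)
    idx <- sample(nrow(grid$points), k)
    w <- runif(k); w <- w / sum(w)
    des <- approx_design(grid$points[idx, ], w)
    expect_lte(d_efficiency(des, opt, spec, th), 100 + 1e-6)
  }
  expect_equal(as.numeric(d_efficiency(opt, opt, spec, th)), 100)
  # a 3-point design is singular for a 4-parameter model
  sing <- approx_design(log_corners()[1:3, ], rep(1/3, 3))
  e <- d_efficiency(sing, opt, spec, th)
  expect_equal(as.numeric(e), 0)
  expect_true(attr(e, "singular"))
})
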