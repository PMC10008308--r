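test_that("simulated errors have the stated distribution and positivity", {
  des <- exact_design(data.frame(xS = 10, xI = 5), 1e5)
  sN <- model_spec("noncompetitive", "log")
  thN <- nominal_estimates("noncompetitive", "log")$theta
  sig <- 0.5128
  dat <- simulate_dataset(des, sN, thN, sig, seed = 101)
  expect_true(all(dat$rate > 0))
  eta <- eval_rate(model_spec("noncompetitive"), thN, 10, 5)
  z <- log(dat$rate) - log(eta)
  ks <- stats::ks.test(z, "pnorm", 0, sig)
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(z), 0, tolerance = 0.01)
  expect_equal(sd(z), sig, tolerance = 0.01)
  # sigma = 0 reproduces the mean surface exactly
  d0 <- simulate_dataset(exact_design(log_corners(), c(1, 2, 2, 1)),
                         sN, thN, 0)
  expect_equal(d0$rate, eval_rate(model_spec("noncompetitive"), thN,
                                  d0$substrate, d0$inhibitor))
  # huge multiplicative noise still yields positive rates
  dbig <- simulate_dataset(des <- exact_design(log_corners(), rep(3, 4)),
                           sN, thN, 10, seed = 5)
  expect_true(all(dbig$rate > 0))
})

test_that("classification picks the generating model on clean data and ties on x_I = 0", {
  sC <- model_spec("competitive", "log")
  sN <- model_spec("noncompetitive", "log")
  thC <- nominal_estimates("competitive", "log")$theta
  thN <- nominal_estimates("noncompetitive", "log")$theta
  des <- round_design(approx_design(log_corners(), printed_A2_weights), 8)
  clean <- simulate_dataset(des, sC, thC, 1e-4, seed = 6)
  expect_equal(as.character(classify(clean, sN, sC, thN, thC)), "competitive")
  clean_n <- simulate_dataset(des, sN, thN, 1e-4, seed = 6)
  expect_equal(as.character(classify(clean_n, sN, sC, thN, thC)),
               "noncompetitive")
  # without inhibitor the models coincide: classification is a coin flip,
  # but must still return one of the two labels
  des0 <- exact_design(data.frame(xS = c(0.5, 2, 8, 30), xI = 0),
                       c(2, 2, 2, 2))
  d0 <- simulate_dataset(des0, sC, thC, 0.2, seed = 8)
  labs <- replicate(20, as.character(classify(d0, sN, sC, thN, thC)))
  expect_true(all(labs %in% c("competitive", "noncompetitive")))
})

test_that("classification agrees with an independent cross-optimizer refit", {
  sC <- model_spec("competitive", "log")
  sN <- model_spec("noncompetitive", "log")
  thC <- nominal_estimates("competitive", "log")$theta
  thN <- nominal_estimates("noncompetitive", "log")$theta
  des <- round_design(approx_design(log_corners(), printed_A2_weights), 8)
  # independent route: Nelder-Mead on the log-scale SSE with multistart
  nm_sse <- function(data, spec, init) {
    obj <- function(th) {
      if (any(th[1:3] <= 0)) return(1e10)
      if (spec$m == 4 && (th[4] < 0 || th[4] > 1)) return(1e10)
      sum((log(data$rate) -
             eval_rate(spec, th, data$substrate, data$inhibitor))^2)
    }
    min(vapply(list(init, init * 0.6, init * 1.7), function(st)
      optim(st, obj, method = "Nelder-Mead",
            control = list(maxit = 4000, reltol = 1e-13))$value, 0))
  }
  agree <- 0L
  for (s in 1:20) {
    truth <- if (s %% 2 == 0) list(sC, thC) else list(sN, thN)
    dat <- simulate_dataset(des, truth[[1]], truth[[2]], 0.5128,
                            seed = 900 + s)
    win <- as.character(classify(dat, sN, sC, thN, thC))
    win_nm <- if (nm_sse(dat, sN, thN) < nm_sse(dat, sC, thC))
      "noncompetitive" else "competitive"
    agree <- agree + (win == win_nm)
  }
  expect_gte(agree, 19L)
})

test_that("hit rates respond to noise and design informativeness as expected", {
  sC <- model_spec("competitive", "log")
  sN <- model_spec("noncompetitive", "log")
  thC <- nominal_estimates("competitive", "log")$theta
  thN <- nominal_estimates("noncompetitive", "log")$theta
  A2 <- round_design(approx_design(log_corners(), printed_A2_weights), 6)
  # vanishing noise: essentially perfect discrimination
  hr0 <- hit_rate_study(list(A2 = A2), sN, sC, thN, thC, sigma = 0.001,
                        B = 30, seed = 2)
  expect_gte(hr0$avg_hit_rate, 99)
  # stochastically non-increasing in sigma
  rates <- vapply(c(0.1, 0.5, 2.0), function(s)
    hit_rate_study(list(A2 = A2), sN, sC, thN, thC, sigma = s, B = 150,
                   seed = 3)$avg_hit_rate, 0)
  expect_true(all(diff(rates) < 8))     # allow Monte-Carlo slack
  expect_gt(rates[1] - rates[3], 10)
  # an inhibitor-free design cannot discriminate: chance level
  flat <- exact_design(data.frame(xS = c(0.5, 2, 8, 30), xI = 0),
                       c(2, 2, 1, 1))
  hrf <- hit_rate_study(list(flat = flat), sN, sC, thN, thC, sigma = 0.5128,
                        B = 100, seed = 4)
  expect_lt(abs(hrf$avg_hit_rate - 50), 15)
  # reproducibility: identical seeds give identical tables
  h1 <- hit_rate_study(list(A2 = A2), sN, sC, thN, thC, 0.5128, B = 20,
                       seed = 9)
  h2 <- hit_rate_study(list(A2 = A2), sN, sC, thN, thC, 0.5128, B = 20,
                       seed = 9)
  expect_identical(h1, h2)
})
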