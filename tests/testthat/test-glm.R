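simple_design <- function(n, fs = 2, seed = 1) {
  set.seed(seed)
  stim <- stim_design(onsets = seq(10, n / fs - 30, by = 40), durations = 10)
  design_matrix(build_task_design(stim, n, fs), fs = fs)
}

test_that("OLS matches the normal-equations oracle and interpolates noiseless data", {
  n <- 120
  des <- simple_design(n)
  x <- cbind(1, des$xtask)
  set.seed(2)
  beta0 <- c(0.3, 1.7)
  y <- drop(x %*% beta0)
  f <- ols_fit(matrix(y, ncol = 1), des)
  expect_equal(f$details[[1]]$beta, beta0, tolerance = 1e-10,
               ignore_attr = TRUE)

  yr <- y + rnorm(n)
  f2 <- ols_fit(matrix(yr, ncol = 1), des)
  oracle <- solve(crossprod(x), crossprod(x, yr))
  expect_equal(unname(f2$details[[1]]$beta), unname(drop(oracle)),
               tolerance = 1e-10)
  # classical t/p from Student-t with n - rank dof
  expect_equal(f2$stats$dof, n - 2)
  expect_equal(f2$stats$p,
               2 * pt(-abs(f2$stats$t), df = n - 2), tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  des <- simple_design(100)
  des2 <- design_matrix(cbind(a = des$xtask[, 1], b = des$xtask[, 1]),
                        fs = des$fs)
  expect_error(ols_fit(matrix(rnorm(100), ncol = 1), des2), "collinear")
})

test_that("AR-IRLS agrees with OLS on white noise and recovers AR(1) structure", {
  n <- 400
  des <- simple_design(n, seed = 3)
  set.seed(4)
  y <- matrix(rnorm(n), ncol = 1)
  fo <- ols_fit(y, des)
  fa <- suppressWarnings(ar_irls_fit(y, des, max_ar_order = 8))
  expect_lte(length(fa$details[[1]]$ar), 2)   # near-white: tiny AR order
  expect_lt(abs(fa$stats$beta - fo$stats$beta), 2 * fo$stats$se)

  # AR(1) phi = 0.8, n = 2000: phi recovered within 0.05, beta within 3 se
  n2 <- 2000
  des2 <- simple_design(n2, seed = 5)
  beta0 <- 0.8
  set.seed(6)
  noise <- as.numeric(arima.sim(list(ar = 0.8), n2))
  y2 <- matrix(des2$xtask %*% beta0 + noise, ncol = 1)
  f2 <- suppressWarnings(ar_irls_fit(y2, des2, max_ar_order = 16))
  expect_lt(abs(f2$details[[1]]$ar[1] - 0.8), 0.05)
  expect_lt(abs(f2$stats$beta - beta0), 3 * f2$stats$se)
})

test_that("whitened residuals of exact AR noise pass Ljung-Box", {
  n <- 800
  des <- simple_design(n, seed = 7)
  pass <- logical(40)
  for (i in seq_along(pass)) {
    set.seed(100 + i)
    y <- matrix(as.numeric(arima.sim(list(ar = c(0.6, 0.2)), n)), ncol = 1)
    f <- suppressWarnings(ar_irls_fit(y, des, max_ar_order = 10))
    r <- f$details[[1]]$resid
    pass[i] <- Box.test(r, lag = 15, type = "Ljung-Box")$p.value > 0.01
  }
  expect_gte(mean(pass), 0.95)
})

test_that("solvers are scale-equivariant: beta scales, t and p unchanged", {
  n <- 300
  des <- simple_design(n, seed = 8)
  set.seed(9)
  y <- matrix(as.numeric(arima.sim(list(ar = 0.5), n)) +
              drop(des$xtask) * 0.5, ncol = 2, nrow = n)
  y[, 2] <- y[, 2] + rnorm(n, sd = 0.1)
  z <- sweep(matrix(rnorm(n * 2), n, 2), 2, c(0, 0))
  desz <- design_matrix(des$xtask, z, fs = des$fs)
  for (fit in list(
    function(v) ols_fit(v, des),
    function(v) suppressWarnings(ar_irls_fit(v, des, max_ar_order = 6)),
    function(v) suppressWarnings(me_ar_irls_fit(v, desz, max_ar_order = 6)))) {
    f1 <- fit(y)
    f2 <- fit(y * 7)
    expect_equal(f2$stats$beta, 7 * f1$stats$beta, tolerance = 1e-6)
    expect_equal(f2$stats$t, f1$stats$t, tolerance = 1e-6)
    expect_equal(f2$stats$p, f1$stats$p, tolerance = 1e-6)
  }
})

test_that("null p-values are uniform for OLS and AR-IRLS on white noise", {
  n <- 150
  des <- simple_design(n, seed = 10)
  set.seed(11)
  y <- matrix(rnorm(n * 2000), n, 2000)
  p_ols <- ols_fit(y, des)$stats$p
  expect_gt(ks.test(p_ols, "punif")$p.value, 0.01)

  set.seed(12)
  y2 <- matrix(rnorm(n * 300), n, 300)
  p_ar <- suppressWarnings(ar_irls_fit(y2, des, max_ar_order = 4))$stats$p
  expect_gt(ks.test(p_ar, "punif")$p.value, 0.01)
})

test_that("robust weights lie in (0, 1] and dof stays positive", {
  n <- 250
  des <- simple_design(n, seed = 13)
  set.seed(14)
  y <- rnorm(n); y[c(20, 90)] <- c(25, -30)      # gross outliers
  f <- suppressWarnings(ar_irls_fit(matrix(y, ncol = 1), des))
  w <- f$details[[1]]$weights
  expect_true(all(w > 0 & w <= 1))
  expect_gt(f$stats$dof, 0)
  expect_true(all(f$stats$p >= 0 & f$stats$p <= 1))
  # the outliers get the smallest weights
  expect_true(all(rank(w)[c(20, 90)] <= 4))
})

test_that("ME with infinite prior reproduces AR-IRLS with appended regressors", {
  n <- 300
  des0 <- simple_design(n, seed = 15)
  set.seed(16)
  z <- matrix(rnorm(n * 3), n, 3)
  z <- scale(z)[, ]                      # unit variance, like SS traces
  y <- matrix(rnorm(n * 4), n, 4) + drop(des0$xtask) %*% t(rep(0.5, 4))
  des <- design_matrix(des0$xtask, z, fs = des0$fs)
  fme <- suppressWarnings(me_ar_irls_fit(y, des, max_ar_order = 4,
                                         max_outer = 1))
  far <- suppressWarnings(ar_irls_fit(y, des, max_ar_order = 4))
  expect_equal(fme$stats$beta, far$stats$beta, tolerance = 1e-6)
})

test_that("ME recovers the pooled random-effect scale", {
  # channels share Z; Gamma_jk ~ N(0, 0.25) so sigma = 0.5
  n <- 250; n_ch <- 22
  des0 <- simple_design(n, seed = 17)
  sig_hat <- numeric(50)
  for (r in seq_len(50)) {
    set.seed(300 + r)
    z <- scale(matrix(rnorm(n * 2), n, 2))[, ]
    gam <- matrix(rnorm(2 * n_ch, sd = 0.5), 2, n_ch)
    y <- z %*% gam + matrix(rnorm(n * n_ch, sd = 1), n, n_ch)
    des <- design_matrix(des0$xtask, z, fs = des0$fs)
    fme <- suppressWarnings(me_ar_irls_fit(y, des, max_ar_order = 2,
                                           max_outer = 8))
    sig_hat[r] <- fme$me_state$sigma
  }
  expect_lt(abs(median(sig_hat) - 0.5) / 0.5, 0.35)
})

test_that("ME pooling narrows globally-shared SS coefficients", {
  # identical true Gamma in all channels: pooled estimates vary less
  # across channels than unpooled ones
  n <- 250; n_ch <- 16
  des0 <- simple_design(n, seed = 18)
  set.seed(19)
  z <- scale(matrix(rnorm(n * 2), n, 2))[, ]
  gam <- c(0.8, -0.5)
  y <- z %*% matrix(gam, 2, n_ch) + matrix(rnorm(n * n_ch), n, n_ch)
  des <- design_matrix(des0$xtask, z, fs = des0$fs)
  fme <- suppressWarnings(me_ar_irls_fit(y, des, max_ar_order = 2))
  far <- suppressWarnings(ar_irls_fit(y, des, max_ar_order = 2))
  v_me <- sum(apply(fme$beta_short, 2, var))
  v_ar <- sum(apply(far$beta_short, 2, var))
  expect_lt(v_me, v_ar)
})

test_that("stronger priors never increase the SS coefficient norm", {
  n <- 200
  des0 <- simple_design(n, seed = 20)
  set.seed(21)
  z <- scale(matrix(rnorm(n * 2), n, 2))[, ]
  y <- drop(z %*% c(1, -1)) + rnorm(n)
  x <- cbind(`(Intercept)` = 1, des0$xtask, z)
  norms <- sapply(c(Inf, 1, 0.3, 0.1, 0.03), function(sig) {
    ridge <- if (is.finite(sig)) {
      rows <- matrix(0, 2, ncol(x)); rows[1, 3] <- rows[2, 4] <- 1 / sig
      list(rows = rows)
    } else NULL
    fit <- nirsphysio:::ar_irls_channel(x, y, max_ar_order = 2,
                                        max_iter = 5, tol = 1e-4,
                                        ridge = ridge)
    sqrt(sum(fit$beta[3:4]^2))
  })
  expect_true(all(diff(norms) <= 1e-8))
})

test_that("ME precondition errors are explicit", {
  des <- simple_design(100)
  expect_error(me_ar_irls_fit(matrix(rnorm(200), 100, 2), des),
               "at least two SS regressors")
  z <- matrix(rnorm(200), 100, 2)
  desz <- design_matrix(des$xtask, z, fs = des$fs)
  expect_error(me_ar_irls_fit(matrix(rnorm(100), ncol = 1), desz),
               "at least two channels")
})

test_that("Hotelling T2 combines chromophores and matches the direct formula", {
  n <- 200
  des <- simple_design(n, seed = 22)
  set.seed(23)
  y1 <- matrix(rnorm(n * 3), n, 3)
  y2 <- matrix(rnorm(n * 3), n, 3)
  f1 <- ols_fit(y1, des); f2 <- ols_fit(y2, des)
  hj <- hotelling_joint(f1, f2)
  # diagonal covariance: T2 = t1^2 + t2^2
  expect_equal(hj$t2, f1$stats$t^2 + f2$stats$t^2, tolerance = 1e-10)
  # direct b' C^-1 b evaluation
  b <- c(f1$stats$beta[1], f2$stats$beta[1])
  C <- diag(c(f1$stats$se[1]^2, f2$stats$se[1]^2))
  expect_equal(hj$t2[1], drop(b %*% solve(C) %*% b), tolerance = 1e-10)
  expect_true(all(hj$p >= 0 & hj$p <= 1))
})

test_that("joint test p-values are uniform under the null", {
  n <- 150
  des <- simple_design(n, seed = 24)
  set.seed(25)
  f1 <- ols_fit(matrix(rnorm(n * 2000), n, 2000), des)
  f2 <- ols_fit(matrix(rnorm(n * 2000), n, 2000), des)
  hj <- hotelling_joint(f1, f2)
  expect_gt(ks.test(hj$p, "punif")$p.value, 0.01)
})
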