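test_that("linear detrending removes trends and matches the OLS oracle", {
  T_ <- 100
  t_ <- seq_len(T_)
  # pure trend vanishes
  ts <- rbind(2 * t_ + 5, -0.3 * t_ + 1)
  expect_equal(remove_linear_trend(ts), matrix(0, 2, T_), tolerance = 1e-10)

  # arbitrary series: equals lm() residuals node by node
  set.seed(11)
  ts <- matrix(rnorm(5 * T_), 5, T_) + outer(runif(5), t_)
  out <- remove_linear_trend(ts)
  for (i in 1:5) {
    expect_equal(unname(out[i, ]), unname(resid(lm(ts[i, ] ~ t_))),
                 tolerance = 1e-10)
  }
  expect_lt(max(abs(rowMeans(out))), 1e-10)

  # an in-band sinusoid survives nearly unchanged (small endpoint leakage),
  # and the leakage equals the closed-form OLS projection exactly
  s <- sin(2 * pi * 0.05 * t_ * 2)
  d <- remove_linear_trend(rbind(s))
  expect_lt(sqrt(mean((d - s)^2)) / sqrt(mean(s^2)), 0.10)
  expect_equal(unname(d[1, ]), unname(resid(lm(s ~ t_))), tolerance = 1e-10)

  expect_lt(max(abs(remove_linear_trend(rbind(rep(3, 50))))), 1e-12)
})

test_that("Friston-24 expansion lays out parameters, lags and squares", {
  T_ <- 20
  expect_equal(friston24_expand(matrix(0, 6, T_)), matrix(0, 24, T_))

  m <- matrix(2, 6, T_)
  f <- friston24_expand(m)
  expect_identical(dim(f), c(24L, 20L))
  expect_equal(f[13, ], rep(4, T_))  # squared block

  m <- matrix(0, 6, T_)
  m[3, 5] <- 1
  f <- friston24_expand(m)
  expect_equal(which(f[9, ] != 0), 6L)   # lag block row for parameter 3
  expect_equal(f[9, 6], 1)
  expect_error(friston24_expand(matrix(0, 5, T_)), "6 rows")
})

test_that("nuisance regression produces orthogonal residuals", {
  T_ <- 80
  set.seed(21)
  ts <- matrix(rnorm(4 * T_), 4, T_)

  # no regressors: demeaning
  expect_equal(regress_nuisance(ts), ts - rowMeans(ts), tolerance = 1e-12)

  # a node equal to a regressor is annihilated
  reg <- matrix(rnorm(3 * T_), 3, T_)
  ts2 <- rbind(reg[1, ], ts)
  out <- regress_nuisance(ts2, reg)
  expect_lt(sqrt(sum(out[1, ]^2)), 1e-8 * sqrt(sum(ts2[1, ]^2)))

  # residuals orthogonal to every regressor (normal equations)
  reg5 <- matrix(rnorm(5 * T_), 5, T_)
  out <- regress_nuisance(ts, reg5)
  dots <- abs(out %*% t(reg5)) / (sqrt(rowSums(out^2)) %o% sqrt(rowSums(reg5^2)))
  expect_lt(max(dots), 1e-8)

  # collinear design rejected with the offending rows named
  regc <- rbind(reg5, reg5[2, ] * 2)
  expect_error(regress_nuisance(ts, regc), "collinear")
})

test_that("ideal band-pass filter passes in-band and rejects out-of-band", {
  T_ <- 230
  tr <- 2
  t_ <- seq_len(T_) - 1
  f_in <- 18 / (T_ * tr)    # 0.0391 Hz, integer number of cycles
  f_out <- 92 / (T_ * tr)   # 0.2000 Hz
  s_in <- sin(2 * pi * f_in * t_ * tr)
  s_out <- sin(2 * pi * f_out * t_ * tr)

  keep <- bandpass_filter(rbind(s_in), tr, 0.01, 0.08)
  expect_lt(sqrt(mean((keep - s_in)^2)) / sqrt(mean(s_in^2)), 1e-6)

  kill <- bandpass_filter(rbind(s_out), tr, 0.01, 0.08)
  expect_lt(sqrt(mean(kill^2)), 1e-6 * sqrt(mean(s_out^2)))

  mix <- bandpass_filter(rbind(s_in + s_out), tr, 0.01, 0.08)
  expect_lt(sqrt(mean((mix - s_in)^2)) / sqrt(mean(s_in^2)), 1e-6)

  expect_error(bandpass_filter(rbind(s_in), tr, 0.01, 0.3), "Nyquist")
  expect_error(bandpass_filter(rbind(s_in), tr, 0.08, 0.01), "low < high")
})

test_that("Fisher-Z connectivity is clipped, symmetric and affine-invariant", {
  set.seed(31)
  ts <- matrix(rnorm(6 * 200), 6, 200)

  # duplicated node: clipped Fisher Z, finite
  ts_dup <- rbind(ts, ts[1, ])
  z <- pearson_fc(ts_dup)
  expect_equal(z[1, 7], atanh(1 - 1e-7))
  expect_true(all(is.finite(z)))
  expect_equal(unname(diag(z)), rep(0, 7))
  expect_equal(z, t(z))

  # analytically constructed r = 0.5 pair
  u <- ts[1, ] - mean(ts[1, ])
  u <- u / sqrt(sum(u^2))
  w <- ts[2, ] - mean(ts[2, ])
  w <- w - sum(w * u) * u
  w <- w / sqrt(sum(w^2))
  pair <- rbind(u, 0.5 * u + sqrt(0.75) * w)
  expect_equal(pearson_fc(pair)[1, 2], atanh(0.5), tolerance = 1e-4)

  # invariance to per-node affine rescaling
  z0 <- pearson_fc(ts)
  z1 <- pearson_fc(ts * c(2, 0.1, 5, 1, 3, 10) + c(-4, 0, 7, 1, 2, 0))
  expect_equal(z0, z1, tolerance = 1e-12)

  # white-noise null: |Z| concentrated within 3 Fisher SDs
  set.seed(32)
  big <- matrix(rnorm(30 * 2000), 30, 2000)
  zb <- pearson_fc(big)
  frac <- mean(abs(zb[upper.tri(zb)]) < 3 / sqrt(2000 - 3))
  expect_gt(frac, 0.95)

  expect_error(pearson_fc(rbind(ts, 0 * ts[1, ])), "zero-variance")
})

test_that("edge vectorization round-trips in canonical order", {
  set.seed(41)
  m <- matrix(rnorm(123^2), 123)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  v <- vectorize_edges(m)
  expect_length(v, 7503)
  expect_identical(names(v)[1:3], c("FC_1_2", "FC_1_3", "FC_1_4"))
  expect_identical(names(v)[123], "FC_2_3")  # row-major upper triangle
  expect_identical(devectorize_edges(v), m)

  m4 <- matrix(rnorm(16), 4)
  m4 <- (m4 + t(m4)) / 2
  diag(m4) <- 0
  expect_length(vectorize_edges(m4), 6)
})

test_that("planted covariance survives the cleaning + FC pipeline", {
  cv <- diag(5)
  cv[1, 2] <- cv[2, 1] <- 0.8
  ts <- sample_subject_timeseries(cv, 10000, seed = 3)
  z <- pearson_fc(clean_timeseries(ts, tr = 2))
  # band-pass removes frequencies but not the cross-correlation structure
  expect_lt(abs(z[1, 2] - atanh(0.8)), 0.1)
  # without filtering, recovery is within 3 Fisher SDs
  z_raw <- pearson_fc(ts)
  expect_lt(abs(z_raw[1, 2] - atanh(0.8)), 3 / sqrt(10000 - 3))
})
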