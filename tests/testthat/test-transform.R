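eiip_sig <- function(values, id = "x") numeric_signal(id, values, "eiip")

test_that("band-pass keeps the 2*pi/3 tone and rejects DC and 2*pi/4", {
  n <- 0:299
  tone3 <- eiip_sig(cos(2 * pi * n / 3))
  out3 <- bandpass_period3(tone3)
  ratio3 <- mean(out3$value^2) / mean(tone3$value^2)
  expect_gte(ratio3, 0.9)

  dc <- eiip_sig(rep(0.126, 300))
  outdc <- bandpass_period3(dc)
  expect_lte(mean(outdc$value^2) / mean(dc$value^2), 1e-4)

  tone4 <- eiip_sig(cos(2 * pi * n / 4))
  out4 <- bandpass_period3(tone4)
  ratio4 <- mean(out4$value^2) / mean(tone4$value^2)
  expect_lte(ratio4, 0.05 * ratio3)

  expect_equal(nrow(out3), 300L)
  expect_equal(unique(out3$stage), "bandpassed")
  expect_error(bandpass_period3(eiip_sig(rnorm(12))), "too short")
})

test_that("the FIR design meets the same passband contract", {
  n <- 0:599
  spec <- bandpass_spec(order = 400L, design = "fir_window")
  out <- bandpass_period3(eiip_sig(cos(2 * pi * n / 3)), spec)
  expect_gte(mean(out$value^2) / mean(cos(2 * pi * n / 3)^2), 0.9)
  outdc <- bandpass_period3(eiip_sig(rep(1, 600)), spec)
  expect_lte(mean(outdc$value^2), 1e-4)
})

test_that("energy profile localizes a confined 2*pi/3 tone", {
  x <- numeric(300)
  x[101:200] <- cos(2 * pi * (0:99) / 3)
  d <- dwt_decompose(x, "coif5", levels = 2)
  prof <- energy_profile(d, smooth_window = 9)
  inside <- prof$value[101:200]
  outside <- prof$value[c(1:100, 201:300)]
  expect_gte(mean(inside), 5 * mean(outside))
  expect_equal(nrow(prof), 300L)
  expect_true(all(prof$value >= 0))
})

test_that("profile length equals the original length for any input length", {
  for (n in c(121, 256, 333, 1000)) {
    d <- dwt_decompose(rnorm(n), "coif5", levels = 2)
    expect_equal(nrow(energy_profile(d)), n)
  }
})

test_that("band-pass + energy pipeline is shift-covariant", {
  # Profile displacement is measured by the cross-correlation peak: the raw
  # argmax of the profile snaps to the 6 nt ripple of the squared 2*pi/3
  # carrier on the coefficient grid, while the correlation lag tracks the
  # whole envelope.
  bump <- exp(-((0:899 - 450)^2) / (2 * 60^2))
  base <- bump * cos(2 * pi * (0:899) / 3)
  run <- function(v) {
    p <- bandpass_period3(eiip_sig(v))
    energy_profile(dwt_decompose(p, "coif5", 2), smooth_window = 101)$value
  }
  best_lag <- function(a, b, maxlag = 10) {
    lags <- -maxlag:maxlag
    idx <- (1 + maxlag):(length(a) - maxlag)
    score <- vapply(lags, function(l) sum(a[idx] * b[idx + l]), 1.0)
    lags[which.max(score)]
  }
  p0 <- run(base)
  for (shift in c(3, 6)) {
    shifted <- c(numeric(shift), base[1:(900 - shift)])
    lag <- -best_lag(run(shifted), p0)
    expect_lte(abs(lag - shift), 1)
  }
})

test_that("moving-average denoising halves flat-region variance, window 1 is identity", {
  en <- function(v, id = "x") numeric_signal(id, v, "energy")
  rect <- c(rep(0, 100), rep(1, 100), rep(0, 100))
  out1 <- adaptive_denoise(en(rect), denoise_spec(window = 1))
  expect_equal(out1$value, rect)

  set.seed(33)
  noisy <- rect + abs(rnorm(300, sd = 0.2))
  out9 <- adaptive_denoise(en(noisy), denoise_spec(window = 9))
  flat <- c(5:95, 205:295)   # away from the edges of the rectangle
  expect_lte(var(out9$value[flat]), 0.5 * var(noisy[flat]))
  expect_true(all(out9$value >= 0))
  expect_equal(unique(out9$stage), "denoised")
})

test_that("denoising a smooth unimodal profile barely moves its peak", {
  en <- numeric_signal("x", exp(-((1:400 - 170)^2) / (2 * 40^2)), "energy")
  for (m in c("moving_average", "wavelet_shrink")) {
    out <- adaptive_denoise(en, denoise_spec(method = m, window = 9))
    expect_lte(abs(which.max(out$value) - 170), 9 %/% 2 + 1)
  }
})

test_that("alternative denoisers return valid same-length non-negative profiles", {
  set.seed(34)
  en <- numeric_signal("x", abs(rnorm(400)) + 0.1, "energy")
  for (m in c("lms_canceller", "wavelet_shrink")) {
    out <- adaptive_denoise(en, denoise_spec(method = m))
    expect_equal(nrow(out), 400L)
    expect_true(all(out$value >= 0))
  }
  expect_error(denoise_spec(mu = 1.5), "mu")
  expect_error(denoise_spec(window = 8), "odd")
})

test_that("normalization scales to [0, 1] and rejects all-zero profiles", {
  en <- function(v) numeric_signal("x", v, "energy")
  expect_equal(normalize_profile(en(c(2, 4)))$value, c(0.5, 1.0))
  expect_equal(normalize_profile(en(c(1, 1, 1)))$value, c(1, 1, 1))
  expect_error(normalize_profile(en(c(0, 0))), "degenerate")
  expect_equal(unique(normalize_profile(en(c(2, 4)))$stage), "normalized")
})
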