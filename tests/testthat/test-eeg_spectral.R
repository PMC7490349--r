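test_that("Slepian tapers are orthonormal and concentrated", {
  tap <- dpss_tapers(128, 2, 3)
  expect_equal(crossprod(tap), diag(3), tolerance = 1e-8)
  # in-band spectral concentration decreases with taper order
  conc <- apply(tap, 2, function(h) {
    f <- seq(-2 / 128, 2 / 128, length.out = 101)
    resp <- vapply(f, function(ff)
      abs(sum(h * exp(2i * pi * ff * seq_len(128))))^2, numeric(1))
    mean(resp)
  })
  expect_true(all(diff(conc) < 0))
})

test_that("a pure tone localizes at its frequency bin", {
  rate <- 200
  tt <- seq(-1, 3, by = 1 / rate)
  x <- array(sin(2 * pi * 6 * tt), c(1, 1, length(tt)))
  tfr <- multitaper_tfr(x, rate, time = tt, freqs = 3:29)
  mid <- tfr$time > 0 & tfr$time < 2
  profile <- rowMeans(tfr$power[1, , mid])
  # the analysis bandwidth spans ~2 nearby bins; the peak must sit within it
  expect_lte(abs(tfr$freqs[which.max(profile)] - 6), 1)
  expect_gt(profile[tfr$freqs == 6], 0.5 * max(profile))
  # power is near-constant over the interior (small sidelobe ripple only)
  p6 <- tfr$power[1, 4, mid]
  expect_lt(diff(range(p6)) / mean(p6), 0.05)
})

test_that("multitaper power scales with variance and vanishes for silence", {
  set.seed(42)
  rate <- 200
  w <- array(rnorm(3 * 2 * 1500), c(3, 2, 1500))
  tfr1 <- multitaper_tfr(w, rate, freqs = c(6, 12, 24))
  tfr2 <- multitaper_tfr(2 * w, rate, freqs = c(6, 12, 24))
  interior <- 300:1200
  expect_equal(mean(tfr2$power[, , interior]) /
                 mean(tfr1$power[, , interior]), 4, tolerance = 1e-10)
  # Parseval-style: unit-variance white noise has expected power 1
  expect_equal(mean(tfr1$power[, , interior]), 1, tolerance = 0.2)
  z <- multitaper_tfr(array(0, c(1, 1, 400)), rate, freqs = c(6, 12))
  expect_true(all(z$power == 0))
})

test_that("epochs too short for the lowest frequency are refused", {
  expect_error(multitaper_tfr(array(rnorm(100), c(1, 1, 100)), 200,
                              freqs = c(3, 10)),
               "3 Hz")
})

test_that("percent baselining is exact and flags zero baselines", {
  rate <- 50
  tt <- seq(-1, 3, by = 1 / rate)
  n <- length(tt)
  p <- array(2, c(1, 2, n))
  p[1, 1, tt >= 0] <- 4  # doubles after onset
  tfr <- structure(list(power = p, channels = c("A", "B"), freqs = c(5, 10),
                        time = tt, rate = rate, units = "power",
                        n_trials = 1, params = list()), class = "tfr")
  bc <- crop_and_baseline(tfr, crop = c(-0.5, 3), baseline = c(-0.5, 0))
  expect_equal(unique(bc$power[1, 1, bc$time >= 0]), 100)
  expect_equal(unique(bc$power[1, 2, ]), 0)
  expect_true(all(bc$time >= -0.5 & bc$time < 3))
  bsel <- bc$time >= -0.5 & bc$time < 0
  expect_equal(max(abs(rowMeans(bc$power[, , bsel]))), 0, tolerance = 1e-10)
  # zero baseline -> undefined percent change, flagged as NA
  p0 <- p; p0[1, 2, ] <- 0
  tfr0 <- tfr; tfr0$power <- p0
  bc0 <- crop_and_baseline(tfr0)
  expect_true(all(is.na(bc0$power[1, 2, ])))
  expect_gt(attr(bc0, "n_undefined"), 0)
})

test_that("temporal downsampling bins, drops partials and preserves means", {
  mk_const <- function(rate, n) {
    tt <- (seq_len(n) - 1) / rate
    structure(list(power = array(7, c(1, 1, n)), channels = "A", freqs = 5,
                   time = tt, rate = rate, units = "power", n_trials = 1,
                   params = list()), class = "tfr")
  }
  # 3500 samples at 1 ms -> 175 bins of 20 ms
  ds <- downsample_time(mk_const(1000, 3500), bin = 0.02)
  expect_equal(length(ds$time), 175)
  expect_true(all(ds$power == 7))
  # trailing partial bin is dropped
  expect_equal(length(downsample_time(mk_const(1000, 3510), 0.02)$time), 175)
  # alternating +/-1 at 500 Hz averages to zero in every even-length bin
  alt <- mk_const(500, 3500)
  alt$power[1, 1, ] <- rep(c(1, -1), length.out = 3500)
  expect_true(all(downsample_time(alt, 0.02)$power == 0))
  expect_error(downsample_time(mk_const(500, 100), 0.0001),
               "smaller than the native")
})

test_that("condition contrasts difference TFRs and apply the trial floor", {
  mk <- function(val, n_trials) {
    structure(list(power = array(val, c(2, 3, 10)), channels = c("A", "B"),
                   freqs = c(4, 6, 8), time = seq(0, 0.9, 0.1), rate = 10,
                   units = "percent", n_trials = n_trials, params = list()),
              class = "tfr")
  }
  res <- condition_tfr_contrast(list(mk(5, 8), mk(5, 4)),
                                list(mk(5, 8), mk(5, 9)))
  expect_equal(length(res$diffs), 1)
  expect_equal(res$excluded, "P02")
  expect_true(all(res$diffs[[1]]$power == 0))
})

test_that("band averages respect band, window and channel selection", {
  p <- array(0, c(2, 4, 20))
  freqs <- c(4, 6, 10, 16)
  tt <- seq(0, 1.9, 0.1)
  p[, freqs >= 3 & freqs <= 8, ] <- -10
  tfr <- structure(list(power = p, channels = c("A", "B"), freqs = freqs,
                        time = tt, rate = 10, units = "percent",
                        n_trials = 4, params = list()), class = "tfr")
  expect_equal(band_average(tfr, band = c(3, 8), window = c(0, 2)), -10)
  expect_equal(band_average(tfr, band = c(8, 12), window = c(0, 2)), 0)
  half <- tfr
  half$power[, , tt >= 1] <- 0
  expect_equal(band_average(half, band = c(3, 8), window = c(0, 2)), -5)
  onechan <- tfr
  onechan$power[2, , ] <- 100
  expect_equal(band_average(onechan, band = c(3, 8), window = c(0, 2),
                            channels = "A"), -10)
})
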