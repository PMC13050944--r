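# Filtering, resampling, interpolation, referencing, epoching.

test_that("band-pass removes DC and preserves the passband center", {
  srate <- 250; n <- 5000; t <- (0:(n - 1)) / srate
  dc <- rep(3, n)
  # away from the edge transients of the 0.5 Hz high-pass corner
  expect_lt(max(abs(bandpass(dc, 0.5, 30, srate)[1500:3500])), 0.05)
  s10 <- sin(2 * pi * 10 * t)
  out <- bandpass(s10, 0.5, 30, srate)
  mid <- 1500:3500
  expect_equal(sd(out[mid]) / sd(s10[mid]), 1, tolerance = 0.01)
})

test_that("60 Hz is attenuated at least 90% (transfer-function oracle)", {
  srate <- 250; n <- 2000; t <- (0:(n - 1)) / srate
  s60 <- sin(2 * pi * 60 * t)
  out <- bandpass(s60, 0.5, 30, srate)
  att <- sd(out[500:1500]) / sd(s60[500:1500])
  expect_lt(att, 0.10)
  # independent oracle: squared magnitude of the designed Butterworth at 60 Hz
  bf <- signal::butter(4, c(0.5, 30) / (srate / 2), type = "pass")
  z <- exp(-1i * 2 * pi * 60 / srate)
  H <- sum(bf$b * z^(seq_along(bf$b) - 1)) / sum(bf$a * z^(seq_along(bf$a) - 1))
  gainFB <- Mod(H)^2                 # forward-backward application
  expect_lt(gainFB, 0.10)
  expect_equal(att, gainFB, tolerance = 0.02)
})

test_that("band-pass rejects invalid passbands and short series", {
  expect_error(bandpass(rnorm(100), 0, 30, 250), "passband")
  expect_error(bandpass(rnorm(100), 0.5, 130, 250), "passband")
  expect_error(bandpass(rnorm(10), 0.5, 30, 250), "too short")
})

test_that("filtering is linear", {
  set.seed(2); x <- rnorm(500); y <- rnorm(500)
  lhs <- bandpass(2 * x + 3 * y, 0.5, 30, 250)
  rhs <- 2 * bandpass(x, 0.5, 30, 250) + 3 * bandpass(y, 0.5, 30, 250)
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("downsampling halves 500 Hz data and preserves a 5 Hz tone", {
  n <- 500                                    # 1 s at 500 Hz
  x <- sin(2 * pi * 5 * (0:(n - 1)) / 500)
  y <- downsample(x, 500, 250)
  expect_length(y, 250)
  ref <- sin(2 * pi * 5 * (0:249) / 250)
  mid <- 50:200
  expect_equal(sd(y[mid]) / sd(ref[mid]), 1, tolerance = 0.01)
  expect_identical(downsample(x, 250, 250), x)   # identity ratio
  expect_error(downsample(x, 500, 300), "integer multiple")
})

test_that("bad-channel interpolation uses inverse-distance weights", {
  nb <- manualNeighborhood(distances = c(1, 1, 1))
  x <- matrix(0, 4, 10)
  x[2, ] <- 1; x[3, ] <- 2; x[4, ] <- 3
  out <- interpolateBadChannels(x, 1, nb)
  expect_equal(out[1, ], rep(2, 10))             # unweighted mean
  # identical neighbor signals reproduce the signal
  x2 <- matrix(rep(sin(1:10), each = 4), 4, 10, byrow = FALSE)
  x2[2:4, ] <- rep(sin(1:10), each = 3)
  out2 <- interpolateBadChannels(rbind(0, x2[2:4, ]), 1, nb)
  expect_equal(out2[1, ], sin(1:10))
  # asymmetric distances: hand-computed inverse-distance weights
  nbA <- manualNeighborhood(distances = c(1, 2, 4))
  w <- (1 / c(1, 2, 4)) / sum(1 / c(1, 2, 4))
  expected <- sum(w * c(1, 2, 3))
  outA <- interpolateBadChannels(x, 1, nbA)
  expect_equal(outA[1, 1], expected, tolerance = 1e-12)
  # all neighbors bad -> error
  expect_error(interpolateBadChannels(x, c(1, 2, 3, 4), nb), "strict subset")
  nb5 <- manualNeighborhood(nChannels = 5)     # channel 1's neighbors: 2,3,4
  expect_error(interpolateBadChannels(matrix(0, 5, 10), 1:4, nb5),
               "all neighbors")
})

test_that("average reference zeroes channel means and is idempotent", {
  set.seed(5)
  x <- matrix(rnorm(32 * 100), 32)
  y <- rereferenceAverage(x)
  expect_lt(max(abs(colMeans(y))), 1e-12)
  expect_equal(rereferenceAverage(y), y, tolerance = 1e-14)
  # constant offset across channels is removed
  expect_equal(rereferenceAverage(x + 7), y, tolerance = 1e-12)
})

test_that("variance flagger spots a dead and a noisy channel", {
  set.seed(6)
  x <- matrix(rnorm(20 * 5000), 20)
  x[3, ] <- x[3, ] * 1e4
  expect_true(3 %in% flagBadChannels(x))
  expect_length(flagBadChannels(matrix(rnorm(20 * 5000), 20)), 0)
})

test_that("pre-movement epoch extraction uses a half-open window", {
  srate <- 250
  x <- matrix(seq_len(32 * 1000), 32)   # distinguishable samples
  res <- extractPremovementEpochs(x, onsets = 250, windowMs = c(-500, 0),
                                  srate = srate)
  expect_equal(dim(res$epochs), c(1, 32, 125))
  # covers samples 125..249, baseline-corrected per channel
  raw <- x[, 125:249]
  expect_equal(res$epochs[1, , ], raw - rowMeans(raw))
  # constant channel becomes all-zero
  xc <- matrix(5, 4, 600)
  rc <- extractPremovementEpochs(xc, onsets = 300, srate = srate)
  expect_equal(max(abs(rc$epochs)), 0)
  # one epoch per valid onset; early onsets dropped with a warning
  on10 <- seq(200, 1000, length.out = 10)
  r10 <- extractPremovementEpochs(x, onsets = round(on10), srate = srate)
  expect_equal(dim(r10$epochs)[1], 10)
  expect_warning(
    rEarly <- extractPremovementEpochs(x, onsets = c(50, 500), srate = srate),
    "dropped")
  expect_equal(rEarly$kept, 2L)
})

test_that("line-noise band-stop attenuates the mains tone", {
  srate <- 500; t <- (0:1999) / srate
  x <- sin(2 * pi * 50 * t) + sin(2 * pi * 10 * t)
  y <- lineNoiseFilter(x, srate, mainsHz = 50, widthHz = 3)
  sp <- function(v, f) {
    n <- length(v)
    Mod(fft(v))[round(f * n / srate) + 1]
  }
  expect_lt(sp(y, 50) / sp(x, 50), 0.2)
  expect_gt(sp(y, 10) / sp(x, 10), 0.9)
})
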