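# A noise-free single-label control built by hand: channel A carries a
# two-level signal, channel B an exact linear fraction of it.
exactControl <- function(k, brightnessA = 200, background = 0,
                         dim = c(6L, 12L, 12L)) {
  sig <- array(0, dim)
  sig[1:3, , ] <- brightnessA
  a <- array(0, c(2, dim))
  a[1, , , ] <- sig + background
  a[2, , , ] <- k * sig + background
  MultiChannelStack(a, c("A", "B"))
}

test_that("ratio distribution reflects exact mixing", {
  # unpopulated channel all zero -> every ratio 0, all mass in bin 1
  d0 <- ratioDistribution(exactControl(0), "A", "B")
  expect_identical(which(d0@counts > 0), 1L)
  expect_equal(sum(d0@counts), d0@nVoxels)
  expect_lt(crosstalkCoefficient(d0), (1.5 / 256) / 2 + 1e-12)

  # exact mixing at 0.10: every ratio is exactly 0.10, a single bin
  d1 <- ratioDistribution(exactControl(0.10), "A", "B")
  occupied <- which(d1@counts > 0)
  expect_length(occupied, 1L)
  centers <- (d1@breaks[-1] + d1@breaks[-length(d1@breaks)]) / 2
  expect_lt(abs(centers[occupied] - 0.10), (1.5 / 256) / 2 + 1e-12)
  # direct per-voxel division oracle: recompute ratios by hand
  s <- exactControl(0.10)
  fg <- getChannel(s, "A") > 100
  expect_true(all(abs(getChannel(s, "B")[fg] / getChannel(s, "A")[fg] -
                        0.10) < 1e-12))

  expect_error(ratioDistribution(exactControl(0.1), "A", "A"), "differ")
  # a constant stack has no calibration foreground
  flat <- MultiChannelStack(array(5, c(2, 4, 8, 8)), c("A", "B"))
  expect_error(suppressWarnings(ratioDistribution(flat, "A", "B")),
               "no calibration signal")
})

test_that("noisy ratio histograms peak at the true coefficient", {
  # k = 0.10 with additive noise; recompute the histogram independently
  set.seed(21)
  dim <- c(6L, 20L, 20L)
  sig <- array(0, dim); sig[1:3, , ] <- 200
  a <- array(0, c(2, dim))
  a[1, , , ] <- pmax(sig + rnorm(length(sig), sd = 2), 0)
  a[2, , , ] <- pmax(0.10 * sig + rnorm(length(sig), sd = 2), 0)
  s <- MultiChannelStack(a, c("A", "B"))
  d <- ratioDistribution(s, "A", "B", sigma = c(0, 0, 0))
  est <- crosstalkCoefficient(d)
  binw <- 1.5 / 256
  expect_lt(abs(est - 0.10), binw)      # mode in the bin containing 0.10
  # independent histogram: hist() over the same foreground ratios
  fg <- getChannel(s, "A") > liThreshold(getChannel(s, "A"))
  r <- getChannel(s, "B")[fg] / getChannel(s, "A")[fg]
  h <- hist(r[r >= 0 & r <= 1.5], breaks = seq(0, 1.5, length.out = 257),
            plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)] - est), binw + 1e-12)
})

test_that("the coefficient is the lowest bin among tied modes", {
  breaks <- seq(0, 1.5, length.out = 257)
  counts <- numeric(256)
  binOf <- function(v) floor(v / (1.5 / 256)) + 1
  counts[binOf(0.05)] <- 10
  counts[binOf(0.20)] <- 10
  counts[binOf(0.40)] <- 3
  d <- new("RatioDistribution", breaks = breaks, counts = counts,
           nVoxels = sum(counts), sourceChannel = "A",
           targetChannel = "B")
  expect_lt(abs(crosstalkCoefficient(d) - 0.05), (1.5 / 256) / 2 + 1e-12)
  empty <- new("RatioDistribution", breaks = breaks,
               counts = numeric(256), nVoxels = 0,
               sourceChannel = "A", targetChannel = "B")
  expect_error(crosstalkCoefficient(empty), "empty")
})

test_that("matrix estimation recovers rendered mixing coefficients", {
  # crosstalk-free controls -> identity matrix
  k0 <- estimateK(0, noiseSd = 0, dim = c(16, 32, 32))
  expect_lt(max(abs(k0 - diag(2))), (1.5 / 256) / 2 + 1e-12)

  # asymmetric three-channel truth, noise-free render
  species <- c("A", "B", "C")
  ktrue <- diag(3); dimnames(ktrue) <- list(species, species)
  ktrue["A", "B"] <- 0.05; ktrue["B", "C"] <- 0.10; ktrue["A", "C"] <- 0.02
  m <- imagingModel(species, brightness = 200, brightnessSdLog = 0.2,
                    background = 8, mixing = ktrue, noiseSd = 0, seed = 5)
  controls <- renderControls(species, m, dim = c(16, 32, 32), seed = 5)
  kest <- coefficients(buildCrosstalkMatrix(controls))
  expect_lt(max(abs(kest - ktrue)), (1.5 / 256) / 2 + 1e-12)

  expect_error(buildCrosstalkMatrix(controls[c("A", "B")]),
               "missing control")
})

test_that("the estimated coefficient is scale invariant", {
  # same true k rendered at two brightness levels -> same matrix
  kLo <- estimateK(0.10, noiseSd = 0, dim = c(16, 32, 32))
  m2 <- imagingModel(c("A", "B"), brightness = 2 * 200,
                     brightnessSdLog = 0.2, background = 8, mixing = 0.10,
                     psfSigma = c(0, 1, 1), noiseSd = 0, seed = 42)
  controls2 <- renderControls(c("A", "B"), m2, dim = c(16, 32, 32),
                              seed = 42)
  kHi <- coefficients(buildCrosstalkMatrix(controls2))
  expect_lt(max(abs(kHi - kLo)), 1.5 / 256 + 1e-12)  # within one bin
})

test_that("correction removes bleed-through", {
  species <- c("A", "B")
  idm <- CrosstalkMatrix(structure(diag(2),
                                   dimnames = list(species, species)))
  spec <- twoLayerSpec(dim = c(8L, 12L, 12L), split = 3L, top = 6L)
  truth <- makeScene(spec)
  m <- imagingModel(species, brightness = 200, brightnessSdLog = 0.2,
                    background = 0, mixing = 0.10, psfSigma = c(0, 0, 0),
                    noiseSd = 0, seed = 8)
  # one-directional mixing for the subtractive ground-truth check
  m@mixing["B", "A"] <- 0
  r <- renderScene(truth, m)

  # identity matrix -> identity map
  same <- correctStack(r$stack, idm)
  expect_equal(intensities(same), intensities(r$stack))

  # subtractive correction restores channel B's pre-mixing signal
  corr <- correctStack(r$stack, CrosstalkMatrix(r$mixing))
  sigB <- r$signal[2, , , ]
  expect_lt(max(abs(getChannel(corr, "B") - sigB)), 1e-9)

  # full unmixing solves the exact linear system
  m@mixing["B", "A"] <- 0.07
  r2 <- renderScene(truth, m)
  un <- correctStack(r2$stack, CrosstalkMatrix(r2$mixing),
                     method = "unmix")
  expect_lt(max(abs(intensities(un) -
                      array(r2$signal, dim(r2$signal)))), 1e-9)
  expect_true(all(intensities(un) >= 0))

  # singular matrix cannot be unmixed
  ks <- matrix(1, 2, 2, dimnames = list(species, species))
  expect_error(correctStack(r$stack, CrosstalkMatrix(ks),
                            method = "unmix"), "singular")
})

test_that("subtractive correction matches unmixing to first order", {
  spec <- twoLayerSpec(dim = c(8L, 12L, 12L), split = 3L, top = 6L)
  truth <- makeScene(spec)
  m <- imagingModel(c("A", "B"), brightness = 200, brightnessSdLog = 0,
                    background = 0, mixing = 0.10, psfSigma = c(0, 0, 0),
                    noiseSd = 0, seed = 8)
  r <- renderScene(truth, m)
  k <- CrosstalkMatrix(r$mixing)
  sub <- correctStack(r$stack, k, method = "subtractive")
  un <- correctStack(r$stack, k, method = "unmix")
  # discrepancy is second order: <= k^2 x mean foreground brightness
  expect_lte(max(abs(intensities(sub) - intensities(un))),
             0.10^2 * 200 + 1e-9)
})
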