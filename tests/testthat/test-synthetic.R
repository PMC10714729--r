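test_that("layer scenes honour their geometry exactly", {
  geom <- list(A = list(list(type = "layer", zlo = 0, zhi = 3)))
  truth <- makeScene(sceneSpec(c(10L, 8L, 8L), geom, seed = 1))
  expect_equal(unname(truth@sliceFraction["A", ]),
               c(rep(1, 4), rep(0, 6)))
  expect_equal(unname(shares(truth)), 100)

  spec <- twoLayerSpec(dim = c(10L, 8L, 8L), split = 5L, top = 10L)
  t2 <- makeScene(spec)
  expect_equal(unname(shares(t2)), c(50, 50))
  expect_false(any(occupancyMasks(t2)$A & occupancyMasks(t2)$B))
})

test_that("exclusive overlapping layers are rejected", {
  geom <- list(
    A = list(list(type = "layer", zlo = 0, zhi = 4)),
    B = list(list(type = "layer", zlo = 3, zhi = 7)))
  expect_error(makeScene(sceneSpec(c(10L, 8L, 8L), geom)),
               "overlaps")
  # the same request without exclusivity is allowed
  t0 <- makeScene(sceneSpec(c(10L, 8L, 8L), geom, exclusive = FALSE))
  expect_true(any(occupancyMasks(t0)$A & occupancyMasks(t0)$B))
})

test_that("generator shares equal composition on the truth masks", {
  set.seed(17)
  for (i in 1:10) {
    split <- sample(2:6, 1)
    spec <- twoLayerSpec(dim = c(8L, 10L, 10L), split = split, top = 8L,
                         seed = i)
    truth <- makeScene(spec)
    masks <- Map(asMask, occupancyMasks(truth), names(occupancyMasks(truth)))
    co <- composition(unname(masks))
    expect_equal(unname(shares(co)), unname(shares(truth)),
                 tolerance = 1e-12)
  }
})

test_that("sandwich geometry is flagged by layer ordering", {
  geom <- list(
    A = list(list(type = "layer", zlo = 0, zhi = 1),
             list(type = "layer", zlo = 6, zhi = 7)),
    B = list(list(type = "layer", zlo = 2, zhi = 5)))
  truth <- makeScene(sceneSpec(c(8L, 8L, 8L), geom, seed = 1))
  masks <- Map(asMask, occupancyMasks(truth), names(occupancyMasks(truth)))
  lo <- layerOrder(unname(masks))
  expect_true(lo[lo$channel == "A", "sandwich"])
  expect_false(lo[lo$channel == "B", "sandwich"])
})

test_that("rendering follows the linear mixing model exactly", {
  spec <- twoLayerSpec(dim = c(6L, 8L, 8L), split = 3L, top = 6L)
  truth <- makeScene(spec)
  # identity mixing, zero PSF/noise/background: channel == signal
  m0 <- imagingModel(c("A", "B"), brightness = 200, brightnessSdLog = 0.2,
                     background = 0, mixing = 0, psfSigma = c(0, 0, 0),
                     noiseSd = 0, seed = 6)
  r0 <- renderScene(truth, m0)
  expect_equal(intensities(r0$stack), r0$signal, tolerance = 1e-12)

  # k[A -> B] = 0.10: channel B = own signal + 0.10 x channel A signal
  m1 <- m0
  m1@mixing["A", "B"] <- 0.10
  r1 <- renderScene(truth, m1)
  expect_equal(getChannel(r1$stack, "B"),
               r1$signal[2, , , ] + 0.10 * r1$signal[1, , , ],
               tolerance = 1e-12)

  # fixed seed renders bit-identically
  r2 <- renderScene(truth, m1)
  expect_identical(intensities(r1$stack), intensities(r2$stack))

  # a scene re-generated from the same spec is identical too
  expect_identical(occupancyMasks(makeScene(spec)),
                   occupancyMasks(truth))
})

test_that("noise-free rendering plus segmentation recovers truth masks", {
  # 10x brightness/background separation, identity mixing, no PSF/noise
  spec <- twoLayerSpec(dim = c(8L, 12L, 12L), split = 4L, top = 8L)
  truth <- makeScene(spec)
  m <- imagingModel(c("A", "B"), brightness = 100, brightnessSdLog = 0,
                    background = 10, mixing = 0, psfSigma = c(0, 0, 0),
                    noiseSd = 0, seed = 9)
  stk <- renderScene(truth, m)$stack
  masks <- segmentStack(stk, sigma = c(0, 0, 0))
  expect_identical(maskArray(masks$A), occupancyMasks(truth)$A)
  expect_identical(maskArray(masks$B), occupancyMasks(truth)$B)
})

test_that("presets encode the documented phenotypes", {
  # exclusion: one species absent, the other a dense bottom biofilm
  pe <- biofilmPreset("exclusion_72h")
  te <- makeScene(pe$spec)
  expect_equal(sum(occupancyMasks(te)$SH1000), 0)
  expect_equal(unname(shares(te)), c(0, 100))

  # sandwich: three bands, outer species' edge shares beat its mid share
  ps <- biofilmPreset("dual_sandwich")
  ts <- makeScene(ps$spec)
  expect_equal(unname(shares(ts)), c(76, 24))
  masks <- Map(asMask, occupancyMasks(ts), names(occupancyMasks(ts)))
  lo <- layerOrder(unname(masks))
  expect_true(lo[lo$channel == "K279a", "sandwich"])

  # layered dual: thin bottom band vs dominant upper species
  pl <- biofilmPreset("dual_layered")
  tl <- makeScene(pl$spec)
  expect_equal(unname(shares(tl)), c(7, 93))

  # triple: disjoint bands, bottom species first in the layer order
  pt3 <- biofilmPreset("triple_layered")
  tt <- makeScene(pt3$spec)
  expect_equal(unname(shares(tt)), c(65.2, 4.4, 30.4), tolerance = 1e-3)
  masks3 <- Map(asMask, occupancyMasks(tt), names(occupancyMasks(tt)))
  lo3 <- layerOrder(unname(masks3))
  expect_identical(lo3$channel, c("K279a", "SH1000", "PAO1"))

  # hyphae grow from the base and carry satellite cells nearby
  ph <- biofilmPreset("dual_hypha")
  th <- makeScene(ph$spec)
  expect_gt(sum(occupancyMasks(th)$SC5314), 0)
  expect_gt(sum(occupancyMasks(th)$K279a), 0)
  expect_false(any(occupancyMasks(th)$SC5314 & occupancyMasks(th)$K279a))

  expect_error(biofilmPreset("no_such_preset"))
})

test_that("stack quantisation clamps to the 16-bit range", {
  a <- array(c(-3.2, 0.4, 200.6, 70000), c(1, 1, 2, 2))
  # bypass the non-negativity check via direct rendering-like input
  s <- MultiChannelStack(pmax(a, 0), "A")
  q <- quantizeStack(s)
  expect_true(all(intensities(q) == round(intensities(q))))
  expect_lte(max(intensities(q)), 65535)
})
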