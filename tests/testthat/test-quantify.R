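test_that("slice profiles count voxels exactly", {
  full <- asMask(array(TRUE, c(4, 4, 4)), "A")
  p <- sliceProfile(full)
  expect_equal(p@sliceFraction, rep(1, 4))
  expect_equal(p@totalFraction, 1)

  m <- array(FALSE, c(2, 3, 3)); m[1, 2, 2] <- TRUE
  p1 <- sliceProfile(asMask(m, "A"))
  expect_equal(p1@sliceFraction, c(1 / 9, 0))
  expect_equal(p1@totalFraction, 1 / 18)
  expect_equal(p1@occupiedVoxels, 1)

  empty <- sliceProfile(asMask(array(FALSE, c(3, 2, 2)), "A"))
  expect_equal(empty@sliceFraction, rep(0, 3))
  expect_equal(empty@totalFraction, 0)

  # physical volume scales with the voxel volume
  pv <- sliceProfile(asMask(m, "A"), voxelSize = c(0.5, 0.2, 0.2))
  expect_equal(pv@physicalVolume, 1 * 0.5 * 0.2 * 0.2)
})

test_that("per-slice sums are conserved for arbitrary masks", {
  set.seed(31)
  for (i in 1:25) {
    d <- c(sample(2:6, 1), sample(3:8, 1), sample(3:8, 1))
    m <- array(runif(prod(d)) < runif(1), d)
    p <- sliceProfile(asMask(m, "A"))
    expect_identical(sum(apply(m, 1, sum)), as.integer(p@occupiedVoxels))
    expect_equal(sum(p@sliceFraction * d[2] * d[3]), p@occupiedVoxels)
  }
})

test_that("composition shares follow the cell-ratio definition", {
  mk <- function(n, ch, d = c(4, 5, 5)) {
    m <- array(FALSE, d); if (n > 0) m[seq_len(n)] <- TRUE
    asMask(m, ch)
  }
  # two channels occupying 76 and 24 voxels -> 76% / 24%
  co <- composition(list(mk(76, "K279a"), mk(24, "SH1000")))
  expect_equal(unname(shares(co)), c(76, 24))
  expect_equal(sum(shares(co)), 100, tolerance = 1e-9)

  co2 <- composition(list(mk(0, "A"), mk(40, "B")))
  expect_equal(unname(shares(co2)), c(0, 100))

  co3 <- composition(list(mk(10, "A"), mk(10, "B"), mk(20, "C")))
  expect_equal(unname(shares(co3)), c(25, 25, 50))

  # all-empty input is flagged, not an error
  co4 <- composition(list(mk(0, "A"), mk(0, "B")))
  expect_true(co4@degenerate)
  expect_equal(unname(shares(co4)), c(0, 0))

  # overlapping voxels count for both channels and are reported
  m1 <- mk(20, "A"); m2 <- mk(10, "B")   # B's voxels inside A's
  co5 <- composition(list(m1, m2))
  expect_equal(unname(shares(co5)), c(200 / 3, 100 / 3))
  expect_equal(co5@overlapFraction, 10 / 20)

  expect_error(composition(list(mk(2, "A"), mk(2, "B", d = c(3, 5, 5)))),
               "mismatched")
})

test_that("replicate summaries match closed forms", {
  prof <- function(fracs, ch = "A") {
    nz <- length(fracs)
    # build via explicit voxel counts: fracs must be multiples of 1/4
    m <- array(FALSE, c(nz, 2, 2))
    for (z in seq_len(nz)) if (fracs[z] > 0)
      m[z, , ][seq_len(round(fracs[z] * 4))] <- TRUE
    sliceProfile(asMask(m, ch))
  }
  # three identical profiles -> mean = profile, SD = 0
  p <- prof(c(1, 0.5, 0))
  rs <- averageReplicates(list(p, p, p))
  expect_equal(rs@meanSlice, p@sliceFraction)
  expect_equal(rs@sdSlice, rep(0, 3))
  expect_equal(rs@meanTotal, p@totalFraction)
  expect_equal(rs@sdTotal, 0)

  # totals {0.2, 0.4} -> mean 0.3, SD sqrt(0.02); slice-wise {0,1},{1,0}
  # -> mean 0.5, SD sqrt(0.5) per slice
  pa <- prof(c(0, 1)); pb <- prof(c(1, 0))
  rs2 <- averageReplicates(list(pa, pb))
  expect_equal(rs2@meanSlice, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(rs2@sdSlice, rep(sqrt(0.5), 2), tolerance = 1e-9)
  pc <- prof(c(0.25, 0.5, 0.25, 0.25, 0.25, 0.25, 0.25, 0))  # total 0.25
  pd <- prof(c(0.75, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.25))    # total 0.5
  expect_equal(pc@totalFraction, 0.25)
  expect_equal(pd@totalFraction, 0.5)
  rs3 <- averageReplicates(list(pc, pd))
  expect_equal(rs3@meanTotal, 0.375, tolerance = 1e-9)
  expect_equal(rs3@sdTotal, sd(c(0.25, 0.5)), tolerance = 1e-9)

  expect_error(averageReplicates(list(p)), "at least 2")
  expect_error(averageReplicates(list(p, prof(c(1, 0)))), "mismatched")
  expect_error(averageReplicates(list(p, prof(c(1, 0, 0), ch = "B"))),
               "mix channels")
})

test_that("volume comparison matches the Welch formula", {
  a <- c(10, 11, 12); b <- c(20, 21, 22)
  got <- compareVolumes(a, b)
  want <- welchOracle(a, b)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(got$df, want$df, tolerance = 1e-9)
  expect_equal(got$p.value, want$p.value, tolerance = 1e-9)

  # equal groups with spread: t = 0, p = 1
  same <- compareVolumes(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # identical constant groups are a defined edge case; different constant
  # groups are not
  expect_equal(compareVolumes(c(2, 2), c(2, 2))$p.value, 1)
  expect_error(compareVolumes(c(1, 1), c(2, 2)), "zero variance")
  expect_error(compareVolumes(1, c(1, 2)), "at least 2")
})

test_that("layer order and sandwich flags describe vertical structure", {
  bandMask <- function(zs, ch, nz, d = c(4, 4)) {
    m <- array(FALSE, c(nz, d))
    m[zs + 1, , ] <- TRUE
    asMask(m, ch)
  }
  # A fills slices 0-2, B slices 3-5: order [A, B], no sandwich
  lo <- layerOrder(list(bandMask(0:2, "A", 6), bandMask(3:5, "B", 6)))
  expect_identical(lo$channel, c("A", "B"))
  expect_false(any(lo$sandwich))

  # A in slices 0-1 and 6-7 of 8, B in 2-5: A sandwich, B not
  lo2 <- layerOrder(list(bandMask(c(0, 1, 6, 7), "A", 8),
                         bandMask(2:5, "B", 8)))
  a <- lo2[lo2$channel == "A", ]
  expect_true(a$sandwich)
  expect_equal(a$bottomShare, 0.5); expect_equal(a$topShare, 0.5)
  expect_equal(a$midShare, 0)
  expect_false(lo2[lo2$channel == "B", ]$sandwich)

  # single channel
  lo3 <- layerOrder(list(bandMask(1:2, "only", 5)))
  expect_identical(lo3$channel, "only")

  expect_error(layerOrder(list(bandMask(integer(0), "A", 4))), "empty")
})
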