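# Boundary tracing, cleft-centre location, extrema search, the three
# indices, filters and unit conversions — validated on analytic fixtures.

# slab mask with a V notch of given apex half-angle carved at x = ax
slabWithV <- function(width = 120, height = 90, surfaceY = 30, depth = 30,
                      halfAngleDeg = 30, ax = width / 2, margin = 10) {
  mask <- matrix(0L, width, height)
  mask[(margin + 1):(width - margin), surfaceY:(height - margin)] <- 1L
  hw <- depth * tan(halfAngleDeg * pi / 180)
  for (y in surfaceY:(surfaceY + depth)) {
    t <- (y - surfaceY) / depth
    lo <- max(1, ax - hw * (1 - t)); hi <- min(width, ax + hw * (1 - t))
    xr <- seq.int(ceiling(lo), floor(hi))
    if (length(xr) && hi >= lo) mask[xr, y] <- 0L
  }
  mask
}

test_that("boundary tracing returns the ordered epithelium-matrix contour", {
  mask <- matrix(0L, 20, 20)
  mask[6:15, 6:15] <- 1L                      # 10x10 solid block
  tr <- traceBoundary(mask)
  expect_equal(nrow(tr), 36)                  # border sites of a 10x10 block
  expect_true(isTRUE(attr(tr, "closed")))
  # consecutive points 8-connected, no repeats
  n <- nrow(tr)
  gaps <- pmax(abs(diff(tr[, 1])), abs(diff(tr[, 2])))
  expect_true(all(gaps == 1))
  expect_equal(max(abs(tr[1, ] - tr[n, ])), 1)
  expect_equal(nrow(unique(tr)), n)
  # counter-clockwise normalization: positive shoelace area
  nxt <- c(2:n, 1)
  expect_gt(sum(tr[, 1] * tr[nxt, 2] - tr[nxt, 1] * tr[, 2]) / 2, 0)

  expect_error(traceBoundary(matrix(0L, 5, 5)), "0 components")
  two <- matrix(0L, 20, 20); two[2:4, 2:4] <- 1L; two[10:12, 10:12] <- 1L
  expect_error(traceBoundary(two), "found 2")
})

test_that("the cleft centre is the lowest 8-distance neighbour angle", {
  # straight boundary: all interior angles are 180 degrees, nothing is
  # cleft-like
  mask <- matrix(0L, 60, 40); mask[11:50, 16:30] <- 1L
  tr <- traceBoundary(mask)
  ang <- cleftsim:::traceAngles(tr, 8L)
  onTop <- which(tr[, 2] == 16 & tr[, 1] > 20 & tr[, 1] < 40)
  expect_true(all(ang[onTop] > 175))
  expect_true(is.na(findCleftCenter(tr, candidates = onTop)))

  # synthetic V with a 60-degree apex: the centre lands on the apex
  mask <- slabWithV(halfAngleDeg = 30)
  tr <- traceBoundary(mask)
  ctr <- findCleftCenter(tr)
  expect_false(is.na(ctr))
  apex <- tr[ctr, ]
  expect_lte(abs(apex[1] - 60), 1.5)
  expect_lte(abs(apex[2] - 60), 1.5)          # surfaceY 30 + depth 30

  # two Vs, 60 and 120 degrees: the sharper apex wins
  mask2 <- slabWithV(width = 260, halfAngleDeg = 60, ax = 180)
  hw <- 30 * tan(pi / 6)
  for (y in 30:60) {                           # carve the 60-degree V at 70
    t <- (y - 30) / 30
    xr <- seq.int(ceiling(70 - hw * (1 - t)), floor(70 + hw * (1 - t)))
    mask2[xr, y] <- 0L
  }
  tr2 <- traceBoundary(mask2)
  ctr2 <- findCleftCenter(tr2)
  expect_lte(abs(tr2[ctr2, 1] - 70), 2)
})

test_that("extrema growth stops when the line-fit MSE exceeds the threshold", {
  mask <- slabWithV()
  tr <- traceBoundary(mask)
  ctr <- findCleftCenter(tr)
  ext <- findExtrema(tr, ctr, mseThreshold = 2)
  # extrema near the cleft mouth (y ~ surface, x ~ ax +- hw)
  expect_lt(max(abs(tr[ext, 2] - 30)), 4)

  # threshold 0 on a non-collinear side returns the minimal window
  ext0 <- findExtrema(tr, ctr, mseThreshold = 0)
  expect_lte(abs(ext0[["left"]] - ctr), 2 + nrow(tr) * 0 + 2)

  # perfectly straight side: MSE stays 0 and the window runs to its cap
  maskL <- matrix(0L, 60, 60); maskL[11:50, 21:50] <- 1L
  trL <- traceBoundary(maskL)
  onTop <- which(trL[, 2] == 21)
  mid <- onTop[which.min(abs(trL[onTop, 1] - 30))]
  extL <- findExtrema(trL, mid, mseThreshold = 0.5, maxSpan = 8)
  expect_true(any(attr(extL, "exhausted")))

  # wall turning 90 degrees at a known point stops within 2 points of it
  ext2 <- findExtrema(trL, mid, mseThreshold = 0.5)
  # the top edge is straight until the corners at x = 11 / x = 50
  expect_lte(abs(trL[ext2[["left"]], 1] - c(50)), 2 + 40)  # reached a corner
  cornerDist <- min(abs(trL[ext2, 1] - 11), abs(trL[ext2, 1] - 50))
  expect_lte(cornerDist, 2)
})

test_that("depth, spanning and tilt match vector-geometry oracles", {
  # symmetric right angle: depth 10, spanning 90, tilt 90
  m <- measureCleft(c(0, 0), rbind(c(-10, 10), c(10, 10)))
  expect_equal(m$depth_px, 10)
  expect_equal(m$spanning_deg, 90)
  expect_equal(m$tilt_deg, 90)

  # asymmetric case, frozen from an independent oracle:
  #   depth = |(5,10)| = 11.1803; spanning via atan2: |atan2(10,0) -
  #   atan2(10,10)| = 45 deg (law of cosines agrees); tilt between segment
  #   direction (10,0) and (5,10): acos(50/(10*11.1803)) = 63.4349 deg
  m <- measureCleft(c(0, 0), rbind(c(0, 10), c(10, 10)))
  expect_equal(m$depth_px, sqrt(125), tolerance = 1e-9)
  expect_equal(m$spanning_deg, 45, tolerance = 1e-9)
  expect_equal(m$tilt_deg, 63.43495, tolerance = 1e-4)

  # ranges always hold
  set.seed(8)
  for (i in 1:50) {
    pts <- matrix(runif(6, -20, 20), 3, 2)
    m <- measureCleft(pts[1, ], pts[2:3, ])
    if (m$status == "invalid") next
    expect_gt(m$spanning_deg, 0); expect_lte(m$spanning_deg, 180)
    expect_gte(m$tilt_deg, 0); expect_lte(m$tilt_deg, 90)
  }

  # degenerate geometry flagged
  expect_equal(measureCleft(c(0, 0), rbind(c(0, 0), c(1, 1)))$status,
               "invalid")
})

test_that("filters apply at the published thresholds in precedence order", {
  row <- function(depth, span, tilt)
    data.frame(depth_px = depth, spanning_deg = span, tilt_deg = tilt,
               status = "valid")
  expect_equal(applyFilters(row(4.9, 60, 80))$status, "discarded_shallow")
  expect_equal(applyFilters(row(5.0, 60, 80))$status, "valid")
  expect_equal(applyFilters(row(20, 161, 80))$status, "discarded_wide")
  expect_equal(applyFilters(row(20, 160, 80))$status, "valid")
  expect_equal(applyFilters(row(20, 60, 44))$status, "failed_tilt")
  expect_equal(applyFilters(row(20, 60, 45))$status, "valid")
  # precedence: shallow beats wide beats tilt
  expect_equal(applyFilters(row(3, 170, 10))$status, "discarded_shallow")
  expect_equal(applyFilters(row(20, 170, 10))$status, "discarded_wide")
})

test_that("unit conversions match the published calibration", {
  expect_equal(mcsToHours(1500), 20)                   # 48 s per MCS
  expect_equal(pxToUm(34.1), 36.146)                   # x 1.06
  expect_equal(pxToUm(10, unitConversions(umPerPx = 1)), 10)
  m <- data.frame(depth_px = 34.1, depth_um = NA, mcs = 1500)
  m <- convertUnits(m)
  expect_equal(m$depth_um, 36.146)
  expect_equal(m$time_h, 20)
})

test_that("synthetic fixtures are recovered within 1 px / 3 degrees", {
  cases <- list(
    list(shape = "V", depth = 30, hw = 12, off = 0),
    list(shape = "V", depth = 36, hw = 15, off = 0),
    list(shape = "V", depth = 28, hw = 10, off = 4),   # tilted apex
    list(shape = "U", depth = 30, hw = 8, off = 0),
    list(shape = "U", depth = 32, hw = 12, off = 4))
  for (cs in cases) {
    mask <- syntheticCleftMask(depth = cs$depth, mouthHalfWidth = cs$hw,
                               apexOffset = cs$off, shape = cs$shape)
    truth <- attr(mask, "truth")
    m <- measureClefts(mask, refineMouth = TRUE)
    expect_equal(nrow(m), 1)
    expect_lte(abs(m$depth_px - truth$depth), 1.05)
    expect_lte(abs(m$spanning_deg - truth$spanning), 3)
    expect_lte(abs(m$tilt_deg - truth$tilt), 3)
  }
})

test_that("measurements are equivariant under quarter-turn rotation", {
  mask <- syntheticCleftMask(depth = 30, mouthHalfWidth = 12)
  m0 <- measureClefts(mask, refineMouth = TRUE)
  m90 <- measureClefts(rotateMask90(mask), refineMouth = TRUE)
  expect_lt(abs(m0$depth_px - m90$depth_px), 1)
  expect_lt(abs(m0$spanning_deg - m90$spanning_deg), 2)
  expect_lt(abs(m0$tilt_deg - m90$tilt_deg), 2)
})

test_that("multi-cleft extraction masks each detected span and repeats", {
  mask <- slabWithV(width = 200, halfAngleDeg = 25, ax = 60)
  hw <- 30 * tan(35 * pi / 180)
  for (y in 30:60) {
    t <- (y - 30) / 30
    xr <- seq.int(ceiling(140 - hw * (1 - t)), floor(140 + hw * (1 - t)))
    mask[xr, y] <- 0L
  }
  m <- measureClefts(mask, nClefts = 2)
  expect_equal(nrow(m), 2)
  expect_equal(sort(round(m$cx, -1)), c(60, 140))
})
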