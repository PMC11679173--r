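test_that("binarize matches per-pixel comparison", {
  expect_true(all(maskData(binarize(probMask(matrix(0.6, 5, 5)), 0.5))))
  expect_false(any(maskData(binarize(probMask(matrix(0.6, 5, 5)), 0.7))))
  set.seed(2)
  p <- matrix(runif(40 * 30), 40, 30)
  expect_identical(maskData(binarize(probMask(p), 0.37)), p >= 0.37)
  expect_error(binarize(probMask(p), 1), class = "nailsenseParameterError")
})

test_that("majority fill closes pinholes and matches the sliding-window oracle", {
  m <- matrix(FALSE, 30, 30)
  m[6:25, 6:25] <- TRUE
  m[15, 15] <- FALSE                      # interior pinhole
  out <- maskData(fillHolesMedian(binMask(m), 3))
  expect_true(out[15, 15])
  expect_false(any(maskData(fillHolesMedian(binMask(matrix(FALSE, 8, 8)), 3))))
  ## checkerboard and random masks against the brute-force majority
  chk <- outer(1:12, 1:12, function(r, cc) (r + cc) %% 2 == 0)
  expect_identical(maskData(fillHolesMedian(binMask(chk), 3)),
                   bruteMajority(chk, 3))
  set.seed(3)
  for (k in c(3, 5)) {
    r <- randomMask(17, 23, 0.5)
    expect_identical(maskData(fillHolesMedian(binMask(r), k)),
                     bruteMajority(r, k))
  }
  expect_error(fillHolesMedian(binMask(m), 4),
               class = "nailsenseParameterError")
})

test_that("erosion shrinks a full square by floor(k/2) per edge", {
  m <- matrix(TRUE, 100, 100)
  out <- maskData(erodeMask(binMask(m), 21))
  expected <- matrix(FALSE, 100, 100)
  expected[11:90, 11:90] <- TRUE          # centered 80x80
  expect_identical(out, expected)
  expect_false(any(maskData(erodeMask(binMask(matrix(FALSE, 20, 20)), 7))))
})

test_that("erosion matches the brute-force oracle, including even elements", {
  set.seed(4)
  for (k in c(2, 3, 5, 6)) {
    m <- randomMask(25, 19, 0.8)
    expect_identical(maskData(erodeMask(binMask(m), k)), bruteErode(m, k))
  }
})

test_that("erosion is anti-extensive and monotone in the element side", {
  set.seed(6)
  m <- randomMask(40, 40, 0.85)
  prev <- m
  for (k in c(2, 3, 5, 9)) {
    cur <- maskData(erodeMask(binMask(m), k))
    expect_true(all(cur <= m))            # output subset of input
    expect_true(all(cur <= prev))         # larger element -> subset
    prev <- cur
  }
})

test_that("a 3-px bridge between blobs is severed by erode_filter = 5", {
  m <- matrix(FALSE, 40, 100)
  m[6:35, 6:35] <- TRUE
  m[6:35, 61:90] <- TRUE
  m[19:21, 36:60] <- TRUE                 # 3-px-wide bridge
  expect_equal(floodFillCount(m), 1)
  out <- maskData(erodeMask(binMask(m), 5))
  expect_equal(floodFillCount(out), 2)
  expect_length(extractNailContours(binMask(out), 1), 2)
})

test_that("contour extraction filters by area and orders by descending area", {
  m <- matrix(FALSE, 30, 30)
  m[2:6, 2:11] <- TRUE                    # 50 px
  m[20:24, 20:25] <- TRUE                 # 30 px
  cts <- extractNailContours(binMask(m), 10)
  expect_length(cts, 2)
  expect_equal(vapply(cts, contourArea, integer(1)), c(50L, 30L))
  expect_length(extractNailContours(binMask(m), 40), 1)
  expect_length(extractNailContours(binMask(matrix(FALSE, 5, 5)), 1), 0)
})

test_that("component counts agree with a flood-fill oracle on random masks", {
  set.seed(7)
  for (i in 1:200) {
    m <- randomMask(64, 64, runif(1, 0.15, 0.6))
    lab <- nailsense:::labelComponents(m)
    expect_identical(lab$n, floodFillCount(m))
    ## labels partition exactly the TRUE pixels
    expect_identical(lab$labels > 0L, m)
  }
})

test_that("five-finger partition tiles the width with the remainder on the last band", {
  p <- makeFingerPartition(800, 800)
  spans <- t(vapply(fingerRegions(p), function(r) c(r@x0, r@x1),
                    integer(2)))
  expect_equal(spans[, 1], c(0L, 160L, 320L, 480L, 640L))
  expect_equal(spans[, 2], c(160L, 320L, 480L, 640L, 800L))
  p7 <- makeFingerPartition(7, 10)
  w <- vapply(fingerRegions(p7), function(r) r@x1 - r@x0, integer(1))
  expect_equal(w, c(1L, 1L, 1L, 1L, 3L))
  expect_error(makeFingerPartition(4, 10), class = "nailsenseParameterError")
})

test_that("contours are assigned by centroid, largest kept, one per finger", {
  part <- makeFingerPartition(800, 600)
  mk <- function(x0, y0, w, h) {
    g <- expand.grid(x = x0:(x0 + w - 1), y = y0:(y0 + h - 1))
    nailsense:::newContour(cbind(x = g$x, y = g$y))
  }
  big <- mk(200, 100, 10, 8)     # centroid x ~204, region 2, 80 px
  small <- mk(260, 300, 6, 5)    # region 2, 30 px
  mid <- mk(395, 50, 11, 9)      # centroid x 400 -> region 3
  out <- assignContours(list(small, big, mid), part)
  expect_null(out[[1]])
  expect_equal(contourArea(out[[2]]), 80L)
  expect_equal(fingerIndex(out[[2]]), 2L)
  expect_equal(fingerIndex(out[[3]]), 3L)
  expect_null(out[[4]]); expect_null(out[[5]])
  ## no contour is ever assigned twice
  idx <- vapply(out[!vapply(out, is.null, logical(1))], fingerIndex,
                integer(1))
  expect_false(anyDuplicated(idx) > 0)
})

test_that("region scaling shrinks and grows areas toward the factor", {
  g <- expand.grid(x = 10:19, y = 20:29)           # 10x10 square
  ct <- nailsense:::newContour(cbind(x = g$x, y = g$y))
  expect_identical(contourPixels(scaleRegion(ct, 1)), contourPixels(ct))
  half <- scaleRegion(ct, 0.5)
  expect_lte(contourArea(half), 50L)
  expect_gte(contourArea(half), 1L)
  m <- matrix(FALSE, 40, 40)
  m[contourPixels(half)[, 2] + 1, contourPixels(half)[, 1] + 1] <- TRUE
  expect_equal(floodFillCount(m), 1)               # still connected
  grown <- scaleRegion(ct, 2, rect(0, 0, 60, 60))
  expect_gte(contourArea(grown), 200L)
  clipped <- scaleRegion(ct, 3, rect(10, 20, 20, 30))
  expect_equal(contourArea(clipped), 100L)         # cannot grow past clip
  expect_error(scaleRegion(ct, 0.1), class = "nailsenseParameterError")
})
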