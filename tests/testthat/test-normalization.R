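test_that("patch layout follows the stated geometry rule", {
  lay <- makePatchLayout(800, 800, 0.05)
  expect_equal(lay@patchSide, 40L)
  corn <- lapply(lay@corners, function(r) c(r@x0, r@y0, r@x1, r@y1))
  expect_setequal(vapply(corn, paste, character(1), collapse = ","),
                  c("0,0,40,40", "760,0,800,40", "0,760,40,800",
                    "760,760,800,800"))
  cent <- lapply(lay@centrals, function(r) c(r@x0, r@y0, r@x1, r@y1))
  expect_equal(cent[[2]], c(380, 0, 420, 40))

  small <- makePatchLayout(100, 100, 0.05)
  expect_equal(small@patchSide, 5L)
  rects <- c(small@corners, small@centrals)
  expect_length(rects, 7L)
  for (i in seq_along(rects)) for (j in seq_along(rects))
    if (i < j) expect_false(nailsense:::rectsIntersect(rects[[i]],
                                                       rects[[j]]))
  expect_error(makePatchLayout(800, 800, 0.5),
               class = "nailsenseParameterError")
})

patchedImage <- function(side, corner_col, central_col, fill = c(128, 128, 128)) {
  lay <- makePatchLayout(side, side, 0.05)
  px <- array(0L, dim = c(side, side, 3))
  for (ch in 1:3) px[, , ch] <- fill[ch]
  for (r in lay@corners) for (ch in 1:3)
    px[nailsense:::rectRows(r), nailsense:::rectCols(r), ch] <- corner_col[ch]
  for (r in lay@centrals) for (ch in 1:3)
    px[nailsense:::rectRows(r), nailsense:::rectCols(r), ch] <- central_col[ch]
  list(img = rgbImage(px), lay = lay)
}

test_that("reference extraction uses per-channel min over corners, max over centrals", {
  p <- patchedImage(100, c(10, 12, 14), c(240, 238, 236))
  refs <- extractReferences(p$img, p$lay)
  expect_equal(refBlack(refs), c(10, 12, 14))
  expect_equal(refWhite(refs), c(240, 238, 236))

  ## one darker corner pixel drags the min down
  px <- pixelArray(p$img)
  px[1, 1, ] <- c(0L, 5L, 5L)
  refs2 <- extractReferences(rgbImage(px), p$lay)
  expect_equal(refBlack(refs2), c(0, 5, 5))

  flat <- patchedImage(100, c(50, 50, 50), c(50, 50, 50))
  expect_error(extractReferences(flat$img, flat$lay),
               class = "nailsenseDegenerateReferenceError")
})

test_that("reference extraction is invariant to patch ordering", {
  set.seed(11)
  px <- array(sample(0:255, 100 * 100 * 3, replace = TRUE),
              dim = c(100, 100, 3))
  img <- rgbImage(px)
  lay <- makePatchLayout(100, 100, 0.05)
  shuffled <- new("PatchLayout", corners = lay@corners[c(3, 1, 4, 2)],
                  centrals = lay@centrals[c(2, 3, 1)],
                  patchSide = lay@patchSide)
  for (st in c("minmax", "patchmean")) {
    a <- extractReferences(img, lay, st)
    b <- extractReferences(img, shuffled, st)
    expect_equal(refBlack(a), refBlack(b))
    expect_equal(refWhite(a), refWhite(b))
  }
})

test_that("normalizeValue matches the linear map with clipping", {
  expect_equal(normalizeValue(20, 20, 220), 0)
  expect_equal(normalizeValue(220, 20, 220), 1)
  expect_equal(normalizeValue(120, 20, 220), 0.5)
  expect_equal(normalizeValue(10, 20, 220), 0)   # clipped below
  expect_equal(normalizeValue(255, 20, 220), 1)  # clipped above
  expect_error(normalizeValue(100, 100, 100),
               class = "nailsenseDegenerateReferenceError")
  ## monotone in I for fixed references
  v <- normalizeValue(0:255, 30, 200)
  expect_true(all(diff(v) >= 0))
})

test_that("normalizeImage equals element-wise normalizeValue", {
  set.seed(5)
  px <- array(sample(0:255, 12 * 9 * 3, replace = TRUE), dim = c(12, 9, 3))
  img <- rgbImage(px)
  refs <- new("ReferenceValues", black = c(10, 20, 5),
              white = c(240, 230, 250))
  out <- etaArray(normalizeImage(img, refs))
  for (ch in 1:3) for (r in 1:12) for (cc in 1:9)
    expect_identical(out[r, cc, ch],
                     normalizeValue(px[r, cc, ch], refBlack(refs)[ch],
                                    refWhite(refs)[ch]))
  ## constants at the reference levels map to all-zero / all-one
  blackImg <- rgbImage(array(rep(c(10L, 20L, 5L), each = 12 * 9),
                             dim = c(12, 9, 3)))
  expect_true(all(etaArray(normalizeImage(blackImg, refs)) == 0))
  whiteImg <- rgbImage(array(rep(c(240L, 230L, 250L), each = 12 * 9),
                             dim = c(12, 9, 3)))
  expect_true(all(etaArray(normalizeImage(whiteImg, refs)) == 1))
})

test_that("normalization cancels per-channel affine illumination", {
  for (seed in 1:4) {
    fx <- generateHand(smallSpec(seed = seed, gains = 1, offsets = 0))
    img0 <- fixtureImage(fx)
    gains <- c(0.8, 0.7, 0.9)
    offsets <- c(15, 25, 8)
    img1 <- applyIllumination(img0, gains, offsets)
    lay <- makePatchLayout(400, 400, 0.05)
    n0 <- normalizeImage(img0, extractReferences(img0, lay))
    n1 <- normalizeImage(img1, extractReferences(img1, lay))
    expect_lt(max(abs(etaArray(n0) - etaArray(n1))), 2 / 255)
  }
})

test_that("patch-mean reference mode is unbiased under zero-mean noise", {
  fx <- generateHand(syntheticHandSpec(seed = 3, gains = 0.8,
                                       offsets = 10, noise_sd = 2))
  lay <- makePatchLayout(800, 800, 0.05)
  refs <- extractReferences(fixtureImage(fx), lay, "patchmean")
  expect_true(all(abs(refBlack(refs) - 10) < 0.5))
  expect_true(all(abs(refWhite(refs) - (0.8 * 255 + 10)) < 0.5))
  ## strict min/max sits several noise SDs beyond the true levels
  strict <- extractReferences(fixtureImage(fx), lay, "minmax")
  expect_true(all(refBlack(strict) < refBlack(refs)))
  expect_true(all(refWhite(strict) > refWhite(refs)))
})
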