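test_that("generation is deterministic for a fixed seed", {
  a <- generateHand(smallSpec(seed = 42))
  b <- generateHand(smallSpec(seed = 42))
  expect_identical(pixelArray(fixtureImage(a)), pixelArray(fixtureImage(b)))
  expect_identical(maskData(fixtureMask(a)), maskData(fixtureMask(b)))
  c <- generateHand(smallSpec(seed = 43))
  expect_false(identical(pixelArray(fixtureImage(a)),
                         pixelArray(fixtureImage(c))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(77); before <- runif(3)
  set.seed(77); invisible(generateHand(smallSpec(seed = 5)))
  expect_identical(runif(3), before)
})

test_that("occluded fingers are absent from the ground truth", {
  fx <- generateHand(smallSpec(seed = 1, occlude = 1L))
  expect_equal(floodFillCount(maskData(fixtureMask(fx))), 4)
  expect_true(fixtureTruth(fx)$occluded[1])
  expect_equal(fixtureTruth(fx)$area[1], 0L)
  fx2 <- generateHand(smallSpec(seed = 1, occlude = c(2L, 5L)))
  expect_equal(floodFillCount(maskData(fixtureMask(fx2))), 3)
})

test_that("identity illumination with zero noise renders true colors exactly", {
  fx <- generateHand(smallSpec(seed = 1, gains = 1, offsets = 0,
                               noise_sd = 0))
  px <- pixelArray(fixtureImage(fx))
  gt <- maskData(fixtureMask(fx))
  tr <- fixtureTruth(fx)
  part <- makeFingerPartition(400, 400)
  for (i in 1:5) {
    r <- part@regions[[i]]
    sub <- gt
    sub[, -((r@x0 + 1):r@x1)] <- FALSE    # this finger's nail only
    for (ch in 1:3) {
      plane <- px[, , ch]
      expect_true(all(plane[sub] == tr[i, c("R", "G", "B")][[ch]]))
    }
  }
})

test_that("ground-truth areas equal brute-force ellipse rasterization", {
  fx <- generateHand(smallSpec(seed = 2, noise_sd = 0))
  tr <- fixtureTruth(fx)
  sp <- fixtureSpec(fx)
  for (i in 1:5) {
    cnt <- 0L
    for (x in 0:399) for (y in 0:399)
      if (((x - tr$cx[i]) / sp@nailAxes[i, 1])^2 +
          ((y - tr$cy[i]) / sp@nailAxes[i, 2])^2 <= 1) cnt <- cnt + 1L
    expect_equal(tr$area[i], cnt)
  }
})

test_that("reference extraction inverts the rendered illumination", {
  fx <- generateHand(smallSpec(seed = 3, gains = c(0.7, 0.8, 0.85),
                               offsets = c(10, 20, 30), noise_sd = 0))
  refs <- extractReferences(fixtureImage(fx), makePatchLayout(400, 400))
  expect_true(all(abs(refBlack(refs) - c(10, 20, 30)) <= 1))
  expect_true(all(abs(refWhite(refs) -
                      (c(0.7, 0.8, 0.85) * 255 + c(10, 20, 30))) <= 1))
})

test_that("specs that would clip under illumination are rejected", {
  expect_error(generateHand(smallSpec(gains = 1.1, offsets = 30)),
               class = "nailsenseParameterError")
  expect_error(generateHand(smallSpec(gains = 1, offsets = 5)),
               class = "nailsenseParameterError")
  ## same spec passes once clipping is explicitly enabled
  fx <- generateHand(smallSpec(gains = 1.1, offsets = 30, allow_clip = TRUE))
  expect_lte(max(pixelArray(fixtureImage(fx))), 255)
  ## geometry that leaves the finger band is rejected
  bad <- smallSpec(nail_axes = c(60, 31))
  expect_error(generateHand(bad), class = "nailsenseParameterError")
})

test_that("evaluation sets are written in reproducible pairs with sidecars", {
  root <- withr::local_tempdir()
  n <- generateEvalSet(4, smallSpec(), file.path(root, "a"), seed = 9)
  expect_equal(n, 4)
  imgs <- list.files(file.path(root, "a", "images"))
  msks <- list.files(file.path(root, "a", "masks"))
  expect_equal(imgs, sprintf("fixture_%03d.png", 1:4))
  expect_equal(imgs, msks)
  truth <- jsonlite::read_json(file.path(root, "a", "truth",
                                         "fixture_001.json"))
  expect_length(truth$truth, 5)
  generateEvalSet(4, smallSpec(), file.path(root, "b"), seed = 9)
  for (f in file.path("images", imgs))
    expect_identical(readBin(file.path(root, "a", f), "raw", 1e6),
                     readBin(file.path(root, "b", f), "raw", 1e6))
  expect_error(generateEvalSet(0, smallSpec(), file.path(root, "c")),
               class = "nailsenseParameterError")
})
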