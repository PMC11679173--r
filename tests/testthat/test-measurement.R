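constImage <- function(h, w, rgb) {
  px <- array(0L, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- as.integer(rgb[ch])
  rgbImage(px)
}

test_that("means over a uniform region are exact; unassigned fingers are missing", {
  img <- constImage(40, 40, c(180, 60, 60))
  refs <- new("ReferenceValues", black = c(0, 0, 0), white = c(255, 255, 255))
  norm <- normalizeImage(img, refs)
  g <- expand.grid(x = 5:14, y = 5:14)
  ct <- nailsense:::newContour(cbind(x = g$x, y = g$y), 2L)
  meas <- measureNails(img, norm, list(NULL, ct, NULL, NULL, NULL))
  expect_equal(meas$missing, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(meas$pixel_count[2], 100L)
  expect_equal(unlist(meas[2, c("R", "G", "B")]), c(R = 180, G = 60, B = 60))
  expect_equal(meas$eta_R[2], 180 / 255)
  expect_true(all(is.na(meas$R[meas$missing])))
  allMissing <- measureNails(img, norm, vector("list", 5))
  expect_true(all(allMissing$missing))
  expect_true(all(allMissing$pixel_count == 0L))
})

test_that("means equal a brute-force per-pixel accumulation", {
  set.seed(14)
  px <- array(sample(0:255, 50 * 50 * 3, replace = TRUE), dim = c(50, 50, 3))
  img <- rgbImage(px)
  refs <- new("ReferenceValues", black = c(10, 5, 0), white = c(250, 240, 255))
  norm <- normalizeImage(img, refs)
  pts <- unique(cbind(x = sample(0:49, 120, TRUE), y = sample(0:49, 120, TRUE)))
  ct <- nailsense:::newContour(pts, 4L)
  meas <- measureNails(img, norm, list(NULL, NULL, NULL, ct, NULL))
  accR <- 0; accEta <- 0
  for (i in seq_len(nrow(pts))) {
    accR <- accR + px[pts[i, 2] + 1, pts[i, 1] + 1, 1]
    accEta <- accEta + etaArray(norm)[pts[i, 2] + 1, pts[i, 1] + 1, 1]
  }
  expect_equal(meas$R[4], accR / nrow(pts))
  expect_equal(meas$eta_R[4], accEta / nrow(pts))
})

test_that("mean-of-normalized equals normalized-of-mean on clip-free regions", {
  set.seed(15)
  px <- array(sample(30:220, 30 * 30 * 3, replace = TRUE), dim = c(30, 30, 3))
  img <- rgbImage(px)
  refs <- new("ReferenceValues", black = c(20, 20, 20), white = c(230, 230, 230))
  norm <- normalizeImage(img, refs)
  g <- expand.grid(x = 2:20, y = 3:25)
  ct <- nailsense:::newContour(cbind(x = g$x, y = g$y), 1L)
  meas <- measureNails(img, norm, list(ct, NULL, NULL, NULL, NULL))
  for (ch in 1:3) {
    direct <- normalizeValue(unlist(meas[1, c("R", "G", "B")])[ch],
                             refBlack(refs)[ch], refWhite(refs)[ch])
    expect_lt(abs(unlist(meas[1, c("eta_R", "eta_G", "eta_B")])[ch] - direct),
              1 / 255)
  }
})

test_that("history is append-only in blocks of five and exports/imports exactly", {
  img <- constImage(20, 20, c(100, 150, 200))
  refs <- new("ReferenceValues", black = c(0, 0, 0), white = c(255, 255, 255))
  norm <- normalizeImage(img, refs)
  g <- expand.grid(x = 3:8, y = 3:8)
  ct <- nailsense:::newContour(cbind(x = g$x, y = g$y))
  h <- newHistory()
  path <- withr::local_tempfile(fileext = ".csv")
  expect_equal(exportHistory(h, path), 0)
  expect_equal(readLines(path),
               "timestamp,finger,pixel_count,missing,R,G,B,eta_R,eta_G,eta_B")
  for (t in 1:3) {
    asg <- if (t == 2) vector("list", 5) else list(ct, NULL, ct, NULL, NULL)
    h <- appendAcquisition(h, measureNails(img, norm, asg, t))
  }
  expect_equal(exportHistory(h, path), 15)
  back <- readHistory(path)
  r0 <- historyRecords(h); r1 <- historyRecords(back)
  expect_equal(r1$missing, r0$missing)
  expect_equal(r1$pixel_count, r0$pixel_count)
  for (cn in c("R", "G", "B", "eta_R", "eta_G", "eta_B"))
    expect_equal(r1[[cn]], round(r0[[cn]], 6))
  ## missing rows carry empty color cells in the CSV
  lines <- readLines(path)
  expect_true(all(grepl(",TRUE,,,,,,$", lines[1 + which(r0$missing)])))
  expect_false(any(grepl(",,", lines[1 + which(!r0$missing)])))
  expect_error(appendAcquisition(h, r0[1:3, ]),
               class = "nailsenseInputError")
})

test_that("history plotting writes a PNG panel per finger", {
  img <- constImage(20, 20, c(100, 150, 200))
  refs <- new("ReferenceValues", black = c(0, 0, 0), white = c(255, 255, 255))
  norm <- normalizeImage(img, refs)
  g <- expand.grid(x = 3:8, y = 3:8)
  ct <- nailsense:::newContour(cbind(x = g$x, y = g$y))
  h <- appendAcquisition(newHistory(),
                         measureNails(img, norm, list(ct, NULL, ct, ct, ct), 1))
  path <- withr::local_tempfile(fileext = ".png")
  plotHistory(h, path)
  expect_true(file.exists(path) && file.size(path) > 0)
})
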