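## Seeded synthetic fixtures emulating the guided-box acquisition: five
## vertical skin-toned finger bars, one elliptical nail of known true color
## per finger, true-black corner patches and true-white central patches
## rendered BEFORE the per-channel affine illumination — so the
## reference-extraction rule genuinely inverts the illumination model —
## then additive Gaussian sensor noise. Every stage of the pipeline is
## testable against the returned ground truth with no external data.

runWithSeed <- function(seed, fn) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Specify a synthetic guided hand image
#'
#' Defaults describe the study conditions the package is calibrated at: an
#' 800 px square frame, pinkish nail plates on a more saturated skin tone,
#' nail ellipses large enough to survive the stock erode_filter = 70
#' clean-up, a mild controlled-box illumination (gain 0.9, offset 12 —
#' chosen so the 0/255 reference patches stay inside the 8-bit range under
#' the affine map) and sensor noise of 2 grey levels. All geometry scales
#' with \code{image_side}.
#'
#' @param image_side square frame side, pixels (default 800).
#' @param nail_colors 5x3 matrix (or length-3 vector recycled) of true nail
#'   RGB.
#' @param skin_color,background_color RGB triplets.
#' @param nail_axes 5x2 matrix (or length-2 vector) of ellipse semi-axes.
#' @param nail_centers 5x2 matrix of ellipse centers; default centers each
#'   nail in its finger band.
#' @param gains,offsets per-channel illumination gain/offset (scalars
#'   recycled).
#' @param noise_sd Gaussian noise SD in grey levels, >= 0.
#' @param occlude integer finger indices to render without a nail.
#' @param allow_clip allow the affine illumination to clip at [0, 255].
#' @param patch_fraction reference-patch side fraction (default 0.05).
#' @param seed RNG seed for the noise stream.
#' @return a \code{SyntheticHandSpec}.
#' @export
syntheticHandSpec <- function(image_side = 800L,
                              nail_colors = NULL,
                              skin_color = c(205, 140, 110),
                              background_color = c(70, 66, 62),
                              nail_axes = NULL,
                              nail_centers = NULL,
                              gains = c(0.9, 0.9, 0.9),
                              offsets = c(12, 12, 12),
                              noise_sd = 2,
                              occlude = integer(0),
                              allow_clip = FALSE,
                              patch_fraction = 0.05,
                              seed = 1L) {
  side <- as.integer(image_side)
  s <- side / 800
  if (is.null(nail_colors))
    nail_colors <- rbind(c(226, 188, 178), c(231, 190, 180),
                         c(224, 184, 176), c(228, 192, 184),
                         c(222, 186, 178))
  if (is.vector(nail_colors) && length(nail_colors) == 3L)
    nail_colors <- matrix(nail_colors, 5L, 3L, byrow = TRUE)
  if (is.null(nail_axes)) nail_axes <- round(cbind(rep(50 * s, 5),
                                                   rep(62 * s, 5)))
  if (is.vector(nail_axes) && length(nail_axes) == 2L)
    nail_axes <- matrix(nail_axes, 5L, 2L, byrow = TRUE)
  if (is.null(nail_centers))
    nail_centers <- cbind(round((seq_len(5) - 0.5) * side / 5),
                          rep(round(170 * s), 5))
  spec <- new("SyntheticHandSpec", imageSide = side,
              patchFraction = patch_fraction,
              nailColors = nail_colors,
              skinColor = as.numeric(skin_color),
              backgroundColor = as.numeric(background_color),
              nailAxes = nail_axes, nailCenters = nail_centers,
              gains = rep_len(as.numeric(gains), 3L),
              offsets = rep_len(as.numeric(offsets), 3L),
              noiseSd = as.numeric(noise_sd),
              occlude = as.integer(sort(unique(occlude))),
              allowClip = isTRUE(allow_clip), seed = as.integer(seed))
  spec
}

ellipsePixels <- function(cx, cy, ax, ay, side) {
  x <- 0:(side - 1)
  y <- 0:(side - 1)
  ex <- ((x - cx) / ax)^2
  ey <- ((y - cy) / ay)^2
  outer(ey, ex, "+") <= 1          # [y, x] logical
}

#' Render a synthetic hand fixture
#'
#' Renders background, skin bars, nail ellipses and reference patches (the
#' patches last, at true black 0 and true white 255), validates that the
#' nail ellipses sit inside their finger bands clear of every reference
#' patch, applies the affine illumination (erroring if the deterministic
#' map would leave [0, 255] and clipping is not enabled), then adds seeded
#' Gaussian noise, with tails clamped at the range ends as sensor
#' saturation.
#'
#' @param spec a \code{SyntheticHandSpec}.
#' @return a \code{SyntheticHandFixture}; its ground-truth mask marks
#'   exactly the nail ellipse pixels of the non-occluded fingers.
#' @export
generateHand <- function(spec) {
  stopifnot(is(spec, "SyntheticHandSpec"))
  side <- spec@imageSide
  s <- side / 800
  layout <- makePatchLayout(side, side, spec@patchFraction)
  partition <- makeFingerPartition(side, side)
  base <- array(0, dim = c(side, side, 3L))
  for (ch in 1:3) base[, , ch] <- spec@backgroundColor[ch]
  ## skin bars, inset in each finger band
  mx <- round(20 * s); ytop <- round(60 * s); ybot <- side - round(20 * s)
  for (r in partition@regions) {
    rows <- (ytop + 1L):ybot
    cols <- (r@x0 + mx + 1L):(r@x1 - mx)
    for (ch in 1:3) base[rows, cols, ch] <- spec@skinColor[ch]
  }
  ## nail ellipses + ground truth
  gt <- matrix(FALSE, side, side)
  truth <- data.frame(finger = 1:5, R = spec@nailColors[, 1],
                      G = spec@nailColors[, 2], B = spec@nailColors[, 3],
                      cx = spec@nailCenters[, 1], cy = spec@nailCenters[, 2],
                      area = 0L, occluded = (1:5) %in% spec@occlude)
  patchRects <- c(layout@corners, layout@centrals)
  for (i in 1:5) {
    if (truth$occluded[i]) next
    cx <- spec@nailCenters[i, 1]; cy <- spec@nailCenters[i, 2]
    ax <- spec@nailAxes[i, 1]; ay <- spec@nailAxes[i, 2]
    reg <- partition@regions[[i]]
    if (cx - ax < reg@x0 || cx + ax >= reg@x1 ||
        cy - ay < 0 || cy + ay >= side)
      stopParameter("nail ellipse for finger ", i,
                    " does not fit inside its finger band")
    bbox <- rect(floor(cx - ax), floor(cy - ay),
                 ceiling(cx + ax) + 1L, ceiling(cy + ay) + 1L)
    for (p in patchRects)
      if (rectsIntersect(bbox, p))
        stopParameter("nail ellipse for finger ", i,
                      " intersects a reference patch")
    e <- ellipsePixels(cx, cy, ax, ay, side)
    gt <- gt | e
    truth$area[i] <- sum(e)
    for (ch in 1:3) {
      plane <- base[, , ch]
      plane[e] <- spec@nailColors[i, ch]
      base[, , ch] <- plane
    }
  }
  ## reference patches last: true black corners, true white centrals
  for (p in layout@corners)
    base[rectRows(p), rectCols(p), ] <- 0
  for (p in layout@centrals)
    base[rectRows(p), rectCols(p), ] <- 255
  ## affine illumination (deterministic part validated)
  for (ch in 1:3)
    base[, , ch] <- spec@gains[ch] * base[, , ch] + spec@offsets[ch]
  if (!spec@allowClip && (min(base) < -0.5 || max(base) > 255.49))
    stopParameter("illumination would clip: value range [",
                  round(min(base), 2), ", ", round(max(base), 2),
                  "] leaves [0, 255]; enable allow_clip to saturate")
  ## seeded sensor noise; tails saturate at the range ends
  if (spec@noiseSd > 0)
    base <- base + runWithSeed(spec@seed, function()
      array(stats::rnorm(length(base), sd = spec@noiseSd), dim = dim(base)))
  img <- rgbImage(pmin(pmax(round(base), 0), 255))
  new("SyntheticHandFixture", image = img,
      gtMask = new("BinaryMask", values = gt), truth = truth, spec = spec)
}

#' Write a dataset of synthetic fixtures
#'
#' Generates \code{n} fixtures from a template with seeded jitter of nail
#' positions (+-10 px at the 800 px scale) and colors (+-8 grey levels),
#' writing \code{images/fixture_NNN.png}, \code{masks/fixture_NNN.png}
#' (ground truth, 0/255) and a JSON truth sidecar per fixture under
#' \code{out_dir}. The same seed reproduces the directory byte for byte.
#'
#' @param n number of fixtures, >= 1.
#' @param spec_template a \code{SyntheticHandSpec} to jitter.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving jitter and per-fixture noise.
#' @return number of (image, mask) pairs written, i.e. \code{n}.
#' @export
generateEvalSet <- function(n, spec_template = syntheticHandSpec(),
                            out_dir, seed = 1L) {
  n <- as.integer(n)
  if (n < 1L) stopParameter("n must be >= 1, got ", n)
  stopifnot(is(spec_template, "SyntheticHandSpec"))
  for (d in file.path(out_dir, c("images", "masks", "truth")))
    if (!dir.create(d, recursive = TRUE, showWarnings = FALSE) &&
        !dir.exists(d))
      stopInput("cannot create output directory ", d)
  s <- spec_template@imageSide / 800
  jit <- runWithSeed(as.integer(seed), function()
    list(dx = sample(-10:10, n, replace = TRUE),
         dy = sample(-10:10, n, replace = TRUE),
         dc = matrix(sample(-8:8, n * 15L, replace = TRUE), n, 15L)))
  for (i in seq_len(n)) {
    spec <- spec_template
    spec@nailCenters <- spec@nailCenters +
      cbind(rep(round(jit$dx[i] * s), 5), rep(round(jit$dy[i] * s), 5))
    spec@nailColors <- pmin(pmax(spec@nailColors +
                                 matrix(jit$dc[i, ], 5L, 3L), 0), 255)
    spec@seed <- as.integer((as.integer(seed) + 131L * i) %% .Machine$integer.max)
    fx <- generateHand(spec)
    stem <- sprintf("fixture_%03d", i)
    saveImage(fx@image, file.path(out_dir, "images", paste0(stem, ".png")))
    saveMask(fx@gtMask, file.path(out_dir, "masks", paste0(stem, ".png")))
    jsonlite::write_json(
      list(seed = spec@seed,
           truth = fx@truth),
      file.path(out_dir, "truth", paste0(stem, ".json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  n
}
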