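## The batch workflows: single-image snapshot and ordered multi-image
## batch (the stored-frame counterpart of repeated timed acquisition).
## Chain: resize -> reference extraction -> normalization -> backend ->
## threshold -> majority fill -> erosion -> contours -> finger assignment
## -> (optional size regulation) -> measurement -> color lookup.

configKeys <- c("working_side", "patch_fraction", "reference_stat",
                "backend", "brightness_min", "saturation_max", "mask_path",
                "threshold", "median_kernel", "erode_filter", "min_area",
                "region_scale", "max_distance", "disease_table",
                "timestamp_mode", "history_csv", "plot_png", "verbose")

#' Assemble and validate a pipeline configuration
#'
#' Defaults follow the pipeline's stock operating point: 800 px working
#' size, 5 percent reference patches, classical backend, threshold 0.5,
#' 3 px majority kernel, erode_filter 70, minimum contour area 50 px and
#' unit region scale. \code{erode_filter} and \code{min_area} are defined
#' at the 800 px working size and rescale automatically (linearly and by
#' area) when \code{working_side} differs.
#'
#' @param ... configuration values overriding the defaults; unknown keys
#'   are rejected.
#' @return a validated config list of class \code{nailsenseConfig}.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(working_side = 800L, patch_fraction = 0.05,
              reference_stat = "minmax", backend = "classical",
              brightness_min = 0.6, saturation_max = 0.35,
              mask_path = NULL, threshold = 0.5, median_kernel = 3L,
              erode_filter = 70L, min_area = 50L, region_scale = 1.0,
              max_distance = 60, disease_table = NULL,
              timestamp_mode = "sequence", history_csv = NULL,
              plot_png = NULL, verbose = FALSE)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  unknown <- setdiff(names(over), configKeys)
  if (length(unknown))
    stopConfig("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg$working_side <- as.integer(cfg$working_side)
  if (cfg$working_side < 32L) stopConfig("working_side must be >= 32")
  if (cfg$patch_fraction <= 0 || cfg$patch_fraction > 0.2)
    stopConfig("patch_fraction must lie in (0, 0.2]")
  if (!cfg$reference_stat %in% c("minmax", "patchmean"))
    stopConfig("reference_stat must be 'minmax' or 'patchmean'")
  if (!cfg$backend %in% c("classical", "maskfile"))
    stopConfig("backend must be 'classical' or 'maskfile'")
  if (cfg$backend == "maskfile" && is.null(cfg$mask_path))
    stopConfig("maskfile backend requires mask_path")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stopConfig("threshold must lie in (0, 1)")
  if (cfg$median_kernel < 3L || cfg$median_kernel %% 2L == 0L)
    stopConfig("median_kernel must be odd and >= 3")
  if (cfg$erode_filter < 0L) stopConfig("erode_filter must be >= 0")
  if (cfg$min_area < 1L) stopConfig("min_area must be >= 1")
  if (cfg$region_scale < 0.2 || cfg$region_scale > 3)
    stopConfig("region_scale must lie in [0.2, 3]")
  if (cfg$max_distance <= 0) stopConfig("max_distance must be positive")
  if (!cfg$timestamp_mode %in% c("sequence", "clock"))
    stopConfig("timestamp_mode must be 'sequence' or 'clock'")
  class(cfg) <- "nailsenseConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value YAML with the keys of \code{\link{pipelineConfig}};
#' values passed in \code{...} override the file (flags win).
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file.
#' @return a validated config list.
#' @export
readPipelineConfig <- function(path, ...) {
  if (!file.exists(path)) stopInput("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stopConfig("config file must hold key: value pairs")
  over <- list(...)
  vals[names(over)] <- over
  pipelineConfig(vals)
}

configDigest <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251L)))
}

scaledErode <- function(cfg) {
  if (cfg$erode_filter <= 1L) return(0L)
  max(1L, as.integer(round(cfg$erode_filter * cfg$working_side / 800)))
}

scaledMinArea <- function(cfg) {
  max(1L, as.integer(round(cfg$min_area * (cfg$working_side / 800)^2)))
}

#' Process a single hand image (snapshot modality)
#'
#' Runs the full chain on one image and appends one acquisition (five
#' finger rows, missing where no contour was found) to the history. For
#' each measured finger the mean normalized color, rescaled by 255, is
#' matched against the disease color table.
#'
#' @param image an \code{RGBImage} or a path to a PNG/JPEG file.
#' @param config a \code{\link{pipelineConfig}} list.
#' @param history a \code{MeasurementHistory} to append to; a fresh one by
#'   default.
#' @param timestamp optional acquisition label; defaults to the sequence
#'   index (or wall-clock ISO-8601 when \code{timestamp_mode = "clock"}).
#' @return list with elements \code{measurements} (5-row data.frame),
#'   \code{matches} (per finger, a ranked match table or NULL),
#'   \code{assignment}, \code{mask} (the assigned-contour
#'   \code{BinaryMask}), \code{refs} and \code{history}.
#' @export
runSnapshot <- function(image, config = pipelineConfig(),
                        history = newHistory(), timestamp = NULL) {
  if (!is(config, "nailsenseConfig")) config <- pipelineConfig(config)
  img <- if (is.character(image)) loadImage(image) else image
  stopifnot(is(img, "RGBImage"))
  side <- config$working_side
  img <- resizeToWorking(img, side)
  layout <- makePatchLayout(side, side, config$patch_fraction)
  refs <- extractReferences(img, layout, config$reference_stat)
  norm <- normalizeImage(img, refs)
  partition <- makeFingerPartition(side, side)
  prob <- if (config$backend == "classical") {
    segmentClassical(norm, partition, config$brightness_min,
                     config$saturation_max)
  } else {
    p <- loadMask(config$mask_path)
    if (!identical(dim(p@values), dim(img@pixels)[1:2]))
      stopInput("mask file dimensions ", paste(dim(p@values), collapse = "x"),
                " do not match the working image ", side, "x", side)
    p
  }
  m <- binarize(prob, config$threshold)
  m <- fillHolesMedian(m, config$median_kernel)
  ef <- scaledErode(config)
  if (ef > 1L) m <- erodeMask(m, ef)
  contours <- extractNailContours(m, scaledMinArea(config))
  assignment <- assignContours(contours, partition)
  if (config$region_scale != 1) {
    for (i in 1:5)
      if (!is.null(assignment[[i]]))
        assignment[[i]] <- scaleRegion(assignment[[i]], config$region_scale,
                                       partition@regions[[i]])
  }
  if (is.null(timestamp)) {
    timestamp <- if (config$timestamp_mode == "clock")
      format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    else as.character(nrow(history@records) / 5L + 1L)
  }
  meas <- measureNails(img, norm, assignment, timestamp)
  table <- if (is.null(config$disease_table)) defaultDiseaseTable()
  else if (is.character(config$disease_table))
    readDiseaseTable(config$disease_table)
  else config$disease_table
  matches <- lapply(1:5, function(i) {
    if (meas$missing[i]) return(NULL)
    eta255 <- pmin(pmax(255 * c(meas$eta_R[i], meas$eta_G[i],
                                meas$eta_B[i]), 0), 255)
    classifyColor(eta255, table, config$max_distance)
  })
  history <- appendAcquisition(history, meas)
  if (config$verbose)
    message("nailsense snapshot | config ", configDigest(config),
            " | backend ", config$backend, " | px: ",
            paste(meas$pixel_count, collapse = " "))
  if (all(meas$missing))
    warning("all five fingers missing in this acquisition")
  if (!is.null(config$history_csv)) exportHistory(history, config$history_csv)
  if (!is.null(config$plot_png)) plotHistory(history, config$plot_png)
  list(measurements = meas, matches = matches, assignment = assignment,
       mask = contoursToMask(assignment, side, side), refs = refs,
       history = history)
}

#' Process a directory of images (batch modality)
#'
#' Images are processed in lexicographic filename order — the stored-frame
#' counterpart of timed repeated acquisition — appending one acquisition
#' per readable image to a shared history. Unreadable images are skipped
#' with a warning and reported in the result.
#'
#' @param dir directory containing PNG/JPEG images.
#' @param config a \code{\link{pipelineConfig}} list.
#' @param history starting \code{MeasurementHistory}.
#' @return list with \code{processed} (count), \code{failures} (file
#'   names) and \code{history}.
#' @export
runBatch <- function(dir, config = pipelineConfig(),
                     history = newHistory()) {
  if (!is(config, "nailsenseConfig")) config <- pipelineConfig(config)
  if (!dir.exists(dir)) stopInput("no such directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.(png|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stopInput("no images found in ", dir)
  failures <- character(0)
  for (f in files) {
    res <- tryCatch(runSnapshot(f, config, history),
                    error = function(e) {
                      warning("skipping '", basename(f), "': ",
                              conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) failures <- c(failures, basename(f))
    else history <- res$history
  }
  if (!is.null(config$history_csv)) exportHistory(history, config$history_csv)
  list(processed = length(files) - length(failures), failures = failures,
       history = history)
}
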