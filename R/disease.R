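## Nail-color to symptom lookup. The built-in palette pairs six canonical
## nail discolorations with the conditions they are classically associated
## with in the dermatological literature. Matching is nearest-neighbor in
## raw 0-255 RGB space. None of this is a diagnosis: a measured color near
## a palette entry is at most a prompt to consult a dermatologist.

#' Built-in nail-color/symptom reference table
#'
#' @return data.frame with columns color, R, G, B, symptoms.
#' @export
#' @examples
#' defaultDiseaseTable()
defaultDiseaseTable <- function() {
  data.frame(
    color = c("Yellow", "Green", "Brown", "Red", "White", "Purple"),
    R = c(255, 0, 165, 255, 255, 128),
    G = c(255, 255, 42, 0, 255, 0),
    B = c(0, 0, 42, 0, 255, 128),
    symptoms = c(
      "Diabetes or psoriasis, lung disease",
      "Allergies to cleaning agents, localized fungal infection",
      "Arsenic or copper poisoning, nicotine",
      "Injury, splinter hemorrhage, high blood pressure",
      "Protein deficiency, anemia",
      "Oxygen deprivation, circulatory problems"),
    stringsAsFactors = FALSE)
}

#' Read a custom color/symptom table from CSV
#'
#' Expected columns: color (or name), R, G, B, symptoms.
#'
#' @param path CSV path.
#' @return validated data.frame usable by \code{\link{classifyColor}}.
#' @export
readDiseaseTable <- function(path) {
  if (!file.exists(path)) stopInput("no such table file: ", path)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tb)[names(tb) == "name"] <- "color"
  validateDiseaseTable(tb)
  tb[c("color", "R", "G", "B", "symptoms")]
}

validateDiseaseTable <- function(table) {
  need <- c("color", "R", "G", "B", "symptoms")
  if (!all(need %in% names(table)))
    stopConfig("disease table must have columns ",
               paste(need, collapse = ", "))
  if (nrow(table) < 1L) stopConfig("disease table must have >= 1 entry")
  if (anyDuplicated(table$color))
    stopConfig("disease table color names must be unique")
  rgb <- as.matrix(table[c("R", "G", "B")])
  if (anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255)
    stopConfig("disease table RGB values must lie in [0, 255]")
  invisible(TRUE)
}

#' Match a measured color against the reference palette
#'
#' Euclidean distance in 0-255 RGB space to every table entry, returned in
#' ascending order (ties keep table order); entries within
#' \code{max_distance} are flagged confident. Normalized measurements
#' should be rescaled by 255 before matching (\code{\link{runSnapshot}}
#' does this).
#'
#' @param rgb numeric length-3 measured color on the 0-255 scale.
#' @param table reference table, default \code{\link{defaultDiseaseTable}}.
#' @param max_distance confidence radius in RGB units, default 60.
#' @return data.frame with columns color, distance, symptoms, confident,
#'   sorted by ascending distance.
#' @export
#' @examples
#' classifyColor(c(250, 250, 250))[1, ]   # nearest: White
classifyColor <- function(rgb, table = defaultDiseaseTable(),
                          max_distance = 60) {
  validateDiseaseTable(table)
  if (length(rgb) != 3L || anyNA(rgb) || min(rgb) < 0 || max(rgb) > 255)
    stopParameter("rgb must be a length-3 triplet in [0, 255]")
  if (max_distance <= 0) stopParameter("max_distance must be positive")
  d <- sqrt((table$R - rgb[1])^2 + (table$G - rgb[2])^2 +
            (table$B - rgb[3])^2)
  ord <- order(d, seq_along(d))
  data.frame(color = table$color[ord], distance = d[ord],
             symptoms = table$symptoms[ord],
             confident = d[ord] <= max_distance,
             stringsAsFactors = FALSE)
}
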