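#' Standard 32-channel 10/20 montage with 2-D positions
#'
#' Returns the electrode layout used by the synthetic session generator: 30
#' scalp electrodes of the extended international 10/20 system plus the two
#' ocular channels (HEOG, VEOG). Positions are schematic 2-D head-plane
#' coordinates in head-radius units (vertex at the origin, preauricular
#' points at x = +/-1), adequate for computing inter-electrode distances for
#' the spatial spread of event-related desynchronization. Ocular channels sit
#' outside the scalp disc and are typed `"eog"`.
#'
#' @param includeEOG keep the HEOG/VEOG rows (default `TRUE`).
#' @return data.frame with columns `label`, `x`, `y`, `type`.
#' @examples
#' m <- montage1020()
#' subset(m, label %in% c("C3", "C4", "CZ"))
#' @export
montage1020 <- function(includeEOG = TRUE) {
  m <- data.frame(
    label = c(
      "FP1", "FP2",
      "F7", "F3", "FZ", "F4", "F8",
      "FT7", "FC3", "FCZ", "FC4", "FT8",
      "T3", "C3", "CZ", "C4", "T4",
      "TP7", "CP3", "CPZ", "CP4", "TP8",
      "T5", "P3", "PZ", "P4", "T6",
      "O1", "OZ", "O2",
      "HEOG", "VEOG"
    ),
    x = c(
      -0.31, 0.31,
      -0.81, -0.45, 0, 0.45, 0.81,
      -0.92, -0.48, 0, 0.48, 0.92,
      -1, -0.5, 0, 0.5, 1,
      -0.92, -0.48, 0, 0.48, 0.92,
      -0.81, -0.45, 0, 0.45, 0.81,
      -0.31, 0, 0.31,
      -1.3, 1.25
    ),
    y = c(
      0.95, 0.95,
      0.59, 0.51, 0.5, 0.51, 0.59,
      0.31, 0.26, 0.25, 0.26, 0.31,
      0, 0, 0, 0, 0,
      -0.31, -0.26, -0.25, -0.26, -0.31,
      -0.59, -0.51, -0.5, -0.51, -0.59,
      -0.95, -1, -0.95,
      1.2, 1.25
    ),
    type = c(rep("eeg", 30), rep("eog", 2)),
    stringsAsFactors = FALSE
  )
  if (!includeEOG) m <- m[m$type == "eeg", , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Euclidean distances from one electrode to every row of a montage.
montageDistance <- function(montage, from) {
  i <- match(from, montage$label)
  if (is.na(i)) stop("channel '", from, "' not found in montage")
  sqrt((montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2)
}
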