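# Image-stack and table I/O. Image sequences travel as multi-page TIFF with a
# JSON sidecar carrying spacing, frame rate and the grey-value scale.

#' Write an image sequence as a multi-page TIFF with JSON sidecar
#'
#' Frames are stored as 32-bit float pages scaled into [0, 1]; the sidecar
#' (`<path>.json`) records the scale factor, pixel spacing, frame rate and
#' frame count, so [readImageStack()] restores the original grey values.
#'
#' @param seq an [ImageSequence-class].
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
writeImageStack <- function(seq, path) {
  stopifnot(is(seq, "ImageSequence"))
  fr <- seq@frames
  lo <- min(fr); hi <- max(fr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(fr)[3]), function(f) (fr[, , f] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(spacing_mm = seq@spacing, fps = seq@fps,
                  n_frames = dim(fr)[3], offset = lo, scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image sequence from a multi-page TIFF
#'
#' @param path TIFF path written by [writeImageStack()] (or any multi-page
#'   TIFF; without a sidecar, `spacing`/`fps` defaults are used and values are
#'   taken as stored).
#' @param spacing,fps fallbacks when no sidecar is present.
#' @return an [ImageSequence-class].
#' @export
readImageStack <- function(path, spacing = 1.4, fps = 55) {
  if (!file.exists(path)) stop(sprintf("I/O error: cannot read '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- paste0(path, ".json")
  offset <- 0; scale <- 1
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$n_frames) && meta$n_frames != length(pages))
      stop(sprintf("I/O error: '%s' has %d frames but metadata says %d",
                   path, length(pages), meta$n_frames))
    spacing <- meta$spacing_mm %||% spacing
    fps <- meta$fps %||% fps
    offset <- meta$offset %||% 0
    scale <- meta$scale %||% 1
  }
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]   # collapse grayscale channels
    arr[, , f] <- pg * scale + offset
  }
  ImageSequence(arr, spacing = spacing, fps = fps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  path
}
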