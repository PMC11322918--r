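# TIFF input/output for microscopy data. The tiff package is an optional
# dependency: everything in the analysis chain also accepts plain matrices,
# so the package works end to end (and is fully testable) without it.

need_tiff <- function() {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop_fm("reading/writing TIFF files needs the `tiff` package")
  }
}

#' Read a grayscale image (TIFF) as a row-down matrix
#'
#' Multi-channel images are averaged to grayscale.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_image <- function(path) {
  need_tiff()
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Read a multi-page TIFF as a list of row-down matrices
#' @param path File path.
#' @return List of numeric matrices.
#' @export
read_image_stack <- function(path) {
  need_tiff()
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(img) {
    if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
    img
  })
}

#' Read a FRAP stack plus its acquisition metadata
#'
#' @param path Multi-page TIFF of the FRAP time series.
#' @param metadata Either a YAML file path or a named list with
#'   `frame_interval` (s), `pixel_size` (um/px), optional
#'   `bleach_diameter` (um).
#' @return A [frap_sequence()].
#' @export
read_frap_stack <- function(path, metadata) {
  frames <- read_image_stack(path)
  if (is.character(metadata)) metadata <- yaml::read_yaml(metadata)
  frap_sequence(
    frames,
    frame_interval = metadata$frame_interval,
    pixel_size = metadata$pixel_size,
    bleach_diameter = metadata$bleach_diameter %||% 30
  )
}

#' Write a list of matrices as a multi-page float TIFF
#'
#' @param frames List of numeric matrices (or one matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path) {
  need_tiff()
  if (is.matrix(frames)) frames <- list(frames)
  rng <- range(unlist(lapply(frames, range)))
  # writeTIFF stores [0,1]; rescale and record the original range alongside
  scale <- if (diff(rng) > 0) diff(rng) else 1
  norm <- lapply(frames, function(f) (f - rng[1]) / scale)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  jsonlite::write_json(
    list(offset = rng[1], scale = scale),
    paste0(path, ".range.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
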