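#' Read and write two-channel scenes as multi-page TIFF
#'
#' Scenes are stored as one grayscale page per channel (page 1 = fill,
#' page 2 = marker), 32-bit float samples. TIFF float samples must lie in
#' \[0, 1\], so intensities are divided by `scale` on write and multiplied
#' back on read; the scale is recorded in the run manifest.
#'
#' @param scene An `ais_scene`.
#' @param path Output path (`.tif`).
#' @param scale Intensity divisor used to map onto \[0, 1\].
#' @return `write_scene_tiff()` returns `path` invisibly.
#' @export
write_scene_tiff <- function(scene, path, scale = 65535) {
  pages <- list(scene$fill / scale, scene$marker / scale)
  if (any(vapply(pages, function(p) any(p < 0 | p > 1), logical(1)))) {
    abort("Scene intensities outside [0, scale]; increase `scale`.")
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_scene_tiff
#' @param pixel_size µm/px recorded on the returned scene.
#' @export
read_scene_tiff <- function(path, scale = 65535, pixel_size = NA_real_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) abort("Expected a two-page (two-channel) TIFF.")
  structure(
    list(fill = pages[[1]] * scale, marker = pages[[2]] * scale,
         pixel_size = pixel_size),
    class = "ais_scene"
  )
}

#' Read and write ground-truth tables
#'
#' CSV serialization of [truth_table()]; numeric fields round-trip exactly.
#'
#' @param path File path.
#' @return `read_truth_csv()` returns the truth tibble.
#' @export
read_truth_csv <- function(path) {
  # base read.csv parses doubles via strtod (correctly rounded), so the
  # 17-digit serialization round-trips bit-exactly
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_truth_csv
#' @param truth Truth tibble from [truth_table()].
#' @export
write_truth_csv <- function(truth, path) {
  # 17 significant digits guarantee an exact double round-trip
  out <- dplyr::mutate(truth, dplyr::across(
    dplyr::where(is.double),
    \(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  ))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
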