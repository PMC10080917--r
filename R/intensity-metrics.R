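#' Integrated density within a masked region
#'
#' The sum of pixel values inside the mask, with unit pixel area — the
#' standard "summed pixel values" reading of integrated density (mean
#' intensity times area equals the sum, so no extra area factor is applied).
#' When `pixel_size` is supplied the physically scaled value
#' (`x * pixel_size^2`, intensity·µm²) is attached as attribute
#' `"integrated_density_um2"`.
#'
#' @param image Single-channel numeric matrix.
#' @param mask Logical matrix congruent with `image`; `NULL` means the whole
#'   image.
#' @param pixel_size Optional pixel size in µm/px.
#' @return Numeric scalar (intensity·px).
#' @export
integrated_density <- function(image, mask = NULL, pixel_size = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!identical(dim(image), dim(mask))) {
    abort("`image` and `mask` must have identical dimensions.")
  }
  val <- sum(image[mask])
  if (!is.null(pixel_size)) {
    attr(val, "integrated_density_um2") <- val * pixel_size^2
  }
  val
}

#' Pearson colocalization over a masked region
#'
#' Pearson correlation coefficient of two channels over the pixels selected
#' by the mask (the Coloc-2-style global Pearson statistic, without Costes
#' auto-thresholding). The result is invariant to positive affine rescaling
#' of either channel.
#'
#' @param ch1,ch2 Numeric matrices of identical dimensions.
#' @param mask Logical matrix with at least 2 selected pixels; `NULL` means
#'   the whole image.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_colocalization <- function(ch1, ch2, mask = NULL) {
  if (!identical(dim(ch1), dim(ch2))) {
    abort("`ch1` and `ch2` must have identical dimensions.")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  if (!identical(dim(ch1), dim(mask))) {
    abort("`mask` must match the image dimensions.")
  }
  a <- ch1[mask]
  b <- ch2[mask]
  if (length(a) < 2) abort("Mask must select at least 2 pixels.")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("Correlation undefined: a channel is constant within the mask.")
  }
  cor(a, b)
}

#' Manders overlap coefficients
#'
#' Optional complement to the Pearson statistic: `m1` is the fraction of
#' channel-1 intensity found in pixels where channel 2 is above zero (or the
#' given thresholds), and vice versa for `m2`.
#'
#' @inheritParams pearson_colocalization
#' @param threshold1,threshold2 Intensity thresholds defining "positive"
#'   pixels in each channel.
#' @return Named numeric vector `c(m1 = , m2 = )`.
#' @export
manders_coefficients <- function(ch1, ch2, mask = NULL,
                                 threshold1 = 0, threshold2 = 0) {
  if (!identical(dim(ch1), dim(ch2))) {
    abort("`ch1` and `ch2` must have identical dimensions.")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  a <- ch1[mask]
  b <- ch2[mask]
  if (sum(a) == 0 || sum(b) == 0) {
    abort("Manders coefficients undefined for an all-zero channel.")
  }
  c(m1 = sum(a[b > threshold2]) / sum(a),
    m2 = sum(b[a > threshold1]) / sum(b))
}

#' Build a region mask from the cell-fill channel
#'
#' Restricts metrics to fill-positive pixels (e.g., tdTomato-expressing
#' processes). Thresholding is either Otsu's between-class-variance rule
#' (via `EBImage::otsu` on a 256-level histogram) or a fixed cut; the method
#' and the numeric threshold are recorded as attributes for provenance.
#'
#' @param fill Numeric matrix, the fill channel.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_value Threshold used when `threshold_method = "fixed"`.
#' @return Logical mask matrix with attributes `threshold` and `method`.
#'   All-background or all-foreground results raise a warning, not an error.
#' @export
mask_from_fill_channel <- function(fill, threshold_method = c("otsu", "fixed"),
                                   fixed_value = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (any(!is.finite(fill))) abort("`fill` must be finite.")
  if (threshold_method == "otsu") {
    rng <- range(fill)
    if (diff(rng) == 0) {
      warn("Constant fill channel; returning an empty mask.")
      thr <- rng[2]
    } else {
      norm <- (fill - rng[1]) / diff(rng)
      thr_norm <- EBImage::otsu(EBImage::Image(t(norm)), range = c(0, 1),
                                levels = 256)
      thr <- rng[1] + thr_norm * diff(rng)
    }
  } else {
    if (is.null(fixed_value)) abort("`fixed_value` is required for the fixed method.")
    thr <- fixed_value
  }
  mask <- fill > thr
  if (!any(mask)) warn("Threshold yields an empty mask.")
  if (all(mask)) warn("Threshold yields an all-foreground mask.")
  attr(mask, "threshold") <- as.numeric(thr)
  attr(mask, "method") <- threshold_method
  mask
}

#' Per-region metric table for a two-channel image
#'
#' Convenience wrapper producing one tidy row per region: pixel area,
#' integrated density of each channel, and their Pearson correlation.
#'
#' @param ch1,ch2 Numeric matrices of identical dimensions.
#' @param regions Named list of logical masks.
#' @param pixel_size Optional µm/px for physically scaled densities.
#' @return Tibble with one row per region.
#' @export
region_metrics <- function(ch1, ch2, regions, pixel_size = NULL) {
  purrr::imap(regions, function(mask, label) {
    tibble(
      region = label,
      area_px = sum(mask),
      integ_density_ch1 = as.numeric(integrated_density(ch1, mask)),
      integ_density_ch2 = as.numeric(integrated_density(ch2, mask)),
      pearson_r = if (sum(mask) >= 2 &&
                        sd(ch1[mask]) > 0 && sd(ch2[mask]) > 0) {
        pearson_colocalization(ch1, ch2, mask)
      } else {
        NA_real_
      },
      area_um2 = if (is.null(pixel_size)) NA_real_ else sum(mask) * pixel_size^2
    )
  }) |>
    purrr::list_rbind()
}
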