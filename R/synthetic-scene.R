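## internal: rasterize one polyline stroke into channel matrices.
## Coverage is anti-aliased: a linear 1-px ramp around the nominal half-width,
## combined across segments by max so joints do not double-brighten.
## `fill_fun` / `marker_fun` map arc-length (µm from the polyline start) to
## the channel intensity at full coverage; `marker_fun = NULL` skips ch2.
render_path_onto <- function(fill, marker, path, pixel_size, half_w,
                             fill_fun, marker_fun = NULL) {
  ny <- nrow(fill)
  nx <- ncol(fill)
  dx <- diff(path[, 1])
  dy <- diff(path[, 2])
  seg_len <- sqrt(dx^2 + dy^2)
  cum <- c(0, cumsum(seg_len))
  reach <- half_w + 1.5
  for (i in seq_along(seg_len)) {
    if (seg_len[i] == 0) next
    p <- path[i, ]
    ux <- dx[i] / seg_len[i]
    uy <- dy[i] / seg_len[i]
    xlo <- max(0, floor(min(path[i:(i + 1), 1]) - reach))
    xhi <- min(nx - 1, ceiling(max(path[i:(i + 1), 1]) + reach))
    ylo <- max(0, floor(min(path[i:(i + 1), 2]) - reach))
    yhi <- min(ny - 1, ceiling(max(path[i:(i + 1), 2]) + reach))
    if (xhi < xlo || yhi < ylo) next
    xs <- xlo:xhi
    ys <- ylo:yhi
    gx <- rep(xs, each = length(ys))
    gy <- rep(ys, times = length(xs))
    wx <- gx - p[1]
    wy <- gy - p[2]
    tt <- pmin(pmax(wx * ux + wy * uy, 0), seg_len[i])
    d <- sqrt((wx - tt * ux)^2 + (wy - tt * uy)^2)
    cov <- pmin(1, pmax(0, half_w + 0.5 - d))
    sel <- cov > 0
    if (!any(sel)) next
    idx <- gx[sel] * ny + gy[sel] + 1 # column-major, 0-based (x, y)
    arc_um <- (cum[i] + tt[sel]) * pixel_size
    fill[idx] <- pmax(fill[idx], fill_fun(arc_um) * cov[sel])
    if (!is.null(marker_fun)) {
      marker[idx] <- pmax(marker[idx], marker_fun(arc_um) * cov[sel])
    }
  }
  list(fill = fill, marker = marker)
}

## internal: anti-aliased disk onto a matrix
render_disk_onto <- function(im, center, radius, value) {
  ny <- nrow(im)
  nx <- ncol(im)
  xlo <- max(0, floor(center[1] - radius - 2))
  xhi <- min(nx - 1, ceiling(center[1] + radius + 2))
  ylo <- max(0, floor(center[2] - radius - 2))
  yhi <- min(ny - 1, ceiling(center[2] + radius + 2))
  xs <- xlo:xhi
  ys <- ylo:yhi
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  d <- sqrt((gx - center[1])^2 + (gy - center[2])^2)
  cov <- pmin(1, pmax(0, radius + 0.5 - d))
  sel <- cov > 0
  idx <- gx[sel] * ny + gy[sel] + 1
  im[idx] <- pmax(im[idx], value * cov[sel])
  im
}

## internal: point on a polyline at a given arc length (µm)
point_at_arc <- function(path, arc_um, pixel_size) {
  dx <- diff(path[, 1])
  dy <- diff(path[, 2])
  seg_len <- sqrt(dx^2 + dy^2)
  cum <- c(0, cumsum(seg_len))
  a_px <- min(max(arc_um / pixel_size, 0), cum[length(cum)])
  i <- max(1, min(findInterval(a_px, cum, rightmost.closed = TRUE), length(seg_len)))
  t <- a_px - cum[i]
  c(path[i, 1] + dx[i] / seg_len[i] * t, path[i, 2] + dy[i] / seg_len[i] * t)
}

#' Render the noiseless two-channel scene of a ground-truth neuron
#'
#' Channel 1 ("fill") carries the soma disk and every neurite stroke;
#' channel 2 ("marker") carries intensity only along the true AIS spans,
#' shaped by [ais_shape()]. If an axonopathy effect is attached to the
#' neuron, varicosity bumps are added to channel 1 and intensities distal
#' to the attenuation onset are scaled by `1 - distal_attenuation_fraction`
#' on both channels of the affected neurite.
#'
#' @param neuron A `ground_truth_neuron`.
#' @param stroke_width_px Neurite stroke width in pixels.
#' @return An `ais_scene`: list with numeric matrices `fill` and `marker`
#'   and the pixel size.
#' @export
render_scene <- function(neuron, stroke_width_px = 3) {
  ny <- neuron$image_dim[["ny"]]
  nx <- neuron$image_dim[["nx"]]
  fill <- matrix(0, ny, nx)
  marker <- matrix(0, ny, nx)
  half_w <- stroke_width_px / 2
  eff <- neuron$effect

  fill <- render_disk_onto(fill, neuron$soma_center_px, neuron$soma_radius_px,
                           neuron$fill_intensity)

  for (nrt in neuron$neurites) {
    path_um <- sum(sqrt(diff(nrt$path[, 1])^2 + diff(nrt$path[, 2])^2)) *
      neuron$pixel_size
    atten <- function(arc_um) rep(1, length(arc_um))
    marker_fun <- NULL
    if (nrt$is_ais) {
      if (nrt$ais_start_um + nrt$ais_length_um > path_um + 1e-6) {
        abort(sprintf(
          "AIS span (%.2f + %.2f um) exceeds neurite %s length (%.2f um).",
          nrt$ais_start_um, nrt$ais_length_um, nrt$neurite_id, path_um
        ))
      }
      if (!is.null(eff) && eff$distal_attenuation_fraction > 0) {
        onset <- eff$attenuation_start_um %||%
          (nrt$ais_start_um + nrt$ais_length_um)
        frac <- eff$distal_attenuation_fraction
        atten <- function(arc_um) 1 - frac * (arc_um > onset)
      }
      amp <- neuron$ais_amplitude
      s0 <- nrt$ais_start_um
      l0 <- nrt$ais_length_um
      marker_fun <- function(arc_um) amp * ais_shape(arc_um, s0, l0) * atten(arc_um)
    }
    fill_val <- neuron$fill_intensity
    fill_fun <- function(arc_um) fill_val * atten(arc_um)
    res <- render_path_onto(fill, marker, nrt$path, neuron$pixel_size, half_w,
                            fill_fun, marker_fun)
    fill <- res$fill
    marker <- res$marker
  }

  if (!is.null(neuron$varicosities)) {
    sigma_px <- neuron$varicosities$sigma_um / neuron$pixel_size
    nrt <- purrr::detect(neuron$neurites,
                         ~ .x$neurite_id == neuron$varicosities$neurite_id)
    for (arc in neuron$varicosities$arcs_um) {
      ctr <- point_at_arc(nrt$path, arc, neuron$pixel_size)
      xs <- max(0, floor(ctr[1] - 4 * sigma_px)):min(nx - 1, ceiling(ctr[1] + 4 * sigma_px))
      ys <- max(0, floor(ctr[2] - 4 * sigma_px)):min(ny - 1, ceiling(ctr[2] + 4 * sigma_px))
      gx <- rep(xs, each = length(ys))
      gy <- rep(ys, times = length(xs))
      d2 <- (gx - ctr[1])^2 + (gy - ctr[2])^2
      idx <- gx * ny + gy + 1
      fill[idx] <- fill[idx] +
        neuron$varicosities$amplitude * exp(-d2 / (2 * sigma_px^2))
    }
  }

  structure(list(fill = fill, marker = marker, pixel_size = neuron$pixel_size),
            class = "ais_scene")
}

## internal: noise over one channel matrix (clean -> Poisson -> Gaussian ->
## background, clamped at 0); consumes the current RNG stream
apply_noise_matrix <- function(m, nm) {
  v <- as.vector(m)
  if (nm$poisson_scale > 0) {
    v <- rpois(length(v), v * nm$poisson_scale) / nm$poisson_scale
  }
  if (nm$gaussian_sigma > 0) {
    v <- v + rnorm(length(v), 0, nm$gaussian_sigma)
  }
  ny <- nrow(m)
  nx <- ncol(m)
  x0 <- rep(0:(nx - 1), each = ny)
  y0 <- rep(0:(ny - 1), times = nx)
  v <- v + nm$background_level +
    nm$background_gradient[1] * x0 + nm$background_gradient[2] * y0
  matrix(pmax(v, 0), ny, nx)
}

#' Apply the noise model to a rendered scene
#'
#' @param scene An `ais_scene` (clean render).
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical seed and parameters give a
#'   bit-identical scene.
#' @return The noisy `ais_scene`.
#' @export
add_scene_noise <- function(scene, noise = noise_model(), seed = 1) {
  set.seed(as.integer(seed %% 2147483647))
  scene$fill <- apply_noise_matrix(scene$fill, noise)
  scene$marker <- apply_noise_matrix(scene$marker, noise)
  scene
}

## sub-seed derivation: keeps geometry, noise and effect placement on
## separate reproducible streams, all below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e9) * 31 + k * 7919) %% 2147483629L + 1L
}

#' Simulate one ground-truth neuron and its rendered scene
#'
#' Draws the localization class, AIS geometry and neurite polylines from
#' the generator settings, renders the clean two-channel scene, and applies
#' the noise model. All draws are reproducible from `seed`: geometry and
#' noise use separate sub-streams derived from it, so re-rendering the same
#' neuron (e.g., after a null axonopathy effect) reproduces the scene
#' bit-for-bit.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @param neuron_id Identifier for the simulated cell.
#' @return List with elements `truth` (a `ground_truth_neuron`) and `scene`
#'   (an `ais_scene`).
#' @export
simulate_neuron <- function(config = generator_config(), seed = 1,
                            neuron_id = "sim1") {
  if (!inherits(config, "generator_config")) {
    abort("`config` must be a generator_config().")
  }
  set.seed(derive_seed(seed, 1))
  truth <- draw_neuron_truth(config, neuron_id)
  truth$seed <- seed
  scene <- render_scene(truth, config$stroke_width_px)
  scene <- add_scene_noise(scene, config$noise, derive_seed(seed, 2))
  list(truth = truth, scene = scene)
}

#' Simulate a cohort of neurons
#'
#' @inheritParams simulate_neuron
#' @param n Number of neurons.
#' @param id_prefix Prefix for neuron ids.
#' @return List of `simulate_neuron()` results.
#' @export
simulate_cohort <- function(n, config = generator_config(), seed = 1,
                            id_prefix = "sim") {
  purrr::map(seq_len(n), function(i) {
    simulate_neuron(config, seed = derive_seed(seed, 100 + i),
                    neuron_id = sprintf("%s%04d", id_prefix, i))
  })
}

#' Simulate arc-length marker profiles directly (1D fast path)
#'
#' Generates the same statistical structure as a rendered scene plus
#' extraction — a raised-cosine AIS span on a neurite sampled every pixel
#' from the soma edge, with Poisson, Gaussian and smooth background noise —
#' without rasterizing an image. Used for large property sweeps where only
#' the profile-level algorithm is under test.
#'
#' @param n Number of profiles.
#' @param config A [generator_config()]; the truth distributions, pixel
#'   size, amplitude and noise model are taken from it.
#' @param seed Integer seed.
#' @return List with `truth` (tibble: `neuron_id`, `localization_class`,
#'   `true_start_um`, `true_length_um`, `amplitude`) and `profiles`
#'   (stacked profile tibble as from [extract_profile()]).
#' @export
simulate_profiles <- function(n, config = generator_config(), seed = 1) {
  px <- config$pixel_size
  nm <- config$noise
  res <- purrr::map(seq_len(n), function(i) {
    set.seed(derive_seed(seed, 200 + i))
    cls <- sample(LOCALIZATION_CLASSES, 1,
                  prob = config$class_probs[LOCALIZATION_CLASSES])
    key <- if (cls == "acd") "acd" else "direct"
    lower <- if (cls == "acd") config$branch_range_um[2] + 1 else 0
    start <- rtrunc_norm(1, config$start_mean_um[[key]],
                         config$start_sd_um[[key]], lower = lower)
    len <- rtrunc_norm(1, config$length_mean_um, config$length_sd_um, lower = 0.5)
    total <- start + len + config$distal_margin_um
    d <- seq(0, total, by = px)
    clean <- config$ais_amplitude * ais_shape(d, start, len)
    v <- clean
    if (nm$poisson_scale > 0) v <- rpois(length(v), v * nm$poisson_scale) / nm$poisson_scale
    if (nm$gaussian_sigma > 0) v <- v + rnorm(length(v), 0, nm$gaussian_sigma)
    v <- v + nm$background_level + nm$background_gradient[1] * (d / px)
    id <- sprintf("sim%05d", i)
    list(
      truth = tibble(neuron_id = id, localization_class = cls,
                     true_start_um = start, true_length_um = len,
                     amplitude = config$ais_amplitude),
      profile = tibble(neuron_id = id, localization_class = cls,
                       distance_um = d, intensity = pmax(v, 0))
    )
  })
  list(
    truth = purrr::list_rbind(purrr::map(res, "truth")),
    profiles = purrr::list_rbind(purrr::map(res, "profile"))
  )
}
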