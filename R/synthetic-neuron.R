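#' Noise model for synthetic scenes
#'
#' Noise is composed in a fixed order so renders are reproducible:
#' clean signal, then Poisson resampling (photon shot noise at
#' `poisson_scale` photons per intensity unit; 0 disables), then additive
#' Gaussian read noise, then the smooth additive background (a constant
#' level plus a linear gradient per pixel along x and y). Negative values
#' are clamped at zero, as in a detector image.
#'
#' @param background_level Constant background intensity (>= 0).
#' @param background_gradient Length-2 numeric, intensity per pixel along
#'   x and y.
#' @param poisson_scale Photons per intensity unit; 0 disables shot noise.
#' @param gaussian_sigma SD of additive Gaussian noise (>= 0).
#' @return A `noise_model` list.
#' @export
noise_model <- function(background_level = 20,
                        background_gradient = c(0.01, 0.005),
                        poisson_scale = 5,
                        gaussian_sigma = 2) {
  nm <- list(
    background_level = background_level,
    background_gradient = rep_len(as.numeric(background_gradient), 2),
    poisson_scale = poisson_scale,
    gaussian_sigma = gaussian_sigma
  )
  bad <- c(
    if (nm$background_level < 0) "`background_level` must be >= 0",
    if (any(nm$background_gradient < 0)) "`background_gradient` must be >= 0",
    if (nm$poisson_scale < 0) "`poisson_scale` must be >= 0",
    if (nm$gaussian_sigma < 0) "`gaussian_sigma` must be >= 0"
  )
  if (length(bad)) abort(paste0("Invalid noise model:\n- ", paste(bad, collapse = "\n- ")))
  structure(nm, class = "noise_model")
}

#' Generator settings for synthetic neurons
#'
#' Defines the study conditions the generator emulates: a soma disk,
#' anti-aliased neurite polylines of three topologies (direct,
#' axon-carrying dendrite, multi), and an elevated marker-channel span —
#' the AIS — with a raised-cosine plateau profile whose half-maximum
#' crossings sit exactly at the true start and end. Truth distributions
#' are truncated normals; AcD starts lie farther from the soma than direct
#' starts, and strictly distal to the dendritic bifurcation.
#'
#' @param pixel_size µm per pixel (> 0).
#' @param class_probs Named probabilities for `direct`, `acd`, `multi`.
#' @param start_mean_um,start_sd_um Named (direct/acd) truncated-normal
#'   parameters of the AIS start distance from the soma edge, µm.
#' @param length_mean_um,length_sd_um AIS length distribution, µm,
#'   truncated at 0.
#' @param ais_amplitude Marker intensity above background on the AIS span.
#' @param fill_intensity Fill-channel intensity of soma and neurites.
#' @param soma_radius_um Soma disk radius.
#' @param stroke_width_px Anti-aliased neurite stroke width in pixels.
#' @param distal_margin_um Neurite length beyond the AIS end (traces extend
#'   past the labeled span).
#' @param vertex_step_um Polyline vertex spacing.
#' @param direction_jitter_deg SD of the per-vertex heading jitter, degrees.
#' @param branch_range_um AcD bifurcation distance range (uniform), µm.
#' @param n_plain_dendrites Extra AIS-free neurites rendered per cell.
#' @param multi_n_probs Probabilities of 2 or 3 AIS-bearing neurites for
#'   `multi` cells.
#' @param noise A [noise_model()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(pixel_size = 0.2,
                             class_probs = c(direct = 0.593, acd = 0.353, multi = 0.054),
                             start_mean_um = c(direct = 3, acd = 8),
                             start_sd_um = c(direct = 1.5, acd = 3),
                             length_mean_um = 20,
                             length_sd_um = 5,
                             ais_amplitude = 100,
                             fill_intensity = 100,
                             soma_radius_um = 5,
                             stroke_width_px = 3,
                             distal_margin_um = 10,
                             vertex_step_um = 2,
                             direction_jitter_deg = 4,
                             branch_range_um = c(2, 5),
                             n_plain_dendrites = 2,
                             multi_n_probs = c(`2` = 0.8, `3` = 0.2),
                             noise = noise_model()) {
  cfg <- list(
    pixel_size = pixel_size, class_probs = class_probs,
    start_mean_um = start_mean_um, start_sd_um = start_sd_um,
    length_mean_um = length_mean_um, length_sd_um = length_sd_um,
    ais_amplitude = ais_amplitude, fill_intensity = fill_intensity,
    soma_radius_um = soma_radius_um, stroke_width_px = stroke_width_px,
    distal_margin_um = distal_margin_um, vertex_step_um = vertex_step_um,
    direction_jitter_deg = direction_jitter_deg,
    branch_range_um = branch_range_um,
    n_plain_dendrites = n_plain_dendrites,
    multi_n_probs = multi_n_probs,
    noise = noise
  )
  bad <- c(
    if (!is.numeric(pixel_size) || pixel_size <= 0) "`pixel_size` must be positive",
    if (!all(LOCALIZATION_CLASSES %in% names(class_probs)) ||
          any(class_probs < 0) || abs(sum(class_probs) - 1) > 1e-8)
      "`class_probs` must be named direct/acd/multi probabilities summing to 1",
    if (!all(c("direct", "acd") %in% names(start_mean_um)))
      "`start_mean_um` needs direct and acd entries",
    if (any(start_sd_um <= 0) || length_sd_um <= 0) "truth SDs must be positive",
    if (length_mean_um <= 0) "`length_mean_um` must be positive",
    if (ais_amplitude < 0) "`ais_amplitude` must be >= 0",
    if (soma_radius_um <= 0) "`soma_radius_um` must be positive",
    if (stroke_width_px < 1) "`stroke_width_px` must be >= 1",
    if (!inherits(noise, "noise_model")) "`noise` must be a noise_model()"
  )
  if (length(bad)) {
    abort(paste0("Invalid generator configuration:\n- ", paste(bad, collapse = "\n- ")))
  }
  structure(cfg, class = "generator_config")
}

#' Truncated-normal draws via the inverse CDF
#' @noRd
rtrunc_norm <- function(n, mean, sd, lower = 0) {
  p0 <- pnorm(lower, mean, sd)
  qnorm(runif(n, p0, 1), mean, sd)
}

#' Raised-cosine AIS intensity shape
#'
#' Unit-amplitude longitudinal profile of the AIS span: a flat plateau with
#' smooth cosine shoulders spanning 10% of the length on each side, placed
#' so the half-maximum crossings fall exactly at `start` and
#' `start + length`. This makes half-of-range bound recovery non-trivial
#' (the edges are not steps) yet analytically checkable.
#'
#' @param arc_um Arc-length positions, µm from the soma edge.
#' @param start,length AIS start and length, µm.
#' @return Shape values in \[0, 1\].
#' @export
ais_shape <- function(arc_um, start, length) {
  w <- 0.1 * length
  s <- numeric(length(arc_um))
  a <- arc_um - start
  e <- arc_um - (start + length)
  s[a > w / 2 & e < -w / 2] <- 1
  i <- abs(a) <= w / 2
  s[i] <- 0.5 * (1 + sin(pi * a[i] / w))
  i <- abs(e) <= w / 2
  s[i] <- 0.5 * (1 - sin(pi * e[i] / w))
  s
}

## internal: build one neurite path; returns Nx2 matrix in px, first row = origin;
## vertices every vertex_step_um with small heading jitter
neurite_path <- function(origin, angle0, length_um, cfg) {
  step <- cfg$vertex_step_um
  n_seg <- max(1L, ceiling(length_um / step))
  steps <- rep(step, n_seg)
  steps[n_seg] <- length_um - (n_seg - 1) * step
  jitter <- cfg$direction_jitter_deg * pi / 180
  angles <- angle0 + cumsum(c(0, rnorm(n_seg - 1, 0, jitter)))
  dx <- steps * cos(angles) / cfg$pixel_size
  dy <- steps * sin(angles) / cfg$pixel_size
  cbind(x = origin[1] + c(0, cumsum(dx)),
        y = origin[2] + c(0, cumsum(dy)))
}

## internal: draw a ground-truth neuron using the current RNG stream.
## Coordinates are built around a soma at (0, 0) and translated to positive
## pixel space afterwards.
draw_neuron_truth <- function(cfg, neuron_id) {
  cls <- sample(LOCALIZATION_CLASSES, 1,
                prob = cfg$class_probs[LOCALIZATION_CLASSES])
  r_px <- cfg$soma_radius_um / cfg$pixel_size

  n_ais <- switch(cls,
    direct = 1L, acd = 1L,
    multi = sample(as.integer(names(cfg$multi_n_probs)), 1, prob = cfg$multi_n_probs)
  )
  n_total <- n_ais + cfg$n_plain_dendrites
  base <- runif(1, 0, 2 * pi)
  angles <- base + (seq_len(n_total) - 1) * 2 * pi / n_total +
    runif(n_total, -0.25, 0.25)

  neurites <- list()
  k <- 0L
  add <- function(lst, nrt) c(lst, list(nrt))

  for (i in seq_len(n_ais)) {
    k <- k + 1L
    ang <- angles[i]
    origin <- r_px * c(cos(ang), sin(ang))
    if (cls == "acd" && i == 1L) {
      branch_um <- runif(1, cfg$branch_range_um[1], cfg$branch_range_um[2])
      start_um <- rtrunc_norm(1, cfg$start_mean_um[["acd"]],
                              cfg$start_sd_um[["acd"]], lower = branch_um + 1)
    } else {
      branch_um <- NA_real_
      start_um <- rtrunc_norm(1, cfg$start_mean_um[["direct"]],
                              cfg$start_sd_um[["direct"]], lower = 0)
    }
    length_um <- rtrunc_norm(1, cfg$length_mean_um, cfg$length_sd_um, lower = 0.5)
    total_um <- start_um + length_um + cfg$distal_margin_um

    if (is.na(branch_um)) {
      path <- neurite_path(origin, ang, total_um, cfg)
    } else {
      trunk <- neurite_path(origin, ang, branch_um, cfg)
      split_ang <- runif(1, 0.3, 0.6) * sample(c(-1, 1), 1)
      arm <- neurite_path(trunk[nrow(trunk), ], ang + split_ang,
                          total_um - branch_um, cfg)
      path <- rbind(trunk, arm[-1, , drop = FALSE])
      # sibling dendrite on the other side of the bifurcation
      sib <- neurite_path(trunk[nrow(trunk), ], ang - split_ang,
                          runif(1, 8, 15), cfg)
      k_sib <- k # trunk shared; sibling gets its own entry below
      neurites <- add(neurites, list(
        neurite_id = sprintf("n%02d_branch", k_sib), role = "branch_dendrite",
        path = sib, is_ais = FALSE, length_um = NA_real_,
        ais_start_um = NA_real_, ais_length_um = NA_real_,
        branch_point_um = NA_real_
      ))
    }
    neurites <- add(neurites, list(
      neurite_id = sprintf("n%02d", k), role = "ais_axon", path = path,
      is_ais = TRUE, length_um = total_um,
      ais_start_um = start_um, ais_length_um = length_um,
      branch_point_um = branch_um
    ))
  }
  for (i in seq_len(cfg$n_plain_dendrites)) {
    k <- k + 1L
    ang <- angles[n_ais + i]
    origin <- r_px * c(cos(ang), sin(ang))
    neurites <- add(neurites, list(
      neurite_id = sprintf("n%02d", k), role = "dendrite",
      path = neurite_path(origin, ang, runif(1, 10, 20), cfg),
      is_ais = FALSE, length_um = NA_real_, ais_start_um = NA_real_,
      ais_length_um = NA_real_, branch_point_um = NA_real_
    ))
  }

  # translate to positive pixel space and size the canvas to fit
  pts <- do.call(rbind, lapply(neurites, function(n) n$path))
  pad <- cfg$stroke_width_px + 6
  lo <- pmin(apply(pts, 2, min), -r_px) - pad
  hi <- pmax(apply(pts, 2, max), r_px) + pad
  offset <- -lo
  neurites <- lapply(neurites, function(n) {
    n$path <- sweep(n$path, 2, offset, `+`)
    n
  })
  dims <- ceiling(hi + offset) + 1

  structure(
    list(
      neuron_id = neuron_id,
      localization_class = cls,
      pixel_size = cfg$pixel_size,
      soma_center_px = unname(offset),
      soma_radius_px = r_px,
      ais_amplitude = cfg$ais_amplitude,
      fill_intensity = cfg$fill_intensity,
      image_dim = c(ny = unname(ceiling(dims[2])), nx = unname(ceiling(dims[1]))),
      neurites = neurites,
      effect = NULL,
      varicosities = NULL,
      clamped = FALSE
    ),
    class = "ground_truth_neuron"
  )
}

#' Truth table for one or more ground-truth neurons
#'
#' One row per neurite, with the soma geometry repeated; this is the CSV
#' serialization of the generator's ground truth.
#'
#' @param neurons A `ground_truth_neuron` or list of them.
#' @return A tibble.
#' @export
truth_table <- function(neurons) {
  if (inherits(neurons, "ground_truth_neuron")) neurons <- list(neurons)
  purrr::map(neurons, function(nn) {
    purrr::map(nn$neurites, function(nrt) {
      tibble(
        neuron_id = nn$neuron_id,
        neurite_id = nrt$neurite_id,
        role = nrt$role,
        localization_class = nn$localization_class,
        is_ais = nrt$is_ais,
        length_um = nrt$length_um,
        ais_start_um = nrt$ais_start_um,
        ais_length_um = nrt$ais_length_um,
        branch_point_um = nrt$branch_point_um,
        ais_amplitude = nn$ais_amplitude,
        clamped = nn$clamped,
        soma_x_px = nn$soma_center_px[1],
        soma_y_px = nn$soma_center_px[2],
        soma_radius_px = nn$soma_radius_px,
        pixel_size = nn$pixel_size
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
}

#' Hand-trace surrogates for the AIS-bearing neurites of a neuron
#'
#' Returns the polyline(s) a human tracer would draw: from the soma edge
#' along each AIS-bearing neurite (through the bifurcation, for AcD cells).
#' Trace ids are `neuron_id/neurite_id` so that multi cells yield one trace
#' per AIS-bearing neurite.
#'
#' @param neuron A `ground_truth_neuron`.
#' @return Trace tibble (see [polyline_trace()]).
#' @export
traces_from_neuron <- function(neuron) {
  neuron$neurites |>
    purrr::keep(~ .x$is_ais) |>
    purrr::map(function(nrt) {
      tibble(
        neuron_id = paste0(neuron$neuron_id, "/", nrt$neurite_id),
        vertex_index = seq_len(nrow(nrt$path)),
        x_px = nrt$path[, 1],
        y_px = nrt$path[, 2],
        localization_class = neuron$localization_class
      )
    }) |>
    purrr::list_rbind()
}
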