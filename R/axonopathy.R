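#' Colchicine-like axonopathy effect
#'
#' Parameterizes the synthetic axon-injury phenotype: a proximal shift of
#' the AIS toward the soma, focal varicosity bumps on the fill channel
#' distal to the AIS, and multiplicative attenuation of both channels
#' beyond an onset distance (modeling distal degeneration and loss of
#' labeling).
#'
#' @param ais_start_shift Shift of the AIS start toward the soma, µm
#'   (>= 0). The default (3 µm) is small enough that clamping at the soma
#'   edge is rare under the AcD start distribution, yet many sampling steps
#'   wide, so recovery is unambiguous.
#' @param varicosity_count Number of varicosity bumps (integer >= 0).
#' @param varicosity_amplitude Added fill intensity at a bump center.
#' @param varicosity_sigma_um Gaussian radius of a bump, µm.
#' @param distal_attenuation_fraction In \[0, 1\]; intensities beyond the
#'   onset are multiplied by `1 - fraction`.
#' @param attenuation_start_um Onset distance for attenuation, µm from the
#'   soma edge; `NULL` (default) uses each neurite's AIS end.
#' @return An `axonopathy_effect` list.
#' @export
axonopathy_effect <- function(ais_start_shift = 3,
                              varicosity_count = 4,
                              varicosity_amplitude = 60,
                              varicosity_sigma_um = 0.5,
                              distal_attenuation_fraction = 0.5,
                              attenuation_start_um = NULL) {
  eff <- list(
    ais_start_shift = ais_start_shift,
    varicosity_count = as.integer(varicosity_count),
    varicosity_amplitude = varicosity_amplitude,
    varicosity_sigma_um = varicosity_sigma_um,
    distal_attenuation_fraction = distal_attenuation_fraction,
    attenuation_start_um = attenuation_start_um
  )
  bad <- c(
    if (!is.numeric(ais_start_shift) || ais_start_shift < 0)
      "`ais_start_shift` must be >= 0",
    if (is.na(eff$varicosity_count) || eff$varicosity_count < 0)
      "`varicosity_count` must be an integer >= 0",
    if (varicosity_amplitude < 0) "`varicosity_amplitude` must be >= 0",
    if (varicosity_sigma_um <= 0) "`varicosity_sigma_um` must be positive",
    if (distal_attenuation_fraction < 0 || distal_attenuation_fraction > 1)
      "`distal_attenuation_fraction` must lie in [0, 1]"
  )
  if (length(bad)) {
    abort(paste0("Invalid axonopathy effect:\n- ", paste(bad, collapse = "\n- ")))
  }
  structure(eff, class = "axonopathy_effect")
}

#' Apply an axonopathy effect to a ground-truth neuron
#'
#' Updates the truth — every AIS start is reduced by `ais_start_shift`
#' (clamped at 0 and flagged via the `clamped` field), lengths are
#' untouched — places varicosities at uniform-random arc positions distal
#' to the AIS on the first AIS-bearing neurite, and re-renders the scene
#' with distal attenuation. The noise sub-stream is derived from `seed`
#' exactly as in [simulate_neuron()], so a null effect reproduces the
#' original scene bit-for-bit and paired vehicle/effect cohorts share
#' their noise realizations.
#'
#' @param neuron A `ground_truth_neuron` with at least one AIS-bearing
#'   neurite.
#' @param effect An [axonopathy_effect()].
#' @param seed Integer seed; defaults to the seed the neuron was simulated
#'   with.
#' @param config A [generator_config()] supplying stroke width and noise.
#' @return List with updated `truth` and re-rendered `scene`.
#' @export
apply_axonopathy <- function(neuron, effect = axonopathy_effect(),
                             seed = neuron$seed, config = generator_config()) {
  if (!inherits(effect, "axonopathy_effect")) {
    abort("`effect` must be an axonopathy_effect().")
  }
  ais_idx <- which(purrr::map_lgl(neuron$neurites, "is_ais"))
  if (length(ais_idx) == 0) {
    abort("`neuron` has no AIS-bearing neurite.")
  }

  treated <- neuron
  for (i in ais_idx) {
    old <- treated$neurites[[i]]$ais_start_um
    shifted <- old - effect$ais_start_shift
    if (shifted < 0) {
      treated$clamped <- TRUE
      shifted <- 0
    }
    treated$neurites[[i]]$ais_start_um <- shifted
  }
  treated$effect <- effect

  if (effect$varicosity_count > 0) {
    set.seed(derive_seed(seed, 3))
    nrt <- treated$neurites[[ais_idx[1]]]
    lo <- nrt$ais_start_um + nrt$ais_length_um + 1
    hi <- nrt$length_um - 1
    if (hi <= lo) {
      abort(sprintf("Neurite %s too short to place varicosities.", nrt$neurite_id))
    }
    # bumps at least 4 sigma apart stay resolvable as distinct maxima
    arcs <- draw_separated_uniform(effect$varicosity_count, lo, hi,
                                   min_sep = 4 * effect$varicosity_sigma_um)
    treated$varicosities <- list(
      neurite_id = nrt$neurite_id,
      arcs_um = arcs,
      amplitude = effect$varicosity_amplitude,
      sigma_um = effect$varicosity_sigma_um
    )
  }

  scene <- render_scene(treated, config$stroke_width_px)
  scene <- add_scene_noise(scene, config$noise, derive_seed(seed, 2))
  list(truth = treated, scene = scene)
}

## uniform draws on [lo, hi] with a minimum pairwise separation; falls back
## to an evenly spaced grid if rejection fails (interval nearly saturated)
draw_separated_uniform <- function(n, lo, hi, min_sep, max_tries = 200) {
  if (n == 1) return(runif(1, lo, hi))
  for (k in seq_len(max_tries)) {
    x <- sort(runif(n, lo, hi))
    if (all(diff(x) >= min_sep)) return(x)
  }
  seq(lo, hi, length.out = n)
}
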