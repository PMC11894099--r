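#' Synthetic migration regime
#'
#' A regime bundles the generative parameters of one confinement
#' condition: the open extracellular space of the early wing, where
#' nuclei are mostly round and deform rarely, or the vessel-like
#' channels of later stages, where nuclei are more elongated and undergo
#' more frequent and longer squeezing episodes.
#'
#' Squeezing is generated as a two-state Markov chain (round/squeeze)
#' with per-frame entry and exit probabilities. At 30 s frames the
#' vessel defaults (`p_enter_squeeze = 0.15`, `p_exit_squeeze = 0.25`)
#' give a stationary squeezing occupancy of
#' \eqn{p_{enter}/(p_{enter}+p_{exit}) = 0.375} and a mean episode of 4
#' frames (2 min); the open defaults (0.05, 0.5) give occupancy ~0.09
#' and 1-min episodes.
#'
#' @param name `"open"` or `"vessel"`; selects the default parameter set.
#' @param nucleus_diameter_um nuclear diameter in micrometres.
#' @param speed_um_per_min migration speed.
#' @param p_enter_squeeze,p_exit_squeeze per-frame Markov transition
#'   probabilities into and out of the squeezing state.
#' @param sf_baseline,sf_squeeze emitted shape factor in the round state
#'   (must be < 0.4) and squeezing state (must be >= 0.4).
#' @param sf_jitter_sd standard deviation of the truncated Gaussian
#'   jitter added to the emitted SF (truncated so the emitted value
#'   stays on its state's side of the 0.4 squeezing threshold).
#' @param channel_width_um vessel channel width, or `NULL` for
#'   unconfined motion.
#' @return object of class `synth_regime`.
#' @examples
#' synth_regime("vessel")
#' @export
synth_regime <- function(name = c("open", "vessel"),
                         nucleus_diameter_um = NULL,
                         speed_um_per_min = NULL,
                         p_enter_squeeze = NULL,
                         p_exit_squeeze = NULL,
                         sf_baseline = NULL,
                         sf_squeeze = NULL,
                         sf_jitter_sd = 0.03,
                         channel_width_um = NULL) {
  name <- match.arg(name)
  def <- if (name == "vessel") {
    list(nucleus_diameter_um = 5, speed_um_per_min = 2,
         p_enter_squeeze = 0.15, p_exit_squeeze = 0.25,
         sf_baseline = 0.25, sf_squeeze = 0.65, channel_width_um = 6)
  } else {
    list(nucleus_diameter_um = 5, speed_um_per_min = 2,
         p_enter_squeeze = 0.05, p_exit_squeeze = 0.5,
         sf_baseline = 0.2, sf_squeeze = 0.5, channel_width_um = NULL)
  }
  r <- list(
    name = name,
    nucleus_diameter_um = nucleus_diameter_um %||% def$nucleus_diameter_um,
    speed_um_per_min = speed_um_per_min %||% def$speed_um_per_min,
    p_enter_squeeze = p_enter_squeeze %||% def$p_enter_squeeze,
    p_exit_squeeze = p_exit_squeeze %||% def$p_exit_squeeze,
    sf_baseline = sf_baseline %||% def$sf_baseline,
    sf_squeeze = sf_squeeze %||% def$sf_squeeze,
    sf_jitter_sd = sf_jitter_sd,
    channel_width_um = if (is.null(channel_width_um) && name == "vessel")
      def$channel_width_um else channel_width_um
  )
  validate_regime(r)
  structure(r, class = "synth_regime")
}

validate_regime <- function(r) {
  for (p in c("p_enter_squeeze", "p_exit_squeeze")) {
    v <- r[[p]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort(sprintf("%s must be a probability in [0, 1]", p))
    }
  }
  if (r$nucleus_diameter_um <= 0) abort("nucleus_diameter_um must be positive")
  if (r$speed_um_per_min < 0) abort("speed_um_per_min must be non-negative")
  if (r$sf_baseline < 0 || r$sf_baseline >= 0.4) {
    abort("sf_baseline must be in [0, 0.4)")
  }
  if (r$sf_squeeze < 0.4 || r$sf_squeeze >= 1) {
    abort("sf_squeeze must be in [0.4, 1)")
  }
  if (r$sf_jitter_sd < 0) abort("sf_jitter_sd must be non-negative")
  if (!is.null(r$channel_width_um) && r$channel_width_um <= 0) {
    abort("channel_width_um must be positive")
  }
  invisible(r)
}

#' @export
print.synth_regime <- function(x, ...) {
  occ <- if (x$p_enter_squeeze + x$p_exit_squeeze > 0) {
    x$p_enter_squeeze / (x$p_enter_squeeze + x$p_exit_squeeze)
  } else 0
  cat(sprintf(
    "synth_regime '%s': d=%.1f um, v=%.1f um/min, p_enter=%.2f, p_exit=%.2f\n",
    x$name, x$nucleus_diameter_um, x$speed_um_per_min,
    x$p_enter_squeeze, x$p_exit_squeeze
  ))
  cat(sprintf("  SF %.2f/%.2f (round/squeeze), stationary occupancy %.3f\n",
              x$sf_baseline, x$sf_squeeze, occ))
  invisible(x)
}

#' Synthetic movie configuration
#'
#' @param regime a [synth_regime()].
#' @param n_nuclei number of nuclei.
#' @param n_frames number of timepoints (>= 2).
#' @param frame_interval_s frame interval in seconds. The default 30 s
#'   makes a 40-frame movie span the standard 20-min imaging window.
#' @param pixel_size_um in-plane pixel size; the default 0.3 makes a
#'   17-px heatmap bin about 5 um.
#' @param z_step_um spacing between z slices.
#' @param z_slices number of z slices.
#' @param field_px `(y, x)` field size in pixels.
#' @param noise_gaussian_sd additive Gaussian read-noise SD (intensity
#'   units).
#' @param noise_poisson logical; apply Poisson shot noise.
#' @param fg_intensity,bg_intensity nuclear and background intensities.
#' @param seed master seed; per-nucleus streams are derived from it by a
#'   stable hash of the nucleus id, so adding a nucleus does not perturb
#'   the trajectories of the others.
#' @return object of class `synth_movie_config`.
#' @export
synth_movie_config <- function(regime = synth_regime("vessel"),
                               n_nuclei = 3, n_frames = 40,
                               frame_interval_s = 30, pixel_size_um = 0.3,
                               z_step_um = 1, z_slices = 5,
                               field_px = c(160, 200),
                               noise_gaussian_sd = 5, noise_poisson = TRUE,
                               fg_intensity = 200, bg_intensity = 20,
                               seed = 1) {
  if (!inherits(regime, "synth_regime")) abort("regime must be a synth_regime")
  if (n_frames < 2) abort("n_frames must be >= 2")
  if (n_nuclei < 1) abort("n_nuclei must be >= 1")
  if (pixel_size_um <= 0) abort("pixel_size_um must be positive")
  if (frame_interval_s <= 0) abort("frame_interval_s must be positive")
  if (z_slices < 1) abort("z_slices must be >= 1")
  if (length(field_px) != 2 || any(field_px < 8)) {
    abort("field_px must be (y, x) with both >= 8")
  }
  structure(
    list(
      regime = regime, n_nuclei = as.integer(n_nuclei),
      n_frames = as.integer(n_frames),
      frame_interval_s = frame_interval_s, pixel_size_um = pixel_size_um,
      z_step_um = z_step_um, z_slices = as.integer(z_slices),
      field_px = as.integer(field_px),
      noise_gaussian_sd = noise_gaussian_sd,
      noise_poisson = isTRUE(noise_poisson),
      fg_intensity = fg_intensity, bg_intensity = bg_intensity,
      seed = as.integer(seed)
    ),
    class = "synth_movie_config"
  )
}

# stable per-nucleus RNG seed derived from the master seed; keeps each
# nucleus's trajectory independent of how many others are simulated
nucleus_seed <- function(master_seed, nucleus_id) {
  as.integer((as.double(master_seed) * 48271 + nucleus_id * 16807) %%
               2147483647)
}
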