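#' Simulation configuration for synthetic wound-repair movies
#'
#' Defines the acquisition geometry and timing of a synthetic two-photon
#' laser-ablation experiment. Defaults mirror the conditions of the imaging
#' assays the generator emulates: 512 x 512 pixel frames, a circular wound
#' ROI of 2.5 um^2 (20 pixels in diameter, fixing the pixel size at
#' ~0.0892 um), two pre-wound frames followed by 100 post-wound frames, and
#' a resealing phase of ~30 s.
#'
#' Frame `f` is acquired at time `(f - n_prewound_frames) * frame_interval`,
#' so the last pre-wound frame is at t = 0 and the first post-wound frame at
#' t = `frame_interval`.
#'
#' @param image_shape integer length-2, image size in pixels (rows = y,
#'   columns = x).
#' @param pixel_size pixel edge length in um. The default makes the 2.5 um^2
#'   wound ROI 20 pixels in diameter.
#' @param n_frames total number of frames including pre-wound frames.
#' @param frame_interval time between frames in seconds.
#' @param n_prewound_frames frames recorded before ablation (>= 1).
#' @param wound_center wound ROI center `(x, y)` in um; `NULL` places it at
#'   the cell center.
#' @param wound_area wound ROI area in um^2.
#' @param reseal_time time (s post-wound) at which resealing typically
#'   completes; the endocytic burst of the event process starts here.
#' @param cell_center,cell_axes center `(x, y)` and semi-axes `(a, b)` of the
#'   elliptical cell footprint, um. `NULL` centers the cell in the field with
#'   semi-axes at 42% and 36% of the field size.
#' @param neighbor_cell logical; render a second, unwounded cell (used as the
#'   background reference for influx normalization).
#' @param rng_seed integer seed used by the generator unless overridden.
#'
#' @return An object of class `wound_sim_config` (a named list).
#' @seealso [event_params()], [simulate_movie()]
#' @export
#' @examples
#' cfg <- sim_config(image_shape = c(128, 128), pixel_size = 0.2, n_frames = 12)
#' cfg$wound_radius
sim_config <- function(image_shape = c(512L, 512L),
                       pixel_size = sqrt(2.5 / pi) / 10,
                       n_frames = 102L,
                       frame_interval = 1,
                       n_prewound_frames = 2L,
                       wound_center = NULL,
                       wound_area = 2.5,
                       reseal_time = 30,
                       cell_center = NULL,
                       cell_axes = NULL,
                       neighbor_cell = TRUE,
                       rng_seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8))
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  if (n_prewound_frames < 1) abort("`n_prewound_frames` must be >= 1.")
  if (n_frames <= n_prewound_frames) abort("`n_frames` must exceed `n_prewound_frames`.")
  if (frame_interval <= 0) abort("`frame_interval` must be > 0.")
  if (wound_area <= 0) abort("`wound_area` must be > 0.")
  if (reseal_time < 0) abort("`reseal_time` must be >= 0.")

  field <- rev(image_shape) * pixel_size # (x extent, y extent) um
  if (is.null(cell_center)) cell_center <- field / 2
  if (is.null(cell_axes)) cell_axes <- c(0.42, 0.36) * min(field)
  if (any(cell_axes <= 0)) abort("`cell_axes` must be > 0.")
  if (is.null(wound_center)) wound_center <- cell_center
  if (any(wound_center < 0) || wound_center[1] > field[1] || wound_center[2] > field[2]) {
    abort("`wound_center` must lie inside the image.")
  }

  structure(
    list(
      image_shape = as.integer(image_shape),
      pixel_size = pixel_size,
      n_frames = as.integer(n_frames),
      frame_interval = frame_interval,
      n_prewound_frames = as.integer(n_prewound_frames),
      wound_center = as.numeric(wound_center),
      wound_area = wound_area,
      wound_radius = sqrt(wound_area / pi),
      reseal_time = reseal_time,
      cell_center = as.numeric(cell_center),
      cell_axes = as.numeric(cell_axes),
      neighbor_cell = isTRUE(neighbor_cell),
      rng_seed = as.integer(rng_seed)
    ),
    class = "wound_sim_config"
  )
}

#' Event-process parameters for the synthetic generator
#'
#' Punctae are generated as an inhomogeneous spatio-temporal Poisson process
#' over the elliptical cell footprint. A steady birth-death process (birth
#' rate `steady_rate` per um^2 per s, exponential lifetimes) runs on both
#' marker channels for the whole acquisition; a wound-evoked exocytic burst
#' multiplies the exocytic-marker rate by `exo_boost_by_ring[k]` inside
#' concentric ring k during `exo_window`; a delayed endocytic burst
#' multiplies the endocytic-marker rate by `endo_boost` after the resealing
#' phase. Each burst endocytic event is, with probability `assoc_prob`,
#' placed at the position of a uniformly chosen earlier exocytic event plus
#' isotropic Gaussian jitter of standard deviation `assoc_sd`; otherwise it
#' is placed uniformly in the cell.
#'
#' @param steady_rate steady-state event birth rate, events um^-2 s^-1.
#' @param exo_boost_by_ring multiplicative rate factors per concentric ring
#'   during the exocytic window (ring 1 innermost); regions beyond the last
#'   ring keep factor 1.
#' @param exo_window `(t0, t1]` seconds post-wound of the exocytic burst.
#' @param endo_boost multiplicative factor for the endocytic-marker rate
#'   during the endocytic window (from `reseal_time` to the end).
#' @param assoc_prob probability that a burst endocytic event is coupled to a
#'   previous exocytic site.
#' @param assoc_sd spatial jitter (um) of coupled endocytic placements.
#' @param lifetime_mean mean punctae lifetime, s.
#' @param ring_increment diameter increment (um) of the rings that scale the
#'   exocytic burst (matching the analysis-side default of 20 um).
#' @param spot_amplitude peak intensity of a rendered puncta (arbitrary units).
#' @param spot_sigma Gaussian PSF sigma of a rendered puncta, um.
#' @param bleach_rate photobleaching rate, s^-1 (multiplicative
#'   `exp(-bleach_rate * t)` applied before noise).
#' @param noise_sd Gaussian read-noise standard deviation (intensity units).
#' @param shot_noise logical; add Poisson shot noise on the rendered signal.
#'
#' @return An object of class `wound_event_params`.
#' @export
event_params <- function(steady_rate = 5e-4,
                         exo_boost_by_ring = c(25, 8, 3, 1, 1, 1),
                         exo_window = c(0, 10),
                         endo_boost = 4,
                         assoc_prob = 0.8,
                         assoc_sd = 0.5,
                         lifetime_mean = 4,
                         ring_increment = 20,
                         spot_amplitude = 200,
                         spot_sigma = 0.15,
                         bleach_rate = 0.005,
                         noise_sd = 20,
                         shot_noise = FALSE) {
  if (steady_rate < 0) abort("`steady_rate` must be >= 0.")
  if (any(exo_boost_by_ring < 0)) abort("`exo_boost_by_ring` must be >= 0.")
  if (length(exo_window) != 2 || diff(exo_window) <= 0) {
    abort("`exo_window` must be an increasing (t0, t1] pair.")
  }
  if (endo_boost < 0) abort("`endo_boost` must be >= 0.")
  if (assoc_prob < 0 || assoc_prob > 1) abort("`assoc_prob` must be in [0, 1].")
  if (assoc_sd < 0) abort("`assoc_sd` must be >= 0.")
  if (lifetime_mean <= 0) abort("`lifetime_mean` must be > 0.")
  if (ring_increment <= 0) abort("`ring_increment` must be > 0.")
  if (spot_sigma <= 0) abort("`spot_sigma` must be > 0.")
  if (bleach_rate < 0 || noise_sd < 0) abort("rates and noise must be >= 0.")

  structure(
    list(
      steady_rate = steady_rate,
      exo_boost_by_ring = exo_boost_by_ring,
      exo_window = exo_window,
      endo_boost = endo_boost,
      assoc_prob = assoc_prob,
      assoc_sd = assoc_sd,
      lifetime_mean = lifetime_mean,
      ring_increment = ring_increment,
      spot_amplitude = spot_amplitude,
      spot_sigma = spot_sigma,
      bleach_rate = bleach_rate,
      noise_sd = noise_sd,
      shot_noise = isTRUE(shot_noise)
    ),
    class = "wound_event_params"
  )
}

#' @export
print.wound_sim_config <- function(x, ...) {
  cat("<wound_sim_config>\n")
  cat(sprintf("  image: %d x %d px @ %.4f um/px (%.1f x %.1f um)\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size,
              x$image_shape[2] * x$pixel_size, x$image_shape[1] * x$pixel_size))
  cat(sprintf("  frames: %d (%d pre-wound) @ %.2f s\n",
              x$n_frames, x$n_prewound_frames, x$frame_interval))
  cat(sprintf("  wound: %.2f um^2 (r = %.3f um) at (%.1f, %.1f) um; reseal ~%.0f s\n",
              x$wound_area, x$wound_radius, x$wound_center[1], x$wound_center[2],
              x$reseal_time))
  invisible(x)
}

# Frame acquisition times (s): last pre-wound frame at t = 0.
frame_times <- function(cfg) {
  (seq_len(cfg$n_frames) - cfg$n_prewound_frames) * cfg$frame_interval
}

# Uniform samples inside the elliptical cell footprint.
sample_in_ellipse <- function(n, center, axes) {
  r <- sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = center[1] + axes[1] * r * cos(th),
        y = center[2] + axes[2] * r * sin(th))
}

in_ellipse <- function(x, y, center, axes) {
  ((x - center[1]) / axes[1])^2 + ((y - center[2]) / axes[2])^2 <= 1
}
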