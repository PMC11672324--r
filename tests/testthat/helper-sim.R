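# Shared fixtures: small synthetic configurations sized for fast tests.
# Geometry is events-only where possible; rendering tests use small frames.

small_cfg <- function(n_frames = 50L, reseal_time = 30, seed = 1L,
                      image = 256L, px = 0.2) {
  sim_config(image_shape = c(image, image), pixel_size = px,
             n_frames = n_frames, frame_interval = 1,
             n_prewound_frames = 2L, reseal_time = reseal_time,
             rng_seed = seed)
}

# events-only geometry: a large cell in physical units (no rendering),
# rings with an 8 um diameter increment so circle 6 fits inside the cell
events_cfg <- function(n_frames = 50L, reseal_time = 30, seed = 1L) {
  sim_config(image_shape = c(512L, 512L), pixel_size = 0.125,
             n_frames = n_frames, frame_interval = 1,
             n_prewound_frames = 2L, reseal_time = reseal_time,
             cell_axes = c(30, 26), rng_seed = seed)
}

events_rings <- function(cfg) {
  build_rings(cfg$wound_center, cfg$wound_area, n_rings = 6,
              diameter_increment = 8)
}

# a tiny rendering config for detection tests: fine pixels, sparse spots
render_cfg <- function(n_frames = 8L, seed = 1L) {
  sim_config(image_shape = c(160L, 160L), pixel_size = sqrt(2.5 / pi) / 10,
             n_frames = n_frames, frame_interval = 1,
             n_prewound_frames = 2L, rng_seed = seed)
}

# punctae tibble from bare coordinates (single frame)
punctae_tbl <- function(x, y, frame = 1L, time_s = NULL) {
  tibble::tibble(frame = frame, time_s = time_s %||% rep(1, length(x)),
                 label = seq_along(x), x_um = x, y_um = y,
                 area_um2 = NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# blank single-channel movie builder for detector tests
blank_movie <- function(ny = 64, nx = 64, n_frames = 1, value = 0, px = 0.1) {
  as_wound_movie(array(value, dim = c(n_frames, 1, ny, nx)),
                 pixel_size = px, frame_interval = 1, wound_frame = 2L,
                 wound_center = c(nx, ny) / 2 * px, channels = "exo")
}

# attach movie metadata to hand-built punctae tables
set_punctae_meta_pub <- function(p, n_frames, wound_frame) {
  attr(p, "movie_meta") <- list(n_frames = n_frames, frame_interval = 1,
                                wound_frame = wound_frame, pixel_size = 1)
  p
}
set_meta_1frame <- function(p) set_punctae_meta_pub(p, 1L, 1L)

# add a Gaussian spot to a [y, x] matrix at 0-based pixel-center coords (um)
add_spot <- function(img, x_um, y_um, amplitude, sigma_um, px) {
  ny <- nrow(img); nx <- ncol(img)
  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px
  img + amplitude * outer(exp(-(ys - y_um)^2 / (2 * sigma_um^2)),
                          exp(-(xs - x_um)^2 / (2 * sigma_um^2)))
}
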