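#' Simulate a calibrated multi-channel wound-repair movie with ground truth
#'
#' Renders a synthetic time-lapse stack emulating a laser-ablation repair
#' experiment. Channel 1 carries the membrane-impermeable wound dye: an
#' elliptical cell drawn as a bright outline plus low interior signal, with
#' post-wound dye influx that either saturates (`I0 * (1 - exp(-t / tau))`,
#' resealed cell) or grows linearly (failed resealing), plus a localized
#' dye accumulation at the wound site. Channel 2 renders the exocytic-marker
#' punctae and channel 3 (when the endocytic process is enabled) the
#' endocytic-marker punctae, each live event as an isotropic Gaussian spot.
#' Photobleaching multiplies all signal by `exp(-bleach_rate * t)` before
#' Gaussian read noise (and optional Poisson shot noise) is added.
#'
#' Identical `cfg`, `proc` and `seed` produce bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @param proc an [event_params()].
#' @param resealed logical: does the wound reseal (saturating influx) or fail
#'   (linear influx)?
#' @param seed integer seed; defaults to `cfg$rng_seed`.
#' @param influx_amplitude saturating-influx plateau amplitude (resealed).
#' @param influx_tau saturation time constant, s.
#' @param influx_slope linear influx slope (failed), intensity/s.
#' @param membrane_amplitude,interior_amplitude dye baseline intensities of
#'   the cell outline band and interior.
#' @param wound_blob_amplitude,wound_blob_sigma localized wound-site dye
#'   accumulation (peak intensity, Gaussian sigma in um).
#'
#' @return A list with elements `movie` (a `wound_movie`) and `truth` (the
#'   ground truth: `events` table, `influx_class`, `influx_params`).
#' @export
simulate_movie <- function(cfg, proc, resealed = TRUE, seed = cfg$rng_seed,
                           influx_amplitude = 60, influx_tau = 8,
                           influx_slope = 2.5,
                           membrane_amplitude = 100, interior_amplitude = 10,
                           wound_blob_amplitude = 80, wound_blob_sigma = 1.5) {
  stopifnot(inherits(cfg, "wound_sim_config"), inherits(proc, "wound_event_params"))
  events <- simulate_events(cfg, proc, seed = seed)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed + 1L)  # independent of the event draw, still seed-determined

  ny <- cfg$image_shape[1]; nx <- cfg$image_shape[2]
  px <- cfg$pixel_size
  xs <- (seq_len(nx) - 1) * px
  ys <- (seq_len(ny) - 1) * px
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)

  e_val <- sqrt(((X - cfg$cell_center[1]) / cfg$cell_axes[1])^2 +
                ((Y - cfg$cell_center[2]) / cfg$cell_axes[2])^2)
  cell_mask <- e_val <= 1
  outline <- e_val <= 1 & e_val >= 0.93
  dye_base <- membrane_amplitude * outline + interior_amplitude * cell_mask

  neighbor_mask <- matrix(FALSE, ny, nx)
  if (cfg$neighbor_cell) {
    n_ctr <- c(min(xs) + 0.14 * diff(range(xs)), min(ys) + 0.14 * diff(range(ys)))
    n_ax <- 0.35 * cfg$cell_axes
    ne_val <- sqrt(((X - n_ctr[1]) / n_ax[1])^2 + ((Y - n_ctr[2]) / n_ax[2])^2)
    # the unwounded reference cell is rendered dimmer than the wounded cell
    # (its corrected pre-wound intensity must stay below the wounded cell's)
    neighbor_mask <- ne_val <= 1 & !cell_mask
    dye_base <- dye_base +
      0.5 * membrane_amplitude * (ne_val <= 1 & ne_val >= 0.93 & !cell_mask) +
      0.5 * interior_amplitude * neighbor_mask
  }

  wound_blob <- exp(-((X - cfg$wound_center[1])^2 + (Y - cfg$wound_center[2])^2) /
                      (2 * wound_blob_sigma^2))

  n_channels <- if (proc$endo_boost > 1 || any(events$marker == "endo")) 3L else 2L
  tt <- frame_times(cfg)
  dat <- array(0, dim = c(cfg$n_frames, n_channels, ny, nx))

  for (f in seq_len(cfg$n_frames)) {
    t <- tt[f]
    bleach <- exp(-proc$bleach_rate * (t - tt[1]))
    # channel 1: dye
    ch1 <- dye_base
    if (t > 0) {
      influx <- if (resealed) influx_amplitude * (1 - exp(-t / influx_tau)) else
        influx_slope * t
      ch1 <- ch1 + influx * cell_mask +
        wound_blob_amplitude * (1 - exp(-t / influx_tau)) * wound_blob
    }
    dat[f, 1, , ] <- add_noise(ch1 * bleach, proc)
    # marker channels
    for (ch in 2:n_channels) {
      mk <- if (ch == 2) "exo" else "endo"
      alive <- events$marker == mk &
        events$t_birth <= t & t < events$t_birth + events$lifetime
      img <- render_spots(events$x[alive], events$y[alive], ny, nx, px,
                          proc$spot_amplitude, proc$spot_sigma)
      dat[f, ch, , ] <- add_noise(img * bleach, proc)
    }
  }

  movie <- structure(
    list(
      data = dat,
      pixel_size = px,
      frame_interval = cfg$frame_interval,
      wound_frame = cfg$n_prewound_frames + 1L,
      wound_center = cfg$wound_center,
      wound_area = cfg$wound_area,
      cell_mask = cell_mask,
      neighbor_mask = neighbor_mask,
      channels = c("dye", "exo", "endo")[seq_len(n_channels)]
    ),
    class = "wound_movie"
  )
  truth <- list(
    events = events,
    influx_class = if (resealed) "resealed" else "failed",
    influx_params = if (resealed) {
      c(amplitude = influx_amplitude, tau = influx_tau)
    } else {
      c(slope = influx_slope)
    }
  )
  list(movie = movie, truth = truth)
}

# Gaussian spots rendered on local windows (+-4 sigma) for speed.
render_spots <- function(x, y, ny, nx, px, amplitude, sigma) {
  img <- matrix(0, ny, nx)
  if (length(x) == 0) return(img)
  s_px <- sigma / px
  half <- max(1L, ceiling(4 * s_px))
  for (i in seq_along(x)) {
    cx <- x[i] / px; cy <- y[i] / px  # 0-based pixel coordinates
    c0 <- round(cx) + 1L; r0 <- round(cy) + 1L
    cols <- max(1L, c0 - half):min(nx, c0 + half)
    rows <- max(1L, r0 - half):min(ny, r0 + half)
    if (length(cols) == 0 || length(rows) == 0) next
    gx <- exp(-((cols - 1) - cx)^2 / (2 * s_px^2))
    gy <- exp(-((rows - 1) - cy)^2 / (2 * s_px^2))
    img[rows, cols] <- img[rows, cols] + amplitude * outer(gy, gx)
  }
  img
}

add_noise <- function(img, proc) {
  if (proc$shot_noise) {
    img <- matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img))
  }
  if (proc$noise_sd > 0) {
    img <- img + rnorm(length(img), 0, proc$noise_sd)
  }
  img
}

#' Assemble a calibrated movie object
#'
#' Wraps an intensity array and its acquisition metadata into the
#' `wound_movie` container used across the package — the entry point for
#' externally acquired data (see also [read_movie_tiff()]).
#'
#' @param data numeric array in `[frame, channel, y, x]` order.
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval seconds per frame.
#' @param wound_frame 1-based index of the first post-wound frame (must
#'   leave at least one pre-wound frame).
#' @param wound_center `(x, y)` of the wound ROI center, um.
#' @param wound_area wound ROI area, um^2.
#' @param cell_mask,neighbor_mask optional logical `[y, x]` masks of the
#'   wounded cell and an unwounded reference cell.
#' @param channels channel names.
#' @return A `wound_movie`.
#' @export
as_wound_movie <- function(data, pixel_size, frame_interval = 1,
                           wound_frame = 3L, wound_center, wound_area = 2.5,
                           cell_mask = NULL, neighbor_mask = NULL,
                           channels = NULL) {
  d <- dim(data)
  if (length(d) != 4) abort("`data` must be a [frame, channel, y, x] array.")
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  if (wound_frame < 2) abort("`wound_frame` must leave at least one pre-wound frame.")
  if (wound_center[1] < 0 || wound_center[1] > d[4] * pixel_size ||
      wound_center[2] < 0 || wound_center[2] > d[3] * pixel_size) {
    abort("`wound_center` must lie within the image bounds.")
  }
  if (is.null(channels)) channels <- c("dye", "exo", "endo")[seq_len(d[2])]
  structure(
    list(data = data, pixel_size = pixel_size,
         frame_interval = frame_interval, wound_frame = as.integer(wound_frame),
         wound_center = as.numeric(wound_center), wound_area = wound_area,
         cell_mask = cell_mask, neighbor_mask = neighbor_mask,
         channels = channels),
    class = "wound_movie"
  )
}

#' @export
print.wound_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<wound_movie> %d frames x %d channels x %d x %d px (%.4f um/px, %.2f s/frame)\n",
              d[1], d[2], d[3], d[4], x$pixel_size, x$frame_interval))
  cat(sprintf("  wound frame %d; wound %.2f um^2 at (%.1f, %.1f) um; channels: %s\n",
              x$wound_frame, x$wound_area, x$wound_center[1], x$wound_center[2],
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Extract one frame image from a movie
#'
#' @param movie a `wound_movie`.
#' @param frame frame index (1-based).
#' @param channel channel index or name.
#' @return A `[y, x]` intensity matrix.
#' @export
frame_image <- function(movie, frame, channel = 1) {
  if (is.character(channel)) channel <- match(channel, movie$channels)
  d <- dim(movie$data)
  stopifnot(frame >= 1, frame <= d[1], !is.na(channel), channel >= 1,
            channel <= d[2])
  matrix(movie$data[frame, channel, , ], d[3], d[4])
}

#' Frame acquisition times of a movie
#'
#' Times are in seconds with the last pre-wound frame at t = 0.
#' @param movie a `wound_movie`.
#' @return Numeric vector, one time per frame.
#' @export
movie_times <- function(movie) {
  (seq_len(dim(movie$data)[1]) - (movie$wound_frame - 1L)) * movie$frame_interval
}
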