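#' Write / read a movie as multi-page TIFF with a JSON sidecar
#'
#' Movies are written as 32-bit float multi-page TIFF in TCYX page order
#' (frame-major, channels within frame). Intensities are scaled into
#' `[0, 1]` for storage; the scale factor and all calibration metadata
#' (pixel size, frame interval, wound geometry, channel names) travel in a
#' JSON sidecar at `<path>.json`, which [read_movie_tiff()] uses to restore
#' the calibrated `wound_movie`. Masks are stored as extra pages listed in
#' the sidecar.
#'
#' @param movie a `wound_movie`.
#' @param path output TIFF path.
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` returns a `wound_movie`.
#' @export
write_movie_tiff <- function(movie, path) {
  d <- dim(movie$data)
  offset <- min(movie$data)
  scale <- max(max(movie$data) - offset, 1e-12)
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (f in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      pages[[k]] <- (frame_image(movie, f, ch) - offset) / scale
      k <- k + 1L
    }
  }
  n_masks <- 0L
  for (m in list(movie$cell_mask, movie$neighbor_mask)) {
    if (!is.null(m)) {
      pages[[length(pages) + 1L]] <- matrix(as.numeric(m), d[3], d[4])
      n_masks <- n_masks + 1L
    }
  }
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  meta <- list(
    dimension_order = "TCYX",
    n_frames = d[1], n_channels = d[2], ny = d[3], nx = d[4],
    pixel_size_um = movie$pixel_size,
    frame_interval_s = movie$frame_interval,
    wound_frame = movie$wound_frame,
    wound_center_um = movie$wound_center,
    wound_area_um2 = movie$wound_area,
    channels = movie$channels,
    intensity_scale = scale,
    intensity_offset = offset,
    mask_pages = if (n_masks > 0) {
      as.list(setNames(d[1] * d[2] + seq_len(n_masks),
                       c("cell_mask", "neighbor_mask")[seq_len(n_masks)]))
    } else NULL
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- c(meta$n_frames, meta$n_channels, meta$ny, meta$nx)
  dat <- array(0, dim = d)
  k <- 1L
  for (f in seq_len(d[1])) {
    for (ch in seq_len(d[2])) {
      dat[f, ch, , ] <- pages[[k]] * meta$intensity_scale +
        (meta$intensity_offset %||% 0)
      k <- k + 1L
    }
  }
  cell_mask <- neighbor_mask <- NULL
  if (!is.null(meta$mask_pages)) {
    mp <- meta$mask_pages
    if ("cell_mask" %in% names(mp)) cell_mask <- pages[[mp[["cell_mask"]]]] > 0.5
    if ("neighbor_mask" %in% names(mp)) neighbor_mask <- pages[[mp[["neighbor_mask"]]]] > 0.5
  }
  structure(
    list(data = dat, pixel_size = meta$pixel_size_um,
         frame_interval = meta$frame_interval_s,
         wound_frame = meta$wound_frame,
         wound_center = meta$wound_center_um,
         wound_area = meta$wound_area_um2,
         cell_mask = cell_mask, neighbor_mask = neighbor_mask,
         channels = meta$channels),
    class = "wound_movie"
  )
}

#' Write / read punctae tables as CSV
#'
#' The `pixels` mask column is dropped on write (CSV holds the per-frame
#' punctae geometry: frame, label, centroid, area).
#'
#' @param punctae a punctae tibble.
#' @param path CSV path.
#' @export
write_punctae_csv <- function(punctae, path) {
  keep <- intersect(c("frame", "time_s", "label", "x_um", "y_um", "area_um2",
                      "type"), names(punctae))
  readr::write_csv(as_tibble(punctae)[, keep], path)
  invisible(path)
}

#' @rdname write_punctae_csv
#' @export
read_punctae_csv <- function(path) {
  as_tibble(readr::read_csv(path, show_col_types = FALSE))
}

#' Write ground-truth events as CSV plus a JSON sidecar of scalars
#'
#' @param truth the `truth` element of [simulate_movie()].
#' @param path CSV path for the event table; scalars go to `<path>.json`.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(truth$events, path)
  scalars <- list(influx_class = truth$influx_class,
                  influx_params = as.list(truth$influx_params))
  jsonlite::write_json(scalars, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
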