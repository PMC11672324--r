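#' Detector parameters
#'
#' The detector replaces interactive pixel classification with a
#' deterministic pipeline: band-pass filtering (difference of Gaussians),
#' thresholding, connected-component labeling, and size filtering. The
#' workflow's probability-map route is preserved via
#' [binarize_probability_maps()].
#'
#' Threshold kinds for intensity mode:
#' * `"zscore"` (default): threshold at `median + threshold * mad` of the
#'   band-pass image — robust and scale-adaptive; a blank frame yields no
#'   detections. The default of 6 is the standard preset; `preset =
#'   "strict"` uses 10, the higher-stringency setting used for
#'   nearest-neighbor reference compilation.
#' * `"quantile"`: threshold at the given intensity quantile (0, 1).
#' * `"absolute"`: threshold at the given band-pass intensity.
#'
#' @param band_pass_sigma spot scale for the band-pass filter, um (match the
#'   PSF sigma).
#' @param threshold threshold value, interpreted per `threshold_kind`.
#' @param threshold_kind one of `"zscore"`, `"quantile"`, `"absolute"`.
#' @param min_area,max_area puncta area bounds, um^2 (inclusive).
#' @param mode `"intensity"` (detect on raw frames) or `"probability_map"`.
#' @param preset `"default"` or `"strict"` (sets `threshold` to 10 under the
#'   zscore kind unless given explicitly).
#' @return A `wound_detector_params` list.
#' @export
detector_params <- function(band_pass_sigma = 0.15,
                            threshold = NULL,
                            threshold_kind = c("zscore", "quantile", "absolute"),
                            min_area = 0.02, max_area = 3,
                            mode = c("intensity", "probability_map"),
                            preset = c("default", "strict")) {
  threshold_kind <- match.arg(threshold_kind)
  mode <- match.arg(mode)
  preset <- match.arg(preset)
  if (is.null(threshold)) {
    threshold <- switch(threshold_kind,
      zscore = if (preset == "strict") 10 else 6,
      quantile = 0.995,
      absolute = abort("`threshold` must be given for the absolute kind.")
    )
  }
  if (band_pass_sigma <= 0) abort("`band_pass_sigma` must be > 0.")
  if (min_area >= max_area) abort("`min_area` must be < `max_area`.")
  if (threshold_kind == "quantile" && (threshold <= 0 || threshold >= 1)) {
    abort("Quantile threshold must be in (0, 1).")
  }
  structure(list(band_pass_sigma = band_pass_sigma, threshold = threshold,
                 threshold_kind = threshold_kind, min_area = min_area,
                 max_area = max_area, mode = mode, preset = preset),
            class = "wound_detector_params")
}

#' Detect punctae in a movie channel
#'
#' Per frame: difference-of-Gaussians band-pass (sigma and 3x sigma),
#' threshold, connected components, area filter, intensity-weighted
#' centroids in um. Frames are processed independently (no temporal
#' coupling) and the result is deterministic for fixed input.
#'
#' @param movie a `wound_movie` (or any list with `data` in
#'   frame x channel x y x x order plus `pixel_size`, `frame_interval`,
#'   `wound_frame`).
#' @param channel channel index or name (e.g. `"exo"`).
#' @param params a [detector_params()].
#' @return A punctae tibble: `frame`, `time_s`, `label`, `x_um`, `y_um`,
#'   `area_um2`, and a `pixels` list-column of linear pixel indices (the
#'   puncta mask), with movie metadata attached as attributes.
#' @export
detect_punctae <- function(movie, channel = 2, params = detector_params()) {
  d <- dim(movie$data)
  if (is.null(d) || d[1] == 0) abort("Empty movie.")
  if (is.character(channel)) channel <- match(channel, movie$channels)
  if (is.na(channel) || channel < 1 || channel > d[2]) abort("No such channel.")
  px <- movie$pixel_size
  tt <- movie_times(movie)

  out <- purrr::map_dfr(seq_len(d[1]), function(f) {
    img <- frame_image(movie, f, channel)
    p <- detect_frame(img, px, params)
    if (nrow(p) > 0) {
      p$frame <- f
      p$time_s <- tt[f]
    }
    p
  })
  if (nrow(out) == 0) {
    out <- tibble(frame = integer(), time_s = numeric(), label = integer(),
                  x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
                  pixels = list())
  } else {
    out <- out[, c("frame", "time_s", "label", "x_um", "y_um", "area_um2",
                   "pixels")]
  }
  set_punctae_meta(as_tibble(out), list(
    n_frames = d[1], frame_interval = movie$frame_interval,
    wound_frame = movie$wound_frame, pixel_size = px
  ))
}

detect_frame <- function(img, px, params) {
  s1 <- max(params$band_pass_sigma / px, 0.5)
  dog <- EBImage::gblur(img, sigma = s1) - EBImage::gblur(img, sigma = 3 * s1)
  thr <- switch(params$threshold_kind,
    zscore = median(dog) + params$threshold * mad(dog),
    quantile = as.numeric(quantile(dog, params$threshold)),
    absolute = params$threshold
  )
  binary <- dog > thr
  label_and_measure(binary, weights = dog - thr, px = px,
                    min_area = params$min_area, max_area = params$max_area)
}

# Connected components + size filter + centroids (shared by both detection
# routes). `weights` NULL means binary (unweighted) centroids.
label_and_measure <- function(binary, weights = NULL, px, min_area, max_area) {
  empty <- tibble(label = integer(), x_um = numeric(), y_um = numeric(),
                  area_um2 = numeric(), pixels = list())
  if (!any(binary)) return(empty)
  lab <- EBImage::bwlabel(matrix(as.numeric(binary), nrow(binary), ncol(binary)))
  lab <- round(as.numeric(lab))
  idx <- which(lab > 0)
  comp <- lab[idx]
  n_obj <- max(comp)
  if (n_obj > 1e4) warn(sprintf("%d objects in one frame; threshold may be too low.", n_obj))
  npix <- tabulate(comp, nbins = n_obj)
  areas <- npix * px^2
  keep <- which(areas >= min_area & areas <= max_area)
  if (length(keep) == 0) return(empty)

  ny <- nrow(binary)
  rows <- ((idx - 1) %% ny) + 1
  cols <- ((idx - 1) %/% ny) + 1
  w <- if (is.null(weights)) rep(1, length(idx)) else pmax(weights[idx], 1e-12)
  sw <- rowsum(w, comp)[, 1]
  sx <- rowsum(w * (cols - 1), comp)[, 1]
  sy <- rowsum(w * (rows - 1), comp)[, 1]
  pix_by_comp <- split(idx, comp)

  tibble(
    label = seq_along(keep),
    x_um = unname((sx[keep] / sw[keep]) * px),
    y_um = unname((sy[keep] / sw[keep]) * px),
    area_um2 = areas[keep],
    pixels = unname(pix_by_comp[as.character(keep)])
  )
}

#' Punctae from externally supplied probability maps
#'
#' Ingests per-pixel probability maps (e.g. from a trained pixel
#' classifier), thresholds them and applies the same labeling and size
#' filter contract as [detect_punctae()]. Centroids are binary-mask
#' centroids.
#'
#' @param maps a `[y, x]` matrix, a `[y, x, frame]` array, or a list of
#'   matrices with values in `[0, 1]`.
#' @param threshold probability threshold in (0, 1); pixels strictly above
#'   it are foreground.
#' @param min_area,max_area puncta area bounds, um^2.
#' @param pixel_size um per pixel.
#' @param frame_interval,wound_frame optional timing metadata attached to
#'   the output.
#' @return A punctae tibble as in [detect_punctae()].
#' @export
binarize_probability_maps <- function(maps, threshold = 0.5,
                                      min_area = 0.02, max_area = 3,
                                      pixel_size = 1, frame_interval = 1,
                                      wound_frame = NULL) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  if (min_area >= max_area) abort("`min_area` must be < `max_area`.")
  frames <- if (is.list(maps)) maps
    else if (length(dim(maps)) == 3) purrr::map(seq_len(dim(maps)[3]), ~ maps[, , .x])
    else list(maps)
  rng <- range(unlist(purrr::map(frames, range)))
  if (rng[1] < 0 || rng[2] > 1) abort("Probability maps must have values in [0, 1].")

  out <- purrr::map_dfr(seq_along(frames), function(f) {
    p <- label_and_measure(frames[[f]] > threshold, weights = NULL,
                           px = pixel_size, min_area = min_area,
                           max_area = max_area)
    if (nrow(p) > 0) {
      p$frame <- f
      p$time_s <- if (is.null(wound_frame)) (f - 1) * frame_interval else
        (f - (wound_frame - 1)) * frame_interval
    }
    p
  })
  if (nrow(out) == 0) {
    out <- tibble(frame = integer(), time_s = numeric(), label = integer(),
                  x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
                  pixels = list())
  } else {
    out <- out[, c("frame", "time_s", "label", "x_um", "y_um", "area_um2",
                   "pixels")]
  }
  set_punctae_meta(as_tibble(out), list(
    n_frames = length(frames), frame_interval = frame_interval,
    wound_frame = wound_frame, pixel_size = pixel_size
  ))
}

#' Match detected punctae to ground truth
#'
#' One-to-one greedy nearest matching within a distance tolerance, per
#' frame: candidate pairs are visited in order of increasing distance (ties
#' broken by lowest truth then detected label) and accepted when both
#' members are still unmatched. Precision is the matched fraction of
#' detections, recall the matched fraction of ground-truth punctae, pooled
#' over frames.
#'
#' @param detected,truth punctae tibbles with `frame`, `x_um`, `y_um`.
#' @param tol matching tolerance, um.
#' @return A list: `precision`, `recall`, `n_matched`, `n_detected`,
#'   `n_truth`.
#' @export
match_punctae <- function(detected, truth, tol) {
  if (tol <= 0) abort("`tol` must be > 0.")
  frames <- union(unique(detected$frame), unique(truth$frame))
  n_match <- 0L
  for (f in frames) {
    dd <- detected[detected$frame == f, , drop = FALSE]
    gg <- truth[truth$frame == f, , drop = FALSE]
    if (nrow(dd) == 0 || nrow(gg) == 0) next
    dm <- outer(gg$x_um, dd$x_um, "-")^2 + outer(gg$y_um, dd$y_um, "-")^2
    cand <- which(dm <= tol^2, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    ord <- order(dm[cand], cand[, 1], cand[, 2])
    used_g <- logical(nrow(gg)); used_d <- logical(nrow(dd))
    for (k in ord) {
      gi <- cand[k, 1]; di <- cand[k, 2]
      if (!used_g[gi] && !used_d[di]) {
        used_g[gi] <- TRUE; used_d[di] <- TRUE
        n_match <- n_match + 1L
      }
    }
  }
  nd <- nrow(detected); ng <- nrow(truth)
  list(precision = if (nd > 0) n_match / nd else NA_real_,
       recall = if (ng > 0) n_match / ng else NA_real_,
       n_matched = n_match, n_detected = nd, n_truth = ng)
}
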