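#' Wound-dye influx curve
#'
#' Computes the resealing read-out from the wound-dye channel: per frame,
#' the mean channel-1 intensity over the wounded cell minus the mean over a
#' nearby unwounded cell (background/bleaching correction), normalized to
#' the corrected intensity at the reference frame (the last pre-wound
#' frame). A plateau of the curve indicates successful resealing; an
#' unbounded (linear) increase indicates failed repair.
#'
#' @param movie a `wound_movie`.
#' @param wounded_mask,unwounded_mask logical `[y, x]` masks; default to the
#'   movie's `cell_mask` and `neighbor_mask`. Must be disjoint and
#'   non-empty.
#' @param channel dye channel (default 1).
#' @return A `wound_resealing_curve` tibble: `frame`, `time_s`,
#'   `intensity` (background-corrected), `normalized_intensity`; attributes
#'   `reference_frame`, `wound_frame`, `frame_interval`.
#' @export
influx_curve <- function(movie, wounded_mask = NULL, unwounded_mask = NULL,
                         channel = 1) {
  if (is.null(wounded_mask)) wounded_mask <- movie$cell_mask
  if (is.null(unwounded_mask)) unwounded_mask <- movie$neighbor_mask
  if (is.null(wounded_mask) || !any(wounded_mask)) abort("`wounded_mask` is empty.")
  if (is.null(unwounded_mask) || !any(unwounded_mask)) abort("`unwounded_mask` is empty.")
  if (any(wounded_mask & unwounded_mask)) abort("Masks must be disjoint.")

  d <- dim(movie$data)
  tt <- movie_times(movie)
  iw <- which(wounded_mask); iu <- which(unwounded_mask)
  intensity <- vapply(seq_len(d[1]), function(f) {
    img <- frame_image(movie, f, channel)
    mean(img[iw]) - mean(img[iu])
  }, numeric(1))

  ref_frame <- movie$wound_frame - 1L
  ref <- intensity[ref_frame]
  if (!is.finite(ref) || ref <= 0) {
    abort("Background-corrected reference intensity is not positive; cannot normalize.")
  }
  structure(
    tibble(frame = seq_len(d[1]), time_s = tt, intensity = intensity,
           normalized_intensity = intensity / ref),
    class = c("wound_resealing_curve", class(tibble())),
    reference_frame = ref_frame,
    wound_frame = movie$wound_frame,
    frame_interval = movie$frame_interval,
    roi = "whole_cell"
  )
}

#' Classify a resealing curve as resealed, failed, or indeterminate
#'
#' Codifies the plateau-versus-linear criterion as a slope-ratio rule:
#' least-squares slopes are fitted on an early and a late post-wound
#' window; the curve is called `"resealed"` when the late/early slope
#' ratio falls below `slope_ratio_threshold` (influx has stopped),
#' `"failed"` when the ratio stays at or above it with a positive late
#' slope (influx continues), and `"indeterminate"` when the early slope is
#' not credibly positive (no influx signal: slope <= 0 or below twice its
#' standard error).
#'
#' @param curve a [influx_curve()] result (or any tibble with `time_s` and
#'   `normalized_intensity`).
#' @param early_window,late_window `(t0, t1)` in seconds post-wound;
#'   defaults are the first and last thirds of the post-wound record.
#' @param slope_ratio_threshold resealed/failed decision boundary on the
#'   late/early slope ratio.
#' @return A `wound_reseal_call`: list with `classification`,
#'   `early_slope`, `late_slope`, `slope_ratio`, and the windows used.
#'   Supports [tidy()] and [glance()].
#' @export
classify_resealing <- function(curve, early_window = NULL, late_window = NULL,
                               slope_ratio_threshold = 0.2) {
  post <- curve[curve$time_s > 0, , drop = FALSE]
  if (nrow(post) < 6) abort("Too few post-wound samples to classify.")
  tmax <- max(post$time_s)
  if (is.null(early_window)) early_window <- c(0, tmax / 3)
  if (is.null(late_window)) late_window <- c(2 * tmax / 3, tmax)

  slope_in <- function(win) {
    seg <- post[post$time_s > win[1] & post$time_s <= win[2], , drop = FALSE]
    if (nrow(seg) < 3) abort("Classification windows must contain at least 3 samples.")
    fit <- lm(normalized_intensity ~ time_s, data = seg)
    # an exact fit has zero residual variance; its SE of 0 is meaningful here
    s <- suppressWarnings(summary(fit))$coefficients
    c(slope = unname(coef(fit)[2]),
      se = if (nrow(s) >= 2) s[2, 2] else NA_real_)
  }
  early <- slope_in(early_window)
  late <- slope_in(late_window)

  ratio <- unname(late["slope"] / early["slope"])
  cls <- if (!is.finite(early["slope"]) || early["slope"] <= 0 ||
             (is.finite(early["se"]) && early["slope"] < 2 * early["se"])) {
    "indeterminate"
  } else if (ratio < slope_ratio_threshold) {
    "resealed"
  } else if (late["slope"] > 0) {
    "failed"
  } else {
    "resealed"
  }
  structure(
    list(classification = cls,
         early_slope = unname(early["slope"]), late_slope = unname(late["slope"]),
         slope_ratio = if (is.finite(ratio)) ratio else NA_real_,
         early_window = early_window, late_window = late_window,
         slope_ratio_threshold = slope_ratio_threshold),
    class = "wound_reseal_call"
  )
}

#' @export
print.wound_reseal_call <- function(x, ...) {
  cat(sprintf("<wound_reseal_call> %s (early slope %.4g, late slope %.4g, ratio %.3g, threshold %.2g)\n",
              x$classification, x$early_slope, x$late_slope, x$slope_ratio,
              x$slope_ratio_threshold))
  invisible(x)
}

#' Dye intensity in a wound-centered circular ROI
#'
#' The hydrogel-experiment metric: mean dye intensity inside a circle of
#' the given diameter centered on the wound, per frame, normalized to the
#' whole-cell mean intensity at the reference (last pre-wound) frame.
#'
#' @param movie a `wound_movie`.
#' @param diameter ROI diameter, um (default 20).
#' @param channel dye channel.
#' @return A `wound_resealing_curve` tibble (attribute `roi =
#'   "around_wound"`); if the ROI does not intersect the cell mask the
#'   attribute `outside_cell` is `TRUE` and the curve reports background
#'   only.
#' @export
around_wound_intensity <- function(movie, diameter = 20, channel = 1) {
  d <- dim(movie$data)
  px <- movie$pixel_size
  xs <- (seq_len(d[4]) - 1) * px
  ys <- (seq_len(d[3]) - 1) * px
  X <- matrix(xs, d[3], d[4], byrow = TRUE)
  Y <- matrix(ys, d[3], d[4])
  r <- diameter / 2
  ctr <- movie$wound_center
  if (ctr[1] - r < min(xs) - px / 2 || ctr[1] + r > max(xs) + px / 2 ||
      ctr[2] - r < min(ys) - px / 2 || ctr[2] + r > max(ys) + px / 2) {
    abort("Wound-centered ROI extends beyond the image.")
  }
  disk <- (X - ctr[1])^2 + (Y - ctr[2])^2 <= r^2
  cell <- if (!is.null(movie$cell_mask)) movie$cell_mask else
    matrix(TRUE, d[3], d[4])
  outside_cell <- !any(disk & cell)
  if (outside_cell) {
    warn("Wound-centered ROI does not intersect the cell mask; curve reports background only.")
  }

  tt <- movie_times(movie)
  ref_frame <- movie$wound_frame - 1L
  ref <- mean(frame_image(movie, ref_frame, channel)[cell])
  if (!is.finite(ref) || ref <= 0) abort("Whole-cell reference intensity is not positive.")
  vals <- vapply(seq_len(d[1]), function(f) {
    mean(frame_image(movie, f, channel)[disk])
  }, numeric(1))
  structure(
    tibble(frame = seq_len(d[1]), time_s = tt, intensity = vals,
           normalized_intensity = vals / ref),
    class = c("wound_resealing_curve", class(tibble())),
    reference_frame = ref_frame,
    wound_frame = movie$wound_frame,
    frame_interval = movie$frame_interval,
    roi = "around_wound",
    outside_cell = outside_cell
  )
}

#' Wound delineation area as a fraction of the cell area
#'
#' @param delineation_mask,cell_mask logical masks; the delineation must be
#'   contained in the cell.
#' @return Fraction in `[0, 1]`.
#' @export
delineation_area_fraction <- function(delineation_mask, cell_mask) {
  if (!any(cell_mask)) abort("`cell_mask` is empty.")
  if (any(delineation_mask & !cell_mask)) {
    abort("`delineation_mask` must be contained in `cell_mask`.")
  }
  sum(delineation_mask) / sum(cell_mask)
}

#' Scrape-assay repair percentage
#'
#' Population repair efficiency from flow-count tables: the percentage of
#' repaired (dye-positive, PI-negative) cells among all scrape-wounded
#' (dye-positive) cells, `100 * (n_wounded - n_failed) / n_wounded`.
#'
#' @param n_wounded count of wounded (AF488-positive) cells (> 0).
#' @param n_failed count of non-resealed (PI-positive among AF488-positive)
#'   cells; `0 <= n_failed <= n_wounded`.
#' @return Repair percentage(s) in `[0, 100]` (vectorized).
#' @export
#' @examples
#' scrape_repair_percentage(1000, 250) # 75
scrape_repair_percentage <- function(n_wounded, n_failed) {
  if (any(n_wounded <= 0)) abort("`n_wounded` must be > 0.")
  if (any(n_failed < 0) || any(n_failed > n_wounded)) {
    abort("`n_failed` must be between 0 and `n_wounded`.")
  }
  100 * (n_wounded - n_failed) / n_wounded
}
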