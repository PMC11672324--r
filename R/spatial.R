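#' Object-based colocalization of two punctae sets
#'
#' Returns the subset of `a` colocalized with `b` on the same frame, under
#' one of two rules: `"mask_overlap"` (a puncta of `a` is colocalized iff
#' its pixel mask shares at least one pixel with any mask of `b`) or
#' `"centroid_distance"` (nearest `b` centroid within `tol` um). Each
#' `a`-puncta is counted at most once.
#'
#' @param a,b punctae tibbles for a single common frame.
#' @param rule `"mask_overlap"` or `"centroid_distance"`.
#' @param tol centroid-distance tolerance, um (required for the centroid
#'   rule).
#' @return The colocalized rows of `a`.
#' @export
colocalize <- function(a, b, rule = c("mask_overlap", "centroid_distance"),
                       tol = NULL) {
  rule <- match.arg(rule)
  fa <- unique(a$frame); fb <- unique(b$frame)
  if (length(fa) > 1 || length(fb) > 1 ||
      (length(fa) == 1 && length(fb) == 1 && fa != fb)) {
    abort("`a` and `b` must come from the same single frame.")
  }
  if (nrow(a) == 0 || nrow(b) == 0) return(a[0, , drop = FALSE])
  hit <- switch(rule,
    mask_overlap = {
      if (is.null(a$pixels) || is.null(b$pixels)) {
        abort("The mask_overlap rule needs the `pixels` list-column.")
      }
      bp <- unique(unlist(b$pixels))
      vapply(a$pixels, function(p) any(p %in% bp), logical(1))
    },
    centroid_distance = {
      if (is.null(tol) || tol <= 0) abort("`tol` must be > 0 for the centroid rule.")
      dm <- outer(a$x_um, b$x_um, "-")^2 + outer(a$y_um, b$y_um, "-")^2
      apply(dm, 1, min) <= tol^2
    }
  )
  a[hit, , drop = FALSE]
}

#' Normalized colocalization matrix over rings and time
#'
#' Applies [colocalize()] frame by frame and quantifies the colocalized
#' punctae of `a` with the same ring/baseline/area normalization contract
#' as [count_matrix()] (baseline = colocalized count at the last pre-wound
#' frame, zero baselines clamped to 1, values divided by ring area).
#'
#' @param a,b punctae tibbles over frames (series A is quantified).
#' @param rings a [build_rings()] partition.
#' @param wound_frame first post-wound frame index; defaults from `a`'s
#'   metadata.
#' @param rule,tol passed to [colocalize()].
#' @param ... passed to [count_matrix()].
#' @return A `wound_count_matrix` of colocalized-event densities.
#' @export
coloc_matrix <- function(a, b, rings, wound_frame = NULL,
                         rule = c("mask_overlap", "centroid_distance"),
                         tol = NULL, ...) {
  rule <- match.arg(rule)
  frames <- sort(unique(a$frame))
  kept <- purrr::map_dfr(frames, function(f) {
    colocalize(a[a$frame == f, , drop = FALSE],
               b[b$frame == f, , drop = FALSE], rule = rule, tol = tol)
  })
  kept <- set_punctae_meta(kept, punctae_meta(a))
  count_matrix(kept, rings, wound_frame = wound_frame, ...)
}

#' Compile reference exocytic event positions
#'
#' Pools the centroids of exocytic punctae detected within the stated
#' ring(s) during a post-wound time window — the reference set against
#' which later endocytic punctae are mapped (the wound-evoked exocytic
#' burst of the first ~10 s in circle 1, by default).
#'
#' @param exo punctae tibble of the exocytic marker.
#' @param rings a [build_rings()] partition.
#' @param window `(t0, t1]` in seconds post-wound.
#' @param ring_set ring indices to pool (e.g. `1`, `c(1, 2)`, or `6` for
#'   the far-field control).
#' @return A tibble `frame`, `time_s`, `x_um`, `y_um` of reference
#'   positions; errors if the reference set is empty.
#' @export
reference_events <- function(exo, rings, window = c(0, 10), ring_set = 1) {
  lab <- assign_ring(exo$x_um, exo$y_um, rings)
  keep <- exo$time_s > window[1] & exo$time_s <= window[2] &
    lab %in% paste0("ring", ring_set)
  out <- exo[keep, intersect(c("frame", "time_s", "x_um", "y_um"), names(exo)),
             drop = FALSE]
  if (nrow(out) == 0) {
    abort("Empty reference set: no exocytic punctae in the requested rings and window.")
  }
  as_tibble(out)
}

#' Nearest-neighbor distance series from endocytic punctae to reference sites
#'
#' For every frame, computes the Euclidean distance from each endocytic
#' puncta to its nearest reference position and averages them; the per-frame
#' means are then normalized to the mean at `normalization_frame`. Frames
#' without endocytic punctae propagate as missing values — never as zero,
#' which would fake perfect association. A post-resealing dip of the
#' normalized series below its pre-resealing level indicates endocytosis at
#' or near prior exocytic sites.
#'
#' @param endo punctae tibble of the endocytic marker.
#' @param reference reference positions from [reference_events()] (or any
#'   table with `x_um`, `y_um`).
#' @param normalization_frame frame whose mean distance defines 1; default
#'   is the earliest post-wound frame with at least one endocytic puncta.
#' @param agg per-frame aggregate, `"mean"` (default) or `"median"`.
#' @param region_label optional label stored on the result (e.g.
#'   `"circle1"`).
#' @return A `wound_nn_series` tibble: `frame`, `time_s`, `n`,
#'   `mean_distance_um`, `normalized_distance`.
#' @export
nn_series <- function(endo, reference, normalization_frame = NULL,
                      agg = c("mean", "median"), region_label = NULL) {
  agg <- match.arg(agg)
  if (nrow(reference) == 0) abort("Empty reference set.")
  meta <- punctae_meta(endo)
  frames <- if (!is.null(meta$n_frames)) seq_len(meta$n_frames) else
    sort(unique(endo$frame))
  dt <- if (!is.null(meta$frame_interval)) meta$frame_interval else 1
  wf <- meta$wound_frame

  per_frame <- purrr::map_dfr(frames, function(f) {
    e <- endo[endo$frame == f, , drop = FALSE]
    if (nrow(e) == 0) {
      return(tibble(frame = f, n = 0L, mean_distance_um = NA_real_))
    }
    d <- nn_distances(e$x_um, e$y_um, reference$x_um, reference$y_um)
    tibble(frame = f, n = nrow(e),
           mean_distance_um = if (agg == "mean") mean(d) else median(d))
  })
  per_frame$time_s <- (per_frame$frame - (if (!is.null(wf)) wf - 1L else 0L)) * dt

  if (is.null(normalization_frame)) {
    cand <- per_frame$frame[per_frame$time_s > 0 & per_frame$n > 0]
    if (length(cand) == 0) abort("No post-wound frame with endocytic punctae to normalize by.")
    normalization_frame <- cand[1]
  }
  norm <- per_frame$mean_distance_um[per_frame$frame == normalization_frame]
  if (length(norm) != 1 || !is.finite(norm) || norm == 0) {
    abort("Normalization-frame mean distance is missing or zero; cannot normalize.")
  }
  per_frame$normalized_distance <- per_frame$mean_distance_um / norm
  structure(
    per_frame[, c("frame", "time_s", "n", "mean_distance_um",
                  "normalized_distance")],
    class = c("wound_nn_series", class(tibble())),
    normalization_frame = normalization_frame,
    region_label = region_label %||% "reference",
    agg = agg
  )
}

#' Far-field control nearest-neighbor series
#'
#' Convenience wrapper: compiles the reference set from a ring far from the
#' wound (circle 6 by default) over the same window and computes the
#' [nn_series()]. Under association confined to the wound zone this control
#' series shows no systematic post-resealing decrease.
#'
#' @inheritParams nn_series
#' @param exo punctae tibble of the exocytic marker.
#' @param rings a [build_rings()] partition.
#' @param window reference time window, s post-wound.
#' @param control_ring ring index of the far-field reference.
#' @return A `wound_nn_series`.
#' @export
nn_control <- function(endo, exo, rings, window = c(0, 10), control_ring = 6,
                       normalization_frame = NULL, agg = "mean") {
  ref <- reference_events(exo, rings, window = window, ring_set = control_ring)
  nn_series(endo, ref, normalization_frame = normalization_frame, agg = agg,
            region_label = paste0("circle", paste(control_ring, collapse = "-")))
}

# Vectorized nearest-neighbor distances from query points to reference
# points. Ties in neighbor identity resolve to the lowest reference index
# (irrelevant for the distance value).
nn_distances <- function(qx, qy, rx, ry) {
  dm <- outer(qx, rx, "-")^2 + outer(qy, ry, "-")^2
  sqrt(apply(dm, 1, min))
}

#' Distribution of punctae distances to the wound
#'
#' Per-puncta Euclidean distance to the wound center, normalized by the
#' cell's maximum extent from the wound, as samples for density rendering.
#'
#' @param punctae punctae tibble.
#' @param wound_center `(x, y)` um.
#' @param max_extent normalizing extent, um; default is the largest observed
#'   distance.
#' @return A tibble `distance_um`, `normalized_distance` (empty input gives
#'   an empty tibble).
#' @export
wound_distance_density <- function(punctae, wound_center, max_extent = NULL) {
  if (nrow(punctae) == 0) {
    return(tibble(distance_um = numeric(), normalized_distance = numeric()))
  }
  d <- sqrt((punctae$x_um - wound_center[1])^2 +
            (punctae$y_um - wound_center[2])^2)
  if (is.null(max_extent)) max_extent <- max(d)
  tibble(distance_um = d,
         normalized_distance = if (max_extent > 0) d / max_extent else d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
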