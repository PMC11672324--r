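#' Concentric quantification rings around the wound site
#'
#' Builds the ring partition used to quantify event counts at increasing
#' distances from the wound: the circular wound ROI of area `wound_area` is
#' surrounded by `n_rings` annuli whose outer diameters grow by
#' `diameter_increment` per ring, i.e. outer radius of ring k is
#' `wound_radius + k * diameter_increment / 2`. Ring 1 is closest to the
#' wound, ring `n_rings` the farthest.
#'
#' @param wound_center `(x, y)` in um.
#' @param wound_area wound ROI area in um^2 (default the 2.5 um^2 ablation ROI).
#' @param n_rings number of annuli.
#' @param diameter_increment growth of the outer diameter per ring, um.
#' @return A `wound_rings` object: a tibble with one row per ring (`ring`,
#'   `r_inner`, `r_outer`, `area_um2`) and attributes `wound_center`,
#'   `wound_radius`.
#' @export
#' @examples
#' rg <- build_rings(c(25, 25))
#' rg$r_outer[1] # 0.892 + 10 um
build_rings <- function(wound_center, wound_area = 2.5, n_rings = 6L,
                        diameter_increment = 20) {
  if (wound_area <= 0) abort("`wound_area` must be > 0.")
  if (n_rings < 1) abort("`n_rings` must be >= 1.")
  if (diameter_increment <= 0) abort("`diameter_increment` must be > 0.")
  r0 <- sqrt(wound_area / pi)
  outer <- r0 + seq_len(n_rings) * diameter_increment / 2
  inner <- c(r0, outer[-n_rings])
  out <- tibble(
    ring = seq_len(n_rings),
    r_inner = inner,
    r_outer = outer,
    area_um2 = pi * (outer^2 - inner^2)
  )
  structure(out, class = c("wound_rings", class(out)),
            wound_center = as.numeric(wound_center), wound_radius = r0)
}

#' Assign points to wound, ring, or outside
#'
#' Annuli are half-open: a point exactly on a boundary belongs to the inner
#' region, so the wound disk is `d <= wound_radius` and ring k is
#' `r_outer[k-1] < d <= r_outer[k]`.
#'
#' @param x,y point coordinates in um (vectorized).
#' @param rings a [build_rings()] partition.
#' @return A factor with levels `"wound"`, `"ring1"` ... `"ringN"`,
#'   `"outside"`.
#' @export
assign_ring <- function(x, y, rings) {
  ctr <- attr(rings, "wound_center")
  r0 <- attr(rings, "wound_radius")
  d <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  brks <- c(-Inf, r0, rings$r_outer, Inf)
  labs <- c("wound", paste0("ring", rings$ring), "outside")
  cut(d, breaks = brks, labels = labs, right = TRUE)
}

#' Normalized ring-by-time event count matrix
#'
#' Counts punctae per ring per frame and applies the heatmap normalization:
#' each ring's counts are divided by the punctae count of that ring at the
#' baseline frame (the last pre-wound frame) and by the ring area in um^2.
#' A baseline count of zero is clamped to 1 so that normalization is defined
#' for every cell (this can underestimate the relative event increase).
#'
#' @param punctae punctae tibble with `frame`, `x_um`, `y_um` columns
#'   ([detect_punctae()] or [ground_truth_punctae()] output).
#' @param rings a [build_rings()] partition.
#' @param wound_frame index (1-based) of the first post-wound frame; defaults
#'   to the value carried by `punctae`.
#' @param frames full frame index vector (frames without punctae count as 0);
#'   defaults to `1:n_frames` from the punctae metadata.
#' @param frame_interval seconds per frame, for the time axis.
#' @param normalization `"baseline_and_area"` (default), `"area_only"`, or
#'   `"raw"`.
#' @param cumulative if `TRUE`, rings are treated as nested disks (ring k
#'   covers all annuli 1..k) rather than disjoint annuli.
#' @param include_wound count punctae inside the wound disk as part of ring 1
#'   (default `FALSE`: the ablated zone is excluded).
#' @return A `wound_count_matrix`: tibble with `ring`, `frame`, `time_s`,
#'   `count`, `baseline`, `area_um2`, `value`, plus attributes
#'   (`normalization`, `reference_frame`, `rings`).
#' @export
count_matrix <- function(punctae, rings, wound_frame = NULL, frames = NULL,
                         frame_interval = NULL,
                         normalization = c("baseline_and_area", "area_only", "raw"),
                         cumulative = FALSE, include_wound = FALSE) {
  normalization <- match.arg(normalization)
  meta <- punctae_meta(punctae)
  if (is.null(wound_frame)) wound_frame <- meta$wound_frame
  if (is.null(frames)) {
    frames <- if (!is.null(meta$n_frames)) seq_len(meta$n_frames) else
      seq_len(max(punctae$frame, 1L))
  }
  if (is.null(frame_interval)) {
    frame_interval <- if (!is.null(meta$frame_interval)) meta$frame_interval else 1
  }
  if (normalization == "baseline_and_area") {
    if (is.null(wound_frame) || wound_frame < 2 || !((wound_frame - 1) %in% frames)) {
      abort("Baseline normalization needs at least one pre-wound frame.")
    }
  }

  counts <- ring_frame_counts(punctae, rings, frames,
                              cumulative = cumulative,
                              include_wound = include_wound)
  areas <- ring_areas(rings, cumulative = cumulative,
                      include_wound = include_wound)
  counts$area_um2 <- areas[counts$ring]

  reference_frame <- if (!is.null(wound_frame)) wound_frame - 1L else NA_integer_
  if (!is.na(reference_frame) && reference_frame %in% frames) {
    base <- counts$count[counts$frame == reference_frame]
    counts$baseline <- base[counts$ring]
  } else {
    counts$baseline <- NA_real_
  }

  counts$value <- switch(normalization,
    raw = counts$count,
    area_only = counts$count / counts$area_um2,
    baseline_and_area = counts$count / pmax(counts$baseline, 1) / counts$area_um2
  )
  tz <- if (!is.null(wound_frame)) wound_frame - 1L else 0L
  counts$time_s <- (counts$frame - tz) * frame_interval
  out <- counts[, c("ring", "frame", "time_s", "count", "baseline",
                    "area_um2", "value")]
  structure(as_tibble(out),
            class = c("wound_count_matrix", class(as_tibble(out))),
            normalization = normalization,
            reference_frame = reference_frame,
            cumulative = cumulative,
            rings = rings)
}

#' Area-normalized steady-state count matrix
#'
#' The un-baselined variant used for non-wounded controls: punctae counts
#' per ring per frame, normalized to ring area only. Equal to the
#' [count_matrix()] values multiplied back by `max(baseline, 1)`.
#'
#' @inheritParams count_matrix
#' @return A `wound_count_matrix` with `normalization = "area_only"`.
#' @export
steady_state_matrix <- function(punctae, rings, frames = NULL,
                                frame_interval = NULL, cumulative = FALSE,
                                include_wound = FALSE) {
  count_matrix(punctae, rings, wound_frame = NULL, frames = frames,
               frame_interval = frame_interval, normalization = "area_only",
               cumulative = cumulative, include_wound = include_wound)
}

#' @export
as.matrix.wound_count_matrix <- function(x, value = "value", ...) {
  frames <- sort(unique(x$frame))
  rings <- sort(unique(x$ring))
  m <- matrix(NA_real_, length(rings), length(frames),
              dimnames = list(paste0("ring", rings), frames))
  m[cbind(match(x$ring, rings), match(x$frame, frames))] <- x[[value]]
  m
}

# shared counting core ------------------------------------------------------

ring_frame_counts <- function(punctae, rings, frames, cumulative = FALSE,
                              include_wound = FALSE) {
  n <- nrow(rings)
  grid <- tidyr::expand_grid(ring = seq_len(n), frame = frames)
  if (nrow(punctae) == 0) {
    grid$count <- 0
    return(grid)
  }
  lab <- assign_ring(punctae$x_um, punctae$y_um, rings)
  ring_idx <- as.integer(lab) - 1L            # wound -> 0, ring k -> k, outside -> n+1
  if (include_wound) ring_idx[ring_idx == 0L] <- 1L
  keep <- ring_idx >= 1L & ring_idx <= n
  tab <- table(factor(ring_idx[keep], levels = seq_len(n)),
               factor(punctae$frame[keep], levels = frames))
  cnt <- as.matrix(tab)
  if (cumulative) cnt <- apply(cnt, 2, cumsum)
  grid$count <- as.vector(cnt[cbind(grid$ring, match(grid$frame, frames))])
  grid
}

ring_areas <- function(rings, cumulative = FALSE, include_wound = FALSE) {
  r0 <- attr(rings, "wound_radius")
  inner0 <- if (include_wound) 0 else r0
  if (cumulative) {
    pi * (rings$r_outer^2 - inner0^2)
  } else {
    a <- rings$area_um2
    if (include_wound) a[1] <- a[1] + pi * r0^2
    a
  }
}
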