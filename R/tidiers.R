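#' Tidy and glance methods for woundsight result objects
#'
#' Broom-style accessors: `tidy()` returns the per-observation table of a
#' result, `glance()` a one-row summary.
#'
#' @param x a woundsight result object.
#' @param ... unused.
#' @return A tibble.
#' @name woundsight-tidiers
NULL

#' @rdname woundsight-tidiers
#' @export
tidy.wound_count_matrix <- function(x, ...) {
  as_tibble(x)
}

#' @rdname woundsight-tidiers
#' @export
glance.wound_count_matrix <- function(x, ...) {
  tibble(
    n_rings = length(unique(x$ring)),
    n_frames = length(unique(x$frame)),
    normalization = attr(x, "normalization"),
    reference_frame = attr(x, "reference_frame") %||% NA_integer_,
    total_count = sum(x$count),
    peak_value = max(x$value)
  )
}

#' @rdname woundsight-tidiers
#' @export
tidy.wound_reseal_call <- function(x, ...) {
  tibble(
    term = c("early_slope", "late_slope", "slope_ratio"),
    estimate = c(x$early_slope, x$late_slope, x$slope_ratio)
  )
}

#' @rdname woundsight-tidiers
#' @export
glance.wound_reseal_call <- function(x, ...) {
  tibble(
    classification = x$classification,
    early_slope = x$early_slope,
    late_slope = x$late_slope,
    slope_ratio = x$slope_ratio,
    slope_ratio_threshold = x$slope_ratio_threshold
  )
}

#' @rdname woundsight-tidiers
#' @export
tidy.wound_tether_fit <- function(x, ...) {
  tibble(
    term = c("peak_pN", "plateau_pN", "baseline_pN", "noise_sd_pN"),
    estimate = c(x$peak_pN, x$plateau_pN, x$baseline_pN, x$noise_sd_pN)
  )
}

#' @rdname woundsight-tidiers
#' @export
glance.wound_tether_fit <- function(x, ...) {
  tibble(
    peak_pN = x$peak_pN, plateau_pN = x$plateau_pN,
    n_plateau = x$n_plateau, plateau_start = x$plateau_start,
    baseline_pN = x$baseline_pN, noise_sd_pN = x$noise_sd_pN
  )
}

#' @rdname woundsight-tidiers
#' @export
tidy.wound_nn_series <- function(x, ...) {
  out <- as_tibble(x)
  out$region <- attr(x, "region_label")
  out
}

#' @rdname woundsight-tidiers
#' @export
glance.wound_nn_series <- function(x, ...) {
  post <- x$normalized_distance[x$time_s > 0]
  tibble(
    region = attr(x, "region_label"),
    normalization_frame = attr(x, "normalization_frame"),
    n_frames = nrow(x),
    mean_post_wound = mean(post, na.rm = TRUE),
    min_normalized = suppressWarnings(min(x$normalized_distance, na.rm = TRUE))
  )
}
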