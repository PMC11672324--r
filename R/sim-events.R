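#' Simulate the ground-truth event process of a wounded cell
#'
#' Draws the spatio-temporal Poisson event process described in
#' [event_params()] without rendering any pixels. The returned table is the
#' generator's ground truth: every puncta that will appear in the movie, its
#' marker channel, birth time, lifetime, position, and (for coupled
#' endocytic events) the identity of the parent exocytic event.
#'
#' Punctae already alive when acquisition starts (the stationary standing
#' population) are included with `t_birth` before the first frame time, so
#' pre-wound frames carry baseline punctae. Event counts of births inside
#' the recorded window are exactly Poisson with mean `rate * area * duration`.
#'
#' @param cfg a [sim_config()].
#' @param proc an [event_params()].
#' @param seed integer seed; defaults to `cfg$rng_seed`.
#'
#' @return A tibble with columns `id`, `marker` (`"exo"`/`"endo"` channel),
#'   `type` (`"steady"`, `"exo"`, `"endo"`), `t_birth` (s, wound at 0),
#'   `lifetime` (s), `x`, `y` (um), `parent_id` (id of the coupled exocytic
#'   event or `NA`).
#' @export
#' @examples
#' ev <- simulate_events(sim_config(image_shape = c(64, 64), pixel_size = 0.4,
#'                                  n_frames = 10), event_params())
#' table(ev$type)
simulate_events <- function(cfg, proc, seed = cfg$rng_seed) {
  stopifnot(inherits(cfg, "wound_sim_config"), inherits(proc, "wound_event_params"))
  area <- pi * prod(cfg$cell_axes)
  max_boost <- max(proc$exo_boost_by_ring, proc$endo_boost, 1)
  if (proc$steady_rate * area * proc$lifetime_mean * max_boost >
      prod(cfg$image_shape)) {
    abort("Event density too high: expected live spots exceed the pixel count.")
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  tt <- frame_times(cfg)
  t_first <- tt[1]
  t_last <- tt[length(tt)]
  duration <- t_last - t_first

  draw_steady <- function(marker) {
    # standing population at t_first (stationary M/M/inf), then fresh births
    n0 <- rpois(1, proc$steady_rate * area * proc$lifetime_mean)
    age <- rexp(n0, 1 / proc$lifetime_mean)
    p0 <- sample_in_ellipse(n0, cfg$cell_center, cfg$cell_axes)
    standing <- tibble(
      marker = marker, type = "steady",
      t_birth = t_first - age,
      lifetime = age + rexp(n0, 1 / proc$lifetime_mean),
      x = p0[, 1], y = p0[, 2]
    )
    n1 <- rpois(1, proc$steady_rate * area * duration)
    p1 <- sample_in_ellipse(n1, cfg$cell_center, cfg$cell_axes)
    births <- tibble(
      marker = marker, type = "steady",
      t_birth = runif(n1, t_first, t_last),
      lifetime = rexp(n1, 1 / proc$lifetime_mean),
      x = p1[, 1], y = p1[, 2]
    )
    bind_rows(standing, births)
  }

  steady <- bind_rows(draw_steady("exo"), draw_steady("endo"))

  # Wound-evoked exocytic burst: Poisson thinning of a homogeneous candidate
  # process at the maximum extra rate; acceptance by the per-ring factor.
  rings <- build_rings(cfg$wound_center, cfg$wound_area,
                       n_rings = length(proc$exo_boost_by_ring),
                       diameter_increment = proc$ring_increment)
  exo <- tibble(marker = character(), type = character(), t_birth = numeric(),
                lifetime = numeric(), x = numeric(), y = numeric(),
                exo_row = integer())
  bmax <- max(proc$exo_boost_by_ring)
  w <- proc$exo_window
  w[2] <- min(w[2], t_last)
  if (bmax > 1 && diff(w) > 0) {
    nc <- rpois(1, proc$steady_rate * (bmax - 1) * area * diff(w))
    pc <- sample_in_ellipse(nc, cfg$cell_center, cfg$cell_axes)
    ring <- assign_ring(pc[, 1], pc[, 2], rings)
    # the ablated disk itself is treated with the innermost factor: the
    # burst is concentrated at/near the wound edge
    idx <- as.integer(ring)            # wound = 1, ring k = k + 1, outside = n + 2
    boost <- c(proc$exo_boost_by_ring[1], proc$exo_boost_by_ring, 1)[idx]
    keep <- runif(nc) < (boost - 1) / (bmax - 1)
    nk <- sum(keep)
    if (nk > 0) {
      exo <- tibble(
        marker = "exo", type = "exo",
        t_birth = runif(nk, w[1], w[2]),
        lifetime = rexp(nk, 1 / proc$lifetime_mean),
        x = pc[keep, 1], y = pc[keep, 2],
        exo_row = seq_len(nk)
      )
    }
  }

  # Post-resealing endocytic burst, spatially coupled to prior exocytic sites.
  endo <- tibble(marker = character(), type = character(), t_birth = numeric(),
                 lifetime = numeric(), x = numeric(), y = numeric(),
                 parent_row = integer())
  ew <- c(cfg$reseal_time, t_last)
  if (proc$endo_boost > 1 && diff(ew) > 0) {
    ne <- rpois(1, proc$steady_rate * (proc$endo_boost - 1) * area * diff(ew))
    if (ne > 0) {
      tb <- sort(runif(ne, ew[1], ew[2]))
      coupled <- runif(ne) < proc$assoc_prob
      pos <- sample_in_ellipse(ne, cfg$cell_center, cfg$cell_axes)
      parent_row <- rep(NA_integer_, ne)
      n_exo <- nrow(exo)
      for (i in which(coupled)) {
        cand <- which(exo$t_birth <= tb[i])
        if (length(cand) == 0) next
        pick <- cand[sample.int(length(cand), 1)]
        parent_row[i] <- pick
        pos[i, ] <- c(exo$x[pick], exo$y[pick]) + rnorm(2, 0, proc$assoc_sd)
      }
      endo <- tibble(
        marker = "endo", type = "endo",
        t_birth = tb, lifetime = rexp(ne, 1 / proc$lifetime_mean),
        x = pos[, 1], y = pos[, 2], parent_row = parent_row
      )
    }
  }

  ev <- bind_rows(steady, exo, endo)
  ev <- ev[order(ev$t_birth), , drop = FALSE]
  ev$id <- seq_len(nrow(ev))
  # map parent references (rows of the exo table) to final event ids
  ev$parent_id <- NA_integer_
  if ("parent_row" %in% names(ev) && "exo_row" %in% names(ev)) {
    exo_ids <- ev$id[match(seq_len(nrow(exo)), ev$exo_row)]
    has_parent <- !is.na(ev$parent_row)
    ev$parent_id[has_parent] <- exo_ids[ev$parent_row[has_parent]]
  }
  ev$parent_row <- NULL
  ev$exo_row <- NULL
  as_tibble(ev[, c("id", "marker", "type", "t_birth", "lifetime", "x", "y",
                   "parent_id")])
}

#' Ground-truth punctae table for a marker channel
#'
#' Expands simulated events into the per-frame punctae representation used by
#' the analysis functions: one row per event alive at each frame time
#' (`t_birth <= t < t_birth + lifetime`). This is the oracle counterpart of
#' [detect_punctae()] output and can be fed to any downstream function.
#'
#' @param events table from [simulate_events()].
#' @param cfg the [sim_config()] used to generate them.
#' @param marker `"exo"` or `"endo"` channel, or `"all"`.
#' @return A punctae tibble (`frame`, `time_s`, `label`, `x_um`, `y_um`,
#'   `area_um2`, `type`) carrying movie metadata attributes.
#' @export
ground_truth_punctae <- function(events, cfg, marker = c("exo", "endo", "all")) {
  marker <- match.arg(marker)
  if (marker != "all") events <- events[events$marker == marker, , drop = FALSE]
  tt <- frame_times(cfg)
  out <- purrr::map_dfr(seq_along(tt), function(f) {
    alive <- events$t_birth <= tt[f] & tt[f] < events$t_birth + events$lifetime
    tibble(frame = f, time_s = tt[f], label = events$id[alive],
           x_um = events$x[alive], y_um = events$y[alive],
           area_um2 = NA_real_, type = events$type[alive])
  })
  set_punctae_meta(out, list(
    n_frames = cfg$n_frames, frame_interval = cfg$frame_interval,
    wound_frame = cfg$n_prewound_frames + 1L, pixel_size = cfg$pixel_size
  ))
}

set_punctae_meta <- function(x, meta) {
  attr(x, "movie_meta") <- meta
  x
}

punctae_meta <- function(x) attr(x, "movie_meta")
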