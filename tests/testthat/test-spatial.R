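# Colocalization and nearest-neighbor association statistics.

test_that("a set colocalizes fully with itself and not at all with a disjoint set", {
  a <- punctae_tbl(c(1, 2, 3), c(1, 2, 3))
  a$pixels <- list(1:3, 4:6, 7:9)
  b <- a
  expect_identical(nrow(colocalize(a, b, "mask_overlap")), 3L)
  b2 <- a; b2$pixels <- list(100:102, 103:105, 106:108)
  expect_identical(nrow(colocalize(a, b2, "mask_overlap")), 0L)
  expect_identical(nrow(colocalize(a, b, "centroid_distance", tol = 0.1)), 3L)
  far <- punctae_tbl(c(50, 60), c(50, 60))
  expect_identical(nrow(colocalize(a, far, "centroid_distance", tol = 1)), 0L)
})

test_that("mismatched frames and missing tolerances are refused", {
  a <- punctae_tbl(1, 1, frame = 1L)
  b <- punctae_tbl(1, 1, frame = 2L)
  expect_error(colocalize(a, b, "centroid_distance", tol = 1), "same single frame")
  expect_error(colocalize(a, a, "centroid_distance"), "tol")
})

test_that("a planted overlapping fraction is recovered within binomial error", {
  set.seed(10)
  n <- 100; p_overlap <- 0.3
  hits <- 0; total <- 0
  for (rep in 1:10) {
    ax <- runif(n, 0, 100); ay <- runif(n, 0, 100)
    overlap <- seq_len(n) <= n * p_overlap
    bx <- ifelse(overlap, ax + runif(n, -0.05, 0.05), runif(n, 200, 300))
    by <- ifelse(overlap, ay + runif(n, -0.05, 0.05), runif(n, 200, 300))
    a <- punctae_tbl(ax, ay)
    b <- punctae_tbl(bx, by)
    hits <- hits + nrow(colocalize(a, b, "centroid_distance", tol = 0.2))
    total <- total + n
  }
  expect_lt(abs(hits / total - p_overlap),
            3 * sqrt(p_overlap * (1 - p_overlap) / total))
})

test_that("centroid-rule colocalization is symmetric for matched configurations", {
  set.seed(11)
  a <- punctae_tbl(runif(40, 0, 20), runif(40, 0, 20))
  b <- punctae_tbl(a$x_um + rnorm(40, 0, 0.05), a$y_um + rnorm(40, 0, 0.05))
  n_ab <- nrow(colocalize(a, b, "centroid_distance", tol = 0.3))
  n_ba <- nrow(colocalize(b, a, "centroid_distance", tol = 0.3))
  expect_identical(n_ab, n_ba)
})

test_that("the coloc matrix is zero when channel B is empty", {
  cfg <- events_cfg(n_frames = 16L)
  proc <- event_params(steady_rate = 2e-3, exo_boost_by_ring = 1, endo_boost = 0)
  a <- ground_truth_punctae(simulate_events(cfg, proc, seed = 4), cfg, "exo")
  b <- a[0, , drop = FALSE]
  rg <- events_rings(cfg)
  cm <- coloc_matrix(a, b, rg, rule = "centroid_distance", tol = 1)
  expect_true(all(cm$count == 0))
  expect_true(all(cm$value == 0))
})

test_that("a coupled endocytic channel elevates post-resealing colocalization in inner rings", {
  cfg <- events_cfg(n_frames = 50L, reseal_time = 30)
  proc <- event_params(steady_rate = 8e-4, exo_boost_by_ring = c(25, 1, 1, 1, 1, 1),
                       endo_boost = 10, assoc_prob = 0.95, assoc_sd = 0.3,
                       ring_increment = 8)
  rg <- events_rings(cfg)
  inner <- outer_r <- 0
  for (s in 1:8) {
    ev <- simulate_events(cfg, proc, seed = 700 + s)
    exo <- ground_truth_punctae(ev, cfg, "exo")
    endo <- ground_truth_punctae(ev, cfg, "endo")
    cm <- coloc_matrix(endo, exo, rg, rule = "centroid_distance", tol = 1)
    post <- cm$time_s > 30
    inner <- inner + sum(cm$count[cm$ring == 1 & post])
    outer_r <- outer_r + sum(cm$count[cm$ring == 6 & post])
  }
  dens_ratio <- (inner / rg$area_um2[1]) / max(outer_r / rg$area_um2[6], 1e-9)
  expect_gt(dens_ratio, 3)
})

test_that("reference events pool the configured rings and window", {
  cfg <- events_cfg()
  proc <- event_params(steady_rate = 8e-4,
                       exo_boost_by_ring = c(40, 1, 1, 1, 1, 1),
                       endo_boost = 0, ring_increment = 8)
  ev <- simulate_events(cfg, proc, seed = 2)
  exo <- ground_truth_punctae(ev, cfg, "exo")
  rg <- events_rings(cfg)
  ref <- reference_events(exo, rg, window = c(0, 10), ring_set = 1)
  lab <- assign_ring(ref$x_um, ref$y_um, rg)
  expect_true(all(lab == "ring1"))
  expect_true(all(ref$time_s > 0 & ref$time_s <= 10))
  # empty reference refuses with an explicit signal
  expect_error(reference_events(exo[0, ], rg), "Empty reference")
})

test_that("nearest-neighbor distances follow plane geometry", {
  ref <- punctae_tbl(0, 0)
  endo <- punctae_tbl(3, 4)
  endo <- set_meta_1frame(endo)
  ser <- nn_series(endo, ref, normalization_frame = 1L)
  expect_equal(ser$mean_distance_um, 5)
  # identical sets give a zero series (and refuse normalization by zero)
  same <- set_meta_1frame(punctae_tbl(c(1, 2), c(1, 2)))
  expect_error(nn_series(same, punctae_tbl(c(1, 2), c(1, 2)),
                         normalization_frame = 1L), "zero")
})

test_that("nearest-neighbor search equals the exhaustive all-pairs minimum", {
  set.seed(12)
  qx <- runif(200, 0, 50); qy <- runif(200, 0, 50)
  rx <- runif(150, 0, 50); ry <- runif(150, 0, 50)
  got <- woundsight:::nn_distances(qx, qy, rx, ry)
  want <- vapply(seq_along(qx), function(i) {
    best <- Inf
    for (j in seq_along(rx)) {
      dij <- sqrt((qx[i] - rx[j])^2 + (qy[i] - ry[j])^2)
      if (dij < best) best <- dij
    }
    best
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("NN distances are permutation-invariant and monotone under reference growth", {
  set.seed(13)
  qx <- runif(50, 0, 30); qy <- runif(50, 0, 30)
  rx <- runif(40, 0, 30); ry <- runif(40, 0, 30)
  d1 <- woundsight:::nn_distances(qx, qy, rx, ry)
  perm <- sample(40)
  expect_equal(woundsight:::nn_distances(qx, qy, rx[perm], ry[perm]), d1)
  d2 <- woundsight:::nn_distances(qx, qy, c(rx, 15), c(ry, 15))
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("frames without endocytic punctae propagate as missing, never zero", {
  p <- dplyr::bind_rows(punctae_tbl(1, 1, frame = 1L),
                        punctae_tbl(2, 2, frame = 3L))
  p <- set_punctae_meta_pub(p, n_frames = 3L, wound_frame = 1L)
  ser <- nn_series(p, punctae_tbl(0, 0), normalization_frame = 1L)
  expect_true(is.na(ser$mean_distance_um[ser$frame == 2]))
  expect_identical(ser$n[ser$frame == 2], 0L)
})

test_that("coupled movies dip after resealing for circle-1 reference but not circle 6", {
  cfg <- events_cfg(n_frames = 50L, reseal_time = 30)
  proc <- event_params(steady_rate = 8e-4,
                       exo_boost_by_ring = c(25, 8, 1, 1, 1, 1),
                       endo_boost = 6, assoc_prob = 0.9, assoc_sd = 1,
                       ring_increment = 8)
  rg <- events_rings(cfg)
  ev <- simulate_events(cfg, proc, seed = 99)
  exo <- ground_truth_punctae(ev, cfg, "exo")
  endo <- ground_truth_punctae(ev, cfg, "endo")
  ref1 <- reference_events(exo, rg, window = c(0, 10), ring_set = 1)
  s1 <- nn_series(endo, ref1)
  pre <- s1$time_s > 0 & s1$time_s <= 30
  post <- s1$time_s > 30
  expect_lt(mean(s1$normalized_distance[post], na.rm = TRUE),
            mean(s1$normalized_distance[pre], na.rm = TRUE))
  s6 <- nn_control(endo, exo, rg, window = c(0, 10), control_ring = 6)
  expect_gte(mean(s6$normalized_distance[post], na.rm = TRUE),
             0.8 * mean(s6$normalized_distance[pre], na.rm = TRUE))
})

test_that("wound-distance density matches the triangle law for a uniform disk", {
  set.seed(14)
  n <- 20000
  r <- sqrt(runif(n)) * 10
  th <- runif(n, 0, 2 * pi)
  p <- punctae_tbl(5 + r * cos(th), 5 + r * sin(th))
  d <- wound_distance_density(p, c(5, 5), max_extent = 10)
  expect_true(all(d$normalized_distance >= 0 & d$normalized_distance <= 1))
  # P(r <= u) = u^2 for the triangle density 2u
  h <- stats::ecdf(d$normalized_distance)
  u <- seq(0.1, 0.9, by = 0.2)
  expect_lt(max(abs(h(u) - u^2)), 0.02)
  # degenerate cases
  expect_identical(nrow(wound_distance_density(p[0, ], c(0, 0))), 0L)
  at0 <- wound_distance_density(punctae_tbl(c(5, 5), c(5, 5)), c(5, 5))
  expect_true(all(at0$distance_um == 0))
})
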