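# Resealing kinetics: influx curves, classification, hydrogel metrics,
# scrape arithmetic.

make_flat_movie <- function(w_val = 50, u_val = 20, n_frames = 12) {
  dat <- array(0, dim = c(n_frames, 1, 32, 32))
  wmask <- matrix(FALSE, 32, 32); wmask[5:15, 5:15] <- TRUE
  umask <- matrix(FALSE, 32, 32); umask[20:30, 20:30] <- TRUE
  for (f in seq_len(n_frames)) {
    img <- matrix(0, 32, 32)
    img[wmask] <- w_val
    img[umask] <- u_val
    dat[f, 1, , ] <- img
  }
  mv <- as_wound_movie(dat, pixel_size = 0.5, wound_frame = 3L,
                       wound_center = c(5, 5), cell_mask = wmask,
                       neighbor_mask = umask, channels = "dye")
  mv
}

test_that("constant signals give a constant unit curve", {
  mv <- make_flat_movie()
  cur <- influx_curve(mv)
  expect_equal(cur$normalized_intensity, rep(1, 12))
  expect_equal(cur$time_s[attr(cur, "reference_frame")], 0)
})

test_that("the influx curve is invariant to global intensity scaling", {
  cfg <- small_cfg(n_frames = 20L, image = 96L, px = 0.35)
  proc <- event_params(steady_rate = 0, exo_boost_by_ring = 1, endo_boost = 0)
  mv <- simulate_movie(cfg, proc)$movie
  cur1 <- influx_curve(mv)
  mv$data <- mv$data * 3.7
  cur2 <- influx_curve(mv)
  expect_equal(cur2$normalized_intensity, cur1$normalized_intensity,
               tolerance = 1e-12)
})

test_that("closed-form saturating and linear curves classify as resealed and failed", {
  t <- seq(-1, 60)
  sat <- tibble::tibble(time_s = t,
                        normalized_intensity = 1 + (1 - exp(-pmax(t, 0) / 5)))
  lin <- tibble::tibble(time_s = t, normalized_intensity = 1 + 0.05 * pmax(t, 0))
  expect_identical(classify_resealing(sat)$classification, "resealed")
  expect_identical(classify_resealing(lin)$classification, "failed")
  # a perfectly flat curve carries no influx signal
  flat <- tibble::tibble(time_s = t, normalized_intensity = rep(1, length(t)))
  expect_identical(classify_resealing(flat)$classification, "indeterminate")
})

test_that("classification is invariant to adding a constant to the curve", {
  t <- seq(-1, 60)
  set.seed(3)
  curve <- tibble::tibble(
    time_s = t,
    normalized_intensity = 1 + (1 - exp(-pmax(t, 0) / 5)) + rnorm(length(t), 0, 0.02))
  a <- classify_resealing(curve)
  curve$normalized_intensity <- curve$normalized_intensity + 5
  b <- classify_resealing(curve)
  expect_identical(a$classification, b$classification)
  expect_equal(a$early_slope, b$early_slope, tolerance = 1e-10)
})

test_that("generator movies classify according to their influx ground truth", {
  cfg <- small_cfg(n_frames = 42L, image = 96L, px = 0.35, seed = 21L)
  proc <- event_params(steady_rate = 0, exo_boost_by_ring = 1, endo_boost = 0)
  r <- simulate_movie(cfg, proc, resealed = TRUE)
  f <- simulate_movie(cfg, proc, resealed = FALSE)
  expect_identical(classify_resealing(influx_curve(r$movie))$classification,
                   "resealed")
  expect_identical(classify_resealing(influx_curve(f$movie))$classification,
                   "failed")
  expect_identical(r$truth$influx_class, "resealed")
  expect_identical(f$truth$influx_class, "failed")
})

test_that("windows below three samples are refused", {
  t <- seq(-1, 30)
  curve <- tibble::tibble(time_s = t, normalized_intensity = 1 + 0.1 * pmax(t, 0))
  expect_error(classify_resealing(curve, early_window = c(0, 1)), "3 samples")
})

test_that("a non-positive corrected reference refuses to normalize", {
  mv <- make_flat_movie(w_val = 10, u_val = 30)
  expect_error(influx_curve(mv), "not positive")
  mv2 <- make_flat_movie()
  expect_error(influx_curve(mv2, mv2$cell_mask, mv2$cell_mask), "disjoint")
})

test_that("around-wound intensity is unity for a uniform image and exceeds the whole-cell curve for wound-localized influx", {
  n <- 12
  dat <- array(42, dim = c(n, 1, 64, 64))
  mv <- as_wound_movie(dat, pixel_size = 0.5, wound_frame = 3L,
                       wound_center = c(16, 16), channels = "dye")
  aw <- around_wound_intensity(mv, diameter = 10)
  expect_equal(aw$normalized_intensity, rep(1, n))

  cfg <- small_cfg(n_frames = 20L, image = 128L, px = 0.35, seed = 4L)
  proc <- event_params(steady_rate = 0, exo_boost_by_ring = 1, endo_boost = 0,
                       bleach_rate = 0)
  mvs <- simulate_movie(cfg, proc, resealed = TRUE)$movie
  aw2 <- around_wound_intensity(mvs, diameter = 5)
  # whole-cell curve under the same normalization (same reference)
  cell <- mvs$cell_mask
  ref <- mean(frame_image(mvs, 2, 1)[cell])
  whole <- vapply(seq_len(20), function(f) mean(frame_image(mvs, f, 1)[cell]),
                  numeric(1)) / ref
  late <- aw2$time_s >= 8 # once the wound-site accumulation has built up
  expect_true(all(aw2$normalized_intensity[late] > whole[late]))
})

test_that("an out-of-cell ROI is flagged and an out-of-image ROI refused", {
  n <- 4
  dat <- array(1, dim = c(n, 1, 64, 64))
  cell <- matrix(FALSE, 64, 64); cell[40:60, 40:60] <- TRUE
  mv <- as_wound_movie(dat, pixel_size = 0.5, wound_frame = 3L,
                       wound_center = c(5, 5), cell_mask = cell,
                       channels = "dye")
  expect_warning(aw <- around_wound_intensity(mv, diameter = 6), "background")
  expect_true(attr(aw, "outside_cell"))
  expect_error(around_wound_intensity(mv, diameter = 40), "beyond")
})

test_that("delineation area fraction follows mask geometry", {
  cell <- matrix(TRUE, 20, 20)
  half <- matrix(FALSE, 20, 20); half[1:10, ] <- TRUE
  expect_equal(delineation_area_fraction(cell, cell), 1)
  expect_equal(delineation_area_fraction(matrix(FALSE, 20, 20), cell), 0)
  expect_equal(delineation_area_fraction(half, cell), 0.5)
  expect_error(delineation_area_fraction(cell, matrix(FALSE, 20, 20)), "empty")
  expect_error(delineation_area_fraction(cell, half), "contained")
})

test_that("scrape repair percentage is the repaired fraction of wounded cells", {
  expect_equal(scrape_repair_percentage(1000, 250), 75)
  expect_equal(scrape_repair_percentage(500, 0), 100)
  expect_equal(scrape_repair_percentage(500, 500), 0)
  expect_equal(scrape_repair_percentage(c(100, 200), c(10, 30)), c(90, 85))
  expect_error(scrape_repair_percentage(0, 0), "n_wounded")
  expect_error(scrape_repair_percentage(10, 11), "between")
})
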