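# Hole energetics and tether-force plateau extraction.

test_that("enthalpy components follow the line/tension decomposition", {
  p <- membrane_params(energy = 2e-19)
  h0 <- hole_enthalpy(0, p)
  expect_equal(h0$enthalpy_J, 2 * p$energy)
  expect_equal(h0$line_J, p$energy)
  expect_equal(h0$tension_J, p$energy)
  R <- 5e-8
  h <- hole_enthalpy(R, p)
  expect_equal(h$enthalpy_J, h$line_J + h$tension_J)
  expect_equal(h$line_J - p$energy, 2 * pi * R * p$line_tension)
  expect_equal(h$tension_J - p$energy, -pi * R^2 * p$membrane_tension)
  expect_error(hole_enthalpy(-1e-9, p), ">= 0")
})

test_that("the barrier height at the critical radius is pi * lambda^2 / sigma", {
  p <- membrane_params()
  rc <- critical_radius(p)
  barrier <- hole_enthalpy(rc, p)$enthalpy_J - hole_enthalpy(0, p)$enthalpy_J
  expect_equal(barrier, pi * p$line_tension^2 / p$membrane_tension,
               tolerance = 1e-12)
  expect_equal(barrier, pi * 1e-19, tolerance = 1e-12)
})

test_that("the enthalpy derivative vanishes at the critical radius (finite differences)", {
  for (lam in c(5e-13, 1e-12, 4e-12)) {
    for (sig in c(1e-6, 1e-5, 1e-4)) {
      p <- membrane_params(lam, sig)
      rc <- critical_radius(p)
      h <- 1e-6 * rc
      dH <- (hole_enthalpy(rc + h, p)$enthalpy_J -
               hole_enthalpy(rc - h, p)$enthalpy_J) / (2 * h)
      # slope scale of H is 2*pi*lambda; the stationary point must be flat
      expect_lt(abs(dH) / (2 * pi * lam), 1e-6)
      # concavity: the stationary point is a barrier maximum
      d2H <- (hole_enthalpy(rc + h, p)$enthalpy_J -
                2 * hole_enthalpy(rc, p)$enthalpy_J +
                hole_enthalpy(rc - h, p)$enthalpy_J) / h^2
      expect_equal(d2H, -2 * pi * sig, tolerance = 1e-3)
    }
  }
})

test_that("critical radius equals line tension over membrane tension", {
  expect_equal(critical_radius(membrane_params(1e-12, 1e-5)), 1e-7)   # 100 nm
  expect_equal(critical_radius(membrane_params(1e-12, 1e-6)), 1e-6)   # 1 um
  expect_equal(critical_radius(membrane_params(0, 1e-5)), 0)
  expect_error(critical_radius(membrane_params(1e-12, 0)), "membrane_tension")
  # unit consistency over 4 decades: linear in lambda, inverse in sigma
  for (k in 10^(0:3)) {
    expect_equal(critical_radius(membrane_params(1e-12 * k, 1e-5)), 1e-7 * k)
    expect_equal(critical_radius(membrane_params(1e-12, 1e-5 * k)), 1e-7 / k)
  }
})

test_that("hole fate matches a gradient-flow relaxation of the enthalpy", {
  p <- membrane_params()
  rc <- critical_radius(p)
  expect_identical(hole_fate(50e-9, p), "reseal")
  expect_identical(hole_fate(200e-9, p), "grow")
  expect_identical(hole_fate(rc, p), "critical")

  # oracle: descend H along -dH/dR and watch where the radius goes
  gradient_flow_fate <- function(R, p, rc) {
    dH <- function(r) 2 * pi * p$line_tension - 2 * pi * p$membrane_tension * r
    eta <- 0.05 * rc / (2 * pi * p$line_tension)
    for (i in 1:2000) {
      R <- R - eta * dH(R)
      if (R <= 0) return("reseal")
      if (R >= 10 * rc) return("grow")
    }
    "critical"
  }
  set.seed(21)
  for (i in 1:50) {
    R <- runif(1, 0.1, 3) * rc
    if (abs(R - rc) < 1e-3 * rc) next
    expect_identical(hole_fate(R, p), gradient_flow_fate(R, p, rc))
  }
})

test_that("reducing membrane tension converts growth to resealing, monotonically", {
  sc <- tension_scan(1e-6, membrane_params(), tension_factors = c(1, 0.1, 0.05))
  expect_identical(sc$fate, c("grow", "critical", "reseal"))
  # descending factors: once a hole reseals it stays resealing
  sc2 <- tension_scan(1e-6, membrane_params(),
                      tension_factors = sort(10^runif(20, -2, 0), decreasing = TRUE))
  f <- sc2$fate[sc2$fate != "critical"]
  expect_true(all(diff(f == "reseal") >= 0))
  # small holes reseal at any factor <= 1
  sc3 <- tension_scan(50e-9, membrane_params(), tension_factors = c(1, 0.5, 0.1))
  expect_true(all(sc3$fate == "reseal"))
  expect_error(tension_scan(1e-6, tension_factors = c(1, -1)), "> 0")
})

test_that("noise-free plateau extraction is exact", {
  ft <- simulate_force_trace(45, 20, noise_sd = 0, n_samples = 1000, seed = 1)
  pf <- plateau_force(ft$trace)
  expect_identical(pf$plateau_pN, 20)
  expect_identical(pf$peak_pN, 45)
  expect_gte(pf$plateau_start, ft$truth$plateau_start)
})

test_that("a flat zero trace raises a no-tether error", {
  flat <- tibble::tibble(time_s = (0:199) / 1000, force_pN = rep(0, 200))
  expect_error(plateau_force(flat), "No tether")
  set.seed(5)
  noise_only <- tibble::tibble(time_s = (0:499) / 1000,
                               force_pN = rnorm(500))
  expect_error(plateau_force(noise_only), "No tether")
})

test_that("plateau recovery stays within the CLT bound on a noisy trace", {
  ft <- simulate_force_trace(45, 20, noise_sd = 1, n_samples = 1000, seed = 31)
  pf <- plateau_force(ft$trace)
  expect_lt(abs(pf$plateau_pN - 20), 3 / sqrt(pf$n_plateau))
  # the detected window must lie inside the true plateau segment
  expect_gte(pf$plateau_start, ft$truth$plateau_start)
})

test_that("plateau extraction is invariant to a constant force offset", {
  ft <- simulate_force_trace(45, 20, noise_sd = 1, n_samples = 800, seed = 6)
  base <- plateau_force(ft$trace)
  shifted <- ft$trace
  shifted$force_pN <- shifted$force_pN + 12.5
  off <- plateau_force(shifted)
  expect_equal(off$plateau_pN - 12.5, base$plateau_pN, tolerance = 1e-9)
  expect_identical(off$plateau_start, base$plateau_start)
})

test_that("short traces are refused", {
  expect_error(plateau_force(tibble::tibble(time_s = 1:10, force_pN = 1:10)),
               "50 samples")
})
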