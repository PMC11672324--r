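#' Membrane mechanical parameters
#'
#' Standard material parameters of the hole-energetics model: line tension
#' lambda (energy per unit length of the open hole edge, default 1 pN) and
#' membrane tension sigma (energy per unit area, default 1e-5 N/m), plus
#' the arbitrary additive system energy E. SI units throughout.
#'
#' @param line_tension lambda in N (1 pN = 1e-12 N).
#' @param membrane_tension sigma in N/m.
#' @param energy additive system energy E in J (drops out of fates and the
#'   critical radius).
#' @return A `wound_membrane_params` list.
#' @export
membrane_params <- function(line_tension = 1e-12, membrane_tension = 1e-5,
                            energy = 0) {
  if (line_tension < 0) abort("`line_tension` must be >= 0.")
  structure(list(line_tension = line_tension,
                 membrane_tension = membrane_tension,
                 energy = energy),
            class = "wound_membrane_params")
}

#' Hole enthalpy and its components
#'
#' Total effective enthalpy of a circular membrane hole of radius R:
#' `H(R) = 2E + 2*pi*R*lambda - pi*R^2*sigma`, the sum of the edge (line
#' tension) contribution `H_line = E + 2*pi*R*lambda` and the area
#' (membrane tension) contribution `H_tension = E - pi*R^2*sigma`. H is
#' concave in R (`d2H/dR2 = -2*pi*sigma < 0`), so its stationary point at
#' `R_c = lambda/sigma` is an energy barrier: smaller holes lower H by
#' shrinking, larger holes by growing.
#'
#' @param R hole radius in m (vectorized, >= 0).
#' @param params a [membrane_params()].
#' @return A tibble `R_m`, `enthalpy_J`, `line_J`, `tension_J`.
#' @export
#' @examples
#' hole_enthalpy(c(0, 50e-9, 100e-9), membrane_params())
hole_enthalpy <- function(R, params = membrane_params()) {
  if (any(R < 0)) abort("Hole radius must be >= 0.")
  lam <- params$line_tension; sig <- params$membrane_tension; E <- params$energy
  tibble(
    R_m = R,
    enthalpy_J = 2 * E + 2 * pi * R * lam - pi * R^2 * sig,
    line_J = E + 2 * pi * R * lam,
    tension_J = E - pi * R^2 * sig
  )
}

#' Critical hole radius
#'
#' The stationary point of the hole enthalpy, `R_c = lambda / sigma`: holes
#' smaller than R_c self-reseal, larger holes grow. With the standard
#' lambda = 1 pN and sigma = 1e-5 N/m this is 100 nm; reducing the membrane
#' tension by an order of magnitude moves it to 1 um.
#'
#' @param params a [membrane_params()] with `membrane_tension > 0`.
#' @return Critical radius in m.
#' @export
#' @examples
#' critical_radius(membrane_params()) * 1e9 # 100 nm
critical_radius <- function(params = membrane_params()) {
  if (params$membrane_tension <= 0) {
    abort("`membrane_tension` must be > 0 for a finite critical radius.")
  }
  params$line_tension / params$membrane_tension
}

#' Fate of a membrane hole
#'
#' Decides whether a hole of radius R reseals (`R < R_c`, enthalpy decreases
#' toward R = 0), grows (`R > R_c`), or sits at the critical point (equality
#' within relative tolerance).
#'
#' @param R hole radius in m (vectorized).
#' @param params a [membrane_params()].
#' @param rel_tol relative tolerance for the critical equality.
#' @return Character vector in `{"reseal", "grow", "critical"}`.
#' @export
hole_fate <- function(R, params = membrane_params(), rel_tol = 1e-12) {
  if (any(R < 0)) abort("Hole radius must be >= 0.")
  rc <- critical_radius(params)
  out <- ifelse(abs(R - rc) <= rel_tol * max(rc, .Machine$double.xmin),
                "critical", ifelse(R < rc, "reseal", "grow"))
  as.character(out)
}

#' Hole fate under scaled membrane tension
#'
#' Evaluates [hole_fate()] with the membrane tension multiplied by each
#' factor — the model's account of how a local tension reduction (e.g. by an
#' order of magnitude after exocytic membrane supply and actin
#' depolymerization) converts a growing hole into a self-resealing one.
#' Reducing tension never flips a resealing hole to growth.
#'
#' @param R hole radius in m.
#' @param params a [membrane_params()].
#' @param tension_factors positive multiplicative factors applied to sigma.
#' @return A tibble `factor`, `membrane_tension`, `critical_radius_m`,
#'   `fate`.
#' @export
#' @examples
#' tension_scan(1e-6, tension_factors = c(1, 0.1, 0.05))
tension_scan <- function(R, params = membrane_params(),
                         tension_factors = c(1, 0.1, 0.05)) {
  if (any(tension_factors <= 0)) abort("`tension_factors` must be > 0.")
  purrr::map_dfr(tension_factors, function(f) {
    p <- membrane_params(params$line_tension, params$membrane_tension * f,
                         params$energy)
    tibble(factor = f, membrane_tension = p$membrane_tension,
           critical_radius_m = critical_radius(p),
           fate = hole_fate(R, p))
  })
}

#' Tether-force plateau extraction
#'
#' Extracts the peak force and the average plateau force from an
#' optical-tweezers tether-pulling trace. The plateau force immediately
#' after the peak is the membrane-tension indicator. Procedure: baseline
#' and noise are estimated from the leading `baseline_frac` of the trace;
#' a trace whose maximum does not exceed baseline by `min_snr` noise
#' standard deviations is rejected ("no tether"). The peak is the global
#' maximum; after a `guard`-sample post-peak gap, the plateau onset is the
#' change-point where the smoothed derivative magnitude first falls to
#' `deriv_frac` of its post-peak maximum; the plateau window then starts
#' half the relaxation span later again (so residual relaxation cannot bias
#' the mean) and runs to the end of the trace.
#'
#' @param trace a force trace tibble (`time_s`, `force_pN`).
#' @param baseline_frac leading fraction used for baseline/noise estimation.
#' @param min_snr "no tether" rejection threshold, in noise SDs above
#'   baseline.
#' @param guard samples skipped immediately after the peak.
#' @param deriv_frac derivative-magnitude fraction defining the
#'   change-point.
#' @param smooth running-mean half-width (samples) for the derivative
#'   estimate; default scales with trace length.
#' @return A `wound_tether_fit`: list with `peak_pN`, `plateau_pN`,
#'   `peak_index`, `plateau_start`, `n_plateau`, `baseline_pN`,
#'   `noise_sd_pN`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
plateau_force <- function(trace, baseline_frac = 0.1, min_snr = 5,
                          guard = 10L, deriv_frac = 0.05, smooth = NULL) {
  f <- trace$force_pN
  n <- length(f)
  if (n < 50) abort("Trace must contain at least 50 samples.")
  nb <- max(5L, floor(baseline_frac * n))
  baseline <- median(f[seq_len(nb)])
  noise <- mad(f[seq_len(nb)])

  peak_index <- which.max(f)
  if (f[peak_index] <= baseline + min_snr * noise || f[peak_index] <= baseline) {
    abort("No tether: trace maximum does not rise above baseline noise.")
  }

  if (is.null(smooth)) smooth <- max(3L, round(n / 100))
  s <- running_mean(f, smooth)
  dv <- c(0, diff(s))
  dv <- running_mean(dv, smooth)

  # skip past both the configured guard and the smoothing support, so the
  # rise-to-relaxation transition (where the smoothed derivative crosses
  # zero) cannot masquerade as the plateau onset
  i0 <- min(peak_index + max(guard, 2L * smooth + 1L), n - 1L)
  post <- abs(dv[i0:n])
  # plateau onset: the smoothed derivative has settled AND the smoothed
  # force agrees with the tail-of-trace plateau level. The value condition
  # protects against shallow relaxations whose derivative is buried in
  # noise.
  m0 <- mean(f[floor(3 * n / 4):n])
  sigma_s <- noise / sqrt(2 * smooth + 1)
  val_tol <- max(3 * sigma_s, 1e-9 * max(abs(f)))
  ok <- post <= deriv_frac * max(post) &
    abs(s[i0:n] - m0) <= val_tol
  cp_rel <- which(ok)[1]
  cp <- if (is.na(cp_rel)) i0 + which.min(post) - 1L else i0 + cp_rel - 1L
  start <- min(cp + ceiling((cp - peak_index) / 2), n - 1L)
  plateau_win <- start:n
  plateau <- mean(f[plateau_win])

  structure(
    list(peak_pN = f[peak_index] , plateau_pN = plateau,
         peak_index = peak_index, plateau_start = start,
         n_plateau = length(plateau_win),
         baseline_pN = baseline, noise_sd_pN = noise,
         trace = as_tibble(trace)),
    class = "wound_tether_fit"
  )
}

# centered running mean with partial windows at the edges
running_mean <- function(x, half_width) {
  hw <- as.integer(half_width)
  n <- length(x)
  if (hw < 1 || 2L * hw + 1L >= n) return(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - hw, 1L)
  hi <- pmin(seq_len(n) + hw, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' @export
print.wound_tether_fit <- function(x, ...) {
  cat(sprintf("<wound_tether_fit> peak %.2f pN, plateau %.2f pN over %d samples (baseline %.2f pN, noise %.2f pN)\n",
              x$peak_pN, x$plateau_pN, x$n_plateau, x$baseline_pN, x$noise_sd_pN))
  invisible(x)
}
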