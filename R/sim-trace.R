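#' Simulate an optical-tweezers tether force trace
#'
#' Generates a force-time trace with the canonical tether-pulling shape:
#' a zero-force baseline, a linear rise to the peak force at tether
#' formation, a linear relaxation to the plateau force, and a plateau
#' segment of at least `n_samples / 2` points, with additive Gaussian
#' noise. The relaxation reaches the plateau exactly at the segment end, so
#' in the noise-free case the plateau samples are identically the plateau
#' force.
#'
#' @param peak peak force, pN (>= `plateau`).
#' @param plateau plateau force, pN (>= 0).
#' @param noise_sd Gaussian noise standard deviation, pN.
#' @param n_samples number of samples in the trace.
#' @param seed integer seed.
#' @param sampling_rate samples per second (traces are recorded at 1000 s^-1
#'   by default).
#' @param baseline_frac,rise_frac,decay_frac fractions of the trace spent in
#'   the baseline, rise and relaxation segments (the remainder, at least
#'   half, is plateau).
#' @return A list with `trace` (a `wound_force_trace` tibble: `time_s`,
#'   `force_pN`) and `truth` (`peak`, `plateau`, `plateau_start` index,
#'   `noise_sd`).
#' @export
#' @examples
#' ft <- simulate_force_trace(45, 20, noise_sd = 1, n_samples = 1000, seed = 1)
#' plateau_force(ft$trace)
simulate_force_trace <- function(peak, plateau, noise_sd = 1,
                                 n_samples = 1000L, seed = 1L,
                                 sampling_rate = 1000,
                                 baseline_frac = 0.15, rise_frac = 0.1,
                                 decay_frac = 0.2) {
  if (plateau < 0) abort("`plateau` must be >= 0.")
  if (peak < plateau) abort("`plateau` must not exceed `peak`.")
  if (n_samples < 50) abort("`n_samples` must be >= 50.")
  if (baseline_frac + rise_frac + decay_frac > 0.5) {
    abort("baseline + rise + decay must leave at least half of the trace for the plateau.")
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  n_base <- round(baseline_frac * n_samples)
  n_rise <- round(rise_frac * n_samples)
  n_decay <- round(decay_frac * n_samples)
  n_plateau <- n_samples - n_base - n_rise - n_decay

  force <- c(
    rep(0, n_base),
    seq(0, peak, length.out = n_rise + 1)[-1],
    seq(peak, plateau, length.out = n_decay + 1)[-1],
    rep(plateau, n_plateau)
  )
  if (noise_sd > 0) force <- force + rnorm(n_samples, 0, noise_sd)

  trace <- structure(
    tibble(time_s = (seq_len(n_samples) - 1) / sampling_rate,
           force_pN = force),
    class = c("wound_force_trace", class(tibble())),
    sampling_rate = sampling_rate
  )
  list(
    trace = trace,
    truth = list(peak = peak, plateau = plateau,
                 plateau_start = n_base + n_rise + n_decay + 1L,
                 noise_sd = noise_sd)
  )
}

#' Read / write force traces as two-column CSV
#'
#' @param path file path; columns `time_s`, `force_pN`.
#' @return [read_force_trace()] returns a `wound_force_trace` tibble.
#' @export
read_force_trace <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("time_s", "force_pN") %in% names(x))) {
    abort("Force trace CSV must have columns `time_s`, `force_pN`.")
  }
  dt <- diff(x$time_s)
  structure(as_tibble(x[, c("time_s", "force_pN")]),
            class = c("wound_force_trace", class(tibble())),
            sampling_rate = if (length(dt)) 1 / median(dt) else NA_real_)
}

#' @param trace a force trace tibble.
#' @rdname read_force_trace
#' @export
write_force_trace <- function(trace, path) {
  readr::write_csv(as_tibble(trace)[, c("time_s", "force_pN")], path)
  invisible(path)
}
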