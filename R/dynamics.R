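# Twin-cutoff contact dynamics: binary contact trajectories with hysteresis
# and exponential relaxation-time estimation from the contact autocorrelation.

#' Binary contact trajectory under the twin-cutoff (hysteresis) scheme
#'
#' A contact is formed when the pair distance drops below `r_on` and broken
#' only once it exceeds `r_off`; distances in the dead zone
#' `[r_on, r_off]` retain the previous state, suppressing spurious boundary
#' recrossings.  When the series starts inside the dead zone the first
#' unambiguous state is back-filled by default (`initial = "drop"` instead
#' removes the leading undetermined frames).
#'
#' @param distance_series per-frame distances in nm.
#' @param r_on inner (formation) cutoff, nm; default 0.45.
#' @param r_off outer (breaking) cutoff, nm; default 0.6; must exceed `r_on`.
#' @param dt frame spacing in ns.
#' @param pair optional `(i, j)` label.
#' @param initial handling of a leading dead-zone stretch.
#' @return object of class `fib_contact_states`: logical `states`
#'   (TRUE = formed) plus the parameters.
#' @examples
#' contact_state_trajectory(c(0.3, 0.5, 0.5, 0.7), dt = 0.1)$states
#' @export
contact_state_trajectory <- function(distance_series, r_on = 0.45,
                                     r_off = 0.6, dt = 1,
                                     pair = NULL,
                                     initial = c("backfill", "drop")) {
  initial <- match.arg(initial)
  if (r_on >= r_off)
    .fib_err("r_on must be smaller than r_off", "fibmod_parameter_error")
  if (!length(distance_series))
    .fib_err("empty distance series", "fibmod_parameter_error")
  s <- ifelse(distance_series < r_on, 1,
              ifelse(distance_series > r_off, 0, NA))
  det <- which(!is.na(s))
  if (!length(det))
    .fib_err("distance series never leaves the dead zone",
             "fibmod_state_error")
  # carry last determined state forward; rule = 2 back-fills the head
  filled <- stats::approx(det, s[det], xout = seq_along(s),
                          method = "constant", f = 0, rule = 2)$y
  dropped <- 0L
  if (initial == "drop" && det[1L] > 1L) {
    dropped <- det[1L] - 1L
    filled <- filled[-seq_len(dropped)]
  }
  structure(list(states = as.logical(filled), r_on = r_on, r_off = r_off,
                 dt = dt, pair = pair, dropped_frames = dropped),
            class = "fib_contact_states")
}

#' @export
print.fib_contact_states <- function(x, ...) {
  cat(sprintf(
    "Contact-state trajectory: %d frames, %.1f%% formed (r_on %.2f / r_off %.2f nm, dt %g ns)\n",
    length(x$states), 100 * mean(x$states), x$r_on, x$r_off, x$dt))
  invisible(x)
}

# FFT autocorrelation of a centred series, biased normalisation (divide by n)
.autocorr <- function(x, max_lag) {
  n <- length(x)
  x <- x - mean(x)
  m <- 2^ceiling(log2(2L * n))
  fx <- stats::fft(c(x, numeric(m - n)))
  ac <- Re(stats::fft(Mod(fx)^2, inverse = TRUE))[seq_len(max_lag + 1L)] / m
  ac / ac[1L]
}

#' Contact relaxation time from the autocorrelation decay
#'
#' Computes the normalised fluctuation autocorrelation C(t) of a binary
#' contact trajectory and fits a single exponential by log-linear least
#' squares (through the origin, lag 0 excluded) over lags up to where C(t)
#' first drops below 0.05, capped at 10% of the trajectory length.  For a
#' two-state (telegraph) contact with rates k_on and k_off the estimator
#' recovers tau = 1/(k_on + k_off).
#'
#' @param states a [contact_state_trajectory()] result, or a logical/0-1
#'   vector together with `dt`.
#' @param dt frame spacing in ns (ignored when `states` carries one).
#' @param c_floor autocorrelation level ending the fit window.
#' @return object of class `fib_relaxation`: `tau` (ns; `NA` when the decay
#'   is not exponential-like), `fit_window` (ns), `fit_quality` (RMS residual
#'   of the log-linear fit; `Inf` when rejected), `n_lags`, `ok`.
#' @examples
#' st <- simulate_telegraph_states(2e4, k_on = 0.2, k_off = 0.2,
#'                                 dt = 0.05, seed = 1)
#' contact_relaxation_time(st)$tau  # about 1 / 0.4 = 2.5 ns
#' @export
contact_relaxation_time <- function(states, dt = NULL, c_floor = 0.05) {
  pair <- NULL
  if (inherits(states, "fib_contact_states")) {
    dt <- states$dt; pair <- states$pair; states <- states$states
  }
  if (is.null(dt)) dt <- 1
  s <- as.numeric(states)
  if (length(unique(s)) < 2L)
    .fib_err("constant contact state: relaxation undefined (non-fluctuating pair)",
             "fibmod_constant_states_error")
  n <- length(s)
  max_lag <- max(floor(0.1 * n), 2L)
  C <- .autocorr(s, max_lag)
  below <- which(C[-1L] < c_floor)
  last <- if (length(below)) below[1L] - 1L else max_lag
  lags <- seq_len(last)
  lags <- lags[C[lags + 1L] > 0]
  bad <- length(lags) < 2L
  tau <- NA_real_; quality <- Inf; slope <- NA_real_
  if (!bad) {
    tt <- lags * dt
    lc <- log(C[lags + 1L])
    slope <- sum(tt * lc) / sum(tt * tt)
    if (slope < 0) {
      tau <- -1 / slope
      quality <- sqrt(mean((lc - slope * tt)^2))
    }
  }
  structure(list(pair = pair, tau = tau,
                 fit_window = c(0, last * dt),
                 fit_quality = quality, n_lags = length(lags),
                 ok = is.finite(tau) && is.finite(quality)),
            class = "fib_relaxation")
}

#' @export
print.fib_relaxation <- function(x, ...) {
  if (x$ok)
    cat(sprintf("Contact relaxation: tau = %.3f ns (window %.2f ns, RMS log-residual %.3f)\n",
                x$tau, x$fit_window[2], x$fit_quality))
  else
    cat("Contact relaxation: fit rejected (non-exponential or degenerate decay)\n")
  invisible(x)
}
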