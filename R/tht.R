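# Thioflavin T aggregation kinetics: logistic fitting with residual-bootstrap
# uncertainties and dose-response summaries across ligand ratios.

#' Assemble a ThT kinetics dataset
#'
#' @param time time points in minutes, strictly increasing.
#' @param replicates numeric matrix (time x replicates) of fluorescence
#'   traces in arbitrary units, or a single trace.
#' @param condition label (e.g. `"1:5"`).
#' @param ratio numeric ligand:protein molar ratio for dose-response tables.
#' @return object of class `fib_tht_data`.
#' @export
tht_dataset <- function(time, replicates, condition = "", ratio = NA_real_) {
  if (any(diff(time) <= 0))
    .fib_err("time vector must be strictly increasing", "fibmod_input_error")
  replicates <- as.matrix(replicates)
  if (nrow(replicates) != length(time))
    .fib_err("traces must have one row per time point", "fibmod_input_error")
  structure(list(time = as.numeric(time), replicates = replicates,
                 condition = condition, ratio = as.numeric(ratio)),
            class = "fib_tht_data")
}

#' Read plate-reader kinetics from long-format CSV
#'
#' Expects columns `time_min, value, replicate, condition` and optionally
#' `ratio`; returns one [tht_dataset()] per condition.
#'
#' @param file CSV path.
#' @return named list of `fib_tht_data`.
#' @export
read_tht_csv <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("time_min", "value", "replicate", "condition")
  if (!all(need %in% names(tab)))
    .fib_err("kinetics CSV needs columns time_min, value, replicate, condition",
             "fibmod_format_error")
  out <- lapply(split(tab, tab$condition), function(sub) {
    reps <- split(sub, sub$replicate)
    time <- sort(unique(sub$time_min))
    mat <- vapply(reps, function(r)
      r$value[match(time, r$time_min)], numeric(length(time)))
    ratio <- if ("ratio" %in% names(sub)) sub$ratio[1L] else NA_real_
    tht_dataset(time, mat, condition = sub$condition[1L], ratio = ratio)
  })
  out[order(vapply(out, function(d) d$ratio, numeric(1)))]
}

# logistic growth model: baseline F0 rising to plateau Fmax with apparent
# rate k and half-time t_half
.logistic <- function(t, F0, Fmax, k, t_half)
  F0 + (Fmax - F0) / (1 + exp(-k * (t - t_half)))

# deterministic starting values: baseline/plateau from the trace extremes,
# t_half from the half-rise crossing, k from the 10-90% rise width
.logistic_start <- function(time, y) {
  F0 <- min(y); Fmax <- max(y)
  lvl <- function(q) {
    target <- F0 + q * (Fmax - F0)
    idx <- which(y >= target)[1L]
    if (is.na(idx) || idx == 1L) return(time[1L])
    stats::approx(y[(idx - 1L):idx], time[(idx - 1L):idx], xout = target,
                  ties = "ordered")$y
  }
  t10 <- lvl(0.1); t50 <- lvl(0.5); t90 <- lvl(0.9)
  k <- if (t90 > t10) 4 / (t90 - t10) else 4 / diff(range(time))
  list(F0 = F0, Fmax = Fmax, k = k, t_half = t50)
}

.fit_logistic_once <- function(time, y, start, lower, upper) {
  df <- data.frame(t = time, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ F0 + (Fmax - F0) / (1 + exp(-k * (t - t_half))),
                      data = df, start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.list(stats::coef(fit))
}

#' Fit a logistic growth model to ThT aggregation kinetics
#'
#' Replicates are averaged into a mean trace (with SEM) and fitted to
#' `F(t) = F0 + (Fmax - F0) / (1 + exp(-k (t - t_half)))` by bounded
#' nonlinear least squares.  The lag time is derived by the standard
#' tangent-intersection identity `lag = t_half - 2/k`.  Parameter
#' uncertainties are 2.5/97.5 bootstrap percentiles from seeded residual
#' resampling on the mean trace (`bootstrap = "replicates"` instead resamples
#' replicate traces).  Traces whose total rise stays below
#' `no_agg_sd_mult` times the baseline noise SD are flagged
#' `no_aggregation` and left unfitted, mirroring conditions where
#' aggregation is fully suppressed.
#'
#' @param dataset a [tht_dataset()] (at least 8 time points).
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param bootstrap `"residual"` (default) or `"replicates"`.
#' @param no_agg_sd_mult rise threshold in baseline-noise SD units.
#' @return object of class `tht_fit`: coefficients (`F0, Fmax, k, t_half`),
#'   `lag`, `ci` (data.frame of percentile intervals), `fit_flag`
#'   (`"ok"`, `"no_aggregation"` or `"poor_fit"`), the mean trace, fitted
#'   values and residuals.
#' @examples
#' t <- seq(0, 700, by = 7)
#' y <- 0.1 + 0.9 / (1 + exp(-0.05 * (t - 300)))
#' fit <- fit_logistic(tht_dataset(t, y), n_boot = 50, seed = 1)
#' coef(fit); fit$lag  # 300 - 2/0.05 = 260 min
#' @export
fit_logistic <- function(dataset, n_boot = 1000L, seed = 1L,
                         bootstrap = c("residual", "replicates"),
                         no_agg_sd_mult = 5) {
  bootstrap <- match.arg(bootstrap)
  stopifnot(inherits(dataset, "fib_tht_data"))
  time <- dataset$time
  if (length(time) < 8L)
    .fib_err("at least 8 time points required", "fibmod_input_error")
  reps <- dataset$replicates
  y <- rowMeans(reps)
  sem <- if (ncol(reps) > 1L) apply(reps, 1, stats::sd) / sqrt(ncol(reps))
         else rep(NA_real_, length(y))
  blank <- function(flag) structure(
    list(coefficients = c(F0 = NA_real_, Fmax = NA_real_, k = NA_real_,
                          t_half = NA_real_),
         lag = NA_real_, ci = NULL, fit_flag = flag, n_boot = n_boot,
         seed = seed, time = time, mean_trace = y, sem = sem,
         fitted = rep(NA_real_, length(y)),
         residuals = rep(NA_real_, length(y)),
         condition = dataset$condition, ratio = dataset$ratio),
    class = "tht_fit")

  # high-frequency noise estimate, robust to the sigmoidal trend; the rise is
  # measured on a lightly smoothed trace so pure noise cannot fake a signal
  noise_sd <- stats::sd(diff(y)) / sqrt(2)
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  rise <- diff(range(ys, na.rm = TRUE))
  if (!is.finite(noise_sd)) noise_sd <- 0
  if (noise_sd > 0 && rise < no_agg_sd_mult * noise_sd)
    return(blank("no_aggregation"))

  start <- .logistic_start(time, y)
  tspan <- diff(range(time))
  lower <- c(F0 = -Inf, Fmax = -Inf, k = 1e-8,
             t_half = min(time) - 0.5 * tspan)
  upper <- c(F0 = Inf, Fmax = Inf, k = Inf,
             t_half = max(time) + 0.5 * tspan)
  co <- .fit_logistic_once(time, y, start, lower, upper)
  if (is.null(co) || co$Fmax < co$F0) return(blank("poor_fit"))
  fitted <- .logistic(time, co$F0, co$Fmax, co$k, co$t_half)
  resid <- y - fitted

  ci <- NULL
  if (n_boot > 0L) {
    set.seed(seed)
    boot <- matrix(NA_real_, n_boot, 5L,
                   dimnames = list(NULL, c("F0", "Fmax", "k", "t_half", "lag")))
    for (b in seq_len(n_boot)) {
      yb <- if (bootstrap == "residual")
        fitted + sample(resid, replace = TRUE)
      else
        rowMeans(reps[, sample(ncol(reps), replace = TRUE), drop = FALSE])
      cb <- .fit_logistic_once(time, yb, co, lower, upper)
      if (!is.null(cb))
        boot[b, ] <- c(cb$F0, cb$Fmax, cb$k, cb$t_half,
                       cb$t_half - 2 / cb$k)
    }
    boot <- boot[stats::complete.cases(boot), , drop = FALSE]
    if (nrow(boot) >= 10L) {
      qs <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
      ci <- data.frame(parameter = colnames(boot),
                       lower = qs[1L, ], upper = qs[2L, ],
                       row.names = NULL)
    }
  }
  structure(list(coefficients = c(F0 = co$F0, Fmax = co$Fmax, k = co$k,
                                  t_half = co$t_half),
                 lag = co$t_half - 2 / co$k, ci = ci, fit_flag = "ok",
                 n_boot = n_boot, seed = seed, time = time, mean_trace = y,
                 sem = sem, fitted = fitted, residuals = resid,
                 condition = dataset$condition, ratio = dataset$ratio),
            class = "tht_fit")
}

#' @export
print.tht_fit <- function(x, ...) {
  if (x$fit_flag != "ok") {
    cat("ThT logistic fit [", x$condition, "]: ", x$fit_flag, "\n", sep = "")
    return(invisible(x))
  }
  co <- x$coefficients
  cat(sprintf("ThT logistic fit [%s]: F0 = %.3g, Fmax = %.3g, k = %.4g /min, t_half = %.4g min, lag = %.4g min\n",
              x$condition, co["F0"], co["Fmax"], co["k"], co["t_half"], x$lag))
  invisible(x)
}

#' @export
summary.tht_fit <- function(object, ...) {
  out <- list(coefficients = object$coefficients, lag = object$lag,
              ci = object$ci, fit_flag = object$fit_flag,
              condition = object$condition, n_boot = object$n_boot,
              rms_residual = sqrt(mean(object$residuals^2)))
  class(out) <- "summary.tht_fit"
  out
}

#' @export
print.summary.tht_fit <- function(x, ...) {
  cat("ThT logistic fit [", x$condition, "] - ", x$fit_flag, "\n", sep = "")
  if (x$fit_flag == "ok") {
    est <- c(x$coefficients, lag = x$lag)
    tab <- data.frame(estimate = est)
    if (!is.null(x$ci)) {
      tab$ci_2.5 <- x$ci$lower[match(rownames(tab), x$ci$parameter)]
      tab$ci_97.5 <- x$ci$upper[match(rownames(tab), x$ci$parameter)]
    }
    print(signif(as.matrix(tab), 5))
    cat(sprintf("RMS residual: %.4g (%d bootstrap resamples)\n",
                x$rms_residual, x$n_boot))
  }
  invisible(x)
}

#' @export
coef.tht_fit <- function(object, ...) object$coefficients

#' @export
residuals.tht_fit <- function(object, ...) object$residuals

#' @export
predict.tht_fit <- function(object, newdata = NULL, ...) {
  if (object$fit_flag != "ok")
    .fib_err("no parameters available (fit not ok)", "fibmod_input_error")
  t <- if (is.null(newdata)) object$time
       else if (is.list(newdata)) newdata$time else newdata
  co <- object$coefficients
  .logistic(t, co["F0"], co["Fmax"], co["k"], co["t_half"])
}

#' @export
plot.tht_fit <- function(x, ...) {
  plot(x$time, x$mean_trace, pch = 16, cex = 0.5,
       xlab = "time (min)", ylab = "ThT fluorescence (a.u.)",
       main = paste("ThT kinetics", x$condition), ...)
  if (x$fit_flag == "ok") {
    graphics::lines(x$time, x$fitted, col = "#d62728", lwd = 2)
    graphics::abline(v = c(x$lag, x$coefficients["t_half"]), lty = 3)
  }
  invisible(x)
}

#' @export
simulate.tht_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$fit_flag != "ok")
    .fib_err("no parameters available (fit not ok)", "fibmod_input_error")
  if (!is.null(seed)) set.seed(seed)
  sd <- stats::sd(object$residuals)
  out <- replicate(nsim, object$fitted + stats::rnorm(length(object$fitted),
                                                      0, sd))
  as.data.frame(out)
}

#' Dose-response summary across ligand ratios
#'
#' @param fits list of [fit_logistic()] results.
#' @return data.frame with one row per condition: ratio, F_max, t_half, lag,
#'   k and their bootstrap CIs, plus the fit flag (conditions without
#'   aggregation appear flagged, with `NA` parameters).
#' @export
dose_response_summary <- function(fits) {
  if (!length(fits))
    .fib_err("at least one fit required", "fibmod_input_error")
  getci <- function(f, par, side) {
    if (is.null(f$ci)) return(NA_real_)
    f$ci[[side]][match(par, f$ci$parameter)]
  }
  out <- do.call(rbind, lapply(fits, function(f) {
    co <- f$coefficients
    data.frame(condition = f$condition, ratio = f$ratio,
               fit_flag = f$fit_flag,
               Fmax = co[["Fmax"]],
               Fmax_lo = getci(f, "Fmax", "lower"),
               Fmax_hi = getci(f, "Fmax", "upper"),
               t_half = co[["t_half"]],
               t_half_lo = getci(f, "t_half", "lower"),
               t_half_hi = getci(f, "t_half", "upper"),
               lag = f$lag,
               lag_lo = getci(f, "lag", "lower"),
               lag_hi = getci(f, "lag", "upper"),
               k = co[["k"]],
               k_lo = getci(f, "k", "lower"),
               k_hi = getci(f, "k", "upper"))
  }))
  rownames(out) <- NULL
  out[order(out$ratio), , drop = FALSE]
}

#' Write ThT datasets as long-format CSV
#'
#' Inverse of [read_tht_csv()]: columns `time_min, value, replicate,
#' condition, ratio`.
#'
#' @param datasets a [tht_dataset()] or list of them.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tht_csv <- function(datasets, file) {
  if (inherits(datasets, "fib_tht_data")) datasets <- list(datasets)
  out <- do.call(rbind, lapply(datasets, function(d) {
    do.call(rbind, lapply(seq_len(ncol(d$replicates)), function(r)
      data.frame(time_min = d$time, value = d$replicates[, r],
                 replicate = r, condition = d$condition, ratio = d$ratio)))
  }))
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
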