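# Device-performance and growth metrics from plate-reader curves:
# Hill induction fits, steady-state fluorescence, rolling-regression
# maximum specific rates, Gompertz-with-lag growth fits, dynamic ranges.

#' Construct an induction curve
#'
#' Per-concentration replicate measurements of OD-normalized steady-state
#' fluorescence (Fss) for one host and one inducer.
#'
#' @param inducer "Ara" (mM) or "aTc" (nM).
#' @param concentrations non-negative inducer concentrations, one per
#'   observation. Must include zero-inducer wells (the empirical baseline)
#'   and at least 4 distinct concentrations.
#' @param fss Fss values (RFU), same length.
#' @param replicate optional replicate index per observation.
#' @param host optional host label.
#' @return object of class `induction_curve`.
#' @export
induction_curve <- function(inducer, concentrations, fss,
                            replicate = NULL, host = NULL) {
  stop_if_not(length(concentrations) == length(fss),
              "concentrations and fss must have equal length")
  stop_if_not(all(concentrations >= 0), "negative inducer concentration")
  stop_if_not(length(unique(concentrations)) >= 4,
              "need >= 4 distinct concentrations")
  stop_if_not(any(concentrations == 0), "zero-inducer wells required")
  structure(list(inducer = inducer, concentrations = concentrations,
                 fss = fss, replicate = replicate, host = host),
            class = "induction_curve")
}

#' Steady-state fluorescence over a late-growth window
#'
#' Arithmetic mean of an OD-normalized fluorescence (or OD) series over a
#' time window, default 6-12 h, the late growth phase.
#'
#' @param time time points (h), strictly increasing.
#' @param value series values.
#' @param window numeric pair `c(t0, t1)` in hours.
#' @return the mean value over the window.
#' @export
steady_state_fss <- function(time, value, window = c(6, 12)) {
  stop_if_not(length(time) == length(value), "time/value length mismatch")
  idx <- time >= window[1] & time <= window[2]
  stop_if_not(sum(idx) >= 2,
              "window contains fewer than 2 samples of the curve")
  mean(value[idx])
}

#' Fit the Hill induction model to an induction curve
#'
#' Fits `Fss = beta * x^n / (K^n + x^n) + C` by non-linear least squares
#' on per-concentration replicate means. The baseline `C` is not fitted:
#' it is fixed to the empirical mean Fss of the zero-inducer wells.
#' `beta`, `K` and `n` are estimated with multi-start
#' Levenberg-Marquardt (starts: `K` at the geometric median of the
#' positive concentrations, `n` in {0.5, 1, 2, 4}) under positivity
#' bounds; the best converged start by residual sum of squares wins.
#'
#' @param curve an [induction_curve()].
#' @return object of class `hill_fit`: list with beta, K, n, C, DR
#'   (= beta / C), rss, converged, and the fitted means.
#' @export
#' @examples
#' x <- rep(c(0, 2^(0:6)), each = 3)
#' y <- hill_response(x, beta = 1000, K = 10, n = 2, C = 50)
#' fit <- fit_hill(induction_curve("aTc", x, y))
#' unlist(fit[c("beta", "K", "n", "C")])
fit_hill <- function(curve) {
  stop_if_not(inherits(curve, "induction_curve"),
              "curve must be an induction_curve")
  x_all <- curve$concentrations
  C <- mean(curve$fss[x_all == 0])
  pos <- x_all > 0
  means <- tapply(curve$fss[pos], x_all[pos], mean)
  x <- as.numeric(names(means))
  y <- as.numeric(means) - C

  k0 <- exp(stats::median(log(x)))
  beta0 <- max(max(y), 1e-6)
  # K is only identifiable near the tested range; bounding it one decade
  # beyond the grid keeps saturated or unresponsive curves from running
  # to a degenerate optimum
  k_lo <- min(x) / 10
  k_hi <- max(x) * 10
  best <- NULL
  for (n0 in c(0.5, 1, 2, 4)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ beta * x^n / (K^n + x^n),
        start = list(beta = beta0, K = k0, n = n0),
        lower = c(beta = 0, K = k_lo, n = 1e-3),
        upper = c(beta = Inf, K = k_hi, n = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) {
    out <- list(beta = NA_real_, K = NA_real_, n = NA_real_, C = C,
                DR = NA_real_, rss = NA_real_, converged = FALSE,
                inducer = curve$inducer, host = curve$host)
  } else {
    cf <- best$coef
    out <- list(beta = unname(cf["beta"]), K = unname(cf["K"]),
                n = unname(cf["n"]), C = C,
                DR = if (C > 0) unname(cf["beta"]) / C else NA_real_,
                rss = best$rss, converged = TRUE,
                inducer = curve$inducer, host = curve$host)
  }
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit (%s%s): beta=%.4g K=%.4g n=%.3g C=%.4g DR=%.3g %s\n",
    x$inducer %||% "?", if (!is.null(x$host)) paste0(", ", x$host) else "",
    x$beta, x$K, x$n, x$C, x$DR,
    if (isTRUE(x$converged)) "" else "[not converged]"))
  invisible(x)
}

#' Dynamic range of an induction fit
#'
#' The ratio of the fitted maximal output `beta` to the empirical baseline
#' `C`, expressed as a fold-change value: the largest fold-change
#' measurable from the reporter.
#'
#' @param fit a [fit_hill()] result (or any list with beta and C).
#' @return `beta / C`; NA with a warning when `C <= 0`.
#' @export
dynamic_range <- function(fit) {
  if (is.na(fit$C) || fit$C <= 0) {
    warning("dynamic range undefined: baseline C <= 0")
    return(NA_real_)
  }
  fit$beta / fit$C
}

# max OLS slope of value vs time over h-point windows (raw scale)
max_window_slope <- function(time, value, h = 5L) {
  n <- length(time)
  if (n < h) return(NA_real_)
  best <- -Inf
  for (i in seq_len(n - h + 1L)) {
    idx <- i:(i + h - 1L)
    tt <- time[idx]; v <- value[idx]
    s <- sum((tt - mean(tt)) * (v - mean(v))) / sum((tt - mean(tt))^2)
    if (is.finite(s) && s > best) best <- s
  }
  best
}

#' Maximum specific rate by rolling log-linear regression
#'
#' Slides a window of `h` consecutive points along the curve, fits
#' ordinary least squares of `ln(value)` versus time in each window, and
#' returns the maximum slope among windows whose fit passes a minimum-R2
#' filter. This is the standard estimator of the maximum specific growth
#' (or fluorescence accumulation) rate.
#'
#' @param time time points (h), strictly increasing.
#' @param value positive series values.
#' @param h window size in points (default 5).
#' @param r2_min minimum within-window R2 (default 0.95). Exactly
#'   constant windows (zero variance, zero residuals) count as R2 = 1.
#' @return list with `mu` (max slope, 1/h; NA if no window passes),
#'   `window_start` (time of the winning window), `r2` of the winning
#'   window, and `ok` flag.
#' @export
rolling_max_rate <- function(time, value, h = 5L, r2_min = 0.95) {
  n <- length(time)
  stop_if_not(n >= h, "curve has fewer points than the window size")
  stop_if_not(any(value > 0), "no positive values in curve")
  best_mu <- -Inf
  best <- list(mu = NA_real_, window_start = NA_real_, r2 = NA_real_,
               ok = FALSE)
  for (i in seq_len(n - h + 1L)) {
    idx <- i:(i + h - 1L)
    v <- value[idx]
    if (any(v <= 0)) next
    tt <- time[idx]
    ly <- log(v)
    tm <- mean(tt); lm_ <- mean(ly)
    sxx <- sum((tt - tm)^2)
    sxy <- sum((tt - tm) * (ly - lm_))
    slope <- sxy / sxx
    sst <- sum((ly - lm_)^2)
    ssr <- sst - sxy^2 / sxx
    r2 <- if (sst < 1e-18) {
      if (ssr < 1e-18) 1 else 0
    } else 1 - ssr / sst
    if (r2 >= r2_min && slope > best_mu) {
      best_mu <- slope
      best <- list(mu = slope, window_start = tt[1], r2 = r2, ok = TRUE)
    }
  }
  best
}

#' Fit the modified Gompertz growth model with lag
#'
#' Least-squares fit of the Zwietering form
#' `y(t) = y0 + A * exp(-exp((mu * e / A) * (lambda - t) + 1))` with
#' multi-start Levenberg-Marquardt. Starting values come from the data
#' extremes (y0, A) and from the maximum raw-window slope (mu); several
#' lag starts are tried.
#'
#' `mu` is the maximum slope of the fitted curve itself. For OD600 or
#' fluorescence data, pass the curve on the natural-log scale
#' (`log(value)`): `mu` is then the maximum *specific* rate and agrees
#' with [rolling_max_rate()] applied to the raw curve, and `A` is the
#' log-fold plateau (carrying capacity in log units).
#'
#' @param time time points (h).
#' @param value curve values (log OD600 or log normalized fluorescence
#'   for specific-rate semantics; any sigmoid curve works).
#' @return object of class `gompertz_fit`: list with A, mu, lambda, y0,
#'   rss, converged.
#' @export
#' @examples
#' t <- seq(0, 24, by = 0.25)
#' y <- gompertz_response(t, A = 1.2, mu = 0.4, lambda = 3, y0 = 0.05)
#' fit <- fit_gompertz_lag(t, y)
#' unlist(fit[c("A", "mu", "lambda")])
fit_gompertz_lag <- function(time, value) {
  stop_if_not(length(time) == length(value), "time/value length mismatch")
  if (min(value) > 0) {
    stop_if_not(max(value) > 2 * min(value),
                "curve must span lag and plateau phases")
  } else {
    stop_if_not(diff(range(value)) > log(2),
                "curve must span lag and plateau phases")
  }
  y0_0 <- min(value)
  A0 <- max(value) - min(value)
  # max slope of the raw curve from 5-point OLS windows seeds mu
  mu0 <- max_window_slope(time, value, h = 5L)
  if (!is.finite(mu0) || mu0 <= 0) mu0 <- A0 / diff(range(time)) * 4
  tspan <- diff(range(time))
  best <- NULL
  for (lam0 in c(0, tspan / 8, tspan / 4, tspan / 2)) {
    for (mu_try in unique(c(mu0, A0 / tspan * 4))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          value ~ y0 + A * exp(-exp((mu * exp(1) / A) * (lambda - time) + 1)),
          start = list(y0 = y0_0, A = A0, mu = mu_try, lambda = lam0),
          lower = c(y0 = -Inf, A = 1e-12, mu = 1e-9, lambda = 0),
          control = minpack.lm::nls.lm.control(maxiter = 300)
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(coef = stats::coef(fit), rss = rss)
      }
    }
  }
  if (is.null(best)) {
    out <- list(A = NA_real_, mu = NA_real_, lambda = NA_real_,
                y0 = NA_real_, rss = NA_real_, converged = FALSE)
  } else {
    cf <- best$coef
    out <- list(A = unname(cf["A"]), mu = unname(cf["mu"]),
                lambda = unname(cf["lambda"]), y0 = unname(cf["y0"]),
                rss = best$rss, converged = TRUE)
  }
  class(out) <- "gompertz_fit"
  out
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("Gompertz fit: A=%.4g mu=%.4g/h lambda=%.3g h %s\n",
              x$A, x$mu, x$lambda,
              if (isTRUE(x$converged)) "" else "[not converged]"))
  invisible(x)
}

#' Relative percentage change in maximum specific growth rate
#'
#' `delta_mu = ((mu_1 - mu_2) / mu_1) * 100`. Positive values mean
#' condition 2 grows slower than condition 1 (growth inhibition); negative
#' values mean a growth increase.
#'
#' @param mu_1 reference maximum specific growth rate (> 0).
#' @param mu_2 comparison rate.
#' @return percentage change.
#' @export
delta_mu <- function(mu_1, mu_2) {
  stop_if_not(all(mu_1 > 0), "mu_1 must be positive")
  (mu_1 - mu_2) / mu_1 * 100
}

#' Specific dynamic range
#'
#' Induced-state steady-state fluorescence relative to the same host and
#' channel's non-induced (NI) baseline. Values below 1 mean the induced
#' output dropped under the baseline (e.g. hysteresis-attenuated output
#' after toggling).
#'
#' @param fss_induced induced-state Fss.
#' @param fss_baseline NI-state Fss of the same host x channel (> 0).
#' @return `fss_induced / fss_baseline`; NA with a warning if the baseline
#'   is not positive.
#' @export
specific_dynamic_range <- function(fss_induced, fss_baseline) {
  if (any(fss_baseline <= 0)) {
    warning("specific dynamic range undefined: baseline <= 0")
    return(rep(NA_real_, length(fss_induced)))
  }
  fss_induced / fss_baseline
}

#' Toggle-assay fluorescence metrics per host, channel and state
#'
#' From long-format fluorescence curves, computes for every host x channel
#' x induction state: Fss (window mean, [steady_state_fss()]), Rate
#' ([rolling_max_rate()]), Lag (lambda of [fit_gompertz_lag()]) and DR_S
#' ([specific_dynamic_range()] against the same host x channel NI state).
#'
#' @param fluorescence data.frame with columns host, condition, channel,
#'   time_h, value.
#' @param window Fss window (default `c(6, 12)` h).
#' @param h,r2_min rolling-regression controls.
#' @return data.frame: host, channel, condition, Fss, Rate, Lag, DR_S.
#' @export
toggle_metrics <- function(fluorescence, window = c(6, 12), h = 5L,
                           r2_min = 0.95) {
  keys <- unique(fluorescence[, c("host", "channel", "condition")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- fluorescence[fluorescence$host == k$host &
                          fluorescence$channel == k$channel &
                          fluorescence$condition == k$condition, ]
    sub <- sub[order(sub$time_h), ]
    fss <- steady_state_fss(sub$time_h, sub$value, window)
    rate <- rolling_max_rate(sub$time_h, sub$value, h, r2_min)$mu
    lag <- tryCatch(fit_gompertz_lag(sub$time_h, log(sub$value))$lambda,
                    error = function(e) NA_real_)
    data.frame(host = k$host, channel = k$channel, condition = k$condition,
               Fss = fss, Rate = rate, Lag = lag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  ni <- out[out$condition == "NI", c("host", "channel", "Fss")]
  names(ni)[3] <- "Fss_NI"
  out <- merge(out, ni, by = c("host", "channel"), sort = FALSE)
  out$DR_S <- specific_dynamic_range(out$Fss, out$Fss_NI)
  out$Fss_NI <- NULL
  out[order(out$host, out$channel, out$condition), ]
}

#' Assemble a hosts x metrics device-performance matrix
#'
#' Fits the Hill model to every host's induction curves (both inducers)
#' and the Gompertz model to every host's growth curves, and assembles a
#' performance-metric panel. The "report" panel carries, per inducer,
#' log K, log beta, n, log C and log DR, plus log mu, log A and lambda
#' for every growth condition -- the full metric table a practitioner
#' would inspect. The "ordination" panel, meant as input to
#' [pca_project()], is non-redundant and entirely on the log scale: the
#' eight Hill parameters (log K, log beta, log n, log C per inducer) and
#' the non-induced growth parameters (log mu, log A, log lambda). It
#' excludes derived metrics (DR is beta over C) and repeated induction
#' conditions so that no direction of host-to-host variation is counted
#' twice, and one unit of log-fold variation is comparable across all
#' features.
#'
#' @param induction named list of [induction_curve()] objects
#'   (`host.inducer` names as produced by [simulate_curves()]).
#' @param growth long data.frame: host, condition, time_h, value.
#' @param panel "report" (default) or "ordination".
#' @return numeric matrix, hosts x metrics.
#' @export
performance_matrix <- function(induction, growth,
                               panel = c("report", "ordination")) {
  panel <- match.arg(panel)
  hosts <- sort(unique(vapply(induction, function(cv) cv$host, "")))
  conds <- if (panel == "ordination") "NI" else unique(growth$condition)
  conds <- intersect(conds, unique(growth$condition))
  rows <- lapply(hosts, function(hh) {
    vals <- c()
    for (ind in c("Ara", "aTc")) {
      fit <- fit_hill(induction[[paste(hh, ind, sep = ".")]])
      vals <- c(vals, if (panel == "ordination") {
        stats::setNames(
          c(log(fit$K), log(fit$beta), log(fit$n), log(fit$C)),
          paste0(c("logK_", "logbeta_", "logn_", "logC_"), ind))
      } else {
        stats::setNames(
          c(log(fit$K), log(fit$beta), fit$n, log(fit$C), log(fit$DR)),
          paste0(c("logK_", "logbeta_", "n_", "logC_", "logDR_"), ind))
      })
    }
    for (cond in conds) {
      sub <- growth[growth$host == hh & growth$condition == cond, ]
      sub <- sub[order(sub$time_h), ]
      gf <- fit_gompertz_lag(sub$time_h, log(sub$value))
      vals <- c(vals, if (panel == "ordination") {
        stats::setNames(c(log(gf$mu), log(gf$A), log(max(gf$lambda,
                                                         1e-3))),
                        paste0(c("logmu_", "logA_", "loglambda_"), cond))
      } else {
        stats::setNames(c(log(gf$mu), log(gf$A), gf$lambda),
                        paste0(c("logmu_", "logA_", "lambda_"), cond))
      })
    }
    vals
  })
  out <- do.call(rbind, rows)
  rownames(out) <- hosts
  out
}
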