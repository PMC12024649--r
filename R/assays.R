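# Plate-reader kinetics: background correction, growth-segment extraction,
# growth rates, Miller-assay activity, promoter activity, and the
# sliding-window expression estimate.

#' Plate time series container
#'
#' One well's kinetics: time (h), OD600 and a reporter channel (OD420 for
#' the Miller assay, or fluorescence).
#'
#' @param time hours, strictly increasing
#' @param od600 optical density
#' @param signal reporter channel (same length)
#' @param meta named list of well metadata (strain, media, tmg_uM,
#'   replicate, ...)
#' @return an object of class `plate_series`
#' @export
plate_series <- function(time, od600, signal, meta = list()) {
  stopifnot(length(time) == length(od600), length(time) == length(signal),
            !is.unsorted(time, strictly = TRUE))
  structure(list(time = time, od600 = od600, signal = signal, meta = meta),
            class = "plate_series")
}

#' @export
print.plate_series <- function(x, ...) {
  cat(sprintf("plate series: %d points over %.2f h; OD %.3g-%.3g\n",
              length(x$time), diff(range(x$time)), min(x$od600), max(x$od600)))
  invisible(x)
}

window_mean_at_min <- function(v, w = 20) {
  n <- length(v)
  i <- which.min(v)
  start <- i - (w %/% 2 - 1)              # w-point window centred on the minimum
  start <- max(1, min(start, n - w + 1))
  mean(v[start:(start + w - 1)])
}

#' Background-correct a plate series
#'
#' Estimates the background of each channel as the mean over a `w`-point
#' window centred on that channel's minimum observation (window clipped at
#' the series edges) and subtracts it channelwise.
#'
#' @param series a [plate_series()]
#' @param w window length (points)
#' @return the corrected `plate_series`
#' @export
background_correct <- function(series, w = 20) {
  if (length(series$time) < w)
    stop(sprintf("need at least %d time points", w))
  series$od600 <- series$od600 - window_mean_at_min(series$od600, w)
  series$signal <- series$signal - window_mean_at_min(series$signal, w)
  series
}

#' Identify the exponential growth segment of a plate series
#'
#' Looking backward from the time point of maximum background-corrected OD,
#' takes the maximal contiguous run of points with OD below OD_max/3, OD
#' above `od_floor`, and positive reporter signal. Measurement noise makes
#' the OD flicker around the OD_max/3 boundary, so the *longest* qualifying
#' run before the peak is used (ties resolved towards the peak) rather than
#' the run immediately adjacent to it. Segments shorter than `min_points`
#' are rejected.
#'
#' @param series a background-corrected [plate_series()]
#' @param od_floor minimum usable OD (default 0.01)
#' @param min_points minimum segment length (default 21)
#' @return a list with `ok` (logical); when `ok`, integer `start`/`end`
#'   indices (inclusive); otherwise a `reason` string
#' @export
find_growth_segment <- function(series, od_floor = 0.01, min_points = 21) {
  od <- series$od600; sig <- series$signal
  i_max <- which.max(od)
  od_cap <- od[i_max] / 3
  pre <- seq_len(i_max)
  valid <- od[pre] < od_cap & od[pre] > od_floor & sig[pre] > 0
  if (!any(valid)) return(list(ok = FALSE, reason = "no qualifying points"))
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[order(-r$lengths[runs], -ends[runs])][1]
  lo <- starts[best]; hi <- ends[best]
  if (hi - lo + 1 < min_points)
    return(list(ok = FALSE,
                reason = sprintf("segment of %d points is below the %d-point minimum",
                                 hi - lo + 1, min_points)))
  list(ok = TRUE, start = lo, end = hi)
}

#' Growth rate of a segment
#'
#' OLS slope of log2(OD) against time (h) over the segment: the doubling
#' rate in doublings/hour, with its standard error.
#'
#' @param series a [plate_series()]
#' @param segment a segment from [find_growth_segment()]
#' @return list with `lam_dbl` (doublings/h), `lam_se`
#' @export
growth_rate_of_segment <- function(series, segment) {
  stopifnot(isTRUE(segment$ok))
  idx <- segment$start:segment$end
  od <- series$od600[idx]
  if (any(od <= 0)) stop("non-positive OD inside growth segment")
  fit <- stats::lm(log2(od) ~ series$time[idx])
  s <- summary(fit)$coefficients
  list(lam_dbl = unname(s[2, 1]), lam_se = unname(s[2, 2]))
}

#' Miller-assay beta-galactosidase activity
#'
#' Computes the activity A = 1000 s / (0.5 OD600) where s is the initial
#' OD420 slope per minute over the first 30 minutes of usable kinetics. At
#' low enzyme concentrations the OD420 sometimes starts by decreasing for up
#' to one hour; that initial decreasing phase (up to the first local
#' minimum within the first hour) is discarded before taking the slope.
#'
#' @param time_h assay times (h), strictly increasing, spanning >= 30 min of
#'   usable kinetics
#' @param od420 OD420 readings
#' @param od600_sample OD600 of the assayed culture sample (1-cm path
#'   equivalent)
#' @return activity in Miller units
#' @export
miller_activity <- function(time_h, od420, od600_sample) {
  stopifnot(length(time_h) == length(od420), od600_sample > 0,
            !is.unsorted(time_h, strictly = TRUE))
  start <- 1
  if (length(od420) > 2 && od420[2] < od420[1]) {
    in_hour <- which(time_h - time_h[1] <= 1)
    d <- diff(od420[in_hour])
    rise <- which(d > 0)
    if (!length(rise))
      stop("OD420 still decreasing after 1 h: no usable kinetics window")
    start <- rise[1]                       # first local minimum within 1 h
  }
  tt <- time_h[start:length(time_h)] - time_h[start]
  vv <- od420[start:length(od420)]
  use <- tt <= 0.5 + 1e-9                  # first 30 min
  if (sum(use) < 3 || max(tt[use]) < 0.5 - 1e-9)
    stop("need at least 30 min of OD420 kinetics after the initial decline")
  slope_per_h <- unname(stats::coef(stats::lm(vv[use] ~ tt[use]))[2])
  s <- slope_per_h / 60                    # per-minute slope, Miller convention
  1000 * s / (0.5 * od600_sample)
}

#' Promoter activity from Miller activity and growth rate
#'
#' For a stable enzyme in balanced exponential growth, turnover is set by
#' dilution, so the promoter activity is alpha = A * lambda with lambda the
#' doubling rate (doublings/hour).
#'
#' @param A Miller-unit activity
#' @param lam_dbl doubling rate (doublings/hour), > 0
#' @return promoter activity (Miller units x doublings/hour)
#' @export
promoter_activity <- function(A, lam_dbl) {
  if (any(lam_dbl <= 0)) stop("growth rate must be positive")
  A * lam_dbl
}

#' Sliding-window expression and growth estimate
#'
#' Moves a window of length `w` across the growth segment; in each window
#' fits log OD and log signal against time, extracting the window's
#' expression log-ratio y = mean(log signal - log OD) and doubling rate.
#' Windows are combined by inverse-variance weighting into a single (y,
#' lambda) pair with standard errors. Overlapping windows are correlated, so
#' the combined SEs are indicative rather than exact; they are used as
#' relative weights downstream.
#'
#' @param series a background-corrected [plate_series()]
#' @param segment a segment from [find_growth_segment()]
#' @param w window length (points, default 21)
#' @return list with `y_expr`, `y_se`, `lam_dbl`, `lam_se`, `n_windows`
#' @export
expression_sliding_windows <- function(series, segment, w = 21) {
  stopifnot(isTRUE(segment$ok))
  idx <- segment$start:segment$end
  if (length(idx) < w)
    stop(sprintf("segment of %d points is shorter than the window (%d)",
                 length(idx), w))
  tt <- series$time[idx]; od <- series$od600[idx]; sig <- series$signal[idx]
  if (any(od <= 0) || any(sig <= 0))
    stop("non-positive OD or signal inside growth segment")
  n_win <- length(idx) - w + 1
  y <- lam <- y_var <- lam_var <- numeric(n_win)
  for (j in seq_len(n_win)) {
    jj <- j:(j + w - 1)
    d <- log(sig[jj]) - log(od[jj])
    y[j] <- mean(d)
    y_var[j] <- stats::var(d) / w
    fit <- summary(stats::lm(log2(od[jj]) ~ tt[jj]))$coefficients
    lam[j] <- fit[2, 1]
    lam_var[j] <- fit[2, 2]^2
  }
  y_var <- pmax(y_var, 1e-12); lam_var <- pmax(lam_var, 1e-12)
  wy <- 1 / y_var; wl <- 1 / lam_var
  list(y_expr = sum(wy * y) / sum(wy), y_se = sqrt(1 / sum(wy)),
       lam_dbl = sum(wl * lam) / sum(wl), lam_se = sqrt(1 / sum(wl)),
       n_windows = n_win)
}

#' Process one well end to end
#'
#' Convenience wrapper: background-correct, find the growth segment, and
#' extract growth rate and expression. Returns `ok = FALSE` with the reject
#' reason when the well has no usable growth segment.
#'
#' @param series a raw [plate_series()]
#' @param w sliding-window length
#' @return list with `ok`, and when ok: `lam_dbl`, `lam_se`, `y_expr`,
#'   `y_se`, `activity` (= exp(y_expr) * lam_dbl), `segment`
#' @export
process_well <- function(series, w = 21) {
  bc <- background_correct(series)
  seg <- find_growth_segment(bc)
  if (!seg$ok) return(list(ok = FALSE, reason = seg$reason))
  est <- expression_sliding_windows(bc, seg, w)
  list(ok = TRUE, lam_dbl = est$lam_dbl, lam_se = est$lam_se,
       y_expr = est$y_expr, y_se = est$y_se,
       activity = exp(est$y_expr) * est$lam_dbl,
       activity_se = exp(est$y_expr) *
         sqrt(est$lam_dbl^2 * est$y_se^2 + est$lam_se^2),
       segment = seg)
}
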