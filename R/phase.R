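# Phase classification, bistability boundaries, critical curves.
#
# Classification counts stable fixed points on a dense sign-change scan
# (cheap; no bisection needed for counting), so phase diagrams and boundary
# bisection stay fast.

count_roots <- function(spec, signal, ctx, n_grid = 2000) {
  sc <- model_scales(spec, signal, ctx)
  xg <- exp(seq(log(sc$x_max * 1e-9), log(sc$x_max), length.out = n_grid))
  fv <- reduced_rhs(spec, xg, signal, ctx)
  s <- sign(fv)
  n <- sum(s[-1] * s[-length(s)] < 0)
  # boundary root at exactly zero (zero basal production)
  if (abs(reduced_rhs(spec, 0, signal, ctx)) < 1e-12 && fv[1] < 0) n <- n + 1
  n
}

#' Classify a switch state as off, on or bistable
#'
#' The system is `bistable` when the reduced equation has two stable fixed
#' points; otherwise the unique stable state is called `off` or `on`
#' according to whether it lies below or above the discriminating level
#' `x_mid`. The default `x_mid` is the geometric mean of the basal and
#' full-induction expression scales (falling back to the geometric mean of
#' the promoter half-max and the full scale when basal production is zero).
#'
#' @inheritParams reduced_rhs
#' @param x_mid off/on discriminating concentration for monostable states
#'   (uM); `NULL` for the model-derived default
#' @return one of `"off"`, `"on"`, `"bistable"`
#' @export
classify_state <- function(spec, signal = 0, ctx, x_mid = NULL) {
  n <- count_roots(spec, signal, ctx)
  if (n >= 3) return("bistable")
  fp <- find_fixed_points(spec, signal, ctx)
  st <- fp$x[fp$stable]
  if (length(st) >= 2) return("bistable")
  if (is.null(x_mid)) x_mid <- model_scales(spec, signal, ctx)$x_mid
  if (st[1] > x_mid) "on" else "off"
}

#' Phase diagram over doubling time and signal
#'
#' Classifies every cell of a (doubling time x signal) grid with
#' [classify_state()].
#'
#' @param spec a `switch_model`
#' @param t_axis doubling times (h), sorted ascending
#' @param s_axis signal levels, sorted ascending
#' @param delta molecular decay rate (h^-1); defaults to the model's
#'   [default_delta()]
#' @return an object of class `phase_grid`: list with `t_axis`, `s_axis` and
#'   a character `phase` matrix (rows = doubling times)
#' @export
phase_diagram <- function(spec, t_axis, s_axis, delta = default_delta(spec)) {
  stopifnot(all(t_axis > 0), all(s_axis >= 0),
            !is.unsorted(t_axis), !is.unsorted(s_axis))
  phase <- matrix(NA_character_, length(t_axis), length(s_axis),
                  dimnames = list(signif(t_axis, 6), signif(s_axis, 6)))
  for (i in seq_along(t_axis)) {
    ctx <- growth_context(doubling_time = t_axis[i], delta = delta)
    for (j in seq_along(s_axis))
      phase[i, j] <- classify_state(spec, s_axis[j], ctx)
  }
  structure(list(t_axis = t_axis, s_axis = s_axis, phase = phase),
            class = "phase_grid")
}

#' @export
print.phase_grid <- function(x, ...) {
  tab <- table(factor(x$phase, levels = c("off", "bistable", "on")))
  cat(sprintf("phase grid %d x %d (doubling time %g-%g h): %s\n",
              length(x$t_axis), length(x$s_axis),
              min(x$t_axis), max(x$t_axis),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' As tidy data.frame
#' @param x a `phase_grid`
#' @param ... unused
#' @export
as.data.frame.phase_grid <- function(x, ...) {
  data.frame(doubling_time_h = rep(x$t_axis, times = length(x$s_axis)),
             signal = rep(x$s_axis, each = length(x$t_axis)),
             phase = as.vector(x$phase))
}

#' Saddle-node boundaries of the bistable signal interval
#'
#' Scans the signal axis for the interval on which the system is bistable at
#' doubling time `T` and refines each edge by bisection in log signal to a
#' relative tolerance. Returns `NULL` (with a warning) when no bistable
#' signal exists in the scan range. An infinite `s_high` means the system
#' stays bistable up to the top of the scan range (bistable for arbitrarily
#' strong signal, within numerical reach).
#'
#' @param spec a `switch_model`
#' @param T doubling time (h)
#' @param delta molecular decay rate (h^-1)
#' @param s_range signal scan range; default `[1e-6, 1e6]` times the model's
#'   characteristic signal scale
#' @param n_scan log-spaced scan points before bisection
#' @param rel_tol relative tolerance of the bisection
#' @return named numeric `c(s_low =, s_high =)`, or `NULL`
#' @export
bistability_boundaries <- function(spec, T, delta = default_delta(spec),
                                   s_range = NULL, n_scan = 400,
                                   rel_tol = 1e-4) {
  stopifnot(T > 0)
  ctx <- growth_context(doubling_time = T, delta = delta)
  if (is.null(s_range)) s_range <- signal_scale(spec, ctx) * c(1e-6, 1e6)
  sg <- exp(seq(log(s_range[1]), log(s_range[2]), length.out = n_scan))
  bi <- vapply(sg, function(s) count_roots(spec, s, ctx) >= 3, NA)
  ib <- which(bi)
  if (!length(ib)) {
    warning(sprintf(
      "no bistable signal found for doubling time %g h scanning [%.3g, %.3g]",
      T, s_range[1], s_range[2]))
    return(NULL)
  }
  bisect <- function(lo, hi, inside_is_upper) {
    # invariant: exactly one of (lo, hi) is bistable
    while (hi / lo - 1 > rel_tol) {
      m <- sqrt(lo * hi)
      m_bi <- count_roots(spec, m, ctx) >= 3
      if (m_bi == inside_is_upper) hi <- m else lo <- m
    }
    sqrt(lo * hi)
  }
  s_low <- if (ib[1] == 1) sg[1] else bisect(sg[ib[1] - 1], sg[ib[1]], TRUE)
  last <- ib[length(ib)]
  s_high <- if (last == length(sg)) Inf
            else bisect(sg[last], sg[last + 1], FALSE)
  c(s_low = s_low, s_high = s_high)
}

#' Critical-concentration curve across doubling times
#'
#' Computes the bistability boundaries at each doubling time and the centre
#' of the bistable region, defined as the geometric mean of the two
#' saddle-node signals (the midpoint on the log axis used throughout the
#' phase diagrams).
#'
#' @inheritParams bistability_boundaries
#' @param t_axis doubling times (h)
#' @return an object of class `critical_curve`: data.frame with columns
#'   `doubling_time_h`, `s_low`, `s_high`, `s_center`; doubling times with no
#'   bistable interval are dropped
#' @export
critical_curve <- function(spec, t_axis, delta = default_delta(spec),
                           s_range = NULL, n_scan = 400, rel_tol = 1e-4) {
  rows <- lapply(t_axis, function(T) {
    b <- withCallingHandlers(
      bistability_boundaries(spec, T, delta, s_range, n_scan, rel_tol),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(b)) return(NULL)
    data.frame(doubling_time_h = T, s_low = b[["s_low"]],
               s_high = b[["s_high"]],
               s_center = sqrt(b[["s_low"]] * b[["s_high"]]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(doubling_time_h = numeric(0), s_low = numeric(0),
                      s_high = numeric(0), s_center = numeric(0))
  class(out) <- c("critical_curve", "data.frame")
  out
}

#' Power-law exponent of the critical curve
#'
#' Ordinary least-squares slope of log10 s_center against log10 doubling
#' time over the requested window. The Bayesian errors-in-variables
#' machinery ([fit_loglog_slope()]) is used instead when per-point errors
#' are available.
#'
#' @param curve a `critical_curve` (or data.frame with `doubling_time_h` and
#'   `s_center`)
#' @param t_min,t_max doubling-time window (h)
#' @return the fitted slope (dimensionless exponent)
#' @export
scaling_exponent <- function(curve, t_min = -Inf, t_max = Inf) {
  d <- curve[curve$doubling_time_h >= t_min & curve$doubling_time_h <= t_max &
               is.finite(curve$s_center) & curve$s_center > 0, ]
  if (nrow(d) < 3) stop("need at least 3 curve points inside [t_min, t_max]")
  unname(stats::coef(stats::lm(log10(s_center) ~ log10(doubling_time_h),
                               data = d))[2])
}
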