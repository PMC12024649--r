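# Single-cell lineage analysis: per-cell growth rates, induction
# classification, photobleach correction, instantaneous-rate estimation,
# quadrant-based switch detection on 3-cell lineages, and the
# switcher-vs-nonswitcher growth comparison.

#' Cell record container
#'
#' One tracked cell: identity, parentage and per-frame measurements. The
#' fluorescence channel is typically sampled less often than phase contrast;
#' frames without a fluorescence exposure carry `NA` fluorescence.
#'
#' @param cell_id cell identifier
#' @param parent_id parent identifier or `NA` for founders
#' @param time frame times (h), strictly increasing
#' @param length cell length (um), > 0
#' @param fluor total fluorescence (molecules); `NA` on frames without an
#'   exposure
#' @param daughters character vector of 0-2 daughter ids
#' @return an object of class `cell_record`
#' @export
cell_record <- function(cell_id, parent_id = NA_character_, time, length,
                        fluor = rep(NA_real_, base::length(time)),
                        daughters = character(0)) {
  stopifnot(base::length(time) >= 1, !is.unsorted(time, strictly = TRUE),
            all(length > 0), base::length(length) == base::length(time),
            base::length(fluor) == base::length(time),
            base::length(daughters) <= 2)
  structure(list(cell_id = as.character(cell_id),
                 parent_id = as.character(parent_id),
                 time = time, length = length, fluor = fluor,
                 daughters = as.character(daughters)),
            class = "cell_record")
}

#' Per-cell growth rate
#'
#' OLS slope of log2(length) against time. Cells monitored for fewer than
#' `min_frames` consecutive frames are filtered (returned with `ok = FALSE`),
#' matching the 10-frame (30 min) monitoring rule.
#'
#' @param cell a [cell_record()]
#' @param min_frames minimum number of frames (default 10)
#' @return list with `ok`; when ok, `lam_dbl` (doublings/h), `lam_se`,
#'   `n_frames`
#' @export
cell_growth_rate <- function(cell, min_frames = 10) {
  n <- length(cell$time)
  if (n < min_frames)
    return(list(ok = FALSE, n_frames = n,
                reason = sprintf("%d frames is below the %d-frame minimum",
                                 n, min_frames)))
  s <- summary(stats::lm(log2(cell$length) ~ cell$time))$coefficients
  list(ok = TRUE, lam_dbl = unname(s[2, 1]), lam_se = unname(s[2, 2]),
       n_frames = n)
}

#' Photobleaching correction of a concentration estimate
#'
#' At steady state the unbleached-reporter concentration is
#' c_u = q/(lambda + beta) while the total is c = q/lambda, so
#' c = c_u (1 + beta/lambda).
#'
#' @param c_u measured (unbleached) concentration
#' @param beta photobleaching rate (h^-1), >= 0
#' @param lam growth rate (h^-1), > 0
#' @return the bleach-corrected total concentration
#' @export
bleach_correct <- function(c_u, beta, lam) {
  if (any(lam <= 0)) stop("growth rate must be positive")
  if (any(beta < 0)) stop("bleach rate must be non-negative")
  c_u * (1 + beta / lam)
}

#' Classify a cell trace as induced, uninduced or mixed
#'
#' A trace is `induced` when at least 95% of its fluorescence frames are
#' above the molecule threshold, `uninduced` when at most 5% are, and
#' `mixed` otherwise; mixed traces are discarded downstream.
#'
#' @param cell a [cell_record()]
#' @param threshold_molecules induced/uninduced threshold (default 250)
#' @return one of `"induced"`, `"uninduced"`, `"mixed"`
#' @export
classify_trace <- function(cell, threshold_molecules = 250) {
  fl <- cell$fluor[!is.na(cell$fluor)]
  if (!length(fl)) stop("trace has no fluorescence frames")
  frac <- mean(fl > threshold_molecules)
  if (frac >= 0.95) "induced" else if (frac <= 0.05) "uninduced" else "mixed"
}

#' Spherocylinder volume
#'
#' V = pi r^2 (L - 2r) + 4/3 pi r^3, using the per-condition mean radius
#' (per-frame diameters are too noisy to use directly).
#'
#' @param length cell length (um)
#' @param diameter mean cell diameter for the condition (um)
#' @return volume in um^3 (= fL)
#' @export
spherocylinder_volume <- function(length, diameter = 0.9) {
  r <- diameter / 2
  L <- pmax(length, 2 * r)
  pi * r^2 * (L - 2 * r) + 4 / 3 * pi * r^3
}

rolling_slope <- function(t, v, w) {
  n <- length(t)
  out <- rep(NA_real_, n)
  h <- (w - 1) %/% 2
  for (i in seq_len(n)) {
    jj <- max(1, i - h):min(n, i + h)
    if (length(jj) >= 3)
      out[i] <- stats::cov(t[jj], v[jj]) / stats::var(t[jj])
  }
  out
}

#' Instantaneous growth, volumic production and concentration of one cell
#'
#' Windowed-regression estimates on a single cell's frames (regressions are
#' never taken across a division): growth rate from a centred rolling
#' regression of log2(length) on time; volumic production as the rolling
#' slope of total fluorescence divided by the cell volume; concentration as
#' total fluorescence over volume. Fluorescence-derived quantities are
#' estimated on the frames that carry an exposure.
#'
#' @param cell a [cell_record()]
#' @param w rolling window (frames), odd (default 5)
#' @param diameter per-condition mean cell diameter (um)
#' @param beta photobleaching rate (h^-1) applied via [bleach_correct()]
#'   using the cell's mean growth rate; 0 to skip
#' @return a data.frame with `time`, `growth_dbl` (doublings/h),
#'   `production` (molecules/um^3/h), `concentration` (molecules/um^3);
#'   production/concentration are `NA` on frames without fluorescence
#' @export
estimate_instantaneous <- function(cell, w = 5, diameter = 0.9, beta = 0) {
  if (w %% 2 == 0) stop("window w must be odd (centred regression)")
  if (length(cell$time) < w) stop("trace shorter than the window")
  growth <- rolling_slope(cell$time, log2(cell$length), w)
  vol <- spherocylinder_volume(cell$length, diameter)
  has_f <- which(!is.na(cell$fluor))
  production <- concentration <- rep(NA_real_, length(cell$time))
  if (length(has_f) >= 3) {
    fl <- cell$fluor[has_f]
    tf <- cell$time[has_f]
    dfdt <- rolling_slope(tf, fl, w)
    production[has_f] <- dfdt / vol[has_f]
    # concentration smoothed over the same centred window as the slopes
    conc_raw <- fl / vol[has_f]
    h <- (w - 1) %/% 2
    conc_sm <- vapply(seq_along(conc_raw), function(i) {
      jj <- max(1, i - h):min(length(conc_raw), i + h)
      mean(conc_raw[jj])
    }, 0)
    concentration[has_f] <- conc_sm
    if (beta > 0) {
      lam_mean <- max(mean(growth, na.rm = TRUE) * log(2), 1e-6)
      concentration[has_f] <- bleach_correct(concentration[has_f], beta,
                                             lam_mean)
      production[has_f] <- production[has_f] +
        beta * concentration[has_f] * lam_mean / (lam_mean + beta)
    }
  }
  data.frame(time = cell$time, growth_dbl = growth,
             production = production, concentration = concentration)
}

#' Assemble a 3-cell lineage trace around a focal cell
#'
#' Switches usually span several cell cycles, so detection operates on
#' lineages of three cells: the parent's frames are prepended and the
#' frame-wise average of the two daughters' estimates (truncated at the
#' shorter daughter) is appended to the focal cell. Instantaneous estimates
#' are computed per cell, never across divisions.
#'
#' @param cells named list of [cell_record()] (names = cell ids)
#' @param focal_id id of the focal cell
#' @param w,diameter,beta passed to [estimate_instantaneous()]
#' @return an object of class `lineage_trace`: data.frame of per-frame
#'   estimates with a `part` column (`parent`, `focal`, `daughters`) and
#'   attribute `focal_id`
#' @export
lineage_trace <- function(cells, focal_id, w = 5, diameter = 0.9, beta = 0) {
  focal <- cells[[focal_id]]
  if (is.null(focal)) stop("unknown focal cell id: ", focal_id)
  parts <- list()
  pid <- focal$parent_id
  if (!is.na(pid) && !is.null(cells[[pid]])) {
    e <- estimate_instantaneous(cells[[pid]], w, diameter, beta)
    e$part <- "parent"
    parts <- c(parts, list(e))
  }
  ef <- estimate_instantaneous(focal, w, diameter, beta)
  ef$part <- "focal"
  parts <- c(parts, list(ef))
  ds <- focal$daughters[focal$daughters %in% names(cells)]
  ds <- ds[vapply(ds, function(d) length(cells[[d]]$time) >= w, NA)]
  if (length(ds) >= 1) {
    de <- lapply(ds, function(d) estimate_instantaneous(cells[[d]], w,
                                                        diameter, beta))
    n_min <- min(vapply(de, nrow, 0L))
    avg <- de[[1]][seq_len(n_min), ]
    if (length(de) == 2) {
      for (col in c("growth_dbl", "production", "concentration"))
        avg[[col]] <- rowMeans(cbind(de[[1]][[col]][seq_len(n_min)],
                                     de[[2]][[col]][seq_len(n_min)]),
                               na.rm = FALSE)
      avg$time <- rowMeans(cbind(de[[1]]$time[seq_len(n_min)],
                                 de[[2]]$time[seq_len(n_min)]))
    }
    avg$part <- "daughters"
    parts <- c(parts, list(avg))
  }
  out <- do.call(rbind, parts)
  out <- out[order(out$time), ]
  rownames(out) <- NULL
  class(out) <- c("lineage_trace", "data.frame")
  attr(out, "focal_id") <- focal_id
  out
}

# quadrant on the log scale: both production and concentration against one
# threshold. "low" = blue, "prod_high" = green, "high" = yellow,
# "conc_high" = orange.
quadrant_of <- function(lp, lc, th) {
  ifelse(lp > th,
         ifelse(lc > th, "high", "prod_high"),
         ifelse(lc > th, "conc_high", "low"))
}

#' Detect on/off switches on a lineage trace
#'
#' Classifies each fluorescence frame into quadrants of (log volumic
#' production, log concentration) against a common threshold. An on-switch
#' is a passage from the low/low quadrant to the high/high quadrant; its
#' time is the (interpolated) time at which the volumic production crossed
#' the threshold on the way up. Off-switches are the mirror image.
#' Excursions in which production crosses but concentration never follows
#' are not events.
#'
#' @param trace a [lineage_trace()] (or data.frame with `time`,
#'   `production`, `concentration`)
#' @param log_threshold natural-log threshold separating induced from
#'   uninduced in both variables (default 5.5)
#' @param min_dwell minimum number of consecutive frames a stable quadrant
#'   must persist to count as reached (default 2; guards against single
#'   noisy frames faking a completed switch). The final frames of a trace
#'   always count.
#' @return a data.frame of events: `direction` (`"on"`/`"off"`), `t_switch`
#'   (h), `pre_growth_dbl` (mean growth in the window before the switch)
#' @export
detect_switches <- function(trace, log_threshold = 5.5, min_dwell = 2) {
  ok <- !is.na(trace$production) & !is.na(trace$concentration) &
    trace$production > 0 & trace$concentration > 0
  d <- trace[ok, ]
  if (nrow(d) < 2) return(empty_events())
  lp <- log(d$production); lc <- log(d$concentration)
  qd <- quadrant_of(lp, lc, log_threshold)
  # demote too-short stable-quadrant visits to transition status
  r <- rle(qd)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  short <- r$lengths < min_dwell &
    r$values %in% c("low", "high") &
    seq_along(r$lengths) < length(r$lengths)
  qd[short[run_id]] <- "transient"
  events <- list()
  state <- NA_character_                  # last stable quadrant seen
  cross_t <- NA_real_                     # production crossing starting the transit
  for (i in seq_along(qd)) {
    q <- qd[i]
    if (q %in% c("low", "high")) {
      if (!is.na(state) && q != state) {
        dir <- if (q == "high") "on" else "off"
        t_sw <- if (is.na(cross_t)) d$time[i] else cross_t
        pre <- d$growth_dbl[d$time < t_sw & d$time >= t_sw - 1]
        events[[length(events) + 1]] <-
          data.frame(direction = dir, t_switch = t_sw,
                     pre_growth_dbl = mean(pre, na.rm = TRUE))
      }
      state <- q
      cross_t <- NA_real_
    } else if (i > 1 && is.na(cross_t)) {
      # production crossed the threshold leaving a stable quadrant
      prev_in <- qd[i - 1] %in% c("low", "high")
      crossed <- (lp[i] > log_threshold) != (lp[i - 1] > log_threshold)
      if (prev_in && crossed) {
        f <- (log_threshold - lp[i - 1]) / (lp[i] - lp[i - 1])
        cross_t <- d$time[i - 1] + f * (d$time[i] - d$time[i - 1])
      }
    }
  }
  if (!length(events)) return(empty_events())
  do.call(rbind, events)
}

empty_events <- function() {
  data.frame(direction = character(0), t_switch = numeric(0),
             pre_growth_dbl = numeric(0))
}

#' Compare growth of switching and returning lineages
#'
#' Lineages that entered a transition quadrant (high production at low
#' concentration for prospective on-switches; low production at high
#' concentration for off-switches) are sampled once each and grouped by
#' fate: those that completed the switch versus those that returned.
#' Reports group medians, interquartile ranges and the Welch two-sample t
#' test on growth rates.
#'
#' @param switched growth rates (doublings/h) of lineages that completed the
#'   switch, one value per lineage
#' @param returned growth rates of lineages that returned to their previous
#'   state
#' @param direction `"on"` or `"off"` (annotation only)
#' @return a list with `direction`, `n`, `median`, `iqr`, `t`, `p_value`,
#'   and `delta_median` (switched minus returned)
#' @export
compare_switcher_growth <- function(switched, returned,
                                    direction = c("on", "off")) {
  direction <- match.arg(direction)
  switched <- switched[is.finite(switched)]
  returned <- returned[is.finite(returned)]
  if (length(switched) < 2 || length(returned) < 2)
    stop("need at least 2 lineages per group")
  tt <- stats::t.test(switched, returned)
  list(direction = direction,
       n = c(switched = length(switched), returned = length(returned)),
       median = c(switched = stats::median(switched),
                  returned = stats::median(returned)),
       iqr = c(switched = stats::IQR(switched),
               returned = stats::IQR(returned)),
       t = unname(tt$statistic), p_value = tt$p.value,
       delta_median = stats::median(switched) - stats::median(returned))
}

#' Sample transition-quadrant occupancies of a lineage trace
#'
#' Finds every excursion of the trace into a transition quadrant and records
#' its fate (switched or returned) and the mean growth rate while in the
#' quadrant; each excursion is sampled once. Feeds
#' [compare_switcher_growth()].
#'
#' @inheritParams detect_switches
#' @param which_quadrant `"prod_high"` (green; prospective on-switches) or
#'   `"conc_high"` (orange; prospective off-switches)
#' @return data.frame with `fate` (`"switched"`/`"returned"`) and
#'   `growth_dbl`
#' @export
transition_occupancy <- function(trace, log_threshold = 5.5,
                                 which_quadrant = c("prod_high",
                                                    "conc_high")) {
  which_quadrant <- match.arg(which_quadrant)
  ok <- !is.na(trace$production) & !is.na(trace$concentration) &
    trace$production > 0 & trace$concentration > 0
  d <- trace[ok, ]
  if (nrow(d) < 2)
    return(data.frame(fate = character(0), growth_dbl = numeric(0)))
  qd <- quadrant_of(log(d$production), log(d$concentration), log_threshold)
  out <- list()
  i <- 1
  n <- length(qd)
  while (i <= n) {
    if (qd[i] == which_quadrant) {
      j <- i
      while (j < n && qd[j + 1] == which_quadrant) j <- j + 1
      # fate: the next stable quadrant reached after the excursion
      k <- j + 1
      while (k <= n && !(qd[k] %in% c("low", "high"))) k <- k + 1
      target <- if (which_quadrant == "prod_high") "high" else "low"
      fate <- if (k <= n && qd[k] == target) "switched" else "returned"
      out[[length(out) + 1]] <-
        data.frame(fate = fate,
                   growth_dbl = mean(d$growth_dbl[i:j], na.rm = TRUE))
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(out))
    return(data.frame(fate = character(0), growth_dbl = numeric(0)))
  do.call(rbind, out)
}
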