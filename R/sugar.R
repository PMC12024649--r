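# Monod growth kinetics, the inverse-Monod criterion, C-line calibration,
# and concentration-dependent sugar choice.

#' Monod growth kinetics
#'
#' `monod()` evaluates the hyperbolic Monod law
#' \eqn{\lambda(c) = \lambda_{max} c / (K_s + c)}; `inverse_monod()` returns
#' the nutrient concentration required to attain a growth rate,
#' \eqn{c(\lambda) = K_s \lambda / (\lambda_{max} - \lambda)}.
#'
#' @param c nutrient concentration (uM), >= 0
#' @param p a [monod_params()] object (fields `lam_max`, `K_s`)
#' @return growth rate in h^-1 (`monod`), concentration in uM
#'   (`inverse_monod`)
#' @export
monod <- function(c, p) {
  if (any(c < 0)) stop("negative concentration")
  p$lam_max * c / (p$K_s + c)
}

#' @rdname monod
#' @param lam growth rate (h^-1), `0 <= lam < lam_max`
#' @export
inverse_monod <- function(lam, p) {
  if (any(lam < 0)) stop("negative growth rate")
  if (any(lam >= p$lam_max))
    stop("unattainable growth rate: lam >= lam_max")
  p$K_s * lam / (p$lam_max - lam)
}

#' Monod parameter container
#'
#' @param lam_max maximal growth rate (h^-1)
#' @param K_s half-saturation concentration (uM)
#' @export
monod_params <- function(lam_max, K_s) {
  stopifnot(lam_max > 0, K_s > 0)
  structure(list(lam_max = lam_max, K_s = K_s), class = "monod_params")
}

#' Solve Monod parameters from two (concentration, growth-rate) anchors
#'
#' Two observed points determine the hyperbola exactly:
#' \eqn{K_s = c_1 c_2 (\lambda_1 - \lambda_2) /
#'   (c_1 \lambda_2 - c_2 \lambda_1)} up to ordering, then
#' \eqn{\lambda_{max} = \lambda_1 (K_s + c_1)/c_1}.
#'
#' @param c1,c2 concentrations (uM)
#' @param dbl1,dbl2 measured growth at those concentrations, in
#'   doublings/hour (the unit the growth curves are quoted in)
#' @return a [monod_params()] (rates in h^-1)
#' @export
monod_from_anchors <- function(c1, dbl1, c2, dbl2) {
  l1 <- dbl_to_lam(dbl1); l2 <- dbl_to_lam(dbl2)
  K_s <- c1 * c2 * (l1 - l2) / (l2 * c1 - l1 * c2)
  if (!is.finite(K_s) || K_s <= 0)
    stop("anchors are not consistent with a Monod curve")
  monod_params(lam_max = l1 * (K_s + c1) / c1, K_s = K_s)
}

#' Packaged default Monod parameters for glucose and lactose
#'
#' Glucose is anchored to single-cell growth measurements: 1.06 doublings/h
#' at 11,100 uM (0.2%) and 0.19 doublings/h at 2 uM. Lactose takes
#' lam_max = 0.72 h^-1 (1.04 doublings/h, the growth rate at which the
#' C-line reaches zero) with K_s chosen so that saturating lactose (550 uM)
#' supports the same growth rate as 50 uM glucose, the observed crossover of
#' the glucose/lactose preference. The lactose K_s is therefore a
#' calibration, not an independent measurement.
#'
#' @param sugar `"glucose"` or `"lactose"`
#' @return a [monod_params()]
#' @export
sugar_monod_default <- function(sugar = c("glucose", "lactose")) {
  sugar <- match.arg(sugar)
  glc <- monod_from_anchors(11100, 1.06, 2, 0.19)
  if (sugar == "glucose") return(glc)
  lam_max <- 0.72
  lam_at_sat <- monod(50, glc)          # growth on 50 uM glucose
  K_s <- 550 * (lam_max - lam_at_sat) / lam_at_sat
  monod_params(lam_max = lam_max, K_s = K_s)
}

#' Calibrate the C-line so the lac critical curve tracks inverse Monod
#'
#' Optimizes the C-line parameters (y0, lam_star) of a lac model in
#' `"c_line"` mode so that the centre of its bistable region, as a function
#' of growth rate, tracks the inverse Monod curve of the target sugar. The
#' objective is the sup-norm of the log ratio over `lam_grid` (the natural
#' metric on the log-log phase diagrams). Because y0 is a pure scale factor
#' of the critical curve, it is profiled out analytically (log-midpoint);
#' only lam_star is searched numerically.
#'
#' The calibration is run at `delta = 0`: the optimal-tracking theory
#' concerns molecules whose decay is dominated by dilution, and exact
#' tracking is only attainable in that idealization.
#'
#' @param lac a lac `switch_model` (its y_h_mode is forced to `"c_line"`)
#' @param target [monod_params()] of the sugar whose inverse Monod curve is
#'   to be tracked
#' @param lam_grid growth rates (h^-1) inside `(0, target$lam_max)` on which
#'   tracking is enforced
#' @param delta molecular decay rate used in the evaluation (default 0)
#' @return a list with `y0` (uM), `lam_star` (h^-1), `tracking_error`
#'   (sup |log s_center / inverse_monod|), and `curve` (data.frame of the
#'   calibrated s_center against the target)
#' @export
calibrate_cline <- function(lac, target, lam_grid = NULL, delta = 0) {
  stopifnot(inherits(lac, "switch_model"), lac$kind == "lac",
            inherits(target, "monod_params"))
  if (is.null(lam_grid))
    lam_grid <- seq(0.1, 0.9, length.out = 7) * target$lam_max
  stopifnot(all(lam_grid > 0), all(lam_grid < target$lam_max))
  inv <- inverse_monod(lam_grid, target)
  # residual profile for a given lam_star at unit y0; y0 scales s_center
  # as 1/y0, so the optimal log-scale shift is the midpoint of the range.
  center_curve <- function(lam_star) {
    p <- lac$params
    p$y_h_mode <- "c_line"; p$y0 <- 1; p$lam_star <- lam_star
    m <- lac
    m$params <- p
    vapply(lam_grid, function(l) {
      b <- bistability_boundaries(m, T = log(2) / l, delta = delta,
                                  n_scan = 200)
      if (is.null(b) || !is.finite(b[["s_high"]])) return(NA_real_)
      sqrt(b[["s_low"]] * b[["s_high"]])
    }, 0)
  }
  objective <- function(lam_star) {
    sc <- center_curve(lam_star)
    if (anyNA(sc)) return(1e6)
    r <- log(sc / inv)
    (max(r) - min(r)) / 2
  }
  opt <- stats::optimize(objective, interval = c(max(lam_grid) * 1.0001,
                                                 2 * target$lam_max),
                         tol = 1e-4 * target$lam_max)
  lam_star <- opt$minimum
  sc <- center_curve(lam_star)
  if (anyNA(sc)) stop("calibration failed: no bistable interval on the grid")
  r <- log(sc / inv)
  shift <- (max(r) + min(r)) / 2          # log y0
  y0 <- exp(shift)
  list(y0 = y0, lam_star = lam_star, tracking_error = (max(r) - min(r)) / 2,
       curve = data.frame(lam = lam_grid, s_center = sc / y0,
                          inverse_monod = inv))
}

#' Tracking error of an arbitrary lac growth law against inverse Monod
#'
#' Measures sup |log(s_center / inverse_monod)| over `lam_grid` for the lac
#' model as given (any y_h mode), after an optimal overall log-scale shift.
#' Used to show that growth laws other than the calibrated C-line cannot
#' track the inverse Monod curve.
#'
#' @inheritParams calibrate_cline
#' @param allow_rescale optimise over an overall scale factor (default TRUE)
#' @return the sup-norm log tracking error
#' @export
cline_tracking_error <- function(lac, target, lam_grid = NULL, delta = 0,
                                 allow_rescale = TRUE) {
  if (is.null(lam_grid))
    lam_grid <- seq(0.1, 0.9, length.out = 7) * target$lam_max
  inv <- inverse_monod(lam_grid, target)
  sc <- vapply(lam_grid, function(l) {
    b <- bistability_boundaries(lac, T = log(2) / l, delta = delta,
                                n_scan = 200)
    if (is.null(b) || !is.finite(b[["s_high"]])) return(NA_real_)
    sqrt(b[["s_low"]] * b[["s_high"]])
  }, 0)
  if (anyNA(sc)) stop("no bistable interval at some grid growth rates")
  r <- log(sc / inv)
  if (allow_rescale) (max(r) - min(r)) / 2 else max(abs(r))
}

#' Concentration-dependent sugar choice
#'
#' Given the sugars present and their concentrations, computes the growth
#' rate attainable on each via its Monod curve and returns the set predicted
#' to have a supercritical (induced) regulatory switch: the sugar(s)
#' offering the highest attainable growth rate, provided it exceeds the
#' current growth rate when one is designated. Exact ties are returned
#' together and flagged; the tie neighbourhood is precisely the regime where
#' both phenotypes coexist.
#'
#' @param options a list of sugar options, each a list with `name`,
#'   `concentration` (uM) and `monod` (a [monod_params()])
#' @param current_lam current growth rate (h^-1), or `NULL`
#' @param tol relative tolerance for calling a tie
#' @return a data.frame with `name`, `concentration_uM`, `attainable_lambda`
#'   (h^-1), `supercritical` (logical) and `tie` (logical)
#' @export
predict_induced_set <- function(options, current_lam = NULL, tol = 1e-9) {
  stopifnot(length(options) >= 1)
  lam <- vapply(options, function(o) monod(o$concentration, o$monod), 0)
  best <- max(lam)
  is_best <- lam >= best * (1 - tol)
  sup <- is_best
  if (!is.null(current_lam)) sup <- sup & (lam > current_lam)
  data.frame(
    name = vapply(options, function(o) o$name, ""),
    concentration_uM = vapply(options, function(o) o$concentration, 0),
    attainable_lambda = lam,
    supercritical = sup,
    tie = is_best & sum(is_best) > 1)
}
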