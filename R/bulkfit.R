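# Bulk fitting: the Hill induction-curve fit and the Bayesian
# errors-in-variables log-log slope posterior.

#' Induction curve container
#'
#' A dose-response curve of promoter activity against inducer concentration,
#' with per-point uncertainty.
#'
#' @param conc inducer concentrations (uM), non-negative; ties are allowed
#'   (replicate measurements are fitted as individual points) and the curve
#'   is stored sorted by concentration
#' @param activity promoter activity (Miller units x h^-1, or a
#'   fluorescence/OD ratio) on the linear scale
#' @param sigma per-point activity uncertainty, same units as `activity`
#' @return an object of class `induction_curve`
#' @export
induction_curve <- function(conc, activity, sigma) {
  stopifnot(length(conc) == length(activity), length(conc) == length(sigma),
            all(conc >= 0), all(sigma > 0), all(activity > 0))
  ord <- order(conc)
  structure(list(conc = conc[ord], activity = activity[ord],
                 sigma = sigma[ord]),
            class = "induction_curve")
}

hill_response <- function(c, b, f, k, m) b * (1 + f * (c / k)^m) / (1 + (c / k)^m)

#' Fit a Hill induction curve
#'
#' Fits the four-parameter response
#' \deqn{\alpha(c) = b \, \frac{1 + f (c/k)^m}{1 + (c/k)^m}}
#' (basal activity b, fold change f, critical inducer concentration k, Hill
#' coefficient m) by weighted least squares in log-activity space, with
#' multi-start over k (each observed concentration) and m (1, 2, 4).
#' Parameters are fitted on the log scale to enforce positivity; f is
#' parameterized as 1 + exp(.) to enforce f >= 1. Asymptotic standard errors
#' come from the converged fit's covariance; the relative error of k is the
#' standard error of log k.
#'
#' When the fitted fold change is below `f_min` the threshold k is
#' unidentifiable (at f = 1, k drops out of the response) and the fit is
#' flagged accordingly.
#'
#' @param curve an [induction_curve()]
#' @param f_min identifiability floor on the fitted fold change
#' @return an object of class `hill_fit`: list with `b`, `f`, `k`, `m`,
#'   standard errors `se_b`, `se_f`, `se_k`, `se_m`, `rel_err_k`,
#'   `identifiable`, `rss`, and `fitted`
#' @export
fit_hill <- function(curve, f_min = 1.2) {
  stopifnot(inherits(curve, "induction_curve"))
  cc <- curve$conc; y <- log(curve$activity)
  if (length(cc) < 5) stop("need >= 5 points")
  pos <- cc[cc > 0]
  if (max(pos) / min(pos) < 10) stop("concentrations must span >= 1 decade")
  w <- (curve$activity / curve$sigma)^2    # var(log a) ~ (sigma/a)^2
  fit1 <- function(b0, f0, k0, m0) {
    st <- list(lb = log(b0), lf = log(max(f0 - 1, 1e-3)),
               lk = log(k0), lm = log(m0))
    tryCatch(
      minpack.lm::nlsLM(
        y ~ log(hill_response(cc, exp(lb), 1 + exp(lf), exp(lk), exp(lm))),
        start = st, weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  b0 <- max(min(curve$activity), 1e-12)
  f0 <- max(curve$activity) / b0
  best <- NULL; best_rss <- Inf
  for (k0 in unique(pmax(cc, min(pos)))) for (m0 in c(1, 2, 4)) {
    ft <- fit1(b0, max(f0, 1.5), k0, m0)
    if (is.null(ft)) next
    rss <- sum(w * stats::residuals(ft)^2)
    if (rss < best_rss) { best <- ft; best_rss <- rss }
  }
  if (is.null(best)) stop("Hill fit did not converge from any start")
  cf <- stats::coef(best)
  vc <- tryCatch(stats::vcov(best), error = function(e) matrix(NA, 4, 4))
  se_log <- sqrt(pmax(diag(vc), 0))
  b <- exp(cf[["lb"]]); f <- 1 + exp(cf[["lf"]])
  k <- exp(cf[["lk"]]); m <- exp(cf[["lm"]])
  out <- list(b = b, f = f, k = k, m = m,
              se_b = b * se_log[1], se_f = exp(cf[["lf"]]) * se_log[2],
              se_k = k * se_log[3], se_m = m * se_log[4],
              rel_err_k = se_log[3],
              identifiable = f >= f_min,
              rss = best_rss,
              fitted = hill_response(cc, b, f, k, m))
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "Hill fit: b=%.4g  f=%.4g  k=%.4g uM (rel err %.2g)  m=%.3g%s\n",
    x$b, x$f, x$k, x$rel_err_k, x$m,
    if (x$identifiable) "" else "  [threshold unidentifiable: f < 1.2]"))
  invisible(x)
}

#' Log-likelihood of the errors-in-variables linear model
#'
#' Exact log density of the data under the line y = a x + b with per-point
#' Gaussian measurement noise sigma_i and intrinsic scatter sigma: each
#' point contributes a normal term with total variance sigma^2 + sigma_i^2.
#' Includes the full normalization.
#'
#' @param points a data.frame with columns `x`, `y`, `sigma_i`
#' @param a slope
#' @param b intercept
#' @param sigma intrinsic scatter (>= 0)
#' @return the log probability of the data
#' @export
slope_log_likelihood <- function(points, a, b, sigma) {
  stopifnot(sigma >= 0, all(points$sigma_i > 0))
  v <- sigma^2 + points$sigma_i^2
  sum(-0.5 * log(2 * pi * v) - (points$y - a * points$x - b)^2 / (2 * v))
}

# log marginal posterior density of log sigma: b and a integrated out
# analytically under flat priors. Under the scale prior d sigma / sigma the
# prior over log sigma is flat, so on the log scale the posterior density
# is the marginalized likelihood itself (maximizing the density of sigma
# rather than of log sigma would diverge at sigma -> 0).
slope_sigma_logpost <- function(points, sigma) {
  v <- sigma^2 + points$sigma_i^2
  w <- 1 / v
  S <- sum(w); Sx <- sum(w * points$x); Sy <- sum(w * points$y)
  Sxx <- sum(w * points$x^2); Sxy <- sum(w * points$x * points$y)
  Syy <- sum(w * points$y^2)
  A <- Sxx - Sx^2 / S                      # posterior precision of a
  if (A <= 0) return(-Inf)
  a_hat <- (Sxy - Sx * Sy / S) / A
  q_res <- Syy - Sy^2 / S - A * a_hat^2    # residual quadratic form
  -0.5 * sum(log(v)) - 0.5 * log(S) - 0.5 * log(A) - 0.5 * q_res
}

#' Bayesian log-log slope with intrinsic scatter
#'
#' Posterior of the slope a of y = a x + b given points with per-point
#' measurement SDs sigma_i and unknown intrinsic scatter sigma. Uses flat
#' priors on a and b (marginalized analytically; the conditional posterior
#' of a at fixed sigma is Gaussian) and the scale prior d sigma / sigma.
#' The posterior is maximized over sigma by bounded 1-D optimization on the
#' log-sigma scale, where the scale prior is flat. Returns the Gaussian
#' posterior mean and SD of a at the optimal sigma.
#'
#' @param points a data.frame with columns `x`, `y`, `sigma_i` (e.g. x = log
#'   doubling time, y = log critical concentration, sigma_i = relative error
#'   of the Hill-fit threshold)
#' @param sigma_bounds search bounds for the intrinsic scatter
#' @return an object of class `slope_fit`: list with `a_mean`, `a_sd`,
#'   `sigma_hat`, `b_profile`, `logpost`
#' @export
fit_loglog_slope <- function(points, sigma_bounds = c(1e-4, 10)) {
  stopifnot(nrow(points) >= 2, all(points$sigma_i > 0))
  if (length(unique(points$x)) < 2)
    stop("slope undefined: all x identical")
  opt <- stats::optimize(function(ls) slope_sigma_logpost(points, exp(ls)),
                         interval = log(sigma_bounds), maximum = TRUE,
                         tol = 1e-8)
  sigma_hat <- exp(opt$maximum)
  # prefer the lower boundary when the posterior is monotone decreasing
  # (zero-scatter data): optimize() cannot return an endpoint.
  if (slope_sigma_logpost(points, sigma_bounds[1]) >= opt$objective) {
    sigma_hat <- sigma_bounds[1]
  }
  v <- sigma_hat^2 + points$sigma_i^2
  w <- 1 / v
  S <- sum(w); Sx <- sum(w * points$x); Sy <- sum(w * points$y)
  Sxx <- sum(w * points$x^2); Sxy <- sum(w * points$x * points$y)
  A <- Sxx - Sx^2 / S
  a_mean <- (Sxy - Sx * Sy / S) / A
  b_profile <- (Sy - a_mean * Sx) / S
  out <- list(a_mean = a_mean, a_sd = sqrt(1 / A), sigma_hat = sigma_hat,
              b_profile = b_profile,
              logpost = slope_sigma_logpost(points, sigma_hat))
  class(out) <- "slope_fit"
  out
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("log-log slope: a = %.3f +/- %.3f (intrinsic scatter %.3g)\n",
              x$a_mean, x$a_sd, x$sigma_hat))
  invisible(x)
}
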