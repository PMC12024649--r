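#' Growth context: specific growth rate, doubling time, molecular decay
#'
#' Bundles the specific growth rate \eqn{\lambda} (h\eqn{^{-1}}), the
#' equivalent doubling time (h) and a first-order molecular decay rate
#' \eqn{\delta} (h\eqn{^{-1}}). For a molecule that is stable on the timescale
#' of a cell cycle, the effective concentration decay rate is
#' \eqn{\lambda + \delta}, dominated by dilution.
#'
#' @param doubling_time doubling time in hours (alternative to `lam`)
#' @param lam specific growth rate in h^-1 (\eqn{\lambda = \ln 2 /} doubling time)
#' @param delta first-order molecular decay rate in h^-1 (default 0)
#' @return an object of class `growth_context` with fields `lam`,
#'   `doubling_time`, `delta`
#' @examples
#' growth_context(doubling_time = 1)
#' growth_context(lam = 0.35, delta = log(2) / 48)
#' @export
growth_context <- function(doubling_time = NULL, lam = NULL, delta = 0) {
  if (is.null(lam) && is.null(doubling_time))
    stop("supply either `doubling_time` or `lam`")
  if (is.null(lam)) {
    stopifnot(doubling_time > 0)
    lam <- log(2) / doubling_time
  } else if (is.null(doubling_time)) {
    stopifnot(lam >= 0)
    doubling_time <- if (lam > 0) log(2) / lam else Inf
  }
  if (lam < 0) stop("growth rate `lam` must be >= 0")
  if (delta < 0) stop("decay rate `delta` must be >= 0")
  if (lam > 0 && abs(doubling_time * lam - log(2)) > 1e-8 * log(2))
    stop("inconsistent doubling_time and lam")
  structure(list(lam = lam, doubling_time = doubling_time, delta = delta),
            class = "growth_context")
}

#' @export
print.growth_context <- function(x, ...) {
  cat(sprintf("growth context: lam = %.4g /h (%.4g dbl/h, doubling %.4g h), delta = %.4g /h\n",
              x$lam, x$lam / log(2), x$doubling_time, x$delta))
  invisible(x)
}

#' Convert between specific growth rate and doublings per hour
#'
#' Figures in this field quote growth in doublings/hour; the models work in
#' the exponential rate \eqn{\lambda} (h^-1). `dbl_per_h = lam / ln 2`.
#'
#' @param lam specific growth rate (h^-1)
#' @param dbl doublings per hour
#' @return the converted rate
#' @export
lam_to_dbl <- function(lam) lam / log(2)

#' @rdname lam_to_dbl
#' @export
dbl_to_lam <- function(dbl) dbl * log(2)
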