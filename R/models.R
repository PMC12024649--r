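#' @keywords internal
hill_fn <- function(x, K, n) {
  x_n <- x^n
  x_n / (K^n + x_n)
}

#' Switch model constructors
#'
#' Each constructor builds a growth-rate-aware regulatory switch model that
#' reduces to a single scalar steady-state equation in the concentration of
#' its feedback protein. All concentrations are in uM, time in hours. The
#' four circuits are:
#'
#' * `autoactivator_model()`: a transcription factor (TF) activating its own
#'   expression; dx/dt = b + beta * x^n/(K^n + x^n) - (lam + delta) * x.
#' * `protease_model()`: the same positive feedback, with an external signal
#'   repressing a protease that degrades the TF; the decay term becomes
#'   (lam + delta + delta_p / (1 + (s/s0)^h_p)) * x.
#' * `two_component_model()`: TF and membrane kinase on one autoregulated
#'   operon; the signal activates the kinase, phosphorylated TF dimerizes and
#'   the active dimer drives the promoter. The fast phosphorylation and
#'   dimerization steps are at quasi-steady state.
#' * `lac_model()`: the lac operon positive feedback: LacY imports the
#'   inducer, intracellular inducer (at quasi-steady state with import and
#'   dilution) de-represses LacY expression.
#'
#' @param b basal production rate (uM/h)
#' @param beta maximal regulated production rate (uM/h)
#' @param K activation half-max concentration (uM) of the promoter input
#' @param n promoter Hill coefficient (>= 1)
#' @param modulation how growth rate is externally modulated; `"nutrient"` or
#'   `"translation"` (affects only the lac model's full-induction scaling)
#' @return an object of class `switch_model`
#' @seealso [switch_preset()] for the default parameterizations,
#'   [reduced_rhs()], [find_fixed_points()], [integrate_model()]
#' @export
autoactivator_model <- function(b = 2e-4, beta = 0.28, K = 1, n = 2,
                                modulation = "nutrient") {
  stopifnot(b >= 0, beta > 0, K > 0, n >= 1)
  new_switch_model("autoactivator",
                   list(b = b, beta = beta, K = K, n = n),
                   modulation)
}

#' @rdname autoactivator_model
#' @param delta_p maximal protease-mediated decay rate (h^-1)
#' @param s0 signal strength at half-maximal protease activity (signal units)
#' @param h_p protease-repression Hill coefficient
#' @export
protease_model <- function(b = 0.01, beta = 1, K = 1, n = 2,
                           delta_p = 1, s0 = 1, h_p = 2,
                           modulation = "nutrient") {
  stopifnot(b >= 0, beta > 0, K > 0, n >= 1, delta_p > 0, s0 > 0, h_p >= 1)
  new_switch_model("protease",
                   list(b = b, beta = beta, K = K, n = n,
                        delta_p = delta_p, s0 = s0, h_p = h_p),
                   modulation)
}

#' @rdname autoactivator_model
#' @param rho kinase-to-TF stoichiometric expression ratio (dimensionless)
#' @param k_act signal-activation half-max (signal units)
#' @param k_phos phosphorylation rate constant (per uM kinase per hour)
#' @param k_deph dephosphorylation rate (h^-1)
#' @param K_D dimerization dissociation constant (uM)
#' @export
two_component_model <- function(b = 0.4, beta = 25, K = 1, n = 2,
                                rho = 1, k_act = 1, k_phos = 1, k_deph = 100,
                                K_D = 1, modulation = "nutrient") {
  stopifnot(b >= 0, beta > 0, K > 0, n >= 1, rho > 0, k_act > 0,
            k_phos > 0, k_deph > 0, K_D > 0)
  new_switch_model("two_component",
                   list(b = b, beta = beta, K = K, n = n, rho = rho,
                        k_act = k_act, k_phos = k_phos, k_deph = k_deph,
                        K_D = K_D),
                   modulation)
}

#' @rdname autoactivator_model
#' @param leak basal expression as a fraction of full induction (0..1)
#' @param y_h_mode growth-rate scaling of full-induction expression, one of
#'   `"constant_activity"` (production rate at full induction independent of
#'   growth rate, so the expression *level* scales as 1/(lam+delta); the
#'   CRP-locked scenario), `"constant_level"` (expression level independent of
#'   growth rate), `"c_line"` (level = y0 * (1 - lam/lam_star), the catabolic
#'   growth law under nutrient modulation), `"r_line"` (level = kappa * lam,
#'   the behaviour under translation inhibition)
#' @param q0 full-induction production rate (uM/h), used by
#'   `"constant_activity"`
#' @param y_level full-induction expression level (uM), used by
#'   `"constant_level"`
#' @param y0 zero-growth intercept of the C-line (uM)
#' @param lam_star growth rate at which C-line expression reaches zero (h^-1)
#' @param kappa R-line slope: expression level per unit growth rate (uM h)
#' @param alpha_imp import rate per uM LacY per uM external inducer (h^-1)
#' @param K_tau intracellular inducer half-induction concentration (uM)
#' @param n_tau induction Hill coefficient
#' @param delta_mol molecular decay rate of LacY and inducer (h^-1); default
#'   ln 2 / 48 (48-hour half-life)
#' @param k_hyd inducer removal rate per uM of enzyme (h^-1 per uM); 0 for
#'   gratuitous inducers such as TMG
#' @param z_ratio enzyme-to-transporter concentration ratio (the removal term
#'   uses Z = z_ratio * Y)
#' @param ktau_scaling exponent theta of K_tau proportional to lam^theta
#'   (default 0; K_tau is then evaluated at the reference rate `lam_ref`)
#' @param lam_ref reference growth rate (h^-1) at which `K_tau` is quoted
#' @param volume_fl cell volume (fL) for molecule/concentration conversion
#' @export
lac_model <- function(leak = 1e-3,
                      y_h_mode = c("constant_activity", "constant_level",
                                   "c_line", "r_line"),
                      q0 = 50, y_level = 70, y0 = 46, lam_star = 0.72,
                      kappa = 70,
                      alpha_imp = 0.01, K_tau = 10, n_tau = 2,
                      delta_mol = log(2) / 48, k_hyd = 0, z_ratio = 1,
                      ktau_scaling = 0, lam_ref = 0.72, volume_fl = 2.5,
                      modulation = "nutrient") {
  y_h_mode <- match.arg(y_h_mode)
  stopifnot(leak >= 0, leak <= 1, alpha_imp > 0, K_tau > 0, n_tau >= 1,
            delta_mol >= 0, k_hyd >= 0, z_ratio >= 0, volume_fl > 0,
            lam_ref > 0)
  if (y_h_mode == "c_line") stopifnot(y0 > 0, lam_star > 0)
  new_switch_model("lac",
                   list(leak = leak, y_h_mode = y_h_mode, q0 = q0,
                        y_level = y_level, y0 = y0, lam_star = lam_star,
                        kappa = kappa, alpha_imp = alpha_imp, K_tau = K_tau,
                        n_tau = n_tau, delta_mol = delta_mol, k_hyd = k_hyd,
                        z_ratio = z_ratio, ktau_scaling = ktau_scaling,
                        lam_ref = lam_ref, volume_fl = volume_fl),
                   modulation)
}

new_switch_model <- function(kind, params, modulation) {
  modulation <- match.arg(modulation, c("nutrient", "translation"))
  structure(list(kind = kind, params = params, modulation = modulation),
            class = "switch_model")
}

#' Default preset for each switch circuit
#'
#' Returns the packaged default parameterization of one of the four switch
#' circuits. The defaults are chosen so that each circuit reproduces the
#' qualitative phase-diagram topology of its archetype: the autoactivator is
#' bistable over an intermediate band of doubling times; the protease switch
#' stays bistable at arbitrarily long doubling times for intermediate signal;
#' the two-component switch stays bistable at arbitrarily strong signal for
#' fast growth while its onset threshold falls roughly quadratically with
#' doubling time; and the lac switch's critical inducer concentration falls
#' quadratically with doubling time until the assumed 48-hour molecular
#' half-life flattens it.
#'
#' @param kind one of `"autoactivator"`, `"protease"`, `"two_component"`,
#'   `"lac"`
#' @param ... overrides passed on to the matching constructor
#' @return a `switch_model`
#' @export
switch_preset <- function(kind = c("autoactivator", "protease",
                                   "two_component", "lac"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         autoactivator = autoactivator_model(...),
         protease      = protease_model(...),
         two_component = two_component_model(...),
         lac           = lac_model(...))
}

#' @export
print.switch_model <- function(x, ...) {
  cat(sprintf("switch model <%s> (%s modulation)\n", x$kind, x$modulation))
  p <- x$params
  cat("  ", paste(sprintf("%s=%s", names(p),
                          vapply(p, function(v) paste(format(v, digits = 4),
                                                      collapse = ","), "")),
                  collapse = ", "), "\n")
  invisible(x)
}

#' Full-induction expression level and production rate of the lac model
#'
#' `lac_y_h()` returns the full-induction expression *level* y_h(lam) in uM
#' under the model's growth-law mode; `lac_production_max()` returns the
#' corresponding production rate y_h(lam) * (lam + delta) in uM/h.
#'
#' @param params the `params` list of a lac `switch_model` (or the model)
#' @param ctx a [growth_context()]
#' @return a scalar (uM, or uM/h)
#' @export
lac_y_h <- function(params, ctx) {
  if (inherits(params, "switch_model")) params <- params$params
  lam <- ctx$lam
  dil <- lam + ctx$delta
  switch(params$y_h_mode,
         constant_activity = params$q0 / dil,
         constant_level    = params$y_level,
         c_line = {
           if (lam >= params$lam_star)
             stop("c_line mode: lam >= lam_star gives non-positive full induction")
           params$y0 * (1 - lam / params$lam_star)
         },
         r_line = params$kappa * lam)
}

#' @rdname lac_y_h
#' @export
lac_production_max <- function(params, ctx) {
  if (inherits(params, "switch_model")) params <- params$params
  lac_y_h(params, ctx) * (ctx$lam + ctx$delta)
}

lac_K_tau <- function(params, ctx) {
  th <- params$ktau_scaling
  if (th == 0) return(params$K_tau)
  params$K_tau * (ctx$lam / params$lam_ref)^th
}

#' Default molecular decay rate for a model
#'
#' The lac preset assumes a 48-hour half-life for LacY and the inducer; the
#' abstract circuits default to perfectly stable molecules (decay by dilution
#' only).
#'
#' @param spec a `switch_model`
#' @return decay rate delta in h^-1
#' @export
default_delta <- function(spec) {
  if (spec$kind == "lac") spec$params$delta_mol else 0
}

#' Reduced scalar right-hand side of a switch model
#'
#' Evaluates dx/dt of the one-dimensional reduction of the circuit, with the
#' fast variables (phosphorylation, dimerization, intracellular inducer) at
#' quasi-steady state. `x` is the concentration (uM) of the feedback protein:
#' the TF for the abstract circuits, LacY for the lac model. Vectorized over
#' `x`.
#'
#' @param spec a `switch_model`
#' @param x protein concentration (uM), >= 0; may be a vector
#' @param signal external signal: signal units for the protease and
#'   two-component circuits, external inducer concentration (uM) for lac;
#'   ignored by the autoactivator
#' @param ctx a [growth_context()]
#' @return dx/dt in uM/h, same length as `x`
#' @export
reduced_rhs <- function(spec, x, signal = 0, ctx) {
  stopifnot(inherits(spec, "switch_model"), inherits(ctx, "growth_context"))
  if (any(x < 0)) stop("negative concentration x")
  if (any(signal < 0)) stop("negative signal")
  p <- spec$params
  dil <- ctx$lam + ctx$delta
  switch(spec$kind,
    autoactivator =
      p$b + p$beta * hill_fn(x, p$K, p$n) - dil * x,
    protease = {
      d_eff <- dil + p$delta_p / (1 + (signal / p$s0)^p$h_p)
      p$b + p$beta * hill_fn(x, p$K, p$n) - d_eff * x
    },
    two_component = {
      a <- signal / (signal + p$k_act)
      kin <- p$rho * x
      r <- p$k_deph / p$k_phos
      p_frac <- a * kin / (a * kin + r)
      D <- (p_frac * x)^2 / p$K_D
      p$b + p$beta * hill_fn(D, p$K, p$n) - dil * x
    },
    lac = {
      q <- lac_production_max(p, ctx)
      tau <- p$alpha_imp * x * signal / (dil + p$k_hyd * p$z_ratio * x)
      q * (p$leak + (1 - p$leak) * hill_fn(tau, lac_K_tau(p, ctx), p$n_tau)) -
        dil * x
    })
}

# characteristic scales used by root scanning and off/on discrimination
model_scales <- function(spec, signal, ctx) {
  p <- spec$params
  dil <- ctx$lam + ctx$delta
  if (spec$kind == "lac") {
    q <- lac_production_max(p, ctx)
    x_on <- q / dil
    x_off <- p$leak * q / dil
    list(x_max = 1.5 * x_on + 1e-12,
         x_mid = if (x_off > 0) sqrt(x_off * x_on) else sqrt(p$K_tau * x_on))
  } else {
    d_eff <- dil
    if (spec$kind == "protease")
      d_eff <- dil + p$delta_p / (1 + (signal / p$s0)^p$h_p)
    x_on <- (p$b + p$beta) / d_eff
    x_off <- p$b / d_eff
    list(x_max = 1.5 * x_on + 1e-12,
         x_mid = if (x_off > 0) sqrt(x_off * x_on) else sqrt(p$K * x_on))
  }
}

# signal scale for boundary scans
signal_scale <- function(spec, ctx) {
  p <- spec$params
  switch(spec$kind,
         protease = p$s0,
         two_component = p$k_act,
         lac = tryCatch(lac_threshold_relation(spec, ctx),
                        error = function(e) p$K_tau),
         1)
}

#' Fixed points of the reduced switch equation
#'
#' Locates all steady states of [reduced_rhs()] by a sign-change scan on a
#' dense log-spaced grid followed by bisection, and classifies their
#' stability from the slope of the right-hand side. For these circuits the
#' right-hand side is positive at x = 0 whenever basal production is
#' positive, so roots alternate stable/unstable; an exact root at x = 0
#' (zero basal production) is detected separately.
#'
#' @inheritParams reduced_rhs
#' @param tol_abs absolute tolerance on |rhs| at a reported root (bisection
#'   target)
#' @param n_grid number of log-spaced scan points
#' @return a data.frame with columns `x` (ascending) and `stable` (logical)
#' @export
find_fixed_points <- function(spec, signal = 0, ctx, tol_abs = 1e-10,
                              n_grid = 2000) {
  sc <- model_scales(spec, signal, ctx)
  x_max <- sc$x_max
  f <- function(x) reduced_rhs(spec, x, signal, ctx)
  xg <- exp(seq(log(x_max * 1e-9), log(x_max), length.out = n_grid))
  fv <- f(xg)
  roots <- numeric(0)
  idx <- which(fv[-1] * fv[-length(fv)] < 0)
  for (i in idx) {
    r <- stats::uniroot(f, c(xg[i], xg[i + 1]), tol = .Machine$double.eps^0.75)
    if (abs(f(r$root)) > max(tol_abs, 1e-8 * abs(f(xg[i]))))
      r$root <- stats::uniroot(f, c(xg[i], xg[i + 1]),
                               tol = .Machine$double.eps)$root
    roots <- c(roots, r$root)
  }
  roots <- c(roots, xg[fv == 0])
  if (abs(f(0)) < tol_abs) roots <- c(0, roots)
  roots <- sort(unique(roots))
  # merge near-coincident roots (saddle-node resolution)
  if (length(roots) > 1) {
    merge_tol <- 1e-6 * x_max / 1.5
    keep <- c(TRUE, diff(roots) > merge_tol)
    roots <- roots[keep]
  }
  if (!length(roots))
    stop(sprintf("no fixed point found scanning x in [%.3g, %.3g]",
                 x_max * 1e-9, x_max))
  h <- 1e-6 * x_max
  slope <- vapply(roots, function(r) {
    lo <- max(r - h, 0)
    (f(r + h) - f(lo)) / (r + h - lo)
  }, 0)
  data.frame(x = roots, stable = slope < 0)
}

#' Closed-form scaling estimate of the lac critical inducer concentration
#'
#' For a gratuitous inducer (no hydrolysis), the external inducer
#' concentration at the centre of the bistable region scales as
#' \deqn{c^* = \gamma \, K_\tau(\lambda) \, (\lambda+\delta)^2 /
#'   (\alpha_{imp} \, q_h(\lambda))}
#' where \eqn{q_h} is the full-induction production rate. One power of
#' \eqn{(\lambda+\delta)} comes from dilution of the intracellular inducer
#' and one from dilution of LacY itself. The order-one constant
#' \eqn{\gamma = 5.623} was calibrated once against the numerical bistability
#' boundaries at the default leak (1e-3) and induction Hill coefficient (2);
#' the grouping is exactly growth-rate invariant, so the calibration holds at
#' every growth rate. Intended as a fast cross-check oracle for the numerical
#' phase boundaries.
#'
#' @param spec a lac `switch_model` (or its params list)
#' @param ctx a [growth_context()]
#' @param gamma the calibrated order-one constant
#' @return estimated critical external inducer concentration (uM)
#' @export
lac_threshold_relation <- function(spec, ctx, gamma = 5.623) {
  p <- if (inherits(spec, "switch_model")) spec$params else spec
  if (p$k_hyd != 0)
    stop("threshold relation applies to the gratuitous-inducer regime (k_hyd = 0)")
  dil <- ctx$lam + ctx$delta
  q <- lac_production_max(p, ctx)
  gamma * lac_K_tau(p, ctx) * dil^2 / (p$alpha_imp * q)
}

#' Integrate the full (un-reduced) switch dynamics
#'
#' ODE-integration oracle for the steady-state machinery. The autoactivator
#' and protease circuits are already scalar; the two-component and lac
#' circuits are integrated with their fast variables as explicit states
#' (phosphorylation/dephosphorylation and a fast non-sequestering dimer
#' readout for the two-component circuit; the intracellular inducer for lac),
#' so their fixed points coincide with the quasi-steady-state reduction up to
#' terms of order dilution/fast-rate.
#'
#' @param spec a `switch_model`
#' @param x0 initial full state vector: scalar `x` (autoactivator, protease);
#'   `c(X, P, D, Kk)` for two_component (monomer, phospho-monomer, active
#'   dimer, kinase); `c(Y, tau)` for lac. A scalar is expanded to a
#'   consistent full state.
#' @param t_grid strictly increasing times (h)
#' @param signal external signal (see [reduced_rhs()])
#' @param ctx a [growth_context()]
#' @param k_fast rate (h^-1) of the fast dimer-readout equilibration
#' @return a data.frame: `time`, the state columns, and `x` (the reduced
#'   coordinate: total TF for two_component, LacY for lac)
#' @export
integrate_model <- function(spec, x0, t_grid, signal = 0, ctx, k_fast = 1e4) {
  stopifnot(all(diff(t_grid) > 0), all(x0 >= 0))
  p <- spec$params
  dil <- ctx$lam + ctx$delta
  if (spec$kind %in% c("autoactivator", "protease")) {
    rhs <- function(t, y, parms)
      list(reduced_rhs(spec, max(y[1], 0), signal, ctx))
    out <- deSolve::ode(y = c(x = unname(x0[1])), times = t_grid, func = rhs,
                        parms = NULL, method = "lsoda")
    res <- as.data.frame(out)
    res$x <- res[["x"]]
    return(res)
  }
  if (spec$kind == "two_component") {
    a <- signal / (signal + p$k_act)
    if (length(x0) == 1) {
      r <- p$k_deph / p$k_phos
      kin <- p$rho * x0
      pf <- a * kin / (a * kin + r)
      x0 <- c(X = unname(x0 * (1 - pf)), P = unname(x0 * pf),
              D = unname((pf * x0)^2 / p$K_D), Kk = unname(p$rho * x0))
    } else names(x0) <- c("X", "P", "D", "Kk")
    rhs <- function(t, y, parms) {
      y <- pmax(y, 0)
      prod <- p$b + p$beta * hill_fn(y["D"], p$K, p$n)
      phos <- p$k_phos * a * y["Kk"] * y["X"]
      deph <- p$k_deph * y["P"]
      list(c(prod - phos + deph - dil * y["X"],
             phos - deph - dil * y["P"],
             k_fast * ((y["P"]^2 / p$K_D) - y["D"]),
             p$rho * prod - dil * y["Kk"]))
    }
    out <- deSolve::ode(y = x0, times = t_grid, func = rhs, parms = NULL,
                        method = "lsoda")
    res <- as.data.frame(out)
    res$x <- res$X + res$P
    return(res)
  }
  # lac
  if (length(x0) == 1) {
    tau0 <- p$alpha_imp * x0 * signal /
      (dil + p$k_hyd * p$z_ratio * x0)
    x0 <- c(Y = unname(x0), tau = unname(tau0))
  } else names(x0) <- c("Y", "tau")
  q <- lac_production_max(p, ctx)
  Kt <- lac_K_tau(p, ctx)
  rhs <- function(t, y, parms) {
    y <- pmax(y, 0)
    prod <- q * (p$leak + (1 - p$leak) * hill_fn(y["tau"], Kt, p$n_tau))
    list(c(prod - dil * y["Y"],
           p$alpha_imp * y["Y"] * signal -
             (dil + p$k_hyd * p$z_ratio * y["Y"]) * y["tau"]))
  }
  out <- deSolve::ode(y = x0, times = t_grid, func = rhs, parms = NULL,
                      method = "lsoda")
  res <- as.data.frame(out)
  res$x <- res$Y
  res
}
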