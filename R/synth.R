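# Synthetic-data generators with ground-truth sidecars. All generators are
# pure functions of (config, seed).

#' Configuration for the plate-reader dataset generator
#'
#' @param conditions data.frame with one row per growth condition: `media`
#'   (label), `dbl_rate` (true doubling rate, doublings/h), and the true
#'   induction-curve parameters `b`, `f`, `k`, `m` (activity units, uM)
#' @param tmg_grid inducer concentrations (uM) per condition
#' @param replicates technical replicates per (condition, TMG)
#' @param od_cv,signal_cv multiplicative measurement noise (coefficient of
#'   variation) per point
#' @param interval_min sampling interval (min)
#' @param duration_h total monitored time (h)
#' @param od0,od_max inoculum and saturation OD
#' @param lag_h lag-phase duration (h)
#' @param od_bg,signal_bg instrument backgrounds added to both channels
#' @param seed RNG seed
#' @return a list of class `plate_gen_config`
#' @export
plate_gen_config <- function(conditions,
                             tmg_grid = c(0, 2, 5, 10, 20, 50, 100, 500),
                             replicates = 3,
                             od_cv = 0.02, signal_cv = 0.05,
                             interval_min = 4, duration_h = 16,
                             od0 = 7.5e-4, od_max = 0.6, lag_h = 1,
                             od_bg = 0.05, signal_bg = 10, seed = 1) {
  stopifnot(is.data.frame(conditions),
            all(c("media", "dbl_rate", "b", "f", "k", "m") %in%
                  names(conditions)),
            all(conditions$dbl_rate > 0), replicates >= 1,
            od_cv >= 0, signal_cv >= 0)
  structure(as.list(environment()), class = "plate_gen_config")
}

#' Default plate generator conditions
#'
#' Eight media spanning doubling rates 0.17 to 1.4 doublings/hour
#' (doubling times about 0.7 to 6 h). The true critical concentration k
#' falls quadratically with doubling time (the GCS expectation) and the
#' basal activity, fold change and Hill coefficient are growth-rate
#' independent.
#'
#' @param k_ref critical concentration (uM) at 1 h doubling time
#' @return a conditions data.frame for [plate_gen_config()]
#' @export
default_plate_conditions <- function(k_ref = 50) {
  dbl <- exp(seq(log(1.4), log(0.17), length.out = 8))
  t_dbl <- 1 / dbl
  data.frame(media = sprintf("medium_%d", seq_along(dbl)),
             dbl_rate = dbl, b = 2, f = 80, k = k_ref / t_dbl^2, m = 2)
}

#' Generate a plate-reader dataset
#'
#' Emulates batch growth curves with lag, exponential growth and saturation,
#' and a reporter channel proportional to OD times the steady-state
#' expression set by the condition's Hill induction curve at its inducer
#' concentration (expression level = activity / doubling rate, the stable-
#' enzyme balance). Instrument backgrounds are added and multiplicative
#' log-normal noise applied per point.
#'
#' @param cfg a [plate_gen_config()]
#' @return list with `wells` (list of [plate_series()], with metadata) and
#'   `truth` (data.frame of every generating parameter per well)
#' @export
gen_plate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "plate_gen_config"))
  set.seed(cfg$seed)
  wells <- list(); truth <- list()
  for (ci in seq_len(nrow(cfg$conditions))) {
    cond <- cfg$conditions[ci, ]
    lam_e <- dbl_to_lam(cond$dbl_rate)
    # monitor each condition long enough to pass through mid-exponential
    # and saturate (the protocol's dilution-factor/delay combinations serve
    # the same purpose: growth is observed over the full usable OD range)
    need_h <- cfg$lag_h +
      (log2(cfg$od_max / cfg$od0) + 2) / cond$dbl_rate
    dur <- max(cfg$duration_h, ceiling(need_h))
    times <- seq(0, dur, by = cfg$interval_min / 60)
    for (tmg in cfg$tmg_grid) for (rep in seq_len(cfg$replicates)) {
      g <- exp(lam_e * pmax(times - cfg$lag_h, 0))
      # exponential growth with abrupt saturation at substrate exhaustion:
      # on a single carbon source with K_s far below the feed concentration
      # the rate stays constant until the substrate runs out
      od_true <- pmin(cfg$od0 * g, cfg$od_max)
      alpha <- hill_response(tmg, cond$b, cond$f, cond$k, cond$m)
      expr <- alpha / cond$dbl_rate
      od_noise <- if (cfg$od_cv > 0)
        exp(stats::rnorm(length(times), -cfg$od_cv^2 / 2, cfg$od_cv)) else 1
      sig_noise <- if (cfg$signal_cv > 0)
        exp(stats::rnorm(length(times), -cfg$signal_cv^2 / 2, cfg$signal_cv)) else 1
      od_obs <- od_true * od_noise + cfg$od_bg
      sig_obs <- od_true * expr * sig_noise + cfg$signal_bg
      meta <- list(media = cond$media, tmg_uM = tmg, replicate = rep)
      wells[[length(wells) + 1]] <- plate_series(times, od_obs, sig_obs,
                                                 meta)
      truth[[length(truth) + 1]] <-
        data.frame(media = cond$media, tmg_uM = tmg, replicate = rep,
                   dbl_rate = cond$dbl_rate, b = cond$b, f = cond$f,
                   k = cond$k, m = cond$m, alpha = alpha)
    }
  }
  list(wells = wells, truth = do.call(rbind, truth))
}

#' Generate critical-concentration points from a switch model
#'
#' Computes the centre of the bistable region of `spec` at each doubling
#' time, then draws `n_rep` replicate observations per doubling time with
#' log-normal scatter: k_i = s_center(T_i) * exp(eps), eps ~ N(0,
#' sigma_rep^2). Points are returned on natural-log axes ready for
#' [fit_loglog_slope()], with sigma_i = sigma_rep (floored at 1e-6 so
#' exact data remain usable).
#'
#' @param spec a `switch_model`
#' @param t_list doubling times (h)
#' @param sigma_rep replicate log-scatter SD
#' @param n_rep replicates per doubling time
#' @param seed RNG seed
#' @param delta molecular decay rate (h^-1)
#' @return list with `points` (data.frame `x`, `y`, `sigma_i`,
#'   `doubling_time_h`, `k`) and `truth` (the noise-free critical curve)
#' @export
gen_threshold_dataset <- function(spec, t_list, sigma_rep = 0.15, n_rep = 3,
                                  seed = 1, delta = default_delta(spec)) {
  stopifnot(all(t_list > 0), sigma_rep >= 0, n_rep >= 1)
  set.seed(seed)
  curve <- critical_curve(spec, t_list, delta = delta)
  if (nrow(curve) < length(t_list))
    warning("some doubling times had no bistable interval and were dropped")
  pts <- do.call(rbind, lapply(seq_len(nrow(curve)), function(i) {
    eps <- stats::rnorm(n_rep, 0, sigma_rep)
    k <- curve$s_center[i] * exp(eps)
    data.frame(x = log(curve$doubling_time_h[i]), y = log(k),
               sigma_i = max(sigma_rep, 1e-6),
               doubling_time_h = curve$doubling_time_h[i], k = k)
  }))
  list(points = pts, truth = curve)
}

#' Configuration for the single-cell lineage generator
#'
#' The generator emulates mother-machine experiments on glucose/lactose
#' mixtures: per-lineage Ornstein-Uhlenbeck growth-rate fluctuations, the
#' lac switch ODE driven by the instantaneous growth rate, growth on the
#' currently usable sugar (glucose Monod when uninduced, lactose Monod when
#' induced), division at a threshold length with binomial fluorophore
#' partitioning, fluorescence observed at a lower cadence than phase
#' contrast, and photobleaching applied per exposure.
#'
#' @param lac a lac `switch_model` (typically c_line mode calibrated to the
#'   lactose Monod curve)
#' @param glucose_uM,lactose_uM sugar concentrations
#' @param monod_glc,monod_lac [monod_params()] per sugar
#' @param ou_reversion OU mean-reversion rate (h^-1)
#' @param ou_cv stationary coefficient of variation of the growth-rate
#'   fluctuation factor
#' @param div_length division threshold length (um)
#' @param asym_sd SD of the division-asymmetry fraction around 1/2
#' @param bleach_per_exposure fraction of fluorophores bleached per
#'   fluorescence exposure (continuous-rate equivalent beta =
#'   -log(1 - fraction)/dt_fluor)
#' @param dt_phase,dt_fluor phase-contrast and fluorescence frame intervals
#'   (h); `dt_fluor` must be a multiple of `dt_phase`
#' @param n_channels number of mother-machine channels (lineages)
#' @param duration_h experiment duration (h)
#' @param length_cv,fluor_cv multiplicative measurement noise per frame
#' @param diameter mean cell diameter (um)
#' @param n_switch_threshold molecule count at which the growth substrate
#'   switches (the induction criterion inside the generator)
#' @param init_state start all lineages `"uninduced"` (the glucose
#'   preculture) or `"induced"`
#' @param seed RNG seed
#' @return a list of class `lineage_gen_config`
#' @export
lineage_gen_config <- function(lac,
                               glucose_uM = 64, lactose_uM = 550,
                               monod_glc = sugar_monod_default("glucose"),
                               monod_lac = sugar_monod_default("lactose"),
                               ou_reversion = 0.5, ou_cv = 0.3,
                               div_length = 4, asym_sd = 0.025,
                               bleach_per_exposure = 0.044,
                               dt_phase = 0.05, dt_fluor = 0.15,
                               n_channels = 40, duration_h = 30,
                               length_cv = 0.01, fluor_cv = 0.02,
                               diameter = 0.9,
                               n_switch_threshold = 250,
                               init_state = c("uninduced", "induced"),
                               seed = 1) {
  init_state <- match.arg(init_state)
  stopifnot(inherits(lac, "switch_model"), lac$kind == "lac",
            glucose_uM >= 0, lactose_uM >= 0, duration_h > 0,
            ou_cv >= 0, abs(dt_fluor / dt_phase -
                              round(dt_fluor / dt_phase)) < 1e-9)
  structure(as.list(environment()), class = "lineage_gen_config")
}

MOLE_PER_UM_FL <- 602.214  # molecules per fL at 1 uM

#' Generate a single-cell lineage dataset
#'
#' Simulates the mother line of each channel (plus short tracks of the
#' sibling daughter at each division, so 3-cell lineages can be assembled),
#' with ground truth. See [lineage_gen_config()] for the mechanism.
#'
#' The truth sidecar records, per channel, the noise-free concentration and
#' volumic production series of the mother line and the completed switch
#' events obtained by applying the quadrant rule to that noise-free series;
#' detection tests compare the analysis pipeline run on the *observed* data
#' against these.
#'
#' @param cfg a [lineage_gen_config()]
#' @return list with `cells` (named list of [cell_record()]), `truth`
#'   (per-channel list: `events`, `series`, and per-cell `state` table)
#' @export
gen_lineage_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "lineage_gen_config"))
  set.seed(cfg$seed)
  p <- cfg$lac$params
  delta <- p$delta_mol
  n_per_fluor <- round(cfg$dt_fluor / cfg$dt_phase)
  beta_cont <- -log(1 - cfg$bleach_per_exposure) / cfg$dt_fluor
  n_steps <- floor(cfg$duration_h / cfg$dt_phase)
  nc <- cfg$n_channels
  th <- cfg$ou_reversion
  sd_ou <- cfg$ou_cv
  r_lac <- if (cfg$lactose_uM > 0) monod(cfg$lactose_uM, cfg$monod_lac) else 0
  r_glc <- if (cfg$glucose_uM > 0) monod(cfg$glucose_uM, cfg$monod_glc) else 0
  # induced cells use whichever sugar supports faster growth (a cell that
  # keeps its lac operon on in glucose-rich medium still grows on glucose);
  # uninduced cells can only use glucose.
  base_of <- function(induced) ifelse(induced, pmax(r_lac, r_glc), r_glc)
  lam_of <- function(induced, eta) base_of(induced) * exp(eta - sd_ou^2 / 2)
  production_rate <- function(Y, lam, lam_base) {
    # lac production (uM/h). The growth-law expression level is evaluated at
    # the nutrient-set base rate (catabolic regulation tracks nutrient
    # quality, not fast single-cell fluctuations); dilution of the
    # intracellular inducer uses the instantaneous rate, which is the
    # growth-coupling that drives stochastic switching.
    lvl <- switch(p$y_h_mode,
                  constant_activity = p$q0 / (lam_base + delta),
                  constant_level = p$y_level,
                  c_line = p$y0 * max(1 - lam_base / p$lam_star, 0),
                  r_line = p$kappa * lam_base)
    q <- lvl * (lam_base + delta)
    tau <- p$alpha_imp * Y * cfg$lactose_uM / (lam + delta)
    q * (p$leak + (1 - p$leak) * hill_fn(tau, p$K_tau, p$n_tau))
  }
  vol_of <- function(L) spherocylinder_volume(L, cfg$diameter)

  # state vectors over channels
  eta <- stats::rnorm(nc, 0, sd_ou)
  L <- cfg$div_length / 2 * exp(stats::runif(nc, -0.15, 0.15))
  if (cfg$init_state == "induced") {
    r0 <- max(r_lac, r_glc)
    Y <- rep(1, nc)
    for (it in 1:200) Y <- production_rate(Y[1], r0, r0) / (r0 + delta) + 0 * Y
    Y <- rep(production_rate(Y[1], r0, r0) / (r0 + delta), nc)
    induced <- rep(TRUE, nc)
  } else {
    Y <- rep(production_rate(1e-9, r_glc, r_glc) / (r_glc + delta), nc)
    induced <- rep(FALSE, nc)
  }
  Yu <- Y                                  # unbleached
  cell_no <- rep(1L, nc)

  rec_L <- matrix(NA_real_, n_steps + 1, nc)
  rec_Nu <- matrix(NA_real_, n_steps + 1, nc)
  rec_cell <- matrix(NA_integer_, n_steps + 1, nc)
  true_c <- matrix(NA_real_, n_steps + 1, nc)   # molecules / um^3
  true_q <- matrix(NA_real_, n_steps + 1, nc)
  true_lam <- matrix(NA_real_, n_steps + 1, nc)
  sib_states <- list()                     # spawned siblings

  a_ou <- exp(-th * cfg$dt_phase)
  s_ou <- sd_ou * sqrt(1 - a_ou^2)
  times <- (0:n_steps) * cfg$dt_phase

  for (s in 0:n_steps) {
    i <- s + 1
    base <- base_of(induced)
    lam <- base * exp(eta - sd_ou^2 / 2)
    V <- vol_of(L)
    pr <- vapply(seq_len(nc), function(j)
      production_rate(Y[j], lam[j], base[j]), 0)
    # record phase frame
    rec_L[i, ] <- L * exp(stats::rnorm(nc, 0, cfg$length_cv))
    rec_cell[i, ] <- cell_no
    true_c[i, ] <- Y * MOLE_PER_UM_FL
    true_q[i, ] <- pr * MOLE_PER_UM_FL
    true_lam[i, ] <- lam / log(2)
    if (s %% n_per_fluor == 0) {
      N_u <- Yu * V * MOLE_PER_UM_FL
      rec_Nu[i, ] <- N_u * exp(stats::rnorm(nc, 0, cfg$fluor_cv))
      Yu <- Yu * (1 - cfg$bleach_per_exposure)   # bleach after readout
    }
    if (s == n_steps) break
    # advance
    Y <- pmax(Y + cfg$dt_phase * (pr - lam * Y), 0)
    Yu <- pmax(Yu + cfg$dt_phase * (pr - lam * Yu), 0)
    L <- L * exp(lam * cfg$dt_phase)
    eta <- a_ou * eta + stats::rnorm(nc, 0, s_ou)
    induced <- (Y * vol_of(L) * MOLE_PER_UM_FL) > cfg$n_switch_threshold
    # divisions
    div <- which(L >= cfg$div_length)
    for (j in div) {
      phi <- min(max(0.5 + stats::rnorm(1, 0, cfg$asym_sd), 0.35), 0.65)
      Vj <- vol_of(L[j])
      N_tot <- Y[j] * Vj * MOLE_PER_UM_FL
      N_keep <- if (N_tot > 0) stats::rbinom(1, round(N_tot), phi) else 0
      frac_u <- if (Y[j] > 0) Yu[j] / Y[j] else 0
      L_new <- L[j] * phi
      V_new <- vol_of(L_new)
      sib_states[[length(sib_states) + 1]] <- list(
        channel = j, mother_cell = cell_no[j], step = s,
        L = L[j] * (1 - phi),
        Y = if (N_tot > 0) (round(N_tot) - N_keep) /
          (vol_of(L[j] * (1 - phi)) * MOLE_PER_UM_FL) else 0,
        frac_u = frac_u, eta = eta[j], induced = induced[j])
      Y[j] <- N_keep / (V_new * MOLE_PER_UM_FL)
      Yu[j] <- Y[j] * frac_u
      L[j] <- L_new
      cell_no[j] <- cell_no[j] + 1L
    }
  }

  # assemble mother-line cell records
  cells <- list()
  cell_state <- list()
  for (j in seq_len(nc)) {
    ids <- unique(rec_cell[, j])
    for (k in seq_along(ids)) {
      rows <- which(rec_cell[, j] == ids[k])
      id <- sprintf("ch%02d_c%03d", j, ids[k])
      parent <- if (k == 1) NA_character_ else
        sprintf("ch%02d_c%03d", j, ids[k - 1])
      daughters <- character(0)
      if (k < length(ids))
        daughters <- sprintf("ch%02d_c%03d", j, ids[k + 1])
      cells[[id]] <- cell_record(id, parent, times[rows], rec_L[rows, j],
                                 rec_Nu[rows, j], daughters)
      cell_state[[length(cell_state) + 1]] <-
        data.frame(cell_id = id, channel = j,
                   t_start = times[rows[1]], t_end = times[rows[length(rows)]],
                   mean_true_conc = mean(true_c[rows, j]))
    }
  }

  # short sibling tracks (up to their own division or sib_max_h)
  sib_max_h <- 2
  for (sb in sib_states) {
    t0_step <- sb$step + 1
    if (t0_step > n_steps) next
    n_sib <- min(n_steps - t0_step, round(sib_max_h / cfg$dt_phase))
    if (n_sib < 3) next
    Ls <- sb$L; Ys <- sb$Y; Yus <- sb$Y * sb$frac_u; etas <- sb$eta
    inds <- sb$induced
    tt <- Lv <- Nv <- numeric(0)
    for (s in t0_step:(t0_step + n_sib)) {
      base_s <- base_of(inds)
      lam <- base_s * exp(etas - sd_ou^2 / 2)
      tt <- c(tt, times[s + 1])
      Lv <- c(Lv, Ls * exp(stats::rnorm(1, 0, cfg$length_cv)))
      Nv <- c(Nv, if ((s %% n_per_fluor) == 0)
        Yus * vol_of(Ls) * MOLE_PER_UM_FL *
          exp(stats::rnorm(1, 0, cfg$fluor_cv)) else NA_real_)
      if ((s %% n_per_fluor) == 0)
        Yus <- Yus * (1 - cfg$bleach_per_exposure)
      prs <- production_rate(Ys, lam, base_s)
      Ys <- max(Ys + cfg$dt_phase * (prs - lam * Ys), 0)
      Yus <- max(Yus + cfg$dt_phase * (prs - lam * Yus), 0)
      Ls <- Ls * exp(lam * cfg$dt_phase)
      etas <- a_ou * etas + stats::rnorm(1, 0, s_ou)
      inds <- (Ys * vol_of(Ls) * MOLE_PER_UM_FL) > cfg$n_switch_threshold
      if (Ls >= cfg$div_length) break
    }
    mother_id <- sprintf("ch%02d_c%03d", sb$channel, sb$mother_cell)
    id <- sprintf("ch%02d_c%03d_sib", sb$channel, sb$mother_cell)
    if (length(tt) >= 3 && !is.null(cells[[mother_id]])) {
      cells[[id]] <- cell_record(id, mother_id, tt, Lv, Nv)
      cells[[mother_id]]$daughters <- c(cells[[mother_id]]$daughters, id)
    }
  }

  # truth: switch events from the noise-free series, per channel
  truth_events <- vector("list", nc)
  truth_series <- vector("list", nc)
  for (j in seq_len(nc)) {
    ser <- data.frame(time = times, production = true_q[, j],
                      concentration = true_c[, j],
                      growth_dbl = true_lam[, j])
    truth_series[[j]] <- ser
    truth_events[[j]] <- detect_switches(ser)
  }
  list(cells = cells,
       truth = list(events = truth_events, series = truth_series,
                    cell_state = do.call(rbind, cell_state),
                    beta = beta_cont))
}
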