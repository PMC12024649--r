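make_exp_cell <- function(id = "c1", dbl = 1, L0 = 2, hours = 1,
                          dt = 0.05, fluor = NULL, parent = NA_character_) {
  tt <- seq(0, hours, by = dt)
  L <- L0 * 2^(dbl * tt)
  if (is.null(fluor)) fluor <- rep(NA_real_, length(tt))
  cell_record(id, parent, tt, L, fluor)
}

test_that("cell growth rates come from log-length regression with a 10-frame filter", {
  cell <- make_exp_cell(dbl = 1, hours = 1)   # doubles over one hour
  g <- cell_growth_rate(cell)
  expect_true(g$ok)
  expect_equal(g$lam_dbl, 1, tolerance = 1e-12)
  nine <- make_exp_cell(hours = 0.4)          # 9 frames
  expect_equal(length(nine$time), 9)
  r <- cell_growth_rate(nine)
  expect_false(r$ok)
  set.seed(3)
  hits <- 0
  for (i in 1:400) {
    tt <- seq(0, 0.5, by = 0.05)
    L <- 2 * 2^(0.5 * tt) * exp(stats::rnorm(length(tt), 0, 0.01))
    g <- cell_growth_rate(cell_record("x", NA, tt, L))
    if (abs(g$lam_dbl - 0.5) <= 2 * g$lam_se) hits <- hits + 1
  }
  expect_gte(hits / 400, 0.93)
})

test_that("bleach correction follows c = c_u (1 + beta/lambda)", {
  expect_equal(bleach_correct(10, 0, 0.5), 10)
  expect_equal(bleach_correct(10, 0.5, 0.5), 20)
  expect_error(bleach_correct(10, 0.1, 0), "positive")
})

test_that("bleach-corrected concentrations match the generator's ground truth", {
  # low glucose: the whole population induces and reaches steady expression
  gen <- gen_lineage_dataset(lineage_gen_config(
    calibrated_lac(), glucose_uM = 2, n_channels = 12, duration_h = 18,
    seed = 5))
  beta <- gen$truth$beta
  ids <- names(gen$cells)
  ids <- ids[!grepl("_sib$", ids)]
  est <- truth <- numeric(0)
  for (id in ids) {
    cl <- gen$cells[[id]]
    if (cl$time[1] < 10 || length(cl$time) < 10) next
    e <- estimate_instantaneous(cl, beta = beta)
    est <- c(est, mean(e$concentration, na.rm = TRUE))
    ch <- as.integer(sub("^ch(\\d+)_.*$", "\\1", id))
    ser <- gen$truth$series[[ch]]
    rows <- ser$time >= cl$time[1] & ser$time <= cl$time[length(cl$time)]
    truth <- c(truth, mean(ser$concentration[rows]))
  }
  expect_gt(length(est), 30)
  expect_equal(mean(est), mean(truth), tolerance = 0.03)
  # without the correction the bleaching bias is visible
  est_u <- vapply(ids[1:20], function(id) {
    cl <- gen$cells[[id]]
    if (length(cl$time) < 10) return(NA_real_)
    mean(estimate_instantaneous(cl, beta = 0)$concentration, na.rm = TRUE)
  }, 0)
  expect_lt(mean(est_u, na.rm = TRUE), mean(truth))
})

test_that("trace classification applies the 250-molecule and 5/95% rules", {
  low <- make_exp_cell(fluor = rep(10, 21))
  expect_equal(classify_trace(low), "uninduced")
  hi <- make_exp_cell(fluor = rep(1e4, 21))
  expect_equal(classify_trace(hi), "induced")
  half <- make_exp_cell(fluor = c(rep(10, 10), rep(1e4, 11)))
  expect_equal(classify_trace(half), "mixed")
  # frames exactly at the threshold are not "above" it
  at <- make_exp_cell(fluor = rep(250, 21))
  expect_equal(classify_trace(at), "uninduced")
  just <- make_exp_cell(fluor = rep(251, 21))
  expect_equal(classify_trace(just), "induced")
  # exactly 5% induced frames stays uninduced; one more frame is mixed
  f20 <- make_exp_cell(hours = 0.95, fluor = c(rep(1e4, 1), rep(10, 19)))
  expect_equal(classify_trace(f20), "uninduced")
  f20b <- make_exp_cell(hours = 0.95, fluor = c(rep(1e4, 2), rep(10, 18)))
  expect_equal(classify_trace(f20b), "mixed")
})

test_that("instantaneous estimates are flat for deterministic growth", {
  lam <- dbl_to_lam(0.8)
  tt <- seq(0, 1.5, by = 0.05)
  L <- 2 * exp(lam * tt)
  V <- spherocylinder_volume(L, 0.9)
  q <- 500                                  # molecules per um^3 per hour
  F_tot <- c(0, cumsum((V[-1] + V[-length(V)]) / 2 * q * diff(tt)))
  F_tot <- F_tot + 200
  cell <- cell_record("c", NA, tt, L, F_tot)
  est <- estimate_instantaneous(cell, w = 5, diameter = 0.9)
  mid <- 5:(length(tt) - 4)
  expect_true(all(abs(est$growth_dbl[mid] - 0.8) < 0.02 * 0.8))
  expect_true(all(abs(est$production[mid] - q) < 0.02 * q))
  expect_equal(est$concentration, F_tot / V, tolerance = 0.2)
  # zero fluorescence increments mean zero production
  cell0 <- cell_record("c0", NA, tt, L, rep(300, length(tt)))
  est0 <- estimate_instantaneous(cell0)
  expect_true(all(abs(est0$production[mid]) < 1e-9))
  expect_error(estimate_instantaneous(cell, w = 4), "odd")
})

test_that("divisions do not produce growth-rate spikes in lineage traces", {
  lam <- dbl_to_lam(1)
  tt1 <- seq(0, 1, by = 0.05)
  parent <- cell_record("p", NA, tt1, 2 * exp(lam * tt1),
                        1000 * exp(lam * tt1), daughters = c("f"))
  tt2 <- seq(1.05, 2, by = 0.05)
  focal <- cell_record("f", "p", tt2, 2 * exp(lam * (tt2 - 1.05)),
                       1000 * exp(lam * (tt2 - 1.05)))
  tr <- lineage_trace(list(p = parent, f = focal), "f")
  expect_true(all(abs(tr$growth_dbl - 1) < 0.05, na.rm = TRUE))
  expect_equal(unique(tr$part), c("parent", "focal"))
})

test_that("daughter averages are appended and truncated at the shorter daughter", {
  lam <- dbl_to_lam(1)
  tt <- seq(0, 1, by = 0.05)
  mk <- function(id, n, L0) cell_record(id, "f", tt[seq_len(n)] + 2,
                                        L0 * exp(lam * tt[seq_len(n)]),
                                        500 * exp(lam * tt[seq_len(n)]))
  focal <- cell_record("f", NA, tt + 1, 2 * exp(lam * tt),
                       800 * exp(lam * tt), daughters = c("d1", "d2"))
  cells <- list(f = focal, d1 = mk("d1", 21, 2), d2 = mk("d2", 15, 2.2))
  tr <- lineage_trace(cells, "f")
  expect_equal(sum(tr$part == "daughters"), 15)
})

test_that("switch detection follows the quadrant path semantics", {
  th <- 5.5
  lo <- exp(4); hi <- exp(7)
  tt <- seq(0, 3, by = 0.15)
  n <- length(tt)
  # blue -> green -> yellow: production leads, concentration follows
  prod <- c(rep(lo, 6), rep(hi, n - 6))
  conc <- c(rep(lo, 12), rep(hi, n - 12))
  tr <- data.frame(time = tt, production = prod, concentration = conc,
                   growth_dbl = 1)
  ev <- detect_switches(tr, th)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "on")
  # timed at the production crossing, not the concentration crossing
  expect_lt(abs(ev$t_switch - mean(tt[5:6])), 0.16)
  # blue -> green -> blue is an excursion, not a switch
  prod2 <- c(rep(lo, 6), rep(hi, 6), rep(lo, n - 12))
  tr2 <- data.frame(time = tt, production = prod2, concentration = lo,
                    growth_dbl = 1)
  expect_equal(nrow(detect_switches(tr2, th)), 0)
  # constant uninduced trace: nothing to report
  tr3 <- data.frame(time = tt, production = lo, concentration = lo,
                    growth_dbl = 1)
  expect_equal(nrow(detect_switches(tr3, th)), 0)
  # the mirrored path is an off-switch
  tr4 <- data.frame(time = tt, production = rev(prod),
                    concentration = rev(conc), growth_dbl = 1)
  ev4 <- detect_switches(tr4, th)
  expect_equal(ev4$direction, "off")
})

test_that("transition occupancy groups lineage fates correctly", {
  th <- 5.5
  lo <- exp(4); hi <- exp(7)
  tt <- seq(0, 3, by = 0.15); n <- length(tt)
  conc <- c(rep(lo, 12), rep(hi, n - 12))
  prod <- c(rep(lo, 6), rep(hi, n - 6))
  tr <- data.frame(time = tt, production = prod, concentration = conc,
                   growth_dbl = 0.4)
  occ <- transition_occupancy(tr, th, "prod_high")
  expect_equal(occ$fate, "switched")
  expect_equal(occ$growth_dbl, 0.4)
  prod2 <- c(rep(lo, 6), rep(hi, 6), rep(lo, n - 12))
  tr2 <- data.frame(time = tt, production = prod2, concentration = lo,
                    growth_dbl = 0.9)
  occ2 <- transition_occupancy(tr2, th, "prod_high")
  expect_equal(occ2$fate, "returned")
})

test_that("the Welch comparison is exact, calibrated and powered", {
  # two identical groups give t = 0 exactly
  g <- c(0.4, 0.5, 0.6, 0.7)
  r0 <- compare_switcher_growth(g, g, "on")
  expect_equal(r0$t, 0)
  expect_equal(r0$delta_median, 0)
  expect_error(compare_switcher_growth(0.5, g, "on"), "at least 2")
  # type-I error at the nominal 5% level
  set.seed(8)
  rej <- 0
  for (i in 1:1000) {
    a <- stats::rnorm(40, 0.6, 0.1); b <- stats::rnorm(40, 0.6, 0.1)
    if (compare_switcher_growth(a, b, "on")$p_value < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 1000, 0.03)
  expect_lt(rej / 1000, 0.07)
  # power: a 20% growth deficit is detected with n = 100 per group
  pow <- 0
  for (i in 1:200) {
    sw <- stats::rnorm(100, 0.8 * 0.6, 0.1)
    ns <- stats::rnorm(100, 0.6, 0.1)
    r <- compare_switcher_growth(sw, ns, "on")
    if (r$p_value < 0.05 && r$t < 0) pow <- pow + 1
  }
  expect_gte(pow / 200, 0.9)
})
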