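make_logistic_series <- function(dbl = 0.5, od0 = 0.002, od_max = 0.9,
                                 kappa = 40, hours = 16, dt = 4 / 60,
                                 od_bg = 0, sig_bg = 0) {
  tt <- seq(0, hours, by = dt)
  g <- exp(dbl_to_lam(dbl) * tt)
  od <- od_max * od0 * g / (od_max + od0 * (g - 1))
  plate_series(tt, od + od_bg, kappa * od + sig_bg)
}

test_that("background estimation uses the 20-point window at the minimum", {
  s <- plate_series(seq_len(60) / 10, rep(3, 60), rep(7, 60))
  bc <- background_correct(s)
  expect_true(all(abs(bc$od600) < 1e-12))
  expect_true(all(abs(bc$signal) < 1e-12))
  # minimum near the left edge: the window is clipped to the first 20 points
  v <- c(5, 4, 3, 2, 30:85)
  s2 <- plate_series(seq_along(v) / 10, v, v)
  expect_equal(background_correct(s2)$od600[1], 5 - mean(v[1:20]))
  expect_error(background_correct(plate_series(1:10, 1:10, 1:10)),
               "20 time points")
})

test_that("a known background is removed to within the window bias", {
  s <- make_logistic_series(od_bg = 0.07, sig_bg = 12)
  bc <- background_correct(s)
  clean <- make_logistic_series()
  # during the lag the corrected OD is near zero, not near 0.07
  expect_lt(abs(bc$od600[1] - clean$od600[1]), 0.005)
  expect_lt(abs(bc$signal[1] - clean$signal[1]), 0.5)
})

test_that("growth segments follow the three acceptance rules", {
  s <- background_correct(make_logistic_series(od_bg = 0.05, sig_bg = 5))
  seg <- find_growth_segment(s)
  expect_true(seg$ok)
  idx <- seg$start:seg$end
  od_max <- max(s$od600)
  expect_true(all(s$od600[idx] > 0.01 & s$od600[idx] < od_max / 3 &
                    s$signal[idx] > 0))
  # the point just before the segment violates a rule (or is the start)
  if (seg$start > 1) {
    prev <- seg$start - 1
    expect_false(s$od600[prev] > 0.01 && s$od600[prev] < od_max / 3 &&
                   s$signal[prev] > 0)
  }
  # hand-walked boundary: the segment is exactly the qualifying run
  before_peak <- seq_len(which.max(s$od600))
  qual <- before_peak[s$od600[before_peak] > 0.01 &
                        s$od600[before_peak] < od_max / 3 &
                        s$signal[before_peak] > 0]
  expect_equal(idx, qual)
})

test_that("segments shorter than 21 points are rejected, as are dead signals", {
  # constructed curve whose qualifying run is exactly 20 points
  run20 <- 0.012 * 1.17^(0:19)            # all inside (0.01, 0.3)
  od <- c(rep(0.004, 6), run20, 0.45, 0.7, 0.9)
  tt <- seq_along(od) / 10
  s20 <- plate_series(tt, od, rep(1, length(od)))
  r <- find_growth_segment(s20)
  expect_false(r$ok)
  expect_match(r$reason, "21-point")
  # one more qualifying point reaches the minimum
  od21 <- c(rep(0.004, 6), 0.0103, run20, 0.45, 0.7, 0.9)
  s21 <- plate_series(seq_along(od21) / 10, od21, rep(1, length(od21)))
  expect_true(find_growth_segment(s21)$ok)
  # zero signal everywhere: no qualifying points at all
  s0 <- make_logistic_series()
  s0$signal <- rep(0, length(s0$signal))
  expect_false(find_growth_segment(s0)$ok)
})

test_that("segment growth rates are exact on clean exponentials", {
  tt <- seq(0, 4, by = 0.1)
  s <- plate_series(tt, 0.02 * 2^tt, rep(1, length(tt)))
  seg <- list(ok = TRUE, start = 1, end = length(tt))
  g <- growth_rate_of_segment(s, seg)
  expect_equal(g$lam_dbl, 1, tolerance = 1e-12)
  expect_lt(g$lam_se, 1e-12)
  se <- plate_series(tt, 0.02 * exp(tt), rep(1, length(tt)))
  expect_equal(growth_rate_of_segment(se, seg)$lam_dbl, 1 / log(2),
               tolerance = 1e-12)
})

test_that("noisy growth-rate estimates are within 2 SE at near-nominal rate", {
  set.seed(4)
  tt <- seq(0, 5, by = 4 / 60)
  hits <- 0
  n_sim <- 400
  for (i in seq_len(n_sim)) {
    od <- 0.02 * 2^(0.5 * tt) * exp(stats::rnorm(length(tt), 0, 0.02))
    s <- plate_series(tt, od, rep(1, length(tt)))
    g <- growth_rate_of_segment(s, list(ok = TRUE, start = 1,
                                        end = length(tt)))
    if (abs(g$lam_dbl - 0.5) <= 2 * g$lam_se) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.93)
})

test_that("Miller activity implements A = 1000 s / (0.5 OD600)", {
  tt <- seq(0, 1, by = 1 / 60)            # one hour, 1-min sampling
  expect_equal(miller_activity(tt, rep(0.2, length(tt)), 0.3), 0)
  # slope 0.01 per minute at OD 0.2 gives 100 Miller units
  expect_equal(miller_activity(tt, 0.05 + 0.01 * tt * 60, 0.2), 100,
               tolerance = 1e-9)
  # a 40-minute initial decline is discarded before the slope is taken
  tt2 <- seq(0, 2, by = 1 / 60)
  dec <- ifelse(tt2 < 40 / 60, 0.3 - 0.1 * tt2, 0.3 - 0.1 * 40 / 60 +
                  0.012 * (tt2 - 40 / 60) * 60)
  expect_equal(miller_activity(tt2, dec, 0.2), 1000 * 0.012 / (0.5 * 0.2),
               tolerance = 1e-6)
  # monotone decline throughout the first hour is an error
  expect_error(miller_activity(tt, 0.3 - 0.1 * tt, 0.2), "decreasing")
})

test_that("promoter activity is Miller activity times the doubling rate", {
  expect_equal(promoter_activity(100, 0.5), 50)
  expect_equal(promoter_activity(42, 1), 42)
  expect_error(promoter_activity(10, 0), "positive")
})

test_that("promoter activity recovers the generator's production rate", {
  # steady state: expression per biomass = activity / dilution, so the
  # assays chain activity = exp(y) * lambda must return the true activity
  cfg <- plate_gen_config(default_plate_conditions()[c(2, 5), ],
                          tmg_grid = c(50), replicates = 2,
                          od_cv = 0.01, signal_cv = 0.02, seed = 9)
  gen <- gen_plate_dataset(cfg)
  for (i in seq_along(gen$wells)) {
    pw <- process_well(gen$wells[[i]])
    expect_true(pw$ok)
    expect_equal(pw$activity, gen$truth$alpha[i], tolerance = 0.05)
  }
})

test_that("sliding windows reproduce constant expression ratios exactly", {
  s <- make_logistic_series(kappa = 40)
  seg <- find_growth_segment(s)
  est <- expression_sliding_windows(s, seg)
  expect_equal(est$y_expr, log(40), tolerance = 1e-9)
  expect_lt(est$y_se, 1e-6)
  expect_error(expression_sliding_windows(s, seg, w = 10000), "shorter")
})

test_that("windowed and whole-segment estimates agree in balanced growth", {
  set.seed(12)
  tt <- seq(0, 6, by = 4 / 60)
  od <- 0.05 * 2^(0.6 * tt) * exp(stats::rnorm(length(tt), 0, 0.02))
  sig <- 30 * 0.05 * 2^(0.6 * tt) * exp(stats::rnorm(length(tt), 0, 0.03))
  s <- plate_series(tt, od, sig)
  seg <- list(ok = TRUE, start = 1, end = length(tt))
  est <- expression_sliding_windows(s, seg)
  whole_y <- mean(log(sig) - log(od))
  whole_l <- unname(stats::coef(stats::lm(log2(od) ~ tt))[2])
  expect_equal(est$y_expr, whole_y, tolerance = 0.01)
  expect_equal(est$lam_dbl, whole_l, tolerance = 0.05)
})

test_that("background correction does not move the segment of a clean curve", {
  s <- make_logistic_series(od0 = 2e-4)     # zero true background
  seg_raw <- find_growth_segment(s)
  seg_bc <- find_growth_segment(background_correct(s))
  expect_true(seg_raw$ok && seg_bc$ok)
  # the estimated background (~ the inoculum OD) may shift the 0.01-OD
  # boundary by at most a point or two
  expect_lte(abs(seg_raw$start - seg_bc$start), 2)
  expect_lte(abs(seg_raw$end - seg_bc$end), 2)
})

test_that("the full bulk pipeline recovers induction thresholds within 15%", {
  conds <- default_plate_conditions()[c(1, 4, 7), ]
  cfg <- plate_gen_config(conds, replicates = 2, seed = 31)
  gen <- gen_plate_dataset(cfg)
  for (ci in seq_len(nrow(conds))) {
    sel <- which(gen$truth$media == conds$media[ci])
    act <- conc <- sig <- numeric(0)
    for (i in sel) {
      pw <- process_well(gen$wells[[i]])
      if (!pw$ok) next
      act <- c(act, pw$activity)
      sig <- c(sig, max(pw$activity_se, 0.02 * pw$activity))
      conc <- c(conc, gen$truth$tmg_uM[i])
    }
    fit <- fit_hill(induction_curve(conc, act, sig))
    expect_equal(fit$k, conds$k[ci], tolerance = 0.15)
  }
})

test_that("Miller and fluorimetry pipelines give concordant thresholds", {
  conds <- default_plate_conditions()
  cfg <- plate_gen_config(conds, replicates = 1, seed = 17)
  gen <- gen_plate_dataset(cfg)
  set.seed(17)
  k_fluor <- k_miller <- rep(NA_real_, nrow(conds))
  tt_m <- seq(0, 1, by = 1 / 60)
  for (ci in seq_len(nrow(conds))) {
    sel <- which(gen$truth$media == conds$media[ci])
    act_f <- act_m <- conc <- sig_f <- numeric(0)
    for (i in sel) {
      pw <- process_well(gen$wells[[i]])
      if (!pw$ok) next
      conc <- c(conc, gen$truth$tmg_uM[i])
      act_f <- c(act_f, pw$activity)
      sig_f <- c(sig_f, max(pw$activity_se, 0.02 * pw$activity))
      # Miller route: OD420 kinetics with slope proportional to enzyme per
      # biomass = alpha / lambda, assayed at OD600 = 0.2
      A_true <- gen$truth$alpha[i] / gen$truth$dbl_rate[i]
      slope_min <- A_true * 0.5 * 0.2 / 1000
      od420 <- 0.1 + slope_min * tt_m * 60 *
        exp(stats::rnorm(length(tt_m), 0, 0.01))
      A <- miller_activity(tt_m, od420, 0.2)
      act_m <- c(act_m, promoter_activity(A, pw$lam_dbl))
    }
    f_f <- fit_hill(induction_curve(conc, act_f, sig_f))
    f_m <- fit_hill(induction_curve(conc, pmax(act_m, 1e-6),
                                    pmax(0.05 * act_m, 1e-6)))
    k_fluor[ci] <- f_f$k
    k_miller[ci] <- f_m$k
  }
  expect_equal(order(k_fluor), order(k_miller))
  expect_gt(stats::cor(log(k_fluor), log(k_miller)), 0.9)
})
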