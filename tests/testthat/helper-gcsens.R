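# shared fixtures and small oracles used across test files

ctx_T <- function(T, delta = 0) growth_context(doubling_time = T, delta = delta)

# the calibrated lac model used in lineage-generator tests (C-line tracking
# the default lactose Monod curve; values from calibrate_cline at defaults)
calibrated_lac <- function() lac_model(y_h_mode = "c_line", y0 = 46.4,
                                       lam_star = 0.72)

# closed-form expected log10-log10 slope of the lac critical curve with
# constant full-induction production: s_center is proportional to
# (lam + delta)^2, so the OLS slope over a doubling-time grid follows from
# the exact relation (independent of the numerical boundary machinery)
closed_form_lac_slope <- function(t_grid, delta) {
  y <- 2 * log10(log(2) / t_grid + delta)
  unname(stats::coef(stats::lm(y ~ log10(t_grid)))[2])
}

# greedy matching of detected switch events against ground-truth events
match_switch_events <- function(det, truth, tol_h = 0.75) {
  tp <- 0L
  terr <- numeric(0)
  if (!is.null(truth) && nrow(truth) > 0 && nrow(det) > 0) {
    used <- rep(FALSE, nrow(det))
    for (i in seq_len(nrow(truth))) {
      cand <- which(!used & det$channel == truth$channel[i] &
                      det$direction == truth$direction[i] &
                      abs(det$t_switch - truth$t_switch[i]) < tol_h)
      if (length(cand)) {
        j <- cand[which.min(abs(det$t_switch[cand] - truth$t_switch[i]))]
        used[j] <- TRUE
        tp <- tp + 1L
        terr <- c(terr, abs(det$t_switch[j] - truth$t_switch[i]))
      }
    }
  }
  n_truth <- if (is.null(truth)) 0L else nrow(truth)
  list(tp = tp, n_det = nrow(det), n_truth = n_truth,
       precision = if (nrow(det) > 0) tp / nrow(det) else NA_real_,
       recall = if (n_truth > 0) tp / n_truth else NA_real_,
       t_err = terr)
}

flatten_truth_events <- function(gen) {
  do.call(rbind, lapply(seq_along(gen$truth$events), function(ch) {
    e <- gen$truth$events[[ch]]
    if (nrow(e)) e$channel <- ch
    e
  }))
}
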