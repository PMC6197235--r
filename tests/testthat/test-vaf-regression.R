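eligibility_table <- function(kinds) {
  # kinds: list of per-trial character vectors of "s" (sample) / "t" (target)
  rows <- list()
  for (tid in seq_along(kinds)) {
    k <- kinds[[tid]]
    for (f in seq_along(k)) {
      rows[[length(rows) + 1L]] <- data.frame(
        trial_id = tid, flash_index = f, is_target = k[f] == "t",
        is_cue_trial = FALSE, outcome = if (k[f] == "t") "hit" else "none",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("eligible flashes are samples preceded by a sample on the same trial", {
  fl <- eligibility_table(list(c("s", "s", "t")))
  expect_equal(select_eligible_flashes(fl), 2L)
  fl2 <- eligibility_table(list(c("s", "t")))
  expect_equal(length(select_eligible_flashes(fl2)), 0L)
  fl3 <- eligibility_table(list(c("s", "s", "s", "s", "s")))
  expect_equal(select_eligible_flashes(fl3), 2:5)
  # cue trials excluded
  fl4 <- eligibility_table(list(c("s", "s", "s")))
  fl4$is_cue_trial <- TRUE
  expect_equal(length(select_eligible_flashes(fl4)), 0L)
})

two_flash_session <- function(burst_unit = "u01", n_trials = 6) {
  flashes <- do.call(rbind, lapply(seq_len(n_trials), function(tid) {
    data.frame(
      session_id = "sr", trial_id = tid, flash_index = 1:3,
      onset_ms = c(400L, 1200L, 2000L), is_cue_trial = FALSE,
      cue_location = "RF", stimulus_locations = "bilateral",
      orientation_RF = 45, is_target = c(FALSE, FALSE, TRUE),
      target_location = c("none", "none", "RF"),
      delta_orientation = c(0, 0, 3), outcome = c("none", "none", "hit"),
      response_time_ms = c(NA, NA, 250), stringsAsFactors = FALSE)
  }))
  units <- data.frame(unit_id = c("u01", "u02"), snr = NA_real_,
                      stringsAsFactors = FALSE)
  sp <- list()
  for (tid in seq_len(n_trials)) {
    base <- seq(10, 2900, by = 40)  # ~25 sp/s baseline for both units
    sp[[length(sp) + 1L]] <- data.frame(unit_id = "u01", trial_id = tid,
                                        time_ms = as.integer(base))
    sp[[length(sp) + 1L]] <- data.frame(unit_id = "u02", trial_id = tid,
                                        time_ms = as.integer(base + 3))
    burst <- as.integer(1200 + seq(40, 120, by = 4))  # burst after flash 2
    sp[[length(sp) + 1L]] <- data.frame(unit_id = burst_unit, trial_id = tid,
                                        time_ms = burst)
  }
  session_data(flashes, do.call(rbind, sp), units)
}

test_that("stimulus-response axis points at the responding unit and is scale invariant", {
  ses <- two_flash_session()
  ax <- fit_stimulus_response_axis(ses)
  # u02 contributes only baseline ripple, so the axis is essentially e1
  expect_gt(ax[["u01"]], 0.99)
  expect_lt(abs(ax[["u02"]]), 0.12)
  expect_gt(attr(ax, "t_star_ms"), 20)
  expect_lt(attr(ax, "t_star_ms"), 160)

  # doubling all counts leaves the direction unchanged
  ses2 <- ses
  ses2$spikes <- rbind(ses2$spikes, ses2$spikes)
  ax2 <- fit_stimulus_response_axis(ses2)
  expect_equal(as.numeric(ax2), as.numeric(ax), tolerance = 1e-8)
})

test_that("the trajectory peak lands at the smoothed template transient", {
  gen <- small_session()
  cfg <- small_config()
  ax <- fit_stimulus_response_axis(gen$session)
  # oracle: smoothed deviation-from-baseline of the rate template
  tau <- 0:399
  psi <- cfg$psth_sustained_amp * (tau >= cfg$psth_sustained_onset) +
    cfg$psth_transient_amp *
    exp(-(tau - cfg$psth_transient_latency)^2 / (2 * cfg$psth_transient_width^2))
  v <- c(numeric(100), psi, numeric(200))  # [-100, 600) around onset
  sm <- smooth_spike_train(v, 20)
  oracle_t <- (-100:599)[which.max(sm)]
  expect_lt(abs(attr(ax, "t_star_ms") - oracle_t), 10)
})

test_that("two-step VAF matches its closed forms in degenerate and random cases", {
  set.seed(7)
  n <- 40
  a_post <- rnorm(n)
  r <- outer(rep(2, 5), a_post - mean(a_post))  # r_t = 2 * centered a_post
  v <- two_step_vaf(r, a_post, rnorm(n))
  expect_equal(v$vaf_post, rep(1, 5), tolerance = 1e-12)
  expect_equal(v$vaf_pre, rep(0, 5), tolerance = 1e-10)

  # response along a pre predictor orthogonal to a_post in sample
  a_post2 <- rnorm(n); a_post2 <- a_post2 - mean(a_post2)
  a_pre2 <- rnorm(n); a_pre2 <- a_pre2 - mean(a_pre2)
  a_pre2 <- a_pre2 - sum(a_pre2 * a_post2) / sum(a_post2^2) * a_post2
  r2 <- outer(rep(1, 4), a_pre2)
  v2 <- two_step_vaf(r2, a_post2, a_pre2)
  expect_equal(v2$vaf_post, rep(0, 4), tolerance = 1e-12)
  expect_equal(v2$vaf_pre, rep(1, 4), tolerance = 1e-12)

  expect_error(two_step_vaf(r2, rep(1, n), a_pre2), "zero-variance")
})

test_that("beta and VAF agree with an independent least-squares oracle", {
  set.seed(17)
  n <- 50
  r <- matrix(rnorm(6 * n), nrow = 6)
  a_post <- rnorm(n); a_pre <- rnorm(n)
  v <- two_step_vaf(r, a_post, a_pre)
  rc <- r - rowMeans(r)
  ap <- a_post - mean(a_post); aq <- a_pre - mean(a_pre)
  for (t in 1:6) {
    fit1 <- stats::lm(rc[t, ] ~ 0 + ap)
    expect_equal(v$beta_post[t], unname(stats::coef(fit1)), tolerance = 1e-10)
    vaf1 <- 1 - sum(stats::resid(fit1)^2) / sum(rc[t, ]^2)
    expect_equal(v$vaf_post[t], vaf1, tolerance = 1e-10)
    fit2 <- stats::lm(stats::resid(fit1) ~ 0 + aq)
    vaf2 <- 1 - sum(stats::resid(fit2)^2) / sum(stats::resid(fit1)^2)
    expect_equal(v$vaf_pre[t], vaf2, tolerance = 1e-10)
  }
  expect_true(all(v$vaf_post >= 0 & v$vaf_post <= 1))
  expect_true(all(v$vaf_pre >= 0 & v$vaf_pre <= 1))
})

test_that("sequential VAF equals the joint two-predictor fit for orthogonal predictors", {
  set.seed(27)
  n <- 60
  ap <- rnorm(n); ap <- ap - mean(ap)
  aq <- rnorm(n); aq <- aq - mean(aq)
  aq <- aq - sum(aq * ap) / sum(ap^2) * ap  # sample-orthogonal
  r <- matrix(rnorm(4 * n), nrow = 4)
  v <- two_step_vaf(r, ap, aq)
  rc <- r - rowMeans(r)
  for (t in 1:4) {
    joint <- stats::lm(rc[t, ] ~ 0 + ap + aq)
    r2 <- 1 - sum(stats::resid(joint)^2) / sum(rc[t, ]^2)
    total <- v$vaf_post[t] + (1 - v$vaf_post[t]) * v$vaf_pre[t]
    expect_equal(total, r2, tolerance = 1e-10)
  }
})

test_that("shuffled null approaches 1/(n-1) and flags the degenerate n = 2 case", {
  set.seed(37)
  n <- 80
  r <- matrix(rnorm(3 * n), nrow = 3)
  nul <- shuffled_null_vaf(r, rnorm(n), rnorm(n), n_shuffles = 400)
  expect_equal(nul$theory, 1 / (n - 1), tolerance = 1e-12)
  expect_lt(abs(nul$null - nul$theory), 3 * nul$theory)
  expect_error(shuffled_null_vaf(r[, 1:2], rnorm(2), rnorm(2), 10), "n = 2")
})

test_that("run-length threshold is small for white noise and grows with autocorrelation", {
  set.seed(47)
  make_vaf <- function(phi, S = 8, T = 400) {
    t(vapply(seq_len(S), function(i) {
      as.numeric(stats::filter(rnorm(T), phi, method = "recursive"))
    }, numeric(T)))
  }
  th0 <- runlength_threshold(make_vaf(0.01), n_sims = 300, seed = 1)$threshold
  th5 <- runlength_threshold(make_vaf(0.5), n_sims = 300, seed = 1)$threshold
  th9 <- runlength_threshold(make_vaf(0.9), n_sims = 300, seed = 1)$threshold
  expect_lte(th0, 4)
  expect_lte(th0, th5)
  expect_lte(th5, th9)
  expect_gt(th9, 4)
})

test_that("significance mask requires runs and erases isolated points", {
  S <- 8; T <- 300
  flat <- matrix(0.01, nrow = S, ncol = T)
  m0 <- significance_mask(flat, 0.01, run_threshold = 20)
  expect_false(any(m0$mask))

  set.seed(57)
  noisy <- matrix(rnorm(S * T, 0.01, 1e-4), nrow = S, ncol = T)
  noisy[, 150] <- noisy[, 150] + 1  # one isolated significant millisecond
  m1 <- significance_mask(noisy, 0.01, run_threshold = 20)
  expect_false(any(m1$mask))
  m2 <- significance_mask(noisy, 0.01, run_threshold = 1)
  expect_true(m2$mask[150])
  expect_error(significance_mask(noisy, 0.01, 0), "run_threshold")
})

test_that("pre-axis VAF peaks on the onset transient, post-axis later", {
  set.seed(67)
  mats <- lapply(1:6, function(i) {
    gen <- generate_session(small_config())
    ses <- gen$session
    proj <- cross_validated_projections(ses, n_folds = 25)
    series <- stimulus_response_series(ses)
    pred <- align_projection_predictors(series, proj$records, ses$flashes)
    two_step_vaf(series, pred$a_post, pred$a_pre)
  })
  vpost <- do.call(rbind, lapply(mats, function(v) v$vaf_post))
  vpre <- do.call(rbind, lapply(mats, function(v) v$vaf_pre))
  t_ms <- mats[[1]]$time_ms
  stim <- t_ms >= 0  # peaks compared within the response window
  peak_pre <- t_ms[stim][which.max(colMeans(vpre)[stim])]
  peak_post <- t_ms[stim][which.max(colMeans(vpost)[stim])]
  expect_lt(peak_pre, 150)
  expect_gt(peak_post, peak_pre)
})
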