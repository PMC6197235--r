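make_rate_session <- function(block_spikes, total_ms = 10000) {
  # one trial spanning total_ms with spikes placed explicitly
  flashes <- data.frame(
    session_id = "rate", trial_id = 1L, flash_index = 1L,
    onset_ms = as.integer(total_ms - 700L), is_cue_trial = FALSE,
    cue_location = "RF", stimulus_locations = "bilateral",
    orientation_RF = 45, is_target = FALSE, target_location = "none",
    delta_orientation = 0, outcome = "none", response_time_ms = NA_real_,
    stringsAsFactors = FALSE
  )
  units <- data.frame(unit_id = "u01", snr = NA_real_, stringsAsFactors = FALSE)
  spikes <- data.frame(unit_id = "u01", trial_id = 1L,
                       time_ms = as.integer(block_spikes), stringsAsFactors = FALSE)
  session_data(flashes, spikes, units)
}

test_that("blockwise CV screening matches hand computation", {
  # session of 10,000 ms; block 1 = [0, 1000): 1 sp/s there, silence after
  ses <- make_rate_session(seq(0, 999, by = 1000 / 1))  # 1 spike in block 1
  # CV of rates (1,0,...,0): mean 0.1, sample SD sqrt(0.1) -> CV = sqrt(10)
  rep1 <- screen_units(ses)
  expect_equal(rep1$cv, sqrt(10), tolerance = 1e-12)
  expect_false(rep1$kept)
  expect_equal(rep1$reason, "unstable")

  # constant-rate unit at 2 sp/s: CV = 0, kept
  ses2 <- make_rate_session(seq(0, 9999, by = 500))
  rep2 <- screen_units(ses2)
  expect_equal(rep2$cv, 0)
  expect_true(rep2$kept)

  # uniform 0.5 sp/s: stable but low rate (2 spikes per 4000 ms block)
  ses3 <- make_rate_session(seq(0, 39999, by = 2000), total_ms = 40000)
  rep3 <- screen_units(ses3)
  expect_false(rep3$kept)
  expect_equal(rep3$reason, "low_rate")
})

test_that("screening is invariant to unit relabeling", {
  gen <- tiny_session()
  ses <- gen$session
  rep1 <- screen_units(ses)
  ses2 <- ses
  perm <- rev(seq_len(nrow(ses$units)))
  relab <- setNames(ses$units$unit_id[perm], ses$units$unit_id)
  ses2$units$unit_id <- unname(relab[ses2$units$unit_id])
  ses2$spikes$unit_id <- unname(relab[ses2$spikes$unit_id])
  rep2 <- screen_units(ses2)
  m <- match(unname(relab[rep1$unit_id]), rep2$unit_id)
  expect_equal(rep2$cv[m], rep1$cv)
  expect_equal(rep2$mean_rate[m], rep1$mean_rate)
})

test_that("visual responsiveness flags driven units and not silent ones", {
  gen <- small_session()
  ses <- gen$session
  # generator units are strongly driven (2x transient + sustained)
  expect_true(test_visual_responsiveness(ses, ses$units$unit_id[1]))
  # a unit with no spikes at all: degenerate windows are skipped
  ghost <- ses
  ghost$units <- rbind(ghost$units, data.frame(unit_id = "zz99", snr = NA_real_))
  expect_false(test_visual_responsiveness(ghost, "zz99"))
})

test_that("normalized PSTH has unit extreme deviation and zero baseline", {
  gen <- small_session()
  ses <- gen$session
  u <- ses$units$unit_id[3]
  psth <- compute_normalized_psth(ses, u)
  resp <- psth$pooled[psth$time_ms >= 0]
  expect_equal(max(abs(resp)), 1, tolerance = 1e-10)
  expect_equal(mean(psth$pooled[psth$time_ms >= -100 & psth$time_ms < 0]), 0,
               tolerance = 1e-10)
  # driven template peaks positive
  expect_equal(max(resp), 1, tolerance = 1e-10)
})

test_that("normalization divisor is condition independent (count scaling)", {
  gen <- tiny_session()
  ses <- gen$session
  u <- ses$units$unit_id[1]
  p1 <- compute_normalized_psth(ses, u)
  # duplicate every spike of that unit (scales counts by 2)
  dup <- ses$spikes[ses$spikes$unit_id == u, ]
  ses2 <- ses
  ses2$spikes <- rbind(ses2$spikes, dup)
  p2 <- compute_normalized_psth(ses2, u)
  expect_equal(p2$divisor, 2 * p1$divisor, tolerance = 1e-10)
  expect_equal(p2$pooled, p1$pooled, tolerance = 1e-8)
})

test_that("purely suppressed units normalize to a trough of -1", {
  # build a unit that is silenced during the stimulus: baseline spikes only
  gen <- tiny_session()
  ses <- gen$session
  fl <- ses$flashes
  tlns <- attnaxes:::session_timeline(ses)
  # spikes everywhere except the stimulus period [0, 400) of every flash:
  # baseline intact, rate fully suppressed during the stimulus
  all_ms <- seq(5, tlns$total - 5, by = 7)
  keep <- rep(TRUE, length(all_ms))
  ons <- tlns$offsets[as.character(fl$trial_id)] + fl$onset_ms
  for (o in ons) keep[all_ms >= o & all_ms < o + 400] <- FALSE
  all_ms <- all_ms[keep]
  tr_ix <- findInterval(all_ms, c(0, cumsum(tlns$durations)))
  supp <- data.frame(unit_id = "supp1",
                     trial_id = tlns$trial_ids[tr_ix],
                     time_ms = as.integer(all_ms - tlns$offsets[tr_ix]),
                     stringsAsFactors = FALSE)
  ses$units <- rbind(ses$units, data.frame(unit_id = "supp1", snr = NA_real_))
  ses$spikes <- rbind(ses$spikes, supp)
  p <- compute_normalized_psth(ses, "supp1")
  resp <- p$pooled[p$time_ms >= 0]
  expect_equal(min(resp), -1, tolerance = 1e-10)
  expect_lt(max(resp), 1)
})

test_that("grand-average comparison masks differences and finds onset timing", {
  t_ms <- seq(-300, 699)
  flat <- list(time_ms = t_ms, cue_rf = rep(0.5, 1000), cue_away = rep(0.5, 1000),
               n_units = 10)
  sessions <- replicate(6, flat, simplify = FALSE)
  g0 <- grand_average_comparison(sessions)
  expect_false(any(g0$significant))
  expect_true(is.na(attr(g0, "earliest_significant_ms")))

  # constant offset in one condition plus tiny session noise -> all significant
  set.seed(9)
  sessions2 <- lapply(1:8, function(i) {
    list(time_ms = t_ms, cue_rf = stats::rnorm(1000, 0, 0.005) + 0.2,
         cue_away = stats::rnorm(1000, 0, 0.005), n_units = 10)
  })
  g1 <- grand_average_comparison(sessions2)
  expect_true(all(g1$significant))
  expect_equal(attr(g1, "earliest_significant_ms"), -300)
  expect_error(grand_average_comparison(sessions2[1]), "at least 2")
})

test_that("post-only modulation concentrates significance in the stimulus period", {
  set.seed(123)
  sessions <- lapply(1:8, function(i) {
    cfg <- small_config(pre_mod_sd = 0, transient_state_coupling = 0)
    session_mean_psth(generate_session(cfg)$session)
  })
  g <- grand_average_comparison(sessions)
  pre_frac <- mean(g$significant[g$time_ms >= -300 & g$time_ms < 0])
  sus_frac <- mean(g$significant[g$time_ms >= 250 & g$time_ms < 400])
  # pre-stimulus significance stays near the nominal 5% false-positive
  # level of the uncorrected per-ms test; sustained-period significance is
  # driven by the injected gain
  expect_lt(pre_frac, 0.25)
  expect_gt(sus_frac, 0.35)
  expect_gt(sus_frac, pre_frac + 0.2)
})
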