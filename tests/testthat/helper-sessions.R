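# Shared fixtures, generated once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, maker(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

tiny_config <- function(...) {
  generator_config(n_units = 12, hits_per_block = 6, n_blocks = 2,
                   cue_trial_hits = 2, ...)
}

small_config <- function(...) {
  generator_config(n_units = 25, hits_per_block = 12, n_blocks = 2,
                   cue_trial_hits = 3, ...)
}

tiny_session <- function() fixture("tiny", function() generate_session(tiny_config(), seed = 101))
small_session <- function() fixture("small", function() generate_session(small_config(), seed = 202))

# Large session for parameter-recovery checks (many training targets).
big_session <- function() {
  fixture("big", function() {
    generate_session(generator_config(n_units = 40, n_blocks = 4,
                                      hits_per_block = 60), seed = 303)
  })
}

# Synthetic projection records for procedure-level statistical checks:
# two flashes per trial (sample then RF target), iid normal projections,
# optional mean shift for hit trials.
make_fake_result <- function(n_targets, shift = 0) {
  tid <- seq_len(n_targets)
  flashes <- data.frame(
    trial_id = rep(tid, each = 2), flash_index = rep(1:2, n_targets),
    is_target = rep(c(FALSE, TRUE), n_targets),
    target_location = rep(c("none", "RF"), n_targets),
    outcome = rep(c("none", NA), n_targets), is_cue_trial = FALSE,
    stringsAsFactors = FALSE
  )
  hit <- stats::runif(n_targets) < 0.6
  flashes$outcome[seq(2, 2 * n_targets, by = 2)] <- ifelse(hit, "hit", "miss")
  records <- data.frame(
    trial_id = flashes$trial_id, flash_index = flashes$flash_index,
    a_pre = stats::rnorm(2 * n_targets) + shift * rep(hit, each = 2),
    a_post = stats::rnorm(2 * n_targets) + shift * rep(hit, each = 2)
  )
  list(records = records, flashes = flashes)
}

# Minimal hand-written session: 1 trial, 2 flashes (sample then target),
# one unit with spikes at known offsets from the flash onsets.
hand_session <- function(spike_times = integer(0), n_units = 1,
                         outcome = "hit") {
  flashes <- data.frame(
    session_id = "hand", trial_id = 1L, flash_index = 1:2,
    onset_ms = c(400L, 1200L), is_cue_trial = FALSE, cue_location = "RF",
    stimulus_locations = "bilateral", orientation_RF = 45,
    is_target = c(FALSE, TRUE), target_location = c("none", "RF"),
    delta_orientation = c(0, 3), outcome = c("none", outcome),
    response_time_ms = c(NA_real_, if (outcome == "hit") 250 else NA_real_),
    stringsAsFactors = FALSE
  )
  units <- data.frame(unit_id = sprintf("u%02d", seq_len(n_units)),
                      snr = NA_real_, stringsAsFactors = FALSE)
  spikes <- data.frame(unit_id = rep("u01", length(spike_times)),
                       trial_id = rep(1L, length(spike_times)),
                       time_ms = as.integer(spike_times),
                       stringsAsFactors = FALSE)
  session_data(flashes, spikes, units)
}
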