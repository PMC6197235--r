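#' Generator configuration for synthetic change-detection sessions
#'
#' Returns the full parameter set of the synthetic session generator. The
#' defaults encode the task as run in the experiments this package targets:
#' a block-cued two-location orientation change-detection task with a
#' uniform per-flash target hazard (30\%), 90\% cue validity, blocks that
#' switch after 80 correct detections, and an initial unilateral cue phase
#' lasting 5 correct detections. Neural defaults give a population of 40
#' units with log-normal baseline rates, a transient+sustained PSTH
#' template, post-stimulus attention gains averaging +9\%, and mixed-sign
#' near-zero-mean pre-stimulus modulations correlated with the gains
#' (Pearson 0.46).
#'
#' A single latent attention state evolves as an AR(1) across trials with a
#' cue-side-dependent mean, plus fast per-interval fluctuations; it drives
#' both the firing-rate modulations and, through a logistic link, the
#' probability of detecting each target.
#'
#' @param ... named overrides of any default field.
#' @return Object of class \code{generator_config} (a named list).
#' @export
generator_config <- function(...) {
  cfg <- list(
    session_id = "synth",
    # task structure
    n_units = 40,
    n_blocks = 2,
    hits_per_block = 80,
    cue_trial_hits = 5,
    p_target_per_flash = 0.3,
    p_valid = 0.9,
    fixation_ms = c(300, 500),
    isi_ms = c(300, 500),
    stimulus_ms = 400,
    valid_deltas = c(1, 3, 6, 15),
    invalid_delta = 3,
    # firing-rate model
    baseline_rate_meanlog = log(8),
    baseline_rate_sdlog = 0.5,
    psth_transient_amp = 2,
    psth_transient_latency = 60,
    psth_transient_width = 15,
    psth_sustained_amp = 1,
    psth_sustained_onset = 40,
    post_gain_mean = 1.09,
    post_gain_sd = 0.15,
    pre_mod_mean = 0,
    pre_mod_sd = 0.15,
    gain_mod_correlation = 0.46,
    transient_state_coupling = 1,
    # latent attention state
    state_mean = 1.25,
    state_ar = 0.7,
    state_sd = 0.3,
    state_fast_sd = 0.35,
    # behavior link
    behavior_intercept = -1,
    behavior_delta_slope = 0.6,
    behavior_attention_slope = 1.5,
    fa_rate = 0.012,
    fa_state_slope = 0.3,
    rt_shift_ms = 100,
    rt_meanlog = log(80),
    rt_sdlog = 0.25,
    rt_attention_slope = 0.15,
    # gain-only control: pre modulation forced collinear with the gains
    gain_only_scale = 0.5,
    max_flashes_per_trial = 200
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown generator_config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(over)] <- over
  check_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

check_generator_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      stop(sprintf("generator_config$%s must be a probability in [0, 1] (got %s)",
                   field, format(v)), call. = FALSE)
    }
  }
  for (f in c("p_target_per_flash", "p_valid", "fa_rate")) chk_prob(f)
  for (f in c("n_units", "n_blocks", "hits_per_block", "cue_trial_hits")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 1 || v != round(v)) {
      stop(sprintf("generator_config$%s must be a positive integer", f), call. = FALSE)
    }
  }
  if (cfg$stimulus_ms <= 0) stop("stimulus_ms must be positive", call. = FALSE)
  if (any(cfg$fixation_ms <= 0) || any(cfg$isi_ms <= 0)) {
    stop("fixation_ms and isi_ms ranges must be positive", call. = FALSE)
  }
  if (abs(cfg$gain_mod_correlation) > 1) {
    stop("gain_mod_correlation must be in [-1, 1]", call. = FALSE)
  }
  invisible(cfg)
}

state_squash <- function(state) (1 + tanh(state)) / 2  # maps R -> (0, 1)

# Core task-sequence simulation. Returns the flash table plus the latent
# per-trial and per-flash attention states that drove it.
simulate_task <- function(cfg) {
  rows <- list()
  trial_states <- list()
  flash_states <- list()
  trial_id <- 0L
  slow <- 0  # AR(1) deviation around the cue-side mean
  ar_innov_sd <- cfg$state_sd * sqrt(1 - cfg$state_ar^2)

  for (block in seq_len(cfg$n_blocks)) {
    cue <- if (block %% 2 == 1) "RF" else "away"
    cue_sign <- if (cue == "RF") 1 else -1
    block_hits <- 0L
    cue_phase_hits <- 0L
    guard <- 0L
    while (block_hits < cfg$hits_per_block) {
      guard <- guard + 1L
      if (guard > 200L * cfg$hits_per_block) {
        stop("task simulation failed to accumulate hits; check behavior link", call. = FALSE)
      }
      trial_id <- trial_id + 1L
      is_cue_trial <- cue_phase_hits < cfg$cue_trial_hits
      slow <- cfg$state_ar * slow + stats::rnorm(1, 0, ar_innov_sd)
      a_trial <- cue_sign * cfg$state_mean + slow
      orientation <- sample(c(45, 135), 1)

      onset <- sample(cfg$fixation_ms[1]:cfg$fixation_ms[2], 1)
      f <- 0L
      repeat {
        f <- f + 1L
        if (f > cfg$max_flashes_per_trial) break
        state_f <- a_trial + stats::rnorm(1, 0, cfg$state_fast_sd)   # ISI/transient state
        state2_f <- a_trial + stats::rnorm(1, 0, cfg$state_fast_sd)  # sustained-response state
        s_f <- tanh(state_f)

        is_target <- if (is_cue_trial) {
          f > 1L && stats::runif(1) < cfg$p_target_per_flash
        } else {
          f > 1L && stats::runif(1) < cfg$p_target_per_flash
        }
        target_loc <- "none"
        delta <- 0
        outcome <- "none"
        rt <- NA_real_

        if (is_target) {
          if (is_cue_trial) {
            target_loc <- cue  # unilateral stimulus: targets only at the cued location
            delta_mag <- sample(cfg$valid_deltas, 1)
          } else if (stats::runif(1) < cfg$p_valid) {
            target_loc <- cue
            delta_mag <- sample(cfg$valid_deltas, 1)
          } else {
            target_loc <- if (cue == "RF") "away" else "RF"
            delta_mag <- cfg$invalid_delta
          }
          delta <- delta_mag * sample(c(-1, 1), 1)
          attn_toward <- if (target_loc == "RF") s_f else -s_f
          p_hit <- stats::plogis(cfg$behavior_intercept +
                                   cfg$behavior_delta_slope * log2(delta_mag) +
                                   cfg$behavior_attention_slope * attn_toward)
          if (stats::runif(1) < p_hit) {
            outcome <- "hit"
            rt <- cfg$rt_shift_ms +
              stats::rlnorm(1, cfg$rt_meanlog - cfg$rt_attention_slope * attn_toward,
                            cfg$rt_sdlog)
            block_hits <- block_hits + 1L
            if (is_cue_trial) cue_phase_hits <- cue_phase_hits + 1L
          } else {
            outcome <- "miss"
          }
        } else {
          p_fa <- stats::plogis(stats::qlogis(cfg$fa_rate) + cfg$fa_state_slope * s_f)
          if (stats::runif(1) < p_fa) outcome <- "false_alarm"
        }

        stim_loc <- if (!is_cue_trial) "bilateral" else if (cue == "RF") "RF-only" else "away-only"
        ori_rf <- if (stim_loc == "away-only") NA_real_ else {
          if (is_target && target_loc == "RF") orientation + delta else orientation
        }
        rows[[length(rows) + 1L]] <- list(
          session_id = cfg$session_id, trial_id = trial_id, flash_index = f,
          onset_ms = as.integer(onset), is_cue_trial = is_cue_trial,
          cue_location = cue, stimulus_locations = stim_loc,
          orientation_RF = ori_rf, is_target = is_target,
          target_location = target_loc, delta_orientation = delta,
          outcome = outcome, response_time_ms = if (is.na(rt)) NA_real_ else round(rt, 1)
        )
        flash_states[[length(flash_states) + 1L]] <- list(
          trial_id = trial_id, flash_index = f, state = state_f,
          u_pre = state_squash(state_f), u_post = state_squash(state2_f)
        )
        if (outcome %in% c("hit", "miss", "false_alarm")) break
        onset <- onset + cfg$stimulus_ms + sample(cfg$isi_ms[1]:cfg$isi_ms[2], 1)
      }
      trial_states[[length(trial_states) + 1L]] <- list(
        trial_id = trial_id, block = block, cue_location = cue, a = a_trial
      )
    }
  }
  list(
    flashes = rbind_lists(rows),
    trials = rbind_lists(trial_states),
    flash_states = rbind_lists(flash_states)
  )
}

rbind_lists <- function(lst) {
  cols <- names(lst[[1]])
  out <- lapply(cols, function(cn) unlist(lapply(lst, `[[`, cn), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Simulate the behavioral task sequence only
#'
#' Runs the block-cued change-detection task model (uniform target hazard,
#' cue validity, cue-trial phase, latent-state-linked hit/miss outcomes)
#' without generating spikes.
#'
#' @param config generator_config.
#' @param seed optional integer; if given, seeds the global RNG.
#' @return Flash table data.frame (see \code{\link{session_data}}).
#' @export
generate_task_sequence <- function(config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  simulate_task(config)$flashes
}

# Per-unit latent parameters: baseline rate, post-stimulus gain g and
# pre-stimulus modulation m, with corr(g - 1, m) = gain_mod_correlation
# (bivariate normal; clamped to keep all rates positive).
draw_units <- function(cfg, gain_only = FALSE) {
  n <- cfg$n_units
  lambda <- stats::rlnorm(n, cfg$baseline_rate_meanlog, cfg$baseline_rate_sdlog)
  z1 <- stats::rnorm(n)
  rho <- cfg$gain_mod_correlation
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  g <- cfg$post_gain_mean + cfg$post_gain_sd * z1
  g <- pmax(g, 0.05)
  if (gain_only) {
    m <- cfg$gain_only_scale * (g - 1)
  } else {
    m <- cfg$pre_mod_mean + cfg$pre_mod_sd * z2
  }
  m <- pmin(pmax(m, -0.9), 0.9)
  data.frame(unit_id = sprintf("u%03d", seq_len(n)), lambda = lambda,
             gain = g, pre_mod = m, stringsAsFactors = FALSE)
}

# Modulation envelopes for one trial: v1 multiplies lambda, v2 multiplies
# lambda*m, v3 multiplies lambda*(g-1); one value per 1 ms bin.
simulate_trial_envelope <- function(cfg, trial_flashes, trial_flash_states) {
  n_fl <- nrow(trial_flashes)
  last_onset <- trial_flashes$onset_ms[n_fl]
  T <- last_onset + cfg$stimulus_ms + 300L
  v1 <- rep(1, T)               # unmodulated envelope
  v2 <- numeric(T)              # multiplies lambda * m
  v3 <- numeric(T)              # multiplies lambda * (g - 1)
  u_pre <- trial_flash_states$u_pre
  u_post <- trial_flash_states$u_post

  # baseline modulation: the fixation period and each inter-stimulus
  # segment carry the state of the flash they precede; the tail after the
  # final offset reuses the final state (post-target data are excluded
  # from analysis anyway)
  onsets <- trial_flashes$onset_ms
  offsets <- onsets + cfg$stimulus_ms
  seg_starts <- c(0L, offsets)                       # n_fl + 1 segments
  seg_ends <- c(onsets, T)                           # [start, end) in bin time
  seg_u <- c(u_pre, u_pre[n_fl])
  for (k in seq_along(seg_starts)) {
    if (seg_ends[k] > seg_starts[k]) {
      v2[(seg_starts[k] + 1L):seg_ends[k]] <- seg_u[k]
    }
  }

  rf_stim <- trial_flashes$stimulus_locations %in% c("bilateral", "RF-only")
  tau <- seq_len(cfg$stimulus_ms) - 1L
  psi_t <- cfg$psth_transient_amp *
    exp(-(tau - cfg$psth_transient_latency)^2 / (2 * cfg$psth_transient_width^2))
  psi_s <- cfg$psth_sustained_amp * as.numeric(tau >= cfg$psth_sustained_onset)
  cc <- cfg$transient_state_coupling
  for (f in seq_len(n_fl)) {
    seg <- onsets[f] + seq_len(cfg$stimulus_ms)
    if (rf_stim[f]) {
      # during the stimulus the baseline + sustained components carry the
      # attention gain pattern (g - 1); the onset transient carries the
      # pre-stimulus pattern m in proportion to transient_state_coupling
      v1[seg] <- 1 + psi_s + psi_t
      v2[seg] <- cc * psi_t * u_pre[f]
      v3[seg] <- (1 + psi_s + (1 - cc) * psi_t) * u_post[f]
    } else {
      v2[seg] <- u_pre[f]
    }
  }

  cbind(v1, v2, v3)
}

# Exact sampling of the inhomogeneous Poisson process for every unit.
# Each unit's rate is a 3-component mixture lambda*(v1 + m*v2 + (g-1)*v3);
# spikes are drawn per component by inverse-CDF sampling of a Poisson
# number of event times, and components with negative coefficients are
# handled by thinning the positive-part process. This touches only actual
# spikes rather than every (bin, unit) cell.
simulate_session_spikes <- function(cfg, units, flashes, flash_states) {
  trial_ids <- unique(flashes$trial_id)
  envs <- lapply(trial_ids, function(tid) {
    simulate_trial_envelope(cfg, flashes[flashes$trial_id == tid, , drop = FALSE],
                            flash_states[flash_states$trial_id == tid, , drop = FALSE])
  })
  V <- do.call(rbind, envs)
  Tn <- vapply(envs, nrow, integer(1))
  starts <- c(0L, cumsum(Tn))
  cums <- list(cumsum(V[, 1]), cumsum(V[, 2]), cumsum(V[, 3]))
  totals <- vapply(cums, function(x) x[length(x)], numeric(1))

  draw_component <- function(coef, k) {
    mass <- coef * totals[k]
    if (mass <= 0) return(integer(0))
    n <- stats::rpois(1, mass)
    if (n == 0) return(integer(0))
    pmin(findInterval(stats::runif(n) * totals[k], cums[[k]]) + 1L, nrow(V))
  }

  out <- vector("list", nrow(units))
  for (j in seq_len(nrow(units))) {
    co <- units$lambda[j] / 1000 * c(1, units$pre_mod[j], units$gain[j] - 1)
    bins <- c(draw_component(co[1], 1), draw_component(max(co[2], 0), 2),
              draw_component(max(co[3], 0), 3))
    if (length(bins) && (co[2] < 0 || co[3] < 0)) {
      pos <- co[1] * V[bins, 1] + max(co[2], 0) * V[bins, 2] +
        max(co[3], 0) * V[bins, 3]
      neg <- max(-co[2], 0) * V[bins, 2] + max(-co[3], 0) * V[bins, 3]
      bins <- bins[stats::runif(length(bins)) * pos >= neg]
    }
    if (!length(bins)) next
    tr_ix <- findInterval(bins - 1L, starts, rightmost.closed = FALSE)
    out[[j]] <- data.frame(unit_id = units$unit_id[j],
                           trial_id = trial_ids[tr_ix],
                           time_ms = bins - 1L - starts[tr_ix],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(unit_id = character(0), trial_id = integer(0),
                      time_ms = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Generate a complete synthetic session
#'
#' Simulates the task sequence, the latent attention state, behavior and
#' Poisson spiking around a transient+sustained PSTH template. During the
#' stimulus, the baseline and sustained response components of unit i are
#' scaled by \code{1 + (g_i - 1) * u}; during inter-stimulus intervals the
#' baseline is scaled by \code{1 + m_i * u}, where \code{u} in (0, 1) is
#' the squashed latent attention state (1 = full attention to the RF). The
#' onset transient is coupled to the pre-stimulus state through the
#' mixed-sign pattern \code{m_i} in proportion to
#' \code{transient_state_coupling} (and to the gain pattern for the
#' remainder), so anticipatory states leave a signature on the earliest
#' part of the visual response.
#'
#' @param config generator_config.
#' @param seed optional integer seed for the global RNG.
#' @param gain_only if TRUE, pre-stimulus modulations are forced collinear
#'   with the post-stimulus gains (stimulation-invariant-gain control).
#' @return List with elements \code{session} (session_data) and
#'   \code{truth} (list: \code{units}, \code{trials}, \code{flash_states}).
#' @export
generate_session <- function(config = generator_config(), seed = NULL,
                             gain_only = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  task <- simulate_task(config)
  units <- draw_units(config, gain_only = gain_only)
  fl <- task$flashes
  spikes <- simulate_session_spikes(config, units, fl, task$flash_states)
  spikes <- spikes[, c("unit_id", "trial_id", "time_ms")]
  unit_tbl <- data.frame(unit_id = units$unit_id, snr = NA_real_,
                         stringsAsFactors = FALSE)
  params <- default_session_params()
  params$stimulus_ms <- config$stimulus_ms
  session <- canonicalize_session(session_data(fl, spikes, unit_tbl, params))
  list(session = session,
       truth = list(units = units, trials = task$trials,
                    flash_states = task$flash_states))
}

#' Stimulation-invariant-gain control session
#'
#' As \code{\link{generate_session}} but the per-unit pre-stimulus
#' modulation is a single shared multiple of the post-stimulus gain, so the
#' pre-stimulus modulation pattern is collinear with the post-stimulus
#' pattern. Used as a negative control: after orthogonalization the
#' pre-stimulus attention axis should carry no condition information on
#' these data.
#'
#' @inheritParams generate_session
#' @return As \code{\link{generate_session}}.
#' @export
generate_gain_only_session <- function(config = generator_config(), seed = NULL) {
  generate_session(config, seed = seed, gain_only = TRUE)
}

#' Write generator ground truth to CSV
#'
#' Writes \code{groundtruth.csv} (per-unit baseline rate, gain and
#' pre-stimulus modulation) and \code{latent.csv} (per-trial latent
#' attention state) for a generated session.
#'
#' @param truth the \code{truth} element returned by
#'   \code{\link{generate_session}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(units = file.path(dir, "groundtruth.csv"),
             latent = file.path(dir, "latent.csv"))
  utils::write.csv(truth$units, paths["units"], row.names = FALSE, quote = FALSE)
  utils::write.csv(truth$trials, paths["latent"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Two-neuron population-coupling model
#'
#' Minimal rate model of differential population coupling: neuron A's rate
#' is the stimulus drive scaled by an attention gain; neuron B's rate is a
#' monotone function of A's rate only. With a decreasing (or saturating)
#' coupling, attention can facilitate A while suppressing B in the absence
#' of drive, reproducing sign-flipping attention effects between
#' unstimulated and stimulated states.
#'
#' @param stimulus_drive non-negative numeric rate series (spikes/s).
#' @param gain attention gain factor applied to the drive.
#' @param coupling monotone function mapping A's rate to B's rate.
#' @return List with numeric rate series \code{a} and \code{b}.
#' @export
simulate_coupled_pair <- function(stimulus_drive, gain, coupling) {
  if (any(stimulus_drive < 0)) stop("stimulus_drive must be non-negative", call. = FALSE)
  a <- gain * stimulus_drive
  b <- coupling(a)
  list(a = a, b = b)
}
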