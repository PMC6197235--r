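#' Unit stability and rate screening
#'
#' Splits the session timeline into 10 equal-duration blocks, computes each
#' unit's mean firing rate per block and the coefficient of variation (CV,
#' sample SD over mean) of those block rates. Units with CV > 1 are flagged
#' unstable; units with a whole-session mean rate below 1 spike/s are
#' flagged low-rate. A unit is kept iff CV <= 1 and mean rate >= 1.
#'
#' @param session session_data.
#' @param n_blocks number of equal-duration blocks (default 10).
#' @return data.frame with one row per unit: \code{unit_id}, blockwise
#'   rates (\code{rate_block_1..n}), \code{cv}, \code{mean_rate},
#'   \code{kept}, \code{reason} (\code{ok}, \code{unstable},
#'   \code{low_rate}).
#' @export
screen_units <- function(session, n_blocks = 10) {
  tl <- session_timeline(session)
  if (tl$total < n_blocks) stop("session too short to screen", call. = FALSE)
  sp <- session$spikes
  abs_t <- tl$offsets[as.character(sp$trial_id)] + sp$time_ms
  edges <- seq(0, tl$total, length.out = n_blocks + 1)
  block_dur <- tl$total / n_blocks
  units <- session$units$unit_id
  blk <- pmin(findInterval(abs_t, edges, rightmost.closed = TRUE), n_blocks)
  tab <- table(factor(sp$unit_id, levels = units), factor(blk, levels = seq_len(n_blocks)))
  rates <- matrix(as.numeric(tab), nrow = length(units)) / (block_dur / 1000)
  mean_rate <- rowSums(matrix(as.numeric(tab), nrow = length(units))) / (tl$total / 1000)
  cv <- apply(rates, 1, function(r) {
    m <- mean(r)
    if (m == 0) Inf else stats::sd(r) / m
  })
  kept <- cv <= 1 & mean_rate >= 1
  reason <- ifelse(cv > 1, "unstable", ifelse(mean_rate < 1, "low_rate", "ok"))
  out <- data.frame(unit_id = units, rates, cv = cv, mean_rate = mean_rate,
                    kept = kept, reason = reason, stringsAsFactors = FALSE)
  names(out)[2:(n_blocks + 1)] <- paste0("rate_block_", seq_len(n_blocks))
  rownames(out) <- NULL
  out
}

# Flashes usable for visual-response statistics: non-target flashes of
# bilateral trials (the RF always contains a stimulus there).
sample_flash_filter <- function(fl) {
  !fl$is_target & !fl$is_cue_trial & fl$outcome != "false_alarm"
}

#' Visual responsiveness screen
#'
#' Tests whether any 50 ms window within the stimulus period [0, 400) ms
#' (sliding in 10 ms steps) has per-flash spike counts different from the
#' rate-matched per-flash baseline ([-100, 0) ms, halved to 50 ms
#' equivalents) by a paired two-tailed t-test at alpha = 0.05, uncorrected.
#' Degenerate windows (zero variance of the paired differences) are
#' skipped, so a unit with no spikes is not responsive.
#'
#' @param session session_data.
#' @param unit unit id.
#' @param alpha significance level per window.
#' @return Logical flag.
#' @export
test_visual_responsiveness <- function(session, unit, alpha = 0.05) {
  filt <- sample_flash_filter(session$flashes)
  if (sum(filt) < 2) stop("need at least 2 non-target flashes", call. = FALSE)
  m <- per_flash_binned_counts(session, unit, filt, win = c(-100, 400))
  base50 <- rowSums(m[, 1:100, drop = FALSE]) / 2
  cum <- cbind(0, t(apply(m[, 101:500, drop = FALSE], 1, cumsum)))
  for (s in seq(0, 350, by = 10)) {
    d <- (cum[, s + 51] - cum[, s + 1]) - base50
    if (stats::sd(d) == 0) next
    if (stats::t.test(d)$p.value < alpha) return(TRUE)
  }
  FALSE
}

# flashes-by-bins (1 ms) count matrix for one unit over win = c(start, end)
# relative to flash onset
per_flash_binned_counts <- function(session, unit, flash_filter, win) {
  fl <- session$flashes
  rows <- which(flash_filter)
  tl <- session_timeline(session)
  sp <- session$spikes
  abs_t <- sort(tl$offsets[as.character(sp$trial_id[sp$unit_id == unit])] +
                  sp$time_ms[sp$unit_id == unit])
  abs_on <- tl$offsets[as.character(fl$trial_id[rows])] + fl$onset_ms[rows]
  n_bins <- win[2] - win[1]
  m <- matrix(0L, nrow = length(rows), ncol = n_bins)
  lo <- findInterval(abs_on + win[1] - 0.5, abs_t)
  hi <- findInterval(abs_on + win[2] - 0.5, abs_t)
  for (i in seq_along(rows)) {
    if (hi[i] > lo[i]) {
      rel <- abs_t[(lo[i] + 1L):hi[i]] - (abs_on[i] + win[1])
      m[i, ] <- tabulate(rel + 1L, nbins = n_bins)
    }
  }
  rownames(m) <- paste0(fl$trial_id[rows], ":", fl$flash_index[rows])
  m
}

#' Normalized peristimulus time histogram for one unit
#'
#' Trial-averaged, causal half-Gaussian smoothed (sigma = 20 ms) firing
#' rate over the PSTH window [-300, 700) ms around each non-target sample
#' flash, baseline-subtracted (mean over [-100, 0) ms of the
#' condition-pooled trace) and divided by the absolute value of the most
#' extreme pooled deviation from baseline over [0, 700) ms. The
#' cue-in-RF and cue-away traces share the pooled baseline and divisor, so
#' the pooled trace has baseline mean 0 and extreme deviation magnitude 1.
#'
#' @param session session_data.
#' @param unit unit id.
#' @param sigma_ms smoothing kernel SD (ms).
#' @return List: \code{unit_id}, \code{time_ms}, \code{pooled},
#'   \code{cue_rf}, \code{cue_away} (normalized rate series),
#'   \code{divisor} (spikes/s), \code{baseline} (spikes/s).
#' @export
compute_normalized_psth <- function(session, unit, sigma_ms = 20) {
  win <- session$params$epochs$psth
  pad <- floor(4 * sigma_ms)
  filt <- sample_flash_filter(session$flashes)
  fl <- session$flashes
  rows <- which(filt)
  if (!length(rows)) stop("no sample flashes", call. = FALSE)
  tl <- session_timeline(session)
  sp <- session$spikes
  sp <- sp[sp$unit_id == unit, , drop = FALSE]
  abs_t <- tl$offsets[as.character(sp$trial_id)] + sp$time_ms
  abs_on <- tl$offsets[as.character(fl$trial_id[rows])] + fl$onset_ms[rows]

  n_bins <- (win[2] - win[1]) + pad
  t0 <- win[1] - pad
  abs_t <- sort(abs_t)
  cond <- fl$cue_location[rows]
  sums <- list(RF = numeric(n_bins), away = numeric(n_bins))
  n_by <- c(RF = 0, away = 0)
  lo <- findInterval(abs_on + t0 - 0.5, abs_t)
  hi <- findInterval(abs_on + t0 + n_bins - 0.5, abs_t)
  for (i in seq_along(rows)) {
    if (hi[i] > lo[i]) {
      rel <- abs_t[(lo[i] + 1L):hi[i]] - (abs_on[i] + t0)
      ci <- tabulate(rel + 1L, nbins = n_bins)
    } else {
      ci <- numeric(n_bins)
    }
    sums[[cond[i]]] <- sums[[cond[i]]] + ci
    n_by[cond[i]] <- n_by[cond[i]] + 1
  }
  pooled_counts <- (sums$RF + sums$away) / sum(n_by)
  trim <- (pad + 1):n_bins
  time_ms <- seq(win[1], win[2] - 1)
  smooth_trim <- function(x) smooth_spike_train(x, sigma_ms)[trim]
  pooled <- smooth_trim(pooled_counts)
  tr_rf <- if (n_by["RF"] > 0) smooth_trim(sums$RF / n_by["RF"]) else rep(NA_real_, length(trim))
  tr_aw <- if (n_by["away"] > 0) smooth_trim(sums$away / n_by["away"]) else rep(NA_real_, length(trim))

  base_idx <- time_ms >= -100 & time_ms < 0
  resp_idx <- time_ms >= 0
  baseline <- mean(pooled[base_idx])
  divisor <- max(abs(pooled[resp_idx] - baseline))
  if (divisor == 0) stop(sprintf("unit %s: zero normalization divisor (unresponsive)", unit),
                         call. = FALSE)
  list(unit_id = unit, time_ms = time_ms,
       pooled = (pooled - baseline) / divisor,
       cue_rf = (tr_rf - baseline) / divisor,
       cue_away = (tr_aw - baseline) / divisor,
       divisor = divisor, baseline = baseline)
}

#' Session-mean normalized PSTH
#'
#' Screens units (\code{\link{screen_units}}), drops visually unresponsive
#' units (\code{\link{test_visual_responsiveness}}), and averages their
#' normalized PSTHs per cue condition.
#'
#' @param session session_data.
#' @param sigma_ms smoothing kernel SD (ms).
#' @return List: \code{time_ms}, \code{cue_rf}, \code{cue_away} (mean
#'   normalized traces), \code{n_units}.
#' @export
session_mean_psth <- function(session, sigma_ms = 20) {
  scr <- screen_units(session)
  keep <- scr$unit_id[scr$kept]
  keep <- keep[vapply(keep, function(u) test_visual_responsiveness(session, u),
                      logical(1))]
  if (!length(keep)) stop("no responsive units in session", call. = FALSE)
  traces <- lapply(keep, function(u) compute_normalized_psth(session, u, sigma_ms))
  list(time_ms = traces[[1]]$time_ms,
       cue_rf = rowMeans(vapply(traces, `[[`, numeric(length(traces[[1]]$cue_rf)), "cue_rf")),
       cue_away = rowMeans(vapply(traces, `[[`, numeric(length(traces[[1]]$cue_away)), "cue_away")),
       n_units = length(keep))
}

#' Grand-average PSTH condition comparison
#'
#' Averages session-mean normalized PSTHs across sessions and tests the
#' cue-in-RF vs cue-away difference at each millisecond with a paired
#' t-test (alpha = 0.05, uncorrected). Normality of the per-ms paired
#' differences is spot-checked on a 100 ms grid with a Lilliefors-type
#' composite test; violations produce a warning, not an abort.
#'
#' @param sessions list of session-mean PSTHs (\code{\link{session_mean_psth}})
#'   or of session_data objects.
#' @param alpha per-ms significance level.
#' @return data.frame per ms: \code{time_ms}, \code{mean_rf},
#'   \code{sem_rf}, \code{mean_away}, \code{sem_away}, \code{t}, \code{p},
#'   \code{significant}; attribute \code{earliest_significant_ms}.
#' @export
grand_average_comparison <- function(sessions, alpha = 0.05) {
  if (length(sessions) < 2) stop("need at least 2 sessions", call. = FALSE)
  if (inherits(sessions[[1]], "session_data")) {
    sessions <- lapply(sessions, session_mean_psth)
  }
  time_ms <- sessions[[1]]$time_ms
  rf <- vapply(sessions, `[[`, numeric(length(time_ms)), "cue_rf")
  aw <- vapply(sessions, `[[`, numeric(length(time_ms)), "cue_away")
  d <- rf - aw
  n <- ncol(d)
  md <- rowMeans(d)
  sdd <- apply(d, 1, stats::sd)
  tt <- ifelse(sdd > 0, md / (sdd / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(-abs(tt), df = n - 1)
  p[is.na(p)] <- 1
  sig <- p < alpha

  if (n >= 5) {
    grid <- which(time_ms %% 100 == 0)
    viol <- 0
    for (i in grid) {
      di <- d[i, ]
      if (stats::sd(di) == 0) next
      lp <- tryCatch(nortest::lillie.test(di)$p.value, error = function(e) NA_real_)
      if (!is.na(lp) && lp < 0.05) viol <- viol + 1
    }
    if (viol > 0.25 * length(grid)) {
      warning(sprintf("normality check: %d of %d spot-checked time points violate Lilliefors at 0.05",
                      viol, length(grid)), call. = FALSE)
    }
  }
  out <- data.frame(
    time_ms = time_ms,
    mean_rf = rowMeans(rf), sem_rf = apply(rf, 1, stats::sd) / sqrt(n),
    mean_away = rowMeans(aw), sem_away = apply(aw, 1, stats::sd) / sqrt(n),
    t = tt, p = p, significant = sig
  )
  attr(out, "earliest_significant_ms") <-
    if (any(sig)) time_ms[which(sig)[1]] else NA_real_
  out
}
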