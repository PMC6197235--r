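#' Flashes eligible for the stimulus-response regression
#'
#' Eligible flashes are sample (non-target) stimuli that were preceded by
#' another sample stimulus on the same trial. Cue trials and false-alarm
#' flashes (contaminated by the saccade) are excluded.
#'
#' @param flash_table flash table.
#' @return Integer row indices into the flash table.
#' @export
select_eligible_flashes <- function(flash_table) {
  fl <- flash_table
  key <- paste(fl$trial_id, fl$flash_index)
  pred <- match(paste(fl$trial_id, fl$flash_index - 1L), key)
  ok <- !fl$is_target & !fl$is_cue_trial & fl$outcome != "false_alarm" &
    !is.na(pred) & !fl$is_target[ifelse(is.na(pred), 1L, pred)]
  which(ok)
}

#' Fit the stimulus-response axis
#'
#' The stimulus-response axis is the unit vector from the trial-averaged
#' baseline point (mean smoothed population rate over [-100, 0) ms
#' relative to flash onset) to the point on the trial-averaged smoothed
#' population trajectory over [-100, 600) ms that is furthest from
#' baseline (the high-dimensional analog of the onset-transient peak).
#'
#' @param session session_data.
#' @param units unit ids (default: all).
#' @param flash_rows flash rows to average over (default:
#'   \code{\link{select_eligible_flashes}}).
#' @param sigma_ms smoothing kernel SD (ms).
#' @return Unit-norm vector over units; attributes \code{t_star_ms} (time
#'   of the furthest point) and \code{baseline} (per-unit baseline rates).
#' @export
fit_stimulus_response_axis <- function(session, units = NULL, flash_rows = NULL,
                                       sigma_ms = 20) {
  if (is.null(units)) units <- session$units$unit_id
  if (is.null(flash_rows)) flash_rows <- select_eligible_flashes(session$flashes)
  if (!length(flash_rows)) stop("no eligible flashes", call. = FALSE)
  win <- session$params$epochs$response
  pad <- floor(4 * sigma_ms)
  filt <- seq_len(nrow(session$flashes)) %in% flash_rows
  traj <- vapply(units, function(u) {
    m <- per_flash_binned_counts(session, u, filt, win = c(win[1] - pad, win[2]))
    smooth_spike_train(colMeans(m), sigma_ms)[(pad + 1):(pad + (win[2] - win[1]))]
  }, numeric(win[2] - win[1]))
  time_ms <- seq(win[1], win[2] - 1)
  b <- colMeans(traj[time_ms >= -100 & time_ms < 0, , drop = FALSE])
  dev <- sweep(traj, 2, b)
  dist <- sqrt(rowSums(dev^2))
  t_star <- which.max(dist)
  d <- dev[t_star, ]
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("degenerate stimulus-response axis: trajectory never leaves baseline",
                    call. = FALSE)
  structure(d / nd, names = units, t_star_ms = time_ms[t_star], baseline = b)
}

#' One-dimensional population stimulus responses
#'
#' Projects each eligible flash's smoothed population activity over
#' [-100, 600) ms onto the stimulus-response axis, giving the
#' time-resolved scalar response r_ti; responses are mean-centered across
#' flashes at each time point.
#'
#' @param session session_data.
#' @param units unit ids (default: all).
#' @param sigma_ms smoothing kernel SD (ms).
#' @return List of class \code{stimulus_response_series}: \code{r}
#'   (time x flash matrix, centered), \code{time_ms}, \code{axis},
#'   \code{t_star_ms}, \code{flash_rows}.
#' @export
stimulus_response_series <- function(session, units = NULL, sigma_ms = 20) {
  if (is.null(units)) units <- session$units$unit_id
  flash_rows <- select_eligible_flashes(session$flashes)
  axis <- fit_stimulus_response_axis(session, units, flash_rows, sigma_ms)
  win <- session$params$epochs$response
  pad <- floor(4 * sigma_ms)
  T <- win[2] - win[1]
  filt <- seq_len(nrow(session$flashes)) %in% flash_rows
  # project per-flash binned counts of each unit onto the axis, then smooth
  proj <- matrix(0, nrow = T + pad, ncol = length(flash_rows))
  for (j in seq_along(units)) {
    m <- per_flash_binned_counts(session, units[j], filt, win = c(win[1] - pad, win[2]))
    proj <- proj + t(m) * axis[j]
  }
  r <- apply(proj, 2, function(x) smooth_spike_train(x, sigma_ms))[(pad + 1):(pad + T), , drop = FALSE]
  r <- r - rowMeans(r)
  structure(list(r = r, time_ms = seq(win[1], win[2] - 1), axis = axis,
                 t_star_ms = attr(axis, "t_star_ms"), flash_rows = flash_rows),
            class = "stimulus_response_series")
}

#' Align attention projections to eligible flashes
#'
#' The predictors of the two-step regression: for each eligible flash, the
#' post-stimulus attention projection measured during the response to the
#' preceding stimulus and the pre-stimulus projection measured during the
#' immediately preceding inter-stimulus interval.
#'
#' @param series stimulus_response_series.
#' @param records projection records.
#' @param flashes flash table.
#' @return data.frame: \code{flash_row}, \code{a_post}, \code{a_pre}.
#' @export
align_projection_predictors <- function(series, records, flashes) {
  rows <- series$flash_rows
  key <- paste(flashes$trial_id, flashes$flash_index)
  pred <- match(paste(flashes$trial_id[rows], flashes$flash_index[rows] - 1L), key)
  data.frame(flash_row = rows, a_post = records$a_post[pred],
             a_pre = records$a_pre[rows])
}

#' Two-step time-resolved VAF regression
#'
#' Step 1 regresses the centered population stimulus response at each
#' time point onto the (centered) post-stimulus attention projection with
#' a single scalar coefficient, and records the proportion of variance
#' accounted for. Step 2 regresses the step-1 residual onto the
#' (centered) pre-stimulus attention projection and records the
#' proportion of residual variance accounted for.
#'
#' @param r time x flash matrix of centered responses (or a
#'   \code{stimulus_response_series}).
#' @param a_post,a_pre predictor vectors aligned to the flash columns.
#' @return data.frame per time point: \code{beta_post}, \code{vaf_post},
#'   \code{beta_pre}, \code{vaf_pre}; attribute \code{n} (flashes used).
#' @export
two_step_vaf <- function(r, a_post, a_pre) {
  if (inherits(r, "stimulus_response_series")) {
    time_ms <- r$time_ms
    r <- r$r
  } else {
    time_ms <- seq_len(nrow(r))
  }
  ok <- is.finite(a_post) & is.finite(a_pre)
  r <- r[, ok, drop = FALSE]
  a_post <- a_post[ok]; a_pre <- a_pre[ok]
  n <- length(a_post)
  if (n < 3) stop("need at least 3 flashes with finite predictors", call. = FALSE)
  a_post <- a_post - mean(a_post)
  a_pre <- a_pre - mean(a_pre)
  if (sum(a_post^2) == 0 || sum(a_pre^2) == 0) {
    stop("zero-variance predictor", call. = FALSE)
  }
  r <- r - rowMeans(r)
  beta_post <- as.numeric(r %*% a_post) / sum(a_post^2)
  resid <- r - outer(beta_post, a_post)
  ss_r <- rowSums(r^2)
  ss_e <- rowSums(resid^2)
  vaf_post <- ifelse(ss_r > 0, 1 - ss_e / ss_r, 0)
  beta_pre <- as.numeric(resid %*% a_pre) / sum(a_pre^2)
  resid2 <- resid - outer(beta_pre, a_pre)
  # residual variance at floating-point roundoff means step 1 explained
  # everything; step 2 then accounts for nothing
  ss_e_real <- ss_e > 1e-12 * pmax(ss_r, .Machine$double.eps)
  vaf_pre <- ifelse(ss_e_real, 1 - rowSums(resid2^2) / ss_e, 0)
  beta_pre[!ss_e_real] <- 0
  structure(data.frame(time_ms = time_ms, beta_post = beta_post,
                       vaf_post = vaf_post, beta_pre = beta_pre,
                       vaf_pre = vaf_pre),
            n = n)
}

#' Shuffled-control null VAF level
#'
#' Permutes the flash order of the attention projections, recomputes both
#' VAF series, and averages over shuffles and time. Under independence of
#' Gaussian predictor and response the expected VAF is 1/(n-1), which is
#' reported alongside for reference.
#'
#' @param r centered response matrix or stimulus_response_series.
#' @param a_post,a_pre aligned predictors.
#' @param n_shuffles number of random permutations.
#' @param seed optional seed.
#' @return List: \code{null} (grand mean VAF over both steps, shuffles and
#'   time), \code{null_post}, \code{null_pre}, \code{theory} = 1/(n-1),
#'   \code{n}.
#' @export
shuffled_null_vaf <- function(r, a_post, a_pre, n_shuffles = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(r, "stimulus_response_series")) r <- r$r
  ok <- is.finite(a_post) & is.finite(a_pre)
  r <- r[, ok, drop = FALSE]
  a_post <- a_post[ok]; a_pre <- a_pre[ok]
  n <- length(a_post)
  if (n < 3) stop("need n >= 3 (n = 2 gives VAF = 1 identically)", call. = FALSE)
  mp <- ms <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    perm <- sample(n)
    v <- two_step_vaf(r, a_post[perm], a_pre[perm])
    mp[s] <- mean(v$vaf_post)
    ms[s] <- mean(v$vaf_pre)
  }
  list(null = mean(c(mp, ms)), null_post = mean(mp), null_pre = mean(ms),
       theory = 1 / (n - 1), n = n)
}

#' Run-length threshold for consecutive-significance correction
#'
#' Calibrates the minimum number of consecutive individually significant
#' time points required for a family-wise error rate of \code{alpha},
#' using null simulations matched to the average autocorrelation of the
#' observed VAF series (AR fit of order \code{ar_order} per session,
#' coefficients averaged). Each simulated experiment draws one AR series
#' per session, applies the same per-time one-sample t-test, and records
#' its maximum significant run length; the threshold is the smallest run
#' length attained in at most \code{alpha} of the simulated experiments.
#'
#' @param vaf_sessions sessions x time matrix of VAF values (one row per
#'   session), or a list of such matrices/vectors.
#' @param alpha significance level (per-time and family-wise).
#' @param ar_order autoregressive order for the matched null (default 1).
#' @param n_sims number of simulated experiments.
#' @param seed optional seed.
#' @param alternative sidedness of the per-time test (matched to
#'   \code{\link{significance_mask}}).
#' @return List: \code{threshold} (samples), \code{ar_coef},
#'   \code{max_run_quantiles}, \code{n_sims}.
#' @export
runlength_threshold <- function(vaf_sessions, alpha = 0.05, ar_order = 1,
                                n_sims = 1000, seed = NULL,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (!is.null(seed)) set.seed(seed)
  if (is.list(vaf_sessions)) vaf_sessions <- do.call(rbind, vaf_sessions)
  S <- nrow(vaf_sessions); T <- ncol(vaf_sessions)
  if (S < 2) stop("need >= 2 sessions", call. = FALSE)
  coefs <- matrix(0, nrow = S, ncol = ar_order)
  for (i in seq_len(S)) {
    x <- vaf_sessions[i, ] - mean(vaf_sessions[i, ])
    fit <- tryCatch(stats::ar(x, aic = FALSE, order.max = ar_order,
                              method = "yule-walker"),
                    error = function(e) NULL)
    if (!is.null(fit) && length(fit$ar)) coefs[i, seq_along(fit$ar)] <- fit$ar
  }
  phi <- colMeans(coefs)
  if (sum(abs(phi)) >= 1) {
    # Yule-Walker keeps AR(1) stationary; higher orders can in principle
    # average to an unstable polynomial -- fall back to lag-1 only
    warning("averaged AR fit unstable; falling back to AR(1)", call. = FALSE)
    phi <- min(max(mean(coefs[, 1]), -0.999), 0.999)
  }
  crit <- if (alternative == "greater") stats::qt(1 - alpha, df = S - 1) else
    stats::qt(1 - alpha / 2, df = S - 1)
  max_runs <- integer(n_sims)
  burn <- 50
  for (sim in seq_len(n_sims)) {
    e <- matrix(stats::rnorm(S * (T + burn)), nrow = S)
    x <- t(apply(e, 1, function(row) stats::filter(row, phi, method = "recursive")))
    x <- x[, (burn + 1):(T + burn), drop = FALSE]
    mu <- colMeans(x)
    sdv <- sqrt(colSums(sweep(x, 2, mu)^2) / (S - 1))
    tstat <- mu / (sdv / sqrt(S))
    sig <- if (alternative == "greater") tstat > crit else abs(tstat) > crit
    rl <- rle(sig)
    max_runs[sim] <- if (any(rl$values)) max(rl$lengths[rl$values]) else 0L
  }
  threshold <- 1L
  while (mean(max_runs >= threshold) > alpha) threshold <- threshold + 1L
  list(threshold = threshold, ar_coef = phi,
       max_run_quantiles = stats::quantile(max_runs, c(0.5, 0.95, 0.99)),
       n_sims = n_sims)
}

#' Significance mask with run-length correction
#'
#' Per-time one-sample t-test of the across-session VAF values against the
#' null level; significant runs shorter than the run-length threshold are
#' erased. The peak time of the session-mean VAF is reported.
#'
#' @param vaf_sessions sessions x time matrix (or list of rows).
#' @param null_level scalar null VAF.
#' @param run_threshold minimum run length (samples).
#' @param alpha per-time significance level.
#' @param time_ms optional time axis for reporting.
#' @param alternative \code{"greater"} (default: VAF above the null) or
#'   \code{"two.sided"}.
#' @return List: \code{mask} (logical per time), \code{p} (per-time
#'   p-values), \code{peak_time}, \code{mean_vaf}.
#' @export
significance_mask <- function(vaf_sessions, null_level, run_threshold,
                              alpha = 0.05, time_ms = NULL,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (run_threshold < 1) stop("run_threshold must be >= 1", call. = FALSE)
  if (is.list(vaf_sessions)) vaf_sessions <- do.call(rbind, vaf_sessions)
  S <- nrow(vaf_sessions); T <- ncol(vaf_sessions)
  if (is.null(time_ms)) time_ms <- seq_len(T)
  d <- vaf_sessions - null_level
  mu <- colMeans(d)
  sdv <- sqrt(colSums(sweep(d, 2, mu)^2) / (S - 1))
  tstat <- ifelse(sdv > 0, mu / (sdv / sqrt(S)), NA_real_)
  p <- if (alternative == "greater") stats::pt(-tstat, df = S - 1) else
    2 * stats::pt(-abs(tstat), df = S - 1)
  p[is.na(p)] <- 1
  sig <- p < alpha
  rl <- rle(sig)
  keep <- rl$values & rl$lengths >= run_threshold
  mask <- rep(rep(keep, rl$lengths))
  mv <- colMeans(vaf_sessions)
  list(mask = mask, p = p, peak_time = time_ms[which.max(mv)], mean_vaf = mv)
}
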