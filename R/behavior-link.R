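#' Signal-detection discriminability index
#'
#' d' = qnorm(hit rate) - qnorm(false-alarm rate). When any rate is 0 or 1
#' the log-linear correction is applied (0.5 added to each cell, 1 to each
#' denominator) so d' stays finite.
#'
#' @param hits,misses target counts.
#' @param fa false-alarm count.
#' @param fa_opportunities number of non-target opportunities (denominator
#'   of the false-alarm rate).
#' @return d' (numeric scalar).
#' @export
compute_dprime <- function(hits, misses, fa, fa_opportunities) {
  if (any(c(hits, misses, fa, fa_opportunities) < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (hits + misses == 0) stop("no targets: d' undefined", call. = FALSE)
  if (fa_opportunities == 0) stop("no false-alarm opportunities", call. = FALSE)
  H <- hits / (hits + misses)
  F <- fa / fa_opportunities
  if (H %in% c(0, 1) || F %in% c(0, 1)) {
    H <- (hits + 0.5) / (hits + misses + 1)
    F <- (fa + 0.5) / (fa_opportunities + 1)
  }
  stats::qnorm(H) - stats::qnorm(F)
}

#' Session behavioral summary
#'
#' Hit/miss counts and d' per orientation-change magnitude and cue
#' validity, mean response times per validity, and the session
#' false-alarm rate. False-alarm opportunities are all completed
#' non-target flashes. Cue trials are excluded.
#'
#' @param session session_data.
#' @return List: \code{by_condition} data.frame (delta, validity, hits,
#'   misses, dprime), \code{rt} data.frame (validity, mean_rt_ms, n),
#'   \code{fa_rate}, \code{n_fa}, \code{n_fa_opportunities}.
#' @export
behavioral_summary <- function(session) {
  fl <- session$flashes[!session$flashes$is_cue_trial, , drop = FALSE]
  nt <- fl[!fl$is_target, , drop = FALSE]
  n_fa <- sum(nt$outcome == "false_alarm")
  n_opp <- nrow(nt)
  tg <- fl[fl$is_target & fl$outcome %in% c("hit", "miss"), , drop = FALSE]
  tg$validity <- ifelse(tg$target_location == tg$cue_location, "valid", "invalid")
  tg$delta <- abs(tg$delta_orientation)
  combos <- unique(tg[, c("delta", "validity")])
  combos <- combos[order(combos$validity, combos$delta), , drop = FALSE]
  by_cond <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- tg$delta == combos$delta[i] & tg$validity == combos$validity[i]
    h <- sum(tg$outcome[sel] == "hit"); m <- sum(sel) - h
    data.frame(delta = combos$delta[i], validity = combos$validity[i],
               hits = h, misses = m,
               dprime = compute_dprime(h, m, n_fa, n_opp))
  }))
  rt <- do.call(rbind, lapply(c("valid", "invalid"), function(v) {
    sel <- tg$validity == v & tg$outcome == "hit" & !is.na(tg$response_time_ms)
    data.frame(validity = v,
               mean_rt_ms = if (any(sel)) mean(tg$response_time_ms[sel]) else NA_real_,
               n = sum(sel))
  }))
  list(by_condition = by_cond, rt = rt,
       fa_rate = if (n_opp > 0) n_fa / n_opp else NA_real_,
       n_fa = n_fa, n_fa_opportunities = n_opp)
}

# rank-based quintile assignment; stable ties (first occurrence to the
# lower bin), group sizes differ by at most 1
quintile_bins <- function(x, k = 5) {
  n <- length(x)
  if (length(unique(x)) < 2) {
    stop("all projections identical on an axis; quintile binning impossible", call. = FALSE)
  }
  r <- rank(x, ties.method = "first")
  floor((r - 1) * k / n) + 1L
}

#' 5x5 quintile performance map
#'
#' Bins the attention-axis projections of target-preceding intervals into
#' quintiles per axis (pre-stimulus projection of the interval preceding
#' the target; post-stimulus projection of the response to the preceding
#' sample flash), and computes the hit rate and normalized hit rate
#' (divided by the session's overall hit rate over these intervals) in
#' each of the 25 cells. Empty cells are NA.
#'
#' @param records projection records.
#' @param flashes flash table of the same session.
#' @param target_side \code{"RF"} or \code{"away"}.
#' @return List of class \code{performance_map}: \code{cells} data.frame
#'   (pre_q, post_q, n, hit_rate, norm_hit_rate), \code{overall_hit_rate},
#'   \code{n_intervals}.
#' @export
bin_projections_quintiles <- function(records, flashes, target_side = "RF") {
  key <- paste(flashes$trial_id, flashes$flash_index)
  targ <- which(flashes$is_target & flashes$target_location == target_side &
                  flashes$outcome %in% c("hit", "miss") & !flashes$is_cue_trial)
  pred <- match(paste(flashes$trial_id[targ], flashes$flash_index[targ] - 1L), key)
  ok <- !is.na(pred)
  targ <- targ[ok]; pred <- pred[ok]
  ok <- is.finite(records$a_pre[targ]) & is.finite(records$a_post[pred])
  targ <- targ[ok]; pred <- pred[ok]
  n <- length(targ)
  if (n < 25) warning(sprintf("only %d target-preceding intervals; 5x5 map will be sparse", n),
                      call. = FALSE)
  a_pre <- records$a_pre[targ]
  a_post <- records$a_post[pred]
  hit <- flashes$outcome[targ] == "hit"
  qp <- quintile_bins(a_pre); qo <- quintile_bins(a_post)
  overall <- mean(hit)
  cells <- expand.grid(pre_q = 1:5, post_q = 1:5)
  cells$n <- 0L; cells$hit_rate <- NA_real_; cells$norm_hit_rate <- NA_real_
  for (i in seq_len(nrow(cells))) {
    sel <- qp == cells$pre_q[i] & qo == cells$post_q[i]
    cells$n[i] <- sum(sel)
    if (any(sel)) {
      hr <- mean(hit[sel])
      cells$hit_rate[i] <- hr
      cells$norm_hit_rate[i] <- if (overall > 0) hr / overall else NA_real_
    }
  }
  structure(list(cells = cells, overall_hit_rate = overall, n_intervals = n),
            class = "performance_map")
}

#' Marginal performance along one attention axis
#'
#' Unweighted mean of the defined cells' normalized hit rates within each
#' quintile of the chosen axis (averaging over the other axis to isolate
#' the unique contribution of the chosen one).
#'
#' @param map performance_map.
#' @param axis \code{"pre"} or \code{"post"}.
#' @return Numeric vector of 5 normalized hit rates (NA where a quintile
#'   has no defined cell).
#' @export
marginal_performance <- function(map, axis = c("pre", "post")) {
  axis <- match.arg(axis)
  qcol <- if (axis == "pre") "pre_q" else "post_q"
  vapply(1:5, function(q) {
    v <- map$cells$norm_hit_rate[map$cells[[qcol]] == q]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

#' Across-session rank correlation between axis quintile and hit rate
#'
#' Per session, Spearman's rho between the chosen axis's quintile index
#' and the hit rate across the defined cells of the 5x5 map. The rhos are
#' Fisher z-transformed (perfect correlations clipped at |r| = 1 - 1e-10),
#' tested against zero with a one-sample two-tailed t-test, compared
#' between the two axes with a paired two-tailed t-test, and the mean z is
#' back-transformed to r for reporting. Normality of the z values is
#' checked with a Lilliefors-type test (warning on violation).
#'
#' @param maps list of performance_map objects (one per session).
#' @param alpha significance level used only for the normality warning.
#' @return List: \code{per_axis} data.frame (axis, mean_rho, t, df,
#'   p_value, n_sessions), \code{paired} (t, df, p_value), \code{z} matrix
#'   of per-session z values.
#' @export
rank_correlation_sessions <- function(maps, alpha = 0.05) {
  if (length(maps) < 3) stop("need at least 3 sessions", call. = FALSE)
  zmat <- matrix(NA_real_, nrow = length(maps), ncol = 2,
                 dimnames = list(NULL, c("pre", "post")))
  for (i in seq_along(maps)) {
    cells <- maps[[i]]$cells
    def <- !is.na(cells$hit_rate)
    for (ax in c("pre", "post")) {
      qcol <- if (ax == "pre") "pre_q" else "post_q"
      hr <- cells$hit_rate[def]
      if (length(hr) < 3 || stats::sd(hr) == 0) next  # rho undefined, excluded
      rho <- suppressWarnings(
        stats::cor(cells[[qcol]][def], hr, method = "spearman"))
      rho <- max(min(rho, 1 - 1e-10), -1 + 1e-10)
      zmat[i, ax] <- atanh(rho)
    }
  }
  dropped <- sum(!stats::complete.cases(zmat))
  if (dropped > 0) {
    message(sprintf("%d session(s) with undefined rank correlation excluded", dropped))
  }
  per_axis <- do.call(rbind, lapply(c("pre", "post"), function(ax) {
    z <- zmat[, ax]
    z <- z[!is.na(z)]
    if (length(z) >= 5) {
      lp <- tryCatch(nortest::lillie.test(z)$p.value, error = function(e) NA_real_)
      if (!is.na(lp) && lp < alpha) {
        warning(sprintf("z-transformed rank correlations (%s axis) violate normality (Lilliefors p = %.3g)",
                        ax, lp), call. = FALSE)
      }
    }
    if (length(z) < 2 || stats::sd(z) == 0) {
      # all sessions identical (e.g. every rho clipped at 1): the t-test is
      # degenerate; report the mean with an undefined test statistic
      return(data.frame(axis = ax, mean_rho = tanh(mean(z)), t = NA_real_,
                        df = length(z) - 1, p_value = NA_real_,
                        n_sessions = length(z)))
    }
    tt <- stats::t.test(z)
    data.frame(axis = ax, mean_rho = tanh(mean(z)), t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               n_sessions = length(z))
  }))
  cc <- stats::complete.cases(zmat)
  paired <- if (sum(cc) >= 2 && stats::sd(zmat[cc, "pre"] - zmat[cc, "post"]) > 0) {
    tt <- stats::t.test(zmat[cc, "pre"], zmat[cc, "post"], paired = TRUE)
    data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value)
  } else {
    data.frame(t = NA_real_, df = NA_real_, p_value = NA_real_)
  }
  list(per_axis = per_axis, paired = paired, z = zmat)
}
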