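#' Fit a difference-of-means attention axis
#'
#' The attention axis is the unit vector along the line connecting the
#' trial-averaged population count vectors of the two cue conditions,
#' oriented so the cue-in-RF side is positive.
#'
#' @param counts_in matrix (flashes x units) of cue-in-RF counts.
#' @param counts_away matrix of cue-away counts over the same units.
#' @return Unit-norm numeric vector over units.
#' @export
fit_attention_axis <- function(counts_in, counts_away) {
  if (!nrow(counts_in) || !nrow(counts_away)) {
    stop("both condition groups must be nonempty", call. = FALSE)
  }
  d <- colMeans(counts_in) - colMeans(counts_away)
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("degenerate axis: condition means are identical", call. = FALSE)
  d / nd
}

#' Orthogonalize the pre-stimulus axis against the post-stimulus axis
#'
#' Gram-Schmidt step: removes from the raw pre-stimulus difference vector
#' its component along the (fixed) post-stimulus attention axis and
#' renormalizes. Errors if the raw pre vector is within \code{min_angle_deg}
#' of the post axis, where the orthogonal complement is numerically
#' meaningless.
#'
#' @param pre_raw raw pre-stimulus difference-of-means vector.
#' @param w_post unit-norm post-stimulus attention axis.
#' @param min_angle_deg degeneracy threshold in degrees (default 1).
#' @return Unit-norm vector orthogonal to \code{w_post}.
#' @export
orthogonalize_pre_axis <- function(pre_raw, w_post, min_angle_deg = 1) {
  npre <- sqrt(sum(pre_raw^2))
  if (npre == 0) stop("degenerate pre-stimulus axis: zero difference vector", call. = FALSE)
  cosang <- abs(sum(pre_raw * w_post)) / npre
  if (cosang > cos(min_angle_deg * pi / 180)) {
    stop(sprintf("degenerate pre-stimulus axis: within %g deg of the post-stimulus axis",
                 min_angle_deg), call. = FALSE)
  }
  v <- pre_raw - sum(pre_raw * w_post) * w_post
  v / sqrt(sum(v^2))
}

# eligible training targets: validly cued, correctly detected, preceded by
# a sample flash on the same trial, outside the cue-trial phase
training_eligible_targets <- function(fl) {
  which(fl$is_target & fl$outcome == "hit" & !fl$is_cue_trial &
          fl$target_location == fl$cue_location & fl$flash_index >= 2)
}

predecessor_rows <- function(fl, rows) {
  key <- paste(fl$trial_id, fl$flash_index)
  match(paste(fl$trial_id[rows], fl$flash_index[rows] - 1L), key)
}

#' Cross-validated attention-axis projections
#'
#' Fits post-stimulus and orthogonalized pre-stimulus attention axes with
#' repeated random half-splits of the training-eligible intervals (the
#' pre-target interval and preceding-stimulus response of validly cued hit
#' targets), stratified by cue condition. Within each fold, both axes are
#' fit on the training half (post axis first; the pre axis is then
#' orthogonalized against it), and the projections of every interval in
#' the session are affinely normalized so the fold's training-condition
#' mean projections are exactly +1 (cue in RF) and -1 (cue away). Each
#' interval's reported projection is the average over the folds in which
#' it was not used for training; intervals never eligible for training are
#' averaged over all folds. Held-out averages are not constrained to be
#' +/-1.
#'
#' @param session session_data.
#' @param n_folds number of random half-split folds (default 1000).
#' @param seed optional integer seed.
#' @param min_angle_deg degeneracy threshold passed to
#'   \code{\link{orthogonalize_pre_axis}}; degenerate folds are resampled
#'   (up to 20 attempts) with a warning counter.
#' @return List of class \code{attention_projections}:
#'   \itemize{
#'     \item \code{records}: data.frame per flash row with \code{trial_id},
#'       \code{flash_index}, \code{is_target}, \code{a_pre}, \code{a_post},
#'       \code{n_folds_pre}, \code{n_folds_post}, \code{role}.
#'     \item \code{model}: unit list, full-data \code{w_post} and
#'       \code{w_pre}, per-fold normalization table, per-fold
#'       |<w_pre, w_post>| values, and degenerate-fold resample count.
#'   }
#' @export
cross_validated_projections <- function(session, n_folds = 1000, seed = NULL,
                                        min_angle_deg = 1) {
  if (!is.null(seed)) set.seed(seed)
  fl <- session$flashes
  units <- session$units$unit_id

  X_pre <- extract_epoch_counts(session, "pre")
  stopifnot(nrow(X_pre) == nrow(fl))
  post_part <- extract_epoch_counts(session, "post")
  X_post <- matrix(NA_real_, nrow = nrow(fl), ncol = length(units),
                   dimnames = list(NULL, units))
  X_post[attr(post_part, "flash_rows"), ] <- post_part

  targ_rows <- training_eligible_targets(fl)
  pred_rows <- predecessor_rows(fl, targ_rows)
  ok <- !is.na(pred_rows)
  targ_rows <- targ_rows[ok]; pred_rows <- pred_rows[ok]
  cond <- fl$cue_location[targ_rows]
  n_rf <- sum(cond == "RF"); n_aw <- sum(cond == "away")
  if (n_rf < 2 || n_aw < 2) {
    stop(sprintf("insufficient training-eligible targets (RF: %d, away: %d; need >= 2 each)",
                 n_rf, n_aw), call. = FALSE)
  }
  Tpre <- X_pre[targ_rows, , drop = FALSE]
  Tpost <- X_post[pred_rows, , drop = FALSE]
  i_rf <- which(cond == "RF"); i_aw <- which(cond == "away")

  U <- length(units)
  W_post <- matrix(0, U, n_folds); W_pre <- matrix(0, U, n_folds)
  c_post <- s_post <- c_pre <- s_pre <- numeric(n_folds)
  train_sets <- vector("list", n_folds)
  dots <- numeric(n_folds)
  n_resampled <- 0L

  fit_fold <- function(train) {
    w_po <- fit_attention_axis(Tpost[intersect(train, i_rf), , drop = FALSE],
                               Tpost[intersect(train, i_aw), , drop = FALSE])
    pre_raw <- colMeans(Tpre[intersect(train, i_rf), , drop = FALSE]) -
      colMeans(Tpre[intersect(train, i_aw), , drop = FALSE])
    w_pr <- orthogonalize_pre_axis(pre_raw, w_po, min_angle_deg)
    list(w_po = w_po, w_pr = w_pr)
  }

  for (b in seq_len(n_folds)) {
    fit <- NULL
    for (attempt in 1:20) {
      train <- c(sample(i_rf, floor(n_rf / 2)), sample(i_aw, floor(n_aw / 2)))
      fit <- tryCatch(fit_fold(train), error = function(e) NULL)
      if (!is.null(fit)) break
      n_resampled <- n_resampled + 1L
    }
    if (is.null(fit)) stop("could not find a non-degenerate fold in 20 attempts", call. = FALSE)
    W_post[, b] <- fit$w_po
    W_pre[, b] <- fit$w_pr
    dots[b] <- abs(sum(fit$w_po * fit$w_pr))
    tr_rf <- intersect(train, i_rf); tr_aw <- intersect(train, i_aw)
    p_in <- mean(Tpost[tr_rf, , drop = FALSE] %*% fit$w_po)
    p_aw <- mean(Tpost[tr_aw, , drop = FALSE] %*% fit$w_po)
    c_post[b] <- (p_in + p_aw) / 2; s_post[b] <- (p_in - p_aw) / 2
    q_in <- mean(Tpre[tr_rf, , drop = FALSE] %*% fit$w_pr)
    q_aw <- mean(Tpre[tr_aw, , drop = FALSE] %*% fit$w_pr)
    c_pre[b] <- (q_in + q_aw) / 2; s_pre[b] <- (q_in - q_aw) / 2
    train_sets[[b]] <- train
  }
  if (n_resampled > 0) {
    warning(sprintf("%d degenerate fold fit(s) were resampled", n_resampled), call. = FALSE)
  }

  P_pre <- sweep(sweep(X_pre %*% W_pre, 2, c_pre, "-"), 2, s_pre, "/")
  P_post <- sweep(sweep(X_post %*% W_post, 2, c_post, "-"), 2, s_post, "/")
  # mask out training intervals in the folds that used them
  for (b in seq_len(n_folds)) {
    tr <- train_sets[[b]]
    P_pre[targ_rows[tr], b] <- NA_real_
    P_post[pred_rows[tr], b] <- NA_real_
  }
  n_pre <- rowSums(!is.na(P_pre))
  n_post <- rowSums(!is.na(P_post))
  a_pre <- rowMeans(P_pre, na.rm = TRUE)
  a_post <- rowMeans(P_post, na.rm = TRUE)
  a_pre[n_pre == 0] <- NA_real_
  a_post[n_post == 0] <- NA_real_

  role <- rep("always-held-out", nrow(fl))
  role[c(targ_rows, pred_rows)] <- "training-eligible"
  records <- data.frame(
    trial_id = fl$trial_id, flash_index = fl$flash_index,
    is_target = fl$is_target, a_pre = a_pre, a_post = a_post,
    n_folds_pre = n_pre, n_folds_post = n_post, role = role,
    # first-flash pre intervals fall in the fixation period rather than an
    # inter-stimulus interval; flagged so users can exclude them
    pre_from_fixation = fl$flash_index == 1L,
    stringsAsFactors = FALSE
  )
  full <- fit_fold(seq_along(targ_rows))
  model <- structure(list(
    units = units, w_post = full$w_po, w_pre = full$w_pr,
    normalization = data.frame(fold = seq_len(n_folds), c_post = c_post,
                               s_post = s_post, c_pre = c_pre, s_pre = s_pre),
    fold_train_targets = train_sets, target_rows = targ_rows,
    predecessor_rows = pred_rows, condition = cond,
    abs_dot = dots, n_degenerate_resampled = n_resampled
  ), class = "attention_axis_model")
  structure(list(records = records, model = model,
                 fold_projections = NULL),
            class = "attention_projections")
}

#' Within-fold normalized training projections
#'
#' Recomputes, for one cross-validation fold of a fitted model, the mean
#' normalized projection of the training intervals per condition and axis.
#' By the normalization contract these are exactly +1 (cue in RF) and -1
#' (cue away).
#'
#' @param session session_data used to fit the model.
#' @param proj result of \code{\link{cross_validated_projections}}.
#' @param fold fold index.
#' @return data.frame: axis, condition, mean_projection.
#' @export
fold_training_means <- function(session, proj, fold = 1) {
  m <- proj$model
  train <- m$fold_train_targets[[fold]]
  X_pre <- extract_epoch_counts(session, "pre")
  post_part <- extract_epoch_counts(session, "post")
  X_post <- matrix(NA_real_, nrow = nrow(session$flashes), ncol = length(m$units))
  X_post[attr(post_part, "flash_rows"), ] <- post_part
  Tpre <- X_pre[m$target_rows, , drop = FALSE]
  Tpost <- X_post[m$predecessor_rows, , drop = FALSE]
  tr_rf <- intersect(train, which(m$condition == "RF"))
  tr_aw <- intersect(train, which(m$condition == "away"))
  # refit the fold's axes from its stored training set
  w_po <- fit_attention_axis(Tpost[tr_rf, , drop = FALSE], Tpost[tr_aw, , drop = FALSE])
  pre_raw <- colMeans(Tpre[tr_rf, , drop = FALSE]) - colMeans(Tpre[tr_aw, , drop = FALSE])
  w_pr <- orthogonalize_pre_axis(pre_raw, w_po)
  nm <- proj$model$normalization[fold, ]
  data.frame(
    axis = rep(c("post", "pre"), each = 2),
    condition = rep(c("RF", "away"), 2),
    mean_projection = c(
      (mean(Tpost[tr_rf, , drop = FALSE] %*% w_po) - nm$c_post) / nm$s_post,
      (mean(Tpost[tr_aw, , drop = FALSE] %*% w_po) - nm$c_post) / nm$s_post,
      (mean(Tpre[tr_rf, , drop = FALSE] %*% w_pr) - nm$c_pre) / nm$s_pre,
      (mean(Tpre[tr_aw, , drop = FALSE] %*% w_pr) - nm$c_pre) / nm$s_pre
    ),
    stringsAsFactors = FALSE
  )
}

#' Per-session hit/miss projection means
#'
#' For target flashes on the requested side, the pre-stimulus projection is
#' taken from the interval immediately preceding the target and the
#' post-stimulus projection from the response to the preceding sample
#' flash; means are computed separately for hits and misses.
#'
#' @param records projection records (from
#'   \code{\link{cross_validated_projections}}).
#' @param flashes flash table of the same session.
#' @param target_side \code{"RF"} or \code{"away"}.
#' @return One-row data.frame of means and counts, or NULL if the session
#'   has no hit or no miss of that side.
#' @export
hit_miss_session_means <- function(records, flashes, target_side = "RF") {
  key <- paste(flashes$trial_id, flashes$flash_index)
  targ <- which(flashes$is_target & flashes$target_location == target_side &
                  flashes$outcome %in% c("hit", "miss") & !flashes$is_cue_trial)
  if (!length(targ)) return(NULL)
  pred <- match(paste(flashes$trial_id[targ], flashes$flash_index[targ] - 1L), key)
  a_pre <- records$a_pre[targ]
  a_post <- records$a_post[pred]
  hit <- flashes$outcome[targ] == "hit"
  if (!any(hit) || all(hit)) return(NULL)
  data.frame(
    pre_hit = mean(a_pre[hit], na.rm = TRUE),
    pre_miss = mean(a_pre[!hit], na.rm = TRUE),
    post_hit = mean(a_post[hit], na.rm = TRUE),
    post_miss = mean(a_post[!hit], na.rm = TRUE),
    n_hit = sum(hit), n_miss = sum(!hit)
  )
}

#' Across-session hit/miss projection comparison
#'
#' Paired one-tailed t-tests across sessions of mean projections preceding
#' hits vs misses, per axis. For RF targets the alternative is that hits
#' are shifted toward +1; for away targets, toward -1. Sessions lacking a
#' hit or a miss of the requested side are excluded (with a message).
#'
#' @param session_results list; each element a list with \code{records}
#'   and \code{flashes} (or an \code{attention_projections} plus flash
#'   table as \code{$flashes}).
#' @param target_side \code{"RF"} or \code{"away"}.
#' @return List: \code{per_session} data.frame, \code{tests} data.frame
#'   (axis, t, df, p_value), \code{n_sessions_used},
#'   \code{n_sessions_excluded}.
#' @export
compare_hit_miss_projections <- function(session_results, target_side = "RF") {
  rows <- list()
  excluded <- 0L
  for (sr in session_results) {
    recs <- if (!is.null(sr$records)) sr$records else sr
    m <- hit_miss_session_means(recs, sr$flashes, target_side)
    if (is.null(m) || any(!is.finite(unlist(m[1, 1:4])))) {
      excluded <- excluded + 1L
      next
    }
    rows[[length(rows) + 1L]] <- m
  }
  if (excluded > 0) {
    message(sprintf("%d session(s) excluded from the paired hit/miss test (no %s-side hit or miss)",
                    excluded, target_side))
  }
  if (length(rows) < 2) stop("need >= 2 usable sessions for the paired test", call. = FALSE)
  per <- do.call(rbind, rows)
  alt <- if (target_side == "RF") "greater" else "less"
  tests <- lapply(c(pre = "pre", post = "post"), function(ax) {
    d <- per[[paste0(ax, "_hit")]] - per[[paste0(ax, "_miss")]]
    if (stats::sd(d) == 0) {
      return(data.frame(axis = ax, t = NA_real_, df = length(d) - 1,
                        p_value = NA_real_))
    }
    tt <- stats::t.test(d, alternative = alt)
    data.frame(axis = ax, t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value)
  })
  list(per_session = per, tests = do.call(rbind, c(tests, make.row.names = FALSE)),
       n_sessions_used = nrow(per), n_sessions_excluded = excluded)
}
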