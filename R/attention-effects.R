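#' Relative attention effect for one unit and epoch
#'
#' Effect = (mean cue-in-RF - mean cue-away) / mean cue-away on raw
#' per-flash spike counts, with a two-sided Mann-Whitney (rank-sum) test on
#' the counts. The ratio is scale-invariant and the p-value is invariant
#' under strictly monotone transforms of the counts.
#'
#' @param counts_in numeric vector of per-flash counts, cue in RF.
#' @param counts_away numeric vector of per-flash counts, cue away.
#' @return List: \code{effect} (NA if the cue-away mean is zero),
#'   \code{p_value}.
#' @export
relative_attention_effect <- function(counts_in, counts_away) {
  if (!length(counts_in) || !length(counts_away)) {
    stop("both count samples must be nonempty", call. = FALSE)
  }
  m_away <- mean(counts_away)
  eff <- if (m_away > 0) (mean(counts_in) - m_away) / m_away else NA_real_
  p <- suppressWarnings(
    stats::wilcox.test(counts_in, counts_away, exact = NULL)$p.value
  )
  if (is.nan(p)) p <- 1  # identical constant samples
  list(effect = eff, p_value = p)
}

#' Per-unit attention effects for a session
#'
#' Computes the relative attention effect and rank-sum p-value for every
#' unit in both epochs of interest (pre-stimulus [-200, 0) and
#' post-stimulus [200, 400) ms), using all non-target sample flashes of
#' bilateral trials grouped by the block cue location.
#'
#' @param session session_data.
#' @param units unit ids (default: all).
#' @param alpha significance level.
#' @return data.frame: \code{unit_id}, \code{epoch}, \code{effect},
#'   \code{p_value}, \code{significant}.
#' @export
attention_effect_table <- function(session, units = NULL, alpha = 0.05) {
  if (is.null(units)) units <- session$units$unit_id
  filt <- sample_flash_filter(session$flashes)
  out <- list()
  for (epoch in c("pre", "post")) {
    cnt <- extract_epoch_counts(session, epoch, units = units, flash_filter = filt)
    rows <- attr(cnt, "flash_rows")
    cue <- session$flashes$cue_location[rows]
    for (j in seq_len(ncol(cnt))) {
      r <- relative_attention_effect(cnt[cue == "RF", j], cnt[cue == "away", j])
      out[[length(out) + 1L]] <- list(unit_id = colnames(cnt)[j], epoch = epoch,
                                      effect = r$effect, p_value = r$p_value,
                                      significant = r$p_value < alpha)
    }
  }
  rbind_lists(out)
}

#' Joint pre/post classification of attention effects
#'
#' Among units with significant effects in both epochs, counts the four
#' sign quadrants (post vs pre) and the fraction that flip the direction
#' of their attention modulation between the unstimulated and stimulated
#' states.
#'
#' @param pre data.frame of pre-epoch effects (unit_id, effect,
#'   significant), e.g. a subset of \code{\link{attention_effect_table}}.
#' @param post matching data.frame of post-epoch effects.
#' @return List: \code{quadrants} (2x2 table, rows = pre sign, cols = post
#'   sign), \code{n_both_significant}, \code{n_flipped},
#'   \code{flip_fraction}.
#' @export
classify_joint_effects <- function(pre, post) {
  if (!setequal(pre$unit_id, post$unit_id)) {
    stop("pre and post effect tables must cover the same units", call. = FALSE)
  }
  post <- post[match(pre$unit_id, post$unit_id), , drop = FALSE]
  both <- pre$significant & post$significant &
    !is.na(pre$effect) & !is.na(post$effect)
  sp <- sign(pre$effect[both])
  so <- sign(post$effect[both])
  quad <- table(factor(ifelse(sp >= 0, "pre+", "pre-"), levels = c("pre+", "pre-")),
                factor(ifelse(so >= 0, "post+", "post-"), levels = c("post+", "post-")))
  n_flip <- sum(sp != so)
  list(quadrants = quad, n_both_significant = sum(both), n_flipped = n_flip,
       flip_fraction = if (sum(both) > 0) n_flip / sum(both) else NA_real_)
}

#' Correlation of attention effects across epochs
#'
#' Pearson correlation between per-unit pre-stimulus and post-stimulus
#' relative attention effects.
#'
#' @param pre numeric vector of pre-epoch effects (or effect table subset).
#' @param post matching vector of post-epoch effects.
#' @return List: \code{r}, \code{p_value}, \code{n}.
#' @export
correlate_effects_across_epochs <- function(pre, post) {
  if (is.data.frame(pre)) pre <- pre$effect
  if (is.data.frame(post)) post <- post$effect
  ok <- is.finite(pre) & is.finite(post)
  pre <- pre[ok]; post <- post[ok]
  if (length(pre) < 3) stop("need at least 3 paired finite effects", call. = FALSE)
  if (stats::sd(pre) == 0 || stats::sd(post) == 0) {
    stop("zero variance in effects; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(pre, post, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(pre))
}
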