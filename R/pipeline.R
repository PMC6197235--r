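#' Validate and normalize a generator configuration
#'
#' Accepts a YAML file path or a named list of overrides, fills all
#' defaults from \code{\link{generator_config}}, range-checks every field
#' and warns about unknown keys (suggesting the nearest known key).
#'
#' @param x YAML file path, named list, or NULL (full defaults).
#' @return generator_config.
#' @export
validate_config <- function(x = NULL) {
  if (is.null(x)) return(generator_config())
  if (is.character(x) && length(x) == 1) {
    x <- yaml::read_yaml(x)
    if (is.null(x)) x <- list()
  }
  if (!is.list(x)) stop("config must be a file path or a named list", call. = FALSE)
  known <- names(generator_config())
  unknown <- setdiff(names(x), known)
  for (u in unknown) {
    near <- known[which.min(utils::adist(u, known))]
    warning(sprintf("unknown config key '%s' ignored (did you mean '%s'?)", u, near),
            call. = FALSE)
  }
  do.call(generator_config, x[intersect(names(x), known)])
}

analysis_units <- function(session) {
  scr <- screen_units(session)
  scr$unit_id[scr$kept]
}

#' Run a complete synthetic experiment
#'
#' Generates \code{n_sessions} synthetic sessions and runs every analysis
#' stage: unit screening, grand-average PSTH comparison, per-unit
#' attention effects with joint classification, cross-validated attention
#' axes, hit/miss projection comparison, quintile performance maps with
#' rank correlations, and the two-step VAF regression with shuffled null
#' and run-length-corrected significance masks. Figure-ready CSVs and a
#' JSON run manifest are written to \code{out_dir}.
#'
#' @param config generator_config (or anything \code{\link{validate_config}}
#'   accepts).
#' @param n_sessions number of sessions.
#' @param seed integer seed for the whole run.
#' @param out_dir output directory.
#' @param n_folds cross-validation folds per session.
#' @param gain_only if TRUE, uses the stimulation-invariant-gain control
#'   generator and labels pre-axis results as negative controls.
#' @param n_shuffles shuffles for the null VAF.
#' @param runlength_sims simulated experiments for the run-length
#'   calibration.
#' @param deterministic if TRUE (default) the manifest omits wall-clock
#'   timestamps so identical runs produce byte-identical outputs.
#' @return Invisibly, a list with all stage results and \code{files}, the
#'   manifest path list.
#' @export
run_experiment <- function(config = generator_config(), n_sessions = 4, seed = 1,
                           out_dir = tempfile("attnaxes_run_"), n_folds = 100,
                           gain_only = FALSE, n_shuffles = 20,
                           runlength_sims = 500, deterministic = TRUE) {
  config <- validate_config(if (inherits(config, "generator_config")) unclass(config) else config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  session_seeds <- sample.int(2^31 - 2, n_sessions)

  sessions <- vector("list", n_sessions)
  psths <- vector("list", n_sessions)
  effects <- vector("list", n_sessions)
  axis_results <- vector("list", n_sessions)
  maps <- vector("list", n_sessions)
  vaf_post_rows <- vaf_pre_rows <- vector("list", n_sessions)
  null_levels <- numeric(n_sessions)
  time_ms <- NULL

  for (i in seq_len(n_sessions)) {
    cfg_i <- config
    cfg_i$session_id <- sprintf("%s-%02d", config$session_id, i)
    gen <- generate_session(cfg_i, seed = session_seeds[i], gain_only = gain_only)
    ses <- gen$session
    keep <- analysis_units(ses)
    message(sprintf("[session %02d] seed=%d units_kept=%d/%d trials=%d",
                    i, session_seeds[i], length(keep), nrow(ses$units),
                    length(unique(ses$flashes$trial_id))))
    psths[[i]] <- session_mean_psth(ses)
    eff <- attention_effect_table(ses, units = keep)
    eff$session <- i
    effects[[i]] <- eff
    proj <- cross_validated_projections(ses, n_folds = n_folds)
    axis_results[[i]] <- list(records = proj$records, model = proj$model,
                              flashes = ses$flashes)
    maps[[i]] <- bin_projections_quintiles(proj$records, ses$flashes, "RF")
    series <- stimulus_response_series(ses, units = keep)
    predictors <- align_projection_predictors(series, proj$records, ses$flashes)
    vaf <- two_step_vaf(series, predictors$a_post, predictors$a_pre)
    nul <- shuffled_null_vaf(series, predictors$a_post, predictors$a_pre,
                             n_shuffles = n_shuffles)
    vaf_post_rows[[i]] <- vaf$vaf_post
    vaf_pre_rows[[i]] <- vaf$vaf_pre
    null_levels[i] <- nul$null
    time_ms <- vaf$time_ms
    sessions[[i]] <- ses
  }

  grand <- grand_average_comparison(psths)
  eff_all <- do.call(rbind, effects)
  pre_eff <- eff_all[eff_all$epoch == "pre", ]
  post_eff <- eff_all[eff_all$epoch == "post", ]
  pre_eff$uid <- paste(pre_eff$session, pre_eff$unit_id)
  post_eff$uid <- paste(post_eff$session, post_eff$unit_id)
  joint <- classify_joint_effects(
    data.frame(unit_id = pre_eff$uid, effect = pre_eff$effect,
               significant = pre_eff$significant),
    data.frame(unit_id = post_eff$uid, effect = post_eff$effect,
               significant = post_eff$significant))
  eff_cor <- correlate_effects_across_epochs(pre_eff$effect, post_eff$effect)
  hitmiss <- compare_hit_miss_projections(axis_results, "RF")
  rankcor <- if (n_sessions >= 3) rank_correlation_sessions(maps) else NULL

  vaf_post_mat <- do.call(rbind, vaf_post_rows)
  vaf_pre_mat <- do.call(rbind, vaf_pre_rows)
  null_level <- mean(null_levels)
  rl <- runlength_threshold(rbind(vaf_post_mat, vaf_pre_mat),
                            n_sims = runlength_sims)
  mask_post <- significance_mask(vaf_post_mat, null_level, rl$threshold,
                                 time_ms = time_ms)
  mask_pre <- significance_mask(vaf_pre_mat, null_level, rl$threshold,
                                time_ms = time_ms)

  files <- list(
    psth = file.path(out_dir, "psth_grand.csv"),
    effects = file.path(out_dir, "effects.csv"),
    quadrants = file.path(out_dir, "quadrants.csv"),
    hitmiss = file.path(out_dir, "hitmiss.csv"),
    perf_map = file.path(out_dir, "perf_map.csv"),
    marginals = file.path(out_dir, "marginals.csv"),
    vaf = file.path(out_dir, "vaf.csv"),
    runlength = file.path(out_dir, "runlength.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  utils::write.csv(grand, files$psth, row.names = FALSE)
  utils::write.csv(eff_all[, c("session", "unit_id", "epoch", "effect",
                               "p_value", "significant")],
                   files$effects, row.names = FALSE)
  quad <- as.data.frame(joint$quadrants)
  names(quad) <- c("pre_sign", "post_sign", "n")
  quad$flip_fraction <- joint$flip_fraction
  quad$effect_correlation_r <- eff_cor$r
  utils::write.csv(quad, files$quadrants, row.names = FALSE)
  hm <- hitmiss$per_session
  utils::write.csv(hm, files$hitmiss, row.names = FALSE)
  cells_all <- do.call(rbind, lapply(seq_along(maps), function(i) {
    cbind(session = i, maps[[i]]$cells)
  }))
  utils::write.csv(cells_all, files$perf_map, row.names = FALSE)
  marg <- do.call(rbind, lapply(seq_along(maps), function(i) {
    data.frame(session = i, quintile = 1:5,
               pre = marginal_performance(maps[[i]], "pre"),
               post = marginal_performance(maps[[i]], "post"))
  }))
  utils::write.csv(marg, files$marginals, row.names = FALSE)
  n_s <- nrow(vaf_post_mat)
  vaf_df <- data.frame(
    t_ms = time_ms,
    vaf_post_mean = colMeans(vaf_post_mat),
    vaf_post_sem = apply(vaf_post_mat, 2, stats::sd) / sqrt(n_s),
    vaf_pre_mean = colMeans(vaf_pre_mat),
    vaf_pre_sem = apply(vaf_pre_mat, 2, stats::sd) / sqrt(n_s),
    null = null_level,
    sig_post = mask_post$mask,
    sig_pre = mask_pre$mask
  )
  utils::write.csv(vaf_df, files$vaf, row.names = FALSE)
  jsonlite::write_json(
    list(threshold = rl$threshold, ar_coef = rl$ar_coef,
         n_sims = rl$n_sims, seed = seed),
    files$runlength, auto_unbox = TRUE, digits = NA)

  stage_files <- files[setdiff(names(files), "manifest")]
  manifest <- list(
    package_version = as.character(utils::packageVersion("attnaxes")),
    seed = seed,
    n_sessions = n_sessions,
    n_folds = n_folds,
    gain_only = gain_only,
    negative_control = if (gain_only)
      "pre-axis behavior and VAF outputs are negative controls (gain-only generator)" else NULL,
    config = unclass(config),
    digests = as.list(tools::md5sum(unlist(stage_files)))
  )
  if (!deterministic) manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE, digits = NA,
                       null = "null")

  invisible(list(
    files = files, sessions = sessions, grand_psth = grand,
    effects = eff_all, joint = joint, effect_correlation = eff_cor,
    hitmiss = hitmiss, maps = maps, rank_correlation = rankcor,
    vaf_post = vaf_post_mat, vaf_pre = vaf_pre_mat, time_ms = time_ms,
    null_level = null_level, runlength = rl,
    mask_post = mask_post, mask_pre = mask_pre
  ))
}
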