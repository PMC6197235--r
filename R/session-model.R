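#' Default analysis epochs
#'
#' Epoch windows in ms relative to flash onset. All windows are half-open
#' \code{[start, end)} so that a spike contributes to exactly one of two
#' abutting epochs.
#'
#' @return Named list of length-2 numeric vectors (start, end), ms.
#' @export
default_epochs <- function() {
  list(
    pre      = c(-200, 0),
    post     = c(200, 400),
    baseline = c(-100, 0),
    response = c(-100, 600),
    psth     = c(-300, 700)
  )
}

#' Default session parameters
#'
#' @return List with epoch definitions and the stimulus duration (ms).
#' @export
default_session_params <- function() {
  list(epochs = default_epochs(), stimulus_ms = 400)
}

FLASH_COLUMNS <- c(
  "session_id", "trial_id", "flash_index", "onset_ms", "is_cue_trial",
  "cue_location", "stimulus_locations", "orientation_RF", "is_target",
  "target_location", "delta_orientation", "outcome", "response_time_ms"
)
SPIKE_COLUMNS <- c("unit_id", "trial_id", "time_ms")
UNIT_COLUMNS <- c("unit_id", "snr")

#' Assemble and validate a session
#'
#' Bundles a flash table (one row per stimulus flash), a spike-event table
#' (one row per spike), a unit metadata table and session parameters, and
#' checks all structural invariants (increasing flash indices and onsets,
#' target/outcome consistency, block-constant cue location, and
#' cross-references between tables).
#'
#' @param flashes data.frame with columns
#'   \code{session_id, trial_id, flash_index, onset_ms, is_cue_trial,
#'   cue_location, stimulus_locations, orientation_RF, is_target,
#'   target_location, delta_orientation, outcome, response_time_ms}.
#' @param spikes data.frame with columns \code{unit_id, trial_id, time_ms}.
#' @param units data.frame with columns \code{unit_id} and optional
#'   \code{snr}.
#' @param params list of session parameters; see
#'   \code{\link{default_session_params}}.
#' @return Object of class \code{session_data}.
#' @export
session_data <- function(flashes, spikes, units, params = default_session_params()) {
  x <- structure(
    list(flashes = flashes, spikes = spikes, units = units, params = params),
    class = "session_data"
  )
  validate_session(x)
  x
}

#' @export
print.session_data <- function(x, ...) {
  cat(sprintf(
    "<session_data> %s: %d trials, %d flashes, %d units, %d spikes\n",
    x$flashes$session_id[1], length(unique(x$flashes$trial_id)),
    nrow(x$flashes), nrow(x$units), nrow(x$spikes)
  ))
  invisible(x)
}

stop_schema <- function(file, row, column, msg) {
  stop(sprintf("schema violation in %s (row %s, column %s): %s",
               file, paste(row, collapse = ","), column, msg), call. = FALSE)
}

#' Validate a session_data object
#'
#' @param x session_data.
#' @return Invisibly \code{x}; throws a diagnostic error on violation.
#' @export
validate_session <- function(x) {
  fl <- x$flashes
  sp <- x$spikes
  un <- x$units
  miss <- setdiff(FLASH_COLUMNS, names(fl))
  if (length(miss)) stop_schema("flashes", NA, paste(miss, collapse = ","), "missing column(s)")
  miss <- setdiff(SPIKE_COLUMNS, names(sp))
  if (length(miss)) stop_schema("spikes", NA, paste(miss, collapse = ","), "missing column(s)")
  if (!"unit_id" %in% names(un)) stop_schema("units", NA, "unit_id", "missing column")

  if (nrow(sp) && any(sp$time_ms < 0)) {
    stop_schema("spikes", which(sp$time_ms < 0)[1], "time_ms", "negative spike time")
  }
  # per-trial structure
  for (tid in unique(fl$trial_id)) {
    tf <- fl[fl$trial_id == tid, , drop = FALSE]
    tf <- tf[order(tf$flash_index), , drop = FALSE]
    if (!identical(as.integer(tf$flash_index), seq_len(nrow(tf)))) {
      stop_schema("flashes", which(fl$trial_id == tid), "flash_index",
                  sprintf("trial %s: flash_index must be 1,2,... without gaps", tid))
    }
    if (nrow(tf) > 1 && any(diff(tf$onset_ms) <= 0)) {
      stop_schema("flashes", which(fl$trial_id == tid), "onset_ms",
                  sprintf("trial %s: onsets not strictly increasing", tid))
    }
    if (length(unique(tf$cue_location)) != 1) {
      stop_schema("flashes", which(fl$trial_id == tid), "cue_location",
                  sprintf("trial %s: cue_location not constant", tid))
    }
    n_targ <- sum(tf$is_target)
    if (n_targ > 1) {
      stop_schema("flashes", which(fl$trial_id == tid), "is_target",
                  sprintf("trial %s: more than one target", tid))
    }
    if (n_targ == 1 && which(tf$is_target) != nrow(tf)) {
      stop_schema("flashes", which(fl$trial_id == tid), "is_target",
                  sprintf("trial %s: target is not the final flash", tid))
    }
  }
  bad <- fl$is_target & (fl$target_location == "none" | fl$delta_orientation == 0)
  if (any(bad)) {
    stop_schema("flashes", which(bad)[1], "target_location",
                "target flash must have a target_location and nonzero delta_orientation")
  }
  bad <- fl$outcome %in% c("hit", "miss") & !fl$is_target
  if (any(bad)) {
    stop_schema("flashes", which(bad)[1], "outcome",
                "hit/miss outcome on a non-target flash")
  }
  bad <- fl$outcome == "false_alarm" & fl$is_target
  if (any(bad)) {
    stop_schema("flashes", which(bad)[1], "outcome", "false_alarm on a target flash")
  }
  # cross references
  orphan <- setdiff(unique(sp$unit_id), un$unit_id)
  if (length(orphan)) {
    stop(sprintf("cross-reference failure: spike unit_id(s) not in units table: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  orphan <- setdiff(unique(sp$trial_id), unique(fl$trial_id))
  if (length(orphan)) {
    stop(sprintf("cross-reference failure: spike trial_id(s) not in flash table: %s",
                 paste(orphan, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

resolve_session_paths <- function(paths) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- list(
      flashes = file.path(paths, "flashes.csv"),
      spikes = file.path(paths, "spikes.csv"),
      units = file.path(paths, "units.csv")
    )
  }
  stopifnot(all(c("flashes", "spikes", "units") %in% names(paths)))
  paths
}

#' Read a session from delimited files
#'
#' Reads \code{flashes.csv}, \code{spikes.csv} and \code{units.csv}
#' (comma-delimited, UTF-8, header row required) and returns a validated
#' \code{session_data}. \code{paths} may be a directory containing those
#' three files or a named list of file paths.
#'
#' @param paths directory or named list (\code{flashes}, \code{spikes},
#'   \code{units}).
#' @param params session parameters.
#' @return session_data.
#' @export
read_session <- function(paths, params = default_session_params()) {
  paths <- resolve_session_paths(paths)
  check_cols <- function(path, expected) {
    got <- names(utils::read.csv(path, nrows = 0))
    if (!identical(got, expected)) {
      stop_schema(path, NA, paste(got, collapse = ","),
                  sprintf("columns must be exactly: %s", paste(expected, collapse = ",")))
    }
  }
  check_cols(paths$flashes, FLASH_COLUMNS)
  check_cols(paths$spikes, SPIKE_COLUMNS)
  check_cols(paths$units, UNIT_COLUMNS)
  fl <- utils::read.csv(paths$flashes, stringsAsFactors = FALSE,
                        colClasses = c(
                          session_id = "character", trial_id = "integer",
                          flash_index = "integer", onset_ms = "integer",
                          is_cue_trial = "logical", cue_location = "character",
                          stimulus_locations = "character",
                          orientation_RF = "numeric", is_target = "logical",
                          target_location = "character",
                          delta_orientation = "numeric", outcome = "character",
                          response_time_ms = "numeric"
                        ))
  if (!identical(names(fl), FLASH_COLUMNS)) {
    stop_schema(paths$flashes, NA, paste(names(fl), collapse = ","),
                sprintf("columns must be exactly: %s", paste(FLASH_COLUMNS, collapse = ",")))
  }
  sp <- utils::read.csv(paths$spikes, stringsAsFactors = FALSE,
                        colClasses = c(unit_id = "character",
                                       trial_id = "integer", time_ms = "integer"))
  if (!identical(names(sp), SPIKE_COLUMNS)) {
    stop_schema(paths$spikes, NA, paste(names(sp), collapse = ","),
                sprintf("columns must be exactly: %s", paste(SPIKE_COLUMNS, collapse = ",")))
  }
  un <- utils::read.csv(paths$units, stringsAsFactors = FALSE,
                        colClasses = c(unit_id = "character", snr = "numeric"))
  if (!identical(names(un), UNIT_COLUMNS)) {
    stop_schema(paths$units, NA, paste(names(un), collapse = ","),
                sprintf("columns must be exactly: %s", paste(UNIT_COLUMNS, collapse = ",")))
  }
  session_data(fl, sp, un, params)
}

canonicalize_session <- function(session) {
  fl <- session$flashes
  sp <- session$spikes
  un <- session$units
  session$flashes <- fl[order(fl$trial_id, fl$flash_index), , drop = FALSE]
  session$spikes <- sp[order(sp$unit_id, sp$trial_id, sp$time_ms), , drop = FALSE]
  session$units <- un[order(un$unit_id), , drop = FALSE]
  rownames(session$flashes) <- NULL
  rownames(session$spikes) <- NULL
  rownames(session$units) <- NULL
  session
}

#' Write a session to delimited files
#'
#' Writes the three session tables in canonical row order
#' (\code{trial_id, flash_index} for flashes; \code{unit_id, trial_id,
#' time_ms} for spikes) so that write/read round trips are the identity on
#' canonicalized sessions. Missing response times are written as empty
#' fields.
#'
#' @param session session_data.
#' @param paths output directory (created if needed) or named list of paths.
#' @return Invisibly, the named list of file paths written.
#' @export
write_session <- function(session, paths) {
  if (is.character(paths) && length(paths) == 1) {
    dir.create(paths, showWarnings = FALSE, recursive = TRUE)
    paths <- list(flashes = file.path(paths, "flashes.csv"),
                  spikes = file.path(paths, "spikes.csv"),
                  units = file.path(paths, "units.csv"))
  }
  session <- canonicalize_session(session)
  utils::write.csv(session$flashes, paths$flashes, row.names = FALSE,
                   quote = FALSE, na = "")
  utils::write.csv(session$spikes, paths$spikes, row.names = FALSE, quote = FALSE)
  un <- session$units
  if (!"snr" %in% names(un)) un$snr <- NA_real_
  utils::write.csv(un[, UNIT_COLUMNS], paths$units, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(paths)
}

# Absolute spike times on a concatenated session timeline. Trials are laid
# out end to end in trial_id order; trial duration is the last flash onset
# plus the stimulus duration plus a 300 ms tail (or the last spike, if
# later).
session_timeline <- function(session) {
  fl <- session$flashes
  sp <- session$spikes
  trial_ids <- sort(unique(fl$trial_id))
  last_onset <- tapply(fl$onset_ms, fl$trial_id, max)[as.character(trial_ids)]
  dur <- last_onset + session$params$stimulus_ms + 300
  if (nrow(sp)) {
    sp_max <- tapply(sp$time_ms, sp$trial_id, max)
    idx <- match(names(sp_max), as.character(trial_ids))
    dur[idx] <- pmax(dur[idx], sp_max + 1)
  }
  offsets <- c(0, cumsum(as.numeric(dur)))[seq_along(trial_ids)]
  names(offsets) <- as.character(trial_ids)
  list(trial_ids = trial_ids, offsets = offsets, durations = as.numeric(dur),
       total = sum(as.numeric(dur)))
}

#' Extract an epoch spike-count matrix
#'
#' Returns a flashes-by-units matrix of spike counts in the half-open window
#' \code{[onset + start, onset + end)} around each flash onset. Neural data
#' from the time of target onset onwards are excluded: for any epoch whose
#' window extends to or past onset, target flashes are dropped; the
#' pre-stimulus epoch of a target flash ends strictly before target onset
#' and is retained.
#'
#' @param session session_data.
#' @param epoch epoch name (see \code{\link{default_epochs}}) or a length-2
#'   numeric window (ms relative to onset).
#' @param units character vector of unit ids (default: all units).
#' @param flash_filter optional logical vector over flash rows, or a
#'   function taking the flash table and returning one.
#' @return Integer matrix with one row per retained flash (rownames
#'   \code{"<trial>:<flash>"}) and one column per unit. Attributes:
#'   \code{epoch}, \code{flash_rows} (row indices into the flash table).
#' @export
extract_epoch_counts <- function(session, epoch, units = NULL, flash_filter = NULL) {
  if (is.character(epoch)) {
    if (!epoch %in% names(session$params$epochs)) {
      stop(sprintf("unknown epoch '%s'; defined: %s", epoch,
                   paste(names(session$params$epochs), collapse = ", ")), call. = FALSE)
    }
    win <- session$params$epochs[[epoch]]
    epoch_label <- epoch
  } else {
    win <- epoch
    epoch_label <- sprintf("[%g,%g)", win[1], win[2])
  }
  if (is.null(units)) units <- session$units$unit_id
  unknown <- setdiff(units, session$units$unit_id)
  if (length(unknown)) {
    stop(sprintf("unknown unit(s): %s", paste(unknown, collapse = ", ")), call. = FALSE)
  }
  fl <- session$flashes
  keep <- rep(TRUE, nrow(fl))
  if (!is.null(flash_filter)) {
    if (is.function(flash_filter)) flash_filter <- flash_filter(fl)
    keep <- keep & flash_filter
  }
  if (win[2] > 0) keep <- keep & !fl$is_target  # no data at/after target onset
  rows <- which(keep)

  tl <- session_timeline(session)
  off <- tl$offsets[as.character(fl$trial_id[rows])]
  abs_start <- off + fl$onset_ms[rows] + win[1]
  abs_end <- off + fl$onset_ms[rows] + win[2]

  sp <- session$spikes
  counts <- matrix(0L, nrow = length(rows), ncol = length(units),
                   dimnames = list(paste0(fl$trial_id[rows], ":", fl$flash_index[rows]),
                                   units))
  if (nrow(sp)) {
    sp_abs <- tl$offsets[as.character(sp$trial_id)] + sp$time_ms
    by_unit <- split(sp_abs, factor(sp$unit_id, levels = units))
    for (j in seq_along(units)) {
      tj <- sort(by_unit[[j]])
      if (!length(tj)) next
      # integer times: count of t in [start, end) = #(t <= end-1) - #(t <= start-1)
      counts[, j] <- findInterval(abs_end - 0.5, tj) - findInterval(abs_start - 0.5, tj)
    }
  }
  structure(counts, epoch = epoch_label, flash_rows = rows)
}

#' Causal half-Gaussian spike-train smoothing
#'
#' Convolves a 1 ms binned spike count series with a causal half-Gaussian
#' kernel (nonzero only for non-negative lags, standard deviation
#' \code{sigma_ms}, truncated at 4 sigma and renormalized to unit mass) and
#' scales to spikes/s. The filter is strictly causal: the output is zero
#' before the first spike.
#'
#' @param binned_spikes numeric vector of per-ms spike counts (or any
#'   per-ms signal; smoothing is linear).
#' @param sigma_ms kernel standard deviation in ms (default 20).
#' @return Numeric vector of the same length, in spikes/s.
#' @export
smooth_spike_train <- function(binned_spikes, sigma_ms = 20) {
  if (sigma_ms <= 0) stop("sigma_ms must be positive", call. = FALSE)
  k <- half_gaussian_kernel(sigma_ms)
  n <- length(binned_spikes)
  pad <- length(k) - 1
  y <- stats::filter(c(rep(0, pad), binned_spikes), k, method = "convolution",
                     sides = 1)
  as.numeric(y[(pad + 1):(pad + n)]) * 1000
}

half_gaussian_kernel <- function(sigma_ms) {
  u <- 0:floor(4 * sigma_ms)
  k <- stats::dnorm(u, mean = 0, sd = sigma_ms)
  k / sum(k)
}
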