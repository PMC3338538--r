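#' Discrete-cosine high-pass basis
#'
#' Cosine basis functions with period at least `1/cutoff` seconds, the
#' standard drift model in fMRI GLMs. The number of columns is
#' `floor(2 * n_scans * tr * cutoff)`.
#'
#' @param n_scans Number of scans.
#' @param tr Repetition time (seconds).
#' @param cutoff High-pass cutoff frequency in Hz (default 1/128).
#' @return A scans x K matrix (K may be 0).
#' @export
dct_basis <- function(n_scans, tr, cutoff = 1 / 128) {
  K <- floor(2 * n_scans * tr * cutoff)
  if (K < 1) return(matrix(numeric(0), n_scans, 0))
  sapply(seq_len(K), function(k)
    cos(pi * k * (2 * seq_len(n_scans) - 1) / (2 * n_scans)))
}

#' Regress motion and low-frequency drift out of a voxel time series
#'
#' Ordinary least-squares residuals of every voxel on an intercept, the
#' motion regressors, and a discrete-cosine high-pass basis up to `cutoff`
#' (default 1/128 Hz). Applied once to the whole session, before epoching.
#'
#' @param series Scans x voxels matrix (or a `bold_sim`, whose series and
#'   motion are used).
#' @param motion Scans x m matrix of motion regressors (may be `NULL`).
#' @param tr Repetition time in seconds.
#' @param cutoff High-pass cutoff in Hz.
#' @return Residual scans x voxels matrix.
#' @export
regress_confounds <- function(series, motion = NULL, tr, cutoff = 1 / 128) {
  if (inherits(series, "bold_sim")) {
    if (is.null(motion)) motion <- series$motion
    if (missing(tr)) tr <- series$tr
    series <- series$series
  }
  n <- nrow(series)
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n)
      stop_invalid("motion regressors must have one row per scan")
  }
  X <- cbind(1, motion, dct_basis(n, tr, cutoff))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient confound matrix; using pseudo-inverse fit")
    P <- X %*% MASS_ginv(X)
    return(series - P %*% series)
  }
  series - X %*% qr.coef(qrX, series)
}

# Moore-Penrose pseudo-inverse via SVD (kept local: only the degenerate
# confound path needs it).
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

scan_midpoints <- function(n_scans, tr) (seq_len(n_scans) - 0.5) * tr

# Average the listed scans per kept event into a samples x voxels matrix.
sample_matrix <- function(series, scan_list, idx_keep) {
  if (length(idx_keep) == 0L)
    return(matrix(numeric(0), 0, ncol(series)))
  do.call(rbind, lapply(idx_keep, function(i)
    colMeans(series[scan_list[[i]], , drop = FALSE])))
}

new_sample_set <- function(X, labels, block, scans, dropped = NULL) {
  labels <- factor(labels, levels = categories())
  stopifnot(nrow(X) == length(labels), nrow(X) == length(block))
  structure(list(X = X, labels = labels, block = as.integer(block),
                 scans = scans, dropped = dropped),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set: %d samples x %d voxels, %d blocks>\n",
              nrow(x$X), ncol(x$X), length(unique(x$block))))
  print(table(x$labels))
  invisible(x)
}

#' Subset a sample set by sample index
#'
#' @param x A `sample_set`.
#' @param i Sample indices (logical or integer).
#' @param ... Unused.
#' @return A `sample_set` with the selected samples.
#' @export
subset_samples <- function(x, i, ...) {
  new_sample_set(x$X[i, , drop = FALSE], x$labels[i], x$block[i], x$scans[i],
                 dropped = x$dropped)
}

#' Extract per-event samples from a paced exploration session
#'
#' For each event, scans whose acquisition midpoints fall in the half-open
#' window `[onset + hrf_delay, onset + hrf_delay + window)` are averaged
#' into one sample, correcting for the hemodynamic delay in continuous
#' time. Events whose window extends past the run are dropped with a
#' warning and recorded in the result's `dropped` table.
#'
#' @param series Scans x voxels matrix of (confound-regressed) signal.
#' @param events An `event_table` from an exploration-type design.
#' @param tr Repetition time in seconds.
#' @param hrf_delay Hemodynamic delay in seconds (default 6).
#' @param window Averaging window in seconds, normally the stimulus
#'   duration (default 3).
#' @return A `sample_set`; `$scans` records the scan indices averaged into
#'   each sample.
#' @export
extract_exploration_samples <- function(series, events, tr, hrf_delay = 6,
                                        window = 3) {
  n <- nrow(series)
  mid <- scan_midpoints(n, tr)
  keep <- logical(nrow(events)); scans <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    lo <- events$onset[i] + hrf_delay
    hi <- lo + window
    idx <- which(mid >= lo & mid < hi)
    if (length(idx) == 0L || hi > n * tr) next
    keep[i] <- TRUE; scans[[i]] <- idx
  }
  if (!all(keep))
    warning(sum(!keep), " event(s) dropped: averaging window empty or past run end")
  idx_keep <- which(keep)
  X <- sample_matrix(series, scans, idx_keep)
  dropped <- if (any(!keep))
    data.frame(event = which(!keep), reason = "empty_or_out_of_run")
  new_sample_set(X, events$category[idx_keep], events$block[idx_keep],
                 scans[idx_keep], dropped = dropped)
}

#' Extract per-event samples from a self-paced imagery session
#'
#' Events are paced by key presses. For each event the candidate scans are
#' those whose midpoints fall in the delay-corrected inter-key-press
#' interval `[previous keypress + hrf_delay, keypress + hrf_delay)` (the
#' event's own onset bounds the first interval of a path), truncated to the
#' last `max_scans` scans before the delay-corrected key press. A scan
#' assignable to two different events is excluded from both, so no TR mixes
#' two stimuli; events left without scans yield no sample.
#'
#' @inheritParams extract_exploration_samples
#' @param max_scans Maximum number of scans averaged per event (default 2,
#'   i.e. 4.08 s at TR 2.04 s).
#' @return A `sample_set`; dropped events are listed in `$dropped`.
#' @export
extract_imagery_samples <- function(series, events, tr, hrf_delay = 6,
                                    max_scans = 2) {
  if (!all(is.finite(events$keypress_time)))
    stop_invalid("imagery events must carry keypress_time")
  n <- nrow(series)
  mid <- scan_midpoints(n, tr)
  ne <- nrow(events)
  cand <- vector("list", ne)
  for (i in seq_len(ne)) {
    prev_kp <- if (i > 1 && !is.na(events$path[i]) &&
                   identical(events$path[i], events$path[i - 1]))
      events$keypress_time[i - 1] else events$onset[i]
    lo <- prev_kp + hrf_delay
    hi <- events$keypress_time[i] + hrf_delay
    idx <- which(mid >= lo & mid < hi & mid < n * tr)
    if (length(idx) > max_scans)
      idx <- idx[(length(idx) - max_scans + 1):length(idx)]
    cand[[i]] <- idx
  }
  # overlap exclusion: a scan claimed by two different events serves neither
  all_idx <- unlist(cand)
  dup <- unique(all_idx[duplicated(all_idx)])
  if (length(dup))
    cand <- lapply(cand, function(ix) setdiff(ix, dup))
  keep <- lengths(cand) > 0L
  if (!all(keep))
    message(sum(!keep), " imagery event(s) yielded no sample ",
            "(no scan in window after overlap exclusion)")
  idx_keep <- which(keep)
  X <- sample_matrix(series, cand, idx_keep)
  dropped <- if (any(!keep))
    data.frame(event = which(!keep), reason = "no_scan_after_exclusion")
  new_sample_set(X, events$category[idx_keep], events$block[idx_keep],
                 cand[idx_keep], dropped = dropped)
}
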