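# File formats: BIDS-dialect events TSV, NIfTI-1 or plain-matrix series,
# motion regressor text files, and the run configuration defaults.

#' Read an events table (BIDS events dialect)
#'
#' Tab-separated with header columns `onset`, `duration`, `trial_type` at
#' minimum; `block`, `path` and `response_time` are used when present and
#' any extra columns are preserved untouched. Times are seconds.
#'
#' @param path File path.
#' @return An `event_table`.
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_invalid("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("onset", "duration")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop_invalid("non-numeric ", col, " at line ", bad[1] + 1)
    df[[col]] <- v
  }
  bad_cat <- which(!df$trial_type %in% categories())
  if (length(bad_cat))
    stop_invalid("unknown category '", df$trial_type[bad_cat[1]],
                 "' at line ", bad_cat[1] + 1)
  bad_dur <- which(df$duration <= 0)
  if (length(bad_dur))
    stop_invalid("non-positive duration at line ", bad_dur[1] + 1)
  out <- df
  names(out)[names(out) == "trial_type"] <- "category"
  names(out)[names(out) == "response_time"] <- "keypress_time"
  if (is.null(out$block)) out$block <- 1L
  if (is.null(out$path)) out$path <- NA_integer_
  if (is.null(out$keypress_time)) out$keypress_time <- NA_real_
  session <- if (all(is.na(out$keypress_time))) "exploration" else "imagery"
  if (session == "imagery" &&
      any(out$keypress_time < out$onset, na.rm = TRUE))
    stop_invalid("keypress_time before onset at line ",
                 which(out$keypress_time < out$onset)[1] + 1)
  new_event_table(out, session = session)
}

#' Write an events table (BIDS events dialect)
#'
#' @param events An `event_table`.
#' @param path Output path (tab-separated, header
#'   onset/duration/trial_type/block/path/response_time).
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  names(df)[names(df) == "category"] <- "trial_type"
  names(df)[names(df) == "keypress_time"] <- "response_time"
  first <- intersect(c("onset", "duration", "trial_type", "block", "path",
                       "response_time"), names(df))
  df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a voxel time series
#'
#' Either as a NIfTI-1 4-D volume (scans along the 4th dimension, voxels
#' unravelled x-fastest over a small grid, TR stored in the header) or as
#' a plain tab-separated matrix (scans x voxels, TR recorded on a `#tr=`
#' comment line) so the pipeline can run without any imaging dependency.
#'
#' @param series Scans x voxels matrix (or `bold_sim`).
#' @param path Output path; `.nii`/`.nii.gz` selects NIfTI, anything else
#'   the matrix format.
#' @param tr Repetition time in seconds.
#' @param dim3 For NIfTI: 3-D grid to unravel voxels into (defaults to a
#'   thin grid `c(nv, 1, 1)` padded as needed).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, tr, dim3 = NULL) {
  if (inherits(series, "bold_sim")) {
    if (missing(tr)) tr <- series$tr
    series <- series$series
  }
  n <- nrow(series); v <- ncol(series)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (is.null(dim3)) dim3 <- c(v, 1L, 1L)
    if (prod(dim3) < v) stop_invalid("`dim3` too small for ", v, " voxels")
    arr <- array(0, c(dim3, n))
    flat <- matrix(0, prod(dim3), n)
    flat[seq_len(v), ] <- t(series)
    arr[] <- flat
    img <- RNifti::asNifti(arr)
    img <- RNifti::`pixdim<-`(img, c(3, 3, 3, tr))
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "w")
    writeLines(sprintf("#tr=%.10g", tr), con)
    utils::write.table(series, con, sep = "\t", quote = FALSE,
                       row.names = FALSE,
                       col.names = paste0("v", seq_len(v)))
    close(con)
  }
  invisible(path)
}

#' Read a voxel time series
#'
#' Counterpart of [write_series()]. For NIfTI input the TR is taken from
#' the header (4th pixdim); voxels are unravelled x-fastest (0-based
#' within-volume order) and an optional logical/integer `mask` restricts
#' the voxels returned.
#'
#' @param path File path (`.nii`/`.nii.gz` or matrix format).
#' @param mask Optional voxel mask (logical over the 3-D grid, or indices).
#' @return List with `series` (scans x voxels) and `tr`.
#' @export
read_series <- function(path, mask = NULL) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    d <- dim(img)
    if (length(d) != 4) stop_invalid("expected a 4-D NIfTI, got ",
                                     length(d), "-D")
    tr <- RNifti::pixdim(img)[4]
    if (!is.finite(tr) || tr <= 0) stop_invalid("missing TR in NIfTI header")
    series <- t(matrix(img, prod(d[1:3]), d[4]))
  } else {
    first <- readLines(path, n = 1)
    if (!grepl("^#tr=", first)) stop_invalid("missing #tr= header line")
    tr <- as.numeric(sub("^#tr=", "", first))
    series <- as.matrix(utils::read.delim(path, sep = "\t", skip = 1))
  }
  if (!is.null(mask)) {
    idx <- if (is.logical(mask)) which(mask) else as.integer(mask)
    series <- series[, idx, drop = FALSE]
  }
  list(series = unname(series), tr = tr)
}

#' Write / read motion regressors (6-column text file)
#'
#' @param motion Scans x 6 matrix.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_motion <- function(motion, path) {
  utils::write.table(motion, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_motion
#' @export
read_motion <- function(path) {
  as.matrix(utils::read.delim(path, sep = "\t", header = FALSE))
}

#' Serialize a fitted binary classifier to JSON text
#'
#' Writes the reproducibility-relevant parts of a fitted model —
#' hyperparameters plus weights, bias and support indices for the SVM, or
#' kernel scale and EP site parameters for the GP — as a flat JSON
#' object. `read_model()` restores a predict-capable object (the GP
#' additionally needs its training matrix, which is included).
#'
#' @param model A `linear_svm` or `gp_probit`.
#' @param path Output path.
#' @return `path` (write) or the restored model (read), invisibly.
#' @export
write_model <- function(model, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop_invalid("model serialization needs the jsonlite package")
  obj <- if (inherits(model, "linear_svm")) {
    list(type = "linear_svm", C = model$C, w = model$w, b = model$b,
         index = model$index, alpha = model$alpha, sv_y = model$sv_y,
         levels = model$levels)
  } else if (inherits(model, "gp_probit")) {
    list(type = "gp_probit", sigma = model$sigma, kscale = model$kscale,
         centering = model$centering, tau = model$tau, nu = model$nu,
         converged = model$converged, levels = model$levels,
         X = model$X, y = model$y)
  } else stop_invalid("unsupported model class")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop_invalid("model serialization needs the jsonlite package")
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "linear_svm")) {
    obj$type <- NULL
    structure(obj, class = "linear_svm")
  } else if (identical(obj$type, "gp_probit")) {
    obj$type <- NULL
    obj$X <- as.matrix(obj$X)
    K0 <- center_kernel(linear_kernel_inhom(obj$X, obj$X, sigma = 1,
                                            sigma0sq = 0))
    obj$Kc <- (obj$sigma^2 / obj$kscale) * K0
    structure(obj, class = "gp_probit")
  } else stop_invalid("unrecognized model file")
}

#' Default run configuration
#'
#' All defaults reproduce the pipeline's reference settings: TR 2.04 s,
#' hemodynamic delay 6 s, high-pass cutoff 1/128 Hz, SVM C = 1, specific
#' filter size 1000, global F-threshold 0.5, RFA grid 5-150 in steps of
#' 25, 100 permutations per cross-validation step, independent kernel
#' centering.
#'
#' @param ... Named overrides of any default.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(tr = 2.04, hrf_delay = 6, highpass_cutoff = 1 / 128,
              C = 1, topk = 1000, f_threshold = 0.5,
              rfa_n_min = 5, rfa_n_max = 150, rfa_delta = 25,
              n_perm = 100, centering = "independent",
              window = 3, max_scans = 2,
              fixation_range = c(15, 18), n_repetitions = 5,
              n_tests = 54, recall_prob = c(1, 1, 1),
              duration_range = c(0.2, 4), paths_per_block = 6)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_invalid("unknown config field(s): ", paste(bad, collapse = ", "))
  structure(utils::modifyList(cfg, over), class = "run_config")
}
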