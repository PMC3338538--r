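#' Acquisition parameters for a simulated scanning session
#'
#' @param tr Repetition time in seconds per scan (default 2.04).
#' @param n_scans Number of scans (volumes).
#' @param n_voxels Number of voxels.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(tr = 2.04, n_scans = 300, n_voxels = 1000) {
  if (tr <= 0) stop_invalid("`tr` must be positive")
  if (n_scans < 1 || n_voxels < 1)
    stop_invalid("`n_scans` and `n_voxels` must be >= 1")
  structure(list(tr = tr, n_scans = as.integer(n_scans),
                 n_voxels = as.integer(n_voxels)),
            class = "acq_params")
}

new_event_table <- function(df, session) {
  stopifnot(all(c("onset", "duration", "category", "block") %in% names(df)))
  if (is.unsorted(df$onset)) stop_invalid("event onsets must be non-decreasing")
  if (any(df$duration <= 0)) stop_invalid("event durations must be positive")
  df$category <- factor(df$category, levels = categories())
  structure(df, class = c("event_table", "data.frame"), session = session)
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table: %s session, %d events, %d blocks>\n",
              attr(x, "session"), nrow(x), length(unique(x$block))))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more events\n")
  invisible(x)
}

#' Generate a paced maze-exploration event table
#'
#' Emulates a paced session in which a two-dimensional maze of images is
#' traversed: each traversal consists of `n_blocks` blocks of 27 images
#' (9 faces, then 9 buildings, then 9 animals, always in that order), each
#' image shown for `stim_duration` seconds with no gap within a block, and a
#' fixation period drawn uniformly from `fixation_range` between blocks. The
#' whole traversal is repeated `n_repetitions` times, so block identifiers
#' enumerate all `n_blocks * n_repetitions` blocks.
#'
#' @param n_repetitions Number of maze traversals (default 5).
#' @param n_blocks Blocks per traversal (default 3).
#' @param images_per_category Images of each category per block (default 9).
#' @param stim_duration Stimulus presentation time in seconds (default 3).
#' @param fixation_range Inter-block fixation interval bounds in seconds
#'   (default `c(15, 18)`); also used for the initial fixation.
#' @param seed RNG seed; the design is deterministic given the seed.
#' @return An `event_table` with columns onset, duration, category, block.
#' @export
#' @examples
#' ev <- make_exploration_design(seed = 1)
#' table(ev$category)  # 135 events per category
make_exploration_design <- function(n_repetitions = 5, n_blocks = 3,
                                    images_per_category = 9,
                                    stim_duration = 3,
                                    fixation_range = c(15, 18),
                                    seed = NULL) {
  if (n_repetitions < 1) stop_invalid("`n_repetitions` must be >= 1")
  if (n_blocks < 1) stop_invalid("`n_blocks` must be >= 1")
  if (stim_duration <= 0) stop_invalid("`stim_duration` must be positive")
  if (length(fixation_range) != 2 || diff(fixation_range) < 0)
    stop_invalid("`fixation_range` must be an increasing pair of seconds")
  with_seed(seed, {
    per_block <- 3L * images_per_category
    total_blocks <- n_blocks * n_repetitions
    gaps <- stats::runif(total_blocks, fixation_range[1], fixation_range[2])
    onset <- numeric(0); block <- integer(0)
    t <- 0
    for (b in seq_len(total_blocks)) {
      t <- t + gaps[b]
      onset <- c(onset, t + stim_duration * (seq_len(per_block) - 1))
      block <- c(block, rep.int(b, per_block))
      t <- t + stim_duration * per_block
    }
    category <- rep(rep(categories(), each = images_per_category), total_blocks)
    new_event_table(
      data.frame(onset = onset, duration = stim_duration,
                 category = category, block = block,
                 path = NA_integer_, keypress_time = NA_real_),
      session = "exploration")
  })
}

#' Generate a self-paced mental-imagery event table
#'
#' Emulates a session of `n_tests` memory tests. In each test the subject
#' mentally travels a path of 3 to 6 images of a single category (path
#' lengths balanced so the average is 4.5, and categories balanced across
#' paths so the *planned* number of images per category is equal). Each
#' planned image is actually recalled — and hence emitted as an event with a
#' key press at its end — with category-specific probability
#' `recall_prob`; unequal recall probabilities are the mechanism that
#' produces class imbalance. Event durations are drawn uniformly from
#' `duration_range`, successive events are separated by a 0–0.5 s jitter,
#' and paths are grouped into blocks of `paths_per_block` consecutive paths
#' (the cross-validation and permutation unit).
#'
#' @param n_tests Number of mental paths (default 54).
#' @param path_length_range Inclusive bounds on images per path (default 3:6).
#' @param recall_prob Named or positional numeric triple of per-category
#'   recall probabilities in `[0,1]`, order faces/buildings/animals
#'   (default all 1).
#' @param duration_range Event duration bounds in seconds
#'   (default `c(0.2, 4)`, i.e. 200-4000 ms).
#' @param paths_per_block Consecutive paths per cross-validation block
#'   (default 6).
#' @param cue_duration Seconds the start/target cue is displayed before
#'   recall begins (default 4).
#' @param inter_test_gap Seconds between tests (default 6).
#' @param seed RNG seed; deterministic given the seed.
#' @return An `event_table` with columns onset, duration, category, block,
#'   path, keypress_time.
#' @export
make_imagery_design <- function(n_tests = 54, path_length_range = c(3, 6),
                                recall_prob = c(faces = 1, buildings = 1,
                                                animals = 1),
                                duration_range = c(0.2, 4),
                                paths_per_block = 6, cue_duration = 4,
                                inter_test_gap = 6, seed = NULL) {
  if (n_tests < 1) stop_invalid("`n_tests` must be >= 1")
  recall_prob <- rep_len(as.numeric(recall_prob), 3L)
  if (any(recall_prob < 0 | recall_prob > 1))
    stop_invalid("`recall_prob` entries must lie in [0, 1]")
  if (duration_range[1] <= 0 || diff(duration_range) < 0)
    stop_invalid("`duration_range` must be positive and increasing")
  lens_pool <- seq.int(path_length_range[1], path_length_range[2])
  with_seed(seed, {
    # Balanced categories across paths, balanced lengths within category.
    n_cat <- rep(n_tests %/% 3L, 3L)
    extra <- n_tests %% 3L
    if (extra > 0) {
      pick <- sample.int(3L, extra)
      n_cat[pick] <- n_cat[pick] + 1L
    }
    path_cat <- integer(0); path_len <- integer(0)
    for (ci in 1:3) {
      nl <- n_cat[ci] %/% length(lens_pool)
      lens <- rep(lens_pool, nl)
      rem <- n_cat[ci] - length(lens)
      if (rem > 0) lens <- c(lens, sample(lens_pool, rem, replace = TRUE))
      path_cat <- c(path_cat, rep.int(ci, n_cat[ci]))
      path_len <- c(path_len, lens)
    }
    ord <- sample.int(n_tests)
    path_cat <- path_cat[ord]; path_len <- path_len[ord]

    rows <- vector("list", n_tests)
    t <- 0
    for (p in seq_len(n_tests)) {
      t <- t + cue_duration
      ci <- path_cat[p]
      recalled <- stats::runif(path_len[p]) <= recall_prob[ci]
      onsets <- numeric(0); durs <- numeric(0)
      for (img in seq_len(path_len[p])) {
        if (!recalled[img]) next
        on <- t + stats::runif(1, 0, 0.5)
        du <- stats::runif(1, duration_range[1], duration_range[2])
        onsets <- c(onsets, on); durs <- c(durs, du)
        t <- on + du
      }
      if (length(onsets))
        rows[[p]] <- data.frame(
          onset = onsets, duration = durs,
          category = categories()[ci],
          block = as.integer(ceiling(p / paths_per_block)),
          path = p, keypress_time = onsets + durs)
      t <- t + inter_test_gap
    }
    df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    rownames(df) <- NULL
    new_event_table(df, session = "imagery")
  })
}

#' Category-selective voxel activation patterns
#'
#' Builds per-category amplitude maps over `n_voxels` voxels: each category
#' activates exactly `n_informative` voxels at amplitude `effect_size`
#' (baseline-signal units), and each pair of categories shares
#' `round(overlap_fraction * n_informative)` of its informative voxels
#' (a stand-in for partially overlapping category-selective regions).
#'
#' @param n_voxels Total voxel count.
#' @param n_informative Informative voxels per category.
#' @param effect_size Response amplitude at informative voxels.
#' @param overlap_fraction Fraction of each category's informative voxels
#'   shared with each other category, in `[0, 1]`.
#' @param seed RNG seed.
#' @return An `activation_patterns` object: a `n_voxels` x 3 matrix with an
#'   `informative` attribute listing each category's voxel indices.
#' @export
make_activation_patterns <- function(n_voxels, n_informative, effect_size = 1,
                                     overlap_fraction = 0, seed = NULL) {
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop_invalid("`overlap_fraction` must lie in [0, 1]")
  n_shared <- round(overlap_fraction * n_informative)
  if (2 * n_shared > n_informative)
    stop_invalid("`overlap_fraction` too large: shared voxels exceed map size")
  n_unique <- n_informative - 2 * n_shared
  need <- 3 * n_shared + 3 * n_unique
  if (need > n_voxels)
    stop_invalid("infeasible: ", need, " informative voxels needed but only ",
                 n_voxels, " available")
  with_seed(seed, {
    idx <- sample.int(n_voxels, need)
    take <- function(n) {
      if (n == 0L) return(integer(0))
      out <- idx[seq_len(n)]; idx <<- idx[-seq_len(n)]; out
    }
    fb <- take(n_shared); fa <- take(n_shared); ba <- take(n_shared)
    uf <- take(n_unique); ub <- take(n_unique); ua <- take(n_unique)
    sets <- list(faces = c(fb, fa, uf),
                 buildings = c(fb, ba, ub),
                 animals = c(fa, ba, ua))
    maps <- matrix(0, n_voxels, 3, dimnames = list(NULL, categories()))
    for (ci in 1:3) maps[sets[[ci]], ci] <- effect_size
    structure(maps, informative = sets, effect_size = effect_size,
              class = c("activation_patterns", "matrix", "array"))
  })
}

#' Simulate a BOLD voxel time series from an event table
#'
#' Forward model mirroring the analysis GLM: each category's event boxcar is
#' convolved with the canonical double-gamma HRF and scaled by that
#' category's voxel amplitude map; low-frequency drift, motion-correlated
#' nuisance signal, and AR(1) Gaussian noise are added on top of a constant
#' baseline. The six motion series are returned alongside, playing the role
#' of realignment parameters.
#'
#' @param events An `event_table`.
#' @param patterns An `activation_patterns` matrix (voxels x 3).
#' @param params An `acq_params` object; events must fit in
#'   `n_scans * tr` seconds.
#' @param noise List with elements `white_sd` (marginal noise sd),
#'   `ar1_coef` (temporal autocorrelation, default 0.3), `drift_amp`
#'   (low-frequency drift scale) and `motion_amp` (motion-leakage scale).
#' @param baseline Constant baseline signal (default 100).
#' @param seed RNG seed; deterministic given the seed.
#' @return A `bold_sim` object: list with `series` (scans x voxels matrix,
#'   signal sampled at scan acquisition midpoints), `motion` (scans x 6),
#'   `times` (scan midpoints, seconds) and `components` (evoked, drift,
#'   motion_effect, noise — the series equals baseline plus their sum).
#' @export
simulate_bold <- function(events, patterns, params,
                          noise = list(white_sd = 1, ar1_coef = 0.3,
                                       drift_amp = 1, motion_amp = 0.5),
                          baseline = 100, seed = NULL) {
  stopifnot(inherits(params, "acq_params"))
  n <- params$n_scans; v <- nrow(patterns); tr <- params$tr
  if (max(events$onset + events$duration) > n * tr)
    stop_invalid("events extend past the scan window (",
                 round(max(events$onset + events$duration), 2), " s > ",
                 round(n * tr, 2), " s)")
  noise <- utils::modifyList(
    list(white_sd = 1, ar1_coef = 0.3, drift_amp = 1, motion_amp = 0.5),
    as.list(noise))
  times <- (seq_len(n) - 0.5) * tr
  with_seed(seed, {
    evoked <- matrix(0, n, v)
    for (ci in 1:3) {
      sel <- events$category == categories()[ci]
      if (!any(sel)) next
      g <- convolve_events(events$onset[sel], events$duration[sel], times)
      evoked <- evoked + outer(g, patterns[, ci])
    }
    # slow drift: first three cosine harmonics with random voxel loadings
    dct <- sapply(1:3, function(k) cos(pi * k * (2 * seq_len(n) - 1) / (2 * n)))
    drift <- dct %*% matrix(stats::rnorm(3 * v), 3, v) * noise$drift_amp
    # motion: six smooth random-walk-like series plus leakage into voxels
    motion <- apply(matrix(stats::rnorm(n * 6, sd = 0.05), n, 6), 2,
                    function(e) as.numeric(stats::filter(e, 0.95,
                                                         method = "recursive")))
    motion_effect <- motion %*% matrix(stats::rnorm(6 * v), 6, v) *
      noise$motion_amp
    eps <- if (noise$white_sd > 0) {
      innov_sd <- noise$white_sd * sqrt(1 - noise$ar1_coef^2)
      e <- matrix(stats::rnorm(n * v, sd = innov_sd), n, v)
      if (noise$ar1_coef != 0)
        apply(e, 2, function(x) as.numeric(stats::filter(x, noise$ar1_coef,
                                                         method = "recursive")))
      else e
    } else matrix(0, n, v)
    series <- baseline + evoked + drift + motion_effect + eps
    structure(list(series = series, motion = motion, times = times,
                   tr = tr, baseline = baseline,
                   components = list(evoked = evoked, drift = drift,
                                     motion_effect = motion_effect,
                                     noise = eps)),
              class = "bold_sim")
  })
}

#' @export
print.bold_sim <- function(x, ...) {
  cat(sprintf("<bold_sim: %d scans x %d voxels, TR %.3f s>\n",
              nrow(x$series), ncol(x$series), x$tr))
  invisible(x)
}
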