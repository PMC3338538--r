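# Two-level feature selection: univariate GLM filters and the multivariate
# recursive-feature-addition wrapper driven by SVM weights.

fmap_from_design <- function(Y, X_full, X_red) {
  qf <- qr(X_full); qr_ <- qr(X_red)
  if (qf$rank < ncol(X_full)) {
    cn <- colnames(X_full)
    bad <- if (is.null(cn)) "(unnamed)" else
      paste(cn[-seq_len(qf$rank)], collapse = ", ")
    stop_invalid("singular design matrix; collinear columns: ", bad)
  }
  rss1 <- colSums(qr.resid(qf, Y)^2)
  rss0 <- colSums(qr.resid(qr_, Y)^2)
  p <- qf$rank - qr_$rank
  df2 <- nrow(Y) - qf$rank
  f <- pmax(0, (rss0 - rss1) / p) / (rss1 / df2)
  structure(as.numeric(f), df = c(p, df2), class = "fmap")
}

#' Per-voxel omnibus F map for condition effects
#'
#' Tests, for each voxel, the three category effects jointly against a
#' confound-only model. Two routes are supported: a time-series GLM (the
#' voxel series regressed on HRF-convolved category regressors plus
#' confounds) and a sample-level one-way layout (each sample-set row
#' regressed on class indicators), the latter being what the per-fold
#' filter in [run_procedure()] uses so that selection sees training folds
#' only.
#'
#' @param x A scans x voxels matrix, `bold_sim`, or `sample_set`.
#' @param ... Passed to methods.
#' @return An `fmap`: numeric vector of F statistics with a `df` attribute.
#' @export
glm_fmap <- function(x, ...) UseMethod("glm_fmap")

#' @rdname glm_fmap
#' @param events An `event_table` (matrix route).
#' @param tr Repetition time, seconds (matrix route).
#' @param motion Optional motion regressors (matrix route).
#' @param cutoff High-pass cutoff in Hz (matrix route).
#' @export
glm_fmap.matrix <- function(x, events, tr, motion = NULL, cutoff = 1 / 128,
                            ...) {
  n <- nrow(x)
  mid <- scan_midpoints(n, tr)
  cond <- sapply(categories(), function(cc) {
    sel <- events$category == cc
    convolve_events(events$onset[sel], events$duration[sel], mid)
  })
  conf <- cbind(intercept = 1,
                if (!is.null(motion)) as.matrix(motion),
                dct_basis(n, tr, cutoff))
  fmap_from_design(x, cbind(cond, conf), conf)
}

#' @rdname glm_fmap
#' @export
glm_fmap.bold_sim <- function(x, events, cutoff = 1 / 128, ...) {
  glm_fmap.matrix(x$series, events = events, tr = x$tr, motion = x$motion,
                  cutoff = cutoff)
}

#' @rdname glm_fmap
#' @export
glm_fmap.sample_set <- function(x, ...) {
  ind <- stats::model.matrix(~ 0 + x$labels)
  colnames(ind) <- levels(x$labels)
  fmap_from_design(x$X, ind, matrix(1, nrow(x$X), 1))
}

#' Global GLM filter: all voxels above an F threshold
#'
#' @param fmap An `fmap` (or numeric vector of F values).
#' @param f_threshold Threshold; selection is strict (`F > f_threshold`).
#'   Default 0.5.
#' @return Integer vector of selected voxel indices.
#' @export
select_global <- function(fmap, f_threshold = 0.5) {
  which(as.numeric(fmap) > f_threshold)
}

#' Specific GLM filter: the k most significant voxels
#'
#' @param fmap An `fmap` (or numeric vector of F values).
#' @param k Number of voxels to keep (default 1000). If `k` exceeds the
#'   voxel count all voxels are returned with a warning. Boundary ties are
#'   broken by lowest voxel index.
#' @return Integer vector of selected voxel indices (decreasing F order).
#' @export
select_topk <- function(fmap, k = 1000) {
  f <- as.numeric(fmap)
  if (k >= length(f)) {
    if (k > length(f))
      warning("k exceeds voxel count; returning all voxels")
    return(order(-f, seq_along(f)))
  }
  order(-f, seq_along(f))[seq_len(k)]
}

#' Rank voxels by linear-SVM weight magnitude for one binary comparison
#'
#' Trains the linear SVM (C fixed) on the samples of the two named
#' categories and ranks voxels by decreasing absolute weight — the voxel's
#' discriminating power. The sign of the weight assigns each voxel to the
#' condition it points towards (positive: first-named category). Ties are
#' broken by lowest voxel index.
#'
#' @param samples A `sample_set` (may contain other classes; they are
#'   dropped).
#' @param pair Character pair of category names, e.g.
#'   `c("faces", "buildings")`.
#' @param C SVM regularization constant (default 1).
#' @return A `feature_ranking`: list with `order` (all voxels by decreasing
#'   `|w|`), `weights`, and per-condition lists `pos` / `neg`.
#' @export
rank_by_svm_weights <- function(samples, pair, C = 1) {
  keep <- samples$labels %in% pair
  y <- factor(as.character(samples$labels[keep]), levels = pair)
  if (nlevels(droplevels(y)) < 2)
    stop_invalid("both classes of the pair must be present")
  fit <- train_linear_svm(samples$X[keep, , drop = FALSE], y, C = C)
  w <- fit$w
  ord <- order(-abs(w), seq_along(w))
  structure(list(order = ord, weights = w, pair = pair,
                 pos = ord[w[ord] > 0], neg = ord[w[ord] < 0]),
            class = "feature_ranking")
}

#' The recursive-feature-addition grid
#'
#' Candidate numbers of voxels per condition and binary comparison: from
#' `n_min` in steps of `delta`, capped at `n_max` (defaults 5, 25, 150,
#' giving 5, 30, 55, 80, 105, 130, 150).
#'
#' @param n_min,n_max,delta Grid bounds and step.
#' @return Integer vector.
#' @export
rfa_grid <- function(n_min = 5, n_max = 150, delta = 25) {
  g <- seq(n_min, n_max, by = delta)
  if (g[length(g)] < n_max) g <- c(g, n_max)
  as.integer(g)
}

#' RFA stopping decision over a global-accuracy trace
#'
#' The wrapper stops once the current global accuracy falls strictly below
#' both of the two preceding iterations' values; the selected iteration is
#' the argmax over everything evaluated (first maximum on ties).
#'
#' @param acc Numeric vector of global accuracies in evaluation order.
#' @return List with `stop` (`TRUE` if the rule fires at the last entry)
#'   and `selected` (index of the best iteration so far).
#' @export
rfa_stopping <- function(acc) {
  k <- length(acc)
  stop_now <- k >= 3 && acc[k] < acc[k - 1] && acc[k] < acc[k - 2]
  list(stop = stop_now, selected = which.max(acc))
}

#' Recursive Feature Addition by SVM weight rank
#'
#' Forward wrapper selection with an inner leave-one-block-out
#' cross-validation. For each candidate size `n` in `grid`, each of the
#' three binary comparisons contributes its top `n` positive-weight and top
#' `n` negative-weight voxels (ranked on the inner-training blocks); an SVM
#' on those voxels is scored on the left-out block, and the *global
#' accuracy* is the sum of the three binary accuracies (range 0-3),
#' averaged over inner folds. Iteration stops when the global accuracy
#' drops below both of the two previous iterations (see [rfa_stopping()]).
#' The returned voxel set is the union, over comparisons and conditions, of
#' the top-`n*` voxels ranked on *all* provided blocks, where `n*` is the
#' best iteration's size.
#'
#' @param samples A `sample_set` (the training data of an outer fold).
#' @param blocks Block id per sample (default `samples$block`); at least 3
#'   distinct blocks are required.
#' @param grid Candidate per-condition sizes, see [rfa_grid()].
#' @param C SVM regularization constant.
#' @return List with `voxels` (selected indices) and `trace` (an
#'   `rfa_trace` data frame: iteration, n, set_size, global_accuracy, with
#'   attributes `selected` and `stopped_at`).
#' @export
rfa_select <- function(samples, blocks = samples$block, grid = rfa_grid(),
                       C = 1) {
  ub <- unique(blocks)
  if (length(ub) < 2)
    stop_invalid("RFA needs >= 2 training blocks for the inner ",
                 "cross-validation; use a filter-only procedure")
  pairs <- category_pairs()
  # one ranking per (inner fold, comparison), reused across grid values
  fold_rank <- lapply(ub, function(b) {
    tr_idx <- which(blocks != b)
    tr_set <- subset_samples(samples, tr_idx)
    lapply(pairs, function(p) rank_by_svm_weights(tr_set, p, C = C))
  })
  full_rank <- lapply(pairs, function(p) rank_by_svm_weights(samples, p, C = C))

  top_set <- function(rk, n) c(utils::head(rk$pos, n), utils::head(rk$neg, n))
  acc <- numeric(0); set_sizes <- integer(0)
  for (gi in seq_along(grid)) {
    n <- grid[gi]
    fold_acc <- vapply(seq_along(ub), function(fi) {
      b <- ub[fi]
      tr_idx <- which(blocks != b); te_idx <- which(blocks == b)
      tr_set <- subset_samples(samples, tr_idx)
      s <- 0
      for (pi in seq_along(pairs)) {
        p <- pairs[[pi]]
        vox <- top_set(fold_rank[[fi]][[pi]], n)
        keep_tr <- tr_set$labels %in% p
        keep_te <- te_idx[samples$labels[te_idx] %in% p]
        if (length(keep_te) == 0L) next
        y_tr <- factor(as.character(tr_set$labels[keep_tr]), levels = p)
        fit <- train_linear_svm(tr_set$X[keep_tr, vox, drop = FALSE], y_tr,
                                C = C)
        pred <- predict(fit, samples$X[keep_te, vox, drop = FALSE])
        truth <- ifelse(samples$labels[keep_te] == p[1], 1, -1)
        s <- s + mean(pred == truth)
      }
      s
    }, numeric(1))
    acc[gi] <- mean(fold_acc)
    set_sizes[gi] <- length(unique(unlist(
      lapply(full_rank, top_set, n = n))))
    dec <- rfa_stopping(acc)
    if (dec$stop) break
  }
  evaluated <- length(acc)
  sel <- which.max(acc)
  voxels <- sort(unique(unlist(lapply(full_rank, top_set, n = grid[sel]))))
  trace <- data.frame(iteration = seq_len(evaluated),
                      n = grid[seq_len(evaluated)],
                      set_size = set_sizes,
                      global_accuracy = acc)
  attr(trace, "selected") <- sel
  attr(trace, "stopped_at") <- evaluated
  class(trace) <- c("rfa_trace", "data.frame")
  list(voxels = voxels, trace = trace)
}

#' @export
print.rfa_trace <- function(x, ...) {
  cat(sprintf("<rfa_trace: %d iterations, selected n = %d>\n",
              nrow(x), x$n[attr(x, "selected")]))
  print.data.frame(x, ...)
  invisible(x)
}
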