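# Orchestration: the five decoding procedures under leave-one-block-out
# (and, for RFA, double) cross-validation, balanced accuracy, and the
# within-block permutation test.

#' The five decoding procedure configurations
#'
#' | id | filter            | wrapper | classifier |
#' |----|-------------------|---------|------------|
#' | 1  | specific (top-k)  | none    | SVM        |
#' | 2  | specific (top-k)  | none    | GP         |
#' | 3  | global (F > 0.5)  | RFA     | GP         |
#' | 4  | specific (top-k)  | RFA     | GP         |
#' | 5  | specific (top-k)  | RFA     | SVM        |
#'
#' @param id Procedure number 1-5.
#' @return List with `id`, `filter`, `wrapper`, `classifier`.
#' @export
procedure_config <- function(id) {
  if (!id %in% 1:5) stop_invalid("procedure id must be in 1..5")
  cfg <- list(
    list(filter = "specific", wrapper = "none", classifier = "svm"),
    list(filter = "specific", wrapper = "none", classifier = "gp"),
    list(filter = "global", wrapper = "rfa", classifier = "gp"),
    list(filter = "specific", wrapper = "rfa", classifier = "gp"),
    list(filter = "specific", wrapper = "rfa", classifier = "svm"))[[id]]
  cfg$id <- as.integer(id)
  cfg
}

#' Cross-validation fold definition from an event table
#'
#' One fold per block: for an exploration session each maze block of each
#' repetition is a fold; for an imagery session each group of 6 consecutive
#' paths forms a block (already encoded in the event table's `block`
#' column). A final smaller group triggers a warning; a single block is an
#' error since no cross-validation is possible.
#'
#' @param events An `event_table`.
#' @return Integer vector of fold ids, one per event, with the distinct
#'   fold ids as attribute `folds`.
#' @export
make_blocks <- function(events) {
  b <- events$block
  ub <- sort(unique(b))
  if (length(ub) < 2)
    stop_invalid("cannot cross-validate: only one block present")
  sizes <- table(b)
  if (attr(events, "session") == "imagery") {
    pp <- table(events$block[!duplicated(events$path)])
    if (length(unique(pp)) > 1 && pp[length(pp)] < max(pp))
      warning("final block has fewer paths than the others (",
              pp[length(pp)], " vs ", max(pp), ")")
  }
  structure(as.integer(b), folds = as.integer(ub))
}

#' Balanced accuracy from a confusion matrix
#'
#' The unweighted mean of per-class accuracies
#' (diagonal / row sum), robust to class imbalance. Classes absent from
#' the test set (empty rows) are excluded with a warning.
#'
#' @param confusion Square confusion matrix, rows = true class,
#'   columns = predicted class.
#' @return Value in `[0, 1]`.
#' @export
balanced_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  rs <- rowSums(confusion)
  if (all(rs == 0)) stop_invalid("confusion matrix has no observations")
  if (any(rs == 0))
    warning("class(es) with no test observations excluded: ",
            paste(rownames(confusion)[rs == 0], collapse = ", "))
  keep <- rs > 0
  mean(diag(confusion)[keep] / rs[keep])
}

# Train the three binary classifiers on (possibly permuted) training
# labels, classify the test rows, return predicted classes.
classify_fold <- function(X_tr, y_tr, X_te, classifier, C = 1,
                          centering = "independent", gp_optimize = FALSE) {
  pairs <- category_pairs()
  scheme <- if (classifier == "svm") "prediction" else "probability"
  tab <- codeword_table(scheme)
  votes <- matrix(NA_real_, nrow(X_te), 3)
  sv_prop <- vector("list", 3)
  for (pi in seq_along(pairs)) {
    p <- pairs[[pi]]
    keep <- y_tr %in% p
    yb <- factor(as.character(y_tr[keep]), levels = p)
    if (classifier == "svm") {
      fit <- train_linear_svm(X_tr[keep, , drop = FALSE], yb, C = C)
      votes[, pi] <- predict(fit, X_te)
      sv_prop[[pi]] <- sv_class_proportions(fit)
    } else {
      fit <- gp_ep_train(X_tr[keep, , drop = FALSE], yb,
                         centering = centering,
                         optimize_sigma = gp_optimize)
      votes[, pi] <- gp_predict_prob(fit, X_te)
    }
  }
  pred <- character(nrow(X_te)); tie <- logical(nrow(X_te))
  for (i in seq_len(nrow(X_te))) {
    a <- assign_class(votes[i, ], tab)
    pred[i] <- a$class; tie[i] <- a$tie
  }
  list(pred = factor(pred, levels = categories()), votes = votes,
       tie = tie, sv_prop = sv_prop)
}

run_procedure_core <- function(samples, config, folds, train_labels,
                               topk = 1000, f_threshold = 0.5,
                               grid = rfa_grid(), C = 1,
                               centering = "independent",
                               gp_optimize = FALSE) {
  ub <- sort(unique(folds))
  cats <- categories()
  confusion <- matrix(0L, 3, 3, dimnames = list(true = cats, pred = cats))
  fold_rows <- list(); traces <- list(); n_features <- integer(0)
  skipped <- integer(0); sv_props <- list()
  for (b in ub) {
    tr_idx <- which(folds != b); te_idx <- which(folds == b)
    y_tr <- train_labels[tr_idx]
    if (length(unique(y_tr[!is.na(y_tr)])) < 3 ||
        any(table(factor(y_tr, levels = cats)) == 0)) {
      warning("fold ", b, " skipped: a class is missing from training data")
      skipped <- c(skipped, b)
      next
    }
    tr_set <- new_sample_set(samples$X[tr_idx, , drop = FALSE], y_tr,
                             samples$block[tr_idx], samples$scans[tr_idx])
    fm <- glm_fmap(tr_set)
    vox <- if (config$filter == "specific") select_topk(fm, k = topk)
           else select_global(fm, f_threshold = f_threshold)
    trace <- NULL
    if (config$wrapper == "rfa") {
      sub <- new_sample_set(tr_set$X[, vox, drop = FALSE], tr_set$labels,
                            tr_set$block, tr_set$scans)
      rfa <- rfa_select(sub, grid = grid, C = C)
      vox <- vox[rfa$voxels]
      trace <- rfa$trace
    }
    cf <- classify_fold(tr_set$X[, vox, drop = FALSE], tr_set$labels,
                        samples$X[te_idx, vox, drop = FALSE],
                        config$classifier, C = C, centering = centering,
                        gp_optimize = gp_optimize)
    truth <- factor(samples$labels[te_idx], levels = cats)
    confusion <- confusion + unclass(table(truth, cf$pred))
    cls_acc <- diag(table(truth, cf$pred)) /
      pmax(table(truth), 1)
    fold_rows[[as.character(b)]] <- data.frame(
      fold = b, t(as.numeric(cls_acc)),
      balanced_accuracy = mean(as.numeric(cls_acc)[table(truth) > 0]),
      n_features = length(vox))
    n_features <- c(n_features, length(vox))
    traces[[as.character(b)]] <- trace
    sv_props[[as.character(b)]] <- cf$sv_prop
  }
  if (length(fold_rows) == 0) stop_invalid("all folds were skipped")
  per_fold <- do.call(rbind, fold_rows)
  names(per_fold)[2:4] <- cats
  rownames(per_fold) <- NULL
  list(confusion = confusion, per_fold = per_fold, traces = traces,
       n_features = n_features, skipped = skipped, sv_props = sv_props)
}

#' Run one decoding procedure under leave-one-block-out cross-validation
#'
#' Per outer fold: the GLM filter (and, for procedures 3-5, the RFA
#' wrapper with its inner leave-one-block-out loop) is fitted on the
#' training folds only; the three binary classifiers are trained on the
#' selected voxels; the held-out block is classified through the ECOC
#' codewords; confusions are accumulated. The fold sequence is the sorted
#' block order, identical across procedures, so procedures can be compared
#' on the same folds.
#'
#' @param samples A `sample_set`.
#' @param procedure Procedure id 1-5 or a [procedure_config()] list.
#' @param folds Fold id per sample (default `samples$block`).
#' @param seed RNG seed (ECOC tie-breaks are the only random element).
#' @param topk Specific-filter size (default 1000).
#' @param f_threshold Global-filter threshold (default 0.5).
#' @param grid RFA grid, see [rfa_grid()].
#' @param C SVM regularization constant (default 1).
#' @param centering GP kernel centering mode.
#' @param gp_optimize Refine the GP kernel scale by marginal likelihood?
#' @return A `procedure_result`: confusion matrix, per-fold class and
#'   balanced accuracies, per-class accuracies, balanced accuracy,
#'   selected-feature counts, RFA traces and (for SVM procedures)
#'   support-vector proportions.
#' @export
run_procedure <- function(samples, procedure, folds = samples$block,
                          seed = NULL, topk = 1000, f_threshold = 0.5,
                          grid = rfa_grid(), C = 1,
                          centering = "independent", gp_optimize = FALSE) {
  config <- if (is.numeric(procedure)) procedure_config(procedure)
            else procedure
  min_folds <- if (config$wrapper == "rfa") 3 else 2
  if (length(unique(folds)) < min_folds)
    stop_invalid("need >= ", min_folds, " blocks for procedure ", config$id)
  res <- with_seed(seed, run_procedure_core(
    samples, config, folds, train_labels = samples$labels, topk = topk,
    f_threshold = f_threshold, grid = grid, C = C, centering = centering,
    gp_optimize = gp_optimize))
  cls_acc <- diag(res$confusion) / pmax(rowSums(res$confusion), 1)
  structure(list(config = config, confusion = res$confusion,
                 class_accuracy = cls_acc,
                 balanced_accuracy = balanced_accuracy(res$confusion),
                 per_fold = res$per_fold, n_features = res$n_features,
                 traces = res$traces, sv_props = res$sv_props,
                 skipped = res$skipped, seed = seed,
                 n_folds = length(unique(folds))),
            class = "procedure_result")
}

#' @export
print.procedure_result <- function(x, ...) {
  cat(sprintf("<procedure_result: procedure %d (%s filter%s, %s)>\n",
              x$config$id, x$config$filter,
              if (x$config$wrapper == "rfa") " + RFA" else "",
              toupper(x$config$classifier)))
  cat(sprintf("balanced accuracy: %.4f over %d folds\n",
              x$balanced_accuracy, x$n_folds))
  print(round(x$class_accuracy, 4))
  invisible(x)
}

#' @export
summary.procedure_result <- function(object, ...) {
  cat("Confusion (true x predicted):\n")
  print(object$confusion)
  cat("\nPer-fold results:\n")
  print(object$per_fold, digits = 3)
  if (length(object$n_features))
    cat(sprintf("\nfeatures per fold: mean %.1f (sd %.1f)\n",
                mean(object$n_features), stats::sd(object$n_features)))
  invisible(object)
}

#' Within-block permutation test for a decoding procedure
#'
#' For each permutation replicate, training labels are permuted within
#' each block (preserving per-block class frequencies, hence respecting
#' the temporal correlation structure); the full procedure — including
#' feature selection — is rerun on each outer fold with the permuted
#' training labels, while test labels stay untouched, and a null balanced
#' accuracy is assembled from the fold-wise confusions. The p-value uses
#' the finite-sample +1 correction:
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' In `"paired"` mode (default) the r-th permutation of every fold is
#' assembled into one subject-level null value, giving `n_perm` nulls; in
#' `"pooled"` mode every fold-level balanced accuracy enters the null,
#' giving `n_perm * n_folds` values.
#'
#' @inheritParams run_procedure
#' @param n_perm Number of permutation replicates per fold (default 100).
#' @param observed A fitted `procedure_result` for the same data and
#'   configuration (computed if missing).
#' @param mode `"paired"` or `"pooled"` null aggregation.
#' @param ... Passed on to [run_procedure()] / the core runner.
#' @return A `permutation_test` object: observed value, null values,
#'   p-value, and the total shuffle count `n_perm * n_folds`.
#' @export
permutation_test <- function(samples, procedure, folds = samples$block,
                             n_perm = 100, seed = NULL, observed = NULL,
                             mode = c("paired", "pooled"), ...) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop_invalid("`n_perm` must be >= 1")
  config <- if (is.numeric(procedure)) procedure_config(procedure)
            else procedure
  if (is.null(observed))
    observed <- run_procedure(samples, config, folds = folds, seed = seed,
                              ...)
  obs <- observed$balanced_accuracy
  null_vals <- with_seed(seed, {
    unlist(lapply(seq_len(n_perm), function(r) {
      perm <- permute_within_blocks(samples$labels, samples$block)
      res <- run_procedure_core(samples, config, folds,
                                train_labels = perm, ...)
      if (mode == "paired") balanced_accuracy(res$confusion)
      else res$per_fold$balanced_accuracy
    }))
  })
  p <- (1 + sum(null_vals >= obs)) / (1 + length(null_vals))
  structure(list(observed = obs, null = null_vals, p = p, n_perm = n_perm,
                 n_total_shuffles = n_perm * length(unique(folds)),
                 mode = mode, config = config, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf(paste0("<permutation_test: procedure %d, observed %.4f, ",
                     "p = %.4g (%d replicates, %d total shuffles, %s)>\n"),
              x$config$id, x$observed, x$p, length(x$null),
              x$n_total_shuffles, x$mode))
  invisible(x)
}

#' Permute labels within blocks
#'
#' @param labels Factor or vector of labels.
#' @param blocks Block id per label.
#' @return Labels permuted independently within each block (per-block
#'   class counts preserved exactly).
#' @export
permute_within_blocks <- function(labels, blocks) {
  out <- labels
  for (b in unique(blocks)) {
    idx <- which(blocks == b)
    out[idx] <- labels[idx][sample.int(length(idx))]
  }
  out
}
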