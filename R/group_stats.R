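# Rank-based group-level statistics for comparing procedures across
# subjects and relating accuracies to behavioral measures.

#' Friedman test on a subjects x conditions table
#'
#' Within-subject mid-ranks, chi-square approximation with the standard
#' tie correction. With no ties this equals `stats::friedman.test`.
#'
#' @param table Numeric matrix, rows = subjects, columns = conditions
#'   (>= 3 subjects, >= 2 conditions, no missing cells).
#' @return List with `statistic`, `df`, `p.value`.
#' @export
friedman_test <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  if (n < 3 || k < 2) stop_invalid("need >= 3 subjects and >= 2 conditions")
  if (anyNA(table)) stop_invalid("Friedman input must have no missing cells")
  R <- t(apply(table, 1, rank))
  if (all(apply(R, 1, function(r) length(unique(r)) == 1)))
    stop_invalid("degenerate input: every row is constant")
  Rj <- colSums(R)
  # tie correction: C = 1 - sum(t^3 - t) / (n k (k^2 - 1))
  tie_sum <- sum(apply(table, 1, function(row) {
    t_ <- table(row); sum(t_^3 - t_)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  stat <- (12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)) / C
  df <- k - 1
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Paired Wilcoxon signed-rank test with Bonferroni adjustment
#'
#' Signed-rank statistic on the paired differences; zero differences are
#' dropped (Wilcoxon's original policy). The p-value is exact for up to 25
#' non-zero pairs without ties, otherwise a normal approximation is used.
#' The adjusted p multiplies by the comparison family size, capped at 1.
#'
#' @param x,y Paired numeric vectors.
#' @param family Number of comparisons in the Bonferroni family
#'   (default 1).
#' @return List with `statistic` (V), `p.value` (raw), `p.adjusted`.
#' @export
wilcoxon_paired <- function(x, y, family = 1) {
  d <- x - y
  if (all(d == 0)) stop_invalid("degenerate: all paired differences are zero")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE,
                       exact = sum(d != 0) <= 25, correct = FALSE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       p.adjusted = min(1, wt$p.value * family))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks; p-value from the t approximation.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List with `rho` and `p.value`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4)
    stop_invalid("need equal-length vectors of length >= 4")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop_invalid("correlation undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value)
}

#' Support-vector proportion vs class accuracy associations
#'
#' Spearman correlation of each per-comparison support-vector proportion
#' column against each class-accuracy column across subjects, with the
#' correlation signs tabulated for consistency inspection (e.g. a high
#' proportion of majority-class support vectors is expected to go with a
#' lower minority-class accuracy).
#'
#' @param sv_proportions Subjects x measures matrix of SV proportions
#'   (e.g. faces SV fraction in F-B, faces SV in F-A, animals SV in B-A).
#' @param class_accuracies Subjects x classes matrix of class accuracies.
#' @return Data frame with one row per (SV measure, class) pair: rho,
#'   p.value and sign.
#' @export
sv_accuracy_association <- function(sv_proportions, class_accuracies) {
  sv_proportions <- as.matrix(sv_proportions)
  class_accuracies <- as.matrix(class_accuracies)
  if (nrow(sv_proportions) != nrow(class_accuracies))
    stop_invalid("subject counts differ between the two tables")
  svn <- colnames(sv_proportions)
  if (is.null(svn)) svn <- paste0("sv", seq_len(ncol(sv_proportions)))
  can <- colnames(class_accuracies)
  if (is.null(can)) can <- paste0("class", seq_len(ncol(class_accuracies)))
  rows <- list()
  for (i in seq_along(svn)) for (j in seq_along(can)) {
    sc <- spearman_corr(sv_proportions[, i], class_accuracies[, j])
    rows[[length(rows) + 1]] <- data.frame(
      sv_measure = svn[i], class = can[j], rho = sc$rho,
      p.value = sc$p.value, sign = sign(sc$rho))
  }
  do.call(rbind, rows)
}
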