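#' Train a soft-margin linear SVM (fixed C)
#'
#' Two-class linear support vector machine with regularization constant
#' `C = 1` by default, fitted with LIBSVM (via e1071) without feature
#' scaling and without class weights. The returned object exposes the
#' primal weight vector, bias, support-vector indices and dual
#' coefficients, so weight-based feature ranking and support-vector
#' proportion analyses can be carried out.
#'
#' @param X Samples x features matrix.
#' @param y Labels: a two-level factor (first level is the positive class)
#'   or a numeric vector in `{-1, +1}`.
#' @param C Regularization constant (default 1).
#' @return A `linear_svm` object: list with `w`, `b`, `C`, `index`
#'   (support-vector sample indices), `alpha` (dual coefficients in
#'   `(0, C]`), `sv_y` (support-vector labels, +/-1), `levels`, and
#'   `objective` (dual objective value).
#' @export
train_linear_svm <- function(X, y, C = 1) {
  X <- as.matrix(X)
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop_invalid("numeric labels must be -1/+1")
    lev <- c("+1", "-1")
    yf <- factor(ifelse(y > 0, "+1", "-1"), levels = lev)
  } else {
    yf <- droplevels(as.factor(y)); lev <- levels(yf)
  }
  if (length(unique(as.character(yf))) != 2)
    stop_invalid("exactly two classes required")
  fit <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE,
                    type = "C-classification")
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the decision function so f > 0 <=> first level
  f <- drop(X %*% w) + b
  pred <- predict(fit, X)
  agree <- mean((f > 0) == (pred == lev[1]))
  if (agree < 0.5) { w <- -w; b <- -b }
  ypm <- ifelse(yf == lev[1], 1, -1)
  alpha <- abs(drop(fit$coefs))
  structure(list(w = w, b = b, C = C, index = fit$index, alpha = alpha,
                 sv_y = ypm[fit$index], levels = lev, n = nrow(X),
                 objective = sum(alpha) - 0.5 * sum(w^2)),
            class = "linear_svm")
}

#' Predict with a linear SVM
#'
#' @param object A `linear_svm`.
#' @param newdata Samples x features matrix.
#' @param type `"class"` for +/-1 votes (a decision value of exactly zero
#'   maps to +1 by convention) or `"decision"` for raw decision values
#'   `w.x + b`.
#' @param ... Unused.
#' @return Numeric vector of votes or decision values; +1 denotes the
#'   first level of the training labels.
#' @export
predict.linear_svm <- function(object, newdata, type = c("class", "decision"),
                               ...) {
  type <- match.arg(type)
  f <- drop(as.matrix(newdata) %*% object$w) + object$b
  if (type == "decision") return(f)
  ifelse(f >= 0, 1, -1)
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm: %d features, C = %g, %d SVs (%s vs %s)>\n",
              length(x$w), x$C, length(x$index), x$levels[1], x$levels[2]))
  invisible(x)
}

#' Per-class support-vector proportions
#'
#' Fraction of a fitted SVM's support vectors belonging to each class; the
#' two fractions sum to one. Markedly asymmetric proportions diagnose the
#' effect of class imbalance on the sparse SVM solution.
#'
#' @param model A `linear_svm`.
#' @return Named numeric vector (positive class first).
#' @export
sv_class_proportions <- function(model) {
  stopifnot(inherits(model, "linear_svm"))
  n_sv <- length(model$index)
  out <- c(sum(model$sv_y == 1), sum(model$sv_y == -1)) / n_sv
  names(out) <- model$levels
  out
}
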