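# Error-correcting output codes for the three-class problem: each class
# carries a codeword over the three binary comparisons (F-B, F-A, B-A) and
# a test point is assigned to the nearest codeword.

#' Codeword table for the three-class ECOC scheme
#'
#' Rows are classes (faces, buildings, animals), columns the three binary
#' comparisons in fixed order F-B, F-A, B-A. Under the `"prediction"`
#' scheme entries are the +1/-1 votes a binary SVM should emit for the
#' class (0 where the class is not part of the comparison). Under the
#' `"probability"` scheme entries are the target probabilities of the
#' comparison's first-named class (0.5 where the class does not take
#' part).
#'
#' @param scheme `"prediction"` or `"probability"`.
#' @return A 3 x 3 numeric matrix with dimnames.
#' @export
codeword_table <- function(scheme = c("prediction", "probability")) {
  scheme <- match.arg(scheme)
  tab <- if (scheme == "prediction")
    rbind(faces = c(1, 1, 0), buildings = c(-1, 0, 1), animals = c(0, -1, -1))
  else
    rbind(faces = c(1, 1, 0.5), buildings = c(0, 0.5, 1),
          animals = c(0.5, 0, 0))
  colnames(tab) <- pair_names()
  tab
}

#' Assign a class from binary votes or probabilities
#'
#' For the prediction scheme the distance of the vote triple to each
#' class's codeword is the Hamming count of mismatching positions (a +/-1
#' vote always mismatches a 0 entry). For the probability scheme it is the
#' sum of absolute differences between the probabilities (each oriented as
#' P(first-named class) of its comparison) and the codeword entries. The
#' class at minimal distance wins; exact ties are broken uniformly at
#' random and flagged.
#'
#' @param votes Numeric triple in comparison order (F-B, F-A, B-A):
#'   +/-1 votes or probabilities in `[0, 1]`.
#' @param table A codeword table from [codeword_table()]; its scheme is
#'   inferred from its entries.
#' @return List with `class` (character), `distances` (named triple) and
#'   `tie` (logical).
#' @export
assign_class <- function(votes, table = codeword_table()) {
  stopifnot(length(votes) == 3)
  prediction_scheme <- any(table == -1)
  if (prediction_scheme) {
    d <- apply(table, 1, function(cw) sum(votes != cw))
  } else {
    if (any(votes < 0 | votes > 1))
      stop_invalid("probabilities must lie in [0, 1]")
    d <- apply(table, 1, function(cw) sum(abs(votes - cw)))
  }
  best <- which(d == min(d))
  tie <- length(best) > 1
  pick <- if (tie) best[sample.int(length(best), 1)] else best
  list(class = rownames(table)[pick], distances = d, tie = tie)
}
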