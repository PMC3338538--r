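# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
      stop("`seed` must be a single finite number", call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

#' Image categories used throughout the package
#'
#' The three stimulus categories, in canonical order. All event tables,
#' sample sets and codeword tables use this ordering.
#'
#' @return Character vector `c("faces", "buildings", "animals")`.
#' @export
categories <- function() c("faces", "buildings", "animals")

# Canonical order of the three binary comparisons.
category_pairs <- function() {
  list(c("faces", "buildings"), c("faces", "animals"), c("buildings", "animals"))
}

pair_names <- function() c("F-B", "F-A", "B-A")
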