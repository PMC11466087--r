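#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, evaluates `code` in the caller's frame, then restores the
#' global RNG state, so seeded package functions never perturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

## Validate a class-label vector against the package's two classes.
.check_classes <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), tolerance_classes())
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         "; expected ", paste(tolerance_classes(), collapse = " or "),
         call. = FALSE)
  }
  factor(y, levels = tolerance_classes())
}

## Stratified fold assignment: within each class, shuffle members and deal
## them round-robin into folds. Consumes the current RNG stream.
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
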