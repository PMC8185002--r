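#' @keywords internal
"_PACKAGE"

#' @importFrom stats p.adjust fisher.test cor rnbinom rbinom
#'   runif rnorm pchisq
#' @importFrom utils read.delim write.table head
NULL

# stop() with call. = FALSE everywhere; errors name the offending value.
abort <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(x == floor(x))

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("'%s' must be a single finite number", name))
  }
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps `N`
#' positions as `N`.
#'
#' @param x A character scalar over `{A,C,G,T,N}`.
#' @return A character scalar.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Run code with a private RNG stream so callers' RNG state is untouched and
# results are reproducible given `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
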