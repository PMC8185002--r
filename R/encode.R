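# One-hot encoding and dataset splitting ------------------------------------

BASES <- c("A", "C", "G", "T")
RESPONSE_CLASSES <- c("inclusion", "exclusion", "unchanged")

#' One-hot encode a 400-base triplet sequence
#'
#' Rows are A, C, G, T in that order; `N` gives an all-zero column.
#'
#' @param seq A 400-character string (or a `triplet_sequence`).
#' @return A 4 x 400 numeric matrix with rownames A, C, G, T.
#' @export
one_hot_encode <- function(seq) {
  if (inherits(seq, "triplet_sequence")) seq <- seq$sequence
  chars <- strsplit(toupper(seq), "")[[1L]]
  if (length(chars) != 400L) {
    abort(sprintf("sequence length must be 400, got %d", length(chars)))
  }
  bad <- setdiff(unique(chars), c(BASES, "N"))
  if (length(bad)) {
    abort(sprintf("unknown character(s) in sequence: %s",
                  paste(bad, collapse = ", ")))
  }
  m <- matrix(0, 4L, 400L, dimnames = list(BASES, NULL))
  hit <- match(chars, BASES)
  ok <- !is.na(hit)
  m[cbind(hit[ok], which(ok))] <- 1
  m
}

#' Encode a set of sequences (and optional labels) for the network
#'
#' @param seqs Character vector of 400-base sequences.
#' @param labels Optional character vector over
#'   `{inclusion, exclusion, unchanged}`.
#' @return A list: `x`, an `N x 1600` matrix (each row a 4 x 400 one-hot
#'   matrix flattened column-major, base index fastest), and `y`, an `N x 3`
#'   0/1 label matrix (or `NULL`).
#' @export
encode_dataset <- function(seqs, labels = NULL) {
  x <- t(vapply(seqs, function(s) as.vector(one_hot_encode(s)),
                numeric(1600L), USE.NAMES = FALSE))
  y <- NULL
  if (!is.null(labels)) {
    if (any(!labels %in% RESPONSE_CLASSES)) {
      abort("labels must be inclusion/exclusion/unchanged")
    }
    y <- matrix(0, length(labels), 3L,
                dimnames = list(NULL, RESPONSE_CLASSES))
    y[cbind(seq_along(labels), match(labels, RESPONSE_CLASSES))] <- 1
  }
  list(x = x, y = y)
}

#' Stratified 70/20/10 split
#'
#' Within each class, `round(f_val * n)` ids go to validation and
#' `round(f_test * n)` to test; the remainder trains.  Membership is random
#' given `seed`; the three sets are disjoint and exhaustive.
#'
#' @param labels Named character vector (names = ids) or plain character
#'   vector (ids default to indices).
#' @param fractions Train/validation/test fractions (must sum to 1).
#' @param seed Integer seed.
#' @return A list of id vectors: `train`, `validation`, `test`.
#' @export
split_dataset <- function(labels, fractions = c(0.7, 0.2, 0.1), seed = 122) {
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  ids <- names(labels) %||% as.character(seq_along(labels))
  out <- list(train = character(0), validation = character(0),
              test = character(0))
  with_seed(seed, {
    for (cl in unique(labels)) {
      cid <- ids[labels == cl]
      n <- length(cid)
      if (n < 3L) abort(sprintf("class '%s' has fewer than 3 members", cl))
      n_val <- round(fractions[2L] * n)
      n_test <- round(fractions[3L] * n)
      if (n_val + n_test >= n) abort("split leaves an empty training set")
      perm <- sample(cid)
      out$validation <- c(out$validation, perm[seq_len(n_val)])
      out$test <- c(out$test, perm[n_val + seq_len(n_test)])
      out$train <- c(out$train, perm[-seq_len(n_val + n_test)])
    }
  })
  out
}
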