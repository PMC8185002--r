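# Model interpretation --------------------------------------------------------

# post-ReLU first-layer activations: (w1 * n) x F1 matrix, rows ordered
# (position, then sample)
conv1_activations <- function(model, x) {
  cfg <- model$config
  xc <- conv1_cols(x, cfg)
  z1 <- sweep(crossprod(xc, model$W1), 2L, model$b1, "+")
  z1[z1 < 0] <- 0
  z1
}

# decode the width-w window starting at position p of sample i from the
# one-hot row; unresolved (N) positions decode to "N"
decode_window <- function(xrow, p, w) {
  out <- character(w)
  for (j in seq_len(w)) {
    col <- xrow[(p + j - 2L) * 4L + 1:4]
    hit <- which(col == 1)
    out[j] <- if (length(hit) == 1L) BASES[hit] else "N"
  }
  paste(out, collapse = "")
}

#' First-layer filter motifs as position probability matrices
#'
#' For each first-layer filter, collects every input window whose activation
#' is at least `threshold` times that filter's maximum activation over the
#' dataset, and tabulates column-wise base frequencies with a pseudocount.
#'
#' @param model A trained `splice_cnn`.
#' @param x Encoded dataset (`N x 1600`).
#' @param threshold Fraction of the per-filter maximum activation a window
#'   must reach (default 0.5).
#' @param pseudocount Added to every base count (default 1).
#' @return A list: `ppm` (list of 4 x width matrices, columns summing to 1),
#'   `n_windows` (contributing windows per filter), `empty` (logical: filter
#'   never activated; its PPM is uniform).
#' @export
filter_to_ppm <- function(model, x, threshold = 0.5, pseudocount = 1) {
  cfg <- model$config
  w <- cfg$filter_width1
  act <- conv1_activations(model, x)
  w1 <- cfg$dims$conv1
  n <- nrow(x)
  ppms <- vector("list", cfg$n_filters1)
  nwin <- integer(cfg$n_filters1)
  empty <- logical(cfg$n_filters1)
  for (f in seq_len(cfg$n_filters1)) {
    a <- act[, f]
    mx <- max(a)
    counts <- matrix(pseudocount, 4L, w, dimnames = list(BASES, NULL))
    if (mx <= 0) {
      empty[f] <- TRUE
    } else {
      hits <- which(a >= threshold * mx)
      nwin[f] <- length(hits)
      p <- (hits - 1L) %% w1 + 1L
      i <- (hits - 1L) %/% w1 + 1L
      for (h in seq_along(hits)) {
        start <- (p[h] - 1L) * 4L + 1L
        xb <- matrix(x[i[h], start + 0:(4L * w - 1L)], 4L, w)
        counts <- counts + xb
      }
    }
    ppms[[f]] <- sweep(counts, 2L, colSums(counts), "/")
  }
  list(ppm = ppms, n_windows = nwin, empty = empty)
}

#' Filter-ablation contribution to classification
#'
#' Zeroes one first-layer filter's output at a time (all other parameters
#' untouched), re-scores the test set, and reports the per-class AUC drop
#' `dAUC = AUC(original) - AUC(ablated)`.  A filter is `identified` when its
#' contribution is positive in any class and a `top` contributor when it is
#' at least `top_threshold` in any class.
#'
#' @param model A trained `splice_cnn`.
#' @param x,y Encoded test set with 0/1 labels (all classes present).
#' @param top_threshold Top-contributor threshold on dAUC (default 0.05).
#' @return A `data.frame`: `filter`, one `dauc_<class>` column per class,
#'   `max_dauc`, `identified`, `top`.
#' @export
motif_contribution <- function(model, x, y, top_threshold = 0.05) {
  if (any(colSums(y) == 0L)) abort("test set must contain every class")
  cfg <- model$config
  base_scores <- cnn_forward(model, x)$scores
  auc0 <- vapply(seq_len(ncol(y)), function(k)
    compute_auc(base_scores[, k], y[, k] == 1), 0)
  dmat <- matrix(NA_real_, cfg$n_filters1, ncol(y))
  for (f in seq_len(cfg$n_filters1)) {
    sc <- cnn_forward(model, x, ablate_filters = f)$scores
    dmat[f, ] <- auc0 - vapply(seq_len(ncol(y)), function(k)
      compute_auc(sc[, k], y[, k] == 1), 0)
  }
  out <- data.frame(filter = seq_len(cfg$n_filters1))
  cls <- colnames(y) %||% RESPONSE_CLASSES[seq_len(ncol(y))]
  for (k in seq_len(ncol(y))) out[[paste0("dauc_", cls[k])]] <- dmat[, k]
  out$max_dauc <- apply(dmat, 1L, max)
  out$identified <- out$max_dauc > 0
  out$top <- out$max_dauc >= top_threshold
  out
}

#' Positional importance of each first-layer filter
#'
#' Mean post-ReLU first-layer activation per position across sequences,
#' z-scored across positions within each filter.
#'
#' @param model A trained `splice_cnn`.
#' @param x Encoded dataset.
#' @return A matrix (positions x filters) of z-scores; constant-activation
#'   filters get all-zero rows.  Attribute `xi2_positions` marks the conv
#'   positions whose window starts inside the XI2 block.
#' @export
positional_importance <- function(model, x) {
  cfg <- model$config
  w1 <- cfg$dims$conv1
  n <- nrow(x)
  act <- conv1_activations(model, x)
  pos_mean <- apply(act, 2L, function(a) {
    rowMeans(matrix(a, w1, n))
  })
  z <- apply(pos_mean, 2L, function(m) {
    s <- stats::sd(m)
    if (!is.finite(s) || s == 0) return(rep(0, length(m)))
    (m - mean(m)) / s
  })
  # population (1/n) z-scores so each column has unit variance
  z <- sweep(z, 2L, sqrt((w1 - 1) / w1), "/")
  z[, apply(pos_mean, 2L, stats::sd) == 0] <- 0
  attr(z, "xi2_positions") <- intersect(seq_len(w1), 201:300)
  z
}

#' In silico saturation mutagenesis of one sequence
#'
#' Every position is mutated to the three alternative bases; the summed
#' 3-class binary cross-entropy against the sequence's label is compared to
#' the original loss, and the maximum increase per position is recorded.
#' Letter heights are the per-position maxima scaled so the largest equals 1,
#' floored at `min_height`.
#'
#' @param model A trained `splice_cnn`.
#' @param x One encoded sequence (length-1600 vector or 1 x 1600 matrix), or
#'   a 400-base string.
#' @param label The sequence's class (`inclusion`, `exclusion`, `unchanged`),
#'   or a length-3 0/1 vector.
#' @param min_height Minimum rendered letter height (default 0.25).
#' @return A `data.frame` with one row per position: `position`,
#'   `max_loss_change`, `height`.
#' @export
saturation_mutagenesis <- function(model, x, label, min_height = 0.25) {
  if (is.character(x) && length(x) == 1L && nchar(x) > 3L) {
    x <- encode_dataset(x)$x
  }
  x <- as.numeric(x)
  if (length(x) != 4L * model$config$input_width) {
    abort("x must encode a single sequence")
  }
  if (is.character(label)) {
    y <- as.numeric(RESPONSE_CLASSES == label)
    if (sum(y) != 1) abort("unknown label")
  } else {
    y <- as.numeric(label)
  }
  width <- model$config$input_width
  loss0 <- bce_loss(predict_cnn(model, x), matrix(y, 1L))
  # batch all mutants: 3 alternatives per position
  muts <- matrix(x, nrow = 3L * width, ncol = length(x), byrow = TRUE)
  rowinfo <- expand.grid(alt = 1:3, pos = seq_len(width))
  keep <- logical(nrow(muts))
  for (r in seq_len(nrow(muts))) {
    p <- rowinfo$pos[r]
    col <- x[(p - 1L) * 4L + 1:4]
    orig <- which(col == 1)
    alts <- if (length(orig) == 1L) setdiff(1:4, orig) else 1:4
    a <- rowinfo$alt[r]
    if (a > length(alts)) next       # N column: only when fewer than 3 alts
    keep[r] <- TRUE
    muts[r, (p - 1L) * 4L + 1:4] <- 0
    muts[r, (p - 1L) * 4L + alts[a]] <- 1
  }
  muts <- muts[keep, , drop = FALSE]
  info <- rowinfo[keep, , drop = FALSE]
  losses <- bce_loss(predict_cnn(model, muts),
                     matrix(y, nrow(muts), 3L, byrow = TRUE))
  dl <- losses - loss0
  max_change <- vapply(seq_len(width), function(p) {
    v <- dl[info$pos == p]
    if (length(v)) max(v) else 0
  }, 0)
  scale_ref <- max(max_change)
  heights <- if (scale_ref > 0) pmax(max_change / scale_ref, min_height)
             else rep(min_height, width)
  data.frame(position = seq_len(width), max_loss_change = max_change,
             height = heights)
}

#' Discriminative 5-mer enrichment at the middle-exon donor
#'
#' Extracts the -3..+7 window around the middle exon's 5' splice site from
#' each sequence and, per class, tests every observed k-mer for enrichment
#' against the pooled other classes with a one-sided Fisher exact test on
#' presence/absence counts, BH-adjusted.  Enriched k-mers (adjusted p below
#' `alpha`) are stacked (all same length, weighted by sequence count, plus a
#' pseudocount) into one PPM per class.
#'
#' @param sequences Character vector of 400-base triplet sequences.
#' @param classes Class label per sequence.
#' @param k k-mer length (default 5; must not exceed the window).
#' @param window Offsets relative to the donor (default -3..+7; negative =
#'   exonic, no position 0).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param pseudocount PPM pseudocount.
#' @return A list: `table` (class, kmer, counts, p, padj, enriched) and
#'   `class_ppm` (named list of 4 x k matrices, `NULL` where nothing is
#'   enriched).
#' @export
kmer_enrichment <- function(sequences, classes, k = 5, window = c(-3, 7),
                            alpha = 0.05, pseudocount = 1) {
  win <- donor_window(sequences, window)
  if (k > nchar(win[1L])) abort("k exceeds the window length")
  kmers_of <- function(s) {
    n <- nchar(s) - k + 1L
    unique(substring(s, seq_len(n), seq_len(n) + k - 1L))
  }
  by_seq <- lapply(win, kmers_of)
  cls <- unique(classes)
  rows <- list()
  for (cl in cls) {
    in_cl <- classes == cl
    all_km <- unique(unlist(by_seq[in_cl]))
    for (km in all_km) {
      has <- vapply(by_seq, function(v) km %in% v, NA)
      a <- sum(has & in_cl); b <- sum(!has & in_cl)
      c_ <- sum(has & !in_cl); d <- sum(!has & !in_cl)
      p <- fisher.test(matrix(c(a, b, c_, d), 2L),
                       alternative = "greater")$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, kmer = km, n_class = a, n_other = c_,
        size_class = a + b, size_other = c_ + d, p = p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$padj <- NA_real_
  for (cl in cls) {
    m <- tab$class == cl
    tab$padj[m] <- bh_fdr(tab$p[m])
  }
  tab$enriched <- tab$padj < alpha
  class_ppm <- lapply(cls, function(cl) {
    e <- tab[tab$class == cl & tab$enriched, , drop = FALSE]
    if (nrow(e) == 0L) return(NULL)
    counts <- matrix(pseudocount, 4L, k, dimnames = list(BASES, NULL))
    for (i in seq_len(nrow(e))) {
      chars <- strsplit(e$kmer[i], "")[[1L]]
      hit <- match(chars, BASES)
      ok <- !is.na(hit)
      counts[cbind(hit[ok], which(ok))] <-
        counts[cbind(hit[ok], which(ok))] + e$n_class[i]
    }
    sweep(counts, 2L, colSums(counts), "/")
  })
  names(class_ppm) <- cls
  list(table = tab, class_ppm = class_ppm)
}

# the -3..+7 (default) window around the middle-exon donor: XI2 occupies
# sequence positions 201..300 with the exon/intron boundary between block
# positions 25 and 26 (global 225/226)
donor_window <- function(sequences, window = c(-3, 7)) {
  lo <- 225L + window[1L] + 1L   # -1 is global 225
  hi <- 225L + window[2L]
  if (lo < 201L || hi > 300L) abort("window must lie inside the XI2 block")
  substring(sequences, lo, hi)
}

#' PPM of a bare k-mer
#'
#' @param kmer A DNA string.
#' @param pseudocount Added per cell before normalising.
#' @return A 4 x k column-stochastic matrix.
#' @export
kmer_ppm <- function(kmer, pseudocount = 0.01) {
  chars <- strsplit(toupper(kmer), "")[[1L]]
  m <- matrix(pseudocount, 4L, length(chars), dimnames = list(BASES, NULL))
  m[cbind(match(chars, BASES), seq_along(chars))] <- 1
  sweep(m, 2L, colSums(m), "/")
}

#' Pearson correlation between two position probability matrices
#'
#' Matrices are flattened and correlated; both must share dimensions (4 x k).
#'
#' @param ppm1,ppm2 Numeric matrices of equal dimension.
#' @return A list with `r` and `r2`.
#' @export
correlate_ppm <- function(ppm1, ppm2) {
  if (!all(dim(ppm1) == dim(ppm2))) abort("PPM dimensions differ")
  v1 <- as.vector(ppm1); v2 <- as.vector(ppm2)
  # a constant (e.g. uniform) matrix has no defined correlation
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    return(list(r = NA_real_, r2 = NA_real_))
  }
  r <- cor(v1, v2)
  list(r = r, r2 = r^2)
}

#' Write PPMs in MEME minimal motif format
#'
#' @param ppms Named list of 4 x k PPMs.
#' @param path Output path.
#' @param background Background base frequencies.
#' @export
write_meme <- function(ppms, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.3f", BASES, background), collapse = " "),
               ""), con)
  nm <- names(ppms) %||% paste0("motif_", seq_along(ppms))
  for (i in seq_along(ppms)) {
    p <- ppms[[i]]
    writeLines(sprintf("MOTIF %s", nm[i]), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d",
                       ncol(p)), con)
    writeLines(apply(p, 2L, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
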