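# Differential splicing quantification --------------------------------------

#' Percent spliced-in of the middle exon
#'
#' `psi = 0.5 (R1 + R2) / (0.5 (R1 + R2) + R3)`, where `R1`/`R2` count reads
#' over the two inclusion junctions and `R3` reads over the skipping junction.
#' Vectorised; returns `NA` where the denominator is zero (uninformative
#' replicate).
#'
#' @param r1,r2,r3 Non-negative integer junction read counts.
#' @return psi in \[0, 1\], or `NA` where no informative reads exist.
#' @examples
#' compute_psi(10, 10, 10)  # 0.5
#' compute_psi(18, 22, 10)  # 2/3
#' @export
compute_psi <- function(r1, r2, r3) {
  if (any(c(r1, r2, r3) < 0, na.rm = TRUE)) {
    abort("junction counts must be non-negative")
  }
  inc <- 0.5 * (r1 + r2)
  den <- inc + r3
  ifelse(den > 0, inc / den, NA_real_)
}

#' Cochran-Mantel-Haenszel test over replicate strata
#'
#' Tests for association between treatment and middle-exon splicing across K
#' replicate strata of 2x2 tables (rows: treated/control; columns:
#' inclusion-supporting/skipping-supporting reads).  The chi-square statistic
#' is computed without continuity correction and referred to 1 df.  Strata
#' with a zero row or column margin carry no information and are dropped.
#'
#' @param tables A 2x2xK array, or a list of 2x2 matrices.
#' @param correct Apply the continuity correction (default `FALSE`).
#' @return A list with `statistic` and `p.value` (both `NA` when all strata
#'   are degenerate).
#' @export
cmh_test <- function(tables, correct = FALSE) {
  if (is.list(tables)) {
    tables <- array(unlist(tables), dim = c(2L, 2L, length(tables)))
  }
  if (length(dim(tables)) == 2L) tables <- array(tables, c(2L, 2L, 1L))
  if (!all(dim(tables)[1:2] == 2L)) abort("strata must be 2x2 tables")
  keep <- apply(tables, 3L, function(tab) {
    all(rowSums(tab) > 0) && all(colSums(tab) > 0)
  })
  tables <- tables[, , keep, drop = FALSE]
  k <- dim(tables)[3L]
  if (k == 0L) {
    return(list(statistic = NA_real_, p.value = NA_real_))
  }
  # Mantel-Haenszel chi-square: (|sum a - sum E[a]| - cc)^2 / sum Var(a),
  # where a is the treated-inclusion cell and E/Var are hypergeometric under
  # the fixed margins of each stratum (stats::mantelhaen.test computes the
  # same quantity but requires >= 2 strata)
  a <- tables[1L, 1L, ]
  r1 <- tables[1L, 1L, ] + tables[1L, 2L, ]
  r2 <- tables[2L, 1L, ] + tables[2L, 2L, ]
  c1 <- tables[1L, 1L, ] + tables[2L, 1L, ]
  c2 <- tables[1L, 2L, ] + tables[2L, 2L, ]
  n <- r1 + r2
  e <- r1 * c1 / n
  v <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  if (sum(v) <= 0) return(list(statistic = NA_real_, p.value = NA_real_))
  dev <- abs(sum(a) - sum(e))
  if (correct) dev <- max(0, dev - 0.5)
  stat <- dev^2 / sum(v)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA` entries are passed through untouched.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (may contain `NA`).
#' @return Adjusted values, monotone in the order statistics, capped at 1.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Classify the treatment response of one exon triplet
#'
#' Inclusion: `dpsi >= dpsi_threshold` and `fdr < alpha`.  Exclusion:
#' `dpsi <= -dpsi_threshold` and `fdr < alpha`.  Unchanged: pre-treatment psi
#' within `psi_range`, `|dpsi| < unchanged_dpsi` and `fdr >= alpha`.
#' Everything else is `"other"` (excluded from classifier training).
#'
#' @param psi_before Mean control psi.
#' @param dpsi Mean treated psi minus mean control psi.
#' @param fdr BH-adjusted p-value.
#' @param dpsi_threshold Responsive-effect threshold (default 0.1).
#' @param alpha FDR threshold (default 0.1).
#' @param unchanged_dpsi Unchanged-effect bound (default 0.01, on `|dpsi|`).
#' @param psi_range Pre-treatment psi range required for the unchanged class.
#' @param signed_unchanged If `TRUE`, apply the unchanged bound to signed
#'   `dpsi < unchanged_dpsi` instead of `|dpsi|`.
#' @param require_unchanged_fdr If `FALSE`, drop the `fdr >= alpha` condition
#'   from the unchanged class.
#' @return Character vector over `{inclusion, exclusion, unchanged, other}`;
#'   `NA` inputs give `NA`.
#' @export
classify_response <- function(psi_before, dpsi, fdr,
                              dpsi_threshold = 0.1, alpha = 0.1,
                              unchanged_dpsi = 0.01,
                              psi_range = c(0.1, 0.9),
                              signed_unchanged = FALSE,
                              require_unchanged_fdr = TRUE) {
  n <- max(length(psi_before), length(dpsi), length(fdr))
  psi_before <- rep_len(psi_before, n)
  dpsi <- rep_len(dpsi, n)
  fdr <- rep_len(fdr, n)
  small <- if (signed_unchanged) dpsi < unchanged_dpsi else
    abs(dpsi) < unchanged_dpsi
  unchanged_ok <- psi_before >= psi_range[1L] & psi_before <= psi_range[2L] &
    small & (if (require_unchanged_fdr) fdr >= alpha else TRUE)
  out <- ifelse(dpsi >= dpsi_threshold & fdr < alpha, "inclusion",
         ifelse(dpsi <= -dpsi_threshold & fdr < alpha, "exclusion",
         ifelse(unchanged_ok, "unchanged", "other")))
  out[is.na(psi_before) | is.na(dpsi) | is.na(fdr)] <- NA_character_
  out
}

#' Quantify differential splicing for every triplet in a count table
#'
#' Per triplet: per-replicate psi by condition, condition means, delta-psi,
#' a CMH test across replicate strata (one 2x2 table per replicate:
#' treated/control x inclusion/skipping reads), BH FDR across all expressed
#' triplets, and the response class.
#'
#' A triplet is *expressed* when each of R1, R2, R3 summed over replicates is
#' positive in both conditions and the mean informative read count
#' (`0.5 (R1 + R2) + R3`) is at least `min_mean_reads`.  A call additionally
#' requires `min_informative` informative replicates per condition.
#'
#' @param counts A junction-count table (see [read_junction_counts()]).
#' @param min_mean_reads Minimum mean informative reads for the expressed
#'   flag (default 10).
#' @param min_informative Minimum informative replicates per condition for a
#'   call (default 2).
#' @param cell_mode How inclusion-supporting reads enter the CMH 2x2 cells:
#'   `"half"` (default) uses `round(0.5 (R1 + R2))`, matching the psi
#'   estimator's weighting; `"raw"` uses `R1 + R2`.
#' @param ... Passed to [classify_response()].
#' @return A `data.frame` of splicing calls, one row per triplet:
#'   `triplet_id`, `expressed`, `n_informative_control`,
#'   `n_informative_treated`, `psi_control`, `psi_treated`, `dpsi`,
#'   `cmh_stat`, `p_value`, `fdr`, `class`.
#' @export
quantify <- function(counts, min_mean_reads = 10, min_informative = 2,
                     cell_mode = c("half", "raw"), ...) {
  counts <- validate_junction_counts(counts)
  cell_mode <- match.arg(cell_mode)
  ids <- unique(counts$triplet_id)
  rows <- lapply(ids, function(id) {
    quantify_one(counts[counts$triplet_id == id, , drop = FALSE],
                 min_mean_reads, min_informative, cell_mode)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(ifelse(out$expressed, out$p_value, NA_real_))
  out$class <- classify_response(out$psi_control, out$dpsi, out$fdr, ...)
  out$class[!out$expressed] <- NA_character_
  rownames(out) <- NULL
  out
}

quantify_one <- function(d, min_mean_reads, min_informative, cell_mode) {
  ctrl <- d[d$condition == "control", , drop = FALSE]
  trt <- d[d$condition == "treated", , drop = FALSE]
  psi_c <- compute_psi(ctrl$R1, ctrl$R2, ctrl$R3)
  psi_t <- compute_psi(trt$R1, trt$R2, trt$R3)
  informative <- function(x) 0.5 * (x$R1 + x$R2) + x$R3
  expressed <- nrow(ctrl) > 0 && nrow(trt) > 0 &&
    all(colSums(ctrl[, c("R1", "R2", "R3")]) > 0) &&
    all(colSums(trt[, c("R1", "R2", "R3")]) > 0) &&
    mean(c(informative(ctrl), informative(trt))) >= min_mean_reads
  n_ic <- sum(!is.na(psi_c)); n_it <- sum(!is.na(psi_t))
  callable <- expressed && n_ic >= min_informative && n_it >= min_informative

  stat <- NA_real_; p <- NA_real_
  if (callable) {
    # pair replicates by sample id where both conditions share it
    samples <- intersect(ctrl$sample, trt$sample)
    tabs <- lapply(samples, function(s) {
      a <- trt[trt$sample == s, ][1L, ]
      b <- ctrl[ctrl$sample == s, ][1L, ]
      inc <- function(x) if (cell_mode == "half") round(0.5 * (x$R1 + x$R2))
                         else x$R1 + x$R2
      matrix(c(inc(a), inc(b), a$R3, b$R3), 2L, 2L,
             dimnames = list(c("treated", "control"),
                             c("inclusion", "skipping")))
    })
    if (length(tabs)) {
      res <- cmh_test(tabs)
      stat <- res$statistic; p <- res$p.value
    }
  }
  data.frame(
    triplet_id = d$triplet_id[1L],
    expressed = expressed,
    n_informative_control = n_ic,
    n_informative_treated = n_it,
    psi_control = if (n_ic >= min_informative) mean(psi_c, na.rm = TRUE)
                  else NA_real_,
    psi_treated = if (n_it >= min_informative) mean(psi_t, na.rm = TRUE)
                  else NA_real_,
    dpsi = if (callable) mean(psi_t, na.rm = TRUE) - mean(psi_c, na.rm = TRUE)
           else NA_real_,
    cmh_stat = stat,
    p_value = p,
    stringsAsFactors = FALSE
  )
}
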