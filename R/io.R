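# Tabular and variant I/O ---------------------------------------------------

#' Read a junction read-count table
#'
#' Expects a TSV with header and columns `triplet_id`, `sample`, `condition`
#' (`control` or `treated`), `R1`, `R2`, `R3`.  `R1` and `R2` count reads
#' spanning the two middle-exon inclusion junctions, `R3` reads spanning the
#' skipping junction; all must be non-negative integers.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` of junction counts.
#' @export
read_junction_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_junction_counts(df)
}

#' @rdname read_junction_counts
#' @param counts A junction-count `data.frame`.
#' @export
write_junction_counts <- function(counts, path) {
  validate_junction_counts(counts)
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_junction_counts <- function(df) {
  need <- c("triplet_id", "sample", "condition", "R1", "R2", "R3")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("junction count table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(df[, need, drop = FALSE])
  bad <- !df$condition %in% c("control", "treated")
  if (any(bad)) {
    abort(sprintf("unknown condition label(s): %s",
                  paste(unique(df$condition[bad]), collapse = ", ")))
  }
  for (col in c("R1", "R2", "R3")) {
    if (!is_count(df[[col]])) {
      abort(sprintf("column %s must contain non-negative integers", col))
    }
  }
  df[, c(need, setdiff(names(df), need)), drop = FALSE]
}

#' Write / read a result table (splicing calls, predictions, rescue calls)
#'
#' Plain TSV with header; round-trips losslessly for atomic columns.
#'
#' @param x A `data.frame`.
#' @param path Output path.
#' @export
write_results <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read variant records from a VCF
#'
#' @param path Path to a VCF (v4.x) file.
#' @return A `data.frame` with `chrom`, `pos`, `id`, `ref`, `alt`, and
#'   `significance` (the `CLNSIG` INFO field where present).
#' @export
read_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_frame(v)
  sig <- tryCatch(vcfR::extract.info(v, "CLNSIG"),
                  error = function(e) rep(NA_character_, nrow(fix)))
  data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    id = fix$ID,
    ref = fix$REF,
    alt = fix$ALT,
    significance = sig,
    stringsAsFactors = FALSE
  )
}

#' Read allele frequencies from a VCF `AF` INFO field
#'
#' @param path Path to a VCF file.
#' @return A `data.frame` with `chrom`, `pos`, `ref`, `alt`, `af`.
#' @export
read_af_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf_fix_frame(v)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
  data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, af = af,
    stringsAsFactors = FALSE
  )
}

#' Read a splice-effect score table
#'
#' A TSV of SpliceAI-style records: one row per (variant, influenced splice
#' junction): columns `variant_id`, `chrom`, `pos`, `ref`, `alt`, `isj`
#' (genomic coordinate of the influenced junction, given as the terminal
#' exonic base the package uses for donors/acceptors), `effect`
#' (`gain`/`loss`) and `score` in \[0, 1\].
#'
#' @param path Path to a TSV file.
#' @return A validated `data.frame`.
#' @export
read_splice_effects <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  validate_splice_effects(df)
}

validate_splice_effects <- function(df) {
  need <- c("variant_id", "chrom", "pos", "ref", "alt", "isj", "effect",
            "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("splice-effect table lacks column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (nrow(df) && any(!df$effect %in% c("gain", "loss"))) {
    abort("splice-effect 'effect' must be 'gain' or 'loss'")
  }
  if (nrow(df) && (any(df$score < 0) || any(df$score > 1))) {
    abort("splice-effect 'score' must lie in [0, 1]")
  }
  df
}

# vcfR::getFIX drops to a bare vector for single-record files
vcf_fix_frame <- function(v) {
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)
  as.data.frame(fix, stringsAsFactors = FALSE)
}

# Minimal VCF v4.2 writer used by the fixture generator.  `af`, when given,
# is written as an INFO AF field.
write_minimal_vcf <- function(df, path, af = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "##INFO=<ID=CLNSIG,Number=.,Type=String,Description=\"Clinical significance\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(df)) {
    info <- rep(".", nrow(df))
    if (!is.null(af)) info <- sprintf("AF=%.6g", af)
    if (!is.null(df$significance)) {
      cln <- sprintf("CLNSIG=%s", df$significance)
      info <- ifelse(info == ".", cln, paste(info, cln, sep = ";"))
    }
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                       df$chrom, df$pos, df$id %||% ".", df$ref, df$alt, info),
               con)
  }
  invisible(path)
}

#' Write a triplet index as GTF exon features
#'
#' One transcript per triplet, three exon lines each; useful for exporting
#' simulated annotations.
#'
#' @param index A triplet index.
#' @param path Output GTF path.
#' @export
write_triplet_gtf <- function(index, path) {
  lines <- character(0)
  for (i in seq_len(nrow(index))) {
    t <- index[i, ]
    exs <- rbind(c(t$exon1_start, t$exon1_end),
                 c(t$exon2_start, t$exon2_end),
                 c(t$exon3_start, t$exon3_end))
    exs <- exs[order(exs[, 1L]), , drop = FALSE]
    lines <- c(lines, sprintf(
      "%s\tsplicetriplet\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
      t$chrom, exs[, 1L], exs[, 2L], t$strand, t$gene_id, t$transcript_id))
  }
  writeLines(lines, path)
  invisible(path)
}
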