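# Exon-triplet index -------------------------------------------------------
#
# An exon triplet is three consecutive exons of one transcript.  All
# coordinates are GTF-style: 1-based, inclusive, genomic.  Exons are stored in
# transcript orientation (exon2 is the middle exon); on the minus strand
# transcript order is descending genomic order.  Junction coordinates are the
# terminal exonic base on each side:
#   donor    = last exonic base at a 5' splice site (exon end on +, start on -)
#   acceptor = first exonic base at a 3' splice site (exon start on +, end on -)

#' Build the exon-triplet index from a transcript annotation
#'
#' Slides a window of three consecutive exons along every transcript and
#' records each window as one exon triplet, together with the four derived
#' splice-junction coordinates of its two introns.  Triplets whose coordinate
#' trio is identical across transcripts are deduplicated (key: chromosome,
#' strand, and the six exon boundaries), keeping the first transcript
#' encountered in a stable ordering.
#'
#' @param annotation Path to a GTF file (Ensembl dialect, exon features with
#'   `gene_id`/`transcript_id` attributes), or a [GenomicRanges::GRanges] as
#'   returned by [rtracklayer::import()].
#' @return A `data.frame` with one row per unique triplet: `triplet_id`,
#'   `gene_id`, `transcript_id`, `chrom`, `strand`, `exon{1,2,3}_start`,
#'   `exon{1,2,3}_end`, and junction coordinates `donor1`, `acceptor2`,
#'   `donor2`, `acceptor3` (genomic positions of the terminal exonic bases).
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(c(
#'   paste("chr1\tx\texon\t101\t200\t.\t+\t.",
#'         'gene_id "g1"; transcript_id "t1";'),
#'   paste("chr1\tx\texon\t301\t400\t.\t+\t.",
#'         'gene_id "g1"; transcript_id "t1";'),
#'   paste("chr1\tx\texon\t501\t600\t.\t+\t.",
#'         'gene_id "g1"; transcript_id "t1";')
#' ), gtf)
#' build_triplet_index(gtf)
#' @export
build_triplet_index <- function(annotation) {
  gr <- read_exon_annotation(annotation)
  if (length(gr) == 0L) return(empty_triplet_index())

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(gr$transcript_id),
    stringsAsFactors = FALSE
  )
  if (any(!df$strand %in% c("+", "-"))) {
    abort("exon features must be stranded (+/-)")
  }

  pieces <- lapply(split(df, df$transcript_id), transcript_triplets)
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0L) return(empty_triplet_index())

  # stable deterministic order, then exact-coordinate deduplication
  key <- with(out, paste(chrom, strand, exon1_start, exon1_end, exon2_start,
                         exon2_end, exon3_start, exon3_end, sep = ":"))
  ord <- order(out$chrom, out$exon1_start, out$exon3_end, out$strand,
               out$transcript_id)
  out <- out[ord, , drop = FALSE]
  key <- key[ord]
  out <- out[!duplicated(key), , drop = FALSE]
  out$triplet_id <- paste0(out$chrom, out$strand, ":",
                           out$exon1_start, "-", out$exon1_end, ":",
                           out$exon2_start, "-", out$exon2_end, ":",
                           out$exon3_start, "-", out$exon3_end)
  rownames(out) <- NULL
  out[, c("triplet_id", "gene_id", "transcript_id", "chrom", "strand",
          "exon1_start", "exon1_end", "exon2_start", "exon2_end",
          "exon3_start", "exon3_end",
          "donor1", "acceptor2", "donor2", "acceptor3")]
}

read_exon_annotation <- function(annotation) {
  if (inherits(annotation, "GRanges")) {
    gr <- annotation
  } else if (is.character(annotation) && length(annotation) == 1L) {
    gr <- tryCatch(
      rtracklayer::import(annotation, format = "gtf"),
      error = function(e) {
        abort(sprintf("failed to parse GTF '%s': %s", annotation,
                      conditionMessage(e)))
      }
    )
  } else {
    abort("'annotation' must be a GTF path or a GRanges")
  }
  if (!is.null(gr$type)) gr <- gr[gr$type == "exon"]
  if (length(gr) > 0L &&
      (is.null(gr$transcript_id) || is.null(gr$gene_id))) {
    abort("GTF exons must carry gene_id and transcript_id attributes")
  }
  gr
}

transcript_triplets <- function(tx) {
  tx <- tx[order(tx$start), , drop = FALSE]
  n <- nrow(tx)
  if (n >= 2L && any(tx$start[-1L] <= tx$end[-n])) {
    abort(sprintf("transcript '%s' has overlapping or unordered exons",
                  tx$transcript_id[1L]))
  }
  if (n < 3L) return(NULL)
  # transcript orientation: minus strand reads right-to-left
  if (tx$strand[1L] == "-") tx <- tx[n:1L, , drop = FALSE]
  idx <- seq_len(n - 2L)
  e1 <- tx[idx, ]; e2 <- tx[idx + 1L, ]; e3 <- tx[idx + 2L, ]
  minus <- tx$strand[1L] == "-"
  data.frame(
    gene_id = e1$gene_id, transcript_id = e1$transcript_id,
    chrom = e1$chrom, strand = e1$strand,
    exon1_start = e1$start, exon1_end = e1$end,
    exon2_start = e2$start, exon2_end = e2$end,
    exon3_start = e3$start, exon3_end = e3$end,
    donor1 = if (minus) e1$start else e1$end,
    acceptor2 = if (minus) e2$end else e2$start,
    donor2 = if (minus) e2$start else e2$end,
    acceptor3 = if (minus) e3$end else e3$start,
    stringsAsFactors = FALSE
  )
}

empty_triplet_index <- function() {
  data.frame(
    triplet_id = character(), gene_id = character(),
    transcript_id = character(), chrom = character(), strand = character(),
    exon1_start = integer(), exon1_end = integer(),
    exon2_start = integer(), exon2_end = integer(),
    exon3_start = integer(), exon3_end = integer(),
    donor1 = integer(), acceptor2 = integer(), donor2 = integer(),
    acceptor3 = integer(), stringsAsFactors = FALSE
  )
}
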