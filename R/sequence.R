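# Junction-flank sequence extraction ---------------------------------------
#
# Every triplet yields four 100-base blocks, each 25 exonic + 75 intronic
# bases, reported 5'->3' in transcript orientation and concatenated as
# UI1 || I1X || XI2 || I2D (length 400):
#   UI1 spans the donor of exon 1, I1X the acceptor of exon 2,
#   XI2 the donor of exon 2 (the middle exon's 5' splice site),
#   I2D the acceptor of exon 3.
# Donor blocks put the exon/intron boundary between positions 25 and 26;
# acceptor blocks between positions 75 and 76.  Exons or introns shorter than
# the flank width are padded with N at the end farthest from the junction, so
# the junction stays anchored at its fixed offset.

BLOCK_NAMES <- c("UI1", "I1X", "XI2", "I2D")

#' Coerce a genome argument to a DNAStringSet
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @return A `DNAStringSet` keyed by chromosome name.
#' @export
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    # FASTA headers may carry descriptions after the first token
    names(g) <- vapply(strsplit(names(g), "\\s+"), `[`, "", 1L)
    return(g)
  }
  abort("'genome' must be a DNAStringSet or an existing FASTA path")
}

# Geometry of the four blocks of one triplet, in genomic plus-strand terms.
# Each block has a left and a right side; `near` is the side's base adjacent
# to (or at) the junction, `len` the flank width, `limit` the coordinate
# beyond which the exon/intron ends (padding takes over there).
block_geometry <- function(triplet) {
  t <- as.list(triplet)
  plus <- t$strand == "+"
  side <- function(near, len, limit) list(near = near, len = len,
                                          limit = limit)
  if (plus) {
    list(
      UI1 = list(left = side(t$donor1, 25L, t$exon1_start),
                 right = side(t$donor1 + 1L, 75L, t$exon2_start - 1L),
                 left_role = "exon", right_role = "intron"),
      I1X = list(left = side(t$acceptor2 - 1L, 75L, t$exon1_end + 1L),
                 right = side(t$acceptor2, 25L, t$exon2_end),
                 left_role = "intron", right_role = "exon"),
      XI2 = list(left = side(t$donor2, 25L, t$exon2_start),
                 right = side(t$donor2 + 1L, 75L, t$exon3_start - 1L),
                 left_role = "exon", right_role = "intron"),
      I2D = list(left = side(t$acceptor3 - 1L, 75L, t$exon2_end + 1L),
                 right = side(t$acceptor3, 25L, t$exon3_end),
                 left_role = "intron", right_role = "exon")
    )
  } else {
    # minus strand: exon1 is genomically rightmost; blocks are extracted on
    # the plus strand and reverse-complemented afterwards
    list(
      UI1 = list(left = side(t$donor1 - 1L, 75L, t$exon2_end + 1L),
                 right = side(t$donor1, 25L, t$exon1_end),
                 left_role = "intron", right_role = "exon"),
      I1X = list(left = side(t$acceptor2, 25L, t$exon2_start),
                 right = side(t$acceptor2 + 1L, 75L, t$exon1_start - 1L),
                 left_role = "exon", right_role = "intron"),
      XI2 = list(left = side(t$donor2 - 1L, 75L, t$exon3_end + 1L),
                 right = side(t$donor2, 25L, t$exon2_end),
                 left_role = "intron", right_role = "exon"),
      I2D = list(left = side(t$acceptor3, 25L, t$exon3_start),
                 right = side(t$acceptor3 + 1L, 75L, t$exon2_start - 1L),
                 left_role = "exon", right_role = "intron")
    )
  }
}

# Extract one side of a block (genomic plus-strand orientation), optionally
# with an edit applied.  Left sides are anchored at their right end (the
# junction); right sides at their left end; bases slide in from the far end
# after an indel, and N padding fills where the exon/intron runs out.
extract_side <- function(chromseq, s, which = c("left", "right"),
                         edit = NULL) {
  which <- match.arg(which)
  chromlen <- length(chromseq)
  slack <- if (is.null(edit)) 0L else
    max(0L, nchar(edit$ref) - nchar(edit$alt))
  if (which == "left") {
    lo <- max(s$limit, s$near - s$len + 1L - slack)
    hi <- s$near
  } else {
    lo <- s$near
    hi <- min(s$limit, s$near + s$len - 1L + slack)
  }
  if (hi < lo) {
    raw <- ""
  } else {
    if (lo < 1L || hi > chromlen) {
      abort(sprintf("block window [%d,%d] out of chromosome bounds (1..%d)",
                    lo, hi, chromlen))
    }
    raw <- as.character(Biostrings::subseq(chromseq, lo, hi))
  }
  if (!is.null(edit)) {
    p <- edit$pos; r <- nchar(edit$ref)
    if (p >= lo && p <= hi) {
      if (p + r - 1L > hi) {
        abort("variant reference allele extends beyond the exon/intron block")
      }
      off <- p - lo + 1L
      raw <- paste0(substr(raw, 1L, off - 1L), edit$alt,
                    substr(raw, off + r, nchar(raw)))
    }
  }
  n <- nchar(raw)
  if (which == "left") {
    if (n >= s$len) substr(raw, n - s$len + 1L, n)
    else paste0(strrep("N", s$len - n), raw)
  } else {
    if (n >= s$len) substr(raw, 1L, s$len)
    else paste0(raw, strrep("N", s$len - n))
  }
}

extract_block <- function(chromseq, geom, strand, edits = list()) {
  left_edit <- NULL; right_edit <- NULL
  for (e in edits) {
    if (edit_hits_side(e, geom$left, "left")) left_edit <- e
    if (edit_hits_side(e, geom$right, "right")) right_edit <- e
  }
  blk <- paste0(
    extract_side(chromseq, geom$left, "left", left_edit),
    extract_side(chromseq, geom$right, "right", right_edit)
  )
  if (strand == "-") revcomp(blk) else blk
}

# a variant touches a side if its reference interval intersects the side's
# nominal (unclipped) window
edit_hits_side <- function(e, s, which) {
  span <- if (which == "left") c(s$near - s$len + 1L, s$near)
          else c(s$near, s$near + s$len - 1L)
  r <- nchar(e$ref)
  e$pos <= span[2L] && (e$pos + r - 1L) >= span[1L]
}

#' Extract the 400-base junction-flank sequence of one exon triplet
#'
#' @param triplet One row of the index from [build_triplet_index()] (or any
#'   list with the same fields).
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @return A list of class `triplet_sequence`: `triplet_id`, `blocks` (named
#'   character vector `UI1`, `I1X`, `XI2`, `I2D`, each 100 bases) and
#'   `sequence` (their 400-base concatenation, transcript orientation).
#' @export
extract_triplet_sequence <- function(triplet, genome) {
  genome <- as_genome(genome)
  t <- as.list(triplet)
  if (!t$chrom %in% names(genome)) {
    abort(sprintf("chromosome '%s' not present in the genome", t$chrom))
  }
  chromseq <- genome[[t$chrom]]
  geoms <- block_geometry(t)
  blocks <- vapply(geoms, extract_block, "", chromseq = chromseq,
                   strand = t$strand)
  names(blocks) <- BLOCK_NAMES
  if (any(nchar(blocks) != 100L)) abort("internal error: block length != 100")
  pad <- sum(vapply(blocks, function(b)
    sum(strsplit(b, "")[[1]] == "N"), 0))
  if (pad > 0L) {
    warning(sprintf("triplet %s: %d positions padded with N (short exon or intron)",
                    t$triplet_id %||% "?", pad), call. = FALSE)
  }
  structure(
    list(triplet_id = t$triplet_id %||% NA_character_,
         blocks = blocks,
         sequence = paste(blocks, collapse = "")),
    class = "triplet_sequence"
  )
}

#' Extract sequences for every triplet in an index
#'
#' @param index Output of [build_triplet_index()].
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @return A `data.frame` with columns `triplet_id` and `sequence`.
#' @export
extract_triplet_sequences <- function(index, genome) {
  genome <- as_genome(genome)
  seqs <- vapply(seq_len(nrow(index)), function(i) {
    extract_triplet_sequence(index[i, ], genome)$sequence
  }, "")
  data.frame(triplet_id = index$triplet_id, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Apply a variant to a triplet's junction-flank sequence
#'
#' Substitutions replace the affected base(s) in place (complemented through
#' the reverse-complement on minus-strand triplets, since VCF alleles are
#' plus-strand).  Indels re-extract the affected block side anchored at its
#' splice junction, so every block stays 100 bases and bases slide in from
#' the end farthest from the junction.
#'
#' @param seq A `triplet_sequence` from [extract_triplet_sequence()].
#' @param triplet The matching index row.
#' @param variant A list or one-row data.frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param genome The genome the sequence was extracted from.
#' @return A new `triplet_sequence`.  If the variant touches none of the four
#'   100-base windows the input is returned unchanged with a warning.
#' @export
apply_variant <- function(seq, triplet, variant, genome) {
  genome <- as_genome(genome)
  t <- as.list(triplet)
  v <- as.list(variant)
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  if (!grepl("^[ACGT]+$", v$ref) || !grepl("^[ACGT]+$", v$alt)) {
    abort("variant ref/alt must be non-empty strings over {A,C,G,T}")
  }
  if (!identical(as.character(v$chrom), as.character(t$chrom))) {
    warning("variant is on a different chromosome; sequence unchanged",
            call. = FALSE)
    return(seq)
  }
  chromseq <- genome[[t$chrom]]
  gref <- as.character(Biostrings::subseq(chromseq, v$pos,
                                          v$pos + nchar(v$ref) - 1L))
  if (!identical(toupper(gref), v$ref)) {
    abort(sprintf("reference allele mismatch at %s:%d: genome has '%s', variant says '%s'",
                  t$chrom, v$pos, gref, v$ref))
  }
  geoms <- block_geometry(t)
  hit <- vapply(geoms, function(g) {
    edit_hits_side(v, g$left, "left") || edit_hits_side(v, g$right, "right")
  }, NA)
  if (!any(hit)) {
    warning("variant outside all four junction windows; sequence unchanged",
            call. = FALSE)
    return(seq)
  }
  blocks <- seq$blocks
  for (b in BLOCK_NAMES[hit]) {
    blocks[[b]] <- extract_block(chromseq, geoms[[b]], t$strand,
                                 edits = list(v))
  }
  structure(
    list(triplet_id = seq$triplet_id, blocks = blocks,
         sequence = paste(blocks, collapse = "")),
    class = "triplet_sequence"
  )
}

#' @export
print.triplet_sequence <- function(x, ...) {
  cat("<triplet_sequence>", x$triplet_id, "\n")
  for (b in BLOCK_NAMES) cat(sprintf("  %s %s\n", b, x$blocks[[b]]))
  invisible(x)
}
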