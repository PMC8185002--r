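# Rescue triage of splice-disrupting variants ---------------------------------

RESCUE_CATEGORIES <- c("skipping_rescued_by_inclusion",
                       "inclusion_rescued_by_exclusion",
                       "ptc_rescued_by_frame_preserving_skip",
                       "none")

#' Keep splice-altering effect records
#'
#' A record is splice-altering when its score is no less than `threshold`
#' (default 0.2).
#'
#' @param effects Splice-effect table (see [read_splice_effects()]).
#' @param threshold Minimum score (kept when `score >= threshold`).
#' @return The filtered table.
#' @export
filter_splice_altering <- function(effects, threshold = 0.2) {
  effects <- validate_splice_effects(effects)
  effects[effects$score >= threshold, , drop = FALSE]
}

#' Classify the splicing consequence of an effect record on one triplet
#'
#' A *gain* at either domain of the middle exon (its acceptor or donor
#' coordinate) promotes exon inclusion; a *loss* at the middle exon's 5'
#' splice site (donor) causes exon skipping.  Junction matching is exact
#' coordinate equality, with an optional tolerance.
#'
#' @param effect One effect record (list/one-row data.frame with `isj`,
#'   `effect`).
#' @param triplet One triplet index row.
#' @param tolerance Matching tolerance in bases (default 0 = exact).
#' @return A list: `consequence` (`exon_skipping`, `promoted_inclusion` or
#'   `none`) and `junction` (`middle_donor`, `middle_acceptor` or `NA`).
#' @export
classify_consequence <- function(effect, triplet, tolerance = 0) {
  e <- as.list(effect); t <- as.list(triplet)
  near <- function(a, b) abs(a - b) <= tolerance
  at_donor <- near(e$isj, t$donor2)
  at_acceptor <- near(e$isj, t$acceptor2)
  if (e$effect == "gain" && (at_donor || at_acceptor)) {
    return(list(consequence = "promoted_inclusion",
                junction = if (at_donor) "middle_donor" else "middle_acceptor"))
  }
  if (e$effect == "loss" && at_donor) {
    return(list(consequence = "exon_skipping", junction = "middle_donor"))
  }
  # a loss at the middle-exon acceptor is not covered by either rule and is
  # reported as none (flagged by the junction field)
  list(consequence = "none",
       junction = if (at_acceptor) "middle_acceptor" else
                  if (at_donor) "middle_donor" else NA_character_)
}

#' Premature-termination-codon and reading-frame flags
#'
#' Translates the middle exon (in transcript orientation, starting at its
#' `frame` offset) before and after applying the variant; `creates_ptc` is
#' true when the mutated exon has an in-frame stop codon at a position where
#' the reference has none.  `frame_preserving_skip` is true when the middle
#' exon's length is divisible by 3 (skipping it keeps the reading frame).
#'
#' @param triplet One triplet index row.
#' @param variant Variant record (`chrom`, `pos`, `ref`, `alt`).
#' @param genome Genome the triplet lives on.
#' @param frame Coding frame offset of the middle exon: number of bases that
#'   complete the codon begun in the previous exon (0, 1 or 2).
#' @return A list: `creates_ptc`, `frame_preserving_skip`.
#' @export
detect_ptc <- function(triplet, variant, genome, frame = 0) {
  genome <- as_genome(genome)
  t <- as.list(triplet); v <- as.list(variant)
  chromseq <- genome[[t$chrom]]
  ref_exon <- as.character(Biostrings::subseq(chromseq, t$exon2_start,
                                              t$exon2_end))
  mut_exon <- ref_exon
  if (identical(as.character(v$chrom), as.character(t$chrom)) &&
      v$pos >= t$exon2_start && v$pos + nchar(v$ref) - 1L <= t$exon2_end) {
    off <- v$pos - t$exon2_start + 1L
    gref <- substr(ref_exon, off, off + nchar(v$ref) - 1L)
    if (!identical(toupper(gref), toupper(v$ref))) {
      abort("reference allele mismatch inside the middle exon")
    }
    mut_exon <- paste0(substr(ref_exon, 1L, off - 1L), v$alt,
                       substr(ref_exon, off + nchar(v$ref),
                              nchar(ref_exon)))
  }
  if (t$strand == "-") {
    ref_exon <- revcomp(ref_exon)
    mut_exon <- revcomp(mut_exon)
  }
  stops_at <- function(s) {
    if (nchar(s) < frame + 3L) return(integer(0))
    starts <- seq(frame + 1L, nchar(s) - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    which(codons %in% c("TAA", "TAG", "TGA"))
  }
  new_stop <- length(setdiff(stops_at(mut_exon), stops_at(ref_exon))) > 0
  exon_len <- t$exon2_end - t$exon2_start + 1L
  list(creates_ptc = new_stop,
       frame_preserving_skip = exon_len %% 3L == 0L)
}

#' Apply the three rescue rules
#'
#' Rule 1: predicted exon skipping + predicted inclusion response.  Rule 2:
#' predicted promoted inclusion + predicted exclusion response.  Rule 3:
#' PTC created inside the middle exon + predicted exclusion response + frame
#' preserved on skipping.  Rules are evaluated in order; the first match
#' wins.
#'
#' @param consequence `exon_skipping`, `promoted_inclusion`, or `none`.
#' @param creates_ptc,frame_preserving_skip Flags from [detect_ptc()].
#' @param response Predicted drug response class of the mutant sequence.
#' @return One of `r paste(RESCUE_CATEGORIES, collapse = ", ")`.
#' @export
call_rescue <- function(consequence, creates_ptc, frame_preserving_skip,
                        response) {
  if (consequence == "exon_skipping" && response == "inclusion") {
    return("skipping_rescued_by_inclusion")
  }
  if (consequence == "promoted_inclusion" && response == "exclusion") {
    return("inclusion_rescued_by_exclusion")
  }
  if (isTRUE(creates_ptc) && response == "exclusion" &&
      isTRUE(frame_preserving_skip)) {
    return("ptc_rescued_by_frame_preserving_skip")
  }
  "none"
}

#' Annotate variants with gnomAD-style allele frequencies
#'
#' Variants found only in the exome (or only in the genome) table take that
#' frequency; variants in both take the maximum; variants in neither are
#' `NA`.
#'
#' @param variants Variant table with `chrom`, `pos`, `ref`, `alt`.
#' @param exome,genome_af Allele-frequency tables (`chrom`, `pos`, `ref`,
#'   `alt`, `af`), e.g. from [read_af_vcf()], or VCF paths.
#' @return `variants` with an added `af` column.
#' @export
annotate_allele_frequency <- function(variants, exome, genome_af) {
  as_af <- function(x) {
    if (is.character(x) && length(x) == 1L) read_af_vcf(x) else x
  }
  exome <- as_af(exome); genome_af <- as_af(genome_af)
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  ke <- key(exome); kg <- key(genome_af); kv <- key(variants)
  af_e <- exome$af[match(kv, ke)]
  af_g <- genome_af$af[match(kv, kg)]
  variants$af <- pmax(af_e, af_g, na.rm = TRUE)
  variants$af[is.na(af_e) & is.na(af_g)] <- NA_real_
  variants
}

#' Run the full rescue-triage pipeline
#'
#' Filters effect records at the splice-altering threshold, maps each to the
#' exon triplets whose middle-exon junctions the influenced splice junction
#' hits, applies the variant to the triplet sequence, predicts the mutant's
#' drug response (standardized probabilities), classifies the mutational
#' splicing consequence, evaluates the PTC/frame flags, applies the rescue
#' rules, and annotates allele frequencies.  A variant mapping to several
#' triplets is evaluated once per triplet.
#'
#' @param variants Variant table (`chrom`, `pos`, `id`, `ref`, `alt`).
#' @param effects Splice-effect table (see [read_splice_effects()]).
#' @param index Triplet index.
#' @param genome Genome (DNAStringSet or FASTA path).
#' @param model A trained `splice_cnn` (its `cutoffs` are used), or a
#'   function taking a character vector of mutant 400-base sequences and
#'   returning an `N x 3` score matrix (columns inclusion, exclusion,
#'   unchanged) — useful for audits with a controlled predictor.
#' @param cutoffs Per-class score cutoffs; defaults to `model$cutoffs` or
#'   uniform 0.5 for function predictors.
#' @param frames Named numeric vector of middle-exon frame offsets per
#'   triplet_id (default 0 for all).
#' @param threshold Splice-altering score threshold (default 0.2).
#' @param af_exome,af_genome Optional allele-frequency tables or VCF paths.
#' @return A `data.frame`, one row per (variant, triplet): identifiers,
#'   effect fields, predicted response and standardized probabilities,
#'   consequence, PTC flags, `rescue` category, and `af` when frequency
#'   tables were supplied.
#' @export
run_target_pipeline <- function(variants, effects, index, genome, model,
                                cutoffs = NULL, frames = NULL,
                                threshold = 0.2, af_exome = NULL,
                                af_genome = NULL) {
  genome <- as_genome(genome)
  effects <- filter_splice_altering(effects, threshold)
  if (is.null(cutoffs)) {
    cutoffs <- if (!is.function(model) && !is.null(model$cutoffs))
      model$cutoffs else rep(0.5, 3L)
  }
  predictor <- if (is.function(model)) model else
    function(seqs) predict_cnn(model, seqs)
  if (!is.null(af_exome) && !is.null(af_genome)) {
    variants <- annotate_allele_frequency(variants, af_exome, af_genome)
  }
  rows <- list()
  for (i in seq_len(nrow(effects))) {
    e <- effects[i, ]
    v <- variants[match(e$variant_id, variants$id), ]
    if (nrow(v) == 0L || is.na(v$chrom[1L])) next
    hits <- which(index$chrom == e$chrom &
                    (index$acceptor2 == e$isj | index$donor2 == e$isj))
    if (length(hits) == 0L) {
      rows[[length(rows) + 1L]] <- pipeline_row(e, v, NA_character_, "none",
                                                NA, NA, rep(NA_real_, 3L),
                                                NA_character_, "none")
      next
    }
    for (h in hits) {
      trip <- index[h, ]
      ref_seq <- extract_triplet_sequence(trip, genome)
      mut_seq <- suppressWarnings(
        apply_variant(ref_seq, trip, v, genome))
      scores <- predictor(mut_seq$sequence)
      probs <- standardize_probability(as.numeric(scores), cutoffs)
      response <- RESPONSE_CLASSES[which.max(probs)]
      cons <- classify_consequence(e, trip)
      frame <- if (!is.null(frames) && trip$triplet_id %in% names(frames))
        frames[[trip$triplet_id]] else 0
      ptc <- detect_ptc(trip, v, genome, frame = frame)
      rescue <- call_rescue(cons$consequence, ptc$creates_ptc,
                            ptc$frame_preserving_skip, response)
      rows[[length(rows) + 1L]] <- pipeline_row(
        e, v, trip$triplet_id, cons$consequence, ptc$creates_ptc,
        ptc$frame_preserving_skip, probs, response, rescue,
        junction = cons$junction)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out)) {
    out <- pipeline_row(effects[0, ], variants[0, ], character(0),
                        character(0), logical(0), logical(0),
                        matrix(numeric(0), 0, 3), character(0), character(0))
  }
  rownames(out) <- NULL
  out
}

pipeline_row <- function(e, v, triplet_id, consequence, creates_ptc,
                         frame_preserving, probs, response, rescue,
                         junction = NA_character_) {
  if (is.null(dim(probs))) probs <- matrix(probs, ncol = 3L)
  data.frame(
    variant_id = e$variant_id, chrom = e$chrom, pos = e$pos,
    ref = e$ref, alt = e$alt, isj = e$isj, effect = e$effect,
    score = e$score,
    triplet_id = triplet_id,
    junction = junction,
    consequence = consequence,
    creates_ptc = creates_ptc,
    frame_preserving_skip = frame_preserving,
    p_inclusion = probs[, 1L], p_exclusion = probs[, 2L],
    p_unchanged = probs[, 3L],
    response = response,
    rescue = rescue,
    af = if (!is.null(v$af)) v$af else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Filter triplets suitable for minigene validation
#'
#' Keeps triplets whose total genomic span (introns included) is below
#' `max_genomic_length` and whose splicing call is a detectable response
#' (inclusion or exclusion).  Minigene recapitulation of the endogenous
#' splicing change is an experimental criterion and is carried only as the
#' `minigene_recapitulates` annotation column (`NA` until filled in by hand).
#'
#' @param index Triplet index.
#' @param calls Splicing calls from [quantify()].
#' @param max_genomic_length Maximum span in bases (default 1500; strict
#'   less-than).
#' @return The candidate subset of `index`, with `span`, `class` and
#'   `minigene_recapitulates` columns added.
#' @export
minigene_candidate_filter <- function(index, calls,
                                      max_genomic_length = 1500) {
  span <- pmax(index$exon1_end, index$exon3_end) -
    pmin(index$exon1_start, index$exon3_start) + 1L
  cls <- calls$class[match(index$triplet_id, calls$triplet_id)]
  keep <- span < max_genomic_length & !is.na(cls) &
    cls %in% c("inclusion", "exclusion")
  out <- index[keep, , drop = FALSE]
  out$span <- span[keep]
  out$class <- cls[keep]
  out$minigene_recapitulates <- NA
  rownames(out) <- NULL
  out
}
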