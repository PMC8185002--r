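# Synthetic data generation --------------------------------------------------
#
# Emulates the study design the quantification and classifier modules expect:
# paired treated/control junction counts over biological replicates (distinct
# cell lines), triplet loci whose treatment-response class is encoded by a
# 5-mer planted near the middle exon's 5' splice site, and toy
# variant / splice-effect / allele-frequency fixtures for the rescue workflow.

#' Simulation configuration
#'
#' @param n_inclusion,n_exclusion,n_unchanged Triplets per response class.
#' @param n_replicates Biological replicates per condition (default 6,
#'   mirroring six fibroblast lines; replicate i is the same line in both
#'   conditions and shares a line-specific coverage multiplier).
#' @param mu Mean informative reads per triplet per replicate.
#' @param dispersion Negative-binomial size parameter of the coverage model
#'   (smaller = more overdispersed biological replicates).
#' @param line_sd Standard deviation of the log-normal line-specific coverage
#'   multiplier.
#' @param psi_responsive,psi_unchanged Ranges the baseline (control) psi is
#'   drawn from, for responsive and unchanged triplets.
#' @param dpsi_inclusion,dpsi_exclusion Treatment effects on psi for the two
#'   responsive classes (clamped so psi stays in \[0, 1\]).
#' @param composition Background nucleotide probabilities (A, C, G, T).
#' @param motif_inclusion,motif_exclusion Class 5-mers planted near the
#'   middle-exon donor.  They must be consistent with the canonical `GT`
#'   intron start wherever they overlap it; the defaults begin with `GT` so
#'   two plant offsets are available.  Unchanged triplets get no motif.
#' @param motif_window Offset window (relative to the donor; negative =
#'   exonic, positive = intronic, no position 0) the planted 5-mer must lie
#'   in.  Default -3..+7.
#' @param exon_length,intron_length Locus geometry of simulated triplets.
#' @param strands Strands to alternate simulated loci over.
#' @param seed Integer seed; fully determines all outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_inclusion = 300, n_exclusion = 300,
                       n_unchanged = 300, n_replicates = 6,
                       mu = 100, dispersion = 10, line_sd = 0.3,
                       psi_responsive = c(0.25, 0.75),
                       psi_unchanged = c(0.15, 0.85),
                       dpsi_inclusion = 0.15, dpsi_exclusion = -0.15,
                       composition = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25),
                       motif_inclusion = "GTAAG",
                       motif_exclusion = "GTCCT",
                       motif_window = c(-3, 7),
                       exon_length = 120, intron_length = 300,
                       strands = c("+", "-"),
                       seed = 1) {
  check_scalar_number(mu, "mu"); check_scalar_number(dispersion, "dispersion")
  if (mu <= 0) abort("'mu' must be positive")
  if (dispersion <= 0) abort("'dispersion' must be positive")
  if (abs(dpsi_inclusion) <= 0.1 || abs(dpsi_exclusion) <= 0.1) {
    abort("responsive effect sizes must exceed the 0.1 calling threshold")
  }
  if (max(psi_responsive) + dpsi_inclusion > 1 ||
      min(psi_responsive) + dpsi_exclusion < 0) {
    abort("baseline psi range plus effect size leaves [0, 1]")
  }
  if (identical(motif_inclusion, motif_exclusion)) {
    abort("class motifs must be disjoint")
  }
  composition <- composition / sum(composition)
  cfg <- list(
    n_inclusion = n_inclusion, n_exclusion = n_exclusion,
    n_unchanged = n_unchanged, n_replicates = n_replicates,
    mu = mu, dispersion = dispersion, line_sd = line_sd,
    psi_responsive = psi_responsive, psi_unchanged = psi_unchanged,
    dpsi_inclusion = dpsi_inclusion, dpsi_exclusion = dpsi_exclusion,
    composition = composition,
    motif_inclusion = toupper(motif_inclusion),
    motif_exclusion = toupper(motif_exclusion),
    motif_window = motif_window,
    exon_length = exon_length, intron_length = intron_length,
    strands = strands, seed = seed
  )
  class(cfg) <- "sim_config"
  # planting must be possible somewhere inside the window
  for (m in c(cfg$motif_inclusion, cfg$motif_exclusion)) {
    if (length(allowed_plant_starts(m, cfg$motif_window)) == 0L) {
      abort(sprintf(
        "motif '%s' cannot be planted inside window [%d, %d] without breaking the canonical GT donor",
        m, cfg$motif_window[1L], cfg$motif_window[2L]))
    }
  }
  cfg
}

sim_classes <- function(config) {
  rep(c("inclusion", "exclusion", "unchanged"),
      c(config$n_inclusion, config$n_exclusion, config$n_unchanged))
}

#' Simulate a junction read-count table with known treatment effects
#'
#' Per replicate and condition the informative read total `T` is drawn from a
#' negative binomial with line-scaled mean, the inclusion half-count
#' `H ~ Binomial(T, psi)`, the skipping count `R3 = T - H`, and the two
#' inclusion junction counts split `2H` as `R1 ~ Binomial(2H, 0.5)`,
#' `R2 = 2H - R1`.  With this construction `0.5 (R1 + R2) = H`, so the psi
#' estimator is exactly `H / (H + R3)` and unbiased for the true psi.
#'
#' @param config A [sim_config()].
#' @return A list: `counts` (junction-count table) and `truth` (per triplet:
#'   true control/treated psi and class label).
#' @export
simulate_junction_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    classes <- sim_classes(config)
    n <- length(classes)
    ids <- sprintf("SIM%05d", seq_len(n))
    psi0 <- ifelse(classes == "unchanged",
                   runif(n, config$psi_unchanged[1L], config$psi_unchanged[2L]),
                   runif(n, config$psi_responsive[1L],
                         config$psi_responsive[2L]))
    effect <- c(inclusion = config$dpsi_inclusion,
                exclusion = config$dpsi_exclusion,
                unchanged = 0)[classes]
    psi1 <- pmin(1, pmax(0, psi0 + effect))
    truth <- data.frame(triplet_id = ids, class = classes,
                        psi_control = psi0, psi_treated = psi1,
                        stringsAsFactors = FALSE)
    reps <- seq_len(config$n_replicates)
    grid <- expand.grid(rep = reps, cond = c("control", "treated"),
                        idx = seq_len(n), stringsAsFactors = FALSE)
    # line-specific multiplier shared by the two conditions of a replicate
    mult <- matrix(exp(rnorm(n * config$n_replicates, 0,
                             config$line_sd)),
                   nrow = n)
    psi <- ifelse(grid$cond == "treated", psi1[grid$idx], psi0[grid$idx])
    m <- config$mu * mult[cbind(grid$idx, grid$rep)]
    total <- rnbinom(nrow(grid), mu = m, size = config$dispersion)
    h <- rbinom(nrow(grid), total, psi)
    r3 <- total - h
    r1 <- rbinom(nrow(grid), 2L * h, 0.5)
    r2 <- 2L * h - r1
    counts <- data.frame(
      triplet_id = ids[grid$idx],
      sample = paste0("line", grid$rep),
      condition = grid$cond,
      R1 = r1, R2 = r2, R3 = r3,
      stringsAsFactors = FALSE
    )
    list(counts = counts, truth = truth)
  })
}

# Plant start offsets (relative to the donor: ..,-2,-1 exonic; +1,.. intronic,
# no zero) at which a motif fits in the window and agrees with the canonical
# GT at +1,+2 wherever it overlaps them.
allowed_plant_starts <- function(motif, window) {
  k <- nchar(motif)
  rel_positions <- function(s) {
    p <- s + 0:(k - 1L)
    ifelse(s < 0L & p >= 0L, p + 1L, p)  # skip the non-existent position 0
  }
  starts <- setdiff(seq(window[1L], window[2L]), 0L)
  keep <- vapply(starts, function(s) {
    p <- rel_positions(s)
    if (max(p) > window[2L]) return(FALSE)
    chars <- strsplit(motif, "")[[1L]]
    ok <- TRUE
    for (j in seq_len(k)) {
      if (p[j] == 1L && chars[j] != "G") ok <- FALSE
      if (p[j] == 2L && chars[j] != "T") ok <- FALSE
    }
    ok
  }, NA)
  starts[keep]
}

# One simulated locus in transcript orientation: margin-exon-intron-exon-
# intron-exon-margin, canonical GT/AG stamped at intron ends, optional motif
# planted at `plant_start` (relative to the middle-exon donor).
make_sim_locus <- function(exon_lens, intron_lens, margin, composition,
                           motif = NULL, plant_start = NULL,
                           ptc_codon_at = NULL) {
  len <- 2L * margin + sum(exon_lens) + sum(intron_lens)
  bases <- sample(names(composition), len, replace = TRUE,
                  prob = composition)
  e1s <- margin + 1L; e1e <- e1s + exon_lens[1L] - 1L
  i1s <- e1e + 1L; i1e <- i1s + intron_lens[1L] - 1L
  e2s <- i1e + 1L; e2e <- e2s + exon_lens[2L] - 1L
  i2s <- e2e + 1L; i2e <- i2s + intron_lens[2L] - 1L
  e3s <- i2e + 1L; e3e <- e3s + exon_lens[3L] - 1L
  bases[c(i1s, i2s)] <- "G"; bases[c(i1s + 1L, i2s + 1L)] <- "T"
  bases[c(i1e - 1L, i2e - 1L)] <- "A"; bases[c(i1e, i2e)] <- "G"
  if (!is.null(ptc_codon_at)) {
    # reference codon TGG in frame inside the middle exon; a G>A SNV at its
    # third base creates the TGA stop
    pos <- e2s + ptc_codon_at - 1L
    bases[pos + 0:2] <- c("T", "G", "G")
  }
  if (!is.null(motif)) {
    s <- plant_start
    g0 <- if (s >= 1L) e2e + s else e2e + s + 1L
    chars <- strsplit(motif, "")[[1L]]
    bases[g0 + seq_along(chars) - 1L] <- chars
  }
  list(seq = paste(bases, collapse = ""),
       exons = rbind(c(e1s, e1e), c(e2s, e2e), c(e3s, e3e)),
       length = len)
}

#' Simulate triplet loci with class-determining planted 5-mers
#'
#' Builds one toy locus per triplet (its own chromosome), stamps canonical
#' `GT`/`AG` at both intron ends, plants the class 5-mer at a random
#' GT-compatible offset inside `motif_window` around the middle-exon donor
#' for responsive classes (unchanged triplets get none), and runs the real
#' indexing and extraction path ([build_triplet_index()],
#' [extract_triplet_sequences()]) on the result.  Loci alternate over
#' `config$strands`; minus-strand chromosomes store the reverse complement,
#' so extraction must recover the identical transcript-orientation sequence.
#'
#' @param config A [sim_config()].
#' @return A list: `genome` (DNAStringSet), `index` (triplet index),
#'   `sequences` (data.frame `triplet_id`, `sequence`, `class`), and `truth`
#'   (per triplet: class, planted motif and offset or `NA`).
#' @export
simulate_triplet_sequences <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    classes <- sim_classes(config)
    n <- length(classes)
    chroms <- sprintf("sim%05d", seq_len(n))
    strands <- rep_len(config$strands, n)
    motifs <- c(inclusion = config$motif_inclusion,
                exclusion = config$motif_exclusion,
                unchanged = NA_character_)[classes]
    seqs <- character(n)
    exdf <- vector("list", n)
    offs <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      motif <- if (is.na(motifs[i])) NULL else motifs[i]
      plant <- NULL
      if (!is.null(motif)) {
        ok <- allowed_plant_starts(motif, config$motif_window)
        plant <- if (length(ok) == 1L) ok else sample(ok, 1L)
        offs[i] <- plant
      }
      loc <- make_sim_locus(rep(config$exon_length, 3L),
                            rep(config$intron_length, 2L), 50L,
                            config$composition, motif, plant)
      if (strands[i] == "-") {
        seqs[i] <- revcomp(loc$seq)
        ex <- loc$length - loc$exons + 1L
        ex <- cbind(ex[, 2L], ex[, 1L])
      } else {
        ex <- loc$exons
      }
      exdf[[i]] <- data.frame(
        chrom = chroms[i], start = ex[, 1L], end = ex[, 2L],
        strand = strands[i],
        gene_id = paste0("G", chroms[i]),
        transcript_id = paste0("T", chroms[i]),
        stringsAsFactors = FALSE
      )
      if (strands[i] == "+") seqs[i] <- loc$seq
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms
    ann <- do.call(rbind, exdf)
    gr <- GenomicRanges::GRanges(
      seqnames = ann$chrom,
      ranges = IRanges::IRanges(ann$start, ann$end),
      strand = ann$strand, type = "exon",
      gene_id = ann$gene_id, transcript_id = ann$transcript_id
    )
    index <- build_triplet_index(gr)
    # recover class/truth by chromosome
    cls <- classes[match(index$chrom, chroms)]
    truth <- data.frame(
      triplet_id = index$triplet_id,
      chrom = index$chrom,
      class = cls,
      motif = motifs[match(index$chrom, chroms)],
      offset = offs[match(index$chrom, chroms)],
      stringsAsFactors = FALSE
    )
    sequences <- extract_triplet_sequences(index, genome)
    sequences$class <- cls
    list(genome = genome, index = index, sequences = sequences,
         truth = truth)
  })
}

#' Simulate variant / splice-effect / allele-frequency fixtures
#'
#' Emits a small set of dedicated plus-strand loci with variants planted at
#' triplet junctions so every rescue rule is exercised with known truth:
#' donor-loss SNVs (above and below the 0.2 splice-altering threshold),
#' acceptor-gain SNVs, and PTC-creating middle-exon SNVs for exon lengths
#' both divisible and not divisible by 3.  Each locus also carries the class
#' 5-mer matching the drug response its rescue rule requires, so a classifier
#' trained on [simulate_triplet_sequences()] output predicts the planted
#' response.  Allele-frequency VCF pairs cover exome-only, genome-only, and
#' both-with-different-AF variants.
#'
#' @param config A [sim_config()].
#' @param n_donor_loss,n_subthreshold,n_gain,n_ptc_frame,n_ptc_shift Number
#'   of planted cases per category.
#' @param loss_score,sub_score,gain_score Splice-effect scores used.
#' @return A list: `genome`, `index`, `variants`, `effects`, `af_exome`,
#'   `af_genome` (data.frames), and `truth` (variant_id, category, matched
#'   triplet, planted response, expected rescue rule).
#' @export
simulate_variant_fixtures <- function(config, n_donor_loss = 3,
                                      n_subthreshold = 2, n_gain = 2,
                                      n_ptc_frame = 2, n_ptc_shift = 1,
                                      loss_score = 0.5, sub_score = 0.15,
                                      gain_score = 0.3) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 2L, {
    cats <- rep(c("donor_loss", "subthreshold", "gain", "ptc_frame",
                  "ptc_shift"),
                c(n_donor_loss, n_subthreshold, n_gain, n_ptc_frame,
                  n_ptc_shift))
    n <- length(cats)
    chroms <- sprintf("fix%03d", seq_len(n))
    seqs <- character(n)
    exlist <- vector("list", n)
    vrows <- list(); erows <- list(); trows <- list()
    for (i in seq_len(n)) {
      cat_i <- cats[i]
      e2len <- switch(cat_i, ptc_frame = 84L, ptc_shift = 85L,
                      as.integer(config$exon_length))
      # response motif the rescue rule needs: rule 1 wants inclusion,
      # rules 2/3 want exclusion; subthreshold cases get inclusion too
      motif <- if (cat_i %in% c("donor_loss", "subthreshold"))
        config$motif_inclusion else config$motif_exclusion
      ptc_at <- if (cat_i %in% c("ptc_frame", "ptc_shift")) 31L else NULL
      loc <- make_sim_locus(c(config$exon_length, e2len,
                              config$exon_length),
                            rep(config$intron_length, 2L), 50L,
                            config$composition, motif, plant_start = 3L,
                            ptc_codon_at = ptc_at)
      seqs[i] <- loc$seq
      ex <- loc$exons
      exlist[[i]] <- data.frame(
        chrom = chroms[i], start = ex[, 1L], end = ex[, 2L], strand = "+",
        gene_id = paste0("G", chroms[i]),
        transcript_id = paste0("T", chroms[i]), stringsAsFactors = FALSE
      )
      donor2 <- ex[2L, 2L]; acceptor2 <- ex[2L, 1L]
      vid <- paste0("var", i)
      base_at <- function(p) substr(loc$seq, p, p)
      if (cat_i %in% c("donor_loss", "subthreshold")) {
        pos <- donor2 + 1L            # the G of the canonical GT
        ref <- "G"; alt <- "A"
        isj <- donor2; eff <- "loss"
        score <- if (cat_i == "donor_loss") loss_score else sub_score
        rule <- if (cat_i == "donor_loss") "skipping_rescued_by_inclusion"
                else "none"
        response <- "inclusion"
      } else if (cat_i == "gain") {
        pos <- acceptor2 - 5L          # intronic, near the 3' splice site
        ref <- base_at(pos)
        alt <- setdiff(c("A", "C", "G", "T"), ref)[1L]
        isj <- acceptor2; eff <- "gain"; score <- gain_score
        rule <- "inclusion_rescued_by_exclusion"
        response <- "exclusion"
      } else {
        pos <- acceptor2 + 32L         # third base of the planted TGG codon
        ref <- "G"; alt <- "A"         # TGG -> TGA stop, in frame
        isj <- donor2; eff <- "loss"; score <- loss_score
        # PTC cases are matched to the triplet but classified by frame:
        rule <- if (cat_i == "ptc_frame") "ptc_rescued_by_frame_preserving_skip"
                else "none"
        response <- "exclusion"
      }
      vrows[[i]] <- data.frame(chrom = chroms[i], pos = pos, id = vid,
                               ref = ref, alt = alt,
                               significance = "Pathogenic",
                               stringsAsFactors = FALSE)
      erows[[i]] <- data.frame(variant_id = vid, chrom = chroms[i],
                               pos = pos, ref = ref, alt = alt, isj = isj,
                               effect = eff, score = score,
                               stringsAsFactors = FALSE)
      trows[[i]] <- data.frame(variant_id = vid, category = cat_i,
                               chrom = chroms[i],
                               planted_response = response,
                               expected_rule = rule,
                               stringsAsFactors = FALSE)
    }
    genome <- Biostrings::DNAStringSet(seqs)
    names(genome) <- chroms
    ann <- do.call(rbind, exlist)
    gr <- GenomicRanges::GRanges(
      seqnames = ann$chrom, ranges = IRanges::IRanges(ann$start, ann$end),
      strand = ann$strand, type = "exon", gene_id = ann$gene_id,
      transcript_id = ann$transcript_id
    )
    index <- build_triplet_index(gr)
    variants <- do.call(rbind, vrows)
    effects <- do.call(rbind, erows)
    truth <- do.call(rbind, trows)
    truth$triplet_id <- index$triplet_id[match(truth$chrom, index$chrom)]
    # allele-frequency fixtures: exome-only, genome-only, both (max applies)
    k <- min(3L, nrow(variants))
    af_exome <- variants[seq_len(k), c("chrom", "pos", "ref", "alt")]
    af_exome$af <- c(8.28e-4, NA, 1e-4)[seq_len(k)]
    af_exome <- af_exome[!is.na(af_exome$af), , drop = FALSE]
    af_genome <- variants[seq_len(k), c("chrom", "pos", "ref", "alt")]
    af_genome$af <- c(NA, 5e-5, 2e-4)[seq_len(k)]
    af_genome <- af_genome[!is.na(af_genome$af), , drop = FALSE]
    list(genome = genome, index = index, variants = variants,
         effects = effects, af_exome = af_exome, af_genome = af_genome,
         truth = truth)
  })
}

#' Write simulated inputs to standard formats
#'
#' @param sim Output of [simulate_triplet_sequences()] or
#'   [simulate_variant_fixtures()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             gtf = file.path(dir, "annotation.gtf"))
  Biostrings::writeXStringSet(sim$genome, paths[["fasta"]])
  write_triplet_gtf(sim$index, paths[["gtf"]])
  if (!is.null(sim$variants)) {
    paths[["vcf"]] <- file.path(dir, "variants.vcf")
    write_minimal_vcf(sim$variants, paths[["vcf"]])
    paths[["effects"]] <- file.path(dir, "splice_effects.tsv")
    write_results(sim$effects, paths[["effects"]])
    paths[["af_exome"]] <- file.path(dir, "af_exome.vcf")
    write_minimal_vcf(cbind(sim$af_exome, id = "."),
                      paths[["af_exome"]], af = sim$af_exome$af)
    paths[["af_genome"]] <- file.path(dir, "af_genome.vcf")
    write_minimal_vcf(cbind(sim$af_genome, id = "."),
                      paths[["af_genome"]], af = sim$af_genome$af)
  }
  if (!is.null(sim$sequences)) {
    paths[["labels"]] <- file.path(dir, "labels.tsv")
    write_results(sim$sequences[, c("triplet_id", "class")],
                  paths[["labels"]])
  }
  paths
}
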