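# Splice-altering filter, consequence classification, PTC/frame logic,
# rescue rules, allele frequencies, and the full triage pipeline.

test_that("the splice-altering filter keeps scores at or above 0.2", {
  eff <- data.frame(variant_id = c("a", "b", "c"), chrom = "x",
                    pos = 1:3, ref = "G", alt = "A", isj = 10L,
                    effect = "loss", score = c(0.20, 0.19, 0.9),
                    stringsAsFactors = FALSE)
  kept <- filter_splice_altering(eff)
  expect_equal(kept$variant_id, c("a", "c"))
  empty <- filter_splice_altering(eff[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("splicing consequences follow the junction-matching rules", {
  trip <- toy_plus_triplet()
  eff <- function(isj, effect) list(isj = isj, effect = effect, score = 0.5)
  expect_equal(classify_consequence(eff(400L, "loss"), trip)$consequence,
               "exon_skipping")
  expect_equal(classify_consequence(eff(301L, "gain"), trip)$consequence,
               "promoted_inclusion")
  expect_equal(classify_consequence(eff(400L, "gain"), trip)$consequence,
               "promoted_inclusion")
  # a loss at the downstream exon's acceptor matches no rule
  expect_equal(classify_consequence(eff(501L, "loss"), trip)$consequence,
               "none")
  # a loss at the middle-exon acceptor is unspecified by the rules: none,
  # but the matched junction is reported for audit
  res <- classify_consequence(eff(301L, "loss"), trip)
  expect_equal(res$consequence, "none")
  expect_equal(res$junction, "middle_acceptor")
  # matching is exact by default, fuzzy only on request
  expect_equal(classify_consequence(eff(399L, "loss"), trip)$consequence,
               "none")
  expect_equal(classify_consequence(eff(399L, "loss"), trip,
                                    tolerance = 1)$consequence,
               "exon_skipping")
})

test_that("PTC detection translates the mutated exon in frame", {
  # middle exon 301..400 (length 100); plant TGG at exon offset 31..33 and
  # mutate its third base G>A: TGG -> TGA, in frame for frame = 0
  g <- withr::with_seed(5, paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                                 collapse = ""))
  substr(g, 331, 333) <- "TGG"
  # remove any reference stops in frame so the new stop is unambiguous
  genome <- Biostrings::DNAStringSet(g); names(genome) <- "chr1"
  trip <- toy_plus_triplet()
  v <- list(chrom = "chr1", pos = 333L, ref = "G", alt = "A")
  res <- detect_ptc(trip, v, genome, frame = 0)
  expect_true(res$creates_ptc)
  # length 100 is not divisible by 3
  expect_false(res$frame_preserving_skip)
  # the same substitution out of frame does not create a stop at that codon
  res1 <- detect_ptc(trip, v, genome, frame = 1)
  expect_false(res1$creates_ptc)
  # a variant outside the middle exon never creates a PTC there
  v2 <- list(chrom = "chr1", pos = 450L, ref = substr(g, 450, 450),
             alt = "A")
  expect_false(detect_ptc(trip, v2, genome, frame = 0)$creates_ptc)
  # frame preservation is pure arithmetic on the exon length
  trip84 <- trip; trip84$exon2_end <- trip$exon2_start + 83L
  expect_true(detect_ptc(trip84, v2, genome)$frame_preserving_skip)
  trip85 <- trip; trip85$exon2_end <- trip$exon2_start + 84L
  expect_false(detect_ptc(trip85, v2, genome)$frame_preserving_skip)
})

test_that("rescue rules fire in order with first match winning", {
  expect_equal(call_rescue("exon_skipping", FALSE, FALSE, "inclusion"),
               "skipping_rescued_by_inclusion")
  expect_equal(call_rescue("promoted_inclusion", FALSE, FALSE, "inclusion"),
               "none")
  expect_equal(call_rescue("promoted_inclusion", FALSE, FALSE, "exclusion"),
               "inclusion_rescued_by_exclusion")
  expect_equal(call_rescue("none", TRUE, TRUE, "exclusion"),
               "ptc_rescued_by_frame_preserving_skip")
  expect_equal(call_rescue("none", TRUE, FALSE, "exclusion"), "none")
  expect_equal(call_rescue("none", TRUE, TRUE, "inclusion"), "none")
  # precedence: rule 1 wins over rule 3 when both would fire
  expect_equal(call_rescue("exon_skipping", TRUE, TRUE, "inclusion"),
               "skipping_rescued_by_inclusion")
})

test_that("allele frequencies take the maximum when present in both sources", {
  vars <- data.frame(chrom = "c", pos = 1:4, ref = "G", alt = "A",
                     id = paste0("v", 1:4), stringsAsFactors = FALSE)
  exome <- data.frame(chrom = "c", pos = c(1L, 2L), ref = "G", alt = "A",
                      af = c(1e-4, 8.28e-4), stringsAsFactors = FALSE)
  genome_af <- data.frame(chrom = "c", pos = c(1L, 3L), ref = "G",
                          alt = "A", af = c(2e-4, 5e-5),
                          stringsAsFactors = FALSE)
  out <- annotate_allele_frequency(vars, exome, genome_af)
  expect_equal(out$af, c(2e-4, 8.28e-4, 5e-5, NA))
})

test_that("allele frequencies round-trip through VCF files", {
  vars <- data.frame(chrom = "c1", pos = c(10L, 20L), ref = c("G", "T"),
                     alt = c("A", "C"), id = c("v1", "v2"),
                     stringsAsFactors = FALSE)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  splicetriplet:::write_minimal_vcf(vars, f1, af = c(1e-4, 3e-4))
  splicetriplet:::write_minimal_vcf(vars[1, ], f2, af = 2e-4)
  out <- annotate_allele_frequency(vars, f1, f2)
  expect_equal(out$af, c(2e-4, 3e-4))
})

test_that("the pipeline reproduces the planted rescue categories", {
  cfg <- sim_config(seed = 29)
  fx <- simulate_variant_fixtures(cfg, n_donor_loss = 4, n_subthreshold = 2,
                                  n_gain = 3, n_ptc_frame = 2,
                                  n_ptc_shift = 1)
  out <- run_target_pipeline(fx$variants, fx$effects, fx$index, fx$genome,
                             motif_predictor())
  # subthreshold records are filtered before mapping
  expect_false(any(out$variant_id %in%
                     fx$truth$variant_id[fx$truth$category == "subthreshold"]))
  # every remaining planted case fires its expected rule
  tr <- fx$truth[fx$truth$category != "subthreshold", ]
  m <- match(tr$variant_id, out$variant_id)
  expect_false(anyNA(m))
  expect_equal(out$rescue[m], tr$expected_rule)
  expect_equal(sum(out$rescue == "skipping_rescued_by_inclusion"), 4L)
  expect_equal(sum(out$rescue == "inclusion_rescued_by_exclusion"), 3L)
  expect_equal(sum(out$rescue == "ptc_rescued_by_frame_preserving_skip"), 2L)
  # audit invariant: every category re-derives from the stored fields
  rederived <- mapply(call_rescue, out$consequence, out$creates_ptc,
                      out$frame_preserving_skip, out$response)
  expect_equal(unname(rederived), out$rescue)
  # purity: a second run is identical
  out2 <- run_target_pipeline(fx$variants, fx$effects, fx$index, fx$genome,
                              motif_predictor())
  expect_identical(out, out2)
})

test_that("allele frequencies propagate through the pipeline", {
  cfg <- sim_config(seed = 29)
  fx <- simulate_variant_fixtures(cfg)
  out <- run_target_pipeline(fx$variants, fx$effects, fx$index, fx$genome,
                             motif_predictor(), af_exome = fx$af_exome,
                             af_genome = fx$af_genome)
  v1 <- out[out$variant_id == "var1", ]
  expect_equal(v1$af, 8.28e-4)      # exome-only pass-through
  v3 <- out[out$variant_id == "var3", ]
  if (nrow(v3)) expect_equal(v3$af, 2e-4)  # both: maximum wins
})

test_that("minigene candidates respect the span and response filters", {
  idx <- rbind(
    data.frame(triplet_id = "a", gene_id = "g", transcript_id = "t",
               chrom = "c", strand = "+", exon1_start = 1L, exon1_end = 100L,
               exon2_start = 201L, exon2_end = 300L, exon3_start = 401L,
               exon3_end = 1499L, donor1 = 100L, acceptor2 = 201L,
               donor2 = 300L, acceptor3 = 401L),
    data.frame(triplet_id = "b", gene_id = "g", transcript_id = "t",
               chrom = "c", strand = "+", exon1_start = 1L, exon1_end = 100L,
               exon2_start = 201L, exon2_end = 300L, exon3_start = 401L,
               exon3_end = 1500L, donor1 = 100L, acceptor2 = 201L,
               donor2 = 300L, acceptor3 = 401L),
    data.frame(triplet_id = "c", gene_id = "g", transcript_id = "t",
               chrom = "c", strand = "+", exon1_start = 1L, exon1_end = 100L,
               exon2_start = 201L, exon2_end = 300L, exon3_start = 401L,
               exon3_end = 800L, donor1 = 100L, acceptor2 = 201L,
               donor2 = 300L, acceptor3 = 401L)
  )
  calls <- data.frame(triplet_id = c("a", "b", "c"),
                      class = c("inclusion", "inclusion", "unchanged"),
                      stringsAsFactors = FALSE)
  out <- minigene_candidate_filter(idx, calls)
  expect_equal(out$triplet_id, "a")          # span 1499 kept, 1500 dropped
  expect_equal(out$span, 1499L)
  expect_true(all(is.na(out$minigene_recapitulates)))
})
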