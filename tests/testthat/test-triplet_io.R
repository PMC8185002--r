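# Exon-triplet indexing, sequence extraction and tabular IO.

test_that("indexing emits one triplet per window of three consecutive exons", {
  lines <- c(
    gtf_line("chr1", 101, 200, "+", "g1", "t3"),
    gtf_line("chr1", 301, 400, "+", "g1", "t3"),
    gtf_line("chr1", 501, 600, "+", "g1", "t3"),
    gtf_line("chr2", seq(101, 2101, 500), seq(200, 2200, 500), "-",
             "g2", "t5")[1:5],
    gtf_line("chr3", 101, 200, "+", "g3", "t2"),
    gtf_line("chr3", 301, 400, "+", "g3", "t2")
  )
  idx <- build_triplet_index(write_gtf(lines))
  expect_equal(sum(idx$transcript_id == "t3"), 1L)   # 3 exons -> 1 window
  expect_equal(sum(idx$transcript_id == "t5"), 3L)   # 5 exons -> 3 windows
  expect_equal(sum(idx$transcript_id == "t2"), 0L)   # 2 exons -> none
  # total = sum over transcripts of max(0, n_exons - 2), no shared trios here
  expect_equal(nrow(idx), 4L)
})

test_that("minus-strand triplets are ordered in transcript orientation", {
  lines <- gtf_line("chr2", seq(101, 1101, 500), seq(200, 1200, 500), "-",
                    "g2", "t5")[1:3]
  idx <- build_triplet_index(write_gtf(lines))
  # exon1 is genomically rightmost on the minus strand
  expect_true(idx$exon1_start > idx$exon3_start)
  expect_equal(idx$donor1, idx$exon1_start)
  expect_equal(idx$acceptor2, idx$exon2_end)
  expect_equal(idx$donor2, idx$exon2_start)
})

test_that("identical coordinate trios across transcripts are deduplicated", {
  lines <- c(
    gtf_line("chr1", c(101, 301, 501), c(200, 400, 600), "+", "g1", "tA"),
    gtf_line("chr1", c(101, 301, 501), c(200, 400, 600), "+", "g1", "tB")
  )
  idx <- build_triplet_index(write_gtf(lines))
  expect_equal(nrow(idx), 1L)
})

test_that("overlapping exons within a transcript raise a validation error", {
  lines <- c(
    gtf_line("chr1", 101, 400, "+", "g1", "t1"),
    gtf_line("chr1", 300, 500, "+", "g1", "t1"),
    gtf_line("chr1", 601, 700, "+", "g1", "t1")
  )
  expect_error(build_triplet_index(write_gtf(lines)), "overlapping")
})

test_that("a malformed GTF raises a parse error naming the file", {
  f <- tempfile(fileext = ".gtf")
  writeLines("chr1\tonly\tthree", f)
  expect_error(build_triplet_index(f), "failed to parse GTF")
})

test_that("blocks are 25 exonic + 75 intronic with the junction anchored", {
  genome <- toy_genome()
  trip <- toy_plus_triplet()
  s <- extract_triplet_sequence(trip, genome)
  expect_equal(nchar(s$sequence), 400L)
  expect_equal(unname(nchar(s$blocks)), rep(100L, 4L))
  gchar <- function(p) as.character(Biostrings::subseq(genome[[1]], p, p))
  # donor blocks: position 25 = last exonic base, 26 = first intronic base
  expect_equal(substr(s$blocks[["UI1"]], 25, 25), gchar(200))
  expect_equal(substr(s$blocks[["UI1"]], 26, 26), gchar(201))
  expect_equal(substr(s$blocks[["XI2"]], 25, 25), gchar(400))
  expect_equal(substr(s$blocks[["XI2"]], 26, 26), gchar(401))
  # acceptor blocks: position 75 = last intronic, 76 = first exonic base
  expect_equal(substr(s$blocks[["I1X"]], 75, 75), gchar(300))
  expect_equal(substr(s$blocks[["I1X"]], 76, 76), gchar(301))
  expect_equal(substr(s$blocks[["I2D"]], 76, 76), gchar(501))
})

test_that("a marker planted at the middle-exon donor lands at block-3 position 26", {
  g <- strrep("A", 1000)
  substr(g, 401, 401) <- "C"      # first intronic base after exon2's donor
  genome <- Biostrings::DNAStringSet(g); names(genome) <- "chr1"
  s <- extract_triplet_sequence(toy_plus_triplet(), genome)
  expect_equal(substr(s$blocks[["XI2"]], 26, 26), "C")
  expect_equal(substr(s$sequence, 226, 226), "C")
})

test_that("minus-strand extraction equals the mirrored plus-strand extraction", {
  genome <- toy_genome()
  plus <- extract_triplet_sequence(toy_plus_triplet(), genome)
  rc <- Biostrings::reverseComplement(genome)
  names(rc) <- "chr1"
  minus <- extract_triplet_sequence(
    mirror_minus(toy_plus_triplet(), length(genome[[1]])), rc)
  expect_equal(minus$sequence, plus$sequence)
})

test_that("every block is 100 bases over random annotations on both strands", {
  withr::with_seed(42, {
    for (i in 1:25) {
      # exon/intron lengths deliberately include short ones (< 25 / < 75)
      el <- sample(5:60, 3, TRUE)
      il <- sample(c(8:20, 80:200), 2, TRUE)
      margin <- 100L
      starts <- cumsum(c(margin + 1L, el[1] + il[1], el[2] + il[2]))
      trip <- list(
        triplet_id = "r", chrom = "chr1", strand = "+",
        exon1_start = starts[1], exon1_end = starts[1] + el[1] - 1L,
        exon2_start = starts[2], exon2_end = starts[2] + el[2] - 1L,
        exon3_start = starts[3], exon3_end = starts[3] + el[3] - 1L
      )
      trip$donor1 <- trip$exon1_end; trip$acceptor2 <- trip$exon2_start
      trip$donor2 <- trip$exon2_end; trip$acceptor3 <- trip$exon3_start
      len <- starts[3] + el[3] + margin
      genome <- toy_genome(seed = i, len = len)
      s <- suppressWarnings(extract_triplet_sequence(trip, genome))
      expect_equal(unname(nchar(s$blocks)), rep(100L, 4L))
      # junction stays anchored: block position 25 of XI2 = donor base
      expect_equal(substr(s$blocks[["XI2"]], 25, 25),
                   as.character(Biostrings::subseq(genome[[1]], trip$donor2,
                                                   trip$donor2)))
      # padding (if any) sits at the far-from-junction ends
      ui1 <- strsplit(s$blocks[["UI1"]], "")[[1]]
      if (el[1] < 25) {
        expect_true(all(ui1[seq_len(25 - el[1])] == "N"))
        expect_true(all(ui1[(26 - el[1]):25] != "N"))
      }
      # mirrored minus-strand triplet on the reverse-complemented genome
      rc <- Biostrings::reverseComplement(genome); names(rc) <- "chr1"
      m <- suppressWarnings(
        extract_triplet_sequence(mirror_minus(trip, len), rc))
      expect_equal(m$sequence, s$sequence)
    }
  })
})

test_that("an SNV at donor +6 changes exactly one base of XI2", {
  genome <- toy_genome()
  trip <- toy_plus_triplet()
  s <- extract_triplet_sequence(trip, genome)
  pos <- 406L
  ref <- as.character(Biostrings::subseq(genome[[1]], pos, pos))
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- list(chrom = "chr1", pos = pos, ref = ref, alt = alt)
  s2 <- apply_variant(s, trip, v, genome)
  d <- which(strsplit(s$blocks[["XI2"]], "")[[1]] !=
               strsplit(s2$blocks[["XI2"]], "")[[1]])
  expect_equal(d, 31L)                       # intronic offset 6 = 25 + 6
  expect_equal(substr(s2$blocks[["XI2"]], 31, 31), alt)
  expect_equal(s2$blocks[["UI1"]], s$blocks[["UI1"]])
})

test_that("an intronic deletion re-extracts the block anchored at the junction", {
  genome <- toy_genome()
  trip <- toy_plus_triplet()
  s <- extract_triplet_sequence(trip, genome)
  # delete intron bases +4..+7 after the middle-exon donor (cf. a
  # c.659+4_659+7del-style variant, VCF left-anchored at +3)
  gstr <- as.character(genome[[1]])
  v <- list(chrom = "chr1", pos = 403L, ref = substr(gstr, 403, 407),
            alt = substr(gstr, 403, 403))
  s2 <- apply_variant(s, trip, v, genome)
  expect_equal(nchar(s2$blocks[["XI2"]]), 100L)
  # oracle: apply the deletion to the chromosome string and re-substring
  mut <- paste0(substr(gstr, 1, 403), substr(gstr, 408, nchar(gstr)))
  expect_equal(substr(s2$blocks[["XI2"]], 26, 100),
               substr(mut, 401, 475))
  expect_equal(substr(s2$blocks[["XI2"]], 1, 25), substr(gstr, 376, 400))
})

test_that("variant contract violations are caught", {
  genome <- toy_genome()
  trip <- toy_plus_triplet()
  s <- extract_triplet_sequence(trip, genome)
  ref <- as.character(Biostrings::subseq(genome[[1]], 406, 406))
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(
    apply_variant(s, trip, list(chrom = "chr1", pos = 406L, ref = wrong,
                                alt = ref), genome),
    "reference allele mismatch")
  ref900 <- as.character(Biostrings::subseq(genome[[1]], 900, 900))
  expect_warning(
    out <- apply_variant(s, trip,
                         list(chrom = "chr1", pos = 900L, ref = ref900,
                              alt = setdiff(c("A", "C", "G", "T"), ref900)[1]),
                         genome),
    "outside")
  expect_equal(out$sequence, s$sequence)
})

test_that("junction count tables round-trip and are validated", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(
    triplet_id = rep(c("a", "b"), each = 5),
    sample = paste0("line", rep(1:5, 2)),
    condition = rep(c("control", "treated"), 5),
    R1 = 0:9, R2 = 9:0, R3 = rep(3L, 10),
    stringsAsFactors = FALSE
  )
  write_junction_counts(df, f)
  expect_equal(read_junction_counts(f), df)

  bad <- df; bad$R3[1] <- -1L
  expect_error(write_junction_counts(bad, f), "non-negative")
  bad2 <- df; bad2$condition[1] <- "mock"
  expect_error(write_junction_counts(bad2, f), "condition")

  writeLines("triplet_id\tsample\tcondition\tR1\tR2\tR3", f)
  empty <- read_junction_counts(f)
  expect_equal(nrow(empty), 0L)
})
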