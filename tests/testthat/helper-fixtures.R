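# Shared fixtures, built in code.

# A plus-strand toy locus with known coordinates:
# exon1 101-200, exon2 301-400, exon3 501-600 on a 1000-base chromosome.
toy_plus_triplet <- function() {
  list(
    triplet_id = "toy+", gene_id = "g1", transcript_id = "t1",
    chrom = "chr1", strand = "+",
    exon1_start = 101L, exon1_end = 200L,
    exon2_start = 301L, exon2_end = 400L,
    exon3_start = 501L, exon3_end = 600L,
    donor1 = 200L, acceptor2 = 301L, donor2 = 400L, acceptor3 = 501L
  )
}

toy_genome <- function(seed = 3, len = 1000, chrom = "chr1") {
  g <- withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""))
  gs <- Biostrings::DNAStringSet(g)
  names(gs) <- chrom
  gs
}

# mirror a plus-strand triplet into an equivalent minus-strand one on the
# reverse-complemented chromosome
mirror_minus <- function(triplet, chromlen) {
  flip <- function(a, b) c(chromlen - b + 1L, chromlen - a + 1L)
  e1 <- flip(triplet$exon1_start, triplet$exon1_end)
  e2 <- flip(triplet$exon2_start, triplet$exon2_end)
  e3 <- flip(triplet$exon3_start, triplet$exon3_end)
  list(
    triplet_id = "toy-", gene_id = triplet$gene_id,
    transcript_id = triplet$transcript_id,
    chrom = triplet$chrom, strand = "-",
    exon1_start = e1[1L], exon1_end = e1[2L],
    exon2_start = e2[1L], exon2_end = e2[2L],
    exon3_start = e3[1L], exon3_end = e3[2L],
    donor1 = e1[1L], acceptor2 = e2[2L], donor2 = e2[1L], acceptor3 = e3[2L]
  )
}

gtf_line <- function(chrom, start, end, strand, gene, tx) {
  sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          chrom, start, end, strand, gene, tx)
}

write_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

# small encoded planted-motif corpus for quick network tests
small_corpus <- function(n = 40, seed = 11) {
  cfg <- sim_config(n_inclusion = n, n_exclusion = n, n_unchanged = n,
                    seed = seed)
  sim <- simulate_triplet_sequences(cfg)
  labs <- sim$sequences$class
  names(labs) <- sim$sequences$triplet_id
  sp <- split_dataset(labs, seed = 122)
  enc <- function(ids) {
    i <- match(ids, sim$sequences$triplet_id)
    encode_dataset(sim$sequences$sequence[i], labs[ids])
  }
  tr <- enc(sp$train); va <- enc(sp$validation); te <- enc(sp$test)
  list(sim = sim, labels = labs, split = sp,
       x_train = tr$x, y_train = tr$y, x_val = va$x, y_val = va$y,
       x_test = te$x, y_test = te$y)
}

small_cnn_config <- function(...) {
  args <- list(n_filters1 = 12, n_filters2 = 12, hidden = 48,
               max_epochs = 12, patience = 12, dropout = 0.5,
               batch_size = 16, seed = 5)
  override <- list(...)
  args[names(override)] <- override
  do.call(cnn_config, args)
}

# independent brute-force CMH chi-square: sum(a - E[a])^2 / sum Var(a)
cmh_brute <- function(tables) {
  if (is.list(tables)) tables <- array(unlist(tables),
                                       c(2L, 2L, length(tables)))
  a <- e <- v <- numeric(dim(tables)[3])
  for (k in seq_len(dim(tables)[3])) {
    t2 <- tables[, , k]
    n <- sum(t2); r1 <- sum(t2[1, ]); r2 <- sum(t2[2, ])
    c1 <- sum(t2[, 1]); c2 <- sum(t2[, 2])
    a[k] <- t2[1, 1]
    e[k] <- r1 * c1 / n
    v[k] <- r1 * r2 * c1 * c2 / (n^2 * (n - 1))
  }
  stat <- (sum(a) - sum(e))^2 / sum(v)
  list(statistic = stat,
       p.value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# a controlled predictor keyed on the planted class motif near the donor
motif_predictor <- function() {
  function(seqs) {
    win <- substring(seqs, 221, 240)
    t(vapply(win, function(w) {
      if (grepl("GTAAG", w)) c(0.9, 0.05, 0.05)
      else if (grepl("GTCCT", w)) c(0.05, 0.9, 0.05)
      else c(0.05, 0.05, 0.9)
    }, numeric(3), USE.NAMES = FALSE))
  }
}

# a hand-built model whose only live first-layer filter is an indicator for
# `motif`, with non-negative downstream weights driving the first output
indicator_model <- function(config, motif = "GTAAG", gain = 1) {
  m <- build_model(config)
  for (p in c("W1", "W2", "Wh", "Wo")) m[[p]] <- m[[p]] * 0
  m$b1 <- m$b1 * 0; m$b2 <- m$b2 * 0; m$bh <- m$bh * 0; m$bo <- m$bo * 0
  chars <- strsplit(motif, "")[[1L]]
  stopifnot(length(chars) == config$filter_width1)
  for (j in seq_along(chars)) {
    m$W1[(j - 1L) * 4L + match(chars[j], c("A", "C", "G", "T")), 1L] <- 1
  }
  m$b1[1L] <- -(length(chars) - 1L)      # fires only on an exact match
  m$W2[1L, 1L] <- 1                      # channel 1, offset 0 -> filter 1
  m$Wh[, 1L] <- gain * as.numeric(seq_len(nrow(m$Wh)) <=
                                    config$dims$pool2)  # filter-1 block
  m$Wo[1L, 1L] <- gain
  m$bo[] <- -2                           # low scores in the absence of signal
  m
}
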