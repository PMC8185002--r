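# splicetriplet

Tools for finding exons — and ultimately disease mutations — that respond to
a splicing modulator compound (SMC), from paired treated/control RNA-seq of
cell lines.

The unit of analysis is the **exon triplet**: three consecutive exons of one
transcript, where the middle exon may be included or skipped. For each
triplet and replicate, middle-exon inclusion is estimated from
junction-spanning read counts as

    psi = 0.5 (R1 + R2) / (0.5 (R1 + R2) + R3)

(R1, R2 span the two inclusion junctions, R3 the skipping junction).
Treatment–splicing association is tested per triplet with a stratified
Cochran–Mantel–Haenszel chi-square across replicates, followed by
Benjamini–Hochberg FDR; triplets are called *inclusion* (Δpsi ≥ 0.1,
FDR < 0.1), *exclusion* (Δpsi ≤ −0.1, FDR < 0.1) or *unchanged*
(pre-treatment psi in [0.1, 0.9], |Δpsi| < 0.01, FDR ≥ 0.1).

A small convolutional network then learns which junction-flank sequences
respond: each triplet contributes four 100-base windows around its splice
junctions (25 exonic + 75 intronic bases each), concatenated to a one-hot
4×400 input; two convolutional layers (50×5, 50×2), a 500-unit hidden layer
with 90% dropout, L1 = 0.6 on the convolutional weights, and three sigmoid
outputs (~2.5 M parameters) are trained with early stopping on mean
validation AUC. Interpretation utilities extract first-layer filter motifs
(PPMs), filter-ablation contributions to AUC, positional importance, in
silico saturation mutagenesis maps, and discriminative 5-mer enrichment at
the middle-exon donor.

Finally, a rescue-triage module combines SpliceAI-style splice-effect
records (score ≥ 0.2 = splice-altering) with the model's predicted drug
response of the mutated sequence: variants predicted to cause exon skipping
that the drug would re-include (rule 1), to promote inclusion that the drug
would counter (rule 2), or to create an in-frame-skippable premature stop
codon in the middle exon (rule 3), with gnomAD-style allele-frequency
annotation.

A seeded synthetic-data generator emulates the whole study design (paired
replicates, overdispersed coverage, class-determining 5-mers planted at the
middle-exon donor, variant/effect/AF fixtures) so the entire pipeline is
testable offline.

## Worked example

```r
library(splicetriplet)

# simulate the paired design: 50 triplets per response class, 6 lines
cfg  <- sim_config(n_inclusion = 50, n_exclusion = 50, n_unchanged = 50,
                   seed = 7)
sim  <- simulate_junction_counts(cfg)
calls <- quantify(sim$counts)
head(calls[, c("triplet_id", "psi_control", "psi_treated", "dpsi",
               "p_value", "fdr", "class")], 4)
#>   triplet_id psi_control psi_treated  dpsi  p_value      fdr     class
#> 1   SIM00001       0.326       0.416 0.090 6.35e-05 1.07e-04     other
#> 2   SIM00002       0.684       0.855 0.171 9.48e-14 2.37e-12 inclusion
#> 3   SIM00003       0.334       0.505 0.171 8.94e-09 3.97e-08 inclusion
#> 4   SIM00004       0.367       0.529 0.162 2.07e-07 6.33e-07 inclusion

table(truth = sim$truth$class, called = calls$class)
#>            called
#> truth       exclusion inclusion other unchanged
#>   exclusion        49         0     1         0
#>   inclusion         0        47     3         0
#>   unchanged         0         0    33        17
```

SIM00001's true effect is +0.15 but its sampled Δpsi (0.090) misses the 0.1
threshold — calling power is high, not perfect, at this coverage. Unchanged
triplets split between `unchanged` and `other` because the unchanged call
demands |Δpsi| < 0.01, which sampling noise often exceeds; none are called
responsive.

```r
# sequence corpus with planted class 5-mers; train and interpret
cfg  <- sim_config(n_inclusion = 100, n_exclusion = 100, n_unchanged = 100,
                   seed = 7)
sim  <- simulate_triplet_sequences(cfg)
labs <- sim$sequences$class; names(labs) <- sim$sequences$triplet_id
sp   <- split_dataset(labs, seed = 122)       # stratified 70/20/10
enc  <- function(ids) {
  i <- match(ids, sim$sequences$triplet_id)
  encode_dataset(sim$sequences$sequence[i], labs[ids])
}
tr <- enc(sp$train); va <- enc(sp$validation); te <- enc(sp$test)

model <- train_cnn(build_model(cnn_config(seed = 122)),
                   tr$x, tr$y, va$x, va$y)
mean_auc(predict_cnn(model, te$x), te$y)
#> [1] 0.895

# the planted donor-window 5-mers are recovered by discriminative enrichment
enr <- kmer_enrichment(sim$sequences$sequence, labs)
subset(enr$table, enriched & kmer %in% c("GTAAG", "GTCCT"))[,
       c("class", "kmer", "n_class", "n_other", "padj")]
#>         class  kmer n_class n_other     padj
#>     inclusion GTAAG     100       1 2.53e-78
#>     exclusion GTCCT     100       2 1.31e-76

# standardized probabilities of one held-out sequence (an inclusion triplet)
standardize_probability(as.numeric(predict_cnn(model, te$x[1, , drop = FALSE])),
                        model$cutoffs)
#> [1] 0.831 0.004 0.165
```

At 300 sequences per class (the scale the test suite uses) the same
procedure reaches a mean held-out AUC above 0.99 in a few minutes on one
CPU.

For rescue triage, see `?run_target_pipeline`: it maps splice-effect records
to triplet junctions, mutates and re-scores the sequence, applies the three
rescue rules and annotates allele frequencies;
`simulate_variant_fixtures()` builds a fully controlled toy input set.

A thin command-line front end over the same functions is installed at
`exec/splicetriplet-cli.R` (subcommands `index`, `extract`, `simulate`,
`quantify`, `rescue`); model training and interpretation are R-API
workflows described in the vignette.

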