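# Lazily trained full-scale reference model on the planted-motif corpus
# (300 sequences per class, default architecture).  Built once per test run
# and shared by the end-to-end and interpretation tests.

.fixture_cache <- new.env(parent = emptyenv())

planted_corpus <- function() {
  if (is.null(.fixture_cache$corpus)) {
    cfg <- sim_config(seed = 1)
    sim <- simulate_triplet_sequences(cfg)
    labs <- sim$sequences$class
    names(labs) <- sim$sequences$triplet_id
    sp <- split_dataset(labs, seed = 122)
    enc <- function(ids) {
      i <- match(ids, sim$sequences$triplet_id)
      encode_dataset(sim$sequences$sequence[i], labs[ids])
    }
    tr <- enc(sp$train); va <- enc(sp$validation); te <- enc(sp$test)
    .fixture_cache$corpus <- list(
      config = cfg, sim = sim, labels = labs, split = sp,
      x_train = tr$x, y_train = tr$y, x_val = va$x, y_val = va$y,
      x_test = te$x, y_test = te$y)
  }
  .fixture_cache$corpus
}

trained_reference <- function() {
  if (is.null(.fixture_cache$model)) {
    co <- planted_corpus()
    t0 <- Sys.time()
    model <- train_cnn(build_model(cnn_config()), co$x_train, co$y_train,
                       co$x_val, co$y_val)
    .fixture_cache$train_secs <-
      as.numeric(Sys.time() - t0, units = "secs")
    .fixture_cache$model <- model
  }
  list(model = .fixture_cache$model,
       train_secs = .fixture_cache$train_secs)
}
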