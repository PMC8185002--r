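# Convolutional network for treatment-response prediction --------------------
#
# Architecture (on a 4 x 400 one-hot input, widths for the default config):
#   conv1: 50 filters of width 5 over 4 channels (valid)   -> 50 x 396
#   ReLU, max-pool width 2 stride 2                        -> 50 x 198
#   conv2: 50 filters of width 2 over 50 channels (valid)  -> 50 x 197
#   ReLU, max-pool width 2 stride 2 (floor on odd widths)  -> 50 x 98
#   flatten                                                -> 4900
#   fully connected -> 500, dropout 0.9, ReLU
#   linear -> 3, per-class sigmoid
# Trained by RMSprop on the minibatch objective
#   sum over samples of summed 3-class binary cross-entropy
#   + l1 * L1-norm of the convolutional weights,
# with early stopping on mean one-vs-rest validation AUC (patience 10) and
# best-epoch weight restoration.  Everything runs on base BLAS matrix ops
# (im2col convolutions), deterministically given the seed.

#' Network configuration
#'
#' Defaults give the two-convolutional-layer network with 2,458,103 trainable
#' parameters (~2.5 million).
#'
#' @param n_filters1,filter_width1 First convolution: 50 filters of width 5.
#' @param n_filters2,filter_width2 Second convolution: 50 filters of width 2
#'   over `n_filters1` input channels.
#' @param pool_width Max-pool width/stride after each convolution.
#' @param hidden Hidden fully connected units (500).
#' @param dropout Dropout rate on the hidden layer (0.9), train-time only.
#' @param l1 L1 coefficient on convolutional weights (0.6), applied once per
#'   minibatch.
#' @param lr,rho,epsilon RMSprop learning rate, decay and stabiliser.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience on mean validation AUC.
#' @param input_width Input columns (400).
#' @param n_classes Output classes (3).
#' @param restore_best Restore the best-AUC epoch's weights (default) rather
#'   than the last epoch's.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(n_filters1 = 50, filter_width1 = 5,
                       n_filters2 = 50, filter_width2 = 2,
                       pool_width = 2, hidden = 500, dropout = 0.9,
                       l1 = 0.6, lr = 1e-3, rho = 0.9, epsilon = 1e-8,
                       batch_size = 64, max_epochs = 50, patience = 10,
                       input_width = 400, n_classes = 3,
                       restore_best = TRUE, seed = 122) {
  if (dropout < 0 || dropout >= 1) abort("dropout must lie in [0, 1)")
  cfg <- as.list(environment())
  w1 <- input_width - filter_width1 + 1L
  p1 <- w1 %/% pool_width
  w2 <- p1 - filter_width2 + 1L
  p2 <- w2 %/% pool_width
  if (min(w1, p1, w2, p2) < 1L) {
    abort("configuration inconsistent with the input width")
  }
  cfg$dims <- list(conv1 = w1, pool1 = p1, conv2 = w2, pool2 = p2,
                   flat = p2 * n_filters2)
  class(cfg) <- "cnn_config"
  cfg
}

#' Build an untrained network
#'
#' Weights are Glorot-uniform initialised from `config$seed`; biases zero.
#'
#' @param config A [cnn_config()].
#' @return A list of class `splice_cnn` holding the config and weight
#'   matrices `W1` (4*width1 x F1), `W2` (2*F1... x F2), `Wh`, `Wo` and
#'   biases.
#' @export
build_model <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  d <- config$dims
  glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(runif(nin * nout, -lim, lim), nin, nout)
  }
  with_seed(config$seed, {
    model <- list(
      config = config,
      W1 = glorot(4L * config$filter_width1, config$n_filters1),
      b1 = numeric(config$n_filters1),
      W2 = glorot(config$n_filters1 * config$filter_width2,
                  config$n_filters2),
      b2 = numeric(config$n_filters2),
      Wh = glorot(d$flat, config$hidden),
      bh = numeric(config$hidden),
      Wo = glorot(config$hidden, config$n_classes),
      bo = numeric(config$n_classes)
    )
    class(model) <- "splice_cnn"
    model
  })
}

#' Count trainable parameters
#'
#' @param model A `splice_cnn` (or a `cnn_config`).
#' @return Integer count of weights plus biases.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "cnn_config")) model <- build_model(model)
  sum(vapply(model[c("W1", "b1", "W2", "b2", "Wh", "bh", "Wo", "bo")],
             length, 0L))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# im2col index helpers; `n` is the batch size ------------------------------

# conv1 input columns: window p (1..w1) uses one-hot entries
# (p-1)*4 + 1..4*width; returns the (4*width) x (w1*n) input-column matrix
conv1_cols <- function(x, config) {
  w1 <- config$dims$conv1
  width <- config$filter_width1
  idx <- as.vector(outer(seq_len(4L * width), (seq_len(w1) - 1L) * 4L, "+"))
  xs <- x[, idx, drop = FALSE]              # n x (w1 * 4width), k fastest
  dim(xs) <- NULL
  m <- matrix(t(matrix(xs, nrow = nrow(x))), nrow = 4L * width)
  m                                          # columns ordered (p, then n)
}

pool_pairs <- function(a, width_in, n) {
  # rows of `a` are (position, then sample); pool adjacent positions,
  # dropping a trailing odd position
  w_out <- width_in %/% 2L
  i1 <- as.vector(outer(seq(1L, 2L * w_out, 2L),
                        (seq_len(n) - 1L) * width_in, "+"))
  i2 <- i1 + 1L
  a1 <- a[i1, , drop = FALSE]; a2 <- a[i2, , drop = FALSE]
  list(p = pmax(a1, a2), take_first = a1 >= a2, i1 = i1, i2 = i2)
}

# Forward pass.  `x` is N x (4*input_width).  Returns all intermediates
# needed for backprop when `keep = TRUE`.
cnn_forward <- function(model, x, train = FALSE, keep = FALSE,
                        drop_mask = NULL, ablate_filters = integer(0)) {
  cfg <- model$config; d <- cfg$dims
  n <- nrow(x)
  xc <- conv1_cols(x, cfg)                            # (4w) x (w1 n)
  z1 <- crossprod(xc, model$W1)                       # (w1 n) x F1
  z1 <- sweep(z1, 2L, model$b1, "+")
  a1 <- z1; a1[a1 < 0] <- 0
  if (length(ablate_filters)) a1[, ablate_filters] <- 0
  p1 <- pool_pairs(a1, d$conv1, n)
  # conv2 windows over pooled positions
  w2 <- d$conv2
  j1 <- as.vector(outer(seq_len(w2), (seq_len(n) - 1L) * d$pool1, "+"))
  j2 <- j1 + 1L
  xcol2 <- cbind(p1$p[j1, , drop = FALSE], p1$p[j2, , drop = FALSE])
  z2 <- xcol2 %*% model$W2
  z2 <- sweep(z2, 2L, model$b2, "+")
  a2 <- z2; a2[a2 < 0] <- 0
  p2 <- pool_pairs(a2, w2, n)
  flat <- matrix(aperm(array(p2$p, c(d$pool2, n, cfg$n_filters2)),
                       c(2L, 1L, 3L)), nrow = n)
  hpre <- sweep(flat %*% model$Wh, 2L, model$bh, "+")
  h <- hpre; h[h < 0] <- 0
  if (train && cfg$dropout > 0) {
    if (is.null(drop_mask)) {
      keep_p <- 1 - cfg$dropout
      drop_mask <- matrix(
        (runif(length(h)) < keep_p) / keep_p, nrow(h), ncol(h))
    }
    h <- h * drop_mask
  }
  o <- sweep(h %*% model$Wo, 2L, model$bo, "+")
  s <- sigmoid(o)
  colnames(s) <- RESPONSE_CLASSES[seq_len(cfg$n_classes)]
  if (!keep) return(list(scores = s))
  list(scores = s, xc = xc, z1 = z1, a1 = a1, p1 = p1, j1 = j1, j2 = j2,
       xcol2 = xcol2, z2 = z2, a2 = a2, p2 = p2, flat = flat, hpre = hpre,
       h = h, drop_mask = drop_mask, n = n)
}

# Backward pass for the summed-BCE minibatch objective; returns gradients.
cnn_backward <- function(model, fwd, y) {
  cfg <- model$config; d <- cfg$dims
  n <- fwd$n
  do_ <- fwd$scores - y                               # n x 3
  g <- list()
  g$Wo <- crossprod(fwd$h, do_)
  g$bo <- colSums(do_)
  dh <- do_ %*% t(model$Wo)
  if (!is.null(fwd$drop_mask)) dh <- dh * fwd$drop_mask
  dh[fwd$hpre <= 0] <- 0
  g$Wh <- crossprod(fwd$flat, dh)
  g$bh <- colSums(dh)
  dflat <- dh %*% t(model$Wh)
  dp2 <- matrix(aperm(array(dflat, c(n, d$pool2, cfg$n_filters2)),
                      c(2L, 1L, 3L)), nrow = d$pool2 * n)
  da2 <- matrix(0, d$conv2 * n, cfg$n_filters2)
  da2[fwd$p2$i1, ] <- dp2 * fwd$p2$take_first
  da2[fwd$p2$i2, ] <- da2[fwd$p2$i2, , drop = FALSE] +
    dp2 * !fwd$p2$take_first
  da2[fwd$z2 <= 0] <- 0
  g$W2 <- crossprod(fwd$xcol2, da2)
  g$b2 <- colSums(da2)
  dxcol2 <- da2 %*% t(model$W2)
  f1 <- cfg$n_filters1
  dp1 <- matrix(0, d$pool1 * n, f1)
  dp1[fwd$j1, ] <- dxcol2[, seq_len(f1), drop = FALSE]
  dp1[fwd$j2, ] <- dp1[fwd$j2, , drop = FALSE] +
    dxcol2[, f1 + seq_len(f1), drop = FALSE]
  da1 <- matrix(0, d$conv1 * n, f1)
  da1[fwd$p1$i1, ] <- dp1 * fwd$p1$take_first
  da1[fwd$p1$i2, ] <- da1[fwd$p1$i2, , drop = FALSE] +
    dp1 * !fwd$p1$take_first
  da1[fwd$z1 <= 0] <- 0
  g$W1 <- fwd$xc %*% da1
  g$b1 <- colSums(da1)
  # L1 subgradient on the convolutional layers, once per minibatch
  g$W1 <- g$W1 + cfg$l1 * sign(model$W1)
  g$W2 <- g$W2 + cfg$l1 * sign(model$W2)
  g
}

# summed-per-class binary cross-entropy, per sample
bce_loss <- function(scores, y, eps = 1e-12) {
  s <- pmin(pmax(scores, eps), 1 - eps)
  rowSums(-(y * log(s) + (1 - y) * log(1 - s)))
}

#' Predict raw sigmoid scores
#'
#' @param model A trained (or untrained) `splice_cnn`.
#' @param x Encoded sequences (`N x 1600` matrix from [encode_dataset()]), or
#'   a character vector of 400-base sequences.
#' @return `N x 3` matrix of per-class sigmoid scores.
#' @export
predict_cnn <- function(model, x) {
  if (is.character(x)) x <- encode_dataset(x)$x
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  cnn_forward(model, x)$scores
}

#' Train the network
#'
#' Minimises the per-minibatch objective (summed 3-class binary cross-entropy
#' plus the L1 penalty on convolutional weights) by RMSprop.  After every
#' epoch the mean one-vs-rest AUC on the validation set is recorded; training
#' stops when it fails to improve for `patience` consecutive epochs (or at
#' `max_epochs`), and the best-AUC epoch's weights are restored.  Per-class
#' 95%-specificity score cutoffs are then computed on the validation set.
#'
#' @param model An untrained model from [build_model()].
#' @param x_train,y_train,x_val,y_val Encoded matrices and 0/1 label
#'   matrices (see [encode_dataset()]); all three classes must appear in the
#'   validation labels.
#' @param specificity Specificity level for the per-class cutoffs.
#' @param verbose Print per-epoch progress.
#' @return The trained `splice_cnn`, with `history` (per-epoch `train_loss`,
#'   `val_loss`, `val_auc`), `best_epoch`, and `cutoffs`.
#' @export
train_cnn <- function(model, x_train, y_train, x_val, y_val,
                      specificity = 0.95, verbose = FALSE) {
  stopifnot(inherits(model, "splice_cnn"))
  cfg <- model$config
  if (any(colSums(y_val) == 0L)) {
    abort("every class must be present in the validation set (AUC undefined otherwise)")
  }
  if (nrow(x_train) == 0L) abort("empty training set")
  pars <- c("W1", "b1", "W2", "b2", "Wh", "bh", "Wo", "bo")
  v <- lapply(model[pars], function(w) w * 0)
  names(v) <- pars
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_auc = numeric())
  best <- -Inf; best_epoch <- 0L; best_weights <- model[pars]; wait <- 0L
  n <- nrow(x_train)
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        fwd <- cnn_forward(model, x_train[b, , drop = FALSE], train = TRUE,
                           keep = TRUE)
        losses <- c(losses, bce_loss(fwd$scores, y_train[b, , drop = FALSE]))
        g <- cnn_backward(model, fwd, y_train[b, , drop = FALSE])
        for (p in pars) {
          v[[p]] <- cfg$rho * v[[p]] + (1 - cfg$rho) * g[[p]]^2
          model[[p]] <- model[[p]] -
            cfg$lr * g[[p]] / (sqrt(v[[p]]) + cfg$epsilon)
        }
      }
      val_scores <- cnn_forward(model, x_val)$scores
      val_auc <- mean_auc(val_scores, y_val)
      val_loss <- mean(bce_loss(val_scores, y_val))
      history[epoch, ] <- list(epoch, mean(losses), val_loss, val_auc)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f  auc %.4f",
                        epoch, mean(losses), val_loss, val_auc))
      }
      if (val_auc > best + 1e-8) {
        best <- val_auc; best_epoch <- epoch
        best_weights <- model[pars]; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  if (cfg$restore_best) model[pars] <- best_weights
  model$history <- history
  model$best_epoch <- best_epoch
  val_scores <- cnn_forward(model, x_val)$scores
  model$cutoffs <- vapply(seq_len(cfg$n_classes), function(k) {
    specificity_cutoff(val_scores[, k], y_val[, k] == 1, specificity)
  }, 0)
  names(model$cutoffs) <- colnames(val_scores)
  model
}

#' One-vs-rest ROC AUC (rank definition)
#'
#' Equivalent to the trapezoid area under the ROC curve, with tied scores
#' handled by average ranks (a constant score gives 0.5).
#'
#' @param scores Numeric score vector.
#' @param positive Logical vector: is the sample a positive of this class?
#' @return AUC in \[0, 1\]; `NA` if either group is empty.
#' @export
compute_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname compute_auc
#' @param y `N x K` 0/1 label matrix matching an `N x K` score matrix.
#' @export
mean_auc <- function(scores, y) {
  mean(vapply(seq_len(ncol(y)), function(k) {
    compute_auc(scores[, k], y[, k] == 1)
  }, 0))
}

#' Area under the precision-recall curve (average precision)
#'
#' @inheritParams compute_auc
#' @export
compute_pr_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  if (!any(positive)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  precision <- cumsum(pos) / seq_along(pos)
  # average precision: mean precision at each positive hit
  mean(precision[pos])
}

#' Per-class score cutoff at a target specificity
#'
#' The smallest observed score threshold under which at least `specificity`
#' of the class's negatives fall.  When no observed score qualifies (e.g.
#' specificity 1), the cutoff sits just above the highest negative score.
#'
#' @param scores Validation scores for one class.
#' @param positive Logical class membership.
#' @param specificity Target specificity (default 0.95).
#' @return A scalar cutoff in (0, 1].
#' @export
specificity_cutoff <- function(scores, positive, specificity = 0.95) {
  neg <- scores[!as.logical(positive)]
  if (length(neg) == 0L) abort("no negatives to set a specificity cutoff")
  cand <- sort(unique(neg))
  frac_below <- vapply(cand, function(t) mean(neg < t), 0)
  ok <- cand[frac_below >= specificity]
  if (length(ok)) return(min(ok))
  max(neg) + 1e-9
}

#' Standardized class probabilities
#'
#' Raw sigmoid scores are divided by the per-class 95%-specificity cutoffs
#' (intermediate scores), then normalised to sum to one.
#'
#' @param scores `N x 3` raw score matrix (or length-3 vector).
#' @param cutoffs Length-3 positive cutoff vector.
#' @return Matrix (or vector) of probabilities summing to 1 per sample.
#' @export
standardize_probability <- function(scores, cutoffs) {
  if (any(cutoffs <= 0)) abort("cutoffs must be positive")
  vec <- is.null(dim(scores))
  if (vec) scores <- matrix(scores, nrow = 1L)
  m <- sweep(scores, 2L, cutoffs, "/")
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warning("all intermediate scores zero; returning uniform probabilities",
            call. = FALSE)
    m[zero, ] <- 1
    tot[zero] <- ncol(m)
  }
  p <- m / tot
  colnames(p) <- colnames(scores)
  if (vec) p[1L, ] else p
}

#' Transcriptome-wide evaluation against relaxed truth labels
#'
#' Recruits triplets whose psi lies in \[0.01, 0.99\] before or after
#' treatment, relabels them with the relaxed thresholds (delta-psi >= 0.01
#' inclusion, <= -0.01 exclusion, otherwise unchanged) and reports per-class
#' ROC and PR AUC of the model scores against those labels.
#'
#' @param scores `N x 3` raw model scores, rows matching `psi_before`.
#' @param psi_before,psi_after Per-triplet mean psi by condition.
#' @return A list: `recruited` (logical), `labels`, and a per-class
#'   data.frame `auc` with `roc_auc` and `pr_auc`.
#' @export
evaluate_transcriptome <- function(scores, psi_before, psi_after) {
  recruited <- (psi_before >= 0.01 & psi_before <= 0.99) |
    (psi_after >= 0.01 & psi_after <= 0.99)
  recruited[is.na(recruited)] <- FALSE
  d <- psi_after - psi_before
  labels <- ifelse(d >= 0.01, "inclusion",
            ifelse(d <= -0.01, "exclusion", "unchanged"))
  lab <- labels[recruited]
  sc <- scores[recruited, , drop = FALSE]
  auc <- data.frame(
    class = RESPONSE_CLASSES,
    roc_auc = vapply(RESPONSE_CLASSES, function(cl)
      compute_auc(sc[, cl], lab == cl), 0),
    pr_auc = vapply(RESPONSE_CLASSES, function(cl)
      compute_pr_auc(sc[, cl], lab == cl), 0),
    row.names = NULL
  )
  list(recruited = recruited, labels = labels, auc = auc)
}

#' Random-initialization stability analysis
#'
#' Retrains the network from `n_seeds` different initial parameter draws
#' (same split, same data) and reports the mean test AUC per seed, plus, for
#' each of the reference model's top contributing first-layer filters, the
#' best squared Pearson correlation between its position probability matrix
#' and any filter PPM of each reseeded model.
#'
#' @param data List with `x_train`, `y_train`, `x_val`, `y_val`, `x_test`,
#'   `y_test`.
#' @param config Network configuration used for every run.
#' @param n_seeds Number of reseeded runs (desk-scale default 20).
#' @param reference Optionally a pre-trained reference model.
#' @param n_top Number of top reference filters to track (default 10).
#' @return A list: `auc` (per-seed mean test AUC), `filter_r2` (per-seed mean
#'   best r^2 over tracked filters), `reference`.
#' @export
stability_analysis <- function(data, config = cnn_config(), n_seeds = 20,
                               reference = NULL, n_top = 10) {
  if (is.null(reference)) {
    reference <- train_cnn(build_model(config), data$x_train, data$y_train,
                           data$x_val, data$y_val)
  }
  contrib <- motif_contribution(reference, data$x_test, data$y_test)
  top <- head(order(-contrib$max_dauc), n_top)
  ref_ppm <- filter_to_ppm(reference, data$x_test)
  auc <- numeric(n_seeds); r2 <- numeric(n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    m <- train_cnn(build_model(cfg_i), data$x_train, data$y_train,
                   data$x_val, data$y_val)
    auc[i] <- mean_auc(cnn_forward(m, data$x_test)$scores, data$y_test)
    ppm_i <- filter_to_ppm(m, data$x_test)
    r2[i] <- mean(vapply(top, function(f) {
      max(vapply(ppm_i$ppm, function(q)
        correlate_ppm(ref_ppm$ppm[[f]], q)$r2, 0))
    }, 0))
  }
  list(auc = auc, filter_r2 = r2, reference = reference)
}
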