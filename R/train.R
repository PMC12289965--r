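#' Architecture specification
#'
#' Desk-scale analogs of the four architecture families: convolutional +
#' recurrent (VGG-LSTM-like), video attention (ViViT-like), and their
#' single-timepoint counterparts (conv and patch-attention, VGG/ViT-like).
#' All share the fixed conv stem; the trainable head differs. Temporal
#' variants require more than one timepoint.
#'
#' @param variant one of `"CONV_RECURRENT"`, `"VIDEO_ATTENTION"`,
#'   `"SINGLE_FRAME_CONV"`, `"SINGLE_FRAME_ATTENTION"`.
#' @param input_shape integer vector `(T, Z, H, W)`.
#' @param width hidden width of the trainable head.
#' @return an `arch_spec`.
#' @export
arch_spec <- function(variant = "SINGLE_FRAME_CONV",
                      input_shape = c(1L, 8L, 128L, 128L),
                      width = 64L) {
  variant <- match.arg(variant, c("CONV_RECURRENT", "VIDEO_ATTENTION",
                                  "SINGLE_FRAME_CONV",
                                  "SINGLE_FRAME_ATTENTION"))
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 4L, all(input_shape >= 1L))
  temporal <- variant %in% c("CONV_RECURRENT", "VIDEO_ATTENTION")
  if (temporal && input_shape[1] < 2L)
    stop(variant, " requires T > 1")
  if (!temporal && input_shape[1] != 1L)
    stop(variant, " requires T == 1")
  structure(list(variant = variant, input_shape = input_shape,
                 width = as.integer(width)),
            class = "arch_spec")
}

#' Training configuration
#'
#' Mirrors the published protocol: Adam-style updates at learning rate 1e-5,
#' binary cross-entropy loss, 15 percent of the data held out for test, 20
#' percent of the remainder for validation, early stopping on the validation
#' loss, and checkpointing of the best-validation model.
#'
#' @param learning_rate Adam learning rate.
#' @param test_fraction fraction of data for the test split.
#' @param val_fraction fraction of the remainder for validation.
#' @param patience epochs without validation improvement before stopping.
#' @param max_epochs hard cap on epochs.
#' @param batch_size minibatch size.
#' @param seed integer seed for init and shuffling.
#' @return a `train_config`.
#' @export
train_config <- function(learning_rate = 1e-5, test_fraction = 0.15,
                         val_fraction = 0.20, patience = 10L,
                         max_epochs = 200L, batch_size = 4L, seed = 0L) {
  stopifnot(learning_rate > 0, patience >= 1, max_epochs >= 1,
            batch_size >= 1,
            test_fraction > 0, test_fraction < 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 test_fraction = test_fraction, val_fraction = val_fraction,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Featurize a list of examples for an architecture; returns the batch
# structure plus labels.
featurize_set <- function(examples, variant) {
  feats <- lapply(examples, function(e) featurize_tensor(e$tensor, variant))
  y <- vapply(examples, `[[`, integer(1), "label")
  if (variant == "SINGLE_FRAME_CONV") {
    list(X = do.call(rbind, feats), y = y)
  } else if (variant == "CONV_RECURRENT") {
    Tn <- nrow(feats[[1]]); d <- ncol(feats[[1]])
    X <- array(0, dim = c(length(feats), Tn, d))
    for (i in seq_along(feats)) X[i, , ] <- feats[[i]]
    list(X = X, y = y)
  } else {
    list(X = feats, y = y)
  }
}

feat_stats <- function(batch, variant) {
  M <- switch(variant,
    SINGLE_FRAME_CONV = batch$X,
    CONV_RECURRENT = {
      d <- dim(batch$X)
      matrix(batch$X, d[1] * d[2], d[3])
    },
    do.call(rbind, batch$X))
  mu <- colMeans(M)
  sdv <- apply(M, 2, sd)
  sdv[sdv < 1e-9] <- 1
  list(mu = mu, sd = sdv)
}

standardize_batch <- function(batch, stats, variant) {
  if (variant == "SINGLE_FRAME_CONV") {
    batch$X <- sweep(sweep(batch$X, 2, stats$mu), 2, stats$sd, `/`)
  } else if (variant == "CONV_RECURRENT") {
    d <- dim(batch$X)
    for (t in seq_len(d[2])) {
      M <- matrix(batch$X[, t, ], d[1], d[3])
      batch$X[, t, ] <- sweep(sweep(M, 2, stats$mu), 2, stats$sd, `/`)
    }
  } else {
    batch$X <- lapply(batch$X, function(A)
      sweep(sweep(A, 2, stats$mu), 2, stats$sd, `/`))
  }
  batch
}

subset_batch <- function(batch, i, variant) {
  if (variant == "SINGLE_FRAME_CONV") batch$X[i, , drop = FALSE]
  else if (variant == "CONV_RECURRENT") batch$X[i, , , drop = FALSE]
  else batch$X[i]
}

head_for <- function(arch, batch) {
  switch(arch$variant,
    SINGLE_FRAME_CONV = make_mlp_head(ncol(batch$X), arch$width),
    CONV_RECURRENT = make_rnn_head(dim(batch$X)[3], arch$width),
    SINGLE_FRAME_ATTENTION = make_attn_head(ncol(batch$X[[1]])),
    VIDEO_ATTENTION = make_attn_head(ncol(batch$X[[1]])))
}

#' Train a classifier
#'
#' Minibatch Adam on binary cross-entropy over the trainable head, with
#' early stopping on the validation loss (stop after `patience` epochs
#' without improvement) and checkpointing: the returned model carries the
#' parameters with the minimum validation loss, not the final ones. All
#' randomness (init, shuffling) derives from `cfg$seed`. Examples must
#' already be per-image normalized; the stem applies [normalize_image()]
#' internally, making training invariant to per-image affine rescaling.
#'
#' @param train,val lists of `labeled_example`s.
#' @param arch an [arch_spec()].
#' @param cfg a [train_config()].
#' @return an `sdm_model`: best parameters, arch, feature normalization
#'   contract, decision threshold (0.5) and the training history.
#' @export
train_classifier <- function(train, val, arch, cfg = train_config()) {
  stopifnot(inherits(arch, "arch_spec"), inherits(cfg, "train_config"),
            length(train) > 0, length(val) > 0)
  variant <- arch$variant
  tb <- featurize_set(train, variant)
  vb <- featurize_set(val, variant)
  stats <- feat_stats(tb, variant)
  tb <- standardize_batch(tb, stats, variant)
  vb <- standardize_batch(vb, stats, variant)

  head <- head_for(arch, tb)
  par <- head$init(derive_seed(cfg$seed, "init"))
  state <- NULL
  n <- length(tb$y)
  best <- list(par = par, val_loss = Inf, epoch = 0L)
  waited <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())

  with_seed(derive_seed(cfg$seed, "shuffle"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- base::sample(n)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        i <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- subset_batch(tb, i, variant)
        fw <- head$fwd(par, Xb)
        l <- bce_with_logits(fw$z, tb$y[i])
        if (!is.finite(l$loss))
          stop("training diverged: non-finite loss at epoch ", epoch)
        grad <- head$bwd(par, Xb, fw$cache, l$dz)
        upd <- adam_step(par, grad, state, cfg$learning_rate)
        par <- upd$par; state <- upd$state
        ep_loss <- ep_loss + l$loss; n_batches <- n_batches + 1L
      }
      vl <- bce_with_logits(head$fwd(par, vb$X)$z, vb$y)$loss
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = ep_loss / n_batches,
                                  val_loss = vl))
      if (vl < best$val_loss) {
        best <- list(par = par, val_loss = vl, epoch = epoch)
        waited <- 0L
      } else {
        waited <- waited + 1L
        if (waited >= cfg$patience) break
      }
    }
  })

  structure(list(par = best$par, arch = arch, cfg = cfg,
                 feat_stats = stats, decision_threshold = 0.5,
                 best_epoch = best$epoch, val_loss = best$val_loss,
                 history = history),
            class = "sdm_model")
}

#' Predict on a single example tensor
#'
#' Deterministic at inference; the label is `score >= decision_threshold`
#' (ties go to the positive class).
#'
#' @param model an `sdm_model`.
#' @param tensor a `T x Z x H x W` array matching the model's input shape.
#' @return named numeric vector `c(score, label)` with `score` in `[0, 1]`.
#' @export
predict_example <- function(model, tensor) {
  UseMethod("predict_example")
}

#' @export
predict_example.sdm_model <- function(model, tensor) {
  if (!identical(dim(tensor), as.integer(model$arch$input_shape)))
    stop(sprintf("input shape (%s) does not match model (%s)",
                 paste(dim(tensor), collapse = "x"),
                 paste(model$arch$input_shape, collapse = "x")))
  variant <- model$arch$variant
  f <- featurize_tensor(tensor, variant)
  batch <- if (variant == "SINGLE_FRAME_CONV") list(X = matrix(f, 1))
           else if (variant == "CONV_RECURRENT") {
             X <- array(0, dim = c(1L, nrow(f), ncol(f))); X[1, , ] <- f
             list(X = X)
           } else list(X = list(f))
  batch <- standardize_batch(batch, model$feat_stats, variant)
  head <- head_for(model$arch, batch)
  z <- head$fwd(model$par, batch$X)$z
  score <- stats::plogis(z)
  c(score = score, label = as.numeric(score >= model$decision_threshold))
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("sdm_model [%s] %d params, best epoch %d (val loss %.4f)\n",
              x$arch$variant, length(x$par), x$best_epoch, x$val_loss))
  invisible(x)
}
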