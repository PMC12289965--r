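test_that("normalize_image rescales, handles degenerate input, is idempotent", {
  expect_equal(normalize_image(matrix(c(0, 5, 10), 1)),
               matrix(c(0, 0.5, 1), 1))
  expect_equal(normalize_image(matrix(7, 3, 3)), matrix(0, 3, 3))
  set.seed(1)
  for (k in 1:5) {
    x <- matrix(rnorm(64, sd = 10), 8, 8)
    expect_equal(normalize_image(normalize_image(x)), normalize_image(x))
  }
  expect_error(normalize_image(c(1, NA)), "non-finite")
  expect_error(normalize_image(c(1, Inf)), "non-finite")
})

test_that("split_dataset follows the floor convention and is leakage-free", {
  ds <- simulate_onset_dataset(tiny_config(), 71, 68, T = 1, Z = 1, seed = 0)
  sp <- split_dataset(ds, 0.15, 0.20, seed = 0)
  expect_length(sp$test, 20)   # floor(139 * 0.15)
  expect_length(sp$val, 23)    # floor(119 * 0.20)
  expect_length(sp$train, 96)

  idx <- sp$index
  expect_identical(sort(idx$example), 1:139)  # disjoint and exhaustive
  # stratified to +/- 1 example per class
  for (part in c("test", "val")) {
    got <- sum(idx$label[idx$split == part])
    want <- sum(idx$label) * sum(idx$split == part) / nrow(idx)
    expect_lte(abs(got - want), 1)
  }
  # cell-disjoint: no cell straddles splits
  expect_true(all(tapply(idx$split, idx$cell,
                         function(s) length(unique(s))) == 1))

  expect_identical(split_dataset(ds, seed = 5)$index,
                   split_dataset(ds, seed = 5)$index)
  expect_error(split_dataset(ds, test_fraction = 0), "test_fraction")
  one_class <- ds$examples[vapply(ds$examples, `[[`, integer(1),
                                  "label") == 1]
  expect_error(split_dataset(one_class), "both classes")
})

test_that("compute_metrics matches direct formulas on random matrices", {
  # the smallest integer matrix reproducing the printed headline metrics
  m <- compute_metrics(list(tp = 9, fn = 2, fp = 0, tn = 11))
  expect_equal(m$precision, 1.0)
  expect_equal(round(m$recall, 2), 0.82)
  expect_equal(round(m$f1, 1), 0.9)
  expect_equal(round(m$accuracy, 2), 0.91)

  m1 <- compute_metrics(list(tp = 1, fp = 0, fn = 0, tn = 1))
  expect_equal(unlist(m1[c("precision", "recall", "f1", "accuracy")]),
               c(precision = 1, recall = 1, f1 = 1, accuracy = 1))

  # harmonic-mean identity at the printed precision/recall
  expect_equal(2 * 1.0 * 0.82 / (1.0 + 0.82), 0.901, tolerance = 1e-3)

  set.seed(42)
  for (i in 1:1000) {
    cm <- as.list(setNames(rmultinom(1, sample(1:50, 1), rep(1, 4))[, 1],
                           c("tp", "fp", "fn", "tn")))
    m <- compute_metrics(cm)
    p_ref <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else NA_real_
    r_ref <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_
    f_ref <- if (!is.na(p_ref) && !is.na(r_ref) && p_ref + r_ref > 0)
      2 * p_ref * r_ref / (p_ref + r_ref) else NA_real_
    expect_identical(m$precision, p_ref)
    expect_identical(m$recall, r_ref)
    expect_identical(m$f1, f_ref)
    expect_identical(m$accuracy, (cm$tp + cm$tn) / Reduce(`+`, cm))
  }
})

test_that("degenerate predictors flag undefined metrics correctly", {
  cm <- confusion_matrix(predicted = rep(0, 10),
                         truth = c(rep(1, 4), rep(0, 6)))
  m <- compute_metrics(cm)
  expect_identical(m$recall, 0)
  expect_true(is.na(m$precision))  # no positive predictions
  expect_true(is.na(m$f1))

  # random predictor on a balanced set stays within binomial noise of 0.5
  set.seed(7)
  truth <- rep(0:1, 500)
  pred <- rbinom(1000, 1, 0.5)
  acc <- compute_metrics(confusion_matrix(pred, truth))$accuracy
  expect_lt(abs(acc - 0.5), 0.05)
})

test_that("head gradients match finite differences", {
  set.seed(3)
  check <- function(head, batch, y) {
    par <- head$init(1)
    # move off the zero-init readout so all gradient paths are active
    par <- par + rnorm(length(par), sd = 0.05)
    fw <- head$fwd(par, batch)
    l <- sdmscope:::bce_with_logits(fw$z, y)
    g <- head$bwd(par, batch, fw$cache, l$dz)
    eps <- 1e-6
    idx <- sample(length(par), min(30, length(par)))
    num <- vapply(idx, function(i) {
      p2 <- par; p2[i] <- p2[i] + eps
      (sdmscope:::bce_with_logits(head$fwd(p2, batch)$z, y)$loss - l$loss) /
        eps
    }, numeric(1))
    max(abs(num - g[idx]))
  }
  y <- rep(0:1, 4)
  expect_lt(check(sdmscope:::make_mlp_head(5, 4),
                  matrix(rnorm(40), 8, 5), y), 1e-5)
  expect_lt(check(sdmscope:::make_rnn_head(5, 4),
                  array(rnorm(120), c(8, 3, 5)), y), 1e-5)
  expect_lt(check(sdmscope:::make_attn_head(4),
                  lapply(1:8, function(i) matrix(rnorm(24), 6, 4)), y), 1e-5)
})

test_that("training separates a feature-separable toy problem", {
  ex <- toy_examples(20)
  sp <- split_dataset(ex, 0.25, 0.25, seed = 1)
  arch <- arch_spec("SINGLE_FRAME_CONV", c(1, 1, 64, 64), width = 16)
  m <- train_classifier(sp$train, sp$val, arch, train_config(seed = 1))
  ev <- evaluate(m, sp$test)
  expect_equal(ev$metrics$accuracy, 1.0)
})

test_that("all four architecture variants train and predict", {
  cfg <- tiny_config()
  ds <- simulate_onset_dataset(cfg, 10, 10, T = 3, Z = 2, seed = 2)
  sp <- split_dataset(ds, 0.2, 0.25, seed = 2)
  short <- train_config(seed = 2, max_epochs = 15)
  for (variant in c("CONV_RECURRENT", "VIDEO_ATTENTION")) {
    arch <- arch_spec(variant, c(3, 2, 64, 64), width = 8)
    m <- train_classifier(sp$train, sp$val, arch, short)
    pr <- predict_example(m, sp$test[[1]]$tensor)
    expect_true(pr[["score"]] >= 0 && pr[["score"]] <= 1)
  }
  ds1 <- simulate_onset_dataset(cfg, 10, 10, T = 1, Z = 2, seed = 2)
  sp1 <- split_dataset(ds1, 0.2, 0.25, seed = 2)
  arch <- arch_spec("SINGLE_FRAME_ATTENTION", c(1, 2, 64, 64), width = 8)
  m <- train_classifier(sp1$train, sp1$val, arch, short)
  expect_s3_class(m, "sdm_model")

  # shape contracts
  expect_error(arch_spec("CONV_RECURRENT", c(1, 2, 64, 64)), "T > 1")
  expect_error(arch_spec("SINGLE_FRAME_CONV", c(3, 2, 64, 64)), "T == 1")
  expect_error(predict_example(m, array(0, c(2, 2, 64, 64))), "shape")
})

test_that("prediction is deterministic with ties going positive", {
  ex <- toy_examples(6)
  sp <- split_dataset(ex, 0.25, 0.25, seed = 3)
  arch <- arch_spec("SINGLE_FRAME_CONV", c(1, 1, 64, 64), width = 4)
  m <- train_classifier(sp$train, sp$val, arch,
                        train_config(seed = 3, max_epochs = 5))
  p1 <- predict_example(m, ex[[1]]$tensor)
  p2 <- predict_example(m, ex[[1]]$tensor)
  expect_identical(p1, p2)

  # decision threshold: score exactly at threshold maps to label 1
  m0 <- m
  m0$par[] <- 0  # zero head emits score exactly 0.5
  expect_identical(predict_example(m0, ex[[1]]$tensor)[["label"]], 1)
})

test_that("no signal is found when the cue is absent", {
  cfg <- tiny_config(cue_contrast = 0)
  ds <- simulate_onset_dataset(cfg, 22, 18, T = 1, Z = 1, seed = 4)
  sp <- split_dataset(ds, 0.2, 0.25, seed = 4)
  arch <- arch_spec("SINGLE_FRAME_CONV", c(1, 1, 64, 64))
  m <- train_classifier(sp$train, sp$val, arch, train_config(seed = 4))
  acc <- evaluate(m, sp$test)$metrics$accuracy
  y <- vapply(sp$test, `[[`, integer(1), "label")
  majority <- max(mean(y), 1 - mean(y))
  # within binomial noise of the majority rate
  expect_lte(acc, majority + 3 * sqrt(0.25 / length(y)))
})

test_that("accuracy and scores increase with cue contrast", {
  seeds_fixed <- 6
  levels <- c(0.15, 0.45, 0.9)
  datasets <- lapply(levels, function(cc)
    simulate_onset_dataset(tiny_config(cue_contrast = cc), 16, 16,
                           T = 1, Z = 1, seed = seeds_fixed))
  splits <- lapply(datasets, split_dataset, seed = seeds_fixed)
  arch <- arch_spec("SINGLE_FRAME_CONV", c(1, 1, 64, 64))
  accs <- vapply(splits, function(sp) {
    m <- train_classifier(sp$train, sp$val, arch,
                          train_config(seed = seeds_fixed))
    evaluate(m, sp$test)$metrics$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))

  # a fixed model's mean event score is monotone in cue contrast
  m_mid <- train_classifier(splits[[2]]$train, splits[[2]]$val, arch,
                            train_config(seed = seeds_fixed))
  mean_event_score <- vapply(datasets, function(ds) {
    ev <- ds$examples[vapply(ds$examples, `[[`, integer(1), "label") == 1]
    mean(vapply(ev, function(e)
      predict_example(m_mid, e$tensor)[["score"]], numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_event_score) > 0))
})
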