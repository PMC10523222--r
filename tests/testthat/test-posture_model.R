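test_that("architecture shapes: valid convolutions shrink time by 8, layer sizes match", {
  m <- build_model(posture_config(seed = 3))
  ## first conv layer: 20 channels, kernel 5, 32 filters
  expect_equal(length(m$params$conv[[1]]$W) + length(m$params$conv[[1]]$b),
               20 * 32 * 5 + 32)   # 3232 trainable parameters
  expect_equal(dim(m$params$conv[[2]]$W), c(3 * 32, 64))
  expect_equal(dim(m$params$conv[[3]]$W), c(3 * 64, 64))
  ## BiLSTM 64 outputs = 32 per direction; FC 32 wide; softmax over 2
  expect_equal(dim(m$params$lstm_fwd$Wh), c(32, 128))
  expect_equal(dim(m$params$fc$W), c(64, 32))
  expect_equal(dim(m$params$out$W), c(32, 2))

  ## temporal trace: T rows in, T - 8 after the three valid convolutions
  for (T_ in c(9, 20, 59)) {
    X <- matrix(rnorm(T_ * 20), T_, 20)
    fw <- squatcheck:::model_forward(m$params, m$config, X)
    expect_equal(fw$caches$lstm$Tc, T_ - 8)
    expect_length(fw$probs, 2)
  }
})

test_that("ablation variants drop the right blocks", {
  lo <- build_model(posture_config(variant = "lstm_only", seed = 1))
  expect_null(lo$params$conv)                 # zero convolution parameters
  expect_equal(dim(lo$params$lstm_fwd$Wx), c(20, 128))
  co <- build_model(posture_config(variant = "conv_only", seed = 1))
  expect_null(co$params$lstm_fwd)
  expect_null(co$params$lstm_bwd)
})

test_that("analytic gradients match finite differences for every variant", {
  for (variant in c("full", "conv_only", "lstm_only")) {
    cfg <- posture_config(variant = variant, conv_kernels = c(3L, 2L),
                          conv_filters = c(4L, 5L), lstm_units = 6L,
                          fc_units = 4L, dropout = 0, seed = 6)
    m <- build_model(cfg)
    set.seed(5)
    X <- matrix(rnorm(12 * 20), 12, 20)
    lg <- squatcheck:::loss_and_grads(m$params, cfg, X, 1L, training = TRUE)
    flat <- unlist(m$params)
    gflat <- unlist(lg$grads)
    lossf <- function(v) {
      squatcheck:::loss_and_grads(utils::relist(v, m$params), cfg, X, 1L,
                                  training = TRUE)$loss
    }
    idx <- sample(length(flat), 30)
    eps <- 1e-5
    num <- vapply(idx, function(i) {
      vp <- flat; vp[i] <- vp[i] + eps
      vm <- flat; vm[i] <- vm[i] - eps
      (lossf(vp) - lossf(vm)) / (2 * eps)
    }, 0)
    denom <- pmax(abs(num) + abs(gflat[idx]), 1e-6)
    expect_lt(max(abs(num - gflat[idx]) / denom), 1e-4)
    expect_gt(mean(abs(gflat[idx]) > 0), 0.5)   # probes are not trivially zero
  }
})

test_that("metrics match a brute-force confusion oracle on random predictions", {
  set.seed(77)
  for (trial in 1:100) {
    n <- sample(3:60, 1)
    pred <- sample(c("correct", "incorrect"), n, replace = TRUE)
    truth <- sample(c("correct", "incorrect"), n, replace = TRUE)
    got <- confusion_report(pred, truth)
    want <- oracle_metrics(pred, truth)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(sum(got$confusion), n)
  }
  ## hand-checked confusion: TP=87 FP=13 FN=16 TN=84
  pred <- c(rep("correct", 87), rep("incorrect", 16),
            rep("correct", 13), rep("incorrect", 84))
  truth <- c(rep("correct", 103), rep("incorrect", 97))
  r <- confusion_report(pred, truth)
  expect_equal(r$precision, 0.87)
  expect_equal(r$recall, 87 / 103, tolerance = 1e-12)
  expect_equal(r$accuracy, (87 + 84) / 200)
  ## degenerate predictors
  expect_equal(confusion_report(truth, truth)$accuracy, 1)
  allpos <- confusion_report(rep("correct", 200), truth)
  expect_equal(allpos$recall, 1)
  expect_equal(allpos$accuracy, 103 / 200)
})

test_that("training learns separable data; classify is a deterministic softmax", {
  ds <- simulate_dataset(25, n_subjects_per_class = 5, seed = 301)
  sp <- split_by_subject(ds, seed = 301)
  tr <- featurize(sp$train); va <- featurize(sp$val); te <- featurize(sp$test)
  cfg <- posture_config(conv_filters = c(16L, 24L, 24L), lstm_units = 32L,
                        fc_units = 16L, batch_size = 8L, max_epochs = 50L,
                        patience = 8L, seed = 5L)
  m <- train_model(build_model(cfg), tr, val_data = va)
  expect_true(m$trained)
  expect_gte(max(m$history$val_accuracy), 0.95)
  expect_lte(nrow(m$history), 50)

  ## held-out correct squat scores above 0.5; softmax sums to 1
  correct_te <- Filter(function(d) d$y == "correct", te)
  sc <- classify(m, correct_te[[1]]$x)
  expect_gt(sc, 0.5)
  probs <- squatcheck:::model_forward(m$params, m$config, correct_te[[1]]$x)$probs
  expect_equal(sum(probs), 1, tolerance = 1e-6)
  expect_identical(classify(m, correct_te[[1]]$x), sc)   # deterministic

  ## evaluation is invariant to dataset order
  ev1 <- evaluate_model(m, te)
  ev2 <- evaluate_model(m, rev(te))
  expect_equal(ev1$accuracy, ev2$accuracy)
  expect_equal(ev1$confusion, ev2$confusion)
})

test_that("zero learning rate freezes the loss; single-class data is refused", {
  ds <- simulate_dataset(6, n_subjects_per_class = 2, seed = 55)
  feats <- featurize(ds)
  cfg <- posture_config(learning_rate = 0, dropout = 0, max_epochs = 3L,
                        patience = 10L, conv_filters = c(8L, 8L, 8L),
                        lstm_units = 8L, fc_units = 4L, seed = 2L)
  m <- train_model(build_model(cfg), feats, val_data = feats[1:2])
  expect_equal(m$history$train_loss,
               rep(m$history$train_loss[1], nrow(m$history)), tolerance = 1e-12)

  onecls <- Filter(function(d) d$y == "correct", feats)
  expect_error(train_model(build_model(cfg), onecls, val_data = feats[1:2]),
               "both classes")
})

test_that("too-short inputs are refused with the minimum length named", {
  m <- build_model(posture_config(seed = 1))
  X <- matrix(0, 5, 20)
  expect_error(classify(m, X), "at least 9")
  lo <- build_model(posture_config(variant = "lstm_only", seed = 1))
  expect_silent(classify(lo, X))   # no convolutions: any length >= 1 works
  expect_error(classify(m, matrix(0, 30, 12)), "20 channels")
})

test_that("grid search selects the learnable configuration", {
  ds <- simulate_dataset(12, n_subjects_per_class = 3, seed = 71)
  sp <- split_by_subject(ds, seed = 71)
  tr <- featurize(sp$train); va <- featurize(sp$val)
  base <- posture_config(variant = "conv_only", conv_kernels = c(3L, 3L),
                         conv_filters = c(8L, 8L), fc_units = 4L,
                         dropout = 0, max_epochs = 12L, patience = 12L,
                         seed = 3L)
  gs <- grid_search(tr, va, grid = list(learning_rate = c(0, 0.003)),
                    base_cfg = base)
  expect_equal(nrow(gs$results), 2)              # product of grid sizes
  expect_equal(gs$best_config$learning_rate, 0.003)
  one <- grid_search(tr, va, grid = list(dropout = 0.1), base_cfg = base)
  expect_equal(one$best_config$dropout, 0.1)     # singleton grid returns itself
})

test_that("model checkpoints round-trip through JSON and guard channel order", {
  m <- tiny_trained_model()
  f <- withr::local_tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  expect_true(m2$trained)
  set.seed(10)
  X <- featurize(simulate_dataset(2, n_subjects_per_class = 1, seed = 9))[[1]]$x
  expect_equal(classify(m2, X), classify(m, X), tolerance = 1e-12)

  ## tamper with the stored channel order: refuse to load
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$channels <- rev(obj$channels)
  f2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f2, digits = NA, auto_unbox = TRUE)
  expect_error(load_model(f2), "channel order")
})
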