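## Shared fixtures and independent oracles for the test suite.

## A minimal 10-joint standing pose at a given hip position/torso length.
standing_pose <- function(hip = c(500, 600), torso = 200) {
  jx <- c(Neck = hip[1], MidHip = hip[1],
          LShoulder = hip[1] - 60, RShoulder = hip[1] + 60,
          LHip = hip[1] - 40, RHip = hip[1] + 40,
          LKnee = hip[1] - 44, RKnee = hip[1] + 44,
          LAnkle = hip[1] - 44, RAnkle = hip[1] + 44)
  jy <- c(Neck = hip[2] - torso, MidHip = hip[2],
          LShoulder = hip[2] - torso, RShoulder = hip[2] - torso,
          LHip = hip[2], RHip = hip[2],
          LKnee = hip[2] + 145, RKnee = hip[2] + 145,
          LAnkle = hip[2] + 290, RAnkle = hip[2] + 290)
  list(x = jx, y = jy)
}

## k identical frames of the standing pose (a motionless sequence).
constant_sequence <- function(k, hip = c(500, 600), torso = 200, fps = 30) {
  p <- standing_pose(hip, torso)
  skeleton_sequence(matrix(p$x, k, 10, byrow = TRUE,
                           dimnames = list(NULL, names(p$x))),
                    matrix(p$y, k, 10, byrow = TRUE), fps = fps)
}

## Independent Gaussian-smoothing oracle: explicit reflection padding and
## a double loop, no shared code with the implementation.
oracle_gauss_smooth <- function(v, sigma) {
  r <- ceiling(4 * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  n <- length(v)
  fold <- function(i) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i          # "b a | a b": index 0 maps to 1
      if (i > n) i <- 2 * n + 1 - i  # index n+1 maps to n
    }
    i
  }
  out <- numeric(n)
  for (t in seq_len(n)) {
    s <- 0
    for (d in -r:r) s <- s + w[d + r + 1] * v[fold(t + d)]
    out[t] <- s
  }
  out
}

## Independent confusion-matrix oracle: per-element counting loop.
oracle_metrics <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(pred)) {
    if (truth[i] == "correct" && pred[i] == "correct") tp <- tp + 1
    if (truth[i] == "incorrect" && pred[i] == "correct") fp <- fp + 1
    if (truth[i] == "correct" && pred[i] == "incorrect") fn <- fn + 1
    if (truth[i] == "incorrect" && pred[i] == "incorrect") tn <- tn + 1
  }
  list(accuracy = (tp + tn) / length(pred),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

## Preprocess a labeled dataset once into (x, y) training form.
featurize <- function(dataset, pp_cfg = preprocess_config()) {
  lapply(dataset, function(d) list(x = preprocess(d$seq, pp_cfg), y = d$label))
}

## A small trained model on clearly separated data, built once per session
## and reused by the feedback and pipeline tests.
.tiny_model_cache <- new.env(parent = emptyenv())
tiny_trained_model <- function() {
  if (!is.null(.tiny_model_cache$model)) return(.tiny_model_cache$model)
  ds <- simulate_dataset(30, n_subjects_per_class = 5, seed = 2024)
  sp <- split_by_subject(ds, seed = 2024)
  cfg <- posture_config(conv_filters = c(16L, 24L, 24L), lstm_units = 32L,
                        fc_units = 16L, batch_size = 8L, max_epochs = 30L,
                        patience = 8L, seed = 11L)
  m <- train_model(build_model(cfg), featurize(sp$train),
                   val_data = featurize(sp$val))
  .tiny_model_cache$model <- m
  m
}
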