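#' Posture classifier configuration
#'
#' Hyperparameters of the squat-posture classifier. The default
#' architecture is three temporal (1D) convolution layers with kernel
#' depths 5, 3, 3 and 32, 64, 64 filters, a bidirectional LSTM with 64
#' outputs (32 hidden units per direction, final states concatenated), a
#' 32-unit fully connected layer, and a 2-class softmax; trained with Adam
#' at learning rate 0.003 and dropout 0.3. Two ablation variants are
#' available: `conv_only` replaces the LSTM with temporal mean-pooling,
#' `lstm_only` drops the convolution stack.
#'
#' @param variant `"full"`, `"conv_only"` or `"lstm_only"`.
#' @param conv_kernels temporal kernel depths per convolution layer.
#' @param conv_filters filter counts per convolution layer.
#' @param lstm_units total bidirectional LSTM output width (split evenly
#'   across the two directions; must be even).
#' @param fc_units fully connected layer width.
#' @param dropout dropout rate in `[0, 1)`, active only during training.
#' @param learning_rate Adam learning rate (> 0, or 0 to freeze weights).
#' @param n_classes number of output classes (2: correct / incorrect).
#' @param conv_padding `"valid"` only (stride 1); each layer shortens the
#'   sequence by `kernel - 1` steps.
#' @param batch_size sequences per optimizer step.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience on validation accuracy.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return a validated list of class `posture_config`.
#' @export
posture_config <- function(variant = c("full", "conv_only", "lstm_only"),
                           conv_kernels = c(5L, 3L, 3L),
                           conv_filters = c(32L, 64L, 64L),
                           lstm_units = 64L, fc_units = 32L,
                           dropout = 0.3, learning_rate = 0.003,
                           n_classes = 2L, conv_padding = "valid",
                           batch_size = 32L, max_epochs = 100L,
                           patience = 10L, seed = 1L) {
  variant <- match.arg(variant)
  if (length(conv_kernels) != length(conv_filters)) {
    stop("conv_kernels and conv_filters must have equal length", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)", call. = FALSE)
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  if (lstm_units %% 2L != 0L) stop("lstm_units must be even (bidirectional)",
                                   call. = FALSE)
  if (!identical(conv_padding, "valid")) {
    stop("only 'valid' convolution padding is implemented", call. = FALSE)
  }
  structure(list(variant = variant,
                 conv_kernels = as.integer(conv_kernels),
                 conv_filters = as.integer(conv_filters),
                 lstm_units = as.integer(lstm_units),
                 fc_units = as.integer(fc_units), dropout = dropout,
                 learning_rate = learning_rate,
                 n_classes = as.integer(n_classes),
                 conv_padding = conv_padding,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "posture_config")
}

#' Build an untrained posture model
#'
#' Initializes weights (Glorot-uniform, forget-gate biases at 1) for the
#' configured variant. The model records the expected 20-channel layout so
#' that feature tensors from a differently configured preprocessing
#' pipeline are refused at classification time.
#'
#' @param cfg a [posture_config()].
#' @return an object of class `posture_model`.
#' @export
build_model <- function(cfg = posture_config()) {
  if (!inherits(cfg, "posture_config")) stop("cfg must be a posture_config",
                                             call. = FALSE)
  params <- with_local_seed(cfg$seed, init_params(cfg))
  ch <- as.vector(rbind(paste0(SQUAT_JOINTS, "_x"), paste0(SQUAT_JOINTS, "_y")))
  structure(list(config = cfg, params = params, channels = ch,
                 history = NULL, trained = FALSE),
            class = "posture_model")
}

#' @export
print.posture_model <- function(x, ...) {
  cat(sprintf("<posture_model: %s, %d parameters, %s>\n", x$config$variant,
              n_params(x$params),
              if (x$trained) "trained" else "untrained"))
  if (!is.null(x$history)) {
    best <- max(x$history$val_accuracy, na.rm = TRUE)
    cat(sprintf("  epochs run: %d, best validation accuracy: %.4f\n",
                nrow(x$history), best))
  }
  invisible(x)
}

## Coerce a labeled dataset (from simulate_dataset or a list of
## (x = feature matrix, y = label)) into the internal training form.
as_training_set <- function(dataset, pp_cfg = preprocess_config()) {
  lapply(dataset, function(d) {
    if (inherits(d, "labeled_sequence")) {
      list(x = unclass_features(preprocess(d$seq, pp_cfg)), y = d$label)
    } else if (!is.null(d$x) && !is.null(d$y)) {
      list(x = unclass_features(d$x), y = d$y)
    } else {
      stop("dataset elements must be labeled_sequence or list(x =, y =)",
           call. = FALSE)
    }
  })
}

unclass_features <- function(x) {
  m <- unclass(x)
  attr(m, "channels") <- NULL
  m
}

label_index <- function(y) {
  i <- match(y, c("correct", "incorrect"))
  if (any(is.na(i))) stop("labels must be 'correct' or 'incorrect'",
                          call. = FALSE)
  i
}

#' Train the posture classifier
#'
#' Minimizes 2-class cross-entropy with Adam over minibatches of
#' variable-length sequences (gradients are computed per sequence and
#' averaged over the batch, so no padding or masking is needed). Dropout
#' is active only here. Training stops early when validation accuracy has
#' not improved for `patience` epochs and the best-validation weights are
#' restored. Deterministic given the configuration seed.
#'
#' @param model an untrained or previously trained [build_model()] output.
#' @param dataset training data: list of `labeled_sequence` (preprocessed
#'   internally) or of `list(x = feature matrix, y = label)`.
#' @param val_data optional held-out set in the same form; when absent, a
#'   20% tail split of `dataset` is used for early stopping.
#' @param pp_cfg [preprocess_config()] applied to raw labeled sequences.
#' @param quiet suppress the per-epoch progress line.
#' @return the trained `posture_model` with a `history` data frame of
#'   per-epoch loss and accuracy.
#' @export
train_model <- function(model, dataset, val_data = NULL,
                        pp_cfg = preprocess_config(), quiet = TRUE) {
  if (!inherits(model, "posture_model")) stop("model must be a posture_model",
                                              call. = FALSE)
  if (length(dataset) == 0L) stop("empty training set", call. = FALSE)
  cfg <- model$config
  train <- as_training_set(dataset, pp_cfg)
  if (is.null(val_data)) {
    n_val <- max(1L, floor(0.2 * length(train)))
    idx <- seq_len(length(train) - n_val)
    val <- train[-idx]
    train <- train[idx]
  } else {
    val <- as_training_set(val_data, pp_cfg)
  }
  y_tr <- label_index(vapply(train, `[[`, "", "y"))
  if (length(unique(y_tr)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  min_T <- min_input_length(cfg)
  short <- vapply(train, function(d) nrow(d$x) < min_T, TRUE)
  if (any(short)) {
    stop(sprintf("%d training sequences shorter than the model minimum of %d feature rows",
                 sum(short), min_T), call. = FALSE)
  }

  params <- model$params
  state <- adam_init(params)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  hist <- list()

  with_local_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(length(train))
      ep_loss <- 0; ep_hit <- 0
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        acc_g <- NULL
        for (i in batch) {
          lg <- loss_and_grads(params, cfg, train[[i]]$x, y_tr[i],
                               training = TRUE)
          ep_loss <- ep_loss + lg$loss
          ep_hit <- ep_hit + (which.max(lg$probs) == y_tr[i])
          acc_g <- if (is.null(acc_g)) lg$grads else tree_axpy(acc_g, lg$grads)
        }
        acc_g <- tree_scale(acc_g, 1 / length(batch))
        st <- adam_step(params, acc_g, state, cfg$learning_rate)
        params <- st$params
        state <- st$state
      }
      val_acc <- eval_accuracy(params, cfg, val)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = ep_loss / length(train),
                                  train_accuracy = ep_hit / length(train),
                                  val_accuracy = val_acc)
      if (!quiet) {
        message(sprintf("epoch %3d  loss %.4f  train acc %.3f  val acc %.3f",
                        epoch, ep_loss / length(train), ep_hit / length(train),
                        val_acc))
      }
      if (val_acc > best$acc + 1e-12) {
        best <- list(acc = val_acc, params = params, epoch = epoch)
      }
      if (epoch - best$epoch >= cfg$patience) break
      if (best$acc >= 1 - 1e-12 && epoch - best$epoch >= 2L) break
    }
  })
  model$params <- best$params
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

eval_accuracy <- function(params, cfg, data) {
  if (length(data) == 0L) return(NA_real_)
  y <- label_index(vapply(data, `[[`, "", "y"))
  pred <- vapply(data, function(d) {
    which.max(model_forward(params, cfg, d$x, training = FALSE)$probs)
  }, 0L)
  mean(pred == y)
}

#' Softmax score of the "correct" class for one feature tensor
#'
#' Runs the trained network deterministically (no dropout) and returns the
#' softmax probability assigned to the correct-posture class; the two
#' class probabilities sum to 1.
#'
#' @param model a trained [posture_model].
#' @param feats a `(k-1) x 20` [delta_features()] matrix.
#' @return numeric score in `[0, 1]`.
#' @export
classify <- function(model, feats) {
  if (!inherits(model, "posture_model")) stop("model must be a posture_model",
                                              call. = FALSE)
  X <- unclass_features(feats)
  if (ncol(X) != 20L) {
    stop(sprintf("feature tensor must have 20 channels, got %d", ncol(X)),
         call. = FALSE)
  }
  ch <- attr(feats, "channels")
  if (!is.null(ch) && !identical(ch, model$channels)) {
    stop("channel order of the feature tensor does not match the model's",
         call. = FALSE)
  }
  min_T <- min_input_length(model$config)
  if (nrow(X) < min_T) {
    stop(sprintf("input too short: %d feature rows, the '%s' variant needs at least %d (a %d-frame sequence)",
                 nrow(X), model$config$variant, min_T, min_T + 1L), call. = FALSE)
  }
  model_forward(model$params, model$config, X, training = FALSE)$probs[1L]
}

#' Evaluate a trained model on a labeled dataset
#'
#' Computes the 2x2 confusion matrix with "correct posture" as the
#' positive class, and accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)`.
#'
#' @param model a trained [posture_model].
#' @param dataset labeled data as accepted by [train_model()].
#' @param pp_cfg [preprocess_config()] for raw labeled sequences.
#' @return an `eval_report`: list with `accuracy`, `precision`, `recall`,
#'   `confusion` (2x2 matrix) and `n`.
#' @export
evaluate_model <- function(model, dataset, pp_cfg = preprocess_config()) {
  if (length(dataset) == 0L) stop("empty evaluation set", call. = FALSE)
  data <- as_training_set(dataset, pp_cfg)
  y <- vapply(data, `[[`, "", "y")
  pred <- vapply(data, function(d) {
    p <- model_forward(model$params, model$config, d$x, training = FALSE)$probs
    c("correct", "incorrect")[which.max(p)]
  }, "")
  rep_ <- confusion_report(pred, y)
  rep_$n <- length(y)
  rep_
}

#' Confusion-matrix metrics with "correct" as the positive class
#'
#' @param pred,truth character vectors of `"correct"` / `"incorrect"`.
#' @return list of class `eval_report` with `accuracy`, `precision`,
#'   `recall` and the 2x2 `confusion` matrix (rows = truth, cols = pred).
#' @export
confusion_report <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  tp <- sum(pred == "correct" & truth == "correct")
  fp <- sum(pred == "correct" & truth == "incorrect")
  fn <- sum(pred == "incorrect" & truth == "correct")
  tn <- sum(pred == "incorrect" & truth == "incorrect")
  conf <- matrix(c(tp, fn, fp, tn), 2L,
                 dimnames = list(truth = c("correct", "incorrect"),
                                 pred = c("correct", "incorrect")))
  structure(list(accuracy = (tp + tn) / length(pred),
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 confusion = conf),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f\n",
              x$accuracy, x$precision, x$recall))
  print(x$confusion)
  invisible(x)
}

#' Train and evaluate all architecture variants
#'
#' Builds, trains and evaluates the full model and the two ablations
#' (`conv_only`, `lstm_only`) on the same train/validation/test split and
#' reports a variant-by-split accuracy grid, the standard shape for
#' ablation comparisons of this architecture.
#'
#' @param splits named list `train` / `val` / `test` of labeled data (as
#'   from [split_by_subject()]).
#' @param base_cfg configuration shared by all variants.
#' @param variants variants to include.
#' @param pp_cfg [preprocess_config()].
#' @param quiet suppress progress lines.
#' @return list with `table` (data frame: variant, training/validation/test
#'   accuracy, plus test precision and recall) and `models`.
#' @export
ablation_report <- function(splits, base_cfg = posture_config(),
                            variants = c("full", "conv_only", "lstm_only"),
                            pp_cfg = preprocess_config(), quiet = TRUE) {
  stopifnot(all(c("train", "val", "test") %in% names(splits)))
  rows <- list(); models <- list()
  for (v in variants) {
    cfg <- base_cfg
    cfg$variant <- v
    m <- build_model(cfg)
    m <- train_model(m, splits$train, val_data = splits$val, pp_cfg = pp_cfg,
                     quiet = quiet)
    ev <- lapply(splits, function(d) evaluate_model(m, d, pp_cfg = pp_cfg))
    rows[[v]] <- data.frame(variant = v,
                            train_accuracy = ev$train$accuracy,
                            val_accuracy = ev$val$accuracy,
                            test_accuracy = ev$test$accuracy,
                            test_precision = ev$test$precision,
                            test_recall = ev$test$recall)
    models[[v]] <- m
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
       models = models)
}

#' Grid search over hyperparameters
#'
#' Exhaustively trains one model per combination of the supplied
#' hyperparameter values on a fixed train/validation split and returns the
#' combination with the highest validation accuracy, together with the
#' full result table.
#'
#' @param train_data,val_data labeled datasets (fixed split).
#' @param grid named list of hyperparameter value vectors; names must be
#'   [posture_config()] arguments (e.g. `learning_rate`, `dropout`).
#' @param base_cfg configuration for parameters not in the grid.
#' @param pp_cfg [preprocess_config()].
#' @return list with `best_config`, `best_val_accuracy`, and `results`
#'   (one row per combination).
#' @export
grid_search <- function(train_data, val_data, grid,
                        base_cfg = posture_config(),
                        pp_cfg = preprocess_config()) {
  if (length(grid) == 0L) stop("empty grid", call. = FALSE)
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  best <- list(acc = -Inf, cfg = NULL)
  res <- combos
  res$val_accuracy <- NA_real_
  for (i in seq_len(nrow(combos))) {
    cfg <- base_cfg
    for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][i]
    m <- train_model(build_model(cfg), train_data, val_data = val_data,
                     pp_cfg = pp_cfg)
    acc <- max(m$history$val_accuracy, na.rm = TRUE)
    res$val_accuracy[i] <- acc
    if (acc > best$acc) best <- list(acc = acc, cfg = cfg)
  }
  list(best_config = best$cfg, best_val_accuracy = best$acc, results = res)
}

#' Save / load a trained model as JSON
#'
#' The checkpoint stores the configuration, all weight matrices at full
#' precision, and the channel-order sidecar; [load_model()] refuses a
#' checkpoint whose channel order disagrees with this package's
#' preprocessing layout.
#'
#' @param model a [posture_model].
#' @param path output file.
#' @return `path` invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "posture_model")) stop("model must be a posture_model",
                                              call. = FALSE)
  ## leaves are flattened column-major with their dims alongside, so the
  ## checkpoint layout is independent of how JSON nests arrays
  obj <- list(config = unclass(model$config), channels = model$channels,
              trained = model$trained,
              params = rapply(model$params, as.vector, how = "replace"),
              param_dims = rapply(model$params, function(m) dim(m) %||% length(m),
                                  how = "replace"))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg_in <- lapply(obj$config, unlist)
  cfg <- do.call(posture_config, cfg_in[names(cfg_in) %in%
                                          names(formals(posture_config))])
  m <- build_model(cfg)
  if (!identical(as.character(unlist(obj$channels)), m$channels)) {
    stop("checkpoint channel order does not match this package's preprocessing layout",
         call. = FALSE)
  }
  restore <- function(tmpl, flat, dims) {
    if (is.list(tmpl)) {
      for (n in seq_along(tmpl)) tmpl[[n]] <- restore(tmpl[[n]], flat[[n]], dims[[n]])
      return(tmpl)
    }
    v <- as.numeric(unlist(flat))
    d <- as.integer(unlist(dims))
    if (length(d) == 2L) matrix(v, d[1], d[2]) else v
  }
  m$params <- restore(m$params, obj$params, obj$param_dims)
  m$trained <- isTRUE(obj$trained)
  m
}
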