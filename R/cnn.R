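# Shallow CNN classifier over 48 x 48 x 3 flow feature maps, with
# leave-one-subject-out (LOSO) evaluation.

#' Network architecture configuration
#'
#' Fixed shallow topology: 1x1x12 and 5x5x12 convolutions, 3x3/2 max pool,
#' 3x3x12 convolution, pool, 5x5x24 convolution, pool, then two 1024-unit
#' fully connected layers and a softmax output of `n_classes` units.
#' Convolutions are zero-padded ("same") with stride 1, pools are unpadded,
#' so the spatial side follows 48 -> 48 -> 48 -> 23 -> 23 -> 11 -> 11 -> 5.
#'
#' @param n_classes output classes: 3 (basic) or 7 (compound).
#' @param dropout_rate drop probability on both FC layers (default 0.7).
#' @param batch_norm use batch normalisation after each convolution.
#' @return A `model_config` list with a `layers` tibble describing the
#'   shape chain (`layer, filter, stride, out_h, out_w, out_c`).
#' @export
model_config <- function(n_classes = 7, dropout_rate = 0.7, batch_norm = TRUE) {
  if (!n_classes %in% c(3L, 7L)) {
    if (!(is_scalar_number(n_classes) && n_classes >= 2))
      abort("`n_classes` must be >= 2")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) abort("`dropout_rate` in [0, 1)")
  pool_out <- function(n, k = 3, s = 2) floor((n - k) / s) + 1
  side <- c(input = 48, conv1 = 48, conv2 = 48, pool1 = pool_out(48),
            conv3 = pool_out(48), pool2 = pool_out(pool_out(48)),
            conv4 = pool_out(pool_out(48)),
            pool3 = pool_out(pool_out(pool_out(48))))
  layers <- tibble(
    layer = c("input", "conv1", "conv2", "pool1", "conv3", "pool2",
              "conv4", "pool3", "fc1", "fc2", "output"),
    filter = c(NA, "1x1", "5x5", "3x3", "3x3", "3x3", "5x5", "3x3",
               NA, NA, NA),
    stride = c(NA, 1, 1, 2, 1, 2, 1, 2, NA, NA, NA),
    out_h = c(side, NA, NA, NA),
    out_w = c(side, NA, NA, NA),
    out_c = c(3, 12, 12, 12, 12, 12, 24, 24, 1024, 1024, n_classes))
  structure(list(n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate,
                 batch_norm = isTRUE(batch_norm),
                 layers = layers),
            class = "model_config")
}

#' Training configuration
#'
#' @param batch_size mini-batch size (default 10).
#' @param epochs training epochs (default 500; heavier schedules overfit
#'   small micro-expression sets).
#' @param lr0 initial learning rate (default 0.01).
#' @param decay_interval epochs between ten-fold learning-rate drops
#'   (default 100). The schedule is `lr0 * 0.1^floor(epoch /
#'   decay_interval)`, floored at `lr_floor`.
#' @param lr_floor smallest learning rate used (default 1e-5).
#' @param momentum SGD momentum (default 0.9).
#' @param dropout drop probability for the FC layers (default 0.7).
#' @param seed integer seed fixing initialisation, shuffling and dropout.
#' @param n_classes number of classes.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 10, epochs = 500, lr0 = 0.01,
                         decay_interval = 100, lr_floor = 1e-5,
                         momentum = 0.9, dropout = 0.7, seed = 1,
                         n_classes = 7) {
  if (epochs < 1) abort("`epochs` must be >= 1")
  if (dropout < 0 || dropout >= 1) abort("`dropout` must be in [0, 1)")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr0 = lr0,
                 decay_interval = as.integer(decay_interval),
                 lr_floor = lr_floor, momentum = momentum, dropout = dropout,
                 seed = as.integer(seed), n_classes = as.integer(n_classes)),
            class = "train_config")
}

#' Step learning-rate schedule
#' @param epoch 0-based epoch index (vectorised).
#' @param cfg a [train_config()].
#' @return Learning rate(s): `lr0 * 0.1^floor(epoch / decay_interval)`,
#'   floored at `lr_floor`.
#' @export
learning_rate_schedule <- function(epoch, cfg = train_config()) {
  pmax(cfg$lr0 * 0.1^floor(epoch / cfg$decay_interval), cfg$lr_floor)
}

#' Build (initialise) the network
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the weight initialisation.
#' @return A `cmer_cnn` object holding the weights and the config.
#' @export
build_model <- function(cfg = model_config(), seed = 1) {
  weights <- .cnn_init_cpp(cfg$n_classes, cfg$batch_norm, as.integer(seed))
  structure(list(config = cfg, weights = weights, loss_curve = NULL),
            class = "cmer_cnn")
}

#' @export
print.cmer_cnn <- function(x, ...) {
  cat(sprintf("<cmer_cnn> %d-class shallow CNN (48x48x3 input)%s\n",
              x$config$n_classes,
              if (is.null(x$loss_curve)) ", untrained" else
                sprintf(", trained %d epochs (final loss %.4f)",
                        length(x$loss_curve) - 1, tail(x$loss_curve, 1))))
  invisible(x)
}

#' Softmax cross-entropy loss
#'
#' `-(1/N) sum_i log(exp(h_{y_i}) / sum_j exp(h_j))`, computed with a
#' max-shift for numerical stability.
#'
#' @param logits `N x C` matrix of network outputs.
#' @param labels integer class labels in `1..C`, length `N`.
#' @return Mean negative log-likelihood (scalar).
#' @export
softmax_loss <- function(logits, labels) {
  logits <- as.matrix(logits)
  N <- nrow(logits); C <- ncol(logits)
  labels <- as.integer(labels)
  if (any(labels < 1) || any(labels > C)) abort("labels out of range 1..C")
  shifted <- logits - apply(logits, 1, max)
  logZ <- log(rowSums(exp(shifted)))
  -mean(shifted[cbind(seq_len(N), labels)] - logZ)
}

# Stack a list of 48x48x3 feature maps into the (N, 48, 48, 3) array the
# C++ core expects, resizing if needed.
stack_feature_maps <- function(maps) {
  maps <- lapply(maps, function(m) {
    if (length(dim(m)) == 2L) m <- array(rep(m, 3), c(dim(m), 3))
    if (!identical(dim(m)[1:2], c(48L, 48L))) {
      out <- array(0, c(48, 48, 3))
      for (ch in 1:3) out[, , ch] <- EBImage::resize(m[, , ch], w = 48, h = 48,
                                                     filter = "bilinear")
      m <- out
    }
    m
  })
  N <- length(maps)
  X <- array(0, c(N, 48, 48, 3))
  for (i in seq_len(N)) X[i, , , ] <- maps[[i]]
  X
}

#' Train the classifier
#'
#' Mini-batch SGD with momentum, per-epoch seeded shuffling, the step
#' learning-rate schedule of [learning_rate_schedule()], batch
#' normalisation and FC dropout. Deterministic given `cfg$seed`.
#'
#' @param model a [build_model()] object.
#' @param maps list of `48 x 48 x 3` feature maps (smaller/grayscale inputs
#'   are resized/replicated).
#' @param labels factor or character vector of class labels, length
#'   `length(maps)`; its sorted unique values define the class order unless
#'   `levels` is given.
#' @param cfg a [train_config()].
#' @param levels optional explicit class levels.
#' @return The trained `cmer_cnn`, with `loss_curve` (element 1 is the
#'   pre-training loss, then one mean training loss per epoch) and
#'   `class_levels` attached.
#' @export
train_cnn <- function(model, maps, labels, cfg = train_config(),
                      levels = NULL) {
  if (length(maps) == 0) abort("empty training set")
  levels <- levels %||% sort(unique(as.character(labels)))
  y <- match(as.character(labels), levels)
  if (anyNA(y)) abort("label not in `levels`")
  missing_cls <- setdiff(seq_along(levels), unique(y))
  if (length(missing_cls) > 0) {
    warn(paste0("class(es) absent from training data: ",
                paste(levels[missing_cls], collapse = ", ")))
  }
  if (length(levels) > model$config$n_classes)
    abort("more classes than output units")
  X <- stack_feature_maps(maps)
  res <- .cnn_train_cpp(model$weights, as.numeric(X), as.integer(y - 1L),
                        length(maps), cfg$epochs, cfg$batch_size, cfg$lr0,
                        cfg$decay_interval, cfg$lr_floor, cfg$momentum,
                        cfg$dropout, cfg$seed)
  model$weights <- res$model
  model$loss_curve <- as.numeric(res$loss_curve)
  model$class_levels <- levels
  model
}

#' Predict class probabilities or labels
#'
#' @param object a trained `cmer_cnn`.
#' @param maps list of feature maps.
#' @param type `"prob"` for the `N x C` probability matrix, `"class"` for
#'   predicted labels.
#' @param ... unused.
#' @return Matrix of probabilities or character vector of labels.
#' @export
predict.cmer_cnn <- function(object, maps, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- stack_feature_maps(maps)
  probs <- .cnn_predict_cpp(object$weights, as.numeric(X), length(maps))
  probs <- probs[, seq_along(object$class_levels %||%
                               seq_len(ncol(probs))), drop = FALSE]
  if (!is.null(object$class_levels)) colnames(probs) <- object$class_levels
  if (type == "prob") return(probs)
  lv <- object$class_levels %||% as.character(seq_len(ncol(probs)))
  lv[max.col(probs, ties.method = "first")]
}

# ---- metrics ----------------------------------------------------------------

#' Confusion matrix from true and predicted labels
#' @param truth,pred character/factor vectors of equal length.
#' @param levels class levels (rows = truth, cols = predicted).
#' @return `C x C` integer matrix of counts.
#' @export
confusion_matrix <- function(truth, pred, levels = sort(unique(c(truth, pred)))) {
  tab <- table(factor(truth, levels = levels), factor(pred, levels = levels))
  matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
}

#' Macro-averaged F1 from a confusion matrix
#'
#' Per class, `F1 = 2 P R / (P + R)` with precision `P` and recall `R`
#' taken from the counts (0 where `P + R = 0`); classes are averaged with
#' equal weight.
#'
#' @param confusion `C x C` count matrix, rows = truth, cols = predicted.
#' @return Macro F1 in `[0, 1]`.
#' @export
f1_measure <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0)) abort("negative counts")
  if (sum(confusion) == 0) abort("empty confusion matrix")
  C <- nrow(confusion)
  f1 <- numeric(C)
  for (c in seq_len(C)) {
    tp <- confusion[c, c]
    p <- if (sum(confusion[, c]) > 0) tp / sum(confusion[, c]) else 0
    r <- if (sum(confusion[c, ]) > 0) tp / sum(confusion[c, ]) else 0
    f1[c] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  mean(f1)
}

#' Leave-one-subject-out evaluation
#'
#' One fold per subject: the fold's model trains on every other subject's
#' samples and predicts the held-out subject's. Predictions from all folds
#' are pooled before computing accuracy, macro F1 and the confusion matrix
#' (per-fold accuracies are reported too).
#'
#' @param maps list of feature maps.
#' @param labels class labels, same length.
#' @param subjects subject ids, same length; must contain >= 2 distinct.
#' @param cfg a [train_config()].
#' @param model_cfg a [model_config()]; defaults to one sized for the
#'   observed classes.
#' @param classifier optional override: `function(train_maps, train_labels,
#'   test_maps) -> predicted labels`, substituted for the CNN (used for
#'   stub/oracle testing).
#' @return A `cmer_eval` object: list with `predictions` tibble
#'   (`subject_id, truth, pred`), `confusion`, `accuracy`, `f1`,
#'   `per_fold` tibble.
#' @export
evaluate_loso <- function(maps, labels, subjects, cfg = train_config(),
                          model_cfg = NULL, classifier = NULL) {
  labels <- as.character(labels)
  subjects <- as.character(subjects)
  stopifnot(length(maps) == length(labels), length(maps) == length(subjects))
  subs <- sort(unique(subjects))
  if (length(subs) < 2) abort("LOSO needs at least 2 subjects")
  levels <- sort(unique(labels))
  if (is.null(model_cfg)) {
    nc <- if (length(levels) <= 3) 3L else 7L
    if (length(levels) > 7) nc <- length(levels)
    model_cfg <- model_config(n_classes = nc, dropout_rate = cfg$dropout)
  }
  preds <- character(length(maps))
  fold_rows <- list()
  for (k in seq_along(subs)) {
    te <- which(subjects == subs[k])
    tr <- which(subjects != subs[k])
    if (is.null(classifier)) {
      fold_seed <- cfg$seed + k
      fcfg <- cfg; fcfg$seed <- fold_seed
      m <- build_model(model_cfg, seed = fold_seed)
      m <- train_cnn(m, maps[tr], labels[tr], fcfg, levels = levels)
      preds[te] <- predict(m, maps[te])
    } else {
      preds[te] <- classifier(maps[tr], labels[tr], maps[te])
    }
    fold_rows[[k]] <- tibble(subject_id = subs[k], n = length(te),
                             accuracy = mean(preds[te] == labels[te]))
  }
  cm <- confusion_matrix(labels, preds, levels = levels)
  structure(list(
    predictions = tibble(subject_id = subjects, truth = labels, pred = preds),
    confusion = cm,
    accuracy = sum(diag(cm)) / sum(cm),
    f1 = f1_measure(cm),
    per_fold = dplyr::bind_rows(fold_rows),
    class_levels = levels
  ), class = "cmer_eval")
}

#' @export
print.cmer_eval <- function(x, ...) {
  cat(sprintf("<cmer_eval> %d samples, %d subjects, %d classes\n",
              nrow(x$predictions), nrow(x$per_fold), length(x$class_levels)))
  cat(sprintf("  pooled accuracy: %.4f   macro F1: %.4f\n", x$accuracy, x$f1))
  invisible(x)
}
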