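test_that("built weights realise the printed shape chain", {
  m <- build_model(model_config(n_classes = 7), seed = 1)
  w <- m$weights
  expect_identical(dim(w$W1), c(12L, 3L))     # 1x1x12 over 3 channels
  expect_identical(dim(w$W2), c(12L, 300L))   # 5x5x12 over 12 channels
  expect_identical(dim(w$W3), c(12L, 108L))   # 3x3x12
  expect_identical(dim(w$W4), c(24L, 300L))   # 5x5x24
  expect_identical(dim(w$Wf1), c(1024L, 600L)) # 5*5*24 -> 1024
  expect_identical(dim(w$Wf2), c(1024L, 1024L))
  expect_identical(dim(w$Wo), c(7L, 1024L))
  # pooled sides follow floor((n - 3) / 2) + 1
  pool_out <- function(n) floor((n - 3) / 2) + 1
  expect_equal(pool_out(48), 23)
  expect_equal(pool_out(23), 11)
  expect_equal(pool_out(11), 5)
})

test_that("softmax loss matches a brute-force probability computation", {
  # uniform logits: loss = ln C
  expect_equal(softmax_loss(matrix(3, 1, 7), 4), log(7), tolerance = 1e-12)
  # brute force on random matrices
  set.seed(31)
  for (i in 1:5) {
    logits <- matrix(rnorm(35, sd = 3), 5, 7)
    labels <- sample(7, 5, replace = TRUE)
    probs <- exp(logits) / rowSums(exp(logits))
    expect_equal(softmax_loss(logits, labels),
                 -mean(log(probs[cbind(1:5, labels)])), tolerance = 1e-6)
  }
  # a dominant true-class logit drives the loss toward zero
  strong <- matrix(0, 1, 7); strong[1, 3] <- 50
  expect_lt(softmax_loss(strong, 3), 1e-10)
  # permuting classes together with labels leaves the loss unchanged
  logits <- matrix(rnorm(21), 3, 7)
  labels <- c(2, 7, 5)
  perm <- sample(7)
  expect_equal(softmax_loss(logits[, perm], match(labels, perm)),
               softmax_loss(logits, labels), tolerance = 1e-12)
  expect_error(softmax_loss(logits, c(0, 1, 2)), "out of range")
})

test_that("the learning-rate schedule steps down tenfold and is floored", {
  cfg <- train_config(lr0 = 0.01, decay_interval = 100, lr_floor = 1e-5)
  ep <- 0:499
  lr <- learning_rate_schedule(ep, cfg)
  expect_true(all(diff(lr) <= 0))
  expect_equal(lr[1], 0.01)
  expect_equal(lr[101], 0.001)
  expect_equal(lr[201], 1e-4)
  expect_equal(learning_rate_schedule(1000, cfg), 1e-5) # floor
})

test_that("macro F1 follows the precision/recall definition", {
  expect_equal(f1_measure(diag(c(5, 3, 9))), 1)
  cm <- matrix(c(8, 3, 2, 7), 2, 2) # rows = truth: [[8,2],[3,7]]
  p1 <- 8 / 11; r1 <- 8 / 10; p2 <- 7 / 9; r2 <- 7 / 10
  expect_equal(f1_measure(cm),
               (2 * p1 * r1 / (p1 + r1) + 2 * p2 * r2 / (p2 + r2)) / 2,
               tolerance = 1e-12)
  expect_equal(round(f1_measure(cm), 4), 0.7494)
  # simultaneous row/column permutation leaves macro F1 unchanged
  set.seed(1)
  cm3 <- matrix(rpois(9, 5), 3, 3)
  perm <- c(3, 1, 2)
  expect_equal(f1_measure(cm3[perm, perm]), f1_measure(cm3))
  # an unpredicted class contributes zero F1
  cm0 <- matrix(c(5, 5, 0, 0), 2, 2)
  expect_equal(f1_measure(cm0), (2 * (5 / 10) * 1 / (5 / 10 + 1) + 0) / 2)
  expect_error(f1_measure(matrix(0, 2, 2)), "empty")
})

test_that("LOSO folds never leak the held-out subject and pool predictions", {
  maps <- lapply(1:20, function(i) array(runif(48 * 48 * 3), c(48, 48, 3)))
  labels <- rep(c("A", "B"), 10)
  subjects <- rep(sprintf("s%d", 1:5), each = 4)
  seen <- list()
  stub <- function(train_maps, train_labels, test_maps) {
    seen[[length(seen) + 1]] <<- length(train_maps)
    rep("A", length(test_maps))
  }
  ev <- evaluate_loso(maps, labels, subjects, classifier = stub)
  expect_equal(nrow(ev$per_fold), 5)
  expect_equal(nrow(ev$predictions), 20)
  expect_true(all(unlist(seen) == 16)) # each fold trains on 4 subjects x 4
  expect_equal(sum(ev$confusion), 20)
  # a perfect classifier stub gives a diagonal confusion matrix
  perfect <- function(train_maps, train_labels, test_maps) {
    # identify test samples by their first pixel value
    key <- vapply(test_maps, function(m) m[1, 1, 1], numeric(1))
    all_key <- vapply(maps, function(m) m[1, 1, 1], numeric(1))
    labels[match(key, all_key)]
  }
  ev2 <- evaluate_loso(maps, labels, subjects, classifier = perfect)
  expect_equal(ev2$accuracy, 1)
  expect_equal(ev2$f1, 1)
  expect_true(all(ev2$confusion[row(ev2$confusion) != col(ev2$confusion)] == 0))
  expect_error(evaluate_loso(maps, labels, rep("s1", 20)), "2 subjects")
})

test_that("training is deterministic given a seed and reports the warning for
           absent classes", {
  set.seed(6)
  maps <- lapply(rep(1:2, 6), function(cl) {
    m <- array(runif(48 * 48 * 3, 0, 0.2), c(48, 48, 3))
    if (cl == 2) m[20:30, 20:30, ] <- 0.9
    m
  })
  labels <- rep(c("x", "y"), 6)
  cfg <- train_config(epochs = 8, n_classes = 3, seed = 11, dropout = 0.5)
  tr1 <- train_cnn(build_model(model_config(3), 11), maps, labels, cfg)
  tr2 <- train_cnn(build_model(model_config(3), 11), maps, labels, cfg)
  expect_identical(tr1$loss_curve, tr2$loss_curve)
  expect_length(tr1$loss_curve, 9) # pre-training loss + one per epoch
  expect_warning(
    train_cnn(build_model(model_config(3), 1), maps, labels,
              train_config(epochs = 1, n_classes = 3),
              levels = c("x", "y", "z")),
    "absent")
})

test_that("tidiers expose evaluation and training results as tibbles", {
  maps <- lapply(1:8, function(i) array(runif(48 * 48 * 3), c(48, 48, 3)))
  labels <- rep(c("A", "B"), 4)
  subjects <- rep(c("s1", "s2"), each = 4)
  stub <- function(tr_m, tr_l, te_m) rep("B", length(te_m))
  ev <- evaluate_loso(maps, labels, subjects, classifier = stub)
  td <- tidy(ev)
  expect_true(all(c("truth", "pred", "n", "prop") %in% names(td)))
  expect_equal(sum(td$n), 8)
  gl <- glance(ev)
  expect_equal(gl$n_subjects, 2)
  expect_equal(gl$accuracy, 0.5)
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
})
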