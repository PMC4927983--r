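test_that("the stratified split preserves class balance with floor rounding", {
  tbl <- tibble::tibble(label = rep(c("benign", "malignant"), each = 72),
                        x = runif(144))
  sp <- split_train_validation(tbl, 0.7, seed = 1)
  expect_equal(nrow(sp$train), 100L)
  expect_equal(nrow(sp$validation), 44L)
  expect_equal(sum(sp$train$label == "benign"), 50L)
  expect_equal(sum(sp$validation$label == "malignant"), 22L)
  tiny <- tibble::tibble(label = rep(c("benign", "malignant"), each = 2),
                         x = 1:4)
  sp2 <- split_train_validation(tiny, 0.5, seed = 1)
  expect_equal(nrow(sp2$train), 2L)
  expect_equal(nrow(sp2$validation), 2L)
  sp3 <- split_train_validation(tbl, 0.7, seed = 9)
  sp4 <- split_train_validation(tbl, 0.7, seed = 9)
  expect_identical(sp3$train$x, sp4$train$x)
  expect_error(split_train_validation(tiny, 0.2, seed = 1), "starved")
})

test_that("initialization sizes the network per its topology", {
  m <- mlp_init(3, 2, seed = 1)
  expect_equal(buscad:::n_parameters(m), 14L)   # 3-2-2 network
  m2 <- mlp_init(3, 3, seed = 1)
  expect_equal(buscad:::n_parameters(m2), 20L)  # 3-3-2 network
  expect_true(all(abs(m$W1) <= 0.5) && all(abs(m$W2) <= 0.5))
  expect_true(all(m$b1 == 0) && all(m$b2 == 0))
  expect_identical(mlp_init(3, 2, seed = 5)$W1, mlp_init(3, 2, seed = 5)$W1)
})

test_that("a zero-weight network scores 0.5/0.5 and ties resolve to benign", {
  m <- mlp_init(2, 2, seed = 1)
  m$W1[] <- 0; m$W2[] <- 0
  pred <- mlp_predict(m, matrix(c(0.3, 0.9), 1, 2), normalize = FALSE)
  expect_equal(pred$score_benign, 0.5)
  expect_equal(pred$score_malignant, 0.5)
  expect_equal(pred$pred_label, "benign")
})

test_that("the forward pass matches by-hand arithmetic on a 2-2-2 network", {
  m <- mlp_init(2, 2, seed = 1)
  m$W1 <- matrix(c(0.1, -0.2, 0.3, 0.4), 2, 2)
  m$b1 <- c(0.05, -0.05)
  m$W2 <- matrix(c(0.5, -0.5, 0.25, 0.75), 2, 2)
  m$b2 <- c(0.1, 0.2)
  x <- c(0.6, 0.9)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- sig(c(0.6 * 0.1 + 0.9 * (-0.2) + 0.05,
             0.6 * 0.3 + 0.9 * 0.4 - 0.05))
  o <- sig(c(h[1] * 0.5 + h[2] * (-0.5) + 0.1,
             h[1] * 0.25 + h[2] * 0.75 + 0.2))
  pred <- mlp_predict(m, matrix(x, 1), normalize = FALSE)
  expect_equal(pred$score_benign, o[1], tolerance = 1e-12)
  expect_equal(pred$score_malignant, o[2], tolerance = 1e-12)
  expect_true(all(unlist(pred[, 1:2]) > 0 & unlist(pred[, 1:2]) < 1))
  expect_error(mlp_predict(m, matrix(1, 1, 3), normalize = FALSE), "match")
})

test_that("training solves linearly separable blobs to perfection", {
  set.seed(2)
  blobs <- tibble::tibble(
    label = rep(c("benign", "malignant"), each = 30),
    x1 = c(rnorm(30, 0.3, 0.05), rnorm(30, 0.7, 0.05)),
    x2 = c(rnorm(30, 0.7, 0.05), rnorm(30, 0.3, 0.05)))
  m <- mlp_train(mlp_init(2, 2, seed = 1), blobs, c("x1", "x2"),
                 max_epochs = 500, target_mse = 0.01)
  pred <- mlp_predict(m, blobs)
  expect_equal(mean(pred$pred_label == blobs$label), 1)
  expect_lte(m$epochs_run, 500L)
})

test_that("XOR is learnable with two hidden units for at least one seed", {
  xor_tbl <- tibble::tibble(
    label = c("benign", "malignant", "malignant", "benign"),
    x1 = c(0, 0, 1, 1), x2 = c(0, 1, 0, 1))
  solved <- vapply(1:5, function(s) {
    m <- mlp_train(mlp_init(2, 2, seed = s, learning_rate = 0.5), xor_tbl,
                   c("x1", "x2"), max_epochs = 20000, target_mse = 0.04,
                   seed = s)
    utils::tail(m$mse_trace, 1) < 0.05
  }, logical(1))
  expect_true(any(solved))
})

test_that("zero training epochs leave the model unchanged", {
  tbl <- tibble::tibble(label = rep(c("benign", "malignant"), 5),
                        x1 = runif(10), x2 = runif(10))
  m0 <- mlp_init(2, 2, seed = 3)
  m <- mlp_train(m0, tbl, c("x1", "x2"), max_epochs = 0)
  expect_identical(m$W1, m0$W1)
  expect_identical(m$W2, m0$W2)
  expect_equal(m$epochs_run, 0L)
})

test_that("diagnostic metrics reproduce the printed study statistics", {
  # phantom validation, SOM-segmented inputs
  q <- diagnostic_metrics(list(TP = 68, FN = 4, FP = 7, TN = 65))
  expect_equal(round(q$sensitivity, 3), 0.944)
  expect_equal(round(q$specificity, 3), 0.903)
  expect_equal(round(q$accuracy, 3), 0.924)
  # clinical generalization, SOM-segmented inputs
  q2 <- diagnostic_metrics(list(TP = 23, FN = 0, FP = 33, TN = 117))
  expect_equal(q2$sensitivity, 1)
  expect_equal(q2$specificity, 0.78)
  expect_equal(round(q2$accuracy, 3), 0.809)
  expect_error(diagnostic_metrics(list(TP = 0, FN = 0, FP = 3, TN = 5)),
               "empty")
})

test_that("case confusion counts use malignant as the positive class", {
  truth <- c("malignant", "malignant", "benign", "benign", "benign")
  pred <- c("malignant", "benign", "malignant", "benign", "benign")
  cc <- case_confusion(truth, pred)
  expect_equal(unlist(cc), c(TP = 1L, FN = 1L, FP = 1L, TN = 2L))
})

test_that("the ROC curve is a threshold sweep with trapezoidal AUC", {
  scores <- c(0.9, 0.8, 0.3, 0.2)
  labels <- c("malignant", "malignant", "benign", "benign")
  roc <- roc_curve(scores, labels)
  expect_equal(attr(roc, "auc"), 1)
  expect_equal(roc$fpr[1], 0)
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_error(roc_curve(runif(5), rep("benign", 5)), "both classes")
})

test_that("trapezoidal AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(23)
  for (i in 1:10) {
    n_pos <- sample(5:30, 1); n_neg <- sample(5:30, 1)
    scores <- round(runif(n_pos + n_neg), 2)  # force ties
    labels <- c(rep("malignant", n_pos), rep("benign", n_neg))
    auc <- attr(roc_curve(scores, labels), "auc")
    pos <- scores[labels == "malignant"]; neg <- scores[labels == "benign"]
    u <- sum(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
    expect_equal(auc, u / (n_pos * n_neg), tolerance = 1e-12)
  }
})

test_that("random scores give chance-level AUC", {
  set.seed(29)
  scores <- runif(2000)
  labels <- sample(c("benign", "malignant"), 2000, replace = TRUE)
  expect_equal(attr(roc_curve(scores, labels), "auc"), 0.5, tolerance = 0.05)
})

test_that("pROC independently confirms the AUC", {
  set.seed(37)
  scores <- runif(60)
  labels <- sample(c("benign", "malignant"), 60, replace = TRUE,
                   prob = c(0.5, 0.5))
  labels[scores > 0.7] <- "malignant"  # induce signal
  ours <- attr(roc_curve(scores, labels), "auc")
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("benign", "malignant"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("models serialize to JSON and predict identically after reload", {
  set.seed(2)
  tbl <- tibble::tibble(label = rep(c("benign", "malignant"), each = 20),
                        x1 = c(rnorm(20, 0.3, 0.1), rnorm(20, 0.7, 0.1)),
                        x2 = runif(40))
  m <- mlp_train(mlp_init(2, 2, seed = 1), tbl, c("x1", "x2"),
                 max_epochs = 200)
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp_model(m, path)
  m2 <- read_mlp_model(path)
  expect_equal(mlp_predict(m2, tbl), mlp_predict(m, tbl), tolerance = 1e-12)
})

test_that("tidy and glance summarise a fitted network", {
  m <- mlp_init(3, 2, seed = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 14L)  # one row per parameter
  gl <- glance(m)
  expect_equal(gl$n_parameters, 14L)
  expect_equal(gl$epochs_run, 0L)
  expect_output(print(m), "3-2-2")
})
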