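#' Stratified train/validation split
#'
#' Randomly partitions a labelled table into training and validation parts,
#' preserving the class balance: per class, `floor(fraction * n_class)` cases
#' go to training (e.g. 72 + 72 cases at 0.7 give 100 training and 44
#' validation cases). Deterministic under `seed`.
#'
#' @param data Tibble with a `label` column.
#' @param fraction Training fraction in (0, 1); default 0.7.
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `validation`.
#' @export
split_train_validation <- function(data, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  idx_train <- integer(0)
  for (cl in sort(unique(data$label))) {
    rows <- which(data$label == cl)
    n_tr <- floor(fraction * length(rows))
    if (n_tr < 1L || n_tr >= length(rows))
      stop("class '", cl, "' would be starved in one part", call. = FALSE)
    idx_train <- c(idx_train, sample(rows, n_tr))
  }
  idx_train <- sort(idx_train)
  list(train = data[idx_train, ], validation = data[-idx_train, ])
}

#' Initialize a multilayer perceptron
#'
#' One hidden layer and two sigmoid outputs (benign, malignant scores).
#' Weights are i.i.d. uniform on \[-0.5, 0.5\] under `seed`; biases start at
#' zero.
#'
#' @param n_in Number of input features (>= 1).
#' @param n_hidden Hidden-layer size (>= 1).
#' @param seed Integer seed.
#' @param learning_rate Backpropagation learning rate in (0, 1).
#' @return A `bus_mlp` model object.
#' @export
mlp_init <- function(n_in, n_hidden, seed = 1L, learning_rate = 0.5) {
  stopifnot(n_in >= 1L, n_hidden >= 1L)
  if (learning_rate <= 0 || learning_rate >= 1)
    stop("learning_rate must be in (0, 1)", call. = FALSE)
  set.seed(seed)
  structure(list(
    layer_sizes = c(n_in = n_in, n_hidden = n_hidden, n_out = 2L),
    W1 = matrix(runif(n_in * n_hidden, -0.5, 0.5), n_in, n_hidden),
    b1 = rep(0, n_hidden),
    W2 = matrix(runif(n_hidden * 2L, -0.5, 0.5), n_hidden, 2L),
    b2 = rep(0, 2L),
    learning_rate = learning_rate,
    feature_names = NULL,
    norm_stats = NULL,
    mse_trace = numeric(0),
    epochs_run = 0L,
    converged = NA
  ), class = "bus_mlp")
}

n_parameters <- function(model) {
  length(model$W1) + length(model$b1) + length(model$W2) + length(model$b2)
}

mlp_design <- function(model, data, features) {
  X <- as.matrix(data[, features])
  storage.mode(X) <- "double"
  X
}

#' Train the MLP by online backpropagation
#'
#' Per-sample (online) gradient descent with a fixed learning rate and
#' logistic activations throughout; the presentation order is reshuffled
#' every epoch under `seed`. Features are min-max normalized with statistics
#' taken from the training data (stored in the model for later prediction);
#' targets are one-hot over (benign, malignant). Training stops when the
#' full-pass mean squared error drops to `target_mse` or after `max_epochs`.
#'
#' @param model A [mlp_init()] model.
#' @param train Tibble with a `label` column and the feature columns.
#' @param features Character vector of feature column names; its length must
#'   equal the model's input size.
#' @param max_epochs Epoch cap (default 10000).
#' @param target_mse Stopping error (default 0.01).
#' @param seed Integer seed for the per-epoch shuffles.
#' @return The trained `bus_mlp`, carrying `mse_trace`, `epochs_run` and
#'   `converged`.
#' @export
mlp_train <- function(model, train, features, max_epochs = 10000L,
                      target_mse = 0.01, seed = 1L) {
  stopifnot(inherits(model, "bus_mlp"),
            length(features) == model$layer_sizes[["n_in"]])
  X <- mlp_design(model, train, features)
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  if (any(hi - lo == 0))
    stop("constant feature in training data: ",
         paste(features[hi - lo == 0], collapse = ", "), call. = FALSE)
  Xn <- sweep(sweep(X, 2, lo), 2, hi - lo, "/")
  Y <- cbind(benign = as.numeric(train$label == "benign"),
             malignant = as.numeric(train$label == "malignant"))
  model$feature_names <- features
  model$norm_stats <- list(min = lo, max = hi)
  if (max_epochs == 0L) {
    model$epochs_run <- 0L
    model$converged <- FALSE
    return(model)
  }
  set.seed(seed)
  fit <- mlp_fit_cpp(Xn, Y, model$W1, model$b1, model$W2, model$b2,
                     model$learning_rate, as.integer(max_epochs), target_mse)
  if (fit$diverged)
    stop("training diverged (non-finite error) at epoch ", fit$epochs_run,
         call. = FALSE)
  model$W1 <- fit$W1; model$b1 <- fit$b1
  model$W2 <- fit$W2; model$b2 <- fit$b2
  model$mse_trace <- fit$mse_trace
  model$epochs_run <- fit$epochs_run
  model$converged <- utils::tail(fit$mse_trace, 1) <= target_mse
  model
}

#' Score cases with a trained MLP
#'
#' Applies the training min-max normalization, runs the forward pass, and
#' returns the two sigmoid outputs per case. The hard label is the larger
#' score; an exact tie at 0.5/0.5 is resolved to benign. `score_malignant`
#' is the malignancy score used for ROC analysis.
#'
#' @param model A trained `bus_mlp` (or a fresh one, given a matrix input and
#'   `normalize = FALSE`).
#' @param newdata Tibble containing the model's feature columns, or a
#'   numeric matrix with one row per case.
#' @param normalize Apply the stored training normalization (default `TRUE`
#'   when normalization stats are present).
#' @return A tibble with `score_benign`, `score_malignant` and `pred_label`.
#' @export
mlp_predict <- function(model, newdata, normalize = !is.null(model$norm_stats)) {
  stopifnot(inherits(model, "bus_mlp"))
  X <- if (is.matrix(newdata)) newdata
       else mlp_design(model, newdata, model$feature_names)
  if (ncol(X) != model$layer_sizes[["n_in"]])
    stop("feature vector length ", ncol(X), " does not match model input ",
         model$layer_sizes[["n_in"]], call. = FALSE)
  if (normalize) {
    ns <- model$norm_stats
    X <- sweep(sweep(X, 2, ns$min), 2, ns$max - ns$min, "/")
  }
  sig <- function(z) 1 / (1 + exp(-z))
  Hid <- sig(sweep(X %*% model$W1, 2, model$b1, "+"))
  Out <- sig(sweep(Hid %*% model$W2, 2, model$b2, "+"))
  tibble(
    score_benign = Out[, 1],
    score_malignant = Out[, 2],
    pred_label = ifelse(Out[, 2] > Out[, 1], "malignant", "benign")
  )
}

#' Case-level confusion counts
#'
#' Malignant is the positive class throughout.
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels.
#' @return A one-row tibble with `TP`, `FN`, `FP`, `TN` case counts.
#' @export
case_confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  tibble(
    TP = sum(truth == "malignant" & predicted == "malignant"),
    FN = sum(truth == "malignant" & predicted == "benign"),
    FP = sum(truth == "benign" & predicted == "malignant"),
    TN = sum(truth == "benign" & predicted == "benign")
  )
}

#' Diagnostic statistics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)` and accuracy
#' `(TP+TN)/n`, with malignant as the positive class.
#'
#' @param confusion A one-row tibble/list with `TP`, `FN`, `FP`, `TN`.
#' @return A one-row tibble with `sensitivity`, `specificity`, `accuracy`.
#' @export
diagnostic_metrics <- function(confusion) {
  TP <- confusion$TP; FN <- confusion$FN
  FP <- confusion$FP; TN <- confusion$TN
  if (TP + FN == 0 || FP + TN == 0)
    stop("empty positive or negative class", call. = FALSE)
  tibble(
    sensitivity = TP / (TP + FN),
    specificity = TN / (FP + TN),
    accuracy = (TP + TN) / (TP + FN + FP + TN)
  )
}

#' ROC curve and AUC from malignancy scores
#'
#' Sweeps a decision threshold over the unique scores (plus sentinels beyond
#' both extremes), collecting (FPR, TPR) operating points; the area under
#' the curve is computed by the trapezoidal rule and equals the normalized
#' Mann-Whitney U statistic.
#'
#' @param scores Numeric malignancy scores, higher = more malignant.
#' @param labels True labels (`"benign"` / `"malignant"`).
#' @return A `bus_roc`: tibble of `threshold`, `fpr`, `tpr` ordered by
#'   ascending FPR, with the AUC in `attr(, "auc")`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "malignant"
  if (!any(pos) || all(pos))
    stop("need both classes to compute a ROC curve", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- purrr::map_dfr(thr, function(t) {
    call_pos <- scores >= t
    tibble(threshold = t,
           fpr = sum(call_pos & !pos) / sum(!pos),
           tpr = sum(call_pos & pos) / sum(pos))
  })
  pts <- dplyr::arrange(pts, .data$fpr, .data$tpr)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  structure(pts, class = c("bus_roc", class(pts)), auc = auc)
}

#' @export
autoplot.bus_roc <- function(object, ...) {
  ggplot2::ggplot(as_tibble(unclass(object)[c("fpr", "tpr")]),
                  ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  title = sprintf("ROC (AUC = %.3f)",
                                  attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Evaluate a trained classifier on labelled cases
#'
#' @param model Trained `bus_mlp`.
#' @param data Tibble with `label` and the model's feature columns.
#' @return A list: `predictions` (tibble), `confusion` (tibble), `metrics`
#'   (sensitivity/specificity/accuracy tibble), `roc` (`bus_roc`), `auc`.
#' @export
evaluate_classifier <- function(model, data) {
  pred <- mlp_predict(model, data)
  conf <- case_confusion(data$label, pred$pred_label)
  roc <- roc_curve(pred$score_malignant, data$label)
  list(predictions = pred, confusion = conf,
       metrics = diagnostic_metrics(conf), roc = roc,
       auc = attr(roc, "auc"))
}

#' @export
tidy.bus_mlp <- function(x, ...) {
  w <- function(mat, layer) {
    tibble(layer = layer,
           from = rep(rownames(mat) %||% paste0("in", seq_len(nrow(mat))),
                      ncol(mat)),
           to = rep(paste0("unit", seq_len(ncol(mat))), each = nrow(mat)),
           weight = as.vector(mat))
  }
  W1 <- x$W1
  rownames(W1) <- x$feature_names %||% paste0("in", seq_len(nrow(W1)))
  W2 <- x$W2
  rownames(W2) <- paste0("hidden", seq_len(nrow(W2)))
  dplyr::bind_rows(
    w(W1, "hidden"), w(W2, "output"),
    tibble(layer = "hidden", from = "bias",
           to = paste0("unit", seq_along(x$b1)), weight = x$b1),
    tibble(layer = "output", from = "bias",
           to = paste0("unit", seq_along(x$b2)), weight = x$b2))
}

#' @export
glance.bus_mlp <- function(x, ...) {
  tibble(n_in = x$layer_sizes[["n_in"]],
         n_hidden = x$layer_sizes[["n_hidden"]],
         n_parameters = n_parameters(x),
         learning_rate = x$learning_rate,
         epochs_run = x$epochs_run,
         final_mse = if (length(x$mse_trace)) utils::tail(x$mse_trace, 1)
                     else NA_real_,
         converged = x$converged)
}

#' @export
print.bus_mlp <- function(x, ...) {
  cat(sprintf("<bus_mlp> %d-%d-2 sigmoid network (%d parameters), eta = %g\n",
              x$layer_sizes[["n_in"]], x$layer_sizes[["n_hidden"]],
              n_parameters(x), x$learning_rate))
  if (x$epochs_run > 0L)
    cat(sprintf("  trained %d epochs, final MSE %.4g, converged: %s\n",
                x$epochs_run, utils::tail(x$mse_trace, 1), x$converged))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a trained MLP to JSON and back
#'
#' @param model A `bus_mlp`.
#' @param path JSON file path.
#' @return `write_mlp_model()` returns `path` invisibly; `read_mlp_model()`
#'   returns the model.
#' @export
write_mlp_model <- function(model, path) {
  stopifnot(inherits(model, "bus_mlp"))
  obj <- list(layer_sizes = unname(model$layer_sizes),
              W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              learning_rate = model$learning_rate,
              feature_names = model$feature_names,
              norm_min = unname(model$norm_stats$min),
              norm_max = unname(model$norm_stats$max))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp_model
#' @export
read_mlp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- mlp_init(obj$layer_sizes[1], obj$layer_sizes[2],
                learning_rate = obj$learning_rate)
  m$W1 <- matrix(obj$W1, obj$layer_sizes[1], obj$layer_sizes[2])
  m$b1 <- as.numeric(obj$b1)
  m$W2 <- matrix(obj$W2, obj$layer_sizes[2], 2L)
  m$b2 <- as.numeric(obj$b2)
  m$feature_names <- obj$feature_names
  if (!is.null(obj$norm_min))
    m$norm_stats <- list(min = stats::setNames(obj$norm_min, obj$feature_names),
                         max = stats::setNames(obj$norm_max, obj$feature_names))
  m
}
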