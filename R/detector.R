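#' Detector architecture configuration
#'
#' Three stacked bidirectional LSTM layers with dropout after the first and
#' second, a fully connected layer on the concatenated final recurrent states
#' and a softmax over two classes. The default per-direction hidden sizes
#' `c(200, 100, 50)` make every published weight shape of the architecture
#' mutually consistent (stacked input weights 1600 x 12, recurrent 1600 x 200,
#' then 800 x 400 / 800 x 100, 400 x 200 / 400 x 50, fully connected 2 x 100).
#'
#' @param input_features features per timestep (one per abdominal channel).
#' @param hidden_sizes per-direction hidden units of the three BiLSTM layers.
#' @param dropout_rates dropout after the first and second recurrent layers.
#' @param n_classes number of output classes.
#' @return a `detector_config` list.
#' @export
detector_config <- function(input_features = 12,
                            hidden_sizes = c(200, 100, 50),
                            dropout_rates = c(0.5, 0.5),
                            n_classes = 2) {
  assert_that(all(hidden_sizes > 0) && all(hidden_sizes == round(hidden_sizes)),
              "hidden sizes must be positive integers")
  assert_that(all(dropout_rates >= 0 & dropout_rates < 1), "dropout rates must lie in [0, 1)")
  assert_that(input_features >= 1, "input_features must be >= 1")
  structure(list(input_features = input_features, hidden_sizes = hidden_sizes,
                 dropout_rates = dropout_rates, n_classes = n_classes),
            class = "detector_config")
}

#' Training schedule
#'
#' Adam optimization of the class-weighted cross-entropy with a single
#' scheduled learning-rate drop (factor `lr_drop_factor` after epoch
#' `ceiling(epochs / 2)`) and global L2-norm gradient clipping.
#'
#' @param epochs number of epochs (the published runs used 80-100; scaled
#'   experiments in this package use fewer).
#' @param initial_lr initial learning rate.
#' @param lr_drop_factor multiplicative drop applied halfway.
#' @param grad_clip global gradient-norm threshold.
#' @param batch_size minibatch size.
#' @param seed integer seed fixing initialization, shuffling, dropout and
#'   augmentation.
#' @param class_weights optional named `c(w0, w1)`; computed from the training
#'   labels via [class_weights()] when NULL.
#' @param augment lead-geometry augmentation: each minibatch is viewed through
#'   a random electrode geometry. Labels are untouched. This teaches the
#'   classifier invariance to the montage, which is what varies most between
#'   subjects; without it a frame classifier trained on a handful of subjects
#'   memorizes their lead patterns and transfers poorly.
#' @param aug_flip flip each channel's polarity with probability 1/2 when
#'   augmenting (electrode polarity is arbitrary).
#' @param aug_permute shuffle channel order when augmenting.
#' @param aug_gain_range per-channel gain jitter range when augmenting, or
#'   NULL for none.
#' @return a `train_schedule` list.
#' @export
train_schedule <- function(epochs = 90, initial_lr = 5e-4, lr_drop_factor = 0.1,
                           grad_clip = 1, batch_size = 64, seed = 1,
                           class_weights = NULL, augment = FALSE,
                           aug_flip = TRUE, aug_permute = FALSE,
                           aug_gain_range = NULL) {
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(initial_lr > 0, "initial_lr must be > 0")
  assert_that(grad_clip > 0, "grad_clip must be > 0")
  assert_that(batch_size >= 1, "batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_drop_factor = lr_drop_factor, grad_clip = grad_clip,
                 batch_size = as.integer(batch_size), seed = seed,
                 class_weights = class_weights, augment = isTRUE(augment),
                 aug_flip = isTRUE(aug_flip), aug_permute = isTRUE(aug_permute),
                 aug_gain_range = aug_gain_range),
            class = "train_schedule")
}

# Random electrode-geometry view of a minibatch, applied batch-wise during
# training only.
augment_batch <- function(Xb, schedule) {
  nch <- dim(Xb)[3]
  if (schedule$aug_permute) Xb <- Xb[, , sample.int(nch), drop = FALSE]
  scale <- rep(1, nch)
  if (schedule$aug_flip) scale <- scale * sample(c(-1, 1), nch, replace = TRUE)
  if (!is.null(schedule$aug_gain_range)) {
    scale <- scale * runif(nch, schedule$aug_gain_range[1], schedule$aug_gain_range[2])
  }
  if (!all(scale == 1)) {
    for (ch in seq_len(nch)) Xb[, , ch] <- Xb[, , ch] * scale[ch]
  }
  Xb
}

#' Learning rate at a given epoch
#'
#' Constant at `initial_lr` through epoch `ceiling(epochs / 2)`, then dropped
#' once by `lr_drop_factor` for the remaining epochs.
#'
#' @param epoch epoch number (1-based).
#' @param schedule a [train_schedule()].
#' @return the learning rate.
#' @export
lr_at <- function(epoch, schedule) {
  drop_after <- ceiling(schedule$epochs / 2)
  schedule$initial_lr * ifelse(epoch > drop_after, schedule$lr_drop_factor, 1)
}

#' Describe the network's layers and weight shapes
#'
#' Returns the layer table of the architecture with stacked-bidirectional
#' weight shapes: for a BiLSTM layer with H units per direction and D input
#' features, the stacked input weights are 8H x D, the recurrent weights
#' 8H x H, and the activation width 2H; the fully connected stage maps the
#' 2H-wide final recurrent output to the class logits.
#'
#' @param cfg a [detector_config()].
#' @return a tibble: `layer`, `type`, `activations`, `parameter`, `rows`,
#'   `cols` (NA where a stage has no weights).
#' @export
#' @examples
#' build_network(detector_config())
build_network <- function(cfg = detector_config()) {
  d <- cfg$input_features
  rows <- list(tibble(layer = "sequence_input", type = "input",
                      activations = d, parameter = NA_character_,
                      rows = NA_real_, cols = NA_real_))
  for (l in seq_along(cfg$hidden_sizes)) {
    h <- cfg$hidden_sizes[l]
    rows <- c(rows, list(
      tibble(layer = sprintf("bilstm_%d", l), type = "bilstm",
             activations = 2 * h,
             parameter = c("input_weights", "recurrent_weights", "bias"),
             rows = c(8 * h, 8 * h, 8 * h), cols = c(d, h, 1))
    ))
    if (l <= length(cfg$dropout_rates) && l < length(cfg$hidden_sizes)) {
      rows <- c(rows, list(tibble(layer = sprintf("dropout_%d", l), type = "dropout",
                                  activations = 2 * h, parameter = NA_character_,
                                  rows = NA_real_, cols = NA_real_)))
    }
    d <- 2 * h
  }
  rows <- c(rows, list(
    tibble(layer = "fully_connected", type = "dense", activations = cfg$n_classes,
           parameter = c("weights", "bias"),
           rows = c(cfg$n_classes, cfg$n_classes), cols = c(d, 1)),
    tibble(layer = "softmax", type = "softmax", activations = cfg$n_classes,
           parameter = NA_character_, rows = NA_real_, cols = NA_real_)
  ))
  bind_rows(rows)
}

#' Train the BiLSTM frame classifier
#'
#' Minimizes the class-weighted cross-entropy over labeled 65-ms frames with
#' Adam, the halfway learning-rate drop and global-norm gradient clipping.
#' Training is fully deterministic given `schedule$seed`.
#'
#' @param frames a labeled `frame_set` (see [frpl_label()]); frames should
#'   already be standardized.
#' @param cfg a [detector_config()].
#' @param schedule a [train_schedule()].
#' @param standardizer optional fitted [fit_standardizer()] stored with the
#'   model for later application at prediction time.
#' @param verbose print per-epoch progress.
#' @return a `bilstm_fit` object with elements `params`, `config`, `schedule`,
#'   `class_weights`, `history` (per-epoch tibble: `epoch`, `lr`, `loss`,
#'   `accuracy`).
#' @export
fit_detector <- function(frames, cfg = detector_config(), schedule = train_schedule(),
                         standardizer = NULL, verbose = FALSE) {
  assert_that(inherits(frames, "frame_set") && "label" %in% names(frames$info),
              "fit_detector needs a labeled frame_set")
  y <- frames$info$label
  if (length(unique(y)) < 2) {
    abort("training labels contain a single class; class weights are undefined",
          class = "fetalpeaks_imbalance_error")
  }
  w <- schedule$class_weights %||% class_weights(y)
  X <- frames$x
  n <- dim(X)[1]
  assert_that(dim(X)[3] == cfg$input_features,
              "frame channel count differs from config input_features")

  set.seed(schedule$seed)
  params <- init_bilstm_params(cfg$input_features, cfg$hidden_sizes, cfg$n_classes)
  flat <- flatten_params(params)
  opt <- adam_init(flat)
  history <- vector("list", schedule$epochs)

  for (epoch in seq_len(schedule$epochs)) {
    lr <- lr_at(epoch, schedule)
    idx <- sample.int(n)
    batch_starts <- seq(1, n, by = schedule$batch_size)
    ep_loss <- 0; ep_correct <- 0
    for (bs in batch_starts) {
      bi <- idx[bs:min(bs + schedule$batch_size - 1, n)]
      Xb <- X[bi, , , drop = FALSE]
      if (isTRUE(schedule$augment)) Xb <- augment_batch(Xb, schedule)
      yb <- y[bi]
      fwd <- bilstm_forward(Xb, params, dropout = cfg$dropout_rates, training = TRUE)
      lo <- weighted_ce(fwd$p, yb, w)
      grads <- bilstm_backward(fwd, lo$dlogits, params)
      gflat <- flatten_params(grads)
      gflat <- clip_global_norm(gflat, schedule$grad_clip)
      upd <- adam_step(flat, gflat, opt, lr)
      flat <- upd$params; opt <- upd$state
      params <- unflatten_params(flat, params)
      ep_loss <- ep_loss + lo$loss * length(bi)
      ep_correct <- ep_correct + sum((fwd$p[, 2] >= 0.5) == (yb == 1))
    }
    history[[epoch]] <- tibble(epoch = epoch, lr = lr,
                               loss = ep_loss / n, accuracy = ep_correct / n)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.1e  loss %.4f  acc %.3f",
                      epoch, lr, ep_loss / n, ep_correct / n))
    }
  }

  structure(list(params = params, config = cfg, schedule = schedule,
                 class_weights = w, standardizer = standardizer,
                 history = bind_rows(history)),
            class = "bilstm_fit")
}

#' Initial (untrained) training loss
#'
#' Evaluates the class-weighted cross-entropy of the freshly initialized
#' network on a labeled frame set, without any parameter update. With
#' near-zero logits this sits at `mean(w[label]) * log(2)`.
#'
#' @param frames labeled `frame_set`.
#' @param cfg,schedule as in [fit_detector()].
#' @return scalar loss.
#' @export
initial_loss <- function(frames, cfg = detector_config(), schedule = train_schedule()) {
  y <- frames$info$label
  w <- schedule$class_weights %||% class_weights(y)
  set.seed(schedule$seed)
  params <- init_bilstm_params(cfg$input_features, cfg$hidden_sizes, cfg$n_classes)
  fwd <- bilstm_forward(frames$x, params, training = FALSE, keep_cache = FALSE)
  weighted_ce(fwd$p, y, w)$loss
}

#' Per-frame posteriors and hard labels
#'
#' @param object a fitted `bilstm_fit`.
#' @param frames a `frame_set` matching the configured frame shape.
#' @param threshold Class-1 posterior threshold for the hard label.
#' @param batch_size frames scored per forward pass.
#' @param ... unused.
#' @return a tibble: `frame`, `start`, `subject`, `p1` (Class-1 posterior),
#'   `pred` (0/1), plus `label` when the frame set carries labels.
#' @export
predict.bilstm_fit <- function(object, frames, threshold = 0.5,
                               batch_size = 512, ...) {
  d <- dim(frames$x)
  assert_that(d[3] == object$config$input_features,
              "frame shape does not match the fitted network",
              class = "fetalpeaks_shape_error")
  n <- d[1]
  p1 <- numeric(n)
  for (bs in seq(1, n, by = batch_size)) {
    bi <- bs:min(bs + batch_size - 1, n)
    fwd <- bilstm_forward(frames$x[bi, , , drop = FALSE], object$params,
                          training = FALSE, keep_cache = FALSE)
    p1[bi] <- fwd$p[, 2]
  }
  out <- frames$info |>
    mutate(p1 = p1, pred = as.integer(p1 >= threshold))
  out
}

#' @export
print.bilstm_fit <- function(x, ...) {
  cat(sprintf("<bilstm_fit> hidden %s, %d epochs, final loss %.4f, final train acc %.3f\n",
              paste(x$config$hidden_sizes, collapse = "/"),
              nrow(x$history), tail(x$history$loss, 1), tail(x$history$accuracy, 1)))
  invisible(x)
}

#' Tidy the fitted detector's parameter table
#'
#' One row per parameter tensor with its dimensions and Frobenius norm,
#' broom-style.
#'
#' @param x a `bilstm_fit`.
#' @param ... unused.
#' @return a tibble: `parameter`, `rows`, `cols`, `norm`.
#' @method tidy bilstm_fit
#' @export
tidy.bilstm_fit <- function(x, ...) {
  flat <- flatten_params(x$params)
  bind_rows(lapply(names(flat), function(nm) {
    v <- flat[[nm]]
    tibble(parameter = nm,
           rows = if (is.matrix(v)) nrow(v) else length(v),
           cols = if (is.matrix(v)) ncol(v) else 1L,
           norm = sqrt(sum(v^2)))
  }))
}

#' One-row training summary, broom-style
#'
#' @param x a `bilstm_fit`.
#' @param ... unused.
#' @return a tibble with epochs, final loss/accuracy and class weights.
#' @method glance bilstm_fit
#' @export
glance.bilstm_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history),
         final_loss = tail(x$history$loss, 1),
         final_accuracy = tail(x$history$accuracy, 1),
         w0 = x$class_weights[["w0"]], w1 = x$class_weights[["w1"]],
         n_parameters = sum(vapply(flatten_params(x$params), length, numeric(1))))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot the training history
#'
#' @param fit a `bilstm_fit`.
#' @return a ggplot of loss and training accuracy per epoch.
#' @export
plot_training_history <- function(fit) {
  fit$history |>
    tidyr::pivot_longer(c("loss", "accuracy"), names_to = "metric") |>
    ggplot2::ggplot(ggplot2::aes(epoch, value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
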