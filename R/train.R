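# Training and evaluation: cross-entropy loss, Adam with decoupled weight
# decay, the epoch loop with best-validation checkpointing, and evaluation to
# a confusion matrix.

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 0.001 and weight decay 0.01, batch size 32, 25 epochs, 80/20 stratified
#' train/validation split.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay Decoupled weight decay applied to weight matrices
#'   (not to biases, layer-norm parameters, the class token or the position
#'   table).
#' @param batch_size Images per gradient step.
#' @param epochs Training epochs.
#' @param split_fraction Training fraction for [split_train_val()].
#' @param beta1,beta2,eps Adam moment coefficients and stabiliser.
#' @param seed Integer seed controlling shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, weight_decay = 1e-2,
                         batch_size = 32L, epochs = 25L,
                         split_fraction = 0.8,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 split_fraction = split_fraction,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Mean cross-entropy of softmax probabilities against 0/1 labels.
cross_entropy <- function(probs, labels) {
  p <- probs[cbind(seq_along(labels), labels + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

# Parameters that receive weight decay: 2-D+ weight arrays, by leaf name.
.decay_leaves <- c("W", "Wq", "Wk", "Wv", "Wo", "W1", "W2", "dw", "pw")

adam_init <- function(params) {
  paths <- param_paths(params)
  state <- lapply(paths, function(p) {
    v <- get_leaf(params, p)
    list(m = array(0, dim = if (is.null(dim(v))) length(v) else dim(v)),
         v = array(0, dim = if (is.null(dim(v))) length(v) else dim(v)))
  })
  list(paths = paths, state = state, t = 0L)
}

adam_step <- function(params, grads, opt, cfg) {
  opt$t <- opt$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  lr <- cfg$learning_rate
  for (i in seq_along(opt$paths)) {
    p <- opt$paths[[i]]
    g <- get_leaf(grads, p)
    th <- get_leaf(params, p)
    st <- opt$state[[i]]
    st$m <- b1 * st$m + (1 - b1) * g
    st$v <- b2 * st$v + (1 - b2) * g * g
    opt$state[[i]] <- st
    upd <- (st$m / corr1) / (sqrt(st$v / corr2) + cfg$eps)
    if (p[length(p)] %in% .decay_leaves) {
      upd <- upd + cfg$weight_decay * th
    }
    set_val <- th - lr * upd
    params <- set_leaf(params, p, set_val)
  }
  list(params = params, opt = opt)
}

#' Train a model
#'
#' Minimises softmax cross-entropy with Adam (decoupled weight decay) over
#' shuffled mini-batches. Per-epoch training loss/accuracy (running averages
#' over the batches as seen during the epoch) and validation loss/accuracy are
#' recorded; the parameters with the best validation accuracy are retained in
#' the returned model (ties keep the earlier epoch). All randomness (shuffling,
#' attention dropout) is derived from `config$seed`, so runs are reproducible
#' on one machine. A non-finite loss aborts with a diagnostic.
#'
#' @param model An `rvit_model` (freshly built or warm).
#' @param train_set,val_set `rvit_dataset` objects (non-empty).
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best-validation weights), `final_model` (last
#'   epoch's weights) and `history` (data.frame: epoch, train_loss, train_acc,
#'   val_loss, val_acc).
#' @export
train <- function(model, train_set, val_set, config = train_config(),
                  verbose = FALSE) {
  stopifnot(inherits(model, "rvit_model"),
            inherits(train_set, "rvit_dataset"),
            inherits(val_set, "rvit_dataset"),
            inherits(config, "train_config"))
  n <- length(train_set$images)
  if (n == 0L || length(val_set$images) == 0L) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  params <- model$params
  opt <- adam_init(params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(),
                     val_acc = numeric())
  best <- list(acc = -Inf, params = params, epoch = 0L)
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + config$batch_size - 1L, n)
        idx <- ord[i:j]
        imgs <- train_set$images[idx]
        labs <- train_set$labels[idx]
        m_cur <- structure(list(config = model$config, params = params),
                           class = "rvit_model")
        fw <- model_forward(m_cur, imgs, training = TRUE, want_cache = TRUE)
        loss <- cross_entropy(fw$probs, labs)
        if (!is.finite(loss)) {
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d (batch %d-%d)",
            ep, i, j), call. = FALSE)
        }
        B <- length(idx)
        onehot <- matrix(0, B, 2L)
        onehot[cbind(seq_len(B), labs + 1L)] <- 1
        dlogits <- (fw$probs - onehot) / B
        bw <- model_backward(m_cur, fw$cache, dlogits)
        stepped <- adam_step(params, bw$grads, opt, config)
        params <- stepped$params
        opt <- stepped$opt
        ep_loss <- ep_loss + loss * B
        ep_correct <- ep_correct +
          sum((max.col(fw$probs, ties.method = "first") - 1L) == labs)
        i <- j + 1L
      }
      m_cur <- structure(list(config = model$config, params = params),
                         class = "rvit_model")
      va <- eval_loss_acc(m_cur, val_set, config$batch_size)
      hist <- rbind(hist, data.frame(
        epoch = ep, train_loss = ep_loss / n, train_acc = ep_correct / n,
        val_loss = va$loss, val_acc = va$acc))
      if (va$acc > best$acc) {
        best <- list(acc = va$acc, params = params, epoch = ep)
      }
      if (verbose) {
        message(sprintf(
          "epoch %2d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
          ep, ep_loss / n, ep_correct / n, va$loss, va$acc))
      }
    }
  })
  list(model = structure(list(config = model$config, params = best$params),
                         class = "rvit_model"),
       final_model = structure(list(config = model$config, params = params),
                               class = "rvit_model"),
       best_epoch = best$epoch,
       history = hist)
}

# Loss and accuracy over a dataset in eval mode.
eval_loss_acc <- function(model, dataset, batch_size = 32L) {
  n <- length(dataset$images)
  loss <- 0; correct <- 0L
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    fw <- model_forward(model, dataset$images[i:j], training = FALSE)
    labs <- dataset$labels[i:j]
    loss <- loss + cross_entropy(fw$probs, labs) * (j - i + 1L)
    correct <- correct +
      sum((max.col(fw$probs, ties.method = "first") - 1L) == labs)
    i <- j + 1L
  }
  list(loss = loss / n, acc = correct / n)
}

#' Evaluate a model to a confusion matrix
#'
#' Runs the model in evaluation mode (dropout off), takes the argmax class per
#' image and tallies counts against the dataset labels (positive class =
#' tumor, label 1). Counts always sum to the dataset size.
#'
#' @param model A trained `rvit_model`.
#' @param dataset An `rvit_dataset`.
#' @param batch_size Images per forward batch.
#' @return A [confusion_matrix()].
#' @export
evaluate <- function(model, dataset, batch_size = 32L) {
  stopifnot(inherits(dataset, "rvit_dataset"))
  pred <- predict(model, dataset, type = "class", batch_size = batch_size)
  lab <- dataset$labels
  confusion_matrix(TP = sum(pred == 1L & lab == 1L),
                   FP = sum(pred == 1L & lab == 0L),
                   TN = sum(pred == 0L & lab == 0L),
                   FN = sum(pred == 0L & lab == 1L))
}

#' Write a training history to CSV
#'
#' @param history The `history` data.frame from [train()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
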