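#' Temporally regularized MSE loss
#'
#' The training objective is the batch mean of the squared Euclidean error of
#' the final-shift prediction, optionally extended by weighted squared errors
#' of the two preceding shifts:
#' \deqn{L = \frac{1}{N}\sum_j \|\Delta s_{t_n} - y_{t_n}\|^2
#'   + w_{n-1}\|\Delta s_{t_{n-1}} - y_{t_{n-1}}\|^2
#'   + w_{n-2}\|\Delta s_{t_{n-2}} - y_{t_{n-2}}\|^2}
#' With both weights zero this is exactly the plain MSE objective; the
#' auxiliary terms regularize training and are never used at inference.
#'
#' @param preds list with `y_tn` (3 x N matrix, mm) and, when a weight is
#'   non-zero, `y_tn1` / `y_tn2`.
#' @param targets list with `tn` and, when needed, `tn1` / `tn2` (each N x 3
#'   or 3 x N).
#' @param w_n1,w_n2 regularization weights in [0, 1].
#' @return The scalar loss (mm^2).
#' @export
motion_loss <- function(preds, targets, w_n1 = 0, w_n2 = 0) {
  if (w_n1 < 0 || w_n1 > 1 || w_n2 < 0 || w_n2 > 1)
    stop("loss weights must lie in [0, 1]")
  t_n <- as_3xn(targets$tn)
  y <- preds$y_tn
  if (is.null(y) || ncol(as_3xn(y)) == 0) stop("empty prediction batch")
  y <- as_3xn(y)
  if (ncol(y) != ncol(t_n)) stop("prediction/target batch sizes differ")
  n <- ncol(y)
  loss <- sum((t_n - y)^2) / n
  for (term in list(list(w_n1, preds$y_tn1, targets$tn1, "y_tn1"),
                    list(w_n2, preds$y_tn2, targets$tn2, "y_tn2"))) {
    if (term[[1]] > 0) {
      if (is.null(term[[2]]) || is.null(term[[3]]))
        stop("auxiliary predictions/targets required when ", term[[4]],
             " weight is non-zero")
      loss <- loss + term[[1]] * sum((as_3xn(term[[3]]) - as_3xn(term[[2]]))^2) / n
    }
  }
  loss
}

as_3xn <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, 3, 1)
  if (nrow(x) != 3) x <- t(x)
  x
}

# gradient of motion_loss wrt each prediction head (3 x N matrices)
motion_loss_grad <- function(preds, targets, w_n1 = 0, w_n2 = 0, scale = 1) {
  t_n <- as_3xn(targets$tn)
  n <- ncol(t_n)
  g <- list(y_tn = 2 * (preds$y_tn - t_n) / n * scale)
  if (w_n1 > 0) g$y_tn1 <- 2 * w_n1 * (preds$y_tn1 - as_3xn(targets$tn1)) / n * scale
  if (w_n2 > 0) g$y_tn2 <- 2 * w_n2 * (preds$y_tn2 - as_3xn(targets$tn2)) / n * scale
  g
}

#' Split regions of interest into train/validation/test sets
#'
#' Splitting is by ROI, never by sequence: all sequences acquired on one
#' tissue region share its split, so no region leaks between sets.
#'
#' @param roi_ids vector of distinct ROI identifiers.
#' @param n_test,n_val number of ROIs held out for testing and validation.
#' @param seed seed for the random assignment.
#' @return List with integer vectors `train`, `val`, `test` (disjoint, and
#'   jointly covering `roi_ids`).
#' @export
split_rois <- function(roi_ids, n_test = 5L, n_val = 5L, seed = 1L) {
  roi_ids <- unique(roi_ids)
  if (length(roi_ids) <= n_test + n_val)
    stop(sprintf("need more than %d ROIs to hold out %d test + %d val",
                 n_test + n_val, n_test, n_val))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  shuffled <- sample(roi_ids)
  list(test = sort(shuffled[seq_len(n_test)]),
       val = sort(shuffled[n_test + seq_len(n_val)]),
       train = sort(shuffled[-(seq_len(n_test + n_val))]))
}

#' Training protocol configuration
#'
#' @param epochs training epochs (full-scale protocol: 150; the desk
#'   profile uses 40).
#' @param batch_size sequences per optimization step.
#' @param optimizer only `"adam"` is implemented.
#' @param learning_rate Adam step size (constant schedule).
#' @param seed seed controlling initialization order, shuffling and any
#'   training-time augmentation.
#' @param microbatch sequences processed jointly per engine call (memory
#'   knob; does not affect results beyond floating-point summation order).
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 150L, batch_size = 50L, optimizer = "adam",
                         learning_rate = 1e-3, seed = 1L, microbatch = 10L) {
  if (optimizer != "adam") stop("only the 'adam' optimizer is implemented")
  if (epochs < 1 || batch_size < 1 || learning_rate <= 0)
    stop("epochs, batch_size and learning_rate must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 optimizer = optimizer, learning_rate = learning_rate,
                 seed = as.integer(seed), microbatch = as.integer(microbatch)),
            class = "train_config")
}

#' @rdname train_config
#' @details `desk_train_config()` is the desk-scale protocol: 40 epochs,
#'   batch size 5 (with only 100 training sequences, the full-scale batch
#'   of 50 would allow just two optimizer steps per epoch), learning rate
#'   1e-3, sized to train any of the five architectures in minutes on one
#'   CPU core.
#' @export
desk_train_config <- function(seed = 1L, epochs = 40L) {
  train_config(epochs = epochs, batch_size = 5L, learning_rate = 1e-3,
               seed = seed, microbatch = 5L)
}

#' Train a motion-estimation model
#'
#' Minimizes the (optionally temporally regularized) MSE loss over the
#' training-ROI sequences with Adam, evaluating the validation loss once per
#' epoch. The parameters with the best validation loss are retained as the
#' model's weights; the final-epoch weights are kept alongside. Training is
#' deterministic for a fixed `train_cfg$seed`.
#'
#' @param model an `oct_model` (its `aux_outputs` flag must match non-zero
#'   loss weights).
#' @param dataset an `oct_dataset`.
#' @param split ROI split from [split_rois()].
#' @param train_cfg a [train_config()].
#' @param w_n1,w_n2 temporal regularization weights, see [motion_loss()].
#' @param augment optional training-time augmentation: a function applied to
#'   each `oct_sequence` when a batch is assembled (fresh randomness every
#'   epoch), e.g. `function(s) distort_sequence(s, 0.5, 2L)`.
#' @param verbose print per-epoch losses.
#' @return The trained `oct_model`, with `history` (data.frame: epoch,
#'   train_loss, val_loss), `final_params`, and `best_epoch` fields added.
#' @export
train_model <- function(model, dataset, split, train_cfg = train_config(),
                        w_n1 = 0, w_n2 = 0, augment = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "oct_model"), inherits(dataset, "oct_dataset"))
  if ((w_n1 > 0 || w_n2 > 0) && !model$config$aux_outputs)
    stop("non-zero loss weights require a model built with aux_outputs = TRUE")
  roi <- vapply(dataset$sequences, function(s) s$roi_id, integer(1))
  idx_train <- which(roi %in% split$train)
  idx_val <- which(roi %in% split$val)
  if (length(idx_train) == 0 || length(idx_val) == 0)
    stop("split leaves the training or validation set empty")

  targets_all <- dataset_targets(dataset)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(train_cfg$seed)

  opt <- adam_init(model$params, train_cfg$learning_rate)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best_val <- Inf
  best_params <- model$params
  best_epoch <- NA_integer_

  for (ep in seq_len(train_cfg$epochs)) {
    ord <- sample(idx_train)
    ep_loss <- 0
    nb <- 0
    for (b0 in seq(1, length(ord), by = train_cfg$batch_size)) {
      bidx <- ord[b0:min(length(ord), b0 + train_cfg$batch_size - 1L)]
      step <- train_step(model, dataset, targets_all, bidx, train_cfg,
                         w_n1, w_n2, augment)
      if (!is.finite(step$loss))
        stop(sprintf("non-finite training loss at epoch %d; lower the learning rate",
                     ep))
      model$params <- adam_update(opt, model$params, step$grads)
      ep_loss <- ep_loss + step$loss
      nb <- nb + 1
    }
    val_loss <- batch_loss(model, dataset, targets_all, idx_val, train_cfg,
                           w_n1, w_n2)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   val_loss = val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_params <- model$params
      best_epoch <- ep
    }
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep, ep_loss / nb, val_loss))
  }
  model$final_params <- model$params
  model$params <- best_params          # best-validation checkpoint
  model$best_epoch <- best_epoch
  model$history <- hist
  model$loss_weights <- c(w_n1 = w_n1, w_n2 = w_n2)
  model
}

# one optimization step: loss + gradients accumulated over microbatches;
# training-time augmentation may transform labels, so targets are taken from
# the (augmented) sequences themselves
train_step <- function(model, dataset, targets_all, bidx, train_cfg,
                       w_n1, w_n2, augment) {
  nbatch <- length(bidx)
  grads <- NULL
  loss <- 0
  for (m0 in seq(1, nbatch, by = train_cfg$microbatch)) {
    take <- bidx[m0:min(nbatch, m0 + train_cfg$microbatch - 1L)]
    if (is.null(augment)) {
      X <- assemble_batch(dataset, take)
      tg <- list(tn = targets_all$tn[take, , drop = FALSE],
                 tn1 = targets_all$tn1[take, , drop = FALSE],
                 tn2 = targets_all$tn2[take, , drop = FALSE])
    } else {
      seqs <- lapply(dataset$sequences[take], augment)
      X <- array(0, c(fov_voxels(), 5L, 1L, length(take)))
      for (j in seq_along(seqs)) X[, , , , 1L, j] <- seqs[[j]]$volumes
      sh <- function(row) t(vapply(seqs, function(s) s$shifts[row, ], numeric(3)))
      tg <- list(tn = sh(5), tn1 = sh(4), tn2 = sh(3))
    }
    fw <- net_forward(model, X, keep = TRUE)
    w <- length(take) / nbatch          # microbatch share of the batch mean
    loss <- loss + motion_loss(fw$pred, tg, w_n1, w_n2) * w
    # the micro-batch loss gradient is a mean over the micro batch; scaling
    # by its share turns the accumulated result into the full-batch mean
    dp <- motion_loss_grad(fw$pred, tg, w_n1, w_n2, scale = w)
    g <- net_backward(model, fw$cache, dp)
    grads <- if (is.null(grads)) g else mapply(`+`, grads, g, SIMPLIFY = FALSE)
  }
  list(loss = loss, grads = grads)
}

batch_loss <- function(model, dataset, targets_all, idx, train_cfg, w_n1, w_n2) {
  loss <- 0
  n <- length(idx)
  mb <- max(train_cfg$microbatch, 25L)   # forward-only: larger batches are fine
  for (m0 in seq(1, n, by = mb)) {
    take <- idx[m0:min(n, m0 + mb - 1L)]
    X <- assemble_batch(dataset, take)
    tg <- list(tn = targets_all$tn[take, , drop = FALSE],
               tn1 = targets_all$tn1[take, , drop = FALSE],
               tn2 = targets_all$tn2[take, , drop = FALSE])
    fw <- net_forward(model, X, keep = FALSE)
    loss <- loss + motion_loss(fw$pred, tg, w_n1, w_n2) * length(take) / n
  }
  loss
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

adam_update <- function(st, params, grads) {
  st$t <- st$t + 1L
  b1 <- st$beta1; b2 <- st$beta2
  corr1 <- 1 - b1^st$t
  corr2 <- 1 - b2^st$t
  for (k in names(params)) {
    g <- grads[[k]]
    st$m[[k]] <- b1 * st$m[[k]] + (1 - b1) * g
    st$v[[k]] <- b2 * st$v[[k]] + (1 - b2) * g^2
    params[[k]] <- params[[k]] -
      st$lr * (st$m[[k]] / corr1) / (sqrt(st$v[[k]] / corr2) + st$eps)
  }
  params
}
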