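# Per-channel affine normalization of a sequence array using stored
# training statistics (no-op when the model carries no scalers).
normalize_sequences <- function(sequences, scalers) {
  if (is.null(scalers) || is.null(scalers$seq_mu)) return(sequences)
  d <- dim(sequences)
  flat <- matrix(sequences, d[1] * d[2], d[3])
  flat <- sweep(sweep(flat, 2, scalers$seq_mu), 2, scalers$seq_sd, "/")
  array(flat, d)
}

# Multi-task CNN-LSTM surrogate: configuration, construction, training
# loop (weighted multi-task MSE + L2, triangular cyclical learning rate,
# momentum SGD with global-norm gradient clipping), batch-stratified
# splitting and permutation-based feature attribution. The network forward
# and backward passes live in compiled code (src/surrogate_net.cpp).

#' Network architecture configuration
#'
#' The fixed multi-task architecture: image branch 3x3 conv (3->32, ReLU)
#' -> 2x2 maxpool -> 3x3 conv (32->64, ReLU) -> 2x2 maxpool -> 1x1
#' projection to 8 channels -> 2048-dim flatten; sequence branch LSTM
#' (128->256, tanh, sequence output) -> LSTM (256->128, tanh) with
#' attention pooling over the 50 hidden states; fusion 2048+128 = 2176 ->
#' FC 512 (ReLU) -> 8 linear heads.
#'
#' @param image_dim input image dimensions.
#' @param sequence_dim input sequence dimensions (timesteps, channels).
#' @param cnn_feature_dim flattened CNN feature size.
#' @param lstm_output_dim final LSTM feature size.
#' @param fusion_dim fused feature size; must equal
#'   `cnn_feature_dim + lstm_output_dim`.
#' @param fc1_dim hidden fully-connected size.
#' @param output_dim number of task heads (8).
#' @param d_k attention key dimension.
#' @return An object of class `network_config`.
#' @export
network_config <- function(image_dim = c(64, 64, 3),
                           sequence_dim = c(50, 128),
                           cnn_feature_dim = 2048, lstm_output_dim = 128,
                           fusion_dim = 2176, fc1_dim = 512, output_dim = 8,
                           d_k = 128) {
  cfg <- structure(list(image_dim = image_dim, sequence_dim = sequence_dim,
                        cnn_feature_dim = cnn_feature_dim,
                        lstm_output_dim = lstm_output_dim,
                        fusion_dim = fusion_dim, fc1_dim = fc1_dim,
                        output_dim = output_dim, d_k = d_k),
                   class = "network_config")
  if (fusion_dim != cnn_feature_dim + lstm_output_dim) {
    stop("fusion_dim must equal cnn_feature_dim + lstm_output_dim")
  }
  if (output_dim != 8) stop("the multi-task head is fixed at 8 targets")
  supported <- identical(image_dim, c(64, 64, 3)) &&
    identical(sequence_dim, c(50, 128)) && cnn_feature_dim == 2048 &&
    lstm_output_dim == 128 && fc1_dim == 512
  if (!supported) stop("unsupported architecture dimensions")
  cfg
}

#' Per-task loss weights
#'
#' @param w nonnegative task weights (length 8, conventionally summing
#'   to 1).
#' @param lambda_reg L2 regularization coefficient.
#' @return An object of class `task_weights`.
#' @export
task_weights <- function(w = rep(1 / 8, 8), lambda_reg = 1e-4) {
  stopifnot(length(w) == 8, all(w >= 0), lambda_reg >= 0)
  structure(list(w = w, lambda_reg = lambda_reg), class = "task_weights")
}

#' Training schedule
#'
#' Triangular cyclical learning rate between `lr_min` and `lr_max`
#' (period `2 * cycle` iterations, peak at iteration 0), gradient
#' clipping, 70/15/15 batch-stratified splitting.
#'
#' @param lr_min,lr_max learning-rate range (`0 < lr_min < lr_max`).
#' @param cycle iterations per half-triangle (>= 1).
#' @param max_epochs training epochs.
#' @param clip_norm global gradient-norm clip.
#' @param split train/validation/test fractions.
#' @param batch_size minibatch size.
#' @param momentum SGD momentum.
#' @param rng_seed seed for init, shuffling and splitting.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(lr_min = 1e-4, lr_max = 1e-2, cycle = 200,
                              max_epochs = 10, clip_norm = 1.0,
                              split = c(0.70, 0.15, 0.15), batch_size = 32,
                              momentum = 0.9, rng_seed = 1) {
  stopifnot(lr_min > 0, lr_max > lr_min, cycle >= 1,
            abs(sum(split) - 1) < 1e-9, length(split) == 3)
  structure(list(lr_min = lr_min, lr_max = lr_max, cycle = cycle,
                 max_epochs = max_epochs, clip_norm = clip_norm,
                 split = split, batch_size = batch_size,
                 momentum = momentum, rng_seed = rng_seed),
            class = "training_schedule")
}

#' Triangular cyclical learning rate
#'
#' `lr(t) = lr_min + (lr_max - lr_min) max(0, 1 - |t - 2 k cycle| / cycle)`
#' with `k` the nearest peak index; periodic with period `2 * cycle`,
#' peaking at `t = 0`.
#'
#' @param t iteration (>= 0, vectorised).
#' @param sched a [training_schedule()].
#' @return Learning rate(s) in `[lr_min, lr_max]`.
#' @export
cyclical_lr <- function(t, sched) {
  stopifnot(all(t >= 0))
  k <- round(t / (2 * sched$cycle))
  sched$lr_min + (sched$lr_max - sched$lr_min) *
    pmax(0, 1 - abs(t - 2 * k * sched$cycle) / sched$cycle)
}

#' Build the surrogate network
#'
#' @param cfg a [network_config()].
#' @param rng_seed weight-initialization seed.
#' @return An object of class `surrogate_model` holding the compiled
#'   network state.
#' @export
build_network <- function(cfg = network_config(), rng_seed = 1) {
  stopifnot(inherits(cfg, "network_config"))
  structure(list(ptr = .net_create(as.integer(rng_seed)), config = cfg,
                 scalers = NULL),
            class = "surrogate_model")
}

#' Forward pass of the surrogate
#'
#' @param model a [build_network()] model.
#' @param images array `(n, 64, 64, 3)`.
#' @param sequences array `(n, 50, 128)`.
#' @param chunk internal batch size (memory control).
#' @param rescale map predictions back to original target units using the
#'   training scalers, when available.
#' @return Matrix `(n, 8)` of predictions.
#' @export
predict_surrogate <- function(model, images, sequences, chunk = 64,
                              rescale = TRUE) {
  n <- dim(images)[1]
  out <- matrix(0, n, 8)
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    out[idx, ] <- .net_predict(model$ptr,
                               images[idx, , , , drop = FALSE],
                               normalize_sequences(
                                 sequences[idx, , , drop = FALSE],
                                 model$scalers))
  }
  if (rescale && !is.null(model$scalers)) {
    out <- sweep(sweep(out, 2, model$scalers$sd, "*"), 2,
                 model$scalers$mu, "+")
  }
  out
}

#' Report layer shapes of a forward pass
#'
#' @inheritParams predict_surrogate
#' @return Named list of intermediate activation dimensions; element
#'   `checked` flags whether each compiled activation matched.
#' @export
network_shapes <- function(model, images, sequences) {
  .net_shapes(model$ptr, images, sequences)
}

#' Plain 2-D convolution (reference implementation)
#'
#' The convolutional primitive
#' `y[i, j] = sum_m sum_n x[i + m, j + n] w[m, n] + b` (valid
#' cross-correlation), kept as a readable reference for the compiled
#' network's convolution stages.
#'
#' @param x input matrix.
#' @param w kernel matrix.
#' @param b bias scalar.
#' @return The `(nrow(x) - nrow(w) + 1) x (ncol(x) - ncol(w) + 1)` output.
#' @export
conv2d <- function(x, w, b = 0) {
  M <- nrow(w); N <- ncol(w)
  out_r <- nrow(x) - M + 1
  out_c <- ncol(x) - N + 1
  stopifnot(out_r >= 1, out_c >= 1)
  y <- matrix(0, out_r, out_c)
  for (i in seq_len(out_r)) {
    for (j in seq_len(out_c)) {
      y[i, j] <- sum(x[i:(i + M - 1), j:(j + N - 1)] * w) + b
    }
  }
  y
}

#' Attention-weighted feature pooling
#'
#' `F_att = sum_i alpha_i F_i` with
#' `alpha = softmax(scores / sqrt(d_k))`; the weights sum to 1.
#'
#' @param features matrix with one feature vector per row.
#' @param scores one score per feature vector.
#' @param d_k key dimension used in the softmax temperature.
#' @return List with `pooled` (vector) and `alpha` (weights).
#' @export
attention_pool <- function(features, scores, d_k = ncol(features)) {
  features <- as.matrix(features)
  if (nrow(features) == 0) stop("empty feature list")
  stopifnot(length(scores) == nrow(features), d_k >= 1)
  s <- scores / sqrt(d_k)
  alpha <- exp(s - max(s))
  alpha <- alpha / sum(alpha)
  list(pooled = drop(crossprod(features, alpha)), alpha = alpha)
}

#' Weighted multi-task loss
#'
#' `L = sum_j w_j MSE_j + lambda ||theta||^2`; equals the regularization
#' term alone at perfect prediction.
#'
#' @param preds,targets `(n, 8)` matrices.
#' @param tw a [task_weights()].
#' @param param_sqnorm squared parameter norm `||theta||^2` (0 if
#'   unregularized or unknown).
#' @return The scalar loss.
#' @export
multitask_loss <- function(preds, targets, tw = task_weights(),
                           param_sqnorm = 0) {
  stopifnot(inherits(tw, "task_weights"),
            all(dim(preds) == dim(targets)), ncol(preds) == 8)
  mse <- colMeans((preds - targets)^2)
  sum(tw$w * mse) + tw$lambda_reg * param_sqnorm
}

#' Batch-level stratified 70/15/15 split
#'
#' Partitions whole batches (the experimental unit) into train /
#' validation / test so no batch id spans two partitions. Within each
#' variety stratum, batches are shuffled and assigned by largest-remainder
#' counts, keeping variety proportions close to global across partitions.
#'
#' @param batch_ids character vector, one id per record.
#' @param strata stratification label per record (e.g. variety); batches
#'   must be pure in their stratum.
#' @param sched a [training_schedule()] (fractions and seed).
#' @return List with `train`, `val`, `test`: record index vectors; and
#'   `batches`: the batch-id assignment.
#' @export
split_dataset <- function(batch_ids, strata = rep("all", length(batch_ids)),
                          sched = training_schedule()) {
  ub <- unique(batch_ids)
  if (length(ub) < 3) stop("fewer batches than partitions")
  b_stratum <- tapply(as.character(strata), batch_ids, function(s) s[1])
  assign <- character(0)
  nm <- character(0)
  old <- local_seed(substream_seed(sched$rng_seed, "split"))
  on.exit(restore_seed(old), add = TRUE)
  for (st in unique(b_stratum)) {
    ids <- sample(names(b_stratum)[b_stratum == st])
    n <- length(ids)
    base <- floor(n * sched$split)
    rem <- n * sched$split - base
    extra <- n - sum(base)
    if (extra > 0) {
      give <- order(-rem)[seq_len(extra)]
      base[give] <- base[give] + 1
    }
    assign <- c(assign, rep(c("train", "val", "test"), times = base))
    nm <- c(nm, ids)
  }
  names(assign) <- nm
  part <- assign[batch_ids]
  list(train = which(part == "train"), val = which(part == "val"),
       test = which(part == "test"), batches = assign)
}

#' Train the surrogate on generated fixtures
#'
#' Targets are z-scored per task on the training partition; training uses
#' the weighted multi-task loss, the triangular cyclical learning rate
#' and global-norm gradient clipping. Reproducible for a given schedule
#' seed (single-threaded).
#'
#' @param model a [build_network()] model.
#' @param fixtures a [generate_dataset()] result with arrays included.
#' @param sched a [training_schedule()].
#' @param tw a [task_weights()].
#' @param verbose print per-epoch losses.
#' @return List with `model` (trained, carrying the target scalers),
#'   `metrics` (per-task test `mse` and `r2` on the original target
#'   scale-free z-units), `history` (per-epoch train/val loss),
#'   `split` (the batch partition).
#' @export
train_surrogate <- function(model, fixtures, sched = training_schedule(),
                            tw = task_weights(), verbose = FALSE) {
  stopifnot(inherits(model, "surrogate_model"))
  if (is.null(fixtures$images)) stop("fixtures must include arrays")
  n <- nrow(fixtures$targets)
  if (n < 200) stop("need at least 200 records to train")
  sp <- split_dataset(fixtures$records$batch_id, fixtures$records$variety,
                      sched)
  mu <- colMeans(fixtures$targets[sp$train, , drop = FALSE])
  sd_ <- apply(fixtures$targets[sp$train, , drop = FALSE], 2, stats::sd)
  sd_[sd_ < 1e-9] <- 1
  Tz <- sweep(sweep(fixtures$targets, 2, mu), 2, sd_, "/")
  # per-channel z-scoring of the sensor sequences (training statistics);
  # raw channels carry wildly different scales (temperature ~22, duty ~0.5)
  seq_mu <- apply(fixtures$sequences[sp$train, , , drop = FALSE], 3, mean)
  seq_sd <- apply(fixtures$sequences[sp$train, , , drop = FALSE], 3,
                  stats::sd)
  seq_sd[seq_sd < 1e-9] <- 1
  model$scalers <- list(mu = mu, sd = sd_, seq_mu = seq_mu, seq_sd = seq_sd)

  old <- local_seed(substream_seed(sched$rng_seed, "shuffle"))
  on.exit(restore_seed(old), add = TRUE)
  iter <- 0L
  history <- data.frame()
  best_val <- Inf
  best_weights <- NULL
  for (epoch in seq_len(sched$max_epochs)) {
    ord <- sample(sp$train)
    ep_loss <- 0; n_b <- 0
    for (start in seq(1, length(ord), by = sched$batch_size)) {
      idx <- ord[start:min(start + sched$batch_size - 1, length(ord))]
      lr <- cyclical_lr(iter, sched)
      loss <- .net_train_batch(model$ptr,
                               fixtures$images[idx, , , , drop = FALSE],
                               normalize_sequences(
                                 fixtures$sequences[idx, , , drop = FALSE],
                                 model$scalers),
                               Tz[idx, , drop = FALSE],
                               lr, tw$w, tw$lambda_reg, sched$clip_norm,
                               sched$momentum)
      if (!is.finite(loss)) {
        stop("training diverged at epoch ", epoch, ", iteration ", iter,
             " (loss = ", loss, ", lr = ", signif(lr, 3), ")")
      }
      ep_loss <- ep_loss + loss; n_b <- n_b + 1
      iter <- iter + 1L
    }
    val_pred <- predict_surrogate(model,
      fixtures$images[sp$val, , , , drop = FALSE],
      fixtures$sequences[sp$val, , , drop = FALSE], rescale = FALSE)
    val_loss <- multitask_loss(val_pred, Tz[sp$val, , drop = FALSE], tw,
                               .net_sqnorm(model$ptr))
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n_b,
                                         val_loss = val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss
      best_weights <- .net_get_weights(model$ptr)
    }
    if (verbose) {
      message(sprintf("epoch %d: train %.4f  val %.4f", epoch,
                      ep_loss / n_b, val_loss))
    }
  }
  # test metrics come from the best-validation-epoch checkpoint (the
  # cyclical schedule can end mid-cycle on a noisy step)
  if (!is.null(best_weights)) .net_set_weights(model$ptr, best_weights)
  test_pred <- predict_surrogate(model,
    fixtures$images[sp$test, , , , drop = FALSE],
    fixtures$sequences[sp$test, , , drop = FALSE], rescale = FALSE)
  Tt <- Tz[sp$test, , drop = FALSE]
  mse <- colMeans((test_pred - Tt)^2)
  sst <- apply(Tt, 2, function(y) sum((y - mean(y))^2))
  ssr <- colSums((test_pred - Tt)^2)
  r2 <- ifelse(sst > 0, 1 - ssr / sst, NA_real_)
  metrics <- data.frame(task = colnames(fixtures$targets), mse = mse,
                        r2 = r2, row.names = NULL)
  list(model = model, metrics = metrics, history = history, split = sp)
}

#' Permutation feature attribution
#'
#' Model-agnostic importance: for each named feature group (a set of
#' sequence channels or the whole image), the group's values are permuted
#' across records and the increase in weighted test loss is recorded;
#' importances are clipped at zero and normalized to sum to 1.
#'
#' @param model trained [build_network()] model (with scalers).
#' @param fixtures a [generate_dataset()] result with arrays.
#' @param idx record indices to evaluate on (e.g. the test partition).
#' @param feature_groups named list; each element is either
#'   `list(type = "sequence", channels = <ints>)` or
#'   `list(type = "image")`.
#' @param tw a [task_weights()].
#' @param rng_seed permutation seed.
#' @return Named numeric vector of normalized importances.
#' @export
permutation_attribution <- function(model, fixtures, idx, feature_groups,
                                    tw = task_weights(), rng_seed = 1) {
  stopifnot(length(idx) >= 2)
  for (g in feature_groups) {
    if (!g$type %in% c("sequence", "image")) {
      stop("unknown feature group type: ", g$type)
    }
  }
  mu <- model$scalers$mu; sd_ <- model$scalers$sd
  Tz <- sweep(sweep(fixtures$targets[idx, , drop = FALSE], 2, mu), 2,
              sd_, "/")
  imgs <- fixtures$images[idx, , , , drop = FALSE]
  seqs <- fixtures$sequences[idx, , , drop = FALSE]
  base_pred <- predict_surrogate(model, imgs, seqs, rescale = FALSE)
  base_loss <- multitask_loss(base_pred, Tz, tw)
  old <- local_seed(substream_seed(rng_seed, "permute"))
  on.exit(restore_seed(old), add = TRUE)
  imp <- vapply(feature_groups, function(g) {
    perm <- sample(length(idx))
    if (g$type == "image") {
      pred <- predict_surrogate(model, imgs[perm, , , , drop = FALSE],
                                seqs, rescale = FALSE)
    } else {
      s2 <- seqs
      s2[, , g$channels] <- s2[perm, , g$channels, drop = FALSE]
      pred <- predict_surrogate(model, imgs, s2, rescale = FALSE)
    }
    multitask_loss(pred, Tz, tw) - base_loss
  }, 0)
  imp <- pmax(imp, 0)
  if (sum(imp) > 0) imp <- imp / sum(imp)
  stats::setNames(imp, names(feature_groups))
}
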