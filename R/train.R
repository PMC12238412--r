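#' Local training configuration
#'
#' Hyperparameters a simulated collaborator uses for one round of local SGD.
#' The loss is cross-entropy plus soft Dice in equal (1:1) weighting, the
#' optimizer is plain SGD without momentum; batch order is seeded per
#' (client, round) so whole simulations replay exactly.
#'
#' @param learning_rate Nonnegative SGD step size.
#' @param epochs_per_round Positive integer passes over the local train split.
#' @param batch_size Positive integer cases per gradient step.
#' @param seed Integer seed for batch ordering.
#' @return An object of class `local_train_config`.
#' @export
local_train_config <- function(learning_rate = 0.2, epochs_per_round = 1L,
                               batch_size = 1L, seed = 1L) {
  if (learning_rate < 0) stop("learning_rate must be >= 0")
  if (epochs_per_round < 1) stop("epochs_per_round must be >= 1")
  if (batch_size < 1) stop("batch_size must be >= 1")
  structure(list(learning_rate = as.numeric(learning_rate),
                 epochs_per_round = as.integer(epochs_per_round),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "local_train_config")
}

#' Train a model locally on one client
#'
#' Runs `epochs_per_round` passes of mini-batch SGD over the client's train
#' split, starting from `params` (which is not modified: parameter vectors have
#' value semantics). Returns the updated parameters and post-training local
#' metrics: validation DSC/loss of the updated model and training DSC.
#'
#' @param params A `model_params` (the model received from the aggregator).
#' @param client A `client_dataset`.
#' @param cfg A [local_train_config()].
#' @param round Round index, mixed into the batch-order seed so different
#'   rounds shuffle differently (default 0).
#' @return List with `params` (updated `model_params`) and `metrics`
#'   (`val_dsc`, `val_loss`, `train_dsc`, `n_train`, `n_val`).
#' @export
local_train <- function(params, client, cfg, round = 0L) {
  stopifnot(inherits(params, "model_params"), inherits(client, "client_dataset"),
            inherits(cfg, "local_train_config"))
  if (length(client$cases) == 0) stop("client has no cases")
  tensors <- fold_params(params)
  train_idx <- client$train_indices
  targets <- lapply(client$cases, function(cs) onehot_labels(cs$labels))

  for (epoch in seq_len(cfg$epochs_per_round)) {
    order_seed <- derive_seed(cfg$seed, "order", client$site_id, round, epoch)
    idx <- with_stream(order_seed, sample(train_idx))
    chunks <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    for (batch in chunks) {
      grads <- NULL
      for (i in batch) {
        fw <- model_forward(tensors, client$cases[[i]]$image, keep_cache = TRUE)
        sl <- seg_loss(fw$logits, targets[[i]], with_grad = TRUE)
        if (!is.finite(sl$loss)) {
          stop("non-finite local loss at site ", client$site_id,
               ", round ", round, ", case ", i)
        }
        g <- model_backward(tensors, fw$cache, sl$grad)
        grads <- if (is.null(grads)) g else purrr::map2(grads, g, `+`)
      }
      lr <- cfg$learning_rate / length(batch)
      for (nm in names(tensors)) {
        tensors[[nm]] <- tensors[[nm]] - lr * grads[[nm]]
      }
    }
  }

  updated <- new_model_params(unfold_params(tensors, params$layout),
                              params$layout, params$config)
  vm <- local_validate(updated, client)
  train_dsc <- mean(vapply(train_idx, function(i) {
    case_mean_dsc(predict_labels(updated, client$cases[[i]]),
                  client$cases[[i]]$labels)
  }, numeric(1)))
  list(params = updated,
       metrics = list(val_dsc = vm$val_dsc, val_loss = vm$val_loss,
                      train_dsc = train_dsc,
                      n_train = client$n_train, n_val = client$n_val))
}

#' Validate a model on one client's validation split
#'
#' Pure function: computes the mean validation DSC (averaged over the WT, TC
#' and ET regions, then over validation cases) and the mean validation loss
#' (the training loss function: cross-entropy + soft Dice) on the client's
#' fixed 20% validation split.
#'
#' @param params A `model_params` or [oracle_model()].
#' @param client A `client_dataset`.
#' @return List with `val_dsc`, `val_loss`, `n_train`, `n_val`.
#' @export
local_validate <- function(params, client) {
  stopifnot(inherits(client, "client_dataset"))
  if (length(client$val_indices) == 0) stop("client has an empty validation split")
  scores <- vapply(client$val_indices, function(i) {
    case <- client$cases[[i]]
    pred <- predict_labels(params, case)
    d <- case_mean_dsc(pred, case$labels)
    l <- if (inherits(params, "oracle_model")) {
      seg_loss(onehot_logits(case$labels), onehot_labels(case$labels))$loss
    } else {
      tensors <- fold_params(params)
      seg_loss(model_forward(tensors, case$image)$logits,
               onehot_labels(case$labels))$loss
    }
    c(d, l)
  }, numeric(2))
  list(val_dsc = mean(scores[1, ]), val_loss = mean(scores[2, ]),
       n_train = client$n_train, n_val = client$n_val)
}

# Mean DSC over the three tumor regions of one case.
case_mean_dsc <- function(pred, ref) {
  rp <- regions_from_labels(pred)
  rr <- regions_from_labels(ref)
  mean(c(dsc(rp$WT, rr$WT), dsc(rp$TC, rr$TC), dsc(rp$ET, rr$ET)))
}

# Logits whose softmax is (numerically) the one-hot encoding of `labels`.
onehot_logits <- function(labels) {
  t <- onehot_labels(labels)
  t * 50
}
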