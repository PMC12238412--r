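#' Weighting-term results
#'
#' Aggregation methods compute one or more independent, normalized weighting
#' terms p_i^k per collaborator k, combine them additively or multiplicatively,
#' and use the renormalized result as convex-combination coefficients for the
#' local parameter vectors. A term can weight at three granularities: one
#' weight per client ("model"), one per tensor ("tensor"), or one per scalar
#' parameter ("scalar"). Internally a term is a clients-by-units matrix whose
#' columns each sum to 1.
#'
#' @param term_id Identifier of the term.
#' @param clients Character vector of client ids (rows).
#' @param w Nonnegative numeric matrix (clients x units) or vector (one unit).
#' @param granularity "model", "tensor" or "scalar".
#' @param units Optional column names (tensor names for "tensor").
#' @param flag Optional character note (degenerate fallbacks are flagged).
#' @return An object of class `fl_weights`.
#' @export
fl_weights <- function(term_id, clients, w, granularity = "model",
                       units = NULL, flag = NULL) {
  if (is.null(dim(w))) w <- matrix(w, ncol = 1)
  stopifnot(nrow(w) == length(clients))
  if (any(w < 0)) stop("weights must be nonnegative")
  tot <- colSums(w)
  # normalize per unit; an all-zero unit gets uniform weights
  zero <- tot == 0
  if (any(zero)) {
    w[, zero] <- 1 / nrow(w)
    tot[zero] <- 1
    flag <- c(flag, "all-zero unit(s) fell back to uniform")
  }
  w <- sweep(w, 2, tot, `/`)
  rownames(w) <- clients
  if (!is.null(units)) colnames(w) <- units
  structure(list(term_id = term_id, clients = clients, w = w,
                 granularity = granularity, flag = flag),
            class = "fl_weights")
}

#' @export
print.fl_weights <- function(x, ...) {
  cat("<fl_weights> ", x$term_id, " (", x$granularity, ", ",
      length(x$clients), " clients x ", ncol(x$w), " units)\n", sep = "")
  if (ncol(x$w) == 1) print(stats::setNames(round(x$w[, 1], 4), x$clients))
  if (!is.null(x$flag)) cat("  flag:", paste(x$flag, collapse = "; "), "\n")
  invisible(x)
}

#' Dataset-size weighting (FedAvg)
#'
#' The baseline term every method incorporates: p^k = N_k / sum_k N_k.
#'
#' @param sizes Named vector of per-client sample counts.
#' @return An `fl_weights`.
#' @export
term_fedavg <- function(sizes) {
  if (sum(sizes) <= 0) stop("total client size is zero")
  fl_weights("fedavg", names(sizes), as.numeric(sizes))
}

#' Validation-loss weighting (potential for local optimization)
#'
#' p^k proportional to the local validation loss after local training: clients
#' with high loss can still improve more than low-loss clients. All-zero
#' losses fall back to uniform weights (flagged).
#'
#' @param losses Named nonnegative vector of post-training validation losses.
#' @return An `fl_weights`.
#' @export
term_val_loss <- function(losses) {
  if (any(losses < 0)) stop("validation losses must be nonnegative")
  fl_weights("val_loss", names(losses), as.numeric(losses))
}

#' Local-improvement ratio weighting (CostWAvg-style)
#'
#' p^k proportional to the ratio of the validation metric after local training
#' to the metric of the received global model, DSC(w_t^k) / DSC(w_t^g):
#' clients that improved most on their own data weigh more. Zero denominators
#' are clamped to `eps` and flagged.
#'
#' @param dsc_post Named vector: per-client validation DSC after local
#'   training.
#' @param dsc_pre Named vector: per-client validation DSC of the received
#'   global model (same order).
#' @param eps Clamp for zero denominators.
#' @return An `fl_weights`.
#' @export
term_cost_ratio <- function(dsc_post, dsc_pre, eps = 1e-8) {
  stopifnot(length(dsc_post) == length(dsc_pre))
  flag <- NULL
  if (any(dsc_pre <= 0)) {
    flag <- "zero pre-training DSC clamped to eps"
    dsc_pre <- pmax(dsc_pre, eps)
  }
  fl_weights("cost_ratio", names(dsc_post), as.numeric(dsc_post / dsc_pre),
             flag = flag)
}

#' Inverse parameter-distance weighting
#'
#' Weights clients by the inverse distance between their updated parameters and
#' the uniform mean of all updated parameters, wbar = (1/K) sum_k w^k. At
#' "model" granularity the L1 norm of the whole vector is used; at "tensor"
#' granularity one L1 distance per tensor; at "scalar" granularity the
#' element-wise absolute difference. Zero distances are clamped to `eps`
#' (maximal finite weight) and flagged.
#'
#' @param params_list Named list of `model_params` (>= 2 clients, equal
#'   layouts).
#' @param granularity "model" (default), "tensor" or "scalar".
#' @param eps Clamp for zero distances.
#' @return An `fl_weights` at the requested granularity.
#' @export
term_inv_param_distance <- function(params_list,
                                    granularity = c("model", "tensor",
                                                    "scalar"),
                                    eps = 1e-8) {
  granularity <- match.arg(granularity)
  if (length(params_list) < 2) stop("needs >= 2 clients")
  clients <- names(params_list)
  mat <- do.call(rbind, lapply(params_list, function(p) p$values))
  wbar <- colMeans(mat)
  absdiff <- abs(sweep(mat, 2, wbar, `-`))

  flag <- NULL
  clamp <- function(d) {
    if (any(d == 0)) flag <<- "zero distance clamped to eps"
    pmax(d, eps)
  }
  if (granularity == "model") {
    d <- clamp(rowSums(absdiff))
    fl_weights("inv_param_distance", clients, 1 / d, "model", flag = flag)
  } else if (granularity == "tensor") {
    sizes <- layout_sizes(params_list[[1]])
    groups <- rep(seq_along(sizes), sizes)
    d <- t(apply(absdiff, 1, function(row) tapply(row, groups, sum)))
    d <- clamp(d)
    fl_weights("inv_param_distance", clients, 1 / d, "tensor",
               units = names(sizes), flag = flag)
  } else {
    d <- clamp(absdiff)
    fl_weights("inv_param_distance", clients, 1 / d, "scalar", flag = flag)
  }
}

#' PID-controller weighting terms (FedPIDAvg)
#'
#' Three terms inspired by a proportional-integral-derivative controller:
#' the proportional term is dataset size (FedAvg); the derivative term is the
#' per-client cost reduction L(w_{t-1}^k) - L(w_t^k) (negative reductions
#' floored at 0, since aggregation weights must stay nonnegative); the
#' integral term is the sum of the local loss over the past `window` rounds
#' (the rounds before t), indicating remaining room for improvement. At round
#' 0 the derivative and integral terms fall back to uniform (flagged); shorter
#' histories use the available prefix.
#'
#' @param loss_history Numeric matrix of post-training validation losses,
#'   one row per completed round (row i = round i-1), columns named by client.
#' @param sizes Named per-client sample counts (for the proportional term).
#' @param window Integral window length in rounds (default 5).
#' @return List of three `fl_weights`: `p_P`, `p_D`, `p_I`.
#' @export
term_pid <- function(loss_history, sizes, window = 5L) {
  stopifnot(is.matrix(loss_history), window >= 1)
  clients <- colnames(loss_history)
  t_rows <- nrow(loss_history)
  p_P <- term_fedavg(sizes[clients])

  if (t_rows < 2) {
    uni <- fl_weights("pid_d", clients, rep(1, length(clients)),
                      flag = "round 0: uniform fallback")
    uni_i <- fl_weights("pid_i", clients, rep(1, length(clients)),
                        flag = "round 0: uniform fallback")
    return(list(p_P = p_P, p_D = uni, p_I = uni_i))
  }
  red <- pmax(loss_history[t_rows - 1, ] - loss_history[t_rows, ], 0)
  p_D <- fl_weights("pid_d", clients, red)
  past <- loss_history[seq_len(t_rows - 1), , drop = FALSE]
  take <- min(window, nrow(past))
  sums <- colSums(past[(nrow(past) - take + 1):nrow(past), , drop = FALSE])
  p_I <- fl_weights("pid_i", clients, sums)
  list(p_P = p_P, p_D = p_D, p_I = p_I)
}

#' Inverse training-DSC weighting
#'
#' p^k proportional to 1 / train_dsc^k: penalizes clients that already fit
#' their local data (likely overfitting) and lifts clients with potential for
#' local optimization. Zero DSCs are clamped to `eps`.
#'
#' @param train_dsc Named per-client training DSC values in \[0, 1\].
#' @param eps Clamp for zero DSC.
#' @return An `fl_weights`.
#' @export
term_inv_train_dsc <- function(train_dsc, eps = 1e-8) {
  fl_weights("inv_train_dsc", names(train_dsc),
             1 / pmax(as.numeric(train_dsc), eps))
}

#' Combination rule for weighting terms
#'
#' @param mode "additive" (weighted arithmetic mean, weights `betas`) or
#'   "multiplicative".
#' @param betas Per-term nonnegative combination weights (additive mode only);
#'   normalized to sum 1. Default equal.
#' @return An object of class `combination_spec`.
#' @export
combination_spec <- function(mode = c("additive", "multiplicative"),
                             betas = NULL) {
  mode <- match.arg(mode)
  if (!is.null(betas)) {
    if (any(betas < 0) || sum(betas) == 0) {
      stop("betas must be nonnegative with positive sum")
    }
    betas <- betas / sum(betas)
  }
  structure(list(mode = mode, betas = betas), class = "combination_spec")
}

#' Combine weighting terms into final aggregation weights
#'
#' Additive: sum_i beta_i p_i^k; multiplicative: prod_i p_i^k. The result is
#' renormalized to sum 1 per granularity unit. Terms of coarser granularity
#' are broadcast to the finest granularity present ("model" weights replicate
#' across units; "tensor" weights expand to "scalar" using `sizes`).
#'
#' @param terms List of `fl_weights` over an identical client set.
#' @param spec A [combination_spec()].
#' @param sizes Named tensor sizes ([layout_sizes()]), required only when
#'   "tensor" and "scalar" terms are mixed.
#' @return An `fl_weights` with `term_id = "combined"`.
#' @export
combine_terms <- function(terms, spec = combination_spec("additive"),
                          sizes = NULL) {
  stopifnot(length(terms) >= 1, inherits(spec, "combination_spec"))
  clients <- terms[[1]]$clients
  for (tm in terms) {
    if (!identical(sort(tm$clients), sort(clients))) {
      stop("terms cover different client sets")
    }
  }
  grans <- vapply(terms, function(tm) tm$granularity, character(1))
  target <- c("scalar", "tensor", "model")[
    min(match(grans, c("scalar", "tensor", "model")))]

  mats <- lapply(terms, function(tm) {
    w <- tm$w[clients, , drop = FALSE]
    broadcast_weights(w, tm$granularity, target, sizes)
  })
  n_units <- max(vapply(mats, ncol, integer(1)))
  mats <- lapply(mats, function(m) {
    if (ncol(m) == n_units) m else m[, rep(1L, n_units), drop = FALSE]
  })
  ncols <- vapply(mats, ncol, integer(1))
  if (length(unique(ncols)) != 1) {
    stop("terms disagree on the number of granularity units")
  }

  if (spec$mode == "additive") {
    betas <- spec$betas %||% rep(1 / length(mats), length(mats))
    if (length(betas) != length(mats)) stop("one beta per term required")
    out <- Reduce(`+`, purrr::map2(mats, betas, `*`))
  } else {
    out <- Reduce(`*`, mats)
    dead <- colSums(out) == 0
    if (any(dead)) {
      zero_clients <- clients[apply(out[, dead, drop = FALSE] == 0, 1, all)]
      stop("multiplicative combination is zero for all clients (",
           paste(zero_clients, collapse = ", "), ")")
    }
  }
  fl_weights("combined", clients, out, target,
             units = colnames(mats[[1]]))
}

broadcast_weights <- function(w, from, to, sizes = NULL) {
  if (from == to) return(w)
  if (from == "model") {
    # a per-client weight applies to every unit; number of units is decided
    # by the finer terms, so return a 1-column matrix and recycle later
    return(w)
  }
  if (from == "tensor" && to == "scalar") {
    if (is.null(sizes)) stop("mixing tensor and scalar terms requires `sizes`")
    return(w[, rep(seq_along(sizes), sizes), drop = FALSE])
  }
  stop("cannot broadcast ", from, " weights to ", to, " granularity")
}

#' Aggregate local parameters with normalized weights
#'
#' The element-wise convex combination `sum_k p^k w_t^k` of the clients'
#' parameter vectors, with weights broadcast per granularity: one coefficient
#' per client ("model"), per tensor ("tensor"), or per scalar ("scalar").
#'
#' @param params_list Named list of `model_params` with identical layouts.
#' @param weights An `fl_weights` over the same clients.
#' @return A `model_params` (the aggregated global model).
#' @export
aggregate_params <- function(params_list, weights) {
  stopifnot(inherits(weights, "fl_weights"))
  clients <- weights$clients
  if (!all(clients %in% names(params_list))) {
    stop("weights reference unknown clients")
  }
  layouts <- lapply(params_list, function(p) p$layout)
  if (length(unique(vapply(params_list, function(p) length(p$values),
                           integer(1)))) != 1) {
    stop("parameter layouts differ across clients")
  }
  p0 <- params_list[[clients[1]]]
  n <- length(p0$values)
  expand <- switch(weights$granularity,
    model = function(row) rep(row[1], n),
    tensor = {
      sizes <- layout_sizes(p0)
      function(row) rep(row, sizes)
    },
    scalar = {
      if (ncol(weights$w) != n) stop("scalar weights do not match layout")
      function(row) row
    }
  )
  acc <- numeric(n)
  for (k in clients) {
    acc <- acc + unname(expand(weights$w[k, ])) * params_list[[k]]$values
  }
  new_model_params(acc, p0$layout, p0$config)
}

#' Server-side optimizer state
#'
#' Server optimizers rewrite aggregation as a gradient step: the
#' pseudo-gradient is `Delta_t = w_t^g - aggregate`, and the server applies
#' `w <- w - lambda_s * step(Delta_t)` with step = identity (kind "sgd") or an
#' Adam moment update (kind "adam"). Kind "none" returns the aggregated model
#' unchanged.
#'
#' @param kind "none", "sgd" or "adam".
#' @param lr Server learning rate lambda_s (positive).
#' @param beta1,beta2,eps Adam hyperparameters.
#' @return An object of class `server_optimizer_state`.
#' @export
server_optimizer <- function(kind = c("none", "sgd", "adam"), lr = 1,
                             beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  kind <- match.arg(kind)
  if (lr <= 0) stop("server learning rate must be positive")
  structure(list(kind = kind, lr = lr, beta1 = beta1, beta2 = beta2,
                 eps = eps, m = NULL, v = NULL, t = 0L),
            class = "server_optimizer_state")
}

#' Apply the server optimizer to an aggregated model
#'
#' @param prev_global The global `model_params` from the previous round.
#' @param aggregated The freshly aggregated `model_params`.
#' @param state A [server_optimizer()] state.
#' @return List with `params` (new global model) and `state` (updated moments).
#' @export
server_update <- function(prev_global, aggregated, state) {
  stopifnot(inherits(state, "server_optimizer_state"))
  if (state$kind == "none") {
    return(list(params = aggregated, state = state))
  }
  delta <- prev_global$values - aggregated$values
  if (state$kind == "sgd") {
    step <- delta
  } else { # adam
    if (is.null(state$m)) {
      state$m <- numeric(length(delta))
      state$v <- numeric(length(delta))
    }
    state$t <- state$t + 1L
    state$m <- state$beta1 * state$m + (1 - state$beta1) * delta
    state$v <- state$beta2 * state$v + (1 - state$beta2) * delta^2
    mhat <- state$m / (1 - state$beta1^state$t)
    vhat <- state$v / (1 - state$beta2^state$t)
    step <- mhat / (sqrt(vhat) + state$eps)
  }
  params <- new_model_params(prev_global$values - state$lr * step,
                             prev_global$layout, prev_global$config)
  list(params = params, state = state)
}

#' Rescale client weights by parameter-change magnitude
#'
#' Scales each client's weight by `norm^strength`, where `norm` is the L1 norm
#' of the client's parameter change between the previous and current round,
#' then renormalizes. Positive `strength` up-weights large movers; negative
#' `strength` down-weights them (the stability-motivated default used in the
#' regularized-aggregation preset). With no previous round available the
#' weights are returned unchanged (flagged).
#'
#' @param weights An `fl_weights`.
#' @param change_norms Named per-client nonnegative change norms, or `NULL`
#'   when no previous round exists.
#' @param strength Exponent applied to the norms (0 = identity).
#' @param eps Clamp for zero norms.
#' @return An `fl_weights`.
#' @export
regularize_by_param_change <- function(weights, change_norms, strength = -1,
                                       eps = 1e-8) {
  stopifnot(inherits(weights, "fl_weights"))
  if (is.null(change_norms)) {
    weights$flag <- c(weights$flag, "round 0: no previous parameters")
    return(weights)
  }
  if (strength == 0) return(weights)
  fac <- pmax(as.numeric(change_norms[weights$clients]), eps)^strength
  fl_weights(weights$term_id, weights$clients, weights$w * fac,
             weights$granularity, units = colnames(weights$w),
             flag = weights$flag)
}
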