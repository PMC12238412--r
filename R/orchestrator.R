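#' Learning-rate / epoch schedules
#'
#' @param kind "constant", "step" (multiply by `gamma` every `every` rounds) or
#'   "polynomial" (`base * (1 - t / total_rounds)^power`, clamped at 0 past the
#'   horizon).
#' @param base Base value at round 0.
#' @param gamma,every Step-schedule decay factor and period.
#' @param power,total_rounds Polynomial-schedule exponent and horizon.
#' @return An object of class `fl_schedule`.
#' @export
fl_schedule <- function(kind = c("constant", "step", "polynomial"), base,
                        gamma = 0.5, every = 1L, power = 1,
                        total_rounds = 100L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, base = base, gamma = gamma,
                 every = as.integer(every), power = power,
                 total_rounds = as.integer(total_rounds)),
            class = "fl_schedule")
}

#' Evaluate a schedule at a round
#'
#' @param schedule An [fl_schedule()].
#' @param t Round index (0-based, >= 0).
#' @return The scheduled value.
#' @export
schedule_value <- function(schedule, t) {
  stopifnot(inherits(schedule, "fl_schedule"), t >= 0)
  switch(schedule$kind,
    constant = schedule$base,
    step = schedule$base * schedule$gamma^(t %/% schedule$every),
    polynomial = {
      frac <- 1 - t / schedule$total_rounds
      schedule$base * max(frac, 0)^schedule$power
    }
  )
}

#' Declarative aggregator specification
#'
#' An aggregator is a list of weighting terms, a combination rule, an optional
#' server optimizer and an optional parameter-change regularizer. Term specs
#' are lists with an `id` in `fedavg`, `val_loss`, `cost_ratio`,
#' `inv_param_distance` (extra field `granularity`), `inv_train_dsc`, `pid_d`,
#' `pid_i` (extra field `window`).
#'
#' @param name Human-readable aggregator name.
#' @param terms List of term specs.
#' @param combination A [combination_spec()].
#' @param server A [server_optimizer()].
#' @param regularize_strength Exponent for
#'   [regularize_by_param_change()] (`NULL` = off).
#' @return An object of class `aggregator_spec`.
#' @export
aggregator_spec <- function(name, terms,
                            combination = combination_spec("additive"),
                            server = server_optimizer("none"),
                            regularize_strength = NULL) {
  structure(list(name = name, terms = terms, combination = combination,
                 server = server, regularize_strength = regularize_strength),
            class = "aggregator_spec")
}

#' @rdname aggregator_spec
#' @export
aggregator_fedavg <- function() {
  aggregator_spec("fedavg", list(list(id = "fedavg")))
}

#' @rdname aggregator_spec
#' @export
aggregator_flstar <- function() {
  aggregator_spec("flstar",
                  list(list(id = "fedavg"), list(id = "val_loss")),
                  combination_spec("multiplicative"))
}

#' @rdname aggregator_spec
#' @export
aggregator_costwavg <- function() {
  aggregator_spec("costwavg",
                  list(list(id = "fedavg"), list(id = "cost_ratio")),
                  combination_spec("additive"))
}

#' @rdname aggregator_spec
#' @param betas Combination weights of the proportional, derivative and
#'   integral terms.
#' @param window Integral window (rounds).
#' @export
aggregator_fedpidavg <- function(betas = c(1, 1, 1) / 3, window = 5L) {
  aggregator_spec("fedpidavg",
                  list(list(id = "fedavg"), list(id = "pid_d"),
                       list(id = "pid_i", window = window)),
                  combination_spec("additive", betas))
}

#' @rdname aggregator_spec
#' @export
aggregator_sanctuary <- function() {
  aggregator_spec("sanctuary",
                  list(list(id = "fedavg"),
                       list(id = "inv_param_distance", granularity = "tensor"),
                       list(id = "inv_train_dsc")),
                  combination_spec("multiplicative"))
}

#' @rdname aggregator_spec
#' @param strength Regularization exponent (negative down-weights large
#'   parameter movers).
#' @export
aggregator_httuas <- function(strength = -1) {
  aggregator_spec("httuas",
                  list(list(id = "fedavg"),
                       list(id = "inv_param_distance", granularity = "scalar")),
                  combination_spec("additive"),
                  regularize_strength = strength)
}

#' @rdname aggregator_spec
#' @param server_lr Server (Adam) learning rate.
#' @export
aggregator_rofl <- function(server_lr = 0.5) {
  aggregator_spec("rofl",
                  list(list(id = "fedavg"),
                       list(id = "inv_param_distance", granularity = "scalar")),
                  combination_spec("multiplicative"),
                  server = server_optimizer("adam", lr = server_lr))
}

#' Experiment configuration
#'
#' Bundles everything one simulated FL experiment needs. The master seed fans
#' out into independent named streams (model init, batch order, timing,
#' selection), so two configs differing only in the aggregator consume
#' identical timing and data randomness.
#'
#' @param federation A `federation`.
#' @param aggregator An [aggregator_spec()].
#' @param policy A [selection_policy()].
#' @param base_train A [local_train_config()]; its learning rate and epochs
#'   are overridden by the schedules each round.
#' @param lr_schedule,epochs_schedule [fl_schedule()]s (defaults: constant at
#'   the base config's values).
#' @param timing Named list of [client_timing_params()] (one per site), or
#'   `NULL` to build a size-proportional profile from the master seed.
#' @param budget Simulated-time budget in seconds (default 604800, one week).
#' @param max_rounds Hard cap on rounds (default 1000; the budget usually
#'   terminates first).
#' @param model A [model_config()] or `NULL` (default 32x32, width 4, init
#'   seeded from the master seed).
#' @param seed Master seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(federation, aggregator = aggregator_fedavg(),
                              policy = selection_policy("all"),
                              base_train = local_train_config(),
                              lr_schedule = NULL, epochs_schedule = NULL,
                              timing = NULL, budget = 604800,
                              max_rounds = 1000L, model = NULL, seed = 1L) {
  stopifnot(inherits(federation, "federation"),
            inherits(aggregator, "aggregator_spec"),
            inherits(policy, "selection_policy"),
            inherits(base_train, "local_train_config"), budget > 0)
  lr_schedule <- lr_schedule %||%
    fl_schedule("constant", base_train$learning_rate)
  epochs_schedule <- epochs_schedule %||%
    fl_schedule("constant", base_train$epochs_per_round)
  structure(list(federation = federation, aggregator = aggregator,
                 policy = policy, base_train = base_train,
                 lr_schedule = lr_schedule, epochs_schedule = epochs_schedule,
                 timing = timing, budget = budget,
                 max_rounds = as.integer(max_rounds), model = model,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

# Compute the aggregator's weighting terms for one round.
compute_round_weights <- function(agg, ctx) {
  terms <- lapply(agg$terms, function(ts) {
    switch(ts$id,
      fedavg = term_fedavg(ctx$sizes),
      val_loss = term_val_loss(ctx$post_loss),
      cost_ratio = term_cost_ratio(ctx$post_dsc, ctx$pre_dsc),
      inv_param_distance =
        term_inv_param_distance(ctx$params_list,
                                ts$granularity %||% "model"),
      inv_train_dsc = term_inv_train_dsc(ctx$train_dsc),
      pid_d = term_pid(ctx$loss_history, ctx$sizes)$p_D,
      pid_i = term_pid(ctx$loss_history, ctx$sizes,
                       ts$window %||% 5L)$p_I,
      stop("unknown weighting term: ", ts$id)
    )
  })
  w <- combine_terms(terms, agg$combination, sizes = ctx$layout_sizes)
  if (!is.null(agg$regularize_strength)) {
    w <- regularize_by_param_change(w, ctx$change_norms,
                                    agg$regularize_strength)
  }
  w
}

#' Run one simulated federated-learning experiment
#'
#' The round loop: select collaborators, distribute the global model, validate
#' it locally, train locally, compute weighting terms, combine, aggregate,
#' apply the optional server optimizer, sample the round's simulated time and
#' advance the clock. The run terminates once the cumulative simulated time
#' exceeds the budget (the terminating round is not credited) or `max_rounds`
#' is reached. The per-round global validation DSC is the dataset-size-weighted
#' mean of all clients' validation DSC on the produced model; the final model
#' is the round model (including the initial model) with the highest global
#' validation DSC among credited rounds.
#'
#' @param config An [experiment_config()].
#' @param verbose Print a line per round.
#' @return An object of class `fl_run`: fields `rounds` (tibble), `curve`
#'   ([convergence_curve()]), `final_params`, `final_round`, `selections`,
#'   `timing`, `config`.
#' @export
run_federation <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  fed <- config$federation
  ids <- names(client_sizes(fed))
  sizes <- client_sizes(fed)
  clients <- stats::setNames(fed$clients, ids)

  timing <- config$timing %||%
    make_timing_profile(fed, "size_proportional",
                        seed = derive_seed(config$seed, "timing_profile"))
  model_cfg <- config$model %||%
    model_config(seed = derive_seed(config$seed, "init"))
  global <- build_model(model_cfg)
  server_state <- config$aggregator$server

  # validation metrics of the current global model on every client
  validate_all <- function(params) {
    vapply(ids, function(id) {
      vm <- local_validate(params, clients[[id]])
      c(vm$val_dsc, vm$val_loss)
    }, numeric(2))
  }
  weighted_dsc <- function(vals) sum(vals * sizes) / sum(sizes)

  glob_val <- validate_all(global)
  dsc0 <- weighted_dsc(glob_val[1, ])
  curve_t <- 0
  curve_d <- dsc0
  best_dsc <- dsc0
  best_params <- global
  best_round <- -1L # -1 = initial model

  loss_history <- matrix(glob_val[2, ], nrow = 1,
                         dimnames = list(NULL, ids))
  prev_params <- NULL
  prev_times <- NULL
  cumulative <- 0
  rows <- list()
  selections <- list()

  for (t in seq_len(config$max_rounds) - 1L) {
    sel <- select_clients(config$policy, t, fed, prev_times)
    selections[[t + 1L]] <- as.character(sel)
    lr_t <- schedule_value(config$lr_schedule, t)
    ep_t <- max(1L, as.integer(round(schedule_value(config$epochs_schedule, t))))

    cfg_t <- local_train_config(lr_t, ep_t, config$base_train$batch_size,
                                seed = derive_seed(config$seed, "batches"))
    fits <- lapply(sel, function(id) {
      local_train(global, clients[[id]], cfg_t, round = t)
    })
    names(fits) <- sel
    params_list <- lapply(fits, function(f) f$params)
    post_dsc <- vapply(fits, function(f) f$metrics$val_dsc, numeric(1))
    post_loss <- vapply(fits, function(f) f$metrics$val_loss, numeric(1))
    train_dsc <- vapply(fits, function(f) f$metrics$train_dsc, numeric(1))

    # loss history over all clients, carry-forward for unselected ones
    hist_row <- loss_history[nrow(loss_history), ]
    hist_row[sel] <- post_loss
    loss_history <- rbind(loss_history, hist_row)

    change_norms <- if (is.null(prev_params)) NULL else {
      stats::setNames(vapply(as.character(sel), function(id) {
        if (is.null(prev_params[[id]])) 0
        else sum(abs(params_list[[id]]$values - prev_params[[id]]$values))
      }, numeric(1)), as.character(sel))
    }

    ctx <- list(sizes = sizes[sel], pre_dsc = glob_val[1, sel],
                post_dsc = post_dsc, post_loss = post_loss,
                train_dsc = train_dsc, params_list = params_list,
                loss_history = loss_history[, sel, drop = FALSE],
                change_norms = change_norms,
                layout_sizes = layout_sizes(global))
    weights <- compute_round_weights(config$aggregator, ctx)
    aggregated <- aggregate_params(params_list, weights)
    if (any(!is.finite(aggregated$values))) {
      stop("non-finite global parameters after aggregation in round ", t)
    }
    upd <- server_update(global, aggregated, server_state)
    global <- upd$params
    server_state <- upd$state

    # timing: drawn for ALL clients from a round-indexed stream, so the
    # sequence is identical whatever the aggregator or selection does
    times_all <- with_stream(derive_seed(config$seed, "timing", t), {
      vapply(ids, function(id) {
        sample_client_time(timing[[id]], clients[[id]]$n_train,
                           clients[[id]]$n_val)$t_k
      }, numeric(1))
    })
    prev_times <- times_all[sel]
    rt <- round_time(prev_times)
    cumulative <- cumulative + rt

    exceeded <- cumulative > config$budget
    glob_val <- validate_all(global)
    gdsc <- weighted_dsc(glob_val[1, ])
    if (!exceeded) {
      curve_t <- c(curve_t, cumulative)
      curve_d <- c(curve_d, gdsc)
      if (gdsc > best_dsc) {
        best_dsc <- gdsc
        best_params <- global
        best_round <- t
      }
    }
    mean_w <- rowMeans(weights$w)
    rows[[t + 1L]] <- tibble::tibble(
      round = t, n_selected = length(sel),
      selected = list(as.character(sel)),
      lr = lr_t, epochs = ep_t,
      weights = list(stats::setNames(mean_w, sel)),
      mean_post_dsc = mean(post_dsc), mean_post_loss = mean(post_loss),
      round_time = rt, cumulative_time = cumulative,
      val_dsc = gdsc, credited = !exceeded
    )
    prev_params <- params_list
    if (verbose) {
      message(sprintf("round %d: %d clients, val DSC %.3f, t=%.0fs%s",
                      t, length(sel), gdsc, cumulative,
                      if (exceeded) " (budget exceeded)" else ""))
    }
    if (exceeded) break
  }

  curve <- convergence_curve(curve_t, curve_d, budget = config$budget)
  structure(
    list(rounds = purrr::list_rbind(rows), curve = curve,
         final_params = best_params, final_round = best_round,
         final_val_dsc = best_dsc,
         selections = selections, timing = timing, config = config),
    class = "fl_run"
  )
}

#' @export
print.fl_run <- function(x, ...) {
  cat("<fl_run> ", nrow(x$rounds), " rounds, aggregator '",
      x$config$aggregator$name, "', policy '", x$config$policy$kind, "'\n",
      "  best val DSC ", round(x$final_val_dsc, 4), " (round ",
      x$final_round, "), convergence score ",
      round(convergence_score(x$curve), 4), "\n", sep = "")
  invisible(x)
}

#' @rdname run_federation
#' @param x An `fl_run`.
#' @param ... Unused.
#' @export
tidy.fl_run <- function(x, ...) {
  dplyr::select(x$rounds, "round", "n_selected", "lr", "epochs",
                "mean_post_dsc", "mean_post_loss", "round_time",
                "cumulative_time", "val_dsc", "credited")
}

#' @rdname run_federation
#' @export
glance.fl_run <- function(x, ...) {
  tibble::tibble(
    aggregator = x$config$aggregator$name,
    policy = x$config$policy$kind,
    rounds_completed = sum(x$rounds$credited),
    total_time = max(x$rounds$cumulative_time),
    final_round = x$final_round,
    final_val_dsc = x$final_val_dsc,
    convergence_score = convergence_score(x$curve)
  )
}

#' @rdname run_federation
#' @param object An `fl_run`.
#' @export
autoplot.fl_run <- function(object, ...) {
  ggplot2::autoplot(object$curve) +
    ggplot2::labs(subtitle = paste0("aggregator: ",
                                    object$config$aggregator$name,
                                    ", policy: ", object$config$policy$kind))
}

#' Compare aggregation/selection algorithms under shared conditions
#'
#' Runs several experiment configs that share the same federation, timing
#' profile, budget and master seed, and tabulates their convergence scores and
#' final validation DSCs. Configs must differ only in aggregator, selection
#' policy or schedules; a mismatched federation is an error.
#'
#' @param configs Named list of [experiment_config()]s.
#' @param verbose Passed to [run_federation()].
#' @return List with `table` (one glance row per config) and `runs`.
#' @export
compare_aggregators <- function(configs, verbose = FALSE) {
  stopifnot(length(configs) >= 1)
  if (is.null(names(configs))) {
    names(configs) <- vapply(configs, function(cf) cf$aggregator$name,
                             character(1))
  }
  fed0 <- configs[[1]]$federation
  for (cf in configs) {
    if (!identical(cf$federation, fed0)) {
      stop("compare_aggregators requires a shared federation")
    }
    if (!identical(cf$seed, configs[[1]]$seed) ||
        !identical(cf$budget, configs[[1]]$budget)) {
      stop("compare_aggregators requires shared seed and budget")
    }
  }
  runs <- lapply(configs, run_federation, verbose = verbose)
  table <- purrr::list_rbind(lapply(names(runs), function(nm) {
    dplyr::bind_cols(tibble::tibble(name = nm), glance(runs[[nm]]))
  }))
  list(table = table, runs = runs)
}

#' Write a run's logs to disk
#'
#' Writes `run_log.csv` (one row per round and selected client),
#' `convergence.csv` (the curve points) and `result.json` (summary and
#' conventions). Byte-identical for identical configs and seeds.
#'
#' @param run An `fl_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_log <- function(run, dir) {
  stopifnot(inherits(run, "fl_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_rows <- purrr::list_rbind(lapply(seq_len(nrow(run$rounds)), function(i) {
    r <- run$rounds[i, ]
    tibble::tibble(round = r$round, site_id = r$selected[[1]],
                   weight = unname(r$weights[[1]]),
                   round_time = r$round_time,
                   cumulative_time = r$cumulative_time,
                   val_dsc = r$val_dsc, credited = r$credited)
  }))
  utils::write.csv(log_rows, file.path(dir, "run_log.csv"), row.names = FALSE)
  utils::write.csv(run$curve$points, file.path(dir, "convergence.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(aggregator = run$config$aggregator$name,
         policy = run$config$policy$kind,
         budget = run$config$budget,
         seed = run$config$seed,
         rounds_completed = sum(run$rounds$credited),
         final_round = run$final_round,
         final_val_dsc = run$final_val_dsc,
         convergence_score = convergence_score(run$curve),
         conventions = list(dsc_both_empty = 1, dsc_one_empty = 0,
                            hd95_penalty = 373.13,
                            curve_interpolation = "step")),
    file.path(dir, "result.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
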