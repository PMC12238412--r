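test_that("dataset-size weighting normalizes client sizes", {
  expect_equal(unname(term_fedavg(c(a = 10, b = 30))$w[, 1]), c(0.25, 0.75))
  expect_equal(unname(term_fedavg(c(solo = 7))$w[, 1]), 1)
  expect_equal(unname(term_fedavg(c(a = 5, b = 5, c = 5, d = 5))$w[, 1]),
               rep(0.25, 4))
  expect_error(term_fedavg(c(a = 0, b = 0)), "zero")
})

test_that("validation-loss weighting favors high-loss clients", {
  expect_equal(unname(term_val_loss(c(a = 1, b = 3))$w[, 1]), c(0.25, 0.75))
  expect_equal(unname(term_val_loss(c(a = 2, b = 2))$w[, 1]), c(0.5, 0.5))
  w <- term_val_loss(c(a = 1, b = 1, c = 0))
  expect_equal(unname(w$w["c", 1]), 0)
  u <- term_val_loss(c(a = 0, b = 0))
  expect_equal(unname(u$w[, 1]), c(0.5, 0.5))
  expect_match(u$flag, "uniform")
  expect_error(term_val_loss(c(a = -1, b = 1)), "nonnegative")
})

test_that("improvement-ratio weighting matches hand-computed ratios", {
  w <- term_cost_ratio(c(a = 1.2, b = 0.8), c(a = 1, b = 1))
  expect_equal(unname(w$w[, 1]), c(0.6, 0.4))
  w2 <- term_cost_ratio(c(a = 0.5, b = 0.5), c(a = 0.5, b = 0.5))
  expect_equal(unname(w2$w[, 1]), c(0.5, 0.5))
  # no-improvement client (ratio 1) vs doubling client (ratio 2)
  w3 <- term_cost_ratio(c(a = 0.4, b = 0.8), c(a = 0.4, b = 0.4))
  expect_equal(unname(w3$w[, 1]), c(1 / 3, 2 / 3))
  w4 <- term_cost_ratio(c(a = 0.4, b = 0.4), c(a = 0, b = 0.4))
  expect_match(w4$flag, "clamp")
})

test_that("inverse parameter-distance weighting works at all granularities", {
  # two clients symmetric about the mean get equal weights
  p <- list(a = toy_params(0), b = toy_params(2))
  expect_equal(unname(term_inv_param_distance(p)$w[, 1]), c(0.5, 0.5))
  # asymmetric values, equal distances (0.9, 3 -> mean 1.95)
  p2 <- list(a = toy_params(0.9), b = toy_params(3))
  expect_equal(unname(term_inv_param_distance(p2)$w[, 1]), c(0.5, 0.5))
  # distances (1, 1, 2) -> inverse (1, 1, 0.5) -> (0.4, 0.4, 0.2)
  p3 <- list(a = toy_params(0), b = toy_params(0), c = toy_params(3))
  expect_equal(unname(term_inv_param_distance(p3)$w[, 1]), c(0.4, 0.4, 0.2))
  expect_error(term_inv_param_distance(p3[1]), ">= 2")

  layout <- list(t1 = 2L, t2 = 1L)
  q <- list(a = toy_params(c(0, 0, 1), layout),
            b = toy_params(c(2, 2, 1), layout))
  wt <- term_inv_param_distance(q, "tensor")
  expect_equal(dim(wt$w), c(2L, 2L))
  expect_equal(unname(wt$w[, "t1"]), c(0.5, 0.5))
  # zero-distance tensor: clamped, equal after normalization, flagged
  expect_equal(unname(wt$w[, "t2"]), c(0.5, 0.5))
  expect_match(wt$flag, "zero distance")

  ws <- term_inv_param_distance(q, "scalar")
  expect_equal(dim(ws$w), c(2L, 3L))
  expect_true(all(abs(colSums(ws$w) - 1) < 1e-12))
})

test_that("PID terms: proportional, derivative and integral behavior", {
  hist2 <- rbind(c(a = 0.5, b = 0.5), c(a = 0.3, b = 0.5))
  sizes <- c(a = 10, b = 10)
  pid <- term_pid(hist2, sizes)
  expect_equal(unname(pid$p_P$w[, 1]), c(0.5, 0.5))
  # reductions (0.2, 0) -> derivative weights (1, 0)
  expect_equal(unname(pid$p_D$w[, 1]), c(1, 0))
  # integral over the single past round: proportional to (0.5, 0.5)
  expect_equal(unname(pid$p_I$w[, 1]), c(0.5, 0.5))

  # worsening clients are floored at zero, not negative
  hist3 <- rbind(c(a = 0.3, b = 0.5), c(a = 0.5, b = 0.2))
  pid3 <- term_pid(hist3, sizes)
  expect_equal(unname(pid3$p_D$w[, 1]), c(0, 1))

  # round 0: uniform fallback, flagged
  pid0 <- term_pid(matrix(c(a = 1, b = 2), nrow = 1,
                          dimnames = list(NULL, c("a", "b"))), sizes)
  expect_equal(unname(pid0$p_D$w[, 1]), c(0.5, 0.5))
  expect_match(pid0$p_D$flag, "round 0")

  # window = 1 reduces the integral term to the previous round's loss term
  hist6 <- rbind(c(a = 1, b = 1), c(a = 2, b = 6), c(a = 1, b = 1))
  colnames(hist6) <- c("a", "b")
  pidw <- term_pid(hist6, sizes, window = 1)
  expect_equal(unname(pidw$p_I$w[, 1]),
               unname(term_val_loss(c(a = 2, b = 6))$w[, 1]))

  # identical loss histories give a uniform integral term
  hist_eq <- rbind(c(a = 1, b = 1), c(a = 0.8, b = 0.8), c(a = 0.7, b = 0.7))
  colnames(hist_eq) <- c("a", "b")
  expect_equal(unname(term_pid(hist_eq, sizes)$p_I$w[, 1]), c(0.5, 0.5))
})

test_that("inverse training-DSC penalizes well-fitted clients", {
  w <- term_inv_train_dsc(c(a = 0.5, b = 1.0))
  expect_equal(unname(w$w[, 1]), c(2 / 3, 1 / 3))
  expect_equal(unname(term_inv_train_dsc(c(a = 0.7, b = 0.7))$w[, 1]),
               c(0.5, 0.5))
  w_lo <- term_inv_train_dsc(c(a = 0.4, b = 0.8))
  w_hi <- term_inv_train_dsc(c(a = 0.6, b = 0.8))
  expect_gt(w_lo$w["a", 1], w_hi$w["a", 1])
})

test_that("term combination follows the additive/multiplicative rules", {
  t1 <- fl_weights("x", c("a", "b"), c(0.5, 0.5))
  t2 <- fl_weights("y", c("a", "b"), c(0.8, 0.2))
  expect_equal(unname(combine_terms(list(t1), combination_spec("additive"))$w[, 1]),
               c(0.5, 0.5))
  expect_equal(unname(combine_terms(list(t2),
                                    combination_spec("multiplicative"))$w[, 1]),
               c(0.8, 0.2))
  # products (0.4, 0.1) renormalize to (0.8, 0.2)
  mult <- combine_terms(list(t1, t2), combination_spec("multiplicative"))
  expect_equal(unname(mult$w[, 1]), c(0.8, 0.2))
  add <- combine_terms(list(t1, t2), combination_spec("additive", c(0.5, 0.5)))
  expect_equal(unname(add$w[, 1]), c(0.65, 0.35))

  # multiplying by a uniform term is a no-op (neutral element)
  uni <- fl_weights("u", c("a", "b"), c(1, 1))
  mult2 <- combine_terms(list(t2, uni), combination_spec("multiplicative"))
  expect_equal(mult2$w, t2$w, ignore_attr = TRUE)

  z1 <- fl_weights("z1", c("a", "b"), c(1, 0))
  z2 <- fl_weights("z2", c("a", "b"), c(0, 1))
  expect_error(combine_terms(list(z1, z2), combination_spec("multiplicative")),
               "zero")
})

test_that("all terms emit nonnegative weights summing to 1 per unit", {
  layout <- list(t1 = 3L, t2 = 2L)
  params <- list(a = toy_params(c(1, 2, 3, 4, 5), layout),
                 b = toy_params(c(0, 1, 0, 1, 0), layout),
                 c = toy_params(c(2, 2, 2, 2, 2), layout))
  hist <- rbind(c(a = 1, b = 2, c = 3), c(a = 0.5, b = 2, c = 2.5))
  sizes <- c(a = 5, b = 10, c = 1)
  terms <- c(list(
    term_fedavg(sizes),
    term_val_loss(hist[2, ]),
    term_cost_ratio(c(a = 0.4, b = 0.5, c = 0.6), c(a = 0.3, b = 0.5, c = 0.2)),
    term_inv_param_distance(params, "model"),
    term_inv_param_distance(params, "tensor"),
    term_inv_param_distance(params, "scalar"),
    term_inv_train_dsc(c(a = 0.5, b = 0.9, c = 0.7))
  ), term_pid(hist, sizes))
  for (tm in terms) {
    expect_true(all(tm$w >= 0), info = tm$term_id)
    expect_true(all(abs(colSums(tm$w) - 1) < 1e-12), info = tm$term_id)
  }
  for (mode in c("additive", "multiplicative")) {
    comb <- combine_terms(list(term_fedavg(sizes), term_val_loss(hist[2, ])),
                          combination_spec(mode))
    expect_true(all(comb$w >= 0))
    expect_true(all(abs(colSums(comb$w) - 1) < 1e-12))
  }
})

test_that("aggregation is a convex combination with exact one-hot recovery", {
  params <- list(a = toy_params(c(1, 2, 3)), b = toy_params(c(4, 5, 6)))
  onehot <- fl_weights("w", c("a", "b"), c(0, 1))
  expect_identical(aggregate_params(params, onehot)$values, params$b$values)

  half <- fl_weights("w", c("a", "b"), c(0.5, 0.5))
  expect_equal(aggregate_params(params, half)$values, c(2.5, 3.5, 4.5))

  withr::with_seed(13, {
    for (i in 1:10) {
      w <- runif(2)
      wts <- fl_weights("w", c("a", "b"), w)
      agg <- aggregate_params(params, wts)$values
      lo <- pmin(params$a$values, params$b$values)
      hi <- pmax(params$a$values, params$b$values)
      expect_true(all(agg >= lo - 1e-12 & agg <= hi + 1e-12))
    }
  })
})

test_that("FedAvg aggregation equals the brute-force weighted mean", {
  withr::with_seed(29, {
    params <- list(a = toy_params(rnorm(7)), b = toy_params(rnorm(7)),
                   c = toy_params(rnorm(7)))
  })
  sizes <- c(a = 3, b = 9, c = 6)
  agg <- aggregate_params(params, term_fedavg(sizes))
  manual <- (3 * params$a$values + 9 * params$b$values + 6 * params$c$values) / 18
  expect_equal(agg$values, manual, tolerance = 1e-14)
})

test_that("client relabeling permutes weights, not the aggregate", {
  withr::with_seed(31, {
    vals <- replicate(3, rnorm(5), simplify = FALSE)
  })
  params <- list(a = toy_params(vals[[1]]), b = toy_params(vals[[2]]),
                 c = toy_params(vals[[3]]))
  sizes <- c(a = 1, b = 2, c = 3)
  agg1 <- aggregate_params(params, term_fedavg(sizes))
  perm <- c("c", "a", "b")
  agg2 <- aggregate_params(params[perm], term_fedavg(sizes[perm]))
  expect_equal(agg1$values, agg2$values, tolerance = 1e-14)
})

test_that("tensor and scalar granularity weights broadcast over the layout", {
  layout <- list(t1 = 2L, t2 = 2L)
  params <- list(a = toy_params(c(1, 1, 1, 1), layout),
                 b = toy_params(c(3, 3, 3, 3), layout))
  wt <- fl_weights("w", c("a", "b"), matrix(c(1, 0, 0, 1), 2), "tensor",
                   units = c("t1", "t2"))
  agg <- aggregate_params(params, wt)
  expect_equal(agg$values, c(1, 1, 3, 3))

  ws <- fl_weights("w", c("a", "b"),
                   matrix(c(1, 0, 0, 1, 0.5, 0.5, 0, 1), 2), "scalar")
  aggs <- aggregate_params(params, ws)
  expect_equal(aggs$values, c(1, 3, 2, 3))
})

test_that("server optimizer: none, sgd recovery, and the sgd update formula", {
  prev <- toy_params(c(0, 0))
  agg <- toy_params(c(2, 2))
  no <- server_update(prev, agg, server_optimizer("none"))
  expect_identical(no$params$values, agg$values)

  sgd1 <- server_update(prev, agg, server_optimizer("sgd", lr = 1))
  expect_equal(sgd1$params$values, agg$values, tolerance = 1e-14)

  # lr 0.5, prev 0, aggregated 2: delta = -2, new = 0 - 0.5 * (-2) = 1
  sgd05 <- server_update(prev, agg, server_optimizer("sgd", lr = 0.5))
  expect_equal(sgd05$params$values, c(1, 1), tolerance = 1e-14)

  st <- server_optimizer("adam", lr = 0.1)
  up1 <- server_update(prev, agg, st)
  expect_equal(up1$state$t, 1L)
  # Adam's bias-corrected first step has magnitude ~ lr in the delta direction
  expect_true(all(abs(up1$params$values - 0.1) < 1e-6))
  up2 <- server_update(up1$params, agg, up1$state)
  expect_equal(up2$state$t, 2L)
})

test_that("parameter-change regularization rescales and renormalizes", {
  w <- fl_weights("w", c("a", "b"), c(0.5, 0.5))
  expect_equal(regularize_by_param_change(w, c(a = 1, b = 3), 0)$w, w$w)
  eq <- regularize_by_param_change(w, c(a = 2, b = 2), -1)
  expect_equal(unname(eq$w[, 1]), c(0.5, 0.5))
  up <- regularize_by_param_change(w, c(a = 1, b = 3), 1)
  expect_equal(unname(up$w[, 1]), c(0.25, 0.75))
  down <- regularize_by_param_change(w, c(a = 1, b = 3), -1)
  expect_equal(unname(down$w[, 1]), c(0.75, 0.25))
  r0 <- regularize_by_param_change(w, NULL, -1)
  expect_equal(r0$w, w$w)
  expect_match(r0$flag, "round 0")
})
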