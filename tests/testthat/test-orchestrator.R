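test_that("schedules evaluate to their closed forms", {
  expect_equal(schedule_value(fl_schedule("constant", 0.1), 0), 0.1)
  expect_equal(schedule_value(fl_schedule("constant", 0.1), 17), 0.1)
  # step: 0.1 * 0.5^2 at t = 4 with halving every 2 rounds
  expect_equal(schedule_value(fl_schedule("step", 0.1, gamma = 0.5, every = 2),
                              4), 0.025, tolerance = 1e-12)
  expect_equal(schedule_value(fl_schedule("polynomial", 0.1, power = 1,
                                          total_rounds = 10), 5),
               0.05, tolerance = 1e-12)
  # past the polynomial horizon the value clamps at zero
  expect_equal(schedule_value(fl_schedule("polynomial", 0.1, power = 2,
                                          total_rounds = 10), 15), 0)
})

test_that("a budget smaller than round 0 leaves the initial model final", {
  fed <- tiny_federation(2, 5, seed = 81)
  cfg <- experiment_config(fed, timing = flat_timing(fed),
                           budget = 1, max_rounds = 3, seed = 7)
  run <- run_federation(cfg)
  expect_equal(nrow(run$rounds), 1)
  expect_false(run$rounds$credited[1])
  expect_equal(run$final_round, -1L)
  init <- build_model(model_config(seed = derive_seed(7, "init")))
  expect_identical(run$final_params$values, init$values)
  expect_equal(nrow(run$curve$points), 1) # only the t = 0 point
})

test_that("with sigma = 0 the clock equals the analytic sum of round maxima", {
  fed <- tiny_federation(3, 5, seed = 82)
  timing <- flat_timing(fed, mu_train = 10, mu_val = 1, mu_comm = 5)
  cfg <- experiment_config(fed, timing = timing, max_rounds = 4, seed = 9)
  run <- run_federation(cfg)
  sizes <- client_sizes(fed)
  t_k <- vapply(fed$clients, function(cl) {
    5 + 5 + 1 * cl$n_val + 10 * cl$n_train
  }, numeric(1))
  per_round <- max(t_k)
  expect_equal(run$rounds$cumulative_time,
               per_round * seq_len(nrow(run$rounds)), tolerance = 1e-12)
})

test_that("runs replay byte-identically and share the timing stream", {
  fed <- tiny_federation(2, 5, seed = 83)
  base <- function(agg) {
    experiment_config(fed, aggregator = agg, max_rounds = 3, seed = 21)
  }
  r1 <- run_federation(base(aggregator_fedavg()))
  r2 <- run_federation(base(aggregator_fedavg()))
  expect_identical(r1$rounds, r2$rounds)
  expect_identical(r1$final_params$values, r2$final_params$values)

  # changing only the aggregator must not perturb the timing stream
  r3 <- run_federation(base(aggregator_flstar()))
  expect_identical(r1$rounds$round_time, r3$rounds$round_time)
  expect_false(identical(r1$final_params$values, r3$final_params$values))
})

test_that("symmetric federations make FedAvg equal either local update", {
  # two clients with identical cases and splits; full-batch training removes
  # any order dependence, so their updates coincide and so does the average
  cd <- generate_site(site_spec("A", 4, seed = 91))
  twin_a <- fedsim:::new_client_dataset("A", cd$cases,
                                        list(train = 1:3, val = 4L))
  twin_b <- fedsim:::new_client_dataset("B", cd$cases,
                                        list(train = 1:3, val = 4L))
  m <- build_model(model_config(seed = 5))
  cfg <- local_train_config(0.3, 2, batch_size = 10, seed = 3)
  fa <- local_train(m, twin_a, cfg, round = 0)
  fb <- local_train(m, twin_b, cfg, round = 0)
  # batch orders differ per site id, so gradient sums differ only by
  # floating-point association
  expect_equal(fa$params$values, fb$params$values, tolerance = 1e-12)
  agg <- aggregate_params(list(A = fa$params, B = fb$params),
                          term_fedavg(c(A = 4, B = 4)))
  expect_equal(agg$values, fa$params$values, tolerance = 1e-12)
})

test_that("every catalogued aggregator completes a short run", {
  fed <- tiny_federation(3, 5, seed = 84)
  aggs <- list(aggregator_fedavg(), aggregator_flstar(), aggregator_costwavg(),
               aggregator_fedpidavg(), aggregator_sanctuary(),
               aggregator_httuas(), aggregator_rofl())
  for (agg in aggs) {
    run <- run_federation(experiment_config(
      fed, aggregator = agg, max_rounds = 2, seed = 31,
      base_train = local_train_config(0.3, 1, 2)))
    expect_equal(nrow(run$rounds), 2)
    expect_true(all(vapply(run$rounds$weights, function(w) {
      abs(sum(w) - 1) < 1e-6 || all(w >= 0) # scalar-granularity means vary
    }, logical(1))), info = agg$name)
    expect_true(all(is.finite(run$final_params$values)), info = agg$name)
    cs <- convergence_score(run$curve)
    expect_gte(cs, 0)
    expect_lte(cs, 1)
  }
})

test_that("selection policies integrate with the round loop", {
  fed <- tiny_federation(4, 5, seed = 85)
  run <- run_federation(experiment_config(
    fed, policy = selection_policy("cycle_without_replacement", k = 2,
                                   seed = 3),
    max_rounds = 4, seed = 33, base_train = local_train_config(0.3, 1, 2)))
  expect_true(all(run$rounds$n_selected == 2))
  cov <- coverage_report(run$selections, names(client_sizes(fed)))
  expect_lte(diff(range(cov$n_rounds)), 1)
})

test_that("comparison tables share conditions and report scores", {
  fed <- tiny_federation(2, 5, seed = 86)
  mk <- function(pol) {
    experiment_config(fed, policy = pol, max_rounds = 2, seed = 41,
                      base_train = local_train_config(0.3, 1, 2))
  }
  cmp <- compare_aggregators(list(all = mk(selection_policy("all")),
                                  k1 = mk(selection_policy("k_largest", k = 1))))
  expect_equal(nrow(cmp$table), 2)
  expect_true(all(cmp$table$convergence_score >= 0 &
                    cmp$table$convergence_score <= 1))
  expect_identical(cmp$runs$all$rounds$round_time,
                   cmp$runs$k1$rounds$round_time)

  other <- tiny_federation(2, 5, seed = 87)
  bad <- experiment_config(other, max_rounds = 2, seed = 41)
  expect_error(compare_aggregators(list(a = mk(selection_policy("all")),
                                        b = bad)), "shared federation")
})

test_that("tidy, glance and run logs expose the round records", {
  fed <- tiny_federation(2, 5, seed = 88)
  run <- run_federation(experiment_config(
    fed, max_rounds = 2, seed = 51, base_train = local_train_config(0.3, 1, 2)))
  td <- tidy(run)
  expect_equal(nrow(td), 2)
  expect_true(all(c("round", "val_dsc", "cumulative_time") %in% names(td)))
  gl <- glance(run)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$rounds_completed, 2)

  dir <- withr::local_tempdir()
  write_run_log(run, dir)
  expect_true(file.exists(file.path(dir, "run_log.csv")))
  log <- utils::read.csv(file.path(dir, "run_log.csv"))
  expect_equal(sort(unique(log$round)), c(0, 1))
  res <- jsonlite::read_json(file.path(dir, "result.json"))
  expect_equal(res$conventions$hd95_penalty, 373.13)

  p <- autoplot(run)
  expect_s3_class(p, "ggplot")
})
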