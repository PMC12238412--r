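make_table <- function(df) {
  tibble::as_tibble(df)
}

# long metric table from per-algorithm named value lists
long_table <- function(values, cases, institutions = NULL) {
  rows <- list()
  for (alg in names(values)) {
    i <- 0
    for (cs in cases) {
      i <- i + 1
      for (reg in c("WT", "TC", "ET")) {
        for (met in c("DSC", "HD95")) {
          v <- values[[alg]][[cs]][[paste(reg, met)]]
          rows[[length(rows) + 1]] <- data.frame(
            algorithm = alg, case = cs,
            institution = if (is.null(institutions)) NA else institutions[i],
            region = reg, metric = met, value = v)
        }
      }
    }
  }
  tibble::as_tibble(do.call(rbind, rows))
}

test_that("within-group ranks: direction, min-rank ties, non-finite last", {
  expect_equal(within_group_rank(c(0.9, 0.7, 0.9), "max"), c(1L, 3L, 1L))
  expect_equal(within_group_rank(c(2.0, 5.0), "min"), c(1L, 2L))
  expect_equal(within_group_rank(0.5, "max"), 1L)
  expect_equal(within_group_rank(c(0.8, NA, Inf, 0.6), "max"),
               c(1L, 3L, 3L, 2L))
  expect_equal(within_group_rank(c(3, Inf, 1), "min"), c(2L, 3L, 1L))
})

test_that("task-1 ranking: dominance, total ties, convergence factor 3", {
  vals <- list(
    A = list(c1 = list(`WT DSC` = 0.9, `WT HD95` = 1, `TC DSC` = 0.9,
                       `TC HD95` = 1, `ET DSC` = 0.9, `ET HD95` = 1)),
    B = list(c1 = list(`WT DSC` = 0.5, `WT HD95` = 5, `TC DSC` = 0.5,
                       `TC HD95` = 5, `ET DSC` = 0.5, `ET HD95` = 5))
  )
  tab <- long_table(vals, "c1")
  conv <- tibble::tibble(algorithm = c("A", "B"), score = c(0.8, 0.2))
  rk <- rank_task1(tab, conv)
  expect_equal(rk$ranking_score[rk$algorithm == "A"], 1.0)
  expect_equal(rk$ranking_score[rk$algorithm == "B"], 2.0)
  expect_equal(rk$final_rank, c(1L, 2L))

  # identical metrics and convergence: everyone shares rank 1
  vals$B <- vals$A
  tie <- rank_task1(long_table(vals, "c1"),
                    tibble::tibble(algorithm = c("A", "B"), score = c(1, 1)))
  expect_true(all(tie$final_rank == 1L))
  expect_equal(tie$ranking_score[1], tie$ranking_score[2])

  expect_error(rank_task1(tab, tibble::tibble(algorithm = "A", score = 1)),
               "convergence")
})

test_that("task-1 ranking equals the exhaustive enumeration oracle", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      algos <- c("A", "B", "C")
      cases <- c("c1", "c2")
      vals <- lapply(setNames(algos, algos), function(a) {
        lapply(setNames(cases, cases), function(cs) {
          out <- list()
          for (reg in c("WT", "TC", "ET")) {
            out[[paste(reg, "DSC")]] <- round(runif(1), 2)
            out[[paste(reg, "HD95")]] <- round(runif(1, 0, 10), 1)
          }
          out
        })
      })
      tab <- long_table(vals, cases)
      conv <- tibble::tibble(algorithm = algos, score = round(runif(3), 2))
      got <- rank_task1(tab, conv)
      want <- oracle_rank_task1(tab, conv)
      got <- got[match(want$algorithm, got$algorithm), ]
      expect_equal(got$ranking_score, want$ranking_score, tolerance = 1e-12)
      expect_equal(got$final_rank, want$final_rank)
    }
  })
})

test_that("one-institution task-2 ranking reduces to the case-based scheme", {
  withr::with_seed(23, {
    algos <- c("A", "B", "C")
    cases <- c("c1", "c2", "c3")
    vals <- lapply(setNames(algos, algos), function(a) {
      lapply(setNames(cases, cases), function(cs) {
        out <- list()
        for (reg in c("WT", "TC", "ET")) {
          out[[paste(reg, "DSC")]] <- runif(1)
          out[[paste(reg, "HD95")]] <- runif(1, 0, 10)
        }
        out
      })
    })
  })
  tab <- long_table(vals, cases, institutions = rep("I1", 3))
  rk2 <- rank_task2(tab)
  # task 1 with all convergence scores tied contributes a constant rank of 1
  conv <- tibble::tibble(algorithm = algos, score = c(1, 1, 1))
  rk1 <- rank_task1(tab, conv)
  # remove the tied convergence contribution: score1 = (6n*s2 + 3n*1) / 9n
  n <- length(cases)
  adj <- (rk1$ranking_score * 9 * n - 3 * n) / (6 * n)
  expect_equal(sort(adj), sort(rk2$ranking_score), tolerance = 1e-12)
})

test_that("task-2 ranking weights institutions equally regardless of size", {
  # algorithm A is best on the 2-case site and worst on the 100-case site;
  # B is the mirror image: equal institution weighting makes them tie
  big_cases <- paste0("b", 1:100)
  small_cases <- paste0("s", 1:2)
  mk_vals <- function(best_big) {
    all_cases <- c(big_cases, small_cases)
    lapply(setNames(all_cases, all_cases), function(cs) {
      big <- startsWith(cs, "b")
      good <- if (big) best_big else !best_big
      out <- list()
      for (reg in c("WT", "TC", "ET")) {
        out[[paste(reg, "DSC")]] <- if (good) 0.9 else 0.5
        out[[paste(reg, "HD95")]] <- if (good) 1 else 5
      }
      out
    })
  }
  vals <- list(A = mk_vals(FALSE), B = mk_vals(TRUE))
  insts <- c(rep("big", 100), rep("small", 2))
  tab <- long_table(vals, c(big_cases, small_cases), institutions = insts)
  rk <- rank_task2(tab)
  expect_equal(rk$ranking_score[1], rk$ranking_score[2])
  expect_true(all(rk$final_rank == 1L))

  # permuting case order changes nothing
  tab_perm <- tab[sample(nrow(tab)), ]
  rk_perm <- rank_task2(tab_perm)
  expect_equal(rk_perm$ranking_score[order(rk_perm$algorithm)],
               rk$ranking_score[order(rk$algorithm)])
})

test_that("task-2 ranking is invariant to duplicating an institution's cases", {
  withr::with_seed(29, {
    algos <- c("A", "B")
    cases <- c("c1", "c2")
    vals <- lapply(setNames(algos, algos), function(a) {
      lapply(setNames(cases, cases), function(cs) {
        out <- list()
        for (reg in c("WT", "TC", "ET")) {
          out[[paste(reg, "DSC")]] <- runif(1)
          out[[paste(reg, "HD95")]] <- runif(1, 0, 10)
        }
        out
      })
    })
  })
  tab <- long_table(vals, cases, institutions = c("I1", "I1"))
  dup <- tab
  dup$case <- paste0(dup$case, "_copy")
  rk <- rank_task2(tab)
  rk_dup <- rank_task2(dplyr::bind_rows(tab, dup))
  expect_equal(rk$ranking_score, rk_dup$ranking_score, tolerance = 1e-12)
})

test_that("institutions with unevaluable algorithms are excluded, flagged", {
  vals <- list(
    A = list(c1 = list(`WT DSC` = 0.9, `WT HD95` = 1, `TC DSC` = 0.8,
                       `TC HD95` = 2, `ET DSC` = 0.7, `ET HD95` = 3),
             c2 = list(`WT DSC` = 0.6, `WT HD95` = 4, `TC DSC` = 0.5,
                       `TC HD95` = 5, `ET DSC` = 0.4, `ET HD95` = 6)),
    B = list(c1 = list(`WT DSC` = 0.8, `WT HD95` = 2, `TC DSC` = 0.7,
                       `TC HD95` = 3, `ET DSC` = 0.6, `ET HD95` = 4),
             c2 = list(`WT DSC` = NA, `WT HD95` = NA, `TC DSC` = NA,
                       `TC HD95` = NA, `ET DSC` = NA, `ET HD95` = NA))
  )
  tab <- long_table(vals, c("c1", "c2"), institutions = c("I1", "I2"))
  rk <- rank_task2(tab)
  expect_equal(attr(rk, "excluded"), "I2")
  # only I1 counts: A beats B there on every entry
  expect_equal(rk$final_rank[rk$algorithm == "A"], 1L)
})

test_that("adding a dominated algorithm never hurts the incumbents", {
  withr::with_seed(37, {
    algos <- c("A", "B")
    cases <- c("c1", "c2", "c3")
    vals <- lapply(setNames(algos, algos), function(a) {
      lapply(setNames(cases, cases), function(cs) {
        out <- list()
        for (reg in c("WT", "TC", "ET")) {
          out[[paste(reg, "DSC")]] <- runif(1, 0.3, 1)
          out[[paste(reg, "HD95")]] <- runif(1, 0, 10)
        }
        out
      })
    })
  })
  # strictly dominated: worst possible everywhere
  vals$Z <- lapply(vals$A, function(cs) {
    lapply(cs, function(v) if (grepl("HD95", "x")) 99 else 0)
  })
  for (cs in names(vals$Z)) {
    for (key in names(vals$Z[[cs]])) {
      vals$Z[[cs]][[key]] <- if (grepl("HD95", key)) 99 else 0
    }
  }
  conv <- tibble::tibble(algorithm = c("A", "B", "Z"), score = c(0.5, 0.4, 0))
  with_z <- rank_task1(long_table(vals, cases), conv)
  without_z <- rank_task1(long_table(vals[c("A", "B")], cases), conv[1:2, ])
  for (alg in c("A", "B")) {
    expect_lte(with_z$ranking_score[with_z$algorithm == alg],
               without_z$ranking_score[without_z$algorithm == alg] + 1e-12)
  }
})

test_that("qc screening flags the lowest-DSC fraction with ceil counting", {
  scores <- tibble::tibble(case = paste0("c", 1:10),
                           dsc = seq(0.95, 0.05, length.out = 10))
  out <- qc_screen(scores, q = 0.2)
  expect_equal(out$n_flagged, 2L)
  expect_setequal(out$flagged, c("c10", "c9"))
  expect_equal(qc_screen(scores, q = 1)$n_flagged, 10L)
  expect_error(qc_screen(scores, q = 0), "q must")
  expect_error(qc_screen(scores, q = 1.2), "q must")

  named <- setNames(scores$dsc, scores$case)
  expect_equal(qc_screen(named, 0.3)$n_flagged, 3L)

  out_t <- qc_screen(scores, 0.2, truth = c("c9", "c10", "c1"))
  expect_equal(out_t$capture_fraction, 2 / 3)
})
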