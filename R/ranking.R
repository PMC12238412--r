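#' Min-rank within a comparison group
#'
#' Rank 1 is best. For metrics where high is good (DSC, convergence score) use
#' `direction = "max"`; for distances (HD95) use `"min"`. Ties receive the
#' minimum rank of the tied block. Non-finite values are ranked last (the HD95
#' penalty sentinel and failed evaluations thereby sort to the bottom).
#'
#' @param values Numeric vector (one value per algorithm).
#' @param direction "max" or "min".
#' @return Integer ranks, same length as `values`.
#' @export
within_group_rank <- function(values, direction = c("max", "min")) {
  direction <- match.arg(direction)
  if (length(values) == 0) stop("cannot rank an empty group")
  key <- if (direction == "max") -as.numeric(values) else as.numeric(values)
  key[!is.finite(key)] <- Inf # non-finite is always worst
  as.integer(rank(key, ties.method = "min"))
}

metric_direction <- function(metric) {
  ifelse(toupper(metric) == "HD95", "min", "max")
}

check_metric_table <- function(table, need_institution = FALSE) {
  need <- c("algorithm", "case", "region", "metric", "value")
  if (need_institution) need <- c(need, "institution")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    stop("metric table lacks columns: ", paste(miss, collapse = ", "))
  }
  invisible(table)
}

#' Challenge ranking with a convergence component (Task 1 scheme)
#'
#' Algorithms are ranked per test case on each of 3 regions x 2 metrics (DSC
#' descending, HD95 ascending), and the convergence-score rank (descending) is
#' appended 3 times per case, reflecting the weight efficiency carries in
#' federated training: N cases x 3 x 3 ranks per algorithm. The ranking score
#' is the mean of these ranks (lower is better) and the final ranks are
#' min-rank ties on the score.
#'
#' @param table Long metric tibble with columns `algorithm`, `case`, `region`,
#'   `metric` ("DSC"/"HD95"), `value`.
#' @param convergence Tibble with columns `algorithm`, `score`, one row per
#'   algorithm.
#' @return A tibble (`algorithm`, `ranking_score`, `final_rank`), best first.
#' @export
rank_task1 <- function(table, convergence) {
  check_metric_table(table)
  algos <- sort(unique(table$algorithm))
  if (!all(algos %in% convergence$algorithm)) {
    stop("missing convergence score for: ",
         paste(setdiff(algos, convergence$algorithm), collapse = ", "))
  }
  case_ranks <- table |>
    dplyr::group_by(.data$case, .data$region, .data$metric) |>
    dplyr::mutate(rank = within_group_rank(
      .data$value, metric_direction(.data$metric[1]))) |>
    dplyr::ungroup()

  conv_rank <- tibble::tibble(
    algorithm = convergence$algorithm,
    conv_rank = within_group_rank(convergence$score, "max")
  )
  n_cases <- dplyr::n_distinct(table$case)

  scores <- case_ranks |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(sum_rank = sum(.data$rank), n_rank = dplyr::n(),
                     .groups = "drop") |>
    dplyr::left_join(conv_rank, by = "algorithm") |>
    dplyr::mutate(
      ranking_score = (.data$sum_rank + 3 * n_cases * .data$conv_rank) /
        (.data$n_rank + 3 * n_cases)
    )
  finalize_ranks(scores[, c("algorithm", "ranking_score")])
}

#' Per-institution rank-then-aggregate ranking (Task 2 scheme)
#'
#' Within each testing institution, algorithms are ranked per case, region and
#' metric; the case ranks are averaged to a per-institution rank for each
#' region-metric combination; and the final score is the mean of an
#' algorithm's K x 3 x 2 per-institution ranks — every institution weighs
#' equally regardless of its case count. Institutions where some algorithm has
#' no evaluable cases (missing or all-NA entries) are excluded entirely and
#' reported in the `excluded` attribute, mirroring how incomplete multi-site
#' evaluations are handled.
#'
#' @param table Long metric tibble with columns `algorithm`, `case`,
#'   `institution`, `region`, `metric`, `value`.
#' @return A tibble (`algorithm`, `ranking_score`, `final_rank`), best first,
#'   with attribute `excluded` listing dropped institutions.
#' @export
rank_task2 <- function(table) {
  check_metric_table(table, need_institution = TRUE)
  algos <- sort(unique(table$algorithm))

  evaluable <- table |>
    dplyr::group_by(.data$institution, .data$algorithm) |>
    dplyr::summarise(n_ok = sum(is.finite(.data$value)), .groups = "drop") |>
    tidyr::complete(institution = unique(table$institution),
                    algorithm = algos, fill = list(n_ok = 0L))
  excluded <- evaluable |>
    dplyr::group_by(.data$institution) |>
    dplyr::summarise(ok = all(.data$n_ok > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok) |>
    dplyr::pull(.data$institution)
  kept <- dplyr::filter(table, !(.data$institution %in% excluded))
  if (nrow(kept) == 0) stop("no institution with complete evaluations")

  inst_ranks <- kept |>
    dplyr::group_by(.data$institution, .data$case, .data$region,
                    .data$metric) |>
    dplyr::mutate(rank = within_group_rank(
      .data$value, metric_direction(.data$metric[1]))) |>
    dplyr::ungroup() |>
    dplyr::group_by(.data$algorithm, .data$institution, .data$region,
                    .data$metric) |>
    dplyr::summarise(inst_rank = mean(.data$rank), .groups = "drop")

  scores <- inst_ranks |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(ranking_score = mean(.data$inst_rank), .groups = "drop")
  out <- finalize_ranks(scores)
  attr(out, "excluded") <- as.character(excluded)
  out
}

finalize_ranks <- function(scores) {
  out <- scores |>
    dplyr::mutate(final_rank = within_group_rank(.data$ranking_score, "min")) |>
    dplyr::arrange(.data$final_rank, .data$algorithm)
  tibble::as_tibble(out)
}

#' Annotation quality-control screen by reference-model DSC
#'
#' Sorting test cases by their DSC between a strong reference model's
#' prediction and the provided annotation concentrates annotation errors at
#' the bottom of the list. The screen flags the lowest `q` fraction of cases
#' (`ceil(q * n)` cases) as candidate annotation errors. If a truth labeling
#' of which cases are actually corrupted is supplied, the captured fraction
#' (share of all true errors inside the flagged set) is reported.
#'
#' @param scores Tibble with columns `case` and `dsc` (one row per case), or a
#'   named numeric vector of per-case DSC.
#' @param q Flagged fraction, in (0, 1\].
#' @param truth Optional character vector of truly corrupted case ids.
#' @return List with `flagged` (case ids, lowest DSC first), `n_flagged`, and
#'   (when `truth` given) `capture_fraction`.
#' @export
qc_screen <- function(scores, q = 0.2, truth = NULL) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  if (!is.data.frame(scores)) {
    scores <- tibble::tibble(case = names(scores), dsc = as.numeric(scores))
  }
  stopifnot(all(c("case", "dsc") %in% names(scores)))
  n <- nrow(scores)
  n_flag <- as.integer(ceiling(q * n))
  ord <- order(scores$dsc, scores$case) # ascending DSC, stable by case id
  flagged <- scores$case[ord[seq_len(n_flag)]]
  out <- list(flagged = flagged, n_flagged = n_flag)
  if (!is.null(truth)) {
    out$capture_fraction <- if (length(truth) == 0) NA_real_ else {
      mean(truth %in% flagged)
    }
  }
  out
}
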