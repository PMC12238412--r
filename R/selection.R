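#' Client-selection policies
#'
#' Which collaborators train in a given round. Available kinds:
#' \describe{
#'   \item{all}{every client, every round (the baseline).}
#'   \item{k_largest}{the `k` clients with the largest case counts (ties by
#'     site id), every round — large sites are least prone to overfitting.}
#'   \item{random_groups}{clients are randomly partitioned into groups of `k`;
#'     rounds cycle through the groups, and every `regroup_every` rounds a new
#'     random partition is drawn.}
#'   \item{cycle_without_replacement}{`k` random clients per round, sampled
#'     without replacement; the pool restarts once every client has
#'     participated, guaranteeing all data are seen.}
#'   \item{alternate_drop_slow}{even rounds use full participation; odd rounds
#'     drop clients whose previous round time exceeded `slow_factor` times the
#'     mean previous round time — a compromise between speed and coverage.}
#'   \item{poisson_outlier_drop}{fits a Poisson law to the client sizes
#'     (lambda = mean size) and permanently drops size outliers above the
#'     `outlier_quantile` tail, removing the dominating slow clients.}
#' }
#'
#' @param kind Policy kind (see above).
#' @param k Group/sample size where applicable.
#' @param regroup_every Rounds between random regroupings (random_groups).
#' @param slow_factor Threshold factor on the mean previous round time,
#'   in (0, 1\] (alternate_drop_slow; default 0.75).
#' @param outlier_quantile Poisson upper-tail quantile (default 0.975).
#' @param seed Seed for the policy's own randomness.
#' @return An object of class `selection_policy`.
#' @export
selection_policy <- function(kind = c("all", "k_largest", "random_groups",
                                      "cycle_without_replacement",
                                      "alternate_drop_slow",
                                      "poisson_outlier_drop"),
                             k = NULL, regroup_every = 4L, slow_factor = 0.75,
                             outlier_quantile = 0.975, seed = 1L) {
  kind <- match.arg(kind)
  if (kind %in% c("k_largest", "random_groups", "cycle_without_replacement")) {
    if (is.null(k) || k < 1) stop("policy '", kind, "' requires k >= 1")
    k <- as.integer(k)
  }
  if (slow_factor <= 0 || slow_factor > 1) stop("slow_factor must be in (0, 1]")
  structure(list(kind = kind, k = k, regroup_every = as.integer(regroup_every),
                 slow_factor = slow_factor,
                 outlier_quantile = outlier_quantile, seed = as.integer(seed)),
            class = "selection_policy")
}

#' Select the collaborators for one round
#'
#' Deterministic given (policy, round, federation, previous timing): policies
#' with randomness derive their draws from the policy seed and the round
#' index, never from the global RNG. If a policy would select zero clients it
#' falls back to all clients, flagged in the result.
#'
#' @param policy A [selection_policy()].
#' @param round Round index, 0-based.
#' @param fed A `federation`.
#' @param prev_times Named per-client `T_k` of the previous round's selected
#'   clients (required by alternate_drop_slow after round 0), or `NULL`.
#' @return Character vector of selected site ids; attribute `reason` carries
#'   a short code, attribute `fallback` is TRUE when the empty-selection
#'   fallback fired.
#' @export
select_clients <- function(policy, round, fed, prev_times = NULL) {
  stopifnot(inherits(policy, "selection_policy"), inherits(fed, "federation"))
  sizes <- client_sizes(fed)
  ids <- names(sizes)
  K <- length(ids)

  sel <- switch(policy$kind,
    all = ids,
    k_largest = {
      ord <- order(-sizes, ids) # stable tie-break by site id
      ids[ord[seq_len(min(policy$k, K))]]
    },
    random_groups = {
      epoch <- round %/% policy$regroup_every
      groups <- with_stream(derive_seed(policy$seed, "regroup", epoch), {
        perm <- sample(ids)
        split(perm, ceiling(seq_along(perm) / policy$k))
      })
      groups[[(round %% policy$regroup_every) %% length(groups) + 1L]]
    },
    cycle_without_replacement = {
      per_cycle <- ceiling(K / policy$k)
      cycle <- round %/% per_cycle
      pos <- round %% per_cycle
      perm <- with_stream(derive_seed(policy$seed, "cycle", cycle), sample(ids))
      from <- pos * policy$k + 1L
      perm[from:min(from + policy$k - 1L, K)]
    },
    alternate_drop_slow = {
      if (round %% 2 == 0 || is.null(prev_times)) {
        ids
      } else {
        thresh <- policy$slow_factor * mean(prev_times)
        keep <- names(prev_times)[prev_times <= thresh]
        # clients absent from the previous round carry no time: keep them
        union(setdiff(ids, names(prev_times)), keep)
      }
    },
    poisson_outlier_drop = {
      lambda <- mean(sizes)
      cutoff <- stats::qpois(policy$outlier_quantile, lambda)
      ids[sizes <= cutoff]
    }
  )

  fallback <- FALSE
  if (length(sel) == 0) {
    sel <- ids
    fallback <- TRUE
  }
  sel <- ids[ids %in% sel] # canonical federation order
  structure(sel, reason = policy$kind, fallback = fallback)
}

#' Participation counts over a run
#'
#' Verifies coverage properties of selection policies (e.g., that cycling
#' policies see all available data).
#'
#' @param selections List of per-round character vectors of selected site ids.
#' @param all_ids Optional full roster; defaults to the union of selections.
#' @return A tibble with columns `site_id`, `n_rounds`, `fraction`.
#' @export
coverage_report <- function(selections, all_ids = NULL) {
  stopifnot(length(selections) >= 1)
  if (is.null(all_ids)) all_ids <- unique(unlist(selections))
  counts <- vapply(all_ids, function(id) {
    sum(vapply(selections, function(s) id %in% s, logical(1)))
  }, integer(1))
  tibble::tibble(site_id = unname(all_ids), n_rounds = unname(counts),
                 fraction = unname(counts) / length(selections))
}
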