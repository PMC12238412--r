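#' Assemble a multi-institution federation
#'
#' Builds a federation from per-site specifications. Per-site case counts can
#' be drawn from a size law instead of the spec values, emulating the heavy
#' size skew of real federations: "poisson" draws counts from Poisson(lambda)
#' (lambda defaulting to each spec's `n_cases`), "lognormal" from a log-normal
#' law centered on `log(n_cases)`, and "fixed" keeps the spec counts. Draws of
#' zero cases are redrawn (a federation never contains an empty client). Each
#' client receives a fixed 20% validation split (`n_val = max(1,
#' round(0.2 n))`) drawn once from the federation seed.
#'
#' @param specs List of at least two [site_spec()]s with unique `site_id`s.
#' @param size_law One of "fixed", "poisson", "lognormal".
#' @param rng_seed Integer federation seed (drives size draws and splits).
#' @param geometry Grid shape passed to [generate_site()].
#' @param lambda Optional Poisson mean(s), recycled over sites; defaults to
#'   each spec's `n_cases`.
#' @param sdlog Log-normal sd (default 0.5); the meanlog is `log(n_cases)`.
#' @return An object of class `federation`: list of `client_dataset`s plus
#'   `partitioning_id`.
#' @export
make_federation <- function(specs, size_law = c("fixed", "poisson", "lognormal"),
                            rng_seed = 1L, geometry = c(32, 32),
                            lambda = NULL, sdlog = 0.5) {
  size_law <- match.arg(size_law)
  if (length(specs) < 2) stop("a federation needs at least 2 site specs")
  ids <- vapply(specs, function(s) s$site_id, character(1))
  if (anyDuplicated(ids)) stop("site_ids must be unique")

  if (size_law != "fixed") {
    lam <- if (is.null(lambda)) {
      vapply(specs, function(s) s$n_cases, numeric(1))
    } else {
      rep_len(as.numeric(lambda), length(specs))
    }
    counts <- with_stream(derive_seed(rng_seed, "sizes"), {
      vapply(seq_along(specs), function(i) {
        repeat { # redraw zeros: never emit an empty client
          n <- switch(size_law,
            poisson = stats::rpois(1, lam[i]),
            lognormal = as.integer(round(stats::rlnorm(1, log(lam[i]), sdlog)))
          )
          if (n >= 1) return(as.integer(n))
        }
      }, integer(1))
    })
    specs <- purrr::map2(specs, counts, function(s, n) {
      s$n_cases <- n
      s
    })
  }

  clients <- lapply(specs, function(s) {
    cd <- generate_site(s, geometry)
    # the split is owned by the federation seed so that re-partitioning and
    # reruns under one master seed stay aligned
    split <- with_stream(derive_seed(rng_seed, "split", s$site_id),
                         validation_split(length(cd$cases)))
    new_client_dataset(cd$site_id, cd$cases, split)
  })
  new_federation(clients, "geographic")
}

new_federation <- function(clients, partitioning_id) {
  ids <- vapply(clients, function(cl) cl$site_id, character(1))
  if (anyDuplicated(ids)) stop("site_ids must be unique")
  structure(list(clients = clients, partitioning_id = partitioning_id),
            class = "federation")
}

#' @export
print.federation <- function(x, ...) {
  sizes <- client_sizes(x)
  cat("<federation> ", length(x$clients), " clients, ",
      sum(sizes), " cases (partitioning: ", x$partitioning_id, ")\n", sep = "")
  print(tibble::tibble(site_id = names(sizes), n_cases = unname(sizes)))
  invisible(x)
}

#' Per-client case counts of a federation
#'
#' @param fed A `federation`.
#' @return Named integer vector of case counts, one per client.
#' @export
client_sizes <- function(fed) {
  stopifnot(inherits(fed, "federation"))
  sizes <- vapply(fed$clients, function(cl) length(cl$cases), integer(1))
  names(sizes) <- vapply(fed$clients, function(cl) cl$site_id, character(1))
  sizes
}

#' Artificial partitioning by whole-tumor size
#'
#' Refines a federation by splitting each of the `n_largest` biggest clients
#' into `n_splits` equally large parts after sorting its cases by whole-tumor
#' size (stable sort, ties broken by case index). The resulting sub-sites have
#' systematically different lesion-size distributions, emulating partitioning
#' schemes that sub-divide large institutions along imaging characteristics.
#' Other clients are unchanged; the multiset of cases is preserved. Each new
#' client is re-split 80/20 deterministically from its parent's split seed.
#'
#' @param fed A `federation`.
#' @param n_largest How many of the biggest clients to split (default 5).
#' @param n_splits Parts per split client (default 3); part sizes differ by at
#'   most one.
#' @param rng_seed Seed for the new clients' validation splits.
#' @return A new `federation` with `partitioning_id = "artificial"`.
#' @export
partition_artificial <- function(fed, n_largest = 5L, n_splits = 3L,
                                 rng_seed = 1L) {
  stopifnot(inherits(fed, "federation"))
  n_largest <- as.integer(n_largest)
  n_splits <- as.integer(n_splits)
  if (n_largest == 0L) return(fed)
  if (length(fed$clients) < n_largest) {
    stop("federation has fewer than n_largest clients")
  }
  sizes <- client_sizes(fed)
  # largest n_largest clients; ties broken by site_id for reproducibility
  ord <- order(-sizes, names(sizes))
  split_ids <- names(sizes)[ord[seq_len(n_largest)]]

  clients <- list()
  for (cl in fed$clients) {
    if (!cl$site_id %in% split_ids) {
      clients[[length(clients) + 1L]] <- cl
      next
    }
    if (length(cl$cases) < n_splits) {
      stop("client ", cl$site_id, " has fewer cases (", length(cl$cases),
           ") than n_splits (", n_splits, ")")
    }
    wt <- vapply(cl$cases, function(cs) cs$wt_size, numeric(1))
    case_order <- order(wt, seq_along(wt)) # stable: ties by case index
    chunks <- balanced_chunks(case_order, n_splits)
    for (j in seq_len(n_splits)) {
      sid <- paste0(cl$site_id, "_p", j)
      cases <- cl$cases[chunks[[j]]]
      split <- with_stream(derive_seed(rng_seed, "split", sid),
                           validation_split(length(cases)))
      clients[[length(clients) + 1L]] <- new_client_dataset(sid, cases, split)
    }
  }
  new_federation(clients, "artificial")
}

# Split indices into k contiguous chunks whose sizes differ by at most 1.
balanced_chunks <- function(idx, k) {
  n <- length(idx)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  purrr::map2(starts, ends, function(a, b) idx[a:b])
}

#' Export a federation's cases as NIfTI image/label pairs
#'
#' Writes, per case, a 4-channel image volume and a label map in the standard
#' \{0,1,2,4\} label convention, for use with external tooling or the `eval`
#' CLI. Requires the RNifti package.
#'
#' @param fed A `federation`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a tibble of written file paths.
#' @export
export_nifti <- function(fed, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("export_nifti requires the RNifti package")
  }
  stopifnot(inherits(fed, "federation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (cl in fed$clients) {
    for (cs in cl$cases) {
      img_path <- file.path(dir, paste0(cs$case_id, "_img.nii.gz"))
      lab_path <- file.path(dir, paste0(cs$case_id, "_seg.nii.gz"))
      RNifti::writeNifti(cs$image, img_path)
      RNifti::writeNifti(cs$labels$values, lab_path)
      rows[[length(rows) + 1L]] <-
        tibble::tibble(case_id = cs$case_id, image = img_path, labels = lab_path)
    }
  }
  invisible(purrr::list_rbind(rows))
}
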