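# Independent brute-force oracles used to cross-check the package's metric and
# ranking implementations. Deliberately written with plain loops over voxels /
# table entries, sharing no code with the implementation under test.

# Dice by explicit set counting over voxel index sets.
oracle_dsc <- function(a, b) {
  ia <- which(a)
  ib <- which(b)
  if (length(ia) == 0 && length(ib) == 0) return(1)
  if (length(ia) == 0 || length(ib) == 0) return(0)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

# Boundary voxels by checking all face neighbors with explicit loops.
oracle_boundary <- function(mask, spacing = rep(1, length(dim(mask)))) {
  dims <- dim(mask)
  nd <- length(dims)
  idx <- which(mask)
  coords <- arrayInd(idx, dims)
  keep <- logical(length(idx))
  for (i in seq_along(idx)) {
    cc <- coords[i, ]
    on_boundary <- FALSE
    for (ax in seq_len(nd)) {
      for (dd in c(-1L, 1L)) {
        nb <- cc
        nb[ax] <- nb[ax] + dd
        if (nb[ax] < 1 || nb[ax] > dims[ax]) {
          on_boundary <- TRUE
        } else {
          lin <- nb[1]
          if (nd >= 2) lin <- lin + (nb[2] - 1) * dims[1]
          if (nd >= 3) lin <- lin + (nb[3] - 1) * dims[1] * dims[2]
          if (!mask[lin]) on_boundary <- TRUE
        }
      }
    }
    keep[i] <- on_boundary
  }
  sweep(coords[keep, , drop = FALSE], 2, spacing, `*`)
}

# HD95 by all-pairs distances and the linear-interpolation percentile.
oracle_hd95 <- function(a, b, spacing = rep(1, length(dim(a)))) {
  pa <- oracle_boundary(a, spacing)
  pb <- oracle_boundary(b, spacing)
  d_ab <- vapply(seq_len(nrow(pa)), function(i) {
    min(sqrt(colSums((t(pb) - pa[i, ])^2)))
  }, numeric(1))
  d_ba <- vapply(seq_len(nrow(pb)), function(i) {
    min(sqrt(colSums((t(pa) - pb[i, ])^2)))
  }, numeric(1))
  max(quantile(d_ab, 0.95, names = FALSE, type = 7),
      quantile(d_ba, 0.95, names = FALSE, type = 7))
}

# Random blob-like mask: a few spheres of random radius, possibly empty.
random_mask <- function(dims, n_blobs = sample(0:3, 1)) {
  m <- array(FALSE, dim = dims)
  if (n_blobs == 0) return(m)
  coords <- arrayInd(seq_len(prod(dims)), dims)
  for (b in seq_len(n_blobs)) {
    center <- vapply(dims, function(d) runif(1, 1, d), numeric(1))
    r <- runif(1, 1, max(2, min(dims) / 3))
    d2 <- rowSums(sweep(coords, 2, center, `-`)^2)
    m[d2 <= r^2] <- TRUE
  }
  m
}

# Exhaustive task-1 style ranking: per case/region/metric min-ranks plus the
# convergence rank counted three times per case; mean of all collected ranks.
oracle_rank_task1 <- function(table, convergence) {
  algos <- sort(unique(table$algorithm))
  ranks <- setNames(lapply(algos, function(a) numeric(0)), algos)
  minrank <- function(vals, high_good) {
    key <- if (high_good) -vals else vals
    key[!is.finite(key)] <- Inf
    rank(key, ties.method = "min")
  }
  for (cs in unique(table$case)) {
    for (reg in unique(table$region)) {
      for (met in unique(table$metric)) {
        sub <- table[table$case == cs & table$region == reg &
                       table$metric == met, ]
        sub <- sub[match(algos, sub$algorithm), ]
        r <- minrank(sub$value, toupper(met) != "HD95")
        for (i in seq_along(algos)) {
          ranks[[algos[i]]] <- c(ranks[[algos[i]]], r[i])
        }
      }
    }
    cr <- minrank(convergence$score[match(algos, convergence$algorithm)], TRUE)
    for (i in seq_along(algos)) {
      ranks[[algos[i]]] <- c(ranks[[algos[i]]], rep(cr[i], 3))
    }
  }
  scores <- vapply(ranks, mean, numeric(1))
  data.frame(algorithm = algos, ranking_score = unname(scores),
             final_rank = unname(minrank(scores, FALSE)))
}

# Small fixed federation for orchestrator tests.
tiny_federation <- function(n_sites = 2, n_cases = 6, seed = 101) {
  specs <- lapply(seq_len(n_sites), function(i) {
    site_spec(paste0("T", i), n_cases, seed = seed + i)
  })
  make_federation(specs, "fixed", rng_seed = seed)
}

# Deterministic timing profile (sigma = 0) shared by clock tests.
flat_timing <- function(fed, mu_train = 10, mu_val = 1, mu_comm = 5) {
  ids <- names(client_sizes(fed))
  out <- lapply(ids, function(id) {
    client_timing_params(mu_down = mu_comm, mu_up = mu_comm,
                         mu_val = mu_val, mu_train = mu_train)
  })
  names(out) <- ids
  out
}

# Tiny parameter objects for aggregation tests (1-D "models").
toy_params <- function(values, layout = NULL) {
  layout <- layout %||% list(w = length(values))
  fedsim:::new_model_params(as.numeric(values), layout, NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
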