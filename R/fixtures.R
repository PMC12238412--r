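#' Reference study federations
#'
#' Two ready-made federations used throughout the package's examples, tests
#' and the acceptance script:
#'
#' * `homogeneous_federation()`: `n_sites` statistically identical sites
#'   (same lesion-size and ET-fraction ranges, same noise), differing only in
#'   their random draws — the setting where plain federated averaging should
#'   learn essentially as fast as pooled training.
#' * `skewed_federation()`: one dominant site holding about half of all cases
#'   plus several small sites with mild site-specific intensity shifts — the
#'   regime where the dominant site is also the slowest under
#'   size-proportional timing, so client selection matters.
#'
#' @param n_sites,n_cases Number of sites and cases per site (homogeneous).
#' @param seed Federation seed; all content derives from it.
#' @return A `federation`.
#' @export
homogeneous_federation <- function(n_sites = 4, n_cases = 20, seed = 1L) {
  specs <- lapply(seq_len(n_sites), function(i) {
    site_spec(sprintf("site%02d", i), n_cases,
              seed = derive_seed(seed, "site", i))
  })
  make_federation(specs, "fixed", rng_seed = seed)
}

#' Simulated annotation errors
#'
#' Tools for studying annotation quality control. `corrupt_labels()` simulates
#' a major annotation error: the tumor annotation is erased on one side of a
#' random axis-aligned plane through the lesion (roughly half the lesion
#' loses its labels). `noisy_labels()` simulates ordinary annotation
#' imprecision by relabeling a small random fraction of voxels.
#'
#' @param labels A [label_map()].
#' @param seed Integer seed.
#' @return A [label_map()] of the same shape.
#' @export
corrupt_labels <- function(labels, seed = 1L) {
  stopifnot(inherits(labels, "label_map"))
  v <- labels$values
  idx <- which(v != 0L)
  if (length(idx) == 0) return(labels)
  coords <- arrayInd(idx, dim(v))
  with_stream(derive_seed(seed, "corrupt"), {
    ax <- sample(length(dim(v)), 1)
    cut <- stats::median(coords[, ax])
    side <- sample(c(TRUE, FALSE), 1)
    gone <- if (side) coords[, ax] > cut else coords[, ax] < cut
    v[idx[gone]] <- 0L
  })
  label_map(v, labels$spacing)
}

#' @rdname corrupt_labels
#' @param rate Fraction of voxels relabeled at random (default 0.02).
#' @export
noisy_labels <- function(labels, rate = 0.02, seed = 1L) {
  stopifnot(inherits(labels, "label_map"), rate >= 0, rate <= 1)
  v <- labels$values
  n <- length(v)
  with_stream(derive_seed(seed, "noise"), {
    flip <- sample.int(n, max(0L, round(rate * n)))
    v[flip] <- sample(c(0L, 1L, 2L, 4L), length(flip), replace = TRUE)
  })
  label_map(v, labels$spacing)
}

#' @rdname homogeneous_federation
#' @param big_cases Cases at the dominant site (default 40).
#' @param small_cases Cases at each small site (default 10).
#' @param n_small Number of small sites (default 4).
#' @export
skewed_federation <- function(big_cases = 40, small_cases = 10, n_small = 4,
                              seed = 1L) {
  offsets <- seq(-0.1, 0.1, length.out = n_small)
  specs <- c(
    list(site_spec("big", big_cases, seed = derive_seed(seed, "site", 0))),
    lapply(seq_len(n_small), function(i) {
      site_spec(sprintf("small%02d", i), small_cases,
                intensity_offset = offsets[i],
                seed = derive_seed(seed, "site", i))
    })
  )
  make_federation(specs, "fixed", rng_seed = seed)
}
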