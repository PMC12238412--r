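#' Specification of one simulated institution's phantom data
#'
#' A site spec fixes everything needed to generate one simulated institution:
#' how many cases it holds and its site-specific domain shift (per-channel
#' intensity scale and offset, noise level) plus the lesion-size and
#' enhancing-tumor-fraction ranges its cases are drawn from. Site-level shifts
#' emulate scanner/protocol differences between institutions; skewed `n_cases`
#' across sites emulate the heavily imbalanced case counts seen in real
#' multi-institutional federations.
#'
#' @param site_id Site identifier (character).
#' @param n_cases Number of cases (positive integer).
#' @param intensity_scale Per-channel multiplicative shift (length 1 or 4,
#'   positive).
#' @param intensity_offset Per-channel additive shift (length 1 or 4).
#' @param noise_sigma Additive Gaussian noise standard deviation (positive).
#' @param tumor_radius_range Min/max whole-tumor radius in voxels.
#' @param et_fraction_range Min/max fraction of the tumor core occupied by
#'   enhancing tumor, both in (0, 1).
#' @param seed Integer seed for this site's cases.
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(site_id, n_cases,
                      intensity_scale = 1, intensity_offset = 0,
                      noise_sigma = 0.05,
                      tumor_radius_range = c(4, 9),
                      et_fraction_range = c(0.2, 0.6),
                      seed = 1L) {
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 1) stop("n_cases must be >= 1")
  intensity_scale <- rep_len(as.numeric(intensity_scale), 4)
  intensity_offset <- rep_len(as.numeric(intensity_offset), 4)
  if (any(intensity_scale <= 0)) stop("intensity_scale must be positive")
  if (noise_sigma <= 0) stop("noise_sigma must be positive")
  if (length(tumor_radius_range) != 2 ||
      tumor_radius_range[1] > tumor_radius_range[2] ||
      tumor_radius_range[1] <= 0) {
    stop("tumor_radius_range must be positive with min <= max")
  }
  if (length(et_fraction_range) != 2 ||
      any(et_fraction_range <= 0) || any(et_fraction_range >= 1) ||
      et_fraction_range[1] > et_fraction_range[2]) {
    stop("et_fraction_range bounds must lie in (0, 1) with min <= max")
  }
  structure(
    list(site_id = as.character(site_id), n_cases = n_cases,
         intensity_scale = intensity_scale,
         intensity_offset = intensity_offset,
         noise_sigma = noise_sigma,
         tumor_radius_range = as.numeric(tumor_radius_range),
         et_fraction_range = as.numeric(et_fraction_range),
         seed = as.integer(seed)),
    class = "site_spec"
  )
}

# Mean tissue intensity per (tissue, channel). Channels mirror the standard
# mpMRI sequence order 1:T1, 2:T1-Gd, 3:T2, 4:FLAIR. Only ET is elevated on
# T1-Gd; edema is bright on T2/FLAIR; necrosis is dark on T1.
tissue_means <- function() {
  rbind(
    bg  = c(0.30, 0.30, 0.30, 0.30),
    ncr = c(0.15, 0.30, 0.45, 0.45),
    ed  = c(0.40, 0.30, 0.70, 0.75),
    et  = c(0.45, 0.90, 0.55, 0.55)
  )
}

#' Generate one simulated institution
#'
#' Each case is a 4-channel image (emulating T1, T1-Gd, T2, T2-FLAIR) with a
#' random ellipsoidal lesion of nested sub-regions: an outer edema shell
#' (label 2), and a core split into a central connected enhancing-tumor blob
#' (label 4) and surrounding necrosis (label 1). The T1-Gd channel is elevated
#' only inside ET. Site-level intensity scale/offset and Gaussian noise are
#' applied on top. Generation is a pure function of (spec, geometry).
#'
#' @param spec A [site_spec()].
#' @param geometry Grid shape, 2-D or 3-D, all dims >= 16. Default `c(32, 32)`.
#' @return A `client_dataset`: list with `site_id`, `cases` (each a list with
#'   `image`, `labels`, `wt_size`, `site_id`, `case_id`), `train_indices`,
#'   `val_indices`, `n_train`, `n_val`.
#' @export
generate_site <- function(spec, geometry = c(32, 32)) {
  stopifnot(inherits(spec, "site_spec"))
  nd <- length(geometry)
  if (!nd %in% c(2L, 3L) || any(geometry < 16)) {
    stop("geometry must be 2-D or 3-D with all dims >= 16")
  }
  max_r <- spec$tumor_radius_range[2] * 1.2
  if (2 * max_r + 4 > min(geometry)) {
    stop("tumor_radius_range too large for geometry: lesion of radius ",
         max_r, " cannot fit in grid ", paste(geometry, collapse = "x"))
  }
  cases <- lapply(seq_len(spec$n_cases), function(i) {
    with_stream(derive_seed(spec$seed, "case", i),
                generate_case(spec, geometry, i))
  })
  split <- with_stream(derive_seed(spec$seed, "split"),
                       validation_split(spec$n_cases))
  new_client_dataset(spec$site_id, cases, split)
}

new_client_dataset <- function(site_id, cases, split) {
  structure(
    list(site_id = site_id, cases = cases,
         train_indices = split$train, val_indices = split$val,
         n_train = length(split$train), n_val = length(split$val)),
    class = "client_dataset"
  )
}

#' @export
print.client_dataset <- function(x, ...) {
  cat("<client_dataset> site ", x$site_id, ": ", length(x$cases),
      " cases (", x$n_train, " train / ", x$n_val, " val)\n", sep = "")
  invisible(x)
}

# 20% validation split: n_val = max(1, round(0.2 n)), sampled without
# replacement from the current RNG stream.
validation_split <- function(n) {
  n_val <- max(1L, as.integer(round(0.2 * n)))
  val <- sort(sample.int(n, n_val))
  list(train = setdiff(seq_len(n), val), val = val)
}

generate_case <- function(spec, geometry, case_idx) {
  nd <- length(geometry)
  r <- stats::runif(1, spec$tumor_radius_range[1], spec$tumor_radius_range[2])
  radii <- r * stats::runif(nd, 0.8, 1.2)
  center <- vapply(seq_len(nd), function(ax) {
    lo <- radii[ax] + 2
    hi <- geometry[ax] - radii[ax] - 1
    stats::runif(1, lo, hi)
  }, numeric(1))

  coords <- arrayInd(seq_len(prod(geometry)), geometry)
  # squared normalized distance from lesion center
  d2 <- rowSums(sweep(sweep(coords, 2, center, `-`), 2, radii, `/`)^2)
  wt <- d2 <= 1

  core_frac <- stats::runif(1, 0.4, 0.8) # core radius as fraction of WT radius
  core <- d2 <= core_frac^2
  et_frac <- stats::runif(1, spec$et_fraction_range[1],
                          spec$et_fraction_range[2])
  labels <- integer(prod(geometry))
  labels[wt] <- 2L # edema shell by default
  core_idx <- which(core)
  if (length(core_idx) > 0) {
    n_et <- max(1L, min(length(core_idx),
                        as.integer(round(et_frac * length(core_idx)))))
    inner <- core_idx[order(d2[core_idx])][seq_len(n_et)] # central ET blob
    labels[core_idx] <- 1L
    labels[inner] <- 4L
  }
  labels <- array(labels, dim = geometry)

  tm <- tissue_means()
  tissue <- c("bg", "ncr", "ed", "et")[match(labels, c(0L, 1L, 2L, 4L))]
  img <- array(0, dim = c(geometry, 4L))
  flat <- matrix(tm[tissue, ], ncol = 4)
  for (ch in 1:4) {
    plane <- flat[, ch] * spec$intensity_scale[ch] + spec$intensity_offset[ch]
    plane <- plane + stats::rnorm(prod(geometry), 0, spec$noise_sigma)
    if (nd == 2) img[, , ch] <- plane else img[, , , ch] <- plane
  }
  list(image = img, labels = label_map(labels),
       wt_size = sum(labels != 0L),
       site_id = spec$site_id,
       case_id = paste0(spec$site_id, "-", case_idx))
}
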