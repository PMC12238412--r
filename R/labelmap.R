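#' Label maps with the standard brain-tumor label convention
#'
#' A `label_map` is an integer voxel grid (2-D or 3-D) whose values follow the
#' standard brain-tumor convention: 0 background, 1 necrotic tumor core (NCR),
#' 2 peritumoral
#' edema (ED), 4 enhancing tumor (ET). Voxel spacing along each axis is carried
#' for distance-based metrics.
#'
#' @param values Integer matrix or 3-D array with values in \{0, 1, 2, 4\}.
#' @param spacing Positive numeric vector of per-axis voxel sizes (recycled to
#'   the number of axes; default 1).
#' @return An object of class `label_map`.
#' @export
label_map <- function(values, spacing = 1) {
  if (is.null(dim(values))) stop("`values` must be a matrix or array")
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("label maps must be 2-D or 3-D")
  vals <- as.integer(values)
  bad <- setdiff(unique(vals), c(0L, 1L, 2L, 4L))
  if (length(bad) > 0) {
    stop("invalid label values: ", paste(sort(bad), collapse = ", "),
         " (allowed: 0, 1, 2, 4)")
  }
  spacing <- rep_len(as.numeric(spacing), nd)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be strictly positive")
  }
  structure(
    list(values = array(vals, dim = dim(values)), spacing = spacing),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(x$values, levels = c(0, 1, 2, 4)))
  cat("<label_map> ", paste(dim(x$values), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 3), collapse = "x"), "\n",
      sep = "")
  cat("  labels: 0 (bg)=", tab[["0"]], ", 1 (NCR)=", tab[["1"]],
      ", 2 (ED)=", tab[["2"]], ", 4 (ET)=", tab[["4"]], "\n", sep = "")
  invisible(x)
}

#' Region masks for the three evaluated tumor sub-regions
#'
#' Derives the whole tumor (WT, labels \{1,2,4\}), tumor core (TC, labels
#' \{1,4\}) and enhancing tumor (ET, label \{4\}) masks from a label map.
#' By construction ET is a subset of TC, which is a subset of WT.
#'
#' @param labels A [label_map()].
#' @return A named list of three `region_mask` objects (`WT`, `TC`, `ET`).
#' @export
regions_from_labels <- function(labels) {
  stopifnot(inherits(labels, "label_map"))
  v <- labels$values
  list(
    WT = region_mask(v == 1L | v == 2L | v == 4L, labels$spacing, "WT"),
    TC = region_mask(v == 1L | v == 4L, labels$spacing, "TC"),
    ET = region_mask(v == 4L, labels$spacing, "ET")
  )
}

#' Construct a region mask
#'
#' @param mask Logical matrix/array.
#' @param spacing Per-axis voxel sizes.
#' @param region Region name (one of "WT", "TC", "ET", or any identifier).
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(mask, spacing = 1, region = "mask") {
  if (is.null(dim(mask))) stop("`mask` must be a matrix or array")
  mask <- array(as.logical(mask), dim = dim(mask))
  spacing <- rep_len(as.numeric(spacing), length(dim(mask)))
  structure(list(region = region, mask = mask, spacing = spacing),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("<region_mask> ", x$region, ": ", sum(x$mask), "/", length(x$mask),
      " voxels\n", sep = "")
  invisible(x)
}

as_mask_array <- function(x) {
  if (inherits(x, "region_mask")) x$mask else array(as.logical(x), dim = dim(x))
}

mask_spacing <- function(x, default_nd) {
  if (inherits(x, "region_mask")) x$spacing else rep(1, default_nd)
}
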