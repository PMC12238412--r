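#' Connected-component labeling of a voxel mask
#'
#' Labels connected components of a logical mask using the voxel adjacency
#' graph. "face" connectivity joins voxels sharing a (d-1)-face (4-neighborhood
#' in 2-D, 6 in 3-D); "full" also joins diagonal neighbors (8 / 26).
#'
#' @param mask Logical matrix or 3-D array.
#' @param connectivity "face" (default) or "full".
#' @return Integer array of the same shape: 0 outside the mask, component id
#'   (1-based, decreasing size order) inside.
#' @export
label_components <- function(mask, connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  mask <- as_mask_array(mask)
  dims <- dim(mask)
  nd <- length(dims)
  out <- array(0L, dim = dims)
  idx <- which(mask)
  if (length(idx) == 0) return(out)
  compact <- integer(length(mask))
  compact[idx] <- seq_along(idx)

  offsets <- half_offsets(nd, connectivity)
  coords <- arrayInd(idx, dims)
  strides <- cumprod(c(1, dims[-nd]))
  edges <- list()
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    nb_coords <- sweep(coords, 2, off, `+`)
    ok <- rep(TRUE, nrow(nb_coords))
    for (ax in seq_len(nd)) {
      ok <- ok & nb_coords[, ax] >= 1L & nb_coords[, ax] <= dims[ax]
    }
    if (!any(ok)) next
    nb_lin <- as.vector((nb_coords[ok, , drop = FALSE] - 1) %*% strides) + 1L
    in_mask <- mask[nb_lin]
    if (!any(in_mask)) next
    from <- compact[idx[ok][in_mask]]
    to <- compact[nb_lin[in_mask]]
    edges[[length(edges) + 1L]] <- cbind(from, to)
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  # relabel so component 1 is the largest (stable on ties by first occurrence)
  ord <- order(-comp$csize, seq_along(comp$csize))
  relabel <- integer(length(ord))
  relabel[ord] <- seq_along(ord)
  out[idx] <- relabel[comp$membership]
  out
}

half_offsets <- function(nd, connectivity) {
  if (connectivity == "face") {
    diag(nd)
  } else {
    g <- as.matrix(do.call(expand.grid, rep(list(c(-1L, 0L, 1L)), nd)))
    keep <- apply(g, 1, function(o) {
      nz <- which(o != 0)
      length(nz) > 0 && o[nz[1]] > 0 # one representative per +/- pair
    })
    g[keep, , drop = FALSE]
  }
}

#' Fill healthy-tissue holes inside the tumor core
#'
#' Relabels voxels fully enclosed by tumor core (TC = labels \{1, 4\}) to NCR
#' (label 1), rationale being that solid tumors rarely contain voids of
#' healthy tissue. The operator works slice-wise in 2-D: one pass over all
#' axial slices, then coronal, then sagittal. Within a slice, non-TC pixels
#' form 4-connected regions; regions that do not touch the slice border (and
#' hence are enclosed by TC) are relabeled. Voxels already labeled 1 or 4 are
#' never changed. A 2-D input is treated as a single axial slice.
#'
#' @param labels A [label_map()].
#' @param until_convergence If `TRUE`, repeat the three-orientation cycle until
#'   the map stops changing. Default `FALSE`: exactly one cycle.
#' @return A [label_map()] of the same shape.
#' @export
fill_tc <- function(labels, until_convergence = FALSE) {
  stopifnot(inherits(labels, "label_map"))
  v <- labels$values
  nd <- length(dim(v))
  if (nd == 2L) {
    dim(v) <- c(dim(v), 1L)
  }
  repeat {
    before <- v
    for (ax in 3:1) { # axis held fixed: 3 = axial, 2 = coronal, 1 = sagittal
      v <- fill_tc_orientation(v, ax)
    }
    if (!until_convergence || identical(v, before)) break
  }
  if (nd == 2L) dim(v) <- dim(labels$values)
  label_map(v, labels$spacing)
}

fill_tc_orientation <- function(v, ax) {
  for (s in seq_len(dim(v)[ax])) {
    sl <- slice_index(v, ax, s)
    slice <- v[sl$i1, sl$i2, sl$i3]
    dim(slice) <- dim(v)[-ax]
    tc <- slice == 1L | slice == 4L
    if (!any(tc)) next
    comp <- label_components(!tc, "face")
    border_ids <- unique(c(comp[1, ], comp[nrow(comp), ],
                           comp[, 1], comp[, ncol(comp)]))
    enclosed <- comp > 0 & !(comp %in% border_ids)
    if (any(enclosed)) {
      slice[enclosed] <- 1L
      v[sl$i1, sl$i2, sl$i3] <- slice
    }
  }
  v
}

slice_index <- function(v, ax, s) {
  idx <- lapply(dim(v), seq_len)
  idx[[ax]] <- s
  list(i1 = idx[[1]], i2 = idx[[2]], i3 = idx[[3]])
}

#' Relabel small enhancing-tumor predictions to necrosis
#'
#' False ET predictions are commonly tiny; when the predicted ET volume falls
#' below a threshold, relabeling it to NCR (label 1) improves the ET score on
#' truly ET-free cases. The comparison is strict: ET is relabeled iff its voxel
#' count is `< min_voxels`.
#'
#' @param labels A [label_map()].
#' @param min_voxels Nonnegative integer threshold.
#' @param per_component If `TRUE`, apply the rule to each connected ET
#'   component separately instead of the total ET volume.
#' @param connectivity Component connectivity for `per_component`.
#' @return A [label_map()].
#' @export
small_et_to_ncr <- function(labels, min_voxels, per_component = FALSE,
                            connectivity = "face") {
  stopifnot(inherits(labels, "label_map"), min_voxels >= 0)
  v <- labels$values
  et <- v == 4L
  if (!any(et)) return(labels)
  if (per_component) {
    comp <- label_components(et, connectivity)
    sizes <- tabulate(comp[comp > 0])
    drop_ids <- which(sizes < min_voxels)
    v[comp %in% drop_ids & et] <- 1L
  } else if (sum(et) < min_voxels) {
    v[et] <- 1L
  }
  label_map(v, labels$spacing)
}

#' Remove small connected components of a tumor region
#'
#' Connected components of the chosen region mask (WT, TC or ET) with fewer
#' than `min_voxels` voxels are set to background (label 0). Strict comparison:
#' components of exactly `min_voxels` voxels survive.
#'
#' @param labels A [label_map()].
#' @param region One of "WT", "TC", "ET".
#' @param min_voxels Minimum surviving component size.
#' @param connectivity "face" (default) or "full".
#' @return A [label_map()].
#' @export
drop_small_components <- function(labels, region = c("WT", "TC", "ET"),
                                  min_voxels, connectivity = "face") {
  region <- match.arg(region)
  stopifnot(inherits(labels, "label_map"), min_voxels >= 0)
  v <- labels$values
  keep_labels <- switch(region, WT = c(1L, 2L, 4L), TC = c(1L, 4L), ET = 4L)
  mask <- array(v %in% keep_labels, dim = dim(v))
  if (!any(mask)) return(labels)
  comp <- label_components(mask, connectivity)
  sizes <- tabulate(comp[comp > 0])
  drop_ids <- which(sizes < min_voxels)
  if (length(drop_ids) > 0) {
    v[comp %in% drop_ids & mask] <- 0L
  }
  label_map(v, labels$spacing)
}
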