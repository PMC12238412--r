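#' Dice similarity coefficient
#'
#' Spatial overlap between a predicted and a reference mask,
#' `2 |Y n Yhat| / (|Y| + |Yhat|)`, ranging from 0 (worst) to 1 (best).
#' When both masks are empty the score is 1 (perfect agreement on absence);
#' when exactly one is empty it is 0. These conventions are explicit because
#' the ratio is undefined for empty sets.
#'
#' @param pred,ref Logical arrays or [region_mask()] objects of identical shape.
#' @return A number in \[0, 1\].
#' @export
dsc <- function(pred, ref) {
  p <- as_mask_array(pred)
  r <- as_mask_array(ref)
  if (!identical(dim(p), dim(r))) stop("mask shapes differ")
  np <- sum(p); nr <- sum(r)
  if (np == 0 && nr == 0) return(1)
  if (np == 0 || nr == 0) return(0)
  2 * sum(p & r) / (np + nr)
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Extracts the boundary voxels of both masks (a mask voxel with at least one
#' face-adjacent voxel outside the mask, counting out-of-grid as outside),
#' computes the two directed distance sets d(yhat, Y) and d(y, Yhat) between
#' boundary point sets (voxel centers scaled by `spacing`), and returns the
#' maximum of their 95th percentiles (linear-interpolation percentile,
#' [stats::quantile()] type 7). Lower is better.
#'
#' If either mask is empty the boundary distance is undefined; the configured
#' `penalty` sentinel is returned (default 373.13, the image-diagonal penalty
#' conventional in the brain-tumor segmentation community), with attribute
#' `degenerate = TRUE` so downstream tables can flag it.
#'
#' @param pred,ref Logical arrays or [region_mask()] objects of identical shape
#'   and spacing.
#' @param probs Percentile in (0, 1\]; default 0.95.
#' @param penalty Sentinel returned when either mask is empty.
#' @return A nonnegative number (distance units of `spacing`).
#' @export
hd95 <- function(pred, ref, probs = 0.95, penalty = 373.13) {
  p <- as_mask_array(pred)
  r <- as_mask_array(ref)
  if (!identical(dim(p), dim(r))) stop("mask shapes differ")
  sp <- mask_spacing(pred, length(dim(p)))
  sr <- mask_spacing(ref, length(dim(r)))
  if (!isTRUE(all.equal(sp, sr))) stop("mask spacings differ")
  if (sum(p) == 0 || sum(r) == 0) {
    return(structure(penalty, degenerate = TRUE))
  }
  bp <- boundary_coords(p, sp)
  br <- boundary_coords(r, sp)
  d_pr <- directed_min_dists(bp, br)
  d_rp <- directed_min_dists(br, bp)
  max(stats::quantile(d_pr, probs, names = FALSE, type = 7),
      stats::quantile(d_rp, probs, names = FALSE, type = 7))
}

# Coordinates (scaled by spacing) of mask voxels having >= 1 face-adjacent
# non-mask neighbor; voxels on the grid edge count as boundary.
boundary_coords <- function(mask, spacing) {
  dims <- dim(mask)
  nd <- length(dims)
  interior <- array(TRUE, dim = dims)
  for (ax in seq_len(nd)) {
    lo <- shift_array(mask, ax, +1L) # neighbor at index - 1
    hi <- shift_array(mask, ax, -1L) # neighbor at index + 1
    interior <- interior & lo & hi
  }
  bnd <- mask & !interior
  idx <- which(bnd)
  coords <- arrayInd(idx, dims)
  sweep(coords, 2, spacing, `*`)
}

# Shift an array along axis `ax` by `by` voxels, padding with FALSE.
shift_array <- function(x, ax, by) {
  dims <- dim(x)
  out <- array(FALSE, dim = dims)
  n <- dims[ax]
  if (abs(by) >= n) return(out)
  src <- lapply(dims, seq_len)
  dst <- src
  if (by > 0) {
    dst[[ax]] <- (by + 1L):n
    src[[ax]] <- 1L:(n - by)
  } else if (by < 0) {
    dst[[ax]] <- 1L:(n + by)
    src[[ax]] <- (1L - by):n
  }
  vals <- do.call(`[`, c(list(x), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(value = vals)))
}

# For each row of `a`, the minimum Euclidean distance to the rows of `b`.
directed_min_dists <- function(a, b) {
  # ||a - b||^2 = |a|^2 + |b|^2 - 2 a.b, blocked to bound memory
  b2 <- rowSums(b^2)
  block <- max(1L, floor(2e6 / nrow(b)))
  out <- numeric(nrow(a))
  i <- 1L
  while (i <= nrow(a)) {
    j <- min(i + block - 1L, nrow(a))
    ab <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(ab^2), b2, `+`) - 2 * ab %*% t(b)
    out[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  out
}

#' Convergence curves: validation DSC over simulated time
#'
#' A convergence curve is the sequence of (cumulative simulated time, global
#' validation DSC) points produced by a federated run, with point 0 being the
#' initial model at time 0, plus the total simulated-time budget.
#'
#' @param times Strictly increasing nonnegative times (same unit as `budget`).
#' @param dscs Validation DSC values in \[0, 1\], one per time.
#' @param budget Total simulated-time budget (default 604800, one week in
#'   seconds).
#' @return An object of class `convergence_curve`.
#' @export
convergence_curve <- function(times, dscs, budget = 604800) {
  stopifnot(length(times) == length(dscs), length(times) >= 1, budget > 0)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(times < 0)) stop("times must be nonnegative")
  if (any(dscs < 0 | dscs > 1)) stop("dsc values must lie in [0, 1]")
  keep <- times <= budget
  structure(
    list(points = tibble::tibble(time = times[keep], dsc = dscs[keep]),
         budget = budget,
         truncated = any(!keep)),
    class = "convergence_curve"
  )
}

#' @export
print.convergence_curve <- function(x, ...) {
  cat("<convergence_curve> ", nrow(x$points), " points, budget ", x$budget,
      if (x$truncated) " (truncated)" else "", "\n", sep = "")
  invisible(x)
}

#' Convergence score: normalized area under the projected DSC curve
#'
#' The projected curve `DSC_proj(t) = max_{t' <= t} DSC(t')` never decreases,
#' so late drops in validation DSC (the best model is kept as the final model)
#' are not penalized. The curve is treated as a step function: validation DSC
#' is only observed when a round completes, so the last observed projected
#' value holds until the next point, the value before the first point is 0,
#' and the last value holds to the end of the budget. Points past the budget
#' are not credited. The area is normalized by the budget, giving a score in
#' \[0, 1\]; higher means faster convergence to high DSC.
#'
#' @param curve A [convergence_curve()].
#' @return A number in \[0, 1\].
#' @export
convergence_score <- function(curve) {
  stopifnot(inherits(curve, "convergence_curve"))
  pts <- curve$points
  if (nrow(pts) == 0) return(0)
  proj <- cummax(pts$dsc)
  t <- pts$time
  widths <- diff(c(t, curve$budget))
  area <- sum(proj * widths) # value is 0 before the first point
  area / curve$budget
}

#' @rdname convergence_curve
#' @param object A `convergence_curve`.
#' @param ... Unused.
#' @export
autoplot.convergence_curve <- function(object, ...) {
  pts <- object$points
  pts$proj <- cummax(pts$dsc)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$dsc), color = "grey60") +
    ggplot2::geom_step(ggplot2::aes(y = .data$proj), color = "black") +
    ggplot2::coord_cartesian(xlim = c(0, object$budget), ylim = c(0, 1)) +
    ggplot2::labs(x = "simulated time", y = "validation DSC",
                  title = "Projected convergence curve")
}

#' Per-case, per-region segmentation scores as a tidy table
#'
#' Convenience wrapper computing DSC and HD95 for the three tumor regions of
#' each prediction/reference pair.
#'
#' @param preds,refs Lists of [label_map()]s of equal length.
#' @param case_ids Optional case identifiers (default sequence).
#' @param penalty HD95 sentinel for empty masks (see [hd95()]).
#' @return A tibble with columns `case`, `region`, `dsc`, `hd95`,
#'   `hd95_degenerate`.
#' @export
score_cases <- function(preds, refs, case_ids = NULL, penalty = 373.13) {
  stopifnot(length(preds) == length(refs))
  if (is.null(case_ids)) case_ids <- as.character(seq_along(preds))
  rows <- purrr::map2(seq_along(preds), case_ids, function(i, id) {
    rp <- regions_from_labels(preds[[i]])
    rr <- regions_from_labels(refs[[i]])
    purrr::map(c("WT", "TC", "ET"), function(reg) {
      h <- hd95(rp[[reg]], rr[[reg]], penalty = penalty)
      tibble::tibble(
        case = id, region = reg,
        dsc = dsc(rp[[reg]], rr[[reg]]),
        hd95 = as.numeric(h),
        hd95_degenerate = isTRUE(attr(h, "degenerate"))
      )
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(rows)
}
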