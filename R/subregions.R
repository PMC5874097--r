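## Subregion summarization: resampling of high-resolution ROI labels to
## the DCE grid, 3x3 in-plane neighborhood averaging on the parametric
## maps, deterministic placement of the averaging window, and assembly of
## per-tumor records joining pharmacokinetics with microvessel counts.

#' Resample a label mask between grids
#'
#' Nearest-neighbor label resampling from a high-resolution grid (e.g. the
#' 512 x 512 anatomical matrix the ROI was drawn on) to the DCE grid. Each
#' source voxel votes into the target voxel its center falls in; the
#' target label is the majority vote, with ties broken toward the lower
#' label code. Target voxels receiving no vote (possible when downsampling
#' is not integer) fall back to the source voxel nearest their center.
#' Both grids must cover the same physical extent.
#'
#' @param mask integer label array (2D or 3D) on the source grid
#' @param sourceSpacing,targetSpacing voxel spacing, mm
#' @param targetDim target grid size
#' @return integer label array on the target grid
#' @export
resampleROI <- function(mask, sourceSpacing, targetDim, targetSpacing) {
  d <- dim(mask)
  stopifnot(length(d) == length(targetDim),
            length(sourceSpacing) == length(d),
            length(targetSpacing) == length(d))
  extentS <- d * sourceSpacing
  extentT <- targetDim * targetSpacing
  if (any(abs(extentS - extentT) > pmax(sourceSpacing, targetSpacing)))
    stop("source and target grids cover different physical extents")
  if (identical(as.integer(d), as.integer(targetDim)) &&
      all(abs(sourceSpacing - targetSpacing) < 1e-9))
    return(mask)
  ## index of the target voxel containing each source voxel center
  centerToTarget <- function(n, sp, tsp, tn)
    pmin(pmax(ceiling(((seq_len(n) - 0.5) * sp) / tsp), 1L), tn)
  maps <- lapply(seq_along(d), function(k)
    centerToTarget(d[k], sourceSpacing[k], targetSpacing[k], targetDim[k]))
  src <- which(array(TRUE, d), arr.ind = TRUE)
  tgtIdx <- maps[[1]][src[, 1]]
  mult <- 1
  for (k in seq_along(d)[-1]) {
    mult <- mult * targetDim[k - 1]
    tgtIdx <- tgtIdx + (maps[[k]][src[, k]] - 1L) * mult
  }
  lab <- as.integer(mask)
  out <- integer(prod(targetDim))
  filled <- logical(prod(targetDim))
  ## majority vote per target voxel, ties toward the lower label code
  votes <- table(tgtIdx, lab)
  tIds <- as.integer(rownames(votes))
  labVals <- as.integer(colnames(votes))
  win <- labVals[apply(votes, 1L, which.max)]  # which.max: first (lowest)
  out[tIds] <- win
  filled[tIds] <- TRUE
  if (!all(filled)) {
    ## backward nearest-neighbor for unvoted target voxels
    empty <- which(!filled)
    tix <- arrayInd(empty, targetDim)
    sIdx <- matrix(0L, nrow(tix), length(d))
    for (k in seq_along(d))
      sIdx[, k] <- pmin(pmax(ceiling(((tix[, k] - 0.5) *
        targetSpacing[k]) / sourceSpacing[k]), 1L), d[k])
    lin <- sIdx[, 1]
    mult <- 1
    for (k in seq_along(d)[-1]) {
      mult <- mult * d[k - 1]
      lin <- lin + (sIdx[, k] - 1L) * mult
    }
    out[empty] <- lab[lin]
  }
  array(out, targetDim)
}

#' Mean over the 3x3 in-plane neighborhood
#'
#' Arithmetic mean of the nine values in the in-plane 3 x 3 window centered
#' on a voxel (the center and its second neighborhood), on the same slice.
#' Through-plane neighbors are excluded because the slices are much thicker
#' than the in-plane voxels. The window must lie inside the volume.
#'
#' @param map 2D or 3D numeric array
#' @param center voxel index, c(i, j) or c(i, j, k)
#' @return the 9-voxel mean
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 9
#' neighborhoodMean(m, c(3, 3))  # 1
#' @export
neighborhoodMean <- function(map, center) {
  d <- dim(map)
  i <- center[1]; j <- center[2]
  if (i < 2 || j < 2 || i > d[1] - 1 || j > d[2] - 1)
    stop("3x3 window crosses the volume edge")
  if (length(d) == 2) {
    mean(map[(i - 1):(i + 1), (j - 1):(j + 1)])
  } else {
    k <- center[3]
    stopifnot(k >= 1, k <= d[3])
    mean(map[(i - 1):(i + 1), (j - 1):(j + 1), k])
  }
}

## window means of all eligible centers in a region: voxels whose 3x3
## in-plane window lies fully inside both the volume and the region
regionWindowMeans <- function(labels, code, map) {
  d <- dim(labels)
  idx <- which(labels == code)
  if (!length(idx)) return(NULL)
  pos <- arrayInd(idx, d)
  keep <- pos[, 1] >= 2 & pos[, 1] <= d[1] - 1 &
    pos[, 2] >= 2 & pos[, 2] <= d[2] - 1
  idx <- idx[keep]; pos <- pos[keep, , drop = FALSE]
  if (!length(idx)) return(list(idx = integer(), means = numeric()))
  inRegion <- vapply(seq_along(idx), function(r) {
    i <- pos[r, 1]; j <- pos[r, 2]; k <- pos[r, 3]
    all(labels[(i - 1):(i + 1), (j - 1):(j + 1), k] == code)
  }, logical(1))
  idx <- idx[inRegion]
  means <- vapply(idx, function(li)
    neighborhoodMean(map, arrayInd(li, d)[1, ]), numeric(1))
  list(idx = idx, means = means)
}

#' Pick the representative window center of a region
#'
#' Deterministic stand-in for manual window placement: among all voxels
#' whose 3 x 3 in-plane window lies fully inside the region, picks the one
#' whose window-mean Ktrans is closest to the median of all eligible
#' window means (ties broken by the lower linear voxel index). The median
#' window makes the summary robust to small pockets of outlying voxels.
#' If no window fits inside the region, the region centroid is returned
#' with attribute \code{fallback = TRUE}.
#'
#' @param labels integer label array
#' @param code region label code
#' @param ktransMap the Ktrans map steering the placement
#' @return voxel index c(i, j, k)
#' @export
pickRegionCenter <- function(labels, code, ktransMap) {
  d <- dim(labels)
  if (!any(labels == code)) stop("region not present in the label volume")
  rw <- regionWindowMeans(labels, code, ktransMap)
  if (is.null(rw) || !length(rw$idx)) {
    ## no fully-interior window: fall back to the region voxel nearest
    ## the centroid (the centroid itself can lie outside an annular
    ## region), clamped away from the volume edge
    idx <- which(labels == code)
    pos <- arrayInd(idx, d)
    ctr0 <- colMeans(pos)
    nearest <- which.min(rowSums((pos - matrix(ctr0, nrow(pos), 3,
                                               byrow = TRUE))^2))
    ctr <- pos[nearest, ]
    ctr <- pmin(pmax(ctr, c(2, 2, 1)), d - c(1, 1, 0))
    attr(ctr, "fallback") <- TRUE
    return(ctr)
  }
  med <- stats::median(rw$means)
  best <- which(abs(rw$means - med) == min(abs(rw$means - med)))
  pick <- rw$idx[best[which.min(rw$idx[best])]]
  ctr <- arrayInd(pick, d)[1, ]
  attr(ctr, "fallback") <- FALSE
  ctr
}

#' Summarize one tumor's subregions
#'
#' For each subregion present in the label volume (1 CNA, 2 PNA, 3 VTA),
#' places the representative 3 x 3 window by
#' \code{\link{pickRegionCenter}} on the Ktrans map and reports the
#' window means of Ktrans, ve and vp at that center, joined with the
#' region's microvessel density.
#'
#' @param maps a \code{\linkS4class{ParameterMaps}}
#' @param labels integer label array on the same grid (codes 0-3)
#' @param mvdTable data.frame with columns \code{region} and \code{mvd};
#'   a missing region yields \code{NA} with a warning
#' @param tumorId identifier carried into the output
#' @return data.frame with one row per present region: \code{tumor_id},
#'   \code{region}, \code{ktrans} (/min), \code{ve}, \code{vp}
#'   (fractions), \code{mvd} (vessels per field), \code{center_i/j/k}
#' @export
summarizeTumor <- function(maps, labels, mvdTable = NULL, tumorId = 1L) {
  stopifnot(identical(dim(labels), dim(maps@ktrans)))
  regions <- c("CNA", "PNA", "VTA")
  rows <- lapply(1:3, function(code) {
    if (!any(labels == code)) return(NULL)
    ctr <- pickRegionCenter(labels, code, maps@ktrans)
    mvd <- NA_real_
    if (!is.null(mvdTable)) {
      hit <- mvdTable$region == regions[code]
      if (any(hit)) mvd <- mvdTable$mvd[which(hit)[1]]
      else warning(sprintf("no MVD value for region %s", regions[code]))
    }
    data.frame(tumor_id = tumorId, region = regions[code],
               ktrans = neighborhoodMean(maps@ktrans, ctr),
               ve = neighborhoodMean(maps@ve, ctr),
               vp = neighborhoodMean(maps@vp, ctr),
               mvd = mvd,
               center_i = ctr[1], center_j = ctr[2], center_k = ctr[3])
  })
  do.call(rbind, rows)
}
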