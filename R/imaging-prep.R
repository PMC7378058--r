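## Crop-and-pad preprocessing turning tumor patches into fixed-size
## 3-channel network inputs (80x80 CT, 28x28 PET at defaults), plus the
## multi-scale variant (margins 0/10/20 px per side).

#' Tight bounding-box crop of an image around an ROI mask
#'
#' Returns the axis-aligned minimal sub-image containing every nonzero mask
#' pixel (1-based inclusive row/column ranges).
#'
#' @param image numeric matrix
#' @param roiMask binary matrix of the same shape
#' @return list with \code{patch} (cropped image), \code{maskPatch} and the
#'   ranges \code{rows}, \code{cols}
#' @export
cropToBbox <- function(image, roiMask) {
  if (!all(dim(image) == dim(roiMask))) stop("image and mask shapes differ")
  idx <- which(roiMask != 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty ROI mask")
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  list(patch = image[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
       maskPatch = roiMask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE],
       rows = rr, cols = cc)
}

#' Center a patch on a square zero ("black") canvas
#'
#' The patch is placed in the middle of a \code{canvasSide} x
#' \code{canvasSide} zero matrix; when the leftover space is odd the extra
#' pixel goes to the bottom/right (top-left bias). All non-patch pixels are
#' exactly 0, so the pixel-intensity sum is conserved.
#'
#' @param patch numeric matrix, no larger than the canvas in either dimension
#' @param canvasSide canvas side, pixels
#' @return \code{canvasSide} x \code{canvasSide} numeric matrix
#' @export
padToCanvas <- function(patch, canvasSide) {
  p <- dim(patch)
  if (any(p > canvasSide))
    stop("patch (", p[1], "x", p[2], ") exceeds the canvas (", canvasSide,
         "); the canvas must cover the largest tumor")
  out <- matrix(0, canvasSide, canvasSide)
  r0 <- floor((canvasSide - p[1]) / 2)
  c0 <- floor((canvasSide - p[2]) / 2)
  out[r0 + seq_len(p[1]), c0 + seq_len(p[2])] <- patch
  out
}

#' Stack three same-size slices into a 3-channel input
#'
#' Channel order is (below, middle, above): the tumor middle slice sits in
#' channel 2 with its two immediate neighbors around it.
#'
#' @param middle,below,above equally sized numeric matrices
#' @return array side x side x 3
#' @export
stackSlices <- function(middle, below, above) {
  if (!all(dim(middle) == dim(below)) || !all(dim(middle) == dim(above)))
    stop("slices must share the same shape")
  out <- array(0, c(dim(middle), 3L))
  out[, , 1] <- below; out[, , 2] <- middle; out[, , 3] <- above
  attr(out, "channel_mode") <- "slices"
  out
}

## Crop with a per-side margin (clipped at the image border); pad to the
## canvas when the crop fits, bilinearly downscale (aspect preserved) when
## it does not.
.cropScale <- function(image, roiMask, margin, canvasSide) {
  idx <- which(roiMask != 0, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty ROI mask")
  rr <- range(idx[, 1]); cc <- range(idx[, 2])
  r1 <- max(rr[1] - margin, 1L); r2 <- min(rr[2] + margin, nrow(image))
  c1 <- max(cc[1] - margin, 1L); c2 <- min(cc[2] + margin, ncol(image))
  crop <- image[r1:r2, c1:c2, drop = FALSE]
  if (any(dim(crop) > canvasSide)) {
    f <- canvasSide / max(dim(crop))
    crop <- EBImage::imageData(EBImage::resize(
      EBImage::Image(crop), w = max(round(nrow(crop) * f), 1),
      h = max(round(ncol(crop) * f), 1)))
    crop <- pmin(pmax(crop, 0), max(image))
  }
  padToCanvas(crop, canvasSide)
}

#' Multi-scale 3-channel stack
#'
#' Builds three crops of the same slice with per-side margins (default 0,
#' 10 and 20 px, clipped at the image border) so that channels see the tumor
#' plus progressively more surrounding tissue, standardizes each to the base
#' canvas, and stacks them. The margin-0 channel reproduces the plain
#' crop-and-pad path.
#'
#' @param image numeric matrix (single slice)
#' @param roiMask binary matrix, same shape
#' @param margins three per-side margins in pixels
#' @param canvasSide base canvas side
#' @return array canvasSide x canvasSide x 3 with \code{channel_mode}
#'   attribute "scales"
#' @export
multiscaleStack <- function(image, roiMask, margins = c(0, 10, 20), canvasSide = 80L) {
  if (length(margins) != 3) stop("exactly three margins required")
  out <- array(0, c(canvasSide, canvasSide, 3L))
  for (k in 1:3) out[, , k] <- .cropScale(image, roiMask, margins[k], canvasSide)
  attr(out, "channel_mode") <- "scales"
  out
}

#' Preprocess a cohort into fixed-size network input stacks
#'
#' For every case the index (highest-SUV) tumor is cropped to its ROI
#' bounding box and centered on a zero canvas, per modality. In
#' \code{"slices"} mode the three stored slices form the channels (the
#' middle-slice bounding box is used for all three, keeping them aligned);
#' in \code{"scales"} mode the middle slice is cropped at margins
#' \code{margins} instead.
#'
#' @param cohort a \code{\link{TumorCohort}}
#' @param mode "slices" or "scales"
#' @param canvasCt,canvasPet canvas sides (defaults 80 and 28)
#' @param margins per-side margins for \code{"scales"} mode
#' @return list with arrays \code{ct} (canvasCt x canvasCt x 3 x n) and
#'   \code{pet}, plus \code{caseIds}
#' @export
prepareStacks <- function(cohort, mode = c("slices", "scales"),
                          canvasCt = 80L, canvasPet = 28L,
                          margins = c(0, 10, 20)) {
  mode <- match.arg(mode)
  cases <- cohortCases(cohort)
  n <- length(cases)
  ct <- array(0, c(canvasCt, canvasCt, 3L, n))
  pet <- array(0, c(canvasPet, canvasPet, 3L, n))
  for (i in seq_len(n)) {
    tm <- selectIndexTumor(cases[[i]])
    if (mode == "slices") {
      for (mod in c("ct", "pet")) {
        canvas <- if (mod == "ct") canvasCt else canvasPet
        msk <- tm[[paste0(mod, "_mask")]]
        idx <- which(msk != 0, arr.ind = TRUE)
        rr <- range(idx[, 1]); cc <- range(idx[, 2])
        ch <- lapply(1:3, function(k)
          padToCanvas(tm[[mod]][rr[1]:rr[2], cc[1]:cc[2], k, drop = FALSE][, , 1], canvas))
        stk <- stackSlices(middle = ch[[2]], below = ch[[1]], above = ch[[3]])
        if (mod == "ct") ct[, , , i] <- stk else pet[, , , i] <- stk
      }
    } else {
      ct[, , , i] <- multiscaleStack(tm$ct[, , 2], tm$ct_mask, margins, canvasCt)
      pet[, , , i] <- multiscaleStack(tm$pet[, , 2], tm$pet_mask, margins, canvasPet)
    }
  }
  list(ct = ct, pet = pet,
       caseIds = vapply(cases, `[[`, character(1), "case_id"))
}

#' Min-max intensity normalization fitted on the training set
#'
#' Scales a 4-d stack array to [0, 1] using the minimum and maximum of the
#' training subset only, so no test-set information leaks into the scaling.
#'
#' @param stacks array side x side x 3 x n
#' @param trainIdx indices (into the 4th dimension) of the training cases
#' @return list with the normalized \code{stacks} and the fitted \code{lo},
#'   \code{hi}
#' @export
normalizeStacks <- function(stacks, trainIdx) {
  lo <- min(stacks[, , , trainIdx])
  hi <- max(stacks[, , , trainIdx])
  if (hi <= lo) stop("degenerate intensity range in the training set")
  list(stacks = pmin(pmax((stacks - lo) / (hi - lo), 0), 1), lo = lo, hi = hi)
}
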