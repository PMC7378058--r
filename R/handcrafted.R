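## Hand-crafted radiomics arm: 21 features per modality (7 shape, 8
## intensity, 6 GLCM texture), 42 per case across CT+PET, PCA reduction,
## stepwise Cox.

.largestComponent <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask != 0))
  lab <- EBImage::imageData(lab)
  k <- max(lab)
  if (k <= 1) return(mask != 0)
  sizes <- tabulate(lab[lab > 0], nbins = k)
  lab == which.max(sizes)
}

## Boundary chain of the mask as an ordered point matrix (row, col), plus a
## perimeter estimate with the Vossepoel-Smeulders step weights (0.980 for
## axial, 1.406 for diagonal steps), which removes most of the raster
## overestimation so that a disc scores near 1 on the isoperimetric ratio.
.boundaryChain <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  pts <- oc[[which.max(vapply(oc, nrow, integer(1)))]] + 1  # 0-based -> 1-based
  d <- rbind(diff(pts), pts[1, ] - pts[nrow(pts), ])
  ax <- abs(d[, 1]) + abs(d[, 2])
  per <- sum(ifelse(ax == 1, 0.980, ifelse(ax == 2, 1.406, sqrt(d[, 1]^2 + d[, 2]^2))))
  list(points = pts, perimeter = per)
}

#' Shape features of a tumor ROI mask (7 values)
#'
#' Quantifies the geometry of the (largest connected component of the)
#' mask:
#' \itemize{
#'   \item \code{area_regularity}: isoperimetric ratio \eqn{4\pi A / P^2}
#'     (1 for a disc, smaller for irregular shapes);
#'   \item \code{perimeter_convexity}: convex-hull perimeter / perimeter;
#'   \item \code{radial_cv}: coefficient of variation of the boundary
#'     distances to the centroid;
#'   \item \code{symmetry_h}, \code{symmetry_v}, \code{symmetry_d1},
#'     \code{symmetry_d2}: Jaccard overlap of the mask with its reflection
#'     about the horizontal, vertical and two diagonal axes through the
#'     centroid.
#' }
#'
#' @param roiMask binary matrix (nonempty)
#' @return named numeric vector of length 7
#' @export
shapeFeatures <- function(roiMask) {
  if (sum(roiMask != 0) < 1) stop("empty ROI mask")
  m <- .largestComponent(roiMask)
  A <- sum(m)
  idx <- which(m, arr.ind = TRUE)
  ctr <- colMeans(idx)
  if (A < 3) {
    ## degenerate specks: boundary tracing is meaningless
    bchain <- NULL
    per <- 4
    hull <- per
    radCv <- 0
  } else {
    bchain <- .boundaryChain(m)
    per <- bchain$perimeter
    hp <- bchain$points[grDevices::chull(bchain$points), , drop = FALSE]
    hd <- rbind(diff(hp), hp[1, ] - hp[nrow(hp), ])
    hull <- sum(sqrt(hd[, 1]^2 + hd[, 2]^2))
    rad <- sqrt((bchain$points[, 1] - ctr[1])^2 + (bchain$points[, 2] - ctr[2])^2)
    radCv <- if (mean(rad) > 0) stats::sd(rad) / mean(rad) else 0
  }
  jacc <- function(r2, c2) {
    a <- unique(complex(real = idx[, 1], imaginary = idx[, 2]))
    b <- unique(complex(real = round(r2), imaginary = round(c2)))
    length(intersect(a, b)) / length(union(a, b))
  }
  r <- idx[, 1]; c <- idx[, 2]
  c(area_regularity = min(4 * pi * A / per^2, 1),
    perimeter_convexity = min(hull / per, 1),
    radial_cv = radCv,
    symmetry_h = jacc(2 * ctr[1] - r, c),
    symmetry_v = jacc(r, 2 * ctr[2] - c),
    symmetry_d1 = jacc(ctr[1] + (c - ctr[2]), ctr[2] + (r - ctr[1])),
    symmetry_d2 = jacc(ctr[1] - (c - ctr[2]), ctr[2] - (r - ctr[1])))
}

#' First-order intensity features over an ROI (8 values)
#'
#' Size (pixel count), mean, standard deviation (population form), median,
#' minimum, maximum, excess kurtosis, and skewness of the ROI pixel
#' intensities. For a constant region skewness and kurtosis are defined
#' as 0.
#'
#' @param image numeric matrix
#' @param roiMask binary matrix, same shape
#' @return named numeric vector of length 8
#' @export
intensityFeatures <- function(image, roiMask) {
  if (!all(dim(image) == dim(roiMask))) stop("image and mask shapes differ")
  x <- image[roiMask != 0]
  if (!length(x)) stop("empty ROI mask")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  c(size_px = length(x), mean = m, sd = sqrt(m2), median = median(x),
    min = min(x), max = max(x),
    kurtosis = if (m2 > 0) mean((x - m)^4) / m2^2 - 3 else 0,
    skewness = if (m2 > 0) mean((x - m)^3) / m2^1.5 else 0)
}

## Quantize ROI intensities to `levels` bins over the ROI range (constant
## regions map to bin 1) and accumulate the symmetric GLCM, averaged over
## the four unit offsets.
.glcm <- function(image, roiMask, levels = 32L) {
  inRoi <- roiMask != 0
  x <- image[inRoi]
  rng <- range(x)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  q[inRoi] <- if (rng[2] > rng[1])
    pmin(floor((image[inRoi] - rng[1]) / (rng[2] - rng[1]) * levels) + 1L, levels)
  else 1L
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  acc <- matrix(0, levels, levels)
  used <- 0L
  nr <- nrow(q); nc <- ncol(q)
  for (off in offs) {
    r1 <- max(1, 1 - off[1]):min(nr, nr - off[1])
    c1 <- max(1, 1 - off[2]):min(nc, nc - off[2])
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- matrix(0, levels, levels)
    cnt <- table(factor(a[ok], levels = 1:levels), factor(b[ok], levels = 1:levels))
    tab <- matrix(as.numeric(cnt), levels, levels)
    tab <- tab + t(tab)                               # symmetric
    acc <- acc + tab / sum(tab)
    used <- used + 1L
  }
  if (used == 0L) stop("ROI too small for co-occurrence analysis (< 2 px)")
  acc / used
}

#' Gray-level co-occurrence texture features over an ROI (6 values)
#'
#' Intensities are quantized to \code{levels} bins over the ROI range; the
#' co-occurrence matrix is symmetric, normalized, and averaged over the four
#' unit offsets (0,1), (1,0), (1,1), (1,-1). Features: contrast
#' \eqn{\sum p_{ij}(i-j)^2}; energy \eqn{\sum p_{ij}^2}; correlation
#' (standard GLCM form; 0 when a marginal variance vanishes); homogeneity
#' \eqn{\sum p_{ij}/(1+|i-j|)}; entropy \eqn{-\sum p_{ij}\log_2 p_{ij}} over
#' nonzero cells; normalized entropy = entropy / \eqn{\log_2(\mathrm{levels}^2)}.
#'
#' @param image numeric matrix
#' @param roiMask binary matrix, same shape (ROI of at least 2 pixels)
#' @param levels number of quantization bins
#' @return named numeric vector of length 6
#' @export
textureFeatures <- function(image, roiMask, levels = 32L) {
  if (sum(roiMask != 0) < 2) stop("ROI must contain at least 2 pixels")
  p <- .glcm(image, roiMask, levels)
  i <- row(p); j <- col(p)
  mx <- sum(i * p); my <- sum(j * p)
  vx <- sum((i - mx)^2 * p); vy <- sum((j - my)^2 * p)
  corr <- if (vx > 0 && vy > 0) sum((i - mx) * (j - my) * p) / sqrt(vx * vy) else 0
  nz <- p[p > 0]
  ent <- -sum(nz * log2(nz))
  c(contrast = sum(p * (i - j)^2),
    energy = sum(p^2),
    correlation = corr,
    homogeneity = sum(p / (1 + abs(i - j))),
    entropy = ent,
    norm_entropy = ent / log2(as.numeric(levels)^2))
}

#' Extract the 42-feature hand-crafted radiomics vector of a case
#'
#' Computes 21 features (7 shape, 8 intensity, 6 texture) on the middle
#' slice of the index tumor, per modality, and concatenates CT then PET with
#' modality-prefixed names.
#'
#' @param case one element of \code{cohortCases(cohort)}
#' @param levels GLCM quantization levels
#' @return named numeric vector of length 42
#' @export
caseFeatureVector <- function(case, levels = 32L) {
  tm <- selectIndexTumor(case)
  out <- c()
  for (mod in c("ct", "pet")) {
    img <- tm[[mod]][, , 2]
    msk <- tm[[paste0(mod, "_mask")]]
    v <- c(shapeFeatures(msk), intensityFeatures(img, msk),
           textureFeatures(img, msk, levels))
    names(v) <- paste0(mod, "_", names(v))
    out <- c(out, v)
  }
  out
}

#' Hand-crafted feature table for a whole cohort
#'
#' @param cohort a \code{\link{TumorCohort}}
#' @param levels GLCM quantization levels
#' @return data.frame: one row per case, 42 feature columns, rownames =
#'   case ids
#' @export
extractFeatures <- function(cohort, levels = 32L) {
  cases <- cohortCases(cohort)
  tab <- t(vapply(cases, caseFeatureVector, numeric(42), levels = levels))
  rownames(tab) <- vapply(cases, `[[`, character(1), "case_id")
  as.data.frame(tab)
}

#' Fit a PCA reduction on a training feature table
#'
#' Features are z-scored with training means/scales (zero-variance features
#' are dropped with a warning); components are ordered by explained
#' variance.
#'
#' @param X training feature data.frame/matrix
#' @param nComponents number of components to keep (default 18)
#' @return list with \code{rotation}, \code{center}, \code{scale},
#'   \code{sdev}, \code{kept} (feature names), \code{nComponents}
#' @export
fitPca <- function(X, nComponents = 18L) {
  X <- as.matrix(X)
  v <- apply(X, 2, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance features: ", paste(colnames(X)[v == 0], collapse = ", "))
    X <- X[, v > 0, drop = FALSE]
  }
  nComponents <- as.integer(min(nComponents, nrow(X) - 1L, ncol(X)))
  if (nComponents < 1) stop("n_components must be >= 1 and <= min(n - 1, p)")
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  list(rotation = pc$rotation[, seq_len(nComponents), drop = FALSE],
       center = pc$center, scale = pc$scale, sdev = pc$sdev,
       kept = colnames(X), nComponents = nComponents)
}

#' Project a feature table onto a fitted PCA
#'
#' Uses the training center/scale only, so applying the model to test data
#' leaks no test-set statistics.
#'
#' @param model result of \code{\link{fitPca}}
#' @param X feature data.frame/matrix containing the fitted feature columns
#' @return matrix of component scores (columns PC1..PCk)
#' @export
applyPca <- function(model, X) {
  X <- as.matrix(X)[, model$kept, drop = FALSE]
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, `/`)
  S <- Z %*% model$rotation
  colnames(S) <- paste0("PC", seq_len(ncol(S)))
  S
}

#' Hand-crafted radiomics survival arm
#'
#' Extracts the 42-feature vector per case, fits a PCA on the training
#' cases, and runs backward stepwise Cox selection over the principal
#' components plus the clinical covariates (SUVmax, age, gender, dose).
#' Reports the test-set concordance index of the final model's linear
#' predictor, or NA when no covariate is selected.
#'
#' @param cohort a \code{\link{TumorCohort}}
#' @param outcome one of "OS", "RFS", "DC", "LC"
#' @param split list with \code{train}/\code{test} case ids
#'   (see \code{\link{splitTrainTest}})
#' @param nComponents PCA components (default 18)
#' @param alpha stepwise significance level
#' @param levels GLCM quantization levels
#' @return list with \code{fit} (a \code{CoxModelFit}), \code{cIndex},
#'   \code{pca}, and the covariate table \code{covariates}
#' @export
handcraftedPipeline <- function(cohort, outcome = "OS", split,
                                nComponents = 18L, alpha = 0.05, levels = 32L) {
  feats <- extractFeatures(cohort, levels = levels)
  cl <- clinicalData(cohort)
  rec <- .caseRecords(cohort, outcome)
  pca <- fitPca(feats[split$train, , drop = FALSE], nComponents)
  scores <- applyPca(pca, feats)
  X <- data.frame(scores,
                  suv = cl$suv_max, age = cl$age, gender = cl$gender, dose = cl$dose,
                  row.names = cl$case_id, check.names = FALSE)
  tr <- match(split$train, cl$case_id)
  te <- match(split$test, cl$case_id)
  fit <- stepwiseSelect(X[tr, , drop = FALSE], rec$time[tr], rec$event[tr], alpha = alpha)
  ci <- if (length(fit@selected)) {
    concordanceIndex(coxLinearPredictor(fit, X[te, , drop = FALSE]),
                     rec$time[te], rec$event[te], type = "risk")
  } else NA_real_
  list(fit = fit, cIndex = ci, pca = pca, covariates = X)
}

## one record per case for any outcome; for the tumor-level LC endpoint the
## index tumor's record represents the case
.caseRecords <- function(cohort, outcome) {
  rec <- survivalRecords(cohort, outcome)
  cl <- clinicalData(cohort)
  if (outcome == "LC") {
    idx <- vapply(cohortCases(cohort), selectIndexTumorIdx, integer(1))
    pick <- mapply(function(id, j) which(rec$case_id == id & rec$tumor_id == j),
                   cl$case_id, idx)
    rec <- rec[pick, ]
  }
  rec[match(cl$case_id, rec$case_id), c("case_id", "time", "event")]
}
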