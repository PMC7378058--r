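rasterDisc <- function(r, pad = 4) {
  side <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  m <- outer(seq_len(side), seq_len(side),
             function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
  m * 1
}

test_that("a disc is maximally regular and symmetric; a square has equal symmetries", {
  d <- rasterDisc(20)
  sf <- shapeFeatures(d)
  expect_length(sf, 7)
  expect_gte(sf[["area_regularity"]], 0.9)
  expect_gte(sf[["perimeter_convexity"]], 0.9)
  expect_lt(sf[["radial_cv"]], 0.05)
  expect_true(all(sf[c("symmetry_h", "symmetry_v", "symmetry_d1", "symmetry_d2")] >= 0.95))
  sq <- matrix(0, 41, 41); sq[4:38, 4:38] <- 1       # same spatial scale as the disc
  sfq <- shapeFeatures(sq)
  syms <- sfq[c("symmetry_h", "symmetry_v", "symmetry_d1", "symmetry_d2")]
  expect_equal(max(syms) - min(syms), 0)
  expect_lt(sfq[["area_regularity"]], sf[["area_regularity"]])
  # thin line: reflections along its own axes map it onto itself
  ln <- matrix(0, 9, 13); ln[5, 3:11] <- 1
  sfl <- shapeFeatures(ln)
  expect_equal(sfl[["symmetry_h"]], 1)
  expect_equal(sfl[["symmetry_v"]], 1)
  expect_gt(sfl[["radial_cv"]], 0.3)
  expect_error(shapeFeatures(matrix(0, 5, 5)), "empty")
})

test_that("shape features are invariant under translation and 90-degree rotation", {
  set.seed(8)
  m <- matrix(0, 15, 15)
  m[4:11, 5:12] <- rbinom(64, 1, 0.8)
  m <- (m & rasterDisc(5, 2)[1:15, 1:15]) * 1
  if (sum(m) < 5) m[6:9, 6:9] <- 1
  sf <- shapeFeatures(m)
  big <- matrix(0, 40, 40); big[20 + seq_len(15) - 8, 3 + seq_len(15)] <- m
  expect_equal(shapeFeatures(big), sf, tolerance = 1e-10)
  rot <- t(m[nrow(m):1, ])
  sfr <- shapeFeatures(rot)
  expect_equal(sfr[["area_regularity"]], sf[["area_regularity"]], tolerance = 1e-8)
  expect_equal(sfr[["perimeter_convexity"]], sf[["perimeter_convexity"]], tolerance = 1e-8)
  expect_equal(sfr[["radial_cv"]], sf[["radial_cv"]], tolerance = 1e-8)
  expect_equal(unname(sort(sfr[4:7])), unname(sort(sf[4:7])), tolerance = 1e-8)
})

test_that("intensity features match direct recomputation and handle constants", {
  img <- matrix(5, 10, 10)
  msk <- matrix(1, 10, 10)
  expect_equal(unname(intensityFeatures(img, msk)), c(100, 5, 0, 5, 5, 5, 0, 0))
  # two-valued symmetric ROI
  img2 <- matrix(c(rep(0, 50), rep(10, 50)), 10, 10)
  f2 <- intensityFeatures(img2, msk)
  expect_equal(unname(f2[c("mean", "sd", "skewness")]), c(5, 5, 0))
  # random ROI vs per-pixel recomputation
  set.seed(12)
  img3 <- matrix(rnorm(100), 10, 10)
  msk3 <- matrix(rbinom(100, 1, 0.4), 10, 10)
  msk3[1] <- 1
  x <- img3[msk3 == 1]
  f3 <- intensityFeatures(img3, msk3)
  m2 <- mean((x - mean(x))^2)
  expect_equal(unname(f3), c(length(x), mean(x), sqrt(m2), median(x), min(x), max(x),
                             mean((x - mean(x))^4) / m2^2 - 3,
                             mean((x - mean(x))^3) / m2^1.5))
})

test_that("intensity features are equivariant under affine intensity maps", {
  set.seed(14)
  img <- matrix(runif(64), 8, 8)
  msk <- matrix(1, 8, 8)
  f <- intensityFeatures(img, msk)
  g <- intensityFeatures(3 * img + 2, msk)
  expect_equal(g[["mean"]], 3 * f[["mean"]] + 2)
  expect_equal(g[["median"]], 3 * f[["median"]] + 2)
  expect_equal(g[["min"]], 3 * f[["min"]] + 2)
  expect_equal(g[["max"]], 3 * f[["max"]] + 2)
  expect_equal(g[["sd"]], 3 * f[["sd"]])
  expect_equal(g[["skewness"]], f[["skewness"]])
  expect_equal(g[["kurtosis"]], f[["kurtosis"]])
})

test_that("GLCM texture features match hand-built co-occurrence tables", {
  msk <- matrix(1, 8, 8)
  # constant ROI: a single co-occurrence cell
  tf <- textureFeatures(matrix(3, 8, 8), msk)
  expect_equal(unname(tf), c(0, 1, 0, 1, 0, 0))
  # perfect two-level checkerboard, hand-worked 2x2 table: horizontal and
  # vertical neighbors always differ (p(1,32)=p(32,1)=1/2), diagonal
  # neighbors always agree (p(1,1)=p(32,32)=1/2); averaging the 4 offsets
  # gives 1/4 in each of the 4 cells
  cb <- outer(1:8, 1:8, function(i, j) ((i + j) %% 2) * 10)
  tfc <- textureFeatures(cb, msk, levels = 32)
  expect_equal(tfc[["contrast"]], 0.5 * 31^2)
  expect_equal(tfc[["entropy"]], 2)
  expect_equal(tfc[["energy"]], 0.25)
  expect_equal(tfc[["correlation"]], 0)
  expect_equal(tfc[["homogeneity"]], 0.5 + 0.5 / 32)
  expect_equal(tfc[["norm_entropy"]], 2 / log2(32^2))
  # bounds on random ROIs
  set.seed(15)
  for (rep in 1:10) {
    img <- matrix(rnorm(100), 10, 10)
    m <- matrix(rbinom(100, 1, 0.5), 10, 10)
    if (sum(m) < 4) next
    tf <- textureFeatures(img, m)
    expect_gt(tf[["energy"]], 0)
    expect_lte(tf[["energy"]], 1)
    expect_gte(tf[["norm_entropy"]], 0)
    expect_lte(tf[["norm_entropy"]], 1)
  }
  expect_error(textureFeatures(matrix(1, 4, 4), matrix(c(1, rep(0, 15)), 4, 4)), "2 pixels")
})

test_that("texture features ignore affine intensity rescaling", {
  set.seed(16)
  img <- matrix(sample(0:7, 100, TRUE), 10, 10)
  msk <- matrix(1, 10, 10)
  expect_equal(textureFeatures(img, msk), textureFeatures(5 * img + 1, msk))
})

test_that("every case yields 42 modality-prefixed features", {
  co <- tinyCohort(n = 5, seed = 4)
  fv <- caseFeatureVector(cohortCases(co)[[1]])
  expect_length(fv, 42)
  expect_equal(sum(startsWith(names(fv), "ct_")), 21)
  expect_equal(sum(startsWith(names(fv), "pet_")), 21)
  tab <- extractFeatures(co)
  expect_equal(dim(tab), c(5, 42))
  expect_true(all(is.finite(as.matrix(tab))))
})

test_that("PCA round-trips at full rank, finds planted directions, decorrelates scores", {
  set.seed(17)
  X <- matrix(rnorm(60 * 12), 60, 12)
  colnames(X) <- paste0("f", 1:12)
  mod <- fitPca(X, nComponents = 12)
  S <- applyPca(mod, X)
  back <- sweep(sweep(S %*% t(mod$rotation), 2, mod$scale, `*`), 2, mod$center, `+`)
  expect_equal(unname(back), unname(X), tolerance = 1e-8)
  # planted dominant direction
  dirv <- rnorm(12); dirv <- dirv / sqrt(sum(dirv^2))
  Xp <- X * 0.05 + outer(rnorm(60, sd = 5), dirv)
  colnames(Xp) <- colnames(X)
  modp <- fitPca(Xp, nComponents = 3)
  # in z-scored space the planted direction's loadings scale as 1/sd
  scaledDir <- (dirv / apply(Xp, 2, sd)) / sqrt(sum((dirv / apply(Xp, 2, sd))^2))
  expect_gt(abs(sum(modp$rotation[, 1] * scaledDir)), 0.99)
  # uncorrelated training scores
  Sp <- applyPca(modp, Xp)
  cv <- cov(Sp)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # zero-variance features are dropped with a warning
  Xz <- cbind(X, const = 1)
  expect_warning(mz <- fitPca(Xz, 5), "zero-variance")
  expect_false("const" %in% mz$kept)
})

test_that("hand-crafted survival arm recovers an area-driven planted signal", {
  sel <- 0; cis <- c()
  for (s in 1:5) {
    co <- tinyCohort(n = 80, seed = 300 + s)
    sp <- splitTrainTest(clinicalData(co)$case_id, 0.8, seed = s)
    res <- handcraftedPipeline(co, "OS", sp, nComponents = 10)
    if (length(res$fit@selected)) {
      sel <- sel + 1
      cis <- c(cis, res$cIndex)
    }
  }
  expect_gte(sel, 3)
  expect_gt(median(cis), 0.5)
  # PCA statistics come from the training cases only (no leakage)
  co <- tinyCohort(n = 40, seed = 77)
  sp <- splitTrainTest(clinicalData(co)$case_id, 0.8, seed = 1)
  res <- handcraftedPipeline(co, "OS", sp, nComponents = 5)
  feats <- extractFeatures(co)
  trainFeats <- as.matrix(feats[sp$train, res$pca$kept])
  expect_equal(res$pca$center, colMeans(trainFeats))
})
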