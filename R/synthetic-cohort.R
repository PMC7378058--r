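## Seeded synthetic PET/CT survival cohorts. Tumors are textured elliptical
## blobs on dark backgrounds, drawn on two co-registered modalities; a latent
## log-hazard built from tumor area, mean ROI intensity and texture roughness
## drives proportional-hazards event times with independent + administrative
## censoring.

#' Specification of a synthetic PET/CT survival cohort
#'
#' Defaults emulate the structure of a small SBRT-treated early-stage lung
#' cancer cohort: ~132 cases with occasional multifocal disease (about 150
#' tumors in all), age centered near 75 years, lognormal SUVmax, biologically
#' effective radiation doses around 100 Gy, and follow-up times with a median
#' in the vicinity of 27 months under a 60-month administrative horizon.
#'
#' @param n_cases number of cases (>= 2)
#' @param tumor_probs probability of 1, 2, ... tumors per case
#' @param canvas_ct,canvas_pet side (pixels) of the CT and PET image grids
#' @param beta_image log-hazard coefficient on the latent image risk
#' @param beta_clinical named log-hazard coefficients for the standardized
#'   clinical covariates (age, gender, suv, dose)
#' @param baseline_rate baseline event rate, events per month
#' @param censor_rate rate of the independent exponential censoring process
#' @param admin_horizon administrative censoring time, months
#' @param seed integer RNG seed; identical specs give bit-identical cohorts
#' @return a list of class settings for \code{\link{generateCohort}}
#' @export
cohortSpec <- function(n_cases = 132L,
                       tumor_probs = c(0.87, 0.10, 0.03),
                       canvas_ct = 80L, canvas_pet = 28L,
                       beta_image = log(2),
                       beta_clinical = c(age = 0.15, gender = 0, suv = 0.2, dose = 0),
                       baseline_rate = 0.02,
                       censor_rate = 0.015,
                       admin_horizon = 60,
                       seed = 1L) {
  spec <- list(n_cases = as.integer(n_cases), tumor_probs = tumor_probs,
               canvas_ct = as.integer(canvas_ct), canvas_pet = as.integer(canvas_pet),
               beta_image = beta_image, beta_clinical = beta_clinical,
               baseline_rate = baseline_rate, censor_rate = censor_rate,
               admin_horizon = admin_horizon, seed = as.integer(seed))
  if (spec$n_cases < 2L) stop("n_cases must be >= 2")
  if (spec$canvas_ct < 8L || spec$canvas_pet < 8L) stop("canvases must be positive (>= 8 px)")
  if (spec$baseline_rate <= 0) stop("baseline_rate must be > 0")
  if (spec$censor_rate <= 0) stop("censor_rate must be > 0")
  if (spec$admin_horizon <= 0) stop("admin_horizon must be > 0")
  if (!all(c("age", "gender", "suv", "dose") %in% names(spec$beta_clinical)))
    stop("beta_clinical needs named entries age, gender, suv, dose")
  spec
}

## One textured elliptical tumor drawn on both modalities. The PET geometry
## is the CT geometry scaled by canvas_pet/canvas_ct (co-registration).
.drawTumor <- function(canvasCt, canvasPet, suv) {
  a <- runif(1, 5, 0.42 * canvasCt)   # semi-axes, px (largest fits the canvas)
  b <- runif(1, 5, 0.42 * canvasCt)
  th <- runif(1, 0, pi)
  rough <- runif(1, 0.02, 0.25)       # texture roughness (noise amplitude)
  baseCt <- runif(1, 0.4, 0.85)
  jit <- runif(2, -3, 3)
  mkSlice <- function(canvas, sa, sb, cx, cy, base, amp) {
    g <- expand.grid(r = seq_len(canvas), c = seq_len(canvas))
    dx <- g$c - cx; dy <- g$r - cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    inside <- (u / sa)^2 + (v / sb)^2 <= 1
    img <- matrix(0, canvas, canvas)
    img[cbind(g$r, g$c)[inside, , drop = FALSE]] <-
      pmin(pmax(base + amp * (runif(sum(inside)) - 0.5) * 2, 0), 1)
    list(img = img, mask = matrix(as.numeric(inside), canvas, canvas))
  }
  sc <- canvasPet / canvasCt
  ct <- array(0, c(canvasCt, canvasCt, 3))
  pet <- array(0, c(canvasPet, canvasPet, 3))
  ctr <- canvasCt / 2 + jit
  ctrP <- canvasPet / 2 + jit * sc
  basePet <- pmin(suv / 15, 1) * 0.8 + 0.1
  shrink <- c(0.8, 1, 0.8)            # neighbor slices show a smaller cross-section
  ctMask <- petMask <- NULL
  for (k in 1:3) {
    s <- mkSlice(canvasCt, a * shrink[k], b * shrink[k], ctr[1], ctr[2], baseCt, rough)
    ct[, , k] <- s$img
    p <- mkSlice(canvasPet, max(a * shrink[k] * sc, 1.5), max(b * shrink[k] * sc, 1.5),
                 ctrP[1], ctrP[2], basePet, rough)
    pet[, , k] <- p$img
    if (k == 2) { ctMask <- s$mask; petMask <- p$mask }
  }
  list(ct = ct, pet = pet, ct_mask = ctMask, pet_mask = petMask, suv = suv,
       area = sum(ctMask), meanInt = mean(ct[, , 2][ctMask == 1]), rough = rough)
}

#' Generate a synthetic PET/CT survival cohort
#'
#' Each case receives 1+ tumors (textured elliptical blobs, bright on dark,
#' rendered on co-registered CT and PET grids). The hidden per-tumor latent
#' risk is the sum of within-cohort z-scores of tumor area, mean ROI
#' intensity, and texture roughness; a case's latent risk is that of its
#' index (highest-SUV) tumor. Event times are exponential with rate
#' \code{baseline_rate * exp(beta_image * latent + beta_clinical . z(clinical))};
#' censoring is the minimum of an independent exponential and the
#' administrative horizon; the recorded time is \code{min(T, C)} with
#' \code{event = 1} when the event precedes censoring (simultaneous times
#' count as censored). OS, RFS and DC records are per case; LC records are
#' per tumor (with tumor-specific latent risk).
#'
#' @param spec a \code{\link{cohortSpec}}
#' @return a \code{\link{TumorCohort}}
#' @export
generateCohort <- function(spec = cohortSpec()) {
  spec <- do.call(cohortSpec, spec)       # revalidate
  set.seed(spec$seed)
  n <- spec$n_cases
  age <- pmin(pmax(round(rnorm(n, 74.65, 8)), 52), 92)
  gender <- rbinom(n, 1, 0.5)
  dose <- round(rnorm(n, 100, 15), 1)
  nt <- sample.int(length(spec$tumor_probs), n, replace = TRUE, prob = spec$tumor_probs)
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    suvs <- rlnorm(nt[i], log(5), 0.5)
    cases[[i]] <- list(case_id = sprintf("case%03d", i),
                       tumors = lapply(suvs, function(sv)
                         .drawTumor(spec$canvas_ct, spec$canvas_pet, sv)),
                       latent_risk = NA_real_)
  }
  ## latent risk: z-scores over all tumors in the cohort
  feats <- do.call(rbind, lapply(cases, function(cs)
    t(vapply(cs$tumors, function(tm) c(tm$area, tm$meanInt, tm$rough), numeric(3)))))
  zf <- scale(feats)
  tumorLatent <- rowSums(zf)
  k <- 0L
  for (i in seq_len(n)) {
    for (j in seq_along(cases[[i]]$tumors)) {
      k <- k + 1L
      cases[[i]]$tumors[[j]]$latent <- tumorLatent[k]
    }
  }
  suvMax <- vapply(cases, function(cs) max(vapply(cs$tumors, `[[`, numeric(1), "suv")),
                   numeric(1))
  clinical <- data.frame(case_id = vapply(cases, `[[`, character(1), "case_id"),
                         age = age, gender = gender, suv_max = suvMax, dose = dose,
                         stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    idx <- selectIndexTumorIdx(cases[[i]])
    cases[[i]]$latent_risk <- cases[[i]]$tumors[[idx]]$latent
  }
  zc <- cbind(age = as.numeric(scale(age)),
              gender = if (var(gender) > 0) as.numeric(scale(gender)) else rep(0, n),
              suv = as.numeric(scale(suvMax)),
              dose = as.numeric(scale(dose)))
  etaClin <- as.numeric(zc %*% spec$beta_clinical[colnames(zc)])
  drawRecords <- function(eta, ids, tumorIds = NULL) {
    m <- length(eta)
    tstar <- rexp(m, rate = spec$baseline_rate * exp(eta))
    cens <- pmin(rexp(m, rate = spec$censor_rate), spec$admin_horizon)
    rec <- data.frame(case_id = ids,
                      time = pmax(pmin(tstar, cens), 1e-8),
                      event = as.numeric(tstar < cens),
                      stringsAsFactors = FALSE)
    if (!is.null(tumorIds)) rec$tumor_id <- tumorIds
    rec
  }
  caseEta <- spec$beta_image * vapply(cases, `[[`, numeric(1), "latent_risk") + etaClin
  ids <- clinical$case_id
  surv <- list(OS = drawRecords(caseEta, ids),
               RFS = drawRecords(caseEta, ids),
               DC = drawRecords(caseEta, ids))
  tumorEta <- unlist(lapply(seq_len(n), function(i)
    spec$beta_image * vapply(cases[[i]]$tumors, `[[`, numeric(1), "latent") + etaClin[i]))
  tumorCase <- unlist(lapply(seq_len(n), function(i) rep(ids[i], nt[i])))
  tumorIdx <- unlist(lapply(seq_len(n), function(i) seq_len(nt[i])))
  surv$LC <- drawRecords(tumorEta, tumorCase, tumorIdx)
  new("TumorCohort", cases = cases, clinical = clinical, survival = surv)
}

## index of the highest-SUV tumor, ties broken by lowest index
selectIndexTumorIdx <- function(case) {
  if (!length(case$tumors)) stop("case has no tumors")
  suvs <- vapply(case$tumors, `[[`, numeric(1), "suv")
  which.max(suvs)   # which.max takes the first maximum: lowest-index tie-break
}

#' Select the index tumor of a case
#'
#' For per-case outcomes (OS, RFS, DC) a single tumor must represent a
#' multifocal case; the tumor with the highest SUV is taken. Ties break
#' deterministically toward the lowest tumor index.
#'
#' @param case one element of \code{cohortCases(cohort)}
#' @return the selected tumor structure (fields ct, pet, ct_mask, pet_mask, suv)
#' @export
selectIndexTumor <- function(case) {
  case$tumors[[selectIndexTumorIdx(case)]]
}

#' Case-level train/test split
#'
#' Shuffles case ids with the given seed and assigns the first
#' \code{floor(fraction * n)} (at least 1, at most n - 1) to the training
#' set; all tumors of a case stay on one side by construction.
#'
#' @param caseIds character vector of case ids
#' @param fraction training fraction, strictly between 0 and 1
#' @param seed integer seed
#' @return list with character vectors \code{train} and \code{test}
#' @export
splitTrainTest <- function(caseIds, fraction = 0.8, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie strictly between 0 and 1")
  n <- length(caseIds)
  if (n < 2) stop("need at least 2 cases to split")
  set.seed(seed)
  perm <- sample(caseIds)
  nTrain <- min(max(floor(fraction * n), 1L), n - 1L)
  list(train = sort(perm[seq_len(nTrain)]), test = sort(perm[-seq_len(nTrain)]))
}

#' Write the clinical + survival tables of a cohort to CSV
#'
#' One row per tumor, with per-case clinical covariates and the recorded
#' time/event for every outcome (per-case outcomes repeated across a case's
#' tumors; LC joined per tumor).
#'
#' @param cohort a \code{\link{TumorCohort}}
#' @param path output CSV path
#' @return the written data.frame, invisibly
#' @export
writeCohortCsv <- function(cohort, path) {
  cl <- clinicalData(cohort)
  rows <- list()
  for (cs in cohortCases(cohort)) {
    for (j in seq_along(cs$tumors)) {
      r <- cl[cl$case_id == cs$case_id, ]
      r$tumor_id <- j
      r$suv <- cs$tumors[[j]]$suv
      for (oc in c("OS", "RFS", "DC")) {
        rec <- survivalRecords(cohort, oc)
        rec <- rec[rec$case_id == cs$case_id, ]
        r[[paste0("time_", oc)]] <- rec$time
        r[[paste0("event_", oc)]] <- rec$event
      }
      lc <- survivalRecords(cohort, "LC")
      lc <- lc[lc$case_id == cs$case_id & lc$tumor_id == j, ]
      r$time_LC <- lc$time
      r$event_LC <- lc$event
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Export a tumor patch as PNG for visual inspection
#'
#' @param tumor a tumor structure (see \code{\link{selectIndexTumor}})
#' @param file output PNG path
#' @param modality "ct" or "pet"
#' @param slice channel to show (2 = middle)
#' @return \code{file}, invisibly
#' @export
exportPatchPng <- function(tumor, file, modality = c("ct", "pet"), slice = 2L) {
  modality <- match.arg(modality)
  img <- tumor[[modality]][, , slice]
  grDevices::png(file, width = 4 * ncol(img), height = 4 * nrow(img))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, useRaster = TRUE)
  invisible(file)
}
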