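## End-to-end orchestration: per outcome, preprocess, train the CT and PET
## risk branches, combine the two risks with the clinical factors in a
## stepwise Cox PHM, report test-set concordance plus cut-off/KM tables;
## optional hand-crafted and random-survival-forest arms.

#' Configuration of a full pipeline run
#'
#' @param outcomes subset of c("OS", "RFS", "DC", "LC")
#' @param mode "deep", "handcrafted" or "both" (both = one stepwise Cox over
#'   the concatenated deep + hand-crafted predictor sets)
#' @param channel_mode "slices" (3 neighboring slices) or "scales"
#'   (multi-scale margins 0/10/20 px)
#' @param epochs,learning_rate,batch_size deep-branch training settings;
#'   the defaults (150 epochs, lr 2e-3) are the desk-scale settings used
#'   throughout the package's experiments, the production-scale values
#'   (2000 epochs, lr 1e-5) can be passed explicitly
#' @param pretrain initialize conv trunks from a CAE trained on a disjoint
#'   unlabeled cohort ("cae") or use random init ("random")
#' @param alpha stepwise significance level
#' @param split_fraction training fraction of the case-level split
#' @param n_components PCA components for the hand-crafted arm
#' @param rsf optional \code{\link{forestSpec}} to add an RSF pass (NULL to
#'   skip)
#' @param seed master seed (split, weight init, shuffles derive from it)
#' @return a validated config list
#' @export
runConfig <- function(outcomes = c("OS", "RFS", "DC", "LC"),
                      mode = c("deep", "handcrafted", "both"),
                      channel_mode = c("slices", "scales"),
                      epochs = 150L, learning_rate = 2e-3, batch_size = 32L,
                      pretrain = c("random", "cae"),
                      alpha = 0.05, split_fraction = 0.8,
                      n_components = 18L, rsf = NULL, seed = 1L) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  list(outcomes = outcomes, mode = match.arg(mode),
       channel_mode = match.arg(channel_mode),
       epochs = as.integer(epochs), learning_rate = learning_rate,
       batch_size = as.integer(batch_size), pretrain = match.arg(pretrain),
       alpha = alpha, split_fraction = split_fraction,
       n_components = as.integer(n_components), rsf = rsf,
       seed = as.integer(seed))
}

## train both branches once and score every case; shared across outcomes
.deepRisks <- function(cohort, split, config, caeCohort = NULL, outcome = "OS") {
  prep <- prepareStacks(cohort, mode = config$channel_mode)
  tr <- match(split$train, prep$caseIds)
  rec <- .caseRecords(cohort, outcome)
  out <- list()
  for (mod in c("ct", "pet")) {
    nrm <- normalizeStacks(prep[[mod]], tr)
    side <- dim(prep[[mod]])[1]
    spec <- riskNetSpec(side, batch_size = config$batch_size)
    net <- buildRiskNet(spec, toupper(mod), seed = config$seed + (mod == "pet"))
    if (config$pretrain == "cae") {
      if (is.null(caeCohort)) stop("pretrain = 'cae' needs a disjoint unlabeled cohort")
      cae <- prepareStacks(caeCohort, mode = config$channel_mode)
      caeN <- normalizeStacks(cae[[mod]], seq_len(dim(cae[[mod]])[4]))
      pt <- pretrainCAE(caeN$stacks, spec, seed = config$seed + 100L)
      net <- transferWeights(net, pt$trunk)
    }
    net <- trainRiskNet(net, nrm$stacks[, , , tr, drop = FALSE],
                        rec$time[tr], rec$event[tr],
                        epochs = config$epochs,
                        learning_rate = config$learning_rate,
                        seed = config$seed + 10L * (mod == "pet"))
    out[[paste0(mod, "_risk")]] <- riskScores(net, nrm$stacks)
    out[[paste0(mod, "_net")]] <- net
  }
  out$caseIds <- prep$caseIds
  out
}

.armReport <- function(cohort, outcome, split, X, alpha) {
  rec <- .caseRecords(cohort, outcome)
  cl <- clinicalData(cohort)
  tr <- match(split$train, cl$case_id)
  te <- match(split$test, cl$case_id)
  fit <- stepwiseSelect(X[tr, , drop = FALSE], rec$time[tr], rec$event[tr], alpha = alpha)
  sel <- selectedCovariates(fit)
  ci <- if (length(sel))
    concordanceIndex(coxLinearPredictor(fit, X[te, , drop = FALSE]),
                     rec$time[te], rec$event[te], type = "risk")
  else NA_real_
  cutoffs <- list()
  km <- list()
  for (v in sel) {
    co <- tryCatch(optimalCutoff(X[tr, v], rec$time[tr], rec$event[tr]),
                   error = function(e) NULL)
    if (is.null(co)) next
    cutoffs[[v]] <- list(threshold = co@threshold, statistic = co@statistic,
                         p = co@pValue, nLow = co@nLow, nHigh = co@nHigh)
    lo <- X[tr, v] <= co@threshold
    kmc <- function(keep) {
      s <- kaplanMeier(rec$time[tr][keep], rec$event[tr][keep])
      data.frame(time = s@times, surv = s@surv)
    }
    km[[v]] <- list(low = kmc(lo), high = kmc(!lo))
  }
  list(outcome = outcome, selected = sel,
       hazardRatios = as.list(hazardRatios(fit)[sel]),
       pValues = as.list(fit@pValues[sel]),
       cIndex = ci, cutoffs = cutoffs, km = km)
}

#' Run the full deep-radiomics survival pipeline
#'
#' For every requested outcome: preprocess the cohort, train the CT and PET
#' risk branches on the training cases, run backward stepwise Cox selection
#' over \{CT risk, PET risk, age, gender, SUV, dose\} (deep mode), the
#' 18 principal components + clinical factors (handcrafted mode), or the
#' concatenation of both predictor sets (both mode), and report selected
#' predictors with hazard ratios and p-values, the test-set concordance
#' index (NA when nothing is selected), maximally selected cut-offs and
#' Kaplan-Meier step functions of each selected predictor, and an optional
#' random-survival-forest pass.
#'
#' @param cohort a \code{\link{TumorCohort}}
#' @param config a \code{\link{runConfig}}
#' @param caeCohort optional disjoint \code{TumorCohort} for CAE
#'   pre-training
#' @return a report list (JSON-serializable via
#'   \code{\link{writeReportJson}}) with one entry per outcome
#' @export
runPipeline <- function(cohort, config = runConfig(), caeCohort = NULL) {
  cl <- clinicalData(cohort)
  split <- splitTrainTest(cl$case_id, config$split_fraction, seed = config$seed)
  deep <- NULL
  feats <- NULL
  reports <- list()
  for (oc in config$outcomes) {
    X <- data.frame(row.names = cl$case_id)
    if (config$mode %in% c("deep", "both")) {
      deep <- .deepRisks(cohort, split, config, caeCohort, outcome = oc)
      X$ct_risk <- deep$ct_risk
      X$pet_risk <- deep$pet_risk
    }
    if (config$mode %in% c("handcrafted", "both")) {
      if (is.null(feats)) feats <- extractFeatures(cohort)
      pca <- fitPca(feats[split$train, , drop = FALSE], config$n_components)
      X <- cbind(X, as.data.frame(applyPca(pca, feats)))
    }
    X$age <- cl$age; X$gender <- cl$gender; X$suv <- cl$suv_max; X$dose <- cl$dose
    rep1 <- .armReport(cohort, oc, split, X, config$alpha)
    if (!is.null(config$rsf)) {
      rec <- .caseRecords(cohort, oc)
      tr <- match(split$train, cl$case_id)
      te <- match(split$test, cl$case_id)
      rsfX <- X
      forest <- fitSurvivalForest(rsfX[tr, , drop = FALSE], rec$time[tr],
                                  rec$event[tr], config$rsf)
      horizon <- max(rec$time[tr][rec$event[tr] == 1])
      rs <- riskScore(forest, rsfX[te, , drop = FALSE], horizon)
      rep1$rsf <- list(cIndex = concordanceIndex(rs, rec$time[te], rec$event[te],
                                                 type = "risk"),
                       vimp = as.list(vimp(forest, seed = config$seed)),
                       oobError = oobError(forest))
    }
    reports[[oc]] <- rep1
  }
  list(config = config[setdiff(names(config), "rsf")],
       split = split, outcomes = reports)
}

#' Compare the deep and hand-crafted arms by concordance index
#'
#' @param reportDeep,reportHand reports from \code{\link{runPipeline}} run
#'   on the same cohort and split with mode "deep" and "handcrafted"
#' @return data.frame with per-outcome c-index pairs and their difference
#'   (NA propagates)
#' @export
compareArms <- function(reportDeep, reportHand) {
  od <- names(reportDeep$outcomes)
  oh <- names(reportHand$outcomes)
  if (!identical(od, oh)) stop("reports cover different outcomes")
  ci <- function(rep, oc) {
    v <- rep$outcomes[[oc]]$cIndex
    if (is.null(v)) NA_real_ else v
  }
  d <- vapply(od, ci, numeric(1), rep = reportDeep)
  h <- vapply(od, ci, numeric(1), rep = reportHand)
  data.frame(outcome = od, cIndex_deep = d, cIndex_handcrafted = h,
             difference = d - h, row.names = NULL)
}

#' Serialize a pipeline report to JSON
#'
#' @param report result of \code{\link{runPipeline}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeReportJson <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
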