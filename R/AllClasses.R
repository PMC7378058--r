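#' @useDynLib DeepRadSurv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rexp rbinom sd quantile cor prcomp pchisq
#'   median rlnorm setNames var
NULL

#' TumorCohort: paired CT/PET tumor patches with clinical and survival data
#'
#' Central container for a (synthetic or real) cohort. Each case carries one
#' or more tumors; a tumor is a pair of co-registered 3-slice image stacks
#' (CT and PET) with binary ROI masks and a per-tumor SUV. Clinical
#' covariates (age, gender, SUVmax, radiation dose) live in a per-case table,
#' and each time-to-event endpoint (OS, RFS, DC, LC) has its own record
#' table. OS/RFS/DC records are per case; LC records are per tumor.
#'
#' @slot cases list; one element per case with fields \code{case_id},
#'   \code{tumors} (list of \code{ct}, \code{pet} arrays side x side x 3,
#'   \code{ct_mask}, \code{pet_mask} matrices, \code{suv}) and
#'   \code{latent_risk} (hidden ground-truth log-hazard contribution, kept
#'   for validation only).
#' @slot clinical data.frame with columns case_id, age, gender, suv_max, dose.
#' @slot survival named list of data.frames (one per outcome) with columns
#'   case_id, (tumor_id for LC), time, event.
#' @export
setClass("TumorCohort",
  slots = c(cases = "list", clinical = "data.frame", survival = "list"))

setValidity("TumorCohort", function(object) {
  msg <- character()
  if (length(object@cases) < 1L) msg <- c(msg, "cohort must contain at least one case")
  need <- c("case_id", "age", "gender", "suv_max", "dose")
  if (!all(need %in% names(object@clinical)))
    msg <- c(msg, paste("clinical table must contain:", paste(need, collapse = ", ")))
  if (nrow(object@clinical) != length(object@cases))
    msg <- c(msg, "clinical table must have one row per case")
  for (cs in object@cases) {
    if (length(cs$tumors) < 1L) { msg <- c(msg, "every case needs >= 1 tumor"); break }
    suvs <- vapply(cs$tumors, `[[`, numeric(1), "suv")
    sm <- object@clinical$suv_max[object@clinical$case_id == cs$case_id]
    if (abs(sm - max(suvs)) > 1e-8) { msg <- c(msg, "suv_max must equal max per-tumor SUV"); break }
    for (tm in cs$tumors) {
      if (sum(tm$ct_mask) < 1 || sum(tm$pet_mask) < 1) { msg <- c(msg, "ROI masks must be nonempty"); break }
    }
  }
  for (nm in names(object@survival)) {
    rec <- object@survival[[nm]]
    if (any(rec$time <= 0)) msg <- c(msg, sprintf("%s: times must be > 0", nm))
    if (!all(rec$event %in% c(0, 1))) msg <- c(msg, sprintf("%s: event must be 0/1", nm))
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TumorCohort compact summary
#' @param object a \code{TumorCohort}
#' @export
setMethod("show", "TumorCohort", function(object) {
  nt <- sum(vapply(object@cases, function(cs) length(cs$tumors), integer(1)))
  cat(sprintf("TumorCohort: %d cases, %d tumors\n", length(object@cases), nt))
  cat("  outcomes:", paste(names(object@survival), collapse = ", "), "\n")
  ev <- vapply(object@survival, function(r) mean(r$event), numeric(1))
  cat("  event fractions:", paste(sprintf("%s=%.2f", names(ev), ev), collapse = " "), "\n")
})

#' HazardCurve: Nelson-Aalen cumulative hazard estimate
#'
#' Step function \eqn{\hat H(t) = \sum_{t_l \le t} d_l / Y_l} over the
#' distinct observed event times, together with the at-risk and death counts
#' that define each increment.
#'
#' @slot times ordered distinct event times
#' @slot chf cumulative hazard at each event time (non-decreasing; 0 before
#'   the first event)
#' @slot atRisk number at risk at each event time
#' @slot deaths number of events at each event time
#' @export
setClass("HazardCurve",
  slots = c(times = "numeric", chf = "numeric", atRisk = "numeric", deaths = "numeric"))

setValidity("HazardCurve", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE) && length(object@times) > 1)
    msg <- c(msg, "times must be strictly increasing")
  if (any(diff(c(0, object@chf)) < -1e-12)) msg <- c(msg, "chf must be non-decreasing")
  if (length(unique(c(length(object@times), length(object@chf),
                      length(object@atRisk), length(object@deaths)))) != 1)
    msg <- c(msg, "slot lengths must agree")
  if (length(msg)) msg else TRUE
})

#' @describeIn HazardCurve compact summary
#' @param object a \code{HazardCurve}
#' @export
setMethod("show", "HazardCurve", function(object) {
  cat(sprintf("HazardCurve: %d event times, H(max) = %.4f\n",
              length(object@times), if (length(object@chf)) max(object@chf) else 0))
})

#' SurvivalCurve: Kaplan-Meier product-limit estimate
#'
#' @slot times ordered distinct event times
#' @slot surv survival probability S(t) at each event time (S(0) = 1,
#'   non-increasing, in [0, 1])
#' @slot atRisk number at risk at each event time
#' @slot deaths number of events at each event time
#' @export
setClass("SurvivalCurve",
  slots = c(times = "numeric", surv = "numeric", atRisk = "numeric", deaths = "numeric"))

setValidity("SurvivalCurve", function(object) {
  msg <- character()
  if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12)) msg <- c(msg, "S(t) must lie in [0,1]")
  if (any(diff(c(1, object@surv)) > 1e-12)) msg <- c(msg, "S(t) must be non-increasing from S(0)=1")
  if (length(msg)) msg else TRUE
})

#' @describeIn SurvivalCurve compact summary
#' @param object a \code{SurvivalCurve}
#' @export
setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve: %d event times, S(max) = %.4f\n",
              length(object@times), if (length(object@surv)) min(object@surv) else 1))
})

#' CoxModelFit: fitted Cox proportional-hazards model
#'
#' Result of \code{\link{fitCoxModel}} or \code{\link{stepwiseSelect}}.
#' Hazard ratios are \code{exp(coefficients)}; p-values come from
#' likelihood-ratio tests of the model against the model with the covariate
#' removed (the restricted-vs-unrestricted comparison).
#'
#' @slot coefficients named log-hazard coefficients of the retained covariates
#' @slot hazardRatios exp(coefficients)
#' @slot pValues per-covariate nested likelihood-ratio p-values
#' @slot selected names of retained covariates (may be empty after stepwise
#'   elimination)
#' @slot logLik maximized partial log-likelihood
#' @slot fit the underlying \code{survival::coxph} object (NULL when the
#'   selection is empty)
#' @export
setClass("CoxModelFit",
  slots = c(coefficients = "numeric", hazardRatios = "numeric",
            pValues = "numeric", selected = "character",
            logLik = "numeric", fit = "ANY"))

setValidity("CoxModelFit", function(object) {
  msg <- character()
  if (length(object@coefficients) &&
      max(abs(object@hazardRatios - exp(object@coefficients))) > 1e-8)
    msg <- c(msg, "hazardRatios must equal exp(coefficients)")
  if (!all(object@selected %in% names(object@coefficients)) &&
      length(object@coefficients))
    msg <- c(msg, "selected must be a subset of the coefficient names")
  if (length(msg)) msg else TRUE
})

#' @describeIn CoxModelFit compact summary
#' @param object a \code{CoxModelFit}
#' @export
setMethod("show", "CoxModelFit", function(object) {
  if (!length(object@selected)) {
    cat("CoxModelFit: no significant predictors\n")
    return(invisible(NULL))
  }
  cat("CoxModelFit:\n")
  for (v in object@selected)
    cat(sprintf("  %s  HR = %.3f  p = %.4g\n", v, object@hazardRatios[v], object@pValues[v]))
})

#' CutoffResult: maximally selected logrank cut-off
#'
#' @slot threshold the covariate value splitting low/high-risk groups
#' @slot statistic the (maximal) logrank chi-square
#' @slot pValue uncorrected 1-df p-value of the maximal statistic (no
#'   multiplicity adjustment is applied; see the methods vignette)
#' @slot nLow,nHigh group sizes at the chosen threshold
#' @export
setClass("CutoffResult",
  slots = c(threshold = "numeric", statistic = "numeric", pValue = "numeric",
            nLow = "integer", nHigh = "integer"))

#' @describeIn CutoffResult compact summary
#' @param object a \code{CutoffResult}
#' @export
setMethod("show", "CutoffResult", function(object) {
  cat(sprintf("CutoffResult: threshold %.4g (chi-square %.3f, p = %.4g; %d low / %d high)\n",
              object@threshold, object@statistic, object@pValue, object@nLow, object@nHigh))
})

#' RiskNet: convolutional survival risk network
#'
#' A small CNN (conv 3x3/32 - pool 2x2 - conv 3x3/32 - pool 2x2 - FC 32 -
#' FC 1 linear) mapping a 3-channel tumor patch to a scalar log-risk, trained
#' by stochastic gradient descent on the negative Cox partial likelihood.
#'
#' @slot spec hyperparameter list (see \code{\link{riskNetSpec}})
#' @slot params list of weight matrices/vectors (W1,b1,W2,b2,W3,b3,W4,b4)
#' @slot trained logical
#' @slot modality "CT" or "PET"
#' @slot history per-epoch mean training loss
#' @export
setClass("RiskNet",
  slots = c(spec = "list", params = "list", trained = "logical",
            modality = "character", history = "numeric"))

#' @describeIn RiskNet compact summary
#' @param object a \code{RiskNet}
#' @export
setMethod("show", "RiskNet", function(object) {
  cat(sprintf("RiskNet (%s): input %dx%dx3, %s\n", object@modality,
              object@spec$input_side, object@spec$input_side,
              if (object@trained) sprintf("trained %d epochs (final loss %.4f)",
                                          length(object@history), utils::tail(object@history, 1))
              else "untrained"))
})

#' SurvivalForest: random survival forest
#'
#' Ensemble of survival trees grown on bootstrap samples with logrank
#' splitting; each terminal node stores the Nelson-Aalen cumulative hazard of
#' its in-bag members. Prediction averages per-tree terminal CHFs on the
#' union grid of in-bag event times.
#'
#' @slot trees list of tree structures (node tables)
#' @slot spec hyperparameters (see \code{\link{forestSpec}})
#' @slot varNames covariate names used at fit time
#' @slot inbag list of in-bag index vectors, one per tree
#' @slot grid sorted distinct event times used for ensemble evaluation
#' @slot trainX training covariate matrix (kept for OOB error / VIMP)
#' @slot trainTime,trainEvent training outcomes
#' @export
setClass("SurvivalForest",
  slots = c(trees = "list", spec = "list", varNames = "character",
            inbag = "list", grid = "numeric", trainX = "matrix",
            trainTime = "numeric", trainEvent = "numeric"))

#' @describeIn SurvivalForest compact summary
#' @param object a \code{SurvivalForest}
#' @export
setMethod("show", "SurvivalForest", function(object) {
  cat(sprintf("SurvivalForest: %d trees, %d covariates, %d training cases\n",
              length(object@trees), length(object@varNames), nrow(object@trainX)))
})
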