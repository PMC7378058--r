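#' Number of cases in a cohort
#' @param object a \code{TumorCohort}
#' @return integer count of cases
#' @export
setGeneric("nCases", function(object) standardGeneric("nCases"))

#' @rdname nCases
#' @export
setMethod("nCases", "TumorCohort", function(object) length(object@cases))

#' Clinical covariate table of a cohort
#' @param object a \code{TumorCohort}
#' @return data.frame with case_id, age, gender, suv_max, dose
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))

#' @rdname clinicalData
#' @export
setMethod("clinicalData", "TumorCohort", function(object) object@clinical)

#' Survival records of a cohort for one outcome
#' @param object a \code{TumorCohort}
#' @param outcome one of "OS", "RFS", "DC", "LC"
#' @return data.frame with case_id (tumor_id for LC), time, event
#' @export
setGeneric("survivalRecords", function(object, outcome = "OS") standardGeneric("survivalRecords"))

#' @rdname survivalRecords
#' @export
setMethod("survivalRecords", "TumorCohort", function(object, outcome = "OS") {
  outcome <- match.arg(outcome, names(object@survival))
  object@survival[[outcome]]
})

#' Case list of a cohort
#' @param object a \code{TumorCohort}
#' @return list of case structures
#' @export
setGeneric("cohortCases", function(object) standardGeneric("cohortCases"))

#' @rdname cohortCases
#' @export
setMethod("cohortCases", "TumorCohort", function(object) object@cases)

#' Hidden ground-truth latent risk of each case
#'
#' Available only for synthetic cohorts; intended for validation of the
#' downstream estimators, never as a model input.
#' @param object a \code{TumorCohort}
#' @return named numeric vector, one value per case
#' @export
setGeneric("latentRisk", function(object) standardGeneric("latentRisk"))

#' @rdname latentRisk
#' @export
setMethod("latentRisk", "TumorCohort", function(object) {
  setNames(vapply(object@cases, function(cs) cs$latent_risk, numeric(1)),
           vapply(object@cases, function(cs) as.character(cs$case_id), character(1)))
})

#' Evaluate a hazard or survival curve at arbitrary times
#'
#' Right-continuous step-function evaluation: a \code{HazardCurve} is 0
#' before its first event time; a \code{SurvivalCurve} is 1 before its first
#' event time.
#' @param object a \code{HazardCurve} or \code{SurvivalCurve}
#' @param t numeric vector of evaluation times
#' @return numeric vector of curve values at \code{t}
#' @export
setGeneric("curveAt", function(object, t) standardGeneric("curveAt"))

#' @rdname curveAt
#' @export
setMethod("curveAt", "HazardCurve", function(object, t) {
  .stepEval(object@times, object@chf, t, before = 0)
})

#' @rdname curveAt
#' @export
setMethod("curveAt", "SurvivalCurve", function(object, t) {
  .stepEval(object@times, object@surv, t, before = 1)
})

.stepEval <- function(times, values, t, before) {
  idx <- findInterval(t, times)
  out <- c(before, values)[idx + 1L]
  out
}

#' Selected covariates of a fitted Cox model
#' @param object a \code{CoxModelFit}
#' @return character vector (possibly empty)
#' @export
setGeneric("selectedCovariates", function(object) standardGeneric("selectedCovariates"))

#' @rdname selectedCovariates
#' @export
setMethod("selectedCovariates", "CoxModelFit", function(object) object@selected)

#' Hazard ratios of a fitted Cox model
#' @param object a \code{CoxModelFit}
#' @return named numeric vector exp(beta)
#' @export
setGeneric("hazardRatios", function(object) standardGeneric("hazardRatios"))

#' @rdname hazardRatios
#' @export
setMethod("hazardRatios", "CoxModelFit", function(object) object@hazardRatios)
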