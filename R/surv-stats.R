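## Statistical core: Cox partial likelihood, stepwise PHM, concordance,
## Kaplan-Meier, Nelson-Aalen, logrank, maximally selected cut-offs.

.checkRecords <- function(time, event) {
  if (length(time) != length(event)) stop("time and event must have equal length")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be positive and finite")
  if (!all(event %in% c(0, 1))) stop("event must be a 0/1 indicator")
}

#' Cox partial log-likelihood
#'
#' Computes \eqn{\sum_{i:\delta_i=1} [\eta_i - \log \sum_{j: T_j \ge T_i}
#' e^{\eta_j}]} for per-subject linear predictors \eqn{\eta}. Tied event
#' times are handled with the Breslow convention (each tied event uses the
#' full risk set at that time). The log-sum-exp is stabilized by centering.
#'
#' @param risks numeric vector of linear predictors, one per subject
#' @param time positive event/censoring times
#' @param event 0/1 event indicator (1 = event observed)
#' @return the partial log-likelihood (scalar)
#' @examples
#' # two subjects with equal risk, one event at the earlier time: log(1/2)
#' coxPartialLoglik(c(0, 0), c(1, 2), c(1, 0))
#' @export
coxPartialLoglik <- function(risks, time, event) {
  .checkRecords(time, event)
  if (length(risks) != length(time)) stop("risks and records must be aligned")
  if (sum(event) < 1) stop("partial likelihood undefined with zero events")
  m <- max(risks)
  ll <- sum(risks[event == 1])
  for (tl in unique(time[event == 1])) {
    atRisk <- time >= tl
    dl <- sum(event == 1 & time == tl)
    ll <- ll - dl * (m + log(sum(exp(risks[atRisk] - m))))
  }
  ll
}

#' Gradient of the Cox partial log-likelihood with respect to the risks
#'
#' @inheritParams coxPartialLoglik
#' @return numeric vector, same length as \code{risks}
#' @export
coxPartialLoglikGradient <- function(risks, time, event) {
  .checkRecords(time, event)
  if (sum(event) < 1) stop("partial likelihood undefined with zero events")
  g <- as.numeric(event)
  m <- max(risks)
  w <- exp(risks - m)
  for (tl in unique(time[event == 1])) {
    atRisk <- time >= tl
    dl <- sum(event == 1 & time == tl)
    g[atRisk] <- g[atRisk] - dl * w[atRisk] / sum(w[atRisk])
  }
  g
}

.lrtPValue <- function(llFull, llRestricted, df = 1) {
  stat <- 2 * (llFull - llRestricted)
  pchisq(max(stat, 0), df = df, lower.tail = FALSE)
}

.coxphFit <- function(X, time, event) {
  df <- data.frame(X, check.names = FALSE)
  df$.time <- time
  df$.event <- event
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(X)), collapse = " + ")))
  fit <- survival::coxph(fml, data = df,
                         control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  ## separation/divergence: flag per-SD effects beyond exp(+-50), which no
  ## finite maximum produces (the raw coefficient scale depends on the
  ## covariate units, so the check is scale-aware)
  sdX <- vapply(X, function(col) stats::sd(as.numeric(col)), numeric(1))
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) * sdX > 50))
    stop("Cox model did not converge (possible separation)")
  fit
}

#' Fit a Cox proportional-hazards model
#'
#' Fits \eqn{h(t|x) = h_0(t) \exp(\beta^T x)} by partial-likelihood
#' maximization (Newton-Raphson via \code{survival::coxph}). Per-covariate
#' p-values are likelihood-ratio chi-square tests comparing the full
#' (unrestricted) model against the model with that covariate removed
#' (restricted model), 1 degree of freedom each.
#'
#' @param X data.frame of covariates (no constant columns)
#' @param time positive event/censoring times
#' @param event 0/1 event indicator
#' @return a \code{\link{CoxModelFit}}
#' @export
fitCoxModel <- function(X, time, event) {
  .checkRecords(time, event)
  X <- as.data.frame(X)
  if (ncol(X) < 1) stop("at least one covariate required")
  if (nrow(X) <= ncol(X)) stop("need more subjects than covariates")
  cv <- vapply(X, function(col) stats::var(as.numeric(col)), numeric(1))
  if (any(cv == 0)) stop("constant covariate: ", paste(names(X)[cv == 0], collapse = ", "))
  fit <- .coxphFit(X, time, event)
  beta <- stats::coef(fit)
  llFull <- fit$loglik[2]
  pv <- vapply(names(X), function(v) {
    if (ncol(X) == 1L) {
      .lrtPValue(llFull, fit$loglik[1])
    } else {
      red <- .coxphFit(X[setdiff(names(X), v)], time, event)
      .lrtPValue(llFull, red$loglik[2])
    }
  }, numeric(1))
  new("CoxModelFit", coefficients = beta, hazardRatios = exp(beta),
      pValues = pv, selected = names(X), logLik = llFull, fit = fit)
}

#' Backward stepwise covariate selection for the Cox model
#'
#' Starting from the full model, repeatedly removes the covariate whose
#' nested likelihood-ratio test has the largest p-value at or above
#' \code{alpha}, refitting after each removal, until every remaining
#' covariate is significant at \code{alpha}. When no covariate survives, an
#' empty \code{CoxModelFit} is returned and downstream concordance indices
#' are reported as NA.
#'
#' @inheritParams fitCoxModel
#' @param alpha significance level for retention (default 0.05)
#' @return a \code{\link{CoxModelFit}} whose \code{selected} slot holds the
#'   retained covariates (possibly none)
#' @export
stepwiseSelect <- function(X, time, event, alpha = 0.05) {
  X <- as.data.frame(X)
  if (ncol(X) < 1) stop("at least one covariate required")
  vars <- names(X)
  repeat {
    if (!length(vars))
      return(new("CoxModelFit", coefficients = numeric(0), hazardRatios = numeric(0),
                 pValues = numeric(0), selected = character(0),
                 logLik = NA_real_, fit = NULL))
    fit <- fitCoxModel(X[vars], time, event)
    pv <- fit@pValues
    if (max(pv) >= alpha) {
      vars <- vars[-which.max(pv)]
    } else {
      return(fit)
    }
  }
}

#' Linear predictor of a fitted Cox model on new data
#'
#' @param fit a \code{\link{CoxModelFit}}
#' @param newX data.frame containing at least the selected covariates
#' @return numeric risk scores (NA vector when the selection is empty)
#' @export
coxLinearPredictor <- function(fit, newX) {
  if (!length(fit@selected)) return(rep(NA_real_, nrow(newX)))
  as.numeric(as.matrix(newX[fit@selected]) %*% fit@coefficients[fit@selected])
}

#' Concordance index (c-index)
#'
#' Fraction of permissible ordered pairs whose predicted ordering agrees
#' with the observed event-time ordering. A pair (i, j) is permissible when
#' subject i's event is observed and \eqn{T_j > T_i}. With
#' \code{type = "time"}, agreement means the predicted time of i is smaller
#' than that of j; with \code{type = "risk"}, higher risk stands for earlier
#' predicted time (internal sign flip). \code{tiePolicy = "half"} (the
#' Harrell convention, default) credits tied predictions 1/2 so that a
#' constant predictor scores 0.5; \code{tiePolicy = "strict"} awards ties 0.
#'
#' @param predictions per-subject predicted times or risk scores
#' @param time positive event/censoring times
#' @param event 0/1 event indicator
#' @param tiePolicy "half" or "strict"
#' @param type "risk" (default) or "time"
#' @return the c-index in [0, 1]
#' @export
concordanceIndex <- function(predictions, time, event,
                             tiePolicy = c("half", "strict"),
                             type = c("risk", "time")) {
  tiePolicy <- match.arg(tiePolicy)
  type <- match.arg(type)
  .checkRecords(time, event)
  if (length(predictions) != length(time)) stop("predictions and records must be aligned")
  if (any(!is.finite(predictions))) stop("predictions must be finite")
  f <- if (type == "risk") -predictions else predictions
  num <- 0; den <- 0
  for (i in which(event == 1)) {
    js <- time > time[i]
    den <- den + sum(js)
    num <- num + sum(f[i] < f[js])
    if (tiePolicy == "half") num <- num + 0.5 * sum(f[i] == f[js])
  }
  if (den == 0) stop("no permissible pairs (need an observed event with a later time)")
  num / den
}

#' Kaplan-Meier product-limit survival estimate
#'
#' Wraps \code{survival::survfit} and reports the curve at the distinct
#' event times: \eqn{S(t) = \prod_{t_l \le t} (1 - d_l/Y_l)}.
#'
#' @inheritParams coxPartialLoglik
#' @return a \code{\link{SurvivalCurve}}
#' @export
kaplanMeier <- function(time, event) {
  .checkRecords(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- sf$n.event > 0
  new("SurvivalCurve", times = sf$time[keep], surv = sf$surv[keep],
      atRisk = sf$n.risk[keep], deaths = sf$n.event[keep])
}

#' Nelson-Aalen cumulative hazard estimate
#'
#' \eqn{\hat H(t) = \sum_{t_l \le t} d_l / Y_l} over distinct event times
#' \eqn{t_l}, with \eqn{d_l} events and \eqn{Y_l} subjects at risk at
#' \eqn{t_l}. Zero before the first event; identically zero when no events
#' are observed.
#'
#' @inheritParams coxPartialLoglik
#' @return a \code{\link{HazardCurve}}
#' @export
nelsonAalen <- function(time, event) {
  .checkRecords(time, event)
  tl <- sort(unique(time[event == 1]))
  if (!length(tl))
    return(new("HazardCurve", times = numeric(0), chf = numeric(0),
               atRisk = numeric(0), deaths = numeric(0)))
  d <- vapply(tl, function(t0) sum(time == t0 & event == 1), numeric(1))
  y <- vapply(tl, function(t0) sum(time >= t0), numeric(1))
  new("HazardCurve", times = tl, chf = cumsum(d / y), atRisk = y, deaths = d)
}

#' Two-group logrank test
#'
#' Standard 1-df logrank chi-square comparing the survival distributions of
#' two groups (via \code{survival::survdiff}).
#'
#' @param time1,event1 records of group 1
#' @param time2,event2 records of group 2
#' @return list with elements \code{statistic} and \code{p}
#' @export
logrankTest <- function(time1, event1, time2, event2) {
  .checkRecords(time1, event1)
  .checkRecords(time2, event2)
  if (!length(time1) || !length(time2)) stop("both groups must be nonempty")
  if (sum(event1) + sum(event2) < 1) stop("need at least one event")
  d <- data.frame(time = c(time1, time2), event = c(event1, event2),
                  g = rep(1:2, c(length(time1), length(time2))))
  sdf <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  list(statistic = as.numeric(sdf$chisq),
       p = pchisq(as.numeric(sdf$chisq), df = 1, lower.tail = FALSE))
}

## Logrank chi-square for every admissible split "x <= threshold", computed
## in one sweep (used by optimalCutoff and by the survival-forest splitter).
## Returns a data.frame(threshold, statistic, nLeft) -- possibly empty.
.logrankSweep <- function(x, time, event, minLeft = 1L, minRight = 1L) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; ts <- time[ord]; es <- event[ord]
  tl <- sort(unique(ts[es == 1]))
  if (!length(tl)) return(data.frame(threshold = numeric(0), statistic = numeric(0),
                                     nLeft = integer(0)))
  K <- length(tl)
  ## K x n indicator matrices, cumulated over the sorted-x axis
  atRisk <- outer(tl, ts, `<=`)                      # Y contribution
  death <- outer(tl, ts, `==`) & matrix(es == 1, K, n, byrow = TRUE)
  Y1 <- t(apply(atRisk, 1, cumsum))                  # K x n: group "x <= xs[j]"
  D1 <- t(apply(death, 1, cumsum))
  Yk <- Y1[, n]; Dk <- D1[, n]
  ## candidate cut positions: after j where xs[j] < xs[j+1]
  js <- which(diff(xs) > 0)
  js <- js[js >= minLeft & (n - js) >= minRight]
  if (!length(js)) return(data.frame(threshold = numeric(0), statistic = numeric(0),
                                     nLeft = integer(0)))
  stats <- vapply(js, function(j) {
    y1 <- Y1[, j]; d1 <- D1[, j]
    U <- sum(d1 - Dk * y1 / Yk)
    V <- sum(ifelse(Yk > 1,
                    Dk * (y1 / Yk) * (1 - y1 / Yk) * (Yk - Dk) / (Yk - 1), 0))
    if (V <= 0) 0 else U^2 / V
  }, numeric(1))
  data.frame(threshold = (xs[js] + xs[js + 1]) / 2, statistic = stats, nLeft = js)
}

#' Maximally selected logrank cut-off
#'
#' Scans the midpoints between consecutive sorted unique covariate values
#' whose induced low/high groups both contain at least
#' \code{minGroupFraction} of the subjects, and returns the threshold
#' maximizing the logrank chi-square. The reported p-value is the
#' uncorrected 1-df tail probability of the maximal statistic; because the
#' threshold is chosen to maximize the statistic, this p-value is
#' optimistic (no multiplicity correction is applied).
#'
#' @param values non-constant numeric covariate
#' @inheritParams coxPartialLoglik
#' @param minGroupFraction minimum fraction of subjects in each group
#' @return a \code{\link{CutoffResult}}
#' @export
optimalCutoff <- function(values, time, event, minGroupFraction = 0.1) {
  .checkRecords(time, event)
  if (length(values) != length(time)) stop("values and records must be aligned")
  if (length(unique(values)) < 2) stop("covariate is constant; no cut-off exists")
  n <- length(values)
  minSize <- max(1L, ceiling(minGroupFraction * n))
  sweep <- .logrankSweep(values, time, event, minLeft = minSize, minRight = minSize)
  if (!nrow(sweep)) stop("no admissible threshold satisfies the group-size constraint")
  best <- which.max(sweep$statistic)
  new("CutoffResult", threshold = sweep$threshold[best],
      statistic = sweep$statistic[best],
      pValue = pchisq(sweep$statistic[best], df = 1, lower.tail = FALSE),
      nLow = as.integer(sweep$nLeft[best]),
      nHigh = as.integer(n - sweep$nLeft[best]))
}
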