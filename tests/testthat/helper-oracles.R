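## Independent brute-force oracles used across the suite. These deliberately
## re-derive each quantity from first principles (scalar loops, explicit
## risk-set enumeration) so they share no code with the implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

## concordance by exhaustive scalar enumeration of ordered pairs; f = values
## interpreted as predicted times (smaller = earlier)
cIndexOracle <- function(f, time, event, tiePolicy = "half") {
  num <- 0; den <- 0
  n <- length(f)
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (time[j] <= time[i]) next
      den <- den + 1
      if (f[i] < f[j]) num <- num + 1
      else if (f[i] == f[j] && tiePolicy == "half") num <- num + 0.5
    }
  }
  num / den
}

## Cox partial log-likelihood by explicit risk-set enumeration, one event
## term at a time (Breslow handling of ties)
coxLoglikOracle <- function(eta, time, event) {
  ll <- 0
  for (i in seq_along(eta)) {
    if (event[i] != 1) next
    rs <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[rs])))
  }
  ll
}

## Nelson-Aalen by explicit per-time counting
naOracle <- function(time, event) {
  tl <- sort(unique(time[event == 1]))
  chf <- numeric(length(tl))
  acc <- 0
  for (k in seq_along(tl)) {
    d <- sum(time == tl[k] & event == 1)
    y <- sum(time >= tl[k])
    acc <- acc + d / y
    chf[k] <- acc
  }
  list(times = tl, chf = chf)
}

## two-group logrank chi-square from the textbook O-E / V sums
logrankOracle <- function(time1, event1, time2, event2) {
  time <- c(time1, time2); event <- c(event1, event2)
  g1 <- c(rep(TRUE, length(time1)), rep(FALSE, length(time2)))
  tl <- sort(unique(time[event == 1]))
  U <- 0; V <- 0
  for (t0 in tl) {
    y <- sum(time >= t0); y1 <- sum(time >= t0 & g1)
    d <- sum(time == t0 & event == 1)
    d1 <- sum(time == t0 & event == 1 & g1)
    U <- U + d1 - d * y1 / y
    if (y > 1) V <- V + d * (y1 / y) * (1 - y1 / y) * (y - d) / (y - 1)
  }
  U^2 / V
}

## small synthetic cohort with fast (tiny-canvas) images for pipeline tests
tinyCohort <- function(n = 30, seed = 1, beta_image = 1, canvasCt = 16, canvasPet = 8) {
  generateCohort(cohortSpec(
    n_cases = n, canvas_ct = canvasCt, canvas_pet = canvasPet,
    beta_image = beta_image,
    beta_clinical = c(age = 0, gender = 0, suv = 0, dose = 0),
    seed = seed))
}

## proportional-hazards survival data with a single planted predictor
phData <- function(n, beta, seed, censorRate = 0.3, binary = FALSE) {
  set.seed(seed)
  x <- if (binary) rbinom(n, 1, 0.5) else rnorm(n)
  t0 <- rexp(n, rate = 0.1 * exp(beta * x))
  cens <- rexp(n, rate = censorRate * 0.1)
  list(x = x, time = pmax(pmin(t0, cens), 1e-8), event = as.numeric(t0 <= cens))
}
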