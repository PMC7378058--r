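test_that("Cox partial log-likelihood matches closed forms and enumeration", {
  # symmetric risk set: two subjects, equal risk, event at the earlier time
  expect_equal(coxPartialLoglik(c(0, 0), c(1, 2), c(1, 0)), log(1 / 2))
  # all eta = 0, n distinct event times, no censoring: -log(n!)
  for (n in c(3, 6, 9))
    expect_equal(coxPartialLoglik(rep(0, n), seq_len(n), rep(1, n)), -sum(log(seq_len(n))))
  # mixed censoring against explicit risk-set enumeration
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    eta <- rnorm(n)
    time <- round(rexp(n) + 0.1, 2)   # rounding provokes occasional ties
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    expect_equal(coxPartialLoglik(eta, time, event),
                 coxLoglikOracle(eta, time, event))
  }
  expect_error(coxPartialLoglik(c(0, 0), c(1, 2), c(0, 0)), "zero events")
})

test_that("partial-likelihood gradient matches central finite differences", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 12
    eta <- rnorm(n)
    time <- rexp(n) + 0.1
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) event[2] <- 1
    g <- coxPartialLoglikGradient(eta, time, event)
    h <- 1e-6
    fd <- vapply(seq_len(n), function(i) {
      ep <- em <- eta
      ep[i] <- ep[i] + h; em[i] <- em[i] - h
      (coxPartialLoglik(ep, time, event) - coxPartialLoglik(em, time, event)) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("fitCoxModel recovers a planted coefficient and reports HR = exp(beta)", {
  d <- phData(500, beta = log(2), seed = 1, binary = TRUE)
  fit <- fitCoxModel(data.frame(x = d$x), d$time, d$event)
  se <- sqrt(diag(vcov(fit@fit)))
  expect_lt(abs(fit@coefficients[["x"]] - log(2)), 3 * se)
  expect_identical(fit@hazardRatios, exp(fit@coefficients))
  expect_lt(fit@pValues[["x"]], 0.05)
  # agrees with coxph run directly
  direct <- survival::coxph(survival::Surv(d$time, d$event) ~ x,
                            data = data.frame(x = d$x))
  expect_equal(unname(fit@coefficients), unname(coef(direct)), tolerance = 1e-6)
})

test_that("fitCoxModel rejects degenerate inputs", {
  d <- phData(50, beta = 0, seed = 2)
  expect_error(fitCoxModel(data.frame(x = rep(1, 50)), d$time, d$event), "constant")
  expect_error(fitCoxModel(data.frame(x = d$x), d$time, rep(0, 50)))
})

test_that("backward stepwise selection keeps signal, drops noise, and never returns p >= alpha", {
  set.seed(11)
  keptStrong <- 0
  for (s in 1:8) {
    d <- phData(400, beta = 1, seed = 100 + s)
    X <- data.frame(strong = d$x, n1 = rnorm(400), n2 = rnorm(400), n3 = rnorm(400))
    fit <- stepwiseSelect(X, d$time, d$event, alpha = 0.05)
    if ("strong" %in% fit@selected) keptStrong <- keptStrong + 1
    if (length(fit@selected)) expect_true(all(fit@pValues < 0.05))
  }
  expect_gte(keptStrong, 7)
  # single clearly significant covariate is selected
  d <- phData(300, beta = 1.2, seed = 5)
  fit <- stepwiseSelect(data.frame(x = d$x), d$time, d$event)
  expect_identical(fit@selected, "x")
  # all-noise covariates usually give the empty model; the empty model
  # reports no coefficients (downstream c-index becomes NA)
  empties <- 0
  for (s in 1:10) {
    d <- phData(150, beta = 0, seed = 200 + s)
    X <- data.frame(a = rnorm(150), b = rnorm(150))
    fit <- stepwiseSelect(X, d$time, d$event)
    if (!length(fit@selected)) empties <- empties + 1
  }
  expect_gte(empties, 6)
})

test_that("concordance index equals pair enumeration, respects ties and sign conventions", {
  # perfect prediction of times
  set.seed(3)
  tt <- sort(rexp(20)) + 0.1
  expect_equal(concordanceIndex(tt, tt, rep(1, 20), type = "time"), 1)
  # reversed ordering, no ties
  expect_equal(concordanceIndex(rev(tt), tt, rep(1, 20), type = "time"), 0)
  # mixed censoring vs the O(n^2) oracle
  for (rep in 1:30) {
    n <- sample(6:12, 1)
    f <- sample(seq_len(n))                # occasional prediction ties below
    f[sample(n, 2)] <- f[1]
    time <- round(rexp(n), 2) + 0.05
    event <- rbinom(n, 1, 0.7)
    if (sum(event[order(time)][-n]) == 0) event[which.min(time)] <- 1
    expect_equal(concordanceIndex(f, time, event, type = "time"),
                 cIndexOracle(f, time, event, "half"))
    expect_equal(concordanceIndex(f, time, event, tiePolicy = "strict", type = "time"),
                 cIndexOracle(f, time, event, "strict"))
  }
  # risk input = sign-flipped time prediction
  f <- rnorm(15); time <- rexp(15) + 0.1; event <- rep(1, 15)
  expect_equal(concordanceIndex(f, time, event, type = "risk"),
               concordanceIndex(-f, time, event, type = "time"))
  # c(f) + c(-f) = 1 without ties
  f <- rnorm(15)
  cf <- concordanceIndex(f, time, event, type = "time")
  expect_equal(cf + concordanceIndex(-f, time, event, type = "time"), 1)
  # agrees with survival::concordance (Harrell convention) without time ties
  set.seed(9)
  time <- rexp(40) + 0.1; event <- rbinom(40, 1, 0.6); event[1] <- 1
  f <- rnorm(40)
  sc <- survival::concordance(survival::Surv(time, event) ~ f, reverse = TRUE)
  expect_equal(concordanceIndex(f, time, event, type = "risk"),
               unname(sc$concordance), tolerance = 1e-10)
  expect_error(concordanceIndex(1, 5, 0), "aligned|permissible")
})

test_that("Kaplan-Meier matches hand-worked product-limit values", {
  # all censored: S stays 1 (no event times on the curve)
  km <- kaplanMeier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(curveAt(km, c(0.5, 2, 10)), c(1, 1, 1))
  # one subject, event at 5
  km <- kaplanMeier(5, 1)
  expect_equal(curveAt(km, c(4.9, 5, 6)), c(1, 0, 0))
  # events at 1 and 2, censored at 1.5 and 3
  km <- kaplanMeier(c(1, 1.5, 2, 3), c(1, 0, 1, 0))
  expect_equal(km@times, c(1, 2))
  expect_equal(km@surv, c(3 / 4, 3 / 8))
})

test_that("Nelson-Aalen equals explicit enumeration and survfit's cumulative hazard", {
  # no events
  na <- nelsonAalen(c(1, 2), c(0, 0))
  expect_equal(curveAt(na, c(1, 5)), c(0, 0))
  # two subjects, one event first
  na <- nelsonAalen(c(1, 2), c(1, 0))
  expect_equal(na@chf, 1 / 2)
  # mixed cases vs oracle and vs survival::survfit
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:15, 1)
    time <- round(rexp(n), 1) + 0.1
    event <- rbinom(n, 1, 0.6)
    na <- nelsonAalen(time, event)
    or <- naOracle(time, event)
    expect_equal(na@times, or$times)
    expect_equal(na@chf, or$chf)
    if (sum(event)) {
      sf <- survival::survfit(survival::Surv(time, event) ~ 1, stype = 2, ctype = 1)
      keep <- sf$n.event > 0
      expect_equal(na@chf, sf$cumhaz[keep], tolerance = 1e-12)
    }
  }
  # increments are d/Y and the curve is non-decreasing
  time <- c(1, 1, 2, 3, 4); event <- c(1, 1, 0, 1, 0)
  na <- nelsonAalen(time, event)
  expect_equal(diff(c(0, na@chf)), na@deaths / na@atRisk)
  expect_true(all(diff(na@chf) >= 0))
})

test_that("logrank test matches the textbook formula and a permutation null", {
  # identical groups
  lt <- logrankTest(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_equal(lt$statistic, 0, tolerance = 1e-12)
  expect_equal(lt$p, 1, tolerance = 1e-12)
  # fully separated groups exceed the 5% critical value
  t1 <- seq(0.1, 1, length.out = 12); t2 <- t1 + 10
  lt <- logrankTest(t1, rep(1, 12), t2, rep(1, 12))
  expect_gt(lt$statistic, qchisq(0.95, 1))
  # textbook-formula cross-check on random data
  set.seed(13)
  for (rep in 1:10) {
    n1 <- sample(5:12, 1); n2 <- sample(5:12, 1)
    a <- rexp(n1) + 0.1; b <- rexp(n2, 0.6) + 0.1
    e1 <- rbinom(n1, 1, 0.7); e2 <- rbinom(n2, 1, 0.7)
    if (sum(e1) + sum(e2) == 0) e1[1] <- 1
    lt <- logrankTest(a, e1, b, e2)
    expect_equal(lt$statistic, logrankOracle(a, e1, b, e2), tolerance = 1e-8)
  }
  # permutation check: p close to the permutation-null tail probability
  set.seed(17)
  n <- 16
  time <- rexp(2 * n) + 0.1; event <- rbinom(2 * n, 1, 0.8)
  obs <- logrankTest(time[1:n], event[1:n], time[(n + 1):(2 * n)], event[(n + 1):(2 * n)])
  perm <- replicate(400, {
    idx <- sample(2 * n, n)
    logrankTest(time[idx], event[idx], time[-idx], event[-idx])$statistic
  })
  pPerm <- mean(perm >= obs$statistic)
  expect_lt(abs(pPerm - obs$p), 3 * sqrt(0.25 / 400) + 0.05)
  expect_error(logrankTest(numeric(0), numeric(0), c(1), c(1)), "nonempty")
})

test_that("maximally selected cut-off equals the exhaustive survdiff scan", {
  # binary covariate separating early/late events
  time <- c(rexp(10, 2), rexp(10, 0.1) + 3) + 0.05
  event <- rep(1, 20)
  values <- rep(c(0, 1), each = 10)
  co <- optimalCutoff(values, time, event)
  expect_equal(co@threshold, 0.5)
  expect_error(optimalCutoff(rep(1, 20), time, event), "constant")
  # 20-subject random case vs brute-force scan over every admissible split
  set.seed(31)
  v <- rnorm(20); time <- rexp(20) + 0.1; event <- rbinom(20, 1, 0.8)
  event[order(time)[1]] <- 1
  co <- optimalCutoff(v, time, event, minGroupFraction = 0.1)
  us <- sort(unique(v))
  cand <- (us[-1] + us[-length(us)]) / 2
  stats <- vapply(cand, function(th) {
    lo <- v <= th
    if (sum(lo) < 2 || sum(!lo) < 2) return(-Inf)
    d <- data.frame(time = time, event = event, g = lo)
    as.numeric(survival::survdiff(survival::Surv(time, event) ~ g, data = d)$chisq)
  }, numeric(1))
  expect_equal(co@statistic, max(stats), tolerance = 1e-8)
  expect_equal(co@threshold, cand[which.max(stats)])
  expect_gte(co@nLow, 2)
  expect_gte(co@nHigh, 2)
})

test_that("KM and Nelson-Aalen agree to first order when increments are small", {
  set.seed(41)
  time <- rexp(300) + 0.1
  event <- rbinom(300, 1, 0.3)
  km <- kaplanMeier(time, event)
  na <- nelsonAalen(time, event)
  # the approximation applies while every increment d/Y stays below 0.1
  keep <- cumsum(na@deaths / na@atRisk >= 0.1) == 0
  expect_gt(sum(keep), 50)
  expect_equal(km@surv[keep], exp(-na@chf[keep]), tolerance = 0.02)
})
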