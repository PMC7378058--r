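## A hand-crafted forest whose single-node trees carry known CHF curves
craftForest <- function(chfList, grid, n = 4, p = 2) {
  trees <- lapply(chfList, function(cc)
    list(list(var = NA_integer_, thr = NA_real_, left = NA_integer_,
              right = NA_integer_, times = cc$times, chf = cc$chf, size = n)))
  new("SurvivalForest", trees = trees,
      spec = forestSpec(n_trees = length(trees), min_node_size = 2),
      varNames = paste0("x", seq_len(p)),
      inbag = rep(list(seq_len(n)), length(trees)), grid = grid,
      trainX = matrix(0, n, p, dimnames = list(NULL, paste0("x", seq_len(p)))),
      trainTime = seq_len(n), trainEvent = rep(1, n))
}

test_that("a perfectly separating binary covariate is chosen at the root", {
  set.seed(1)
  n <- 20
  x1 <- rep(c(0, 1), each = n / 2)
  time <- ifelse(x1 == 0, runif(n, 0.1, 1), runif(n, 5, 6))
  X <- cbind(sep = x1, noise = rnorm(n))
  f <- fitSurvivalForest(X, time, rep(1, n),
                         forestSpec(n_trees = 5, min_node_size = 3,
                                    mtry = 2, bootstrap = FALSE, seed = 1))
  for (tree in f@trees) {
    expect_equal(tree[[1]]$var, 1L)
    expect_equal(tree[[1]]$thr, 0.5)
  }
})

test_that("unsplittable nodes reproduce the in-bag Nelson-Aalen curve", {
  set.seed(2)
  n <- 15
  X <- cbind(x = rnorm(n))
  time <- rexp(n) + 0.1; event <- rbinom(n, 1, 0.7); event[1] <- 1
  f <- fitSurvivalForest(X, time, event,
                         forestSpec(n_trees = 3, min_node_size = 10,
                                    bootstrap = FALSE, seed = 2))
  na <- nelsonAalen(time, event)
  for (tree in f@trees) {
    expect_length(tree, 1)
    expect_equal(tree[[1]]$times, na@times)
    expect_equal(tree[[1]]$chf, na@chf)
  }
  # ensemble of identical single-node trees = the cohort curve
  chf <- predictChf(f, X)
  expect_equal(chf[[1]]@chf, curveAt(na, f@grid))
})

test_that("event-free in-bag samples give a flat zero CHF with a warning", {
  X <- cbind(x = rnorm(8))
  expect_warning(
    f <- fitSurvivalForest(X, rexp(8) + 0.1, rep(0, 8),
                           forestSpec(n_trees = 2, min_node_size = 2,
                                      bootstrap = FALSE, seed = 3)),
    "fewer than 2 events")
  chf <- predictChf(f, X)
  expect_true(all(curveAt(chf[[1]], c(1, 10, 100)) == 0))
})

test_that("ensemble CHF is the tree average and risk scores sum the grid values", {
  H <- list(times = c(6, 18), chf = c(0.4, 1.0))
  zero <- list(times = numeric(0), chf = numeric(0))
  f <- craftForest(list(zero, H), grid = c(6, 18))
  cc <- predictChf(f, matrix(0, 1, 2, dimnames = list(NULL, c("x1", "x2"))))[[1]]
  expect_equal(cc@chf, c(0.2, 0.5))       # pointwise mean of 0 and H
  expect_true(all(diff(cc@chf) >= 0))
  # two-term risk score: CHF values (0.2, 0.5) at months (6, 18), horizon 24
  rs <- riskScore(f, matrix(0, 1, 2), horizon = 24)
  expect_equal(rs, 0.7)
  expect_equal(riskScore(f, matrix(0, 1, 2), horizon = 10), 0.2)
  expect_equal(riskScore(craftForest(list(zero, zero), c(6, 18)),
                         matrix(0, 1, 2), horizon = 24), 0)
  expect_error(riskScore(f, matrix(0, 1, 2), horizon = 0), "horizon")
})

test_that("ensemble prediction equals brute-force per-tree lookup and grows with horizon", {
  set.seed(4)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  d <- phData(n, beta = 1, seed = 4)
  time <- d$time; event <- d$event
  X[, "a"] <- d$x
  f <- fitSurvivalForest(X, time, event,
                         forestSpec(n_trees = 15, min_node_size = 5, seed = 4))
  newX <- X[1:5, , drop = FALSE]
  pred <- predictChf(f, newX)
  dropCase <- function(tree, x) {
    id <- 1
    while (!is.na(tree[[id]]$var))
      id <- if (x[tree[[id]]$var] <= tree[[id]]$thr) tree[[id]]$left else tree[[id]]$right
    tree[[id]]
  }
  for (i in 1:5) {
    acc <- numeric(length(f@grid))
    for (tree in f@trees) {
      nd <- dropCase(tree, newX[i, ])
      acc <- acc + vapply(f@grid, function(t0)
        if (!length(nd$times)) 0 else { k <- sum(nd$times <= t0); if (k) nd$chf[k] else 0 },
        numeric(1))
    }
    expect_equal(pred[[i]]@chf, acc / length(f@trees))
    expect_true(all(diff(pred[[i]]@chf) >= -1e-12))
    # risk score monotone in horizon
    hs <- c(2, 5, 10, 50)
    rs <- vapply(hs, function(h) riskScore(f, newX[i, , drop = FALSE], h), numeric(1))
    expect_true(all(diff(rs) >= 0))
  }
  expect_error(predictChf(f, matrix(0, 1, 2, dimnames = list(NULL, c("a", "zzz")))),
               "covariates")
})

test_that("forests are reproducible from their seed", {
  set.seed(5)
  X <- cbind(a = rnorm(40), b = rnorm(40))
  time <- rexp(40) + 0.1; event <- rbinom(40, 1, 0.8); event[1] <- 1
  f1 <- fitSurvivalForest(X, time, event, forestSpec(n_trees = 10, min_node_size = 5, seed = 6))
  f2 <- fitSurvivalForest(X, time, event, forestSpec(n_trees = 10, min_node_size = 5, seed = 6))
  expect_identical(f1@trees, f2@trees)
  expect_identical(f1@inbag, f2@inbag)
  f3 <- fitSurvivalForest(X, time, event, forestSpec(n_trees = 10, min_node_size = 5, seed = 7))
  expect_false(identical(f1@trees, f3@trees))
})

test_that("OOB error is calibrated: ~0.5 under the null, low with a strong predictor", {
  errsNull <- vapply(1:6, function(s) {
    set.seed(s)
    X <- cbind(a = rnorm(90), b = rnorm(90))
    time <- rexp(90) + 0.1; event <- rbinom(90, 1, 0.8); event[1] <- 1
    f <- fitSurvivalForest(X, time, event,
                           forestSpec(n_trees = 40, min_node_size = 10, seed = s))
    oobError(f)
  }, numeric(1))
  expect_true(all(errsNull >= 0 & errsNull <= 1))
  expect_lt(abs(mean(errsNull) - 0.5), 0.07)
  d <- phData(120, beta = 1.5, seed = 30)
  set.seed(30)
  X <- cbind(sig = d$x, noise = rnorm(120))
  f <- fitSurvivalForest(X, d$time, d$event,
                         forestSpec(n_trees = 60, min_node_size = 10, seed = 30))
  expect_lt(oobError(f), 0.4)
})

test_that("VIMP separates planted signal from noise and is 0 for unused variables", {
  set.seed(40)
  n <- 120
  x <- rnorm(n)
  tstar <- rexp(n, rate = 0.1 * exp(1.5 * x))
  cens <- rexp(n, rate = 0.03)
  tm <- pmax(pmin(tstar, cens), 1e-8); ev <- as.numeric(tstar <= cens)
  X <- cbind(sig = x, n1 = rnorm(n), n2 = rnorm(n))
  f <- fitSurvivalForest(X, tm, ev,
                         forestSpec(n_trees = 150, min_node_size = 10, seed = 40))
  v <- vimp(f, seed = 1)
  expect_equal(names(which.max(v)), "sig")
  expect_gt(v[["sig"]], 0.05)
  expect_lt(max(abs(v[c("n1", "n2")])), v[["sig"]])
  # a constant column can never be used in a split: its VIMP is exactly 0
  X2 <- cbind(X, flat = rep(2, n))
  f2 <- fitSurvivalForest(X2, tm, ev,
                          forestSpec(n_trees = 20, min_node_size = 10, seed = 41))
  v2 <- vimp(f2, seed = 1)
  expect_identical(v2[["flat"]], 0)
})

test_that("OOB ranking broadly agrees with an independent survival-forest implementation", {
  skip_if_not_installed("ranger")
  d <- phData(150, beta = 1.2, seed = 50)
  set.seed(50)
  X <- data.frame(sig = d$x, noise = rnorm(150))
  f <- fitSurvivalForest(X, d$time, d$event,
                         forestSpec(n_trees = 80, min_node_size = 10, seed = 50))
  rg <- ranger::ranger(survival::Surv(time, event) ~ sig + noise,
                       data = cbind(X, time = d$time, event = d$event),
                       num.trees = 80, min.node.size = 10, seed = 50)
  myErr <- oobError(f)
  rgErr <- rg$prediction.error
  expect_lt(abs(myErr - rgErr), 0.12)
  expect_lt(myErr, 0.45)
  expect_lt(rgErr, 0.45)
})
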