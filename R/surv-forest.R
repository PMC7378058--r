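## Random survival forest: bootstrap samples, logrank splitting over random
## covariate subsets, Nelson-Aalen cumulative hazards in the terminal nodes,
## ensemble CHF prediction, OOB error and random-daughter-assignment VIMP.

#' Hyperparameters of a random survival forest
#'
#' @param n_trees number of survival trees (production default 10000; tests
#'   and examples use far fewer)
#' @param max_depth maximum tree depth (root = depth 1)
#' @param min_node_size minimum number of (bootstrap) cases per node
#' @param mtry covariates tried per split; default \code{ceiling(sqrt(p))},
#'   resolved at fit time when NULL
#' @param bootstrap draw a with-replacement bootstrap per tree (TRUE) or use
#'   the full sample (FALSE)
#' @param seed integer RNG seed; same spec + seed gives identical forests
#' @return list of settings for \code{\link{fitSurvivalForest}}
#' @export
forestSpec <- function(n_trees = 10000L, max_depth = 10L, min_node_size = 10L,
                       mtry = NULL, bootstrap = TRUE, seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (max_depth < 1) stop("max_depth must be >= 1")
  if (min_node_size < 2) stop("min_node_size must be >= 2")
  list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
       min_node_size = as.integer(min_node_size), mtry = mtry,
       bootstrap = isTRUE(bootstrap), seed = as.integer(seed))
}

## Grow one survival tree on the rows `rows` (with multiplicity). Nodes are
## stored pre-order in a list: split nodes carry (var, thr, left, right),
## terminal nodes carry the in-node Nelson-Aalen curve.
.growTree <- function(X, time, event, spec, rows, mtry) {
  nodes <- list()
  p <- ncol(X)
  build <- function(mem, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list()                     # reserve pre-order slot
    terminal <- function() {
      na <- nelsonAalen(time[mem], event[mem])
      nodes[[id]] <<- list(var = NA_integer_, thr = NA_real_,
                           left = NA_integer_, right = NA_integer_,
                           times = na@times, chf = na@chf, size = length(mem))
      id
    }
    if (depth >= spec$max_depth || length(mem) < 2L * spec$min_node_size ||
        sum(event[mem]) < 1) return(terminal())
    best <- NULL
    for (v in sample.int(p, min(mtry, p))) {
      sw <- .logrankSweep(X[mem, v], time[mem], event[mem],
                          minLeft = spec$min_node_size, minRight = spec$min_node_size)
      if (nrow(sw)) {
        j <- which.max(sw$statistic)
        if (is.null(best) || sw$statistic[j] > best$stat)
          best <- list(var = v, thr = sw$threshold[j], stat = sw$statistic[j])
      }
    }
    if (is.null(best) || best$stat <= 0) return(terminal())
    goLeft <- X[mem, best$var] <= best$thr
    l <- build(mem[goLeft], depth + 1L)
    r <- build(mem[!goLeft], depth + 1L)
    nodes[[id]] <<- list(var = best$var, thr = best$thr, left = l, right = r,
                         times = NULL, chf = NULL, size = length(mem))
    id
  }
  build(rows, 1L)
  nodes
}

#' Fit a random survival forest
#'
#' Each tree is grown on a bootstrap sample; at every node the logrank
#' chi-square is evaluated over the midpoint split candidates of
#' \code{mtry} randomly chosen covariates (daughters must each hold at
#' least \code{min_node_size} cases) and the maximizing split is taken.
#' Terminal nodes store the Nelson-Aalen cumulative hazard of their in-bag
#' members. A bootstrap with fewer than 2 events yields a single-root tree
#' with a warning.
#'
#' @param X covariate matrix or data.frame (numeric)
#' @param time positive event/censoring times
#' @param event 0/1 event indicator
#' @param spec a \code{\link{forestSpec}}
#' @return a \code{\link{SurvivalForest}}
#' @export
fitSurvivalForest <- function(X, time, event, spec = forestSpec()) {
  .checkRecords(time, event)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < spec$min_node_size) stop("need at least min_node_size cases")
  mtry <- if (is.null(spec$mtry)) ceiling(sqrt(ncol(X))) else as.integer(spec$mtry)
  set.seed(spec$seed)
  trees <- vector("list", spec$n_trees)
  inbag <- vector("list", spec$n_trees)
  for (b in seq_len(spec$n_trees)) {
    rows <- if (spec$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    if (sum(event[rows]) < 2)
      warning("bootstrap sample ", b, " holds fewer than 2 events; single-root tree")
    trees[[b]] <- .growTree(X, time, event, spec, rows, mtry)
    inbag[[b]] <- rows
  }
  new("SurvivalForest", trees = trees, spec = spec, varNames = colnames(X),
      inbag = inbag, grid = sort(unique(time[event == 1])),
      trainX = X, trainTime = as.numeric(time), trainEvent = as.numeric(event))
}

## terminal node id for one case in one tree; when perturbVar is hit at a
## split, the daughter is chosen uniformly at random (VIMP perturbation)
.treeTerminal <- function(tree, x, perturbVar = NA_integer_) {
  id <- 1L
  repeat {
    nd <- tree[[id]]
    if (is.na(nd$var)) return(id)
    goLeft <- if (!is.na(perturbVar) && nd$var == perturbVar) runif(1) < 0.5
              else x[nd$var] <= nd$thr
    id <- if (goLeft) nd$left else nd$right
  }
}

## n x |grid| ensemble CHF matrix; treeSel restricts the ensemble per case
## (list of tree index vectors, for OOB), perturbVar triggers random
## daughter assignment
.ensembleChf <- function(forest, newX, treeSel = NULL, perturbVar = NA_integer_) {
  grid <- forest@grid
  newX <- as.matrix(newX)
  n <- nrow(newX)
  ## per-tree cache of terminal-node CHF evaluated on the grid
  caches <- lapply(forest@trees, function(tree) new.env(parent = emptyenv()))
  nodeChf <- function(b, id) {
    key <- as.character(id)
    cache <- caches[[b]]
    if (!exists(key, envir = cache, inherits = FALSE)) {
      nd <- forest@trees[[b]][[id]]
      assign(key, c(0, nd$chf)[findInterval(grid, nd$times) + 1L], envir = cache)
    }
    get(key, envir = cache, inherits = FALSE)
  }
  out <- matrix(0, n, length(grid))
  for (i in seq_len(n)) {
    bs <- if (is.null(treeSel)) seq_along(forest@trees) else treeSel[[i]]
    if (!length(bs)) { out[i, ] <- NA_real_; next }
    acc <- numeric(length(grid))
    for (b in bs)
      acc <- acc + nodeChf(b, .treeTerminal(forest@trees[[b]], newX[i, ], perturbVar))
    out[i, ] <- acc / length(bs)
  }
  out
}

#' Ensemble cumulative hazard prediction
#'
#' Drops each case down every tree, evaluates the terminal-node
#' Nelson-Aalen CHF on the union grid of training event times, and averages
#' over trees.
#'
#' @param forest a fitted \code{\link{SurvivalForest}}
#' @param newX covariate matrix/data.frame with the training columns
#' @return a list of \code{\link{HazardCurve}} objects, one per row of
#'   \code{newX}
#' @export
predictChf <- function(forest, newX) {
  newX <- as.matrix(newX)
  if (!all(forest@varNames %in% colnames(newX))) {
    if (ncol(newX) == length(forest@varNames)) colnames(newX) <- forest@varNames
    else stop("newX lacks the training covariates")
  }
  newX <- newX[, forest@varNames, drop = FALSE]
  M <- .ensembleChf(forest, newX)
  lapply(seq_len(nrow(newX)), function(i)
    new("HazardCurve", times = forest@grid, chf = M[i, ],
        atRisk = rep(NA_real_, length(forest@grid)),
        deaths = rep(NA_real_, length(forest@grid))))
}

#' Cumulative-CHF risk score
#'
#' Sums the ensemble CHF values at every distinct event-time grid point up
#' to \code{horizon} (e.g. 24 months for a 2-year risk score): patients
#' whose ensemble hazard accumulates faster score higher.
#'
#' @param forest a fitted \code{\link{SurvivalForest}}
#' @param newX covariate matrix/data.frame
#' @param horizon months; only grid points at or below it contribute
#' @return numeric risk score per row of \code{newX}
#' @export
riskScore <- function(forest, newX, horizon) {
  if (horizon <= 0) stop("horizon must be > 0")
  newX <- as.matrix(newX)
  if (is.null(colnames(newX)) && ncol(newX) == length(forest@varNames))
    colnames(newX) <- forest@varNames
  newX <- newX[, forest@varNames, drop = FALSE]
  M <- .ensembleChf(forest, newX)
  keep <- forest@grid <= horizon
  if (!any(keep)) return(rep(0, nrow(newX)))
  rowSums(M[, keep, drop = FALSE])
}

.oobRisk <- function(forest, perturbVar = NA_integer_) {
  n <- nrow(forest@trainX)
  treeSel <- lapply(seq_len(n), function(i)
    which(vapply(forest@inbag, function(rows) !(i %in% rows), logical(1))))
  M <- .ensembleChf(forest, forest@trainX, treeSel = treeSel, perturbVar = perturbVar)
  keep <- forest@grid <= max(forest@trainTime[forest@trainEvent == 1])
  list(risk = rowSums(M[, keep, drop = FALSE]),
       covered = vapply(treeSel, length, integer(1)) > 0)
}

#' Out-of-bag prediction error
#'
#' For each training case the ensemble risk score (horizon = last event
#' time) is computed over the trees whose bootstrap missed it; the error is
#' 1 minus the concordance index of those OOB risk scores against the
#' outcomes. Cases that are never OOB are excluded with a warning.
#'
#' @param forest a fitted \code{\link{SurvivalForest}}
#' @return the OOB error in [0, 1]
#' @export
oobError <- function(forest) {
  ob <- .oobRisk(forest)
  if (!all(ob$covered))
    warning(sum(!ob$covered), " case(s) never out-of-bag; excluded")
  k <- ob$covered
  1 - concordanceIndex(ob$risk[k], forest@trainTime[k], forest@trainEvent[k],
                       type = "risk")
}

#' Variable importance by random daughter assignment
#'
#' For each covariate, OOB cases are dropped down the trees again, but
#' whenever a split on that covariate is met the daughter node is chosen
#' uniformly at random; the VIMP is the resulting increase in OOB error
#' (perturbed minus original). Positive values indicate predictive
#' importance; zero or negative values indicate none. A covariate never
#' used in any split has VIMP exactly 0.
#'
#' @param forest a fitted \code{\link{SurvivalForest}}
#' @param seed RNG seed for the random daughter draws
#' @return named numeric vector, one VIMP per covariate
#' @export
vimp <- function(forest, seed = 1L) {
  set.seed(seed)
  base <- .oobRisk(forest)
  k <- base$covered
  tt <- forest@trainTime[k]; ee <- forest@trainEvent[k]
  err0 <- 1 - concordanceIndex(base$risk[k], tt, ee, type = "risk")
  ## variables actually used in at least one split
  usedVars <- unique(unlist(lapply(forest@trees, function(tree)
    vapply(tree, function(nd) nd$var, integer(1)))))
  out <- setNames(numeric(length(forest@varNames)), forest@varNames)
  for (v in seq_along(forest@varNames)) {
    if (!(v %in% usedVars)) next                 # perturbation is a no-op
    pb <- .oobRisk(forest, perturbVar = v)
    out[v] <- (1 - concordanceIndex(pb$risk[k], tt, ee, type = "risk")) - err0
  }
  out
}
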