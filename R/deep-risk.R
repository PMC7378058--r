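## Deep risk branch: small CNNs mapping 3-channel tumor patches to a scalar
## log-risk, trained by SGD on the negative Cox partial likelihood, with
## optional convolutional auto-encoder pre-training of the conv trunk.

#' Hyperparameters of a risk network
#'
#' The architecture is fixed (conv 3x3/32 + ReLU, pool 2x2, conv 3x3/32 +
#' ReLU, pool 2x2, FC 32 + ReLU, FC 1 linear); the spec records the input
#' side and the training settings. Production defaults: learning rate 1e-5,
#' 2000 epochs, batch size 32; experiments at desk scale pass smaller
#' epoch counts (and a correspondingly larger learning rate) explicitly.
#'
#' @param input_side input side in pixels; must be a positive multiple of 4
#'   (two 2x2 pooling stages)
#' @param channels input channels (3 slices or 3 scales)
#' @param feature_maps feature maps per conv layer
#' @param fc_width width of the first fully connected layer
#' @param learning_rate SGD learning rate
#' @param epochs training epochs
#' @param batch_size SGD batch size (risk sets are restricted to the batch)
#' @return a validated list of settings
#' @export
riskNetSpec <- function(input_side, channels = 3L, feature_maps = 32L,
                        fc_width = 32L, learning_rate = 1e-5,
                        epochs = 2000L, batch_size = 32L) {
  input_side <- as.integer(input_side)
  if (input_side < 8L || input_side %% 4L != 0L)
    stop("input_side must be a multiple of 4 and >= 8 (two 2x2 pooling stages)")
  if (channels != 3L) stop("exactly 3 input channels are supported")
  list(input_side = input_side, channels = 3L,
       feature_maps = as.integer(feature_maps), fc_width = as.integer(fc_width),
       learning_rate = learning_rate, epochs = as.integer(epochs),
       batch_size = as.integer(batch_size))
}

#' Trainable parameter count of a risk network
#'
#' Pure function of the spec: two 3x3 conv layers, the flattened
#' (side/4)^2 x feature_maps to fc_width layer, and the linear output unit.
#'
#' @param spec a \code{\link{riskNetSpec}}
#' @return integer parameter count
#' @export
riskNetParamCount <- function(spec) {
  K <- spec$feature_maps; H <- spec$fc_width
  f <- (spec$input_side / 4L)^2 * K
  as.integer((9 * 3) * K + K + (9 * K) * K + K + f * H + H + H + 1)
}

.glorot <- function(nin, nout, nrow, ncol) {
  l <- sqrt(6 / (nin + nout))
  matrix(runif(nrow * ncol, -l, l), nrow, ncol)
}

#' Build an (untrained) risk network
#'
#' Initializes all weights with seeded Glorot-uniform draws and zero biases.
#'
#' @param spec a \code{\link{riskNetSpec}}
#' @param modality "CT" or "PET" (label only)
#' @param seed integer seed for the weight initialization
#' @return a \code{\link{RiskNet}}
#' @export
buildRiskNet <- function(spec, modality = c("CT", "PET"), seed = 1L) {
  modality <- match.arg(modality)
  K <- spec$feature_maps; H <- spec$fc_width
  f <- (spec$input_side / 4L)^2 * K
  set.seed(seed)
  params <- list(
    W1 = .glorot(27, 9 * K, 27, K), b1 = numeric(K),
    W2 = .glorot(9 * K, 9 * K, 9 * K, K), b2 = numeric(K),
    W3 = .glorot(f, H, f, H), b3 = numeric(H),
    W4 = .glorot(H, 1, H, 1), b4 = numeric(1))
  new("RiskNet", spec = spec, params = params, trained = FALSE,
      modality = modality, history = numeric(0))
}

#' Batch Cox loss
#'
#' Negative Cox partial log-likelihood with the risk sets restricted to the
#' batch, normalized by the number of events in the batch (Breslow ties,
#' log-sum-exp stabilized). An event-free batch cannot contribute a
#' gradient step and returns the sentinel \code{NA}.
#'
#' @param risks batch linear predictors
#' @param time,event batch records
#' @return scalar loss, or \code{NA} for an event-free batch
#' @export
batchCoxLoss <- function(risks, time, event) {
  if (sum(event) == 0) return(NA_real_)
  -coxPartialLoglik(risks, time, event) / sum(event)
}

.checkStacks <- function(stacks, side) {
  d <- dim(stacks)
  if (length(d) != 4 || d[1] != side || d[2] != side || d[3] != 3)
    stop("stacks must be a side x side x 3 x n array matching the network input")
  d[4]
}

#' Train a risk network by SGD on the batch Cox loss
#'
#' Shuffles the cases every epoch (seeded), walks over batches of
#' \code{spec$batch_size}, skips event-free batches, and applies plain SGD.
#' Identical seeds give identical trained weights.
#'
#' @param net a \code{\link{RiskNet}} (random or CAE-transferred init)
#' @param stacks array side x side x 3 x n of (normalized) inputs
#' @param time,event aligned survival records (at least one event)
#' @param epochs,learning_rate optional overrides of the spec values
#' @param seed seed for the epoch shuffles
#' @return the trained \code{RiskNet} (per-epoch mean loss in
#'   \code{@history})
#' @export
trainRiskNet <- function(net, stacks, time, event,
                         epochs = NULL, learning_rate = NULL, seed = 1L) {
  n <- .checkStacks(stacks, net@spec$input_side)
  .checkRecords(time, event)
  if (length(time) != n) stop("stacks and records must be aligned")
  if (sum(event) < 1) stop("training set has no events")
  epochs <- if (is.null(epochs)) net@spec$epochs else as.integer(epochs)
  lr <- if (is.null(learning_rate)) net@spec$learning_rate else learning_rate
  set.seed(seed)
  perms <- t(vapply(seq_len(epochs), function(e) sample.int(n), integer(n)))
  res <- rnTrainCpp(net@params, as.numeric(stacks), dim(stacks),
                    as.numeric(time), as.integer(event), perms,
                    net@spec$batch_size, lr)
  net@params <- res$params
  net@trained <- TRUE
  net@history <- as.numeric(res$epochLoss)
  net
}

#' Risk scores of a network on a stack array
#'
#' @param net a \code{\link{RiskNet}}
#' @param stacks array side x side x 3 x n
#' @return numeric vector of length n (the final linear unit's output)
#' @export
riskScores <- function(net, stacks) {
  .checkStacks(stacks, net@spec$input_side)
  as.numeric(rnForwardCpp(net@params, as.numeric(stacks), dim(stacks)))
}

#' Penultimate-layer features
#'
#' Activations of the 32-unit fully connected layer before the output, used
#' for correlation analyses against hand-crafted features.
#'
#' @param net a trained \code{\link{RiskNet}}
#' @param stacks array side x side x 3 x n
#' @return n x fc_width numeric matrix
#' @export
extractPenultimate <- function(net, stacks) {
  if (!net@trained) stop("network is untrained")
  .checkStacks(stacks, net@spec$input_side)
  rnPenultimateCpp(net@params, as.numeric(stacks), dim(stacks))
}

#' Pre-train the conv trunk with a convolutional auto-encoder
#'
#' The encoder is the risk net's conv/pool trunk; the decoder mirrors it
#' (nearest-neighbor x2 upsampling, two 3x3/32 ReLU convs, a linear 3x3
#' 3-channel head) and the mean squared reconstruction error is minimized
#' by SGD. The pre-training stacks must come from a dataset disjoint from
#' the survival cohort. Returns the trunk weights for transfer.
#'
#' @param stacks array side x side x 3 x n of unlabeled inputs
#' @param spec a \code{\link{riskNetSpec}} (input_side must match)
#' @param epochs CAE training epochs (default 100)
#' @param learning_rate SGD learning rate for the CAE (default 1e-3)
#' @param seed seed for init and shuffles
#' @return list with \code{trunk} (W1, b1, W2, b2), \code{history}
#'   (per-epoch reconstruction loss) and \code{decoder}
#' @export
pretrainCAE <- function(stacks, spec, epochs = 100L, learning_rate = 1e-3,
                        seed = 1L) {
  n <- .checkStacks(stacks, spec$input_side)
  K <- spec$feature_maps
  set.seed(seed)
  enc <- buildRiskNet(spec, "CT", seed = seed)@params
  dec <- list(W5 = .glorot(9 * K, 9 * K, 9 * K, K), b5 = numeric(K),
              W6 = .glorot(9 * K, 9 * K, 9 * K, K), b6 = numeric(K),
              W7 = .glorot(9 * K, 27, 9 * K, 3), b7 = numeric(3))
  perms <- t(vapply(seq_len(as.integer(epochs)), function(e) sample.int(n), integer(n)))
  res <- caeTrainCpp(enc, dec, as.numeric(stacks), dim(stacks), perms,
                     spec$batch_size, learning_rate)
  list(trunk = res$enc[c("W1", "b1", "W2", "b2")],
       history = as.numeric(res$epochLoss), decoder = res$dec)
}

#' Reconstruction loss of a CAE on held-out stacks
#'
#' @param trunk encoder trunk weights (W1, b1, W2, b2), e.g. from
#'   \code{\link{pretrainCAE}}
#' @param decoder decoder weights (W5..b7)
#' @param stacks array side x side x 3 x n
#' @param spec the matching \code{\link{riskNetSpec}}
#' @return mean squared reconstruction error
#' @export
caeReconstructionLoss <- function(trunk, decoder, stacks, spec) {
  .checkStacks(stacks, spec$input_side)
  enc <- buildRiskNet(spec, "CT", seed = 1L)@params
  enc[names(trunk)] <- trunk
  caeLossCpp(enc, decoder, as.numeric(stacks), dim(stacks))
}

#' Transfer CAE trunk weights into a risk network
#'
#' @param net a \code{\link{RiskNet}}
#' @param trunk list with W1, b1, W2, b2 (shapes must match)
#' @return the network with the conv trunk replaced
#' @export
transferWeights <- function(net, trunk) {
  for (nm in c("W1", "b1", "W2", "b2")) {
    if (is.null(trunk[[nm]])) stop("trunk is missing ", nm)
    if (!identical(dim(net@params[[nm]]), dim(trunk[[nm]])) ||
        length(net@params[[nm]]) != length(trunk[[nm]]))
      stop("shape mismatch transferring ", nm)
    net@params[[nm]] <- trunk[[nm]]
  }
  net
}
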