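#' Construct a multi-task conditional encoder-generator model
#'
#' Builds the four networks: encoder E (gene space -> shared latent space),
#' generator G (latent -> gene space, layer widths mirroring E, final layer
#' linear), discriminator D (gene space -> scalar realness score), and mapping
#' network M (Gaussian noise -> latent codes; plain dense, unconditioned).
#' E, G and D are stacks of tissue-conditioning blocks: a shared fully
#' connected layer, a learnable per-tissue instance-level affine (scale gamma,
#' shift beta), and a leaky ReLU.
#'
#' @param geneDim number of genes.
#' @param tissues character vector: the tissue vocabulary the model is
#'   conditioned on.
#' @param hidden encoder hidden widths, gene -> latent direction (the
#'   generator uses the reverse). Default c(512, 256).
#' @param latentDim dimension of the shared latent space (default 128).
#' @param noiseDim dimension of the Gaussian noise fed to M (default 64).
#' @param mapperHidden hidden widths of M (default 128).
#' @param slope leaky-ReLU negative slope (default 0.2).
#' @param gammaInit sd of the random initialization of the per-tissue affine
#'   scales (default 0.2).
#' @param gammaMean mean of that initialization (default 1: near-identity
#'   scales, the conditional-affine convention; tissue conditions are active
#'   but shared features stay aligned across tissues at initialization).
#' @param seed optional integer; when given, initialization is reproducible.
#' @param scalers optional \linkS4class{TissueScalers} carried along so that
#'   predictions can be de-standardized.
#' @return an \linkS4class{MTMModel}
#' @export
mtmModel <- function(geneDim, tissues, hidden = c(512, 256), latentDim = 128,
                     noiseDim = 64, mapperHidden = 128, slope = 0.2,
                     gammaInit = 0.2, gammaMean = 1, seed = NULL,
                     scalers = NULL) {
  stopifnot(geneDim >= 1, latentDim >= 1, noiseDim >= 1,
            length(tissues) >= 1, !anyDuplicated(tissues))
  if (!is.null(seed)) set.seed(seed)
  tissues <- as.character(tissues)
  nT <- length(tissues)
  encDims <- c(geneDim, hidden, latentDim)
  genDims <- c(latentDim, rev(hidden), geneDim)
  disDims <- c(geneDim, hidden, 1)
  mapDims <- c(noiseDim, mapperHidden, latentDim)
  nE <- length(encDims) - 1L
  nG <- length(genDims) - 1L
  nD <- length(disDims) - 1L
  nM <- length(mapDims) - 1L
  enc <- nnNetwork(encDims, nT, conditioned = rep(TRUE, nE),
                   act = rep("lrelu", nE), slope, gammaInit, gammaMean)
  gen <- nnNetwork(genDims, nT,
                   conditioned = c(rep(TRUE, nG - 1L), FALSE),
                   act = c(rep("lrelu", nG - 1L), "linear"), slope, gammaInit,
                   gammaMean)
  dis <- nnNetwork(disDims, nT,
                   conditioned = c(rep(TRUE, nD - 1L), FALSE),
                   act = c(rep("lrelu", nD - 1L), "linear"), slope, gammaInit,
                   gammaMean)
  map <- nnNetwork(mapDims, nT, conditioned = rep(FALSE, nM),
                   act = rep("lrelu", nM), slope, gammaInit, gammaMean)
  new("MTMModel", encoder = enc, generator = gen, discriminator = dis,
      mapper = map, tissues = tissues,
      config = list(geneDim = geneDim, hidden = hidden, latentDim = latentDim,
                    noiseDim = noiseDim, mapperHidden = mapperHidden,
                    slope = slope, gammaInit = gammaInit,
                    gammaMean = gammaMean),
      scalers = scalers)
}

tissueIndex <- function(model, tissue, n) {
  tissue <- as.character(tissue)
  if (length(tissue) == 1L) tissue <- rep(tissue, n)
  if (length(tissue) != n)
    stop("tissue labels must have length 1 or the batch size")
  idx <- match(tissue, model@tissues)
  if (anyNA(idx))
    stop("unknown tissue label(s): ",
         paste(unique(tissue[is.na(idx)]), collapse = ", "),
         "; declared tissues: ", paste(model@tissues, collapse = ", "))
  idx
}

asBatch <- function(x, dim, what) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != dim)
    stop(what, ": expected ", dim, " columns, got ", ncol(x))
  x
}

#' Encode expression profiles into the shared latent space
#'
#' @param model an \linkS4class{MTMModel}
#' @param x standardized expression batch (samples x genes; a vector is
#'   treated as a single sample).
#' @param tissue source tissue label(s), length 1 or nrow(x).
#' @return matrix of latent codes, samples x latentDim.
#' @export
encode <- function(model, x, tissue) {
  x <- asBatch(x, model@config$geneDim, "encode")
  ti <- tissueIndex(model, tissue, nrow(x))
  nnForward(model@encoder, x, ti)$out
}

#' Generate expression profiles from latent codes
#'
#' @param model an \linkS4class{MTMModel}
#' @param code latent codes (samples x latentDim).
#' @param tissue target tissue label(s).
#' @return matrix of standardized expression profiles (samples x genes).
#' @export
generate <- function(model, code, tissue) {
  code <- asBatch(code, model@config$latentDim, "generate")
  ti <- tissueIndex(model, tissue, nrow(code))
  nnForward(model@generator, code, ti)$out
}

#' Discriminator realness scores for expression profiles
#'
#' @param model an \linkS4class{MTMModel}
#' @param x standardized expression batch.
#' @param tissue tissue condition label(s).
#' @return numeric vector: one unbounded real score per sample.
#' @export
discriminate <- function(model, x, tissue) {
  x <- asBatch(x, model@config$geneDim, "discriminate")
  ti <- tissueIndex(model, tissue, nrow(x))
  drop(nnForward(model@discriminator, x, ti)$out)
}

#' Map Gaussian noise to latent codes through the mapping network
#'
#' @param model an \linkS4class{MTMModel}
#' @param z noise batch (samples x noiseDim), typically N(0, 1) draws.
#' @return matrix of latent codes.
#' @export
mapNoise <- function(model, z) {
  z <- asBatch(z, model@config$noiseDim, "mapNoise")
  nnForward(model@mapper, z)$out
}

#' Per-layer generator activations (the decoding path)
#'
#' Returns the ordered list of generator layer outputs for a batch of latent
#' codes under a tissue condition; the last element equals
#' \code{generate(model, code, tissue)}.
#'
#' @inheritParams generate
#' @return list of activation matrices, one per generator layer.
#' @export
collectActivations <- function(model, code, tissue) {
  code <- asBatch(code, model@config$latentDim, "collectActivations")
  ti <- tissueIndex(model, tissue, nrow(code))
  nnForward(model@generator, code, ti, keepActivations = TRUE)$activations
}

CHECKPOINT_VERSION <- 1L

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding the weights of all four
#' networks, the architecture configuration, the tissue vocabulary and the
#' attached TissueScalers, so a loaded model can standardize inputs and
#' de-standardize predictions exactly as the original.
#'
#' @param model an \linkS4class{MTMModel}
#' @param path file path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "MTMModel"))
  saveRDS(list(format = "mtmap-checkpoint", version = CHECKPOINT_VERSION,
               tissues = model@tissues, config = model@config,
               encoder = model@encoder, generator = model@generator,
               discriminator = model@discriminator, mapper = model@mapper,
               scalers = model@scalers),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read checkpoint '", path,
                                           "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "mtmap-checkpoint"))
    stop("'", path, "' is not a model checkpoint")
  if (!identical(obj$version, CHECKPOINT_VERSION))
    stop("checkpoint version ", obj$version, " not supported (expected ",
         CHECKPOINT_VERSION, ")")
  new("MTMModel", encoder = obj$encoder, generator = obj$generator,
      discriminator = obj$discriminator, mapper = obj$mapper,
      tissues = obj$tissues, config = obj$config, scalers = obj$scalers)
}
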