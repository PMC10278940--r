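#' Training configuration
#'
#' Defaults follow the usual conditional-GAN regime for this model family:
#' Adam with learning rate 5e-4, beta1 = 0.5, beta2 = 0.9, mini-batches of
#' 256 tissue pairs, and at most 200 epochs.
#'
#' @param batchSize mini-batch size (>= 1).
#' @param maxEpochs maximum training epochs.
#' @param learningRate Adam learning rate (> 0).
#' @param adamBeta1,adamBeta2 Adam moment decays in [0, 1).
#' @param weights a \code{\link{lossWeights}} object.
#' @param seed integer seed controlling initialization, pair shuffling and
#'   noise draws.
#' @param dStepsPerGStep discriminator updates per generator update.
#' @param validationEvery epochs between validation-loss evaluations.
#' @return list of class "TrainConfig".
#' @export
trainConfig <- function(batchSize = 256, maxEpochs = 200,
                        learningRate = 5e-4, adamBeta1 = 0.5,
                        adamBeta2 = 0.9, weights = lossWeights(), seed = 1,
                        dStepsPerGStep = 1, validationEvery = 1) {
  stopifnot(batchSize >= 1, maxEpochs >= 1, learningRate > 0,
            adamBeta1 >= 0, adamBeta1 < 1, adamBeta2 >= 0, adamBeta2 < 1,
            dStepsPerGStep >= 1, validationEvery >= 1)
  structure(list(batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 learningRate = learningRate, adamBeta1 = adamBeta1,
                 adamBeta2 = adamBeta2, weights = weights,
                 seed = as.integer(seed),
                 dStepsPerGStep = as.integer(dStepsPerGStep),
                 validationEvery = as.integer(validationEvery)),
            class = "TrainConfig")
}

#' Train the multi-task conditional encoder-generator
#'
#' Per step, a mini-batch of within-individual tissue pairs is drawn together
#' with a matching batch of noise/target-tissue conditions. The discriminator
#' is updated on the hinge loss (generated samples detached); the generator
#' side is then updated on the weighted combination of the adversarial
#' generator loss and latent reconstruction loss (updating G and M) and the
#' individualized and cycle-consistency losses (updating E and G). The
#' best-validation (individualized loss) and last-epoch models are both kept.
#'
#' @param x an \linkS4class{MTMDataSet} (raw TPM-like values).
#' @param trainIds training individual IDs.
#' @param valIds optional validation individual IDs.
#' @param config a \code{\link{trainConfig}}.
#' @param hidden,latentDim,noiseDim,mapperHidden,gammaInit,gammaMean
#'   architecture settings, see \code{\link{mtmModel}}.
#' @param scalers optional pre-fitted \linkS4class{TissueScalers}; fitted on
#'   \code{trainIds} when NULL (never on validation individuals).
#' @param verbose print per-epoch losses.
#' @return list with \code{model} (best-validation checkpoint, or last epoch
#'   when no validation set), \code{lastModel}, \code{history} (per-epoch
#'   loss data.frame), \code{scalers}.
#' @export
trainMTM <- function(x, trainIds, valIds = NULL, config = trainConfig(),
                     hidden = c(512, 256), latentDim = 128, noiseDim = 64,
                     mapperHidden = 128, gammaInit = 0.2, gammaMean = 1,
                     scalers = NULL, verbose = FALSE) {
  stopifnot(is(x, "MTMDataSet"), inherits(config, "TrainConfig"))
  set.seed(config$seed)
  scalers <- scalers %||% fitScalers(x, trainIds)
  Z <- applyScalers(x, scalers)
  meta <- sampleInfo(x)
  pairs <- buildTissuePairs(meta, trainIds)
  if (!nrow(pairs)) stop("empty tissue-pair set: no trainable individuals")
  valPairs <- if (!is.null(valIds)) buildTissuePairs(meta, valIds)
  tissues <- rownames(scalers@center)
  G <- ncol(Z)
  model <- mtmModel(G, tissues, hidden = hidden, latentDim = latentDim,
                    noiseDim = noiseDim, mapperHidden = mapperHidden,
                    gammaInit = gammaInit, gammaMean = gammaMean,
                    scalers = scalers)
  w <- config$weights
  lr <- config$learningRate
  b1 <- config$adamBeta1
  b2 <- config$adamBeta2
  stE <- adamInit(model@encoder)
  stG <- adamInit(model@generator)
  stD <- adamInit(model@discriminator)
  stM <- adamInit(model@mapper)
  hist <- vector("list", config$maxEpochs)
  best <- list(val = Inf, model = NULL, epoch = NA_integer_)
  nP <- nrow(pairs)

  valLI <- function(m) {
    if (is.null(valPairs) || !nrow(valPairs)) return(NA_real_)
    xs <- Z[valPairs$source_sample, , drop = FALSE]
    xt <- Z[valPairs$target_sample, , drop = FALSE]
    individualizedLoss(m, xs, valPairs$source_tissue, xt,
                       valPairs$target_tissue)
  }

  for (epoch in seq_len(config$maxEpochs)) {
    ord <- sample.int(nP)
    starts <- seq(1L, nP, by = config$batchSize)
    eLoss <- c(advD = 0, advG = 0, LR = 0, LI = 0, LC = 0)
    for (s0 in starts) {
      b <- ord[s0:min(s0 + config$batchSize - 1L, nP)]
      n <- length(b)
      xs <- Z[pairs$source_sample[b], , drop = FALSE]
      xt <- Z[pairs$target_sample[b], , drop = FALSE]
      si <- match(pairs$source_tissue[b], model@tissues)
      ti <- match(pairs$target_tissue[b], model@tissues)

      # ---- discriminator: hinge loss, generated batch detached ----
      lossD <- 0
      for (dstep in seq_len(config$dStepsPerGStep)) {
        z <- matrix(stats::rnorm(n * noiseDim), n, noiseDim)
        ct <- nnForward(model@mapper, z)$out
        fake <- nnForward(model@generator, ct, ti)$out
        fr <- nnForward(model@discriminator, xt, ti, keepCache = TRUE)
        ff <- nnForward(model@discriminator, fake, ti, keepCache = TRUE)
        sr <- drop(fr$out)
        sf <- drop(ff$out)
        lossD <- hingeLossD(sr, sf)
        if (!is.finite(lossD))
          stop("non-finite discriminator hinge loss at epoch ", epoch)
        gD <- nnAccGrads(
          nnBackward(model@discriminator, fr$caches,
                     matrix(-(1 - sr > 0) / n, n, 1), ti)$grads,
          nnBackward(model@discriminator, ff$caches,
                     matrix((1 + sf > 0) / n, n, 1), ti)$grads)
        up <- adamStep(model@discriminator, stD, gD, lr, b1, b2)
        model@discriminator <- up$net
        stD <- up$state
      }

      # ---- generator side ----
      gE <- nnZeroGrads(model@encoder)
      gG <- nnZeroGrads(model@generator)
      gM <- nnZeroGrads(model@mapper)

      # adversarial G + latent reconstruction: update G and M
      z <- matrix(stats::rnorm(n * noiseDim), n, noiseDim)
      fm <- nnForward(model@mapper, z, keepCache = TRUE)
      ct <- fm$out
      fg <- nnForward(model@generator, ct, ti, keepCache = TRUE)
      fake <- fg$out
      fd <- nnForward(model@discriminator, fake, ti, keepCache = TRUE)
      sf <- drop(fd$out)
      advG <- hingeLossG(sf)
      fe <- nnForward(model@encoder, fake, ti, keepCache = TRUE)
      rec <- fe$out
      LR <- l1Mean(rec, ct)
      dFake <- matrix(0, n, G)
      if (w$lambdaAdv > 0) {
        bd <- nnBackward(model@discriminator, fd$caches,
                         matrix(-1 / n, n, 1), ti)
        dFake <- dFake + w$lambdaAdv * bd$dX
      }
      dCt <- matrix(0, n, latentDim)
      if (w$lambdaR > 0) {
        be <- nnBackward(model@encoder, fe$caches, l1Grad(rec, ct), ti)
        dFake <- dFake + w$lambdaR * be$dX
        dCt <- dCt - w$lambdaR * l1Grad(rec, ct)  # direct target-side path
      }
      bg <- nnBackward(model@generator, fg$caches, dFake, ti)
      gG <- nnAccGrads(gG, bg$grads)
      dCt <- dCt + bg$dX
      bm <- nnBackward(model@mapper, fm$caches, dCt)
      gM <- nnAccGrads(gM, bm$grads)

      # individualized + cycle: update E and G
      feI <- nnForward(model@encoder, xs, si, keepCache = TRUE)
      ce <- feI$out
      fgI <- nnForward(model@generator, ce, ti, keepCache = TRUE)
      pred <- fgI$out
      LI <- l1Mean(pred, xt)
      feC <- nnForward(model@encoder, pred, ti, keepCache = TRUE)
      c2 <- feC$out
      fgC <- nnForward(model@generator, c2, si, keepCache = TRUE)
      back <- fgC$out
      LC <- l1Mean(back, xs)
      dPred <- matrix(0, n, G)
      if (w$lambdaI > 0) dPred <- dPred + w$lambdaI * l1Grad(pred, xt)
      if (w$lambdaC > 0) {
        bgC <- nnBackward(model@generator, fgC$caches,
                          w$lambdaC * l1Grad(back, xs), si)
        gG <- nnAccGrads(gG, bgC$grads)
        beC <- nnBackward(model@encoder, feC$caches, bgC$dX, ti)
        gE <- nnAccGrads(gE, beC$grads)
        dPred <- dPred + beC$dX  # full cycle backprop, no detachment
      }
      if (w$lambdaI > 0 || w$lambdaC > 0) {
        bgI <- nnBackward(model@generator, fgI$caches, dPred, ti)
        gG <- nnAccGrads(gG, bgI$grads)
        beI <- nnBackward(model@encoder, feI$caches, bgI$dX, si)
        gE <- nnAccGrads(gE, beI$grads)
        up <- adamStep(model@encoder, stE, gE, lr, b1, b2)
        model@encoder <- up$net
        stE <- up$state
      }
      up <- adamStep(model@generator, stG, gG, lr, b1, b2)
      model@generator <- up$net
      stG <- up$state
      up <- adamStep(model@mapper, stM, gM, lr, b1, b2)
      model@mapper <- up$net
      stM <- up$state

      for (nm in c("advG", "LR", "LI", "LC"))
        if (!is.finite(get(nm)))
          stop("non-finite loss term ", nm, " at epoch ", epoch)
      eLoss <- eLoss + c(lossD, advG, LR, LI, LC) * n
    }
    eLoss <- eLoss / nP
    vli <- if (epoch %% config$validationEvery == 0L) valLI(model)
           else NA_real_
    if (is.finite(vli) && vli < best$val)
      best <- list(val = vli, model = model, epoch = epoch)
    hist[[epoch]] <- data.frame(epoch = epoch, advD = eLoss[["advD"]],
                                advG = eLoss[["advG"]], LR = eLoss[["LR"]],
                                LI = eLoss[["LI"]], LC = eLoss[["LC"]],
                                valLI = vli)
    if (verbose)
      message(sprintf(
        "epoch %d | D %.4f advG %.4f LR %.4f LI %.4f LC %.4f valLI %s",
        epoch, eLoss[["advD"]], eLoss[["advG"]], eLoss[["LR"]],
        eLoss[["LI"]], eLoss[["LC"]],
        if (is.na(vli)) "-" else sprintf("%.4f", vli)))
  }
  list(model = if (!is.null(best$model)) best$model else model,
       lastModel = model,
       history = do.call(rbind, hist),
       scalers = scalers,
       bestEpoch = best$epoch)
}

#' Predict a target tissue's expression profiles from source samples
#'
#' Standardizes the source samples with the model's recorded scaling factors,
#' encodes them under their source tissue labels, generates under the target
#' tissue label, and (optionally) de-standardizes with the target tissue's
#' factors. Predicting the source tissue itself (autoencoding direction) is
#' permitted.
#'
#' @param model a trained \linkS4class{MTMModel} carrying TissueScalers.
#' @param x an \linkS4class{MTMDataSet} or raw samples x genes TPM matrix.
#' @param targetTissue single target tissue label.
#' @param tissue per-sample source tissue labels (from \code{x} if an
#'   MTMDataSet).
#' @param destandardize return TPM-scale values (default) or standardized
#'   values.
#' @return samples x genes matrix carrying the source sample IDs as rownames
#'   and the target tissue as attribute \code{"targetTissue"}.
#' @export
predictTissue <- function(model, x, targetTissue, tissue = NULL,
                          destandardize = TRUE) {
  stopifnot(is(model, "MTMModel"), length(targetTissue) == 1)
  if (is.null(model@scalers))
    stop("model carries no TissueScalers; cannot (de)standardize")
  if (is(x, "MTMDataSet")) {
    tissue <- colData(x)$tissue
    x <- exprMatrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (length(tissue) == 1L) tissue <- rep(tissue, nrow(x))
  z <- applyScalers(x, model@scalers, tissue)
  pred <- generate(model, encode(model, z, tissue), targetTissue)
  dimnames(pred) <- dimnames(z)
  if (destandardize)
    pred <- invertScalers(pred, model@scalers, targetTissue)
  attr(pred, "targetTissue") <- targetTissue
  pred
}

# ---------------------------------------------------------------------------
# single-tissue MLP baseline (one independent network per target tissue)

#' Train single-tissue MLP baselines
#'
#' One independent fully connected network with leaky-ReLU activations per
#' target tissue, mapping the standardized source-tissue (blood analogue)
#' profile to the standardized target-tissue profile, trained with the L1
#' loss and Adam. Default maximum epochs 1000; other hyperparameters default
#' to the multi-task model's.
#'
#' @param x an \linkS4class{MTMDataSet}.
#' @param trainIds training individual IDs.
#' @param sourceTissue the fixed input tissue.
#' @param targetTissues target tissues (default: all others).
#' @param hidden hidden widths (default 256).
#' @param config a \code{\link{trainConfig}}; its loss weights are ignored.
#' @param scalers optional pre-fitted scalers (fitted on trainIds when NULL).
#' @param verbose print progress.
#' @return object of class "S3Baseline".
#' @export
trainS3Baseline <- function(x, trainIds, sourceTissue = "blood",
                            targetTissues = NULL, hidden = 256,
                            config = trainConfig(maxEpochs = 1000),
                            scalers = NULL, verbose = FALSE) {
  stopifnot(is(x, "MTMDataSet"))
  set.seed(config$seed)
  scalers <- scalers %||% fitScalers(x, trainIds)
  Z <- applyScalers(x, scalers)
  meta <- sampleInfo(x)
  tissues <- rownames(scalers@center)
  if (!sourceTissue %in% tissues)
    stop("source tissue '", sourceTissue, "' not in the cohort")
  targetTissues <- targetTissues %||% setdiff(tissues, sourceTissue)
  G <- ncol(Z)
  lr <- config$learningRate
  models <- list()
  for (t in targetTissues) {
    src <- meta[meta$tissue == sourceTissue & meta$individual_id %in%
                  trainIds, , drop = FALSE]
    tgt <- meta[meta$tissue == t & meta$individual_id %in% trainIds, ,
                drop = FALSE]
    both <- intersect(src$individual_id, tgt$individual_id)
    if (length(both) < 2) {
      warning("target tissue '", t, "' has fewer than 2 training ",
              "individuals with a ", sourceTissue, " sample; skipped")
      next
    }
    X <- Z[src$sample_id[match(both, src$individual_id)], , drop = FALSE]
    Y <- Z[tgt$sample_id[match(both, tgt$individual_id)], , drop = FALSE]
    dims <- c(G, hidden, G)
    nl <- length(dims) - 1L
    net <- nnNetwork(dims, 1L, conditioned = rep(FALSE, nl),
                     act = c(rep("lrelu", nl - 1L), "linear"))
    st <- adamInit(net)
    n <- nrow(X)
    for (epoch in seq_len(config$maxEpochs)) {
      ord <- sample.int(n)
      for (s0 in seq(1L, n, by = config$batchSize)) {
        b <- ord[s0:min(s0 + config$batchSize - 1L, n)]
        fw <- nnForward(net, X[b, , drop = FALSE], keepCache = TRUE)
        loss <- l1Mean(fw$out, Y[b, , drop = FALSE])
        if (!is.finite(loss))
          stop("non-finite baseline loss for tissue '", t, "'")
        g <- nnBackward(net, fw$caches,
                        l1Grad(fw$out, Y[b, , drop = FALSE]))$grads
        up <- adamStep(net, st, g, lr, config$adamBeta1, config$adamBeta2)
        net <- up$net
        st <- up$state
      }
      if (verbose && epoch %% 50 == 0)
        message(sprintf("S3 [%s] epoch %d | L1 %.4f", t, epoch, loss))
    }
    models[[t]] <- net
  }
  structure(list(models = models, sourceTissue = sourceTissue,
                 scalers = scalers, hidden = hidden),
            class = "S3Baseline")
}

#' Predict with a single-tissue MLP baseline
#'
#' @param fit an object from \code{\link{trainS3Baseline}}.
#' @param x an \linkS4class{MTMDataSet} or raw source-tissue TPM matrix.
#' @param targetTissue target tissue (must have a trained network).
#' @param destandardize return TPM-scale values (default TRUE).
#' @return samples x genes prediction matrix.
#' @export
predictS3Baseline <- function(fit, x, targetTissue, destandardize = TRUE) {
  stopifnot(inherits(fit, "S3Baseline"))
  net <- fit$models[[targetTissue]]
  if (is.null(net))
    stop("no baseline network for target tissue '", targetTissue, "'")
  if (is(x, "MTMDataSet")) {
    meta <- sampleInfo(x)
    keep <- meta$tissue == fit$sourceTissue
    x <- exprMatrix(x)[keep, , drop = FALSE]
  }
  z <- applyScalers(x, fit$scalers, rep(fit$sourceTissue, nrow(x)))
  pred <- nnForward(net, z)$out
  dimnames(pred) <- dimnames(z)
  if (destandardize)
    pred <- invertScalers(pred, fit$scalers, targetTissue)
  attr(pred, "targetTissue") <- targetTissue
  pred
}

# ---------------------------------------------------------------------------
# simplified linear baselines

#' Train simplified linear single-tissue baselines
#'
#' Two variants, one model per gene per target tissue:
#' \describe{
#'   \item{"ridge"}{ridge regression on the top-\code{k} source genes most
#'     correlated with the target gene (feature selection on training data
#'     only), via \code{MASS::lm.ridge}.}
#'   \item{"lassoPC"}{LASSO (\code{glmnet}) on the leading \code{nPC}
#'     principal components of the training source expression; validation
#'     samples are projected onto the training rotation (no leakage).}
#' }
#'
#' @param x an \linkS4class{MTMDataSet}.
#' @param trainIds training individual IDs.
#' @param sourceTissue fixed input tissue.
#' @param variant "ridge" or "lassoPC".
#' @param targetTissues target tissues (default: all others).
#' @param k number of selected features per gene (ridge variant).
#' @param nPC number of principal components (lassoPC variant).
#' @param lambda penalty strength.
#' @param scalers optional pre-fitted scalers.
#' @return object of class "LinearBaseline".
#' @export
trainLinearBaselines <- function(x, trainIds, sourceTissue = "blood",
                                 variant = c("ridge", "lassoPC"),
                                 targetTissues = NULL, k = 30, nPC = 20,
                                 lambda = 1, scalers = NULL) {
  variant <- match.arg(variant)
  stopifnot(is(x, "MTMDataSet"))
  scalers <- scalers %||% fitScalers(x, trainIds)
  Z <- applyScalers(x, scalers)
  meta <- sampleInfo(x)
  tissues <- rownames(scalers@center)
  targetTissues <- targetTissues %||% setdiff(tissues, sourceTissue)
  fits <- list()
  for (t in targetTissues) {
    src <- meta[meta$tissue == sourceTissue & meta$individual_id %in%
                  trainIds, , drop = FALSE]
    tgt <- meta[meta$tissue == t & meta$individual_id %in% trainIds, ,
                drop = FALSE]
    both <- intersect(src$individual_id, tgt$individual_id)
    if (length(both) < 3) {
      warning("target tissue '", t, "' has too few training individuals; ",
              "skipped")
      next
    }
    X <- Z[src$sample_id[match(both, src$individual_id)], , drop = FALSE]
    Y <- Z[tgt$sample_id[match(both, tgt$individual_id)], , drop = FALSE]
    fits[[t]] <- if (variant == "ridge")
      fitRidgeTissue(X, Y, k, lambda)
    else fitLassoPCTissue(X, Y, nPC, lambda)
  }
  structure(list(fits = fits, variant = variant,
                 sourceTissue = sourceTissue, scalers = scalers,
                 k = k, nPC = nPC, lambda = lambda),
            class = "LinearBaseline")
}

fitRidgeTissue <- function(X, Y, k, lambda) {
  G <- ncol(Y)
  k <- min(k, ncol(X))
  sdY <- apply(Y, 2, stats::sd)
  sdX <- apply(X, 2, stats::sd)
  usable <- which(sdX > 0)
  perGene <- vector("list", G)
  for (g in seq_len(G)) {
    if (sdY[g] == 0) {
      perGene[[g]] <- list(features = integer(), coef = numeric(),
                           intercept = mean(Y[, g]), degenerate = TRUE)
      next
    }
    cors <- abs(suppressWarnings(stats::cor(X[, usable, drop = FALSE],
                                            Y[, g])))
    cors[is.na(cors)] <- 0
    feats <- usable[order(cors, decreasing = TRUE)[seq_len(k)]]
    fit <- MASS::lm.ridge(y ~ ., data = data.frame(
      y = Y[, g], X[, feats, drop = FALSE]), lambda = lambda)
    cf <- stats::coef(fit)
    perGene[[g]] <- list(features = feats, coef = unname(cf[-1]),
                         intercept = unname(cf[1]), degenerate = FALSE)
  }
  list(perGene = perGene, genes = colnames(Y))
}

fitLassoPCTissue <- function(X, Y, nPC, lambda) {
  nPC <- min(nPC, ncol(X), nrow(X) - 1L)
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rot <- pca$rotation[, seq_len(nPC), drop = FALSE]
  ctr <- pca$center
  P <- pca$x[, seq_len(nPC), drop = FALSE]
  G <- ncol(Y)
  perGene <- vector("list", G)
  for (g in seq_len(G)) {
    if (stats::sd(Y[, g]) == 0) {
      perGene[[g]] <- list(coef = numeric(nPC), intercept = mean(Y[, g]),
                           degenerate = TRUE)
      next
    }
    fit <- glmnet::glmnet(P, Y[, g], alpha = 1, lambda = lambda,
                          standardize = FALSE)
    cf <- as.numeric(stats::coef(fit))
    perGene[[g]] <- list(coef = cf[-1], intercept = cf[1],
                         degenerate = FALSE)
  }
  list(perGene = perGene, genes = colnames(Y), rotation = rot, center = ctr)
}

#' Predict with a linear baseline
#'
#' @param fit a "LinearBaseline" from \code{\link{trainLinearBaselines}}.
#' @param x an \linkS4class{MTMDataSet} or raw source-tissue TPM matrix.
#' @param targetTissue target tissue.
#' @param destandardize return TPM-scale values (default TRUE).
#' @return samples x genes prediction matrix.
#' @export
predictLinearBaseline <- function(fit, x, targetTissue,
                                  destandardize = TRUE) {
  stopifnot(inherits(fit, "LinearBaseline"))
  tf <- fit$fits[[targetTissue]]
  if (is.null(tf))
    stop("no linear model for target tissue '", targetTissue, "'")
  if (is(x, "MTMDataSet")) {
    meta <- sampleInfo(x)
    x <- exprMatrix(x)[meta$tissue == fit$sourceTissue, , drop = FALSE]
  }
  z <- applyScalers(x, fit$scalers, rep(fit$sourceTissue, nrow(x)))
  n <- nrow(z)
  pred <- matrix(NA_real_, n, length(tf$perGene),
                 dimnames = list(rownames(z), tf$genes))
  if (fit$variant == "lassoPC") {
    P <- sweep(z, 2, tf$center, "-") %*% tf$rotation
    for (g in seq_along(tf$perGene))
      pred[, g] <- tf$perGene[[g]]$intercept + P %*% tf$perGene[[g]]$coef
  } else {
    for (g in seq_along(tf$perGene)) {
      pg <- tf$perGene[[g]]
      pred[, g] <- if (length(pg$features))
        pg$intercept + z[, pg$features, drop = FALSE] %*% pg$coef
      else rep(pg$intercept, n)
    }
  }
  if (destandardize)
    pred <- invertScalers(pred, fit$scalers, targetTissue)
  attr(pred, "targetTissue") <- targetTissue
  pred
}
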