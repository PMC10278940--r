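#' Loss weights for the combined training objective
#'
#' The total generator-side objective is
#' \code{lambdaAdv * L_adv(G) + lambdaR * L_R + lambdaI * L_I + lambdaC * L_C}
#' where L_R is the latent-code reconstruction loss, L_I the individualized
#' cross-tissue prediction loss and L_C the cycle-consistency loss; the
#' discriminator is trained on the hinge loss alone. \code{lambdaAdv}
#' defaults to 1 (the adversarial term enters the combination with unit
#' weight) but is exposed so the adversarial pressure can be reduced.
#'
#' @param lambdaR,lambdaI,lambdaC,lambdaAdv non-negative finite reals.
#' @return a list of class "LossWeights".
#' @export
lossWeights <- function(lambdaR = 1, lambdaI = 10, lambdaC = 1,
                        lambdaAdv = 1) {
  w <- list(lambdaR = lambdaR, lambdaI = lambdaI, lambdaC = lambdaC,
            lambdaAdv = lambdaAdv)
  bad <- names(w)[!vapply(w, function(v)
    is.numeric(v) && length(v) == 1 && is.finite(v) && v >= 0, logical(1))]
  if (length(bad))
    stop("loss weights must be non-negative finite scalars: ",
         paste(bad, collapse = ", "))
  class(w) <- "LossWeights"
  w
}

#' Hinge adversarial loss, discriminator side (score level)
#'
#' \code{mean(max(0, 1 - realScores)) + mean(max(0, 1 + fakeScores))}.
#' Zero is attained when the discriminator scores all real samples above +1
#' and all generated samples below -1.
#'
#' @param realScores,fakeScores numeric score vectors.
#' @export
hingeLossD <- function(realScores, fakeScores) {
  mean(pmax(0, 1 - realScores)) + mean(pmax(0, 1 + fakeScores))
}

#' Hinge adversarial loss, generator side (score level)
#'
#' Negative mean discriminator score of generated samples.
#' @param fakeScores numeric score vector for generated samples.
#' @export
hingeLossG <- function(fakeScores) -mean(fakeScores)

#' Latent-code reconstruction loss
#'
#' L1 distance between a mapped code c~ and its reconstruction after a
#' round trip through the generator and encoder under the same tissue
#' condition: \code{mean |E(G(c~|t)|t) - c~|}. The mean is taken over both
#' the batch and the latent dimensions.
#'
#' @param model an \linkS4class{MTMModel}
#' @param ctilde latent codes (typically \code{mapNoise(model, z)}).
#' @param tissue tissue condition label(s).
#' @export
reconLoss <- function(model, ctilde, tissue) {
  ctilde <- asBatch(ctilde, model@config$latentDim, "reconLoss")
  rec <- encode(model, generate(model, ctilde, tissue), tissue)
  l1Mean(rec, ctilde)
}

#' Adversarial losses at the model level
#'
#' \code{advLossD} scores a real batch and a generated batch under the target
#' tissue condition and applies the hinge loss; the generated batch is taken
#' as given (no generator gradients are involved at the numeric level).
#' \code{advLossG} is the negative mean score of the generated batch.
#'
#' @param model an \linkS4class{MTMModel}
#' @param xReal,xFake standardized expression batches.
#' @param tissue tissue condition label(s).
#' @export
advLossD <- function(model, xReal, xFake, tissue) {
  hingeLossD(discriminate(model, xReal, tissue),
             discriminate(model, xFake, tissue))
}

#' @rdname advLossD
#' @export
advLossG <- function(model, xFake, tissue) {
  hingeLossG(discriminate(model, xFake, tissue))
}

#' Individualized cross-tissue prediction loss
#'
#' For source/target sample pairs from the same individual:
#' \code{mean |G(E(x_s|s)|t) - x_t|}, mean over batch and genes.
#'
#' @param model an \linkS4class{MTMModel}
#' @param xs,xt standardized source and target expression batches, row i of
#'   both belonging to the same individual.
#' @param s,t source and target tissue labels.
#' @export
individualizedLoss <- function(model, xs, s, xt, t) {
  xs <- asBatch(xs, model@config$geneDim, "individualizedLoss")
  xt <- asBatch(xt, model@config$geneDim, "individualizedLoss")
  if (nrow(xs) != nrow(xt)) stop("source/target batches differ in size")
  pred <- generate(model, encode(model, xs, s), t)
  l1Mean(pred, xt)
}

#' Cycle-consistency loss
#'
#' Translate a source profile to the target tissue and back, then compare to
#' the original: \code{mean |G(E(G(E(x_s|s)|t)|t)|s) - x_s|}.
#'
#' @inheritParams individualizedLoss
#' @export
cycleLoss <- function(model, xs, s, t) {
  xs <- asBatch(xs, model@config$geneDim, "cycleLoss")
  there <- generate(model, encode(model, xs, s), t)
  back <- generate(model, encode(model, there, t), s)
  l1Mean(back, xs)
}

#' Combine loss parts into the training objectives
#'
#' Generator-side objective: \code{lambdaAdv*advG + lambdaR*reconstruction +
#' lambdaI*individualized + lambdaC*cycle}. Discriminator objective: the
#' hinge D loss alone (pass it through \code{advD} for bookkeeping). Which
#' networks each part updates during training: advG and the reconstruction
#' loss update G and M; the individualized and cycle losses update E and G;
#' the discriminator is updated only by its own hinge loss.
#'
#' @param parts named list with elements \code{advG},
#'   \code{reconstruction}, \code{individualized}, \code{cycle} (and
#'   optionally \code{advD}).
#' @param weights a \code{\link{lossWeights}} object.
#' @return list with \code{generator} (the weighted sum) and \code{discriminator}
#'   (advD, or NA if absent).
#' @export
totalLoss <- function(parts, weights = lossWeights()) {
  need <- c("advG", "reconstruction", "individualized", "cycle")
  miss <- setdiff(need, names(parts))
  if (length(miss))
    stop("missing loss part(s): ", paste(miss, collapse = ", "))
  for (p in need)
    if (!is.finite(parts[[p]]))
      stop("non-finite loss part: ", p)
  gen <- weights$lambdaAdv * parts$advG +
    weights$lambdaR * parts$reconstruction +
    weights$lambdaI * parts$individualized +
    weights$lambdaC * parts$cycle
  list(generator = gen,
       discriminator = if (!is.null(parts$advD)) parts$advD else NA_real_)
}
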