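#' Pearson correlation with explicit undefined-value handling
#'
#' Standard Pearson formula; returns NA (the undefined flag) when either
#' vector is constant, rather than erroring or zero-filling.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return correlation in [-1, 1], or NA when undefined.
#' @export
pearsonRho <- function(x, y) {
  if (length(x) != length(y))
    stop("length mismatch: ", length(x), " vs ", length(y))
  if (length(x) < 2) stop("need at least 2 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

checkAligned <- function(pred, obs) {
  if (!identical(dim(pred), dim(obs)))
    stop("prediction and observation matrices differ in shape")
  if (!identical(rownames(pred), rownames(obs)) ||
      !identical(colnames(pred), colnames(obs)))
    stop("prediction and observation matrices are not aligned ",
         "(sample/gene identifiers differ)")
}

#' Sample-wise prediction accuracy
#'
#' Per sample, Pearson rho across all genes between the predicted and the
#' observed standardized profile, grouped by tissue. Computed on Z-scored
#' data so the statistic reflects individual variance within each tissue.
#'
#' @param pred,obs aligned samples x genes matrices in standardized space.
#' @param tissue per-sample tissue labels.
#' @return data.frame (sample, tissue, rho); NA rho flags undefined
#'   (constant-profile) cases.
#' @export
samplewiseAccuracy <- function(pred, obs, tissue) {
  checkAligned(pred, obs)
  if (length(tissue) != nrow(pred))
    stop("tissue labels must match the number of samples")
  rho <- vapply(seq_len(nrow(pred)),
                function(i) {
                  if (stats::sd(pred[i, ]) == 0 || stats::sd(obs[i, ]) == 0)
                    NA_real_ else stats::cor(pred[i, ], obs[i, ])
                }, numeric(1))
  data.frame(sample = rownames(pred) %||% as.character(seq_along(rho)),
             tissue = as.character(tissue), rho = rho,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Gene-wise prediction accuracy
#'
#' Per (tissue, gene), Pearson rho across individuals between predicted and
#' observed expression. Pearson rho is invariant to per-gene affine
#' standardization, so standardized and raw scales coincide. Tissues with a
#' single individual are skipped with a warning; constant genes are flagged
#' NA.
#'
#' @inheritParams samplewiseAccuracy
#' @return data.frame (tissue, gene, rho).
#' @export
genewiseAccuracy <- function(pred, obs, tissue) {
  checkAligned(pred, obs)
  if (length(tissue) != nrow(pred))
    stop("tissue labels must match the number of samples")
  out <- list()
  for (t in unique(tissue)) {
    rows <- which(tissue == t)
    if (length(rows) < 2) {
      warning("tissue '", t, "' has a single sample; skipped")
      next
    }
    P <- pred[rows, , drop = FALSE]
    O <- obs[rows, , drop = FALSE]
    sdP <- apply(P, 2, stats::sd)
    sdO <- apply(O, 2, stats::sd)
    rho <- rep(NA_real_, ncol(P))
    ok <- sdP > 0 & sdO > 0
    if (any(ok)) {
      cp <- colSums(scale(P[, ok, drop = FALSE], scale = FALSE) *
                      scale(O[, ok, drop = FALSE], scale = FALSE))
      rho[ok] <- cp / ((length(rows) - 1) * sdP[ok] * sdO[ok])
    }
    out[[t]] <- data.frame(tissue = t,
                           gene = colnames(P) %||%
                             as.character(seq_len(ncol(P))),
                           rho = rho, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predictable genes (pGenes)
#'
#' Genes whose gene-wise rho is strictly greater than the threshold;
#' undefined (NA-flagged) correlations never qualify.
#'
#' @param geneRho either a numeric vector of gene-wise rho values (named or
#'   not) or the data.frame returned by \code{\link{genewiseAccuracy}}.
#' @param threshold strict lower bound (default 0.3).
#' @return for a vector: the names (or indices) of qualifying genes; for a
#'   data.frame: a named list of qualifying gene ID vectors per tissue.
#' @export
countPGenes <- function(geneRho, threshold = 0.3) {
  if (is.data.frame(geneRho)) {
    out <- lapply(split(geneRho, geneRho$tissue), function(df)
      df$gene[!is.na(df$rho) & df$rho > threshold])
    return(out[unique(geneRho$tissue)])
  }
  hit <- !is.na(geneRho) & geneRho > threshold
  if (!is.null(names(geneRho))) names(geneRho)[hit] else which(hit)
}

#' Assemble an EvaluationReport from aligned predictions
#'
#' @param pred,obs aligned standardized matrices.
#' @param tissue per-sample tissue labels.
#' @param threshold pGene threshold (default 0.3).
#' @param modelId label stored in the report.
#' @param folds fold-provenance list (optional).
#' @return an \linkS4class{EvaluationReport}.
#' @export
evaluatePredictions <- function(pred, obs, tissue, threshold = 0.3,
                                modelId = "model", folds = list()) {
  sw <- samplewiseAccuracy(pred, obs, tissue)
  gw <- genewiseAccuracy(pred, obs, tissue)
  new("EvaluationReport", sampleRho = sw, geneRho = gw,
      pGenes = countPGenes(gw, threshold), threshold = threshold,
      modelId = modelId, folds = folds)
}

#' Cross-validated evaluation with concatenated predictions
#'
#' Individual-level k-fold protocol: for each fold, a model is fitted on the
#' other k-1 folds by \code{factory}, the held-out individuals' target
#' tissues are predicted from their source-tissue (blood analogue) profiles,
#' predictions are concatenated across folds, and all statistics are
#' computed once on the concatenated matrices. Observed data are
#' standardized with each fold's training-only scaling factors.
#'
#' @param x an \linkS4class{MTMDataSet}.
#' @param factory function(x, trainIds) returning a list with elements
#'   \code{predictStd = function(sourceRaw, targetTissue, targetSamples)}
#'   (standardized predictions for the given source samples) and
#'   \code{scalers} (the fold's \linkS4class{TissueScalers}).
#' @param k number of folds (default 5).
#' @param sourceTissue the input tissue used at evaluation time.
#' @param seed fold-assignment seed.
#' @param threshold pGene threshold.
#' @param modelId label stored in the report.
#' @return an \linkS4class{EvaluationReport}.
#' @export
crossvalEvaluate <- function(x, factory, k = 5, sourceTissue = "blood",
                             seed = 1, threshold = 0.3, modelId = "model") {
  stopifnot(is(x, "MTMDataSet"))
  meta <- sampleInfo(x)
  expr <- exprMatrix(x)
  folds <- makeCVFolds(x, k = k, seed = seed)
  targets <- setdiff(unique(meta$tissue), sourceTissue)
  predAll <- list()
  obsAll <- list()
  tisAll <- list()
  for (j in seq_along(folds)) {
    trainIds <- folds[[j]]$train
    testIds <- folds[[j]]$test
    srcMeta <- meta[meta$tissue == sourceTissue &
                      meta$individual_id %in% testIds, , drop = FALSE]
    if (!nrow(srcMeta))
      stop("fold ", j, " has no ", sourceTissue, " samples to use as input")
    fit <- factory(x, trainIds)
    for (t in targets) {
      tgtMeta <- meta[meta$tissue == t &
                        meta$individual_id %in% testIds, , drop = FALSE]
      both <- intersect(srcMeta$individual_id, tgtMeta$individual_id)
      if (!length(both)) next
      srcSamp <- srcMeta$sample_id[match(both, srcMeta$individual_id)]
      tgtSamp <- tgtMeta$sample_id[match(both, tgtMeta$individual_id)]
      p <- fit$predictStd(expr[srcSamp, , drop = FALSE], t, tgtSamp)
      rownames(p) <- tgtSamp
      o <- applyScalers(expr[tgtSamp, , drop = FALSE], fit$scalers,
                        rep(t, length(tgtSamp)))
      predAll[[length(predAll) + 1L]] <- p
      obsAll[[length(obsAll) + 1L]] <- o
      tisAll[[length(tisAll) + 1L]] <- rep(t, length(tgtSamp))
    }
  }
  if (!length(predAll)) stop("no evaluable (source, target) individuals")
  evaluatePredictions(do.call(rbind, predAll), do.call(rbind, obsAll),
                      unlist(tisAll), threshold = threshold,
                      modelId = modelId,
                      folds = lapply(folds, `[[`, "test"))
}

#' Cross-validation factories for the bundled models
#'
#' Adapters plugging \code{\link{trainMTM}}, \code{\link{trainS3Baseline}}
#' and an identity oracle (predicts the observed standardized target data;
#' useful for protocol bookkeeping checks) into
#' \code{\link{crossvalEvaluate}}.
#'
#' @param sourceTissue evaluation-time input tissue.
#' @param config a \code{\link{trainConfig}}.
#' @param ... passed to the underlying training function.
#' @return a factory function(x, trainIds).
#' @export
mtmFactory <- function(sourceTissue = "blood", config = trainConfig(), ...) {
  function(x, trainIds) {
    res <- trainMTM(x, trainIds, config = config, ...)
    list(predictStd = function(sourceRaw, targetTissue, targetSamples) {
      predictTissue(res$model, sourceRaw, targetTissue,
                    tissue = rep(sourceTissue, nrow(sourceRaw)),
                    destandardize = FALSE)
    }, scalers = res$scalers)
  }
}

#' @rdname mtmFactory
#' @export
s3Factory <- function(sourceTissue = "blood", config = trainConfig(), ...) {
  function(x, trainIds) {
    fit <- trainS3Baseline(x, trainIds, sourceTissue = sourceTissue,
                           config = config, ...)
    list(predictStd = function(sourceRaw, targetTissue, targetSamples) {
      predictS3Baseline(fit, sourceRaw, targetTissue, destandardize = FALSE)
    }, scalers = fit$scalers)
  }
}

#' @rdname mtmFactory
#' @export
identityFactory <- function() {
  function(x, trainIds) {
    scalers <- fitScalers(x, trainIds)
    expr <- exprMatrix(x)
    meta <- sampleInfo(x)
    list(predictStd = function(sourceRaw, targetTissue, targetSamples) {
      applyScalers(expr[targetSamples, , drop = FALSE], scalers,
                   rep(targetTissue, length(targetSamples)))
    }, scalers = scalers)
  }
}
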