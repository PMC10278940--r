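#' Pairwise tissue similarity
#'
#' Pearson rho across genes between per-tissue mean expression profiles on
#' the log2(TPM + pseudocount) scale. Symmetric with unit diagonal; tissues
#' without samples are excluded.
#'
#' @param x an \linkS4class{MTMDataSet} or samples x genes TPM matrix.
#' @param tissue per-sample tissue labels (from \code{x} if an MTMDataSet).
#' @param log2 average on the log2 scale (default TRUE).
#' @param pseudocount pseudocount for the log transform (default 1).
#' @return tissue x tissue correlation matrix.
#' @export
tissueSimilarity <- function(x, tissue = NULL, log2 = TRUE,
                             pseudocount = 1) {
  if (is(x, "MTMDataSet")) {
    tissue <- colData(x)$tissue
    x <- exprMatrix(x)
  }
  if (length(tissue) != nrow(x))
    stop("tissue labels must match the number of samples")
  tset <- unique(tissue)
  if (length(tset) < 2) stop("need at least 2 tissues")
  if (log2) x <- base::log2(x + pseudocount)
  means <- vapply(tset, function(t)
    colMeans(x[tissue == t, , drop = FALSE]), numeric(ncol(x)))
  sim <- stats::cor(means)
  dimnames(sim) <- list(tset, tset)
  sim
}

#' Spearman agreement between two pairwise tissue matrices
#'
#' Flattens the upper triangles (diagonal excluded) of two symmetric
#' matrices over the same tissue set and computes Spearman's rho with
#' average ranks for ties.
#'
#' @param statMatrix,simMatrix symmetric tissue x tissue matrices with
#'   identical dimensions (and dimnames, when present).
#' @return Spearman rho (NA when either flattened vector is constant).
#' @export
comparePairwiseToSimilarity <- function(statMatrix, simMatrix) {
  if (!identical(dim(statMatrix), dim(simMatrix)))
    stop("matrices differ in dimension")
  if (!is.null(dimnames(statMatrix)) && !is.null(dimnames(simMatrix)) &&
      !identical(rownames(statMatrix), rownames(simMatrix)))
    stop("matrices cover different tissue sets")
  ut <- upper.tri(statMatrix)
  a <- statMatrix[ut]
  b <- simMatrix[ut]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = "spearman")
}

#' Intra- vs inter-individual latent-code similarity
#'
#' Encodes every sample with its own tissue label, computes all pairwise
#' Pearson correlations between latent codes, and partitions them into
#' intra-individual pairs (different samples of the same individual) and
#' inter-individual pairs. A two-group Wilcoxon rank-sum test summarizes the
#' gap.
#'
#' @param model an \linkS4class{MTMModel} carrying TissueScalers.
#' @param x an \linkS4class{MTMDataSet}.
#' @return list with \code{intra}, \code{inter} (rho vectors),
#'   \code{meanIntra}, \code{meanInter}, and \code{pValue}.
#' @export
latentCodeSimilarity <- function(model, x) {
  stopifnot(is(model, "MTMModel"), is(x, "MTMDataSet"))
  if (is.null(model@scalers))
    stop("model carries no TissueScalers")
  z <- applyScalers(x, model@scalers)
  cd <- colData(x)
  codes <- encode(model, z, cd$tissue)
  cc <- suppressWarnings(stats::cor(t(codes)))
  n <- nrow(codes)
  same <- outer(cd$individual, cd$individual, "==")
  ut <- upper.tri(cc)
  intra <- cc[ut & same]
  inter <- cc[ut & !same]
  pv <- if (length(intra) && length(inter))
    stats::wilcox.test(intra, inter)$p.value else NA_real_
  list(intra = intra, inter = inter,
       meanIntra = mean(intra), meanInter = mean(inter), pValue = pv)
}

#' Decoding-path similarity across tissue conditions
#'
#' Decodes one latent code under every tissue condition, computes per
#' generator layer the pairwise Pearson similarity of the activations across
#' tissues, and compares each layer's similarity matrix to a reference
#' tissue-similarity matrix with Spearman's rho.
#'
#' @param model an \linkS4class{MTMModel}.
#' @param code a single latent code (vector or 1-row matrix).
#' @param tissues tissue labels to decode to (>= 3).
#' @param simMatrix reference tissue x tissue similarity over
#'   \code{tissues}.
#' @return numeric vector: one Spearman rho per generator layer (NA flags a
#'   degenerate, constant-similarity layer).
#' @export
decodingPathSimilarity <- function(model, code, tissues, simMatrix) {
  if (length(tissues) < 3)
    stop("need at least 3 tissues for a meaningful rank correlation")
  if (is.null(dim(code))) code <- matrix(code, nrow = 1)
  if (nrow(code) != 1) stop("provide a single latent code")
  acts <- lapply(tissues, function(t) collectActivations(model, code, t))
  nLayers <- length(acts[[1]])
  sub <- simMatrix[tissues, tissues]
  vapply(seq_len(nLayers), function(l) {
    A <- vapply(acts, function(a) drop(a[[l]]),
                numeric(length(acts[[1]][[l]])))
    sims <- suppressWarnings(stats::cor(A))
    dimnames(sims) <- list(tissues, tissues)
    if (anyNA(sims[upper.tri(sims)])) return(NA_real_)
    comparePairwiseToSimilarity(sims, sub)
  }, numeric(1))
}

#' Trait-association preservation
#'
#' Per gene, the Pearson association between expression and a per-individual
#' trait is computed in the predicted and in the observed data; the
#' preservation statistic is the Pearson rho across genes between the two
#' association vectors, per tissue. Restricting to pGenes (the paper-style
#' protocol) is supported through \code{genes}.
#'
#' @param pred,obs aligned samples x genes matrices (any common scale; the
#'   statistic is correlation-based).
#' @param tissue per-sample tissue labels.
#' @param trait numeric trait value per sample (i.e. per individual, repeated
#'   for each of their samples).
#' @param genes optional gene subset: character vector, or named list per
#'   tissue (e.g. from \code{\link{countPGenes}}).
#' @return data.frame (tissue, rho, nGenes).
#' @export
traitAssociationPreservation <- function(pred, obs, tissue, trait,
                                         genes = NULL) {
  checkAligned(pred, obs)
  if (length(trait) != nrow(pred))
    stop("trait must have one value per sample")
  out <- list()
  for (t in unique(tissue)) {
    rows <- which(tissue == t)
    if (length(rows) < 3) next
    tv <- trait[rows]
    if (stats::sd(tv) == 0) stop("trait is constant within tissue '", t, "'")
    gsel <- if (is.list(genes)) genes[[t]] else genes
    gsel <- gsel %||% colnames(pred)
    gsel <- intersect(gsel, colnames(pred))
    if (length(gsel) < 3) next
    P <- pred[rows, gsel, drop = FALSE]
    O <- obs[rows, gsel, drop = FALSE]
    aP <- suppressWarnings(as.numeric(stats::cor(P, tv)))
    aO <- suppressWarnings(as.numeric(stats::cor(O, tv)))
    ok <- !is.na(aP) & !is.na(aO)
    rho <- if (sum(ok) >= 3 && stats::sd(aP[ok]) > 0 &&
               stats::sd(aO[ok]) > 0)
      stats::cor(aP[ok], aO[ok]) else NA_real_
    out[[t]] <- data.frame(tissue = t, rho = rho, nGenes = sum(ok),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-group differential expression by Wilcoxon rank-sum test
#'
#' Per gene, a two-sided Wilcoxon rank-sum test between cases and controls
#' (exact for small untied samples, normal approximation with tie correction
#' otherwise, as in \code{stats::wilcox.test}), Benjamini-Hochberg FDR, and
#' \code{log2fc = log2(mean_case + pseudocount) - log2(mean_control +
#' pseudocount)} on the TPM scale.
#'
#' @param expr samples x genes TPM matrix.
#' @param group logical or 0/1 vector, TRUE/1 = case.
#' @param minGroupN minimum samples per group (default 10; error below it).
#' @param pseudocount log2fc pseudocount (default 1).
#' @param fdrThreshold significance threshold for the direction call
#'   (default 0.05).
#' @return data.frame (gene, log2fc, p_value, fdr, direction); direction is
#'   "none" unless fdr < fdrThreshold.
#' @export
deAnalysis <- function(expr, group, minGroupN = 10, pseudocount = 1,
                       fdrThreshold = 0.05) {
  group <- as.logical(group)
  if (length(group) != nrow(expr))
    stop("group must have one value per sample")
  nCase <- sum(group)
  nCtrl <- sum(!group)
  if (min(nCase, nCtrl) < minGroupN)
    stop("each group needs at least minGroupN = ", minGroupN,
         " samples (got ", nCase, " cases, ", nCtrl, " controls)")
  ca <- expr[group, , drop = FALSE]
  co <- expr[!group, , drop = FALSE]
  pv <- vapply(seq_len(ncol(expr)), function(g)
    suppressWarnings(stats::wilcox.test(ca[, g], co[, g],
                                        alternative = "two.sided"))$p.value,
    numeric(1))
  lfc <- log2(colMeans(ca) + pseudocount) - log2(colMeans(co) + pseudocount)
  fdr <- stats::p.adjust(pv, method = "BH")
  dir <- ifelse(fdr < fdrThreshold,
                ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
                "none")
  data.frame(gene = colnames(expr) %||% as.character(seq_along(pv)),
             log2fc = unname(lfc), p_value = pv, fdr = fdr, direction = dir,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Concordance between two differential-expression results
#'
#' Over a shared gene universe: the fraction of genes whose log2 fold
#' changes share a sign (genes with a zero fold change in either result are
#' excluded from numerator and denominator), the Pearson rho of the fold
#' changes, upper-tail hypergeometric overlap p-values for the up- and
#' down-regulated DEG sets, and F1 scores treating the reference DEGs as
#' truth. An empty reference DEG set flags the corresponding overlap/F1 as
#' NA (undefined), never zero.
#'
#' @param dePred,deRef data.frames from \code{\link{deAnalysis}} over the
#'   same genes.
#' @return list of class "ConcordanceReport" with signConsistency, lfcRho,
#'   overlapPUp, overlapPDown, f1Up, f1Down.
#' @export
concordance <- function(dePred, deRef) {
  if (!setequal(dePred$gene, deRef$gene))
    stop("prediction and reference cover different gene universes")
  deRef <- deRef[match(dePred$gene, deRef$gene), , drop = FALSE]
  nz <- dePred$log2fc != 0 & deRef$log2fc != 0
  signCons <- if (any(nz))
    mean(sign(dePred$log2fc[nz]) == sign(deRef$log2fc[nz])) else NA_real_
  lfcRho <- pearsonRho(dePred$log2fc, deRef$log2fc)
  N <- nrow(dePred)
  one <- function(dirn) {
    refSet <- deRef$gene[deRef$direction == dirn]
    predSet <- dePred$gene[dePred$direction == dirn]
    if (!length(refSet))
      return(list(p = NA_real_, f1 = NA_real_))
    ov <- length(intersect(refSet, predSet))
    p <- stats::phyper(ov - 1, length(refSet), N - length(refSet),
                       length(predSet), lower.tail = FALSE)
    f1 <- if (!length(predSet)) 0
    else {
      prec <- ov / length(predSet)
      rec <- ov / length(refSet)
      if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }
    list(p = p, f1 = f1)
  }
  up <- one("up")
  dn <- one("down")
  structure(list(signConsistency = signCons, lfcRho = lfcRho,
                 overlapPUp = up$p, overlapPDown = dn$p,
                 f1Up = up$f1, f1Down = dn$f1),
            class = "ConcordanceReport")
}
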