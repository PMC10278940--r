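#' @importFrom SummarizedExperiment assays
NULL

#' Expression matrix in samples x genes orientation
#'
#' @param x an \linkS4class{MTMDataSet}
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
exprMatrix <- function(x) {
  stopifnot(is(x, "MTMDataSet"))
  t(assay(x, "expr"))
}

#' Sample metadata as a plain data.frame
#'
#' @param x an \linkS4class{MTMDataSet}
#' @return data.frame with sample_id, individual_id, tissue.
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "MTMDataSet"))
  cd <- colData(x)
  data.frame(sample_id = rownames(cd),
             individual_id = cd$individual,
             tissue = cd$tissue,
             stringsAsFactors = FALSE)
}

#' Tissue labels present in a cohort
#' @param x an \linkS4class{MTMDataSet}
#' @export
cohortTissues <- function(x) sort(unique(colData(x)$tissue))

#' Individual identifiers present in a cohort
#' @param x an \linkS4class{MTMDataSet}
#' @export
cohortIndividuals <- function(x) sort(unique(colData(x)$individual))

#' Per-individual trait table of a cohort (or NULL)
#' @param x an \linkS4class{MTMDataSet}
#' @export
cohortTraits <- function(x) metadata(x)$traits

#' Simulation ground truth attached to a cohort (or NULL)
#' @param x an \linkS4class{MTMDataSet}
#' @export
cohortTruth <- function(x) metadata(x)$truth

#' @describeIn TissueScalers-class tissue x gene matrix of recorded means
#' @param object a \linkS4class{TissueScalers}
#' @export
scalerMeans <- function(object) object@center

#' @describeIn TissueScalers-class tissue x gene matrix of recorded sds
#' @export
scalerSds <- function(object) object@scale

#' @describeIn EvaluationReport-class per-sample accuracy table
#' @param object an \linkS4class{EvaluationReport}
#' @export
sampleRho <- function(object) object@sampleRho

#' @describeIn EvaluationReport-class per-gene accuracy table
#' @export
geneRho <- function(object) object@geneRho

#' @describeIn EvaluationReport-class per-tissue predictable-gene sets
#' @export
pGenes <- function(object) object@pGenes

#' @describeIn MTMModel-class the declared tissue vocabulary
#' @param object an \linkS4class{MTMModel}
#' @export
modelTissues <- function(object) object@tissues

#' @describeIn MTMModel-class architecture configuration list
#' @export
modelConfig <- function(object) object@config

#' @describeIn MTMModel-class the attached TissueScalers (or NULL)
#' @export
modelScalers <- function(object) object@scalers

setMethod("show", "MTMDataSet", function(object) {
  cd <- colData(object)
  cat("MTMDataSet:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  individuals:", length(unique(cd$individual)),
      " tissues:", length(unique(cd$tissue)), "\n")
  if (!is.null(metadata(object)$truth))
    cat("  simulation ground truth attached\n")
  invisible(NULL)
})

setMethod("show", "TissueScalers", function(object) {
  cat("TissueScalers:", nrow(object@center), "tissues x",
      ncol(object@center), "genes",
      if (object@log2) sprintf("(log2(x + %g) scale)", object@pseudocount)
      else "(raw scale)", "\n")
  nz <- sum(object@zeroSd)
  if (nz) cat("  zero-sd (tissue, gene) entries flagged:", nz, "\n")
  invisible(NULL)
})

setMethod("show", "MTMModel", function(object) {
  cfg <- object@config
  cat("MTMModel (conditional encoder-generator)\n")
  cat("  genes:", cfg$geneDim, " latent:", cfg$latentDim,
      " noise:", cfg$noiseDim, "\n")
  cat("  encoder widths:", paste(cfg$hidden, collapse = "-"),
      "| tissues:", length(object@tissues), "\n")
  invisible(NULL)
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport [", object@modelId, "]\n", sep = "")
  sr <- object@sampleRho$rho; gr <- object@geneRho$rho
  cat(sprintf("  sample-wise rho: mean %.3f (n=%d)\n",
              mean(sr, na.rm = TRUE), length(sr)))
  cat(sprintf("  gene-wise rho:   mean %.3f (n=%d)\n",
              mean(gr, na.rm = TRUE), length(gr)))
  cat("  pGenes (rho >", object@threshold, "):",
      paste(vapply(names(object@pGenes),
                   function(t) sprintf("%s=%d", t, length(object@pGenes[[t]])),
                   character(1)), collapse = " "), "\n")
  invisible(NULL)
})
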