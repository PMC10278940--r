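#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MTMDataSet: a multi-tissue, multi-individual expression cohort
#'
#' Extends \linkS4class{SummarizedExperiment}. The single assay \code{"expr"}
#' holds genes x samples expression values (TPM-like, non-negative on input;
#' standardized variants are unbounded). \code{colData} must carry an
#' \code{individual} and a \code{tissue} column. Per-individual trait tables
#' and simulation ground truth, when present, live in \code{metadata()} under
#' \code{traits} and \code{truth}.
#'
#' @slot .   see \linkS4class{SummarizedExperiment}
#' @export
setClass("MTMDataSet", contains = "SummarizedExperiment")

setValidity("MTMDataSet", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!all(c("individual", "tissue") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'individual' and 'tissue' columns")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be present and unique")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (length(assays(object)) >= 1L && !all(is.finite(assay(object))))
    msg <- c(msg, "expression values must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct an MTMDataSet
#'
#' @param expr numeric matrix, samples x genes (rows = samples, matching the
#'   on-disk orientation), with sample IDs as rownames and gene IDs as
#'   colnames.
#' @param meta data.frame with columns \code{sample_id}, \code{individual_id},
#'   \code{tissue}; every row of \code{expr} must have exactly one record.
#' @param traits optional per-individual data.frame (keyed by
#'   \code{individual_id}).
#' @param truth optional simulation ground-truth list.
#' @return an \linkS4class{MTMDataSet}
#' @export
MTMDataSet <- function(expr, meta, traits = NULL, truth = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs sample rownames and gene colnames")
  req <- c("sample_id", "individual_id", "tissue")
  if (!all(req %in% colnames(meta)))
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  missing_meta <- setdiff(rownames(expr), meta$sample_id)
  if (length(missing_meta))
    stop("metadata missing for sample(s): ",
         paste(utils::head(missing_meta, 5), collapse = ", "))
  extra_meta <- setdiff(meta$sample_id, rownames(expr))
  if (length(extra_meta))
    stop("metadata has record(s) with no expression sample: ",
         paste(utils::head(extra_meta, 5), collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  meta <- meta[match(rownames(expr), meta$sample_id), , drop = FALSE]
  cd <- DataFrame(individual = as.character(meta$individual_id),
                  tissue = as.character(meta$tissue),
                  row.names = meta$sample_id)
  se <- SummarizedExperiment(assays = list(expr = t(expr)), colData = cd)
  obj <- new("MTMDataSet", se)
  if (!is.null(traits)) metadata(obj)$traits <- traits
  if (!is.null(truth)) metadata(obj)$truth <- truth
  validObject(obj)
  obj
}

#' Per-tissue per-gene Z-scoring factors
#'
#' Means and standard deviations learned on training samples only, applied to
#' any sample of a known tissue; the scaling factors are recorded so that
#' validation/external data are standardized without information leakage.
#'
#' @slot center tissue x gene matrix of means (on the modelling scale).
#' @slot scale tissue x gene matrix of standard deviations (>= 0; zeros are
#'   legal and flagged, see \code{zeroSd}).
#' @slot log2 logical; whether values are log2(x + pseudocount) transformed
#'   before standardization.
#' @slot pseudocount numeric pseudocount used by the log transform.
#' @slot zeroSd logical tissue x gene matrix flagging sd == 0 entries.
#' @export
setClass("TissueScalers",
  representation(center = "matrix", scale = "matrix", log2 = "logical",
                 pseudocount = "numeric", zeroSd = "matrix"))

setValidity("TissueScalers", function(object) {
  msg <- character()
  if (!identical(dim(object@center), dim(object@scale)))
    msg <- c(msg, "center and scale must have identical dimensions")
  if (any(object@scale < 0)) msg <- c(msg, "scale must be non-negative")
  if (is.null(rownames(object@center)) || is.null(colnames(object@center)))
    msg <- c(msg, "center/scale need tissue rownames and gene colnames")
  if (length(msg)) msg else TRUE
})

#' The four-network multi-task model
#'
#' Holds the unified encoder E, generator G, discriminator D and mapping
#' network M, all assembled from tissue-conditioning blocks (shared dense
#' layer + per-tissue learnable affine + leaky ReLU), plus the architecture
#' configuration, the tissue vocabulary, and (optionally) the
#' \linkS4class{TissueScalers} used to (de)standardize data.
#'
#' @slot encoder,generator,discriminator,mapper internal network lists.
#' @slot tissues character vector: the declared tissue vocabulary.
#' @slot config list of architecture hyperparameters.
#' @slot scalers a \linkS4class{TissueScalers} or NULL.
#' @export
setClass("MTMModel",
  representation(encoder = "list", generator = "list",
                 discriminator = "list", mapper = "list",
                 tissues = "character", config = "list", scalers = "ANY"))

setValidity("MTMModel", function(object) {
  msg <- character()
  if (!length(object@tissues)) msg <- c(msg, "tissue vocabulary is empty")
  ok <- vapply(list(object@encoder, object@generator, object@discriminator,
                    object@mapper),
               function(n) all(vapply(n$layers, function(l)
                 all(is.finite(l$W)) && all(is.finite(l$b)), logical(1))),
               logical(1))
  if (!all(ok)) msg <- c(msg, "network parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' Accuracy report for cross-tissue prediction
#'
#' @slot sampleRho data.frame (sample, tissue, rho): per-sample Pearson rho
#'   across genes between predicted and observed standardized profiles.
#' @slot geneRho data.frame (tissue, gene, rho): per-gene Pearson rho across
#'   individuals within each tissue; NA flags undefined (constant) cases.
#' @slot pGenes named list of character vectors, per tissue: genes with
#'   gene-wise rho strictly above \code{threshold}.
#' @slot threshold numeric pGene threshold (default 0.3).
#' @slot modelId character label of the evaluated model.
#' @slot folds list describing fold provenance (may be empty).
#' @export
setClass("EvaluationReport",
  representation(sampleRho = "data.frame", geneRho = "data.frame",
                 pGenes = "list", threshold = "numeric",
                 modelId = "character", folds = "list"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  r <- object@geneRho$rho
  if (length(r) && any(abs(r) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "gene-wise rho outside [-1, 1]")
  r <- object@sampleRho$rho
  if (length(r) && any(abs(r) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "sample-wise rho outside [-1, 1]")
  if (length(msg)) msg else TRUE
})
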