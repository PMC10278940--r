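#' Read an expression table (samples x genes)
#'
#' Tab- or comma-delimited text with a header row of gene identifiers and the
#' sample identifier in the first column; gzip-compressed files are read
#' transparently.
#'
#' @param path file path.
#' @param sep field separator; NULL (default) auto-detects tab vs comma from
#'   the header line.
#' @return numeric matrix, samples x genes, with dimnames.
#' @export
readExpression <- function(path, sep = NULL) {
  sep <- sep %||% detectSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate sample identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad))
    stop("non-numeric expression column(s) in ", path, ": ",
         paste(utils::head(colnames(vals)[bad], 5), collapse = ", "))
  if (anyDuplicated(colnames(vals)))
    stop("duplicate gene identifiers in ", path)
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (!all(is.finite(m))) stop("non-finite expression values in ", path)
  m
}

#' Read a sample metadata table
#'
#' Expects columns sample_id, individual_id, tissue.
#' @inheritParams readExpression
#' @return data.frame.
#' @export
readMetadata <- function(path, sep = NULL) {
  sep <- sep %||% detectSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("sample_id", "individual_id", "tissue")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("metadata ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in ", path)
  df[req]
}

detectSep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (lengths(regmatches(l1, gregexpr("\t", l1))) > 0) "\t"
  else if (lengths(regmatches(l1, gregexpr(",", l1, fixed = TRUE))) > 0) ","
  else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter a cohort to well-sampled tissues and multi-sample individuals
#'
#' Iterates to a fixed point: tissues with fewer than \code{minTissueN}
#' samples are removed, then individuals with fewer than
#' \code{minSamplesPerIndividual} remaining samples, and so on. The defaults
#' keep tissues with sample sizes strictly greater than 50 and individuals
#' with at least two samples.
#'
#' @param x an \linkS4class{MTMDataSet}.
#' @param minTissueN minimum per-tissue sample count (default 51).
#' @param minSamplesPerIndividual minimum per-individual sample count
#'   (default 2).
#' @return the filtered \linkS4class{MTMDataSet}.
#' @export
filterCohort <- function(x, minTissueN = 51, minSamplesPerIndividual = 2) {
  stopifnot(is(x, "MTMDataSet"))
  repeat {
    cd <- colData(x)
    tn <- table(cd$tissue)
    keepT <- cd$tissue %in% names(tn)[tn >= minTissueN]
    x2 <- x[, keepT]
    cd <- colData(x2)
    if (ncol(x2)) {
      im <- table(cd$individual)
      keepI <- cd$individual %in% names(im)[im >= minSamplesPerIndividual]
      x2 <- x2[, keepI]
    }
    if (ncol(x2) == 0)
      stop("no data after filtering (minTissueN=", minTissueN,
           ", minSamplesPerIndividual=", minSamplesPerIndividual, ")")
    if (ncol(x2) == ncol(x)) return(x2)
    x <- x2
  }
}

#' Split individuals into training and validation sets
#'
#' The partition is by individual: every sample follows its individual, so no
#' individual ever spans both sets.
#'
#' @param x an \linkS4class{MTMDataSet} or a metadata data.frame with an
#'   \code{individual_id} column.
#' @param trainFraction fraction of individuals assigned to training
#'   (default 0.8).
#' @param seed integer seed; the split is deterministic given it.
#' @return list with character vectors \code{train} and \code{validation}.
#' @export
splitByIndividual <- function(x, trainFraction = 0.8, seed = 1) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  ids <- individualIdsOf(x)
  if (length(ids) < 2) stop("need at least 2 individuals to split")
  set.seed(seed)
  ids <- sample(ids)
  nTrain <- round(length(ids) * trainFraction)
  nTrain <- max(1L, min(length(ids) - 1L, nTrain))
  list(train = sort(ids[seq_len(nTrain)]),
       validation = sort(ids[-seq_len(nTrain)]))
}

individualIdsOf <- function(x) {
  if (is(x, "MTMDataSet")) unique(colData(x)$individual)
  else if (is.data.frame(x)) unique(x$individual_id)
  else stop("expected an MTMDataSet or a metadata data.frame")
}

#' k-fold cross-validation partitions by individual
#'
#' Each individual appears in exactly one test fold; fold sizes differ by at
#' most one individual.
#'
#' @inheritParams splitByIndividual
#' @param k number of folds (>= 2).
#' @return list of k lists, each with \code{train} and \code{test} individual
#'   ID vectors.
#' @export
makeCVFolds <- function(x, k = 5, seed = 1) {
  ids <- individualIdsOf(x)
  if (k < 2) stop("k must be >= 2")
  if (k > length(ids))
    stop("k = ", k, " exceeds the number of individuals (", length(ids), ")")
  set.seed(seed)
  ids <- sample(ids)
  fold <- rep(seq_len(k), length.out = length(ids))
  lapply(seq_len(k), function(j)
    list(train = sort(ids[fold != j]), test = sort(ids[fold == j])))
}

#' Fit per-tissue, per-gene Z-scoring factors on training individuals
#'
#' Means and sample standard deviations (ddof = 1 by default) are computed
#' from training samples only; the recorded factors are then applied to
#' validation or external data so no information leaks from held-out
#' individuals. By default values are log2(x + 1) transformed before
#' standardization; set \code{log2 = FALSE} for Z-scoring on the raw scale.
#'
#' @param x an \linkS4class{MTMDataSet}.
#' @param trainIds individual IDs of the training set (default: all).
#' @param log2 log-transform before standardizing (default TRUE).
#' @param pseudocount pseudocount for the log transform (default 1).
#' @param ddof degrees-of-freedom correction for the sd (1 = sample sd).
#' @return a \linkS4class{TissueScalers}.
#' @export
fitScalers <- function(x, trainIds = NULL, log2 = TRUE, pseudocount = 1,
                       ddof = 1) {
  stopifnot(is(x, "MTMDataSet"))
  cd <- colData(x)
  trainIds <- trainIds %||% unique(cd$individual)
  sel <- cd$individual %in% trainIds
  tissues <- sort(unique(cd$tissue))
  m <- exprMatrix(x)[sel, , drop = FALSE]
  tt <- cd$tissue[sel]
  absent <- setdiff(tissues, unique(tt))
  if (length(absent))
    stop("tissue(s) absent from the training set: ",
         paste(absent, collapse = ", "))
  if (log2) m <- log2(m + pseudocount)
  G <- ncol(m)
  center <- matrix(NA_real_, length(tissues), G,
                   dimnames = list(tissues, colnames(m)))
  scale <- center
  for (t in tissues) {
    rows <- which(tt == t)
    if (length(rows) < 2)
      stop("tissue '", t, "' has fewer than 2 training samples")
    sub <- m[rows, , drop = FALSE]
    mu <- colMeans(sub)
    va <- colSums(sub^2) - length(rows) * mu^2
    denom <- length(rows) - ddof
    sd <- sqrt(pmax(va, 0) / denom)
    center[t, ] <- mu
    scale[t, ] <- sd
  }
  zero <- scale == 0
  if (any(zero))
    message(sum(zero), " (tissue, gene) entr",
            if (sum(zero) == 1) "y has" else "ies have",
            " zero training sd; such genes standardize to 0")
  new("TissueScalers", center = center, scale = scale, log2 = log2,
      pseudocount = pseudocount, zeroSd = zero)
}

#' Standardize expression with recorded scaling factors
#'
#' \code{z = (x - mean) / sd} per (tissue, gene), on the scalers' modelling
#' scale (log2-transformed when the scalers were fitted that way). Genes with
#' zero recorded sd map to 0.
#'
#' @param x an \linkS4class{MTMDataSet} or a samples x genes TPM matrix.
#' @param scalers a \linkS4class{TissueScalers}.
#' @param tissue tissue labels per sample (taken from \code{x} when it is an
#'   MTMDataSet).
#' @return standardized samples x genes matrix.
#' @export
applyScalers <- function(x, scalers, tissue = NULL) {
  stopifnot(is(scalers, "TissueScalers"))
  if (is(x, "MTMDataSet")) {
    tissue <- colData(x)$tissue
    x <- exprMatrix(x)
  }
  if (is.null(tissue) || length(tissue) != nrow(x))
    stop("per-sample tissue labels are required")
  unknown <- setdiff(unique(tissue), rownames(scalers@center))
  if (length(unknown))
    stop("tissue(s) not covered by the scalers: ",
         paste(unknown, collapse = ", "))
  x <- alignGenes(x, scalers)
  if (scalers@log2) x <- log2(x + scalers@pseudocount)
  ti <- match(tissue, rownames(scalers@center))
  sd <- scalers@scale[ti, , drop = FALSE]
  z <- (x - scalers@center[ti, , drop = FALSE]) / sd
  z[sd == 0] <- 0
  z
}

#' Invert standardization back to the TPM scale
#'
#' Exact inverse of \code{\link{applyScalers}} for genes with nonzero sd;
#' zero-sd genes map back to the recorded tissue mean.
#'
#' @param z standardized samples x genes matrix.
#' @param scalers a \linkS4class{TissueScalers}.
#' @param tissue tissue labels per sample.
#' @return samples x genes matrix on the original TPM scale.
#' @export
invertScalers <- function(z, scalers, tissue) {
  stopifnot(is(scalers, "TissueScalers"))
  if (length(tissue) == 1L) tissue <- rep(tissue, nrow(z))
  unknown <- setdiff(unique(tissue), rownames(scalers@center))
  if (length(unknown))
    stop("tissue(s) not covered by the scalers: ",
         paste(unknown, collapse = ", "))
  ti <- match(tissue, rownames(scalers@center))
  x <- z * scalers@scale[ti, , drop = FALSE] +
    scalers@center[ti, , drop = FALSE]
  if (scalers@log2) x <- pmax(2^x - scalers@pseudocount, 0)
  x
}

alignGenes <- function(x, scalers) {
  genes <- colnames(scalers@center)
  if (identical(colnames(x), genes)) return(x)
  miss <- setdiff(genes, colnames(x))
  if (length(miss))
    stop("expression matrix lacks gene(s) required by the scalers: ",
         paste(utils::head(miss, 5), collapse = ", "))
  x[, genes, drop = FALSE]
}

#' Within-individual ordered tissue pairs for training
#'
#' All ordered pairs (source, target) of distinct samples within each listed
#' individual; both directions are included so the model learns the mapping
#' between any two tissues. Self-pairs (source sample = target sample) are
#' excluded by default.
#'
#' @param x an \linkS4class{MTMDataSet} or metadata data.frame.
#' @param individualIds individuals to include (default: all).
#' @param includeSelf also emit (a, a) pairs (default FALSE).
#' @return data.frame with individual, source_sample, source_tissue,
#'   target_sample, target_tissue.
#' @export
buildTissuePairs <- function(x, individualIds = NULL, includeSelf = FALSE) {
  meta <- if (is(x, "MTMDataSet")) sampleInfo(x) else x
  individualIds <- individualIds %||% unique(meta$individual_id)
  meta <- meta[meta$individual_id %in% individualIds, , drop = FALSE]
  out <- lapply(split(meta, meta$individual_id), function(mi) {
    n <- nrow(mi)
    idx <- expand.grid(src = seq_len(n), tgt = seq_len(n))
    if (!includeSelf) idx <- idx[idx$src != idx$tgt, , drop = FALSE]
    if (!nrow(idx)) return(NULL)
    data.frame(individual = mi$individual_id[idx$src],
               source_sample = mi$sample_id[idx$src],
               source_tissue = mi$tissue[idx$src],
               target_sample = mi$sample_id[idx$tgt],
               target_tissue = mi$tissue[idx$tgt],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(individual = character(), source_sample = character(),
                      source_tissue = character(),
                      target_sample = character(),
                      target_tissue = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Align an external cohort's per-tissue gene statistics to a reference
#'
#' Rescales external expression so that each gene's per-tissue mean and
#' standard deviation equal the reference's recorded values (a light batch
#' alignment): external values are standardized with their own per-tissue
#' statistics and re-expressed with the reference scaling factors, on the
#' reference's modelling scale. Genes missing from the reference are dropped
#' with a message; zero-variance external genes with nonzero reference sd are
#' mapped to the reference mean and flagged.
#'
#' @param x an \linkS4class{MTMDataSet} or samples x genes TPM matrix.
#' @param reference a \linkS4class{TissueScalers} fitted on the reference
#'   cohort.
#' @param tissue tissue labels per sample (from \code{x} if an MTMDataSet).
#' @return samples x genes matrix on the reference modelling scale, with a
#'   \code{"flaggedGenes"} attribute listing zero-variance external genes.
#' @export
alignExternal <- function(x, reference, tissue = NULL) {
  stopifnot(is(reference, "TissueScalers"))
  if (is(x, "MTMDataSet")) {
    tissue <- colData(x)$tissue
    x <- exprMatrix(x)
  }
  if (is.null(tissue) || length(tissue) != nrow(x))
    stop("per-sample tissue labels are required")
  refGenes <- colnames(reference@center)
  dropped <- setdiff(colnames(x), refGenes)
  if (length(dropped))
    message("dropping ", length(dropped),
            " gene(s) missing from the reference")
  shared <- intersect(colnames(x), refGenes)
  if (!length(shared)) stop("no genes shared with the reference")
  x <- x[, shared, drop = FALSE]
  unknown <- setdiff(unique(tissue), rownames(reference@center))
  if (length(unknown))
    stop("external tissue(s) not present in the reference: ",
         paste(unknown, collapse = ", "))
  if (reference@log2) x <- log2(x + reference@pseudocount)
  out <- x
  flagged <- character()
  for (t in unique(tissue)) {
    rows <- which(tissue == t)
    sub <- x[rows, , drop = FALSE]
    mu <- colMeans(sub)
    sd <- apply(sub, 2, stats::sd)
    z <- sweep(sub, 2, mu, "-")
    nz <- sd > 0
    z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sd[nz], "/")
    z[, !nz] <- 0
    flagged <- union(flagged, colnames(x)[!nz])
    ti <- match(t, rownames(reference@center))
    out[rows, ] <- sweep(sweep(z, 2, reference@scale[ti, shared], "*"),
                         2, reference@center[ti, shared], "+")
  }
  attr(out, "flaggedGenes") <- flagged
  out
}

#' Serialize / restore scaling factors as TSV
#'
#' Long format (tissue, gene, mean, sd); the log-transform setting is kept in
#' a header comment so the factors are reusable exactly.
#'
#' @param scalers a \linkS4class{TissueScalers}.
#' @param path file path.
#' @export
writeScalers <- function(scalers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mtmap scalers v1 log2=%s pseudocount=%.17g",
                     scalers@log2, scalers@pseudocount), con)
  df <- data.frame(
    tissue = rep(rownames(scalers@center), ncol(scalers@center)),
    gene = rep(colnames(scalers@center), each = nrow(scalers@center)),
    mean = as.vector(scalers@center),
    sd = as.vector(scalers@scale))
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScalers
#' @export
readScalers <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# mtmap scalers v1"))
    stop("'", path, "' is not a scalers file")
  log2 <- grepl("log2=TRUE", hdr)
  pc <- as.numeric(sub(".*pseudocount=([0-9eE.+-]+).*", "\\1", hdr))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          stringsAsFactors = FALSE)
  tissues <- unique(df$tissue)
  genes <- unique(df$gene)
  center <- matrix(NA_real_, length(tissues), length(genes),
                   dimnames = list(tissues, genes))
  scale <- center
  center[cbind(df$tissue, df$gene)] <- df$mean
  scale[cbind(df$tissue, df$gene)] <- df$sd
  new("TissueScalers", center = center, scale = scale, log2 = log2,
      pseudocount = pc, zeroSd = scale == 0)
}
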