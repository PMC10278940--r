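#' Configuration for the synthetic multi-tissue cohort simulator
#'
#' The simulator emulates the statistical structure the multi-task model
#' assumes: each individual i carries a latent vector u_i (a static,
#' genetics-like block shared across tissues plus a dynamic, state-like block,
#' both constant across the individual's tissues); tissue k has a loading
#' matrix A_k and per-gene intercepts b_k, and the pre-noise signal for
#' individual i in tissue k is A_k u_i + b_k. Cross-tissue relatedness is
#' induced by mixing a shared loading component into each tissue's loadings
#' (\code{loadingCor}); trait-correlated genes and case/control dysregulated
#' genes are planted additively; Gaussian noise is added; and the result is
#' mapped to TPM-like non-negative values by the monotone transform
#' \code{x -> 2^(x / tau)}, so planted shifts of \code{degLog2fc * tau} are
#' exact log2 fold changes.
#'
#' @param nIndividuals,nTissues,nGenes positive counts.
#' @param latentDimStatic,latentDimDynamic latent block sizes (sum >= 1).
#' @param noiseSd additive Gaussian noise sd on the signal scale (>= 0; 0 is
#'   the noiseless limit).
#' @param tissueMeanScale sd of per-tissue per-gene intercepts.
#' @param missingRate probability in [0, 1) that an (individual, tissue)
#'   sample is absent; a scalar, or one probability per tissue so that some
#'   tissues can be made deliberately scarce. Every individual always keeps
#'   >= 2 samples, and tissues in \code{missingExempt} are never dropped.
#' @param missingExempt tissue labels exempt from dropout. Default: the first
#'   tissue ("blood"), emulating a surrogate-sample design where the
#'   accessible tissue is collected for every individual; use
#'   \code{character()} for uniform dropout.
#' @param nTraitGenes,traitEffect number of genes with an additive
#'   trait-linked term and its size per sd of the trait.
#' @param nDeg,degLog2fc number of dysregulated genes and their planted log2
#'   fold change in cases (applied in \code{degTissues}).
#' @param caseFraction probability an individual is a case.
#' @param loadingCor fraction (scalar or per-tissue vector in [0, 1]) of each
#'   tissue's loading matrix drawn from the shared component; graded values
#'   give a ground-truth tissue-similarity ordering.
#' @param degTissues tissue labels carrying the dysregulation (default: all).
#' @param tau scale of the non-negativity transform (default 1).
#' @param seed integer seed; the simulation is fully deterministic given it.
#' @return list of class "SimulationConfig".
#' @export
simulationConfig <- function(nIndividuals = 60, nTissues = 4, nGenes = 200,
                             latentDimStatic = 5, latentDimDynamic = 3,
                             noiseSd = 1, tissueMeanScale = 2,
                             missingRate = 0, nTraitGenes = 10,
                             traitEffect = 1, nDeg = 10, degLog2fc = 2,
                             caseFraction = 0.5, loadingCor = 0.5,
                             degTissues = NULL, missingExempt = "blood",
                             tau = 1, seed = 1) {
  cfg <- list(nIndividuals = nIndividuals, nTissues = nTissues,
              nGenes = nGenes, latentDimStatic = latentDimStatic,
              latentDimDynamic = latentDimDynamic, noiseSd = noiseSd,
              tissueMeanScale = tissueMeanScale, missingRate = missingRate,
              nTraitGenes = nTraitGenes, traitEffect = traitEffect,
              nDeg = nDeg, degLog2fc = degLog2fc,
              caseFraction = caseFraction, loadingCor = loadingCor,
              degTissues = degTissues, missingExempt = missingExempt,
              tau = tau, seed = seed)
  checkCount <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < min || v != round(v))
      stop("invalid SimulationConfig field '", field, "': must be a count >= ",
           min)
  }
  for (f in c("nIndividuals", "nTissues", "nGenes")) checkCount(f)
  for (f in c("latentDimStatic", "latentDimDynamic", "nTraitGenes", "nDeg"))
    checkCount(f, min = 0)
  if (cfg$latentDimStatic + cfg$latentDimDynamic < 1)
    stop("invalid SimulationConfig field 'latentDimStatic': ",
         "latentDimStatic + latentDimDynamic must be >= 1")
  if (cfg$nTraitGenes + cfg$nDeg > cfg$nGenes)
    stop("invalid SimulationConfig field 'nTraitGenes': ",
         "nTraitGenes + nDeg must not exceed nGenes")
  if (!is.numeric(cfg$noiseSd) || cfg$noiseSd < 0)
    stop("invalid SimulationConfig field 'noiseSd': must be >= 0")
  if (cfg$tissueMeanScale < 0)
    stop("invalid SimulationConfig field 'tissueMeanScale': must be >= 0")
  if (any(cfg$missingRate < 0) || any(cfg$missingRate >= 1))
    stop("invalid SimulationConfig field 'missingRate': must be in [0, 1)")
  if (!length(cfg$missingRate) %in% c(1L, cfg$nTissues))
    stop("invalid SimulationConfig field 'missingRate': length 1 or nTissues")
  if (cfg$caseFraction < 0 || cfg$caseFraction > 1)
    stop("invalid SimulationConfig field 'caseFraction': must be in [0, 1]")
  if (any(cfg$loadingCor < 0) || any(cfg$loadingCor > 1))
    stop("invalid SimulationConfig field 'loadingCor': must be in [0, 1]")
  if (!length(cfg$loadingCor) %in% c(1L, cfg$nTissues))
    stop("invalid SimulationConfig field 'loadingCor': length 1 or nTissues")
  if (cfg$tau <= 0)
    stop("invalid SimulationConfig field 'tau': must be > 0")
  if (cfg$nTissues < 2)
    stop("invalid SimulationConfig field 'nTissues': need >= 2 tissues")
  class(cfg) <- "SimulationConfig"
  cfg
}

simTissueNames <- function(nTissues) {
  c("blood", sprintf("tissue%d", seq_len(nTissues - 1L) + 1L))
}

#' Simulate a multi-tissue, multi-individual expression cohort
#'
#' See \code{\link{simulationConfig}} for the generative model. The returned
#' cohort carries the per-individual trait table (a continuous age-like trait
#' and a binary disease flag) and the full ground truth (loadings, latents,
#' intercepts, planted gene sets, and the noise-free signal on the TPM scale)
#' in its metadata.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return an \linkS4class{MTMDataSet}.
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  N <- config$nIndividuals
  K <- config$nTissues
  G <- config$nGenes
  L <- config$latentDimStatic + config$latentDimDynamic
  tissues <- simTissueNames(K)
  genes <- sprintf("gene%04d", seq_len(G))
  inds <- sprintf("IND%04d", seq_len(N))
  rk <- rep(config$loadingCor, length.out = K)
  degTissues <- if (is.null(config$degTissues)) tissues else config$degTissues
  if (!all(degTissues %in% tissues))
    stop("degTissues must be drawn from the simulated tissue labels")

  U <- matrix(stats::rnorm(N * L), N, L, dimnames = list(inds, NULL))
  A0 <- matrix(stats::rnorm(G * L, sd = 1 / sqrt(L)), G, L)
  loadings <- lapply(seq_len(K), function(k) {
    Bk <- matrix(stats::rnorm(G * L, sd = 1 / sqrt(L)), G, L)
    Ak <- sqrt(rk[k]) * A0 + sqrt(1 - rk[k]) * Bk
    dimnames(Ak) <- list(genes, NULL)
    Ak
  })
  names(loadings) <- tissues
  # intercepts share the same cross-tissue mixing as the loadings, so related
  # tissues also have related mean profiles (the tissue-similarity ground
  # truth visible on the raw scale)
  b0 <- stats::rnorm(G, sd = config$tissueMeanScale)
  intercepts <- matrix(NA_real_, K, G, dimnames = list(tissues, genes))
  for (k in seq_len(K))
    intercepts[k, ] <- sqrt(rk[k]) * b0 +
      sqrt(1 - rk[k]) * stats::rnorm(G, sd = config$tissueMeanScale)

  age <- stats::rnorm(N, 50, 15)
  ageZ <- as.numeric(scale(age))
  disease <- stats::rbinom(N, 1, config$caseFraction)
  traits <- data.frame(individual_id = inds, age = age, disease = disease,
                       stringsAsFactors = FALSE)

  # reserved, disjoint planted gene blocks
  traitGenes <- if (config$nTraitGenes > 0)
    genes[seq_len(config$nTraitGenes)] else character()
  degGenesAll <- if (config$nDeg > 0)
    genes[config$nTraitGenes + seq_len(config$nDeg)] else character()
  degGenes <- lapply(tissues, function(t)
    if (t %in% degTissues) degGenesAll else character())
  names(degGenes) <- tissues

  # sample presence, >= 2 tissues per individual always retained
  keep <- matrix(TRUE, N, K, dimnames = list(inds, tissues))
  if (any(config$missingRate > 0)) {
    mr <- rep(config$missingRate, length.out = K)
    keep[] <- stats::runif(N * K) >= matrix(mr, N, K, byrow = TRUE)
    exempt <- tissues %in% config$missingExempt
    keep[, exempt] <- TRUE
    for (i in seq_len(N)) {
      if (sum(keep[i, ]) < 2) {
        forced <- sample.int(K, 2)
        keep[i, forced] <- TRUE
      }
    }
  }

  nSamp <- sum(keep)
  expr <- matrix(NA_real_, nSamp, G)
  signalTPM <- matrix(NA_real_, nSamp, G)
  sampleId <- character(nSamp)
  indivId <- character(nSamp)
  tissueId <- character(nSamp)
  row <- 0L
  for (k in seq_len(K)) {
    who <- which(keep[, k])
    if (!length(who)) next
    sig <- U[who, , drop = FALSE] %*% t(loadings[[k]]) +
      matrix(intercepts[k, ], length(who), G, byrow = TRUE)
    if (length(traitGenes)) {
      ix <- match(traitGenes, genes)
      sig[, ix] <- sig[, ix] + config$traitEffect * ageZ[who]
    }
    if (length(degGenes[[k]])) {
      ix <- match(degGenes[[k]], genes)
      shift <- config$degLog2fc * config$tau * disease[who]
      sig[, ix] <- sig[, ix] + shift
    }
    noisy <- sig
    if (config$noiseSd > 0)
      noisy <- noisy + matrix(stats::rnorm(length(who) * G,
                                           sd = config$noiseSd),
                              length(who), G)
    rows <- row + seq_along(who)
    expr[rows, ] <- 2^(noisy / config$tau)
    signalTPM[rows, ] <- 2^(sig / config$tau)
    sampleId[rows] <- paste0(inds[who], "_", tissues[k])
    indivId[rows] <- inds[who]
    tissueId[rows] <- tissues[k]
    row <- row + length(who)
  }
  dimnames(expr) <- list(sampleId, genes)
  dimnames(signalTPM) <- list(sampleId, genes)

  meta <- data.frame(sample_id = sampleId, individual_id = indivId,
                     tissue = tissueId, stringsAsFactors = FALSE)
  truth <- list(config = config, latents = U, loadings = loadings,
                intercepts = intercepts, traitGenes = traitGenes,
                degGenes = degGenes, tau = config$tau,
                ageZ = stats::setNames(ageZ, inds),
                signalTPM = signalTPM)
  MTMDataSet(expr, meta, traits = traits, truth = truth)
}

#' Write a cohort to a directory of delimited text files
#'
#' Emits \code{expression.tsv} (samples x genes; first column sample_id),
#' \code{metadata.tsv} (sample_id, individual_id, tissue), \code{traits.tsv},
#' and, when simulation ground truth is attached, \code{truth.txt} (a
#' sectioned plain-text format documented in the file header; the noise-free
#' signal is recomputed from it on read rather than stored).
#'
#' @param cohort an \linkS4class{MTMDataSet}.
#' @param directory output directory, created if needed.
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, directory) {
  stopifnot(is(cohort, "MTMDataSet"))
  if (!is.character(directory) || length(directory) != 1 ||
      !nzchar(directory))
    stop("'directory' must be a non-empty path")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  files <- character()
  ef <- file.path(directory, "expression.tsv")
  em <- cbind(data.frame(sample_id = rownames(exprMatrix(cohort)),
                         stringsAsFactors = FALSE),
              as.data.frame(exprMatrix(cohort)))
  utils::write.table(em, ef, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, ef)
  mf <- file.path(directory, "metadata.tsv")
  utils::write.table(sampleInfo(cohort), mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, mf)
  tr <- cohortTraits(cohort)
  if (!is.null(tr)) {
    tf <- file.path(directory, "traits.tsv")
    utils::write.table(tr, tf, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, tf)
  }
  truth <- cohortTruth(cohort)
  if (!is.null(truth)) {
    uf <- file.path(directory, "truth.txt")
    writeTruthFile(truth, uf)
    files <- c(files, uf)
  }
  invisible(files)
}

fmtNum <- function(x) format(x, digits = 15, trim = TRUE, scientific = TRUE)

writeTruthFile <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# mtmap simulation truth v1")
  w("# sections: [config] key\\tvalue; [latents] individual\\tvalues...;")
  w("# [loadings:<tissue>] gene\\tvalues...; [intercepts] tissue\\tvalues...;")
  w("# [trait_genes] / [deg_genes:<tissue>] one gene id per line")
  w("[config]")
  cfg <- truth$config
  for (k in names(cfg)) {
    v <- cfg[[k]]
    if (is.null(v)) v <- "NULL"
    w(k, "\t", paste(v, collapse = ","))
  }
  w("[latents]")
  for (i in rownames(truth$latents))
    w(i, "\t", paste(fmtNum(truth$latents[i, ]), collapse = "\t"))
  for (t in names(truth$loadings)) {
    w("[loadings:", t, "]")
    A <- truth$loadings[[t]]
    for (g in rownames(A))
      w(g, "\t", paste(fmtNum(A[g, ]), collapse = "\t"))
  }
  w("[intercepts]")
  for (t in rownames(truth$intercepts))
    w(t, "\t", paste(fmtNum(truth$intercepts[t, ]), collapse = "\t"))
  w("[age_z]")
  for (i in names(truth$ageZ)) w(i, "\t", fmtNum(truth$ageZ[[i]]))
  w("[trait_genes]")
  for (g in truth$traitGenes) w(g)
  for (t in names(truth$degGenes)) {
    w("[deg_genes:", t, "]")
    for (g in truth$degGenes[[t]]) w(g)
  }
  invisible(path)
}

readTruthFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  secAt <- grep("^\\[", lines)
  secName <- gsub("^\\[|\\]$", "", lines[secAt])
  secEnd <- c(secAt[-1] - 1L, length(lines))
  body <- function(j) {
    if (secAt[j] + 1L > secEnd[j]) return(character())
    lines[(secAt[j] + 1L):secEnd[j]]
  }
  out <- list()
  for (j in seq_along(secAt)) {
    nm <- secName[j]
    b <- body(j)
    b <- b[nzchar(b)]
    if (nm == "config") {
      kv <- strsplit(b, "\t", fixed = TRUE)
      cfg <- list()
      for (p in kv) {
        val <- p[2]
        if (identical(val, "NULL")) cfg[p[1]] <- list(NULL)
        else {
          num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
          cfg[[p[1]]] <- if (anyNA(num)) strsplit(val, ",")[[1]] else num
        }
      }
      out$config <- cfg
    } else if (nm %in% c("latents", "intercepts") ||
               startsWith(nm, "loadings:")) {
      kv <- strsplit(b, "\t", fixed = TRUE)
      ids <- vapply(kv, `[`, character(1), 1)
      vals <- t(vapply(kv, function(p) as.numeric(p[-1]),
                       numeric(length(kv[[1]]) - 1L)))
      rownames(vals) <- ids
      if (nm == "latents") out$latents <- vals
      else if (nm == "intercepts") out$intercepts <- vals
      else out$loadings[[sub("^loadings:", "", nm)]] <- vals
    } else if (nm == "age_z") {
      kv <- strsplit(b, "\t", fixed = TRUE)
      out$ageZ <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]),
                                         numeric(1)),
                                  vapply(kv, `[`, character(1), 1))
    } else if (nm == "trait_genes") {
      out$traitGenes <- b
    } else if (startsWith(nm, "deg_genes:")) {
      out$degGenes[[sub("^deg_genes:", "", nm)]] <- b
    }
  }
  out
}

#' Read a cohort written by \code{\link{writeCohort}}
#'
#' @param directory directory containing the files.
#' @return an \linkS4class{MTMDataSet}; ground truth (with the noise-free
#'   signal recomputed) is re-attached when \code{truth.txt} is present.
#' @export
readCohort <- function(directory) {
  expr <- readExpression(file.path(directory, "expression.tsv"))
  meta <- readMetadata(file.path(directory, "metadata.tsv"))
  tf <- file.path(directory, "traits.tsv")
  traits <- if (file.exists(tf))
    utils::read.delim(tf, stringsAsFactors = FALSE) else NULL
  uf <- file.path(directory, "truth.txt")
  truth <- NULL
  if (file.exists(uf)) {
    truth <- readTruthFile(uf)
    cfg <- truth$config
    ind <- meta$individual_id
    tis <- meta$tissue
    tau <- cfg$tau
    sig <- matrix(NA_real_, nrow(expr), ncol(expr),
                  dimnames = dimnames(expr))
    genes <- colnames(expr)
    for (k in unique(tis)) {
      rows <- which(tis == k)
      A <- truth$loadings[[k]]
      s <- truth$latents[ind[rows], , drop = FALSE] %*% t(A) +
        matrix(truth$intercepts[k, ], length(rows), ncol(expr), byrow = TRUE)
      if (length(truth$traitGenes)) {
        ix <- match(truth$traitGenes, genes)
        s[, ix] <- s[, ix] + cfg$traitEffect * truth$ageZ[ind[rows]]
      }
      dg <- truth$degGenes[[k]]
      if (length(dg)) {
        ix <- match(dg, genes)
        dis <- traits$disease[match(ind[rows], traits$individual_id)]
        s[, ix] <- s[, ix] + cfg$degLog2fc * tau * dis
      }
      sig[rows, ] <- 2^(s / tau)
    }
    truth$tau <- tau
    truth$signalTPM <- sig
  }
  MTMDataSet(expr, meta, traits = traits, truth = truth)
}
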