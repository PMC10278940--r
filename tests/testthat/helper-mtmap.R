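# shared fixtures and independent oracles

tinyCohort <- function(nInd = 12, nTissues = 3, nGenes = 20, noiseSd = 0.5,
                       seed = 1, ...) {
  simulateCohort(simulationConfig(nIndividuals = nInd, nTissues = nTissues,
                                  nGenes = nGenes, noiseSd = noiseSd,
                                  latentDimStatic = 2, latentDimDynamic = 1,
                                  nTraitGenes = 2, nDeg = 2, seed = seed,
                                  ...))
}

# a small fully deterministic cohort built by hand (no simulator involved)
handCohort <- function() {
  set.seed(99)
  nInd <- 6
  tissues <- c("blood", "liver")
  rows <- expand.grid(ind = sprintf("I%02d", 1:nInd), tissue = tissues,
                      stringsAsFactors = FALSE)
  expr <- matrix(abs(rnorm(nrow(rows) * 5, 10, 3)), nrow(rows), 5,
                 dimnames = list(paste(rows$ind, rows$tissue, sep = "_"),
                                 paste0("g", 1:5)))
  meta <- data.frame(sample_id = rownames(expr), individual_id = rows$ind,
                     tissue = rows$tissue, stringsAsFactors = FALSE)
  MTMDataSet(expr, meta)
}

# brute-force Pearson from the definition
refPearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  num / den
}

# Spearman with average ranks, from the definition
refSpearman <- function(x, y) {
  rk <- function(v) {
    sapply(seq_along(v), function(i)
      sum(v < v[i]) + (sum(v == v[i]) + 1) / 2)
  }
  refPearson(rk(x), rk(y))
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
exactWilcoxP <- function(a, b) {
  vals <- c(a, b)
  n <- length(a)
  U <- function(idx) {
    ra <- rank(vals)[idx]
    sum(ra) - n * (n + 1) / 2
  }
  obs <- U(seq_len(n))
  combos <- utils::combn(length(vals), n)
  us <- apply(combos, 2, U)
  muU <- n * length(b) / 2
  mean(abs(us - muU) >= abs(obs - muU) - 1e-12)
}

# exact hypergeometric upper tail P(X >= k) by enumerating subsets
exactHyperP <- function(N, K, n, k) {
  combos <- utils::combn(N, n)
  hits <- apply(combos, 2, function(s) sum(s <= K))
  mean(hits >= k)
}

# small trained model cache (training is the slow part; several tests share)
.trainedCache <- new.env(parent = emptyenv())

cachedTrainedModel <- function() {
  if (!is.null(.trainedCache$fit)) return(.trainedCache$fit)
  coh <- simulateCohort(simulationConfig(
    nIndividuals = 40, nTissues = 4, nGenes = 60,
    latentDimStatic = 3, latentDimDynamic = 2, noiseSd = 0.6,
    loadingCor = c(0.9, 0.9, 0.9, 0.15), nTraitGenes = 0, nDeg = 0,
    seed = 21))
  sp <- splitByIndividual(coh, 0.8, seed = 1)
  res <- trainMTM(coh, sp$train, NULL,
                  config = trainConfig(batchSize = 32, maxEpochs = 30,
                                       learningRate = 1e-3, adamBeta1 = 0.9,
                                       adamBeta2 = 0.999, seed = 1,
                                       weights = lossWeights(
                                         lambdaR = 0.1, lambdaI = 10,
                                         lambdaC = 1, lambdaAdv = 0.05)),
                  hidden = c(48, 32), latentDim = 16, noiseDim = 8,
                  mapperHidden = 16)
  .trainedCache$fit <- list(cohort = coh, split = sp, res = res)
  .trainedCache$fit
}
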