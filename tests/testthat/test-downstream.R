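test_that("tissue similarity is a symmetric unit-diagonal correlation of
           mean log2 profiles, ordered by ground-truth loading sharing", {
  set.seed(41)
  expr <- matrix(abs(rnorm(40 * 25, 8, 2)), 40, 25,
                 dimnames = list(paste0("s", 1:40), paste0("g", 1:25)))
  tis <- rep(c("a", "b"), each = 20)
  # duplicated tissue: identical sample values under two labels
  expr2 <- rbind(expr, expr[tis == "a", ])
  rownames(expr2) <- c(rownames(expr), paste0("dup", 1:20))
  tis2 <- c(tis, rep("a2", 20))
  sim <- tissueSimilarity(expr2, tis2)
  expect_equal(sim["a", "a2"], 1)
  expect_equal(sim, t(sim))
  expect_equal(unname(diag(sim)), rep(1, 3))

  # cohort with graded loading correlation: the two high-sharing tissues
  # rank mutually closer than either does to the low-sharing one
  coh <- simulateCohort(simulationConfig(
    nIndividuals = 50, nTissues = 4, nGenes = 300,
    loadingCor = c(0.9, 0.9, 0.9, 0.05), noiseSd = 0.5,
    nTraitGenes = 0, nDeg = 0, seed = 42))
  simC <- tissueSimilarity(coh)
  hi <- c("blood", "tissue2", "tissue3")
  lo <- "tissue4"
  for (t in hi) {
    others <- setdiff(hi, t)
    expect_gt(min(simC[t, others]), simC[t, lo])
  }
})

test_that("pairwise-matrix agreement uses Spearman on the upper triangle", {
  set.seed(43)
  m <- matrix(rnorm(16), 4, 4)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  expect_equal(comparePairwiseToSimilarity(m, m), 1)
  expect_equal(comparePairwiseToSimilarity(-m, m), -1)
  m2 <- matrix(rnorm(16), 4, 4)
  m2 <- (m2 + t(m2)) / 2
  expect_equal(comparePairwiseToSimilarity(m, m2),
               refSpearman(m[upper.tri(m)], m2[upper.tri(m2)]),
               tolerance = 1e-12)
  expect_error(comparePairwiseToSimilarity(m, matrix(0, 3, 3)), "dimension")
  expect_true(is.na(comparePairwiseToSimilarity(matrix(1, 4, 4), m)))
})

test_that("latent-code similarity partitions pairs by individual with the
           right counts", {
  fit <- cachedTrainedModel()
  ls <- latentCodeSimilarity(fit$res$lastModel, fit$cohort)
  meta <- sampleInfo(fit$cohort)
  cnt <- table(meta$individual_id)
  nIntra <- sum(cnt * (cnt - 1) / 2)
  nTot <- nrow(meta) * (nrow(meta) - 1) / 2
  expect_length(ls$intra, nIntra)
  expect_length(ls$inter, nTot - nIntra)
  # trained on a shared-latent cohort: individualized codes
  expect_gt(ls$meanIntra, ls$meanInter)
  expect_lt(ls$pValue, 0.01)
})

test_that("decoding paths reflect tissue similarity in a trained model", {
  fit <- cachedTrainedModel()
  m <- fit$res$lastModel
  expect_error(decodingPathSimilarity(m, rnorm(16), c("blood", "tissue2"),
                                      diag(2)), "3 tissues")
  tis <- cohortTissues(fit$cohort)
  simC <- tissueSimilarity(fit$cohort)
  set.seed(44)
  code <- encode(m, applyScalers(fit$cohort, fit$res$scalers)[1, ], "blood")
  dps <- decodingPathSimilarity(m, code, tis, simC)
  expect_length(dps, length(m@generator$layers))
  # loadings/intercepts: blood/tissue2/tissue3 share 90%, tissue4 5%; a
  # trained generator's decoding paths should echo that ordering
  expect_gt(median(dps, na.rm = TRUE), 0)

  # degenerate: identical affines across tissues -> all similarities 1 -> NA
  m0 <- m
  net <- m0@generator
  for (i in seq_along(net$layers)) {
    if (net$layers[[i]]$conditioned) {
      net$layers[[i]]$gamma[] <- 1
      net$layers[[i]]$beta[] <- 0
    }
  }
  m0@generator <- net
  dps0 <- decodingPathSimilarity(m0, code, tis, simC)
  expect_true(all(is.na(dps0)))
})

test_that("trait-association preservation is 1 for identical data, ~0 for
           permuted individuals, and recovers planted signals", {
  cfg <- simulationConfig(nIndividuals = 60, nTissues = 2, nGenes = 80,
                          noiseSd = 0.3, nTraitGenes = 10, traitEffect = 1,
                          nDeg = 0, seed = 45)
  coh <- simulateCohort(cfg)
  meta <- sampleInfo(coh)
  traits <- cohortTraits(coh)
  age <- traits$age[match(meta$individual_id, traits$individual_id)]
  obs <- log2(exprMatrix(coh) + 1)
  tp <- traitAssociationPreservation(obs, obs, meta$tissue, age)
  expect_equal(tp$rho, rep(1, 2))

  pred <- log2(cohortTruth(coh)$signalTPM + 1)
  tp2 <- traitAssociationPreservation(pred, obs, meta$tissue, age)
  expect_true(all(tp2$rho > 0.9))

  set.seed(46)
  perms <- replicate(6, {
    pp <- pred
    for (t in unique(meta$tissue)) {
      r <- which(meta$tissue == t)
      pp[r, ] <- pred[sample(r), ]
    }
    mean(traitAssociationPreservation(pp, obs, meta$tissue, age)$rho)
  })
  expect_lt(abs(mean(perms)), 0.3)
  expect_error(traitAssociationPreservation(obs, obs, meta$tissue,
                                            rep(1, nrow(obs))), "constant")
})

test_that("Wilcoxon DE matches exact enumeration and recovers planted
           shifts", {
  # tiny case from first principles: {1,2,3} vs {4,5,6}
  expect_equal(suppressWarnings(
    stats::wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value), 0.1)
  expr <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
                 dimnames = list(paste0("s", 1:6), "g1"))
  de <- deAnalysis(expr, c(1, 1, 1, 0, 0, 0), minGroupN = 3)
  expect_equal(de$p_value, 0.1)
  expect_equal(de$p_value, exactWilcoxP(c(1, 2, 3), c(4, 5, 6)))
  expect_error(deAnalysis(expr, c(1, 1, 1, 0, 0, 0), minGroupN = 10),
               "minGroupN")

  # implementation matches the exact-permutation oracle for small groups
  set.seed(47)
  for (i in 1:15) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    a <- round(rnorm(n1), 3)
    b <- round(rnorm(n2), 3)
    expect_equal(suppressWarnings(stats::wilcox.test(a, b)$p.value),
                 exactWilcoxP(a, b), tolerance = 1e-12,
                 label = sprintf("wilcox n1=%d n2=%d", n1, n2))
  }

  # planted dysregulation at low noise is recovered with direction 'up'
  cfg <- simulationConfig(nIndividuals = 80, nTissues = 2, nGenes = 60,
                          noiseSd = 0.3, nDeg = 8, degLog2fc = 1.5,
                          nTraitGenes = 0, caseFraction = 0.5, seed = 48)
  coh <- simulateCohort(cfg)
  meta <- sampleInfo(coh)
  rows <- which(meta$tissue == "tissue2")
  dis <- cohortTraits(coh)$disease[match(meta$individual_id[rows],
                                         cohortTraits(coh)$individual_id)]
  de2 <- deAnalysis(exprMatrix(coh)[rows, ], dis)
  planted <- cohortTruth(coh)$degGenes[["tissue2"]]
  expect_true(all(de2$direction[match(planted, de2$gene)] == "up"))

  # identical groups: null p-values, no discoveries expected
  set.seed(49)
  nullExpr <- matrix(abs(rnorm(40 * 100, 8, 2)), 40, 100,
                     dimnames = list(paste0("s", 1:40), paste0("g", 1:100)))
  deN <- deAnalysis(nullExpr, rep(c(0, 1), 20))
  expect_lte(sum(deN$direction != "none"), 2)
  expect_gt(mean(deN$p_value), 0.3)  # roughly uniform
})

test_that("DE concordance: sign consistency, fold-change correlation,
           exact hypergeometric overlap and F1", {
  mkDE <- function(lfc, dirn) data.frame(
    gene = paste0("g", seq_along(lfc)), log2fc = lfc,
    p_value = 0.5, fdr = 0.5, direction = dirn, stringsAsFactors = FALSE)
  set.seed(50)
  lfc <- rnorm(100)
  dirn <- rep("none", 100)
  dirn[order(lfc, decreasing = TRUE)[1:10]] <- "up"
  ref <- mkDE(lfc, dirn)
  cc <- concordance(ref, ref)
  expect_equal(cc$signConsistency, 1)
  expect_equal(cc$lfcRho, 1)
  expect_equal(cc$f1Up, 1)
  # universe 100, 10 ref up, 10 pred up, overlap 10: p = 1 / C(100, 10)
  expect_equal(cc$overlapPUp, 1 / choose(100, 10), tolerance = 1e-12)
  expect_true(is.na(cc$overlapPDown))  # empty reference set -> undefined
  expect_true(is.na(cc$f1Down))

  # disjoint predictions: F1 = 0
  dirn2 <- rep("none", 100)
  dirn2[order(lfc)[1:10]] <- "up"
  pred <- mkDE(lfc, dirn2)
  expect_equal(concordance(pred, ref)$f1Up, 0)

  # zero fold changes are excluded from sign consistency
  refZ <- mkDE(c(0, 1, -1, 2), rep("none", 4))
  prdZ <- mkDE(c(5, 1, 1, 2), rep("none", 4))
  expect_equal(concordance(prdZ, refZ)$signConsistency, 2 / 3)

  # gene-order invariance
  shuf <- ref[sample(100), ]
  cc2 <- concordance(shuf, ref)
  expect_equal(cc2$signConsistency, 1)
  expect_equal(cc2$overlapPUp, cc$overlapPUp)
  expect_error(concordance(ref, mkDE(rnorm(3), rep("none", 3))),
               "different gene universes")
})

test_that("hypergeometric overlap p matches subset enumeration on small
           universes", {
  cases <- list(c(N = 10, K = 4, n = 3, k = 2),
                c(N = 12, K = 5, n = 4, k = 1),
                c(N = 9, K = 3, n = 3, k = 3),
                c(N = 11, K = 6, n = 2, k = 0))
  for (cs in cases) {
    pImpl <- stats::phyper(cs["k"] - 1, cs["K"], cs["N"] - cs["K"],
                           cs["n"], lower.tail = FALSE)
    expect_equal(unname(pImpl),
                 exactHyperP(cs["N"], cs["K"], cs["n"], cs["k"]),
                 tolerance = 1e-12,
                 label = paste(names(cs), cs, collapse = " "))
  }
})

test_that("BH-FDR direction calls are monotone in the threshold", {
  set.seed(51)
  expr <- matrix(abs(rnorm(40 * 60, 8, 2)), 40, 60,
                 dimnames = list(paste0("s", 1:40), paste0("g", 1:60)))
  expr[1:20, 1:10] <- expr[1:20, 1:10] * 4
  g <- rep(c(1, 0), each = 20)
  de05 <- deAnalysis(expr, g, fdrThreshold = 0.05)
  de01 <- deAnalysis(expr, g, fdrThreshold = 0.01)
  strict <- de01$gene[de01$direction != "none"]
  loose <- de05$gene[de05$direction != "none"]
  expect_true(all(strict %in% loose))
})
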