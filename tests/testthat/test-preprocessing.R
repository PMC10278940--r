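test_that("delimited expression and metadata tables read back typed", {
  dir <- withr::local_tempdir()
  ef <- file.path(dir, "e.tsv")
  writeLines(c("sample_id\tg1\tg2\tg3\tg4\tg5",
               "s1\t1\t2\t3\t4\t5",
               "s2\t2\t3\t4\t5\t6",
               "s3\t0\t1\t0\t1\t0"), ef)
  m <- readExpression(ef)
  expect_identical(dim(m), c(3L, 5L))
  expect_identical(rownames(m), c("s1", "s2", "s3"))

  # comma dialect auto-detected
  cf <- file.path(dir, "e.csv")
  writeLines(c("sample_id,g1,g2", "s1,1,2", "s2,3,4"), cf)
  expect_identical(dim(readExpression(cf)), c(2L, 2L))

  # gzip transparently
  gz <- gzfile(file.path(dir, "e.tsv.gz"), "w")
  writeLines(readLines(ef), gz)
  close(gz)
  expect_identical(readExpression(file.path(dir, "e.tsv.gz")), m)

  dup <- file.path(dir, "dup.tsv")
  writeLines(c("sample_id\tg1", "s1\t1", "s1\t2"), dup)
  expect_error(readExpression(dup), "duplicate sample")

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("sample_id\tg1\tg2", "s1\t1\tx", "s2\t2\ty"), bad)
  expect_error(readExpression(bad), "non-numeric")
})

test_that("constructing a data set requires complete metadata", {
  expr <- matrix(1:6, 2, 3,
                 dimnames = list(c("s1", "s2"), c("g1", "g2", "g3")))
  meta <- data.frame(sample_id = "s1", individual_id = "i1",
                     tissue = "blood")
  expect_error(MTMDataSet(expr, meta), "s2")
})

test_that("filtering removes small tissues then lone individuals to a
           fixed point", {
  set.seed(4)
  nBig <- 55
  ids <- c(sprintf("i%03d", 1:nBig), sprintf("i%03d", 1:nBig),
           sprintf("i%03d", 1:50))
  tis <- c(rep("blood", nBig), rep("liver", nBig), rep("lung", 50))
  meta <- data.frame(sample_id = sprintf("s%03d", seq_along(ids)),
                     individual_id = ids, tissue = tis,
                     stringsAsFactors = FALSE)
  expr <- matrix(abs(rnorm(length(ids) * 4, 5)), length(ids), 4,
                 dimnames = list(meta$sample_id, paste0("g", 1:4)))
  x <- MTMDataSet(expr, meta)
  f <- filterCohort(x)  # lung has exactly 50 samples -> removed (> 50 kept)
  expect_false("lung" %in% cohortTissues(f))
  expect_identical(sort(cohortTissues(f)), c("blood", "liver"))
  expect_identical(ncol(f), 110L)
  # idempotence on an already-conforming cohort
  f2 <- filterCohort(f)
  expect_identical(colnames(f2), colnames(f))

  # individual with one remaining sample is removed
  meta2 <- meta[-(nBig + 1), ]  # drop i001's liver sample
  x2 <- MTMDataSet(expr[meta2$sample_id, ], meta2)
  # default thresholds: lung (50 samples) goes first, then i001 is left with
  # a single blood sample and is removed too
  f3 <- filterCohort(x2)
  expect_false("i001" %in% cohortIndividuals(f3))

  expect_error(filterCohort(x, minTissueN = 1000), "no data after filtering")
})

test_that("individual-level splits are exact, disjoint and seeded", {
  meta <- data.frame(sample_id = paste0("s", 1:200),
                     individual_id = rep(sprintf("i%03d", 1:100), 2),
                     tissue = rep(c("a", "b"), each = 100))
  sp <- splitByIndividual(meta, 0.8, seed = 5)
  expect_identical(length(sp$train), 80L)
  expect_identical(length(sp$validation), 20L)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), unique(meta$individual_id))
  expect_identical(splitByIndividual(meta, 0.8, seed = 5), sp)
  for (s in 1:5) {
    spi <- splitByIndividual(meta, 0.7, seed = s)
    expect_length(intersect(spi$train, spi$validation), 0)
  }
  expect_error(splitByIndividual(meta[1, , drop = FALSE], 0.8), "2 individuals")
})

test_that("CV folds partition individuals with near-equal sizes", {
  meta <- data.frame(sample_id = paste0("s", 1:10),
                     individual_id = paste0("i", 1:10),
                     tissue = "blood")
  folds <- makeCVFolds(meta, k = 5, seed = 2)
  expect_length(folds, 5)
  sizes <- vapply(folds, function(f) length(f$test), integer(1))
  expect_true(all(sizes == 2))
  expect_setequal(unlist(lapply(folds, `[[`, "test")), meta$individual_id)
  for (f in folds) expect_length(intersect(f$train, f$test), 0)

  # 944 individuals in 5 folds: sizes 188 or 189 (integer-division oracle)
  big <- data.frame(sample_id = paste0("s", 1:944),
                    individual_id = paste0("i", 1:944), tissue = "blood")
  sizes <- vapply(makeCVFolds(big, 5, seed = 1), function(f)
    length(f$test), integer(1))
  expect_setequal(sizes, c(188L, 189L))
  expect_identical(sum(sizes), 944L)
  expect_error(makeCVFolds(meta, k = 11), "exceeds")
})

test_that("scaling factors are fitted on training samples only, with the
           sample-sd convention", {
  expr <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2,
                 dimnames = list(c("s1", "s2", "s3"), c("g1", "g2")))
  meta <- data.frame(sample_id = rownames(expr),
                     individual_id = c("i1", "i2", "i3"), tissue = "blood")
  x <- MTMDataSet(expr, meta)
  sc <- suppressMessages(fitScalers(x, log2 = FALSE))
  expect_equal(unname(scalerMeans(sc)["blood", "g1"]), 2)
  expect_equal(unname(scalerSds(sc)["blood", "g1"]), 1)  # ddof = 1
  # constant gene: sd 0 flagged, standardizes to 0
  expect_equal(unname(scalerSds(sc)["blood", "g2"]), 0)
  expect_message(fitScalers(x, log2 = FALSE), "zero training sd")
  z <- applyScalers(x, sc)
  expect_equal(unname(z[, "g2"]), c(0, 0, 0))

  # train-applied Z-scores have mean 0, sd 1 per tissue and gene
  coh <- tinyCohort(seed = 6)
  ids <- cohortIndividuals(coh)
  train <- ids[1:8]
  sc2 <- fitScalers(coh, train)
  meta2 <- sampleInfo(coh)
  z2 <- applyScalers(coh, sc2)
  trRows <- meta2$individual_id %in% train & meta2$tissue == "blood"
  expect_equal(unname(colMeans(z2[trRows, ])), rep(0, ncol(z2)),
               tolerance = 1e-10)
  expect_equal(unname(apply(z2[trRows, ], 2, sd)), rep(1, ncol(z2)),
               tolerance = 1e-10)
  # validation rows standardized with training factors: nonzero means
  vaRows <- !meta2$individual_id %in% train & meta2$tissue == "blood"
  expect_gt(max(abs(colMeans(z2[vaRows, ]))), 1e-4)

  # permuting sample order does not change the fitted factors
  perm <- sample(ncol(coh))
  cohP <- coh[, perm]
  scP <- fitScalers(cohP, train)
  expect_equal(scalerMeans(scP), scalerMeans(sc2))
  expect_equal(scalerSds(scP), scalerSds(sc2))

  expect_error(fitScalers(coh, character(0)), "absent from the training")
})

test_that("standardization applies the recorded factors and inverts
           exactly", {
  sc <- new("TissueScalers",
            center = matrix(3, 1, 1, dimnames = list("blood", "g1")),
            scale = matrix(2, 1, 1, dimnames = list("blood", "g1")),
            log2 = FALSE, pseudocount = 1,
            zeroSd = matrix(FALSE, 1, 1,
                            dimnames = list("blood", "g1")))
  x <- matrix(5, 1, 1, dimnames = list("s1", "g1"))
  expect_equal(unname(applyScalers(x, sc, "blood")[1, 1]), 1.0)
  expect_error(applyScalers(x, sc, "brain"), "not covered")

  coh <- tinyCohort(seed = 8)
  sc2 <- fitScalers(coh)
  z <- applyScalers(coh, sc2)
  back <- invertScalers(z, sc2, sampleInfo(coh)$tissue)
  expect_equal(unname(back), unname(exprMatrix(coh)), tolerance = 1e-9)
})

test_that("scaler serialization round-trips", {
  coh <- tinyCohort(seed = 9)
  sc <- fitScalers(coh)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeScalers(sc, f)
  back <- readScalers(f)
  expect_equal(scalerMeans(back), scalerMeans(sc), tolerance = 1e-12)
  expect_equal(scalerSds(back), scalerSds(sc), tolerance = 1e-12)
  expect_identical(back@log2, sc@log2)
})

test_that("tissue pairs enumerate ordered within-individual combinations", {
  meta <- data.frame(
    sample_id = c("a1", "a2", "a3", "b1", "b2", "c1"),
    individual_id = c("A", "A", "A", "B", "B", "C"),
    tissue = c("t1", "t2", "t3", "t1", "t2", "t1"))
  p <- buildTissuePairs(meta)
  expect_identical(sum(p$individual == "A"), 6L)  # 3 samples -> 3*2
  expect_identical(sum(p$individual == "B"), 2L)
  expect_identical(sum(p$individual == "C"), 0L)
  # symmetry: (a, b) present iff (b, a) present
  key <- paste(p$source_sample, p$target_sample)
  rev <- paste(p$target_sample, p$source_sample)
  expect_setequal(key, rev)

  # combinatorial oracle on a random cohort
  coh <- tinyCohort(nInd = 15, nTissues = 4, seed = 10,
                    missingRate = 0.3, missingExempt = character())
  meta2 <- sampleInfo(coh)
  p2 <- buildTissuePairs(coh)
  cnt <- table(meta2$individual_id)
  expect_equal(nrow(p2), sum(cnt * (cnt - 1)))
  expect_true(all(p2$individual == meta2$individual_id[
    match(p2$source_sample, meta2$sample_id)]))
})

test_that("external cohorts are aligned to reference statistics", {
  # closed form on the raw scale: external mean 10, sd 2 -> (x - 10) / 2
  refSc <- new("TissueScalers",
               center = matrix(0, 1, 3,
                               dimnames = list("blood", c("g1", "g2", "g3"))),
               scale = matrix(1, 1, 3,
                              dimnames = list("blood", c("g1", "g2", "g3"))),
               log2 = FALSE, pseudocount = 1,
               zeroSd = matrix(FALSE, 1, 3,
                               dimnames = list("blood", c("g1", "g2", "g3"))))
  set.seed(12)
  ext <- matrix(rnorm(60, 10, 2), 20, 3,
                dimnames = list(paste0("s", 1:20), c("g1", "g2", "g3")))
  al <- alignExternal(ext, refSc, rep("blood", 20))
  mu <- colMeans(ext)
  sdv <- apply(ext, 2, sd)
  expect_equal(unname(al), unname(sweep(sweep(ext, 2, mu), 2, sdv, "/")),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(colMeans(al)), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(al, 2, sd)), c(1, 1, 1), tolerance = 1e-9)

  # aligning a cohort to its own statistics is the identity (on the
  # modelling scale)
  coh <- tinyCohort(seed = 14)
  sc <- fitScalers(coh)
  al2 <- alignExternal(coh, sc)
  expect_equal(unname(al2), unname(log2(exprMatrix(coh) + 1)),
               tolerance = 1e-9, ignore_attr = TRUE)

  # genes missing from the reference are dropped with a message
  ext2 <- cbind(ext, gX = rnorm(20))
  expect_message(alignExternal(ext2, refSc, rep("blood", 20)), "dropping")
  expect_error(alignExternal(ext, refSc, rep("brain", 20)), "not present")
})
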