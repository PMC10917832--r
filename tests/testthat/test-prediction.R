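# Kernel BLUP prediction, cross-validation bookkeeping, the quality
# filter, scenario assembly, weight search and date subsets.

test_that("predictive ability handles the degenerate cases", {
  x <- rnorm(10)
  expect_equal(pearsonPA(x, x), 1)
  expect_equal(pearsonPA(x, -x), -1)
  expect_true(is.na(pearsonPA(x, rep(0.3, 10))))   # zero variance
  expect_true(is.na(pearsonPA(x[1:2], x[1:2])))    # < 3 pairs
  expect_equal(pearsonPA(c(x, NA), c(x, 1)), 1)    # NA pairs dropped
})

test_that("an identity kernel shares no information between clones", {
  set.seed(41)
  ids <- sprintf("c%02d", 1:30)
  y <- setNames(rnorm(30, 5), ids)
  I30 <- relationshipMatrix(diag(30) |> `dimnames<-`(list(ids, ids)), "G")
  fit <- fitBlup(y[1:25], I30)
  pred <- predictMasked(fit, I30, ids[26:30])
  # held-out predictions collapse to the training intercept
  expect_equal(unname(pred), rep(unname(fixedEffects(fit)[1]), 5),
               tolerance = 1e-8)
})

test_that("a noiseless marker-linear trait is interpolated exactly", {
  set.seed(42)
  dos <- makeDosage(60, 40, seed = 42)
  Zc <- scale(dosages(dos), scale = FALSE)
  y <- setNames(drop(Zc %*% rnorm(40)) + 20, rownames(Zc))
  G <- additiveKernel(dos)
  fit <- fitBlup(y[1:48], G)
  pred <- predictMasked(fit, G, names(y)[49:60])
  expect_gt(pearsonPA(y[49:60], pred), 0.99)
})

test_that("single-kernel BLUP equals kernel ridge regression at the
           REML penalty", {
  inst <- makeKernelInstance(n = 18, m = 50, seed = 43)
  fit <- fitBlup(inst$y, inst$K)
  vc <- varComp(fit)
  lambda <- vc[["residual"]] / vc[["u"]]
  Kv <- relValues(inst$K)
  mu <- unname(fixedEffects(fit)[1])
  ridge <- drop(Kv %*% solve(Kv + lambda * diag(18), inst$y - mu))
  expect_equal(unname(ranefBlups(fit)$u), unname(ridge), tolerance = 1e-6)
})

test_that("masked-equation and closed-form predictions coincide", {
  inst <- makeKernelInstance(n = 20, m = 60, seed = 7)
  tr <- names(inst$y)[1:15]; val <- names(inst$y)[16:20]
  fit <- fitBlup(inst$y[tr], inst$K)
  p1 <- predictMasked(fit, inst$K, val)
  p2 <- predictMaskedMME(fit, inst$K, val)
  expect_lt(max(abs(p1 - p2)), 1e-8)
  # a clone absent from the kernel yields a missing prediction
  p3 <- predictMasked(fit, inst$K, c(val, "ghost"))
  expect_true(is.na(p3[["ghost"]]))
})

test_that("fold assignments partition the clones and are seeded", {
  set.seed(44)
  ids <- sprintf("c%03d", 1:63)
  folds <- psblup:::.foldAssignments(ids, 5, 25, seed = 9)
  expect_length(folds, 25)
  for (r in folds) {
    expect_setequal(unlist(r), ids)                   # exactly once each
    sizes <- lengths(r)
    expect_lte(diff(range(sizes)), 1)                 # near-equal folds
  }
  folds2 <- psblup:::.foldAssignments(ids, 5, 25, seed = 9)
  expect_identical(folds, folds2)
})

test_that("five folds and 25 replicates give 125 PA slots, reproducibly", {
  set.seed(45)
  dos <- makeDosage(40, 30, seed = 45)
  G <- additiveKernel(dos)
  y <- setNames(drop(scale(dosages(dos), scale = FALSE) %*% rnorm(30, 0, 0.3)) +
                  rnorm(40, 0, 0.5) + 10, cloneIds(dos))
  res <- crossValidate(y, G, nFolds = 5, nReps = 25, seed = 6)
  expect_length(predictiveAbilities(res), 125)
  res2 <- crossValidate(y, G, nFolds = 5, nReps = 25, seed = 6)
  expect_identical(predictiveAbilities(res), predictiveAbilities(res2))
  expect_equal(medianPA(res),
               median(predictiveAbilities(res), na.rm = TRUE))
})

test_that("the quality filter applies its two clauses as printed", {
  mk <- function(pa) psblup:::.newPredictionResult(pa, "lab", 1)
  expect_true(passedFilter(mk(rep(0.5, 125))))            # CV = 0
  expect_false(passedFilter(mk(c(rep(0.4, 15), rep(NA, 110)))))  # >100 miss
  expect_true(passedFilter(mk(c(rep(0.4, 30), rep(NA, 95)))))    # 95 ok
  set.seed(46)
  wild <- runif(125, -0.5, 0.5)
  wild <- wild - mean(wild) + 0.001            # |CV| far beyond 150
  expect_false(passedFilter(mk(wild)))
  # thresholds are adjustable
  expect_true(passedFilter(qualityFilter(mk(wild), cvMax = Inf)))
})

test_that("scenario constraints and assembly follow the study design", {
  cases <- enumerateScenarios(c("W19", "W20", "G20", "W21", "G21"),
                              c("W20", "W21"))
  expect_equal(sum(cases$id == "S2"), 8)
  expect_equal(sum(cases$id == "S1"), 2)
  expect_equal(sum(cases$id == "S4"), 10)
  expect_error(scenarioSpec("S2", "W20", "W20"), "differ")
  expect_error(scenarioSpec("S1", "W20", "W21"), "matching")
  expect_error(scenarioSpec("S3b", "loo:W20", "W21"), "exclude")
  expect_error(scenarioSpec("S6", "W20", "W20"), "genomic")
  # S7 is definitionally a cross-validation on across-environment AEMs
  dos <- makeDosage(30, 25, seed = 47)
  G <- additiveKernel(dos)
  y <- setNames(rnorm(30, 8), cloneIds(dos))
  s7 <- runScenario(scenarioSpec("S7", "across", "G"),
                    aems = list(across = y), kernels = list(G = G),
                    nReps = 4, seed = 3)
  direct <- crossValidate(y, G, nReps = 4, seed = 3)
  expect_identical(predictiveAbilities(s7), predictiveAbilities(direct))
})

test_that("weight-grid endpoints reproduce the pure kernels bit for bit", {
  set.seed(48)
  dos <- makeDosage(45, 40, seed = 48)
  G <- additiveKernel(dos)
  ids <- cloneIds(dos)
  Mv <- tcrossprod(matrix(rnorm(45 * 10), 45)) / 10
  dimnames(Mv) <- list(ids, ids)
  M <- relationshipMatrix(Mv, "M")
  y <- setNames(drop(scale(dosages(dos), scale = FALSE) %*% rnorm(40, 0, 0.3)) +
                  rnorm(45, 0, 1) + 5, ids)
  gs <- weightGridSearch(y, M, G, grid = seq(0, 1, 0.25), nReps = 3,
                         seed = 11)
  pureG <- crossValidate(y, G, nReps = 3, seed = 11)
  pureM <- crossValidate(y, M, nReps = 3, seed = 11)
  expect_equal(predictiveAbilities(gs$results[[1]]),
               predictiveAbilities(pureG), tolerance = 1e-12)
  expect_equal(predictiveAbilities(gs$results[[5]]),
               predictiveAbilities(pureM), tolerance = 1e-12)
  expect_gte(max(gs$table$medianPA) + 1e-12,
             max(gs$table$medianPA[c(1, 5)]))
  expect_error(weightGridSearch(y, M, G, grid = c(0, 1.5)), "\\[0, 1\\]")
})

test_that("flight-date subsets enumerate and reduce the kernel correctly", {
  b <- tinyBundle()
  pr <- processSpectra(b$spectra, seed = 5)
  S <- pr$cloneSpectra$W20
  pl <- adjustForTrial(b$plots, estimateTrialEffects(b$plots))
  a <- aemValues(computeAems(pl, "maturity", "across",
                             withCovariance = FALSE))
  tab <- flightDateSubsets(S, a, nReps = 2, seed = 13)
  expect_equal(nrow(tab), 7)                      # 2^3 - 1 subsets
  expect_equal(tab$mS[tab$subset == "D1+D2+D3"], 21)
  full <- crossValidate(a, spectralKernel(S), nReps = 2, seed = 13)
  expect_equal(tab$medianPA[tab$subset == "D1+D2+D3"], medianPA(full),
               tolerance = 1e-12)
  expect_error(flightDateSubsets(S, a, subsets = list(character(0))),
               "empty")
})
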