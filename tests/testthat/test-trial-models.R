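# Trial adjustment, entry means and heritability against small-instance
# oracles and parameter-recovery checks.

trialConfig <- function(seed = 21) {
  simConfig(nClones = 80, nFamilies = 20, nChecks = 6, nFounders = 12,
            nMarkers = 60, nCausal = 30, nBlocks = 8, seed = seed,
            varTrial = 0, trialEffects = list(W21 = c(0, 5), G21 = c(0, 0)),
            traits = data.frame(name = "t", h2 = 0.85, domFrac = 0.1,
                                gxeFrac = 0.1, overlap = 0.2,
                                transform = FALSE))
}

test_that("an injected trial effect is recovered from the checks and
           removed by adjustment", {
  b <- simulateStudy(trialConfig())
  eff <- estimateTrialEffects(b$plots, trait = "t", env = "W21")
  e2 <- eff$effect[eff$trial == 2]
  expect_lt(abs(e2 - 5), 1)
  # single-trial environments are a no-op
  effW19 <- estimateTrialEffects(b$plots, trait = "t", env = "W19")
  expect_equal(effW19$effect, 0)
  # fixed point: after adjustment the re-estimated contrast is ~0
  adj <- adjustForTrial(b$plots, estimateTrialEffects(b$plots))
  eff2 <- estimateTrialEffects(adj, trait = "t", env = "W21")
  expect_lt(abs(eff2$effect[eff2$trial == 2]), 1e-6)
  # zero recorded effects leave the table unchanged
  eff0 <- eff; eff0$effect <- 0
  expect_identical(adjustForTrial(b$plots, eff0)$value, b$plots$value)
})

test_that("entry means reduce to raw clone means without nuisance variance", {
  set.seed(22)
  d <- expand.grid(clone = sprintf("c%02d", 1:10), env = c("E01", "E02"),
                   stringsAsFactors = FALSE)
  d <- do.call(rbind, replicate(3, d, simplify = FALSE))
  d$trial <- 1; d$block <- rep(1:3, each = 20)
  d$row <- rep(1:6, 10); d$column <- rep(1:5, 12)
  d$trait <- "t"
  d$value <- rnorm(10)[match(d$clone, unique(d$clone))] + rnorm(nrow(d), 0, 0.3)
  a <- computeAems(d, "t", "across", outlierZ = Inf)
  raw <- tapply(d$value, d$clone, mean)
  expect_equal(unname(aemValues(a)[names(raw)]), as.vector(raw),
               tolerance = 1e-5)
})

test_that("entry means are invariant to relabeling of design levels", {
  b <- tinyBundle()
  pl <- adjustForTrial(b$plots, estimateTrialEffects(b$plots))
  a1 <- computeAems(pl, "yield", "single", env = "W20", outlierZ = Inf)
  pl2 <- pl
  pl2$block <- max(pl2$block) + 1 - pl2$block     # reverse block labels
  pl2$row <- paste0("R", pl2$row)                 # rename rows
  a2 <- computeAems(pl2, "yield", "single", env = "W20", outlierZ = Inf)
  expect_equal(aemValues(a1), aemValues(a2), tolerance = 1e-6)
})

test_that("entry means match the generalized-least-squares oracle", {
  b <- tinyBundle()
  pl <- adjustForTrial(b$plots, estimateTrialEffects(b$plots))
  keep <- pl$trait == "yield" & pl$env %in% c("W20", "G20") &
    pl$clone %in% sort(unique(pl$clone))[1:12]
  d <- pl[keep, ]
  a <- computeAems(d, "yield", "across", outlierZ = Inf, fast = FALSE)
  fit <- fitReml("value", d, fixed = "clone",
                 random = c("env", "clone:env", "env:block", "env:row",
                            "env:column"), noIntercept = TRUE)
  vc <- varComp(fit)
  # direct GLS at the fitted variance components
  d$cloneF <- factor(d$clone)
  X <- stats::model.matrix(~ 0 + cloneF, d)
  V <- diag(vc[["residual"]], nrow(d))
  for (term in c("env", "clone:env", "env:block", "env:row", "env:column")) {
    parts <- strsplit(term, ":", fixed = TRUE)[[1]]
    f <- interaction(d[parts], drop = TRUE)
    Zt <- stats::model.matrix(~ 0 + f)
    V <- V + vc[[term]] * tcrossprod(Zt)
  }
  Vinv <- solve(V)
  A <- crossprod(X, Vinv %*% X)
  blue <- solve(A, crossprod(X, Vinv %*% d$value))
  expect_equal(unname(aemValues(a)[sub("^cloneF", "", rownames(blue))]),
               unname(drop(blue)), tolerance = 1e-5)
  expect_equal(unname(diag(aemCovariance(a))),
               unname(diag(solve(A))), tolerance = 1e-4)
})

test_that("the heritability formula and its guards are exact", {
  fit <- new("LmmFit", varComp = c(clone = 3, residual = 1),
             beta = c(mu = 0), Vbeta = matrix(0, 1, 1), blups = list(),
             logRL = 0, converged = TRUE, nobs = 10, details = list())
  aems <- new("AdjustedEntryMeans",
              values = setNames(rnorm(6), paste0("c", 1:6)),
              Vblue = diag(1, 6), response = "t", scope = "across")
  h <- heritability(fit, aems)          # vbar of diag(1) is exactly 2
  expect_equal(h@vbar, 2)
  expect_equal(h@H2, 3 / 4)
  fit0 <- fit; fit0@varComp[["clone"]] <- 0
  expect_equal(heritability(fit0, aems)@H2, 0)
  degen <- aems; degen@Vblue <- matrix(1, 6, 6)
  expect_error(heritability(fit, degen), "vbar")
  # plot basis: sigma2g over the sum of all components
  expect_equal(heritability(fit, basis = "plot")@H2, 3 / 4)
})

test_that("simulated heritability is recovered by the entry-mean formula", {
  b <- tinyBundle()   # starch configured at H2 = 0.90
  pl <- adjustForTrial(b$plots, estimateTrialEffects(b$plots))
  h <- traitHeritability(pl, "starch")
  expect_lt(abs(h@H2 - 0.90), 0.12)
  expect_equal(h@H2, h@sigma2g / (h@sigma2g + h@vbar / 2))
})

test_that("the square-root transform hook reports on the transformed scale", {
  b <- tinyBundle()
  pl <- b$plots[b$plots$trait == "yield", ]
  pl$value <- pl$value^2
  a1 <- computeAems(pl, "yield", "single", env = "W19",
                    sqrtTransform = TRUE, outlierZ = Inf)
  pl2 <- pl; pl2$value <- sqrt(pl2$value)
  a2 <- computeAems(pl2, "yield", "single", env = "W19", outlierZ = Inf)
  expect_equal(aemValues(a1), aemValues(a2))
  pl$value[1] <- -1
  expect_error(computeAems(pl, "yield", "single", env = "W19",
                           sqrtTransform = TRUE), "non-negative")
})

test_that("the studentized-residual outlier pass pulls entry means back", {
  b <- tinyBundle()
  pl <- adjustForTrial(b$plots, estimateTrialEffects(b$plots))
  pl <- pl[pl$trait == "yield", ]
  victim <- pl$clone[pl$env == "W19"][1]
  i <- which(pl$clone == victim & pl$env == "W19")[1]
  clean <- aemValues(computeAems(pl, "yield", "across", outlierZ = Inf))
  pl$value[i] <- pl$value[i] + 40
  noGuard <- aemValues(computeAems(pl, "yield", "across", outlierZ = Inf))
  guarded <- aemValues(computeAems(pl, "yield", "across", outlierZ = 4))
  expect_lt(abs(guarded[victim] - clean[victim]),
            abs(noGuard[victim] - clean[victim]))
})

test_that("channel heritabilities come out per date and across dates", {
  b <- tinyBundle()
  perDate <- channelHeritability(b$spectra, mode = "per-date")
  expect_equal(nrow(perDate), length(unique(paste(b$spectra$channel,
                                                  b$spectra$flight_date))))
  expect_true(all(perDate$H2 >= 0 & perDate$H2 < 1))
  across <- channelHeritability(
    b$spectra[b$spectra$channel %in% c("c490", "c550"), ],
    mode = "across-dates", basis = "plot")
  expect_equal(nrow(across), 2)
  expect_true(all(across$H2 >= 0 & across$H2 < 1))
  # the across-date clone variance excludes the date-specific genetic
  # part, so it cannot exceed the per-date estimate by much; with the
  # date-dominated latent defaults it is clearly smaller
  med <- tapply(perDate$H2[perDate$channel %in% c("c490", "c550")],
                perDate$channel[perDate$channel %in% c("c490", "c550")],
                median)
  entry <- channelHeritability(
    b$spectra[b$spectra$channel %in% c("c490", "c550"), ],
    mode = "across-dates", basis = "entry-mean")
  expect_lt(median(entry$H2), median(med) + 0.05)
})
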