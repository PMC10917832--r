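# The REML engine against closed-form, brute-force and invariance oracles.

test_that("balanced one-way REML reproduces the ANOVA estimators", {
  set.seed(10)
  g <- 20; n <- 5
  d <- data.frame(grp = gl(g, n),
                  y = rep(rnorm(g, 0, 1.2), each = n) + rnorm(g * n))
  fit <- fitReml("y", d, random = "grp")
  gm <- tapply(d$y, d$grp, mean)
  msb <- n * sum((gm - mean(d$y))^2) / (g - 1)
  msw <- sum((d$y - gm[d$grp])^2) / (g * (n - 1))
  expect_equal(unname(varComp(fit)[["grp"]]), (msb - msw) / n,
               tolerance = 1e-6)
  expect_equal(unname(varComp(fit)[["residual"]]), msw, tolerance = 1e-6)
})

test_that("an irrelevant grouping lands at the zero boundary", {
  set.seed(11)
  d <- data.frame(grp = gl(10, 10), y = rnorm(100))
  fit <- fitReml("y", d, random = "grp")
  expect_lt(varComp(fit)[["grp"]], 0.02)
})

test_that("single-kernel REML dominates a brute-force variance grid", {
  inst <- makeKernelInstance(n = 8, m = 30, seed = 12)
  fit <- fitReml(inst$y, kernels = inst$K)
  X <- matrix(1, 8, 1)
  Kv <- relValues(inst$K)
  grid <- expand.grid(s2u = seq(0.02, 8, length.out = 100),
                      s2e = seq(0.02, 8, length.out = 100))
  gridBest <- max(vapply(seq_len(nrow(grid)), function(i)
    bruteLogRL(inst$y, Kv, X, grid$s2u[i], grid$s2e[i]), 0))
  expect_gte(logRestrictedLik(fit) + 1e-6, gridBest)
  # the profiled form agrees with the dense definition at the optimum
  vc <- varComp(fit)
  expect_equal(logRestrictedLik(fit),
               bruteLogRL(inst$y, Kv, X, vc[["u"]], vc[["residual"]]),
               tolerance = 1e-6)
})

test_that("eigendecomposition and direct kernel solvers agree", {
  inst <- makeKernelInstance(n = 25, m = 80, seed = 13)
  fe <- fitReml(inst$y, kernels = inst$K, method = "eigen")
  fd <- fitReml(inst$y, kernels = inst$K, method = "direct")
  expect_equal(varComp(fe), varComp(fd), tolerance = 1e-6)
  expect_equal(logRestrictedLik(fe), logRestrictedLik(fd),
               tolerance = 1e-6)
  expect_equal(ranefBlups(fe)$u, ranefBlups(fd)$u, tolerance = 1e-5)
})

test_that("restricted likelihood ignores the fixed-effect parameterization", {
  set.seed(14)
  d <- data.frame(clone = gl(8, 6), blk = factor(rep(1:6, 8)))
  d$y <- rnorm(8)[d$clone] + rnorm(6, 0, 0.5)[d$blk] + rnorm(48, 0, 0.7)
  fTreat <- fitReml("y", d, fixed = "clone", random = "blk")
  fMeans <- fitReml("y", d, fixed = "clone", random = "blk",
                    noIntercept = TRUE)
  expect_equal(logRestrictedLik(fTreat), logRestrictedLik(fMeans),
               tolerance = 1e-8)
  # and the clone means agree between parameterizations
  m1 <- fixedEffects(fTreat)
  means1 <- c(m1[["(Intercept)"]],
              m1[["(Intercept)"]] + m1[paste0("clone", 2:8)])
  expect_equal(unname(means1), unname(fixedEffects(fMeans)),
               tolerance = 1e-6)
})

test_that("identity-covariance BLUPs center at zero", {
  b <- tinyBundle()
  fit <- fitReml("value", b$plots[b$plots$trait == "yield", ],
                 random = c("clone", "env", "env:block"))
  for (term in names(ranefBlups(fit))) {
    u <- ranefBlups(fit)[[term]]
    expect_lt(abs(sum(u)), 1e-8 * max(1, max(abs(u))) * length(u))
  }
})

test_that("known variance components are recovered without bias", {
  set.seed(15)
  ests <- t(replicate(30, {
    d <- data.frame(grp = gl(15, 6),
                    y = rep(rnorm(15, 0, 1), each = 6) + rnorm(90, 0, 1))
    varComp(fitReml("y", d, random = "grp"))[c("grp", "residual")]
  }))
  for (j in 1:2)
    expect_lt(abs(mean(ests[, j]) - 1), 3 * sd(ests[, j]) / sqrt(30))
})

test_that("the column-variance likelihood-ratio test detects real columns", {
  set.seed(16)
  d <- expand.grid(clone = factor(1:25), block = factor(1:4),
                   column = factor(1:5))
  d$y <- rnorm(25)[d$clone] + rnorm(4, 0, 0.4)[d$block] +
    rnorm(5, 0, 1.5)[d$column] + rnorm(nrow(d), 0, 0.8)
  rl <- rlrtColumnEffect("y", d, randomFull = c("clone", "block", "column"),
                         term = "column", method = "mixture")
  expect_gt(rl$statistic, 0)
  expect_lt(rl$pValue, 0.05)
  expect_true(rl$include)
  # parametric bootstrap agrees on a strong effect
  rb <- rlrtColumnEffect("y", d, randomFull = c("clone", "block", "column"),
                         term = "column", nSim = 60, seed = 2)
  expect_lt(rb$pValue, 0.05)
  # a null column effect is usually not declared significant
  d$y0 <- rnorm(25)[d$clone] + rnorm(nrow(d), 0, 1)
  r0 <- rlrtColumnEffect("y0", d, randomFull = c("clone", "block", "column"),
                         term = "column", nSim = 60, seed = 3)
  expect_true(r0$pValue >= 0 && r0$pValue <= 1)
  expect_error(
    rlrtColumnEffect("y", d, randomFull = c("clone", "block"),
                     term = "column"),
    "must be one of")
})

test_that("aliased fixed designs are rejected with the offending columns", {
  d <- data.frame(a = factor(rep(1:2, 10)), b = factor(rep(1:2, 10)),
                  g = gl(4, 5), y = rnorm(20))
  expect_error(fitReml("y", d, fixed = c("a", "b"), random = "g"),
               "aliased")
})

test_that("missing responses are dropped, absent clones yield no estimate", {
  set.seed(17)
  d <- data.frame(clone = gl(6, 4), blk = factor(rep(1:4, 6)),
                  y = rnorm(24))
  d$y[d$clone == "6"] <- NA
  fit <- fitReml("y", d, fixed = "clone", random = "blk",
                 noIntercept = TRUE)
  expect_equal(length(fixedEffects(fit)), 5)
  expect_equal(fit@nobs, 20)
})
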