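test_that("additive kernel reproduces hand arithmetic and clone identity", {
  z <- matrix(c(3, 1), 2, 1, dimnames = list(c("a", "b"), "m1"))
  G <- additiveKernel(dosageMatrix(z))   # centered to +-1
  expect_equal(relValues(G), matrix(c(1, -1, -1, 1), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))))
  # identical clones give identical kernel rows
  dos <- makeDosage(6, 25, seed = 31)
  Z <- dosages(dos); Z[2, ] <- Z[1, ]
  G2 <- relValues(additiveKernel(dosageMatrix(Z)))
  expect_equal(G2[1, ], G2[2, ],
               ignore_attr = TRUE)
  expect_error(additiveKernel(dosageMatrix(Z[, 0, drop = FALSE])), "m = 0")
  # raw mode reproduces the literal cross-product over m
  Graw <- additiveKernel(dos, center = FALSE)
  expect_equal(relValues(Graw), tcrossprod(dosages(dos)) / 25,
               ignore_attr = TRUE)
})

test_that("full sibs are more related than unrelated clones in G", {
  b <- tinyBundle()
  G <- relValues(additiveKernel(qcMarkers(b$dosage)))
  ped <- b$pedigree[!b$pedigree$is_check, ]
  G <- G[ped$clone, ped$clone]
  fam <- outer(ped$family, ped$family, "==")
  off <- upper.tri(G)
  expect_gt(mean(G[off & fam]), mean(G[off & !fam]))
})

test_that("dominance covariate counts heterozygous allele pairs", {
  # dosage d contributes d(4-d)/6 heterozygous pairings of 4 alleles:
  # 0 or 4 -> 0, 2 -> 4/6 (enumerated over the C(4,2) = 6 pairs)
  z <- matrix(c(0, 2, 4, 2, 2, 2), 3, 2,
              dimnames = list(c("a", "b", "c"), c("m1", "m2")))
  W <- z * (4 - z) / 6
  expect_equal(W[, "m1"], c(a = 0, b = 4 / 6, c = 0))
  D <- dominanceKernel(dosageMatrix(z))
  expect_equal(mean(diag(relValues(D))), 1)
  # fully homozygous population carries no dominance variation
  zh <- matrix(c(0, 4, 4, 0), 2, 2,
               dimnames = list(c("a", "b"), c("m1", "m2")))
  expect_warning(D0 <- dominanceKernel(dosageMatrix(zh)), "zero matrix")
  expect_true(all(relValues(D0) == 0))
})

test_that("epistatic kernels are rescaled Hadamard products", {
  dos <- makeDosage(5, 30, seed = 32)
  G <- additiveKernel(dos); D <- dominanceKernel(dos)
  epi <- epistaticKernels(G, D)
  g <- relValues(G); d <- relValues(D)
  expect_equal(relValues(epi$AA), g * g / mean(diag(g * g)),
               ignore_attr = TRUE)
  expect_equal(relValues(epi$AD), g * d / mean(diag(g * d)),
               ignore_attr = TRUE)
  expect_equal(relValues(epi$DD), d * d / mean(diag(d * d)),
               ignore_attr = TRUE)
  # identity stays identity under self-product
  I3 <- relationshipMatrix(
    diag(3) |> `dimnames<-`(list(letters[1:3], letters[1:3])), "G")
  epiI <- epistaticKernels(I3, I3)
  expect_equal(relValues(epiI$AA), diag(3), ignore_attr = TRUE)
  G2 <- additiveKernel(makeDosage(4, 30, seed = 33))
  expect_error(epistaticKernels(G, G2), "identical clone sets")
})

test_that("spectral kernel divides the cross product by m_s", {
  V <- matrix(c(1, -1), 2, 1, dimnames = list(c("a", "b"), "W20.D1.c490"))
  M <- spectralKernel(spectraMatrix(V))
  expect_equal(relValues(M), matrix(c(1, -1, -1, 1), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))))
  expect_equal(M@provenance$m_s, 1)
  # duplicated spectral rows duplicate kernel rows
  V2 <- matrix(rnorm(8), 4, 2, dimnames = list(letters[1:4], c("f1", "f2")))
  V2[2, ] <- V2[1, ]
  M2 <- relValues(spectralKernel(spectraMatrix(V2)))
  expect_equal(M2[1, ], M2[2, ], ignore_attr = TRUE)
})

test_that("column-joining equal-width scaled spectra averages the kernels", {
  set.seed(34)
  mk <- function(seed) {
    set.seed(seed)
    V <- matrix(rnorm(40 * 6), 40, 6,
                dimnames = list(sprintf("c%02d", 1:40), paste0("f", 1:6)))
    scaleSpectra(spectraMatrix(V, data.frame(env = paste0("E", seed),
                                             date = "D1",
                                             channel = paste0("f", 1:6))))
  }
  S1 <- mk(1); S2 <- mk(2)
  cj <- combineSpectra(S1, S2, mode = "cjM")
  expect_equal(featureCount(cj), 12)
  Kcj <- relValues(spectralKernel(cj, "cjM"))
  Kavg <- (relValues(spectralKernel(S1)) + relValues(spectralKernel(S2))) / 2
  expect_lt(max(abs(Kcj - Kavg)), 1e-10)
  expect_error(combineSpectra(S1, mk(3), mode = "MAEM"), "plot-level")
})

test_that("MAEM combination returns per-clone means across environments", {
  b <- tinyBundle()
  pr <- processSpectra(b$spectra, seed = 5)
  maem <- combineSpectra(mode = "MAEM", spectraPlots = pr$cleanLong)
  expect_equal(featureCount(maem), 21)
  expect_true(all(sort(unique(pr$cleanLong$clone)) %in% cloneIds(maem)))
})

test_that("weighted kernel combination is convex and exact at endpoints", {
  dos <- makeDosage(10, 40, seed = 35)
  G <- additiveKernel(dos)
  M <- relationshipMatrix(
    diag(10) |> `dimnames<-`(dimnames(relValues(G))), "M")
  expect_identical(relValues(weightedKernel(M, G, 0)), relValues(G))
  expect_identical(relValues(weightedKernel(M, G, 1)), relValues(M))
  M2 <- relationshipMatrix(
    diag(2) |> `dimnames<-`(list(c("a", "b"), c("a", "b"))), "M")
  G2 <- relationshipMatrix(matrix(c(1, 0.5, 0.5, 1), 2,
                                  dimnames = list(c("a", "b"),
                                                  c("a", "b"))), "G")
  expect_equal(relValues(weightedKernel(M2, G2, 0.5)),
               matrix(c(1, 0.25, 0.25, 1), 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))
  expect_error(weightedKernel(M, G, 1.2), "\\[0, 1\\]")
  # PSD preserved across the grid (validity runs in the constructor)
  for (x in seq(0, 1, 0.25))
    expect_s4_class(weightedKernel(M, G, x), "RelationshipMatrix")
})

test_that("every pipeline kernel passes the symmetry/PSD validity checks", {
  b <- tinyBundle()
  ks <- buildKernels(qcMarkers(b$dosage), processSpectra(b$spectra, seed = 5))
  flat <- c(ks[!vapply(ks, is.list, TRUE)],
            ks[["G+D+E"]])
  for (K in flat) {
    v <- relValues(K)
    expect_lt(max(abs(v - t(v))), 1e-10)
    ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(abs(ev)))
  }
  # spectral and genomic relatedness are nearly uncorrelated patterns
  offd <- upper.tri(relValues(ks$G))
  r <- cor(relValues(ks$G)[offd], relValues(ks$W20)[offd])
  expect_lt(abs(r), 0.3)
})
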