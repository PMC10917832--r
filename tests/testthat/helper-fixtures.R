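# Shared in-code fixtures. Everything is generated programmatically under
# fixed seeds; the tiny study bundle is cached per test run.

tinyConfig <- function(seed = 11, ...) {
  simConfig(nClones = 60, nFamilies = 15, nChecks = 4, nFounders = 10,
            nMarkers = 80, nCausal = 40, nBlocks = 4, seed = seed, ...)
}

tinyBundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateStudy(tinyConfig())
    cache
  }
})

# small dosage matrix with clone/marker names
makeDosage <- function(n, m, seed = 1, p = 0.5) {
  set.seed(seed)
  Z <- matrix(rbinom(n * m, 4, p), n, m,
              dimnames = list(sprintf("c%03d", seq_len(n)),
                              sprintf("m%03d", seq_len(m))))
  dosageMatrix(Z)
}

# well-conditioned kernel BLUP instance: y = mu + u + e with u drawn from
# the (uncentered, full-rank) additive kernel so the residual variance is
# identifiable
makeKernelInstance <- function(n = 20, m = 60, seed = 7, noiseSd = 1) {
  set.seed(seed)
  dos <- makeDosage(n, m, seed = seed)
  K <- additiveKernel(dos, center = FALSE)
  Kv <- relValues(K)
  u <- drop(t(chol(Kv + diag(1e-8, n))) %*% rnorm(n))
  y <- setNames(10 + u + rnorm(n, 0, noiseSd), rownames(Kv))
  list(K = K, y = y, dos = dos)
}

# restricted log-likelihood of the single-kernel model computed from the
# definition (dense V), independent of the engine's profiled form
bruteLogRL <- function(y, K, X, s2u, s2e) {
  n <- length(y)
  V <- s2u * K + s2e * diag(n)
  Vinv <- solve(V)
  A <- crossprod(X, Vinv %*% X)
  beta <- solve(A, crossprod(X, Vinv %*% y))
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V, logarithm = TRUE)$modulus +
                       determinant(A, logarithm = TRUE)$modulus +
                       crossprod(r, Vinv %*% r) +
                       (n - ncol(X)) * log(2 * pi)))
}
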