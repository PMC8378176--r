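test_that("factor initialization is reproducible, strictly positive, and validated", {
  a <- initializeFactors(6, 3, seed = 99)
  b <- initializeFactors(6, 3, seed = 99)
  expect_identical(a@F, b@F)
  expect_identical(a@S, b@S)
  expect_identical(a@G, b@G)
  expect_true(all(a@F > 0) && all(a@S > 0) && all(a@G > 0))
  expect_s4_class(initializeFactors(4, 4, seed = 1), "TriFactorization")
  expect_error(initializeFactors(4, 0, seed = 1), "rank")
  expect_error(initializeFactors(4, 5, seed = 1), "rank")
})

test_that("Frobenius objective matches the brute-force residual sum", {
  set.seed(3)
  P <- matrix(runif(16), 4, 4)
  fac <- initializeFactors(4, 2, seed = 5)
  expect_equal(nmtfObjective(P, fac),
               oracle_objective(P, fac@F, fac@S, fac@G), tolerance = 1e-12)
  # zero-residual case
  facI <- fac
  facI@F <- diag(4); facI@G <- diag(4); facI@S <- P
  facI@k <- 4L
  expect_equal(nmtfObjective(P, facI), 0)
  # zero target reduces to the factor product norm
  expect_equal(nmtfObjective(matrix(0, 4, 4), fac),
               sum((fac@F %*% fac@S %*% t(fac@G))^2))
  expect_error(nmtfObjective(matrix(0, 5, 5), fac), "dimension")
})

test_that("multiplicative sweeps preserve non-negativity and never increase the objective", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(5:20, 1); k <- sample(2:4, 1)
    M <- matrix(runif(n * n), n, n)
    P <- (M + t(M)) / 2
    fac <- initializeFactors(n, k, seed = rep)
    prev <- nmtfObjective(P, fac)
    for (i in 1:100) fac <- nmtfUpdate(P, fac)
    tr <- c(prev, fac@objectiveTrace)
    expect_true(all(diff(tr) <= 1e-9 * utils::head(tr, -1)))
    expect_true(all(fac@F >= 0) && all(fac@S >= 0) && all(fac@G >= 0))
  }
})

test_that("a balanced KKT point is a fixed point of the update", {
  # F = G = I, S = P: numerators equal denominators elementwise
  n <- 4
  set.seed(8)
  M <- matrix(runif(n * n), n, n); P <- (M + t(M)) / 2
  fac <- initializeFactors(n, n, seed = 1)
  fac@F <- diag(n) + 0; fac@G <- diag(n) + 0; fac@S <- P
  out <- nmtfUpdate(P, fac, eps = 0)
  expect_equal(out@F, fac@F, tolerance = 1e-12)
  expect_equal(out@G, fac@G, tolerance = 1e-12)
  expect_equal(out@S, fac@S, tolerance = 1e-12)
})

test_that("factorization stopping rules and determinism behave as documented", {
  set.seed(13)
  M <- matrix(runif(36), 6, 6); P <- (M + t(M)) / 2
  one <- suppressMessages(nmtf(P, k = 2, seed = 1, maxIter = 50, relTol = Inf))
  expect_equal(one@iterations, 1L)
  expect_equal(one@stopReason, "relTol")

  a <- suppressMessages(nmtf(P, k = 2, seed = 4, maxIter = 100, relTol = 0))
  b <- suppressMessages(nmtf(P, k = 2, seed = 4, maxIter = 100, relTol = 0))
  expect_identical(a@objectiveTrace, b@objectiveTrace)
  expect_identical(a@F, b@F)
  expect_equal(a@iterations, 100L)
  expect_equal(a@stopReason, "maxIter")

  # zero target: factors collapse to zero in one sweep, no error
  z <- suppressMessages(nmtf(matrix(0, 5, 5), k = 2, seed = 2, maxIter = 500))
  expect_true(all(is.finite(z@objectiveTrace)))
  expect_equal(utils::tail(z@objectiveTrace, 1), 0)
})

test_that("reconstruction matches the brute-force triple product", {
  fac <- initializeFactors(4, 3, seed = 17)
  Y <- assocMatrix(reconstruct(fac, ids = letters[1:4]))
  n <- 4
  Yo <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    for (u in 1:3) for (v in 1:3)
      Yo[i, j] <- Yo[i, j] + fac@F[i, u] * fac@S[u, v] * fac@G[j, v]
  expect_equal(unname(Y), Yo, tolerance = 1e-12)
  expect_true(all(Y >= 0))
  # identity-like factors reproduce the target; zero core gives zero
  set.seed(2); P <- matrix(runif(16), 4, 4)
  facI <- fac; facI@F <- diag(4); facI@G <- diag(4); facI@S <- P; facI@k <- 4L
  expect_equal(unname(assocMatrix(reconstruct(facI))), P)
  fac0 <- fac; fac0@S <- matrix(0, 3, 3)
  expect_true(all(assocMatrix(reconstruct(fac0)) == 0))
})

test_that("transition matrix follows the max/row-sum rule and renormalization", {
  # asymmetric 2x2: row 1 sum = 1, entry = max(1,3) = 3 before renormalization
  Y <- matrix(c(0, 3, 1, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  Y <- t(Y)  # Y = [[0,1],[3,0]]
  raw <- transitionMatrix(Y, rowRenormalize = FALSE)
  expect_equal(unname(probMatrix(raw)), matrix(c(0, 3, 3, 0), 2, 2, byrow = TRUE) / c(1, 3))
  ren <- transitionMatrix(Y, rowRenormalize = TRUE)
  expect_equal(unname(probMatrix(ren)), matrix(c(0, 1, 1, 0), 2, 2))

  # symmetric input with equal row sums: plain division by the row sum
  S <- matrix(c(0, 2, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(probMatrix(transitionMatrix(S))), S / 2, ignore_attr = TRUE)

  # zero row stays zero; other rows sum to one
  Z <- matrix(c(0, 1, 0, 2, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  tz <- transitionMatrix(Z)
  expect_equal(rowSums(probMatrix(tz)), c(1, 1, 0), ignore_attr = TRUE)
  expect_error(transitionMatrix(matrix(c(0, -1, 1, 0), 2, 2)), "non-negative")
})

test_that("symmetric reconstructions make renormalization equal plain row normalization", {
  set.seed(31)
  M <- matrix(runif(64), 8, 8); Y <- M + t(M)
  P1 <- probMatrix(transitionMatrix(Y, rowRenormalize = TRUE))
  expect_equal(unname(P1), unname(Y / rowSums(Y)), tolerance = 1e-12)
  expect_equal(unname(rowSums(P1)), rep(1, 8), tolerance = 1e-12)
})

test_that("factor checkpoints round-trip through plain-text files", {
  set.seed(41)
  M <- matrix(runif(49), 7, 7)
  ids <- sprintf("y%02d", 1:7)
  dimnames(M) <- list(ids, ids)
  fac <- suppressMessages(nmtf(M + t(M), k = 3, seed = 6, maxIter = 40))
  dir <- tempfile()
  writeFactors(fac, dir)
  back <- readFactors(dir)
  expect_equal(back@F, fac@F, tolerance = 1e-12)
  expect_equal(back@S, fac@S, tolerance = 1e-12)
  expect_equal(back@G, fac@G, tolerance = 1e-12)
  expect_identical(back@k, fac@k)
  expect_identical(back@stopReason, fac@stopReason)
  expect_equal(utils::tail(back@objectiveTrace, 1),
               utils::tail(fac@objectiveTrace, 1), tolerance = 1e-12)
  expect_identical(rownames(back@F), ids)
})
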