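.as_assoc <- function(x) {
  if (is(x, "WeightedNetwork")) assocMatrix(x)
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected a WeightedNetwork or a numeric matrix")
}

#' Random initialization of the tri-factorization
#'
#' Fills F (n x k), S (k x k) and G (n x k) with independent draws uniform
#' on (0, 1]. Strict positivity matters: multiplicative updates can never
#' move an entry off an exact zero, so a zero-free start keeps the whole
#' parameter space reachable. Reproducible for a fixed seed.
#'
#' @param n number of proteins (rows of F and G).
#' @param k factorization rank, `1 <= k <= n`.
#' @param seed integer RNG seed.
#' @return a [TriFactorization-class] with an empty objective trace.
#' @export
initializeFactors <- function(n, k, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 1L || k > n) stop("rank k must satisfy 1 <= k <= n")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  draw <- function(nr, nc) matrix(1 - stats::runif(nr * nc), nr, nc) # (0, 1]
  new("TriFactorization",
      F = draw(n, k), S = draw(k, k), G = draw(n, k),
      k = k, seed = as.integer(seed), objectiveTrace = numeric(0),
      iterations = 0L, stopReason = "")
}

#' Frobenius objective of a tri-factorization
#'
#' \eqn{D = ||P_{CoN} - F S G^T||_F^2}, the quantity minimized by the
#' multiplicative updates.
#'
#' @param P target matrix (CoN-weighted [WeightedNetwork-class] or matrix).
#' @param fac a [TriFactorization-class].
#' @return a single non-negative number.
#' @export
nmtfObjective <- function(P, fac) {
  P <- .as_assoc(P)
  if (nrow(P) != nrow(fac@F))
    stop("matrix dimension does not match the factorization")
  R <- P - fac@F %*% fac@S %*% t(fac@G)
  sum(R * R)
}

.nmtf_sweep <- function(P, Pt, F_, S, G, eps) {
  F_ <- F_ * (P %*% G %*% t(S)) / (F_ %*% S %*% crossprod(G) %*% t(S) + eps)
  G  <- G * (Pt %*% F_ %*% S) / (G %*% t(S) %*% crossprod(F_) %*% S + eps)
  S  <- S * (t(F_) %*% P %*% G) / (crossprod(F_) %*% S %*% crossprod(G) + eps)
  list(F = F_, S = S, G = G)
}

#' One multiplicative update sweep
#'
#' Applies, in order and each using the freshest factors,
#' \deqn{F \leftarrow F \odot \frac{P G S^T}{F S G^T G S^T + \epsilon},\quad
#'       G \leftarrow G \odot \frac{P^T F S}{G S^T F^T F S + \epsilon},\quad
#'       S \leftarrow S \odot \frac{F^T P G}{F^T F S G^T G + \epsilon}.}
#' These are the KKT-derived rules for the Frobenius objective; the small
#' \eqn{\epsilon} in every denominator guards exact zeros. Non-negativity is
#' preserved exactly and the objective does not increase (to rounding).
#'
#' @param P target matrix (CoN-weighted network or numeric matrix).
#' @param fac current [TriFactorization-class].
#' @param eps denominator guard, default `1e-12`.
#' @return the updated [TriFactorization-class], with the post-sweep
#'   objective appended to its trace.
#' @export
nmtfUpdate <- function(P, fac, eps = 1e-12) {
  P <- .as_assoc(P)
  up <- .nmtf_sweep(P, t(P), fac@F, fac@S, fac@G, eps)
  if (anyNA(up$F) || anyNA(up$S) || anyNA(up$G) ||
      !all(is.finite(up$F)) || !all(is.finite(up$S)) || !all(is.finite(up$G)))
    stop(sprintf("NaN/Inf in factors at iteration %d", fac@iterations + 1L))
  fac@F <- up$F; fac@S <- up$S; fac@G <- up$G
  fac@iterations <- fac@iterations + 1L
  R <- P - up$F %*% up$S %*% t(up$G)
  fac@objectiveTrace <- c(fac@objectiveTrace, sum(R * R))
  fac
}

#' Non-negative matrix tri-factorization by multiplicative updates
#'
#' Factorizes a non-negative association matrix as \eqn{P \approx F S G^T}
#' by iterating [nmtfUpdate()] sweeps from a uniform-(0,1] start, recording
#' the full objective trace. Iteration stops when the relative per-sweep
#' objective decrease falls below `relTol`, when the objective falls below
#' `targetObjective` (if given), or at `maxIter`; the stop reason is
#' recorded on the result and reported via a message.
#'
#' The rank default follows the regime used for genome-scale PPI networks
#' (a few thousand proteins); for small matrices pass a small `k`.
#'
#' @param P CoN-weighted [WeightedNetwork-class] or non-negative matrix.
#' @param k factorization rank.
#' @param seed RNG seed for [initializeFactors()].
#' @param maxIter maximum number of update sweeps.
#' @param relTol relative objective-decrease stopping threshold.
#' @param eps denominator guard passed to the update rules.
#' @param targetObjective optional absolute objective value below which
#'   iteration stops early (e.g. a relative tolerance times
#'   \eqn{||P||_F^2}).
#' @return a [TriFactorization-class]; row names of F and G carry the
#'   protein identifiers when `P` is a WeightedNetwork.
#' @export
nmtf <- function(P, k = 100L, seed = 1L, maxIter = 2000L, relTol = 1e-6,
                 eps = 1e-12, targetObjective = NULL) {
  ids <- if (is(P, "WeightedNetwork")) proteinIds(P) else rownames(P)
  P <- .as_assoc(P)
  if (any(P < 0)) stop("NMTF requires a non-negative target matrix")
  fac <- initializeFactors(nrow(P), k, seed)
  F_ <- fac@F; S <- fac@S; G <- fac@G
  Pt <- t(P)
  prev <- {R <- P - F_ %*% S %*% t(G); sum(R * R)}
  trace <- numeric(maxIter)
  reason <- "maxIter"
  it <- 0L
  for (i in seq_len(maxIter)) {
    up <- .nmtf_sweep(P, Pt, F_, S, G, eps)
    F_ <- up$F; S <- up$S; G <- up$G
    R <- P - F_ %*% S %*% t(G)
    ob <- sum(R * R)
    if (is.na(ob) || !is.finite(ob))
      stop(sprintf("NaN/Inf in factors at iteration %d", i))
    trace[i] <- ob
    it <- i
    if (!is.null(targetObjective) && ob < targetObjective) {
      reason <- "targetObjective"
      break
    }
    if ((prev - ob) <= relTol * prev) {
      reason <- "relTol"
      break
    }
    prev <- ob
  }
  message(sprintf("nmtf: stopped after %d sweeps (%s), objective %.6g",
                  it, reason, trace[it]))
  if (!is.null(ids)) {
    rownames(F_) <- ids
    rownames(G) <- ids
  }
  new("TriFactorization", F = F_, S = S, G = G, k = as.integer(k),
      seed = as.integer(seed), objectiveTrace = trace[seq_len(it)],
      iterations = it, stopReason = reason)
}

#' Reconstruct the completed association matrix
#'
#' \eqn{Y = F S G^T}: the dense, entrywise non-negative reconstruction in
#' which latent protein associations absent from the CoN matrix surface as
#' positive entries.
#'
#' @param fac a [TriFactorization-class].
#' @param ids protein identifiers for the result; defaults to the row names
#'   carried by the factors.
#' @return a [WeightedNetwork-class] with `stage = "reconstructed"`.
#' @export
reconstruct <- function(fac, ids = rownames(fac@F)) {
  Y <- fac@F %*% fac@S %*% t(fac@G)
  Y[Y < 0] <- 0  # guard rounding; factors are non-negative
  if (is.null(ids)) ids <- sprintf("p%0*d", nchar(nrow(Y)), seq_len(nrow(Y)))
  WeightedNetwork(ids, Y, "reconstructed")
}

#' Transition matrix from a reconstructed network
#'
#' Builds the propagation operator
#' \deqn{P^*(i,j) = \frac{\max(Y_{ij}, Y_{ji})}{\sum_k Y_{ik}}}
#' for rows with a positive sum, and an all-zero row otherwise. The
#' max-symmetrization restores the undirectedness of protein interaction
#' that the tri-factorization does not enforce, but the row-sum denominator
#' makes the result row-oriented rather than symmetric; with
#' `rowRenormalize = TRUE` (default) every nonzero row is afterwards
#' rescaled to sum exactly to 1, which bounds the operator's spectral
#' radius by 1 and makes the damped ranking iteration a contraction for
#' any damping factor below 1. `rowRenormalize = FALSE` keeps the raw
#' quotient form.
#'
#' @param Y reconstructed [WeightedNetwork-class] or non-negative matrix.
#' @param rowRenormalize rescale nonzero rows to sum 1 (default `TRUE`).
#' @return a [TransitionMatrix-class].
#' @export
transitionMatrix <- function(Y, rowRenormalize = TRUE) {
  ids <- if (is(Y, "WeightedNetwork")) proteinIds(Y) else rownames(Y)
  Y <- .as_assoc(Y)
  if (any(Y < 0)) stop("transition matrix requires a non-negative input")
  if (is.null(ids)) ids <- sprintf("p%0*d", nchar(nrow(Y)), seq_len(nrow(Y)))
  M <- pmax(Y, t(Y))
  rs <- rowSums(Y)
  P <- M / ifelse(rs > 0, rs, 1)
  P[rs == 0, ] <- 0
  if (rowRenormalize) {
    rs2 <- rowSums(P)
    P <- P / ifelse(rs2 > 0, rs2, 1)
  }
  new("TransitionMatrix", ids = ids, P = unname(P),
      rowRenormalized = isTRUE(rowRenormalize))
}

#' Write / read a tri-factorization checkpoint
#'
#' Persists the three factors as plain TSV matrices (`F.tsv`, `S.tsv`,
#' `G.tsv`) plus a `metadata.json` carrying the rank, seed, iteration count,
#' stop reason and final objective, so long factorizations can be resumed or
#' audited. `readFactors()` restores an equivalent [TriFactorization-class]
#' (the full objective trace is not persisted; the final value is).
#'
#' @param fac a [TriFactorization-class].
#' @param dir checkpoint directory (created if needed).
#' @return `writeFactors()`: `dir`, invisibly. `readFactors()`: a
#'   [TriFactorization-class].
#' @export
writeFactors <- function(fac, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(M, name)
    utils::write.table(M, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  wr(fac@F, "F.tsv"); wr(fac@S, "S.tsv"); wr(fac@G, "G.tsv")
  if (!is.null(rownames(fac@F)))
    writeLines(rownames(fac@F), file.path(dir, "ids.txt"))
  jsonlite::write_json(
    list(k = fac@k, seed = fac@seed, iterations = fac@iterations,
         stopReason = fac@stopReason,
         finalObjective = if (length(fac@objectiveTrace))
           utils::tail(fac@objectiveTrace, 1L) else NULL),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeFactors
#' @export
readFactors <- function(dir) {
  rd <- function(name)
    as.matrix(utils::read.table(file.path(dir, name), sep = "\t"))
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  F_ <- unname(rd("F.tsv")); S <- unname(rd("S.tsv")); G <- unname(rd("G.tsv"))
  idsPath <- file.path(dir, "ids.txt")
  if (file.exists(idsPath)) {
    ids <- readLines(idsPath)
    rownames(F_) <- ids
    rownames(G) <- ids
  }
  new("TriFactorization", F = F_, S = S, G = G,
      k = as.integer(meta$k), seed = as.integer(meta$seed),
      objectiveTrace = if (is.null(meta$finalObjective)) numeric(0)
                       else as.numeric(meta$finalObjective),
      iterations = as.integer(meta$iterations),
      stopReason = as.character(meta$stopReason))
}
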