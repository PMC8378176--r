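#' Homology (conservation) scores
#'
#' \eqn{S_H(p_i) = H(p_i) / \max_j H(p_j)}: each protein's ortholog-species
#' count normalized by the network-wide maximum, reflecting the observation
#' that proteins conserved across more reference species are more likely to
#' be essential. If every count is zero the scores are all zero and a
#' warning is raised.
#'
#' @param ann an [AnnotationSet-class].
#' @param index optional protein identifiers to align to (defaults to the
#'   annotation set's own index).
#' @return a [ScoreVector-class] with `stage = "SH"`, values in [0, 1].
#' @export
homologyScores <- function(ann, index = proteinIds(ann)) {
  H <- homologyCounts(ann)[index]
  H[is.na(H)] <- 0L
  mx <- max(H)
  if (mx == 0L) {
    warning("all homology counts are zero; S_H is identically 0")
    return(ScoreVector(index, numeric(length(index)), "SH"))
  }
  ScoreVector(index, as.numeric(H) / mx, "SH")
}

#' Compartment occurrence frequencies
#'
#' \eqn{OF(r) = |SN(r)| / \max_k |SN(k)|} where \eqn{|SN(r)|} counts the
#' indexed proteins annotated to compartment r: the most populated
#' compartment scores 1 and every other compartment scores its relative
#' occupancy.
#'
#' @inheritParams homologyScores
#' @return named numeric vector, compartment -> frequency in (0, 1]; empty
#'   (with a warning) when no protein carries a compartment label.
#' @export
localizationFrequencies <- function(ann, index = proteinIds(ann)) {
  C <- compartmentSets(ann)[index]
  labels <- unlist(C, use.names = FALSE)
  if (length(labels) == 0L) {
    warning("no subcellular-localization annotations; frequency map is empty")
    return(stats::setNames(numeric(0), character(0)))
  }
  cnt <- table(labels)
  stats::setNames(as.numeric(cnt) / max(cnt), names(cnt))
}

#' Subcellular-localization scores
#'
#' \eqn{S_L(p_i) = \max_{r \in C(p_i)} OF(r)}: a protein scores the
#' frequency of its most common compartment, and 0 when it has no
#' localization annotation. Essential proteins tend to concentrate in a few
#' heavily populated compartments, which this score rewards.
#'
#' @param ann an [AnnotationSet-class].
#' @param OF compartment frequency map from [localizationFrequencies()].
#' @param index optional identifiers to align to.
#' @return a [ScoreVector-class] with `stage = "SL"`, values in [0, 1].
#' @export
localizationScores <- function(ann, OF = localizationFrequencies(ann, index),
                               index = proteinIds(ann)) {
  C <- compartmentSets(ann)[index]
  vals <- vapply(C, function(cs) {
    f <- OF[cs]
    f <- f[!is.na(f)]
    if (length(f)) max(f) else 0
  }, numeric(1))
  ScoreVector(index, vals, "SL")
}

#' Initial scores
#'
#' \eqn{S_I(p_i) = S_H(p_i) \times S_L(p_i)}: the product of the
#' conservation and localization scores, used both as the seed and as the
#' restart distribution of the ranking iteration. A protein must carry both
#' signals to receive a positive initial score.
#'
#' @param SH homology [ScoreVector-class].
#' @param SL localization [ScoreVector-class] on the same index.
#' @return a [ScoreVector-class] with `stage = "SI"`.
#' @export
initialScores <- function(SH, SL) {
  if (!identical(proteinIds(SH), proteinIds(SL)))
    stop("S_H and S_L must be aligned to the same protein index")
  vals <- scoreValues(SH) * scoreValues(SL)
  if (all(vals == 0))
    warning("all initial scores are zero; the ranking will be driven by network propagation only")
  ScoreVector(proteinIds(SH), unname(vals), "SI")
}

#' Rank proteins by damped fixed-point iteration
#'
#' Solves \eqn{S_F = \alpha P^* S_F + (1-\alpha) S_I} by Jacobi iteration
#' \deqn{S_F^{(t)} = \alpha P^* S_F^{(t-1)} + (1-\alpha) S_I,\qquad
#'       S_F^{(0)} = S_I,}
#' a personalized-PageRank analogue in which each protein accumulates a
#' damped share of its neighbors' scores on top of its own annotation-based
#' initial score. Row i of \eqn{P^*} holds the outgoing weights of protein
#' i, so protein i receives \eqn{\alpha \sum_j P^*(i,j) S_F(j)}. With row
#' sums of \eqn{P^*} at most 1 and \eqn{\alpha < 1} the map is an
#' \eqn{\alpha}-contraction in the L1 norm, so the iteration converges
#' geometrically to the unique fixed point.
#'
#' Iteration stops when \eqn{||S_F^{(t)} - S_F^{(t-1)}||_1 < \epsilon};
#' non-convergence at `maxIter` yields a warning with the final residual and
#' the last iterate is returned.
#'
#' @param Pstar a [TransitionMatrix-class].
#' @param SI initial [ScoreVector-class] on the same index.
#' @param alpha damping factor in [0, 1): weight of the neighbor-induction
#'   term. Default 0.2, the operating point at which the method performs
#'   well across top-k cutoffs.
#' @param epsilon L1 stopping threshold (default `1e-6`).
#' @param maxIter iteration cap (default `10000`).
#' @return a [ScoreVector-class] with `stage = "SF"`; `metadata` records
#'   `iterations`, `residual` and `converged`.
#' @export
rankProteins <- function(Pstar, SI, alpha = 0.2, epsilon = 1e-6,
                         maxIter = 10000L) {
  stopifnot(is(Pstar, "TransitionMatrix"), is(SI, "ScoreVector"))
  if (alpha < 0 || alpha >= 1) stop("alpha must satisfy 0 <= alpha < 1")
  if (!identical(proteinIds(Pstar), proteinIds(SI)))
    stop("transition matrix and initial scores must share one protein index")
  P <- probMatrix(Pstar)
  si <- unname(scoreValues(SI))
  sf <- si
  it <- 0L
  resid <- Inf
  repeat {
    it <- it + 1L
    new <- alpha * as.numeric(P %*% sf) + (1 - alpha) * si
    resid <- sum(abs(new - sf))
    sf <- new
    if (resid < epsilon || it >= maxIter) break
  }
  converged <- resid < epsilon
  if (!converged)
    warning(sprintf("ranking iteration did not converge in %d iterations (L1 residual %.3g)",
                    it, resid))
  ScoreVector(proteinIds(SI), sf, "SF",
              metadata = list(iterations = it, residual = resid,
                              converged = converged, alpha = alpha))
}

#' Top-K proteins of a score vector
#'
#' Proteins sorted by score, descending, ties broken lexicographically by
#' identifier so ranked tables are reproducible; the first K are returned.
#'
#' @param SF a [ScoreVector-class].
#' @param K number of proteins to return, `K <= n`. Defaults to the full
#'   ranking.
#' @return character vector of K protein identifiers, best first.
#' @export
topProteins <- function(SF, K = length(proteinIds(SF))) {
  ids <- proteinIds(SF)
  if (K > length(ids)) stop("K exceeds the number of proteins")
  v <- scoreValues(SF)
  ord <- order(-unname(v), ids, method = "radix")
  ids[ord][seq_len(K)]
}
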