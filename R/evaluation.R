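.check_gold <- function(ranking, gold) {
  gold <- intersect(gold, ranking)
  if (length(gold) == 0L)
    stop("gold-standard set has no overlap with the ranked proteins")
  gold
}

#' True-essential counts at top-K cutoffs
#'
#' For each requested cutoff K, the number of gold-standard essentials among
#' the first K ranked proteins — the headline comparison used to contrast
#' ranking methods (conventionally at K = 100, 200, ..., 600).
#'
#' @param ranking character vector of protein identifiers, best first.
#' @param gold character vector of gold-standard essential identifiers.
#' @param cutoffs integer vector of K values, each `<= length(ranking)`.
#' @return named integer vector, cutoff -> hit count.
#' @export
topkHitCounts <- function(ranking, gold,
                          cutoffs = c(100L, 200L, 300L, 400L, 500L, 600L)) {
  gold <- .check_gold(ranking, gold)
  if (any(cutoffs > length(ranking)))
    stop("cutoffs must not exceed the ranking length")
  hits <- cumsum(ranking %in% gold)
  stats::setNames(as.integer(hits[cutoffs]), cutoffs)
}

#' Precision-recall curve over all ranking cutoffs
#'
#' Treating the top k proteins as the positive prediction for every cutoff
#' k = 1..n: precision = hits(k)/k, recall = hits(k)/|gold|. The AUC is the
#' trapezoidal area over the achieved (recall, precision) points, with no
#' interpolation to recall 0, so curves from different methods on the same
#' universe integrate identically.
#'
#' @inheritParams topkHitCounts
#' @return list with `points` (data.frame `k`, `recall`, `precision`) and
#'   `auc`.
#' @export
prCurve <- function(ranking, gold) {
  gold <- .check_gold(ranking, gold)
  n <- length(ranking)
  hits <- cumsum(ranking %in% gold)
  k <- seq_len(n)
  recall <- hits / length(gold)
  precision <- hits / k
  auc <- sum(diff(recall) * (utils::head(precision, -1) +
                             utils::tail(precision, -1)) / 2)
  list(points = data.frame(k = k, recall = recall, precision = precision),
       auc = auc)
}

#' Jackknife (cumulative-hits) curve
#'
#' The running count of gold essentials among the top k ranked proteins for
#' k = 1..kMax; early enrichment lifts the whole curve. The AUC is
#' normalized by `kMax * min(|gold|, kMax)` so a perfect ranking approaches
#' 1 (short of the initial ramp) and values are comparable across methods.
#'
#' @inheritParams topkHitCounts
#' @param kMax largest cutoff (default: the full ranking).
#' @return list with `points` (data.frame `k`, `hits`) and `auc`.
#' @export
jackknifeCurve <- function(ranking, gold, kMax = length(ranking)) {
  gold <- .check_gold(ranking, gold)
  if (kMax > length(ranking)) stop("kMax must not exceed the ranking length")
  hits <- cumsum(ranking %in% gold)[seq_len(kMax)]
  auc <- sum(hits) / (kMax * min(length(gold), kMax))
  list(points = data.frame(k = seq_len(kMax), hits = as.integer(hits)),
       auc = auc)
}

#' Overlap and difference of two top-K predictions
#'
#' Compares the top-K sets A and B of two ranking methods: the overlap
#' size, the two difference sets, and the number and percentage of gold
#' essentials inside each difference set — the lens used to ask whether two
#' methods find the *same* essentials. Identical top-K sets have empty
#' differences, reported with the `"-"` sentinel instead of a percentage.
#'
#' @param rankA,rankB character rankings, best first.
#' @param gold gold-standard essential identifiers.
#' @param K cutoff, at most the length of either ranking.
#' @return one-row data.frame with columns `K`, `overlap`, `onlyA`,
#'   `onlyB`, `goldOnlyA`, `goldOnlyB`, `pctGoldOnlyA`, `pctGoldOnlyB`
#'   (percentages as character, `"-"` when the difference set is empty).
#' @export
overlapDifferenceTable <- function(rankA, rankB, gold, K = 100L) {
  if (K > length(rankA) || K > length(rankB))
    stop("K exceeds a ranking length")
  A <- rankA[seq_len(K)]
  B <- rankB[seq_len(K)]
  onlyA <- setdiff(A, B)
  onlyB <- setdiff(B, A)
  stopifnot(length(onlyA) == length(onlyB),
            length(onlyA) == K - length(intersect(A, B)))
  pct <- function(diffset) {
    if (length(diffset) == 0L) "-"
    else sprintf("%.1f%%", 100 * sum(diffset %in% gold) / length(diffset))
  }
  data.frame(K = K, overlap = length(intersect(A, B)),
             onlyA = length(onlyA), onlyB = length(onlyB),
             goldOnlyA = sum(onlyA %in% gold),
             goldOnlyB = sum(onlyB %in% gold),
             pctGoldOnlyA = pct(onlyA), pctGoldOnlyB = pct(onlyB),
             stringsAsFactors = FALSE)
}

#' Classical centrality baselines
#'
#' Topology-only essentiality scores for comparison with the full pipeline:
#' \describe{
#'   \item{DC}{degree centrality — the number of interaction partners.}
#'   \item{BC}{shortest-path betweenness centrality.}
#'   \item{CC}{closeness centrality with per-component normalization:
#'     \eqn{(s_i - 1)/\sum_j d(i,j)} over the \eqn{s_i} proteins of node i's
#'     connected component; singletons score 0.}
#'   \item{SC}{subgraph centrality, \eqn{SC_i = \sum_j v_{ij}^2 e^{\lambda_j}}
#'     from the adjacency eigendecomposition (weighted count of closed walks).}
#' }
#'
#' @param net an adjacency-stage [WeightedNetwork-class].
#' @param method one of `"DC"`, `"BC"`, `"CC"`, `"SC"`.
#' @return a [ScoreVector-class] with `stage = method`.
#' @export
baselineCentrality <- function(net, method = c("DC", "BC", "CC", "SC")) {
  stopifnot(is(net, "WeightedNetwork"))
  method <- match.arg(method)
  A <- assocMatrix(net)
  ids <- proteinIds(net)
  vals <- switch(method,
    DC = rowSums(A),
    BC = {
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      igraph::betweenness(g, directed = FALSE)
    },
    CC = {
      g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
      comp <- igraph::components(g)$membership
      d <- igraph::distances(g)
      vapply(seq_along(ids), function(i) {
        same <- which(comp == comp[i])
        if (length(same) < 2L) return(0)
        (length(same) - 1) / sum(d[i, setdiff(same, i)])
      }, numeric(1))
    },
    SC = {
      e <- eigen(A, symmetric = TRUE)
      # subtract the leading eigenvalue before exponentiating for overflow
      # safety; a common positive rescaling does not change the ranking
      as.numeric((e$vectors^2) %*% exp(e$values - max(e$values)))
    })
  ScoreVector(ids, unname(vals), method)
}

#' Evaluate a ranking against a gold standard
#'
#' Bundles the three evaluation protocols — top-k hit counts,
#' precision-recall curve with trapezoidal AUC, and jackknife curve with
#' normalized AUC — into one [EvaluationReport-class]. The gold set is
#' first projected onto the ranked universe.
#'
#' @param ranking full ranking of protein identifiers, best first (or a
#'   [ScoreVector-class], ranked via [topProteins()]).
#' @param gold gold-standard essential identifiers.
#' @param cutoffs top-k cutoffs to tabulate (entries beyond the ranking
#'   length are dropped).
#' @return an [EvaluationReport-class].
#' @export
evaluateRanking <- function(ranking, gold,
                            cutoffs = c(100L, 200L, 300L, 400L, 500L, 600L)) {
  if (is(ranking, "ScoreVector")) ranking <- topProteins(ranking)
  gold <- .check_gold(ranking, gold)
  cutoffs <- cutoffs[cutoffs <= length(ranking)]
  pr <- prCurve(ranking, gold)
  jk <- jackknifeCurve(ranking, gold)
  new("EvaluationReport",
      rankedIds = ranking,
      topkHits = topkHitCounts(ranking, gold, cutoffs),
      prPoints = pr$points, prAuc = pr$auc,
      jackknifePoints = jk$points, jackknifeAuc = jk$auc,
      nGold = length(gold))
}

#' Plot evaluation curves
#'
#' Base-graphics rendering of the precision-recall curve and the jackknife
#' curve of one or more reports, for visual method comparison.
#'
#' @param reports a named list of [EvaluationReport-class] objects.
#' @param which `"pr"` or `"jackknife"`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plotEvaluation <- function(reports, which = c("pr", "jackknife"), ...) {
  which <- match.arg(which)
  if (is(reports, "EvaluationReport")) reports <- list(method = reports)
  cols <- seq_along(reports)
  if (which == "pr") {
    graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "Recall", ylab = "Precision", ...)
    for (i in cols) {
      p <- reports[[i]]@prPoints
      graphics::lines(p$recall, p$precision, col = i)
    }
  } else {
    kmax <- max(vapply(reports, function(r) max(r@jackknifePoints$k), numeric(1)))
    ymax <- max(vapply(reports, function(r) max(r@jackknifePoints$hits), numeric(1)))
    graphics::plot(NA, xlim = c(1, kmax), ylim = c(0, ymax),
                   xlab = "Rank cutoff", ylab = "Cumulative essentials", ...)
    for (i in cols) {
      p <- reports[[i]]@jackknifePoints
      graphics::lines(p$k, p$hits, col = i)
    }
  }
  graphics::legend("bottomright", legend = names(reports), col = cols, lty = 1)
  invisible(NULL)
}
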