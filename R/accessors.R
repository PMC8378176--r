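#' @describeIn proteinIds network protein index
#' @export
setMethod("proteinIds", "WeightedNetwork", function(x) x@ids)

#' @describeIn proteinIds transition-operator protein index
#' @export
setMethod("proteinIds", "TransitionMatrix", function(x) x@ids)

#' @describeIn proteinIds annotated protein index
#' @export
setMethod("proteinIds", "AnnotationSet", function(x) x@ids)

#' @describeIn proteinIds scored protein index
#' @export
setMethod("proteinIds", "ScoreVector", function(x) x@ids)

#' @describeIn assocMatrix weight matrix with identifier dimnames
#' @export
setMethod("assocMatrix", "WeightedNetwork", function(x) {
  M <- x@W
  dimnames(M) <- list(x@ids, x@ids)
  M
})

#' @describeIn stageLabel network stage ("adjacency", "con", "reconstructed")
#' @export
setMethod("stageLabel", "WeightedNetwork", function(x) x@stage)

#' @describeIn stageLabel score stage ("SH", "SL", "SI", "SF", centrality name)
#' @export
setMethod("stageLabel", "ScoreVector", function(x) x@stage)

#' @describeIn probMatrix propagation weights with identifier dimnames
#' @export
setMethod("probMatrix", "TransitionMatrix", function(x) {
  M <- x@P
  dimnames(M) <- list(x@ids, x@ids)
  M
})

#' @describeIn scoreValues named score vector
#' @export
setMethod("scoreValues", "ScoreVector", function(x)
  stats::setNames(x@values, x@ids))

#' @describeIn homologyCounts named count vector
#' @export
setMethod("homologyCounts", "AnnotationSet", function(x)
  stats::setNames(x@H, x@ids))

#' @describeIn compartmentSets named list of label sets
#' @export
setMethod("compartmentSets", "AnnotationSet", function(x)
  stats::setNames(x@compartments, x@ids))

#' @describeIn objectiveTrace objective after each completed update sweep
#' @export
setMethod("objectiveTrace", "TriFactorization", function(x) x@objectiveTrace)

#' @describeIn assocMatrix coerce a WeightedNetwork to its weight matrix
#' @param x object to coerce.
#' @export
setMethod("as.matrix", "WeightedNetwork", function(x) assocMatrix(x))

setMethod("show", "WeightedNetwork", function(object) {
  n <- length(object@ids)
  nz <- sum(object@W > 0)
  cat(sprintf("WeightedNetwork (stage '%s'): %d proteins, %d nonzero entries",
              object@stage, n, nz), "\n")
  if (object@stage == "adjacency")
    cat(sprintf("  %d undirected edges\n", nz %/% 2L))
})

setMethod("show", "TriFactorization", function(object) {
  cat(sprintf(
    "TriFactorization: n = %d, k = %d, %d sweeps (seed %d)\n",
    nrow(object@F), object@k, object@iterations, object@seed))
  if (length(object@objectiveTrace))
    cat(sprintf("  final objective %.6g%s\n",
                utils::tail(object@objectiveTrace, 1L),
                if (nzchar(object@stopReason))
                  sprintf(" (stopped: %s)", object@stopReason) else ""))
})

setMethod("show", "TransitionMatrix", function(object) {
  rs <- rowSums(object@P)
  cat(sprintf(
    "TransitionMatrix: %d proteins, %d zero rows, row renormalization %s\n",
    length(object@ids), sum(rs == 0),
    if (object@rowRenormalized) "ON" else "OFF"))
})

setMethod("show", "AnnotationSet", function(object) {
  cat(sprintf(
    "AnnotationSet: %d proteins; H in [%d, %d]; %d with compartment labels\n",
    length(object@ids), min(object@H), max(object@H),
    sum(lengths(object@compartments) > 0)))
})

setMethod("show", "ScoreVector", function(object) {
  cat(sprintf("ScoreVector (stage '%s'): %d proteins, range [%.4g, %.4g]\n",
              object@stage, length(object@ids),
              min(object@values), max(object@values)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d ranked proteins, %d gold essentials\n",
              length(object@rankedIds), object@nGold))
  cat(sprintf("  PR AUC %.4f, jackknife AUC %.4f\n",
              object@prAuc, object@jackknifeAuc))
  if (length(object@topkHits)) {
    cat("  top-k hits:",
        paste(sprintf("%s:%d", names(object@topkHits), object@topkHits),
              collapse = " "), "\n")
  }
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: n = %d, m = %d, %.0f%% essential, hubBias %.1f, seed %d\n",
    object@n, object@attachM, 100 * object@essentialFraction,
    object@hubBias, object@seed))
  cat(sprintf("  ortholog p: %.2f (essential) vs %.2f (background) over %d species\n",
              object@pOrthologEssential, object@pOrthologBackground,
              object@nSpecies))
  cat(sprintf("  %d compartments, '%s' enriched (p = %.2f)\n",
              length(object@compartments), object@compartments[1L],
              object@enrichment))
})
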