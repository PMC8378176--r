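#' @import methods
NULL

.check_square_nonneg <- function(ids, M, what) {
  msg <- character(0)
  if (anyDuplicated(ids))
    msg <- c(msg, "protein identifiers must be unique")
  if (!is.matrix(M) || !is.numeric(M))
    msg <- c(msg, sprintf("%s must be a numeric matrix", what))
  else {
    if (nrow(M) != ncol(M))
      msg <- c(msg, sprintf("%s must be square", what))
    if (nrow(M) != length(ids))
      msg <- c(msg, sprintf("%s dimension must match the number of proteins", what))
    if (anyNA(M) || any(!is.finite(M)))
      msg <- c(msg, sprintf("%s contains NA or non-finite entries", what))
    else if (any(M < 0))
      msg <- c(msg, sprintf("%s must be entrywise non-negative", what))
  }
  msg
}

#' WeightedNetwork: an indexed protein association matrix
#'
#' Container for a PPI network at any stage of the pipeline: the raw binary
#' adjacency read from an edge list (`stage = "adjacency"`), the co-neighbor
#' weighted matrix produced by [conMatrix()] (`stage = "con"`), or the dense
#' NMTF reconstruction \eqn{Y = F S G^T} produced by [reconstruct()]
#' (`stage = "reconstructed"`). Protein identifiers are stored once, sorted
#' lexicographically in the C locale, and row/column `i` of the matrix always
#' refers to `proteinIds(x)[i]`.
#'
#' Adjacency and CoN stages are constrained to be symmetric with a zero
#' diagonal; a reconstruction may be asymmetric (the tri-factorization does
#' not enforce \eqn{F = G}).
#'
#' @slot ids character vector of unique protein identifiers (sorted).
#' @slot W square numeric matrix of non-negative association weights.
#' @slot stage one of `"adjacency"`, `"con"`, `"reconstructed"`.
#'
#' @seealso [readEdgeList()], [conMatrix()], [reconstruct()]
#' @export
setClass("WeightedNetwork",
  representation(ids = "character", W = "matrix", stage = "character"),
  validity = function(object) {
    msg <- .check_square_nonneg(object@ids, object@W, "W")
    if (length(object@stage) != 1L ||
        !object@stage %in% c("adjacency", "con", "reconstructed"))
      msg <- c(msg, "stage must be one of 'adjacency', 'con', 'reconstructed'")
    if (length(msg) == 0L && object@stage %in% c("adjacency", "con")) {
      if (max(abs(object@W - t(object@W))) > 0)
        msg <- c(msg, sprintf("%s-stage matrix must be symmetric", object@stage))
      if (any(diag(object@W) != 0))
        msg <- c(msg, sprintf("%s-stage matrix must have a zero diagonal", object@stage))
    }
    if (length(msg)) msg else TRUE
  })

WeightedNetwork <- function(ids, W, stage) {
  dimnames(W) <- list(ids, ids)
  new("WeightedNetwork", ids = as.character(ids), W = W, stage = stage)
}

#' TriFactorization: the three NMTF factors with optimization trace
#'
#' Result of [nmtf()] / state advanced by [nmtfUpdate()]. Holds the latent
#' factors \eqn{F} (n x k), \eqn{S} (k x k) and \eqn{G} (n x k), all
#' entrywise non-negative, the factorization rank `k`, the RNG seed used for
#' initialization, and the Frobenius objective value after every completed
#' update sweep.
#'
#' @slot F,S,G non-negative factor matrices (n x k, k x k, n x k).
#' @slot k integer factorization rank.
#' @slot seed integer seed used by [initializeFactors()].
#' @slot objectiveTrace numeric vector, objective after each update sweep.
#' @slot iterations integer, number of update sweeps applied.
#' @slot stopReason character, why iteration stopped ("" while in progress).
#' @export
setClass("TriFactorization",
  representation(F = "matrix", S = "matrix", G = "matrix", k = "integer",
                 seed = "integer", objectiveTrace = "numeric",
                 iterations = "integer", stopReason = "character"),
  validity = function(object) {
    msg <- character(0)
    k <- object@k
    if (length(k) != 1L || k < 1L) msg <- c(msg, "k must be a positive integer")
    if (ncol(object@F) != k || ncol(object@G) != k ||
        any(dim(object@S) != c(k, k)))
      msg <- c(msg, "factor dimensions must agree with rank k")
    if (nrow(object@F) != nrow(object@G))
      msg <- c(msg, "F and G must have the same number of rows")
    for (nm in c("F", "S", "G")) {
      M <- slot(object, nm)
      if (anyNA(M) || any(!is.finite(M)))
        msg <- c(msg, sprintf("factor %s contains NA or non-finite entries", nm))
      else if (any(M < 0))
        msg <- c(msg, sprintf("factor %s must be entrywise non-negative", nm))
    }
    if (length(msg)) msg else TRUE
  })

#' TransitionMatrix: row-normalized propagation operator
#'
#' The operator built from an NMTF reconstruction by [transitionMatrix()]:
#' entry \eqn{(i,j)} is \eqn{\max(Y_{ij}, Y_{ji})} divided by the i-th row
#' sum of \eqn{Y} (zero when that row sum is zero), optionally rescaled so
#' every nonzero row sums to one. It drives the damped fixed-point ranking
#' iteration in [rankProteins()].
#'
#' @slot ids protein identifiers, aligned with rows/columns of `P`.
#' @slot P square non-negative matrix.
#' @slot rowRenormalized logical, whether nonzero rows were rescaled to sum 1.
#' @export
setClass("TransitionMatrix",
  representation(ids = "character", P = "matrix", rowRenormalized = "logical"),
  validity = function(object) {
    msg <- .check_square_nonneg(object@ids, object@P, "P")
    if (length(msg)) msg else TRUE
  })

#' AnnotationSet: per-protein homology counts and compartment labels
#'
#' Ortholog-conservation counts `H` (number of reference species in which
#' the protein has a direct ortholog) and subcellular-compartment label sets
#' `C`, both aligned to a protein identifier vector. Proteins missing from
#' the source tables carry the documented defaults: `H = 0` and an empty
#' compartment set.
#'
#' @slot ids protein identifiers.
#' @slot H integer vector of non-negative ortholog-species counts, one per id.
#' @slot compartments list of character vectors (possibly empty), one per id.
#' @export
setClass("AnnotationSet",
  representation(ids = "character", H = "integer", compartments = "list"),
  validity = function(object) {
    msg <- character(0)
    n <- length(object@ids)
    if (anyDuplicated(object@ids)) msg <- c(msg, "ids must be unique")
    if (length(object@H) != n || length(object@compartments) != n)
      msg <- c(msg, "H and compartments must have one entry per protein id")
    if (anyNA(object@H) || any(object@H < 0L))
      msg <- c(msg, "homology counts must be non-negative integers")
    if (!all(vapply(object@compartments, is.character, logical(1))))
      msg <- c(msg, "compartment sets must be character vectors")
    if (length(msg)) msg else TRUE
  })

AnnotationSet <- function(ids, H, C) {
  new("AnnotationSet", ids = as.character(ids), H = as.integer(H),
      compartments = C)
}

#' ScoreVector: per-protein non-negative scores
#'
#' A stage-labelled score vector aligned to a protein index: the homology
#' score S_H, localization score S_L, initial score S_I = S_H * S_L, the
#' final ranking score S_F, or a baseline centrality. Normalized stages
#' (S_H, S_L) are bounded by 1.
#'
#' @slot ids protein identifiers.
#' @slot values numeric vector of non-negative scores, one per id.
#' @slot stage label such as `"SH"`, `"SL"`, `"SI"`, `"SF"`, `"DC"`.
#' @slot metadata list of stage details (e.g. iteration count and final
#'   residual for S_F).
#' @export
setClass("ScoreVector",
  representation(ids = "character", values = "numeric", stage = "character",
                 metadata = "list"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@values) != length(object@ids))
      msg <- c(msg, "values must have one entry per protein id")
    if (anyNA(object@values) || any(!is.finite(object@values)))
      msg <- c(msg, "scores contain NA or non-finite values")
    else {
      if (any(object@values < 0)) msg <- c(msg, "scores must be non-negative")
      if (object@stage %in% c("SH", "SL") &&
          any(object@values > 1 + 1e-12))
        msg <- c(msg, sprintf("%s scores must not exceed 1", object@stage))
    }
    if (length(msg)) msg else TRUE
  })

ScoreVector <- function(ids, values, stage, metadata = list()) {
  new("ScoreVector", ids = as.character(ids),
      values = stats::setNames(as.numeric(values), ids),
      stage = stage, metadata = metadata)
}

#' EvaluationReport: ranking evaluated against a gold standard
#'
#' Produced by [evaluateRanking()]: the full descending ranking, true-hit
#' counts at the requested cutoffs, the precision-recall curve and its
#' trapezoidal AUC, and the jackknife (cumulative-hits) curve with its
#' normalized AUC.
#'
#' @slot rankedIds full ranking, best first.
#' @slot topkHits named integer vector, cutoff K -> gold hits in top K.
#' @slot prPoints data.frame with columns `k`, `recall`, `precision`.
#' @slot prAuc trapezoidal area under the precision-recall curve.
#' @slot jackknifePoints data.frame with columns `k`, `hits`.
#' @slot jackknifeAuc normalized area under the jackknife curve.
#' @slot nGold number of gold-standard essentials in the ranked universe.
#' @export
setClass("EvaluationReport",
  representation(rankedIds = "character", topkHits = "integer",
                 prPoints = "data.frame", prAuc = "numeric",
                 jackknifePoints = "data.frame", jackknifeAuc = "numeric",
                 nGold = "integer"))

#' SyntheticSpec: parameters of the synthetic benchmark generator
#'
#' Describes a scale-free benchmark in which a planted essential set is
#' simultaneously hub-biased, ortholog-rich and compartment-enriched — the
#' three signals the ranking method integrates. See [generateSynthetic()]
#' for the generative procedure and [syntheticSpec()] for defaults.
#'
#' @slot n node count.
#' @slot attachM preferential-attachment edges per new node.
#' @slot essentialFraction fraction of nodes planted as essential, in (0,1).
#' @slot hubBias exponent of the degree-proportional essential sampling
#'   weight (0 = uniform, no topology signal).
#' @slot nSpecies homology scale: number of reference species.
#' @slot pOrthologEssential,pOrthologBackground per-species ortholog
#'   probabilities for essentials / background proteins.
#' @slot compartments compartment label vocabulary; the first entry is the
#'   enriched compartment.
#' @slot enrichment probability that an essential protein is annotated to
#'   the enriched compartment.
#' @slot seed RNG seed.
#' @export
setClass("SyntheticSpec",
  representation(n = "integer", attachM = "integer",
                 essentialFraction = "numeric", hubBias = "numeric",
                 nSpecies = "integer", pOrthologEssential = "numeric",
                 pOrthologBackground = "numeric", compartments = "character",
                 enrichment = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    ef <- object@essentialFraction
    if (ef <= 0 || ef >= 1) msg <- c(msg, "essentialFraction must lie in (0, 1)")
    if (object@hubBias < 0) msg <- c(msg, "hubBias must be >= 0")
    for (nm in c("pOrthologEssential", "pOrthologBackground", "enrichment")) {
      p <- slot(object, nm)
      if (p < 0 || p > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", nm))
    }
    if (object@pOrthologEssential < object@pOrthologBackground)
      msg <- c(msg, "pOrthologEssential must be >= pOrthologBackground")
    if (object@n < 4L) msg <- c(msg, "n must be at least 4")
    if (object@attachM < 1L) msg <- c(msg, "attachM must be >= 1")
    if (length(object@compartments) < 1L ||
        anyDuplicated(object@compartments))
      msg <- c(msg, "compartments must be a non-empty set of unique labels")
    if (length(msg)) msg else TRUE
  })
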