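#' Protein identifiers of an object
#'
#' All pipeline containers share one protein index: a lexicographically
#' sorted identifier vector whose i-th element labels row/column or entry i.
#'
#' @param x a WeightedNetwork, TransitionMatrix, AnnotationSet or ScoreVector.
#' @return character vector of protein identifiers.
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' Association matrix of a WeightedNetwork
#'
#' @param x a WeightedNetwork.
#' @return the square numeric weight matrix, with identifier dimnames.
#' @export
setGeneric("assocMatrix", function(x) standardGeneric("assocMatrix"))

#' Stage label of a pipeline object
#'
#' @param x a WeightedNetwork or ScoreVector.
#' @return a single character label.
#' @export
setGeneric("stageLabel", function(x) standardGeneric("stageLabel"))

#' Transition probabilities of a TransitionMatrix
#'
#' @param x a TransitionMatrix.
#' @return the square numeric matrix of propagation weights.
#' @export
setGeneric("probMatrix", function(x) standardGeneric("probMatrix"))

#' Score values of a ScoreVector
#'
#' @param x a ScoreVector.
#' @return named numeric vector of per-protein scores.
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' Homology counts of an AnnotationSet
#'
#' @param x an AnnotationSet.
#' @return named integer vector: protein -> ortholog-species count.
#' @export
setGeneric("homologyCounts", function(x) standardGeneric("homologyCounts"))

#' Compartment label sets of an AnnotationSet
#'
#' @param x an AnnotationSet.
#' @return named list of character vectors: protein -> compartments.
#' @export
setGeneric("compartmentSets", function(x) standardGeneric("compartmentSets"))

#' Objective trace of a TriFactorization
#'
#' @param x a TriFactorization.
#' @return numeric vector of Frobenius objective values, one per update sweep.
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
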