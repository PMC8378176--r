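.default_compartments <- c("Nucleus", "Cytosol", "Mitochondrion",
                           "Endoplasmic", "Golgi", "Vacuole", "Plasma",
                           "Cytoskeleton", "Endosome", "Peroxisome",
                           "Extracellular")

#' Construct a synthetic benchmark specification
#'
#' Defaults describe the study conditions used throughout the package's
#' tests: a 500-protein scale-free network (preferential attachment, 3
#' edges per arriving node), 20% of proteins planted as essential with
#' sampling weight proportional to degree squared, ortholog counts drawn
#' per protein as Binomial(99, 0.8) for essentials versus Binomial(99, 0.3)
#' for the background, and 11 yeast-style compartments with essentials
#' annotated to the enriched first compartment with probability 0.8. These
#' mirror, at desk scale, the premises the ranking method relies on: hubs,
#' conserved proteins and compartment-concentrated proteins are more likely
#' essential.
#'
#' @param n node count.
#' @param attachM preferential-attachment edges per new node.
#' @param essentialFraction planted essential fraction, in (0, 1).
#' @param hubBias degree exponent of the essential-sampling weight; 0 makes
#'   the essential set a uniform draw (negative control).
#' @param nSpecies number of reference species for ortholog counts.
#' @param pOrthologEssential,pOrthologBackground per-species ortholog
#'   probabilities (essential >= background).
#' @param compartments compartment vocabulary; first entry is enriched.
#' @param enrichment probability an essential is annotated to the enriched
#'   compartment.
#' @param seed RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(n = 500L, attachM = 3L, essentialFraction = 0.2,
                          hubBias = 2, nSpecies = 99L,
                          pOrthologEssential = 0.8,
                          pOrthologBackground = 0.3,
                          compartments = .default_compartments,
                          enrichment = 0.8, seed = 1L) {
  new("SyntheticSpec", n = as.integer(n), attachM = as.integer(attachM),
      essentialFraction = essentialFraction, hubBias = hubBias,
      nSpecies = as.integer(nSpecies),
      pOrthologEssential = pOrthologEssential,
      pOrthologBackground = pOrthologBackground,
      compartments = as.character(compartments),
      enrichment = enrichment, seed = as.integer(seed))
}

#' Generate a synthetic benchmark dataset
#'
#' Builds, reproducibly for the spec's seed:
#' \enumerate{
#'   \item a scale-free PPI network by preferential attachment;
#'   \item a planted essential set sampled without replacement with weight
#'     proportional to \eqn{degree^{hubBias}};
#'   \item ortholog-species counts \eqn{H \sim Binomial(nSpecies, p)} with
#'     the essential/background probabilities;
#'   \item 1-3 compartments per protein, essentials biased toward the
#'     enriched compartment.
#' }
#' Protein identifiers are zero-padded (`P0001`, ...) so lexicographic
#' index order equals generation order.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with components `network` ([WeightedNetwork-class]), `gold`
#'   (character vector of planted essential ids), `annotations`
#'   ([AnnotationSet-class]) and `truth` (list: per-protein degree, the
#'   essential indicator, and the enriched compartment label).
#' @export
generateSynthetic <- function(spec = syntheticSpec()) {
  stopifnot(is(spec, "SyntheticSpec"))
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec@seed)
  n <- spec@n
  ids <- sprintf("P%0*d", nchar(n), seq_len(n))

  g <- igraph::sample_pa(n, power = 1, m = spec@attachM, directed = FALSE)
  A <- unname(as.matrix(igraph::as_adjacency_matrix(g)))
  A[A > 1] <- 1  # collapse multi-edges from attachment
  diag(A) <- 0
  net <- WeightedNetwork(ids, A, "adjacency")

  deg <- rowSums(A)
  nEss <- max(1L, round(spec@essentialFraction * n))
  w <- (deg + 1e-9)^spec@hubBias
  essIdx <- sample.int(n, nEss, prob = w)
  gold <- sort(ids[essIdx], method = "radix")

  H <- integer(n)
  isEss <- seq_len(n) %in% essIdx
  H[isEss] <- stats::rbinom(sum(isEss), spec@nSpecies, spec@pOrthologEssential)
  H[!isEss] <- stats::rbinom(sum(!isEss), spec@nSpecies,
                             spec@pOrthologBackground)

  nc <- length(spec@compartments)
  C <- vector("list", n)
  for (i in seq_len(n)) {
    k_i <- sample.int(3L, 1L)
    if (isEss[i] && stats::runif(1) < spec@enrichment) {
      extra <- if (k_i > 1L) sample.int(nc - 1L, k_i - 1L) + 1L else integer(0)
      C[[i]] <- spec@compartments[c(1L, extra)]
    } else {
      C[[i]] <- spec@compartments[sample.int(nc, k_i)]
    }
    C[[i]] <- sort(C[[i]])
  }
  ann <- AnnotationSet(ids, H, C)

  list(network = net, gold = gold, annotations = ann,
       truth = list(degree = stats::setNames(deg, ids),
                    essential = stats::setNames(isEss, ids),
                    enrichedCompartment = spec@compartments[1L]))
}

#' Write a synthetic dataset in the package's input formats
#'
#' Emits `edges.tsv`, `essential.txt`, `homology.tsv`, `localization.tsv`
#' and `truth.json` into a directory, in exactly the formats
#' [readEdgeList()], [readEssentialList()] and [readAnnotations()] consume,
#' so generated benchmarks round-trip through the regular input path.
#'
#' @param dataset result of [generateSynthetic()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSyntheticData <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEdgeList(dataset$network, file.path(dir, "edges.tsv"))
  writeLines(dataset$gold, file.path(dir, "essential.txt"))
  ids <- proteinIds(dataset$annotations)
  H <- homologyCounts(dataset$annotations)
  writeLines(paste(ids, H[ids], sep = "\t"), file.path(dir, "homology.tsv"))
  C <- compartmentSets(dataset$annotations)
  loc <- unlist(lapply(ids, function(id)
    if (length(C[[id]])) paste(id, C[[id]], sep = "\t") else character(0)))
  writeLines(loc, file.path(dir, "localization.tsv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Degree-distribution summary of a network
#'
#' Fixture sanity check for generated benchmarks: reports the maximum and
#' mean degree and a heavy-tail indicator — the fraction of edges incident
#' to the top 5% highest-degree nodes. Scale-free-like networks concentrate
#' a large share of edges on that top slice (a star concentrates all of
#' them); degree-homogeneous graphs such as rings sit near 5%.
#'
#' @param net an adjacency-stage [WeightedNetwork-class].
#' @return list with `maxDegree`, `meanDegree`, `topFraction`.
#' @export
degreeDistributionCheck <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  A <- assocMatrix(net)
  deg <- rowSums(A)
  nTop <- max(1L, ceiling(0.05 * length(deg)))
  top <- order(-deg)[seq_len(nTop)]
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  inTop <- idx[, 1L] %in% top | idx[, 2L] %in% top
  list(maxDegree = max(deg), meanDegree = mean(deg),
       topFraction = if (nrow(idx)) mean(inTop) else 0)
}
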