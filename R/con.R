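#' Neighbor sets of a binary network
#'
#' @param net an adjacency-stage [WeightedNetwork-class].
#' @return named list: protein -> integer vector of neighbor indices (a
#'   protein is never its own neighbor; isolated proteins map to an empty
#'   set).
#' @export
neighborSets <- function(net) {
  stopifnot(is(net, "WeightedNetwork"))
  W <- unname(assocMatrix(net))
  stats::setNames(apply(W > 0, 1L, which, simplify = FALSE), proteinIds(net))
}

#' Co-neighbor (CoN) weighting of a binary PPI network
#'
#' Scores every protein pair by its shared neighborhood: for proteins i and
#' j with neighbor sets N(i), N(j), both of size at least 2,
#' \deqn{P_{CoN}(i,j) = \frac{|N(i) \cap N(j)|^2}{(|N(i)|-1)(|N(j)|-1)}}
#' and 0 otherwise. Any pair sharing at least one common neighbor is taken
#' to be associated, so the CoN matrix can contain edges absent from the raw
#' network (`domain = "all-pairs"`, the default); `domain = "edges-only"`
#' restricts the statistic to pairs already adjacent in the input.
#'
#' For adjacent pairs the statistic lies in [0, 1]; non-adjacent pairs can
#' exceed 1 (e.g. opposite corners of a 4-cycle score 4), so values are
#' clamped at 1 to keep the weighted matrix on the stated scale. Clamping is
#' reported via a message when triggered.
#'
#' @param net an adjacency-stage [WeightedNetwork-class].
#' @param domain `"all-pairs"` (score every pair with a common neighbor) or
#'   `"edges-only"` (only pairs adjacent in the raw network).
#' @return a [WeightedNetwork-class] with `stage = "con"`: symmetric, zero
#'   diagonal, entries in [0, 1].
#' @examples
#' f <- tempfile()
#' writeLines(c("a\tb", "b\tc", "c\ta"), f)  # triangle
#' con <- conMatrix(readEdgeList(f))
#' assocMatrix(con)["a", "b"]  # 1: one shared neighbor, degrees 2
#' @export
conMatrix <- function(net, domain = c("all-pairs", "edges-only")) {
  stopifnot(is(net, "WeightedNetwork"))
  domain <- match.arg(domain)
  if (stageLabel(net) != "adjacency")
    stop("conMatrix expects a binary adjacency-stage network")
  A <- assocMatrix(net)
  n <- nrow(A)
  if (n < 2L) stop("CoN weighting needs at least two proteins")
  deg <- rowSums(A)
  CN <- A %*% A                       # common-neighbor counts; diag = degree
  D <- outer(deg - 1, deg - 1)
  P <- matrix(0, n, n)
  ok <- D > 0
  P[ok] <- CN[ok]^2 / D[ok]
  diag(P) <- 0
  if (domain == "edges-only") P[A == 0] <- 0
  nclamp <- sum(P > 1)
  if (nclamp > 0L) {
    P[P > 1] <- 1
    message(sprintf("conMatrix: clamped %d entries above 1", nclamp))
  }
  if (all(P == 0))
    warning("conMatrix: degenerate input, all CoN weights are zero")
  WeightedNetwork(proteinIds(net), P, "con")
}
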