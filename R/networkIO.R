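#' Read an undirected PPI edge list
#'
#' Reads a plain-text edge list (two identifier columns; extra columns
#' ignored; `#`-prefixed comment lines and blank lines skipped) into a
#' binary-adjacency [WeightedNetwork-class]. Self-interactions are dropped
#' and duplicate interactions (in either orientation) are collapsed, the
#' filtering applied to the source interaction databases before analysis.
#' Identifiers are compared case-sensitively after stripping surrounding
#' whitespace; the node order is lexicographic in the C locale, so the index
#' is invariant under permutation of input lines.
#'
#' Nodes whose only mentions are self-loops are retained with degree zero:
#' they keep the index reproducible and are still scored through their
#' annotation-derived initial score.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator (default tab).
#' @return a [WeightedNetwork-class] with `stage = "adjacency"`.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "B\tB", "A\tC"), f)
#' net <- readEdgeList(f)
#' sum(assocMatrix(net)) / 2  # 2 edges: A-B collapsed, B-B dropped
#' @export
readEdgeList <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("edge list is empty: ", path)
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop(sprintf("malformed edge line %d (fewer than 2 fields): %s",
                 lineno[bad[1L]], lines[bad[1L]]))
  a <- trimws(vapply(parts, `[[`, character(1), 1L))
  b <- trimws(vapply(parts, `[[`, character(1), 2L))
  if (any(!nzchar(a)) || any(!nzchar(b)))
    stop("empty protein identifier in edge list")
  ids <- sort(unique(c(a, b)), method = "radix")
  i <- match(a, ids)
  j <- match(b, ids)
  self <- i == j
  i2 <- pmin(i[!self], j[!self])
  j2 <- pmax(i[!self], j[!self])
  uniq <- !duplicated(cbind(i2, j2))
  i2 <- i2[uniq]; j2 <- j2[uniq]
  n <- length(ids)
  W <- matrix(0, n, n)
  W[cbind(i2, j2)] <- 1
  W[cbind(j2, i2)] <- 1
  message(sprintf("readEdgeList: %d proteins, %d edges (%d self-loops and %d duplicate lines removed)",
                  n, length(i2), sum(self), sum(!self) - length(i2)))
  WeightedNetwork(ids, W, "adjacency")
}

#' Write a binary network back to an edge-list file
#'
#' Inverse of [readEdgeList()] for adjacency-stage networks: one line per
#' unordered edge, endpoints in index order, tab-separated.
#'
#' @param net a [WeightedNetwork-class] with `stage = "adjacency"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  stopifnot(is(net, "WeightedNetwork"))
  if (stageLabel(net) != "adjacency")
    stop("writeEdgeList expects an adjacency-stage network")
  W <- assocMatrix(net)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  ids <- proteinIds(net)
  writeLines(paste(ids[idx[, 1L]], ids[idx[, 2L]], sep = "\t"), path)
  invisible(path)
}

#' Read homology and subcellular-localization annotation tables
#'
#' Homology rows are `(protein, integer ortholog-species count)`;
#' localization rows are `(protein, compartment label)`, one compartment per
#' row. The network defines the protein universe: proteins present in the
#' index but absent from a table receive the defaults `H = 0` and an empty
#' compartment set, and table rows for proteins outside the index are
#' dropped with a warning giving the count.
#'
#' @param homologyPath path to the homology TSV (or `NULL` for none).
#' @param localizationPath path to the localization TSV (or `NULL`).
#' @param index character vector of network protein identifiers, or any
#'   object with a [proteinIds()] method.
#' @param delimiter field separator (default tab).
#' @return an [AnnotationSet-class] aligned to `index`.
#' @export
readAnnotations <- function(homologyPath, localizationPath, index,
                            delimiter = "\t") {
  if (!is.character(index)) index <- proteinIds(index)
  n <- length(index)
  H <- stats::setNames(integer(n), index)
  C <- stats::setNames(rep(list(character(0)), n), index)
  dropped <- 0L

  read_rows <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    parts <- strsplit(lines, delimiter, fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad))
      stop(sprintf("malformed annotation row in %s: %s", path, lines[bad[1L]]))
    data.frame(id = trimws(vapply(parts, `[[`, character(1), 1L)),
               value = trimws(vapply(parts, `[[`, character(1), 2L)),
               stringsAsFactors = FALSE)
  }

  if (!is.null(homologyPath)) {
    rows <- read_rows(homologyPath)
    cnt <- suppressWarnings(as.numeric(rows$value))
    if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
      stop("homology counts must be non-negative integers")
    known <- rows$id %in% index
    dropped <- dropped + sum(!known)
    H[rows$id[known]] <- as.integer(cnt[known])
  }
  if (!is.null(localizationPath)) {
    rows <- read_rows(localizationPath)
    known <- rows$id %in% index
    dropped <- dropped + sum(!known)
    rows <- rows[known, , drop = FALSE]
    for (id in unique(rows$id))
      C[[id]] <- sort(unique(rows$value[rows$id == id]))
  }
  if (dropped > 0L)
    warning(sprintf("readAnnotations: %d annotation rows for proteins outside the network were ignored", dropped))
  AnnotationSet(index, unname(H), unname(C))
}

#' Read a gold-standard essential-protein list
#'
#' One identifier per line; the returned set is the intersection with the
#' network's protein universe. Identifiers not present in the network are
#' counted and reported; an empty intersection yields a warning (downstream
#' evaluation then refuses to run), not an error.
#'
#' @param path path to the list file.
#' @param index protein identifiers (or object with [proteinIds()]).
#' @return character vector of matched identifiers (sorted).
#' @export
readEssentialList <- function(path, index) {
  if (!is.character(index)) index <- proteinIds(index)
  lines <- readLines(path, warn = FALSE)
  ids <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  ids <- unique(ids)
  hit <- ids %in% index
  message(sprintf("readEssentialList: %d of %d gold identifiers matched the network",
                  sum(hit), length(ids)))
  if (length(ids) > 0L && !any(hit))
    warning("no gold-standard identifier matches the network")
  sort(ids[hit], method = "radix")
}

#' Export an association matrix in MatrixMarket format
#'
#' Writes the weight matrix in MatrixMarket coordinate format plus a sidecar
#' identifier list (`<path>.ids`, one identifier per line, row order), for
#' interoperability with other toolchains.
#'
#' @param x a [WeightedNetwork-class] or [TransitionMatrix-class].
#' @param path output path for the `.mtx` file.
#' @return `path`, invisibly.
#' @export
exportMatrixMarket <- function(x, path) {
  M <- if (is(x, "TransitionMatrix")) probMatrix(x) else assocMatrix(x)
  Matrix::writeMM(methods::as(Matrix::Matrix(M, sparse = TRUE), "generalMatrix"),
                  path)
  writeLines(proteinIds(x), paste0(path, ".ids"))
  invisible(path)
}
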