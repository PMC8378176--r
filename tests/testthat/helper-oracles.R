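# Independent brute-force oracles and tiny fixture builders.
# The oracles deliberately share no code with the package internals.

# write an edge list file from a two-column character matrix of endpoints
write_edges <- function(pairs, path = tempfile(fileext = ".tsv")) {
  writeLines(apply(pairs, 1L, paste, collapse = "\t"), path)
  path
}

# adjacency-stage WeightedNetwork straight from endpoint pairs
net_from_pairs <- function(pairs) {
  suppressMessages(readEdgeList(write_edges(pairs)))
}

# Erdos-Renyi-style random binary network on n nodes
random_net <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A <- A + t(A)
  ids <- sprintf("n%03d", seq_len(n))
  dimnames(A) <- list(ids, ids)
  new("WeightedNetwork", ids = ids, W = A, stage = "adjacency")
}

# naive per-pair evaluation of the CoN statistic: explicit neighbor sets,
# explicit intersection, clamp at 1
oracle_con <- function(A) {
  n <- nrow(A)
  nb <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  P <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    di <- length(nb[[i]]); dj <- length(nb[[j]])
    if (di > 1 && dj > 1) {
      cn <- length(intersect(nb[[i]], nb[[j]]))
      P[i, j] <- min(cn^2 / ((di - 1) * (dj - 1)), 1)
    }
  }
  P
}

# elementwise sum of squared residuals with a triple-loop matrix product
oracle_objective <- function(P, F_, S, G) {
  n <- nrow(P); k <- ncol(F_)
  FS <- matrix(0, n, k)
  for (i in seq_len(n)) for (u in seq_len(k))
    FS[i, u] <- sum(F_[i, ] * S[, u])
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    tot <- tot + (P[i, j] - sum(FS[i, ] * G[j, ]))^2
  tot
}

# closed-form fixed point of the damped iteration
oracle_rank_solve <- function(P, si, alpha) {
  as.numeric(solve(diag(nrow(P)) - alpha * P, (1 - alpha) * si))
}

# naive metric recomputation from a ranking
oracle_hits_at <- function(ranking, gold, K) sum(ranking[seq_len(K)] %in% gold)
oracle_pr <- function(ranking, gold) {
  n <- length(ranking)
  prec <- rec <- numeric(n)
  for (k in seq_len(n)) {
    h <- sum(ranking[1:k] %in% gold)
    prec[k] <- h / k
    rec[k] <- h / length(gold)
  }
  auc <- 0
  for (k in 2:n)
    auc <- auc + (rec[k] - rec[k - 1]) * (prec[k] + prec[k - 1]) / 2
  list(precision = prec, recall = rec, auc = auc)
}
oracle_jackknife <- function(ranking, gold, kMax) {
  hits <- vapply(seq_len(kMax),
                 function(k) sum(ranking[1:k] %in% gold), numeric(1))
  list(hits = hits, auc = sum(hits) / (kMax * min(length(gold), kMax)))
}

# a planted exact-rank non-negative target with its generating factors
planted_target <- function(n, k, seed) {
  set.seed(seed)
  F0 <- matrix(runif(n * k), n, k)
  S0 <- matrix(runif(k * k), k, k)
  G0 <- matrix(runif(n * k), n, k)
  list(P = F0 %*% S0 %*% t(G0), F = F0, S = S0, G = G0)
}
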