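test_that("top-k hit counts and their edge cases", {
  expect_equal(topkHitCounts(c("B", "A", "C"), "A", cutoffs = 1:2),
               c("1" = 0L, "2" = 1L))
  ids <- sprintf("p%d", 1:5)
  expect_equal(unname(topkHitCounts(ids, ids, cutoffs = 1:5)), 1:5)
  expect_equal(topkHitCounts(ids, c("p2", "p4"), cutoffs = 5L)[["5"]], 2L)
  expect_error(topkHitCounts(ids, character(0)), "gold")
  expect_error(topkHitCounts(ids, "p1", cutoffs = 6L), "exceed")
})

test_that("precision-recall curve matches hand and brute-force computations", {
  # gold ranked last among two: points (0,0) then (1,0.5), trapezoid 0.25
  pr <- prCurve(c("x", "g"), "g")
  expect_equal(pr$points$precision, c(0, 0.5))
  expect_equal(pr$points$recall, c(0, 1))
  expect_equal(pr$auc, 0.25)

  # perfect ranking: precision 1 until recall 1
  prP <- prCurve(c("g1", "g2", "x1", "x2"), c("g1", "g2"))
  expect_true(all(prP$points$precision[1:2] == 1))
  expect_equal(max(prP$points$recall), 1)

  set.seed(19)
  for (rep in 1:5) {
    n <- sample(20:100, 1)
    ids <- sprintf("p%03d", 1:n)
    ranking <- sample(ids)
    gold <- sample(ids, sample(3:10, 1))
    got <- prCurve(ranking, gold)
    want <- oracle_pr(ranking, gold)
    expect_equal(got$points$precision, want$precision)
    expect_equal(got$points$recall, want$recall)
    expect_equal(got$auc, want$auc, tolerance = 1e-12)
  }
})

test_that("random rankings give PR AUC near the gold prevalence", {
  set.seed(23)
  n <- 2000
  ids <- sprintf("p%04d", 1:n)
  gold <- sample(ids, 200)
  aucs <- replicate(10, prCurve(sample(ids), gold)$auc)
  expect_lt(abs(mean(aucs) - 0.1), 0.02)
})

test_that("jackknife curve, normalization and consistency with top-k counts", {
  jk <- jackknifeCurve(c("A", "B", "C"), c("A", "C"), kMax = 3)
  expect_equal(jk$points$hits, c(1L, 1L, 2L))
  expect_equal(jk$auc, (1 + 1 + 2) / (3 * 2))

  # perfect ranking climbs the ramp min(k, g); worst ranking scores 0
  ids <- sprintf("p%02d", 1:10)
  gold <- ids[1:4]
  perfect <- jackknifeCurve(ids, gold)
  expect_equal(perfect$points$hits, pmin(1:10, 4))
  worst <- jackknifeCurve(rev(ids), gold, kMax = 6)
  expect_equal(worst$auc, 0)
  expect_true(all(diff(perfect$points$hits) >= 0))
  expect_equal(max(perfect$points$hits), length(gold))

  set.seed(29)
  ranking <- sample(ids)
  want <- oracle_jackknife(ranking, gold, 10)
  got <- jackknifeCurve(ranking, gold, 10)
  expect_equal(got$points$hits, as.integer(want$hits))
  expect_equal(got$auc, want$auc)
  # jackknife point at K equals the top-K hit count exactly
  for (K in c(1L, 5L, 10L))
    expect_equal(got$points$hits[K],
                 unname(topkHitCounts(ranking, gold, cutoffs = K)))
})

test_that("overlap/difference tables count gold in each difference set", {
  tab <- overlapDifferenceTable(c("A", "B", "C"), c("B", "C", "D"),
                                gold = c("A", "D"), K = 3)
  expect_equal(tab$overlap, 2L)
  expect_equal(tab$onlyA, 1L)
  expect_equal(tab$goldOnlyA, 1L)
  expect_equal(tab$pctGoldOnlyA, "100.0%")
  expect_equal(tab$pctGoldOnlyB, "100.0%")

  same <- overlapDifferenceTable(c("A", "B"), c("A", "B"), gold = "A", K = 2)
  expect_equal(same$overlap, 2L)
  expect_identical(same$pctGoldOnlyA, "-")

  disj <- overlapDifferenceTable(c("g1", "g2", "x"), c("y1", "y2", "y3"),
                                 gold = c("g1", "g2", "x"), K = 3)
  expect_equal(disj$pctGoldOnlyA, "100.0%")
  expect_equal(disj$pctGoldOnlyB, "0.0%")
})

test_that("baseline centralities rank canonical graphs correctly", {
  star <- net_from_pairs(cbind("h", c("w", "x", "y", "z")))
  expect_identical(topProteins(baselineCentrality(star, "DC"), 1), "h")

  path <- net_from_pairs(rbind(c("a", "b"), c("b", "c")))
  bc <- scoreValues(baselineCentrality(path, "BC"))
  expect_gt(bc[["b"]], bc[["a"]])
  expect_equal(unname(bc[c("a", "c")]), c(0, 0))

  tri <- net_from_pairs(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  sc <- scoreValues(baselineCentrality(tri, "SC"))
  expect_equal(unname(sc), rep(sc[[1]], 3), tolerance = 1e-12)

  expect_error(baselineCentrality(tri, "EC"), "arg")
})

test_that("closeness uses per-component normalization and agrees with igraph when connected", {
  # two components: a-b-c path and isolated pair d-e
  net <- net_from_pairs(rbind(c("a", "b"), c("b", "c"), c("d", "e")))
  cc <- scoreValues(baselineCentrality(net, "CC"))
  expect_equal(cc[["b"]], 1)            # (3-1)/(1+1)
  expect_equal(cc[["a"]], 2 / 3)
  expect_equal(cc[["d"]], 1)            # (2-1)/1 within its component
  # connected case: matches igraph's normalized closeness
  set.seed(6)
  repeat {
    rn <- random_net(12, 0.4)
    g <- igraph::graph_from_adjacency_matrix(assocMatrix(rn), mode = "undirected")
    if (igraph::is_connected(g)) break
  }
  ours <- unname(scoreValues(baselineCentrality(rn, "CC")))
  ref <- unname(igraph::closeness(g, normalized = TRUE))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("evaluateRanking bundles consistent metrics", {
  set.seed(37)
  ids <- sprintf("p%03d", 1:60)
  ranking <- sample(ids)
  gold <- sample(ids, 12)
  rep <- evaluateRanking(ranking, gold, cutoffs = c(10L, 20L, 40L))
  expect_s4_class(rep, "EvaluationReport")
  expect_equal(rep@nGold, 12L)
  expect_true(all(diff(rep@topkHits) >= 0))
  expect_true(all(rep@topkHits <= c(10, 20, 40)))
  expect_equal(rep@topkHits[["20"]], rep@jackknifePoints$hits[20])
  expect_equal(utils::tail(rep@prPoints$recall, 1), 1)
  expect_equal(utils::tail(rep@jackknifePoints$hits, 1), 12L)
})
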