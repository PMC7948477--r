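test_that("hypergeometric tail matches exact combinatorics", {
  expect_equal(hypergeom_pvalue(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeom_pvalue(0, 5, 5, 10), 1)      # P(X >= 0)
  expect_equal(hypergeom_pvalue(2, 2, 2, 4), 1 / 6)   # 1 / C(4,2)
  expect_error(hypergeom_pvalue(3, 2, 5, 10), "<=")
  expect_error(hypergeom_pvalue(1, 11, 5, 10), "<=")
  # monotone non-increasing in k for fixed (K, n, N)
  p_seq <- vapply(0:5, hypergeom_pvalue, numeric(1), K = 6, n = 5, N = 20)
  expect_true(all(diff(p_seq) <= 1e-15))
  # spot-check against exhaustive enumeration
  for (case in list(c(2, 4, 5, 10), c(1, 3, 3, 9), c(4, 6, 7, 11))) {
    expect_equal(hypergeom_pvalue(case[1], case[2], case[3], case[4]),
                 oracle_hyper_upper(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
  # lower tail is the depletion probability
  expect_equal(hypergeom_pvalue(0, 5, 5, 10, lower = TRUE),
               choose(5, 5) / choose(10, 5))
})

test_that("pathway over-representation counts, tests, and gates", {
  universe <- sprintf("u%02d", 1:10)
  col <- pathway_collection(list(full = universe[1:5]))
  res <- enrich_pathways(universe[1:5], col, universe)
  expect_equal(res$k, 5)
  expect_equal(res$p_value, 1 / choose(10, 5))
  expect_true(res$significant)
  # disjoint query: k = 0, p = 1, nothing significant
  res0 <- enrich_pathways(universe[6:10], col, universe)
  expect_equal(res0$k, 0)
  expect_equal(res0$p_value, 1)
  expect_false(res0$significant)
  # members outside the universe are dropped and counted
  res_d <- enrich_pathways(c(universe[1:5], "alien"), col, universe)
  expect_equal(attr(res_d, "n_query_dropped"), 1)
  expect_error(enrich_pathways("alien", col, universe), "empty")
})

test_that("a planted enriched pathway attains the minimum p-value", {
  withr::with_seed(17, {
    universe <- sprintf("g%03d", 1:200)
    sets <- c(list(planted = universe[1:20]),
              lapply(1:9, function(i) sample(universe, 20)))
    names(sets) <- c("planted", paste0("bg", 1:9))
    col <- pathway_collection(sets)
    query <- c(universe[1:20], sample(universe[21:200], 10))
    res <- enrich_pathways(query, col, universe)
    expect_equal(res$pathway[which.min(res$p_value)], "planted")
    expect_true(res$significant[res$pathway == "planted"])
  })
})

test_that("jaccard is the intersection-over-union on sets", {
  expect_equal(jaccard(letters[1:4], letters[1:4]), 1)
  expect_equal(jaccard(c("a", "b"), c("x", "y")), 0)
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_error(jaccard(character(0), character(0)), "empty")
  for (s in 1:10) {
    withr::with_seed(s, {
      a <- sample(letters, sample(1:10, 1))
      b <- sample(letters, sample(1:10, 1))
      j <- jaccard(a, b)
      expect_equal(j, jaccard(b, a))
      expect_gte(j, 0); expect_lte(j, 1)
      expect_equal(j == 1, setequal(a, b))
    })
  }
})

toy_enrichment <- function(pathways, detected, query = detected) {
  # minimal EnrichmentResult marking every pathway significant
  col <- pathway_collection(pathways)
  universe <- unique(c(unlist(pathways), detected))
  res <- enrich_pathways(query, col, universe, p_max = 1.01)
  list(result = res, collection = col)
}

test_that("pathway graph keeps exactly the edges at or above j_min", {
  # hand-built detected sets; J(A,B) = 8/16 = 0.5, J(B,C) = 4/28 = 0.143,
  # J(A,C) = 0 (below threshold)
  d <- sprintf("d%02d", 1:40)
  pws <- list(A = d[1:12],
              B = c(d[1:8], d[13:16]),
              C = c(d[13:16], d[17:32]))
  te <- toy_enrichment(pws, detected = d)
  pg <- build_pathway_graph(te$result, te$collection, detected = d,
                            j_min = 0.1)
  el <- igraph::as_edgelist(pg$graph)
  w <- setNames(igraph::E(pg$graph)$weight,
                apply(el, 1, paste, collapse = "-"))
  expect_setequal(names(w), c("A-B", "B-C"))
  expect_equal(unname(w["A-B"]), 8 / 16, tolerance = 1e-12)
  expect_equal(unname(w["B-C"]), 4 / 28, tolerance = 1e-12)
  # identical detected sets give one edge of weight 1
  te2 <- toy_enrichment(list(X = d[1:5], Y = d[1:5]), detected = d)
  pg2 <- build_pathway_graph(te2$result, te2$collection, d, j_min = 0.1)
  expect_equal(igraph::ecount(pg2$graph), 1)
  expect_equal(igraph::E(pg2$graph)$weight, 1)
  # all pairwise J below threshold: nodes but no edges
  te3 <- toy_enrichment(list(X = d[1:5], Y = d[6:10]), detected = d)
  pg3 <- build_pathway_graph(te3$result, te3$collection, d, j_min = 0.1)
  expect_equal(igraph::vcount(pg3$graph), 2)
  expect_equal(igraph::ecount(pg3$graph), 0)
})

test_that("pathway graph is invariant to pathway ordering and drops
           undetected pathways", {
  d <- sprintf("d%02d", 1:20)
  pws <- list(A = d[1:6], B = d[4:9], C = d[10:14])
  te_f <- toy_enrichment(pws, detected = d)
  te_r <- toy_enrichment(rev(pws), detected = d)
  pf <- build_pathway_graph(te_f$result, te_f$collection, d, 0.1)
  pr <- build_pathway_graph(te_r$result, te_r$collection, d, 0.1)
  canon <- function(pg) {
    el <- igraph::as_edgelist(pg$graph)
    o <- order(el[, 1], el[, 2])
    cbind(el[o, , drop = FALSE], igraph::E(pg$graph)$weight[o])
  }
  expect_equal(canon(pf), canon(pr))
  # a significant pathway with no detected member is excluded with warning
  pws2 <- list(A = d[1:6], ghost = c("z1", "z2"))
  te2 <- toy_enrichment(pws2, detected = d,
                        query = d[1:6])
  expect_warning(pg2 <- build_pathway_graph(te2$result, te2$collection,
                                            d, 0.1), "ghost")
  expect_equal(igraph::V(pg2$graph)$name, "A")
  # no significant pathway: empty graph with a warning, not an error
  col3 <- pathway_collection(list(A = d[1:6]))
  res3 <- enrich_pathways(d[7:12], col3, d)   # k = 0, not significant
  expect_warning(pg3 <- build_pathway_graph(res3, col3, d, 0.1),
                 "no significant")
  expect_equal(igraph::vcount(pg3$graph), 0)
})

test_that("designed pathway overlaps are exactly the retained edges", {
  # pathways built pairwise-disjoint except for the planted consecutive
  # overlaps, so retained edges must match the designed pairs exactly
  universe <- sprintf("u%03d", 1:60)
  sets <- list(P1 = universe[1:10],
               P2 = c(universe[6:10], universe[11:15]),   # shares 5 with P1
               P3 = c(universe[14:15], universe[16:23]),  # shares 2 with P2
               P4 = universe[24:33])                      # disjoint
  te <- toy_enrichment(sets, detected = universe)
  pg <- build_pathway_graph(te$result, te$collection, universe, j_min = 0.1)
  el <- apply(igraph::as_edgelist(pg$graph), 1, paste, collapse = "-")
  expect_setequal(el, c("P1-P2", "P2-P3"))  # J = 5/15 and 2/18
})

test_that("modularity modules split disconnected cliques exactly", {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, 7, name = c(paste0("a", 1:4), paste0("b", 1:3)))
  clique_edges <- function(nodes) t(utils::combn(nodes, 2))
  g <- igraph::add_edges(g, t(rbind(clique_edges(paste0("a", 1:4)),
                                    clique_edges(paste0("b", 1:3)))))
  igraph::E(g)$weight <- 1
  memb <- detect_modules(g, seed = 1)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[paste0("a", 1:4)])), 1)
  expect_equal(length(unique(memb[paste0("b", 1:3)])), 1)
  # agrees with the exhaustive modularity search up to relabeling
  oracle <- oracle_best_partition(g)
  expect_equal(length(unique(oracle$membership)), 2)
  same_split <- function(m1, m2) {
    all(outer(m1, m1, "==") == outer(m2, m2, "=="))
  }
  expect_true(same_split(memb[names(oracle$membership)],
                         oracle$membership))
  # module ids are stable: larger clique first
  expect_equal(unname(memb["a1"]), 1L)
  # determinism and singleton handling
  expect_identical(detect_modules(g, seed = 1), detect_modules(g, seed = 1))
  g1 <- igraph::add_vertices(igraph::make_empty_graph(0, directed = FALSE),
                             1, name = "solo")
  expect_equal(unname(detect_modules(g1)), 1L)
})

test_that("GMT files round-trip with source labels", {
  dir <- withr::local_tempdir()
  col <- pathway_collection(list(alpha = c("g1", "g2", "g3"),
                                 beta = c("g2", "g4")),
                            source = c("KEGG", "Reactome"))
  path <- file.path(dir, "sets.gmt")
  write_gmt(col, path)
  back <- read_gmt(path)
  expect_equal(unclass(back)[order(names(back))],
               unclass(col)[order(names(col))],
               ignore_attr = TRUE)
  expect_equal(unname(attr(back, "source")), c("KEGG", "Reactome"))
  writeLines("badline", file.path(dir, "bad.gmt"))
  expect_error(read_gmt(file.path(dir, "bad.gmt")), "malformed")
})
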