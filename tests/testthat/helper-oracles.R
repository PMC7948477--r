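# Independent oracles used to check the package's statistics: a plain
# adjacency-list BFS (no graph library), the literal Benjamini-Hochberg
# step-up definition, exhaustive hypergeometric enumeration, and an
# exhaustive modularity partition search. These deliberately avoid the
# code paths they verify.

# adjacency list from a two-column character edge matrix
adj_list <- function(edges) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (a == b) next
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# BFS shortest-path distances from `from` to every node (Inf if unreachable)
bfs_dist <- function(adj, from) {
  dist <- setNames(rep(Inf, length(adj)), names(adj))
  dist[from] <- 0
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (!is.finite(dist[v])) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# brute-force closest distance: per-source BFS, min over targets, mean over
# sources that can reach at least one target
oracle_closest_distance <- function(edges, S, T) {
  adj <- adj_list(edges)
  mins <- vapply(S, function(s) min(bfs_dist(adj, s)[T]), numeric(1))
  mean(mins[is.finite(mins)])
}

# literal BH step-up: q_(i) = min_{j >= i} (m p_(j) / j), clipped to 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive hypergeometric upper tail: enumerate every n-subset of 1..N,
# count those overlapping the K-set {1..K} in at least k elements
oracle_hyper_upper <- function(k, K, n, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# all set partitions of 1..n as membership vectors (restricted growth)
all_partitions <- function(n) {
  out <- list()
  recurse <- function(memb, maxid) {
    i <- length(memb) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- memb
      return()
    }
    for (g in seq_len(maxid + 1L)) {
      recurse(c(memb, g), max(maxid, g))
    }
  }
  recurse(integer(0), 0L)
  out
}

# exhaustive modularity maximum over every partition of a small graph
oracle_best_partition <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n <= 8)
  w <- if (igraph::ecount(graph) > 0) igraph::E(graph)$weight else NULL
  best <- NULL
  best_q <- -Inf
  for (memb in all_partitions(n)) {
    q <- igraph::modularity(graph, memb, weights = w)
    if (q > best_q + 1e-12) {
      best_q <- q
      best <- memb
    }
  }
  list(membership = setNames(best, igraph::V(graph)$name),
       modularity = best_q)
}

# tiny labelled Erdos-Renyi-style graph for oracle comparisons; always
# returns at least one edge
random_test_graph <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    repeat {
      m <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- stats::runif(nrow(m)) < p_edge
      if (any(keep)) break
    }
    edges <- cbind(sprintf("n%02d", m[keep, 1]), sprintf("n%02d", m[keep, 2]))
    list(edges = edges,
         graph = igraph::graph_from_edgelist(edges, directed = FALSE))
  })
}

# small paired peptide table builder used across quant tests
toy_peptides <- function() {
  peptide_table(data.frame(
    peptide = c("AAA", "AAA", "AAA", "BBB", "BBB", "BBB", "CCC", "CCC", "CCC"),
    protein_id = c("P1", "P1", "P1", "P1", "P1", "P1", "P2", "P2", "P2"),
    donor = "d1",
    condition = rep(c("NFNC", "F", "C"), 3),
    intensity = c(10, 10, 20, 5, 10, 5, 8, 8, 8),
    stringsAsFactors = FALSE
  ))
}
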