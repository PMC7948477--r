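# Pathway over-representation and crosstalk: exact hypergeometric
# enrichment with Benjamini-Hochberg control, the Jaccard index on
# detected-protein subsets, the thresholded pathway crosstalk graph, and
# modularity-based module detection.

#' Pathway collection
#'
#' An ordered, named list of gene sets with a source label per pathway
#' (e.g. the database a pathway came from).
#'
#' @param sets named list of non-empty character vectors; names must be
#'   unique.
#' @param source a single label or one label per pathway.
#' @return an object of class `PathwayCollection`.
#' @export
pathway_collection <- function(sets, source = "unknown") {
  stopifnot(is.list(sets), length(sets) >= 1)
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(names(sets) == "")) {
    stop("pathways must have unique non-empty names")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0)) stop("pathway member sets must be non-empty")
  source <- rep_len(as.character(source), length(sets))
  names(source) <- names(sets)
  structure(sets, source = source, class = "PathwayCollection")
}

#' @export
print.PathwayCollection <- function(x, ...) {
  cat(sprintf("PathwayCollection: %d pathways, sizes %d-%d, %d genes\n",
              length(x), min(lengths(x)), max(lengths(x)),
              length(unique(unlist(x)))))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one pathway per
#' line, `name <tab> description <tab> member1 <tab> member2 ...`. The
#' description column is kept as the pathway's source label on reading
#' (most GMT readers discard it) and written back on writing.
#'
#' @param path file path.
#' @return `read_gmt` returns a [pathway_collection()]; `write_gmt`
#'   returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1], " (need name, description, members)")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1)
  pathway_collection(sets,
                     source = vapply(fields, `[[`, character(1), 2))
}

#' @rdname read_gmt
#' @param collection a [pathway_collection()].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "PathwayCollection"))
  src <- attr(collection, "source")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, src[[nm]], collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `k` query genes inside a pathway of
#' size `K` when drawing `n` genes without replacement from a universe of
#' `N`: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. This is the
#' over-representation tail; set `lower = TRUE` for the depletion tail
#' `P(X <= k)`.
#'
#' @param k overlap count, `0 <= k <= min(K, n)`.
#' @param K pathway size within the universe.
#' @param n query size within the universe.
#' @param N universe size; `K, n <= N`.
#' @param lower return the depletion tail instead.
#' @return the tail probability in (0, 1].
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_pvalue <- function(k, K, n, N, lower = FALSE) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || N < 0 || K > N || n > N ||
      k > min(K, n)) {
    stop("require 0 <= k <= min(K, n) and K, n <= N")
  }
  if (lower) {
    phyper(k, K, N - K, n, lower.tail = TRUE)
  } else {
    # P(X >= k) = P(X > k - 1); exact upper tail
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
}

#' Hypergeometric pathway over-representation
#'
#' Tests each pathway for over-representation of the query set against a
#' background universe (conventionally: the genes of the collection
#' intersected with the detected proteome). Query members outside the
#' universe are dropped and counted. Per pathway with at least one
#' universe member: `k` = |query ∩ pathway ∩ universe|, `K` = |pathway ∩
#' universe|, `n` = |query ∩ universe|, `N` = |universe|; p from
#' [hypergeom_pvalue()]; q by Benjamini-Hochberg across the tested
#' pathways. A pathway is flagged significant when p < `p_max`; the
#' companion FDR level `q_report` is recorded alongside.
#'
#' @param query character vector of gene identifiers.
#' @param collection a [pathway_collection()].
#' @param universe character vector; the background gene universe.
#' @param p_max significance gate on the hypergeometric p (default 0.05).
#' @param q_report FDR level reported alongside (default 0.15).
#' @return a data frame of class `EnrichmentResult` with columns
#'   `pathway`, `k`, `K`, `n`, `N`, `p_value`, `q_value`, `significant`,
#'   `overlap` (comma-separated members); attributes `n_query_dropped`,
#'   `p_max`, `q_report`.
#' @export
enrich_pathways <- function(query, collection, universe, p_max = 0.05,
                            q_report = 0.15) {
  stopifnot(inherits(collection, "PathwayCollection"))
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  q_in <- intersect(query, universe)
  n_dropped <- length(query) - length(q_in)
  if (length(q_in) == 0) {
    stop("query is empty after intersection with the universe")
  }
  N <- length(universe)
  n <- length(q_in)
  rows <- lapply(names(collection), function(nm) {
    pw <- intersect(collection[[nm]], universe)
    if (length(pw) == 0) return(NULL)
    ov <- intersect(q_in, pw)
    data.frame(pathway = nm, k = length(ov), K = length(pw), n = n, N = N,
               p_value = hypergeom_pvalue(length(ov), length(pw), n, N),
               overlap = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no pathway has members in the universe")
  res$q_value <- compute_qvalues(res$p_value)
  res$significant <- res$p_value < p_max
  res <- res[, c("pathway", "k", "K", "n", "N", "p_value", "q_value",
                 "significant", "overlap")]
  attr(res, "n_query_dropped") <- n_dropped
  attr(res, "p_max") <- p_max
  attr(res, "q_report") <- q_report
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Jaccard index of two sets
#'
#' `|a ∩ b| / |a ∪ b|`: 1 for identical sets, 0 for disjoint ones.
#'
#' @param a,b character vectors (treated as sets); their union must be
#'   non-empty.
#' @return the Jaccard index in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) stop("jaccard undefined for two empty sets")
  length(intersect(a, b)) / length(u)
}

#' Build the Jaccard-weighted pathway crosstalk graph
#'
#' Nodes are the significant pathways of an enrichment result. For each
#' pathway A, `s_A` is the set of its members actually detected in the
#' proteomics experiment; an edge (A, B) carries weight `jaccard(s_A,
#' s_B)` and is kept only when the weight is at least `j_min` (edges below
#' the threshold carry little shared signal and are discarded). Pathways
#' whose detected subset is empty are excluded with a warning.
#'
#' @param results an [enrich_pathways()] result.
#' @param collection the [pathway_collection()] the result was computed
#'   from.
#' @param detected character vector of detected gene identifiers.
#' @param j_min minimum Jaccard weight for an edge to be retained
#'   (default 0.1).
#' @return an object of class `PathwayGraph`: a list with `graph` (an
#'   [igraph::igraph] whose edges carry a `weight` attribute),
#'   `detected_sets` (the `s_A` per node), and `j_min`. No significant
#'   pathway yields an empty graph with a warning.
#' @export
build_pathway_graph <- function(results, collection, detected,
                                j_min = 0.1) {
  stopifnot(inherits(results, "EnrichmentResult"),
            inherits(collection, "PathwayCollection"))
  detected <- unique(as.character(detected))
  if (length(detected) == 0) stop("detected set must be non-empty")
  sig <- results$pathway[results$significant]
  if (length(sig) == 0) {
    warning("no significant pathways; returning an empty pathway graph")
    return(structure(list(graph = igraph::make_empty_graph(0,
                                                           directed = FALSE),
                          detected_sets = list(), j_min = j_min),
                     class = "PathwayGraph"))
  }
  sig <- sort(sig)
  s_sets <- lapply(sig, function(nm) intersect(collection[[nm]], detected))
  names(s_sets) <- sig
  empty <- lengths(s_sets) == 0
  if (any(empty)) {
    warning("pathway(s) with no detected members excluded: ",
            paste(sig[empty], collapse = ", "))
    s_sets <- s_sets[!empty]
  }
  nodes <- names(s_sets)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(nodes) >= 2) {
    pairs <- utils::combn(nodes, 2)
    w <- apply(pairs, 2, function(pr) jaccard(s_sets[[pr[1]]],
                                              s_sets[[pr[2]]]))
    keep <- w >= j_min
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
      igraph::E(g)$weight <- w[keep]
    }
  }
  structure(list(graph = g, detected_sets = s_sets, j_min = j_min),
            class = "PathwayGraph")
}

#' @export
print.PathwayGraph <- function(x, ...) {
  cat(sprintf("PathwayGraph: %d pathways, %d crosstalk edges (J >= %g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$j_min))
  invisible(x)
}

#' Detect pathway modules by modularity maximization
#'
#' Groups pathways into modules by greedy agglomerative modularity
#' maximization on the Jaccard-weighted crosstalk graph (deterministic:
#' repeated runs give identical assignments; `seed` is accepted for
#' interface stability). Isolated pathways form singleton modules. Module
#' ids are stable: modules are numbered by decreasing size, ties broken by
#' the lexicographically smallest member.
#'
#' @param graph a [build_pathway_graph()] result (or a plain weighted
#'   undirected igraph).
#' @param seed integer; retained so callers can treat all analysis stages
#'   uniformly.
#' @return named integer vector mapping pathway name to module id.
#' @export
detect_modules <- function(graph, seed = 1L) {
  g <- if (inherits(graph, "PathwayGraph")) graph$graph else graph
  stopifnot(inherits(g, "igraph"))
  if (igraph::vcount(g) == 0) return(setNames(integer(0), character(0)))
  w <- if (igraph::ecount(g) > 0) igraph::E(g)$weight else NULL
  memb <- if (igraph::ecount(g) == 0) {
    seq_len(igraph::vcount(g))
  } else {
    igraph::membership(igraph::cluster_fast_greedy(g, weights = w))
  }
  memb <- as.integer(memb)
  names(memb) <- igraph::V(g)$name
  # stable relabeling: size desc, then smallest member name
  info <- data.frame(old = unique(memb))
  info$size <- vapply(info$old, function(m) sum(memb == m), integer(1))
  info$first <- vapply(info$old, function(m) min(names(memb)[memb == m]),
                       character(1))
  info <- info[order(-info$size, info$first), , drop = FALSE]
  relabel <- setNames(seq_len(nrow(info)), info$old)
  out <- relabel[as.character(memb)]
  names(out) <- names(memb)
  out
}

#' Write enrichment and pathway-graph artifacts
#'
#' `write_enrichment` writes the per-pathway table as TSV.
#' `write_pathway_graph` writes three files under a prefix: a GraphML
#' graph (`<prefix>.graphml`), an edge list
#' (`<prefix>_edges.tsv`: pathway_A, pathway_B, jaccard) and a node table
#' (`<prefix>_nodes.tsv`: pathway, module, size, p, q).
#'
#' @param results an `EnrichmentResult`.
#' @param path,prefix output locations.
#' @export
write_enrichment <- function(results, path) {
  write_tsv(as.data.frame(results), path)
}

#' @rdname write_enrichment
#' @param graph a `PathwayGraph`.
#' @param modules a [detect_modules()] assignment for the graph's nodes.
#' @export
write_pathway_graph <- function(graph, results, modules, prefix) {
  stopifnot(inherits(graph, "PathwayGraph"))
  g <- graph$graph
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    edges <- data.frame(pathway_A = el[, 1], pathway_B = el[, 2],
                        jaccard = igraph::E(g)$weight,
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(pathway_A = character(0), pathway_B = character(0),
                        jaccard = numeric(0))
  }
  write_tsv(edges, paste0(prefix, "_edges.tsv"))
  nm <- igraph::V(g)$name
  idx <- match(nm, results$pathway)
  nodes <- data.frame(pathway = nm,
                      module = as.integer(modules[nm]),
                      size = lengths(graph$detected_sets[nm]),
                      p = results$p_value[idx],
                      q = results$q_value[idx],
                      stringsAsFactors = FALSE)
  write_tsv(nodes, paste0(prefix, "_nodes.tsv"))
  invisible(prefix)
}
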