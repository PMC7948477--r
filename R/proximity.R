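# Interactome proximity: edge-list I/O, gene-set mapping, induced
# subnetworks, the closest-distance statistic d_c, and its
# degree-preserving randomization null with empirical p-values.

#' Load a protein-protein interaction network from an edge list
#'
#' Reads a two-column whitespace- or tab-separated edge list (extra
#' columns ignored) into an undirected simple graph: self-loops are
#' dropped and duplicate edges collapsed, with counts reported as
#' attributes. Node identifiers are case-preserved strings.
#'
#' @param path edge-list file.
#' @param header `"auto"` (default: the first line is treated as a header
#'   when its first two tokens look like column names such as
#'   `from`/`to`/`source`/`target`), `"none"`, or `"present"`.
#' @return an undirected [igraph::igraph] with attributes
#'   `n_self_loops_dropped` and `n_duplicates_collapsed`.
#' @export
load_network <- function(path, header = c("auto", "none", "present")) {
  header <- match.arg(header)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty network file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(toks) < 2)
  if (length(bad)) {
    stop("malformed edge at line ", bad[1], " of ", path,
         " (need two identifiers)")
  }
  header_words <- c("from", "to", "source", "target", "node1", "node2",
                    "gene1", "gene2", "protein1", "protein2",
                    "interactor_a", "interactor_b")
  drop_first <- switch(header,
    none = FALSE,
    present = TRUE,
    auto = any(tolower(toks[[1]][1:2]) %in% header_words))
  if (drop_first) toks <- toks[-1]
  if (length(toks) == 0) stop("no edges in ", path)
  a <- vapply(toks, `[[`, character(1), 1)
  b <- vapply(toks, `[[`, character(1), 2)
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]
  if (length(a) == 0) stop("no non-loop edges in ", path)
  # canonical order so (x,y) and (y,x) collapse
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  g <- igraph::graph_from_edgelist(cbind(lo[!dup], hi[!dup]),
                                   directed = FALSE)
  g$n_self_loops_dropped <- n_self
  g$n_duplicates_collapsed <- sum(dup)
  g
}

#' @rdname load_network
#' @param network an [igraph::igraph] with named nodes.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  write_tsv(data.frame(from = el[, 1], to = el[, 2],
                       stringsAsFactors = FALSE), path)
}

#' Partition a gene set into network members and non-members
#'
#' Exact, case-sensitive identifier matching against the network's node
#' names.
#'
#' @param genes character vector of gene identifiers.
#' @param network an [igraph::igraph] with named nodes.
#' @return list with `mapped` (character vector) and `unmapped`
#'   (character vector); a warning is issued when nothing maps.
#' @export
map_to_network <- function(genes, network) {
  genes <- unique(as.character(genes))
  nodes <- igraph::V(network)$name
  mapped <- genes[genes %in% nodes]
  unmapped <- genes[!genes %in% nodes]
  if (length(mapped) == 0 && length(genes) > 0) {
    warning("none of ", length(genes), " genes map to the network")
  }
  list(mapped = mapped, unmapped = unmapped)
}

#' Induced subnetwork on a gene set
#'
#' Subgraph on the given genes (intersected with the node set) with all
#' edges among them; connected-component sizes are attached as the
#' `component_sizes` attribute.
#'
#' @inheritParams map_to_network
#' @return an [igraph::igraph].
#' @export
induced_subnetwork <- function(network, genes) {
  keep <- intersect(unique(as.character(genes)), igraph::V(network)$name)
  sub <- igraph::induced_subgraph(network, keep)
  comp <- igraph::components(sub)
  sub$component_sizes <- sort(as.integer(comp$csize), decreasing = TRUE)
  sub
}

# Minimum shortest-path distance from every node of the graph to the set
# `to` (named numeric vector; Inf when unreachable).
min_dist_to_set <- function(network, to) {
  d <- igraph::distances(network, v = to)
  if (length(to) == 1) d[1, ] else apply(d, 2, min)
}

#' Closest-distance statistic between two gene sets
#'
#' For each source gene s in S, the shortest-path distance (number of
#' edges) to the nearest target gene in T; d_c is the mean of these
#' per-source minima. A source inside T contributes 0, so S a subset of T
#' gives d_c = 0. Sources with no reachable target are excluded from the
#' mean and listed (an error is raised if all are unreachable).
#'
#' @param network an undirected [igraph::igraph] with named nodes.
#' @param S,T non-empty character vectors of node names (map identifiers
#'   first with [map_to_network()]).
#' @return list with `d_c` (numeric), `excluded` (unreachable sources) and
#'   `per_source` (named vector of per-source minima, included sources
#'   only).
#' @examples
#' g <- igraph::make_graph(~ a - b - c - d - e)
#' closest_distance(g, "a", "e")$d_c  # 4
#' @export
closest_distance <- function(network, S, T) {
  nodes <- igraph::V(network)$name
  S <- unique(as.character(S)); T <- unique(as.character(T))
  if (length(S) == 0 || length(T) == 0) stop("S and T must be non-empty")
  if (!all(S %in% nodes) || !all(T %in% nodes)) {
    stop("S and T must be subsets of the network nodes; ",
         "use map_to_network() first")
  }
  mind <- min_dist_to_set(network, T)[S]
  excluded <- names(mind)[!is.finite(mind)]
  kept <- mind[is.finite(mind)]
  if (length(kept) == 0) stop("no source can reach any target")
  list(d_c = mean(kept), excluded = excluded, per_source = kept)
}

# Assign every node to a logarithmic (base-2) degree bin; adjacent bins
# are merged, lowest first, until each holds at least `min_bin_size`
# nodes. Returns an integer bin id per node name.
degree_bins <- function(network, min_bin_size = 10L) {
  deg <- igraph::degree(network)
  raw <- ifelse(deg == 0, -1L, floor(log2(deg)))
  lv <- sort(unique(raw))
  counts <- vapply(lv, function(x) sum(raw == x), integer(1))
  # merge upward while a bin is under the minimum
  merged <- integer(length(lv))  # merged group id per raw level
  gid <- 1L
  acc <- 0L
  for (i in seq_along(lv)) {
    merged[i] <- gid
    acc <- acc + counts[i]
    if (acc >= min_bin_size) {
      gid <- gid + 1L
      acc <- 0L
    }
  }
  # a trailing underfull group is merged into the previous one
  if (acc > 0L && gid > 1L) {
    merged[merged == gid] <- gid - 1L
  }
  bins <- merged[match(raw, lv)]
  setNames(as.integer(bins), names(deg))
}

#' Degree-matched random gene set
#'
#' Draws a random node set with the same binned degree profile as the
#' template: nodes are grouped into logarithmic (base-2) degree bins,
#' adjacent bins merged until each holds at least `min_bin_size` nodes,
#' and for every template member one node is drawn without replacement
#' from that member's bin. This is the null that keeps hub bias from
#' inflating proximity significance.
#'
#' @param network an [igraph::igraph] with named nodes.
#' @param template character vector of node names to match.
#' @param seed integer seed.
#' @param min_bin_size minimum nodes per merged degree bin (default 10).
#' @return character vector of node names, same length as `template`.
#' @export
degree_matched_sample <- function(network, template, seed,
                                  min_bin_size = 10L) {
  with_seed(seed, {
    degree_matched_draw(network, template,
                        degree_bins(network, min_bin_size))
  })
}

# One degree-matched draw using the caller's RNG stream and precomputed
# bins. Shared by degree_matched_sample() and proximity_test().
degree_matched_draw <- function(network, template, bins) {
  template <- unique(as.character(template))
  if (!all(template %in% names(bins))) {
    stop("template must be a subset of the network nodes")
  }
  need <- table(bins[template])
  out <- character(0)
  for (b in names(need)) {
    pool <- names(bins)[bins == as.integer(b)]
    if (length(pool) < need[[b]]) {
      stop("degree bin ", b, " holds ", length(pool),
           " nodes but the template needs ", need[[b]])
    }
    out <- c(out, sample(pool, need[[b]]))
  }
  out
}

#' Proximity test: closest distance against a degree-preserving null
#'
#' Computes the observed closest distance d_c between S and T, then a
#' null distribution by replacing S, T, or both with degree-matched
#' random sets ([degree_matched_sample()]) `n_randomizations` times. The
#' z-score is `(observed - null_mean) / null_sd`, and the one-sided
#' empirical p-value is `(r + 1) / (n + 1)` with `r` the number of null
#' statistics less than or equal to the observed (small d_c = proximity).
#'
#' @param network an [igraph::igraph] with named nodes.
#' @param S,T non-empty sets of node names (source and target).
#' @param n_randomizations null draws (>= 1; 200 is the conventional
#'   default).
#' @param seed integer seed governing all draws.
#' @param randomize which set(s) to randomize: `"S"` (default), `"T"`, or
#'   `"both"`.
#' @param min_bin_size minimum nodes per merged degree bin.
#' @param retry_budget redraws allowed when a null draw has no reachable
#'   source-target pair.
#' @return an object of class `ProximityResult`: a list with
#'   `observed_dc`, `n_source`, `n_target`, `excluded_sources`,
#'   `null` (the full null vector), `null_mean`, `null_sd`, `z_score`
#'   (`NA` when `null_sd` is 0), `empirical_p`, `n_randomizations`,
#'   `randomize`, `seed`.
#' @export
proximity_test <- function(network, S, T, n_randomizations = 200L, seed = 1L,
                           randomize = c("S", "T", "both"),
                           min_bin_size = 10L, retry_budget = 100L) {
  randomize <- match.arg(randomize)
  stopifnot(n_randomizations >= 1)
  obs <- closest_distance(network, S, T)
  bins <- degree_bins(network, min_bin_size)
  S <- unique(as.character(S)); T <- unique(as.character(T))

  null_dc <- with_seed(seed, {
    # T fixed: one BFS from T gives min distances for every candidate S
    dist_to_T <- if (randomize == "S") min_dist_to_set(network, T) else NULL
    retries <- 0L
    vapply(seq_len(n_randomizations), function(i) {
      repeat {
        Si <- if (randomize %in% c("S", "both")) {
          degree_matched_draw(network, S, bins)
        } else S
        Ti <- if (randomize %in% c("T", "both")) {
          degree_matched_draw(network, T, bins)
        } else T
        d <- if (randomize == "S") {
          v <- dist_to_T[Si]
          if (any(is.finite(v))) mean(v[is.finite(v)]) else Inf
        } else {
          dm <- igraph::distances(network, v = Si, to = Ti)
          v <- apply(dm, 1, min)
          if (any(is.finite(v))) mean(v[is.finite(v)]) else Inf
        }
        if (is.finite(d)) return(d)
        retries <<- retries + 1L
        if (retries > retry_budget) {
          stop("null draws exhausted the retry budget: no reachable ",
               "source-target pair")
        }
      }
    }, numeric(1))
  })

  mu <- mean(null_dc)
  sdv <- sd(null_dc)
  r <- sum(null_dc <= obs$d_c)
  structure(list(
    observed_dc = obs$d_c,
    n_source = length(S),
    n_target = length(T),
    excluded_sources = obs$excluded,
    null = null_dc,
    null_mean = mu,
    null_sd = sdv,
    z_score = if (sdv > 0) (obs$d_c - mu) / sdv else NA_real_,
    empirical_p = (r + 1) / (n_randomizations + 1),
    n_randomizations = as.integer(n_randomizations),
    randomize = randomize,
    seed = as.integer(seed)
  ), class = "ProximityResult")
}

#' @export
print.ProximityResult <- function(x, ...) {
  cat(sprintf(paste0(
    "ProximityResult: d_c = %.4g (|S| = %d, |T| = %d)\n",
    "null (%d draws, randomize=%s): mean = %.4g, sd = %.4g\n",
    "z = %.3g, empirical p = %.4g\n"),
    x$observed_dc, x$n_source, x$n_target, x$n_randomizations,
    x$randomize, x$null_mean, x$null_sd,
    if (is.na(x$z_score)) NA else x$z_score, x$empirical_p))
  if (length(x$excluded_sources)) {
    cat("excluded (unreachable) sources:",
        paste(x$excluded_sources, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a proximity result as JSON plus a TSV null distribution
#'
#' @param result a `ProximityResult`.
#' @param prefix output prefix: writes `<prefix>.json` (summary, with a
#'   reference to the null file) and `<prefix>_null.tsv` (one null d_c
#'   per row).
#' @export
write_proximity <- function(result, prefix) {
  stopifnot(inherits(result, "ProximityResult"))
  null_path <- paste0(prefix, "_null.tsv")
  write_tsv(data.frame(null_dc = result$null), null_path)
  summary <- result[setdiff(names(result), "null")]
  summary$null_file <- basename(null_path)
  jsonlite::write_json(summary, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}
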