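# Seeded generators for every input the analysis chain consumes: a
# scale-free interaction network, pathway collections with controlled
# overlap, gene sets planted at known network proximity, and log-normal
# abundance tables with planted condition effects. All generators are pure
# functions of (parameters, seed) and return a ground-truth record so
# downstream recovery can be tested without external data.

#' Ground truth attached to synthetic inputs
#'
#' A plain record of what a generator planted: enriched protein ids and the
#' log2 effect behind them, source/target node sets with the planting
#' radius, the generator parameters, and the seed. Fields not applicable to
#' a given generator are `NULL`.
#'
#' @param ... named truth fields (e.g. `planted_enriched_ids`,
#'   `effect_log2fc`, `planted_source_set`, `planted_target_set`,
#'   `planted_radius`, `generator_params`, `seed`).
#' @return an object of class `synthetic_truth` (a named list).
#' @export
synthetic_truth <- function(...) {
  structure(list(...), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.list(v)) v <- sprintf("<%d entries>", length(v))
    if (length(v) > 6) v <- c(as.character(head(v, 6)), "...")
    cat(" ", nm, ":", paste(v, collapse = " "), "\n")
  }
  invisible(x)
}

node_ids <- function(n) {
  sprintf(paste0("G%0", max(4L, nchar(n)), "d"), seq_len(n))
}

#' Generate a scale-free interaction network
#'
#' Preferential-attachment (Barabasi-Albert) construction: nodes arrive one
#' at a time and attach `edges_per_node` edges to existing nodes with
#' probability proportional to degree. The result is connected, simple
#' (no self-loops or multi-edges), and has the heavy-tailed degree
#' distribution that makes degree-preserving null models non-trivial --
#' the regime protein-protein interaction networks live in.
#'
#' @param n_nodes number of nodes (> `edges_per_node`).
#' @param edges_per_node edges attached by each arriving node (>= 1).
#' @param seed integer seed; identical calls are bit-for-bit reproducible.
#' @return an undirected [igraph::igraph] with node names `"G0001"`-style.
#' @examples
#' g <- generate_network(100, 2, seed = 1)
#' igraph::vcount(g)
#' @export
generate_network <- function(n_nodes, edges_per_node, seed) {
  stopifnot(n_nodes >= 1, edges_per_node >= 1)
  if (n_nodes <= edges_per_node) {
    stop("n_nodes must exceed edges_per_node")
  }
  g <- with_seed(seed, {
    igraph::sample_pa(n_nodes, m = edges_per_node, directed = FALSE)
  })
  g <- igraph::simplify(g)
  igraph::V(g)$name <- node_ids(n_nodes)
  g
}

#' Generate a pathway collection with controlled overlap
#'
#' Draws `n_pathways` gene sets from `universe` with sizes uniform in
#' `[size_min, size_max]`. Consecutive pathway pairs (1-2, 2-3, ...) are
#' given `ceiling(overlap_fraction * size_min)` shared members so that
#' Jaccard crosstalk edges exist by design; the truth records which pairs
#' were seeded with overlap and with which genes.
#'
#' @param universe character vector of available gene identifiers.
#' @param n_pathways number of pathways (>= 1).
#' @param size_min,size_max pathway size bounds; `size_min >= 2`,
#'   `size_max <= length(universe)`.
#' @param overlap_fraction fraction of `size_min` planted as shared members
#'   between consecutive pathways, in `[0, 1]`.
#' @param seed integer seed.
#' @return a list with `collection` (a [pathway_collection()]) and `truth`
#'   (a [synthetic_truth()] whose `designed_overlaps` lists, per consecutive
#'   pair, the planted shared genes).
#' @export
generate_pathways <- function(universe, n_pathways, size_min, size_max,
                              overlap_fraction, seed) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe must be non-empty")
  stopifnot(n_pathways >= 1, size_min >= 2,
            overlap_fraction >= 0, overlap_fraction <= 1)
  if (size_min > size_max) stop("size_min must not exceed size_max")
  if (size_max > length(universe)) stop("size_max exceeds universe size")
  n_shared <- ceiling(overlap_fraction * size_min)
  sets <- vector("list", n_pathways)
  overlaps <- list()
  with_seed(seed, {
    for (i in seq_len(n_pathways)) {
      size <- if (size_min == size_max) size_min else
        sample(size_min:size_max, 1)
      if (i > 1 && n_shared > 0) {
        shared <- sample(sets[[i - 1]], n_shared)
        rest <- sample(setdiff(universe, shared), size - n_shared)
        sets[[i]] <- c(shared, rest)
        overlaps[[sprintf("PW%03d|PW%03d", i - 1, i)]] <- shared
      } else {
        sets[[i]] <- sample(universe, size)
      }
    }
  })
  names(sets) <- sprintf("PW%03d", seq_len(n_pathways))
  list(
    collection = pathway_collection(sets, source = "synthetic"),
    truth = synthetic_truth(
      designed_overlaps = overlaps,
      generator_params = list(n_pathways = n_pathways, size_min = size_min,
                              size_max = size_max,
                              overlap_fraction = overlap_fraction),
      seed = seed
    )
  )
}

#' Generate a multi-condition abundance matrix with planted enrichment
#'
#' Emulates a paired multi-tissue design: each donor contributes one sample
#' per condition. Intensities are log-normal; on the log2 scale each value
#' is
#' \deqn{baseline_p + effect_{p,c} + donor_{p,d} + batch_{p,b} + noise}
#' where `effect` equals `effect_log2fc` for planted proteins in the
#' designated enriched condition and 0 otherwise, donor intercepts are
#' shared across a donor's samples (sd `donor_sd`), batches group donors
#' (sd `batch_sd`), and noise has sd `noise_sd`. In the noiseless limit a
#' planted protein's fold change is exactly `2^effect_log2fc`.
#' Unique-peptide counts are drawn uniformly from 1..10.
#'
#' @param n_proteins number of proteins.
#' @param donors number of donors (>= 3).
#' @param conditions character vector of >= 2 condition labels; the last is
#'   the enriched condition unless `enriched_condition` says otherwise.
#' @param planted_fraction fraction of proteins planted as enriched, in
#'   (0,1); `planted_fraction * n_proteins` must be >= 1.
#' @param effect_log2fc log2 fold change planted into enriched proteins.
#' @param noise_sd residual sd on the log2 scale (> 0).
#' @param batch_sd sd of per-(protein, batch) offsets (>= 0).
#' @param seed integer seed.
#' @param donor_sd sd of per-(protein, donor) intercepts; small by default
#'   because a shared intercept across a donor's samples cancels from
#'   between-condition contrasts but inflates within-group variance.
#' @param enriched_condition condition receiving the planted effect.
#' @param n_batches number of processing batches donors are split into.
#' @param protein_ids optional protein identifiers (e.g. network node
#'   names) to use instead of `"P0001"`-style ids.
#' @param planted_ids optional explicit set of planted protein ids; when
#'   given it overrides random selection (extra random proteins are added
#'   if `planted_fraction` asks for more).
#' @return a list with `matrix` (an [abundance_matrix()]) and `truth`
#'   (a [synthetic_truth()] with `planted_enriched_ids`).
#' @export
generate_abundance <- function(n_proteins, donors, conditions,
                               planted_fraction, effect_log2fc, noise_sd,
                               batch_sd, seed, donor_sd = 0.05,
                               enriched_condition = NULL, n_batches = 3L,
                               protein_ids = NULL, planted_ids = NULL) {
  conditions <- as.character(conditions)
  stopifnot(length(conditions) >= 2, donors >= 3, n_proteins >= 1,
            noise_sd > 0, batch_sd >= 0, donor_sd >= 0,
            planted_fraction > 0, planted_fraction < 1)
  n_planted <- floor(planted_fraction * n_proteins)
  if (n_planted < 1) stop("planted_fraction * n_proteins must be >= 1")
  enriched_condition <- enriched_condition %||% conditions[length(conditions)]
  if (!enriched_condition %in% conditions) stop("unknown enriched condition")
  if (is.null(protein_ids)) {
    protein_ids <- sprintf(paste0("P%0", max(4L, nchar(n_proteins)), "d"),
                           seq_len(n_proteins))
  }
  protein_ids <- as.character(protein_ids)
  stopifnot(length(protein_ids) == n_proteins,
            !anyDuplicated(protein_ids))
  if (!is.null(planted_ids) && !all(planted_ids %in% protein_ids)) {
    stop("planted_ids must be a subset of protein_ids")
  }

  donor_lab <- sprintf("d%02d", seq_len(donors))
  batch_of_donor <- sprintf("batch%d", ((seq_len(donors) - 1L) %% n_batches) + 1L)
  design <- expand.grid(donor = donor_lab, condition = conditions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design$batch <- batch_of_donor[match(design$donor, donor_lab)]
  design$sample_id <- paste(design$donor, design$condition, sep = "_")
  n_samp <- nrow(design)

  res <- with_seed(seed, {
    planted <- if (is.null(planted_ids)) {
      sample(protein_ids, n_planted)
    } else {
      extra <- n_planted - length(planted_ids)
      if (extra > 0) {
        c(planted_ids, sample(setdiff(protein_ids, planted_ids), extra))
      } else planted_ids
    }
    baseline <- rnorm(n_proteins, mean = 25, sd = 2)
    donor_eff <- matrix(rnorm(n_proteins * donors, sd = donor_sd),
                        n_proteins, donors,
                        dimnames = list(protein_ids, donor_lab))
    batches <- unique(design$batch)
    batch_eff <- matrix(rnorm(n_proteins * length(batches), sd = batch_sd),
                        n_proteins, length(batches),
                        dimnames = list(protein_ids, batches))
    log2int <- matrix(baseline, n_proteins, n_samp,
                      dimnames = list(protein_ids, design$sample_id))
    for (j in seq_len(n_samp)) {
      log2int[, j] <- log2int[, j] +
        donor_eff[, design$donor[j]] + batch_eff[, design$batch[j]] +
        rnorm(n_proteins, sd = noise_sd)
      if (design$condition[j] == enriched_condition) {
        log2int[planted, j] <- log2int[planted, j] + effect_log2fc
      }
    }
    upep <- sample(1:10, n_proteins, replace = TRUE)
    list(log2int = log2int, planted = planted, upep = upep)
  })

  meta <- design[, c("sample_id", "donor", "condition", "batch")]
  mat <- abundance_matrix(2^res$log2int, meta,
                          setNames(res$upep, protein_ids))
  list(
    matrix = mat,
    truth = synthetic_truth(
      planted_enriched_ids = sort(res$planted),
      effect_log2fc = effect_log2fc,
      enriched_condition = enriched_condition,
      generator_params = list(n_proteins = n_proteins, donors = donors,
                              conditions = conditions,
                              planted_fraction = planted_fraction,
                              noise_sd = noise_sd, batch_sd = batch_sd,
                              donor_sd = donor_sd, n_batches = n_batches),
      seed = seed
    )
  )
}

#' Plant gene sets at known network proximity
#'
#' Samples a target set T uniformly, then samples a source set S from nodes
#' whose shortest-path distance to the nearest target is at most `radius`.
#' With `radius = 0` the sources are drawn from T itself (so the closest
#' distance is exactly 0); with `radius >= 1` sources are disjoint from T
#' and every source lies within `radius` edges of some target, so the
#' closest-distance statistic is bounded by `radius` by construction.
#'
#' @param network an undirected [igraph::igraph] with named nodes.
#' @param source_size,target_size set sizes; their sum must not exceed the
#'   node count.
#' @param radius maximum planted source-to-target distance (edges, >= 0).
#' @param seed integer seed.
#' @param max_tries target-set redraws attempted before giving up when the
#'   graph cannot host the requested geometry.
#' @return a list with `source`, `target` (character vectors) and `truth`.
#' @export
plant_proximal_sets <- function(network, source_size, target_size, radius,
                                seed, max_tries = 25L) {
  nodes <- igraph::V(network)$name
  stopifnot(source_size >= 1, target_size >= 1, radius >= 0)
  if (source_size + target_size > length(nodes)) {
    stop("source_size + target_size exceeds node count")
  }
  if (radius == 0 && source_size > target_size) {
    stop("radius 0 requires source_size <= target_size (sources come from T)")
  }
  picked <- with_seed(seed, {
    for (try in seq_len(max_tries)) {
      tgt <- sample(nodes, target_size)
      if (radius == 0) {
        return(list(source = sample(tgt, source_size), target = tgt))
      }
      d <- igraph::distances(network, v = tgt)
      mind <- apply(d, 2, min)
      eligible <- setdiff(names(mind)[mind >= 1 & mind <= radius], tgt)
      if (length(eligible) >= source_size) {
        return(list(source = sample(eligible, source_size), target = tgt))
      }
    }
    stop("could not place ", source_size, " sources within radius ", radius,
         " of a ", target_size, "-node target set after ", max_tries,
         " attempts")
  })
  list(
    source = picked$source,
    target = picked$target,
    truth = synthetic_truth(
      planted_source_set = sort(picked$source),
      planted_target_set = sort(picked$target),
      planted_radius = radius,
      generator_params = list(source_size = source_size,
                              target_size = target_size),
      seed = seed
    )
  )
}

#' Write a ground-truth record as JSON
#'
#' @param truth a [synthetic_truth()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
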