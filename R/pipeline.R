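# Orchestration: a declarative run configuration, a study-level synthetic
# generator that wires planted proteins, pathways, and proximal gene sets
# together, and a seeded end-to-end pipeline that writes every intermediate
# artifact with a manifest.

#' Default run configuration
#'
#' Returns the full configuration the pipeline runs on: simulation
#' parameters emulating a 3-condition, 9-donor tissue proteomics design on
#' a 500-node scale-free interactome, and the analysis thresholds
#' (unique-peptide filter, q-value and fold-change gates, hypergeometric
#' significance, Jaccard edge threshold, randomization count). Every field
#' can be overridden via `read_run_config()` or by editing the returned
#' list.
#'
#' @return a named list of class `RunConfig`.
#' @export
default_run_config <- function() {
  structure(list(
    sim = list(
      n_nodes = 500L, edges_per_node = 2L,
      n_pathways = 12L, pathway_size_min = 10L, pathway_size_max = 25L,
      overlap_fraction = 0.2,
      source_size = 20L, target_size = 25L, radius = 1L,
      donors = 9L, conditions = c("NFNC", "F", "C"),
      planted_fraction = 0.1, effect_log2fc = 1.5,
      noise_sd = 0.3, batch_sd = 0.1, donor_sd = 0.05
    ),
    thresholds = list(
      min_unique = 2L, q_max = 0.1, fc_min = 1, p_max = 0.05,
      j_min = 0.1, n_randomizations = 200L, randomize = "S",
      min_bin_size = 10L
    ),
    method = "auto",
    batch_covariate = TRUE,
    reference = "NFNC",
    seed = 1L,
    outdir = "proxikit_run"
  ), class = c("RunConfig", "list"))
}

#' Read / write a run configuration as YAML
#'
#' Fields absent from the file take their [default_run_config()] values;
#' the result is validated. Writing and re-reading a configuration is
#' lossless.
#'
#' @param path YAML file.
#' @return a validated `RunConfig`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) {
    if (nm %in% c("sim", "thresholds") && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param config a `RunConfig`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

validate_run_config <- function(cfg) {
  th <- cfg$thresholds
  stopifnot(th$min_unique >= 1, th$q_max >= 0, th$q_max <= 1,
            th$fc_min >= 0, th$p_max > 0, th$p_max <= 1,
            th$j_min >= 0, th$j_min <= 1, th$n_randomizations >= 1,
            th$randomize %in% c("S", "T", "both"))
  s <- cfg$sim
  stopifnot(s$n_nodes > s$edges_per_node, length(s$conditions) >= 2,
            s$donors >= 3, s$planted_fraction > 0, s$planted_fraction < 1,
            s$noise_sd > 0, s$batch_sd >= 0)
  stopifnot(cfg$reference %in% cfg$sim$conditions,
            cfg$method %in% c("auto", "anova", "kruskal_wallis"))
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Simulate a complete, internally consistent study
#'
#' Generates every input of the analysis chain with aligned ground truth:
#' a scale-free interactome whose nodes double as protein identifiers; a
#' source set S planted within `radius` edges of a target set T; a pathway
#' collection in which one pathway ("PW_PLANTED") is exactly S, alongside
#' random pathways with controlled overlap; and an abundance matrix in
#' which the planted enriched proteins include all of S. Downstream, the
#' differential stage should recover the planted proteins, enrichment
#' should rank PW_PLANTED first, and the proximity test of PW_PLANTED's
#' detected members against T should be significant.
#'
#' @param config a `RunConfig` (see [default_run_config()]).
#' @param seed integer seed; sub-generators derive fixed offsets from it.
#' @return list with `network`, `collection`, `abundance` (an
#'   [abundance_matrix()]), `source`, `target`, and `truth`.
#' @export
simulate_study <- function(config = default_run_config(),
                           seed = config$seed) {
  s <- config$sim
  network <- generate_network(s$n_nodes, s$edges_per_node, seed)
  planted <- plant_proximal_sets(network, s$source_size, s$target_size,
                                 s$radius, seed + 1L)
  nodes <- igraph::V(network)$name
  pw <- generate_pathways(nodes, s$n_pathways - 1L, s$pathway_size_min,
                          s$pathway_size_max, s$overlap_fraction, seed + 2L)
  sets <- c(list(PW_PLANTED = planted$source), unclass(pw$collection))
  collection <- pathway_collection(sets,
    source = c("planted", rep("synthetic", length(pw$collection))))
  ab <- generate_abundance(
    n_proteins = s$n_nodes, donors = s$donors, conditions = s$conditions,
    planted_fraction = s$planted_fraction,
    effect_log2fc = s$effect_log2fc, noise_sd = s$noise_sd,
    batch_sd = s$batch_sd, seed = seed + 3L, donor_sd = s$donor_sd,
    protein_ids = nodes, planted_ids = planted$source
  )
  truth <- synthetic_truth(
    planted_enriched_ids = ab$truth$planted_enriched_ids,
    effect_log2fc = s$effect_log2fc,
    enriched_condition = ab$truth$enriched_condition,
    planted_source_set = planted$truth$planted_source_set,
    planted_target_set = planted$truth$planted_target_set,
    planted_radius = s$radius,
    planted_pathway = "PW_PLANTED",
    generator_params = s,
    seed = seed
  )
  list(network = network, collection = collection, abundance = ab$matrix,
       source = planted$source, target = planted$target, truth = truth)
}

add_artifact <- function(manifest, stage, paths) {
  for (p in paths) {
    manifest$artifacts[[length(manifest$artifacts) + 1L]] <- list(
      file = basename(p), stage = stage,
      md5 = unname(tools::md5sum(p)))
  }
  manifest
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: simulate -> quantify (unique-peptide and
#' complete-case filters) -> differential (omnibus test, q-values, fold
#' changes, enrichment calls) -> pathway enrichment -> crosstalk graph and
#' modules -> interactome proximity of the top enriched pathway's detected
#' members against the target set. Every intermediate artifact is written
#' under `config$outdir` and recorded in `manifest.json` with an MD5 hash;
#' identical configuration and seed reproduce all artifacts byte for byte.
#' A stage that cannot run (e.g. no enriched proteins survive the gates)
#' is skipped and the reason recorded; it does not abort the run.
#'
#' @param config a `RunConfig`.
#' @param outdir output directory (overrides `config$outdir`).
#' @return the manifest (a list with `config`, `artifacts`, per-stage
#'   `summary`, and any `skipped` records), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         outdir = config$outdir) {
  config <- validate_run_config(config)
  th <- config$thresholds
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(outdir, paste0(...))
  cfg_record <- unclass(config)
  cfg_record$outdir <- NULL  # a run is identified by its content, not its path
  manifest <- list(tool = "proxikit",
                   version = as.character(utils::packageVersion("proxikit")),
                   seed = config$seed, config = cfg_record,
                   artifacts = list(), summary = list(), skipped = list())

  # 1. simulate ------------------------------------------------------------
  study <- simulate_study(config, config$seed)
  write_network(study$network, pth("network.tsv"))
  write_gmt(study$collection, pth("pathways.gmt"))
  write_abundance(study$abundance, pth("abundance"))
  write_truth(study$truth, pth("truth.json"))
  manifest <- add_artifact(manifest, "simulate",
    c(pth("network.tsv"), pth("pathways.gmt"), pth("truth.json"),
      paste0(pth("abundance"), c("_matrix.tsv", "_samples.tsv",
                                 "_peptides.tsv"))))

  # 2. quantify ------------------------------------------------------------
  mat <- filter_by_unique_peptides(study$abundance, th$min_unique)
  mat <- filter_complete_cases(mat)
  write_abundance(mat, pth("filtered"))
  manifest$summary$quantify <- list(
    n_proteins_in = nrow(study$abundance$intensities),
    n_proteins_retained = nrow(mat$intensities))
  manifest <- add_artifact(manifest, "quantify",
    paste0(pth("filtered"), c("_matrix.tsv", "_samples.tsv",
                              "_peptides.tsv")))

  # 3. differential --------------------------------------------------------
  diff <- multigroup_test(mat, method = config$method,
                          batch_covariate = config$batch_covariate)
  fc <- fold_changes(mat, config$reference)
  diff <- merge(diff, fc, by = "protein_id", sort = TRUE)
  comparisons <- lapply(setdiff(unique(mat$sample_meta$condition),
                                config$reference),
                        function(cc) c(cc, config$reference))
  enriched <- call_enriched(diff, th$q_max, th$fc_min, comparisons)
  diff$enriched <- diff$protein_id %in% enriched$protein_id
  write_differential(diff, pth("differential.tsv"))
  write_tsv(enriched, pth("enriched_proteins.tsv"))
  manifest$summary$differential <- list(
    n_tested = nrow(diff), n_enriched = nrow(enriched),
    q_max = th$q_max, fc_min = th$fc_min)
  manifest <- add_artifact(manifest, "differential",
    c(pth("differential.tsv"), pth("enriched_proteins.tsv")))

  # 4. pathway enrichment ---------------------------------------------------
  detected <- rownames(mat$intensities)
  universe <- intersect(unique(unlist(study$collection)), detected)
  query <- intersect(enriched$protein_id, universe)
  if (length(query) == 0) {
    manifest$skipped <- c(manifest$skipped, list(list(
      stage = "enrich",
      reason = "no enriched protein falls in the pathway universe")))
    return(finish_manifest(manifest, outdir))
  }
  enr <- enrich_pathways(query, study$collection, universe,
                         p_max = th$p_max)
  write_enrichment(enr, pth("enrichment.tsv"))
  manifest$summary$enrich <- list(
    n_pathways_tested = nrow(enr),
    n_significant = sum(enr$significant),
    top_pathway = enr$pathway[which.min(enr$p_value)])
  manifest <- add_artifact(manifest, "enrich", pth("enrichment.tsv"))

  # 5. crosstalk graph + modules -------------------------------------------
  if (!any(enr$significant)) {
    manifest$skipped <- c(manifest$skipped, list(list(
      stage = "pathway_graph", reason = "no significant pathways")))
    return(finish_manifest(manifest, outdir))
  }
  pg <- build_pathway_graph(enr, study$collection, detected,
                            j_min = th$j_min)
  modules <- detect_modules(pg, seed = config$seed)
  write_pathway_graph(pg, enr, modules, pth("pathway_graph"))
  manifest$summary$pathway_graph <- list(
    n_nodes = igraph::vcount(pg$graph), n_edges = igraph::ecount(pg$graph),
    n_modules = length(unique(modules)))
  manifest <- add_artifact(manifest, "pathway_graph",
    c(pth("pathway_graph.graphml"), pth("pathway_graph_edges.tsv"),
      pth("pathway_graph_nodes.tsv")))

  # 6. proximity ------------------------------------------------------------
  top <- enr$pathway[which.min(enr$p_value)]
  src <- map_to_network(pg$detected_sets[[top]] %||%
                          intersect(study$collection[[top]], detected),
                        study$network)$mapped
  tgt <- map_to_network(study$target, study$network)$mapped
  if (length(src) == 0 || length(tgt) == 0) {
    manifest$skipped <- c(manifest$skipped, list(list(
      stage = "proximity", reason = "source or target set empty on network")))
    return(finish_manifest(manifest, outdir))
  }
  prox <- proximity_test(study$network, src, tgt,
                         n_randomizations = th$n_randomizations,
                         seed = config$seed, randomize = th$randomize,
                         min_bin_size = th$min_bin_size)
  write_proximity(prox, pth("proximity"))
  manifest$summary$proximity <- list(
    source_pathway = top, observed_dc = prox$observed_dc,
    z_score = prox$z_score, empirical_p = prox$empirical_p)
  manifest <- add_artifact(manifest, "proximity",
    c(pth("proximity.json"), pth("proximity_null.tsv")))

  finish_manifest(manifest, outdir)
}

finish_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
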