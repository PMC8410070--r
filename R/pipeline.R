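# End-to-end orchestration: one seeded config drives simulation (or file
# input), QC, clustering, annotation, EC selection, marker discovery,
# cross-atlas similarity, BBB module construction, coexpression and
# anatomic mapping, producing a run manifest with per-stage summaries,
# wall times and content digests of every written file. A single global
# seed fans out to per-stage derived seeds so stages are individually
# reproducible.

#' Default run configuration
#'
#' Returns the configuration `run_full()` executes: either a fully
#' synthetic run (the default) or a run on files supplied under `inputs`.
#' Exactly one of the two must be set per data stream.
#'
#' @param seed global run seed; per-stage seeds are derived from it.
#' @param out_dir output directory.
#' @param atlas a [sim_config()] for the synthetic atlas (its seed is
#'   overridden by the derived stage seed).
#' @param inputs optional named list of input paths: `counts` (list with
#'   `matrix`, `features`, `barcodes`, `meta`), `class_panels` (GMT),
#'   `bulk` (TSV), `disease` (TSV), `regions` (TSV), `vascular_panel`
#'   (GMT), `homolog` (TSV). Streams without a path are simulated.
#' @param params per-stage parameters; see the function body for the full
#'   set and defaults.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("ecatlas_run_"),
                               atlas = sim_config(), inputs = NULL,
                               params = list()) {
  defaults <- list(qc = qc_thresholds(), n_pcs = 20, k_classes = 8,
                   k_ec = atlas$n_ec_subclusters, alpha = 0.05, top_k = 50,
                   mds_dims = 2, min_cpm = 100, min_fold = 2,
                   min_models = 3, min_cells = 1,
                   homolog_drop = 0.1, bulk_extra_brain = 2,
                   disease_extra = 3)
  defaults[names(params)] <- params
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 atlas = atlas, inputs = inputs, params = defaults),
            class = "run_config")
}

#' @noRd
validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  flat <- as.character(unlist(config$inputs))
  missing <- flat[!file.exists(flat)]
  if (!length(flat)) missing <- character()
  if (length(missing))
    stop("config points to missing input file(s): ", fmt_list(missing))
  invisible(config)
}

#' Read a run configuration from YAML
#'
#' Top-level keys `seed`, `out_dir`, `inputs`, `params` and `atlas`
#' (arguments to [sim_config()]) override the defaults of
#' [default_run_config()].
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  atlas <- if (!is.null(y$atlas)) do.call(sim_config, y$atlas) else sim_config()
  default_run_config(seed = y$seed %||% 1,
                     out_dir = y$out_dir %||% tempfile("ecatlas_run_"),
                     atlas = atlas, inputs = y$inputs,
                     params = y$params %||% list())
}

#' Run the full atlas pipeline
#'
#' Executes all stages in dependency order (simulate/read -> QC ->
#' normalize -> cluster -> annotate -> EC selection -> EC subclustering ->
#' markers -> Jaccard/MDS -> EC enrichment and core/periphery split ->
#' core and dysfunction modules -> homolog mapping -> detection restriction
#' -> module coexpression -> anatomic mapping), writing every result under
#' `config$out_dir` and returning a manifest. Identical config and seed
#' give identical digests for every output file. When the run is synthetic
#' the manifest also carries recovery metrics against the planted truth
#' (ARI, marker precision/recall, EC-enrichment F1, module Jaccards,
#' coexpression means, anatomic argmax accuracy).
#'
#' @param config a [default_run_config()] / [read_run_config()] result.
#' @return List of class `run_result` with `manifest` and `results` (the
#'   in-memory stage outputs). A stage failure aborts with the stage name;
#'   the partial manifest is still written.
#' @export
run_full <- function(config = default_run_config()) {
  validate_run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- config$params
  seed <- config$seed
  manifest <- list(schema_version = "1.0", tool = "ecatlas",
                   version = as.character(utils::packageVersion("ecatlas")),
                   seed = seed, stages = list(), files = list(),
                   metrics = list())
  results <- list()
  current_stage <- NULL
  add_file <- function(path) {
    manifest$files[[basename(path)]] <<- file_digest(path)
  }
  run_stage <- function(name, expr) {
    current_stage <<- name
    t <- system.time(value <- force(expr))
    manifest$stages[[name]] <<- list(wall_time_s = unname(t[["elapsed"]]))
    value
  }
  on.exit({
    write_manifest(manifest, file.path(out_dir, "run_manifest.json"))
  })
  tryCatch({

  # --- atlas input ---------------------------------------------------------
  synthetic <- is.null(config$inputs$counts)
  atlas <- run_stage("atlas_input", {
    if (synthetic) {
      cfg <- config$atlas
      cfg$seed <- stage_seed(seed, "atlas")
      sim <- simulate_atlas(cfg)
      write_counts(sim$counts, file.path(out_dir, "atlas"))
      write_gene_sets(sim$class_panels, file.path(out_dir, "class_panels.gmt"))
      write_manifest(sim$truth, file.path(out_dir, "truth_atlas.json"))
      sim
    } else {
      cp <- config$inputs$counts
      list(counts = read_counts(cp$matrix, cp$features, cp$barcodes, cp$meta),
           truth = NULL,
           class_panels = read_gene_sets(config$inputs$class_panels))
    }
  })
  truth <- atlas$truth

  # --- QC + normalization --------------------------------------------------
  qc <- run_stage("qc", qc_filter(atlas$counts, p$qc))
  write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"))
  add_file(file.path(out_dir, "qc_report.tsv"))
  manifest$metrics$cells_in <- length(atlas$counts$barcodes)
  manifest$metrics$cells_removed_qc <- nrow(qc$report)
  nm <- run_stage("normalize", normalize_counts(qc$counts, p$qc))

  # --- class-level clustering, annotation, EC selection --------------------
  cl_all <- run_stage("cluster_classes",
                      cluster_cells(nm, n_pcs = p$n_pcs, k = p$k_classes,
                                    seed = stage_seed(seed, "cluster_classes")))
  ann <- run_stage("annotate", annotate_clusters(nm, cl_all,
                                                 atlas$class_panels))
  sel <- run_stage("select_ecs",
                   select_ecs(nm, cl_all, ann, atlas$class_panels))
  write_tsv(sel$report, file.path(out_dir, "doublet_report.tsv"))
  add_file(file.path(out_dir, "doublet_report.tsv"))
  manifest$metrics$clusters_found <- cl_all$n_clusters
  manifest$metrics$ec_cells <- length(sel$nm_ec$barcodes)
  manifest$metrics$doublets_flagged <- nrow(sel$report)

  # --- EC subclustering + markers ------------------------------------------
  nm_ec <- sel$nm_ec
  cl_ec <- run_stage("cluster_ec",
                     cluster_cells(nm_ec, n_pcs = p$n_pcs, k = p$k_ec,
                                   seed = stage_seed(seed, "cluster_ec")))
  manifest$metrics$ec_subclusters_found <- cl_ec$n_clusters
  mt <- run_stage("markers", find_all_markers(nm_ec, cl_ec, alpha = p$alpha))
  write_tsv(as.data.frame(mt), file.path(out_dir, "marker_table.tsv"))
  add_file(file.path(out_dir, "marker_table.tsv"))
  tops <- top_k_markers(mt, k = p$top_k)
  names(tops) <- paste0("GBM.EC", names(tops))
  write_gene_sets(tops, file.path(out_dir, "top_markers.gmt"))
  add_file(file.path(out_dir, "top_markers.gmt"))

  # --- cross-atlas similarity ----------------------------------------------
  sim_mat <- run_stage("similarity", jaccard_matrix(tops))
  emb <- classical_mds(sim_mat, dims = p$mds_dims)
  write_matrix_tsv(sim_mat$J, file.path(out_dir, "jaccard_matrix.tsv"),
                   id_col = "cluster")
  write_matrix_tsv(emb$coordinates, file.path(out_dir, "mds_coordinates.tsv"),
                   id_col = "cluster")
  add_file(file.path(out_dir, "jaccard_matrix.tsv"))
  add_file(file.path(out_dir, "mds_coordinates.tsv"))

  # --- EC enrichment + core/periphery split --------------------------------
  ec_set <- run_stage("ec_enrichment",
                      ec_enriched_genes(nm, cl_all, ann, alpha = p$alpha))
  manifest$metrics$ec_enriched_genes <- length(ec_set$genes)
  diff <- run_stage("differential",
                    differential_ec_genes(nm_ec, ec_set, alpha = p$alpha))
  manifest$metrics$up_in_core <-
    length(if (is.null(diff$up_in_core)) character() else diff$up_in_core$genes)
  manifest$metrics$down_in_core <-
    length(if (is.null(diff$down_in_core)) character() else
      diff$down_in_core$genes)

  # --- BBB modules ---------------------------------------------------------
  bulk <- run_stage("bulk_input", {
    if (!is.null(config$inputs$bulk))
      list(panel = read_bulk_panel(config$inputs$bulk), truth = NULL)
    else {
      brain_genes <- c(mouse_case(truth$bbb_core_genes),
                       sprintf("Bulkonly%02d", seq_len(p$bulk_extra_brain)))
      simulate_bulk_organ_panel(brain_enriched = brain_genes,
                                seed = stage_seed(seed, "bulk"))
    }
  })
  core_raw <- run_stage("core_module",
                        build_core_module(bulk$panel, min_cpm = p$min_cpm,
                                          min_fold = p$min_fold,
                                          alpha = p$alpha))
  disease <- run_stage("disease_input", {
    if (!is.null(config$inputs$disease))
      list(table = read_disease_table(config$inputs$disease), truth = NULL)
    else {
      set.seed(stage_seed(seed, "disease_plant"))
      planted <- c(setNames(sample(3:4, length(truth$bbb_dysf_genes), TRUE),
                            mouse_case(truth$bbb_dysf_genes)),
                   setNames(rep(3, p$disease_extra),
                            sprintf("Dysfonly%02d", seq_len(p$disease_extra))))
      simulate_disease_models(planted,
                              background_genes =
                                sprintf("Dbg%03d", seq_len(50)),
                              seed = stage_seed(seed, "disease"))
    }
  })
  dysf_raw <- run_stage("dysfunction_module",
                        build_dysfunction_module(disease$table,
                                                 min_models = p$min_models))
  hm <- run_stage("homolog_map", {
    if (!is.null(config$inputs$homolog))
      list(map = read_homolog_map(config$inputs$homolog), dropped = NULL)
    else simulate_homolog_map(unique(c(core_raw$genes, dysf_raw$genes)),
                              drop_fraction = p$homolog_drop,
                              seed = stage_seed(seed, "homolog"))
  })
  core_mod <- restrict_to_detected(map_homologs(core_raw, hm$map), nm_ec,
                                   min_cells = p$min_cells)
  dysf_mod <- restrict_to_detected(map_homologs(dysf_raw, hm$map), nm_ec,
                                   min_cells = p$min_cells)
  write_module(core_mod, file.path(out_dir, "bbb_core_module.gmt"))
  write_module(dysf_mod, file.path(out_dir, "bbb_dysfunction_module.gmt"))
  add_file(file.path(out_dir, "bbb_core_module.gmt"))
  add_file(file.path(out_dir, "bbb_dysfunction_module.gmt"))
  manifest$metrics$core_module_sizes <-
    setNames(lapply(core_mod$provenance, function(s) length(s$genes)),
             vapply(core_mod$provenance, `[[`, character(1), "stage"))
  manifest$metrics$dysfunction_module_sizes <-
    setNames(lapply(dysf_mod$provenance, function(s) length(s$genes)),
             vapply(dysf_mod$provenance, `[[`, character(1), "stage"))
  coexpr <- run_stage("coexpression",
                      module_coexpression(nm_ec, core_mod, dysf_mod))
  manifest$metrics$coexpression <- list(
    mean_within_core = coexpr$mean_within_core,
    mean_within_dysf = coexpr$mean_within_dysf,
    mean_cross = coexpr$mean_cross)

  # --- anatomic mapping ----------------------------------------------------
  regions <- run_stage("regions_input", {
    if (!is.null(config$inputs$regions))
      list(panel = read_region_panel(config$inputs$regions),
           vascular_panel =
             read_gene_sets(config$inputs$vascular_panel)[[1]],
           truth = NULL)
    else {
      planted_sets <- lapply(names(truth$planted_markers), function(nm_)
        gene_set(nm_, truth$planted_markers[[nm_]]))
      simulate_anatomic_regions(planted_sets,
                                seed = stage_seed(seed, "regions"))
    }
  })
  scores <- run_stage("anatomic",
                      microvascular_score(regions$panel,
                                          regions$vascular_panel))
  panel_norm <- normalize_by_score(regions$panel, scores)
  enrich <- region_enrichment_profile(panel_norm, tops)
  write_matrix_tsv(enrich$values, file.path(out_dir, "region_enrichment.tsv"),
                   id_col = "marker_set")
  add_file(file.path(out_dir, "region_enrichment.tsv"))

  # --- recovery metrics against planted truth ------------------------------
  if (synthetic) {
    manifest$metrics$recovery <- run_stage("recovery", {
      recovery_metrics(truth, nm, nm_ec, cl_ec, tops, ec_set, diff,
                       core_raw, core_mod, bulk$truth,
                       dysf_raw, disease$truth,
                       enrich, regions$truth, scores)
    })
  }
  results <- list(atlas = atlas, qc = qc, nm = nm, clusters = cl_all,
                  annotation = ann, selection = sel, nm_ec = nm_ec,
                  clusters_ec = cl_ec, markers = mt, top_markers = tops,
                  similarity = sim_mat, embedding = emb,
                  ec_enriched = ec_set, differential = diff,
                  core_module = core_mod, dysfunction_module = dysf_mod,
                  coexpression = coexpr, scores = scores,
                  enrichment = enrich)
  }, error = function(e) {
    stop("pipeline stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  structure(list(manifest = manifest, results = results),
            class = "run_result")
}

#' @noRd
mouse_case <- function(x) {
  paste0(substr(x, 1, 1), tolower(substring(x, 2)))
}

# Map each planted EC subcluster to the found cluster with the largest cell
# overlap, then score marker recovery, EC-enrichment, differential splits,
# module construction, coexpression and anatomic localization against the
# truth manifest.
#' @noRd
recovery_metrics <- function(truth, nm, nm_ec, cl_ec, tops, ec_set, diff,
                             core_raw, core_mod, bulk_truth,
                             dysf_raw, disease_truth,
                             enrich, region_truth, scores) {
  out <- list()
  truth_sub <- truth$ec_subcluster[nm_ec$barcodes]
  usable <- !is.na(truth_sub)
  found <- cl_ec$labels[usable]
  out$ari_ec_subclusters <-
    unname(mclust::adjustedRandIndex(found, truth_sub[usable]))

  tab <- table(found, truth_sub[usable])
  planted_names <- colnames(tab)
  best_found <- rownames(tab)[apply(tab, 2, which.max)]
  prec <- rec <- setNames(numeric(length(planted_names)), planted_names)
  for (i in seq_along(planted_names)) {
    pl <- planted_names[i]
    fs <- tops[[paste0("GBM.EC", best_found[i])]]
    found_genes <- if (is.null(fs)) character() else fs$genes$genes
    planted_genes <- truth$planted_markers[[pl]]
    hit <- length(intersect(found_genes, planted_genes))
    prec[pl] <- if (length(found_genes)) hit / length(found_genes) else 0
    rec[pl] <- hit / length(planted_genes)
  }
  out$marker_precision <- as.list(prec)
  out$marker_recall <- as.list(rec)
  out$marker_precision_min <- min(prec)
  out$marker_recall_min <- min(rec)

  truth_ec <- truth$ec_program_genes
  found_ec <- ec_set$genes
  tp <- length(intersect(found_ec, truth_ec))
  precision <- if (length(found_ec)) tp / length(found_ec) else 0
  recall <- tp / length(truth_ec)
  out$ec_enriched_f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  out$ec_enriched_precision <- precision
  out$ec_enriched_recall <- recall

  up <- if (is.null(diff$up_in_core)) character() else diff$up_in_core$genes
  down <- if (is.null(diff$down_in_core)) character() else
    diff$down_in_core$genes
  correct <- sum(truth$core_up_genes %in% up) +
    sum(truth$core_down_genes %in% down)
  wrong_side <- sum(truth$core_up_genes %in% down) +
    sum(truth$core_down_genes %in% up)
  out$differential_partition_accuracy <-
    correct / (length(truth$core_up_genes) + length(truth$core_down_genes))
  out$differential_wrong_side <- wrong_side

  if (!is.null(bulk_truth)) {
    out$core_module_jaccard_raw <-
      jaccard(core_raw$genes, bulk_truth$brain_enriched_genes)
    decoys <- unlist(bulk_truth$decoys, use.names = FALSE)
    out$core_module_decoys_rejected <-
      sum(!decoys %in% core_raw$genes) / length(decoys)
  }
  if (!is.null(disease_truth))
    out$dysfunction_module_jaccard <-
      jaccard(dysf_raw$genes, disease_truth$dysfunction_genes)

  if (!is.null(region_truth)) {
    out$vascular_score_cor <-
      unname(cor(scores[names(region_truth$vascular_factor)],
                 region_truth$vascular_factor))
    # map each found marker set to its planted subcluster's home region
    argmax <- colnames(enrich$values)[apply(enrich$values, 1, which.max)]
    names(argmax) <- rownames(enrich$values)
    hits <- 0; total <- 0
    for (i in seq_along(planted_names)) {
      fs_name <- as.character(best_found[i])
      if (fs_name %in% names(argmax)) {
        total <- total + 1
        home <- region_truth$home_regions[[planted_names[i]]]
        if (identical(argmax[[fs_name]], home)) hits <- hits + 1
      }
    }
    out$region_argmax_accuracy <- if (total) hits / total else NA_real_
  }
  out
}
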