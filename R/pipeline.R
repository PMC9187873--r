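#' Workflow configuration
#'
#' All stage parameters with their standard defaults: `k_max` 30, pruning
#' threshold 0.6, clustering resolution 1, DE alpha 0.01, minimum mean
#' expression 0.5 counts per cell, 500 permutations, nu grid
#' (0.25, 0.5, 0.75), kill threshold -90%, consistency threshold -80%,
#' minimum 3 replicates.
#'
#' @param ... overrides of any default.
#' @return object of class `run_config` (a named list); unknown names are
#'   rejected.
#' @export
run_config <- function(...) {
  defaults <- list(
    qc_preset = "mcf7", mito_prefix = "MT-",
    n_components = 15, n_soft_clusters = 10, theta = 2,
    batch_correct = TRUE,
    k_max = 30, prune_threshold = 0.6, resolution = 1, n_neighbors = 30,
    merge_threshold = 0.95, prune_order = "cluster_first",
    alpha = 0.01, min_expression = 0.5,
    smode = TRUE, n_mixtures = 150, cells_per_mixture = 1000,
    nu_grid = c(0.25, 0.5, 0.75), nperm = 500,
    kill_threshold = -90, consistency_threshold = -80, min_replicates = 3,
    strict_consistency = FALSE,
    seed = 1)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  .assert(length(unknown) == 0L, "run_config: unknown parameter(s): %s",
          paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "run_config")
}

#' Run the full workflow on in-memory inputs
#'
#' Executes subpopulation learning (PCA embedding, optional batch
#' correction, multi-level archetypal analysis, pruning, Leiden
#' clustering), signature construction, deconvolution of the screen bulk
#' (with S-mode adjustment), susceptibility scoring and the greedy
#' cocktail search, writing every intermediate artifact as annotated TSV.
#' Stages whose artifact already exists are skipped when `resume = TRUE`,
#' making reruns idempotent.
#'
#' @param cells a [cell_matrix()] of raw single-cell counts (QC-filtered
#'   or not; QC runs first).
#' @param bulk a linear-scale [bulk_matrix()] of the screen samples.
#' @param meta a [sample_meta()] table for `bulk`.
#' @param config a [run_config()].
#' @param out_dir artifact directory (created if needed).
#' @param batch optional batch label per cell (defaults to the metadata
#'   `batch` column, with clone and phase columns concatenated when
#'   present, e.g. `"WT3_S"`).
#' @param resume skip stages whose artifact already exists.
#' @return list of the in-memory stage results: `model`, `signature`,
#'   `compositions`, `susceptibility`, `cocktail`, plus `manifest`.
#' @export
run_workflow <- function(cells, bulk, meta, config = run_config(),
                         out_dir = tempfile("subpopscreen_run_"),
                         batch = NULL, resume = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- unclass(config)
  hash <- .config_hash(params)
  logmsg <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  artifact <- function(name) file.path(out_dir, name)

  # -- preprocess ---------------------------------------------------------
  logmsg("preprocess", "QC filtering %d cells (preset %s)",
         length(cells$cell_ids), config$qc_preset)
  cells_qc <- qc_filter(cells, qc_preset(config$qc_preset),
                        mito_prefix = config$mito_prefix)
  if (is.null(batch)) {
    cm <- cells_qc$cell_meta
    parts <- cm[, intersect(c("clone", "batch", "phase"), names(cm)), drop = FALSE]
    batch <- if (ncol(parts)) do.call(paste, c(parts, sep = "_"))
             else rep("all", nrow(cm))
  } else {
    batch <- batch[match(cells_qc$cell_ids, cells$cell_ids)]
  }
  emb <- embed_pca(cells_qc, n_components = config$n_components)
  if (config$batch_correct && length(unique(batch)) > 1L) {
    logmsg("preprocess", "batch correction over %d batches", length(unique(batch)))
    emb <- correct_batches(emb, batch,
                           n_soft_clusters = config$n_soft_clusters,
                           theta = config$theta, seed = config$seed)
  }

  # -- archetypes ---------------------------------------------------------
  logmsg("learn", "archetypal analysis, k_max = %d", config$k_max)
  model <- fit_archetypes(emb, k_max = config$k_max,
                          merge_threshold = config$merge_threshold,
                          seed = config$seed)
  if (config$prune_order == "prune_first") {
    model <- prune_ambiguous_cells(model, config$prune_threshold)
    model <- cluster_subpopulations(model, n_neighbors = config$n_neighbors,
                                    resolution = config$resolution,
                                    seed = config$seed)
  } else {
    # ambiguous cells bridge the footprint patterns of one biological
    # subpopulation; clustering with them present and pruning afterwards
    # keeps those communities whole
    model <- cluster_subpopulations(model, n_neighbors = config$n_neighbors,
                                    resolution = config$resolution,
                                    seed = config$seed)
    model <- prune_ambiguous_cells(model, config$prune_threshold)
  }
  labels <- paste0("sp", model$subpop)
  utils::write.table(
    data.frame(cell_id = model$cell_ids, subpop = labels,
               confidence = model$confidence),
    artifact("subpopulations.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  # -- signature ----------------------------------------------------------
  sig_path <- artifact("signature.tsv")
  cells_lab <- cell_matrix(cells_qc$counts[, model$cell_ids, drop = FALSE],
                           cell_meta = cells_qc$cell_meta[
                             match(model$cell_ids, cells_qc$cell_ids), , drop = FALSE])
  if (resume && file.exists(sig_path)) {
    logmsg("signature", "resuming from %s", sig_path)
    sig <- read_results(sig_path)
  } else {
    logmsg("signature", "Wilcoxon DE at alpha %g over %d subpopulations",
           config$alpha, length(unique(labels)))
    de <- wilcoxon_de(cells_lab, labels, alpha = config$alpha)
    sig <- build_signature(cells_lab, labels, de,
                           min_expression = config$min_expression)
    write_results(sig, sig_path, params = params)
  }

  # -- deconvolution ------------------------------------------------------
  comp_path <- artifact("compositions.tsv")
  if (resume && file.exists(comp_path)) {
    logmsg("deconvolve", "resuming from %s", comp_path)
    comp <- read_results(comp_path)
  } else {
    sig_used <- sig
    if (config$smode) {
      logmsg("deconvolve", "S-mode adjustment with %d artificial mixtures",
             config$n_mixtures)
      art <- make_artificial_mixtures(cells_lab, labels,
                                      n_mixtures = config$n_mixtures,
                                      cells_per_mixture = config$cells_per_mixture,
                                      seed = config$seed)
      sig_used <- smode_adjust(sig, art, bulk)
    }
    logmsg("deconvolve", "nu-SVR over %d samples", length(bulk$sample_ids))
    comp <- deconvolve(bulk, sig_used, nu_grid = config$nu_grid,
                       n_perm = config$nperm, seed = config$seed)
    write_results(comp, comp_path, params = params)
  }

  # -- perturbation -------------------------------------------------------
  logmsg("perturb", "susceptibility table (>= %d replicates)",
         config$min_replicates)
  susc <- build_susceptibility_table(comp, meta,
                                     kill_threshold = config$kill_threshold,
                                     min_replicates = config$min_replicates)
  write_results(susc, artifact("susceptibility.tsv"), params = params)

  # -- cocktail -----------------------------------------------------------
  logmsg("cocktail", "greedy search (kill < %g, consistency <= %g)",
         config$kill_threshold, config$consistency_threshold)
  ctl <- greedy_cocktail(susc, kill_threshold = config$kill_threshold,
                         consistency_threshold = config$consistency_threshold,
                         strict_consistency = config$strict_consistency)
  write_results(ctl, artifact("cocktail.tsv"), params = params)

  manifest <- list(package = "subpopscreen",
                   version = as.character(utils::packageVersion("subpopscreen")),
                   config = params, config_hash = hash,
                   n_cells_in = length(cells$cell_ids),
                   n_cells_used = length(model$cell_ids),
                   n_subpops = length(unique(model$subpop)),
                   n_archetypes = ncol(model$archetypes),
                   n_samples = length(bulk$sample_ids))
  jsonlite::write_json(manifest, artifact("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(model = model, signature = sig, compositions = comp,
                 susceptibility = susc, cocktail = ctl, manifest = manifest,
                 out_dir = out_dir))
}
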