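#' Default analysis configuration
#'
#' Thresholds and counts default to the pipeline's standard operating values:
#' DA significance 0.05, edge weight 0.01, absolute correlation 0.5, module
#' size 5, 1000 permutations, 10 inference runs, 100 label shuffles, 10 ICs.
#'
#' @param ... overrides of any default entry.
#' @return list of class `analysis_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    da_p = 0.05, edge_w = 0.01, edge_cor = 0.5, module_min_size = 5,
    n_perm = 1000, n_runs = 10, n_shuffles = 100, n_ics = 10,
    n_trees = 1000, tree_method = "rf", min_targets = 5, seed = 1L,
    simulation = list()
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- c("analysis_config", "list")
  validate_config(cfg)
}

#' Validate a configuration (YAML path or list)
#'
#' Fills defaults for missing entries, warns on unknown keys, and reports all
#' range violations together.
#'
#' @param config a YAML file path, a list, or an `analysis_config`.
#' @return validated `analysis_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  base <- list(
    da_p = 0.05, edge_w = 0.01, edge_cor = 0.5, module_min_size = 5,
    n_perm = 1000, n_runs = 10, n_shuffles = 100, n_ics = 10,
    n_trees = 1000, tree_method = "rf", min_targets = 5, seed = 1L,
    simulation = list()
  )
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    warning("unknown config keys ignored: ", paste(unknown, collapse = ", "))
  cfg <- base
  known <- intersect(names(config), names(base))
  cfg[known] <- config[known]
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$da_p > 0 && cfg$da_p <= 1, "da_p must lie in (0, 1]")
  chk(cfg$edge_w >= 0 && cfg$edge_w <= 1, "edge_w must lie in [0, 1]")
  chk(cfg$edge_cor >= 0 && cfg$edge_cor <= 1, "edge_cor must lie in [0, 1]")
  chk(cfg$module_min_size >= 1, "module_min_size must be >= 1")
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(cfg$n_runs >= 1, "n_runs must be >= 1")
  chk(cfg$n_shuffles >= 1, "n_shuffles must be >= 1")
  chk(cfg$n_ics >= 1, "n_ics must be >= 1")
  chk(cfg$tree_method %in% c("rf", "et"), "tree_method must be 'rf' or 'et'")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed is mandatory")
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  class(cfg) <- c("analysis_config", "list")
  cfg
}

#' Run the full pipeline on a synthetic dataset
#'
#' Orchestrates simulate -> preprocess -> activity -> DA selection ->
#' per-condition tree-ensemble inference (n_runs, stability intersection) ->
#' differential-activity correlation networks -> consensus -> topology
#' statistics -> ICA, writing every artefact to `out_dir` together with a
#' reproducibility manifest (config snapshot, seeds, per-file md5 hashes).
#' Every random draw derives from `config$seed` via named substreams, so two
#' runs with the same config produce identical manifests.
#'
#' @param config an `analysis_config` (see [default_config()]); its
#'   `simulation` entry holds [sim_config()] overrides.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @return list with all intermediate and final objects plus `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  seed <- as.integer(config$seed)
  scfg <- do.call(sim_config, c(config$simulation, list(seed = seed)))

  ds <- simulate_dataset(scfg)
  counts <- filter_genes(ds$counts)
  sf <- size_factors(counts)
  norm <- normalise_counts(counts, sf)
  std <- standardise_genes(norm)
  act <- activity_matrix(std, ds$regulons$regulon,
                         min_targets = config$min_targets)

  da <- differential_activity_all(norm, ds$design, ds$regulons$regulon,
                                  alpha = config$da_p,
                                  n_perm = config$n_perm,
                                  min_targets = config$min_targets,
                                  seed = substream(seed, 2L))
  da_set <- select_da_tfs(da, alpha = config$da_p)
  act_da <- act[intersect(rownames(act), da_set$tf), , drop = FALSE]
  decay <- estimate_decay(act_da, ds$design)

  infer_cond <- function(cond, off) {
    runs <- lapply(seq_len(config$n_runs), function(r)
      fit_dyn_network(act_da, ds$design, cond, decay$pooled,
                      n_trees = config$n_trees,
                      method = config$tree_method,
                      seed = substream(seed, off + r)))
    stability_intersect(runs, w_min = config$edge_w)
  }
  net_auto <- infer_cond("autologous", 3000L)
  net_mono <- infer_cond("monoculture", 4000L)
  directed <- merge_conditions(net_auto, net_mono)

  corr_auto <- diff_corr_network(da, "autologous", cor_min = config$edge_cor,
                                 alpha = config$da_p)
  corr_mono <- diff_corr_network(da, "monoculture", cor_min = config$edge_cor,
                                 alpha = config$da_p)
  corr <- merge_corr_conditions(corr_auto, corr_mono)
  consensus <- consensus_network(directed, corr)

  annotations <- annotate_nodes(da_set)
  stats_out <- NULL
  if (nrow(consensus)) {
    betw <- betweenness_table(consensus, annotations)
    feats <- c(condition = "condition_tag", patient = "patient_tag",
               time = "time_tag")
    assort <- lapply(seq_along(feats), function(i) {
      labs <- stats::setNames(annotations[[feats[i]]], annotations$name)
      nodes <- unique(c(consensus$regulator, consensus$target))
      res <- tryCatch(
        assortativity_ztest(consensus, labs[nodes],
                            n_shuffles = config$n_shuffles,
                            seed = substream(seed, 5000L + i)),
        error = function(e) list(r = NA_real_, null_mean = NA_real_,
                                 null_sd = NA_real_, z = NA_real_,
                                 n_shuffles = config$n_shuffles))
      c(list(feature = names(feats)[i]), res)
    })
    modules <- ecc_communities(consensus, min_size = config$module_min_size)
    stats_out <- list(betweenness = betw, assortativity = assort,
                      modules = modules,
                      module_features = module_feature_table(modules,
                                                             annotations))
  }

  logn <- log2(norm + 1)
  k <- min(config$n_ics, dim(logn) - 1L)
  ica <- ica_decompose(logn, k = k, seed = substream(seed, 6000L))
  pves <- pve_report(logn, ica)

  res <- list(config = config, sim_config = scfg, dataset = ds,
              counts_filtered = counts, size_factors = sf,
              normalised = norm, activity = act, diff_activity = da,
              da_tfs = da_set, decay = decay,
              net_autologous = net_auto, net_monoculture = net_mono,
              directed = directed, correlation = corr,
              consensus = consensus, annotations = annotations,
              network_stats = stats_out, ica = ica, pve = pves,
              recovery = evaluate_recovery(consensus, ds$truth_net))

  if (!is.null(out_dir)) {
    res$manifest <- write_artefacts(res, out_dir)
  }
  res
}

# serialise pipeline artefacts and build the manifest
write_artefacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  num_tsv <- function(df, f) {
    out <- df
    for (j in seq_along(out))
      if (is.numeric(out[[j]]))
        out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
    utils::write.table(out, fp(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_expression(res$counts_filtered, fp("counts_filtered.tsv"),
                   design = res$dataset$design, design_path = fp("design.tsv"))
  write_expression(res$normalised, fp("normalised.tsv"))
  write_expression(res$activity, fp("activity.tsv"))
  num_tsv(data.frame(sample_id = names(res$size_factors),
                     size_factor = res$size_factors), "size_factors.tsv")
  num_tsv(res$diff_activity, "diff_activity.tsv")
  num_tsv(res$da_tfs, "da_tfs.tsv")
  cons <- res$consensus
  edge_out <- data.frame(source = cons$regulator, target = cons$target,
                         weight = cons$weight, sign = cons$sign,
                         correlation = cons$cor,
                         provenance = cons$conditions)
  write_network(edge_out, fp("consensus.tsv"), "tsv")
  write_network(edge_out, fp("consensus.graphml"), "graphml",
                directed = TRUE, node_attrs = res$annotations)
  if (!is.null(res$network_stats)) {
    num_tsv(res$network_stats$betweenness, "betweenness.tsv")
    jsonlite::write_json(res$network_stats$assortativity,
                         fp("assortativity.json"), auto_unbox = TRUE,
                         digits = NA)
    memb <- res$network_stats$modules$membership
    num_tsv(data.frame(name = names(memb), module = as.integer(memb)),
            "modules.tsv")
  }
  num_tsv(res$pve, "pve.tsv")
  files <- sort(list.files(out_dir, full.names = TRUE))
  manifest <- list(
    config = unclass(res$config)[setdiff(names(res$config), "simulation")],
    simulation = unclass(res$sim_config),
    seed = res$config$seed,
    hashes = as.list(stats::setNames(unname(tools::md5sum(files)),
                                     basename(files)))
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest
}
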