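#' Pipeline configuration
#'
#' Assembles and validates the knobs of the full pipeline. Either pass a
#' YAML file path (keys as the arguments below) or arguments directly;
#' values from the file take precedence over argument defaults.
#'
#' @param config_file optional YAML file.
#' @param out_dir output directory (created if absent).
#' @param stages subset of \code{simulate, de, enrich, compare, gem}, run
#'   in dependency order.
#' @param alpha FDR cutoff used throughout.
#' @param min_set_size gene-set size filter.
#' @param objective_fraction MADE/FVA functionality fraction f.
#' @param eps FVA capacity-change tolerance.
#' @param w_max DE-weight cap.
#' @param seed RNG seed for the simulation stage.
#' @param sim named list of \code{\link{sim_config}} overrides.
#' @param model_path path to a model JSON for the gem stage; default uses
#'   the built-in toy network.
#' @param reference_path optional enrichment-direction reference TSV.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config_file = NULL, out_dir = "fibroprog_out",
                            stages = c("simulate", "de", "enrich",
                                       "compare", "gem"),
                            alpha = 0.05, min_set_size = 5L,
                            objective_fraction = 0.3, eps = 1e-6,
                            w_max = 10, seed = 1L, sim = list(),
                            model_path = NULL, reference_path = NULL) {
  cfg <- list(out_dir = out_dir, stages = stages, alpha = alpha,
              min_set_size = min_set_size,
              objective_fraction = objective_fraction, eps = eps,
              w_max = w_max, seed = seed, sim = sim,
              model_path = model_path, reference_path = reference_path)
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      stop("pipeline_config: config file not found: ", config_file)
    fromfile <- yaml::read_yaml(config_file)
    bad <- setdiff(names(fromfile), names(cfg))
    if (length(bad))
      stop("pipeline_config: unknown key(s) in config file: ",
           paste(bad, collapse = ", "))
    for (k in names(fromfile)) cfg[[k]] <- fromfile[[k]]
  }
  known <- c("simulate", "de", "enrich", "compare", "gem")
  bad <- setdiff(cfg$stages, known)
  if (length(bad))
    stop("pipeline_config: unknown stage(s): ", paste(bad, collapse = ", "))
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("pipeline_config: alpha must be in (0, 1)")
  if (!is.null(cfg$model_path) && !file.exists(cfg$model_path))
    stop("pipeline_config: model file not found: ", cfg$model_path)
  if (!is.null(cfg$reference_path) && !file.exists(cfg$reference_path))
    stop("pipeline_config: reference file not found: ", cfg$reference_path)
  structure(cfg, class = "pipeline_config")
}

#' Run the cross-model analysis pipeline
#'
#' Executes the requested stages in dependency order on simulated
#' studies: differential expression per model, gene-set enrichment,
#' cross-model comparison (Venn, similarity matrices, clustering of the
#' common program) and metabolic integration. All outputs are TSV files
#' with \code{#}-prefixed metadata lines, plus a JSON run manifest;
#' outputs are deterministic given the seed.
#'
#' @param config a \code{\link{pipeline_config}} (or arguments for one).
#' @param ... passed to \code{\link{pipeline_config}} when \code{config}
#'   is NULL.
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = NULL, ...) {
  if (is.null(config)) config <- pipeline_config(...)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, paste0(...))
  meta <- list(package = "fibroprog",
               version = as.character(utils::packageVersion("fibroprog")),
               seed = config$seed, alpha = config$alpha)
  res <- list()

  scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  sim <- simulate_studies(scfg)
  res$truth <- sim$truth
  res$studies <- sim$studies
  if ("simulate" %in% config$stages) {
    for (m in names(sim$studies))
      write_expression_tsv(sim$studies[[m]],
                           outfile("expression_", m, ".tsv"),
                           outfile("samples_", m, ".tsv"))
    write_truth_json(sim$truth, outfile("ground_truth.json"))
  }

  need_de <- any(c("de", "enrich", "compare", "gem") %in% config$stages)
  if (need_de) {
    res$de <- lapply(sim$studies, run_de, alpha = config$alpha)
    if ("de" %in% config$stages) {
      for (m in names(res$de)) {
        d <- res$de[[m]]
        write_tsv_with_meta(
          data.frame(gene_id = d$gene_id, logFC = d$beta, t = d$t_mod,
                     p = d$p, fdr = d$fdr, direction = d$direction),
          outfile("degs_", m, ".tsv"), c(meta, model = m))
      }
    }
  }

  if (any(c("enrich", "compare") %in% config$stages)) {
    raw_sets <- simulate_gene_sets(scfg, sim$truth)
    if ("enrich" %in% config$stages)
      write_gmt(raw_sets, outfile("gene_sets.gmt"))
    coll <- build_collection(raw_sets, rownames(sim$studies[[1]]$matrix),
                             min_size = config$min_set_size)
    res$enrichment <- lapply(sim$studies, function(st)
      set_inference(pgsea_scores(st, coll), alpha = config$alpha))
    if ("enrich" %in% config$stages) {
      for (m in names(res$enrichment))
        write_tsv_with_meta(res$enrichment[[m]],
                            outfile("enrichment_", m, "_custom.tsv"),
                            c(meta, model = m))
    }
  }

  if ("compare" %in% config$stages) {
    gene_part <- partition_by_direction(res$de)
    set_part <- partition_by_direction(res$enrichment)
    for (dir in c("up", "down")) {
      write_tsv_with_meta(venn_counts(gene_part, dir),
                          outfile("venn_genes_", dir, ".tsv"), meta)
      write_tsv_with_meta(venn_counts(set_part, dir),
                          outfile("venn_sets_", dir, ".tsv"), meta)
    }
    simm <- similarity_matrices(gene_part)
    for (dir in c("pos", "neg"))
      write_tsv_with_meta(
        data.frame(model = rownames(simm[[dir]]), simm[[dir]],
                   check.names = FALSE),
        outfile("similarity_", dir, ".tsv"), meta)
    res$similarity <- simm
    common_up <- Reduce(intersect, lapply(gene_part, `[[`, "up"))
    if (length(common_up) >= 2L) {
      big <- do.call(cbind, lapply(sim$studies, `[[`, "matrix"))
      res$clustering <- scale_and_cluster(big, common_up)
    }
    res$summary <- summarize_enrichment(res$enrichment, k = 3L)
    write_tsv_with_meta(res$summary, outfile("enrichment_summary.tsv"),
                        meta)
    if (!is.null(config$reference_path)) {
      refs <- read_reference_signs(config$reference_path)
      for (m in names(res$enrichment)) {
        ov <- reference_sign_overlap(res$enrichment[[m]], refs)
        write_tsv_with_meta(ov$table,
                            outfile("reference_overlap_", m, ".tsv"),
                            c(meta, model = m))
      }
    }
  }

  if ("gem" %in% config$stages) {
    model <- if (is.null(config$model_path)) toy_metabolic_model(sim$truth)
             else read_model_json(config$model_path)
    res$gem <- lapply(res$de, function(stats)
      run_gem(model, stats, alpha = config$alpha,
              f = config$objective_fraction, w_max = config$w_max,
              eps = config$eps))
    for (m in names(res$gem)) {
      g <- res$gem[[m]]
      write_tsv_with_meta(
        data.frame(g$classification,
                   subsystem = unname(model$subsystems[
                     g$classification$reaction]),
                   lo_WT = g$fva_wt$lo, hi_WT = g$fva_wt$hi,
                   lo_KO = g$fva_ko$lo, hi_KO = g$fva_ko$hi),
        outfile("gem_reactions_", m, ".tsv"), c(meta, model = m))
      write_tsv_with_meta(g$subsystems,
                          outfile("gem_subsystems_", m, ".tsv"),
                          c(meta, model = m))
    }
  }

  manifest <- list(package = "fibroprog",
                   version = as.character(
                     utils::packageVersion("fibroprog")),
                   r_version = as.character(getRversion()),
                   seed = config$seed, stages = config$stages,
                   parameters = config[c("alpha", "min_set_size",
                                         "objective_fraction", "eps",
                                         "w_max")],
                   sim = unclass(scfg),
                   outputs = list.files(config$out_dir))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Cross-model enrichment summary
#'
#' Wide set-by-model table of enrichment estimates with non-significant
#' entries masked (NA), restricted to sets significant in at least
#' \code{k} models.
#'
#' @param enrichment named list of per-model \code{set_stats}.
#' @param k minimum number of models in which a set must be significant.
#' @return \code{data.frame}: \code{set}, \code{n_significant}, one
#'   estimate column per model.
#' @export
summarize_enrichment <- function(enrichment, k = 3L) {
  stopifnot(is.list(enrichment), length(enrichment) >= 1L)
  models <- names(enrichment)
  sets <- sort(unique(unlist(lapply(enrichment, `[[`, "set"))))
  est <- sapply(enrichment, function(e) {
    idx <- match(sets, e$set)
    val <- e$est[idx]
    val[is.na(idx) | e$direction[idx] == "ns"] <- NA_real_
    val
  })
  est <- matrix(est, nrow = length(sets),
                dimnames = list(sets, models))
  n_sig <- rowSums(!is.na(est))
  keep <- n_sig >= k
  out <- data.frame(set = sets[keep], n_significant = n_sig[keep],
                    est[keep, , drop = FALSE], check.names = FALSE,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n_significant, out$set), , drop = FALSE]
}
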