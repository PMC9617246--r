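#' Build or load a pipeline configuration
#'
#' The pipeline is configured by a YAML (or JSON) file, or an equivalent
#' named list: a `seed`, an `out_dir`, the stages to run, and per-stage
#' parameters. Unspecified fields fall back to documented defaults.
#'
#' @param config Path to a YAML/JSON config file, or a named list.
#' @param overrides Named list applied on top (CLI flag overrides).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), overrides = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  defaults <- list(
    seed = 1L,
    out_dir = "clonotrace_out",
    input_dir = NULL,           # NULL: the simulate stage generates inputs
    stages = c("simulate", "qc", "clonotype", "stats", "shm", "score",
               "prognosis"),
    receptor = "BCR",
    min_umis = 2L,
    hamming_threshold = 0.1,
    min_genes = 500L,
    max_mito = 0.10,
    n_bins = 25L,
    n_ctrl = 50L,
    top_k = 20L,
    top_n_clones = 20L,
    roc_horizon = 365,
    sim = list()                # passed to sim_config()
  )
  cfg <- utils::modifyList(defaults, config)
  cfg <- utils::modifyList(cfg, overrides)
  stopifnot(cfg$hamming_threshold > 0, cfg$hamming_threshold <= 1,
            cfg$min_umis >= 0, cfg$roc_horizon > 0)
  unknown <- setdiff(cfg$stages, defaults$stages)
  if (length(unknown) > 0) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[clonotrace:%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order — simulate (or load),
#' contig QC, clonotyping, repertoire statistics, SHM/selection, signature
#' scoring, prognosis — writing every artifact under `out_dir` and a
#' `manifest.json` listing each output with its MD5 content hash. All
#' randomness derives from the configured seed, so reruns with the same
#' config produce identical manifests.
#'
#' @param config A `pipeline_config` (or anything [pipeline_config()]
#'   accepts).
#' @return The manifest (named list of file -> md5), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(path) artifacts <<- c(artifacts, path)
  input_dir <- config$input_dir

  if ("simulate" %in% config$stages) {
    run_stage("simulate", {
      sim_cfg <- do.call(sim_config, c(list(seed = config$seed),
                                       config$sim))
      input_dir <- file.path(config$out_dir, "simulated")
      ds <- write_synthetic_dataset(sim_cfg, input_dir)
      for (p in unlist(ds$paths)) {
        if (dir.exists(p)) emit(list.files(p, full.names = TRUE))
        else emit(p)
      }
      pipeline_log("simulate", "%d contigs, %d cells, %d patients",
                   nrow(ds$repertoire$contigs),
                   ncol(ds$expression$dataset$counts), nrow(ds$survival))
    })
  }
  if (is.null(input_dir)) {
    stop("stage 'qc' failed: no input_dir configured and simulate stage ",
         "not requested", call. = FALSE)
  }
  if (!dir.exists(input_dir)) {
    stop("input path not found: ", input_dir, call. = FALSE)
  }

  contigs <- NULL
  paired <- NULL
  if ("qc" %in% config$stages) {
    run_stage("qc", {
      contig_path <- file.path(input_dir, "filtered_contig_annotations.csv")
      if (!file.exists(contig_path)) {
        stop("input path not found: ", contig_path)
      }
      contigs <- read_contigs(contig_path, "10x-contig-csv")
      airr_path <- file.path(input_dir, "airr_rearrangement.tsv")
      if (file.exists(airr_path)) {
        airr <- read_contigs(airr_path, "airr-tsv")
        keep <- c("sequence_alignment", "germline_alignment", "c_call")
        m <- match(contigs$contig_id, airr$contig_id)
        for (col in keep) contigs[[col]] <- airr[[col]][m]
      }
      filtered <- filter_contigs(contigs, config$min_umis)
      paired <- pair_chains(filtered, config$receptor)
      qc_path <- file.path(config$out_dir, "contig_qc_summary.tsv")
      write_qc_summary(filtered, qc_path)
      emit(qc_path)
      pipeline_log("qc", "%d/%d contigs retained; %d cells paired",
                   nrow(filtered), nrow(contigs), nrow(paired))
      contigs <- filtered
    })
  }

  assignment <- NULL
  if ("clonotype" %in% config$stages) {
    run_stage("clonotype", {
      if (is.null(paired)) stop("clonotype requires the qc stage")
      assignment <- if (config$receptor == "BCR") {
        group_bcr_clones(paired, config$hamming_threshold)
      } else call_tcr_clonotypes(paired)
      assignment <- assign_expansion_level(assignment)
      clone_path <- file.path(config$out_dir, "clones.tsv")
      write_clone_table(assignment, clone_path)
      emit(clone_path)
      pipeline_log("clonotype", "%d clones over %d cells",
                   nrow(assignment$clones), nrow(assignment$cells))
    })
  }

  truth <- NULL
  truth_path <- file.path(input_dir, "ground_truth.json")
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
  }

  if ("stats" %in% config$stages) {
    run_stage("stats", {
      if (is.null(assignment)) stop("stats requires the clonotype stage")
      if (is.null(truth)) stop("stats requires donor/group metadata ",
                               "(ground_truth.json)")
      ct <- truth$clone_truth
      donor_of <- stats::setNames(ct$donor, ct$barcode)
      group_of <- stats::setNames(ct$group, ct$barcode)
      metrics <- repertoire_metrics(assignment, donor_of,
                                    config$top_n_clones)
      metrics$group <- sub("_d[0-9]+$", "", metrics$stratum)
      mpath <- file.path(config$out_dir, "repertoire_metrics.tsv")
      write.table(metrics, mpath, sep = "\t", row.names = FALSE,
                  quote = FALSE)
      emit(mpath)
      groups <- group_of[assignment$cells$barcode]
      usage <- vgene_usage(paired$v_call_1, group_of[paired$barcode])
      upath <- file.path(config$out_dir, "vgene_usage.tsv")
      write.table(usage, upath, sep = "\t", quote = FALSE)
      emit(upath)
      counts <- as.matrix(table(donor_of[assignment$cells$barcode], groups))
      roe_mat <- roe(counts)
      rpath <- file.path(config$out_dir, "roe_matrix.tsv")
      write.table(roe_mat$roe, rpath, sep = "\t", quote = FALSE)
      emit(rpath)
      pipeline_log("stats", "metrics for %d strata", nrow(metrics))
    })
  }

  if ("shm" %in% config$stages && config$receptor == "BCR") {
    run_stage("shm", {
      if (is.null(contigs)) stop("shm requires the qc stage")
      shm <- analyze_shm(contigs[contigs$locus == "IGH", , drop = FALSE])
      spath <- file.path(config$out_dir, "shm_selection.tsv")
      write.table(shm, spath, sep = "\t", row.names = FALSE, quote = FALSE)
      emit(spath)
      pipeline_log("shm", "%d sequences analyzed, mean SHM %.4f",
                   nrow(shm), mean(shm$shm_freq))
    })
  }

  scores_tbl <- NULL
  if ("score" %in% config$stages) {
    run_stage("score", {
      expr_dir <- file.path(input_dir, "expression")
      if (!dir.exists(expr_dir)) stop("input path not found: ", expr_dir)
      ds <- read_mtx_dataset(expr_dir)
      ds <- filter_cells_qc(ds, config$min_genes, config$max_mito)
      ds <- log_normalize(ds)
      sets <- read_gmt(file.path(input_dir, "gene_sets.gmt"))
      isg <- module_score(ds, sets[["ISG"]], config$n_bins, config$n_ctrl,
                          config$seed)
      pw_names <- grep("^PATHWAY_", names(sets), value = TRUE)
      pw_scores <- rank_signature_scores(ds, sets[pw_names])
      comp <- comprehensive_metabolic_score(pw_scores, config$top_k)
      scores_tbl <- data.frame(barcode = colnames(ds$logcounts),
                                donor = ds$meta$donor,
                                group = ds$meta$group,
                                isg_score = isg,
                                metabolic_score = comp$score,
                                stringsAsFactors = FALSE)
      spath <- file.path(config$out_dir, "signature_scores.csv")
      write.csv(scores_tbl, spath, row.names = FALSE)
      emit(spath)
      donor_means <- stats::aggregate(cbind(isg_score, metabolic_score) ~ donor,
                               scores_tbl, mean)
      cpath <- file.path(config$out_dir, "score_correlation.json")
      corr <- score_correlation(donor_means$isg_score,
                                donor_means$metabolic_score)
      jsonlite::write_json(corr, cpath, auto_unbox = TRUE, digits = NA)
      emit(cpath)
      pipeline_log("score", "%d cells scored; donor-level rho = %.3f",
                   nrow(scores_tbl), corr$rho)
    })
  }

  if ("prognosis" %in% config$stages) {
    run_stage("prognosis", {
      surv_path <- file.path(input_dir, "survival.csv")
      if (!file.exists(surv_path)) stop("input path not found: ", surv_path)
      surv <- read.csv(surv_path, stringsAsFactors = FALSE)
      surv$event <- as.logical(surv$event)
      curve <- roc_auc(surv$time_days, surv$event, surv$marker,
                       config$roc_horizon)
      cut <- youden_cutoff(curve)
      high <- surv$marker >= cut$threshold
      km_high <- km_estimate(surv$time_days[high], surv$event[high])
      km_low <- km_estimate(surv$time_days[!high], surv$event[!high])
      lr <- logrank_test(surv$time_days[high], surv$event[high],
                         surv$time_days[!high], surv$event[!high])
      rpath <- file.path(config$out_dir, "roc_points.csv")
      write.csv(curve$points, rpath, row.names = FALSE)
      emit(rpath)
      kpath <- file.path(config$out_dir, "km_steps.csv")
      km_high$steps$stratum <- "high"
      km_low$steps$stratum <- "low"
      write.csv(rbind(km_high$steps, km_low$steps), kpath,
                row.names = FALSE)
      emit(kpath)
      jpath <- file.path(config$out_dir, "prognosis.json")
      jsonlite::write_json(list(
        auc = curve$auc, n_pos = curve$n_pos, n_neg = curve$n_neg,
        positive_class = "death_within_horizon",
        youden = list(threshold = cut$threshold, j = cut$j,
                      sensitivity = cut$sensitivity,
                      specificity = cut$specificity),
        logrank = list(statistic = lr$statistic, df = lr$df,
                       p_value = lr$p_value)
      ), jpath, auto_unbox = TRUE, digits = NA)
      emit(jpath)
      pipeline_log("prognosis", "AUC %.3f, cutoff %.3f, log-rank p %.4g",
                   curve$auc, cut$threshold, lr$p_value)
    })
  }

  artifacts <- unique(artifacts[file.exists(artifacts)])
  manifest <- as.list(tools::md5sum(artifacts))
  names(manifest) <- sub(paste0("^", config$out_dir, "/?"), "",
                         names(manifest))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  pipeline_log("done", "%d artifacts in %s", length(manifest),
               config$out_dir)
  invisible(manifest)
}
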