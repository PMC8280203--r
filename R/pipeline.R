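config_defaults <- function() {
  list(
    stage = "spike-in",
    output_dir = "scmirna_out",
    seed = NULL,                       # mandatory, no default
    protocol = "SBN_CL",
    reference = list(fasta = NULL, n_seqs = 1006L,
                     len_min = 20L, len_max = 25L),
    simulate = list(enabled = TRUE, n_samples = 3L, n_reads = 50000L,
                    frac_dimer = 0.30, frac_other_rna = 0.15,
                    frac_junk = 0.05, bias_beta_g = 1.5, bias_sigma = 1.0,
                    pcr_mean_reads_per_molecule = 4.74,
                    pcr_dispersion = 2.0, seq_error_rate = 0.002,
                    low_quality_tail_frac = 0.05, unique_umis = FALSE),
    samples = NULL,                    # list of (id, fastq) when not simulating
    trim = list(quality_cutoff = 20L, max_error_rate = 0.10,
                max_rounds = 3L, max_n = 2L, min_len = 18L,
                dimer_max_len = 3L),
    subsample = list(enabled = FALSE, n = 300000L, seed = 42L),
    mapping = list(min_identity = 0.80),
    class_assignment = list(min_overlap = 0.90),
    detection = list(threshold = 1L),
    dedup = list(group_by_length = TRUE),
    qc = list(min_molecules = 50L),
    metrics = list(pseudocount = 1, cv_detected_only = FALSE),
    cluster = list(enabled = FALSE, n_variable_features = NULL,
                   n_pcs = 15L, umap_neighbors = 15L,
                   louvain_resolution = 1.4, snn_k = 20L)
  )
}

merge_section <- function(defaults, user, path, provenance) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ",
         paste(paste0(path, unknown), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      res <- merge_section(defaults[[k]], user[[k]], paste0(path, k, "."),
                           provenance)
      defaults[[k]] <- res$value
      provenance <- res$provenance
    } else {
      defaults[k] <- user[k]
      provenance[[paste0(path, k)]] <- "user"
    }
  }
  list(value = defaults, provenance = provenance)
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML file (or takes a list), rejects unknown keys, fills every
#' missing setting with the benchmark defaults (quality cutoff 20, 10%
#' adapter error rate, 3 trimming rounds, at most 2 N bases, minimum
#' length 18, dimer below 4 bases, mapping identity 0.80, class overlap
#' 0.90, detection threshold 1, subsample 300,000 reads at seed 42,
#' minimum 50 molecules per cell) and records per-key provenance
#' (`"default"` or `"user"`). A configuration without a top-level seed is
#' rejected: every stochastic step derives its seed from it.
#'
#' @param config path to a YAML file or a named list.
#' @return The normalized configuration (class `pipeline_config`) with a
#'   `provenance` attribute.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("malformed config file")
  }
  defaults <- config_defaults()
  provenance <- list()
  flat <- function(x, path = "") {
    for (k in names(x)) {
      if (is.list(x[[k]]) && !is.null(names(x[[k]]))) {
        flat(x[[k]], paste0(path, k, "."))
      } else provenance[[paste0(path, k)]] <<- "default"
    }
  }
  flat(defaults)
  res <- merge_section(defaults, config, "", provenance)
  cfg <- res$value
  if (is.null(cfg$seed)) stop("config error: a top-level seed is required")
  if (!isTRUE(cfg$simulate$enabled)) {
    if (is.null(cfg$samples)) {
      stop("config error: either simulate.enabled or a samples list ",
           "is required")
    }
    for (s in cfg$samples) {
      if (!file.exists(s$fastq)) {
        stop("config error: missing input file ", s$fastq)
      }
    }
  }
  if (!is.null(cfg$reference$fasta) && !file.exists(cfg$reference$fasta)) {
    stop("config error: missing reference FASTA ", cfg$reference$fasta)
  }
  if (!cfg$protocol %in% names(protocol_presets())) {
    stop("config error: unknown protocol ", cfg$protocol)
  }
  attr(cfg, "provenance") <- res$provenance
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Run the pipeline for one stage configuration
#'
#' Executes simulate (optional) -> preprocess -> quantify -> dedup ->
#' metrics in order, writing per-step outputs (trimmed FASTQ, status
#' summaries, count-matrix TSVs, metrics JSON) and a run manifest with the
#' configuration hash and per-file checksums under `config$output_dir`.
#' Re-running an identical configuration reproduces identical outputs.
#'
#' @param config a `pipeline_config` from [validate_config()] (or a
#'   path/list, validated on the fly).
#' @return The manifest, invisibly; results are also returned in the
#'   `results` element (count container, metrics list, per-sample QC).
#' @export
run_stage <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  arch <- protocol_presets()[[config$protocol]]
  tcfg <- trim_config_for(arch,
                          quality_cutoff = config$trim$quality_cutoff,
                          max_error_rate = config$trim$max_error_rate,
                          max_rounds = config$trim$max_rounds,
                          max_n = config$trim$max_n,
                          min_len = config$trim$min_len,
                          dimer_max_len = config$trim$dimer_max_len)
  # --- reference ---
  refs <- if (!is.null(config$reference$fasta)) {
    read_fasta_reference(config$reference$fasta)
  } else {
    generate_reference(config$reference$n_seqs,
                       c(config$reference$len_min, config$reference$len_max),
                       seed = config$seed)
  }
  # --- simulate or load reads ---
  truth <- NULL
  if (isTRUE(config$simulate$enabled)) {
    sc <- config$simulate
    cfg <- library_sim_config(
      n_reads = sc$n_reads, frac_dimer = sc$frac_dimer,
      frac_other_rna = sc$frac_other_rna, frac_junk = sc$frac_junk,
      bias_beta_g = sc$bias_beta_g, bias_sigma = sc$bias_sigma,
      pcr_mean_reads_per_molecule = sc$pcr_mean_reads_per_molecule,
      pcr_dispersion = sc$pcr_dispersion,
      seq_error_rate = sc$seq_error_rate,
      low_quality_tail_frac = sc$low_quality_tail_frac,
      seed = config$seed + 1L, unique_umis = sc$unique_umis)
    ids <- sprintf("%s_rep%d", config$protocol,
                   seq_len(config$simulate$n_samples))
    sims <- simulate_samples(refs, arch, cfg, ids)
    reads <- lapply(sims, `[[`, "records")
    truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
    for (id in ids) {
      write_fastq(sims[[id]]$records,
                  file.path(out_dir, paste0(id, ".fastq")))
    }
    utils::write.table(truth, file.path(out_dir, "ground_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ids <- vapply(config$samples, `[[`, character(1), "id")
    reads <- lapply(config$samples, function(s) read_fastq(s$fastq))
    names(reads) <- ids
  }
  # --- preprocess ---
  kept <- list()
  qc_rows <- list()
  for (id in ids) {
    rec <- reads[[id]]
    if (isTRUE(config$subsample$enabled)) {
      rec <- subsample_reads(rec, config$subsample$n, config$subsample$seed)
    }
    rec <- extract_umi(rec, arch$umi_len)
    tr <- trim_reads(rec, tcfg)
    kept[[id]] <- tr$records[tr$status == "kept", , drop = FALSE]
    attr(kept[[id]], "phred_offset") <- phred_offset(rec)
    class(kept[[id]]) <- c("smallrna_records", "data.frame")
    s <- tr$summary
    qc_rows[[id]] <- data.frame(sample_id = id,
                                status = s$status, n = s$n,
                                fraction = s$fraction,
                                stringsAsFactors = FALSE)
    write_fastq(kept[[id]], file.path(out_dir, paste0(id, ".trimmed.fastq")))
  }
  qc <- do.call(rbind, qc_rows)
  utils::write.table(qc, file.path(out_dir, "trim_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # --- quantify ---
  hits <- lapply(ids, function(id) {
    h <- map_to_reference(kept[[id]], refs,
                          min_identity = config$mapping$min_identity)
    h$sample_id <- rep(id, nrow(h))
    h
  })
  names(hits) <- ids
  raw <- count_features(hits, refs)
  raw <- raw[, ids, drop = FALSE]
  rpmm <- rpmm_normalize(raw)
  det <- detection_calls(raw, config$detection$threshold)
  # --- dedup ---
  layers <- list(raw = raw, rpmm = rpmm)
  molecules <- NULL
  rpu <- NULL
  if (arch$umi_len > 0L) {
    ut <- umi_table(do.call(rbind, hits),
                    records = do.call(rbind, lapply(kept, function(k) {
                      as.data.frame(k)
                    })),
                    group_by_length = config$dedup$group_by_length)
    molecules <- dedup_counts(ut, refs, sample_ids = ids)
    layers$molecules <- molecules
    rpu <- reads_per_umi(ut)
  }
  meta <- data.frame(sample_id = ids, protocol = config$protocol,
                     stage = config$stage, stringsAsFactors = FALSE)
  se <- make_count_matrix(layers, metadata = meta)
  write_count_matrix(se, file.path(out_dir, "counts"))
  # --- metrics ---
  metrics <- list(
    detected_per_sample = as.list(det$per_sample),
    cv = as.list(apply(rpmm, 2L, coefficient_of_variation,
                       detected_only = config$metrics$cv_detected_only)))
  assoc <- gcontent_detection_association(refs, det$per_feature)
  metrics$gcontent_rho <- assoc$rho
  metrics$gcontent_p <- assoc$p_value
  if (!is.null(molecules)) {
    totals <- molecules_per_cell(molecules, refs)
    metrics$molecules_per_cell <- as.list(totals)
    metrics$cells_passing_qc <- filter_cells(totals, config$qc$min_molecules)
    metrics$reads_per_umi_mean <- rpu$cohort$mean
    metrics$reads_per_umi_sd <- rpu$cohort$sd
  }
  if (length(ids) >= 2L) {
    groups <- stats::setNames(meta$protocol, meta$sample_id)
    dists <- reproducibility_distances(rpmm, groups,
                                       config$metrics$pseudocount)
    utils::write.table(dists$pairs, file.path(out_dir, "distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    metrics$median_within_distance <- stats::median(dists$within)
    if (length(dists$between) > 0L) {
      metrics$median_between_distance <- stats::median(dists$between)
    }
  }
  if (isTRUE(config$cluster$enabled) && length(ids) >= 3L) {
    ccfg <- cluster_config(
      n_variable_features = config$cluster$n_variable_features,
      n_pcs = config$cluster$n_pcs,
      umap_neighbors = config$cluster$umap_neighbors,
      louvain_resolution = config$cluster$louvain_resolution,
      snn_k = config$cluster$snn_k, seed = config$seed + 2L)
    emb <- embed_and_cluster(lognormalize(raw), ccfg, raw = raw)
    coords <- data.frame(sample_id = emb$sample_ids,
                         umap1 = emb$embedding[, 1L],
                         umap2 = emb$embedding[, 2L],
                         cluster = emb$clusters, stringsAsFactors = FALSE)
    utils::write.table(coords, file.path(out_dir, "embedding.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    metrics$n_clusters <- length(unique(emb$clusters))
  }
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # --- manifest ---
  files <- sort(list.files(out_dir, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("scmirna")),
    config_hash = rlang::hash(unclass(config)),
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest$results <- list(counts = se, metrics = metrics, qc = qc,
                           truth = truth, refs = refs)
  invisible(manifest)
}
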