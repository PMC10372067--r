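.write_table <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

#' Run the full synthetic-to-statistics pipeline
#'
#' Orchestrates the analysis end to end: simulate (or load) a paired
#' reference/spatial dataset, spatial and reference QC, normalization,
#' HVG selection, cluster entropy, reference marker detection, two-pass
#' label transfer to the spatial cells, and the spatial statistics
#' (co-localization, surface distances, neighborhoods, abundance
#' correlations). Every intermediate table is written as CSV under
#' `outdir` together with a JSON run manifest carrying the config
#' snapshot, seed, per-stage status and output file hashes; rerunning
#' with the same config and seed reproduces identical hashes.
#'
#' @param config a `PipelineConfig`, or path to a YAML config file. To
#'   run on synthetic data the config carries a `design` entry: a (possibly
#'   empty) list of [simulation_design()] overrides. Alternatively a
#'   `data` entry may point at `reference_dir`, `spatial_dir`,
#'   `reference_meta`, `spatial_meta`, `surface` files in the package's
#'   own formats.
#' @param outdir output directory.
#' @return The run manifest, invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$design) && is.null(config$data))
    stop("configuration error: config needs either a 'design' (synthetic ",
         "run) or 'data' (dataset paths) entry")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("mucospat")),
                   seed = config$seed, config = unclass(config),
                   stages = list(), files = list())
  stage_files <- character(0)
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      .finish_manifest(manifest, outdir, stage_files)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  truth <- NULL
  if (!is.null(config$design)) {
    sim <- run_stage("simulate", function() {
      design <- do.call(simulation_design,
                        c(config$design,
                          list(seed = derive_seed(config$seed, "simulate"))))
      simulate_paired(design)
    })
    reference <- sim$reference
    spatial <- sim$spatial
    surface <- sim$spatial$surface
    truth <- sim$spatial$truth
    stage_files <- c(stage_files, .write_table(
      data.frame(cell_id = names(truth$true_type),
                 true_type = unname(truth$true_type),
                 true_niche = unname(truth$true_niche)),
      outdir, "ground_truth"))
  } else {
    reference <- run_stage("load_reference", function() {
      list(counts = read_count_matrix(
        file.path(config$data$reference_dir, "matrix.mtx"),
        file.path(config$data$reference_dir, "matrix.genes.tsv"),
        file.path(config$data$reference_dir, "matrix.barcodes.tsv")),
        meta = read_cell_meta(config$data$reference_meta))
    })
    spatial <- run_stage("load_spatial", function() {
      list(counts = read_count_matrix(
        file.path(config$data$spatial_dir, "matrix.mtx"),
        file.path(config$data$spatial_dir, "matrix.genes.tsv"),
        file.path(config$data$spatial_dir, "matrix.barcodes.tsv")),
        meta = read_cell_meta(config$data$spatial_meta))
    })
    surface <- if (!is.null(config$data$surface))
      read_surface_polyline(config$data$surface)
  }
  run_stage("validate", function()
    validate_paired_dataset(reference, spatial))

  sp_qc <- run_stage("qc_spatial", function()
    filter_spatial_cells(spatial$counts, spatial$meta,
                         negprobe_mean_max = config$qc$smi_negprobe_mean_max,
                         min_features = config$qc$smi_min_features))
  stage_files <- c(stage_files,
                   .write_table(sp_qc$report$cells, outdir, "qc_spatial"))

  norm_ref <- run_stage("normalize_reference", function()
    lognormalize(reference$counts,
                 scale_target = config$normalize$scale_target))
  sp_bio <- sp_qc$counts[!sp_qc$counts$is_negative_probe, ]
  norm_sp <- run_stage("normalize_spatial", function()
    lognormalize(sp_bio, scale_target = config$normalize$scale_target))

  hvg <- run_stage("hvg", function()
    model_gene_variance(norm_sp, sp_qc$meta, block_by_sample = TRUE,
                        span = config$normalize$hvg_span))
  stage_files <- c(stage_files, .write_table(
    data.frame(gene = hvg$hvgs, rank = seq_along(hvg$hvgs)),
    outdir, "hvg"))

  entropy <- run_stage("entropy", function()
    cluster_entropy(reference$meta$subtype, reference$meta$sample_id,
                    flag_below = config$entropy$flag_below))
  stage_files <- c(stage_files, .write_table(entropy, outdir, "entropy"))

  markers <- run_stage("markers", function()
    find_markers(norm_ref, reference$meta$subtype,
                 min_pct = config$markers$min_pct,
                 logfc_min = config$markers$logfc_min))
  stage_files <- c(stage_files, .write_table(markers, outdir, "markers"))

  annotation <- run_stage("transfer", function()
    two_pass_annotation(norm_ref, reference$meta, norm_sp,
                        top_n = config$transfer$top_n,
                        min_overlap = config$transfer$min_overlap))
  stage_files <- c(stage_files,
                   .write_table(annotation, outdir, "annotation"))

  sp_meta <- sp_qc$meta
  sp_meta$subtype <- annotation$subtype[match(sp_meta$cell_id,
                                              annotation$cell_id)]
  sp_meta$compartment <- annotation$compartment[match(sp_meta$cell_id,
                                                      annotation$cell_id)]
  accuracy <- NULL
  if (!is.null(truth)) {
    tt <- truth$true_type[sp_meta$cell_id]
    accuracy <- list(
      subtype = mean(sp_meta$subtype == tt),
      compartment = mean(sp_meta$compartment ==
                           truth$compartment_of_type[tt]))
  }

  coloc <- run_stage("coloc", function()
    colocalization_scores(sp_meta, grid_n = config$spatial$grid_n,
                          min_cells = config$spatial$min_cells,
                          bandwidth_floor = config$spatial$bandwidth_floor))
  stage_files <- c(stage_files, .write_table(coloc, outdir, "coloc"))
  coloc_summary <- summarize_colocalization(
    coloc, stats::setNames(sp_meta$group, sp_meta$sample_id))
  stage_files <- c(stage_files,
                   .write_table(coloc_summary, outdir, "coloc_summary"))

  surfdist <- if (!is.null(surface)) {
    sd_res <- run_stage("surface_distance", function()
      distance_to_surface(sp_meta, surface,
                          min_cells = config$spatial$min_cells))
    if (!is.null(sd_res$summary))
      stage_files <- c(stage_files, .write_table(sd_res$summary, outdir,
                                                 "surface_distance"))
    sd_res
  }

  nbhd <- run_stage("neighborhoods", function()
    detect_neighborhoods(sp_meta, k = config$spatial$neighborhood_k,
                         K = config$spatial$neighborhood_K,
                         seed = derive_seed(config$seed, "neighborhoods")))
  stage_files <- c(stage_files,
                   .write_table(nbhd$assignment, outdir, "neighborhoods"))

  abcorr <- run_stage("abundance_correlation", function()
    abundance_correlation(sp_meta))
  stage_files <- c(stage_files,
                   .write_table(abcorr, outdir, "abundance_correlation"))

  summary <- c(
    sprintf("spatial cells: %d in, %d retained (%.1f%%)",
            sp_qc$report$n_input,
            sp_qc$report$n_input - sp_qc$report$n_removed,
            100 * sp_qc$report$retained_fraction),
    sprintf("HVGs selected: %d", length(hvg$hvgs)),
    sprintf("entropy range: %.3f - %.3f (%d flagged)",
            min(entropy$H), max(entropy$H), sum(entropy$flagged)),
    if (!is.null(accuracy))
      sprintf("transfer accuracy: compartment %.3f, subtype %.3f",
              accuracy$compartment, accuracy$subtype),
    sprintf("top co-localized pair: %s - %s (mean score %.3f)",
            coloc_summary$type_a[1], coloc_summary$type_b[1],
            coloc_summary$mean_score[1]))
  writeLines(summary, file.path(outdir, "summary.txt"))
  stage_files <- c(stage_files, file.path(outdir, "summary.txt"))

  manifest$accuracy <- accuracy
  .finish_manifest(manifest, outdir, stage_files)
}

.finish_manifest <- function(manifest, outdir, files) {
  hashes <- tools::md5sum(files)
  manifest$files <- as.list(stats::setNames(unname(hashes),
                                            basename(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Regenerate the human-readable summary of a completed run
#'
#' Reads only the stored manifest and tables; nothing is recomputed.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return Character vector of summary lines (also printed).
#' @export
report <- function(run_dir) {
  manifest_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("error: no manifest.json in ", run_dir)
  manifest <- jsonlite::read_json(manifest_path)
  lines <- c(sprintf("mucospat run (package %s, seed %s)",
                     manifest$package_version, manifest$seed),
             sprintf("stages: %s",
                     paste(names(manifest$stages), collapse = ", ")))
  for (f in names(manifest$files)) {
    path <- file.path(run_dir, f)
    if (!file.exists(path)) next
    if (grepl("\\.csv$", f)) {
      tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                      error = function(e)
                        stop("error: corrupt table: ", f, call. = FALSE))
      ncol_line <- vapply(strsplit(readLines(path), ","), length, 1L)
      if (length(unique(ncol_line)) != 1)
        stop("error: corrupt table (ragged columns): ", f)
      lines <- c(lines, sprintf("%s: %d rows", f, nrow(tab)))
    }
  }
  if (file.exists(file.path(run_dir, "summary.txt")))
    lines <- c(lines, readLines(file.path(run_dir, "summary.txt")))
  cat(lines, sep = "\n")
  invisible(lines)
}
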