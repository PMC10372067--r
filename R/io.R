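#' Read a MatrixMarket count matrix with gene and barcode sidecars
#'
#' Reads the standard triplet of files used for sparse single-cell count
#' matrices: a MatrixMarket `.mtx` file (1-based coordinates) plus
#' one-column TSV files listing gene identifiers (rows) and cell barcodes
#' (columns). Genes whose identifier starts with `negprobe_prefix` are
#' flagged as negative-control probes.
#'
#' @param mtx_path path to the MatrixMarket file.
#' @param genes_path path to the one-column gene TSV.
#' @param barcodes_path path to the one-column barcode TSV.
#' @param negprobe_prefix identifier prefix marking negative probes.
#'
#' @return A [CountMatrix()].
#' @export
read_count_matrix <- function(mtx_path, genes_path, barcodes_path,
                              negprobe_prefix = "NegPrb") {
  for (p in c(mtx_path, genes_path, barcodes_path))
    if (!file.exists(p)) stop("format error: file not found: ", p)
  m <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  if (nrow(m) != length(genes))
    stop("format error: ", genes_path, " lists ", length(genes),
         " genes but MTX declares ", nrow(m), " rows")
  if (ncol(m) != length(barcodes))
    stop("format error: ", barcodes_path, " lists ", length(barcodes),
         " barcodes but MTX declares ", ncol(m), " columns")
  dimnames(m) <- list(genes, barcodes)
  CountMatrix(m, negprobe_prefix = negprobe_prefix)
}

#' Write a CountMatrix as MTX plus gene/barcode TSVs
#'
#' @param x a [CountMatrix()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_count_matrix <- function(x, dir, prefix = "matrix") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, paste0(prefix, ".mtx"))
  genes <- file.path(dir, paste0(prefix, ".genes.tsv"))
  barcodes <- file.path(dir, paste0(prefix, ".barcodes.tsv"))
  Matrix::writeMM(x$counts, mtx)
  writeLines(gene_ids(x), genes)
  writeLines(cell_ids(x), barcodes)
  invisible(c(mtx = mtx, genes = genes, barcodes = barcodes))
}

#' Read per-cell metadata from CSV
#'
#' The CSV must have a header with at least `cell_id`, `sample_id` and
#' `group`; optional columns (`fov_id`, `x_um`, `y_um`, `compartment`,
#' `subtype`, `qc_pass`, `qc_reason`) are populated when present.
#'
#' @param csv_path path to the metadata CSV.
#' @return Validated data.frame, one row per cell.
#' @export
read_cell_meta <- function(csv_path) {
  if (!file.exists(csv_path)) stop("format error: file not found: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  for (col in intersect(c("cell_id", "sample_id", "group", "fov_id",
                          "compartment", "subtype", "qc_reason"), names(df))) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][df[[col]] == ""] <- NA_character_
  }
  validate_cell_meta(df)
  df
}

#' Write per-cell metadata to CSV
#'
#' @param meta metadata data.frame.
#' @param csv_path output path.
#' @return Invisibly, `csv_path`.
#' @export
write_cell_meta <- function(meta, csv_path) {
  validate_cell_meta(meta)
  utils::write.csv(meta, csv_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(csv_path)
}

#' Read a mucosal-surface polyline from CSV
#'
#' Columns `x_um`, `y_um`; vertex order is row order.
#'
#' @param csv_path path to the polyline CSV.
#' @return A [surface_polyline()].
#' @export
read_surface_polyline <- function(csv_path) {
  if (!file.exists(csv_path)) stop("format error: file not found: ", csv_path)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("format error: polyline CSV needs columns x_um,y_um")
  surface_polyline(df$x_um, df$y_um)
}

#' Write a mucosal-surface polyline to CSV
#' @param poly a [surface_polyline()].
#' @param csv_path output path.
#' @return Invisibly, `csv_path`.
#' @export
write_surface_polyline <- function(poly, csv_path) {
  utils::write.csv(as.data.frame(poly), csv_path, row.names = FALSE,
                   quote = FALSE)
  invisible(csv_path)
}

#' Default pipeline configuration
#'
#' Collects every threshold and seed used by the downstream stages. Values
#' follow the published analysis where one is stated (negative-probe mean
#' 0.5, minimum 20 detected features, 65% mitochondrial cap for
#' epithelial cells, marker thresholds min.pct = 0.25 and log-FC 0.25,
#' regulated-gene rule FDR < 0.05 with FC > 1.2 or < 0.83, 100 transfer
#' markers, more-than-10-cell validity rule for spatial statistics);
#' remaining knobs carry documented package defaults.
#'
#' @param ... named overrides of any top-level or nested entry, e.g.
#'   `default_config(qc = list(sc_mito_max_pct = 30))`.
#' @return Nested list of class `PipelineConfig`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    io = list(negprobe_prefix = "NegPrb", mito_prefix = "MT-",
              ig_prefixes = c("IGH", "IGK", "IGL")),
    qc = list(smi_negprobe_mean_max = 0.5, smi_min_features = 20L,
              sc_mito_max_pct = 25, sc_mito_max_pct_epithelial = 65,
              sc_min_genes = 200L, lineage_expr_min = 0),
    normalize = list(scale_target = 1e4, hvg_span = 0.3),
    markers = list(min_pct = 0.25, logfc_min = 0.25,
                   regulated_p = 0.05, regulated_fc_up = 1.2,
                   regulated_fc_down = 0.83),
    transfer = list(top_n = 100L, quantile = 0.8, min_overlap = 20L),
    spatial = list(grid_n = 64L, min_cells = 10L, bandwidth_floor = 1,
                   neighborhood_k = 20L, neighborhood_K = 6L),
    entropy = list(flag_below = 0.2)
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  if (!is.numeric(cfg$seed) || cfg$seed < 0)
    stop("validation error: seed must be a non-negative integer")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Missing entries are filled from [default_config()].
#'
#' @param path path to a YAML config file.
#' @return `PipelineConfig` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  do.call(default_config, user)
}

#' Validate a paired reference/spatial dataset
#'
#' Checks gene-space compatibility between a scRNA-seq reference and a
#' targeted spatial panel, and basic metadata integrity. A panel sharing
#' zero biological genes with the reference cannot be annotated and is a
#' hard error.
#'
#' @param reference,spatial lists with elements `counts` (a
#'   [CountMatrix()]) and `meta` (metadata data.frame).
#' @return List report: `n_overlap`, `overlap_genes`,
#'   `n_spatial_without_coords`, `n_duplicated_cells`.
#' @export
validate_paired_dataset <- function(reference, spatial) {
  ref_genes <- gene_ids(reference$counts)
  sp_genes <- gene_ids(spatial$counts)[!spatial$counts$is_negative_probe]
  overlap <- intersect(sp_genes, ref_genes)
  if (length(overlap) == 0)
    stop("incompatible-panels error: spatial panel shares no biological ",
         "genes with the reference")
  validate_cell_meta(reference$meta)
  validate_cell_meta(spatial$meta)
  no_xy <- if ("x_um" %in% names(spatial$meta))
    sum(is.na(spatial$meta$x_um)) else nrow(spatial$meta)
  dup <- sum(duplicated(c(cell_ids(reference$counts),
                          cell_ids(spatial$counts))))
  list(n_overlap = length(overlap), overlap_genes = overlap,
       n_spatial_without_coords = no_xy, n_duplicated_cells = dup)
}
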