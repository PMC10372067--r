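#' Construct a CountMatrix
#'
#' A `CountMatrix` bundles a sparse genes x cells matrix of non-negative
#' integer counts with a per-gene flag marking negative-control probes.
#' Negative-control probes target no transcript; their counts estimate
#' background and drive spatial cell QC.
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer counts with unique rownames (gene identifiers) and colnames
#'   (cell identifiers).
#' @param is_negative_probe logical vector, one entry per gene. If `NULL`,
#'   probes are detected from `negprobe_prefix`.
#' @param negprobe_prefix identifier prefix marking negative-control probes.
#'
#' @return An object of class `CountMatrix` with elements `counts`
#'   (a `dgCMatrix`) and `is_negative_probe` (named logical).
#' @export
CountMatrix <- function(counts, is_negative_probe = NULL,
                        negprobe_prefix = "NegPrb") {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("counts must carry gene rownames and cell colnames")
  if (anyDuplicated(gene_ids))
    stop("validation error: duplicate gene identifiers: ",
         paste(utils::head(gene_ids[duplicated(gene_ids)], 3), collapse = ", "))
  if (anyDuplicated(cell_ids))
    stop("validation error: duplicate cell identifiers: ",
         paste(utils::head(cell_ids[duplicated(cell_ids)], 3), collapse = ", "))
  if (any(counts@x < 0)) stop("validation error: negative counts")
  if (any(counts@x != round(counts@x)))
    stop("validation error: non-integer counts")
  if (is.null(is_negative_probe)) {
    is_negative_probe <- startsWith(gene_ids, negprobe_prefix)
  }
  stopifnot(length(is_negative_probe) == nrow(counts))
  names(is_negative_probe) <- gene_ids
  structure(list(counts = counts, is_negative_probe = is_negative_probe),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d genes x %d cells (%d negative probes)\n",
              nrow(x$counts), ncol(x$counts), sum(x$is_negative_probe)))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Gene identifiers of a CountMatrix
#' @param x a `CountMatrix`.
#' @return character vector.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' Cell identifiers of a CountMatrix
#' @param x a `CountMatrix`.
#' @return character vector.
#' @export
cell_ids <- function(x) colnames(x$counts)

#' Subset a CountMatrix by genes and/or cells
#'
#' @param x a `CountMatrix`.
#' @param i gene index (integer, logical or character).
#' @param j cell index (integer, logical or character).
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @export
`[.CountMatrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  CountMatrix(x$counts[i, j, drop = FALSE],
              is_negative_probe = unname(x$is_negative_probe[i]))
}

#' Counts restricted to biological (non-probe) genes
#' @param x a `CountMatrix`.
#' @return sparse matrix of biological gene counts.
#' @export
biological_counts <- function(x) {
  x$counts[!x$is_negative_probe, , drop = FALSE]
}

.valid_groups <- c("HC", "CD", "UC")
.valid_compartments <- c("epithelium", "stroma", "tcells", "plasmas", "myeloid")

#' Assemble and validate a per-cell metadata table
#'
#' Per-cell records carry sample and disease-group membership and, for
#' spatial cells, the field of view (FoV) and centroid coordinates in
#' micrometres. Cells must belong to one of the groups HC (healthy
#' control), CD (Crohn's disease) or UC (ulcerative colitis).
#'
#' @param cell_id,sample_id character vectors.
#' @param group character vector of disease groups (`HC`, `CD`, `UC`).
#' @param fov_id optional FoV identifiers (NA when absent).
#' @param x_um,y_um optional centroid coordinates in micrometres.
#' @param compartment optional coarse lineage label (one of
#'   `epithelium`, `stroma`, `tcells`, `plasmas`, `myeloid`).
#' @param subtype optional fine cell-type label.
#' @param qc_pass logical QC flag (default `TRUE`).
#' @param qc_reason reason string, non-empty exactly when `qc_pass` is
#'   `FALSE`.
#'
#' @return data.frame with one row per cell.
#' @export
cell_meta <- function(cell_id, sample_id, group,
                      fov_id = NA_character_, x_um = NA_real_, y_um = NA_real_,
                      compartment = NA_character_, subtype = NA_character_,
                      qc_pass = TRUE, qc_reason = NA_character_) {
  df <- data.frame(cell_id = as.character(cell_id),
                   sample_id = as.character(sample_id),
                   group = as.character(group),
                   fov_id = as.character(fov_id),
                   x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                   compartment = as.character(compartment),
                   subtype = as.character(subtype),
                   qc_pass = as.logical(qc_pass),
                   qc_reason = as.character(qc_reason),
                   stringsAsFactors = FALSE)
  validate_cell_meta(df)
  df
}

#' Validate a per-cell metadata table
#'
#' @param meta data.frame as produced by [cell_meta()] or
#'   [read_cell_meta()].
#' @return `meta`, invisibly, after validation.
#' @export
validate_cell_meta <- function(meta) {
  required <- c("cell_id", "sample_id", "group")
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop("format error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$cell_id))
    stop("validation error: duplicate cell_id in metadata")
  bad <- !meta$group %in% .valid_groups
  if (any(bad))
    stop("validation error: unknown group value(s): ",
         paste(unique(meta$group[bad]), collapse = ", "))
  if (all(c("x_um", "y_um") %in% names(meta))) {
    has_xy <- !is.na(meta$x_um) | !is.na(meta$y_um)
    if (any(is.na(meta$x_um) != is.na(meta$y_um)))
      stop("validation error: x_um and y_um must be present together")
    if ("fov_id" %in% names(meta)) {
      if (any(has_xy & is.na(meta$fov_id)))
        stop("validation error: coordinates present without FoV id")
    }
  }
  if ("compartment" %in% names(meta)) {
    bad <- !is.na(meta$compartment) &
      !meta$compartment %in% .valid_compartments
    if (any(bad))
      stop("validation error: unknown compartment: ",
           paste(unique(meta$compartment[bad]), collapse = ", "))
  }
  if (all(c("qc_pass", "qc_reason") %in% names(meta))) {
    reason_ok <- ifelse(meta$qc_pass,
                        is.na(meta$qc_reason) | meta$qc_reason == "",
                        !is.na(meta$qc_reason) & meta$qc_reason != "")
    if (!all(reason_ok))
      stop("validation error: qc_reason must be non-empty iff qc_pass is FALSE")
  }
  invisible(meta)
}

#' Construct a mucosal-surface polyline
#'
#' The mucosal surface is an imaginary piecewise-linear curve traced along
#' the apical epithelium; cell depths are measured as the Euclidean
#' distance to its nearest point.
#'
#' @param x,y numeric vectors of ordered vertex coordinates in micrometres
#'   (at least two vertices; consecutive vertices must be distinct).
#' @return An object of class `SurfacePolyline`: a data.frame with columns
#'   `x_um`, `y_um`.
#' @export
surface_polyline <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2)
    stop("validation error: polyline needs at least 2 vertices")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("validation error: non-finite polyline vertex")
  dx <- diff(x); dy <- diff(y)
  if (any(dx == 0 & dy == 0))
    stop("validation error: consecutive polyline vertices must be distinct")
  structure(data.frame(x_um = as.numeric(x), y_um = as.numeric(y)),
            class = c("SurfacePolyline", "data.frame"))
}
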