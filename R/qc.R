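#' Filter spatial cells on negative-probe background and detected features
#'
#' A spatial cell is removed when its mean negative-control probe count
#' exceeds `negprobe_mean_max` (strictly) or it detects fewer than
#' `min_features` biological genes. The two criteria are combined with OR
#' (a cell failing either is removed).
#'
#' @param counts spatial [CountMatrix()] with flagged negative probes.
#' @param meta matching metadata.
#' @param negprobe_mean_max maximum allowed mean negative-probe count
#'   (default 0.5).
#' @param min_features minimum detected biological features (default 20).
#' @return List: `counts` and `meta` restricted to retained cells; `meta`
#'   of removed cells carries `qc_pass = FALSE` with a reason in the
#'   `report$cells` table; `report` lists per-criterion removal counts and
#'   the retained fraction.
#' @export
filter_spatial_cells <- function(counts, meta,
                                 negprobe_mean_max = 0.5,
                                 min_features = 20L) {
  if (ncol(counts$counts) == 0) stop("error: empty count matrix")
  probes <- counts$is_negative_probe
  if (!any(probes)) {
    warning("no negative probes flagged; probe criterion skipped")
    neg_mean <- rep(0, ncol(counts$counts))
  } else {
    neg_mean <- Matrix::colMeans(counts$counts[probes, , drop = FALSE])
  }
  bio <- counts$counts[!probes, , drop = FALSE]
  n_feat <- Matrix::colSums(bio > 0)
  fail_probe <- neg_mean > negprobe_mean_max
  fail_feat <- n_feat < min_features
  keep <- !(fail_probe | fail_feat)
  reason <- rep(NA_character_, length(keep))
  reason[fail_feat] <- "low_features"
  reason[fail_probe] <- "high_negprobe_mean"
  reason[fail_probe & fail_feat] <- "high_negprobe_mean;low_features"
  cells <- data.frame(cell_id = cell_ids(counts), qc_pass = keep,
                      qc_reason = reason, negprobe_mean = neg_mean,
                      n_features = n_feat, stringsAsFactors = FALSE)
  meta <- meta[match(cell_ids(counts), meta$cell_id), , drop = FALSE]
  list(counts = counts[, keep],
       meta = meta[keep, , drop = FALSE],
       report = list(n_input = length(keep),
                     n_removed_negprobe = sum(fail_probe),
                     n_removed_features = sum(fail_feat),
                     n_removed = sum(!keep),
                     retained_fraction = mean(keep),
                     cells = cells))
}

#' Filter reference cells on mitochondrial fraction and detected genes
#'
#' Cells pre-labelled as epithelial are allowed a less stringent
#' mitochondrial cap (default 65% of counts) than other cells.
#'
#' @param counts reference [CountMatrix()].
#' @param meta metadata; an optional `compartment` column identifies
#'   epithelial cells.
#' @param mito_max_pct mitochondrial percentage cap for non-epithelial
#'   cells (default 25).
#' @param mito_max_pct_epithelial cap for epithelial cells (default 65).
#' @param min_genes minimum detected genes per cell (default 200).
#' @param mito_prefix gene-identifier prefix of mitochondrial genes.
#' @return List `counts`, `meta`, `report` as in
#'   [filter_spatial_cells()].
#' @export
filter_reference_cells <- function(counts, meta, mito_max_pct = 25,
                                   mito_max_pct_epithelial = 65,
                                   min_genes = 200L, mito_prefix = "MT-") {
  if (ncol(counts$counts) == 0) stop("error: empty count matrix")
  mito <- startsWith(gene_ids(counts), mito_prefix)
  lib <- Matrix::colSums(counts$counts)
  if (any(mito)) {
    mito_pct <- 100 * Matrix::colSums(counts$counts[mito, , drop = FALSE]) /
      pmax(lib, 1)
  } else {
    warning("no genes match mito_prefix '", mito_prefix,
            "'; mitochondrial filter skipped")
    mito_pct <- rep(0, ncol(counts$counts))
  }
  meta <- meta[match(cell_ids(counts), meta$cell_id), , drop = FALSE]
  epi <- if ("compartment" %in% names(meta))
    !is.na(meta$compartment) & meta$compartment == "epithelium"
  else rep(FALSE, nrow(meta))
  cap <- ifelse(epi, mito_max_pct_epithelial, mito_max_pct)
  n_genes <- Matrix::colSums(counts$counts > 0)
  fail_mito <- mito_pct > cap
  fail_genes <- n_genes < min_genes
  keep <- !(fail_mito | fail_genes)
  reason <- rep(NA_character_, length(keep))
  reason[fail_genes] <- "low_genes"
  reason[fail_mito] <- "high_mito_pct"
  reason[fail_mito & fail_genes] <- "high_mito_pct;low_genes"
  cells <- data.frame(cell_id = cell_ids(counts), qc_pass = keep,
                      qc_reason = reason, mito_pct = mito_pct,
                      n_genes = n_genes, stringsAsFactors = FALSE)
  list(counts = counts[, keep], meta = meta[keep, , drop = FALSE],
       report = list(n_input = length(keep),
                     n_removed_mito = sum(fail_mito),
                     n_removed_genes = sum(fail_genes),
                     n_removed = sum(!keep),
                     n_retained = sum(keep),
                     retained_fraction = mean(keep),
                     cells = cells))
}

#' Default lineage-contamination rules
#'
#' Marker genes that are forbidden within each compartment: a cell
#' labelled epithelial but expressing T-cell receptor complex genes,
#' complement `C1QA` (macrophages), `DERL3` (plasma cells) or `MS4A1`
#' (B cells) is treated as a cross-lineage doublet, and likewise for the
#' other compartments.
#'
#' @return Named list mapping compartment to forbidden gene identifiers.
#' @export
default_lineage_rules <- function() {
  cd3 <- c("CD3D", "CD3E", "CD3G")
  list(epithelium = c(cd3, "C1QA", "DERL3", "MS4A1"),
       plasmas = c(cd3, "C1QA", "EPCAM"),
       stroma = c(cd3, "C1QA", "DERL3", "MS4A1", "EPCAM"),
       tcells = c("DERL3", "MS4A1", "C1QA", "EPCAM", "CD79A"),
       myeloid = c(cd3, "THY1", "DERL3", "MS4A1"))
}

#' Remove cross-lineage contaminated cells
#'
#' Within each compartment, cells whose normalized expression of any
#' forbidden marker for that compartment exceeds `lineage_expr_min` are
#' removed as putative doublets.
#'
#' @param counts [CountMatrix()].
#' @param meta metadata with a populated `compartment` column.
#' @param rules named list compartment -> forbidden genes; defaults to
#'   [default_lineage_rules()].
#' @param lineage_expr_min normalized-expression threshold above which a
#'   forbidden gene counts as expressed (default 0: any detection).
#' @param scale_target library-size target for the internal
#'   normalization.
#' @return List `counts`, `meta`, `report` (removed cells and the gene
#'   that triggered each removal).
#' @export
lineage_contamination_filter <- function(counts, meta,
                                         rules = default_lineage_rules(),
                                         lineage_expr_min = 0,
                                         scale_target = 1e4) {
  meta <- meta[match(cell_ids(counts), meta$cell_id), , drop = FALSE]
  if (!"compartment" %in% names(meta) || all(is.na(meta$compartment)))
    stop("error: compartment labels required for lineage filtering")
  if (length(rules) == 0) {
    return(list(counts = counts, meta = meta,
                report = list(n_removed = 0, removed = data.frame(
                  cell_id = character(0), compartment = character(0),
                  gene = character(0)))))
  }
  norm <- lognormalize(counts, scale_target = scale_target)
  removed <- list()
  for (comp in names(rules)) {
    in_comp <- !is.na(meta$compartment) & meta$compartment == comp
    if (!any(in_comp)) next
    genes <- rules[[comp]]
    missing <- setdiff(genes, rownames(norm))
    if (length(missing)) {
      warning("lineage rule gene(s) absent from matrix, skipped: ",
              paste(missing, collapse = ", "))
      genes <- setdiff(genes, missing)
    }
    if (!length(genes)) next
    sub <- norm[genes, in_comp, drop = FALSE]
    hit <- sub > lineage_expr_min
    any_hit <- Matrix::colSums(hit) > 0
    if (any(any_hit)) {
      first_gene <- apply(as.matrix(hit[, any_hit, drop = FALSE]), 2,
                          function(z) genes[which(z)[1]])
      removed[[comp]] <- data.frame(
        cell_id = colnames(sub)[any_hit], compartment = comp,
        gene = unname(first_gene), stringsAsFactors = FALSE)
    }
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(cell_id = character(0), compartment = character(0),
               gene = character(0), stringsAsFactors = FALSE)
  keep <- !cell_ids(counts) %in% removed$cell_id
  list(counts = counts[, keep], meta = meta[keep, , drop = FALSE],
       report = list(n_removed = sum(!keep), removed = removed))
}

#' Drop immunoglobulin genes outside the B/plasma compartment
#'
#' Immunoglobulin transcripts ambiently contaminate non-B lineages; they
#' are removed from every compartment except B/plasma cells.
#'
#' @param counts [CountMatrix()].
#' @param compartment the compartment this matrix represents.
#' @param ig_prefixes identifier prefixes of immunoglobulin genes.
#' @return [CountMatrix()] without IG rows (unchanged for `plasmas`).
#' @export
remove_ig_genes <- function(counts, compartment,
                            ig_prefixes = c("IGH", "IGK", "IGL")) {
  if (compartment %in% c("plasmas", "B")) return(counts)
  ig <- Reduce(`|`, lapply(ig_prefixes, startsWith, x = gene_ids(counts)))
  if (!any(ig)) return(counts)
  counts[!ig, ]
}
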