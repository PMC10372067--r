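#' Expression-bin-matched module score
#'
#' Scores each cell for a gene set as the mean expression of the set
#' minus the mean expression of control genes matched on average
#' expression: genes are cut into `n_bins` equal-frequency bins by their
#' mean across cells and, for every set gene, `n_ctrl` control genes are
#' sampled with replacement from its bin (excluding set genes). The
#' control term per set gene is the mean of its control draw; the cell
#' score is the set mean minus the average of these control terms.
#'
#' @param norm genes x cells normalized matrix.
#' @param gene_set character vector of set genes (absent genes dropped
#'   with a warning; an entirely absent set is an error).
#' @param n_bins number of average-expression bins (default 24).
#' @param n_ctrl control genes sampled per set gene (default 100).
#' @param seed integer seed making the control draw reproducible.
#' @param ctrl_mode `"sample"` (default) or `"full_bin"`, which uses
#'   every gene of the bin as control (deterministic; set genes are not
#'   excluded, so a set equal to all genes scores exactly 0).
#' @return Named numeric vector: one score per cell.
#' @export
module_score <- function(norm, gene_set, n_bins = 24L, n_ctrl = 100L,
                         seed = 0L, ctrl_mode = c("sample", "full_bin")) {
  ctrl_mode <- match.arg(ctrl_mode)
  if (!length(gene_set)) stop("error: empty gene set")
  gene_set <- unique(gene_set)
  absent <- setdiff(gene_set, rownames(norm))
  if (length(absent) == length(gene_set))
    stop("error: no gene of the set is present in the matrix")
  if (length(absent)) {
    warning("dropping ", length(absent), " set gene(s) absent from matrix")
    gene_set <- setdiff(gene_set, absent)
  }
  avg <- Matrix::rowMeans(norm)
  n_bins <- min(n_bins, nrow(norm))
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins,
             labels = FALSE)
  names(bin) <- rownames(norm)
  set_mean <- Matrix::colMeans(norm[gene_set, , drop = FALSE])
  set.seed(derive_seed(seed, "module_score"))
  ctrl_terms <- matrix(0, length(gene_set), ncol(norm))
  for (i in seq_along(gene_set)) {
    g <- gene_set[i]
    pool <- names(bin)[bin == bin[g]]
    if (ctrl_mode == "sample") {
      pool <- setdiff(pool, gene_set)
      if (!length(pool)) pool <- names(bin)[bin == bin[g]]
      ctrl <- sample(pool, n_ctrl, replace = TRUE)
    } else {
      ctrl <- pool
    }
    ctrl_terms[i, ] <- Matrix::colMeans(
      norm[match(ctrl, rownames(norm)), , drop = FALSE])
  }
  score <- set_mean - colMeans(ctrl_terms)
  stats::setNames(as.numeric(score), colnames(norm))
}
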