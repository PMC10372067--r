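#' Reference-to-query label transfer by rank correlation
#'
#' Marker-driven label transfer in the style of correlation-based
#' annotators: (1) per-label markers are detected on the reference
#' (positive log-fold changes, optionally blocked by sample) and the top
#' `top_n` per label retained; (2) the working gene space is the union of
#' the marker lists intersected with the query genes; (3) every query
#' cell is Spearman-correlated with every reference cell on that space;
#' (4) the per-label score of a query cell is the `score_quantile`
#' quantile of its correlations to that label's cells; (5) the assigned
#' label maximizes the score (ties broken lexicographically).
#'
#' Rank correlation makes the result invariant to any monotone per-cell
#' transformation of the query expression, so raw and log-scale query
#' inputs are equivalent.
#'
#' @param ref_norm reference genes x cells normalized matrix.
#' @param ref_labels per-reference-cell labels.
#' @param query_norm query genes x cells matrix (any monotone scale).
#' @param ref_samples optional per-reference-cell sample ids; when given,
#'   marker detection blocks by sample.
#' @param top_n markers retained per label (default 100).
#' @param score_quantile quantile aggregating per-label correlations
#'   (default 0.8).
#' @param min_overlap minimum working-space size (default 20).
#' @param markers optional precomputed named list label -> marker genes,
#'   bypassing marker detection.
#' @param chunk_size query cells correlated per block.
#' @return List of class `LabelTransferResult`: `assignment` data.frame
#'   (`cell_id`, `label`, `score`, `margin`, `reason`), `scores` query x
#'   label matrix, `working_genes`.
#' @export
transfer_labels <- function(ref_norm, ref_labels, query_norm,
                            ref_samples = NULL, top_n = 100L,
                            score_quantile = 0.8, min_overlap = 20L,
                            markers = NULL, chunk_size = 1000L) {
  ref_labels <- as.character(ref_labels)
  stopifnot(length(ref_labels) == ncol(ref_norm))
  labels <- sort(unique(ref_labels))
  if (length(labels) < 2)
    stop("error: label transfer needs at least 2 reference labels")
  if (is.null(markers)) {
    mt <- find_markers(ref_norm, ref_labels, positive_only = TRUE,
                       block_by_sample = !is.null(ref_samples),
                       samples = ref_samples)
    markers <- top_markers(mt, n = top_n)
  }
  working <- intersect(unique(unlist(markers)), rownames(query_norm))
  working <- intersect(working, rownames(ref_norm))
  if (length(working) < min_overlap)
    stop("error: only ", length(working), " marker genes overlap the ",
         "query panel (need >= ", min_overlap, "); check panel compatibility")
  rmat <- as.matrix(ref_norm[working, , drop = FALSE])
  qmat <- as.matrix(query_norm[working, , drop = FALSE])
  rank_cols <- function(m) apply(m, 2, rank)
  rr <- rank_cols(rmat)
  qvar <- apply(qmat, 2, function(v) stats::var(v) > 0)
  scores <- matrix(NA_real_, ncol(qmat), length(labels),
                   dimnames = list(colnames(qmat), labels))
  label_cols <- lapply(labels, function(l) which(ref_labels == l))
  idx_ok <- which(qvar)
  for (start in seq(1, length(idx_ok), by = chunk_size)) {
    j <- idx_ok[start:min(start + chunk_size - 1, length(idx_ok))]
    qr <- rank_cols(qmat[, j, drop = FALSE])
    cors <- stats::cor(qr, rr)
    for (k in seq_along(labels)) {
      scores[j, k] <- apply(cors[, label_cols[[k]], drop = FALSE], 1,
                            stats::quantile, probs = score_quantile,
                            names = FALSE)
    }
  }
  assigned <- rep(NA_character_, ncol(qmat))
  best <- rep(NA_real_, ncol(qmat))
  margin <- rep(NA_real_, ncol(qmat))
  reason <- rep(NA_character_, ncol(qmat))
  for (j in seq_len(ncol(qmat))) {
    if (!qvar[j]) {
      assigned[j] <- "unassigned"
      reason[j] <- "zero-variance query cell on working gene space"
      next
    }
    s <- scores[j, ]
    k <- which.max(s)          # labels sorted: first max = lexicographic
    assigned[j] <- labels[k]
    best[j] <- s[k]
    margin[j] <- if (length(s) > 1) s[k] - max(s[-k]) else 0
  }
  structure(list(
    assignment = data.frame(cell_id = colnames(qmat), label = assigned,
                            score = best, margin = margin, reason = reason,
                            stringsAsFactors = FALSE),
    scores = scores, working_genes = working, markers = markers),
    class = "LabelTransferResult")
}

#' Two-pass compartment-then-subtype annotation
#'
#' Pass 1 transfers the five coarse compartment labels from the reference
#' to the query. Pass 2 restricts reference and query to each assigned
#' compartment and re-runs marker detection and transfer at subtype
#' resolution, so subtypes can only be assigned within their own
#' compartment. A compartment with fewer than two reference subtypes
#' contributes its own name as the subtype.
#'
#' @param ref_norm reference genes x cells normalized matrix.
#' @param ref_meta reference metadata with `compartment` and `subtype`
#'   (and optionally `sample_id` for blocked marker detection).
#' @param query_norm query genes x cells matrix.
#' @param top_n markers per label (default 100).
#' @param ... passed on to [transfer_labels()].
#' @return data.frame per query cell: `cell_id`, `compartment`,
#'   `compartment_score`, `subtype`, `subtype_score`.
#' @export
two_pass_annotation <- function(ref_norm, ref_meta, query_norm,
                                top_n = 100L, ...) {
  ref_meta <- ref_meta[match(colnames(ref_norm), ref_meta$cell_id), ,
                       drop = FALSE]
  if (anyNA(ref_meta$compartment) || anyNA(ref_meta$subtype))
    stop("error: reference metadata needs compartment and subtype labels")
  samples <- if ("sample_id" %in% names(ref_meta)) ref_meta$sample_id
  pass1 <- transfer_labels(ref_norm, ref_meta$compartment, query_norm,
                           ref_samples = samples, top_n = top_n, ...)
  out <- data.frame(cell_id = colnames(query_norm),
                    compartment = pass1$assignment$label,
                    compartment_score = pass1$assignment$score,
                    subtype = NA_character_, subtype_score = NA_real_,
                    stringsAsFactors = FALSE)
  for (comp in sort(unique(ref_meta$compartment))) {
    q_cells <- which(out$compartment == comp)
    if (!length(q_cells)) next
    r_cells <- which(ref_meta$compartment == comp)
    subtypes <- unique(ref_meta$subtype[r_cells])
    if (length(subtypes) < 2) {
      out$subtype[q_cells] <- comp
      out$subtype_score[q_cells] <- out$compartment_score[q_cells]
      next
    }
    pass2 <- transfer_labels(ref_norm[, r_cells, drop = FALSE],
                             ref_meta$subtype[r_cells],
                             query_norm[, q_cells, drop = FALSE],
                             ref_samples = if (!is.null(samples))
                               samples[r_cells],
                             top_n = top_n, ...)
    out$subtype[q_cells] <- pass2$assignment$label
    out$subtype_score[q_cells] <- pass2$assignment$score
  }
  out$subtype[out$compartment == "unassigned"] <- "unassigned"
  out
}
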