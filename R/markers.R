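#' Exact two-sided Wilcoxon rank-sum p by enumeration
#'
#' Enumerates every assignment of group labels to the pooled sample
#' (handling ties through midranks) and doubles the smaller tail of the
#' rank-sum statistic. Used when both groups have at most 8 observations.
#'
#' @param x pooled numeric values.
#' @param in_group logical vector marking group-1 membership.
#' @return Two-sided p-value.
#' @export
wilcox_exact_p <- function(x, in_group) {
  n <- length(x)
  n1 <- sum(in_group)
  r <- rank(x)
  obs <- sum(r[in_group])
  combs <- utils::combn(n, n1)
  W <- colSums(matrix(r[combs], nrow = n1))
  lo <- mean(W <= obs)
  hi <- mean(W >= obs)
  min(1, 2 * min(lo, hi))
}

# Tie-corrected normal-approximation z for the rank-sum statistic of the
# cells indexed by j1 within one gene's pooled values.
.rank_sum_z <- function(x, j1) {
  n <- length(x)
  n1 <- length(j1)
  n2 <- n - n1
  r <- rank(x)
  W <- sum(r[j1])
  mu <- n1 * (n + 1) / 2
  tb <- tabulate(match(x, unique(x)))
  tie <- sum(tb^3 - tb)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie / (n * (n - 1)))
  if (sigma2 <= 0) return(0)
  (W - mu) / sqrt(sigma2)
}

#' Per-cluster marker detection by Wilcoxon rank-sum
#'
#' Each cluster is compared to all remaining cells. Genes are
#' pre-filtered to those detected in at least `min_pct` of either group
#' and with `|log2 FC| >= logfc_min`; surviving genes are tested with a
#' two-sided Wilcoxon rank-sum (tie-corrected normal approximation, or
#' exact enumeration when both groups have at most 8 cells) and adjusted
#' by Benjamini-Hochberg within each cluster. Fold changes are ratios of
#' de-logged normalized means with a pseudocount of `pseudocount` in
#' numerator and denominator.
#'
#' With `block_by_sample = TRUE` the test statistic is computed per
#' sample and combined by Stouffer's method weighted by sample size, so
#' that a sample-specific shift cannot masquerade as a marker.
#'
#' @param norm genes x cells matrix of log-normalized expression.
#' @param clusters per-cell cluster labels (named by cell or aligned to
#'   columns).
#' @param min_pct detection-fraction pre-filter (default 0.25).
#' @param logfc_min minimum absolute log2 fold change (default 0.25).
#' @param block_by_sample combine per-sample tests by Stouffer's method.
#' @param samples per-cell sample identifiers (required when blocking).
#' @param positive_only keep only genes elevated in the cluster.
#' @param pseudocount pseudocount on the de-logged means (default 0.01).
#' @param exact_max largest group size for exact enumeration (default 8).
#' @return `MarkerTable` data.frame: `cluster`, `gene`, `fc`, `log2fc`,
#'   `pct_in`, `pct_out`, `p_raw`, `p_adj`, `rank` (within cluster, by
#'   ascending `p_adj` then descending `|log2fc|`, ties broken by gene
#'   id).
#' @export
find_markers <- function(norm, clusters, min_pct = 0.25, logfc_min = 0.25,
                         block_by_sample = FALSE, samples = NULL,
                         positive_only = FALSE, pseudocount = 0.01,
                         exact_max = 8L) {
  clusters <- as.character(clusters)
  stopifnot(length(clusters) == ncol(norm))
  if (block_by_sample && is.null(samples))
    stop("error: samples required when block_by_sample = TRUE")
  cl_levels <- sort(unique(clusters))
  if (length(cl_levels) < 2)
    stop("error: marker detection needs at least 2 clusters")
  detected <- norm > 0
  expr <- norm
  expr@x <- expm1(expr@x)
  out <- list()
  for (cl in cl_levels) {
    j1 <- which(clusters == cl)
    j2 <- which(clusters != cl)
    if (length(j1) < 3) {
      warning("cluster '", cl, "' has fewer than 3 cells; skipped")
      next
    }
    pct_in <- Matrix::rowMeans(detected[, j1, drop = FALSE])
    pct_out <- Matrix::rowMeans(detected[, j2, drop = FALSE])
    mean_in <- Matrix::rowMeans(expr[, j1, drop = FALSE])
    mean_out <- Matrix::rowMeans(expr[, j2, drop = FALSE])
    fc <- (mean_in + pseudocount) / (mean_out + pseudocount)
    log2fc <- log2(fc)
    keep <- (pct_in >= min_pct | pct_out >= min_pct) &
      abs(log2fc) >= logfc_min
    if (positive_only) keep <- keep & log2fc > 0
    genes <- rownames(norm)[keep]
    if (!length(genes)) next
    sub <- as.matrix(norm[genes, , drop = FALSE])
    if (!block_by_sample) {
      if (length(j1) <= exact_max && length(j2) <= exact_max) {
        in_group <- seq_len(ncol(sub)) %in% j1
        p <- apply(sub, 1, wilcox_exact_p, in_group = in_group)
      } else {
        z <- apply(sub, 1, .rank_sum_z, j1 = j1)
        p <- 2 * stats::pnorm(-abs(z))
      }
    } else {
      sam <- as.character(samples)
      zmat <- sapply(sort(unique(sam)), function(s) {
        js <- which(sam == s)
        js1 <- intersect(js, j1)
        js2 <- intersect(js, j2)
        if (length(js1) < 2 || length(js2) < 2)
          return(rep(NA_real_, length(genes)))
        apply(sub[, js, drop = FALSE], 1, .rank_sum_z,
              j1 = match(js1, js))
      })
      zmat <- matrix(zmat, nrow = length(genes))
      wts <- vapply(sort(unique(sam)), function(s) sum(sam == s), 1)
      z <- apply(zmat, 1, function(zz) {
        ok <- !is.na(zz)
        if (!any(ok)) return(NA_real_)
        sum(wts[ok] * zz[ok]) / sqrt(sum(wts[ok]^2))
      })
      p <- 2 * stats::pnorm(-abs(z))
    }
    p_adj <- stats::p.adjust(p, method = "BH")
    tbl <- data.frame(cluster = cl, gene = genes, fc = fc[keep],
                      log2fc = log2fc[keep], pct_in = pct_in[keep],
                      pct_out = pct_out[keep], p_raw = p, p_adj = p_adj,
                      row.names = NULL, stringsAsFactors = FALSE)
    ord <- order(tbl$p_adj, -abs(tbl$log2fc), tbl$gene)
    tbl <- tbl[ord, , drop = FALSE]
    tbl$rank <- seq_len(nrow(tbl))
    out[[cl]] <- tbl
  }
  if (!length(out))
    stop("error: no testable cluster")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call regulated genes from a marker or DEG table
#'
#' A gene is regulated when its FDR-adjusted p-value is below `p_max`
#' and its fold change exceeds `fc_up` (up) or falls below `fc_down`
#' (down); both inequalities are strict.
#'
#' @param table data.frame with columns `gene`, `fc`, `p_adj`.
#' @param p_max adjusted-p cutoff (default 0.05).
#' @param fc_up,fc_down ratio-scale fold-change cutoffs (defaults 1.2 and
#'   0.83).
#' @return Subset of `table` with a `direction` column (`up`/`down`).
#' @export
call_regulated_genes <- function(table, p_max = 0.05, fc_up = 1.2,
                                 fc_down = 0.83) {
  stopifnot(all(c("fc", "p_adj") %in% names(table)))
  up <- table$p_adj < p_max & table$fc > fc_up
  down <- table$p_adj < p_max & table$fc < fc_down
  out <- table[up | down, , drop = FALSE]
  out$direction <- ifelse(out$fc > fc_up, "up", "down")
  rownames(out) <- NULL
  out
}

#' Jaccard matching of per-cluster marker lists
#'
#' Computes `J(A, B) = |A ∩ B| / |A ∪ B|` for every pair of clusters
#' from two datasets' top-marker lists; high values indicate
#' corresponding cell types.
#'
#' @param markers_a,markers_b named lists of (deduplicated) marker gene
#'   vectors per cluster.
#' @return List: `jaccard` matrix (rows = clusters of `markers_a`),
#'   `best_match` data.frame with the argmax per row (ties broken by
#'   cluster name order).
#' @export
jaccard_match <- function(markers_a, markers_b) {
  if (!length(markers_a) || !length(markers_b))
    stop("error: empty marker list collection")
  markers_a <- lapply(markers_a, unique)
  markers_b <- lapply(markers_b, unique)
  if (any(!vapply(c(markers_a, markers_b), length, 1L)))
    stop("error: empty marker list")
  J <- matrix(0, length(markers_a), length(markers_b),
              dimnames = list(names(markers_a), names(markers_b)))
  for (i in seq_along(markers_a)) {
    for (j in seq_along(markers_b)) {
      a <- markers_a[[i]]; b <- markers_b[[j]]
      J[i, j] <- length(intersect(a, b)) / length(union(a, b))
    }
  }
  cols <- colnames(J)[order(colnames(J))]
  best <- apply(J[, cols, drop = FALSE], 1, function(r)
    cols[which.max(r)])
  list(jaccard = J,
       best_match = data.frame(cluster = rownames(J), match = unname(best),
                               jaccard = J[cbind(rownames(J), unname(best))],
                               stringsAsFactors = FALSE))
}

#' Top-N marker gene lists from a MarkerTable
#'
#' @param markers a `MarkerTable` from [find_markers()].
#' @param n list length per cluster.
#' @return Named list of gene vectors ordered by within-cluster rank.
#' @export
top_markers <- function(markers, n = 100L) {
  lapply(split(markers, markers$cluster), function(d)
    utils::head(d$gene[order(d$rank)], n))
}
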