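#' Library-size log-normalization
#'
#' Each count is scaled to a common library-size target and
#' log-transformed: `log(1 + count * scale_target / library)`, with the
#' natural logarithm by default and a configurable base.
#'
#' @param counts [CountMatrix()] or genes x cells matrix.
#' @param scale_target library-size target (default 10,000).
#' @param base logarithm base (default `exp(1)`).
#' @param size_factors optional per-cell size factors replacing raw
#'   library sizes, e.g. from [rescale_to_lowest_coverage()]; counts are
#'   divided by `size_factors * scale_target^-1` equivalents so that
#'   value = `log(1 + count * scale_target / (lib * factor))` when factors
#'   are relative, or directly `log(1 + count / size_factor)` when
#'   `scale_target = NULL`.
#' @return Sparse genes x cells matrix of normalized expression.
#' @export
lognormalize <- function(counts, scale_target = 1e4, base = exp(1),
                         size_factors = NULL) {
  m <- if (inherits(counts, "CountMatrix")) counts$counts else counts
  if (is.null(size_factors)) {
    lib <- Matrix::colSums(m)
    zero <- lib == 0
    if (any(zero))
      stop("error: zero library size for cell(s): ",
           paste(utils::head(colnames(m)[zero], 3), collapse = ", "))
    denom <- lib / scale_target
  } else {
    if (any(size_factors <= 0))
      stop("error: size factors must be positive")
    denom <- size_factors
  }
  out <- m %*% Matrix::Diagonal(x = 1 / denom)
  out@x <- log1p(out@x)
  if (!isTRUE(all.equal(base, exp(1)))) out@x <- out@x / log(base)
  dimnames(out) <- dimnames(m)
  methods::as(out, "CsparseMatrix")
}

#' Size factors rescaling every sample to the lowest-coverage sample
#'
#' Per-cell size factor = (cell library / its sample's mean library) x
#' (sample mean library / minimum sample mean library). After dividing
#' counts by these factors, every sample's mean normalized coverage
#' equals that of the lowest-coverage sample, making samples of unequal
#' depth comparable.
#'
#' @param counts [CountMatrix()].
#' @param meta metadata with `sample_id`.
#' @return Named numeric vector of positive per-cell size factors.
#' @export
rescale_to_lowest_coverage <- function(counts, meta) {
  meta <- meta[match(cell_ids(counts), meta$cell_id), , drop = FALSE]
  lib <- Matrix::colSums(counts$counts)
  sample_mean <- tapply(lib, meta$sample_id, mean)
  if (any(sample_mean == 0))
    stop("error: sample with zero mean library: ",
         paste(names(sample_mean)[sample_mean == 0], collapse = ", "))
  ref <- min(sample_mean)
  f <- as.numeric(lib / ref)
  stats::setNames(f, cell_ids(counts))
}

#' Model per-gene variance and select highly variable genes
#'
#' For each sample (when `block_by_sample`), per-gene means and variances
#' of normalized expression are computed and a smooth non-negative
#' technical trend is fit to variance ~ mean by local regression. The
#' biological component of a gene is its variance minus the trend value
#' at its mean; components are averaged (unweighted) across samples and
#' genes with a positive combined biological component form the HVG set,
#' ordered by decreasing component.
#'
#' @param norm normalized genes x cells matrix.
#' @param meta metadata with `sample_id` (ignored when
#'   `block_by_sample = FALSE`).
#' @param block_by_sample model each sample separately and combine.
#' @param span loess span of the mean-variance trend (default 0.3).
#' @return List: `stats` data.frame (gene, mean, total, tech, bio =
#'   combined biological component), `per_sample` list of per-sample
#'   data.frames, `hvgs` character vector.
#' @export
model_gene_variance <- function(norm, meta = NULL, block_by_sample = TRUE,
                                span = 0.3) {
  if (nrow(norm) < 10)
    stop("error: fewer than 10 genes; cannot fit mean-variance trend")
  blocks <- if (block_by_sample) {
    if (is.null(meta)) stop("error: meta required when blocking by sample")
    meta <- meta[match(colnames(norm), meta$cell_id), , drop = FALSE]
    split(seq_len(ncol(norm)), meta$sample_id)
  } else {
    list(all = seq_len(ncol(norm)))
  }
  small <- vapply(blocks, length, 1L) < 2
  if (any(small))
    stop("error: sample(s) with fewer than 2 cells: ",
         paste(names(blocks)[small], collapse = ", "))
  per_sample <- lapply(blocks, function(j) {
    x <- norm[, j, drop = FALSE]
    n <- length(j)
    mu <- Matrix::rowMeans(x)
    v <- (Matrix::rowSums(x^2) - n * mu^2) / (n - 1)
    fit <- stats::loess(v ~ mu, span = span, degree = 2,
                        family = "symmetric")
    tech <- pmax(unname(stats::fitted(fit)), 0)
    data.frame(gene = rownames(norm), mean = mu, total = v, tech = tech,
               bio = v - tech, row.names = NULL, stringsAsFactors = FALSE)
  })
  bio <- rowMeans(vapply(per_sample, function(d) d$bio,
                         numeric(nrow(norm))))
  mu <- rowMeans(vapply(per_sample, function(d) d$mean,
                        numeric(nrow(norm))))
  total <- rowMeans(vapply(per_sample, function(d) d$total,
                           numeric(nrow(norm))))
  stats_df <- data.frame(gene = rownames(norm), mean = mu, total = total,
                         tech = total - bio, bio = bio,
                         row.names = NULL, stringsAsFactors = FALSE)
  hvgs <- stats_df$gene[stats_df$bio > 0]
  hvgs <- hvgs[order(-stats_df$bio[stats_df$bio > 0])]
  list(stats = stats_df, per_sample = per_sample, hvgs = hvgs)
}

#' Per-cluster sample-composition entropy
#'
#' For each cluster, with `p_i` the proportion of its cells contributed
#' by sample i, the entropy is `H = 1 - sum(p_i^2)` (the complement of
#' the Simpson index). H is 0 when a cluster is private to one sample and
#' at most `1 - 1/S` over S samples (attained at uniform contribution);
#' clusters with low H are candidate batch artifacts.
#'
#' @param clusters per-cell cluster assignment.
#' @param samples per-cell sample identifiers (same length).
#' @param flag_below clusters with `H` strictly below this value are
#'   flagged (default 0.2).
#' @return data.frame per cluster: `cluster`, `n_cells`, `H`, `flagged`;
#'   attribute `proportions` holds the per-cluster sample proportions.
#' @export
cluster_entropy <- function(clusters, samples, flag_below = 0.2) {
  stopifnot(length(clusters) == length(samples))
  if (anyNA(clusters) || anyNA(samples))
    stop("error: every cell needs a cluster and a sample")
  cl <- sort(unique(as.character(clusters)))
  props <- list()
  H <- numeric(length(cl))
  n <- integer(length(cl))
  for (i in seq_along(cl)) {
    in_cl <- clusters == cl[i]
    n[i] <- sum(in_cl)
    if (n[i] == 0) {
      warning("empty cluster skipped: ", cl[i])
      H[i] <- NA_real_
      next
    }
    p <- table(samples[in_cl]) / n[i]
    props[[cl[i]]] <- as.numeric(p)
    H[i] <- 1 - sum(p^2)
  }
  out <- data.frame(cluster = cl, n_cells = n, H = H,
                    flagged = !is.na(H) & H < flag_below,
                    stringsAsFactors = FALSE)
  attr(out, "proportions") <- props
  out
}
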