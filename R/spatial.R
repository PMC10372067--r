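# Silverman's rule of thumb, 0.9 min(sd, IQR/1.34) n^(-1/5); degenerate
# (zero-spread) samples are floored at `floor_um` with a warning rather
# than inheriting bw.nrd0's |x|-based fallback.
.silverman_bw <- function(v, floor_um = 1) {
  spread <- min(stats::sd(v), stats::IQR(v) / 1.34)
  bw <- 0.9 * spread * length(v)^(-0.2)
  if (!is.finite(bw) || bw <= 0) {
    warning("degenerate point spread; bandwidth floored at ",
            floor_um, " um")
    bw <- floor_um
  }
  max(bw, floor_um)
}

# Gaussian product-kernel KDE of points (x, y) on an n x n lattice over
# `lims` = c(xmin, xmax, ymin, ymax). MASS::kde2d treats its `h` as four
# times the kernel standard deviation, hence the 4 * bandwidth below.
.kde_grid <- function(x, y, bw, n, lims) {
  MASS::kde2d(x, y, h = 4 * bw, n = n, lims = lims)$z
}

#' Kernel-density co-localization scores per sample, FoV and type pair
#'
#' For every sample, FoV and unordered pair of cell types with more than
#' `min_cells` cells each, two-dimensional Gaussian kernel density
#' estimates of the two types' cell centroids are evaluated on a shared
#' `grid_n` x `grid_n` lattice spanning the union bounding box of the
#' two point sets (padded by one bandwidth per side), and the score is
#' the Pearson correlation of the two flattened density grids: 1 for
#' identical patterns, near 0 for independent placement, negative for
#' mutual exclusion.
#'
#' @param meta spatial metadata with `sample_id`, `fov_id`, `x_um`,
#'   `y_um` and a type column.
#' @param type_col name of the column holding the cell-type label.
#' @param grid_n grid resolution per axis (default 64).
#' @param bandwidth `NULL` for per-type, per-axis Silverman bandwidths,
#'   or a single shared value in micrometres.
#' @param min_cells validity threshold; both types must exceed it
#'   (strictly; default 10).
#' @param bandwidth_floor lower bound on the bandwidth in micrometres.
#' @return data.frame of `ColocRecord`s: `sample_id`, `fov_id`,
#'   `type_a`, `type_b` (`type_a` < `type_b`), `n_a`, `n_b`, `valid`,
#'   `score` (NA when invalid).
#' @export
colocalization_scores <- function(meta, type_col = "subtype", grid_n = 64L,
                                  bandwidth = NULL, min_cells = 10L,
                                  bandwidth_floor = 1) {
  need <- c("sample_id", "fov_id", "x_um", "y_um", type_col)
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("error: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(meta$x_um) || anyNA(meta$fov_id))
    stop("error: every cell needs FoV and centroid")
  out <- list()
  for (key in split(seq_len(nrow(meta)),
                    paste(meta$sample_id, meta$fov_id, sep = "\r"))) {
    sub <- meta[key, , drop = FALSE]
    types <- sort(unique(sub[[type_col]]))
    if (length(types) < 2) next
    pts <- split(seq_len(nrow(sub)), sub[[type_col]])
    dens_cache <- new.env(parent = emptyenv())
    for (ia in seq_len(length(types) - 1)) {
      for (ib in (ia + 1):length(types)) {
        a <- types[ia]; b <- types[ib]
        ja <- pts[[a]]; jb <- pts[[b]]
        n_a <- length(ja); n_b <- length(jb)
        valid <- n_a > min_cells && n_b > min_cells
        score <- NA_real_
        if (valid) {
          xa <- sub$x_um[ja]; ya <- sub$y_um[ja]
          xb <- sub$x_um[jb]; yb <- sub$y_um[jb]
          if (is.null(bandwidth)) {
            bwa <- c(.silverman_bw(xa, bandwidth_floor),
                     .silverman_bw(ya, bandwidth_floor))
            bwb <- c(.silverman_bw(xb, bandwidth_floor),
                     .silverman_bw(yb, bandwidth_floor))
          } else {
            bwa <- bwb <- rep(bandwidth, 2)
          }
          pad <- pmax(bwa, bwb)
          lims <- c(min(xa, xb) - pad[1], max(xa, xb) + pad[1],
                    min(ya, yb) - pad[2], max(ya, yb) + pad[2])
          za <- .kde_grid(xa, ya, bwa, grid_n, lims)
          zb <- .kde_grid(xb, yb, bwb, grid_n, lims)
          score <- stats::cor(as.vector(za), as.vector(zb))
        }
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sub$sample_id[1], fov_id = sub$fov_id[1],
          type_a = a, type_b = b, n_a = n_a, n_b = n_b,
          valid = valid, score = score, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), fov_id = character(0),
                      type_a = character(0), type_b = character(0),
                      n_a = integer(0), n_b = integer(0),
                      valid = logical(0), score = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pool co-localization records by type pair and disease group
#'
#' @param records output of [colocalization_scores()].
#' @param groups optional named vector mapping `sample_id` to disease
#'   group; when omitted all samples pool into one group.
#' @return data.frame per (group, type pair): `n_fov` valid FoVs,
#'   `mean_score`, `median_score`, `sd_score`.
#' @export
summarize_colocalization <- function(records, groups = NULL) {
  if (!any(records$valid))
    return(data.frame(group = character(0), type_a = character(0),
                      type_b = character(0), n_fov = integer(0),
                      mean_score = numeric(0), median_score = numeric(0),
                      sd_score = numeric(0)))
  rec <- records[records$valid, , drop = FALSE]
  rec$group <- if (is.null(groups)) "all" else
    as.character(groups[rec$sample_id])
  keys <- split(rec, list(rec$group, rec$type_a, rec$type_b), drop = TRUE)
  out <- do.call(rbind, lapply(keys, function(d) data.frame(
    group = d$group[1], type_a = d$type_a[1], type_b = d$type_b[1],
    n_fov = nrow(d), mean_score = mean(d$score),
    median_score = stats::median(d$score), sd_score = stats::sd(d$score),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$group, -out$mean_score), , drop = FALSE]
}

#' Distance from each point to a polyline
#'
#' Minimum over segments of the clamped point-to-segment Euclidean
#' distance; degenerate zero-length segments are skipped.
#'
#' @param x,y point coordinates.
#' @param poly a [surface_polyline()].
#' @return Numeric vector of distances (micrometres).
#' @export
point_polyline_distance <- function(x, y, poly) {
  px <- poly$x_um; py <- poly$y_um
  best <- rep(Inf, length(x))
  for (s in seq_len(length(px) - 1)) {
    dx <- px[s + 1] - px[s]; dy <- py[s + 1] - py[s]
    len2 <- dx * dx + dy * dy
    if (len2 == 0) next
    t <- pmin(pmax(((x - px[s]) * dx + (y - py[s]) * dy) / len2, 0), 1)
    d2 <- (x - (px[s] + t * dx))^2 + (y - (py[s] + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Distance of every cell to the mucosal surface, with summaries
#'
#' Computes each cell's Euclidean distance to the nearest point of the
#' surface polyline and summarises distances per (cluster, group) for
#' clusters with at least `min_cells` cells in that stratum.
#'
#' @param meta spatial metadata with centroids and a type column.
#' @param poly a [surface_polyline()].
#' @param type_col cell-type column name (default `subtype`).
#' @param min_cells minimum cells for a summary row (default 10).
#' @return List: `distances` (per-cell data.frame with `distance_um`),
#'   `summary` (`DistanceSummary` rows: cluster, group, n_cells, min,
#'   mean, median, max, sd).
#' @export
distance_to_surface <- function(meta, poly, type_col = "subtype",
                                min_cells = 10L) {
  if (anyNA(meta$x_um)) stop("error: cells without centroid")
  d <- point_polyline_distance(meta$x_um, meta$y_um, poly)
  distances <- data.frame(cell_id = meta$cell_id, cluster = meta[[type_col]],
                          group = meta$group, distance_um = d,
                          stringsAsFactors = FALSE)
  strata <- split(distances, list(distances$cluster, distances$group),
                  drop = TRUE)
  rows <- lapply(strata, function(s) {
    if (nrow(s) < min_cells) return(NULL)
    data.frame(cluster = s$cluster[1], group = s$group[1],
               n_cells = nrow(s), min = min(s$distance_um),
               mean = mean(s$distance_um),
               median = stats::median(s$distance_um),
               max = max(s$distance_um), sd = stats::sd(s$distance_um),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (!is.null(summary)) rownames(summary) <- NULL
  list(distances = distances, summary = summary)
}

#' Detect composition neighborhoods by k-NN profiles and k-means
#'
#' For every cell, the composition vector is the cell-type frequency
#' among its `k` nearest neighbours (Euclidean on centroids) within the
#' same sample and FoV. Vectors are pooled across samples and clustered
#' with k-means into `K` neighborhoods (seeded, `nstart` restarts).
#' Cells in FoVs with at most `k` cells are left unassigned with a
#' warning. The procedure itself (k-NN composition + k-means) is a
#' package design choice for recovering recurring multicellular domains.
#'
#' @param meta spatial metadata with centroids and a type column.
#' @param type_col cell-type column (default `subtype`).
#' @param k neighbours per cell (default 20).
#' @param K number of neighborhoods (default 6).
#' @param seed integer seed for k-means.
#' @param nstart k-means restarts (default 10).
#' @return List: `assignment` (per-cell data.frame with `neighborhood`,
#'   NA when unassigned), `composition` (K x type matrix of mean
#'   composition, rows sum to 1), `prevalence` (group x neighborhood
#'   proportions), `profiles` (per-cell composition matrix).
#' @export
detect_neighborhoods <- function(meta, type_col = "subtype", k = 20L,
                                 K = 6L, seed = 1L, nstart = 10L) {
  types <- sort(unique(meta[[type_col]]))
  n <- nrow(meta)
  prof <- matrix(NA_real_, n, length(types),
                 dimnames = list(meta$cell_id, types))
  fovs <- split(seq_len(n), paste(meta$sample_id, meta$fov_id, sep = "\r"))
  skipped <- 0L
  for (j in fovs) {
    if (length(j) <= k) {
      skipped <- skipped + length(j)
      next
    }
    D <- as.matrix(stats::dist(cbind(meta$x_um[j], meta$y_um[j])))
    diag(D) <- Inf
    for (i in seq_along(j)) {
      nb <- j[order(D[i, ])[seq_len(k)]]
      tb <- table(factor(meta[[type_col]][nb], levels = types))
      prof[j[i], ] <- as.numeric(tb) / k
    }
  }
  if (skipped > 0)
    warning(skipped, " cell(s) in FoVs with <= k cells left unassigned")
  ok <- !is.na(prof[, 1])
  assignment <- data.frame(cell_id = meta$cell_id,
                           neighborhood = NA_integer_,
                           stringsAsFactors = FALSE)
  if (!any(ok)) {
    return(list(assignment = assignment,
                composition = matrix(numeric(0), 0, length(types),
                                     dimnames = list(NULL, types)),
                prevalence = NULL, profiles = prof))
  }
  if (K == 1) {
    assignment$neighborhood[ok] <- 1L
    km_centers <- matrix(colMeans(prof[ok, , drop = FALSE]), 1,
                         dimnames = list(NULL, types))
  } else {
    set.seed(derive_seed(seed, "neighborhoods"))
    km <- stats::kmeans(prof[ok, , drop = FALSE], centers = K,
                        nstart = nstart, iter.max = 50)
    assignment$neighborhood[ok] <- km$cluster
    km_centers <- km$centers
  }
  composition <- km_centers / rowSums(km_centers)
  prev <- prop.table(table(meta$group[ok], assignment$neighborhood[ok]),
                     margin = 1)
  list(assignment = assignment, composition = composition,
       prevalence = prev, profiles = prof)
}

#' Cross-patient cell-type abundance correlations
#'
#' Aggregates cell counts per patient and cell type, correlates every
#' type pair across patients (Pearson), derives two-sided p-values from
#' the t distribution with n - 2 degrees of freedom, and adjusts them by
#' Benjamini-Hochberg over all pairs.
#'
#' @param meta metadata with `sample_id` (patient) and a type column.
#' @param type_col cell-type column (default `subtype`).
#' @param mode `"proportion"` (default; per-patient type proportions,
#'   robust to cell-yield differences) or `"count"` (raw per-patient
#'   counts).
#' @return data.frame per unordered type pair: `type_a`, `type_b`, `r`,
#'   `p_raw`, `p_adj`, `n_patients`; attribute `abundance` holds the
#'   patient x type abundance matrix.
#' @export
abundance_correlation <- function(meta, type_col = "subtype",
                                  mode = c("proportion", "count")) {
  mode <- match.arg(mode)
  tab <- table(meta$sample_id, meta[[type_col]])
  if (nrow(tab) < 4)
    stop("error: abundance correlation needs at least 4 patients")
  ab <- if (mode == "proportion") prop.table(tab, margin = 1) else tab
  ab <- matrix(as.numeric(ab), nrow(tab), ncol(tab),
               dimnames = dimnames(tab))
  empty <- colSums(ab) == 0
  if (any(empty)) {
    warning("type(s) absent in all patients dropped: ",
            paste(colnames(ab)[empty], collapse = ", "))
    ab <- ab[, !empty, drop = FALSE]
  }
  types <- colnames(ab)
  n <- nrow(ab)
  pairs <- utils::combn(types, 2)
  r <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    va <- ab[, pairs[1, i]]; vb <- ab[, pairs[2, i]]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
      r[i] <- NA_real_; p[i] <- NA_real_
      next
    }
    r[i] <- stats::cor(va, vb)
    tt <- r[i] * sqrt((n - 2) / max(1 - r[i]^2, .Machine$double.eps))
    p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  out <- data.frame(type_a = pairs[1, ], type_b = pairs[2, ], r = r,
                    p_raw = p, p_adj = stats::p.adjust(p, method = "BH"),
                    n_patients = n, stringsAsFactors = FALSE)
  attr(out, "abundance") <- ab
  out
}
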