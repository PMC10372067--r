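#' Derive a stage-specific random seed
#'
#' Fans a single global seed out to per-stage seeds so that inserting a
#' stage does not shift the random stream of the others.
#'
#' @param seed non-negative integer global seed.
#' @param stage stage name.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  v <- utf8ToInt(stage)
  h <- sum(v * seq_along(v)) %% 1000003L
  as.integer((as.numeric(seed) * 1000003 + h) %% (.Machine$integer.max - 1L))
}

#' Describe a synthetic paired-dataset simulation
#'
#' The generator emulates the structure of a paired colonic-mucosa study:
#' a droplet scRNA-seq reference (genome-wide gene space) and a targeted
#' single-cell spatial dataset (a ~panel-sized gene subset plus
#' negative-control probes, FoV geometry, a mucosal surface at y = 0),
#' with three disease groups (HC/CD/UC) whose per-sample cell-type
#' composition differs, cell types organised into five coarse
#' compartments, planted marker genes, and niche-driven co-localization.
#'
#' Counts follow a negative binomial with a single shared dispersion: gene
#' g in a cell of type t has mean `baseline_mean * marker_fold^[g is a
#' marker of t]`, scaled by a per-cell log-normal library factor. In the
#' spatial modality each cell first draws its type from its sample's
#' composition vector, then a niche with weight proportional to
#' `niche_floor + attraction[type, anchor(niche)]`, and a position equal
#' to the niche centre plus isotropic Gaussian jitter; its y coordinate is
#' blended (weight `surface_weight`) towards the type's surface offset so
#' that depth below the mucosal surface is type-structured.
#'
#' @param n_types number of cell types.
#' @param n_compartments number of coarse compartments (at most 5).
#' @param markers_per_type planted marker genes per type.
#' @param marker_fold fold elevation of a marker in its own type (> 1).
#' @param n_genes_reference biological genes in the reference.
#' @param panel_size biological genes on the spatial panel (includes all
#'   planted markers).
#' @param n_negative_probes negative-control probes on the panel.
#' @param baseline_mean negative-binomial mean of a non-marker gene.
#' @param dispersion shared NB dispersion (size = 1/dispersion).
#' @param library_sdlog sdlog of the per-cell log-normal library factor.
#' @param samples_per_group samples per disease group.
#' @param cells_per_sample reference cells per sample.
#' @param fovs_per_sample fields of view per spatial sample.
#' @param cells_per_fov spatial cells per FoV.
#' @param fov_width_um,fov_height_um FoV rectangle in micrometres; the
#'   mucosal surface is the line y = 0.
#' @param niche_count niche centres per FoV.
#' @param niche_sd_um isotropic Gaussian jitter around the niche centre.
#' @param niche_floor baseline niche weight for unattracted types.
#' @param attraction symmetric matrix in `[0, 1]` over type pairs with
#'   unit diagonal; `attraction[a, b]` tilts type-a cells towards niches
#'   anchored on type b.
#' @param surface_offset_by_type per-type target depth (micrometres).
#' @param surface_weight blend weight of the surface offset into y.
#' @param spatial_depth coverage down-sampling factor of panel counts
#'   relative to the reference profile.
#' @param negprobe_mean Poisson mean of a negative-probe count per cell.
#' @param composition optional named list of per-group type-proportion
#'   vectors (must sum to 1); defaults to uniform for HC and opposite
#'   linear tilts for CD and UC.
#' @param seed non-negative integer seed; the same design reproduces
#'   byte-identical data.
#'
#' @return List of class `SimulationDesign`.
#' @export
simulation_design <- function(n_types = 10L, n_compartments = 5L,
                              markers_per_type = 20L, marker_fold = 4,
                              n_genes_reference = 2000L, panel_size = 300L,
                              n_negative_probes = 20L,
                              baseline_mean = 0.5, dispersion = 0.5,
                              library_sdlog = 0.3,
                              samples_per_group = 2L, cells_per_sample = 400L,
                              fovs_per_sample = 4L, cells_per_fov = 250L,
                              fov_width_um = 500, fov_height_um = 500,
                              niche_count = 3L, niche_sd_um = 40,
                              niche_floor = 0.05,
                              attraction = NULL,
                              surface_offset_by_type = NULL,
                              surface_weight = 0.3,
                              spatial_depth = 0.6, negprobe_mean = 0.05,
                              composition = NULL, seed = 1L) {
  if (n_compartments > length(.valid_compartments))
    stop("design error: at most ", length(.valid_compartments),
         " compartments supported")
  if (marker_fold <= 0) stop("design error: marker_fold must be positive")
  if (panel_size > n_genes_reference)
    stop("design error: panel_size exceeds n_genes_reference")
  if (markers_per_type * n_types > panel_size)
    stop("design error: panel cannot hold all planted markers")
  if (is.null(attraction)) attraction <- diag(n_types)
  attraction <- as.matrix(attraction)
  if (!isTRUE(all.equal(attraction, t(attraction))) ||
      any(diag(attraction) != 1) ||
      any(attraction < 0 | attraction > 1))
    stop("design error: attraction must be symmetric in [0,1] with unit diagonal")
  if (nrow(attraction) != n_types)
    stop("design error: attraction dimension must equal n_types")
  if (is.null(surface_offset_by_type))
    surface_offset_by_type <- seq(40, fov_height_um - 40,
                                  length.out = n_types)
  if (length(surface_offset_by_type) != n_types)
    stop("design error: surface_offset_by_type length must equal n_types")
  if (is.null(composition)) {
    tilt <- seq(-0.5, 0.5, length.out = n_types)
    composition <- list(HC = rep(1 / n_types, n_types),
                        CD = (1 + tilt) / sum(1 + tilt),
                        UC = (1 - tilt) / sum(1 - tilt))
  }
  if (!setequal(names(composition), .valid_groups))
    stop("design error: composition must be named HC, CD, UC")
  for (g in names(composition)) {
    if (length(composition[[g]]) != n_types)
      stop("design error: composition vector length != n_types for ", g)
    if (abs(sum(composition[[g]]) - 1) > 1e-9)
      stop("design error: composition for ", g, " does not sum to 1")
  }
  design <- list(n_types = as.integer(n_types),
                 n_compartments = as.integer(n_compartments),
                 markers_per_type = as.integer(markers_per_type),
                 marker_fold = marker_fold,
                 n_genes_reference = as.integer(n_genes_reference),
                 panel_size = as.integer(panel_size),
                 n_negative_probes = as.integer(n_negative_probes),
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 library_sdlog = library_sdlog,
                 samples_per_group = as.integer(samples_per_group),
                 cells_per_sample = as.integer(cells_per_sample),
                 fovs_per_sample = as.integer(fovs_per_sample),
                 cells_per_fov = as.integer(cells_per_fov),
                 fov_width_um = fov_width_um, fov_height_um = fov_height_um,
                 niche_count = as.integer(niche_count),
                 niche_sd_um = niche_sd_um, niche_floor = niche_floor,
                 attraction = attraction,
                 surface_offset_by_type = surface_offset_by_type,
                 surface_weight = surface_weight,
                 spatial_depth = spatial_depth, negprobe_mean = negprobe_mean,
                 composition = composition, seed = as.integer(seed))
  class(design) <- "SimulationDesign"
  design
}

type_names <- function(design) sprintf("type%02d", seq_len(design$n_types))

#' Compartment of each simulated cell type
#' @param design a [simulation_design()].
#' @return Named character vector mapping type name to compartment.
#' @export
design_compartments <- function(design) {
  comp <- .valid_compartments[
    ((seq_len(design$n_types) - 1L) %% design$n_compartments) + 1L]
  stats::setNames(comp, type_names(design))
}

#' Planted marker genes per type
#' @param design a [simulation_design()].
#' @return Named list of marker gene identifiers per type.
#' @export
design_markers <- function(design) {
  tn <- type_names(design)
  out <- lapply(seq_len(design$n_types), function(t) {
    sprintf("GENE%05d", ((t - 1L) * design$markers_per_type + 1L):
              (t * design$markers_per_type))
  })
  stats::setNames(out, tn)
}

#' Expected expression profile per type (reference gene space)
#' @param design a [simulation_design()].
#' @return genes x types matrix of negative-binomial means.
#' @export
design_profiles <- function(design) {
  genes <- sprintf("GENE%05d", seq_len(design$n_genes_reference))
  tn <- type_names(design)
  M <- matrix(design$baseline_mean, length(genes), design$n_types,
              dimnames = list(genes, tn))
  mk <- design_markers(design)
  for (t in tn) M[mk[[t]], t] <- design$baseline_mean * design$marker_fold
  M
}

design_panel_genes <- function(design) {
  genes <- sprintf("GENE%05d", seq_len(design$n_genes_reference))
  markers <- unlist(design_markers(design), use.names = FALSE)
  fill <- setdiff(genes, markers)
  c(markers, fill[seq_len(design$panel_size - length(markers))])
}

design_samples <- function(design, prefix = "") {
  grp <- rep(.valid_groups, each = design$samples_per_group)
  idx <- rep(seq_len(design$samples_per_group), times = length(.valid_groups))
  data.frame(sample_id = paste0(prefix, grp, idx), group = grp,
             stringsAsFactors = FALSE)
}

.sim_counts <- function(profiles, types, lib_factor, dispersion) {
  n_genes <- nrow(profiles)
  out <- matrix(0L, n_genes, length(types))
  for (t in unique(types)) {
    j <- which(types == t)
    mu <- outer(profiles[, t], lib_factor[j])
    out[, j] <- stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  rownames(out) <- rownames(profiles)
  out
}

#' Simulate a scRNA-seq reference dataset
#'
#' @param design a [simulation_design()].
#' @return List with `counts` (a [CountMatrix()]), `meta` (per-cell
#'   metadata) and `truth` (list: `true_type` named by cell, `markers`,
#'   `compartment_of_type`, `profiles`).
#' @export
simulate_reference <- function(design) {
  stopifnot(inherits(design, "SimulationDesign"))
  set.seed(derive_seed(design$seed, "reference"))
  profiles <- design_profiles(design)
  tn <- type_names(design)
  samples <- design_samples(design)
  blocks <- vector("list", nrow(samples))
  meta <- vector("list", nrow(samples))
  truth_type <- character(0)
  for (s in seq_len(nrow(samples))) {
    n <- design$cells_per_sample
    ids <- sprintf("%s_c%04d", samples$sample_id[s], seq_len(n))
    types <- sample(tn, n, replace = TRUE,
                    prob = design$composition[[samples$group[s]]])
    libf <- stats::rlnorm(n, meanlog = 0, sdlog = design$library_sdlog)
    cnt <- .sim_counts(profiles, types, libf, design$dispersion)
    colnames(cnt) <- ids
    blocks[[s]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                               "CsparseMatrix")
    meta[[s]] <- data.frame(cell_id = ids,
                            sample_id = samples$sample_id[s],
                            group = samples$group[s],
                            stringsAsFactors = FALSE)
    truth_type <- c(truth_type, stats::setNames(types, ids))
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, meta)
  comp <- design_compartments(design)
  meta$compartment <- unname(comp[truth_type[meta$cell_id]])
  meta$subtype <- unname(truth_type[meta$cell_id])
  list(counts = CountMatrix(counts), meta = meta,
       truth = list(true_type = truth_type, markers = design_markers(design),
                    compartment_of_type = comp, profiles = profiles))
}

#' Simulate a paired single-cell spatial dataset
#'
#' Panel counts are down-sampled negative-binomial draws from each type's
#' reference profile restricted to the panel; negative probes are
#' Poisson with mean `design$negprobe_mean`. Each FoV receives
#' `niche_count` uniformly placed niche centres whose anchor types cycle
#' through the type list; cells choose a niche with weight
#' `niche_floor + attraction[type, anchor]`.
#'
#' @param design a [simulation_design()].
#' @param reference_profiles optional genes x types matrix of NB means;
#'   defaults to the design's analytic profiles.
#' @return List with `counts`, `meta`, `surface` (a [surface_polyline()])
#'   and `truth` (`true_type`, `true_niche` per cell, plus the design
#'   maps).
#' @export
simulate_spatial <- function(design, reference_profiles = NULL) {
  stopifnot(inherits(design, "SimulationDesign"))
  set.seed(derive_seed(design$seed, "spatial"))
  if (is.null(reference_profiles)) reference_profiles <- design_profiles(design)
  tn <- type_names(design)
  if (!all(tn %in% colnames(reference_profiles)))
    stop("design error: reference profiles missing for some types")
  panel <- design_panel_genes(design)
  if (!all(panel %in% rownames(reference_profiles)))
    stop("design error: panel gene absent from reference profiles")
  prof <- reference_profiles[panel, tn, drop = FALSE] * design$spatial_depth
  samples <- design_samples(design, prefix = "SP_")
  anchors <- ((seq_len(design$niche_count) - 1L) %% design$n_types) + 1L
  W <- design$fov_width_um; H <- design$fov_height_um
  blocks <- list(); metas <- list()
  truth_type <- character(0); truth_niche <- character(0)
  for (s in seq_len(nrow(samples))) {
    for (f in seq_len(design$fovs_per_sample)) {
      n <- design$cells_per_fov
      fov <- sprintf("f%02d", f)
      ids <- sprintf("%s_%s_c%04d", samples$sample_id[s], fov, seq_len(n))
      nx <- stats::runif(design$niche_count, 0, W)
      ny <- stats::runif(design$niche_count, 0, H)
      t_idx <- sample.int(design$n_types, n, replace = TRUE,
                          prob = design$composition[[samples$group[s]]])
      wts <- design$niche_floor + design$attraction[, anchors, drop = FALSE]
      niche <- vapply(t_idx, function(t)
        sample.int(design$niche_count, 1L, prob = wts[t, ]), integer(1))
      x <- pmin(pmax(nx[niche] + stats::rnorm(n, 0, design$niche_sd_um), 0), W)
      y_raw <- ny[niche] + stats::rnorm(n, 0, design$niche_sd_um)
      y <- (1 - design$surface_weight) * y_raw +
        design$surface_weight * design$surface_offset_by_type[t_idx]
      y <- pmin(pmax(y, 0), H)
      libf <- stats::rlnorm(n, meanlog = 0, sdlog = design$library_sdlog)
      cnt <- .sim_counts(prof, tn[t_idx], libf, design$dispersion)
      neg <- matrix(stats::rpois(design$n_negative_probes * n,
                                 design$negprobe_mean),
                    design$n_negative_probes, n)
      rownames(neg) <- sprintf("NegPrb%03d", seq_len(design$n_negative_probes))
      cnt <- rbind(cnt, neg)
      colnames(cnt) <- ids
      blocks[[length(blocks) + 1L]] <-
        methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")
      metas[[length(metas) + 1L]] <-
        data.frame(cell_id = ids, sample_id = samples$sample_id[s],
                   group = samples$group[s], fov_id = fov,
                   x_um = x, y_um = y, stringsAsFactors = FALSE)
      truth_type <- c(truth_type, stats::setNames(tn[t_idx], ids))
      truth_niche <- c(truth_niche, stats::setNames(
        sprintf("%s_%s_n%d", samples$sample_id[s], fov, niche), ids))
    }
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  surface <- surface_polyline(seq(0, W, length.out = 5), rep(0, 5))
  list(counts = CountMatrix(counts), meta = meta, surface = surface,
       truth = list(true_type = truth_type, true_niche = truth_niche,
                    markers = design_markers(design),
                    compartment_of_type = design_compartments(design)))
}

#' Simulate a paired reference + spatial dataset
#'
#' @param design a [simulation_design()].
#' @return List with elements `reference` and `spatial`.
#' @export
simulate_paired <- function(design) {
  reference <- simulate_reference(design)
  spatial <- simulate_spatial(design, reference$truth$profiles)
  list(reference = reference, spatial = spatial)
}

#' Plant QC failures into a spatial dataset
#'
#' Forces selected cells to fail the spatial QC rule: low-feature cells
#' keep fewer than 20 detected biological features (surplus genes are
#' zeroed), high-background cells get every negative-probe count inflated
#' so the per-cell probe mean exceeds 0.5.
#'
#' @param counts spatial [CountMatrix()].
#' @param meta matching metadata.
#' @param n_low_feature number of cells forced below 20 features.
#' @param n_high_negprobe number of cells forced above probe mean 0.5.
#' @param seed integer seed for the victim draw.
#' @return List with mutated `counts`, untouched `meta`, and `truth`
#'   data.frame (`cell_id`, `mode`).
#' @export
plant_qc_failures <- function(counts, meta, n_low_feature, n_high_negprobe,
                              seed = 1L) {
  n_total <- n_low_feature + n_high_negprobe
  if (n_total > ncol(counts$counts))
    stop("error: fewer cells than requested failures")
  if (n_total == 0)
    return(list(counts = counts, meta = meta,
                truth = data.frame(cell_id = character(0),
                                   mode = character(0))))
  set.seed(derive_seed(seed, "plant_qc"))
  victims <- sample(cell_ids(counts), n_total)
  low <- victims[seq_len(n_low_feature)]
  high <- setdiff(victims, low)
  m <- as.matrix(counts$counts)
  bio <- which(!counts$is_negative_probe)
  for (cid in low) {
    detected <- bio[m[bio, cid] > 0]
    keep <- utils::head(detected, 10L)
    m[setdiff(bio, keep), cid] <- 0L
  }
  probes <- which(counts$is_negative_probe)
  if (length(high) && length(probes) == 0)
    stop("error: cannot plant high-negprobe failures without probes")
  for (cid in high) m[probes, cid] <- m[probes, cid] + 1L
  truth <- data.frame(cell_id = c(low, high),
                      mode = rep(c("low_feature", "high_negprobe"),
                                 c(length(low), length(high))),
                      stringsAsFactors = FALSE)
  list(counts = CountMatrix(m, unname(counts$is_negative_probe)),
       meta = meta, truth = truth)
}
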