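# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default paired dataset (10 types, 20 markers at fold 4, 300-gene panel,
# seed 1): the standard benchmark conditions.
default_pair <- function() cached("default_pair", {
  simulate_paired(simulation_design(seed = 1))
})

default_annotation <- function() cached("default_annotation", {
  sim <- default_pair()
  norm_ref <- lognormalize(sim$reference$counts)
  sp_bio <- sim$spatial$counts[!sim$spatial$counts$is_negative_probe, ]
  norm_sp <- lognormalize(sp_bio)
  list(ann = two_pass_annotation(norm_ref, sim$reference$meta, norm_sp),
       norm_ref = norm_ref, norm_sp = norm_sp)
})

default_reference_markers <- function() cached("default_markers", {
  sim <- default_pair()
  find_markers(lognormalize(sim$reference$counts),
               sim$reference$meta$subtype)
})

# Small count matrix with explicit values; genes x cells.
small_count_matrix <- function(m, gene_prefix = "G", neg = NULL) {
  rownames(m) <- if (is.null(rownames(m)))
    sprintf("%s%02d", gene_prefix, seq_len(nrow(m))) else rownames(m)
  colnames(m) <- if (is.null(colnames(m)))
    sprintf("c%02d", seq_len(ncol(m))) else colnames(m)
  CountMatrix(m, is_negative_probe = neg)
}

# Spatial metadata for point-pattern tests: one sample/FoV, two types.
pattern_meta <- function(xa, ya, xb, yb, type_a = "A", type_b = "B") {
  n <- length(xa) + length(xb)
  data.frame(cell_id = sprintf("c%04d", seq_len(n)), sample_id = "S1",
             group = "HC", fov_id = "f1", x_um = c(xa, xb),
             y_um = c(ya, yb),
             subtype = rep(c(type_a, type_b),
                           c(length(xa), length(xb))),
             stringsAsFactors = FALSE)
}

# Design used for co-localization benchmarks: every type anchors a niche,
# types 1 and 2 attracted at 0.9, flat depth offsets, ~200 cells/type/FoV
# over 21 FoVs.
coloc_design <- function(seed = 1) {
  att <- diag(4)
  att[1, 2] <- att[2, 1] <- 0.9
  simulation_design(n_types = 4, n_compartments = 4, niche_count = 4,
                    attraction = att, samples_per_group = 1,
                    fovs_per_sample = 7, cells_per_fov = 800,
                    surface_offset_by_type = rep(250, 4),
                    composition = list(HC = rep(0.25, 4), CD = rep(0.25, 4),
                                       UC = rep(0.25, 4)),
                    seed = seed)
}

coloc_records <- function() cached("coloc_records", {
  sp <- simulate_spatial(coloc_design())
  sp$meta$subtype <- unname(sp$truth$true_type[sp$meta$cell_id])
  colocalization_scores(sp$meta)
})

# Three fully anchored types, one niche each: ground-truth niches are
# recoverable from k-NN composition profiles.
niche_design <- function(seed = 1) {
  simulation_design(n_types = 3, n_compartments = 3, niche_count = 3,
                    surface_offset_by_type = rep(250, 3),
                    composition = list(HC = rep(1, 3) / 3,
                                       CD = rep(1, 3) / 3,
                                       UC = rep(1, 3) / 3),
                    seed = seed)
}
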