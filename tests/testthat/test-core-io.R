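test_that("MTX round trip preserves counts, identifiers and probe flags", {
  set.seed(42)
  m <- matrix(rpois(300, 0.8), 30, 10)
  rownames(m) <- c(sprintf("GENE%03d", 1:27), sprintf("NegPrb%03d", 1:3))
  colnames(m) <- sprintf("cell%02d", 1:10)
  cm <- CountMatrix(m)
  expect_equal(sum(cm$is_negative_probe), 3)
  dir <- withr::local_tempdir()
  write_count_matrix(cm, dir)
  back <- read_count_matrix(file.path(dir, "matrix.mtx"),
                            file.path(dir, "matrix.genes.tsv"),
                            file.path(dir, "matrix.barcodes.tsv"))
  expect_identical(gene_ids(back), rownames(m))
  expect_identical(cell_ids(back), colnames(m))
  expect_equal(as.matrix(back$counts), m, ignore_attr = TRUE)
  expect_identical(back$is_negative_probe, cm$is_negative_probe)
})

test_that("MTX reader applies direct file content and flags probes", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 4", "3 2 1"), file.path(dir, "m.mtx"))
  writeLines(c("GENE1", "GENE2", "NegPrb001"), file.path(dir, "g.tsv"))
  writeLines(c("b1", "b2"), file.path(dir, "b.tsv"))
  cm <- read_count_matrix(file.path(dir, "m.mtx"), file.path(dir, "g.tsv"),
                          file.path(dir, "b.tsv"))
  expect_equal(unname(Matrix::colSums(cm$counts)), c(4, 1))
  expect_equal(unname(cm$is_negative_probe), c(FALSE, FALSE, TRUE))
})

test_that("MTX reader rejects dimension mismatches naming the file", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 1", "1 1 4"), file.path(dir, "m.mtx"))
  writeLines(c("GENE1", "GENE2", "GENE3"), file.path(dir, "g.tsv"))
  writeLines(c("b1", "b2", "b3"), file.path(dir, "b.tsv"))
  expect_error(read_count_matrix(file.path(dir, "m.mtx"),
                                 file.path(dir, "g.tsv"),
                                 file.path(dir, "b.tsv")),
               "b.tsv.*3 barcodes.*2 columns")
})

test_that("duplicate identifiers are rejected", {
  m <- matrix(1, 2, 2)
  rownames(m) <- c("G1", "G1")
  colnames(m) <- c("c1", "c2")
  expect_error(CountMatrix(m), "duplicate gene")
  rownames(m) <- c("G1", "G2")
  colnames(m) <- c("c1", "c1")
  expect_error(CountMatrix(m), "duplicate cell")
})

test_that("cell metadata round trips and validates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "meta.csv")
  writeLines(c("cell_id,sample_id,group,fov_id,x_um,y_um",
               "c1,S1,HC,f1,10.0,20.0"), path)
  meta <- read_cell_meta(path)
  expect_equal(meta$x_um, 10)
  expect_equal(meta$y_um, 20)

  set.seed(7)
  big <- cell_meta(cell_id = sprintf("c%03d", 1:100),
                   sample_id = sample(c("S1", "S2"), 100, TRUE),
                   group = sample(c("HC", "CD", "UC"), 100, TRUE),
                   fov_id = "f1", x_um = round(runif(100), 6),
                   y_um = round(runif(100), 6))
  write_cell_meta(big, path)
  back <- read_cell_meta(path)
  expect_equal(back[names(big)], big)
})

test_that("metadata validation rejects malformed records", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "meta.csv")
  writeLines(c("cell_id,sample_id,group", "c1,S1,XX"), path)
  expect_error(read_cell_meta(path), "unknown group")
  writeLines(c("cell_id,sample_id", "c1,S1"), path)
  expect_error(read_cell_meta(path), "missing mandatory column")
  writeLines(c("cell_id,sample_id,group,fov_id,x_um,y_um",
               "c1,S1,HC,,10.0,20.0"), path)
  expect_error(read_cell_meta(path), "without FoV")
  expect_error(cell_meta("c1", "S1", "HC", qc_pass = FALSE),
               "qc_reason")
})

test_that("surface polylines round trip and validate", {
  poly <- surface_polyline(c(0, 100, 250, 400), c(0, 10, -5, 0))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "surface.csv")
  write_surface_polyline(poly, path)
  expect_equal(as.data.frame(read_surface_polyline(path)),
               as.data.frame(poly))
  expect_error(surface_polyline(c(0), c(0)), "at least 2")
  expect_error(surface_polyline(c(0, 0, 1), c(5, 5, 5)), "distinct")
})

test_that("YAML config fills defaults and validates the seed", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.yaml")
  writeLines(c("seed: 7", "qc:", "  sc_mito_max_pct: 30"), path)
  cfg <- read_pipeline_config(path)
  expect_equal(cfg$seed, 7)
  expect_equal(cfg$qc$sc_mito_max_pct, 30)
  expect_equal(cfg$qc$smi_negprobe_mean_max, 0.5)  # untouched default
  expect_error(default_config(seed = -1), "seed")
})

test_that("paired-dataset validation reports overlap and rejects disjoint panels", {
  sim <- default_pair()
  rep <- validate_paired_dataset(sim$reference, sim$spatial)
  expect_equal(rep$n_overlap, 300)   # generator guarantees panel subset
  expect_equal(rep$n_duplicated_cells, 0)

  m <- matrix(1, 3, 3)
  rownames(m) <- c("X1", "X2", "X3"); colnames(m) <- c("q1", "q2", "q3")
  other <- list(counts = CountMatrix(m),
                meta = cell_meta(colnames(m), "S9", "HC"))
  expect_error(validate_paired_dataset(sim$reference, other),
               "incompatible-panels")
})
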