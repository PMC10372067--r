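make_spatial_toy <- function(neg_sums, n_features, n_probes = 10,
                             n_bio = 60) {
  # builds integer counts whose per-cell probe means are neg_sums/n_probes
  n <- length(neg_sums)
  bio <- matrix(0L, n_bio, n)
  for (j in seq_len(n)) bio[seq_len(n_features[j]), j] <- 1L
  neg <- matrix(0L, n_probes, n)
  for (j in seq_len(n)) {
    full <- neg_sums[j] %/% n_probes
    rem <- neg_sums[j] %% n_probes
    neg[, j] <- full
    if (rem > 0) neg[seq_len(rem), j] <- neg[seq_len(rem), j] + 1L
  }
  m <- rbind(bio, neg)
  rownames(m) <- c(sprintf("G%03d", seq_len(n_bio)),
                   sprintf("NegPrb%03d", seq_len(n_probes)))
  colnames(m) <- sprintf("c%02d", seq_len(n))
  list(counts = CountMatrix(m),
       meta = cell_meta(colnames(m), "S1", "HC"))
}

test_that("spatial filter applies the probe-mean OR feature rule", {
  # probe means 0.0, 0.6, 0.2, 0.1, 0.9; features 50, 50, 10, 30, 25
  toy <- make_spatial_toy(neg_sums = c(0, 6, 2, 1, 9),
                          n_features = c(50, 50, 10, 30, 25))
  res <- filter_spatial_cells(toy$counts, toy$meta)
  expect_identical(cell_ids(res$counts), c("c01", "c04"))
  expect_equal(res$report$retained_fraction, 2 / 5)
  expect_equal(res$report$n_removed_negprobe, 2)
  expect_equal(res$report$n_removed_features, 1)
})

test_that("spatial filter boundaries are strict: mean 0.5 and 20 features pass", {
  toy <- make_spatial_toy(neg_sums = c(5, 5, 6), n_features = c(20, 19, 20))
  res <- filter_spatial_cells(toy$counts, toy$meta)
  expect_identical(cell_ids(res$counts), "c01")
  expect_match(res$report$cells$qc_reason[2], "low_features")
  expect_match(res$report$cells$qc_reason[3], "high_negprobe_mean")
})

test_that("spatial filter is idempotent and removes exactly the planted set", {
  sim <- default_pair()
  planted <- plant_qc_failures(sim$spatial$counts, sim$spatial$meta,
                               5, 5, seed = 1)
  res <- filter_spatial_cells(planted$counts, planted$meta)
  removed <- setdiff(cell_ids(planted$counts), cell_ids(res$counts))
  expect_setequal(removed, planted$truth$cell_id)
  res2 <- filter_spatial_cells(res$counts, res$meta)
  expect_identical(cell_ids(res2$counts), cell_ids(res$counts))
  expect_equal(res2$report$n_removed, 0)
})

test_that("reference filter respects the laxer epithelial mitochondrial cap", {
  m <- matrix(0L, 12, 3)
  rownames(m) <- c(sprintf("GENE%02d", 1:10), "MT-ND1", "MT-CO1")
  colnames(m) <- c("epi", "str", "low")
  m[1:10, "epi"] <- 4L; m[11:12, "epi"] <- 30L   # 60% mito
  m[1:10, "str"] <- 4L; m[11:12, "str"] <- 30L   # 60% mito
  m[1, "low"] <- 1L                              # 1 detected gene
  meta <- cell_meta(colnames(m), "S1", "HC",
                    compartment = c("epithelium", "stroma", "stroma"))
  res <- filter_reference_cells(CountMatrix(m), meta, mito_max_pct = 25,
                                min_genes = 2)
  expect_identical(cell_ids(res$counts), "epi")
  rep <- res$report$cells
  expect_match(rep$qc_reason[rep$cell_id == "str"], "high_mito_pct")
  expect_match(rep$qc_reason[rep$cell_id == "low"], "low_genes")
  expect_warning(
    filter_reference_cells(CountMatrix(m[1:10, ]), meta, min_genes = 1),
    "mitochondrial filter skipped")
})

test_that("reference filter retains everything under permissive thresholds", {
  sim <- default_pair()
  # simulated gene space carries no mitochondrial genes: filter warns
  expect_warning(
    res <- filter_reference_cells(sim$reference$counts,
                                  sim$reference$meta, min_genes = 1),
    "skipped")
  expect_equal(res$report$retained_fraction, 1)
})

test_that("lineage filter removes forbidden-marker cells and constructed doublets", {
  set.seed(1)
  n_per <- 100
  genes <- c("C1QA", "CD3D", "CD3E", "CD3G", "EPCAM", "MS4A1", "DERL3",
             sprintf("GENE%02d", 1:20))
  epi <- matrix(0L, length(genes), n_per, dimnames = list(genes, NULL))
  epi["EPCAM", ] <- rpois(n_per, 5)
  epi[8:17, ] <- rpois(10 * n_per, 2)
  mye <- matrix(0L, length(genes), n_per, dimnames = list(genes, NULL))
  mye["C1QA", ] <- rpois(n_per, 3)
  mye[18:27, ] <- rpois(10 * n_per, 2)
  doublets <- epi + mye
  m <- cbind(epi, doublets)
  colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  meta <- cell_meta(colnames(m), "S1", "HC", compartment = "epithelium")
  res <- lineage_contamination_filter(CountMatrix(m), meta)
  doublet_ids <- colnames(m)[(n_per + 1):(2 * n_per)]
  removed <- res$report$removed$cell_id
  expect_gte(mean(doublet_ids %in% removed), 0.9)
  # clean epithelial cells without C1QA expression survive
  clean <- colnames(m)[seq_len(n_per)][epi["C1QA", ] == 0]
  expect_true(all(clean %in% cell_ids(res$counts)))

  identity_res <- lineage_contamination_filter(CountMatrix(m), meta,
                                               rules = list())
  expect_equal(identity_res$report$n_removed, 0)
  no_derl3 <- m[rownames(m) != "DERL3", ]
  expect_warning(
    lineage_contamination_filter(CountMatrix(no_derl3), meta,
                                 rules = list(epithelium = c("DERL3"))),
    "absent from matrix")
})

test_that("IG genes are dropped except in the B/plasma compartment", {
  m <- matrix(1L, 4, 2)
  rownames(m) <- c("IGHM", "IGKC", "IGLL5", "ACTB")
  colnames(m) <- c("c1", "c2")
  cm <- CountMatrix(m)
  expect_identical(gene_ids(remove_ig_genes(cm, "epithelium")), "ACTB")
  expect_identical(gene_ids(remove_ig_genes(cm, "plasmas")), rownames(m))
  no_ig <- cm[4, , drop = FALSE]
  expect_identical(gene_ids(remove_ig_genes(no_ig, "stroma")), "ACTB")
})
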