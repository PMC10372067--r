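test_that("identical point patterns score exactly 1 and records are symmetric", {
  set.seed(31)
  x <- runif(50, 0, 400); y <- runif(50, 0, 400)
  m <- pattern_meta(x, y, x, y)
  rec <- colocalization_scores(m)
  expect_equal(rec$score, 1, tolerance = 1e-9)
  expect_true(rec$valid)
  # swapping the type labels leaves the (unordered) pair score unchanged
  m2 <- m
  m2$subtype <- rev(m2$subtype)
  expect_equal(colocalization_scores(m2)$score, rec$score,
               tolerance = 1e-12)
})

test_that("segregated clusters score negative at a bandwidth matching their scale", {
  set.seed(1)
  m <- pattern_meta(rnorm(50, 0, 10), rnorm(50, 0, 10),
                    rnorm(50, 500, 10), rnorm(50, 0, 10))
  rec <- colocalization_scores(m, bandwidth = 100)
  expect_lt(rec$score, -0.2)
})

test_that("the more-than-10-cells validity rule is strict", {
  set.seed(32)
  m <- pattern_meta(runif(10), runif(10), runif(30), runif(30))
  rec <- colocalization_scores(m)
  expect_false(rec$valid)
  expect_true(is.na(rec$score))
  expect_equal(rec$n_a, 10)
  m11 <- pattern_meta(runif(11), runif(11), runif(30), runif(30))
  expect_true(colocalization_scores(m11)$valid)
})

test_that("scores are invariant to translation and axis-aligned rotation", {
  set.seed(33)
  x1 <- runif(40, 0, 300); y1 <- runif(40, 0, 300)
  x2 <- x1 + rnorm(40, 20, 15); y2 <- y1 + rnorm(40, -10, 15)
  base <- colocalization_scores(pattern_meta(x1, y1, x2, y2),
                                bandwidth = 30)$score
  shifted <- colocalization_scores(
    pattern_meta(x1 + 1234.5, y1 - 67.8, x2 + 1234.5, y2 - 67.8),
    bandwidth = 30)$score
  rotated <- colocalization_scores(  # (x, y) -> (-y, x)
    pattern_meta(-y1, x1, -y2, x2), bandwidth = 30)$score
  half_turn <- colocalization_scores(
    pattern_meta(-x1, -y1, -x2, -y2), bandwidth = 30)$score
  expect_equal(shifted, base, tolerance = 1e-6)
  expect_equal(rotated, base, tolerance = 1e-6)
  expect_equal(half_turn, base, tolerance = 1e-6)
})

test_that("independent uniform patterns average near zero at sub-window bandwidths", {
  set.seed(34)
  scores <- replicate(100, {
    m <- pattern_meta(runif(60, 0, 400), runif(60, 0, 400),
                      runif(60, 0, 400), runif(60, 0, 400))
    colocalization_scores(m, bandwidth = 10)$score
  })
  expect_lt(abs(mean(scores)), 0.1)
})

test_that("degenerate point patterns trigger the bandwidth floor", {
  m <- pattern_meta(rep(100, 12), rep(100, 12),
                    runif(12, 0, 200), runif(12, 0, 200))
  w <- testthat::capture_warnings(rec <- colocalization_scores(m))
  expect_true(all(grepl("floored", w)))
  expect_gte(length(w), 1)
  expect_true(is.finite(rec$score))
})

test_that("pooled summaries aggregate only valid records", {
  rec <- data.frame(sample_id = c("S1", "S1", "S2"), fov_id = c("f1", "f2", "f1"),
                    type_a = "A", type_b = "B", n_a = c(20, 20, 5),
                    n_b = c(20, 20, 5), valid = c(TRUE, TRUE, FALSE),
                    score = c(0.4, 0.6, NA))
  s <- summarize_colocalization(rec)
  expect_equal(s$mean_score, 0.5)
  expect_equal(s$n_fov, 2)
  single <- summarize_colocalization(rec[1, ])
  expect_equal(single$mean_score, 0.4)
  empty <- summarize_colocalization(rec[3, ])
  expect_equal(nrow(empty), 0)
})

test_that("attraction plants co-localization and independence stays near zero", {
  rec <- coloc_records()
  att <- rec$valid & rec$type_a == "type01" & rec$type_b == "type02"
  expect_gte(mean(rec$score[att]), 0.5)
  ind <- rec$valid & !(rec$type_a == "type01" & rec$type_b == "type02")
  expect_lte(mean(abs(rec$score[ind])), 0.15)
})

test_that("point-to-polyline distances are exact in analytic cases", {
  horiz <- surface_polyline(c(-10, 10), c(0, 0))
  expect_equal(point_polyline_distance(0, 3, horiz), 3)
  expect_equal(point_polyline_distance(20, 3, horiz), sqrt(109))
  # perpendicular feet across a grid against |y|
  grid <- expand.grid(x = seq(-9, 9, by = 3), y = seq(-50, 50, by = 10))
  expect_equal(point_polyline_distance(grid$x, grid$y, horiz),
               abs(grid$y))
  # degenerate zero-length segment is skipped, not propagated
  degen <- structure(data.frame(x_um = c(0, 0, 10), y_um = c(0, 0, 0)),
                     class = c("SurfacePolyline", "data.frame"))
  expect_equal(point_polyline_distance(5, 4, degen), 4)
})

test_that("polyline distances agree with a dense-sampling oracle", {
  set.seed(35)
  poly <- surface_polyline(c(0, 120, 260, 380, 500),
                           c(0, 40, -20, 10, 0))
  x <- runif(1000, -50, 550); y <- runif(1000, -100, 300)
  d <- point_polyline_distance(x, y, poly)
  # oracle: 10,000 points sampled densely along the polyline
  seg_len <- sqrt(diff(poly$x_um)^2 + diff(poly$y_um)^2)
  t_all <- seq(0, sum(seg_len), length.out = 10000)
  cum <- c(0, cumsum(seg_len))
  seg <- findInterval(t_all, cum, rightmost.closed = TRUE)
  seg[seg > 4] <- 4
  frac <- (t_all - cum[seg]) / seg_len[seg]
  px <- poly$x_um[seg] + frac * diff(poly$x_um)[seg]
  py <- poly$y_um[seg] + frac * diff(poly$y_um)[seg]
  oracle <- vapply(seq_along(x), function(i)
    sqrt(min((x[i] - px)^2 + (y[i] - py)^2)), 1)
  expect_lt(max(abs(d - oracle)), 0.5)
  expect_true(all(d <= oracle + 1e-9))  # sampling can only overestimate
})

test_that("distance summaries respect the minimum-cell rule", {
  set.seed(36)
  meta <- data.frame(cell_id = sprintf("c%02d", 1:25), sample_id = "S1",
                     group = "HC", fov_id = "f1",
                     x_um = runif(25, 0, 100), y_um = runif(25, 10, 90),
                     subtype = rep(c("big", "small"), c(20, 5)))
  res <- distance_to_surface(meta, surface_polyline(c(0, 100), c(0, 0)))
  expect_identical(res$summary$cluster, "big")
  expect_equal(res$summary$n_cells, 20)
  expect_true(with(res$summary, min <= median & median <= max))
  expect_equal(res$summary$mean,
               mean(meta$y_um[meta$subtype == "big"]))
})

test_that("two separated pure blocks are recovered exactly at K = 2", {
  set.seed(37)
  n <- 60
  meta <- data.frame(
    cell_id = sprintf("c%03d", seq_len(2 * n)), sample_id = "S1",
    group = "HC", fov_id = "f1",
    x_um = c(runif(n, 0, 100), runif(n, 400, 500)),
    y_um = runif(2 * n, 0, 100),
    subtype = rep(c("A", "B"), each = n))
  nb <- detect_neighborhoods(meta, k = 10, K = 2, seed = 1)
  truth <- rep(1:2, each = n)
  expect_equal(mclust::adjustedRandIndex(nb$assignment$neighborhood, truth), 1)
  expect_equal(unname(rowSums(nb$composition)), c(1, 1), tolerance = 1e-9)
  one <- detect_neighborhoods(meta, k = 10, K = 1, seed = 1)
  expect_true(all(one$assignment$neighborhood == 1))
})

test_that("small FoVs are left unassigned with a warning", {
  meta <- data.frame(cell_id = sprintf("c%02d", 1:15), sample_id = "S1",
                     group = "HC", fov_id = "f1",
                     x_um = runif(15), y_um = runif(15), subtype = "A")
  expect_warning(nb <- detect_neighborhoods(meta, k = 20, K = 2),
                 "unassigned")
  expect_true(all(is.na(nb$assignment$neighborhood)))
})

test_that("synthetic niches are recovered from k-NN composition profiles", {
  sp <- simulate_spatial(niche_design())
  sp$meta$subtype <- unname(sp$truth$true_type[sp$meta$cell_id])
  nb <- detect_neighborhoods(sp$meta, K = 3, seed = 1)
  niche_idx <- sub("^.*_n", "", sp$truth$true_niche[nb$assignment$cell_id])
  ok <- !is.na(nb$assignment$neighborhood)
  ari <- mclust::adjustedRandIndex(nb$assignment$neighborhood[ok],
                                   niche_idx[ok])
  expect_gte(ari, 0.7)
})

test_that("abundance correlations follow the t-distribution law and BH", {
  # two types with proportional abundance across 6 patients
  counts <- c(10, 20, 30, 40, 50, 60)
  meta <- do.call(rbind, lapply(1:6, function(p) data.frame(
    cell_id = sprintf("p%d_c%03d", p, seq_len(counts[p] * 2 + 100)),
    sample_id = sprintf("P%d", p), group = "HC",
    subtype = rep(c("A", "B", "C"), c(counts[p], counts[p], 100)))))
  res <- abundance_correlation(meta)
  ab_row <- res[res$type_a == "A" & res$type_b == "B", ]
  expect_equal(ab_row$r, 1, tolerance = 1e-9)
  expect_lt(ab_row$p_raw, 1e-6)
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
  expect_error(abundance_correlation(meta[meta$sample_id %in%
                                            c("P1", "P2", "P3"), ]),
               "at least 4 patients")
})

test_that("a shared patient factor between two types is detectable with power", {
  set.seed(38)
  hits <- replicate(100, {
    u <- rnorm(12)
    nA <- rpois(12, 40 * exp(0.9 * u))
    nB <- rpois(12, 40 * exp(0.9 * u))
    nC <- rpois(12, 40)
    nD <- rpois(12, 40)
    meta <- do.call(rbind, lapply(1:12, function(p) data.frame(
      cell_id = sprintf("q%d_c%04d", p,
                        seq_len(nA[p] + nB[p] + nC[p] + nD[p])),
      sample_id = sprintf("P%02d", p), group = "HC",
      subtype = rep(c("A", "B", "C", "D"),
                    c(nA[p], nB[p], nC[p], nD[p])))))
    res <- abundance_correlation(meta, mode = "count")
    row <- res[res$type_a == "A" & res$type_b == "B", ]
    row$r > 0.6 && row$p_adj < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
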