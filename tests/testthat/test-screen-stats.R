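# Well aggregation, B-score, robust Z, replicate merging, hit calling.

toy_cells <- function() {
  data.frame(
    plate = 1, row = "A", col = rep(1:2, each = 5), replicate = 1,
    solidity = c(0.80, 0.80, rep(0.95, 8)),
    area_um2 = c(rep(100, 5), 25, rep(100, 4)),
    clustering_score = 1:10,
    spot_count = rep(46, 10),
    mean_norm_radial = rep(0.66, 10)
  )
}

test_that("QC filtering applies the strict morphology thresholds", {
  res <- qc_filter_cells(toy_cells())
  expect_equal(nrow(res$cells), 7)
  expect_equal(nrow(res$excluded), 3)
  expect_equal(sum(res$counts$n_low_solidity), 2)
  expect_equal(sum(res$counts$n_low_area), 1)

  # boundary cells are retained: thresholds are strict inequalities
  edge <- data.frame(solidity = c(0.85, 0.8499999), area_um2 = c(30, 30))
  r2 <- qc_filter_cells(edge)
  expect_equal(nrow(r2$cells), 1)
  expect_equal(r2$cells$solidity, 0.85)

  empty <- qc_filter_cells(toy_cells()[0, ])
  expect_equal(nrow(empty$cells), 0)
  expect_error(qc_filter_cells(data.frame(a = 1)), "missing required")
})

test_that("well aggregation averages QC-passing cells per well", {
  pm <- data.frame(plate = 1, row = "A", col = 1:3,
                   well = paste0("A", 1:3),
                   perturbation = c("G1", "G2", "G3"),
                   control_class = "library")
  cells <- data.frame(plate = 1, row = "A", col = c(1, 1, 1, 2),
                      replicate = 1,
                      clustering_score = c(1, 2, 3, 7),
                      spot_count = c(40, 50, 60, 10),
                      area_um2 = 100, solidity = 0.95,
                      mean_norm_radial = 0.6)
  ws <- aggregate_wells(cells, pm)
  expect_equal(ws$mean_clustering_score[ws$col == 1], 2)
  expect_equal(ws$mean_spot_count[ws$col == 1], 50)
  expect_equal(ws$n_cells, c(3L, 1L, 0L))
  expect_true(ws$empty_well[3])
  expect_true(is.na(ws$mean_clustering_score[3]))

  orphan <- cells
  orphan$col[1] <- 9
  expect_error(aggregate_wells(orphan, pm), "absent from the plate map")
})

test_that("median polish removes pure additive row/column structure", {
  set.seed(1)
  mat <- matrix(0, 8, 10)
  mat[3, ] <- mat[3, ] + 2 # planted row offset
  lib <- matrix(TRUE, 8, 10)
  # a pinch of noise so the residual spread is nonzero
  mat <- mat + matrix(rnorm(80, 0, 1e-3), 8, 10)
  bs <- bscore_normalize(mat, lib)
  expect_true(all(abs(bs$residuals) < 0.01))
})

test_that("a single planted outlier well keeps its effect after polish", {
  set.seed(2)
  mat <- matrix(rnorm(8 * 10, 0, 0.1), 8, 10)
  mat <- sweep(mat, 1, seq(-0.7, 0.7, length.out = 8), `+`)
  mat <- sweep(mat, 2, seq(-0.5, 0.5, length.out = 10), `+`)
  true_effect <- 5 * mad(rnorm(1000, 0, 0.1)) # ~5 robust SDs
  mat[4, 5] <- mat[4, 5] + true_effect
  bs <- bscore_normalize(mat, matrix(TRUE, 8, 10))
  expect_gt(bs$b_scores[4, 5], 3.5)
  # the planted well stands clear of every background well
  background <- abs(bs$b_scores[-(4 + 8 * 4)])
  expect_lt(max(background), bs$b_scores[4, 5])
  expect_lt(median(background), 1)
})

test_that("B-scores match the brute-force median-polish oracle", {
  set.seed(3)
  mat <- matrix(rnorm(6 * 7), 6, 7)
  lib <- matrix(TRUE, 6, 7)
  bs <- bscore_normalize(mat, lib, max_iter = 100, tol = 1e-9)
  oracle <- brute_force_polish(mat - median(mat))
  o_scale <- mad(oracle$residuals)
  expect_equal(bs$b_scores, oracle$residuals / o_scale, tolerance = 1e-6)
  # convergence contract: residual row and column medians vanish
  expect_lt(max(abs(apply(bs$residuals, 1, median))), 1e-6)
  expect_lt(max(abs(apply(bs$residuals, 2, median))), 1e-6)
})

test_that("control wells receive B-scores without driving the polish", {
  set.seed(11)
  mat <- matrix(rnorm(36, 0, 0.1), 6, 6)
  lib <- matrix(TRUE, 6, 6)
  lib[, 1] <- FALSE # control column with a huge planted phenotype
  mat[, 1] <- mat[, 1] + 50
  bs <- bscore_normalize(mat, lib)
  # the control column's offset is preserved in its scores, not absorbed
  expect_true(all(bs$b_scores[, 1] > 10))
  # library wells score far below the control column
  expect_lt(max(abs(bs$b_scores[, -1])), min(bs$b_scores[, 1]) / 10)
})

test_that("robust Z has the stated centre, scale and fallbacks", {
  ref <- c(1, 2, 3, 4, 5, 6, 7, 100)
  expect_equal(robust_z(median(ref), ref), 0)
  expect_equal(robust_z(median(ref) + mad(ref), ref), 1)

  set.seed(4)
  ref2 <- rnorm(10000)
  z <- robust_z(ref2, ref2)
  expect_lt(abs(mean(z)), 0.05)
  expect_gt(sd(z), 0.95); expect_lt(sd(z), 1.05)

  expect_warning(zc <- robust_z(c(5, 5, 5, 6), c(5, 5, 5, 5, 5, 5, 6, 4)),
                 "MAD is zero")
  expect_true(all(is.finite(zc)))
  expect_error(robust_z(1, c(1, 2, 3)), "at least 8")
})

test_that("replicate merging computes mean Z and the two-point SD", {
  t1 <- data.frame(perturbation = c("A", "B"), metric = "m", z = c(2, 1))
  t2 <- data.frame(perturbation = c("A", "B"), metric = "m", z = c(4, 1))
  m <- merge_replicates(list(t1, t2))
  expect_equal(m$mean_z[m$perturbation == "A"], 3)
  expect_equal(m$z_sd[m$perturbation == "A"], sqrt(2))
  expect_equal(m$z_sd[m$perturbation == "B"], 0)

  single <- merge_replicates(list(t1))
  expect_equal(single$mean_z, t1$z[order(t1$perturbation)])
  expect_true(all(is.na(single$z_sd)))

  bad <- data.frame(perturbation = c("A", "C"), metric = "m", z = 0)
  expect_error(merge_replicates(list(t1, bad)), "mismatched keys")
})

test_that("hit calling applies thresholds, directions and exclusions", {
  zs <- data.frame(
    perturbation = rep(c("hitA", "incons", "toxic", "neut"), each = 2),
    metric = rep(c("clustering_score", "spot_count"), 4),
    mean_z = c(3.1, -1.0, 3.0, 0.2, 4.0, 4.0, 0.3, -0.1),
    z_sd = c(0.4, 0.3, 3.5, 0.1, 0.2, 0.2, 0.2, 0.2),
    n_replicates = 2
  )
  cc <- data.frame(perturbation = c("hitA", "incons", "toxic", "neut"),
                   mean_z = c(-1.0, 0, -3.0, 0))
  hits <- call_hits(zs, cc)
  h <- hits[hits$perturbation == "hitA", ]
  expect_true(h$hit_clustering)
  expect_equal(h$direction_clustering, "clustered")
  expect_false(h$hit_spot)

  inc <- hits[hits$perturbation == "incons", ]
  expect_false(inc$hit_clustering) # |3.0| < 3.5 replicate SD
  expect_match(inc$reasons, "inconsistent:clustering_score")

  tox <- hits[hits$perturbation == "toxic", ]
  expect_false(tox$hit)
  expect_true(tox$excluded)
  expect_match(tox$reasons, "cytotoxic")

  expect_false(hits[hits$perturbation == "neut", "hit"])

  # idempotent: calling again on the same inputs is identical
  expect_identical(hits, call_hits(zs, cc))
})

test_that("hit categories follow the joint sign pattern of both metrics", {
  mk <- function(gene, zc, zsct) data.frame(
    perturbation = gene, metric = c("clustering_score", "spot_count"),
    mean_z = c(zc, zsct), z_sd = 0.1, n_replicates = 2)
  zs <- rbind(mk("g_clust", 3, -3), mk("g_disp", -3, 3),
              mk("g_fewer", -3, -3), mk("g_more", 3, 3),
              mk("g_conly", 3, 0), mk("g_sonly", 0, 3))
  cc <- data.frame(perturbation = unique(zs$perturbation), mean_z = 0)
  cats <- categorize_hits(call_hits(zs, cc))
  lookup <- setNames(cats$genes$category, cats$genes$perturbation)
  expect_equal(lookup[["g_clust"]], "higher overall clustering")
  expect_equal(lookup[["g_disp"]], "overall dispersion")
  expect_equal(lookup[["g_fewer"]], "global dispersion, local clustering")
  expect_equal(lookup[["g_conly"]], "clustering-only")
  expect_equal(lookup[["g_sonly"]], "count-only")
  expect_equal(sum(cats$counts), 6)
})
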