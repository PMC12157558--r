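# Generators: nucleus masks, spot point processes, rendered images,
# cell-cycle mixtures and screen simulation.

test_that("nucleus masks have the requested geometry and ground truth", {
  px <- 0.2
  nm <- generate_nucleus_mask(nucleus_shape_params(8), px, seed = 2)
  expect_lt(abs(nm$truth$area_um2 - pi * 64) / (pi * 64), 0.1)
  expect_gte(nm$truth$solidity, 0.99) # convex disk

  # a single connected component
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(nm$mask)))
  expect_equal(max(lab), 1)

  # deep notches push solidity below the dysmorphic threshold
  for (s in 1:5) {
    notched <- generate_nucleus_mask(
      nucleus_shape_params(8, concavity_count = 4), px, seed = s)
    expect_lt(notched$truth$solidity, 0.85)
    lab <- as.matrix(EBImage::bwlabel(EBImage::Image(notched$mask)))
    expect_equal(max(lab), 1)
  }

  # solidity decreases with concavity count in expectation
  mean_sol <- sapply(c(0L, 2L, 4L), function(cc) {
    mean(sapply(1:8, function(s)
      generate_nucleus_mask(nucleus_shape_params(8, concavity_count = cc),
                            px, seed = s)$truth$solidity))
  })
  expect_true(all(diff(mean_sol) < 0))

  expect_error(generate_nucleus_mask(nucleus_shape_params(0.2), 0.108),
               "3 pixels")
})

test_that("mask generation is deterministic under a fixed seed", {
  p <- nucleus_shape_params(6, eccentricity = 0.5,
                            boundary_roughness = 0.08,
                            concavity_count = 2)
  a <- generate_nucleus_mask(p, 0.2, seed = 42)
  b <- generate_nucleus_mask(p, 0.2, seed = 42)
  expect_identical(a$mask, b$mask)
  expect_identical(a$truth$solidity, b$truth$solidity)
})

test_that("CSR sampling is uniform over the mask support", {
  px <- 0.2
  mask <- disk_mask(8, px)
  sp <- sample_spots(mask, spot_process_params("CSR", 1000), px, seed = 5)
  expect_equal(nrow(sp), 1000)
  expect_true(all(points_ok <- sp$x_um > 0 & sp$y_um > 0))
  # centroid of many uniform points is near the disk centre
  ctr <- (nrow(mask) / 2) * px
  se <- 8 / sqrt(2) / sqrt(1000) # sd of a coordinate ~ R/2
  expect_lt(abs(mean(sp$x_um) - ctr), 3 * se)
  expect_lt(abs(mean(sp$y_um) - ctr), 3 * se)

  # chi-square over quadrats of a square mask
  sq <- rect_mask(20, 20, px)
  pts <- sample_spots(sq, spot_process_params("CSR", 10000), px, seed = 8)
  qx <- cut(pts$x_um, seq(0, 20, by = 4))
  qy <- cut(pts$y_um, seq(0, 20, by = 4))
  tab <- table(qx, qy)
  p <- suppressWarnings(chisq.test(as.vector(tab))$p.value)
  expect_gt(p, 0.01)
})

test_that("spot samples always lie inside the mask", {
  px <- 0.2
  masks <- irregular_masks(px, 1:4)
  configs <- list(
    spot_process_params("CSR", 40),
    spot_process_params("cluster", 40, n_parents = 3,
                        cluster_sigma_um = 0.6),
    spot_process_params("regular", 15, inhibition_radius_um = 1.2)
  )
  for (m in masks) {
    for (cfg in configs) {
      sp <- sample_spots(m, cfg, px, seed = 11)
      inside <- centroscreen:::points_in_mask(m, sp$x_um, sp$y_um, px)
      expect_true(all(inside))
      expect_equal(nrow(sp), cfg$n_spots)
    }
  }
})

test_that("cluster process collapses as sigma goes to zero and beats CSR", {
  px <- 0.2
  mask <- disk_mask(7, px)
  tight <- sample_spots(mask,
                        spot_process_params("cluster", 20, n_parents = 1,
                                            cluster_sigma_um = 1e-4),
                        px, seed = 3)
  expect_lt(max(dist(cbind(tight$x_um, tight$y_um))), 0.01)

  # mean nearest-neighbour distance below CSR expectation, over many cells
  nn_cl <- nn_csr <- numeric(100)
  for (i in 1:100) {
    cl <- sample_spots(mask,
                       spot_process_params("cluster", 23, n_parents = 3,
                                           cluster_sigma_um = 0.7),
                       px, seed = i)
    cs <- sample_spots(mask, spot_process_params("CSR", 23), px,
                       seed = i + 1000)
    nn_cl[i] <- mean(nn_distances(cl$x_um, cl$y_um))
    nn_csr[i] <- mean(nn_distances(cs$x_um, cs$y_um))
  }
  expect_lt(mean(nn_cl), mean(nn_csr))
})

test_that("uniform points in a disk have mean relative radius 2/3", {
  px <- 0.15
  mask <- disk_mask(8, px)
  sp <- sample_spots(mask, spot_process_params("CSR", 20000), px, seed = 2)
  ctr <- (nrow(mask) / 2) * px
  r <- sqrt((sp$x_um - ctr)^2 + (sp$y_um - ctr)^2)
  expect_lt(abs(mean(r / 8) - 2 / 3), 0.01)
})

test_that("infeasible hard-core packing raises an error", {
  px <- 0.2
  mask <- disk_mask(3, px) # area ~28 um2
  expect_error(
    sample_spots(mask,
                 spot_process_params("regular", 50,
                                     inhibition_radius_um = 2),
                 px, seed = 1, max_tries = 2000),
    "packing"
  )
})

test_that("rendered images honour the noise and PSF contracts", {
  px <- 0.108
  nm <- generate_nucleus_mask(nucleus_shape_params(4), px, seed = 1)
  none <- sample_spots(nm$mask, spot_process_params("CSR", 1), px, 1)[0, ]
  img0 <- render_cell_image(nm$mask, none, 0.25, Inf, px,
                            background = 0.02)
  expect_equal(max(abs(img0$spots - 0.02)), 0)

  sp <- sample_spots(nm$mask,
                     spot_process_params("regular", 8,
                                         inhibition_radius_um = 1.6),
                     px, seed = 4)
  img <- render_cell_image(nm$mask, sp, 0.25, Inf, px)
  expect_false(img$truth$merged_spots)
  # noiseless, well-separated: per-spot peak pixel within 0.5 px of truth
  for (i in seq_len(nrow(sp))) {
    r0 <- floor(sp$y_um[i] / px) + 1
    c0 <- floor(sp$x_um[i] / px) + 1
    w <- img$spots[(r0 - 3):(r0 + 3), (c0 - 3):(c0 + 3)]
    pk <- which(w == max(w), arr.ind = TRUE)[1, ]
    peak_xy <- c((c0 - 4 + pk[2] - 0.5) * px, (r0 - 4 + pk[1] - 0.5) * px)
    err <- sqrt(sum((peak_xy - c(sp$x_um[i], sp$y_um[i]))^2)) / px
    expect_lt(err, 1) # pixel-grid peak is within one pixel diagonal
  }

  # spots closer than the resolvability limit carry the merged flag
  two <- data.frame(x_um = c(5, 5 + 1.5 * 0.25), y_um = c(5, 5))
  imgm <- render_cell_image(nm$mask, two, 0.25, Inf, px)
  expect_true(imgm$truth$merged_spots)
  # and the rendered profile between them indeed has a single maximum
  prof <- imgm$spots[floor(5 / px) + 1, ]
  expect_equal(sum(diff(sign(diff(prof))) == -2), 1)
})

test_that("cell-cycle mixtures reproduce their planted composition", {
  p_all_g1 <- cell_cycle_mixture_params(fractions = c(1, 0, 0))
  pop <- simulate_cell_cycle_population(p_all_g1, 500, seed = 1)
  expect_true(all(pop$true_phase == "G1"))
  expect_lt(mean(pop$edu_integrated), p_all_g1$edu_pos_mean / 10)

  p_g2 <- cell_cycle_mixture_params(fractions = c(0, 0, 1))
  pop2 <- simulate_cell_cycle_population(p_g2, 2000, seed = 2)
  expect_lt(abs(mean(pop2$dapi_integrated) - 2 * p_g2$dapi_2n_mean) /
              (2 * p_g2$dapi_2n_mean), 0.02)
  expect_true(all(pop2$true_spot_count == 2 * p_g2$spot_count_g1))

  p_mix <- cell_cycle_mixture_params(fractions = c(0.5, 0.25, 0.25))
  pop3 <- simulate_cell_cycle_population(p_mix, 10000, seed = 3)
  fr <- prop.table(table(pop3$true_phase))
  expect_lt(abs(fr[["G1"]] - 0.5), 0.02)
  expect_lt(abs(fr[["S"]] - 0.25), 0.02)
  expect_lt(abs(fr[["G2M"]] - 0.25), 0.02)

  # log2 DAPI is bimodal for the G1/G2M subpopulations
  ld <- log2(pop3$dapi_integrated[pop3$true_phase != "S"])
  dens <- density(ld)
  n_modes <- sum(diff(sign(diff(dens$y))) == -2)
  expect_gte(n_modes, 2)
})

test_that("screen simulation plants effects and lethality as configured", {
  # no effects, no artifacts: well means scatter around the baseline
  des0 <- small_screen_design()
  sim0 <- simulate_screen(des0)
  lib <- sim0$cells[sim0$cells$control_class == "library", ]
  wm <- tapply(lib$clustering_score,
               paste(lib$replicate, lib$well), mean)
  expect_lt(abs(mean(wm)), 0.1)
  expect_lt(sd(wm), 3 * sim0$truth$sd_well_clustering)

  # lethal control wells are far below the baseline cell count
  counts <- table(sim0$cells$control_class,
                  paste(sim0$cells$replicate, sim0$cells$well))
  lethal_wells <- sim0$plate_map$well[
    sim0$plate_map$control_class == "lethal_ctrl"]
  n_lethal <- sapply(lethal_wells, function(w)
    sum(sim0$cells$well == w & sim0$cells$replicate == 1))
  base_median <- median(table(
    sim0$cells$well[sim0$cells$control_class == "library" &
                      sim0$cells$replicate == 1]))
  expect_lt(mean(n_lethal), 0.1 * base_median)

  # planted effect shifts the well means in the right direction
  planted <- data.frame(perturbation = "GENE0010", d_clustering = 4,
                        d_spot = 0, d_cellcount = 0)
  simp <- simulate_screen(small_screen_design(planted = planted))
  g10 <- simp$cells[simp$cells$perturbation == "GENE0010", ]
  others <- simp$cells[simp$cells$control_class == "library" &
                         simp$cells$perturbation != "GENE0010", ]
  expect_gt(mean(g10$clustering_score),
            mean(others$clustering_score) +
              2 * simp$truth$sd_well_clustering)

  # unknown planted perturbation is rejected
  expect_error(simulate_screen(small_screen_design(
    planted = data.frame(perturbation = "NOPE", d_clustering = 1,
                         d_spot = 0, d_cellcount = 0))),
    "unknown perturbation")

  # determinism
  sim0b <- simulate_screen(des0)
  expect_identical(sim0$cells, sim0b$cells)
})
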