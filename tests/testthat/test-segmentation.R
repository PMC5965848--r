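test_that("edge weights follow the Gaussian law on normalized intensities", {
  # equal intensities give weight exactly 1
  wt <- build_weights(array(3.7, c(3, 3, 3)))
  expect_true(all(wt$w == 1))
  # maximal normalized contrast gives exp(-beta)
  v <- array(0, c(2, 1, 1)); v[2, 1, 1] <- 5
  wt <- build_weights(v, rw_params(beta = 90))
  expect_equal(wt$w, exp(-90))
  expect_true(all(wt$w > 0 & wt$w <= 1))
  expect_error(build_weights(array(numeric(0), c(0, 1, 1))), "empty")
})

test_that("weights match a brute-force double loop on random volumes", {
  set.seed(8)
  for (conn in c(6, 18, 26)) {
    vals <- array(runif(27), c(3, 3, 3))
    wt <- build_weights(vals, rw_params(beta = 50, connectivity = conn))
    W <- oracle_weights_dense(vals, beta = 50, connectivity = conn)
    # same edge set, same weights, symmetric
    Wpkg <- matrix(0, 27, 27)
    Wpkg[cbind(wt$i, wt$j)] <- wt$w
    Wpkg[cbind(wt$j, wt$i)] <- wt$w
    expect_equal(Wpkg, W, tolerance = 1e-12)
  }
})

test_that("fully seeded volumes return the seed indicator exactly", {
  lab <- array(1L, c(3, 3, 2))
  lab[1:2, 1, 1] <- 2L
  pm <- solve_rw(array(runif(18), c(3, 3, 2)), seed_map(lab))
  expect_identical(pm$prob, array(as.numeric(lab == 2L), dim(lab)))
})

test_that("uniform 1D chain yields the linear harmonic solution", {
  for (n in c(3, 5, 9)) {
    lab <- array(0L, c(n, 1, 1))
    lab[1, 1, 1] <- 1L            # background end
    lab[n, 1, 1] <- 2L            # target end
    pm <- solve_rw(array(1, c(n, 1, 1)), seed_map(lab))
    expect_equal(as.numeric(pm$prob), (0:(n - 1)) / (n - 1),
                 tolerance = 1e-12)
  }
})

test_that("solver matches the absorbing-Markov-chain oracle on random lattices", {
  set.seed(12)
  for (rep in 1:20) {
    inst <- random_rw_instance(4L)
    pm <- solve_rw(inst$values, seed_map(inst$labels),
                   rw_params(beta = inst$beta))
    expect_lt(max(abs(pm$prob - oracle_rw_dense(inst$values, inst$labels,
                                                beta = inst$beta))),
              1e-6)
    # maximum principle and two-label conservation
    expect_true(all(pm$prob >= 0 & pm$prob <= 1))
    swapped <- inst$labels
    swapped[inst$labels == 1L] <- 2L
    swapped[inst$labels == 2L] <- 1L
    pm2 <- solve_rw(inst$values, seed_map(swapped),
                    rw_params(beta = inst$beta))
    expect_equal(pm$prob + pm2$prob, array(1, dim(inst$labels)),
                 tolerance = 1e-9)
  }
})

test_that("interior probabilities never exceed their neighborhood maximum", {
  set.seed(13)
  inst <- random_rw_instance(4L)
  pm <- solve_rw(inst$values, seed_map(inst$labels),
                 rw_params(beta = inst$beta))
  d <- dim(pm$prob)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (inst$labels[i, j, k] != 0L) next
    nb <- c()
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- c(i, j, k) + o
      if (all(p >= 1) && all(p <= d)) nb <- c(nb, pm$prob[p[1], p[2], p[3]])
    }
    expect_lte(pm$prob[i, j, k], max(nb) + 1e-9)
    expect_gte(pm$prob[i, j, k], min(nb) - 1e-9)
  }
})

test_that("iterative and direct solvers agree", {
  set.seed(21)
  vals <- array(runif(6 * 6 * 6), c(6, 6, 6))
  lab <- array(0L, c(6, 6, 6))
  lab[1, , ] <- 1L
  lab[4, 3:4, 3:4] <- 2L
  direct <- solve_rw(vals, seed_map(lab), rw_params(beta = 12))
  iterative <- solve_rw(vals, seed_map(lab),
                        rw_params(beta = 12, direct_limit = 1,
                                  solver_tolerance = 1e-12))
  expect_lt(max(abs(direct$prob - iterative$prob)), 1e-6)
})

test_that("seed-partitioned chains solve each side independently, silently", {
  # seeds split the unlabeled set into two components, each with its own
  # Dirichlet boundary; on a connected lattice every unlabeled component
  # borders a seed, so no orphan warning is ever raised here
  vals <- array(1, c(7, 1, 1))
  lab <- array(0L, c(7, 1, 1))
  lab[c(2, 6), 1, 1] <- 1L
  lab[4, 1, 1] <- 2L
  expect_silent(pm <- solve_rw(vals, seed_map(lab)))
  # interior of each 3-chain (bkg, ?, tgt) is harmonic: 1/2
  expect_equal(pm$prob[3, 1, 1], 0.5, tolerance = 1e-12)
  expect_equal(pm$prob[5, 1, 1], 0.5, tolerance = 1e-12)
  # end voxels hang off a background seed only: absorbed there
  expect_equal(pm$prob[1, 1, 1], 0)
  expect_equal(pm$prob[7, 1, 1], 0)
})

test_that("thresholding is monotone and respects the seeds", {
  set.seed(14)
  inst <- random_rw_instance(4L)
  pm <- solve_rw(inst$values, seed_map(inst$labels))
  masks <- lapply(c(0.2, 0.5, 0.8), function(p)
    threshold_map(pm, rw_params(prob_threshold = p))$values)
  expect_true(all(masks[[2]] <= masks[[1]]))
  expect_true(all(masks[[3]] <= masks[[2]]))
  for (m in masks) {
    expect_true(all(m[inst$labels == 2L]))
    expect_false(any(m[inst$labels == 1L]))
  }
})

test_that("automatic seeding handles hot spots, uniform ROIs and phantoms", {
  # single hot voxel becomes the only target seed
  v <- array(0, c(5, 5, 5)); v[3, 3, 3] <- 10
  sm <- auto_seeds(v)
  expect_identical(which(sm$labels == 2L), which(v == 10))
  expect_gt(sum(sm$labels == 1L), 0)
  # uniform ROI still produces disjoint non-empty seed sets
  smu <- auto_seeds(array(1, c(4, 4, 4)))
  expect_gt(sum(smu$labels == 2L), 0)
  expect_gt(sum(smu$labels == 1L), 0)
  expect_false(any(smu$labels == 1L & smu$labels == 2L))
  # noiseless phantom: every target seed lies inside the truth mask
  sp <- phantom_spec(c(20, 20, 20),
                     lesions = list(list(center = c(10, 10, 10),
                                         semi_axes = 3,
                                         uptake_contrast = 5)),
                     psf_fwhm = 0.8, noise = "none")
  ph <- make_phantom(sp, seed = 1)
  roi <- mask_bbox(ph$truth, pad = 3)
  seg <- segment_lesion(ph$volume, roi)
  tgt_full <- array(FALSE, dim(ph$volume$values))
  tgt_full[(roi$lo[1] + 1):roi$hi[1], (roi$lo[2] + 1):roi$hi[2],
           (roi$lo[3] + 1):roi$hi[3]] <- seg$seeds$labels == 2L
  expect_true(all(ph$truth$values[tgt_full]))
  expect_error(auto_seeds(array(1, c(1, 1, 1))), "too small")
})

test_that("phantom segmentation recovers the truth mask (median Dice >= 0.9)", {
  dices <- vapply(1:20, function(rep) {
    sp <- phantom_spec(c(24, 24, 24),
                       lesions = list(list(center = c(12, 12, 12),
                                           semi_axes = 4,
                                           uptake_contrast = 5)),
                       background_suv = 1, psf_fwhm = 1,
                       noise = "gaussian", noise_scale = 0.5)
    ph <- make_phantom(sp, seed = 700 + rep)
    seg <- segment_lesion(ph$volume, mask_bbox(ph$truth, pad = 4))
    dice_coef(seg$mask$values, ph$truth$values)
  }, 0)
  expect_gte(median(dices), 0.9)
})
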