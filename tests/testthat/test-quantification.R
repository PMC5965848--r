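test_that("SUV normalization maps whole-body-uniform uptake to 1", {
  m <- acquisition_meta(10, 25)
  conc <- array(10 * 1000 / 25, c(6, 6, 6))     # kBq/mL
  v <- image_volume(conc, units = "activity_concentration", meta = m)
  s <- to_suv(v)
  expect_true(all(abs(s$values - 1) < 1e-12))
  expect_equal(s$units, "suv")
})

test_that("SUV is linear in concentration and inverse in injected activity", {
  set.seed(3)
  conc <- array(runif(64, 1, 100), c(4, 4, 4))
  v1 <- image_volume(conc, units = "activity_concentration",
                     meta = acquisition_meta(5, 25))
  v2 <- image_volume(conc, units = "activity_concentration",
                     meta = acquisition_meta(10, 25))
  expect_equal(to_suv(v1)$values, 2 * to_suv(v2)$values, tolerance = 1e-12)
})

test_that("to_suv is the identity on volumes already in SUV units", {
  v <- image_volume(array(2, c(4, 4, 4)), units = "suv")
  expect_identical(to_suv(v), v)
  raw <- image_volume(array(2, c(4, 4, 4)), units = "activity_concentration")
  expect_error(to_suv(raw), "metadata")
})

test_that("uniform and single-voxel masks give the textbook metrics", {
  vals <- array(0.5, c(10, 10, 10))
  m <- array(FALSE, c(10, 10, 10))
  m[1:4, 1:5, 1:5] <- TRUE                       # 100 voxels
  vals[m] <- 2
  vol <- image_volume(vals, spacing = c(1, 1, 1))
  mm <- lesion_metrics(vol, lesion_mask(m))
  expect_equal(mm$suv_max, 2)
  expect_equal(mm$suv_mean, 2)
  expect_equal(mm$mtv, 100)
  expect_equal(mm$total_lesion, 200)
  one <- array(FALSE, c(10, 10, 10)); one[3, 3, 3] <- TRUE
  m1 <- lesion_metrics(vol, lesion_mask(one))
  expect_equal(m1$suv_max, m1$suv_mean)
  expect_equal(m1$mtv, 1)
})

test_that("MTV scales with voxel volume, and empty masks are flagged not fatal", {
  vals <- array(1, c(6, 6, 6))
  m <- array(FALSE, c(6, 6, 6)); m[2:3, 2:3, 2:3] <- TRUE
  vol <- image_volume(vals, spacing = c(0.5, 0.5, 2))
  mm <- lesion_metrics(vol, lesion_mask(m, spacing = c(0.5, 0.5, 2)))
  expect_equal(mm$mtv, 8 * 0.5 * 0.5 * 2)
  e <- lesion_metrics(vol, lesion_mask(array(FALSE, c(6, 6, 6)),
                                       spacing = c(0.5, 0.5, 2)))
  expect_equal(e$mtv, 0)
  expect_true(is.na(e$suv_max))
  expect_equal(e$total_lesion, 0)
})

test_that("metric identities hold on random segmented phantoms", {
  set.seed(9)
  for (rep in 1:5) {
    sp <- phantom_spec(c(16, 16, 16),
                       lesions = list(list(center = c(8, 8, 8),
                                           semi_axes = runif(1, 2, 4),
                                           uptake_contrast = runif(1, 2, 9))),
                       psf_fwhm = runif(1, 0, 1.5),
                       noise = "gaussian", noise_scale = 0.1)
    ph <- make_phantom(sp, seed = 30 + rep)
    mm <- lesion_metrics(ph$volume, ph$truth)
    expect_identical(mm$total_lesion, mm$suv_mean * mm$mtv)
    expect_lte(mm$suv_mean, mm$suv_max)
  }
})

test_that("noiseless sphere MTV and SUVmean equal the analytic truth", {
  sp <- phantom_spec(c(24, 24, 24),
                     lesions = list(list(center = c(12, 12, 12),
                                         semi_axes = 3,
                                         uptake_contrast = 4)),
                     background_suv = 1.5, psf_fwhm = 0, noise = "none")
  ph <- make_phantom(sp, seed = 1)
  mm <- lesion_metrics(ph$volume, ph$truth)
  expect_equal(mm$mtv, oracle_ellipsoid_count(3) * 1)
  expect_equal(mm$suv_mean, 4 * 1.5)
  expect_equal(mm$suv_max, 4 * 1.5)
})

test_that("percentage changes follow the definition and flag zero baselines", {
  mk <- function(sm, sn, mtv, tracer = "FDG")
    structure(list(suv_max = sm, suv_mean = sn, mtv = mtv,
                   total_lesion = sn * mtv, tracer = tracer),
              class = "lesion_metrics")
  d0 <- pct_change(mk(3, 2, 50), mk(3, 2, 50))
  expect_equal(d0$d_suv_max, 0)
  expect_equal(d0$d_mtv, 0)
  d <- pct_change(mk(10, 5, 50), mk(1.131, 5, 125))
  expect_equal(d$d_suv_max, -88.69)
  expect_equal(d$d_mtv, 150)
  # zero baseline flags only the affected delta
  dz <- pct_change(mk(10, 5, 0), mk(5, 5, 10))
  expect_true(is.na(dz$d_mtv))
  expect_equal(dz$d_suv_max, -50)
  expect_error(pct_change(mk(1, 1, 1), mk(1, 1, 1, tracer = "FLT")),
               "tracer")
})

test_that("pct_change of SUV metrics is invariant to SUV rescaling", {
  mk <- function(sm, sn, mtv)
    structure(list(suv_max = sm, suv_mean = sn, mtv = mtv,
                   total_lesion = sn * mtv, tracer = "FDG"),
              class = "lesion_metrics")
  for (k in c(0.2, 1, 7.5)) {
    a <- pct_change(mk(8, 4, 60), mk(2, 1.5, 30))
    b <- pct_change(mk(8 * k, 4 * k, 60), mk(2 * k, 1.5 * k, 30))
    expect_equal(a$d_suv_max, b$d_suv_max, tolerance = 1e-12)
    expect_equal(a$d_suv_mean, b$d_suv_mean, tolerance = 1e-12)
    expect_equal(a$d_mtv, b$d_mtv)                 # MTV untouched by k
  }
})
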