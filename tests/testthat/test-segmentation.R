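test_that("breast segmentation recovers the phantom with the auto threshold", {
  ph <- quiet_phantom()
  br <- segment_breast(ph$volume)
  expect_gte(dice(br, ph$masks$breast), 0.99)
  expect_true(attr(br, "threshold") > 0 && attr(br, "threshold") < 60)
})

test_that("degenerate inputs signal 'no breast found'", {
  z <- dce_volume(array(0, c(6, 6, 6, 4)), spacing = c(1, 1, 1))
  expect_error(segment_breast(z, skin_threshold = 1), "no breast")
  ph <- quiet_phantom()
  expect_error(segment_breast(ph$volume,
                              skin_threshold = max(ph$volume$data) + 1),
               "no breast")
})

test_that("chest-wall exclusion removes the flagged side", {
  ph <- quiet_phantom()
  cw <- chest_wall_plane(dim(ph$volume$data)[1:3], axis = 3, k = 4,
                         side = "le")
  br <- segment_breast(ph$volume, chest_wall = cw)
  expect_false(any(br[, , 1:4]))
  expect_true(any(br[, , 5:10]))
})

test_that("region growing recovers a separable tumor exactly and honors the seed", {
  ph <- quiet_phantom()
  ctr <- round(colMeans(which(ph$masks$tumor, arr.ind = TRUE)))
  tm <- region_grow_tumor(ph$volume, seed_point = ctr,
                          intensity_band = c(250, 350))
  expect_identical(as.vector(tm), as.vector(ph$masks$tumor))
  expect_false(attr(tm, "touches_boundary"))
  # a seed in adipose tissue is rejected
  adi <- which(ph$masks$adipose, arr.ind = TRUE)[1, ]
  expect_error(region_grow_tumor(ph$volume, seed_point = adi,
                                 intensity_band = c(250, 350)),
               "invalid seed")
})

test_that("growth from one of two disjoint spheres stays in the seeded one", {
  # toy volume: two spheres of value 300 in background 100
  dm <- c(21, 11, 11)
  v <- array(100, dm)
  mk_sphere <- function(c0, r) {
    arr <- array(FALSE, dm)
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3])
      if (sum((c(x, y, z) - c0)^2) <= r^2) arr[x, y, z] <- TRUE
    arr
  }
  s1 <- mk_sphere(c(5, 6, 6), 3); s2 <- mk_sphere(c(16, 6, 6), 3)
  v[s1] <- 300; v[s2] <- 300
  vol <- dce_volume(array(rep(v, 4), c(dm, 4)), spacing = c(1, 1, 1))
  tm <- region_grow_tumor(vol, seed_point = c(5, 6, 6),
                          intensity_band = c(250, 350))
  expect_identical(as.vector(tm), as.vector(s1))
})

test_that("region growing is monotone in the intensity band", {
  ph <- generate_dce_phantom(phantom_spec(seed = 5))  # noisy
  ctr <- round(colMeans(which(ph$masks$tumor, arr.ind = TRUE)))
  narrow <- region_grow_tumor(ph$volume, ctr, c(260, 340))
  wide <- region_grow_tumor(ph$volume, ctr, c(240, 360))
  expect_true(all(wide[narrow]))
})

test_that("fuzzy c-means finds bimodal centroids and exact assignment", {
  dm <- c(15, 10, 10)
  v <- array(50, dm)
  v[1:5, , ] <- 200  # 500 voxels bright, 1000 dark
  vol <- dce_volume(array(rep(v, 4), c(dm, 4)), spacing = c(1, 1, 1))
  mask <- array(TRUE, dm)
  fit <- fuzzy_cmeans_partition(vol, mask)
  expect_equal(fit$centers, c(200, 50), tolerance = 1e-3)
  expect_identical(as.vector(fit$parenchyma), as.vector(v == 200))
  expect_equal(rowSums(fit$membership), rep(1, sum(mask)), tolerance = 1e-12)
  # label orientation is configurable
  fit2 <- fuzzy_cmeans_partition(vol, mask, parenchyma_is = "darker")
  expect_identical(as.vector(fit2$parenchyma), as.vector(v == 50))
})

test_that("fuzzy c-means agrees with an independent implementation", {
  set.seed(42)
  x <- c(rnorm(300, 60, 8), rnorm(200, 180, 12))
  vol <- dce_volume(array(rep(pmax(x, 0), 4), c(500, 1, 1, 4)),
                    spacing = c(1, 1, 1))
  fit <- fuzzy_cmeans_partition(vol, array(TRUE, c(500, 1, 1)))
  ref <- e1071::cmeans(matrix(x, ncol = 1), centers = matrix(c(60, 180)),
                       m = 2, iter.max = 300)
  expect_equal(sort(fit$centers), sort(as.numeric(ref$centers)),
               tolerance = 1e-3)
})

test_that("identical intensities are a degenerate clustering", {
  vol <- dce_volume(array(5, c(4, 4, 4, 4)), spacing = c(1, 1, 1))
  expect_error(fuzzy_cmeans_partition(vol, array(TRUE, c(4, 4, 4))),
               "degenerate")
})

test_that("phantom parenchyma is recovered and density is faithful", {
  ph <- generate_dce_phantom(phantom_spec(
    parenchyma_fraction = 0.35, noise_sd = 0,
    bpe_heterogeneity = list(variance = 0, corr_length = 6)))
  br <- segment_breast(ph$volume)
  ctr <- round(colMeans(which(ph$masks$tumor, arr.ind = TRUE)))
  tm <- region_grow_tumor(ph$volume, ctr, c(250, 350))
  fcm <- fuzzy_cmeans_partition(ph$volume, mask = br & !tm)
  expect_gte(dice(fcm$parenchyma, ph$masks$parenchyma), 0.95)
  masks <- compartment_masks(br | tm, tm, fcm$parenchyma & !tm)
  expect_lt(abs(breast_density(masks) - 35), 2)
})

test_that("breast density is voxel-count arithmetic with guarded edge cases", {
  dm <- c(10, 10, 10)
  breast <- array(TRUE, dm)
  par <- array(FALSE, dm); par[1:2, , ] <- TRUE          # 200 of 1000
  m <- compartment_masks(breast, array(FALSE, dm), par)
  expect_equal(breast_density(m), 20)
  m0 <- compartment_masks(breast, array(FALSE, dm), array(FALSE, dm))
  expect_equal(breast_density(m0), 0)
  expect_equal(breast_density(compartment_masks(breast, array(FALSE, dm),
                                                breast)), 100)
  expect_error(compartment_masks(array(FALSE, dm), array(FALSE, dm),
                                 par), "outside")
})
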