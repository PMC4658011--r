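test_that("first-order statistics follow the sample conventions", {
  s <- first_order_stats(1:5)
  expect_equal(unname(s["mean"]), 3)
  expect_equal(unname(s["std"]), sd(1:5))
  expect_equal(unname(s["skewness"]), 0)
  # constant input: zero spread, undefined shape
  s0 <- first_order_stats(rep(5, 4))
  expect_equal(unname(s0["std"]), 0)
  expect_true(is.na(s0["skewness"]) && is.na(s0["kurtosis"]))
  # insufficient n returns missing moments, never zero
  expect_true(is.na(first_order_stats(c(1, 2))["skewness"]))
  expect_true(is.na(first_order_stats(c(1, 2, 3))["kurtosis"]))
  expect_error(first_order_stats(numeric(0)), "no valid samples")
  # large-sample normal draws have near-zero excess kurtosis
  set.seed(1)
  g2 <- unname(first_order_stats(rnorm(1e5))["kurtosis"])
  expect_lt(abs(g2), 0.05)
})

test_that("quantization is uniform, monotone, and maps extremes correctly", {
  dm <- c(8, 1, 1)
  q <- quantize(array(0:7, dm), array(TRUE, dm), G = 8)
  expect_identical(q$levels[, 1, 1], 0:7)
  q2 <- quantize(array(c(10, 20), c(2, 1, 1)), array(TRUE, c(2, 1, 1)), G = 8)
  expect_identical(q2$levels[, 1, 1], c(0L, 7L))
  qc <- quantize(array(3, dm), array(TRUE, dm), G = 8)
  expect_true(qc$constant_region)
  expect_true(all(qc$levels == 0))
  # uniform values give a uniform level histogram
  set.seed(7)
  x <- array(runif(1e4), c(1e4, 1, 1))
  qu <- quantize(x, array(TRUE, dim(x)[1:3]), G = 8)
  gof <- chisq.test(tabulate(qu$levels + 1L, 8))
  expect_gt(gof$p.value, 0.01)
})

test_that("a constant region has the degenerate co-occurrence signature", {
  dm <- c(4, 4, 4)
  q <- quantize(array(2, dm), array(TRUE, dm), G = 8)
  f <- glcm_3d(q)
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Inertia"]), 0)
  expect_equal(unname(f["Homogeneity"]), 1)
  expect_equal(unname(f["ClusterShade"]), 0)
})

test_that("the hand-countable 2x2 checkerboard matches along (1,0,0)", {
  lv <- array(c(0L, 1L, 1L, 0L), c(2, 2, 1))
  q <- structure(list(levels = lv, G = 2L, mask = array(TRUE, c(2, 2, 1)),
                      bounds = c(0, 1), constant_region = FALSE),
                 class = "quantized_volume")
  f <- glcm_3d(q)
  per <- attr(f, "per_direction")
  dirs <- radbpe:::neighbor_offsets(26)
  r <- which(dirs[, 1] == 1 & dirs[, 2] == 0 & dirs[, 3] == 0)
  # pairs (0,1) and (1,0), each probability 1/2, all off-diagonal
  expect_equal(unname(per[r, "Energy"]), 0.5)
  expect_equal(unname(per[r, "Entropy"]), log(2))
  expect_equal(unname(per[r, "Inertia"]), 1)
})

test_that("the 26-direction engine equals the brute-force pair enumerator", {
  for (s in 1:20) {
    set.seed(s)
    dm <- c(6, 6, 6)
    vals <- array(rnorm(prod(dm)), dm)
    mask <- array(runif(prod(dm)) > 0.3, dm)
    if (sum(mask) < 8) mask[1:8] <- TRUE
    q <- quantize(vals, mask, G = 4)
    f <- glcm_3d(q)
    o <- oracle_glcm_features(q$levels, q$mask, q$G)
    expect_equal(unname(as.vector(f)), o, tolerance = 1e-10)
  }
})

test_that("co-occurrence features are invariant to affine map rescaling", {
  set.seed(3)
  dm <- c(7, 7, 5)
  vals <- array(rnorm(prod(dm)), dm)
  mask <- array(TRUE, dm)
  f1 <- glcm_3d(quantize(vals, mask, G = 8))
  f2 <- glcm_3d(quantize(3.7 * vals + 11, mask, G = 8))
  expect_equal(as.vector(f1), as.vector(f2), tolerance = 1e-12)
})

test_that("maximal energy coincides with zero entropy and vice versa", {
  set.seed(8)
  for (s in 1:5) {
    dm <- c(5, 5, 5)
    vals <- array(sample(0:3, prod(dm), TRUE), dm)
    f <- glcm_3d(quantize(vals, array(TRUE, dm), G = 4))
    expect_true(f["Energy"] < 1 || f["Entropy"] == 0)
    expect_true(f["Entropy"] > 0 || f["Energy"] == 1)
  }
})

test_that("a compartment yields 39 named features; two compartments 78", {
  ph <- generate_dce_phantom(phantom_spec(seed = 2, class_label = "TN"))
  maps <- parametric_maps(ph$volume, ph$masks$breast)
  ft <- extract_compartment_features(maps, ph$masks$tumor, "tumor")
  fp <- extract_compartment_features(maps, ph$masks$parenchyma, "parenchyma")
  expect_length(ft, 39)
  expect_length(fp, 39)
  expect_true("tumor SER mean" %in% names(ft))
  expect_true("parenchyma SER skewness" %in% names(fp))
  expect_length(unique(c(names(ft), names(fp))), 78)
})

test_that("zero-noise tumor maps are constant: zero spread, unit energy", {
  ph <- quiet_phantom()
  maps <- parametric_maps(ph$volume, ph$masks$breast)
  f <- extract_compartment_features(maps, ph$masks$tumor, "tumor")
  for (mp in c("rate in", "PE", "SER")) {
    expect_equal(unname(f[paste("tumor", mp, "std")]), 0)
    expect_equal(unname(f[paste("tumor", mp, "Energy")]), 1)
  }
})

test_that("BPE heterogeneity raises parenchymal rate-in spread across seeds", {
  wins <- 0L
  for (s in 1:20) {
    lo <- generate_dce_phantom(phantom_spec(seed = s, class_label = "non-TN"))
    hi <- generate_dce_phantom(phantom_spec(seed = s, class_label = "TN"))
    f_lo <- parametric_maps(lo$volume, lo$masks$parenchyma)
    f_hi <- parametric_maps(hi$volume, hi$masks$parenchyma)
    if (sd(f_hi$rate_in[hi$masks$parenchyma]) >
        sd(f_lo$rate_in[lo$masks$parenchyma])) wins <- wins + 1L
  }
  expect_gte(wins, 18)
})
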