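# Regional radiomics feature extraction: arithmetic oracles on enumerated
# fixtures, closed-form shape geometry, degenerate inputs, normalization
# and redundancy pruning.

test_that("first-order features match brute-force arithmetic on an enumerated region", {
  fx <- enumerated_region()
  fm <- extract_region_features(fx$volume, fx$parcellation)
  x <- fx$values
  n <- length(x)
  got <- fm$matrix[1, ]
  expect_equal(got[["fo_mean"]], sum(x) / n, tolerance = 1e-12)
  expect_equal(got[["fo_median"]], median(x))
  expect_equal(got[["fo_sd"]], sqrt(sum((x - mean(x))^2) / (n - 1)))
  expect_equal(got[["fo_variance"]], sum((x - mean(x))^2) / (n - 1))
  m2 <- mean((x - mean(x))^2); m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  expect_equal(got[["fo_skewness"]], m3 / m2^1.5)
  expect_equal(got[["fo_kurtosis"]], m4 / m2^2)
  expect_equal(got[["fo_energy"]], sum(x^2))
  expect_equal(got[["fo_min"]], min(x))
  expect_equal(got[["fo_max"]], max(x))
  expect_equal(got[["fo_range"]], max(x) - min(x))
  expect_equal(got[["fo_mad"]], mean(abs(x - mean(x))))
  expect_equal(got[["fo_rms"]], sqrt(sum(x^2) / n))
  # histogram features from a hand-built 32-bin fixed-width histogram
  b <- pmin(floor((x - min(x)) / (max(x) - min(x)) * 32) + 1, 32)
  p <- as.vector(table(factor(b, levels = 1:32))) / n
  expect_equal(got[["fo_entropy"]], -sum(p[p > 0] * log2(p[p > 0])))
  expect_equal(got[["fo_uniformity"]], sum(p^2))
})

test_that("constant-intensity region yields zero spread and zero texture contrast", {
  vol <- array(7, c(5, 5, 5))
  parc <- array(1L, c(5, 5, 5))
  fm <- extract_region_features(vol, parc)
  expect_equal(fm$matrix[1, "fo_sd"], 0)
  expect_equal(fm$matrix[1, "fo_entropy"], 0)
  expect_equal(fm$matrix[1, "glcm_contrast"], 0)
  expect_equal(fm$matrix[1, "glcm_dissimilarity"], 0)
  # single grey level: low/high grey-level emphases collapse to 1
  expect_equal(fm$matrix[1, "glrlm_lgre"], 1)
  expect_equal(fm$matrix[1, "glrlm_hgre"], 1)
  expect_equal(fm$matrix[1, "fo_uniformity"], 1)
})

test_that("cube mask shape features match closed-form geometry", {
  for (s in c(3, 5)) {
    vol <- array(rnorm((s + 4)^3), rep(s + 4, 3))
    parc <- array(0L, rep(s + 4, 3))
    parc[3:(s + 2), 3:(s + 2), 3:(s + 2)] <- 1L
    fm <- extract_region_features(vol, parc)
    v <- s^3
    a <- 6 * s^2
    expect_equal(fm$matrix[1, "sh_volume"], v)
    expect_equal(fm$matrix[1, "sh_surface_area"], a)
    expect_equal(fm$matrix[1, "sh_sphericity"],
                 pi^(1 / 3) * (6 * v)^(2 / 3) / a)
    expect_equal(fm$matrix[1, "sh_compactness2"], 36 * pi * v^2 / a^3)
    # farthest corners of the voxel-centre lattice
    expect_equal(fm$matrix[1, "sh_max_diameter"], sqrt(3) * (s - 1))
  }
})

test_that("GLCM features on a tiny two-voxel-pair fixture match hand computation", {
  # 2x1x1 region, values -> bins 1 and 32; only the x direction pairs
  vol <- array(c(0, 1), c(2, 1, 1))
  parc <- array(1L, c(2, 1, 1))
  fm <- extract_region_features(vol, parc)
  # symmetric GLCM: one (1,32) and one (32,1) entry, each p = 1/2
  expect_equal(fm$matrix[1, "glcm_contrast"], 31^2)
  expect_equal(fm$matrix[1, "glcm_dissimilarity"], 31)
  expect_equal(fm$matrix[1, "glcm_energy"], 0.5)
  expect_equal(fm$matrix[1, "glcm_entropy"], 1)
  expect_equal(fm$matrix[1, "glcm_max_probability"], 0.5)
  expect_equal(fm$matrix[1, "glcm_correlation"], -1)
  expect_equal(fm$matrix[1, "glcm_sum_average"], 33)
})

test_that("GLRLM counts on a striped line fixture match hand enumeration", {
  # 6x1x1 region with values AABBBA -> runs along x: (A,2),(B,3),(A,1).
  # Every other direction leaves the 6x1x1 box after one step, so each of
  # the remaining 12 directions contributes 6 singleton runs.
  vol <- array(c(5, 5, 9, 9, 9, 5), c(6, 1, 1))
  parc <- array(1L, c(6, 1, 1))
  fm <- extract_region_features(vol, parc)
  counts <- r2sn:::glrlm_counts(array(r2sn:::quantize_bins(c(5, 5, 9, 9, 9, 5)),
                                      c(6, 1, 1)))
  nr <- sum(counts)
  expect_equal(nr, 3 + 12 * 6)
  lens <- rep(col(counts)[counts > 0], counts[counts > 0])
  expect_equal(sort(unique(lens)), c(1, 2, 3))
  # run percentage: total runs over voxels x directions
  expect_equal(fm$matrix[1, "glrlm_rp"], nr / (6 * 13))
  sre_oracle <- sum(counts / matrix(seq_len(ncol(counts)),
                                    nrow(counts), ncol(counts),
                                    byrow = TRUE)^2) / nr
  expect_equal(fm$matrix[1, "glrlm_sre"], sre_oracle)
})

test_that("extraction is shift-equivariant for mean and shift-invariant for spread/texture", {
  fx <- enumerated_region()
  base <- extract_region_features(fx$volume, fx$parcellation)$matrix
  shifted <- extract_region_features(fx$volume + 50, fx$parcellation)$matrix
  expect_equal(shifted[1, "fo_mean"], base[1, "fo_mean"] + 50)
  expect_equal(shifted[1, "fo_sd"], base[1, "fo_sd"])
  expect_equal(shifted[1, "glcm_contrast"], base[1, "glcm_contrast"])
  expect_equal(shifted[1, "glrlm_sre"], base[1, "glrlm_sre"])
})

test_that("empty and malformed parcellations are rejected with informative errors", {
  vol <- array(rnorm(27), c(3, 3, 3))
  parc <- array(1L, c(3, 3, 3))
  parc[1] <- 3L  # labels 1 and 3 exist, 2 is empty
  expect_error(extract_region_features(vol, parc), "region label 2 is empty")
  expect_error(extract_region_features(vol, array(1.5, c(3, 3, 3))),
               "integer")
  expect_error(extract_region_features(vol, array(1L, c(4, 3, 3))),
               "shapes differ")
})

test_that("min-max normalization maps each column onto [0, 1] and is idempotent", {
  m <- fm_from_matrix(cbind(a = c(2, 4, 6), b = c(10, 0, 5)))
  nm <- minmax_normalize(m)
  expect_equal(unname(nm$matrix[, "a"]), c(0, 0.5, 1))
  expect_equal(min(nm$matrix[, "b"]), 0)
  expect_equal(max(nm$matrix[, "b"]), 1)
  expect_true(nm$normalized)
  again <- minmax_normalize(nm)
  expect_equal(again$matrix, nm$matrix)
  # constant column is an error naming the feature
  bad <- fm_from_matrix(cbind(ok = c(1, 2, 3), flat = c(4, 4, 4)))
  expect_error(minmax_normalize(bad), "flat")
})

test_that("redundancy pruning matches an exhaustive-verification oracle on a random fixture", {
  set.seed(11)
  base <- matrix(rnorm(20 * 3), 20, 3)
  m <- cbind(base,
             base[, 1] + rnorm(20, 0, 0.05),   # near-duplicate of col 1
             -base[, 2] + rnorm(20, 0, 0.05),  # anti-correlated with col 2
             rnorm(20))
  colnames(m) <- paste0("f", 1:6)
  fm <- fm_from_matrix(m, normalized = TRUE)
  pr <- prune_redundant_features(fm, threshold = 0.9)
  # oracle 1: no surviving pair exceeds the threshold
  cc <- abs(cor(m[, pr$retained]))
  diag(cc) <- 0
  expect_true(all(cc <= 0.9))
  # oracle 2: replay the greedy drop sequence by brute force
  keep <- colnames(m)
  dropped <- character(0)
  repeat {
    cc2 <- abs(cor(m[, keep, drop = FALSE])); diag(cc2) <- 0
    deg <- rowSums(cc2 > 0.9)
    if (max(deg) == 0) break
    victim <- keep[max(which(deg == max(deg)))]
    dropped <- c(dropped, victim)
    keep <- setdiff(keep, victim)
  }
  expect_identical(pr$retained, keep)
  expect_identical(pr$dropped, dropped)
})

test_that("pruning drops the later-ordered of two duplicated columns and nothing else", {
  set.seed(3)
  m <- matrix(rnorm(30), 10, 3)
  m <- cbind(m, m[, 2])
  colnames(m) <- c("f1", "f2", "f3", "f4")
  pr <- prune_redundant_features(fm_from_matrix(m, normalized = TRUE), 0.9)
  expect_identical(pr$dropped, "f4")
  expect_identical(pr$retained, c("f1", "f2", "f3"))
  # near-unity threshold on independent columns removes nothing
  pr2 <- prune_redundant_features(fm_from_matrix(m[, 1:3], normalized = TRUE),
                                  0.999)
  expect_identical(pr2$dropped, character(0))
  expect_error(prune_redundant_features(fm_from_matrix(m), 1.2),
               "threshold")
})

test_that("the default registry has 47 uniquely named features in fixed family blocks", {
  reg <- feature_registry()
  expect_identical(nrow(reg), 47L)
  expect_identical(anyDuplicated(reg$name), 0L)
  counts <- as.vector(table(reg$family)[c("firstorder", "shape", "glcm",
                                          "glrlm")])
  expect_equal(counts, c(14, 8, 13, 12))
})
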