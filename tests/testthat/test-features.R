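# Morphology -----------------------------------------------------------------

test_that("a filled square has its closed-form shape descriptors", {
  m <- morphology_features(square_mask())
  expect_equal(unname(m["area"]), 100)
  expect_equal(unname(m["bbox_area"]), 100)
  expect_equal(unname(m["extent"]), 1)
  expect_equal(unname(m["solidity"]), 1)
  expect_equal(unname(m["filled_area"]), 100)
  expect_equal(unname(m["euler_number"]), 1)
  expect_equal(unname(m["equivalent_diameter"]), sqrt(400 / pi))
  expect_equal(unname(m["perimeter"]), 40)
  expect_equal(unname(m["eccentricity"]), 0)  # 4-fold symmetry
})

test_that("eccentricity separates disks from stretched shapes", {
  disk <- disk_mask(40, 19.5, 19.5, 12)
  stretched <- matrix(FALSE, 40, 40); stretched[15:24, 3:38] <- TRUE
  e_disk <- morphology_features(disk)["eccentricity"]
  e_str <- morphology_features(stretched)["eccentricity"]
  expect_lt(e_disk, 0.05)
  expect_gt(e_str, e_disk)
})

test_that("a donut has Euler number 0 and filled area above area", {
  donut <- disk_mask(40, 19.5, 19.5, 12) & !disk_mask(40, 19.5, 19.5, 5)
  m <- morphology_features(donut)
  expect_equal(unname(m["euler_number"]), 0)
  expect_gt(m["filled_area"], m["area"])
})

test_that("Hu moments are invariant to translation and 90-degree rotation", {
  base <- matrix(FALSE, 50, 50)
  base[10:20, 8:30] <- TRUE; base[18:26, 8:14] <- TRUE
  img <- matrix(runif(2500, 10, 100), 50, 50)
  h0 <- morphology_features(base, img)[paste0("hu", 1:7)]
  shifted <- matrix(FALSE, 50, 50)
  shifted[15:25, 13:35] <- TRUE; shifted[23:31, 13:19] <- TRUE
  h1 <- morphology_features(shifted, img)[paste0("hu", 1:7)]
  rot <- t(base)[ncol(base):1, ]          # 90-degree rotation
  h2 <- morphology_features(rot, img)[paste0("hu", 1:7)]
  expect_equal(h1, h0, tolerance = 1e-10)
  expect_equal(h2, h0, tolerance = 1e-6)
})

test_that("morphology ignores intensity scaling and empty masks are missing", {
  msk <- square_mask()
  img <- matrix(runif(400, 1, 10), 20, 20)
  m1 <- morphology_features(msk, img)
  m2 <- morphology_features(msk, img * 1000)
  expect_equal(m1, m2, tolerance = 1e-12)   # weighted Hu are scale-normalized
  expect_true(all(is.na(morphology_features(matrix(FALSE, 5, 5)))))
})

# Intensity -------------------------------------------------------------------

test_that("constant masked intensities give degenerate statistics", {
  iv <- intensity_features(matrix(7, 6, 6), matrix(TRUE, 6, 6))
  expect_equal(unname(iv[c("min", "max", "mean")]), c(7, 7, 7))
  expect_equal(unname(iv["sd"]), 0)
  expect_equal(unname(iv["entropy"]), 0)
})

test_that("percentiles use linear interpolation between closest ranks", {
  img <- matrix(1:100, 10, 10)
  iv <- intensity_features(img, matrix(TRUE, 10, 10))
  expect_equal(unname(iv["p10"]), 10.9)
  expect_equal(unname(iv["p50"]), 50.5)
})

test_that("intensity features see only masked pixels", {
  set.seed(1)
  img <- matrix(runif(400, 0, 1000), 20, 20)
  msk <- square_mask()
  iv1 <- intensity_features(img, msk)
  img2 <- img
  img2[!msk] <- 9999
  expect_identical(intensity_features(img2, msk), iv1)
  expect_true(all(is.na(intensity_features(img, matrix(FALSE, 20, 20)))))
})

# Texture ---------------------------------------------------------------------

test_that("constant images give the degenerate co-occurrence matrix", {
  tv <- texture_features(matrix(5, 10, 10), matrix(TRUE, 10, 10))
  expect_equal(unname(tv["glcm_contrast"]), 0)
  expect_equal(unname(tv["glcm_dissimilarity"]), 0)
  expect_equal(unname(tv["glcm_homogeneity"]), 1)
  expect_equal(unname(tv["glcm_ASM"]), 1)
  expect_equal(unname(tv["glcm_energy"]), 1)
  expect_equal(unname(tv["glcm_correlation"]), 1)
})

test_that("checkerboard contrast matches a hand-built two-level GLCM", {
  n <- 8
  board <- outer(1:n, 1:n, function(i, j) (i + j) %% 2)
  img <- board * 100 + 10
  tv <- texture_features(img, matrix(TRUE, n, n), levels = 32)
  # hand-built angle-pooled GLCM: the two values quantize to levels 1 and
  # 32; all n*(n-1) horizontal and vertical pairs differ by 31 levels, all
  # (n-1)^2 pairs per diagonal are equal
  n_diff <- 2 * n * (n - 1)           # 0 and 90 degrees
  n_same <- 2 * (n - 1)^2             # 45 and 135 degrees
  expect_equal(unname(tv["glcm_contrast"]),
               31^2 * n_diff / (n_diff + n_same))
  expect_equal(unname(tv["glcm_dissimilarity"]),
               31 * n_diff / (n_diff + n_same))
})

test_that("energy is the square root of ASM on random masked images", {
  set.seed(2)
  for (i in 1:10) {
    img <- matrix(sample(0:500, 144, replace = TRUE), 12, 12)
    msk <- matrix(runif(144) < 0.7, 12, 12)
    if (sum(msk) < 8) next
    tv <- texture_features(img, msk)
    expect_equal(unname(tv["glcm_energy"]), sqrt(unname(tv["glcm_ASM"])))
  }
})

# Co-localization -------------------------------------------------------------

test_that("mask-overlap distances match set arithmetic", {
  A <- matrix(FALSE, 2, 2); A[1, 1] <- A[1, 2] <- TRUE
  B <- matrix(FALSE, 2, 2); B[1, 2] <- B[2, 2] <- TRUE
  cv <- colocalization_features(matrix(1, 2, 2), A, matrix(1, 2, 2), B)
  expect_equal(unname(cv["dice_dist"]), 0.5)
  expect_equal(unname(cv["jaccard_dist"]), 2 / 3)
  expect_equal(unname(cv["inter_area"]), 1)
  expect_equal(unname(cv["union_area"]), 3)
})

test_that("identical channels are perfectly co-localized", {
  set.seed(3)
  img <- matrix(sample(1:1000, 100), 10, 10)   # distinct values, none at mean
  msk <- disk_mask(10, 4.5, 4.5, 4)
  cv <- colocalization_features(img, msk, img, msk)
  expect_equal(unname(cv["dice_dist"]), 0)
  expect_equal(unname(cv["hausdorff"]), 0)
  expect_equal(unname(cv["pearson"]), 1)
  expect_equal(unname(cv["eucl_dist"]), 0)
  expect_equal(unname(cv["ssim"]), 1)
  expect_equal(unname(cv["icq"]), 0.5, tolerance = 0.02)
  expect_equal(unname(cv["manders_m1"]), 1)
})

test_that("Hausdorff distance between single pixels is Euclidean", {
  ma <- matrix(FALSE, 6, 6); ma[1, 1] <- TRUE    # (0,0)
  mb <- matrix(FALSE, 6, 6); mb[4, 5] <- TRUE    # (3,4)
  cv <- colocalization_features(matrix(1, 6, 6), ma, matrix(1, 6, 6), mb)
  expect_equal(unname(cv["hausdorff"]), 5)
})

test_that("co-localization values respect their documented ranges", {
  set.seed(4)
  for (i in 1:25) {
    img_a <- matrix(sample(0:300, 64, TRUE), 8, 8)
    img_b <- matrix(sample(0:300, 64, TRUE), 8, 8)
    ma <- matrix(runif(64) < 0.5, 8, 8)
    mb <- matrix(runif(64) < 0.5, 8, 8)
    if (!any(ma) && !any(mb)) next
    cv <- colocalization_features(img_a, ma, img_b, mb)
    expect_true(is.na(cv["dice_dist"]) ||
                  (cv["dice_dist"] >= 0 && cv["dice_dist"] <= 1))
    expect_true(cv["jaccard_dist"] >= 0 && cv["jaccard_dist"] <= 1)
    for (d in c("eucl_dist", "corr_dist", "cosine_dist", "hausdorff",
                "mutual_info"))
      expect_true(is.na(cv[d]) || cv[d] >= 0)
    expect_true(is.na(cv["icq"]) || abs(cv["icq"]) <= 0.5)
    for (mm in c("manders_m1", "manders_m2", "overlap_coef"))
      expect_true(is.na(cv[mm]) || (cv[mm] >= 0 && cv[mm] <= 1 + 1e-12))
  }
  both_empty <- colocalization_features(matrix(1, 3, 3), matrix(FALSE, 3, 3),
                                        matrix(1, 3, 3), matrix(FALSE, 3, 3))
  expect_true(all(is.na(both_empty)))
})

# Synapse mask and enrichment --------------------------------------------------

test_that("synapse mask is the intersection of dilated cell masks", {
  # disjoint masks separated by more than twice the dilation radius
  rec <- tiny_record()
  rec$masks[, , ] <- FALSE
  rec$masks[2:5, 2:5, 4] <- TRUE        # CD3
  rec$masks[20:28, 20:28, 3] <- TRUE    # MHCII
  expect_equal(sum(derive_synapse_mask(rec)), 0)

  rec$masks[, , 3] <- rec$masks[, , 4]  # identical masks
  syn <- derive_synapse_mask(rec)
  expect_true(all(syn[rec$masks[, , 4]]))

  rec$masks[, , 4] <- FALSE
  expect_error(derive_synapse_mask(rec, t_channel = "nope"), "nope")
})

test_that("two-disk contact zone area matches brute-force rasterization", {
  size <- 40
  mt <- disk_mask(size, 20, 12, 5)
  mb <- disk_mask(size, 20, 24, 5)
  img <- array(0, c(size, size, 5)); img[, , 4] <- mt; img[, , 3] <- mb
  rec <- cell_record("x", c("BF", "Factin", "MHCII", "CD3", "PCD3z"),
                     img, array(c(mt | mb, mt | mb, mb, mt, mt),
                                c(size, size, 5)),
                     list(donor_id = "d", experiment_id = "e",
                          condition = "c"))
  syn <- derive_synapse_mask(rec, dilation = 3)
  # oracle: dilation = union of brush translates, computed pixel by pixel
  brush <- as.matrix(EBImage::makeBrush(7, "disc")) > 0
  brute_dilate <- function(m) {
    out <- matrix(FALSE, size, size)
    for (r in 1:size) for (c in 1:size) {
      if (!m[r, c]) next
      for (dr in -3:3) for (dc in -3:3) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= size && cc >= 1 && cc <= size &&
            brush[dr + 4, dc + 4]) out[rr, cc] <- TRUE
      }
    }
    out
  }
  oracle <- brute_dilate(mt) & brute_dilate(mb)
  expect_gt(sum(oracle), 0)
  expect_identical(unclass(syn)[, ], oracle)
})

test_that("enrichment ratios follow their definitions", {
  cell <- disk_mask(20, 9.5, 9.5, 6)
  syn <- disk_mask(20, 9.5, 9.5, 2)
  img <- matrix(0, 20, 20); img[cell] <- 5
  sv <- synaptic_features(img, cell, syn)
  expect_equal(unname(sv["enrich_mean"]), 1)    # uniform intensity

  img2 <- matrix(0, 20, 20); img2[syn] <- 7     # all signal inside synapse
  sv2 <- synaptic_features(img2, cell, syn)
  expect_equal(unname(sv2["enrich_sum"]), 1)

  # cell pixels {4, 6, 0, 0, 0} have mean 2; synapse pixels are {4, 6}
  cellm <- matrix(FALSE, 5, 5); cellm[1, 1:5] <- TRUE
  img3 <- matrix(0, 5, 5); img3[1, 1:5] <- c(4, 6, 0, 0, 0)
  synm <- matrix(FALSE, 5, 5); synm[1, 1:2] <- TRUE
  sv3 <- synaptic_features(img3, cellm, synm)
  expect_equal(unname(sv3["enrich_mean"]), 2.5)
  expect_equal(unname(sv3["enrich_max"]), 3)

  empty_syn <- matrix(FALSE, 5, 5)
  expect_equal(unname(synaptic_features(img3, cellm, empty_syn)),
               c(0, 0, 0))
  zero_img <- matrix(0, 5, 5)
  expect_true(all(is.na(synaptic_features(zero_img, cellm, synm))))
})

test_that("enrichment of a uniform channel is 1 for any non-empty synapse", {
  set.seed(5)
  cell <- disk_mask(30, 14.5, 14.5, 10)
  img <- matrix(0, 30, 30); img[cell] <- 42
  for (i in 1:10) {
    syn <- cell & (matrix(runif(900), 30, 30) < 0.4)
    if (!any(syn)) next
    expect_equal(unname(synaptic_features(img, cell, syn)["enrich_mean"]), 1)
  }
})

# QC ---------------------------------------------------------------------------

test_that("gradient RMS detects defocus and background mean needs background", {
  rec <- tiny_record()
  rec$image[, , 1] <- 100                       # constant channel
  expect_equal(unname(qc_features(rec)["BF_grms"]), 0)

  sharp <- render_record(scene_spec("single B-LCL", noise_sd = 0), 1)
  blurred <- render_record(scene_spec("single B-LCL", noise_sd = 0,
                                      blur_sd = 2), 1)
  expect_gt(qc_features(sharp)["MHCII_grms"], qc_features(blurred)["MHCII_grms"])

  rec$masks[, , ] <- TRUE                       # mask covers the full frame
  expect_true(is.na(qc_features(rec)["BF_bgmean"]))
})
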