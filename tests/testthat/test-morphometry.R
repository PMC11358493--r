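# Morphometry: nuclei segmentation, rigid registration, contour erosion,
# DRVH, regional S-value dosimetry.

disk_image <- function(n, centers, radius = 3, intensity = 1) {
  img <- matrix(0, n, n)
  for (i in seq_len(nrow(centers))) {
    d2 <- (row(img) - centers$x[i])^2 + (col(img) - centers$y[i])^2
    img[d2 <= radius^2] <- intensity
  }
  img
}

test_that("well-separated nuclei are counted exactly", {
  centers <- expand.grid(x = seq(10, 70, by = 15), y = seq(10, 70, by = 15))
  img <- disk_image(80, centers)
  s <- segment_nuclei(img, min_area = 5, max_area = 100)
  expect_equal(nrow(s$centroids), nrow(centers))
  expect_equal(sum(s$density), nrow(centers))
  # counting is invariant under intensity rescaling (relative threshold)
  s2 <- segment_nuclei(img * 387.5, min_area = 5, max_area = 100)
  expect_equal(nrow(s2$centroids), nrow(centers))
  # area filter rejects out-of-range blobs
  s3 <- segment_nuclei(img, min_area = 50, max_area = 100)
  expect_equal(nrow(s3$centroids), 0)
})

test_that("touching nuclei are split by the watershed", {
  img <- disk_image(40, data.frame(x = c(18, 25), y = c(20, 20)), radius = 4.5)
  s <- segment_nuclei(img, min_area = 5, max_area = 200)
  expect_equal(nrow(s$centroids), 2)
})

test_that("blank images yield zero counts without error", {
  s <- segment_nuclei(matrix(0, 30, 30), min_area = 2, max_area = 50)
  expect_equal(nrow(s$centroids), 0)
  expect_true(all(s$density == 0))
})

test_that("centroids bin onto the coarser DAR grid", {
  img <- disk_image(78, data.frame(x = c(5, 50, 70), y = c(5, 50, 8)))
  s <- segment_nuclei(img, min_area = 5, max_area = 100, bin_factor = 39)
  expect_equal(dim(s$density), c(2, 2))
  expect_equal(sum(s$density), 3)
  expect_equal(s$density[1, 1], 1)
  expect_equal(s$density[2, 2], 1)
  expect_equal(s$density[2, 1], 1)
})

test_that("rigid registration recovers identity and known transforms", {
  blob <- matrix(0, 64, 64)
  d2 <- (row(blob) - 30)^2 / 120 + (col(blob) - 36)^2 / 60
  blob <- exp(-d2) + 0.3 * exp(-((row(blob) - 45)^2 + (col(blob) - 20)^2) / 40)
  id <- rigid_register(blob, blob)
  expect_lt(abs(id$tx), 0.1)
  expect_lt(abs(id$ty), 0.1)
  expect_lt(abs(id$theta_deg), 0.1)
  fixed <- apply_rigid(blob, 3.2, -1.7, 4)
  reg <- rigid_register(blob, fixed)
  expect_lt(abs(reg$tx - 3.2), 0.2)
  expect_lt(abs(reg$ty + 1.7), 0.2)
  expect_lt(abs(reg$theta_deg - 4), 0.2)
  # the sum-preservation contract is enforced after resampling
  expect_lt(abs(sum(reg$resampled) - sum(blob)) / sum(blob), 1e-6)
})

test_that("positive-contour erosion matches set arithmetic", {
  expect_equal(erode_positive_contour(matrix(0, 10, 10)), matrix(0, 10, 10))
  rect <- matrix(0, 20, 24)
  rect[5:16, 4:19] <- 2.5
  er <- erode_positive_contour(rect, erosion_px = 5)
  expect_equal(sum(er > 0), (12 - 4) * (16 - 4))
  # interior values unchanged
  expect_equal(er[8, 8], 2.5)
  # a single isolated positive pixel is removed
  single <- matrix(0, 9, 9); single[5, 5] <- 1
  expect_true(all(erode_positive_contour(single) == 0))
})

test_that("DRVH histograms partition regions and reconstruct means", {
  set.seed(23)
  labels <- array(0L, c(10, 10, 4))
  labels[2:9, 2:5, ] <- 1L
  labels[2:9, 6:9, ] <- 2L
  dose <- array(runif(400, 5, 25), c(10, 10, 4))
  mask <- region_mask(labels, c("1" = "cortex", "2" = "medulla"))
  h <- drvh(dose, mask, bins = 12)
  stats <- drvh_stats(h)
  # counts partition each region exactly
  counts <- tapply(h$n_voxels, h$region, sum)
  expect_equal(as.numeric(counts[stats$region]), stats$n_voxels)
  expect_equal(stats$n_voxels, c(sum(labels == 1), sum(labels == 2)))
  # cumulative curves are non-increasing and start at 1
  for (rg in unique(h$region)) {
    cc <- h$cum_frac_ge_lo[h$region == rg]
    expect_true(all(diff(cc) <= 1e-12))
    expect_equal(cc[1], 1)
  }
  # region means reconstruct the masked volume mean exactly
  vol_mean <- sum(stats$mean * stats$n_voxels) / sum(stats$n_voxels)
  expect_equal(vol_mean, mean(dose[labels > 0]))
  # uniform dose in a region lands in a single bin
  dose_u <- dose; dose_u[labels == 1L] <- 10
  hu <- drvh(dose_u, mask, bins = 8)
  expect_equal(sum(hu$n_voxels[hu$region == "cortex"] > 0), 1)
})

test_that("kidney-phantom compartment ratios survive the DRVH pipeline", {
  ph <- kidney_phantom(phantom_spec(shape = c(32, 32, 16), seed = 4))
  # noiseless imaging: dose-rate proportional to activity
  h <- drvh(ph$activity$activity * 1e6, ph$mask, bins = 25)
  stats <- drvh_stats(h)
  expect_equal(stats$region, c("cortex", "ISOM/OSOM", "IM/Pa", "V/Pe"))
  expect_equal(stats$ratio_to_first, c(1, 0.50, 0.88, 1.19), tolerance = 0.02)
})

test_that("empty regions are excluded with a warning", {
  labels <- matrix(0L, 6, 6); labels[2:4, 2:4] <- 1L
  mask <- region_mask(labels, c("1" = "a", "2" = "b"))
  expect_warning(h <- drvh(matrix(1, 6, 6), mask, bins = 4), "empty region")
  expect_equal(unique(h$region), "a")
})

test_that("regional S-value dosimetry is linear and composes", {
  s <- matrix(c(4e-12, 1e-13, 2e-13, 5e-12), 2, 2,
              dimnames = list(c("cortex", "medulla"), c("cortex", "medulla")))
  fr <- c(cortex = 0.7, medulla = 0.3)
  d <- regional_s_dose(1000, fr, s)
  want_cortex <- 1000 * (0.7 * 4e-12 + 0.3 * 1e-13) * 1000 * 3600
  expect_equal(d$dose_rate_mGy_h[d$region == "cortex"], want_cortex)
  # single region
  d1 <- regional_s_dose(50, c(whole = 1), matrix(3e-12, 1, 1,
                                                 dimnames = list("whole", "whole")))
  expect_equal(d1$dose_rate_mGy_h, 50 * 3e-12 * 3.6e6)
  # linearity in total activity
  d2 <- regional_s_dose(2000, fr, s)
  expect_equal(d2$dose_rate_mGy_h, 2 * d$dose_rate_mGy_h)
  expect_error(regional_s_dose(10, c(a = 0.6, b = 0.3), s),
               class = "alphadose3d_contract_error")
})

test_that("combined S-value regions are mass-unweighted means", {
  regions <- c("ISOM", "OSOM", "IM", "Pa")
  s <- matrix(seq(1, 16) * 1e-12, 4, 4, dimnames = list(regions, regions))
  comb <- combine_s_regions(s, c("ISOM", "OSOM"), "ISOM/OSOM")
  expect_equal(comb["ISOM/OSOM", "IM"], mean(s[c("ISOM", "OSOM"), "IM"]))
  expect_equal(comb["IM", "ISOM/OSOM"], mean(s["IM", c("ISOM", "OSOM")]))
  expect_equal(dim(comb), c(3, 3))
})
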