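# DAR dosimetry: calibration, cloning vs sequential reconstruction,
# convolution, 3D assembly, sampling, gamma index.

chain <- test_chain()

test_that("count calibration implements the absolute-efficiency chain", {
  cal <- calibration_factors()
  expect_equal(round(cal$absolute_efficiency, 2), 0.38)
  # zero counts -> zero activity
  img <- count_image(matrix(0, 4, 4), 39, live_time = 3600)
  expect_true(all(counts_to_activity_image(img, cal, chain)$activity == 0))
  # a known count rate inverts through the factor chain
  img1 <- count_image(matrix(3600, 1, 1), 39, live_time = 3600)
  act <- counts_to_activity_image(img1, cal, chain)$activity[1, 1]
  expect_equal(act, 1 * cal$frame_factor / (4 * 0.5 * (1 - 0.238)))
  # acquisition one parent half-life after sacrifice doubles the estimate
  img2 <- count_image(matrix(3600, 1, 1), 39, live_time = 3600,
                      start_offset = "9.9 d")
  expect_equal(counts_to_activity_image(img2, cal, chain)$activity[1, 1],
               2 * act)
})

test_that("simulated counts invert through calibration without bias", {
  cal <- calibration_factors()
  truth <- activity_image(matrix(0.02, 8, 8), 39)
  recov <- vapply(1:100, function(i) {
    ci <- simulate_counts(truth, cal, live_time = 4 * 3600, chain, seed = i)
    mean(counts_to_activity_image(ci, cal, chain)$activity)
  }, numeric(1))
  mu_counts <- 0.02 * 4 * 0.5 * (1 - 0.238) * 4 * 3600 / cal$frame_factor
  sigma_rel <- 1 / sqrt(mu_counts * 64 * 100)
  expect_lt(abs(mean(recov) / 0.02 - 1), 2 * sigma_rel)
})

test_that("cloning builds exact replicated volumes", {
  slice <- activity_image(matrix(runif(64), 8), 39)
  v1 <- clone_volume(slice, 1)
  expect_equal(v1$activity[, , 1], slice$activity)
  v21 <- clone_volume(slice, 21)
  expect_identical(sum(v21$activity), 21 * sum(slice$activity))
  for (z in seq_len(21)) expect_identical(v21$activity[, , z], slice$activity)
  expect_error(clone_volume(slice, 4), class = "alphadose3d_contract_error")
})

test_that("convolution satisfies the delta and equilibrium identities", {
  kv <- test_kernel_iso()
  kd <- dim(kv$voxel_kernel)
  # delta source: dose rate = A * 3600 * kernel
  n <- kd + 10
  act <- array(0, n)
  cpos <- (n + 1) %/% 2
  act[cpos[1], cpos[2], cpos[3]] <- 2.5
  dr <- convolve_dose_rate(activity_volume(act, c(39, 39, 39)), kv)
  sub <- dr$dose_rate[cpos[1] + (-(kd[1] - 1) / 2):((kd[1] - 1) / 2),
                      cpos[2] + (-(kd[2] - 1) / 2):((kd[2] - 1) / 2),
                      cpos[3] + (-(kd[3] - 1) / 2):((kd[3] - 1) / 2)]
  expect_equal(sub, 2.5 * 3600 * kv$voxel_kernel, tolerance = 1e-10)
  # uniform volume: interior dose rate = A * 3600 * sum(kernel)
  act_u <- array(0.01, c(15, 15, 15))
  dr_u <- convolve_dose_rate(activity_volume(act_u, c(39, 39, 39)), kv)
  expect_equal(dr_u$dose_rate[8, 8, 8], 0.01 * 3600 * sum(kv$voxel_kernel),
               tolerance = 1e-10)
  # voxel-dimension contract
  expect_error(
    convolve_dose_rate(activity_volume(act_u, c(39, 39, 10)), kv),
    class = "alphadose3d_contract_error"
  )
})

test_that("FFT convolution matches a direct double-sum oracle", {
  set.seed(5)
  x <- array(runif(21^3), c(21, 21, 21))
  k <- array(runif(5 * 5 * 5), c(5, 5, 5))
  kern <- structure(
    list(voxel_kernel = k, voxel_dims = c(39, 39, 39),
         radial = NULL, support_radius_um = 100, total_energy_MeV = 1,
         per_decay = TRUE),
    class = "dose_point_kernel"
  )
  got <- convolve_dose_rate(activity_volume(x, c(39, 39, 39)), kern)$dose_rate
  want <- conv3d_direct(x, k) * 3600
  expect_lt(max(abs(got - want)) / max(want), 1e-8)
})

test_that("convolution is linear and translation-equivariant", {
  kv <- test_kernel_iso()
  set.seed(6)
  a1 <- array(runif(14^3), c(14, 14, 14))
  a2 <- array(runif(14^3), c(14, 14, 14))
  d <- function(a) convolve_dose_rate(activity_volume(a, c(39, 39, 39)), kv)$dose_rate
  expect_equal(d(a1 + a2), d(a1) + d(a2), tolerance = 1e-10)
  # translation equivariance away from boundaries
  sh <- array(0, c(14, 14, 14))
  sh[2:14, , ] <- a1[1:13, , ]
  d1 <- d(a1); dsh <- d(sh)
  kd <- (dim(kv$voxel_kernel) - 1) / 2
  interior_x <- (kd[1] + 2):(14 - kd[1])
  interior_yz <- (kd[2] + 1):(14 - kd[2])
  expect_equal(dsh[interior_x, interior_yz, interior_yz],
               d1[interior_x - 1, interior_yz, interior_yz], tolerance = 1e-10)
})

test_that("sequential and cloning methods agree on z-uniform stacks", {
  kv <- test_kernel()
  set.seed(8)
  m <- matrix(runif(20 * 20, 0.001, 0.01), 20)
  slices <- lapply(1:10, function(i) activity_image(m, 39, 10))
  seq_img <- sequential_dose_rate(slices, kv)
  clone_img <- cloning_dose_rate(slices[[5]], kv, n_clones = 21)
  # 10 slices do not span the 19-plane kernel: compare via an 21-slice stack
  slices21 <- lapply(1:21, function(i) activity_image(m, 39, 10))
  seq21 <- sequential_dose_rate(slices21, kv)
  expect_equal(clone_img$dose_rate, seq21$dose_rate, tolerance = 1e-10)
  # a 10-slice stack truncates the 19-plane kernel support: small bias only
  expect_lt(method_error(clone_img, seq_img), 15)
  expect_error(sequential_dose_rate(slices[1], kv),
               class = "alphadose3d_contract_error")
})

test_that("sequential reconstruction matches the direct oracle on a gradient", {
  kv <- test_kernel()
  base <- matrix(0.005, 12, 12)
  slices <- lapply(1:9, function(i) activity_image(base * i, 39, 10))
  seq_img <- sequential_dose_rate(slices, kv)
  vol <- array(unlist(lapply(slices, function(s) s$activity)), c(12, 12, 9))
  want <- conv3d_direct(vol, kv$voxel_kernel)[, , 5] * 3600
  expect_equal(seq_img$dose_rate, want, tolerance = 1e-8)
})

test_that("mean-dose-rate method error behaves as a relative difference", {
  img <- structure(list(dose_rate = matrix(2, 4, 4), pixel_size_um = 39),
                   class = "dose_rate_image")
  expect_equal(method_error(img, img), 0)
  img2 <- img; img2$dose_rate <- img$dose_rate * 1.05
  expect_equal(method_error(img2, img), 5, tolerance = 1e-10)
  z <- img; z$dose_rate <- matrix(0, 4, 4)
  expect_error(method_error(img, z), class = "alphadose3d_domain_error")
})

test_that("3D assembly uses the slice-pitch voxel convention", {
  slices <- lapply(1:23, function(i) {
    structure(list(dose_rate = matrix(i, 6, 6), pixel_size_um = 39,
                   provenance = "cloning"),
              class = "dose_rate_image")
  })
  vol <- assemble_3d(slices, z_pitch_um = 200, slice_thickness_um = 10)
  expect_equal(vol$voxel_dims_um, c(39, 39, 210))
  expect_equal(dim(vol$dose_rate), c(6, 6, 23))
  expect_equal(mean(vol$dose_rate), mean(1:23))
  for (z in c(1, 12, 23)) {
    expect_identical(extract_plane(vol, z)$dose_rate, slices[[z]]$dose_rate)
  }
  expect_error(assemble_3d(slices[1]), class = "alphadose3d_contract_error")
})

test_that("sampling plans count positions and slices", {
  expect_equal(sampling_plan(5000, 200, 1)$total_slices, 25)
  expect_equal(sampling_plan(5000, 200, 10)$total_slices, 250)
  expect_equal(sampling_plan(5000, 10, 1)$total_slices, 500)
  expect_warning(p <- sampling_plan(100, 200, 1))
  expect_equal(p$positions, 0)
})

test_that("gamma index satisfies its closed-form cases", {
  ref <- structure(list(dose_rate = matrix(4, 16, 16), pixel_size_um = 39),
                   class = "dose_rate_image")
  g0 <- gamma_index(ref, ref)
  expect_true(all(g0$gamma_map == 0))
  expect_equal(g0$pass_rate, 1)
  # uniform field scaled by 1.05 at 10% local tolerance: gamma = 0.5
  ev <- ref; ev$dose_rate <- ref$dose_rate * 1.05
  g <- gamma_index(ref, ev, dose_tol = 0.10, dist_tol = 117)
  expect_equal(max(abs(g$gamma_map - 0.5)), 0, tolerance = 1e-12)
  # scale invariance under joint scaling with local normalization
  r2 <- smooth_image(16, seed = 31)
  e2 <- r2 * (1 + 0.08 * sin(row(r2) / 2))
  ga <- gamma_index(r2, e2, pixel_size_um = 39)
  gb <- gamma_index(10 * r2, 10 * e2, pixel_size_um = 39)
  expect_equal(ga$gamma_map, gb$gamma_map, tolerance = 1e-12)
})

test_that("gamma index matches an exhaustive all-voxel search oracle", {
  ref <- smooth_image(32, seed = 71)
  ev <- smooth_image(32, seed = 72)
  got <- gamma_index(ref, ev, dose_tol = 0.10, dist_tol = 117,
                     search_radius_factor = Inf, pixel_size_um = 39)
  want <- gamma_direct(ref, ev, 0.10, 117, 39)
  expect_equal(got$gamma_map, want, tolerance = 1e-10)
  # global normalization route
  gotg <- gamma_index(ref, ev, dose_tol = 0.10, dist_tol = 117,
                      normalization = "global",
                      search_radius_factor = Inf, pixel_size_um = 39)
  wantg <- gamma_direct(ref, ev, 0.10, 117, 39, normalization = "global")
  expect_equal(gotg$gamma_map, wantg, tolerance = 1e-10)
  # low-dose floor excludes voxels from the pass rate
  gf <- gamma_index(ref, ev, floor = 0.95, pixel_size_um = 39)
  expect_lt(gf$n_evaluated, length(ref))
  expect_error(gamma_index(ref, ev, floor = 2, pixel_size_um = 39),
               class = "alphadose3d_empty_evaluation_error")
})
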