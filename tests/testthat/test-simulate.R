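unpose <- function(mesh, pose) apply_transform(mesh, rt_invert(pose),
                                               frame = "phantom")

sim_rms_vs <- function(mesh, pose, truth_idx, n = 3000, seed = 1) {
  s <- sample_surface(unpose(mesh, pose), n = n, seed = seed)
  sqrt(mean(point_to_surface_distance(s$points, truth_idx)$distance^2))
}

test_that("simulators are bit-deterministic in their seed", {
  ph <- test_phantom()
  p <- test_modality_params()
  a <- simulate_sls(ph, p, pose_seed = 9L)
  b <- simulate_sls(ph, p, pose_seed = 9L)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$true_pose, b$true_pose)
  u1 <- simulate_us(ph, p, pose_seed = 9L)
  u2 <- simulate_us(ph, p, pose_seed = 9L)
  expect_identical(u1$medial_mesh$vertices, u2$medial_mesh$vertices)
  c1 <- simulate_ct(ph, p, pose_seed = 9L)
  c2 <- simulate_ct(ph, p, pose_seed = 9L)
  expect_identical(c1$mesh$vertices, c2$mesh$vertices)
  # different seed moves the pose
  c3 <- simulate_ct(ph, p, pose_seed = 10L)
  expect_false(identical(c1$true_pose, c3$true_pose))
})

test_that("the recorded pose is the pose that was applied", {
  ph <- test_phantom()
  p <- modality_params(sls = list(resolution_mm = 0.5, point_noise_sd_mm = 0))
  sim <- simulate_sls(ph, p, pose_seed = 4L)
  # undoing the recorded pose lands back on the outer surface
  d <- sim_rms_vs(sim$mesh, sim$true_pose, mesh_index(ph$outer_surface))
  expect_lt(d, 0.05)
})

test_that("SLS error sits at the configured point accuracy", {
  ph <- test_phantom()
  p <- test_modality_params()
  truth <- mesh_index(ph$outer_surface)
  rms <- vapply(1:6, function(s) {
    sim <- simulate_sls(ph, p, pose_seed = 300 + s)
    sim_rms_vs(sim$mesh, sim$true_pose, truth, seed = s)
  }, numeric(1))
  expect_gt(mean(rms), 0.03)
  expect_lt(mean(rms), 0.08)
})

test_that("CT sees bone at quantisation accuracy but not cartilage", {
  ph <- test_phantom()
  p <- test_modality_params()
  sim <- simulate_ct(ph, p, pose_seed = 21L)
  # error against the bone surface matches the half-voxel quantisation scale
  rms <- sim_rms_vs(sim$mesh, sim$true_pose, mesh_index(ph$bone_surface))
  q <- mean(c(p$ct$pixel_mm, p$ct$pixel_mm, p$ct$slice_mm)) / (2 * sqrt(3))
  expect_gt(rms, 0.5 * q)
  expect_lt(rms, 1.5 * q)
  # the cartilage-covered articular surface is missing from CT: distances
  # from the outer articular zone to CT match the cartilage thickness
  ct_idx <- mesh_index(unpose(sim$mesh, sim$true_pose))
  sel <- ph$cartilage_mask >= 1 & ph$bump_max < 0.01
  d <- point_to_surface_distance(ph$outer_surface$vertices[sel, ], ct_idx)$distance
  expect_gt(mean(d), 2.0 - 0.45)
  expect_lt(mean(d), 2.6 + 0.45)
})

test_that("osteophyte visibility in CT follows the ossified fraction", {
  p <- test_modality_params()
  base_os <- tibble::tibble(id = "o1", side = "medial", phi_deg = 0,
                            grade = 2L, ossified_fraction = 1)
  # fully ossified: depicted within twice the voxel diagonal
  ph1 <- make_phantom(phantom_spec(mesh_edge_mm = 0.8, osteophytes = base_os,
                                   margin_angle_deg = 72))
  sim1 <- simulate_ct(ph1, p, pose_seed = 5L)
  r1 <- region_rms(ph1$regions[[1]], ph1$outer_surface,
                   unpose(sim1$mesh, sim1$true_pose), seed = 1)
  vox_diag <- sqrt(2 * p$ct$pixel_mm^2 + p$ct$slice_mm^2)
  expect_lt(r1$rms_mm, 2 * vox_diag)

  # fully cartilaginous: absent from CT, RMS tracks the bump profile
  os0 <- base_os
  os0$ossified_fraction <- 0
  ph0 <- make_phantom(phantom_spec(mesh_edge_mm = 0.8, osteophytes = os0,
                                   margin_angle_deg = 72))
  sim0 <- simulate_ct(ph0, p, pose_seed = 5L)
  r0 <- region_rms(ph0$regions[[1]], ph0$outer_surface,
                   unpose(sim0$mesh, sim0$true_pose), seed = 1)
  h <- ph0$spec$osteophytes$height_mm[1]
  # analytic RMS of the Gaussian bump over its labelled footprint: ~0.54 h
  expect_gt(r0$rms_mm, 0.4 * h)
  expect_lt(r0$rms_mm, 0.7 * h)
  expect_gt(r0$rms_mm, 5 * r1$rms_mm)
})

test_that("US covers only the acoustic windows and at voxel accuracy", {
  ph <- test_phantom()
  p <- test_modality_params()
  sim <- simulate_us(ph, p, pose_seed = 31L)
  for (side in c("medial_mesh", "lateral_mesh")) {
    m <- unpose(sim[[side]], sim$true_pose)
    az <- atan2(mesh_face_centroids(m)[, 3], mesh_face_centroids(m)[, 1]) * 180 / pi
    w <- if (side == "medial_mesh") abs(az) else 180 - abs(az)
    # no face centroid inside the excluded anterior/posterior sectors
    expect_lt(max(w), p$us$coverage_half_angle_deg + 3)
  }
  # noise + quantisation error matches the configured scale
  rms <- sim_rms_vs(sim$medial_mesh, sim$true_pose, mesh_index(ph$outer_surface))
  scale <- sqrt((p$us$voxel_mm / (2 * sqrt(3)))^2 + p$us$surface_noise_sd_mm^2)
  expect_gt(rms, 0.5 * scale)
  expect_lt(rms, 1.5 * scale)
  # full coverage + zero noise reduces to quantisation alone
  p0 <- modality_params(sls = list(resolution_mm = 0.5),
                        us = list(surface_noise_sd_mm = 0,
                                  coverage_half_angle_deg = 90))
  sim0 <- simulate_us(ph, p0, pose_seed = 31L)
  rms0 <- sim_rms_vs(sim0$medial_mesh, sim0$true_pose,
                     mesh_index(ph$outer_surface))
  expect_lt(rms0, 1.5 * p0$us$voxel_mm / (2 * sqrt(3)) + 0.05)
  # degenerate / overlapping windows are refused up front
  expect_error(modality_params(us = list(coverage_half_angle_deg = 0)),
               "acoustic windows")
  expect_error(modality_params(us = list(coverage_half_angle_deg = 120)),
               "acoustic windows")
})

test_that("US depicts mostly-cartilaginous osteophytes better than CT", {
  os <- tibble::tibble(id = c("o1", "o2"), side = c("medial", "lateral"),
                       phi_deg = c(0, 180), grade = c(2L, 2L),
                       ossified_fraction = c(0.3, 0.5))
  ph <- make_phantom(phantom_spec(mesh_edge_mm = 0.8, osteophytes = os))
  p <- test_modality_params()
  wins <- vapply(1:3, function(s) {
    ct <- simulate_ct(ph, p, pose_seed = 400 + s)
    us <- simulate_us(ph, p, pose_seed = 500 + s)
    ct_idx <- mesh_index(unpose(ct$mesh, ct$true_pose))
    us_idx <- mesh_index(unpose(
      merge_meshes(us$medial_mesh, us$lateral_mesh), us$true_pose))
    ct_rms <- mean(vapply(ph$regions, function(r)
      region_rms(r, ph$outer_surface, ct_idx, seed = s)$rms_mm, numeric(1)))
    us_rms <- mean(vapply(ph$regions, function(r)
      region_rms(r, ph$outer_surface, us_idx, seed = s)$rms_mm, numeric(1)))
    us_rms < ct_rms
  }, logical(1))
  expect_true(all(wins))
})
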