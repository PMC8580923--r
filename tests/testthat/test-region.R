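test_that("circumscription selects faces by centroid distance", {
  s <- sphere_mesh(radius = 10, level = 3)
  pole <- c(0, 10, 0)
  # radius larger than the mesh diameter selects everything
  all_r <- circumscribe_region(s, pole, 100)
  expect_equal(length(all_r$face_indices), nrow(s$faces))
  # enumeration oracle at half the sphere radius
  rg <- circumscribe_region(s, pole, 5)
  cen <- mesh_face_centroids(s)
  expected <- which(sqrt(rowSums(sweep(cen, 2, pole)^2)) <= 5)
  expect_equal(rg$face_indices, expected)
  # off-surface seeds are refused
  expect_error(circumscribe_region(s, c(0, 25, 0), 5), "from the surface")
  expect_error(region_label("o1", integer(0)), "non-empty")
  expect_error(region_label("o1", 1L, grade = 5L), "grade")
})

test_that("region RMS matches analytic plane cases", {
  ref <- plane_mesh(n = 25, frame = "a")
  rg <- region_label("o1", seq_len(nrow(ref$faces)), reference = ref)
  # identical surfaces -> 0
  expect_equal(region_rms(rg, ref, ref, seed = 1)$rms_mm, 0, tolerance = 1e-12)
  # constant offset 0.7 -> exactly 0.7
  off <- apply_transform(ref, rigid_transform(translation = c(0, 0, 0.7)))
  expect_equal(region_rms(rg, ref, off, seed = 1)$rms_mm, 0.7, tolerance = 1e-6)
  # tilted plane z = x against the flat unit patch
  tilt <- plane_mesh(n = 25, frame = "a", z = function(x, y) x)
  # extend the tilted plane so perpendicular feet stay interior:
  vt <- tilt$vertices
  vt[, 1] <- vt[, 1] * 3 - 1
  vt[, 3] <- vt[, 1]
  tilt3 <- triangle_mesh(vt, tilt$faces, frame = "a")
  got <- region_rms(rg, ref, tilt3, samples_per_mm2 = 20000, seed = 2)$rms_mm
  # vertical gap x has perpendicular distance x / sqrt(2); RMS = sqrt(1/6)
  expect_equal(got, sqrt(1 / 6), tolerance = 0.01)

  # frame mismatch is refused
  expect_error(region_rms(rg, ref, plane_mesh(n = 5, frame = "b"), seed = 1),
               "Frame mismatch")
})

test_that("region RMS is rigid-invariant, dominates the mean, and is stable in density", {
  ph <- test_phantom()
  ct_like <- ph$bone_surface
  rg <- ph$regions[[1]]
  r1 <- region_rms(rg, ph$outer_surface, ct_like, seed = 3)
  t <- rt_axis_angle(c(1, 1, 1), 25, c(5, 6, -7))
  r2 <- region_rms(rg, apply_transform(ph$outer_surface, t),
                   apply_transform(ct_like, t), seed = 3)
  expect_equal(r1$rms_mm, r2$rms_mm, tolerance = 1e-6)
  # Jensen: rms >= mean >= 0
  expect_gte(r1$rms_mm, r1$mean_mm)
  expect_gte(r1$mean_mm, 0)
  # doubling density changes the estimate by < 1% on the analytic tilt case
  ref <- plane_mesh(n = 25, frame = "a")
  rgp <- region_label("p", seq_len(nrow(ref$faces)), reference = ref)
  vt <- plane_mesh(n = 25, frame = "a", z = function(x, y) x)$vertices
  vt[, 1] <- vt[, 1] * 3 - 1
  vt[, 3] <- vt[, 1]
  tilt3 <- triangle_mesh(vt, plane_mesh(n = 25)$faces, frame = "a")
  a <- region_rms(rgp, ref, tilt3, samples_per_mm2 = 20000, seed = 5)$rms_mm
  b <- region_rms(rgp, ref, tilt3, samples_per_mm2 = 40000, seed = 5)$rms_mm
  expect_lt(abs(a - b) / a, 0.01)
})

test_that("topographic maps bin distances as constructed", {
  ref <- plane_mesh(n = 10, frame = "a")
  # identical surfaces -> everything in the lowest bin
  m0 <- topographic_map(ref, ref)
  expect_true(all(as.integer(m0$bin) == 1L))
  # constant 2.3 mm offset with bins [0,1,2,3] -> all in (2,3]
  off <- apply_transform(ref, rigid_transform(translation = c(0, 0, 2.3)))
  m1 <- topographic_map(ref, off, bin_edges_mm = c(0, 1, 2, 3))
  expect_true(all(m1$bin == "(2,3]"))
  expect_error(topographic_map(ref, off, bin_edges_mm = c(0, 2, 1)),
               "strictly increasing")
  # tidier and plot
  td <- tidy(m1)
  expect_equal(nrow(td), nrow(ref$vertices))
  p <- autoplot(m1)
  expect_s3_class(p, "ggplot")
  # colour PLY export round-trips vertex count
  path <- withr::local_tempfile(fileext = ".ply")
  write_distance_map(m1, path)
  again <- load_mesh(path)
  expect_equal(nrow(again$vertices), nrow(ref$vertices))
})

test_that("region JSON files round trip both representations", {
  s <- sphere_mesh(radius = 10, level = 3)
  rg <- circumscribe_region(s, c(0, 10, 0), 4, region_id = "o2",
                            specimen = "sp1", side = "lateral", grade = 2L)
  p <- withr::local_tempfile(fileext = ".json")
  write_regions(list(rg), p)
  back <- read_regions(p, reference = s)[[1]]
  expect_equal(back$face_indices, rg$face_indices)
  expect_equal(back$grade, 2L)
  # seed-point form
  writeLines(jsonlite::toJSON(list(list(
    region_id = "o9", specimen = "sp1", side = "medial", grade = 1,
    seed_point = c(0, 10, 0), radius_mm = 4)), auto_unbox = TRUE), p)
  seeded <- read_regions(p, reference = s)[[1]]
  expect_equal(seeded$face_indices, rg$face_indices)
})
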