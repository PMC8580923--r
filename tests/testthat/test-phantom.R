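test_that("a bare phantom carries an exact-thickness cartilage layer", {
  sp <- phantom_spec(mesh_edge_mm = 0.8,
                     osteophytes = tibble::tibble(
                       id = character(), side = character(),
                       phi_deg = numeric(), grade = integer(),
                       ossified_fraction = numeric()))
  ph <- make_phantom(sp)
  expect_length(ph$regions, 0)
  # articular outer surface sits cartilage_thickness above the bone
  sel <- ph$cartilage_mask >= 1
  expect_gt(sum(sel), 1000)
  pts <- ph$outer_surface$vertices[sel, ]
  d <- point_to_surface_distance(pts, ph$bone_surface)$distance
  expect_lt(max(abs(d - sp$cartilage_thickness_mm)), 0.05)
})

test_that("osteophyte regions grow strictly with grade", {
  os <- tibble::tibble(
    id = c("g1", "g2", "g3"), side = c("medial", "medial", "lateral"),
    phi_deg = c(-30, 30, 180), grade = 1:3,
    ossified_fraction = c(0.5, 0.5, 0.5))
  ph <- make_phantom(phantom_spec(mesh_edge_mm = 0.8, osteophytes = os))
  areas <- vapply(ph$regions, function(r)
    sum(mesh_face_areas(ph$outer_surface)[r$face_indices]), numeric(1))
  names(areas) <- vapply(ph$regions, `[[`, "", "region_id")
  expect_true(areas[["g1"]] < areas[["g2"]])
  expect_true(areas[["g2"]] < areas[["g3"]])
  # bump heights visible on the outer surface scale with grade too
  idx <- mesh_index(ph$bone_surface)
  heights <- vapply(ph$regions, function(r) {
    sub <- submesh(ph$outer_surface, r$face_indices)
    max(point_to_surface_distance(sub$vertices, idx)$distance)
  }, numeric(1))
  names(heights) <- names(areas)
  expect_true(all(diff(heights[c("g1", "g2", "g3")]) > 0))
})

test_that("phantom generation is deterministic and validates its spec", {
  a <- make_phantom(phantom_spec(mesh_edge_mm = 1.2))
  b <- make_phantom(phantom_spec(mesh_edge_mm = 1.2))
  expect_identical(a$bone_surface$vertices, b$bone_surface$vertices)
  expect_identical(a$outer_surface$vertices, b$outer_surface$vertices)
  expect_identical(a$outer_surface$labels, b$outer_surface$labels)

  # overlapping osteophytes are refused
  os <- tibble::tibble(id = c("a", "b"), side = "medial",
                       phi_deg = c(0, 4), grade = c(3L, 3L),
                       ossified_fraction = 0.5)
  expect_error(make_phantom(phantom_spec(osteophytes = os)), "overlap")
  # grade and fraction validation
  expect_error(phantom_spec(osteophytes = tibble::tibble(
    id = "x", side = "medial", phi_deg = 0, grade = 4L,
    ossified_fraction = 0.5)), "grade")
  expect_error(phantom_spec(osteophytes = tibble::tibble(
    id = "x", side = "medial", phi_deg = 0, grade = 2L,
    ossified_fraction = 1.5)), "ossified_fraction")
  # a non-monotone explicit size mapping is refused
  expect_error(phantom_spec(osteophytes = tibble::tibble(
    id = c("x", "y"), side = "medial", phi_deg = c(0, 60), grade = c(1L, 2L),
    ossified_fraction = 0.5, height_mm = c(3, 2), base_width_mm = c(6, 4))),
    "strictly larger")
})

test_that("phantom fiducials and landmarks are usable for registration", {
  ph <- test_phantom()
  expect_equal(nrow(ph$fiducials), 4)
  expect_gte(nrow(ph$landmarks), 4)
  # all sit on the bone surface
  d <- point_to_surface_distance(as.matrix(ph$fiducials[, c("x", "y", "z")]),
                                 ph$bone_surface)$distance
  expect_lt(max(d), 0.05)
  # labels cover all three tissue classes
  expect_setequal(sort(unique(sub(":.*$", "", ph$outer_surface$labels))),
                  c("bone", "cartilage", "osteophyte"))
})
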