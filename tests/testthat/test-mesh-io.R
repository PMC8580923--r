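test_that("PLY round trip preserves geometry and labels", {
  m <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, path)
  m2 <- load_mesh(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(m2$faces, m$faces)

  lab <- triangle_mesh(m$vertices, m$faces,
                       labels = c("bone", "bone", "cartilage", "osteophyte:o1"))
  write_mesh(lab, path)
  lab2 <- load_mesh(path)
  expect_equal(lab2$labels, lab$labels)

  s <- sphere_mesh(radius = 3, level = 3)
  write_mesh(s, path)
  s2 <- load_mesh(path)
  expect_equal(s2$vertices, s$vertices, tolerance = 1e-6)
  expect_equal(nrow(s2$faces), nrow(s$faces))
})

test_that("binary little-endian PLY is read correctly", {
  m <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               "element vertex 4",
               "property float x", "property float y", "property float z",
               "element face 4",
               "property list uchar int vertex_indices", "end_header"), con)
  for (i in 1:4) writeBin(as.numeric(m$vertices[i, ]), con, size = 4,
                          endian = "little")
  for (i in 1:4) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(m$faces[i, ] - 1L), con, size = 4, endian = "little")
  }
  close(con)
  m2 <- load_mesh(path)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-6)
  expect_equal(m2$faces, m$faces)
})

test_that("STL (ascii and binary) and OBJ are read correctly", {
  m <- tetra_mesh()
  # ascii STL
  pa <- withr::local_tempfile(fileext = ".stl")
  lines <- c("solid tetra")
  for (i in 1:4) {
    tri <- m$vertices[m$faces[i, ], ]
    lines <- c(lines, " facet normal 0 0 0", "  outer loop",
               sprintf("   vertex %g %g %g", tri[, 1], tri[, 2], tri[, 3]),
               "  endloop", " endfacet")
  }
  writeLines(c(lines, "endsolid tetra"), pa)
  ma <- load_mesh(pa)
  expect_equal(nrow(ma$vertices), 4)
  expect_equal(nrow(ma$faces), 4)
  expect_equal(sort(mesh_face_areas(ma)), sort(mesh_face_areas(m)), tolerance = 1e-6)

  # binary STL
  pb <- withr::local_tempfile(fileext = ".stl")
  con <- file(pb, "wb")
  writeBin(raw(80), con)
  writeBin(4L, con, size = 4, endian = "little")
  for (i in 1:4) {
    writeBin(numeric(3), con, size = 4, endian = "little") # normal
    tri <- m$vertices[m$faces[i, ], ]
    writeBin(as.numeric(t(tri)), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  close(con)
  mb <- load_mesh(pb)
  expect_equal(nrow(mb$vertices), 4)
  expect_equal(sort(mesh_face_areas(mb)), sort(mesh_face_areas(m)), tolerance = 1e-6)

  # OBJ
  po <- withr::local_tempfile(fileext = ".obj")
  writeLines(c(sprintf("v %g %g %g", m$vertices[, 1], m$vertices[, 2],
                       m$vertices[, 3]),
               sprintf("f %d %d %d", m$faces[, 1], m$faces[, 2], m$faces[, 3])),
             po)
  mo <- load_mesh(po)
  expect_equal(mo$vertices, m$vertices)
  expect_equal(mo$faces, m$faces)
})

test_that("malformed mesh files raise informative errors", {
  expect_error(load_mesh("does-not-exist.ply"), "not found")
  # face referencing vertex 99 of a 4-vertex mesh
  path <- withr::local_tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 3",
               "property double x", "property double y", "property double z",
               "element face 1",
               "property list uchar int vertex_indices", "end_header",
               "0 0 0", "1 0 0", "0 1 0", "3 0 1 99"), path)
  expect_error(load_mesh(path), "invalid vertex indices.*1")
  # unknown extension
  expect_error(load_mesh(withr::local_tempfile(fileext = ".xyz")), "Cannot infer")
})

test_that("fiducial CSV/JSON round trip and validation", {
  fs <- fiducial_set(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(1, 2, 12)),
                     frame = "ct")
  for (ext in c(".csv", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_fiducials(fs, p)
    fs2 <- read_fiducials(p, frame = "ct")
    expect_equal(fid_matrix <- as.matrix(fs2[, c("x", "y", "z")]),
                 as.matrix(fs[, c("x", "y", "z")]), tolerance = 1e-9)
    expect_equal(fs2$name, fs$name)
  }
  expect_error(fiducial_set(rbind(c(0, 0, 0), c(1, 0, 0))), "at least 3")
  expect_error(
    fiducial_set(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))),
    "collinear"
  )
  expect_error(
    fiducial_set(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 names = c("a", "a", "b")),
    "unique"
  )
})
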