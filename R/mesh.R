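#' Triangle surface meshes
#'
#' `triangle_mesh()` builds the package's universal surface representation: a
#' triangle mesh in millimetres, with optional per-vertex tissue labels
#' (`"bone"`, `"cartilage"`, or `"osteophyte:<id>"`) and a named coordinate
#' frame. All registration, distance and simulation functions consume and
#' produce this class.
#'
#' Invariants enforced on construction: every face references valid vertices,
#' vertex coordinates are finite, and no face is degenerate (area below
#' 1e-12 mm^2).
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param labels optional character vector of per-vertex tissue labels,
#'   length `nrow(vertices)`.
#' @param frame name of the coordinate frame the vertices live in. Functions
#'   that compare two meshes refuse to mix frames silently.
#' @param validate set to `FALSE` to skip invariant checks (internal use on
#'   meshes already known valid).
#' @return An object of class `osteo_mesh`.
#' @examples
#' m <- triangle_mesh(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   faces = rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
#' )
#' mesh_area(m)
#' @export
triangle_mesh <- function(vertices, faces, labels = NULL,
                          frame = "unspecified", validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) abort("`vertices` must have 3 columns (x, y, z in mm).")
  if (ncol(faces) != 3L) abort("`faces` must have 3 columns (triangle vertex indices).")
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(vertices)) {
      abort("`labels` must have one entry per vertex.")
    }
  }
  mesh <- structure(
    list(vertices = vertices, faces = faces, labels = labels,
         frame = as.character(frame)[1]),
    class = "osteo_mesh"
  )
  if (validate) validate_mesh(mesh)
  mesh
}

#' @rdname triangle_mesh
#' @param x,mesh an `osteo_mesh`.
#' @export
is_triangle_mesh <- function(x) inherits(x, "osteo_mesh")

#' @rdname triangle_mesh
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(v) < 3L || nrow(f) < 1L) abort("Mesh must have at least 3 vertices and 1 face.")
  if (!all(is.finite(v))) abort("Mesh vertices contain non-finite coordinates.")
  bad_idx <- which(f < 1L | f > nrow(v), arr.ind = TRUE)
  if (length(bad_idx)) {
    abort(paste0(
      "Faces reference invalid vertex indices: face(s) ",
      paste(sort(unique(bad_idx[, 1])), collapse = ", ")
    ))
  }
  areas <- mesh_face_areas(mesh)
  degen <- which(areas <= 1e-12)
  if (length(degen)) {
    abort(paste0(
      "Degenerate (zero-area) face(s): ",
      paste(head(degen, 20), collapse = ", "),
      if (length(degen) > 20) sprintf(" ... (%d total)", length(degen)) else ""
    ))
  }
  invisible(mesh)
}

#' @export
print.osteo_mesh <- function(x, ...) {
  cat(sprintf(
    "<osteo_mesh> %d vertices, %d faces, frame '%s'%s\n",
    nrow(x$vertices), nrow(x$faces), x$frame,
    if (is.null(x$labels)) "" else
      sprintf(", labels: %s", paste(sort(unique(sub(":.*$", "", x$labels))), collapse = "/"))
  ))
  invisible(x)
}

#' @export
format.osteo_mesh <- function(x, ...) {
  sprintf("<osteo_mesh: %d vertices, %d faces>", nrow(x$vertices), nrow(x$faces))
}

#' Mesh measurements
#'
#' Per-face unsigned areas (mm^2), total surface area, face centroids and
#' area-weighted outward vertex normals.
#'
#' @param mesh an `osteo_mesh`.
#' @return `mesh_face_areas()`: numeric vector (mm^2); `mesh_area()`: scalar;
#'   `mesh_face_centroids()`: matrix; `mesh_vertex_normals()`: unit-normal
#'   matrix (orientation follows face winding).
#' @export
mesh_face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname mesh_face_areas
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

#' @rdname mesh_face_areas
#' @export
mesh_face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] + v[f[, 3], , drop = FALSE]) / 3
}

#' @rdname mesh_face_areas
#' @export
mesh_vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  n <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    for (k in 1:3) {
      acc <- rowsum(fn[, k], group = f[, j], reorder = FALSE)
      n[as.integer(rownames(acc)), k] <- n[as.integer(rownames(acc)), k] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Extract the submesh spanned by a set of faces
#'
#' Vertex indices are re-packed and per-vertex labels carried over.
#'
#' @param mesh an `osteo_mesh`.
#' @param face_idx integer vector of face indices to keep.
#' @return An `osteo_mesh` in the same frame.
#' @export
submesh <- function(mesh, face_idx) {
  face_idx <- sort(unique(as.integer(face_idx)))
  if (!length(face_idx)) abort("Empty face selection.")
  if (any(face_idx < 1L | face_idx > nrow(mesh$faces))) {
    abort("Face indices out of range.")
  }
  f <- mesh$faces[face_idx, , drop = FALSE]
  keep_v <- sort(unique(as.vector(f)))
  remap <- integer(nrow(mesh$vertices))
  remap[keep_v] <- seq_along(keep_v)
  triangle_mesh(
    vertices = mesh$vertices[keep_v, , drop = FALSE],
    faces = matrix(remap[f], ncol = 3),
    labels = if (is.null(mesh$labels)) NULL else mesh$labels[keep_v],
    frame = mesh$frame,
    validate = FALSE
  )
}

#' Concatenate two meshes in the same frame
#'
#' Used to combine the medial and lateral 3D-US surface models into one
#' complete model before registration.
#'
#' @param a,b `osteo_mesh` objects in the same frame.
#' @return The combined `osteo_mesh`.
#' @export
merge_meshes <- function(a, b) {
  if (!identical(a$frame, b$frame)) {
    abort(sprintf("Cannot merge meshes from different frames ('%s' vs '%s').",
                  a$frame, b$frame))
  }
  labels <- NULL
  if (!is.null(a$labels) || !is.null(b$labels)) {
    labels <- c(a$labels %||% rep("bone", nrow(a$vertices)),
                b$labels %||% rep("bone", nrow(b$vertices)))
  }
  triangle_mesh(
    vertices = rbind(a$vertices, b$vertices),
    faces = rbind(a$faces, b$faces + nrow(a$vertices)),
    labels = labels,
    frame = a$frame,
    validate = FALSE
  )
}

#' Keep only faces whose vertices all carry a kept label
#'
#' Mirrors the registration protocol step in which surface models are
#' cropped to contain only bony surfaces before ICP refinement.
#'
#' @param mesh a labelled `osteo_mesh`.
#' @param keep character vector of labels to keep. Entries may be exact
#'   labels (`"bone"`, `"osteophyte:o1"`) or the prefix `"osteophyte"` to
#'   keep every osteophyte region.
#' @return The cropped `osteo_mesh` (indices re-packed, labels preserved).
#' @export
crop_by_label <- function(mesh, keep) {
  if (is.null(mesh$labels)) abort("Mesh has no vertex labels to crop by.")
  base <- sub(":.*$", "", mesh$labels)
  v_keep <- mesh$labels %in% keep | base %in% keep
  if (!any(v_keep)) {
    abort(sprintf("No vertices carry the requested label(s): %s",
                  paste(keep, collapse = ", ")))
  }
  ok <- matrix(v_keep[mesh$faces], ncol = 3)
  face_idx <- which(rowSums(ok) == 3L)
  if (!length(face_idx)) {
    abort(sprintf("No face has all three vertices labelled %s.",
                  paste(keep, collapse = "/")))
  }
  submesh(mesh, face_idx)
}

# Weld exactly coincident vertices and drop degenerate faces. Used to clean
# isosurface / quantized meshes before they become osteo_mesh objects.
clean_mesh_arrays <- function(vertices, faces, labels = NULL, digits = 9) {
  remap <- vctrs::vec_group_id(data.frame(
    x = round(vertices[, 1], digits),
    y = round(vertices[, 2], digits),
    z = round(vertices[, 3], digits)
  ))
  first <- !duplicated(remap)
  v <- vertices[first, , drop = FALSE]
  f <- matrix(remap[faces], ncol = 3)
  lab <- if (is.null(labels)) NULL else labels[first]
  # drop collapsed and zero-area faces
  distinct <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  f <- f[distinct, , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  a2 <- (e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])^2 +
    (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3])^2 +
    (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2
  f <- f[0.5 * sqrt(a2) > 1e-12, , drop = FALSE]
  # drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  remap2 <- integer(nrow(v))
  remap2[used] <- seq_along(used)
  list(
    vertices = v[used, , drop = FALSE],
    faces = matrix(remap2[f], ncol = 3),
    labels = if (is.null(lab)) NULL else lab[used]
  )
}
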