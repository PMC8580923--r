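#' Osteophyte region labels
#'
#' A named, circumscribed osteophyte region: a set of faces on the
#' reference (ground-truth) model, plus the metadata used for grouping in
#' the downstream summary tables. Grades follow the semi-quantitative
#' ultrasound atlas: 0 none, 1 small, 2 medium, 3 large.
#'
#' @param region_id region identifier (e.g. `"o1"`).
#' @param face_indices integer face indices on the reference mesh.
#' @param specimen,side grouping metadata; `side` is `"medial"` or
#'   `"lateral"`.
#' @param grade integer 0-3.
#' @param reference optional mesh to validate the indices against.
#' @return An object of class `region_label`.
#' @export
region_label <- function(region_id, face_indices, specimen = "specimen",
                         side = c("medial", "lateral"), grade = 1L,
                         reference = NULL) {
  side <- match.arg(side)
  face_indices <- sort(unique(as.integer(face_indices)))
  if (!length(face_indices)) abort("`face_indices` must be non-empty.")
  if (!grade %in% 0:3) abort("`grade` must be an integer in 0..3.")
  if (!is.null(reference) &&
      any(face_indices < 1L | face_indices > nrow(reference$faces))) {
    abort("Region face indices out of range for the reference mesh.")
  }
  structure(
    list(region_id = as.character(region_id), specimen = as.character(specimen),
         side = side, grade = as.integer(grade), face_indices = face_indices),
    class = "region_label"
  )
}

#' @export
print.region_label <- function(x, ...) {
  cat(sprintf("<region_label> %s (%s %s, grade %d): %d faces\n",
              x$region_id, x$specimen, x$side, x$grade, length(x$face_indices)))
  invisible(x)
}

#' Circumscribe a region around a surface point
#'
#' Mechanises the manual outlining of an osteophyte area: selects all faces
#' whose centroids lie within `radius_mm` of `seed_point`. The seed must lie
#' on (within 2 mm of) the mesh surface.
#'
#' @param mesh the reference `osteo_mesh`.
#' @param seed_point length-3 point on the surface (mm).
#' @param radius_mm selection radius (mm).
#' @inheritParams region_label
#' @return A [region_label()].
#' @export
circumscribe_region <- function(mesh, seed_point, radius_mm,
                                region_id = "o1", specimen = "specimen",
                                side = "medial", grade = 1L) {
  d <- point_to_surface_distance(seed_point, mesh)$distance
  if (d > 2) {
    abort(sprintf("Seed point is %.2f mm from the surface (limit 2 mm).", d))
  }
  cen <- mesh_face_centroids(mesh)
  dd <- sqrt((cen[, 1] - seed_point[1])^2 + (cen[, 2] - seed_point[2])^2 +
               (cen[, 3] - seed_point[3])^2)
  idx <- which(dd <= radius_mm)
  if (!length(idx)) abort("Circumscribed selection is empty.")
  region_label(region_id, idx, specimen = specimen, side = side,
               grade = grade, reference = mesh)
}

#' Recover region labels from per-vertex osteophyte labels
#'
#' Builds one [region_label()] per `osteophyte:<id>` label present on the
#' mesh, selecting faces whose three vertices all carry that label.
#'
#' @param mesh a labelled `osteo_mesh`.
#' @param specimen specimen name for the metadata.
#' @param grades optional named integer vector (`id -> grade`).
#' @param sides optional named character vector (`id -> side`).
#' @return A list of `region_label`s.
#' @export
regions_from_labels <- function(mesh, specimen = "specimen", grades = NULL,
                                sides = NULL) {
  if (is.null(mesh$labels)) abort("Mesh has no vertex labels.")
  ids <- sort(unique(sub("^osteophyte:", "",
                         grep("^osteophyte:", mesh$labels, value = TRUE))))
  lapply(ids, function(id) {
    lab <- paste0("osteophyte:", id)
    v_in <- mesh$labels == lab
    ok <- matrix(v_in[mesh$faces], ncol = 3)
    face_idx <- which(rowSums(ok) == 3L)
    if (!length(face_idx)) face_idx <- which(rowSums(ok) >= 2L)
    region_label(
      id, face_idx, specimen = specimen,
      side = if (!is.null(sides) && id %in% names(sides)) sides[[id]] else "medial",
      grade = if (!is.null(grades) && id %in% names(grades)) grades[[id]] else 1L,
      reference = mesh
    )
  })
}

#' Per-region RMS surface distance
#'
#' The depiction-accuracy metric: points are sampled uniformly by area on
#' the region's faces of the reference (ground-truth) model, the unsigned
#' distance of each sample to the test model is measured, and the RMS
#' (square root of the mean squared distance) is returned. With
#' `direction = "symmetric"` the same is also done from the test surface
#' (restricted to the part nearest the region) back to the reference, and
#' the RMS of the pooled samples is reported.
#'
#' @param region a [region_label()] defined on `reference`.
#' @param reference ground-truth `osteo_mesh` (SLS role).
#' @param test `osteo_mesh` or [mesh_index()] under evaluation (CT or 3D-US
#'   role); must be in the same frame as `reference`.
#' @param samples_per_mm2 sampling density (default 25 points/mm^2).
#' @param seed integer seed making the sampling reproducible.
#' @param direction `"reference_to_test"` (default) or `"symmetric"`.
#' @param modality_pair label stored in the output record (e.g. `"CT-SLS"`).
#' @return A one-row tibble (an RMS record) with columns `specimen`, `side`,
#'   `region_id`, `grade`, `modality_pair`, `rms_mm`, `mean_mm`,
#'   `n_samples`.
#' @export
region_rms <- function(region, reference, test, samples_per_mm2 = 25,
                       seed = 1L, direction = c("reference_to_test", "symmetric"),
                       modality_pair = NA_character_) {
  direction <- match.arg(direction)
  if (!inherits(region, "region_label")) abort("`region` must be a region_label.")
  test_idx <- if (inherits(test, "mesh_index")) test else mesh_index(test)
  if (!identical(reference$frame, test_idx$mesh$frame)) {
    abort(sprintf("Frame mismatch: reference in '%s', test in '%s'. Register first.",
                  reference$frame, test_idx$mesh$frame))
  }
  if (any(region$face_indices > nrow(reference$faces))) {
    abort("Region face indices out of range for `reference`.")
  }
  smp <- sample_surface(reference, density = samples_per_mm2,
                        faces = region$face_indices, seed = seed)
  d <- point_to_surface_distance(smp$points, test_idx)$distance
  n <- length(d)
  if (direction == "symmetric") {
    ref_idx <- mesh_index(reference)
    # sample the test surface near the region (within the region's extent)
    q <- point_to_surface_distance(smp$points, test_idx)
    near_faces <- unique(q$face)
    smp2 <- sample_surface(test_idx$mesh, n = n, faces = near_faces,
                           seed = seed + 1L)
    d2 <- point_to_surface_distance(smp2$points, ref_idx)$distance
    d <- c(d, d2)
    n <- length(d)
  }
  tibble(
    specimen = region$specimen, side = region$side,
    region_id = region$region_id, grade = region$grade,
    modality_pair = modality_pair,
    rms_mm = sqrt(mean(d^2)), mean_mm = mean(d), n_samples = n
  )
}

#' Colour-coded topographic error map
#'
#' Per-vertex unsigned distances from the reference surface (a whole mesh or
#' one circumscribed region) to the test model, binned into colour ranges.
#' Following the published convention, low distances are warm
#' (yellow-to-red) and high distances cool (green-to-blue).
#'
#' @param reference ground-truth `osteo_mesh`.
#' @param test test `osteo_mesh` or [mesh_index()] in the same frame.
#' @param region optional [region_label()]; if given, the map covers only
#'   that region's submesh.
#' @param bin_edges_mm strictly increasing distance bin edges; distances
#'   beyond the last edge fall in an overflow bin.
#' @return An object of class `osteo_distance_map`: list with the submesh,
#'   per-vertex `distance`, `bin` (factor), `bin_edges_mm` and `colors`.
#' @export
topographic_map <- function(reference, test, region = NULL,
                            bin_edges_mm = c(0, 0.5, 1, 2, 3)) {
  if (any(diff(bin_edges_mm) <= 0)) abort("`bin_edges_mm` must be strictly increasing.")
  test_idx <- if (inherits(test, "mesh_index")) test else mesh_index(test)
  if (!identical(reference$frame, test_idx$mesh$frame)) {
    abort(sprintf("Frame mismatch: reference in '%s', test in '%s'.",
                  reference$frame, test_idx$mesh$frame))
  }
  mesh <- if (is.null(region)) reference else submesh(reference, region$face_indices)
  d <- point_to_surface_distance(mesh$vertices, test_idx)$distance
  edges <- c(bin_edges_mm, Inf)
  bin <- cut(d, breaks = edges, include.lowest = TRUE, right = TRUE)
  pal <- topo_palette(length(levels(bin)))
  structure(
    list(mesh = mesh, distance = d, bin = bin,
         bin_edges_mm = bin_edges_mm, colors = pal),
    class = "osteo_distance_map"
  )
}

# warm (low error) to cool (high error)
topo_palette <- function(n) {
  base <- c("#FFEE58", "#FFA726", "#EF5350", "#66BB6A", "#42A5F5", "#283593")
  if (n <= length(base)) base[seq_len(n)] else grDevices::colorRampPalette(base)(n)
}

#' @export
print.osteo_distance_map <- function(x, ...) {
  cat(sprintf("<osteo_distance_map> %d vertices; bins (mm): %s\n",
              length(x$distance),
              paste(x$bin_edges_mm, collapse = ", ")))
  print(table(x$bin))
  invisible(x)
}

#' @export
tidy.osteo_distance_map <- function(x, ...) {
  v <- x$mesh$vertices
  d <- x$distance
  b <- x$bin
  tibble(
    vertex = seq_len(nrow(v)),
    x = v[, 1], y = v[, 2], z = v[, 3],
    distance_mm = d, bin = b
  )
}

#' Write a topographic map as a colour-per-vertex PLY (plus a PNG legend)
#'
#' @param map an `osteo_distance_map`.
#' @param path output PLY path.
#' @param legend_path optional PNG path for the colour legend; silently
#'   skipped if no graphics device is available.
#' @return `path`, invisibly.
#' @export
write_distance_map <- function(map, path, legend_path = NULL) {
  cols <- t(grDevices::col2rgb(map$colors[as.integer(map$bin)]))
  write_mesh(map$mesh, path, colors = cols)
  if (!is.null(legend_path)) {
    try({
      grDevices::png(legend_path, width = 480, height = 160)
      on.exit(grDevices::dev.off(), add = TRUE)
      graphics::par(mar = c(3, 1, 2, 1))
      n <- length(levels(map$bin))
      graphics::image(matrix(seq_len(n), ncol = 1), col = map$colors,
                      axes = FALSE, main = "surface distance (mm)")
      graphics::axis(1, at = seq(0, 1, length.out = n + 1),
                     labels = c(map$bin_edges_mm, Inf))
    }, silent = TRUE)
  }
  invisible(path)
}

#' Plot a topographic error map
#'
#' A 2D orthographic projection of the mapped surface vertices coloured by
#' distance bin (warm = low error, cool = high error), in the style of the
#' published absolute-error colour maps.
#'
#' @param object an `osteo_distance_map`.
#' @param axes which two coordinates to plot (default x and z).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.osteo_distance_map <- function(object, axes = c("x", "z"), ...) {
  df <- tidy(object)
  pal <- setNames(object$colors, levels(object$bin))
  ggplot2::ggplot(df, ggplot2::aes(.data[[axes[1]]], .data[[axes[2]]],
                                   colour = .data$bin)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_manual(values = pal, name = "distance (mm)",
                                 drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("%s (mm)", axes[1]),
                  y = sprintf("%s (mm)", axes[2]),
                  title = "Surface-distance topographic map") +
    ggplot2::theme_minimal()
}

#' Read and write region-definition JSON files
#'
#' Each region is an object
#' `{region_id, specimen, side, grade, face_indices}` or
#' `{region_id, specimen, side, grade, seed_point, radius_mm}` (the latter
#' is circumscribed against `reference` on read).
#'
#' @param path JSON file path.
#' @param reference reference mesh used to validate/circumscribe regions.
#' @return `read_regions()`: list of [region_label()]s.
#' @export
read_regions <- function(path, reference = NULL) {
  spec <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(spec, function(r) {
    if (!is.null(r$face_indices)) {
      region_label(r$region_id, unlist(r$face_indices),
                   specimen = r$specimen %||% "specimen",
                   side = r$side %||% "medial", grade = r$grade %||% 1L,
                   reference = reference)
    } else {
      if (is.null(reference)) abort("Seed-point regions require `reference`.")
      circumscribe_region(reference, unlist(r$seed_point), r$radius_mm,
                          region_id = r$region_id,
                          specimen = r$specimen %||% "specimen",
                          side = r$side %||% "medial", grade = r$grade %||% 1L)
    }
  })
}

#' @rdname read_regions
#' @param regions list of [region_label()]s.
#' @export
write_regions <- function(regions, path) {
  out <- lapply(regions, function(r) {
    list(region_id = r$region_id, specimen = r$specimen, side = r$side,
         grade = r$grade, face_indices = r$face_indices)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
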