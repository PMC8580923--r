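#' Synthetic condylar phantom specification
#'
#' Describes a knee-like ground-truth geometry: two ellipsoidal condyles and
#' a connecting shaft blended into a smooth, star-shaped bone surface, an
#' articular cartilage layer of uniform thickness (physiological femoral
#' hyaline cartilage: 2.0-2.6 mm) over the condylar articular zone, and
#' bump-like marginal osteophytes of graded size. Each osteophyte has an
#' `ossified_fraction` f in `[0, 1]`: the calcified core visible to CT has
#' height `f * height`, while the full (osseocartilaginous) bump appears on
#' the true outer surface and to ultrasound.
#'
#' The grade-to-size mapping is monotone: grade 1 (small) 1.5 mm, grade 2
#' (medium) 3 mm, grade 3 (large) 5 mm high, base width twice the height.
#'
#' @param condyle_semi_axes semi-axes (mm) of each condylar ellipsoid.
#' @param condyle_offset centre offset of the condyles (mirrored in x).
#' @param shaft_semi_axes,shaft_center ellipsoid for the connecting shaft.
#' @param cartilage_thickness_mm uniform articular cartilage thickness;
#'   default 2.3, physiological range 2.0-2.6.
#' @param osteophytes tibble with columns `id`, `side`
#'   (`medial`/`lateral`), `phi_deg` (azimuth along the articular margin),
#'   `grade` (1-3), `ossified_fraction`, and optional `height_mm`,
#'   `base_width_mm` overriding the grade mapping. `NULL` gives a default
#'   mixed-composition set of four.
#' @param articular_axis direction of the centre of the articular cap.
#' @param articular_cap_deg angle (degrees) at which cartilage coverage ends;
#'   the transition to bare bone spans ~6 degrees.
#' @param margin_angle_deg angular position of the osteophyte margin ring.
#' @param blend_mm smooth-max temperature blending the three ellipsoids.
#' @param mesh_edge_mm target triangle edge length of the generated
#'   ground-truth meshes.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(condyle_semi_axes = c(10, 13, 16),
                         condyle_offset = c(8, -3, -2),
                         shaft_semi_axes = c(9, 22, 9),
                         shaft_center = c(0, 12, 1),
                         cartilage_thickness_mm = 2.3,
                         osteophytes = NULL,
                         articular_axis = c(0, -0.9, -0.44),
                         articular_cap_deg = 62,
                         margin_angle_deg = 63,
                         blend_mm = 1.0,
                         mesh_edge_mm = 0.5) {
  if (cartilage_thickness_mm < 0) abort("Cartilage thickness must be >= 0.")
  osteophytes <- osteophytes %||% tibble(
    id = c("o1", "o2", "o3", "o4"),
    side = c("medial", "medial", "lateral", "lateral"),
    phi_deg = c(-25, 25, 155, 205),
    grade = c(2L, 1L, 3L, 2L),
    ossified_fraction = c(0.6, 0.3, 0.9, 0.4)
  )
  osteophytes <- as_tibble(osteophytes)
  if (nrow(osteophytes)) {
    if (anyDuplicated(osteophytes$id)) abort("Osteophyte ids must be unique.")
    if (!all(osteophytes$grade %in% 1:3)) abort("Osteophyte grades must be 1, 2 or 3.")
    if (any(osteophytes$ossified_fraction < 0 | osteophytes$ossified_fraction > 1)) {
      abort("`ossified_fraction` must lie in [0, 1].")
    }
    if (!"height_mm" %in% names(osteophytes)) {
      osteophytes$height_mm <- c(1.5, 3, 5)[osteophytes$grade]
    }
    if (!"base_width_mm" %in% names(osteophytes)) {
      osteophytes$base_width_mm <- 2 * osteophytes$height_mm
    }
    # monotone grade -> size check
    byg <- osteophytes |> dplyr::arrange(.data$grade)
    if (nrow(byg) > 1) {
      for (i in 2:nrow(byg)) {
        if (byg$grade[i] > byg$grade[i - 1] &&
            (byg$height_mm[i] <= byg$height_mm[i - 1] ||
             byg$base_width_mm[i] <= byg$base_width_mm[i - 1])) {
          abort("Higher osteophyte grades must map to strictly larger sizes.")
        }
      }
    }
  }
  structure(list(
    condyle_semi_axes = condyle_semi_axes, condyle_offset = condyle_offset,
    shaft_semi_axes = shaft_semi_axes, shaft_center = shaft_center,
    cartilage_thickness_mm = cartilage_thickness_mm,
    osteophytes = osteophytes,
    articular_axis = articular_axis / sqrt(sum(articular_axis^2)),
    articular_cap_deg = articular_cap_deg,
    margin_angle_deg = margin_angle_deg,
    blend_mm = blend_mm, mesh_edge_mm = mesh_edge_mm
  ), class = "phantom_spec")
}

# radial support of an axis-aligned ellipsoid (centre inside origin's star
# domain): distance t along unit direction u with |(t u - c) / a| = 1
ellipsoid_radial <- function(U, center, semi_axes) {
  A <- (U[, 1] / semi_axes[1])^2 + (U[, 2] / semi_axes[2])^2 +
    (U[, 3] / semi_axes[3])^2
  B <- -2 * (U[, 1] * center[1] / semi_axes[1]^2 +
               U[, 2] * center[2] / semi_axes[2]^2 +
               U[, 3] * center[3] / semi_axes[3]^2)
  C <- sum((center / semi_axes)^2) - 1
  if (C >= 0) abort("Phantom ellipsoid does not contain the origin; shrink its offset.")
  (-B + sqrt(B^2 - 4 * A * C)) / (2 * A)
}

# base (osteophyte-free) radial field: smooth max over the three ellipsoids
phantom_base_radial <- function(spec, U) {
  r1 <- ellipsoid_radial(U, spec$condyle_offset, spec$condyle_semi_axes)
  off2 <- spec$condyle_offset * c(-1, 1, 1)
  r2 <- ellipsoid_radial(U, off2, spec$condyle_semi_axes)
  r3 <- ellipsoid_radial(U, spec$shaft_center, spec$shaft_semi_axes)
  tau <- spec$blend_mm
  m <- pmax(r1, pmax(r2, r3))
  m + tau * log(exp((r1 - m) / tau) + exp((r2 - m) / tau) + exp((r3 - m) / tau))
}

# unit direction of an osteophyte from its azimuth along the margin ring
margin_direction <- function(spec, phi_deg) {
  d <- spec$articular_axis
  e1 <- c(1, 0, 0)
  e1 <- e1 - sum(e1 * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  th <- spec$margin_angle_deg * pi / 180
  phi <- phi_deg * pi / 180
  u <- cos(th) * d + sin(th) * (cos(phi) * e1 + sin(phi) * e2)
  u / sqrt(sum(u^2))
}

# per-osteophyte geometry in angular terms
osteophyte_geometry <- function(spec) {
  os <- spec$osteophytes
  if (!nrow(os)) return(NULL)
  dirs <- t(vapply(os$phi_deg, function(p) margin_direction(spec, p), numeric(3)))
  Rbase <- phantom_base_radial(spec, dirs)
  sigma <- (os$base_width_mm / 2) / (2.45 * Rbase)  # base edge at ~2.45 sigma
  list(dirs = dirs, sigma_ang = sigma, height = os$height_mm,
       frac = os$ossified_fraction, id = os$id, grade = os$grade,
       side = os$side)
}

# Gaussian bump profiles (n x n_osteophytes), in units of full bump height
bump_profiles <- function(geom, U) {
  if (is.null(geom)) return(NULL)
  out <- matrix(0, nrow(U), length(geom$id))
  for (i in seq_along(geom$id)) {
    cosang <- pmin(1, pmax(-1, U %*% geom$dirs[i, ]))
    psi <- acos(cosang)
    out[, i] <- exp(-0.5 * (psi / geom$sigma_ang[i])^2)
  }
  out
}

# articular cartilage coverage mask in [0, 1], smoothstep over ~6 degrees.
# The intercondylar notch (midline groove between the condyles) is excluded:
# cartilage covers the two convex condylar facets, not the concave blend.
articular_mask <- function(spec, U) {
  cosang <- pmin(1, pmax(-1, U %*% spec$articular_axis))
  c_full <- cos((spec$articular_cap_deg - 3) * pi / 180)
  c_zero <- cos((spec$articular_cap_deg + 3) * pi / 180)
  x <- pmin(1, pmax(0, (cosang - c_zero) / (c_full - c_zero)))
  cap <- x^2 * (3 - 2 * x)
  g <- pmin(1, pmax(0, (abs(U[, 1]) - 0.12) / 0.10))
  notch <- g^2 * (3 - 2 * g)
  # keep cartilage off the concave condyle-shaft blend valley as well: the
  # normal offset is only thickness-exact on the convex condylar facets
  r1 <- ellipsoid_radial(U, spec$condyle_offset, spec$condyle_semi_axes)
  r2 <- ellipsoid_radial(U, spec$condyle_offset * c(-1, 1, 1),
                         spec$condyle_semi_axes)
  r3 <- ellipsoid_radial(U, spec$shaft_center, spec$shaft_semi_axes)
  h <- pmin(1, pmax(0, (pmax(r1, r2) - r3 - 0.5) / 2))
  valley <- h^2 * (3 - 2 * h)
  as.numeric(cap * notch * valley)
}

# bone radial field (includes ossified osteophyte cores)
phantom_bone_radial <- function(spec, U, geom = osteophyte_geometry(spec)) {
  r <- phantom_base_radial(spec, U)
  b <- bump_profiles(geom, U)
  if (!is.null(b)) r <- r + as.numeric(b %*% (geom$frac * geom$height))
  r
}

# tissue label for each unit direction
phantom_labels <- function(spec, U, geom = osteophyte_geometry(spec)) {
  lab <- rep("bone", nrow(U))
  mask <- articular_mask(spec, U)
  if (spec$cartilage_thickness_mm > 0) {
    lab[mask * spec$cartilage_thickness_mm > 0.1] <- "cartilage"
  }
  b <- bump_profiles(geom, U)
  if (!is.null(b)) {
    for (i in seq_along(geom$id)) {
      lab[b[, i] > 0.2] <- paste0("osteophyte:", geom$id[i])
    }
  }
  lab
}

# subdivided icosahedron: unit directions + faces
icosphere <- function(level) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(6, 5, 10), c(12, 3, 5), c(11, 7, 3), c(8, 9, 7), c(2, 10, 9)
  )
  for (l in seq_len(level)) {
    nv <- nrow(v)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    key <- pmin(e[, 1], e[, 2]) * 2^26 + pmax(e[, 1], e[, 2])
    uk <- !duplicated(key)
    mid_id <- nv + match(key, key[uk])
    mids <- (v[e[uk, 1], , drop = FALSE] + v[e[uk, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    nf <- nrow(f)
    m12 <- mid_id[seq_len(nf)]
    m23 <- mid_id[nf + seq_len(nf)]
    m13 <- mid_id[2 * nf + seq_len(nf)]
    f <- rbind(
      cbind(f[, 1], m12, m13),
      cbind(m12, f[, 2], m23),
      cbind(m13, m23, f[, 3]),
      cbind(m12, m23, m13)
    )
  }
  list(vertices = v, faces = f)
}

icosphere_level_for_edge <- function(max_radius, edge_mm) {
  max(2L, min(8L, ceiling(log2(1.0514 * max_radius / edge_mm))))
}

#' Generate a synthetic phantom
#'
#' Builds the ground-truth surfaces of a [phantom_spec()]: the bone surface
#' (blended condyles + shaft + ossified osteophyte cores), the outer surface
#' (bone plus the articular cartilage layer, offset along the surface
#' normal, plus the full osteophyte bumps), per-vertex tissue labels, one
#' region label per osteophyte, four shaft fiducials (the bone-screw
#' analogues) and five anatomical landmarks. Deterministic: the same spec
#' yields bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `osteo_phantom` with elements `spec`,
#'   `bone_surface`, `outer_surface` (both `osteo_mesh`es in frame
#'   `"phantom"`), `regions` (list of [region_label()]), `fiducials`,
#'   `landmarks` ([fiducial_set()]s), the exact surface parameterisation
#'   (`directions`: per-vertex unit directions; `cartilage_mask`: cartilage
#'   coverage in `[0, 1]`; `bump_max`: largest osteophyte bump profile at
#'   each vertex) and a private cache.
#' @examples
#' ph <- make_phantom(phantom_spec(mesh_edge_mm = 1.5))
#' ph$outer_surface
#' @export
make_phantom <- function(spec = phantom_spec()) {
  geom <- osteophyte_geometry(spec)
  if (!is.null(geom) && length(geom$id) > 1) {
    for (i in seq_along(geom$id)) {
      for (j in seq_len(i - 1)) {
        sep <- acos(pmin(1, pmax(-1, sum(geom$dirs[i, ] * geom$dirs[j, ]))))
        if (sep < 2.45 * (geom$sigma_ang[i] + geom$sigma_ang[j])) {
          abort(sprintf("Osteophytes '%s' and '%s' overlap; move them apart.",
                        geom$id[i], geom$id[j]))
        }
      }
    }
  }
  rmax <- max(phantom_base_radial(spec, icosphere(2)$vertices)) +
    (if (is.null(geom)) 0 else max(geom$height)) + spec$cartilage_thickness_mm
  level <- icosphere_level_for_edge(rmax, spec$mesh_edge_mm)
  sph <- icosphere(level)
  U <- sph$vertices

  r_bone <- phantom_bone_radial(spec, U, geom)
  bone_surface <- triangle_mesh(U * r_bone, sph$faces,
                                labels = rep("bone", nrow(U)),
                                frame = "phantom", validate = FALSE)

  b <- bump_profiles(geom, U)
  r_outer_radial <- phantom_base_radial(spec, U)
  if (!is.null(b)) r_outer_radial <- r_outer_radial + as.numeric(b %*% geom$height)
  outer_radial_mesh <- triangle_mesh(U * r_outer_radial, sph$faces,
                                     frame = "phantom", validate = FALSE)
  nrm <- mesh_vertex_normals(outer_radial_mesh)
  # orient outward
  flip <- rowSums(nrm * U) < 0
  nrm[flip, ] <- -nrm[flip, ]
  mask <- articular_mask(spec, U)
  outer_v <- outer_radial_mesh$vertices +
    nrm * (mask * spec$cartilage_thickness_mm)
  labels <- phantom_labels(spec, U, geom)
  outer_surface <- triangle_mesh(outer_v, sph$faces, labels = labels,
                                 frame = "phantom", validate = FALSE)
  bump_max <- if (is.null(b)) rep(0, nrow(U)) else
    apply(b, 1, max)

  regions <- if (is.null(geom)) list() else regions_from_labels(
    outer_surface, specimen = "phantom",
    grades = setNames(as.integer(geom$grade), geom$id),
    sides = setNames(as.character(geom$side), geom$id)
  )

  fid_dirs <- rbind(c(0.3, 1, 0.25), c(-0.3, 1, 0.25),
                    c(0.3, 1, -0.25), c(-0.3, 1, -0.25))
  fid_dirs <- fid_dirs / sqrt(rowSums(fid_dirs^2))
  fid_pts <- fid_dirs * phantom_bone_radial(spec, fid_dirs, geom)
  fiducials <- fiducial_set(fid_pts, names = paste0("F", 1:4), frame = "phantom")

  lm_dirs <- rbind(
    medial_epicondyle = c(1, 0.15, 0),
    lateral_epicondyle = c(-1, 0.15, 0),
    trochlea_ridge = c(0, 0.2, 1),
    posterior_shaft = c(0, 0.8, -1),
    anterior_shaft = c(0, 1, 0.6)
  )
  lm_dirs <- lm_dirs / sqrt(rowSums(lm_dirs^2))
  lm_pts <- lm_dirs * phantom_bone_radial(spec, lm_dirs, geom)
  landmarks <- fiducial_set(lm_pts, names = rownames(lm_dirs), frame = "phantom")

  structure(list(
    spec = spec, bone_surface = bone_surface, outer_surface = outer_surface,
    regions = regions, fiducials = fiducials, landmarks = landmarks,
    directions = U, cartilage_mask = as.numeric(mask), bump_max = bump_max,
    cache = new.env(parent = emptyenv())
  ), class = "osteo_phantom")
}

#' @export
print.osteo_phantom <- function(x, ...) {
  cat(sprintf(
    "<osteo_phantom> %d osteophyte region(s), cartilage %.2f mm\n  bone: %s\n  outer: %s\n",
    length(x$regions), x$spec$cartilage_thickness_mm,
    format(x$bone_surface), format(x$outer_surface)
  ))
  invisible(x)
}
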