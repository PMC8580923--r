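#' Modality degradation parameters
#'
#' Acquisition parameters of the three modalities being emulated, all in mm:
#' the structured-light scanner (0.1 mm resolution, 0.05 mm point accuracy),
#' CT (0.625 mm slice thickness, 0.36 mm in-plane pixels, bone only — the
#' segmentation threshold that keeps voxels above bone density excludes
#' cartilage), and freehand 3D ultrasound reconstructed at 0.5 mm voxels
#' with partial (medial + lateral acoustic window) coverage and extra
#' surface noise. `fiducial_noise_sd_mm` models screw-fiducial localisation
#' error, `landmark_noise_sd_mm` the less precise anatomical-landmark picks.
#'
#' @param sls list: `resolution_mm`, `point_noise_sd_mm`.
#' @param ct list: `slice_mm`, `pixel_mm`, `includes_cartilage` (FALSE).
#' @param us list: `voxel_mm`, `surface_noise_sd_mm`, `coverage_half_angle_deg`
#'   (wedge half-angle of each acoustic window about the +x / -x axes),
#'   `includes_cartilage` (TRUE).
#' @param fiducial_noise_sd_mm,landmark_noise_sd_mm point localisation noise.
#' @param pose_max_angle_deg,pose_max_translation_mm bounds of the random
#'   rigid pose applied per acquisition (kept inside the ICP capture basin;
#'   larger displacements are what the landmark stage is for).
#' @return A list of class `modality_params`.
#' @export
modality_params <- function(sls = list(resolution_mm = 0.1, point_noise_sd_mm = 0.05),
                            ct = list(slice_mm = 0.625, pixel_mm = 0.36,
                                      includes_cartilage = FALSE),
                            us = list(voxel_mm = 0.5, surface_noise_sd_mm = 0.15,
                                      coverage_half_angle_deg = 55,
                                      includes_cartilage = TRUE),
                            fiducial_noise_sd_mm = 0.3,
                            landmark_noise_sd_mm = 0.5,
                            pose_max_angle_deg = 10,
                            pose_max_translation_mm = 5) {
  sls <- modifyList(eval(formals(modality_params)$sls), sls)
  ct <- modifyList(eval(formals(modality_params)$ct), ct)
  us <- modifyList(eval(formals(modality_params)$us), us)
  stopifnot(sls$resolution_mm > 0, ct$slice_mm > 0, ct$pixel_mm > 0,
            us$voxel_mm > 0)
  if (us$coverage_half_angle_deg <= 0 || us$coverage_half_angle_deg > 90) {
    abort("`coverage_half_angle_deg` must lie in (0, 90]; the two acoustic windows must not overlap.")
  }
  structure(list(
    sls = sls, ct = ct, us = us,
    fiducial_noise_sd_mm = fiducial_noise_sd_mm,
    landmark_noise_sd_mm = landmark_noise_sd_mm,
    pose_max_angle_deg = pose_max_angle_deg,
    pose_max_translation_mm = pose_max_translation_mm
  ), class = "modality_params")
}

jitter_fiducials <- function(fs, sd) {
  p <- fid_matrix(fs)
  if (sd > 0) p <- p + matrix(rnorm(length(p), sd = sd), nrow(p), 3)
  fiducial_set(p, names = fs$name, frame = fid_frame(fs))
}

#' Simulate a structured-light-scan acquisition
#'
#' Remeshes the phantom's outer surface (bone + cartilage + full
#' osteophytes) at approximately the scanner's resolution, perturbs each
#' vertex with isotropic Gaussian noise at the scanner's point accuracy,
#' applies a random rigid pose (recorded as `true_pose`), and emits the
#' anatomical landmarks with localisation noise, all in the new `"sls"`
#' frame. Tissue labels are kept.
#'
#' @param phantom an [make_phantom()] result.
#' @param params a [modality_params()].
#' @param pose_seed integer seed driving the pose and all noise; identical
#'   seeds give bit-identical output.
#' @return List with `mesh`, `true_pose`, `landmarks`, `fiducials`.
#' @export
simulate_sls <- function(phantom, params = modality_params(), pose_seed = 1L) {
  spec <- phantom$spec
  withr::with_seed(pose_seed, {
    geom <- osteophyte_geometry(spec)
    rmax <- max(phantom_base_radial(spec, icosphere(2)$vertices)) +
      (if (is.null(geom)) 0 else max(geom$height)) + spec$cartilage_thickness_mm
    level <- icosphere_level_for_edge(rmax, params$sls$resolution_mm)
    key <- paste0("sls_core_", level)
    core <- phantom$cache[[key]]
    if (is.null(core)) {
      core <- remesh_outer(phantom, level)
      phantom$cache[[key]] <- core
    }
    v <- core$vertices
    if (params$sls$point_noise_sd_mm > 0) {
      v <- v + matrix(rnorm(length(v), sd = params$sls$point_noise_sd_mm),
                      nrow(v), 3)
    }
    pose <- random_rigid_transform(params$pose_max_angle_deg,
                                   params$pose_max_translation_mm)
    mesh <- triangle_mesh(rt_apply(pose, v), core$faces, labels = core$labels,
                          frame = "sls", validate = FALSE)
    landmarks <- transform_fiducials(
      jitter_fiducials(phantom$landmarks, params$landmark_noise_sd_mm),
      pose, frame = "sls")
    fiducials <- transform_fiducials(
      jitter_fiducials(phantom$fiducials, params$fiducial_noise_sd_mm),
      pose, frame = "sls")
    list(mesh = mesh, true_pose = pose, landmarks = landmarks,
         fiducials = fiducials)
  })
}

# re-evaluate the parametric outer surface on a fresh icosphere
remesh_outer <- function(phantom, level) {
  spec <- phantom$spec
  geom <- osteophyte_geometry(spec)
  sph <- icosphere(level)
  U <- sph$vertices
  b <- bump_profiles(geom, U)
  r <- phantom_base_radial(spec, U)
  if (!is.null(b)) r <- r + as.numeric(b %*% geom$height)
  radial_mesh <- triangle_mesh(U * r, sph$faces, frame = "phantom",
                               validate = FALSE)
  nrm <- mesh_vertex_normals(radial_mesh)
  flip <- rowSums(nrm * U) < 0
  nrm[flip, ] <- -nrm[flip, ]
  mask <- articular_mask(spec, U)
  v <- radial_mesh$vertices + nrm * (mask * spec$cartilage_thickness_mm)
  list(vertices = v, faces = sph$faces, labels = phantom_labels(spec, U, geom),
       U = U)
}

#' Simulate a CT acquisition
#'
#' Voxelises only the bone surface — cartilage and the cartilaginous
#' fraction of each osteophyte are excluded, emulating segmentation at a
#' bone-density threshold; an osteophyte with `ossified_fraction` f
#' contributes only its f-scaled calcified core. Occupancy is sampled on an
#' anisotropic grid (pixel x pixel x slice) and the bone surface is
#' extracted from the binary volume by marching tetrahedra, reproducing the
#' staircase quantisation of a thresholded scan. A random rigid pose is then
#' applied and the screw fiducials and landmarks are emitted with noise in
#' the `"ct"` frame.
#'
#' @inheritParams simulate_sls
#' @return List with `mesh` (all-bone labels), `true_pose`, `fiducials`,
#'   `landmarks`.
#' @export
simulate_ct <- function(phantom, params = modality_params(), pose_seed = 1L) {
  spec <- phantom$spec
  withr::with_seed(pose_seed, {
    key <- paste0("ct_core_", params$ct$pixel_mm, "_", params$ct$slice_mm)
    core <- phantom$cache[[key]]
    if (is.null(core)) {
      core <- voxelize_bone(phantom, c(params$ct$pixel_mm, params$ct$pixel_mm,
                                       params$ct$slice_mm))
      phantom$cache[[key]] <- core
    }
    pose <- random_rigid_transform(params$pose_max_angle_deg,
                                   params$pose_max_translation_mm)
    mesh <- triangle_mesh(rt_apply(pose, core$vertices), core$faces,
                          labels = rep("bone", nrow(core$vertices)),
                          frame = "ct", validate = FALSE)
    fiducials <- transform_fiducials(
      jitter_fiducials(phantom$fiducials, params$fiducial_noise_sd_mm),
      pose, frame = "ct")
    landmarks <- transform_fiducials(
      jitter_fiducials(phantom$landmarks, params$landmark_noise_sd_mm),
      pose, frame = "ct")
    list(mesh = mesh, true_pose = pose, fiducials = fiducials,
         landmarks = landmarks)
  })
}

# binary occupancy of the bone field on an anisotropic grid + isosurface
voxelize_bone <- function(phantom, spacing) {
  spec <- phantom$spec
  geom <- osteophyte_geometry(spec)
  bb_lo <- apply(phantom$bone_surface$vertices, 2, min) - 2 * spacing
  bb_hi <- apply(phantom$bone_surface$vertices, 2, max) + 2 * spacing
  dims <- pmax(4L, as.integer(ceiling((bb_hi - bb_lo) / spacing)) + 1L)
  origin <- bb_lo
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  xs <- origin[1] + (seq_len(nx) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(ny) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(nz) - 1) * spacing[3]
  vals <- numeric(nx * ny * nz)
  # chunk over z-slabs to bound memory
  slab <- max(1L, floor(5e5 / (nx * ny)))
  xy <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  for (k0 in seq(1L, nz, by = slab)) {
    ks <- k0:min(nz, k0 + slab - 1L)
    P <- cbind(xy[rep(seq_len(nx * ny), times = length(ks)), , drop = FALSE],
               rep(zs[ks], each = nx * ny))
    nrm <- sqrt(rowSums(P^2))
    nrm[nrm == 0] <- 1e-12
    U <- P / nrm
    f <- nrm - phantom_bone_radial(spec, U, geom)
    occ <- ifelse(f < 0, -1, 1)  # binary occupancy: inside bone vs outside
    vals[(k0 - 1L) * nx * ny + seq_along(occ)] <- occ
  }
  iso <- cpp_marching_tets(vals, dims, origin, spacing, 0)
  clean_mesh_arrays(iso$vertices, iso$faces)
}

#' Simulate a 3D freehand-ultrasound acquisition
#'
#' Extracts the outer surface (bone + cartilage + full osteophytes, since
#' ultrasound sees the soft-tissue interface) restricted to the medial and
#' lateral acoustic windows — the anterior (patellar shadow) and posterior
#' sectors are absent by construction — quantises the surface to the
#' reconstruction voxel grid, adds surface noise, applies a random rigid
#' pose and emits the four screw fiducials with localisation noise, all in
#' the `"us"` frame.
#'
#' @inheritParams simulate_sls
#' @return List with `medial_mesh`, `lateral_mesh` (labelled), `true_pose`,
#'   `fiducials`.
#' @export
simulate_us <- function(phantom, params = modality_params(), pose_seed = 1L) {
  spec <- phantom$spec
  withr::with_seed(pose_seed, {
    geom <- osteophyte_geometry(spec)
    rmax <- max(phantom_base_radial(spec, icosphere(2)$vertices)) +
      (if (is.null(geom)) 0 else max(geom$height)) + spec$cartilage_thickness_mm
    level <- icosphere_level_for_edge(rmax, 0.6 * params$us$voxel_mm)
    key <- paste0("us_core_", level, "_", params$us$voxel_mm)
    core <- phantom$cache[[key]]
    if (is.null(core)) {
      rm_ <- remesh_outer(phantom, level)
      vq <- round(rm_$vertices / params$us$voxel_mm) * params$us$voxel_mm
      core <- clean_mesh_arrays(vq, rm_$faces, labels = rm_$labels)
      phantom$cache[[key]] <- core
    }
    half <- params$us$coverage_half_angle_deg
    side_of <- function(v) {
      az <- atan2(v[, 3], v[, 1]) * 180 / pi
      ifelse(abs(az) <= half, "medial",
             ifelse(180 - abs(az) <= half, "lateral", NA_character_))
    }
    vside <- side_of(core$vertices)
    take_side <- function(side_name) {
      v_in <- !is.na(vside) & vside == side_name
      ok <- matrix(v_in[core$faces], ncol = 3)
      fidx <- which(rowSums(ok) == 3L)
      if (!length(fidx)) {
        abort(sprintf("US coverage window selects no faces on the %s side.",
                      side_name))
      }
      full <- triangle_mesh(core$vertices, core$faces, labels = core$labels,
                            frame = "phantom", validate = FALSE)
      submesh(full, fidx)
    }
    med <- take_side("medial")
    lat <- take_side("lateral")
    pose <- random_rigid_transform(params$pose_max_angle_deg,
                                   params$pose_max_translation_mm)
    degrade <- function(m) {
      v <- m$vertices
      if (params$us$surface_noise_sd_mm > 0) {
        v <- v + matrix(rnorm(length(v), sd = params$us$surface_noise_sd_mm),
                        nrow(v), 3)
      }
      triangle_mesh(rt_apply(pose, v), m$faces, labels = m$labels,
                    frame = "us", validate = FALSE)
    }
    fiducials <- transform_fiducials(
      jitter_fiducials(phantom$fiducials, params$fiducial_noise_sd_mm),
      pose, frame = "us")
    list(medial_mesh = degrade(med), lateral_mesh = degrade(lat),
         true_pose = pose, fiducials = fiducials)
  })
}
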