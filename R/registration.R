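#' Closed-form rigid alignment of matched point sets
#'
#' Least-squares rigid registration of two fiducial/landmark sets matched by
#' name, via SVD of the cross-covariance of the centred point sets (the
#' Kabsch/Horn solution) with reflection correction, so the returned rotation
#' always has determinant +1 even for near-planar configurations. The
#' reported RMS is the fiducial registration error (FRE): the RMS of residual
#' point-pair distances after alignment.
#'
#' @param source,target [fiducial_set()] objects with matching names
#'   (order may differ; matching is by name).
#' @return A `registration_result`: list with `transform` (mapping source
#'   frame into target frame), `rms_error` (mm), `iterations` (1),
#'   `converged` (TRUE) and `method = "landmark"`.
#' @examples
#' src <- fiducial_set(rbind(c(0,0,0), c(10,0,0), c(0,10,0), c(0,0,10)))
#' pose <- rt_axis_angle(c(1, 1, 0), 20, c(5, -3, 2))
#' tgt <- transform_fiducials(src, pose)
#' fit <- landmark_register(src, tgt)
#' fit$rms_error # ~ 0
#' @export
landmark_register <- function(source, target) {
  if (!inherits(source, "fiducial_set") || !inherits(target, "fiducial_set")) {
    abort("`source` and `target` must be fiducial_set objects.")
  }
  if (nrow(source) != nrow(target)) {
    abort("Source and target fiducial sets differ in size.")
  }
  ord <- match(source$name, target$name)
  if (anyNA(ord)) {
    abort(sprintf("Fiducial names do not match: missing in target: %s",
                  paste(source$name[is.na(ord)], collapse = ", ")))
  }
  S <- fid_matrix(source)
  T_ <- fid_matrix(target)[ord, , drop = FALSE]
  fit <- kabsch(S, T_)
  resid <- rt_apply(fit, S) - T_
  registration_result(
    transform = fit,
    rms_error = sqrt(mean(rowSums(resid^2))),
    iterations = 1L, converged = TRUE, method = "landmark",
    source_frame = fid_frame(source), target_frame = fid_frame(target)
  )
}

# closed-form least-squares rotation + translation, reflection-corrected
kabsch <- function(S, T_, weights = NULL) {
  w <- weights %||% rep(1, nrow(S))
  w <- w / sum(w)
  cs <- colSums(S * w)
  ct <- colSums(T_ * w)
  H <- crossprod(S * w - outer(w, cs), T_ - matrix(ct, nrow(T_), 3, byrow = TRUE))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  rigid_transform(R, ct - as.numeric(R %*% cs))
}

registration_result <- function(transform, rms_error, iterations, converged,
                                method, source_frame = NA_character_,
                                target_frame = NA_character_,
                                rms_history = NULL, n_correspondences = NA_integer_) {
  structure(
    list(transform = transform, rms_error = rms_error,
         iterations = as.integer(iterations), converged = isTRUE(converged),
         method = method, source_frame = source_frame,
         target_frame = target_frame, rms_history = rms_history,
         n_correspondences = as.integer(n_correspondences)),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> %s: RMS %.4f mm, %d iteration(s)%s ('%s' -> '%s')\n",
    x$method, x$rms_error, x$iterations,
    if (x$converged) ", converged" else ", max iterations reached",
    x$source_frame, x$target_frame
  ))
  invisible(x)
}

#' @export
tidy.registration_result <- function(x, ...) {
  tibble(
    method = x$method, rms_error_mm = x$rms_error, iterations = x$iterations,
    converged = x$converged, n_correspondences = x$n_correspondences,
    source_frame = x$source_frame, target_frame = x$target_frame
  )
}

#' @export
glance.registration_result <- function(x, ...) tidy(x)

#' ICP parameter set
#'
#' Defaults: 2,000 uniformly sampled source points, trimming at the 90th
#' percentile of correspondence distances (guards against partial-overlap
#' bias — the 3D-US model only covers the medial and lateral acoustic
#' windows), convergence when the accepted-correspondence RMS changes by
#' less than 1e-4 mm (well below the 0.05 mm SLS point accuracy), at most
#' 100 iterations.
#'
#' @param max_iterations iteration cap.
#' @param convergence_tol_mm stop when RMS changes less than this.
#' @param correspondence_rejection_quantile keep correspondences up to this
#'   distance quantile (1 disables trimming).
#' @param sample_count number of source surface samples.
#' @param seed integer seed for source sampling.
#' @return A list of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100L, convergence_tol_mm = 1e-4,
                       correspondence_rejection_quantile = 0.9,
                       sample_count = 2000L, seed = 1L) {
  structure(list(
    max_iterations = as.integer(max_iterations),
    convergence_tol_mm = convergence_tol_mm,
    correspondence_rejection_quantile = correspondence_rejection_quantile,
    sample_count = as.integer(sample_count),
    seed = as.integer(seed)
  ), class = "icp_params")
}

#' Iterative-closest-point rigid refinement
#'
#' Point-to-surface ICP: (a) sample points uniformly on the source surface
#' (once, seeded), then iterate (b) exact closest-point lookup on the
#' target, (c) rejection of correspondences beyond the configured distance
#' quantile, (d) closed-form rigid update on the accepted set. The
#' accepted-correspondence RMS is non-increasing across iterations; the
#' final value is reported as `rms_error` (the registration-error figure of
#' the three-way protocol).
#'
#' @param source,target `osteo_mesh` objects (already roughly aligned, e.g.
#'   by [landmark_register()]).
#' @param init initial `rigid_transform` applied to the source.
#' @param params an [icp_params()] list.
#' @return A `registration_result`; `transform` maps original source
#'   coordinates into the target frame (the initial transform is folded in),
#'   and `rms_history` records the per-iteration accepted RMS.
#' @export
icp_register <- function(source, target, init = rt_identity(),
                         params = icp_params()) {
  if (!is_triangle_mesh(source)) abort("`source` must be an osteo_mesh.")
  if (!is_triangle_mesh(target) && !inherits(target, "mesh_index")) {
    abort("`target` must be an osteo_mesh or mesh_index.")
  }
  idx <- if (inherits(target, "mesh_index")) target else mesh_index(target)
  target_frame <- idx$mesh$frame
  if (params$sample_count < 3L) {
    abort("Degenerate correspondence set: ICP needs at least 3 source samples.")
  }
  smp <- sample_surface(source, n = params$sample_count, seed = params$seed)
  P0 <- smp$points
  n_keep <- max(3L, floor(nrow(P0) * params$correspondence_rejection_quantile))
  if (n_keep < 3L || n_keep > nrow(P0)) {
    abort("Degenerate correspondence set (< 3 points after rejection).")
  }

  current <- init
  rms_prev <- Inf
  history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < params$max_iterations) {
    iter <- iter + 1L
    P <- rt_apply(current, P0)
    q <- cpp_mesh_index_query(idx$ptr, P)
    d <- q$distance
    keep <- order(d)[seq_len(n_keep)]
    if (length(keep) < 3L) abort("Degenerate correspondence set (< 3 points after rejection).")
    rms <- sqrt(mean(d[keep]^2))
    history <- c(history, rms)
    if (abs(rms_prev - rms) < params$convergence_tol_mm) {
      converged <- TRUE
      break
    }
    rms_prev <- rms
    upd <- kabsch(P[keep, , drop = FALSE], q$point[keep, , drop = FALSE])
    current <- rt_compose(upd, current)
  }
  registration_result(
    transform = current, rms_error = history[length(history)],
    iterations = iter, converged = converged, method = "icp",
    source_frame = source$frame, target_frame = target_frame,
    rms_history = history, n_correspondences = n_keep
  )
}

#' Three-way SLS / 3D-US / CT alignment protocol
#'
#' Aligns the structured-light-scan (ground truth) and 3D-ultrasound surface
#' models into the CT coordinate system, chosen as the reference because the
#' CT model shows the largest portion of the anatomy:
#'
#' 1. SLS -> CT global initialisation from matched anatomical landmarks;
#' 2. ICP refinement restricted to the bone-labelled submeshes of SLS and
#'    CT, with the result applied to the complete SLS model (bone plus
#'    cartilage);
#' 3. the medial and lateral 3D-US models combined into one complete model,
#'    initialised by screw-fiducial registration into the CT frame;
#' 4. ICP refinement of the bone-only US submesh against the bone-only,
#'    already-registered SLS model, with the result applied to the complete
#'    US model.
#'
#' @param sls complete SLS mesh with bone/cartilage labels.
#' @param us_medial,us_lateral the two 3D-US surface models (labelled).
#' @param ct CT bone mesh.
#' @param us_fiducials,ct_fiducials screw-fiducial sets in US and CT frames.
#' @param sls_landmarks,ct_landmarks matched anatomical landmark sets.
#' @param params [icp_params()] used for both ICP stages.
#' @return A list with `sls_in_ct` and `us_in_ct` (complete registered
#'   meshes in the CT frame), `stages` (named list of
#'   `registration_result`s: `sls_landmark`, `sls_icp`, `us_fiducial`,
#'   `us_icp`), and `report`, a tibble of per-stage RMS errors including the
#'   US bone surface evaluated both against the registered SLS and directly
#'   against CT.
#' @export
three_way_register <- function(sls, us_medial, us_lateral, ct,
                               us_fiducials, ct_fiducials,
                               sls_landmarks, ct_landmarks,
                               params = icp_params()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("three_way_register stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  # (1) SLS -> CT landmark initialisation
  lm_fit <- stage("sls_landmark_init",
                  landmark_register(sls_landmarks, ct_landmarks))
  # (2) bone-only ICP, applied to the complete SLS model
  sls_bone <- stage("sls_bone_crop", crop_by_label(sls, "bone"))
  ct_target <- mesh_index(ct)
  sls_icp <- stage("sls_icp",
                   icp_register(sls_bone, ct_target, init = lm_fit$transform,
                                params = params))
  sls_in_ct <- apply_transform(sls, sls_icp$transform, frame = ct$frame)
  # (3) combine US sides; fiducial initialisation into CT frame
  us_full <- stage("us_combine", merge_meshes(us_medial, us_lateral))
  fid_fit <- stage("us_fiducial_init",
                   landmark_register(us_fiducials, ct_fiducials))
  # (4) bone-only ICP of US against the registered SLS (its bone submesh)
  us_bone <- stage("us_bone_crop", crop_by_label(us_full, "bone"))
  sls_reg_bone <- stage("sls_registered_bone_crop",
                        crop_by_label(sls_in_ct, "bone"))
  us_icp <- stage("us_icp",
                  icp_register(us_bone, sls_reg_bone, init = fid_fit$transform,
                               params = params))
  us_in_ct <- apply_transform(us_full, us_icp$transform, frame = ct$frame)

  # The US registration error is ambiguous between "against the registered
  # SLS" (the ICP objective here) and "against CT directly"; report both.
  us_bone_in_ct <- apply_transform(us_bone, us_icp$transform, frame = ct$frame)
  us_smp <- sample_surface(us_bone_in_ct, n = params$sample_count,
                           seed = params$seed)
  us_vs_ct_rms <- sqrt(mean(
    point_to_surface_distance(us_smp$points, ct_target)$distance^2))

  stages <- list(sls_landmark = lm_fit, sls_icp = sls_icp,
                 us_fiducial = fid_fit, us_icp = us_icp)
  report <- dplyr::bind_rows(
    tibble(stage = "sls_landmark", comparison = "SLS-CT landmarks",
           rms_error_mm = lm_fit$rms_error, iterations = lm_fit$iterations,
           converged = lm_fit$converged),
    tibble(stage = "sls_icp", comparison = "SLS-CT",
           rms_error_mm = sls_icp$rms_error, iterations = sls_icp$iterations,
           converged = sls_icp$converged),
    tibble(stage = "us_fiducial", comparison = "3DUS-CT fiducials",
           rms_error_mm = fid_fit$rms_error, iterations = fid_fit$iterations,
           converged = fid_fit$converged),
    tibble(stage = "us_icp", comparison = "3DUS-SLS(registered)",
           rms_error_mm = us_icp$rms_error, iterations = us_icp$iterations,
           converged = us_icp$converged),
    tibble(stage = "us_vs_ct", comparison = "3DUS-CT",
           rms_error_mm = us_vs_ct_rms, iterations = NA_integer_,
           converged = NA)
  )
  list(sls_in_ct = sls_in_ct, us_in_ct = us_in_ct, stages = stages,
       report = report)
}
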