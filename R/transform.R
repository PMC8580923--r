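#' Rigid transforms
#'
#' A rigid transform maps points of one coordinate frame into another as
#' `R %*% p + t`, with `R` a proper rotation (orthonormal, determinant +1 —
#' reflections are rejected) and `t` a translation in mm. These are the
#' outputs of both registration stages and the recorded true poses of the
#' modality simulators.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric translation (mm).
#' @return An object of class `rigid_transform`.
#' @examples
#' t1 <- rt_axis_angle(c(0, 0, 1), 90)
#' rt_apply(t1, c(1, 0, 0)) # ~ (0, 1, 0)
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) abort("`rotation` must be a 3x3 matrix.")
  if (length(translation) != 3L) abort("`translation` must have length 3.")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    abort("`rotation` is not orthonormal within 1e-9.")
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    abort("`rotation` must be a proper rotation (det +1); reflections are not rigid poses.")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' @rdname rigid_transform
#' @param axis rotation axis (length 3, need not be unit).
#' @param angle_deg rotation angle in degrees.
#' @export
rt_axis_angle <- function(axis, angle_deg, translation = c(0, 0, 0)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, translation)
}

#' @rdname rigid_transform
#' @param a,b `rigid_transform` objects; `rt_compose(a, b)` applies `b`
#'   first, then `a`.
#' @export
rt_compose <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @export
rt_invert <- function(a) {
  rigid_transform(t(a$rotation), as.numeric(-t(a$rotation) %*% a$translation))
}

#' @rdname rigid_transform
#' @param transform a `rigid_transform`.
#' @param points numeric matrix (n x 3) or length-3 vector.
#' @export
rt_apply <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  out <- p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to a mesh
#'
#' Every vertex `v` becomes `R v + t`; faces and labels are unchanged. The
#' typical use is carrying the refined bone-only registration over to the
#' complete (bone + cartilage) surface model.
#'
#' @param mesh an `osteo_mesh`.
#' @param transform a `rigid_transform`.
#' @param frame optional new frame name for the result (defaults to the
#'   input frame, i.e. the caller asserts the transform is frame-internal).
#' @return The transformed `osteo_mesh`.
#' @export
apply_transform <- function(mesh, transform, frame = mesh$frame) {
  if (!inherits(transform, "rigid_transform")) {
    abort("`transform` must be a rigid_transform.")
  }
  triangle_mesh(rt_apply(transform, mesh$vertices), mesh$faces,
                labels = mesh$labels, frame = frame, validate = FALSE)
}

#' Draw a random rigid pose
#'
#' Uniform random rotation axis, rotation angle uniform in
#' `[-max_angle_deg, max_angle_deg]`, translation components uniform in
#' `[-max_translation_mm, max_translation_mm]`. Bounded poses keep ICP inside
#' its convergence basin; larger displacements require the landmark stage.
#'
#' @param max_angle_deg largest rotation magnitude (degrees).
#' @param max_translation_mm largest per-axis translation (mm).
#' @param seed optional integer seed (the current RNG state is restored).
#' @return A `rigid_transform`.
#' @export
random_rigid_transform <- function(max_angle_deg = 10, max_translation_mm = 5,
                                   seed = NULL) {
  draw <- function() {
    ax <- rnorm(3)
    rt_axis_angle(ax, runif(1, -max_angle_deg, max_angle_deg),
                  runif(3, -max_translation_mm, max_translation_mm))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
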