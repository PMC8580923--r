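test_that("landmark registration recovers exact poses and validates input", {
  src <- fiducial_set(rbind(c(0, 0, 0), c(30, 0, 0), c(0, 25, 0), c(5, 5, 20)),
                      frame = "sls")
  # target = source -> identity, FRE 0
  fit0 <- landmark_register(src, src)
  expect_equal(fit0$transform$rotation, diag(3), tolerance = 1e-9)
  expect_lt(fit0$rms_error, 1e-9)

  # known pose, noiseless -> exact recovery
  pose <- rt_axis_angle(c(1, -2, 0.5), 40, c(12, -7, 3))
  tgt <- transform_fiducials(src, pose, frame = "ct")
  fit <- landmark_register(src, tgt)
  expect_lt(max(abs(fit$transform$rotation - pose$rotation)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - pose$translation)), 1e-9)
  expect_lt(fit$rms_error, 1e-9)

  # matching is by name, not order
  perm <- fiducial_set(fid_matrix <- as.matrix(tgt[c(3, 1, 4, 2), c("x", "y", "z")]),
                       names = tgt$name[c(3, 1, 4, 2)], frame = "ct")
  fit2 <- landmark_register(src, perm)
  expect_lt(fit2$rms_error, 1e-9)

  # name mismatch errors
  bad <- fiducial_set(as.matrix(tgt[, c("x", "y", "z")]),
                      names = c("a", "b", "c", "d"))
  expect_error(landmark_register(src, bad), "names do not match")
})

test_that("closed-form landmark fit attains the least-squares optimum", {
  # oracle 1: objective never beaten by random rigid transforms
  # oracle 2: objective matches a direct numerical minimisation
  obj <- function(R, tr, S, T_) mean(rowSums((S %*% t(R) +
    matrix(tr, nrow(S), 3, byrow = TRUE) - T_)^2))
  rot_from <- function(p) {
    th <- sqrt(sum(p^2))
    if (th < 1e-12) return(diag(3))
    rt_axis_angle(p / th, th * 180 / pi)$rotation
  }
  set.seed(11)
  fres <- numeric(0)
  opt_fres <- numeric(0)
  for (s in 1:25) {
    S <- matrix(rnorm(12, sd = 10), 4, 3)
    if (svd(scale(S, scale = FALSE))$d[2] < 1) next
    T_ <- rt_apply(random_rigid_transform(20, 10), S) +
      matrix(rnorm(12, sd = 0.2), 4, 3)
    fit <- landmark_register(fiducial_set(S), fiducial_set(T_))
    f_closed <- obj(fit$transform$rotation, fit$transform$translation, S, T_)
    # random-transform lower-bound check
    for (k in 1:200) {
      rnd <- random_rigid_transform(180, 20)
      expect_gte(obj(rnd$rotation, rnd$translation, S, T_), f_closed - 1e-12)
    }
    # numerical optimiser over axis-angle + translation
    opt <- optim(rep(0, 6), function(p)
      obj(rot_from(p[1:3]), p[4:6], S, T_), method = "BFGS",
      control = list(maxit = 500, reltol = 1e-14))
    expect_lte(f_closed, opt$value + 1e-8)
    fres <- c(fres, sqrt(f_closed))
    opt_fres <- c(opt_fres, sqrt(opt$value))
  }
  # mean FRE within 10% of the numerical-optimiser oracle
  expect_lt(abs(mean(fres) - mean(opt_fres)) / mean(opt_fres), 0.1)
})

test_that("returned rotations are proper even for near-planar fiducials", {
  set.seed(5)
  for (i in 1:20) {
    S <- cbind(matrix(rnorm(8, sd = 10), 4, 2), rnorm(4, sd = 1e-4))
    T_ <- S[, c(2, 1, 3)] # a reflection-like correspondence
    fit <- landmark_register(fiducial_set(S), fiducial_set(T_))
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  }
})

test_that("ICP converges to zero error on identical meshes", {
  m <- test_phantom()$bone_surface
  fit <- icp_register(m, m, params = icp_params(seed = 2))
  expect_true(fit$converged)
  expect_lt(fit$rms_error, 1e-9)
})

test_that("ICP recovers a known pose within the capture basin", {
  ph <- test_phantom()
  bone <- ph$bone_surface
  idx <- mesh_index(bone)
  for (s in 1:5) {
    pose <- random_rigid_transform(10, 5, seed = 100 + s)
    src <- apply_transform(bone, pose)
    fit <- icp_register(src, idx,
                        params = icp_params(seed = s,
                                            convergence_tol_mm = 1e-6))
    # composed recovered transform must undo the pose vertex-wise
    sub <- src$vertices[seq(1, nrow(src$vertices), by = 23), ]
    back <- rt_apply(fit$transform, sub)
    truth <- rt_apply(rt_invert(pose), sub)
    expect_lt(max(sqrt(rowSums((back - truth)^2))), 0.01)
  }
})

test_that("ICP error settles at the noise floor under vertex noise", {
  mesh <- sphere_mesh(radius = 20, level = 5, frame = "a")
  sigma <- 0.1
  set.seed(31)
  rmss <- vapply(1:6, function(i) {
    tgt <- triangle_mesh(
      mesh$vertices + matrix(rnorm(length(mesh$vertices), sd = sigma), ncol = 3),
      mesh$faces, frame = "a")
    icp_register(mesh, tgt, params = icp_params(seed = i))$rms_error
  }, numeric(1))
  expect_gt(mean(rmss), 0.5 * sigma)
  expect_lt(mean(rmss), 1.5 * sigma)
})

test_that("accepted-correspondence RMS is non-increasing across iterations", {
  mesh <- sphere_mesh(radius = 15, level = 4, frame = "a")
  set.seed(13)
  for (s in 1:3) {
    tgt <- triangle_mesh(
      mesh$vertices + matrix(rnorm(length(mesh$vertices), sd = 0.08), ncol = 3),
      mesh$faces, frame = "a")
    src <- apply_transform(mesh, random_rigid_transform(8, 4, seed = s))
    h <- icp_register(src, tgt, params = icp_params(seed = s))$rms_history
    expect_gt(length(h), 1)
    expect_true(all(diff(h) <= 1e-9))
  }
})

test_that("ICP rejects degenerate correspondence configurations", {
  m <- tetra_mesh()
  expect_error(icp_register(m, m, params = icp_params(sample_count = 2)),
               "Degenerate")
})
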