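# Independent oracles and shared fixtures, built in code.

# Brute-force point-to-mesh distance, by a different route than the package
# kernel: per triangle, min of (plane projection if the foot lies inside,
# else the three edge-segment distances).
brute_force_distance <- function(p, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  seg <- function(p0, p1) {
    d <- p1 - p0
    t <- rowSums(d * sweep(-p0, 2, p, "+")) / rowSums(d * d)
    t <- pmin(1, pmax(0, t))
    q <- p0 + d * t
    sqrt(rowSums(sweep(-q, 2, p, "+")^2))
  }
  n <- cbind(
    (b[, 2] - a[, 2]) * (c_[, 3] - a[, 3]) - (b[, 3] - a[, 3]) * (c_[, 2] - a[, 2]),
    (b[, 3] - a[, 3]) * (c_[, 1] - a[, 1]) - (b[, 1] - a[, 1]) * (c_[, 3] - a[, 3]),
    (b[, 1] - a[, 1]) * (c_[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c_[, 1] - a[, 1])
  )
  n <- n / sqrt(rowSums(n^2))
  h <- rowSums(sweep(-a, 2, p, "+") * n)
  qq <- sweep(-n * h, 2, p, "+")
  v0 <- b - a; v1 <- c_ - a; v2 <- qq - a
  d00 <- rowSums(v0 * v0); d01 <- rowSums(v0 * v1); d11 <- rowSums(v1 * v1)
  d20 <- rowSums(v2 * v0); d21 <- rowSums(v2 * v1)
  den <- d00 * d11 - d01 * d01
  u <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  inside <- u >= -1e-12 & w >= -1e-12 & (u + w) <= 1 + 1e-12
  min(pmin(ifelse(inside, abs(h), Inf), seg(a, b), seg(b, c_), seg(a, c_)))
}

# regular-ish tetrahedron mesh
tetra_mesh <- function() {
  triangle_mesh(
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  )
}

# sphere mesh of a given radius (icosphere subdivision)
sphere_mesh <- function(radius = 10, level = 3, frame = "unspecified") {
  sph <- osteorms:::icosphere(level)
  triangle_mesh(sph$vertices * radius, sph$faces, frame = frame)
}

# planar patch z = 0 over [0,1]^2, regular grid triangulation
plane_mesh <- function(n = 20, frame = "unspecified", z = function(x, y) 0 * x) {
  g <- seq(0, 1, length.out = n + 1)
  xy <- expand.grid(x = g, y = g)
  v <- cbind(xy$x, xy$y, z(xy$x, xy$y))
  id <- function(i, j) (j - 1) * (n + 1) + i
  fl <- list()
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      fl[[length(fl) + 1]] <- c(id(i, j), id(i + 1, j), id(i, j + 1))
      fl[[length(fl) + 1]] <- c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1))
    }
  }
  triangle_mesh(v, do.call(rbind, fl), frame = frame)
}

# small reduced-scale phantom shared across test files (cached per session)
local_phantom_cache <- new.env(parent = emptyenv())
test_phantom <- function(key = "default", ...) {
  if (is.null(local_phantom_cache[[key]])) {
    local_phantom_cache[[key]] <- make_phantom(phantom_spec(mesh_edge_mm = 0.8, ...))
  }
  local_phantom_cache[[key]]
}
test_modality_params <- function(...) {
  modality_params(sls = list(resolution_mm = 0.5), ...)
}
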