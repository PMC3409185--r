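#' Spherical head model
#'
#' Single-sphere conductor model used both for forward simulation and for
#' beamforming. For MEG a homogeneous sphere is an exact conductor model:
#' the external magnetic field is given in closed form (Sarvas) and is blind
#' to radial dipole components and to the conductivity profile.
#'
#' The default sphere is centered at MNI (0, -18, 15) mm with a 95 mm radius
#' so that the posterior cortical sites used in face-processing work
#' (lateral occipital, occipital pole, fusiform) are interior points.
#'
#' @param center_mm Sphere center, MNI mm (RAS axes), length-3 numeric.
#' @param radius_mm Sphere radius in mm, > 0.
#' @return An object of class `head_model`.
#' @export
head_model <- function(center_mm = c(0, -18, 15), radius_mm = 95) {
  stopifnot(is.numeric(center_mm), length(center_mm) == 3, all(is.finite(center_mm)))
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || radius_mm <= 0)
    stop("head_model: radius_mm must be a positive scalar")
  structure(list(center = as.numeric(center_mm), radius = as.numeric(radius_mm)),
            class = "head_model")
}

#' Quasi-uniform magnetometer array on an upper-hemisphere shell
#'
#' Places `n_sensors` point magnetometers on the upper hemisphere of a shell
#' concentric with the head sphere using a deterministic Fibonacci layout,
#' with coil normals pointing radially inward (toward the sphere center).
#' Optional seed-driven angular jitter perturbs the layout reproducibly.
#'
#' @param n_sensors Number of sensors (>= 8). Default 248, a whole-head
#'   magnetometer count.
#' @param shell_radius_mm Shell radius in mm; must exceed the head radius.
#' @param head A [head_model()].
#' @param jitter_deg SD of angular jitter in degrees (0 = none).
#' @param seed Integer seed for the jitter; ignored when `jitter_deg == 0`.
#' @return An object of class `sensor_array` with fields `positions`
#'   (n x 3 mm, absolute MNI coordinates), `orientations` (n x 3 unit
#'   vectors), `names`.
#' @export
build_sensor_array <- function(n_sensors = 248, shell_radius_mm = 120,
                               head = head_model(), jitter_deg = 0, seed = NULL) {
  if (n_sensors < 8) stop("build_sensor_array: n_sensors must be >= 8")
  if (shell_radius_mm <= head$radius)
    stop("build_sensor_array: sensor shell (", shell_radius_mm,
         " mm) must lie outside the head sphere (radius ", head$radius, " mm)")
  i <- seq_len(n_sensors) - 0.5
  golden <- pi * (3 - sqrt(5))
  # upper hemisphere: z = cos(theta) in (0, 1]
  z <- 1 - i / n_sensors            # in (0, 1)
  theta <- acos(z)
  phi <- golden * (seq_len(n_sensors) - 1)
  if (jitter_deg > 0) {
    jit <- withr::with_seed(if (is.null(seed)) 0L else seed, {
      matrix(stats::rnorm(2 * n_sensors, sd = jitter_deg * pi / 180), ncol = 2)
    })
    theta <- pmin(pmax(theta + jit[, 1], 0), pi / 2)
    phi <- phi + jit[, 2]
  }
  u <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  positions <- sweep(u * shell_radius_mm, 2, head$center, "+")
  orientations <- -u  # radially inward unit normals
  structure(list(positions = positions,
                 orientations = orientations,
                 names = sprintf("MEG%03d", seq_len(n_sensors))),
            class = "sensor_array")
}

#' Isotropic source grid inside the head sphere
#'
#' Axis-aligned lattice in MNI mm, with lattice nodes at integer multiples of
#' `spacing` so the grid is identical across subjects (each subject's grid is
#' obtained later by warping this one with their affine). Points within
#' `margin` of the sphere surface and within `center_exclusion` of the center
#' are dropped: superficial lead fields are distorted by the surface, and
#' near-center lead fields are near-zero and destabilize beamformer weights.
#' Ordering is lexicographic in (x, y, z) ascending.
#'
#' @param spacing Grid spacing in mm (> 0). Default 5.
#' @param head A [head_model()].
#' @param margin Minimum distance to the sphere surface, mm (>= 0).
#' @param center_exclusion Minimum distance to the sphere center, mm.
#' @return An object of class `source_grid` with fields `points` (n x 3 mm),
#'   `spacing`, `head`.
#' @export
build_source_grid <- function(spacing = 5, head = head_model(), margin = 5,
                              center_exclusion = 20) {
  if (spacing <= 0) stop("build_source_grid: spacing must be > 0")
  if (margin < 0) stop("build_source_grid: margin must be >= 0")
  r_max <- head$radius - margin
  if (r_max <= 0) stop("build_source_grid: empty grid (margin >= radius)")
  ax <- function(c0) seq(ceiling((c0 - r_max) / spacing),
                         floor((c0 + r_max) / spacing)) * spacing
  xs <- ax(head$center[1]); ys <- ax(head$center[2]); zs <- ax(head$center[3])
  if (!length(xs) || !length(ys) || !length(zs))
    stop("build_source_grid: empty grid (spacing too coarse for this sphere)")
  pts <- as.matrix(expand.grid(z = zs, y = ys, x = xs))[, 3:1, drop = FALSE]
  colnames(pts) <- c("x", "y", "z")
  d <- sqrt(rowSums(sweep(pts, 2, head$center)^2))
  keep <- d <= r_max & d >= center_exclusion
  if (!any(keep)) stop("build_source_grid: empty grid after exclusion rules")
  pts <- pts[keep, , drop = FALSE]
  pts <- pts[order(pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]
  structure(list(points = pts, spacing = spacing, head = head),
            class = "source_grid")
}

#' Restrict a grid to an axis-aligned region of interest
#'
#' @param grid A `source_grid`.
#' @param lower,upper Length-3 numeric bounds in mm (inclusive).
#' @return A `source_grid` containing only points inside the box.
#' @export
crop_grid <- function(grid, lower, upper) {
  stopifnot(inherits(grid, "source_grid"), length(lower) == 3, length(upper) == 3)
  p <- grid$points
  keep <- p[, 1] >= lower[1] & p[, 1] <= upper[1] &
          p[, 2] >= lower[2] & p[, 2] <= upper[2] &
          p[, 3] >= lower[3] & p[, 3] <= upper[3]
  if (!any(keep)) stop("crop_grid: no grid points inside the box")
  out <- grid
  out$points <- p[keep, , drop = FALSE]
  out
}

#' Apply an affine transform to grid points
#'
#' Maps every grid point through a 4x4 affine in homogeneous coordinates
#' (e.g. the MNI-to-subject transform). Point count and ordering are
#' preserved, which keeps maps comparable across subjects.
#'
#' @param grid A `source_grid`.
#' @param affine 4x4 invertible matrix (last row c(0,0,0,1)).
#' @return A `source_grid` in the target space. The `head` field is carried
#'   over unchanged (the subject sphere is assumed rigidly close to MNI).
#' @export
warp_grid <- function(grid, affine) {
  stopifnot(inherits(grid, "source_grid"))
  affine <- .check_affine(affine)
  n <- nrow(grid$points)
  ph <- cbind(grid$points, 1) %*% t(affine)
  out <- grid
  out$points <- ph[, 1:3, drop = FALSE]
  colnames(out$points) <- c("x", "y", "z")
  stopifnot(nrow(out$points) == n)
  out
}

.check_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  affine
}

#' Map a single point through an affine
#' @param point_mm Length-3 coordinate, mm.
#' @param affine 4x4 matrix.
#' @return Length-3 transformed coordinate.
#' @export
warp_point <- function(point_mm, affine) {
  affine <- .check_affine(affine)
  as.numeric((affine %*% c(point_mm, 1))[1:3])
}

# Orthonormal tangential basis at a source location (relative to the sphere
# center). Radial dipoles are magnetically silent in a sphere, so only these
# two directions are used.
.tangential_basis <- function(pos, center, center_exclusion = 1e-6) {
  u <- pos - center
  nu <- sqrt(sum(u^2))
  if (nu < center_exclusion)
    stop("tangential basis undefined at the sphere center")
  u <- u / nu
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- .cross3(ref, u); t1 <- t1 / sqrt(sum(t1^2))
  t2 <- .cross3(u, t1)
  cbind(t1, t2)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Sarvas closed-form field of a current dipole in a homogeneous sphere,
# evaluated at all sensors and projected onto the coil normals.
# pos, sensors in mm; moment q in nA*m; output in tesla.
.sarvas_field <- function(pos_mm, q_nAm, sensors, head) {
  mu0_4pi <- 1e-7
  r0 <- (pos_mm - head$center) * 1e-3                    # m, relative to center
  R <- sweep(sensors$positions, 2, head$center) * 1e-3   # N x 3, m
  q <- q_nAm * 1e-9                                      # A*m
  a_vec <- sweep(R, 2, r0)                               # R - r0
  a <- sqrt(rowSums(a_vec^2))
  r <- sqrt(rowSums(R^2))
  ar <- rowSums(sweep(R, 2, r0, function(x, y) x * y))   # R . r0 per sensor
  adotR <- rowSums(a_vec * R)                            # (R - r0) . R
  F_ <- a * (r * a + r^2 - ar)
  cF1 <- a^2 / r + adotR / a + 2 * a + 2 * r
  cF2 <- a + 2 * r + adotR / a
  gradF <- R * cF1 - matrix(r0, nrow(R), 3, byrow = TRUE) * cF2
  qxr0 <- .cross3(q, r0)
  B <- (matrix(qxr0, nrow(R), 3, byrow = TRUE) * F_ -
          gradF * as.numeric(R %*% qxr0)) * (mu0_4pi / F_^2)
  rowSums(B * sensors$orientations)
}

#' Lead field at one source location
#'
#' Analytic spherical-conductor (Sarvas) field of unit current dipoles along
#' the two tangential basis directions at `pos_mm`, projected onto the
#' sensor normals. Units: tesla per nA·m.
#'
#' @param pos_mm Source location, mm (same frame as the sensors/head).
#' @param sensors A `sensor_array`.
#' @param head A `head_model`.
#' @param center_exclusion Reject points closer than this to the sphere
#'   center (mm), where the tangential basis and the field degenerate.
#' @return List with `L` (n_sensors x 2 matrix) and `basis` (3 x 2 matrix of
#'   the tangential directions).
#' @export
lead_field_point <- function(pos_mm, sensors, head, center_exclusion = 1e-3) {
  pos_mm <- as.numeric(pos_mm)
  d <- sqrt(sum((pos_mm - head$center)^2))
  if (d < center_exclusion)
    stop("lead_field_point: source inside the center exclusion zone")
  if (d >= head$radius)
    stop("lead_field_point: source outside the head sphere")
  basis <- .tangential_basis(pos_mm, head$center)
  L <- cbind(.sarvas_field(pos_mm, basis[, 1], sensors, head),
             .sarvas_field(pos_mm, basis[, 2], sensors, head))
  list(L = L, basis = basis)
}

#' Lead fields for every grid point
#'
#' @param grid A `source_grid` (subject space if warped).
#' @param sensors A `sensor_array`.
#' @param head A `head_model`.
#' @return An object of class `lead_field`: `L` is an array
#'   (n_sensors x 2 x n_points) in tesla per nA·m, `basis` (3 x 2 x n_points),
#'   plus the grid and sensor geometry used.
#' @export
lead_field_matrix <- function(grid, sensors, head = grid$head) {
  p <- grid$points
  n_pts <- nrow(p)
  n_ch <- nrow(sensors$positions)
  L <- array(NA_real_, c(n_ch, 2, n_pts))
  basis <- array(NA_real_, c(3, 2, n_pts))
  valid <- rep(TRUE, n_pts)
  for (i in seq_len(n_pts)) {
    lf <- tryCatch(lead_field_point(p[i, ], sensors, head),
                   error = function(e) NULL)
    if (is.null(lf)) { valid[i] <- FALSE; next }  # outside sphere after warp
    L[, , i] <- lf$L
    basis[, , i] <- lf$basis
  }
  if (!any(valid)) stop("lead_field_matrix: no valid grid points")
  structure(list(L = L, basis = basis, valid = valid, grid = grid,
                 sensors = sensors, head = head), class = "lead_field")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat("<sensor_array> ", nrow(x$positions), " magnetometers, radial normals\n",
      sep = "")
  invisible(x)
}

#' @export
print.source_grid <- function(x, ...) {
  cat("<source_grid> ", nrow(x$points), " points, ", x$spacing,
      " mm spacing\n", sep = "")
  invisible(x)
}
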