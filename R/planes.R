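#' @useDynLib mprreg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rnorm median sd setNames
NULL

# ---- small vector helpers (internal) ----------------------------------------

vnorm <- function(x) sqrt(sum(x * x))

unitize <- function(x, tol = 1e-12) {
  n <- vnorm(x)
  if (n < tol) stop("cannot normalize a near-zero vector")
  x / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Standard MPR plane
#'
#' A standard (multiplanar-reconstruction) plane is parameterized by its
#' center position \eqn{A} in millimeters and two orthonormal in-plane unit
#' vectors \eqn{e_u} (row direction) and \eqn{e_v} (column direction). The
#' plane normal \eqn{e_w = e_u \times e_v} is always derived, never stored,
#' so orthonormality cannot drift silently.
#'
#' @param name one of \code{"axial"}, \code{"coronal"}, \code{"semicoronal"},
#'   \code{"sagittal"}.
#' @param center numeric length-3, plane center in mm (volume coordinate
#'   system: right-handed, origin at the volume center, axes parallel to the
#'   voxel axes).
#' @param e_u,e_v numeric length-3 unit vectors spanning the plane.
#' @param tol orthonormality tolerance.
#' @return an object of class \code{standard_plane}.
#' @export
standard_plane <- function(name, center, e_u, e_v, tol = 1e-9) {
  name <- match.arg(name, c("axial", "coronal", "semicoronal", "sagittal"))
  center <- as.numeric(center); e_u <- as.numeric(e_u); e_v <- as.numeric(e_v)
  stopifnot(length(center) == 3L, length(e_u) == 3L, length(e_v) == 3L)
  if (abs(vnorm(e_u) - 1) > tol || abs(vnorm(e_v) - 1) > tol)
    stop("e_u and e_v must be unit vectors (tol ", tol, ")")
  if (abs(sum(e_u * e_v)) > tol)
    stop("e_u and e_v must be orthogonal (tol ", tol, ")")
  structure(list(name = name, center = center, e_u = e_u, e_v = e_v),
            class = "standard_plane")
}

#' Plane normal
#'
#' The derived normal \eqn{e_w = e_u \times e_v} of a standard plane.
#' @param plane a \code{standard_plane}.
#' @return unit length-3 numeric.
#' @export
plane_normal <- function(plane) {
  unitize(cross3(plane$e_u, plane$e_v))
}

#' @export
print.standard_plane <- function(x, ...) {
  cat(sprintf("<standard_plane %s>\n  center: [%s] mm\n  e_u: [%s]\n  e_v: [%s]\n",
              x$name,
              paste(signif(x$center, 6), collapse = ", "),
              paste(signif(x$e_u, 6), collapse = ", "),
              paste(signif(x$e_v, 6), collapse = ", ")))
  invisible(x)
}

#' Point on a plane
#'
#' Evaluates the parametric plane equation
#' \eqn{P_{\lambda,\mu} = A + \lambda e_u + \mu e_v}.
#'
#' @param plane a \code{standard_plane}.
#' @param lam,mu in-plane coordinates (mm).
#' @return length-3 numeric, mm.
#' @export
plane_point <- function(plane, lam, mu) {
  plane$center + lam * plane$e_u + mu * plane$e_v
}

#' Ordered triplet of standard planes for one body region
#'
#' Regions with orthogonal standard planes (ankle, knee, wrist) carry
#' \code{axial}, \code{coronal}, \code{sagittal}; the calcaneus replaces the
#' coronal by the oblique \code{semicoronal} plane.
#'
#' @param region one of \code{"calcaneus"}, \code{"ankle"}, \code{"knee"},
#'   \code{"wrist"}.
#' @param planes list of three \code{standard_plane}s in the fixed order
#'   axial, (semi)coronal, sagittal.
#' @return an object of class \code{plane_triplet}.
#' @export
plane_triplet <- function(region, planes) {
  region <- match.arg(region, c("calcaneus", "ankle", "knee", "wrist"))
  stopifnot(is.list(planes), length(planes) == 3L)
  if (!all(vapply(planes, inherits, logical(1), "standard_plane")))
    stop("planes must be standard_plane objects")
  expected <- c("axial", if (region == "calcaneus") "semicoronal" else "coronal",
                "sagittal")
  got <- vapply(planes, `[[`, character(1), "name")
  if (!identical(got, expected))
    stop("plane order/names for region '", region, "' must be ",
         paste(expected, collapse = ", "), " but got ",
         paste(got, collapse = ", "))
  structure(list(region = region, planes = planes), class = "plane_triplet")
}

#' @export
print.plane_triplet <- function(x, ...) {
  cat(sprintf("<plane_triplet %s: %s>\n", x$region,
              paste(vapply(x$planes, `[[`, character(1), "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Rigid (proper) homogeneous transform
#'
#' A 4x4 homogeneous matrix whose upper-left 3x3 block is a proper rotation
#' and whose bottom row is (0,0,0,1).
#'
#' @param matrix 4x4 numeric matrix.
#' @param tol orthonormality tolerance.
#' @return an object of class \code{rigid_transform}.
#' @export
rigid_transform <- function(matrix, tol = 1e-9) {
  matrix <- as.matrix(matrix)
  stopifnot(identical(dim(matrix), c(4L, 4L)))
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > tol)
    stop("bottom row must be [0,0,0,1]")
  R <- matrix[1:3, 1:3]
  if (max(abs(crossprod(R) - diag(3))) > tol)
    stop("rotation block is not orthonormal")
  if (det(R) < 0)
    stop("rotation block has negative determinant (reflection rejected)")
  structure(list(matrix = matrix), class = "rigid_transform")
}

#' Compose a rigid transform from a rotation and a translation
#' @param R 3x3 proper rotation matrix.
#' @param t length-3 translation, mm.
#' @return a \code{rigid_transform}.
#' @export
rigid_from_rt <- function(R, t = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  rigid_transform(m)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n")
  print(signif(x$matrix, 6))
  invisible(x)
}

#' Homogeneous transform of a plane
#'
#' Builds the homogeneous transform \eqn{T} from the plane coordinate system
#' to the volume coordinate system: rotation columns
#' \eqn{[e_u\; e_v\; e_w]}, translation \eqn{A}. Applying \eqn{T} to
#' \eqn{(\lambda, \mu, 0, 1)^\top} yields \code{\link{plane_point}}.
#'
#' @param plane a \code{standard_plane}.
#' @return a \code{rigid_transform}.
#' @export
plane_to_transform <- function(plane) {
  R <- cbind(plane$e_u, plane$e_v, plane_normal(plane))
  rigid_from_rt(R, plane$center)
}

#' Plane from a homogeneous transform
#'
#' Inverse of \code{\link{plane_to_transform}}: reads \eqn{e_u, e_v} from the
#' first two rotation columns and the center from the translation.
#'
#' @param transform a \code{rigid_transform} (rejects improper rotations).
#' @param name plane name for the result.
#' @return a \code{standard_plane}.
#' @export
transform_to_plane <- function(transform, name = "axial") {
  m <- transform$matrix
  standard_plane(name, m[1:3, 4], m[1:3, 1], m[1:3, 2])
}

#' Apply a rigid transform to every plane of a triplet
#'
#' Centers are mapped by the full transform, directions by its rotation
#' block; orthonormality is preserved exactly.
#'
#' @param triplet a \code{plane_triplet}.
#' @param transform a \code{rigid_transform}.
#' @return the mapped \code{plane_triplet}.
#' @export
apply_rigid_to_triplet <- function(triplet, transform) {
  m <- transform$matrix
  R <- m[1:3, 1:3]; t <- m[1:3, 4]
  planes <- lapply(triplet$planes, function(p) {
    standard_plane(p$name,
                   as.numeric(R %*% p$center + t),
                   unitize(as.numeric(R %*% p$e_u)),
                   unitize(as.numeric(R %*% p$e_v)))
  })
  plane_triplet(triplet$region, planes)
}

#' Volume geometry
#'
#' Shape (voxels), isotropic or anisotropic spacing (mm/voxel) and the fixed
#' coordinate convention: right-handed axes parallel to the voxel axes,
#' millimeters, origin at the geometric center of the volume. Voxel index
#' \code{i} (0-based) maps to physical coordinate
#' \code{(i - (shape-1)/2) * spacing} along each axis.
#'
#' @param shape integer length-3, voxels per axis.
#' @param spacing numeric length-3 (or scalar), mm per voxel.
#' @return an object of class \code{volume_geometry}.
#' @export
volume_geometry <- function(shape, spacing) {
  shape <- as.integer(shape)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape > 0L),
            length(spacing) == 3L, all(spacing > 0))
  structure(list(shape = shape, spacing = spacing,
                 extent = shape * spacing),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry %s voxels @ [%s] mm, extent [%s] mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 6), collapse = ", "),
              paste(signif(x$extent, 6), collapse = ", ")))
  invisible(x)
}

#' Normalize a center position to the volume's half extent
#'
#' Maps millimeter coordinates (origin at the volume center) to the bounded
#' range used as network target: each component is divided by half the
#' physical extent, so centers inside the volume land in [-1, 1]. Values are
#' deliberately not clamped: augmented planes may legitimately leave the
#' volume and the loss should see that (a warning is emitted).
#'
#' @param center length-3 numeric, mm.
#' @param geom a \code{volume_geometry}.
#' @return length-3 numeric.
#' @export
normalize_translation <- function(center, geom) {
  out <- as.numeric(center) / (geom$extent / 2)
  if (any(abs(out) > 1))
    warning("center lies outside the physical volume extent")
  out
}

#' @rdname normalize_translation
#' @param v normalized length-3 numeric.
#' @export
denormalize_translation <- function(v, geom) {
  as.numeric(v) * (geom$extent / 2)
}
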