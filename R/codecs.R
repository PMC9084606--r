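# Rotation codecs: bidirectional maps between a proper 3x3 rotation matrix
# and a bounded parameter vector. Four variants: Euler sine/cosine (6),
# unit quaternion (4), and the two 6D Gram-Schmidt variants (6 each).
# For exact rotations every encoding lies in [-1, 1] componentwise; decode
# always returns a proper rotation for any reasonable network output.

#' Rotation codec descriptor
#'
#' @param kind one of \code{"euler_sincos"}, \code{"quaternion"},
#'   \code{"six_d_xy"}, \code{"six_d_xz"}.
#' @return an object of class \code{rotation_codec} with fields \code{kind}
#'   and \code{n_params} (6, 4, 6, 6 respectively).
#' @export
rotation_codec <- function(kind = c("six_d_xy", "six_d_xz", "euler_sincos",
                                    "quaternion")) {
  kind <- match.arg(kind)
  n <- switch(kind, euler_sincos = 6L, quaternion = 4L,
              six_d_xy = 6L, six_d_xz = 6L)
  structure(list(kind = kind, n_params = n), class = "rotation_codec")
}

#' @export
print.rotation_codec <- function(x, ...) {
  cat(sprintf("<rotation_codec %s, %d parameters>\n", x$kind, x$n_params))
  invisible(x)
}

#' Encode / decode a rotation with a codec
#'
#' Dispatches to the codec-specific functions.
#' @param codec a \code{\link{rotation_codec}}.
#' @param R 3x3 proper rotation matrix.
#' @param v numeric parameter vector of length \code{codec$n_params}.
#' @return \code{encode_rotation}: numeric vector; \code{decode_rotation}:
#'   3x3 rotation matrix.
#' @export
encode_rotation <- function(codec, R) {
  switch(codec$kind,
         euler_sincos = encode_euler_sincos(R),
         quaternion   = encode_quaternion(R),
         six_d_xy     = encode_six_d(R, "xy"),
         six_d_xz     = encode_six_d(R, "xz"))
}

#' @rdname encode_rotation
#' @export
decode_rotation <- function(codec, v) {
  if (length(v) != codec$n_params)
    stop("expected ", codec$n_params, " parameters, got ", length(v))
  switch(codec$kind,
         euler_sincos = decode_euler_sincos(v),
         quaternion   = decode_quaternion(v),
         six_d_xy     = decode_six_d(v, "xy"),
         six_d_xz     = decode_six_d(v, "xz"))
}

# ---- Euler sine/cosine ------------------------------------------------------

# Convention: intrinsic Z-Y-X (yaw alpha about z, pitch beta about y, roll
# gamma about x), R = Rz(alpha) %*% Ry(beta) %*% Rx(gamma). Any fixed
# convention satisfies the round-trip contract; this one is isolated here.

rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a),
                              0, 1, 0,
                              sin(a), 0, cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0,
                              -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)

euler_zyx_from_matrix <- function(R) {
  # R = Rz(a) Ry(b) Rx(g); R[3,1] = -sin(b)
  sb <- -R[3, 1]
  sb <- max(-1, min(1, sb))
  b <- asin(sb)
  if (abs(sb) < 1 - 1e-12) {
    a <- atan2(R[2, 1], R[1, 1])
    g <- atan2(R[3, 2], R[3, 3])
  } else {
    # gimbal lock: split is not unique; put everything into alpha
    a <- atan2(-R[1, 2], R[2, 2])
    g <- 0
  }
  c(a, b, g)
}

#' Euler sine/cosine codec
#'
#' Instead of regressing raw angles (discontinuous at the wrap-around), the
#' sine and cosine of each of the three intrinsic Z-Y-X Euler angles are
#' regressed; decoding uses \code{atan2(sin, cos)}, which is scale invariant
#' in its two arguments, so unnormalized network outputs are fine. A (0,0)
#' pair decodes to angle 0 by convention.
#'
#' @param R 3x3 proper rotation.
#' @return length-6 numeric: \code{(sin a, cos a, sin b, cos b, sin g, cos g)}.
#' @export
encode_euler_sincos <- function(R) {
  ang <- euler_zyx_from_matrix(R)
  as.numeric(rbind(sin(ang), cos(ang)))
}

#' @rdname encode_euler_sincos
#' @param v length-6 numeric (unconstrained network output).
#' @export
decode_euler_sincos <- function(v) {
  stopifnot(length(v) == 6L)
  ang <- vapply(1:3, function(i) {
    s <- v[2 * i - 1]; co <- v[2 * i]
    if (s == 0 && co == 0) 0 else atan2(s, co)
  }, numeric(1))
  rot_z(ang[1]) %*% rot_y(ang[2]) %*% rot_x(ang[3])
}

# ---- quaternion -------------------------------------------------------------

#' Unit quaternion codec
#'
#' Encoding returns the unit quaternion \code{(w, x, y, z)} with canonical
#' sign (scalar part nonnegative; a tie at w = 0 is broken by the first
#' nonzero component being positive) to remove the q/-q double cover from the
#' regression target. Decoding normalizes first, so arbitrary nonzero network
#' outputs map to proper rotations.
#'
#' @param R 3x3 proper rotation.
#' @return length-4 numeric unit quaternion.
#' @export
encode_quaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s,
           0.25 * s,
           (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s,
           (R[1, 2] + R[2, 1]) / s,
           0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s,
           (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s,
           0.25 * s)
  }
  q <- q / vnorm(q)
  canonical_quaternion_sign(q)
}

canonical_quaternion_sign <- function(q) {
  if (q[1] < 0) return(-q)
  if (q[1] > 0) return(q)
  nz <- which(q != 0)
  if (length(nz) && q[nz[1]] < 0) -q else q
}

#' @rdname encode_quaternion
#' @param v length-4 numeric with \code{||v|| > 1e-8}.
#' @export
decode_quaternion <- function(v) {
  stopifnot(length(v) == 4L)
  n <- vnorm(v)
  if (n < 1e-8) stop("near-zero quaternion: rotation undefined")
  q <- v / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# ---- 6D Gram-Schmidt --------------------------------------------------------

#' 6D rotation codec (two matrix columns, Gram-Schmidt decode)
#'
#' The \code{xy} variant regresses rotation columns 1 and 2 (\eqn{e_u},
#' \eqn{e_v}); the \code{xz} variant regresses columns 1 and 3 (\eqn{e_u} and
#' the plane normal \eqn{e_w}). Decoding normalizes the first vector,
#' orthogonalizes the second against it (Gram-Schmidt), and fills in the
#' missing column by a cross product ordered so the determinant is +1:
#' for \code{xy}, columns \code{[a, b, a x b]}; for \code{xz}, columns
#' \code{[a, b x a, b]}.
#'
#' @param R 3x3 proper rotation.
#' @param variant \code{"xy"} or \code{"xz"}.
#' @return length-6 numeric.
#' @export
encode_six_d <- function(R, variant = c("xy", "xz")) {
  variant <- match.arg(variant)
  cols <- if (variant == "xy") c(1L, 2L) else c(1L, 3L)
  as.numeric(R[, cols])
}

#' @rdname encode_six_d
#' @param v length-6 numeric; the two halves must be away from zero and not
#'   near parallel (degeneracy threshold 1e-8).
#' @export
decode_six_d <- function(v, variant = c("xy", "xz")) {
  variant <- match.arg(variant)
  stopifnot(length(v) == 6L)
  a <- v[1:3]; b <- v[4:6]
  if (vnorm(a) < 1e-8 || vnorm(b) < 1e-8)
    stop("degenerate 6D input: near-zero column")
  a <- a / vnorm(a)
  bh <- b / vnorm(b)
  if (abs(sum(a * bh)) > 1 - 1e-8)
    stop("degenerate 6D input: columns near parallel")
  b <- unitize(b - sum(b * a) * a)
  if (variant == "xy") cbind(a, b, cross3(a, b), deparse.level = 0)
  else cbind(a, cross3(b, a), b, deparse.level = 0)
}

# ---- parameter vector -------------------------------------------------------

#' Network parameter vector for a plane triplet
#'
#' Concatenates, per plane in the fixed order axial, (semi)coronal, sagittal,
#' the normalized translation (3 values) followed by the rotation code
#' (\code{codec$n_params} values); total length \code{3 * (3 + n_params)}.
#' \code{parse_parameter_vector} is the exact inverse up to the codec
#' round-trip.
#'
#' @param triplet a \code{\link{plane_triplet}}.
#' @param codec a \code{\link{rotation_codec}}.
#' @param geom a \code{\link{volume_geometry}} used for translation
#'   normalization.
#' @return numeric vector.
#' @export
build_parameter_vector <- function(triplet, codec, geom) {
  unlist(lapply(triplet$planes, function(p) {
    R <- cbind(p$e_u, p$e_v, plane_normal(p))
    c(normalize_translation(p$center, geom), encode_rotation(codec, R))
  }), use.names = FALSE)
}

#' @rdname build_parameter_vector
#' @param v numeric vector of length \code{3 * (3 + codec$n_params)}.
#' @param region body region for the reconstructed triplet.
#' @export
parse_parameter_vector <- function(v, codec, geom, region = "ankle") {
  k <- 3L + codec$n_params
  if (length(v) != 3L * k)
    stop("expected parameter vector of length ", 3L * k, ", got ", length(v))
  names_ <- c("axial", if (region == "calcaneus") "semicoronal" else "coronal",
              "sagittal")
  planes <- lapply(seq_len(3L), function(j) {
    seg <- v[((j - 1L) * k + 1L):(j * k)]
    center <- denormalize_translation(seg[1:3], geom)
    R <- decode_rotation(codec, seg[-(1:3)])
    standard_plane(names_[j], center, R[, 1], R[, 2])
  })
  plane_triplet(region, planes)
}

#' Uniformly random rotation matrix
#'
#' Random-axis / random-angle sampling used by the property tests and the
#' synthetic pose generator; uses R's RNG stream.
#' @param n number of rotations.
#' @return one 3x3 matrix if \code{n == 1}, else a list of matrices.
#' @export
random_rotation <- function(n = 1L) {
  one <- function() {
    # Shoemake's uniform quaternion sampling
    u <- runif(3)
    q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
           sqrt(1 - u[1]) * cos(2 * pi * u[2]),
           sqrt(u[1]) * sin(2 * pi * u[3]),
           sqrt(u[1]) * cos(2 * pi * u[3]))
    decode_quaternion(q)
  }
  if (n == 1L) one() else replicate(n, one(), simplify = FALSE)
}
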