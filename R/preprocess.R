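# Spatial augmentation as a single composed homogeneous matrix (one
# interpolation pass), mirror augmentation with the label handedness fix,
# and the sigmoid-window intensity normalization.
#
# Orientation convention: the composed matrix T_m maps OUTPUT physical
# coordinates (mm, center origin) into the INPUT volume, i.e. resampling
# pulls v_out(p) = v_in(T_m p). Plane labels consequently transform by
# T_m^{-1}, so a translation component +u shifts both the rendered content
# and the plane centers by -u.

#' Augmentation configuration
#'
#' Ranges and probabilities of the online augmentation: rotation within
#' \code{[-45, 45]} degrees, isotropic scaling in \code{[0.95, 1.05]},
#' translation within \code{[-12, 12]} mm, each activated independently with
#' probability 0.5; mirroring in x with probability 0.5; intensity factor
#' drawn uniformly from \code{[0.95, 1.05]}.
#'
#' @param rotation_deg half-range of the per-axis rotation angles, degrees.
#' @param scale_range range of the isotropic scale factor.
#' @param translation_mm half-range of the per-axis translation, mm.
#' @param prob per-op activation probability.
#' @param mirror_prob probability of the x-mirror.
#' @param intensity_range range of the intensity factor f.
#' @param crop center-crop fraction realized inside the subsampling matrix
#'   (1 = full field of view).
#' @return an object of class \code{augmentation_config}.
#' @export
augmentation_config <- function(rotation_deg = 45, scale_range = c(0.95, 1.05),
                                translation_mm = 12, prob = 0.5,
                                mirror_prob = 0.5,
                                intensity_range = c(0.95, 1.05), crop = 1) {
  stopifnot(prob >= 0, prob <= 1, mirror_prob >= 0, mirror_prob <= 1,
            crop > 0, crop <= 1, length(scale_range) == 2L,
            length(intensity_range) == 2L)
  structure(list(rotation_deg = rotation_deg, scale_range = scale_range,
                 translation_mm = translation_mm, prob = prob,
                 mirror_prob = mirror_prob, intensity_range = intensity_range,
                 crop = crop),
            class = "augmentation_config")
}

homog <- function(R = diag(3), t = c(0, 0, 0)) {
  m <- diag(4); m[1:3, 1:3] <- R; m[1:3, 4] <- t; m
}

#' Composed spatial transform
#'
#' The single matrix \eqn{T_m = T_r T_s T_t T_R} combining subsampling /
#' center-crop (\eqn{T_r}), isotropic scaling (\eqn{T_s}), translation
#' (\eqn{T_t}) and rotation (\eqn{T_R}); the product is formed exactly in
#' that order.
#'
#' @param rotation 3x3 rotation matrix (\eqn{T_R}).
#' @param translation length-3, mm (\eqn{T_t}).
#' @param scale isotropic scale factor (\eqn{T_s}).
#' @param crop center-crop fraction (\eqn{T_r}).
#' @return an object of class \code{composed_transform} with fields
#'   \code{matrix} and \code{components}.
#' @export
composed_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                               scale = 1, crop = 1) {
  T_R <- homog(rotation)
  T_t <- homog(t = translation)
  T_s <- homog(diag(3) * scale)
  T_r <- homog(diag(3) * crop)
  structure(list(matrix = T_r %*% T_s %*% T_t %*% T_R,
                 components = list(T_r = T_r, T_s = T_s, T_t = T_t, T_R = T_R),
                 scale = scale * crop),
            class = "composed_transform")
}

#' @export
print.composed_transform <- function(x, ...) {
  cat("<composed_transform T_m = T_r T_s T_t T_R>\n")
  print(signif(x$matrix, 6))
  invisible(x)
}

#' Sample one online augmentation
#'
#' Each spatial operation (rotation, scaling, translation) is independently
#' activated with the configured probability and its parameters drawn
#' uniformly from the configured range; the mirror flag and the intensity
#' factor are drawn likewise. Uses R's RNG stream, so results are
#' reproducible under \code{set.seed}.
#'
#' @param cfg an \code{\link{augmentation_config}}.
#' @return list with \code{transform} (a \code{\link{composed_transform}}),
#'   \code{mirror} (logical), \code{intensity_factor}, and the raw draws in
#'   \code{params}.
#' @export
sample_augmentation <- function(cfg = augmentation_config()) {
  act <- runif(3) < cfg$prob
  ang <- if (act[1]) runif(3, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180
         else c(0, 0, 0)
  R <- rot_z(ang[1]) %*% rot_y(ang[2]) %*% rot_x(ang[3])
  s <- if (act[2]) runif(1, cfg$scale_range[1], cfg$scale_range[2]) else 1
  t <- if (act[3]) runif(3, -cfg$translation_mm, cfg$translation_mm)
       else c(0, 0, 0)
  mirror <- runif(1) < cfg$mirror_prob
  f <- runif(1, cfg$intensity_range[1], cfg$intensity_range[2])
  list(transform = composed_transform(R, t, s, cfg$crop),
       mirror = mirror, intensity_factor = f,
       params = list(active = act, angles = ang, scale = s, translation = t))
}

#' Resample a volume through a composed transform
#'
#' One trilinear interpolation pass: every output voxel center is mapped by
#' \eqn{T_m} (optionally pre-composed with the x-mirror) into the input
#' volume and sampled; out-of-field positions are filled with air
#' (-1000 HU).
#'
#' @param vol 3D numeric array, HU.
#' @param geom the input \code{\link{volume_geometry}}.
#' @param transform a \code{\link{composed_transform}} or plain 4x4 matrix.
#' @param out_shape integer length-3, output resolution (network input,
#'   e.g. 72^3).
#' @param out_spacing output spacing; defaults to covering the full input
#'   extent with \code{out_shape} voxels.
#' @param mirror apply the x-mirror.
#' @param fill out-of-field value, HU.
#' @return 3D numeric array of dimension \code{out_shape}.
#' @export
resample_volume <- function(vol, geom, transform, out_shape,
                            out_spacing = NULL, mirror = FALSE,
                            fill = -1000) {
  m <- if (inherits(transform, "composed_transform")) transform$matrix
       else as.matrix(transform)
  if (abs(det(m[1:3, 1:3])) < 1e-12) stop("singular composed transform")
  out_shape <- as.integer(out_shape)
  if (is.null(out_spacing)) out_spacing <- geom$extent / out_shape
  if (length(out_spacing) == 1L) out_spacing <- rep(out_spacing, 3L)
  if (mirror) m <- m %*% diag(c(-1, 1, 1, 1))
  resample_trilinear_cpp(vol, geom$spacing, m, out_shape,
                         as.numeric(out_spacing), fill)
}

#' Transform plane labels consistently with a resampled volume
#'
#' Maps every plane by the inverse of the volume-resampling action so the
#' plane keeps marking the same anatomical content: centers by
#' \eqn{T_m^{-1}} (an isotropic similarity, so directions are mapped by its
#' linear part and renormalized), then, if mirrored, x-components of centers
#' and directions are negated and the normal is re-derived as
#' \eqn{e_u \times e_v} — which flips the frame handedness relative to a
#' naive reflection and is exactly the left/right-handedness simulation the
#' mirror augmentation is for.
#'
#' @param triplet a \code{\link{plane_triplet}}.
#' @param transform a \code{\link{composed_transform}} or 4x4 matrix.
#' @param mirror logical, as sampled with the augmentation.
#' @return transformed \code{plane_triplet}.
#' @export
transform_labels <- function(triplet, transform, mirror = FALSE) {
  m <- if (inherits(transform, "composed_transform")) transform$matrix
       else as.matrix(transform)
  mi <- solve(m)
  L <- mi[1:3, 1:3]; t <- mi[1:3, 4]
  planes <- lapply(triplet$planes, function(p) {
    center <- as.numeric(L %*% p$center + t)
    e_u <- unitize(as.numeric(L %*% p$e_u))
    e_v <- unitize(as.numeric(L %*% p$e_v))
    if (mirror) {
      center[1] <- -center[1]
      e_u[1] <- -e_u[1]
      e_v[1] <- -e_v[1]
    }
    standard_plane(p$name, center, e_u, e_v)
  })
  plane_triplet(triplet$region, planes)
}

# ---- intensity --------------------------------------------------------------

#' Intensity windowing configuration
#'
#' HU values are shifted by +1000, multiplied by the augmentation factor f,
#' clipped to the shifted clip range \code{[510, 2040]} (i.e.
#' \code{[-490, 1040]} HU before the shift), rescaled to the unit interval,
#' and passed through a logistic window \eqn{w(x) = 1/(1+e^{g(0.5-x)})} with
#' gain \eqn{g = \log((1-y)/y)/0.4} for \eqn{y = 0.02} on the rescaled unit
#' range. Compared with min-max normalization this compresses the variance
#' of air and metal, which carry little information about the planes.
#'
#' @param clip_hu clip range in HU before the +1000 shift.
#' @param offset_hu additive shift.
#' @param y window tail parameter on the unit range.
#' @return an object of class \code{intensity_window_config} (fields include
#'   the derived gain \code{g}).
#' @export
intensity_window_config <- function(clip_hu = c(-490, 1040),
                                    offset_hu = 1000, y = 0.02) {
  stopifnot(clip_hu[2] > clip_hu[1], y > 0, y < 0.5)
  structure(list(clip_hu = clip_hu, offset_hu = offset_hu, y = y,
                 g = log((1 - y) / y) / 0.4),
            class = "intensity_window_config")
}

#' Sigmoid-window intensity normalization
#'
#' @param vol numeric array (any shape), HU.
#' @param cfg an \code{\link{intensity_window_config}}.
#' @param f intensity augmentation factor (1 at inference).
#' @return array of the same shape with values strictly in (0, 1).
#' @export
intensity_normalize <- function(vol, cfg = intensity_window_config(), f = 1) {
  lo <- cfg$clip_hu[1] + cfg$offset_hu
  hi <- cfg$clip_hu[2] + cfg$offset_hu
  x <- f * (vol + cfg$offset_hu)
  x <- pmin(pmax(x, lo), hi)
  u <- (x - lo) / (hi - lo)
  out <- 1 / (1 + exp(cfg$g * (0.5 - u)))
  if (!is.null(dim(vol))) dim(out) <- dim(vol)
  out
}
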