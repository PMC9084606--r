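# Algorithmic orthogonality restoration. The three planes are regressed
# decoupled (no orthogonality constraint in the loss), and the axial plane --
# empirically the most accurately regressed one -- is then used as the
# reference to (1) zero the in-plane rotation of the coronal and sagittal
# planes relative to the axial intersection and (2) re-orthogonalize the
# sagittal normal for regions whose standard planes are mutually orthogonal.

rotate_about_axis <- function(v, axis, angle) {
  # Rodrigues rotation of v about unit axis
  axis <- unitize(axis)
  v * cos(angle) + cross3(axis, v) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

#' In-plane rotation correction against the axial intersection
#'
#' For the coronal (or semicoronal) and sagittal planes, the intersection
#' direction with the axial plane is \eqn{v = e_{w,axial} \times e_w}. The
#' in-plane frame is rotated about the plane's own normal so that the
#' projection of \eqn{v} onto the plane becomes parallel (not merely
#' collinear) to the row direction \eqn{e_u}: the antiparallel case is
#' resolved toward alignment, so a 180-degree in-plane error is corrected by
#' a 180-degree rotation. The axial plane, all centers, and all normals are
#' left untouched.
#'
#' @param triplet a \code{\link{plane_triplet}}.
#' @return corrected \code{plane_triplet}.
#' @export
correct_inplane <- function(triplet) {
  ax <- triplet$planes[[1L]]
  n_ax <- plane_normal(ax)
  fix <- function(p) {
    n_p <- plane_normal(p)
    v <- cross3(n_ax, n_p)
    if (vnorm(v) < 1e-8) {
      warning("axial normal parallel to ", p$name,
              " normal; plane left unchanged")
      return(p)
    }
    v <- unitize(v)          # already lies in the plane (v . n_p = 0)
    # signed angle from e_u to v about n_p
    ang <- atan2(sum(cross3(p$e_u, v) * n_p), sum(p$e_u * v))
    standard_plane(p$name, p$center,
                   unitize(rotate_about_axis(p$e_u, n_p, ang)),
                   unitize(rotate_about_axis(p$e_v, n_p, ang)))
  }
  plane_triplet(triplet$region,
                list(ax, fix(triplet$planes[[2L]]), fix(triplet$planes[[3L]])))
}

#' Sagittal-normal orthogonalization
#'
#' For regions with mutually orthogonal standard planes (everything but the
#' calcaneus, whose semicoronal plane is oblique), the sagittal normal is
#' replaced by \eqn{\pm(e_{w,axial} \times e_{w,coronal})}, the sign chosen
#' to minimize the angle to the current sagittal normal. The in-plane frame
#' is rebuilt by projecting the previous \eqn{e_u} onto the new plane and
#' setting \eqn{e_v = e_w \times e_u}; the center is unchanged.
#'
#' @param triplet a \code{\link{plane_triplet}}.
#' @return adjusted \code{plane_triplet} (calcaneus triplets are returned
#'   unchanged).
#' @export
orthogonalize_sagittal <- function(triplet) {
  if (triplet$region == "calcaneus") return(triplet)
  ax <- triplet$planes[[1L]]; cor <- triplet$planes[[2L]]
  sag <- triplet$planes[[3L]]
  n_new <- cross3(plane_normal(ax), plane_normal(cor))
  if (vnorm(n_new) < 1e-8) {
    warning("axial and coronal normals parallel; sagittal left unchanged")
    return(triplet)
  }
  n_new <- unitize(n_new)
  if (sum(n_new * plane_normal(sag)) < 0) n_new <- -n_new
  e_u <- sag$e_u - sum(sag$e_u * n_new) * n_new
  if (vnorm(e_u) < 1e-8)
    stop("sagittal row direction parallel to new normal; cannot rebuild frame")
  e_u <- unitize(e_u)
  e_v <- cross3(n_new, e_u)
  plane_triplet(triplet$region,
                list(ax, cor, standard_plane("sagittal", sag$center, e_u, e_v)))
}

#' Full postprocessing of a regressed triplet
#'
#' \code{\link{correct_inplane}} followed by
#' \code{\link{orthogonalize_sagittal}}; idempotent.
#'
#' @param triplet a \code{\link{plane_triplet}}.
#' @return postprocessed \code{plane_triplet}.
#' @export
postprocess_triplet <- function(triplet) {
  orthogonalize_sagittal(correct_inplane(triplet))
}
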