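# Synthetic phantom generator. An anatomy-like HU phantom (soft-tissue
# envelope, bone shaft cylinder, joint-head ellipsoid, an off-axis marker
# sphere that breaks mirror symmetry so left/right handedness is learnable,
# optional metal sphere) is rendered analytically on the posed grid --
# signed-distance thresholding with one-voxel linear edge smoothing, no
# meshes -- so the ground-truth standard planes are exact: the canonical
# triplet mapped by the sampled rigid pose.

#' Phantom recipe
#'
#' The canonical phantom frame has the joint-head center at the origin, the
#' bone shaft along -z, and the asymmetry marker offset along +x. Canonical
#' standard planes: axial normal z, coronal normal y, sagittal normal x, all
#' centered at the joint-head center; with \code{oblique = TRUE} the coronal
#' is replaced by a semicoronal plane tilted 30 degrees about x (the
#' calcaneus-style oblique layout).
#'
#' @param shape voxels per axis (scalar or length-3). The 128-voxel default
#'   at 1.25 mm mirrors a (160 mm)^3 field of view at desk scale; use 512 at
#'   0.3125 mm for full fidelity.
#' @param spacing mm per voxel (scalar or length-3).
#' @param shaft_radius,shaft_length bone shaft cylinder, mm; HU
#'   \code{shaft_hu}.
#' @param head_semiaxes joint-head ellipsoid semi-axes, mm; HU
#'   \code{head_hu}.
#' @param marker_radius,marker_offset asymmetry marker sphere (radius, +x
#'   center offset), mm; HU \code{marker_hu}.
#' @param soft_semiaxes,soft_center soft-tissue envelope ellipsoid, mm; HU
#'   \code{soft_hu}.
#' @param metal include a metal sphere (HU \code{metal_hu}) at
#'   \code{metal_center}.
#' @param shaft_hu,head_hu,marker_hu,soft_hu,metal_hu,air_hu material HU.
#' @param noise_sd additive Gaussian HU noise (after compositing).
#' @param edge_mm width of the linear edge blending between materials;
#'   defaults to one voxel (the smallest spacing component). Larger values
#'   give a smoother phantom, useful when comparing interpolation pipelines.
#' @param oblique use the semicoronal (calcaneus-style) plane layout.
#' @return an object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(shape = 128, spacing = 1.25,
                         shaft_radius = 9, shaft_length = 70,
                         head_semiaxes = c(24, 15, 11),
                         marker_radius = 6, marker_offset = 28,
                         soft_semiaxes = c(38, 26, 72),
                         soft_center = c(0, 0, -20),
                         metal = FALSE, metal_center = c(0, 18, -30),
                         metal_radius = 5,
                         shaft_hu = 1200, head_hu = 900, marker_hu = 1500,
                         soft_hu = 50, metal_hu = 3000, air_hu = -1000,
                         noise_sd = 15, edge_mm = NULL, oblique = FALSE) {
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Canonical ground-truth triplet of the phantom
#'
#' Axial (normal z), coronal (normal y) or semicoronal (tilted 30 degrees
#' about x), and sagittal (normal x) planes, all centered at the joint-head
#' center (the phantom-frame origin).
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return a \code{\link{plane_triplet}} in the canonical phantom frame.
#' @export
canonical_triplet <- function(spec) {
  # In-plane frames follow the same convention the postprocessing enforces:
  # each non-axial plane's row direction e_u is parallel to its intersection
  # with the axial plane (e_u = e_w_axial x e_w_plane up to normalization),
  # so a consistent triplet is a fixed point of the in-plane correction.
  axial <- standard_plane("axial", c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  sagittal <- standard_plane("sagittal", c(0, 0, 0), c(0, 1, 0), c(0, 0, 1))
  if (spec$oblique) {
    tilt <- rot_x(30 * pi / 180)
    second <- standard_plane("semicoronal", c(0, 0, 0),
                             c(-1, 0, 0),
                             as.numeric(tilt %*% c(0, 0, 1)))
    plane_triplet("calcaneus", list(axial, second, sagittal))
  } else {
    coronal <- standard_plane("coronal", c(0, 0, 0), c(-1, 0, 0), c(0, 0, 1))
    plane_triplet("ankle", list(axial, coronal, sagittal))
  }
}

# signed distances (negative inside), evaluated on n x 3 coordinate matrix
sdf_ellipsoid <- function(q, center, semiaxes) {
  s <- sweep(sweep(q, 2, center), 2, semiaxes, "/")
  (sqrt(rowSums(s^2)) - 1) * min(semiaxes)
}

sdf_sphere <- function(q, center, radius) {
  sqrt(rowSums(sweep(q, 2, center)^2)) - radius
}

sdf_capped_cylinder_z <- function(q, radius, z_lo, z_hi) {
  dr <- sqrt(q[, 1]^2 + q[, 2]^2) - radius
  dz <- pmax(z_lo - q[, 3], q[, 3] - z_hi)
  pmax(dr, dz)
}

#' Render a posed phantom volume with exact ground-truth planes
#'
#' The pose maps the canonical phantom frame into the volume coordinate
#' system; occupancy is evaluated analytically at the pulled-back grid
#' coordinates, materials are composited in priority order (soft tissue,
#' shaft, head, marker, metal) with one-voxel linear edge blending, and
#' Gaussian HU noise is added last. The returned ground-truth triplet is
#' the canonical triplet mapped by the pose — exact by construction.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @param pose a \code{\link{rigid_transform}} (canonical frame -> volume).
#' @return list with \code{volume} (3D HU array), \code{geom}
#'   (\code{\link{volume_geometry}}), \code{triplet} (ground truth),
#'   \code{region} and \code{pose}.
#' @export
render_phantom <- function(spec, pose = rigid_from_rt(diag(3))) {
  geom <- volume_geometry(spec$shape, spec$spacing)
  n <- geom$shape
  ax <- lapply(1:3, function(i) (seq_len(n[i]) - 1 - (n[i] - 1) / 2) *
                 geom$spacing[i])
  # physical grid coordinates, then pull back into the canonical frame
  grid <- cbind(rep(ax[[1]], times = n[2] * n[3]),
                rep(rep(ax[[2]], each = n[1]), times = n[3]),
                rep(ax[[3]], each = n[1] * n[2]))
  mi <- solve(pose$matrix)
  q <- grid %*% t(mi[1:3, 1:3]) + matrix(mi[1:3, 4], nrow(grid), 3,
                                         byrow = TRUE)
  edge <- if (is.null(spec$edge_mm)) min(geom$spacing) else spec$edge_mm
  vol <- rep(spec$air_hu, nrow(q))
  paint <- function(vol, d, hu) {
    w <- pmin(pmax(0.5 - d / edge, 0), 1)
    vol * (1 - w) + hu * w
  }
  vol <- paint(vol, sdf_ellipsoid(q, spec$soft_center, spec$soft_semiaxes),
               spec$soft_hu)
  vol <- paint(vol, sdf_capped_cylinder_z(q, spec$shaft_radius,
                                          -spec$shaft_length, 0),
               spec$shaft_hu)
  vol <- paint(vol, sdf_ellipsoid(q, c(0, 0, 0), spec$head_semiaxes),
               spec$head_hu)
  vol <- paint(vol, sdf_sphere(q, c(spec$marker_offset, 0, 0),
                               spec$marker_radius), spec$marker_hu)
  if (spec$metal)
    vol <- paint(vol, sdf_sphere(q, spec$metal_center, spec$metal_radius),
                 spec$metal_hu)
  if (spec$noise_sd > 0) vol <- vol + rnorm(length(vol), sd = spec$noise_sd)
  dim(vol) <- n
  trip <- apply_rigid_to_triplet(canonical_triplet(spec), pose)
  list(volume = vol, geom = geom, triplet = trip, region = trip$region,
       pose = pose)
}

#' Sample a random rigid pose
#'
#' Euler angles uniform within \code{[-rot_deg, rot_deg]} per axis
#' (intrinsic Z-Y-X) and translation uniform within
#' \code{[-trans_mm, trans_mm]} per component.
#'
#' @param rot_deg rotation half-range, degrees.
#' @param trans_mm translation half-range, mm.
#' @return a \code{\link{rigid_transform}}.
#' @export
sample_pose <- function(rot_deg = 45, trans_mm = 12) {
  ang <- runif(3, -rot_deg, rot_deg) * pi / 180
  rigid_from_rt(rot_z(ang[1]) %*% rot_y(ang[2]) %*% rot_x(ang[3]),
                runif(3, -trans_mm, trans_mm))
}

#' Generate a synthetic dataset of posed phantoms
#'
#' Renders \code{n} phantoms with poses sampled uniformly in the given
#' ranges, assigns synthetic patient identifiers, and builds a k-fold split
#' in which all volumes of one patient stay in the same fold. With
#' \code{metal_pairs = TRUE} each patient contributes two volumes sharing
#' the same pose, one with and one without the metal sphere (emulating the
#' twice-scanned cadavers). With \code{dir} set, volumes (NIfTI), plane
#' annotations (JSON) and a manifest CSV are also written to disk.
#'
#' @param n number of volumes.
#' @param spec a \code{\link{phantom_spec}}.
#' @param rot_deg,trans_mm pose sampling ranges.
#' @param folds number of cross-validation folds.
#' @param metal_pairs render metal/no-metal pairs per patient.
#' @param dir optional output directory.
#' @return list with \code{samples} (each as required by
#'   \code{\link{train_model}}, plus \code{patient_id} and \code{fold}) and
#'   \code{manifest} (data.frame).
#' @export
generate_dataset <- function(n, spec = phantom_spec(), rot_deg = 45,
                             trans_mm = 12, folds = 5L, metal_pairs = FALSE,
                             dir = NULL) {
  stopifnot(n >= folds)
  n_patients <- if (metal_pairs) ceiling(n / 2) else n
  pid_of <- if (metal_pairs) rep(seq_len(n_patients), each = 2)[1:n]
            else seq_len(n)
  fold_of_patient <- setNames(
    rep_len(seq_len(folds), n_patients)[order(runif(n_patients))],
    seq_len(n_patients))
  poses <- vector("list", n_patients)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- pid_of[i]
    if (is.null(poses[[pid]])) poses[[pid]] <- sample_pose(rot_deg, trans_mm)
    sp <- spec
    if (metal_pairs) sp$metal <- i %% 2 == 0
    ph <- render_phantom(sp, poses[[pid]])
    samples[[i]] <- c(ph, list(patient_id = pid,
                               fold = unname(fold_of_patient[as.character(pid)]),
                               metal = isTRUE(sp$metal)))
  }
  manifest <- data.frame(
    id = seq_len(n),
    patient_id = vapply(samples, `[[`, numeric(1), "patient_id"),
    fold = vapply(samples, `[[`, numeric(1), "fold"),
    region = vapply(samples, `[[`, character(1), "region"),
    metal = vapply(samples, `[[`, logical(1), "metal"))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_volume(samples[[i]]$volume, samples[[i]]$geom,
                   file.path(dir, sprintf("vol_%03d.nii.gz", i)))
      write_planes(samples[[i]]$triplet, samples[[i]]$geom,
                   file.path(dir, sprintf("vol_%03d.json", i)))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}
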