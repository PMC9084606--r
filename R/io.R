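# Readers and writers. Volumes are exchanged as NIfTI with axis-aligned
# orientation (the package's fixed center-origin convention); plane
# annotations as a small JSON schema, one file per volume; metric tables as
# CSV; configuration as YAML.

#' Write / read a volume as NIfTI
#'
#' HU values and per-axis spacing are preserved. On read, the orientation is
#' reduced to the package's axis-aligned center-origin convention; a file
#' whose rotation part is not axis-aligned (oblique direction cosines) is
#' rejected with an explicit error rather than silently reinterpreted.
#'
#' @param vol 3D numeric array, HU.
#' @param geom a \code{\link{volume_geometry}}.
#' @param path file path (\code{.nii} or \code{.nii.gz}).
#' @return \code{read_volume}: list with \code{volume} and \code{geom}.
#' @export
write_volume <- function(vol, geom, path) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- geom$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D scalar volume, got ", length(d), " dimensions")
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("missing or invalid voxel spacing")
  x <- RNifti::xform(img)
  R <- x[1:3, 1:3]
  Rn <- sweep(abs(R), 2, sqrt(colSums(R^2)), "/")
  if (any(apply(Rn, 2, max) < 1 - 1e-6))
    stop("volume has oblique direction cosines; this package requires ",
         "axis-aligned volumes in its center-origin convention")
  vol <- as.array(img)
  attributes(vol) <- list(dim = d)
  list(volume = vol, geom = volume_geometry(d, sp[1:3]))
}

# ---- plane annotation JSON --------------------------------------------------

#' Write / read a plane-annotation JSON file
#'
#' Schema (one file per volume):
#' \preformatted{
#' { "region": str,
#'   "volume": {"shape": [i,j,k], "spacing_mm": [x,y,z]},
#'   "planes": [{"name": str, "center_mm": [..], "e_u": [..], "e_v": [..]}] }
#' }
#' Numbers are written with 17 significant digits so geometry round-trips
#' bit-stably. On read the plane invariants are re-checked: unit norms and
#' orthogonality to 1e-6, with optional Gram-Schmidt re-orthogonalization
#' behind the \code{reorthogonalize} flag; region/plane-name consistency is
#' enforced.
#'
#' @param triplet a \code{\link{plane_triplet}}.
#' @param geom a \code{\link{volume_geometry}}.
#' @param path JSON file path.
#' @return \code{read_planes}: list with \code{triplet} and \code{geom}.
#' @export
write_planes <- function(triplet, geom, path) {
  obj <- list(
    region = triplet$region,
    volume = list(shape = geom$shape, spacing_mm = geom$spacing),
    planes = lapply(triplet$planes, function(p)
      list(name = p$name, center_mm = p$center, e_u = p$e_u, e_v = p$e_v)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_planes
#' @param reorthogonalize repair mildly non-orthonormal frames
#'   (Gram-Schmidt) instead of erroring.
#' @param tol invariant tolerance on load.
#' @export
read_planes <- function(path, reorthogonalize = FALSE, tol = 1e-6) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$region) || is.null(obj$planes))
    stop("plane annotation file missing 'region' or 'planes'")
  geom <- volume_geometry(obj$volume$shape, obj$volume$spacing_mm)
  pl <- obj$planes
  if (NROW(pl) != 3L) stop("expected exactly 3 planes")
  planes <- lapply(seq_len(3L), function(j) {
    name <- pl$name[j]
    center <- as.numeric(pl$center_mm[[j]])
    e_u <- as.numeric(pl$e_u[[j]])
    e_v <- as.numeric(pl$e_v[[j]])
    if (reorthogonalize) {
      e_u <- unitize(e_u)
      e_v <- unitize(e_v - sum(e_v * e_u) * e_u)
    }
    standard_plane(name, center, e_u, e_v, tol = tol)
  })
  list(triplet = plane_triplet(obj$region, planes), geom = geom)
}

# ---- config -----------------------------------------------------------------

#' Read a YAML run configuration
#'
#' Recognized sections: \code{augmentation} (ranges, probabilities, crop),
#' \code{preprocess} (HU clip range, window tail y, network input shape),
#' \code{train} (epochs, lr, decay, step, momentum, batch size, oversample,
#' seed). Missing entries fall back to the package defaults.
#'
#' @param path YAML file.
#' @return list with \code{aug} (\code{\link{augmentation_config}}),
#'   \code{window} (\code{\link{intensity_window_config}}),
#'   \code{input_shape} and \code{train} (\code{\link{train_config}}).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(x, nm, default) if (!is.null(x[[nm]])) x[[nm]] else default
  a <- y$augmentation
  aug <- augmentation_config(
    rotation_deg = take(a, "rotation_deg", 45),
    scale_range = unlist(take(a, "scale_range", c(0.95, 1.05))),
    translation_mm = take(a, "translation_mm", 12),
    prob = take(a, "prob", 0.5),
    mirror_prob = take(a, "mirror_prob", 0.5),
    intensity_range = unlist(take(a, "intensity_range", c(0.95, 1.05))),
    crop = take(a, "crop", 1))
  p <- y$preprocess
  window <- intensity_window_config(
    clip_hu = unlist(take(p, "clip_hu", c(-490, 1040))),
    offset_hu = take(p, "offset_hu", 1000),
    y = take(p, "y", 0.02))
  input_shape <- unlist(take(p, "input_shape", c(72, 72, 72)))
  tr <- y$train
  train <- train_config(
    epochs = take(tr, "epochs", 400L),
    lr = take(tr, "lr", 0.00164),
    lr_decay = take(tr, "lr_decay", 0.27291),
    lr_step = take(tr, "lr_step", 75L),
    momentum = take(tr, "momentum", 0.957437),
    batch_size = take(tr, "batch_size", 9L),
    augment = take(tr, "augment", TRUE),
    aug_config = aug,
    oversample = take(tr, "oversample", FALSE),
    seed = take(tr, "seed", NULL))
  list(aug = aug, window = window, input_shape = input_shape, train = train)
}

#' Write an error-report table as CSV
#'
#' One row per volume and plane with the three error terms, plus the score
#' as an attribute column.
#'
#' @param reports list of \code{plane_error_report}s.
#' @param path CSV path.
#' @param ids optional volume identifiers.
#' @return the written data.frame, invisibly.
#' @export
write_report_csv <- function(reports, path, ids = seq_along(reports)) {
  rows <- Map(function(r, id) {
    df <- as.data.frame(r)
    df$volume <- id
    df$score <- score_value(r)
    df
  }, reports, ids)
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
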