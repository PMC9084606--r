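# Per-plane error terms and the weighted performance score. The reference
# plane is always the manual (or synthetic ground-truth) annotation; d is
# deliberately asymmetric in pred/ref and normal flips score ~180 deg (no
# flip forgiveness: plane flips are a real failure mode that postprocessing
# is meant to expose and fix).

#' Translation error along the reference normal
#'
#' \eqn{d = |(A_{pred} - A_{ref}) \cdot e_{w,ref}|} in mm. Center offsets
#' within the reference plane are invisible by construction: they do not
#' change which slice is displayed.
#'
#' @param pred,ref \code{\link{standard_plane}}s.
#' @return nonnegative scalar, mm.
#' @export
translation_error <- function(pred, ref) {
  abs(sum((pred$center - ref$center) * plane_normal(ref)))
}

#' Normal deviation angle
#'
#' Angle in degrees between the predicted and reference plane normals,
#' \code{acos} of the clamped dot product. A flipped normal scores ~180.
#'
#' @param pred,ref \code{\link{standard_plane}}s.
#' @return scalar in [0, 180] degrees.
#' @export
normal_error <- function(pred, ref) {
  d <- sum(plane_normal(pred) * plane_normal(ref))
  acos(max(-1, min(1, d))) * 180 / pi
}

#' In-plane rotation error
#'
#' Projects the predicted row and column directions onto the reference
#' plane, renormalizes, and averages the two unsigned angles to the
#' reference \eqn{e_u} and \eqn{e_v} respectively.
#'
#' @param pred,ref \code{\link{standard_plane}}s; errors if a predicted
#'   direction is (near) parallel to the reference normal (degenerate
#'   projection).
#' @return scalar in [0, 180] degrees.
#' @export
inplane_error <- function(pred, ref) {
  n <- plane_normal(ref)
  ang <- function(dir, ref_dir) {
    proj <- dir - sum(dir * n) * n
    if (vnorm(proj) < 1e-8)
      stop("degenerate projection: predicted direction parallel to reference normal")
    proj <- proj / vnorm(proj)
    acos(max(-1, min(1, sum(proj * ref_dir)))) * 180 / pi
  }
  (ang(pred$e_u, ref$e_u) + ang(pred$e_v, ref$e_v)) / 2
}

#' Weighted plane-error score
#'
#' Per plane j the three error terms are combined as
#' \eqn{0.2 d_j + 0.6 \epsilon_{n,j} + 0.2 \epsilon_{i,j}} (mm and degrees
#' mixed by design; the normal carries the largest weight because fixing it
#' requires out-of-plane rotations, whereas in-plane rotation and position
#' are easy to correct manually), and the score is the mean over the three
#' planes.
#'
#' @param pred,ref \code{\link{plane_triplet}}s of the same region.
#' @return an object of class \code{plane_error_report}: a data.frame with
#'   one row per plane (columns \code{plane}, \code{d_mm}, \code{eps_n_deg},
#'   \code{eps_i_deg}) and attribute \code{score}.
#' @export
plane_score <- function(pred, ref) {
  if (!identical(pred$region, ref$region))
    stop("region mismatch: ", pred$region, " vs ", ref$region)
  rows <- lapply(seq_len(3L), function(j) {
    p <- pred$planes[[j]]; r <- ref$planes[[j]]
    data.frame(plane = r$name,
               d_mm = translation_error(p, r),
               eps_n_deg = normal_error(p, r),
               eps_i_deg = inplane_error(p, r),
               stringsAsFactors = FALSE)
  })
  rep_ <- do.call(rbind, rows)
  score <- mean(0.2 * rep_$d_mm + 0.6 * rep_$eps_n_deg + 0.2 * rep_$eps_i_deg)
  structure(rep_, score = score, region = ref$region,
            class = c("plane_error_report", "data.frame"))
}

#' @export
print.plane_error_report <- function(x, ...) {
  cat(sprintf("<plane_error_report %s, score p = %.4g>\n",
              attr(x, "region"), attr(x, "score")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Score value of a report
#' @param report a \code{plane_error_report}.
#' @return scalar score p.
#' @export
score_value <- function(report) attr(report, "score")

#' Aggregate per-volume error reports across cross-validation folds
#'
#' For each metric (d, eps_n, eps_i per plane position, and the score) the
#' median within each fold is taken first, then the mean and sample standard
#' deviation of the fold medians. With a single fold the sd is undefined and
#' reported as 0 with \code{sd_defined = FALSE}.
#'
#' @param reports list of \code{plane_error_report}s.
#' @param folds integer/character vector assigning each report to a fold.
#' @return data.frame with columns \code{metric}, \code{mean}, \code{sd},
#'   \code{sd_defined}.
#' @export
aggregate_folds <- function(reports, folds) {
  stopifnot(length(reports) == length(folds), length(reports) >= 1L)
  per_vol <- data.frame(
    fold = as.character(folds),
    d_mm = vapply(reports, function(r) mean(r$d_mm), numeric(1)),
    eps_n_deg = vapply(reports, function(r) mean(r$eps_n_deg), numeric(1)),
    eps_i_deg = vapply(reports, function(r) mean(r$eps_i_deg), numeric(1)),
    score = vapply(reports, score_value, numeric(1)))
  if (any(table(per_vol$fold) == 0L)) stop("empty fold")
  metrics <- c("d_mm", "eps_n_deg", "eps_i_deg", "score")
  out <- lapply(metrics, function(m) {
    med <- tapply(per_vol[[m]], per_vol$fold, median)
    sd_def <- length(med) > 1L
    data.frame(metric = m, mean = mean(med),
               sd = if (sd_def) sd(med) else 0,
               sd_defined = sd_def, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
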