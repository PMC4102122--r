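# Pore-aligned coordinate frame: z = 0 at the centroid of the reference
# selection (the S4-site threonines in the real channel), z increasing
# toward the selectivity filter, cytoplasmic side negative.

#' Compute the pore-aligned coordinate frame for one frame
#'
#' The origin is the centroid of the reference selection; the axis is the
#' lab z-axis (`axis_mode = "fixed_z"`, default) or the principal axis of a
#' pore-lining selection (`axis_mode = "principal"`). The pore coordinate of
#' a point p is `dot(p - origin, axis)`.
#'
#' @param frame a frame from [get_frame()] or an n x 3 coordinate matrix.
#' @param ref_sel `atom_selection` defining z = 0 (non-empty).
#' @param axis_mode `"fixed_z"` or `"principal"`.
#' @param lining_sel `atom_selection` of pore-lining atoms, required for
#'   `axis_mode = "principal"`.
#' @return an object of class `pore_frame` with `origin`, `axis` (unit),
#'   and in-plane unit vectors `e1`, `e2`.
#' @export
compute_pore_frame <- function(frame, ref_sel, axis_mode = c("fixed_z", "principal"),
                               lining_sel = NULL) {
  axis_mode <- match.arg(axis_mode)
  coords <- frame_coords(frame)
  if (length(ref_sel$indices) == 0L) abort("reference selection is empty")
  origin <- colMeans(coords[ref_sel$indices, , drop = FALSE])
  if (axis_mode == "fixed_z") {
    axis <- c(0, 0, 1)
  } else {
    if (is.null(lining_sel)) abort("axis_mode = 'principal' requires lining_sel")
    p <- coords[lining_sel$indices, , drop = FALSE]
    if (nrow(p) < 3L) abort("principal axis needs at least 3 lining atoms")
    cv <- stats::cov(p)
    ev <- eigen(cv, symmetric = TRUE)
    if (ev$values[1] < 1.05 * ev$values[2]) {
      abort("degenerate principal axis: lining selection is nearly isotropic")
    }
    axis <- ev$vectors[, 1]
    if (axis[3] < 0) axis <- -axis
    axis <- axis / sqrt(sum(axis^2))
  }
  # in-plane basis from the lab direction least aligned with the axis
  ref_dir <- diag(3)[, which.min(abs(axis))]
  e1 <- ref_dir - sum(ref_dir * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  structure(list(origin = as.numeric(origin), axis = as.numeric(axis),
                 e1 = e1, e2 = e2, axis_mode = axis_mode),
            class = "pore_frame")
}

# accept a get_frame() list or a bare coordinate matrix
frame_coords <- function(frame) {
  if (is.list(frame) && !is.null(frame$coords)) frame$coords else as.matrix(frame)
}

#' Pore-axis coordinate of points
#' @param frame a frame or coordinate matrix.
#' @param pore_frame a [compute_pore_frame()] result.
#' @param indices optional row subset.
#' @return numeric vector of z values (Angstrom; 0 at the reference).
#' @export
pore_z <- function(frame, pore_frame, indices = NULL) {
  coords <- frame_coords(frame)
  if (!is.null(indices)) coords <- coords[indices, , drop = FALSE]
  as.numeric(sweep(coords, 2, pore_frame$origin) %*% pore_frame$axis)
}

# in-plane distance from the pore axis
pore_rho <- function(frame, pore_frame, indices = NULL) {
  coords <- frame_coords(frame)
  if (!is.null(indices)) coords <- coords[indices, , drop = FALSE]
  d <- sweep(coords, 2, pore_frame$origin)
  z <- as.numeric(d %*% pore_frame$axis)
  sqrt(pmax(rowSums(d^2) - z^2, 0))
}
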