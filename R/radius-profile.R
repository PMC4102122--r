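# HOLE-style maximal-sphere pore radius profile. At each z slice the probe
# center is constrained to the slice plane and the radius is
#   max over in-plane p of  min over atoms i of (|p - x_i| - vdw_i)
# using true 3D distances (spheres, not 2D sections). The in-plane maximum
# is located by simulated annealing seeded from the previous slice's
# optimum, followed by a deterministic Nelder-Mead polish.

#' Maximal-sphere pore radius profile
#'
#' @param frame a frame from [get_frame()] or an n x 3 coordinate matrix.
#' @param struct the [md_structure()] providing vdW radii.
#' @param sel `atom_selection` of pore-forming atoms (non-empty).
#' @param pore_frame a [compute_pore_frame()] result.
#' @param z_range `(z_lo, z_hi)` in pore coordinates; default: the z extent
#'   of the selected atoms.
#' @param z_step slice spacing (Angstrom), default 0.5.
#' @param n_proposals annealing proposals per slice, default 2000.
#' @param step_init initial in-plane proposal step (Angstrom), default 0.5;
#'   multiplied by `step_decay` every `decay_every` proposals.
#' @param step_decay multiplicative cooling factor, default 0.9.
#' @param decay_every proposals per cooling step, default 100.
#' @param temp_init initial acceptance temperature (Angstrom of radius),
#'   default 0.1; cooled on the same schedule.
#' @param cutoff only atoms within this axial distance of a slice are
#'   considered (Angstrom), default 12; a slice with no atoms in reach gets
#'   radius `Inf` with a warning.
#' @param seed integer seed for the proposal stream.
#' @return an object of class `pore_radius_profile`: `z` (pore coordinates),
#'   `radius` (Angstrom, clipped at 0), plus probe-center tracks.
#' @export
radius_profile <- function(frame, struct, sel, pore_frame,
                           z_range = NULL, z_step = 0.5,
                           n_proposals = 2000L, step_init = 0.5,
                           step_decay = 0.9, decay_every = 100L,
                           temp_init = 0.1, cutoff = 12, seed = 1L) {
  if (z_step <= 0) abort("z_step must be positive")
  if (length(sel$indices) == 0L) abort("atom selection is empty")
  coords <- frame_coords(frame)
  xyz <- coords[sel$indices, , drop = FALSE]
  vdw <- struct$atoms$vdw[sel$indices]
  az <- pore_z(xyz, pore_frame)
  if (is.null(z_range)) z_range <- c(min(az), max(az))
  zs <- seq(z_range[1], z_range[2], by = z_step)

  # radius of the probe sphere centered at origin + z*axis + u*e1 + v*e2
  pf <- pore_frame
  eval_f <- function(uv, z, sub_xyz, sub_vdw) {
    p <- pf$origin + z * pf$axis + uv[1] * pf$e1 + uv[2] * pf$e2
    d <- sqrt((sub_xyz[, 1] - p[1])^2 + (sub_xyz[, 2] - p[2])^2 +
                (sub_xyz[, 3] - p[3])^2)
    min(d - sub_vdw)
  }

  radii <- numeric(length(zs))
  centers_u <- numeric(length(zs))
  centers_v <- numeric(length(zs))
  with_seed(seed, {
    start <- c(0, 0)
    for (si in seq_along(zs)) {
      z <- zs[si]
      near <- abs(az - z) <= cutoff
      if (!any(near)) {
        warn("no atoms within %.3g A of slice z = %.3g; radius reported as Inf",
             cutoff, z)
        radii[si] <- Inf
        centers_u[si] <- start[1]; centers_v[si] <- start[2]
        next
      }
      sub_xyz <- xyz[near, , drop = FALSE]
      sub_vdw <- vdw[near]
      cur <- start
      f_cur <- eval_f(cur, z, sub_xyz, sub_vdw)
      best <- cur; f_best <- f_cur
      steps <- step_init * step_decay^((seq_len(n_proposals) - 1L) %/% decay_every)
      temps <- temp_init * step_decay^((seq_len(n_proposals) - 1L) %/% decay_every)
      dz1 <- stats::rnorm(n_proposals); dz2 <- stats::rnorm(n_proposals)
      us <- stats::runif(n_proposals)
      for (k in seq_len(n_proposals)) {
        prop <- cur + steps[k] * c(dz1[k], dz2[k])
        f_p <- eval_f(prop, z, sub_xyz, sub_vdw)
        if (f_p >= f_cur || us[k] < exp((f_p - f_cur) / temps[k])) {
          cur <- prop; f_cur <- f_p
          if (f_cur > f_best) { best <- cur; f_best <- f_cur }
        }
      }
      # deterministic polish of the annealing optimum
      opt <- stats::optim(best, function(uv) -eval_f(uv, z, sub_xyz, sub_vdw),
                          method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 500))
      if (-opt$value > f_best) { best <- opt$par; f_best <- -opt$value }
      radii[si] <- max(f_best, 0)
      centers_u[si] <- best[1]; centers_v[si] <- best[2]
      start <- best
    }
  })
  structure(list(z = zs, radius = radii, center_u = centers_u,
                 center_v = centers_v, z_step = z_step,
                 classification = NULL, thresholds = NULL),
            class = "pore_radius_profile")
}

#' Classify a radius profile against thresholds
#'
#' With the default single threshold of 1.2 Angstrom, slices with
#' `r < 1.2` are labelled `"sub_threshold"` and slices with `r >= 1.2`
#' `"open"` (strict inequality, so exactly 1.2 is open). Multiple ascending
#' thresholds produce interval labels `"band_1"` ... `"band_k"`, `"open"`.
#'
#' @param profile a [radius_profile()] result.
#' @param thresholds ascending numeric thresholds (Angstrom), default 1.2.
#' @return the profile with a `classification` character vector attached;
#'   radii are unchanged.
#' @export
classify_profile <- function(profile, thresholds = 1.2) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("thresholds must be sorted strictly ascending")
  }
  labels <- if (length(thresholds) == 1L) {
    c("sub_threshold", "open")
  } else {
    c(paste0("band_", seq_along(thresholds)), "open")
  }
  cls <- as.character(cut(profile$radius, breaks = c(-Inf, thresholds, Inf),
                          labels = labels, right = FALSE))
  cls[is.infinite(profile$radius)] <- "open"
  profile$classification <- cls
  profile$thresholds <- thresholds
  profile
}

#' @export
print.pore_radius_profile <- function(x, ...) {
  cat(sprintf("pore_radius_profile: %d slices over z = [%.1f, %.1f], min r = %.2f A at z = %.1f\n",
              length(x$z), min(x$z), max(x$z), min(x$radius),
              x$z[which.min(x$radius)]))
  if (!is.null(x$classification)) {
    tb <- table(x$classification)
    cat("  classification:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
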