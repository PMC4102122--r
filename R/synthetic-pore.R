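# Pseudo-atomic pore structures with an analytically known radius profile.
# Wall atoms are placed on rings of radius wall_radius(z) + vdw at regular z
# steps, so the maximal inscribed probe radius at z equals the requested
# wall radius; two anchor pseudo-atoms at z = 0 play the role of the S4
# reference residues (Thr117/Thr225 analogues on chains A and B).

#' Specify a synthetic pore geometry
#'
#' The wall radius is a piecewise-linear function of z given as knots; it is
#' clamped to the end values outside the knot range.
#'
#' @param axis_length pore length along z (Angstrom); the wall spans
#'   `[-axis_length/2, +axis_length/2]` around the reference plane z = 0.
#' @param radius_knots two-column matrix/data.frame of `(z, r)` knots,
#'   Angstrom; z strictly increasing, r > 0.
#' @param wall_atom_spacing spacing of wall pseudo-atoms along z and around
#'   each ring (Angstrom), default 1.0.
#' @param wall_vdw_radius vdW radius of wall pseudo-atoms (Angstrom),
#'   default 1.5.
#' @param constriction_zone `(z_lo, z_hi)` of the hydrophobic constriction
#'   (the gate slab of the wetting generator), default `c(-10, -5)` —
#'   matching the gate region 5-10 Angstrom below the S4 reference.
#' @return an object of class `pore_spec`.
#' @export
pore_spec <- function(axis_length, radius_knots, wall_atom_spacing = 1.0,
                      wall_vdw_radius = 1.5, constriction_zone = c(-10, -5)) {
  if (!is_scalar_num(axis_length) || axis_length <= 0) {
    abort("axis_length must be a positive number")
  }
  if (!is_scalar_num(wall_atom_spacing) || wall_atom_spacing <= 0) {
    abort("wall_atom_spacing must be positive")
  }
  if (!is_scalar_num(wall_vdw_radius) || wall_vdw_radius <= 0) {
    abort("wall_vdw_radius must be positive")
  }
  k <- as.matrix(radius_knots)
  if (ncol(k) != 2L) abort("radius_knots must have two columns (z, r)")
  if (nrow(k) >= 2L && any(diff(k[, 1]) <= 0)) {
    abort("radius_knots must be strictly increasing in z")
  }
  if (any(k[, 2] <= 0)) abort("wall radii must be positive")
  if (length(constriction_zone) != 2L || constriction_zone[1] >= constriction_zone[2]) {
    abort("constriction_zone must be (z_lo, z_hi) with z_lo < z_hi")
  }
  structure(list(axis_length = axis_length, radius_knots = k,
                 wall_atom_spacing = wall_atom_spacing,
                 wall_vdw_radius = wall_vdw_radius,
                 constriction_zone = as.numeric(constriction_zone)),
            class = "pore_spec")
}

#' Analytic wall radius of a pore spec
#'
#' @param spec a [pore_spec()].
#' @param z numeric vector of axial positions (Angstrom).
#' @return wall radius at each z (Angstrom), clamped to the knot end values.
#' @export
wall_radius <- function(spec, z) {
  k <- spec$radius_knots
  if (nrow(k) == 1L) return(rep(k[1, 2], length(z)))
  stats::approx(k[, 1], k[, 2], xout = z, rule = 2)$y
}

#' Generate a pseudo-atomic pore structure
#'
#' Wall pseudo-atoms (residue WAL, element C, the spec's vdW radius) sit on
#' rings of radius `wall_radius(z) + wall_vdw_radius` at z steps of
#' `wall_atom_spacing`, each ring with a seeded random angular offset. Two
#' anchor pseudo-atoms (THR 117 chain A, THR 225 chain B, atom OG1) are
#' placed diametrically outside the wall at z = 0; their centroid is the
#' pore-frame origin.
#'
#' @param spec a [pore_spec()].
#' @param seed integer seed (ring phase offsets).
#' @return an [md_structure()] with coordinates; the `vdw` column of wall
#'   atoms equals `spec$wall_vdw_radius`.
#' @export
gen_pore_structure <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "pore_spec"))
  half <- spec$axis_length / 2
  zs <- seq(-half, half, by = spec$wall_atom_spacing)
  with_seed(seed, {
    rings <- lapply(zs, function(z) {
      ring_r <- wall_radius(spec, z) + spec$wall_vdw_radius
      n_ring <- max(8L, ceiling(2 * pi * ring_r / spec$wall_atom_spacing))
      phase <- stats::runif(1, 0, 2 * pi)
      theta <- phase + 2 * pi * (seq_len(n_ring) - 1) / n_ring
      cbind(ring_r * cos(theta), ring_r * sin(theta), z)
    })
    wall_xyz <- do.call(rbind, rings)
  })
  anchor_r <- max(wall_radius(spec, 0)) + spec$wall_vdw_radius + 5
  anchor_xyz <- rbind(c(anchor_r, 0, 0), c(-anchor_r, 0, 0))
  n_wall <- nrow(wall_xyz)
  atoms <- data.frame(
    name = c(rep("W", n_wall), "OG1", "OG1"),
    resname = c(rep("WAL", n_wall), "THR", "THR"),
    resno = c(rep(1L, n_wall), 117L, 225L),
    chain = c(rep("P", n_wall), "A", "B"),
    element = c(rep("C", n_wall), "O", "O"),
    vdw = c(rep(spec$wall_vdw_radius, n_wall), 1.52, 1.52),
    stringsAsFactors = FALSE
  )
  md_structure(atoms, coords = rbind(wall_xyz, anchor_xyz))
}
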