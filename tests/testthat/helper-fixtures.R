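# Shared fixtures, all generated in code.

cylinder_spec <- function(r = 5, length = 30, spacing = 1.0, vdw = 1.5) {
  pore_spec(length, rbind(c(-length / 2, r), c(length / 2, r)),
            wall_atom_spacing = spacing, wall_vdw_radius = vdw)
}

# gentle-sloped hourglass: 4 A at the mouths, 2 A at the constriction
hourglass_spec <- function(r_end = 4, r_mid = 2, length = 30) {
  pore_spec(length, rbind(c(-length / 2, r_end), c(0, r_mid),
                          c(length / 2, r_end)))
}

# small random water-box structure + single-frame "trajectory"
random_water_frame <- function(n = 100, box = 30, seed = 1) {
  withr::with_seed(seed, {
    atoms <- data.frame(
      name = "OW", resname = "SOL", resno = 1000L + seq_len(n), chain = "W",
      element = "O", vdw = 1.52, stringsAsFactors = FALSE
    )
    coords <- matrix(runif(n * 3, -box / 2, box / 2), ncol = 3)
    list(struct = md_structure(atoms, coords = coords), coords = coords)
  })
}

# dense 2D grid search for the maximal-sphere radius at one slice:
# coarse pass then local refinement. Independent of the annealing path.
grid_search_radius <- function(coords, vdw, pore_frame, z, half_width = 2,
                               coarse = 0.1, fine = 0.005) {
  eval_grid <- function(cu, cv, half, step) {
    u <- seq(cu - half, cu + half, by = step)
    v <- seq(cv - half, cv + half, by = step)
    g <- expand.grid(u = u, v = v)
    p0 <- pore_frame$origin + z * pore_frame$axis
    px <- p0[1] + g$u * pore_frame$e1[1] + g$v * pore_frame$e2[1]
    py <- p0[2] + g$u * pore_frame$e1[2] + g$v * pore_frame$e2[2]
    pz <- p0[3] + g$u * pore_frame$e1[3] + g$v * pore_frame$e2[3]
    f <- vapply(seq_len(nrow(g)), function(i) {
      d <- sqrt((coords[, 1] - px[i])^2 + (coords[, 2] - py[i])^2 +
                  (coords[, 3] - pz[i])^2)
      min(d - vdw)
    }, numeric(1))
    list(f = max(f), u = g$u[which.max(f)], v = g$v[which.max(f)])
  }
  c1 <- eval_grid(0, 0, half_width, coarse)
  c2 <- eval_grid(c1$u, c1$v, 2 * coarse, fine)
  max(c1$f, c2$f, 0)
}

# GRO rendering of a structure (nm), for cross-format tests
write_gro_fixture <- function(struct, path) {
  n <- n_atoms(struct)
  a <- struct$atoms
  xyz <- struct$coords / 10
  lines <- c("fixture", sprintf("%5d", n))
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                              a$resno[i] %% 100000L, a$resname[i], a$name[i],
                              i %% 100000L, xyz[i, 1], xyz[i, 2], xyz[i, 3]))
  }
  lines <- c(lines, sprintf("%10.5f%10.5f%10.5f", 10, 10, 10))
  writeLines(lines, path)
  path
}
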