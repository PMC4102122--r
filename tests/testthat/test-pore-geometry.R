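test_that("pore frame maps lab coordinates affinely to pore z", {
  ref_coords <- rbind(c(3, 1, 50), c(-3, -1, 50))
  atoms <- data.frame(name = "OG1", resname = "THR", resno = c(117, 225),
                      chain = c("A", "B"), element = "O", vdw = 1.52)
  st <- md_structure(atoms, coords = ref_coords)
  ref <- select_atoms(st, resname = "THR")
  pf <- compute_pore_frame(st$coords, ref)
  expect_equal(pf$origin, c(0, 0, 50))
  expect_equal(pore_z(matrix(c(5, -2, 44), 1), pf), -6)
  expect_equal(sqrt(sum(pf$axis^2)), 1, tolerance = 1e-9)
})

test_that("principal axis of a straight pore wall is the z axis", {
  st <- gen_pore_structure(cylinder_spec(), seed = 1)
  wall <- select_atoms(st, resname = "WAL")
  ref <- select_atoms(st, resname = "THR")
  pf <- compute_pore_frame(st$coords, ref, axis_mode = "principal",
                           lining_sel = wall)
  expect_lt(abs(abs(pf$axis[3]) - 1), 1e-3)
  # an exactly isotropic selection (octahedron vertices) has no principal axis
  oct <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  atoms <- data.frame(name = "W", resname = "WAL", resno = 1L, chain = "P",
                      element = "C", vdw = 1.5)[rep(1, 6), ]
  iso <- md_structure(atoms, coords = oct)
  sel <- select_atoms(iso, resname = "WAL")
  expect_error(
    compute_pore_frame(iso$coords, sel, axis_mode = "principal",
                       lining_sel = sel),
    "degenerate")
})

test_that("profile matches a dense grid search within 0.05 A", {
  spec <- hourglass_spec()
  st <- gen_pore_structure(spec, seed = 1)
  ref <- select_atoms(st, resname = "THR")
  wall <- select_atoms(st, resname = "WAL")
  pf <- compute_pore_frame(st$coords, ref)
  prof <- radius_profile(st$coords, st, wall, pf, z_range = c(-10, 10),
                         z_step = 2.5, seed = 41)
  wall_xyz <- st$coords[wall$indices, ]
  vdw <- st$atoms$vdw[wall$indices]
  for (i in seq_along(prof$z)) {
    oracle <- grid_search_radius(wall_xyz, vdw, pf, prof$z[i])
    expect_lt(abs(prof$radius[i] - oracle), 0.05)
  }
  # hourglass minimum sits at the constriction, within one z step
  full <- radius_profile(st$coords, st, wall, pf, z_range = c(-12, 12),
                         z_step = 0.5, seed = 42)
  expect_lte(abs(full$z[which.min(full$radius)]), 0.5)
})

test_that("more proposals never lose more than 0.05 A against the oracle", {
  spec <- hourglass_spec()
  st <- gen_pore_structure(spec, seed = 1)
  ref <- select_atoms(st, resname = "THR")
  wall <- select_atoms(st, resname = "WAL")
  pf <- compute_pore_frame(st$coords, ref)
  lo <- radius_profile(st$coords, st, wall, pf, z_range = c(-6, 6),
                       z_step = 2, n_proposals = 2000, seed = 43)
  hi <- radius_profile(st$coords, st, wall, pf, z_range = c(-6, 6),
                       z_step = 2, n_proposals = 4000, seed = 43)
  expect_true(all(hi$radius - lo$radius > -0.05))
})

test_that("profile is equivariant under rigid transformation", {
  st <- gen_pore_structure(hourglass_spec(), seed = 1)
  ref <- select_atoms(st, resname = "THR")
  wall <- select_atoms(st, resname = "WAL")
  pf <- compute_pore_frame(st$coords, ref)
  prof <- radius_profile(st$coords, st, wall, pf, z_range = c(-8, 8),
                         z_step = 2, seed = 44)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(13, -4, 27)
  coords2 <- sweep(st$coords %*% t(R), 2, -shift)
  pf2 <- compute_pore_frame(coords2, ref)
  prof2 <- radius_profile(coords2, st, wall, pf2, z_range = c(-8, 8),
                          z_step = 2, seed = 44)
  expect_lt(max(abs(prof2$radius - prof$radius)), 1e-3)
})

test_that("removing an atom never shrinks the true slice radius", {
  st <- gen_pore_structure(cylinder_spec(r = 3, length = 12), seed = 1)
  ref <- select_atoms(st, resname = "THR")
  wall <- select_atoms(st, resname = "WAL")
  pf <- compute_pore_frame(st$coords, ref)
  wall_xyz <- st$coords[wall$indices, ]
  vdw <- st$atoms$vdw[wall$indices]
  for (z in c(-4, 0, 4)) {
    full <- grid_search_radius(wall_xyz, vdw, pf, z)
    reduced <- grid_search_radius(wall_xyz[-1, ], vdw[-1], pf, z)
    expect_gte(reduced, full - 1e-9)
  }
})

test_that("classification uses a strict sub-threshold inequality at 1.2 A", {
  prof <- structure(list(z = c(0, 1, 2), radius = c(1.19, 1.2, 5),
                         z_step = 1, classification = NULL, thresholds = NULL),
                    class = "pore_radius_profile")
  cls <- classify_profile(prof)
  expect_equal(cls$classification, c("sub_threshold", "open", "open"))
  st <- gen_pore_structure(cylinder_spec(), seed = 1)
  ref <- select_atoms(st, resname = "THR")
  pf <- compute_pore_frame(st$coords, ref)
  wide <- radius_profile(st$coords, st, select_atoms(st, resname = "WAL"),
                         pf, z_range = c(-10, 10), z_step = 2, seed = 45)
  expect_true(all(classify_profile(wide)$classification == "open"))
})

test_that("a slice with no atoms in reach reports an infinite radius", {
  st <- gen_pore_structure(cylinder_spec(r = 3, length = 10), seed = 1)
  ref <- select_atoms(st, resname = "THR")
  pf <- compute_pore_frame(st$coords, ref)
  wall <- select_atoms(st, resname = "WAL")
  expect_warning(
    prof <- radius_profile(st$coords, st, wall, pf, z_range = c(30, 30),
                           z_step = 1, cutoff = 5, seed = 46),
    "Inf")
  expect_true(is.infinite(prof$radius[1]))
})
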