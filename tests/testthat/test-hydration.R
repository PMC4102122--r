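make_frame_at_z <- function(zs) {
  n <- length(zs)
  atoms <- data.frame(name = "OW", resname = "SOL", resno = 1000L + seq_len(n),
                      chain = "W", element = "O", vdw = 1.52)
  st <- md_structure(atoms, coords = cbind(0, 0, zs))
  list(struct = st, sel = select_atoms(st, preset = "water_oxygens"))
}

identity_pf <- function() {
  compute_pore_frame(rbind(c(1, 0, 0), c(-1, 0, 0)),
                     structure(list(indices = 1:2, label = "ref"),
                               class = "atom_selection"))
}

test_that("slab counting uses half-open bounds [z_lo, z_hi)", {
  fx <- make_frame_at_z(c(-6, -7, -12, -5, -10))
  pf <- identity_pf()
  # -5 excluded (upper bound), -10 included (lower bound)
  expect_equal(count_waters_in_slab(fx$struct$coords, fx$sel, pf), 3)
  expect_equal(count_waters_in_slab(fx$struct$coords, fx$sel, pf,
                                    slab_region(-8, -5)), 2)
})

test_that("slab counts equal a brute-force linear scan on random fixtures", {
  pf <- identity_pf()
  region <- slab_region(-10, -5, radial_cutoff = 6)
  for (seed in 1:20) {
    fx <- random_water_frame(n = 200, box = 30, seed = seed)
    sel <- select_atoms(fx$struct, preset = "water_oxygens")
    fast <- count_waters_in_slab(fx$coords, sel, pf, region)
    slow <- 0L
    for (i in sel$indices) {
      p <- fx$coords[i, ]
      if (p[3] >= -10 && p[3] < -5 && sqrt(p[1]^2 + p[2]^2) < 6) slow <- slow + 1L
    }
    expect_identical(fast, slow)
  }
})

test_that("occupancy series matches strided subsampling and generator truth", {
  spec <- pore_spec(24, rbind(c(-12, 4), c(0, 2.5), c(12, 4)),
                    wall_atom_spacing = 1.5)
  gen <- gen_wetting_trajectory(
    spec, wetting_params(k_dry = 0, k_wet = 1, lambda_full = 12,
                         n_frames = 600, seed = 51))
  ws <- select_atoms(gen$structure, preset = "water_oxygens")
  ref <- select_atoms(gen$structure, resname = "THR")
  s1 <- occupancy_series(gen$trajectory, ws, ref)
  s2 <- occupancy_series(gen$trajectory, ws, ref, stride = 2)
  expect_equal(s2$counts, s1$counts[seq(1, 600, 2)])
  expect_lt(abs(mean(s1$counts) - 12), 3 * sqrt(12 / 600))
})

test_that("occupancy histogram normalizes and pools by concatenation", {
  ser <- structure(list(times = (0:3) / 10, counts = c(0L, 0L, 1L, 2L),
                        region = slab_region()), class = "occupancy_series")
  h <- occupancy_histogram(ser)
  expect_equal(h$count_values, 0:2)
  expect_equal(h$probabilities, c(0.5, 0.25, 0.25))
  expect_equal(sum(h$probabilities), 1)
  h2 <- occupancy_histogram(list(ser, ser))
  expect_equal(h2$probabilities, h$probabilities)
  expect_equal(h2$n_frames, 8)
  # fraction_zero equals histogram P(0) exactly
  expect_identical(summarize_occupancy(ser)$fraction_zero, h$probabilities[1])
})

test_that("occupancy summary reports mu, dry fraction and dwell episodes", {
  ser <- structure(list(times = (0:3) / 10, counts = c(0L, 0L, 1L, 2L),
                        region = slab_region()), class = "occupancy_series")
  sm <- summarize_occupancy(ser)
  expect_equal(sm$mu, 0.75)
  expect_equal(sm$fraction_zero, 0.5)
  dry <- sm$dwell[sm$dwell$state == "dry", ]
  expect_equal(nrow(dry), 1)
  expect_equal(dry$duration, 0.2)
  expect_true(dry$censored)  # touches the series start
  same <- summarize_occupancy(ser, partner = ser)
  expect_equal(same$delta_mu, 0)
})

test_that("delta mu between wet and dry generators recovers lambda", {
  spec <- pore_spec(24, rbind(c(-12, 4), c(0, 2.5), c(12, 4)),
                    wall_atom_spacing = 1.5)
  wet <- gen_wetting_trajectory(
    spec, wetting_params(k_dry = 0, k_wet = 1, lambda_full = 12,
                         n_frames = 500, seed = 52))
  dry <- gen_wetting_trajectory(
    spec, wetting_params(k_dry = 1, k_wet = 0, lambda_full = 12,
                         n_frames = 500, seed = 53, init_state = "dry"))
  series_of <- function(gen) {
    occupancy_series(gen$trajectory,
                     select_atoms(gen$structure, preset = "water_oxygens"),
                     select_atoms(gen$structure, resname = "THR"))
  }
  sm <- summarize_occupancy(series_of(wet), partner = series_of(dry))
  expect_lt(abs(sm$delta_mu - 12), 3 * sm$se_delta_mu)
  # mismatched frame spacing is refused
  short <- series_of(wet)
  short$times <- short$times * 2
  expect_error(summarize_occupancy(short, partner = series_of(dry)),
               "frame spacing")
})

test_that("occupancy is invariant under rigid motion of frames and references", {
  fx <- random_water_frame(n = 150, box = 24, seed = 54)
  ref_xyz <- rbind(c(2, 0, 5), c(-2, 0, 5))
  atoms <- rbind(fx$struct$atoms,
                 data.frame(name = "OG1", resname = "THR", resno = c(117, 225),
                            chain = c("A", "B"), element = "O", vdw = 1.52))
  coords <- rbind(fx$coords, ref_xyz)
  st <- md_structure(atoms, coords = coords)
  ws <- select_atoms(st, preset = "water_oxygens")
  ref <- select_atoms(st, resname = "THR")
  pf <- compute_pore_frame(coords, ref)
  n0 <- count_waters_in_slab(coords, ws, pf)
  shifted <- sweep(coords, 2, c(-7, 3, 11))
  pf2 <- compute_pore_frame(shifted, ref)
  expect_identical(count_waters_in_slab(shifted, ws, pf2), n0)
})

test_that("density grid conserves deposits and normalizes bulk to one", {
  fx <- random_water_frame(n = 200, box = 20, seed = 55)
  nfr <- 20
  coords <- array(runif(200 * 3 * nfr, -10, 10), dim = c(200, 3, nfr))
  traj <- md_trajectory(coords, (0:(nfr - 1)) * 0.1, c(20, 20, 20))
  sel <- select_atoms(fx$struct, preset = "water_oxygens")
  g <- water_density_grid(traj, sel, origin = c(-10, -10, -10),
                          dims = c(40, 40, 40), spacing = 0.5,
                          bulk_density = 200 / 20^3)
  expect_identical(g$binned + g$overflow, nfr * 200)
  expect_equal(mean(g$normalized), 1, tolerance = 0.02)
  # empty region stays zero; shrunken grid warns and tallies overflow
  expect_warning(
    g2 <- water_density_grid(traj, sel, origin = c(-10, -10, -10),
                             dims = c(20, 40, 40), spacing = 0.5),
    "overflow")
  expect_identical(g2$binned + g2$overflow, nfr * 200)
  expect_gt(g2$overflow, 0)
})
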