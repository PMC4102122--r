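# Two-state (telegraph) wetting/dewetting trajectories with known ground
# truth. The gate slab alternates between a wet state, holding
# Poisson(lambda_full) water oxygens, and a dry state holding none, driven
# by a continuous-time two-state Markov chain sampled at the frame interval.
# The rest of the pore lumen and a bulk reservoir above the pore carry a
# constant background of waters at bulk density, giving density-map
# normalization a known truth.

#' Parameters of the synthetic wetting process
#'
#' @param k_dry wet-to-dry transition rate (events/ns).
#' @param k_wet dry-to-wet transition rate (events/ns).
#' @param lambda_full expected water count in the gate slab when wet;
#'   default 12 (the hydrated inner-pore count used for the mutant PMF
#'   starting structure).
#' @param frame_dt frame interval (ns), default 0.1 (the analysis stride
#'   used throughout).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @param init_state `"auto"` (stationary draw; forced wet/dry when a rate
#'   is zero), `"wet"`, `"dry"` or `"stationary"`.
#' @return an object of class `wetting_params`.
#' @export
wetting_params <- function(k_dry, k_wet, lambda_full = 12, frame_dt = 0.1,
                           n_frames = 1000L, seed = 1L,
                           init_state = c("auto", "stationary", "wet", "dry")) {
  init_state <- match.arg(init_state)
  if (k_dry < 0 || k_wet < 0) abort("rates must be non-negative")
  if (lambda_full < 0) abort("lambda_full must be non-negative")
  if (frame_dt <= 0) abort("frame_dt must be positive")
  if (n_frames <= 0) abort("n_frames must be positive")
  structure(list(k_dry = k_dry, k_wet = k_wet, lambda_full = lambda_full,
                 frame_dt = frame_dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed), init_state = init_state),
            class = "wetting_params")
}

#' Stationary dry fraction of the telegraph process
#' @param params a [wetting_params()].
#' @return `k_dry / (k_dry + k_wet)` (NA if both rates are zero).
#' @export
stationary_dry_fraction <- function(params) {
  tot <- params$k_dry + params$k_wet
  if (tot == 0) return(NA_real_)
  params$k_dry / tot
}

# Exact skeleton of the 2-state CTMC at step dt. Returns logical wet[1..n].
# Caller is responsible for seeding.
simulate_telegraph_states <- function(params) {
  n <- params$n_frames
  kd <- params$k_dry; kw <- params$k_wet; dt <- params$frame_dt
  lam <- kd + kw
  init <- params$init_state
  if (init == "auto") {
    init <- if (kd == 0) "wet" else if (kw == 0) "dry" else "stationary"
  }
  wet0 <- switch(init,
                 wet = TRUE,
                 dry = FALSE,
                 stationary = {
                   if (lam == 0) abort("stationary initial state undefined when both rates are zero")
                   stats::runif(1) < kw / lam
                 })
  if (lam == 0) return(rep(wet0, n))
  e <- exp(-lam * dt)
  pi_w <- kw / lam
  p_ww <- pi_w + (1 - pi_w) * e     # P(wet -> wet)
  p_dw <- pi_w * (1 - e)            # P(dry -> wet)
  wet <- logical(n)
  wet[1] <- wet0
  u <- stats::runif(n - 1L)
  for (i in seq_len(n - 1L)) {
    wet[i + 1L] <- u[i] < (if (wet[i]) p_ww else p_dw)
  }
  wet
}

# Uniform points in the solid of revolution of radius r(z) over z-intervals.
# intervals: 2-column matrix of (lo, hi); n points. Caller seeds.
sample_in_lumen <- function(spec, intervals, n) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  dz <- 0.05
  grids <- lapply(seq_len(nrow(intervals)), function(i) {
    lo <- intervals[i, 1]; hi <- intervals[i, 2]
    if (hi - lo <= 0) return(NULL)
    z <- seq(lo + dz / 2, hi - dz / 2, by = dz)
    z
  })
  zg <- unlist(grids)
  w <- wall_radius(spec, zg)^2
  cell <- sample.int(length(zg), n, replace = TRUE, prob = w)
  z <- zg[cell] + stats::runif(n, -dz / 2, dz / 2)
  r <- wall_radius(spec, z) * sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(r * cos(th), r * sin(th), z)
}

# volume of the solid of revolution over z-intervals
lumen_volume <- function(spec, intervals) {
  dz <- 0.01
  tot <- 0
  for (i in seq_len(nrow(intervals))) {
    lo <- intervals[i, 1]; hi <- intervals[i, 2]
    if (hi - lo <= 0) next
    z <- seq(lo + dz / 2, hi - dz / 2, by = dz)
    tot <- tot + sum(pi * wall_radius(spec, z)^2) * dz
  }
  tot
}

#' Generate a synthetic wetting/dewetting trajectory
#'
#' Simulates the telegraph wet/dry state sequence, places
#' `Poisson(lambda_full)` water oxygens uniformly in the gate slab in wet
#' frames (none in dry frames), a constant background of waters at
#' `bulk_density` in the rest of the pore lumen and in a bulk box above the
#' pore, and returns the trajectory together with the hidden state sequence.
#' The total atom count is fixed: slab waters not in use in a frame are
#' parked on a reservoir plane far below the pore.
#'
#' @param spec a [pore_spec()]; its `constriction_zone` is the gate slab.
#' @param params a [wetting_params()].
#' @param bulk_depth depth of the bulk water box above the pore (Angstrom),
#'   default 10.
#' @param bulk_density background water number density (per cubic Angstrom),
#'   default 0.0334.
#' @param background if `FALSE`, omit pore-background and bulk waters
#'   (gate-slab waters only).
#' @return list with `trajectory` ([md_trajectory()]), `states` (logical,
#'   `TRUE` = wet), `structure` ([md_structure()]) and `params`.
#' @export
gen_wetting_trajectory <- function(spec, params, bulk_depth = 10,
                                   bulk_density = .bulk_density_default,
                                   background = TRUE) {
  stopifnot(inherits(spec, "pore_spec"), inherits(params, "wetting_params"))
  half <- spec$axis_length / 2
  cz <- spec$constriction_zone
  slab <- c(max(cz[1], -half), min(cz[2], half))
  if (slab[1] >= slab[2]) abort("constriction_zone lies outside the pore")

  pore_struct <- gen_pore_structure(spec, seed = params$seed)
  n_scaffold <- n_atoms(pore_struct)
  max_r <- max(wall_radius(spec, seq(-half, half, by = 0.5)))
  box_xy <- 2 * ceiling(max_r + spec$wall_vdw_radius + 6)

  bg_intervals <- rbind(c(-half, slab[1]), c(slab[2], half))
  n_bg <- if (background) round(bulk_density * lumen_volume(spec, bg_intervals)) else 0L
  n_bulk <- if (background) round(bulk_density * box_xy^2 * bulk_depth) else 0L
  lam <- params$lambda_full
  n_slab_max <- max(1L, ceiling(lam + 8 * sqrt(lam) + 8))
  n_water <- n_bg + n_bulk + n_slab_max

  water_atoms <- data.frame(
    name = "OW", resname = "SOL",
    resno = 1000L + seq_len(n_water), chain = "W", element = "O", vdw = 1.52,
    stringsAsFactors = FALSE
  )
  struct <- md_structure(rbind(pore_struct$atoms, water_atoms))
  n_total <- n_scaffold + n_water
  nf <- params$n_frames
  park_z <- -(half + 20)
  box <- c(box_xy, box_xy, spec$axis_length + bulk_depth + 50)

  coords <- array(NA_real_, dim = c(n_total, 3, nf))
  states <- NULL
  with_seed(params$seed, {
    states <- simulate_telegraph_states(params)
    scaffold <- pore_struct$coords
    slab_int <- matrix(slab, ncol = 2)
    for (f in seq_len(nf)) {
      n_slab <- if (states[f]) min(stats::rpois(1, lam), n_slab_max) else 0L
      slab_xyz <- sample_in_lumen(spec, slab_int, n_slab)
      parked <- n_slab_max - n_slab
      park_xyz <- if (parked > 0) {
        cbind(stats::runif(parked, -box_xy / 2, box_xy / 2),
              stats::runif(parked, -box_xy / 2, box_xy / 2),
              rep(park_z, parked))
      } else matrix(numeric(0), ncol = 3)
      bg_xyz <- if (n_bg > 0) sample_in_lumen(spec, bg_intervals, n_bg) else
        matrix(numeric(0), ncol = 3)
      bulk_xyz <- if (n_bulk > 0) {
        cbind(stats::runif(n_bulk, -box_xy / 2, box_xy / 2),
              stats::runif(n_bulk, -box_xy / 2, box_xy / 2),
              stats::runif(n_bulk, half, half + bulk_depth))
      } else matrix(numeric(0), ncol = 3)
      coords[, , f] <- rbind(scaffold, slab_xyz, park_xyz, bg_xyz, bulk_xyz)
    }
  })
  times <- (seq_len(nf) - 1L) * params$frame_dt
  list(trajectory = md_trajectory(coords, times, box),
       states = states, structure = struct, params = params)
}

#' Recover telegraph rates from a sampled state sequence
#'
#' A state sequence observed at interval `dt` is the exact discrete skeleton
#' of the two-state chain; the self-transition probabilities determine the
#' rates in closed form, which avoids the O(dt) bias of naive mean run
#' lengths. Standard errors come from the delta method on the binomial
#' transition counts.
#'
#' @param wet logical state sequence (`TRUE` = wet) or an integer count
#'   series (dry taken as count == 0).
#' @param dt sampling interval (ns).
#' @return list with `k_dry`, `k_wet` (events/ns), `mean_dwell_wet`,
#'   `mean_dwell_dry` (ns, `1/k`), `dry_fraction`, and standard errors
#'   `se_dwell_wet`, `se_dwell_dry`, `se_dry_fraction`.
#' @export
fit_telegraph <- function(wet, dt) {
  if (is.numeric(wet)) wet <- wet > 0
  n <- length(wet)
  if (n < 2L) abort("need at least 2 frames")
  from <- wet[-n]; to <- wet[-1L]
  n_w <- sum(from); n_d <- sum(!from)
  if (n_w == 0L || n_d == 0L) abort("sequence never changes state; rates unidentifiable")
  p_ww <- sum(from & to) / n_w
  p_dd <- sum(!from & !to) / n_d
  rates_from_p <- function(p_ww, p_dd) {
    s <- p_ww + p_dd - 1
    if (s <= 0 || s >= 1) return(c(NA_real_, NA_real_))
    lam <- -log(s) / dt
    pi_d <- (1 - p_ww) / (1 - s)
    c(k_dry = pi_d * lam, k_wet = (1 - pi_d) * lam)
  }
  k <- rates_from_p(p_ww, p_dd)
  # delta-method SEs from Var(p_hat) = p(1-p)/n
  eps <- 1e-6
  g_ww <- (rates_from_p(p_ww + eps, p_dd) - rates_from_p(p_ww - eps, p_dd)) / (2 * eps)
  g_dd <- (rates_from_p(p_ww, p_dd + eps) - rates_from_p(p_ww, p_dd - eps)) / (2 * eps)
  v_ww <- p_ww * (1 - p_ww) / n_w
  v_dd <- p_dd * (1 - p_dd) / n_d
  var_k <- g_ww^2 * v_ww + g_dd^2 * v_dd
  dry_frac <- mean(!wet)
  lam <- sum(k)
  rho <- exp(-lam * dt)
  # autocorrelation-corrected SE for the time-average dry fraction
  se_df <- sqrt(dry_frac * (1 - dry_frac) / n * (1 + rho) / (1 - rho))
  list(k_dry = unname(k[1]), k_wet = unname(k[2]),
       mean_dwell_wet = 1 / unname(k[1]), mean_dwell_dry = 1 / unname(k[2]),
       dry_fraction = dry_frac,
       se_dwell_wet = sqrt(unname(var_k[1])) / unname(k[1])^2,
       se_dwell_dry = sqrt(unname(var_k[2])) / unname(k[2])^2,
       se_dry_fraction = se_df)
}
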