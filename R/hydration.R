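# Water occupancy of the gate slab: per-frame counts, occupancy histograms,
# mean occupancy mu and mutant-minus-WT delta mu, and dry/wet dwell
# episodes. The default slab is the region 5-10 Angstrom below the S4
# reference, i.e. pore z in [-10, -5): the stated open bounds would be
# empty as printed, and the half-open convention lets adjacent slabs tile
# without double counting.

#' Define a slab region along the pore axis
#'
#' @param z_lo,z_hi slab bounds in pore coordinates (Angstrom); waters count
#'   when `z_lo <= z < z_hi`. Default `(-10, -5)`.
#' @param radial_cutoff optional cylindrical cap: waters also require
#'   in-plane distance from the axis below this value (Angstrom). Default
#'   `NULL` (z bounds only, matching the literal region definition).
#' @return an object of class `slab_region`.
#' @export
slab_region <- function(z_lo = -10, z_hi = -5, radial_cutoff = NULL) {
  if (z_lo >= z_hi) abort("slab requires z_lo < z_hi")
  if (!is.null(radial_cutoff) && radial_cutoff <= 0) {
    abort("radial_cutoff must be positive")
  }
  structure(list(z_lo = z_lo, z_hi = z_hi, radial_cutoff = radial_cutoff),
            class = "slab_region")
}

#' Count water oxygens inside the gate slab for one frame
#'
#' @param frame a frame from [get_frame()] or a coordinate matrix.
#' @param water_sel `atom_selection` of water oxygens.
#' @param pore_frame a [compute_pore_frame()] result.
#' @param region a [slab_region()].
#' @return integer count (nH2O).
#' @export
count_waters_in_slab <- function(frame, water_sel, pore_frame,
                                 region = slab_region()) {
  z <- pore_z(frame, pore_frame, indices = water_sel$indices)
  inside <- z >= region$z_lo & z < region$z_hi
  if (!is.null(region$radial_cutoff)) {
    rho <- pore_rho(frame, pore_frame, indices = water_sel$indices)
    inside <- inside & rho < region$radial_cutoff
  }
  sum(inside)
}

#' Water-occupancy time series over a trajectory
#'
#' Recomputes the pore frame from the reference selection at every retained
#' frame, then counts slab waters.
#'
#' @param traj an [md_trajectory()].
#' @param water_sel water-oxygen selection.
#' @param ref_sel reference selection defining z = 0.
#' @param region a [slab_region()].
#' @param stride keep every `stride`-th frame, default 1.
#' @param axis_mode passed to [compute_pore_frame()].
#' @param lining_sel passed to [compute_pore_frame()].
#' @return an object of class `occupancy_series`: `times` (ns), `counts`
#'   (integer), `region`.
#' @export
occupancy_series <- function(traj, water_sel, ref_sel, region = slab_region(),
                             stride = 1L, axis_mode = "fixed_z",
                             lining_sel = NULL) {
  keep <- seq(1L, n_frames(traj), by = stride)
  counts <- integer(length(keep))
  for (j in seq_along(keep)) {
    fr <- get_frame(traj, keep[j])
    pf <- compute_pore_frame(fr, ref_sel, axis_mode = axis_mode,
                             lining_sel = lining_sel)
    counts[j] <- count_waters_in_slab(fr, water_sel, pf, region)
  }
  structure(list(times = traj$times[keep], counts = counts, region = region),
            class = "occupancy_series")
}

#' @export
print.occupancy_series <- function(x, ...) {
  cat(sprintf("occupancy_series: %d frames, mu = %.2f, fraction dry = %.2f\n",
              length(x$counts), mean(x$counts), mean(x$counts == 0)))
  invisible(x)
}

series_dt <- function(series) {
  if (length(series$times) < 2L) return(NA_real_)
  stats::median(diff(series$times))
}

#' Normalized occupancy histogram
#'
#' Accepts one series or a list of series (pooled runs are concatenated
#' before normalization).
#'
#' @param series an `occupancy_series` or a list of them.
#' @return an object of class `occupancy_histogram`: `count_values`
#'   (0..max), `probabilities` (sum to 1), `n_frames`.
#' @export
occupancy_histogram <- function(series) {
  counts <- if (inherits(series, "occupancy_series")) {
    series$counts
  } else {
    unlist(lapply(series, function(s) s$counts))
  }
  if (length(counts) == 0L) abort("cannot build a histogram from an empty series")
  values <- 0:max(counts)
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  p <- tab / sum(tab)
  stopifnot(abs(sum(p) - 1) < 1e-12)
  structure(list(count_values = values, probabilities = p,
                 n_frames = length(counts)),
            class = "occupancy_histogram")
}

#' Summarize a water-occupancy series
#'
#' Reports the mean occupancy mu, the fraction of dry (count 0) frames,
#' dwell episodes (maximal runs of dry/wet frames, durations in ns,
#' boundary episodes flagged censored), and, when a partner series is given,
#' `delta_mu = mu(self) - mu(partner)` with a standard error from the two
#' series' autocorrelation-naive variances.
#'
#' @param series an `occupancy_series` (e.g. the mutant).
#' @param partner optional second series (e.g. the WT); must share the frame
#'   spacing.
#' @return an object of class `occupancy_summary` with `mu`,
#'   `fraction_zero`, `dwell` (data.frame: state, start_time, duration,
#'   censored), and optionally `delta_mu`, `se_delta_mu`.
#' @export
summarize_occupancy <- function(series, partner = NULL) {
  if (length(series$counts) == 0L) abort("series is empty")
  dt <- series_dt(series)
  mu <- mean(series$counts)
  fraction_zero <- mean(series$counts == 0)
  r <- rle(series$counts == 0)
  n_ep <- length(r$lengths)
  starts <- cumsum(c(1L, r$lengths[-n_ep]))
  dwell <- data.frame(
    state = ifelse(r$values, "dry", "wet"),
    start_time = series$times[starts],
    duration = r$lengths * dt,
    censored = seq_len(n_ep) %in% c(1L, n_ep),
    stringsAsFactors = FALSE
  )
  out <- list(mu = mu, fraction_zero = fraction_zero, dwell = dwell)
  if (!is.null(partner)) {
    dt_p <- series_dt(partner)
    if (is.finite(dt) && is.finite(dt_p) && abs(dt - dt_p) > 1e-9) {
      abort("partner series frame spacing (%.4g ns) differs from self (%.4g ns)",
            dt_p, dt)
    }
    out$delta_mu <- mu - mean(partner$counts)
    out$se_delta_mu <- sqrt(stats::var(series$counts) / length(series$counts) +
                              stats::var(partner$counts) / length(partner$counts))
  }
  structure(out, class = "occupancy_summary")
}

#' @export
print.occupancy_summary <- function(x, ...) {
  cat(sprintf("occupancy_summary: mu = %.3f, fraction dry = %.3f, %d dwell episodes\n",
              x$mu, x$fraction_zero, nrow(x$dwell)))
  if (!is.null(x$delta_mu)) {
    cat(sprintf("  delta_mu (self - partner) = %.3f +/- %.3f\n",
                x$delta_mu, x$se_delta_mu))
  }
  invisible(x)
}
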