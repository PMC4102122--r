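# 1D weighted histogram analysis method (WHAM) for umbrella-sampling
# windows with harmonic bias, plus PMF construction and WT/mutant
# comparison. Self-consistent iteration:
#   P(z_b) = sum_i n_i(z_b) / sum_i N_i exp((F_i - U_i(z_b)) / kT)
#   exp(-F_i / kT) = sum_b P(z_b) exp(-U_i(z_b) / kT)
# with the gauge F_1 = 0 and P renormalized each sweep.

# Boltzmann constant, kJ mol-1 K-1
.kB <- 0.0083145

#' Thermal energy kT for a temperature
#' @param temperature kelvin; 310 K gives the default 2.577 kJ mol-1.
#' @return kT in kJ mol-1.
#' @export
kT_from_temperature <- function(temperature) .kB * temperature

#' Construct an umbrella window
#'
#' @param center restraint center z_i (Angstrom).
#' @param k harmonic force constant (kJ mol-1 A-2); the reference protocol
#'   uses 10.
#' @param kT thermal energy (kJ mol-1).
#' @param samples numeric vector of z samples (Angstrom).
#' @param time_ps optional sample times (ps).
#' @return an object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, k, kT, samples, time_ps = NULL) {
  if (k < 0) abort("force constant must be non-negative")
  if (kT <= 0) abort("kT must be positive")
  if (length(samples) == 0L) abort("window must contain at least one sample")
  if (is.null(time_ps)) time_ps <- (seq_along(samples) - 1L) * 0.02
  structure(list(center = center, k = k, kT = kT,
                 samples = as.numeric(samples), n = length(samples),
                 time_ps = time_ps),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("umbrella_window: center %.2f A, k %.3g kJ/mol/A^2, %d samples\n",
              x$center, x$k, x$n))
  invisible(x)
}

#' Harmonic bias energy of a window at position z
#' @param window an [umbrella_window()].
#' @param z numeric vector (Angstrom).
#' @return `0.5 * k * (z - center)^2` in kJ mol-1.
#' @export
bias_energy <- function(window, z) 0.5 * window$k * (z - window$center)^2

#' Write an umbrella window to disk
#'
#' Two-column TSV (`time_ps`, `z_A`) plus a YAML sidecar
#' `<path>.meta.yaml` carrying center, force constant and kT.
#'
#' @param window an [umbrella_window()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_umbrella_window <- function(window, path) {
  df <- data.frame(time_ps = fmt_num(window$time_ps),
                   z_A = fmt_num(window$samples))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(center = window$center, force_constant = window$k, kT = window$kT)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read an umbrella window written by [write_umbrella_window()]
#' @param path TSV path (sidecar `<path>.meta.yaml` must exist).
#' @return an [umbrella_window()].
#' @export
read_umbrella_window <- function(path) {
  meta_path <- paste0(path, ".meta.yaml")
  if (!file.exists(path)) abort("window file not found: %s", path)
  if (!file.exists(meta_path)) abort("window metadata not found: %s", meta_path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- yaml::read_yaml(meta_path)
  umbrella_window(center = meta$center, k = meta$force_constant, kT = meta$kT,
                  samples = df$z_A, time_ps = df$time_ps)
}

#' Solve WHAM over a set of umbrella windows
#'
#' @param windows list of [umbrella_window()]; all must share the same kT.
#' @param bin_width histogram bin width (Angstrom), default 0.1.
#' @param tolerance convergence threshold on `max |delta F_i|`
#'   (kJ mol-1), default 1e-6.
#' @param max_iter iteration cap, default 1e5; non-convergence returns the
#'   best iterate flagged `converged = FALSE`.
#' @param bin_range optional `(lo, hi)` overriding the automatic bin range.
#' @return an object of class `wham_solution` with `bin_centers`, `P`
#'   (sums to 1 over sampled bins), `F` (window free energies, kJ mol-1,
#'   gauge `F[1] = 0`), `mask` (TRUE for sampled bins), `iterations`,
#'   `converged`, `residuals` (per-iteration `max |delta F|`), `kT`,
#'   `bin_width`.
#' @export
wham <- function(windows, bin_width = 0.1, tolerance = 1e-6, max_iter = 1e5,
                 bin_range = NULL) {
  if (length(windows) == 0L) abort("need at least one window")
  kTs <- vapply(windows, function(w) w$kT, numeric(1))
  if (max(kTs) - min(kTs) > 1e-9) abort("all windows must share the same kT")
  kT <- kTs[1]
  all_z <- unlist(lapply(windows, function(w) w$samples))
  if (is.null(bin_range)) {
    bin_range <- c(floor(min(all_z) / bin_width) * bin_width,
                   ceiling(max(all_z) / bin_width) * bin_width)
  }
  edges <- seq(bin_range[1], bin_range[2], by = bin_width)
  if (edges[length(edges)] < bin_range[2]) edges <- c(edges, bin_range[2])
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(centers)
  nw <- length(windows)

  n_ib <- vapply(windows, function(w) {
    h <- findInterval(w$samples, edges, rightmost.closed = TRUE)
    h[h < 1L] <- 1L; h[h > nb] <- nb
    tabulate(h, nbins = nb)
  }, numeric(nb))
  n_ib <- matrix(n_ib, nrow = nb)
  N_i <- colSums(n_ib)
  n_tot <- rowSums(n_ib)

  if (nw > 1L) {
    occ <- n_ib > 0
    shared <- crossprod(occ)        # windows x windows shared-bin counts
    diag(shared) <- 0
    isolated <- which(rowSums(shared) == 0)
    if (length(isolated)) {
      abort("window(s) %s share no histogram bins with any other window",
            paste(isolated, collapse = ", "))
    }
  }

  sampled <- n_tot > 0
  interior_empty <- !sampled &
    seq_len(nb) > min(which(sampled)) & seq_len(nb) < max(which(sampled))
  if (any(interior_empty)) {
    warn("%d empty bin(s) interior to the sampled range; masked from the PMF",
         sum(interior_empty))
  }

  # bias energies per bin per window, as Boltzmann factors
  U_ib <- vapply(windows, function(w) bias_energy(w, centers), numeric(nb))
  U_ib <- matrix(U_ib, nrow = nb)
  c_ib <- exp(-U_ib / kT)

  Fi <- numeric(nw)
  residuals <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    fi <- exp(Fi / kT)
    denom <- c_ib %*% (N_i * fi)
    P <- n_tot / pmax(denom, .Machine$double.xmin)
    P[!sampled] <- 0
    P <- P / sum(P)
    stopifnot(abs(sum(P) - 1) < 1e-12)
    zi <- crossprod(c_ib, P)        # sum_b P_b exp(-U_ib/kT), per window
    F_new <- -kT * log(pmax(zi, .Machine$double.xmin))
    F_new <- F_new - F_new[1]
    res <- max(abs(F_new - Fi))
    residuals <- c(residuals, res)
    Fi <- as.numeric(F_new)
    iterations <- it
    if (res < tolerance) { converged <- TRUE; break }
  }
  if (!converged) {
    warn("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
         iterations, residuals[length(residuals)])
  }
  fi <- exp(Fi / kT)
  P <- n_tot / pmax(as.numeric(c_ib %*% (N_i * fi)), .Machine$double.xmin)
  P[!sampled] <- 0
  P <- P / sum(P)
  structure(list(bin_centers = centers, P = as.numeric(P), F = Fi,
                 mask = sampled, iterations = iterations,
                 converged = converged, residuals = residuals,
                 tolerance = tolerance, kT = kT, bin_width = bin_width,
                 n_ib = n_ib),
            class = "wham_solution")
}

#' @export
print.wham_solution <- function(x, ...) {
  cat(sprintf("wham_solution: %d bins @ %.3g A, %d windows, %d iterations, %s\n",
              length(x$bin_centers), x$bin_width, length(x$F), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Convert a WHAM solution to a potential of mean force
#'
#' `G(z) = -ln P(z)` in kT units, shifted so G = 0 at the reference:
#' `"bulk_end"` (default) uses the most cytoplasmic (lowest z) sampled bin,
#' matching a barrier-relative-to-bulk reading; `"bulk_mean"` zeroes the
#' mean G over the lowest `bulk_width` Angstrom of sampled bins, which
#' avoids propagating the counting noise of a single edge bin into every
#' downstream difference; `"minimum"` uses the global minimum.
#'
#' @param solution a [wham_solution][wham()].
#' @param reference `"bulk_end"`, `"bulk_mean"` or `"minimum"`.
#' @param bulk_width width of the bulk averaging window for
#'   `reference = "bulk_mean"` (Angstrom), default 2.
#' @return an object of class `pmf_profile` with `z`, `G` (kT; NA on
#'   unsampled bins), `reference`, `kT`.
#' @export
to_pmf <- function(solution, reference = c("bulk_end", "bulk_mean", "minimum"),
                   bulk_width = 2) {
  reference <- match.arg(reference)
  if (!any(solution$mask)) abort("solution has no sampled bins")
  G <- rep(NA_real_, length(solution$P))
  G[solution$mask] <- -log(solution$P[solution$mask])
  if (reference == "bulk_mean") {
    z0 <- min(solution$bin_centers[solution$mask])
    in_bulk <- solution$mask & solution$bin_centers <= z0 + bulk_width
    G <- G - mean(G[in_bulk])
  } else {
    ref_idx <- switch(reference,
                      bulk_end = min(which(solution$mask)),
                      minimum = which.min(ifelse(solution$mask, G, Inf)))
    if (!solution$mask[ref_idx]) abort("reference bin is masked")
    G <- G - G[ref_idx]
  }
  structure(list(z = solution$bin_centers, G = G, reference = reference,
                 kT = solution$kT, bin_width = solution$bin_width),
            class = "pmf_profile")
}

#' Construct a PMF profile directly
#'
#' For profiles that do not come from WHAM (analytic truths, file import).
#'
#' @param z bin centers (Angstrom), strictly increasing, uniform step.
#' @param G free energy (kT units).
#' @param reference label of the zero convention.
#' @param kT kJ mol-1, recorded for provenance.
#' @return a `pmf_profile`.
#' @export
pmf_profile <- function(z, G, reference = "bulk_end",
                        kT = kT_from_temperature(310)) {
  if (length(z) != length(G)) abort("z and G must have equal length")
  if (length(z) >= 2L && any(diff(z) <= 0)) abort("z must be strictly increasing")
  structure(list(z = z, G = G, reference = reference, kT = kT,
                 bin_width = if (length(z) >= 2L) z[2] - z[1] else NA_real_),
            class = "pmf_profile")
}

#' Compare two PMF profiles over a region
#'
#' Computes `deltaG(z) = G_a(z) - G_b(z)` on profile a's bins (profile b is
#' linearly interpolated when binnings differ), the peak deltaG inside
#' `region`, and the integrated area of positive deltaG over `region`
#' (kT Angstrom; rectangle rule over bins whose centers fall in
#' `[region[1], region[2])`).
#'
#' @param pmf_a,pmf_b `pmf_profile` objects (e.g. WT and mutant).
#' @param region `(z_lo, z_hi)`; default: the overlap of the two domains.
#' @return list of class `pmf_comparison` with `z`, `delta_G`, `peak`,
#'   `peak_z`, `area_positive`, `region`.
#' @export
compare_pmfs <- function(pmf_a, pmf_b, region = NULL) {
  lo <- max(min(pmf_a$z), min(pmf_b$z))
  hi <- min(max(pmf_a$z), max(pmf_b$z))
  if (lo >= hi) abort("PMF domains are disjoint")
  if (is.null(region)) region <- c(lo, hi)
  if (region[1] >= region[2]) abort("region must be (z_lo, z_hi) with z_lo < z_hi")
  if (region[1] < lo - 1e-9 || region[2] > hi + 1e-9) {
    abort("region [%.3g, %.3g] extends beyond the shared domain [%.3g, %.3g]",
          region[1], region[2], lo, hi)
  }
  gb <- if (length(pmf_b$z) == length(pmf_a$z) &&
            max(abs(pmf_b$z - pmf_a$z)) < 1e-9) {
    pmf_b$G
  } else {
    ok <- !is.na(pmf_b$G)
    stats::approx(pmf_b$z[ok], pmf_b$G[ok], xout = pmf_a$z, rule = 1)$y
  }
  delta <- pmf_a$G - gb
  dz <- pmf_a$bin_width
  in_region <- pmf_a$z >= region[1] & pmf_a$z < region[2]
  d_in <- delta[in_region]
  if (all(is.na(d_in))) abort("no sampled bins inside the comparison region")
  peak <- max(d_in, na.rm = TRUE)
  peak_z <- pmf_a$z[in_region][which.max(ifelse(is.na(d_in), -Inf, d_in))]
  area <- sum(pmax(d_in, 0), na.rm = TRUE) * dz
  structure(list(z = pmf_a$z, delta_G = delta, peak = peak, peak_z = peak_z,
                 area_positive = area, region = region),
            class = "pmf_comparison")
}

#' @export
print.pmf_comparison <- function(x, ...) {
  cat(sprintf(
    "pmf_comparison: peak deltaG %.2f kT at z = %.1f A; positive area %.1f kT.A over [%.1f, %.1f]\n",
    x$peak, x$peak_z, x$area_positive, x$region[1], x$region[2]))
  invisible(x)
}
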