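# End-to-end runs from a config list or YAML file: hydration analysis
# (occupancy series, histogram, summary, density grid), PMF reconstruction
# from umbrella windows, and WT-vs-mutant comparison reports. All artifacts
# are plain text (TSV / JSON / DX) with fixed numeric formatting, so a rerun
# with the same config and seed is byte-identical.

#' Read a run configuration from YAML
#'
#' A config describes one system: either file inputs (`structure`,
#' `trajectory`, and/or `windows`) or a `synthetic` block (`pore`,
#' `wetting`, `pmf` sub-blocks), plus `selections`, `region`, `grid`,
#' `wham`, `seed`, `stride` and `outdir`.
#'
#' @param path YAML file path.
#' @return a validated config list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a run configuration
#' @param config a named list (see [read_run_config()]).
#' @return the config with defaults filled in (class `run_config`).
#' @export
validate_run_config <- function(config) {
  has_files <- !is.null(config$structure) || !is.null(config$trajectory)
  has_synth <- !is.null(config$synthetic)
  if (has_files && has_synth) {
    abort("config: give either file inputs or a 'synthetic' block, not both")
  }
  if (!has_files && !has_synth && is.null(config$windows)) {
    abort("config: needs file inputs, a 'synthetic' block, or 'windows'")
  }
  if (has_files && (is.null(config$structure) || is.null(config$trajectory)) &&
      is.null(config$windows)) {
    abort("config: file input needs both 'structure' and 'trajectory'")
  }
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$stride <- if (is.null(config$stride)) 1L else as.integer(config$stride)
  if (is.null(config$name)) config$name <- "system"
  if (is.null(config$region)) config$region <- list(z_lo = -10, z_hi = -5)
  if (is.null(config$grid)) config$grid <- list(spacing = 0.5)
  if (is.null(config$wham)) config$wham <- list()
  class(config) <- c("run_config", "list")
  config
}

config_pore_spec <- function(p) {
  knots <- do.call(rbind, lapply(p$radius_knots, as.numeric))
  pore_spec(
    axis_length = p$axis_length, radius_knots = knots,
    wall_atom_spacing = if (is.null(p$wall_atom_spacing)) 1.0 else p$wall_atom_spacing,
    wall_vdw_radius = if (is.null(p$wall_vdw_radius)) 1.5 else p$wall_vdw_radius,
    constriction_zone = if (is.null(p$constriction_zone)) c(-10, -5) else
      as.numeric(p$constriction_zone)
  )
}

# Load or generate the system a config describes.
build_system <- function(config) {
  config <- validate_run_config(config)
  states <- NULL
  if (!is.null(config$synthetic)) {
    spec <- config_pore_spec(config$synthetic$pore)
    w <- config$synthetic$wetting
    params <- wetting_params(
      k_dry = w$k_dry, k_wet = w$k_wet,
      lambda_full = if (is.null(w$lambda_full)) 12 else w$lambda_full,
      frame_dt = if (is.null(w$frame_dt)) 0.1 else w$frame_dt,
      n_frames = if (is.null(w$n_frames)) 1000L else w$n_frames,
      seed = config$seed,
      init_state = if (is.null(w$init_state)) "auto" else w$init_state
    )
    gen <- gen_wetting_trajectory(spec, params)
    struct <- gen$structure; traj <- gen$trajectory; states <- gen$states
  } else {
    struct <- read_structure(config$structure)
    traj <- read_trajectory(config$trajectory, struct, stride = 1L)
  }
  selc <- config$selections
  water_sel <- if (is.null(selc$water)) {
    select_atoms(struct, preset = "water_oxygens")
  } else {
    do.call(select_atoms, c(list(struct), selc$water))
  }
  ref_args <- if (is.null(selc$reference)) {
    list(resname = "THR", resno = c(117L, 225L))
  } else {
    selc$reference
  }
  ref_sel <- do.call(select_atoms, c(list(struct), ref_args, label = "reference"))
  list(struct = struct, traj = traj, water_sel = water_sel, ref_sel = ref_sel,
       states = states, config = config)
}

provenance_block <- function(config, extra = list()) {
  cfg <- unclass(config)
  c(list(config_hash = object_hash(cfg), seed = config$seed,
         package = "poregate",
         package_version = as.character(utils::packageVersion("poregate")),
         r_version = paste(R.version$major, R.version$minor, sep = ".")),
    extra)
}

write_tsv_artifact <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run the hydration analysis described by a config
#'
#' Computes the occupancy series, histogram, summary and bulk-normalized
#' density grid, and writes `occupancy.tsv`, `histogram.tsv`,
#' `summary.json`, `density.dx` and `provenance.json` to the output
#' directory. Idempotent for a fixed config and seed.
#'
#' @param config a config list or path to a YAML config.
#' @param outdir output directory (default `config$outdir`, or a temp dir).
#' @return list with `series`, `histogram`, `summary`, `grid`, `paths`.
#' @export
run_hydration <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  if (is.null(outdir)) outdir <- if (!is.null(config$outdir)) config$outdir else
    tempfile("hydration_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sys <- build_system(config)
  region <- do.call(slab_region, config$region)
  series <- occupancy_series(sys$traj, sys$water_sel, sys$ref_sel,
                             region = region, stride = config$stride)
  hist <- occupancy_histogram(series)
  summary <- summarize_occupancy(series)
  spacing <- if (is.null(config$grid$spacing)) 0.5 else config$grid$spacing
  grid <- water_density_grid(sys$traj, sys$water_sel, spacing = spacing)
  paths <- list(
    occupancy = write_tsv_artifact(
      data.frame(time_ns = fmt_num(series$times), n_waters = series$counts),
      file.path(outdir, "occupancy.tsv")),
    histogram = write_tsv_artifact(
      data.frame(count = hist$count_values,
                 probability = fmt_num(hist$probabilities)),
      file.path(outdir, "histogram.tsv")),
    summary = write_json_artifact(
      list(name = config$name, mu = summary$mu,
           fraction_zero = summary$fraction_zero,
           n_frames = hist$n_frames,
           region = list(z_lo = region$z_lo, z_hi = region$z_hi),
           iso_voxels = grid$iso_voxels, grid_overflow = grid$overflow),
      file.path(outdir, "summary.json")),
    density = write_dx(grid, file.path(outdir, "density.dx")),
    provenance = write_json_artifact(provenance_block(config),
                                     file.path(outdir, "provenance.json"))
  )
  list(series = series, histogram = hist, summary = summary, grid = grid,
       paths = paths, config = config)
}

# windows from a config: file paths or the synthetic pmf block
config_windows <- function(config) {
  if (!is.null(config$windows)) {
    lapply(config$windows, read_umbrella_window)
  } else if (!is.null(config$synthetic$pmf)) {
    p <- config$synthetic$pmf
    pmf <- analytic_pmf(form = p$form, params = p$params,
                        domain = as.numeric(p$domain))
    centers <- if (!is.null(p$centers)) {
      as.numeric(p$centers)
    } else {
      # reference protocol: 25 windows every 1 Angstrom
      first <- if (is.null(p$center_start)) p$domain[[1]] + 0.5 else p$center_start
      n <- if (is.null(p$n_windows)) 25L else p$n_windows
      sp <- if (is.null(p$spacing)) 1.0 else p$spacing
      first + sp * (seq_len(n) - 1L)
    }
    gen_umbrella_samples(
      pmf, centers,
      k_bias = if (is.null(p$k_bias)) 10 else p$k_bias,
      kT = if (is.null(p$temperature)) kT_from_temperature(310) else
        kT_from_temperature(p$temperature),
      n_per_window = if (is.null(p$n_per_window)) 1000L else p$n_per_window,
      seed = config$seed
    )
  } else {
    abort("config has neither 'windows' files nor a synthetic pmf block")
  }
}

#' Run the PMF reconstruction described by a config
#'
#' Reads or generates umbrella windows, solves WHAM, and writes
#' `window_histograms.tsv`, `wham_convergence.tsv`, `pmf.tsv` and
#' `provenance.json`.
#'
#' @param config a config list or path to a YAML config (needs `windows`
#'   file paths or a `synthetic$pmf` block).
#' @param outdir output directory.
#' @return list with `windows`, `solution`, `pmf`, `paths`.
#' @export
run_pmf <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  if (is.null(outdir)) outdir <- if (!is.null(config$outdir)) config$outdir else
    tempfile("pmf_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  windows <- config_windows(config)
  wc <- config$wham
  sol <- wham(windows,
              bin_width = if (is.null(wc$bin_width)) 0.1 else wc$bin_width,
              tolerance = if (is.null(wc$tolerance)) 1e-6 else wc$tolerance,
              max_iter = if (is.null(wc$max_iter)) 1e5 else wc$max_iter)
  pmf <- to_pmf(sol, reference = if (is.null(wc$reference)) "bulk_end" else
    wc$reference)
  wh <- do.call(rbind, lapply(seq_along(windows), function(i) {
    data.frame(window = i, bin_center = fmt_num(sol$bin_centers),
               count = sol$n_ib[, i])
  }))
  paths <- list(
    window_histograms = write_tsv_artifact(
      wh, file.path(outdir, "window_histograms.tsv")),
    convergence = write_tsv_artifact(
      data.frame(iteration = seq_along(sol$residuals),
                 residual_kJ_mol = fmt_num(sol$residuals)),
      file.path(outdir, "wham_convergence.tsv")),
    pmf = write_tsv_artifact(
      data.frame(z_A = fmt_num(pmf$z), G_kT = fmt_num(pmf$G)),
      file.path(outdir, "pmf.tsv")),
    provenance = write_json_artifact(
      provenance_block(config, list(converged = sol$converged,
                                    iterations = sol$iterations)),
      file.path(outdir, "provenance.json"))
  )
  list(windows = windows, solution = sol, pmf = pmf, paths = paths,
       config = config)
}

#' Compare a wild-type and a mutant system
#'
#' Runs the hydration analysis for both configs (and the PMF stage when
#' windows are configured), then reports `delta_mu = mu(mutant) - mu(WT)`
#' with its standard error, overlaid occupancy histograms, and the
#' additional free-energy barrier of the WT relative to the mutant (peak and
#' positive area of `G_wt - G_mut`). Writes `comparison.json`,
#' `histogram_overlay.tsv` and, when PMFs are present, `pmf_delta.tsv`.
#'
#' @param config_wt,config_mut config lists or YAML paths.
#' @param outdir output directory for the comparison artifacts.
#' @param pmf_region optional `(z_lo, z_hi)` for the PMF comparison.
#' @return list of class `comparison_report`.
#' @export
run_compare <- function(config_wt, config_mut, outdir = NULL,
                        pmf_region = NULL) {
  if (is.character(config_wt)) config_wt <- read_run_config(config_wt)
  if (is.character(config_mut)) config_mut <- read_run_config(config_mut)
  config_wt <- validate_run_config(config_wt)
  config_mut <- validate_run_config(config_mut)
  if (is.null(outdir)) outdir <- tempfile("compare_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  has_traj <- function(cfg) !is.null(cfg$trajectory) ||
    !is.null(cfg$synthetic$wetting)
  res <- list()
  if (has_traj(config_wt) && has_traj(config_mut)) {
    r_wt <- run_hydration(config_wt, file.path(outdir, "wt"))
    r_mut <- run_hydration(config_mut, file.path(outdir, "mut"))
    if (abs(series_dt(r_wt$series) - series_dt(r_mut$series)) > 1e-9) {
      abort("WT and mutant series have different frame spacing")
    }
    sm <- summarize_occupancy(r_mut$series, partner = r_wt$series)
    res$delta_mu <- sm$delta_mu
    res$se_delta_mu <- sm$se_delta_mu
    res$mu_wt <- r_wt$summary$mu
    res$mu_mut <- r_mut$summary$mu
    res$fraction_zero_wt <- r_wt$summary$fraction_zero
    res$fraction_zero_mut <- r_mut$summary$fraction_zero
    nmax <- max(max(r_wt$histogram$count_values), max(r_mut$histogram$count_values))
    pad <- function(h) c(h$probabilities, rep(0, nmax + 1L - length(h$probabilities)))
    write_tsv_artifact(
      data.frame(count = 0:nmax, p_wt = fmt_num(pad(r_wt$histogram)),
                 p_mut = fmt_num(pad(r_mut$histogram))),
      file.path(outdir, "histogram_overlay.tsv"))
  }
  has_windows <- function(cfg) !is.null(cfg$windows) || !is.null(cfg$synthetic$pmf)
  if (has_windows(config_wt) && has_windows(config_mut)) {
    p_wt <- run_pmf(config_wt, file.path(outdir, "wt_pmf"))
    p_mut <- run_pmf(config_mut, file.path(outdir, "mut_pmf"))
    cmp <- compare_pmfs(p_wt$pmf, p_mut$pmf, region = pmf_region)
    res$pmf_peak_delta_G <- cmp$peak
    res$pmf_peak_z <- cmp$peak_z
    res$pmf_area_positive <- cmp$area_positive
    write_tsv_artifact(
      data.frame(z_A = fmt_num(cmp$z), delta_G_kT = fmt_num(cmp$delta_G)),
      file.path(outdir, "pmf_delta.tsv"))
  }
  res$provenance <- list(
    wt = provenance_block(config_wt), mut = provenance_block(config_mut))
  write_json_artifact(res, file.path(outdir, "comparison.json"))
  res$outdir <- outdir
  class(res) <- c("comparison_report", "list")
  res
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n")
  if (!is.null(x$delta_mu)) {
    cat(sprintf("  delta_mu (mutant - WT) = %.3f +/- %.3f\n",
                x$delta_mu, x$se_delta_mu))
    cat(sprintf("  fraction dry: WT %.3f, mutant %.3f\n",
                x$fraction_zero_wt, x$fraction_zero_mut))
  }
  if (!is.null(x$pmf_peak_delta_G)) {
    cat(sprintf("  PMF: peak deltaG(WT - mutant) = %.2f kT at z = %.1f, positive area %.1f kT.A\n",
                x$pmf_peak_delta_G, x$pmf_peak_z, x$pmf_area_positive))
  }
  invisible(x)
}
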