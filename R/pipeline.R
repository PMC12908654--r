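#' Read and validate a run configuration (YAML)
#'
#' A run config names the seed, output directory and the parameters of the
#' synthesize / analyze / sweep stages. Referenced input files must exist
#' at validation time.
#'
#' @param path YAML config file.
#' @return A `cw_config` (named list with attribute `hash`, the MD5 of the
#'   config file, recorded in every output header).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("config must set 'seed'")
  if (is.null(cfg$outdir)) stop("config must set 'outdir'")
  for (p in c(cfg$analyze$trajectory, cfg$analyze$parameters,
              unlist(lapply(cfg$sweep$runs, `[[`, "trajectory"))))
    if (!is.null(p) && !file.exists(p))
      stop("config references a missing file: ", p)
  attr(cfg, "hash") <- unname(tools::md5sum(path))
  class(cfg) <- "cw_config"
  cfg
}

cw_version <- function() {
  as.character(utils::packageVersion("confinedwater"))
}

# Commented-header TSV writer: '#'-prefixed metadata lines (artifact
# version, config hash, seed, units), then the table. Deterministic for
# fixed input.
write_tsv_report <- function(df, path, meta = character()) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0("# ", meta), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  lines <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.10g", col) else as.character(col)
  }), sep = "\t"))
  writeLines(lines, con)
  invisible(path)
}

std_meta <- function(cfg, extra = character()) {
  c(sprintf("confinedwater %s", cw_version()),
    sprintf("config_hash: %s", attr(cfg, "hash")),
    sprintf("seed: %s", cfg$seed),
    extra)
}

manifest_path <- function(cfg) file.path(cfg$outdir, "manifest.yaml")

manifest_init <- function(cfg, stage) {
  mf <- if (file.exists(manifest_path(cfg))) {
    yaml::read_yaml(manifest_path(cfg))
  } else {
    list(version = cw_version(), config_hash = attr(cfg, "hash"), stages = list())
  }
  mf$stages[[stage]] <- list(status = "running", outputs = list())
  yaml::write_yaml(mf, manifest_path(cfg))
  mf
}

manifest_done <- function(cfg, stage, outputs, status = "ok") {
  mf <- yaml::read_yaml(manifest_path(cfg))
  mf$stages[[stage]] <- list(status = status, outputs = as.list(outputs))
  yaml::write_yaml(mf, manifest_path(cfg))
  invisible(mf)
}

#' Synthesize a trajectory from a run config
#'
#' Generates the configured synthetic system (jump, exchange or Brownian
#' mode), writes the trajectory (GRO), the parameter file and the
#' ground-truth record into `outdir`, and updates the run manifest.
#' Re-running with the same config and seed reproduces the files
#' byte-for-byte. Existing outputs are refused unless `force = TRUE`.
#'
#' @param cfg A `cw_config` (see [read_run_config()]); needs a
#'   `synthesize` section.
#' @param force Overwrite existing outputs.
#' @return Invisible named vector of output paths.
#' @export
run_synthesize <- function(cfg, force = FALSE) {
  sy <- cfg$synthesize
  if (is.null(sy)) stop("config has no 'synthesize' section")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  outs <- file.path(cfg$outdir, c(trajectory = "trajectory.gro",
                                  parameters = "parameters.yaml",
                                  truth = "truth.yaml"))
  names(outs) <- c("trajectory", "parameters", "truth")
  if (!force && any(file.exists(outs)))
    stop("outputs already exist in ", cfg$outdir, "; use force = TRUE")
  manifest_init(cfg, "synthesize")
  mode <- if (is.null(sy$mode)) "jump" else sy$mode
  gen <- switch(mode,
    jump = {
      pore <- do.call(pore_model, sy$pore %||% list())
      tr <- do.call(ground_truth, sy$truth %||% list())
      generate_jump_trajectory(pore, tr, sy$n_waters, sy$n_frames,
                               dt = sy$dt %||% 0.1, seed = cfg$seed)
    },
    exchange = generate_exchange_trajectory(
      sy$exchange_rate, sy$n_waters, sy$n_frames, dt = sy$dt %||% 0.1,
      cutoff = sy$cutoff %||% 1.0, seed = cfg$seed),
    brownian = {
      pore <- do.call(pore_model, sy$pore %||% list())
      generate_brownian_trajectory(pore, sy$diffusivity %||% 0.002,
                                   sy$n_waters, sy$n_frames,
                                   dt = sy$dt %||% 0.1, seed = cfg$seed)
    },
    stop("unknown synthesize mode: ", mode))
  if (!is.null(sy$libration))
    gen$traj <- add_libration(gen$traj, sy$libration$mode,
                              sy$libration$amplitude_deg,
                              sy$libration$frequency_THz, seed = cfg$seed)
  write_trajectory(gen$traj, outs[["trajectory"]])
  write_parameters(gen$traj$topology, outs[["parameters"]])
  write_ground_truth(gen$truth, outs[["truth"]])
  manifest_done(cfg, "synthesize", outs)
  invisible(outs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the enabled analyses of a config on a trajectory
#'
#' Loads the configured trajectory and parameter file and emits one
#' commented-header TSV per enabled analysis (`residence`, `density`,
#' `dipole`, `hh`, `hbonds`, `rdf`, `energies`, `local_counts`,
#' `retention`). A failing stage aborts with the stage name; completed
#' outputs stay on disk and the manifest marks the run partial.
#'
#' @param cfg A `cw_config` with an `analyze` section.
#' @return Invisible character vector of output paths.
#' @export
run_analyze <- function(cfg) {
  an <- cfg$analyze
  if (is.null(an)) stop("config has no 'analyze' section")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_init(cfg, "analyze")
  traj <- tryCatch({
    tr <- read_trajectory(an$trajectory, dt = an$dt %||% 0.1)
    if (!is.null(an$parameters))
      tr$topology <- load_parameters(an$parameters, tr$topology)
    tr
  }, error = function(e) {
    manifest_done(cfg, "analyze", character(0), status = "failed")
    stop("analysis stage 'load' failed: ", conditionMessage(e), call. = FALSE)
  })
  enable <- an$enable %||% c("residence", "density")
  outs <- character(0)
  stage <- function(name, fn) {
    if (!name %in% enable) return(invisible(NULL))
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) {
      manifest_done(cfg, "analyze", outs, status = "partial")
      stop("analysis stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] done in %.2f s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    outs <<- c(outs, res)
  }
  zr <- an$z_range
  if (!is.null(zr)) zr <- as.numeric(zr)
  stage("residence", function() {
    rp <- residence_profile(traj, zr, an$slab_width %||% 0.1)
    p <- file.path(cfg$outdir, "residence_profile.tsv")
    write_tsv_report(as.data.frame(rp), p,
                     std_meta(cfg, "units: z_nm mean_ps n n density_per_nm"))
    p
  })
  stage("density", function() {
    dp <- density_profile(traj, zr, an$slab_width %||% 0.1)
    p <- file.path(cfg$outdir, "density_profile.tsv")
    write_tsv_report(dp, p, std_meta(cfg, "units: z_nm count density_per_nm"))
    p
  })
  stage("dipole", function() {
    dp <- dipole_angle_profile(traj, zr, an$slab_width %||% 0.1)
    p <- file.path(cfg$outdir, "dipole_profile.tsv")
    write_tsv_report(as.data.frame(dp), p,
                     std_meta(cfg, "units: z_nm deg deg count"))
    p
  })
  stage("hh", function() {
    h <- hh_plane_histogram(traj, plane = an$hh_plane %||% "xz")
    df <- data.frame(c1_nm = rep(h$c1, times = length(h$c2)),
                     c2_nm = rep(h$c2, each = length(h$c1)),
                     count = as.vector(h$counts))
    df <- df[df$count > 0, ]
    p <- file.path(cfg$outdir, "hh_hist.tsv")
    write_tsv_report(df, p, std_meta(cfg, sprintf(
      "plane: %s; spread_nm: %.6f %.6f", h$plane, h$spread_nm[1], h$spread_nm[2])))
    p
  })
  stage("hbonds", function() {
    hb <- hbond_count_series(traj, an$hbond_group_a %||% "water",
                             an$hbond_group_b %||% "not water")
    p <- file.path(cfg$outdir, "hbonds.tsv")
    write_tsv_report(as.data.frame(hb), p,
                     std_meta(cfg, sprintf("mean_count: %.6f", attr(hb, "mean"))))
    p
  })
  stage("rdf", function() {
    g <- rdf(traj, an$rdf_reference %||% "resname REF", an$rdf_target %||% "water",
             r_max = an$rdf_r_max %||% NULL, bin = an$rdf_bin %||% 0.02)
    p <- file.path(cfg$outdir, "rdf.tsv")
    write_tsv_report(as.data.frame(g), p, std_meta(cfg, "units: r_nm g"))
    p
  })
  stage("energies", function() {
    resids <- an$residues %||% unique(
      traj$topology$atoms$resid[traj$topology$atoms$resname == "REF"])
    et <- interaction_energy_per_residue(traj, resids,
                                         cutoff = an$energy_cutoff %||% NULL)
    p <- file.path(cfg$outdir, "energies.tsv")
    write_tsv_report(as.data.frame(et), p,
                     std_meta(cfg, "units: residue kJ/mol kJ/mol kJ/mol"))
    p
  })
  stage("local_counts", function() {
    resids <- an$residues %||% unique(
      traj$topology$atoms$resid[traj$topology$atoms$resname == "REF"])
    lc <- local_water_count(traj, resids, cutoff = an$count_cutoff %||% 0.5)
    p <- file.path(cfg$outdir, "local_counts.tsv")
    write_tsv_report(lc, p, std_meta(cfg, "units: residue count"))
    p
  })
  stage("retention", function() {
    rc <- retention_curve(traj, an$retention_reference %||% "resname REF",
                          cutoff = an$retention_cutoff %||% 1.0,
                          max_lag = an$retention_max_lag %||% NULL)
    mr <- mean_residence_from_retention(rc)
    p <- file.path(cfg$outdir, "retention.tsv")
    write_tsv_report(as.data.frame(rc), p, std_meta(cfg, c(
      "units: lag_ps fraction",
      sprintf("mean_residence_ps: %.6f (censored: %s)", mr$mean_ps, mr$censored))))
    p
  })
  manifest_done(cfg, "analyze", outs)
  invisible(outs)
}

#' Print and return the librational mode table
#'
#' Convenience wrapper around [librational_table()] for pipeline/CLI use:
#' prints the three-row mode/inertia/frequency table and returns it
#' invisibly.
#'
#' @param E_b_kcal Binding energy, kcal/mol (default 19).
#' @param r_oh_A,hoh_deg Water geometry (defaults: rigid TIP3P).
#' @return The `cw_mode_table`, invisibly.
#' @export
run_librational_table <- function(E_b_kcal = 19, r_oh_A = tip3p$r_oh_A,
                                  hoh_deg = tip3p$hoh_deg) {
  tab <- librational_table(E_b_kcal, water_geometry(r_oh_A, hoh_deg))
  print(tab)
  invisible(tab)
}

#' Merge labelled runs into a frequency-response report
#'
#' Reads each configured run (frequency + trajectory path), measures the
#' mean in-region residence time, writes `freq_response.tsv` and returns
#' the table with the extremum summary attached.
#'
#' @param cfg A `cw_config` with a `sweep` section: `runs` (list of
#'   `{frequency, trajectory, parameters?}`), and `region`
#'   (`{z: [lo, hi]}` slab, default the full box).
#' @return The `cw_freq_response`, invisibly.
#' @export
run_sweep_report <- function(cfg) {
  sw <- cfg$sweep
  if (is.null(sw) || length(sw$runs) < 2) stop("sweep needs >= 2 labelled runs")
  freqs <- vapply(sw$runs, function(r) as.numeric(r$frequency), numeric(1))
  if (length(unique(freqs)) < 2) stop("sweep needs >= 2 distinct frequencies")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest_init(cfg, "sweep")
  runs <- lapply(sw$runs, function(r) {
    traj <- read_trajectory(r$trajectory, dt = r$dt %||% 0.1)
    if (!is.null(r$parameters))
      traj$topology <- load_parameters(r$parameters, traj$topology)
    list(field = field_spec(amplitude_E0 = r$amplitude %||% 0.4,
                            frequency = r$frequency),
         traj = traj)
  })
  region <- if (!is.null(sw$region$z)) {
    region_spec("slab", z = as.numeric(sw$region$z))
  } else {
    region_spec("slab", z = c(0, runs[[1]]$traj$box[1, 3]))
  }
  fr <- frequency_response(runs, region)
  p <- file.path(cfg$outdir, "freq_response.tsv")
  write_tsv_report(as.data.frame(fr), p, std_meta(cfg, c(
    "units: THz ps ps count ratio",
    sprintf("residence_min_at_THz: %s", attr(fr, "f_min") %||% NA),
    sprintf("residence_max_at_THz: %s", attr(fr, "f_max") %||% NA))))
  manifest_done(cfg, "sweep", p)
  invisible(fr)
}
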