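#' Read and validate a pipeline configuration
#'
#' Configurations are YAML with top-level sections \code{materials}
#' (nested by tissue: pfm, perineal_body, bulbospongiosus, anal_sphincter,
#' fetal_head), \code{viscoelastic} (matrix/fiber branch sets),
#' \code{protocol}, \code{anatomy}, \code{calibration} and \code{seed}.
#' Unknown keys and invalid values raise a schema error listing the
#' offenders. The packaged default configuration
#' (\code{system.file("extdata", "default_config.yaml", package =
#' "vadsim")}) reproduces the 12-scenario sweep.
#'
#' @param path path to a YAML config file; default the packaged one.
#' @return Validated config list of class \code{"vadsim_config"}.
#' @export
read_config <- function(path = default_config_path()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  attr(cfg, "path") <- path
  attr(cfg, "md5") <- unname(tools::md5sum(path))
  class(cfg) <- "vadsim_config"
  cfg
}

#' @rdname read_config
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "vadsim",
              mustWork = TRUE)
}

validate_config <- function(cfg) {
  known_top <- c("materials", "viscoelastic", "protocol", "anatomy",
                 "calibration", "seed")
  bad <- setdiff(names(cfg), known_top)
  errs <- character(0)
  if (length(bad)) errs <- c(errs, paste("unknown keys:",
                                         paste(bad, collapse = ", ")))
  known_tissues <- c("pfm", "perineal_body", "bulbospongiosus",
                     "anal_sphincter", "fetal_head")
  bad_t <- setdiff(names(cfg$materials), known_tissues)
  if (length(bad_t)) errs <- c(errs, paste("unknown tissues:",
                                           paste(bad_t, collapse = ", ")))
  p <- cfg$protocol
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(all(p$contractions_s > 0), "protocol: contractions_s must be > 0")
  chk(all(p$rests_s > 0), "protocol: rests_s must be > 0")
  chk(all(p$pulls >= 1), "protocol: pulls must be >= 1")
  chk(p$engagement_s > 0, "protocol: engagement_s must be > 0")
  chk(p$total_descent_mm > 0, "protocol: total_descent_mm must be > 0")
  chk(p$dt_s > 0, "protocol: dt_s must be > 0")
  a <- cfg$anatomy
  chk(a$head_radius_mm > 0, "anatomy: head_radius_mm must be > 0")
  chk(a$lambda_eng >= 1, "anatomy: lambda_eng must be >= 1")
  ca <- cfg$calibration
  chk(ca$E_true_MPa > 0, "calibration: E_true_MPa must be > 0")
  chk(ca$n_points >= 3, "calibration: n_points must be >= 3")
  chk(ca$noise_cv >= 0, "calibration: noise_cv must be >= 0")
  if (length(errs)) {
    stop("config schema error:\n  ", paste(errs, collapse = "\n  "))
  }
  invisible(TRUE)
}

config_materials <- function(cfg) {
  m <- cfg$materials
  v <- cfg$viscoelastic
  list(
    pfm = martins_params(c = m$pfm$c_MPa, b = m$pfm$b, A = m$pfm$A_MPa,
                         a = m$pfm$a, T0M = m$pfm$T0M_MPa,
                         theta = m$pfm$theta, D = m$pfm$D_per_MPa),
    perineum = linear_elastic_params(E = m$perineal_body$E_kPa / 1000,
                                     nu = m$perineal_body$nu, unit = "MPa"),
    anal_sphincter = neo_hookean_params(c10 = m$anal_sphincter$c10_MPa),
    fetal_head = linear_elastic_params(E = m$fetal_head$E_MPa,
                                       nu = m$fetal_head$nu, unit = "MPa"),
    branches_matrix = maxwell_branches(v$matrix$B, v$matrix$tau),
    branches_fiber = maxwell_branches(v$fiber$B, v$fiber$tau)
  )
}

config_anatomy <- function(cfg) {
  a <- cfg$anatomy
  default_anatomy(R = a$head_radius_mm, lambda_eng = a$lambda_eng,
                  area_levator = a$area_levator_mm2,
                  area_urogenital = a$area_urogenital_mm2)
}

#' Run the full reporting pipeline
#'
#' Sweeps the configured scenario grid on the configured anatomy, runs the
#' head-modulus calibration, and writes: one tidy CSV per scenario
#' (\code{scenario_<label>.csv}), a cross-scenario comparison table
#' (\code{comparison.csv}), per-phase summaries
#' (\code{phase_summaries.csv}), a calibration report
#' (\code{calibration.csv}), a JSON summary (\code{summary.json}) and a run
#' log (\code{run_log.txt}) recording the config hash, seed and package
#' version. Outputs are deterministic for a fixed config and seed.
#'
#' @param config path to a YAML config, or a \code{"vadsim_config"}.
#' @param out_dir output directory (created if missing).
#' @param seed optional override of the config seed.
#' @return Invisibly, a list with \code{results}, \code{comparison},
#'   \code{calibration}, \code{out_dir}.
#' @export
run_pipeline <- function(config = default_config_path(), out_dir, seed = NULL) {
  cfg <- if (inherits(config, "vadsim_config")) config else read_config(config)
  if (is.null(seed)) seed <- if (is.null(cfg$seed)) 1 else cfg$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  scen <- build_scenarios(cfg$protocol$contractions_s, cfg$protocol$rests_s,
                          cfg$protocol$pulls)
  anatomy <- config_anatomy(cfg)
  materials <- config_materials(cfg)
  results <- run_sweep(scen, anatomy, materials,
                       dt = cfg$protocol$dt_s,
                       engagement_duration = cfg$protocol$engagement_s,
                       total_descent = cfg$protocol$total_descent_mm)

  for (nm in names(results)) {
    utils::write.csv(tidy_series(results[[nm]]),
                     file.path(out_dir, paste0("scenario_", nm, ".csv")),
                     row.names = FALSE)
  }

  comparison <- compare_scenarios(results)
  utils::write.csv(as.data.frame(comparison),
                   file.path(out_dir, "comparison.csv"), row.names = FALSE)

  phases <- do.call(rbind, lapply(names(results), function(nm) {
    cbind(scenario = nm, phase_summaries(results[[nm]]))
  }))
  utils::write.csv(phases, file.path(out_dir, "phase_summaries.csv"),
                   row.names = FALSE)

  ca <- cfg$calibration
  curve <- synthetic_compression_curve(ca$E_true_MPa, ca$n_points,
                                       ca$noise_cv, seed = seed,
                                       R = ca$radius_mm,
                                       max_deflection = ca$max_deflection_mm)
  cal <- calibrate_young_modulus(curve, R = ca$radius_mm)
  utils::write.csv(data.frame(E_true_MPa = ca$E_true_MPa,
                              E_recovered_MPa = cal$E,
                              relative_se = cal$relative_se,
                              residual_norm_N = cal$residual_norm,
                              n_points = cal$n, noise_cv = ca$noise_cv,
                              seed = seed),
                   file.path(out_dir, "calibration.csv"), row.names = FALSE)

  pk <- anatomy_peak_stretches(anatomy)
  summary <- list(
    n_scenarios = nrow(scen),
    peak_stretch = stats::setNames(as.list(pk$peak_stretch), pk$ring),
    d_at_peak_stretch = stats::setNames(as.list(pk$d_at_peak), pk$ring),
    peak_sigma1 = stats::setNames(as.list(comparison$peak_sigma1),
                                  comparison$scenario),
    peak_force = stats::setNames(as.list(comparison$peak_force),
                                 comparison$scenario),
    E_recovered_MPa = cal$E
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  log <- c(
    paste("vadsim", as.character(utils::packageVersion("vadsim"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("config:", if (is.null(attr(cfg, "path"))) "<in-memory>"
          else attr(cfg, "path")),
    paste("config_md5:", if (is.null(attr(cfg, "md5"))) "<none>"
          else attr(cfg, "md5")),
    paste("seed:", seed),
    paste("scenarios:", nrow(scen))
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))

  invisible(list(results = results, comparison = comparison,
                 calibration = cal, out_dir = out_dir))
}
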