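# Config-driven pipeline: a validated YAML config mapping to the package's
# parameter objects, and a deterministic runner writing JSON/TSV results
# with a hashed manifest.

.config_schema <- list(
  top = c("kind", "seed", "output_dir", "input_dir", "tpm", "fd", "polymer",
          "tether", "binding", "isotherm", "sweep", "log_level"),
  tpm = c("drift_window_s", "stuck_threshold_nm", "anisotropy_max",
          "bin_width_nm", "tracking_noise_nm"),
  fd = c("force_min_pN", "force_max_pN", "min_drop_pN", "max_span_um",
         "min_events"),
  polymer = c("persistence_length_nm", "contour_length_um",
              "stretch_modulus_pN", "thermal_energy"),
  tether = c("dna_length_bp", "segment_length_nm", "bead_radius_nm"),
  binding = c("mode", "footprint_bp", "bend_angle_deg", "filament_lp_nm",
              "unwind_factor"),
  isotherm = c("kd_nM", "footprint_bp", "omega", "stiffening_onset",
               "onset_width", "salt_label"),
  sweep = c("concentrations_nM", "n_samples", "burnin", "thin")
)

.config_defaults <- function() list(
  seed = 1L,
  log_level = "info",
  tpm = list(drift_window_s = 4, stuck_threshold_nm = 60,
             anisotropy_max = 1.3, bin_width_nm = 5, tracking_noise_nm = 10),
  fd = list(force_min_pN = 0.5, force_max_pN = 30, min_drop_pN = 2,
            max_span_um = 0.2, min_events = 3),
  polymer = list(persistence_length_nm = 47.2, contour_length_um = 16.4,
                 stretch_modulus_pN = 1200, thermal_energy = KBT_ROOM),
  tether = list(dna_length_bp = 685, segment_length_nm = 5,
                bead_radius_nm = 230),
  binding = list(mode = "bend", footprint_bp = 25, bend_angle_deg = 60,
                 filament_lp_nm = 61, unwind_factor = 0.1),
  isotherm = list(kd_nM = 1, footprint_bp = 25, omega = 1,
                  stiffening_onset = 0.878, onset_width = 0.04,
                  salt_label = ""),
  sweep = list(concentrations_nM = c(0, 1, 5, 20, 50, 100, 500, 1000, 3000),
               n_samples = 4000, burnin = 10000, thin = 10)
)

.merge_defaults <- function(given, defaults) {
  for (k in names(defaults)) {
    if (is.null(given[[k]])) given[[k]] <- defaults[[k]]
  }
  given
}

.check_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad)) {
    stop(sprintf("unknown config key%s in %s: %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
}

.check_pos_key <- function(value, key) {
  if (!is.numeric(value) || any(is.na(value)) || any(value <= 0)) {
    stop(sprintf("config key '%s' must be positive", key), call. = FALSE)
  }
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, applies documented
#' defaults and validates physical parameters (all must be positive);
#' validation errors name the offending key.
#'
#' @param path YAML file path
#' @return an object of class \code{run_config}
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  .check_keys(cfg, .config_schema$top, "config")
  if (is.null(cfg$kind) || !cfg$kind %in% c("tpm", "fd", "sweep")) {
    stop("config key 'kind' must be one of: tpm, fd, sweep", call. = FALSE)
  }
  defaults <- .config_defaults()
  for (blk in c("tpm", "fd", "polymer", "tether", "binding", "isotherm",
                "sweep")) {
    if (!is.null(cfg[[blk]])) .check_keys(cfg[[blk]], .config_schema[[blk]], blk)
    cfg[[blk]] <- .merge_defaults(cfg[[blk]], defaults[[blk]])
  }
  cfg <- .merge_defaults(cfg, defaults[c("seed", "log_level")])
  for (key in c("kd_nM", "footprint_bp", "omega")) {
    .check_pos_key(cfg$isotherm[[key]], paste0("isotherm.", key))
  }
  for (key in c("persistence_length_nm", "contour_length_um",
                "stretch_modulus_pN", "thermal_energy")) {
    .check_pos_key(cfg$polymer[[key]], paste0("polymer.", key))
  }
  for (key in c("dna_length_bp", "segment_length_nm", "bead_radius_nm")) {
    .check_pos_key(cfg$tether[[key]], paste0("tether.", key))
  }
  if (!cfg$binding$mode %in% c("none", "bend", "stiffen", "bridge")) {
    stop("config key 'binding.mode' must be none/bend/stiffen/bridge",
         call. = FALSE)
  }
  if (cfg$kind %in% c("tpm", "fd") && is.null(cfg$input_dir)) {
    stop(sprintf("config key 'input_dir' is required for kind '%s'", cfg$kind),
         call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Serialize a run configuration back to YAML
#' @param config a \code{run_config}
#' @param path output path
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.cfg_polymer <- function(cfg) {
  polymer_params(cfg$polymer$persistence_length_nm,
                 cfg$polymer$contour_length_um * 1000,
                 cfg$polymer$stretch_modulus_pN,
                 cfg$polymer$thermal_energy)
}

.cfg_isotherm <- function(cfg) {
  isotherm_params(cfg$isotherm$kd_nM, cfg$isotherm$footprint_bp,
                  cfg$isotherm$omega, cfg$isotherm$stiffening_onset,
                  cfg$isotherm$onset_width, cfg$isotherm$salt_label)
}

#' Run the analysis pipeline described by a configuration
#'
#' Dispatches on \code{config$kind}:
#' \describe{
#'   \item{tpm}{read every trajectory TSV in \code{input_dir}, drift-correct,
#'     select tethers, compute per-tether RMS and the population Gaussian
#'     fit; writes \code{tpm_results.json} and \code{per_tether.tsv}.}
#'   \item{fd}{read every FD TSV in \code{input_dir}; serrated extension
#'     curves get rupture tables, clean ones eWLC fits; writes
#'     \code{fd_results.json}.}
#'   \item{sweep}{forward model: \code{\link{predict_mechanics}} table and
#'     the simulated \code{\link{rms_concentration_curve}}; writes
#'     \code{sweep.tsv} and \code{sweep_results.json}.}
#' }
#' Every run writes \code{manifest.json} listing each output file with its
#' MD5 content hash plus the fully-resolved configuration; reruns with the
#' same seed produce byte-identical payloads.
#'
#' @param config a \code{\link{load_config}} result
#' @return (invisibly) the manifest as a list
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  if (is.null(out)) stop("config key 'output_dir' is required", call. = FALSE)
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  files <- character(0)

  if (config$kind == "tpm") {
    paths <- sort(list.files(config$input_dir, pattern = "\\.tsv$",
                             full.names = TRUE))
    if (!length(paths)) stop("no trajectory TSV files in input_dir",
                             call. = FALSE)
    trajs <- lapply(paths, read_trajectory_tsv)
    corrected <- lapply(trajs, function(tr) {
      w <- min(config$tpm$drift_window_s, .traj_duration(tr) / 4)
      drift_correct(tr, max(1, w))
    })
    sel <- select_tethers(corrected, config$tpm$stuck_threshold_nm,
                          config$tpm$anisotropy_max)
    rms <- vapply(sel$accepted, rms_of_trajectory, numeric(1))
    pop <- population_rms(rms, config$tpm$bin_width_nm)
    per <- data.frame(file = basename(paths)[sel$index], rms_nm = rms)
    f1 <- file.path(out, "per_tether.tsv")
    write.table(format(per, digits = 8, trim = TRUE), f1, sep = "\t",
                quote = FALSE, row.names = FALSE)
    f2 <- file.path(out, "tpm_results.json")
    .write_result_json(list(
      population_mean_nm = pop$population_mean,
      population_sem_nm = pop$population_sem,
      gaussian_sigma_nm = pop$gaussian_sigma,
      n_tethers = pop$n_tethers,
      fit_converged = pop$converged,
      multimodal = pop$multimodal,
      n_rejected = nrow(sel$rejected),
      rejections = if (nrow(sel$rejected)) sel$rejected else NULL), f2)
    files <- c(f1, f2)
  } else if (config$kind == "fd") {
    paths <- sort(list.files(config$input_dir, pattern = "\\.tsv$",
                             full.names = TRUE))
    if (!length(paths)) stop("no FD TSV files in input_dir", call. = FALSE)
    res <- lapply(paths, function(pth) {
      cv <- read_fd_tsv(pth)
      if (cv$direction != "extension") {
        return(list(file = basename(pth), direction = cv$direction))
      }
      ev <- detect_ruptures(cv, config$fd$min_drop_pN, config$fd$max_span_um,
                            ref_lp = config$polymer$persistence_length_nm,
                            ref_k = config$polymer$stretch_modulus_pN,
                            thermal_energy = config$polymer$thermal_energy)
      serr <- nrow(ev) >= config$fd$min_events
      fit <- if (!serr) {
        ft <- fit_ewlc(cv, c(config$fd$force_min_pN, config$fd$force_max_pN),
                       thermal_energy = config$polymer$thermal_energy,
                       min_drop = config$fd$min_drop_pN,
                       max_span = config$fd$max_span_um,
                       min_events = config$fd$min_events)
        list(persistence_length_nm = ft$persistence_length,
             contour_length_um = ft$contour_length,
             stretch_modulus_pN = ft$stretch_modulus,
             residual_rms_pN = ft$residual_rms, converged = ft$converged)
      } else NULL
      list(file = basename(pth), direction = "extension", serrated = serr,
           n_events = nrow(ev),
           events = if (nrow(ev)) ev else NULL, fit = fit)
    })
    f1 <- file.path(out, "fd_results.json")
    .write_result_json(res, f1)
    files <- f1
  } else {  # sweep
    iso <- .cfg_isotherm(config)
    base <- .cfg_polymer(config)
    concs <- sort(unique(c(0, config$sweep$concentrations_nM)))
    mech <- predict_mechanics(concs[concs > 0], iso,
                              kink_spec(config$binding$bend_angle_deg,
                                        bp_to_nm(config$binding$footprint_bp)),
                              config$binding$filament_lp_nm, base,
                              config$binding$unwind_factor)
    model <- tether_model(config$tether$dna_length_bp,
                          config$tether$segment_length_nm,
                          config$polymer$persistence_length_nm,
                          config$tether$bead_radius_nm,
                          thermal_energy = config$polymer$thermal_energy)
    template <- binding_state(config$binding$mode,
                              footprint = config$binding$footprint_bp,
                              bend_angle = config$binding$bend_angle_deg,
                              filament_lp = config$binding$filament_lp_nm,
                              unwind_factor = config$binding$unwind_factor)
    sweep <- rms_concentration_curve(model, template, iso, concs,
                                     n_samples = config$sweep$n_samples,
                                     seed = config$seed,
                                     thin = config$sweep$thin,
                                     burnin = config$sweep$burnin)
    f1 <- file.path(out, "sweep.tsv")
    write_rms_curve_tsv(sweep, f1)
    f2 <- file.path(out, "sweep_results.json")
    .write_result_json(list(rms_curve = as.data.frame(sweep),
                            predicted_mechanics = mech), f2)
    files <- c(f1, f2)
  }

  manifest <- list(
    kind = config$kind,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("archdna")),
    config = unclass(config),
    outputs = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  .write_result_json(manifest, file.path(out, "manifest.json"))
  invisible(manifest)
}
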