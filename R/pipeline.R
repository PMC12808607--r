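#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Unknown
#' keys are rejected; every analysis parameter surfaces here with the
#' study-design defaults (0.008-0.1 Hz band, 600-s intervals, 300-s window
#' stepped by one TR, FDR threshold 0.01).
#'
#' @param mode input mode: `"simulate"`, `"tables"` or `"volumes"`.
#' @param input input directory for `tables`/`volumes` modes (a cohort
#'   written by [export_cohort()]).
#' @param out_dir output directory for the result bundle.
#' @param seed integer seed (simulation and ICA).
#' @param simulation named list of [simulation_config()] overrides
#'   (simulate mode).
#' @param preprocessing named list: `band` (length-2 Hz), `detrend_order`,
#'   `nuisance` (`"stored"` or `"none"`).
#' @param segmentation named list: `interval_length_s`.
#' @param window named list: `window_length_s`, `step_samples`,
#'   `compute_dfc` (logical; the sliding-window stage can be skipped for
#'   speed).
#' @param contrast named list: `alpha`.
#' @param ica named list: `n_comp`, `run` (logical), `segment_length_s`
#'   (Welch).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "tables", "volumes"),
                            input = NULL, out_dir, seed = 1,
                            simulation = list(),
                            preprocessing = list(),
                            segmentation = list(),
                            window = list(),
                            contrast = list(),
                            ica = list()) {
  mode <- match.arg(mode)
  defaults <- list(
    preprocessing = list(band = c(0.008, 0.1), detrend_order = 1,
                         nuisance = "stored"),
    segmentation = list(interval_length_s = 600),
    window = list(window_length_s = 300, step_samples = 1,
                  compute_dfc = TRUE),
    contrast = list(alpha = 0.01),
    ica = list(n_comp = 20, run = TRUE, segment_length_s = 256)
  )
  merge_block <- function(name, user) {
    d <- defaults[[name]]
    unknown <- setdiff(names(user), names(d))
    if (length(unknown))
      stop("unknown key(s) in '", name, "' block: ",
           paste(unknown, collapse = ", "))
    utils::modifyList(d, user)
  }
  if (mode == "simulate") {
    unknown <- setdiff(names(simulation), names(formals(simulation_config)))
    if (length(unknown))
      stop("unknown key(s) in 'simulation' block: ",
           paste(unknown, collapse = ", "))
  } else if (is.null(input)) {
    stop("mode '", mode, "' requires an input directory")
  }
  structure(list(mode = mode, input = input, out_dir = out_dir,
                 seed = as.integer(seed), simulation = simulation,
                 preprocessing = merge_block("preprocessing", preprocessing),
                 segmentation = merge_block("segmentation", segmentation),
                 window = merge_block("window", window),
                 contrast = merge_block("contrast", contrast),
                 ica = merge_block("ica", ica)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()].
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown top-level key(s) in config: ",
         paste(unknown, collapse = ", "))
  if (!is.null(y$preprocessing$band))
    y$preprocessing$band <- as.numeric(unlist(y$preprocessing$band))
  do.call(pipeline_config, y)
}

.log_stage <- function(log_path, msg) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", msg)
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Loads or simulates a cohort, preprocesses it, segments conditions, and
#' writes per-run artifacts to the output directory: interval FC matrices,
#' consecutive-interval difference matrices, FC variability, global-FC
#' time courses, the drug-specific edge-contrast tables per genotype (with
#' injection-artifact exclusion and significant-edge lists), ICA component
#' maps/time-course amplitudes, slow-band power statistics, and a JSON
#' manifest (config, seed, package version). Identical config and seed
#' produce identical bundles.
#'
#' @param config a [pipeline_config()] or a YAML path.
#' @return invisibly, a result list (`tsset`, `segmentation`, `fc_var`,
#'   `edge_tables`, `global_fc`, `ica`, `band_tests`, `manifest_path`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  t0 <- Sys.time()
  stage <- function(msg) .log_stage(log_path, msg)

  truth <- NULL
  if (config$mode == "simulate") {
    stage("simulate: generating synthetic cohort")
    sim_args <- utils::modifyList(list(seed = config$seed), config$simulation)
    sim <- simulate_cohort(do.call(simulation_config, sim_args))
    tsset <- sim$tsset; truth <- sim$truth
  } else {
    stage(paste0("load: reading cohort from ", config$input))
    tsset <- read_cohort(config$input)
  }

  stage("preprocess: detrend + nuisance regression + band-pass")
  nuis <- if (identical(config$preprocessing$nuisance, "none")) NULL else "stored"
  pp <- preprocess(tsset, nuisance = nuis,
                   band = config$preprocessing$band,
                   detrend_order = config$preprocessing$detrend_order)

  stage("segment: condition intervals")
  seg <- segment_conditions(pp, config$segmentation$interval_length_s)
  utils::write.csv(as.data.frame(seg), file.path(out, "segmentation.csv"),
                   row.names = FALSE)

  stage("static FC: interval matrices and differences")
  fc_dir <- file.path(out, "fc_matrices")
  dir.create(fc_dir, showWarnings = FALSE)
  fcints <- interval_fc_matrices(pp, seg)
  for (nm in names(fcints)) {
    zl <- fcints[[nm]]
    for (lb in names(zl))
      utils::write.csv(unclass(zl[[lb]]),
                       file.path(fc_dir, paste0(nm, "_", lb, "_z.csv")))
    for (k in seq_along(zl)[-1]) {
      d <- interval_difference(zl[[k]], zl[[k - 1]])
      utils::write.csv(d, file.path(fc_dir, paste0(
        nm, "_", names(zl)[k], "_minus_", names(zl)[k - 1], ".csv")))
    }
  }

  stage("static FC: variability by condition")
  fcv <- fc_variability_table(pp, seg)
  utils::write.csv(fcv, file.path(out, "fc_variability.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(fcv, "tests"),
                   file.path(out, "fc_variability_tests.csv"),
                   row.names = FALSE)

  gfc <- NULL
  if (isTRUE(config$window$compute_dfc)) {
    stage("dynamic FC: global-FC time courses")
    genos <- unique(vapply(pp$animals, `[[`, "", "genotype"))
    gfc <- lapply(genos, function(g) {
      gs <- global_fc_series(subset_genotype(pp, g),
                             window_length_s = config$window$window_length_s,
                             step_samples = config$window$step_samples)
      m <- t(gs$mean)
      colnames(m) <- pp$roi_labels
      tab <- data.frame(time_s = gs$window_start_times_s, m,
                        check.names = FALSE)
      utils::write.csv(tab, file.path(out, paste0("global_fc_", g, ".csv")),
                       row.names = FALSE)
      gs
    })
    names(gfc) <- genos
  }

  stage("edge statistics: drug contrast with artifact exclusion")
  genos <- unique(vapply(pp$animals, `[[`, "", "genotype"))
  edge_tables <- lapply(genos, function(g) {
    tab <- amylin_edge_analysis(subset_genotype(pp, g), seg,
                                alpha = config$contrast$alpha)
    export_edges(tab, file.path(out, paste0("edges_", g, ".csv")))
    tab
  })
  names(edge_tables) <- genos

  cs <- NULL; band_tests <- NULL
  if (isTRUE(config$ica$run)) {
    stage("ICA: group decomposition and slow-band spectra")
    cs <- group_ica(pp, n_comp = config$ica$n_comp, seed = config$seed)
    utils::write.csv(cs$spatial_maps, file.path(out, "ica_maps.csv"))
    amp <- do.call(rbind, lapply(names(cs$time_courses), function(nm) {
      do.call(rbind, lapply(seq_len(cs$n_comp), function(k) {
        a <- condition_amplitude(cs$time_courses[[nm]][k, ], seg)
        data.frame(animal = nm, component = k, condition = names(a),
                   amplitude = unname(a))
      }))
    }))
    utils::write.csv(amp, file.path(out, "ica_amplitudes.csv"),
                     row.names = FALSE)
    band_tests <- do.call(rbind, lapply(seq_len(cs$n_comp), function(k) {
      bt <- band_power_analysis(cs, k, pp, seg,
                                segment_length_s = config$ica$segment_length_s)
      cbind(component = k, bt$tests)
    }))
    utils::write.csv(band_tests, file.path(out, "band_power_tests.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    package = "pharmfc",
    version = as.character(utils::packageVersion("pharmfc")),
    seed = config$seed,
    mode = config$mode,
    config = unclass(config)[setdiff(names(unclass(config)), "out_dir")],
    n_animals = length(pp$animals),
    n_roi = length(pp$roi_labels),
    n_samples = ncol(pp$animals[[1]]$signal),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  manifest_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  stage("done")
  invisible(list(tsset = pp, truth = truth, segmentation = seg,
                 fc_var = fcv, edge_tables = edge_tables, global_fc = gfc,
                 ica = cs, band_tests = band_tests,
                 manifest_path = manifest_path))
}
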