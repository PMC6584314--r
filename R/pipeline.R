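#' Validate and normalize a pipeline configuration
#'
#' Accepts a configuration as a YAML/JSON file path or a nested list,
#' rejects unknown keys, injects documented defaults, normalizes units
#' (lengths to um, times to s, concentrations to nM — values may be bare
#' numbers in the target unit or `"value unit"` strings such as
#' `"1.8 mm"`), and range-checks every field.
#'
#' Blocks: `geometry` ([chip_geometry()] arguments), `tracer`
#' ([tracer_spec()] arguments or `preset: 10kDa/70kDa`), `transport`
#' (`p_scaffold`, optional `p_endothelium`, `apical_fill_tau`, or
#' `acellular: true`), `acquisition` ([acquisition_config()] arguments
#' minus the seed), `analysis` (`rel_tol`, `window`, `pixel_size`,
#' `sectors`, `method`, `scaffold`: a number, `"from-acellular-run"`, or
#' null), `seeds` (non-empty integer vector), `output_dir` (optional).
#'
#' @param config path to a YAML/JSON file, or a nested list.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not found", config))
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a list")
  known_top <- c("geometry", "tracer", "transport", "acquisition",
                 "analysis", "seeds", "output_dir", "truth")
  check_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop(sprintf("unknown key(s) in %s: %s", where,
                   paste(bad, collapse = ", ")))
  }
  check_keys(config, known_top, "config")

  g <- config$geometry
  check_keys(g, c("apical_width", "channel_height", "chamber_diameter",
                  "pore_width", "pore_height", "pore_depth", "pore_spacing"),
             "geometry")
  g <- lapply(g, parse_quantity, target = "um")
  geometry <- do.call(chip_geometry, g)

  tr <- config$tracer
  check_keys(tr, c("preset", "name", "molecular_weight_kda",
                   "stokes_radius_A", "inlet_concentration_nM",
                   "brightness_gain"), "tracer")
  if (!is.null(tr$preset)) {
    preset <- tr$preset; tr$preset <- NULL
    tracer <- do.call(fitc_dextran, c(list(size = preset), tr))
  } else {
    if (!is.null(tr$inlet_concentration_nM))
      tr$inlet_concentration_nM <- parse_quantity(tr$inlet_concentration_nM, "nM")
    tracer <- do.call(tracer_spec, tr)
  }

  tp <- config$transport
  check_keys(tp, c("p_endothelium", "p_scaffold", "apical_fill_tau",
                   "acellular"), "transport")
  acellular <- isTRUE(tp$acellular)
  if (is.null(tp$p_endothelium) && !acellular)
    stop("transport: either p_endothelium must be given or acellular: true set")
  if (!is.null(tp$p_endothelium) && acellular)
    stop("transport: p_endothelium and acellular: true are mutually exclusive")
  ps <- parse_quantity(tp$p_scaffold, "cm/s", "transport.p_scaffold")
  if (is.null(ps) || ps <= 0) stop("transport.p_scaffold must be positive")
  pe <- if (acellular) NULL else
    parse_quantity(tp$p_endothelium, "cm/s", "transport.p_endothelium")
  if (!is.null(pe) && pe <= 0) stop("transport.p_endothelium must be positive")
  tau <- if (is.null(tp$apical_fill_tau)) 300
         else parse_quantity(tp$apical_fill_tau, "s", "transport.apical_fill_tau")
  transport <- transport_params(p_scaffold = ps, p_endothelium = pe,
                                vs_ratio = geometry$vs_ratio_cm,
                                apical_fill_tau = tau)

  aq <- config$acquisition
  check_keys(aq, c("frame_interval", "n_frames", "bit_depth",
                   "background_level", "photon_gain", "read_noise_sd",
                   "bleach_rate"), "acquisition")
  if (!is.null(aq$frame_interval))
    aq$frame_interval <- parse_quantity(aq$frame_interval, "s",
                                        "acquisition.frame_interval")
  acquisition <- do.call(acquisition_config, aq)

  an <- config$analysis
  check_keys(an, c("rel_tol", "window", "pixel_size", "sectors", "method",
                   "scaffold"), "analysis")
  analysis <- list(
    rel_tol = if (is.null(an$rel_tol)) 0.02 else an$rel_tol,
    window = if (is.null(an$window)) 5L else as.integer(an$window),
    pixel_size = if (is.null(an$pixel_size)) 10
                 else parse_quantity(an$pixel_size, "um", "analysis.pixel_size"),
    sectors = isTRUE(an$sectors),
    method = if (is.null(an$method)) "slope" else
      match.arg(an$method, c("slope", "log-slope")),
    scaffold = an$scaffold)
  if (!is.null(analysis$scaffold) && is.character(analysis$scaffold) &&
      analysis$scaffold != "from-acellular-run")
    stop("analysis.scaffold must be a number, 'from-acellular-run', or null")
  if (is.numeric(analysis$scaffold) && analysis$scaffold <= 0)
    stop("analysis.scaffold must be positive")
  if (analysis$rel_tol <= 0 || analysis$rel_tol >= 1)
    stop("analysis.rel_tol must be in (0, 1)")

  seeds <- as.integer(config$seeds)
  if (length(seeds) == 0 || anyNA(seeds))
    stop("seeds must be a non-empty list of integers")

  out <- list(geometry = geometry, tracer = tracer, transport = transport,
              acellular = acellular, acquisition = acquisition,
              analysis = analysis, seeds = seeds,
              output_dir = config$output_dir)
  class(out) <- "pipeline_config"
  out
}

# one simulate -> extract -> normalize -> fit pass; scaffold handling is the
# caller's job (p_scaffold = NULL returns raw p_total only)
run_single <- function(cfg, transport, seed, masks, p_scaffold = NULL) {
  acq <- cfg$acquisition
  acq$seed <- as.integer(seed)
  sim <- generate_acquisition(cfg$geometry, cfg$tracer, transport, acq,
                              masks = masks)
  ts <- extract_timeseries(sim, masks, sectors = cfg$analysis$sectors)
  prof <- normalize_profile(ts, rel_tol = cfg$analysis$rel_tol,
                            window = cfg$analysis$window)
  fit_permeability(prof, vs_ratio = cfg$geometry$vs_ratio_cm,
                   p_scaffold = p_scaffold, method = cfg$analysis$method,
                   sectors = cfg$analysis$sectors)
}

#' Run the simulate/extract/fit recovery pipeline over seeds
#'
#' For every seed, simulates an acquisition at the configured ground
#' truth, extracts and normalizes the intensity profile, and fits the
#' permeability. When `analysis$scaffold` is `"from-acellular-run"`, a
#' companion acellular acquisition is simulated per seed and the mean
#' acellular \eqn{P_{total}} across seeds is used as the scaffold value
#' for the endothelial subtraction; a numeric `analysis$scaffold` is used
#' directly. Identical configuration and seeds give an identical report.
#'
#' @param config a [validate_config()] result, or anything it accepts.
#' @return An object of class `pipeline_report`: `runs` (one row per
#'   seed: recovered `p_total`, CI, `p_endothelium`, detected times,
#'   `r_squared`), `acellular_runs` (when simulated), `summary`
#'   (medians/IQRs alongside the ground truths), `warnings`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  masks <- rasterize_chip(cfg$geometry, cfg$analysis$pixel_size)
  logs <- character(0)
  note <- function(stage, seed, msg)
    logs <<- c(logs, sprintf("[%s seed %d] %s", stage, seed, msg))

  scaffold_cfg <- cfg$analysis$scaffold
  ac_rows <- NULL
  p_scaffold_used <- NULL
  if (identical(scaffold_cfg, "from-acellular-run")) {
    ac_transport <- transport_params(p_scaffold = cfg$transport$p_scaffold,
                                     p_endothelium = NULL,
                                     vs_ratio = cfg$transport$vs_ratio,
                                     apical_fill_tau = cfg$transport$apical_fill_tau)
    for (s in cfg$seeds) {
      f <- withCallingHandlers(
        tryCatch(run_single(cfg, ac_transport, s + 10000L, masks),
                 error = function(e) { note("acellular", s, conditionMessage(e)); NULL }),
        warning = function(w) { note("acellular", s, conditionMessage(w))
                                invokeRestart("muffleWarning") })
      if (!is.null(f))
        ac_rows <- rbind(ac_rows, data.frame(seed = s, p_total = f$p_total,
                                             ci_lo = f$ci95_p[1],
                                             ci_hi = f$ci95_p[2],
                                             r_squared = f$fit$r_squared))
    }
    if (is.null(ac_rows)) stop("all acellular runs failed")
    p_scaffold_used <- mean(ac_rows$p_total)
  } else if (is.numeric(scaffold_cfg)) {
    p_scaffold_used <- scaffold_cfg
  }

  rows <- NULL
  sector_tabs <- list()
  for (s in cfg$seeds) {
    f <- withCallingHandlers(
      tryCatch(run_single(cfg, cfg$transport, s, masks,
                          p_scaffold = if (cfg$acellular) NULL else p_scaffold_used),
               error = function(e) { note("cellular", s, conditionMessage(e)); NULL }),
      warning = function(w) { note("cellular", s, conditionMessage(w))
                              invokeRestart("muffleWarning") })
    if (is.null(f)) next
    rows <- rbind(rows, data.frame(
      seed = s, p_total = f$p_total,
      ci_lo = f$ci95_p[1], ci_hi = f$ci95_p[2],
      p_endothelium = if (is.null(f$p_endothelium)) NA_real_ else f$p_endothelium,
      t_inflection_s = f$t_inflection, t_plateau_s = f$t_plateau,
      r_squared = f$fit$r_squared))
    if (!is.null(f$sectors)) sector_tabs[[as.character(s)]] <- f$sectors
  }
  if (is.null(rows)) stop("all pipeline runs failed")

  iqr <- function(x) unname(diff(stats::quantile(x, c(0.25, 0.75), na.rm = TRUE)))
  summ <- list(
    n_seeds = length(cfg$seeds), n_ok = nrow(rows),
    truth_p_total = cfg$transport$p_total,
    truth_p_endothelium = cfg$transport$p_endothelium,
    truth_p_scaffold = cfg$transport$p_scaffold,
    p_scaffold_used = p_scaffold_used,
    median_p_total = stats::median(rows$p_total), iqr_p_total = iqr(rows$p_total),
    median_p_endothelium = if (all(is.na(rows$p_endothelium))) NA_real_
                           else stats::median(rows$p_endothelium, na.rm = TRUE),
    iqr_p_endothelium = if (all(is.na(rows$p_endothelium))) NA_real_
                        else iqr(rows$p_endothelium))
  out <- list(runs = rows, acellular_runs = ac_rows, summary = summ,
              sectors = if (length(sector_tabs)) sector_tabs else NULL,
              warnings = logs, config = cfg)
  class(out) <- "pipeline_report"
  if (!is.null(cfg$output_dir)) {
    if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
    utils::write.csv(rows, file.path(cfg$output_dir, "runs.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summ, file.path(cfg$output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         null = "null")
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Recovery pipeline: %d/%d seeds analysed\n", s$n_ok, s$n_seeds))
  cat(sprintf("  truth   P_total = %.4g cm/s", s$truth_p_total))
  if (!is.null(s$truth_p_endothelium))
    cat(sprintf(", P_e = %.4g, P_scaffold = %.4g",
                s$truth_p_endothelium, s$truth_p_scaffold))
  cat("\n")
  cat(sprintf("  median  P_total = %.4g cm/s (IQR %.2g)\n",
              s$median_p_total, s$iqr_p_total))
  if (!is.null(s$p_scaffold_used))
    cat(sprintf("  scaffold used   = %.4g cm/s\n", s$p_scaffold_used))
  if (!is.na(s$median_p_endothelium))
    cat(sprintf("  median  P_e     = %.4g cm/s (IQR %.2g)\n",
                s$median_p_endothelium, s$iqr_p_endothelium))
  if (length(x$warnings))
    cat(sprintf("  %d warnings/errors logged\n", length(x$warnings)))
  invisible(x)
}

#' Packaged fixture configurations
#'
#' Ready-made pipeline configurations encoding the reference study
#' conditions: 10 and 70 kDa FITC-dextran runs, cellular and acellular,
#' at the published ground-truth permeabilities and chip geometry.
#'
#' @param name one of `"cellular_10kDa"`, `"cellular_70kDa"`,
#'   `"acellular_10kDa"`, `"acellular_70kDa"`.
#' @return The path of the packaged YAML file.
#' @export
fixture_config <- function(name = c("cellular_10kDa", "cellular_70kDa",
                                    "acellular_10kDa", "acellular_70kDa")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "permchip")
  if (path == "") stop("fixture not found; is the package installed?")
  path
}
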