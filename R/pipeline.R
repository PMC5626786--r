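# --- end-to-end orchestration ------------------------------------------------

#' Default run configuration
#'
#' Nested list of every stage's parameters with explicit seeds; round-trips
#' losslessly through YAML ([read_config()] / [write_config()]).
#'
#' @param seed Master seed; stage seeds derive from it.
#' @return A named list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    system = list(template = "sh3_like", n_sites = 14, nucleus = "15N",
                  kex = 182, p_b = 0.029, dw_range = c(0.2, 3)),
    grid = list(np = c(64, 48), sw = c(2400, 2500), labels = c("h", "n")),
    cpmg = list(nu = default_nu_grid(), t_relax = 0.04, field = 18.8),
    noise_sigma = 0.05,
    schedule = list(nus_fraction = 0.25, t_match = 0.1, coupled = FALSE),
    reconstruction = list(method = "comdd", n_components_extra = 2,
                          lambda = 1e-4, n_iter = 2000, irls_iter = 30,
                          irls_p = 0.5),
    quantify = list(window = 3),
    errors = list(method = "jackknife", n_trials = 20, omit_frac = 0.175),
    fit = list(starts = 10, alpha = 0.01)
  )
}

#' Read / write run configurations
#'
#' @param config A configuration list.
#' @param path YAML file path.
#' @return `read_config` returns the list; `write_config` returns `path`
#'   invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config(cfg$seed %||% 1)
  utils::modifyList(base, cfg)
}

build_stage_objects <- function(config) {
  grid <- grid_spec(np = config$grid$np, sw = config$grid$sw,
                    labels = config$grid$labels)
  spec <- cpmg_spec(nu = config$cpmg$nu, t_relax = config$cpmg$t_relax,
                    field = config$cpmg$field,
                    nucleus = config$system$nucleus)
  system <- make_system(
    template = config$system$template, n_sites = config$system$n_sites,
    seed = config$seed, nucleus = config$system$nucleus,
    kex = config$system$kex, p_b = config$system$p_b,
    dw_range = config$system$dw_range, grid = grid,
    field = config$cpmg$field
  )
  list(grid = grid, spec = spec, system = system)
}

# reconstructor closure for a config (used by the pipeline, jackknife and TA)
config_reconstructor <- function(config, n_peaks) {
  method <- config$reconstruction$method
  if (method == "comdd") {
    function(td) {
      comdd_reconstruct(comdd_fit(
        td, n_components = n_peaks + config$reconstruction$n_components_extra,
        lambda = config$reconstruction$lambda,
        n_iter = config$reconstruction$n_iter,
        seed = config$seed + 7L
      ))
    }
  } else if (method == "irls_ve") {
    function(td) {
      irls_ve_reconstruct(td, n_iter = config$reconstruction$irls_iter,
                          p = config$reconstruction$irls_p)
    }
  } else if (method == "full_ft") {
    full_ft
  } else {
    stop("unknown reconstruction method: ", method)
  }
}

#' Run the complete dispersion pipeline
#'
#' Simulate a system, sample it, reconstruct, quantify, estimate errors,
#' screen for significant exchange and fit the global two-state model.
#' With a fixed configuration (and its seeds) the run is deterministic and
#' the written CSV outputs are byte-identical between invocations.
#'
#' @param config Configuration list (see [default_config()]) or a YAML path.
#' @param out_dir Optional output directory for the documented file formats.
#' @return List: `system`, `schedule`, `spectra`, `intensities`, `curves`,
#'   `screen`, `fit` (`NULL` for flat systems with < 2 significant residues).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  st <- build_stage_objects(config)
  n_peaks <- nrow(st$system$sites)

  td_full <- synthesize_fid(st$system, st$grid, st$spec,
                            noise_sigma = config$noise_sigma,
                            seed = config$seed + 1L)
  use_nus <- config$reconstruction$method != "full_ft"
  if (use_nus) {
    schedule <- generate_schedule(
      st$grid, n_planes(st$spec), config$schedule$nus_fraction,
      t_match = config$schedule$t_match, seed = config$seed + 2L,
      coupled = isTRUE(config$schedule$coupled)
    )
    td <- apply_schedule(td_full, schedule)
  } else {
    schedule <- NULL
    td <- td_full
  }

  reconstructor <- config_reconstructor(config, n_peaks)
  spectra <- reconstructor(td)
  peaks <- peak_list(st$system, st$grid, window = config$quantify$window)
  intens <- extract_intensities(spectra, peaks)

  jk <- NULL
  if (use_nus && config$errors$method == "jackknife") {
    plan <- jackknife_plan(
      nrow(schedule),
      d = max(ceiling(sqrt(nrow(schedule))),
              round(config$errors$omit_frac * nrow(schedule))),
      n_trials = config$errors$n_trials, seed = config$seed + 3L
    )
    jk <- jackknife_errors(td, plan, reconstructor, peaks)
    intens <- with_jackknife_errors(intens, jk)
    curves <- with_jackknife_r2_errors(compute_r2eff(intens), jk)
  } else {
    intens <- with_noise_floor_errors(intens, spectra)
    curves <- compute_r2eff(intens)
  }
  screen <- significant_peaks(curves, alpha = config$fit$alpha)
  sig <- screen$peak[screen$significant]
  fit <- if (length(sig) >= 2) {
    fit_global(curves[curves$peak %in% sig, ],
               starts = config$fit$starts, seed = config$seed + 4L)
  } else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.yml"))
    write_system(st$system, file.path(out_dir, "system.txt"))
    if (!is.null(schedule)) {
      write_nuslist(schedule, file.path(out_dir, "nuslist.txt"))
    }
    write_peak_list(peaks, file.path(out_dir, "peaks.tsv"))
    write_intensity_table(intens, file.path(out_dir, "intensities.tsv"))
    write_dispersion_csv(curves, file.path(out_dir, "dispersion.csv"))
    utils::write.csv(screen, file.path(out_dir, "significance.csv"),
                     row.names = FALSE)
    if (!is.null(fit)) {
      write_fit_report(fit, file.path(out_dir, "fit_report.txt"))
      utils::write.csv(tidy(fit), file.path(out_dir, "fit.csv"),
                       row.names = FALSE)
    }
  }

  list(system = st$system, schedule = schedule, spectra = spectra,
       intensities = intens, curves = curves, screen = screen, fit = fit)
}
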