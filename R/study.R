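# --- canned study protocols ---------------------------------------------------
#
# Reproducible end-to-end experiments at the conditions of the validation
# study: two-dimensional parameter recovery against fully sampled reference
# spectra, the NUS-bias comparison, jackknife error calibration against a
# Monte-Carlo ground truth, and targeted-acquisition error tracking. These
# functions are what the acceptance script and the heavier tests run.

#' Two-dimensional parameter recovery at full sampling
#'
#' Simulates the partially ligand-bound SH3-like system (14 exchanging
#' residues for 15N, 17 for 13CO, global parameters kex = 182 s^-1 /
#' p_b = 2.9% and 173 s^-1 / 3.6% respectively), records the fully sampled
#' 2D series with duplicate CPMG frequencies, processes it with the
#' reference FT, estimates the global rate error from the duplicates and
#' fits the global two-state model.
#'
#' @param nucleus `"15N"` or `"13CO"`.
#' @param seed Integer seed for system, noise and fit starts.
#' @param n_sites Residue count; defaults to the per-nucleus study value.
#' @param noise_sigma Time-domain noise; the default reproduces a rate error
#'   of roughly 0.1 s^-1, the precision scale of a well-recorded series.
#' @return List: `fit` (a `two_state_fit`), `system`, `curves`,
#'   `sigma_dup` (duplicate-based global error), `dw_rmsd` (fitted vs true
#'   shift differences, ppm).
#' @export
study_recovery_2d <- function(nucleus = c("15N", "13CO"), seed = 1,
                              n_sites = NULL, noise_sigma = 0.05) {
  nucleus <- match.arg(nucleus)
  if (is.null(n_sites)) n_sites <- if (nucleus == "15N") 14 else 17
  grid <- default_grid_2d(nucleus)
  spec <- cpmg_spec(nu = c(default_nu_grid(), 50, 200, 800),
                    nucleus = nucleus)
  sys <- make_system("sh3_like", n_sites, seed = seed, nucleus = nucleus,
                     grid = grid)
  td <- synthesize_fid(sys, grid, spec, noise_sigma = noise_sigma,
                       seed = seed + 1L)
  pk <- peak_list(sys, grid)
  cv <- compute_r2eff(extract_intensities(full_ft(td), pk))
  dup <- duplicate_global_error(cv)
  cva <- with_duplicate_errors(average_duplicates(cv), dup)
  fit <- fit_global(cva, starts = 10, seed = seed + 2L)
  rmsd <- dw_rmsd(fit$residues$delta_omega,
                  sys$sites$delta_omega[match(fit$residues$peak,
                                              sys$sites$residue_id)])
  list(fit = fit, system = sys, curves = cva, sigma_dup = dup$sigma_r2,
       dw_rmsd = rmsd)
}

#' NUS bias study: co-MDD at 25% sampling against full sampling
#'
#' Repeats the 15N recovery over independent noise realizations, processing
#' each both through the fully sampled reference FT and through a 25% NUS
#' schedule reconstructed with co-MDD, and fitting the global model either
#' way. Both fits use the duplicate-derived weights of the full-sampling
#' pass so the comparison isolates the reconstruction.
#'
#' @param seed Integer seed.
#' @param n_realizations Noise realizations (default 20).
#' @param nus_fraction NUS level for the sparse branch (default 0.25).
#' @param n_sites,noise_sigma As in [study_recovery_2d()].
#' @param fit_starts Multi-start count per fit.
#' @return Tibble with one row per realization: `kex_full`, `pb_full`,
#'   `kex_nus`, `pb_nus`.
#' @export
study_nus_bias <- function(seed = 1, n_realizations = 20, nus_fraction = 0.25,
                           n_sites = 14, noise_sigma = 0.05, fit_starts = 4) {
  grid <- default_grid_2d("15N")
  spec <- cpmg_spec(nu = c(default_nu_grid(), 50, 200, 800))
  sys <- make_system("sh3_like", n_sites, seed = seed, grid = grid)
  pk <- peak_list(sys, grid)
  P <- n_planes(spec)
  sch <- generate_schedule(grid, P, nus_fraction, seed = seed + 1L)

  one <- function(i) {
    td <- synthesize_fid(sys, grid, spec, noise_sigma = noise_sigma,
                         seed = seed + 10L + i)
    cv_full <- compute_r2eff(extract_intensities(full_ft(td), pk))
    dup <- duplicate_global_error(cv_full)
    cva_full <- with_duplicate_errors(average_duplicates(cv_full), dup)
    fit_full <- fit_global(cva_full, starts = fit_starts, seed = seed + 2L)

    m <- comdd_fit(apply_schedule(td, sch),
                   n_components = n_sites + 2, seed = seed + 3L)
    cv_nus <- compute_r2eff(extract_intensities(comdd_reconstruct(m), pk))
    cva_nus <- with_duplicate_errors(average_duplicates(cv_nus), dup)
    fit_nus <- fit_global(cva_nus, starts = fit_starts, seed = seed + 2L)

    tibble::tibble(kex_full = fit_full$kex, pb_full = fit_full$p_b,
                   kex_nus = fit_nus$kex, pb_nus = fit_nus$p_b)
  }
  dplyr::bind_rows(lapply(seq_len(n_realizations), one))
}

# 3D study geometry shared by the jackknife and TA protocols
study_grid_3d <- function(np_ind = 24) {
  grid_spec(np = c(24, np_ind, np_ind), sw = c(2400, 2250, 1400),
            labels = c("h", "n", "co"))
}

study_case_3d <- function(seed, n_sites = 6, noise_sigma = 0.06,
                          nus_fraction = 0.083, coupled = FALSE,
                          np_ind = 24) {
  grid <- study_grid_3d(np_ind)
  spec <- cpmg_spec(nu = c(50, 100, 200, 400, 1000))
  sys <- make_system("sh3_like", n_sites, seed = seed, grid = grid)
  pk <- peak_list(sys, grid, window = 2)
  sch <- generate_schedule(grid, n_planes(spec), nus_fraction,
                           seed = seed + 1L, coupled = coupled)
  list(grid = grid, spec = spec, sys = sys, pk = pk, sch = sch,
       noise_sigma = noise_sigma)
}

#' Jackknife calibration against a Monte-Carlo ground truth
#'
#' On a 3D series sampled at 8.3% NUS and reconstructed with co-MDD, runs a
#' delete-d jackknife (20 trials, 15% omission, inflation sqrt(N/d)) and
#' compares its per-point rate errors with the true spread over independent
#' noise realizations of the same schedule.
#'
#' @param seed Integer seed.
#' @param n_mc Monte-Carlo noise realizations (default 30).
#' @param n_jk_real Independent datasets the jackknife is run on; ratios are
#'   pooled across them.
#' @param omit_frac Omitted fraction per trial.
#' @return List: `ratio_median` (jackknife / Monte-Carlo sigma_R2, median
#'   over cells), `under_median` (Monte-Carlo / uninflated SD, the factor the
#'   raw spread underestimates by), `ratio_raw_pooled`, `inflation`, and the
#'   per-cell tibble `cells`.
#' @export
study_jackknife_calibration <- function(seed = 1, n_mc = 30, n_jk_real = 3,
                                        omit_frac = 0.15,
                                        noise_sigma = 0.06) {
  # the indirect grid is the largest the single-CPU validation budget
  # tolerates: the jackknife-vs-Monte-Carlo ratio converges toward 1 from
  # above as the NUS point count grows toward experimental scale
  cs <- study_case_3d(seed, noise_sigma = noise_sigma, np_ind = 40)
  recon <- function(td) {
    comdd_reconstruct(comdd_fit(td, n_components = nrow(cs$sys$sites) + 2,
                                seed = seed + 2L))
  }
  N <- nrow(cs$sch)

  mc_runs <- lapply(seq_len(n_mc), function(i) {
    td <- synthesize_fid(cs$sys, cs$grid, cs$spec,
                         noise_sigma = cs$noise_sigma, seed = seed + 100L + i)
    suppressWarnings(compute_r2eff(
      extract_intensities(recon(apply_schedule(td, cs$sch)), cs$pk)))
  })
  mc_tab <- mc_runs[[1]][, c("peak", "nu")]
  mc_tab$sigma_mc <- apply(sapply(mc_runs, `[[`, "r2eff"), 1, stats::sd)

  cells <- dplyr::bind_rows(lapply(seq_len(n_jk_real), function(r) {
    td <- apply_schedule(
      synthesize_fid(cs$sys, cs$grid, cs$spec, noise_sigma = cs$noise_sigma,
                     seed = seed + 200L + r), cs$sch)
    plan <- jackknife_plan(N, d = round(omit_frac * N), n_trials = 20,
                           seed = seed + 300L + r)
    jk <- jackknife_errors(td, plan, recon, cs$pk)
    jkp <- jk[!is.na(jk$nu), ]
    jkp$sigma_mc <- mc_tab$sigma_mc[match(paste(jkp$peak, jkp$nu),
                                          paste(mc_tab$peak, mc_tab$nu))]
    tibble::tibble(realization = r, peak = jkp$peak, nu = jkp$nu,
                   sigma_jk = jkp$sigma_r2, sd_raw = jkp$sd_raw_r2,
                   sigma_mc = jkp$sigma_mc)
  }))

  ratio_median <- stats::median(cells$sigma_jk / cells$sigma_mc, na.rm = TRUE)
  list(
    ratio_median = ratio_median,
    # per-cell underestimation factor of the raw (uninflated) SD; its median
    # equals inflation / ratio_median by construction of sigma_jk
    under_median = stats::median(cells$sigma_mc / cells$sd_raw, na.rm = TRUE),
    ratio_raw_pooled = sqrt(mean(cells$sd_raw^2, na.rm = TRUE)) /
      sqrt(mean(cells$sigma_mc^2)),
    inflation = sqrt(N / round(omit_frac * N)),
    cells = cells
  )
}

#' Targeted-acquisition study at the staged-NUS protocol
#'
#' Processes a 3D 8.3% NUS series in nested steps from 3.3% NUS, 1% added
#' per step, over several random orderings, with a delete-d jackknife at
#' every step (RMS aggregation over peaks and planes).
#'
#' @param seed Integer seed.
#' @param n_realizations Random orderings (default 4 for the scaled study;
#'   [ta_run()] itself defaults to the full 15).
#' @param jk_trials Jackknife trials per step.
#' @return A `ta_report`; summarise with [ta_summary()].
#' @export
study_ta <- function(seed = 1, n_realizations = 4, jk_trials = 6) {
  cs <- study_case_3d(seed)
  td <- apply_schedule(
    synthesize_fid(cs$sys, cs$grid, cs$spec, noise_sigma = cs$noise_sigma,
                   seed = seed + 5L), cs$sch)
  recon <- function(x) {
    comdd_reconstruct(comdd_fit(x, n_components = nrow(cs$sys$sites) + 2,
                                n_iter = 1000, seed = seed + 6L))
  }
  ta_run(td, steps = seq(0.033, 0.083, by = 0.01),
         n_realizations = n_realizations, reconstructor = recon,
         peaks = cs$pk, jk_trials = jk_trials, aggregate = "rms",
         seed = seed + 7L)
}
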