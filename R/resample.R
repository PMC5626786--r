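# --- resampling-based error estimation ---------------------------------------

#' Delete-d jackknife plan
#'
#' Describes a delete-d jackknife over the N sampled NUS points: each trial
#' omits `d` randomly chosen points, and the standard deviation over trials
#' is up-scaled by the inflation factor `F = sqrt(N / d)` (omitted subsets
#' overlap heavily, so the raw spread underestimates the true error).
#'
#' @param n_total Number of sampled NUS points N.
#' @param d Points omitted per trial; default 17.5% of N. Theory asks for
#'   `d >= sqrt(N)` (a warning is issued below that).
#' @param n_trials Number of random trials (default 20).
#' @param seed Integer seed.
#' @return A `jackknife_plan` list with the inflation factor.
#' @export
jackknife_plan <- function(n_total, d = round(0.175 * n_total), n_trials = 20,
                           seed = 1) {
  stopifnot(n_total >= 2, d >= 1, d < n_total, n_trials >= 2)
  if (d < sqrt(n_total)) {
    warning("d = ", d, " is below sqrt(N) = ", round(sqrt(n_total), 1),
            "; jackknife theory asks for d >= sqrt(N)")
  }
  structure(
    list(n_total = n_total, d = d, n_trials = n_trials,
         inflation = sqrt(n_total / d), seed = seed),
    class = "jackknife_plan"
  )
}

# draw a sub-schedule omitting d rows while keeping every plane non-empty
omit_rows <- function(schedule, d, max_tries = 50) {
  P <- length(unique(schedule$plane))
  for (t in seq_len(max_tries)) {
    drop <- sample.int(nrow(schedule), d)
    kept <- schedule[-drop, , drop = FALSE]
    if (length(unique(kept$plane)) == P) return(as_schedule(kept, schedule))
  }
  stop("omitting ", d, " points empties a CPMG plane even after ",
       max_tries, " redraws")
}

#' Per-peak, per-plane intensity errors by delete-d jackknife
#'
#' Reconstructs and quantifies `n_trials` subsampled datasets, each omitting
#' `d` random NUS points, and reports `sigma_i = inflation * SD` over trials
#' for every (peak, plane) cell — individual errors, in contrast to the
#' single global value duplicate measurements give.
#'
#' @param td A sparse `td_series` (with schedule).
#' @param plan A [jackknife_plan()]; its `n_total` must match the schedule.
#' @param reconstructor Function `td_series -> spectrum_series`, e.g.
#'   `function(x) comdd_reconstruct(comdd_fit(x, n_components = ...))`.
#' @param peaks A [peak_list()] tibble.
#' @return Tibble `peak`, `plane`, `nu`, `sigma_i`/`sd_raw_i` (inflated and
#'   raw intensity SD over trials) and `sigma_r2`/`sd_raw_r2` (the same for
#'   the per-trial effective rates, `NA` on the reference plane),
#'   `method = "jackknife"`. The rate errors are taken over the per-trial
#'   `log(I0/I)/T` values rather than propagated from the intensity errors:
#'   subsampling perturbs a peak's overall reconstructed scale coherently
#'   across planes, and that common mode cancels in the rates.
#' @export
jackknife_errors <- function(td, plan, reconstructor, peaks) {
  schedule <- td$schedule
  if (is.null(schedule)) stop("jackknife needs a NUS series with a schedule")
  if (plan$n_total != nrow(schedule)) {
    stop("plan n_total (", plan$n_total, ") does not match the schedule (",
         nrow(schedule), " points)")
  }
  t_relax <- td$spec$t_relax
  trials <- with_seed(plan$seed, {
    lapply(seq_len(plan$n_trials), function(i) omit_rows(schedule, plan$d))
  })
  vals <- lapply(trials, function(sub) {
    sp <- reconstructor(apply_schedule(td, sub))
    ii <- extract_intensities(sp, peaks)
    i0 <- ii$intensity[ii$is_ref][match(ii$peak, ii$peak[ii$is_ref])]
    ii$r2 <- ifelse(ii$is_ref | ii$intensity <= 0 | i0 <= 0, NA_real_,
                    log(i0 / ii$intensity) / t_relax)
    ii
  })
  stacked <- dplyr::bind_rows(vals, .id = "trial")
  out <- stacked |>
    dplyr::group_by(.data$peak, .data$plane, .data$nu) |>
    dplyr::summarise(sd_raw_i = stats::sd(.data$intensity),
                     sd_raw_r2 = if (all(is.na(.data$r2))) NA_real_
                                 else stats::sd(.data$r2, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(sigma_i = plan$inflation * .data$sd_raw_i,
                  sigma_r2 = plan$inflation * .data$sd_raw_r2,
                  method = "jackknife")
  out[, c("peak", "plane", "nu", "sigma_i", "sd_raw_i", "sigma_r2",
          "sd_raw_r2", "method")]
}

#' Attach jackknife rate errors to dispersion curves
#'
#' @param curves A dispersion tibble from [compute_r2eff()].
#' @param jk Output of [jackknife_errors()].
#' @return The curves with `sigma` set to the jackknife `sigma_r2`.
#' @export
with_jackknife_r2_errors <- function(curves, jk) {
  jkp <- jk[!is.na(jk$nu), ]
  m <- match(paste(curves$peak, curves$nu), paste(jkp$peak, jkp$nu))
  curves$sigma <- jkp$sigma_r2[m]
  curves
}

#' Attach jackknife intensity errors to an intensity series
#'
#' @param intens An intensity series.
#' @param jk Output of [jackknife_errors()].
#' @return The intensity series with `sigma_i` replaced by the jackknife
#'   estimates.
#' @export
with_jackknife_errors <- function(intens, jk) {
  m <- match(paste(intens$peak, intens$plane),
             paste(jk$peak, jk$plane))
  intens$sigma_i <- jk$sigma_i[m]
  intens
}

#' Global R2eff error from duplicate CPMG frequencies
#'
#' Classical estimate used when some CPMG frequencies are measured twice:
#' the root-mean-square of the half-differences between duplicate `R2eff`
#' values, pooled over peaks and duplicated frequencies. This estimates the
#' error of the duplicate-averaged rates; a configurable floor guards the
#' noiseless limit.
#'
#' @param curves A dispersion tibble containing repeated `nu` values.
#' @param floor Minimum returned sigma.
#' @return One-row tibble: `sigma_r2`, `n_pairs`, `method = "duplicates"`.
#' @export
duplicate_global_error <- function(curves, floor = 0) {
  use <- curves[curves$ok & !is.na(curves$r2eff), ]
  groups <- split(use$r2eff, paste(use$peak, use$nu))
  groups <- groups[lengths(groups) >= 2]
  if (length(groups) == 0) stop("no repeated CPMG frequencies in the curves")
  hd2 <- vapply(groups, function(x) {
    pairs <- utils::combn(x, 2)
    mean(((pairs[1, ] - pairs[2, ]) / 2)^2)
  }, numeric(1))
  tibble::tibble(sigma_r2 = max(sqrt(mean(hd2)), floor),
                 n_pairs = length(hd2), method = "duplicates")
}

#' Targeted-acquisition error tracking
#'
#' Emulates incremental NUS acquisition with concurrent processing: the
#' sampled points are put in a random order and processed in nested steps of
#' growing NUS fraction. The step-to-step change of the peak intensities is
#' the real-time precision estimate; a delete-d jackknife at each step
#' provides the reference track. Both are aggregated over peaks and planes
#' (RMS by default, median optionally).
#'
#' The previous step is exactly one delete-d resample of the current one
#' (the d points added since then are 'omitted'), so the aggregated step
#' difference is up-scaled by the same inflation factor,
#' `sqrt(N_s / (N_s - N_(s-1)))`, that a multi-trial jackknife would use;
#' this puts the single-resample track on the same scale as the jackknife
#' track. The raw (uninflated) aggregate is kept in `raw_step_error`.
#'
#' @param td Sparse `td_series` holding the full NUS point set.
#' @param steps Increasing NUS fractions (of the full indirect x plane grid);
#'   the last must not exceed the available fraction. Default: 3.3% to the
#'   available fraction in 1% steps.
#' @param n_realizations Random orderings to average over (default 15).
#' @param reconstructor Function `td_series -> spectrum_series`.
#' @param peaks A [peak_list()] tibble.
#' @param target_sigma Optional intensity-error target; the report flags the
#'   first step whose jackknife error falls at or below it.
#' @param jk_trials,jk_frac Jackknife trials and omitted fraction per step.
#' @param aggregate `"rms"` or `"median"` over (peak, plane) cells.
#' @param seed Integer seed.
#' @return A `ta_report` tibble: one row per (realization, step) with
#'   `fraction`, `n_points`, `step_error`, `jk_error`, `stop`. Summarise with
#'   [ta_summary()].
#' @export
ta_run <- function(td, steps = NULL, n_realizations = 15, reconstructor,
                   peaks, target_sigma = NULL, jk_trials = 20,
                   jk_frac = 0.175, aggregate = c("rms", "median"), seed = 1) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "rms") function(x) sqrt(mean(x^2)) else stats::median
  schedule <- td$schedule
  if (is.null(schedule)) stop("targeted acquisition needs a NUS schedule")
  P <- n_planes(td$spec)
  n_cells <- prod(td$grid$np[-1]) * P
  avail <- nrow(schedule) / n_cells
  if (is.null(steps)) steps <- seq(0.033, avail, by = 0.01)
  # allow rounding slack of one grid cell on the last step
  stopifnot(all(diff(steps) > 0), max(steps) <= avail + 1 / n_cells)
  counts <- pmin(round(steps * n_cells), nrow(schedule))
  if (counts[1] < P) stop("first step leaves an empty CPMG plane")

  run_real <- function(r) {
    perm <- NULL
    for (t in 1:50) {
      cand <- sample.int(nrow(schedule))
      if (length(unique(schedule$plane[cand[seq_len(counts[1])]])) == P) {
        perm <- cand
        break
      }
    }
    if (is.null(perm)) stop("first TA step cannot cover every plane")
    prev <- NULL
    rows <- vector("list", length(steps))
    for (s in seq_along(steps)) {
      sub <- as_schedule(schedule[sort(perm[seq_len(counts[s])]), ], schedule)
      sub_td <- apply_schedule(td, sub)
      intens <- extract_intensities(reconstructor(sub_td), peaks)
      jk <- jackknife_errors(
        sub_td,
        jackknife_plan(nrow(sub),
                       d = max(ceiling(sqrt(nrow(sub))),
                               round(jk_frac * nrow(sub))),
                       n_trials = jk_trials, seed = r * 1000L + s),
        reconstructor, peaks
      )
      raw_step <- if (is.null(prev)) NA_real_ else {
        agg(abs(intens$intensity - prev$intensity))
      }
      infl_s <- if (s == 1) NA_real_ else {
        sqrt(counts[s] / (counts[s] - counts[s - 1]))
      }
      jk_err <- agg(jk$sigma_i)
      rows[[s]] <- tibble::tibble(
        realization = r, step = s, fraction = counts[s] / n_cells,
        n_points = counts[s], step_error = raw_step * infl_s,
        raw_step_error = raw_step, jk_error = jk_err,
        stop = if (is.null(target_sigma)) FALSE else jk_err <= target_sigma
      )
      prev <- intens
    }
    dplyr::bind_rows(rows)
  }

  out <- with_seed(seed, dplyr::bind_rows(lapply(seq_len(n_realizations), run_real)))
  class(out) <- c("ta_report", class(out))
  out
}

#' Summarise a targeted-acquisition report over realizations
#'
#' @param report A [ta_run()] result.
#' @return Tibble: `step`, `fraction`, `rms_step_error`, `rms_jackknife_error`,
#'   `stop_flag` (all realizations stopped).
#' @export
ta_summary <- function(report) {
  report |>
    dplyr::group_by(.data$step, .data$fraction) |>
    dplyr::summarise(
      rms_step_error = if (all(is.na(.data$step_error))) NA_real_
                       else stats::median(.data$step_error, na.rm = TRUE),
      rms_jackknife_error = stats::median(.data$jk_error),
      stop_flag = all(.data$stop), .groups = "drop"
    )
}
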