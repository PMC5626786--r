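# --- peak quantification -----------------------------------------------------

#' Peak list for a synthetic system
#'
#' Expected peak positions (ppm per dimension) with a search window in grid
#' points, ready for [extract_intensities()].
#'
#' @param system An `exchange_system`.
#' @param grid The acquisition [grid_spec()].
#' @param window Half-width of the search window, in points of the processed
#'   spectrum, per dimension.
#' @return A tibble with one row per peak: `peak`, one `pos_<label>` column
#'   per dimension (ppm), and `window`.
#' @export
peak_list <- function(system, grid, window = 3) {
  stopifnot(window >= 0)
  cols <- lapply(grid$labels, function(lab) {
    system$sites[[switch(lab, h = "pos_h", n = "pos_n", co = "pos_co")]]
  })
  names(cols) <- paste0("pos_", grid$labels)
  out <- tibble::tibble(peak = system$sites$residue_id, !!!cols,
                        window = window)
  out
}

# nearest grid index of a ppm position on an ascending Hz axis
axis_index <- function(axis_hz, pos_ppm, nucleus, field) {
  vapply(pos_ppm, function(p) {
    which.min(abs(axis_hz - ppm_to_hz(p, nucleus, field)))
  }, integer(1))
}

#' Extract per-plane peak intensities from a spectrum series
#'
#' For each peak the maximum grid point within the search window is located
#' on the reference plane; the same grid point is then read on every plane
#' (peak positions and line shapes are invariant to the CPMG frequency, so a
#' shared readout point preserves intensity ratios).
#'
#' @param spectra A `spectrum_series`.
#' @param peaks A [peak_list()] tibble.
#' @param field Static field used for the ppm-to-Hz mapping.
#' @return An intensity series tibble: `peak`, `plane`, `nu` (`NA` for the
#'   reference plane), `is_ref`, `intensity`, `sigma_i` (`NA` until an error
#'   estimate is attached). Carries the series metadata as attributes.
#' @export
extract_intensities <- function(spectra, peaks,
                                field = spectra$spec$field) {
  grid <- spectra$grid
  K <- length(grid$np)
  d <- dim(spectra$values)
  P <- d[K + 1L]
  nus <- plane_nu(spectra$spec)

  res <- vector("list", nrow(peaks))
  for (j in seq_len(nrow(peaks))) {
    ctr <- integer(K)
    for (k in seq_len(K)) {
      ctr[k] <- axis_index(spectra$axes[[k]],
                           peaks[[paste0("pos_", grid$labels[k])]][j],
                           dim_nucleus(grid$labels[k]), field)
    }
    w <- peaks$window[j]
    rng <- lapply(seq_len(K), function(k) {
      lo <- max(1L, ctr[k] - w); hi <- min(d[k], ctr[k] + w)
      lo:hi
    })
    if (any(lengths(rng) == 0)) stop("empty search window for peak ", peaks$peak[j])
    ref <- do.call(`[`, c(list(spectra$values), rng, list(1L), list(drop = FALSE)))
    best <- which.max(ref)
    bidx <- arrayInd(best, lengths(rng))
    pos <- mapply(function(r, b) r[b], rng, as.integer(bidx))
    if (any(bidx == 1L & lengths(rng) > 1L) ||
        any(as.integer(bidx) == lengths(rng) & lengths(rng) > 1L)) {
      warning("maximum on the search-window boundary for peak ",
              peaks$peak[j])
    }
    vals <- vapply(seq_len(P), function(p) {
      do.call(`[`, c(list(spectra$values), as.list(pos), list(p)))
    }, numeric(1))
    res[[j]] <- tibble::tibble(
      peak = peaks$peak[j], plane = seq_len(P), nu = nus,
      is_ref = seq_len(P) == 1L, intensity = vals, sigma_i = NA_real_
    )
  }
  out <- dplyr::bind_rows(res)
  attr(out, "t_relax") <- spectra$spec$t_relax
  attr(out, "field") <- field
  attr(out, "nucleus") <- spectra$spec$nucleus
  attr(out, "provenance") <- spectra$provenance
  class(out) <- c("intensity_series", class(out))
  out
}

#' Attach a spectral noise-floor error to an intensity series
#'
#' Fills `sigma_i` with the plane-independent noise floor estimated by
#' [estimate_noise_floor()]; per-peak, per-plane errors from resampling can
#' replace it via [jackknife_errors()].
#'
#' @param intens An intensity series.
#' @param spectra The `spectrum_series` it was extracted from.
#' @return The intensity series with `sigma_i` filled.
#' @export
with_noise_floor_errors <- function(intens, spectra) {
  intens$sigma_i <- estimate_noise_floor(spectra)
  intens
}

#' Convert an intensity series to effective relaxation rates
#'
#' `R2eff(nu) = log(I0 / I(nu)) / t_relax`, with `I0` the reference-plane
#' intensity. Errors propagate as
#' `sigma_R2 = sqrt((sigma_I/I)^2 + (sigma_I0/I0)^2) / t_relax`. Non-positive
#' intensities cannot be log-converted: such points are flagged (`ok =
#' FALSE`, `r2eff = NA`) and reported via a warning rather than silently
#' dropped. Repeated CPMG frequencies are kept as separate rows; use
#' [duplicate_global_error()] to turn them into a global error estimate.
#'
#' @param intens An intensity series (from [extract_intensities()]).
#' @param t_relax Constant relaxation delay (s); defaults to the value the
#'   series was recorded with.
#' @return A dispersion tibble: `peak`, `nu`, `r2eff`, `sigma`, `ok`.
#' @export
compute_r2eff <- function(intens, t_relax = attr(intens, "t_relax")) {
  stopifnot(!is.null(t_relax), t_relax > 0)
  refs <- intens[intens$is_ref, c("peak", "intensity", "sigma_i")]
  names(refs) <- c("peak", "i0", "sigma_i0")
  if (any(refs$i0 <= 0)) {
    warning("non-positive reference intensity for peak(s) ",
            paste(refs$peak[refs$i0 <= 0], collapse = ", "))
  }
  pl <- dplyr::left_join(intens[!intens$is_ref, ], refs, by = "peak")
  ok <- pl$intensity > 0 & pl$i0 > 0
  if (any(!ok)) {
    warning(sum(!ok), " dispersion point(s) with non-positive intensity ",
            "flagged and excluded")
  }
  out <- tibble::tibble(
    peak = pl$peak, nu = pl$nu,
    r2eff = ifelse(ok, log(pl$i0 / pl$intensity) / t_relax, NA_real_),
    sigma = ifelse(ok & !is.na(pl$sigma_i),
                   sqrt((pl$sigma_i / pl$intensity)^2 +
                          (pl$sigma_i0 / pl$i0)^2) / t_relax, NA_real_),
    ok = ok
  )
  attr(out, "t_relax") <- t_relax
  attr(out, "field") <- attr(intens, "field")
  attr(out, "nucleus") <- attr(intens, "nucleus")
  class(out) <- c("dispersion", class(out))
  out
}

#' Average duplicate CPMG frequencies of a dispersion table
#'
#' Repeated `nu` measurements are averaged; the number of repeats is kept in
#' `n_rep` so [with_duplicate_errors()] can scale the global error per point.
#'
#' @param curves A dispersion tibble.
#' @return A dispersion tibble with one row per (peak, nu) and an `n_rep`
#'   column.
#' @export
average_duplicates <- function(curves) {
  out <- curves |>
    dplyr::filter(.data$ok) |>
    dplyr::group_by(.data$peak, .data$nu) |>
    dplyr::summarise(
      r2eff = mean(.data$r2eff),
      sigma = if (all(is.na(.data$sigma))) NA_real_
              else sqrt(sum(.data$sigma^2, na.rm = TRUE)) / dplyr::n(),
      n_rep = dplyr::n(),
      ok = TRUE, .groups = "drop"
    )
  for (a in c("t_relax", "field", "nucleus")) attr(out, a) <- attr(curves, a)
  class(out) <- c("dispersion", class(out))
  out
}

#' Attach the duplicate-based global error to averaged curves
#'
#' [duplicate_global_error()] estimates the error of a duplicate-averaged
#' point (the RMS half-difference). A point averaged over `n_rep` repeats
#' therefore gets `sigma = sigma_r2 * sqrt(2 / n_rep)`: `sigma_r2` itself for
#' pairs, `sqrt(2)` larger for frequencies measured once.
#'
#' @param curves Averaged curves from [average_duplicates()].
#' @param dup Output of [duplicate_global_error()] (or a bare sigma).
#' @return The curves with `sigma` set per point.
#' @export
with_duplicate_errors <- function(curves, dup) {
  s <- if (is.numeric(dup)) dup else dup$sigma_r2
  n_rep <- curves$n_rep %||% rep(1L, nrow(curves))
  curves$sigma <- s * sqrt(2 / n_rep)
  curves
}
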