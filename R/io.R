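# --- file formats ------------------------------------------------------------
#
# Time-domain series and spectra are exchanged as a flat little-endian binary
# of doubles plus a plain-text header describing dims and calibrations;
# tabular results are TSV/CSV.

#' Write / read a time-domain series
#'
#' Flat binary (interleaved real/imaginary doubles, direct index fastest)
#' with a text header (`.hdr`) carrying grid, CPMG and noise metadata.
#' Missing (unsampled) cells are stored as NaN; the schedule itself travels
#' separately as a nuslist.
#'
#' @param td A `td_series`.
#' @param prefix Path prefix; writes `<prefix>.hdr` and `<prefix>.dat`.
#' @return `prefix`, invisibly.
#' @export
write_td <- function(td, prefix) {
  hdr <- c(
    sprintf("np %s", paste(td$grid$np, collapse = " ")),
    sprintf("sw %s", paste(td$grid$sw, collapse = " ")),
    sprintf("labels %s", paste(td$grid$labels, collapse = " ")),
    sprintf("nu %s", paste(td$spec$nu, collapse = " ")),
    sprintf("t_relax %.10g", td$spec$t_relax),
    sprintf("field %.10g", td$spec$field),
    sprintf("nucleus %s", td$spec$nucleus),
    sprintf("noise_sigma %.10g", td$noise_sigma)
  )
  writeLines(hdr, paste0(prefix, ".hdr"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  v <- as.vector(td$values)
  buf <- numeric(2 * length(v))
  buf[c(TRUE, FALSE)] <- Re(v)
  buf[c(FALSE, TRUE)] <- Im(v)
  writeBin(buf, con, size = 8, endian = "little")
  invisible(prefix)
}

#' @rdname write_td
#' @param prefix Path prefix written by [write_td()].
#' @export
read_td <- function(prefix) {
  hdr <- readLines(paste0(prefix, ".hdr"))
  get <- function(key) {
    line <- hdr[startsWith(hdr, paste0(key, " "))]
    if (length(line) != 1) stop("missing header field: ", key)
    strsplit(sub(paste0("^", key, " "), "", line), " ")[[1]]
  }
  grid <- grid_spec(np = as.integer(get("np")), sw = as.numeric(get("sw")),
                    labels = get("labels"))
  spec <- cpmg_spec(nu = as.numeric(get("nu")),
                    t_relax = as.numeric(get("t_relax")),
                    field = as.numeric(get("field")),
                    nucleus = get("nucleus"))
  dims <- td_dims(grid, spec)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  buf <- readBin(con, numeric(), n = 2 * prod(dims), size = 8,
                 endian = "little")
  v <- complex(real = buf[c(TRUE, FALSE)], imaginary = buf[c(FALSE, TRUE)])
  values <- array(v, dim = dims)
  mask <- array(TRUE, dim = c(grid$np[-1], n_planes(spec)))
  structure(
    list(values = values, grid = grid, spec = spec, mask = mask,
         noise_sigma = as.numeric(get("noise_sigma")), schedule = NULL),
    class = "td_series"
  )
}

#' Write / read a spectrum series
#'
#' One flat binary of doubles per series plus a text header with the grid
#' dimensions, axis calibrations and provenance.
#'
#' @param spectra A `spectrum_series`.
#' @param prefix Path prefix; writes `<prefix>.hdr` and `<prefix>.dat`.
#' @return `prefix`, invisibly.
#' @export
write_spectrum <- function(spectra, prefix) {
  d <- dim(spectra$values)
  hdr <- c(
    sprintf("dims %s", paste(d, collapse = " ")),
    sprintf("np %s", paste(spectra$grid$np, collapse = " ")),
    sprintf("sw %s", paste(spectra$grid$sw, collapse = " ")),
    sprintf("labels %s", paste(spectra$grid$labels, collapse = " ")),
    sprintf("nu %s", paste(spectra$spec$nu, collapse = " ")),
    sprintf("t_relax %.10g", spectra$spec$t_relax),
    sprintf("field %.10g", spectra$spec$field),
    sprintf("nucleus %s", spectra$spec$nucleus),
    sprintf("apod %d", as.integer(isTRUE(spectra$proc$apod))),
    sprintf("zf %d", spectra$proc$zf),
    sprintf("provenance %s", spectra$provenance)
  )
  writeLines(hdr, paste0(prefix, ".hdr"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(spectra$values), con, size = 8, endian = "little")
  invisible(prefix)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(prefix) {
  hdr <- readLines(paste0(prefix, ".hdr"))
  get <- function(key) {
    line <- hdr[startsWith(hdr, paste0(key, " "))]
    if (length(line) != 1) stop("missing header field: ", key)
    strsplit(sub(paste0("^", key, " "), "", line), " ")[[1]]
  }
  d <- as.integer(get("dims"))
  grid <- grid_spec(np = as.integer(get("np")), sw = as.numeric(get("sw")),
                    labels = get("labels"))
  spec <- cpmg_spec(nu = as.numeric(get("nu")),
                    t_relax = as.numeric(get("t_relax")),
                    field = as.numeric(get("field")),
                    nucleus = get("nucleus"))
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = prod(d), size = 8, endian = "little")
  K <- length(grid$np)
  axes <- lapply(seq_len(K), function(k) freq_axis(d[k], grid$sw[k]))
  names(axes) <- grid$labels
  structure(
    list(values = array(vals, dim = d), axes = axes, grid = grid,
         spec = spec,
         proc = list(apod = as.integer(get("apod")) == 1L,
                     zf = as.integer(get("zf"))),
         provenance = get("provenance")),
    class = "spectrum_series"
  )
}

#' Write / read peak lists as tab-separated text
#'
#' @param peaks A [peak_list()] tibble.
#' @param path File path.
#' @return `read_peak_list` returns the tibble; `write_peak_list` returns
#'   `path` invisibly.
#' @export
write_peak_list <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Write / read intensity tables (seriesTab-style layout)
#'
#' One row per peak, one column per plane: `ref` for the reference plane and
#' `nu_<rate>` for the CPMG planes (duplicate rates gain a `.k` suffix).
#'
#' @param intens An intensity series.
#' @param path File path.
#' @return `read_intensity_table` rebuilds an intensity series (metadata from
#'   the `t_relax`, `field`, `nucleus` arguments); `write_intensity_table`
#'   returns `path` invisibly.
#' @export
write_intensity_table <- function(intens, path) {
  lab <- ifelse(intens$is_ref, "ref", paste0("nu_", intens$nu))
  lab <- stats::ave(lab, intens$peak, lab, FUN = function(x) {
    if (length(x) > 1) paste0(x, ".", seq_along(x)) else x
  })
  wide <- tidyr::pivot_wider(
    tibble::tibble(peak = intens$peak, plane = lab,
                   intensity = intens$intensity),
    names_from = "plane", values_from = "intensity"
  )
  utils::write.table(wide, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intensity_table
#' @param t_relax,field,nucleus Metadata to attach on reading.
#' @export
read_intensity_table <- function(path, t_relax = 0.04, field = 18.8,
                                 nucleus = "15N") {
  wide <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
  long <- tidyr::pivot_longer(tibble::as_tibble(wide), -"peak",
                              names_to = "label", values_to = "intensity")
  base <- sub("\\.[0-9]+$", "", long$label)
  out <- tibble::tibble(
    peak = long$peak,
    nu = ifelse(base == "ref", NA_real_, as.numeric(sub("^nu_", "", base))),
    is_ref = base == "ref",
    intensity = long$intensity,
    sigma_i = NA_real_
  )
  out <- out |>
    dplyr::group_by(.data$peak) |>
    dplyr::mutate(plane = dplyr::row_number()) |>
    dplyr::ungroup()
  out <- out[, c("peak", "plane", "nu", "is_ref", "intensity", "sigma_i")]
  attr(out, "t_relax") <- t_relax
  attr(out, "field") <- field
  attr(out, "nucleus") <- nucleus
  class(out) <- c("intensity_series", class(out))
  out
}

#' Write / read dispersion curves as CSV
#'
#' Columns `peak`, `nu`, `r2eff`, `err` (plus the exclusion flag).
#'
#' @param curves A dispersion tibble.
#' @param path File path.
#' @param t_relax,field,nucleus Metadata attached on reading.
#' @return `read_dispersion_csv` returns a dispersion tibble;
#'   `write_dispersion_csv` returns `path` invisibly.
#' @export
write_dispersion_csv <- function(curves, path) {
  utils::write.csv(
    data.frame(peak = curves$peak, nu = curves$nu, r2eff = curves$r2eff,
               err = curves$sigma, ok = curves$ok),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_dispersion_csv
#' @export
read_dispersion_csv <- function(path, t_relax = 0.04, field = 18.8,
                                nucleus = "15N") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- tibble::tibble(peak = df$peak, nu = df$nu, r2eff = df$r2eff,
                        sigma = df$err, ok = as.logical(df$ok))
  attr(out, "t_relax") <- t_relax
  attr(out, "field") <- field
  attr(out, "nucleus") <- nucleus
  class(out) <- c("dispersion", class(out))
  out
}

#' Write a targeted-acquisition report as CSV
#'
#' @param report A `ta_report`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_ta_report <- function(report, path) {
  s <- ta_summary(report)
  utils::write.csv(
    data.frame(step = s$step, fraction = s$fraction,
               rms_step_error = s$rms_step_error,
               rms_jackknife_error = s$rms_jackknife_error,
               stop_flag = s$stop_flag),
    path, row.names = FALSE
  )
  invisible(path)
}
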