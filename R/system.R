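#' CPMG series specification
#'
#' Describes the pseudo (relaxation) dimension of a dispersion series: the
#' CPMG repetition rates, the constant relaxation delay and the probed
#' nucleus/field. The series always carries a reference plane (the experiment
#' recorded without the relaxation delay) as plane 1, followed by one plane
#' per entry of `nu`.
#'
#' @param nu CPMG repetition rates in Hz. Repeats are allowed and are treated
#'   as duplicate measurements.
#' @param t_relax Constant relaxation delay in seconds.
#' @param field Static field, tesla.
#' @param nucleus Probed nucleus, `"15N"` or `"13CO"`.
#' @return A `cpmg_spec` object.
#' @export
cpmg_spec <- function(nu = default_nu_grid(), t_relax = 0.04, field = 18.8,
                      nucleus = c("15N", "13CO")) {
  nucleus <- match.arg(nucleus)
  stopifnot(all(nu > 0), t_relax > 0, field > 0)
  structure(
    list(nu = as.numeric(nu), t_relax = t_relax, field = field,
         nucleus = nucleus),
    class = "cpmg_spec"
  )
}

#' Default CPMG frequency grid
#'
#' Eleven roughly log-spaced repetition rates between 25 and 1000 Hz, chosen
#' so that every rate corresponds to an even number of 180-degree pulses in
#' the default 40 ms relaxation delay.
#'
#' @return Numeric vector of CPMG frequencies (Hz).
#' @export
default_nu_grid <- function() {
  c(25, 50, 75, 100, 150, 200, 300, 400, 600, 800, 1000)
}

n_planes <- function(spec) length(spec$nu) + 1L
# nu per plane; NA marks the reference plane
plane_nu <- function(spec) c(NA_real_, spec$nu)

#' Acquisition grid specification
#'
#' @param np Points per dimension (direct first), e.g. `c(h = 64, n = 48)`.
#'   Indirect entries count complex (hypercomplex) increments.
#' @param sw Spectral width per dimension, Hz, same order and length as `np`.
#' @param labels Dimension labels; the first is the direct (1H) dimension,
#'   the remaining ones indirect (`"n"`, `"co"`).
#' @return A `grid_spec` object; acquisition times are `np/sw`.
#' @export
grid_spec <- function(np = c(64, 48), sw = c(2400, 2500),
                      labels = c("h", "n")) {
  stopifnot(length(np) == length(sw), length(np) == length(labels),
            all(np >= 4), all(sw > 0), length(np) %in% c(2L, 3L))
  structure(
    list(np = as.integer(np), sw = as.numeric(sw), labels = labels,
         at = as.integer(np) / as.numeric(sw)),
    class = "grid_spec"
  )
}

#' Default grids for the supported experiment geometries
#'
#' Two-dimensional grids pair the amide proton with the probed nucleus;
#' the three-dimensional grid is HNCO-like (1H, 15N, 13CO).
#'
#' @param nucleus Probed nucleus for the 2D geometry.
#' @return A [grid_spec()].
#' @export
default_grid_2d <- function(nucleus = c("15N", "13CO")) {
  nucleus <- match.arg(nucleus)
  if (nucleus == "15N") {
    grid_spec(np = c(64, 48), sw = c(2400, 2500), labels = c("h", "n"))
  } else {
    grid_spec(np = c(64, 48), sw = c(2400, 1400), labels = c("h", "co"))
  }
}

#' @rdname default_grid_2d
#' @export
default_grid_3d <- function() {
  grid_spec(np = c(32, 16, 16), sw = c(2400, 2250, 1400),
            labels = c("h", "n", "co"))
}

# nucleus associated with a dimension label
dim_nucleus <- function(label) {
  switch(label, h = "1H", n = "15N", co = "13CO",
         stop("unknown dimension label: ", label))
}

# ppm window (relative to the carrier) covered by a grid dimension
grid_window_ppm <- function(grid, k, field = 18.8) {
  nuc <- dim_nucleus(grid$labels[k])
  half <- grid$sw[k] / 2 / larmor_mhz(nuc, field)
  c(-half, half)
}

#' Generate a synthetic exchanging spin system
#'
#' Creates per-residue ground truth for a dispersion simulation. The
#' `sh3_like` template emulates a small folded domain partially bound to a
#' peptide ligand: all sites share global two-state parameters (`kex`, `p_b`)
#' and draw their shift differences uniformly from `dw_range`. The `idp_flat`
#' template emulates a disordered chain without millisecond exchange: every
#' dispersion is flat at `r2_0`.
#'
#' @param template `"sh3_like"` or `"idp_flat"`.
#' @param n_sites Number of residues to generate.
#' @param seed Integer seed; identical seeds give identical systems.
#' @param nucleus Probed nucleus; switches the default global parameters.
#' @param kex,p_b Global exchange parameters. Defaults: 182 s^-1 / 0.029 for
#'   15N, 173 s^-1 / 0.036 for 13CO.
#' @param dw_range Range (ppm) for the uniform draw of per-site `|dw|`.
#' @param grid Grid used to place peaks inside the spectral windows; peaks are
#'   drawn with a minimum mutual separation so they stay resolvable.
#' @param field Static field, tesla.
#' @param r2_0_range Range for per-site intrinsic rates, s^-1.
#' @param amp_range Range for per-site amplitudes (arbitrary units).
#' @return An `exchange_system`: a list with a `sites` tibble (residue_id,
#'   positions in ppm, linewidths in Hz, r2_0, delta_omega, amplitude) and
#'   global fields `kex`, `p_b`, `flat`, `nucleus`, `field`.
#' @export
make_system <- function(template = c("sh3_like", "idp_flat"), n_sites, seed,
                        nucleus = c("15N", "13CO"),
                        kex = NULL, p_b = NULL, dw_range = NULL,
                        grid = NULL, field = 18.8,
                        r2_0_range = c(6, 14), amp_range = c(0.6, 1)) {
  template <- match.arg(template)
  nucleus <- match.arg(nucleus)
  stopifnot(n_sites >= 1)
  if (is.null(kex)) kex <- if (nucleus == "15N") 182 else 173
  if (is.null(p_b)) p_b <- if (nucleus == "15N") 0.029 else 0.036
  if (is.null(dw_range)) {
    dw_range <- if (nucleus == "15N") c(0.2, 3) else c(0.1, 1.2)
  }
  if (is.null(grid)) grid <- default_grid_2d(nucleus)

  flat <- template == "idp_flat"
  if (!flat) stopifnot(kex > 0, p_b > 0, p_b < 0.5)

  with_seed(seed, {
    pos <- draw_positions(n_sites, grid, field)
    sites <- tibble::tibble(
      residue_id = sprintf("R%02d", seq_len(n_sites)),
      pos_h = pos$h, pos_n = pos$n, pos_co = pos$co,
      lw_h = stats::runif(n_sites, 18, 28),
      lw_n = stats::runif(n_sites, 4, 9),
      lw_co = stats::runif(n_sites, 3, 7),
      r2_0 = stats::runif(n_sites, r2_0_range[1], r2_0_range[2]),
      delta_omega = if (flat) rep(0, n_sites)
                    else stats::runif(n_sites, dw_range[1], dw_range[2]),
      amplitude = stats::runif(n_sites, amp_range[1], amp_range[2])
    )
  })

  structure(
    list(sites = sites, kex = if (flat) 0 else kex,
         p_b = if (flat) 0 else p_b, flat = flat,
         nucleus = nucleus, field = field),
    class = "exchange_system"
  )
}

# rejection-sample peak positions (ppm) with a minimum grid-point separation:
# two peaks must be >= 4 points apart in some indirect dimension or >= 6
# points apart in the direct dimension
draw_positions <- function(n_sites, grid, field) {
  K <- length(grid$np)
  margin <- 0.12
  draw_dim <- function(k, n) {
    w <- grid_window_ppm(grid, k, field)
    span <- diff(w)
    stats::runif(n, w[1] + margin * span, w[2] - margin * span)
  }
  pts_per_ppm <- function(k) {
    larmor_mhz(dim_nucleus(grid$labels[k]), field) * grid$np[k] / grid$sw[k]
  }
  for (try in 1:5000) {
    pos <- lapply(seq_len(K), function(k) draw_dim(k, n_sites))
    ok <- TRUE
    if (n_sites > 1) {
      dmat <- lapply(seq_len(K), function(k) {
        abs(outer(pos[[k]], pos[[k]], "-")) * pts_per_ppm(k)
      })
      sep_dir <- dmat[[1]] >= 6
      sep_ind <- Reduce(`|`, lapply(dmat[-1], function(d) d >= 3))
      sep <- sep_dir | sep_ind
      diag(sep) <- TRUE
      ok <- all(sep)
    }
    if (ok) {
      names(pos) <- grid$labels
      return(list(h = pos$h,
                  n = pos$n %||% rep(NA_real_, n_sites),
                  co = pos$co %||% rep(NA_real_, n_sites)))
    }
  }
  stop("could not place ", n_sites, " peaks with the required separation; ",
       "use a larger grid or fewer sites")
}

#' Ground-truth effective relaxation rate of a site
#'
#' Forward model used by the simulator: flat systems (and sites with zero
#' shift difference) relax at `r2_0` for every CPMG frequency; exchanging
#' sites follow the numerical Bloch-McConnell propagation.
#'
#' @param system An [make_system()] result.
#' @param site A single row of `system$sites` (or its index).
#' @param nu CPMG frequency (Hz), vectorized.
#' @param spec A [cpmg_spec()].
#' @return Effective rate(s), s^-1.
#' @export
r2eff_true <- function(system, site, nu, spec) {
  if (is.numeric(site)) site <- system$sites[site, ]
  if (system$flat || site$delta_omega == 0) return(rep(site$r2_0, length(nu)))
  bm_r2eff(nu, site$r2_0, site$delta_omega, system$kex, system$p_b,
           spec$t_relax, field = system$field, nucleus = system$nucleus)
}

#' @export
print.exchange_system <- function(x, ...) {
  cat("<exchange_system> ", nrow(x$sites), " sites, nucleus ", x$nucleus,
      ", field ", x$field, " T\n", sep = "")
  if (x$flat) cat("  flat (no millisecond exchange)\n")
  else cat("  kex = ", x$kex, " s^-1, p_b = ", x$p_b, "\n", sep = "")
  print(x$sites, n = 5)
  invisible(x)
}

#' Write / read an exchange system as structured text
#'
#' One site per row (id, positions, linewidths, r2_0, delta_omega, amplitude)
#' preceded by header lines carrying the global parameters.
#'
#' @param system An `exchange_system`.
#' @param path File path.
#' @return `write_system` returns `path` invisibly; `read_system` returns the
#'   reconstructed `exchange_system`.
#' @export
write_system <- function(system, path) {
  hdr <- c(
    sprintf("# kex %.10g", system$kex),
    sprintf("# p_b %.10g", system$p_b),
    sprintf("# flat %d", as.integer(system$flat)),
    sprintf("# nucleus %s", system$nucleus),
    sprintf("# field %.10g", system$field)
  )
  tab <- utils::capture.output(
    utils::write.table(system$sites, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  )
  writeLines(c(hdr, tab), path)
  invisible(path)
}

#' @rdname write_system
#' @export
read_system <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), " "))
  val <- stats::setNames(kv[, 2], kv[, 1])
  sites <- utils::read.table(path, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  sites[-1] <- lapply(sites[-1], as.numeric)
  structure(
    list(sites = tibble::as_tibble(sites),
         kex = as.numeric(val[["kex"]]), p_b = as.numeric(val[["p_b"]]),
         flat = as.integer(val[["flat"]]) == 1L,
         nucleus = val[["nucleus"]], field = as.numeric(val[["field"]])),
    class = "exchange_system"
  )
}
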