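# --- time-domain synthesis and NUS sampling ---------------------------------
#
# Hypercomplex (States) layout: the direct dimension is stored complex; every
# indirect dimension contributes an axis of length 2*np whose odd/even slices
# hold the cosine/sine-modulated components of that evolution period. The
# final axis enumerates CPMG planes (plane 1 = reference).

td_dims <- function(grid, spec) {
  c(grid$np[1], 2L * grid$np[-1], n_planes(spec))
}

#' Synthesize a fully sampled multidimensional CPMG time-domain series
#'
#' Each site contributes a separable product of exponentially damped complex
#' sinusoids (one factor per dimension, States quadrature for the indirect
#' dimensions). The plane recorded at CPMG frequency `nu` is scaled by
#' `exp(-R2eff(nu) * t_relax)` relative to the reference plane, with `R2eff`
#' from [r2eff_true()]. Complex Gaussian noise of scale `noise_sigma` is added
#' independently to every stored point.
#'
#' @param system An [make_system()] result.
#' @param grid A [grid_spec()]; dimension labels must be resolvable for the
#'   system's sites.
#' @param spec A [cpmg_spec()].
#' @param noise_sigma Standard deviation of the real and imaginary noise per
#'   time-domain point, in the site amplitude units.
#' @param seed Integer seed for the noise.
#' @return A `td_series`: values (complex array), grid, spec, mask (complete),
#'   noise_sigma.
#' @export
synthesize_fid <- function(system, grid, spec, noise_sigma = 0, seed = 1) {
  K <- length(grid$np) - 1L
  dims <- td_dims(grid, spec)
  P <- n_planes(spec)
  values <- array(0 + 0i, dim = dims)
  nus <- plane_nu(spec)

  pos_col <- function(lab) switch(lab, h = "pos_h", n = "pos_n", co = "pos_co")
  lw_col <- function(lab) switch(lab, h = "lw_h", n = "lw_n", co = "lw_co")

  for (s in seq_len(nrow(system$sites))) {
    site <- system$sites[s, ]
    # direct dimension: complex damped sinusoid
    t_d <- (0:(grid$np[1] - 1)) / grid$sw[1]
    f_d <- ppm_to_hz(site[[pos_col(grid$labels[1])]], dim_nucleus(grid$labels[1]),
                     system$field)
    d <- exp(2i * pi * f_d * t_d - pi * site[[lw_col(grid$labels[1])]] * t_d)
    # indirect dimensions: interleaved cos/sin components
    ind <- lapply(seq_len(K), function(k) {
      kk <- k + 1L
      tt <- (0:(grid$np[kk] - 1)) / grid$sw[kk]
      f <- ppm_to_hz(site[[pos_col(grid$labels[kk])]],
                     dim_nucleus(grid$labels[kk]), system$field)
      dec <- exp(-pi * site[[lw_col(grid$labels[kk])]] * tt)
      v <- numeric(2L * grid$np[kk])
      v[seq(1, by = 2, length.out = grid$np[kk])] <- cos(2 * pi * f * tt) * dec
      v[seq(2, by = 2, length.out = grid$np[kk])] <- sin(2 * pi * f * tt) * dec
      v
    })
    r2 <- r2eff_true(system, site, spec$nu, spec)
    scale <- site$amplitude * c(1, exp(-r2 * spec$t_relax))
    shape <- d
    for (k in seq_len(K)) shape <- outer(shape, ind[[k]])
    for (p in seq_len(P)) {
      if (K == 1L) values[, , p] <- values[, , p] + scale[p] * shape
      else values[, , , p] <- values[, , , p] + scale[p] * shape
    }
  }

  if (noise_sigma > 0) {
    values <- values + with_seed(seed, {
      n <- length(values)
      complex(real = stats::rnorm(n, 0, noise_sigma),
              imaginary = stats::rnorm(n, 0, noise_sigma))
    })
  }

  structure(
    list(values = values, grid = grid, spec = spec,
         mask = array(TRUE, dim = c(grid$np[-1], P)),
         noise_sigma = noise_sigma, schedule = NULL),
    class = "td_series"
  )
}

mask_complete <- function(td) all(td$mask)

# --- sampling schedules ------------------------------------------------------

#' Generate a NUS sampling schedule
#'
#' Samples (indirect coordinate, plane) cells without replacement. The
#' density over indirect coordinates is proportional to
#' `exp(-t / t_match)` with `t` the summed evolution time of the coordinate
#' (exponential weighting matched to `t_match`); the distribution across
#' CPMG planes is flat. In `coupled` mode the same indirect coordinates are
#' used for every plane.
#'
#' @param grid A [grid_spec()].
#' @param n_planes Number of planes (reference included).
#' @param nus_fraction Fraction of the full (indirect x plane) space to keep,
#'   in (0, 1].
#' @param t_match Time constant (s) of the exponential weighting; `Inf` gives
#'   a flat distribution. Default 0.1 s (matched to a 100 ms acquisition).
#' @param seed Integer seed.
#' @param coupled Couple the indirect draws across planes.
#' @param ensure_coverage Repair the draw so every indirect coordinate is
#'   sampled in at least one plane (cells are moved from the most-covered
#'   coordinates). Shared-shape decomposition leaves never-sampled
#'   coordinates unconstrained, so full coverage makes the co-MDD model
#'   identifiable point by point; the repair slightly perturbs the target
#'   density.
#' @return A `sampling_schedule` tibble with columns `i1` (, `i2`) and
#'   `plane` (1-based), plus grid/fraction attributes.
#' @export
generate_schedule <- function(grid, n_planes, nus_fraction, t_match = 0.1,
                              seed = 1, coupled = FALSE,
                              ensure_coverage = FALSE) {
  stopifnot(nus_fraction > 0, nus_fraction <= 1, n_planes >= 1)
  np_ind <- grid$np[-1]
  sw_ind <- grid$sw[-1]
  K <- length(np_ind)
  n_coord <- prod(np_ind)
  n_cells <- n_coord * n_planes
  total <- round(nus_fraction * n_cells)
  if (total < n_planes) {
    stop("nus_fraction ", nus_fraction, " leaves fewer points (", total,
         ") than planes (", n_planes, "): some plane would be empty")
  }

  coords <- do.call(expand.grid, lapply(np_ind, seq_len))
  names(coords) <- paste0("i", seq_len(K))
  tsum <- Reduce(`+`, lapply(seq_len(K), function(k) {
    (coords[[k]] - 1) / sw_ind[k]
  }))
  w <- if (is.infinite(t_match)) rep(1, n_coord) else exp(-tsum / t_match)

  sched <- with_seed(seed, {
    if (coupled) {
      n_per_plane <- round(total / n_planes)
      if (n_per_plane < 1) stop("coupled schedule would leave planes empty")
      idx <- sample.int(n_coord, n_per_plane, prob = w)
      tibble::tibble(coord = rep(idx, n_planes),
                     plane = rep(seq_len(n_planes), each = n_per_plane))
    } else {
      for (try in 1:100) {
        cell <- sample.int(n_cells, total, prob = rep(w, n_planes))
        plane <- (cell - 1L) %/% n_coord + 1L
        idx <- (cell - 1L) %% n_coord + 1L
        if (length(unique(plane)) == n_planes) break
        if (try == 100) stop("could not draw a schedule covering every plane")
      }
      if (ensure_coverage) {
        repeat {
          cov <- tabulate(idx, n_coord)
          missing <- which(cov == 0)
          if (length(missing) == 0) break
          donor_cells <- which(idx == which.max(cov))
          mv <- donor_cells[sample.int(length(donor_cells), 1)]
          idx[mv] <- missing[1]
        }
      }
      tibble::tibble(coord = idx, plane = plane)
    }
  })

  out <- dplyr::bind_cols(coords[sched$coord, , drop = FALSE],
                          tibble::tibble(plane = sched$plane))
  out <- dplyr::arrange(out, .data$plane, dplyr::across(dplyr::starts_with("i")))
  out <- tibble::as_tibble(out)
  attr(out, "np_ind") <- np_ind
  attr(out, "n_planes") <- n_planes
  attr(out, "nus_fraction") <- nrow(out) / n_cells
  class(out) <- c("sampling_schedule", class(out))
  out
}

#' Full (exhaustive) sampling schedule
#' @inheritParams generate_schedule
#' @return A `sampling_schedule` covering every cell exactly once.
#' @export
schedule_full <- function(grid, n_planes) {
  np_ind <- grid$np[-1]
  coords <- do.call(expand.grid, lapply(np_ind, seq_len))
  names(coords) <- paste0("i", seq_along(np_ind))
  out <- dplyr::bind_cols(
    coords[rep(seq_len(nrow(coords)), n_planes), , drop = FALSE],
    tibble::tibble(plane = rep(seq_len(n_planes), each = nrow(coords)))
  )
  out <- tibble::as_tibble(out)
  attr(out, "np_ind") <- np_ind
  attr(out, "n_planes") <- n_planes
  attr(out, "nus_fraction") <- 1
  class(out) <- c("sampling_schedule", class(out))
  out
}

schedule_coord_cols <- function(schedule) {
  grep("^i[0-9]+$", names(schedule), value = TRUE)
}

# rebuild schedule attributes after a dplyr verb stripped the subclass
as_schedule <- function(df, template) {
  df <- tibble::as_tibble(df)
  attr(df, "np_ind") <- attr(template, "np_ind")
  attr(df, "n_planes") <- attr(template, "n_planes")
  n_cells <- prod(attr(template, "np_ind")) * attr(template, "n_planes")
  attr(df, "nus_fraction") <- nrow(df) / n_cells
  class(df) <- c("sampling_schedule", setdiff(class(df), "sampling_schedule"))
  df
}

#' Restrict a time-domain series to a sampling schedule
#'
#' Keeps exactly the scheduled (indirect coordinate, plane) cells — all
#' hypercomplex components of a sampled coordinate are retained — and marks
#' everything else as missing.
#'
#' @param full A complete `td_series`.
#' @param schedule A `sampling_schedule`.
#' @return A sparse `td_series` whose mask matches the schedule.
#' @export
apply_schedule <- function(full, schedule) {
  np_ind <- full$grid$np[-1]
  K <- length(np_ind)
  cc <- schedule_coord_cols(schedule)
  stopifnot(length(cc) == K)
  P <- dim(full$mask)[K + 1L]
  for (k in seq_len(K)) {
    if (any(schedule[[cc[k]]] < 1 | schedule[[cc[k]]] > np_ind[k])) {
      stop("schedule coordinate outside grid in dimension ", k)
    }
  }
  if (any(schedule$plane < 1 | schedule$plane > P)) {
    stop("schedule plane index outside series")
  }
  if (length(unique(schedule$plane)) < P) {
    stop("schedule leaves at least one CPMG plane empty")
  }

  mask <- array(FALSE, dim = c(np_ind, P))
  midx <- as.matrix(cbind(schedule[cc], schedule$plane))
  mask[midx] <- TRUE

  values <- full$values
  # expand the coordinate mask to the hypercomplex axes
  exp_mask <- mask
  for (k in seq_len(K)) {
    exp_mask <- apply_rep_axis(exp_mask, k)
  }
  full_dim <- dim(values)
  keep <- array(rep(exp_mask, each = full_dim[1]), dim = full_dim)
  values[!keep] <- NA_complex_

  out <- full
  out$values <- values
  out$mask <- mask
  out$schedule <- schedule
  out
}

# duplicate axis k of a logical array (coordinate mask -> cos/sin pairs)
apply_rep_axis <- function(a, k) {
  d <- dim(a)
  perm <- c(k, setdiff(seq_along(d), k))
  b <- aperm(a, perm)
  b2 <- array(rep(b, each = 2), dim = c(2 * d[k], d[perm][-1]))
  aperm(b2, order(perm))
}

# --- nuslist text files ------------------------------------------------------

#' Read / write sampling schedules as nuslist text files
#'
#' Whitespace-separated 0-based integer grid indices, one sampled point per
#' line; the last column is the CPMG plane index.
#'
#' @param schedule A `sampling_schedule`.
#' @param path File path.
#' @param np_ind,n_planes Grid geometry used to validate and rebuild the
#'   schedule on reading.
#' @return `read_nuslist` returns a `sampling_schedule`; `write_nuslist`
#'   returns `path` invisibly.
#' @export
write_nuslist <- function(schedule, path) {
  cc <- schedule_coord_cols(schedule)
  m <- as.matrix(cbind(schedule[cc], plane = schedule$plane)) - 1L
  utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_nuslist
#' @export
read_nuslist <- function(path, np_ind, n_planes) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  ncols <- unique(lengths(parts))
  if (length(ncols) != 1L) {
    bad <- which(lengths(parts) != lengths(parts)[1])[1]
    stop("malformed nuslist line ", bad, " in ", path)
  }
  vals <- suppressWarnings(as.integer(unlist(parts)))
  if (anyNA(vals)) {
    bad <- which(vapply(parts, function(p) anyNA(suppressWarnings(as.integer(p))),
                        logical(1)))[1]
    stop("malformed nuslist line ", bad, " in ", path, ": not an integer")
  }
  m <- matrix(vals, ncol = ncols, byrow = TRUE)
  if (any(m < 0)) {
    stop("negative index on nuslist line ", which(rowSums(m < 0) > 0)[1],
         " in ", path)
  }
  K <- ncols - 1L
  stopifnot(length(np_ind) == K)
  for (k in seq_len(K)) {
    if (any(m[, k] >= np_ind[k])) {
      stop("nuslist index out of range in dimension ", k, " (grid size ",
           np_ind[k], ")")
    }
  }
  if (any(m[, ncols] >= n_planes)) stop("nuslist plane index out of range")
  out <- tibble::as_tibble(as.data.frame(m + 1L))
  names(out) <- c(paste0("i", seq_len(K)), "plane")
  out <- dplyr::arrange(out, .data$plane,
                        dplyr::across(dplyr::starts_with("i")))
  attr(out, "np_ind") <- np_ind
  attr(out, "n_planes") <- n_planes
  attr(out, "nus_fraction") <- nrow(out) / (prod(np_ind) * n_planes)
  class(out) <- c("sampling_schedule", class(out))
  out
}
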