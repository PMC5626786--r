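# --- co-MDD: co-processed multi-dimensional decomposition --------------------

# expanded observation table: one row per (hypercomplex component, plane) cell
# of the schedule; indices 0-based for the C++ core
expand_obs <- function(schedule, K) {
  cc <- schedule_coord_cols(schedule)
  combos <- expand.grid(rep(list(0:1), K))
  m <- nrow(schedule)
  out <- matrix(0L, nrow = m * nrow(combos), ncol = K + 1L)
  r <- 1L
  for (ci in seq_len(nrow(combos))) {
    for (k in seq_len(K)) {
      out[r:(r + m - 1L), k] <- 2L * (schedule[[cc[k]]] - 1L) + combos[ci, k]
    }
    out[r:(r + m - 1L), K + 1L] <- schedule$plane - 1L
    r <- r + m
  }
  out
}

#' Fit a co-MDD decomposition model to sparse data
#'
#' Models the whole CPMG series jointly as a sum of `n_components` rank-one
#' components: per component one normalized shape vector per dimension, shared
#' by all planes, and one real amplitude per plane. The direct dimension is
#' Fourier transformed first, so shapes along it live in the frequency domain
#' while indirect shapes stay in the (hypercomplex) time domain. Fitting is
#' alternating least squares restricted to the sampled cells, each sub-step a
#' Tikhonov-regularised linear problem (penalty `lambda * ||x||^2`), sweeping
#' direct shapes, indirect shapes, then amplitudes, with shapes renormalised
#' every sweep.
#'
#' @param td A sparse (or complete) `td_series` with a schedule/mask.
#' @param n_components Number of components; defaults to expected peaks + 2
#'   spare components for noise when a `peaks` hint is given.
#' @param lambda Regularisation weight (default 1e-4). The penalty acts on
#'   data normalised to unit Frobenius norm, so `lambda` is scale-invariant;
#'   besides stabilising ill-conditioned sub-problems it suppresses the
#'   degenerate growth of mutually cancelling components.
#' @param n_iter Iteration budget (default 2000).
#' @param tol Relative residual-change tolerance for early stopping.
#' @param seed Seed for the random initialisation.
#' @param n_starts Independent random initialisations; the fit with the
#'   lowest residual is kept. Masked alternating least squares occasionally
#'   converges to a component-swapped local optimum, which a restart detects
#'   and repairs.
#' @param apod,zf Processing options; keep identical to the [full_ft()] call
#'   you compare against.
#' @return A `decomposition_model`.
#' @export
comdd_fit <- function(td, n_components, lambda = 1e-4, n_iter = 2000,
                      tol = 1e-9, seed = 1, n_starts = 2, apod = TRUE,
                      zf = 2) {
  stopifnot(n_components >= 1)
  schedule <- td$schedule
  if (is.null(schedule)) {
    if (!mask_complete(td)) stop("sparse series carries no schedule")
    schedule <- schedule_full(td$grid, n_planes(td$spec))
  }
  P <- n_planes(td$spec)
  if (length(unique(schedule$plane)) < P) {
    stop("every CPMG plane needs at least one sampled point")
  }
  K <- length(td$grid$np) - 1L

  arr <- direct_stage(td$values, apod, zf)
  Fdim <- dim(arr)[1]
  obs <- expand_obs(schedule, K)
  Xmat <- matrix(0, nrow = Fdim, ncol = nrow(obs))
  d_arr <- dim(arr)
  for (j in seq_len(nrow(obs))) {
    idx <- as.list(obs[j, ] + 1L)
    Xmat[, j] <- do.call(`[`, c(list(arr), list(TRUE), idx))
  }

  xscale <- sqrt(mean(Xmat^2))
  if (xscale > 0) Xmat <- Xmat / xscale

  dof_data <- length(Xmat)
  dof_model <- n_components * (Fdim + sum(2L * td$grid$np[-1]) + P)
  if (dof_model > dof_data) {
    warning("n_components = ", n_components, " exceeds the sampled-data ",
            "degrees of freedom; proceeding anyway")
  }

  sv <- svd(Xmat, nu = min(n_components, ncol(Xmat)), nv = 0)
  make_init <- function(s) with_seed(s, {
    normc <- function(m) sweep(m, 2, pmax(sqrt(colSums(m^2)), 1e-300), "/")
    # anchor direct-dimension shapes to the data (left singular vectors),
    # padding with random vectors beyond the numerical rank
    A0 <- matrix(stats::rnorm(Fdim * n_components), Fdim)
    A0[, seq_len(ncol(sv$u))] <- sv$u
    f <- c(list(normc(A0)),
           lapply(td$grid$np[-1], function(n) {
             normc(matrix(stats::rnorm(2 * n * n_components), 2 * n))
           }))
    # plane amplitudes are attenuation factors (positive, order one): a flat
    # positive start avoids the sign-scrambled stationary points random
    # amplitudes produce on masked data
    list(factors = f,
         amp = matrix(1, P, n_components))
  })

  fit <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    init <- make_init(seed + (s - 1L) * 100003L)
    cand <- .comdd_als_cpp(Xmat, obs, init$factors, init$amp, lambda,
                           as.integer(n_iter), tol)
    if (is.null(fit) || utils::tail(cand$residual_trace, 1) <
          utils::tail(fit$residual_trace, 1)) {
      fit <- cand
    }
  }

  structure(
    list(factors = fit$factors, amplitudes = fit$amplitudes * xscale,
         n_components = n_components, lambda = lambda,
         n_iter = n_iter, n_sweeps = fit$n_sweeps,
         residual_trace = fit$residual_trace,
         grid = td$grid, spec = td$spec,
         proc = list(apod = apod, zf = zf)),
    class = "decomposition_model"
  )
}

#' Reconstruct the spectrum series from a decomposition model
#'
#' Evaluates the fitted components on the full grid and pushes the indirect
#' dimensions through the same processing as [full_ft()].
#'
#' @param model A `decomposition_model` from [comdd_fit()].
#' @param grid Grid to evaluate on; must match the fitted grid.
#' @return A `spectrum_series` with provenance `"comdd"`.
#' @export
comdd_reconstruct <- function(model, grid = model$grid) {
  if (!identical(as.integer(grid$np), as.integer(model$grid$np))) {
    stop("grid does not match the fitted model")
  }
  A <- model$factors[[1]]
  K <- length(grid$np) - 1L
  P <- nrow(model$amplitudes)
  Fdim <- nrow(A)
  tdim <- vapply(model$factors[-1], nrow, integer(1))
  arr <- array(0, dim = c(Fdim, tdim, P))
  if (K == 1L) {
    B <- model$factors[[2]]
    for (p in seq_len(P)) {
      arr[, , p] <- A %*% (t(B) * model$amplitudes[p, ])
    }
  } else {
    B <- model$factors[[2]]; C <- model$factors[[3]]
    for (p in seq_len(P)) {
      acc <- array(0, dim = c(Fdim, tdim))
      for (i in seq_len(ncol(A))) {
        acc <- acc + model$amplitudes[p, i] *
          outer(outer(A[, i], B[, i]), C[, i])
      }
      arr[, , , p] <- acc
    }
  }
  for (k in seq_len(K)) {
    arr <- indirect_stage(arr, k + 1L, model$proc$apod, model$proc$zf)
  }
  assemble_spectrum(arr, grid, model$spec, model$proc, provenance = "comdd")
}

#' @export
print.decomposition_model <- function(x, ...) {
  cat("<decomposition_model> ", x$n_components, " components, ",
      x$n_sweeps, " sweeps, final relative residual ",
      signif(utils::tail(x$residual_trace, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Dump a decomposition model as structured text
#'
#' Writes amplitudes and shape vectors as labelled tab-separated blocks for
#' inspection.
#'
#' @param model A `decomposition_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# comdd model: %d components, lambda %g, %d sweeps",
            model$n_components, model$lambda, model$n_sweeps)
  ), con)
  blocks <- c(list(amplitudes = model$amplitudes),
              stats::setNames(model$factors,
                              c("direct", paste0("indirect", seq_len(length(model$factors) - 1L)))))
  for (nm in names(blocks)) {
    writeLines(sprintf("## %s", nm), con)
    utils::write.table(blocks[[nm]], con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
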