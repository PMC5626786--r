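# --- IRLS-VE: per-plane compressed-sensing reconstruction --------------------

#' Virtual-echo extension of an indirect-dimension vector
#'
#' Builds the length-`2n` conjugate-symmetric extension of a complex
#' time-domain vector: the first point (made real) is kept once, points
#' `2..n` appear at both `+t` and mirrored `-t` positions with conjugate
#' values, and the fold point is zero. The Fourier transform of the result is
#' real for an absorptive, phase-aligned signal.
#'
#' @param y Complex vector of `n` time-domain samples, first point at t = 0.
#' @return Complex vector of length `2n`.
#' @export
virtual_echo <- function(y) {
  n <- length(y)
  ve <- complex(2L * n)
  ve[1] <- Re(y[1])
  if (n > 1) {
    ve[2:n] <- y[2:n]
    ve[(2L * n):(n + 2L)] <- Conj(y[2:n])
  }
  ve
}

# inverse-DFT measurement rows (real-stacked) for one dimension:
# row for sample k (0-based): (2 - (k==0))/M * exp(+2*pi*i*k*m/M), m=0..M-1
ve_rows_1d <- function(ks, M) {
  E <- exp(2i * pi * outer(ks, 0:(M - 1)) / M) * (2 / M)
  E[ks == 0, ] <- E[ks == 0, , drop = FALSE] / 2
  E
}

# Nyquist-mode constraint rows (RHS zero): the fold-frequency content of the
# doubled real spectrum vanishes for data zero beyond the measured half
nyquist_rows_1d <- function(M) matrix((-1)^(0:(M - 1)), nrow = 1)

#' Reconstruct a sparse series by per-plane IRLS with virtual echo
#'
#' The direct dimension (always fully sampled) is Fourier transformed first.
#' For every (direct frequency, CPMG plane) column an independent sparse
#' reconstruction is run over the indirect dimension(s): the unknown is the
#' real absorptive spectrum on the virtual-echo-doubled grid, the
#' measurements are the sampled hypercomplex time-domain points, and
#' iteratively reweighted least squares drives the solution toward an
#' lp-sparse spectrum (`w = (|x|^2 + eps)^((p-2)/2)` with `eps` decayed each
#' iteration).
#'
#' @param td A sparse `td_series` (direct dimension complete).
#' @param n_iter IRLS iterations (default 30).
#' @param p Sparsity exponent of the reweighting (default 0.5).
#' @param apod Cosine apodization, applied to the sampled points and thereby
#'   to the recovered spectrum; keep identical to the [full_ft()] reference.
#' @param zf Zero-filling factor for the direct dimension.
#' @param reg Relative ridge added to the normal equations.
#' @return A `spectrum_series` with provenance `"irls_ve"`. Indirect axes are
#'   doubled (the virtual-echo grid), matching [full_ft()] with `zf = 2`.
#' @export
irls_ve_reconstruct <- function(td, n_iter = 30, p = 0.5, apod = TRUE,
                                zf = 2, reg = 1e-9) {
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
  np_ind <- td$grid$np[-1]
  M <- 2L * np_ind

  arr <- direct_stage(td$values, apod, zf)
  Fdim <- dim(arr)[1]
  cc <- schedule_coord_cols(schedule)

  out <- array(0, dim = c(Fdim, M, P))
  for (pl in seq_len(P)) {
    rows_pl <- schedule[schedule$plane == pl, , drop = FALSE]
    if (nrow(rows_pl) == 0) stop("plane ", pl, " has no samples")
    if (K == 1L) {
      k1 <- rows_pl[[cc[1]]] - 1L
      ap <- apod_vec(np_ind[1], apod)[k1 + 1L]
      half <- ifelse(k1 == 0L, 0.5, 1)
      # measured complex points: cos + i*sin slices, halved at t=0, apodized
      zre <- arr[, 2L * k1 + 1L, pl, drop = FALSE]
      zim <- arr[, 2L * k1 + 2L, pl, drop = FALSE]
      z <- (matrix(zre, nrow = Fdim) + 1i * matrix(zim, nrow = Fdim)) *
        rep(ap * half, each = Fdim)
      E <- ve_rows_1d(k1, M[1])
      A <- rbind(Re(E), Im(E)[k1 != 0L, , drop = FALSE], nyquist_rows_1d(M[1]))
      B <- rbind(t(Re(z)), t(Im(z))[k1 != 0L, , drop = FALSE],
                 matrix(0, 1, Fdim))
      out[, , pl] <- t(.irls_core_cpp(A, B, p, n_iter, reg))
    } else {
      sol <- irls_plane_2d(arr, rows_pl, cc, np_ind, M, pl, apod, p, n_iter, reg)
      out[, , , pl] <- sol
    }
  }

  assemble_spectrum(out, td$grid, td$spec, proc = list(apod = apod, zf = 2),
                    provenance = "irls_ve")
}

# two indirect dimensions: unknown real spectrum on the M1 x M2 doubled grid.
# The four hypercomplex components of a sampled (k1, k2) point combine into
# P/N-type complex measurements
#   zP = (cc - ss) + i(sc + cs) = c * T(+k1, k2)
#   zN = (cc + ss) + i(sc - cs) = c * conj(T(-k1, k2))
# with T the 2D inverse DFT of the spectrum and c the per-dimension first
# point factors; the N-type row duplicates the P-type one when k1 or k2 is 0.
irls_plane_2d <- function(arr, rows_pl, cc, np_ind, M, pl, apod, p, n_iter, reg) {
  Fdim <- dim(arr)[1]
  k1 <- rows_pl[[cc[1]]] - 1L
  k2 <- rows_pl[[cc[2]]] - 1L
  ap1 <- apod_vec(np_ind[1], apod)
  ap2 <- apod_vec(np_ind[2], apod)
  w <- ap1[k1 + 1L] * ap2[k2 + 1L] *
    ifelse(k1 == 0L, 0.5, 1) * ifelse(k2 == 0L, 0.5, 1)

  comp <- function(o1, o2) {
    matrix(arr[cbind(rep(seq_len(Fdim), length(k1)),
                     rep(2L * k1 + o1, each = Fdim),
                     rep(2L * k2 + o2, each = Fdim),
                     pl)],
           nrow = Fdim)
  }
  ccm <- comp(1L, 1L); csm <- comp(1L, 2L)
  scm <- comp(2L, 1L); ssm <- comp(2L, 2L)
  zP <- t((ccm - ssm) + 1i * (scm + csm)) * w
  zN <- t((ccm + ssm) + 1i * (scm - csm)) * w

  m1 <- 0:(M[1] - 1); m2 <- 0:(M[2] - 1)
  row2d <- function(kk1, kk2) {
    f1 <- exp(2i * pi * kk1 %o% m1 / M[1]) * (2 / M[1])
    f1[kk1 == 0, ] <- f1[kk1 == 0, , drop = FALSE] / 2
    f2 <- exp(2i * pi * kk2 %o% m2 / M[2]) * (2 / M[2])
    f2[kk2 == 0, ] <- f2[kk2 == 0, , drop = FALSE] / 2
    # kron per row: unknown vectorized with m1 fastest
    t(vapply(seq_along(kk1),
             function(j) as.vector(outer(f1[j, ], f2[j, ])),
             complex(M[1] * M[2])))
  }
  EP <- row2d(k1, k2)
  keepN <- k1 != 0L & k2 != 0L
  EN <- row2d(-k1[keepN], k2[keepN])
  # conj(T(-k1,k2)) = zN  =>  T(-k1,k2) = conj(zN)
  zNk <- Conj(zN[keepN, , drop = FALSE])

  Ecplx <- rbind(EP, EN)
  Bc <- rbind(zP, zNk)
  k0 <- c(k1 == 0L & k2 == 0L, rep(FALSE, sum(keepN)))
  # Nyquist constraints: fold-frequency content zero along each dimension
  nyq1 <- t(vapply(seq_len(M[2]), function(j) {
    v <- matrix(0, M[1], M[2]); v[, j] <- (-1)^m1; as.vector(v)
  }, numeric(M[1] * M[2])))
  nyq2 <- t(vapply(seq_len(M[1]), function(i) {
    v <- matrix(0, M[1], M[2]); v[i, ] <- (-1)^m2; as.vector(v)
  }, numeric(M[1] * M[2])))

  A <- rbind(Re(Ecplx), Im(Ecplx)[!k0, , drop = FALSE], nyq1, nyq2)
  B <- rbind(Re(Bc), Im(Bc)[!k0, , drop = FALSE],
             matrix(0, nrow(nyq1) + nrow(nyq2), ncol(Bc)))
  sol <- .irls_core_cpp(A, B, p, n_iter, reg)
  array(t(sol), dim = c(Fdim, M[1], M[2]))
}
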