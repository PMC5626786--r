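#' Effective relaxation rate from numerical Bloch-McConnell propagation
#'
#' Propagates the two-state in-phase transverse magnetization through an
#' explicit CPMG pulse train: alternating free-precession blocks of duration
#' `tau = 1/(4 nu)` and instantaneous 180-degree pulses (complex conjugation),
#' with `n = round(2 * nu * t_relax / 2) * 2` refocusing pulses so the train
#' fills the constant relaxation delay. The effective rate is
#' `R2eff = -log(s) / t_relax` where `s` is the surviving ground-state
#' magnetization relative to its initial value.
#'
#' The CPMG frequency convention is `nu = 1/(2 * delta)` with `delta` the
#' spacing between the centres of successive 180-degree pulses.
#'
#' @param nu CPMG repetition rate(s) in Hz.
#' @param r2_0 Intrinsic transverse relaxation rate, s^-1.
#' @param delta_omega Chemical-shift difference between the states, ppm,
#'   for the probed nucleus.
#' @param kex Exchange rate `k_AB + k_BA`, s^-1.
#' @param p_b Population of the minor (excited) state, in (0, 0.5).
#' @param t_relax Constant relaxation delay, s.
#' @param field Static field in tesla.
#' @param nucleus Probed nucleus, `"15N"` or `"13CO"`.
#' @return Vector of effective rates, s^-1, one per `nu`.
#' @seealso [cr_r2eff()] for the closed-form equivalent.
#' @export
bm_r2eff <- function(nu, r2_0, delta_omega, kex, p_b, t_relax,
                     field = 18.8, nucleus = "15N") {
  stopifnot(all(nu > 0), r2_0 >= 0, delta_omega >= 0, t_relax > 0)
  if (delta_omega == 0 || kex == 0 || p_b == 0) return(rep(r2_0, length(nu)))
  stopifnot(kex > 0, p_b > 0, p_b < 0.5)
  dw <- dw_rad(delta_omega, nucleus, field)
  pa <- 1 - p_b
  kab <- p_b * kex
  kba <- pa * kex
  L <- matrix(c(-r2_0 - kab + 0i, kab, kba, -r2_0 - kba + 1i * dw), 2, 2)
  vapply(nu, function(v) {
    n180 <- max(2L, round(2 * v * t_relax / 2) * 2)
    tau <- t_relax / (2 * n180)
    e <- eigen(L)
    P <- e$vectors %*% diag(exp(e$values * tau)) %*% solve(e$vectors)
    m <- c(pa, p_b)
    for (j in seq_len(n180)) {
      m <- P %*% m
      m <- Conj(m)
      m <- P %*% m
    }
    -log(Re(m[1]) / pa) / t_relax
  }, numeric(1))
}

#' Effective relaxation rate from the closed-form two-state solution
#'
#' Carver-Richards-type closed form for in-phase two-state exchange with equal
#' intrinsic rates, evaluated exactly for the finite pulse train from the
#' eigenstructure of the two-echo propagator (stable cosh/arccosh-free
#' algebra). For large pulse numbers it coincides with the classical
#' dominant-eigenvalue Carver-Richards expression; at the few-pulse end of a
#' dispersion curve it keeps the transient terms the classical formula drops.
#' Used as the fast model evaluator inside the fitting routines; the stepwise
#' propagator [bm_r2eff()] serves as its independent cross-check.
#'
#' @inheritParams bm_r2eff
#' @return Vector of effective rates, s^-1, one per `nu`.
#' @export
cr_r2eff <- function(nu, r2_0, delta_omega, kex, p_b, t_relax,
                     field = 18.8, nucleus = "15N") {
  stopifnot(all(nu > 0), r2_0 >= 0, delta_omega >= 0, t_relax > 0)
  if (delta_omega == 0 || kex == 0 || p_b == 0) return(rep(r2_0, length(nu)))
  stopifnot(kex > 0, p_b > 0, p_b < 0.5)
  dw <- dw_rad(delta_omega, nucleus, field)
  .cr_r2eff_cpp(r2_0, dw, kex, p_b, as.numeric(nu), t_relax)
}
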