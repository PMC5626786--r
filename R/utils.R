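#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @useDynLib nusrd, .registration = TRUE
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic entry points route through this
# so that identical seeds give identical results without clobbering the
# session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Proton frequency scale: 800.13 MHz at 18.8 T.
H1_MHZ_PER_TESLA <- 800.13 / 18.8

# gamma(X)/gamma(1H); 15N value is negative physically, magnitudes are what
# matter for shift-to-Hz conversion.
GAMMA_RATIO <- c(`1H` = 1, `15N` = 0.10136767, `13CO` = 0.25144953)

#' Larmor frequency of a nucleus
#'
#' @param nucleus One of `"1H"`, `"15N"`, `"13CO"`.
#' @param field Static magnetic field in tesla.
#' @return Frequency in MHz.
#' @export
larmor_mhz <- function(nucleus, field = 18.8) {
  nucleus <- match.arg(nucleus, names(GAMMA_RATIO))
  unname(field * H1_MHZ_PER_TESLA * GAMMA_RATIO[[nucleus]])
}

# ppm <-> Hz offsets from the carrier (carrier at 0)
ppm_to_hz <- function(ppm, nucleus, field = 18.8) ppm * larmor_mhz(nucleus, field)
hz_to_ppm <- function(hz, nucleus, field = 18.8) hz / larmor_mhz(nucleus, field)

# |dw| in ppm -> rad/s for the probed nucleus
dw_rad <- function(dw_ppm, nucleus, field = 18.8) {
  dw_ppm * larmor_mhz(nucleus, field) * 2 * pi
}

fftshift_idx <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))

# frequency axis (Hz, ascending, carrier at 0) matching fftshift of an
# unshifted length-n FFT
freq_axis <- function(n, sw) {
  f <- (0:(n - 1)) * sw / n
  f[f >= sw / 2] <- f[f >= sw / 2] - sw
  sort(f)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
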