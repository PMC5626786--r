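# --- ggplot2 methods ---------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot dispersion curves
#'
#' Effective relaxation rate against CPMG frequency, one panel per peak,
#' with error bars where available.
#'
#' @param object A dispersion tibble (from [compute_r2eff()]).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dispersion <- function(object, ...) {
  d <- object[object$ok & !is.na(object$r2eff), ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$nu, y = .data$r2eff)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$peak), scales = "free_y") +
    ggplot2::labs(x = expression(nu[CPMG] ~ "(Hz)"),
                  y = expression(R[2 * ",eff"] ~ (s^-1)))
  if (!all(is.na(d$sigma))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$r2eff - .data$sigma,
                   ymax = .data$r2eff + .data$sigma), width = 0
    )
  }
  p
}

#' Plot a global two-state fit
#'
#' Experimental dispersion points with the fitted global model overlaid,
#' one panel per residue.
#'
#' @param object A `two_state_fit`.
#' @param n_curve Number of model evaluation points per panel.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.two_state_fit <- function(object, n_curve = 80, ...) {
  d <- object$curves
  d <- d[d$ok & !is.na(d$r2eff) & d$peak %in% object$residues$peak, ]
  nus <- exp(seq(log(min(d$nu)), log(max(d$nu)), length.out = n_curve))
  lines <- purrr::pmap_dfr(
    object$residues[, c("peak", "delta_omega", "r2_0")],
    function(peak, delta_omega, r2_0) {
      tibble::tibble(
        peak = peak, nu = nus,
        r2eff = r2_0 + rex_eval(nus, delta_omega, object$kex, object$p_b,
                                object$meta$t_relax, object$meta$field,
                                object$meta$nucleus)
      )
    }
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$nu, y = .data$r2eff)) +
    ggplot2::geom_line(data = lines, colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$r2eff - .data$sigma,
                   ymax = .data$r2eff + .data$sigma), width = 0
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$peak), scales = "free_y") +
    ggplot2::labs(x = expression(nu[CPMG] ~ "(Hz)"),
                  y = expression(R[2 * ",eff"] ~ (s^-1)))
}

#' Plot targeted-acquisition error tracks
#'
#' Median step-to-step and jackknife intensity-error tracks against the NUS
#' fraction, mirroring the real-time quality monitoring view.
#'
#' @param object A `ta_report` from [ta_run()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.ta_report <- function(object, ...) {
  s <- ta_summary(object)
  long <- tidyr::pivot_longer(
    s, c("rms_step_error", "rms_jackknife_error"),
    names_to = "track", values_to = "error"
  )
  long$track <- ifelse(long$track == "rms_step_error",
                       "step difference", "jackknife")
  ggplot2::ggplot(long[!is.na(long$error), ],
                  ggplot2::aes(x = 100 * .data$fraction, y = .data$error,
                               colour = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "NUS (%)", y = "intensity error", colour = NULL)
}
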