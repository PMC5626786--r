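# per-residue screening and the global two-state fit

make_curve <- function(nu, y, sigma) {
  out <- tibble::tibble(peak = "P1", nu = nu, r2eff = y, sigma = sigma,
                        ok = TRUE)
  attr(out, "t_relax") <- 0.04
  attr(out, "field") <- 18.8
  attr(out, "nucleus") <- "15N"
  class(out) <- c("dispersion", class(out))
  out
}

test_that("a flat noiseless curve has zero flat-fit RMSD and p near 1", {
  nu <- default_nu_grid()
  f <- fit_residue(make_curve(nu, rep(12, 11), rep(0.2, 11)))
  expect_equal(f$flat$rmsd, 0)
  expect_equal(f$flat$r2_0, 12)
  expect_gte(f$p_value, 0.5)
})

test_that("a strong exchanger is overwhelmingly significant", {
  nu <- default_nu_grid()
  y <- cr_r2eff(nu, 10, 2, 182, 0.029, 0.04)
  set.seed(55)
  f <- fit_residue(make_curve(nu, y + stats::rnorm(11, 0, 0.2), rep(0.2, 11)))
  expect_lt(f$p_value, 1e-6)
  expect_gt(f$exchange$delta_omega, 0.5)
})

test_that("degenerate errors fall back to an unweighted fit with a warning", {
  nu <- default_nu_grid()
  expect_warning(fit_residue(make_curve(nu, rep(10, 11), rep(0, 11))),
                 "unweighted")
})

test_that("the global fit recovers noiseless parameters exactly", {
  nu <- default_nu_grid()
  dws <- c(0.6, 1.2, 2.1)
  curves <- dplyr::bind_rows(lapply(seq_along(dws), function(i) {
    tibble::tibble(peak = sprintf("P%d", i), nu = nu,
                   r2eff = cr_r2eff(nu, 8 + i, dws[i], 182, 0.029, 0.04),
                   sigma = 0.1, ok = TRUE)
  }))
  attr(curves, "t_relax") <- 0.04
  fit <- fit_global(curves, starts = 10, seed = 1)
  expect_lt(abs(fit$kex - 182) / 182, 1e-3)
  expect_lt(abs(fit$p_b - 0.029) / 0.029, 1e-3)
  expect_lt(max(abs(fit$residues$delta_omega - dws)), 1e-3)
  expect_false(fit$boundary)

  # appending a duplicate of every curve leaves the estimates unchanged
  dup <- dplyr::bind_rows(curves, dplyr::mutate(curves, peak = paste0(peak, "b")))
  attr(dup, "t_relax") <- 0.04
  fit2 <- fit_global(dup, starts = 10, seed = 1)
  expect_equal(fit2$kex, fit$kex, tolerance = 1e-4)
  expect_equal(fit2$p_b, fit$p_b, tolerance = 1e-4)
})

test_that("tidy and glance expose the fit in broom shapes", {
  nu <- default_nu_grid()
  curves <- dplyr::bind_rows(lapply(1:2, function(i) {
    tibble::tibble(peak = sprintf("P%d", i), nu = nu,
                   r2eff = cr_r2eff(nu, 9, 0.5 * i, 182, 0.029, 0.04),
                   sigma = 0.1, ok = TRUE)
  }))
  attr(curves, "t_relax") <- 0.04
  fit <- fit_global(curves, starts = 4, seed = 2)
  td <- tidy(fit)
  expect_equal(td$term[1:2], c("kex", "p_b"))
  expect_equal(nrow(td), 2 + 2)
  expect_true(all(c("estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("kex", "p_b", "chi2", "dof", "cor_kex_pb") %in% names(gl)))
  expect_lt(gl$cor_kex_pb, 0)  # the kex / p_b trade-off ridge
})

test_that("significance screening separates exchangers from flat residues", {
  nu <- default_nu_grid()
  set.seed(56)
  curves <- dplyr::bind_rows(
    tibble::tibble(peak = "EX", nu = nu,
                   r2eff = cr_r2eff(nu, 9, 1.5, 182, 0.029, 0.04) +
                     stats::rnorm(11, 0, 0.2),
                   sigma = 0.2, ok = TRUE),
    tibble::tibble(peak = "FLAT", nu = nu,
                   r2eff = 9 + stats::rnorm(11, 0, 0.2),
                   sigma = 0.2, ok = TRUE)
  )
  attr(curves, "t_relax") <- 0.04
  scr <- significant_peaks(curves)
  expect_true(scr$significant[scr$peak == "EX"])
  expect_false(scr$significant[scr$peak == "FLAT"])
  expect_lt(scr$flat_rmsd[scr$peak == "FLAT"], 0.6)
})

test_that("shift-difference RMSD follows its definition", {
  expect_equal(dw_rmsd(c(1, 2), c(1, 2)), 0)
  expect_equal(dw_rmsd(1.0, 1.2), 0.2)
  expect_error(dw_rmsd(c(1, 2), 1), "length")
})

test_that("resampled refits summarise the parameter spread", {
  nu <- default_nu_grid()
  set.seed(57)
  trials <- lapply(1:3, function(i) {
    curves <- dplyr::bind_rows(lapply(1:3, function(j) {
      tibble::tibble(peak = sprintf("P%d", j), nu = nu,
                     r2eff = cr_r2eff(nu, 9, 0.5 + 0.5 * j, 182, 0.029, 0.04) +
                       stats::rnorm(11, 0, 0.15),
                     sigma = 0.15, ok = TRUE)
    }))
    attr(curves, "t_relax") <- 0.04
    curves
  })
  out <- fit_global_resampled(trials, inflation = 2, starts = 4, seed = 3)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "sd_kex"), 2 * stats::sd(out$kex))
})
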