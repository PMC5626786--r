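# peak intensity extraction and rate conversion

test_that("plane intensity ratios follow the forward attenuation model", {
  cs <- one_site_case()
  ii <- extract_intensities(full_ft(cs$td), cs$peaks)
  i0 <- ii$intensity[ii$is_ref]
  ratios <- ii$intensity[!ii$is_ref] / i0
  want <- exp(-cs$truth * cs$spec$t_relax)
  expect_lt(max(abs(ratios - want)), 1e-3)
})

test_that("well-separated peaks are read out independently", {
  grid <- tiny_grid_2d(np = c(64, 48))
  spec <- tiny_spec(nu = c(100, 400))
  sys <- make_system("sh3_like", 2, seed = 36, grid = grid)
  both <- synthesize_fid(sys, grid, spec, noise_sigma = 0)
  pk <- peak_list(sys, grid)
  h_both <- extract_intensities(full_ft(both), pk)

  for (s in 1:2) {
    solo <- sys
    solo$sites <- sys$sites[s, ]
    td <- synthesize_fid(solo, grid, spec, noise_sigma = 0)
    h_solo <- extract_intensities(full_ft(td), pk[s, ])
    m <- match(paste(h_solo$peak, h_solo$plane),
               paste(h_both$peak, h_both$plane))
    expect_lt(max(abs(h_both$intensity[m] - h_solo$intensity) /
                    h_solo$intensity), 0.005)
  }
})

test_that("an empty spectrum yields zero intensities and a boundary warning", {
  cs <- one_site_case()
  sp <- full_ft(cs$td)
  sp$values[] <- 0
  expect_warning(ii <- extract_intensities(sp, cs$peaks), "boundary")
  expect_true(all(ii$intensity == 0))
})

test_that("rates follow the closed-form log ratio", {
  intens <- tibble::tibble(
    peak = "P1", plane = 1:2, nu = c(NA, 100), is_ref = c(TRUE, FALSE),
    intensity = c(1, exp(-1)), sigma_i = NA_real_
  )
  attr(intens, "t_relax") <- 0.05
  cv <- compute_r2eff(intens, t_relax = 0.05)
  expect_equal(cv$r2eff, 20)

  intens$intensity <- c(1, 1)
  expect_equal(compute_r2eff(intens, t_relax = 0.05)$r2eff, 0)
})

test_that("non-positive intensities are flagged, not dropped silently", {
  intens <- tibble::tibble(
    peak = "P1", plane = 1:3, nu = c(NA, 100, 400),
    is_ref = c(TRUE, FALSE, FALSE),
    intensity = c(1, -0.1, 0.5), sigma_i = 0.01
  )
  expect_warning(cv <- compute_r2eff(intens, t_relax = 0.04), "flagged")
  expect_equal(nrow(cv), 2)
  expect_false(cv$ok[cv$nu == 100])
  expect_true(is.na(cv$r2eff[cv$nu == 100]))
  expect_true(cv$ok[cv$nu == 400])
})

test_that("error propagation combines plane and reference contributions", {
  intens <- tibble::tibble(
    peak = "P1", plane = 1:2, nu = c(NA, 100), is_ref = c(TRUE, FALSE),
    intensity = c(2, 1), sigma_i = c(0.02, 0.03)
  )
  cv <- compute_r2eff(intens, t_relax = 0.04)
  expect_equal(cv$sigma, sqrt((0.03 / 1)^2 + (0.02 / 2)^2) / 0.04)
})

test_that("duplicate planes are averaged with their repeat count", {
  curves <- tibble::tibble(
    peak = "P1", nu = c(100, 100, 400), r2eff = c(10, 10.2, 8),
    sigma = NA_real_, ok = TRUE
  )
  attr(curves, "t_relax") <- 0.04
  avg <- average_duplicates(curves)
  expect_equal(nrow(avg), 2)
  expect_equal(avg$r2eff[avg$nu == 100], 10.1)
  expect_equal(avg$n_rep, c(2L, 1L))
  dup <- duplicate_global_error(curves)
  expect_equal(dup$sigma_r2, 0.1)
  withdup <- with_duplicate_errors(avg, dup)
  expect_equal(withdup$sigma[withdup$nu == 100], 0.1)
  expect_equal(withdup$sigma[withdup$nu == 400], 0.1 * sqrt(2))
})

test_that("round trip recovers the true rates within predicted errors", {
  grid <- tiny_grid_2d(np = c(48, 32))
  spec <- tiny_spec()
  sys <- make_system("sh3_like", 3, seed = 37, grid = grid)
  pk <- peak_list(sys, grid)
  truth <- unlist(lapply(1:3, function(s) r2eff_true(sys, s, spec$nu, spec)))
  cover <- sapply(1:60, function(i) {
    td <- synthesize_fid(sys, grid, spec, noise_sigma = 0.05, seed = 500 + i)
    sp <- full_ft(td)
    cv <- compute_r2eff(with_noise_floor_errors(extract_intensities(sp, pk), sp))
    abs(cv$r2eff - truth) <= 2 * cv$sigma
  })
  # ~95% of points inside 2-sigma error bars
  expect_gt(mean(cover), 0.9)
})
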