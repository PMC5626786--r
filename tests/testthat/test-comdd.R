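# co-MDD: masked alternating least squares and reconstruction

test_that("noiseless rank-1 data are recovered exactly", {
  cs <- one_site_case()
  # fully sampled, lambda small enough for the oracle tolerance
  m <- comdd_fit(cs$td, n_components = 1, lambda = 1e-8, seed = 1)
  expect_lt(utils::tail(m$residual_trace, 1), 1e-6)
  # reconstruction equals the reference FT
  sp <- full_ft(cs$td)
  rec <- comdd_reconstruct(m)
  expect_lt(max(abs(rec$values - sp$values)) / max(abs(sp$values)), 1e-6)
})

test_that("noiseless rank-1 NUS data are recovered through the shared model", {
  cs <- one_site_case()
  P <- nusrd:::n_planes(cs$spec)
  sch <- covered_schedule(cs$grid, P, 0.25, seed = 21)
  m <- comdd_fit(apply_schedule(cs$td, sch), n_components = 1, lambda = 1e-8,
                 seed = 1)
  sp <- full_ft(cs$td)
  rec <- comdd_reconstruct(m)
  hf <- extract_intensities(sp, cs$peaks)$intensity
  hc <- extract_intensities(rec, cs$peaks)$intensity
  expect_lt(max(abs(hc - hf) / hf), 0.005)
})

test_that("rank-2 NUS fit generalises to held-out coordinates", {
  grid <- tiny_grid_2d()
  spec <- tiny_spec()
  sys <- make_system("sh3_like", 2, seed = 22, grid = grid)
  td <- synthesize_fid(sys, grid, spec, noise_sigma = 0)
  P <- nusrd:::n_planes(spec)
  sch <- covered_schedule(grid, P, 0.25, seed = 23)
  # exact-rank ALS crosses a slow swamp on this instance; the iteration
  # budget is cheap at this size
  m <- comdd_fit(apply_schedule(td, sch), n_components = 2, lambda = 1e-8,
                 n_iter = 12000, seed = 1)
  # model evaluated in the time domain against the full noiseless tensor
  arr_true <- nusrd:::direct_stage(td$values, TRUE, 2)
  A <- m$factors[[1]]; B <- m$factors[[2]]
  err2 <- 0; norm2 <- 0
  for (p in seq_len(P)) {
    mod <- A %*% (t(B) * m$amplitudes[p, ])
    err2 <- err2 + sum((mod - arr_true[, , p])^2)
    norm2 <- norm2 + sum(arr_true[, , p]^2)
  }
  expect_lt(sqrt(err2 / norm2), 1e-3)
})

test_that("reconstructed intensities are linear in the data scale", {
  cs <- one_site_case()
  P <- nusrd:::n_planes(cs$spec)
  sch <- covered_schedule(cs$grid, P, 0.3, seed = 24)
  sparse <- apply_schedule(cs$td, sch)
  m1 <- comdd_fit(sparse, n_components = 1, lambda = 1e-8, seed = 2)
  sparse2 <- sparse
  sparse2$values <- sparse$values * 3
  m2 <- comdd_fit(sparse2, n_components = 1, lambda = 1e-8, seed = 2)
  h1 <- extract_intensities(comdd_reconstruct(m1), cs$peaks)$intensity
  h2 <- extract_intensities(comdd_reconstruct(m2), cs$peaks)$intensity
  expect_lt(max(abs(h2 / h1 - 3)), 1e-8 * 3)
})

test_that("zero amplitudes give zero spectra and doubling doubles them", {
  cs <- one_site_case()
  m <- comdd_fit(cs$td, n_components = 1, lambda = 1e-8, seed = 1)
  m0 <- m
  m0$amplitudes <- m$amplitudes * 0
  expect_true(all(comdd_reconstruct(m0)$values == 0))
  m2 <- m
  m2$amplitudes <- m$amplitudes * 2
  expect_equal(comdd_reconstruct(m2)$values, 2 * comdd_reconstruct(m)$values,
               tolerance = 1e-12)
})

test_that("flat-system amplitudes are constant across planes", {
  grid <- tiny_grid_2d()
  spec <- tiny_spec()
  sys <- make_system("idp_flat", 1, seed = 25, grid = grid)
  P <- nusrd:::n_planes(spec)
  sch <- covered_schedule(grid, P, 0.3, seed = 26)
  cvs <- sapply(1:6, function(i) {
    td <- synthesize_fid(sys, grid, spec, noise_sigma = 0.02, seed = 30 + i)
    m <- comdd_fit(apply_schedule(td, sch), n_components = 1, seed = 3)
    amp <- m$amplitudes[-1, 1]   # CPMG planes share one scale for flat data
    stats::sd(amp) / mean(amp)
  })
  # noise-predicted bound: per-plane relative error ~ sigma_I/I, generously x5
  expect_lt(stats::median(cvs), 0.05)
})

test_that("oversized component counts warn but proceed", {
  grid <- tiny_grid_2d(np = c(8, 6))
  spec <- tiny_spec(nu = c(100, 400))
  sys <- make_system("sh3_like", 1, seed = 27, grid = grid)
  td <- synthesize_fid(sys, grid, spec, noise_sigma = 0)
  sch <- generate_schedule(grid, 3, 0.5, seed = 28)
  expect_warning(
    comdd_fit(apply_schedule(td, sch), n_components = 12, n_iter = 20,
              seed = 1),
    "degrees of freedom"
  )
})

test_that("NUS reconstruction leaves rates unbiased at the noise level", {
  # shared shapes make subsampling distortions common-mode in each peak, so
  # the R2eff ratios stay centred on the truth
  grid <- tiny_grid_3d(np = c(16, 10, 10))
  spec <- tiny_spec(nu = c(50, 200, 1000))
  sys <- make_system("sh3_like", 3, seed = 29, grid = grid)
  pk <- peak_list(sys, grid, window = 2)
  P <- nusrd:::n_planes(spec)
  sch <- generate_schedule(grid, P, 0.083, seed = 30)
  truth <- unlist(lapply(1:3, function(s) r2eff_true(sys, s, spec$nu, spec)))
  r2 <- sapply(1:50, function(i) {
    td <- synthesize_fid(sys, grid, spec, noise_sigma = 0.03, seed = 400 + i)
    m <- comdd_fit(apply_schedule(td, sch), n_components = 5, n_iter = 800,
                   seed = 5)
    compute_r2eff(extract_intensities(comdd_reconstruct(m), pk))$r2eff
  })
  bias <- rowMeans(r2) - truth
  sdv <- apply(r2, 1, stats::sd)
  # mean deviation under a third of its spread, pooled over peaks and planes
  expect_lt(sqrt(mean(bias^2)), mean(sdv) / 3 + sqrt(mean(sdv^2) / 50))
})
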