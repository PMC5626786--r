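# reference FT path and noise-floor estimation

test_that("a single noiseless site gives one maximum at its position", {
  cs <- one_site_case()
  sp <- full_ft(cs$td)
  d <- dim(sp$values)
  for (p in seq_len(d[3])) {
    idx <- arrayInd(which.max(sp$values[, , p]), d[1:2])
    f_hat <- sp$axes[[1]][idx[1]]
    g_hat <- sp$axes[[2]][idx[2]]
    expect_lt(abs(f_hat - ppm_to_hz(cs$sys$sites$pos_h, "1H")),
              cs$grid$sw[1] / d[1] + 1e-9)
    expect_lt(abs(g_hat - ppm_to_hz(cs$sys$sites$pos_n, "15N")),
              cs$grid$sw[2] / d[2] + 1e-9)
  }
})

test_that("the processing chain is linear", {
  a <- one_site_case(seed = 11)
  b <- one_site_case(seed = 12)
  sum_td <- a$td
  sum_td$values <- a$td$values + b$td$values
  expect_equal(full_ft(sum_td)$values,
               full_ft(a$td)$values + full_ft(b$td)$values,
               tolerance = 1e-12)
})

test_that("flat systems produce identical planes", {
  grid <- tiny_grid_2d()
  spec <- tiny_spec()
  sys <- make_system("idp_flat", 3, seed = 13, grid = grid)
  sp <- full_ft(synthesize_fid(sys, grid, spec, noise_sigma = 0))
  scale <- exp(sys$sites$r2_0[1] * spec$t_relax)  # single shared plane scale?
  P <- dim(sp$values)[3]
  rel <- sapply(3:P, function(p) {
    max(abs(sp$values[, , p] - sp$values[, , 2])) / max(abs(sp$values[, , 2]))
  })
  expect_lt(max(rel), 1e-10)
})

test_that("full_ft refuses sparse input", {
  cs <- one_site_case()
  sch <- generate_schedule(cs$grid, nusrd:::n_planes(cs$spec), 0.5, seed = 1)
  expect_error(full_ft(apply_schedule(cs$td, sch)), "fully sampled")
})

test_that("spectral noise floor scales as sigma * sqrt(n) under a plain FT", {
  grid <- tiny_grid_2d(np = c(64, 32))
  spec <- tiny_spec(nu = c(100, 400))
  sys <- make_system("idp_flat", 1, seed = 14, grid = grid)
  sys$sites$amplitude <- 0  # pure noise
  for (ns in c(0.5, 1)) {
    td <- synthesize_fid(sys, grid, spec, noise_sigma = ns, seed = 15)
    sp <- full_ft(td, apod = FALSE, zf = 1)
    got <- stats::sd(sp$values)
    # unnormalized FT over n_direct then n_indirect points; first-point
    # halving removes one half point per dimension, a negligible correction
    want <- ns * sqrt(grid$np[1] * grid$np[2])
    expect_lt(abs(got - want) / want, 0.10)
  }
})

test_that("noise floor estimator tracks the injected noise", {
  grid <- tiny_grid_2d(np = c(64, 48))
  spec <- tiny_spec()
  sys <- make_system("sh3_like", 5, seed = 16, grid = grid)
  td0 <- synthesize_fid(sys, grid, spec, noise_sigma = 0)
  td <- synthesize_fid(sys, grid, spec, noise_sigma = 0.05, seed = 17)
  truth <- stats::sd(full_ft(td)$values - full_ft(td0)$values)
  est <- estimate_noise_floor(full_ft(td))
  expect_lt(abs(est - truth) / truth, 0.25)
})
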