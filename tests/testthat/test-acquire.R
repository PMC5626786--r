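# FID synthesis, NUS schedule design and nuslist I/O

test_that("reference-plane first point equals the site amplitude", {
  grid <- tiny_grid_2d()
  spec <- tiny_spec()
  sys <- make_system("sh3_like", 1, seed = 2, grid = grid)
  td <- synthesize_fid(sys, grid, spec, noise_sigma = 0)
  # t = 0 everywhere, cosine component: product of unit factors
  expect_equal(Re(td$values[1, 1, 1]), sys$sites$amplitude,
               tolerance = 1e-12)
})

test_that("flat systems give nu-independent planes with the r2_0 scaling", {
  grid <- tiny_grid_2d()
  spec <- tiny_spec()
  sys <- make_system("idp_flat", 2, seed = 3, grid = grid)
  td <- synthesize_fid(sys, grid, spec, noise_sigma = 0)
  P <- length(spec$nu) + 1
  for (p in 3:P) {
    expect_equal(td$values[, , p], td$values[, , 2], tolerance = 1e-12)
  }
  # single-site check of the exp(-r2_0 T) attenuation
  sys1 <- make_system("idp_flat", 1, seed = 4, grid = grid)
  td1 <- synthesize_fid(sys1, grid, spec, noise_sigma = 0)
  expect_equal(td1$values[1, 1, 2] / td1$values[1, 1, 1],
               exp(-sys1$sites$r2_0 * spec$t_relax) + 0i, tolerance = 1e-10)
})

test_that("per-dimension FT peaks at the site position", {
  grid <- tiny_grid_2d(np = c(64, 32))
  spec <- tiny_spec(nu = c(100))
  sys <- make_system("sh3_like", 1, seed = 5, grid = grid)
  td <- synthesize_fid(sys, grid, spec, noise_sigma = 0)
  # direct dimension: plain FFT of the first indirect component
  v <- td$values[, 1, 1]
  f_axis <- (0:63) * grid$sw[1] / 64
  f_axis[f_axis >= grid$sw[1] / 2] <- f_axis[f_axis >= grid$sw[1] / 2] - grid$sw[1]
  f_hat <- f_axis[which.max(Mod(fft(v)))]
  f_true <- sys$sites$pos_h * larmor_mhz("1H", sys$field)
  expect_lt(abs(f_hat - f_true), grid$sw[1] / 64 / 2 + 1e-9)
  # indirect dimension: combine cos/sin pairs at the first direct point
  z <- td$values[1, seq(1, 63, by = 2), 1] + 1i * td$values[1, seq(2, 64, by = 2), 1]
  g_axis <- (0:31) * grid$sw[2] / 32
  g_axis[g_axis >= grid$sw[2] / 2] <- g_axis[g_axis >= grid$sw[2] / 2] - grid$sw[2]
  g_hat <- g_axis[which.max(Mod(fft(z)))]
  g_true <- sys$sites$pos_n * larmor_mhz("15N", sys$field)
  expect_lt(abs(g_hat - g_true), grid$sw[2] / 32 / 2 + 1e-9)
})

test_that("noise is reproducible under a fixed seed", {
  cs <- one_site_case(noise_sigma = 0.05, seed = 6)
  cs2 <- one_site_case(noise_sigma = 0.05, seed = 6)
  expect_identical(cs$td$values, cs2$td$values)
})

test_that("full-fraction schedules enumerate every cell once", {
  grid <- tiny_grid_2d(np = c(16, 8))
  sch <- generate_schedule(grid, 4, 1, seed = 1)
  expect_equal(nrow(sch), 8 * 4)
  expect_false(any(duplicated(sch)))
  expect_equal(sort(unique(sch$plane)), 1:4)
})

test_that("flat weighting samples indirect coordinates uniformly", {
  grid <- grid_spec(np = c(8, 20), sw = c(2400, 2500), labels = c("h", "n"))
  counts <- integer(20)
  for (s in 1:40) {
    sch <- generate_schedule(grid, 10, 0.5, t_match = Inf, seed = s)
    counts <- counts + tabulate(sch$i1, 20)
  }
  # chi-square uniformity over 4000 draws
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("exponential weighting matches the target density", {
  grid <- grid_spec(np = c(8, 64), sw = c(2400, 2500), labels = c("h", "n"))
  t_match <- 0.004  # strong decay across the 25.6 ms grid
  draws <- integer(0)
  for (s in 1:30) {
    sch <- generate_schedule(grid, 8, 0.2, t_match = t_match, seed = s)
    draws <- c(draws, sch$i1)
  }
  tt <- (draws - 1) / grid$sw[2]
  t_max <- 64 / grid$sw[2]
  # empirical density tracks exp(-t/t_match): compare occupancy of the four
  # time quartiles with the (without-replacement-damped) exponential ranking
  qocc <- tabulate(findInterval(tt, seq(0, t_max, length.out = 5),
                                rightmost.closed = TRUE), 4)
  expect_true(all(diff(qocc) < 0))
  expect_gt(qocc[1] / max(qocc[4], 1), exp(1))
  expect_gt(mean(tt < t_max / 2), 0.75)
})

test_that("plane occupancy stays balanced at low fractions", {
  # indirect space comparable to a 3D experiment, where 8.3% NUS leaves
  # > 100 points per plane
  grid <- grid_spec(np = c(8, 1800), sw = c(2400, 2500), labels = c("h", "n"))
  ratios <- sapply(1:50, function(s) {
    sch <- generate_schedule(grid, 11, 0.083, seed = s)
    cnt <- tabulate(sch$plane, 11)
    max(cnt) / min(cnt)
  })
  expect_lte(max(ratios), 2)
})

test_that("too-small fractions and empty planes are rejected", {
  grid <- tiny_grid_2d(np = c(16, 8))
  expect_error(generate_schedule(grid, 12, 0.01, seed = 1), "empty")
  sys <- make_system("sh3_like", 1, seed = 2, grid = grid)
  spec <- tiny_spec()
  td <- synthesize_fid(sys, grid, spec, noise_sigma = 0)
  sch <- generate_schedule(grid, nusrd:::n_planes(spec), 0.5, seed = 1)
  bad <- sch[sch$plane != 2, ]
  expect_error(apply_schedule(td, bad), "empty")
})

test_that("coverage repair leaves no unsampled indirect coordinate", {
  grid <- tiny_grid_2d(np = c(16, 48))
  sch <- generate_schedule(grid, 12, 0.25, seed = 3, ensure_coverage = TRUE)
  expect_equal(sort(unique(sch$i1)), 1:48)
  expect_false(any(duplicated(sch)))
})

test_that("applying a schedule keeps exactly the scheduled cells", {
  cs <- one_site_case()
  P <- nusrd:::n_planes(cs$spec)
  sch <- generate_schedule(cs$grid, P, 0.3, seed = 7)
  sparse <- apply_schedule(cs$td, sch)
  expect_equal(sum(sparse$mask), nrow(sch))
  expect_equal(sum(!is.na(sparse$values)),
               nrow(sch) * 2L * cs$grid$np[1])
  # full schedule is the identity
  full <- apply_schedule(cs$td, schedule_full(cs$grid, P))
  expect_identical(full$values, cs$td$values)
  # out-of-grid coordinates are rejected
  bad <- sch
  bad$i1[1] <- cs$grid$np[2] + 1L
  expect_error(apply_schedule(cs$td, bad), "outside grid")
})

test_that("nuslist files round-trip and validate", {
  grid <- tiny_grid_2d(np = c(16, 12))
  sch <- generate_schedule(grid, 6, 0.4, seed = 9)
  path <- withr::local_tempfile(fileext = ".txt")
  write_nuslist(sch, path)
  back <- read_nuslist(path, np_ind = 12, n_planes = 6)
  expect_equal(as.data.frame(back), as.data.frame(sch), ignore_attr = TRUE)

  # format definition: "3 7" means indirect index 3 (0-based), plane 7
  writeLines("3 7", path)
  one <- read_nuslist(path, np_ind = 12, n_planes = 8)
  expect_equal(one$i1, 4L)
  expect_equal(one$plane, 8L)

  writeLines(c("1 2", "x 3"), path)
  expect_error(read_nuslist(path, 12, 6), "malformed")
  writeLines("-1 2", path)
  expect_error(read_nuslist(path, 12, 6), "negative")
  writeLines("13 2", path)
  expect_error(read_nuslist(path, 12, 6), "out of range")
})
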