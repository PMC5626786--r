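# shared small-scale builders for the test suite

tiny_grid_2d <- function(np = c(32, 24)) {
  grid_spec(np = np, sw = c(2400, 2500), labels = c("h", "n"))
}

tiny_grid_3d <- function(np = c(16, 8, 8)) {
  grid_spec(np = np, sw = c(2400, 2250, 1400), labels = c("h", "n", "co"))
}

tiny_spec <- function(nu = c(50, 100, 200, 400, 1000), t_relax = 0.04) {
  cpmg_spec(nu = nu, t_relax = t_relax)
}

# one-site 2D dataset with known truth
one_site_case <- function(noise_sigma = 0, seed = 2, grid = tiny_grid_2d(),
                          spec = tiny_spec()) {
  sys <- make_system("sh3_like", 1, seed = seed, grid = grid)
  td <- synthesize_fid(sys, grid, spec, noise_sigma = noise_sigma,
                       seed = seed + 100)
  list(sys = sys, grid = grid, spec = spec, td = td,
       peaks = peak_list(sys, grid),
       truth = r2eff_true(sys, 1, spec$nu, spec))
}

# draw a schedule guaranteed to cover every indirect coordinate (point-wise
# identifiability for shared-shape decomposition oracles)
covered_schedule <- function(grid, n_planes, frac, seed) {
  generate_schedule(grid, n_planes, frac, seed = seed, ensure_coverage = TRUE)
}
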