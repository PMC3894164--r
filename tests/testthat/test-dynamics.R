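test_that("integrator configuration validates cadences", {
  cfg <- bd_config()
  expect_equal(cfg$dt_ps, 0.125)
  expect_equal(unname(cfg$steps[c("list", "medium", "tensor", "snapshot",
                                  "check")]),
               c(48, 8, 192, 800, 48))
  expect_error(bd_config(timestep_fs = 125, list_interval_ps = 6.0001),
               "integer multiples")
})

test_that("identical seeds give bitwise-identical trajectories", {
  top <- mk_chain_top(random_chain_xyz(12, 3),
                      mk_beads(12, charge = rep(c(1, -1, 0), 4)))
  cfg <- bd_config()
  a <- run_dynamics(top, ff0, cfg, duration_ns = 0.5, seed = 42,
                    monitors = FALSE, store_coords = TRUE)
  b <- run_dynamics(top, ff0, cfg, duration_ns = 0.5, seed = 42,
                    monitors = FALSE, store_coords = TRUE)
  c3 <- run_dynamics(top, ff0, cfg, duration_ns = 0.5, seed = 43,
                     monitors = FALSE)
  expect_identical(a$final, b$final)
  expect_identical(a$frames, b$frames)
  expect_false(isTRUE(all.equal(a$final, c3$final)))
})

test_that("free-draining mobilities follow Stokes-Einstein", {
  D <- diffusion_model(radii = 5.3, mode = "free-draining")$D
  kB <- 1.380649e-23
  want <- kB * 298 / (6 * pi * 8.9e-4 * 5.3e-10) * 1e8  # A^2/ps
  expect_equal(D, want, tolerance = 1e-12)
  # nucleotide beads diffuse faster
  expect_gt(diffusion_model(radii = 3.5, mode = "free-draining")$D, D)
})

test_that("the pairwise mobility tensor is SPD and decouples at range", {
  xyz <- gophos:::with_seed_(5, matrix(rnorm(60, sd = 12), 20, 3))
  dm <- diffusion_model(xyz, radii = rep(5.3, 20), mode = "tensor")
  expect_true(isSymmetric(dm$tensor, tol = 1e-12))
  expect_gt(min(eigen(dm$tensor, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  # two infinitely separated beads: off-diagonal blocks vanish
  far <- diffusion_model(rbind(c(0, 0, 0), c(1e6, 0, 0)),
                         radii = c(5.3, 5.3), mode = "tensor")
  D0 <- diffusion_model(radii = 5.3, mode = "free-draining")$D
  expect_equal(unname(diag(far$tensor)), rep(D0, 6), tolerance = 1e-5)
  expect_lt(max(abs(far$tensor[1:3, 4:6])), 1e-5 * D0)
})

test_that("noise factors reproduce the target covariance", {
  xyz <- gophos:::with_seed_(6, matrix(rnorm(24, sd = 8), 8, 3))
  D <- diffusion_model(xyz, radii = rep(5.3, 8), mode = "tensor")$tensor
  B <- gophos:::noise_factor(D, "cholesky")
  expect_equal(B %*% t(B), D, tolerance = 1e-10, ignore_attr = TRUE)
  # truncated expansion: marginal variances are matched exactly
  Bt <- gophos:::noise_factor(D, "tea")
  expect_equal(diag(Bt %*% t(Bt)), diag(D), tolerance = 1e-10)
})

test_that("tensor-mode propagation runs and is seeded", {
  top <- mk_chain_top(random_chain_xyz(6, 8))
  cfg <- bd_config(hydrodynamics = "tensor")
  a <- run_dynamics(top, ff0, cfg, duration_ns = 0.05, seed = 9,
                    monitors = FALSE)
  b <- run_dynamics(top, ff0, cfg, duration_ns = 0.05, seed = 9,
                    monitors = FALSE)
  expect_identical(a$final, b$final)
  cfg2 <- bd_config(hydrodynamics = "tensor", noise_scheme = "tea")
  expect_silent(run_dynamics(top, ff0, cfg2, duration_ns = 0.02, seed = 9,
                             monitors = FALSE))
})

test_that("a max-time terminator stops exactly on time", {
  top <- cg_topology(matrix(0, 1, 3), mk_beads(1))
  r <- run_dynamics(top, ff0, bd_config(), duration_ns = 1, seed = 1,
                    monitors = FALSE)
  expect_equal(r$termination$reason, "max-time")
  expect_equal(r$termination$time_ns, 1)
})

test_that("bond-length sampling matches the Boltzmann density (small step)", {
  # first-order Brownian integration carries an O(dt) stationary bias on the
  # stiffest term, so the distribution check runs in the small-step regime
  top <- mk_chain_top(cbind(c(0, 3.8), 0, 0))
  cfg <- bd_config(timestep_fs = 5, list_interval_ps = 6,
                   snapshot_interval_ps = 1)
  r <- run_dynamics(top, ff0, cfg, duration_ns = 2.4, seed = 31,
                    monitors = FALSE, store_coords = TRUE)
  rs <- vapply(r$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)),
               numeric(1))
  rs <- rs[-(1:400)]                       # burn-in
  beta <- 1 / ff0$kBT
  dens <- function(x) x^2 * exp(-beta * 20 * (x - 3.8)^2)
  grid <- seq(2.8, 4.8, length.out = 4001)
  cdf_tab <- cumsum(dens(grid)); cdf_tab <- cdf_tab / cdf_tab[length(cdf_tab)]
  cdf <- approxfun(grid, cdf_tab, yleft = 0, yright = 1)
  ks <- suppressWarnings(stats::ks.test(rs, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("harmonic test systems satisfy equipartition (small step)", {
  top <- mk_chain_top(cbind(c(0, 3.8), 0, 0))
  cfg <- bd_config(timestep_fs = 10, snapshot_interval_ps = 1)
  r <- run_dynamics(top, ff0, cfg, duration_ns = 3, seed = 77,
                    monitors = FALSE, store_coords = TRUE)
  rs <- vapply(r$frames, function(f) sqrt(sum((f[1, ] - f[2, ])^2)),
               numeric(1))[-(1:300)]
  eb <- mean(20 * (rs - 3.8)^2)
  # one quadratic degree of freedom -> kBT/2, within Monte-Carlo error
  expect_equal(eb, ff0$kBT / 2, tolerance = 0.12)
})

test_that("soft walls contain TM and compartment beads", {
  spec <- toy_dimer_spec(tethers = list(A = 10, B = 10), seed = 4)
  top <- make_toy_dimer(spec)
  r <- run_dynamics(strip_psite_attractions(top), ff0, cfg_toy(),
                    duration_ns = 3, seed = 2, monitors = FALSE,
                    store_coords = TRUE)
  for (f in r$frames) {
    expect_true(all(abs(f[top$beads$is_tm, 3]) <= 16.5 + 3))
    ec <- top$beads$side == 1L & !top$beads$is_tm
    expect_true(all(f[ec, 3] >= 16.5 - 3))
  }
})

test_that("runaway displacements raise an instability error when uncapped", {
  top <- cg_topology(rbind(c(0, 0, 0), c(60, 0, 0)),
                     rbind(mk_beads(1, "A"), mk_beads(1, "B")),
                     bonds = data.frame(i = 1, j = 2, r_eq = 3.8))
  cfg <- bd_config(max_step_A = Inf)
  expect_error(run_dynamics(top, ff0, cfg, duration_ns = 0.01, seed = 1,
                            monitors = FALSE),
               "instability")
  # with the default clamp the same start relaxes instead
  r <- run_dynamics(top, ff0, bd_config(), duration_ns = 0.05, seed = 1,
                    monitors = FALSE)
  expect_gt(r$n_capped, 0)
  expect_lt(abs(sqrt(sum((r$final[1, ] - r$final[2, ])^2)) - 3.8), 1)
})
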