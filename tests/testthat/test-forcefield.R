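test_that("harmonic and dihedral constants act as written", {
  top <- mk_chain_top(cbind(c(0, 3.8), 0, 0))
  co <- top$coords; co[2, 1] <- 4.8
  expect_equal(bonded_energy(top, ff0, co)$energy, 20)   # +1 A -> k_bond
  expect_equal(bonded_energy(top, ff0)$energy, 0)
  expect_equal(max(abs(bonded_energy(top, ff0)$forces)), 0)
  # angle displaced by 0.3 rad -> k_angle * 0.3^2
  ta <- mk_chain_top(rbind(c(3.8, 0, 0), c(0, 0, 0), c(0, 3.8, 0)))
  ta$angles$theta_eq <- pi / 2 - 0.3
  expect_equal(bonded_energy(ta, ff0)$energy, 10 * 0.09, tolerance = 1e-12)
  # dihedral minimum at the native angle, maxima height V1 + V3
  td <- mk_chain_top(random_chain_xyz(4, 5))
  expect_equal(bonded_energy(td, ff0)$energy, 0, tolerance = 1e-12)
})

test_that("the contact well has its minimum -epsilon at sigma and decays", {
  mk2 <- function(r, sigma = 6, form = "12-10-6") {
    top <- cg_topology(rbind(c(0, 0, 0), c(r, 0, 0)),
                       rbind(mk_beads(1, "A"), mk_beads(1, "B")),
                       contacts = data.frame(i = 1, j = 2, sigma = sigma,
                                             eps = 0.6, tag = "fold",
                                             active = TRUE))
    ff <- go_forcefield(contact_form = form)
    contact_energy(top, ff)
  }
  expect_equal(mk2(6)$energy, -0.6)
  expect_lt(abs(mk2(60)$energy), 1e-5)
  # zero slope at the minimum (finite-difference derivative)
  h <- 1e-6
  expect_lt(abs((mk2(6 + h)$energy - mk2(6 - h)$energy) / (2 * h)), 1e-6)
  # the alternative 12-10 form shares minimum and depth
  expect_equal(mk2(6, form = "12-10")$energy, -0.6)
  expect_lt(abs((mk2(6 + h, form = "12-10")$energy -
                 mk2(6 - h, form = "12-10")$energy) / (2 * h)), 1e-6)
})

test_that("generic repulsion takes its printed value and is monotone", {
  mk2 <- function(r) {
    top <- cg_topology(rbind(c(0, 0, 0), c(r, 0, 0)),
                       rbind(mk_beads(1, "A"), mk_beads(1, "B")))
    repulsive_energy(top, ff0)$energy
  }
  expect_equal(mk2(4), 0.6)
  expect_equal(mk2(8), 0.6 / 4096)
  grid <- seq(3, 12, by = 0.5)
  vals <- vapply(grid, mk2, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0))
})

test_that("screened electrostatics matches the scalar formula with no cutoff", {
  lam <- ff0$lambda_debye
  expect_equal(lam, 7.85, tolerance = 0.01)
  gophos:::with_seed_(11, {
    for (k in 1:100) {
      r <- runif(1, 3, 120)
      q <- sample(c(-1, 1, 2, -4 / 3), 2, replace = TRUE)
      top <- cg_topology(rbind(c(0, 0, 0), c(r, 0, 0)),
                         rbind(mk_beads(1, "A", charge = q[1]),
                               mk_beads(1, "B", charge = q[2])))
      want <- 332.0637 * q[1] * q[2] * exp(-r / lam) / (78.4 * r)
      expect_equal(electrostatic_energy(top, ff0)$energy, want,
                   tolerance = 1e-12)
    }
  })
  # zero charge -> zero energy
  top0 <- cg_topology(rbind(c(0, 0, 0), c(5, 0, 0)),
                      rbind(mk_beads(1, "A", charge = 0),
                            mk_beads(1, "B", charge = 1)))
  expect_equal(electrostatic_energy(top0, ff0)$energy, 0)
  # vanishing ionic strength recovers the bare Coulomb law
  ffc <- go_forcefield(ionic_strength = 1e-12)
  topc <- cg_topology(rbind(c(0, 0, 0), c(10, 0, 0)),
                      rbind(mk_beads(1, "A", charge = 1),
                            mk_beads(1, "B", charge = 1)))
  expect_equal(electrostatic_energy(topc, ffc)$energy,
               332.0637 / (78.4 * 10), tolerance = 1e-5)
})

test_that("membrane terms restrain TM beads and wall off the slab", {
  wall <- cg_topology(matrix(c(0, 0, 20), 1), mk_beads(1, side = 1L))
  expect_equal(membrane_energy(wall, ff0)$energy, 0)
  expect_equal(membrane_energy(wall, ff0, matrix(c(0, 0, 15.5), 1))$energy,
               5.0)
  tm <- cg_topology(matrix(0, 1, 3), mk_beads(1, is_tm = TRUE, z0 = 0))
  expect_equal(membrane_energy(tm, ff0, matrix(c(0, 0, 2), 1))$energy, 20)
  # intracellular bead above the lower wall is pushed back
  ic <- cg_topology(matrix(c(0, 0, -20), 1), mk_beads(1, side = -1L))
  expect_equal(membrane_energy(ic, ff0)$energy, 0)
  expect_equal(membrane_energy(ic, ff0, matrix(c(0, 0, -15), 1))$energy,
               5.0 * 1.5^2)
})

test_that("every term's force is the exact negative gradient", {
  funs <- list(bonded_energy, contact_energy, repulsive_energy,
               electrostatic_energy, membrane_energy, total_energy)
  for (k in 1:20) {
    xyz <- random_chain_xyz(6, 100 + k)
    beads <- mk_beads(6, charge = c(1, 0, -1, 0, 1, -4 / 3),
                      side = c(0L, 1L, -1L, 0L, 0L, 0L),
                      is_tm = c(TRUE, rep(FALSE, 5)),
                      z0 = c(0.4, rep(NA_real_, 5)))
    top <- mk_chain_top(xyz, beads,
                        contacts = data.frame(i = c(1, 2), j = c(4, 6),
                                              sigma = c(6, 5), eps = 0.6,
                                              tag = "fold", active = TRUE))
    for (fun in funs) {
      res <- fun(top, ff0)
      num <- fd_forces(fun, top, ff0, top$coords)
      scale <- max(1, max(abs(res$forces)))
      expect_lt(max(abs(num - res$forces)) / scale, 1e-5)
    }
  }
})

test_that("net force vanishes for all terms except the membrane restraints", {
  xyz <- random_chain_xyz(8, 77)
  beads <- mk_beads(8, charge = rep(c(1, -1), 4))
  top <- mk_chain_top(xyz, beads,
                      contacts = data.frame(i = 1, j = 5, sigma = 6,
                                            eps = 0.6, tag = "fold",
                                            active = TRUE))
  for (fun in list(bonded_energy, contact_energy, repulsive_energy,
                   electrostatic_energy))
    expect_lt(max(abs(colSums(fun(top, ff0)$forces))), 1e-9)
})

test_that("the energy breakdown sums to the total", {
  spec <- toy_dimer_spec(tethers = list(A = 10, B = 10), seed = 3)
  top <- make_toy_dimer(spec)
  res <- total_energy(top, ff0)
  expect_equal(sum(res$terms), res$energy, tolerance = 1e-10)
})

test_that("pair scheduling classifies by distance with unrestricted electrostatics", {
  mk2 <- function(r, q = c(0, 0)) {
    cg_topology(rbind(c(0, 0, 0), c(r, 0, 0)),
                rbind(mk_beads(1, "A", charge = q[1]),
                      mk_beads(1, "B", charge = q[2])))
  }
  s <- build_schedule(mk2(10), ff0)
  expect_equal(nrow(s$short), 1); expect_equal(nrow(s$medium), 0)
  s <- build_schedule(mk2(20), ff0)
  expect_equal(nrow(s$short), 0); expect_equal(nrow(s$medium), 1)
  s <- build_schedule(mk2(30), ff0)
  expect_equal(nrow(s$short) + nrow(s$medium) +
               nrow(s$electrostatic_far), 0)
  s <- build_schedule(mk2(30, c(1, -1)), ff0)
  expect_equal(nrow(s$electrostatic_far), 1)
})

test_that("schedule classification equals a brute-force distance scan", {
  n <- 50
  xyz <- gophos:::with_seed_(9, matrix(runif(3 * n, 0, 45), n, 3))
  beads <- mk_beads(n, charge = rep(c(1, 0), length.out = n))
  beads$chain <- rep(c("A", "B"), length.out = n)
  beads$resno <- rep(1:25, 2)
  top <- cg_topology(xyz, beads)
  s <- build_schedule(top, ff0)
  short <- NULL; med <- NULL; far <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (beads$chain[i] == beads$chain[j] &&
        abs(beads$resno[i] - beads$resno[j]) < 3) next
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (r <= 12.5) short <- rbind(short, c(i, j))
    else if (r < 25) med <- rbind(med, c(i, j))
    else if (beads$charge[i] != 0 && beads$charge[j] != 0)
      far <- rbind(far, c(i, j))
  }
  expect_equal(unname(s$short), unname(short))
  expect_equal(unname(s$medium), unname(med))
  expect_equal(unname(s$electrostatic_far), unname(far))
})

test_that("overlapping beads raise a singular-geometry error", {
  top <- cg_topology(rbind(c(0, 0, 0), c(1e-9, 0, 0)),
                     rbind(mk_beads(1, "A"), mk_beads(1, "B")))
  expect_error(repulsive_energy(top, ff0), "singular")
})

test_that("collinear angles are evaluated without NaN", {
  top <- mk_chain_top(cbind(3.8 * (1:3), 0, 0))
  res <- bonded_energy(top, ff0)
  expect_true(all(is.finite(res$forces)))
  expect_true(is.finite(res$energy))
})
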