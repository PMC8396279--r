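test_that("compiled forces reproduce the independent R pair-sum oracle", {
  fx <- make_mechanical_fixtures()
  # random 50-bead periodic cell, no bonds
  cell <- fx$random_cell$config
  ref <- r_reference_forces(cell)
  for (m in c("cell", "brute")) {
    got <- compute_forces(cell, method = m)
    expect_equal(got$epot, ref$epot, tolerance = 1e-12)
    expect_lt(max(abs(got$forces - ref$forces)), 1e-10)
  }
  # bonded + mixed-species hairy system with fluid
  cfg <- insert_fluid(build_hairy_particle(sigma_c = 4, f = 3, M = 4, L = 14,
                                           check_box = FALSE, seed = 21),
                      0.02, seed = 22)
  ref <- r_reference_forces(cfg)
  got <- compute_forces(cfg, method = "brute")
  expect_equal(got$epot, ref$epot, tolerance = 1e-12)
  expect_lt(max(abs(got$forces - ref$forces)), 1e-10)
})

test_that("cell-list forces equal the brute-force route exactly", {
  cfg <- insert_fluid(build_hairy_particle(sigma_c = 4, f = 10, M = 10, L = 30,
                                           seed = 31),
                      0.05, seed = 32)
  a <- compute_forces(cfg, method = "cell")
  b <- compute_forces(cfg, method = "brute")
  expect_true(a$used_cell)
  expect_equal(a$epot, b$epot, tolerance = 1e-14)
  expect_lt(max(abs(a$forces - b$forces)), 1e-12)
  # Newton's third law: net force (including reactions on frozen beads)
  expect_lt(max(abs(colSums(a$forces))), 1e-9)
})

test_that("mechanical fixtures hit their precomputed oracles", {
  fx <- make_mechanical_fixtures()
  for (name in c("dimer_rest", "repulsive_pair_beyond_cutoff",
                 "attractive_pair_at_cutoff")) {
    got <- compute_forces(fx[[name]]$config, method = "brute")
    expect_equal(got$epot, fx[[name]]$oracle$epot, tolerance = 1e-12,
                 info = name)
    expect_lt(max(abs(got$forces)), 1e-12)
  }
  inwell <- compute_forces(fx$attractive_pair_in_well$config, method = "brute")
  expect_equal(inwell$epot, fx$attractive_pair_in_well$oracle$epot,
               tolerance = 1e-12)
  expect_equal(max(abs(inwell$forces[1, ])),
               fx$attractive_pair_in_well$oracle$fmag, tolerance = 1e-10)
  expect_equal(compute_forces(fx$random_cell$config)$epot,
               fx$random_cell$oracle$epot, tolerance = 1e-12)
})

test_that("a quiescent system does not move", {
  fx <- make_mechanical_fixtures()
  cfg <- fx$dimer_rest$config  # at rest length, zero velocity, zero force
  out <- run_md(cfg, 100, ensemble = "nve", esample = 0)
  expect_equal(out$config$positions, cfg$positions, tolerance = 1e-14)
})

test_that("free bonded dimer oscillates at 2 sqrt(kss/m)", {
  # reduced mass m/2 against stiffness 2 kss: omega = 2 sqrt(kss) = 63.246
  tab <- make_interaction_table("M1", sigma_c = 4)
  L <- 20
  pos <- rbind(c(L / 2 - 0.515, L / 2, L / 2), c(L / 2 + 0.515, L / 2, L / 2))
  cfg <- hairyMD:::new_md_config(pos, matrix(0, 2, 3), c(2L, 2L), c(TRUE, TRUE),
                                 matrix(c(1L, 2L), 1, 2),
                                 hairyMD:::cubic_box(L), tab,
                                 spec = list(geometry = "sphere"))
  dt <- 5e-4
  out <- run_md(cfg, 4000, dt = dt, ensemble = "nve", esample = 0, fsample = 1,
                method = "brute")
  sep <- vapply(out$frames, function(f) f[2, 1] - f[1, 1], numeric(1))
  x <- sep - 1  # displacement from rest length
  tgrid <- seq_along(x) * dt
  ic <- which(diff(sign(x)) != 0)
  # interpolated zero-crossing times; half a period between crossings
  tc <- tgrid[ic] - x[ic] * dt / (x[ic + 1] - x[ic])
  omega <- pi * (length(tc) - 1) / (tc[length(tc)] - tc[1])
  expect_equal(omega, 2 * sqrt(1000), tolerance = 0.01)
})

test_that("NVE total energy is conserved", {
  # attractive fluid (M1a: P-P attractive) thermalised then run NVE
  cfg <- hairyMD:::new_md_config(
    matrix(0, 0, 3), matrix(0, 0, 3), integer(), logical(),
    matrix(integer(), 0, 2), hairyMD:::cubic_box(12),
    make_interaction_table("M1a", sigma_c = 4), spec = list(geometry = "sphere"))
  cfg <- insert_fluid(cfg, 0.05, seed = 55)
  warm <- run_md(cfg, 2000, ensemble = "nvt", T_star = 1, esample = 0)
  out <- run_md(warm$config, 10000, dt = 0.002, ensemble = "nve", esample = 100)
  etot <- out$series$epot + out$series$ekin
  expect_lt(max(abs(etot - etot[1])) / abs(etot[1]), 1e-4)
})

test_that("Nose-Hoover thermostat holds the target temperature", {
  cfg <- hairyMD:::new_md_config(
    matrix(0, 0, 3), matrix(0, 0, 3), integer(), logical(),
    matrix(integer(), 0, 2), hairyMD:::cubic_box(10),
    make_interaction_table("M1a", sigma_c = 4), spec = list(geometry = "sphere"))
  cfg <- insert_fluid(cfg, 0.2, seed = 77)
  out <- run_md(cfg, 30000, ensemble = "nvt", T_star = 1, esample = 50)
  keep <- out$series$step > 5000
  Tm <- mean(out$series$Tstar[keep])
  expect_equal(Tm, 1, tolerance = 0.02)
  # canonical temperature fluctuations: relative variance ~ 2/(3N), loose 3x
  relvar <- var(out$series$Tstar[keep]) / Tm^2
  nmob <- sum(cfg$mobile)
  expect_lt(relvar, 3 * 2 / (3 * nmob))
  expect_gt(relvar, (2 / (3 * nmob)) / 3)
})

test_that("frozen beads never move and instability is detected", {
  cfg <- insert_fluid(build_hairy_particle(sigma_c = 4, f = 5, M = 5, L = 30,
                                           seed = 91),
                      0.01, seed = 92)
  out <- run_md(cfg, 2000, ensemble = "nvt", fsample = 500, esample = 0)
  frozen <- which(!cfg$mobile)
  for (f in out$frames)
    expect_identical(f[frozen, ], cfg$positions[frozen, ])
  bad <- cfg
  bad$velocities[which(cfg$mobile)[1], 1] <- 1e4
  expect_error(run_md(bad, 10, ensemble = "nve"), "instability")
})

test_that("hard walls reflect specularly and exempt nothing they shouldn't", {
  tab <- make_interaction_table("M1", sigma_c = 4)
  # one fluid bead heading for the bottom wall, far from anything else
  pos <- matrix(c(3, 3, 2), 1, 3)
  vel <- matrix(c(0.3, 0, -2), 1, 3)
  cfg <- hairyMD:::new_md_config(pos, vel, 3L, TRUE, matrix(integer(), 0, 2),
                                 hairyMD:::slab_box(6, 6, 20), tab,
                                 spec = list(geometry = "flat"))
  out <- run_md(cfg, 1000, dt = 0.002, ensemble = "nve", esample = 0)
  v <- out$config$velocities[1, ]
  expect_equal(v[3], 2)          # z-velocity reversed by the wall
  expect_equal(v[1], 0.3)        # tangential velocity untouched
  expect_gte(out$config$positions[1, 3], 0.5)
  # slab NVE conserves energy to the bulk tolerance; specular reflection at
  # discrete steps injects O(dt) per wall collision, so a slightly smaller dt
  # buys back the hard-wall discretisation error
  slab <- hairyMD:::new_md_config(
    matrix(0, 0, 3), matrix(0, 0, 3), integer(), logical(),
    matrix(integer(), 0, 2), hairyMD:::slab_box(8, 8, 20),
    make_interaction_table("M1a", sigma_c = 4), spec = list(geometry = "flat"))
  slab <- insert_fluid(slab, 0.05, seed = 14)
  warm <- run_md(slab, 2000, ensemble = "nvt", esample = 0)
  out2 <- run_md(warm$config, 10000, dt = 0.001, ensemble = "nve", esample = 100)
  etot <- out2$series$epot + out2$series$ekin
  expect_lt(max(abs(etot - etot[1])) / abs(etot[1]), 1e-4)
})

test_that("protocols are deterministic and flag convergence honestly", {
  proto <- md_protocol(equilibration_steps = 2000, production_steps = 2000,
                       sample_interval = 500)
  mk <- function() insert_fluid(build_hairy_particle(sigma_c = 4, f = 5, M = 5,
                                                     L = 30, seed = 101),
                                0.01, seed = 102)
  t1 <- run_protocol(mk(), proto)
  t2 <- run_protocol(mk(), proto)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$prod_series, t2$prod_series)
  expect_equal(length(t1$frames), 4)
  expect_true(is.logical(t1$converged) || is.na(t1$converged))
  # zero production steps: valid, empty frame list
  t0 <- run_protocol(mk(), md_protocol(equilibration_steps = 1000,
                                       production_steps = 0))
  expect_identical(t0$frames, list())
  # sample interval must divide production
  expect_error(md_protocol(production_steps = 1000, sample_interval = 300),
               "divide")
})
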