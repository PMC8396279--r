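test_that("anchor layouts sit on the tethering sphere and respect spacing", {
  lay <- place_anchors(f = 20, sigma_c = 4, min_separation = 0.8, seed = 42)
  expect_equal(lay$sigma_cs, 2.5)
  expect_equal(sqrt(rowSums(lay$directions^2)), rep(1, 20), tolerance = 1e-12)
  pts <- lay$directions * lay$sigma_cs
  d <- as.matrix(dist(pts))
  expect_gte(min(d[upper.tri(d)]), 0.8)
  # deterministic under the same seed
  lay2 <- place_anchors(f = 20, sigma_c = 4, min_separation = 0.8, seed = 42)
  expect_identical(lay, lay2)
  # single anchor always possible
  expect_equal(nrow(place_anchors(1, 2, seed = 1)$directions), 1)
  # impossible packing errors out
  expect_error(place_anchors(f = 200, sigma_c = 2, min_separation = 1, seed = 1,
                             max_tries = 2000),
               "packing")
})

test_that("rigid chains are radial arithmetic progressions", {
  ch <- grow_chain(c(0, 0, 1), M = 10, mode = "rigid", sigma_c = 4)
  expect_equal(ch[, 3], 2.5 + 0:9)
  expect_equal(ch[, 1], rep(0, 10))
})

test_that("flexible growth keeps bond length and stays outside the core", {
  set.seed(5)
  ch <- grow_chain(c(1, 0, 0), M = 2, mode = "flexible", sigma_c = 4)
  expect_equal(sqrt(sum((ch[2, ] - ch[1, ])^2)), 1, tolerance = 1e-12)
  expect_gte(sqrt(sum(ch[2, ]^2)), 2.5)
  ch20 <- grow_chain(c(0, 1, 0), M = 20, mode = "flexible", sigma_c = 4)
  bl <- sqrt(rowSums((ch20[-1, ] - ch20[-20, ])^2))
  expect_equal(bl, rep(1, 19), tolerance = 1e-12)
  expect_true(all(sqrt(rowSums(ch20^2)) >= 2.5 - 1e-12))
})

test_that("hairy-particle builds have the right bookkeeping", {
  cfg <- build_hairy_particle(sigma_c = 4, f = 20, M = 20, L = 57, seed = 3)
  expect_equal(nrow(cfg$positions), 1 + 20 * 20)
  expect_equal(nrow(cfg$bonds), 20 * 19)
  expect_identical(cfg$species[1], 1L)
  expect_false(cfg$mobile[1])
  # anchors frozen at exactly sigma_cs from the core center
  anch <- cfg$positions[cfg$anchor_idx, ]
  r <- sqrt(rowSums(sweep(anch, 2, cfg$positions[1, ])^2))
  expect_equal(r, rep(2.5, 20), tolerance = 1e-12)
  expect_true(all(!cfg$mobile[cfg$anchor_idx]))
  # grafting density of the reference systems
  expect_equal(cfg$spec$rho_gr, 20 / (16 * pi), tolerance = 1e-12)
  # no overlapping pair at build time
  small <- build_hairy_particle(sigma_c = 4, f = 5, M = 5, L = 30, seed = 8)
  expect_gte(min_pair_gap(small), 0.9 - 1e-12)
  # deterministic
  expect_identical(build_hairy_particle(sigma_c = 4, f = 5, M = 5, L = 30, seed = 8),
                   small)
  # box check reports the violated inequality
  expect_error(build_hairy_particle(sigma_c = 4, f = 5, M = 20, L = 30),
               "box too small")
  # rigid variants freeze every ligand bead
  hedge <- build_hairy_particle(sigma_c = 4, f = 10, M = 5, variant = "M2",
                                L = 30, seed = 2)
  expect_true(all(!hedge$mobile))
})

test_that("flat brushes derive their area from the grafting density", {
  cfg <- build_flat_brush(f = 20, M = 10, rho_gr = 0.398, Lz = 40, seed = 4)
  expect_equal(cfg$box$L[1], sqrt(20 / 0.398), tolerance = 1e-12)
  expect_equal(nrow(cfg$positions), 200)
  # anchors frozen in contact with the wall
  expect_equal(cfg$positions[cfg$anchor_idx, 3], rep(0.5, 20))
  expect_true(all(!cfg$mobile[cfg$anchor_idx]))
  expect_identical(cfg$box$periodic, c(TRUE, TRUE, FALSE))
  # bare wall is a valid degenerate brush
  bare <- build_flat_brush(f = 0, M = 10, Lz = 40, seed = 1)
  expect_equal(nrow(bare$positions), 0)
})

test_that("fluid insertion hits round(rho0 V) and avoids overlaps", {
  cfg <- build_hairy_particle(sigma_c = 4, f = 5, M = 5, L = 20,
                              check_box = FALSE, seed = 6)
  cfg <- insert_fluid(cfg, 0.1, seed = 7)
  expect_equal(sum(cfg$species == 3), 800)  # 0.1 * 20^3
  expect_equal(cfg$spec$N_P, 800)
  # rho0 = 0 leaves the configuration untouched
  cfg0 <- build_hairy_particle(sigma_c = 4, f = 5, M = 5, L = 30, seed = 6)
  expect_equal(nrow(insert_fluid(cfg0, 0, seed = 1)$positions), 26)
  # tiny density rounds to a handful of particles
  cfg57 <- build_hairy_particle(sigma_c = 4, f = 5, M = 5, L = 57, seed = 6)
  expect_equal(insert_fluid(cfg57, 1e-4, seed = 1)$spec$N_P, round(1e-4 * 57^3))
  # overlap criterion holds against every bead
  sm <- build_hairy_particle(sigma_c = 4, f = 3, M = 3, L = 12,
                             check_box = FALSE, seed = 9)
  sm <- insert_fluid(sm, 0.05, seed = 10)
  expect_gte(min_pair_gap(sm), 0.9 - 1e-12)
  # deterministic
  sm2 <- insert_fluid(build_hairy_particle(sigma_c = 4, f = 3, M = 3, L = 12,
                                           check_box = FALSE, seed = 9),
                      0.05, seed = 10)
  expect_identical(sm, sm2)
})

test_that("grafting density matches the reference systems", {
  expect_equal(grafting_density(20, "sphere", sigma_c = 4), 0.398, tolerance = 1e-3)
  expect_equal(grafting_density(5, "sphere", sigma_c = 2),
               grafting_density(20, "sphere", sigma_c = 4))
  expect_equal(grafting_density(0, "sphere", sigma_c = 4), 0)
  expect_equal(grafting_density(20, "flat", area = 50.25),
               20 / 50.25)
  expect_error(grafting_density(5, "flat", area = 0), "area")
})

test_that("relaxed flexible chains keep the bond length near sigma", {
  # brush-only system: equilibrate briefly and check <b> within 2% of sigma
  cfg <- build_hairy_particle(sigma_c = 4, f = 5, M = 20, L = 50, seed = 12)
  out <- run_md(cfg, 5000, dt = 0.002, ensemble = "nvt", T_star = 1)
  pos <- out$config$positions
  b <- sqrt(rowSums((pos[out$config$bonds[, 1], ] - pos[out$config$bonds[, 2], ])^2))
  expect_equal(mean(b), 1, tolerance = 0.02)
})
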