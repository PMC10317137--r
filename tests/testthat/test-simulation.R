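test_that("pack_spheres respects hard geometric constraints", {
  cell <- cubic_cell(60)
  set.seed(1)
  sp <- pack_spheres(cell, protein_radius = 0, r_range = c(5, 5),
                     q_range = c(1, 1), max_consecutive_rejections = 100)
  expect_gte(length(sp), 1)
  centers <- t(vapply(sp, function(s) s$center, numeric(3)))
  abc <- c(60, 60, 60)
  if (nrow(centers) > 1) {
    for (i in seq_len(nrow(centers) - 1))
      for (j in (i + 1):nrow(centers)) {
        d <- centers[i, ] - centers[j, ]
        d <- d - round(d)
        expect_gte(sqrt(sum((d * abc)^2)), 10 - 1e-9)
      }
  }

  # protein region occupying everything leaves no room
  expect_error(pack_spheres(cell, protein_radius = 60), "whole cell")

  # spheres avoid the protein ball
  set.seed(2)
  sp2 <- pack_spheres(cell, protein_radius = 20, r_range = c(3, 6),
                      max_consecutive_rejections = 50)
  for (s in sp2) {
    d <- s$center - c(0.5, 0.5, 0.5)
    d <- d - round(d)
    expect_gte(sqrt(sum((d * abc)^2)), 20 + s$radius - 1e-9)
  }
})

test_that("default packed configuration lands in the expected count band", {
  # Monte-Carlo characterization at the scenario defaults (25% protein);
  # reference band is 20-60 spheres per seed
  counts <- vapply(1:25, function(s) {
    set.seed(s)
    cell <- cubic_cell(46)
    rp <- (3 * 0.25 * cell$volume / (4 * pi))^(1 / 3)
    length(pack_spheres(cell, protein_radius = rp))
  }, integer(1))
  expect_true(all(counts >= 20 & counts <= 60))
  expect_true(median(counts) >= 30 && median(counts) <= 50)
})

test_that("simulate_fobs composes components linearly", {
  cr <- small_crystal(seed = 17)
  ms <- generate_hkl(cr$cell, 4)
  comps <- crystal_components(cr, ms)

  cr0 <- cr; cr0$true_k <- rep(0, length(cr$true_k))
  obs0 <- simulate_fobs(cr0, ms, comps)
  expect_equal(obs0$f_obs, Mod(comps[[1]]$f), tolerance = 1e-12)

  # single sphere: amplitudes scale linearly with k (the sphere carries its
  # own smearing B, so no extra smearing is applied here)
  sp <- cr$spheres[[1]]; sp$occupancy <- 1
  f_sp <- sphere_structure_factors(sp, ms)
  cr1 <- cr
  cr1$spheres <- cr$spheres[1]
  cr1$true_k <- 2
  comps1 <- crystal_components(cr1, ms)
  obs1 <- simulate_fobs(cr1, ms, comps1)
  expect_equal(obs1$f_obs, Mod(comps1[[1]]$f + 2 * f_sp$f), tolerance = 1e-10)
})

test_that("closed loop: fit recovers the generating scales for every algorithm class", {
  cr <- small_crystal(seed = 23)
  ms <- generate_hkl(cr$cell, 3.2)
  comps <- crystal_components(cr, ms)
  obs <- simulate_fobs(cr, ms, comps)
  sh <- bin_shells(ms, n_shells = 4, min_per_shell = 30)
  set.seed(231)
  ki <- c(1, cr$true_k * 10^runif(length(cr$true_k), -1, 1))
  for (alg in c("2", "2h", "4")) {
    fit <- fit_driver(obs, comps, sh, alg, options = list(tol = 1e-8, k_init = ki))
    kr <- recovered_scales(fit, comps, sh)[-1]
    expect_equal(kr, cr$true_k, tolerance = 1e-6,
                 label = sprintf("algorithm %s recovery", alg))
  }
})

test_that("perturb_coordinates hits the target RMSD exactly and isotropically", {
  cr <- small_crystal(seed = 29)
  expect_identical(perturb_coordinates(cr$atoms, cr$cell, 0), cr$atoms)

  set.seed(5)
  pert <- perturb_coordinates(cr$atoms, cr$cell, 0.4)
  d <- sweep(pert$positions - cr$atoms$positions, 2,
             c(cr$cell$a, cr$cell$b, cr$cell$c), "*")
  expect_equal(sqrt(mean(rowSums(d^2))), 0.4, tolerance = 1e-6)

  # isotropy: mean displacement direction of many atoms is ~0
  big <- atom_set(matrix(runif(3e4), 1e4, 3), weights = 1)
  set.seed(6)
  pb <- perturb_coordinates(big, cr$cell, 1)
  db <- sweep(pb$positions - big$positions, 2,
              c(cr$cell$a, cr$cell$b, cr$cell$c), "*")
  expect_lt(max(abs(colMeans(db))), 0.05)
})

test_that("add_data_errors calibrates the injected noise to the target R", {
  cr <- small_crystal(seed = 31)
  ms <- generate_hkl(cr$cell, 4)
  obs <- simulate_fobs(cr, ms)
  expect_identical(add_data_errors(obs, 0), obs)

  set.seed(7)
  for (tr in c(0.05, 0.10, 0.25)) {
    noisy <- add_data_errors(obs, tr)
    expect_equal(r_factor(obs$f_obs, noisy$f_obs), tr, tolerance = 1e-4)
    expect_true(all(noisy$f_obs >= 0))
  }

  # independence: errors from two seeds are uncorrelated
  set.seed(8);  n1 <- add_data_errors(obs, 0.10)$f_obs - obs$f_obs
  set.seed(80); n2 <- add_data_errors(obs, 0.10)$f_obs - obs$f_obs
  expect_lt(abs(cor(n1, n2)), 0.1)
})

test_that("run_benchmark is deterministic given a seed", {
  cr <- small_crystal(seed = 37)
  b1 <- run_benchmark("error_free", n_trials = 2, algorithms = "4", seed = 7,
                      crystal = cr, d_min = 3.5, min_per_shell = 30)
  b2 <- run_benchmark("error_free", n_trials = 2, algorithms = "4", seed = 7,
                      crystal = cr, d_min = 3.5, min_per_shell = 30)
  expect_identical(b1$summary, b2$summary)
  expect_true(all(b1$summary$mean_r_initial >= b1$summary$mean_r))
})
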