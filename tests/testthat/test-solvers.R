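test_that("cross_v matches direct complex arithmetic", {
  cell <- cubic_cell(12)
  ms <- generate_hkl(cell, 6)
  n <- nrow(ms$hkl)
  c1 <- component("a", rep(complex(real = 1), n))
  c2 <- component("b", rep(complex(imaginary = 1), n))
  ct <- cross_v(list(c1, c2))
  expect_equal(ct$v[, 1, 2], rep(0, n))        # orthogonal phases
  c3 <- component("c", rep(complex(real = 2), n))
  expect_equal(cross_v(list(c3))$v[, 1, 1], rep(4, n))

  set.seed(4)
  f1 <- complex(real = rnorm(n), imaginary = rnorm(n))
  f2 <- complex(real = rnorm(n), imaginary = rnorm(n))
  ct2 <- cross_v(list(component("x", f1), component("y", f2)))
  oracle <- Re((f1 * Conj(f2) + Conj(f1) * f2) / 2)   # half-sum of conjugates
  expect_equal(ct2$v[, 1, 2], oracle, tolerance = 1e-14)
  expect_equal(ct2$v[, 2, 1], ct2$v[, 1, 2])
  expect_true(all(ct2$v[, 1, 1] >= 0))
})

test_that("ls_residual matches hand arithmetic and a brute-force oracle", {
  cell <- cubic_cell(12)
  ms <- miller_set(cbind(1L, 0L, 0L), cell)
  ct <- cross_v(list(component("a", complex(real = 1))))
  obs <- observed_data(i_obs = 4)
  expect_equal(ls_residual(1, ct, obs, 1L), 9)   # (4 - 1)^2
  expect_error(ls_residual(1, ct, obs, integer(0)), "empty")

  # random instance vs naive double loop
  set.seed(11)
  ms2 <- generate_hkl(cell, 4)
  comps <- random_components(ms2, 3, seed = 11)
  ct2 <- cross_v(comps)
  k <- c(0.7, 1.3, 0.4)
  obs2 <- observed_data(i_obs = runif(nrow(ms2$hkl), 0, 5))
  shell <- 3:17
  naive <- 0
  for (s in shell) {
    q <- 0
    for (a in 1:3) for (b in 1:3)
      q <- q + k[a] * k[b] * Re(comps[[a]]$f[s] * Conj(comps[[b]]$f[s]))
    naive <- naive + (obs2$i_obs[s] - q)^2
  }
  expect_equal(ls_residual(k, ct2, obs2, shell), naive, tolerance = 1e-12)

  # residual is invariant under a global sign flip of all scales
  expect_equal(ls_residual(-k, ct2, obs2, shell),
               ls_residual(k, ct2, obs2, shell), tolerance = 1e-12)

  # zero at the generating truth on error-free data
  obs_t <- obs_from_truth(comps, k)
  expect_lt(ls_residual(k, ct2, obs_t, shell), 1e-18)
})

test_that("gradient and Hessian match finite differences", {
  cell <- cubic_cell(12)
  ms <- generate_hkl(cell, 4)
  comps <- random_components(ms, 3, seed = 21)
  ct <- cross_v(comps)
  set.seed(22)
  obs <- observed_data(i_obs = runif(nrow(ms$hkl), 0, 5))
  shell <- seq_len(nrow(ms$hkl))
  k <- c(0.8, 0.3, 1.4)

  g <- ls_gradient(k, ct, obs, shell)
  g_fd <- vapply(1:3, function(p) {
    hstep <- 1e-6 * (1 + abs(k[p]))
    kp <- k; km <- k
    kp[p] <- kp[p] + hstep; km[p] <- km[p] - hstep
    (ls_residual(kp, ct, obs, shell) - ls_residual(km, ct, obs, shell)) / (2 * hstep)
  }, numeric(1))
  expect_equal(g, g_fd, tolerance = 1e-5)

  h <- ls_hessian(k, ct, obs, shell)
  h_fd <- vapply(1:3, function(p) {
    hstep <- 1e-6 * (1 + abs(k[p]))
    kp <- k; km <- k
    kp[p] <- kp[p] + hstep; km[p] <- km[p] - hstep
    (ls_gradient(kp, ct, obs, shell) - ls_gradient(km, ct, obs, shell)) / (2 * hstep)
  }, numeric(3))
  expect_equal(h, (h_fd + t(h_fd)) / 2, tolerance = 1e-4)
  expect_equal(h, t(h), tolerance = 1e-10)

  # gradient vanishes at the truth on error-free data
  obs_t <- obs_from_truth(comps, k)
  expect_lt(max(abs(ls_gradient(k, ct, obs_t, shell))), 1e-9)
})

test_that("algorithm 2 minimizes the quartic residual", {
  cell <- cubic_cell(12)
  ms <- generate_hkl(cell, 4)
  comps <- random_components(ms, 2, seed = 31)
  ct <- cross_v(comps)
  kt <- c(0.9, 0.55)
  obs <- obs_from_truth(comps, kt)
  shell <- seq_len(nrow(ms$hkl))

  # truth in -> truth out
  k0 <- solve_shell_alg2(ct, obs, shell, k_init = kt)
  expect_equal(as.numeric(k0), kt, tolerance = 1e-10)

  # perturbed start recovers the truth, with and without the Hessian
  set.seed(32)
  ki <- kt * 10^runif(2, -1, 1)
  for (uh in c(FALSE, TRUE)) {
    kk <- solve_shell_alg2(ct, obs, shell, k_init = ki, use_hessian = uh)
    expect_equal(as.numeric(kk), kt, tolerance = 1e-7)
    expect_lte(attr(kk, "residual"), ls_residual(ki, ct, obs, shell))
  }

  # dense grid-search oracle on a noisy 2-parameter instance
  set.seed(33)
  obs_n <- observed_data(f_obs = pmax(obs$f_obs + rnorm(length(obs$f_obs), sd = 0.2), 0))
  sub <- 1:25
  kg <- seq(0, 2, by = 1e-3)
  f1 <- comps[[1]]$f[sub]; f2 <- comps[[2]]$f[sub]
  v11 <- Re(f1 * Conj(f1)); v22 <- Re(f2 * Conj(f2)); v12 <- Re(f1 * Conj(f2))
  io <- obs_n$i_obs[sub]
  best <- c(NA, NA); bestval <- Inf
  for (k1 in kg) {
    q <- outer(io, rep(1, length(kg))) -
      (k1^2 * v11 %o% rep(1, length(kg)) + 2 * k1 * v12 %o% kg + v22 %o% kg^2)
    vals <- colSums(q^2)
    j <- which.min(vals)
    if (vals[j] < bestval) { bestval <- vals[j]; best <- c(k1, kg[j]) }
  }
  k_opt <- solve_shell_alg2(ct, obs_n, sub, k_init = best)
  expect_lt(max(abs(as.numeric(k_opt) - best)), 1.5e-3)  # within grid resolution
})

test_that("algorithm 3 solves products then recovers scales", {
  cell <- cubic_cell(12)
  ms <- generate_hkl(cell, 4)

  # N = 0 closed form
  comps1 <- random_components(ms, 1, seed = 41)
  ct1 <- cross_v(comps1)
  kt1 <- 1.37
  obs1 <- obs_from_truth(comps1, kt1)
  shell <- seq_len(nrow(ms$hkl))
  v00 <- ct1$v[, 1, 1]
  closed <- sqrt(sum(obs1$i_obs * v00) / sum(v00^2))
  expect_equal(as.numeric(solve_shell_alg3(ct1, obs1, shell)), closed, tolerance = 1e-10)
  expect_equal(closed, kt1, tolerance = 1e-10)

  # forward simulation: u = k k' recovered, then k
  comps <- random_components(ms, 3, seed = 42)
  ct <- cross_v(comps)
  kt <- c(1.1, 0.6, 0.85)
  obs <- obs_from_truth(comps, kt)
  k3 <- solve_shell_alg3(ct, obs, shell)
  expect_equal(attr(k3, "u"), outer(kt, kt), tolerance = 1e-8)
  expect_equal(as.numeric(k3), kt, tolerance = 1e-8)

  # exact product table fed to the log least-squares step alone
  u <- outer(kt, kt)
  k_rec <- mcsf:::recover_k_from_u(u, 3, integer(0), numeric(3))
  expect_equal(k_rec, kt, tolerance = 1e-12)
})

test_that("algorithm 4 solves the phased linear system", {
  cell <- cubic_cell(12)
  ms <- generate_hkl(cell, 4)
  comps <- random_components(ms, 3, seed = 51)
  ct <- cross_v(comps)
  kt <- c(1, 0.45, 0.8)
  obs <- obs_from_truth(comps, kt)
  shell <- seq_len(nrow(ms$hkl))

  # exact phases: one linear solve returns the exact truth
  fmat <- sapply(comps, function(cc) cc$f)
  phi <- Arg(fmat %*% kt)
  k_ph <- solve_shell_alg4(ct, obs, shell, k_init = c(1, 1, 1), phases = as.numeric(phi))
  expect_equal(as.numeric(k_ph), kt, tolerance = 1e-10)
  expect_equal(attr(k_ph, "iterations"), 1L)

  # fixed point: starting at the truth stays at the truth
  k_fp <- solve_shell_alg4(ct, obs, shell, k_init = kt, max_iter = 1, tol = 0)
  expect_equal(as.numeric(k_fp), kt, tolerance = 1e-9)

  # perturbed start recovers
  set.seed(52)
  k4 <- solve_shell_alg4(ct, obs, shell, k_init = kt * 10^runif(3, -1, 1))
  expect_equal(as.numeric(k4), kt, tolerance = 1e-6)

  # manufactured two-reflection instance vs a hand Cramer solve
  ms2 <- miller_set(rbind(c(1L, 0L, 0L), c(0L, 1L, 0L)), cell)
  g1 <- component("g1", c(2 + 0i, 1 + 1i))
  g2 <- component("g2", c(0 + 1i, 3 - 1i))
  ct2 <- cross_v(list(g1, g2))
  amp <- c(2.2, 3.1)
  phi2 <- c(0.3, -1.2)
  a_s <- complex(modulus = amp, argument = phi2)
  w <- c(sum(Re(a_s * Conj(g1$f))), sum(Re(a_s * Conj(g2$f))))
  m <- matrix(c(sum(Re(g1$f * Conj(g1$f))), sum(Re(g1$f * Conj(g2$f))),
                sum(Re(g2$f * Conj(g1$f))), sum(Re(g2$f * Conj(g2$f)))), 2, 2)
  hand <- c(m[2, 2] * w[1] - m[1, 2] * w[2], m[1, 1] * w[2] - m[2, 1] * w[1]) /
    (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  obs2 <- observed_data(f_obs = amp)
  k_cr <- solve_shell_alg4(ct2, obs2, 1:2, k_init = c(1, 1), phases = phi2)
  expect_equal(as.numeric(k_cr), hand, tolerance = 1e-12)
})

test_that("algorithm 1 fits sequentially and loses to algorithm 2 when correlated", {
  cell <- cubic_cell(12)
  ms <- generate_hkl(cell, 4)
  n <- nrow(ms$hkl)

  # orthogonal (disjoint-support) components: sequential fit is exact
  f1 <- complex(real = c(rnorm(n %/% 2), rep(0, n - n %/% 2)))
  f2 <- complex(real = c(rep(0, n %/% 2), rnorm(n - n %/% 2)))
  set.seed(61)
  comps <- list(component("a", f1), component("b", f2))
  ct <- cross_v(comps)
  kt <- c(0.8, 1.6)
  obs <- obs_from_truth(comps, kt)
  k1 <- solve_shell_alg1(ct, obs, seq_len(n))
  expect_equal(as.numeric(k1), kt, tolerance = 1e-6)

  # single free component vs 1-D grid search
  ctb <- cross_v(comps[1])
  obs_b <- observed_data(f_obs = Mod(f1) * 1.23 + 0.05)
  kg <- seq(0, 4, by = 1e-4)
  amp <- Mod(f1[1:(n %/% 2)])
  vals <- vapply(kg, function(kk) sum((obs_b$f_obs[1:(n %/% 2)] - kk * amp)^2), numeric(1))
  k_grid <- kg[which.min(vals)]
  k_seq <- solve_shell_alg1(ctb, obs_b, seq_len(n %/% 2))
  expect_lt(abs(as.numeric(k_seq) - k_grid), 1e-4)

  # strongly correlated components: greedy residual >= simultaneous residual
  base <- complex(real = rnorm(n), imaginary = rnorm(n))
  cc <- list(component("p", base), component("q", base + 0.1 * rnorm(n)))
  ctc <- cross_v(cc)
  obs_c <- obs_from_truth(cc, c(0.5, 1.2))
  ks <- solve_shell_alg1(ctc, obs_c, seq_len(n))
  k2 <- solve_shell_alg2(ctc, obs_c, seq_len(n), k_init = c(0.6, 1.0))
  amp_of <- function(k) Mod(sapply(cc, function(x) x$f) %*% as.numeric(k))
  res_amp <- function(k) sum((obs_c$f_obs - amp_of(k))^2)
  expect_gte(res_amp(ks) + 1e-12, res_amp(k2))
})

test_that("r_factor follows its definition", {
  expect_equal(r_factor(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(r_factor(c(1, 2, 3), c(0, 0, 0)), 1)
  expect_equal(r_factor(c(10, 10), c(9, 12)), 0.15)
})

test_that("algorithms 2, 3 and 4 agree on well-conditioned error-free instances", {
  cell <- cubic_cell(15)
  ms <- generate_hkl(cell, 5)
  set.seed(71)
  for (rep in 1:10) {
    p <- sample(2:4, 1)
    comps <- random_components(ms, p, seed = 700 + rep)
    ct <- cross_v(comps)
    kt <- runif(p, 0.2, 2)
    obs <- obs_from_truth(comps, kt)
    shell <- seq_len(nrow(ms$hkl))
    ki <- kt * 10^runif(p, -0.5, 0.5)
    k2 <- as.numeric(solve_shell_alg2(ct, obs, shell, k_init = ki))
    k3 <- as.numeric(solve_shell_alg3(ct, obs, shell))
    k4 <- as.numeric(solve_shell_alg4(ct, obs, shell, k_init = ki))
    expect_equal(k2, kt, tolerance = 1e-4)
    expect_equal(k3, kt, tolerance = 1e-4)
    expect_equal(k4, kt, tolerance = 1e-4)
  }
})
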