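# shared fixtures: everything is generated in code, no data files

cubic_cell <- function(a = 10) unit_cell(a, a, a)

# random aligned components on a miller set, reproducible via seed
random_components <- function(miller, p, seed = 1, scale = 1) {
  set.seed(seed)
  n <- nrow(miller$hkl)
  lapply(seq_len(p), function(j)
    component(paste0("c", j),
              complex(real = rnorm(n, sd = scale), imaginary = rnorm(n, sd = scale))))
}

# error-free observations generated from known scales
obs_from_truth <- function(components, k_true) {
  fmat <- vapply(components, function(cc) cc$f, complex(length(components[[1]]$f)))
  observed_data(f_obs = Mod(fmat %*% k_true))
}

# small synthetic crystal for closed-loop tests (cheap: ~1500 reflections)
small_crystal <- function(seed = 1) {
  synthetic_crystal("regions", seed = seed, cell_edge = 30, n_atoms = 150,
                    n_spheres = 4, sphere_r_range = c(2, 3.5))
}
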