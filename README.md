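# mcsf — multi-component structure-factor scaling

Crystallographic diffraction data measure the scattering of *everything*
in the unit cell. Atomic models account for the ordered part; bulk
solvent, disordered ligands, semi-ordered lipid layers and unmodelled
loops scatter too, and ignoring them biases refinement and maps. `mcsf`
implements a multi-component description of the total structure factor

    F_model(s) = k_overall(s) * ( k0 * F_0(s) + sum_n k_n(s) * F_n(s) )

in which the atomic contribution `F_0` is joined by N additional
components `F_n` (binary-mask regions, analytic spheres, Gaussian blobs,
or externally computed structure factors), each with its own per-
resolution-shell scale factor `k_n` — interpretable as an occupancy when
the components share a form factor. The package provides four per-shell
scale-search algorithms and the machinery to test them on synthetic
crystals:

1. **sequential** 1-D fits, one component at a time (cheap, greedy);
2. **simultaneous quartic least squares** on intensities, minimized by
   L-BFGS-B with analytic gradients, optionally polished by damped Newton
   steps with the analytic Hessian (`"2h"`);
3. **two-step analytic search** over products `u_nm = k_n k_m` (linear
   normal equations, then log-least-squares recovery of the scales) —
   exact but ill-conditioned beyond a few components;
4. **iterative phased search**: phases approximated by the current model
   turn the fit into a small linear system per iteration (the default).

It is aimed at methods developers and students of crystallographic
scaling: everything is plain R, self-contained, and backed by a synthetic
parameter-recovery suite (error-free data, coordinate errors at a
controlled RMSD, amplitude errors calibrated to a target R factor).

## Worked example

Simulate a small P1 crystal — a protein mimic occupying 25% of a 30 Å
cube plus four sphere components smeared with B = 50 Å² — then recover
the generating scales from the error-free amplitudes:

```r
library(mcsf)
cr  <- synthetic_crystal("regions", seed = 42, cell_edge = 30,
                         n_atoms = 200, n_spheres = 4,
                         sphere_r_range = c(2, 3.5))
ms  <- generate_hkl(cr$cell, d_min = 3)          # 2084 unique reflections
comps <- crystal_components(cr, ms)              # F_0 + 4 smeared spheres
obs <- simulate_fobs(cr, ms, comps)              # |F_total| as "data"
sh  <- bin_shells(ms, n_shells = 5, min_per_shell = 50)
fit <- fit_driver(obs, comps, sh, algorithm = "4", options = list(tol = 1e-8))
print(fit)
```

```
scale_set: 3 shells, algorithm 4, R = 0.0000 (converged, 17 outer iterations)
  shell   d_max  d_min n_refl k_overall k_atoms k_sphere01 k_sphere02
1     1 30.0000 7.5357    125         1       1    0.18845    0.10874
2     2  7.5357 4.7547    385         1       1    0.18845    0.10874
3     3  4.7547 3.0000   1574         1       1    0.18845    0.10874
  k_sphere03 k_sphere04    r_shell
1    0.74381    0.11508 7.5457e-10
2    0.74381    0.11508 1.7303e-11
3    0.74381    0.11508 1.5433e-13
```

Five shells were requested; the two sparse low-resolution ones were merged
into their neighbours (`min_per_shell = 50`). Each row reports the shell's
d-range, reflection count, overall scale, per-component scales and
amplitude R factor; `R = 0.0000` and per-shell `r_shell ~ 1e-10` say the
model reproduces the data to numerical precision. Pooling the per-shell
scales (weighted median across shells) and comparing with the truth:

```r
k_hat <- recovered_scales(fit, comps, sh)
round(rbind(truth = c(1, cr$true_k), recovered = k_hat), 6)
```

```
          [,1]     [,2]     [,3]     [,4]     [,5]
truth        1 0.188449 0.108742 0.743815 0.115077
recovered    1 0.188449 0.108742 0.743815 0.115077
```

All four sphere occupancies are recovered to ~1e-9 relative error, the
behaviour the error-free acceptance benchmark checks at scale (50 trials,
~10⁴ reflections, 7 components, starts perturbed by factors in [0.1, 10]).

## Command line

```sh
Rscript -e 'mcsf::mcsf_cli()' simulate --scenario regions --seed 1 --out sim
Rscript -e 'mcsf::mcsf_cli()' fit --input sim.refl --algorithm 4 --out fit.tsv
Rscript -e 'mcsf::mcsf_cli()' benchmark --scenario coord_error \
    --doses 0,0.2,0.4 --trials 50 --algorithms 2h,4 --seed 1 --out bench.tsv
```

`simulate` writes a columnar reflection file (`h k l f_obs i_obs
re_<id> im_<id> ...`, cell and component ids in `#` headers) plus a JSON
truth sidecar; `fit` writes the per-shell scale table and a JSON run log
(algorithm, iterations, condition numbers, convergence flags);
`benchmark` writes a tab-separated summary. An adapter for mmCIF
reflection loops (`read_mmcif_reflections()`) imports cell and amplitude
columns.

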