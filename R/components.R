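#' Scattering components
#'
#' A component is one independently scaled part of the unit-cell content —
#' the ordered atomic model, a solvent sub-region, a disordered ligand blob —
#' represented by its complex structure factors aligned to a Miller set.
#'
#' @param id Character label.
#' @param f Complex vector, one structure factor per reflection.
#' @param kind One of `"sphere"`, `"atoms"`, `"mask"`, `"external"`.
#' @return An object of class `component`.
#' @export
component <- function(id, f, kind = "external") {
  kind <- match.arg(kind, c("sphere", "atoms", "mask", "external"))
  f <- as.complex(f)
  if (any(!is.finite(Re(f)) | !is.finite(Im(f))))
    stop("component structure factors must be finite")
  structure(list(id = as.character(id), f = f, kind = kind), class = "component")
}

#' @export
print.component <- function(x, ...) {
  cat(sprintf("component '%s' (%s): %d reflections, mean |F| = %.6g\n",
              x$id, x$kind, length(x$f), mean(Mod(x$f))))
  invisible(x)
}

#' Define a smeared sphere scatterer
#'
#' @param center Fractional coordinates (length 3).
#' @param radius Sphere radius in Angstrom (> 0).
#' @param occupancy Dimensionless scale q multiplying the density.
#' @param B Smearing B factor in Angstrom^2 (>= 0) softening the boundary.
#' @return An object of class `sphere`.
#' @export
sphere <- function(center, radius, occupancy = 1, B = 0) {
  stopifnot(length(center) == 3, radius > 0, B >= 0)
  structure(list(center = as.numeric(center), radius = radius,
                 occupancy = occupancy, B = B), class = "sphere")
}

# Sphere shape transform: Phi(x) = 3 (sin x - x cos x) / x^3, Phi(0) = 1.
# Series below 1e-2 avoids catastrophic cancellation near x = 0.
sphere_phi <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' Analytic structure factors of a smeared sphere
#'
#' For a uniform sphere of radius R, occupancy q and Gaussian smearing B
#' centred at fractional position x0:
#' f(s) = q (4/3) pi R^3 Phi(2 pi s R) exp(-B s^2 / 4) exp(2 pi i h.x0),
#' with Phi(x) = 3 (sin x - x cos x) / x^3 and Phi(0) = 1.
#'
#' @param sph A [sphere()].
#' @param miller A [miller_set()].
#' @return A [component()] of kind `"sphere"`.
#' @export
sphere_structure_factors <- function(sph, miller) {
  stopifnot(inherits(sph, "sphere"), inherits(miller, "miller_set"))
  s <- miller$s
  vol <- 4 / 3 * pi * sph$radius^3
  amp <- sph$occupancy * vol * sphere_phi(2 * pi * s * sph$radius) *
    exp(-sph$B * s^2 / 4)
  phase <- 2 * pi * as.numeric(miller$hkl %*% sph$center)
  component(id = sprintf("sphere_r%.3g", sph$radius),
            f = amp * complex(modulus = 1, argument = phase),
            kind = "sphere")
}

#' Define a set of Gaussian point atoms
#'
#' Single-Gaussian atoms standing in for a full atomic model: each atom j
#' has scattering weight w_j and isotropic width B_j.
#'
#' @param positions n x 3 matrix of fractional coordinates.
#' @param weights Scattering amplitudes, one per atom (> 0).
#' @param widths Per-atom Gaussian B in Angstrom^2 (>= 0); recycled.
#' @return An object of class `atom_set`.
#' @export
atom_set <- function(positions, weights, widths = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) >= 1)
  n <- nrow(positions)
  weights <- rep_len(as.numeric(weights), n)
  widths <- rep_len(as.numeric(widths), n)
  stopifnot(all(weights > 0), all(widths >= 0))
  structure(list(positions = positions, weights = weights, widths = widths),
            class = "atom_set")
}

#' Structure factors of Gaussian point atoms by direct summation
#'
#' f(s) = sum_j w_j exp(-B_j s^2 / 4) exp(2 pi i h.x_j)
#'
#' @param atoms An [atom_set()].
#' @param miller A [miller_set()].
#' @return A [component()] of kind `"atoms"`.
#' @export
atom_structure_factors <- function(atoms, miller) {
  stopifnot(inherits(atoms, "atom_set"), inherits(miller, "miller_set"))
  phase <- 2 * pi * (miller$hkl %*% t(atoms$positions))   # n_refl x n_atoms
  damp <- exp(outer(miller$s^2, atoms$widths) / -4)
  wre <- damp * cos(phase)
  wim <- damp * sin(phase)
  f <- complex(real = as.numeric(wre %*% atoms$weights),
               imaginary = as.numeric(wim %*% atoms$weights))
  component(id = "atoms", f = f, kind = "atoms")
}

#' Define a binary grid mask over the unit cell
#'
#' @param values Logical or 0/1 numeric 3-d array (dimensions = grid points
#'   along a, b, c).
#' @param cell A [unit_cell()].
#' @return An object of class `grid_mask`.
#' @export
grid_mask <- function(values, cell) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3, inherits(cell, "unit_cell"))
  if (!all(values %in% c(0, 1)))
    stop("grid mask values must be 0 or 1")
  structure(list(values = values, dim = dim(values), cell = cell),
            class = "grid_mask")
}

#' Structure factors of a binary grid mask
#'
#' Discrete Fourier transform of the mask scaled by V_cell / N_gridpoints,
#' sampled at the Miller indices. Requires the grid to oversample the
#' resolution limit: d_min >= 2 x (largest grid spacing).
#'
#' @param mask A [grid_mask()].
#' @param miller A [miller_set()].
#' @return A [component()] of kind `"mask"`.
#' @export
mask_structure_factors <- function(mask, miller) {
  stopifnot(inherits(mask, "grid_mask"), inherits(miller, "miller_set"))
  dims <- mask$dim
  spacing <- c(mask$cell$a, mask$cell$b, mask$cell$c) / dims
  d_min <- min(miller$d)
  if (d_min < 2 * max(spacing) - 1e-9)
    stop(sprintf(
      "grid too coarse: d_min = %.4g A needs grid spacing <= %.4g A (have %.4g); use a grid of at least %d x %d x %d",
      d_min, d_min / 2, max(spacing),
      ceiling(2 * mask$cell$a / d_min), ceiling(2 * mask$cell$b / d_min),
      ceiling(2 * mask$cell$c / d_min)))
  # unnormalized inverse DFT realizes the exp(+2 pi i h.x) convention
  ft <- stats::fft(mask$values, inverse = TRUE) * mask$cell$volume / prod(dims)
  idx <- sweep(miller$hkl %% matrix(dims, nrow(miller$hkl), 3, byrow = TRUE), 2, c(1L, 1L, 1L), "+")
  f <- ft[idx]
  component(id = "mask", f = f, kind = "mask")
}

#' Apply exponential resolution-dependent smearing to a component
#'
#' Multiplies each structure factor by exp(-B s^2 / 4); used to soften the
#' sharp boundary of a binary mask, as in the flat bulk-solvent model.
#'
#' @param comp A [component()].
#' @param miller The aligned [miller_set()].
#' @param B Smearing B factor in Angstrom^2 (>= 0).
#' @return A new [component()].
#' @export
apply_smearing <- function(comp, miller, B) {
  stopifnot(inherits(comp, "component"), inherits(miller, "miller_set"), B >= 0)
  if (length(comp$f) != n_reflections(miller))
    stop("component not aligned to miller set")
  component(comp$id, comp$f * exp(-B * miller$s^2 / 4), comp$kind)
}

# Stack a list of components into an n_refl x P complex matrix (P = N + 1
# when the atomic part is first). Errors on misaligned lengths.
component_matrix <- function(components, n_refl = NULL) {
  stopifnot(length(components) >= 1)
  lens <- vapply(components, function(cc) length(cc$f), integer(1))
  if (length(unique(lens)) != 1L)
    stop("components are not aligned to a single miller set")
  if (!is.null(n_refl) && lens[1] != n_refl)
    stop("components are not aligned to the miller set")
  fmat <- vapply(components, function(cc) cc$f, complex(lens[1]))
  if (is.null(dim(fmat))) fmat <- matrix(fmat, nrow = lens[1])
  colnames(fmat) <- vapply(components, function(cc) cc$id, character(1))
  fmat
}
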