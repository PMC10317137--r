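#' Create a P1 unit cell
#'
#' A triclinic unit cell described by edge lengths and inter-axial angles.
#' The direct metric tensor must be positive definite; its inverse (the
#' reciprocal metric tensor) is precomputed and used for all resolution
#' calculations.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Inter-axial angles in degrees, each in (0, 180).
#'   `alpha` is the angle between b and c, `beta` between a and c, `gamma`
#'   between a and b.
#' @return An object of class `unit_cell` with fields `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, the direct metric tensor `g`, the reciprocal
#'   metric tensor `g_star` and the cell `volume` in cubic Angstrom.
#' @examples
#' cell <- unit_cell(60, 60, 60)
#' cell$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c))
  if (!all(c(a, b, c) > 0))
    stop("unit cell lengths must be positive")
  if (!all(c(alpha, beta, gamma) > 0 & c(alpha, beta, gamma) < 180))
    stop("unit cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180)
  cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180)
  g <- matrix(c(
    a * a,      a * b * cg, a * c * cb,
    a * b * cg, b * b,      b * c * ca,
    a * c * cb, b * c * ca, c * c
  ), 3, 3, byrow = TRUE)
  detg <- det(g)
  if (!is.finite(detg) || detg <= 0)
    stop("unit cell metric tensor is not positive definite")
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         g = g, g_star = solve(g), volume = sqrt(detg)),
    class = "unit_cell"
  )
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("P1 unit cell: a=%.4g b=%.4g c=%.4g  alpha=%.4g beta=%.4g gamma=%.4g  V=%.6g A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Reciprocal-space magnitude of reflections
#'
#' Computes |s| = 1/d for one or more Miller indices via the reciprocal
#' metric tensor: s^2 = h' G* h. For an orthorhombic cell this reduces to
#' sqrt((h/a)^2 + (k/b)^2 + (l/c)^2).
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer vector of length 3, or an n x 3 matrix of Miller
#'   indices (one row per reflection).
#' @return Numeric vector of |s| values in 1/Angstrom.
#' @examples
#' s_magnitude(unit_cell(10, 10, 10), c(1, 0, 0))  # 0.1
#' @export
s_magnitude <- function(cell, hkl) {
  stopifnot(inherits(cell, "unit_cell"))
  h <- as_hkl_matrix(hkl)
  if (any(rowSums(h != 0L) == 0))
    stop("resolution of (0,0,0) is undefined")
  sqrt(rowSums((h %*% cell$g_star) * h))
}

as_hkl_matrix <- function(hkl) {
  if (is.matrix(hkl)) {
    if (ncol(hkl) != 3L) stop("hkl matrix must have three columns")
    storage.mode(hkl) <- "double"
    hkl
  } else {
    if (length(hkl) != 3L) stop("hkl must have three elements")
    matrix(as.numeric(hkl), 1L, 3L)
  }
}
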