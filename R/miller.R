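#' Enumerate the unique half-set of reflections to a resolution limit
#'
#' Generates every Miller index triple with resolution d >= `d_min` for a P1
#' cell, keeping one member per Friedel pair and excluding (0,0,0). The
#' half-set convention keeps (h,k,l) when h > 0, or h = 0 and k > 0, or
#' h = k = 0 and l > 0. Output is ordered lexicographically on (h, k, l).
#'
#' @param cell A [unit_cell()].
#' @param d_min High-resolution cutoff in Angstrom (smallest d kept).
#' @param max_reflections Safety cap on the enumeration volume; exceeding it
#'   raises an error rather than exhausting memory.
#' @return An object of class `miller_set`: a list with integer matrix `hkl`
#'   (n x 3), numeric vectors `s` (1/d, 1/Angstrom) and `d` (Angstrom), and
#'   the `cell`.
#' @examples
#' ms <- generate_hkl(unit_cell(10, 10, 10), d_min = 5)
#' nrow(ms$hkl)
#' @export
generate_hkl <- function(cell, d_min, max_reflections = 2e6) {
  stopifnot(inherits(cell, "unit_cell"), d_min > 0)
  s_max <- 1 / d_min
  # |h| <= |a| * s_max etc. bounds the index ranges for any (also triclinic) cell
  hmax <- floor(cell$a * s_max)
  kmax <- floor(cell$b * s_max)
  lmax <- floor(cell$c * s_max)
  n_grid <- (2 * hmax + 1) * (2 * kmax + 1) * (2 * lmax + 1)
  if (n_grid > 8 * max_reflections)
    stop(sprintf("d_min = %g would enumerate ~%g candidate indices (cap %g); raise d_min or max_reflections",
                 d_min, n_grid, 8 * max_reflections))
  grid <- as.matrix(expand.grid(l = -lmax:lmax, k = -kmax:kmax, h = -hmax:hmax))[, 3:1, drop = FALSE]
  colnames(grid) <- c("h", "k", "l")
  half <- grid[, 1] > 0 |
    (grid[, 1] == 0 & grid[, 2] > 0) |
    (grid[, 1] == 0 & grid[, 2] == 0 & grid[, 3] > 0)
  grid <- grid[half, , drop = FALSE]
  s <- sqrt(rowSums((grid %*% cell$g_star) * grid))
  keep <- s <= s_max + 1e-12
  if (!any(keep))
    stop(sprintf("no reflections with d >= %g Angstrom in this cell", d_min))
  grid <- grid[keep, , drop = FALSE]
  s <- s[keep]
  ord <- order(grid[, 1], grid[, 2], grid[, 3])
  grid <- grid[ord, , drop = FALSE]
  s <- s[ord]
  storage.mode(grid) <- "integer"
  rownames(grid) <- NULL
  miller_set(grid, cell, s = s)
}

#' Construct a Miller set from explicit indices
#'
#' @param hkl Integer n x 3 matrix of Miller indices (no (0,0,0) row).
#' @param cell A [unit_cell()].
#' @param s Optional precomputed |s| values; computed from the cell if omitted.
#' @return A `miller_set` object; see [generate_hkl()].
#' @export
miller_set <- function(hkl, cell, s = NULL) {
  hkl <- as_hkl_matrix(hkl)
  storage.mode(hkl) <- "integer"
  if (is.null(s)) s <- s_magnitude(cell, hkl)
  if (any(s <= 0)) stop("all reflections must have s > 0")
  structure(list(hkl = hkl, s = s, d = 1 / s, cell = cell),
            class = "miller_set")
}

#' @export
print.miller_set <- function(x, ...) {
  cat(sprintf("miller_set: %d reflections, d range [%.4g, %.4g] A\n",
              nrow(x$hkl), min(x$d), max(x$d)))
  invisible(x)
}

n_reflections <- function(miller) nrow(miller$hkl)
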