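#' Partition reflections into logarithmic resolution shells
#'
#' Shell boundaries are spaced uniformly in ln(d) between the lowest and
#' highest resolution present. Scale factors are treated as constant inside
#' each shell, so shells must be thin; they must also hold enough
#' reflections for the per-shell fit to be statistically meaningful, so any
#' shell poorer than `min_per_shell` is merged with its neighbour on the
#' low-resolution (larger d) side. The lowest-resolution shell, having no
#' such neighbour, merges toward higher resolution instead.
#'
#' @param miller A [miller_set()].
#' @param n_shells Number of shells before merging. Default: one shell per
#'   ~100 reflections, clamped to \[1, 50\].
#' @param min_per_shell Minimum reflections per shell after merging.
#' @return An object of class `resolution_shells`: list with `boundaries`
#'   (descending d values, length n_shells + 1), `assignment` (per-reflection
#'   shell index, 1-based), `counts`, and `n_shells`.
#' @examples
#' ms <- generate_hkl(unit_cell(30, 30, 30), d_min = 3)
#' sh <- bin_shells(ms, n_shells = 5, min_per_shell = 10)
#' sh$counts
#' @export
bin_shells <- function(miller, n_shells = NULL, min_per_shell = 50) {
  stopifnot(inherits(miller, "miller_set"))
  n <- n_reflections(miller)
  if (n == 0L) stop("empty miller_set")
  if (is.null(n_shells)) n_shells <- max(1L, min(50L, as.integer(round(n / 100))))
  stopifnot(n_shells >= 1)
  if (n < min_per_shell && n_shells > 1L) {
    warning(sprintf("only %d reflections (< min_per_shell = %d); using a single shell",
                    n, min_per_shell))
    n_shells <- 1L
  }
  ln_d <- log(miller$d)
  lo <- max(ln_d)   # lowest resolution, largest d
  hi <- min(ln_d)
  if (lo - hi < 1e-12 || n_shells == 1L) {
    edges <- c(lo, hi)
    assignment <- rep(1L, n)
  } else {
    edges <- seq(lo, hi, length.out = n_shells + 1)
    # shell i covers d in (exp(edges[i+1]), exp(edges[i])]; d_max goes to shell 1
    assignment <- findInterval(-ln_d, -edges, rightmost.closed = TRUE)
    assignment[assignment < 1L] <- 1L
    assignment[assignment > n_shells] <- n_shells
  }
  counts <- tabulate(assignment, nbins = n_shells)
  # merge sparse shells toward lower resolution (larger d); scan high-res first
  if (n_shells > 1L) {
    repeat {
      counts <- tabulate(assignment, nbins = length(edges) - 1L)
      poor <- which(counts < min_per_shell & counts >= 0L)
      poor <- poor[counts[poor] < min_per_shell]
      if (length(poor) == 0L || length(edges) <= 2L) break
      i <- max(poor)  # highest-resolution offender first
      if (i == 1L) {
        # no larger-d neighbour: merge into shell 2
        edges <- edges[-2L]
        assignment[assignment >= 2L] <- assignment[assignment >= 2L] - 1L
      } else {
        # merge shell i into shell i-1 (larger d)
        edges <- edges[-i]
        assignment[assignment >= i] <- assignment[assignment >= i] - 1L
      }
    }
    counts <- tabulate(assignment, nbins = length(edges) - 1L)
  }
  structure(list(boundaries = exp(edges), assignment = assignment,
                 counts = counts, n_shells = length(edges) - 1L),
            class = "resolution_shells")
}

#' @export
print.resolution_shells <- function(x, ...) {
  cat(sprintf("resolution_shells: %d shells, counts [%s]\n",
              x$n_shells, paste(x$counts, collapse = ", ")))
  invisible(x)
}

#' Reflection indices belonging to one shell
#' @param shells A [bin_shells()] result.
#' @param i Shell index (1-based).
#' @return Integer vector of reflection indices.
#' @export
shell_indices <- function(shells, i) which(shells$assignment == i)
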