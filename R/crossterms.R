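#' Observed reflection data
#'
#' @param f_obs Observed amplitudes (>= 0), or NULL if only intensities given.
#' @param i_obs Observed intensities; defaults to f_obs^2.
#' @param sigmas Optional per-reflection uncertainties (carried, unused by
#'   the solvers, which minimize unweighted residuals).
#' @return An object of class `observed_data`.
#' @export
observed_data <- function(f_obs = NULL, i_obs = NULL, sigmas = NULL) {
  if (is.null(f_obs) && is.null(i_obs))
    stop("provide amplitudes and/or intensities")
  if (!is.null(f_obs) && any(f_obs < 0))
    stop("observed amplitudes must be non-negative")
  if (is.null(i_obs)) i_obs <- f_obs^2
  if (is.null(f_obs)) f_obs <- sqrt(pmax(i_obs, 0))
  if (length(f_obs) != length(i_obs))
    stop("f_obs and i_obs lengths differ")
  structure(list(f_obs = as.numeric(f_obs), i_obs = as.numeric(i_obs),
                 sigmas = sigmas), class = "observed_data")
}

#' Cross-term table of a set of components
#'
#' For components n, m = 0..N the per-reflection cross-terms
#' v_nm(s) = Re(F_n(s) conj(F_m(s))) couple pairs of components in the
#' model intensity |sum_n k_n F_n|^2 = sum_n sum_m k_n k_m v_nm. Being
#' half-sums of complex conjugates they are real; the table is symmetric
#' with v_nn = |F_n|^2 >= 0.
#'
#' @param components List of aligned [component()]s (atomic part first by
#'   convention).
#' @return An object of class `cross_terms`: list with `v` (array n_refl x
#'   P x P), the component matrix `F` (complex, n_refl x P) and `ids`.
#' @export
cross_v <- function(components) {
  fmat <- component_matrix(components)
  n <- nrow(fmat); p <- ncol(fmat)
  v <- array(NA_real_, c(n, p, p))
  for (a in seq_len(p))
    for (b in seq_len(a)) {
      vab <- Re(fmat[, a] * Conj(fmat[, b]))
      v[, a, b] <- vab
      v[, b, a] <- vab
    }
  structure(list(v = v, F = fmat, ids = colnames(fmat)), class = "cross_terms")
}

#' Phased cross-terms w_n = Re(A conj(F_n))
#'
#' With A = |F_obs| exp(i phi) built from observed amplitudes and phases
#' approximated by the current model, the phased least-squares target is
#' linear in the scales and w_n are its right-hand-side coefficients.
#'
#' @param ct A [cross_v()] result.
#' @param amplitudes Observed amplitudes aligned to the components.
#' @param phases Phase angles in radians (typically from the model sum).
#' @param shell Optional integer vector of reflection indices to restrict to.
#' @return Numeric matrix (reflections x components) of w_n values.
#' @export
cross_w <- function(ct, amplitudes, phases, shell = NULL) {
  stopifnot(inherits(ct, "cross_terms"))
  fmat <- ct$F
  if (!is.null(shell)) {
    fmat <- fmat[shell, , drop = FALSE]
    amplitudes <- amplitudes[shell]
    phases <- phases[shell]
  }
  a <- complex(modulus = amplitudes, argument = phases)
  Re(Conj(fmat) * a)
}
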