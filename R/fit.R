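#' Fit per-shell component scales to observed data
#'
#' Outer driver around the per-shell scale searches. The model in each
#' resolution shell is
#' `F_model = k_overall * (k_0 F_0 + sum_{n>=1} k_n F_n)`.
#' Internally all scales, including the atomic one, are solved
#' simultaneously in absolute terms; solving component scales against data
#' pre-divided by a frozen overall scale creates a degenerate feedback
#' (inflated component scales shrink the overall scale further), so the
#' overall scale is instead read off the fitted atomic scale. With the
#' default `k0 = "fixed"` the atomic scale is reported as `k_overall` and
#' `k_0 = 1`; with `k0 = "refine"` the overall scale is reported as 1 and
#' the atomic scale refines openly.
#'
#' The driver initializes from a single phased linear solve per shell that
#' lumps all non-atomic components into one (split equally afterwards), or
#' from the amplitude ratio if that solve fails, then repeats per-shell
#' solves until the maximum relative parameter change drops below `tol`.
#'
#' @param obs An [observed_data()] aligned to the components.
#' @param components List of aligned [component()]s, atomic part first.
#' @param shells A [bin_shells()] partition.
#' @param algorithm One of `"1"` (sequential), `"2"` (quartic LS, L-BFGS),
#'   `"2h"` (quartic LS with analytic Hessian), `"3"` (two-step analytic),
#'   `"4"` (iterative phased, default).
#' @param options Named list overriding defaults: `tol` (1e-4), `max_outer`
#'   (100), `clip` (TRUE: negative scales clipped to 0 on output), `k0`
#'   (`"fixed"` or `"refine"`), `k_init` (absolute scales: vector length P
#'   or n_shells x P matrix, atomic part first), `max_iter` (inner cap),
#'   `alg4_tol` (1e-6), `alg4_max_iter` (50), `cond_threshold` (1e12),
#'   `lower` (0; `-Inf` disables the bound).
#' @return An object of class `scale_set`: data frame with one row per
#'   shell (d range, reflection count, `k_overall`, one `k_*` column per
#'   component, shell R factor) plus a `log` attribute (algorithm,
#'   iterations, convergence flag, R-factor trajectory, warnings).
#' @export
fit_driver <- function(obs, components, shells, algorithm = c("4", "2", "2h", "3", "1"),
                       options = list()) {
  algorithm <- match.arg(algorithm)
  opts <- utils::modifyList(list(
    tol = 1e-4, max_outer = 100, clip = TRUE, k0 = "fixed", k_init = NULL,
    max_iter = 100, alg4_tol = 1e-6, alg4_max_iter = 50, cond_threshold = 1e12,
    lower = 0
  ), options)
  opts$k0 <- match.arg(opts$k0, c("fixed", "refine"))
  stopifnot(inherits(shells, "resolution_shells"))
  ct <- cross_v(components)
  p <- ncol(ct$F)
  n <- nrow(ct$F)
  if (length(obs$f_obs) != n) stop("observed data not aligned to components")
  ns <- shells$n_shells
  idx_list <- lapply(seq_len(ns), function(i) shell_indices(shells, i))
  warn_log <- character(0)
  capture_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  # with k0 = "fixed" the atomic coefficient is pinned during every inner
  # solve (it anchors the landscape the way the unscaled atomic part does
  # in practice) and is refreshed afterwards by an exact 1-D coordinate-
  # descent step; with k0 = "refine" all scales are solved jointly
  fixed <- if (opts$k0 == "fixed" && p > 1L) 1L else integer(0)

  solve_one <- function(i, ke_i, fx) {
    idx <- idx_list[[i]]
    switch(algorithm,
      "1" = solve_shell_alg1(ct, obs, idx, k_init = ke_i, lower = opts$lower,
                             fixed = fx),
      "2" = solve_shell_alg2(ct, obs, idx, k_init = ke_i,
                             use_hessian = FALSE, max_iter = opts$max_iter,
                             lower = opts$lower, fixed = fx),
      "2h" = solve_shell_alg2(ct, obs, idx, k_init = ke_i,
                              use_hessian = TRUE, max_iter = opts$max_iter,
                              lower = opts$lower, fixed = fx),
      "3" = solve_shell_alg3(ct, obs, idx, cond_threshold = opts$cond_threshold,
                             fixed = fx, k_fixed_values = ke_i[fx]),
      "4" = solve_shell_alg4(ct, obs, idx, k_init = ke_i,
                             max_iter = opts$alg4_max_iter, tol = opts$alg4_tol,
                             fixed = fx))
  }

  fit_once <- function(ke) {
  r_trace <- numeric(0)
  best <- list(r = Inf, ke = ke)
  n_rise <- 0L
  n_stall <- 0L
  converged <- FALSE
  iters_used <- 0L
  cond_max <- 0
  for (outer in seq_len(opts$max_outer)) {
    ke_old <- ke
    for (i in seq_len(ns)) {
      k_new <- capture_warn(solve_one(i, ke[i, ], fixed))
      if (!is.null(attr(k_new, "cond")))
        cond_max <- max(cond_max, attr(k_new, "cond"))
      ke[i, ] <- as.numeric(k_new)
      if (length(fixed))
        ke[i, 1] <- refit_scalar(ct, obs, idx_list[[i]], ke[i, ], 1L, opts$lower)
    }
    # negative scales are allowed within a shell solve but clipped between
    # outer passes (occupancy semantics): persistent negative/positive
    # cancellation pairs can otherwise overfit noise with huge scales
    if (opts$clip) ke <- pmax(ke, 0)
    iters_used <- outer
    r_now <- overall_r(obs, ct, ke, idx_list)
    r_trace <- c(r_trace, r_now)
    improvement <- best$r - r_now
    if (r_now <= best$r) best <- list(r = r_now, ke = ke)
    # a significant rise signals divergence; a machine-level plateau is
    # ordinary convergence in the presence of data noise
    if (r_now > best$r * (1 + 1e-3)) {
      n_rise <- n_rise + 1L
      if (n_rise >= 3L) break
    } else n_rise <- 0L
    if (improvement < max(1e-10 * best$r, 1e-16)) {
      n_stall <- n_stall + 1L
      if (n_stall >= 3L) { converged <- TRUE; break }
    } else n_stall <- 0L
    delta <- max(abs(ke - ke_old) / (abs(ke_old) + 1e-8))
    if (delta <= opts$tol) { converged <- TRUE; break }
  }
  diverged <- n_rise >= 3L
  if (diverged || best$r < overall_r(obs, ct, ke, idx_list)) ke <- best$ke
  list(ke = ke, r = overall_r(obs, ct, ke, idx_list), converged = converged,
       diverged = diverged, iters = iters_used, r_trace = r_trace,
       cond_max = cond_max)
  }

  ke0 <- capture_warn(init_scales(ct, obs, idx_list, p, opts))
  res <- fit_once(ke0)
  if (!is.null(opts$k_init)) {
    # guard against local minima reachable from a user-supplied start: if
    # the fit failed to converge, diverged, or is beaten by the driver's
    # own (unfitted!) sequential initialization, refit from that
    # initialization and keep whichever solution agrees better with the data
    opts2 <- opts; opts2$k_init <- NULL
    ke_self <- capture_warn(init_scales(ct, obs, idx_list, p, opts2))
    if (!res$converged || res$diverged ||
        res$r > overall_r(obs, ct, ke_self, idx_list)) {
      res2 <- fit_once(ke_self)
      if (res2$r < res$r) res <- res2
    }
  }
  ke <- res$ke
  converged <- res$converged
  diverged <- res$diverged
  iters_used <- res$iters
  r_trace <- res$r_trace
  cond_max <- res$cond_max
  if (length(fixed) && res$r < 1e-4 && algorithm %in% c("2", "2h", "4")) {
    # near-exact regime: the pinned iteration converges linearly in its
    # last digits, so finish with a few joint (unpinned) passes of the
    # same per-shell search; kept only if the agreement does not degrade
    ke_p <- ke
    for (pass in 1:5) {
      ke_old <- ke_p
      for (i in seq_len(ns))
        ke_p[i, ] <- as.numeric(capture_warn(solve_one(i, ke_p[i, ], integer(0))))
      if (max(abs(ke_p - ke_old) / (abs(ke_old) + 1e-8)) <= opts$tol) break
    }
    if (overall_r(obs, ct, ke_p, idx_list) <= res$r) ke <- ke_p
  }
  if (opts$clip) ke <- pmax(ke, 0)
  # decompose absolute scales into the reported parameterization
  if (opts$k0 == "fixed") {
    k_ov <- pmax(ke[, 1], 1e-12)
    kk <- cbind(1, ke[, -1, drop = FALSE] / k_ov)
  } else {
    k_ov <- rep(1, ns)
    kk <- ke
  }
  r_shell <- vapply(seq_len(ns), function(i) {
    idx <- idx_list[[i]]
    r_factor(obs$f_obs[idx], Mod(ct$F[idx, , drop = FALSE] %*% ke[i, ]))
  }, numeric(1))
  tab <- data.frame(
    shell = seq_len(ns),
    d_max = shells$boundaries[-(ns + 1)],
    d_min = shells$boundaries[-1],
    n_refl = shells$counts,
    k_overall = k_ov
  )
  kt <- as.data.frame(kk)
  names(kt) <- paste0("k_", make.names(ct$ids, unique = TRUE))
  tab <- cbind(tab, kt, r_shell = r_shell)
  structure(tab,
            class = c("scale_set", "data.frame"),
            ids = ct$ids,
            log = list(algorithm = algorithm, outer_iterations = iters_used,
                       converged = converged, diverged = diverged,
                       r_trace = r_trace,
                       r_factor = overall_r(obs, ct, ke, idx_list),
                       cond_max = cond_max, warnings = warn_log,
                       k0 = opts$k0, clip = opts$clip))
}

ratio_or_one <- function(num, den) if (den > 0) num / den else 1

# exact 1-D refresh of scale j with the others frozen: the stationarity
# condition of the quartic intensity residual in a single scale is a cubic,
# solved in closed form (monotone coordinate-descent step)
refit_scalar <- function(ct, obs, shell, k, j, lower = 0) {
  f0 <- ct$F[shell, j]
  m <- as.complex(ct$F[shell, -j, drop = FALSE] %*% k[-j])
  a <- Re(f0 * Conj(f0))
  b <- Re(f0 * Conj(m))
  r0 <- obs$i_obs[shell] - Re(m * Conj(m))
  coefs <- c(sum(r0 * b),                     # c^0
             sum(r0 * a) - 2 * sum(b^2),      # c^1
             -3 * sum(a * b),                 # c^2
             -sum(a^2))                       # c^3
  if (abs(coefs[4]) < 1e-300) return(k[j])
  roots <- polyroot(coefs)
  real <- Re(roots[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))])
  cand <- unique(c(pmax(real, lower), k[j]))
  ls1 <- function(cc) sum((r0 - cc^2 * a - 2 * cc * b)^2)
  cand[which.min(vapply(cand, ls1, numeric(1)))]
}

overall_r <- function(obs, ct, ke, idx_list) {
  amp <- numeric(length(obs$f_obs))
  for (i in seq_along(idx_list)) {
    idx <- idx_list[[i]]
    amp[idx] <- Mod(ct$F[idx, , drop = FALSE] %*% ke[i, ])
  }
  r_factor(obs$f_obs, amp)
}

# initial absolute scales. The atomic scale is anchored on the
# highest-resolution shells, where smeared bulk-like components have
# decayed and the atomic part dominates; one sequential single-component
# pass per shell then seeds the component scales inside the right basin.
init_scales <- function(ct, obs, idx_list, p, opts) {
  ns <- length(idx_list)
  ke <- matrix(0, ns, p)
  ke[, 1] <- 1
  if (!is.null(opts$k_init)) {
    ki <- opts$k_init
    if (is.matrix(ki)) {
      stopifnot(nrow(ki) == ns, ncol(ki) == p)
      ke[] <- ki
    } else {
      stopifnot(length(ki) == p)
      ke <- matrix(rep(as.numeric(ki), each = ns), ns, p)
    }
    return(ke)
  }
  if (p == 1L) {
    for (i in seq_len(ns))
      ke[i, 1] <- ratio_or_one(sum(obs$f_obs[idx_list[[i]]]),
                               sum(Mod(ct$F[idx_list[[i]], 1])))
    return(ke)
  }
  hi <- idx_list[[ns]]
  if (ns > 1L) hi <- c(idx_list[[ns - 1L]], hi)
  c_atoms <- ratio_or_one(sum(obs$f_obs[hi]), sum(Mod(ct$F[hi, 1])))
  for (i in seq_len(ns)) {
    ke[i, 1] <- c_atoms
    k1 <- tryCatch(
      solve_shell_alg1(ct, obs, idx_list[[i]],
                       k_init = c(c_atoms, rep(0, p - 1)), fixed = 1L),
      error = function(e) NULL)
    if (!is.null(k1) && all(is.finite(k1))) ke[i, ] <- as.numeric(k1)
  }
  ke
}

#' @export
print.scale_set <- function(x, ...) {
  lg <- attr(x, "log")
  cat(sprintf("scale_set: %d shells, algorithm %s, R = %.4f (%s, %d outer iterations)\n",
              nrow(x), lg$algorithm, lg$r_factor,
              if (lg$converged) "converged" else "not converged",
              lg$outer_iterations))
  print.data.frame(x, digits = 5)
  invisible(x)
}
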