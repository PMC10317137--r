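#' Quartic intensity least-squares residual
#'
#' The per-shell target LS(k) = sum_s (I_obs,s - sum_n sum_m k_n k_m v_nm,s)^2,
#' a fourth-degree polynomial in the scale factors k.
#'
#' @param k Scale vector, one entry per component (atomic part first).
#' @param ct A [cross_v()] table.
#' @param obs An [observed_data()] aligned to the components.
#' @param shell Integer vector of reflection indices forming the shell.
#' @return Scalar residual.
#' @export
ls_residual <- function(k, ct, obs, shell) {
  sub <- ct_shell(ct, obs, shell, length(k))
  q <- sub$vflat %*% as.numeric(outer(k, k))
  sum((sub$i_obs - q)^2)
}

#' @rdname ls_residual
#' @return `ls_gradient`: gradient vector dLS/dk_p =
#'   -4 sum_s (I_obs - Q) (sum_m k_m v_pm).
#' @export
ls_gradient <- function(k, ct, obs, shell) {
  sub <- ct_shell(ct, obs, shell, length(k))
  p <- length(k)
  vk <- matrix(matrix(sub$v, sub$n * p, p) %*% k, sub$n, p)
  r <- sub$i_obs - rowSums(vk * rep(k, each = sub$n))
  as.numeric(-4 * crossprod(vk, r))
}

#' @rdname ls_residual
#' @return `ls_hessian`: P x P matrix of second derivatives
#'   d2LS/dk_p dk_q = sum_s \[8 (Vk)_p (Vk)_q - 4 (I_obs - Q) v_pq\].
#' @export
ls_hessian <- function(k, ct, obs, shell) {
  sub <- ct_shell(ct, obs, shell, length(k))
  p <- length(k)
  vk <- matrix(matrix(sub$v, sub$n * p, p) %*% k, sub$n, p)
  r <- sub$i_obs - rowSums(vk * rep(k, each = sub$n))
  8 * crossprod(vk) - 4 * matrix(colSums(r * sub$vflat), p, p)
}

ct_shell <- function(ct, obs, shell, p_expect = NULL) {
  stopifnot(inherits(ct, "cross_terms"), inherits(obs, "observed_data"))
  if (length(shell) == 0L) stop("empty resolution shell")
  p <- dim(ct$v)[2]
  if (!is.null(p_expect) && p_expect != p)
    stop(sprintf("scale vector length %d does not match %d components", p_expect, p))
  v <- ct$v[shell, , , drop = FALSE]
  list(v = v, vflat = matrix(v, length(shell), p * p),
       i_obs = obs$i_obs[shell], f_obs = obs$f_obs[shell],
       F = ct$F[shell, , drop = FALSE], n = length(shell))
}

# Fast residual/gradient/Hessian on the complex component matrix:
# Q = |F k|^2, (Vk)_p = Re(F_p conj(F k)).
ls_parts_fast <- function(k, fmat, i_obs, want = c("r", "g", "h")) {
  fk <- as.complex(fmat %*% k)
  q <- Re(fk * Conj(fk))
  r <- i_obs - q
  out <- list(residual = sum(r^2))
  if (any(c("g", "h") %in% want)) {
    vk <- Re(fmat * Conj(fk))
    if ("g" %in% want) out$gradient <- as.numeric(-4 * crossprod(vk, r))
    if ("h" %in% want)
      out$hessian <- 8 * crossprod(vk) - 4 * Re(t(fmat * r) %*% Conj(fmat))
  }
  out
}

#' Algorithm 2: simultaneous quartic least-squares search
#'
#' Minimizes [ls_residual()] over all free scale factors at once with a
#' quasi-Newton method (L-BFGS-B) using the analytic gradient, or, when
#' `use_hessian = TRUE`, with a damped Newton iteration using the analytic
#' second derivatives. Requires initial values reasonably close to the
#' solution.
#'
#' @param ct A [cross_v()] table.
#' @param obs An [observed_data()].
#' @param shell Integer vector of reflection indices.
#' @param k_init Initial scale vector (length = number of components).
#' @param use_hessian Use analytic second derivatives (damped Newton).
#' @param max_iter Iteration cap.
#' @param lower Box lower bound on the scales (0 keeps occupancy semantics;
#'   `-Inf` disables).
#' @param fixed Integer indices of components whose scale is held at its
#'   `k_init` value (e.g. 1 to keep the atomic part at 1).
#' @return Scale vector with attributes `converged`, `iterations`,
#'   `residual`.
#' @export
solve_shell_alg2 <- function(ct, obs, shell, k_init, use_hessian = FALSE,
                             max_iter = 100, lower = 0, fixed = NULL) {
  sub <- ct_shell(ct, obs, shell, length(k_init))
  p <- length(k_init)
  free <- setdiff(seq_len(p), fixed)
  if (length(free) == 0L) return(structure(k_init, converged = TRUE,
                                           iterations = 0L,
                                           residual = ls_parts_fast(k_init, sub$F, sub$i_obs, "r")$residual))
  k <- as.numeric(k_init)
  fn_full <- function(kf) {
    k[free] <- kf
    val <- ls_parts_fast(k, sub$F, sub$i_obs, "r")$residual
    if (!is.finite(val))
      stop(nonfinite_condition("non-finite residual in algorithm 2", k))
    val
  }
  gr_full <- function(kf) {
    k[free] <- kf
    ls_parts_fast(k, sub$F, sub$i_obs, c("r", "g"))$gradient[free]
  }
  res0 <- ls_parts_fast(k, sub$F, sub$i_obs, "r")$residual
  # quasi-Newton stage, in units of k_init/10: the first steps are then
  # small relative to the distance to the k = 0 boundary, which is a
  # stationary saddle of the quartic that would otherwise trap the search.
  # Restart (which resets the L-BFGS memory) while the gradient test fails:
  # line-search breakdown near the solution is otherwise left unpolished.
  it <- 0L
  res_prev <- res0
  k_prev <- k[free]
  for (round in 1:5) {
    h <- pmax(abs(k[free]), 1e-3) / 10
    opt <- stats::optim(k[free] / h,
                        function(z) fn_full(z * h),
                        function(z) h * gr_full(z * h),
                        method = "L-BFGS-B", lower = lower / h,
                        control = list(maxit = max_iter, factr = 1, pgtol = 0,
                                       fnscale = max(res0, 1e-300)))
    k[free] <- opt$par * h
    it <- it + opt$counts[["function"]]
    # stop restarting once a round yields no meaningful progress
    no_move <- max(abs(k[free] - k_prev)) <= 1e-12 * (1 + max(abs(k_prev)))
    no_drop <- opt$value >= res_prev - 1e-12 * (1 + res_prev)
    if (no_move || no_drop) break
    res_prev <- opt$value
    k_prev <- k[free]
  }
  # Gauss-Newton finisher (first derivatives only): the line searches of
  # L-BFGS bottom out a few digits above the representable minimum
  for (gn in 1:10) {
    fk <- as.complex(sub$F %*% k)
    rres <- sub$i_obs - Re(fk * Conj(fk))
    vk <- Re(sub$F * Conj(fk))[, free, drop = FALSE]
    jtj <- 4 * crossprod(vk)
    step <- tryCatch(solve(jtj, 2 * as.numeric(crossprod(vk, rres))),
                     error = function(e) NULL)
    if (is.null(step)) break
    cap <- 1 + max(abs(k[free]))
    if (max(abs(step)) > cap) step <- step * cap / max(abs(step))
    f0 <- sum(rres^2)
    alpha <- 1
    moved <- FALSE
    for (ls in 1:20) {
      kt <- k
      kt[free] <- pmax(k[free] + alpha * step, lower)
      ft <- ls_parts_fast(kt, sub$F, sub$i_obs, "r")$residual
      if (is.finite(ft) && ft < f0) { k <- kt; moved <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!moved || max(abs(alpha * step)) <= 1e-14 * (1 + max(abs(k[free])))) break
  }
  if (use_hessian) {
    # Newton polish with the analytic second derivatives: near the
    # quasi-Newton solution the Hessian is essentially positive definite
    # and a damped Newton iteration converges quadratically
    mu <- 0
    for (iter in seq_len(30L)) {
      parts <- ls_parts_fast(k, sub$F, sub$i_obs, c("r", "g", "h"))
      g <- parts$gradient[free]
      tol_g <- 1e-12 * (1 + abs(parts$residual))
      if (max(abs(g)) <= tol_g) break
      hh <- parts$hessian[free, free, drop = FALSE]
      step <- NULL
      mu_try <- mu
      for (damp in 1:30) {
        hd <- hh + diag(mu_try, length(free))
        step <- tryCatch(solve(hd, -g), error = function(e) NULL)
        if (!is.null(step) && sum(step * g) < 0) break
        step <- NULL
        mu_try <- max(mu_try * 10, 1e-8 * max(abs(diag(hh)), 1))
      }
      if (is.null(step)) break
      mu <- mu_try / 4
      # cap the step so near-null directions of H cannot carry the iterate
      # arbitrarily far through flat regions of the residual surface
      cap <- 1 + max(abs(k[free]))
      if (max(abs(step)) > cap) step <- step * cap / max(abs(step))
      # backtracking line search with projection onto the lower bound
      alpha <- 1
      f0 <- parts$residual
      improved <- FALSE
      for (ls in 1:40) {
        kt <- k
        kt[free] <- pmax(k[free] + alpha * step, lower)
        ft <- ls_parts_fast(kt, sub$F, sub$i_obs, "r")$residual
        if (!is.finite(ft)) stop(nonfinite_condition("non-finite residual in algorithm 2", k))
        if (ft < f0) { k <- kt; improved <- TRUE; break }
        alpha <- alpha / 2
      }
      it <- it + 1L
      if (!improved) break
    }
  }
  parts <- ls_parts_fast(k, sub$F, sub$i_obs, c("r", "g"))
  if (parts$residual > res0) {  # never return worse than the start
    k <- as.numeric(k_init)
    parts <- ls_parts_fast(k, sub$F, sub$i_obs, c("r", "g"))
  }
  grad_ok <- max(abs(parts$gradient[free])) <= 1e-8 * (1 + abs(parts$residual))
  structure(k, converged = grad_ok, iterations = it, residual = parts$residual)
}

nonfinite_condition <- function(msg, iterate) {
  structure(class = c("mcsf_nonfinite_error", "error", "condition"),
            list(message = msg, call = sys.call(-1), iterate = iterate))
}

pair_index <- function(p) {
  idx <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "col"], idx[, "row"]), c("row", "col"), drop = FALSE]
}

#' Algorithm 3: non-iterative two-step product-variable search
#'
#' Step 1 substitutes u_nm = k_n k_m, turning the quartic target into a
#' quadratic one whose minimum solves a linear normal-equation system over
#' the (N+1)(N+2)/2 independent products (terms nm and mn merge with a
#' multiplicity factor 2 - delta_nm). Step 2 recovers the individual scales
#' from the products by linear least squares on lambda_n = ln k_n over all
#' pairs with u_nm > 0: minimize sum (ln u_nm - lambda_n - lambda_m)^2.
#' Needs no initial values, but the large system is sensitive to rounding
#' errors; condition numbers above `cond_threshold` trigger a pseudo-inverse
#' fallback with a warning.
#'
#' @inheritParams solve_shell_alg2
#' @param k_fixed_values Values for the `fixed` components (default 1).
#' @param cond_threshold Condition-number threshold for the normal equations.
#' @return Scale vector with attributes `u` (product table), `cond`
#'   (condition number) and `converged`.
#' @export
solve_shell_alg3 <- function(ct, obs, shell, fixed = NULL, k_fixed_values = NULL,
                             cond_threshold = 1e12) {
  sub <- ct_shell(ct, obs, shell)
  p <- dim(ct$v)[2]
  if (is.null(k_fixed_values)) k_fixed_values <- rep(1, length(fixed))
  kf <- numeric(p); kf[fixed] <- k_fixed_values
  pairs <- pair_index(p)
  mult <- ifelse(pairs[, 1] == pairs[, 2], 1, 2)
  both_fixed <- pairs[, 1] %in% fixed & pairs[, 2] %in% fixed
  # design columns: (2 - delta_nm) v_nm per free pair; known pairs go to the RHS
  cols <- lapply(seq_len(nrow(pairs)), function(j)
    mult[j] * sub$v[, pairs[j, 1], pairs[j, 2]])
  rhs <- sub$i_obs
  for (j in which(both_fixed))
    rhs <- rhs - cols[[j]] * kf[pairs[j, 1]] * kf[pairs[j, 2]]
  free_pairs <- which(!both_fixed)
  a <- do.call(cbind, cols[free_pairs])
  ata <- crossprod(a)
  atb <- crossprod(a, rhs)
  cond <- tryCatch(kappa(ata, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cond) || cond > cond_threshold) {
    warning(sprintf("algorithm 3 normal equations ill-conditioned (cond = %.3g); using pseudo-inverse", cond))
    u_free <- as.numeric(pinv_solve(ata, atb))
  } else {
    u_free <- as.numeric(solve(ata, atb))
  }
  u <- matrix(NA_real_, p, p)
  for (jj in seq_along(free_pairs)) {
    j <- free_pairs[jj]
    u[pairs[j, 1], pairs[j, 2]] <- u_free[jj]
    u[pairs[j, 2], pairs[j, 1]] <- u_free[jj]
  }
  for (j in which(both_fixed)) {
    val <- kf[pairs[j, 1]] * kf[pairs[j, 2]]
    u[pairs[j, 1], pairs[j, 2]] <- val
    u[pairs[j, 2], pairs[j, 1]] <- val
  }
  k <- recover_k_from_u(u, p, fixed, kf)
  structure(k, u = u, cond = cond, converged = TRUE)
}

# log least squares over positive products: ln u_nm = lambda_n + lambda_m
recover_k_from_u <- function(u, p, fixed, kf) {
  free <- setdiff(seq_len(p), fixed)
  pairs <- pair_index(p)
  rows <- list(); rhs <- numeric(0)
  for (j in seq_len(nrow(pairs))) {
    n <- pairs[j, 1]; m <- pairs[j, 2]
    if (n %in% fixed && m %in% fixed) next
    if (!is.finite(u[n, m]) || u[n, m] <= 0) next
    row <- numeric(length(free))
    y <- log(u[n, m])
    if (n %in% fixed) y <- y - log(kf[n]) else row[match(n, free)] <- row[match(n, free)] + 1
    if (m %in% fixed) y <- y - log(kf[m]) else row[match(m, free)] <- row[match(m, free)] + 1
    rows[[length(rows) + 1L]] <- row
    rhs <- c(rhs, y)
  }
  k <- numeric(p); k[fixed] <- kf[fixed]
  if (length(rows) == 0L) {
    if (length(free)) warning("no positive products for any free component; scales set to 0")
    return(k)
  }
  a <- do.call(rbind, rows)
  seen <- colSums(abs(a)) > 0
  lam <- rep(-Inf, length(free))
  if (any(seen)) {
    fit <- stats::lm.fit(a[, seen, drop = FALSE], rhs)
    lam[seen] <- fit$coefficients
    lam[!is.finite(lam) & seen] <- -Inf
  }
  if (any(!seen))
    warning("components with no positive product estimates; their scales set to 0")
  k[free] <- exp(lam)
  k[free][!is.finite(k[free])] <- 0
  k
}

pinv_solve <- function(a, b, rtol = 1e-12) {
  sv <- svd(a)
  keep <- sv$d > rtol * max(sv$d)
  sv$v[, keep, drop = FALSE] %*% ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
}

#' Algorithm 4: iterative phased linear search
#'
#' Compares structure factors as complex values instead of intensities. Each
#' iteration (a) takes phases phi_s from the current model sum, (b) forms
#' A_s = |F_obs,s| exp(i phi_s), (c) computes w_n = sum_s Re(A_s conj(F_n,s)),
#' and (d) solves the (N+1)-dimensional linear system
#' sum_m k_m sum_s v_nm,s = w_n. Iterates until the maximum relative change
#' in k drops below `tol` (typically a few dozen iterations suffice).
#'
#' @inheritParams solve_shell_alg2
#' @param tol Convergence threshold on the max relative change in k.
#' @param phases Optional fixed phase angles (radians): a single linear
#'   solve with these phases is returned (exact-phase mode).
#' @param cond_threshold Condition-number threshold of the linear system
#'   above which a truncated pseudo-inverse is used (with a warning):
#'   components spanning near-null directions are then left at the
#'   minimum-norm solution instead of diverging.
#' @return Scale vector with attributes `converged`, `iterations`, `cond`.
#' @export
solve_shell_alg4 <- function(ct, obs, shell, k_init, max_iter = 50,
                             tol = 1e-6, fixed = NULL, phases = NULL,
                             cond_threshold = 1e12) {
  sub <- ct_shell(ct, obs, shell, length(k_init))
  p <- length(k_init)
  free <- setdiff(seq_len(p), fixed)
  k <- as.numeric(k_init)
  if (length(free) == 0L) return(structure(k, converged = TRUE, iterations = 0L))
  fmat <- sub$F
  fobs <- sub$f_obs
  vsum <- matrix(colSums(sub$vflat), p, p)
  cond_seen <- 0
  warned <- FALSE
  one_solve <- function(phi, valid) {
    a <- complex(modulus = fobs[valid], argument = phi[valid])
    w <- as.numeric(crossprod(Re(Conj(fmat[valid, , drop = FALSE]) * a),
                              rep(1, sum(valid))))
    m <- if (all(valid)) vsum else
      matrix(colSums(matrix(ct$v[shell[valid], , , drop = FALSE], sum(valid), p * p)), p, p)
    rhs <- w[free]
    if (length(fixed))
      rhs <- rhs - as.numeric(m[free, fixed, drop = FALSE] %*% k[fixed])
    mff <- m[free, free, drop = FALSE]
    cond <- tryCatch(kappa(mff, exact = TRUE), error = function(e) Inf)
    cond_seen <<- max(cond_seen, cond)
    if (!is.finite(cond) || cond > cond_threshold) {
      if (!warned) {
        warning(sprintf("phased linear system ill-conditioned (cond = %.3g); using least-squares pseudo-solution", cond))
        warned <<- TRUE
      }
      return(as.numeric(pinv_solve(mff, rhs, rtol = 1 / cond_threshold)))
    }
    as.numeric(solve(mff, rhs))
  }
  if (!is.null(phases)) {
    phi <- if (length(phases) == length(obs$f_obs)) phases[shell] else phases
    k[free] <- one_solve(phi, rep(TRUE, sub$n))
    return(structure(k, converged = TRUE, iterations = 1L, cond = cond_seen))
  }
  converged <- FALSE
  it <- 0L
  for (iter in seq_len(max_iter)) {
    fk <- as.complex(fmat %*% k)
    valid <- Mod(fk) > 0
    if (!any(valid)) break
    k_new <- k
    k_new[free] <- one_solve(Arg(fk), valid)
    delta <- max(abs(k_new - k) / pmax(abs(k), 1e-12))
    k <- k_new
    it <- iter
    if (delta <= tol) { converged <- TRUE; break }
  }
  structure(k, converged = converged, iterations = it, cond = cond_seen)
}

#' Algorithm 1: sequential single-component search
#'
#' Adds components one at a time (default order: descending total power
#' sum |F_n|^2), fitting each new scale by 1-D minimization of the amplitude
#' residual sum (|F_obs| - |F_partial + k_n F_n|)^2 with all previously
#' fitted scales frozen. One pass per call; the outer driver repeats passes.
#' Cheap but greedy: errors in early scales propagate into later ones, and
#' with strongly correlated components its residual cannot beat the
#' simultaneous search of algorithm 2.
#'
#' @inheritParams solve_shell_alg2
#' @param order Integer ordering of the free components; default descending
#'   sum |F_n|^2 within the shell.
#' @return Scale vector with attribute `order`.
#' @export
solve_shell_alg1 <- function(ct, obs, shell, k_init = NULL, order = NULL,
                             fixed = NULL, lower = 0) {
  p <- dim(ct$v)[2]
  if (is.null(k_init)) k_init <- c(1, numeric(p - 1))
  sub <- ct_shell(ct, obs, shell, length(k_init))
  free <- setdiff(seq_len(p), fixed)
  if (is.null(order)) {
    power <- colSums(Mod(sub$F)^2)
    order <- free[order(power[free], decreasing = TRUE)]
  }
  k <- as.numeric(k_init)
  k[free] <- 0
  f_partial <- as.complex(sub$F %*% k)
  for (n in order) {
    fn <- sub$F[, n]
    target <- function(kn) sum((sub$f_obs - Mod(f_partial + kn * fn))^2)
    # bracket from the linear phased estimate, generously widened
    est <- sum(Re(Conj(fn) * f_partial) + sub$f_obs * Mod(fn)) / sum(Mod(fn)^2)
    hi <- max(10, 4 * abs(est))
    lo <- if (is.finite(lower)) lower else -hi
    opt <- stats::optimize(target, c(lo, hi), tol = 1e-10)
    k[n] <- opt$minimum
    f_partial <- f_partial + k[n] * fn
  }
  structure(k, order = order)
}

#' Crystallographic R factor
#'
#' R = sum | |F_obs| - |F_model| | / sum |F_obs|.
#'
#' @param f_obs,f_model Aligned non-empty amplitude vectors.
#' @return Scalar R factor.
#' @examples
#' r_factor(c(10, 10), c(9, 12))  # 0.15
#' @export
r_factor <- function(f_obs, f_model) {
  stopifnot(length(f_obs) == length(f_model), length(f_obs) > 0)
  sum(abs(f_obs - f_model)) / sum(f_obs)
}
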