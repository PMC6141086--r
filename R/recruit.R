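#' Recruitment solver configuration
#'
#' @param p Polynomial exponent of the recruitment criterion (default 3:
#'   minimize the sum of cubed activations).
#' @param tol Convergence tolerance on the moment-equilibrium residual,
#'   relative to `max(1, |tau|)` (default 1e-9).
#' @param max_iter Newton iteration cap (default 300).
#' @param upper_bound Optional activation upper bound (e.g. 1); `NULL`
#'   (default) leaves activations unbounded above, consistent with
#'   constant-strength actuators under a polynomial criterion.
#' @return List of class `recruitment_config`.
#' @export
recruitment_config <- function(p = 3, tol = 1e-9, max_iter = 300,
                               upper_bound = NULL) {
  stopifnot(p >= 2, tol > 0)
  structure(list(p = p, tol = tol, max_iter = max_iter,
                 upper_bound = upper_bound), class = "recruitment_config")
}

#' Static-optimization muscle recruitment for one frame
#'
#' Solves
#' \deqn{\min_f \sum_i (f_i/N_i)^p \quad \mathrm{s.t.}\; R f = \tau,\; f \ge 0}
#' (defaults to `p = 3`, the minimum sum of cubed activations) through its
#' exact KKT conditions: with `s = R^T lambda`, the unique primal solution is
#' `f_i = N_i^{p/(p-1)} (max(s_i, 0)/p)^{1/(p-1)}`, and the multipliers
#' `lambda` solve the monotone system `R f(lambda) = tau`, here by a damped
#' (Levenberg-regularized) Newton iteration.  The solve is deterministic
#' (fixed least-squares initialization, no warm start) and invariant to
#' muscle column ordering.
#'
#' @param tau Named numeric vector of net joint moments on the constrained
#'   dofs (N m, generalized forces).
#' @param R Moment-arm matrix, `length(tau)` x n muscles (m); see
#'   [moment_arm_matrix()].
#' @param strengths Muscle strengths `N_i` (N), length = `ncol(R)`.
#' @param config A [recruitment_config()].
#' @return List with `f` (muscle forces, N), `a` (activations `f/N`),
#'   `lambda` (dof multipliers), `residual` (max abs equilibrium residual,
#'   N m), `converged`, `iterations`.
#' @export
solve_recruitment <- function(tau, R, strengths, config = recruitment_config()) {
  stopifnot(inherits(config, "recruitment_config"))
  R <- as.matrix(R)
  nd <- nrow(R); nm <- ncol(R)
  stopifnot(length(tau) == nd, length(strengths) == nm, all(strengths > 0))
  if (any(!is.finite(tau)) || any(!is.finite(R))) {
    stop("moment targets and moment arms must be finite", call. = FALSE)
  }
  p <- config$p
  N <- as.numeric(strengths)
  f_cap <- if (is.null(config$upper_bound)) rep(Inf, nm) else
    N * config$upper_bound

  scale <- max(1, max(abs(tau)))
  if (max(abs(tau)) <= config$tol * scale) {
    return(recruitment_result(rep(0, nm), N, rep(0, nd), 0, TRUE, 0L, R, p))
  }

  # primal force and its sensitivity to s = R^T lambda
  coef <- N^(p / (p - 1)) * (1 / p)^(1 / (p - 1))
  f_of_s <- function(s) {
    f <- ifelse(s > 0, coef * pmax(s, 0)^(1 / (p - 1)), 0)
    pmin(f, f_cap)
  }
  w_of_s <- function(s) {
    w <- ifelse(s > 0, coef / (p - 1) * pmax(s, 1e-300)^((2 - p) / (p - 1)), 0)
    w[f_of_s(s) >= f_cap] <- 0
    w
  }

  # deterministic initialization: least-squares pseudo-inverse force,
  # mapped back through the stationarity condition
  G <- R %*% t(R) + 1e-12 * mean(diag(R %*% t(R)) + 1e-30) * diag(nd)
  f0 <- pmax(as.numeric(t(R) %*% solve(G, tau)), 0)
  s0 <- p * (f0 / N)^(p - 1) / N
  pos <- s0 > 0
  lambda <- if (any(pos)) {
    A <- t(R[, pos, drop = FALSE])
    as.numeric(solve(crossprod(A) + 1e-10 * diag(nd), crossprod(A, s0[pos])))
  } else rep(0, nd)

  g_at <- function(lam) as.numeric(R %*% f_of_s(as.numeric(t(R) %*% lam))) - tau
  g <- g_at(lambda)
  RRt <- R %*% t(R)
  mu <- 1e-8
  it <- 0L
  while (max(abs(g)) > config$tol * scale && it < config$max_iter) {
    it <- it + 1L
    s <- as.numeric(t(R) %*% lambda)
    w <- w_of_s(s)
    J <- R %*% (t(R) * w)
    if (max(w) == 0) {
      # all muscles inactive but the target is unmet: steer the multipliers
      # toward the active region along the least-squares direction
      J <- RRt
    }
    step_ok <- FALSE
    for (try in 1:20) {
      d <- tryCatch(solve(J + mu * diag(nd), -g), error = function(e) NULL)
      if (!is.null(d)) {
        alpha <- 1
        for (ls in 1:40) {
          g_new <- g_at(lambda + alpha * d)
          if (sum(g_new^2) < sum(g^2)) {
            lambda <- lambda + alpha * d
            g <- g_new
            mu <- max(mu / 3, 1e-14)
            step_ok <- TRUE
            break
          }
          alpha <- alpha / 2
        }
      }
      if (step_ok) break
      mu <- mu * 10
    }
    if (!step_ok) break
  }

  f <- f_of_s(as.numeric(t(R) %*% lambda))
  resid <- max(abs(g))
  if (resid > config$tol * scale) {
    # the dual Newton can stall on an activation-boundary kink (the cubic
    # criterion has unbounded dual slope at activation onset); finish with
    # an augmented-Lagrangian solve on the primal activations
    al <- recruit_augmented_lagrangian(tau, R, N, config, f, lambda)
    if (al$resid < resid) {
      lambda <- al$lambda
      f <- al$f
      resid <- al$resid
    }
  }
  converged <- resid <= config$tol * scale
  if (!converged && resid > 1e-4 * scale) {
    g <- as.numeric(R %*% f) - tau
    bad <- which(abs(g) > config$tol * scale)
    dn <- names(tau) %||% rownames(R) %||% as.character(seq_along(tau))
    stop("recruitment infeasible: no nonnegative muscle forces satisfy the ",
         "moment equilibrium on dof(s) ", paste(dn[bad], collapse = ", "),
         " (residual ", signif(resid, 3), " N m)", call. = FALSE)
  }
  recruitment_result(f, N, lambda, resid, converged, it, R, p)
}

# Augmented-Lagrangian fallback on the primal activations x = f/N:
# minimize sum x^p + lam' (A x - tau) + rho/2 ||A x - tau||^2, x >= 0
# (A = R diag(N)), with multiplier updates until the equilibrium residual
# meets tolerance.  Deterministic; used only when the dual Newton stalls.
recruit_augmented_lagrangian <- function(tau, R, N, config, f_init, lambda_init) {
  p <- config$p
  A <- R * rep(N, each = nrow(R))
  x <- pmax(f_init / N, 0)
  ub <- config$upper_bound %||% Inf
  lam <- -lambda_init
  scale <- max(1, max(abs(tau)))
  rho <- 1e2 / max(sum(A^2), 1)
  best <- list(resid = Inf)
  for (outer in 1:60) {
    fn <- function(xx) {
      r <- as.numeric(A %*% xx) - tau
      sum(xx^p) + sum(lam * r) + rho / 2 * sum(r^2)
    }
    gr <- function(xx) {
      r <- as.numeric(A %*% xx) - tau
      p * xx^(p - 1) + as.numeric(t(A) %*% (lam + rho * r))
    }
    o <- stats::optim(x, fn, gr, method = "L-BFGS-B", lower = 0, upper = ub,
                      control = list(maxit = 500, factr = 10))
    x <- o$par
    r <- as.numeric(A %*% x) - tau
    resid <- max(abs(r))
    if (resid < best$resid) {
      best <- list(f = x * N, lambda = -lam, resid = resid)
    }
    if (resid <= config$tol * scale) break
    lam <- lam + rho * r
    if (outer %% 2 == 0) rho <- min(rho * 10, 1e9)
  }
  best
}

recruitment_result <- function(f, N, lambda, resid, converged, it, R, p) {
  names(f) <- colnames(R)
  list(f = f, a = f / N, lambda = lambda, residual = resid,
       converged = converged, iterations = it,
       objective = sum((f / N)^p))
}
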