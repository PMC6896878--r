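# Laplace/penalized-likelihood engine for Poisson log-linear models with
# Gaussian random effects:
#
#   y_i ~ Poisson(E_i * exp(x_i' beta + z_i' b)),   b ~ N(0, Q(theta)^-1)
#
# For given variance parameters theta, the joint mode of (beta, b) is found
# by Newton iteration with step halving; theta is estimated by maximizing
# the Laplace approximation to the marginal likelihood (fixed effects
# profiled at the joint mode). Intervals are Wald on the log scale from the
# joint Hessian. Structures supply Z, Q(theta) and log|Q(theta)|; the
# Gaussian-process structure is whitened (b = chol(Sigma)' s with s standard
# normal) so its prior precision is the identity.

# Cholesky with escalating ridge for near-singular Hessians (e.g. an
# almost-empty stratum); the gradient criterion still governs convergence.
#' @keywords internal
safe_chol <- function(H) {
  sc <- mean(diag(H))
  for (ridge in c(0, sc * 10^c(-10, -8, -6, -4))) {
    R <- tryCatch(chol(H + diag(ridge, nrow(H))), error = function(e) NULL)
    if (!is.null(R)) return(R)
  }
  stop("Hessian is numerically singular")
}

# Newton solver for the penalized Poisson log-likelihood at fixed theta.
# The row design C stays sparse for the weighted crossproduct; the (p+q)
# Hessian is small enough in every supported structure to factor densely.
#' @keywords internal
inner_newton <- function(y, logE, X, Z, Q, start = NULL,
                         maxit = 100L, tol = 1e-9) {
  n <- length(y); p <- ncol(X); q <- ncol(Z)
  C <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  Qd <- as.matrix(Q)
  Pd <- matrix(0, p + q, p + q)
  Pd[(p + 1L):(p + q), (p + 1L):(p + q)] <- Qd
  co <- if (!is.null(start) && length(start) == p + q) start else {
    s <- numeric(p + q)
    s[1L] <- log(max(sum(y), 0.5) / sum(exp(logE)))  # intercept init
    s
  }
  pen_ll <- function(co, eta) {
    b <- co[(p + 1L):(p + q)]
    sum(y * eta - exp(eta)) - 0.5 * sum(b * (Qd %*% b))
  }
  hessian <- function(mu) as.matrix(Matrix::crossprod(C * sqrt(mu))) + Pd
  eta <- logE + as.numeric(C %*% co)
  f <- pen_ll(co, eta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- exp(eta)
    g <- as.numeric(Matrix::crossprod(C, y - mu)) - drop(Pd %*% co)
    R <- safe_chol(hessian(mu))
    step <- backsolve(R, backsolve(R, g, transpose = TRUE))
    # step halving on the penalized log-likelihood
    t <- 1
    repeat {
      co_new <- co + t * step
      eta_new <- logE + as.numeric(C %*% co_new)
      f_new <- pen_ll(co_new, eta_new)
      if (is.finite(f_new) && f_new >= f - 1e-12) break
      t <- t / 2
      if (t < 1e-10) { co_new <- co; eta_new <- eta; f_new <- f; break }
    }
    delta <- f_new - f
    co <- co_new; eta <- eta_new; f <- f_new
    if (max(abs(g)) < tol * (1 + abs(f)) || delta < tol * (1 + abs(f))) {
      converged <- TRUE
      break
    }
  }
  mu <- exp(eta)
  H <- hessian(mu)
  b <- co[(p + 1L):(p + q)]
  Rbb <- safe_chol(H[(p + 1L):(p + q), (p + 1L):(p + q), drop = FALSE])
  list(coef = co, beta = co[seq_len(p)], b = b, mu = as.numeric(mu),
       H = H, logdet_Hbb = 2 * sum(log(diag(Rbb))),
       loglik_pois = sum(stats::dpois(y, mu, log = TRUE)),
       quad = sum(b * (Qd %*% b)),
       converged = converged, iter = it, grad_norm = max(abs(g)))
}

# Laplace log marginal likelihood at theta (constants dropped)
#' @keywords internal
laplace_objective <- function(theta, y, logE, X, structure, state) {
  parts <- structure$build(theta)
  fit <- inner_newton(y, logE, X, parts$Z, parts$Q, start = state$co)
  state$co <- fit$coef
  ll <- fit$loglik_pois - 0.5 * fit$quad +
    0.5 * parts$logdetQ - 0.5 * fit$logdet_Hbb
  attr(ll, "fit") <- fit
  ll
}

#' Fit a Poisson mixed model by Laplace approximation
#'
#' Workhorse behind [fit_smr_model()]; exposed for programming.
#'
#' @param y integer counts.
#' @param E positive offsets on the rate scale.
#' @param X fixed-effects design matrix (first column the intercept).
#' @param structure a random-effects structure (see [structure_iid()] and
#'   friends): a list with `build(theta)` returning `Z`, `Q`, `logdetQ`,
#'   plus `theta_init`, `theta_lower`, `theta_upper`, `theta_names` and
#'   `varcomp(theta)`.
#' @return list with `beta`, `se_beta`, `vcov_beta`, `b`, `mu`, `theta`,
#'   `varcomp`, `loglik_laplace`, `converged`, `diagnostics`.
#' @keywords internal
laplace_fit <- function(y, E, X, structure) {
  logE <- log(E)
  state <- new.env(parent = emptyenv()); state$co <- NULL
  obj <- function(theta)
    as.numeric(laplace_objective(theta, y, logE, X, structure, state))
  d <- length(structure$theta_init)
  if (d == 1L) {
    opt <- stats::optimize(obj, lower = structure$theta_lower,
                           upper = structure$theta_upper,
                           maximum = TRUE, tol = 1e-5)
    theta <- opt$maximum
    outer_conv <- TRUE
  } else {
    opt <- stats::optim(structure$theta_init, obj,
                        method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 200,
                                       reltol = 1e-7))
    theta <- opt$par
    outer_conv <- opt$convergence == 0L
  }
  ll <- laplace_objective(theta, y, logE, X, structure, state)
  fit <- attr(ll, "fit")
  p <- ncol(X)
  V <- chol2inv(safe_chol(fit$H))[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(V) <- list(colnames(X), colnames(X))
  out <- list(beta = stats::setNames(fit$beta, colnames(X)),
              se_beta = stats::setNames(sqrt(diag(V)), colnames(X)),
              vcov_beta = V,
              b = fit$b, mu = fit$mu,
              theta = stats::setNames(theta, structure$theta_names),
              varcomp = structure$varcomp(theta),
              loglik_laplace = as.numeric(ll),
              converged = fit$converged && outer_conv,
              diagnostics = list(inner_converged = fit$converged,
                                 outer_converged = outer_conv,
                                 inner_iter = fit$iter,
                                 grad_norm = fit$grad_norm,
                                 refinement = "laplace"))
  # for the IID structure the marginal likelihood factorizes by cluster:
  # refine the Laplace solution by adaptive Gauss-Hermite quadrature, which
  # matters when clusters carry only a handful of events
  if (!is.null(structure$agq)) {
    ref <- agq_refine_iid(y, logE, X, structure$agq$cluster,
                          structure$agq$ids, fit$beta, theta[1L])
    if (is.finite(ref$loglik)) {
      out$beta <- stats::setNames(ref$beta, colnames(X))
      out$b <- ref$u
      out$mu <- ref$mu
      out$theta <- stats::setNames(ref$logsigma, structure$theta_names)
      out$varcomp <- structure$varcomp(ref$logsigma)
      out$loglik_laplace <- ref$loglik
      out$converged <- out$converged && ref$converged
      out$diagnostics$refinement <- "agq25"
      se <- suppressWarnings(sqrt(diag(ref$vcov_beta)))
      if (all(is.finite(se))) {
        # quadrature-based Wald variances; near a variance boundary the
        # numerical Hessian can degenerate, in which case the joint-mode
        # (Laplace) variances above are retained
        Vr <- ref$vcov_beta
        dimnames(Vr) <- list(colnames(X), colnames(X))
        out$se_beta <- stats::setNames(se, colnames(X))
        out$vcov_beta <- Vr
      }
    }
  }
  out
}

# ---- adaptive Gauss-Hermite refinement for the IID structure ---------------

# Gauss-Hermite nodes/weights for weight exp(-t^2) (Golub-Welsch)
#' @keywords internal
gauss_hermite <- function(n) {
  b <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), 2:n)] <- b
  J[cbind(2:n, seq_len(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1L, ]^2)
}

# Exact (quadrature) ML for the Poisson random-intercept model. The marginal
# likelihood factorizes into one 1-D integral per cluster, each computed by
# adaptive Gauss-Hermite quadrature centered at the conditional mode; (beta,
# log sigma_u) are then maximized directly. This removes the Laplace error
# that is material when clusters carry only a handful of events.
#' @keywords internal
agq_refine_iid <- function(y, logE, X, cluster, ids, beta0, logsigma0,
                           nodes = 25L) {
  gh <- gauss_hermite(nodes)
  jidx <- match(cluster, ids)
  J <- length(ids)
  state <- new.env(parent = emptyenv())
  state$u <- numeric(J)
  lconst <- sum(lgamma(y + 1))
  objective <- function(par) {
    p <- length(par) - 1L
    beta <- par[seq_len(p)]
    sigma <- exp(par[p + 1L])
    fix <- logE + as.numeric(X %*% beta)
    # conditional modes by vectorized Newton across clusters
    u <- state$u
    for (it in 1:30) {
      mu <- exp(fix + u[jidx])
      g <- as.numeric(rowsum(y - mu, jidx, reorder = TRUE)) - u / sigma^2
      h <- as.numeric(rowsum(mu, jidx, reorder = TRUE)) + 1 / sigma^2
      step <- g / h
      u <- u + step
      if (max(abs(step)) < 1e-10) break
    }
    state$u <- u
    mu <- exp(fix + u[jidx])
    s <- 1 / sqrt(as.numeric(rowsum(mu, jidx, reorder = TRUE)) + 1 / sigma^2)
    # log integrand at each node, per cluster, with log-sum-exp
    lse <- matrix(-Inf, J, nodes)
    for (k in seq_len(nodes)) {
      uk <- u + sqrt(2) * s * gh$nodes[k]
      eta <- fix + uk[jidx]
      gk <- as.numeric(rowsum(y * eta - exp(eta), jidx, reorder = TRUE))
      lse[, k] <- log(gh$weights[k]) + gh$nodes[k]^2 + gk +
        stats::dnorm(uk, 0, sigma, log = TRUE)
    }
    m <- apply(lse, 1L, max)
    sum(m + log(rowSums(exp(lse - m))) + log(sqrt(2) * s)) - lconst
  }
  par0 <- c(beta0, logsigma0)
  lower <- c(rep(-20, length(beta0)), log(1e-4))
  upper <- c(rep(20, length(beta0)), log(5))
  opt <- stats::optim(par0, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(fnscale = -1, maxit = 200))
  if (opt$convergence != 0) {  # retry from the solution: line-search hiccups
    opt2 <- stats::optim(opt$par, objective, method = "L-BFGS-B",
                         lower = lower, upper = upper,
                         control = list(fnscale = -1, maxit = 200))
    if (opt2$value >= opt$value) opt <- opt2
  }
  converged <- opt$convergence == 0L
  if (!converged) {
    # L-BFGS-B line searches can stall on a flat boundary (sigma_u -> 0);
    # accept the solution if the fixed-effect score is numerically zero
    h <- 1e-5
    gmax <- max(vapply(seq_along(beta0), function(i) {
      e <- replace(numeric(length(opt$par)), i, h)
      abs(objective(opt$par + e) - objective(opt$par - e)) / (2 * h)
    }, numeric(1)))
    converged <- gmax < 1e-3 * (1 + abs(opt$value))
  }
  Hn <- stats::optimHess(opt$par, function(par) -objective(par))
  V <- tryCatch(solve((Hn + t(Hn)) / 2), error = function(e)
    matrix(NA_real_, length(opt$par), length(opt$par)))
  p <- length(beta0)
  # conditional modes and fitted means at the optimum
  objective(opt$par)
  mu <- exp(logE + as.numeric(X %*% opt$par[seq_len(p)]) + state$u[jidx])
  list(beta = opt$par[seq_len(p)], logsigma = opt$par[p + 1L],
       vcov_beta = V[seq_len(p), seq_len(p), drop = FALSE],
       u = state$u, mu = mu, loglik = opt$value,
       converged = converged)
}

# ---- random-effects structures ---------------------------------------------

# sparse cluster indicator matrix for rows -> clusters
#' @keywords internal
cluster_indicator <- function(cluster, ids) {
  j <- match(cluster, ids)
  Matrix::sparseMatrix(i = seq_along(cluster), j = j,
                       x = 1, dims = c(length(cluster), length(ids)))
}

#' IID cluster random-intercept structure
#'
#' `u_j ~ N(0, sigma_u^2)`; theta is `log sigma_u`.
#'
#' @param cluster per-row cluster ids.
#' @param ids cluster id universe (defines the effect order).
#' @return a structure list for [laplace_fit()].
#' @keywords internal
structure_iid <- function(cluster, ids) {
  Zc <- cluster_indicator(cluster, ids)
  k <- length(ids)
  list(build = function(theta) {
         s2 <- exp(2 * theta[1L])
         list(Z = Zc, Q = Matrix::Diagonal(k, 1 / s2),
              logdetQ = -2 * k * theta[1L])
       },
       theta_init = log(0.2), theta_lower = log(1e-4), theta_upper = log(5),
       theta_names = "log_sigma_u",
       varcomp = function(theta) list(sigma_u = exp(theta[1L])),
       effect_names = list(u = ids),
       agq = list(cluster = cluster, ids = ids),
       map_effects = function(b) list(u = stats::setNames(b, ids)))
}

# sum-to-zero basis and constrained ICAR precision ingredients
#' @keywords internal
icar_parts <- function(adj, jitter = 1e-6) {
  W <- adj$W
  k <- nrow(W)
  L <- diag(rowSums(W)) - W
  A <- qr.Q(qr(matrix(1, k, 1)), complete = TRUE)[, -1L, drop = FALSE]
  M <- crossprod(A, (L + diag(jitter, k)) %*% A)
  M <- (M + t(M)) / 2
  list(A = A, M = Matrix::Matrix(M),
       logdetM = as.numeric(determinant(M)$modulus))
}

#' Intrinsic CAR structure on the cluster graph
#'
#' Improper Besag prior with precision `tau * (D - W)`, a sum-to-zero
#' constraint (enforced by reparameterizing on the orthogonal complement of
#' the constant vector) and a 1e-6 propriety jitter; theta is `log tau`.
#'
#' @inheritParams structure_iid
#' @param adj a `queen_adjacency` over `ids` (same order).
#' @keywords internal
structure_car <- function(cluster, ids, adj) {
  stopifnot(identical(adj$cluster_ids, ids))
  Zc <- cluster_indicator(cluster, ids)
  parts <- icar_parts(adj)
  Zv <- Zc %*% parts$A
  k <- length(ids)
  list(build = function(theta) {
         tau <- exp(theta[1L])
         list(Z = Zv, Q = tau * parts$M,
              logdetQ = (k - 1) * theta[1L] + parts$logdetM)
       },
       theta_init = log(10), theta_lower = log(1e-3), theta_upper = log(1e6),
       theta_names = "log_tau_v",
       varcomp = function(theta) list(tau_v = exp(theta[1L])),
       map_effects = function(b)
         list(v = stats::setNames(as.numeric(parts$A %*% b), ids)))
}

#' BYM structure: IID plus intrinsic CAR cluster effects
#'
#' @inheritParams structure_car
#' @keywords internal
structure_bym <- function(cluster, ids, adj) {
  stopifnot(identical(adj$cluster_ids, ids))
  Zc <- cluster_indicator(cluster, ids)
  parts <- icar_parts(adj)
  Zv <- Zc %*% parts$A
  k <- length(ids)
  Z <- cbind(Zc, Zv)
  list(build = function(theta) {
         s2 <- exp(2 * theta[1L]); tau <- exp(theta[2L])
         list(Z = Z,
              Q = Matrix::bdiag(Matrix::Diagonal(k, 1 / s2), tau * parts$M),
              logdetQ = -2 * k * theta[1L] +
                (k - 1) * theta[2L] + parts$logdetM)
       },
       theta_init = c(log(0.2), log(10)),
       theta_lower = c(log(1e-4), log(1e-3)),
       theta_upper = c(log(5), log(1e6)),
       theta_names = c("log_sigma_u", "log_tau_v"),
       varcomp = function(theta) list(sigma_u = exp(theta[1L]),
                                      tau_v = exp(theta[2L])),
       map_effects = function(b) {
         u <- b[seq_len(k)]
         s <- b[(k + 1L):length(b)]
         list(u = stats::setNames(u, ids),
              v = stats::setNames(as.numeric(parts$A %*% s), ids))
       })
}

#' Gaussian-process structure: IID cluster effect plus a household-level
#' exponential-covariance field
#'
#' The field has covariance `sigma^2 * exp(-d / rho)` evaluated densely at
#' the household coordinates (its precision is a dense inverse, the design
#' an identity, keeping the Newton algebra sparse); theta is
#' `(log sigma_u, log sigma, log rho)`.
#'
#' @inheritParams structure_iid
#' @param coords two-column coordinate matrix for the rows.
#' @param rho_init initial correlation range in meters.
#' @keywords internal
structure_gp <- function(cluster, ids, coords, rho_init = NULL) {
  Zc <- cluster_indicator(cluster, ids)
  k <- length(ids)
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  if (is.null(rho_init)) rho_init <- stats::median(D)
  list(build = function(theta) {
         s2 <- exp(2 * theta[1L])
         sig <- exp(theta[2L]); rho <- exp(theta[3L])
         S <- exp_covariance(D, sig, rho) + diag(sig^2 * 1e-8 + 1e-10, n)
         cS <- chol(S)
         Qf <- chol2inv(cS)
         list(Z = cbind(Zc, Matrix::Diagonal(n)),
              Q = Matrix::bdiag(Matrix::Diagonal(k, 1 / s2),
                                Matrix::Matrix(Qf)),
              logdetQ = -2 * k * theta[1L] - 2 * sum(log(diag(cS))))
       },
       theta_init = c(log(0.2), log(0.2), log(rho_init)),
       theta_lower = c(log(1e-4), log(1e-4), log(1)),
       theta_upper = c(log(5), log(5), log(1e6)),
       theta_names = c("log_sigma_u", "log_gp_sigma", "log_gp_range"),
       varcomp = function(theta) list(sigma_u = exp(theta[1L]),
                                      gp_sigma = exp(theta[2L]),
                                      gp_range = exp(theta[3L])),
       map_effects = function(b) {
         list(u = stats::setNames(b[seq_len(k)], ids),
              field = b[(k + 1L):length(b)])
       })
}

#' Exponential covariance kernel
#'
#' `sigma^2 * exp(-d / rho)`: variance `sigma^2` at distance zero and
#' `exp(-1) * sigma^2` at the range `rho` (the Matern family at
#' smoothness 1/2).
#'
#' @param d distances in meters.
#' @param sigma field SD.
#' @param rho range in meters.
#' @return covariances.
#' @export
exp_covariance <- function(d, sigma, rho) sigma^2 * exp(-d / rho)
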