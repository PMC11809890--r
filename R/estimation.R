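# Marginal-likelihood machinery: Laplace approximation, adaptive
# Gauss-Hermite cross-check, and the quasi-Newton fitting loop.  The hot
# paths run on the precomputed likelihood context (likelihood-core.R).

# damped Newton mode search for all clusters simultaneously.
# Numeric curvature by central differences of the analytic gradient.
# Returns list(u, hess, iters); hess is the second-derivative information:
# d=1 a vector, d=2 an n x 3 matrix (h11, h22, h12).
.mode_search <- function(ctx, u_start = NULL, tol = 1e-10, maxit = 100) {
  nc <- ctx$nc
  d <- .re_dim(ctx$params)
  u <- if (!is.null(u_start)) u_start
       else if (d == 1L) rep(0, nc) else matrix(0, nc, 2)
  h <- 1e-4
  obj <- .ctx_obj(ctx, u)
  curv <- function(u) {
    if (d == 1L) {
      hess <- (.ctx_obj_grad(ctx, u + h) - .ctx_obj_grad(ctx, u - h)) /
        (2 * h)
      pmin(hess, -1e-10)
    } else {
      e1 <- cbind(rep(h, nc), 0); e2 <- cbind(0, rep(h, nc))
      gp1 <- (.ctx_obj_grad(ctx, u + e1) - .ctx_obj_grad(ctx, u - e1)) /
        (2 * h)
      gp2 <- (.ctx_obj_grad(ctx, u + e2) - .ctx_obj_grad(ctx, u - e2)) /
        (2 * h)
      cbind(gp1[, 1], gp2[, 2], (gp1[, 2] + gp2[, 1]) / 2)
    }
  }
  for (it in seq_len(maxit)) {
    g <- .ctx_obj_grad(ctx, u)
    if (max(abs(g)) < tol) break
    hess <- curv(u)
    if (d == 1L) {
      step <- -g / hess
    } else {
      h11 <- hess[, 1]; h22 <- hess[, 2]; h12 <- hess[, 3]
      det <- h11 * h22 - h12^2
      bad <- det <= 1e-12 | h11 >= 0
      h11[bad] <- -1; h22[bad] <- -1; h12[bad] <- 0
      det <- h11 * h22 - h12^2
      step <- -cbind((h22 * g[, 1] - h12 * g[, 2]) / det,
                     (h11 * g[, 2] - h12 * g[, 1]) / det)
    }
    # per-cluster step halving: never accept a decrease in the objective
    for (try in 1:30) {
      u_new <- u + step
      obj_new <- .ctx_obj(ctx, u_new)
      worse <- obj_new < obj - 1e-12
      if (!any(worse)) break
      if (d == 1L) step[worse] <- step[worse] / 2
      else step[worse, ] <- step[worse, , drop = FALSE] / 2
    }
    moved <- max(abs(step))
    u <- u_new; obj <- obj_new
    if (moved < 1e-12) break
  }
  g <- .ctx_obj_grad(ctx, u)
  if (it == maxit && max(abs(g)) > 1e-4)
    stop("random-effect mode search failed to converge (cluster index ",
         which.max(abs(g)), ")", call. = FALSE)
  list(u = u, hess = curv(u), iters = it)
}

.sigma_is_zero <- function(params) {
  max(params$sigma[seq_len(min(2, length(params$sigma)))]) < 1e-10
}

#' Laplace-approximated marginal log-likelihood
#'
#' Integrates the cluster random effects out of the joint likelihood by a
#' Laplace approximation: per cluster, the conditional log-likelihood
#' ([cluster_conditional_loglik()]) is maximised over u by damped Newton
#' iteration, and the integral is approximated by
#' \eqn{h(\hat u) + (d/2)\log 2\pi - \tfrac12 \log\det(-H(\hat u))},
#' with d the random-effect dimension.  When all random-effect scales are
#' zero the integral is degenerate and the fixed-effect log-likelihood is
#' returned exactly.
#'
#' @param params a [bivml_parameters()].
#' @param design a `bivml_design` from [encode_design()].
#' @param weighted apply unit weights to the data terms
#'   (pseudo-likelihood).
#' @param u_start optional warm start for the mode search.
#' @return scalar log-likelihood, with the modes attached as attribute
#'   `"modes"`.
#' @export
laplace_marginal_loglik <- function(params, design, weighted = FALSE,
                                    u_start = NULL) {
  nc <- length(design$cluster_levels)
  ctx <- .make_ctx(params, design, weighted)
  if (.sigma_is_zero(params)) {
    d <- .re_dim(params)
    u0 <- if (d == 1L) rep(0, nc) else matrix(0, nc, 2)
    return(structure(sum(.ctx_data_ll(ctx, u0)), modes = u0))
  }
  ms <- .mode_search(ctx, u_start)
  obj <- .ctx_obj(ctx, ms$u)
  d <- .re_dim(params)
  logdet <- if (d == 1L) log(-ms$hess)
            else log(ms$hess[, 1] * ms$hess[, 2] - ms$hess[, 3]^2)
  structure(sum(obj + (d / 2) * log(2 * pi) - 0.5 * logdet), modes = ms$u)
}

#' Adaptive Gauss-Hermite marginal log-likelihood
#'
#' Numerical cross-check for [laplace_marginal_loglik()]: Gauss-Hermite
#' quadrature with nodes recentred at the Laplace mode and rescaled by the
#' curvature there (tensor-product grid for two-dimensional structures).
#' One node reproduces the Laplace approximation exactly.
#'
#' @inheritParams laplace_marginal_loglik
#' @param nodes number of quadrature nodes per dimension (>= 1).
#' @return scalar log-likelihood.
#' @export
agq_marginal_loglik <- function(params, design, nodes = 15,
                                weighted = FALSE) {
  if (nodes < 1) stop("nodes must be >= 1")
  nc <- length(design$cluster_levels)
  if (.sigma_is_zero(params)) return(
    laplace_marginal_loglik(params, design, weighted))
  ctx <- .make_ctx(params, design, weighted)
  ms <- .mode_search(ctx)
  gh <- if (nodes == 1) list(x = 0, w = sqrt(pi))
        else pracma::gaussHermite(nodes)
  d <- .re_dim(params)
  if (d == 1L) {
    s <- 1 / sqrt(-ms$hess)                       # per-cluster scale
    logterms <- matrix(NA_real_, nc, nodes)
    for (k in seq_len(nodes)) {
      uk <- ms$u + sqrt(2) * s * gh$x[k]
      logterms[, k] <- log(gh$w[k]) + gh$x[k]^2 +
        .ctx_obj(ctx, uk)
    }
    m <- apply(logterms, 1, max)
    percl <- m + log(rowSums(exp(logterms - m))) + 0.5 * log(2) + log(s)
    sum(percl)
  } else {
    # A = -H per cluster; scale by A^{-1/2} from the 2x2 Cholesky
    h11 <- -ms$hess[, 1]; h22 <- -ms$hess[, 2]; h12 <- -ms$hess[, 3]
    l11 <- sqrt(h11); l21 <- h12 / l11; l22 <- sqrt(pmax(h22 - l21^2, 1e-12))
    grid <- expand.grid(i = seq_len(nodes), j = seq_len(nodes))
    logterms <- matrix(NA_real_, nc, nrow(grid))
    for (g in seq_len(nrow(grid))) {
      z1 <- gh$x[grid$i[g]]; z2 <- gh$x[grid$j[g]]
      # solve L' t = z  (back substitution), u = mode + sqrt(2) t
      t2 <- z2 / l22
      t1 <- (z1 - l21 * t2) / l11
      uk <- ms$u + sqrt(2) * cbind(t1, t2)
      logterms[, g] <- log(gh$w[grid$i[g]] * gh$w[grid$j[g]]) +
        z1^2 + z2^2 + .ctx_obj(ctx, uk)
    }
    m <- apply(logterms, 1, max)
    percl <- m + log(rowSums(exp(logterms - m))) + log(2) - log(l11 * l22)
    sum(percl)
  }
}

#' Latent-threshold intraclass correlation
#'
#' On the latent-logistic scale the unit-level residual variance is
#' pi^2/3 (= 3.2898..., conventionally displayed as 3.29), so the share of
#' latent variance attributable to clusters is
#' \eqn{ICC = \sigma^2 / (\sigma^2 + \pi^2/3)}.
#'
#' @param sigma2 cluster-level variance, >= 0.
#' @return ICC in [0, 1).
#' @export
icc <- function(sigma2) {
  if (any(sigma2 < 0)) stop("sigma2 must be >= 0", call. = FALSE)
  sigma2 / (sigma2 + pi^2 / 3)
}

#' Information criteria for a fitted model
#'
#' AIC = -2 loglik + 2 p.  For BIC the effective sample size of a
#' multilevel model is taken as the number of clusters (level-2 units) by
#' default, matching the convention of mixed-model software that counts
#' subjects rather than observations; switch with `bic_n = "units"`.
#'
#' @param loglik maximised log-likelihood.
#' @param p_count number of estimated parameters.
#' @param n_units,n_clusters sample sizes at the two levels.
#' @param bic_n which size enters the BIC penalty.
#' @return named vector `c(aic, bic)`.
#' @export
information_criteria <- function(loglik, p_count, n_units, n_clusters,
                                 bic_n = c("clusters", "units")) {
  bic_n <- match.arg(bic_n)
  n <- if (bic_n == "clusters") n_clusters else n_units
  c(aic = -2 * loglik + 2 * p_count,
    bic = -2 * loglik + p_count * log(n))
}
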